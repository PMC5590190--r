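#' Allele-fraction bins for sensitivity reporting
#'
#' The three conventional reporting bins: low (`<=10%`), intermediate
#' (`10-20%`) and high (`>=20%`) allele fraction. Edge handling: the
#' low bin is `(0, 0.10]`, the intermediate bin `(0.10, 0.20)`, the
#' high bin `[0.20, 1]`, so the bins partition `(0, 1]`.
#'
#' @return A `data.frame` with columns `label`, `lower`, `upper`,
#'   `lower_open`, `upper_open`.
#' @export
maf_bins <- function() {
  data.frame(
    label = c("<=10%", "10-20%", ">=20%"),
    lower = c(0, 0.10, 0.20),
    upper = c(0.10, 0.20, 1),
    lower_open = c(TRUE, TRUE, FALSE),
    upper_open = c(FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
}

#' Assign true allele fractions to reporting bins
#'
#' @param maf Numeric vector of true allele fractions in (0, 1].
#' @return Character vector of bin labels (see [maf_bins()]).
#' @export
assign_maf_bin <- function(maf) {
  bins <- maf_bins()
  out <- rep(NA_character_, length(maf))
  for (i in seq_len(nrow(bins))) {
    lo_ok <- if (bins$lower_open[i]) maf > bins$lower[i] else maf >= bins$lower[i]
    hi_ok <- if (bins$upper_open[i]) maf < bins$upper[i] else maf <= bins$upper[i]
    out[lo_ok & hi_ok] <- bins$label[i]
  }
  out
}

#' Sensitivity-versus-depth curve by in-silico downsampling
#'
#' Reproduces a depth-titration experiment: for each replicate and each
#' grid depth, every full-depth pileup is downsampled to that depth
#' (sampling reads without replacement), the filter cascade is run, and
#' the fraction of truth variants called PASS is recorded per
#' allele-fraction bin (binned by *true* fraction) and pooled. The
#' sensitivity reported is the mean over replicates with its standard
#' error (s.e.m.).
#'
#' @param truth A truth `data.frame`; rows correspond one-to-one with
#'   `pileup`.
#' @param pileup Full-depth pileups for the truth set; every site's
#'   depth must reach `max(depth_grid)`.
#' @param depth_grid Integer vector of target depths (x).
#' @param replicates Number of downsampling replicates.
#' @param thresholds A [call_thresholds()] object.
#' @param seed Integer seed; replicate `r` uses child seed
#'   `derive_seed(seed, r)`.
#' @return A `sensitivity_curve` `data.frame`: `depth`, `bin`
#'   (including `"overall"`), `sensitivity`, `sem`, `n_true`.
#' @export
sensitivity_by_depth <- function(truth, pileup, depth_grid,
                                 replicates = 10L,
                                 thresholds = call_thresholds(),
                                 seed = NULL) {
  stopifnot(nrow(truth) == nrow(pileup), length(depth_grid) >= 1L)
  d <- pileup_depth(pileup)
  if (max(depth_grid) > min(d)) {
    stop("depth_grid entry ", max(depth_grid),
         " exceeds available depth (min ", min(d), ")")
  }
  if (replicates == 1L) {
    warning("replicates = 1: s.e.m. reported as 0")
  }
  bin <- assign_maf_bin(truth$true_maf)
  labels <- c(maf_bins()$label, "overall")
  # sens[replicate, depth, bin]
  sens <- array(NA_real_, c(replicates, length(depth_grid), length(labels)),
                dimnames = list(NULL, depth_grid, labels))
  for (r in seq_len(replicates)) {
    if (!is.null(seed)) set.seed(derive_seed(seed, r))
    for (di in seq_along(depth_grid)) {
      ds <- downsample_pileup(pileup, depth_grid[di])
      calls <- apply_filters(ds, thresholds)
      for (lab in labels) {
        sel <- if (lab == "overall") rep(TRUE, nrow(truth)) else bin == lab
        if (any(sel)) sens[r, di, lab] <- mean(calls$pass[sel])
      }
    }
  }
  rows <- expand.grid(depth = depth_grid, bin = labels,
                      stringsAsFactors = FALSE)
  rows$sensitivity <- NA_real_
  rows$sem <- NA_real_
  rows$n_true <- NA_integer_
  for (i in seq_len(nrow(rows))) {
    v <- sens[, as.character(rows$depth[i]), rows$bin[i]]
    rows$sensitivity[i] <- mean(v)
    rows$sem[i] <- if (replicates > 1L) stats::sd(v) / sqrt(replicates) else 0
    rows$n_true[i] <- if (rows$bin[i] == "overall") length(bin) else
      sum(bin == rows$bin[i])
  }
  rows <- rows[!is.na(rows$sensitivity), , drop = FALSE]
  rownames(rows) <- NULL
  structure(rows, class = c("sensitivity_curve", "data.frame"),
            replicates = replicates)
}

#' @export
print.sensitivity_curve <- function(x, ...) {
  cat("Sensitivity curve (", attr(x, "replicates"), " replicate(s)):\n",
      sep = "")
  print.data.frame(as.data.frame(x), digits = 4)
  invisible(x)
}

#' @export
plot.sensitivity_curve <- function(x, ...) {
  bins <- unique(x$bin)
  cols <- seq_along(bins)
  plot(NA, xlim = range(x$depth), ylim = c(0, 1),
       xlab = "Coverage (x)", ylab = "Sensitivity", ...)
  for (i in seq_along(bins)) {
    b <- x[x$bin == bins[i], ]
    graphics::lines(b$depth, b$sensitivity, col = cols[i], type = "b", pch = 16)
    graphics::arrows(b$depth, b$sensitivity - b$sem,
                     b$depth, b$sensitivity + b$sem,
                     angle = 90, code = 3, length = 0.03, col = cols[i])
  }
  graphics::legend("bottomright", legend = bins, col = cols, lty = 1, pch = 16)
  invisible(x)
}

#' Plateau depth of a sensitivity curve
#'
#' The smallest grid depth at which sensitivity is within `epsilon` of
#' the curve's maximum over the grid, per bin.
#'
#' @param curve A `sensitivity_curve` object.
#' @param epsilon Tolerance below the maximum still counted as
#'   plateaued.
#' @return A `data.frame` with columns `bin`, `plateau_depth`,
#'   `max_sensitivity`.
#' @export
find_plateau <- function(curve, epsilon = 0.002) {
  stopifnot(nrow(curve) > 0L)
  bins <- unique(curve$bin)
  res <- lapply(bins, function(b) {
    cc <- curve[curve$bin == b, ]
    cc <- cc[order(cc$depth), ]
    mx <- max(cc$sensitivity)
    data.frame(bin = b,
               plateau_depth = cc$depth[which(cc$sensitivity >= mx - epsilon)[1L]],
               max_sensitivity = mx, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Copy-number limit of detection over a purity dilution series
#'
#' Emulates diluting a tumor cell line with its matched normal: at each
#' purity in the grid the coverage is simulated, the full copy-number
#' pipeline is run, and per-gene amplification detection is recorded.
#' The limit of detection per gene is the lowest purity at which the
#' amplification is still called.
#'
#' @param panel A `panel` object with `gc_fraction` set.
#' @param amplicons Amplicon specification (see [simulate_coverage()]).
#' @param purity_grid Strictly decreasing purity grid.
#' @param depth Expected reads per region (see [simulate_coverage()]).
#' @param seed Integer seed; purity step `i` uses
#'   `derive_seed(seed, i)`.
#' @param ... Passed to [call_cnv()] (`lambda`, `cn_threshold`,
#'   `min_log2`, `n_strata`).
#' @return A `dilution_result` list: `detection` (gene x purity logical
#'   `data.frame`) and `lod` (named numeric, `NA` when never
#'   detected).
#' @export
dilution_lod <- function(panel, amplicons,
                         purity_grid = c(0.5, 0.4, 0.3, 0.2, 0.1),
                         depth = 2000, seed = NULL, ...) {
  stopifnot(nrow(amplicons) > 0L)
  if (any(diff(purity_grid) >= 0)) stop("purity_grid must be strictly decreasing")
  det <- matrix(FALSE, nrow(amplicons), length(purity_grid),
                dimnames = list(amplicons$gene, purity_grid))
  for (i in seq_along(purity_grid)) {
    p <- purity_grid[i]
    cov <- simulate_coverage(panel, amplicons, purity = p, depth = depth,
                             seed = if (is.null(seed)) NULL else derive_seed(seed, i))
    if (p == 0) next  # no tumor content: nothing detectable
    seg <- suppressMessages(call_cnv(cov, purity = p, ...))
    st <- gene_amplification(seg, cov)
    det[, i] <- st$amplified[match(amplicons$gene, st$gene)]
  }
  lod <- apply(det, 1L, function(row) {
    hit <- which(row)
    if (length(hit)) purity_grid[max(hit)] else NA_real_
  })
  structure(list(detection = as.data.frame(det), lod = lod,
                 purity_grid = purity_grid),
            class = "dilution_result")
}

#' @export
print.dilution_result <- function(x, ...) {
  cat("Amplification detection across the purity dilution series:\n")
  print(x$detection)
  cat("Limit of detection (lowest purity detected):\n")
  print(x$lod)
  invisible(x)
}

#' Concordance of NGS calls against an orthogonal assay
#'
#' Builds the 2x2 table of per-sample binary calls and reports
#' sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, PPV
#' `tp/(tp+fp)`, NPV `tn/(tn+fn)` and overall agreement, each with its
#' exact count fraction. In `paper_mode`, the headline "specificity" is
#' the PPV — the convention used when every compared sample is
#' NGS-positive and the orthogonal assay confirms the calls — and both
#' definitions remain in the output.
#'
#' @param ngs_calls,orthogonal_labels `data.frame`s with columns
#'   `sample` and `positive` (logical), or named logical vectors. The
#'   sample sets must match.
#' @param paper_mode Report PPV under the `specificity` headline.
#' @return A `concordance_result` list with counts, rates (fractions
#'   in \[0, 1\]), percent values, and exact fraction strings.
#' @export
concordance <- function(ngs_calls, orthogonal_labels, paper_mode = FALSE) {
  as_df <- function(x) {
    if (is.data.frame(x)) {
      stopifnot(all(c("sample", "positive") %in% names(x)))
      x
    } else {
      data.frame(sample = names(x), positive = as.logical(x),
                 stringsAsFactors = FALSE)
    }
  }
  ngs <- as_df(ngs_calls)
  ort <- as_df(orthogonal_labels)
  only_ngs <- setdiff(ngs$sample, ort$sample)
  only_ort <- setdiff(ort$sample, ngs$sample)
  if (length(only_ngs) || length(only_ort)) {
    stop("sample sets differ; only in NGS: {",
         paste(only_ngs, collapse = ", "), "}; only in orthogonal: {",
         paste(only_ort, collapse = ", "), "}")
  }
  m <- match(ort$sample, ngs$sample)
  n_pos <- ngs$positive[m]
  o_pos <- ort$positive
  tp <- sum(n_pos & o_pos); fp <- sum(n_pos & !o_pos)
  fn <- sum(!n_pos & o_pos); tn <- sum(!n_pos & !o_pos)
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  frac <- function(num, den) paste0(num, "/", den)
  res <- list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = rate(tp, tp + fn),
    specificity = if (paper_mode) rate(tp, tp + fp) else rate(tn, tn + fp),
    specificity_standard = rate(tn, tn + fp),
    ppv = rate(tp, tp + fp),
    npv = rate(tn, tn + fn),
    agreement = rate(tp + tn, tp + fp + fn + tn),
    fractions = c(sensitivity = frac(tp, tp + fn),
                  specificity = if (paper_mode) frac(tp, tp + fp) else frac(tn, tn + fp),
                  ppv = frac(tp, tp + fp),
                  npv = frac(tn, tn + fn),
                  agreement = frac(tp + tn, tp + fp + fn + tn)),
    paper_mode = paper_mode)
  res$sensitivity_pct <- 100 * res$sensitivity
  res$specificity_pct <- 100 * res$specificity
  res$agreement_pct <- 100 * res$agreement
  structure(res, class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("2x2 concordance (NGS vs orthogonal):\n")
  cat(sprintf("  TP %d  FP %d  FN %d  TN %d\n", x$tp, x$fp, x$fn, x$tn))
  fmt <- function(v, f) if (is.na(v)) "NA" else
    sprintf("%.1f%% (%s)", 100 * v, f)
  cat("  sensitivity:", fmt(x$sensitivity, x$fractions["sensitivity"]), "\n")
  cat("  specificity:", fmt(x$specificity, x$fractions["specificity"]),
      if (x$paper_mode) " [PPV convention]" else "", "\n")
  cat("  agreement:  ", fmt(x$agreement, x$fractions["agreement"]), "\n")
  invisible(x)
}
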