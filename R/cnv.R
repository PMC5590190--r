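#' Matched-normal log2-ratio coverage profile
#'
#' Library-size-normalizes tumor and matched-normal read counts per
#' target region and takes `log2((tumor/T) / (normal/N))`, where `T`
#' and `N` are the total tumor and normal counts. Bins with zero normal
#' coverage carry no ratio information and are masked rather than
#' imputed; their count is recorded in the `n_masked` attribute.
#'
#' @param bins A coverage `data.frame` (see [simulate_coverage()]):
#'   columns `chrom`, `start`, `end`, `gene`, `gc_fraction`,
#'   `tumor_count`, `normal_count`, one row per target region.
#' @return The bins with columns `log2_ratio` and `masked` added.
#' @export
log2_ratio_profile <- function(bins) {
  need <- c("chrom", "start", "end", "tumor_count", "normal_count")
  if (!all(need %in% names(bins))) {
    stop("coverage bins must have columns: ", paste(need, collapse = ", "))
  }
  if (any(bins$tumor_count < 0 | bins$normal_count < 0)) {
    stop("negative read counts")
  }
  masked <- bins$normal_count == 0L
  t_tot <- sum(bins$tumor_count[!masked])
  n_tot <- sum(bins$normal_count[!masked])
  if (t_tot == 0 || n_tot == 0) stop("no usable coverage in tumor or normal")
  lr <- rep(NA_real_, nrow(bins))
  lr[!masked] <- log2((bins$tumor_count[!masked] / t_tot) /
                        (bins$normal_count[!masked] / n_tot))
  lr[!masked][bins$tumor_count[!masked] == 0L] <- -Inf
  bins$log2_ratio <- lr
  bins$masked <- masked
  if (any(masked)) {
    message("log2_ratio_profile: masked ", sum(masked),
            " bin(s) with zero normal coverage")
  }
  attr(bins, "n_masked") <- sum(masked)
  bins
}

#' GC-bias correction of a log2-ratio profile
#'
#' Capture efficiency depends on region GC content; any residual
#' difference between tumor and normal library preparation shows up as
#' a GC-dependent trend in the log2 ratio. The correction subtracts,
#' per GC stratum (equal-width strata on \[0, 1\]), the stratum median
#' log2 ratio computed over putatively neutral bins, so the corrected
#' neutral profile is centred at zero per stratum. Strata holding fewer
#' than `min_stratum` usable bins fall back to the global median.
#'
#' @param bins Output of [log2_ratio_profile()]; `gc_fraction` must be
#'   present.
#' @param n_strata Number of equal-width GC strata.
#' @param min_stratum Minimum bins per stratum before falling back to
#'   the global median.
#' @param neutral Logical vector marking bins assumed copy-neutral for
#'   estimating the trend; default all unmasked bins (the median is
#'   robust to a minority of amplified bins).
#' @return The bins with `log2_ratio` replaced by its corrected value
#'   (original kept as `log2_ratio_raw`).
#' @export
gc_correct <- function(bins, n_strata = 20L, min_stratum = 5L,
                       neutral = NULL) {
  if (is.null(bins$gc_fraction) || anyNA(bins$gc_fraction)) {
    stop("gc_fraction must be present on every bin")
  }
  if (is.null(bins$log2_ratio)) stop("run log2_ratio_profile() first")
  if (is.null(neutral)) neutral <- !bins$masked
  usable <- !bins$masked & is.finite(bins$log2_ratio)
  est <- usable & neutral
  stratum <- pmin(pmax(ceiling(bins$gc_fraction * n_strata), 1L), n_strata)
  global_med <- stats::median(bins$log2_ratio[est])
  offset <- rep(global_med, nrow(bins))
  fell_back <- 0L
  for (s in unique(stratum)) {
    in_s <- stratum == s
    if (sum(in_s & est) >= min_stratum) {
      offset[in_s] <- stats::median(bins$log2_ratio[in_s & est])
    } else {
      fell_back <- fell_back + 1L
    }
  }
  if (fell_back > 0L) {
    message("gc_correct: ", fell_back,
            " stratum/strata below ", min_stratum,
            " bins; used global median")
  }
  bins$log2_ratio_raw <- bins$log2_ratio
  bins$log2_ratio <- bins$log2_ratio - offset
  bins
}

#' BIC-guided segmentation of a log2-ratio profile
#'
#' Agglomerative merging under the Bayesian Information Criterion of a
#' piecewise-constant Gaussian model on the log2 ratios:
#' `BIC = RSS / sigma^2 + lambda * k * log(n)` with `k` segments over
#' `n` bins, where the noise scale `sigma` is held fixed at a robust
#' estimate from first differences of the profile (the usual profiled
#' variance `n * log(RSS/n)` is degenerate at the one-bin-per-segment
#' start, where RSS is identically zero). Starting from one segment
#' per bin, the adjacent pair whose merge most decreases the BIC is
#' merged until no merge decreases it (ties broken by the leftmost
#' pair); a merge therefore happens when it raises the residual sum of
#' squares by less than `lambda * sigma^2 * log(n)`. Segmentation
#' never crosses a chromosome boundary and is deterministic.
#'
#' @param bins Output of [gc_correct()] (or [log2_ratio_profile()]),
#'   ordered by `(chrom, start)`; masked bins are dropped.
#' @param lambda Penalty multiplier on the model-size term.
#' @param sigma Noise scale of the per-bin log2 ratios; `NULL`
#'   (default) estimates it robustly from first differences over the
#'   whole profile. Supply the scale explicitly to re-segment derived
#'   profiles (such as segment means) whose bin-to-bin differences are
#'   dominated by true copy-number jumps rather than noise.
#' @return A `cnv_segments` `data.frame`: `chrom`, `start`, `end`,
#'   `n_bins`, `mean_log2`; the noise scale used is stored in the
#'   `sigma` attribute.
#' @export
bic_segment <- function(bins, lambda = 2, sigma = NULL) {
  bins <- bins[!bins$masked & is.finite(bins$log2_ratio), , drop = FALSE]
  if (is.null(sigma)) {
    # robust sigma from first differences within chromosomes (a diff
    # of neighbouring same-level bins has variance 2*sigma^2)
    dd <- unlist(lapply(split(bins$log2_ratio, bins$chrom), diff),
                 use.names = FALSE)
    sigma <- if (length(dd)) {
      stats::median(abs(dd)) / (0.6744898 * sqrt(2))
    } else 0
  }
  # floored so a noiseless profile still merges its zero-cost pairs
  sigma2 <- max(sigma^2, 1e-12)
  out <- list()
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    out[[ch]] <- segment_one_chrom(b, lambda, sigma2)
  }
  seg <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               n_bins = integer(), mean_log2 = numeric())
  rownames(seg) <- NULL
  structure(seg, class = c("cnv_segments", "data.frame"), sigma = sqrt(sigma2))
}

segment_one_chrom <- function(b, lambda, sigma2) {
  m <- nrow(b)
  x <- b$log2_ratio
  # per-segment sufficient statistics
  n_i <- rep(1, m); s_i <- x; q_i <- x^2
  start_i <- b$start; end_i <- b$end
  n <- m
  repeat {
    k <- length(n_i)
    if (k <= 1L) break
    rss_i <- pmax(q_i - s_i^2 / n_i, 0)
    # merge cost for each adjacent pair
    nn <- n_i[-k] + n_i[-1L]
    ss <- s_i[-k] + s_i[-1L]
    qq <- q_i[-k] + q_i[-1L]
    rss_pair_new <- pmax(qq - ss^2 / nn, 0)
    d_rss <- rss_pair_new - rss_i[-k] - rss_i[-1L]
    d_bic <- d_rss / sigma2 - lambda * log(n)
    j <- which.min(d_bic)
    if (d_bic[j] >= 0) break
    n_i <- c(n_i[seq_len(j - 1L)], nn[j], n_i[seq(j + 2L, length.out = k - j - 1L)])
    s_i <- c(s_i[seq_len(j - 1L)], ss[j], s_i[seq(j + 2L, length.out = k - j - 1L)])
    q_i <- c(q_i[seq_len(j - 1L)], qq[j], q_i[seq(j + 2L, length.out = k - j - 1L)])
    start_i <- c(start_i[seq_len(j - 1L)], start_i[j],
                 start_i[seq(j + 2L, length.out = k - j - 1L)])
    end_i <- c(end_i[seq_len(j - 1L)], end_i[j + 1L],
               end_i[seq(j + 2L, length.out = k - j - 1L)])
  }
  data.frame(chrom = b$chrom[1L], start = start_i, end = end_i,
             n_bins = as.integer(n_i), mean_log2 = s_i / n_i,
             stringsAsFactors = FALSE)
}

#' Purity-aware amplification call on segments
#'
#' Inverts the purity mixing identity. A tumor sample with purity `p`
#' and tumor copy number `CN_t` has expected observed copy number
#' `p * CN_t + 2 * (1 - p)` against a diploid normal, so
#' `mean_log2 = log2((p * CN_t + 2 * (1 - p)) / 2)` and the inferred
#' tumor copy number is
#' `(2 * 2^mean_log2 - 2 * (1 - p)) / p`.
#' A segment is flagged amplified when the inferred tumor copy number
#' reaches `cn_threshold` (within half a copy, absorbing estimation
#' noise) **and** the observed ratio clears the detectability floor
#' `min_log2` — below that floor the diluted signal is within baseline
#' noise regardless of the purity-corrected value, which is what makes
#' low-level amplifications undetectable in low-purity specimens.
#'
#' @param segments A `cnv_segments` `data.frame`.
#' @param purity Tumor cell fraction in (0, 1].
#' @param cn_threshold Tumor copy number at or above which a segment is
#'   amplified.
#' @param min_log2 Minimum observed (GC-corrected) segment log2 ratio.
#' @return The segments with `inferred_tumor_cn` and `amplified` added.
#' @export
call_amplification <- function(segments, purity, cn_threshold = 4,
                               min_log2 = 0.3) {
  if (purity <= 0) stop("tumor copy number is unidentifiable at purity 0")
  if (purity > 1) stop("purity must lie in (0, 1]")
  cn <- (2 * 2^segments$mean_log2 - 2 * (1 - purity)) / purity
  segments$inferred_tumor_cn <- cn
  segments$amplified <- cn >= cn_threshold - 0.5 &
    segments$mean_log2 >= min_log2
  segments
}

#' Full copy-number pipeline on a coverage table
#'
#' Ratio profile, GC correction, BIC segmentation, and purity-aware
#' amplification calling in one call.
#'
#' @param coverage A coverage `data.frame`.
#' @param purity Tumor cell fraction in (0, 1].
#' @param lambda Segmentation penalty (see [bic_segment()]).
#' @param cn_threshold,min_log2 Amplification call parameters (see
#'   [call_amplification()]).
#' @param n_strata GC strata (see [gc_correct()]).
#' @return A `cnv_segments` `data.frame` with amplification calls.
#' @export
call_cnv <- function(coverage, purity, lambda = 2, cn_threshold = 4,
                     min_log2 = 0.3, n_strata = 20L) {
  prof <- log2_ratio_profile(coverage)
  prof <- gc_correct(prof, n_strata = n_strata)
  seg <- bic_segment(prof, lambda = lambda)
  call_amplification(seg, purity, cn_threshold = cn_threshold,
                     min_log2 = min_log2)
}

#' @export
print.cnv_segments <- function(x, ...) {
  cat("Copy-number segments: ", nrow(x), " segment(s)", sep = "")
  if ("amplified" %in% names(x)) cat(", ", sum(x$amplified), " amplified", sep = "")
  cat("\n")
  print.data.frame(as.data.frame(x))
  invisible(x)
}

# Gene-level amplification status: a gene is detected when at least
# half of its bins lie inside amplified segments.
gene_amplification <- function(segments, coverage) {
  genes <- unique(coverage$gene[!is.na(coverage$gene)])
  amp <- segments[segments$amplified, , drop = FALSE]
  detected <- vapply(genes, function(g) {
    b <- coverage[!is.na(coverage$gene) & coverage$gene == g, , drop = FALSE]
    if (!nrow(b)) return(FALSE)
    inside <- vapply(seq_len(nrow(b)), function(i) {
      any(amp$chrom == b$chrom[i] & amp$start <= b$start[i] &
            amp$end >= b$end[i])
    }, logical(1L))
    mean(inside) >= 0.5
  }, logical(1L))
  data.frame(gene = genes, amplified = unname(detected),
             stringsAsFactors = FALSE)
}
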