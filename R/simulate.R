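#' Allele-fraction spectrum models for simulated truth sets
#'
#' The generator supports four spectra:
#' \describe{
#'   \item{`germline_pool`}{pooled germline DNA from diploid cell lines:
#'     heterozygous SNPs mixed across a pool of up to 10 lines give the
#'     discrete fractions 0.05, 0.10, ..., 1.00, drawn uniformly —
#'     a broad 5-100\% spectrum.}
#'   \item{`cellline_pool`}{pooled cancer cell lines, where subclonal
#'     somatic variants concentrate at low fractions: Beta(1.2, 12)
#'     truncated to \[0.01, 1\], which puts about 97.5\% of its mass
#'     below 0.30.}
#'   \item{`uniform`}{uniform on `[lo, hi]`.}
#'   \item{`fixed`}{every variant at fraction `value`.}
#' }
#'
#' @param kind One of `"germline_pool"`, `"cellline_pool"`, `"uniform"`,
#'   `"fixed"`.
#' @param lo,hi Bounds for `kind = "uniform"`.
#' @param value Fraction for `kind = "fixed"`.
#' @return A `maf_model` object.
#' @export
maf_model <- function(kind = c("cellline_pool", "germline_pool", "uniform", "fixed"),
                      lo = 0.05, hi = 1, value = 0.5) {
  kind <- match.arg(kind)
  if (kind == "uniform" && !(lo > 0 && lo < hi && hi <= 1)) {
    stop("uniform maf_model requires 0 < lo < hi <= 1")
  }
  if (kind == "fixed" && !(value > 0 && value <= 1)) {
    stop("fixed maf_model requires value in (0, 1]")
  }
  structure(list(kind = kind, lo = lo, hi = hi, value = value),
            class = "maf_model")
}

draw_maf <- function(model, n) {
  switch(model$kind,
    germline_pool = sample(seq(0.05, 1, by = 0.05), n, replace = TRUE),
    cellline_pool = {
      # truncated Beta(1.2, 12) via inverse-CDF so draws are one-to-one
      # with the uniform stream (stable under vector length changes)
      plo <- stats::pbeta(0.01, 1.2, 12)
      stats::qbeta(plo + stats::runif(n) * (1 - plo), 1.2, 12)
    },
    uniform = stats::runif(n, model$lo, model$hi),
    fixed = rep(model$value, n)
  )
}

#' Simulate a ground-truth variant set over a panel
#'
#' Draws variant positions uniformly over the panel's bases without
#' replacement and allele fractions from the chosen spectrum model.
#' Deterministic given `seed`.
#'
#' @param panel A `panel` object.
#' @param n_snv,n_indel Numbers of SNVs and indels to place.
#' @param model A [maf_model()] (used for both kinds).
#' @param hotspot_frac Fraction of SNVs flagged as hotspots.
#' @param repeat_frac Fraction of indels flagged as lying in repeats.
#' @param seed Integer seed; `NULL` leaves the RNG stream untouched.
#' @return A truth `data.frame` (see [read_truth()] for columns).
#' @export
simulate_truth <- function(panel, n_snv, n_indel = 0L,
                           model = maf_model("cellline_pool"),
                           hotspot_frac = 0, repeat_frac = 0, seed = NULL) {
  stopifnot(inherits(panel, "panel"), n_snv >= 0, n_indel >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- n_snv + n_indel
  widths <- panel$end - panel$start
  total <- sum(widths)
  if (n > total) stop("requested ", n, " variants but panel spans only ",
                      total, " bases")
  offs <- sort(sample.int(total, n))
  cum <- cumsum(widths)
  reg <- findInterval(offs - 1L, c(0L, cum), rightmost.closed = FALSE)
  pos <- panel$start[reg] + (offs - 1L - c(0L, cum)[reg])
  kind <- c(rep("SNV", n_snv), rep("indel", n_indel))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  if (n_indel > 0L) {
    ins <- sample(c(TRUE, FALSE), n_indel, replace = TRUE)
    extra <- vapply(seq_len(n_indel), function(i)
      paste(sample(bases, sample(1:6, 1L), replace = TRUE), collapse = ""), "")
    idx <- n_snv + seq_len(n_indel)
    ref[idx] <- ifelse(ins, ref[idx], paste0(ref[idx], extra))
    alt[idx] <- ifelse(ins, paste0(ref[idx], extra), substr(ref[idx], 1L, 1L))
  }
  maf <- draw_maf(model, n)
  is_hot <- logical(n)
  if (n_snv > 0L && hotspot_frac > 0) {
    is_hot[seq_len(n_snv)] <- stats::runif(n_snv) < hotspot_frac
  }
  in_rep <- logical(n)
  if (n_indel > 0L && repeat_frac > 0) {
    in_rep[n_snv + seq_len(n_indel)] <- stats::runif(n_indel) < repeat_frac
  }
  validate_truth(data.frame(
    chrom = panel$chrom[reg], pos = pos, ref = ref, alt = alt,
    var_kind = kind, true_maf = maf, is_hotspot = is_hot,
    in_repeat = in_rep, stringsAsFactors = FALSE))
}

#' Simulate stranded tumor/normal pileups for a truth set
#'
#' The read-level sequencing process is abstracted to counts: total
#' depth per site is Poisson around the nominal coverage (or held fixed
#' with `depth_model = "fixed"`), the alt count is Binomial(depth,
#' true_maf), strand assignment is Binomial with forward probability
#' `strand_prob`, and the matched normal is generated the same way with
#' allele fraction `error_rate` (background sequencing error).
#' Deterministic given `seed`; vectorised over truth rows.
#'
#' @param truth A truth `data.frame`.
#' @param depth Nominal coverage (x).
#' @param error_rate Background alt fraction of the matched normal
#'   (must be < 0.01).
#' @param strand_prob Expected fraction of reads on the forward strand.
#' @param depth_model `"poisson"` (default) or `"fixed"` (exact depth).
#' @param normal_depth Nominal matched-normal coverage; defaults to
#'   `depth`.
#' @param seed Integer seed; `NULL` leaves the RNG stream untouched.
#' @return A pileup `data.frame` with columns `chrom`, `pos`, `ref`,
#'   `alt`, `alt_fwd`, `alt_rev`, `ref_fwd`, `ref_rev`, `normal_alt`,
#'   `normal_depth`, plus the truth annotation columns `var_kind`,
#'   `is_hotspot`, `in_repeat`, `true_maf`.
#' @export
simulate_pileup <- function(truth, depth, error_rate = 0.001,
                            strand_prob = 0.5,
                            depth_model = c("poisson", "fixed"),
                            normal_depth = depth, seed = NULL) {
  depth_model <- match.arg(depth_model)
  stopifnot(depth >= 0, error_rate >= 0, error_rate < 0.01,
            strand_prob >= 0, strand_prob <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(truth)
  d <- if (depth_model == "poisson") stats::rpois(n, depth) else rep(as.integer(round(depth)), n)
  alt <- stats::rbinom(n, d, truth$true_maf)
  ref <- d - alt
  alt_fwd <- stats::rbinom(n, alt, strand_prob)
  ref_fwd <- stats::rbinom(n, ref, strand_prob)
  nd <- if (depth_model == "poisson") stats::rpois(n, normal_depth) else rep(as.integer(round(normal_depth)), n)
  nalt <- stats::rbinom(n, nd, error_rate)
  data.frame(
    chrom = truth$chrom, pos = truth$pos, ref = truth$ref, alt = truth$alt,
    alt_fwd = alt_fwd, alt_rev = alt - alt_fwd,
    ref_fwd = ref_fwd, ref_rev = ref - ref_fwd,
    normal_alt = nalt, normal_depth = nd,
    var_kind = truth$var_kind, is_hotspot = truth$is_hotspot,
    in_repeat = truth$in_repeat, true_maf = truth$true_maf,
    stringsAsFactors = FALSE)
}

pileup_depth <- function(pileup) {
  pileup$alt_fwd + pileup$alt_rev + pileup$ref_fwd + pileup$ref_rev
}

#' Downsample pileups to a target depth
#'
#' Emulates in-silico depth titration: `target_depth` reads are drawn
#' without replacement from each site's original read multiset
#' (hypergeometric draw of alt versus ref, then of forward versus
#' reverse within each class), so the expected allele fraction is
#' preserved. Tumor counts only; the matched-normal columns pass
#' through unchanged.
#'
#' @param pileup A pileup `data.frame`.
#' @param target_depth Target coverage; must not exceed any site's
#'   depth.
#' @param seed Integer seed; `NULL` leaves the RNG stream untouched.
#' @return The pileup with tumor counts downsampled.
#' @export
downsample_pileup <- function(pileup, target_depth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- pileup_depth(pileup)
  if (any(target_depth > d)) {
    stop("target_depth ", target_depth, " exceeds available depth (min ",
         min(d), ")")
  }
  n <- nrow(pileup)
  alt <- pileup$alt_fwd + pileup$alt_rev
  ref <- pileup$ref_fwd + pileup$ref_rev
  new_alt <- stats::rhyper(n, alt, ref, target_depth)
  new_ref <- target_depth - new_alt
  new_alt_fwd <- stats::rhyper(n, pileup$alt_fwd, pileup$alt_rev, new_alt)
  new_ref_fwd <- stats::rhyper(n, pileup$ref_fwd, pileup$ref_rev, new_ref)
  out <- pileup
  out$alt_fwd <- new_alt_fwd
  out$alt_rev <- new_alt - new_alt_fwd
  out$ref_fwd <- new_ref_fwd
  out$ref_rev <- new_ref - new_ref_fwd
  out
}

# Unimodal capture-efficiency weight in GC fraction; maximal at 0.5,
# down to 0.5 at the extremes.
gc_weight <- function(gc) 1 - 2 * (gc - 0.5)^2

#' Simulate paired tumor/normal coverage over a panel
#'
#' Emulates a tumor-purity dilution experiment: the tumor sample is a
#' mixture of `purity` tumor cells (carrying the amplified copy numbers
#' in `amplicons`) and `1 - purity` normal diploid cells. The expected
#' tumor read count per target region is
#' `depth * (purity * CN + 2 * (1 - purity)) / 2 * gc_weight(gc)` and
#' counts are Poisson; the matched normal uses copy number 2 with the
#' same GC weight (set `gc_decouple = TRUE` to apply GC bias to the
#' tumor only, leaving it for the correction step to remove).
#'
#' @param panel A `panel` object with `gc_fraction` set.
#' @param amplicons `data.frame` with columns `gene`,
#'   `tumor_copy_number` (integer >= 2); genes must exist in the panel.
#' @param purity Tumor cell fraction in \[0, 1\].
#' @param depth Expected read count per region at copy number 2 and
#'   neutral GC.
#' @param gc_decouple Apply GC weight to tumor only (default `FALSE`).
#' @param seed Integer seed; `NULL` leaves the RNG stream untouched.
#' @return A coverage `data.frame`: `chrom`, `start`, `end`, `gene`,
#'   `gc_fraction`, `tumor_count`, `normal_count`.
#' @export
simulate_coverage <- function(panel, amplicons, purity, depth = 500,
                              gc_decouple = FALSE, seed = NULL) {
  stopifnot(inherits(panel, "panel"), purity >= 0, purity <= 1, depth >= 0)
  if (nrow(amplicons)) {
    stopifnot(all(c("gene", "tumor_copy_number") %in% names(amplicons)))
    if (any(amplicons$tumor_copy_number < 2)) {
      stop("tumor_copy_number must be >= 2")
    }
    missing <- setdiff(amplicons$gene, panel$gene)
    if (length(missing)) {
      stop("amplicon gene(s) absent from panel: ",
           paste(missing, collapse = ", "))
    }
  }
  if (!is.null(seed)) set.seed(seed)
  cn <- rep(2, nrow(panel))
  if (nrow(amplicons)) {
    m <- match(panel$gene, amplicons$gene)
    cn[!is.na(m)] <- amplicons$tumor_copy_number[m[!is.na(m)]]
  }
  gcw <- gc_weight(panel$gc_fraction)
  mu_t <- depth * (purity * cn + 2 * (1 - purity)) / 2 * gcw
  mu_n <- depth * (if (gc_decouple) 1 else gcw)
  data.frame(
    chrom = panel$chrom, start = panel$start, end = panel$end,
    gene = panel$gene, gc_fraction = panel$gc_fraction,
    tumor_count = stats::rpois(nrow(panel), mu_t),
    normal_count = stats::rpois(nrow(panel), mu_n),
    stringsAsFactors = FALSE)
}

#' Simulate read pairs around a rearrangement junction
#'
#' Emits `n_split` pairs whose first read is soft-clipped exactly at
#' breakpoint A (with the mate just across the junction on side B),
#' `n_discordant` pairs whose mates straddle the junction without
#' clipping, and `n_background` concordant pairs near side A. Breakpoint
#' orientation uses strand `"+"` for a junction at the right end of the
#' retained segment and `"-"` for one at its left end. Read ends
#' adjacent to the junction are placed within `jitter` bp of it, so the
#' default clustering window recovers the junction. Deterministic given
#' `seed`.
#'
#' @param break_a,break_b Lists `list(chrom=, pos=, strand=)` (0-based
#'   pos).
#' @param n_split,n_discordant,n_background Pair counts (>= 0).
#' @param read_len Read length in bp.
#' @param insert_mean Concordant-pair insert size (background pairs).
#' @param clip_len Soft-clip length on split reads.
#' @param jitter Maximum distance between a junction-adjacent read end
#'   and the breakpoint.
#' @param seed Integer seed; `NULL` leaves the RNG stream untouched.
#' @return A read-pair `data.frame`, one row per pair, with columns
#'   `pair_id` and `r1_`/`r2_`-prefixed `chrom`, `pos`, `strand`,
#'   `aligned_len`, `clip_left`, `clip_right`.
#' @export
simulate_fusion_reads <- function(break_a, break_b, n_split = 5L,
                                  n_discordant = 5L, n_background = 20L,
                                  read_len = 100L, insert_mean = 300L,
                                  clip_len = 30L, jitter = 40L, seed = NULL) {
  if (n_split < 0 || n_discordant < 0 || n_background < 0) {
    stop("pair counts must be non-negative")
  }
  if (!is.null(seed)) set.seed(seed)
  stopifnot(clip_len >= 1, read_len > clip_len)
  empty <- data.frame(pair_id = character(),
                      r1_chrom = character(), r1_pos = integer(),
                      r1_strand = character(), r1_aligned_len = integer(),
                      r1_clip_left = integer(), r1_clip_right = integer(),
                      r2_chrom = character(), r2_pos = integer(),
                      r2_strand = character(), r2_aligned_len = integer(),
                      r2_clip_left = integer(), r2_clip_right = integer(),
                      stringsAsFactors = FALSE)
  rows <- list(empty)

  # A read facing the junction from a given breakpoint side: strand "+"
  # means the junction is at pos + aligned_len, "-" means at pos.
  facing_read <- function(brk, alen, dist) {
    if (brk$strand == "+") {
      list(chrom = brk$chrom, pos = brk$pos - dist - alen, strand = "+")
    } else {
      list(chrom = brk$chrom, pos = brk$pos + dist, strand = "-")
    }
  }
  pair_row <- function(id, r1, r2) {
    data.frame(pair_id = id,
               r1_chrom = r1$chrom, r1_pos = as.integer(r1$pos),
               r1_strand = r1$strand, r1_aligned_len = as.integer(r1$alen),
               r1_clip_left = as.integer(r1$cl), r1_clip_right = as.integer(r1$cr),
               r2_chrom = r2$chrom, r2_pos = as.integer(r2$pos),
               r2_strand = r2$strand, r2_aligned_len = as.integer(r2$alen),
               r2_clip_left = as.integer(r2$cl), r2_clip_right = as.integer(r2$cr),
               stringsAsFactors = FALSE)
  }
  if (n_split > 0L) {
    for (i in seq_len(n_split)) {
      alen <- read_len - clip_len
      # clipped read: aligned segment abuts breakpoint A exactly
      if (break_a$strand == "+") {
        r1 <- list(chrom = break_a$chrom, pos = break_a$pos - alen,
                   strand = "+", alen = alen, cl = 0L, cr = clip_len)
      } else {
        r1 <- list(chrom = break_a$chrom, pos = break_a$pos,
                   strand = "-", alen = alen, cl = clip_len, cr = 0L)
      }
      m <- facing_read(break_b, read_len,
                       dist = sample.int(jitter, 1L) - 1L)
      r2 <- list(chrom = m$chrom, pos = m$pos, strand = m$strand,
                 alen = read_len, cl = 0L, cr = 0L)
      rows[[length(rows) + 1L]] <- pair_row(sprintf("split_%03d", i), r1, r2)
    }
  }
  if (n_discordant > 0L) {
    for (i in seq_len(n_discordant)) {
      a <- facing_read(break_a, read_len, dist = sample.int(jitter, 1L) - 1L)
      b <- facing_read(break_b, read_len, dist = sample.int(jitter, 1L) - 1L)
      r1 <- list(chrom = a$chrom, pos = a$pos, strand = a$strand,
                 alen = read_len, cl = 0L, cr = 0L)
      r2 <- list(chrom = b$chrom, pos = b$pos, strand = b$strand,
                 alen = read_len, cl = 0L, cr = 0L)
      rows[[length(rows) + 1L]] <- pair_row(sprintf("disc_%03d", i), r1, r2)
    }
  }
  if (n_background > 0L) {
    for (i in seq_len(n_background)) {
      p <- break_a$pos + sample.int(2000L, 1L) - 1000L
      r1 <- list(chrom = break_a$chrom, pos = p, strand = "+",
                 alen = read_len, cl = 0L, cr = 0L)
      r2 <- list(chrom = break_a$chrom,
                 pos = p + insert_mean - read_len, strand = "-",
                 alen = read_len, cl = 0L, cr = 0L)
      rows[[length(rows) + 1L]] <- pair_row(sprintf("bg_%03d", i), r1, r2)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
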