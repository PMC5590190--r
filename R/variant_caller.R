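#' Filter-cascade thresholds for SNV/indel calling
#'
#' The caller's published gates, each a named constant:
#' \describe{
#'   \item{`min_depth`}{total reads at the variant position may not be
#'     less than this; depth equal to the bound passes.}
#'   \item{`max_normal_maf`}{maximum allowed variant frequency in the
#'     matched normal control; the bound itself is allowed (read as an
#'     allowed maximum), strictly above it fails.}
#'   \item{`maf_min`, `maf_min_hotspot`}{final calls are cut at
#'     MAF > `maf_min` (strict), relaxed to `maf_min_hotspot` at
#'     hotspot sites.}
#'   \item{`strand_bias_low`, `strand_bias_high`}{fraction of alt reads
#'     on the forward strand must lie in `[low, high]`; outside fails.
#'     Skipped when fewer than `min_alt_for_strand` alt reads exist
#'     (a single read always has fraction 0 or 1).}
#'   \item{`repeat_maf_min`, `repeat_min_alt`}{empirically increased
#'     requirement for indels inside repeat tracts: MAF at least
#'     `repeat_maf_min` (inclusive) and at least `repeat_min_alt`
#'     supporting reads.}
#' }
#'
#' @param min_depth Minimum total depth (reads).
#' @param max_normal_maf Maximum matched-normal allele fraction.
#' @param maf_min,maf_min_hotspot Strict lower MAF cutoffs.
#' @param strand_bias_low,strand_bias_high Allowed forward-fraction
#'   band.
#' @param min_alt_for_strand Minimum alt reads before the strand test
#'   applies.
#' @param repeat_maf_min,repeat_min_alt Extra indel requirements in
#'   repeats.
#' @return A `call_thresholds` object (validated list).
#' @export
call_thresholds <- function(min_depth = 30L, max_normal_maf = 0.03,
                            maf_min = 0.01, maf_min_hotspot = 0.005,
                            strand_bias_low = 0.1, strand_bias_high = 0.9,
                            min_alt_for_strand = 2L,
                            repeat_maf_min = 0.02, repeat_min_alt = 8L) {
  th <- list(min_depth = min_depth, max_normal_maf = max_normal_maf,
             maf_min = maf_min, maf_min_hotspot = maf_min_hotspot,
             strand_bias_low = strand_bias_low,
             strand_bias_high = strand_bias_high,
             min_alt_for_strand = min_alt_for_strand,
             repeat_maf_min = repeat_maf_min, repeat_min_alt = repeat_min_alt)
  if (!(maf_min_hotspot > 0 && maf_min_hotspot <= maf_min && maf_min < 1)) {
    stop("need 0 < maf_min_hotspot <= maf_min < 1")
  }
  if (!(strand_bias_low < strand_bias_high)) {
    stop("strand_bias_low must be below strand_bias_high")
  }
  if (min_depth < 0 || max_normal_maf < 0) stop("thresholds must be non-negative")
  structure(th, class = "call_thresholds")
}

# Exact fraction comparisons: a/b OP t without floating-point division.
# Thresholds with at most 9 decimals are scaled to integers, so both
# sides are exact in doubles (counts well below 2^53 / 1e9).
frac_gt <- function(num, den, t) num * 1e9 > den * round(t * 1e9)
frac_ge <- function(num, den, t) num * 1e9 >= den * round(t * 1e9)
frac_lt <- function(num, den, t) num * 1e9 < den * round(t * 1e9)

#' Observed mutation allele frequency of a pileup
#'
#' @param pileup A pileup `data.frame` (see [simulate_pileup()]).
#' @return `(alt_fwd + alt_rev) / depth` per row; error on zero depth.
#' @export
observed_maf <- function(pileup) {
  d <- pileup_depth(pileup)
  if (any(d == 0L)) stop("MAF undefined at zero depth")
  (pileup$alt_fwd + pileup$alt_rev) / d
}

#' Forward-strand fraction of alt reads
#'
#' @param pileup A pileup `data.frame`.
#' @return `alt_fwd / (alt_fwd + alt_rev)` per row; `NA` where no alt
#'   reads exist (the strand-bias filter is then not applied).
#' @export
strand_fraction <- function(pileup) {
  alt <- pileup$alt_fwd + pileup$alt_rev
  ifelse(alt > 0L, pileup$alt_fwd / alt, NA_real_)
}

#' Posterior probability that a site carries a real variant
#'
#' An advisory beta-binomial score: with prior Beta(a, b) on the allele
#' fraction, the posterior after observing `alt` of `depth` reads is
#' Beta(a + alt, b + depth - alt), and the score is the posterior mass
#' above the background error rate. Hotspot sites use a prior with more
#' pseudo-successes, encoding the prior expectation that recurrent
#' sites are mutated. The score is reported in the output but is not a
#' gate: calls are decided by the threshold cascade alone.
#'
#' @param pileup A pileup `data.frame`.
#' @param hotspot Logical (recycled): use the hotspot prior.
#' @param error_rate Background allele fraction the variant must
#'   exceed.
#' @param prior,prior_hotspot Length-2 `c(a, b)` pseudo-count priors.
#' @return Posterior probabilities in \[0, 1\].
#' @export
posterior_variant_prob <- function(pileup, hotspot = FALSE,
                                   error_rate = 0.001,
                                   prior = c(1, 99),
                                   prior_hotspot = c(5, 95)) {
  d <- pileup_depth(pileup)
  if (any(d == 0L)) stop("posterior undefined at zero depth")
  alt <- pileup$alt_fwd + pileup$alt_rev
  hotspot <- rep_len(hotspot, nrow(pileup))
  a <- ifelse(hotspot, prior_hotspot[1L], prior[1L])
  b <- ifelse(hotspot, prior_hotspot[2L], prior[2L])
  1 - stats::pbeta(error_rate, a + alt, b + d - alt)
}

#' Apply the somatic filter cascade to pileup records
#'
#' Evaluates the four published gates per site and returns one call per
#' row. Filters (any firing fails the call):
#' \describe{
#'   \item{`LOW_DEPTH`}{depth below `min_depth`.}
#'   \item{`NORMAL_EVIDENCE`}{matched-normal allele fraction strictly
#'     above `max_normal_maf`.}
#'   \item{`STRAND_BIAS`}{forward fraction of alt reads outside
#'     `[strand_bias_low, strand_bias_high]`, evaluated only with at
#'     least `min_alt_for_strand` alt reads.}
#'   \item{`LOW_MAF`}{observed MAF not strictly above `maf_min`
#'     (`maf_min_hotspot` at hotspots); for indels in repeat tracts the
#'     stricter repeat requirement (MAF >= `repeat_maf_min` and alt
#'     reads >= `repeat_min_alt`) is folded into this filter.}
#' }
#' All fraction comparisons are carried out in exact integer
#' arithmetic, never on formatted decimals.
#'
#' @param pileup A pileup `data.frame`; columns `var_kind`,
#'   `is_hotspot`, `in_repeat` are honoured when present and can be
#'   overridden by the arguments.
#' @param thresholds A [call_thresholds()] object.
#' @param hotspot,in_repeat Logical vectors (recycled) overriding the
#'   pileup's annotation columns.
#' @param var_kind `"SNV"`/`"indel"` vector (recycled) overriding the
#'   pileup's column.
#' @return A `variant_calls` `data.frame`: site identity, `depth`,
#'   `alt_count`, `observed_maf`, `strand_fraction`, `posterior`,
#'   `filters` (semicolon-joined, `""` when none), `pass`.
#' @export
apply_filters <- function(pileup, thresholds = call_thresholds(),
                          hotspot = NULL, in_repeat = NULL,
                          var_kind = NULL) {
  n <- nrow(pileup)
  counts <- as.matrix(pileup[, c("alt_fwd", "alt_rev", "ref_fwd", "ref_rev",
                                 "normal_alt", "normal_depth")])
  if (any(counts < 0)) stop("negative read counts in pileup")
  if (is.null(hotspot)) {
    hotspot <- if ("is_hotspot" %in% names(pileup)) pileup$is_hotspot else FALSE
  }
  if (is.null(in_repeat)) {
    in_repeat <- if ("in_repeat" %in% names(pileup)) pileup$in_repeat else FALSE
  }
  if (is.null(var_kind)) {
    var_kind <- if ("var_kind" %in% names(pileup)) pileup$var_kind else "SNV"
  }
  hotspot <- rep_len(hotspot, n)
  in_repeat <- rep_len(in_repeat, n)
  var_kind <- rep_len(var_kind, n)

  th <- thresholds
  d <- pileup_depth(pileup)
  alt <- pileup$alt_fwd + pileup$alt_rev

  low_depth <- d < th$min_depth
  normal_ev <- pileup$normal_depth > 0L &
    frac_gt(pileup$normal_alt, pileup$normal_depth, th$max_normal_maf)
  sf_applies <- alt >= th$min_alt_for_strand
  strand_bias <- sf_applies &
    (frac_gt(pileup$alt_fwd, alt, th$strand_bias_high) |
       frac_lt(pileup$alt_fwd, alt, th$strand_bias_low))
  maf_cut <- ifelse(hotspot, th$maf_min_hotspot, th$maf_min)
  low_maf <- d > 0L & !frac_gt(alt, d, maf_cut)
  rep_indel <- var_kind == "indel" & in_repeat
  low_maf <- low_maf | (rep_indel & d > 0L &
                          (!frac_ge(alt, d, th$repeat_maf_min) |
                             alt < th$repeat_min_alt))

  fl <- cbind(LOW_DEPTH = low_depth, NORMAL_EVIDENCE = normal_ev,
              STRAND_BIAS = strand_bias, LOW_MAF = low_maf)
  filters <- apply(fl, 1L, function(f)
    paste(sort(colnames(fl)[f]), collapse = ";"))
  calls <- data.frame(
    chrom = if ("chrom" %in% names(pileup)) pileup$chrom else NA_character_,
    pos = if ("pos" %in% names(pileup)) pileup$pos else NA_integer_,
    ref = if ("ref" %in% names(pileup)) pileup$ref else NA_character_,
    alt = if ("alt" %in% names(pileup)) pileup$alt else NA_character_,
    var_kind = var_kind,
    depth = d, alt_count = alt,
    observed_maf = ifelse(d > 0L, alt / d, NA_real_),
    strand_fraction = strand_fraction(pileup),
    posterior = {
      post <- rep(NA_real_, n)
      if (any(d > 0L)) {
        post[d > 0L] <- posterior_variant_prob(pileup[d > 0L, , drop = FALSE],
                                               hotspot = hotspot[d > 0L])
      }
      post
    },
    is_hotspot = hotspot, in_repeat = in_repeat,
    filters = filters, pass = filters == "",
    stringsAsFactors = FALSE)
  class(calls) <- c("variant_calls", "data.frame")
  calls
}

#' Call variants over a panel
#'
#' Runs [apply_filters()] on pileup records after restricting to the
#' targeted regions; sites outside the panel are dropped and their
#' count recorded in the `n_outside_panel` attribute. Hotspot status is
#' looked up in the catalog by exact `(chrom, pos, ref, alt)` match by
#' default, or by position only with `hotspot_match = "position"` (the
#' appropriate granularity is a configuration point).
#'
#' @param pileup A pileup `data.frame`.
#' @param panel A `panel` object.
#' @param thresholds A [call_thresholds()] object.
#' @param hotspots A hotspot `data.frame` from [read_hotspots()], or
#'   `NULL` to use the pileup's own `is_hotspot` column.
#' @param hotspot_match `"exact"` or `"position"`.
#' @return A `variant_calls` `data.frame` with attribute
#'   `n_outside_panel`.
#' @export
call_variants <- function(pileup, panel, thresholds = call_thresholds(),
                          hotspots = NULL,
                          hotspot_match = c("exact", "position")) {
  hotspot_match <- match.arg(hotspot_match)
  inside <- in_panel(panel, pileup$chrom, pileup$pos)
  n_out <- sum(!inside)
  if (n_out > 0L) {
    message("call_variants: dropped ", n_out, " site(s) outside the panel")
  }
  pu <- pileup[inside, , drop = FALSE]
  hot <- NULL
  if (!is.null(hotspots)) {
    key <- if (hotspot_match == "exact") {
      paste(pu$chrom, pu$pos, pu$ref, pu$alt)
    } else {
      paste(pu$chrom, pu$pos)
    }
    hkey <- if (hotspot_match == "exact") {
      paste(hotspots$chrom, hotspots$pos, hotspots$ref, hotspots$alt)
    } else {
      paste(hotspots$chrom, hotspots$pos)
    }
    hot <- key %in% hkey
  }
  calls <- apply_filters(pu, thresholds, hotspot = hot)
  attr(calls, "n_outside_panel") <- n_out
  calls
}

#' @export
print.variant_calls <- function(x, ...) {
  cat("Variant calls: ", nrow(x), " site(s), ", sum(x$pass), " PASS\n", sep = "")
  if (nrow(x)) {
    tab <- table(unlist(strsplit(x$filters[x$filters != ""], ";")))
    if (length(tab)) {
      cat("Filter counts:\n")
      print(tab)
    }
  }
  invisible(x)
}

#' @export
summary.variant_calls <- function(object, ...) {
  list(n = nrow(object), n_pass = sum(object$pass),
       median_depth = stats::median(object$depth),
       median_maf = stats::median(object$observed_maf, na.rm = TRUE),
       n_outside_panel = attr(object, "n_outside_panel"))
}
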