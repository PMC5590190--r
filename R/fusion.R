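# Breakpoint-evidence conventions
# -------------------------------
# Each evidence record carries two junction sides (a, b), each a
# (chrom, pos, orient) triple with orient "R" when the retained
# segment lies left of the breakpoint (junction at the segment's right
# end) and "L" when it lies right of it. Sides are stored in canonical
# order (side a <= side b by chrom then pos) so identical junctions
# cluster regardless of which mate was seen first.

read_side <- function(chrom, pos, strand, aligned_len) {
  # a read facing the junction: "+" reads point right (junction at the
  # right end of the alignment), "-" reads point left
  if (strand == "+") {
    list(chrom = chrom, pos = pos + aligned_len, orient = "R")
  } else {
    list(chrom = chrom, pos = pos, orient = "L")
  }
}

evidence_frame <- function(chrom_a = character(), pos_a = integer(),
                           orient_a = character(), chrom_b = character(),
                           pos_b = integer(), orient_b = character(),
                           evidence = character(), pair_id = character()) {
  data.frame(chrom_a = chrom_a, pos_a = pos_a, orient_a = orient_a,
             chrom_b = chrom_b, pos_b = pos_b, orient_b = orient_b,
             evidence = evidence, pair_id = pair_id,
             stringsAsFactors = FALSE)
}

canonicalize_evidence <- function(ev) {
  if (!nrow(ev)) return(ev)
  swap <- ev$chrom_a > ev$chrom_b |
    (ev$chrom_a == ev$chrom_b & ev$pos_a > ev$pos_b)
  if (any(swap)) {
    tmp <- ev[swap, c("chrom_a", "pos_a", "orient_a")]
    ev[swap, c("chrom_a", "pos_a", "orient_a")] <-
      ev[swap, c("chrom_b", "pos_b", "orient_b")]
    ev[swap, c("chrom_b", "pos_b", "orient_b")] <- tmp
  }
  ev
}

#' Extract clipped-read breakpoint evidence
#'
#' A soft-clipped read marks a rearrangement junction at its clip
#' boundary: a right clip places the breakpoint at
#' `pos + aligned_len`, a left clip at `pos`. The mate, which lies on
#' the partner side of the junction, supplies the second breakpoint
#' side (approximately, from its junction-facing end). One evidence
#' record is emitted per read whose clip reaches `min_clip`.
#'
#' @param reads A read-pair `data.frame` (see
#'   [simulate_fusion_reads()]).
#' @param min_clip Minimum soft-clip length in bp.
#' @return An evidence `data.frame` with canonical side ordering and
#'   `evidence = "split"`.
#' @export
extract_clipped <- function(reads, min_clip = 10L) {
  if (min_clip < 1L) stop("min_clip must be at least 1")
  rows <- list(evidence_frame())
  for (i in seq_len(nrow(reads))) {
    for (rd in c("r1", "r2")) {
      mate <- if (rd == "r1") "r2" else "r1"
      g <- function(f, who = rd) reads[[paste0(who, "_", f)]][i]
      cl <- g("clip_left"); cr <- g("clip_right")
      if (cl < min_clip && cr < min_clip) next
      if (cr >= cl) {
        bp <- g("pos") + g("aligned_len"); orient <- "R"
      } else {
        bp <- g("pos"); orient <- "L"
      }
      m <- read_side(g("chrom", mate), g("pos", mate),
                     g("strand", mate), g("aligned_len", mate))
      rows[[length(rows) + 1L]] <- evidence_frame(
        g("chrom"), bp, orient, m$chrom, m$pos, m$orient,
        "split", reads$pair_id[i])
    }
  }
  ev <- do.call(rbind, rows)
  rownames(ev) <- NULL
  canonicalize_evidence(ev)
}

#' Select discordant read pairs
#'
#' A pair is kept as rearrangement evidence iff (a) its mates map to
#' different chromosomes, or (b) to the same chromosome at an outer
#' span (leftmost start to rightmost end) greater than
#' `max_concordant_span`, or (c) its mates align in the same direction
#' (both `+` or both `-`). Everything else is a concordant pair.
#'
#' @param reads A read-pair `data.frame`.
#' @param max_concordant_span Largest span (bp) still considered
#'   concordant; the classic 2 kb rule.
#' @return The subset of `reads` that is discordant.
#' @export
select_discordant <- function(reads, max_concordant_span = 2000L) {
  if (!nrow(reads)) return(reads)
  diff_chrom <- reads$r1_chrom != reads$r2_chrom
  span <- pmax(reads$r1_pos + reads$r1_aligned_len,
               reads$r2_pos + reads$r2_aligned_len) -
    pmin(reads$r1_pos, reads$r2_pos)
  far <- !diff_chrom & span > max_concordant_span
  same_dir <- reads$r1_strand == reads$r2_strand
  keep <- diff_chrom | far | same_dir
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Discordant pairs to breakpoint evidence: each mate's junction-facing
# end approximates one breakpoint side.
discordant_evidence <- function(pairs) {
  rows <- list(evidence_frame())
  for (i in seq_len(nrow(pairs))) {
    a <- read_side(pairs$r1_chrom[i], pairs$r1_pos[i],
                   pairs$r1_strand[i], pairs$r1_aligned_len[i])
    b <- read_side(pairs$r2_chrom[i], pairs$r2_pos[i],
                   pairs$r2_strand[i], pairs$r2_aligned_len[i])
    rows[[length(rows) + 1L]] <- evidence_frame(
      a$chrom, a$pos, a$orient, b$chrom, b$pos, b$orient,
      "discordant", pairs$pair_id[i])
  }
  ev <- do.call(rbind, rows)
  rownames(ev) <- NULL
  canonicalize_evidence(ev)
}

#' Cluster breakpoint evidence into candidate junctions
#'
#' Single-linkage clustering over evidence records sharing chromosomes
#' and orientations on both sides: a record joins a cluster when both
#' its side positions are within `window` bp of the cluster's most
#' recently added member. Records are processed in sorted order, so the
#' result is deterministic.
#'
#' @param evidence An evidence `data.frame` (rbind of
#'   [extract_clipped()] and `discordant` evidence from
#'   [select_discordant()] pairs, via [call_fusions()]).
#' @param window Clustering window in bp.
#' @return A `data.frame` of clusters: both sides (median positions),
#'   `n_split`, `n_discordant`.
#' @export
cluster_breakpoints <- function(evidence, window = 50L) {
  if (window < 0L) stop("window must be non-negative")
  cols <- c("chrom_a", "orient_a", "chrom_b", "orient_b")
  empty <- data.frame(chrom_a = character(), pos_a = integer(),
                      orient_a = character(), chrom_b = character(),
                      pos_b = integer(), orient_b = character(),
                      n_split = integer(), n_discordant = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(evidence)) return(empty)
  ev <- evidence[order(evidence$chrom_a, evidence$chrom_b,
                       evidence$orient_a, evidence$orient_b,
                       evidence$pos_a, evidence$pos_b), , drop = FALSE]
  key <- do.call(paste, c(ev[cols], sep = "\r"))
  out <- list()
  for (k in unique(key)) {
    g <- ev[key == k, , drop = FALSE]
    cl_id <- integer(nrow(g))
    cl_id[1L] <- 1L
    last_a <- g$pos_a[1L]; last_b <- g$pos_b[1L]
    for (i in seq_len(nrow(g))[-1L]) {
      if (abs(g$pos_a[i] - last_a) <= window &&
          abs(g$pos_b[i] - last_b) <= window) {
        cl_id[i] <- cl_id[i - 1L]
      } else {
        cl_id[i] <- cl_id[i - 1L] + 1L
      }
      last_a <- g$pos_a[i]; last_b <- g$pos_b[i]
    }
    for (cid in unique(cl_id)) {
      m <- g[cl_id == cid, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        chrom_a = m$chrom_a[1L],
        pos_a = as.integer(round(stats::median(m$pos_a))),
        orient_a = m$orient_a[1L],
        chrom_b = m$chrom_b[1L],
        pos_b = as.integer(round(stats::median(m$pos_b))),
        orient_b = m$orient_b[1L],
        n_split = sum(m$evidence == "split"),
        n_discordant = sum(m$evidence == "discordant"),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify a rearrangement from its junction geometry
#'
#' Rules: different chromosomes give a translocation; on one
#' chromosome, matching orientations on the two sides (an inverted
#' junction) give an inversion; opposite orientations with the
#' left-retaining side (`"R"`) at the lower coordinate and a gap above
#' `min_del_gap` give a long deletion; the reversed arrangement gives a
#' tandem duplication.
#'
#' @param cluster A one-row cluster `data.frame` (or several rows;
#'   vectorised).
#' @param min_del_gap Minimum gap (bp) for a deletion-type junction.
#' @return Character vector of kinds: `"translocation"`,
#'   `"inversion"`, `"long_deletion"`, `"tandem_duplication"`, or
#'   `"unclassified"`.
#' @export
classify_rearrangement <- function(cluster, min_del_gap = 2000L) {
  vapply(seq_len(nrow(cluster)), function(i) {
    c1 <- cluster[i, ]
    if (c1$chrom_a != c1$chrom_b) return("translocation")
    if (c1$orient_a == c1$orient_b) return("inversion")
    lo_orient <- if (c1$pos_a <= c1$pos_b) c1$orient_a else c1$orient_b
    gap <- abs(c1$pos_b - c1$pos_a)
    if (lo_orient == "R") {
      if (gap > min_del_gap) "long_deletion" else "unclassified"
    } else {
      "tandem_duplication"
    }
  }, character(1L))
}

#' Call fusion events from read-pair records
#'
#' The full rearrangement pipeline: clipped-read evidence extraction,
#' discordant-pair selection, breakpoint clustering, classification,
#' panel annotation. Calls are restricted to the baited regions: a
#' cluster with both sides outside the panel is dropped (count in the
#' `n_outside_panel` attribute). A cluster passes when its split-read
#' support reaches `min_split` or its discordant-pair support reaches
#' `min_discordant`; otherwise it is reported with `low_support`
#' status.
#'
#' @param reads A read-pair `data.frame`, or a pre-built cluster
#'   `data.frame` (recognised by an `n_split` column).
#' @param panel A `panel` object.
#' @param min_clip,window,max_concordant_span Evidence parameters.
#' @param min_split,min_discordant Support thresholds for PASS.
#' @return A `fusion_events` `data.frame`: cluster columns plus
#'   `rearrangement_kind`, `gene_a`, `gene_b`, `status`.
#' @export
call_fusions <- function(reads, panel, min_clip = 10L, window = 50L,
                         max_concordant_span = 2000L,
                         min_split = 3L, min_discordant = 5L) {
  stopifnot(inherits(panel, "panel"), nrow(panel) > 0L)
  if ("n_split" %in% names(reads)) {
    clusters <- reads
  } else {
    split_ev <- extract_clipped(reads, min_clip = min_clip)
    # clipped pairs already contribute split evidence; discordant
    # geometry is assessed on the remaining pairs
    disc <- select_discordant(reads, max_concordant_span)
    disc <- disc[!disc$pair_id %in% split_ev$pair_id, , drop = FALSE]
    clusters <- cluster_breakpoints(rbind(split_ev, discordant_evidence(disc)),
                                    window = window)
  }
  if (!nrow(clusters)) {
    ev <- cbind(clusters,
                data.frame(rearrangement_kind = character(),
                           gene_a = character(), gene_b = character(),
                           status = character(), stringsAsFactors = FALSE))
    class(ev) <- c("fusion_events", "data.frame")
    attr(ev, "n_outside_panel") <- 0L
    return(ev)
  }
  gene_a <- panel_gene_at(panel, clusters$chrom_a, clusters$pos_a)
  gene_b <- panel_gene_at(panel, clusters$chrom_b, clusters$pos_b)
  in_a <- in_panel(panel, clusters$chrom_a, clusters$pos_a)
  in_b <- in_panel(panel, clusters$chrom_b, clusters$pos_b)
  outside <- !in_a & !in_b
  n_out <- sum(outside)
  if (n_out > 0L) {
    message("call_fusions: dropped ", n_out,
            " cluster(s) with both sides outside the panel")
  }
  cl <- clusters[!outside, , drop = FALSE]
  ev <- cbind(cl, data.frame(
    rearrangement_kind = classify_rearrangement(cl,
                                                min_del_gap = max_concordant_span),
    gene_a = gene_a[!outside], gene_b = gene_b[!outside],
    status = ifelse(cl$n_split >= min_split |
                      cl$n_discordant >= min_discordant,
                    "PASS", "low_support"),
    stringsAsFactors = FALSE))
  rownames(ev) <- NULL
  class(ev) <- c("fusion_events", "data.frame")
  attr(ev, "n_outside_panel") <- n_out
  ev
}

#' @export
print.fusion_events <- function(x, ...) {
  cat("Fusion events: ", nrow(x), " cluster(s), ",
      sum(x$status == "PASS"), " PASS\n", sep = "")
  print.data.frame(as.data.frame(x))
  invisible(x)
}
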