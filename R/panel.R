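#' Read a capture panel from a BED file
#'
#' Reads the target regions of a hybrid-capture panel from a BED3+ file.
#' Coordinates follow the BED convention: 0-based, half-open
#' `[start, end)`. Optional columns 4-6 are interpreted as the gene
#' symbol, the region kind (`"exon"` or `"intron"`; intronic baits are
#' how rearrangement-prone genes are tiled), and the GC fraction of the
#' region. Regions are sorted by `(chrom, start)` and validated:
#' `start < end` everywhere and no two regions on the same chromosome
#' overlap.
#'
#' @param path Path to a BED file. Lines starting with `#`, `track` or
#'   `browser` are ignored.
#' @return A `panel` object: a `data.frame` with columns `chrom`,
#'   `start`, `end`, `gene`, `region_kind`, `gc_fraction`.
#' @seealso [write_panel_bed()], [annotate_gc()], [in_panel()]
#' @export
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr2\t100\t300\tALK\tintron\t0.45", bed)
#' read_panel_bed(bed)
read_panel_bed <- function(path) {
  if (!file.exists(path)) stop("panel BED not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) stop("panel BED contains no regions: ", path)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("malformed BED line ", idx[which(nf < 3L)[1L]],
         ": fewer than 3 tab-separated fields")
  }
  get_col <- function(i, default = NA_character_) {
    vapply(fields, function(f) if (length(f) >= i) f[[i]] else default, "")
  }
  start <- suppressWarnings(as.integer(get_col(2L)))
  end <- suppressWarnings(as.integer(get_col(3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop("malformed BED line ", idx[bad[1L]], ": non-integer coordinates")
  }
  gc <- suppressWarnings(as.numeric(get_col(6L, NA_character_)))
  panel <- data.frame(
    chrom = get_col(1L),
    start = start,
    end = end,
    gene = get_col(4L),
    region_kind = ifelse(is.na(get_col(5L)), "exon", get_col(5L)),
    gc_fraction = gc,
    stringsAsFactors = FALSE
  )
  inv <- which(panel$start >= panel$end)
  if (length(inv)) {
    stop("invalid region at BED line ", idx[inv[1L]],
         ": start >= end (", panel$start[inv[1L]], " >= ", panel$end[inv[1L]], ")")
  }
  if (any(!is.na(gc) & (gc < 0 | gc > 1))) stop("gc_fraction outside [0, 1]")
  new_panel(panel, name = basename(path))
}

new_panel <- function(df, name = "panel") {
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  for (ch in unique(df$chrom)) {
    r <- df[df$chrom == ch, ]
    if (nrow(r) > 1L && any(r$start[-1L] < r$end[-nrow(r)])) {
      stop("overlapping regions on ", ch, " after sorting; panel must be disjoint")
    }
  }
  structure(df, class = c("panel", "data.frame"), name = name)
}

#' Write a panel back to BED
#'
#' Inverse of [read_panel_bed()]; coordinates round-trip bit-exactly.
#'
#' @param panel A `panel` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_bed <- function(panel, path) {
  stopifnot(inherits(panel, "panel"))
  gc <- ifelse(is.na(panel$gc_fraction), ".",
               formatC(panel$gc_fraction, format = "fg", digits = 15))
  lines <- paste(panel$chrom, panel$start, panel$end,
                 ifelse(is.na(panel$gene), ".", panel$gene),
                 panel$region_kind, gc, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.panel <- function(x, ...) {
  cat("Capture panel '", attr(x, "name"), "': ", nrow(x), " regions, ",
      sum(x$end - x$start), " bp on ", length(unique(x$chrom)),
      " chromosome(s)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("... and", nrow(x) - 6L, "more regions\n")
  invisible(x)
}

#' Read a hotspot catalog
#'
#' Hotspots are recurrently mutated, clinically annotated sites (the
#' EGFR L858R class) that are granted a relaxed allele-fraction cutoff
#' by the caller. The file is a TSV with columns chrom, pos (1-based),
#' ref, alt; positions are converted to the package's internal 0-based
#' convention and exact duplicate rows are removed.
#'
#' @param path Path to the hotspot TSV (no header).
#' @return A `data.frame` with columns `chrom`, `pos` (0-based), `ref`,
#'   `alt`.
#' @export
read_hotspots <- function(path) {
  if (!file.exists(path)) stop("hotspot file not found: ", path)
  raw <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      colClasses = c("character", "integer", "character", "character"),
                      col.names = c("chrom", "pos", "ref", "alt")),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) {
        data.frame(chrom = character(), pos = integer(),
                   ref = character(), alt = character())
      } else stop(e)
    })
  if (nrow(raw)) {
    ok <- grepl("^[ACGT]+$", raw$ref) & grepl("^[ACGT]+$", raw$alt)
    if (any(!ok)) {
      stop("hotspot alleles must be non-empty strings over {A,C,G,T}; offending row ",
           which(!ok)[1L])
    }
    raw$pos <- raw$pos - 1L
    raw <- unique(raw)
    rownames(raw) <- NULL
  }
  raw
}

#' Read a truth set of declared variants
#'
#' A truth set declares ground-truth alterations with their true allele
#' fractions, as used for sensitivity validation. TSV columns: chrom,
#' pos (1-based), ref, alt, var_kind (`SNV`/`indel`), true_maf,
#' is_hotspot (0/1), in_repeat (0/1).
#'
#' @param path Path to the truth TSV (no header).
#' @return A `data.frame` with 0-based `pos` and logical flag columns.
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stop("truth file not found: ", path)
  tr <- utils::read.table(
    path, sep = "\t", header = FALSE,
    colClasses = c("character", "integer", "character", "character",
                   "character", "numeric", "integer", "integer"),
    col.names = c("chrom", "pos", "ref", "alt", "var_kind",
                  "true_maf", "is_hotspot", "in_repeat"))
  validate_truth(within(tr, {
    pos <- pos - 1L
    is_hotspot <- is_hotspot != 0L
    in_repeat <- in_repeat != 0L
  }))
}

validate_truth <- function(tr) {
  if (any(tr$true_maf <= 0 | tr$true_maf > 1)) stop("true_maf must lie in (0, 1]")
  if (!all(tr$var_kind %in% c("SNV", "indel"))) stop("var_kind must be SNV or indel")
  is_snv <- nchar(tr$ref) == 1L & nchar(tr$alt) == 1L
  if (any(is_snv != (tr$var_kind == "SNV"))) {
    stop("var_kind inconsistent with allele lengths")
  }
  tr
}

#' Write a truth set (inverse of [read_truth()])
#' @param truth A truth `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  out <- data.frame(truth$chrom, truth$pos + 1L, truth$ref, truth$alt,
                    truth$var_kind, truth$true_maf,
                    as.integer(truth$is_hotspot), as.integer(truth$in_repeat))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Annotate panel regions with GC fraction from sequence
#'
#' GC content drives capture and amplification bias, which the
#' copy-number stage corrects; this fills `gc_fraction` from actual
#' region sequences.
#'
#' @param panel A `panel` object.
#' @param sequence_source A function `(chrom, start, end) -> character`
#'   returning the nucleotide sequence of the region.
#' @return The panel with `gc_fraction` computed as (#G + #C) / length.
#' @export
annotate_gc <- function(panel, sequence_source) {
  stopifnot(inherits(panel, "panel"), is.function(sequence_source))
  gc <- numeric(nrow(panel))
  for (i in seq_len(nrow(panel))) {
    s <- toupper(sequence_source(panel$chrom[i], panel$start[i], panel$end[i]))
    len <- panel$end[i] - panel$start[i]
    if (nchar(s) != len) {
      stop("sequence length ", nchar(s), " != region length ", len,
           " for region ", i)
    }
    gc[i] <- sum(strsplit(s, "")[[1L]] %in% c("G", "C")) / len
  }
  panel$gc_fraction <- gc
  panel
}

#' Panel membership test
#'
#' Half-open interval semantics: position `p` is inside a region
#' `[start, end)` iff `start <= p < end`. All callers restrict their
#' output to panel positions through this test.
#'
#' @param panel A `panel` object.
#' @param chrom,pos Vectors of chromosome names and 0-based positions.
#' @return Logical vector.
#' @export
in_panel <- function(panel, chrom, pos) {
  !is.na(panel_region_index(panel, chrom, pos))
}

# Index of the panel region containing each (chrom, pos), NA if none.
panel_region_index <- function(panel, chrom, pos) {
  out <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    reg <- which(panel$chrom == ch)
    if (!length(reg)) next
    # regions are sorted and disjoint, so findInterval on starts suffices
    k <- findInterval(pos[sel], panel$start[reg])
    hit <- k >= 1L & pos[sel] < panel$end[reg][pmax(k, 1L)]
    out[sel[hit]] <- reg[k[hit]]
  }
  out
}

# Gene symbol at each (chrom, pos), NA outside the panel.
panel_gene_at <- function(panel, chrom, pos) {
  i <- panel_region_index(panel, chrom, pos)
  ifelse(is.na(i), NA_character_, panel$gene[i])
}
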