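# Shared fixtures and independent oracles for the test suite.

toy_panel_path <- function() {
  system.file("extdata", "toy_panel.bed", package = "panelval")
}

toy_panel <- function() read_panel_bed(toy_panel_path())

# A small single-chromosome panel built in code.
flat_panel <- function(n_bins = 100L, chrom = "chr1", gene = "GENE",
                       width = 100L, gc = 0.5) {
  start <- as.integer((0:(n_bins - 1L)) * width)
  panelval:::new_panel(data.frame(
    chrom = chrom, start = start, end = start + width,
    gene = gene, region_kind = "exon", gc_fraction = gc,
    stringsAsFactors = FALSE))
}

# Construct a pileup row (or rows) directly from counts.
make_pileup <- function(alt_fwd, alt_rev, ref_fwd, ref_rev,
                        normal_alt = 0L, normal_depth = 500L,
                        chrom = "chr1", pos = 50L, ref = "A", alt = "T") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             alt_fwd = alt_fwd, alt_rev = alt_rev,
             ref_fwd = ref_fwd, ref_rev = ref_rev,
             normal_alt = normal_alt, normal_depth = normal_depth,
             stringsAsFactors = FALSE)
}

# Independent brute-force re-statement of the four filter rules, written
# directly from their definitions (depth not less than 30; normal
# variant frequency at most 0.03; strand bias outside (0.1, 0.9)
# complement; final calls at MAF > 1%, > 0.5% at hotspots). Scalar,
# deliberately naive.
brute_force_filters <- function(alt_fwd, alt_rev, ref_fwd, ref_rev,
                                normal_alt, normal_depth,
                                hotspot = FALSE, in_repeat = FALSE,
                                indel = FALSE) {
  depth <- alt_fwd + alt_rev + ref_fwd + ref_rev
  alt <- alt_fwd + alt_rev
  fired <- character(0)
  if (depth < 30) fired <- c(fired, "LOW_DEPTH")
  if (normal_depth > 0 && normal_alt / normal_depth > 0.03) {
    fired <- c(fired, "NORMAL_EVIDENCE")
  }
  if (alt >= 2) {
    sf <- alt_fwd / alt
    if (sf > 0.9 || sf < 0.1) fired <- c(fired, "STRAND_BIAS")
  }
  cut <- if (hotspot) 0.005 else 0.01
  low_maf <- depth > 0 && !(alt / depth > cut)
  if (indel && in_repeat && depth > 0) {
    if (!(alt / depth >= 0.02) || alt < 8) low_maf <- TRUE
  }
  if (low_maf) fired <- c(fired, "LOW_MAF")
  paste(sort(fired), collapse = ";")
}

# Brute-force discordance predicate: the plain disjunction of the three
# selection rules.
brute_force_discordant <- function(r1_chrom, r1_pos, r1_strand, r1_len,
                                   r2_chrom, r2_pos, r2_strand, r2_len) {
  if (r1_chrom != r2_chrom) return(TRUE)
  span <- max(r1_pos + r1_len, r2_pos + r2_len) - min(r1_pos, r2_pos)
  if (span > 2000) return(TRUE)
  r1_strand == r2_strand
}

# Amplicon table for the dilution fixture: four high-level
# amplifications and one low-level (AKT1), the first to fall below
# detection as purity drops.
dilution_amplicons <- function() {
  data.frame(gene = c("CCND1", "FGF3", "FGF4", "FGF19", "AKT1"),
             tumor_copy_number = c(10L, 10L, 10L, 10L, 4L),
             stringsAsFactors = FALSE)
}
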