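# Tabular readers/writers for the pipeline's exchange formats. All
# point-variant TSVs carry 1-based positions on disk (converted to the
# internal 0-based convention on read); BED/BEDPE stay 0-based
# half-open.

#' Write / read a pileup table
#'
#' TSV with header: chrom, pos (1-based), ref, alt, alt_fwd, alt_rev,
#' ref_fwd, ref_rev, normal_alt, normal_depth, plus any annotation
#' columns present (`var_kind`, `is_hotspot`, `in_repeat`,
#' `true_maf`).
#'
#' @param pileup A pileup `data.frame`.
#' @param path File path.
#' @return `write_pileup`: `path`, invisibly. `read_pileup`: the
#'   pileup `data.frame` (0-based `pos`).
#' @export
write_pileup <- function(pileup, path) {
  out <- pileup
  out$pos <- out$pos + 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pileup
#' @export
read_pileup <- function(path) {
  pu <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  pu$pos <- pu$pos - 1L
  pu
}

#' Write / read a coverage table
#'
#' TSV with header: chrom, start, end (0-based half-open), gene,
#' gc_fraction, tumor_count, normal_count.
#'
#' @param coverage A coverage `data.frame`.
#' @param path File path.
#' @return `write_coverage`: `path`, invisibly; `read_coverage`: the
#'   coverage `data.frame`.
#' @export
write_coverage <- function(coverage, path) {
  utils::write.table(coverage, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_coverage
#' @export
read_coverage <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write variant calls as VCF 4.2
#'
#' Positions are converted to the VCF 1-based convention. `FILTER` is
#' `PASS` or the semicolon-joined (sorted) failing filter names; INFO
#' carries `MAF`, `SB` (forward-strand fraction of alt reads), `DP`
#' and `POSTERIOR`. The header documents every threshold in use.
#'
#' @param calls A `variant_calls` `data.frame`.
#' @param path Output path.
#' @param thresholds The [call_thresholds()] the calls were made with
#'   (recorded in the header).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, thresholds = call_thresholds()) {
  th <- thresholds
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=panelval",
    sprintf("##panelval_thresholds=min_depth=%d,max_normal_maf=%g,maf_min=%g,maf_min_hotspot=%g,strand_bias=[%g,%g],repeat_maf_min=%g,repeat_min_alt=%d",
            th$min_depth, th$max_normal_maf, th$maf_min, th$maf_min_hotspot,
            th$strand_bias_low, th$strand_bias_high,
            th$repeat_maf_min, th$repeat_min_alt),
    sprintf("##FILTER=<ID=LOW_DEPTH,Description=\"Total depth below %d reads\">", th$min_depth),
    sprintf("##FILTER=<ID=NORMAL_EVIDENCE,Description=\"Matched-normal allele fraction above %g\">", th$max_normal_maf),
    sprintf("##FILTER=<ID=STRAND_BIAS,Description=\"Forward fraction of alt reads outside [%g,%g]\">", th$strand_bias_low, th$strand_bias_high),
    sprintf("##FILTER=<ID=LOW_MAF,Description=\"MAF not above %g (%g at hotspots; repeat indels need MAF >= %g and >= %d alt reads)\">",
            th$maf_min, th$maf_min_hotspot, th$repeat_maf_min, th$repeat_min_alt),
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Observed mutation allele frequency\">",
    "##INFO=<ID=SB,Number=1,Type=Float,Description=\"Forward-strand fraction of alt reads\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##INFO=<ID=POSTERIOR,Number=1,Type=Float,Description=\"Beta-binomial posterior probability of a real variant\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character(0)
  if (nrow(calls)) {
    fmt_num <- function(v) ifelse(is.na(v), ".", formatC(v, format = "g", digits = 6))
    info <- paste0("MAF=", fmt_num(calls$observed_maf),
                   ";SB=", fmt_num(calls$strand_fraction),
                   ";DP=", calls$depth,
                   ";POSTERIOR=", fmt_num(calls$posterior))
    body <- paste(calls$chrom, calls$pos + 1L, ".", calls$ref, calls$alt,
                  ".", ifelse(calls$pass, "PASS", calls$filters), info,
                  sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write fusion events as BEDPE
#'
#' One line per event: both breakpoint sides as 0-based half-open
#' single-base intervals, the event name, split-read support as the
#' score, side orientations as strands, then kind, discordant support,
#' genes and status as extra columns. A comment header names the
#' columns.
#'
#' @param fusions A `fusion_events` `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(fusions, path) {
  hdr <- paste0("#chrom1\tstart1\tend1\tchrom2\tstart2\tend2\tname\t",
                "n_split\tstrand1\tstrand2\tkind\tn_discordant\t",
                "gene1\tgene2\tstatus")
  body <- character(0)
  if (nrow(fusions)) {
    orient_strand <- function(o) ifelse(o == "R", "+", "-")
    body <- paste(
      fusions$chrom_a, fusions$pos_a, fusions$pos_a + 1L,
      fusions$chrom_b, fusions$pos_b, fusions$pos_b + 1L,
      sprintf("fusion_%03d", seq_len(nrow(fusions))),
      fusions$n_split,
      orient_strand(fusions$orient_a), orient_strand(fusions$orient_b),
      fusions$rearrangement_kind, fusions$n_discordant,
      ifelse(is.na(fusions$gene_a), ".", fusions$gene_a),
      ifelse(is.na(fusions$gene_b), ".", fusions$gene_b),
      fusions$status, sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write copy-number segments in SEG format
#'
#' Tab-separated SEG (1-based starts, as segmentation viewers expect)
#' with the inferred tumor copy number and amplification flag as extra
#' columns.
#'
#' @param segments A `cnv_segments` `data.frame`.
#' @param path Output path.
#' @param sample Sample identifier for the first column.
#' @return `path`, invisibly.
#' @export
write_seg <- function(segments, path, sample = "tumor") {
  df <- data.frame(
    ID = sample, chrom = segments$chrom,
    loc.start = segments$start + 1L, loc.end = segments$end,
    num.mark = segments$n_bins,
    seg.mean = segments$mean_log2)
  if ("inferred_tumor_cn" %in% names(segments)) {
    df$inferred_cn <- segments$inferred_tumor_cn
    df$amplified <- as.integer(segments$amplified)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Derive a per-stage child seed from a run seed
#'
#' One top-level seed fans out to independent stage seeds so any stage
#' can be re-run in isolation: `child = (seed * 48271 + index) mod
#' (2^31 - 1)` (a Lehmer-style mixing step; the modulus keeps seeds in
#' integer range).
#'
#' @param seed Integer run seed.
#' @param index Stage or replicate index (>= 1).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index) %% 2147483647)
}

#' Run the full simulate-call-validate pipeline
#'
#' Executes every stage on synthetic inputs under one configuration:
#' (1) simulate truth variants, pileups, tumor/normal coverage and
#' fusion-supporting read pairs; (2) call SNVs/indels, copy-number
#' segments and fusions; (3) validate: sensitivity-versus-depth curve
#' and purity dilution series. All outputs are reproducible
#' bit-exactly from `(config, seed)`; a JSON manifest records the
#' package version, seed, thresholds and completed stages.
#'
#' @param config A configuration list or path to a YAML file. Required
#'   key: `panel` (path to a panel BED). Optional keys with defaults:
#'   `hotspots` (path), `seed`, `n_snv`, `n_indel`, `depth`,
#'   `error_rate`, `maf_model`, `purity`, `coverage_depth`,
#'   `amplicons` (list of `gene:`/`tumor_copy_number:`), `fusion`
#'   (list with `chrom_a`, `pos_a`, `strand_a`, `chrom_b`, `pos_b`,
#'   `strand_b`, `n_split`, `n_discordant`), `depth_grid`,
#'   `replicates`, `purity_grid`, and a `thresholds` block passed to
#'   [call_thresholds()].
#' @param out_dir Output directory (created if missing).
#' @param seed Overrides `config$seed` when non-`NULL`.
#' @return Invisibly, a list with the manifest and the main result
#'   objects.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$panel)) {
    stop("config must name a panel BED under key 'panel'")
  }
  if (!file.exists(config$panel)) stop("panel path does not exist: ", config$panel)
  cfg <- utils::modifyList(list(
    seed = 1L, n_snv = 200L, n_indel = 50L, depth = 1000,
    error_rate = 0.001, maf_model = "cellline_pool",
    purity = 0.5, coverage_depth = 2000,
    amplicons = list(list(gene = "CCND1", tumor_copy_number = 10L),
                     list(gene = "FGF3", tumor_copy_number = 10L),
                     list(gene = "FGF4", tumor_copy_number = 10L),
                     list(gene = "FGF19", tumor_copy_number = 10L),
                     list(gene = "AKT1", tumor_copy_number = 4L)),
    fusion = list(chrom_a = "chr2", pos_a = 42522656, strand_a = "+",
                  chrom_b = "chr2", pos_b = 29446394, strand_b = "-",
                  n_split = 6L, n_discordant = 8L),
    depth_grid = c(100L, 200L, 300L, 400L, 500L, 600L, 700L, 800L),
    replicates = 5L, purity_grid = c(0.5, 0.4, 0.3, 0.2, 0.1),
    thresholds = list()), config)
  if (!is.null(seed)) cfg$seed <- seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  th <- do.call(call_thresholds, cfg$thresholds)
  stages <- character(0)
  log_stage <- function(s) {
    message("[panelval] stage: ", s)
    stages <<- c(stages, s)
  }

  log_stage("simulate")
  panel <- read_panel_bed(cfg$panel)
  hotspots <- if (!is.null(cfg$hotspots)) read_hotspots(cfg$hotspots) else NULL
  truth <- simulate_truth(panel, cfg$n_snv, cfg$n_indel,
                          model = maf_model(cfg$maf_model),
                          seed = derive_seed(cfg$seed, 1L))
  pileup <- simulate_pileup(truth, depth = cfg$depth,
                            error_rate = cfg$error_rate,
                            seed = derive_seed(cfg$seed, 2L))
  amp <- do.call(rbind, lapply(cfg$amplicons, as.data.frame))
  coverage <- simulate_coverage(panel, amp, purity = cfg$purity,
                                depth = cfg$coverage_depth,
                                seed = derive_seed(cfg$seed, 3L))
  fu <- cfg$fusion
  reads <- simulate_fusion_reads(
    list(chrom = fu$chrom_a, pos = fu$pos_a, strand = fu$strand_a),
    list(chrom = fu$chrom_b, pos = fu$pos_b, strand = fu$strand_b),
    n_split = fu$n_split, n_discordant = fu$n_discordant,
    seed = derive_seed(cfg$seed, 4L))
  write_truth(truth, file.path(out_dir, "truth.tsv"))
  write_pileup(pileup, file.path(out_dir, "pileup.tsv"))
  write_coverage(coverage, file.path(out_dir, "coverage.tsv"))
  utils::write.table(reads, file.path(out_dir, "reads.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  log_stage("call_snv_indel")
  calls <- call_variants(pileup, panel, thresholds = th, hotspots = hotspots)
  write_vcf(calls, file.path(out_dir, "calls.vcf"), thresholds = th)

  log_stage("call_cnv")
  segments <- suppressMessages(call_cnv(coverage, purity = cfg$purity))
  write_seg(segments, file.path(out_dir, "segments.seg"))

  log_stage("call_fusion")
  fusions <- call_fusions(reads, panel)
  write_bedpe(fusions, file.path(out_dir, "fusions.bedpe"))

  log_stage("validate")
  curve <- sensitivity_by_depth(truth, pileup, cfg$depth_grid,
                                replicates = cfg$replicates,
                                thresholds = th,
                                seed = derive_seed(cfg$seed, 5L))
  utils::write.table(as.data.frame(curve),
                     file.path(out_dir, "sensitivity_curve.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dil <- dilution_lod(panel, amp, purity_grid = cfg$purity_grid,
                      depth = cfg$coverage_depth,
                      seed = derive_seed(cfg$seed, 6L))
  dil_df <- data.frame(gene = rownames(dil$detection), dil$detection,
                       lod = dil$lod, check.names = FALSE)
  utils::write.table(dil_df, file.path(out_dir, "dilution.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "panelval",
    version = as.character(utils::packageVersion("panelval")),
    seed = cfg$seed,
    thresholds = unclass(th),
    stages = stages,
    outputs = list.files(out_dir))
  manifest$outputs <- setdiff(manifest$outputs, "manifest.json")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(manifest = manifest, calls = calls, segments = segments,
                 fusions = fusions, curve = curve, dilution = dil))
}
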