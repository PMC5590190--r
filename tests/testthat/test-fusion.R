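mk_pair <- function(r1_chrom, r1_pos, r1_strand, r2_chrom, r2_pos, r2_strand,
                    r1_len = 100L, r2_len = 100L,
                    r1_cl = 0L, r1_cr = 0L, id = "p1") {
  data.frame(pair_id = id,
             r1_chrom = r1_chrom, r1_pos = as.integer(r1_pos),
             r1_strand = r1_strand, r1_aligned_len = as.integer(r1_len),
             r1_clip_left = as.integer(r1_cl), r1_clip_right = as.integer(r1_cr),
             r2_chrom = r2_chrom, r2_pos = as.integer(r2_pos),
             r2_strand = r2_strand, r2_aligned_len = as.integer(r2_len),
             r2_clip_left = 0L, r2_clip_right = 0L,
             stringsAsFactors = FALSE)
}

test_that("clipped-read extraction places breakpoints at clip boundaries", {
  # right clip: breakpoint at pos + aligned_len
  r <- mk_pair("chr1", 100L, "+", "chr2", 5000L, "-", r1_len = 80L, r1_cr = 20L)
  ev <- extract_clipped(r, min_clip = 10L)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$pos_a[ev$chrom_a == "chr1"], 180L)
  # left clip: breakpoint at pos
  r <- mk_pair("chr1", 100L, "-", "chr2", 5000L, "-", r1_len = 80L, r1_cl = 20L)
  ev <- extract_clipped(r, min_clip = 10L)
  expect_equal(ev$pos_a[ev$chrom_a == "chr1"], 100L)
  # no or short clips yield no evidence
  expect_equal(nrow(extract_clipped(mk_pair("chr1", 100L, "+", "chr1", 300L, "-"))), 0L)
  r <- mk_pair("chr1", 100L, "+", "chr2", 5000L, "-", r1_len = 95L, r1_cr = 5L)
  expect_equal(nrow(extract_clipped(r, min_clip = 10L)), 0L)
})

test_that("discordant selection implements the three keep rules", {
  # separate chromosomes: kept
  expect_equal(nrow(select_discordant(mk_pair("chr2", 100L, "+", "chr21", 100L, "-"))), 1L)
  # same chromosome, 1.5 kb apart, opposite strands: excluded
  expect_equal(nrow(select_discordant(mk_pair("chr2", 1000L, "+", "chr2", 2400L, "-"))), 0L)
  # same span but same direction: kept
  expect_equal(nrow(select_discordant(mk_pair("chr2", 1000L, "+", "chr2", 2400L, "+"))), 1L)
  # outer span just over 2 kb: kept
  expect_equal(nrow(select_discordant(mk_pair("chr2", 1000L, "+", "chr2", 2901L, "-"))), 1L)
  # outer span exactly 2 kb: concordant
  expect_equal(nrow(select_discordant(mk_pair("chr2", 1000L, "+", "chr2", 2900L, "-"))), 0L)
})

test_that("discordant selection equals the brute-force disjunction on random pairs", {
  set.seed(17)
  n <- 10000L
  pairs <- data.frame(
    pair_id = sprintf("r%05d", seq_len(n)),
    r1_chrom = sample(c("chr1", "chr2"), n, TRUE),
    r1_pos = sample.int(10000L, n, TRUE),
    r1_strand = sample(c("+", "-"), n, TRUE),
    r1_aligned_len = sample(50:150, n, TRUE),
    r1_clip_left = 0L, r1_clip_right = 0L,
    r2_chrom = sample(c("chr1", "chr2"), n, TRUE),
    r2_pos = sample.int(10000L, n, TRUE),
    r2_strand = sample(c("+", "-"), n, TRUE),
    r2_aligned_len = sample(50:150, n, TRUE),
    r2_clip_left = 0L, r2_clip_right = 0L,
    stringsAsFactors = FALSE)
  kept <- select_discordant(pairs)
  expected <- vapply(seq_len(n), function(i) {
    brute_force_discordant(pairs$r1_chrom[i], pairs$r1_pos[i],
                           pairs$r1_strand[i], pairs$r1_aligned_len[i],
                           pairs$r2_chrom[i], pairs$r2_pos[i],
                           pairs$r2_strand[i], pairs$r2_aligned_len[i])
  }, logical(1))
  expect_setequal(kept$pair_id, pairs$pair_id[expected])
})

test_that("breakpoint clustering groups nearby evidence deterministically", {
  ev <- data.frame(
    chrom_a = "chr1", pos_a = c(1000L, 1004L, 1010L),
    orient_a = "R", chrom_b = "chr9", pos_b = c(5000L, 5008L, 5003L),
    orient_b = "L", evidence = "split",
    pair_id = c("a", "b", "c"), stringsAsFactors = FALSE)
  cl <- cluster_breakpoints(ev, window = 50L)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_split, 3L)
  expect_equal(cl$pos_a, 1004L)  # median position
  # junctions 10 kb apart do not merge
  ev2 <- rbind(ev, within(ev, pos_a <- pos_a + 10000L))
  expect_equal(nrow(cluster_breakpoints(ev2, window = 50L)), 2L)
  # empty in, empty out
  expect_equal(nrow(cluster_breakpoints(ev[0L, ])), 0L)
})

test_that("junction geometry classifies into the four rearrangement kinds", {
  cl <- function(ca, pa, oa, cb, pb, ob)
    data.frame(chrom_a = ca, pos_a = pa, orient_a = oa,
               chrom_b = cb, pos_b = pb, orient_b = ob,
               stringsAsFactors = FALSE)
  expect_equal(classify_rearrangement(cl("chr2", 100L, "R", "chr21", 5e6, "L")),
               "translocation")
  expect_equal(classify_rearrangement(cl("chr2", 100L, "R", "chr2", 5e6, "R")),
               "inversion")
  expect_equal(classify_rearrangement(cl("chr7", 1e5, "R", "chr7", 2e5, "L")),
               "long_deletion")
  expect_equal(classify_rearrangement(cl("chr7", 1e5, "L", "chr7", 2e5, "R")),
               "tandem_duplication")
})

test_that("simulated junctions round-trip through the caller for every kind", {
  p <- toy_panel()
  alk <- p[p$gene == "ALK", ][1L, ]  # baited ALK intron bin
  inside_alk <- as.integer(alk$start + 50L)
  cases <- list(
    translocation = list(a = list(chrom = "chr7", pos = 55086800L, strand = "+"),
                         b = list(chrom = "chr2", pos = inside_alk, strand = "-")),
    inversion = list(a = list(chrom = "chr2", pos = 42396600L, strand = "+"),
                     b = list(chrom = "chr2", pos = inside_alk, strand = "+")),
    long_deletion = list(a = list(chrom = "chr2", pos = inside_alk, strand = "+"),
                         b = list(chrom = "chr2", pos = inside_alk + 100000L,
                                  strand = "-")))
  for (kind in names(cases)) {
    brk <- cases[[kind]]
    reads <- simulate_fusion_reads(brk$a, brk$b, n_split = 4L,
                                   n_discordant = 6L, n_background = 15L,
                                   seed = 31)
    res <- suppressMessages(call_fusions(reads, p))
    pass <- res[res$status == "PASS", ]
    expect_equal(nrow(pass), 1L)
    expect_equal(pass$rearrangement_kind, kind)
    # breakpoints recovered within the clustering window
    pos <- sort(c(pass$pos_a, pass$pos_b))
    truth <- sort(c(brk$a$pos, brk$b$pos))
    expect_true(all(abs(pos - truth) <= 50L))
    # one side is the baited ALK region
    expect_true("ALK" %in% c(pass$gene_a, pass$gene_b))
  }
})

test_that("support thresholds and panel restriction gate the calls", {
  p <- toy_panel()
  alk <- p[p$gene == "ALK", ][1L, ]
  inside <- as.integer(alk$start + 10L)
  # low support: below both defaults
  cl <- data.frame(chrom_a = "chr2", pos_a = inside, orient_a = "R",
                   chrom_b = "chr2", pos_b = inside + 50000L, orient_b = "L",
                   n_split = 1L, n_discordant = 1L, stringsAsFactors = FALSE)
  res <- call_fusions(cl, p)
  expect_equal(res$status, "low_support")
  # discordant support alone can rescue
  cl$n_discordant <- 5L
  expect_equal(call_fusions(cl, p)$status, "PASS")
  # both sides outside the panel: dropped
  cl2 <- cl
  cl2$chrom_a <- "chr22"; cl2$chrom_b <- "chr22"
  expect_message(res2 <- call_fusions(cl2, p), "outside the panel")
  expect_equal(nrow(res2), 0L)
  expect_equal(attr(res2, "n_outside_panel"), 1L)
})
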