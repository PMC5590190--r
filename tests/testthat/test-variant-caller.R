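test_that("observed MAF and strand fraction follow their definitions", {
  expect_equal(observed_maf(make_pileup(3L, 2L, 300L, 195L)), 0.01)
  expect_equal(observed_maf(make_pileup(0L, 0L, 50L, 50L)), 0)
  expect_equal(observed_maf(make_pileup(30L, 30L, 0L, 0L)), 1)
  expect_error(observed_maf(make_pileup(0L, 0L, 0L, 0L)), "zero depth")

  expect_equal(strand_fraction(make_pileup(19L, 1L, 100L, 100L)), 0.95)
  expect_equal(strand_fraction(make_pileup(5L, 5L, 100L, 100L)), 0.5)
  expect_equal(strand_fraction(make_pileup(0L, 10L, 100L, 100L)), 0)
  expect_true(is.na(strand_fraction(make_pileup(0L, 0L, 100L, 100L))))
})

test_that("boundary semantics of every gate match the stated rules", {
  th <- call_thresholds()
  # depth not less than 30: 29 fails, 30 passes
  expect_match(apply_filters(make_pileup(5L, 5L, 10L, 9L), th)$filters,
               "LOW_DEPTH")
  expect_false(grepl("LOW_DEPTH",
                     apply_filters(make_pileup(5L, 5L, 10L, 10L), th)$filters))
  # MAF cut is strict: exactly 1% fails, just above passes
  c1 <- apply_filters(make_pileup(3L, 2L, 300L, 195L), th)  # 5/500 = 0.01
  expect_match(c1$filters, "LOW_MAF")
  c2 <- apply_filters(make_pileup(3L, 3L, 300L, 194L), th)  # 6/500
  expect_true(c2$pass)
  # hotspot relaxation: 0.007 passes at a hotspot (0.007 > 0.005)
  c3 <- apply_filters(make_pileup(4L, 3L, 500L, 493L), th, hotspot = TRUE)
  expect_true(c3$pass)
  c4 <- apply_filters(make_pileup(4L, 3L, 500L, 493L), th, hotspot = FALSE)
  expect_match(c4$filters, "LOW_MAF")
  # normal control: 0.03 is the allowed maximum, 0.04 fails
  c5 <- apply_filters(make_pileup(25L, 25L, 225L, 225L,
                                  normal_alt = 4L, normal_depth = 100L), th)
  expect_match(c5$filters, "NORMAL_EVIDENCE")
  c6 <- apply_filters(make_pileup(25L, 25L, 225L, 225L,
                                  normal_alt = 3L, normal_depth = 100L), th)
  expect_true(c6$pass)
  # strand bias: fraction above 0.9 or below 0.1 fails; a single alt
  # read is never tested
  c7 <- apply_filters(make_pileup(19L, 1L, 240L, 240L), th)
  expect_match(c7$filters, "STRAND_BIAS")
  c8 <- apply_filters(make_pileup(1L, 0L, 250L, 249L), th)
  expect_false(grepl("STRAND_BIAS", c8$filters))
  # repeat-tract indels need MAF >= 2% and >= 8 alt reads
  rep_lo <- apply_filters(make_pileup(4L, 3L, 250L, 243L), th,
                          in_repeat = TRUE, var_kind = "indel")  # 7 reads, 1.4%
  expect_match(rep_lo$filters, "LOW_MAF")
  rep_ok <- apply_filters(make_pileup(5L, 5L, 245L, 245L), th,
                          in_repeat = TRUE, var_kind = "indel")  # 10 reads, 2%
  expect_true(rep_ok$pass)
  # negative counts rejected
  expect_error(apply_filters(make_pileup(-1L, 0L, 10L, 10L), th), "negative")
})

test_that("filter cascade agrees with the brute-force predicate on a depth<=60 grid", {
  th <- call_thresholds()
  grid <- expand.grid(
    depth = c(0L, 1L, 5L, 20L, 29L, 30L, 31L, 45L, 60L),
    alt_bucket = 0:6,
    fwd_share = c(0, 0.25, 0.5, 1),
    normal_alt = c(0L, 1L, 3L, 4L, 20L),
    normal_depth = c(0L, 100L),
    hotspot = c(FALSE, TRUE),
    repeat_indel = c(FALSE, TRUE))
  grid$alt <- pmin(grid$alt_bucket * 10L, grid$depth)
  grid$alt_fwd <- as.integer(floor(grid$alt * grid$fwd_share))
  mism <- 0L
  pu <- make_pileup(grid$alt_fwd, grid$alt - grid$alt_fwd,
                    as.integer(ceiling((grid$depth - grid$alt) / 2)),
                    as.integer(floor((grid$depth - grid$alt) / 2)),
                    normal_alt = pmin(grid$normal_alt, grid$normal_depth),
                    normal_depth = grid$normal_depth)
  calls <- apply_filters(pu, th, hotspot = grid$hotspot,
                         in_repeat = grid$repeat_indel,
                         var_kind = ifelse(grid$repeat_indel, "indel", "SNV"))
  expected <- vapply(seq_len(nrow(grid)), function(i) {
    brute_force_filters(pu$alt_fwd[i], pu$alt_rev[i], pu$ref_fwd[i],
                        pu$ref_rev[i], pu$normal_alt[i], pu$normal_depth[i],
                        hotspot = grid$hotspot[i],
                        in_repeat = grid$repeat_indel[i],
                        indel = grid$repeat_indel[i])
  }, character(1))
  expect_identical(calls$filters, expected)
})

test_that("hotspot relaxation and alt-count monotonicity hold", {
  th <- call_thresholds()
  set.seed(11)
  n <- 300L
  depth <- sample(30:400, n, replace = TRUE)
  alt <- vapply(depth, function(d) sample(0:d, 1L), integer(1))
  alt_fwd <- vapply(alt, function(a) sample(0:a, 1L), integer(1))
  ref <- depth - alt
  pu <- make_pileup(alt_fwd, alt - alt_fwd,
                    as.integer(ceiling(ref / 2)), as.integer(floor(ref / 2)),
                    normal_alt = sample(0:3, n, replace = TRUE),
                    normal_depth = 200L)
  plain <- apply_filters(pu, th, hotspot = FALSE)
  hot <- apply_filters(pu, th, hotspot = TRUE)
  # every PASS without the hotspot flag remains PASS with it
  expect_true(all(hot$pass[plain$pass]))
  # adding alt reads on both strands (ref fixed) never loses PASS
  pu2 <- pu
  pu2$alt_fwd <- pu$alt_fwd + 5L
  pu2$alt_rev <- pu$alt_rev + 5L
  more <- apply_filters(pu2, th, hotspot = FALSE)
  expect_true(all(more$pass[plain$pass]))
})

test_that("posterior score matches numeric integration and orders sensibly", {
  # P(p > e | alt, depth) under Beta(a, b) prior, by direct integration
  numeric_post <- function(alt, depth, a, b, e = 0.001) {
    stats::integrate(function(p) stats::dbeta(p, a + alt, b + depth - alt),
                     e, 1)$value
  }
  cases <- data.frame(alt = c(0L, 5L, 100L, 400L),
                      depth = c(1000L, 200L, 200L, 400L))
  for (i in seq_len(nrow(cases))) {
    pu <- make_pileup(cases$alt[i], 0L, cases$depth[i] - cases$alt[i], 0L)
    expect_equal(posterior_variant_prob(pu),
                 numeric_post(cases$alt[i], cases$depth[i], 1, 99),
                 tolerance = 1e-6)
  }
  # no evidence: below one half; strong evidence: essentially one
  expect_lt(posterior_variant_prob(make_pileup(0L, 0L, 500L, 500L)), 0.5)
  expect_gt(posterior_variant_prob(make_pileup(50L, 50L, 50L, 50L)), 0.999)
  # hotspot prior can only raise the posterior
  pu <- make_pileup(2L, 1L, 200L, 197L)
  expect_gte(posterior_variant_prob(pu, hotspot = TRUE),
             posterior_variant_prob(pu, hotspot = FALSE))
  # monotone in alt count at fixed depth
  post <- vapply(0:30, function(a)
    posterior_variant_prob(make_pileup(a, 0L, 100L - a, 0L)), numeric(1))
  expect_true(all(diff(post) >= 0))
})

test_that("call_variants restricts to the panel and annotates hotspots", {
  p <- flat_panel(n_bins = 10L)  # chr1 [0, 1000)
  pu <- make_pileup(c(10L, 10L, 10L), c(10L, 10L, 10L),
                    c(240L, 240L, 240L), c(240L, 240L, 240L),
                    chrom = "chr1", pos = c(100L, 5000L, 200L))
  expect_message(calls <- call_variants(pu, p), "outside the panel")
  expect_equal(nrow(calls), 2L)
  expect_equal(attr(calls, "n_outside_panel"), 1L)
  # empty input, empty output
  empty <- call_variants(pu[0L, ], p)
  expect_equal(nrow(empty), 0L)
  # hotspot annotation by exact allele match
  hs <- data.frame(chrom = "chr1", pos = 100L, ref = "A", alt = "T")
  calls <- call_variants(pu[c(1L, 3L), ], p, hotspots = hs)
  expect_equal(calls$is_hotspot, c(TRUE, FALSE))
  # positional matching behind the flag
  hs2 <- data.frame(chrom = "chr1", pos = 100L, ref = "G", alt = "C")
  calls2 <- call_variants(pu[c(1L, 3L), ], p, hotspots = hs2,
                          hotspot_match = "position")
  expect_equal(calls2$is_hotspot, c(TRUE, FALSE))
})
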