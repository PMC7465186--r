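test_that("fragments are assigned to bins by their start coordinate", {
  cfg <- sim_config(seed = 1)
  model <- gen_genome_model(cfg)

  none <- bin_fragments(data.frame(chrom = character(0), start = numeric(0)),
                        model)
  expect_true(all(none$count == 0))

  # half-open boundary: a fragment starting exactly at 50,000 is in bin 2
  one <- bin_fragments(data.frame(chrom = "chr1", start = 50000), model)
  expect_equal(one$count[one$chrom == "chr1"][1:2], c(0, 1))

  uni <- bin_fragments(
    data.frame(chrom = "chr1",
               start = rep(seq(0, 12e6 - 50000, by = 50000), each = 10) + 100),
    model)
  expect_true(all(uni$count[uni$chrom == "chr1"] == 10))

  expect_warning(
    skipped <- bin_fragments(data.frame(chrom = c("chrZ", "chr1"),
                                        start = c(10, 10)), model),
    "skipped")
  expect_equal(sum(skipped$count), 1)
})

test_that("depth normalization centers unmasked autosomal bins at ratio 1", {
  b <- normalize_depth(make_bins(rep(7, 10)))
  expect_true(all(b$ratio == 1))

  b1 <- normalize_depth(make_bins(c(10, 10, 20, 10, 10)))
  expect_equal(b1$ratio, c(10, 10, 20, 10, 10) / 12)
  b2 <- normalize_depth(make_bins(2 * c(10, 10, 20, 10, 10)))
  expect_equal(b2$ratio, b1$ratio)  # scale invariance
  expect_equal(mean(b1$ratio), 1)

  # masked bins and chrX are excluded from the reference mean
  bx <- rbind(make_bins(rep(10, 6)),
              make_bins(rep(100, 4), chrom = "chrX"),
              make_bins(1000, masked = TRUE))
  expect_equal(normalize_depth(bx)$ratio[1], 1)

  expect_error(normalize_depth(make_bins(rep(0, 5))), "non-zero")
})

test_that("LOWESS correction flattens a known unimodal GC bias", {
  set.seed(8)
  n <- 1200
  gc <- runif(n, 0.3, 0.6)
  bias <- 1 - 0.3 * ((gc - 0.45) / 0.15)^2
  counts <- rpois(n, 600 * bias)
  b <- gc_correct(normalize_depth(make_bins(counts, gc = gc)))
  interior <- gc >= quantile(gc, 0.1) & gc <= quantile(gc, 0.9)
  refit <- lowess(gc[interior], b$ratio[interior], f = 0.3, iter = 2)
  expect_true(all(abs(refit$y - 1) < 0.02))

  # a copy-number spike superimposed on the bias survives correction
  cn <- rep(1, n)
  cn[200:240] <- 2
  spiked <- gc_correct(normalize_depth(
    make_bins(rpois(n, 600 * bias * cn), gc = gc)))
  expect_gt(mean(spiked$ratio[200:240]),
            mean(spiked$ratio[-(200:240)]) + 0.8)

  expect_warning(gc_correct(normalize_depth(
    make_bins(rpois(50, 100), gc = rep(0.45, 50)))), "degenerate GC")
  expect_error(gc_correct(normalize_depth(make_bins(rpois(10, 100)))),
               "at least 30")
})

test_that("segmentation recovers a clean step with the boundary within one bin", {
  set.seed(5)
  y <- c(rnorm(60, 0, 0.05), rnorm(20, 0.8, 0.05))
  b <- make_bins(rep(1, 80))
  b$log2_ratio <- y
  seg <- segment_log2(b)
  expect_equal(nrow(seg), 2)
  expect_lt(abs(seg$start[2] / 1e6 - 60), 1.5)  # boundary within +/- 1 bin
  expect_equal(seg$log2[1], mean(y[seq_len(seg$start[2] / 1e6)]))

  const <- make_bins(rep(1, 50))
  const$log2_ratio <- 0.3
  expect_equal(nrow(segment_log2(const)), 1)

  expect_error(segment_log2(const, penalty = 0), "penalty")
})

test_that("segmentation equals the exhaustive enumeration oracle on small instances", {
  set.seed(11)
  for (i in 1:40) {
    y <- random_segmentation_instance(max_n = 24)
    b <- make_bins(rep(1, length(y)))
    b$log2_ratio <- y
    seg <- segment_log2(b, penalty = 10)
    got <- seg$start / 1e6 + 1
    want <- oracle_segment_starts(y, 10 * var(y), 3L)
    expect_equal(as.integer(got), as.integer(want))
  }
})

test_that("flank means are length-weighted, pooled and truncated", {
  seg <- make_segments("chr1", c(0, 30e6, 31e6), c(30e6, 31e6, 61e6),
                       c(0, 0.5, 0))
  expect_equal(weighted_flank_mean(seg, 2), 0)

  seg2 <- make_segments("chr1", c(10e6, 30e6, 31e6), c(30e6, 31e6, 51e6),
                        c(0.2, 0.9, 0.4))
  expect_equal(weighted_flank_mean(seg2, 2), 0.3)  # equal 20 Mb flanks

  # target at the chromosome start: downstream flank only
  seg3 <- make_segments("chr1", c(0, 1e6), c(1e6, 30e6), c(0.7, 0.1))
  expect_equal(weighted_flank_mean(seg3, 1), 0.1)

  lone <- make_segments("chr1", 0, 1e6, 0.7)
  expect_true(is.na(weighted_flank_mean(lone, 1)))
})

test_that("the all-pass segment is called as a driver amplification", {
  fx <- focal_fixture()
  calls <- call_focal_events(fx$segments, fx$tracks)
  tg <- calls[fx$target, ]
  expect_true(tg$called)
  expect_equal(tg$class, "amplification")
  expect_true(tg$contains_driver)
  expect_true(all(unlist(tg[paste0("crit_", c("size", "magnitude", "genes",
                                              "contrast", "segdup",
                                              "known_cnv"))])))
  expect_false(any(calls$called[-fx$target]))
  expect_true(call_ar_amplification(calls))
})

test_that("each focal criterion can be violated in isolation", {
  crit_cols <- paste0("crit_", c("size", "magnitude", "genes", "contrast",
                                 "segdup", "known_cnv"))
  check_single_fault <- function(calls, target, failing) {
    tg <- calls[target, ]
    expect_false(tg$called)
    flags <- unlist(tg[crit_cols])
    expect_false(flags[[failing]])
    expect_true(all(flags[setdiff(crit_cols, failing)]))
  }

  # (1) size: stretch the target past 20 Mb
  fx <- focal_fixture()
  fx$segments$end[2] <- fx$segments$start[2] + 25e6
  fx$segments$start[3] <- fx$segments$end[2]
  check_single_fault(call_focal_events(fx$segments, fx$tracks), 2, "crit_size")

  # (2) magnitude: log2 0.15; flanks at -0.1 keep the driver contrast intact
  fx <- focal_fixture()
  fx$segments$log2 <- c(-0.1, 0.15, -0.1)
  check_single_fault(call_focal_events(fx$segments, fx$tracks), 2,
                     "crit_magnitude")

  # (3) genes: more than 100 genes over the segment
  fx <- focal_fixture()
  extra <- data.frame(chrom = "chr1",
                      start = seq(40.0e6, 40.99e6, length.out = 101),
                      end = seq(40.0e6, 40.99e6, length.out = 101) + 5e3,
                      name = sprintf("g%03d", 1:101), driver = FALSE)
  fx$tracks$genes <- rbind(fx$tracks$genes, extra)
  check_single_fault(call_focal_events(fx$segments, fx$tracks), 2,
                     "crit_genes")

  # (4) contrast: no driver gene -> the 0.58 margin applies and 0.5 fails
  fx <- focal_fixture()
  fx$tracks$genes$driver <- FALSE
  check_single_fault(call_focal_events(fx$segments, fx$tracks), 2,
                     "crit_contrast")

  # (5) segmental duplications covering > 50% of the segment
  fx <- focal_fixture()
  fx$tracks$segdups <- data.frame(chrom = "chr1", start = 40e6,
                                  end = 40.6e6)
  check_single_fault(call_focal_events(fx$segments, fx$tracks), 2,
                     "crit_segdup")

  # (6) known germline CNV covering >= 50% of the segment
  fx <- focal_fixture()
  fx$tracks$known_cnvs <- data.frame(chrom = "chr1", start = 40.2e6,
                                     end = 40.8e6)
  check_single_fault(call_focal_events(fx$segments, fx$tracks), 2,
                     "crit_known_cnv")
})

test_that("deletions are called with mirrored thresholds", {
  fx <- focal_fixture()
  fx$segments$log2[2] <- -0.5
  calls <- call_focal_events(fx$segments, fx$tracks)
  expect_true(calls$called[2])
  expect_equal(calls$class[2], "deletion")
  expect_false(call_ar_amplification(calls))  # deletion over AR is not an amp
})

test_that("AR amplification status requires a called amplification over AR", {
  fx <- focal_fixture()
  empty <- call_focal_events(fx$segments[1, , drop = FALSE], fx$tracks)
  expect_false(call_ar_amplification(empty))
})

test_that("naive tumor fraction inverts a single-copy gain", {
  flat <- make_segments(c("chr1", "chr2"), c(0, 0), c(50e6, 50e6), c(0, 0))
  est0 <- estimate_tumor_fraction_naive(flat)
  expect_equal(est0$tf, 0)
  expect_false(est0$quantifiable)

  # segment at ratio 1.1 (log2 ~ 0.1375) -> tf 0.2 by closed form
  seg <- make_segments(c("chr1", "chr1", "chr2"), c(0, 10e6, 0),
                       c(10e6, 50e6, 50e6), c(log2(1.1), 0, 0))
  est <- estimate_tumor_fraction_naive(seg)
  expect_equal(est$tf, 0.2, tolerance = 1e-12)
  expect_true(est$quantifiable)

  xonly <- make_segments("chrX", 0, 50e6, 0.4)
  expect_error(estimate_tumor_fraction_naive(xonly), "autosomal")
  tiny <- make_segments("chr1", 0, 1e6, 0.4)
  expect_error(estimate_tumor_fraction_naive(tiny), "min_span")
})

test_that("the full plasma pipeline recovers a spiked AR amplification", {
  cfg <- sim_config(seed = 17, tumor_fraction = 0.1,
                    amp_locus = list(chrom = "chrX", start = 7e6,
                                     end = 7.5e6, cn = 4))
  model <- gen_genome_model(cfg)
  res <- cnv_call(gen_plasma_counts(model, cfg), model$tracks)
  expect_true(res$ar_amplified)
  # without tumor content there is nothing to call
  null <- cnv_call(gen_plasma_counts(model, cfg, tumor_fraction = 0),
                   model$tracks)
  expect_false(null$ar_amplified)
})

test_that("tumor fraction is recovered from a simulated single-copy gain", {
  cfg <- sim_config(seed = 23, depth = 300, tumor_fraction = 0.2,
                    amp_locus = list(chrom = "chr1", start = 2e6, end = 7e6,
                                     cn = 3))
  model <- gen_genome_model(cfg)
  res <- cnv_call(gen_plasma_counts(model, cfg), model$tracks)
  expect_lt(abs(res$tf$tf - 0.2), 0.05)
  expect_true(res$tf$quantifiable)
})
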