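test_that("all generators are byte-identical under an identical config", {
  cfg <- tiny_config(seed = 7)
  model <- gen_genome_model(cfg)
  for (gen in list(
    function() gen_cell_table(cfg, "control"),
    function() gen_cell_table(cfg, "patient"),
    function() gen_cq_table(cfg),
    function() gen_genome_model(cfg),
    function() gen_plasma_counts(model, cfg),
    function() gen_ledger_fixture(cfg))) {
    expect_identical(gen(), gen())
  }
})

test_that("generator streams are independent of each other", {
  cfg <- tiny_config(seed = 7)
  a <- gen_cq_table(cfg)
  gen_cell_table(cfg, "control")  # interleave another generator
  expect_identical(gen_cq_table(cfg), a)
})

test_that("config validation rejects malformed parameters", {
  expect_error(tiny_config(background_rcp_rate = list(
    "KLK3" = c(0.5, 0.4), "AR-V7" = c(1, 0), "AR-FL" = c(1, 0))),
    "probability")
  expect_error(tiny_config(cq_sds = list(
    control = c(GUSB = -1, KLK3 = 1, `AR-FL` = 1, `AR-V7` = 1),
    patient = c(GUSB = 1, KLK3 = 1, `AR-FL` = 1, `AR-V7` = 1))),
    "negative Cq sd")
  expect_error(tiny_config(tumor_fraction = 1.2), "tumor_fraction")
  expect_error(tiny_config(bin_size = 0), "bin_size")
  expect_error(tiny_config(depth = 0), "depth")
  expect_error(tiny_config(
    amp_locus = list(chrom = "chr9", start = 0, end = 1e6, cn = 4)),
    "amp_locus")
})

test_that("degenerate background distribution yields all-zero counts", {
  cfg <- tiny_config(background_rcp_rate = list(
    "KLK3" = c(1, 0, 0, 0), "AR-V7" = c(1), "AR-FL" = c(1, 0)))
  cells <- gen_cell_table(cfg, "control")
  expect_true(all(cells$arv7_rcp == 0))
  expect_true(all(cells$arfl_rcp == 0))
})

test_that("background RCP frequencies converge to configured rates", {
  cfg <- sim_config(seed = 13, n_control_samples = 1,
                    n_control_cells = 30000)
  cells <- gen_cell_table(cfg, "control")
  n <- nrow(cells)
  for (marker in c("arv7_rcp", "arfl_rcp")) {
    p1 <- switch(marker, arv7_rcp = 0.0077, arfl_rcp = 0.0106)
    obs <- sum(cells[[marker]] == 1)
    expect_lt(abs(obs - n * p1), 3 * sqrt(n * p1 * (1 - p1)))
  }
})

test_that("patient tables mix background and tumor cells", {
  cfg <- tiny_config(seed = 2, n_cells_per_patient = 100, n_tumor_cells = 5)
  cells <- gen_cell_table(cfg, "patient")
  expect_equal(nrow(cells), cfg$n_patients * 105)
  # AR-FL-high tumor cells (mu = 9) are far outside background support (<= 3)
  per_patient <- tapply(cells$arfl_rcp > 3, cells$sample_id, sum)
  expect_true(all(per_patient >= 1))
})

test_that("Cq table has the configured shape and dropout structure", {
  cfg <- sim_config(seed = 3, n_controls_qpcr = 16, n_patients_qpcr = 16,
                    n_replicates = 2)
  cq <- gen_cq_table(cfg)
  expect_equal(length(unique(cq$sample_id)), 32)
  expect_equal(nrow(cq), 32 * 4 * 2)
  expect_setequal(unique(cq$gene), c("AR-V7", "AR-FL", "KLK3", "GUSB"))
  expect_false(anyNA(cq$cq[cq$gene == "GUSB"]))
  expect_true(all(cq$cq <= 45 & cq$cq > 0, na.rm = TRUE))

  all_drop <- gen_cq_table(tiny_config(dropout_prob = list(
    control = c(KLK3 = 0, `AR-FL` = 0, `AR-V7` = 1),
    patient = c(KLK3 = 0, `AR-FL` = 0, `AR-V7` = 1))))
  expect_true(all(is.na(all_drop$cq[all_drop$gene == "AR-V7"])))

  no_noise <- gen_cq_table(tiny_config(
    cq_sds = list(
      control = c(GUSB = 0, KLK3 = 0, `AR-FL` = 0, `AR-V7` = 0),
      patient = c(GUSB = 0, KLK3 = 0, `AR-FL` = 0, `AR-V7` = 0)),
    dropout_prob = list(
      control = c(KLK3 = 0, `AR-FL` = 0, `AR-V7` = 0),
      patient = c(KLK3 = 0, `AR-FL` = 0, `AR-V7` = 0))))
  spread <- tapply(no_noise$cq, paste(no_noise$sample_id, no_noise$gene),
                   function(x) diff(range(x, na.rm = TRUE)))
  expect_true(all(spread == 0, na.rm = TRUE))
})

test_that("genome bins tile each chromosome without gap or overlap", {
  cfg <- sim_config(seed = 1)
  model <- gen_genome_model(cfg)
  for (i in seq_len(nrow(cfg$genome))) {
    b <- model$bins[model$bins$chrom == cfg$genome$chrom[i], ]
    expect_equal(b$start[1], 0)
    expect_equal(b$end[nrow(b)], cfg$genome$length[i])
    expect_true(all(b$start[-1] == b$end[-nrow(b)]))
    expect_true(all(b$end > b$start))
    expect_true(all(b$gc >= 0 & b$gc <= 1))
  }
  expect_true(any(model$bins$masked))
  expect_true(all(model$bins$chrom[model$bins$masked] == "chrX"))
})

test_that("null genome counts are Poisson around the configured depth", {
  cfg <- sim_config(seed = 5, tumor_fraction = 0, gc_bias_amplitude = 0)
  model <- gen_genome_model(cfg)
  b <- gen_plasma_counts(model, cfg)
  auto <- b[b$chrom != "chrX", ]
  m <- mean(auto$count)
  expect_lt(abs(m - cfg$depth), 3 * sqrt(cfg$depth / nrow(auto)))
})

test_that("amplification locus counts follow the mixture expectation", {
  # clonal CN 4 on an autosome: expected locus count = 2 x depth
  cfg <- sim_config(seed = 5, tumor_fraction = 1, gc_bias_amplitude = 0,
                    amp_locus = list(chrom = "chr1", start = 2e6, end = 6e6,
                                     cn = 4))
  model <- gen_genome_model(cfg)
  b <- gen_plasma_counts(model, cfg)
  loc <- b$chrom == "chr1" & b$start >= 2e6 & b$start < 6e6
  m <- mean(b$count[loc])
  expect_lt(abs(m - 2 * cfg$depth), 3 * sqrt(2 * cfg$depth / sum(loc)))

  # subclonal blend: tf 0.2, CN 4 -> locus/flank expected ratio 1.2
  cfg2 <- sim_config(seed = 6, tumor_fraction = 0.2, gc_bias_amplitude = 0,
                     amp_locus = list(chrom = "chr1", start = 2e6, end = 6e6,
                                      cn = 4))
  b2 <- gen_plasma_counts(gen_genome_model(cfg2), cfg2)
  loc2 <- b2$chrom == "chr1" & b2$start >= 2e6 & b2$start < 6e6
  flank <- b2$chrom %in% c("chr2", "chr3")
  ratio <- mean(b2$count[loc2]) / mean(b2$count[flank])
  expect_lt(abs(ratio - 1.2), 0.05)
})

test_that("ledger fixture reproduces requested marginals exactly", {
  cfg <- sim_config(seed = 4)
  led <- gen_ledger_fixture(cfg)
  for (a in unique(led$assay)) {
    sub <- led[led$assay == a, ]
    expect_equal(sum(sub$result == "positive"),
                 unname(cfg$ledger$positives[[a]]))
    expect_equal(sum(sub$result != "not_assayed"),
                 length(cfg$ledger$assayed[[a]]))
  }
  cfg0 <- sim_config(seed = 4, ledger = utils::modifyList(
    sim_config()$ledger,
    list(positives = c(insitu_CTC = 0L, insitu_ARV7 = 0L, insitu_ARFL = 0L,
                       insitu_KLK3 = 0L, qpcr_ARV7 = 0L, qpcr_ARFL = 0L,
                       qpcr_KLK3 = 0L, ctdna_AR_amp = 0L))))
  expect_equal(informative_rate(gen_ledger_fixture(cfg0))$percent, 0)
})
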