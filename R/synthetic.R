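# Seed offsets: one independent RNG stream per generator, so adding or
# re-running one generator never perturbs the draws of another.
.rng_offsets <- c(cells_control = 101L, cells_patient = 102L, cq = 103L,
                  genome = 104L, plasma = 105L, ledger = 106L)

.qpcr_targets <- c("AR-V7", "AR-FL", "KLK3")

#' Configuration for the synthetic liquid-biopsy cohort
#'
#' Bundles and validates every parameter of the synthetic generators. The
#' defaults emulate the study conditions of the assays this package
#' implements: PBMC background RCP rates matching the published healthy
#' control distributions, VCaP-like tumor-cell expression, a 19-patient
#' cohort with 16 qPCR samples and 10 plasma samples, 50 kb genome bins at
#' ~180 fragments per diploid bin (11.3 M reads over a 50 kb-binned genome),
#' and an AR-like driver amplification on a haploid chrX surrogate.
#'
#' @param seed integer seed; every generator derives its own stream from it.
#' @param n_control_samples,n_control_cells in situ control samples and
#'   analyzed cells per control sample.
#' @param background_rcp_rate marker-named list of probability vectors over
#'   RCP counts `0..k` for background (non-tumor) cells.
#' @param tumor_cell_params list with marker-named `mu` and `size` of the
#'   negative-binomial RCP count distribution of tumor cells.
#' @param n_patients,n_cells_per_patient,n_tumor_cells in situ patient
#'   samples, background cells analyzed per patient, and spiked tumor cells
#'   per patient sample.
#' @param n_controls_qpcr,n_patients_qpcr,n_replicates qPCR cohort sizes and
#'   technical replicates per reaction.
#' @param cq_means,cq_sds per-group (control/patient), gene-named Cq means
#'   and standard deviations (cycles), including the reference gene GUSB.
#' @param dropout_prob per-group, gene-named probability that a target
#'   reaction yields no amplification (the reference gene never drops out).
#' @param genome data frame `chrom`, `length` (bp) of the miniature genome.
#' @param bin_size genomic bin width in bp (default 50,000).
#' @param depth expected fragments per diploid bin.
#' @param gc_bias_amplitude relative depth loss at the extremes of the GC
#'   range of the unimodal multiplicative GC bias curve (0 = no bias).
#' @param tumor_fraction fraction of plasma DNA derived from tumor, in
#'   `[0, 1]`.
#' @param amp_locus list `chrom`, `start`, `end`, `cn`: the spiked focal
#'   amplification (total copy number `cn` in tumor cells).
#' @param haploid_x simulate a single-copy chrX (male genome)?
#' @param par_mask_bp span at the chrX start emitted with the masked flag
#'   (pseudoautosomal surrogate).
#' @param n_plasma,amp_prevalence plasma samples in the full-cohort run and
#'   the fraction of them carrying the amplification.
#' @param ledger marginals of the synthetic assay ledger: list with
#'   `n_patients`, `assayed` (assay-named patient index vectors) and
#'   `positives` (assay-named positive counts).
#' @return Validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 7, n_control_cells = 500)
#' head(gen_cell_table(cfg, "control"))
sim_config <- function(
    seed = 1L,
    n_control_samples = 2L,
    n_control_cells = 30000L,
    background_rcp_rate = list(
      "KLK3" = c(1, 0, 0, 0),
      "AR-V7" = c(0.9923, 0.0077, 0, 0),
      "AR-FL" = c(0.9891, 0.0106, 0.0003, 0)),
    tumor_cell_params = list(
      mu = c("KLK3" = 0.01, "AR-V7" = 2.6, "AR-FL" = 9),
      size = c("KLK3" = 0.5, "AR-V7" = 1.5, "AR-FL" = 3)),
    n_patients = 19L,
    n_cells_per_patient = 2000L,
    n_tumor_cells = 3L,
    n_controls_qpcr = 16L,
    n_patients_qpcr = 16L,
    n_replicates = 2L,
    cq_means = list(
      control = c("GUSB" = 25, "KLK3" = 40, "AR-FL" = 37.5, "AR-V7" = 43),
      patient = c("GUSB" = 25, "KLK3" = 36, "AR-FL" = 35.5, "AR-V7" = 41)),
    cq_sds = list(
      control = c("GUSB" = 0.8, "KLK3" = 1.5, "AR-FL" = 1.5, "AR-V7" = 1.5),
      patient = c("GUSB" = 0.8, "KLK3" = 1.5, "AR-FL" = 1.5, "AR-V7" = 1.5)),
    dropout_prob = list(
      control = c("KLK3" = 0, "AR-FL" = 0, "AR-V7" = 0.5625),
      patient = c("KLK3" = 0, "AR-FL" = 0, "AR-V7" = 0.5625)),
    genome = data.frame(
      chrom = c("chr1", "chr2", "chr3", "chrX"),
      length = c(12e6, 12e6, 12e6, 15e6)),
    bin_size = 50000L,
    depth = 180,
    gc_bias_amplitude = 0.3,
    tumor_fraction = 0.1,
    amp_locus = list(chrom = "chrX", start = 7e6, end = 7.5e6, cn = 8),
    haploid_x = TRUE,
    par_mask_bp = 150000L,
    n_plasma = 10L,
    amp_prevalence = 0.5,
    ledger = list(
      n_patients = 19L,
      assayed = list(
        insitu_CTC = 1:19, insitu_ARV7 = 1:19, insitu_ARFL = 1:19,
        insitu_KLK3 = 1:19, qpcr_ARV7 = 1:16, qpcr_ARFL = 1:16,
        qpcr_KLK3 = 1:16, ctdna_AR_amp = 1:10),
      positives = c(
        insitu_CTC = 10L, insitu_ARV7 = 10L, insitu_ARFL = 3L,
        insitu_KLK3 = 4L, qpcr_ARV7 = 1L, qpcr_ARFL = 5L,
        qpcr_KLK3 = 6L, ctdna_AR_amp = 5L))) {
  cfg <- list(
    seed = as.integer(seed),
    n_control_samples = n_control_samples,
    n_control_cells = n_control_cells,
    background_rcp_rate = background_rcp_rate,
    tumor_cell_params = tumor_cell_params,
    n_patients = n_patients,
    n_cells_per_patient = n_cells_per_patient,
    n_tumor_cells = n_tumor_cells,
    n_controls_qpcr = n_controls_qpcr,
    n_patients_qpcr = n_patients_qpcr,
    n_replicates = n_replicates,
    cq_means = cq_means, cq_sds = cq_sds, dropout_prob = dropout_prob,
    genome = genome, bin_size = bin_size, depth = depth,
    gc_bias_amplitude = gc_bias_amplitude,
    tumor_fraction = tumor_fraction, amp_locus = amp_locus,
    haploid_x = haploid_x, par_mask_bp = par_mask_bp,
    n_plasma = n_plasma, amp_prevalence = amp_prevalence,
    ledger = ledger)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  for (m in names(cfg$background_rcp_rate)) {
    p <- cfg$background_rcp_rate[[m]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop("background_rcp_rate for ", m,
           " is not a probability vector (non-negative, summing to 1)")
    }
  }
  for (grp in names(cfg$cq_sds)) {
    if (any(cfg$cq_sds[[grp]] < 0)) stop("negative Cq sd for group ", grp)
    if (any(cfg$dropout_prob[[grp]] < 0 | cfg$dropout_prob[[grp]] > 1)) {
      stop("dropout_prob for group ", grp, " outside [0, 1]")
    }
  }
  if (cfg$tumor_fraction < 0 || cfg$tumor_fraction > 1) {
    stop("tumor_fraction must lie in [0, 1]")
  }
  if (cfg$bin_size <= 0) stop("bin_size must be positive")
  if (cfg$depth <= 0) stop("depth must be positive")
  gi <- match(cfg$amp_locus$chrom, cfg$genome$chrom)
  if (is.na(gi) || cfg$amp_locus$start < 0 ||
      cfg$amp_locus$end > cfg$genome$length[gi] ||
      cfg$amp_locus$end <= cfg$amp_locus$start) {
    stop("amp_locus does not lie within the model genome")
  }
  invisible(cfg)
}

#' Generate a synthetic per-cell RCP count table
#'
#' Control samples draw every cell's per-marker RCP count independently from
#' the configured background occupancy probabilities. Patient samples mix
#' the same background cells with `n_tumor_cells` tumor cells whose counts
#' follow the configured negative-binomial marker distributions.
#'
#' @param config [sim_config()] object.
#' @param group `"control"` or `"patient"`.
#' @return Cells data frame (`sample_id`, `cell_id`, `source`, `klk3_rcp`,
#'   `arv7_rcp`, `arfl_rcp`); byte-identical for identical configs.
#' @export
gen_cell_table <- function(config, group = c("control", "patient")) {
  group <- match.arg(group)
  validate_sim_config(config)
  offset <- if (group == "control") .rng_offsets[["cells_control"]] else
    .rng_offsets[["cells_patient"]]
  with_rng(config$seed + offset, {
    draw_background <- function(n) {
      cols <- lapply(marker_names(), function(m) {
        p <- config$background_rcp_rate[[m]]
        sample(seq_along(p) - 1L, n, replace = TRUE, prob = p)
      })
      matrix(unlist(cols), ncol = length(cols))
    }
    build <- function(sample_id, source, n_bg, n_tumor = 0L) {
      counts <- draw_background(n_bg)
      if (n_tumor > 0L) {
        tumor <- lapply(marker_names(), function(m) {
          as.integer(stats::rnbinom(
            n_tumor, mu = config$tumor_cell_params$mu[[m]],
            size = config$tumor_cell_params$size[[m]]))
        })
        counts <- rbind(counts, matrix(unlist(tumor), ncol = length(tumor)))
      }
      n <- nrow(counts)
      data.frame(sample_id = rep(sample_id, n),
                 cell_id = sprintf("%s_c%05d", sample_id, seq_len(n)),
                 source = source,
                 klk3_rcp = counts[, 1L], arv7_rcp = counts[, 2L],
                 arfl_rcp = counts[, 3L], stringsAsFactors = FALSE)
    }
    if (group == "control") {
      do.call(rbind, lapply(seq_len(config$n_control_samples), function(i) {
        build(sprintf("HC%02d", i), "slide", config$n_control_cells)
      }))
    } else {
      do.call(rbind, lapply(seq_len(config$n_patients), function(i) {
        build(sprintf("P%02d", i), "collector", config$n_cells_per_patient,
              config$n_tumor_cells)
      }))
    }
  })
}

# Truncated-normal sampler on (lo, hi] via inverse CDF; sd = 0 degenerates
# to the (clamped) mean.
rtrunc_norm <- function(n, mean, sd, lo = 0, hi = 45) {
  if (sd == 0) return(rep(min(max(mean, lo + 1e-9), hi), n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Generate a synthetic qPCR Cq table
#'
#' Per sample, gene and technical replicate, Cq values are drawn from a
#' normal distribution truncated to (0, 45] cycles. With the configured
#' per-gene dropout probability a target reaction yields no amplification
#' and is emitted as missing (`NA`) — the 46-cycle imputation is the
#' analysis module's job, see [impute_no_amplification()]. The reference
#' gene GUSB never drops out.
#'
#' @param config [sim_config()] object.
#' @return Cq data frame (`sample_id`, `group`, `gene`, `replicate`, `cq`).
#' @export
gen_cq_table <- function(config) {
  validate_sim_config(config)
  with_rng(config$seed + .rng_offsets[["cq"]], {
    genes <- c(.qpcr_targets, "GUSB")
    rows <- list()
    emit <- function(sample_id, grp) {
      for (g in genes) {
        cq <- rtrunc_norm(config$n_replicates,
                          config$cq_means[[grp]][[g]],
                          config$cq_sds[[grp]][[g]])
        if (g != "GUSB") {
          p_drop <- config$dropout_prob[[grp]][[g]]
          cq[stats::runif(config$n_replicates) < p_drop] <- NA_real_
        }
        rows[[length(rows) + 1L]] <<- data.frame(
          sample_id = sample_id, group = grp, gene = g,
          replicate = seq_len(config$n_replicates), cq = cq,
          stringsAsFactors = FALSE)
      }
    }
    for (i in seq_len(config$n_controls_qpcr)) emit(sprintf("HC%02d", i), "control")
    for (i in seq_len(config$n_patients_qpcr)) emit(sprintf("P%02d", i), "patient")
    do.call(rbind, rows)
  })
}

gc_bias_curve <- function(gc, amplitude) {
  pmax(1 - amplitude * ((gc - 0.45) / 0.15)^2, 0.05)
}

#' Generate the miniature genome model
#'
#' Tiles each configured chromosome with `bin_size` windows (0-based
#' half-open; the last bin of a chromosome may be shorter), assigns each bin
#' a smoothly varying GC fraction, flags a pseudoautosomal-like masked span
#' at the chrX start, and lays down annotation tracks: genes (with the AR
#' driver inside the configured amplification locus plus autosomal drivers),
#' segmental duplications and known germline CNV regions.
#'
#' @param config [sim_config()] object.
#' @return List of class `genome_model`: `bins` (chrom, start, end, gc,
#'   masked), `genome`, and `tracks` (`genes` with `name`/`driver`,
#'   `segdups`, `known_cnvs`), all 0-based half-open.
#' @export
gen_genome_model <- function(config) {
  validate_sim_config(config)
  with_rng(config$seed + .rng_offsets[["genome"]], {
    bins <- do.call(rbind, lapply(seq_len(nrow(config$genome)), function(i) {
      chrom <- config$genome$chrom[i]
      len <- config$genome$length[i]
      start <- seq(0, len - 1, by = config$bin_size)
      end <- pmin(start + config$bin_size, len)
      mid <- (start + end) / 2
      gc <- 0.45 + 0.1 * sin(2 * pi * mid / 4e6 + i) +
        stats::rnorm(length(start), 0, 0.03)
      gc <- pmin(pmax(gc, 0.28), 0.62)
      masked <- chrom == "chrX" & start < config$par_mask_bp
      data.frame(chrom = chrom, start = start, end = end, gc = gc,
                 masked = masked, stringsAsFactors = FALSE)
    }))
    genes <- do.call(rbind, lapply(seq_len(nrow(config$genome)), function(i) {
      chrom <- config$genome$chrom[i]
      len <- config$genome$length[i]
      n_genes <- floor(len / 4e5)
      start <- sort(round(stats::runif(n_genes, 0, len - 2e5)))
      width <- round(stats::runif(n_genes, 3e4, 1.5e5))
      data.frame(chrom = chrom, start = start,
                 end = pmin(start + width, len),
                 name = sprintf("%s_g%02d", chrom, seq_len(n_genes)),
                 driver = FALSE, stringsAsFactors = FALSE)
    }))
    # driver genes: AR inside the amplification locus, two autosomal drivers
    amp <- config$amp_locus
    drivers <- data.frame(
      chrom = c(amp$chrom, "chr1", "chr2"),
      start = c(amp$start + 2e4, 3e6, 5e6),
      end = c(min(amp$start + 2e5, amp$end), 3.1e6, 5.1e6),
      name = c("AR", "MYC_like", "PTEN_like"),
      driver = TRUE, stringsAsFactors = FALSE)
    drivers <- drivers[drivers$chrom %in% config$genome$chrom, , drop = FALSE]
    genes <- rbind(genes, drivers)
    genes <- genes[order(match(genes$chrom, config$genome$chrom), genes$start), ]
    segdups <- data.frame(
      chrom = c("chr1", "chr3"), start = c(9e6, 1e6),
      end = c(9.25e6, 1.4e6), stringsAsFactors = FALSE)
    known_cnvs <- data.frame(
      chrom = c("chr2", "chr3"), start = c(2e6, 8e6),
      end = c(2.6e6, 8.4e6), stringsAsFactors = FALSE)
    segdups <- segdups[segdups$chrom %in% config$genome$chrom, , drop = FALSE]
    known_cnvs <- known_cnvs[known_cnvs$chrom %in% config$genome$chrom, , drop = FALSE]
    structure(list(bins = bins, genome = config$genome,
                   tracks = list(genes = genes, segdups = segdups,
                                 known_cnvs = known_cnvs)),
              class = "genome_model")
  })
}

#' Generate synthetic plasma fragment counts per genomic bin
#'
#' The expected count of each bin is `depth * CN/2 * bias(gc)`, where the
#' local copy number blends the tumor copy number into the germline
#' background at the given tumor fraction: `CN = tf * cn_amp + (1 - tf) *
#' cn_base`, with `cn_base = 1` on a haploid chrX and 2 elsewhere, and
#' `cn_amp` equal to the amplification locus' total copy number inside the
#' locus (baseline elsewhere). Observed counts are Poisson. Masked bins are
#' emitted with their flag and a count, but are ignored downstream.
#'
#' @param model [gen_genome_model()] output.
#' @param config [sim_config()] object.
#' @param tumor_fraction,amp override the configured tumor fraction or drop
#'   the amplification entirely (`amp = FALSE`).
#' @param rng_offset offset added to the seed, letting callers draw
#'   independent replicate samples from one config.
#' @return Bin counts data frame: `chrom`, `start`, `end`, `gc`, `count`,
#'   `masked`.
#' @export
gen_plasma_counts <- function(model, config, tumor_fraction = NULL,
                              amp = TRUE,
                              rng_offset = .rng_offsets[["plasma"]]) {
  validate_sim_config(config)
  tf <- if (is.null(tumor_fraction)) config$tumor_fraction else tumor_fraction
  if (tf < 0 || tf > 1) stop("tumor_fraction must lie in [0, 1]")
  bins <- model$bins
  with_rng(config$seed + rng_offset, {
    cn_base <- ifelse(!is_autosome(bins$chrom) & config$haploid_x, 1, 2)
    cn_tumor <- cn_base
    if (amp) {
      loc <- config$amp_locus
      hit <- bins$chrom == loc$chrom & bins$start < loc$end &
        bins$end > loc$start
      cn_tumor[hit] <- loc$cn
    }
    cn <- tf * cn_tumor + (1 - tf) * cn_base
    expected <- config$depth * cn / 2 *
      gc_bias_curve(bins$gc, config$gc_bias_amplitude)
    bins$count <- stats::rpois(nrow(bins), expected)
    bins[, c("chrom", "start", "end", "gc", "count", "masked")]
  })
}

.ledger_assays <- c("insitu_CTC", "insitu_ARV7", "insitu_ARFL", "insitu_KLK3",
                    "qpcr_ARV7", "qpcr_ARFL", "qpcr_KLK3", "ctdna_AR_amp")

#' Generate a synthetic per-patient assay ledger
#'
#' Draws a tri-state (positive / negative / not_assayed) patient-by-assay
#' matrix with exactly the configured marginals: each assay is positive in
#' `positives[assay]` patients sampled uniformly among its assayed patients,
#' and `not_assayed` elsewhere. This is a fixture for the integration
#' arithmetic, not a joint model of assay dependence.
#'
#' @param config [sim_config()] object (`config$ledger` holds the marginals).
#' @return Long-format ledger data frame: `patient_id`, `assay`, `result`.
#' @export
gen_ledger_fixture <- function(config) {
  validate_sim_config(config)
  spec <- config$ledger
  with_rng(config$seed + .rng_offsets[["ledger"]], {
    patients <- sprintf("P%02d", seq_len(spec$n_patients))
    rows <- lapply(.ledger_assays, function(a) {
      assayed <- spec$assayed[[a]]
      n_pos <- spec$positives[[a]]
      if (n_pos > length(assayed)) {
        stop("requested more positives than assayed patients for ", a)
      }
      res <- rep("not_assayed", spec$n_patients)
      res[assayed] <- "negative"
      res[sample(assayed, n_pos)] <- "positive"
      data.frame(patient_id = patients, assay = a, result = res,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
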