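stage_msg <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(fmt, ...))
}

#' Run the full multi-analyte pipeline on a synthetic cohort
#'
#' Orchestrates one reproducible end-to-end run: simulate all inputs from
#' the configuration, derive CTC cut-offs from controls and call patient
#' CTCs, run the delta-Cq qPCR arm, run the plasma copy-number arm for every
#' plasma sample, assemble the per-patient ledger and compute the
#' integration report. Every artifact is written as plain text under
#' `outdir`, and `manifest.json` records the configuration echo, seed,
#' package version and an MD5 checksum of every file, so a rerun with the
#' same configuration is byte-identical.
#'
#' The simulated plasma samples carry the configured amplification with
#' probability `amp_prevalence` (decided per patient from the seeded RNG);
#' each sample gets its own derived RNG stream.
#'
#' @param config [sim_config()] object.
#' @param outdir output directory (created if missing).
#' @param quiet suppress per-stage progress messages?
#' @param resume skip the simulation stage and analyze the input files
#'   already present in `outdir`?
#' @return Invisibly, a list with the `ledger`, the `report`
#'   ([integration_report()]), per-plasma-sample CNV results, and the
#'   manifest.
#' @export
run_all <- function(config = sim_config(), outdir, quiet = FALSE,
                    resume = FALSE) {
  if (missing(outdir)) stop("outdir is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  t0 <- proc.time()[["elapsed"]]
  plasma_patients <- sprintf("P%02d", seq_len(config$n_plasma))

  ## stage 1: simulate -------------------------------------------------
  if (!resume) {
    stage_msg(quiet, "[simulate] generating cohort (seed %d)", config$seed)
    model <- gen_genome_model(config)
    control_cells <- gen_cell_table(config, "control")
    patient_cells <- gen_cell_table(config, "patient")
    cq <- gen_cq_table(config)
    write_cells(control_cells, p("controls.tsv"))
    write_cells(patient_cells, p("cells.tsv"))
    write_cq(cq, p("cq.csv"))
    write_bed(model$tracks$genes, p("genes.bed"))
    write_bed(model$tracks$segdups, p("segdups.bed"))
    write_bed(model$tracks$known_cnvs, p("known_cnv.bed"))
    amp_present <- with_rng(config$seed + 301L,
                            stats::runif(config$n_plasma) < config$amp_prevalence)
    names(amp_present) <- plasma_patients
    for (i in seq_along(plasma_patients)) {
      b <- gen_plasma_counts(model, config, amp = amp_present[i],
                             rng_offset = 400L + i)
      write_bins(b, p(sprintf("bins_%s.tsv", plasma_patients[i])))
    }
    write_json_file(config_echo(config), p("config.json"))
  }

  ## stage 2: in situ CTC arm ------------------------------------------
  stage_msg(quiet, "[ctc-call] deriving cut-offs and calling CTCs")
  control_cells <- read_cells(p("controls.tsv"))
  cutoffs <- derive_cutoffs(control_cells)
  calls <- call_ctcs(read_cells(p("cells.tsv")), cutoffs)
  write_cells(calls, p("calls.tsv"))
  ctc_summaries <- do.call(rbind, lapply(unique(calls$sample_id), function(s) {
    summarize_patient(calls, s)
  }))
  write_tsv(ctc_summaries, p("patient_summary.tsv"))
  dist <- summarize_distribution(control_cells)
  write_tsv(dist$bins, p("distribution.tsv"))

  ## stage 3: qPCR arm --------------------------------------------------
  stage_msg(quiet, "[qpcr-call] delta-Cq normalization and thresholding")
  cq_in <- impute_no_amplification(read_cq(p("cq.csv")))
  deltas <- compute_delta_cq(cq_in)
  thresholds <- derive_thresholds(deltas[deltas$group == "control", ])
  expr_calls <- call_expression(deltas[deltas$group == "patient", ],
                                thresholds)
  write_tsv(deltas, p("delta_cq.tsv"))
  write_json_file(as.list(unclass(thresholds)), p("thresholds.json"))
  write_tsv(expr_calls, p("expression_calls.tsv"))

  ## stage 4: plasma copy-number arm ------------------------------------
  stage_msg(quiet, "[cnv-call] plasma copy-number analysis (%d samples)",
            length(plasma_patients))
  for (f in c("genes.bed", "segdups.bed", "known_cnv.bed")) {
    if (!file.exists(p(f))) {
      stop("cnv stage: required annotation file not found: ", p(f))
    }
  }
  tracks <- list(genes = read_bed(p("genes.bed")),
                 segdups = read_bed(p("segdups.bed")),
                 known_cnvs = read_bed(p("known_cnv.bed")))
  cnv_results <- list()
  ar_amp <- logical(0)
  for (pt in plasma_patients) {
    res <- cnv_call(read_bins(p(sprintf("bins_%s.tsv", pt))), tracks,
                    haploid_x = config$haploid_x)
    cnv_results[[pt]] <- res
    ar_amp[pt] <- res$ar_amplified
    write_tsv(res$segments, p(sprintf("segments_%s.tsv", pt)))
    write_tsv(as.data.frame(res$calls), p(sprintf("focal_events_%s.tsv", pt)))
    write_json_file(list(
      sample = pt, ar_amplification = res$ar_amplified,
      tumor_fraction_naive_surrogate = res$tf$tf,
      quantifiable = res$tf$quantifiable),
      p(sprintf("cnv_summary_%s.json", pt)))
  }

  ## stage 5: integration -----------------------------------------------
  stage_msg(quiet, "[integrate] assembling ledger and report")
  patients <- sprintf("P%02d", seq_len(config$n_patients))
  ledger <- assemble_ledger(patients, ctc_summaries, expr_calls, ar_amp)
  write_ledger(ledger, p("ledger.tsv"))
  report <- integration_report(ledger)
  write_json_file(report_as_json(report), p("integration_report.json"))
  mat <- ledger_matrix(ledger)
  mat_df <- data.frame(patient_id = rownames(mat),
                       ifelse(is.na(mat), "NA", ifelse(mat, "Y", "N")),
                       check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(mat_df, p("ledger_matrix.tsv"))

  ## manifest ------------------------------------------------------------
  files <- sort(setdiff(list.files(outdir), "manifest.json"))
  manifest <- list(
    package = "liquidmix",
    version = as.character(utils::packageVersion("liquidmix")),
    seed = config$seed,
    config = config_echo(config),
    checksums = as.list(tools::md5sum(file.path(outdir, files))))
  names(manifest$checksums) <- files
  write_json_file(manifest, p("manifest.json"))
  stage_msg(quiet, "[done] %.1f s elapsed", proc.time()[["elapsed"]] - t0)

  invisible(list(cutoffs = cutoffs, ctc_summaries = ctc_summaries,
                 thresholds = thresholds, expression_calls = expr_calls,
                 cnv = cnv_results, ledger = ledger, report = report,
                 manifest = manifest))
}

# JSON-friendly config echo (data frames as records)
config_echo <- function(config) {
  cfg <- unclass(config)
  cfg$genome <- as.list(as.data.frame(cfg$genome))
  cfg
}

report_as_json <- function(report) {
  list(
    informative = report$informative[c("n_informative", "n_patients",
                                       "fraction", "percent")],
    resistance = report$resistance[c("n_resistant", "percent_resistant",
                                     "n_exclusive", "percent_exclusive")],
    positivity = report$positivity,
    concordance = report$concordance)
}
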