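# Small fixture builders shared across test files.

tiny_config <- function(seed = 1, ...) {
  defaults <- list(seed = seed, n_control_samples = 2, n_control_cells = 300,
                   n_patients = 4, n_cells_per_patient = 200,
                   n_tumor_cells = 3, n_controls_qpcr = 4,
                   n_patients_qpcr = 4, n_plasma = 2)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

make_cells <- function(klk3 = 0, arv7 = 0, arfl = 0, sample_id = "S1") {
  n <- max(length(klk3), length(arv7), length(arfl))
  data.frame(sample_id = rep_len(sample_id, n),
             cell_id = sprintf("c%03d", seq_len(n)),
             source = "collector",
             klk3_rcp = rep_len(klk3, n),
             arv7_rcp = rep_len(arv7, n),
             arfl_rcp = rep_len(arfl, n),
             stringsAsFactors = FALSE)
}

paper_cutoffs <- function() {
  structure(c("KLK3" = 1L, "AR-V7" = 2L, "AR-FL" = 3L), class = "ctc_cutoffs")
}

make_cq <- function(sample_id, group, gene, cq, replicate = NULL) {
  n <- max(length(sample_id), length(gene), length(cq))
  df <- data.frame(sample_id = rep_len(sample_id, n),
                   group = rep_len(group, n),
                   gene = rep_len(gene, n),
                   cq = rep_len(cq, n),
                   stringsAsFactors = FALSE)
  df$replicate <- if (is.null(replicate)) {
    stats::ave(seq_len(n), df$sample_id, df$gene, FUN = seq_along)
  } else rep_len(replicate, n)
  df
}

# uniform bins on one or more chromosomes, 1 Mb wide by default
make_bins <- function(counts, chrom = "chr1", width = 1e6, gc = NULL,
                      masked = FALSE) {
  n <- length(counts)
  start <- (seq_len(n) - 1) * width
  data.frame(chrom = rep_len(chrom, n), start = start, end = start + width,
             gc = if (is.null(gc)) rep(0.45, n) else gc,
             count = counts, masked = rep_len(masked, n),
             stringsAsFactors = FALSE)
}

make_segments <- function(chrom, start, end, log2, n_bins = 10L) {
  data.frame(chrom = chrom, start = start, end = end,
             n_bins = rep_len(n_bins, length(start)), log2 = log2,
             stringsAsFactors = FALSE)
}

# A hand-built scenario in which the second segment passes all six focal
# event criteria (1 Mb driver amplification at log2 0.5 against flat flanks).
focal_fixture <- function() {
  segments <- make_segments(
    "chr1", c(0, 40e6, 41e6), c(40e6, 41e6, 80e6), c(0, 0.5, 0))
  tracks <- list(
    genes = data.frame(chrom = "chr1",
                       start = c(40.2e6, 40.6e6),
                       end = c(40.4e6, 40.8e6),
                       name = c("AR", "chr1_g01"),
                       driver = c(TRUE, FALSE)),
    segdups = data.frame(chrom = character(0), start = numeric(0),
                         end = numeric(0)),
    known_cnvs = data.frame(chrom = character(0), start = numeric(0),
                            end = numeric(0)))
  list(segments = segments, tracks = tracks, target = 2L)
}

# a ledger row block for one assay
ledger_rows <- function(patients, assay, result) {
  data.frame(patient_id = patients, assay = assay,
             result = rep_len(result, length(patients)),
             stringsAsFactors = FALSE)
}

# ledger with given per-assay positive patient index sets; everything else
# negative (or not_assayed where listed)
build_ledger <- function(n = 19, positives = list(), not_assayed = list()) {
  assays <- c("insitu_CTC", "insitu_ARV7", "insitu_ARFL", "insitu_KLK3",
              "qpcr_ARV7", "qpcr_ARFL", "qpcr_KLK3", "ctdna_AR_amp")
  patients <- sprintf("P%02d", seq_len(n))
  do.call(rbind, lapply(assays, function(a) {
    res <- rep("negative", n)
    res[not_assayed[[a]]] <- "not_assayed"
    res[positives[[a]]] <- "positive"
    ledger_rows(patients, a, res)
  }))
}
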