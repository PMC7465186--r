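# Resistance-bearing assays: AR-V7 by either transcript assay, or AR
# amplification in ctDNA.
.resistance_assays <- c("insitu_ARV7", "qpcr_ARV7", "ctdna_AR_amp")

validate_ledger <- function(ledger) {
  stopifnot_cols(ledger, c("patient_id", "assay", "result"), "ledger")
  bad <- setdiff(unique(ledger$result),
                 c("positive", "negative", "not_assayed"))
  if (length(bad)) {
    stop("invalid ledger result value(s): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(ledger[, c("patient_id", "assay")])) {
    stop("ledger has duplicated patient x assay entries")
  }
  invisible(ledger)
}

# wide logical helper: rows = patients, cols = assays, TRUE = positive,
# FALSE = negative, NA = not assayed
ledger_matrix <- function(ledger) {
  validate_ledger(ledger)
  patients <- unique(ledger$patient_id)
  assays <- unique(ledger$assay)
  m <- matrix(NA, nrow = length(patients), ncol = length(assays),
              dimnames = list(patients, assays))
  val <- ifelse(ledger$result == "not_assayed", NA,
                ledger$result == "positive")
  m[cbind(match(ledger$patient_id, patients),
          match(ledger$assay, assays))] <- val
  m
}

drop_unassayed_patients <- function(m) {
  empty <- rowSums(!is.na(m)) == 0L
  if (any(empty)) {
    warning("patient(s) with no assayed result excluded: ",
            paste(rownames(m)[empty], collapse = ", "))
    m <- m[!empty, , drop = FALSE]
  }
  m
}

#' Fraction of patients with any tumor-related information
#'
#' A patient is informative when at least one assayed test is positive. The
#' denominator is every patient in the ledger (patients with no assayed
#' result at all violate the ledger contract and are excluded with a
#' warning).
#'
#' @param ledger long-format ledger (`patient_id`, `assay`, `result` with
#'   values positive/negative/not_assayed).
#' @return List: `n_informative`, `n_patients`, `fraction`, `percent`
#'   (integer, round half up), `informative` (named logical).
#' @export
informative_rate <- function(ledger) {
  m <- ledger_matrix(ledger)
  if (nrow(m) == 0L) stop("empty ledger")
  m <- drop_unassayed_patients(m)
  if (nrow(m) == 0L) stop("no assayed patients in ledger")
  informative <- apply(m, 1L, function(r) any(r, na.rm = TRUE))
  list(n_informative = sum(informative),
       n_patients = nrow(m),
       fraction = mean(informative),
       percent = percent_int(sum(informative), nrow(m)),
       informative = informative)
}

#' Resistance detection and assay exclusivity
#'
#' A patient carries a detected resistance marker when AR-V7 is positive by
#' either transcript assay (in situ CTCs or whole-blood qPCR) or AR
#' amplification is detected in ctDNA. A resistant patient's detection is
#' *exclusive* when exactly one of these three assays is positive. Other
#' markers (AR-FL, KLK3) contribute to informativeness only.
#'
#' @param ledger long-format ledger.
#' @return List: per-patient `calls` data frame (`patient_id`, `resistant`,
#'   `n_resistance_assays_positive`, `exclusive`), `n_resistant`,
#'   `percent_resistant` (of all patients), `n_exclusive`,
#'   `percent_exclusive` (of resistant patients).
#' @export
resistance_summary <- function(ledger) {
  m <- drop_unassayed_patients(ledger_matrix(ledger))
  present <- intersect(.resistance_assays, colnames(m))
  r <- m[, present, drop = FALSE]
  n_pos <- apply(r, 1L, function(x) sum(x, na.rm = TRUE))
  resistant <- n_pos > 0L
  calls <- data.frame(
    patient_id = rownames(m),
    resistant = resistant,
    n_resistance_assays_positive = as.integer(n_pos),
    exclusive = n_pos == 1L,
    row.names = NULL, stringsAsFactors = FALSE)
  list(calls = calls,
       n_resistant = sum(resistant),
       percent_resistant = percent_int(sum(resistant), nrow(m)),
       n_exclusive = sum(calls$exclusive),
       percent_exclusive = percent_int(sum(calls$exclusive), sum(resistant)))
}

#' Concordance between the in situ and qPCR assay for one marker
#'
#' Over patients assayed by both methods for the marker, the fraction whose
#' calls agree (both positive or both negative).
#'
#' @param ledger long-format ledger.
#' @param marker `"ARV7"`, `"ARFL"` or `"KLK3"` (hyphenated spellings are
#'   accepted).
#' @return List: `n_agree`, `n_coassayed`, `fraction`, `percent` (integer).
#' @export
assay_concordance <- function(ledger, marker) {
  marker <- gsub("-", "", toupper(marker))
  if (!marker %in% c("ARV7", "ARFL", "KLK3")) {
    stop("marker must be one of AR-V7, AR-FL, KLK3")
  }
  m <- ledger_matrix(ledger)
  a <- paste0("insitu_", marker)
  b <- paste0("qpcr_", marker)
  if (!all(c(a, b) %in% colnames(m))) {
    stop("ledger lacks assay column(s) ", a, " / ", b)
  }
  both <- !is.na(m[, a]) & !is.na(m[, b])
  if (!any(both)) stop("no patients co-assayed for ", marker)
  agree <- m[both, a] == m[both, b]
  list(n_agree = sum(agree), n_coassayed = sum(both),
       fraction = mean(agree),
       percent = percent_int(sum(agree), sum(both)))
}

#' Per-assay and per-method positivity
#'
#' Positivity of every single assay over the patients actually assayed by
#' it, plus the cumulative positivity of each method (any of its assays
#' positive, over patients with at least one of the method's assays
#' performed) and of the full multi-analyte panel. Assays never performed
#' are reported with `NA` percent, not 0.
#'
#' @param ledger long-format ledger.
#' @return Data frame: `assay`, `n_positive`, `n_assayed`, `percent`;
#'   method-cumulative rows are named `insitu_any`, `qpcr_any`,
#'   `ctdna_any`, and `any_assay` for the full panel.
#' @export
per_assay_positivity <- function(ledger) {
  m <- drop_unassayed_patients(ledger_matrix(ledger))
  one <- function(name, sub) {
    assayed <- rowSums(!is.na(sub)) > 0L
    pos <- apply(sub, 1L, function(r) any(r, na.rm = TRUE)) & assayed
    data.frame(assay = name, n_positive = sum(pos),
               n_assayed = sum(assayed),
               percent = percent_int(sum(pos), sum(assayed)),
               stringsAsFactors = FALSE)
  }
  rows <- lapply(colnames(m), function(a) one(a, m[, a, drop = FALSE]))
  for (method in c("insitu", "qpcr", "ctdna")) {
    cols <- grep(paste0("^", method, "_"), colnames(m), value = TRUE)
    if (length(cols)) {
      rows[[length(rows) + 1L]] <- one(paste0(method, "_any"),
                                       m[, cols, drop = FALSE])
    }
  }
  rows[[length(rows) + 1L]] <- one("any_assay", m)
  do.call(rbind, rows)
}

#' Assemble a ledger from the three assay arms' per-patient results
#'
#' @param patients character vector of all enrolled patient ids.
#' @param ctc_summaries rows from [summarize_patient()] (in situ arm).
#' @param expression_calls [call_expression()] output (qPCR arm).
#' @param ar_amp named logical vector of AR-amplification status per plasma
#'   patient (ctDNA arm).
#' @return Long-format ledger covering all assays for all `patients`, with
#'   `not_assayed` where an arm lacks the patient.
#' @export
assemble_ledger <- function(patients, ctc_summaries, expression_calls,
                            ar_amp) {
  res <- function(ids, values) {
    # values: named logical; not in names -> not_assayed
    v <- values[match(ids, names(values))]
    ifelse(is.na(v), "not_assayed", ifelse(v, "positive", "negative"))
  }
  ctc <- ctc_summaries
  insitu <- list(
    insitu_CTC = stats::setNames(ctc$n_ctcs > 0, ctc$patient_id),
    insitu_ARV7 = stats::setNames(ctc$arv7_pos, ctc$patient_id),
    insitu_ARFL = stats::setNames(ctc$arfl_pos, ctc$patient_id),
    insitu_KLK3 = stats::setNames(ctc$klk3_pos, ctc$patient_id))
  qp <- function(gene) {
    x <- expression_calls[expression_calls$gene == gene, , drop = FALSE]
    stats::setNames(x$positive, x$sample_id)
  }
  qpcr <- list(qpcr_ARV7 = qp("AR-V7"), qpcr_ARFL = qp("AR-FL"),
               qpcr_KLK3 = qp("KLK3"))
  all_assays <- c(insitu, qpcr, list(ctdna_AR_amp = ar_amp))
  out <- lapply(names(all_assays), function(a) {
    data.frame(patient_id = patients, assay = a,
               result = unname(res(patients, all_assays[[a]])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Full integration report over a ledger
#'
#' @param ledger long-format ledger.
#' @return List of class `integration_report`: `informative`, `resistance`,
#'   `positivity`, `concordance` (per marker where co-assayed patients
#'   exist).
#' @export
integration_report <- function(ledger) {
  conc <- list()
  for (mk in c("ARV7", "ARFL", "KLK3")) {
    x <- tryCatch(assay_concordance(ledger, mk), error = function(e) NULL)
    if (!is.null(x)) conc[[mk]] <- x
  }
  structure(list(
    informative = informative_rate(ledger),
    resistance = resistance_summary(ledger),
    positivity = per_assay_positivity(ledger),
    concordance = conc),
    class = "integration_report")
}

#' @export
print.integration_report <- function(x, ...) {
  inf <- x$informative
  res <- x$resistance
  cat(sprintf("Multi-analyte integration over %d patients\n", inf$n_patients))
  cat(sprintf("  informative:          %d/%d (%d%%)\n",
              inf$n_informative, inf$n_patients, inf$percent))
  cat(sprintf("  resistance detected:  %d/%d (%d%%)\n",
              res$n_resistant, inf$n_patients, res$percent_resistant))
  if (res$n_resistant > 0) {
    cat(sprintf("  exclusive detection:  %d/%d resistant (%d%%)\n",
                res$n_exclusive, res$n_resistant, res$percent_exclusive))
  }
  cat("  per-assay positivity:\n")
  p <- x$positivity
  for (i in seq_len(nrow(p))) {
    cat(sprintf("    %-14s %2d/%2d (%s%%)\n", p$assay[i], p$n_positive[i],
                p$n_assayed[i],
                ifelse(is.na(p$percent[i]), "NA", p$percent[i])))
  }
  invisible(x)
}
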