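#' Impute no-amplification qPCR records
#'
#' Reactions that yield no quantification cycle within the 45-cycle run are
#' recorded as missing; for target genes these are assigned a Cq of 46 (one
#' cycle beyond the run) so they enter normalization as minimal-expression
#' values. A missing *reference*-gene Cq cannot be imputed — normalization
#' for that sample is meaningless — so all records of such samples are
#' dropped and the sample is reported as unevaluable.
#'
#' @param records Cq data frame (`sample_id`, `group`, `gene`, `replicate`,
#'   `cq`; `NA` = no amplification).
#' @param reference_gene reference (housekeeping) gene, default `"GUSB"`.
#' @param impute_value Cq assigned to non-amplifying target reactions
#'   (default 46).
#' @return The records with target `NA`s replaced by `impute_value`;
#'   unevaluable samples removed and listed in the `"unevaluable"` attribute.
#'   Idempotent.
#' @export
impute_no_amplification <- function(records, reference_gene = "GUSB",
                                    impute_value = 46) {
  stopifnot_cols(records, c("sample_id", "gene", "cq"), "Cq table")
  bad_ref <- unique(records$sample_id[
    records$gene == reference_gene & is.na(records$cq)])
  if (length(bad_ref)) {
    warning("reference gene ", reference_gene,
            " did not amplify; sample(s) unevaluable: ",
            paste(bad_ref, collapse = ", "))
    records <- records[!(records$sample_id %in% bad_ref), , drop = FALSE]
  }
  miss <- is.na(records$cq) & records$gene != reference_gene
  records$cq[miss] <- impute_value
  attr(records, "unevaluable") <- bad_ref
  records
}

#' Reference-normalized expression (delta-Cq) per sample and gene
#'
#' For each sample, target Cq values are normalized to the reference gene:
#' delta-Cq = Cq(target) - Cq(reference), so *lower* delta-Cq means *higher*
#' expression. Technical replicates are paired by replicate index and the
#' per-replicate delta-Cq values averaged (mean); when target and reference
#' replicate structures differ, each target replicate is normalized against
#' the mean reference Cq instead. Setting `average = "cq_first"` averages Cq
#' per gene before subtracting (the two orders agree exactly for matched
#' replicate structures).
#'
#' @param records imputed Cq data frame (see [impute_no_amplification()];
#'   `NA` Cq values are an error).
#' @param reference_gene reference gene, default `"GUSB"`.
#' @param average `"delta_cq"` (default: average per-replicate delta-Cq) or
#'   `"cq_first"` (average Cq, then subtract).
#' @return Data frame `sample_id`, `group` (if present), `gene`, `delta_cq`.
#' @export
compute_delta_cq <- function(records, reference_gene = "GUSB",
                             average = c("delta_cq", "cq_first")) {
  average <- match.arg(average)
  stopifnot_cols(records, c("sample_id", "gene", "replicate", "cq"),
                 "Cq table")
  if (anyNA(records$cq)) {
    stop("Cq table contains missing values; run impute_no_amplification() first")
  }
  has_group <- "group" %in% names(records)
  out <- list()
  for (s in unique(records$sample_id)) {
    rs <- records[records$sample_id == s, , drop = FALSE]
    ref <- rs[rs$gene == reference_gene, , drop = FALSE]
    if (nrow(ref) == 0L) {
      stop("sample ", s, " has no reference gene (", reference_gene, ") records")
    }
    for (g in setdiff(unique(rs$gene), reference_gene)) {
      tg <- rs[rs$gene == g, , drop = FALSE]
      if (nrow(tg) == 0L) next
      if (average == "cq_first") {
        d <- mean(tg$cq) - mean(ref$cq)
      } else if (setequal(tg$replicate, ref$replicate) &&
                 !anyDuplicated(tg$replicate) && !anyDuplicated(ref$replicate)) {
        d <- mean(tg$cq - ref$cq[match(tg$replicate, ref$replicate)])
      } else {
        d <- mean(tg$cq - mean(ref$cq))
      }
      out[[length(out) + 1L]] <- data.frame(
        sample_id = s,
        group = if (has_group) tg$group[1L] else NA_character_,
        gene = g, delta_cq = d, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (!has_group) res$group <- NULL
  res
}

#' Derive per-gene positivity thresholds from negative controls
#'
#' The positivity threshold for each gene is the lowest mean delta-Cq
#' observed among the negative control samples: no control can then be
#' called positive under the strict-inequality positivity rule.
#'
#' @param control_deltas delta-Cq data frame for control samples
#'   (see [compute_delta_cq()]).
#' @return Named numeric vector of class `cq_thresholds` (delta-Cq cycles).
#' @export
derive_thresholds <- function(control_deltas) {
  stopifnot_cols(control_deltas, c("sample_id", "gene", "delta_cq"),
                 "control delta-Cq table")
  if (nrow(control_deltas) == 0L) stop("no control delta-Cq records")
  thr <- tapply(control_deltas$delta_cq, control_deltas$gene, min)
  structure(as.numeric(thr), names = names(thr), class = "cq_thresholds")
}

#' @export
print.cq_thresholds <- function(x, ...) {
  cat("delta-Cq positivity thresholds (lowest control delta-Cq):\n")
  for (g in names(x)) cat(sprintf("  %-6s < %.3f cycles\n", g, x[[g]]))
  invisible(x)
}

#' Call expression positivity against control-derived thresholds
#'
#' A sample is positive for a gene when its delta-Cq lies *strictly below*
#' the gene's threshold (lower delta-Cq = higher expression); a tie with the
#' threshold is negative, consistent with the controls that define the
#' threshold being negative by construction.
#'
#' @param deltas delta-Cq data frame (patient samples).
#' @param thresholds [derive_thresholds()] output (or named numeric vector).
#' @return `deltas` with logical column `positive` and numeric `threshold`.
#' @export
call_expression <- function(deltas, thresholds) {
  stopifnot_cols(deltas, c("sample_id", "gene", "delta_cq"), "delta-Cq table")
  missing <- setdiff(unique(deltas$gene), names(thresholds))
  if (length(missing)) {
    stop("no threshold for gene(s): ", paste(missing, collapse = ", "))
  }
  deltas$threshold <- as.numeric(thresholds[deltas$gene])
  deltas$positive <- deltas$delta_cq < deltas$threshold
  deltas
}
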