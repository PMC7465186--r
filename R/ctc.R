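#' Derive per-marker CTC-calling cut-offs from control cells
#'
#' The cut-off for each marker is the highest RCP count observed in any
#' control cell for that marker, plus one: the smallest integer threshold
#' under which no control cell would be rated a CTC. A marker never observed
#' in controls therefore gets cut-off 1. Applied to the published healthy
#' control backgrounds ([insitu_reference_cells()]) this yields
#' `{KLK3: 1, AR-V7: 2, AR-FL: 3}`.
#'
#' @param control_cells cells data frame (columns `klk3_rcp`, `arv7_rcp`,
#'   `arfl_rcp`; one row per analyzed control cell).
#' @return An integer vector of class `ctc_cutoffs`, named by marker, giving
#'   the minimum RCPs/cell rating a cell as CTC.
#' @export
#' @examples
#' derive_cutoffs(insitu_reference_cells(paste0("Ctrl", 1:6)))
derive_cutoffs <- function(control_cells) {
  stopifnot_cols(control_cells, unname(.markers), "control cells table")
  if (nrow(control_cells) == 0L) stop("no control cells supplied")
  cutoffs <- vapply(.markers, function(col) {
    x <- control_cells[[col]]
    if (any(x < 0, na.rm = TRUE)) stop("negative RCP count in controls")
    as.integer(max(0, x, na.rm = TRUE)) + 1L
  }, integer(1))
  names(cutoffs) <- names(.markers)
  structure(cutoffs, class = "ctc_cutoffs")
}

#' @export
print.ctc_cutoffs <- function(x, ...) {
  cat("CTC-calling cut-offs (minimum RCPs/cell):\n")
  for (m in names(x)) cat(sprintf("  %-6s >= %d RCPs/cell\n", m, x[[m]]))
  invisible(x)
}

#' Classify cells as CTCs against per-marker cut-offs
#'
#' A cell is rated a CTC if its RCP count reaches the cut-off for at least
#' one marker. Classification is monotone: raising any count never unsets a
#' CTC call.
#'
#' @param cells cells data frame.
#' @param cutoffs marker-named cut-offs as returned by [derive_cutoffs()]
#'   (or a named integer vector covering exactly the marker set).
#' @return The input with logical columns `klk3_pos`, `arv7_pos`, `arfl_pos`,
#'   a comma-joined `positive_markers` string and logical `is_ctc`.
#' @export
call_ctcs <- function(cells, cutoffs) {
  stopifnot_cols(cells, unname(.markers), "cells table")
  if (!setequal(names(cutoffs), marker_names())) {
    stop("cutoffs must be named by exactly the markers ",
         paste(marker_names(), collapse = ", "))
  }
  if (any(cutoffs < 1)) stop("cut-offs must be >= 1 RCP/cell")
  pos <- vapply(marker_names(), function(m) {
    cells[[marker_column(m)]] >= cutoffs[[m]]
  }, logical(nrow(cells)))
  pos <- matrix(pos, nrow = nrow(cells),
                dimnames = list(NULL, marker_names()))
  cells$klk3_pos <- pos[, "KLK3"]
  cells$arv7_pos <- pos[, "AR-V7"]
  cells$arfl_pos <- pos[, "AR-FL"]
  cells$positive_markers <- apply(pos, 1L, function(p) {
    paste(marker_names()[p], collapse = ",")
  })
  cells$is_ctc <- rowSums(pos) > 0
  cells
}

#' Summarize the CTC status of one patient
#'
#' Counts CTCs, records per-marker positivity and maximum expression among
#' CTCs, and flags intrapatient heterogeneity. A patient is heterogeneous
#' when at least two CTCs were found and either (a) two CTCs are positive
#' for different marker sets, or (b) for some marker positive in two or more
#' CTCs the highest and lowest RCP counts differ by more than `het_fold`.
#'
#' @param calls output of [call_ctcs()], possibly covering several samples.
#' @param patient_id patient/sample to summarize; defaults to the single
#'   `sample_id` present in `calls`.
#' @param het_fold fold difference in RCP counts between CTCs sharing a
#'   positive marker above which expression is rated heterogeneous
#'   (default 2, i.e. a > 2-fold spread).
#' @return One-row data frame: `patient_id`, `n_ctcs`, per-marker positivity,
#'   per-marker maximum RCPs among CTCs (`NA` if none), `heterogeneous`.
#' @export
summarize_patient <- function(calls, patient_id = NULL, het_fold = 2) {
  stopifnot_cols(calls, c("is_ctc", "positive_markers", unname(.markers)),
                 "CTC calls table")
  if (is.null(patient_id)) {
    patient_id <- unique(calls$sample_id)
    if (length(patient_id) != 1L) {
      stop("calls cover several samples; supply patient_id")
    }
  } else {
    calls <- calls[calls$sample_id == patient_id, , drop = FALSE]
  }
  ctc <- calls[calls$is_ctc, , drop = FALSE]
  n_ctcs <- nrow(ctc)

  pos_flags <- vapply(marker_names(), function(m) {
    any(ctc[[sub("_rcp$", "_pos", marker_column(m))]])
  }, logical(1))
  max_rcp <- vapply(marker_names(), function(m) {
    col_pos <- sub("_rcp$", "_pos", marker_column(m))
    hit <- ctc[[col_pos]]
    if (!any(hit)) NA_integer_ else
      as.integer(max(ctc[[marker_column(m)]][hit]))
  }, integer(1))

  heterogeneous <- FALSE
  if (n_ctcs >= 2L) {
    if (length(unique(ctc$positive_markers)) > 1L) {
      heterogeneous <- TRUE
    } else {
      for (m in marker_names()) {
        col_pos <- sub("_rcp$", "_pos", marker_column(m))
        counts <- ctc[[marker_column(m)]][ctc[[col_pos]]]
        if (length(counts) >= 2L && max(counts) / min(counts) > het_fold) {
          heterogeneous <- TRUE
          break
        }
      }
    }
  }

  data.frame(
    patient_id = patient_id,
    n_ctcs = n_ctcs,
    klk3_pos = pos_flags[["KLK3"]],
    arv7_pos = pos_flags[["AR-V7"]],
    arfl_pos = pos_flags[["AR-FL"]],
    klk3_max_rcp = max_rcp[["KLK3"]],
    arv7_max_rcp = max_rcp[["AR-V7"]],
    arfl_max_rcp = max_rcp[["AR-FL"]],
    heterogeneous = heterogeneous,
    stringsAsFactors = FALSE
  )
}

#' Per-marker RCP count distribution of a cell population
#'
#' Bins per-cell RCP counts into the occupancy classes 0, 1, 2, 3 and >3
#' RCPs/cell with percentages to two decimals (round half up), and computes
#' the median and quartiles (linear interpolation, type-7 quantiles) of the
#' raw per-cell counts.
#'
#' @param cells cells data frame; every row must be an analyzed cell (samples
#'   for which only positive cells were recorded cannot be summarized).
#' @return An object of class `rcp_distribution`: list with `n_cells`,
#'   `bins` (marker, bin, n, pct) and `stats` (marker, q1, median, q3).
#' @export
summarize_distribution <- function(cells) {
  stopifnot_cols(cells, unname(.markers), "cells table")
  n <- nrow(cells)
  if (n == 0L) stop("no cells supplied")
  bins_lab <- c("0", "1", "2", "3", ">3")
  bins <- do.call(rbind, lapply(marker_names(), function(m) {
    x <- cells[[marker_column(m)]]
    k <- c(sum(x == 0), sum(x == 1), sum(x == 2), sum(x == 3), sum(x > 3))
    data.frame(marker = m, bin = bins_lab, n = k,
               pct = round_half_up(100 * k / n, 2),
               stringsAsFactors = FALSE)
  }))
  stats <- do.call(rbind, lapply(marker_names(), function(m) {
    q <- stats::quantile(cells[[marker_column(m)]], c(0.25, 0.5, 0.75),
                         type = 7, names = FALSE)
    data.frame(marker = m, q1 = q[1], median = q[2], q3 = q[3],
               stringsAsFactors = FALSE)
  }))
  structure(list(n_cells = n, bins = bins, stats = stats),
            class = "rcp_distribution")
}

#' @export
print.rcp_distribution <- function(x, ...) {
  cat(sprintf("RCP count distribution over %d cells\n", x$n_cells))
  wide <- stats::reshape(
    x$bins[, c("marker", "bin", "pct")],
    idvar = "bin", timevar = "marker", direction = "wide")
  print(wide, row.names = FALSE)
  cat("\nPer-cell count quartiles:\n")
  print(x$stats, row.names = FALSE)
  invisible(x)
}

#' Patient-level positivity fractions across a CTC cohort
#'
#' @param summaries data frame of rows from [summarize_patient()].
#' @return Data frame with one row per assay (`CTC` for any-marker CTC
#'   positivity plus the three markers): positives, patients assayed,
#'   fraction and integer percent (round half up).
#' @export
cohort_positivity <- function(summaries) {
  if (NROW(summaries) == 0L) stop("no patient summaries supplied")
  n <- nrow(summaries)
  k <- c("CTC" = sum(summaries$n_ctcs > 0),
         "KLK3" = sum(summaries$klk3_pos),
         "AR-V7" = sum(summaries$arv7_pos),
         "AR-FL" = sum(summaries$arfl_pos))
  data.frame(assay = names(k), n_positive = as.integer(k), n_patients = n,
             fraction = as.numeric(k) / n,
             percent = percent_int(as.numeric(k), n),
             row.names = NULL, stringsAsFactors = FALSE)
}
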