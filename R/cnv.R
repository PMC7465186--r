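#' Count plasma fragments into genomic bins
#'
#' Each fragment is counted once, into the bin containing its start
#' coordinate (0-based, half-open bins), the unambiguous order-independent
#' assignment rule. Fragments on chromosomes absent from the genome model
#' are skipped and their number reported in a warning.
#'
#' @param fragments data frame `chrom`, `start` (0-based bp; an `end`
#'   column, if present, is ignored for assignment).
#' @param model [gen_genome_model()] output (or any list with a `bins`
#'   data frame tiling the genome).
#' @return The model's bins with a `count` column.
#' @export
bin_fragments <- function(fragments, model) {
  stopifnot_cols(fragments, c("chrom", "start"), "fragments table")
  bins <- model$bins
  bins$count <- 0L
  skipped <- 0L
  for (chrom in unique(fragments$chrom)) {
    fr <- fragments[fragments$chrom == chrom, , drop = FALSE]
    sel <- which(bins$chrom == chrom)
    if (length(sel) == 0L) {
      skipped <- skipped + nrow(fr)
      next
    }
    chrom_len <- max(bins$end[sel])
    in_range <- fr$start >= 0 & fr$start < chrom_len
    skipped <- skipped + sum(!in_range)
    idx <- findInterval(fr$start[in_range], bins$start[sel])
    tab <- tabulate(idx, nbins = length(sel))
    bins$count[sel] <- bins$count[sel] + tab
  }
  if (skipped > 0L) {
    warning(skipped, " fragment(s) outside the model genome were skipped")
  }
  bins
}

#' Depth-normalize bin counts
#'
#' Divides every bin count by the mean raw count over unmasked autosomal
#' bins, so the autosomal mean ratio is exactly 1 and the normalization is
#' invariant to total sequencing depth.
#'
#' @param bins bin counts data frame (`chrom`, `start`, `end`, `count`,
#'   `masked`).
#' @return `bins` with a `ratio` column.
#' @export
normalize_depth <- function(bins) {
  stopifnot_cols(bins, c("chrom", "count", "masked"), "bins table")
  ref <- bins$count[!bins$masked & is_autosome(bins$chrom)]
  if (length(ref) == 0L || all(ref == 0)) {
    stop("no unmasked autosomal bins with non-zero counts")
  }
  bins$ratio <- bins$count / mean(ref)
  bins
}

#' LOWESS GC-bias correction of depth-normalized ratios
#'
#' Fits a robust LOWESS curve of ratio against GC fraction over unmasked
#' autosomal bins with non-zero counts, and divides every bin's ratio by
#' the fitted value at its GC (linear interpolation between fitted points;
#' constant extrapolation outside the fitted GC range). `log2_ratio` is the
#' log2 of the corrected ratio, with zero-count bins floored at
#' `log2_floor` to keep downstream segmentation finite.
#'
#' @param bins [normalize_depth()] output.
#' @param span LOWESS smoother span (fraction of points), default 0.3.
#' @param iters robustness iterations, default 2.
#' @param log2_floor log2 value assigned to zero-count bins, default -4.
#' @return `bins` with `ratio` replaced by the GC-corrected ratio, plus
#'   `gc_fit` (fitted bias) and `log2_ratio` columns.
#' @export
gc_correct <- function(bins, span = 0.3, iters = 2, log2_floor = -4) {
  stopifnot_cols(bins, c("chrom", "gc", "count", "ratio", "masked"),
                 "bins table")
  fit_on <- !bins$masked & is_autosome(bins$chrom) & bins$count > 0
  if (sum(fit_on) < 30L) {
    stop("need at least 30 unmasked autosomal bins for GC correction")
  }
  if (diff(range(bins$gc[fit_on])) < 1e-6) {
    warning("degenerate GC range; GC correction skipped")
    bins$gc_fit <- 1
  } else {
    lo <- stats::lowess(bins$gc[fit_on], bins$ratio[fit_on],
                        f = span, iter = iters)
    fitted <- stats::approx(lo$x, lo$y, xout = bins$gc, rule = 2, ties = mean)$y
    bins$gc_fit <- pmax(fitted, 0.01)
  }
  bins$ratio <- bins$ratio / bins$gc_fit
  bins$log2_ratio <- ifelse(bins$count > 0, log2(bins$ratio), log2_floor)
  bins
}

#' Recenter a haploid X chromosome onto the autosomal log2 scale
#'
#' In a male genome the single-copy X sits one log2 unit below the diploid
#' autosomes; adding +1 to X-bin log2 ratios puts balanced X at log2 0 so
#' the same event-calling thresholds apply genome-wide.
#'
#' @param bins [gc_correct()] output.
#' @param chrom X chromosome name, default `"chrX"`.
#' @return `bins` with recentered `log2_ratio` on `chrom`.
#' @export
recenter_haploid_x <- function(bins, chrom = "chrX") {
  stopifnot_cols(bins, c("chrom", "log2_ratio"), "bins table")
  sel <- bins$chrom == chrom
  bins$log2_ratio[sel] <- bins$log2_ratio[sel] + 1
  bins
}

# Exact penalized least-squares segmentation of one numeric series:
# minimizes total within-segment SSE + lambda per additional segment,
# with a minimum segment length, by optimal-partitioning DP.
# Returns the vector of segment start indices.
segment_series <- function(y, lambda, min_len) {
  n <- length(y)
  if (n < 2L * min_len) return(1L)
  s1 <- c(0, cumsum(y))
  s2 <- c(0, cumsum(y * y))
  best <- rep(Inf, n + 1L)
  best[1L] <- 0
  prev <- integer(n + 1L)
  for (j in min_len:n) {
    i <- seq_len(j - min_len + 1L)              # candidate segment starts
    ok <- i == 1L | i > min_len                 # prefix empty or >= min_len
    i <- i[ok & is.finite(best[i])]
    len <- j - i + 1
    sse <- (s2[j + 1L] - s2[i]) - (s1[j + 1L] - s1[i])^2 / len
    cost <- best[i] + sse + lambda * (i > 1L)
    k <- which.min(cost)
    best[j + 1L] <- cost[k]
    prev[j + 1L] <- i[k]
  }
  starts <- integer(0)
  j <- n + 1L
  while (j > 1L) {
    starts <- c(prev[j], starts)
    j <- prev[j]
  }
  starts
}

#' Segment log2 ratios into piecewise-constant copy-number segments
#'
#' Per chromosome, computes the exact penalized least-squares segmentation
#' of the unmasked bins' log2 ratios: the piecewise-constant fit minimizing
#' total within-segment squared error plus a penalty of `penalty *
#' var(log2 ratios of the chromosome)` per additional segment, subject to a
#' minimum segment length. Solved by optimal-partitioning dynamic
#' programming, so the returned segmentation is the global optimum of this
#' criterion, not a greedy approximation.
#'
#' @param bins [gc_correct()] output (ordered by position within
#'   chromosome); masked bins are excluded.
#' @param penalty multiple of the per-chromosome bin variance charged per
#'   additional segment, default 10.
#' @param min_bins minimum bins per segment, default 3.
#' @return Segments data frame: `chrom`, `start`, `end`, `n_bins`, `log2`
#'   (mean of member bins); ordered, non-overlapping, covering all unmasked
#'   bins.
#' @export
segment_log2 <- function(bins, penalty = 10, min_bins = 3L) {
  if (penalty <= 0) stop("penalty must be positive")
  stopifnot_cols(bins, c("chrom", "start", "end", "log2_ratio", "masked"),
                 "bins table")
  out <- list()
  for (chrom in unique(bins$chrom)) {
    b <- bins[bins$chrom == chrom & !bins$masked, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    n <- nrow(b)
    if (n == 0L) next
    y <- b$log2_ratio
    v <- if (n > 1L) stats::var(y) else 0
    # (near-)constant chromosomes: nothing to segment, and a zero penalty
    # would let floating-point ties introduce arbitrary splits
    starts <- if (v < 1e-12) 1L else
      segment_series(y, penalty * v, as.integer(min_bins))
    bounds <- c(starts, n + 1L)
    for (k in seq_along(starts)) {
      i <- bounds[k]
      j <- bounds[k + 1L] - 1L
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = b$start[i], end = b$end[j],
        n_bins = j - i + 1L, log2 = mean(y[i:j]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) stop("no unmasked bins to segment")
  do.call(rbind, out)
}

#' Length-weighted mean log2 ratio of a segment's genomic neighborhood
#'
#' Pools all segment material within `window` bp upstream and `window` bp
#' downstream of the target segment (flanks truncated at chromosome ends,
#' which are taken from the segmented extent) and returns the mean log2
#' ratio weighted by the overlapped length. Returns `NA` when no flanking
#' material exists.
#'
#' @param segments [segment_log2()] output.
#' @param target integer row index of the target segment in `segments`.
#' @param window flank span on each side in bp, default 20 Mb.
#' @return Length-weighted mean flank log2 ratio, or `NA_real_`.
#' @export
weighted_flank_mean <- function(segments, target, window = 2e7) {
  tg <- segments[target, ]
  others <- segments[-target, , drop = FALSE]
  others <- others[others$chrom == tg$chrom, , drop = FALSE]
  if (nrow(others) == 0L) return(NA_real_)
  flanks <- rbind(
    c(tg$start - window, tg$start),
    c(tg$end, tg$end + window))
  w_total <- 0
  acc <- 0
  for (k in 1:2) {
    ov <- pmax(0, pmin(others$end, flanks[k, 2]) - pmax(others$start, flanks[k, 1]))
    w_total <- w_total + sum(ov)
    acc <- acc + sum(ov * others$log2)
  }
  if (w_total == 0) return(NA_real_)
  acc / w_total
}

df_to_gr <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
}

# bp of each query interval covered by the (reduced) subject intervals
overlap_bp <- function(query_gr, subject_df) {
  if (NROW(subject_df) == 0L) return(numeric(length(query_gr)))
  red <- GenomicRanges::reduce(df_to_gr(subject_df))
  hits <- GenomicRanges::findOverlaps(query_gr, red)
  w <- GenomicRanges::width(IRanges::pintersect(
    query_gr[S4Vectors::queryHits(hits)], red[S4Vectors::subjectHits(hits)]))
  out <- numeric(length(query_gr))
  agg <- tapply(w, S4Vectors::queryHits(hits), sum)
  out[as.integer(names(agg))] <- agg
  out
}

#' Call focal copy-number events from segments
#'
#' A segment is called a focal event only if all six criteria hold:
#' \enumerate{
#'   \item size: segment shorter than `max_len` (20 Mb);
#'   \item magnitude: log2 ratio above `+min_log2` (amplification) or below
#'     `-min_log2` (deletion), default 0.2;
#'   \item genes: overlaps at least one but at most `max_genes` (100) genes;
#'   \item neighborhood contrast: log2 ratio at least `driver_contrast`
#'     (0.2) beyond the length-weighted mean of the flanking 20 Mb on both
#'     sides if the segment contains a known tumor driver gene, at least
#'     `nondriver_contrast` (0.58) otherwise, in the event's direction; a
#'     segment with no flanking material fails this criterion;
#'   \item segmental duplications cover at most `segdup_frac` (50\%) of the
#'     segment;
#'   \item known germline CNV entries cover less than `known_cnv_frac`
#'     (50\%) of the segment.
#' }
#' Every segment's per-criterion pass/fail flags are returned, so rejected
#' candidates can be audited.
#'
#' @param segments [segment_log2()] output (log2-recentered X if haploid).
#' @param tracks list with `genes` (chrom/start/end/name/driver), `segdups`
#'   and `known_cnvs` interval data frames (0-based half-open), e.g.
#'   `gen_genome_model()$tracks`.
#' @param min_log2,driver_contrast,nondriver_contrast,max_len,max_genes,segdup_frac,known_cnv_frac
#'   criterion parameters (defaults above).
#' @param flank_window flank span for the contrast criterion, default 20 Mb.
#' @return Data frame of class `focal_calls`: one row per segment with its
#'   class (`amplification`/`deletion` by sign), `n_genes`, `genes`,
#'   `contains_driver`, `flank_mean`, the six `crit_*` flags and `called`.
#' @export
call_focal_events <- function(segments, tracks,
                              min_log2 = 0.2,
                              driver_contrast = 0.2,
                              nondriver_contrast = 0.58,
                              max_len = 2e7,
                              max_genes = 100L,
                              segdup_frac = 0.5,
                              known_cnv_frac = 0.5,
                              flank_window = 2e7) {
  if (is.null(tracks$genes) || is.null(tracks$segdups) ||
      is.null(tracks$known_cnvs)) {
    stop("tracks must provide genes, segdups and known_cnvs")
  }
  stopifnot_cols(segments, c("chrom", "start", "end", "log2"), "segments")
  stopifnot_cols(tracks$genes, c("chrom", "start", "end", "name", "driver"),
                 "genes track")
  n <- nrow(segments)
  gr_seg <- df_to_gr(segments)
  gr_genes <- df_to_gr(tracks$genes)
  hits <- GenomicRanges::findOverlaps(gr_seg, gr_genes)
  gene_lists <- split(tracks$genes$name[S4Vectors::subjectHits(hits)],
                      factor(S4Vectors::queryHits(hits), levels = seq_len(n)))
  n_genes <- lengths(gene_lists)
  driver_hit <- split(tracks$genes$driver[S4Vectors::subjectHits(hits)],
                      factor(S4Vectors::queryHits(hits), levels = seq_len(n)))
  contains_driver <- vapply(driver_hit, any, logical(1))

  seg_len <- segments$end - segments$start
  segdup_bp <- overlap_bp(gr_seg, tracks$segdups)
  cnv_bp <- overlap_bp(gr_seg, tracks$known_cnvs)

  flank_mean <- vapply(seq_len(n), function(i) {
    weighted_flank_mean(segments, i, window = flank_window)
  }, numeric(1))

  cls <- ifelse(segments$log2 >= 0, "amplification", "deletion")
  sgn <- ifelse(cls == "amplification", 1, -1)
  contrast_needed <- ifelse(contains_driver, driver_contrast,
                            nondriver_contrast)

  crit_size <- seg_len < max_len
  crit_magnitude <- sgn * segments$log2 > min_log2
  crit_genes <- n_genes >= 1L & n_genes <= max_genes
  crit_contrast <- !is.na(flank_mean) &
    sgn * (segments$log2 - flank_mean) >= contrast_needed
  crit_segdup <- segdup_bp <= segdup_frac * seg_len
  crit_known_cnv <- cnv_bp < known_cnv_frac * seg_len

  out <- segments
  out$class <- cls
  out$n_genes <- as.integer(n_genes)
  out$genes <- vapply(gene_lists, paste, "", collapse = ",")
  out$contains_driver <- contains_driver
  out$flank_mean <- flank_mean
  out$crit_size <- crit_size
  out$crit_magnitude <- crit_magnitude
  out$crit_genes <- crit_genes
  out$crit_contrast <- crit_contrast
  out$crit_segdup <- crit_segdup
  out$crit_known_cnv <- crit_known_cnv
  out$called <- crit_size & crit_magnitude & crit_genes & crit_contrast &
    crit_segdup & crit_known_cnv
  class(out) <- c("focal_calls", "data.frame")
  out
}

#' @export
print.focal_calls <- function(x, ...) {
  called <- x[x$called, , drop = FALSE]
  cat(sprintf("Focal event calls: %d candidate segment(s), %d called\n",
              nrow(x), nrow(called)))
  if (nrow(called)) {
    print.data.frame(called[, c("chrom", "start", "end", "log2", "class",
                                "genes", "contains_driver")],
                     row.names = FALSE)
  }
  invisible(x)
}

#' Is a named gene focally amplified?
#'
#' @param calls [call_focal_events()] output.
#' @param gene_name gene symbol, default `"AR"`.
#' @return `TRUE` iff a called amplification's gene list contains the gene.
#' @export
call_ar_amplification <- function(calls, gene_name = "AR") {
  amp <- calls[calls$called & calls$class == "amplification", , drop = FALSE]
  any(vapply(strsplit(amp$genes, ","), function(g) gene_name %in% g,
             logical(1)))
}

#' Naive tumor-fraction surrogate from segmented copy-number data
#'
#' A deliberately simple surrogate for probabilistic tumor-fraction models:
#' it takes the autosomal segment (spanning at least `min_span`) deviating
#' most from the diploid baseline, assumes it is a clonal single-copy gain
#' or loss, and inverts the log2 deviation: `tf = 2 * |2^L - 1|`, clipped
#' to `[0, 1]`. The diploid baseline is the length-weighted median of
#' autosomal segment log2 ratios (`baseline = "median"`, the default),
#' which keeps the inversion centered when an aberration shifts the global
#' depth normalization; `baseline = "zero"` uses the raw log2 ratios. A
#' sample is quantifiable when the estimate reaches the 3\% quantitative
#' threshold. All outputs label this estimate a naive surrogate; it assumes
#' one dominant clonal single-copy event and is no replacement for a
#' probabilistic copy-number model.
#'
#' @param segments [segment_log2()] output.
#' @param min_span minimum segment span (bp) considered, default 2.5 Mb.
#' @param baseline `"median"` (length-weighted median autosomal log2) or
#'   `"zero"`.
#' @return List of class `tf_naive`: `tf`, `quantifiable`, `segment`,
#'   `baseline_log2`, `method = "naive single-copy surrogate"`.
#' @export
estimate_tumor_fraction_naive <- function(segments, min_span = 2.5e6,
                                          baseline = c("median", "zero")) {
  baseline <- match.arg(baseline)
  auto <- segments[is_autosome(segments$chrom), , drop = FALSE]
  if (nrow(auto) == 0L) stop("no autosomal segments")
  base_log2 <- 0
  if (baseline == "median") {
    ord <- order(auto$log2)
    w <- (auto$end - auto$start)[ord]
    base_log2 <- auto$log2[ord][which(cumsum(w) >= sum(w) / 2)[1L]]
  }
  auto <- auto[(auto$end - auto$start) >= min_span, , drop = FALSE]
  if (nrow(auto) == 0L) stop("no autosomal segment spans min_span")
  dev <- auto$log2 - base_log2
  i <- which.max(abs(dev))
  tf <- min(max(2 * abs(2^dev[i] - 1), 0), 1)
  structure(list(tf = tf, quantifiable = tf >= 0.03,
                 segment = auto[i, , drop = FALSE],
                 baseline_log2 = base_log2,
                 method = "naive single-copy surrogate"),
            class = "tf_naive")
}

#' @export
print.tf_naive <- function(x, ...) {
  cat(sprintf(
    "Tumor fraction (naive single-copy surrogate): %.3f (%squantifiable at the 3%% threshold)\n",
    x$tf, if (x$quantifiable) "" else "not "))
  invisible(x)
}

#' Full copy-number calling pipeline for one plasma sample
#'
#' Convenience wrapper chaining depth normalization, LOWESS GC correction,
#' optional haploid-X recentering, penalized segmentation, six-criterion
#' focal event calling, AR amplification status and the naive
#' tumor-fraction surrogate.
#'
#' @param bins bin counts data frame (`chrom`, `start`, `end`, `gc`,
#'   `count`, `masked`).
#' @param tracks annotation tracks (see [call_focal_events()]).
#' @param penalty,lowess_span,haploid_x,het_params pipeline parameters;
#'   `het_params` is a named list forwarded to [call_focal_events()].
#' @return List of class `cnv_result`: `bins` (normalized), `segments`,
#'   `calls`, `ar_amplified`, `tf` ([estimate_tumor_fraction_naive()]
#'   output).
#' @export
cnv_call <- function(bins, tracks, penalty = 10, lowess_span = 0.3,
                     haploid_x = TRUE, het_params = list()) {
  bins <- normalize_depth(bins)
  bins <- gc_correct(bins, span = lowess_span)
  if (haploid_x) bins <- recenter_haploid_x(bins)
  segments <- segment_log2(bins, penalty = penalty)
  calls <- do.call(call_focal_events,
                   c(list(segments = segments, tracks = tracks), het_params))
  structure(list(
    bins = bins, segments = segments, calls = calls,
    ar_amplified = call_ar_amplification(calls),
    tf = estimate_tumor_fraction_naive(segments)),
    class = "cnv_result")
}

#' @export
print.cnv_result <- function(x, ...) {
  cat(sprintf("Copy-number result: %d segments, AR amplification: %s\n",
              nrow(x$segments), if (x$ar_amplified) "yes" else "no"))
  print(x$tf)
  invisible(x)
}
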