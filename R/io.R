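# Readers/writers for the pipeline's plain-text interchange formats.
# Tables are TSV/CSV with a header line; BED files are standard 0-based
# half-open BED handled through rtracklayer; JSON through jsonlite.

#' Read / write pipeline tables
#'
#' `write_cells()`/`read_cells()` handle the per-cell RCP table (TSV),
#' `write_cq()`/`read_cq()` the qPCR Cq table (CSV, empty field = no
#' amplification), `write_bins()`/`read_bins()` the genomic bin counts
#' (TSV), and `write_ledger()`/`read_ledger()` the per-patient assay ledger
#' (TSV). All round-trip losslessly.
#'
#' @param x data frame to write.
#' @param path file path.
#' @return Readers return the data frame; writers return `path` invisibly.
#' @name pipeline_io
NULL

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname pipeline_io
#' @export
write_cells <- function(x, path) write_tsv(x, path)

#' @rdname pipeline_io
#' @export
read_cells <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname pipeline_io
#' @export
write_cq <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_cq <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(cq = "numeric"))
}

#' @rdname pipeline_io
#' @export
write_bins <- function(x, path) write_tsv(x, path)

#' @rdname pipeline_io
#' @export
read_bins <- function(path) {
  b <- utils::read.delim(path, stringsAsFactors = FALSE)
  b$masked <- as.logical(b$masked)
  b
}

#' @rdname pipeline_io
#' @export
write_ledger <- function(x, path) write_tsv(x, path)

#' @rdname pipeline_io
#' @export
read_ledger <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read / write annotation intervals as BED
#'
#' Intervals are held internally as 0-based half-open data frames
#' (`chrom`, `start`, `end`, optionally `name` and logical `driver`), and
#' written as standard BED via rtracklayer; the driver flag travels in the
#' BED score column (1 = driver).
#'
#' @param x interval data frame.
#' @param path BED file path.
#' @return `read_bed()` returns the interval data frame; `write_bed()`
#'   returns `path` invisibly.
#' @export
write_bed <- function(x, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    name = if ("name" %in% names(x)) x$name else ".",
    score = if ("driver" %in% names(x)) as.integer(x$driver) else 0L)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
  nm <- gr$name
  if (!is.null(nm) && !all(is.na(nm)) && !all(nm == ".")) out$name <- nm
  sc <- gr$score
  if (!is.null(sc) && !all(is.na(sc))) out$driver <- sc > 0
  out
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
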