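#' Round half away from zero
#'
#' Commercial ("round half up") rounding, as used for all printed percentages
#' in this package: `round_half_up(0.5) == 1`, `round_half_up(37.5, 0) == 38`,
#' unlike base [round()]'s banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return numeric vector rounded half up.
#' @export
#' @examples
#' round_half_up(c(37.5, 85.9545), c(0, 2))
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # 1e-9 guards against binary representation of exact .5 boundaries
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Integer percentage of a count fraction
#'
#' @param k numerator count.
#' @param n denominator count.
#' @return integer percent, rounded half up; `NA` when `n == 0`.
#' @export
#' @examples
#' percent_int(17, 19) # 89
#' percent_int(6, 16)  # 38
percent_int <- function(k, n) {
  out <- round_half_up(100 * k / n, 0)
  out[rep_len(n == 0, length(out))] <- NA_real_
  unname(out)
}

# Fixed in situ marker set: display name -> cells-table column
.markers <- c("KLK3" = "klk3_rcp", "AR-V7" = "arv7_rcp", "AR-FL" = "arfl_rcp")

marker_names <- function() names(.markers)

marker_column <- function(marker) {
  idx <- match(marker, names(.markers))
  if (anyNA(idx)) {
    stop("unknown marker(s): ", paste(marker[is.na(idx)], collapse = ", "),
         "; expected one of ", paste(names(.markers), collapse = ", "))
  }
  unname(.markers[idx])
}

# Evaluate expr with a temporary RNG state seeded by `seed`; the caller's
# RNG stream is untouched, so generators never perturb each other.
with_rng <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed %% .Machine$integer.max)
  expr
}

is_autosome <- function(chrom) {
  !(chrom %in% c("chrX", "chrY", "X", "Y"))
}

stopifnot_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  invisible(df)
}
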