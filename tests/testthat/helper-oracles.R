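# Independent oracles, computed by brute force rather than through the
# package's code paths.

# Exhaustive penalized least-squares segmentation: enumerates every
# composition of n into parts >= min_len, scores each from scratch
# (SSE + lambda per additional segment), returns segment start indices.
oracle_segment_starts <- function(y, lambda, min_len = 3L) {
  n <- length(y)
  best_cost <- Inf
  best_parts <- n
  recurse <- function(parts, remaining) {
    if (remaining == 0L) {
      starts <- cumsum(c(1L, parts[-length(parts)]))
      cost <- lambda * (length(parts) - 1L)
      for (k in seq_along(parts)) {
        seg <- y[starts[k]:(starts[k] + parts[k] - 1L)]
        cost <- cost + sum((seg - mean(seg))^2)
      }
      if (cost < best_cost) {
        best_cost <<- cost
        best_parts <<- parts
      }
      return(invisible())
    }
    for (len in min_len:remaining) {
      rest <- remaining - len
      if (rest == 0L || rest >= min_len) recurse(c(parts, len), rest)
    }
  }
  if (n < min_len) return(1L)
  recurse(integer(0), n)
  cumsum(c(1L, best_parts[-length(best_parts)]))
}

# Random piecewise-constant test instance: n bins, 0-2 changepoints
# respecting the minimum segment length, levels ~ N(0, 0.5), noise sd 0.1.
random_segmentation_instance <- function(min_n = 6L, max_n = 30L) {
  n <- sample(min_n:max_n, 1L)
  n_cp <- sample(0:2, 1L)
  cps <- integer(0)
  if (n_cp > 0 && n >= 3L * (n_cp + 1L)) {
    # segment lengths >= 3 via composition sampling
    repeat {
      cps <- sort(sample(seq(4L, n - 2L), n_cp))
      lens <- diff(c(1L, cps, n + 1L))
      if (all(lens >= 3L)) break
    }
  }
  levels <- stats::rnorm(length(cps) + 1L, 0, 0.5)
  starts <- c(1L, cps)
  ends <- c(cps - 1L, n)
  y <- numeric(n)
  for (k in seq_along(starts)) y[starts[k]:ends[k]] <- levels[k]
  y + stats::rnorm(n, 0, 0.1)
}

# Brute-force delta-Cq for one sample x gene: replicate-paired differences
# averaged, written independently of compute_delta_cq()
oracle_delta_cq <- function(target_cq, ref_cq) {
  mean(target_cq - ref_cq)
}
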