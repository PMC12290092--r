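# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All simulator randomness goes through this so that
# sessions are reproducible without clobbering the user's stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-unit child seed from a master seed; stays below 2^31.
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 2654435761 + index * 40503) %% 2147483647)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(paste0("`", name, "` must be a single finite number."))
  }
  if (positive && x <= 0) abort(paste0("`", name, "` must be positive."))
  invisible(x)
}

# Check that a grid is uniform to within a tight relative tolerance.
is_uniform_grid <- function(x, tol = 1e-9) {
  if (length(x) < 2L) return(TRUE)
  d <- diff(x)
  all(abs(d - mean(d)) < tol * max(abs(mean(d)), 1))
}

# Merge possibly-overlapping closed intervals given as a two-column matrix /
# data frame (start, end); returns a tibble sorted by start with overlaps and
# abutting intervals coalesced.
merge_intervals <- function(start, end) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0L) {
    return(tibble(start_s = numeric(0), end_s = numeric(0)))
  }
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (k in seq_along(start)[-1]) {
    if (start[k] <= me) {
      me <- max(me, end[k])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[k]; me <- end[k]
    }
  }
  tibble(start_s = c(out_s, ms), end_s = c(out_e, me))
}

# TRUE for points x lying inside any of the [start, end] intervals.
points_in_intervals <- function(x, start, end) {
  if (length(start) == 0L) return(rep(FALSE, length(x)))
  hit <- rep(FALSE, length(x))
  for (k in seq_along(start)) hit <- hit | (x >= start[k] & x <= end[k])
  hit
}

# TRUE where [a1, a2] overlaps any [start, end] interval.
ranges_overlap_any <- function(a1, a2, start, end) {
  if (length(start) == 0L) return(rep(FALSE, length(a1)))
  hit <- rep(FALSE, length(a1))
  for (k in seq_along(start)) hit <- hit | (a1 <= end[k] & a2 >= start[k])
  hit
}

# Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch via symmetric
# tridiagonal eigen-decomposition); used for the kernel quadratures.
gauss_legendre <- function(n) {
  if (n == 1L) return(list(x = 0, w = 2))
  k <- seq_len(n - 1L)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1L)] <- b
  J[cbind(k + 1L, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = 2 * e$vectors[1, ]^2)
}
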