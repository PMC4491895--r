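#' Histogram mutual information between a series and its lagged copy
#'
#' Estimates the mutual information (in nats) between `Z_t` and `Z_(t+lag)`
#' with equal-width binning over each marginal's observed range. Used to
#' pick the embedding delay: a good delay keeps the components of the
#' reconstructed state related while minimizing their shared information.
#'
#' @param series numeric vector (at least 50 points).
#' @param lag non-negative integer, `lag < length(series) / 2`. `lag = 0`
#'   gives the self-information (entropy of the binned marginal).
#' @param n_bins number of bins per marginal; the default
#'   `min(16, floor(sqrt(N / 5)))` keeps roughly five samples per joint
#'   histogram cell and bounds the estimator bias (about `(k-1)^2 / 2N`
#'   nats for independent data) well below the MI scale of interest.
#' @return mutual information in nats (>= 0).
#' @export
#' @examples
#' z <- sin(2 * pi * (1:500) / 40)
#' mutual_information(z, 10)
mutual_information <- function(series, lag,
                               n_bins = default_bins(length(series))) {
  series <- check_series(series)
  N <- length(series)
  lag <- as.integer(lag)
  if (is.na(lag) || lag < 0L || lag >= N / 2)
    stop("`lag` must satisfy 0 <= lag < N/2", call. = FALSE)
  if (n_bins < 2L) stop("`n_bins` must be >= 2", call. = FALSE)
  x <- series[seq_len(N - lag)]
  y <- series[seq_len(N - lag) + lag]
  hist_mi(x, y, n_bins)
}

default_bins <- function(n) max(2L, min(16L, floor(sqrt(n / 5))))

# neighbor statistics in dimension m need roughly an order of magnitude of
# data per dimension; beyond this, "nearest" neighbors at a 3% recurrence
# rate are no longer local
default_max_dim <- function(n) max(2L, min(10L, floor(log10(n)) + 1L))

# equal-width histogram MI in nats; 0 * log 0 treated as 0
hist_mi <- function(x, y, n_bins) {
  bx <- bin_index(x, n_bins)
  by <- bin_index(y, n_bins)
  joint <- tabulate(bx + n_bins * (by - 1L), nbins = n_bins * n_bins)
  p <- joint / length(x)
  px <- tabulate(bx, nbins = n_bins) / length(x)
  py <- tabulate(by, nbins = n_bins) / length(y)
  pp <- outer(px, py)
  nz <- p > 0
  max(0, sum(p[nz] * log(p[nz] / pp[nz])))
}

bin_index <- function(v, n_bins) {
  rng <- range(v)
  if (rng[1L] == rng[2L]) return(rep.int(1L, length(v)))
  idx <- floor((v - rng[1L]) / (rng[2L] - rng[1L]) * n_bins) + 1L
  pmin.int(idx, n_bins)
}

check_series <- function(series) {
  series <- as.numeric(series)
  if (anyNA(series)) stop("series contains NA", call. = FALSE)
  if (length(series) < 50L)
    stop("series must have at least 50 points", call. = FALSE)
  series
}

#' Select the embedding delay by the first minimum of mutual information
#'
#' Scans lags `1..max_lag` and returns the smallest lag that is a strict
#' local minimum of the mutual-information profile (both neighbors larger;
#' lag 0 uses the self-information). Noise-dominated series often have a
#' monotonically decreasing profile with no minimum; the conservative
#' fallback is then delay 1, flagged.
#'
#' @inheritParams mutual_information
#' @param max_lag largest lag scanned; default `min(100, N %/% 2 - 2)`.
#' @return list with `delay` (integer), `flagged` (TRUE when the fallback
#'   was used), and `mi` (the profile over lags `0..max_lag`).
#' @export
select_delay <- function(series, max_lag = NULL,
                         n_bins = default_bins(length(series))) {
  series <- check_series(series)
  N <- length(series)
  if (is.null(max_lag)) max_lag <- min(100L, N %/% 2L - 2L)
  max_lag <- as.integer(max_lag)
  if (max_lag < 1L || max_lag >= N / 2)
    stop("`max_lag` must satisfy 1 <= max_lag < N/2", call. = FALSE)
  mi <- vapply(0:max_lag, function(l) mutual_information(series, l, n_bins),
               numeric(1))
  for (lag in 1:(max_lag - 1L)) {
    if (mi[lag] > mi[lag + 1L] && mi[lag + 1L] < mi[lag + 2L])
      return(list(delay = lag, flagged = FALSE, mi = mi))
  }
  list(delay = 1L, flagged = TRUE, mi = mi)
}

# delay-embedded state matrix: row i = (Z_i, Z_{i+d}, ..., Z_{i+(m-1)d})
embed_states <- function(series, delay, dim) {
  n_states <- length(series) - (dim - 1L) * delay
  idx <- outer(seq_len(n_states), (seq_len(dim) - 1L) * delay, "+")
  matrix(series[idx], nrow = n_states, ncol = dim)
}

#' Fraction of false nearest neighbors at a given embedding dimension
#'
#' For each state embedded at dimension `dim`, finds its nearest neighbor
#' and declares the pair false when increasing the dimension to `dim + 1`
#' separates them: either the distance increment ratio exceeds `r_tol`, or
#' the `(dim+1)`-dimensional distance exceeds `a_tol` series standard
#' deviations (the classical double criterion). A high fraction means the
#' attractor is still folded by projection; the fraction of a well-embedded
#' deterministic signal is near zero.
#'
#' @inheritParams mutual_information
#' @param delay embedding delay (frames).
#' @param dim embedding dimension at which neighbors are found.
#' @param r_tol distance-ratio tolerance (default 15).
#' @param a_tol absolute tolerance in series standard deviations (default 2).
#' @return fraction in `[0, 1]`. Degenerate series with all states
#'   coincident give 0 (no false neighbor is distinguishable).
#' @export
false_nearest_neighbors_fraction <- function(series, delay, dim,
                                             r_tol = 15, a_tol = 2) {
  series <- check_series(series)
  delay <- as.integer(delay); dim <- as.integer(dim)
  if (delay < 1L || dim < 1L)
    stop("`delay` and `dim` must be positive integers", call. = FALSE)
  # only states extendable to dim + 1 can be examined
  n_use <- length(series) - dim * delay
  if (n_use < 10L)
    stop("too few states to examine dimension ", dim + 1L, call. = FALSE)
  E <- embed_states(series, delay, dim)[seq_len(n_use), , drop = FALSE]
  D <- as.matrix(stats::dist(E))
  diag(D) <- Inf
  nn <- max.col(-D, ties.method = "first")
  r_m <- D[cbind(seq_len(n_use), nn)]
  extra <- abs(series[seq_len(n_use) + dim * delay] -
                 series[nn + dim * delay])
  sd_a <- stats::sd(series)
  if (sd_a == 0) return(0)
  r_m1 <- sqrt(r_m^2 + extra^2)
  # distance floor: coincident states (exactly periodic signals) have
  # rounding-level r_m, making the increment ratio meaningless
  floor_d <- 1e-8 * sd_a
  mean(extra > r_tol * pmax(r_m, floor_d) | r_m1 > a_tol * sd_a)
}

#' Select the embedding dimension by false nearest neighbors
#'
#' Returns the smallest dimension `m <= max_dim` whose false-nearest-neighbor
#' fraction falls below `threshold`; if none does (typical for
#' noise-dominated series), returns `max_dim`, flagged.
#'
#' @inheritParams false_nearest_neighbors_fraction
#' @param max_dim largest dimension examined; the default
#'   `floor(log10(N)) + 1` (capped to 2..10) reflects that neighbor
#'   statistics need roughly an order of magnitude of data per embedding
#'   dimension.
#' @param threshold FNN fraction below which the trajectory is considered
#'   unfolded (default 0.01).
#' @return list with `dimension`, `flagged`, and `fractions` (the FNN
#'   fraction at each examined dimension).
#' @export
select_dimension <- function(series, delay,
                             max_dim = default_max_dim(length(series)),
                             threshold = 0.01, r_tol = 15, a_tol = 2) {
  series <- check_series(series)
  max_dim <- as.integer(max_dim)
  if (max_dim < 1L) stop("`max_dim` must be >= 1", call. = FALSE)
  fractions <- numeric(0)
  for (m in seq_len(max_dim)) {
    f <- false_nearest_neighbors_fraction(series, delay, m, r_tol, a_tol)
    fractions[m] <- f
    if (f < threshold)
      return(list(dimension = m, flagged = FALSE, fractions = fractions))
  }
  list(dimension = max_dim, flagged = TRUE, fractions = fractions)
}

#' Delay-embed a scalar series into phase space
#'
#' Reconstructs the phase-space trajectory by the method of delays: state
#' `i` is `(Z_i, Z_{i+d}, ..., Z_{i+(m-1)d})`, giving
#' `N - (m-1) d` states.
#'
#' @inheritParams false_nearest_neighbors_fraction
#' @param dim embedding dimension `m`.
#' @param residue_id optional label carried through to recurrence objects.
#' @return object of class `phase_trajectory`: the state matrix
#'   (`n_states` x `m`) with attributes `delay`, `dim`, `residue_id`.
#' @export
#' @examples
#' embed_series(c(1, 2, 3, 4, 5) * 1.0, delay = 1, dim = 2)
embed_series <- function(series, delay, dim, residue_id = NULL) {
  series <- as.numeric(series)
  if (anyNA(series)) stop("series contains NA", call. = FALSE)
  delay <- as.integer(delay); dim <- as.integer(dim)
  if (delay < 1L || dim < 1L)
    stop("`delay` and `dim` must be positive integers", call. = FALSE)
  n_states <- length(series) - (dim - 1L) * delay
  if (n_states < 10L)
    stop("series too short: N - (m-1)d = ", n_states,
         " states (need >= 10)", call. = FALSE)
  structure(embed_states(series, delay, dim),
            delay = delay, residue_id = residue_id,
            class = c("phase_trajectory", "matrix", "array"))
}

#' @export
print.phase_trajectory <- function(x, ...) {
  cat("Phase trajectory: ", nrow(x), " states\n", sep = "")
  cat("  delay d =", attr(x, "delay"), ", dimension m =", ncol(x), "\n")
  if (!is.null(attr(x, "residue_id")))
    cat("  residue:", attr(x, "residue_id"), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Choose embedding parameters for every residue
#'
#' Applies [select_delay()] then [select_dimension()] to each row of the
#' series matrix. Each residue gets its own `(d, m)`; set `global = TRUE`
#' to force the component-wise maximum on all residues (aligned state
#' counts).
#'
#' @param series residue x frame numeric matrix (rownames = residue ids).
#' @param max_lag,n_bins passed to [select_delay()].
#' @param max_dim,threshold,r_tol,a_tol passed to [select_dimension()].
#' @param global force a single `(d, m)` = per-column maximum.
#' @return data frame with columns `residue_id`, `delay`, `dimension`,
#'   `delay_flagged`, `dimension_flagged`.
#' @export
select_embedding <- function(series, max_lag = NULL, n_bins = NULL,
                             max_dim = NULL, threshold = 0.01,
                             r_tol = 15, a_tol = 2, global = FALSE) {
  if (!is.matrix(series)) stop("`series` must be a matrix", call. = FALSE)
  ids <- rownames(series) %||% as.character(seq_len(nrow(series)))
  if (is.null(n_bins)) n_bins <- default_bins(ncol(series))
  if (is.null(max_dim)) max_dim <- default_max_dim(ncol(series))
  rows <- lapply(seq_len(nrow(series)), function(r) {
    z <- series[r, ]
    dsel <- if (is.null(max_lag)) select_delay(z, n_bins = n_bins)
            else select_delay(z, max_lag = max_lag, n_bins = n_bins)
    msel <- select_dimension(z, dsel$delay, max_dim = max_dim,
                             threshold = threshold,
                             r_tol = r_tol, a_tol = a_tol)
    data.frame(residue_id = ids[r], delay = dsel$delay,
               dimension = msel$dimension,
               delay_flagged = dsel$flagged,
               dimension_flagged = msel$flagged)
  })
  out <- do.call(rbind, rows)
  if (global) {
    out$delay <- max(out$delay)
    out$dimension <- max(out$dimension)
  }
  rownames(out) <- NULL
  out
}
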