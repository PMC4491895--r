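#' Calibrate the recurrence threshold to a target recurrence rate
#'
#' Chooses the threshold distance epsilon so that the achieved recurrence
#' rate — black dots over total matrix points, line of identity included —
#' is the smallest achievable value at or above `target_rate`. The
#' calibration is an exact quantile selection on the sorted list of all
#' pairwise state distances; no bisection is involved, and the achieved
#' rate is reported alongside.
#'
#' @param traj a [embed_series()] phase trajectory (or any numeric state
#'   matrix, rows = states).
#' @param target_rate target recurrence rate in `(0, 1)`; default 0.03.
#' @return list with `epsilon`, `achieved_rate`, `n_states`, and
#'   `flagged` (TRUE for the degenerate all-states-identical case, where
#'   any positive epsilon saturates the matrix).
#' @export
#' @examples
#' traj <- embed_series(sin(2 * pi * (1:300) / 40), delay = 10, dim = 2)
#' calibrate_epsilon(traj, 0.03)
calibrate_epsilon <- function(traj, target_rate = 0.03) {
  if (!is.numeric(target_rate) || target_rate <= 0 || target_rate >= 1)
    stop("`target_rate` must lie in (0, 1)", call. = FALSE)
  states <- unclass_states(traj)
  n <- nrow(states)
  d <- as.numeric(stats::dist(states))
  if (max(d) == 0) {
    warning("all states identical: any positive epsilon gives rate 1")
    return(list(epsilon = .Machine$double.xmin, achieved_rate = 1,
                n_states = n, flagged = TRUE))
  }
  # rate with k off-diagonal upper-triangle recurrences: (2k + n) / n^2
  k_needed <- ceiling((target_rate * n^2 - n) / 2)
  if (k_needed <= 0) {
    # the diagonal alone already meets the target (plus any coincident states)
    eps <- min(d[d > 0]) / 2
    return(list(epsilon = eps,
                achieved_rate = (2 * sum(d <= eps) + n) / n^2,
                n_states = n, flagged = FALSE))
  }
  eps <- sort(d, partial = k_needed)[k_needed]
  k_achieved <- sum(d <= eps)  # ties at eps recur too
  list(epsilon = eps, achieved_rate = (2 * k_achieved + n) / n^2,
       n_states = n, flagged = FALSE)
}

unclass_states <- function(traj) {
  if (!is.matrix(traj) || !is.numeric(unclass(traj)))
    stop("`traj` must be a numeric state matrix", call. = FALSE)
  m <- unclass(traj)
  attributes(m) <- list(dim = dim(m))
  m
}

# (i, j) row/column indices, i < j, for the vector returned by stats::dist
dist_pair_indices <- function(n) {
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  cbind(i = i, j = j)
}

#' Build a recurrence matrix from a phase trajectory
#'
#' Marks state pairs whose Euclidean distance is at most `epsilon`
#' (Heaviside convention: ties at the threshold recur). The result is a
#' symmetric binary matrix with a unit diagonal, stored sparsely as the
#' strictly-upper-triangle recurrent pairs.
#'
#' @inheritParams calibrate_epsilon
#' @param epsilon threshold distance (> 0), e.g. from
#'   [calibrate_epsilon()].
#' @return object of class `recurrence_matrix`: list with `pairs`
#'   (2-column matrix of recurrent `i < j`), `n_states`, `epsilon`,
#'   `recurrence_rate` (diagonal included), `residue_id`. Use
#'   [as.matrix()] for the dense 0/1 form.
#' @export
recurrence_matrix <- function(traj, epsilon) {
  if (!is.numeric(epsilon) || epsilon <= 0)
    stop("`epsilon` must be > 0", call. = FALSE)
  states <- unclass_states(traj)
  n <- nrow(states)
  d <- as.numeric(stats::dist(states))
  sel <- which(d <= epsilon)
  pairs <- dist_pair_indices(n)[sel, , drop = FALSE]
  structure(
    list(pairs = pairs, n_states = n, epsilon = epsilon,
         recurrence_rate = (2 * length(sel) + n) / n^2,
         residue_id = attr(traj, "residue_id")),
    class = "recurrence_matrix")
}

#' @export
print.recurrence_matrix <- function(x, ...) {
  cat("Recurrence matrix: ", x$n_states, " x ", x$n_states,
      " states, epsilon = ", signif(x$epsilon, 4),
      ", rate = ", signif(x$recurrence_rate, 4), "\n", sep = "")
  if (!is.null(x$residue_id)) cat("  residue:", x$residue_id, "\n")
  invisible(x)
}

#' @export
as.matrix.recurrence_matrix <- function(x, ...) {
  m <- diag(1L, x$n_states)
  if (nrow(x$pairs)) {
    m[x$pairs] <- 1L
    m[x$pairs[, c(2L, 1L)]] <- 1L
  }
  m
}

#' Embed a residue series and build its rate-calibrated recurrence matrix
#'
#' Convenience wrapper: delay-embed, calibrate epsilon to `target_rate`,
#' and return the recurrence matrix (with `calibration` attached).
#'
#' @inheritParams embed_series
#' @inheritParams calibrate_epsilon
#' @return a [recurrence_matrix()] with a `calibration` element.
#' @export
residue_recurrence <- function(series, delay, dim, target_rate = 0.03,
                               residue_id = NULL) {
  traj <- embed_series(series, delay, dim, residue_id = residue_id)
  cal <- calibrate_epsilon(traj, target_rate)
  rp <- recurrence_matrix(traj, cal$epsilon)
  rp$calibration <- cal
  rp
}

# strictly-upper-triangle linear keys of recurrent pairs with both
# indices <= n (truncation to the common leading window)
truncated_keys <- function(rp, n) {
  p <- rp$pairs
  p <- p[p[, 2L] <= n, , drop = FALSE]
  # key of (i, j), i < j <= n, in column-major upper-triangle order
  (p[, 2L] - 1L) * (p[, 2L] - 2L) / 2 + p[, 1L]
}

#' Count joint recurrences of two residues
#'
#' A joint recurrence occurs at a time pair `(i, j)` when both residues
#' simultaneously recur to their previous states: `R^x_ij = R^y_ij = 1`.
#' The line of identity is excluded (it recurs trivially for every
#' residue) and each unordered time pair is counted once. When the two
#' matrices have different state counts they are truncated to the common
#' leading window `1..min(n_x, n_y)`, preserving simultaneity of time
#' indices.
#'
#' @param rx,ry [recurrence_matrix()] objects.
#' @return list with `residues` (the pair of labels), `count`, and
#'   `n_states` (common window size).
#' @export
joint_recurrence_count <- function(rx, ry) {
  if (!inherits(rx, "recurrence_matrix") ||
      !inherits(ry, "recurrence_matrix"))
    stop("both arguments must be recurrence_matrix objects", call. = FALSE)
  n <- min(rx$n_states, ry$n_states)
  if (n < 2L) stop("common state window too small", call. = FALSE)
  kx <- truncated_keys(rx, n)
  ky <- truncated_keys(ry, n)
  list(residues = c(rx$residue_id %||% NA, ry$residue_id %||% NA),
       count = length(intersect(kx, ky)), n_states = n)
}

#' Joint-recurrence counts for every residue pair
#'
#' Truncates all recurrence matrices to the common leading window
#' `n_min = min(n_states)` and counts, for every unordered residue pair,
#' the strictly-upper-triangle time pairs at which both recur. The count
#' is computed as a sparse indicator cross-product over matrix cells,
#' which keeps the full-scale case (hundreds of residues, ~10^6-cell
#' matrices) to seconds.
#'
#' @param rps list of [recurrence_matrix()] objects (one per residue).
#' @return data frame with columns `res_a`, `res_b`, `count` (all unordered
#'   pairs, `a` before `b` in input order), and attribute `n_states` = the
#'   common truncated window.
#' @export
joint_recurrence_counts <- function(rps) {
  if (!is.list(rps) || length(rps) < 2L)
    stop("`rps` must be a list of at least two recurrence matrices",
         call. = FALSE)
  ok <- vapply(rps, inherits, logical(1), "recurrence_matrix")
  if (!all(ok))
    stop("all elements of `rps` must be recurrence_matrix objects",
         call. = FALSE)
  ids <- vapply(seq_along(rps), function(k)
    as.character(rps[[k]]$residue_id %||% k), character(1))
  n_min <- min(vapply(rps, `[[`, numeric(1), "n_states"))
  n_cells <- n_min * (n_min - 1L) / 2
  keys <- lapply(rps, truncated_keys, n = n_min)
  M <- Matrix::sparseMatrix(
    i = unlist(keys),
    j = rep.int(seq_along(rps), lengths(keys)),
    x = 1, dims = c(n_cells, length(rps)))
  counts <- as.matrix(Matrix::crossprod(M))
  idx <- which(upper.tri(counts), arr.ind = TRUE)
  out <- data.frame(res_a = ids[idx[, 1L]], res_b = ids[idx[, 2L]],
                    count = as.integer(counts[idx]))
  attr(out, "n_states") <- as.integer(n_min)
  out
}

#' Export a recurrence matrix as a plain 0/1 text grid
#'
#' @param rp a [recurrence_matrix()].
#' @param path output file; rows are space-separated 0/1.
#' @export
write_recurrence_grid <- function(rp, path) {
  m <- as.matrix(rp)
  utils::write.table(m, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write joint-recurrence counts as a three-column TSV
#'
#' @param counts data frame from [joint_recurrence_counts()].
#' @param path output file with columns `res_a`, `res_b`, `count`.
#' @export
write_jr_counts_tsv <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
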