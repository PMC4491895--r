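#' Define a synthetic coupled-oscillator system
#'
#' Describes a chain of residues whose per-residue scalar observables are
#' stationary AR(1) processes, with selected residue pairs coupled through a
#' shared latent AR(1) driver. The generator stands in for per-residue RMSD
#' traces from a molecular dynamics trajectory: every downstream stage
#' (embedding, recurrence, joint recurrence, network, centrality) can be
#' exercised against a known coupling topology and analytic straight-chain
#' geometry.
#'
#' Coupled pairs share a latent driver added to both members with weight
#' `coupling_strength`; the residue's own AR(1) component is scaled by
#' `sqrt(1 - k * coupling_strength^2)` (k = number of pairs the residue
#' belongs to) so every series keeps unit stationary variance. The
#' correlation induced between the members of a coupled pair is therefore
#' `coupling_strength^2`.
#'
#' @param n_residues number of residues (>= 3).
#' @param n_frames number of frames per series (>= 100).
#' @param coupling_pairs residue-index pairs sharing a latent driver; a list
#'   of length-2 vectors or a 2-column matrix. No self-pairs.
#' @param coupling_strength weight of the shared driver, in `[0, 1)`.
#' @param noise_sd standard deviation of additive white observation noise.
#' @param ar1 lag-1 autocorrelation of the AR(1) components, in `[0, 1)`.
#'   The default 0.9 gives series with non-trivial embedding structure.
#' @param chain_spacing consecutive C-alpha spacing in Angstrom (default 3.8,
#'   the consecutive C-alpha distance of a real polypeptide chain).
#' @param seed integer seed; output is deterministic given the system.
#' @return an object of class `synthetic_system`.
#' @seealso [generate_series()], [generate_reference_coordinates()]
#' @export
#' @examples
#' sys <- synthetic_system(12, 400, coupling_pairs = list(c(2, 5)),
#'                         coupling_strength = 0.8, seed = 7)
#' Z <- generate_series(sys)
#' dim(Z)
synthetic_system <- function(n_residues, n_frames, coupling_pairs = list(),
                             coupling_strength = 0, noise_sd = 0.1,
                             ar1 = 0.9, chain_spacing = 3.8, seed = 1L) {
  n_residues <- as.integer(n_residues)
  n_frames <- as.integer(n_frames)
  if (is.na(n_residues) || n_residues < 3L)
    stop("`n_residues` must be an integer >= 3", call. = FALSE)
  if (is.na(n_frames) || n_frames < 100L)
    stop("`n_frames` must be an integer >= 100", call. = FALSE)
  if (!is.numeric(coupling_strength) || coupling_strength < 0 ||
      coupling_strength >= 1)
    stop("`coupling_strength` must lie in [0, 1)", call. = FALSE)
  if (!is.numeric(ar1) || ar1 < 0 || ar1 >= 1)
    stop("`ar1` must lie in [0, 1)", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be >= 0", call. = FALSE)
  if (!is.numeric(chain_spacing) || chain_spacing <= 0)
    stop("`chain_spacing` must be > 0", call. = FALSE)

  pairs <- normalize_pairs(coupling_pairs, n_residues)
  # per-residue driver load must leave positive variance for the own process
  if (nrow(pairs)) {
    load <- tabulate(c(pairs), nbins = n_residues) * coupling_strength^2
    if (any(load >= 1))
      stop("a residue's total coupling load (k * coupling_strength^2) ",
           "must be < 1", call. = FALSE)
  }

  structure(
    list(n_residues = n_residues, n_frames = n_frames,
         coupling_pairs = pairs, coupling_strength = coupling_strength,
         noise_sd = noise_sd, ar1 = ar1, chain_spacing = chain_spacing,
         seed = as.integer(seed)),
    class = "synthetic_system")
}

# canonical 2-column matrix of unordered pairs, a < b, no self-pairs, no dups
normalize_pairs <- function(coupling_pairs, n_residues) {
  if (is.matrix(coupling_pairs)) {
    pairs <- coupling_pairs
  } else if (is.list(coupling_pairs)) {
    if (!length(coupling_pairs))
      return(matrix(integer(), ncol = 2L,
                    dimnames = list(NULL, c("a", "b"))))
    pairs <- do.call(rbind, lapply(coupling_pairs, as.integer))
  } else {
    stop("`coupling_pairs` must be a list of pairs or a 2-column matrix",
         call. = FALSE)
  }
  if (ncol(pairs) != 2L)
    stop("coupling pairs must have exactly two members", call. = FALSE)
  storage.mode(pairs) <- "integer"
  if (any(is.na(pairs)) || any(pairs < 1L) || any(pairs > n_residues))
    stop("coupling pair indices must lie in 1..n_residues", call. = FALSE)
  if (any(pairs[, 1L] == pairs[, 2L]))
    stop("coupling pairs must not be self-pairs", call. = FALSE)
  pairs <- t(apply(pairs, 1L, sort))
  pairs <- unique(pairs)
  dimnames(pairs) <- list(NULL, c("a", "b"))
  pairs
}

#' @export
print.synthetic_system <- function(x, ...) {
  cat("Synthetic residue system:", x$n_residues, "residues x",
      x$n_frames, "frames\n")
  cat("  AR(1) autocorrelation:", x$ar1, " observation noise sd:",
      x$noise_sd, "\n")
  if (nrow(x$coupling_pairs)) {
    cat("  coupled pairs (strength ", x$coupling_strength, "): ",
        paste(sprintf("(%d,%d)", x$coupling_pairs[, 1L],
                      x$coupling_pairs[, 2L]), collapse = ", "), "\n",
        sep = "")
  } else cat("  no coupled pairs\n")
  cat("  chain spacing:", x$chain_spacing, "A, seed:", x$seed, "\n")
  invisible(x)
}

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# rows of stationary unit-variance AR(1) series, vectorized over rows
ar1_rows <- function(n_rows, n_cols, phi) {
  if (n_rows == 0L)
    return(matrix(numeric(), nrow = 0L, ncol = n_cols))
  innov_sd <- sqrt(1 - phi^2)
  x0 <- stats::rnorm(n_rows)
  innov <- matrix(stats::rnorm(n_rows * n_cols, sd = innov_sd),
                  nrow = n_rows)
  out <- matrix(0, nrow = n_rows, ncol = n_cols)
  for (r in seq_len(n_rows)) {
    out[r, ] <- stats::filter(innov[r, ], phi, method = "recursive",
                              init = x0[r])
  }
  out
}

#' Generate the per-residue scalar time-series matrix
#'
#' Simulates one observable per residue over evenly spaced frames. Each
#' residue is a stationary unit-variance AR(1) process; members of each
#' coupling pair additionally share a latent AR(1) driver (see
#' [synthetic_system()]), and white observation noise of sd `noise_sd` is
#' added. Output is bit-identical for identical systems (including seed).
#'
#' @param sys a [synthetic_system()].
#' @return numeric matrix, `n_residues` x `n_frames`, rownames = residue ids.
#' @export
generate_series <- function(sys) {
  if (!inherits(sys, "synthetic_system"))
    stop("`sys` must be a synthetic_system", call. = FALSE)
  with_seed(sys$seed, {
    n <- sys$n_residues
    N <- sys$n_frames
    base <- ar1_rows(n, N, sys$ar1)
    pairs <- sys$coupling_pairs
    cs <- sys$coupling_strength
    drivers <- ar1_rows(nrow(pairs), N, sys$ar1)
    load <- if (nrow(pairs))
      tabulate(c(pairs), nbins = n) * cs^2 else numeric(n)
    Z <- sqrt(pmax(0, 1 - load)) * base
    for (p in seq_len(nrow(pairs))) {
      Z[pairs[p, 1L], ] <- Z[pairs[p, 1L], ] + cs * drivers[p, ]
      Z[pairs[p, 2L], ] <- Z[pairs[p, 2L], ] + cs * drivers[p, ]
    }
    if (sys$noise_sd > 0)
      Z <- Z + matrix(stats::rnorm(n * N, sd = sys$noise_sd), nrow = n)
    dimnames(Z) <- list(as.character(seq_len(n)), NULL)
    Z
  })
}

#' Reference C-alpha coordinates for a synthetic system
#'
#' Places the residues on a straight line spaced `chain_spacing` Angstrom
#' apart, so geometric expectations (pairwise distances, the 7 A cutoff
#' network being a path graph) are analytic.
#'
#' @param sys a [synthetic_system()].
#' @return data frame with columns `residue_id`, `x`, `y`, `z` (Angstrom).
#' @export
generate_reference_coordinates <- function(sys) {
  if (!inherits(sys, "synthetic_system"))
    stop("`sys` must be a synthetic_system", call. = FALSE)
  data.frame(residue_id = seq_len(sys$n_residues),
             x = (seq_len(sys$n_residues) - 1) * sys$chain_spacing,
             y = 0, z = 0)
}
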