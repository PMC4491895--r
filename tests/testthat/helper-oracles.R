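# Independent brute-force oracles. These deliberately re-derive every
# quantity with naive loops so agreement with the package's vectorized /
# library-backed implementations is a meaningful check.

# histogram mutual information, nested loops over bins
naive_mi <- function(x, y, n_bins) {
  bin_of <- function(v) {
    r <- range(v)
    if (r[1] == r[2]) return(rep(1L, length(v)))
    pmin(floor((v - r[1]) / (r[2] - r[1]) * n_bins) + 1L, n_bins)
  }
  bx <- bin_of(x); by <- bin_of(y)
  n <- length(x)
  mi <- 0
  for (a in 1:n_bins) for (b in 1:n_bins) {
    pab <- sum(bx == a & by == b) / n
    if (pab > 0) {
      pa <- sum(bx == a) / n
      pb <- sum(by == b) / n
      mi <- mi + pab * log(pab / (pa * pb))
    }
  }
  mi
}

# dense recurrence matrix by double loop (diagonal = 1, ties recur)
naive_recurrence <- function(states, eps) {
  n <- nrow(states)
  R <- matrix(0L, n, n)
  for (i in 1:n) for (j in 1:n) {
    d <- sqrt(sum((states[i, ] - states[j, ])^2))
    if (d <= eps) R[i, j] <- 1L
  }
  R
}

# joint count: strictly-upper-triangle AND of dense matrices, after
# truncating both to the common leading window
naive_jr_count <- function(Rx, Ry) {
  n <- min(nrow(Rx), nrow(Ry))
  cnt <- 0L
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (Rx[i, j] == 1L && Ry[i, j] == 1L) cnt <- cnt + 1L
  }
  cnt
}

# all-pairs shortest paths over an edge-length matrix (Inf = no edge)
floyd_warshall <- function(L) {
  n <- nrow(L)
  D <- L
  diag(D) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

oracle_closeness <- function(L) {
  D <- floyd_warshall(L)
  n <- nrow(D)
  sapply(1:n, function(v) {
    d <- D[v, -v]
    reach <- is.finite(d)
    if (any(reach)) sum(reach) / sum(d[reach]) else 0
  })
}

# enumerate every shortest path s -> t (distance-consistent edges)
enum_shortest_paths <- function(s, t, L, D, tol = 1e-9) {
  if (s == t) return(list(s))
  out <- list()
  for (u in which(is.finite(L[s, ]))) {
    if (u != s && abs(L[s, u] + D[u, t] - D[s, t]) < tol) {
      for (p in enum_shortest_paths(u, t, L, D, tol))
        out <- c(out, list(c(s, p)))
    }
  }
  out
}

# betweenness by explicit shortest-path enumeration, fractional credit
oracle_betweenness <- function(L) {
  n <- nrow(L)
  D <- floyd_warshall(L)
  B <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t])) next
    paths <- enum_shortest_paths(s, t, L, D)
    inner <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
    if (length(inner)) {
      tab <- table(inner)
      idx <- as.integer(names(tab))
      B[idx] <- B[idx] + as.numeric(tab) / length(paths)
    }
  }
  B
}

# random weighted residue network + its edge-length matrix for the oracles
random_weighted_net <- function(seed, max_nodes = 15) {
  set.seed(seed)
  n <- sample(5:max_nodes, 1)
  coords <- data.frame(residue_id = 1:n, x = runif(n, 0, 50),
                       y = runif(n, 0, 50), z = runif(n, 0, 50))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < 0.45
  pairs <- pairs[keep, , drop = FALSE]
  w <- runif(nrow(pairs), 0.5, 2)
  net <- build_contact_network(
    coords, contacts = data.frame(res_a = pairs[, 1], res_b = pairs[, 2],
                                  count = w))
  L <- matrix(Inf, n, n)
  L[pairs] <- 1 / w
  L[pairs[, c(2, 1), drop = FALSE]] <- 1 / w
  # centrality vectors come back in igraph vertex order (= 1..n here)
  list(net = net, L = L, n = n)
}

# random small phase trajectory for recurrence oracles
random_trajectory <- function(seed, max_states = 50) {
  set.seed(seed)
  n <- sample(10:max_states, 1)
  m <- sample(1:3, 1)
  structure(matrix(rnorm(n * m), n, m), residue_id = paste0("r", seed),
            class = c("phase_trajectory", "matrix", "array"))
}
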