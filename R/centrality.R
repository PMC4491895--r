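network_distances <- function(net) {
  g <- net$graph
  w <- if (igraph::ecount(g)) igraph::E(g)$path_length else NULL
  igraph::distances(g, weights = w, algorithm = "dijkstra")
}

#' Closeness centrality of every residue
#'
#' `C_n = (j - 1) / sum_i sd(i, n)` where `sd(i, n)` is the shortest-path
#' distance from node `n` to node `i` and `j` the number of nodes
#' considered. On a weighted network the path distance sums edge path
#' lengths (see [path_length_from_weight()]). In a disconnected network
#' the sum is restricted to the `r` reachable nodes and the numerator
#' becomes `r - 1`; such nodes are flagged via the `"disconnected"`
#' attribute. Isolated nodes get closeness 0.
#'
#' @param net a `residue_network`.
#' @return named numeric vector of closeness values, with a logical
#'   attribute `"disconnected"` marking nodes that cannot reach the whole
#'   network.
#' @export
closeness_centrality <- function(net) {
  stopifnot(inherits(net, "residue_network"))
  D <- network_distances(net)
  n <- nrow(D)
  cl <- numeric(n)
  disc <- logical(n)
  for (v in seq_len(n)) {
    d <- D[v, -v]
    reach <- is.finite(d)
    disc[v] <- !all(reach)
    cl[v] <- if (any(reach)) sum(reach) / sum(d[reach]) else 0
  }
  names(cl) <- rownames(D)
  attr(cl, "disconnected") <- disc
  cl
}

#' Betweenness centrality of every residue
#'
#' Raw (unnormalized) shortest-path betweenness: for every unordered pair
#' of other nodes, the node is credited with the fraction of their
#' shortest paths that pass through it. Computed over the weighted
#' shortest paths defined by the edge path lengths.
#'
#' @param net a `residue_network`.
#' @return named numeric vector of betweenness values.
#' @export
betweenness_centrality <- function(net) {
  stopifnot(inherits(net, "residue_network"))
  g <- net$graph
  w <- if (igraph::ecount(g)) igraph::E(g)$path_length else NULL
  igraph::betweenness(g, weights = w, directed = FALSE,
                      normalized = FALSE)
}

#' Standardize centrality values to z-scores
#'
#' Subtracts the mean and divides by the population standard deviation,
#' so the output has mean 0 and population SD 1.
#'
#' @param values numeric vector (at least 2 values).
#' @return z-scores (names preserved).
#' @export
#' @examples
#' standardize(c(1, 2, 3))
standardize <- function(values) {
  if (length(values) < 2L)
    stop("need at least 2 values to standardize", call. = FALSE)
  mu <- mean(values)
  sigma <- sqrt(mean((values - mu)^2))
  if (sigma == 0)
    stop("degenerate distribution: standard deviation is 0",
         call. = FALSE)
  (values - mu) / sigma
}

#' Betweenness/closeness centrality table with z-scores
#'
#' Computes raw betweenness `B` and closeness `C` for every residue,
#' standardizes each to z-scores, and flags residues exceeding the
#' significance thresholds (defaults: `z_B > 2`, `z_C > 1.5`).
#'
#' @param net a `residue_network`.
#' @param z_b_min,z_c_min significance thresholds on the z-scores.
#' @return data frame with columns `residue_id`, `B`, `C`, `z_B`, `z_C`,
#'   `significant_B`, `significant_C`, `disconnected`.
#' @export
centrality_table <- function(net, z_b_min = 2, z_c_min = 1.5) {
  B <- betweenness_centrality(net)
  C <- closeness_centrality(net)
  z_B <- standardize(B)
  z_C <- standardize(as.numeric(C))
  data.frame(residue_id = names(B), B = as.numeric(B),
             C = as.numeric(C), z_B = as.numeric(z_B), z_C = z_C,
             significant_B = as.numeric(z_B) > z_b_min,
             significant_C = z_C > z_c_min,
             disconnected = attr(C, "disconnected"),
             row.names = NULL)
}

#' Significant residues with their first-degree neighbors
#'
#' Filters the centrality table for residues exceeding either z-score
#' threshold and annotates each with its first-degree network neighbors
#' that are themselves significant or carry a user annotation (e.g.
#' experimentally known hotspots or ion binding sites).
#'
#' @param table centrality table from [centrality_table()].
#' @param net the `residue_network` the table was computed on.
#' @param z_b_min,z_c_min z-score thresholds (defaults 2 and 1.5).
#' @param annotations optional data frame with `residue_id`, `label`
#'   (e.g. hotspot-cluster names); annotated neighbors are reported with
#'   their label even when not significant themselves.
#' @return data frame with `residue_id`, `criterion` (`"B"`, `"C"`, or
#'   `"B+C"`), `z_B`, `z_C`, `label`, `significant_neighbors`
#'   (comma-separated, possibly empty). Empty data frame when nothing is
#'   significant.
#' @export
significant_residues <- function(table, net, z_b_min = 2, z_c_min = 1.5,
                                 annotations = NULL) {
  stopifnot(inherits(net, "residue_network"))
  sig_b <- table$z_B > z_b_min
  sig_c <- table$z_C > z_c_min
  sel <- which(sig_b | sig_c)
  ann <- character(0)
  if (!is.null(annotations)) {
    if (!all(c("residue_id", "label") %in% names(annotations)))
      stop("`annotations` must have columns residue_id, label",
           call. = FALSE)
    ann <- stats::setNames(as.character(annotations$label),
                           as.character(annotations$residue_id))
  }
  sig_ids <- as.character(table$residue_id[sel])
  g <- net$graph
  rows <- lapply(sel, function(i) {
    id <- as.character(table$residue_id[i])
    nb <- if (id %in% igraph::V(g)$name)
      igraph::neighbors(g, id)$name else character(0)
    keep <- nb[nb %in% sig_ids | nb %in% names(ann)]
    keep_lab <- vapply(keep, function(x)
      if (x %in% names(ann)) paste0(x, " (", ann[[x]], ")") else x,
      character(1))
    data.frame(
      residue_id = id,
      criterion = if (sig_b[i] && sig_c[i]) "B+C"
                  else if (sig_b[i]) "B" else "C",
      z_B = table$z_B[i], z_C = table$z_C[i],
      label = if (id %in% names(ann)) ann[[id]] else "",
      significant_neighbors = paste(keep_lab, collapse = ", "))
  })
  if (!length(rows))
    return(data.frame(residue_id = character(), criterion = character(),
                      z_B = numeric(), z_C = numeric(),
                      label = character(),
                      significant_neighbors = character()))
  out <- do.call(rbind, rows)
  # rank by the larger exceedance so the strongest candidates lead
  out[order(pmax(out$z_B - z_b_min, out$z_C - z_c_min),
            decreasing = TRUE), , drop = FALSE]
}

#' Write a Markdown report of significant residues
#'
#' One section per centrality, listing each significant residue with its
#' z-scores, optional RSA, annotation label, and significant first-degree
#' neighbors.
#'
#' @param table centrality table from [centrality_table()].
#' @param net the `residue_network`.
#' @param path output Markdown file.
#' @param exposure optional exposure table (from [exposure_table()]) used
#'   to report per-residue RSA.
#' @inheritParams significant_residues
#' @return the path, invisibly.
#' @export
write_significant_report <- function(table, net, path, z_b_min = 2,
                                     z_c_min = 1.5, annotations = NULL,
                                     exposure = NULL) {
  rsa_of <- function(id) {
    if (is.null(exposure)) return("-")
    i <- match(id, as.character(exposure$residue_id))
    if (is.na(i)) "-" else sprintf("%.2f", exposure$rsa[i])
  }
  section <- function(which_z, thr, title) {
    sel <- if (which_z == "B") table$z_B > thr else table$z_C > thr
    lines <- c(sprintf("## %s (z > %g)", title, thr), "",
               "| Residue | RSA | z-score | Significant neighbors |",
               "|---|---|---|---|")
    sig <- significant_residues(table, net,
                                z_b_min = if (which_z == "B") thr else Inf,
                                z_c_min = if (which_z == "C") thr else Inf,
                                annotations = annotations)
    if (!nrow(sig)) return(c(lines, "| (none) | | | |"))
    z <- if (which_z == "B") sig$z_B else sig$z_C
    c(lines, sprintf("| %s%s | %s | %.2f | %s |",
                     sig$residue_id,
                     ifelse(sig$label == "", "",
                            paste0(" (", sig$label, ")")),
                     vapply(sig$residue_id, rsa_of, character(1)),
                     z,
                     ifelse(sig$significant_neighbors == "", "-",
                            sig$significant_neighbors)))
  }
  lines <- c(sprintf("# Significant residues (%s network)", net$kind), "",
             section("B", z_b_min, "Betweenness centrality"), "",
             section("C", z_c_min, "Closeness centrality"), "")
  writeLines(lines, path)
  invisible(path)
}
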