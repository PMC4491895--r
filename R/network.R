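#' Convert edge weights to shortest-path edge lengths
#'
#' Shortest-path centralities on a weighted residue network need a
#' weight-to-length mapping: a stronger interaction must mean a shorter
#' path. The default is the reciprocal, `length = 1/weight`, the usual
#' convention of the residue-network literature. The alternative
#' `"neglog"` uses `-log(weight / max(weight))` (lengths >= 0, the
#' strongest edge has length 0). This is the single place the mapping
#' lives, so alternatives apply uniformly.
#'
#' @param weight positive numeric vector of edge weights.
#' @param rule `"reciprocal"` (default) or `"neglog"`.
#' @return numeric vector of edge lengths.
#' @export
path_length_from_weight <- function(weight,
                                    rule = c("reciprocal", "neglog")) {
  rule <- match.arg(rule)
  if (any(weight <= 0)) stop("edge weights must be > 0", call. = FALSE)
  switch(rule,
         reciprocal = 1 / weight,
         neglog = -log(weight / max(weight)))
}

# assemble a residue_network from an edge data frame + coordinates
make_network <- function(edges, coords, kind, length_rule) {
  check_coords(coords)
  ids <- as.character(coords$residue_id)
  g <- igraph::graph_from_data_frame(
    d = edges, directed = FALSE,
    vertices = data.frame(name = ids, x = coords$x, y = coords$y,
                          z = coords$z))
  if (igraph::ecount(g))
    igraph::E(g)$path_length <-
      path_length_from_weight(igraph::E(g)$weight, length_rule)
  structure(list(graph = g, kind = kind, length_rule = length_rule),
            class = "residue_network")
}

#' @export
print.residue_network <- function(x, ...) {
  cat("Residue network (", x$kind, "): ",
      igraph::vcount(x$graph), " nodes, ", igraph::ecount(x$graph),
      " edges\n", sep = "")
  cat("  weight -> path length rule:", x$length_rule, "\n")
  invisible(x)
}

# Euclidean distances between two sets of residue coordinates
pair_distances <- function(coords, a, b) {
  ia <- match(as.character(a), as.character(coords$residue_id))
  ib <- match(as.character(b), as.character(coords$residue_id))
  missing <- unique(c(as.character(a)[is.na(ia)],
                      as.character(b)[is.na(ib)]))
  if (length(missing))
    stop("no coordinates for residue(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  sqrt((coords$x[ia] - coords$x[ib])^2 +
         (coords$y[ia] - coords$y[ib])^2 +
         (coords$z[ia] - coords$z[ib])^2)
}

#' Build the joint-recurrence weighted residue network
#'
#' An edge connects every residue pair with at least one joint recurrence;
#' its weight is the accumulated joint-recurrence count divided by the
#' C-alpha--C-alpha distance of the pair in the reference structure. No
#' cutoff distance is applied, so long-range (including solvent-mediated)
#' interactions are retained; the distance division encodes that equally
#' synchronized pairs interact more strongly when geometrically close.
#'
#' @param counts data frame with `res_a`, `res_b`, `count`, e.g. from
#'   [joint_recurrence_counts()].
#' @param coords reference C-alpha coordinates (`residue_id`, `x`, `y`,
#'   `z`), e.g. from [read_ca_pdb()].
#' @param length_rule weight-to-path-length rule, see
#'   [path_length_from_weight()].
#' @return object of class `residue_network` (kind `"jrp_weighted"`).
#' @export
build_jrp_network <- function(counts, coords,
                              length_rule = c("reciprocal", "neglog")) {
  length_rule <- match.arg(length_rule)
  need <- c("res_a", "res_b", "count")
  if (!is.data.frame(counts) || !all(need %in% names(counts)))
    stop("`counts` must have columns res_a, res_b, count", call. = FALSE)
  keep <- counts$count > 0
  edges <- counts[keep, , drop = FALSE]
  d <- pair_distances(coords, edges$res_a, edges$res_b)
  if (any(d == 0))
    stop("zero C-alpha distance between distinct residues: ",
         paste(sprintf("(%s,%s)", edges$res_a[d == 0],
                       edges$res_b[d == 0]), collapse = ", "),
         call. = FALSE)
  make_network(
    data.frame(from = as.character(edges$res_a),
               to = as.character(edges$res_b),
               weight = edges$count / d),
    coords, "jrp_weighted", length_rule)
}

#' Build the unweighted distance-cutoff residue network
#'
#' Classical static residue network: an edge of weight 1 joins residues
#' whose C-alpha atoms are at most `cutoff` Angstrom apart (boundary
#' included).
#'
#' @inheritParams build_jrp_network
#' @param cutoff distance threshold in Angstrom (default 7).
#' @return object of class `residue_network` (kind `"unweighted_cutoff"`).
#' @export
build_unweighted_network <- function(coords, cutoff = 7) {
  if (!is.numeric(cutoff) || cutoff <= 0)
    stop("`cutoff` must be > 0", call. = FALSE)
  check_coords(coords)
  xyz <- as.matrix(coords[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  idx <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  ids <- as.character(coords$residue_id)
  make_network(
    data.frame(from = ids[idx[, 1L]], to = ids[idx[, 2L]], weight = 1),
    coords, "unweighted_cutoff", "reciprocal")
}

#' Build the atomic-contact weighted residue network
#'
#' Edge weights are per-pair inter-atomic contact counts, either supplied
#' as a table or approximated from a full-atom structure as the number of
#' heavy-atom pairs within `atom_cutoff` Angstrom. The approximation is a
#' generic geometric contact definition; it does not reproduce
#' surface-complementarity contact classifications.
#'
#' @inheritParams build_jrp_network
#' @param contacts data frame with `res_a`, `res_b`, `count`; or `NULL`
#'   to derive counts from `pdb`.
#' @param pdb path to a full-atom PDB file (used when `contacts` is
#'   `NULL`).
#' @param atom_cutoff heavy-atom contact distance in Angstrom
#'   (default 4.5).
#' @return object of class `residue_network` (kind `"contact_weighted"`).
#' @export
build_contact_network <- function(coords, contacts = NULL, pdb = NULL,
                                  atom_cutoff = 4.5,
                                  length_rule = c("reciprocal", "neglog")) {
  length_rule <- match.arg(length_rule)
  if (is.null(contacts)) {
    if (is.null(pdb))
      stop("supply either a contact table or a full-atom PDB",
           call. = FALSE)
    contacts <- contact_counts_from_pdb(pdb, atom_cutoff)
  }
  need <- c("res_a", "res_b", "count")
  if (!is.data.frame(contacts) || !all(need %in% names(contacts)))
    stop("`contacts` must have columns res_a, res_b, count",
         call. = FALSE)
  edges <- contacts[contacts$count > 0, , drop = FALSE]
  make_network(
    data.frame(from = as.character(edges$res_a),
               to = as.character(edges$res_b),
               weight = edges$count),
    coords, "contact_weighted", length_rule)
}

#' Count heavy-atom contacts between residues of a PDB structure
#'
#' Counts, for every residue pair of the first model, the heavy-atom
#' (non-hydrogen) atom pairs within `atom_cutoff` Angstrom.
#'
#' @param pdb path to a PDB file.
#' @param atom_cutoff contact distance in Angstrom (default 4.5).
#' @param chain optional chain restriction.
#' @return data frame with `res_a`, `res_b`, `count` (pairs with at least
#'   one contact).
#' @export
contact_counts_from_pdb <- function(pdb, atom_cutoff = 4.5, chain = NULL) {
  p <- bio3d::read.pdb(pdb, multi = FALSE, verbose = FALSE)
  at <- p$atom
  keep <- at$type == "ATOM" & !(at$elesy %in% c("H", "D"))
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  at <- at[keep, , drop = FALSE]
  xyz <- as.matrix(at[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  idx <- which(upper.tri(d) & d <= atom_cutoff, arr.ind = TRUE)
  ra <- at$resno[idx[, 1L]]
  rb <- at$resno[idx[, 2L]]
  diffres <- ra != rb
  ra <- ra[diffres]; rb <- rb[diffres]
  a <- pmin(ra, rb); b <- pmax(ra, rb)
  if (!length(a))
    return(data.frame(res_a = integer(), res_b = integer(),
                      count = integer()))
  tab <- table(paste(a, b, sep = "_"))
  parts <- do.call(rbind, strsplit(names(tab), "_", fixed = TRUE))
  out <- data.frame(res_a = as.integer(parts[, 1L]),
                    res_b = as.integer(parts[, 2L]),
                    count = as.integer(tab))
  out[order(out$res_a, out$res_b), , drop = FALSE]
}

#' Extract the edge list of a residue network
#'
#' @param net a `residue_network`.
#' @return data frame with `res_a`, `res_b`, `weight`, `path_length`.
#' @export
edge_list <- function(net) {
  stopifnot(inherits(net, "residue_network"))
  g <- net$graph
  if (!igraph::ecount(g))
    return(data.frame(res_a = character(), res_b = character(),
                      weight = numeric(), path_length = numeric()))
  ends <- igraph::ends(g, igraph::E(g))
  data.frame(res_a = ends[, 1L], res_b = ends[, 2L],
             weight = igraph::E(g)$weight,
             path_length = igraph::E(g)$path_length)
}
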