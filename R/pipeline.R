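#' Pipeline configuration
#'
#' Collects the inputs and tunable parameters of the end-to-end residue
#' network pipeline. Defaults follow the method: recurrence rate target
#' 3%, unweighted-network cutoff 7 Angstrom, significance thresholds
#' `z_B > 2` and `z_C > 1.5`.
#'
#' @param series_tsv path to the residue time-series TSV
#'   ([write_series_tsv()] layout).
#' @param pdb path to the reference structure (C-alpha coordinates are
#'   taken from the first model).
#' @param out_dir output directory (created if absent).
#' @param asa_tsv optional ASA table (`residue_id`, `residue_type`,
#'   `asa`).
#' @param contacts_tsv optional atomic contact-count table (`res_a`,
#'   `res_b`, `count`); when absent and `"contact"` is requested, contacts
#'   are approximated from the PDB heavy atoms.
#' @param annotations_tsv optional annotation table (`residue_id`,
#'   `label`).
#' @param networks which networks to build: subset of `"jrp"`,
#'   `"unweighted"`, `"contact"`.
#' @param chain optional PDB chain restriction.
#' @param target_recurrence_rate recurrence-rate target in `(0, 1)`.
#' @param cutoff_distance unweighted-network cutoff (Angstrom).
#' @param z_b_min,z_c_min centrality z-score significance thresholds.
#' @param n_bins,max_lag mutual-information estimator settings
#'   (`NULL` = per-series defaults).
#' @param max_dim,fnn_threshold false-nearest-neighbor settings
#'   (`max_dim = NULL` = per-series default, see [select_dimension()]).
#' @param global_embedding force one `(d, m)` for all residues.
#' @param length_rule weight-to-path-length rule
#'   ([path_length_from_weight()]).
#' @param seed integer seed recorded in the manifest (the pipeline itself
#'   is deterministic given its inputs).
#' @return object of class `jrp_config`.
#' @export
jrp_config <- function(series_tsv, pdb, out_dir,
                       asa_tsv = NULL, contacts_tsv = NULL,
                       annotations_tsv = NULL,
                       networks = c("jrp", "unweighted"),
                       chain = NULL,
                       target_recurrence_rate = 0.03,
                       cutoff_distance = 7,
                       z_b_min = 2, z_c_min = 1.5,
                       n_bins = NULL, max_lag = NULL,
                       max_dim = NULL, fnn_threshold = 0.01,
                       global_embedding = FALSE,
                       length_rule = "reciprocal",
                       seed = 1L) {
  networks <- match.arg(networks, c("jrp", "unweighted", "contact"),
                        several.ok = TRUE)
  if (target_recurrence_rate <= 0 || target_recurrence_rate >= 1)
    stop("`target_recurrence_rate` must lie in (0, 1)", call. = FALSE)
  if (cutoff_distance <= 0)
    stop("`cutoff_distance` must be > 0", call. = FALSE)
  if (!is.finite(z_b_min) || !is.finite(z_c_min))
    stop("z-score thresholds must be finite", call. = FALSE)
  structure(list(
    series_tsv = series_tsv, pdb = pdb, out_dir = out_dir,
    asa_tsv = asa_tsv, contacts_tsv = contacts_tsv,
    annotations_tsv = annotations_tsv, networks = networks,
    chain = chain,
    target_recurrence_rate = target_recurrence_rate,
    cutoff_distance = cutoff_distance,
    z_b_min = z_b_min, z_c_min = z_c_min,
    n_bins = n_bins, max_lag = max_lag,
    max_dim = if (!is.null(max_dim)) as.integer(max_dim),
    fnn_threshold = fnn_threshold,
    global_embedding = isTRUE(global_embedding),
    length_rule = length_rule, seed = as.integer(seed)),
    class = "jrp_config")
}

# flat key=value serialization; NULL fields are omitted
config_to_lines <- function(config) {
  flat <- config[!vapply(config, is.null, logical(1))]
  vapply(names(flat), function(k)
    paste0(k, "=", paste(flat[[k]], collapse = ",")), character(1))
}

#' Write / read a pipeline configuration as a flat key=value file
#'
#' @param config a [jrp_config()].
#' @param path file path.
#' @return `write_config` returns the path; `read_config` the
#'   reconstructed `jrp_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "jrp_config"))
  writeLines(config_to_lines(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, `[`, character(1), 2L)
  args <- stats::setNames(as.list(vals), keys)
  # only constructor arguments survive (manifests carry extra keys)
  args <- args[names(args) %in% names(formals(jrp_config))]
  num <- c("target_recurrence_rate", "cutoff_distance", "z_b_min",
           "z_c_min", "fnn_threshold")
  int <- c("max_dim", "seed", "n_bins", "max_lag")
  for (k in intersect(num, names(args))) args[[k]] <- as.numeric(args[[k]])
  for (k in intersect(int, names(args))) args[[k]] <- as.integer(args[[k]])
  if ("global_embedding" %in% names(args))
    args$global_embedding <- as.logical(args$global_embedding)
  if ("networks" %in% names(args))
    args$networks <- strsplit(args$networks, ",", fixed = TRUE)[[1L]]
  do.call(jrp_config, args)
}

#' Run the joint-recurrence network pipeline end to end
#'
#' Reads the per-residue time series and reference structure, reconciles
#' residue identities (PDB numbering is authoritative; series rows map by
#' id), selects per-residue embedding parameters, calibrates and builds
#' recurrence matrices, accumulates joint recurrences over the common
#' state window, builds the requested networks, and writes centrality
#' tables, edge lists, a significant-residue report, and a manifest from
#' which the run can be re-executed.
#'
#' @param config a [jrp_config()].
#' @return invisibly, a list with the in-memory results: `params`
#'   (embedding table), `rates` (achieved recurrence rates), `jr_counts`,
#'   `networks`, `centrality` (one table per network), `exposure`
#'   (or `NULL`), and `files` (paths of all written artifacts).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "jrp_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  files <- character(0)

  series <- read_series_tsv(config$series_tsv)
  coords <- read_ca_pdb(config$pdb, chain = config$chain)

  sids <- rownames(series)
  cids <- as.character(coords$residue_id)
  missing_coord <- setdiff(sids, cids)
  if (length(missing_coord))
    stop("residue(s) in the time series but not in the structure: ",
         paste(missing_coord, collapse = ", "), call. = FALSE)
  extra_coord <- setdiff(cids, sids)
  if (length(extra_coord))
    stop("residue(s) in the structure but not in the time series: ",
         paste(extra_coord, collapse = ", "), call. = FALSE)
  coords <- coords[match(sids, cids), , drop = FALSE]

  params <- select_embedding(
    series, max_lag = config$max_lag, n_bins = config$n_bins,
    max_dim = config$max_dim, threshold = config$fnn_threshold,
    global = config$global_embedding)
  files["params"] <- out("embedding_params.tsv")
  utils::write.table(params, files["params"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  rps <- lapply(seq_len(nrow(series)), function(r)
    residue_recurrence(series[r, ], params$delay[r], params$dimension[r],
                       target_rate = config$target_recurrence_rate,
                       residue_id = params$residue_id[r]))
  rates <- data.frame(
    residue_id = params$residue_id,
    n_states = vapply(rps, `[[`, numeric(1), "n_states"),
    epsilon = vapply(rps, `[[`, numeric(1), "epsilon"),
    achieved_rate = vapply(rps, `[[`, numeric(1), "recurrence_rate"))
  files["rates"] <- out("recurrence_rates.tsv")
  utils::write.table(rates, files["rates"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  jr <- joint_recurrence_counts(rps)
  files["jr_counts"] <- out("jr_counts.tsv")
  write_jr_counts_tsv(jr, files["jr_counts"])

  exposure <- NULL
  if (!is.null(config$asa_tsv)) {
    exposure <- exposure_table(read_asa_tsv(config$asa_tsv))
    files["exposure"] <- out("exposure.csv")
    utils::write.csv(exposure, files["exposure"], row.names = FALSE)
  }
  annotations <- if (!is.null(config$annotations_tsv))
    utils::read.delim(config$annotations_tsv) else NULL

  nets <- list()
  for (kind in config$networks) {
    nets[[kind]] <- switch(kind,
      jrp = build_jrp_network(jr, coords,
                              length_rule = config$length_rule),
      unweighted = build_unweighted_network(
        coords, cutoff = config$cutoff_distance),
      contact = {
        contacts <- if (!is.null(config$contacts_tsv))
          read_contacts_tsv(config$contacts_tsv) else NULL
        build_contact_network(coords, contacts = contacts,
                              pdb = if (is.null(contacts)) config$pdb,
                              length_rule = config$length_rule)
      })
  }

  cents <- list()
  for (kind in names(nets)) {
    net <- nets[[kind]]
    el_path <- out(paste0("edges_", kind, ".tsv"))
    utils::write.table(edge_list(net), el_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files[paste0("edges_", kind)] <- el_path
    ct <- centrality_table(net, z_b_min = config$z_b_min,
                           z_c_min = config$z_c_min)
    ct_path <- out(paste0("centrality_", kind, ".csv"))
    utils::write.csv(ct, ct_path, row.names = FALSE)
    files[paste0("centrality_", kind)] <- ct_path
    cents[[kind]] <- ct
    rep_path <- out(paste0("report_", kind, ".md"))
    write_significant_report(ct, net, rep_path,
                             z_b_min = config$z_b_min,
                             z_c_min = config$z_c_min,
                             annotations = annotations,
                             exposure = exposure)
    files[paste0("report_", kind)] <- rep_path
  }

  files["manifest"] <- out("manifest.txt")
  writeLines(c(
    "# jrpnet run manifest (key=value; re-runnable via read_config)",
    config_to_lines(config),
    paste0("n_states_common=", attr(jr, "n_states")),
    paste0("achieved_rates=",
           paste(sprintf("%s:%.6f", rates$residue_id,
                         rates$achieved_rate), collapse = ",")),
    paste0("flagged_delay=",
           paste(params$residue_id[params$delay_flagged],
                 collapse = ",")),
    paste0("flagged_dimension=",
           paste(params$residue_id[params$dimension_flagged],
                 collapse = ","))),
    files["manifest"])

  invisible(list(params = params, rates = rates, jr_counts = jr,
                 networks = nets, centrality = cents,
                 exposure = exposure, files = files))
}
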