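#' Write a residue time-series matrix as TSV
#'
#' Rows are residues, columns frames; the first column holds the residue id
#' and the header row the frame indices.
#'
#' @param series numeric matrix (residues x frames) with rownames = ids.
#' @param path output file.
#' @export
write_series_tsv <- function(series, path) {
  if (!is.matrix(series) || !is.numeric(series))
    stop("`series` must be a numeric matrix", call. = FALSE)
  ids <- rownames(series)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(series)))
  df <- data.frame(residue_id = ids, series, check.names = FALSE)
  colnames(df) <- c("residue_id", seq_len(ncol(series)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a residue time-series matrix from TSV
#'
#' @param path TSV written by [write_series_tsv()] (first column residue id,
#'   remaining columns one frame each).
#' @return numeric matrix with rownames = residue ids.
#' @export
read_series_tsv <- function(path) {
  df <- tryCatch(
    utils::read.delim(path, check.names = FALSE, colClasses = NA),
    error = function(e) stop("failed to parse time-series TSV '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  if (ncol(df) < 2L)
    stop("time-series TSV '", path,
         "' needs a residue_id column plus frame columns", call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!apply(df[, -1L, drop = FALSE], 2L,
                        function(col) all(!is.na(suppressWarnings(
                          as.numeric(col))))))[1L]
    stop("non-numeric values in time-series TSV '", path, "' column ",
         bad + 1L, call. = FALSE)
  }
  rownames(m) <- as.character(df[[1L]])
  colnames(m) <- NULL
  m
}

#' Write C-alpha coordinates as a minimal PDB file
#'
#' Emits one `ATOM` record per residue (atom name `CA`, residue `ALA`,
#' chain `A`) in fixed-width PDB format.
#'
#' @param coords data frame with `residue_id`, `x`, `y`, `z` (Angstrom).
#' @param path output file.
#' @export
write_ca_pdb <- function(coords, path) {
  check_coords(coords)
  lines <- sprintf(
    "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(coords)), as.integer(coords$residue_id),
    coords$x, coords$y, coords$z)
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

#' Read C-alpha coordinates from a PDB file
#'
#' Parses the first model's `ATOM` records and keeps the C-alpha atoms,
#' optionally restricted to one chain.
#'
#' @param path PDB file.
#' @param chain optional chain identifier; default keeps all chains.
#' @return data frame with `residue_id`, `x`, `y`, `z`.
#' @export
read_ca_pdb <- function(path, chain = NULL) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) stop("failed to parse PDB '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  at <- pdb$atom
  keep <- at$elety == "CA" & at$type == "ATOM"
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  at <- at[keep, , drop = FALSE]
  if (!nrow(at))
    stop("no C-alpha ATOM records found in '", path, "'", call. = FALSE)
  # one CA per residue: keep the first occurrence (altloc duplicates)
  at <- at[!duplicated(at$resno), , drop = FALSE]
  data.frame(residue_id = at$resno, x = at$x, y = at$y, z = at$z)
}

check_coords <- function(coords) {
  if (!is.data.frame(coords) ||
      !all(c("residue_id", "x", "y", "z") %in% names(coords)))
    stop("coordinates must be a data frame with columns ",
         "residue_id, x, y, z", call. = FALSE)
  if (anyDuplicated(coords$residue_id))
    stop("duplicate residue ids in coordinates", call. = FALSE)
  invisible(coords)
}

#' Read a per-residue accessible-surface-area table
#'
#' @param path TSV with columns `residue_id`, `residue_type`, `asa` (A^2).
#' @return data frame with those three columns.
#' @export
read_asa_tsv <- function(path) {
  df <- utils::read.delim(path)
  need <- c("residue_id", "residue_type", "asa")
  if (!all(need %in% names(df)))
    stop("ASA table '", path, "' must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  df[need]
}

#' Read a per-pair atomic contact-count table
#'
#' @param path TSV with columns `res_a`, `res_b`, `count`.
#' @return data frame with those three columns.
#' @export
read_contacts_tsv <- function(path) {
  df <- utils::read.delim(path)
  need <- c("res_a", "res_b", "count")
  if (!all(need %in% names(df)))
    stop("contact table '", path, "' must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  df[need]
}
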