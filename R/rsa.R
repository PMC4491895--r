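# Theoretical maximum accessible surface areas (A^2) per standard amino
# acid, from the Gly-X-Gly theoretical maxima of Tien et al. (2013),
# PLoS ONE 8:e80635. Used to normalize ASA to relative solvent
# accessibility.
max_asa_theoretical <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
  GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
  LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
  SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

one_to_three <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

#' Maximum accessible surface area of an amino acid
#'
#' Theoretical maximum solvent-accessible surface area (Angstrom^2) used
#' as the RSA denominator. Accepts one- or three-letter codes.
#'
#' @param residue_type character vector of amino-acid codes.
#' @return numeric vector of maxima in Angstrom^2.
#' @export
#' @examples
#' max_asa(c("ALA", "W"))
max_asa <- function(residue_type) {
  code <- toupper(as.character(residue_type))
  code <- ifelse(nchar(code) == 1L, one_to_three[code], code)
  out <- max_asa_theoretical[code]
  if (anyNA(out))
    stop("unknown residue type(s): ",
         paste(unique(residue_type[is.na(out)]), collapse = ", "),
         call. = FALSE)
  unname(out)
}

#' Relative solvent accessibility of a residue
#'
#' RSA = ASA / max-ASA for the residue's amino-acid type. Values above 1
#' are allowed (observed ASA can exceed the theoretical maximum in
#' distorted conformations) but flagged with a warning.
#'
#' @param asa accessible surface area in Angstrom^2 (>= 0).
#' @param residue_type amino-acid code (one- or three-letter).
#' @return dimensionless RSA values.
#' @export
#' @examples
#' compute_rsa(64.5, "ALA")  # 0.5
compute_rsa <- function(asa, residue_type) {
  if (any(asa < 0)) stop("`asa` must be >= 0", call. = FALSE)
  rsa <- asa / max_asa(residue_type)
  if (any(rsa > 1))
    warning(sum(rsa > 1), " RSA value(s) exceed 1")
  rsa
}

#' Classify residue solvent exposure from RSA
#'
#' Buried: RSA < 5%; partially buried: 5% <= RSA < 20%; exposed:
#' RSA >= 20%.
#'
#' @param rsa non-negative relative solvent accessibility.
#' @return factor with levels `buried`, `partially_buried`, `exposed`.
#' @export
#' @examples
#' classify_exposure(c(0.03, 0.10, 0.25))
classify_exposure <- function(rsa) {
  if (any(rsa < 0)) stop("`rsa` must be >= 0", call. = FALSE)
  cut(rsa, breaks = c(-Inf, 0.05, 0.20, Inf), right = FALSE,
      labels = c("buried", "partially_buried", "exposed"))
}

#' Per-residue exposure table from an ASA table
#'
#' @param asa_table data frame with `residue_id`, `residue_type`, `asa`
#'   (Angstrom^2), e.g. from [read_asa_tsv()].
#' @return data frame with added `rsa` and `category` columns.
#' @export
exposure_table <- function(asa_table) {
  need <- c("residue_id", "residue_type", "asa")
  if (!is.data.frame(asa_table) || !all(need %in% names(asa_table)))
    stop("`asa_table` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  asa_table$rsa <- compute_rsa(asa_table$asa, asa_table$residue_type)
  asa_table$category <- classify_exposure(asa_table$rsa)
  asa_table
}
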