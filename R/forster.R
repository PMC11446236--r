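#' Convert a donor-acceptor distance to FRET efficiency
#'
#' Evaluates the Forster relation \eqn{E = 1 / (1 + (r/R_0)^6)}. At
#' \eqn{r = R_0} the transfer efficiency is exactly 0.5; efficiency decreases
#' strictly with distance and equals 1 at contact.
#'
#' @param r Donor-acceptor separation in Angstrom (vectorized, each >= 0).
#' @param r0 Forster radius in Angstrom. The default, 51, is the standard
#'   value for the AF555/AF647 dye pair.
#' @return FRET efficiency in (0, 1], same length as `r`.
#' @examples
#' fret_from_distance(51)          # 0.5 by definition of the Forster radius
#' fret_from_distance(102)         # 1/65
#' @seealso [distance_from_fret()] for the exact inverse.
#' @export
fret_from_distance <- function(r, r0 = 51) {
  check_number(r0, "r0", lower = 0, strict_lower = TRUE)
  if (!is.numeric(r) || any(!is.finite(r)))
    abort_smfret("`r` must be finite numeric")
  if (any(r < 0))
    abort_smfret("`r` must be non-negative (distance in Angstrom)")
  1 / (1 + (r / r0)^6)
}

#' Convert a FRET efficiency to donor-acceptor distance
#'
#' Inverts the Forster relation: \eqn{r = R_0 (1/E - 1)^{1/6}}. Only
#' efficiencies strictly inside (0, 1) map to a finite positive distance.
#'
#' @param e FRET efficiency, each value in (0, 1) (vectorized).
#' @inheritParams fret_from_distance
#' @return Distance in Angstrom, same length as `e`.
#' @examples
#' distance_from_fret(0.5)         # 51 A, the AF555/AF647 Forster radius
#' @export
distance_from_fret <- function(e, r0 = 51) {
  check_number(r0, "r0", lower = 0, strict_lower = TRUE)
  if (!is.numeric(e) || any(!is.finite(e)))
    abort_smfret("`e` must be finite numeric")
  if (any(e <= 0 | e >= 1))
    abort_smfret("`e` must lie strictly inside (0, 1) to invert the Forster relation")
  r0 * (1 / e - 1)^(1 / 6)
}

#' Describe one atom in a coordinate file
#'
#' A selector naming a single atom by chain, residue number, and atom name.
#' The default atom is the beta-carbon (`"CB"`), the conventional reference
#' point when dye-linker geometry is not modeled.
#'
#' @param chain_id Chain identifier as it appears in the file.
#' @param residue_number Residue number (file numbering, >= 1).
#' @param atom_name PDB atom name; default `"CB"`.
#' @return An object of class `residue_selector`.
#' @export
residue_selector <- function(chain_id, residue_number, atom_name = "CB") {
  if (!is.character(chain_id) || length(chain_id) != 1L)
    abort_smfret("`chain_id` must be a single string")
  check_number(residue_number, "residue_number", lower = 1)
  if (!is.character(atom_name) || length(atom_name) != 1L)
    abort_smfret("`atom_name` must be a single string")
  structure(
    list(chain_id = chain_id, residue_number = as.integer(residue_number),
         atom_name = atom_name),
    class = "residue_selector")
}

#' @export
format.residue_selector <- function(x, ...) {
  sprintf("chain %s, residue %d, atom %s", x$chain_id, x$residue_number, x$atom_name)
}

#' @export
print.residue_selector <- function(x, ...) {
  cat("<residue_selector>", format(x), "\n")
  invisible(x)
}

#' Distance between two selected atoms in a PDB file
#'
#' Reads a PDB-format coordinate file and returns the Euclidean distance in
#' Angstrom between the two atoms named by the selectors. When a selection
#' matches several alternate locations, the highest-occupancy record is used
#' (policy `"occupancy"`); with policy `"error"` any ambiguity is an error.
#'
#' @param structure_file Path to a PDB-format file.
#' @param sel_a,sel_b [residue_selector()] objects.
#' @param altloc_policy `"occupancy"` (default) or `"error"`.
#' @return Distance in Angstrom (single number).
#' @export
residue_pair_distance <- function(structure_file, sel_a, sel_b,
                                  altloc_policy = c("occupancy", "error")) {
  altloc_policy <- match.arg(altloc_policy)
  if (!file.exists(structure_file))
    abort_smfret("structure file not found: ", structure_file)
  pdb <- bio3d::read.pdb(structure_file, rm.alt = FALSE, verbose = FALSE)
  xa <- resolve_selector(pdb, sel_a, altloc_policy)
  xb <- resolve_selector(pdb, sel_b, altloc_policy)
  sqrt(sum((xa - xb)^2))
}

resolve_selector <- function(pdb, sel, altloc_policy) {
  if (!inherits(sel, "residue_selector"))
    abort_smfret("selectors must be created with residue_selector()")
  atoms <- pdb$atom
  hit <- which(trimws(atoms$chain) == sel$chain_id &
                 atoms$resno == sel$residue_number &
                 trimws(atoms$elety) == sel$atom_name)
  if (length(hit) == 0L)
    abort_smfret("no atom matches selector (", format(sel), ")")
  if (length(hit) > 1L) {
    if (altloc_policy == "error")
      abort_smfret("ambiguous selection (", format(sel), "): ",
                   length(hit), " matching atoms")
    occ <- atoms$o[hit]
    occ[is.na(occ)] <- 0
    hit <- hit[which.max(occ)]
  }
  c(atoms$x[hit], atoms$y[hit], atoms$z[hit])
}
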