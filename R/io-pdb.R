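#' Read atom records for one chain of a PDB file
#'
#' Parses fixed-column `ATOM`/`HETATM` records via \pkg{bio3d} and returns
#' the heavy atoms of the requested chain as a tibble. Hydrogens and
#' alternate locations other than `' '`/`'A'` are excluded. Residues
#' missing from the coordinate model are simply absent from the result;
#' downstream accessibility calculations exclude them.
#'
#' @param path Path to a PDB-format file.
#' @param chain Chain identifier to extract.
#' @return A tibble with columns `chain`, `residue_index`, `residue_name`,
#'   `atom_name`, `element` (one of `C`,`N`,`O`,`P`,`other`) and
#'   coordinates `x`, `y`, `z` in Angstrom.
#' @export
read_pdb_atoms <- function(path, chain) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "probeval_io_error")
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  at <- pdb$atom
  at <- at[at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  at <- at[is.na(at$alt) | at$alt %in% c("", " ", "A"), , drop = FALSE]
  elem <- toupper(trimws(at$elesy))
  blank <- is.na(elem) | elem == ""
  # fall back to the first letter of the atom name when the element
  # column is absent (common in minimal/toy PDB files)
  elem[blank] <- substr(gsub("[^A-Za-z].*$", "",
                             gsub("^[0-9]+", "", trimws(at$elety[blank]))), 1, 1)
  keep <- elem != "H" & elem != "D"
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]
  sel <- trimws(at$chain) == chain
  if (!any(sel)) {
    abort(sprintf("%s: no atoms found for chain '%s'.", path, chain),
          class = "probeval_empty_selection_error")
  }
  at <- at[sel, , drop = FALSE]
  elem <- elem[sel]
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))) {
    abort(sprintf("%s: non-finite coordinates in chain '%s'.", path, chain),
          class = "probeval_validation_error")
  }
  tibble(
    chain = trimws(at$chain),
    residue_index = as.integer(at$resno),
    residue_name = trimws(at$resid),
    atom_name = trimws(at$elety),
    element = ifelse(elem %in% c("C", "N", "O", "P"), elem, "other"),
    x = at$x, y = at$y, z = at$z
  )
}
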