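# Construction of nitrenium cation start geometries from an optimized
# neutral conformer: delete one amine hydrogen (the portable equivalent of
# replacing it with a dummy atom) and set the total charge to +1. Both amine
# hydrogens are tried and the lower-energy optimized cation is kept.

#' Build nitrenium cation start geometries
#'
#' For a primary aromatic amine site (a nitrogen carrying exactly two
#' hydrogens), returns one start geometry per amine hydrogen with that
#' hydrogen deleted and all other atoms unchanged. The cation keeps the
#' heavy-atom topology of the neutral; its net charge is +1.
#'
#' @param mol3d Molecule record defining the topology (atom order must match
#'   `xyz`).
#' @param xyz Optimized neutral geometry (n x 3 matrix, angstrom).
#' @param site One row of [find_primary_aromatic_amines()] output (or any
#'   list with `n_idx`).
#' @return A list of candidates: `list(z, xyz, removed_h, atom_map)` where
#'   `atom_map[k]` gives the original atom index of cation row k.
#' @export
build_nitrenium_candidates <- function(mol3d, xyz, site) {
  stopifnot(inherits(mol3d, "amine_mol"))
  n_idx <- site$n_idx[[1]]
  at <- mol3d$atoms
  nb <- .neighbors(mol3d, n_idx)
  hs <- nb[at$element[nb] == "H"]
  if (length(hs) != 2)
    stop("site nitrogen must carry exactly two hydrogens (found ",
         length(hs), ")", call. = FALSE)
  lapply(hs, function(h) {
    keep <- setdiff(seq_len(nrow(at)), h)
    list(z = at$z[keep], xyz = xyz[keep, , drop = FALSE],
         removed_h = h, atom_map = keep)
  })
}
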