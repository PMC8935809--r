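# Dataset-eligibility criteria for the local QSAR applicability domain and
# location of the primary aromatic amine site.

.neighbors <- function(mol, i) {
  b <- mol$bonds
  c(b$j[b$i == i], b$i[b$j == i])
}

#' Locate primary aromatic amine sites
#'
#' A site is a trivalent nitrogen bearing exactly two hydrogens, no formal
#' charge, and bonded to exactly one aromatic carbon (the SMARTS pattern
#' `[NX3;H2;+0][c]`). Sulfonamide, aliphatic and substituted amine nitrogens
#' do not match.
#'
#' @param mol An `amine_mol` record.
#' @return A tibble with one row per site: `n_idx` (nitrogen atom index) and
#'   `c_idx` (attached aromatic carbon index); zero rows when there is none.
#' @export
find_primary_aromatic_amines <- function(mol) {
  stopifnot(inherits(mol, "amine_mol"))
  out <- tibble::tibble(n_idx = integer(), c_idx = integer())
  if (!is.na(mol$error)) return(out)
  at <- mol$atoms
  for (i in at$idx[at$element == "N" & at$charge == 0L]) {
    nb <- .neighbors(mol, i)
    hs <- nb[at$element[nb] == "H"]
    heavy <- nb[at$element[nb] != "H"]
    if (length(hs) == 2 && length(heavy) == 1 &&
        at$element[heavy] == "C" && at$aromatic[heavy]) {
      out <- tibble::add_row(out, n_idx = i, c_idx = heavy)
    }
  }
  out
}

# rotatable bond: single, acyclic, both atoms non-terminal heavy atoms,
# excluding amide C-N
.count_rotatable <- function(mol) {
  at <- mol$atoms; b <- mol$bonds
  heavy_deg <- function(i) sum(at$element[.neighbors(mol, i)] != "H")
  is_amide_cn <- function(i, j) {
    # C(=O)-N in either orientation
    for (ord in list(c(i, j), c(j, i))) {
      ci <- ord[1]; ni <- ord[2]
      if (at$element[ci] == "C" && at$element[ni] == "N") {
        nb <- .neighbors(mol, ci)
        dbl_o <- any(at$element[nb] == "O" &
                       vapply(nb, function(k) {
                         any((b$i == ci & b$j == k | b$j == ci & b$i == k) &
                               b$order == 2)
                       }, logical(1)))
        if (dbl_o) return(TRUE)
      }
    }
    FALSE
  }
  n <- 0L
  for (k in seq_len(nrow(b))) {
    if (b$order[k] != 1 || b$in_ring[k]) next
    i <- b$i[k]; j <- b$j[k]
    if (at$element[i] == "H" || at$element[j] == "H") next
    if (heavy_deg(i) < 2 || heavy_deg(j) < 2) next
    if (is_amide_cn(i, j)) next
    n <- n + 1L
  }
  n
}

# potential tetrahedral stereocenters: sp3 carbon with four topologically
# distinct substituent branches (unassigned centers count too)
.count_stereocenters <- function(mol, depth = 8) {
  at <- mol$atoms; b <- mol$bonds
  nbl <- lapply(at$idx, function(i) .neighbors(mol, i))
  branch_sig <- function(start, banned) {
    # breadth-first signature of the branch rooted at `start`, not passing
    # through `banned`
    level <- start
    seen <- c(banned, start)
    sig <- at$element[start]
    for (d in seq_len(depth)) {
      nxt <- sort(unlist(lapply(level, function(i) setdiff(nbl[[i]], seen))))
      if (length(nxt) == 0) break
      sig <- paste0(sig, "|", paste(sort(at$element[nxt]), collapse = ""))
      seen <- c(seen, nxt)
      level <- nxt
    }
    sig
  }
  n <- 0L
  for (i in at$idx[at$element == "C" & !at$aromatic]) {
    nb <- nbl[[i]]
    if (length(nb) != 4) next
    all_single <- all(vapply(nb, function(k)
      any((b$i == i & b$j == k | b$j == i & b$i == k) & b$order == 1),
      logical(1)))
    if (!all_single) next
    sigs <- vapply(nb, function(k) branch_sig(k, i), character(1))
    if (length(unique(sigs)) == 4) n <- n + 1L
  }
  n
}

.has_aromatic_nitro <- function(mol) {
  at <- mol$atoms
  for (i in at$idx[at$element == "N"]) {
    nb <- .neighbors(mol, i)
    term_o <- nb[vapply(nb, function(k) {
      at$element[k] == "O" &&
        sum(at$element[.neighbors(mol, k)] != "H") == 1 &&
        !any(at$element[.neighbors(mol, k)] == "H")
    }, logical(1))]
    if (length(term_o) >= 2 && any(at$aromatic[setdiff(nb, term_o)]))
      return(TRUE)
  }
  FALSE
}

.mol_mw <- function(mol) sum(.MASS[mol$atoms$element])

#' Check the six dataset-eligibility criteria
#'
#' Applies the curation filters used to assemble the local QSAR domain:
#' (i) no formal charge, (ii) molecular weight below 500 Da (strict),
#' (iii) at most one (potential) stereocenter, (iv) fewer than 10 rotatable
#' bonds, (v) exactly one primary aromatic amine functionality, and (vi) no
#' aromatic nitro group. All criteria are evaluated independently and every
#' failure is reported.
#'
#' @param mol An `amine_mol` record.
#' @return A one-row tibble with `eligible`, `failed_criteria` (list column
#'   of roman-numeral codes), the amine site count, and the measured
#'   quantities (`mw`, `n_rotatable`, `n_stereocenters`, `net_formal_charge`).
#' @examples
#' \donttest{
#' check_eligibility(parse_smiles("Nc1ccccc1")[[1]])        # eligible
#' check_eligibility(parse_smiles("Nc1ccc(cc1)[N+](=O)[O-]")[[1]])  # fails vi
#' }
#' @export
check_eligibility <- function(mol) {
  stopifnot(inherits(mol, "amine_mol"))
  if (!is.na(mol$error))
    return(tibble::tibble(id = mol$id, eligible = FALSE,
                          failed_criteria = list("parse"),
                          n_amine_sites = NA_integer_, mw = NA_real_,
                          n_rotatable = NA_integer_,
                          n_stereocenters = NA_integer_,
                          net_formal_charge = NA_integer_))
  sites <- find_primary_aromatic_amines(mol)
  mw <- .mol_mw(mol)
  nrot <- .count_rotatable(mol)
  nst <- .count_stereocenters(mol)
  net <- sum(mol$atoms$charge)
  failed <- character(0)
  if (net != 0L) failed <- c(failed, "i")
  if (!(mw < 500)) failed <- c(failed, "ii")
  if (nst > 1) failed <- c(failed, "iii")
  if (!(nrot < 10)) failed <- c(failed, "iv")
  if (nrow(sites) != 1) failed <- c(failed, "v")
  if (.has_aromatic_nitro(mol)) failed <- c(failed, "vi")
  tibble::tibble(id = mol$id, eligible = length(failed) == 0,
                 failed_criteria = list(failed),
                 n_amine_sites = nrow(sites), mw = mw, n_rotatable = nrot,
                 n_stereocenters = nst, net_formal_charge = as.integer(net))
}
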