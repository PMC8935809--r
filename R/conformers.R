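# Conformer enumeration of the neutral amine: seeded stochastic
# distance-geometry embedding (ETKDG, via a bundled RDKit helper script),
# MMFF94 minimization of every trial, an energy window above the minimum,
# and heavy-atom RMSD deduplication. The retained members seed the AM1
# refinement; the protocol's only job is to find the global minimum.

.python_bin <- function() {
  p <- Sys.which("python")
  if (p == "") p <- Sys.which("python3")
  if (p == "")
    stop("python (with RDKit) was not found on the PATH; it is required ",
         "for conformer embedding", call. = FALSE)
  p
}

.embed_error <- function(id) {
  stop(structure(class = c("nitrenium_embed_error", "error", "condition"),
                 list(message = paste0("3D construction failed for ", id),
                      call = NULL)))
}

# run the embedding helper; returns the raw multi-record SDF lines
.run_embedder <- function(smiles, window, rmsd_threshold, max_conformers,
                          seed, id) {
  script <- system.file("python", "embed_conformers.py",
                        package = "nitrenium", mustWork = TRUE)
  out <- suppressWarnings(
    tryCatch(system2(.python_bin(),
                     c(shQuote(script), shQuote(smiles), format(window),
                       format(rmsd_threshold), format(max_conformers),
                       format(seed)),
                     stdout = TRUE, stderr = FALSE),
             error = function(e) character(0)))
  status <- attr(out, "status") %||% 0L
  if (status != 0L || length(out) < 4) .embed_error(id)
  out
}

#' Enumerate low-energy conformers of a neutral molecule
#'
#' Embeds `N` trial geometries by seeded stochastic distance geometry
#' (N grows with the rotatable-bond count, between 20 and 300), minimizes
#' each with MMFF94, discards members above `window` kcal/mol of the
#' ensemble minimum, removes duplicates below the heavy-atom RMSD threshold,
#' and returns the ensemble sorted by energy. The same seed gives a
#' bit-identical ensemble on every run.
#'
#' @param mol An `amine_mol` record (no parse error).
#' @param window Energy cutoff in kcal/mol above the minimum (default 7).
#' @param rmsd_threshold Heavy-atom RMSD (angstrom) below which two
#'   conformers are duplicates (default 0.5).
#' @param max_conformers Keep at most this many lowest members (default 30).
#' @param seed Embedding seed (default 20220321).
#' @return A `conf_ensemble`: list with `mol3d` (record with coordinates of
#'   the most stable member), `xyz` (list of coordinate matrices),
#'   `energies` (MMFF94 kcal/mol, ascending), `window`, `seed`.
#' @export
enumerate_conformers <- function(mol, window = 7, rmsd_threshold = 0.5,
                                 max_conformers = 30, seed = 20220321) {
  stopifnot(inherits(mol, "amine_mol"), is.na(mol$error))
  sdf <- .run_embedder(mol$smiles, window, rmsd_threshold, max_conformers,
                       seed, mol$id)
  ends <- grep("^\\$\\$\\$\\$", sdf)
  if (length(ends) == 0) .embed_error(mol$id)
  starts <- c(1, head(ends, -1) + 1)
  xyzs <- vector("list", length(starts))
  energies <- rep(NA_real_, length(starts))
  for (k in seq_along(starts)) {
    block <- sdf[starts[k]:ends[k]]
    p <- .parse_sdf(block)
    if (is.null(p)) .embed_error(mol$id)
    xyzs[[k]] <- p$xyz
    ei <- grep("^>\\s+<energy_kcal>", block)
    if (length(ei) == 1) energies[k] <- as.numeric(block[ei + 1])
  }
  if (anyNA(energies)) energies <- seq_along(xyzs) * 0

  # topology + aromaticity from the first (most stable) record
  mol3d <- .record_from_sdf(sdf[starts[1]:ends[1]], id = mol$id,
                            source = mol$source, name = mol$name,
                            keep_coords = TRUE)
  if (!is.na(mol3d$error)) .embed_error(mol$id)

  structure(list(mol3d = mol3d, xyz = xyzs, energies = energies,
                 window = window, seed = seed),
            class = "conf_ensemble")
}

#' Select the most stable conformer of an ensemble
#'
#' Ties (within numerical precision) are broken by generation order, which is
#' stable across reruns under a fixed seed.
#'
#' @param ensemble A `conf_ensemble`.
#' @return A list with `xyz`, `energy`, and `index`.
#' @export
select_lowest <- function(ensemble) {
  stopifnot(inherits(ensemble, "conf_ensemble"), length(ensemble$xyz) > 0)
  i <- which.min(ensemble$energies)  # first minimum on ties
  list(xyz = ensemble$xyz[[i]], energy = ensemble$energies[i], index = i)
}

#' @export
print.conf_ensemble <- function(x, ...) {
  cat(sprintf("<conf_ensemble %s: %d conformer(s), window %.1f kcal/mol>\n",
              x$mol3d$id, length(x$xyz), x$window))
  invisible(x)
}
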