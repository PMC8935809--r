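# Quantum-engine abstraction. Three adapters share one interface:
#  * engine_am1()   - the bundled AM1 implementation (compiled code)
#  * engine_mopac() - an external MOPAC-dialect program run as a subprocess
#  * engine_mock()  - scripted energies, for tests without any QM at all
# optimize_species(engine, z, xyz, charge) returns
# list(hf, xyz, converged, detail).

#' Bundled AM1 engine
#'
#' Geometry optimization with the bundled semi-empirical AM1 implementation
#' (restricted closed-shell SCF over the NDDO integral approximation with the
#' published AM1 parameter set; elements H, C, N, O, F, S, Cl, Br). Heats of
#' formation are in kcal/mol. AM1 is the reference Hamiltonian of the method;
#' results from other engines/Hamiltonians are off-reference.
#'
#' @param gnorm Gradient-norm convergence threshold, kcal/mol/angstrom.
#' @param max_geom_iter Maximum geometry-optimization steps.
#' @return A `qm_engine` object.
#' @export
engine_am1 <- function(gnorm = 0.5, max_geom_iter = 600) {
  structure(list(name = "am1",
                 fingerprint = sprintf("am1-bundled-%.6f", .am1_param_checksum()),
                 gnorm = gnorm, max_geom_iter = max_geom_iter),
            class = c("am1_engine", "qm_engine"))
}

#' Mock engine with scripted energies
#'
#' For testing the scoring and reporting layers without quantum chemistry.
#' `fn(z, xyz, charge)` must return a heat of formation (kcal/mol), `NA` for
#' a non-converged run, or a full result list.
#'
#' @param fn Energy callback.
#' @param fingerprint Cache key for the engine.
#' @return A `qm_engine` object.
#' @export
engine_mock <- function(fn, fingerprint = "mock") {
  stopifnot(is.function(fn))
  structure(list(name = "mock", fingerprint = fingerprint, fn = fn),
            class = c("mock_engine", "qm_engine"))
}

#' External MOPAC-dialect engine
#'
#' Drives an external semi-empirical program through MOPAC-format input decks
#' (keyword line, title, Cartesian coordinate block) and parses the final
#' heat of formation and geometry from its output. Only useful where such a
#' program is installed; the bundled [engine_am1()] needs no external
#' software.
#'
#' @param path Path to the executable.
#' @param method Hamiltonian keyword (default `"AM1"`; anything else is
#'   off-reference for this QSAR).
#' @param timeout Seconds allowed per species (default 300).
#' @return A `qm_engine` object.
#' @export
engine_mopac <- function(path = "mopac", method = "AM1", timeout = 300) {
  if (Sys.which(path) == "" && !file.exists(path))
    stop("MOPAC executable not found at '", path,
         "'; install it or use engine_am1()", call. = FALSE)
  structure(list(name = "mopac", path = path, method = method,
                 timeout = timeout,
                 fingerprint = paste0("mopac-", method, "-", basename(path))),
            class = c("mopac_engine", "qm_engine"))
}

#' Optimize one species with a QM engine
#'
#' @param engine A `qm_engine`.
#' @param z Integer vector of atomic numbers.
#' @param xyz Numeric matrix (n x 3) of Cartesian coordinates, angstrom.
#' @param charge Total charge (0 for the amine, +1 for the nitrenium ion).
#' @return `list(hf, xyz, converged, detail)`; `hf` is `NA` when not
#'   converged.
#' @export
optimize_species <- function(engine, z, xyz, charge = 0) {
  UseMethod("optimize_species")
}

#' @export
optimize_species.am1_engine <- function(engine, z, xyz, charge = 0) {
  r <- tryCatch(
    .am1_optimize(as.integer(z), as.matrix(xyz), as.integer(charge),
                  engine$gnorm, engine$max_geom_iter),
    error = function(e) list(hf = NA_real_, converged = FALSE, xyz = xyz,
                             gnorm = NA_real_, iterations = 0L,
                             scf_failed = TRUE, message = conditionMessage(e)))
  list(hf = if (isTRUE(r$converged)) r$hf else NA_real_,
       xyz = r$xyz, converged = isTRUE(r$converged), detail = r)
}

#' @export
optimize_species.mock_engine <- function(engine, z, xyz, charge = 0) {
  r <- engine$fn(z, xyz, charge)
  if (is.list(r)) {
    list(hf = r$hf, xyz = r$xyz %||% xyz,
         converged = r$converged %||% !is.na(r$hf), detail = r)
  } else {
    list(hf = r, xyz = xyz, converged = !is.na(r), detail = NULL)
  }
}

#' @export
optimize_species.mopac_engine <- function(engine, z, xyz, charge = 0) {
  deck <- write_mopac_deck(z, xyz, charge, method = engine$method)
  base <- .tempfile("")
  fin <- paste0(base, ".mop")
  writeLines(deck, fin)
  on.exit(unlink(paste0(base, c(".mop", ".out", ".arc", ".aux", ".end"))),
          add = TRUE)
  status <- suppressWarnings(
    system2(engine$path, fin, stdout = FALSE, stderr = FALSE,
            timeout = engine$timeout))
  fout <- paste0(base, ".out")
  if (!file.exists(fout))
    return(list(hf = NA_real_, xyz = xyz, converged = FALSE,
                detail = list(status = status, log = "no output file")))
  res <- parse_mopac_output(readLines(fout, warn = FALSE))
  list(hf = if (res$converged) res$hf else NA_real_,
       xyz = res$xyz %||% xyz, converged = res$converged,
       detail = list(status = status, log = res$log))
}

#' Write a MOPAC-dialect input deck
#'
#' @param z Atomic numbers.
#' @param xyz Coordinate matrix, angstrom.
#' @param charge Total charge.
#' @param method Hamiltonian keyword.
#' @return Character vector of input lines (keywords, title, Cartesian block
#'   with all coordinates flagged for optimization).
#' @export
write_mopac_deck <- function(z, xyz, charge = 0, method = "AM1") {
  sym <- names(.ZMAP)[match(z, .ZMAP)]
  kw <- sprintf("%s SINGLET %sXYZ", method,
                if (charge != 0) sprintf("CHARGE=%+d ", charge) else "")
  c(kw, "generated by nitrenium", "",
    sprintf("%-2s %12.6f 1 %12.6f 1 %12.6f 1",
            sym, xyz[, 1], xyz[, 2], xyz[, 3]))
}

#' Parse MOPAC-dialect output
#'
#' Extracts the final heat of formation (kcal/mol) and the last Cartesian
#' geometry block; a missing heat of formation or an explicit failure marker
#' means non-convergence.
#'
#' @param lines Character vector of output lines.
#' @return `list(hf, xyz, converged, log)`.
#' @export
parse_mopac_output <- function(lines) {
  bad <- grepl("EXCESS NUMBER OF OPTIMIZATION CYCLES|UNABLE TO ACHIEVE SELF-CONSISTENCE|CALCULATION ABANDONED|GEOMETRY IS NOT OPTIMIZED",
               lines)
  hfl <- grep("FINAL HEAT OF FORMATION", lines, value = TRUE)
  hf <- if (length(hfl) > 0)
    suppressWarnings(as.numeric(
      sub(".*FINAL HEAT OF FORMATION\\s*=\\s*(-?[0-9.]+)\\s*KCAL.*", "\\1",
          hfl[length(hfl)]))) else NA_real_
  xyz <- NULL
  blk <- grep("CARTESIAN COORDINATES", lines)
  if (length(blk) > 0) {
    start <- blk[length(blk)] + 1
    rows <- list()
    for (k in start:length(lines)) {
      f <- strsplit(trimws(lines[k]), "\\s+")[[1]]
      if (length(f) == 5 && !is.na(suppressWarnings(as.integer(f[1]))) &&
          f[2] %in% names(.ZMAP)) {
        rows[[length(rows) + 1]] <- as.numeric(f[3:5])
      } else if (length(rows) > 0) break
    }
    if (length(rows) > 0) xyz <- do.call(rbind, rows)
  }
  list(hf = hf, xyz = xyz, converged = !any(bad) && !is.na(hf),
       log = paste(utils::tail(lines, 30), collapse = "\n"))
}

#' Check aromatic-ring integrity after optimization
#'
#' Re-perceives connectivity from the optimized geometry with a covalent
#' radius criterion (bonded when the distance is below 1.25 times the sum of
#' covalent radii) and reports whether every aromatic ring bond of the input
#' topology survived. Molecules with no aromatic ring bonds pass vacuously.
#'
#' @param mol3d The molecule record whose bond table defines the rings.
#' @param xyz_opt Optimized coordinates, with rows matching `mol3d` atoms
#'   (or a subset given by `atom_map` after a hydrogen was removed).
#' @param atom_map Optional integer vector: row k of `xyz_opt` is atom
#'   `atom_map[k]` of `mol3d`.
#' @return `TRUE` if all aromatic ring bonds are intact.
#' @export
check_ring_integrity <- function(mol3d, xyz_opt, atom_map = NULL) {
  stopifnot(inherits(mol3d, "amine_mol"))
  b <- mol3d$bonds
  arb <- b[b$aromatic & b$in_ring, , drop = FALSE]
  if (nrow(arb) == 0) return(TRUE)
  el <- mol3d$atoms$element
  if (is.null(atom_map)) atom_map <- seq_len(nrow(mol3d$atoms))
  pos <- match(seq_len(nrow(mol3d$atoms)), atom_map)
  for (k in seq_len(nrow(arb))) {
    pi <- pos[arb$i[k]]; pj <- pos[arb$j[k]]
    if (is.na(pi) || is.na(pj)) next  # an atom of this bond was removed
    d <- sqrt(sum((xyz_opt[pi, ] - xyz_opt[pj, ])^2))
    if (d > 1.25 * (.RCOV[el[arb$i[k]]] + .RCOV[el[arb$j[k]]])) return(FALSE)
  }
  TRUE
}
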