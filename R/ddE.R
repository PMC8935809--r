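# The ddE score: relative nitrenium stabilization energy versus the aniline
# reference pair, and the sign-rule classifier built on it.

.ANILINE_SMILES <- "Nc1ccccc1"

# run the conformer + QM protocol for one parsed molecule; returns
# list(e_neutral, e_cation, n_conformers, candidate_h, n_ring_broken,
#      n_unconverged) or signals a condition with a remark class
.species_energies <- function(mol, engine, window = 7,
                              cation_from_all_conformers = TRUE,
                              force_sites = FALSE, seed = 20220321) {
  fail <- function(remark) {
    stop(structure(class = c("nitrenium_pipeline_error", "error", "condition"),
                   list(message = remark, call = NULL)))
  }
  ens <- tryCatch(enumerate_conformers(mol, window = window, seed = seed),
                  nitrenium_embed_error = function(e) NULL)
  if (is.null(ens)) fail("NaN")
  mol3d <- ens$mol3d
  sites <- find_primary_aromatic_amines(mol3d)
  if (nrow(sites) == 0) fail("no aromatic amine")
  if (!force_sites) sites <- sites[1, , drop = FALSE]

  # AM1-optimize every windowed conformer of the neutral; the most stable
  # conformer is the one with the lowest heat of formation
  ring_broken <- 0L; unconverged <- 0L
  neutrals <- list()
  for (k in seq_along(ens$xyz)) {
    r <- optimize_species(engine, mol3d$atoms$z, ens$xyz[[k]], charge = 0L)
    if (!r$converged) { unconverged <- unconverged + 1L; next }
    if (!check_ring_integrity(mol3d, r$xyz)) { ring_broken <- ring_broken + 1L; next }
    neutrals[[length(neutrals) + 1]] <- r
  }
  if (length(neutrals) == 0)
    fail(if (ring_broken > 0) "aromatic ring opening" else "NaN")
  hf_n <- vapply(neutrals, `[[`, numeric(1), "hf")
  e_neutral <- min(hf_n)
  seeds <- if (cation_from_all_conformers) neutrals
           else neutrals[which.min(hf_n)]

  # cation candidates: one per amine hydrogen (per site when forced),
  # started from each retained neutral geometry; the lowest result is kept
  e_cation <- Inf; cand_h <- NA_integer_
  cat_ring_broken <- 0L; cat_unconverged <- 0L; n_cand <- 0L
  for (s in seq_len(nrow(sites))) {
    for (nt in seeds) {
      cands <- build_nitrenium_candidates(mol3d, nt$xyz, sites[s, ])
      for (cd in cands) {
        n_cand <- n_cand + 1L
        r <- optimize_species(engine, cd$z, cd$xyz, charge = 1L)
        if (!r$converged) { cat_unconverged <- cat_unconverged + 1L; next }
        if (!check_ring_integrity(mol3d, r$xyz, atom_map = cd$atom_map)) {
          cat_ring_broken <- cat_ring_broken + 1L; next
        }
        if (r$hf < e_cation) { e_cation <- r$hf; cand_h <- cd$removed_h }
      }
    }
  }
  if (!is.finite(e_cation))
    fail(if (cat_ring_broken > 0) "aromatic ring opening" else "NaN")
  list(e_neutral = e_neutral, e_cation = e_cation,
       n_conformers = length(ens$xyz), candidate_h = cand_h,
       n_ring_broken = ring_broken + cat_ring_broken,
       n_unconverged = unconverged + cat_unconverged)
}

#' Aniline reference energies
#'
#' Runs the full neutral + nitrenium protocol on aniline and caches the two
#' heats of formation per engine fingerprint; the pair defines the zero of
#' the ddE scale, so the ddE of aniline itself is 0 by construction. A second
#' call with the same engine returns the cached values without engine work.
#'
#' @param engine A `qm_engine`.
#' @param window Conformer energy window, kcal/mol.
#' @param refresh Recompute even if cached.
#' @return A `ddE_reference`: list with `E_PhNH2`, `E_PhNHplus` (kcal/mol)
#'   and the engine fingerprint.
#' @export
reference_energies <- function(engine, window = 7, refresh = FALSE) {
  stopifnot(inherits(engine, "qm_engine"))
  key <- paste0(engine$fingerprint, "|w", format(window))
  if (!refresh && !is.null(.nitrenium_cache[[key]]))
    return(.nitrenium_cache[[key]])
  mol <- .record_from_smiles(.ANILINE_SMILES, id = "aniline")
  res <- tryCatch(
    .species_energies(mol, engine, window = window,
                      cation_from_all_conformers = FALSE),
    nitrenium_pipeline_error = function(e)
      stop("reference calculation on aniline failed (", conditionMessage(e),
           "); nothing downstream is meaningful with this engine",
           call. = FALSE))
  if (res$e_cation <= res$e_neutral)
    stop("engine returned a nitrenium cation more stable than neutral ",
         "aniline; refusing to build a reference from it", call. = FALSE)
  ref <- structure(list(E_PhNH2 = res$e_neutral, E_PhNHplus = res$e_cation,
                        fingerprint = engine$fingerprint, window = window),
                   class = "ddE_reference")
  .nitrenium_cache[[key]] <- ref
  ref
}

#' Classify a ddE value with the sign rule
#'
#' A compound with ddE below the cutoff is predicted mutagenic (its nitrenium
#' ion is more stabilized than the reference), otherwise nonmutagenic. The
#' boundary itself is nonmutagenic, consistent with aniline (ddE = 0) being
#' Ames-negative. The default cutoff 0 is the plain sign rule; +2.5 kcal/mol
#' is the best-accuracy cutoff reported for the method and can be selected
#' explicitly.
#'
#' @param ddE Numeric vector, kcal/mol.
#' @param cutoff Decision threshold, kcal/mol (default 0).
#' @return Character vector, `"mutagenic"` or `"nonmutagenic"` (`NA` in,
#'   `NA` out).
#' @export
classify <- function(ddE, cutoff = 0) {
  ifelse(is.na(ddE), NA_character_,
         ifelse(ddE < cutoff, "mutagenic", "nonmutagenic"))
}

#' Compute ddE for one molecule
#'
#' Runs conformer enumeration, AM1 optimization of the neutral and of the
#' nitrenium cation candidates (one per amine hydrogen, lowest kept), and
#' returns ddE = E(ArNH+) + E(PhNH2) - E(ArNH2) - E(PhNH+). Failures never
#' raise: they are reported in the `remark` column (`"NaN"` for
#' non-convergence or embedding failure, `"aromatic ring opening"`,
#' `"no aromatic amine"`, `"ineligible:<criteria>"`, `"parse error"`), with
#' an inconclusive prediction.
#'
#' @param mol An `amine_mol` record.
#' @param ref Reference energies from [reference_energies()].
#' @param engine The `qm_engine` used for `ref`.
#' @param cutoff Classification cutoff, kcal/mol.
#' @param window Conformer energy window, kcal/mol.
#' @param force Score the compound even if it fails eligibility criteria
#'   (the failure is still recorded in the remark).
#' @param cation_from_all_conformers If `TRUE` (default) the cation is
#'   started from every retained neutral conformer and the lowest ddE
#'   adopted; if `FALSE`, only from the most stable neutral conformer.
#' @param equivocal_band Optional half-width (kcal/mol); when set, compounds
#'   with |ddE - cutoff| below it are labelled `"equivocal"` instead of a
#'   binary call. Off (`NULL`) by default.
#' @param seed Reproducibility seed recorded in the provenance.
#' @return A one-row tibble: `id`, `name`, `smiles`, `ddE`, `prediction`,
#'   `remark`, `e_neutral`, `e_cation`, `n_conformers`, `candidate_h`,
#'   `engine`, `seed`.
#' @export
compute_ddE <- function(mol, ref, engine, cutoff = 0, window = 7,
                        force = FALSE, cation_from_all_conformers = TRUE,
                        equivocal_band = NULL, seed = 20220321) {
  stopifnot(inherits(mol, "amine_mol"), inherits(ref, "ddE_reference"))
  row <- function(ddE = NA_real_, remark = "", e_n = NA_real_,
                  e_c = NA_real_, nconf = NA_integer_, cand = NA_integer_) {
    pred <- if (is.na(ddE)) "inconclusive" else classify(ddE, cutoff)
    if (!is.na(ddE) && !is.null(equivocal_band) &&
        abs(ddE - cutoff) < equivocal_band) pred <- "equivocal"
    tibble::tibble(id = mol$id, name = mol$name,
                   smiles = mol$smiles, ddE = ddE, prediction = pred,
                   remark = remark, e_neutral = e_n, e_cation = e_c,
                   n_conformers = nconf, candidate_h = cand,
                   engine = engine$fingerprint, seed = seed)
  }
  if (!is.na(mol$error)) return(row(remark = mol$error))

  elig <- check_eligibility(mol)
  remark_elig <- ""
  if (!elig$eligible) {
    failed <- elig$failed_criteria[[1]]
    if (identical(failed, "v") && elig$n_amine_sites == 0)
      return(row(remark = "no aromatic amine"))
    remark_elig <- paste0("ineligible:", paste(failed, collapse = "+"))
    if (!force) return(row(remark = remark_elig))
  }

  res <- tryCatch(
    .species_energies(mol, engine, window = window,
                      cation_from_all_conformers = cation_from_all_conformers,
                      force_sites = force, seed = seed),
    nitrenium_pipeline_error = function(e) conditionMessage(e))
  if (is.character(res)) return(row(remark = res))

  ddE <- (res$e_cation + ref$E_PhNH2) - (res$e_neutral + ref$E_PhNHplus)
  row(ddE = ddE, remark = remark_elig, e_n = res$e_neutral,
      e_c = res$e_cation, nconf = res$n_conformers, cand = res$candidate_h)
}

#' Predict Ames mutagenicity for a batch of compounds
#'
#' The front door of the package: takes compounds as a data frame (columns
#' `smiles`, optional `id`, `name`), a character vector of SMILES, or a list
#' of records from [parse_structures()], scores each one with
#' [compute_ddE()], and returns one row per compound. Per-compound failures
#' become remarks, never errors, so batch runs always complete.
#'
#' @param compounds Data frame, character vector, or list of `amine_mol`.
#' @param engine A `qm_engine` (default: the bundled AM1 engine).
#' @param cutoff Classification cutoff, kcal/mol (default 0, the sign rule).
#' @param window Conformer energy window, kcal/mol (default 7).
#' @param force Score compounds that fail eligibility.
#' @param cation_from_all_conformers See [compute_ddE()].
#' @param equivocal_band See [compute_ddE()].
#' @param seed Reproducibility seed.
#' @param verbose Print per-compound progress.
#' @return A `ddE_tbl` tibble, one row per input compound.
#' @examples
#' \dontrun{
#' predict_ddE(c("Cc1ccccc1N", "Nc1ccc(Cl)cc1"))
#' }
#' @export
predict_ddE <- function(compounds, engine = engine_am1(), cutoff = 0,
                        window = 7, force = FALSE,
                        cation_from_all_conformers = TRUE,
                        equivocal_band = NULL, seed = 20220321,
                        verbose = FALSE) {
  mols <- if (is.character(compounds)) {
    parse_smiles(compounds)
  } else if (is.data.frame(compounds)) {
    stopifnot("smiles" %in% names(compounds))
    parse_smiles(compounds$smiles,
                 id = compounds$id %||% NULL,
                 name = compounds$name %||% NULL)
  } else if (is.list(compounds) &&
             all(vapply(compounds, inherits, logical(1), "amine_mol"))) {
    compounds
  } else {
    stop("compounds must be SMILES, a data frame with a 'smiles' column, ",
         "or a list of amine_mol records", call. = FALSE)
  }
  ref <- reference_energies(engine, window = window)
  out <- purrr::map(mols, function(m) {
    t0 <- Sys.time()
    r <- tryCatch(
      compute_ddE(m, ref, engine, cutoff = cutoff, window = window,
                  force = force,
                  cation_from_all_conformers = cation_from_all_conformers,
                  equivocal_band = equivocal_band, seed = seed),
      error = function(e) {
        tibble::tibble(id = m$id, name = m$name, smiles = m$smiles,
                       ddE = NA_real_, prediction = "inconclusive",
                       remark = "NaN", e_neutral = NA_real_,
                       e_cation = NA_real_, n_conformers = NA_integer_,
                       candidate_h = NA_integer_,
                       engine = engine$fingerprint, seed = seed)
      })
    if (verbose)
      message(sprintf("%-16s ddE=%7s  %s (%.1fs)", r$id,
                      ifelse(is.na(r$ddE), "--", sprintf("%.1f", r$ddE)),
                      r$prediction,
                      as.numeric(Sys.time() - t0, units = "secs")))
    r
  })
  res <- dplyr::bind_rows(out)
  class(res) <- c("ddE_tbl", class(res))
  attr(res, "cutoff") <- cutoff
  attr(res, "engine") <- engine$fingerprint
  res
}

#' @export
glance.ddE_tbl <- function(x, ...) {
  tibble::tibble(
    n = nrow(x),
    n_scored = sum(!is.na(x$ddE)),
    n_mutagenic = sum(x$prediction == "mutagenic", na.rm = TRUE),
    n_nonmutagenic = sum(x$prediction == "nonmutagenic", na.rm = TRUE),
    n_inconclusive = sum(x$prediction == "inconclusive", na.rm = TRUE),
    coverage = 100 * sum(!is.na(x$ddE)) / nrow(x),
    cutoff = attr(x, "cutoff") %||% 0
  )
}
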