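# Structure input/output: SMILES and SDF reading through Open Babel,
# salt stripping, and the CSV prediction report.

# build a molecule record from SDF text (explicit hydrogens already added).
# Returns an error record rather than signalling, so batch runs continue.
.record_from_sdf <- function(sdf, id, source, name = NA_character_,
                             keep_coords = FALSE) {
  err <- function(msg) {
    structure(list(id = id, name = name, source = source, smiles = NA_character_,
                   atoms = NULL, bonds = NULL, n_fragments_stripped = 0L,
                   error = msg), class = "amine_mol")
  }
  p <- .parse_sdf(sdf)
  if (is.null(p)) return(err("parse error"))
  unknown <- setdiff(unique(p$element), names(.ZMAP))
  if (length(unknown) > 0)
    return(err(paste0("parse error")))

  # largest organic fragment (salt/counter-ion stripping)
  g <- igraph::make_empty_graph(n = length(p$element), directed = FALSE)
  if (nrow(p$bonds) > 0)
    g <- igraph::add_edges(g, rbind(p$bonds$i, p$bonds$j))
  comp <- igraph::components(g)
  stripped <- 0L
  keep <- seq_along(p$element)
  if (comp$no > 1) {
    heavy <- p$element != "H"
    sizes <- vapply(seq_len(comp$no), function(k)
      sum(heavy & comp$membership == k), integer(1))
    has_c <- vapply(seq_len(comp$no), function(k)
      any(p$element == "C" & comp$membership == k), logical(1))
    cand <- if (any(has_c)) which(has_c) else seq_len(comp$no)
    best <- cand[which.max(sizes[cand])]
    keep <- which(comp$membership == best)
    stripped <- comp$no - 1L
    remap <- match(seq_along(p$element), keep)
    bk <- p$bonds[p$bonds$i %in% keep & p$bonds$j %in% keep, , drop = FALSE]
    bk$i <- remap[bk$i]; bk$j <- remap[bk$j]
    p <- list(element = p$element[keep], xyz = p$xyz[keep, , drop = FALSE],
              bonds = bk, charge = p$charge[keep], title = p$title)
    sdf <- .write_sdf(p$element, p$xyz, p$bonds, p$charge, title = id)
  }

  ar <- .mol2_aromatic(sdf)
  if (is.null(ar)) return(err("parse error"))
  can <- .ob_run(c("-isdf", "-ocan"), input = sdf)
  can <- trimws(sub("\\t.*$", "", can[nzchar(can)][1] %||% ""))
  if (!nzchar(can) || is.na(can)) return(err("parse error"))

  nb <- nrow(p$bonds)
  ring <- rep(FALSE, nb)
  if (nb > 0) {
    g2 <- igraph::graph_from_edgelist(cbind(p$bonds$i, p$bonds$j), directed = FALSE)
    br <- igraph::bridges(g2)
    ring <- !(seq_len(nb) %in% as.integer(br))
  }
  bond_ar <- rep(FALSE, nb)
  if (nb > 0 && nrow(ar$bond) > 0) {
    key <- function(i, j) paste(pmin(i, j), pmax(i, j))
    bond_ar <- key(p$bonds$i, p$bonds$j) %in%
      key(ar$bond$i, ar$bond$j)[ar$bond$ar]
  }

  atoms <- tibble::tibble(
    idx = seq_along(p$element),
    element = p$element,
    z = unname(.ZMAP[p$element]),
    charge = p$charge,
    aromatic = ar$atom,
    x = if (keep_coords) p$xyz[, 1] else NA_real_,
    y = if (keep_coords) p$xyz[, 2] else NA_real_,
    zc = if (keep_coords) p$xyz[, 3] else NA_real_
  )
  bonds <- tibble::tibble(
    i = p$bonds$i, j = p$bonds$j, order = p$bonds$order,
    aromatic = bond_ar, in_ring = ring
  )
  structure(list(id = id, name = name, source = source, smiles = can,
                 atoms = atoms, bonds = bonds,
                 n_fragments_stripped = stripped, error = NA_character_),
            class = "amine_mol")
}

# parse one SMILES string into a record
.record_from_smiles <- function(smiles, id, name = NA_character_) {
  sdf <- .ob_run(c("-ismi", "-osdf", "-h"), input = smiles)
  if (length(sdf) < 4)
    return(structure(list(id = id, name = name, source = "smiles",
                          smiles = NA_character_, atoms = NULL, bonds = NULL,
                          n_fragments_stripped = 0L, error = "parse error"),
                     class = "amine_mol"))
  .record_from_sdf(sdf, id = id, source = "smiles", name = name)
}

#' Read chemical structures from a SMILES or SDF file
#'
#' Reads one molecule per SMILES line (`SMILES [identifier] [name...]`,
#' whitespace-separated) or per SDF (V2000) entry. Each molecule is
#' normalized: explicit hydrogens are added, aromaticity is perceived, and
#' for multi-fragment inputs (salts, mixtures) only the largest
#' carbon-containing fragment is kept, so e.g. aniline hydrochloride is
#' scored as aniline. Entries that cannot be parsed yield records carrying a
#' `"parse error"` remark instead of aborting the run.
#'
#' @param path Path to the input file.
#' @param format `"smiles"` or `"sdf"`.
#' @return A list of molecule records (class `amine_mol`). An empty file
#'   returns an empty list with a warning.
#' @examples
#' \donttest{
#' f <- tempfile(fileext = ".smi")
#' writeLines(c("Nc1ccccc1 aniline", "Cc1ccccc1N o-toluidine"), f)
#' mols <- parse_structures(f, "smiles")
#' length(mols)
#' }
#' @export
parse_structures <- function(path, format = c("smiles", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (format == "smiles") {
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) {
      warning("empty input file: ", path, call. = FALSE)
      return(list())
    }
    recs <- vector("list", length(lines))
    ids <- character(length(lines))
    for (k in seq_along(lines)) {
      f <- strsplit(trimws(lines[k]), "\\s+")[[1]]
      ids[k] <- if (length(f) >= 2) f[2] else sprintf("mol_%03d", k)
      nm <- if (length(f) >= 3) paste(f[-(1:2)], collapse = " ") else NA_character_
      recs[[k]] <- list(smiles = f[1], name = nm)
    }
    ids <- make.unique(ids, sep = "_")
    purrr::map2(recs, ids, function(r, id)
      .record_from_smiles(r$smiles, id = id, name = r$name))
  } else {
    ends <- grep("^\\$\\$\\$\\$", lines)
    if (length(ends) == 0 && length(lines) > 3) ends <- length(lines)
    if (length(ends) == 0) {
      warning("empty input file: ", path, call. = FALSE)
      return(list())
    }
    starts <- c(1, head(ends, -1) + 1)
    ids <- character(length(starts))
    out <- vector("list", length(starts))
    for (k in seq_along(starts)) {
      block <- lines[starts[k]:ends[k]]
      title <- trimws(block[1])
      ids[k] <- if (nzchar(title)) title else sprintf("mol_%03d", k)
      out[[k]] <- block
    }
    ids <- make.unique(ids, sep = "_")
    purrr::map2(out, ids, function(block, id) {
      withH <- .ob_run(c("-isdf", "-osdf", "-h"), input = block)
      if (length(withH) < 4)
        structure(list(id = id, name = NA_character_, source = "sdf",
                       smiles = NA_character_, atoms = NULL, bonds = NULL,
                       n_fragments_stripped = 0L, error = "parse error"),
                  class = "amine_mol")
      else .record_from_sdf(withH, id = id, source = "sdf")
    })
  }
}

#' Parse SMILES strings into molecule records
#'
#' @param smiles Character vector of SMILES.
#' @param id Optional identifiers (defaults to `mol_001`, ...).
#' @param name Optional names.
#' @return A list of `amine_mol` records.
#' @export
parse_smiles <- function(smiles, id = NULL, name = NULL) {
  id <- id %||% sprintf("mol_%03d", seq_along(smiles))
  id <- make.unique(as.character(id), sep = "_")
  name <- name %||% rep(NA_character_, length(smiles))
  purrr::pmap(list(smiles, id, name), .record_from_smiles)
}

#' @export
print.amine_mol <- function(x, ...) {
  if (!is.na(x$error)) {
    cat(sprintf("<amine_mol %s: %s>\n", x$id, x$error))
  } else {
    cat(sprintf("<amine_mol %s: %s, %d atoms (%d heavy)%s>\n", x$id, x$smiles,
                nrow(x$atoms), sum(x$atoms$element != "H"),
                if (x$n_fragments_stripped > 0)
                  sprintf(", %d fragment(s) stripped", x$n_fragments_stripped)
                else ""))
  }
  invisible(x)
}

#' Write the prediction report as CSV
#'
#' Writes one row per input compound with columns
#' `id,ddE_kcal_per_mol,prediction,remark`. The ddE value is printed with one
#' decimal (the reporting precision of the method); inconclusive compounds
#' have an empty ddE field and a remark from the closed vocabulary `""`,
#' `"NaN"`, `"aromatic ring opening"`, `"no aromatic amine"`,
#' `"ineligible:<criterion>"`, `"parse error"`.
#'
#' @param rows A data frame with columns `id`, `ddE`, `prediction`, `remark`
#'   (e.g. the result of [predict_ddE()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(rows, path) {
  stopifnot(is.data.frame(rows), nrow(rows) > 0)
  need <- c("id", "ddE", "prediction", "remark")
  if (!all(need %in% names(rows)))
    stop("rows must have columns ", paste(need, collapse = ", "), call. = FALSE)
  dd <- ifelse(is.na(rows$ddE), "", sprintf("%.1f", .round1(rows$ddE)))
  out <- c("id,ddE_kcal_per_mol,prediction,remark",
           sprintf("%s,%s,%s,%s", rows$id, dd, rows$prediction,
                   ifelse(is.na(rows$remark), "", rows$remark)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}
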