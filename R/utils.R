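# internal helpers: element tables, Open Babel subprocess plumbing, SDF text

.ZMAP <- c(H = 1L, B = 5L, C = 6L, N = 7L, O = 8L, F = 9L, Na = 11L, Si = 14L,
           P = 15L, S = 16L, Cl = 17L, K = 19L, Br = 35L, I = 53L)

# average atomic masses, Da
.MASS <- c(H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
           F = 18.998, Na = 22.990, Si = 28.085, P = 30.974, S = 32.06,
           Cl = 35.45, K = 39.098, Br = 79.904, I = 126.904)

# single-bond covalent radii, angstrom (Cordero et al. consensus values)
.RCOV <- c(H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
           Na = 1.66, Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, K = 2.03,
           Br = 1.20, I = 1.39)

`%||%` <- function(a, b) if (is.null(a)) b else a

.ob_check <- function() {
  if (Sys.which("obabel") == "")
    stop("Open Babel ('obabel') was not found on the PATH; it is required ",
         "for structure parsing and conformer generation", call. = FALSE)
}

# run obabel, returning stdout lines; diagnostics are discarded (obabel
# reports per-molecule failure by simply emitting nothing)
.ob_run <- function(args, input = NULL) {
  .ob_check()
  suppressWarnings(
    tryCatch(system2("obabel", args, stdout = TRUE, stderr = FALSE,
                     input = input),
             error = function(e) character(0))
  )
}

.tempfile <- function(ext) tempfile("nitrenium-", fileext = ext)

# parse the first V2000 molfile in a character vector of SDF lines
.parse_sdf <- function(lines) {
  if (length(lines) < 4) return(NULL)
  counts <- lines[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || na < 1) return(NULL)
  at <- lines[5:(4 + na)]
  xyz <- matrix(NA_real_, na, 3)
  element <- character(na)
  for (i in seq_len(na)) {
    xyz[i, 1] <- as.numeric(substr(at[i], 1, 10))
    xyz[i, 2] <- as.numeric(substr(at[i], 11, 20))
    xyz[i, 3] <- as.numeric(substr(at[i], 21, 30))
    element[i] <- trimws(substr(at[i], 32, 34))
  }
  bonds <- if (nb > 0) {
    bl <- lines[(5 + na):(4 + na + nb)]
    data.frame(
      i = as.integer(substr(bl, 1, 3)),
      j = as.integer(substr(bl, 4, 6)),
      order = as.integer(substr(bl, 7, 9))
    )
  } else data.frame(i = integer(), j = integer(), order = integer())
  charge <- integer(na)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    nset <- f[1]
    for (k in seq_len(nset)) charge[f[2 * k]] <- f[2 * k + 1]
  }
  list(element = element, xyz = xyz, bonds = bonds, charge = charge,
       title = lines[1])
}

# write a minimal V2000 molfile for a molecule record (or element/xyz/bonds)
.write_sdf <- function(element, xyz, bonds, charge = NULL, title = "mol") {
  na <- length(element)
  nb <- nrow(bonds)
  out <- c(title, " nitrenium", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  for (i in seq_len(na)) {
    out <- c(out, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                          xyz[i, 1], xyz[i, 2], xyz[i, 3], element[i]))
  }
  for (b in seq_len(nb)) {
    out <- c(out, sprintf("%3d%3d%3d  0  0  0  0", bonds$i[b], bonds$j[b],
                          bonds$order[b]))
  }
  if (!is.null(charge)) {
    ch <- which(charge != 0L)
    for (i in ch) out <- c(out, sprintf("M  CHG  1 %3d %3d", i, charge[i]))
  }
  c(out, "M  END", "$$$$")
}

# mol2 aromaticity flags for an SDF text (atom order is preserved by obabel)
.mol2_aromatic <- function(sdf_lines) {
  m2 <- .ob_run(c("-isdf", "-omol2"), input = sdf_lines)
  if (length(m2) == 0) return(NULL)
  a0 <- grep("@<TRIPOS>ATOM", m2, fixed = TRUE)[1]
  b0 <- grep("@<TRIPOS>BOND", m2, fixed = TRUE)[1]
  if (is.na(a0) || is.na(b0)) return(NULL)
  sections <- grep("^@", m2)
  a1 <- min(c(sections[sections > a0], length(m2) + 1)) - 1
  at <- m2[(a0 + 1):a1]
  at <- at[nzchar(trimws(at))]
  fields <- strsplit(trimws(at), "\\s+")
  types <- vapply(fields, function(v) v[6], character(1))
  ar_atom <- grepl("\\.ar$", types)
  rest <- m2[(b0 + 1):length(m2)]
  rest <- rest[!grepl("^@", rest)]
  rest <- rest[nzchar(trimws(rest))]
  bf <- strsplit(trimws(rest), "\\s+")
  ar_bond <- data.frame(
    i = vapply(bf, function(v) as.integer(v[2]), integer(1)),
    j = vapply(bf, function(v) as.integer(v[3]), integer(1)),
    ar = vapply(bf, function(v) identical(v[4], "ar"), logical(1))
  )
  list(atom = ar_atom, bond = ar_bond)
}

.round1 <- function(x) floor(x * 10 + 0.5) / 10  # half-up, one decimal

.kabsch_rmsd <- function(a, b) {
  # heavy-atom RMSD after optimal superposition
  ca <- sweep(a, 2, colMeans(a)); cb <- sweep(b, 2, colMeans(b))
  s <- svd(crossprod(ca, cb))                       # H = U S V'
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)        # Ca %*% rot ~ Cb
  sqrt(mean(rowSums((ca %*% rot - cb)^2)))
}
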