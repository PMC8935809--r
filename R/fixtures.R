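# The bundled 23-compound reference panel and a synthetic score generator,
# so every layer above the engine is testable without downloads.

#' The 23-compound aromatic amine reference panel
#'
#' Aniline, its methyl/methoxy/sulfonate/sulfonamide derivatives, and amines
#' from published ICH M7 expert-review case studies, with CAS numbers, Ames
#' calls, and the published ddE values (kcal/mol) for regression. SMILES were
#' resolved from the printed CAS numbers and names at authoring time and are
#' embedded as reviewed constants; no runtime registry lookup happens. Two
#' entries are stored as hydrochloride salts (No. 1 aniline hydrochloride,
#' No. 9 o-anisidine hydrochloride) and exercise the largest-fragment
#' normalization rule: both are scored as their free bases. Commercial-tool
#' calls (`gt1_bmut`, `leadscope`, `derek`, `gt_expert`) are annotation
#' strings only and are never interpreted by this package.
#'
#' @return A 23-row tibble: `no`, `cas`, `name`, `smiles`, `ames`,
#'   `ddE_paper`, and the four annotation columns.
#' @examples
#' reference_set()
#' @export
reference_set <- function() {
  f <- system.file("extdata", "reference_panel.csv", package = "nitrenium",
                   mustWork = TRUE)
  x <- utils::read.csv(f, stringsAsFactors = FALSE)
  tibble::as_tibble(x)
}

#' Synthetic ddE scores for two labelled classes
#'
#' Draws Gaussian ddE scores for mutagens and nonmutagens, emulating the
#' separation seen in practice (small/negative values for mutagens, large
#' positive values for nonmutagens) for exercising the metric and
#' cutoff-sweep machinery without any quantum chemistry. Defaults mirror the
#' composition of the 85-compound benchmark (51 mutagens, 34 nonmutagens)
#' with class means of -8 and +8 kcal/mol and a common 5 kcal/mol spread.
#'
#' @param n_mut,n_non Class sizes (positive integers).
#' @param mu_mut,mu_non Class means, kcal/mol.
#' @param sd Common standard deviation, kcal/mol (nonnegative; 0 gives
#'   perfectly separated classes).
#' @param seed Integer seed; the generator is reproducible and does not
#'   disturb the global RNG state.
#' @return A tibble with `id`, `ames` (`"mutagen"`/`"nonmutagen"`), and
#'   `ddE`.
#' @examples
#' synthetic_scores(seed = 1)
#' @export
synthetic_scores <- function(n_mut = 51, n_non = 34, mu_mut = -8,
                             mu_non = 8, sd = 5, seed = 20220321) {
  stopifnot(n_mut > 0, n_non > 0, sd >= 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  tibble::tibble(
    id = sprintf("syn_%03d", seq_len(n_mut + n_non)),
    ames = rep(c("mutagen", "nonmutagen"), c(n_mut, n_non)),
    ddE = c(stats::rnorm(n_mut, mu_mut, sd), stats::rnorm(n_non, mu_non, sd))
  )
}
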