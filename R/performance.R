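# Benchmark statistics with coverage bookkeeping, and the decision-cutoff
# sweep. Inconclusive and out-of-domain calls are excluded from the
# confusion matrix and surface only through coverage - the convention that
# lets a tool report, say, 77.6% coverage alongside a well-defined accuracy.

.norm_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- dplyr::case_match(x,
    c("mutagen", "mutagenic", "positive", "pos", "1") ~ "mutagen",
    c("nonmutagen", "non mutagen", "non-mutagen", "nonmutagenic",
      "negative", "neg", "0") ~ "nonmutagen",
    .default = NA_character_)
  if (anyNA(out))
    stop("labels must be mutagen/nonmutagen (got: ",
         paste(unique(x[is.na(out)]), collapse = ", "), ")", call. = FALSE)
  out
}

.norm_pred <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[is.na(x)] <- "inconclusive"
  out <- dplyr::case_match(x,
    c("mutagenic", "mutagen", "positive") ~ "mutagenic",
    c("nonmutagenic", "nonmutagen", "negative") ~ "nonmutagenic",
    c("inconclusive", "equivocal", "na", "nan", "") ~ "inconclusive",
    c("out_of_domain", "out of domain") ~ "out_of_domain",
    .default = NA_character_)
  if (anyNA(out))
    stop("predictions must be mutagenic/nonmutagenic/inconclusive/",
         "out_of_domain", call. = FALSE)
  out
}

#' Tally a confusion matrix with coverage bookkeeping
#'
#' Mutagenic predictions are the positive class. Inconclusive and
#' out-of-domain predictions are counted separately and excluded from
#' TP/FP/TN/FN, so `tp + fp + tn + fn + n_inconclusive + n_out_of_domain`
#' always equals the number of records.
#'
#' @param predictions `"mutagenic"`, `"nonmutagenic"`, `"inconclusive"`, or
#'   `"out_of_domain"` (NA counts as inconclusive).
#' @param labels Experimental calls, `"mutagen"` or `"nonmutagen"`.
#' @return A `confusion_counts` list.
#' @export
confusion_counts <- function(predictions, labels) {
  if (length(predictions) != length(labels))
    stop("predictions and labels must have the same length", call. = FALSE)
  p <- .norm_pred(predictions)
  l <- .norm_label(labels)
  structure(list(
    tp = sum(p == "mutagenic" & l == "mutagen"),
    fp = sum(p == "mutagenic" & l == "nonmutagen"),
    tn = sum(p == "nonmutagenic" & l == "nonmutagen"),
    fn = sum(p == "nonmutagenic" & l == "mutagen"),
    n_inconclusive = sum(p == "inconclusive"),
    n_out_of_domain = sum(p == "out_of_domain"),
    total = length(p)), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts TP=%d FP=%d TN=%d FN=%d inconclusive=%d out_of_domain=%d>\n",
              x$tp, x$fp, x$tn, x$fn, x$n_inconclusive, x$n_out_of_domain))
  invisible(x)
}

#' Compute the seven benchmark statistics
#'
#' Accuracy, sensitivity, specificity, positive and negative prediction
#' values and coverage as percentages, plus the Matthews correlation
#' coefficient. A statistic whose denominator is zero is reported as `NA`
#' ("not applicable"), never as 0. Values carry full precision; displays
#' round to one decimal.
#'
#' @param counts A `confusion_counts` object (or list with `tp`, `fp`,
#'   `tn`, `fn`; `n_inconclusive`/`n_out_of_domain`/`total` default to a
#'   fully covered run).
#' @param cutoff Optional cutoff annotation for the row, kcal/mol.
#' @return A one-row tibble (`metrics_row`).
#' @export
compute_metrics <- function(counts, cutoff = NA_real_) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  ninc <- counts$n_inconclusive %||% 0
  nood <- counts$n_out_of_domain %||% 0
  total <- counts$total %||% (tp + fp + tn + fn + ninc + nood)
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  mcc_den <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else NA_real_
  tibble::tibble(
    cutoff = cutoff,
    accuracy = rate(tp + tn, tp + fp + tn + fn),
    sensitivity = rate(tp, tp + fn),
    specificity = rate(tn, tn + fp),
    ppv = rate(tp, tp + fp),
    npv = rate(tn, tn + fn),
    mcc = mcc,
    coverage = rate(tp + fp + tn + fn, total),
    n_inconclusive = ninc,
    n_out_of_domain = nood
  )
}

#' Sweep the classification cutoff over a grid
#'
#' Classifies the ddE values at each cutoff of the grid, computes the full
#' metrics row for each, and identifies the best cutoff by accuracy (ties
#' broken by larger MCC, then by smaller |cutoff|). The default grid is
#' -10 to +10 kcal/mol in steps of 2.5.
#'
#' @param ddE Numeric vector of scores, kcal/mol (NA = inconclusive).
#' @param labels Experimental calls (`"mutagen"`/`"nonmutagen"`).
#' @param grid Cutoff grid, kcal/mol.
#' @return A `nitrenium_sweep` tibble, one row per cutoff, with the best
#'   cutoff in `attr(, "best_cutoff")`.
#' @export
cutoff_sweep <- function(ddE, labels, grid = seq(-10, 10, by = 2.5)) {
  stopifnot(length(grid) > 0)
  if (length(ddE) != length(labels))
    stop("ddE and labels must have the same length", call. = FALSE)
  rows <- purrr::map(grid, function(ct)
    compute_metrics(confusion_counts(classify(ddE, ct), labels), cutoff = ct))
  res <- dplyr::bind_rows(rows)
  ord <- order(-res$accuracy,
               -ifelse(is.na(res$mcc), -Inf, res$mcc),
               abs(res$cutoff))
  best <- res$cutoff[ord[1]]
  structure(res, best_cutoff = best,
            class = c("nitrenium_sweep", class(res)))
}

#' Best cutoff found by a sweep
#' @param sweep A `nitrenium_sweep`.
#' @return The cutoff (kcal/mol) with maximal accuracy.
#' @export
best_cutoff <- function(sweep) attr(sweep, "best_cutoff")

#' Benchmark predictions against Ames labels
#'
#' Convenience wrapper: classify `ddE` at one cutoff and compute the metrics
#' row. Compounds with missing ddE count as inconclusive and reduce
#' coverage.
#'
#' @param data Data frame with a ddE column and a label column.
#' @param ddE_col,label_col Column names.
#' @param cutoff Decision cutoff, kcal/mol.
#' @return A one-row metrics tibble.
#' @export
benchmark_panel <- function(data, ddE_col = "ddE", label_col = "ames",
                            cutoff = 0) {
  stopifnot(is.data.frame(data), ddE_col %in% names(data),
            label_col %in% names(data))
  compute_metrics(
    confusion_counts(classify(data[[ddE_col]], cutoff), data[[label_col]]),
    cutoff = cutoff)
}

#' @export
tidy.nitrenium_sweep <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- setdiff(class(out), "nitrenium_sweep")
  out
}

#' @export
glance.nitrenium_sweep <- function(x, ...) {
  b <- best_cutoff(x)
  row <- x[which(x$cutoff == b)[1], , drop = FALSE]
  tibble::tibble(best_cutoff = b, accuracy = row$accuracy, mcc = row$mcc,
                 n_cutoffs = nrow(x))
}
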