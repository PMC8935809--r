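test_that("confusion counting excludes inconclusive calls from the matrix", {
  cc <- confusion_counts(rep(c("mutagenic", "nonmutagenic"), each = 5),
                         rep(c("mutagen", "nonmutagen"), each = 5))
  expect_equal(cc$tp, 5); expect_equal(cc$tn, 5)
  expect_equal(cc$fp, 0); expect_equal(cc$fn, 0)

  cc2 <- confusion_counts(rep("inconclusive", 6), rep("mutagen", 6))
  expect_equal(cc2$tp + cc2$fp + cc2$tn + cc2$fn, 0)
  expect_equal(compute_metrics(cc2)$coverage, 0)

  p <- c(rep("mutagenic", 4), rep("nonmutagenic", 4), rep("inconclusive", 2))
  l <- rep(c("mutagen", "nonmutagen"), 5)
  cc3 <- confusion_counts(p, l)
  expect_equal(cc3$tp + cc3$fp + cc3$tn + cc3$fn, 8)  # denominator excludes 2
  expect_equal(cc3$n_inconclusive, 2)
  expect_equal(cc3$tp + cc3$fp + cc3$tn + cc3$fn +
                 cc3$n_inconclusive + cc3$n_out_of_domain, 10)
  expect_error(confusion_counts("mutagenic", c("mutagen", "mutagen")), "length")
})

test_that("the seven statistics reproduce the benchmark worked example", {
  # 85 amines: 51 mutagens, 34 nonmutagens; TP=38 FP=13 FN=13 TN=21
  m <- compute_metrics(list(tp = 38, fp = 13, tn = 21, fn = 13))
  r1 <- function(x) floor(x * 10 + 0.5) / 10
  expect_equal(r1(m$accuracy), 69.4)
  expect_equal(r1(m$sensitivity), 74.5)
  expect_equal(r1(m$specificity), 61.8)
  expect_equal(r1(m$ppv), 74.5)
  expect_equal(r1(m$npv), 61.8)
  expect_equal(r1(m$mcc), 0.4)
  expect_equal(m$coverage, 100)
  # full-precision identities behind the rounded display
  expect_equal(m$accuracy, 100 * 59 / 85)
  expect_equal(m$mcc, 629 / 1734, tolerance = 1e-12)
})

test_that("perfect and degenerate classifiers hit the boundary values", {
  perfect <- compute_metrics(list(tp = 10, fp = 0, tn = 10, fn = 0))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$mcc, 1)
  # all-positive predictor on balanced labels: specificity 0, npv undefined
  allpos <- compute_metrics(list(tp = 10, fp = 10, tn = 0, fn = 0))
  expect_equal(allpos$specificity, 0)
  expect_true(is.na(allpos$npv))
  expect_true(is.na(allpos$mcc))
  empty <- compute_metrics(list(tp = 0, fp = 0, tn = 0, fn = 0,
                                n_inconclusive = 4, total = 4))
  expect_true(is.na(empty$accuracy))
})

test_that("metrics agree with a brute-force recount on random instances", {
  set.seed(42)
  for (rep in 1:1000) {
    n <- sample(3:40, 1)
    l <- sample(c("mutagen", "nonmutagen"), n, replace = TRUE)
    p <- sample(c("mutagenic", "nonmutagenic", "inconclusive"), n,
                replace = TRUE, prob = c(0.4, 0.4, 0.2))
    m <- compute_metrics(confusion_counts(p, l))
    # independent recount straight from the raw pairs
    conc <- p != "inconclusive"
    tp <- sum(conc & p == "mutagenic" & l == "mutagen")
    fp <- sum(conc & p == "mutagenic" & l == "nonmutagen")
    tn <- sum(conc & p == "nonmutagenic" & l == "nonmutagen")
    fn <- sum(conc & p == "nonmutagenic" & l == "mutagen")
    acc <- if (sum(conc) > 0) 100 * (tp + tn) / sum(conc) else NA_real_
    expect_identical(is.na(m$accuracy), is.na(acc))
    if (!is.na(acc)) expect_equal(m$accuracy, acc, tolerance = 1e-12)
    expect_equal(m$coverage, 100 * sum(conc) / n, tolerance = 1e-12)
    sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
    expect_equal(m$sensitivity, sens, tolerance = 1e-12)
    # accuracy is the prevalence-weighted mix of sensitivity and specificity
    if (!anyNA(c(m$accuracy, m$sensitivity, m$specificity))) {
      mix <- (m$sensitivity * (tp + fn) + m$specificity * (tn + fp)) /
        (tp + fn + tn + fp)
      expect_equal(m$accuracy, mix, tolerance = 1e-9)
    }
  }
})

test_that("the cutoff sweep recovers the separating threshold", {
  syn <- synthetic_scores(n_mut = 500, n_non = 500, mu_mut = -8, mu_non = 8,
                          sd = 5, seed = 7)
  sw <- cutoff_sweep(syn$ddE, syn$ames)
  expect_equal(nrow(sw), 9)                      # -10 to 10 by 2.5
  expect_lte(abs(best_cutoff(sw)), 2.5)          # within one grid step of 0
  # perfectly separated scores: every interior cutoff is perfect
  dd <- c(rep(-3, 10), rep(3, 10))
  ll <- rep(c("mutagen", "nonmutagen"), each = 10)
  sw2 <- cutoff_sweep(dd, ll, grid = c(-2.5, 0, 2.5))
  expect_true(all(sw2$accuracy == 100))
  sw3 <- cutoff_sweep(dd, ll, grid = 0)
  expect_equal(nrow(sw3), 1)
  expect_equal(best_cutoff(sw3), 0)
})

test_that("sweep results do not depend on compound order", {
  syn <- synthetic_scores(seed = 11)
  p <- sample(nrow(syn))
  sw1 <- cutoff_sweep(syn$ddE, syn$ames)
  sw2 <- cutoff_sweep(syn$ddE[p], syn$ames[p])
  expect_equal(tidy(sw1), tidy(sw2))
})

test_that("best-cutoff ties break by MCC then by smaller |cutoff|", {
  # two cutoffs with identical accuracy; symmetric scores make -2.5/+2.5 tie
  dd <- c(-6, -1, 1, 6)
  ll <- c("mutagen", "mutagen", "nonmutagen", "nonmutagen")
  sw <- cutoff_sweep(dd, ll, grid = c(-5, 0, 5))
  expect_equal(best_cutoff(sw), 0)   # accuracy 100 at 0; 75 at +-5
  sw2 <- cutoff_sweep(dd, ll, grid = c(-7, 7))    # both 75%, same mcc -> |.|
  expect_equal(best_cutoff(sw2), 7 * sign(best_cutoff(sw2)))
})

test_that("benchmark_panel and the tidiers wrap the same computation", {
  syn <- synthetic_scores(seed = 3)
  row <- benchmark_panel(syn, cutoff = 0)
  direct <- compute_metrics(confusion_counts(classify(syn$ddE, 0), syn$ames),
                            cutoff = 0)
  expect_equal(row, direct)
  sw <- cutoff_sweep(syn$ddE, syn$ames)
  expect_s3_class(tidy(sw), "tbl_df")
  g <- glance(sw)
  expect_equal(g$n_cutoffs, 9)
  expect_equal(g$best_cutoff, best_cutoff(sw))
})
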