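test_that("confusion matrices combine by elementwise summation", {
  a <- confusion_counts(1, 0, 0, 1)
  b <- confusion_counts(2, 1, 1, 0)
  s <- combine_confusions(list(a, b))
  expect_equal(unlist(s[c("tp", "fn", "fp", "tn")]),
               c(tp = 3, fn = 1, fp = 1, tn = 1))
  one <- combine_confusions(list(a))
  expect_equal(unlist(one[c("tp", "fn", "fp", "tn")]),
               unlist(a[c("tp", "fn", "fp", "tn")]))
  expect_error(combine_confusions(list()), "at least one")
})

test_that("majority vote matches a brute-force argmax oracle with SSc ties", {
  expect_equal(majority_vote(rep(c("SSc", "Control"), c(130, 110))), "SSc")
  expect_equal(majority_vote(rep(c("SSc", "Control"), c(120, 120))), "SSc")
  expect_error(majority_vote(character(0)), "no image predictions")

  # oracle over every possible split of 240 image predictions
  for (n_ssc in 0:240) {
    votes <- rep(c("SSc", "Control"), c(n_ssc, 240 - n_ssc))
    oracle <- if (n_ssc >= 240 - n_ssc) "SSc" else "Control"
    expect_identical(majority_vote(votes), oracle)
  }
})

test_that("diagnostic metrics reproduce the printed combined-matrix values", {
  m_img <- metrics(confusion_counts(3359, 1201, 1517, 10111))
  expect_equal(round_half_up(m_img$accuracy[["value"]]), 83.2)
  expect_equal(round_half_up(m_img$sensitivity[["value"]]), 73.7)
  # printed as 86.9: the source table truncates 86.954 (see acceptance test)
  expect_equal(round_half_up(m_img$specificity[["value"]], 2), 86.95)

  m_part <- metrics(confusion_counts(15, 5, 7, 44))
  expect_equal(round_half_up(m_part$accuracy[["value"]]), 83.1)
  expect_equal(round_half_up(m_part$sensitivity[["value"]]), 75.0)
  expect_equal(round_half_up(m_part$specificity[["value"]]), 86.3)

  m_perfect <- metrics(confusion_counts(1, 0, 0, 1))
  expect_equal(m_perfect$accuracy[["value"]], 100)
  expect_equal(m_perfect$sensitivity[["value"]], 100)
  expect_equal(m_perfect$specificity[["value"]], 100)

  expect_error(metrics(confusion_counts(0, 0, 1, 1)), "positive-class")
  expect_error(metrics(confusion_counts(1, 1, 0, 0)), "negative-class")

  # interval invariants: low <= point <= high, within [0, 100]
  for (m in list(m_img, m_part)) {
    for (nm in c("accuracy", "sensitivity", "specificity")) {
      v <- m[[nm]]
      expect_true(v[["low"]] <= v[["value"]] &&
                    v[["value"]] <= v[["high"]])
      expect_true(v[["low"]] >= 0 && v[["high"]] <= 100)
    }
  }
})

test_that("metrics are invariant to the order folds are combined in", {
  set.seed(23)
  cms <- lapply(1:10, function(i)
    confusion_counts(sample(0:5, 1), sample(0:5, 1), sample(0:5, 1),
                     sample(1:5, 1)))
  m1 <- metrics(combine_confusions(cms))
  m2 <- metrics(combine_confusions(rev(cms)))
  expect_equal(m1$accuracy, m2$accuracy)
  expect_equal(m1$sensitivity, m2$sensitivity)
})

test_that("exact binomial intervals match printed values and tail inversion", {
  expect_equal(round_half_up(exact_ci(15, 20)),
               c(low = 50.9, high = 91.3))
  expect_equal(round_half_up(exact_ci(44, 51)[["low"]]), 73.7)
  expect_equal(exact_ci(0, 10)[["low"]], 0)
  expect_equal(exact_ci(10, 10)[["high"]], 100)
  expect_error(exact_ci(5, 0), "trials")
  expect_error(exact_ci(11, 10), "successes")

  # independent oracle: invert the binomial tail sums numerically
  tail_invert <- function(k, n) {
    lo <- if (k == 0) 0 else
      stats::uniroot(function(p) stats::pbinom(k - 1, n, p) - 0.975,
                     c(1e-12, 1 - 1e-12), tol = 1e-12)$root
    hi <- if (k == n) 1 else
      stats::uniroot(function(p) stats::pbinom(k, n, p) - 0.025,
                     c(1e-12, 1 - 1e-12), tol = 1e-12)$root
    100 * c(lo, hi)
  }
  for (n in c(10, 20, 51, 71)) {
    for (k in unique(c(0, 1, n %/% 3, n %/% 2, n - 1, n))) {
      ci <- exact_ci(k, n)
      expect_equal(unname(ci), tail_invert(k, n), tolerance = 1e-6)
      expect_true(ci[["low"]] <= 100 * k / n &&
                    100 * k / n <= ci[["high"]])
    }
  }
})

test_that("Clopper-Pearson empirical coverage is at least nominal", {
  set.seed(29)
  for (p in c(0.1, 0.5, 0.9)) {
    for (n in c(20, 51, 71)) {
      cis <- vapply(0:n, function(ki) exact_ci(ki, n), numeric(2))
      inside <- cis[1, ] <= 100 * p & 100 * p <= cis[2, ]
      k <- stats::rbinom(2e5, n, p)
      expect_gte(mean(inside[k + 1]), 0.95)
    }
  }
})

test_that("crosshair export flips specificity into FPR with swapped bounds", {
  m <- metrics(confusion_counts(15, 5, 7, 44))
  out <- crosshair_export(list(cnn = m, again = m))
  expect_equal(nrow(out), 2)
  expect_equal(round_half_up(out$fpr[1]), 13.7)
  expect_equal(round_half_up(out$fpr_low[1]), 100 - 94.3)
  expect_equal(round_half_up(out$fpr_high[1]), 100 - 73.7)
  expect_equal(out$sensitivity[1], m$sensitivity[["value"]])
  expect_equal(out$sens_low[1], m$sensitivity[["low"]])

  path <- withr::local_tempfile(fileext = ".csv")
  crosshair_export(list(cnn = m), file = path)
  expect_equal(nrow(utils::read.csv(path)), 1)
  expect_error(crosshair_export(list()), "at least one")
})

test_that("image predictions aggregate to participant-level majority labels", {
  pred <- data.frame(
    participant_id = rep(c("A", "B"), each = 4),
    truth = rep(c("SSc", "Control"), each = 4),
    predicted = c("SSc", "SSc", "Control", "SSc",
                  "Control", "SSc", "SSc", "Control"))  # B ties -> SSc
  votes <- participant_votes(pred)
  expect_equal(votes$predicted[votes$participant_id == "A"], "SSc")
  expect_equal(votes$predicted[votes$participant_id == "B"], "SSc")
  ev <- evaluate_predictions(pred)
  expect_equal(ev$participant$cm$tp, 1)
  expect_equal(ev$participant$cm$fp, 1)
  expect_equal(ev$image$cm$tp + ev$image$cm$fn, 4)
})
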