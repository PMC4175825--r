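test_that("Wilcoxon signed-rank: all-positive differences at n = 5", {
  # W+ = 15, exact two-sided p = 2 * P(W+ >= 15) = 2/32
  r <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5))
  expect_equal(r$statistic, 15)
  expect_equal(r$p.value, 0.0625)
  expect_true(r$exact)
  expect_error(wilcoxon_signed_rank(1:4, 1:4), "degenerate pairing")
  expect_error(wilcoxon_signed_rank(1:3, 1:4), "equal length")
})

test_that("exact Wilcoxon p equals the full 2^n sign-flip enumeration oracle", {
  withr::with_seed(2024, {
    for (i in 1:50) {
      n <- sample(3:12, 1)
      x <- round(rnorm(n), sample(0:2, 1))   # rounding induces ties
      y <- round(rnorm(n), 1)
      d <- x - y
      d <- d[d != 0]
      if (length(d) < 2) next
      r <- rank(abs(d))
      signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
      Wall <- signs %*% r                     # W+ under every sign assignment
      w <- sum(r[d > 0])
      p_oracle <- min(1, 2 * min(mean(Wall <= w + 1e-9),
                                 mean(Wall >= w - 1e-9)))
      got <- wilcoxon_signed_rank(x, y)
      expect_equal(got$p.value, p_oracle, tolerance = 1e-12)
    }
  })
})

test_that("exact Wilcoxon matches stats::wilcox.test in tie-free cases", {
  withr::with_seed(5, {
    for (i in 1:20) {
      n <- sample(4:12, 1)
      x <- rnorm(n); y <- rnorm(n)
      ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
      got <- wilcoxon_signed_rank(x, y)
      expect_equal(got$statistic, unname(ref$statistic))
      expect_equal(got$p.value, ref$p.value, tolerance = 1e-12)
    }
  })
})

test_that("large-n Wilcoxon uses the tie-corrected normal approximation", {
  withr::with_seed(77, {
    x <- rnorm(30) + 0.5
    y <- rnorm(30)
  })
  got <- wilcoxon_signed_rank(x, y)
  expect_false(got$exact)
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = FALSE)
  expect_equal(got$p.value, ref$p.value, tolerance = 1e-10)
})

test_that("Friedman test: degenerate ties, closed-form check, rank invariance", {
  expect_equal(friedman_test(matrix(5, 4, 3)),
               list(statistic = 0, df = 2, p.value = 1))

  # one model always ranks last, the other two exchangeable: with k = 3,
  # n = 10 and within-patient ranks (r1, r2, 3), chi2 = 12/(n k (k+1)) *
  # sum (R_j - n(k+1)/2)^2 computed directly from the rank sums
  withr::with_seed(10, {
    m <- cbind(rnorm(10, 5), rnorm(10, 5), rnorm(10, 0))
  })
  got <- friedman_test(m)
  rk <- t(apply(m, 1, rank))
  Rj <- colSums(rk)
  chi2 <- 12 / (10 * 3 * 4) * sum((Rj - 10 * 2)^2)
  expect_equal(got$statistic, chi2, tolerance = 1e-9)
  expect_equal(got$p.value, stats::pchisq(chi2, 2, lower.tail = FALSE),
               tolerance = 1e-12)

  expect_equal(friedman_test(m + 100)$statistic, got$statistic)
  expect_error(friedman_test(m[, 1, drop = FALSE]), "at least 2")
  m[2, 2] <- NA
  expect_error(friedman_test(m), "missing cells")
})

test_that("percent difference follows the paired formula", {
  expect_equal(percent_difference(0.64, 0.72), 12.5)
  expect_equal(percent_difference(c(1, 2), c(1, 2)), c(0, 0))
  expect_error(percent_difference(0, 1), "undefined")
})

fake_cv <- function(model, aucs, ids = paste0("P", seq_along(aucs))) {
  structure(list(model = model,
                 per_patient = data.frame(patient_id = ids, auc = aucs,
                                          threshold = 0.5, sensitivity = 0.5,
                                          specificity = 0.5),
                 summary = data.frame(metric = "auc", mean = mean(aucs),
                                      sd = sd(aucs))),
            class = "cv_result")
}

test_that("model comparison gatekeeps pairwise tests behind the Friedman test", {
  base <- withr::with_seed(3, runif(8, 0.55, 0.7))
  cvs <- list(in_gross = fake_cv("in_gross", base),
              PS = fake_cv("PS", base + 0.08),
              SUV = fake_cv("SUV", base + 0.1))
  res <- compare_models(cvs, baselines = "in_gross")
  expect_true(res$gate_passed)
  expect_equal(nrow(res$comparisons), 2)
  ps <- res$comparisons[res$comparisons$model == "PS", ]
  expect_equal(ps$mean_pct_diff, mean((base + 0.08 - base) / base * 100))
  expect_true(all(res$comparisons$p.value < 0.05))

  # no signal: gate closed, no pairwise tests
  cvs2 <- list(in_gross = fake_cv("in_gross", base),
               PS = fake_cv("PS", base[sample(8)]),
               SUV = fake_cv("SUV", base[sample(8, replace = FALSE)]))
  res2 <- compare_models(cvs2, baselines = "in_gross")
  if (!res2$gate_passed) expect_equal(nrow(res2$comparisons), 0)

  # identical models surface as "no difference" rather than an error
  cvs3 <- list(in_gross = fake_cv("in_gross", base),
               PS = fake_cv("PS", base + 0.1),
               COPY = fake_cv("COPY", base))
  res3 <- compare_models(cvs3, baselines = "in_gross")
  if (res3$gate_passed) {
    copy <- res3$comparisons[res3$comparisons$model == "COPY", ]
    expect_identical(copy$note, "no difference")
    expect_equal(copy$mean_pct_diff, 0)
  }

  # mismatched patient sets are an error
  cvs4 <- list(in_gross = fake_cv("in_gross", base),
               PS = fake_cv("PS", base, ids = paste0("Q", 1:8)))
  expect_error(compare_models(cvs4, baselines = "in_gross"),
               "patient sets differ")
})
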