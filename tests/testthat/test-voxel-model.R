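test_that("a binary covariate fit recovers the closed-form 2x2 log odds ratio", {
  # x=1: 20 events / 10 non-events; x=0: 5 / 15 -> beta = ln((20*15)/(10*5))
  tab <- two_by_two_table(20, 10, 5, 15)
  fit <- fit_logistic_irls(tab, model_spec("in_gross"))
  b <- fit$terms$beta[fit$terms$term == "in_gross"]
  expect_equal(b, log(6), tolerance = 1e-8)
  expect_equal(fit$terms$beta[1], log(5 / 15), tolerance = 1e-8)
  expect_true(fit$converged)
  expect_equal(fit$df, 50 - 2)
})

test_that("IRLS agrees with stats::glm on coefficients and standard errors", {
  tab <- toy_table(n = 800)
  fit <- fit_logistic_irls(tab, model_spec(c("BF", "PS", "SUV_BF")))
  ref <- stats::glm(in_progression ~ BF + PS + SUV_BF, binomial(), data = tab)
  expect_equal(fit$terms$beta, unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$terms$se, unname(sqrt(diag(vcov(ref)))), tolerance = 1e-4)
})

test_that("null covariates yield near-zero slopes at large n", {
  tab <- toy_table(n = 4000, beta = c(-0.5, 0))
  fit <- fit_logistic_irls(tab, model_spec("BF"))
  r <- fit$terms[fit$terms$term == "BF", ]
  expect_lt(abs(r$beta), 3 * r$se)
})

test_that("degenerate inputs are rejected with informative errors", {
  tab <- toy_table(n = 100)
  tab$in_progression <- 1L
  expect_error(fit_logistic_irls(tab, model_spec("BF")), "single class")

  tab2 <- toy_table(n = 100)
  tab2$BV <- 2 * tab2$BF          # exact collinearity
  expect_error(fit_logistic_irls(tab2, model_spec(c("BF", "BV"))),
               "collinear.*BV")

  # perfectly separated outcome -> quasi-separation warning, non-converged
  tab3 <- toy_table(n = 100)
  tab3$in_progression <- as.integer(tab3$BF > stats::median(tab3$BF))
  expect_warning(fit3 <- fit_logistic_irls(tab3, model_spec("BF")),
                 "quasi-separation")
  expect_false(fit3$converged)
})

test_that("model specifications are validated", {
  expect_error(model_spec(character(0)), "at least one")
  expect_error(model_spec(c("PS", "PS")), "unique")
  expect_error(model_spec("T1"), "unknown covariate")
  specs <- default_model_specs()
  expect_length(specs, 9)
  expect_equal(sum(lengths(lapply(specs, `[[`, "covariates")) == 1), 7)
  expect_setequal(specs[["BV+PS+SUV_BF"]]$covariates, c("BV", "PS", "SUV_BF"))
  expect_setequal(specs[["BF+BV+PS+SUV"]]$covariates,
                  c("BF", "BV", "PS", "SUV"))
})

test_that("odds ratios, CIs and probability reporting follow the exp/expit identities", {
  fit <- logistic_fit(c("(Intercept)" = -2.41, PS = 0.41, SUV_BF = 2.63),
                      se = c(0.01, 0.005, 1.02))
  o <- odds_ratio(fit, "PS")
  expect_equal(o$or, exp(0.41))
  expect_equal(o$ci, exp(0.41 + c(-1, 1) * 1.959964 * 0.005))
  expect_equal(odds_ratio(logistic_fit(c("(Intercept)" = 0, PS = 0)),
                          "PS")$or, 1)
  expect_error(odds_ratio(fit, "BV"), "unknown term")

  expect_equal(coefficient_probability(fit, "(Intercept)"),
               100 * plogis(-2.41))
  expect_equal(coefficient_probability(fit, "PS"), 100 * plogis(-2.41 + 0.41))
  expect_equal(coefficient_probability(logistic_fit(c("(Intercept)" = 0,
                                                      PS = 0)), "PS"), 50)
  # monotone increasing in the term coefficient
  probs <- vapply(seq(-1, 1, 0.25), function(b)
    coefficient_probability(logistic_fit(c("(Intercept)" = -1, PS = b)), "PS"),
    numeric(1))
  expect_true(all(diff(probs) > 0))
})

test_that("delta scaling is consistent with the per-unit quantities", {
  fit <- logistic_fit(c("(Intercept)" = -2.41, SUV_BF = 2.63))
  s0 <- scaled_odds(fit, "SUV_BF", 0)
  expect_equal(s0$or, 1)
  expect_equal(s0$probability_pct, coefficient_probability(fit, "(Intercept)"))
  s1 <- scaled_odds(fit, "SUV_BF", 1)
  expect_equal(s1$or, odds_ratio(fit, "SUV_BF")$or)
  expect_equal(s1$probability_pct, coefficient_probability(fit, "SUV_BF"))
  expect_error(scaled_odds(fit, "SUV_BF", Inf), "finite")
})

test_that("duplicating every record leaves beta unchanged and shrinks SE by sqrt(2)", {
  tab <- toy_table(n = 500)
  fit1 <- fit_logistic_irls(tab, model_spec("PS"))
  fit2 <- fit_logistic_irls(rbind(tab, tab), model_spec("PS"))
  expect_equal(fit2$terms$beta, fit1$terms$beta, tolerance = 1e-7)
  expect_equal(fit2$terms$se, fit1$terms$se / sqrt(2), tolerance = 1e-6)
})

test_that("SUV computation: Du Bois BSA, zero activity, dose proportionality", {
  expect_equal(round(bsa_dubois(70, 170), 3), 1.810)
  expect_error(bsa_dubois(-1, 170), "positive")

  act <- voxel_grid(array(c(0, 5, 10), c(3, 1)), c(1, 1))
  expect_true(all(compute_suv(array(0, c(3, 3)), 385, 70, 170) == 0))
  s1 <- compute_suv(act, 385, 70, 170)
  s2 <- compute_suv(act, 770, 70, 170)
  expect_equal(as.vector(s1), 2 * as.vector(s2))
  expect_equal(s1[2, 1], 5 * bsa_dubois(70, 170) / 385)
  expect_error(compute_suv(act, 0, 70, 170), "positive")
})

test_that("SUV:BF ratio honours the BF floor and is scale-covariant", {
  suv <- voxel_grid(array(2, c(2, 2)), c(1, 1))
  bf <- voxel_grid(array(c(40, 0, 0.5, 10), c(2, 2)), c(1, 1))
  r <- compute_suv_bf_ratio(suv, bf, bf_floor = 1)
  expect_equal(r[1, 1], 0.05)
  expect_true(is.na(r[2, 1]))     # BF 0 -> missing, never Inf
  expect_true(is.na(r[1, 2]))     # below floor -> missing
  expect_equal(r[2, 2], 0.2)
  r2 <- compute_suv_bf_ratio(suv, voxel_grid(3 * bf, c(1, 1)), bf_floor = 1)
  expect_equal(r2[2, 2], r[2, 2] / 3)
  expect_error(compute_suv_bf_ratio(suv, voxel_grid(-bf, c(1, 1))), "negative")
})
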