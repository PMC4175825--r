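# Pooled voxel-wise logistic regression and derived reporting quantities.

Z975 <- 1.959964  # two-sided 95% normal quantile

ALLOWED_COVARIATES <- c("in_gross", "in_enhancing",
                        "BF", "BV", "PS", "SUV", "SUV_BF")

#' Define a logistic model specification
#'
#' @param covariates character vector drawn from `in_gross`, `in_enhancing`,
#'   `BF`, `BV`, `PS`, `SUV`, `SUV_BF`.  An intercept is always included.
#' @param name model label; defaults to the covariates joined by `+`.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(covariates, name = paste(covariates, collapse = "+")) {
  covariates <- as.character(covariates)
  if (length(covariates) == 0) stop("model must have at least one covariate")
  if (anyDuplicated(covariates)) stop("covariates must be unique")
  bad <- setdiff(covariates, ALLOWED_COVARIATES)
  if (length(bad)) stop("unknown covariate(s): ", paste(bad, collapse = ", "))
  structure(list(name = name, covariates = covariates), class = "model_spec")
}

#' The nine model specifications evaluated by cross-validation
#'
#' Seven single-variable models (pre-RT gross tumour, end-of-RT enhancing
#' lesion, BF, BV, PS, SUV, SUV:BF) and two multivariate models
#' (BV + PS + SUV:BF and BF + BV + PS + SUV).
#'
#' @return named list of `model_spec` objects.
#' @export
default_model_specs <- function() {
  singles <- c("in_gross", "in_enhancing", "BF", "BV", "PS", "SUV", "SUV_BF")
  specs <- c(lapply(singles, model_spec),
             list(model_spec(c("BV", "PS", "SUV_BF")),
                  model_spec(c("BF", "BV", "PS", "SUV"))))
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

#' Construct a logistic fit object from coefficients
#'
#' Used both by [fit_logistic_irls()] and to wrap externally reported
#' coefficients (e.g. a published regression table) so the odds-ratio /
#' probability reporting helpers can be applied to them.
#'
#' @param beta named coefficient vector (log-odds); the intercept must be the
#'   first element, named `(Intercept)`.
#' @param se standard errors (same order), NA when unknown.
#' @param n number of records behind the fit (NA when unknown).
#' @param converged,iterations IRLS convergence metadata.
#' @return object of class `logistic_fit` with a per-term table holding
#'   `beta`, `se`, the odds ratio `exp(beta)` with Wald 95% CI, and the
#'   probability column `100 * expit(beta0 + beta)` (for the intercept row,
#'   `100 * expit(beta0)`).
#' @export
logistic_fit <- function(beta, se = rep(NA_real_, length(beta)), n = NA_integer_,
                         converged = NA, iterations = NA_integer_) {
  if (is.null(names(beta)) || names(beta)[1] != "(Intercept)")
    stop("beta must be named with '(Intercept)' first")
  nm <- names(beta)
  beta <- as.numeric(beta)
  se <- as.numeric(se)
  if (length(se) != length(beta)) stop("se must match beta in length")
  names(beta) <- nm
  b0 <- beta[1]
  or <- exp(beta)
  lo <- exp(beta - Z975 * se)
  hi <- exp(beta + Z975 * se)
  prob <- 100 * expit(ifelse(seq_along(beta) == 1, b0, b0 + beta))
  terms <- data.frame(term = names(beta), beta = beta, se = as.numeric(se),
                      odds_ratio = or, ci_low = lo, ci_high = hi,
                      probability_pct = prob, row.names = NULL,
                      stringsAsFactors = FALSE)
  structure(list(terms = terms, n = n, df = n - length(beta),
                 converged = converged, iterations = iterations),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, digits = 3, ...) {
  cat("<logistic_fit>  n =", x$n, " df =", x$df,
      " converged =", x$converged, "(", x$iterations, "iterations )\n")
  tab <- x$terms
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], signif, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Fit a pooled voxel-wise logistic regression by IRLS
#'
#' Maximum-likelihood logistic regression by iteratively reweighted least
#' squares.  Voxels from all patients are pooled into one fit (no random
#' effects).  Convergence when the largest coefficient update falls below
#' `tol`; standard errors from the inverse observed information; Wald 95%
#' confidence intervals `exp(beta +/- 1.959964 * se)` on the odds-ratio
#' scale.  Covariates enter in raw physiological units.
#'
#' @param table a `voxel_table` (or data.frame with the same columns).
#' @param spec a `model_spec`.
#' @param tol convergence tolerance on `max |delta beta|` (default 1e-8).
#' @param max_iter iteration cap (default 100).
#' @return a `logistic_fit`.  Quasi-separation (diverging coefficients) is
#'   reported as a warning with `converged = FALSE`.
#' @export
fit_logistic_irls <- function(table, spec, tol = 1e-8, max_iter = 100) {
  if (!inherits(spec, "model_spec")) spec <- model_spec(spec)
  y <- table$in_progression
  if (is.null(y)) stop("table has no in_progression column")
  y <- as.numeric(y)
  if (length(unique(y)) < 2)
    stop("outcome has a single class; logistic fit is undefined")
  X <- cbind("(Intercept)" = 1,
             as.matrix(as.data.frame(table)[spec$covariates]))
  if (any(!is.finite(X))) stop("covariates must be finite")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("collinear covariates: ", paste(dep, collapse = ", "),
         " linearly dependent on the others")
  }
  p <- ncol(X)
  beta <- rep(0, p)
  converged <- FALSE
  separated <- FALSE
  iter <- 0
  # scale-invariant divergence check: a slope spanning > 30 log-odds per
  # covariate SD (or a mean linear predictor beyond +/-30) means the MLE is
  # escaping to infinity (quasi-separation)
  col_sd <- c(0, apply(X[, -1, drop = FALSE], 2, stats::sd))
  repeat {
    iter <- iter + 1
    eta <- drop(X %*% beta)
    mu <- expit(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    info <- crossprod(X, X * w)
    delta <- solve(info, crossprod(X, y - mu))
    beta <- beta + drop(delta)
    if (any(!is.finite(beta)) || any(abs(beta * col_sd) > 30) ||
        abs(mean(X %*% beta)) > 30) {
      separated <- TRUE
      break
    }
    if (max(abs(delta)) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  if (separated)
    warning("quasi-separation detected (diverging coefficients); ",
            "fit flagged as non-converged")
  eta <- drop(X %*% beta)
  w <- pmax(expit(eta) * (1 - expit(eta)), 1e-10)
  se <- sqrt(diag(solve(crossprod(X, X * w))))
  names(beta) <- colnames(X)
  logistic_fit(beta, se = se, n = nrow(X),
               converged = converged && !separated, iterations = iter)
}

term_row <- function(fit, term) {
  i <- match(term, fit$terms$term)
  if (is.na(i)) stop("unknown term: ", term)
  fit$terms[i, ]
}

#' Odds ratio and Wald 95% CI for a fitted term
#'
#' @param fit a `logistic_fit`.
#' @param term covariate name.
#' @return list with `or = exp(beta)` and `ci = exp(beta +/- 1.959964 * se)`.
#' @export
odds_ratio <- function(fit, term) {
  r <- term_row(fit, term)
  list(or = r$odds_ratio, ci = c(r$ci_low, r$ci_high))
}

#' Per-unit progression probability for a fitted term
#'
#' The probability column of the regression report:
#' `100 * expit(beta0 + beta_term)` for a covariate row and
#' `100 * expit(beta0)` for the intercept row — the predicted progression
#' probability at one unit of the covariate with all others at zero.
#'
#' @inheritParams odds_ratio
#' @return probability in percent.
#' @export
coefficient_probability <- function(fit, term) {
  term_row(fit, term)$probability_pct
}

#' Odds ratio and probability for a rescaled covariate increment
#'
#' Reports the effect of a `delta`-unit increase of `term`:
#' `OR = exp(beta * delta)` and probability
#' `100 * expit(beta0 + beta * delta)` percent.
#'
#' @inheritParams odds_ratio
#' @param delta covariate increment (e.g. 0.01 for SUV:BF).
#' @return list with `or` and `probability_pct`.
#' @export
scaled_odds <- function(fit, term, delta) {
  if (!is.finite(delta)) stop("delta must be finite")
  b0 <- fit$terms$beta[1]
  b <- term_row(fit, term)$beta
  list(or = exp(b * delta), probability_pct = 100 * expit(b0 + b * delta))
}

#' Predict progression probabilities for voxel records
#'
#' @param object a `logistic_fit` produced with the covariates present in
#'   `newdata`.
#' @param newdata a `voxel_table` or data.frame.
#' @param ... unused.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
predict.logistic_fit <- function(object, newdata, ...) {
  covs <- setdiff(object$terms$term, "(Intercept)")
  X <- cbind(1, as.matrix(as.data.frame(newdata)[covs]))
  expit(drop(X %*% object$terms$beta))
}

#' Du Bois body surface area
#'
#' `BSA (m^2) = 0.007184 * weight^0.425 * height^0.725` with weight in kg and
#' height in cm.
#'
#' @param weight_kg body weight in kg.
#' @param height_cm height in cm.
#' @return body surface area in m^2.
#' @export
bsa_dubois <- function(weight_kg, height_cm) {
  if (any(weight_kg <= 0) || any(height_cm <= 0))
    stop("weight and height must be positive")
  0.007184 * weight_kg^0.425 * height_cm^0.725
}

#' Body-surface-area normalised SUV map
#'
#' `SUV_BSA = activity * BSA / injected dose`, with tissue activity in
#' kBq/mL, the injected dose in MBq and BSA (m^2) from [bsa_dubois()].
#'
#' @param activity_map tracer concentration map in kBq/mL.
#' @param injected_dose_mbq injected activity in MBq.
#' @param weight_kg,height_cm patient anthropometrics.
#' @return SUV map (same grid).
#' @export
compute_suv <- function(activity_map, injected_dose_mbq, weight_kg,
                        height_cm) {
  if (injected_dose_mbq <= 0) stop("injected dose must be positive")
  bsa <- bsa_dubois(weight_kg, height_cm)
  out <- activity_map * bsa / injected_dose_mbq
  if (!is.null(attr(activity_map, "spacing")))
    out <- voxel_grid(out, grid_spacing(activity_map))
  out
}

#' Metabolism-to-flow ratio map (SUV:BF)
#'
#' SUV divided by BF where BF is at or above `bf_floor`; flagged missing
#' (NA) below the floor so downstream table assembly drops those voxels
#' rather than producing unstable ratios.
#'
#' @param suv_map,bf_map congruent grids.
#' @param bf_floor minimum BF (mL/min per 100 g) for a defined ratio;
#'   default 1.
#' @return ratio map with NA below the floor.
#' @export
compute_suv_bf_ratio <- function(suv_map, bf_map, bf_floor = 1) {
  stopifnot_congruent(suv_map, bf_map, "SUV and BF maps")
  if (bf_floor <= 0) stop("bf_floor must be positive")
  if (any(bf_map[is.finite(bf_map)] < -1e-9)) stop("BF map has negative values")
  out <- array(NA_real_, dim(bf_map))
  ok <- is.finite(bf_map) & bf_map >= bf_floor & is.finite(suv_map)
  out[ok] <- suv_map[ok] / bf_map[ok]
  if (!is.null(attr(suv_map, "spacing")))
    out <- voxel_grid(out, grid_spacing(suv_map))
  out
}
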