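# Nonparametric cohort-level comparisons: exact Wilcoxon signed-rank,
# Friedman test, and paired percent-difference summaries of per-patient AUCs.

#' Wilcoxon signed-rank test for paired samples
#'
#' Signed ranks on |differences| with average ranks for ties; zero
#' differences are dropped.  For n <= `exact_n_max` remaining pairs the
#' two-sided p-value is exact, from the full distribution of the positive-rank
#' sum over all 2^n sign assignments (computed by convolution, so ties are
#' handled exactly); above that a normal approximation with tie correction is
#' used.
#'
#' @param x,y equal-length paired samples.
#' @param exact_n_max largest n for the exact distribution (default 15).
#' @return list with `statistic` (W+, the positive-rank sum), `p.value`
#'   (two-sided), `n` (pairs after dropping zeros) and `exact` flag.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_n_max = 15) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("degenerate pairing: all differences are zero")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_n_max) {
    # distribution of W+ on the half-integer rank grid (x2 -> integers)
    r2 <- as.integer(round(2 * r))
    f <- 1
    for (ri in r2) {
      g <- c(f, rep(0, ri))
      g[(ri + 1):(ri + length(f))] <- g[(ri + 1):(ri + length(f))] + f
      f <- g
    }
    f <- f / sum(f)
    w2 <- as.integer(round(2 * W))
    support <- seq_along(f) - 1L
    p <- 2 * min(sum(f[support <= w2]), sum(f[support >= w2]))
    p <- min(1, p)
    list(statistic = W, p.value = p, n = n, exact = TRUE)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu) / sqrt(sig2)
    list(statistic = W, p.value = 2 * stats::pnorm(-abs(z)), n = n,
         exact = FALSE)
  }
}

#' Friedman test across models (within-patient ranks)
#'
#' Tie-corrected chi-squared statistic on within-patient average ranks, with
#' k - 1 degrees of freedom (delegates to [stats::friedman.test()]).  When
#' every patient's values are fully tied the statistic is 0 and p = 1.
#'
#' @param values numeric matrix, patients in rows, models in columns; no
#'   missing cells.
#' @return list with `statistic`, `df`, `p.value`.
#' @export
friedman_test <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) < 2 || ncol(values) < 2)
    stop("need at least 2 patients and 2 models")
  if (any(!is.finite(values))) stop("missing cells in the model x patient matrix")
  k <- ncol(values)
  all_tied <- all(apply(values, 1, function(r) length(unique(r)) == 1))
  if (all_tied)
    return(list(statistic = 0, df = k - 1, p.value = 1))
  ft <- stats::friedman.test(values)
  list(statistic = unname(ft$statistic), df = unname(ft$parameter),
       p.value = ft$p.value)
}

#' Percent difference of paired model summaries
#'
#' `(m2 - m1) / m1 * 100` per patient.
#'
#' @param m1 baseline values (non-zero).
#' @param m2 comparison values.
#' @return percent differences.
#' @export
percent_difference <- function(m1, m2) {
  if (length(m1) != length(m2)) stop("paired values must have equal length")
  if (any(m1 == 0)) stop("percent difference undefined: baseline value is 0")
  (m2 - m1) / m1 * 100
}

#' Compare cross-validated models against baselines
#'
#' Gatekept nonparametric comparison of per-patient AUCs: a Friedman test
#' across all models first; only when its p-value is below `alpha` are
#' pairwise Wilcoxon signed-rank tests of each non-baseline model against
#' each baseline performed.  Pairwise p-values are not multiplicity-corrected
#' (noted in the output).  Percent differences are per-patient
#' `(model - baseline) / baseline * 100`, summarised as mean +/- SD.
#'
#' @param cv_results named list of `cv_result` objects (one per model),
#'   all evaluated on the identical patient set.
#' @param baselines names of the baseline models within `cv_results`
#'   (default the pre-RT gross tumour and end-of-RT enhancing lesion models).
#' @param alpha gate level for the Friedman test (default 0.05).
#' @return list with `friedman`, `gate_passed`, `comparisons` data.frame
#'   (`model`, `baseline`, `mean_pct_diff`, `sd_pct_diff`, `W`, `p.value`,
#'   `note`) and `auc` (patients x models matrix).
#' @export
compare_models <- function(cv_results,
                           baselines = intersect(c("in_gross", "in_enhancing"),
                                                 names(cv_results)),
                           alpha = 0.05) {
  if (is.null(names(cv_results)))
    names(cv_results) <- vapply(cv_results, `[[`, "", "model")
  ids <- lapply(cv_results, function(cv) sort(cv$per_patient$patient_id))
  for (i in seq_along(ids))
    if (!identical(ids[[i]], ids[[1]]))
      stop("patient sets differ between models ", names(cv_results)[1],
           " and ", names(cv_results)[i])
  pat <- ids[[1]]
  aucm <- vapply(cv_results, function(cv) {
    pp <- cv$per_patient
    pp$auc[match(pat, pp$patient_id)]
  }, numeric(length(pat)))
  rownames(aucm) <- pat
  fr <- if (ncol(aucm) >= 2) friedman_test(aucm) else
    list(statistic = NA_real_, df = NA_real_, p.value = NA_real_)
  gate <- is.finite(fr$p.value) && fr$p.value < alpha
  comps <- list()
  bad_base <- setdiff(baselines, colnames(aucm))
  if (length(bad_base))
    stop("baseline model(s) not in cv_results: ", paste(bad_base, collapse = ", "))
  if (gate) {
    for (b in baselines) for (m in setdiff(colnames(aucm), baselines)) {
      pd <- percent_difference(aucm[, b], aucm[, m])
      wt <- tryCatch(wilcoxon_signed_rank(aucm[, m], aucm[, b]),
                     error = function(e) NULL)
      comps[[length(comps) + 1]] <- data.frame(
        model = m, baseline = b,
        mean_pct_diff = mean(pd), sd_pct_diff = stats::sd(pd),
        W = if (is.null(wt)) NA_real_ else wt$statistic,
        p.value = if (is.null(wt)) NA_real_ else wt$p.value,
        note = if (is.null(wt)) "no difference"
               else "uncorrected pairwise p-value",
        stringsAsFactors = FALSE)
    }
  }
  comparisons <- if (length(comps)) do.call(rbind, comps) else
    data.frame(model = character(), baseline = character(),
               mean_pct_diff = numeric(), sd_pct_diff = numeric(),
               W = numeric(), p.value = numeric(), note = character(),
               stringsAsFactors = FALSE)
  list(friedman = fr, gate_passed = gate, comparisons = comparisons,
       auc = aucm)
}
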