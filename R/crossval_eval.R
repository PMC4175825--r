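# Leave-one-patient-out cross-validation, ROC / AUC / Youden evaluation.

#' ROC curve over all distinct predicted probabilities
#'
#' A voxel is called positive when its predicted probability is at or above
#' the threshold.  Thresholds are the distinct predicted values plus -Inf and
#' +Inf sentinels, ordered decreasing, so the curve runs from (0, 0) to
#' (1, 1) in false-positive-rate / sensitivity space.
#'
#' @param probabilities numeric predictions.
#' @param labels binary outcomes (0/1 or logical).
#' @return data.frame (class `roc_points`) with columns `threshold`,
#'   `sensitivity`, `specificity`.
#' @export
roc_curve <- function(probabilities, labels) {
  y <- as.integer(as.logical(labels))
  if (length(probabilities) != length(y))
    stop("probabilities and labels differ in length")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present")
  thr <- c(Inf, sort(unique(probabilities), decreasing = TRUE), -Inf)
  ord <- order(probabilities, decreasing = TRUE)
  ps <- probabilities[ord]; ys <- y[ord]
  # cumulative positives/negatives at each distinct threshold
  last <- c(which(diff(ps) != 0), length(ps))
  tp <- c(0, cumsum(ys)[last], n1)
  fp <- c(0, cumsum(1 - ys)[last], n0)
  out <- data.frame(threshold = thr,
                    sensitivity = tp / n1,
                    specificity = 1 - fp / n0)
  class(out) <- c("roc_points", "data.frame")
  out
}

#' Area under the ROC curve (trapezoidal rule)
#'
#' Equivalent to the Mann-Whitney concordance probability with tied pairs
#' counted as half-concordant.
#'
#' @param roc a `roc_points` data.frame from [roc_curve()].
#' @return AUC in \[0, 1\].
#' @export
auc <- function(roc) {
  fpr <- 1 - roc$specificity
  tpr <- roc$sensitivity
  o <- order(fpr, tpr)
  sum(diff(fpr[o]) * (tpr[o][-1] + tpr[o][-length(tpr)]) / 2)
}

#' Youden-optimal operating point
#'
#' Threshold maximising J = sensitivity + specificity - 1 over all distinct
#' predicted probabilities (a superset of any fixed percent grid).  Ties are
#' broken toward the lowest threshold, favouring sensitivity.
#'
#' @param roc a `roc_points` data.frame.
#' @return list with `threshold`, `sensitivity`, `specificity`, `J`.
#' @export
youden_threshold <- function(roc) {
  if (nrow(roc) == 0) stop("empty ROC")
  J <- roc$sensitivity + roc$specificity - 1
  best <- which(J >= max(J) - 1e-12)
  i <- best[which.min(roc$threshold[best])]
  list(threshold = roc$threshold[i], sensitivity = roc$sensitivity[i],
       specificity = roc$specificity[i], J = J[i])
}

split_by_patient <- function(tables) {
  if (inherits(tables, "voxel_table") || is.data.frame(tables))
    tables <- split(as.data.frame(tables), tables$patient_id)
  if (length(tables) < 2) stop("leave-one-out needs at least 2 patients")
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    names(tables) <- vapply(tables, function(t) as.character(t$patient_id[1]), "")
  tables
}

#' Leave-one-patient-out cross-validation
#'
#' For each patient the model is fitted on the pooled voxels of all other
#' patients and applied to the held-out patient's voxels; ROC, AUC and the
#' Youden operating point are computed per held-out patient, and cohort
#' summaries are unweighted mean +/- SD across patients.
#'
#' @param tables either a pooled `voxel_table` (split on `patient_id`) or a
#'   named list of per-patient tables.
#' @param spec a `model_spec` (or covariate vector).
#' @return object of class `cv_result`: `model`, `per_patient` data.frame
#'   (`patient_id`, `auc`, `threshold`, `sensitivity`, `specificity`),
#'   `probabilities` (named list of held-out predictions), `fits` (named list
#'   of fold fits) and `summary` (mean/sd per metric).
#' @export
loocv <- function(tables, spec) {
  if (!inherits(spec, "model_spec")) spec <- model_spec(spec)
  tables <- split_by_patient(tables)
  ids <- names(tables)
  fits <- probs <- list()
  rows <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    train <- do.call(rbind, lapply(tables[-k], as.data.frame))
    if (length(unique(train$in_progression)) < 2)
      stop("training fold for held-out patient ", ids[k],
           " has a single outcome class")
    fit <- fit_logistic_irls(train, spec)
    held <- as.data.frame(tables[[k]])
    pr <- predict(fit, held)
    roc <- roc_curve(pr, held$in_progression)
    yj <- youden_threshold(roc)
    fits[[ids[k]]] <- fit
    probs[[ids[k]]] <- pr
    rows[[k]] <- data.frame(patient_id = ids[k], auc = auc(roc),
                            threshold = yj$threshold,
                            sensitivity = yj$sensitivity,
                            specificity = yj$specificity,
                            stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, rows)
  summ <- data.frame(
    metric = c("auc", "sensitivity", "specificity"),
    mean = c(mean(per$auc), mean(per$sensitivity), mean(per$specificity)),
    sd = c(stats::sd(per$auc), stats::sd(per$sensitivity),
           stats::sd(per$specificity)))
  structure(list(model = spec$name, spec = spec, per_patient = per,
                 probabilities = probs, fits = fits, summary = summ),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> model:", x$model, "-", nrow(x$per_patient), "patients\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s %.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(x)
}

#' Rebuild a probability map on the acquisition grid
#'
#' Places per-voxel predictions back at their 0-based (row, col, section)
#' coordinates; everything else is NA.
#'
#' @param probabilities numeric vector, one per row of `table`.
#' @param table the `voxel_table` the predictions correspond to.
#' @param grid_dim grid dimensions, e.g. `c(170, 170, 8)`.
#' @param spacing_mm voxel spacing.
#' @return numeric grid with spacing metadata.
#' @export
probability_map <- function(probabilities, table, grid_dim, spacing_mm) {
  if (length(probabilities) != nrow(table))
    stop("one probability per table row required")
  out <- array(NA_real_, grid_dim)
  idx <- cbind(table$row + 1L, table$col + 1L, table$section + 1L)
  out[idx] <- probabilities
  voxel_grid(out, spacing_mm)
}
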