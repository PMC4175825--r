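# End-to-end pipeline: generate (or load) -> preprocess -> fit -> loocv ->
# compare, with every artefact written to a run directory.

#' Pipeline configuration
#'
#' Either `manifest` (a path to a cohort manifest CSV of real, co-registered
#' data) or `synthetic` (a [synthetic_config()]) must be supplied; the
#' default is the default synthetic cohort.
#'
#' @param out_dir run output directory.
#' @param synthetic a `synthetic_config`, or NULL when running from a
#'   manifest.
#' @param manifest path to a cohort manifest CSV, or NULL.
#' @param margin_cm bounding-box margin.
#' @param bf_floor BF floor for SUV:BF.
#' @param models named list of `model_spec`s (default the nine standard
#'   models).
#' @param baselines baseline model names for [compare_models()].
#' @param write_maps write per-patient cross-validated probability maps as
#'   NIfTI (default FALSE).
#' @param seed run seed; overrides the synthetic config's seed so one value
#'   controls the whole run.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, synthetic = synthetic_config(),
                            manifest = NULL, margin_cm = 2, bf_floor = 1,
                            models = default_model_specs(),
                            baselines = c("in_gross", "in_enhancing"),
                            write_maps = FALSE, seed = 1) {
  if (is.null(synthetic) && is.null(manifest))
    stop("pipeline config needs either a manifest or a synthetic block")
  if (!is.null(synthetic)) {
    stopifnot(inherits(synthetic, "synthetic_config"))
    synthetic$seed <- as.integer(seed)
    validate_synthetic_config(synthetic)
  }
  if (!is.null(manifest) && !file.exists(manifest))
    stop("manifest not found: ", manifest)
  if (margin_cm < 0) stop("margin_cm must be non-negative")
  if (bf_floor <= 0) stop("bf_floor must be positive")
  for (m in models) stopifnot(inherits(m, "model_spec"))
  if (is.null(names(models)))
    names(models) <- vapply(models, `[[`, "", "name")
  structure(list(out_dir = out_dir, synthetic = synthetic,
                 manifest = manifest, margin_cm = margin_cm,
                 bf_floor = bf_floor, models = models,
                 baselines = baselines, write_maps = write_maps,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised keys: `out_dir`, `manifest`, `margin_cm`, `bf_floor`, `seed`,
#' `write_maps`, `models` (list of covariate vectors), `baselines`, and a
#' `synthetic` block whose keys are passed to [synthetic_config()].
#'
#' @param path YAML file.
#' @param out_dir overrides the file's `out_dir` when given.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  args <- list()
  args$out_dir <- out_dir %||% y$out_dir
  if (is.null(args$out_dir)) stop("config must set out_dir")
  if (!is.null(y$manifest)) {
    args$manifest <- y$manifest
    args$synthetic <- NULL
  }
  if (!is.null(y$synthetic)) {
    sargs <- y$synthetic
    if (!is.null(sargs$tissue_means))
      sargs$tissue_means <- do.call(rbind, sargs$tissue_means)
    args$synthetic <- do.call(synthetic_config, sargs)
  } else if (!is.null(y$manifest)) {
    args$synthetic <- NULL
  }
  for (k in c("margin_cm", "bf_floor", "seed", "write_maps", "baselines"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(y$models)) {
    args$models <- lapply(y$models, function(m) model_spec(unlist(m)))
    names(args$models) <- vapply(args$models, `[[`, "", "name")
  }
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
}

serialize_fit <- function(fit) {
  list(terms = fit$terms, n = fit$n, df = fit$df,
       converged = fit$converged, iterations = fit$iterations)
}

serialize_cv <- function(cv) {
  list(model = cv$model, per_patient = cv$per_patient, summary = cv$summary)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: cohort generation (or manifest load), voxel-table
#' preprocessing, pooled logistic fits per configured model,
#' leave-one-patient-out cross-validation per model, and the gatekept
#' Friedman / Wilcoxon model comparison.  Every artefact is written under
#' `config$out_dir` (cohort NIfTI + manifest, per-patient voxel tables,
#' fits.json, cv/<model>.json, comparison.csv, friedman.json) along with the
#' run configuration for provenance.  Outputs are pure functions of
#' (inputs, config, seed).
#'
#' @param config a `pipeline_config`.
#' @param quiet suppress progress messages.
#' @return run summary list: paths of artefacts, per-model CV summaries,
#'   comparison results.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[voxelprog] ", ...)

  prov <- list(margin_cm = config$margin_cm, bf_floor = config$bf_floor,
               seed = config$seed,
               models = lapply(config$models, `[[`, "covariates"),
               baselines = config$baselines,
               synthetic = if (!is.null(config$synthetic))
                 lapply(config$synthetic, function(x)
                   if (is.matrix(x)) apply(x, 1, as.list, simplify = FALSE)
                   else x),
               manifest = config$manifest)
  yaml::write_yaml(prov, file.path(out, "run_config.yaml"))

  # -- generate / load -----------------------------------------------------
  cohort <- stage("generate", {
    if (!is.null(config$manifest)) {
      man <- read_manifest(config$manifest)
      say("loading ", nrow(man), " patients from manifest")
      lapply(man$patient_id, function(id)
        load_patient(man, id, bf_floor = config$bf_floor))
    } else {
      say("generating synthetic cohort of ", config$synthetic$n_patients,
          " patients (seed ", config$seed, ")")
      coh <- generate_cohort(config$synthetic)
      write_cohort(coh, file.path(out, "cohort"))
      coh
    }
  })

  # -- preprocess ----------------------------------------------------------
  tables <- stage("preprocess", {
    dir.create(file.path(out, "tables"), showWarnings = FALSE)
    lapply(cohort, function(pt) {
      sp <- pt$maps$spacing
      bbox <- build_bounding_box(pt$masks$gross_tumour,
                                 pt$masks$progressive_tumour,
                                 margin_cm = config$margin_cm)
      analysis <- build_analysis_mask(bbox, pt$masks$exclusion)
      masks <- mask_set(list(gross_tumour = pt$masks$gross_tumour,
                             enhancing_lesion = pt$masks$enhancing_lesion,
                             progressive_tumour = pt$masks$progressive_tumour,
                             exclusion = pt$masks$exclusion,
                             bounding_box = bbox, analysis = analysis), sp)
      tab <- assemble_voxel_table(pt$maps, masks)
      write_voxel_table(tab, file.path(out, "tables",
                                       paste0(pt$maps$patient_id, ".csv")))
      tab
    })
  })
  pooled <- do.call(rbind, lapply(tables, as.data.frame))
  class(pooled) <- c("voxel_table", "data.frame")
  say("pooled voxel table: ", nrow(pooled), " voxels from ",
      length(tables), " patients")

  # -- pooled fits ---------------------------------------------------------
  fits <- stage("fit", lapply(config$models, function(spec)
    fit_logistic_irls(pooled, spec)))
  jsonlite::write_json(lapply(fits, serialize_fit),
                       file.path(out, "fits.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # -- leave-one-patient-out CV -------------------------------------------
  cvs <- stage("loocv", {
    dir.create(file.path(out, "cv"), showWarnings = FALSE)
    res <- list()
    for (nm in names(config$models)) {
      cv <- loocv(tables, config$models[[nm]])
      jsonlite::write_json(serialize_cv(cv),
                           file.path(out, "cv", paste0(gsub("[^A-Za-z0-9_]",
                                                            "_", nm), ".json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      if (config$write_maps && !is.null(config$synthetic)) {
        mdir <- file.path(out, "probmaps", gsub("[^A-Za-z0-9_]", "_", nm))
        dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
        for (i in seq_along(tables)) {
          id <- as.character(tables[[i]]$patient_id[1])
          pm <- probability_map(cv$probabilities[[id]], tables[[i]],
                                cohort[[i]]$maps$dim, cohort[[i]]$maps$spacing)
          write_probability_map(pm, file.path(mdir, paste0(id, ".nii.gz")))
        }
      }
      say("loocv ", nm, ": AUC ",
          sprintf("%.3f +/- %.3f", cv$summary$mean[1], cv$summary$sd[1]))
      res[[nm]] <- cv
    }
    res
  })

  # -- model comparison ----------------------------------------------------
  comparison <- stage("compare", {
    base <- intersect(config$baselines, names(cvs))
    cmp <- compare_models(cvs, baselines = base)
    jsonlite::write_json(cmp$friedman, file.path(out, "friedman.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(cmp$comparisons, file.path(out, "comparison.csv"),
                     row.names = FALSE)
    cmp
  })

  summary <- list(
    out_dir = out, n_patients = length(cohort), n_voxels = nrow(pooled),
    fits = fits, cv = cvs, comparison = comparison,
    artefacts = list(config = file.path(out, "run_config.yaml"),
                     tables = file.path(out, "tables"),
                     fits = file.path(out, "fits.json"),
                     cv = file.path(out, "cv"),
                     comparison = file.path(out, "comparison.csv")))
  say("run complete: ", out)
  invisible(summary)
}
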