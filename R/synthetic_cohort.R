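# Synthetic multiparametric cohort generator with known voxel-level ground
# truth, emulating co-registered CT-perfusion (BF, BV, PS) and FDG-PET (SUV)
# maps over eight 5-mm sections of a 25-cm field of view.

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study geometry: a 10-patient cohort of co-registered
#' 170 x 170 maps over eight 5-mm sections (25-cm in-plane field of view).
#' Tissue-class means are field-plausible values for grey matter, white
#' matter, gross tumour and the progressive-tumour region in
#' (BF mL/min per 100 g, BV mL/100 g, PS mL/min per 100 g, SUV unitless).
#' `true_beta` is the ground-truth voxel-level logistic model (intercept +
#' BF, BV, PS, SUV, SUV:BF) from which progression labels are drawn; its
#' default signs make progression odds increase with PS and SUV:BF and
#' decrease with BF, BV and SUV.
#'
#' @param n_patients cohort size (>= 2).
#' @param grid c(rows, cols, sections).
#' @param spacing_mm voxel size (in-plane, in-plane, section thickness), mm.
#' @param tissue_means 4 x 4 matrix, rows grey/white/gross/progressive,
#'   columns BF/BV/PS/SUV.
#' @param noise_sd per-parameter Gaussian measurement noise SD (BF, BV, PS,
#'   SUV units).
#' @param heterogeneity_sd per-parameter SD of the smooth within-class
#'   biological variation added to the true fields.
#' @param heterogeneity_fwhm_mm in-plane FWHM of that variation.
#' @param smoothing_fwhm_mm in-plane blur applied to the observed (noisy)
#'   maps; 0 disables.
#' @param true_beta named ground-truth coefficients
#'   (`(Intercept)`, `BF`, `BV`, `PS`, `SUV`, `SUV_BF`).
#' @param lesion_geometry list: `gross_axes_mm` (in-plane semi-axis range),
#'   `gross_z_mm` (through-plane semi-axis range), `prog_axes_mm`,
#'   `prog_offset_mm` (in-plane centre offset range between gross and
#'   progressive region), `centre_jitter_mm`, `enh_scale` (enhancing-lesion
#'   axis scale range relative to gross), `label_window_scale` (dilation of
#'   the progressive-region ellipsoid within which label draws are contoured
#'   into the progressive-tumour mask).
#' @param exclusion_geometry list: `ventricle_axes_mm`, `ventricle_offset_mm`,
#'   `vessel_radius_mm`, `vessel_offset_mm`, `cavity_scale`.
#' @param closing_radius_mm radius of the morphological closing that turns
#'   Bernoulli progression draws into a contiguous lesion.
#' @param bf_floor BF floor for the SUV:BF ratio.
#' @param margin_cm bounding-box margin used to pre-build the bounding-box /
#'   analysis masks.
#' @param seed master random seed; per-patient sub-seeds are derived from it.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_patients = 10,
    grid = c(170, 170, 8),
    spacing_mm = c(250 / 170, 250 / 170, 5),
    tissue_means = rbind(
      grey        = c(BF = 50, BV = 4.0, PS = 0.5, SUV = 1.6),
      white       = c(BF = 25, BV = 2.0, PS = 0.3, SUV = 0.8),
      gross       = c(BF = 40, BV = 3.5, PS = 3.0, SUV = 2.2),
      progressive = c(BF = 32, BV = 3.0, PS = 6.0, SUV = 2.4)),
    noise_sd = c(BF = 6, BV = 0.5, PS = 0.5, SUV = 0.2),
    heterogeneity_sd = c(BF = 4, BV = 0.4, PS = 0.5, SUV = 0.15),
    heterogeneity_fwhm_mm = 6,
    smoothing_fwhm_mm = 2,
    true_beta = c("(Intercept)" = -2.2, BF = -0.02, BV = -0.15,
                  PS = 0.9, SUV = -0.9, SUV_BF = 8),
    lesion_geometry = list(gross_axes_mm = c(10, 16), gross_z_mm = c(8, 14),
                           prog_axes_mm = c(8, 14), prog_z_mm = c(7, 12),
                           prog_offset_mm = c(4, 10),
                           centre_jitter_mm = 8, enh_scale = c(0.85, 1.15),
                           label_window_scale = 1.5),
    exclusion_geometry = list(ventricle_axes_mm = c(5, 12, 25),
                              ventricle_offset_mm = 14,
                              vessel_radius_mm = 1.6,
                              vessel_offset_mm = 32,
                              cavity_scale = 0.35),
    closing_radius_mm = 2,
    bf_floor = 1,
    margin_cm = 2,
    seed = 1) {
  cfg <- list(n_patients = as.integer(n_patients), grid = as.integer(grid),
              spacing_mm = as.numeric(spacing_mm),
              tissue_means = tissue_means, noise_sd = noise_sd,
              heterogeneity_sd = heterogeneity_sd,
              heterogeneity_fwhm_mm = heterogeneity_fwhm_mm,
              smoothing_fwhm_mm = smoothing_fwhm_mm, true_beta = true_beta,
              lesion_geometry = lesion_geometry,
              exclusion_geometry = exclusion_geometry,
              closing_radius_mm = closing_radius_mm, bf_floor = bf_floor,
              margin_cm = margin_cm, seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  if (cfg$n_patients < 2) stop("n_patients must be >= 2")
  if (length(cfg$grid) != 3 || any(cfg$grid[1:2] < 16) || cfg$grid[3] < 1)
    stop("grid must be (rows, cols, sections) with rows/cols >= 16, sections >= 1")
  if (any(cfg$spacing_mm <= 0)) stop("all spacing must be positive")
  if (!all(c("grey", "white", "gross", "progressive") %in%
           rownames(cfg$tissue_means)) ||
      !all(MAP_NAMES %in% colnames(cfg$tissue_means)))
    stop("tissue_means needs rows grey/white/gross/progressive and columns BF/BV/PS/SUV")
  if (any(cfg$noise_sd < 0) || any(cfg$heterogeneity_sd < 0))
    stop("noise/heterogeneity SDs must be non-negative")
  need_beta <- c("(Intercept)", MAP_NAMES, "SUV_BF")
  if (!identical(sort(names(cfg$true_beta)), sort(need_beta)))
    stop("true_beta must be named: ", paste(need_beta, collapse = ", "))
  lg <- cfg$lesion_geometry
  if (any(unlist(lg[c("gross_axes_mm", "gross_z_mm", "prog_axes_mm",
                      "prog_z_mm")]) <= 0))
    stop("lesion axes must be positive")
  fov <- cfg$grid[1:2] * cfg$spacing_mm[1:2]
  max_extent <- max(lg$gross_axes_mm, lg$prog_axes_mm) +
    lg$centre_jitter_mm + max(lg$prog_offset_mm)
  if (2 * max_extent > min(fov))
    stop("lesion does not fit in grid: reduce lesion axes or jitter")
  invisible(cfg)
}

# In-plane/3-D ellipsoid membership mask on the mm grid.
ellipsoid_mask <- function(grid, spacing, centre_mm, axes_mm) {
  ax <- function(i) (((seq_len(grid[i]) - 1) * spacing[i] - centre_mm[i]) /
                       axes_mm[i])^2
  u <- ax(1); v <- ax(2)
  w <- if (length(axes_mm) >= 3 && is.finite(axes_mm[3])) ax(3) else
    rep(0, grid[3])
  outer(outer(u, v, "+"), w, "+") <= 1
}

# Seeded smooth Gaussian field with target SD (in-plane smoothing).
smooth_noise_field <- function(grid, spacing, fwhm_mm, sd_target) {
  x <- array(stats::rnorm(prod(grid)), grid)
  if (sd_target == 0) return(array(0, grid))
  sigma_px <- fwhm_mm / 2.3548 / spacing[1]
  if (sigma_px > 0.05) x <- EBImage::gblur(x, sigma = sigma_px)
  x * (sd_target / stats::sd(x))
}

in_plane_blur <- function(x, spacing, fwhm_mm) {
  sigma_px <- fwhm_mm / 2.3548 / spacing[1]
  if (fwhm_mm <= 0 || sigma_px <= 0.05) return(x)
  array(EBImage::gblur(x, sigma = sigma_px), dim(x))
}

patient_subseeds <- function(config) {
  with_local_seed(config$seed,
                  sample.int(2147483646L, config$n_patients))
}

#' Generate one synthetic patient
#'
#' Builds tissue-class mean fields (grey/white background, gross-tumour and
#' progressive-region ellipsoids) plus smooth within-class heterogeneity (the
#' *true* fields), draws voxel progression labels from the ground-truth
#' logistic model applied to those true fields, closes the labels
#' morphologically into a contiguous progressive-tumour mask, and produces
#' observed maps as truth + Gaussian noise + in-plane smoothing.
#'
#' @param config a `synthetic_config`.
#' @param patient_index 1-based index, <= `n_patients`.
#' @return list with `maps` (a `param_maps`), `masks` (a `mask_set`, with
#'   bounding-box and analysis masks pre-built at `config$margin_cm`) and
#'   `truth` (list: `maps` — noiseless covariate fields including `SUV_BF`,
#'   `prob` — true progression probability, `labels` — raw Bernoulli draws
#'   before closing).
#' @export
generate_patient <- function(config, patient_index) {
  stopifnot(inherits(config, "synthetic_config"))
  if (patient_index < 1 || patient_index > config$n_patients)
    stop("patient_index must be in 1..n_patients")
  seed <- patient_subseeds(config)[patient_index]
  with_local_seed(seed, generate_patient_impl(config, patient_index))
}

generate_patient_impl <- function(config, patient_index) {
  g <- config$grid; sp <- config$spacing_mm
  fov <- g * sp
  centre0 <- fov / 2
  lg <- config$lesion_geometry
  eg <- config$exclusion_geometry

  # --- geometry ----------------------------------------------------------
  jit <- stats::runif(2, -lg$centre_jitter_mm, lg$centre_jitter_mm)
  gross_c <- c(centre0[1:2] + jit, centre0[3])
  gross_a <- c(stats::runif(2, lg$gross_axes_mm[1], lg$gross_axes_mm[2]),
               stats::runif(1, lg$gross_z_mm[1], lg$gross_z_mm[2]))
  ang <- stats::runif(1, 0, 2 * pi)
  off <- stats::runif(1, lg$prog_offset_mm[1], lg$prog_offset_mm[2])
  prog_c <- c(gross_c[1] + off * cos(ang), gross_c[2] + off * sin(ang),
              centre0[3])
  prog_a <- c(stats::runif(2, lg$prog_axes_mm[1], lg$prog_axes_mm[2]),
              stats::runif(1, lg$prog_z_mm[1], lg$prog_z_mm[2]))
  for (axd in 1:2) {
    if (gross_c[axd] - gross_a[axd] < 0 || gross_c[axd] + gross_a[axd] > fov[axd] ||
        prog_c[axd] - prog_a[axd] < 0 || prog_c[axd] + prog_a[axd] > fov[axd])
      stop("lesion does not fit in grid")
  }
  enh_c <- c(gross_c[1:2] + stats::runif(2, -3, 3), centre0[3])
  enh_a <- gross_a * stats::runif(1, lg$enh_scale[1], lg$enh_scale[2])

  gross <- ellipsoid_mask(g, sp, gross_c, gross_a)
  prog_region <- ellipsoid_mask(g, sp, prog_c, prog_a)
  enhancing <- ellipsoid_mask(g, sp, enh_c, enh_a)

  brain <- ellipsoid_mask(g, sp, c(centre0[1:2], centre0[3]),
                          c(0.42 * fov[1], 0.46 * fov[2], Inf))
  white <- ellipsoid_mask(g, sp, c(centre0[1:2], centre0[3]),
                          c(0.26 * fov[1], 0.30 * fov[2], Inf))

  ventL <- ellipsoid_mask(g, sp,
                          c(centre0[1], centre0[2] - eg$ventricle_offset_mm,
                            centre0[3]),
                          c(eg$ventricle_axes_mm[1:2], Inf))
  ventR <- ellipsoid_mask(g, sp,
                          c(centre0[1], centre0[2] + eg$ventricle_offset_mm,
                            centre0[3]),
                          c(eg$ventricle_axes_mm[1:2], Inf))
  colpos <- (seq_len(g[2]) - 1) * sp[2]
  vessel_col <- abs(colpos - (gross_c[2] + eg$vessel_offset_mm)) <=
    eg$vessel_radius_mm
  vessel <- array(rep(rep(vessel_col, each = g[1]), g[3]), g)
  cavity <- ellipsoid_mask(g, sp, gross_c, pmax(gross_a * eg$cavity_scale, 1))
  exclusion <- ventL | ventR | vessel | cavity

  # --- true covariate fields --------------------------------------------
  tm <- config$tissue_means
  truth <- list()
  for (p in MAP_NAMES) {
    m <- array(0, g)
    m[brain] <- tm["grey", p]
    m[white & brain] <- tm["white", p]
    m[gross] <- tm["gross", p]
    m[prog_region] <- tm["progressive", p]
    m <- m + smooth_noise_field(g, sp, config$heterogeneity_fwhm_mm,
                                config$heterogeneity_sd[[p]])
    m[m < 0] <- 0
    truth[[p]] <- m
  }
  truth$SUV_BF <- {
    r <- array(NA_real_, g)
    ok <- truth$BF >= config$bf_floor
    r[ok] <- truth$SUV[ok] / truth$BF[ok]
    r
  }

  # --- ground-truth labels ----------------------------------------------
  b <- config$true_beta
  lp <- b[["(Intercept)"]] + b[["BF"]] * truth$BF + b[["BV"]] * truth$BV +
    b[["PS"]] * truth$PS + b[["SUV"]] * truth$SUV +
    b[["SUV_BF"]] * truth$SUV_BF
  prob <- expit(lp)
  labels <- array(FALSE, g)
  ok <- is.finite(prob)
  labels[ok] <- stats::runif(sum(ok)) < prob[ok]

  # The contoured progressive tumour is the contiguous lesion at the
  # progression site: label draws within the (dilated) progression niche,
  # morphologically closed.  Scattered draws far from the lesion stay in
  # truth$labels but are not part of the contour, as with a radiologist's
  # delineation.
  window <- ellipsoid_mask(g, sp, prog_c,
                           prog_a * lg$label_window_scale)
  rad_px <- max(1, round(config$closing_radius_mm / sp[1]))
  brush <- EBImage::makeBrush(2 * rad_px + 1, shape = "disc")
  progressive <- array(EBImage::closing(labels & window, brush) > 0, g)

  # --- observed maps -----------------------------------------------------
  maps <- list()
  for (p in MAP_NAMES) {
    m <- truth[[p]] + array(stats::rnorm(prod(g), 0, config$noise_sd[[p]]), g)
    m <- in_plane_blur(m, sp, config$smoothing_fwhm_mm)
    m[m < 0] <- 0
    maps[[p]] <- m
  }
  pm <- param_maps(paste0("P", sprintf("%02d", patient_index)), maps, sp,
                   bf_floor = config$bf_floor)

  bbox <- build_bounding_box(voxel_grid(gross, sp), voxel_grid(progressive, sp),
                             margin_cm = config$margin_cm)
  analysis <- build_analysis_mask(bbox, voxel_grid(exclusion, sp))
  ms <- mask_set(list(gross_tumour = gross, enhancing_lesion = enhancing,
                      progressive_tumour = progressive, exclusion = exclusion,
                      bounding_box = bbox, analysis = analysis), sp)
  truth <- lapply(truth, voxel_grid, spacing_mm = sp)
  list(maps = pm, masks = ms,
       truth = list(maps = truth, prob = voxel_grid(prob, sp),
                    labels = voxel_grid(labels, sp)))
}

#' Generate a synthetic cohort
#'
#' `n_patients` independent patients with per-patient sub-seeds derived
#' deterministically from the master seed, so the whole cohort is
#' reproducible bit-exactly from the configuration.
#'
#' @param config a `synthetic_config`.
#' @return list of per-patient lists as returned by [generate_patient()].
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  lapply(seq_len(config$n_patients), function(i) generate_patient(config, i))
}

#' Voxel table of the ground truth
#'
#' The analysis-mask voxel table built from the *true* (noiseless) covariate
#' fields and the raw Bernoulli progression draws (before morphological
#' closing) — the table on which the ground-truth logistic model is exactly
#' the data-generating process, used for parameter-recovery validation.
#'
#' @param patient one element of [generate_cohort()] output.
#' @return a `voxel_table`.
#' @export
truth_voxel_table <- function(patient) {
  tm <- param_maps(patient$maps$patient_id, patient$truth$maps,
                   patient$maps$spacing)
  masks <- patient$masks
  raw <- mask_set(list(gross_tumour = masks$gross_tumour,
                       enhancing_lesion = masks$enhancing_lesion,
                       progressive_tumour = patient$truth$labels,
                       exclusion = masks$exclusion,
                       bounding_box = masks$bounding_box,
                       analysis = masks$analysis), patient$maps$spacing)
  assemble_voxel_table(tm, raw)
}

#' Write a cohort to NIfTI volumes plus a CSV manifest
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return path of the written manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(pt) {
    id <- pt$maps$patient_id
    row <- list(patient_id = id)
    for (p in MAP_NAMES) {
      f <- file.path(dir, paste0(id, "_", p, ".nii.gz"))
      write_map(pt$maps$maps[[p]], f)
      row[[p]] <- basename(f)
    }
    for (m in MASK_NAMES) {
      f <- file.path(dir, paste0(id, "_", m, ".nii.gz"))
      write_mask(pt$masks[[m]], f)
      row[[m]] <- basename(f)
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  man <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, path, row.names = FALSE)
  invisible(path)
}
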