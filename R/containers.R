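# S3 containers for one patient's co-registered data.

#' Construct a parametric map set
#'
#' One patient's co-registered covariate maps on a common grid: BF (mL/min
#' per 100 g), BV (mL/100 g), PS (mL/min per 100 g), SUV (unitless,
#' body-surface-area normalised) and the derived SUV:BF ratio (stored as
#' `SUV_BF`, missing where BF is below the configured floor).
#'
#' @param patient_id patient label.
#' @param maps named list of congruent arrays: `BF`, `BV`, `PS`, `SUV` and
#'   optionally `SUV_BF` (computed from SUV and BF when absent).
#' @param spacing_mm voxel spacing in mm.
#' @param bf_floor BF floor for the SUV:BF ratio when it must be derived.
#' @return object of class `param_maps`.
#' @export
param_maps <- function(patient_id, maps, spacing_mm, bf_floor = 1) {
  need <- MAP_NAMES
  missing <- setdiff(need, names(maps))
  if (length(missing))
    stop("missing maps: ", paste(missing, collapse = ", "))
  for (p in names(maps)) stopifnot_congruent(maps$BF, maps[[p]], "maps")
  for (p in c("BF", "BV", "PS")) {
    neg <- maps[[p]][is.finite(maps[[p]])] < -1e-9
    if (any(neg)) stop(p, " map has negative values")
  }
  if (!"SUV_BF" %in% names(maps))
    maps$SUV_BF <- compute_suv_bf_ratio(maps$SUV, maps$BF,
                                        bf_floor = bf_floor)
  maps <- lapply(maps, function(m) voxel_grid(m, spacing_mm))
  structure(list(patient_id = patient_id, maps = maps,
                 dim = dim(maps$BF), spacing = as.numeric(spacing_mm)),
            class = "param_maps")
}

#' @export
print.param_maps <- function(x, ...) {
  cat("<param_maps> patient", x$patient_id, "-",
      paste(x$dim, collapse = "x"), "grid,",
      paste(signif(x$spacing, 5), collapse = "x"), "mm\n")
  cat("  maps:", paste(names(x$maps), collapse = ", "), "\n")
  invisible(x)
}

#' Construct a mask set
#'
#' Binary masks on the map grid: pre-radiotherapy gross tumour, near-end-of-
#' radiotherapy enhancing lesion, progressive tumour, exclusion regions
#' (vessels / surgical cavity / ventricles), and the derived bounding-box and
#' analysis masks (analysis = bounding box AND NOT exclusion).
#'
#' @param masks named list of congruent logical arrays; recognised names are
#'   `gross_tumour`, `enhancing_lesion`, `progressive_tumour`, `exclusion`,
#'   `bounding_box`, `analysis`.  Omitted masks default to all-FALSE.
#' @param spacing_mm voxel spacing in mm.
#' @return object of class `mask_set`.
#' @export
mask_set <- function(masks, spacing_mm) {
  all_names <- c(MASK_NAMES, "bounding_box", "analysis")
  ref <- masks[[1]]
  out <- list()
  for (m in all_names) {
    mk <- masks[[m]]
    if (is.null(mk)) mk <- array(FALSE, dim(ref))
    stopifnot_congruent(ref, mk, "masks")
    if (!is.logical(mk)) {
      if (!all(unique(as.vector(mk)) %in% c(0, 1)))
        stop("mask ", m, " must be binary")
      mk <- array(mk == 1, dim(mk))
    }
    out[[m]] <- voxel_grid(mk, spacing_mm)
  }
  structure(c(out, list(dim = dim(ref), spacing = as.numeric(spacing_mm))),
            class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  nm <- c(MASK_NAMES, "bounding_box", "analysis")
  counts <- vapply(nm, function(m) sum(x[[m]]), numeric(1))
  cat("<mask_set>", paste(x$dim, collapse = "x"), "grid\n")
  for (m in nm) cat(sprintf("  %-18s %d voxels\n", m, counts[[m]]))
  invisible(x)
}
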