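# From registered maps + masks to the analysis voxel table.

#' Resample a map or mask in-plane to a target grid
#'
#' Continuous maps are resampled bilinearly; masks (logical input or
#' `method = "nearest"`) use nearest-neighbour so labels stay binary.
#' 3-D stacks are resampled section by section; in-plane spacing metadata is
#' rescaled so the field of view is preserved.
#'
#' @param x grid with spacing metadata.
#' @param target_rows,target_cols target in-plane size (default 170 x 170).
#' @param method "auto" (bilinear for numeric, nearest for logical),
#'   "bilinear" or "nearest".
#' @return resampled grid with updated spacing.
#' @export
resample_to_grid <- function(x, target_rows = 170, target_cols = 170,
                             method = c("auto", "bilinear", "nearest")) {
  method <- match.arg(method)
  if (target_rows < 1 || target_cols < 1)
    stop("target grid size must be positive")
  sp <- grid_spacing(x)
  d <- dim(x)
  logical_in <- is.logical(x)
  if (method == "auto") method <- if (logical_in) "nearest" else "bilinear"
  if (d[1] == target_rows && d[2] == target_cols) return(x)
  filt <- if (method == "nearest") "none" else "bilinear"
  y <- EBImage::resize(array(as.numeric(x), d),
                       w = target_rows, h = target_cols, filter = filt)
  y <- array(y, c(target_rows, target_cols, if (length(d) > 2) d[3]))
  if (logical_in) y <- array(y > 0.5, dim(y))
  new_sp <- sp
  new_sp[1] <- sp[1] * d[1] / target_rows
  new_sp[2] <- sp[2] * d[2] / target_cols
  voxel_grid(y, new_sp)
}

#' Bounding box around the union of gross and progressive tumour
#'
#' Axis-aligned in-plane box covering the union of the two masks, expanded by
#' `ceiling(margin_cm * 10 / spacing_mm)` voxels per in-plane axis (so the
#' margin is never under the requested distance) and clipped to the grid.
#' By default the box is computed independently per section from that
#' section's own union extent; the margin is never propagated across
#' sections.
#'
#' @param gross,progressive logical masks on congruent grids.
#' @param margin_cm margin in centimetres (default 2).
#' @param per_section compute one box per section (default) or a single
#'   in-plane box from the union over all sections.
#' @return logical bounding-box mask.
#' @export
build_bounding_box <- function(gross, progressive, margin_cm = 2,
                               per_section = TRUE) {
  stopifnot_congruent(gross, progressive, "masks")
  sp <- grid_spacing(gross)
  u <- gross | progressive
  if (!any(u)) stop("no tumour voxels: union of gross and progressive masks is empty")
  d <- dim(u)
  nsec <- if (length(d) > 2) d[3] else 1L
  u <- array(u, c(d[1], d[2], nsec))
  marg <- ceiling(margin_cm * 10 / sp[1:2])
  box <- array(FALSE, dim(u))
  fill_box <- function(sec_idx, sub) {
    rr <- range(which(apply(sub, 1, any)))
    cc <- range(which(apply(sub, 2, any)))
    r <- pmin(pmax(c(rr[1] - marg[1], rr[2] + marg[1]), 1L), d[1])
    cl <- pmin(pmax(c(cc[1] - marg[2], cc[2] + marg[2]), 1L), d[2])
    box[r[1]:r[2], cl[1]:cl[2], sec_idx] <<- TRUE
  }
  if (per_section) {
    for (s in seq_len(nsec)) if (any(u[, , s])) fill_box(s, u[, , s])
  } else {
    flat <- apply(u, c(1, 2), any)
    fill_box(seq_len(nsec), flat)
  }
  voxel_grid(array(box, d), sp)
}

#' Analysis mask: bounding box minus exclusions
#'
#' @param bounding_box,exclusion logical masks on congruent grids.
#' @return logical mask `bounding_box & !exclusion`; warns when empty.
#' @export
build_analysis_mask <- function(bounding_box, exclusion) {
  stopifnot_congruent(bounding_box, exclusion, "masks")
  out <- bounding_box & !exclusion
  if (!any(out)) warning("analysis mask is empty (exclusion covers the box)")
  voxel_grid(array(out, dim(bounding_box)), grid_spacing(bounding_box))
}

#' Assemble the per-voxel analysis table
#'
#' One record per voxel of the analysis mask: 0-based coordinates, the five
#' covariates and the three binary statuses (pre-RT gross tumour,
#' near-end-of-RT enhancing lesion, progressive tumour).  Voxels with any
#' missing covariate (e.g. SUV:BF below the BF floor) are dropped and counted
#' in the `dropped` attribute.
#'
#' @param maps a `param_maps`.
#' @param masks a `mask_set` whose `analysis` mask is built (see
#'   [build_bounding_box()] / [build_analysis_mask()]); when the analysis
#'   mask is empty of any TRUE voxel it is built from `bounding_box` and
#'   `exclusion`.
#' @return a `voxel_table` data.frame with attribute `dropped`.
#' @export
assemble_voxel_table <- function(maps, masks) {
  stopifnot_congruent(maps$maps$BF, masks$gross_tumour, "maps and masks")
  analysis <- masks$analysis
  if (!any(analysis)) {
    if (any(masks$bounding_box))
      analysis <- build_analysis_mask(masks$bounding_box, masks$exclusion)
    else
      stop("mask set has neither an analysis mask nor a bounding box")
  }
  idx <- which(analysis)
  co <- arrayInd(idx, dim(analysis))
  if (ncol(co) == 2) co <- cbind(co, 1L)
  tab <- data.frame(
    patient_id = rep(as.character(maps$patient_id), length(idx)),
    row = co[, 1] - 1L, col = co[, 2] - 1L, section = co[, 3] - 1L,
    BF = as.numeric(maps$maps$BF[idx]),
    BV = as.numeric(maps$maps$BV[idx]),
    PS = as.numeric(maps$maps$PS[idx]),
    SUV = as.numeric(maps$maps$SUV[idx]),
    SUV_BF = as.numeric(maps$maps$SUV_BF[idx]),
    in_gross = as.integer(masks$gross_tumour[idx]),
    in_enhancing = as.integer(masks$enhancing_lesion[idx]),
    in_progression = as.integer(masks$progressive_tumour[idx]),
    stringsAsFactors = FALSE)
  covs <- c("BF", "BV", "PS", "SUV", "SUV_BF")
  ok <- rowSums(!is.finite(as.matrix(tab[covs]))) == 0
  dropped <- sum(!ok)
  if (dropped > 0)
    message("assemble_voxel_table: dropped ", dropped,
            " voxel(s) with missing covariates (patient ",
            maps$patient_id, ")")
  tab <- tab[ok, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "dropped") <- dropped
  class(tab) <- c("voxel_table", "data.frame")
  tab
}

#' Classify the site of progression relative to the primary tumour
#'
#' In-field means every progressive-tumour voxel lies within `threshold_cm`
#' (default 2 cm, in-plane Euclidean distance) of a gross-tumour voxel;
#' out-of-field means none does; otherwise both.  Distances are computed per
#' section; a section with progressive but no gross voxels contributes
#' infinite distances.
#'
#' @param gross,progressive logical masks on congruent grids.
#' @param threshold_cm classification distance in centimetres.
#' @return one of `"in_field"`, `"out_of_field"`, `"both"`.
#' @export
classify_progression_site <- function(gross, progressive, threshold_cm = 2) {
  stopifnot_congruent(gross, progressive, "masks")
  if (!any(progressive)) stop("progressive mask is empty")
  if (!any(gross)) stop("gross mask is empty")
  sp <- grid_spacing(gross)
  if (abs(sp[1] - sp[2]) > 1e-6)
    stop("in-plane spacing must be isotropic for distance classification")
  d <- dim(gross)
  nsec <- if (length(d) > 2) d[3] else 1L
  g <- array(gross, c(d[1], d[2], nsec))
  p <- array(progressive, c(d[1], d[2], nsec))
  dist_mm <- numeric(0)
  for (s in seq_len(nsec)) {
    if (!any(p[, , s])) next
    if (!any(g[, , s])) {
      dist_mm <- c(dist_mm, rep(Inf, sum(p[, , s])))
      next
    }
    dm <- EBImage::distmap(1 - g[, , s]) * sp[1]
    dist_mm <- c(dist_mm, dm[p[, , s]])
  }
  within <- dist_mm <= threshold_cm * 10
  if (all(within)) "in_field" else if (!any(within)) "out_of_field" else "both"
}
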