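# NIfTI map/mask I/O and CSV voxel-table I/O.
#
# All grids use a single internal convention: array index (row, col, section),
# 0-based coordinates in written tables, spacing in mm taken from the NIfTI
# header pixdim.

#' Read a parametric map from a NIfTI file
#'
#' @param path NIfTI-1 file (`.nii` or `.nii.gz`).
#' @param expect_dim optional expected grid dimensions; mismatch is an error.
#' @param context label (e.g. patient/parameter) prefixed to error messages.
#' @return numeric array with a `spacing` attribute (mm).
#' @export
read_map <- function(path, expect_dim = NULL, context = NULL) {
  ctx <- if (is.null(context)) "" else paste0("[", context, "] ")
  if (!file.exists(path)) stop(ctx, "map file not found: ", path)
  img <- RNifti::readNifti(path)
  x <- as.array(img)
  if (!is.null(expect_dim) && !identical(dim(x), as.integer(expect_dim)))
    stop(ctx, "dimensions ", paste(dim(x), collapse = "x"),
         " do not match expected ", paste(expect_dim, collapse = "x"),
         " in ", path)
  voxel_grid(x, RNifti::pixdim(img)[seq_along(dim(x))])
}

#' Write a grid to a NIfTI file
#'
#' @param map grid with spacing metadata (see [voxel_grid()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  sp <- grid_spacing(map)
  img <- RNifti::asNifti(array(as.numeric(map), dim(map)))
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask from a NIfTI file
#'
#' Values must be exactly 0/1; anything else is rejected rather than
#' thresholded silently.
#'
#' @inheritParams read_map
#' @return logical array with spacing metadata.
#' @export
read_mask <- function(path, expect_dim = NULL, context = NULL) {
  x <- read_map(path, expect_dim = expect_dim, context = context)
  vals <- unique(as.vector(x))
  if (!all(vals %in% c(0, 1)))
    stop(if (is.null(context)) "" else paste0("[", context, "] "),
         "mask must be binary (found values ",
         paste(utils::head(setdiff(vals, c(0, 1)), 3), collapse = ", "),
         ") in ", path)
  voxel_grid(array(x == 1, dim(x)), grid_spacing(x))
}

#' Write a binary mask to a NIfTI file
#' @param mask logical grid with spacing metadata.
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  sp <- grid_spacing(mask)
  img <- RNifti::asNifti(array(as.integer(mask), dim(mask)))
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Write a probability map
#'
#' Enforces the probability contract: inside the analysis mask values must be
#' finite; values straying outside \[0, 1\] by float noise (less than 1e-3)
#' are clipped with a message, larger excursions are an error.  Voxels outside
#' the analysis mask are written as NaN (missing).
#'
#' @param map numeric grid of probabilities with spacing metadata.
#' @param path output path.
#' @param analysis optional logical analysis mask; when given, NaN inside the
#'   mask is an error and everything outside is blanked to NaN.
#' @export
write_probability_map <- function(map, path, analysis = NULL) {
  x <- map
  if (!is.null(analysis)) {
    stopifnot_congruent(map, analysis, "map and analysis mask")
    if (any(!is.finite(x[analysis])))
      stop("NaN probability inside analysis mask")
    x[!analysis] <- NaN
  }
  inb <- is.finite(x)
  over <- inb & (x < 0 | x > 1)
  if (any(over)) {
    worst <- max(pmax(x[over] - 1, -x[over]))
    if (worst > 1e-3)
      stop("values are not probabilities (worst excursion ", signif(worst, 3),
           ")")
    message("clipped ", sum(over), " probability value(s) to [0, 1] ",
            "(max excursion ", signif(worst, 3), ")")
    x[inb] <- pmin(pmax(x[inb], 0), 1)
  }
  write_map(voxel_grid(x, grid_spacing(map)), path)
}

#' Write a voxel table as CSV
#'
#' Fixed column order `patient_id, row, col, section, BF, BV, PS, SUV,
#' SUV_BF, in_gross, in_enhancing, in_progression`; coordinates are 0-based.
#' Written at full float precision so tables round-trip losslessly.
#'
#' @param table a `voxel_table` (see [assemble_voxel_table()]).
#' @param path output CSV path.
#' @export
write_voxel_table <- function(table, path) {
  tab <- as.data.frame(table)[, VOXEL_TABLE_COLS, drop = FALSE]
  # %.17g guarantees lossless double round-trip (plain digit output would
  # truncate at 15 significant digits)
  dbl <- vapply(tab, is.double, logical(1))
  tab[dbl] <- lapply(tab[dbl], function(x) sub("^NA$", "", sprintf("%.17g", x)))
  data.table::fwrite(tab, path, quote = FALSE)
  invisible(path)
}

#' Read a voxel table written by [write_voxel_table()]
#' @param path CSV path.
#' @return a `voxel_table` data.frame.
#' @export
read_voxel_table <- function(path) {
  if (!file.exists(path)) stop("voxel table not found: ", path)
  tab <- as.data.frame(data.table::fread(path, colClasses = list(
    character = "patient_id")))
  if (nrow(tab) == 0 && ncol(tab) == 0)  # header-only file
    tab <- as.data.frame(utils::read.csv(path, colClasses = "character"))
  missing <- setdiff(VOXEL_TABLE_COLS, names(tab))
  if (length(missing))
    stop("voxel table is missing columns: ", paste(missing, collapse = ", "))
  tab <- tab[, VOXEL_TABLE_COLS, drop = FALSE]
  class(tab) <- c("voxel_table", "data.frame")
  tab
}

#' Read a cohort manifest
#'
#' A manifest is a CSV with one row per patient: `patient_id`, one column per
#' parameter map (`BF`, `BV`, `PS`, `SUV`) and one per mask
#' (`gross_tumour`, `enhancing_lesion`, `progressive_tumour`, `exclusion`),
#' each holding a file path (relative paths are resolved against the manifest
#' location).
#'
#' @param path manifest CSV.
#' @return data.frame of resolved paths, class `cohort_manifest`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", MAP_NAMES, "gross_tumour", "progressive_tumour")
  missing <- setdiff(need, names(man))
  if (length(missing))
    stop("manifest is missing columns: ", paste(missing, collapse = ", "))
  base <- dirname(normalizePath(path))
  pathcols <- setdiff(names(man), "patient_id")
  for (cn in pathcols) {
    rel <- !grepl("^(/|[A-Za-z]:)", man[[cn]]) & nzchar(man[[cn]])
    man[[cn]][rel] <- file.path(base, man[[cn]][rel])
    bad <- nzchar(man[[cn]]) & !file.exists(man[[cn]])
    if (any(bad))
      stop("manifest references missing file(s) for patient ",
           paste(man$patient_id[bad], collapse = ", "), ": ",
           paste(utils::head(man[[cn]][bad], 3), collapse = ", "))
  }
  class(man) <- c("cohort_manifest", "data.frame")
  man
}

#' Load one patient's maps and masks from a manifest row
#'
#' @param manifest a `cohort_manifest`.
#' @param patient_id patient to load.
#' @param bf_floor blood-flow floor (mL/min per 100 g) below which SUV:BF is
#'   flagged missing; see [compute_suv_bf_ratio()].
#' @return list with elements `maps` (a `param_maps`) and `masks`
#'   (a `mask_set`).
#' @export
load_patient <- function(manifest, patient_id, bf_floor = 1) {
  row <- manifest[manifest$patient_id == patient_id, , drop = FALSE]
  if (nrow(row) != 1) stop("patient ", patient_id, " not in manifest")
  maps <- lapply(MAP_NAMES, function(p)
    read_map(row[[p]], context = paste(patient_id, p)))
  names(maps) <- MAP_NAMES
  dims <- dim(maps$BF)
  for (p in MAP_NAMES) stopifnot_congruent(maps$BF, maps[[p]], "maps")
  maps$SUV_BF <- compute_suv_bf_ratio(maps$SUV, maps$BF, bf_floor = bf_floor)
  masks <- list()
  for (m in MASK_NAMES) {
    if (m %in% names(row) && nzchar(row[[m]])) {
      masks[[m]] <- read_mask(row[[m]], expect_dim = dims,
                              context = paste(patient_id, m))
    } else {
      masks[[m]] <- voxel_grid(array(FALSE, dims), grid_spacing(maps$BF))
    }
  }
  list(
    maps  = param_maps(patient_id, maps, grid_spacing(maps$BF)),
    masks = mask_set(masks, grid_spacing(maps$BF))
  )
}
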