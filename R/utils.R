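#' @keywords internal
"_PACKAGE"

# Canonical voxel-table column order used by every reader/writer.
VOXEL_TABLE_COLS <- c("patient_id", "row", "col", "section",
                      "BF", "BV", "PS", "SUV", "SUV_BF",
                      "in_gross", "in_enhancing", "in_progression")

MAP_NAMES  <- c("BF", "BV", "PS", "SUV")
MASK_NAMES <- c("gross_tumour", "enhancing_lesion", "progressive_tumour",
                "exclusion")

#' Attach spacing metadata to a voxel grid
#'
#' Grids are plain numeric or logical arrays (row, col, section) carrying a
#' `spacing` attribute in millimetres.
#'
#' @param x array (2-D or 3-D).
#' @param spacing_mm numeric vector of voxel sizes in mm, one per dimension.
#' @return `x` with a `spacing` attribute.
#' @export
voxel_grid <- function(x, spacing_mm) {
  if (length(spacing_mm) != length(dim(x)))
    stop("spacing_mm must have one entry per grid dimension")
  if (any(spacing_mm <= 0)) stop("all spacing must be positive")
  attr(x, "spacing") <- as.numeric(spacing_mm)
  x
}

#' Voxel spacing of a grid, in millimetres
#' @param x a grid created by [voxel_grid()] or read by [read_map()].
#' @return numeric vector of voxel sizes in mm.
#' @export
grid_spacing <- function(x) {
  sp <- attr(x, "spacing")
  if (is.null(sp)) stop("grid carries no spacing metadata")
  sp
}

# Evaluate `code` under a given seed without disturbing the caller's RNG
# stream.
with_local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

stopifnot_congruent <- function(a, b, what = "grids") {
  if (!identical(dim(a), dim(b)))
    stop(what, " are not congruent: ", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"))
  invisible(TRUE)
}

expit <- function(x) stats::plogis(x)
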