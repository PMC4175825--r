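test_that("resampling: identity, constancy, and nearest-neighbour block replication", {
  x <- withr::with_seed(3, voxel_grid(array(runif(170 * 170), c(170, 170)), SP2))
  expect_identical(resample_to_grid(x, 170, 170), x)

  const <- voxel_grid(array(7, c(340, 340)), c(250 / 340, 250 / 340))
  y <- resample_to_grid(const, 170, 170)
  expect_true(all(y == 7))
  expect_equal(grid_spacing(y), SP2, tolerance = 1e-9)

  checker <- voxel_grid(array(c(TRUE, FALSE, FALSE, TRUE), c(2, 2)), c(2, 2))
  up <- resample_to_grid(checker, 4, 4)
  expect_type(up, "logical")
  expect_identical(up[, , drop = TRUE],
                   matrix(c(TRUE, TRUE, FALSE, FALSE,
                            TRUE, TRUE, FALSE, FALSE,
                            FALSE, FALSE, TRUE, TRUE,
                            FALSE, FALSE, TRUE, TRUE), 4, 4))
  expect_equal(grid_spacing(up), c(1, 1))
  expect_error(resample_to_grid(checker, 0, 4), "positive")
})

test_that("masks stay binary through any resampling path", {
  m <- withr::with_seed(8, voxel_grid(array(runif(40 * 40) < 0.3, c(40, 40)),
                                      c(2, 2)))
  for (target in list(c(20, 20), c(80, 80), c(37, 53))) {
    r <- resample_to_grid(m, target[1], target[2])
    expect_type(r, "logical")
  }
})

test_that("bounding box: margin arithmetic, zero margin, edge clipping", {
  # single-voxel union at (86, 86) 1-based; ceil(20 mm / 1.4706 mm) = 14
  g <- mask_with(cbind(86, 86, 1), dim = c(170, 170, 1))
  box <- build_bounding_box(g, empty_mask(c(170, 170, 1)), margin_cm = 2)
  idx <- which(box, arr.ind = TRUE)
  expect_equal(range(idx[, 1]), c(86 - 14, 86 + 14))
  expect_equal(range(idx[, 2]), c(86 - 14, 86 + 14))

  box0 <- build_bounding_box(g, empty_mask(c(170, 170, 1)), margin_cm = 0)
  expect_equal(sum(box0), 1)
  expect_true(box0[86, 86, 1])

  edge <- mask_with(cbind(2, 169, 1), dim = c(170, 170, 1))
  boxe <- build_bounding_box(edge, empty_mask(c(170, 170, 1)), margin_cm = 2)
  idxe <- which(boxe, arr.ind = TRUE)
  expect_equal(range(idxe[, 1]), c(1, 16))
  expect_equal(range(idxe[, 2]), c(155, 170))

  expect_error(build_bounding_box(empty_mask(), empty_mask()),
               "no tumour voxels")
})

test_that("bounding box is per-section and monotone in the margin", {
  m <- mask_with(rbind(c(50, 50, 1), c(100, 100, 2)), dim = c(170, 170, 3))
  box <- build_bounding_box(m, empty_mask(c(170, 170, 3)), margin_cm = 1)
  expect_equal(sum(box[, , 3]), 0)                   # no union, no box
  expect_false(box[100, 100, 1])                     # margins stay in-plane
  expect_true(box[50, 50, 1] && box[100, 100, 2])
  bigger <- build_bounding_box(m, empty_mask(c(170, 170, 3)), margin_cm = 2)
  expect_true(all(bigger[box]))                      # superset
})

test_that("analysis mask is box AND NOT exclusion, warning when empty", {
  box <- mask_with(cbind(rep(1:10, 10), rep(1:10, each = 10), 1),
                   dim = c(12, 12, 1))
  vessel <- mask_with(cbind(3:5, 4, 1), dim = c(12, 12, 1))
  a <- build_analysis_mask(box, vessel)
  expect_equal(sum(a), sum(box) - 3)
  expect_identical(build_analysis_mask(box, empty_mask(c(12, 12, 1))),
                   voxel_grid(array(box, dim(box)), SP3))
  expect_warning(build_analysis_mask(vessel, box), "empty")
})

test_that("voxel table assembly counts, statuses and conservation", {
  dims <- c(5, 5, 1)
  sp <- c(1, 1, 5)
  mk <- function(vals) voxel_grid(array(vals, dims), sp)
  maps <- param_maps("X", list(BF = mk(40), BV = mk(3), PS = mk(2),
                               SUV = mk(1.2)), sp)
  analysis <- mask_with(cbind(1:3, 1, 1), dim = dims, spacing = sp)
  analysis[1:3, 2, 1] <- TRUE                       # 6 analysis voxels
  prog <- mask_with(rbind(c(1, 1, 1), c(2, 2, 1)), dim = dims, spacing = sp)
  masks <- mask_set(list(progressive_tumour = prog, analysis = analysis), sp)
  tab <- assemble_voxel_table(maps, masks)
  expect_s3_class(tab, "voxel_table")
  expect_equal(nrow(tab), 6)
  expect_equal(sum(tab$in_progression), 2)
  expect_true(all(tab$in_gross == 0) && all(tab$in_enhancing == 0))
  expect_equal(tab$SUV_BF, rep(1.2 / 40, 6))
  # coordinates are 0-based
  expect_equal(min(tab$row), 0)

  # NaN covariate inside the analysis mask: dropped and logged, row count
  # conserved as mask cardinality minus dropped
  maps$maps$PS[2, 1, 1] <- NaN
  expect_message(tab2 <- assemble_voxel_table(maps, masks), "dropped 1 voxel")
  expect_equal(nrow(tab2), sum(analysis) - attr(tab2, "dropped"))
})

test_that("progression site classification: in-field, out-of-field, both", {
  dims <- c(170, 170, 1)
  disc <- function(centre, r_mm) {
    co <- expand.grid(r = 1:dims[1], c = 1:dims[2])
    d <- sqrt(((co$r - centre[1]) * SP2[1])^2 + ((co$c - centre[2]) * SP2[2])^2)
    m <- array(FALSE, dims)
    m[cbind(co$r, co$c, 1)] <- d <= r_mm
    voxel_grid(m, SP3)
  }
  gross <- disc(c(60, 60), 10)
  expect_identical(classify_progression_site(gross, disc(c(60, 60), 5)),
                   "in_field")
  # progressive centred 5 cm away, 1 cm diameter: nearest edge 3.5 cm > 2 cm
  far <- disc(c(60, 60 + 50 / SP2[2]), 5)
  expect_identical(classify_progression_site(gross, far), "out_of_field")
  both <- voxel_grid(disc(c(60, 60), 5) | far, SP3)
  expect_identical(classify_progression_site(gross, both), "both")
  expect_error(classify_progression_site(gross, empty_mask(dims)), "empty")
})
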