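# Shared fixtures: tiny grids, toy tables, and a small-but-realistic
# synthetic configuration used across test files.

SP2 <- c(250 / 170, 250 / 170)          # in-plane spacing, mm
SP3 <- c(SP2, 5)

# A small synthetic configuration that keeps the default biology/contrast
# but shrinks the grid and cohort so unit tests run in seconds.
small_config <- function(n_patients = 3, seed = 11, grid = c(96, 96, 4), ...) {
  synthetic_config(n_patients = n_patients, grid = grid, seed = seed, ...)
}

# Deterministic toy voxel table: independent covariates drawn once under a
# fixed seed, outcome from a known logistic model on the PS column.
toy_table <- function(n = 400, beta = c(-1, 0.8), seed = 42) {
  withr::with_seed(seed, {
    z <- matrix(stats::rnorm(4 * n), n, 4)
    p <- stats::plogis(beta[1] + beta[2] * z[, 3])
    y <- as.integer(stats::runif(n) < p)
  })
  bf <- pmax(30 + 5 * z[, 1], 1)
  suv <- pmax(1.5 + 0.2 * z[, 4], 0.05)
  data.frame(patient_id = "T", row = seq_len(n) - 1L, col = 0L, section = 0L,
             BF = bf, BV = pmax(3 + 0.5 * z[, 2], 0.1), PS = z[, 3] + 3,
             SUV = suv, SUV_BF = suv / bf,
             in_gross = 0L, in_enhancing = 0L, in_progression = y)
}

# 2x2-cell outcome data for the closed-form log odds ratio check.
two_by_two_table <- function(n11, n01, n10, n00) {
  # x=1: n11 events / n01 non-events; x=0: n10 events / n00 non-events
  x <- c(rep(1, n11 + n01), rep(0, n10 + n00))
  y <- c(rep(1, n11), rep(0, n01), rep(1, n10), rep(0, n00))
  data.frame(patient_id = "T", row = seq_along(x) - 1L, col = 0L,
             section = 0L, BF = 30, BV = 3, PS = x, SUV = 1, SUV_BF = 1 / 30,
             in_gross = as.integer(x), in_enhancing = 0L, in_progression = y)
}

empty_mask <- function(dim = c(10, 10, 2), spacing = SP3[seq_along(dim)]) {
  voxel_grid(array(FALSE, dim), spacing)
}

mask_with <- function(idx, dim = c(10, 10, 2), spacing = SP3[seq_along(dim)]) {
  m <- array(FALSE, dim)
  m[idx] <- TRUE
  voxel_grid(m, spacing)
}
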