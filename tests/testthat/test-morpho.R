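test_that("region volumes follow voxel arithmetic and TBV adjustment", {
  codes <- array(0L, c(10, 10, 10))
  codes[1:4, 1:5, 1:5] <- 1L               # 100 voxels
  lab <- label_map(codes, spacing = c(0.5, 0.5, 0.5))
  rv <- region_volumes(lab, tbv = 1000)
  expect_equal(rv$volume_mm3[rv$code == 1], 12.5)    # 100 * 0.125 mm^3
  expect_equal(rv$adjusted[rv$code == 1], 0.0125)
  expect_equal(rv$volume_mm3[rv$code == 2], 0)       # empty structure
  expect_equal(rv$adjusted[rv$code == 2], 0)
  expect_error(region_volumes(lab, tbv = -5), "positive")
  # TBV from a brain mask
  brain <- array(0L, c(10, 10, 10)); brain[1:8, , ] <- 1L
  rv2 <- region_volumes(lab, tbv = brain)
  expect_equal(rv2$adjusted[rv2$code == 1], 12.5 / (800 * 0.125))
})

test_that("phantom volumes match the generator's own bookkeeping", {
  ph <- generate_phantom(phantom_spec(seed = 2))
  rv <- region_volumes(ph$labels, tbv = 1)
  counts <- tabulate(ph$labels$codes, nbins = 4)
  expect_equal(rv$voxels, as.numeric(counts))
  expect_equal(rv$volume_mm3, counts * prod(ph$labels$spacing))
})

test_that("partial Spearman reduces to plain Spearman without covariates", {
  set.seed(12)
  x <- rnorm(60); y <- 0.5 * x + rnorm(60)
  pc <- spearman_partial(x, y)
  expect_equal(pc$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
  expect_identical(pc$df, 58L)
  expect_equal(spearman_partial(x, exp(x))$rho, 1)   # strictly monotone
  expect_error(spearman_partial(x, rep(1, 60)), "constant")
  expect_error(spearman_partial(x[1:5], y[1:5],
                                cbind(a = rnorm(5), b = rnorm(5))),
               "too few")
})

test_that("rank correlation is invariant to increasing transforms", {
  set.seed(13)
  x <- rexp(80); y <- rnorm(80); z <- cbind(z1 = rnorm(80))
  base <- spearman_partial(x, y, z)$rho
  expect_equal(spearman_partial(log(x), y, z)$rho, base, tolerance = 1e-12)
  expect_equal(spearman_partial(x, 3 * y - 2, z)$rho, base,
               tolerance = 1e-12)
})

test_that("shared covariates are partialled out", {
  set.seed(14)
  z <- rnorm(200)
  x <- exp(z)                     # monotone functions of the same confounder
  y <- z^3 + 2
  pc <- spearman_partial(x, y, cbind(z = z))
  expect_lt(abs(pc$rho), 0.05)
  expect_identical(pc$df, 200L - 2L - 1L)
})

test_that("the brain-behavior matrix covers all cells with correct flags", {
  co <- generate_cohort(60, seed = 21)
  bb <- brain_behavior_matrix(co$table, alpha = 0.05)
  expect_identical(nrow(bb), 12L)          # 4 volumes x 3 outcomes
  expect_true(all(bb$df == 60 - 2 - 3))
  expect_identical(bb$significant, bb$p < 0.05)
  expect_true(all(bb$p_bh >= bb$p - 1e-15))
  expect_error(brain_behavior_matrix(co$table, covariates = "nope"),
               "missing covariates")
})

test_that("false-positive rate under the null is near the nominal level", {
  rho0 <- matrix(0, 4, 3)
  flags <- 0; cells <- 0
  for (r in 1:120) {
    co <- generate_cohort(50, target_rho = rho0, seed = 3000 + r)
    bb <- brain_behavior_matrix(co$table)
    flags <- flags + sum(bb$significant)
    cells <- cells + nrow(bb)
  }
  rate <- flags / cells
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("an embedded right-amygdala signal is detected reliably at n=50", {
  rho <- matrix(0, 4, 3,
                dimnames = list(rownames(default_target_rho()),
                                colnames(default_target_rho())))
  rho["right_amygdala", ] <- -0.6
  hits <- 0
  for (r in 1:20) {
    co <- generate_cohort(50, target_rho = rho, seed = 500 + r)
    bb <- brain_behavior_matrix(co$table)
    amy <- bb[bb$measure == "adj_right_amygdala", ]
    if (all(amy$significant)) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.9)
})
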