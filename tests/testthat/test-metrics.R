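test_that("Dice handles the canonical cases", {
  a <- array(FALSE, c(4, 4, 1)); a[1:2, 1:2, 1] <- TRUE
  b <- array(FALSE, c(4, 4, 1)); b[2:3, 1:2, 1] <- TRUE
  expect_equal(dsc(a, a), 1)
  expect_equal(dsc(a, b), 0.5)              # |A|=|B|=4, |A&B|=2
  expect_equal(dsc(a, !a & FALSE), 0)       # disjoint
  expect_true(is.na(dsc(a & FALSE, b & FALSE)))
  expect_error(dsc(a, array(FALSE, c(3, 3, 1))), "mismatch")
})

test_that("all three metrics agree with brute-force oracles on small masks", {
  set.seed(14)
  checked <- 0
  for (rep in 1:150) {
    a <- random_small_mask(c(3, 3, 1))
    b <- random_small_mask(c(3, 3, 1))
    expect_equal(dsc(a, b), dsc_brute(a, b), tolerance = 1e-12)
    if (any(a) && any(b)) {
      expect_equal(asd(a, b), asd_brute(a, b), tolerance = 1e-9)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 50)
  # larger random blobs for the surface-distance oracle
  for (rep in 1:10) {
    a <- random_small_mask(c(6, 5, 4), p = 0.3)
    b <- random_small_mask(c(6, 5, 4), p = 0.3)
    if (!any(a) || !any(b)) next
    sp <- runif(3, 0.5, 1.5)
    expect_equal(asd(a, b, sp), asd_brute(a, b, sp), tolerance = 1e-9)
  }
})

test_that("ASD respects geometry and spacing", {
  s1 <- array(FALSE, c(9, 5, 5)); s1[2, 2, 2] <- TRUE
  s2 <- array(FALSE, c(9, 5, 5)); s2[4, 2, 2] <- TRUE
  expect_equal(asd(s1, s2, c(0.5, 0.5, 0.5)), 1.0)   # 2 voxels at 0.5 mm
  expect_equal(asd(s1, s1), 0)
  set.seed(4)
  a <- random_small_mask(c(8, 8, 3), 0.2); a[2, 2, 2] <- TRUE
  b <- random_small_mask(c(8, 8, 3), 0.2); b[5, 5, 2] <- TRUE
  expect_equal(asd(a, b), asd(b, a))                 # symmetric
  expect_equal(asd(a, b, c(2, 2, 2)), 2 * asd(a, b, c(1, 1, 1)))
  expect_true(is.na(asd(a & FALSE, b)))
})

test_that("mask ICC matches an aov-based reference and hits its extremes", {
  a <- array(FALSE, c(6, 6, 1)); a[2:4, 2:4, 1] <- TRUE
  expect_equal(icc_masks(a, a), 1)
  set.seed(9)
  for (rep in 1:5) {
    x <- random_small_mask(c(6, 6, 6), 0.4)
    y <- random_small_mask(c(6, 6, 6), 0.4)
    if (!any(x | y)) next
    got <- icc_masks(x, y, roi_dilate = Inf)
    expect_equal(got, icc_aov(as.numeric(x), as.numeric(y)),
                 tolerance = 1e-8)
  }
  # perfect anti-consistency
  m <- array(c(TRUE, FALSE), c(4, 4, 2))
  expect_equal(icc_masks(m, !m, roi_dilate = Inf), -1)
  # zero-variance pairs are undefined
  z <- array(FALSE, c(4, 4, 2))
  expect_true(is.na(icc_masks(z, z, roi_dilate = Inf)))
})

test_that("evaluate_pair isolates structures and flags absences", {
  ph <- generate_phantom(phantom_spec(shape = c(32, 32, 32),
                                      structure_scale = 0.75, seed = 6))
  self <- evaluate_pair(ph$labels, ph$labels)
  expect_equal(self$dsc, rep(1, 4))
  expect_equal(self$icc, rep(1, 4))
  expect_equal(self$asd_mm, rep(0, 4))

  pred <- ph$labels
  pred$codes[pred$codes == 3L] <- 0L        # drop the left amygdala
  rep2 <- evaluate_pair(pred, ph$labels)
  expect_true(is.na(rep2$dsc[rep2$code == 3]))
  expect_match(rep2$note[rep2$code == 3], "absent in prediction")
  expect_equal(rep2$dsc[rep2$code != 3], rep(1, 3))
})

test_that("batched aggregation reproduces hand-computed means", {
  phs <- lapply(1:4, function(s)
    generate_phantom(phantom_spec(shape = c(32, 32, 32),
                                  structure_scale = 0.75, seed = s)))
  reports <- lapply(phs, function(ph) {
    noisy <- simulate_raters(ph$labels, 2, rater_noise_spec(seed = 99))[[1]]
    evaluate_pair(noisy, ph$labels)
  })
  agg <- aggregate_metrics(reports)
  hand <- mean(vapply(reports, function(r)
    r$dsc[r$structure == "left_hippocampus"], numeric(1)))
  got <- agg$mean[agg$structure == "left_hippocampus" & agg$metric == "dsc"]
  expect_equal(got, hand, tolerance = 1e-12)
})

test_that("method comparison runs per-cell ANOVAs with BH adjustment", {
  set.seed(31)
  subj <- 1:20
  base <- data.frame(subject = rep(subj, 3),
                     method = rep(c("m1", "m2", "m3"), each = 20),
                     structure = "left_hippocampus", metric = "dsc")
  # identical value pattern across methods (varies by subject): F = 0, p = 1
  v <- runif(20, 0.6, 0.9)
  d0 <- transform(base, value = rep(v, 3))
  r0 <- compare_methods(d0)
  expect_equal(r0$F, 0, tolerance = 1e-12)
  expect_equal(r0$p, 1, tolerance = 1e-12)
  expect_identical(r0$df_between, 2L)
  expect_true(all(r0$p_adj >= r0$p))

  # a one-sd shift is detected in most seeded replicates
  hits <- 0
  for (rep in 1:25) {
    d <- base
    d$value <- c(rnorm(20, 0.7, 0.05), rnorm(20, 0.75, 0.05),
                 rnorm(20, 0.7, 0.05))
    if (compare_methods(d)$p_adj < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 25, 0.8)

  d_bad <- d0[d0$subject != 3 | d0$method != "m1", ]
  expect_error(compare_methods(d_bad), "unequal subject sets")
})
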