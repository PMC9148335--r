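# Independent reference: the STAPLE EM recurrences written as plain loops
# over voxels and raters, no vectorization shared with the implementation.
staple_reference <- function(D, prior, iters) {
  k <- ncol(D); V <- nrow(D)
  p <- rep(0.99999, k); q <- rep(0.99999, k)
  clamp <- function(x) pmin(pmax(x, 1e-5), 1 - 1e-5)
  W <- numeric(V)
  for (it in seq_len(iters)) {
    for (i in seq_len(V)) {
      a <- prior; b <- 1 - prior
      for (j in seq_len(k)) {
        if (D[i, j] == 1) { a <- a * p[j]; b <- b * (1 - q[j]) }
        else { a <- a * (1 - p[j]); b <- b * q[j] }
      }
      W[i] <- a / (a + b)
    }
    for (j in seq_len(k)) {
      p[j] <- clamp(sum(W[D[, j] == 1]) / sum(W))
      q[j] <- clamp(sum((1 - W)[D[, j] == 0]) / sum(1 - W))
    }
  }
  list(W = W, p = p, q = q)
}

test_that("unanimous raters are an EM fixed point", {
  m <- array(FALSE, c(4, 4, 4)); m[2:3, 2:3, 2:3] <- TRUE
  fit <- staple_binary(replicate(3, m, simplify = FALSE), roi_dilate = Inf)
  expect_identical(array(fit$consensus, dim(m)), m)
  expect_true(all(fit$sensitivity > 0.999))
  expect_true(all(fit$specificity > 0.999))
})

test_that("a contrarian rater is outvoted and scored below chance", {
  truth <- array(FALSE, c(4, 4, 4)); truth[2:3, 2:3, 2:3] <- TRUE
  stack <- c(replicate(4, truth, simplify = FALSE), list(!truth))
  fit <- staple_binary(stack, roi_dilate = Inf)
  expect_identical(array(fit$consensus, dim(truth)), truth)
  expect_lt(fit$sensitivity[5], 0.5)
  expect_true(all(fit$sensitivity[1:4] > 0.9))
})

test_that("vectorized EM matches the straight-from-the-equations reference", {
  set.seed(21)
  for (rep in 1:4) {
    V <- sample(c(27, 64, 125), 1)
    k <- sample(2:3, 1)
    D <- matrix(runif(V * k) < 0.4, V, k) * 1
    if (sum(D) == 0 || sum(D) == V * k) next
    prior <- mean(D)
    iters <- 12
    ref <- staple_reference(D, prior, iters)
    fit <- staple_binary(D, prior = prior, tol = 0, max_iter = iters)
    expect_equal(as.vector(fit$posterior), ref$W, tolerance = 1e-8)
    expect_equal(fit$sensitivity, ref$p, tolerance = 1e-8)
    expect_equal(fit$specificity, ref$q, tolerance = 1e-8)
  }
})

test_that("the observed-data log-likelihood never decreases", {
  set.seed(8)
  ph <- generate_phantom(phantom_spec(shape = c(32, 32, 32),
                                      structure_scale = 0.75, seed = 2))
  m <- ph$labels$codes %in% 1:2
  dim(m) <- dim(ph$labels$codes)
  sims <- lapply(1:5, function(j) {
    r <- array(FALSE, dim(m))
    r[m] <- runif(sum(m)) < 0.9
    r[!m] <- runif(sum(!m)) < 0.05
    r
  })
  fit <- staple_binary(sims, prior = mean(m), roi_dilate = Inf)
  expect_true(all(diff(fit$log_likelihood) >= -1e-6))
  # performance-level recovery: true sensitivity 0.90, specificity 0.95
  expect_true(all(abs(fit$sensitivity - 0.90) <= 0.05))
  expect_true(all(abs(fit$specificity - 0.95) <= 0.02))
})

test_that("degenerate stacks are rejected", {
  z <- array(FALSE, c(3, 3, 3))
  expect_error(staple_binary(list(z, z)), "degenerate")
  f <- array(TRUE, c(3, 3, 3))
  expect_error(staple_binary(list(f, f)), "degenerate")
})

test_that("multilabel consensus is invariant to rater order", {
  ph <- generate_phantom(phantom_spec(shape = c(32, 32, 32),
                                      structure_scale = 0.75, seed = 4))
  rs <- simulate_raters(ph$labels, 3, rater_noise_spec(seed = 6))
  c1 <- consensus_multilabel(rs)
  c2 <- consensus_multilabel(rev(rs))
  expect_identical(c1$codes, c2$codes)
  # identical maps fuse to themselves
  expect_identical(consensus_multilabel(list(ph$labels, ph$labels))$codes,
                   ph$labels$codes)
})

test_that("voxels contested between structures go to the higher posterior", {
  # construct two overlapping structures rated by 3 raters such that one
  # voxel is claimed by both labels with different support
  shp <- c(5, 5, 5)
  mk <- function(vox1, vox2) {
    codes <- array(0L, shp)
    for (v in vox1) codes[v] <- 1L
    for (v in vox2) codes[v] <- 3L
    label_map(codes)
  }
  # voxel 63: all three raters say label 1; two of three say label 3 at 64
  maps <- list(mk(c(62, 63), c(64)), mk(c(63), c(64)), mk(c(63, 64), c()))
  cons <- consensus_multilabel(maps)
  expect_identical(cons$codes[[63]], 1L)
})

test_that("inter-rater QC applies the inclusive 0.6 threshold per structure", {
  ph <- generate_phantom(phantom_spec(seed = 12))
  rs <- simulate_raters(ph$labels, 3, rater_noise_spec(seed = 13))
  qc <- interrater_qc(rs, threshold = 0.6)
  expect_identical(nrow(qc), 4L)
  expect_true(all(qc$mean_pairwise_dsc > 0.5))

  a <- array(0L, c(6, 6, 6)); a[2, 2, 2] <- 1L
  b <- array(0L, c(6, 6, 6)); b[5, 5, 5] <- 1L
  qc2 <- interrater_qc(list(label_map(a), label_map(b)))
  expect_false(qc2$pass[qc2$code == 1])          # disjoint -> DSC 0 -> fail
  expect_true(is.na(qc2$mean_pairwise_dsc[qc2$code == 2]))  # empty everywhere
  expect_false(qc2$pass[qc2$code == 2])

  # exact equality with the threshold passes
  expect_true(interrater_qc(list(label_map(a), label_map(a)),
                            threshold = 1)$pass[1])
})
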