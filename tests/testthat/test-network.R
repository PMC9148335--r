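# closed-form layer-by-layer parameter tally, independent of the builder
analytic_count <- function(F, C, stages = 4, k = 5, cin0 = 1) {
  block <- function(cin) {
    cins <- c(cin, cin + F, cin + 2 * F)
    ks <- c(k, k, 1)
    sum(ks^2 * cins * F + F) +   # conv weights + biases
      sum(2 * cins) +            # batch-norm scale and shift per input ch
      1                          # shared PReLU slope
  }
  block(cin0) + (stages - 1) * block(F) + block(F) + stages * block(2 * F) +
    F * C + C
}

test_that("the default view model has the reference parameter count", {
  net <- build_view_model(view_model_config())
  expect_identical(net$n_parameters, 3520871L)
  expect_identical(3L * net$n_parameters, 10562613L)
})

test_that("parameter count is a pure function of the configuration", {
  for (cfg in list(view_model_config(8, classes = 5),
                   view_model_config(16, classes = 3, stages = 3),
                   view_model_config(4, classes = 5, kernel = 3))) {
    net <- build_view_model(cfg, seed = 1)
    expect_identical(net$n_parameters,
                     as.integer(analytic_count(cfg$base_channels,
                                               cfg$classes, cfg$stages,
                                               cfg$kernel)))
    net2 <- build_view_model(cfg, seed = 99)   # init seed must not matter
    expect_identical(net2$n_parameters, net$n_parameters)
  }
  expect_error(view_model_config(classes = 1), "classes")
  expect_error(view_model_config(base_channels = 0), "channels")
})

test_that("view probabilities are normalized and deterministic", {
  cfg <- view_model_config(base_channels = 3, classes = 5)
  net <- build_view_model(cfg, seed = 3)
  set.seed(10)
  vol <- volume3d(array(rnorm(32 * 32 * 16), c(32, 32, 16)))
  p1 <- predict_view_probs(net, vol, "coronal")
  p2 <- predict_view_probs(net, vol, "coronal")
  expect_identical(p1, p2)
  sums <- apply(p1, 1:3, sum)
  expect_true(all(abs(sums - 1) < 1e-5))
  bad <- volume3d(array(0, c(30, 32, 16)))
  expect_error(predict_view_probs(net, bad, "axial"), "conformed")
})

test_that("fusion matches a per-voxel brute-force evaluation", {
  set.seed(17)
  d <- c(6, 5, 4); C <- 5
  rand_probs <- function() {
    p <- array(runif(prod(d) * C), c(d, C))
    s <- apply(p, 1:3, sum)
    p / as.vector(s)
  }
  pa <- rand_probs(); pc <- rand_probs(); ps <- rand_probs()
  for (w in list(fusion_weights(), fusion_weights(0.2, 0.3, 0.5))) {
    fused <- fuse_views(pa, pc, ps, w)
    brute <- array(0L, d)
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
      score <- w[["axial"]] * pa[i, j, k, ] + w[["coronal"]] * pc[i, j, k, ] +
        w[["sagittal"]] * ps[i, j, k, ]
      brute[i, j, k] <- which.max(score) - 1L
    }
    expect_identical(fused$codes, brute)
  }
})

test_that("degenerate and tied fusion weights behave as documented", {
  set.seed(18)
  d <- c(4, 4, 4); C <- 4
  mk <- function() {
    p <- array(runif(prod(d) * C), c(d, C)); p / as.vector(apply(p, 1:3, sum))
  }
  pa <- mk(); pc <- mk(); ps <- mk()
  only_ax <- fuse_views(pa, pc, ps, fusion_weights(1, 0, 0))
  ax_argmax <- apply(pa, 1:3, which.max) - 1L
  expect_identical(only_ax$codes, array(as.integer(ax_argmax), d))

  # one-hot disagreement: weights 0.4/0.4/0.2 tie between classes 1 and 2,
  # broken toward the lower class index
  onehot <- function(cl) {
    p <- array(0, c(1, 1, 1, C)); p[1, 1, 1, cl] <- 1; p
  }
  tie <- fuse_views(onehot(2), onehot(3), onehot(4), fusion_weights())
  expect_identical(as.integer(tie$codes), 1L)
  agree <- fuse_views(onehot(3), onehot(3), onehot(3), fusion_weights())
  expect_identical(as.integer(agree$codes), 2L)

  expect_error(fusion_weights(0.5, 0.5, 0.5), "sum to 1")
  expect_error(fuse_views(pa, pc, array(0, c(2, 2, 2, C))), "match")
})

test_that("fusion is equivariant under class permutation", {
  set.seed(19)
  d <- c(4, 4, 2); C <- 5
  mk <- function() {
    p <- array(runif(prod(d) * C), c(d, C)); p / as.vector(apply(p, 1:3, sum))
  }
  pa <- mk(); pc <- mk(); ps <- mk()
  base <- fuse_views(pa, pc, ps)
  perm <- c(3L, 1L, 5L, 2L, 4L)    # new position of each old class channel
  pp <- function(p) p[, , , order(perm)]
  permuted <- fuse_views(pp(pa), pp(pc), pp(ps))
  expect_identical(permuted$codes, array(perm[base$codes + 1L] - 1L, d))
})

test_that("backpropagation matches finite differences", {
  cfg <- view_model_config(base_channels = 3, classes = 4, stages = 2,
                           kernel = 3)
  net <- build_view_model(cfg, seed = 2)
  set.seed(5)
  H <- 8; N <- 2
  x <- matrix(rnorm(H * H * N), ncol = 1)
  tb <- idseg:::onehot_slices(sample(0:3, H * H * N, TRUE), 4)
  cw <- c(0.5, 1, 2, 1.5)
  hw <- c(H, H, N)
  lossfun <- function(nn) {
    f <- idseg:::net_fwd(nn, x, hw, training = TRUE)
    idseg:::seg_loss(f$logits, tb, cw)$loss
  }
  f <- idseg:::net_fwd(net, x, hw, training = TRUE)
  ls <- idseg:::seg_loss(f$logits, tb, cw)
  gr <- idseg:::net_bwd(net, f, ls$grad)
  leaves <- list(c("classifier", "W"), c("enc1", "conv1", "W"),
                 c("enc2", "bn3", "gamma"), c("dec1", "conv2", "W"),
                 c("bottleneck", "conv3", "W"), c("enc2", "a"))
  setleaf <- function(obj, path, i, val) {
    if (!length(path)) { obj[i] <- obj[i] + val; return(obj) }
    obj[[path[1]]] <- setleaf(obj[[path[1]]], path[-1], i, val)
    obj
  }
  for (leaf in leaves) {
    g <- gr; p <- net$params
    for (nm in leaf) { g <- g[[nm]]; p <- p[[nm]] }
    i <- min(2, length(p))
    eps <- 1e-5
    n2 <- net
    n2$params <- setleaf(net$params, leaf, i, eps); lp <- lossfun(n2)
    n2$params <- setleaf(net$params, leaf, i, -eps); lm <- lossfun(n2)
    num <- (lp - lm) / (2 * eps)
    expect_lt(abs(num - g[i]) / max(1e-6, abs(num)), 1e-4)
  }
})
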