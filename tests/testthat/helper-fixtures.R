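# Shared fixtures, built in code and cached for the session so expensive
# simulations (default-size phantoms, simulated raters) are reused across
# test files.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# 20 default-geometry phantoms with k = 3 simulated raters each (the
# inter-rater calibration setting).
rater_study <- function() {
  fixture("rater_study", function() {
    lapply(1:20, function(i) {
      ph <- generate_phantom(phantom_spec(seed = i))
      raters <- simulate_raters(ph$labels, k = 3,
                                rater_noise_spec(seed = 100 + i))
      list(phantom = ph, raters = raters)
    })
  })
}

# Desk-scale training world: flattened grid, enlarged structures, 4-channel
# network. These sizes are the package's documented desk-scale experiment.
desk_shape <- c(32, 32, 16)
desk_scale <- 0.7
desk_net_config <- function() view_model_config(base_channels = 4,
                                                classes = 5)

desk_phantom <- function(seed, noisy_labels = FALSE) {
  ph <- generate_phantom(phantom_spec(shape = desk_shape,
                                      structure_scale = desk_scale,
                                      seed = seed))
  ph$volume <- normalize_intensity(ph$volume)
  if (noisy_labels)
    ph$labels <- simulate_raters(
      ph$labels, 2, rater_noise_spec(boundary_sd = 0.4, flip_rate = 0.02,
                                     seed = seed * 3))[[1]]
  ph
}

# Pre-trained desk-scale model (machine-generated noisy labels emulate the
# automated pre-training corpus).
desk_pretrained <- function() {
  fixture("desk_pretrained", function() {
    pre <- lapply(101:110, desk_phantom, noisy_labels = TRUE)
    pretrain(pre, desk_net_config(),
             train_config(lr = 1e-3, batch = 8, epochs = 12, seed = 42,
                          slices_per_subject = 10))
  })
}

# ---- independent metric oracles (deliberately naive) ------------------------

dsc_brute <- function(a, b) {
  a <- as.vector(a != 0); b <- as.vector(b != 0)
  inter <- 0; na <- 0; nb <- 0
  for (i in seq_along(a)) {
    if (a[i] && b[i]) inter <- inter + 1
    if (a[i]) na <- na + 1
    if (b[i]) nb <- nb + 1
  }
  if (na + nb == 0) return(NA_real_)
  2 * inter / (na + nb)
}

# a voxel is surface if any face neighbour is background or out of grid
surface_brute <- function(m) {
  d <- dim(m)
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!m[i, j, k]) next
    faces <- c(if (i > 1) m[i - 1, j, k] else FALSE,
               if (i < d[1]) m[i + 1, j, k] else FALSE,
               if (j > 1) m[i, j - 1, k] else FALSE,
               if (j < d[2]) m[i, j + 1, k] else FALSE,
               if (k > 1) m[i, j, k - 1] else FALSE,
               if (k < d[3]) m[i, j, k + 1] else FALSE)
    out[i, j, k] <- any(!faces)
  }
  out
}

asd_brute <- function(a, b, spacing = c(1, 1, 1)) {
  a <- a != 0; b <- b != 0
  if (!any(a) || !any(b)) return(NA_real_)
  sa <- which(surface_brute(a), arr.ind = TRUE)
  sb <- which(surface_brute(b), arr.ind = TRUE)
  pa <- sweep(sa - 1, 2, spacing, `*`)
  pb <- sweep(sb - 1, 2, spacing, `*`)
  d_ab <- vapply(seq_len(nrow(pa)), function(i)
    sqrt(min(colSums((t(pb) - pa[i, ])^2))), numeric(1))
  d_ba <- vapply(seq_len(nrow(pb)), function(i)
    sqrt(min(colSums((t(pa) - pb[i, ])^2))), numeric(1))
  (mean(d_ab) + mean(d_ba)) / 2
}

# ICC(3,1) straight from the two-way ANOVA table fitted by aov().
icc_aov <- function(x, y) {
  n <- length(x)
  df <- data.frame(score = c(x, y),
                   target = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(1:2, each = n)))
  tab <- summary(stats::aov(score ~ target + rater, data = df))[[1]]
  msr <- tab["target", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + mse)
}

random_small_mask <- function(d = c(3, 3, 1), p = 0.5) {
  array(runif(prod(d)) < p, d)
}
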