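#' View-model architecture configuration
#'
#' One 2D fully-convolutional encoder-decoder is trained per anatomical view;
#' all three share this configuration. Each dense block applies
#' (batch norm -> PReLU -> conv) three times -- two 5x5 convolutions whose
#' inputs are the concatenation of everything computed so far in the block,
#' then a 1x1 compression back to `base_channels` -- with one learnable PReLU
#' slope shared within the block. Four 2x2 max-pool stages (factor 2 each,
#' indices preserved) give the divisible-by-16 input rule; the decoder mirrors
#' them with unpooling plus encoder skip concatenation, and a 1x1
#' classifier maps to `classes` output channels.
#'
#' The default (64 base channels, 88 classes: 87 bilateral brain regions plus
#' background, the label space of the large automated-segmentation corpus
#' used for pre-training) has exactly 3,520,871 trainable parameters per
#' view, 10,562,613 for the three-view model. Phantom work uses
#' `classes = 5`.
#'
#' @param base_channels feature maps per block output (default 64).
#' @param classes output classes C >= 2 (default 88).
#' @param stages down-sampling stages (4 <=> inputs divisible by 16).
#' @param kernel spatial kernel of the two dense convolutions (default 5).
#' @param dropout spatial dropout rate applied to block outputs during
#'   training (default 0).
#' @param in_channels input channels (1 for a single MRI contrast).
#' @return An object of class `idseg_net_config`.
#' @export
view_model_config <- function(base_channels = 64, classes = 88, stages = 4,
                              kernel = 5, dropout = 0, in_channels = 1) {
  if (classes < 2) stop("classes must be >= 2")
  if (base_channels < 1 || in_channels < 1) stop("channels must be >= 1")
  structure(list(base_channels = as.integer(base_channels),
                 classes = as.integer(classes), stages = as.integer(stages),
                 kernel = as.integer(kernel), dropout = dropout,
                 in_channels = as.integer(in_channels),
                 divisor = 2L^as.integer(stages)),
            class = "idseg_net_config")
}

block_param_init <- function(cin, cfg) {
  F <- cfg$base_channels; k <- cfg$kernel
  list(bn1 = bn_init(cin), conv1 = conv_init(k, cin, F),
       bn2 = bn_init(cin + F), conv2 = conv_init(k, cin + F, F),
       bn3 = bn_init(cin + 2 * F), conv3 = conv_init(1, cin + 2 * F, F),
       a = 0.25)
}

block_state_init <- function(cin, cfg) {
  F <- cfg$base_channels
  list(bn1 = list(mean = numeric(cin), var = rep(1, cin)),
       bn2 = list(mean = numeric(cin + F), var = rep(1, cin + F)),
       bn3 = list(mean = numeric(cin + 2 * F), var = rep(1, cin + 2 * F)))
}

#' Build one 2D view network
#'
#' Instantiates the dense encoder-decoder of [view_model_config()] with
#' seeded He-initialized weights and returns the exact trainable-parameter
#' count alongside.
#'
#' @param config an [view_model_config()].
#' @param seed integer seed for weight initialization.
#' @return An `idseg_net`: `config`, `params` (nested list of arrays),
#'   `state` (batch-norm running moments) and `n_parameters`.
#' @export
build_view_model <- function(config = view_model_config(), seed = 1) {
  stopifnot(inherits(config, "idseg_net_config"))
  F <- config$base_channels
  cins <- c(config$in_channels, rep(F, config$stages - 1))
  with_seed(seed, {
    params <- list()
    state <- list()
    for (i in seq_len(config$stages)) {
      params[[paste0("enc", i)]] <- block_param_init(cins[i], config)
      state[[paste0("enc", i)]] <- block_state_init(cins[i], config)
    }
    params$bottleneck <- block_param_init(F, config)
    state$bottleneck <- block_state_init(F, config)
    for (i in seq_len(config$stages)) {
      params[[paste0("dec", i)]] <- block_param_init(2 * F, config)
      state[[paste0("dec", i)]] <- block_state_init(2 * F, config)
    }
    params$classifier <- conv_init(1, F, config$classes)
    net <- structure(list(config = config, params = params, state = state),
                     class = "idseg_net")
    net$n_parameters <- count_parameters(net)
    net
  })
}

#' Trainable-parameter count of a view network
#'
#' Sums the sizes of every trainable tensor (convolution weights and biases,
#' batch-norm scales and shifts, PReLU slopes); running moments are not
#' trainable and are excluded. A pure function of the configuration.
#'
#' @param net an `idseg_net`.
#' @return integer parameter count.
#' @export
count_parameters <- function(net) {
  n <- 0L
  walk <- function(x) {
    if (is.list(x)) for (el in x) walk(el) else n <<- n + length(x)
  }
  walk(net$params)
  n
}

#' @export
print.idseg_net <- function(x, ...) {
  cat(sprintf("<idseg_net> %d-channel dense encoder-decoder, %d stages, %d classes, %s trainable parameters\n",
              x$config$base_channels, x$config$stages, x$config$classes,
              format(x$n_parameters, big.mark = ",")))
  invisible(x)
}

# Dense block forward on a (H*W*N) x C_in activation matrix. Returns the
# (H*W*N) x F output and the caches needed for backward.
block_fwd <- function(m, P, S, training, hw) {
  k <- nrow_k(P$conv1)
  b1 <- bn_fwd(m, P$bn1$gamma, P$bn1$beta, S$bn1, training)
  p1 <- prelu_fwd(b1$y, P$a)
  c1 <- conv_fwd(p1$y, P$conv1$W, P$conv1$b, k, hw)
  x2 <- cbind(m, c1$y)
  b2 <- bn_fwd(x2, P$bn2$gamma, P$bn2$beta, S$bn2, training)
  p2 <- prelu_fwd(b2$y, P$a)
  c2 <- conv_fwd(p2$y, P$conv2$W, P$conv2$b, k, hw)
  x3 <- cbind(x2, c2$y)
  b3 <- bn_fwd(x3, P$bn3$gamma, P$bn3$beta, S$bn3, training)
  p3 <- prelu_fwd(b3$y, P$a)
  c3 <- conv_fwd(p3$y, P$conv3$W, P$conv3$b, 1, hw)
  list(y = c3$y,
       state = list(bn1 = b1$state, bn2 = b2$state, bn3 = b3$state),
       cache = list(b1 = b1$cache, b2 = b2$cache, b3 = b3$cache,
                    p1 = p1[c("pos", "x")], p2 = p2[c("pos", "x")],
                    p3 = p3[c("pos", "x")],
                    c1 = c1$cols, c2 = c2$cols, c3 = c3$cols,
                    cin = ncol(m), k = k, hw = hw))
}

nrow_k <- function(conv) attr(conv$W, "k") %||% 5L

block_bwd <- function(dy, P, cache) {
  k <- cache$k
  F <- ncol(P$conv1$W)
  cin <- cache$cin
  hw <- cache$hw
  cb3 <- conv_bwd(dy, cache$c3, P$conv3$W, 1, cin + 2 * F, hw)
  pb3 <- prelu_bwd(cb3$dx, P$a, cache$p3)
  bb3 <- bn_bwd(pb3$dx, P$bn3$gamma, cache$b3)
  dx <- bb3$dx[, seq_len(cin), drop = FALSE]
  do1 <- bb3$dx[, cin + seq_len(F), drop = FALSE]
  do2 <- bb3$dx[, cin + F + seq_len(F), drop = FALSE]

  cb2 <- conv_bwd(do2, cache$c2, P$conv2$W, k, cin + F, hw)
  pb2 <- prelu_bwd(cb2$dx, P$a, cache$p2)
  bb2 <- bn_bwd(pb2$dx, P$bn2$gamma, cache$b2)
  dx <- dx + bb2$dx[, seq_len(cin), drop = FALSE]
  do1 <- do1 + bb2$dx[, cin + seq_len(F), drop = FALSE]

  cb1 <- conv_bwd(do1, cache$c1, P$conv1$W, k, cin, hw)
  pb1 <- prelu_bwd(cb1$dx, P$a, cache$p1)
  bb1 <- bn_bwd(pb1$dx, P$bn1$gamma, cache$b1)
  dx <- dx + bb1$dx

  grads <- list(bn1 = list(gamma = bb1$dgamma, beta = bb1$dbeta),
                conv1 = list(W = cb1$dW, b = cb1$db),
                bn2 = list(gamma = bb2$dgamma, beta = bb2$dbeta),
                conv2 = list(W = cb2$dW, b = cb2$db),
                bn3 = list(gamma = bb3$dgamma, beta = bb3$dbeta),
                conv3 = list(W = cb3$dW, b = cb3$db),
                a = pb1$da + pb2$da + pb3$da)
  list(dx = dx, grads = grads)
}

# Full forward pass over a batch of slices given as a (H*W*N) x 1 matrix.
# Spatial dropout (inverted scaling) is applied to block outputs when
# training with a positive rate; masks are cached for the backward pass.
net_fwd <- function(net, x, hw, training = FALSE) {
  cfg <- net$config
  P <- net$params; S <- net$state
  caches <- list(); skips <- list(); idxs <- list(); hws <- list()
  drop <- list()
  maybe_drop <- function(y, nm) {
    if (!training || cfg$dropout <= 0) return(y)
    mask <- matrix(runif(length(y)) >= cfg$dropout, nrow(y)) /
      (1 - cfg$dropout)
    drop[[nm]] <<- mask
    y * mask
  }
  h <- x
  for (i in seq_len(cfg$stages)) {
    nm <- paste0("enc", i)
    bf <- block_fwd(h, P[[nm]], S[[nm]], training, hw)
    if (training) S[[nm]] <- bf$state
    caches[[nm]] <- bf$cache
    y <- maybe_drop(bf$y, nm)
    skips[[i]] <- y
    pf <- pool_fwd(y, hw)
    idxs[[i]] <- pf$idx; hws[[i]] <- hw
    hw <- c(hw[1] / 2, hw[2] / 2, hw[3])
    h <- pf$y
  }
  bf <- block_fwd(h, P$bottleneck, S$bottleneck, training, hw)
  if (training) S$bottleneck <- bf$state
  caches$bottleneck <- bf$cache
  h <- maybe_drop(bf$y, "bottleneck")
  for (i in rev(seq_len(cfg$stages))) {
    nm <- paste0("dec", i)
    hw <- hws[[i]]
    up <- unpool_fwd(h, idxs[[i]], prod(hw), cfg$base_channels)
    hcat <- cbind(skips[[i]], up)
    bf <- block_fwd(hcat, P[[nm]], S[[nm]], training, hw)
    if (training) S[[nm]] <- bf$state
    caches[[nm]] <- bf$cache
    h <- if (i > 1) maybe_drop(bf$y, nm) else bf$y
  }
  cc <- conv_fwd(h, P$classifier$W, P$classifier$b, 1, hw)
  caches$classifier <- cc$cols
  list(logits = cc$y, caches = caches, idxs = idxs, hws = hws,
       state = S, drop = drop)
}

# Backward from d(logits); returns nested gradient list mirroring params.
# When `groups` is given, backpropagation stops at the deepest group that
# still needs a gradient (used by the frozen fine-tuning phase, where only
# the classifier and the full-resolution decoder block are trainable).
net_bwd <- function(net, fwd, dlogits, groups = NULL) {
  cfg <- net$config
  P <- net$params
  F <- cfg$base_channels
  stations <- c("classifier", paste0("dec", seq_len(cfg$stages)),
                "bottleneck", paste0("enc", rev(seq_len(cfg$stages))))
  last_needed <- if (is.null(groups)) length(stations)
  else max(match(groups, stations))
  grads <- list()
  undrop <- function(dy, nm) {
    if (!is.null(fwd$drop[[nm]])) dy * fwd$drop[[nm]] else dy
  }
  hw1 <- fwd$caches$dec1$hw
  cb <- conv_bwd(dlogits, fwd$caches$classifier, P$classifier$W, 1, F, hw1)
  grads$classifier <- list(W = cb$dW, b = cb$db)
  dh <- cb$dx
  dskips <- vector("list", cfg$stages)
  for (i in seq_len(cfg$stages)) {
    nm <- paste0("dec", i)
    if (match(nm, stations) > last_needed) return(grads)
    if (i > 1) dh <- undrop(dh, nm)
    bb <- block_bwd(dh, P[[nm]], fwd$caches[[nm]])
    grads[[nm]] <- bb$grads
    dskips[[i]] <- bb$dx[, seq_len(F), drop = FALSE]
    dh <- unpool_bwd(bb$dx[, F + seq_len(F), drop = FALSE], fwd$idxs[[i]])
  }
  if (match("bottleneck", stations) > last_needed) return(grads)
  dh <- undrop(dh, "bottleneck")
  bb <- block_bwd(dh, P$bottleneck, fwd$caches$bottleneck)
  grads$bottleneck <- bb$grads
  dh <- bb$dx
  for (i in rev(seq_len(cfg$stages))) {
    nm <- paste0("enc", i)
    if (match(nm, stations) > last_needed) return(grads)
    dpool <- pool_bwd(dh, fwd$idxs[[i]], prod(fwd$hws[[i]]), F)
    denc <- undrop(dpool + dskips[[i]], nm)
    bb <- block_bwd(denc, P[[nm]], fwd$caches[[nm]])
    grads[[nm]] <- bb$grads
    dh <- bb$dx
  }
  grads
}

#' Per-view class probabilities for a conformed volume
#'
#' Extracts the slice stack for the requested view, pushes slices through the
#' network in inference mode (batch-norm running moments, no dropout), maps
#' class scores through a softmax, and restacks the per-class probability
#' grids to 3D. Deterministic for fixed weights.
#'
#' @param net an `idseg_net`.
#' @param vol a conformed [volume3d()].
#' @param view `"axial"`, `"coronal"` or `"sagittal"`.
#' @param batch slices per forward batch.
#' @return 4D array `(X, Y, Z, classes)` of voxel probabilities (sum 1 per
#'   voxel), with attribute `view`.
#' @export
predict_view_probs <- function(net, vol, view, batch = 8) {
  cfg <- net$config
  arr <- if (inherits(vol, "idseg_volume")) vol$voxels else vol
  if (any(dim(arr) %% cfg$divisor != 0))
    stop("volume is not conformed: dimensions must be divisible by ",
         cfg$divisor)
  stack <- extract_slices(arr, view)
  ns <- dim(stack)[3]
  H <- dim(stack)[1]; W <- dim(stack)[2]
  probs <- array(0, c(H, W, ns, cfg$classes))
  for (start in seq(1, ns, by = batch)) {
    sel <- start:min(start + batch - 1, ns)
    x <- matrix(stack[, , sel], ncol = 1)
    out <- net_fwd(net, x, c(H, W, length(sel)), training = FALSE)
    p <- softmax_rows(out$logits)            # (H*W*n) x C
    probs[, , sel, ] <- array(p, c(H, W, length(sel), cfg$classes))
  }
  full <- array(0, c(dim(arr), cfg$classes))
  for (cl in seq_len(cfg$classes))
    full[, , , cl] <- restack_slices(probs[, , , cl], view)
  attr(full, "view") <- view
  full
}

#' Fusion weights for the three views
#'
#' @param axial,coronal,sagittal nonnegative weights summing to 1 (default
#'   0.4 / 0.4 / 0.2).
#' @return named numeric vector of class `idseg_fusion_weights`.
#' @export
fusion_weights <- function(axial = 0.4, coronal = 0.4, sagittal = 0.2) {
  w <- c(axial = axial, coronal = coronal, sagittal = sagittal)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
    stop("fusion weights must be nonnegative and sum to 1")
  structure(w, class = "idseg_fusion_weights")
}

#' Weighted multi-view probability fusion
#'
#' Per voxel, the final label maximizes the weighted sum of the three view
#' probabilities. Ties are broken toward the lowest class index (so exact
#' ties involving background go to background).
#'
#' @param pa,pc,ps 4D probability arrays from [predict_view_probs()] for the
#'   axial, coronal and sagittal views, on identical grids.
#' @param w a [fusion_weights()] vector.
#' @param spacing voxel spacing for the output label map.
#' @param label_set label codes, by default `0:(C-1)` matching class order.
#' @return An [label_map()] of fused labels.
#' @export
fuse_views <- function(pa, pc, ps, w = fusion_weights(),
                       spacing = c(1, 1, 1), label_set = NULL) {
  if (!identical(dim(pa), dim(pc)) || !identical(dim(pa), dim(ps)))
    stop("probability grids must match")
  if (!inherits(w, "idseg_fusion_weights")) w <- do.call(fusion_weights, as.list(w))
  d <- dim(pa)
  C <- d[4]
  fused <- w[["axial"]] * pa + w[["coronal"]] * pc + w[["sagittal"]] * ps
  m <- matrix(fused, prod(d[1:3]), C)
  lab <- max.col(m, ties.method = "first") - 1L
  label_map(array(lab, d[1:3]), label_set = label_set %||% (0:(C - 1)),
            spacing = spacing)
}
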