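#' Training configuration
#'
#' @param lr learning rate of the adaptive-moment (Adam) optimizer.
#' @param batch slices per gradient step (>= 1).
#' @param epochs passes over the (sampled) training slices.
#' @param val_fraction fraction of subjects held out for validation during
#'   pre-training (0 < f < 1; the training side takes the floor).
#' @param seed seed controlling the split, slice sampling and weight init.
#' @param slice_keep_empty fraction of foreground-free slices retained per
#'   subject and view (default 0.25).
#' @param slices_per_subject cap on slices sampled per subject per epoch
#'   (across views); `Inf` uses all retained slices.
#' @return An `idseg_train_config`.
#' @export
train_config <- function(lr = 1e-3, batch = 8, epochs = 10,
                         val_fraction = 0.2, seed = 1,
                         slice_keep_empty = 0.25,
                         slices_per_subject = Inf) {
  stopifnot(batch >= 1, val_fraction > 0, val_fraction < 1)
  structure(list(lr = lr, batch = as.integer(batch),
                 epochs = as.integer(epochs), val_fraction = val_fraction,
                 seed = as.integer(seed), slice_keep_empty = slice_keep_empty,
                 slices_per_subject = slices_per_subject),
            class = "idseg_train_config")
}

#' Fine-tuning schedule
#'
#' Two-phase transfer learning: phase 1 trains only the final layers (by
#' default the classifier and the full-resolution decoder block) for
#' `frozen_epochs` to avoid propagating errors from a randomly initialized
#' head, then phase 2 unfreezes everything for `full_epochs`. The defaults
#' (5 + 15 epochs, learning rate 5e-4, batch 8) are the transfer protocol
#' this package ships.
#'
#' @param frozen_epochs phase-1 epochs (>= 0).
#' @param full_epochs phase-2 epochs (>= 0).
#' @param lr learning rate for both phases.
#' @param batch slices per gradient step.
#' @param unfreeze parameter groups trainable in phase 1.
#' @return An `idseg_schedule`.
#' @export
finetune_schedule <- function(frozen_epochs = 5, full_epochs = 15,
                              lr = 5e-4, batch = 8,
                              unfreeze = c("classifier", "dec1")) {
  stopifnot(frozen_epochs >= 0, full_epochs >= 0)
  structure(list(frozen_epochs = as.integer(frozen_epochs),
                 full_epochs = as.integer(full_epochs), lr = lr,
                 batch = as.integer(batch), unfreeze = unfreeze),
            class = "idseg_schedule")
}

# ---- loss -------------------------------------------------------------------

# Class weights by median-frequency balancing over a list of label arrays.
class_weights <- function(labels_list, classes) {
  counts <- numeric(classes)
  for (lab in labels_list)
    counts <- counts + tabulate(as.vector(lab) + 1L, nbins = classes)
  freq <- counts / sum(counts)
  freq[freq == 0] <- min(freq[freq > 0])
  w <- stats::median(freq) / freq
  pmin(pmax(w, 0.05), 50)
}

# Composite loss: class-weighted cross-entropy plus soft-Dice over foreground
# classes. Logits and one-hot targets are (voxels x C) matrices; returns the
# loss value and its gradient w.r.t. the logits.
seg_loss <- function(logits, target, classw, eps = 1e-6) {
  C <- ncol(logits)
  pm <- softmax_rows(logits)
  tm <- target
  n <- nrow(pm)
  wvox <- as.vector(tm %*% classw)
  ce <- -sum(wvox * log(rowSums(pm * tm) + 1e-12)) / sum(wvox)
  # d(ce)/d(logits) = w * (p - t) / sum(w)
  gce <- (pm - tm) * wvox / sum(wvox)
  fg <- 2:C
  sp <- colSums(pm); st <- colSums(tm); spt <- colSums(pm * tm)
  dice_c <- (2 * spt[fg] + eps) / (sp[fg] + st[fg] + eps)
  dice_loss <- 1 - mean(dice_c)
  gdice_p <- matrix(0, n, C)
  for (j in seq_along(fg)) {
    cidx <- fg[j]
    S <- sp[cidx] + st[cidx] + eps
    gdice_p[, cidx] <- -(2 * tm[, cidx] * S - (2 * spt[cidx] + eps)) /
      (S^2 * length(fg))
  }
  # chain dice grad through the softmax
  inner <- rowSums(gdice_p * pm)
  gdice <- pm * (gdice_p - inner)
  list(loss = ce + dice_loss, grad = gce + gdice, ce = ce, dice = dice_loss)
}

# ---- optimizer --------------------------------------------------------------

adam_init <- function(params) rapply(params, function(p) {
  list(m = p * 0, v = p * 0)
}, how = "replace", classes = c("matrix", "numeric", "array"))

# Walk params/grads/state in lockstep and apply the Adam update to groups
# listed in `trainable`.
adam_step <- function(params, grads, opt, lr, t, trainable = NULL,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  upd_leaf <- function(p, g, o) {
    o$m <- b1 * o$m + (1 - b1) * g
    o$v <- b2 * o$v + (1 - b2) * g^2
    mhat <- o$m / (1 - b1^t)
    vhat <- o$v / (1 - b2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), o = o)
  }
  walk <- function(p, g, o) {
    if (is.list(p) && !is.null(names(p)) && is.list(g)) {
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], o[[nm]])
        p[[nm]] <- r$p; o[[nm]] <- r$o
      }
      list(p = p, o = o)
    } else {
      k <- attr(p, "k")
      r <- upd_leaf(p, g, o)
      if (!is.null(k)) attr(r$p, "k") <- k
      r
    }
  }
  for (grp in names(params)) {
    if (!is.null(trainable) && !(grp %in% trainable)) next
    if (is.null(grads[[grp]])) next
    r <- walk(params[[grp]], grads[[grp]], opt[[grp]])
    params[[grp]] <- r$p; opt[[grp]] <- r$o
  }
  list(params = params, opt = opt)
}

# ---- slice dataset ----------------------------------------------------------

VIEWS <- c("axial", "coronal", "sagittal")

# Pre-extract per-view slice stacks and per-slice foreground flags.
make_slice_data <- function(dataset, view) {
  lapply(dataset, function(sub) {
    x <- extract_slices(sub$volume$voxels, view)
    y <- extract_slices(sub$labels$codes, view)
    fg <- apply(y > 0, 3, any)
    list(x = x, y = y, fg = fg)
  })
}

# Sample slice indices for one epoch: all foreground slices plus a fraction
# of empty ones, optionally capped (foreground slices first).
sample_slices <- function(sd, keep_empty, cap) {
  do.call(rbind, lapply(seq_along(sd), function(si) {
    fg <- which(sd[[si]]$fg)
    emp <- which(!sd[[si]]$fg)
    emp <- emp[runif(length(emp)) < keep_empty]
    idx <- c(fg, emp)
    if (length(idx) > cap) idx <- sort(idx[sample.int(length(idx), cap)])
    cbind(si, idx)
  }))
}

# One-hot encode a label vector (codes 0..C-1, row order h + Hw + HWn) into
# a (voxels x C) matrix.
onehot_slices <- function(y, C) {
  n <- length(y)
  m <- matrix(0, n, C)
  m[cbind(seq_len(n), as.vector(y) + 1L)] <- 1
  m
}

# One training epoch of a single view net over sampled slices.
train_epoch <- function(net, opt, sd, cfg_t, classw, trainable, step0) {
  pairs <- sample_slices(sd, cfg_t$slice_keep_empty,
                         if (is.finite(cfg_t$slices_per_subject))
                           cfg_t$slices_per_subject else .Machine$integer.max)
  pairs <- matrix(pairs, ncol = 2)
  pairs <- pairs[sample.int(nrow(pairs)), , drop = FALSE]
  C <- net$config$classes
  total <- 0; nb <- 0
  t <- step0
  d2 <- dim(sd[[1]]$x)[1:2]
  for (start in seq(1, nrow(pairs), by = cfg_t$batch)) {
    sel <- start:min(start + cfg_t$batch - 1, nrow(pairs))
    xb <- matrix(vapply(sel, function(r) sd[[pairs[r, 1]]]$x[, , pairs[r, 2]],
                        sd[[1]]$x[, , 1]), ncol = 1)
    yb <- vapply(sel, function(r) sd[[pairs[r, 1]]]$y[, , pairs[r, 2]],
                 sd[[1]]$y[, , 1] * 1)
    tb <- onehot_slices(yb, C)
    fwd <- net_fwd(net, xb, c(d2, length(sel)), training = TRUE)
    net$state <- fwd$state
    ls <- seg_loss(fwd$logits, tb, classw)
    grads <- net_bwd(net, fwd, ls$grad, groups = trainable)
    t <- t + 1
    st <- adam_step(net$params, grads, opt, cfg_t$lr, t, trainable)
    net$params <- st$params; opt <- st$opt
    total <- total + ls$loss; nb <- nb + 1
  }
  list(net = net, opt = opt, loss = total / max(nb, 1), steps = t)
}

# Mean loss of a view net over all foreground slices (inference mode).
eval_loss <- function(net, sd, classw, batch = 8) {
  C <- net$config$classes
  total <- 0; nb <- 0
  for (si in seq_along(sd)) {
    idx <- which(sd[[si]]$fg)
    if (!length(idx)) next
    d2 <- dim(sd[[si]]$x)[1:2]
    for (start in seq(1, length(idx), by = batch)) {
      sel <- idx[start:min(start + batch - 1, length(idx))]
      xb <- matrix(sd[[si]]$x[, , sel], ncol = 1)
      tb <- onehot_slices(sd[[si]]$y[, , sel], C)
      fwd <- net_fwd(net, xb, c(d2, length(sel)), training = FALSE)
      ls <- seg_loss(fwd$logits, tb, classw)
      total <- total + ls$loss; nb <- nb + 1
    }
  }
  total / max(nb, 1)
}

# ---- high-level training ----------------------------------------------------

#' Pre-train the three view networks
#'
#' Splits subjects into training and validation sets by a seeded shuffle
#' (the training side takes the floor of `n * (1 - val_fraction)`), trains
#' one network per anatomical view on that view's slices, and for each view
#' keeps the epoch checkpoint with the lowest validation loss.
#'
#' @param dataset list of subjects, each `list(volume, labels)`, all
#'   conformed to the network's divisibility rule.
#' @param net_config an [view_model_config()].
#' @param config an [train_config()].
#' @return An `idseg_model`: per-view `idseg_net`s, class weights, split
#'   membership and loss history.
#' @export
pretrain <- function(dataset, net_config = view_model_config(classes = 5),
                     config = train_config()) {
  if (length(dataset) < 2) stop("need at least 2 subjects")
  check_dataset(dataset, net_config)
  n <- length(dataset)
  n_train <- floor(n * (1 - config$val_fraction))
  with_seed(config$seed, {
    perm <- sample.int(n)
    tr <- sort(perm[seq_len(n_train)])
    va <- sort(perm[seq(n_train + 1, n)])
    classw <- class_weights(lapply(dataset[tr], function(s) s$labels$codes),
                            net_config$classes)
    nets <- list(); history <- list()
    for (view in VIEWS) {
      sd_tr <- make_slice_data(dataset[tr], view)
      sd_va <- make_slice_data(dataset[va], view)
      net <- build_view_model(net_config, seed = config$seed +
                                match(view, VIEWS))
      opt <- adam_init(net$params)
      best <- list(loss = Inf, net = net)
      trace <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_loss = numeric(0))
      steps <- 0
      for (ep in seq_len(config$epochs)) {
        r <- train_epoch(net, opt, sd_tr, config, classw, NULL, steps)
        net <- r$net; opt <- r$opt; steps <- r$steps
        vl <- eval_loss(net, sd_va, classw, config$batch)
        trace <- rbind(trace, data.frame(epoch = ep, train_loss = r$loss,
                                         val_loss = vl))
        if (vl < best$loss) best <- list(loss = vl, net = net)
      }
      nets[[view]] <- best$net
      history[[view]] <- trace
    }
    structure(list(nets = nets, net_config = net_config,
                   class_weights = classw,
                   split = list(train = tr, validation = va),
                   history = history),
              class = "idseg_model")
  })
}

check_dataset <- function(dataset, net_config) {
  for (s in dataset) {
    if (is.null(s$labels)) stop("dataset subject with missing labels")
    if (any(dim(s$volume$voxels) %% net_config$divisor != 0))
      stop("subjects must be conformed (dims divisible by ",
           net_config$divisor, ")")
  }
  invisible(TRUE)
}

#' Fine-tune (or train from scratch) on a target dataset
#'
#' With pre-trained initial weights, phase 1 updates only the parameter
#' groups in `schedule$unfreeze` (parameter deltas elsewhere are exactly
#' zero), then phase 2 fine-tunes the whole network. With `init = NULL` (the
#' no-pretraining ablation arm) phase 1 is skipped and all layers train from
#' random initialization for the combined epoch budget.
#'
#' @param init an `idseg_model`, or `NULL` for the ablation arm.
#' @param dataset list of conformed subjects.
#' @param schedule an [finetune_schedule()].
#' @param net_config used when `init = NULL`.
#' @param seed seed for slice sampling (and weight init when `init = NULL`).
#' @return An `idseg_model` with a per-view loss trace in `$history`.
#' @export
finetune <- function(init, dataset, schedule = finetune_schedule(),
                     net_config = view_model_config(classes = 5), seed = 1,
                     slice_keep_empty = 0.25, slices_per_subject = Inf) {
  if (!is.null(init)) {
    stopifnot(inherits(init, "idseg_model"))
    net_config <- init$net_config
  }
  check_dataset(dataset, net_config)
  cfg_t <- train_config(lr = schedule$lr, batch = schedule$batch, epochs = 1,
                        seed = seed, slice_keep_empty = slice_keep_empty,
                        slices_per_subject = slices_per_subject)
  classw <- class_weights(lapply(dataset, function(s) s$labels$codes),
                          net_config$classes)
  with_seed(seed, {
    nets <- list(); history <- list()
    for (view in VIEWS) {
      sd <- make_slice_data(dataset, view)
      net <- if (is.null(init)) build_view_model(net_config, seed = seed +
                                                   match(view, VIEWS))
      else init$nets[[view]]
      opt <- adam_init(net$params)
      trace <- data.frame(epoch = integer(0), phase = character(0),
                          train_loss = numeric(0))
      steps <- 0
      phase1 <- if (is.null(init)) 0L else schedule$frozen_epochs
      phase2 <- schedule$full_epochs +
        if (is.null(init)) schedule$frozen_epochs else 0L
      for (ep in seq_len(phase1)) {
        r <- train_epoch(net, opt, sd, cfg_t, classw, schedule$unfreeze,
                         steps)
        net <- r$net; opt <- r$opt; steps <- r$steps
        trace <- rbind(trace, data.frame(epoch = ep, phase = "frozen",
                                         train_loss = r$loss))
      }
      for (ep in seq_len(phase2)) {
        r <- train_epoch(net, opt, sd, cfg_t, classw, NULL, steps)
        net <- r$net; opt <- r$opt; steps <- r$steps
        trace <- rbind(trace, data.frame(epoch = phase1 + ep, phase = "full",
                                         train_loss = r$loss))
      }
      nets[[view]] <- net
      history[[view]] <- trace
    }
    structure(list(nets = nets, net_config = net_config,
                   class_weights = classw, history = history),
              class = "idseg_model")
  })
}

#' @export
print.idseg_model <- function(x, ...) {
  cat(sprintf("<idseg_model> three-view 2D segmentation model (%d classes, %d base channels)\n",
              x$net_config$classes, x$net_config$base_channels))
  cat(sprintf("  %s trainable parameters per view, %s total\n",
              format(x$nets[[1]]$n_parameters, big.mark = ","),
              format(3 * x$nets[[1]]$n_parameters, big.mark = ",")))
  invisible(x)
}

#' Segment a volume with a trained three-view model
#'
#' Runs the three view networks, fuses their probabilities with the given
#' weights, and returns the fused label map.
#'
#' @param object an `idseg_model`.
#' @param vol a conformed [volume3d()].
#' @param lambdas a [fusion_weights()] vector (default 0.4/0.4/0.2).
#' @param ... unused.
#' @return An [label_map()].
#' @export
predict.idseg_model <- function(object, vol, lambdas = fusion_weights(),
                                ...) {
  pa <- predict_view_probs(object$nets$axial, vol, "axial")
  pc <- predict_view_probs(object$nets$coronal, vol, "coronal")
  ps <- predict_view_probs(object$nets$sagittal, vol, "sagittal")
  fuse_views(pa, pc, ps, lambdas, spacing = vol$spacing)
}

#' Leave-one-out cross-validation
#'
#' For each subject, fine-tunes a model on the remaining subjects (starting
#' from `init`, or from random initialization when `init = NULL`), predicts
#' the held-out subject by multi-view prediction and fusion, and evaluates
#' the prediction against the subject's reference labels. The held-out
#' subject contributes no gradient step in its fold; the training ids of
#' each fold are recorded so leakage is checkable.
#'
#' @param dataset list of conformed subjects (n >= 3).
#' @param init pre-trained `idseg_model` or `NULL`.
#' @param schedule an [finetune_schedule()].
#' @param seed base seed; fold i uses `seed + i`.
#' @param ... passed to [finetune()].
#' @return An `idseg_loocv`: list of fold results (held-out index, training
#'   ids, metrics, trace) plus the per-structure metric aggregate.
#' @export
loocv <- function(dataset, init = NULL, schedule = finetune_schedule(),
                  seed = 1, lambdas = fusion_weights(), ...) {
  n <- length(dataset)
  if (n < 3) stop("LOOCV needs at least 3 subjects")
  folds <- vector("list", n)
  for (i in seq_len(n)) {
    train_ids <- setdiff(seq_len(n), i)
    model <- finetune(init, dataset[train_ids], schedule, seed = seed + i,
                      ...)
    pred <- predict(model, dataset[[i]]$volume, lambdas)
    metrics <- evaluate_pair(pred, dataset[[i]]$labels)
    fg_dsc <- dsc(pred$codes > 0, dataset[[i]]$labels$codes > 0)
    folds[[i]] <- list(held_out = i, train_ids = train_ids,
                       prediction = pred, metrics = metrics,
                       foreground_dsc = fg_dsc,
                       trace = model$history)
  }
  structure(list(folds = folds,
                 summary = aggregate_metrics(lapply(folds, `[[`, "metrics")),
                 mean_foreground_dsc =
                   mean(vapply(folds, `[[`, numeric(1), "foreground_dsc"))),
            class = "idseg_loocv")
}

#' @export
print.idseg_loocv <- function(x, ...) {
  cat(sprintf("<idseg_loocv> %d folds, mean held-out foreground DSC %.3f\n",
              length(x$folds), x$mean_foreground_dsc))
  print(x$summary)
  invisible(x)
}
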