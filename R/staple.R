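#' STAPLE fusion of binary rater masks
#'
#' Simultaneous Truth and Performance Level Estimation: an
#' expectation-maximization algorithm that alternates between estimating the
#' per-voxel posterior probability of the true segmentation (E-step) and each
#' rater's sensitivity `p_j` and specificity `q_j` (M-step), yielding a
#' probabilistic consensus that weights raters by their estimated
#' performance.
#'
#' The computation is restricted to a bounding box of the union mask dilated
#' by `roi_dilate` voxels: with the whole skull-stripped background included,
#' the enormous number of trivially-agreeing background voxels pins every
#' specificity at 1 and flattens the prior. Set `roi_dilate = Inf` to use the
#' full grid.
#'
#' @param stack list of k binary masks (logical/0-1 arrays of equal shape),
#'   or a 2D matrix voxels x raters.
#' @param prior scalar prior probability of foreground, or `"auto"` (mean
#'   foreground fraction across raters inside the ROI).
#' @param tol convergence tolerance on `max(|dp|, |dq|)`.
#' @param max_iter iteration cap.
#' @param roi_dilate dilation of the union bounding box, voxels.
#' @return An `idseg_staple` object: `posterior` (full-grid array in
#'   `[0, 1]`), `consensus` (posterior >= 0.5), per-rater `sensitivity` and
#'   `specificity`, `prior`, `iterations`, `converged`, and the per-iteration
#'   observed-data `log_likelihood` trace (non-decreasing).
#' @export
staple_binary <- function(stack, prior = "auto", tol = 1e-6, max_iter = 100,
                          roi_dilate = 5) {
  if (is.list(stack)) {
    arrs <- lapply(stack, function(m) {
      if (inherits(m, "idseg_labels")) m <- m$codes
      m != 0
    })
    shp <- dim(arrs[[1]])
    if (!all(vapply(arrs, function(a) identical(dim(a), shp), logical(1))))
      stop("rater masks must share a grid")
    D_full <- vapply(arrs, as.vector, numeric(prod(shp)))
  } else {
    D_full <- stack != 0
    storage.mode(D_full) <- "double"
    shp <- NULL
    arrs <- NULL
  }
  k <- ncol(D_full)
  if (k < 2) stop("need at least 2 raters")
  tot <- sum(D_full)
  if (tot == 0 || tot == length(D_full))
    stop("degenerate stack: all raters empty or all full")

  if (!is.null(shp) && is.finite(roi_dilate)) {
    union <- Reduce(`|`, arrs)
    idx <- which(union, arr.ind = TRUE)
    lo <- pmax(apply(idx, 2, min) - roi_dilate, 1)
    hi <- pmin(apply(idx, 2, max) + roi_dilate, shp)
    roi <- array(FALSE, shp)
    roi[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
    sel <- as.vector(roi)
  } else sel <- rep(TRUE, nrow(D_full))
  D <- D_full[sel, , drop = FALSE]

  f <- if (identical(prior, "auto")) mean(D) else as.numeric(prior)
  f <- min(max(f, 1e-5), 1 - 1e-5)
  clamp <- function(x) pmin(pmax(x, 1e-5), 1 - 1e-5)
  p <- rep(0.99999, k)
  q <- rep(0.99999, k)
  ll_trace <- numeric(0)
  converged <- FALSE
  it <- 0
  W <- NULL
  repeat {
    it <- it + 1
    # E-step in log space
    la <- log(f) + D %*% log(p) + (1 - D) %*% log(1 - p)
    lb <- log(1 - f) + (1 - D) %*% log(q) + D %*% log(1 - q)
    m <- pmax(la, lb)
    ll_trace <- c(ll_trace, sum(m + log(exp(la - m) + exp(lb - m))))
    W <- 1 / (1 + exp(lb - la))
    # M-step
    sw <- sum(W); swn <- sum(1 - W)
    p_new <- clamp(as.vector(crossprod(D, W)) / sw)
    q_new <- clamp(as.vector(crossprod(1 - D, 1 - W)) / swn)
    delta <- max(abs(p_new - p), abs(q_new - q))
    p <- p_new; q <- q_new
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  post <- numeric(nrow(D_full))
  post[sel] <- as.vector(W)
  if (!is.null(shp)) post <- array(post, shp)
  structure(list(posterior = post, consensus = post >= 0.5,
                 sensitivity = p, specificity = q, prior = f,
                 iterations = it, converged = converged,
                 log_likelihood = ll_trace),
            class = "idseg_staple")
}

#' @export
print.idseg_staple <- function(x, ...) {
  cat(sprintf("<idseg_staple> %d raters, %d iterations (%sconverged)\n",
              length(x$sensitivity), x$iterations,
              if (x$converged) "" else "not "))
  cat("  sensitivity:", paste(sprintf("%.3f", x$sensitivity), collapse = " "),
      "\n  specificity:", paste(sprintf("%.3f", x$specificity), collapse = " "),
      "\n")
  invisible(x)
}

#' Multi-label consensus via per-structure STAPLE
#'
#' Runs [staple_binary()] once per non-background label and assigns each
#' voxel the label with the highest posterior among those reaching 0.5, else
#' background. Invariant to rater order.
#'
#' @param maps list of [label_map()] objects sharing grid and label set.
#' @param ... passed to [staple_binary()].
#' @return An `idseg_labels` consensus, with the per-structure
#'   `idseg_staple` fits in attribute `staple_fits`.
#' @export
consensus_multilabel <- function(maps, ...) {
  stopifnot(length(maps) >= 2, all(vapply(maps, inherits, logical(1),
                                          "idseg_labels")))
  ls <- maps[[1]]$label_set
  if (!all(vapply(maps, function(m) identical(m$label_set, ls), logical(1))))
    stop("inconsistent label sets")
  shp <- dim(maps[[1]]$codes)
  structures <- setdiff(ls, 0L)
  best_post <- array(0, shp)
  codes <- array(0L, shp)
  fits <- list()
  for (s in structures) {
    masks <- lapply(maps, function(m) m$codes == s)
    if (!any(vapply(masks, any, logical(1)))) next
    fit <- staple_binary(masks, ...)
    fits[[as.character(s)]] <- fit
    take <- fit$posterior >= 0.5 & fit$posterior > best_post
    codes[take] <- s
    best_post <- pmax(best_post, fit$posterior * (fit$posterior >= 0.5))
  }
  out <- label_map(codes, label_set = ls, spacing = maps[[1]]$spacing)
  attr(out, "staple_fits") <- fits
  out
}

#' Inter-rater quality control
#'
#' Mean pairwise Dice agreement per structure across raters, with a pass
#' flag at the inclusive threshold. A structure empty in every rater has an
#' undefined DSC: it is reported as `NA` and flagged as failing rather than
#' crashing.
#'
#' @param maps list of [label_map()] objects (>= 2).
#' @param threshold minimum acceptable mean pairwise DSC (default 0.6;
#'   equality passes).
#' @return data.frame: structure, mean pairwise DSC, n pairs, pass flag;
#'   attribute `pass` gives the overall verdict.
#' @export
interrater_qc <- function(maps, threshold = 0.6) {
  stopifnot(length(maps) >= 2)
  ls <- maps[[1]]$label_set
  structures <- setdiff(ls, 0L)
  k <- length(maps)
  rows <- lapply(structures, function(s) {
    vals <- c()
    for (a in seq_len(k - 1)) for (b in seq(a + 1, k))
      vals <- c(vals, dsc(maps[[a]]$codes == s, maps[[b]]$codes == s))
    m <- if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
    data.frame(structure = IDSEG_STRUCTURES[match(s, structures)], code = s,
               mean_pairwise_dsc = m, n_pairs = sum(!is.na(vals)),
               pass = !is.na(m) && m >= threshold)
  })
  out <- do.call(rbind, rows)
  attr(out, "pass") <- all(out$pass)
  attr(out, "threshold") <- threshold
  out
}
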