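#' Dice similarity coefficient
#'
#' `2|A & B| / (|A| + |B|)`. Symmetric; 1 for identical nonempty masks, 0 for
#' disjoint ones. When both masks are empty the value is undefined and `NA`
#' is returned (callers exclude it from means).
#'
#' @param a,b binary masks (logical or 0/1 arrays) on the same grid.
#' @return DSC in `[0, 1]`, or `NA` when both masks are empty.
#' @export
dsc <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("grid mismatch")
  a <- a != 0; b <- b != 0
  s <- sum(a) + sum(b)
  if (s == 0) return(NA_real_)
  2 * sum(a & b) / s
}

# dilate a bounding box of the union by `dilate` voxels, clipped to the grid
union_bbox <- function(a, b, dilate = 5) {
  u <- which((a != 0) | (b != 0), arr.ind = TRUE)
  if (nrow(u) == 0) return(NULL)
  shp <- dim(a)
  lo <- pmax(apply(u, 2, min) - dilate, 1)
  hi <- pmin(apply(u, 2, max) + dilate, shp)
  list(lo = lo, hi = hi)
}

#' Intra-class correlation between two masks
#'
#' ICC(3,1): two-way mixed model, consistency, single measure, computed on
#' the paired voxel values within an analysis region. The default region is
#' the union bounding box dilated by 5 voxels -- over the full volume the
#' metric is dominated by the trivially-agreeing background and loses
#' discrimination.
#'
#' @param a,b binary masks on the same grid.
#' @param roi_dilate dilation of the union bounding box (Inf for full grid).
#' @return ICC in `[-1, 1]`, or `NA` when the paired values have no variance.
#' @export
icc_masks <- function(a, b, roi_dilate = 5) {
  if (!identical(dim(a), dim(b))) stop("grid mismatch")
  a <- a != 0; b <- b != 0
  if (is.finite(roi_dilate)) {
    bb <- union_bbox(a, b, roi_dilate)
    if (is.null(bb)) return(NA_real_)
    a <- a[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3]]
    b <- b[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3]]
  }
  icc31(cbind(as.numeric(a), as.numeric(b)))
}

# ICC(3,1) from the two-way ANOVA decomposition of an n x k ratings matrix.
icc31 <- function(x) {
  n <- nrow(x); k <- ncol(x)
  g <- mean(x)
  ri <- rowMeans(x); cj <- colMeans(x)
  msr <- k * sum((ri - g)^2) / (n - 1)
  mse <- sum((x - outer(ri, rep(1, k)) -
                outer(rep(1, n), cj) + g)^2) / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse
  if (denom <= 0) return(NA_real_)
  (msr - mse) / denom
}

#' Average surface distance
#'
#' Surface voxels are foreground voxels with at least one background (or
#' out-of-grid) face neighbour (6-connectivity). The directed mean
#' nearest-surface distance is computed in both directions in mm, and the
#' returned value is the mean of the two directed means.
#'
#' @param a,b binary masks on the same grid.
#' @param spacing voxel spacing in mm.
#' @return ASD in mm (>= 0), or `NA` when either mask is empty.
#' @export
asd <- function(a, b, spacing = c(1, 1, 1)) {
  if (!identical(dim(a), dim(b))) stop("grid mismatch")
  a <- a != 0; b <- b != 0
  if (!any(a) || !any(b)) return(NA_real_)
  d <- dim(a)
  sa <- array(surface6_nat(as.vector(a), d[1], d[2], d[3]), d)
  sb <- array(surface6_nat(as.vector(b), d[1], d[2], d[3]), d)
  pa <- sweep(which(sa, arr.ind = TRUE) - 1, 2, spacing, `*`)
  pb <- sweep(which(sb, arr.ind = TRUE) - 1, 2, spacing, `*`)
  dab <- nn_dist_nat(pa, pb)
  dba <- nn_dist_nat(pb, pa)
  (mean(dab) + mean(dba)) / 2
}

#' Per-structure metric report for one prediction/reference pair
#'
#' Extracts each non-background structure as a binary mask and computes DSC,
#' ICC and ASD against the reference. Undefined metrics (e.g. a structure
#' absent from the prediction) are recorded as `NA` with a reason, never as
#' silent zeros, and other structures are unaffected.
#'
#' @param pred,ref [label_map()] objects on a shared grid with the same
#'   label set.
#' @param spacing voxel spacing mm (defaults to the reference's).
#' @return data.frame of class `idseg_metrics`: structure, code, dsc, icc,
#'   asd_mm, note.
#' @export
evaluate_pair <- function(pred, ref, spacing = ref$spacing) {
  stopifnot(inherits(pred, "idseg_labels"), inherits(ref, "idseg_labels"))
  if (!identical(dim(pred$codes), dim(ref$codes))) stop("grid mismatch")
  if (!identical(pred$label_set, ref$label_set)) stop("label-set mismatch")
  structures <- setdiff(ref$label_set, 0L)
  rows <- lapply(structures, function(s) {
    pm <- pred$codes == s; rm_ <- ref$codes == s
    note <- ""
    if (!any(pm) && !any(rm_)) note <- "absent in both"
    else if (!any(pm)) note <- "absent in prediction"
    else if (!any(rm_)) note <- "absent in reference"
    defined <- note == ""
    data.frame(structure = IDSEG_STRUCTURES[match(s, structures)], code = s,
               dsc = if (defined) dsc(pm, rm_) else NA_real_,
               icc = if (defined) icc_masks(pm, rm_) else NA_real_,
               asd_mm = if (defined) asd(pm, rm_, spacing) else NA_real_,
               note = note)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("idseg_metrics", "data.frame")
  out
}

#' Aggregate per-subject metric reports
#'
#' @param reports list of [evaluate_pair()] outputs (one per subject).
#' @return data.frame of per-structure mean and sd for each metric,
#'   undefined values excluded.
#' @export
aggregate_metrics <- function(reports) {
  all_df <- do.call(rbind, lapply(seq_along(reports), function(i) {
    r <- as.data.frame(reports[[i]]); r$subject <- i; r
  }))
  agg <- function(metric) {
    m <- aggregate(all_df[[metric]], list(structure = all_df$structure),
                   function(v) c(mean = mean(v, na.rm = TRUE),
                                 sd = sd(v[!is.na(v)])))
    data.frame(structure = m$structure, metric = metric,
               mean = m$x[, "mean"], sd = m$x[, "sd"])
  }
  do.call(rbind, lapply(c("dsc", "icc", "asd_mm"), agg))
}

#' One-way ANOVA comparison of segmentation methods
#'
#' For each structure x metric cell, tests equality of per-subject metric
#' values across methods with a one-way ANOVA, then applies
#' Benjamini-Hochberg adjustment across all tests in the table.
#'
#' @param df long data.frame with columns `subject`, `method`, `structure`,
#'   `metric`, `value`; every method must cover the same subjects.
#' @param p_adjust_method passed to [stats::p.adjust()] (default `"BH"`).
#' @return data.frame: structure, metric, F, df_between, df_within, p, p_adj.
#' @export
compare_methods <- function(df, p_adjust_method = "BH") {
  need <- c("subject", "method", "structure", "metric", "value")
  if (!all(need %in% names(df))) stop("df must have columns ",
                                      paste(need, collapse = ", "))
  methods <- unique(df$method)
  if (length(methods) < 2) stop("need at least 2 methods")
  subj_sets <- lapply(methods, function(m) sort(unique(df$subject[df$method == m])))
  if (!all(vapply(subj_sets, identical, logical(1), subj_sets[[1]])))
    stop("unequal subject sets across methods")
  cells <- unique(df[, c("structure", "metric")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    d <- df[df$structure == cells$structure[i] & df$metric == cells$metric[i] &
              !is.na(df$value), ]
    fit <- stats::anova(stats::lm(value ~ factor(method), data = d))
    data.frame(structure = cells$structure[i], metric = cells$metric[i],
               F = fit$`F value`[1], df_between = fit$Df[1],
               df_within = fit$Df[2], p = fit$`Pr(>F)`[1])
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = p_adjust_method)
  out
}
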