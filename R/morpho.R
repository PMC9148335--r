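#' Structure volumes, raw and TBV-adjusted
#'
#' Raw volume is voxel count times voxel volume in mm^3; adjusted volume is
#' the dimensionless ratio raw / total brain volume.
#'
#' @param labels an [label_map()].
#' @param spacing voxel spacing mm (defaults to the label map's).
#' @param tbv total brain volume in mm^3 (> 0), or a brain mask
#'   (logical/integer 3D array, or `idseg_labels`) from which TBV is computed
#'   as the nonzero-voxel volume.
#' @return data.frame with structure, voxels, raw mm^3 and adjusted ratio.
#' @export
region_volumes <- function(labels, spacing = labels$spacing, tbv) {
  stopifnot(inherits(labels, "idseg_labels"))
  voxvol <- prod(spacing)
  if (!is.numeric(tbv) || length(tbv) > 1) {
    m <- if (inherits(tbv, "idseg_labels")) tbv$codes else tbv
    if (!is.array(m)) stop("tbv must be a positive number or a brain mask")
    tbv <- sum(m != 0) * voxvol
  }
  if (tbv <= 0) stop("tbv must be positive")
  structures <- setdiff(labels$label_set, 0L)
  counts <- vapply(structures, function(s) sum(labels$codes == s), numeric(1))
  data.frame(structure = IDSEG_STRUCTURES[seq_along(structures)],
             code = structures, voxels = counts,
             volume_mm3 = counts * voxvol,
             adjusted = counts * voxvol / tbv)
}

#' Spearman rank partial correlation
#'
#' Rank-transforms all variables (average ranks on ties), projects the ranked
#' `x` and `y` onto the ranked covariates (with intercept), and correlates
#' the residuals. The two-sided p value uses the t transform with
#' `df = n - 2 - k` where `k` is the number of covariates. With no
#' covariates this reduces exactly to the ordinary Spearman correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame / matrix of covariates, or `NULL`.
#' @return An `idseg_pcor` object: rho, df, p, n and the covariate names.
#' @export
spearman_partial <- function(x, y, covariates = NULL) {
  cov_m <- if (is.null(covariates)) NULL else as.matrix(covariates)
  k <- if (is.null(cov_m)) 0L else ncol(cov_m)
  ok <- is.finite(x) & is.finite(y)
  if (!is.null(cov_m)) ok <- ok & apply(cov_m, 1, function(r) all(is.finite(r)))
  x <- x[ok]; y <- y[ok]
  if (!is.null(cov_m)) cov_m <- cov_m[ok, , drop = FALSE]
  n <- length(x)
  if (n < k + 4) stop("too few complete observations")
  if (sd(x) == 0 || sd(y) == 0) stop("constant input")
  rx <- rank(x); ry <- rank(y)
  if (k > 0) {
    rc <- apply(cov_m, 2, rank)
    X <- cbind(1, rc)
    rx <- rx - X %*% qr.coef(qr(X), rx)
    ry <- ry - X %*% qr.coef(qr(X), ry)
  }
  # a variable explained exactly by the covariates has no remaining
  # association: rho is 0 by convention rather than 0/0
  rho <- if (sd(rx) < 1e-12 || sd(ry) < 1e-12) 0
  else as.numeric(cor(rx, ry))
  df <- n - 2L - k
  tval <- rho * sqrt(df / (1 - rho^2))
  p <- 2 * pt(-abs(tval), df)
  structure(list(rho = rho, df = df, p = p, n = n,
                 covariates = colnames(cov_m) %||% character(0)),
            class = "idseg_pcor")
}

#' @export
print.idseg_pcor <- function(x, ...) {
  cat(sprintf("Spearman partial correlation: rho(%d) = %.3f, p = %.3g (n = %d%s)\n",
              x$df, x$rho, x$p, x$n,
              if (length(x$covariates))
                paste0("; adjusting for ", paste(x$covariates, collapse = ", "))
              else ""))
  invisible(x)
}

#' Brain-behavior correlation matrix
#'
#' Computes the Spearman rank partial correlation between every adjusted
#' structure volume and every outcome score, all adjusted for the shared
#' covariate set (default: PMA at scan, maternal education, EPDS). Cells are
#' flagged at unadjusted `p < alpha`; Benjamini-Hochberg adjusted flags
#' across the table are reported alongside.
#'
#' @param table cohort data.frame (see [generate_cohort()] for the schema);
#'   adjusted volume columns start with `adj_`, outcomes with `cbcl_`.
#' @param covariates covariate column names.
#' @param alpha significance threshold for the unadjusted flag.
#' @return data.frame, one row per structure x outcome cell, of class
#'   `idseg_bbmatrix`.
#' @export
brain_behavior_matrix <- function(table,
                                  covariates = c("pma_weeks",
                                                 "maternal_education",
                                                 "epds"),
                                  alpha = 0.05) {
  measures <- grep("^adj_", names(table), value = TRUE)
  outcomes <- grep("^cbcl_", names(table), value = TRUE)
  if (!length(measures) || !length(outcomes))
    stop("table must contain adj_* measure and cbcl_* outcome columns")
  if (!all(covariates %in% names(table)))
    stop("missing covariates: ",
         paste(setdiff(covariates, names(table)), collapse = ", "))
  if (anyDuplicated(table$id %||% seq_len(nrow(table))))
    stop("duplicated subject ids")
  cells <- expand.grid(measure = measures, outcome = outcomes,
                       stringsAsFactors = FALSE)
  res <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    pc <- spearman_partial(table[[cells$measure[i]]],
                           table[[cells$outcome[i]]],
                           table[, covariates, drop = FALSE])
    data.frame(measure = cells$measure[i], outcome = cells$outcome[i],
               rho = pc$rho, df = pc$df, p = pc$p, n = pc$n)
  }))
  res$significant <- res$p < alpha
  res$p_bh <- p.adjust(res$p, method = "BH")
  res$significant_bh <- res$p_bh < alpha
  class(res) <- c("idseg_bbmatrix", "data.frame")
  res
}
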