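IDSEG_STRUCTURES <- c("left_hippocampus", "right_hippocampus",
                      "left_amygdala", "right_amygdala")
IDSEG_OUTCOMES <- c("total", "internalizing", "externalizing")

# CBCL T-score margins used by the cohort generator (mean, sd per outcome).
CBCL_MEAN <- c(total = 48.3, internalizing = 47.6, externalizing = 48.2)
CBCL_SD <- c(total = 10.6, internalizing = 9.12, externalizing = 10.9)

#' Default embedded brain-behavior associations
#'
#' Target partial Spearman correlations (given PMA at scan, maternal
#' education and EPDS) between each adjusted structure volume and each CBCL
#' outcome. The default embeds a right-amygdala signal (-0.62 total, -0.43
#' internalizing, -0.59 externalizing) and leaves the other structures null.
#'
#' @return 4 x 3 numeric matrix, structures x outcomes.
#' @export
default_target_rho <- function() {
  m <- matrix(0, 4, 3, dimnames = list(IDSEG_STRUCTURES, IDSEG_OUTCOMES))
  m["right_amygdala", ] <- c(-0.62, -0.43, -0.59)
  m
}

normalize_target_rho <- function(target_rho) {
  if (is.null(target_rho)) return(default_target_rho())
  if (is.matrix(target_rho)) {
    stopifnot(nrow(target_rho) == 4, ncol(target_rho) == 3)
    rownames(target_rho) <- rownames(target_rho) %||% IDSEG_STRUCTURES
    colnames(target_rho) <- colnames(target_rho) %||% IDSEG_OUTCOMES
    return(target_rho[IDSEG_STRUCTURES, IDSEG_OUTCOMES])
  }
  m <- matrix(0, 4, 3, dimnames = list(IDSEG_STRUCTURES, IDSEG_OUTCOMES))
  if (is.null(names(target_rho)) && length(target_rho) == 1)
    target_rho <- stats::setNames(rep(target_rho, 4), IDSEG_STRUCTURES)
  m[names(target_rho), ] <- target_rho
  m
}

#' Generate a synthetic behavior cohort
#'
#' Draws per-subject structure volumes, covariates (postmenstrual age at
#' scan, maternal education, EPDS) and CBCL-like T scores from a Gaussian
#' copula constructed so that the partial Spearman correlation between each
#' total-brain-volume adjusted structure volume and each outcome, given the
#' three covariates, equals the requested target in expectation. The target
#' is specified on the Spearman scale and converted to the latent Pearson
#' scale via `2 sin(pi rho / 6)`. Covariates load on both volumes (PMA
#' increases them) and outcomes (PMA and education decrease, EPDS increases
#' scores), so genuine confounding is present and the partial-correlation
#' machinery is exercised rather than bypassed.
#'
#' T scores are clipped to `[20, 100]` and rounded to 0.1 (a minor bias at
#' extreme targets). With `images = TRUE` each subject also gets a phantom
#' whose structure radii are scaled to realize the drawn volumes; the table
#' then records volumes measured from the label maps.
#'
#' @param n number of subjects (>= 10).
#' @param target_rho 4 x 3 matrix (structures x outcomes), named vector over
#'   structures (recycled across outcomes), or `NULL` for
#'   [default_target_rho()]. All `|rho| < 1`; each outcome's targets must
#'   satisfy `sum(rho^2) < 1` (else the implied correlation matrix is not
#'   positive-definite).
#' @param seed integer seed; regeneration is bit-identical.
#' @param images generate per-subject phantom volumes and labels (memory- and
#'   time-intensive at large `n`).
#' @param spec base [phantom_spec()] used when `images = TRUE`.
#' @return `list(subjects, table)`: `subjects` is a list of
#'   `list(volume, labels)` (or `NULL` entries when `images = FALSE`);
#'   `table` is a data.frame with id, covariates, TBV, raw and adjusted
#'   volumes, and the three T scores.
#' @export
generate_cohort <- function(n, target_rho = NULL, seed = 1, images = FALSE,
                            spec = phantom_spec()) {
  if (n < 10) stop("need n >= 10 subjects")
  rho_s <- normalize_target_rho(target_rho)
  if (any(abs(rho_s) >= 1)) stop("|target_rho| must be < 1")
  rho_lat <- 2 * sin(pi * rho_s / 6)      # Spearman -> latent Pearson

  alpha <- c(pma = 0.4, edu = 0, epds = 0)        # volume ~ covariate loads
  beta <- c(pma = -0.15, edu = -0.20, epds = 0.30) # outcome ~ covariate loads
  s_vol <- sqrt(1 - sum(alpha^2))
  t_out <- sqrt(1 - sum(beta^2))
  gam <- rho_lat * t_out                   # outcome loads on volume residuals
  delta2 <- t_out^2 - colSums(gam^2)
  if (any(delta2 <= 0))
    stop("infeasible correlation matrix: sum of squared targets per outcome must be < 1")

  with_seed(seed, {
    cmat <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, names(alpha)))
    eps <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, IDSEG_STRUCTURES))
    eta <- matrix(rnorm(n * 3), n, 3)
    e_tbv <- rnorm(n)

    zvol <- cmat %*% matrix(alpha, 3, 4) + s_vol * eps   # unit-variance latents
    yout <- sapply(1:3, function(k)
      as.vector(cmat %*% beta) + eps %*% gam[, k] + sqrt(delta2[k]) * eta[, k])

    # observable margins (all monotone in their latents)
    pma <- 41 + 1.5 * cmat[, "pma"]
    edu <- findInterval(cmat[, "edu"], qnorm(c(0.15, 0.40, 0.70, 0.90))) + 1L
    epds <- round(stats::qgamma(stats::pnorm(cmat[, "epds"]), shape = 2,
                                scale = 3))
    voxvol <- prod(spec$spacing)
    base_counts <- c(left_hippocampus = 264, right_hippocampus = 264,
                     left_amygdala = 180, right_amygdala = 180)
    tbv0 <- 4 / 3 * pi * prod(spec$shape * 0.42) * voxvol
    tbv <- tbv0 * exp(0.06 * (0.5 * cmat[, "pma"] + sqrt(0.75) * e_tbv))
    adj <- sweep(exp(0.12 * zvol), 2, base_counts * voxvol / tbv0, `*`)
    vol_mm3 <- adj * tbv

    tsc <- sapply(1:3, function(k)
      round(pmin(100, pmax(20, CBCL_MEAN[k] + CBCL_SD[k] * yout[, k])), 1))
    colnames(tsc) <- paste0("cbcl_", IDSEG_OUTCOMES)

    subjects <- vector("list", n)
    if (images) {
      for (i in seq_len(n)) {
        target_counts <- vol_mm3[i, ] / voxvol
        sc <- (target_counts / base_counts)^(1 / 3)
        sp_i <- spec
        sp_i$seed <- spec$seed + i
        # a phantom shares radii between hemispheres, so each pair uses its
        # mean scale; measured volumes then carry the pair-mean association
        sp_i$hippo_major <- spec$hippo_major * mean(sc[1:2])
        sp_i$hippo_minor <- spec$hippo_minor * mean(sc[1:2])
        sp_i$amyg_radii <- spec$amyg_radii * mean(sc[3:4])
        subjects[[i]] <- generate_phantom(sp_i)
        counts <- tabulate(subjects[[i]]$labels$codes, nbins = 4)
        vol_mm3[i, ] <- counts * voxvol
        adj[i, ] <- vol_mm3[i, ] / tbv[i]
      }
    }
    tab <- data.frame(id = sprintf("sub-%03d", seq_len(n)),
                      pma_weeks = pma, maternal_education = edu,
                      epds = epds, tbv_mm3 = tbv,
                      stats::setNames(as.data.frame(vol_mm3),
                                      paste0(IDSEG_STRUCTURES, "_mm3")),
                      stats::setNames(as.data.frame(adj),
                                      paste0("adj_", IDSEG_STRUCTURES)),
                      as.data.frame(tsc))
    list(subjects = subjects, table = tab)
  })
}
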