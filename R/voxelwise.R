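#' TFCE parameters
#'
#' Canonical defaults of the threshold-free cluster enhancement method:
#' extent exponent `E = 0.5`, height exponent `H = 2`, integration step
#' `dh = max/100`, 26-connectivity.
#'
#' @param E Extent exponent (> 0).
#' @param H Height exponent (> 0).
#' @param dh Integration step; `NULL` means `max(field) / 100`.
#' @param connectivity One of 6, 18, 26.
#' @return A `tfce_params` list.
#' @export
tfce_params <- function(E = 0.5, H = 2, dh = NULL, connectivity = 26L) {
  if (E <= 0 || H <= 0) stop("`E` and `H` must be positive", call. = FALSE)
  if (!is.null(dh) && dh <= 0) stop("`dh` must be positive", call. = FALSE)
  if (!connectivity %in% c(6L, 18L, 26L)) {
    stop("`connectivity` must be 6, 18 or 26", call. = FALSE)
  }
  structure(list(E = E, H = H, dh = dh, connectivity = as.integer(connectivity)),
            class = "tfce_params")
}

#' Threshold-free cluster enhancement of a statistic field
#'
#' For every voxel `p`, integrates `e(h, p)^E * h^H` over thresholds
#' `h = dh, 2 dh, ...` up to the voxel's own height, where `e(h, p)` is the
#' size of the connected component containing `p` in the suprathreshold set
#' `{field >= h}`. Spatially contiguous signal is boosted without choosing a
#' cluster-forming threshold. Zero voxels stay zero.
#'
#' @param field Non-negative 3D array (or a masked field plus `mask`).
#' @param params A [tfce_params()].
#' @param mask Optional [brain_mask()] when `field` is a masked vector.
#' @return An object of the same shape as `field` with enhanced values.
#' @export
tfce_enhance <- function(field, params = tfce_params(), mask = NULL) {
  stopifnot(inherits(params, "tfce_params"))
  as_vector <- FALSE
  if (!is.null(mask)) {
    field <- field_to_volume(field, mask)
    as_vector <- TRUE
  }
  if (is.null(dim(field))) field <- array(field, dim = c(length(field), 1L, 1L))
  if (length(dim(field)) == 2L) field <- array(field, dim = c(dim(field), 1L))
  stopifnot(length(dim(field)) == 3L)
  if (any(!is.finite(field))) stop("field must be finite", call. = FALSE)
  if (any(field < 0)) stop("field must be non-negative", call. = FALSE)
  fmax <- max(field)
  if (fmax == 0) {
    out <- array(0, dim = dim(field))
  } else {
    dh <- if (is.null(params$dh)) fmax / 100 else params$dh
    out <- array(
      .tfce_cpp(as.numeric(field), as.integer(dim(field)),
                params$E, params$H, dh, params$connectivity),
      dim = dim(field)
    )
  }
  if (as_vector) volume_to_field(out, mask) else out
}

#' Threshold a network template by Gaussian-Gamma mixture modeling
#'
#' Fits a two-component mixture to the template values by
#' expectation-maximization -- a Gaussian null component plus a positive
#' Gamma activation component -- and keeps the voxels whose posterior
#' probability of belonging to the null (the local false-discovery rate) is
#' below `local_fdr`. This is the standard way of reducing an ICA map to the
#' "core" network region. When EM fails or the activation component
#' degenerates, the function falls back to a `z > 3` cut with a warning.
#'
#' @param field Numeric field of template values over the mask.
#' @param mask A [brain_mask()] (used to carry geometry into the result).
#' @param local_fdr Posterior-null cutoff (default 0.05).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @param restarts Number of EM restarts with jittered initializations; the
#'   best-likelihood fit wins. Deterministic: restart `j` uses a fixed
#'   perturbation derived from `j`.
#' @return A `network_mask` list: `inside` (logical over the mask field),
#'   `total_voxels`, `local_fdr` (per-voxel posterior null probability),
#'   `fallback` flag, and the fitted mixture parameters.
#' @export
mixture_threshold <- function(field, mask = NULL, local_fdr = 0.05,
                              max_iter = 500L, tol = 1e-6, restarts = 5L) {
  x <- as.numeric(field)
  if (length(x) < 100L) stop("need at least 100 voxels", call. = FALSE)
  if (stats::sd(x) == 0) stop("degenerate (constant) template map", call. = FALSE)

  fit <- NULL
  best_ll <- -Inf
  for (j in seq_len(restarts)) {
    f <- tryCatch(ggmix_em(x, init_jitter = (j - 1) * 0.25,
                           max_iter = max_iter, tol = tol),
                  error = function(e) NULL)
    if (!is.null(f) && f$loglik > best_ll) {
      best_ll <- f$loglik
      fit <- f
    }
  }

  degenerate <- is.null(fit) || fit$pi1 < 1e-3 || !is.finite(fit$loglik) ||
    fit$gamma_mean <= fit$mu0
  if (degenerate) {
    warning("mixture fit degenerate; falling back to z > 3 thresholding")
    z <- (x - mean(x)) / stats::sd(x)
    inside <- z > 3
    lfdr <- ifelse(inside, 0, 1)
    pars <- NULL
  } else {
    lfdr <- fit$posterior_null
    inside <- lfdr < local_fdr & x > 0
    pars <- fit[c("pi1", "mu0", "sd0", "shape", "rate")]
  }
  structure(
    list(inside = inside, total_voxels = sum(inside), local_fdr = lfdr,
         cutoff = local_fdr, fallback = degenerate, parameters = pars,
         mask = mask),
    class = "network_mask"
  )
}

#' @export
print.network_mask <- function(x, ...) {
  cat(sprintf("<network_mask: %d voxels%s>\n", x$total_voxels,
              if (x$fallback) " (z > 3 fallback)" else ""))
  invisible(x)
}

# EM for pi0 * N(mu0, sd0) + pi1 * Gamma(shape, rate) restricted to x > 0.
ggmix_em <- function(x, init_jitter = 0, max_iter = 500L, tol = 1e-6) {
  n <- length(x)
  med <- stats::median(x)
  madx <- stats::mad(x)
  if (madx == 0) madx <- stats::sd(x)
  # initialize the activation component from the upper tail
  q <- stats::quantile(x, 0.95) * (1 + init_jitter)
  hi <- x[x > q & x > 0]
  if (length(hi) < 3L) hi <- sort(x, decreasing = TRUE)[1:max(3L, n %/% 100L)]
  mu0 <- med
  sd0 <- madx
  gm <- mean(hi)
  gv <- max(stats::var(hi), 1e-6)
  shape <- gm^2 / gv
  rate <- gm / gv
  pi1 <- max(length(hi) / n, 0.01)

  pos <- x > 0
  loglik_old <- -Inf
  for (it in seq_len(max_iter)) {
    d0 <- (1 - pi1) * stats::dnorm(x, mu0, sd0)
    d1 <- numeric(n)
    d1[pos] <- pi1 * stats::dgamma(x[pos], shape = shape, rate = rate)
    tot <- d0 + d1
    tot[tot <= 0] <- 1e-300
    w1 <- d1 / tot
    w0 <- 1 - w1
    loglik <- sum(log(tot))

    pi1 <- mean(w1)
    mu0 <- sum(w0 * x) / sum(w0)
    sd0 <- sqrt(sum(w0 * (x - mu0)^2) / sum(w0))
    sd0 <- max(sd0, 1e-6)
    sw <- sum(w1[pos])
    if (sw > 1e-8 && pi1 > 1e-6) {
      wm <- sum(w1[pos] * x[pos]) / sw
      wml <- sum(w1[pos] * log(x[pos])) / sw
      s <- log(wm) - wml            # MLE gap statistic for the Gamma shape
      if (s > 1e-10) {
        # Newton on log(a) - digamma(a) = s, with a moment start
        a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
        for (nw in 1:25) {
          f <- log(a) - digamma(a) - s
          a_new <- a - f / (1 / a - trigamma(a))
          if (!is.finite(a_new) || a_new <= 0) break
          if (abs(a_new - a) < 1e-10) { a <- a_new; break }
          a <- a_new
        }
        shape <- a
        rate <- a / wm
      }
    }
    if (abs(loglik - loglik_old) < tol * (abs(loglik_old) + 1)) break
    loglik_old <- loglik
  }
  d0 <- (1 - pi1) * stats::dnorm(x, mu0, sd0)
  d1 <- numeric(n)
  d1[pos] <- pi1 * stats::dgamma(x[pos], shape = shape, rate = rate)
  tot <- d0 + d1
  tot[tot <= 0] <- 1e-300
  list(pi1 = pi1, mu0 = mu0, sd0 = sd0, shape = shape, rate = rate,
       gamma_mean = shape / rate, posterior_null = d0 / tot,
       loglik = sum(log(tot)))
}

# Per-voxel GLM t statistics for the group indicator, given a fixed design.
# Y is n x V; returns the t field for the requested contrast sign.
glm_group_t <- function(Y, X, group_col, sign = -1) {
  qrX <- qr(X)
  B <- qr.coef(qrX, Y)
  resid <- Y - X %*% B
  dfres <- nrow(X) - ncol(X)
  sigma2 <- colSums(resid^2) / dfres
  XtXinv_g <- chol2inv(qr.R(qrX))[group_col, group_col]
  tval <- sign * B[group_col, ] / sqrt(pmax(sigma2 * XtXinv_g, 1e-300))
  tval
}

#' Voxel-wise group inference with permutation and TFCE
#'
#' Tests, voxel by voxel inside a thresholded network region, whether
#' controls express the network more strongly than patients, adjusting for
#' covariates. The observed statistic is the per-voxel GLM t for the
#' control-greater-than-patient contrast (negatives clamped to zero),
#' TFCE-enhanced on the 3D grid. Inference uses Freedman-Lane permutation:
#' covariates are regressed out, the residualized data rows are permuted
#' (reduced-model fits added back), the full model is refit and the maximum
#' TFCE statistic over the region is recorded. The family-wise-corrected p
#' of a voxel is the proportion of the `n_perm + 1` statistics (the
#' unpermuted one included) whose maximum reaches the voxel's observed TFCE
#' value, so the smallest attainable p is `1 / (n_perm + 1)`.
#'
#' @param subject_maps `n x V_net` matrix: one row per subject, columns are
#'   the voxels of the network region (`region$inside` within `mask`).
#' @param phenotypes Phenotype tibble (`subject_id`, `group`, covariates);
#'   rows must align with `subject_maps`.
#' @param region A `network_mask` from [mixture_threshold()].
#' @param mask The [brain_mask()] carrying the 3D geometry.
#' @param covariates Covariate columns (default
#'   age/sex/education/mean_fd/gm_fraction; `character()` for none).
#' @param n_perm Number of permutations (default 5000; a warning is issued
#'   below 100).
#' @param params [tfce_params()].
#' @param seed Integer seed; results are reproducible.
#' @param contrast `"control_gt_patient"` (default, network decrease in
#'   patients) or `"patient_gt_control"`.
#' @return A `voxelwise_result`: `p_corrected` (field over the region),
#'   `significant` (corrected p < 0.05), `significant_voxels`,
#'   `total_voxels`, `ratio_percent`, `peak_p`, `tfce_observed`.
#' @export
permutation_glm_tfce <- function(subject_maps, phenotypes, region, mask,
                                 covariates = default_covariates(),
                                 n_perm = 5000L, params = tfce_params(),
                                 seed = 1L,
                                 contrast = c("control_gt_patient",
                                              "patient_gt_control")) {
  contrast <- match.arg(contrast)
  stopifnot(inherits(region, "network_mask"), inherits(mask, "brain_mask"))
  subject_maps <- as.matrix(subject_maps)
  if (ncol(subject_maps) == mask$V) {
    subject_maps <- subject_maps[, region$inside, drop = FALSE]
  }
  if (ncol(subject_maps) != sum(region$inside)) {
    stop("subject maps do not match the network region", call. = FALSE)
  }
  n <- nrow(subject_maps)
  if (nrow(phenotypes) != n) stop("phenotypes do not align with maps", call. = FALSE)
  if (min(table(phenotypes$group)) < 3L) {
    stop("need >= 3 subjects per group", call. = FALSE)
  }
  if (n_perm < 100L) warning("n_perm < 100 gives a very coarse null")

  grp <- as.integer(phenotypes$group == "patient")
  Zc <- if (length(covariates)) {
    stats::model.matrix(
      stats::as.formula(paste("~", paste(covariates, collapse = " + "))),
      data = phenotypes
    )
  } else {
    matrix(1, n, 1L)
  }
  X <- cbind(Zc, group = grp)
  if (qr(X)$rank < ncol(X)) stop("collinear design", call. = FALSE)
  group_col <- ncol(X)
  sgn <- if (contrast == "control_gt_patient") -1 else 1

  # region geometry for TFCE on the full grid
  region_field_idx <- which(region$inside)
  embed <- function(v) {
    f <- numeric(mask$V)
    f[region_field_idx] <- v
    field_to_volume(f, mask)
  }

  tfce_of <- function(tvals) {
    pos <- pmax(tvals, 0)
    vol <- tfce_enhance(embed(pos), params)
    volume_to_field(vol, mask)[region_field_idx]
  }

  t_obs <- glm_group_t(subject_maps, X, group_col, sign = sgn)
  tfce_obs <- tfce_of(t_obs)

  # Freedman-Lane: permute reduced-model residuals, add fitted part back
  qrZ <- qr(Zc)
  fitted_red <- Zc %*% qr.coef(qrZ, subject_maps)
  resid_red <- subject_maps - fitted_red

  max_null <- numeric(n_perm)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n)
      Yb <- fitted_red + resid_red[perm, , drop = FALSE]
      tb <- glm_group_t(Yb, X, group_col, sign = sgn)
      max_null[b] <- max(tfce_of(tb))
    }
  })

  null_all <- c(max_null, max(tfce_obs))
  p_corr <- vapply(tfce_obs, function(v) mean(null_all >= v), numeric(1))
  sig <- p_corr < 0.05
  structure(
    list(
      p_corrected = p_corr, significant = sig,
      significant_voxels = sum(sig), total_voxels = length(p_corr),
      ratio_percent = 100 * sum(sig) / length(p_corr),
      peak_p = min(p_corr),
      tfce_observed = tfce_obs, t_observed = t_obs,
      max_null = max_null, n_perm = n_perm, contrast = contrast,
      region = region, seed = seed
    ),
    class = "voxelwise_result"
  )
}

#' @export
print.voxelwise_result <- function(x, ...) {
  cat(sprintf("<voxelwise_result: %d/%d significant (%.2f%%), peak p = %.4g>\n",
              x$significant_voxels, x$total_voxels, x$ratio_percent, x$peak_p))
  invisible(x)
}

#' Summarize a voxel-wise result as one table row
#'
#' Emits the network-region size, significant-voxel count, their percentage
#' (two decimals) and the peak corrected p value.
#'
#' @param result A `voxelwise_result`.
#' @return A one-row tibble: `total_voxels`, `significant_voxels`,
#'   `ratio_percent`, `peak_p`.
#' @export
summarize_voxelwise <- function(result) {
  stopifnot(inherits(result, "voxelwise_result"))
  tibble::tibble(
    total_voxels = result$total_voxels,
    significant_voxels = result$significant_voxels,
    ratio_percent = round(result$ratio_percent, 2),
    peak_p = result$peak_p
  )
}
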