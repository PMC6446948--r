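#' Temporally concatenate subjects with per-voxel variance normalization
#'
#' Each subject block is demeaned per voxel and scaled to unit per-voxel
#' temporal variance before stacking, the standard preparation for
#' temporal-concatenation group ICA: it makes subjects commensurable so no
#' subject dominates the decomposition. Voxels with zero temporal variance in
#' a subject are set to zero in that block, with a warning.
#'
#' @param series_list List of [bold_series()] sharing one mask.
#' @return A `sum(T_s) x V` numeric matrix.
#' @export
concat_and_normalize <- function(series_list) {
  if (length(series_list) < 1L) stop("need at least one subject", call. = FALSE)
  mask0 <- series_list[[1]]$mask
  blocks <- lapply(series_list, function(s) {
    stopifnot(inherits(s, "bold_series"))
    if (!grids_equal(s$grid, mask0$grid) || s$mask$V != mask0$V) {
      stop("all subjects must share one mask", call. = FALSE)
    }
    x <- s$data
    mu <- colMeans(x)
    x <- sweep(x, 2L, mu)
    sds <- sqrt(colSums(x^2) / (nrow(x) - 1L))
    zero <- sds <= 0
    if (any(zero)) {
      warning(sprintf("subject '%s': %d zero-variance voxel(s) set to 0",
                      s$subject_id, sum(zero)))
      sds[zero] <- 1
      x[, zero] <- 0
    }
    sweep(x, 2L, sds, "/")
  })
  do.call(rbind, blocks)
}

# Eigenvalues of the data covariance over the smaller dimension, plus the
# whitening ingredients reused by spatial_ica(). Rows of `white` are
# uncorrelated with unit variance across voxels (columns of `data`).
pca_eigs <- function(data) {
  nT <- nrow(data)
  V <- ncol(data)
  data <- sweep(data, 2L, colMeans(data))   # remove voxel means
  data <- data - rowMeans(data)             # center each map variable
  if (nT <= V) {
    C <- tcrossprod(data) / V
    e <- eigen(C, symmetric = TRUE)
    list(values = e$values, vectors = e$vectors, data = data,
         dual = FALSE, n_obs = V, d = nT)
  } else {
    G <- crossprod(data)                    # V x V Gram
    e <- eigen(G, symmetric = TRUE)
    list(values = e$values / V, vectors = e$vectors, data = data,
         dual = TRUE, n_obs = V, d = V)
  }
}

whiten_from_eigs <- function(eigs, MO) {
  vals <- pmax(eigs$values[seq_len(MO)], .Machine$double.eps)
  if (!eigs$dual) {
    # rows u_k^T X / sqrt(lambda_k): unit variance across the V columns
    Z <- crossprod(eigs$vectors[, seq_len(MO), drop = FALSE], eigs$data)
    Z / sqrt(vals)
  } else {
    # dual route: unit eigenvectors of the V x V Gram matrix, scaled to unit
    # variance; they lie in the row space of the (row-centered) data
    t(eigs$vectors[, seq_len(MO), drop = FALSE]) * sqrt(eigs$n_obs)
  }
}

#' Estimate the ICA model order by Laplace-approximation evidence
#'
#' Computes the eigenspectrum of the data covariance and maximizes the
#' Laplace approximation to the Bayesian model evidence for a probabilistic
#' PCA of each candidate dimensionality (Minka's criterion, the estimator
#' behind "automatic" order selection in group ICA tools). The estimate is
#' clipped to `[2, max_order]`.
#'
#' @param data `T x V` matrix (or a [bold_series()]).
#' @param max_order Largest order considered; must be below `min(T, V)`.
#' @return Integer estimate of the number of non-noise components.
#' @export
estimate_model_order <- function(data, max_order = 30L) {
  if (inherits(data, "bold_series")) data <- data$data
  stopifnot(is.matrix(data))
  d_min <- min(dim(data))
  if (max_order >= d_min) {
    stop("`max_order` must be below min(T, V)", call. = FALSE)
  }
  eigs <- pca_eigs(data)
  lambda <- eigs$values[seq_len(eigs$d)]
  n <- eigs$n_obs
  lambda <- lambda[lambda > 1e-12 * lambda[1]]
  d <- length(lambda)
  kmax <- min(max_order, d - 1L)
  if (kmax < 2L || stats::sd(lambda) / mean(lambda) < 1e-8) {
    warning("degenerate eigenspectrum; returning the minimum order 2")
    return(2L)
  }
  logev <- vapply(2:kmax, function(k) minka_log_evidence(lambda, k, n, d),
                  numeric(1))
  as.integer((2:kmax)[which.max(logev)])
}

minka_log_evidence <- function(lambda, k, n, d) {
  v <- mean(lambda[(k + 1):d])
  if (v <= 0) return(-Inf)
  # log prior over the Stiefel manifold of principal axes
  i <- seq_len(k)
  log_pu <- -k * log(2) + sum(lgamma((d - i + 1) / 2) -
                                ((d - i + 1) / 2) * log(pi))
  ll <- -n / 2 * sum(log(lambda[1:k])) - n * (d - k) / 2 * log(v)
  m <- d * k - k * (k + 1) / 2
  lam_hat <- c(lambda[1:k], rep(v, d - k))
  log_az <- 0
  for (ii in 1:k) {
    jj <- (ii + 1):d
    log_az <- log_az + sum(log(pmax(1 / lam_hat[jj] - 1 / lam_hat[ii], 1e-300)) +
                             log(pmax(lambda[ii] - lambda[jj], 1e-300)) + log(n))
  }
  log_pu + ll + (m + k) / 2 * log(2 * pi) - log_az / 2 - k / 2 * log(n)
}

row_skewness <- function(M) {
  mu <- rowMeans(M)
  Mc <- M - mu
  s2 <- rowMeans(Mc^2)
  rowMeans(Mc^3) / (s2^1.5 + 1e-300)
}

#' Spatial ICA by the symmetric fixed-point algorithm
#'
#' PCA-whitens the data to `MO` dimensions and runs symmetric fixed-point
#' ICA maximizing the non-Gaussianity of the spatial maps (log-cosh contrast
#' by default), with symmetric decorrelation at each step. Components are
#' canonicalized: each map is z-scored over the mask, its sign flipped so
#' skewness is non-negative, and components are ordered by explained
#' variance, descending. Deterministic given `seed`.
#'
#' @param data `T x V` matrix or [bold_series()].
#' @param MO Model order, `2 <= MO <= min(T, V)`.
#' @param seed Integer seed for the random orthonormal initialization.
#' @param fun Contrast: `"logcosh"` (default) or `"exp"`.
#' @param tol Convergence tolerance on the unmixing update (default `1e-6`).
#' @param max_iter Maximum fixed-point iterations per restart (default 1000).
#' @param restarts Random restarts attempted on non-convergence (default 5).
#' @param eigs Optional precomputed [pca_eigs] result (internal reuse).
#' @return A `component_set`: `maps` (`MO x V`, z-scored), `timecourses`
#'   (`T x MO` mixing series), `explained_variance`, `MO`, `source`.
#' @export
spatial_ica <- function(data, MO, seed = 1L, fun = c("logcosh", "exp"),
                        tol = 1e-6, max_iter = 1000L, restarts = 5L,
                        eigs = NULL) {
  source_label <- "matrix"
  if (inherits(data, "bold_series")) {
    source_label <- paste0("subject:", data$subject_id)
    data <- data$data
  }
  fun <- match.arg(fun)
  stopifnot(is.matrix(data))
  if (MO < 2L || MO > min(dim(data))) {
    stop("`MO` must lie in [2, min(T, V)]", call. = FALSE)
  }
  if (is.null(eigs)) eigs <- pca_eigs(data)
  Z <- whiten_from_eigs(eigs, MO)
  V <- ncol(Z)

  g <- switch(fun,
    logcosh = function(u) tanh(u),
    exp = function(u) u * exp(-u^2 / 2)
  )
  gprime <- switch(fun,
    logcosh = function(u) 1 - tanh(u)^2,
    exp = function(u) (1 - u^2) * exp(-u^2 / 2)
  )

  sym_decorrelate <- function(W) {
    e <- eigen(tcrossprod(W), symmetric = TRUE)
    K <- e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), MO) %*% t(e$vectors)
    K %*% W
  }

  best <- NULL
  converged <- FALSE
  for (attempt in seq_len(restarts)) {
    W <- with_seed(seed + (attempt - 1L) * 101L, {
      qr.Q(qr(matrix(stats::rnorm(MO * MO), MO, MO)))
    })
    W <- sym_decorrelate(W)
    for (it in seq_len(max_iter)) {
      U <- W %*% Z
      GU <- g(U)
      W1 <- tcrossprod(GU, Z) / V - diag(rowMeans(gprime(U)), MO) %*% W
      W1 <- sym_decorrelate(W1)
      delta <- max(abs(abs(rowSums(W1 * W)) - 1))
      W <- W1
      if (delta < tol) break
    }
    if (delta < tol) {
      best <- W
      converged <- TRUE
      break
    }
    if (is.null(best)) best <- W
  }
  if (!converged) {
    rlang::abort(
      sprintf("fixed-point ICA did not converge after %d restart(s)", restarts),
      class = "pmnet_ica_nonconvergence",
      best_unmixing = best
    )
  }

  S <- best %*% Z                                  # MO x V sources, unit var
  A <- eigs$data %*% t(S) / V                      # T x MO mixing time courses
  expl <- colSums(A^2)
  ord <- order(expl, decreasing = TRUE)
  S <- S[ord, , drop = FALSE]
  A <- A[, ord, drop = FALSE]
  expl <- expl[ord]
  # canonical sign: non-negative skewness
  sk <- row_skewness(S)
  flip <- ifelse(sk < 0, -1, 1)
  S <- S * flip
  A <- sweep(A, 2L, flip, "*")
  # z-score each map over the mask
  S <- (S - rowMeans(S)) / sqrt(rowMeans((S - rowMeans(S))^2))

  structure(
    list(maps = S, timecourses = A,
         explained_variance = expl / sum(eigs$values[eigs$values > 0]),
         MO = as.integer(MO), source = source_label, seed = seed),
    class = "component_set"
  )
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("<component_set: %d components over %d voxels (%s)>\n",
              x$MO, ncol(x$maps), x$source))
  invisible(x)
}

#' Construct a template set of named network maps
#'
#' @param maps Named list or named-row matrix of fields over the mask.
#' @param provenance `"sample_specific"` or `"external:<name>"`.
#' @param info Optional tibble of per-network metadata.
#' @return A `template_set`.
#' @export
template_set <- function(maps, provenance = "sample_specific", info = NULL) {
  if (is.list(maps)) maps <- do.call(rbind, maps)
  stopifnot(is.matrix(maps), !is.null(rownames(maps)))
  if (anyDuplicated(rownames(maps))) stop("template names must be unique", call. = FALSE)
  if (!all(is.finite(maps))) stop("template maps must be finite", call. = FALSE)
  structure(
    list(maps = maps, names = rownames(maps), provenance = provenance,
         info = info),
    class = "template_set"
  )
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("<template_set: %s (%s)>\n",
              paste(x$names, collapse = ", "), x$provenance))
  invisible(x)
}

#' Select network components by spatial correlation with references
#'
#' Computes the components-by-references absolute Pearson correlation matrix
#' over the mask and assigns components to reference networks greedily
#' without replacement (see [match_components_greedy()]). Assignments whose
#' best correlation falls below `floor` are flagged low-confidence, the
#' automated stand-in for a visual sanity check.
#'
#' @param components A `component_set`.
#' @param references A [template_set()] of reference network maps.
#' @param floor Low-confidence threshold on `|r|` (default 0.2).
#' @return A [template_set()] of the selected component maps (named after the
#'   references), with a `info` tibble (`network`, `component`, `r_abs`,
#'   `low_confidence`).
#' @export
select_networks <- function(components, references, floor = 0.2) {
  stopifnot(inherits(components, "component_set"),
            inherits(references, "template_set"))
  assignment <- match_components_greedy(components, references)
  low <- assignment$r_abs < floor
  if (any(low)) {
    warning(sprintf("low-confidence match for: %s (|r| < %.2f)",
                    paste(assignment$network[low], collapse = ", "), floor))
  }
  sel <- components$maps[assignment$component, , drop = FALSE]
  rownames(sel) <- assignment$network
  template_set(
    sel,
    provenance = "sample_specific",
    info = tibble::tibble(
      network = assignment$network,
      component = assignment$component,
      r_abs = assignment$r_abs,
      low_confidence = low
    )
  )
}
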