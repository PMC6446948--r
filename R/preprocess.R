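#' High-pass filter a BOLD series
#'
#' Removes slow drifts by regressing out a discrete-cosine basis spanning all
#' frequencies below `cutoff_hz` (together with the constant term), the
#' standard drift model in fMRI GLM software. The output therefore has zero
#' temporal mean per voxel and attenuated low-frequency content; the number of
#' timepoints is unchanged.
#'
#' @param series A [bold_series()].
#' @param cutoff_hz High-pass cutoff in Hz; must be positive and below the
#'   Nyquist frequency `1 / (2 * tr_seconds)`.
#' @return A filtered [bold_series()].
#' @export
highpass_filter <- function(series, cutoff_hz = 0.01) {
  stopifnot(inherits(series, "bold_series"))
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0) {
    stop("`cutoff_hz` must be positive", call. = FALSE)
  }
  nyquist <- 1 / (2 * series$tr_seconds)
  if (cutoff_hz > nyquist) {
    stop(sprintf("cutoff %.4g Hz exceeds Nyquist %.4g Hz", cutoff_hz, nyquist),
         call. = FALSE)
  }
  nT <- series$T
  # DCT-II regressor k has frequency k / (2 * nT * TR); drop all below cutoff
  n_basis <- floor(2 * nT * series$tr_seconds * cutoff_hz)
  X <- dct_basis(nT, n_basis)
  qrX <- qr(X)
  res <- series$data - X %*% qr.coef(qrX, series$data)
  out <- series
  out$data <- res
  out
}

dct_basis <- function(nT, n_basis) {
  t_idx <- seq_len(nT) - 0.5
  cols <- lapply(seq_len(n_basis), function(k) cos(pi * k * t_idx / nT))
  do.call(cbind, c(list(rep(1, nT)), cols))
}

#' Regress confound time series out of a BOLD series
#'
#' Projects each voxel's time series onto the orthogonal complement of
#' `[intercept | confounds]` by ordinary least squares, the standard nuisance
#' regression used with white-matter/ventricle signals, expanded motion
#' parameters and motion-outlier indicator columns.
#'
#' @param series A [bold_series()].
#' @param confounds `T x C` numeric matrix of confound regressors.
#' @param on_rank_deficient What to do when confound columns are linearly
#'   dependent after adding the intercept: `"drop"` (default) removes the
#'   dependent columns with a warning, `"error"` aborts.
#' @return A [bold_series()] of residuals, orthogonal to every confound
#'   column (and mean-zero per voxel).
#' @export
regress_confounds <- function(series, confounds,
                              on_rank_deficient = c("drop", "error")) {
  stopifnot(inherits(series, "bold_series"))
  on_rank_deficient <- match.arg(on_rank_deficient)
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != series$T) {
    stop(sprintf("confounds have %d rows but series has %d timepoints",
                 nrow(confounds), series$T), call. = FALSE)
  }
  X <- cbind(intercept = 1, confounds)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    if (on_rank_deficient == "error") {
      stop("confound matrix is rank deficient", call. = FALSE)
    }
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- setdiff(seq_len(ncol(X)), keep)
    warning(sprintf("dropping %d linearly dependent confound column(s): %s",
                    length(dropped), paste(dropped - 1L, collapse = ", ")))
    X <- X[, sort(keep), drop = FALSE]
    qrX <- qr(X)
  }
  res <- series$data - X %*% qr.coef(qrX, series$data)
  out <- series
  out$data <- res
  out
}

#' Build motion-outlier indicator confounds
#'
#' One indicator column per volume whose frame-wise displacement exceeds the
#' threshold (the scrubbing convention with a 0.5 mm FD cutoff).
#'
#' @param fd Numeric vector of frame-wise displacement values, one per volume.
#' @param threshold_mm FD threshold in mm (default 0.5).
#' @return A `T x n_outlier` indicator matrix (zero columns if none).
#' @export
motion_outlier_confounds <- function(fd, threshold_mm = 0.5) {
  stopifnot(is.numeric(fd), all(fd >= 0 | is.na(fd)))
  idx <- which(fd > threshold_mm)
  out <- matrix(0, nrow = length(fd), ncol = length(idx))
  for (j in seq_along(idx)) out[idx[j], j] <- 1
  colnames(out) <- if (length(idx)) paste0("outlier_", idx) else character()
  out
}
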