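#' Welch's two-sample t test from summary statistics or raw samples
#'
#' Computes `t = (mean2 - mean1) / sqrt(sd1^2/n1 + sd2^2/n2)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p value. Either
#' supply the six summary statistics, or two raw samples via `x` and `y`
#' (summaries are computed first, so both routes agree exactly).
#'
#' @param mean1,sd1,n1 Summary statistics of the first group.
#' @param mean2,sd2,n2 Summary statistics of the second group.
#' @param x,y Alternatively, raw numeric samples.
#' @return A tibble with `t`, `df`, `p` (and the summaries used).
#' @export
#' @examples
#' welch_t(16.89, 6.06, 36, 28.23, 2.01, 43)
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2, x = NULL, y = NULL) {
  if (!is.null(x) || !is.null(y)) {
    stopifnot(is.numeric(x), is.numeric(y))
    mean1 <- mean(x); sd1 <- stats::sd(x); n1 <- length(x)
    mean2 <- mean(y); sd2 <- stats::sd(y); n2 <- length(y)
  }
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  if (sd1 <= 0 && sd2 <= 0) stop("zero variance in both groups", call. = FALSE)
  se1 <- sd1^2 / n1
  se2 <- sd2^2 / n2
  t_stat <- (mean2 - mean1) / sqrt(se1 + se2)
  df <- (se1 + se2)^2 / (se1^2 / (n1 - 1) + se2^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  tibble::tibble(t = t_stat, df = df, p = p,
                 mean1 = mean1, sd1 = sd1, n1 = n1,
                 mean2 = mean2, sd2 = sd2, n2 = n2)
}

#' Yates continuity-corrected chi-square for a 2x2 table
#'
#' `chi2 = N * (max(|ad - bc| - N/2, 0))^2 / (r1 r2 c1 c2)` with one degree
#' of freedom, the classical correction for 2x2 contingency tables such as a
#' sex-by-group breakdown.
#'
#' @param table 2x2 matrix of non-negative counts.
#' @return A tibble with `chi2`, `df` (= 1), `p`.
#' @export
#' @examples
#' yates_chi2(rbind(c(11, 25), c(16, 27)))
yates_chi2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)))
  if (any(table < 0)) stop("counts must be non-negative", call. = FALSE)
  N <- sum(table)
  margins <- c(rowSums(table), colSums(table))
  if (any(margins == 0)) stop("zero margin in 2x2 table", call. = FALSE)
  ad_bc <- table[1, 1] * table[2, 2] - table[1, 2] * table[2, 1]
  num <- max(abs(ad_bc) - N / 2, 0)
  chi2 <- N * num^2 / prod(margins)
  tibble::tibble(chi2 = chi2, df = 1L, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

#' Fisher-Z transform and its inverse
#'
#' @param r Correlation(s) with `|r| < 1`.
#' @param z Fisher-Z value(s).
#' @return `fisher_z()` returns `atanh(r)`; `fisher_z_inverse()` returns
#'   `tanh(z)`.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1", call. = FALSE)
  atanh(r)
}

#' @rdname fisher_z
#' @export
fisher_z_inverse <- function(z) tanh(z)

default_covariates <- function() {
  c("age", "sex", "education", "mean_fd", "gm_fraction")
}

join_records <- function(records, phenotypes, network, method, MO = NULL) {
  sub <- dplyr::filter(records, .data$network == !!network,
                       .data$method == !!method)
  if (!is.null(MO)) sub <- dplyr::filter(sub, .data$MO == as.character(!!MO))
  if (nrow(sub) == 0L) stop("no integrity records match the requested cell",
                            call. = FALSE)
  if (anyDuplicated(sub$subject_id)) {
    stop("multiple records per subject in the requested cell; fix `MO`",
         call. = FALSE)
  }
  df <- dplyr::inner_join(sub, phenotypes, by = "subject_id")
  if (nrow(df) < nrow(sub)) stop("phenotype rows missing for some subjects",
                                 call. = FALSE)
  df
}

#' Covariate-adjusted group comparison of network integrity
#'
#' Fits `z ~ group + age + sex + education + mean_fd + gm_fraction` by
#' ordinary least squares (group coded 1 = patient) and reports the group
#' coefficient's t statistic and two-sided p value, together with raw group
#' means/SDs of the integrity and Cohen's d computed on the unadjusted z
#' values with the pooled standard deviation.
#'
#' @param records Integrity tibble (from [cohort_integrity()] or
#'   [read_integrity_records]).
#' @param phenotypes Phenotype tibble with `subject_id`, `group` and the
#'   covariates.
#' @param network,method,MO Which cell of records to analyze (`MO = NULL`
#'   when the records carry a single model order).
#' @param covariates Covariate column names (default
#'   age/sex/education/mean_fd/gm_fraction; use `character()` for an
#'   unadjusted comparison).
#' @return An `integrity_comparison` object; see [tidy.integrity_comparison()]
#'   and [glance.integrity_comparison()].
#' @export
compare_integrity <- function(records, phenotypes, network, method,
                              MO = NULL, covariates = default_covariates()) {
  df <- join_records(records, phenotypes, network, method, MO)
  if (min(table(df$group)) < 3L) stop("need >= 3 subjects per group", call. = FALSE)
  df$group_patient <- as.integer(df$group == "patient")
  rhs <- c("group_patient", covariates)
  form <- stats::as.formula(paste("z ~", paste(rhs, collapse = " + ")))
  fit <- stats::lm(form, data = df)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("collinear covariates: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  cf <- summary(fit)$coefficients["group_patient", ]
  z_ad <- df$z[df$group == "patient"]
  z_hc <- df$z[df$group == "control"]
  d <- cohens_d_pooled(mean(z_hc), stats::sd(z_hc), length(z_hc),
                       mean(z_ad), stats::sd(z_ad), length(z_ad))
  structure(
    list(
      network = network, method = method,
      MO = if (is.null(MO)) unique(df$MO) else as.character(MO),
      coefficient = unname(cf["Estimate"]),
      t = unname(cf["t value"]), p = unname(cf["Pr(>|t|)"]),
      d = d,
      mean_patient = mean(z_ad), sd_patient = stats::sd(z_ad),
      n_patient = length(z_ad),
      mean_control = mean(z_hc), sd_control = stats::sd(z_hc),
      n_control = length(z_hc),
      covariates = covariates, fit = fit
    ),
    class = "integrity_comparison"
  )
}

#' Cohen's d with pooled standard deviation
#'
#' `d = (mean1 - mean2) / sd_pooled` with
#' `sd_pooled = sqrt(((n1-1) sd1^2 + (n2-1) sd2^2) / (n1 + n2 - 2))`.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summaries.
#' @return The standardized mean difference.
#' @export
cohens_d_pooled <- function(mean1, sd1, n1, mean2, sd2, n2) {
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  (mean1 - mean2) / sp
}

#' @export
print.integrity_comparison <- function(x, ...) {
  cat(sprintf("<integrity_comparison %s / %s / MO %s>\n",
              x$network, x$method, paste(x$MO, collapse = ",")))
  cat(sprintf("  patient %.3f (%.3f, n=%d)  control %.3f (%.3f, n=%d)\n",
              x$mean_patient, x$sd_patient, x$n_patient,
              x$mean_control, x$sd_control, x$n_control))
  cat(sprintf("  group t = %.3f, p = %.4g, Cohen's d = %.3f\n", x$t, x$p, x$d))
  invisible(x)
}

# Ridge-stabilized IRLS logistic fit; used as a fallback when glm reports
# (quasi-)separation. lambda is tiny, so estimates match glm away from
# separation.
ridge_logistic <- function(X, y, lambda = 1e-6, max_iter = 100L, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtWX <- crossprod(X * w, X) + diag(lambda, ncol(X))
    beta_new <- solve(XtWX, crossprod(X * w, z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  drop(beta)
}

#' AUC by the rank (Mann-Whitney) formula
#'
#' Ties count one half. Equals the trapezoidal area under the empirical ROC.
#'
#' @param scores Numeric classifier scores (higher = more patient-like).
#' @param labels Logical or 0/1 vector, `TRUE`/1 = patient.
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("need both classes", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[ord])
  fp <- cumsum(!labels[ord])
  # collapse ties on the threshold
  keep <- c(diff(scores[ord]) != 0, TRUE)
  tibble::tibble(
    fpr = c(0, fp[keep] / sum(!labels)),
    tpr = c(0, tp[keep] / sum(labels))
  )
}

#' Leave-one-out cross-validated logistic classification
#'
#' For each subject, fits a logistic regression of group on network integrity
#' plus covariates using the remaining subjects and predicts the held-out
#' subject's probability of being a patient. The ROC curve is computed over
#' the held-out probabilities and the AUC by the rank formula (ties counted
#' one half). Folds with (quasi-)separation fall back to a tiny-ridge IRLS
#' fit with a warning.
#'
#' @inheritParams compare_integrity
#' @return A `classification_result`: per-subject held-out probabilities,
#'   ROC points, and `auc`. See [tidy.classification_result()].
#' @export
loocv_logistic_auc <- function(records, phenotypes, network, method,
                               MO = NULL, covariates = default_covariates()) {
  df <- join_records(records, phenotypes, network, method, MO)
  if (min(table(df$group)) < 2L) stop("need >= 2 subjects per group", call. = FALSE)
  df$group_patient <- as.integer(df$group == "patient")
  predictors <- c("z", covariates)
  mm <- stats::model.matrix(
    stats::as.formula(paste("~", paste(predictors, collapse = " + "))),
    data = df
  )
  y <- df$group_patient
  n <- nrow(df)
  prob <- numeric(n)
  used_ridge <- FALSE
  for (i in seq_len(n)) {
    Xi <- mm[-i, , drop = FALSE]
    yi <- y[-i]
    fit <- suppressWarnings(
      stats::glm.fit(Xi, yi, family = stats::binomial(),
                     control = list(maxit = 100L, epsilon = 1e-8))
    )
    sep <- !fit$converged ||
      any(fit$fitted.values > 1 - 1e-10 | fit$fitted.values < 1e-10)
    beta <- if (sep) {
      used_ridge <- TRUE
      ridge_logistic(Xi, yi)
    } else {
      stats::coef(fit)
    }
    prob[i] <- stats::plogis(drop(mm[i, ] %*% beta))
  }
  if (used_ridge) {
    warning("separation in at least one fold; ridge fallback (lambda = 1e-6) used")
  }
  roc <- roc_points(prob, y == 1L)
  structure(
    list(
      network = network, method = method,
      MO = if (is.null(MO)) unique(df$MO) else as.character(MO),
      subject_id = df$subject_id, probability = prob, truth = y,
      roc = roc, auc = rank_auc(prob, y == 1L)
    ),
    class = "classification_result"
  )
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result %s / %s: LOOCV AUC = %.3f (n = %d)>\n",
              x$network, x$method, x$auc, length(x$truth)))
  invisible(x)
}
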