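abs_cor_matrix <- function(comp_maps, template_maps) {
  r <- abs(stats::cor(t(comp_maps), t(template_maps)))
  dimnames(r) <- list(NULL, rownames(template_maps))
  r
}

#' Greedy matching of components to network templates
#'
#' Computes the components-by-templates matrix of absolute Pearson
#' correlations, then iteratively picks its global maximum, assigns that
#' (component, template) pair, deletes the pair's row and column, and repeats
#' until every template is assigned. Ties are broken by lower component
#' index, then lexicographic template name, so the result is deterministic.
#' Greedy matching can differ from the sum-optimal assignment; the greedy
#' rule is the one used in practice and is implemented as stated.
#'
#' @param components A `component_set`, or a numeric `K x M` matrix of
#'   absolute correlations (columns named after templates).
#' @param templates A [template_set()] (ignored when `components` is already
#'   a correlation matrix).
#' @return A tibble with one row per template: `network`, `component`
#'   (row index), `r_abs`.
#' @export
match_components_greedy <- function(components, templates = NULL) {
  if (inherits(components, "component_set")) {
    stopifnot(inherits(templates, "template_set"))
    R <- abs_cor_matrix(components$maps, templates$maps)
  } else {
    R <- abs(as.matrix(components))
    if (is.null(colnames(R))) colnames(R) <- paste0("t", seq_len(ncol(R)))
  }
  if (nrow(R) < ncol(R)) {
    stop(sprintf("fewer components (%d) than templates (%d)", nrow(R), ncol(R)),
         call. = FALSE)
  }
  comp_idx <- seq_len(nrow(R))
  tmpl_names <- colnames(R)
  out <- vector("list", ncol(R))
  k <- 0L
  while (length(tmpl_names) > 0L) {
    best <- max(R)
    hits <- which(R == best, arr.ind = TRUE)
    # tie break: lower component index, then lexicographic template name
    hits <- hits[order(comp_idx[hits[, 1]], tmpl_names[hits[, 2]]), ,
                 drop = FALSE]
    i <- hits[1, 1]
    j <- hits[1, 2]
    k <- k + 1L
    out[[k]] <- tibble::tibble(network = tmpl_names[j],
                               component = comp_idx[i],
                               r_abs = best)
    R <- R[-i, -j, drop = FALSE]
    comp_idx <- comp_idx[-i]
    tmpl_names <- tmpl_names[-j]
  }
  res <- dplyr::bind_rows(out)
  res[order(res$network), ]
}

#' Fisher-Z network integrity from a spatial correlation
#'
#' The integrity statistic is `atanh(|r|)`: the Fisher-Z transform of the
#' absolute spatial correlation between an individual network map and its
#' template. Lower values mean greater deviation from the canonical network.
#'
#' @param r Correlation(s) in `(-1, 1)`.
#' @return Non-negative integrity value(s), strictly increasing in `|r|`.
#' @export
#' @examples
#' integrity_from_correlation(c(0, -0.5, 0.9))
integrity_from_correlation <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1", call. = FALSE)
  atanh(abs(r))
}

R_ABS_CLIP <- 1 - 1e-12

integrity_record <- function(subject_id, network, method, MO, r_abs,
                             component = NA_integer_, flagged = FALSE) {
  r_clip <- pmin(abs(r_abs), R_ABS_CLIP)
  tibble::tibble(
    subject_id = subject_id, network = network, method = method,
    MO = as.character(MO), r_abs = r_clip, z = atanh(r_clip),
    component = component,
    low_confidence = flagged | r_clip < 0.2
  )
}

#' Template-matching integrity for one subject
#'
#' Decomposes a subject's series by spatial ICA at the given model order (or
#' a per-subject Laplace-evidence estimate when `MO = "auto"`), matches the
#' resulting components to the network templates greedily, and reports the
#' Fisher-Z integrity of each match. Matches with `|r| < 0.2` are flagged
#' low-confidence.
#'
#' @param series A [bold_series()].
#' @param templates A [template_set()].
#' @param MO Integer model order, or `"auto"`.
#' @param seed Seed for the subject-level ICA.
#' @param max_order Cap used when `MO = "auto"`.
#' @return A list: `records` (integrity tibble, one row per network:
#'   `subject_id network method MO r_abs z component low_confidence`) and
#'   `maps` (named matrix of the matched component maps).
#' @export
template_matching_integrity <- function(series, templates, MO = "auto",
                                        seed = 1L, max_order = 30L) {
  stopifnot(inherits(series, "bold_series"), inherits(templates, "template_set"))
  eigs <- pca_eigs(series$data)
  mo_used <- if (identical(MO, "auto")) {
    estimate_model_order(series$data, max_order = min(max_order, min(dim(series$data)) - 1L))
  } else {
    as.integer(MO)
  }
  mo_used <- max(mo_used, nrow(templates$maps))
  comps <- spatial_ica(series$data, mo_used, seed = seed, eigs = eigs)
  assignment <- match_components_greedy(comps, templates)
  # integrity uses the signed correlation's magnitude over the mask
  records <- integrity_record(
    subject_id = series$subject_id,
    network = assignment$network,
    method = "template_matching",
    MO = if (identical(MO, "auto")) "auto" else as.character(MO),
    r_abs = assignment$r_abs,
    component = assignment$component
  )
  maps <- comps$maps[assignment$component, , drop = FALSE]
  rownames(maps) <- assignment$network
  list(records = records, maps = maps, MO_used = mo_used)
}

#' Dual regression, stage 1: estimate subject time courses
#'
#' Regresses each timepoint's volume on the group component maps (plus an
#' intercept) by ordinary least squares, giving one time course per group
#' component. With `variance_normalize = TRUE` (default) each returned
#' column is scaled to unit variance, so stage-2 maps carry the amplitude.
#'
#' @param series A [bold_series()].
#' @param group_maps A `component_set` or [template_set()] (or `K x V` matrix)
#'   of spatial regressors on the same mask.
#' @param variance_normalize Scale each time course to unit variance.
#' @return `T x K` matrix of time courses.
#' @export
dual_regression_stage1 <- function(series, group_maps, variance_normalize = TRUE) {
  stopifnot(inherits(series, "bold_series"))
  M <- extract_maps(group_maps)
  if (ncol(M) != series$mask$V) {
    stop("group maps are not on the series' mask", call. = FALSE)
  }
  X <- cbind(1, t(M))                       # V x (K+1)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("group maps are collinear; dual regression design is rank deficient",
         call. = FALSE)
  }
  beta <- qr.coef(qrX, t(series$data))      # (K+1) x T
  tc <- t(beta[-1, , drop = FALSE])         # T x K
  colnames(tc) <- rownames(M)
  if (variance_normalize) {
    sds <- apply(tc, 2L, stats::sd)
    sds[sds == 0] <- 1
    tc <- sweep(tc, 2L, sds, "/")
  }
  tc
}

#' Dual regression, stage 2: estimate subject spatial maps
#'
#' Regresses each voxel's time series on the stage-1 time courses (plus an
#' intercept); the regression coefficients form one spatial map per group
#' component.
#'
#' @param series A [bold_series()].
#' @param timecourses `T x K` matrix from [dual_regression_stage1()].
#' @return `K x V` matrix of subject-level spatial maps (rows named after the
#'   time-course columns).
#' @export
dual_regression_stage2 <- function(series, timecourses) {
  stopifnot(inherits(series, "bold_series"))
  timecourses <- as.matrix(timecourses)
  if (nrow(timecourses) != series$T) {
    stop("time courses do not match the series length", call. = FALSE)
  }
  X <- cbind(1, timecourses)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("time courses are collinear; dual regression design is rank deficient",
         call. = FALSE)
  }
  beta <- qr.coef(qrX, series$data)         # (K+1) x V
  maps <- beta[-1, , drop = FALSE]
  rownames(maps) <- colnames(timecourses)
  maps
}

extract_maps <- function(x) {
  if (inherits(x, "component_set")) {
    M <- x$maps
    if (is.null(rownames(M))) rownames(M) <- paste0("IC", seq_len(nrow(M)))
    M
  } else if (inherits(x, "template_set")) {
    x$maps
  } else {
    as.matrix(x)
  }
}

#' Integrity from dual-regression maps
#'
#' Correlates each subject-level map with the group template of the same
#' network over the mask and Fisher-Z transforms the absolute correlation.
#' Saturated correlations are clipped to `1 - 1e-12` and flagged; constant
#' maps yield a flagged record with missing integrity.
#'
#' @param maps `K x V` matrix of subject maps, rows named by network.
#' @param templates A [template_set()] containing those networks.
#' @param subject_id Identifier written into the records.
#' @param MO Model-order label for the records.
#' @return Integrity tibble, one row per network in `templates` that appears
#'   in `maps`.
#' @export
dual_regression_integrity <- function(maps, templates, subject_id = "subject",
                                      MO = "auto") {
  stopifnot(inherits(templates, "template_set"))
  nets <- intersect(templates$names, rownames(maps))
  if (length(nets) == 0L) stop("no shared network names", call. = FALSE)
  out <- lapply(nets, function(nm) {
    m <- maps[nm, ]
    if (stats::sd(m) == 0) {
      rec <- integrity_record(subject_id, nm, "dual_regression", MO, 0,
                              flagged = TRUE)
      rec$z <- NA_real_
      return(rec)
    }
    r <- abs(stats::cor(m, templates$maps[nm, ]))
    integrity_record(subject_id, nm, "dual_regression", MO, r,
                     flagged = r >= R_ABS_CLIP)
  })
  dplyr::bind_rows(out)
}

#' Individual-level integrity for a whole cohort
#'
#' Convenience wrapper running one or both back-reconstruction routes for
#' every subject: dual regression uses all group components as spatial
#' regressors (structured noise components included, so non-neural variance
#' is modeled) and correlates the resulting maps of the selected networks
#' with the group templates; template matching runs a per-subject ICA and
#' matches its components to the templates.
#'
#' @param series_list List of [bold_series()].
#' @param group_components `component_set` from the group ICA (dual
#'   regression regressors).
#' @param templates [template_set()] of the selected group network maps.
#' @param methods Subset of `c("dual_regression", "template_matching")`.
#' @param MO Model-order label (integer or `"auto"`); for template matching
#'   this is also the subject-level ICA order.
#' @param seed Base seed for subject-level ICA.
#' @return A list: `records` (integrity tibble over subjects x networks x
#'   methods) and `maps` (per method, a named list of subject map matrices).
#' @export
cohort_integrity <- function(series_list, group_components, templates,
                             methods = c("dual_regression", "template_matching"),
                             MO = "auto", seed = 1L) {
  methods <- match.arg(methods, several.ok = TRUE)
  records <- list()
  maps_out <- list()
  if ("dual_regression" %in% methods) {
    dr_maps <- list()
    recs <- lapply(series_list, function(s) {
      tc <- dual_regression_stage1(s, group_components)
      sm <- dual_regression_stage2(s, tc)
      # keep only the selected networks' rows, renamed via the selection info
      sel <- template_selection_rows(templates, sm)
      dr_maps[[s$subject_id]] <<- sel
      dual_regression_integrity(sel, templates, subject_id = s$subject_id,
                                MO = MO)
    })
    records <- c(records, recs)
    maps_out$dual_regression <- dr_maps
  }
  if ("template_matching" %in% methods) {
    tm_maps <- list()
    recs <- lapply(seq_along(series_list), function(i) {
      s <- series_list[[i]]
      res <- template_matching_integrity(
        s, templates, MO = MO,
        seed = (seed + i) %% .Machine$integer.max
      )
      tm_maps[[s$subject_id]] <<- res$maps
      res$records
    })
    records <- c(records, recs)
    maps_out$template_matching <- tm_maps
  }
  list(records = dplyr::bind_rows(records), maps = maps_out)
}

# Map dual-regression stage-2 rows (one per group component) to network
# names using the selection info carried by the template set.
template_selection_rows <- function(templates, subject_maps) {
  info <- templates$info
  if (!is.null(info) && all(c("network", "component") %in% names(info))) {
    sel <- subject_maps[info$component, , drop = FALSE]
    rownames(sel) <- info$network
    sel
  } else {
    subject_maps[intersect(rownames(subject_maps), templates$names), ,
                 drop = FALSE]
  }
}
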