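# Shared fixtures and independent oracles for the test suite.

# Small grid/mask used across I/O and preprocessing tests.
tiny_mask <- function(dims = c(4L, 4L, 2L)) {
  brain_mask(volume_grid(dims), array(TRUE, dim = dims))
}

# A reduced generator configuration for calibration loops: same structure as
# the defaults, desk-scale sizes turned down further so hundreds of null
# cohorts fit in a test run. Dual regression needs no ICA, so K_noise = 3
# keeps these cohorts cheap.
small_null_config <- function(seed, n_per_group = 20L) {
  generator_config(
    n_patients = n_per_group, n_controls = n_per_group,
    dims = c(12L, 12L, 6L), n_timepoints = 60L,
    K_networks = 3L, K_noise = 3L,
    delta_mean_patient = 0, seed = seed
  )
}

# Dual-regression integrity of every subject against the ground-truth maps
# (group ICA bypassed; used for calibration of the inferential stages).
truth_dr_records <- function(cohort) {
  truth <- cohort$truth
  templates <- template_set(truth$true_maps[truth$network_names, , drop = FALSE])
  recs <- lapply(cohort$series, function(s) {
    tc <- dual_regression_stage1(s, truth$true_maps)
    maps <- dual_regression_stage2(s, tc)
    dual_regression_integrity(maps, templates, subject_id = s$subject_id)
  })
  dplyr::bind_rows(recs)
}

# Dual-regression subject maps of one network against the ground truth.
truth_dr_maps <- function(cohort, network) {
  do.call(rbind, lapply(cohort$series, function(s) {
    tc <- dual_regression_stage1(s, cohort$truth$true_maps)
    dual_regression_stage2(s, tc)[network, ]
  }))
}

# Memoized default-scale cohort plus one decomposed cell, shared by the
# tests that need a realistic end-to-end fixture.
.demo_cache <- new.env(parent = emptyenv())

get_demo_cohort <- function() {
  if (is.null(.demo_cache$cohort)) {
    .demo_cache$cohort <- simulate_cohort(generator_config(seed = 7L))
  }
  .demo_cache$cohort
}

get_demo_cell <- function() {
  if (is.null(.demo_cache$cell)) {
    cohort <- get_demo_cohort()
    concat <- concat_and_normalize(cohort$series)
    comps <- spatial_ica(concat, 10L, seed = 1L)
    refs <- template_set(
      cohort$truth$true_maps[cohort$truth$network_names, , drop = FALSE]
    )
    templates <- select_networks(comps, refs)
    ci <- cohort_integrity(cohort$series, comps, templates, MO = 10L, seed = 1L)
    .demo_cache$cell <- list(components = comps, templates = templates,
                             records = ci$records, maps = ci$maps)
  }
  .demo_cache$cell
}

# Brute-force TFCE recomputation: explicit per-threshold connected-component
# labeling by breadth-first search, fully independent of the compiled path.
tfce_brute_force <- function(field, E = 0.5, H = 2, dh = NULL,
                             connectivity = 26L) {
  d <- dim(field)
  fmax <- max(field)
  out <- array(0, dim = d)
  if (fmax <= 0) return(out)
  if (is.null(dh)) dh <- fmax / 100
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  manh <- rowSums(abs(offsets))
  offsets <- offsets[manh > 0 & manh <= switch(as.character(connectivity),
                                               "6" = 1, "18" = 2, "26" = 3), ,
                     drop = FALSE]
  coords <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                                  z = seq_len(d[3])))
  nstep <- floor(fmax / dh + 1e-12)
  for (s in seq_len(nstep)) {
    h <- s * dh
    above <- field >= h
    labels <- array(0L, dim = d)
    current <- 0L
    for (i in seq_len(nrow(coords))) {
      p <- coords[i, ]
      if (!above[p[1], p[2], p[3]] || labels[p[1], p[2], p[3]] != 0L) next
      current <- current + 1L
      queue <- list(p)
      labels[p[1], p[2], p[3]] <- current
      while (length(queue)) {
        q <- queue[[1]]
        queue <- queue[-1]
        for (k in seq_len(nrow(offsets))) {
          nb <- q + offsets[k, ]
          if (any(nb < 1L) || any(nb > d)) next
          if (above[nb[1], nb[2], nb[3]] && labels[nb[1], nb[2], nb[3]] == 0L) {
            labels[nb[1], nb[2], nb[3]] <- current
            queue[[length(queue) + 1L]] <- nb
          }
        }
      }
    }
    sizes <- tabulate(labels[labels > 0L])
    idx <- which(above)
    out[idx] <- out[idx] + sizes[labels[idx]]^E * h^H * dh
  }
  out
}

# Exhaustive best-sum assignment of templates to components for small
# matrices (columns = templates), the oracle for greedy matching.
best_assignment <- function(R) {
  K <- nrow(R)
  M <- ncol(R)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  combs <- utils::combn(K, M, simplify = FALSE)
  best <- NULL
  best_sum <- -Inf
  for (cmb in combs) {
    for (p in perms(cmb)) {
      s <- sum(R[cbind(p, seq_len(M))])
      if (s > best_sum) {
        best_sum <- s
        best <- p
      }
    }
  }
  list(assignment = best, total = best_sum)
}

# Independent greedy matcher written against the stated rule, used to check
# the package implementation on divergence cases.
greedy_reference <- function(R) {
  comp <- seq_len(nrow(R))
  tmpl <- seq_len(ncol(R))
  out <- integer(ncol(R))
  while (length(tmpl)) {
    hit <- which(R == max(R), arr.ind = TRUE)
    hit <- hit[order(comp[hit[, 1]], tmpl[hit[, 2]]), , drop = FALSE]
    i <- hit[1, 1]
    j <- hit[1, 2]
    out[tmpl[j]] <- comp[i]
    R <- R[-i, -j, drop = FALSE]
    comp <- comp[-i]
    tmpl <- tmpl[-j]
  }
  out
}
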