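#' Configuration for the synthetic cohort generator
#'
#' The generator emulates preprocessed, registered resting-state data for a
#' two-group study: `K_networks` smooth, spatially structured network maps
#' (the first two adjacent, mimicking the PMN/DMN pair; the third disjoint,
#' a medial-visual-style control), `K_noise` smooth structured noise maps,
#' band-limited time courses, additive sensor noise, and a group-dependent
#' spatial degradation of the first ("target") network that lowers its
#' integrity statistic in patients.
#'
#' Cohort sizes default to 36 patients and 43 controls, time series to 120
#' volumes at TR = 2 s on a 16 x 16 x 8 desk-scale grid. Covariate
#' distributions default to published AD/HC demographics (age 67.97 (7.96)
#' vs 66.86 (5.56) years, 11/25 vs 16/27 male/female, education 9.36 (4.53)
#' vs 10.46 (4.72) years, mean FD 0.23 (0.092) vs 0.23 (0.086) mm); the
#' gray-matter fraction is drawn from one common distribution for both groups
#' so that, by default, group membership is encoded only in the planted
#' network deficit and every null/control comparison is genuinely null.
#' Group-specific gray-matter means can be configured when a structural
#' confound is wanted.
#'
#' @param n_patients,n_controls Group sizes.
#' @param dims Grid dimensions.
#' @param n_timepoints Volumes per subject.
#' @param K_networks,K_noise Numbers of planted network / structured-noise maps.
#' @param noise_sd Sensor noise standard deviation.
#' @param subject_map_jitter_sd SD of the smooth spatial jitter added to each
#'   non-target subject map.
#' @param delta_mean_patient Mean of the patients' integrity-deficit fraction
#'   `delta` in `[0, 1]` (controls have `delta = 0`).
#' @param delta_sd SD of the truncated-normal `delta` draw.
#' @param tr_seconds Repetition time.
#' @param age_patient,age_control,education_patient,education_control,
#'   mean_fd_patient,mean_fd_control,gm_patient,gm_control Mean/SD pairs for
#'   the covariate draws.
#' @param male_frac_patient,male_frac_control Probability of `male`.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_patients = 36L, n_controls = 43L,
                             dims = c(16L, 16L, 8L), n_timepoints = 120L,
                             K_networks = 3L, K_noise = 7L,
                             noise_sd = 0.8, subject_map_jitter_sd = 0.05,
                             delta_mean_patient = 0.5, delta_sd = 0.1,
                             tr_seconds = 2,
                             age_patient = c(67.97, 7.96),
                             age_control = c(66.86, 5.56),
                             male_frac_patient = 11 / 36,
                             male_frac_control = 16 / 43,
                             education_patient = c(9.36, 4.53),
                             education_control = c(10.46, 4.72),
                             mean_fd_patient = c(0.23, 0.092),
                             mean_fd_control = c(0.23, 0.086),
                             gm_patient = c(0.49, 0.028),
                             gm_control = c(0.49, 0.028),
                             seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
    dims = as.integer(dims), n_timepoints = as.integer(n_timepoints),
    K_networks = as.integer(K_networks), K_noise = as.integer(K_noise),
    noise_sd = noise_sd, subject_map_jitter_sd = subject_map_jitter_sd,
    delta_mean_patient = delta_mean_patient, delta_sd = delta_sd,
    tr_seconds = tr_seconds,
    age_patient = age_patient, age_control = age_control,
    male_frac_patient = male_frac_patient, male_frac_control = male_frac_control,
    education_patient = education_patient, education_control = education_control,
    mean_fd_patient = mean_fd_patient, mean_fd_control = mean_fd_control,
    gm_patient = gm_patient, gm_control = gm_control,
    seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  counts <- c(cfg$n_patients, cfg$n_controls, cfg$K_networks, cfg$K_noise,
              cfg$n_timepoints)
  if (any(counts < 1L)) stop("all counts must be >= 1", call. = FALSE)
  if (cfg$noise_sd < 0 || cfg$subject_map_jitter_sd < 0 || cfg$delta_sd < 0) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  if (cfg$delta_mean_patient < 0 || cfg$delta_mean_patient > 1) {
    stop("`delta_mean_patient` must lie in [0, 1]", call. = FALSE)
  }
  if (length(cfg$dims) != 3L || any(cfg$dims < 6L)) {
    stop("`dims` must be three integers >= 6", call. = FALSE)
  }
  invisible(cfg)
}

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Separable Gaussian smoothing of a 3D array, one banded smoothing matrix
# per axis (replicated edges), applied as dense matrix products.
smoothing_matrix <- function(n, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  ker <- exp(-((-r):r)^2 / (2 * sigma^2))
  ker <- ker / sum(ker)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- pmin(pmax((i - r):(i + r), 1L), n)   # replicate edges
    for (j in seq_along(idx)) K[i, idx[j]] <- K[i, idx[j]] + ker[j]
  }
  K
}

gaussian_smooth_3d <- function(arr, sigma) {
  d <- dim(arr)
  # x axis
  arr <- array(smoothing_matrix(d[1], sigma) %*% matrix(arr, d[1]), dim = d)
  # y axis
  arr <- aperm(arr, c(2, 1, 3))
  arr <- array(smoothing_matrix(d[2], sigma) %*% matrix(arr, d[2]),
               dim = d[c(2, 1, 3)])
  arr <- aperm(arr, c(2, 1, 3))
  # z axis
  arr <- aperm(arr, c(3, 1, 2))
  arr <- array(smoothing_matrix(d[3], sigma) %*% matrix(arr, d[3]),
               dim = d[c(3, 1, 2)])
  aperm(arr, c(2, 3, 1))
}

# A smooth random field over the mask: smoothed white noise, masked,
# standardized to zero mean / unit SD over the mask.
smooth_noise_field <- function(mask, sigma = 1.2) {
  arr <- array(stats::rnorm(n_voxels(mask$grid)), dim = mask$grid$dims)
  arr <- gaussian_smooth_3d(arr, sigma)
  f <- volume_to_field(arr, mask)
  as.numeric(scale(f))
}

# Sum-of-Gaussians blob map, truncated at a small fraction of the peak and
# normalized to unit peak. Centers are in fractional grid coordinates.
blob_map <- function(grid, centers_frac, sigma_frac = 0.09, floor_frac = 0.05) {
  d <- grid$dims
  sigma <- sigma_frac * mean(d[1:2])
  co <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  vol <- numeric(nrow(co))
  for (i in seq_len(nrow(centers_frac))) {
    cx <- centers_frac[i, ] * d
    vol <- vol + exp(-((co$x - cx[1])^2 + (co$y - cx[2])^2 +
                         (co$z - cx[3])^2) / (2 * sigma^2))
  }
  vol <- vol / max(vol)
  vol[vol < floor_frac] <- 0
  array(vol, dim = d)
}

default_network_layout <- function() {
  list(
    netA = list(centers = rbind(c(0.40, 0.48, 0.55), c(0.32, 0.60, 0.45),
                                c(0.44, 0.66, 0.58)),
                sigma_frac = 0.09),
    netB = list(centers = rbind(c(0.58, 0.48, 0.55), c(0.66, 0.60, 0.45),
                                c(0.54, 0.66, 0.58)),
                sigma_frac = 0.09),
    # smaller and tucked into the opposite corner so its support stays clear
    # of the adjacent pair
    netC = list(centers = rbind(c(0.82, 0.18, 0.45), c(0.72, 0.12, 0.52)),
                sigma_frac = 0.08)
  )
}

# Ellipsoidal "brain" inside the grid.
default_mask <- function(grid) {
  d <- grid$dims
  co <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  cen <- (d + 1) / 2
  ax <- 0.48 * d
  inside <- ((co$x - cen[1]) / ax[1])^2 + ((co$y - cen[2]) / ax[2])^2 +
    ((co$z - cen[3]) / ax[3])^2 <= 1
  brain_mask(grid, array(inside, dim = d))
}

#' Generate the ground truth for a synthetic cohort
#'
#' Builds the shared grid, brain mask, named network maps (smooth blob unions,
#' unit peak; the first two spatially adjacent, the third disjoint) and the
#' structured-noise maps, and draws the per-subject degradation fractions
#' `delta` and group labels. Deterministic given `config$seed`.
#'
#' @param config A [generator_config()].
#' @return A `synthetic_truth` list with elements `grid`, `mask`, `true_maps`
#'   (named `K x V` matrix rows over the mask), `network_names`, `target`
#'   (name of the degraded network), `phenotypes` (tibble incl. `delta`),
#'   and `seed`.
#' @export
make_truth <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  grid <- volume_grid(config$dims)
  mask <- default_mask(grid)
  layout <- default_network_layout()
  if (config$K_networks > 3L) {
    stop("the generator places at most 3 structured networks", call. = FALSE)
  }
  net_names <- names(layout)[seq_len(config$K_networks)]
  with_seed(config$seed, {
    maps <- lapply(net_names, function(nm) {
      volume_to_field(
        blob_map(grid, layout[[nm]]$centers, sigma_frac = layout[[nm]]$sigma_frac),
        mask
      )
    })
    net_sd <- mean(vapply(maps, stats::sd, numeric(1)))
    noise_amp <- seq(0.8, 0.6, length.out = config$K_noise)
    for (j in seq_len(config$K_noise)) {
      # artifact-like structured noise: smooth but heavy-tailed (cubed
      # smoothed field), so every source stays identifiable to spatial ICA;
      # amplitudes tiered below the networks' so the variance ranking is
      # unambiguous and truncated decompositions keep whole sources
      f <- smooth_noise_field(mask, sigma = 1.5)^3
      f <- as.numeric(scale(f)) * noise_amp[j] * net_sd
      maps[[length(maps) + 1L]] <- f
    }
    names(maps) <- c(net_names, paste0("noise", seq_len(config$K_noise)))
    true_maps <- do.call(rbind, maps)

    check_truth_geometry(true_maps, net_names)

    phen <- draw_phenotypes(config)
  })
  structure(
    list(grid = grid, mask = mask, true_maps = true_maps,
         network_names = net_names, target = net_names[1],
         phenotypes = phen, seed = config$seed, config = config),
    class = "synthetic_truth"
  )
}

check_truth_geometry <- function(true_maps, net_names) {
  if (length(net_names) < 2L) return(invisible(TRUE))
  r_ab <- stats::cor(true_maps[net_names[1], ], true_maps[net_names[2], ])
  if (!(r_ab > 0 && r_ab < 0.5)) {
    stop(sprintf("adjacent networks have spatial correlation %.3f outside (0, 0.5); grid too small", r_ab),
         call. = FALSE)
  }
  if (length(net_names) >= 3L) {
    # disjoint supports; slight negative correlation is the disjointness
    # signature, so the bound is on the signed correlation
    r_ac <- stats::cor(true_maps[net_names[1], ], true_maps[net_names[3], ])
    r_bc <- stats::cor(true_maps[net_names[2], ], true_maps[net_names[3], ])
    overlap <- sum(true_maps[net_names[1], ] > 0 & true_maps[net_names[3], ] > 0) +
      sum(true_maps[net_names[2], ] > 0 & true_maps[net_names[3], ] > 0)
    support_c <- sum(true_maps[net_names[3], ] > 0)
    if (r_ac >= 0.1 || r_bc >= 0.1 || overlap > 0.02 * support_c) {
      stop("control network is not disjoint from the adjacent pair; grid too small",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

rtruncnorm01 <- function(n, mean, sd) {
  if (sd == 0) return(rep(pmin(pmax(mean, 0), 1), n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- stats::rnorm(1, mean, sd)
      if (x >= 0 && x <= 1) break
    }
    out[i] <- x
  }
  out
}

draw_phenotypes <- function(config) {
  n_p <- config$n_patients
  n_c <- config$n_controls
  draw2 <- function(n, ms) stats::rnorm(n, ms[1], ms[2])
  group <- c(rep("patient", n_p), rep("control", n_c))
  tibble::tibble(
    subject_id = sprintf("sub-%03d", seq_len(n_p + n_c)),
    group = factor(group, levels = c("control", "patient")),
    age = c(draw2(n_p, config$age_patient), draw2(n_c, config$age_control)),
    sex = factor(
      ifelse(stats::runif(n_p + n_c) <
               c(rep(config$male_frac_patient, n_p),
                 rep(config$male_frac_control, n_c)),
             "male", "female"),
      levels = c("female", "male")
    ),
    education = pmax(0, c(draw2(n_p, config$education_patient),
                          draw2(n_c, config$education_control))),
    mean_fd = pmax(0.01, c(draw2(n_p, config$mean_fd_patient),
                           draw2(n_c, config$mean_fd_control))),
    gm_fraction = pmin(0.99, pmax(0.01, c(draw2(n_p, config$gm_patient),
                                          draw2(n_c, config$gm_control)))),
    delta = c(if (config$delta_mean_patient == 0) rep(0, n_p) else
                rtruncnorm01(n_p, config$delta_mean_patient, config$delta_sd),
              rep(0, n_c))
  )
}

# Band-limited (0.01-0.1 Hz) Gaussian-process time courses, unit SD.
band_limited_timecourses <- function(nT, tr, K, f_lo = 0.01, f_hi = 0.1) {
  freqs <- seq_len(floor(nT / 2)) / (nT * tr)
  band <- which(freqs >= f_lo & freqs <= f_hi)
  if (length(band) == 0L) band <- 1L
  out <- matrix(0, nT, K)
  t_idx <- seq_len(nT)
  for (k in seq_len(K)) {
    x <- numeric(nT)
    amp <- stats::rnorm(length(band))
    phs <- stats::runif(length(band), 0, 2 * pi)
    for (j in seq_along(band)) {
      x <- x + amp[j] * cos(2 * pi * freqs[band[j]] * tr * t_idx + phs[j])
    }
    out[, k] <- as.numeric(scale(x))
  }
  out
}

#' Simulate one subject's BOLD series from the ground truth
#'
#' The data model is the linear mixing assumption underlying spatial ICA:
#' `data = sum_k timecourse_k(t) * map_k(v) + sensor noise`. The target
#' network's subject map is `(1 - delta) * true_map + delta * e`, where `e`
#' is a smooth random field scaled to the true map's SD over the mask, so
#' `delta = 0` reproduces the canonical network and `delta = 1` replaces it
#' with structured noise of equal variance. All other maps receive mild
#' smooth jitter.
#'
#' @param truth A [make_truth()] result.
#' @param subject_id Identifier.
#' @param delta Degradation fraction in `[0, 1]`.
#' @param seed Integer seed for this subject.
#' @return A list with the [bold_series()] (`series`), the subject's spatial
#'   maps (`maps`, `K x V`) and time courses (`timecourses`, `T x K`).
#' @export
simulate_subject <- function(truth, subject_id, delta, seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (delta < 0 || delta > 1) stop("`delta` must lie in [0, 1]", call. = FALSE)
  cfg <- truth$config
  mask <- truth$mask
  K_all <- nrow(truth$true_maps)
  with_seed(seed, {
    maps <- truth$true_maps
    # degrade the target network's spatial expression
    tgt <- truth$target
    base <- maps[tgt, ]
    if (delta > 0) {
      # heavy-tailed smooth corruption: a degraded network is still spatially
      # structured, and the degraded source stays identifiable to ICA
      eps <- as.numeric(scale(smooth_noise_field(mask)^3)) * stats::sd(base)
      maps[tgt, ] <- (1 - delta) * base + delta * eps
    }
    # mild spatial jitter on every other map
    if (cfg$subject_map_jitter_sd > 0) {
      for (k in setdiff(rownames(maps), tgt)) {
        maps[k, ] <- maps[k, ] + cfg$subject_map_jitter_sd * smooth_noise_field(mask)
      }
    }
    tcs <- band_limited_timecourses(cfg$n_timepoints, cfg$tr_seconds, K_all)
    data <- tcs %*% maps
    if (cfg$noise_sd > 0) {
      data <- data + cfg$noise_sd *
        matrix(stats::rnorm(length(data)), nrow(data), ncol(data))
    }
  })
  list(
    series = bold_series(subject_id, mask, data, tr_seconds = cfg$tr_seconds),
    maps = maps,
    timecourses = tcs
  )
}

#' Simulate a full two-group cohort
#'
#' Patients draw `delta` from a truncated normal
#' `TN(delta_mean_patient, delta_sd)` on `[0, 1]`; controls have `delta = 0`.
#' Covariates follow the configured distributions. Fully reproducible from
#' `config$seed`; per-subject seeds are derived from it.
#'
#' @param config A [generator_config()].
#' @return A `synthetic_cohort` list: `series` (list of [bold_series()]),
#'   `phenotypes` (tibble with `subject_id`, `group`, covariates, `delta`),
#'   and `truth`.
#' @export
simulate_cohort <- function(config) {
  truth <- make_truth(config)
  phen <- truth$phenotypes
  n <- nrow(phen)
  series <- vector("list", n)
  for (i in seq_len(n)) {
    sub_seed <- (config$seed * 1000L + i) %% .Machine$integer.max
    series[[i]] <- simulate_subject(truth, phen$subject_id[i],
                                    delta = phen$delta[i],
                                    seed = sub_seed)$series
  }
  names(series) <- phen$subject_id
  structure(
    list(series = series, phenotypes = phen, truth = truth),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort: %d patients + %d controls, T = %d, V = %d>\n",
              sum(x$phenotypes$group == "patient"),
              sum(x$phenotypes$group == "control"),
              x$series[[1]]$T, x$truth$mask$V))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits one 4D NIfTI per subject, the brain mask, a TSV phenotype table
#' (`subject_id group age sex education mean_fd gm_fraction`), the true
#' network maps as 3D NIfTI files, and a JSON sidecar with the per-subject
#' `delta` values and the generating seed.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mask <- cohort$truth$mask
  write_mask(mask, file.path(dir, "mask.nii.gz"))
  for (id in names(cohort$series)) {
    write_bold(cohort$series[[id]], file.path(dir, paste0(id, "_bold.nii.gz")))
  }
  for (nm in rownames(cohort$truth$true_maps)) {
    write_map(cohort$truth$true_maps[nm, ], mask,
              file.path(dir, paste0("truemap_", nm, ".nii.gz")))
  }
  phen <- cohort$phenotypes
  readr::write_tsv(phen[, c("subject_id", "group", "age", "sex", "education",
                            "mean_fd", "gm_fraction")],
                   file.path(dir, "phenotypes.tsv"))
  jsonlite::write_json(
    list(seed = cohort$truth$seed,
         target = cohort$truth$target,
         delta = stats::setNames(as.list(phen$delta), phen$subject_id)),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a phenotype table
#'
#' @param path TSV with header
#'   `subject_id group age sex education mean_fd gm_fraction`.
#' @return A tibble with `group` and `sex` as factors
#'   (`control`/`patient`, `female`/`male`).
#' @export
read_phenotypes <- function(path) {
  phen <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("subject_id", "group", "age", "sex", "education", "mean_fd",
            "gm_fraction")
  miss <- setdiff(need, names(phen))
  if (length(miss)) {
    stop("phenotype table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  phen$group <- factor(phen$group, levels = c("control", "patient"))
  phen$sex <- factor(phen$sex, levels = c("female", "male"))
  if (any(is.na(phen$group))) stop("group must be 'control' or 'patient'", call. = FALSE)
  if (any(phen$mean_fd < 0)) stop("mean_fd must be >= 0", call. = FALSE)
  if (any(phen$gm_fraction <= 0 | phen$gm_fraction >= 1)) {
    stop("gm_fraction must lie in (0, 1)", call. = FALSE)
  }
  phen
}
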