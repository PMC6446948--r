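test_that("greedy matching follows the stated rule on fixed matrices", {
  R1 <- rbind(c(0.9, 0.3), c(0.4, 0.8))
  colnames(R1) <- c("t1", "t2")
  m1 <- match_components_greedy(R1)
  expect_equal(m1$component[m1$network == "t1"], 1L)
  expect_equal(m1$component[m1$network == "t2"], 2L)
  expect_equal(sort(m1$r_abs, decreasing = TRUE), c(0.9, 0.8))
  # here greedy agrees with the exhaustive best assignment
  expect_equal(best_assignment(R1)$assignment, c(1L, 2L))

  # documented divergence: greedy grabs 0.9 first and is left with 0.2,
  # although the sum-optimal assignment pairs differently
  R2 <- rbind(c(0.9, 0.85), c(0.8, 0.2))
  colnames(R2) <- c("t1", "t2")
  m2 <- match_components_greedy(R2)
  expect_equal(m2$component[m2$network == "t1"], 1L)
  expect_equal(m2$r_abs[m2$network == "t2"], 0.2)
  opt <- best_assignment(R2)$assignment
  expect_equal(opt, c(2L, 1L))   # sum-optimal differs from greedy

  # single component, single template
  m3 <- match_components_greedy(matrix(0.4, 1, 1))
  expect_equal(m3$component, 1L)

  # fewer components than templates is an error
  expect_error(match_components_greedy(matrix(0.5, 1, 2)), "fewer components")
})

test_that("greedy equals the exhaustive assignment whenever its picks are optimal", {
  set.seed(77)
  n_diverge <- 0L
  for (i in 1:1000) {
    R <- matrix(runif(10), 5, 2)
    colnames(R) <- c("t1", "t2")
    got <- match_components_greedy(R)
    got <- got$component[order(got$network)]
    opt <- best_assignment(R)$assignment
    ref <- greedy_reference(R)
    # the implementation always reproduces the greedy rule
    expect_identical(got, ref)
    if (!identical(got, opt)) {
      n_diverge <- n_diverge + 1L
      # divergence only when the sum-optimal assignment avoids the global max
      i_max <- which(R == max(R), arr.ind = TRUE)[1, ]
      expect_false(opt[i_max[2]] == i_max[1])
    }
  }
  # divergences exist but are rare for random matrices
  expect_lt(n_diverge, 250L)
})

test_that("the integrity statistic is atanh of |r| on its domain", {
  expect_equal(integrity_from_correlation(0), 0)
  expect_equal(integrity_from_correlation(-0.5), atanh(0.5), tolerance = 1e-12)
  z <- integrity_from_correlation(c(0.3, 0.4, 0.5))
  expect_true(all(diff(z) > 0))
  expect_error(integrity_from_correlation(1), "< 1")
  # records honor z = atanh(r_abs) exactly
  rec <- pmnet:::integrity_record("s", "netA", "dual_regression", "auto", 0.62)
  expect_identical(rec$z, atanh(rec$r_abs))
})

test_that("dual regression recovers planted time courses and maps exactly", {
  mask <- tiny_mask(c(10L, 10L, 4L))
  V <- mask$V
  set.seed(51)
  map1 <- c(rep(2, 60), rep(0, V - 60))
  # zero-mean pattern on disjoint support: exactly uncorrelated with map1
  map2 <- c(rep(0, V - 80), rep(c(1.5, -1.5), 40))
  tc1 <- sin(seq_len(50) / 3)
  X <- outer(tc1, map1)
  s <- bold_series("s", mask, X)

  # single-map noiseless recovery: correlation 1 with the true time course
  tc_hat <- dual_regression_stage1(s, rbind(net = map1),
                                   variance_normalize = FALSE)
  expect_equal(abs(cor(tc_hat[, 1], tc1)), 1, tolerance = 1e-10)

  # adding an orthogonal zero-weight map leaves its column at zero variance
  tc_two <- dual_regression_stage1(s, rbind(net = map1, other = map2),
                                   variance_normalize = FALSE)
  expect_lt(var(tc_two[, "other"]), 1e-8)

  # variance normalization contract
  tc_norm <- dual_regression_stage1(
    bold_series("s2", mask, X + matrix(rnorm(50 * V, sd = 0.1), 50)),
    rbind(net = map1, other = map2)
  )
  expect_equal(apply(tc_norm, 2, var), c(net = 1, other = 1), tolerance = 1e-8)

  # stage 2 on two-component noiseless data
  tc2 <- cos(seq_len(50) / 5)
  X2 <- outer(tc1, map1) + outer(tc2, map2)
  s2 <- bold_series("s3", mask, X2)
  tcs <- dual_regression_stage1(s2, rbind(a = map1, b = map2))
  maps_hat <- dual_regression_stage2(s2, tcs)
  expect_equal(abs(cor(maps_hat["a", ], map1)), 1, tolerance = 1e-8)
  expect_equal(abs(cor(maps_hat["b", ], map2)), 1, tolerance = 1e-8)
  expect_lt(abs(cor(maps_hat["a", ], map2)), 0.05)

  # residuals orthogonal to the regressors
  fit <- cbind(1, tcs) %*% qr.coef(qr(cbind(1, tcs)), s2$data)
  resid <- s2$data - fit
  expect_lt(max(abs(crossprod(tcs, resid))), 1e-6)

  # collinear maps are refused
  expect_error(dual_regression_stage1(s2, rbind(a = map1, b = 2 * map1)),
               "collinear|rank")
})

test_that("dual-regression integrity follows the correlation model", {
  set.seed(52)
  V <- 1000
  tmpl <- rnorm(V)
  templates <- template_set(rbind(net = tmpl))

  # map equal to template: clipped and flagged as saturated
  rec <- dual_regression_integrity(rbind(net = tmpl), templates, "s")
  expect_lt(rec$r_abs, 1)
  expect_gt(rec$z, 13)
  expect_true(rec$low_confidence)

  # SNR 1 noise: r concentrates near 1/sqrt(2)
  rs <- sapply(1:20, function(i) {
    m <- tmpl + rnorm(V, sd = sd(tmpl))
    dual_regression_integrity(rbind(net = m), templates, "s")$r_abs
  })
  expect_equal(mean(rs), 1 / sqrt(2), tolerance = 0.05)

  # orthogonal map: integrity near zero
  zs <- sapply(1:20, function(i) {
    dual_regression_integrity(rbind(net = rnorm(V)), templates, "s")$z
  })
  expect_lt(mean(abs(zs)), 0.05)

  # constant map: flagged, missing integrity
  rec0 <- dual_regression_integrity(rbind(net = rep(1, V)), templates, "s")
  expect_true(rec0$low_confidence)
  expect_true(is.na(rec0$z))
})

test_that("template matching scores a planted template near-perfectly", {
  # noiseless mixture of three mutually uncorrelated non-Gaussian sources,
  # one of which is the template itself
  mask <- tiny_mask(c(10L, 10L, 6L))
  V <- mask$V
  set.seed(61)
  idx <- seq_len(V)
  s1 <- 3 * exp(-(idx - 150)^2 / (2 * 20^2))            # the template
  s2 <- c(rep(0, 300), rep(c(2, -2), 50), rep(0, V - 400))
  s3 <- c(rep(0, 450), rep(c(1.5, -1.5), 40), rep(0, V - 530))
  S <- rbind(s1, s2, s3)
  X <- matrix(rnorm(60 * 3), 60) %*% S
  series <- bold_series("s", mask, X)
  templates <- template_set(rbind(net = s1))
  res <- template_matching_integrity(series, templates, MO = 3, seed = 2)
  expect_gt(res$records$r_abs, 0.99)
  expect_gt(res$records$z, 2.6)
  expect_identical(res$records$z, atanh(res$records$r_abs))
  expect_equal(res$records$method, "template_matching")
})

test_that("both back-reconstruction routes rank subjects concordantly", {
  cell <- get_demo_cell()
  rec <- cell$records
  z_tm <- rec$z[rec$method == "template_matching" & rec$network == "netA"]
  z_dr <- rec$z[rec$method == "dual_regression" & rec$network == "netA"]
  names(z_tm) <- rec$subject_id[rec$method == "template_matching" &
                                  rec$network == "netA"]
  names(z_dr) <- rec$subject_id[rec$method == "dual_regression" &
                                  rec$network == "netA"]
  common <- intersect(names(z_tm), names(z_dr))
  rho <- cor(z_tm[common], z_dr[common], method = "spearman")
  expect_gt(rho, 0.7)
})

test_that("noiseless cohorts give high integrity for every network and subject", {
  cfg <- generator_config(n_patients = 3, n_controls = 3, seed = 62,
                          noise_sd = 0, subject_map_jitter_sd = 0,
                          delta_mean_patient = 0, K_noise = 2,
                          dims = c(12, 12, 6), n_timepoints = 40)
  co <- simulate_cohort(cfg)
  recs <- truth_dr_records(co)
  expect_true(all(recs$z > 2))
})
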