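test_that("concatenation normalizes each subject block per voxel", {
  mask <- tiny_mask()
  set.seed(41)
  # already standardized input passes through
  X <- matrix(rnorm(50 * mask$V), 50)
  X <- sweep(X, 2, colMeans(X))
  X <- sweep(X, 2, apply(X, 2, sd), "/")
  s <- bold_series("a", mask, X)
  expect_equal(concat_and_normalize(list(s)), X, tolerance = 1e-10)

  # two identical subjects stack to identical blocks
  out <- concat_and_normalize(list(s, s))
  expect_equal(nrow(out), 100L)
  expect_identical(out[1:50, ], out[51:100, ])

  # per-block unit variance after normalization
  Y <- matrix(rnorm(40 * mask$V, sd = 7), 40) + 3
  out2 <- concat_and_normalize(list(bold_series("b", mask, Y)))
  expect_equal(apply(out2, 2, sd), rep(1, mask$V), tolerance = 1e-8)

  # zero-variance voxel zeroed with a warning
  Z <- matrix(rnorm(40 * mask$V), 40)
  Z[, 5] <- 2
  expect_warning(out3 <- concat_and_normalize(list(bold_series("c", mask, Z))),
                 "zero-variance")
  expect_true(all(out3[, 5] == 0))
})

test_that("Laplace-evidence model order recovers planted ranks", {
  make_phantom <- function(seed, snr, K = 3, Tt = 200, V = 500) {
    set.seed(seed)
    A <- matrix(rnorm(Tt * K), Tt)
    S <- matrix(rnorm(K * V), K)
    X <- A %*% S
    X <- X / sd(X) * sqrt(snr)
    X + matrix(rnorm(Tt * V), Tt)
  }
  # rank 3 at SNR 10: correct in all of 10 seeds
  est <- sapply(1:10, function(s) estimate_model_order(make_phantom(s, 10), 20))
  expect_true(all(est == 3L))

  # pure isotropic noise floors at 2
  set.seed(3)
  noise <- matrix(rnorm(200 * 500), 200)
  expect_equal(estimate_model_order(noise, 20), 2L)

  # estimate never decreases with SNR on the same phantom
  ests <- sapply(c(2, 5, 10), function(snr) {
    median(sapply(1:5, function(s) estimate_model_order(make_phantom(s, snr), 20)))
  })
  expect_true(all(diff(ests) >= 0))

  # degenerate spectrum warns and floors
  expect_warning(
    out <- estimate_model_order(matrix(rep(rnorm(100), 50), nrow = 50,
                                       byrow = TRUE), 10),
    "degenerate"
  )
  expect_equal(out, 2L)
})

test_that("fixed-point spatial ICA recovers planted sources deterministically", {
  set.seed(13)
  V <- 800
  Tt <- 60
  S <- rbind(
    c(rep(6, 50), rep(0, V - 50)),
    c(rep(0, V - 90), rep(5, 90))
  ) + matrix(rnorm(2 * V, sd = 0.01), 2)
  A <- matrix(rnorm(Tt * 2), Tt)
  X <- A %*% S

  cs <- spatial_ica(X, 2, seed = 4)
  cc <- abs(cor(t(S), t(cs$maps)))
  expect_true(all(apply(cc, 1, max) > 0.99))

  # canonical form: z-scored maps, non-negative skewness, variance ordering
  expect_equal(rowMeans(cs$maps), c(0, 0), tolerance = 1e-8)
  expect_equal(apply(cs$maps, 1, function(m) mean(m^2)), c(1, 1),
               tolerance = 1e-8)
  expect_true(all(pmnet:::row_skewness(cs$maps) >= 0))
  expect_true(all(diff(cs$explained_variance) <= 1e-12))

  # same seed, same result
  cs2 <- spatial_ica(X, 2, seed = 4)
  expect_equal(cs$maps, cs2$maps, tolerance = 1e-8)

  # noiseless K-source recovery up to K = 5, blob-profile sources as in
  # network maps (continuous and localized)
  set.seed(14)
  K <- 5
  idx <- seq_len(V)
  S5 <- t(sapply(seq_len(K), function(k) {
    4 * exp(-(idx - k * 130)^2 / (2 * 15^2))
  }))
  S5 <- S5 + matrix(rnorm(K * V, sd = 0.01), K)
  X5 <- matrix(rnorm(80 * K), 80) %*% S5
  cs5 <- spatial_ica(X5, K, seed = 2)
  cc5 <- abs(cor(t(S5), t(cs5$maps)))
  expect_gt(min(apply(cc5, 1, max)), 0.99)
})

test_that("whitening and unmixing satisfy their algebraic contracts", {
  set.seed(15)
  X <- matrix(rnorm(80 * 300), 80) %*% matrix(rnorm(300 * 400, sd = 0.3), 300)
  eigs <- pmnet:::pca_eigs(X)
  Z <- pmnet:::whiten_from_eigs(eigs, 6)
  expect_equal(tcrossprod(Z) / ncol(Z), diag(6), tolerance = 1e-8)

  # dual (V < T) route gives whitened rows too
  Xt <- t(X)
  eigs2 <- pmnet:::pca_eigs(Xt)
  Z2 <- pmnet:::whiten_from_eigs(eigs2, 4)
  expect_equal(tcrossprod(Z2) / ncol(Z2), diag(4), tolerance = 1e-8)
})

test_that("network selection matches by spatial correlation with a floor", {
  set.seed(16)
  maps <- matrix(rnorm(3 * 500), 3)
  maps <- (maps - rowMeans(maps)) / sqrt(rowMeans((maps - rowMeans(maps))^2))
  comps <- structure(
    list(maps = maps, timecourses = NULL,
         explained_variance = c(3, 2, 1), MO = 3L, source = "test", seed = 1L),
    class = "component_set"
  )

  # components select themselves at r = 1
  self_refs <- template_set(rbind(one = maps[1, ], three = maps[3, ]))
  sel <- select_networks(comps, self_refs)
  expect_equal(sort(sel$info$component), c(1L, 3L))
  expect_equal(sel$info$r_abs, c(1, 1), tolerance = 1e-12)

  # noisy copies of components 1 and 3 select those components
  noisy <- rbind(n1 = maps[1, ] + rnorm(500, sd = 0.8),
                 n3 = maps[3, ] + rnorm(500, sd = 0.8))
  sel2 <- select_networks(comps, template_set(noisy))
  expect_setequal(sel2$info$component, c(1L, 3L))
  expect_false(any(sel2$info$low_confidence))

  # an unrelated reference triggers the low-confidence warning
  junk <- template_set(rbind(x = rnorm(500, sd = 1)))
  expect_warning(sel3 <- select_networks(comps, junk), "low-confidence")
  expect_true(sel3$info$low_confidence[1])
})
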