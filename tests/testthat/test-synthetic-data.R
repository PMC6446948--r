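test_that("ground truth is deterministic and geometrically valid", {
  cfg <- generator_config(seed = 5)
  t1 <- make_truth(cfg)
  t2 <- make_truth(cfg)
  expect_identical(t1$true_maps, t2$true_maps)
  expect_identical(t1$phenotypes, t2$phenotypes)

  M <- t1$true_maps
  expect_equal(nrow(M), cfg$K_networks + cfg$K_noise)
  r_ab <- cor(M["netA", ], M["netB", ])
  expect_gt(r_ab, 0)
  expect_lt(r_ab, 0.5)
  expect_lt(cor(M["netA", ], M["netC", ]), 0.1)
  # adjacency: the first two networks share support
  expect_gt(sum(M["netA", ] > 0 & M["netB", ] > 0), 0)

  # K_networks = 3, K_noise = 2 -> 5 maps
  t3 <- make_truth(generator_config(K_noise = 2, seed = 5))
  expect_equal(nrow(t3$true_maps), 5L)
})

test_that("subject simulation responds to the degradation fraction", {
  cfg <- generator_config(seed = 9)
  truth <- make_truth(cfg)
  M <- truth$true_maps

  # noiseless identity: data = timecourses x maps, rank = K
  cfg0 <- generator_config(seed = 9, noise_sd = 0,
                           subject_map_jitter_sd = 0)
  truth0 <- make_truth(cfg0)
  sub0 <- simulate_subject(truth0, "s", delta = 0, seed = 3)
  expect_equal(sub0$series$data,
               sub0$timecourses %*% sub0$maps, tolerance = 1e-12)
  expect_equal(qr(sub0$series$data)$rank, nrow(truth0$true_maps))

  # delta = 1 destroys the target expression
  sub1 <- simulate_subject(truth, "s", delta = 1, seed = 3)
  expect_lt(abs(cor(sub1$maps["netA", ], M["netA", ])), 0.2)

  # monotone decay of the target-map correlation in delta, averaged over seeds
  deltas <- c(0, 0.25, 0.5, 0.75, 1)
  mean_r <- sapply(deltas, function(d) {
    mean(sapply(1:10, function(sd) {
      cor(simulate_subject(truth, "s", delta = d, seed = 100 + sd)$maps["netA", ],
          M["netA", ])
    }))
  })
  expect_true(all(diff(mean_r) < 0))
})

test_that("cohorts honor group sizes, null configs and seeds", {
  cfg <- generator_config(seed = 2, dims = c(10, 10, 6), n_timepoints = 30,
                          K_noise = 2)
  co <- simulate_cohort(cfg)
  expect_equal(sum(co$phenotypes$group == "patient"), 36L)
  expect_equal(sum(co$phenotypes$group == "control"), 43L)
  expect_equal(length(co$series), 79L)
  expect_true(all(co$phenotypes$delta[co$phenotypes$group == "control"] == 0))

  # determinism / seed sensitivity
  co_b <- simulate_cohort(cfg)
  expect_identical(co$series[[1]]$data, co_b$series[[1]]$data)
  co_c <- simulate_cohort(generator_config(seed = 3, dims = c(10, 10, 6),
                                           n_timepoints = 30, K_noise = 2))
  expect_false(identical(co$series[[1]]$data, co_c$series[[1]]$data))

  # delta_mean_patient = 0 gives exchangeable groups by construction
  null_cfg <- small_null_config(seed = 4, n_per_group = 5L)
  co0 <- simulate_cohort(null_cfg)
  expect_true(all(co0$phenotypes$delta == 0))
})

test_that("planted deficit strength orders cohorts; control net stays null", {
  # mean patient correlation to the true target map decreases in delta
  mean_target_r <- function(delta_mean, seed) {
    cfg <- generator_config(n_patients = 6, n_controls = 2,
                            dims = c(12, 12, 6), n_timepoints = 30,
                            K_noise = 2, delta_mean_patient = delta_mean,
                            seed = seed)
    co <- simulate_cohort(cfg)
    pat <- which(co$phenotypes$group == "patient")
    mean(sapply(pat, function(i) {
      s <- simulate_subject(co$truth, "x", co$phenotypes$delta[i],
                            seed = cfg$seed * 1000 + i)
      cor(s$maps["netA", ], co$truth$true_maps["netA", ])
    }))
  }
  means <- sapply(c(0.2, 0.5, 0.8), function(d) {
    mean(sapply(1:10, function(s) mean_target_r(d, 400 + s)))
  })
  expect_true(all(diff(means) < 0))

  # control-network expression does not differ between groups
  pvals <- sapply(1:10, function(s) {
    co <- simulate_cohort(
      generator_config(n_patients = 12, n_controls = 12, dims = c(12, 12, 6),
                       n_timepoints = 40, K_noise = 2, seed = 700 + s)
    )
    rs <- sapply(seq_along(co$series), function(i) {
      sub <- simulate_subject(co$truth, "x", co$phenotypes$delta[i],
                              seed = (700 + s) * 1000 + i)
      cor(sub$maps["netC", ], co$truth$true_maps["netC", ])
    })
    t.test(rs[co$phenotypes$group == "patient"],
           rs[co$phenotypes$group == "control"])$p.value
  })
  expect_gte(sum(pvals > 0.01), 9L)
})

test_that("cohorts round-trip through the on-disk layout", {
  cfg <- generator_config(n_patients = 2, n_controls = 2, dims = c(10, 10, 6),
                          n_timepoints = 20, K_noise = 1, seed = 31)
  co <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  loaded <- pmnet:::load_cohort(dir)
  expect_equal(loaded$mask$V, co$truth$mask$V)
  expect_equal(loaded$series[[1]]$data, co$series[[1]]$data, tolerance = 1e-12)
  expect_equal(as.character(loaded$phenotypes$group),
               as.character(co$phenotypes$group))
  expect_equal(loaded$reference_maps["netA", ],
               co$truth$true_maps["netA", ], tolerance = 1e-12)
  truth_json <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth_json$seed, 31L)
})
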