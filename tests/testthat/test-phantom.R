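test_that("presets renormalize printed fractions to a unit simplex", {
  p <- study_preset("invivo", 30, "sham")
  # 0.81 / 0.05 / 0.06 scaled by 1/0.92
  expect_equal(p$fiber_fraction, 0.81 / 0.92, tolerance = 1e-12)
  expect_equal(p$restricted_fraction, 0.05 / 0.92, tolerance = 1e-12)
  expect_equal(p$fiber_fraction + p$restricted_fraction +
                 p$nonrestricted_fraction, 1, tolerance = 1e-12)
  expect_equal(p$renormalization, 1 / 0.92, tolerance = 1e-12)
  expect_equal(p$lambda_par, 1.84)
  expect_equal(p$lambda_perp, 0.14)
  # every study preset is a valid composition
  gm <- study_group_means()
  combos <- unique(gm[, c("mode", "day", "group")])
  for (k in seq_len(nrow(combos))) {
    pk <- study_preset(combos$mode[k], combos$day[k], combos$group[k])
    expect_equal(pk$fiber_fraction + pk$restricted_fraction +
                   pk$nonrestricted_fraction, 1, tolerance = 1e-9)
    expect_lte(pk$lambda_perp, pk$lambda_par)
  }
})

test_that("voxel simulation is seeded and exact without noise", {
  p <- study_preset("invivo", 3, "TBI")
  clean <- simulate_voxel(p, ivs, snr = Inf)
  expect_identical(clean, forward_signal(dbsir:::.preset_model(p), ivs))
  expect_identical(simulate_voxel(p, ivs, snr = 25, seed = 11),
                   simulate_voxel(p, ivs, snr = 25, seed = 11))
  expect_false(identical(simulate_voxel(p, ivs, snr = 25, seed = 11),
                         simulate_voxel(p, ivs, snr = 25, seed = 12)))
  # noise never drives magnitudes negative
  expect_true(all(simulate_voxel(p, ivs, snr = 5, seed = 1) >= 0))
})

test_that("Rician corruption matches closed-form second-moment scaling", {
  snr <- 30
  reps <- dbsir:::with_seed(99, dbsir:::.rician(rep(1, 10000), 1 / snr))
  # E[S^2] = s0^2 + 2 sigma^2, so the RMS is sqrt(1 + 2/snr^2); at this
  # SNR the mean is within 0.5% of the RMS-corrected value
  expect_equal(mean(reps), sqrt(1 + 2 / snr^2), tolerance = 0.005)
  expect_equal(sqrt(mean(reps^2)), sqrt(1 + 2 / snr^2), tolerance = 0.002)
})

test_that("cohort simulation has the declared structure and is reproducible", {
  spec <- cohort_spec("invivo", days = c(1, 30), n_per_group = 2, snr = 30,
                      seed = 5, voxel_dims = c(0.25, 0.25, 1))
  co <- simulate_cohort(spec)
  expect_length(co$nerves, 2 * 2 * 2 * 2)   # groups x animals x eyes x days
  expect_setequal(unique(co$truth$group), c("sham", "TBI"))
  expect_equal(nrow(co$truth), length(co$nerves) * 7)  # 7 truth metrics
  co2 <- simulate_cohort(spec)
  expect_identical(serialize(co, NULL), serialize(co2, NULL))
  co3 <- simulate_cohort(cohort_spec("invivo", days = c(1, 30),
                                     n_per_group = 2, snr = 30, seed = 6,
                                     voxel_dims = c(0.25, 0.25, 1)))
  expect_false(identical(co$nerves[[1]]$dwi, co3$nerves[[1]]$dwi))
})

test_that("eyes of one animal share parameters; animals differ", {
  spec <- cohort_spec("invivo", days = 30, n_per_group = 3, snr = 30,
                      seed = 2, voxel_dims = c(0.25, 0.25, 1))
  tr <- simulate_cohort(spec)$truth
  ff <- tr[tr$metric == "fiber_fraction" & tr$group == "sham", ]
  by_animal <- split(ff$value, ff$animal)
  for (v in by_animal) expect_equal(v[1], v[2])
  expect_gt(length(unique(vapply(by_animal, `[`, 0, 1))), 1L)
})

test_that("nerve cross-sections match volume arithmetic", {
  # 0.14 mm^3 at the reconstructed 0.0586 x 0.0586 x 1 mm grid -> 41 voxels
  vox <- prod(c(0.0586, 0.0586, 1))
  expect_equal(round(0.14 / vox), 41)
  roi <- dbsir:::.nerve_roi(41)
  expect_equal(nrow(roi$voxels), 41)
  expect_equal(anyDuplicated(roi$voxels), 0)
  # a voxel larger than the nerve is refused with guidance
  expect_error(simulate_cohort(cohort_spec("invivo", days = 30,
                                           n_per_group = 1,
                                           voxel_dims = c(1, 1, 1))),
               "voxel_dims")
})

test_that("ground-truth group means converge to preset means", {
  spec <- cohort_spec("invivo", days = 30, n_per_group = 200, snr = 30,
                      seed = 31, voxel_dims = c(0.25, 0.25, 1))
  tr <- simulate_cohort(spec)$truth
  for (grp in c("sham", "TBI")) {
    p <- study_preset("invivo", 30, grp)
    for (m in c("fiber_fraction", "dbsi_lambda_par")) {
      v <- tr$value[tr$metric == m & tr$group == grp]
      v_animal <- tapply(v, tr$animal[tr$metric == m & tr$group == grp], mean)
      se <- sd(v_animal) / sqrt(length(v_animal))
      expect_lt(abs(mean(v_animal) - p[[sub("dbsi_", "", m)]]), 3 * se)
    }
  }
})

test_that("a noise-free single-animal cohort is recovered end to end", {
  spec <- cohort_spec("invivo", days = 30, n_per_group = 1, snr = Inf,
                      seed = 8, voxel_dims = c(0.25, 0.25, 1))
  co <- simulate_cohort(spec)
  tab <- summarize_cohort(co)
  tr <- co$truth
  for (m in c("fiber_fraction", "restricted_fraction", "dbsi_lambda_par")) {
    for (k in seq_len(nrow(tab[tab$metric == m, ]))) {
      row <- tab[tab$metric == m, ][k, ]
      truth_val <- tr$value[tr$metric == m & tr$animal == row$animal &
                              tr$eye == row$eye]
      tol <- if (m == "dbsi_lambda_par") 0.05 else 0.03
      expect_equal(row$value, truth_val, tolerance = tol)
    }
  }
})
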