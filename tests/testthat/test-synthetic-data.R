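test_that("phantom generation is deterministic and internally consistent", {
  spec <- phantom_spec(nx = 32, ny = 32, n_slices = 2, n_lesions = 1,
                       target_wm_long_volume = 0.012, seed = 5)
  ph1 <- make_phantom(spec)
  ph2 <- make_phantom(spec)
  expect_identical(ph1$fractions, ph2$fractions)
  expect_identical(ph1$masks$lesions, ph2$masks$lesions)

  # fractions sum to 1 on every brain voxel, 0 outside
  tot <- apply(ph1$fractions, 1:3, sum)
  expect_equal(tot[ph1$masks$brain], rep(1, sum(ph1$masks$brain)),
               tolerance = 1e-12)
  expect_equal(max(abs(tot[!ph1$masks$brain])), 0)

  # tissue masks partition the brain
  m <- ph1$masks
  expect_false(any(m$white_matter & m$gray_matter))
  expect_false(any(m$white_matter & m$csf))
  expect_true(all(m$lesions[m$lesions] & m$white_matter[m$lesions]))
  expect_true(all((m$white_matter | m$gray_matter | m$csf) == m$brain))

  # lobe labels cover the brain disjointly
  expect_setequal(unique(as.vector(ph1$masks$lobe_labels[m$brain])), 1:8)
  expect_true(all(ph1$masks$lobe_labels[!m$brain] == 0))
})

test_that("the rim amplitude solve hits the target volume exactly", {
  for (tgt in c(0.003, 0.0088, 0.02)) {
    ph <- make_phantom(phantom_spec(nx = 32, ny = 32, n_slices = 2,
                                    n_lesions = if (tgt < 0.005) 0L else 1L,
                                    seed = 3,
                                    target_wm_long_volume = tgt))
    expect_equal(ph$gt_wm_long_volume, tgt, tolerance = 1e-6)
    wm <- ph$masks$white_matter
    ci_long <- which(ph$components$name == "long_t2star")
    got <- sum(ph$fractions[, , , ci_long][wm]) / sum(wm)
    expect_equal(got, tgt, tolerance = 1e-6)
  }
  expect_error(make_phantom(phantom_spec(nx = 32, ny = 32, n_slices = 2,
                                         n_lesions = 8, seed = 3,
                                         target_wm_long_volume = 1e-4)),
               "lesion")
})

test_that("control phantoms have no lesions and only the rim signal", {
  ph <- make_phantom(phantom_spec(nx = 32, ny = 32, n_slices = 2,
                                  n_lesions = 0,
                                  target_wm_long_volume = 0.003, seed = 4))
  expect_equal(sum(ph$masks$lesions), 0)
  expect_equal(max(ph$masks$lesion_probability), 0)
  expect_equal(ph$gt_wm_long_volume, 0.003, tolerance = 1e-6)
})

test_that("different seeds move the lesions but keep the geometry", {
  s1 <- make_phantom(phantom_spec(nx = 32, ny = 32, n_slices = 2,
                                  n_lesions = 1, seed = 10))
  s2 <- make_phantom(phantom_spec(nx = 32, ny = 32, n_slices = 2,
                                  n_lesions = 1, seed = 11))
  expect_false(identical(s1$masks$lesions, s2$masks$lesions))
  expect_identical(s1$masks$brain, s2$masks$brain)
  expect_equal(s1$gt_wm_long_volume, s2$gt_wm_long_volume, tolerance = 1e-6)
})

test_that("noiseless voxel signals are the convex combinations of atoms", {
  ph <- ref_phantom()
  tr <- ref_train()
  acq <- ref_acquisition()
  # pick a mixed white-matter voxel and rebuild its signal by hand
  wm_idx <- which(ph$masks$white_matter)[10]
  co <- arrayInd(wm_idx, dim(ph$masks$brain))
  fr <- ph$fractions[co[1], co[2], co[3], ]
  b1 <- ph$b1[co[1], co[2], co[3]]
  S <- simulate_signals(tr, ph$components$t1_ms, ph$components$t2star_ms,
                        b1_eff = b1)
  expect_equal(acq$series[co[1], co[2], co[3], ], as.numeric(S %*% fr),
               tolerance = 1e-12)
})

test_that("Rician noise has the requested level and keeps magnitudes positive", {
  ph <- ref_phantom()
  acq <- simulate_acquisition(ph, ref_train(), snr = 50, seed = 1)
  expect_true(all(acq$series >= 0))
  # air voxels are pure Rician noise: sigma from their second moment
  air <- !ph$masks$brain
  vals <- as.vector(acq$series[, , , 1])[as.vector(air)]
  sigma_hat <- sqrt(mean(vals^2) / 2)
  expect_lt(abs(sigma_hat - acq$sigma) / acq$sigma, 0.1)
  # determinism given the seed
  acq2 <- simulate_acquisition(ph, ref_train(), snr = 50, seed = 1)
  expect_identical(acq$series, acq2$series)
  expect_error(simulate_acquisition(ph, ref_train(), snr = 0), "snr")
})

test_that("synthetic cohorts reproduce their generative parameters", {
  spec <- cohort_spec(seed = 20)
  tab <- make_cohort(spec)
  expect_identical(tab, make_cohort(spec))
  expect_equal(nrow(tab), 60)
  expect_equal(sum(tab$group == "patient"), 48)
  expect_false(any(duplicated(tab$id)))
  expect_true(all(tab$volume >= 0))
  expect_true(all(is.na(tab$edss[tab$group == "control"])))

  # group means within 3 standard errors of the generative means
  pat <- tab$volume[tab$group == "patient"]
  con <- tab$volume[tab$group == "control"]
  expect_lt(abs(mean(pat) - 0.0088), 3 * 0.0053 / sqrt(48))
  expect_lt(abs(mean(con) - 0.0030), 3 * 0.0020 / sqrt(12))

  expect_error(cohort_spec(vol_mean = c(control = -0.02, patient = 0.0088),
                           vol_sd = c(control = 0.002, patient = 0.0053)),
               "truncation")
})

test_that("cohorts can carry per-subject phantom specifications", {
  tab <- make_cohort(cohort_spec(n_patients = 2, n_controls = 1, seed = 8),
                     phantom_specs = TRUE, nx = 32L, ny = 32L, n_slices = 1L)
  specs <- attr(tab, "phantom_specs")
  expect_length(specs, 3)
  expect_equal(specs[[1]]$target_wm_long_volume, tab$volume[1])
  expect_equal(specs[[3]]$n_lesions, 0L)  # control
  expect_gt(specs[[1]]$n_lesions, 0L)     # patient
})

test_that("maps survive a NIfTI round trip", {
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  path <- tempfile(fileext = ".nii.gz")
  write_nifti_map(x, path, voxel_mm = c(1, 1, 2))
  y <- read_nifti_map(path)
  expect_equal(as.vector(y), as.vector(x), tolerance = 1e-6)
  expect_equal(attr(y, "voxel_mm"), c(1, 1, 2), tolerance = 1e-6)
  unlink(path)
})
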