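rnorm_fix <- function(n, mean, sd) {
  set.seed(n + round(mean))
  rnorm(n, mean, sd)
}

outer_mask <- function(n) {
  m <- array(FALSE, c(n, n, 1)); m[n, n, 1] <- TRUE; m
}

test_that("k-means on log relaxation times recovers separated clusters", {
  pts <- data.frame(
    t1_ms = c(rnorm_fix(25, 970, 5), rnorm_fix(25, 1200, 5)),
    t2star_ms = c(rnorm_fix(25, 45, 0.2), rnorm_fix(25, 46, 0.2)))
  cs <- cluster_components(pts, k = 2, seed = 1)
  means <- sort(cs$summary$t1_mean_ms)
  expect_equal(means, c(mean(pts$t1_ms[1:25]), mean(pts$t1_ms[26:50])),
               tolerance = 1e-9)
  expect_equal(sort(table(cs$assignment)), sort(c(25L, 25L)),
               ignore_attr = TRUE)
})

test_that("k = 1 returns the geometric-mean-backtransformed centroid", {
  pts <- data.frame(t1_ms = c(500, 2000), t2star_ms = c(50, 200))
  cs <- cluster_components(pts, k = 1, seed = 1)
  expect_equal(cs$summary$t1_centroid_ms, sqrt(500 * 2000))
  expect_equal(cs$summary$t2star_centroid_ms, sqrt(50 * 200))
  # arithmetic summaries stay in original units
  expect_equal(cs$summary$t1_mean_ms, 1250)
})

test_that("multi-restart clustering matches a brute-force restart oracle", {
  set.seed(14)
  pts <- data.frame(t1_ms = exp(runif(50, log(100), log(4000))),
                    t2star_ms = exp(runif(50, log(10), log(1000))))
  cs <- cluster_components(pts, k = 3, seed = 7, n_init = 20)
  X <- cbind(log(pts$t1_ms), log(pts$t2star_ms))
  best <- Inf
  set.seed(99)
  for (i in 1:200) {
    km <- stats::kmeans(X, centers = 3)
    best <- min(best, km$tot.withinss)
  }
  expect_lte(cs$tot_withinss, best * (1 + 1e-8))
  expect_error(cluster_components(pts, k = 0), "k must be")
  expect_error(cluster_components(pts, k = 51), "exceed")
})

test_that("long-T2* selection applies strict open bounds and merges maps", {
  comp <- data.frame(pair = 1:4,
                     t1_ms = c(1489, 970, 1489, 4000),
                     t2star_ms = c(1000, 45, 800, 2984))
  fr <- array(0, c(4, 4, 1, 4))
  fr[, , 1, 1] <- 0.1
  fr[, , 1, 3] <- 0.2
  fr[, , 1, 2] <- 0.7
  sol <- structure(list(components = comp, fractions = fr),
                   class = "mcmrf_solution")
  out <- select_long_t2star(sol)
  expect_equal(out$components$pair, c(1L, 3L))   # (970,45) and CSF excluded
  expect_equal(out$map[1, 1, 1], 0.3)
  expect_false(out$empty)
  none <- select_long_t2star(sol, t1_bounds_ms = c(5000, 6000))
  expect_true(none$empty)
  expect_equal(max(none$map), 0)
})

test_that("regional volumes are fraction means over the region", {
  wm <- array(FALSE, c(5, 4, 1)); wm[, 1:2, 1] <- TRUE      # 10 voxels
  masks <- list(white_matter = wm)
  fmap <- array(0, c(5, 4, 1))
  expect_equal(mask_and_volume(fmap, masks), 0)
  fmap[wm] <- 0.5
  expect_equal(mask_and_volume(fmap, masks), 0.5)
  fmap[wm] <- c(1, 1, 0.5, rep(0, 7))
  expect_equal(mask_and_volume(fmap, masks), 0.25)
  expect_error(mask_and_volume(fmap, list(white_matter = array(FALSE, c(5, 4, 1)))),
               "empty region")
})

test_that("lesion exclusion and lobe restriction compose correctly", {
  wm <- array(TRUE, c(6, 6, 1))
  lobes <- array(1L, c(6, 6, 1)); lobes[4:6, , 1] <- 2L
  lesion_p <- array(0, c(6, 6, 1)); lesion_p[1, 1, 1] <- 0.9
  masks <- list(white_matter = wm, lobe_labels = lobes,
                lesion_probability = lesion_p)
  fmap <- array(0.2, c(6, 6, 1)); fmap[1, 1, 1] <- 1
  v_all <- mask_and_volume(fmap, masks, region = 1)
  v_nol <- mask_and_volume(fmap, masks, region = 1, lesions_excluded = TRUE)
  expect_equal(v_all, (17 * 0.2 + 1) / 18)
  expect_equal(v_nol, 0.2)
  expect_lte(v_nol, v_all)   # in-lesion fraction above the regional mean
  # additivity of numerators across disjoint regions
  n1 <- v_all * 18
  n2 <- mask_and_volume(fmap, masks, region = 2) * 18
  expect_equal(n1 + n2, sum(fmap))
})

test_that("lesion overlap reports dice, volumes and excess involvement", {
  a <- array(0, c(8, 8, 1)); a[2:5, 2:5, 1] <- 0.5
  les <- array(FALSE, c(8, 8, 1)); les[2:5, 2:5, 1] <- TRUE
  same <- lesion_overlap(a, les)
  expect_equal(same$dice, 1)
  expect_equal(same$excess_fraction, 0)
  disj <- lesion_overlap(a, array(FALSE, c(8, 8, 1)) | outer_mask(8))
  expect_equal(disj$dice, 0)
  expect_equal(disj$excess_fraction, 1)
  # a rim around the lesion: excess equals rim / total by direct counting
  rim <- a; rim[2:6, 2:6, 1] <- 0.5       # extends one row/col beyond
  ov <- lesion_overlap(rim, les)
  n_total <- 25; n_rim <- 25 - 16
  expect_equal(ov$excess_fraction, n_rim / n_total)
  expect_equal(ov$volume_mcmrf, n_total)
  expect_equal(ov$volume_lesion, 16)
})
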