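test_that("an exact atom matches itself with correlation 1", {
  d <- tiny_dict()
  j <- 25L
  X <- matrix(d$atoms[, j] * d$norms[j], ncol = 1)   # unnormalized signal
  m <- match_single(X, d)
  expect_equal(m$index, j)
  expect_equal(m$match_correlation, 1, tolerance = 1e-12)
  expect_equal(m$m0, 1, tolerance = 1e-12)
  expect_equal(m$t1_ms, d$entries$t1_ms[j])
  # positive scaling changes only M0
  m2 <- match_single(3.7 * X, d)
  expect_equal(m2$index, j)
  expect_equal(m2$m0, 3.7, tolerance = 1e-12)
})

test_that("noiseless grid tissues are recovered exactly, noisy ones nearby", {
  d <- ref_dict()
  set.seed(21)
  idx <- sample(ncol(d$atoms), 1000, replace = TRUE)
  m0 <- runif(1000, 0.5, 3)
  X <- d$atoms[, idx] * rep(d$norms[idx] * m0, each = nrow(d$atoms))
  m <- match_single(X, d)
  expect_equal(m$index, idx)
  expect_equal(m$m0, m0, tolerance = 1e-6)   # compressed-space inner products

  # Rician noise at SNR 50 (peak-signal convention, per tissue). Single-voxel
  # precision at this SNR is a few 10% grid steps: B1/T1 trade-offs and the
  # long-T2* shape degeneracy put a hard ceiling on exact recovery, so the
  # assertions document the achievable accuracy, not perfection.
  sig <- apply(X, 2, max) / 50
  Xn <- sqrt((X + matrix(rnorm(length(X)), nrow(X)) * rep(sig, each = nrow(X)))^2 +
               (matrix(rnorm(length(X)), nrow(X)) * rep(sig, each = nrow(X)))^2)
  mn <- match_single(Xn, d)
  step <- log(1.1)
  d1 <- abs(log(mn$t1_ms) - log(d$entries$t1_ms[idx]))
  d2 <- abs(log(mn$t2star_ms) - log(d$entries$t2star_ms[idx]))
  expect_gte(mean(d1 < 1.5 * step & d2 < 1.5 * step), 0.70)
  expect_lt(median(d1), step)          # typical T1 error below one grid step
  expect_gte(mean(d1 < 1.5 * step), 0.85)
})

test_that("matching equals the exhaustive argmax oracle on a sub-dictionary", {
  d <- tiny_dict()
  set.seed(33)
  keep <- sort(sample(ncol(d$atoms), 200))
  dsub <- d
  dsub$atoms <- d$atoms[, keep]
  dsub$norms <- d$norms[keep]
  dsub$entries <- d$entries[keep, ]
  X <- matrix(abs(rnorm(nrow(d$atoms) * 50)), ncol = 50)
  m <- match_single(X, dsub)
  oracle <- apply(abs(crossprod(dsub$atoms, X)), 2, which.max)
  expect_equal(m$index, oracle)
})

test_that("matching validates the frame count", {
  d <- tiny_dict()
  expect_error(match_single(matrix(1, 5, 3), d), "frames")
})

test_that("the brain mask keeps the largest suprathreshold component", {
  m0r <- array(0, c(20, 20, 4))
  # a large ball and a small distant blob
  for (z in 1:4) {
    m0r[, , z] <- outer(1:20, 1:20, function(x, y) {
      as.numeric((x - 10)^2 + (y - 10)^2 <= 36)
    })
  }
  m0r[1:2, 1:2, 1] <- 1       # 4-voxel distractor
  mask <- brain_mask(m0r, threshold = 0.05)
  expect_true(all(mask[5:15, 5:15, ] == (m0r[5:15, 5:15, ] > 0.05)))
  expect_false(any(mask[1:2, 1:2, 1]))
  expect_error(brain_mask(array(0, c(4, 4, 2))), "empty brain mask")
})

test_that("the matched phantom brain mask agrees with the true head mask", {
  ph <- ref_phantom()
  acq <- ref_acquisition()
  maps <- match_single(acq$series, ref_dict())
  mask <- brain_mask(maps)
  tm <- ph$masks$brain
  dice <- 2 * sum(mask & tm) / (sum(mask) + sum(tm))
  expect_gte(dice, 0.99)
})

test_that("modal B1 smoothing repairs isolated matching errors", {
  b1 <- array(1, c(12, 12, 1))
  b1[, 7:12, 1] <- 1.05                # two smooth bands
  noisy <- b1
  set.seed(4)
  bad <- cbind(sample(3:10, 6), sample(3:10, 6), 1)
  noisy[bad] <- 0.8
  fixed <- smooth_b1(noisy, radius = 2)
  expect_gte(mean(fixed == b1), 0.97)
})
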