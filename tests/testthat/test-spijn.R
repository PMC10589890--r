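test_that("the NNLS solvers agree with an independent implementation", {
  skip_if_not_installed("pracma")
  set.seed(42)
  for (i in 1:25) {
    # overdetermined systems: the NNLS optimum is then a.s. unique and the
    # solution vectors themselves must agree
    n <- sample(3:25, 1); m <- n + sample(2:15, 1)
    A <- matrix(rnorm(m * n), m, n)
    b <- rnorm(m)
    x_ref <- pracma::lsqnonneg(A, b)$x
    expect_equal(fnnls(crossprod(A), as.numeric(crossprod(A, b))), x_ref,
                 tolerance = 1e-7)
    expect_equal(mcmrf:::nnls_ridge(A, as.numeric(crossprod(A, b))), x_ref,
                 tolerance = 1e-7)
  }
  # underdetermined systems have non-unique optima: compare objectives
  for (i in 1:10) {
    m <- sample(5:15, 1); n <- m + sample(5:30, 1)
    A <- matrix(rnorm(m * n), m, n)
    b <- rnorm(m)
    obj <- function(x) sum((A %*% x - b)^2)
    x_ref <- pracma::lsqnonneg(A, b)$x
    x1 <- fnnls(crossprod(A), as.numeric(crossprod(A, b)))
    expect_true(all(x1 >= 0))
    expect_lt(obj(x1), obj(x_ref) + 1e-6 * (1 + obj(x_ref)))
  }
})

test_that("the batched ridge solver is exact against the active-set solver", {
  set.seed(19)
  for (i in 1:10) {
    r <- sample(4:12, 1); n <- sample(30:200, 1); V <- 8
    A <- matrix(abs(rnorm(r * n)), r, n)
    B <- matrix(abs(rnorm(r * V)), r, V)
    pen <- runif(n, 1e-4, 2)
    out <- mcmrf:::ridge_nnls_batch(A, B, pen)
    for (v in seq_len(V)) {
      expect_equal(out$X[, v],
                   mcmrf:::nnls_ridge(A, as.numeric(crossprod(A, B[, v])),
                                      pen = pen),
                   tolerance = 1e-6)
    }
  }
})

test_that("a single-tissue image yields a single component with fraction 1", {
  d <- tiny_dict()
  j <- which(d$entries$b1 == 1)[40]
  pair_j <- d$entries$pair[j]
  X <- d$atoms[, j, drop = FALSE] %*% t(rep(1.5, 60)) * d$norms[j]
  sol <- spijn_solve(X, d, cfg = spijn_config(rank = NULL))
  expect_equal(sol$components$pair, pair_j)
  expect_equal(as.numeric(sol$fractions), rep(1, 60))
  expect_equal(as.numeric(sol$raw_weights), rep(1.5, 60), tolerance = 1e-8)
})

test_that("a two-region mixture recovers the true support and fractions", {
  skip_if_not_installed("pracma")
  d <- tiny_dict()
  ent <- d$entries
  j_wm <- which(abs(ent$t1_ms - 900) < 250 & abs(ent$t2star_ms - 50) < 25 &
                  ent$b1 == 1)[1]
  j_long <- which(ent$t1_ms > 1200 & ent$t1_ms < 2200 &
                    ent$t2star_ms > 700 & ent$b1 == 1)[1]
  a_wm <- d$atoms[, j_wm] * d$norms[j_wm]
  a_long <- d$atoms[, j_long] * d$norms[j_long]
  X <- cbind(matrix(rep(a_wm, 40), ncol = 40),
             matrix(rep(0.6 * a_wm + 0.4 * a_long, 20), ncol = 20))
  sol <- spijn_solve(X, d, cfg = spijn_config(rank = NULL))
  expect_setequal(sol$components$pair, ent$pair[c(j_wm, j_long)])
  # oracle: NNLS restricted to the true atoms
  ora <- pracma::lsqnonneg(cbind(a_wm, a_long), X[, 41])$x
  ora <- ora / sum(ora)
  k_wm <- which(sol$components$pair == ent$pair[j_wm])
  mix_frac <- sol$fractions[, 41]
  expect_equal(unname(mix_frac[k_wm]), ora[1], tolerance = 1e-3)
  expect_equal(unname(sum(mix_frac)), 1, tolerance = 1e-9)
  expect_equal(unname(mix_frac[k_wm]), 0.6, tolerance = 1e-3)
})

test_that("lambda = 0 reduces to independent per-voxel NNLS", {
  skip_if_not_installed("pracma")
  d <- tiny_dict()
  set.seed(8)
  cols <- which(d$entries$b1 == 1)
  w <- matrix(0, ncol(d$atoms), 12)
  w[sample(cols, 6), ] <- runif(6 * 12)
  X <- d$atoms %*% w
  sol <- spijn_solve(X, d, cfg = spijn_config(lambda_norm = 0))
  A1 <- d$atoms[, cols]
  # the dictionary has more atoms than frames, so NNLS optima need not be
  # unique: the solutions must agree in fit, not coefficient-by-coefficient
  An <- sweep(A1, 2, d$norms[cols], "*")   # unnormalized atoms, M0 scale
  for (v in c(1, 5, 12)) {
    ref <- pracma::lsqnonneg(A1, X[, v])$x
    fit_ref <- as.numeric(A1 %*% ref)
    fit_got <- as.numeric(An[, sol$components$pair] %*% sol$raw_weights[, v])
    expect_equal(sum((fit_got - X[, v])^2), sum((fit_ref - X[, v])^2),
                 tolerance = 1e-6)
    expect_lt(max(abs(fit_got - X[, v])), 1e-5 * max(X[, v]))
  }
})

test_that("fraction normalization is exact and flags empty voxels", {
  out <- normalize_fractions(matrix(c(2, 2, 0, 0, 1, 3), nrow = 2))
  expect_equal(out$fractions[, 1], c(0.5, 0.5))
  expect_equal(out$fractions[, 2], c(0, 0))
  expect_true(out$excluded[2])
  expect_equal(colSums(out$fractions[, c(1, 3)]), c(1, 1), tolerance = 1e-12)
  expect_error(normalize_fractions(matrix(c(-1, 1), 2)), "non-negative")
  set.seed(2)
  w <- matrix(runif(60), 6)
  expect_equal(colSums(normalize_fractions(w)$fractions), rep(1, 10),
               tolerance = 1e-12)
})

test_that("the reweighting objective is non-increasing at fixed lambda", {
  acq <- ref_acquisition()
  ph <- ref_phantom()
  sol <- spijn_solve(acq$series, ref_dict(), b1_map = ph$b1,
                     mask = ph$masks$brain,
                     cfg = spijn_config(continuation = FALSE, polish = FALSE,
                                        max_iter = 12))
  # the smoothing floor freezes after iteration 2; require descent from there
  obj <- sol$objective_history[-1]
  expect_true(all(diff(obj) <= 1e-6 * abs(obj[-length(obj)])))
})

test_that("the joint solve is deterministic", {
  d <- tiny_dict()
  set.seed(77)
  w <- matrix(0, ncol(d$atoms), 15)
  w[sample(which(d$entries$b1 == 1), 4), ] <- runif(4 * 15)
  X <- d$atoms %*% w + 0.01 * matrix(abs(rnorm(nrow(d$atoms) * 15)), ncol = 15)
  s1 <- spijn_solve(X, d, cfg = spijn_config(rank = NULL))
  s2 <- spijn_solve(X, d, cfg = spijn_config(rank = NULL))
  expect_identical(s1$components, s2$components)
  expect_identical(s1$fractions, s2$fractions)
})

test_that("input validation catches bad masks and off-grid B1", {
  d <- tiny_dict()
  X <- matrix(1, nrow(d$atoms), 4)
  expect_error(spijn_solve(X, d, mask = rep(FALSE, 4)), "empty mask")
  expect_error(spijn_solve(X, d, b1_map = rep(0.77, 4)), "B1 grid")
})
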