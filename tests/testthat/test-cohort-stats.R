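make_flat_cohort <- function() {
  data.frame(
    id = sprintf("S%02d", 1:12),
    group = rep(c("patient", "control"), each = 6),
    site = rep(c("A", "B"), 6),
    age_years = rep(c(30, 35, 40, 45, 50, 55), 2),
    sex = rep(c("F", "M"), 6),
    volume = rep(c(0.004, 0.006, 0.005, 0.007, 0.003, 0.008), 2))
}

test_that("identical groups give a zero group effect with p near 1", {
  tab <- make_flat_cohort()
  fit <- glm_group(tab)
  expect_equal(fit$b, 0, tolerance = 1e-12)
  expect_gt(fit$p, 0.99)
  expect_true(fit$ci95[1] <= fit$b && fit$b <= fit$ci95[2])
})

test_that("positive coefficients mean larger volumes in patients", {
  tab <- make_flat_cohort()
  tab$volume[tab$group == "patient"] <- tab$volume[tab$group == "patient"] + 0.002
  fit <- glm_group(tab)
  expect_gt(fit$b, 0)
  expect_equal(fit$b, 0.002, tolerance = 1e-9)
  # flipped labels flip the sign exactly
  tab2 <- tab
  tab2$group <- ifelse(tab$group == "patient", "control", "patient")
  expect_equal(glm_group(tab2)$b, -fit$b, tolerance = 1e-12)
})

test_that("with constant covariates the model reduces to a two-sample t-test", {
  tab <- make_flat_cohort()
  set.seed(3)
  tab$volume <- tab$volume + rnorm(12, sd = 1e-3)
  tab$age_years <- 40
  tab$sex <- "F"
  expect_warning(fit <- glm_group(tab), "constant covariate")
  tt <- t.test(volume ~ factor(group, levels = c("control", "patient")),
               data = tab, var.equal = TRUE)
  expect_equal(fit$p, tt$p.value, tolerance = 1e-10)
})

test_that("degenerate designs fail loudly", {
  tab <- make_flat_cohort()
  expect_error(glm_group(tab[c(1, 7:12), ]), "3 subjects")
  tab2 <- make_flat_cohort()
  tab2$age_years <- ifelse(tab2$group == "patient", 30, 50)  # collinear
  expect_error(glm_group(tab2), "collinear")
})

test_that("a simulated two-group cohort recovers its generative effect", {
  spec <- cohort_spec(n_patients = 48, n_controls = 12,
                      confound_age_sex = FALSE, seed = 123)
  bs <- vapply(1:150, function(s) {
    tab <- make_cohort(cohort_spec(n_patients = 48, n_controls = 12,
                                   confound_age_sex = FALSE, seed = s))
    glm_group(tab)$b
  }, numeric(1))
  expect_lt(abs(mean(bs) - 0.0058) / 0.0058, 0.10)
})

test_that("partial Spearman handles exact, confounded and degenerate cases", {
  n <- 24
  tab <- data.frame(severity_score = rep(1:12, 2),
                    volume = rep(1:12, 2)^2,
                    site = rep(c("A", "B"), each = 12))
  ps <- partial_spearman(tab)
  expect_equal(ps$rho, 1, tolerance = 1e-12)

  # site-dependent offset destroys the raw correlation but not the partial
  set.seed(6)
  x <- runif(n)
  tab2 <- data.frame(severity_score = x,
                     volume = x + ifelse(rep(c(TRUE, FALSE), each = 12), 0, 50),
                     site = rep(c("A", "B"), each = 12))
  raw <- cor(rank(tab2$severity_score), rank(tab2$volume))
  ps2 <- partial_spearman(tab2)
  expect_gt(ps2$rho, 0.9)
  expect_lt(raw, 0.6)
  expect_gt(ps2$rho, raw)

  # single-level site reduces exactly to ordinary Spearman
  set.seed(7)
  tab3 <- data.frame(severity_score = sample(1:8, 20, TRUE),
                     volume = runif(20), site = "A")
  ps3 <- partial_spearman(tab3)
  expect_equal(ps3$rho,
               cor(tab3$severity_score, tab3$volume, method = "spearman"),
               tolerance = 1e-12)

  expect_error(partial_spearman(data.frame(severity_score = rep(1, 10),
                                           volume = runif(10), site = "A")),
               "constant")
})

test_that("partial Spearman null behaviour is calibrated", {
  set.seed(42)
  rhos <- numeric(400); ps <- numeric(400)
  for (i in 1:400) {
    tab <- data.frame(severity_score = rnorm(30), volume = rnorm(30),
                      site = rep(c("A", "B"), 15))
    r <- partial_spearman(tab)
    rhos[i] <- r$rho; ps[i] <- r$p
  }
  expect_lt(abs(mean(rhos)), 0.02)
  alpha_hat <- mean(ps < 0.05)
  expect_gt(alpha_hat, 0.03)
  expect_lt(alpha_hat, 0.07)
})

test_that("the paired test follows its documented conventions", {
  tab <- data.frame(mcmrf_volume = runif(10), lesionmap_volume = NA)
  tab$lesionmap_volume <- tab$mcmrf_volume
  same <- paired_volumes_test(tab)
  expect_equal(same$mean_diff, 0)
  expect_true(is.nan(same$p))

  set.seed(9)
  a <- runif(48, 0.004, 0.01)
  tab2 <- data.frame(mcmrf_volume = a + 0.002 + rnorm(48, sd = 1e-4),
                     lesionmap_volume = a)
  t2 <- paired_volumes_test(tab2)
  expect_lt(t2$p, 1e-16)
  expect_equal(t2$mean_diff, 0.002, tolerance = 0.05)
  # antisymmetry
  t3 <- paired_volumes_test(data.frame(mcmrf_volume = tab2$lesionmap_volume,
                                       lesionmap_volume = tab2$mcmrf_volume))
  expect_equal(t3$t, -t2$t, tolerance = 1e-12)
  expect_error(paired_volumes_test(
    data.frame(mcmrf_volume = 1:5 + 0.1, lesionmap_volume = 1:5)),
    "zero-variance")
})

test_that("secondary regressions report per-predictor slopes", {
  set.seed(12)
  tab <- data.frame(volume = numeric(40), edss = sample(seq(0, 6, 0.5), 40, TRUE),
                    disease_duration_years = runif(40, 1, 20),
                    age_years = runif(40, 20, 70),
                    sex = sample(c("F", "M"), 40, TRUE))
  tab$volume <- 0.001 + 0.00117 * tab$edss
  res <- secondary_regressions(tab)
  expect_setequal(res$predictor,
                  c("edss", "disease_duration_years", "age_years", "sex"))
  edss_row <- res[res$predictor == "edss", ]
  expect_equal(edss_row$b, 0.00117, tolerance = 1e-10)
  expect_equal(edss_row$r_squared, 1, tolerance = 1e-9)
  expect_true(all(res$ci_low <= res$b & res$b <= res$ci_high))
  expect_true(all(res$p >= 0 & res$p <= 1))
})

test_that("secondary regression CIs achieve near-nominal coverage", {
  set.seed(30)
  cover <- 0
  for (i in 1:200) {
    tab <- data.frame(volume = rnorm(25), edss = rnorm(25))
    r <- secondary_regressions(tab, predictors = "edss")
    cover <- cover + (r$ci_low <= 0 && 0 <= r$ci_high)
  }
  expect_gt(cover / 200, 0.88)
  expect_lt(cover / 200, 0.995)
})

test_that("an EDSS-linked cohort recovers the generative slope", {
  slopes <- vapply(1:60, function(s) {
    tab <- make_cohort(cohort_spec(edss_slope = 0.00117, seed = s))
    pat <- tab[tab$group == "patient", ]
    secondary_regressions(pat, predictors = "edss")$b
  }, numeric(1))
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 0.00117), 3 * se + 1e-5)
})
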