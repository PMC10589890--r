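## Cohort-level statistics: covariate-adjusted group comparisons of the
## normalized long-T2* volumes, site-corrected partial Spearman correlation
## against the visual severity score, paired comparison of MC-MRF and
## lesion-map volumes, and single-predictor secondary regressions.
## No multiple-testing correction is applied (single primary marker,
## alpha = 0.05 convention); interpret the per-region p-values accordingly.

## Binary codings shared by the models: patient = 1 / control = 0 so a
## positive group coefficient means a larger volume in patients; sex and
## site are two-level indicator columns.
code_binary <- function(x, name) {
  if (is.numeric(x) || is.logical(x)) return(as.numeric(x))
  f <- as.factor(x)
  if (name == "group") {
    hit <- which(tolower(levels(f)) %in% c("control", "hc", "healthy"))
    if (length(hit) == 1L) f <- stats::relevel(f, ref = levels(f)[hit])
  }
  as.numeric(f) - 1
}

check_full_rank <- function(mm) {
  q <- qr(mm)
  if (q$rank < ncol(mm)) {
    bad <- colnames(mm)[q$pivot[(q$rank + 1):ncol(mm)]]
    stop_invalid("rank-deficient design: column(s) %s are collinear",
                 paste(bad, collapse = ", "))
  }
}

#' Covariate-adjusted group comparison of regional volumes
#'
#' Gaussian-identity linear model `volume ~ group + covariates` with Wald
#' inference. Group is coded control = 0, patient = 1, so a positive
#' coefficient indicates a larger volume in the patient group. Covariates
#' that are constant over the analysed subjects carry no information and are
#' dropped with a warning; genuinely collinear non-constant columns raise an
#' error naming the column.
#'
#' @param table Cohort data frame (see [make_cohort()]); needs a `group`
#'   column plus the region and covariate columns.
#' @param region Name of the volume column to analyse (default `"volume"`).
#' @param covariates Character vector of covariate column names (default
#'   `c("age_years", "sex")`).
#' @return A list: `b` (group coefficient), `ci95`, `p`, `n`, `fit`.
#' @export
glm_group <- function(table, region = "volume",
                      covariates = c("age_years", "sex")) {
  assert_that(all(c("group", region, covariates) %in% names(table)),
              "table is missing required columns")
  df <- data.frame(volume = as.numeric(table[[region]]),
                   group = code_binary(table$group, "group"))
  for (cv in covariates) df[[cv]] <- code_binary(table[[cv]], cv)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  assert_that(min(table(df$group)) >= 3 && length(unique(df$group)) == 2,
              "need at least 3 subjects in each of two groups")
  keep <- covariates[vapply(covariates, function(cv) stats::var(df[[cv]]) > 0,
                            logical(1))]
  if (length(keep) < length(covariates)) {
    warning(sprintf("dropping constant covariate(s): %s",
                    paste(setdiff(covariates, keep), collapse = ", ")))
  }
  fm <- stats::reformulate(c("group", keep), response = "volume")
  mm <- stats::model.matrix(fm, df)
  check_full_rank(mm)
  fit <- stats::glm(fm, data = df, family = stats::gaussian())
  co <- summary(fit)$coefficients["group", ]
  ci <- stats::confint.default(fit, "group", level = 0.95)
  list(b = unname(co["Estimate"]), ci95 = unname(c(ci)),
       p = unname(co["Pr(>|t|)"]), n = nrow(df), fit = fit)
}

#' Site-corrected partial Spearman correlation
#'
#' Rank-transforms `x` and `y` (average ranks for ties), residualizes both
#' on the covariate (plus intercept), and correlates the residuals — the
#' standard partial Spearman. With a single-level covariate this reduces
#' exactly to the ordinary Spearman coefficient. The p-value uses a
#' t-statistic with `n - 2 - k` degrees of freedom and the 95% CI a Fisher
#' z-interval with standard error `1 / sqrt(n - 3 - k)`, `k` being the
#' number of covariate indicator columns.
#'
#' @param table Cohort data frame.
#' @param x,y Column names of the two variables (defaults
#'   `"severity_score"`, `"volume"`).
#' @param covariate Column name of the confounder (default `"site"`).
#' @return A list: `rho`, `ci95`, `p`, `n`.
#' @export
partial_spearman <- function(table, x = "severity_score", y = "volume",
                             covariate = "site") {
  assert_that(all(c(x, y, covariate) %in% names(table)),
              "table is missing required columns")
  df <- data.frame(x = as.numeric(table[[x]]), y = as.numeric(table[[y]]),
                   z = as.factor(table[[covariate]]))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  assert_that(n >= 5, "need at least 5 complete cases")
  if (stats::var(df$x) == 0 || stats::var(df$y) == 0) {
    stop_invalid("constant x or y: correlation undefined")
  }
  rx <- rank(df$x); ry <- rank(df$y)
  k <- length(levels(droplevels(df$z))) - 1L
  if (k > 0) {
    Z <- stats::model.matrix(~z, df)
    ex <- stats::lm.fit(Z, rx)$residuals
    ey <- stats::lm.fit(Z, ry)$residuals
  } else {
    ex <- rx - mean(rx); ey <- ry - mean(ry)
  }
  rho <- stats::cor(ex, ey)
  dfree <- n - 2L - k
  if (abs(rho) >= 1 - 1e-15) {
    p <- 0
    ci <- c(sign(rho), sign(rho))
  } else {
    tval <- rho * sqrt(dfree / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = dfree)
    se <- 1 / sqrt(n - 3 - k)
    ci <- tanh(atanh(rho) + c(-1, 1) * stats::qnorm(0.975) * se)
  }
  list(rho = rho, ci95 = ci, p = p, n = n)
}

#' Paired comparison of MC-MRF and lesion-map volumes
#'
#' Two-sided paired t-test on `a - b`. When every pair is identical
#' (zero-variance, zero-mean differences) the t-statistic is undefined and
#' `t = p = NaN` is returned by convention; zero-variance differences with a
#' non-zero mean are an error (the test statistic would be infinite).
#'
#' @param table Cohort data frame.
#' @param a,b Column names of the paired volumes (defaults `"mcmrf_volume"`,
#'   `"lesionmap_volume"`).
#' @return A list: `t`, `p`, `mean_diff`, `ci95`, `df`, `n`.
#' @export
paired_volumes_test <- function(table, a = "mcmrf_volume",
                                b = "lesionmap_volume") {
  assert_that(all(c(a, b) %in% names(table)), "table is missing required columns")
  d <- as.numeric(table[[a]]) - as.numeric(table[[b]])
  d <- d[!is.na(d)]
  n <- length(d)
  assert_that(n >= 3, "need at least 3 complete pairs")
  if (stats::sd(d) <= 1e-10 * max(abs(d), .Machine$double.xmin)) {
    if (mean(d) == 0) {
      return(list(t = NaN, p = NaN, mean_diff = 0, ci95 = c(0, 0),
                  df = n - 1L, n = n))
    }
    stop_invalid("zero-variance differences with non-zero mean: t undefined")
  }
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), p = tt$p.value, mean_diff = mean(d),
       ci95 = unname(tt$conf.int), df = unname(tt$parameter), n = n)
}

#' Single-predictor secondary regressions
#'
#' One ordinary linear regression of the outcome on each predictor in turn
#' (no covariates), mirroring exploratory clinical-association analyses of
#' the volume marker against EDSS, disease duration, age and sex.
#'
#' @param table Cohort data frame.
#' @param outcome Outcome column (default `"volume"`).
#' @param predictors Character vector of predictor columns.
#' @return Data frame: predictor, n, b, ci_low, ci_high, p, r_squared.
#' @export
secondary_regressions <- function(table, outcome = "volume",
                                  predictors = c("edss",
                                                 "disease_duration_years",
                                                 "age_years", "sex")) {
  assert_that(outcome %in% names(table), "missing outcome column")
  rows <- lapply(predictors, function(pv) {
    assert_that(pv %in% names(table), "missing predictor column %s", pv)
    df <- data.frame(y = as.numeric(table[[outcome]]),
                     x = code_binary(table[[pv]], pv))
    df <- df[stats::complete.cases(df), , drop = FALSE]
    assert_that(nrow(df) >= 3, "need at least 3 complete cases for %s", pv)
    assert_that(stats::var(df$x) > 0, "predictor %s is constant", pv)
    fit <- stats::glm(y ~ x, data = df, family = stats::gaussian())
    co <- summary(fit)$coefficients["x", ]
    ci <- stats::confint.default(fit, "x")
    r2 <- 1 - sum(stats::residuals(fit)^2) / sum((df$y - mean(df$y))^2)
    data.frame(predictor = pv, n = nrow(df), b = unname(co["Estimate"]),
               ci_low = ci[1], ci_high = ci[2],
               p = unname(co["Pr(>|t|)"]), r_squared = r2)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
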