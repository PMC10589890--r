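#' Specification of a synthetic two-group cohort
#'
#' Generative defaults follow the published cohort: 48 MS patients (18 site
#' A, 30 site B) and 12 controls (site A), patient ages centred in the
#' late 30s and control ages in the mid 20s, female-majority patients and
#' male-majority controls, and white-matter long-T2* normalized volumes
#' drawn per group from normal distributions truncated at 0 with means/SDs
#' 0.0088/0.0053 (patients) and 0.0030/0.0020 (controls).
#'
#' @param n_patients,n_controls Group sizes (default 48 / 12).
#' @param vol_mean,vol_sd Named numeric `c(control = ..., patient = ...)`
#'   generative volume means and SDs.
#' @param confound_age_sex When TRUE (default) age and sex follow the
#'   group-specific distributions of the real cohort (so they confound the
#'   group contrast, as in the study); when FALSE both groups share pooled
#'   distributions, making the generative group effect exactly
#'   `vol_mean["patient"] - vol_mean["control"]` up to truncation.
#' @param edss_slope Optional linear EDSS effect on the patient volumes; when
#'   set, patient volume = `vol_mean["patient"] + edss_slope * (EDSS - 2) +`
#'   residual noise of sd `edss_resid_sd`.
#' @param edss_resid_sd Residual sd of the EDSS-linked volume model.
#' @param lesionmap_deficit_mean,lesionmap_deficit_sd Mean/sd of the
#'   (positive) amount by which lesion-map volumes undershoot MC-MRF volumes
#'   in patients.
#' @param seed RNG seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 48L, n_controls = 12L,
                        vol_mean = c(control = 0.0030, patient = 0.0088),
                        vol_sd = c(control = 0.0020, patient = 0.0053),
                        confound_age_sex = TRUE,
                        edss_slope = NULL,
                        edss_resid_sd = 0.003,
                        lesionmap_deficit_mean = 0.002,
                        lesionmap_deficit_sd = 5e-4,
                        seed = 1L) {
  assert_that(n_patients >= 1 && n_controls >= 1, "need n >= 1 per group")
  for (g in c("control", "patient")) {
    assert_that(vol_sd[[g]] > 0, "volume sd must be positive")
    if (stats::pnorm(0, vol_mean[[g]], vol_sd[[g]]) > 0.999) {
      stop_invalid("impossible truncation: %s volume mean %.4g << 0 at sd %.4g",
                   g, vol_mean[[g]], vol_sd[[g]])
    }
  }
  structure(list(n_patients = as.integer(n_patients),
                 n_controls = as.integer(n_controls),
                 vol_mean = vol_mean, vol_sd = vol_sd,
                 confound_age_sex = confound_age_sex,
                 edss_slope = edss_slope, edss_resid_sd = edss_resid_sd,
                 lesionmap_deficit_mean = lesionmap_deficit_mean,
                 lesionmap_deficit_sd = lesionmap_deficit_sd,
                 seed = seed),
            class = "cohort_spec")
}

rtruncnorm0 <- function(n, mean, sd) {
  out <- stats::rnorm(n, mean, sd)
  bad <- out < 0
  guard <- 0L
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- out < 0
    guard <- guard + 1L
    if (guard > 10000L) stop_invalid("truncated-normal sampling failed to converge")
  }
  out
}

#' Generate a synthetic cohort table
#'
#' Samples per-subject covariates and ground-truth volumes according to the
#' spec, deterministic given `spec$seed`. The returned table feeds the
#' cohort statistics directly; per-subject phantom specifications (each
#' targeting the subject's sampled volume) can be attached for full
#' end-to-end runs.
#'
#' @param spec A [cohort_spec()].
#' @param phantom_specs Attach a list of per-subject [phantom_spec()]s?
#'   (default FALSE; imaging-scale work is opt-in).
#' @param ... Arguments forwarded to [phantom_spec()] when
#'   `phantom_specs = TRUE` (e.g. `grid`, grid shape).
#' @return A data frame of class `cohort_table` with columns `id`, `group`,
#'   `site`, `age_years`, `sex`, `edss`, `disease_duration_years`,
#'   `severity_score`, `volume`, `mcmrf_volume`, `lesionmap_volume`. When
#'   requested, the phantom specs are in `attr(, "phantom_specs")`.
#' @export
make_cohort <- function(spec, phantom_specs = FALSE, ...) {
  stopifnot(inherits(spec, "cohort_spec"))
  np <- spec$n_patients; nc <- spec$n_controls; n <- np + nc
  tab <- with_seed(spec$seed, {
    group <- c(rep("patient", np), rep("control", nc))
    site <- c(rep(c("A", "B"), c(round(np * 18 / 48), np - round(np * 18 / 48))),
              rep("A", nc))
    if (spec$confound_age_sex) {
      age <- c(pmin(pmax(stats::rnorm(np, 40, 9), 23), 73),
               pmin(pmax(stats::rnorm(nc, 26, 2.5), 22), 30))
      sex <- c(ifelse(stats::runif(np) < 31 / 48, "F", "M"),
               ifelse(stats::runif(nc) < 3 / 12, "F", "M"))
    } else {
      age <- pmin(pmax(stats::rnorm(n, 35, 9), 20), 75)
      sex <- ifelse(stats::runif(n) < 0.5, "F", "M")
    }
    edss_levels <- seq(0, 6, by = 0.5)
    edss_w <- stats::dlnorm(edss_levels + 0.5, meanlog = log(2), sdlog = 0.6)
    edss <- c(sample(edss_levels, np, replace = TRUE, prob = edss_w),
              rep(NA_real_, nc))
    duration <- c(stats::rlnorm(np, meanlog = log(5.5), sdlog = 0.85),
                  rep(NA_real_, nc))
    if (!is.null(spec$edss_slope)) {
      vol_p <- pmax(0, spec$vol_mean[["patient"]] +
                      spec$edss_slope * (edss[seq_len(np)] - 2) +
                      stats::rnorm(np, 0, spec$edss_resid_sd))
    } else {
      vol_p <- rtruncnorm0(np, spec$vol_mean[["patient"]], spec$vol_sd[["patient"]])
    }
    vol_c <- rtruncnorm0(nc, spec$vol_mean[["control"]], spec$vol_sd[["control"]])
    volume <- c(vol_p, vol_c)
    deficit <- c(stats::rnorm(np, spec$lesionmap_deficit_mean,
                              spec$lesionmap_deficit_sd),
                 stats::rnorm(nc, spec$lesionmap_deficit_mean / 4,
                              spec$lesionmap_deficit_sd / 2))
    lesionmap <- pmax(0, volume - deficit)
    severity <- pmin(40, pmax(0, round(volume * 1800 +
                                         stats::rnorm(n, 0, 4) +
                                         ifelse(group == "patient", 4, 2))))
    data.frame(id = sprintf("S%03d", seq_len(n)), group = group, site = site,
               age_years = age, sex = sex, edss = edss,
               disease_duration_years = duration,
               severity_score = as.integer(severity),
               volume = volume, mcmrf_volume = volume,
               lesionmap_volume = lesionmap,
               stringsAsFactors = FALSE)
  })
  class(tab) <- c("cohort_table", class(tab))
  if (phantom_specs) {
    specs <- lapply(seq_len(n), function(i) {
      phantom_spec(n_lesions = if (tab$group[i] == "patient") 4L else 0L,
                   target_wm_long_volume = tab$volume[i],
                   seed = spec$seed + i, ...)
    })
    attr(tab, "phantom_specs") <- specs
  }
  tab
}
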