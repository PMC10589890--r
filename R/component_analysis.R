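#' Cluster component relaxation times across subjects
#'
#' k-means on (log T1, log T2*) — relaxation times live on a multiplicative
#' scale, so clustering in log space keeps short- and long-T components
#' comparable. Uses multiple random restarts with a fixed seed for
#' reproducibility, and reports per-cluster statistics back in original
#' millisecond units: the arithmetic mean and SD of the member relaxation
#' times, plus the back-transformed (geometric-mean) centroid.
#'
#' @param points Data frame with columns `t1_ms`, `t2star_ms` and optionally
#'   `volume` (per-subject total fraction volume of the component).
#' @param k Number of clusters, `1 <= k <= nrow(points)`.
#' @param seed RNG seed for the restarts.
#' @param n_init Number of random restarts (default 20).
#' @return A list of class `component_summary`: `assignment` (cluster per
#'   point), `summary` (data frame: cluster, n, t1_mean_ms, t1_sd_ms,
#'   t2star_mean_ms, t2star_sd_ms, t1_centroid_ms, t2star_centroid_ms,
#'   volume), `tot_withinss`.
#' @export
cluster_components <- function(points, k, seed = 1L, n_init = 20L) {
  assert_that(is.data.frame(points) && all(c("t1_ms", "t2star_ms") %in% names(points)),
              "points must have t1_ms and t2star_ms columns")
  assert_that(k >= 1, "k must be >= 1")
  assert_that(k <= nrow(points), "k cannot exceed the number of points")
  X <- cbind(log(points$t1_ms), log(points$t2star_ms))
  km <- with_seed(seed, stats::kmeans(X, centers = k, nstart = n_init,
                                      iter.max = 100))
  cl <- km$cluster
  vol <- points$volume %||% rep(NA_real_, nrow(points))
  summ <- do.call(rbind, lapply(seq_len(k), function(j) {
    sel <- cl == j
    data.frame(cluster = j, n = sum(sel),
               t1_mean_ms = mean(points$t1_ms[sel]),
               t1_sd_ms = stats::sd(points$t1_ms[sel]),
               t2star_mean_ms = mean(points$t2star_ms[sel]),
               t2star_sd_ms = stats::sd(points$t2star_ms[sel]),
               t1_centroid_ms = exp(km$centers[j, 1]),
               t2star_centroid_ms = exp(km$centers[j, 2]),
               volume = if (all(is.na(vol[sel]))) NA_real_ else sum(vol[sel], na.rm = TRUE))
  }))
  structure(list(assignment = cl, summary = summ,
                 tot_withinss = km$tot.withinss, kmeans = km),
            class = "component_summary")
}

#' Select and merge long-T2* components
#'
#' Sums the fraction maps of every component whose relaxation times lie
#' strictly inside both open intervals (defaults 500–2500 ms for T1 and for
#' T2*) into a single magnetization fraction map — the marker of diffuse
#' white-matter change.
#'
#' @param solution An `mcmrf_solution` from [spijn_solve()].
#' @param t1_bounds_ms,t2star_bounds_ms Open selection intervals (ms).
#' @return A list: `map` (summed fraction map; zeros when no component
#'   qualifies), `components` (selected rows of the component table),
#'   `empty` (flag).
#' @export
select_long_t2star <- function(solution, t1_bounds_ms = c(500, 2500),
                               t2star_bounds_ms = c(500, 2500)) {
  stopifnot(inherits(solution, "mcmrf_solution"))
  comp <- solution$components
  sel <- comp$t1_ms > t1_bounds_ms[1] & comp$t1_ms < t1_bounds_ms[2] &
    comp$t2star_ms > t2star_bounds_ms[1] & comp$t2star_ms < t2star_bounds_ms[2]
  fr <- solution$fractions
  if (length(dim(fr)) == 4L) {
    d <- dim(fr)
    map <- array(0, d[1:3])
    for (j in which(sel)) {
      sl <- fr[, , , j, drop = FALSE]
      dim(sl) <- d[1:3]
      map <- map + sl
    }
  } else {
    map <- if (any(sel)) colSums(fr[sel, , drop = FALSE]) else numeric(ncol(fr))
  }
  list(map = map, components = comp[sel, , drop = FALSE], empty = !any(sel))
}

#' Normalized fraction volume of a map within a white-matter region
#'
#' The regional volume is the sum of per-voxel fractions over the region
#' divided by the region's voxel count, i.e. normalized between 0 and 1 with
#' respect to the region's total white-matter volume. Because both numerator
#' and denominator count voxels of the same grid, anisotropic voxel sizes
#' cancel. Optionally excludes lesions (probability > `lesion_threshold`)
#' from the region first.
#'
#' @param fraction_map 3D fraction map.
#' @param masks A list with at least `white_matter` (logical array);
#'   optionally `lobe_labels` (integer array) and `lesion_probability`.
#' @param region Optional lobe label (value in `lobe_labels`) restricting
#'   the region; `NULL` uses all white matter.
#' @param lesions_excluded Mask out lesions before computing the volume?
#' @param lesion_threshold Probability cut-off defining a lesion voxel
#'   (default 0.5).
#' @return Normalized volume in [0, 1].
#' @export
mask_and_volume <- function(fraction_map, masks, region = NULL,
                            lesions_excluded = FALSE, lesion_threshold = 0.5) {
  wm <- masks$white_matter
  assert_that(!is.null(wm), "masks$white_matter is required")
  assert_that(all(dim(fraction_map) == dim(wm)),
              "fraction_map and masks must share a grid")
  reg <- as.logical(wm)
  if (!is.null(region)) {
    assert_that(!is.null(masks$lobe_labels), "region selection needs masks$lobe_labels")
    reg <- reg & (masks$lobe_labels == region)
  }
  if (lesions_excluded) {
    assert_that(!is.null(masks$lesion_probability),
                "lesion exclusion needs masks$lesion_probability")
    reg <- reg & !(masks$lesion_probability > lesion_threshold)
  }
  n <- sum(reg)
  if (n == 0L) stop_invalid("empty region: no white-matter voxels selected")
  sum(fraction_map[reg]) / n
}

#' Overlap between a thresholded fraction map and a lesion mask
#'
#' Binarizes the fraction map at `threshold` (default 15%, strict) and
#' reports the Dice coefficient with the lesion mask, both volumes (voxel
#' counts), and the fraction of suprathreshold voxels lying outside the
#' lesion mask — the "more extensive involvement" quantity.
#'
#' @param fraction_map 3D fraction map.
#' @param lesion_mask Logical array on the same grid.
#' @param threshold Fraction threshold (default 0.15).
#' @return A list: `dice`, `volume_mcmrf`, `volume_lesion`,
#'   `excess_fraction`. `dice` is `NaN` when both masks are empty and
#'   `excess_fraction` is `NaN` when no voxel is suprathreshold.
#' @export
lesion_overlap <- function(fraction_map, lesion_mask, threshold = 0.15) {
  assert_that(all(dim(fraction_map) == dim(lesion_mask)),
              "fraction_map and lesion_mask must share a grid")
  a <- fraction_map > threshold
  b <- as.logical(lesion_mask)
  na <- sum(a); nb <- sum(b)
  inter <- sum(a & b)
  dice <- if (na + nb == 0L) NaN else 2 * inter / (na + nb)
  excess <- if (na == 0L) NaN else sum(a & !b) / na
  list(dice = dice, volume_mcmrf = na, volume_lesion = nb,
       excess_fraction = excess)
}
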