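#' Marchenko-Pastur PCA denoising of a 4D MRF series
#'
#' Random-matrix denoising of the magnitude timeseries, per slice, across
#' timeframes, in square spatial patches. For each patch the
#' `voxels x frames` Casorati matrix is eigen-decomposed; the noise level is
#' estimated as the largest variance for which the trailing eigenvalue bulk
#' is consistent with the Marchenko-Pastur law, all bulk components are
#' nulled, and the patch is reconstructed from the remaining (signal)
#' components. Overlapping reconstructions are averaged uniformly
#' (stride-1 sliding window by default), or only the patch centre can be
#' kept. Patches are clipped at slice borders rather than padded.
#'
#' The estimator is the standard one for this method: with eigenvalues
#' \eqn{\lambda_1 \ge \dots \ge \lambda_N} of \eqn{X^\top X / M}
#' (M = patch voxels, N = frames; dimensions swapped if M < N), the number of
#' signal components is the smallest `p` for which
#' \deqn{(\lambda_{p+1} - \lambda_N) / (4 \sqrt{(N - p)/M}) \le
#'       \mathrm{mean}(\lambda_{p+1}, \dots, \lambda_N),}
#' i.e. the spread of the trailing eigenvalues no longer exceeds the
#' Marchenko-Pastur support width for their average variance; that average is
#' the noise-variance estimate. Gaussian noise is assumed on the magnitude
#' data (no Rician bias correction); at the SNR of brain MRF data the bias is
#' small but it is a known limitation at very low signal.
#'
#' @param series 4D numeric array `(x, y, slice, frame)`; a 3D array is
#'   treated as a single slice.
#' @param radius_voxels Patch radius; a radius of `r` gives
#'   `(2r+1) x (2r+1)` patches (default 7, i.e. 15 x 15). A patch with fewer
#'   voxels than frames still works but is noisier; a warning is issued.
#' @param stride Patch-centre spacing in voxels (default 1).
#' @param aggregation `"weighted-average"` (uniform average of overlapping
#'   reconstructions, default) or `"center-only"`.
#' @param mask Optional logical array `(x, y, slice)`. Voxels outside the
#'   mask are excluded from patches and pass through unchanged.
#' @return A list of class `mppca_result`: `series` (denoised 4D array),
#'   `sigma` (per-voxel noise-sd estimate, 3D), `n_components` (per-voxel
#'   average retained-component count, 3D).
#' @export
mppca_denoise <- function(series, radius_voxels = 7L, stride = 1L,
                          aggregation = c("weighted-average", "center-only"),
                          mask = NULL) {
  aggregation <- match.arg(aggregation)
  if (length(dim(series)) == 3L) dim(series) <- c(dim(series)[1:2], 1L, dim(series)[3])
  assert_that(length(dim(series)) == 4L, "series must be a 4D (x, y, slice, frame) array")
  d <- dim(series)
  nf <- d[4]
  assert_that(nf >= 2, "denoising needs at least 2 frames")
  assert_that(radius_voxels >= 1, "radius_voxels must be >= 1")
  w <- 2L * as.integer(radius_voxels) + 1L
  assert_that(w >= 2 && (min(d[1], d[2]) >= 2),
              "patch smaller than 2x2 is invalid")
  if (w * w <= nf) {
    warning(sprintf("patch voxel count (%d) <= frame count (%d); noise estimates will be poor",
                    w * w, nf))
  }
  if (!is.null(mask)) {
    if (length(dim(mask)) == 2L) dim(mask) <- c(dim(mask), 1L)
    assert_that(all(dim(mask) == d[1:3]), "mask shape must match the series grid")
    mask <- array(as.logical(mask), d[1:3])
  }
  out <- array(0, d)
  wt <- array(0, d[1:3])
  sig_acc <- array(0, d[1:3])
  ncomp_acc <- array(0, d[1:3])
  r <- as.integer(radius_voxels)
  for (z in seq_len(d[3])) {
    sl <- matrix(series[, , z, ], nrow = d[1] * d[2], ncol = nf)
    msl <- if (is.null(mask)) NULL else mask[, , z]
    centers_x <- unique(pmin(pmax(seq(1L, d[1], by = stride), 1L), d[1]))
    centers_y <- unique(pmin(pmax(seq(1L, d[2], by = stride), 1L), d[2]))
    for (cy in centers_y) {
      ys <- max(1L, cy - r):min(d[2], cy + r)
      for (cx in centers_x) {
        xs <- max(1L, cx - r):min(d[1], cx + r)
        vox <- as.vector(outer(xs, (ys - 1L) * d[1], "+"))
        if (!is.null(msl)) vox <- vox[msl[vox]]
        if (length(vox) < 4L) next
        X <- sl[vox, , drop = FALSE]
        fit <- mp_denoise_patch(X)
        if (aggregation == "center-only") {
          cidx <- cx + (cy - 1L) * d[1]
          hit <- which(vox == cidx)
          if (length(hit) == 1L) {
            ii <- arrayInd(cidx, d[1:2])
            out[ii[1], ii[2], z, ] <- out[ii[1], ii[2], z, ] + fit$X[hit, ]
            wt[cidx + (z - 1L) * d[1] * d[2]] <- wt[cidx + (z - 1L) * d[1] * d[2]] + 1
            sig_acc[cidx + (z - 1L) * d[1] * d[2]] <-
              sig_acc[cidx + (z - 1L) * d[1] * d[2]] + fit$sigma
            ncomp_acc[cidx + (z - 1L) * d[1] * d[2]] <-
              ncomp_acc[cidx + (z - 1L) * d[1] * d[2]] + fit$n_components
          }
        } else {
          g <- vox + (z - 1L) * d[1] * d[2]
          for (k in seq_len(nf)) {
            idx4 <- g + (k - 1L) * d[1] * d[2] * d[3]
            out[idx4] <- out[idx4] + fit$X[, k]
          }
          wt[g] <- wt[g] + 1
          sig_acc[g] <- sig_acc[g] + fit$sigma
          ncomp_acc[g] <- ncomp_acc[g] + fit$n_components
        }
      }
    }
  }
  covered <- wt > 0
  sigma <- array(NA_real_, d[1:3])
  ncomp <- array(NA_real_, d[1:3])
  sigma[covered] <- sig_acc[covered] / wt[covered]
  ncomp[covered] <- ncomp_acc[covered] / wt[covered]
  for (k in seq_len(nf)) {
    fr <- out[, , , k, drop = FALSE]
    dim(fr) <- d[1:3]
    orig <- series[, , , k, drop = FALSE]
    dim(orig) <- d[1:3]
    fr[covered] <- fr[covered] / wt[covered]
    fr[!covered] <- orig[!covered]           # uncovered voxels pass through
    out[, , , k] <- fr
  }
  structure(list(series = out, sigma = sigma, n_components = ncomp),
            class = "mppca_result")
}

## Denoise one Casorati matrix X (voxels x frames). Returns the denoised
## matrix, the noise-sd estimate and the retained component count.
mp_denoise_patch <- function(X) {
  M <- nrow(X); N <- ncol(X)
  flip <- M < N
  A <- if (flip) t(X) else X            # A is tall: nrow >= ncol
  m <- nrow(A); n <- ncol(A)
  G <- crossprod(A)                      # n x n
  e <- eigen(G, symmetric = TRUE)
  lam <- pmax(e$values, 0) / m           # descending eigenvalues of A'A/m
  ## numerical dust below double precision of the leading eigenvalue is
  ## exactly zero (an exactly low-rank patch has no noise bulk to fit)
  lam[lam < 1e-14 * lam[1]] <- 0
  ## candidate p = number of retained signal components (0 .. n-1); the
  ## asymptotic MP support is widened by 5% to absorb the finite-sample
  ## (Tracy-Widom) fluctuation of the bulk edges, which otherwise lets the
  ## largest noise eigenvalue masquerade as signal in ~10% of patches
  tail_mean <- rev(cumsum(rev(lam))) / (n - seq_len(n) + 1)  # mean(lam[p+1..n])
  p_cand <- 0:(n - 1)
  range_sigsq <- (lam[p_cand + 1] - lam[n]) / (1.05 * 4 * sqrt((n - p_cand) / m))
  ok <- range_sigsq <= tail_mean[p_cand + 1]
  p <- if (any(ok)) p_cand[which(ok)[1]] else n - 1L
  sigsq <- tail_mean[p + 1]
  if (p == 0) {
    Xd <- matrix(0, M, N)
  } else {
    V <- e$vectors[, seq_len(p), drop = FALSE]
    Ad <- A %*% V %*% t(V)
    Xd <- if (flip) t(Ad) else Ad
  }
  list(X = Xd, sigma = sqrt(max(sigsq, 0)), n_components = p)
}
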