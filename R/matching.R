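#' Single-component dictionary matching
#'
#' For every voxel the best dictionary atom maximizes the absolute
#' normalized inner product with the voxel's signal evolution; the matched
#' atom's (T1, T2*, B1) grid coordinates become the parameter maps. M0 is
#' the inner product divided by the atom's stored pre-normalization norm
#' (so a voxel whose signal is `c` times an unnormalized atom gets M0 = c),
#' and relative M0 divides by the 99th percentile of M0 over the image, a
#' robust ceiling against bright outliers. Ties are broken toward the first
#' entry in (B1, T1, T2*) dictionary order, which makes matching fully
#' deterministic. When the dictionary has been compressed with
#' [compress_dictionary()], the inner products are evaluated in the low-rank
#' subspace.
#'
#' @param series 4D array `(x, y, slice, frame)` (3D treated as one slice),
#'   or a `frames x voxels` matrix (then maps are returned as vectors).
#' @param dict An `mrf_dictionary`, optionally compressed.
#' @param mask Optional logical array; voxels outside are skipped (maps get
#'   `NA` there, M0 0).
#' @param chunk_voxels Number of voxels scored per block (memory/speed
#'   trade-off).
#' @return An object of class `mrf_maps`: arrays (or vectors) `t1_ms`,
#'   `t2star_ms`, `b1_eff`, `m0`, `m0_relative`, `match_correlation`, and
#'   `index` (matched dictionary column).
#' @export
match_single <- function(series, dict, mask = NULL, chunk_voxels = 256L) {
  stopifnot(inherits(dict, "mrf_dictionary"))
  as_matrix <- is.matrix(series)
  if (!as_matrix) {
    if (length(dim(series)) == 3L) {
      dim(series) <- c(dim(series)[1:2], 1L, dim(series)[3])
    }
    assert_that(length(dim(series)) == 4L,
                "series must be a 4D array or frames x voxels matrix")
    d <- dim(series)
    X <- t(matrix(series, nrow = prod(d[1:3]), ncol = d[4]))
  } else {
    X <- series
    d <- NULL
  }
  nf <- nrow(dict$atoms)
  assert_that(nrow(X) == nf,
              "series has %d frames but the dictionary %d", nrow(X), nf)
  nv <- ncol(X)
  vox <- seq_len(nv)
  if (!is.null(mask)) {
    assert_that(length(mask) == nv, "mask size must match the voxel grid")
    vox <- which(as.logical(mask))
  }
  A <- if (!is.null(dict$projector)) dict$atoms_c else dict$atoms
  best_idx <- integer(nv)
  best_ip <- numeric(nv)
  xnorm <- numeric(nv)
  for (start in seq(1L, length(vox), by = chunk_voxels)) {
    cols <- vox[start:min(start + chunk_voxels - 1L, length(vox))]
    Xc <- X[, cols, drop = FALSE]
    xnorm[cols] <- col_norms(Xc)
    if (!is.null(dict$projector)) Xc <- crossprod(dict$projector, Xc)
    S <- abs(crossprod(A, Xc))                 # entries x chunk
    idx <- max.col(t(S), ties.method = "first")
    best_idx[cols] <- idx
    best_ip[cols] <- S[cbind(idx, seq_along(cols))]
  }
  sel <- vox
  m0 <- numeric(nv)
  m0[sel] <- best_ip[sel] / dict$norms[best_idx[sel]]
  corr <- rep(NA_real_, nv)
  nz <- sel[xnorm[sel] > 0]
  corr[nz] <- pmin(1, best_ip[nz] / xnorm[nz])
  corr[setdiff(sel, nz)] <- 0
  q99 <- stats::quantile(m0[sel], 0.99, names = FALSE)
  m0_rel <- if (q99 > 0) m0 / q99 else m0
  shape_out <- function(v, fill = NA_real_) {
    full <- rep(fill, nv)
    full[sel] <- v[sel]
    if (is.null(d)) full else array(full, d[1:3])
  }
  ent <- dict$entries
  t1 <- t2s <- b1 <- rep(NA_real_, nv)
  t1[sel] <- ent$t1_ms[best_idx[sel]]
  t2s[sel] <- ent$t2star_ms[best_idx[sel]]
  b1[sel] <- ent$b1[best_idx[sel]]
  structure(
    list(t1_ms = shape_out(t1),
         t2star_ms = shape_out(t2s),
         b1_eff = shape_out(b1),
         m0 = shape_out(m0, fill = 0),
         m0_relative = shape_out(m0_rel, fill = 0),
         match_correlation = shape_out(corr),
         index = {
           full <- rep(NA_integer_, nv); full[sel] <- best_idx[sel]
           if (is.null(d)) full else array(full, d[1:3])
         }),
    class = "mrf_maps")
}

#' Spatially regularize a matched flip-angle-efficiency map
#'
#' Transmit-field (B1) inhomogeneity is spatially smooth, but the per-voxel
#' matched efficiency is noisy wherever a voxel mixes tissues (its signal is
#' then not a single dictionary atom). A modal filter replaces each voxel's
#' value by the most frequent grid value in its in-plane neighbourhood,
#' which restores the underlying smooth field while keeping every value on
#' the dictionary's B1 grid.
#'
#' @param b1_map 3D array of matched B1 values (may contain `NA` outside the
#'   head).
#' @param radius In-plane neighbourhood radius in voxels (default 3).
#' @param mask Optional logical array restricting the neighbourhood votes.
#' @return The filtered 3D array; `NA` voxels are filled with 1.
#' @export
smooth_b1 <- function(b1_map, radius = 3L, mask = NULL) {
  d <- dim(b1_map)
  assert_that(length(d) == 3L, "b1_map must be a 3D array")
  out <- b1_map
  r <- as.integer(radius)
  for (z in seq_len(d[3])) {
    sl <- b1_map[, , z]
    msl <- if (is.null(mask)) !is.na(sl) else (mask[, , z] & !is.na(sl))
    res <- sl
    for (x in seq_len(d[1])) {
      xs <- max(1L, x - r):min(d[1], x + r)
      for (y in seq_len(d[2])) {
        if (!msl[x, y]) next
        ys <- max(1L, y - r):min(d[2], y + r)
        vals <- sl[xs, ys][msl[xs, ys]]
        if (length(vals) == 0L) next
        tab <- table(vals)
        best <- names(tab)[tab == max(tab)]
        if (length(best) > 1L) {
          ## tie: keep the candidate closest to the voxel's own value
          bv <- as.numeric(best)
          best <- best[which.min(abs(bv - sl[x, y]))]
        }
        res[x, y] <- as.numeric(best)
      }
    }
    out[, , z] <- res
  }
  out[is.na(out)] <- 1
  out
}

#' Brain mask from the relative M0 map
#'
#' Thresholds relative M0 and keeps the largest 3D connected component
#' (26-connectivity by default) — the region containing the brain.
#'
#' @param maps An `mrf_maps` from [match_single()] (or a bare `m0_relative`
#'   array).
#' @param threshold Relative-M0 threshold (default 0.05, i.e. 5%).
#' @param connectivity 26 (default) or 6.
#' @return Logical array of the input grid shape.
#' @export
brain_mask <- function(maps, threshold = 0.05, connectivity = 26) {
  m0r <- if (inherits(maps, "mrf_maps")) maps$m0_relative else maps
  assert_that(!is.null(dim(m0r)), "brain_mask needs an array m0_relative map")
  above <- m0r > threshold
  if (!any(above)) {
    stop_invalid("empty brain mask: no voxel has relative M0 > %g (max is %g)",
                 threshold, max(m0r))
  }
  largest_component(above, connectivity = connectivity)
}
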