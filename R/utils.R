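#' @keywords internal
"_PACKAGE"

## Internal helpers shared across the pipeline.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop_invalid(...)
  invisible(TRUE)
}

## Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
## state afterwards so library code never clobbers user-level reproducibility.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

## L2 norms of matrix columns.
col_norms <- function(x) sqrt(colSums(x^2))

#' Label connected components of a 3D binary mask
#'
#' Breadth-first flood fill with 26-connectivity (all voxels sharing a face,
#' edge or corner are neighbours). 2D inputs are treated as a single slice.
#'
#' @param mask Logical (or 0/1) array, 2D or 3D.
#' @param connectivity 26 (default) or 6 (face neighbours only).
#' @return Integer array of the same shape: 0 outside the mask, components
#'   labelled 1, 2, ... in decreasing voxel-count order (1 is the largest).
#' @export
label_components <- function(mask, connectivity = 26) {
  if (length(dim(mask)) == 2L) dim(mask) <- c(dim(mask), 1L)
  assert_that(length(dim(mask)) == 3L, "mask must be a 2D or 3D array")
  assert_that(connectivity %in% c(6, 26), "connectivity must be 6 or 26")
  d <- dim(mask)
  m <- array(as.logical(mask), d)
  labels <- array(0L, d)
  nb <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nb <- nb[rowSums(nb != 0) > 0, , drop = FALSE]
  if (connectivity == 6) nb <- nb[rowSums(abs(nb)) == 1, , drop = FALSE]
  idx_all <- which(m)
  if (length(idx_all) == 0L) return(labels)
  lab <- 0L
  sizes <- integer(0)
  queue <- integer(length(idx_all))
  for (start in idx_all) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    queue[1L] <- start
    head <- 1L; tail <- 1L
    labels[start] <- lab
    while (head <= tail) {
      frontier <- queue[head:tail]
      head <- tail + 1L
      cv <- arrayInd(frontier, d)
      for (k in seq_len(nrow(nb))) {
        x <- cv[, 1L] + nb[k, 1L]; y <- cv[, 2L] + nb[k, 2L]; z <- cv[, 3L] + nb[k, 3L]
        ok <- x >= 1L & y >= 1L & z >= 1L & x <= d[1L] & y <= d[2L] & z <= d[3L]
        if (!any(ok)) next
        w <- x[ok] + d[1L] * (y[ok] - 1L) + d[1L] * d[2L] * (z[ok] - 1L)
        w <- unique(w[m[w] & labels[w] == 0L])
        if (length(w) > 0L) {
          labels[w] <- lab
          queue[(tail + 1L):(tail + length(w))] <- w
          tail <- tail + length(w)
        }
      }
    }
    sizes <- c(sizes, tail)
  }
  ## relabel so component 1 is the largest
  ord <- order(sizes, decreasing = TRUE)
  remap <- integer(lab)
  remap[ord] <- seq_len(lab)
  nz <- labels != 0L
  labels[nz] <- remap[labels[nz]]
  labels
}

#' Largest connected component of a binary mask
#' @param mask Logical array (2D or 3D).
#' @param connectivity Passed to [label_components()].
#' @return Logical array of the original shape.
#' @export
largest_component <- function(mask, connectivity = 26) {
  d0 <- dim(mask)
  lab <- label_components(mask, connectivity)
  out <- lab == 1L
  dim(out) <- if (length(d0) == 2L) c(d0, 1L) else d0
  if (length(d0) == 2L) dim(out) <- d0
  out
}
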