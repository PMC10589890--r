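#' Build the (T1, T2*, B1) dictionary grid
#'
#' T1 and T2* values form geometric series starting at the lower bound and
#' including every value not exceeding the upper bound; successive values
#' differ by `step_fraction` (default 5%). Flip-angle-efficiency (B1) values
#' form an inclusive arithmetic series. Pairs with T1 < T2* are physically
#' inadmissible under the dictionary convention and excluded. The published
#' protocol grid — T1 30–4000 ms and T2* 5–3000 ms in 5% steps, B1 0.65–1.35
#' in 0.05 steps — yields 101 x 132 relaxation values, 8,772 admissible
#' pairs, and 131,580 total entries.
#'
#' @param t1_range_ms,t2star_range_ms Two-element ranges (ms).
#' @param step_fraction Multiplicative step of the geometric series.
#' @param b1_range,b1_step Arithmetic B1 series (inclusive endpoints).
#' @return An object of class `mrf_grid` with fields `t1_values_ms`,
#'   `t2star_values_ms`, `b1_values`, `pairs` (data frame of admissible
#'   `(t1_ms, t2star_ms)` with indices) and `n_entries`.
#' @export
build_grid <- function(t1_range_ms = c(30, 4000),
                       t2star_range_ms = c(5, 3000),
                       step_fraction = 0.05,
                       b1_range = c(0.65, 1.35),
                       b1_step = 0.05) {
  assert_that(all(t1_range_ms > 0) && all(t2star_range_ms > 0),
              "relaxation-time ranges must be positive")
  assert_that(step_fraction > 0, "step_fraction must be positive")
  assert_that(b1_step > 0 && all(b1_range > 0), "B1 series must be positive")
  geom_series <- function(r) {
    n <- floor(log(r[2] / r[1]) / log1p(step_fraction) + 1e-9)
    r[1] * (1 + step_fraction)^(0:n)
  }
  t1v <- geom_series(t1_range_ms)
  t2v <- geom_series(t2star_range_ms)
  nb1 <- round((b1_range[2] - b1_range[1]) / b1_step) + 1L
  b1v <- b1_range[1] + b1_step * (seq_len(nb1) - 1L)
  b1v <- b1v[b1v <= b1_range[2] + 1e-9]
  idx <- expand.grid(it2 = seq_along(t2v), it1 = seq_along(t1v))
  keep <- t1v[idx$it1] >= t2v[idx$it2]
  idx <- idx[keep, , drop = FALSE]
  if (nrow(idx) == 0L) {
    stop_invalid("empty grid: no admissible (T1, T2*) pairs with T1 >= T2*")
  }
  pairs <- data.frame(it1 = idx$it1, it2 = idx$it2,
                      t1_ms = t1v[idx$it1], t2star_ms = t2v[idx$it2])
  rownames(pairs) <- NULL
  structure(
    list(t1_values_ms = t1v, t2star_values_ms = t2v, b1_values = b1v,
         pairs = pairs, n_pairs = nrow(pairs),
         n_entries = nrow(pairs) * length(b1v),
         step_fraction = step_fraction),
    class = "mrf_grid")
}

#' @export
print.mrf_grid <- function(x, ...) {
  cat(sprintf(paste0("MRF dictionary grid: %d T1 x %d T2* values (%g%% steps),",
                     " %d admissible pairs, %d B1 values -> %d entries\n"),
              length(x$t1_values_ms), length(x$t2star_values_ms),
              100 * x$step_fraction, x$n_pairs, length(x$b1_values),
              x$n_entries))
  invisible(x)
}

#' Snap relaxation times / B1 values to the nearest grid points
#'
#' Nearest neighbour on a log scale for relaxation times (the grids are
#' geometric) and on a linear scale for B1.
#'
#' @param grid An `mrf_grid`.
#' @param t1_ms,t2star_ms,b1 Values to snap (any may be `NULL`).
#' @return A list with the snapped vectors.
#' @export
snap_to_grid <- function(grid, t1_ms = NULL, t2star_ms = NULL, b1 = NULL) {
  near <- function(x, v, log_scale = TRUE) {
    if (is.null(x)) return(NULL)
    if (log_scale) {
      v[vapply(x, function(z) which.min(abs(log(v) - log(z))), integer(1))]
    } else {
      v[vapply(x, function(z) which.min(abs(v - z)), integer(1))]
    }
  }
  list(t1_ms = near(t1_ms, grid$t1_values_ms),
       t2star_ms = near(t2star_ms, grid$t2star_values_ms),
       b1 = near(b1, grid$b1_values, log_scale = FALSE))
}

#' Build a per-slice MRF signal dictionary
#'
#' Simulates one atom per (T1, T2*) pair x B1 value with the slice's timing
#' offset and L2-normalizes each column; the pre-normalization norms are kept
#' so that matching can recover M0. Entries are ordered B1-major: entry
#' `(b, p)` sits at column `(b - 1) * n_pairs + p`.
#'
#' @param train An `mrf_train`.
#' @param grid An `mrf_grid`.
#' @param slice_index Integer identifier of the slice the timing belongs to
#'   (metadata only).
#' @param slice_offset_ms Excitation offset used in simulation (defaults to
#'   the train's own offset).
#' @param b1_subset Optional subset of `grid$b1_values` to simulate (used for
#'   phantoms whose B1 field spans a narrower range); values must be grid
#'   points.
#' @return An object of class `mrf_dictionary` with `atoms`
#'   (`n_frames x n_entries`, unit-norm columns), `norms`, `entries` (data
#'   frame: `pair`, `b1_index`, `t1_ms`, `t2star_ms`, `b1`), `grid`, `train`,
#'   `slice_index`, `slice_offset_ms`.
#' @export
build_dictionary <- function(train, grid, slice_index = 1L,
                             slice_offset_ms = NULL, b1_subset = NULL) {
  stopifnot(inherits(train, "mrf_train"), inherits(grid, "mrf_grid"))
  offset <- slice_offset_ms %||% train$slice_offset_ms
  b1v <- b1_subset %||% grid$b1_values
  if (!all(vapply(b1v, function(b) any(abs(grid$b1_values - b) < 1e-9), logical(1)))) {
    stop_invalid("b1_subset values must be grid B1 values")
  }
  np <- grid$n_pairs
  atoms <- matrix(0, nrow = train$n_frames, ncol = np * length(b1v))
  for (ib in seq_along(b1v)) {
    cols <- (ib - 1L) * np + seq_len(np)
    atoms[, cols] <- simulate_signals(train, grid$pairs$t1_ms,
                                      grid$pairs$t2star_ms,
                                      b1_eff = b1v[ib],
                                      slice_offset_ms = offset)
  }
  norms <- col_norms(atoms)
  if (any(norms == 0)) stop_invalid("dictionary produced an all-zero atom")
  atoms <- sweep(atoms, 2, norms, "/")
  entries <- data.frame(
    pair = rep(seq_len(np), times = length(b1v)),
    b1_index = rep(seq_along(b1v), each = np),
    t1_ms = rep(grid$pairs$t1_ms, times = length(b1v)),
    t2star_ms = rep(grid$pairs$t2star_ms, times = length(b1v)),
    b1 = rep(b1v, each = np))
  structure(
    list(atoms = atoms, norms = norms, entries = entries, grid = grid,
         b1_values = as.numeric(b1v), train = train,
         slice_index = as.integer(slice_index), slice_offset_ms = offset,
         projector = NULL, singular_values = NULL),
    class = "mrf_dictionary")
}

#' @export
print.mrf_dictionary <- function(x, ...) {
  cat(sprintf("MRF dictionary: %d frames x %d atoms (%d pairs x %d B1), slice %d (offset %g ms)%s\n",
              nrow(x$atoms %||% x$atoms_c), ncol(x$atoms %||% x$atoms_c),
              x$grid$n_pairs, length(x$b1_values), x$slice_index,
              x$slice_offset_ms,
              if (!is.null(x$projector)) sprintf(", compressed rank %d", ncol(x$projector)) else ""))
  invisible(x)
}

#' Low-rank SVD compression of a dictionary
#'
#' Projects atoms onto the leading rank-`rank` left-singular subspace of the
#' atom matrix. Matching and the multi-component solve can then run on
#' `rank`-length vectors instead of full signal evolutions; the absolute
#' inner-product error of any unit signal pair is bounded by the (rank+1)-th
#' singular value. Rank 1 collapses nearly all atoms onto one direction and
#' is unsupported for analysis.
#'
#' @param dict An `mrf_dictionary`.
#' @param rank Target rank, `1 <= rank <= n_frames` (default 10).
#' @return The dictionary with `atoms_c` (rank x entries compressed atoms),
#'   `projector` (`n_frames x rank`, orthonormal columns) and
#'   `singular_values` filled in.
#' @export
compress_dictionary <- function(dict, rank = 10L) {
  stopifnot(inherits(dict, "mrf_dictionary"))
  n <- nrow(dict$atoms)
  assert_that(rank >= 1 && rank <= n, "rank must lie in [1, n_frames]")
  if (rank == 1L) {
    warning("rank-1 compression degenerates matching; unsupported for analysis")
  }
  e <- eigen(tcrossprod(dict$atoms), symmetric = TRUE)
  sv <- sqrt(pmax(e$values, 0))
  V <- e$vectors[, seq_len(rank), drop = FALSE]
  dict$projector <- V
  dict$singular_values <- sv
  dict$atoms_c <- crossprod(V, dict$atoms)
  dict$rank <- as.integer(rank)
  dict
}

#' Project a signal matrix into a dictionary's compressed space
#' @param dict A compressed `mrf_dictionary`.
#' @param x `n_frames x n` signal matrix (or a vector).
#' @return `rank x n` matrix of compressed signals.
#' @export
compress_signals <- function(dict, x) {
  assert_that(!is.null(dict$projector), "dictionary is not compressed; call compress_dictionary()")
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  crossprod(dict$projector, x)
}

#' Cache a dictionary to disk / reload it
#'
#' The atom matrix is stored as a portable flat binary of doubles next to a
#' JSON sidecar carrying the grid, entry table, train and slice metadata.
#'
#' @param dict An `mrf_dictionary`.
#' @param dir Output directory (created if needed).
#' @return `write_dictionary` returns `dir`; `read_dictionary` the dictionary.
#' @export
write_dictionary <- function(dict, dir) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop_invalid("dictionary caching requires the jsonlite package")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(dir, "atoms.bin"), "wb")
  writeBin(as.vector(dict$atoms), con, size = 8, endian = "little")
  close(con)
  meta <- list(
    n_frames = nrow(dict$atoms), n_entries = ncol(dict$atoms),
    norms = dict$norms, b1_values = dict$b1_values,
    slice_index = dict$slice_index, slice_offset_ms = dict$slice_offset_ms,
    grid = list(t1_values_ms = dict$grid$t1_values_ms,
                t2star_values_ms = dict$grid$t2star_values_ms,
                b1_values = dict$grid$b1_values,
                step_fraction = dict$grid$step_fraction,
                pairs = dict$grid$pairs),
    train = unclass(dict$train))
  jsonlite::write_json(meta, file.path(dir, "dictionary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(dir) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop_invalid("dictionary caching requires the jsonlite package")
  }
  meta <- jsonlite::read_json(file.path(dir, "dictionary.json"),
                              simplifyVector = TRUE)
  con <- file(file.path(dir, "atoms.bin"), "rb")
  atoms <- readBin(con, "double", n = meta$n_frames * meta$n_entries,
                   size = 8, endian = "little")
  close(con)
  atoms <- matrix(atoms, nrow = meta$n_frames)
  grid <- structure(
    list(t1_values_ms = meta$grid$t1_values_ms,
         t2star_values_ms = meta$grid$t2star_values_ms,
         b1_values = meta$grid$b1_values,
         pairs = as.data.frame(meta$grid$pairs),
         n_pairs = nrow(meta$grid$pairs),
         n_entries = nrow(meta$grid$pairs) * length(meta$grid$b1_values),
         step_fraction = meta$grid$step_fraction),
    class = "mrf_grid")
  train <- sequence_train(meta$train$flip_angle_deg, meta$train$te_ms,
                          meta$train$tr_ms, meta$train$inversion_times_ms,
                          meta$train$slice_offset_ms,
                          meta$train$inversion_efficiency,
                          meta$train$flip_range_deg)
  np <- grid$n_pairs
  b1v <- meta$b1_values
  entries <- data.frame(
    pair = rep(seq_len(np), times = length(b1v)),
    b1_index = rep(seq_along(b1v), each = np),
    t1_ms = rep(grid$pairs$t1_ms, times = length(b1v)),
    t2star_ms = rep(grid$pairs$t2star_ms, times = length(b1v)),
    b1 = rep(b1v, each = np))
  structure(
    list(atoms = atoms, norms = meta$norms, entries = entries, grid = grid,
         b1_values = b1v, train = train,
         slice_index = meta$slice_index,
         slice_offset_ms = meta$slice_offset_ms,
         projector = NULL, singular_values = NULL),
    class = "mrf_dictionary")
}
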