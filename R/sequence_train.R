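#' Construct an MRF-EPI sequence train
#'
#' A sequence train is the per-timeframe acquisition schedule of a
#' transient-state MRF-EPI protocol: one gradient-echo EPI excitation per
#' frame with its own flip angle, echo time and repetition time, plus global
#' adiabatic inversion pulses at absolute times within the acquisition.
#'
#' @param flip_angle_deg Numeric vector of nominal flip angles (degrees).
#' @param te_ms Echo times per frame (ms).
#' @param tr_ms Repetition times per frame (ms).
#' @param inversion_times_ms Absolute times (ms, from the start of the train)
#'   of global inversion pulses; must be strictly increasing.
#' @param slice_offset_ms Excitation delay of the simulated slice within each
#'   TR (ms). Multi-slice protocols excite each slice at a different offset,
#'   which shifts the inversion times relative to the excitations.
#' @param inversion_efficiency Inversion efficiency in (0, 1]; 1 is a perfect
#'   180-degree inversion.
#' @param flip_range_deg Permitted flip-angle range used for validation.
#' @return An object of class `mrf_train`.
#' @export
sequence_train <- function(flip_angle_deg, te_ms, tr_ms,
                           inversion_times_ms = numeric(0),
                           slice_offset_ms = 0,
                           inversion_efficiency = 1,
                           flip_range_deg = c(34, 86)) {
  n <- length(flip_angle_deg)
  assert_that(n >= 1L, "a sequence train needs at least one frame")
  assert_that(length(te_ms) == n && length(tr_ms) == n,
              "flip_angle_deg, te_ms and tr_ms must have equal length")
  assert_that(all(flip_angle_deg >= flip_range_deg[1] - 1e-9) &&
              all(flip_angle_deg <= flip_range_deg[2] + 1e-9),
              "flip angles outside the configured range [%g, %g] deg",
              flip_range_deg[1], flip_range_deg[2])
  assert_that(all(te_ms > 0) && all(tr_ms > 0),
              "TE and TR must be positive")
  assert_that(all(te_ms < tr_ms), "te_ms[k] must be < tr_ms[k] for every frame")
  if (length(inversion_times_ms) > 1) {
    assert_that(all(diff(inversion_times_ms) > 0),
                "inversion times must be strictly increasing")
  }
  assert_that(all(inversion_times_ms >= 0), "inversion times must be >= 0")
  assert_that(inversion_efficiency > 0 && inversion_efficiency <= 1,
              "inversion_efficiency must lie in (0, 1]")
  assert_that(slice_offset_ms >= 0 && slice_offset_ms < min(tr_ms),
              "slice_offset_ms must lie in [0, min(TR))")
  structure(
    list(n_frames = n,
         flip_angle_deg = as.numeric(flip_angle_deg),
         te_ms = as.numeric(te_ms),
         tr_ms = as.numeric(tr_ms),
         inversion_times_ms = as.numeric(inversion_times_ms),
         slice_offset_ms = slice_offset_ms,
         inversion_efficiency = inversion_efficiency,
         flip_range_deg = flip_range_deg),
    class = "mrf_train")
}

#' Default MRF-EPI sequence train
#'
#' Builds a reproducible default schedule over the protocol's published
#' parameter ranges: flip angles sweep smoothly (quarter-period sinusoidal
#' ramp) from 34 to 86 degrees, TE ramps linearly from 21 to 81.5 ms, TR
#' ramps linearly from 3530 to 6570 ms, and global inversion pulses are
#' placed uniformly so that their count is as close as possible to 3 per
#' minute of cumulative TR. The schedule is fully deterministic; `seed` is
#' accepted for interface symmetry with the stochastic generators but is not
#' consumed (no randomness is involved).
#'
#' @param n_frames Number of timeframes (default 50, about 4.2 minutes of
#'   acquisition at the default TR ramp).
#' @param seed Unused; retained for a uniform generator interface.
#' @param flip_range_deg,te_range_ms,tr_range_ms Schedule endpoint ranges.
#' @param inversions_per_min Target global inversion-pulse rate.
#' @param slice_offset_ms,inversion_efficiency Passed to [sequence_train()].
#' @return An `mrf_train`.
#' @export
default_train <- function(n_frames = 50, seed = NULL,
                          flip_range_deg = c(34, 86),
                          te_range_ms = c(21, 81.5),
                          tr_range_ms = c(3530, 6570),
                          inversions_per_min = 3,
                          slice_offset_ms = 0,
                          inversion_efficiency = 1) {
  assert_that(is.numeric(n_frames) && n_frames >= 1, "n_frames must be >= 1")
  n <- as.integer(n_frames)
  u <- if (n == 1L) 0 else (seq_len(n) - 1) / (n - 1)
  flip <- flip_range_deg[1] + diff(flip_range_deg) * sin(pi / 2 * u)
  te <- te_range_ms[1] + diff(te_range_ms) * u
  tr <- tr_range_ms[1] + diff(tr_range_ms) * u
  total_ms <- sum(tr)
  n_inv <- round(inversions_per_min * total_ms / 60000)
  inv_times <- if (n_inv >= 1) (seq_len(n_inv) - 0.5) * total_ms / n_inv else numeric(0)
  sequence_train(flip, te, tr,
                 inversion_times_ms = inv_times,
                 slice_offset_ms = slice_offset_ms,
                 inversion_efficiency = inversion_efficiency,
                 flip_range_deg = flip_range_deg)
}

#' @export
print.mrf_train <- function(x, ...) {
  cat(sprintf("MRF-EPI sequence train: %d frames, %.1f s total\n",
              x$n_frames, sum(x$tr_ms) / 1000))
  cat(sprintf("  flip %g-%g deg, TE %g-%g ms, TR %g-%g ms\n",
              min(x$flip_angle_deg), max(x$flip_angle_deg),
              min(x$te_ms), max(x$te_ms), min(x$tr_ms), max(x$tr_ms)))
  cat(sprintf("  %d inversion pulses (efficiency %.2f), slice offset %g ms\n",
              length(x$inversion_times_ms), x$inversion_efficiency,
              x$slice_offset_ms))
  invisible(x)
}

#' Write / read a sequence train as a plain-text table
#'
#' One row per frame (`frame`, `flip_deg`, `te_ms`, `tr_ms`) with header
#' comment lines carrying the inversion times, slice offset and inversion
#' efficiency, so trains can be exchanged with other tools.
#'
#' @param train An `mrf_train`.
#' @param path File path.
#' @return `write_train` returns `path` invisibly; `read_train` an `mrf_train`.
#' @export
write_train <- function(train, path) {
  hdr <- c(
    sprintf("# inversion_times_ms: %s",
            paste(format(train$inversion_times_ms, digits = 12), collapse = " ")),
    sprintf("# slice_offset_ms: %g", train$slice_offset_ms),
    sprintf("# inversion_efficiency: %g", train$inversion_efficiency),
    sprintf("# flip_range_deg: %g %g", train$flip_range_deg[1], train$flip_range_deg[2]))
  tab <- data.frame(frame = seq_len(train$n_frames),
                    flip_deg = train$flip_angle_deg,
                    te_ms = train$te_ms,
                    tr_ms = train$tr_ms)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(tab, con, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_train
#' @export
read_train <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get_field <- function(key) {
    ln <- hdr[grepl(paste0("^# ", key, ":"), hdr)]
    if (length(ln) == 0) return(numeric(0))
    as.numeric(strsplit(sub(paste0("^# ", key, ":\\s*"), "", ln[1]), "\\s+")[[1]])
  }
  tab <- utils::read.table(text = lines[!startsWith(lines, "#")],
                           header = TRUE, sep = "\t")
  fr <- get_field("flip_range_deg")
  sequence_train(tab$flip_deg, tab$te_ms, tab$tr_ms,
                 inversion_times_ms = get_field("inversion_times_ms"),
                 slice_offset_ms = {
                   s <- get_field("slice_offset_ms"); if (length(s)) s else 0
                 },
                 inversion_efficiency = {
                   e <- get_field("inversion_efficiency"); if (length(e)) e else 1
                 },
                 flip_range_deg = if (length(fr) == 2) fr else c(34, 86))
}
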