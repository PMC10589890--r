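#' Simulate transient-state MRF-EPI signals
#'
#' Evolves longitudinal magnetization through the sequence train under a
#' spoiled gradient-echo model and returns the magnitude signal of each
#' frame. The model is the standard (T1, T2*) transient-state description of
#' MRF-EPI: perfect spoiling of transverse magnetization between frames, so
#' no echo-pathway bookkeeping is needed; each excitation with nominal flip
#' angle `a` and efficiency `b1` tips the current longitudinal magnetization,
#' giving a gradient-echo magnitude
#' \deqn{s_k = M_0 \, |M_z^{(k)}| \sin(b_1 \alpha_k) \, e^{-TE_k/T_2^*},}
#' after which \eqn{M_z \leftarrow M_z \cos(b_1 \alpha_k)}. Between events
#' \eqn{M_z} relaxes mono-exponentially toward equilibrium with constant T1,
#' and each global inversion pulse applies
#' \eqn{M_z \leftarrow -\eta\, M_z} (efficiency \eqn{\eta}) instantaneously.
#' The slice is excited `slice_offset_ms` after each frame's TR starts and
#' relaxation is integrated over the actual event spacings. When an
#' inversion coincides exactly with an excitation time the inversion is
#' applied first.
#'
#' `simulate_signals()` is the vectorized work-horse: it evolves many tissues
#' simultaneously (one column per tissue) and is what dictionary generation
#' uses. `simulate_signal()` is the single-tissue convenience wrapper.
#'
#' @param train An `mrf_train` from [sequence_train()] or [default_train()].
#' @param t1_ms,t2star_ms Relaxation times (ms); vectors are recycled to a
#'   common length.
#' @param b1_eff Flip-angle efficiency (dimensionless multiplier on the
#'   nominal flip angle).
#' @param m0 Equilibrium magnetization (arbitrary signal units). The signal
#'   is exactly linear in `m0`.
#' @param slice_offset_ms Overrides the train's slice offset when not `NULL`.
#' @return `simulate_signals()`: an `n_frames x n_tissues` matrix of
#'   non-negative magnitude signals. `simulate_signal()`: a vector.
#' @export
simulate_signals <- function(train, t1_ms, t2star_ms, b1_eff = 1, m0 = 1,
                             slice_offset_ms = NULL) {
  stopifnot(inherits(train, "mrf_train"))
  nt <- max(length(t1_ms), length(t2star_ms), length(b1_eff), length(m0))
  t1 <- rep_len(as.numeric(t1_ms), nt)
  t2s <- rep_len(as.numeric(t2star_ms), nt)
  b1 <- rep_len(as.numeric(b1_eff), nt)
  m0 <- rep_len(as.numeric(m0), nt)
  assert_that(all(t1 > 0) && all(t2s > 0), "relaxation times must be positive")
  assert_that(all(b1 > 0), "b1_eff must be positive")
  assert_that(all(m0 >= 0), "m0 must be non-negative")

  n <- train$n_frames
  offset <- slice_offset_ms %||% train$slice_offset_ms
  tr_start <- cumsum(c(0, train$tr_ms))[seq_len(n)]
  t_exc <- tr_start + offset
  ev_time <- c(t_exc, train$inversion_times_ms)
  ev_frame <- c(seq_len(n), rep(0L, length(train$inversion_times_ms)))
  ## inversion (frame 0) sorts before an excitation at the same instant
  ord <- order(ev_time, ev_frame)
  ev_time <- ev_time[ord]
  ev_frame <- ev_frame[ord]

  alpha <- train$flip_angle_deg * pi / 180
  out <- matrix(0, nrow = n, ncol = nt)
  mz <- rep(1, nt)            # normalized to equilibrium = 1; m0 applied at readout
  t_prev <- 0
  for (i in seq_along(ev_time)) {
    dt <- ev_time[i] - t_prev
    if (dt > 0) mz <- 1 + (mz - 1) * exp(-dt / t1)
    k <- ev_frame[i]
    if (k == 0L) {
      mz <- -train$inversion_efficiency * mz
    } else {
      out[k, ] <- abs(mz) * sin(b1 * alpha[k]) * exp(-train$te_ms[k] / t2s)
      mz <- mz * cos(b1 * alpha[k])
    }
    t_prev <- ev_time[i]
  }
  ## m0 applied as a final scaling so the signal is *exactly* linear in m0
  if (any(m0 != 1)) out <- out * rep(m0, each = n)
  out
}

#' @rdname simulate_signals
#' @param tissue Optional list with elements `t1_ms`, `t2star_ms`, `b1_eff`,
#'   `m0` (as produced by [tissue_params()]); overrides the scalar arguments.
#' @export
simulate_signal <- function(train, t1_ms = NULL, t2star_ms = NULL, b1_eff = 1,
                            m0 = 1, slice_offset_ms = NULL, tissue = NULL) {
  if (!is.null(tissue)) {
    t1_ms <- tissue$t1_ms; t2star_ms <- tissue$t2star_ms
    b1_eff <- tissue$b1_eff; m0 <- tissue$m0
  }
  drop(simulate_signals(train, t1_ms, t2star_ms, b1_eff, m0, slice_offset_ms))
}

#' Tissue parameter set for signal simulation
#'
#' Bundles the relaxation and scaling parameters of one tissue. By the
#' dictionary convention, T1 must be at least T2*.
#'
#' @param t1_ms,t2star_ms Relaxation times in ms (strictly positive,
#'   `t1_ms >= t2star_ms`).
#' @param b1_eff Flip-angle efficiency (strictly positive).
#' @param m0 Equilibrium magnetization (non-negative).
#' @return A list of class `tissue_params`.
#' @export
tissue_params <- function(t1_ms, t2star_ms, b1_eff = 1, m0 = 1) {
  assert_that(t1_ms > 0 && t2star_ms > 0, "relaxation times must be positive")
  assert_that(t1_ms >= t2star_ms, "dictionary convention requires t1_ms >= t2star_ms")
  assert_that(b1_eff > 0, "b1_eff must be positive")
  assert_that(m0 >= 0, "m0 must be non-negative")
  structure(list(t1_ms = t1_ms, t2star_ms = t2star_ms,
                 b1_eff = b1_eff, m0 = m0),
            class = "tissue_params")
}

#' Shape difference between two simulated signal evolutions
#'
#' One minus the cosine similarity of the L2-normalized magnitude signals of
#' two tissues under the same train — the quantity that measures how
#' (in)distinguishable two relaxation-time combinations are for a given
#' sequence. Values are dimensionless in [0, 1]; multiply by 100 for percent.
#'
#' @param train An `mrf_train`.
#' @param t1_a,t2star_a,t1_b,t2star_b Relaxation times (ms) of the two tissues.
#' @param b1_eff Shared flip-angle efficiency.
#' @return One minus the normalized inner product of the two signals.
#' @export
signal_shape_difference <- function(train, t1_a, t2star_a, t1_b, t2star_b,
                                    b1_eff = 1) {
  s <- simulate_signals(train, c(t1_a, t1_b), c(t2star_a, t2star_b), b1_eff)
  u <- sweep(s, 2, col_norms(s), "/")
  1 - sum(u[, 1] * u[, 2])
}
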