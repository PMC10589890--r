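#' Fast non-negative least squares on the normal equations
#'
#' Active-set NNLS (Bro-de Jong style FNNLS) working directly from the Gram
#' matrix `G = t(A) %*% A` and the projected data `f = t(A) %*% b`, so one
#' Gram matrix serves many right-hand sides. Supports warm-starting from a
#' previous passive set.
#'
#' @param G Symmetric positive (semi-)definite Gram matrix.
#' @param f Numeric vector `t(A) %*% b`.
#' @param init Optional integer vector: passive-set warm start.
#' @param tol Dual-feasibility tolerance; defaults to
#'   `1e-10 * max(abs(f), 1)`.
#' @return Numeric solution vector `x >= 0` minimizing `||A x - b||^2`.
#' @export
fnnls <- function(G, f, init = NULL, tol = NULL) {
  n <- length(f)
  tol <- tol %||% (1e-10 * max(abs(f), 1))
  solve_passive <- function(idx) {
    Gp <- G[idx, idx, drop = FALSE]
    ## tiny relative jitter keeps rank-deficient passive sets solvable
    ## without a per-call tryCatch in this hot path
    diag(Gp) <- diag(Gp) + 1e-12 * (mean(diag(Gp)) + 1)
    as.numeric(solve(Gp, f[idx]))
  }
  gradient <- function(x, idx) {
    if (length(idx)) f - as.numeric(G[, idx, drop = FALSE] %*% x[idx]) else f
  }
  active_set_nnls(n, f, solve_passive, gradient, init = init, tol = tol)
}

## Ridge-penalized NNLS exploiting a low-rank design: A is r x n (r small),
## penalty `pen` adds pen[i] * x_i^2. Gradients cost O(n r) via
## f - A'(A_P x_P) - pen * x, and passive-set systems are |P| x |P|.
## Returns the solution vector.
nnls_ridge <- function(A, f, pen = NULL, init = NULL, tol = NULL) {
  n <- length(f)
  if (is.null(pen)) pen <- numeric(n)
  tol <- tol %||% (1e-10 * max(abs(f), 1))
  solve_passive <- function(idx) {
    Ap <- A[, idx, drop = FALSE]
    Gp <- crossprod(Ap)
    diag(Gp) <- diag(Gp) + pen[idx] + 1e-12 * (mean(diag(Gp)) + 1)
    as.numeric(solve(Gp, f[idx]))
  }
  gradient <- function(x, idx) {
    if (length(idx)) {
      u <- A[, idx, drop = FALSE] %*% x[idx]
      w <- f - as.numeric(crossprod(A, u))
      w[idx] <- w[idx] - pen[idx] * x[idx]
      w
    } else f
  }
  active_set_nnls(n, f, solve_passive, gradient, init = init, tol = tol)
}

## Batched exact solver for the strictly ridge-penalized NNLS
##   min_{x >= 0} ||A x - b||^2 + sum_i pen_i x_i^2,   pen_i > 0,
## for many right-hand sides sharing A (r x n, r small). The KKT conditions
## give x = max(0, A' r) / pen with residual r = b - A x, so r solves the
## piecewise-linear fixed point (I + A_S diag(1/pen_S) A_S') r = b on the
## active set S = {i : (A' r)_i > 0}. Iterating set-identification and the
## r-dimensional solve converges in a few sweeps; residuals can be
## warm-started across calls. Returns X (n x V) and the residuals R.
ridge_nnls_batch <- function(A, B, pen, R_init = NULL, max_sweeps = 40L,
                             fallback = TRUE, safe = FALSE) {
  rr <- nrow(A); V <- ncol(B)
  n <- ncol(A)
  R <- R_init %||% B
  ## rows penalized 1e10-fold above the minimum contribute below double
  ## precision to the dual system; leave them out of the factorizations
  ## (their coefficients still come out of the final A'R / pen)
  keep <- pen <= 1e10 * min(pen)
  G_full <- A[, keep, drop = FALSE] %*% (t(A[, keep, drop = FALSE]) / pen[keep])
  hvec <- sin(seq_len(n) * 0.7391)      # fixed set-hash vector
  prev_hash <- rep(NA_real_, V)
  prev_size <- rep(-1L, V)
  prev2_hash <- rep(NA_real_, V)        # two sweeps back, for cycle damping
  conv <- rep(FALSE, V)
  delta2 <- rep(Inf, V)                 # last relative residual change
  for (sweep in seq_len(max_sweeps)) {
    todo <- which(!conv)
    if (!length(todo)) break
    W <- crossprod(A, R[, todo, drop = FALSE])
    pos <- (W > 0) & keep
    sizes <- colSums(pos)
    hash <- as.numeric(crossprod(hvec, pos))
    same <- !is.na(prev_hash[todo]) & hash == prev_hash[todo] &
      sizes == prev_size[todo]
    conv[todo[same]] <- TRUE
    ## 2-cycles (set A -> B -> A) get their residuals damped toward the
    ## cycle midpoint, which breaks the oscillation
    cyc <- !same & !is.na(prev2_hash[todo]) & hash == prev2_hash[todo]
    prev2_hash[todo] <- prev_hash[todo]
    prev_hash[todo] <- hash
    prev_size[todo] <- sizes
    work <- which(!same)                # indices into todo / columns of pos
    if (!length(work)) next
    ## voxels sharing an active set share the linear system: factor once,
    ## solve all their right-hand sides together
    key <- paste0(sizes[work], ":", format(hash[work], digits = 17))
    for (grp in split(work, key)) {
      S <- which(pos[, grp[1L]])
      cols <- todo[grp]
      R_old <- R[, cols, drop = FALSE]
      if (length(S) == 0L) {
        R[, cols] <- B[, cols]
        conv[cols][colSums((B[, cols, drop = FALSE] - R_old)^2) <=
                     1e-12 * colSums(R_old^2)] <- TRUE
        next
      }
      if (length(S) <= sum(keep) / 2) {
        As <- A[, S, drop = FALSE]
        C <- As %*% (t(As) / pen[S])
      } else {
        ## large set: subtract the small complement from the cached
        ## full-set Gram instead of indexing thousands of columns
        comp <- setdiff(which(keep), S)
        C <- G_full
        if (length(comp)) {
          Ac <- A[, comp, drop = FALSE]
          C <- C - Ac %*% (t(Ac) / pen[comp])
        }
      }
      if (safe) {
        ## eigen-based inverse: the unit diagonal survives any eigenvalue
        ## magnitude (used as a retry when the penalty spread defeats solve)
        ev <- eigen(C, symmetric = TRUE)
        R_new <- ev$vectors %*%
          (crossprod(ev$vectors, B[, cols, drop = FALSE]) /
             (1 + pmax(ev$values, 0)))
      } else {
        diag(C) <- diag(C) + 1
        R_new <- solve(C, B[, cols, drop = FALSE])
      }
      damp <- cyc[grp]
      if (any(damp)) {
        R_new[, damp] <- 0.5 * (R_new[, damp, drop = FALSE] +
                                  R_old[, damp, drop = FALSE])
      }
      R[, cols] <- R_new
      ## residual-stationary voxels are done even if their active set keeps
      ## flipping between numerically equivalent choices
      d2 <- colSums((R_new - R_old)^2) / pmax(colSums(R_old^2), 1e-300)
      delta2[cols] <- d2
      conv[cols][d2 <= 1e-12] <- TRUE
    }
  }
  X <- crossprod(A, R)
  X[X < 0] <- 0
  X <- X / pen
  ## voxels whose residual genuinely kept moving: exact active-set fallback
  ## (near-stationary stragglers already carry accurate solutions)
  if (fallback && !all(conv)) {
    for (v in which(!conv & delta2 > 1e-8)) {
      x <- nnls_ridge(A, as.numeric(crossprod(A, B[, v])), pen = pen,
                      init = which(X[, v] > 0))
      X[, v] <- x
      S <- which(x > 0)
      R[, v] <- B[, v] - if (length(S)) A[, S, drop = FALSE] %*% x[S] else 0
    }
  }
  list(X = X, R = R, converged = all(conv))
}

## Shared Lawson-Hanson skeleton: `solve_passive(idx)` returns the
## unconstrained solution on the passive set, `gradient(x, idx)` the dual
## vector. Warm start keeps only initial columns that stay strictly positive.
active_set_nnls <- function(n, f, solve_passive, gradient, init = NULL, tol) {
  x <- numeric(n)
  inP <- logical(n)
  idx <- integer(0)
  if (length(init)) {
    idx <- as.integer(init)
    while (length(idx)) {
      s <- solve_passive(idx)
      if (all(s > 0)) { x[idx] <- s; inP[idx] <- TRUE; break }
      idx <- idx[s > 0]
    }
  }
  w <- gradient(x, idx)
  it <- 0L
  max_it <- 3L * n + 50L
  while (it < max_it) {
    it <- it + 1L
    w_free <- w
    w_free[inP] <- -Inf
    j <- which.max(w_free)
    if (!(w_free[j] > tol)) break
    inP[j] <- TRUE
    idx <- which(inP)
    s <- solve_passive(idx)
    inner <- 0L
    while (any(s <= 0) && inner < n + 5L) {
      inner <- inner + 1L
      bad <- s <= 0
      alpha <- min(x[idx][bad] / (x[idx][bad] - s[bad]))
      x[idx] <- x[idx] + alpha * (s - x[idx])
      drop_tol <- 1e-12 * max(x[idx], 1e-300)
      keep <- x[idx] > drop_tol
      keep[which(bad)[which.min(x[idx][bad] / pmax(x[idx][bad] - s[bad], 1e-300))]] <- FALSE
      x[idx][!keep] <- 0
      inP[idx[!keep]] <- FALSE
      idx <- idx[keep]
      if (!length(idx)) break
      s <- solve_passive(idx)
    }
    x[] <- 0
    if (length(idx)) { x[idx] <- s; inP[] <- FALSE; inP[idx] <- TRUE }
    else inP[] <- FALSE
    w <- gradient(x, idx)
  }
  x
}

## Multi-right-hand-side NNLS on a small shared Gram matrix via block
## principal pivoting (Murty's finite backup rule guards against cycling).
## Voxels sharing a passive set share one factorization. Returns X (n x V).
nnls_gram_batch <- function(G, F, max_iter = 200L) {
  n <- nrow(G); V <- ncol(F)
  X <- matrix(0, n, V)
  Y <- -F
  P <- matrix(FALSE, n, V)
  tol <- 1e-12 * (max(diag(G)) + 1)
  ninf_prev <- rep(Inf, V)
  nback <- rep(3L, V)
  alive <- rep(TRUE, V)
  hvec <- 2^seq(0, n - 1)              # exact set id for n <= 50
  for (it in seq_len(max_iter)) {
    I1 <- P & (X < -tol)
    I2 <- (!P) & (Y < -tol)
    ninf <- colSums(I1) + colSums(I2)
    alive <- ninf > 0L
    if (!any(alive)) break
    for (v in which(alive)) {
      if (ninf[v] < ninf_prev[v]) {
        nback[v] <- 3L
        P[, v] <- P[, v] & !I1[, v] | I2[, v]
      } else if (nback[v] > 0L) {
        nback[v] <- nback[v] - 1L
        P[, v] <- P[, v] & !I1[, v] | I2[, v]
      } else {
        j <- max(which(I1[, v] | I2[, v]))   # Murty's single-swap rule
        P[j, v] <- !P[j, v]
      }
      ninf_prev[v] <- ninf[v]
    }
    ids <- as.numeric(crossprod(hvec, P[, alive, drop = FALSE]))
    cols_alive <- which(alive)
    for (grp in split(seq_along(cols_alive), ids)) {
      cols <- cols_alive[grp]
      S <- which(P[, cols[1L]])
      if (!length(S)) {
        X[, cols] <- 0
        Y[, cols] <- -F[, cols, drop = FALSE]
        next
      }
      Gs <- G[S, S, drop = FALSE]
      diag(Gs) <- diag(Gs) + 1e-12 * (mean(diag(Gs)) + 1)
      Xs <- solve(Gs, F[S, cols, drop = FALSE])
      X[, cols] <- 0
      X[S, cols] <- Xs
      Y[, cols] <- G[, S, drop = FALSE] %*% Xs - F[, cols, drop = FALSE]
    }
  }
  bad <- which(colSums(P & (X < -tol)) + colSums((!P) & (Y < -tol)) > 0)
  X[X < 0 & P] <- 0          # numerical dust on near-degenerate sets
  X[!P] <- 0
  ## rank-deficient Grams can defeat block pivoting: finish those few
  ## right-hand sides with the exact active-set solver
  for (v in bad) X[, v] <- fnnls(G, F[, v])
  X
}

## Sum over `vox_sel` of the squared residual of unregularized NNLS
## restricted to the pair support `supp`, in full signal space.
support_residual <- function(X, dict, b1_idx, vox_sel, supp) {
  np <- dict$grid$n_pairs
  tot <- 0
  for (g in unique(b1_idx[vox_sel])) {
    vs <- vox_sel[b1_idx[vox_sel] == g]
    cols <- (g - 1L) * np + supp
    Ag <- dict$atoms[, cols, drop = FALSE]
    G <- crossprod(Ag)
    Fg <- crossprod(Ag, X[, vs, drop = FALSE])
    C <- nnls_gram_batch(G, Fg)
    fit2 <- 2 * colSums(C * Fg) - colSums(C * (G %*% C))
    tot <- tot + sum(colSums(X[, vs, drop = FALSE]^2) - fit2)
  }
  tot
}

## Admissible grid pairs within `radius` steps of pair index `p` in T1
## and/or T2*.
grid_neighbors <- function(grid, p, radius = 1L) {
  it1 <- grid$pairs$it1[p]; it2 <- grid$pairs$it2[p]
  cand <- expand.grid(it1 = it1 + (-radius):radius,
                      it2 = it2 + (-radius):radius)
  cand <- cand[!(cand$it1 == it1 & cand$it2 == it2), ]
  key <- paste(grid$pairs$it1, grid$pairs$it2)
  match_idx <- match(paste(cand$it1, cand$it2), key)
  match_idx[!is.na(match_idx)]
}

#' Configuration for the joint-sparse multi-component solve
#'
#' @param lambda_norm Normalized joint-sparsity regularization (default 11).
#'   The absolute penalty is
#'   `lambda_abs = lambda_norm * (total in-mask signal energy) / n_pairs`;
#'   at the reweighting fixed point the penalty term approaches
#'   `lambda_abs * (number of active rows)`, so scaling by the total energy
#'   makes the data-fit/sparsity trade-off invariant to image intensity
#'   scaling, mask size and grid size.
#' @param max_iter Maximum reweighting iterations (default 20).
#' @param tol Relative row-weight change declaring convergence (default 1e-4).
#' @param epsilon_frac Reweighting floor as a fraction of the maximum row
#'   norm (default 1e-4); keeps the reweighting bounded when rows die out.
#' @param support_floor_frac Rows with norm below this fraction of the
#'   maximum row norm are pruned from the final support (default 1e-3).
#' @param rank SVD compression rank used during the reweighted iterations
#'   (default 20; matches full-space solutions on reference phantoms while
#'   running several-fold faster); the final support re-fit is always done
#'   in full signal space. `NULL` disables compression.
#' @param continuation Ramp the penalty geometrically (lambda/64 -> lambda
#'   over four stages, warm-starting each) instead of starting at the target
#'   penalty (default TRUE). The reweighted objective is non-convex; the
#'   homotopy keeps mass on exactly-fitting atoms while the support
#'   concentrates, instead of letting near-duplicate atoms capture it early.
#' @param stage_iter Reweighting iterations per continuation stage before
#'   the final stage (default 4).
#' @param polish After the final re-fit, try swapping each support pair with
#'   its grid neighbours and keep strict residual reductions (default TRUE).
#'   Corrects the one-to-few-step drift the non-convex reweighting can leave
#'   along weakly-encoded directions such as the long-T2* fan.
#' @param polish_fraction Voxels whose fraction of a component exceeds this
#'   value are used to score that component's swaps (default 0.02).
#' @param polish_passes Maximum sweeps over the support (default 4).
#' @param polish_radius Grid radius of the candidate swaps (default 1;
#'   larger radii allow multi-step moves across shallow local minima at a
#'   proportional cost in scoring work).
#' @return A list of class `spijn_config`.
#' @export
spijn_config <- function(lambda_norm = 11, max_iter = 20L, tol = 1e-4,
                         epsilon_frac = 1e-4, support_floor_frac = 1e-3,
                         rank = 20L, continuation = TRUE, stage_iter = 4L,
                         polish = TRUE, polish_fraction = 0.02,
                         polish_passes = 4L, polish_radius = 1L) {
  assert_that(lambda_norm >= 0, "lambda_norm must be >= 0")
  assert_that(epsilon_frac > 0, "epsilon_frac must be positive")
  assert_that(max_iter >= 1, "max_iter must be >= 1")
  structure(list(lambda_norm = lambda_norm, max_iter = as.integer(max_iter),
                 tol = tol, epsilon_frac = epsilon_frac,
                 support_floor_frac = support_floor_frac,
                 rank = if (is.null(rank)) NULL else as.integer(rank),
                 continuation = isTRUE(continuation),
                 stage_iter = as.integer(stage_iter),
                 polish = isTRUE(polish),
                 polish_fraction = polish_fraction,
                 polish_passes = as.integer(polish_passes),
                 polish_radius = as.integer(polish_radius)),
            class = "spijn_config")
}

#' Joint-sparse multi-component MRF decomposition (SPIJN)
#'
#' Finds a small *global* set of (T1, T2*) components plus per-voxel
#' non-negative magnetization fractions that together explain every in-mask
#' signal, with each voxel's flip-angle efficiency fixed at its
#' single-component estimate. The row-sparsity ("few components shared by
#' all voxels") is obtained by iteratively reweighted Tikhonov-regularized
#' NNLS:
#'
#' 1. each voxel's dictionary is restricted to its fixed B1 slice, so every
#'    voxel shares the same (T1, T2*) pair index;
#' 2. row weights start at `r_i = 1`;
#' 3. per voxel `j`, solve
#'    `c_j = argmin_{c >= 0} ||D_j c - x_j||^2 + lambda_abs * sum_i c_i^2 / (r_i^2 + eps^2)`,
#'    then update `r_i` to the l2 norm of row `i` of the stacked solution
#'    across voxels. The `1 / (r_i^2 + eps^2)` weights are the
#'    majorize-minimize surrogate of the log row-norm penalty
#'    `sum_i log(r_i^2 + eps^2)`, an l0-like row-count penalty: unlike an
#'    l2,1 weight it penalizes *splitting* magnetization across
#'    near-duplicate dictionary atoms, which is what actually drives the
#'    support to a handful of global tissues;
#' 4. stop when the active support is unchanged and the relative row-weight
#'    change falls below `tol`, or at `max_iter`;
#' 5. prune rows below the support floor, re-solve *unregularized* NNLS per
#'    voxel on the final support in full signal space, and normalize the
#'    per-voxel M0-scale weights to fractions.
#'
#' With `lambda_norm = 0` the solve reduces to independent per-voxel NNLS in
#' full signal space (no reweighting, no pruning).
#'
#' @param series 4D array `(x, y, slice, frame)` or `frames x voxels` matrix.
#' @param dict An `mrf_dictionary` (compression handled internally per
#'   `cfg$rank`).
#' @param b1_map Per-voxel flip-angle efficiency (array or vector); every
#'   value must be one of the dictionary's B1 values. Default: all 1.
#' @param mask Logical array/vector of voxels to decompose; must be
#'   non-empty.
#' @param cfg A [spijn_config()].
#' @return An object of class `mcmrf_solution`: `components` (data frame
#'   `pair`, `t1_ms`, `t2star_ms`, ordered by T1), `fractions` (per-voxel
#'   fractions over components; 4D `(x, y, slice, component)` when the input
#'   was 4D, else `components x voxels`), `raw_weights` (M0-scale weights,
#'   same layout), `excluded` (voxels with all-zero fits), `n_iterations`,
#'   `support_history` (support size per reweighting iteration),
#'   `objective_history` (residual energy plus
#'   `lambda_abs * sum_i log(r_i^2 + eps^2)`, the Lyapunov objective of the
#'   reweighting scheme; non-increasing once the smoothing floor is frozen
#'   after the second iteration), `lambda_abs`, `mask`.
#' @export
spijn_solve <- function(series, dict, b1_map = NULL, mask = NULL,
                        cfg = spijn_config()) {
  stopifnot(inherits(dict, "mrf_dictionary"), inherits(cfg, "spijn_config"))
  as_matrix <- is.matrix(series)
  if (!as_matrix) {
    if (length(dim(series)) == 3L) {
      dim(series) <- c(dim(series)[1:2], 1L, dim(series)[3])
    }
    d <- dim(series)
    X_all <- t(matrix(series, nrow = prod(d[1:3]), ncol = d[4]))
  } else {
    d <- NULL
    X_all <- series
  }
  nv_all <- ncol(X_all)
  if (is.null(mask)) mask <- rep(TRUE, nv_all)
  assert_that(length(mask) == nv_all, "mask size must match the voxel grid")
  vox <- which(as.logical(mask))
  if (length(vox) == 0L) stop_invalid("empty mask: nothing to decompose")
  X <- X_all[, vox, drop = FALSE]
  nf <- nrow(dict$atoms)
  assert_that(nrow(X) == nf, "frame count mismatch between series and dictionary")

  b1 <- if (is.null(b1_map)) rep(1, nv_all) else as.numeric(b1_map)
  assert_that(length(b1) == nv_all, "b1_map size must match the voxel grid")
  b1 <- b1[vox]
  b1_idx <- match_b1(b1, dict$b1_values)

  np <- dict$grid$n_pairs
  V <- ncol(X)
  ## Total in-mask energy over grid size keeps the trade-off invariant to
  ## intensity scale, mask size and grid density; the fixed factor maps the
  ## conventional normalized-lambda scale (where ~11 yields on the order of
  ## ten global components in brain data) onto the absolute penalty.
  lambda_abs <- cfg$lambda_norm * sum(colSums(X^2)) / (5500 * np)

  use_rank <- if (cfg$lambda_norm > 0) cfg$rank else NULL
  if (!is.null(use_rank) && use_rank < nf) {
    if (is.null(dict$projector) || ncol(dict$projector) != use_rank) {
      dict <- compress_dictionary(dict, use_rank)
    }
    A_work <- dict$atoms_c
    Xw <- crossprod(dict$projector, X)
  } else {
    A_work <- dict$atoms
    Xw <- X
  }

  groups <- split(seq_len(V), b1_idx)
  gkeys <- as.integer(names(groups))
  Ag_list <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    cols <- (gkeys[gi] - 1L) * np + seq_len(np)
    Ag_list[[gi]] <- A_work[, cols, drop = FALSE]
  }

  r <- rep(1, np)
  support_history <- integer(0)
  objective_history <- numeric(0)
  prev_supp <- NULL
  supp <- seq_len(np)
  n_iter <- 0L
  last_supports <- vector("list", V)

  if (cfg$lambda_norm > 0) {
    Rres <- lapply(groups, function(gv) Xw[, gv, drop = FALSE])
    ## homotopy over lambda: the reweighting objective is non-convex, and
    ## starting at the target penalty from uniform weights lets near-duplicate
    ## atoms capture mass before the true support can emerge; ramping lambda
    ## geometrically with warm starts follows the residual-dominated solution
    ## into the sparse regime
    lam_seq <- if (cfg$continuation) lambda_abs * 4^c(-3, -2, -1, 0) else lambda_abs
    pen_floor <- 1e-12 * mean(colSums(A_work^2))
    eps2 <- NULL
    for (st in seq_along(lam_seq)) {
      lam <- lam_seq[st]
      final_stage <- st == length(lam_seq)
      iters <- if (final_stage) cfg$max_iter else cfg$stage_iter
      for (it in seq_len(iters)) {
        n_iter <- n_iter + 1L
        if (is.null(eps2) || !final_stage || it <= 2L) {
          eps2 <- (cfg$epsilon_frac * max(r))^2
        }
        pen <- lam / (r^2 + eps2)
        ## absolute floor (1e-12 of the mean squared atom norm): a ridge this
        ## far below the Gram curvature is bias-free, while an unbounded
        ## 1/pen would amplify dual round-off into runaway row norms
        pen <- pmax(pen, pen_floor)
        r2 <- numeric(np)
        data_term <- 0
        for (gi in seq_along(groups)) {
          fit <- tryCatch(
            ridge_nnls_batch(Ag_list[[gi]], Xw[, groups[[gi]], drop = FALSE],
                             pen, R_init = Rres[[gi]]),
            error = function(e) {
              ridge_nnls_batch(Ag_list[[gi]], Xw[, groups[[gi]], drop = FALSE],
                               pen, R_init = Rres[[gi]], safe = TRUE)
            })
          Rres[[gi]] <- fit$R
          r2 <- r2 + rowSums(fit$X^2)
          data_term <- data_term + sum(fit$R^2)   # fit$R is exactly b - A x
          gv <- groups[[gi]]
          for (k in seq_along(gv)) last_supports[[gv[k]]] <- which(fit$X[, k] > 0)
        }
        r_new <- sqrt(r2)
        objective_history <- c(objective_history,
                               data_term + lam * sum(log(r2 + eps2)))
        supp <- which(r_new > cfg$support_floor_frac * max(r_new))
        support_history <- c(support_history, length(supp))
        delta <- max(abs(r_new - r)) / max(r_new, 1e-300)
        same_support <- !is.null(prev_supp) && identical(supp, prev_supp)
        prev_supp <- supp
        r <- r_new
        if (final_stage && same_support && delta < cfg$tol) break
      }
    }
  } else {
    n_iter <- 1L
  }
  if (length(supp) == 0L) stop_invalid("regularization removed every component; lower lambda")

  ## final unregularized re-fit on the pruned support, in full signal space
  b1_groups <- integer(V)
  for (gi in seq_along(groups)) b1_groups[groups[[gi]]] <- gkeys[gi]
  refit <- function(supp_now) {
    W <- matrix(0, length(supp_now), V)
    for (gi in seq_along(groups)) {
      cols <- (gkeys[gi] - 1L) * np + supp_now
      Ag <- dict$atoms[, cols, drop = FALSE]
      G <- crossprod(Ag)
      Fg <- crossprod(Ag, X[, groups[[gi]], drop = FALSE])
      atom_norms <- dict$norms[cols]
      gv <- groups[[gi]]
      if (length(supp_now) <= 45L) {
        W[, gv] <- nnls_gram_batch(G, Fg) / atom_norms
      } else {
        for (k in seq_along(gv)) {
          cc <- fnnls(G, Fg[, k])
          W[, gv[k]] <- cc / atom_norms   # M0-scale magnetization weights
        }
      }
    }
    W
  }
  W <- refit(supp)

  ## local support polishing: nonconvex reweighting can settle one or two
  ## grid steps off along weakly-encoded directions (most visibly the
  ## long-T2* fan); swapping each component with its grid neighbours and
  ## keeping strict residual reductions walks the support to the local
  ## optimum. Residuals are scored on the voxels that actually use the
  ## component, so the step is cheap and targeted.
  if (cfg$lambda_norm > 0 && cfg$polish) {
    for (pass in seq_len(cfg$polish_passes)) {
      changed <- FALSE
      for (ii in seq_along(supp)) {
        tot <- colSums(W)
        fsel <- which(W[ii, ] / pmax(tot, 1e-300) > cfg$polish_fraction)
        if (length(fsel) < 5L) next
        if (length(fsel) > 1000L) {
          fsel <- fsel[round(seq(1, length(fsel), length.out = 1000L))]
        }
        cands <- setdiff(grid_neighbors(dict$grid, supp[ii],
                                        radius = cfg$polish_radius), supp)
        if (!length(cands)) next
        cur <- support_residual(X, dict, b1_groups, fsel, supp)
        best <- cur; best_c <- NA_integer_
        for (cc in cands) {
          alt <- supp; alt[ii] <- cc
          rr <- support_residual(X, dict, b1_groups, fsel, alt)
          if (rr < best * (1 - 1e-10)) { best <- rr; best_c <- cc }
        }
        if (!is.na(best_c)) {
          supp[ii] <- best_c
          W <- refit(supp)
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }

  norm_out <- normalize_fractions(W)
  comp <- data.frame(pair = supp,
                     t1_ms = dict$grid$pairs$t1_ms[supp],
                     t2star_ms = dict$grid$pairs$t2star_ms[supp])
  ord <- order(comp$t1_ms, comp$t2star_ms)
  comp <- comp[ord, , drop = FALSE]
  rownames(comp) <- NULL
  W <- W[ord, , drop = FALSE]
  fr <- norm_out$fractions[ord, , drop = FALSE]

  if (!is.null(d)) {
    nc <- nrow(comp)
    fr4 <- array(0, c(d[1:3], nc))
    rw4 <- array(0, c(d[1:3], nc))
    flat <- matrix(0, nv_all, nc)
    flat[vox, ] <- t(fr)
    fr4[] <- flat
    flat[vox, ] <- t(W)
    rw4[] <- flat
    fractions_out <- fr4
    raw_out <- rw4
    excl <- rep(FALSE, nv_all); excl[vox] <- norm_out$excluded
    excl <- array(excl, d[1:3])
  } else {
    fractions_out <- fr
    raw_out <- W
    excl <- norm_out$excluded
  }
  structure(
    list(components = comp, fractions = fractions_out, raw_weights = raw_out,
         excluded = excl, n_iterations = n_iter,
         support_history = support_history,
         objective_history = objective_history,
         lambda_abs = lambda_abs, mask = mask),
    class = "mcmrf_solution")
}

#' @export
print.mcmrf_solution <- function(x, ...) {
  cat(sprintf("MC-MRF solution: %d components after %d iterations\n",
              nrow(x$components), x$n_iterations))
  print(x$components)
  invisible(x)
}

match_b1 <- function(b1, b1_values, tol = 1e-6) {
  vapply(b1, function(b) {
    j <- which.min(abs(b1_values - b))
    if (abs(b1_values[j] - b) > tol) {
      stop_invalid("b1_map value %g is not on the dictionary B1 grid", b)
    }
    j
  }, integer(1))
}

#' Normalize non-negative magnetization weights to per-voxel fractions
#'
#' Each voxel's weights are divided by their sum so fractions sum to 1.
#' Voxels whose weights are all zero keep all-zero fractions and are flagged
#' as excluded.
#'
#' @param raw_weights Non-negative `components x voxels` matrix (or vector).
#' @return A list: `fractions` (same shape) and `excluded` (logical per
#'   voxel).
#' @export
normalize_fractions <- function(raw_weights) {
  w <- if (is.null(dim(raw_weights))) matrix(raw_weights, ncol = 1) else raw_weights
  if (any(w < 0)) stop_invalid("raw weights must be non-negative")
  tot <- colSums(w)
  excluded <- tot == 0
  fr <- w
  if (any(!excluded)) {
    fr[, !excluded] <- sweep(w[, !excluded, drop = FALSE], 2, tot[!excluded], "/")
  }
  if (is.null(dim(raw_weights))) fr <- drop(fr)
  list(fractions = fr, excluded = excluded)
}
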