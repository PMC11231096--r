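# Parallel-imaging calibration: in-plane GRAPPA, split-slice (leak-block) SMS
# kernels, and the coil-coupling k-space shift operator whose fractional
# powers realise sub-grid translations along the phase-encode axis.
#
# All kernels are trained and applied with circular k-space indexing: the
# k-space of a DFT image is exactly periodic, so no calibration area is lost
# at the edges.

ridge_solve <- function(A, B, lambda) {
  if (nrow(A) < ncol(A))
    stop("underdetermined fit: ", nrow(A), " equations for ", ncol(A),
         " unknowns - use more calibration data or a smaller kernel")
  AtA <- Conj(t(A)) %*% A
  reg <- lambda * Re(sum(diag(AtA))) / ncol(A)
  solve(AtA + diag(reg, ncol(A)), Conj(t(A)) %*% B)
}

# column-stack of circularly shifted copies of a (n, m, C) k-space block:
# out[, (d, c)] holds block[kx + dx[d], row + dy[d], c] as a vector.
shift_columns <- function(block, dx, dy) {
  if (length(dim(block)) == 2L) block <- array(block, c(dim(block), 1L))
  d <- dim(block)
  cols <- vector("list", length(dx) * d[3])
  k <- 1L
  for (i in seq_along(dx)) {
    sh <- roll2(block, -dx[i], -dy[i])
    for (c_ in seq_len(d[3])) {
      cols[[k]] <- as.vector(sh[, , c_])
      k <- k + 1L
    }
  }
  do.call(cbind, cols)
}

#' Train the in-plane GRAPPA kernel
#'
#' Least-squares (Tikhonov-regularised) fit of weights mapping the coil
#' neighbourhood of the two adjacent acquired lines (3 readout taps each) to
#' the missing line, trained over the fully sampled calibration k-space of
#' all slices.
#'
#' @param calib a `calibration_set` or a bare (n, n, C, S) complex array.
#' @param lambda ridge factor, relative to the trace of the normal matrix.
#' @param kx_taps readout taps per source line (odd).
#' @return class `grappa_kernel` with fields `W`, `taps`, `relres`.
#' @export
train_inplane_kernel <- function(calib, lambda = 1e-4, kx_taps = 3) {
  ks <- if (inherits(calib, "calibration_set")) calib$calib else calib
  if (length(dim(ks)) == 3L) ks <- array(ks, c(dim(ks), 1L))
  S <- dim(ks)[4]; C <- dim(ks)[3]
  dxs <- seq_len(kx_taps) - (kx_taps + 1L) %/% 2L
  taps <- expand.grid(dx = dxs, dy = c(-1L, 1L))
  A <- do.call(rbind, lapply(seq_len(S), function(s)
    shift_columns(ks[, , , s, drop = TRUE], taps$dx, taps$dy)))
  B <- do.call(rbind, lapply(seq_len(S), function(s)
    matrix(ks[, , , s], ncol = C)))
  W <- ridge_solve(A, B, lambda)
  structure(list(
    W = W, taps = taps, n_coils = C, lambda = lambda, r_inplane = 2L,
    relres = sqrt(sum(Mod(A %*% W - B)^2) / sum(Mod(B)^2))
  ), class = "grappa_kernel")
}

#' Fill missing phase-encode lines with a trained GRAPPA kernel
#'
#' @param ks acquired k-space (n, n_lines, C).
#' @param kernel a `grappa_kernel`.
#' @param ky_idx 1-based full-grid row indices of the acquired lines.
#' @param n full grid size.
#' @return complete k-space (n, n, C); acquired lines are untouched.
#' @export
inplane_fill <- function(ks, kernel, ky_idx, n) {
  d <- dim(ks); C <- d[3]
  if (C != kernel$n_coils) stop("coil count does not match the kernel")
  full <- array(0i, c(n, n, C))
  full[, ky_idx, ] <- ks
  missing_idx <- setdiff(seq_len(n), ky_idx)
  if (!length(missing_idx)) return(full)
  if (!all((1L + (missing_idx - 1L - 1L) %% n) %in% ky_idx))
    stop("acquired-line pattern does not match the kernel geometry")
  Acols <- shift_columns(full, kernel$taps$dx, kernel$taps$dy)
  sel <- as.vector(outer(seq_len(n), (missing_idx - 1L) * n, `+`))
  pred <- Acols[sel, , drop = FALSE] %*% kernel$W
  for (c_ in seq_len(C))
    full[, missing_idx, c_] <- matrix(pred[, c_], n, length(missing_idx))
  full
}

#' Train split-slice SMS unaliasing kernels
#'
#' One kernel per constituent slice of each SMS group, mapping the collapsed
#' CAIPI-encoded undersampled k-space to that slice. The split-slice
#' (leak-block) objective fits each kernel to reproduce its own slice when
#' fed that slice's (synthetically collapsed) calibration data and to return
#' zero when fed the other slice's, which directly penalises inter-slice
#' leakage. Plain slice-GRAPPA is available with `split = FALSE`.
#'
#' @param calib a `calibration_set` or (n, n, C, S) array.
#' @param protocol the acquisition protocol (slice grouping, CAIPI, R).
#' @param lambda ridge factor.
#' @param taps readout/phase taps per source (odd), default 3 x 3.
#' @param split use the leak-block objective (default TRUE).
#' @return class `slice_kernels`.
#' @export
train_slice_kernels <- function(calib, protocol, lambda = 1e-4, taps = 3,
                                split = TRUE) {
  ks <- if (inherits(calib, "calibration_set")) calib$calib else calib
  if (protocol$mb == 1L) {
    return(structure(list(mb = 1L), class = "slice_kernels"))
  }
  C <- dim(ks)[3]
  n <- protocol$n
  cp <- caipi_phase(protocol)
  dxs <- seq_len(taps) - (taps + 1L) %/% 2L
  tg <- expand.grid(dx = dxs, dy = dxs)   # dy in acquired-row lattice units

  groups <- lapply(seq_len(n_groups(protocol)), function(g) {
    sl <- slice_group(protocol, g)
    D1 <- ks[, protocol$ky_idx, , sl[1], drop = TRUE]
    D2 <- ks[, protocol$ky_idx, , sl[2], drop = TRUE] * rep(cp, each = n)
    A1 <- shift_columns(D1, tg$dx, tg$dy)
    A2 <- shift_columns(D2, tg$dx, tg$dy)
    B1 <- matrix(D1, ncol = C)
    B2 <- matrix(D2, ncol = C)
    Z <- matrix(0i, nrow(B1), C)
    if (split) {
      A <- rbind(A1, A2)
      W1 <- ridge_solve(A, rbind(B1, Z), lambda)
      W2 <- ridge_solve(A, rbind(Z, B2), lambda)
    } else {
      A <- A1 + A2
      W1 <- ridge_solve(A, B1, lambda)
      W2 <- ridge_solve(A, B2, lambda)
    }
    leak <- c(
      sqrt(sum(Mod(A2 %*% W1)^2) / sum(Mod(A1 %*% W1)^2)),
      sqrt(sum(Mod(A1 %*% W2)^2) / sum(Mod(A2 %*% W2)^2)))
    list(W = list(W1, W2), leak = leak, slices = sl)
  })

  structure(list(
    mb = protocol$mb, groups = groups, taps = tg, caipi = protocol$caipi,
    lambda = lambda, split = split, n_coils = C
  ), class = "slice_kernels")
}

#' Separate a collapsed SMS frame into its constituent slices
#'
#' Applies the per-slice kernels and removes the CAIPI phase, returning one
#' undersampled k-space per constituent slice.
#'
#' @param data collapsed k-space (n, n_lines, C).
#' @param kernels a `slice_kernels`.
#' @param protocol the acquisition protocol.
#' @param group slice-group index.
#' @return array (n, n_lines, C, mb).
#' @export
sms_unalias <- function(data, kernels, protocol, group = 1L) {
  if (kernels$mb == 1L) {
    return(array(data, c(dim(data), 1L)))
  }
  if (dim(data)[3] != kernels$n_coils)
    stop("coil geometry does not match the slice kernels")
  n <- dim(data)[1]; C <- dim(data)[3]; L <- dim(data)[2]
  A <- shift_columns(data, kernels$taps$dx, kernels$taps$dy)
  gk <- kernels$groups[[group]]
  out <- array(0i, c(n, L, C, kernels$mb))
  cp <- caipi_phase(protocol)
  for (s in seq_len(kernels$mb)) {
    pred <- A %*% gk$W[[s]]
    block <- array(pred, c(n, L, C))
    if (s == 2L) block <- block * rep(Conj(cp), each = n)
    out[, , , s] <- block
  }
  out
}

#' Train the coil-coupling k-space shift operator
#'
#' Fits the GRAPPA-operator weights that advance multi-coil k-space data by
#' one phase-encode step, using all adjacent line pairs of the per-slice
#' calibration data (slices stacked, so the operator shifts any linear
#' combination of the slices consistently). The operator lives in hybrid
#' (x, ky) space, where it reduces to one C x C coil-coupling matrix per
#' readout position; the eigendecomposition of each matrix is cached for
#' fractional powers.
#'
#' With `width = NULL` (default) each readout position gets its own
#' unconstrained ridge fit (full readout resolution). An integer `width`
#' instead fits `width` readout taps in k-space (the classical C x C*w
#' GRAPPA-operator parameterisation) and transforms them to hybrid space;
#' both share the same application and fractional-power machinery.
#'
#' @param calib a `calibration_set` or (n, n, C, S) complex array.
#' @param axis "ky" (phase-encode, default) or "kx".
#' @param width readout taps (odd integer), or NULL for the per-position fit.
#' @param lambda ridge factor, relative to the trace of the normal matrix.
#' @param lam_floor eigenvalue-magnitude floor (see Details in the source):
#'   bounds the gain of negative fractional powers at `lam_floor^-1.5`.
#' @return class `shift_operator` with cached eigendecompositions and the
#'   training residual `relres`.
#' @export
train_shift_operator <- function(calib, axis = c("ky", "kx"), width = NULL,
                                 lambda = 5e-4, lam_floor = 0.25) {
  axis <- match.arg(axis)
  ks <- if (inherits(calib, "calibration_set")) calib$calib else calib
  if (length(dim(ks)) == 3L) ks <- array(ks, c(dim(ks), 1L))
  if (axis == "kx") ks <- aperm(ks, c(2, 1, 3, 4))
  S <- dim(ks)[4]; C <- dim(ks)[3]; n <- dim(ks)[1]

  M <- array(0i, c(C, C, n))
  V <- array(0i, c(C, C, n)); Vi <- array(0i, c(C, C, n))
  lam <- matrix(0i, C, n)
  x <- fov_grid(n)

  if (is.null(width)) {
    # hybrid-space fit: per readout position, predict line ky+1 from line ky
    P <- array(0i, c(n, n, C, S))
    for (s in seq_len(S)) P[, , , s] <- ifft1c(ks[, , , s, drop = TRUE])
    # energy per readout position; positions with (near-)zero signal get the
    # identity (there is nothing to shift there, and a free fit would be
    # singular)
    ex <- apply(Mod(P)^2, 1, sum)
    # readout positions carrying (almost) no object signal get the identity:
    # there is nothing to shift there and an unconstrained fit is singular
    ex_floor <- 1e-5 * max(ex)
    num <- 0; den <- 0
    for (i in seq_len(n)) {
      if (ex[i] <= ex_floor) {
        M[, , i] <- diag(C); V[, , i] <- diag(C); Vi[, , i] <- diag(C)
        lam[, i] <- rep(1 + 0i, C)
        next
      }
      X1 <- do.call(rbind, lapply(seq_len(S), function(s)
        matrix(P[i, , , s], ncol = C)))
      X2 <- do.call(rbind, lapply(seq_len(S), function(s)
        matrix(P[i, c(2:n, 1L), , s], ncol = C)))
      G <- Conj(t(X1)) %*% X1
      reg <- lambda * Re(sum(diag(G))) / C
      Mx <- t(solve(G + diag(reg, C), Conj(t(X1)) %*% X2))
      eg <- eigen(Mx)
      M[, , i] <- Mx
      V[, , i] <- eg$vectors
      Vi[, , i] <- solve(eg$vectors)
      lam[, i] <- eg$values
      num <- num + sum(Mod(X1 %*% t(Mx) - X2)^2)
      den <- den + sum(Mod(X2)^2)
    }
    relres <- sqrt(num / den)
    W <- NULL; dxs <- integer(0)
  } else {
    dxs <- seq_len(width) - (width + 1L) %/% 2L
    A <- do.call(rbind, lapply(seq_len(S), function(s)
      shift_columns(ks[, , , s, drop = TRUE], dxs, rep(0L, width))))
    B <- do.call(rbind, lapply(seq_len(S), function(s)
      matrix(roll2(ks[, , , s, drop = TRUE], 0L, -1L), ncol = C)))
    W <- tryCatch(ridge_solve(A, B, lambda), error = function(e)
      stop("shift-operator fit failed along axis ", axis, ": ",
           conditionMessage(e)))
    relres <- sqrt(sum(Mod(A %*% W - B)^2) / sum(Mod(B)^2))
    # hybrid-space representation: M_x = t(sum_d W_d exp(-2i pi d x))
    for (i in seq_len(n)) {
      Wx <- matrix(0i, C, C)
      for (d in seq_along(dxs)) {
        blk <- W[((d - 1L) * C + 1L):(d * C), , drop = FALSE]
        Wx <- Wx + blk * exp(-2i * pi * dxs[d] * x[i])
      }
      Mx <- t(Wx)
      eg <- eigen(Mx)
      M[, , i] <- Mx
      V[, , i] <- eg$vectors
      Vi[, , i] <- solve(eg$vectors)
      lam[, i] <- eg$values
    }
  }
  # Eigenvalue-magnitude floor: the ridge fit annihilates coil directions the
  # calibration cannot predict, but a fractional shift must stay invertible
  # with bounded gain (|lambda|^-delta would explode for negative shifts).
  # Magnitudes are floored once here (phases kept) and the operator matrices
  # are rebuilt from the floored spectrum, so the exact power semigroup is
  # preserved and the gain of any |delta| <= 1.5 power is at most
  # lam_floor^-1.5. The floor only touches directions the fit had (nearly)
  # suppressed, so the one-step prediction residual is essentially unchanged.
  mag <- Mod(lam)
  n_floored <- sum(mag < lam_floor)
  if (n_floored > 0) {
    ph_l <- lam / ifelse(mag == 0, 1, mag)
    ph_l[mag == 0] <- 1 + 0i
    lam <- ph_l * pmax(mag, lam_floor)
    for (i in seq_len(n)) {
      M[, , i] <- V[, , i] %*% (lam[, i] * Vi[, , i])
    }
  }

  structure(list(
    axis = axis, width = width, lambda = lambda, n = n, n_coils = C,
    W = W, taps = dxs, M = M, V = V, Vi = Vi, lam = lam, relres = relres,
    n_floored = n_floored
  ), class = "shift_operator")
}

# principal-branch eigenvalue power
# principal-branch eigenvalue power
lam_pow <- function(lam, delta) {
  exp(delta * (log(Mod(lam)) + 1i * Arg(lam)))
}

#' Fractional power of a shift operator
#'
#' Realises a sub-grid k-space translation: `W^delta = V diag(lambda^delta)
#' V^-1` per readout position, with the principal branch of the eigenvalue
#' logarithm. Valid for `|delta| <= 1.5`.
#'
#' @param op a `shift_operator`.
#' @param delta shift in grid units.
#' @return class `shift_matrix`: per-readout-position C x C matrices.
#' @export
fractional_shift <- function(op, delta) {
  if (abs(delta) > 1.5)
    stop("|delta| beyond the operator's validity range (1.5 grid units)")
  if (any(Mod(op$lam) < 1e-8))
    stop("shift operator has near-zero eigenvalues; ",
         "retrain with a larger lambda")
  C <- op$n_coils
  mats <- array(0i, c(C, C, op$n))
  for (i in seq_len(op$n)) {
    lp <- lam_pow(op$lam[, i], delta)
    mats[, , i] <- op$V[, , i] %*% (lp * op$Vi[, , i])
  }
  structure(list(mats = mats, delta = delta, axis = op$axis, n = op$n),
            class = "shift_matrix")
}

#' Apply a (possibly fractional) k-space shift to a set of lines
#'
#' `delta = 1` advances each line's content by one phase-encode step
#' (the line then holds the data of `ky + 1`); fractional `delta`
#' interpolates via the cached eigendecomposition.
#'
#' @param op a `shift_operator`.
#' @param lines k-space lines (n, L, C) along the operator's orthogonal axis.
#' @param delta shift in grid units.
#' @return shifted lines, same shape.
#' @export
apply_shift_operator <- function(op, lines, delta) {
  if (delta == 0) return(lines)
  sm <- fractional_shift(op, delta)
  P <- ifft1c(lines)
  out <- array(0i, dim(P))
  for (i in seq_len(op$n)) {
    px <- matrix(P[i, , ], nrow = dim(P)[2])      # (L, C)
    out[i, , ] <- px %*% t(sm$mats[, , i])
  }
  fft1c(out)
}

# Cache for repeated shift evaluations against a fixed reference projection
# (used by the 1-D dky search). Precomputes, per readout position x, the
# matrix VC_x[i, j] = V_x[i, j] * (Vi_x p_x)[j], so that
# (W^delta p)_x = VC_x %*% lam_x^delta becomes one batched elementwise
# multiply across all x.
shift_search_cache <- function(op, ref_proj) {
  C <- op$n_coils; n <- op$n
  VC <- matrix(0i, n * C, C)
  for (i in seq_len(n)) {
    cx <- op$Vi[, , i] %*% ref_proj[i, ]
    VC[((i - 1) * C + 1):(i * C), ] <- op$V[, , i] * rep(cx, each = C)
  }
  list(VC = VC, n = n, C = C,
       lam_log = log(Mod(op$lam)) + 1i * Arg(op$lam),
       xrep = rep(seq_len(n), each = C))
}

# W^delta applied to a projection-space line set (n, C)
shift_projection <- function(op, proj, delta) {
  out <- array(0i, dim(proj))
  for (i in seq_len(op$n)) {
    lp <- lam_pow(op$lam[, i], delta)
    out[i, ] <- op$V[, , i] %*% (lp * (op$Vi[, , i] %*% proj[i, ]))
  }
  out
}

# || W^delta ref - target ||^2 / || target ||^2 in projection space.
# `target` is the (n, C) projection of the current frame's navigators.
shift_objective <- function(op, cache, target, delta) {
  lamd <- exp(delta * cache$lam_log)                     # (C x n)
  pred <- rowSums(cache$VC * t(lamd)[cache$xrep, , drop = FALSE])
  tv <- as.vector(t(target))
  sum(Mod(pred - tv)^2) / sum(Mod(tv)^2)
}
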