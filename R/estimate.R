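# Per-frame off-resonance estimation from the EPI navigators.
#
# Estimation order (each step conditions the next): Nyquist ghost parameters
# from the navigator polarity pairs; zeroth-order phase phi0 and readout
# translation dkx from the projection-space phase against the reference
# navigator; phase-encode translation dky by a 1-D search over fractional
# powers of the ky shift operator.

#' Nyquist ghost parameters from navigator lines
#'
#' Transforms the navigator lines to projection space and fits the
#' magnitude-weighted linear phase of odd x conj(even) line pairs; the
#' even/odd lines are modelled as carrying `+/-(theta0 + theta1 * s)/2` with
#' `s` the centred readout sample index.
#'
#' @param nav navigator lines (n, L >= 2, C).
#' @param polarity readout polarity of each line (+1 / -1).
#' @return list with `theta0` (rad) and `theta1` (rad/sample).
#' @export
ghost_params_from_nav <- function(nav, polarity = c(1, -1, 1)) {
  P <- ifft1c(nav)
  n <- dim(P)[1]; L <- dim(P)[2]
  if (sum(Mod(P)) < 1e-12) stop("all-zero navigator")
  if (L < 2 || length(unique(polarity[seq_len(L)])) < 2)
    stop("need at least two navigator lines of opposite polarity")
  s <- k_grid(n)
  q <- rep(0i, n)
  for (l in seq_len(L - 1)) {
    if (polarity[l] == polarity[l + 1]) next
    a <- if (polarity[l] < 0) P[, l, ] else P[, l + 1, ]   # odd (-) line
    b <- if (polarity[l] < 0) P[, l + 1, ] else P[, l, ]   # even (+) line
    q <- q + rowSums(a * Conj(b))
  }
  fit <- fit_linear_phase(q, s)
  list(theta0 = -fit[["a"]], theta1 = -fit[["b"]])
}

#' Nyquist ghost correction
#'
#' Counter-rotates even/odd readout lines by `-/+(theta0 + theta1*s)/2` in
#' projection space. Applying the correction twice with `theta` and `-theta`
#' is the identity.
#'
#' @param frame a `kspace_frame` (data and navigators are both corrected), or
#'   a bare (n, L, C) line array if `polarity` is given.
#' @param ghost list with `theta0`, `theta1` (see [ghost_params_from_nav()]).
#' @param polarity per-line polarity when `frame` is a bare array.
#' @return corrected frame (or line array).
#' @export
nyquist_correct <- function(frame, ghost, polarity = NULL) {
  correct_lines <- function(lines, pol) {
    n <- dim(lines)[1]
    s <- k_grid(n)
    P <- ifft1c(lines)
    ph <- exp(-0.5i * outer(ghost$theta0 + ghost$theta1 * s, pol))
    fft1c(P * as.vector(ph))
  }
  if (inherits(frame, "kspace_frame")) {
    frame$data <- correct_lines(frame$data, frame$polarity)
    frame$nav <- correct_lines(frame$nav, frame$nav_polarity)
    frame
  } else {
    if (is.null(polarity)) stop("polarity required for bare line arrays")
    correct_lines(frame, polarity)
  }
}

# ghost-corrected mean navigator projection: (n, C)
mean_nav_projection <- function(nav, polarity, ghost = NULL) {
  P <- ifft1c(nav)
  n <- dim(P)[1]
  if (!is.null(ghost)) {
    s <- k_grid(n)
    ph <- exp(-0.5i * outer(ghost$theta0 + ghost$theta1 * s, polarity))
    P <- P * as.vector(ph)
  }
  apply(P, c(1, 3), mean)
}

#' Zeroth-order phase and readout translation from navigator projections
#'
#' Magnitude-weighted least-squares fit of
#' `angle(P_t * conj(P_ref)) = phi0 + 2*pi*dkx*x` over the object support,
#' with `x` in FOV units.
#'
#' @param nav_t,nav_ref ghost-corrected mean navigator projections (n, C).
#' @return numeric `c(phi0, dkx)` (radians, grid units).
#' @export
estimate_phi0_dkx <- function(nav_t, nav_ref) {
  n <- nrow(nav_ref)
  if (sqrt(mean(Mod(nav_ref)^2)) < 1e-12)
    stop("reference navigator has no signal support")
  q <- rowSums(nav_t * Conj(nav_ref))
  fit <- fit_linear_phase(q, fov_grid(n))
  c(phi0 = unname(fit[["a"]]), dkx = unname(fit[["b"]]) / (2 * pi))
}

golden_section <- function(f, lo, hi, tol) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c_ <- b - gr * (b - a); d_ <- a + gr * (b - a)
  fc <- f(c_); fd <- f(d_)
  while (abs(b - a) > tol) {
    if (fc < fd) { b <- d_; d_ <- c_; fd <- fc
      c_ <- b - gr * (b - a); fc <- f(c_)
    } else { a <- c_; c_ <- d_; fc <- fd
      d_ <- a + gr * (b - a); fd <- f(d_)
    }
  }
  if (fc < fd) c_ else d_
}

#' Phase-encode translation from navigators via the shift operator
#'
#' Finds `delta` minimising `||W^delta nav_ref - nav_t||^2 / ||nav_t||^2`
#' by a coarse grid scan followed by golden-section refinement; the data
#' translation estimate is `dky = -argmin`. The search is significance-gated:
#' when the best objective does not improve on `delta = 0` by more than 1%
#' (relative), the estimate snaps to zero, so identical navigators give an
#' exact zero.
#'
#' @param nav_t projection of the current frame's navigators, with phi0/dkx
#'   effects already removed (n, C).
#' @param nav_ref reference navigator projection (n, C).
#' @param op the ky [shift_operator][train_shift_operator()].
#' @param bound search bound (grid units).
#' @param tol golden-section tolerance (grid units).
#' @param step coarse-grid step (grid units).
#' @return `dky` (grid units) with attributes `objective` and
#'   `warn_multimodal`.
#' @export
estimate_dky <- function(nav_t, nav_ref, op, bound = 0.75, tol = 0.005,
                         step = 0.05) {
  cache <- shift_search_cache(op, nav_ref)
  f <- function(d) shift_objective(op, cache, nav_t, d)
  grid <- seq(-bound, bound, by = step)
  vals <- vapply(grid, f, numeric(1))
  i0 <- which.min(vals)
  # multimodality diagnostic: separated local minima within 1% of the best
  loc <- which(diff(sign(diff(vals))) > 0) + 1L
  warn <- sum(vals[loc] <= min(vals) * 1.01 + 1e-15) > 1
  lo <- grid[max(1L, i0 - 1L)]; hi <- grid[min(length(grid), i0 + 1L)]
  d_hat <- golden_section(f, lo, hi, tol)
  o_min <- f(d_hat)
  o_zero <- f(0)
  if (o_zero <= 1e-15 || (o_zero - o_min) < 0.01 * o_zero) {
    d_hat <- 0; o_min <- o_zero
  }
  structure(-d_hat, objective = o_min, warn_multimodal = warn)
}

#' Full (phi0, dkx, dky) estimate from one frame's navigator projection
#'
#' Chains [estimate_phi0_dkx()] and [estimate_dky()], then refits phi0/dkx
#' against the dky-shifted reference: the phase-encode translation moves the
#' object's intrinsic k-space phase into the navigator comparison (a bias of
#' about `2*pi*y_centroid*dky` radians on phi0), which the refinement pass
#' removes.
#'
#' @param nav_t ghost-corrected mean navigator projection of the frame (n, C).
#' @param nav_ref reference navigator projection (n, C).
#' @param op the ky shift operator.
#' @param bound,tol,step see [estimate_dky()].
#' @return list: phi0, dkx, dky, objective, warn_multimodal.
#' @export
estimate_frame_perturbation <- function(nav_t, nav_ref, op, bound = 0.75,
                                        tol = 0.005, step = 0.05) {
  x <- fov_grid(nrow(nav_ref))
  pd <- estimate_phi0_dkx(nav_t, nav_ref)
  Pt2 <- nav_t * exp(-1i * pd[["phi0"]] - 2i * pi * pd[["dkx"]] * x)
  dky <- estimate_dky(Pt2, nav_ref, op, bound = bound, tol = tol, step = step)
  if (as.numeric(dky) != 0) {
    ref2 <- shift_projection(op, nav_ref, -as.numeric(dky))
    pd <- estimate_phi0_dkx(nav_t, ref2)
  }
  list(phi0 = unname(pd[["phi0"]]), dkx = unname(pd[["dkx"]]),
       dky = as.numeric(dky), objective = attr(dky, "objective"),
       warn_multimodal = attr(dky, "warn_multimodal"))
}

#' Apply an off-resonance correction to a frame
#'
#' Removes the global phase `exp(-i*phi0)`, the readout translation `dkx`
#' (exactly, via a projection-space linear phase; the readout is fully
#' sampled) and the phase-encode translation `dky` (via the fractional shift
#' operator applied to every acquired line). Navigators are corrected
#' identically and the applied estimate is recorded on the frame.
#'
#' @param frame a `kspace_frame`.
#' @param est list/row with `phi0`, `dkx`, `dky` (the estimated data
#'   translation; the operator power `+dky` undoes it).
#' @param op_ky the ky shift operator (needed when `dky != 0`).
#' @return corrected `kspace_frame`.
#' @export
correct_frame <- function(frame, est, op_ky = NULL) {
  phi0 <- est$phi0; dkx <- est$dkx; dky <- est$dky
  if (!all(is.finite(c(phi0, dkx, dky)))) stop("non-finite estimate")
  fix_lines <- function(lines) {
    if (dkx != 0) {
      n <- dim(lines)[1]
      ph <- exp(-1i * phi0 - 2i * pi * dkx * fov_grid(n))
      lines <- fft1c(ifft1c(lines) * as.vector(ph))
    } else {
      lines <- lines * exp(-1i * phi0)
    }
    if (dky != 0) {
      if (is.null(op_ky)) stop("dky correction requires the ky shift operator")
      lines <- apply_shift_operator(op_ky, lines, dky)
    }
    lines
  }
  frame$data <- fix_lines(frame$data)
  frame$nav <- fix_lines(frame$nav)
  frame$correction <- list(phi0 = phi0, dkx = dkx, dky = dky)
  frame
}

#' Estimate the per-frame perturbations of a session
#'
#' Uses frame 1's navigators (zero-field by construction) as the reference
#' (or the calibration navigators with `reference = "calibration"`), and
#' returns the ghost parameters and (phi0, dkx, dky) estimates for every
#' frame and slice group.
#'
#' @param session an `sms_session`.
#' @param operators a [train_recon_operators()] bundle (or a bare ky
#'   `shift_operator`).
#' @param reference "frame1" or "calibration".
#' @param bound,tol,step search parameters for [estimate_dky()].
#' @return tibble: frame, group, theta0, theta1, phi0, dkx, dky, objective.
#' @export
estimate_session <- function(session, operators,
                             reference = c("frame1", "calibration"),
                             bound = 0.75, tol = 0.005, step = 0.05) {
  reference <- match.arg(reference)
  op <- if (inherits(operators, "shift_operator")) operators else
    operators$shift_ky
  protocol <- session$protocol
  ngr <- n_groups(protocol)

  refs <- lapply(seq_len(ngr), function(g) {
    nav <- if (reference == "frame1") session$frames[[1]][[g]]$nav else
      session$calibration$nav_ref[[g]]
    gh <- ghost_params_from_nav(nav, protocol$nav_polarity)
    mean_nav_projection(nav, protocol$nav_polarity, gh)
  })

  rows <- vector("list", session$n_frames * ngr)
  k <- 1L
  for (t in seq_len(session$n_frames)) {
    for (g in seq_len(ngr)) {
      fr <- session$frames[[t]][[g]]
      gh <- ghost_params_from_nav(fr$nav, fr$nav_polarity)
      Pt <- mean_nav_projection(fr$nav, fr$nav_polarity, gh)
      est <- estimate_frame_perturbation(Pt, refs[[g]], op, bound = bound,
                                         tol = tol, step = step)
      rows[[k]] <- tibble::tibble(
        frame = t, group = g, theta0 = gh$theta0, theta1 = gh$theta1,
        phi0 = est$phi0, dkx = est$dkx, dky = est$dky,
        objective = est$objective,
        warn_multimodal = est$warn_multimodal)
      k <- k + 1L
    }
  }
  est <- dplyr::bind_rows(rows)
  class(est) <- c("perturbation_estimates", class(est))
  est
}

#' Write per-frame estimates as CSV
#' @param estimates output of [estimate_session()].
#' @param path file path.
#' @export
write_estimates <- function(estimates, path) {
  utils::write.csv(as.data.frame(estimates), path, row.names = FALSE)
  invisible(path)
}
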