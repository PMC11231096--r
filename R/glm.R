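# First-level GLM on reconstructed series, cluster thresholding, a simple
# second level across sessions (one-sample t), and split-half reliability.
#
# Model: BOLD = b0 + b1*offer + b2*action_onset + b3*motor_response +
# b4*outcome, each task regressor a 0.1 s unit boxcar at its event onsets
# convolved with the HRF. offer is locked to trial onset, action_onset and
# motor_response to the go-cue (motor_response only on responded trials,
# making it the binary response-vs-no-response contrast), outcome to reward
# delivery.

#' Build the task design matrix
#'
#' @param events an `event_list`.
#' @param n_frames number of frames T.
#' @param tr repetition time (s).
#' @param hrf HRF parameters ([hrf_params()]).
#' @param dur boxcar duration (s).
#' @return T x 5 design matrix with columns intercept, offer, action_onset,
#'   motor_response, outcome; HRF/TR stored as attributes.
#' @export
build_design <- function(events, n_frames, tr, hrf = hrf_params(),
                         dur = 0.1) {
  t_end <- n_frames * tr
  all_on <- c(events$offer_onset, events$gocue_onset,
              events$outcome_onset[events$responded])
  if (any(all_on > t_end, na.rm = TRUE))
    warning("events beyond the scan end were truncated")
  cols <- cbind(
    intercept = rep(1, n_frames),
    offer = regressor_timecourse(events$offer_onset, n_frames, tr, hrf, dur),
    action_onset = regressor_timecourse(events$gocue_onset, n_frames, tr,
                                        hrf, dur),
    motor_response = regressor_timecourse(
      events$gocue_onset[events$responded], n_frames, tr, hrf, dur),
    outcome = regressor_timecourse(
      events$outcome_onset[events$responded], n_frames, tr, hrf, dur))
  attr(cols, "tr") <- tr
  attr(cols, "hrf") <- hrf
  cols
}

#' Write a design matrix as TSV
#' @param design output of [build_design()].
#' @param path file path.
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Temporal high-pass filtering and in-plane spatial smoothing
#'
#' High-pass: projection onto a discrete-cosine basis (all DCT regressors
#' slower than the cutoff are removed, the temporal mean is kept). Smoothing:
#' Gaussian in-plane (2-D per slice; with only a handful of simulated slices,
#' through-slice smoothing is deliberately omitted), FWHM given in mm and
#' converted through the voxel size.
#'
#' @param series a `recon_series`.
#' @param highpass_s high-pass cutoff period (s); must exceed `2 * TR`.
#' @param fwhm_mm smoothing kernel FWHM (mm); 0 disables smoothing.
#' @return filtered `recon_series`.
#' @export
preprocess_series <- function(series, highpass_s = 100, fwhm_mm = 3) {
  stopifnot(inherits(series, "recon_series"))
  tr <- series$tr
  if (highpass_s <= 2 * tr)
    stop("high-pass cutoff must exceed 2 * TR")
  arr <- series$data
  d <- dim(arr)
  n_frames <- d[4]

  # DCT high-pass
  K <- floor(2 * n_frames * tr / highpass_s)
  if (K >= 1) {
    t_idx <- seq_len(n_frames) - 0.5
    B <- sapply(seq_len(K), function(k)
      cos(pi * k * t_idx / n_frames))
    B <- qr.Q(qr(cbind(1, B)))      # orthonormal basis incl. mean
    Y <- matrix(arr, nrow = prod(d[1:3]))
    mu <- Y %*% B[, 1, drop = FALSE] %*% t(B[, 1, drop = FALSE])
    drift <- Y %*% B[, -1, drop = FALSE] %*% t(B[, -1, drop = FALSE])
    Y <- Y - drift
    arr <- array(Y, d)
  }

  if (fwhm_mm > 0) {
    sig_px <- fwhm_mm / series$voxel_mm / (2 * sqrt(2 * log(2)))
    n <- d[1]
    # exact Gaussian transfer function (continuous-equivalent smoothing)
    f1 <- c(0:(n / 2), (-n / 2 + 1):(-1)) / n
    otf <- exp(-2 * pi^2 * sig_px^2 * outer(f1^2, f1^2, `+`))
    for (s in seq_len(d[3])) for (t in seq_len(n_frames)) {
      arr[, , s, t] <- Re(stats::fft(stats::fft(arr[, , s, t]) * otf,
                                     inverse = TRUE)) / (n * n)
    }
  }
  series$data <- arr
  series$provenance$preprocessed <- list(highpass_s = highpass_s,
                                         fwhm_mm = fwhm_mm)
  series
}

# stable t -> z transform via log tail probabilities
z_from_t <- function(t, df, cap = 40) {
  lp <- stats::pt(abs(t), df, lower.tail = FALSE, log.p = TRUE)
  z <- -stats::qnorm(lp, log.p = TRUE)
  z <- pmin(z, cap)
  sign(t) * z
}

#' Fit the voxelwise GLM with AR(1) prewhitening
#'
#' Ordinary least squares first, a per-voxel AR(1) coefficient from the OLS
#' residuals, then a Cochrane-Orcutt refit (first observation dropped):
#' both data and design are whitened per voxel and the model refit; z-scores
#' are the whitened t-statistics mapped through the t-to-z transform.
#' Regressors are entered as built - no orthogonalisation is applied.
#'
#' @param series a `recon_series`, or a T x V data matrix.
#' @param design design matrix from [build_design()].
#' @param mask logical 3-D mask of voxels to fit (required for arrays;
#'   defaults to mean-intensity support).
#' @return class `glm_fit`: per-voxel `beta`, `se`, `z` (V x p), AR(1)
#'   map `rho`, residual dof, mask and dims for map reshaping.
#' @export
fit_glm <- function(series, design, mask = NULL) {
  X <- unclass(design)
  p <- ncol(X)
  if (qr(X)$rank < p) {
    cc <- colnames(X)[which(abs(stats::cor(X[, -1])) > 0.999, arr.ind = TRUE)]
    stop("rank-deficient design matrix (collinear columns: ",
         paste(unique(cc), collapse = ", "), ")")
  }
  if (inherits(series, "recon_series") ||
      (is.array(series) && length(dim(series)) == 4L)) {
    arr <- if (inherits(series, "recon_series")) series$data else series
    d <- dim(arr)
    if (is.null(mask)) {
      m <- apply(arr, 1:3, mean)
      mask <- m > 0.1 * max(m)
    }
    Y <- t(matrix(arr, nrow = prod(d[1:3]))[as.vector(mask), , drop = FALSE])
    dims <- d[1:3]
  } else {
    Y <- series
    dims <- NULL
    mask <- NULL
  }
  n_frames <- nrow(Y)
  if (n_frames <= p + 10) stop("too few frames for the design")
  V <- ncol(Y)

  # OLS pass
  XtXi <- solve(crossprod(X))
  beta0 <- XtXi %*% crossprod(X, Y)
  E <- Y - X %*% beta0
  rho <- colSums(E[-1, , drop = FALSE] * E[-n_frames, , drop = FALSE]) /
    pmax(colSums(E^2), .Machine$double.eps)

  # Cochrane-Orcutt refit via per-voxel whitened cross-products
  X1 <- X[-n_frames, , drop = FALSE]; X2 <- X[-1, , drop = FALSE]
  Y1 <- Y[-n_frames, , drop = FALSE]; Y2 <- Y[-1, , drop = FALSE]
  A2 <- crossprod(X2); A1 <- crossprod(X1); B <- crossprod(X2, X1)
  C2 <- crossprod(X2, Y2); C21 <- crossprod(X2, Y1)
  C12 <- crossprod(X1, Y2); C1 <- crossprod(X1, Y1)
  y22 <- colSums(Y2^2); y12 <- colSums(Y1 * Y2); y11 <- colSums(Y1^2)

  df <- (n_frames - 1) - p
  beta <- se <- zs <- matrix(NA_real_, V, p)
  for (v in seq_len(V)) {
    r <- rho[v]
    XtX <- A2 - r * (B + t(B)) + r^2 * A1
    Xty <- C2[, v] - r * (C21[, v] + C12[, v]) + r^2 * C1[, v]
    yty <- y22[v] - 2 * r * y12[v] + r^2 * y11[v]
    XtXi_v <- solve(XtX)
    b <- XtXi_v %*% Xty
    rss <- max(yty - 2 * sum(b * Xty) + sum(b * (XtX %*% b)), 0)
    s2 <- rss / df
    beta[v, ] <- b
    se[v, ] <- sqrt(pmax(s2 * diag(XtXi_v), .Machine$double.eps))
    zs[v, ] <- z_from_t(beta[v, ] / se[v, ], df)
  }
  colnames(beta) <- colnames(se) <- colnames(zs) <- colnames(X)

  structure(list(beta = beta, se = se, z = zs, rho = rho, df = df,
                 mask = mask, dims = dims, regressors = colnames(X)),
            class = "glm_fit")
}

#' Extract a 3-D statistic map from a fitted GLM
#'
#' @param fit a `glm_fit` from a 4-D series.
#' @param stat "z", "beta" or "se".
#' @param regressor column name (e.g. "offer").
#' @return 3-D array (0 outside the fitted mask).
#' @export
glm_map <- function(fit, stat = c("z", "beta", "se"), regressor) {
  stat <- match.arg(stat)
  if (is.null(fit$dims)) stop("fit was not run on a 4-D series")
  out <- array(0, fit$dims)
  out[fit$mask] <- fit[[stat]][, regressor]
  out
}

#' @export
tidy.glm_fit <- function(x, z_thr = 3.1, ...) {
  dplyr::bind_rows(lapply(setdiff(x$regressors, "intercept"), function(r) {
    z <- x$z[, r]
    tibble::tibble(regressor = r,
                   n_suprathreshold = sum(z > z_thr),
                   max_z = max(z), median_z = stats::median(z),
                   max_beta = max(x$beta[, r]))
  }))
}

#' @export
glance.glm_fit <- function(x, ...) {
  tibble::tibble(n_voxels = nrow(x$beta), df = x$df,
                 mean_rho = mean(x$rho))
}

#' Broom-style tidiers
#'
#' `tidy()` returns a per-term (or per-ROI/fold) tibble, `glance()` a
#' one-row model summary; methods are provided for the fitted/result objects
#' of this package.
#'
#' @param x object to tidy.
#' @param ... method-specific arguments.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Connected-component cluster thresholding
#'
#' 3-D connected components (face connectivity) of `z > z_thr`; clusters
#' smaller than `min_extent` are dropped. Cluster-extent calibration is
#' available via [cluster_extent_null()] (Gaussian-field p-values are not
#' implemented).
#'
#' @param zmap 3-D z map.
#' @param z_thr voxel inclusion threshold (default 3.1).
#' @param min_extent minimum cluster size (voxels).
#' @return tibble: cluster, size, peak_z, x, y, z (peak location).
#' @export
cluster_threshold <- function(zmap, z_thr = 3.1, min_extent = 0) {
  d <- dim(zmap)
  supra <- which(zmap > z_thr)
  if (!length(supra)) {
    return(tibble::tibble(cluster = integer(0), size = integer(0),
                          peak_z = numeric(0), x = integer(0),
                          y = integer(0), z = integer(0)))
  }
  lab <- array(0L, d)
  lab[supra] <- -1L   # unvisited suprathreshold
  nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
              c(0, 0, 1), c(0, 0, -1))
  cl <- 0L
  rows <- list()
  for (seed in supra) {
    if (lab[seed] != -1L) next
    cl <- cl + 1L
    queue <- matrix(arrayInd(seed, d), ncol = 3)
    lab[seed] <- cl
    members <- seed
    while (nrow(queue)) {
      cur <- queue[1, , drop = FALSE]
      queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(6)) {
        nxt <- cur + nb[k, ]
        if (any(nxt < 1) || any(nxt > d)) next
        idx <- nxt[1] + (nxt[2] - 1L) * d[1] + (nxt[3] - 1L) * d[1] * d[2]
        if (lab[idx] == -1L) {
          lab[idx] <- cl
          members <- c(members, idx)
          queue <- rbind(queue, nxt)
        }
      }
    }
    pk <- members[which.max(zmap[members])]
    pc <- arrayInd(pk, d)
    rows[[cl]] <- tibble::tibble(cluster = cl, size = length(members),
                                 peak_z = max(zmap[members]),
                                 x = pc[1], y = pc[2], z = pc[3])
  }
  out <- dplyr::bind_rows(rows)
  out <- out[out$size >= min_extent, , drop = FALSE]
  out[order(-out$size), ]
}

#' Null-simulation calibration of the cluster extent threshold
#'
#' Simulates smooth Gaussian null z-maps, records the largest cluster above
#' `z_thr` in each, and returns the `1 - alpha` quantile as the minimum
#' cluster extent.
#'
#' @param dims map dimensions (3-vector).
#' @param z_thr voxel threshold.
#' @param fwhm_vox in-plane smoothness of the simulated nulls (voxels).
#' @param n_sim simulations.
#' @param alpha cluster significance level.
#' @param seed integer seed.
#' @return minimum cluster extent (voxels).
#' @export
cluster_extent_null <- function(dims, z_thr = 3.1, fwhm_vox = 1.6,
                                n_sim = 200, alpha = 0.05, seed = 1) {
  set.seed(seed)
  n <- dims[1]
  sig <- fwhm_vox / (2 * sqrt(2 * log(2)))
  g1 <- stats::dnorm(c(0:(n / 2), (-n / 2 + 1):(-1)), sd = sig)
  ker <- outer(g1, g1); ker <- ker / sum(ker)
  otf <- stats::fft(ker)
  sm_scale <- sqrt(sum(Mod(otf)^2) / (n * n))
  mx <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    zm <- array(0, dims)
    for (s in seq_len(dims[3])) {
      w <- matrix(stats::rnorm(n * n), n, n)
      w <- Re(stats::fft(stats::fft(w) * otf, inverse = TRUE)) / (n * n)
      zm[, , s] <- w / sm_scale
    }
    cls <- cluster_threshold(zm, z_thr = z_thr)
    mx[i] <- if (nrow(cls)) max(cls$size) else 0
  }
  as.integer(stats::quantile(mx, 1 - alpha, type = 1) + 1)
}

#' Second-level analysis across sessions
#'
#' Per-voxel one-sample t-test over session maps (a fixed-effects
#' simplification of a mixed-effects session-level analysis), mapped to z.
#' Voxels with (numerically) zero variance and non-zero mean are capped at
#' `z_cap` and flagged.
#'
#' @param maps list of 3-D session maps (beta or z), or a V x S matrix.
#' @param z_cap cap for infinite/overflowing z values.
#' @return 3-D group z map (or vector for matrix input), with attribute
#'   `capped` (logical map).
#' @export
second_level <- function(maps, z_cap = 40) {
  if (is.list(maps)) {
    S <- length(maps)
    if (S < 3) stop("need at least 3 sessions")
    d <- dim(maps[[1]])
    Y <- sapply(maps, as.vector)
  } else {
    Y <- maps
    S <- ncol(Y)
    if (S < 3) stop("need at least 3 sessions")
    d <- NULL
  }
  m <- rowMeans(Y)
  s <- apply(Y, 1, stats::sd)
  tv <- sqrt(S) * m / s
  capped <- !is.finite(tv) & abs(m) > 0
  tv[!is.finite(tv)] <- 0
  z <- z_from_t(tv, df = S - 1, cap = z_cap)
  z[capped] <- sign(m[capped]) * z_cap
  if (!is.null(d)) {
    z <- array(z, d)
    capped <- array(capped, d)
  }
  attr(z, "capped") <- capped
  z
}

#' Split-half reliability of second-level activation estimates
#'
#' Repeatedly splits the sessions into two random halves, runs the second
#' level in each half, and measures per-ROI reliability as the voxelwise
#' linear correlation of the two half z-maps, plus the baseline bias
#' |mean z difference|. Setting `z_thr > 0` restricts the comparison to
#' voxels suprathreshold in either half.
#'
#' @param maps list of per-session 3-D maps (one regressor's beta or z).
#' @param masks named list of ROI masks.
#' @param n_folds number of random splits.
#' @param seed integer seed.
#' @param z_thr optional threshold applied to the half z-maps.
#' @return class `reliability_result`: tibble fold, roi, r, bias.
#' @export
split_half_reliability <- function(maps, masks, n_folds = 10, seed = 1,
                                   z_thr = 0) {
  S <- length(maps)
  if (S < 4) stop("need at least 4 sessions for split-half reliability")
  set.seed(seed)
  rows <- list()
  for (f in seq_len(n_folds)) {
    idx <- sample(S)
    h1 <- idx[seq_len(S %/% 2)]
    h2 <- idx[(S %/% 2 + 1):S]
    z1 <- second_level(maps[h1])
    z2 <- second_level(maps[h2])
    for (nm in names(masks)) {
      v1 <- z1[masks[[nm]]]; v2 <- z2[masks[[nm]]]
      if (z_thr > 0) {
        keep <- v1 > z_thr | v2 > z_thr
        v1 <- v1[keep]; v2 <- v2[keep]
      }
      r <- if (length(v1) > 2 && stats::sd(v1) > 0 && stats::sd(v2) > 0)
        stats::cor(v1, v2) else NA_real_
      rows[[length(rows) + 1L]] <- tibble::tibble(
        fold = f, roi = nm, r = r,
        bias = if (length(v1)) abs(mean(v1) - mean(v2)) else NA_real_)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("reliability_result", class(out))
  out
}

#' @export
glance.reliability_result <- function(x, ...) {
  tibble::tibble(mean_r = mean(x$r, na.rm = TRUE),
                 mean_bias = mean(x$bias, na.rm = TRUE),
                 n_folds = length(unique(x$fold)))
}

#' @export
tidy.reliability_result <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(x, .data$roi),
                   mean_r = mean(.data$r, na.rm = TRUE),
                   mean_bias = mean(.data$bias, na.rm = TRUE),
                   .groups = "drop")
}

#' Compare reliability between two arms
#'
#' Per ROI, paired (by fold) two-sided Wilcoxon test on the correlation
#' values, with BH correction across ROIs.
#'
#' @param rel_a,rel_b `reliability_result` objects for the two arms
#'   (same folds and ROIs).
#' @return tibble: roi, delta_r, delta_bias, p, q.
#' @export
reliability_compare <- function(rel_a, rel_b) {
  rois <- unique(rel_a$roi)
  if (!identical(sort(unique(rel_a$fold)), sort(unique(rel_b$fold))))
    stop("the two reliability results must use the same folds")
  rows <- lapply(rois, function(nm) {
    a <- rel_a[rel_a$roi == nm, ]; b <- rel_b[rel_b$roi == nm, ]
    a <- a[order(a$fold), ]; b <- b[order(b$fold), ]
    ok <- is.finite(a$r) & is.finite(b$r)
    p <- if (sum(ok) >= 2 && any(a$r[ok] != b$r[ok]))
      stats::wilcox.test(a$r[ok], b$r[ok], paired = TRUE, exact = FALSE)$p.value
    else NA_real_
    tibble::tibble(roi = nm, delta_r = mean(a$r[ok] - b$r[ok]),
                   delta_bias = mean(a$bias[ok] - b$bias[ok]), p = p)
  })
  out <- dplyr::bind_rows(rows)
  out$q <- NA_real_
  ok <- is.finite(out$p)
  out$q[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  out
}
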