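# Image reconstruction chain: Nyquist ghost correction -> (corrected arm:
# first-order off-resonance correction) -> zeroth-order phase correction
# (both arms) -> SMS unaliasing -> in-plane GRAPPA completion -> inverse
# transform -> root-sum-of-squares coil combination.

#' Train the reconstruction operator bundle
#'
#' In-plane GRAPPA kernel, split-slice SMS kernels, and the ky shift
#' operator, all from the same zero-field calibration set.
#'
#' @param calibration a `calibration_set`.
#' @param protocol an [sms_protocol()].
#' @param lambda ridge factor shared by the kernel fits.
#' @param shift_lambda ridge factor of the shift-operator fit.
#' @param width shift-operator readout taps (NULL = per-position fit).
#' @param split use the leak-block slice-kernel objective.
#' @return class `recon_operators`.
#' @export
train_recon_operators <- function(calibration, protocol, lambda = 1e-4,
                                  shift_lambda = 5e-4, width = NULL,
                                  split = TRUE) {
  structure(list(
    inplane = train_inplane_kernel(calibration, lambda = lambda),
    slice = train_slice_kernels(calibration, protocol, lambda = lambda,
                                split = split),
    shift_ky = train_shift_operator(calibration, axis = "ky", width = width,
                                    lambda = shift_lambda)
  ), class = "recon_operators")
}

#' Root-sum-of-squares coil combination
#' @param images complex array (n, n, C).
#' @return non-negative magnitude image (n, n).
#' @export
coil_combine <- function(images) {
  if (length(dim(images)) == 2L) return(Mod(images))
  sqrt(apply(Mod(images)^2, c(1, 2), sum))
}

# one frame -> per-slice magnitude images (n, n, mb)
reconstruct_frame <- function(frame, operators, est, arm, protocol) {
  gh <- list(theta0 = est$theta0, theta1 = est$theta1)
  fr <- nyquist_correct(frame, gh)
  corr <- if (arm == "corrected") {
    list(phi0 = est$phi0, dkx = est$dkx, dky = est$dky)
  } else {
    # the uncorrected arm still receives the dynamic zeroth-order correction
    list(phi0 = est$phi0, dkx = 0, dky = 0)
  }
  fr <- correct_frame(fr, corr, operators$shift_ky)
  ks_slices <- sms_unalias(fr$data, operators$slice, protocol, frame$group)
  mb <- dim(ks_slices)[4]
  out <- array(0, c(protocol$n, protocol$n, mb))
  for (s in seq_len(mb)) {
    full <- inplane_fill(ks_slices[, , , s], operators$inplane,
                         frame$ky_idx, protocol$n)
    out[, , s] <- coil_combine(ifft2c(full))
  }
  out
}

#' Reconstruct a session into a magnitude image time series
#'
#' The only difference between the two arms is the first-order off-resonance
#' correction step (dkx, dky); ghost correction and the dynamic zeroth-order
#' phase correction are applied to both.
#'
#' @param session an `sms_session`.
#' @param operators a [train_recon_operators()] bundle.
#' @param estimates per-frame estimates from [estimate_session()]; computed
#'   on the fly when NULL.
#' @param arm "corrected" or "uncorrected".
#' @return class `recon_series`: `data` (n, n, n_slices, T) magnitude array,
#'   `tr`, `voxel_mm`, `arm`, provenance.
#' @export
reconstruct_session <- function(session, operators, estimates = NULL,
                                arm = c("corrected", "uncorrected")) {
  arm <- match.arg(arm)
  protocol <- session$protocol
  if (is.null(session$calibration)) stop("session has no calibration data")
  if (is.null(estimates)) estimates <- estimate_session(session, operators)
  if (arm == "corrected" &&
      !all(c("phi0", "dkx", "dky") %in% names(estimates)))
    stop("corrected arm requires (phi0, dkx, dky) estimates")
  ngr <- n_groups(protocol)
  S <- protocol$n_slices
  vol <- array(0, c(protocol$n, protocol$n, S, session$n_frames))
  key <- paste(estimates$frame, estimates$group)
  idx <- stats::setNames(seq_len(nrow(estimates)), key)
  for (t in seq_len(session$n_frames)) {
    for (g in seq_len(ngr)) {
      est <- estimates[idx[[paste(t, g)]], ]
      mags <- reconstruct_frame(session$frames[[t]][[g]], operators, est,
                                arm, protocol)
      sl <- slice_group(protocol, g)
      for (s in seq_along(sl)) vol[, , sl[s], t] <- mags[, , s]
    }
  }
  structure(list(
    data = vol, tr = protocol$tr, voxel_mm = protocol$voxel_mm, arm = arm,
    provenance = list(arm = arm, package = "smsb0",
                      version = tryCatch(
                        as.character(utils::packageVersion("smsb0")),
                        error = function(e) "dev"),
                      n_frames = session$n_frames)
  ), class = "recon_series")
}

#' @export
print.recon_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("recon_series [%s]: %d x %d x %d slices x %d frames, TR %.3f s\n",
              x$arm, d[1], d[2], d[3], d[4], x$tr))
  invisible(x)
}

#' Write a reconstructed series as NIfTI
#'
#' The voxel size and TR are carried in the header (pixdim); the affine is a
#' plain RAS scaling (no scanner geometry is simulated).
#'
#' @param series a `recon_series` (or bare 4-D array with `tr`, `voxel_mm`).
#' @param path output path (.nii or .nii.gz).
#' @param tr,voxel_mm overrides when `series` is a bare array.
#' @return the path, invisibly.
#' @export
write_series_nifti <- function(series, path, tr = NULL, voxel_mm = NULL) {
  if (inherits(series, "recon_series")) {
    arr <- series$data; tr <- series$tr; voxel_mm <- series$voxel_mm
  } else arr <- series
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, c(voxel_mm, voxel_mm, voxel_mm, tr))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a series written by [write_series_nifti()]
#' @param path NIfTI file path.
#' @param arm provenance label to attach.
#' @return a `recon_series`.
#' @export
read_series_nifti <- function(path, arm = "unknown") {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  structure(list(data = unclass(img)[, , , , drop = FALSE], tr = pd[4],
                 voxel_mm = pd[1], arm = arm,
                 provenance = list(arm = arm, file = path)),
            class = "recon_series")
}

#' Nyquist ghost energy of an image
#'
#' Mean magnitude inside the FOV/2-displaced replica band of the object
#' (excluding the object itself) - the standard scalar used to verify ghost
#' suppression.
#'
#' @param img magnitude image (n, n).
#' @param support logical object mask (n, n).
#' @return mean magnitude in the ghost band.
#' @export
ghost_energy <- function(img, support) {
  n <- nrow(img)
  band <- roll2(array(support, c(n, n, 1)), 0L, n %/% 2L)[, , 1] & !support
  mean(img[band])
}
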