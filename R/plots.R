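# ggplot2 views of the main result types.

#' Plot per-frame perturbation estimates
#'
#' @param estimates output of [estimate_session()].
#' @param truth optional `field_timeline` with the injected states (overlaid
#'   as lines after conversion to shift units).
#' @param te echo time (s), needed when `truth` is given.
#' @return a ggplot object.
#' @export
plot_estimates <- function(estimates, truth = NULL, te = NULL) {
  long <- dplyr::bind_rows(
    dplyr::transmute(estimates, frame = .data$frame, group = .data$group,
                     parameter = "phi0 [rad]", value = .data$phi0),
    dplyr::transmute(estimates, frame = .data$frame, group = .data$group,
                     parameter = "dkx [grid]", value = .data$dkx),
    dplyr::transmute(estimates, frame = .data$frame, group = .data$group,
                     parameter = "dky [grid]", value = .data$dky))
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$frame, .data$value,
                                          colour = factor(.data$group))) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::facet_wrap(~parameter, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "frame", y = NULL, colour = "slice group",
                  title = "Navigator-based off-resonance estimates") +
    ggplot2::theme_minimal()
  if (!is.null(truth)) {
    stopifnot(!is.null(te))
    tr <- dplyr::bind_rows(
      tibble::tibble(frame = truth$frame, parameter = "phi0 [rad]",
                     value = 2 * pi * truth$c0 * te),
      tibble::tibble(frame = truth$frame, parameter = "dkx [grid]",
                     value = truth$cx * te),
      tibble::tibble(frame = truth$frame, parameter = "dky [grid]",
                     value = truth$cy * te))
    p <- p + ggplot2::geom_line(data = tr, ggplot2::aes(.data$frame,
                                                        .data$value),
                                inherit.aes = FALSE, linetype = 2)
  }
  p
}

#' Mosaic view of one reconstructed frame
#'
#' @param object a `recon_series`.
#' @param frame frame index to show.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.recon_series <- function(object, frame = 1, ...) {
  d <- dim(object$data)
  df <- do.call(rbind, lapply(seq_len(d[3]), function(s) {
    data.frame(x = rep(seq_len(d[1]), d[2]),
               y = rep(seq_len(d[2]), each = d[1]),
               slice = paste("slice", s),
               value = as.vector(object$data[, , s, frame]))
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~slice) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s arm, frame %d", object$arm, frame),
                  x = NULL, y = NULL, fill = "a.u.") +
    ggplot2::theme_minimal()
}

#' @export
autoplot <- function(object, ...) UseMethod("autoplot")

#' Paired per-ROI tSNR comparison plot
#'
#' @param roi_tsnr long tibble with columns roi, arm, mean, session (as
#'   produced by [run_study()]'s `roi_tsnr`).
#' @return a ggplot object.
#' @export
plot_roi_tsnr <- function(roi_tsnr) {
  agg <- dplyr::summarise(
    dplyr::group_by(roi_tsnr, .data$roi, .data$arm),
    mean_tsnr = mean(.data$mean, na.rm = TRUE),
    sem = stats::sd(.data$mean, na.rm = TRUE) /
      sqrt(sum(is.finite(.data$mean))),
    .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(.data$roi, .data$mean_tsnr,
                                    fill = .data$arm)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_tsnr - .data$sem,
                                        ymax = .data$mean_tsnr + .data$sem),
                           position = ggplot2::position_dodge(0.9),
                           width = 0.3) +
    ggplot2::labs(x = NULL, y = "tSNR (mean over ROI voxels)",
                  title = "ROI tSNR by reconstruction arm") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Split-half reliability plot
#'
#' @param rel_c,rel_u `reliability_result` objects for the two arms.
#' @return a ggplot object.
#' @export
plot_reliability <- function(rel_c, rel_u) {
  df <- dplyr::bind_rows(dplyr::mutate(rel_c, arm = "corrected"),
                         dplyr::mutate(rel_u, arm = "uncorrected"))
  ggplot2::ggplot(df, ggplot2::aes(.data$roi, .data$r, fill = .data$arm)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "split-half correlation r",
                  title = "Reliability of second-level activation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
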