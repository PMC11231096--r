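# Image-quality quantification: bias against the single-band reference,
# temporal coefficient of variation, tSNR, ROI summaries, paired
# across-session comparison with Benjamini-Hochberg FDR, and histograms.

#' Reconstruction bias map
#'
#' Per-voxel mean over time minus the single-band reference, normalised by
#' the mean reference intensity over the object (reported as a fraction).
#'
#' @param series a `recon_series` (or bare 4-D array).
#' @param sb_ref single-band reference magnitude volume (n, n, slices).
#' @param mask logical object mask; derived from `sb_ref` when NULL.
#' @return 3-D bias map with the mask as attribute `mask`.
#' @export
bias_map <- function(series, sb_ref, mask = NULL) {
  arr <- if (inherits(series, "recon_series")) series$data else series
  if (!all(dim(arr)[1:3] == dim(sb_ref))) stop("grids do not match")
  if (is.null(mask)) mask <- sb_ref > 0.1 * max(sb_ref)
  m <- apply(arr, 1:3, mean)
  out <- (m - sb_ref) / mean(sb_ref[mask])
  attr(out, "mask") <- mask
  out
}

#' Temporal coefficient of variation map
#'
#' Per-voxel standard deviation over time divided by the temporal mean;
#' voxels with mean below `floor` (relative to the volume maximum) are NA.
#'
#' @param series a `recon_series` (or bare 4-D array).
#' @param floor relative mean-intensity floor.
#' @return 3-D CoV map.
#' @export
cov_map <- function(series, floor = 0.05) {
  arr <- if (inherits(series, "recon_series")) series$data else series
  if (length(dim(arr)) != 4L || dim(arr)[4] < 3)
    stop("need a 4-D series with at least 3 frames for temporal statistics")
  m <- apply(arr, 1:3, mean)
  s <- apply(arr, 1:3, stats::sd)
  out <- s / m
  out[m <= floor * max(m)] <- NA_real_
  out
}

#' Temporal SNR map (mean / sd; reciprocal of [cov_map()])
#' @inheritParams cov_map
#' @export
tsnr_map <- function(series, floor = 0.05) {
  1 / cov_map(series, floor = floor)
}

#' Summarise a map over named ROIs
#'
#' @param map 3-D map (e.g. tSNR or bias).
#' @param masks named list of logical 3-D masks.
#' @return tibble: roi, mean, sem, n_vox (empty ROIs are flagged).
#' @export
roi_summary <- function(map, masks) {
  rows <- lapply(names(masks), function(nm) {
    v <- map[masks[[nm]]]
    v <- v[is.finite(v)]
    tibble::tibble(
      roi = nm, mean = if (length(v)) mean(v) else NA_real_,
      sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
      n_vox = length(v), empty = length(v) == 0L)
  })
  dplyr::bind_rows(rows)
}

#' Paired across-session ROI comparison with FDR
#'
#' Takes per-session ROI means for two reconstruction arms, runs a paired
#' two-sided test per ROI (Wilcoxon signed-rank by default, t-test as an
#' option) across sessions, and adjusts p-values with Benjamini-Hochberg.
#'
#' @param tbl tibble with columns `session`, `roi`, `arm`, `value`
#'   (`arm` must have exactly two levels).
#' @param arms character(2): the arms to compare as (test, reference);
#'   delta = test - reference.
#' @param test "wilcoxon" or "ttest".
#' @return tibble: roi, delta (mean paired difference), p, q, n.
#' @export
paired_compare <- function(tbl, arms = c("corrected", "uncorrected"),
                           test = c("wilcoxon", "ttest")) {
  test <- match.arg(test)
  rois <- unique(tbl$roi)
  rows <- lapply(rois, function(r) {
    a <- tbl[tbl$roi == r & tbl$arm == arms[1], ]
    b <- tbl[tbl$roi == r & tbl$arm == arms[2], ]
    a <- a[order(a$session), ]; b <- b[order(b$session), ]
    ok <- is.finite(a$value) & is.finite(b$value)
    if (sum(ok) < 2 || !all(a$session[ok] == b$session[ok])) {
      return(tibble::tibble(roi = r, delta = NA_real_, p = NA_real_,
                            n = sum(ok)))
    }
    d <- a$value[ok] - b$value[ok]
    p <- if (all(d == 0)) 1 else if (test == "wilcoxon") {
      suppressWarnings(stats::wilcox.test(d, exact = TRUE)$p.value)
    } else {
      stats::t.test(d)$p.value
    }
    tibble::tibble(roi = r, delta = mean(d), p = p, n = sum(ok))
  })
  out <- dplyr::bind_rows(rows)
  out$q <- NA_real_
  ok <- is.finite(out$p)
  out$q[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  out
}

#' Histogram of a map over the object, as a tibble
#'
#' Total counts equal the number of (finite) mask voxels.
#'
#' @param map 3-D map.
#' @param mask logical mask.
#' @param breaks number of bins or break vector (passed to [hist()]).
#' @return tibble: lo, hi, count.
#' @export
map_histogram <- function(map, mask, breaks = 50) {
  v <- map[mask]
  v <- v[is.finite(v)]
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  tibble::tibble(lo = h$breaks[-length(h$breaks)], hi = h$breaks[-1],
                 count = h$counts)
}

#' Slice-leakage energy of a reconstructed series
#'
#' Ratio of mean squared reconstructed signal in each slice's "partner-only"
#' zone (voxels inside the simultaneously excited partner slice's support but
#' outside this slice's own support) to the mean squared signal over the
#' slice's own object, median across slices and frames. Sensitive to signal
#' from the other slice of the SMS group landing in this slice.
#'
#' @param series a `recon_series`.
#' @param phantom the ground-truth `sms_phantom` (slice supports).
#' @param protocol the acquisition protocol (slice grouping).
#' @return scalar leakage energy ratio.
#' @export
leakage_energy <- function(series, phantom, protocol) {
  arr <- if (inherits(series, "recon_series")) series$data else series
  S <- phantom$n_slices
  vals <- c()
  for (g in seq_len(n_groups(protocol))) {
    sl <- slice_group(protocol, g)
    if (length(sl) < 2) next
    for (i in seq_along(sl)) {
      s <- sl[i]; partner <- sl[sl != s][1]
      zone <- phantom$support[, , partner] & !phantom$support[, , s]
      own <- phantom$support[, , s]
      if (!any(zone)) next
      num <- apply(arr[, , s, , drop = FALSE], 4, function(v)
        mean(v[zone]^2))
      den <- apply(arr[, , s, , drop = FALSE], 4, function(v)
        mean(v[own]^2))
      vals <- c(vals, stats::median(num / den))
    }
  }
  stats::median(vals)
}

#' Full QC report for a pair of reconstruction arms
#'
#' @param series_c,series_u corrected / uncorrected `recon_series`.
#' @param calibration the session's `calibration_set` (single-band reference).
#' @param masks named ROI masks (e.g. `phantom$masks`).
#' @return class `qc_report`: maps, ROI tables, medians and histograms.
#' @export
qc_report <- function(series_c, series_u, calibration, masks) {
  sb <- calibration$sb_ref
  mask <- sb > 0.1 * max(sb)
  bc <- bias_map(series_c, sb, mask); bu <- bias_map(series_u, sb, mask)
  cc <- cov_map(series_c); cu <- cov_map(series_u)
  tc <- 1 / cc; tu <- 1 / cu
  roi <- dplyr::bind_rows(
    dplyr::mutate(roi_summary(tc, masks), arm = "corrected",
                  metric = "tsnr"),
    dplyr::mutate(roi_summary(tu, masks), arm = "uncorrected",
                  metric = "tsnr"))
  med <- tibble::tibble(
    metric = c("abs_bias", "cov", "tsnr"),
    corrected = c(stats::median(abs(bc[mask])),
                  stats::median(cc[mask], na.rm = TRUE),
                  stats::median(tc[mask], na.rm = TRUE)),
    uncorrected = c(stats::median(abs(bu[mask])),
                    stats::median(cu[mask], na.rm = TRUE),
                    stats::median(tu[mask], na.rm = TRUE)))
  hists <- dplyr::bind_rows(
    dplyr::mutate(map_histogram(abs(bc), mask), arm = "corrected",
                  metric = "abs_bias"),
    dplyr::mutate(map_histogram(abs(bu), mask), arm = "uncorrected",
                  metric = "abs_bias"),
    dplyr::mutate(map_histogram(cc, mask), arm = "corrected",
                  metric = "cov"),
    dplyr::mutate(map_histogram(cu, mask), arm = "uncorrected",
                  metric = "cov"))
  structure(list(bias_c = bc, bias_u = bu, cov_c = cc, cov_u = cu,
                 tsnr_c = tc, tsnr_u = tu, roi_table = roi, medians = med,
                 histograms = hists, mask = mask),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report (medians over object voxels):\n")
  print(as.data.frame(x$medians), row.names = FALSE)
  invisible(x)
}
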