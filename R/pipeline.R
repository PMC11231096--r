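# End-to-end orchestration: simulate a session, estimate and correct,
# reconstruct both arms, quantify image quality and GLM activation, and
# aggregate a multi-session study (paired tSNR comparison, activation
# ordering, split-half reliability).

#' Simulate one functional session from a run configuration
#'
#' @param config a [run_config()].
#' @param seed session seed (timeline, events and noise derive from it).
#' @param phantom,coils optionally reuse a phantom / coil set (defaults are
#'   built from `config$seed` so all sessions of a study share them).
#' @return an `sms_session`.
#' @export
simulate_session <- function(config = run_config(), seed = config$seed,
                             phantom = NULL, coils = NULL) {
  protocol <- config_protocol(config)
  if (is.null(phantom))
    phantom <- make_phantom(config$n, config$n_slices, seed = config$seed,
                            activation_amp = config$activation_amp)
  if (is.null(coils))
    coils <- make_coil_maps(config$n_coils, config$n, seed = config$seed)
  timeline <- make_field_timeline(config$n_frames, config$field_amp,
                                  config$field_model, seed = seed)
  events <- make_task_events(config$n_trials, config$p_respond, seed = seed)
  acquire_session(phantom, coils, timeline, events, protocol,
                  mode = config$mode,
                  hrf = hrf_params(peak = config$hrf_peak), seed = seed)
}

#' Run the full per-session analysis chain
#'
#' Estimation, reconstruction of both arms, QC, preprocessing and first-level
#' GLM; returns compact per-session summaries (the raw k-space and image
#' series are discarded).
#'
#' @param config a [run_config()].
#' @param seed session seed.
#' @param phantom,coils shared study phantom / coils (see
#'   [simulate_session()]).
#' @param keep_series return the reconstructed series as well (memory-heavy).
#' @return list: estimates, qc medians/ROI tables, leakage, GLM summaries and
#'   beta/z maps per arm for the activation-carrying regressors.
#' @export
run_session <- function(config = run_config(), seed = config$seed,
                        phantom = NULL, coils = NULL, keep_series = FALSE) {
  protocol <- config_protocol(config)
  if (is.null(phantom))
    phantom <- make_phantom(config$n, config$n_slices, seed = config$seed,
                            activation_amp = config$activation_amp)
  if (is.null(coils))
    coils <- make_coil_maps(config$n_coils, config$n, seed = config$seed)
  session <- simulate_session(config, seed, phantom, coils)
  operators <- train_recon_operators(session$calibration, protocol,
                                     lambda = config$kernel_lambda)
  estimates <- estimate_session(session, operators,
                                bound = config$search_bound,
                                tol = config$search_tol,
                                step = config$search_step)
  arms <- list(
    corrected = reconstruct_session(session, operators, estimates,
                                    "corrected"),
    uncorrected = reconstruct_session(session, operators, estimates,
                                      "uncorrected"))
  qc <- qc_report(arms$corrected, arms$uncorrected, session$calibration,
                  phantom$masks)
  leakage <- vapply(arms, leakage_energy, numeric(1), phantom = phantom,
                    protocol = protocol)

  design <- build_design(session$truth$events, config$n_frames, protocol$tr,
                         hrf = hrf_params(peak = config$hrf_peak))
  mask <- session$calibration$sb_ref > 0.1 * max(session$calibration$sb_ref)
  act_mask <- phantom$activation > 0
  glm <- list(); maps <- list()
  for (arm in names(arms)) {
    pre <- preprocess_series(arms[[arm]], config$highpass_s, config$fwhm_mm)
    fit <- fit_glm(pre, design, mask)
    glm[[arm]] <- list(tidy = tidy(fit, z_thr = config$z_thr),
                       glance = glance(fit))
    maps[[arm]] <- list(
      beta_offer = glm_map(fit, "beta", "offer"),
      beta_motor = glm_map(fit, "beta", "motor_response"),
      z_offer = glm_map(fit, "z", "offer"),
      z_motor = glm_map(fit, "z", "motor_response"))
    zmap <- maps[[arm]]$z_offer
    zmap2 <- maps[[arm]]$z_motor
    glm[[arm]]$n_supra <- sum(zmap[mask] > config$z_thr) +
      sum(zmap2[mask] > config$z_thr)
    glm[[arm]]$median_z_act <- stats::median(
      c(maps[[arm]]$z_offer[act_mask & phantom$act_label == 1L],
        maps[[arm]]$z_motor[act_mask & phantom$act_label == 2L]))
  }

  out <- list(seed = seed, estimates = estimates, qc_medians = qc$medians,
              roi_tsnr = qc$roi_table, leakage = leakage, glm = glm,
              maps = maps, histograms = qc$histograms)
  if (keep_series) {
    out$series <- arms
    out$qc <- qc
  }
  out
}

#' Run a multi-session study and aggregate arm comparisons
#'
#' All sessions share the phantom and coil set (one simulated animal) and
#' differ in their motion timeline, task events and noise. Aggregates the
#' paired per-ROI tSNR comparison (Wilcoxon + BH FDR), the activation
#' ordering between arms, and split-half reliability of the second-level
#' maps.
#'
#' @param config a [run_config()].
#' @param n_sessions number of sessions.
#' @param seed study seed; session k uses `seed + k`.
#' @param n_folds reliability folds.
#' @return class `sms_study`.
#' @export
run_study <- function(config = run_config(), n_sessions = 10,
                      seed = config$seed, n_folds = 10) {
  phantom <- make_phantom(config$n, config$n_slices, seed = config$seed,
                          activation_amp = config$activation_amp)
  coils <- make_coil_maps(config$n_coils, config$n, seed = config$seed)
  sessions <- lapply(seq_len(n_sessions), function(k) {
    run_session(config, seed = seed + k, phantom = phantom, coils = coils)
  })

  roi_tsnr <- dplyr::bind_rows(lapply(seq_along(sessions), function(k)
    dplyr::mutate(sessions[[k]]$roi_tsnr, session = k)))
  tsnr_cmp <- paired_compare(
    dplyr::transmute(roi_tsnr, session = .data$session, roi = .data$roi,
                     arm = .data$arm, value = .data$mean))

  qc_medians <- dplyr::bind_rows(lapply(seq_along(sessions), function(k)
    dplyr::mutate(sessions[[k]]$qc_medians, session = k)))
  leakage <- t(vapply(sessions, function(s) s$leakage, numeric(2)))

  activation <- dplyr::bind_rows(lapply(seq_along(sessions), function(k) {
    s <- sessions[[k]]
    tibble::tibble(
      session = k,
      n_supra_corrected = s$glm$corrected$n_supra,
      n_supra_uncorrected = s$glm$uncorrected$n_supra,
      median_z_corrected = s$glm$corrected$median_z_act,
      median_z_uncorrected = s$glm$uncorrected$median_z_act)
  }))

  rel <- list(); rel_cmp <- NULL
  if (n_sessions >= 6) {  # two halves of >= 3 sessions each
    act_masks <- active_rois(phantom)
    for (arm in c("corrected", "uncorrected")) {
      maps <- lapply(sessions, function(s) s$maps[[arm]]$beta_offer)
      rel[[arm]] <- split_half_reliability(maps, act_masks,
                                           n_folds = n_folds, seed = seed)
    }
    rel_cmp <- reliability_compare(rel$corrected, rel$uncorrected)
  }

  structure(list(
    config = config, n_sessions = n_sessions, seed = seed,
    sessions = sessions, roi_tsnr = roi_tsnr, tsnr_compare = tsnr_cmp,
    qc_medians = qc_medians, leakage = leakage, activation = activation,
    reliability = rel, reliability_compare = rel_cmp,
    phantom = phantom
  ), class = "sms_study")
}

# ROIs that overlap true activation, plus the activation blobs themselves
active_rois <- function(phantom) {
  act <- phantom$activation > 0
  rois <- Filter(function(m) sum(m & act) >= 10, phantom$masks)
  c(rois, list(offer_blob = phantom$act_label == 1L,
               motor_blob = phantom$act_label == 2L))
}

#' @export
print.sms_study <- function(x, ...) {
  cat(sprintf("SMS-EPI study: %d sessions, T = %d, %s field model\n",
              x$n_sessions, x$config$n_frames, x$config$field_model))
  cat("\nQC medians (session means):\n")
  agg <- stats::aggregate(cbind(corrected, uncorrected) ~ metric,
                          data = x$qc_medians, FUN = mean)
  print(agg, row.names = FALSE)
  inc <- x$tsnr_compare$delta > 0
  cat(sprintf("\ntSNR: improved in %d/%d ROIs; min q = %.4f\n",
              sum(inc, na.rm = TRUE), sum(is.finite(x$tsnr_compare$delta)),
              suppressWarnings(min(x$tsnr_compare$q, na.rm = TRUE))))
  ord <- with(x$activation,
              n_supra_corrected >= n_supra_uncorrected &
                median_z_corrected >= median_z_uncorrected)
  cat(sprintf("activation ordering (corrected >= uncorrected): %d/%d sessions\n",
              sum(ord), length(ord)))
  invisible(x)
}

#' Write a Markdown report of a study
#'
#' @param study an `sms_study`.
#' @param path output .md path.
#' @return the path, invisibly.
#' @export
report_markdown <- function(study, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# Dynamic off-resonance correction: study report")
  w("")
  w("- sessions: %d, frames: %d, field model: %s (amplitudes %s Hz)",
    study$n_sessions, study$config$n_frames, study$config$field_model,
    paste(study$config$field_amp, collapse = "/"))
  w("- config hash: %s, seed: %d", config_hash(study$config), study$seed)
  w("")
  w("## Image quality (medians over object voxels, mean across sessions)")
  w("")
  w("| metric | corrected | uncorrected |")
  w("|---|---|---|")
  agg <- stats::aggregate(cbind(corrected, uncorrected) ~ metric,
                          data = study$qc_medians, FUN = mean)
  for (i in seq_len(nrow(agg)))
    w("| %s | %.4f | %.4f |", agg$metric[i], agg$corrected[i],
      agg$uncorrected[i])
  w("")
  w("- slice-leakage energy (mean): corrected %.4g, uncorrected %.4g",
    mean(study$leakage[, "corrected"]), mean(study$leakage[, "uncorrected"]))
  w("")
  w("## Paired tSNR comparison (per ROI, Wilcoxon + BH)")
  w("")
  w("| roi | delta tSNR | p | q |")
  w("|---|---|---|---|")
  tc <- study$tsnr_compare
  for (i in seq_len(nrow(tc)))
    w("| %s | %.3f | %.4f | %.4f |", tc$roi[i], tc$delta[i], tc$p[i],
      tc$q[i])
  w("")
  w("## Activation (z > %.1f)", study$config$z_thr)
  w("")
  w("| session | N supra (corr) | N supra (uncorr) | median z act (corr) | median z act (uncorr) |")
  w("|---|---|---|---|---|")
  a <- study$activation
  for (i in seq_len(nrow(a)))
    w("| %d | %d | %d | %.3f | %.3f |", a$session[i],
      a$n_supra_corrected[i], a$n_supra_uncorrected[i],
      a$median_z_corrected[i], a$median_z_uncorrected[i])
  if (!is.null(study$reliability_compare)) {
    w("")
    w("## Split-half reliability (fold-mean per ROI)")
    w("")
    w("| roi | delta r | delta bias | q |")
    w("|---|---|---|---|")
    rc <- study$reliability_compare
    for (i in seq_len(nrow(rc)))
      w("| %s | %.3f | %.3f | %.4f |", rc$roi[i], rc$delta_r[i],
        rc$delta_bias[i], rc$q[i])
  }
  invisible(path)
}
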