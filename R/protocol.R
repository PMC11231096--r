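#' Acquisition protocol
#'
#' Collects the sequence parameters of the simulated SMS-EPI protocol.
#' Defaults mirror the acquisition this package emulates where printed
#' (TE 25.4 ms, TR 1.282 s, MB = 2, in-plane R = 2) at a desk-scale geometry
#' (64 matrix, 4 slices, 8 coils instead of 120 mm FOV / 42 slices / 15
#' channels).
#'
#' Line-time convention: imaging line m (0-based, `n/R` lines) is acquired at
#' `t_m = TE + (m - n_lines/2) * esp`, so the k-space centre coincides with
#' the echo time. The three non-phase-encoded navigator echoes are centred on
#' TE as well (`TE - esp, TE, TE + esp`, alternating readout polarity), a
#' simulation convention that makes the navigator-sensed phase equal the net
#' translation at TE under linear phase accrual.
#'
#' @param n grid size (even); `n_lines = n / r_inplane` EPI lines per shot.
#' @param n_slices total slices; SMS groups pair slice `g` with `g + n_slices/mb`.
#' @param n_coils receive channels.
#' @param mb multiband factor (1 or 2).
#' @param r_inplane in-plane acceleration factor (1 or 2).
#' @param caipi logical; blipped inter-slice shift for MB = 2.
#' @param te,tr echo/repetition time (s).
#' @param esp effective echo spacing (s).
#' @param fov_mm field of view (mm); voxel size is `fov_mm / n`.
#' @param sigma complex noise standard deviation per k-space sample
#'   (calibrated so coil-combined object SNR is ~30 at default geometry).
#' @param sigma_calib noise level of the calibration/reference acquisitions
#'   (defaults to `sigma / 4`, an averaged calibration scan).
#' @param ghost_theta0,ghost_theta1 even/odd readout phase error: constant
#'   (rad) and linear (rad per readout sample) terms.
#' @return class `sms_protocol` list.
#' @export
sms_protocol <- function(n = 64, n_slices = 4, n_coils = 8, mb = 2,
                         r_inplane = 2, caipi = TRUE,
                         te = 0.0254, tr = 1.282, esp = 6e-4, fov_mm = 120,
                         sigma = 0.02, sigma_calib = sigma / 4,
                         ghost_theta0 = 0.1, ghost_theta1 = 0.05) {
  if (n %% 2 != 0) stop("grid size must be even")
  if (!mb %in% c(1L, 2L)) stop("only MB in {1, 2} is supported")
  if (!r_inplane %in% c(1L, 2L)) stop("only R in {1, 2} is supported")
  if (mb > 1 && n_slices %% mb != 0) stop("n_slices must be divisible by mb")
  n_lines <- n / r_inplane
  m <- seq_len(n_lines) - 1L
  p <- structure(list(
    n = as.integer(n), n_slices = as.integer(n_slices),
    n_coils = as.integer(n_coils), mb = as.integer(mb),
    r_inplane = as.integer(r_inplane), caipi = isTRUE(caipi),
    te = te, tr = tr, esp = esp, fov_mm = fov_mm,
    sigma = sigma, sigma_calib = sigma_calib,
    ghost_theta0 = ghost_theta0, ghost_theta1 = ghost_theta1,
    n_lines = as.integer(n_lines),
    ky = r_inplane * m - n %/% 2L,                   # grid units
    ky_idx = r_inplane * m + 1L,                      # 1-based row index
    line_times = te + (m - n_lines / 2) * esp,
    nav_times = te + (1:3 - 2) * esp,
    polarity = ifelse(m %% 2 == 0, 1, -1),
    nav_polarity = c(1, -1, 1),
    voxel_mm = fov_mm / n
  ), class = "sms_protocol")
  p
}

#' @export
print.sms_protocol <- function(x, ...) {
  cat(sprintf(
    "SMS-EPI protocol: %dx%d, %d slices, %d coils, MB=%d, R=%d, CAIPI=%s\n",
    x$n, x$n, x$n_slices, x$n_coils, x$mb, x$r_inplane, x$caipi))
  cat(sprintf("  TE/TR = %.1f/%.0f ms, esp = %.2f ms, sigma = %.4g\n",
              x$te * 1e3, x$tr * 1e3, x$esp * 1e3, x$sigma))
  invisible(x)
}

# slice indices of SMS group g (1-based)
slice_group <- function(protocol, g) {
  if (protocol$mb == 1L) return(g)
  c(g, g + protocol$n_slices %/% protocol$mb)
}

n_groups <- function(protocol) protocol$n_slices %/% protocol$mb

#' Simulation run configuration
#'
#' A single list holding every tunable of the simulation and analysis chain,
#' serialisable to YAML/JSON so any run is reproducible from its saved config
#' plus seeds.
#'
#' @param ... overrides for any default entry (unknown names are an error).
#' @return class `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    n = 64, n_slices = 4, n_coils = 8, mb = 2, r_inplane = 2, caipi = TRUE,
    te = 0.0254, tr = 1.282, esp = 6e-4, fov_mm = 120,
    sigma = 0.02, ghost_theta0 = 0.1, ghost_theta1 = 0.05,
    n_frames = 200, n_trials = 18, p_respond = 0.8,
    activation_amp = 0.02, hrf_peak = 3,
    field_amp = c(10, 15, 15), field_model = "smooth", mode = "physics",
    kernel_lambda = 1e-4, shift_width = 3,
    search_bound = 0.75, search_tol = 0.005, search_step = 0.05,
    z_thr = 3.1, highpass_s = 100, fwhm_mm = 3,
    seed = 1
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  structure(cfg, class = c("run_config", "list"))
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path file path ending in .yaml/.yml or .json.
#' @export
write_config <- function(config, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(unclass(config), path)
  }
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  lst <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  # an unquoted YAML key `n` (grid size) parses as the boolean FALSE
  names(lst)[names(lst) == "FALSE"] <- "n"
  do.call(run_config, lst)
}

#' @rdname run_config
#' @export
config_protocol <- function(config) {
  sms_protocol(n = config$n, n_slices = config$n_slices,
               n_coils = config$n_coils, mb = config$mb,
               r_inplane = config$r_inplane, caipi = config$caipi,
               te = config$te, tr = config$tr, esp = config$esp,
               fov_mm = config$fov_mm, sigma = config$sigma,
               ghost_theta0 = config$ghost_theta0,
               ghost_theta1 = config$ghost_theta1)
}

# short provenance hash of a config (used in output files)
config_hash <- function(config) {
  substr(rlang::hash(unclass(config)), 1, 12)
}
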