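# Shared fixtures, built lazily once per test run and cached.

.fx_env <- new.env(parent = emptyenv())

fx <- function(name) {
  if (!exists(name, envir = .fx_env)) {
    val <- switch(
      name,
      phantom = make_phantom(64, 4, seed = 1),
      phantom0 = make_phantom(64, 4, seed = 1, activation_amp = 0),
      coils = make_coil_maps(8, 64, seed = 1),
      proto0 = sms_protocol(sigma = 0, sigma_calib = 0),
      calib0 = acquire_calibration(fx("phantom0"), fx("coils"),
                                   fx("proto0"), sigma = 0),
      ops0 = train_recon_operators(fx("calib0"), fx("proto0")),
      # ghost-corrected reference navigator projection (zero field)
      navref0 = {
        fr <- acquire_frame(fx("phantom0")$img[, , c(1, 3)], fx("coils"),
                            c(0, 0, 0), fx("proto0"), "translate", sigma = 0)
        gh <- ghost_params_from_nav(fr$nav, fr$nav_polarity)
        smsb0:::mean_nav_projection(fr$nav, fr$nav_polarity, gh)
      },
      truth_mag = {
        ph <- fx("phantom0"); rss <- coil_rss(fx("coils"))
        arr <- array(0, c(ph$n, ph$n, ph$n_slices))
        for (s in seq_len(ph$n_slices)) arr[, , s] <- Mod(ph$img[, , s]) * rss
        arr
      },
      stop("unknown fixture: ", name))
    assign(name, val, envir = .fx_env)
  }
  get(name, envir = .fx_env)
}

# acquire a translate- or physics-mode group-1 frame with a given
# (phi0, dkx, dky) injection
inject_frame <- function(phi0 = 0, dkx = 0, dky = 0, mode = "translate",
                         sigma = 0, phantom = fx("phantom0"),
                         protocol = fx("proto0")) {
  st <- shift_to_field(c(phi0, dkx, dky), protocol$te)
  acquire_frame(phantom$img[, , c(1, 3)], fx("coils"), st, protocol,
                mode = mode, sigma = sigma)
}

# ghost-corrected mean navigator projection of a frame
nav_proj <- function(frame) {
  gh <- ghost_params_from_nav(frame$nav, frame$nav_polarity)
  smsb0:::mean_nav_projection(frame$nav, frame$nav_polarity, gh)
}

# full single-frame estimate against the zero-field reference
estimate_injected <- function(frame, op = fx("ops0")$shift_ky,
                              nav_ref = fx("navref0")) {
  estimate_frame_perturbation(nav_proj(frame), nav_ref, op)
}

# study configuration used by the multi-session acceptance blocks
acceptance_config <- function() {
  run_config(n_frames = 120, sigma = 0.006, n_trials = 10)
}

# the shared 10-session perturbed ensemble (expensive; cached)
acceptance_study <- function() {
  if (!exists("study10", envir = .fx_env)) {
    assign("study10",
           run_study(acceptance_config(), n_sessions = 10, seed = 100),
           envir = .fx_env)
  }
  get("study10", envir = .fx_env)
}
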