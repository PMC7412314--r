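#' Default beat-wave template
#'
#' Gaussian-bump morphology for one beat: per wave an amplitude (mV), a
#' Gaussian width (sigma, ms) and an offset from the R centre (ms).  These
#' are fixture constants chosen to look like a plausible sinus beat at the
#' millivolt scale -- not physiological claims.
#'
#' @return A data.frame with columns `wave`, `amp_mv`, `width_ms`,
#'   `offset_ms`.
#' @export
default_wave_set <- function() {
  data.frame(
    wave = c("P", "Q", "R", "S", "T"),
    amp_mv = c(0.15, -0.10, 1.00, -0.25, 0.30),
    width_ms = c(25, 10, 12, 10, 70),
    offset_ms = c(-160, -25, 0, 25, 300))
}

#' Synthetic ECG generator configuration
#'
#' States the world the generator emulates: quasi-periodic Gaussian
#' P-QRS-T beats with log-normal RR variability, optional sudden rate
#' changes, PVC-like wide low-amplitude beats, tall T waves, baseline wander,
#' powerline interference and white noise at a target SNR.
#'
#' @param duration_s Record duration in seconds.
#' @param fs Sampling frequency in Hz (default 360).
#' @param mean_hr_bpm Mean heart rate (default 72).
#' @param rr_cv Coefficient of variation of the RR interval (default 0.05).
#' @param rr_jump Optional list of `c(time_s, factor)` sudden mean-RR changes
#'   (the mean RR is multiplied by `factor` from `time_s` on).
#' @param wave_set Per-wave morphology table, see [default_wave_set].
#' @param r_amp_cv Beat-to-beat R-amplitude coefficient of variation.
#' @param pvc_rate Fraction of beats replaced by a PVC-like beat (R bump
#'   replaced by a 0.45 mV, 60 ms-wide bump, P wave dropped).
#' @param tall_t_rate Fraction of beats whose T amplitude is raised to
#'   0.85 x their R amplitude.
#' @param snr_db White-noise SNR in dB relative to the clean beat signal
#'   (`Inf` = no noise).
#' @param baseline Optional `c(amp_mv, freq_hz)` baseline wander
#'   (freq < 0.5 Hz).
#' @param powerline Optional `c(amp_mv, freq_hz)` powerline interference
#'   (50 or 60 Hz).
#' @param seed Integer seed; the same seed reproduces the sample series
#'   exactly.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(duration_s = 60, fs = 360, mean_hr_bpm = 72,
                         rr_cv = 0.05, rr_jump = NULL,
                         wave_set = default_wave_set(), r_amp_cv = 0.05,
                         pvc_rate = 0, tall_t_rate = 0, snr_db = Inf,
                         baseline = NULL, powerline = NULL, seed = NULL) {
  stopifnot(duration_s > 0, fs > 0, mean_hr_bpm > 0, rr_cv >= 0,
            r_amp_cv >= 0, pvc_rate >= 0, pvc_rate <= 1,
            tall_t_rate >= 0, tall_t_rate <= 1, all(wave_set$width_ms > 0))
  if (!is.null(baseline) && baseline[2L] >= 0.5)
    stop("baseline wander frequency must be < 0.5 Hz", call. = FALSE)
  if (!is.null(powerline) && fs <= 2 * powerline[2L])
    stop("need fs > 2 x powerline frequency", call. = FALSE)
  structure(list(duration_s = duration_s, fs = fs, mean_hr_bpm = mean_hr_bpm,
                 rr_cv = rr_cv, rr_jump = rr_jump, wave_set = wave_set,
                 r_amp_cv = r_amp_cv, pvc_rate = pvc_rate,
                 tall_t_rate = tall_t_rate, snr_db = snr_db,
                 baseline = baseline, powerline = powerline, seed = seed),
            class = "synth_config")
}

#' Named generator presets
#'
#' Fixed scenarios exercising each detector behaviour: `"clean"` (no noise,
#' no ectopy), `"pvc"` (20% PVC-like beats), `"tall_t"` (30% tall T waves),
#' `"noisy"` (10 dB white noise + 0.3 mV / 0.3 Hz baseline wander) and
#' `"rr_jump"` (mean RR drops to 0.65x halfway through).
#'
#' @param name Preset name.
#' @param duration_s Record duration in seconds.
#' @param seed Integer seed.
#' @return A [synth_config].
#' @export
synth_preset <- function(name = c("clean", "pvc", "tall_t", "noisy", "rr_jump"),
                         duration_s = 60, seed = NULL) {
  name <- match.arg(name)
  cfg <- synth_config(duration_s = duration_s, seed = seed)
  switch(name,
    clean = cfg,
    pvc = { cfg$pvc_rate <- 0.2; cfg },
    tall_t = { cfg$tall_t_rate <- 0.3; cfg },
    noisy = { cfg$snr_db <- 10; cfg$baseline <- c(0.3, 0.3); cfg },
    rr_jump = { cfg$rr_jump <- list(c(duration_s / 2, 0.65)); cfg })
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate an annotated synthetic ECG
#'
#' Each beat is a sum of Gaussian bumps placed at log-normally distributed RR
#' intervals; noise is added last.  Ground truth lists the exact R-centre
#' sample of every beat together with its type.
#'
#' @param config A [synth_config].
#' @return A list: `record` (an [ecg_record]), `truth` (a list with
#'   `annotations`, a [beat_annotations] of 0-based true R samples, and
#'   `types`, per-beat labels in `{"normal", "pvc", "tall_t"}`).
#' @export
generate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, generate_impl(config))
}

generate_impl <- function(cfg) {
  fs <- cfg$fs
  n <- as.integer(round(cfg$duration_s * fs))
  t_grid <- (seq_len(n) - 1L) / fs
  base_rr <- 60 / cfg$mean_hr_bpm

  rr_at <- function(tt) {
    m <- base_rr
    if (!is.null(cfg$rr_jump))
      for (j in cfg$rr_jump) if (tt >= j[1L]) m <- m * j[2L]
    m
  }
  draw_rr <- function(m) {
    if (cfg$rr_cv == 0) return(m)
    s2 <- log(1 + cfg$rr_cv^2)
    stats::rlnorm(1L, meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
  }

  # beat schedule: leave room for the P wave before the first R and the T
  # wave after the last
  lead_in <- 0.35
  t_r <- numeric(0)
  tt <- lead_in
  while (tt < cfg$duration_s - 0.6) {
    t_r <- c(t_r, tt)
    tt <- tt + draw_rr(rr_at(tt))
  }
  n_beats <- length(t_r)
  if (n_beats < 1L) stop("duration too short for a single beat", call. = FALSE)

  u <- stats::runif(n_beats)
  types <- rep("normal", n_beats)
  types[u < cfg$pvc_rate] <- "pvc"
  types[u >= cfg$pvc_rate & u < cfg$pvc_rate + cfg$tall_t_rate] <- "tall_t"
  r_scale <- 1 + cfg$r_amp_cv * stats::rnorm(n_beats)

  ws <- cfg$wave_set
  clean <- numeric(n)
  add_bump <- function(sig, centre_s, amp, sigma_s) {
    lo <- max(1L, as.integer(floor((centre_s - 4 * sigma_s) * fs)) + 1L)
    hi <- min(n, as.integer(ceiling((centre_s + 4 * sigma_s) * fs)) + 1L)
    if (hi < lo) return(sig)
    seg <- lo:hi
    sig[seg] <- sig[seg] + amp * exp(-((t_grid[seg] - centre_s)^2) /
                                       (2 * sigma_s^2))
    sig
  }
  for (b in seq_len(n_beats)) {
    waves <- ws
    r_row <- waves$wave == "R"
    waves$amp_mv[r_row] <- waves$amp_mv[r_row] * max(0.2, r_scale[b])
    if (types[b] == "pvc") {
      waves <- waves[waves$wave != "P", ]
      waves$amp_mv[waves$wave == "R"] <- 0.45
      waves$width_ms[waves$wave == "R"] <- 60
    } else if (types[b] == "tall_t") {
      waves$amp_mv[waves$wave == "T"] <- 0.85 * waves$amp_mv[waves$wave == "R"]
    }
    for (k in seq_len(nrow(waves))) {
      clean <- add_bump(clean, t_r[b] + waves$offset_ms[k] / 1000,
                        waves$amp_mv[k], waves$width_ms[k] / 1000)
    }
  }

  sig <- clean
  if (!is.null(cfg$baseline))
    sig <- sig + cfg$baseline[1L] *
      sin(2 * pi * cfg$baseline[2L] * t_grid + stats::runif(1L, 0, 2 * pi))
  if (!is.null(cfg$powerline))
    sig <- sig + cfg$powerline[1L] *
      sin(2 * pi * cfg$powerline[2L] * t_grid + stats::runif(1L, 0, 2 * pi))
  if (is.finite(cfg$snr_db)) {
    noise_sd <- sqrt(mean(clean^2) / 10^(cfg$snr_db / 10))
    sig <- sig + stats::rnorm(n, sd = noise_sd)
  }

  truth_idx <- as.integer(round(t_r * fs))
  list(record = ecg_record(sig, fs = fs, record_id = "synthetic"),
       truth = list(annotations = beat_annotations(truth_idx, labels = types,
                                                   record_length = n),
                    types = types))
}
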