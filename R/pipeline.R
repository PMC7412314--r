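#' Detector configuration
#'
#' All tunables of the five-stage pipeline in one flat object.  Defaults are
#' the reference configuration at any sampling rate: sample-count parameters
#' (accumulation width, window, search radius) are re-derived from their
#' millisecond definitions for the record's `fs`.
#'
#' @param taps,low_hz,high_hz Band-pass design, see [filter_spec].
#' @param transform_mode `"exact"` or `"taylor"`, see [transform_params].
#' @param qrs_duration_ms Accumulation width definition (ms).
#' @param clamp_negative Clamp the Taylor transform at 0.
#' @param window_ms Analysis window length (ms); also the refractory period.
#' @param a,b,th_min,m_factor,search_radius PD-threshold constants, see
#'   [pd_params].
#' @param init_scale,init_window_s Threshold initialisation rule.
#' @param k_divisor Tall-T rejection divisor K.
#' @param tall_t_enabled Enable the tall-T rejection stage.
#' @param tall_t_literal Use the literal larger-than comparison (see
#'   [resolve_tall_t]).
#' @param chunk_samples Analysis-unit size in samples (default `2^14`).
#' @param chunk_state `"persist"` carries the threshold state, RR tracker and
#'   a signal tail across chunk boundaries (streaming mode; seam-safe);
#'   `"reset"` re-initialises per chunk (independent analysis units).
#' @param report_compensation `"group_delay_only"` subtracts the filter group
#'   delay from reported positions; `"refine_to_raw_max"` additionally snaps
#'   each beat to the largest-magnitude raw sample within +/-36 ms.
#' @return Object of class `detector_config`.
#' @export
detector_config <- function(taps = 41L, low_hz = 5, high_hz = 15,
                            transform_mode = c("exact", "taylor"),
                            qrs_duration_ms = 120, clamp_negative = TRUE,
                            window_ms = 260, a = 0.5, b = 0.1, th_min = 0.15,
                            m_factor = 1.5, search_radius = NULL,
                            init_scale = 0.5, init_window_s = 2,
                            k_divisor = 3, tall_t_enabled = TRUE,
                            tall_t_literal = FALSE,
                            chunk_samples = 2^14,
                            chunk_state = c("persist", "reset"),
                            report_compensation = c("group_delay_only",
                                                    "refine_to_raw_max")) {
  structure(list(taps = as.integer(taps), low_hz = low_hz, high_hz = high_hz,
                 transform_mode = match.arg(transform_mode),
                 qrs_duration_ms = qrs_duration_ms,
                 clamp_negative = clamp_negative, window_ms = window_ms,
                 a = a, b = b, th_min = th_min, m_factor = m_factor,
                 search_radius = search_radius, init_scale = init_scale,
                 init_window_s = init_window_s, k_divisor = k_divisor,
                 tall_t_enabled = isTRUE(tall_t_enabled),
                 tall_t_literal = isTRUE(tall_t_literal),
                 chunk_samples = as.integer(chunk_samples),
                 chunk_state = match.arg(chunk_state),
                 report_compensation = match.arg(report_compensation)),
            class = "detector_config")
}

derive_runtime <- function(fs, config) {
  spec <- filter_spec(fs, taps = config$taps, low_hz = config$low_hz,
                      high_hz = config$high_hz)
  tp <- transform_params(fs, mode = config$transform_mode,
                         qrs_duration_ms = config$qrs_duration_ms,
                         clamp_negative = config$clamp_negative)
  pd <- pd_params(fs, a = config$a, b = config$b, th_min = config$th_min,
                  m_factor = config$m_factor,
                  search_radius = config$search_radius,
                  window_ms = config$window_ms,
                  init_scale = config$init_scale,
                  init_window_s = config$init_window_s)
  list(spec = spec, coeffs = design_bandpass(spec), tp = tp, pd = pd,
       context = tp$half_q, group_delay = (spec$taps - 1L) %/% 2L)
}

#' Map a filtered-signal position back to raw coordinates
#'
#' All detection happens in filtered-signal coordinates, which lag the raw
#' signal by the filter group delay ((taps-1)/2 = 20 samples by default).
#' `"group_delay_only"` subtracts that delay; `"refine_to_raw_max"`
#' additionally moves the position to the largest `|amplitude|` raw sample
#' within +/-36 ms.  Underflow is clipped to 0 with a warning.
#'
#' @param filtered_index 0-based position(s) in filtered coordinates.
#' @param group_delay Filter group delay in samples.
#' @param mode Compensation mode.
#' @param record Raw [ecg_record]; required for `"refine_to_raw_max"`.
#' @param refine_ms Refinement search half-width in milliseconds.
#' @return 0-based raw-coordinate position(s).
#' @export
compensate_position <- function(filtered_index, group_delay = 20L,
                                mode = c("group_delay_only",
                                         "refine_to_raw_max"),
                                record = NULL, refine_ms = 36) {
  mode <- match.arg(mode)
  raw <- filtered_index - group_delay
  if (any(raw < 0)) {
    warning("position(s) before the filter delay clipped to 0")
    raw <- pmax(raw, 0)
  }
  if (mode == "refine_to_raw_max") {
    if (is.null(record)) stop("`record` needed for refinement", call. = FALSE)
    rad <- as.integer(floor(refine_ms / 1000 * record$fs))
    n <- length(record$samples)
    raw <- vapply(raw, function(r0) {
      lo <- max(0L, r0 - rad)
      hi <- min(n - 1L, r0 + rad)
      seg <- record$samples[(lo:hi) + 1L]
      lo + which.max(abs(seg)) - 1L
    }, numeric(1))
  }
  raw
}

#' Detect QRS complexes in an ECG record
#'
#' Runs the five-stage pipeline -- band-pass filter, first difference,
#' exponential transform + accumulation, windowed extreme-point detection,
#' PD-controlled adaptive thresholding with refractory and tall-T-wave
#' rejection -- over the record, streaming it in chunks.  In `"persist"` mode
#' (default) signal tails, the threshold state and the RR tracker carry
#' across chunk seams, so the output is identical to processing the whole
#' record at once; `"reset"` mode re-initialises each analysis unit
#' independently.
#'
#' @param record An [ecg_record].
#' @param config A [detector_config].
#' @return Object of class `qrs_detection`: `beat_indices` (0-based raw
#'   sample positions, ascending), `beat_s` (feature value per beat),
#'   `trace` (per-window first-point threshold), `counters` (per-stage
#'   tallies), plus `fs`, `record_id`, `group_delay`.
#' @export
detect <- function(record, config = detector_config()) {
  stopifnot(inherits(record, "ecg_record"))
  rt <- derive_runtime(record$fs, config)
  n <- length(record$samples)
  if (n <= rt$pd$window_samples)
    stop("record shorter than one analysis window (",
         rt$pd$window_samples, " samples)", call. = FALSE)
  if (config$chunk_samples <= rt$pd$window_samples + 2L * rt$context)
    stop("chunk_samples must exceed window + 2*context", call. = FALSE)

  if (config$chunk_state == "reset" && n > config$chunk_samples) {
    return(detect_reset(record, config, rt))
  }

  eng <- new_engine(rt, config)
  starts <- seq.int(1L, n, by = config$chunk_samples)
  for (st in starts)
    engine_feed(eng, record$samples[st:min(st + config$chunk_samples - 1L, n)])
  engine_flush(eng)
  finalize_detection(eng, record, config, rt, offset0 = 0L)
}

# per-chunk independent analysis units (fresh filter, thresholds, RR tracker)
detect_reset <- function(record, config, rt) {
  n <- length(record$samples)
  w <- rt$pd$window_samples
  starts <- seq.int(1L, n, by = config$chunk_samples)
  ends <- pmin(starts + config$chunk_samples - 1L, n)
  if (length(starts) > 1L && (ends[length(ends)] - starts[length(starts)] + 1L) <= w) {
    ends[length(ends) - 1L] <- n         # fold a too-short tail into the
    starts <- starts[-length(starts)]    # previous unit
    ends <- ends[-length(ends)]
  }
  parts <- lapply(seq_along(starts), function(i) {
    sub <- ecg_record(record$samples[starts[i]:ends[i]], fs = record$fs,
                      record_id = record$record_id, lead = record$lead)
    eng <- new_engine(rt, config)
    engine_feed(eng, sub$samples)
    engine_flush(eng)
    finalize_detection(eng, sub, config, rt, offset0 = starts[i] - 1L)
  })
  merge_detections(parts, record, rt)
}

merge_detections <- function(parts, record, rt) {
  idx <- unlist(lapply(parts, `[[`, "beat_indices"))
  sv <- unlist(lapply(parts, `[[`, "beat_s"))
  o <- order(idx)
  idx <- idx[o]; sv <- sv[o]
  # enforce the refractory invariant across unit seams: of any pair closer
  # than one window, keep the larger-s beat
  keep_idx <- numeric(0); keep_s <- numeric(0)
  for (i in seq_along(idx)) {
    if (length(keep_idx) &&
        idx[i] - keep_idx[length(keep_idx)] < rt$pd$refractory_samples) {
      if (sv[i] > keep_s[length(keep_s)]) {
        keep_idx[length(keep_idx)] <- idx[i]
        keep_s[length(keep_s)] <- sv[i]
      }
    } else {
      keep_idx <- c(keep_idx, idx[i])
      keep_s <- c(keep_s, sv[i])
    }
  }
  counters <- Reduce(function(x, y) Map(`+`, x, y),
                     lapply(parts, `[[`, "counters"))
  structure(list(beat_indices = keep_idx, beat_s = keep_s,
                 trace = do.call(rbind, lapply(parts, `[[`, "trace")),
                 counters = counters, fs = record$fs,
                 record_id = record$record_id,
                 group_delay = rt$group_delay),
            class = "qrs_detection")
}

#' @export
print.qrs_detection <- function(x, ...) {
  cat(sprintf("<qrs_detection '%s': %d beats @ %g Hz>\n", x$record_id,
              length(x$beat_indices), x$fs))
  cat(sprintf("  stages: %d extremes -> %d candidates; %d refractory, %d tall-T rejected\n",
              x$counters$extremes, x$counters$candidates,
              x$counters$refractory_rejected, x$counters$tall_t_rejected))
  invisible(x)
}

#' Beat annotations of a detection result
#'
#' @param det A `qrs_detection`.
#' @return A [beat_annotations] of the detected 0-based raw positions.
#' @export
detection_annotations <- function(det) {
  stopifnot(inherits(det, "qrs_detection"))
  beat_annotations(det$beat_indices)
}

# ---------------------------------------------------------------------------
# Streaming engine.  Internal indices are 1-based; the public surface is
# 0-based.  All stages are causal with bounded look-ahead, so feeding chunks
# and flushing at end-of-record reproduces the whole-record result exactly.

new_engine <- function(rt, config) {
  e <- new.env(parent = emptyenv())
  e$rt <- rt
  e$config <- config
  e$x <- numeric(0)        # raw samples
  e$f <- numeric(0)        # filtered (causal, delay uncompensated)
  e$et <- numeric(0)       # exponential-transformed differences
  e$s <- numeric(0)        # accumulated feature signal (exact prefix)
  e$state <- NULL          # threshold state (NULL until initialised)
  e$tracker <- rr_tracker(config$k_divisor)
  e$next_win <- 1L
  e$bidx <- numeric(0)     # accepted beats, filtered coords (1-based)
  e$bs <- numeric(0)
  e$badd <- logical(0)     # did this beat add an RR interval to the tracker?
  e$last_entry_state <- NULL
  e$last_win <- NA_integer_
  e$trace_win <- numeric(0)
  e$trace_th <- numeric(0)
  e$counters <- list(extremes = 0L, candidates = 0L,
                     refractory_rejected = 0L, tall_t_rejected = 0L)
  e$final <- FALSE
  e
}

engine_feed <- function(e, new_samples) {
  e$x <- c(e$x, new_samples)
  engine_extend(e)
  engine_process(e)
}

engine_flush <- function(e) {
  e$final <- TRUE
  engine_extend(e)
  engine_process(e)
}

engine_extend <- function(e) {
  rt <- e$rt
  taps <- rt$spec$taps
  # filtered signal (causal FIR, exact for every emitted sample)
  if (length(e$x) > length(e$f)) {
    start <- length(e$f) + 1L
    pad <- min(start - 1L, taps - 1L)
    seg <- e$x[(start - pad):length(e$x)]
    fc <- causal_fir(seg, rt$coeffs)
    e$f <- c(e$f, fc[(pad + 1L):length(fc)])
  }
  # difference + exponential transform
  hi <- length(e$f) - 1L
  if (hi > length(e$et)) {
    rng <- (length(e$et) + 1L):hi
    d <- e$f[rng + 1L] - e$f[rng]
    tv <- exponential_transform(d, rt$tp)$values
    e$et <- c(e$et, tv)
  }
  # accumulated feature signal: s(n) is final once e(n + half_q) is known
  # (or at end of record, where the window zero-pads)
  s_hi <- if (e$final) length(e$et) else length(e$et) - rt$tp$half_q
  if (s_hi > length(e$s)) {
    cs <- c(0, cumsum(e$et))
    rng <- (length(e$s) + 1L):s_hi
    lo <- pmax(rng - rt$tp$half_q, 1L)
    up <- pmin(rng + rt$tp$half_q, length(e$et))
    e$s <- c(e$s, cs[up + 1L] - cs[lo])
  }
  # threshold initialisation once the startup stretch of s is visible
  if (is.null(e$state)) {
    need <- as.integer(rt$pd$init_window_s * rt$pd$fs)
    if (length(e$s) >= need || e$final)
      if (length(e$s)) e$state <- init_state(e$s, rt$pd)
  }
}

engine_process <- function(e) {
  rt <- e$rt
  if (is.null(e$state)) return(invisible())
  w <- rt$pd$window_samples
  ctx <- rt$context
  hq <- rt$tp$half_q
  sr <- rt$pd$search_radius
  repeat {
    ws <- e$next_win
    if (e$final) {
      if (ws > length(e$x)) break
    } else {
      we_full <- ws + w - 1L
      ready <- (we_full + ctx + hq <= length(e$f) - hq) &&
               (we_full + ctx + sr <= length(e$s))
      if (!ready) break
    }
    engine_window(e, ws)
    e$next_win <- ws + w
  }
  invisible()
}

engine_window <- function(e, ws) {
  rt <- e$rt
  we <- min(ws + rt$pd$window_samples - 1L, length(e$f))
  lo <- max(1L, ws - rt$context)
  hi <- min(we + rt$context, length(e$f))
  hq <- rt$tp$half_q
  slo <- max(1L, lo - hq)
  shi <- min(length(e$f), hi + hq)
  m <- extreme_mask(e$f[slo:shi], hq)
  ext1 <- which(m) + slo - 1L
  ext1 <- ext1[ext1 >= lo & ext1 <= hi]
  e$counters$extremes <- e$counters$extremes + length(ext1)

  e$trace_win <- c(e$trace_win, ws - 1L)
  e$trace_th <- c(e$trace_th, e$state$th_cur)

  entry_state <- e$state
  dec <- screen_window(ext1 - 1L, e$s, e$state, rt$pd, window_origin = ws - 1L,
                       f = e$f)
  if (!dec$detected) {
    e$state <- advance_threshold(e$state, rt$pd)
    return(invisible())
  }
  e$counters$candidates <- e$counters$candidates + 1L
  engine_candidate(e, dec$peak_index + 1L, dec$peak_feature, entry_state,
                   win = (ws - 1L) %/% rt$pd$window_samples + 1L)
}

replay_state <- function(st, k, pd) {
  for (i in seq_len(k)) st <- advance_threshold(st, pd)
  st
}

engine_candidate <- function(e, idx1, sval, entry_state, win) {
  pd <- e$rt$pd
  nb <- length(e$bidx)
  last <- if (nb) e$bidx[nb] else -Inf

  if (nb && idx1 == last) {  # same extreme seen again via shared context
    e$state <- advance_threshold(entry_state, pd)
    return(invisible())
  }

  if (nb && idx1 - last < pd$refractory_samples) {
    # refractory conflict with the previous beat: keep the larger-s one and
    # roll back the loser's threshold registration by replaying from the
    # state at its window entry; an exact s tie (adjacent extremes of the
    # same QRS sharing one search maximum) goes to the larger filtered
    # amplitude, i.e. the apex
    new_wins <- sval > e$bs[nb] ||
      (sval == e$bs[nb] && abs(e$f[idx1]) > abs(e$f[e$bidx[nb]]))
    if (new_wins) {
      st <- replay_state(e$last_entry_state, win - e$last_win, pd)
      e$state <- advance_threshold(register_detection(st, sval, pd), pd)
      if (e$badd[nb] && e$tracker$interval_count > 0L)
        e$tracker$sum <- e$tracker$sum + (idx1 - last)  # extend the interval
      e$bidx[nb] <- idx1
      e$bs[nb] <- sval
      e$last_entry_state <- st
      e$last_win <- win
    } else {
      e$state <- advance_threshold(entry_state, pd)
      e$counters$refractory_rejected <- e$counters$refractory_rejected + 1L
    }
    return(invisible())
  }

  # PD stage accepts: register, then let the tall-T stage arbitrate
  e$state <- advance_threshold(register_detection(entry_state, sval, pd), pd)

  cfg <- e$config
  fire <- FALSE
  if (nb && cfg$tall_t_enabled && e$tracker$interval_count >= 2L) {
    cutoff <- mean_rr(e$tracker) / e$tracker$k_divisor
    interval <- idx1 - last
    fire <- if (cfg$tall_t_literal) interval > cutoff else interval < cutoff
  }
  if (fire) {
    e$counters$tall_t_rejected <- e$counters$tall_t_rejected + 1L
    if (sval > e$bs[nb]) {  # previous beat was the tall T wave
      if (e$badd[nb]) e$tracker$sum <- e$tracker$sum + (idx1 - last)
      e$bidx[nb] <- idx1
      e$bs[nb] <- sval
      e$last_entry_state <- entry_state
      e$last_win <- win
    }
    # else: the new candidate is the tall T wave; drop it
    return(invisible())
  }

  added <- FALSE
  if (nb) {
    e$tracker <- update_mean_rr(e$tracker, idx1 - last)
    added <- TRUE
  }
  e$bidx <- c(e$bidx, idx1)
  e$bs <- c(e$bs, sval)
  e$badd <- c(e$badd, added)
  e$last_entry_state <- entry_state
  e$last_win <- win
  invisible()
}

finalize_detection <- function(e, record, config, rt, offset0 = 0L) {
  raw0 <- suppressWarnings(
    compensate_position(e$bidx - 1L, group_delay = rt$group_delay))
  keep <- raw0 >= rt$spec$taps - 1L          # drop initial-transient beats
  raw0 <- raw0[keep]
  sv <- e$bs[keep]
  if (config$report_compensation == "refine_to_raw_max" && length(raw0)) {
    raw0 <- compensate_position((raw0 + rt$group_delay), rt$group_delay,
                                mode = "refine_to_raw_max", record = record)
    o <- order(raw0)
    raw0 <- raw0[o]; sv <- sv[o]
    dup <- c(FALSE, diff(raw0) == 0)
    raw0 <- raw0[!dup]; sv <- sv[!dup]
  }
  structure(list(beat_indices = raw0 + offset0, beat_s = sv,
                 trace = data.frame(window_start = e$trace_win + offset0,
                                    threshold = e$trace_th),
                 counters = e$counters, fs = record$fs,
                 record_id = record$record_id,
                 group_delay = rt$group_delay),
            class = "qrs_detection")
}
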