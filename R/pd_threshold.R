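#' PD-control threshold parameters
#'
#' Constants of the proportional-derivative threshold recursion and candidate
#' screening.  Defaults are the reference empirical values: floor
#' `th_min = 0.15` (feature-signal units on mV-scale input), proportional
#' constant `a = 0.5`, derivative constant `b = 0.1`, candidate multiplier
#' `M = 1.5`, and a +/-15-point search radius at 360 Hz (rescaled by `fs` for
#' other rates).  The refractory period equals one analysis window (260 ms).
#'
#' @param fs Sampling frequency in Hz.
#' @param a Proportional constant, in (0, 1): pull toward the floor.
#' @param b Derivative constant, in `[0, 1)`: damping on the recent threshold
#'   change.
#' @param th_min Minimal threshold (floor), > 0.
#' @param m_factor Candidate multiplier M (>= 1).
#' @param search_radius Search half-width in samples around an extreme point
#'   (absorbs the differencing/accumulation delay); default `15 * fs / 360`,
#'   rounded.
#' @param window_ms Analysis window in milliseconds (sets `window_samples`
#'   and the refractory period).
#' @param init_scale,init_window_s Threshold initialisation: the starting
#'   threshold is `max(th_min, init_scale * max(s))` over the first
#'   `init_window_s` seconds.
#' @return Object of class `pd_params`.
#' @export
pd_params <- function(fs, a = 0.5, b = 0.1, th_min = 0.15, m_factor = 1.5,
                      search_radius = NULL, window_ms = 260,
                      init_scale = 0.5, init_window_s = 2) {
  if (!(a > 0 && a < 1)) stop("need 0 < a < 1", call. = FALSE)
  if (!(b >= 0 && b < 1)) stop("need 0 <= b < 1", call. = FALSE)
  if (!(th_min > 0)) stop("need th_min > 0", call. = FALSE)
  if (!(m_factor >= 1)) stop("need m_factor >= 1", call. = FALSE)
  if (is.null(search_radius)) search_radius <- as.integer(round(15 * fs / 360))
  window_samples <- as.integer(floor(window_ms / 1000 * fs))
  structure(list(fs = fs, a = a, b = b, th_min = th_min, m_factor = m_factor,
                 search_radius = as.integer(search_radius),
                 window_samples = window_samples,
                 refractory_samples = window_samples,
                 init_scale = init_scale, init_window_s = init_window_s),
            class = "pd_params")
}

new_threshold_state <- function(th_prev, th_cur, th_next) {
  structure(list(th_prev = th_prev, th_cur = th_cur, th_next = th_next),
            class = "threshold_state")
}

#' @export
print.threshold_state <- function(x, ...) {
  cat(sprintf("<threshold_state: TH[w-1]=%.4g TH[w]=%.4g TH[w+1]=%.4g>\n",
              x$th_prev, x$th_cur, x$th_next))
  invisible(x)
}

#' Initialise the threshold state from the feature signal
#'
#' The recursion's starting point is not part of the published constants; the
#' rule here sets the first two window thresholds to
#' `max(th_min, init_scale * max(s over the first init_window_s seconds))`
#' so that the first true beat (whose `s` is near that maximum) still clears
#' the `M = 1.5` multiplier while startup noise does not, and derives the
#' third by one application of the recursion.
#'
#' @param s A `feature_signal` (or bare numeric vector).
#' @param params A [pd_params].
#' @return A `threshold_state`.
#' @export
init_state <- function(s, params) {
  v <- if (inherits(s, "feature_signal")) s$values else as.numeric(s)
  if (!length(v)) stop("empty feature signal", call. = FALSE)
  head_n <- min(length(v), max(1L, as.integer(params$init_window_s * params$fs)))
  peak <- max(v[seq_len(head_n)])
  th0 <- max(params$th_min, params$init_scale * peak)
  st <- new_threshold_state(th0, th0, th0)
  st$th_next <- decay_step(th0, th0, params)   # one application of recursion
  st
}

# TH[w] = TH[w-1] - a (TH[w-1] - th_min) - b (TH[w-1] - TH[w-2])
decay_step <- function(th1, th2_back, params) {
  th1 - params$a * (th1 - params$th_min) - params$b * (th1 - th2_back)
}

#' Advance the threshold state by one window (no detection)
#'
#' The per-window tail of the recursion: the upcoming threshold is decayed,
#' `new th_next = th_next - a (th_next - th_min) - b (th_next - th_prev)`,
#' and the roles shift one window forward (`th_prev <- th_cur`,
#' `th_cur <- old th_next`).  With no detections the threshold decays
#' geometrically toward the floor `th_min`, which is a fixed point.
#'
#' @param state A `threshold_state`.
#' @param params A [pd_params].
#' @return The advanced `threshold_state`.
#' @export
advance_threshold <- function(state, params) {
  new_next <- decay_step(state$th_next, state$th_prev, params)
  new_threshold_state(state$th_cur, state$th_next, new_next)
}

#' Per-point threshold by linear interpolation
#'
#' The threshold at offset `k` into the current window interpolates linearly
#' between the window's first-point threshold and the next window's:
#' `th_cur - (th_cur - th_next) * k / window_samples`.
#'
#' @param state A `threshold_state`.
#' @param offset Sample offset (>= 0) of the point relative to the window's
#'   first sample.
#' @param window_samples Window length in samples.
#' @return The interpolated threshold value.
#' @export
point_threshold <- function(state, offset, window_samples) {
  if (any(offset < 0)) stop("offset must be >= 0", call. = FALSE)
  state$th_cur - (state$th_cur - state$th_next) * offset / window_samples
}

#' Screen a window's extreme points against the adaptive threshold
#'
#' An extreme point qualifies as a QRS candidate iff the maximum of the
#' feature signal over `+/- search_radius` samples around it (the search
#' absorbs the differencing/accumulation delay) exceeds `m_factor` times the
#' interpolated threshold at the extreme's window offset.  Among qualifying
#' extremes the one with the largest qualifying feature value is selected.
#'
#' @param extremes 0-based extreme-point indices (window plus context).
#' @param s A `feature_signal` (or bare numeric vector), full-record scale.
#' @param state A `threshold_state`.
#' @param params A [pd_params].
#' @param window_origin 0-based index of the window's first sample.
#' @param f Optional filtered signal (vector or `filtered_signal`): when two
#'   extremes of the same QRS share the search maximum, the one with the
#'   larger `|f|` (the actual apex) is preferred; without `f`, the one
#'   nearest the feature-energy peak.
#' @return A list (`candidate_decision`): `detected` flag, `peak_index`
#'   (0-based, or `NA`), `peak_feature` (the qualifying max of `s`).
#' @export
screen_window <- function(extremes, s, state, params, window_origin = 0L,
                          f = NULL) {
  v <- if (inherits(s, "feature_signal")) s$values else as.numeric(s)
  if (inherits(f, "filtered_signal")) f <- f$values
  best_idx <- NA_real_
  best_s <- -Inf
  best_tie <- -Inf
  for (e0 in extremes) {
    lo <- max(0L, e0 - params$search_radius)
    hi <- min(length(v) - 1L, e0 + params$search_radius)
    if (hi < lo) next
    seg <- v[(lo:hi) + 1L]
    smax <- max(seg)
    # adjacent extremes of one QRS-complex often share the same search
    # maximum; anchor on the dominant apex
    tie <- if (is.null(f)) -abs(lo + which.max(seg) - 1L - e0)
           else abs(f[e0 + 1L])
    off <- min(max(e0 - window_origin, 0L), params$window_samples)
    th <- point_threshold(state, off, params$window_samples)
    if (smax > params$m_factor * th &&
        (smax > best_s || (smax == best_s && tie > best_tie))) {
      best_s <- smax
      best_tie <- tie
      best_idx <- e0
    }
  }
  structure(list(detected = is.finite(best_s), peak_index = best_idx,
                 peak_feature = if (is.finite(best_s)) best_s else NA_real_),
            class = "candidate_decision")
}

#' Register a detection in the threshold state
#'
#' The detection branch of the per-window update: the current window's
#' first-point threshold is replaced by the detected candidate's feature
#' value, and the upcoming threshold is re-derived from it:
#' `th_cur <- peak_feature`;
#' `th_next <- th_cur - a (th_cur - th_min) - b (th_cur - th_prev)`.
#' The per-window shift ([advance_threshold]) is applied afterwards by the
#' pipeline, exactly mirroring the reference per-window update order.
#'
#' @param state A `threshold_state`.
#' @param peak_feature Feature value of the accepted candidate (> 0).
#' @param params A [pd_params].
#' @return The updated `threshold_state` (before the shift).
#' @export
register_detection <- function(state, peak_feature, params) {
  if (!is.numeric(peak_feature) || length(peak_feature) != 1L ||
      !is.finite(peak_feature) || peak_feature <= 0)
    stop("`peak_feature` must be a single positive number", call. = FALSE)
  th_cur <- peak_feature
  th_next <- th_cur - params$a * (th_cur - params$th_min) -
    params$b * (th_cur - state$th_prev)
  new_threshold_state(state$th_prev, th_cur, th_next)
}
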