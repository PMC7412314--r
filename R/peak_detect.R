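#' Plan the sliding-window tiling of a record
#'
#' The detector scans the filtered signal in consecutive, non-overlapping
#' windows of `floor(window_ms/1000 * fs)` samples (93 at 360 Hz for the
#' default 260 ms); the final partial window is retained.  A context of
#' `half_q` points before and after each window is searched too, so extreme
#' points at window edges are not missed.
#'
#' @param record_length Number of samples.
#' @param fs Sampling frequency in Hz.
#' @param window_ms Window length in milliseconds.
#' @param context Context width in samples; defaults to `floor(q/2)` of the
#'   default transform at this `fs`.
#' @return Object of class `window_plan`: a list with `origins` (0-based
#'   first-sample index of each window), `window_samples`, `context`.
#' @export
plan_windows <- function(record_length, fs, window_ms = 260, context = NULL) {
  window_samples <- as.integer(floor(window_ms / 1000 * fs))
  if (window_samples < 3L)
    stop("window too short (", window_samples, " samples)", call. = FALSE)
  if (record_length <= window_samples)
    stop("record (", record_length, " samples) shorter than one window (",
         window_samples, ")", call. = FALSE)
  if (is.null(context)) context <- transform_params(fs)$half_q
  origins <- seq.int(0L, record_length - 1L, by = window_samples)
  structure(list(origins = origins, window_samples = window_samples,
                 context = as.integer(context),
                 record_length = as.integer(record_length)),
            class = "window_plan")
}

# Logical mask of extreme points: v[n] is extreme iff
# (v[n]-v[n+j])*(v[n]-v[n-j]) > 0 for ALL j = 1..half (ties fail the strict
# inequality); points whose +/-half neighbourhood leaves the vector are FALSE.
extreme_mask <- function(v, half) {
  n <- length(v)
  ok <- rep(TRUE, n)
  if (half >= 1L) {
    ok[seq_len(min(half, n))] <- FALSE
    if (n > half) ok[seq.int(n - half + 1L, n)] <- FALSE else ok[] <- FALSE
    for (j in seq_len(half)) {
      if (!any(ok)) break
      fwd <- c(v[-seq_len(j)], rep(NA_real_, j))   # v[n + j]
      bwd <- c(rep(NA_real_, j), v[seq_len(n - j)]) # v[n - j]
      cond <- (v - fwd) * (v - bwd) > 0
      cond[is.na(cond)] <- FALSE
      ok <- ok & cond
    }
  }
  ok
}

#' Locate extreme points within each window
#'
#' A point `n` is an extreme point iff
#' `(f(n) - f(n+j)) * (f(n) - f(n-j)) > 0` for every `j = 1..half_q`, i.e. it
#' strictly dominates (or is dominated by) both sides at every lag, catching
#' both maxima and minima -- polarity is resolved later by the nonlinear
#' transform.  Each window is searched together with `context` points on
#' either side; points whose full neighbourhood leaves the record are
#' excluded.
#'
#' @param f A `filtered_signal` (or bare numeric vector).
#' @param plan A [plan_windows] result.
#' @param half_q Neighbourhood half-width; defaults to `plan$context`.
#' @return Object of class `extreme_set`: list with `per_window` (list of
#'   0-based index vectors, one per window) and `all` (sorted unique 0-based
#'   indices).
#' @export
find_extremes <- function(f, plan, half_q = NULL) {
  v <- if (inherits(f, "filtered_signal")) f$values else as.numeric(f)
  if (is.null(half_q)) half_q <- plan$context
  mask <- extreme_mask(v, half_q)
  ext1 <- which(mask)                       # 1-based
  per_window <- lapply(plan$origins, function(o1) {
    lo <- o1 + 1L - plan$context            # o1 is 0-based origin
    hi <- o1 + plan$window_samples + plan$context
    ext1[ext1 >= lo & ext1 <= hi] - 1L
  })
  structure(list(per_window = per_window, all = ext1 - 1L,
                 plan = plan), class = "extreme_set")
}
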