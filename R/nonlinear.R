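#' Nonlinear transform parameters
#'
#' The accumulation width `q` defaults to the sample count of a normal
#' QRS-complex duration (120 ms): `q = floor(0.120 * fs)`, i.e. 43 at 360 Hz.
#' The centred accumulation window spans `2 * floor(q/2) + 1` points.
#'
#' @param fs Sampling frequency in Hz.
#' @param mode `"exact"` for `|d| exp(-|d|)` or `"taylor"` for its first-order
#'   approximation `|d| - d^2` (hardware-parity variant).
#' @param qrs_duration_ms Accumulation width definition in milliseconds.
#' @param clamp_negative Clamp the Taylor variant at 0 where `|d| > 1` would
#'   make it negative (the exact transform is non-negative by construction).
#' @return An object of class `transform_params` with fields `mode`, `q`,
#'   `half_q`, `clamp_negative`.
#' @export
transform_params <- function(fs, mode = c("exact", "taylor"),
                             qrs_duration_ms = 120, clamp_negative = TRUE) {
  mode <- match.arg(mode)
  q <- max(1L, as.integer(floor(qrs_duration_ms / 1000 * fs)))
  structure(list(mode = mode, q = q, half_q = q %/% 2L,
                 clamp_negative = isTRUE(clamp_negative)),
            class = "transform_params")
}

#' Exponential transform
#'
#' Converts the signed differenced signal into a positive energy-like series:
#' exact mode `e(n) = |d(n)| exp(-|d(n)|)`, Taylor mode
#' `e(n) = |d(n)| - d(n)^2` (clamped at 0 by default).  The negative
#' exponential acts as an amplitude compressor whose compression ratio grows
#' with `|d|`, narrowing the height gap between large and small QRS peaks --
#' the property the adaptive threshold relies on to catch low-amplitude and
#' wide complexes.  `e` is even in `d`, so both polarities map to positive
#' peaks.
#'
#' @param d A `differenced_signal` (or bare numeric vector).
#' @param params A [transform_params].
#' @return Object of class `transformed_signal` with field `values`.
#' @export
exponential_transform <- function(d, params) {
  v <- if (inherits(d, "differenced_signal")) d$values else as.numeric(d)
  a <- abs(v)
  e <- if (params$mode == "exact") {
    a * exp(-a)
  } else {
    t <- a - a^2
    if (params$clamp_negative) pmax(t, 0) else t
  }
  structure(list(values = e), class = "transformed_signal")
}

#' Moving-window accumulation
#'
#' `s(n) = sum of e(i) for i in [n - half_q, n + half_q]` (zero-padded outside
#' the record): a centred box sum of width `2 * half_q + 1` that enhances and
#' smooths the transformed signal over one QRS duration.
#'
#' @param e A `transformed_signal` (or bare numeric vector).
#' @param params A [transform_params].
#' @return Object of class `feature_signal` with field `values`, same length
#'   as `e`.
#' @export
accumulate <- function(e, params) {
  v <- if (inherits(e, "transformed_signal")) e$values else as.numeric(e)
  structure(list(values = box_sum(v, params$half_q)), class = "feature_signal")
}

# centred box sum via cumulative sums; zero outside [1, n]
box_sum <- function(v, half) {
  n <- length(v)
  if (n == 0L) return(numeric(0))
  cs <- c(0, cumsum(v))
  hi <- pmin(seq_len(n) + half, n)
  lo <- pmax(seq_len(n) - half, 1L)
  cs[hi + 1L] - cs[lo]
}

#' Accumulated absolute value (comparison transform)
#'
#' Same centred accumulation applied to `|d|` instead of the exponential
#' transform; the amplitude deviation between peaks is preserved rather than
#' compressed.
#'
#' @inheritParams accumulate
#' @param d A `differenced_signal` (or bare numeric vector).
#' @return A `feature_signal`.
#' @export
abs_accumulate <- function(d, params) {
  v <- if (inherits(d, "differenced_signal")) d$values else as.numeric(d)
  structure(list(values = box_sum(abs(v), params$half_q)),
            class = "feature_signal")
}

#' Accumulated square (comparison transform)
#'
#' Centred accumulation of `d^2`; amplifies the amplitude deviation between
#' peaks (the opposite of the exponential transform's compression).
#'
#' @inheritParams abs_accumulate
#' @return A `feature_signal`.
#' @export
square_accumulate <- function(d, params) {
  v <- if (inherits(d, "differenced_signal")) d$values else as.numeric(d)
  structure(list(values = box_sum(v^2, params$half_q)),
            class = "feature_signal")
}
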