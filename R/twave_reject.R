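#' Running mean RR-interval tracker
#'
#' Tracks the arithmetic mean of accepted RR intervals within the analysed
#' data; the tall-T rejection stage compares candidate spacings against
#' `mean_rr / k_divisor` (default K = 3).
#'
#' @param k_divisor K, the divisor applied to the mean RR interval (>= 1).
#' @return Object of class `rr_tracker` with fields `sum`, `interval_count`,
#'   `k_divisor`; `mean_rr()` gives the current mean.
#' @export
rr_tracker <- function(k_divisor = 3) {
  if (!(k_divisor >= 1)) stop("need k_divisor >= 1", call. = FALSE)
  structure(list(sum = 0, interval_count = 0L, k_divisor = k_divisor),
            class = "rr_tracker")
}

#' Mean RR interval of a tracker
#' @param tracker An [rr_tracker].
#' @return Mean RR in samples, or `NA` before any interval is recorded.
#' @export
mean_rr <- function(tracker) {
  if (tracker$interval_count < 1L) return(NA_real_)
  tracker$sum / tracker$interval_count
}

#' Record an accepted RR interval
#'
#' @param tracker An [rr_tracker].
#' @param new_interval RR interval in samples (> 0).
#' @return The updated tracker.
#' @export
update_mean_rr <- function(tracker, new_interval) {
  if (!is.numeric(new_interval) || length(new_interval) != 1L ||
      !is.finite(new_interval) || new_interval <= 0)
    stop("`new_interval` must be a single positive number", call. = FALSE)
  tracker$sum <- tracker$sum + new_interval
  tracker$interval_count <- tracker$interval_count + 1L
  tracker
}

#' Resolve a possible tall-T pair of candidates
#'
#' When two successive QRS candidates fall closer than `mean_rr / K`, they are
#' taken to be the QRS-complex and the tall T wave of the same beat: the one
#' with the larger feature value `s` is kept, the other rejected (ties go to
#' the earlier candidate, which precedes its own T wave).  The rule is
#' inactive until at least two intervals have been observed; the tracker is
#' updated only with intervals between finally-kept beats.
#'
#' Note the `literal` flag flips the comparison to fire when the interval is
#' *larger* than `mean_rr / K` (the strictly literal reading of the reference
#' description); with typical rhythms that rejects nearly every normal beat,
#' so the default implements the rule consistent with its stated purpose.
#'
#' @param prev_beat List with `index` (0-based) and `s` for the earlier kept
#'   beat.
#' @param new_candidate Same structure for the newly arrived candidate; must
#'   be later than `prev_beat`.
#' @param tracker An [rr_tracker].
#' @param literal Use the literal larger-than comparison (default `FALSE`).
#' @return List: `kept` (list of kept beats in time order) and `tracker`
#'   (updated only when both beats are kept, with their interval).
#' @export
resolve_tall_t <- function(prev_beat, new_candidate, tracker, literal = FALSE) {
  if (new_candidate$index <= prev_beat$index)
    stop("candidates out of order", call. = FALSE)
  interval <- new_candidate$index - prev_beat$index
  fire <- FALSE
  if (tracker$interval_count >= 2L) {
    cutoff <- mean_rr(tracker) / tracker$k_divisor
    fire <- if (literal) interval > cutoff else interval < cutoff
  }
  if (fire) {
    kept <- if (new_candidate$s > prev_beat$s) list(new_candidate) else list(prev_beat)
    list(kept = kept, tracker = tracker, rejected = TRUE)
  } else {
    list(kept = list(prev_beat, new_candidate),
         tracker = update_mean_rr(tracker, interval), rejected = FALSE)
  }
}
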