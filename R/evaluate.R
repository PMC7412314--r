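#' Match detected beats against reference annotations
#'
#' Greedy one-to-one matching in ascending time: each reference beat is paired
#' with the nearest still-unmatched detection within `tolerance` samples
#' (ties toward the earlier detection).  Unmatched references count as false
#' negatives, unmatched detections as false positives.  Beats inside any
#' exclusion interval (half-open `[from, to)`, e.g. a ventricular-flutter
#' segment) are removed from both sides before matching.
#'
#' @param detected,reference [beat_annotations] (or bare 0-based index
#'   vectors), each strictly increasing.
#' @param tolerance Matching tolerance in samples (> 0).
#' @param exclusions Optional list of `c(from, to)` 0-based half-open
#'   intervals, or a 2-column matrix.
#' @return Object of class `match_result`: counts `tp`, `fp`, `fn` and a
#'   2-column matrix `pairs` of matched (detected, reference) indices.
#' @export
match_beats <- function(detected, reference, tolerance, exclusions = NULL) {
  det <- if (inherits(detected, "beat_annotations")) detected$indices else as.numeric(detected)
  ref <- if (inherits(reference, "beat_annotations")) reference$indices else as.numeric(reference)
  if (length(det) > 1L && any(diff(det) <= 0))
    stop("detected beats must be strictly increasing", call. = FALSE)
  if (length(ref) > 1L && any(diff(ref) <= 0))
    stop("reference beats must be strictly increasing", call. = FALSE)
  if (!is.numeric(tolerance) || tolerance <= 0)
    stop("`tolerance` must be > 0 samples", call. = FALSE)
  if (!is.null(exclusions)) {
    if (is.matrix(exclusions)) exclusions <- asplit(exclusions, 1L)
    for (iv in exclusions) {
      det <- det[det < iv[1L] | det >= iv[2L]]
      ref <- ref[ref < iv[1L] | ref >= iv[2L]]
    }
  }
  used <- rep(FALSE, length(det))
  pairs <- matrix(numeric(0), ncol = 2L,
                  dimnames = list(NULL, c("detected", "reference")))
  j0 <- 1L
  for (r in ref) {
    while (j0 <= length(det) && (used[j0] || det[j0] < r - tolerance))
      j0 <- j0 + 1L
    best <- 0L
    best_d <- Inf
    j <- j0
    while (j <= length(det) && det[j] <= r + tolerance) {
      if (!used[j]) {
        dd <- abs(det[j] - r)
        if (dd < best_d) {
          best_d <- dd
          best <- j
        }
      }
      j <- j + 1L
    }
    if (best > 0L) {
      used[best] <- TRUE
      pairs <- rbind(pairs, c(det[best], r))
    }
  }
  structure(list(tp = nrow(pairs), fp = sum(!used),
                 fn = length(ref) - nrow(pairs), pairs = pairs),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result: TP=%d FP=%d FN=%d>\n", x$tp, x$fp, x$fn))
  invisible(x)
}

round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Detection metrics: sensitivity, positive predictivity, accuracy
#'
#' `Se = TP/(TP+FN)`, `P+ = TP/(TP+FP)`, `Acc = TP/(TP+FP+FN)`, as
#' percentages.  Display values are rounded half-up to 2 decimals (the
#' conventional presentation); raw ratios are retained.  Zero denominators
#' give `NA` rather than an error.
#'
#' @param m A `match_result`, or a list/vector with elements `tp`, `fp`, `fn`.
#' @return Object of class `qrs_metrics`: fields `tp`, `fp`, `fn`, `se`,
#'   `ppv`, `acc` (rounded percentages) and `raw` (unrounded).
#' @export
compute_metrics <- function(m) {
  tp <- as.numeric(m[["tp"]])
  fp <- as.numeric(m[["fp"]])
  fn <- as.numeric(m[["fn"]])
  se <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  ppv <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  acc <- if (tp + fp + fn > 0) 100 * tp / (tp + fp + fn) else NA_real_
  structure(list(tp = tp, fp = fp, fn = fn,
                 se = round_half_up(se), ppv = round_half_up(ppv),
                 acc = round_half_up(acc),
                 raw = c(se = se, ppv = ppv, acc = acc)),
            class = "qrs_metrics")
}

#' @export
print.qrs_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "--" else sprintf("%.2f", v)
  cat(sprintf("<qrs_metrics: TP=%g FP=%g FN=%g | Se=%s%% P+=%s%% Acc=%s%%>\n",
              x$tp, x$fp, x$fn, fmt(x$se), fmt(x$ppv), fmt(x$acc)))
  invisible(x)
}

#' Reference benchmark score table
#'
#' Published per-record QRS-detection tallies (TP/FP/FN and derived Se/P+/Acc)
#' of the ET + PD-threshold detector on the 48-record MIT-BIH Arrhythmia
#' Database, plus the whole-database total and the two analysis-unit summary
#' rows ("unit_16384": 2^14-sample units; "unit_650000": whole records; both
#' exclude the 2-min ventricular-flutter segment of record 207).  Shipped as
#' a plain-text fixture and used to cross-check metric arithmetic.
#'
#' @return A data.frame with columns `record`, `total`, `tp`, `fp`, `fn`,
#'   `se`, `ppv`, `acc`.
#' @export
reference_scores <- function() {
  path <- system.file("extdata", "reference_scores.tsv", package = "etqrs",
                      mustWork = TRUE)
  utils::read.delim(path, colClasses = c(record = "character"))
}
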