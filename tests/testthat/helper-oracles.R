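# Independent brute-force oracles, kept deliberately naive and separate from
# the implementation paths they check.

# centred window sum by explicit loop
oracle_box_sum <- function(e, half) {
  n <- length(e)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in (i - half):(i + half)) if (j >= 1 && j <= n) acc <- acc + e[j]
    out[i] <- acc
  }
  out
}

# literal double-loop extreme-point criterion:
# (f(n)-f(n+j))*(f(n)-f(n-j)) > 0 for all j = 1..half
oracle_extremes <- function(v, half) {
  n <- length(v)
  out <- integer(0)
  for (i in seq_len(n)) {
    if (i - half < 1 || i + half > n) next
    ok <- TRUE
    for (j in 1:half) {
      if (!((v[i] - v[i + j]) * (v[i] - v[i - j]) > 0)) {
        ok <- FALSE
        break
      }
    }
    if (ok) out <- c(out, i)
  }
  out
}

# literal transcription of the per-window pseudocode tail (no-detection
# path), tracking the three first-point thresholds TH1/TH2/TH3; note the
# derivative term reaches back two windows (TH3 - TH1), which is what the
# pseudocode -- the normative form -- prescribes.  Returns the successive
# (TH1, TH2, TH3) triples.
oracle_pd_iterate <- function(n_windows, th1 = 1, th2 = 1, th3 = NULL,
                              a = 0.5, b = 0.1, th_min = 0.15) {
  if (is.null(th3))   # seed TH3 by one proportional step from TH2
    th3 <- th2 - a * (th2 - th_min) - b * (th2 - th1)
  out <- matrix(NA_real_, nrow = n_windows + 1L, ncol = 3L,
                dimnames = list(NULL, c("th1", "th2", "th3")))
  out[1L, ] <- c(th1, th2, th3)
  for (w in seq_len(n_windows)) {
    temp1 <- th3
    temp2 <- th2
    th3 <- th3 - a * (th3 - th_min) - b * (th3 - th1)
    th2 <- temp1
    th1 <- temp2
    out[w + 1L, ] <- c(th1, th2, th3)
  }
  out
}
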