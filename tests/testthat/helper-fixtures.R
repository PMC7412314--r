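# Hand-built records used by several test files.

gauss_bump <- function(sig, t_grid, centre_s, amp, sigma_s, fs) {
  n <- length(sig)
  lo <- max(1L, floor((centre_s - 4 * sigma_s) * fs) + 1L)
  hi <- min(n, ceiling((centre_s + 4 * sigma_s) * fs) + 1L)
  if (hi >= lo) {
    seg <- lo:hi
    sig[seg] <- sig[seg] + amp * exp(-((t_grid[seg] - centre_s)^2) /
                                       (2 * sigma_s^2))
  }
  sig
}

# Slow rhythm (RR 1100 ms) with a sharp tall T wave on every 4th beat: the
# tall T reliably fools the amplitude threshold, and meanRR/3 (367 ms)
# exceeds the 300 ms R-to-T spacing, so the rejection rule can fire.
make_tall_t_record <- function(duration_s = 120, fs = 360) {
  n <- as.integer(duration_s * fs)
  t_grid <- (seq_len(n) - 1L) / fs
  r_times <- seq(0.5, duration_s - 1, by = 1.1)
  tall <- seq_along(r_times) %% 4L == 0L
  x <- numeric(n)
  for (i in seq_along(r_times)) {
    x <- gauss_bump(x, t_grid, r_times[i], 1.0, 0.012, fs)
    x <- gauss_bump(x, t_grid, r_times[i] + 0.025, -0.25, 0.010, fs)
    if (tall[i]) {
      x <- gauss_bump(x, t_grid, r_times[i] + 0.300, 0.85, 0.025, fs)
    } else {
      x <- gauss_bump(x, t_grid, r_times[i] + 0.300, 0.30, 0.070, fs)
    }
  }
  list(record = ecg_record(x, fs, record_id = "tall_t_fixture"),
       truth = beat_annotations(round(r_times * fs)),
       n_tall = sum(tall))
}

ms_to_samples <- function(ms, fs = 360) as.integer(floor(ms / 1000 * fs))
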