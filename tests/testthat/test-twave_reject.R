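test_that("the RR tracker keeps a running arithmetic mean", {
  tr <- rr_tracker()
  expect_true(is.na(mean_rr(tr)))
  tr <- update_mean_rr(tr, 300)
  expect_equal(mean_rr(tr), 300)
  expect_equal(tr$interval_count, 1L)
  tr <- update_mean_rr(tr, 500)
  expect_equal(mean_rr(tr), 400)
  for (i in 1:10) tr2 <- update_mean_rr(rr_tracker(), 750)
  expect_equal(mean_rr(tr2), 750)
  expect_error(update_mean_rr(tr, 0), "positive")
  expect_error(rr_tracker(k_divisor = 0.5), "k_divisor")
})

test_that("resolve_tall_t keeps the larger-s candidate of a close pair", {
  fs <- 360
  tr <- update_mean_rr(update_mean_rr(rr_tracker(), 0.8 * fs), 0.8 * fs)
  # interval 200 ms << cutoff 800/3 ms: the 5.0 beat survives
  res <- resolve_tall_t(list(index = 1000, s = 5.0),
                        list(index = 1000 + 0.2 * fs, s = 1.2), tr)
  expect_true(res$rejected)
  expect_length(res$kept, 1L)
  expect_equal(res$kept[[1L]]$s, 5.0)
  # ... and symmetrically when the later beat is the QRS
  res2 <- resolve_tall_t(list(index = 1000, s = 1.2),
                         list(index = 1000 + 0.2 * fs, s = 5.0), tr)
  expect_equal(res2$kept[[1L]]$s, 5.0)
  # tie goes to the earlier candidate (the QRS precedes its T wave)
  res3 <- resolve_tall_t(list(index = 1000, s = 2),
                         list(index = 1000 + 0.2 * fs, s = 2), tr)
  expect_equal(res3$kept[[1L]]$index, 1000)

  # interval 700 ms > cutoff: both kept, interval recorded
  res4 <- resolve_tall_t(list(index = 1000, s = 5.0),
                         list(index = 1000 + 0.7 * fs, s = 4.0), tr)
  expect_false(res4$rejected)
  expect_length(res4$kept, 2L)
  expect_equal(res4$tracker$interval_count, 3L)

  # rule inactive before two intervals have been seen
  fresh <- update_mean_rr(rr_tracker(), 0.8 * fs)
  res5 <- resolve_tall_t(list(index = 1000, s = 5.0),
                         list(index = 1010, s = 0.1), fresh)
  expect_length(res5$kept, 2L)

  expect_error(resolve_tall_t(list(index = 50, s = 1),
                              list(index = 40, s = 1), tr), "order")
})

test_that("the literal comparison direction fires on ordinary intervals", {
  fs <- 360
  tr <- update_mean_rr(update_mean_rr(rr_tracker(), 0.8 * fs), 0.8 * fs)
  res <- resolve_tall_t(list(index = 0, s = 3),
                        list(index = 0.8 * fs, s = 2.9), tr, literal = TRUE)
  expect_true(res$rejected)                     # 800 ms > 267 ms cutoff
})

test_that("end to end, the stage removes tall-T false positives", {
  fx <- make_tall_t_record()
  d_on <- detect(fx$record)
  d_off <- detect(fx$record, detector_config(tall_t_enabled = FALSE))
  tol <- ms_to_samples(150)
  m_on <- compute_metrics(match_beats(detection_annotations(d_on), fx$truth, tol))
  m_off <- compute_metrics(match_beats(detection_annotations(d_off), fx$truth, tol))

  expect_gt(d_on$counters$tall_t_rejected, 0L)
  expect_lt(m_on$fp, m_off$fp)                  # strictly fewer FPs
  expect_equal(m_on$fn, m_off$fn)               # no sensitivity cost here
  # the stage is purely subtractive
  expect_lte(length(d_on$beat_indices), length(d_off$beat_indices))
  expect_true(all(d_on$beat_indices %in% d_off$beat_indices))
  # every kept consecutive gap clears the cutoff that was in force; with the
  # fixture's stable rhythm the final spacing is never below meanRR/3
  final_cutoff <- mean(diff(d_on$beat_indices)) / 3
  expect_true(all(diff(d_on$beat_indices) >= final_cutoff))
})
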