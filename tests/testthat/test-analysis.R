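test_that("mean rate is spike count over duration", {
  expect_equal(mean_rate(regular_train(13, n_pulses = 156)), 13,
               tolerance = 1e-3)
  expect_equal(mean_rate(spike_train(numeric(0), 10000)), 0)
})

test_that("binned sums partition the cumulative secretion", {
  q <- secretion_params()
  tr <- regular_train(13, duration_s = 72)
  ts <- simulate_secretion(tr, q, record_every = 100L)
  b <- binned_sums(ts, 18)
  expect_length(b, 4)  # 72 s in 18-s windows
  expect_equal(sum(b), ts$cum_x[nrow(ts)], tolerance = 1e-9)
  # decimated and full-resolution recordings agree exactly
  ts1 <- simulate_secretion(tr, q, record_every = 1L)
  expect_equal(binned_sums(ts1, 18), b, tolerance = 1e-12)
  expect_warning(binned_sums(ts, 100), "longer")
})

test_that("moving-average smoothing preserves mass and spreads impulses", {
  x <- rep(3.5, 5000)
  expect_equal(smooth_series(x, 1), x)
  imp <- c(rep(0, 2000), 7, rep(0, 2000))
  sm <- smooth_series(imp, 1)
  expect_equal(max(sm), 7 / 1001, tolerance = 1e-12)
  expect_equal(mean(sm), mean(imp), tolerance = 1e-12)
  # smoothing twice equals a triangular kernel: peak of double-smoothed
  # impulse matches the closed-form triangle apex
  sm2 <- smooth_series(sm, 1)
  expect_equal(max(sm2), 7 / 1001^2 * 1001, tolerance = 1e-6)
  expect_equal(mean(sm2), mean(imp), tolerance = 1e-12)
})

test_that("burst detector recovers known burst/silence structure", {
  tr <- burst_train(13, 72, 30, 1020)  # ten full cycles
  bs <- burst_stats(tr)
  expect_equal(bs$n_bursts, 10)
  expect_true(all(abs(bs$burst_durations_s - 72) <= 1))
  expect_true(all(abs(bs$silence_durations_s - 30) <= 1))
  expect_equal(bs$activity_quotient, 72 / 102, tolerance = 0.02)
  expect_true(all(abs(bs$intraburst_rates_hz - 13) < 0.5))
  # continuous regular train: one burst, AQ ~ 1
  bs2 <- burst_stats(regular_train(5, duration_s = 60))
  expect_equal(bs2$n_bursts, 1)
  expect_gt(bs2$activity_quotient, 0.95)
  # empty train
  bs3 <- burst_stats(spike_train(numeric(0), 10000))
  expect_equal(bs3$activity_quotient, 0)
  expect_equal(bs3$n_bursts, 0L)
})

test_that("secretion per spike ignores appended silent time", {
  q <- secretion_params()
  tail_s <- secretion_tail_s(q)
  tr1 <- regular_train(13, n_pulses = 156, tail_s = tail_s)
  tr2 <- regular_train(13, n_pulses = 156, tail_s = tail_s + 120)
  s1 <- secretion_per_spike(simulate_secretion(tr1, q, record_every = 1000L),
                            tr1)
  s2 <- secretion_per_spike(simulate_secretion(tr2, q, record_every = 1000L),
                            tr2)
  expect_equal(s1, s2, tolerance = 1e-4)
  expect_error(secretion_per_spike(
    simulate_secretion(spike_train(numeric(0), 1000), q),
    spike_train(numeric(0), 1000)), "no spikes")
})

test_that("frequency response is deterministic and ablations behave", {
  fr1 <- frequency_response(secretion_params(), c(5, 13, 25))
  fr2 <- frequency_response(secretion_params(), c(5, 13, 25))
  expect_identical(fr1, fr2)
  # removing the fast feedback (e_inhib ~ 1) removes the high-frequency
  # decline: the response keeps rising (oxytocin-like facilitation), within
  # a 1% slack for the residual slow fatigue at the top end
  q_noe <- secretion_params(e_theta = 1e6)
  fr3 <- frequency_response(q_noe, c(15, 25, 40, 60))
  expect_true(all(diff(fr3$pg_per_spike) > -0.01 * fr3$pg_per_spike[-4]))
  expect_gt(fr3$pg_per_spike[3], fr3$pg_per_spike[1])
  # spike broadening drives most of the low-rate facilitation: ablating it
  # collapses the 1->13 Hz rise several-fold
  q_nob <- secretion_params(k_b = 0)
  fr4 <- frequency_response(q_nob, c(1, 13))
  frd <- frequency_response(secretion_params(), c(1, 13))
  gain <- function(fr) fr$pg_per_spike[2] / fr$pg_per_spike[1]
  expect_gt(gain(frd), 3 * gain(fr4))
})
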