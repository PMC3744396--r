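test_that("calcium entry matches direct evaluation of the Hill forms", {
  q <- secretion_params()
  expect_equal(ca_entry(0, 0, 0, q), 0.5)
  expect_equal(ca_entry(0, 0.07, 0, q), 0.25)  # half-inhibition at threshold
  expect_equal(ca_entry(2, 0.03, 2.8, q),
               2.5 * (1 / (1 + (3 / 7)^5)) * 0.5, tolerance = 1e-12)
  expect_error(ca_entry(-1, 0, 0, q), "non-negative")
})

test_that("compiled stepper agrees with the plain-R reference", {
  q <- secretion_params(r_max = 2e4)  # small store so refill matters
  set.seed(5)
  spikes <- sort(sample(0:29999, 300))
  tr <- spike_train(spikes, 30000)
  ts <- simulate_secretion(tr, q)
  ref <- ref_secretion(spikes, 30000, q)
  for (ch in c("b", "c", "e", "x", "p", "r", "v"))
    expect_equal(ts[[ch]], unname(ref$series[, ch]), tolerance = 1e-12,
                 info = ch)
  expect_equal(attr(ts, "total_secreted"), ref$total, tolerance = 1e-12)
  # fatigue-off route agrees too
  ts0 <- simulate_secretion(tr, set_fatigue(q, FALSE))
  ref0 <- ref_secretion(spikes, 30000, q, fatigue = FALSE)
  expect_equal(ts0$x, unname(ref0$series[, "x"]), tolerance = 1e-12)
})

test_that("an empty train secretes nothing and leaves the pools full", {
  q <- secretion_params()
  ts <- simulate_secretion(spike_train(numeric(0), 5000), q)
  expect_true(all(ts$x == 0))
  expect_true(all(ts$p == q$p_max))
  expect_true(all(ts$r == q$r_max))
  expect_true(all(ts$v == 0))
})

test_that("secretion rate is the scaled cube of e times the pool", {
  # x = alpha * e^3 * p: e = 2, p = 5000, alpha = 5e-4 -> 20 pg/s
  expect_equal(5e-4 * 2^3 * 5000, 20)
  q <- secretion_params()
  tr <- spike_train(10, 1000)
  ts <- simulate_secretion(tr, q)
  i <- 11  # row holding the spike step; x uses the pre-depletion pool
  expect_equal(ts$x[i], q$alpha * ts$e[i]^3 * ts$p[i - 1], tolerance = 1e-9)
})

test_that("broadening plateau matches the geometric-series closed form", {
  tr <- regular_train(13, n_pulses = 520)  # 40 s
  ts <- simulate_secretion(tr, secretion_params())
  b_peak <- 0.05 / (1 - 2^(-(1000 / 13) / 2000))
  expect_equal(max(ts$b) + 0.5, b_peak + 0.5, tolerance = 0.01)
  expect_equal(max(ts$b) + 0.5, 2.40, tolerance = 0.01)
})

test_that("store accounting is conservative at every step", {
  q <- secretion_params(r_max = 5e4)
  tr <- burst_train(13, 40, 20, 300)
  ts <- simulate_secretion(tr, q)
  # (r_max - r) = cumulative refill; cumulative secretion = refill delivered
  # plus the pool deficit
  expect_equal(ts$cum_x, (q$r_max - ts$r) + (q$p_max - ts$p),
               tolerance = 1e-10)
  expect_lte(attr(ts, "total_secreted"), q$r_max + q$p_max)
  expect_equal(attr(ts, "total_refill"), q$r_max - ts$r[nrow(ts)],
               tolerance = 1e-6)
})

test_that("plasma compartment integrates and clears secretion", {
  # constant input reaches x * tau_v; silent input halves every lambda_v
  v <- plasma_concentration(rep(20, 1.2e6), dt_ms = 1, lambda_v = 120)
  expect_equal(v[length(v)], 20 * 120 / log(2), tolerance = 0.01)
  v2 <- plasma_concentration(rep(0, 120000), dt_ms = 1, lambda_v = 120,
                             v0 = 100)
  expect_equal(v2[120000], 50, tolerance = 0.01)
  expect_true(all(plasma_concentration(rep(0, 10), v0 = 0) == 0))
})

test_that("facilitation rises to the teens and declines at high frequency", {
  fr <- frequency_response(secretion_params(),
                           c(1, 3, 5, 7, 9, 11, 13, 20, 30, 40, 60))
  low <- fr$pg_per_spike[fr$freq_hz <= 13]
  high <- fr$pg_per_spike[fr$freq_hz >= 20]
  expect_true(all(diff(low) > 0))
  expect_true(all(diff(high) < 0))
})

test_that("sustained stimulation fatigues and silence restores the response", {
  q <- secretion_params()
  tr <- regular_train(13, duration_s = 72)
  ts <- simulate_secretion(tr, q, record_every = 100L)
  bins <- binned_sums(ts, 18)
  expect_length(bins, 4)
  expect_true(all(diff(bins) < 0))
  expect_gt(bins[1] / bins[4], 1.5)
  # without fatigue the same train secretes at least as much
  ts0 <- simulate_secretion(tr, set_fatigue(q, FALSE), record_every = 100L)
  expect_gte(attr(ts0, "total_secreted"), attr(ts, "total_secreted"))
  # two 40-s bursts separated by 20 s: the second burst's opening response
  # recovers towards the first burst's as c decays in the silence
  tr2 <- burst_train(13, 40, 20, 100)
  ts2 <- simulate_secretion(tr2, q, record_every = 100L)
  w <- binned_sums(ts2, 10)
  late_burst1 <- w[4]    # 30-40 s, fatigued
  open_burst2 <- w[7]    # 60-70 s, after recovery
  expect_gt(open_burst2, late_burst1)
  expect_gt(open_burst2 / w[1], 0.8)  # back towards the initial response
})

test_that("halving the integration step changes total secretion by < 2%", {
  q <- secretion_params()
  tr <- regular_train(13, duration_s = 60)
  t1 <- attr(simulate_secretion(tr, q, record_every = 1000L),
             "total_secreted")
  t05 <- attr(simulate_secretion(tr, q, dt_ms = 0.5, record_every = 2000L),
              "total_secreted")
  expect_lt(abs(t1 - t05) / t1, 0.02)
})

test_that("spike times outside the duration are rejected", {
  q <- secretion_params()
  expect_error(simulate_secretion(spike_train(c(10, 999), 1000), q), NA)
  tr <- spike_train(c(10, 999), 1000)
  tr$times <- c(10, 1500)  # corrupt past validation
  expect_error(simulate_secretion(tr, q), "outside")
})
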