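test_that("synaptic drive is Poisson with the configured rates", {
  p <- spiking_params(I_re = 600, I_ratio = 1)
  set.seed(42)
  ev <- synaptic_drive(p, 1000 * 1000)
  # mean 600k events; 3 SD band = 2324
  expect_lt(abs(sum(ev[, "e"]) - 6e5), 3 * sqrt(6e5))
  expect_lt(abs(sum(ev[, "i"]) - 6e5), 3 * sqrt(6e5))
  # zero rate gives zero events
  ev0 <- synaptic_drive(spiking_params(I_re = 0), 1000)
  expect_true(all(ev0 == 0))
  expect_error(synaptic_drive(p, 0), "positive")
})

test_that("simulation is deterministic given a seed and silent at zero input", {
  p <- spiking_params()
  a <- simulate_spiking(p, 60000, seed = 7)
  b <- simulate_spiking(p, 60000, seed = 7)
  expect_identical(a$times, b$times)
  expect_gt(length(a$times), 0)
  empty <- simulate_spiking(spiking_params(I_re = 0), 60000, seed = 7)
  expect_length(empty$times, 0)
})

test_that("quiescent membrane potential sits at the leak-on rest", {
  p <- spiking_params()
  st <- spiking_state(p)
  out <- step_spiking(st, p, n_e = 0, n_i = 0)
  expect_equal(unname(out["V"]), p$V_rest - p$g_L)
  expect_equal(unname(out["spiked"]), 0)
  # without the leak the cell rests at V_rest
  p0 <- spiking_params(g_L = 0)
  out0 <- step_spiking(spiking_state(p0), p0, 0, 0)
  expect_equal(unname(out0["V"]), p0$V_rest)
})

test_that("a spike triggers the full set of per-spike increments", {
  p <- spiking_params()
  st <- spiking_state(p)
  # drive over threshold with a volley of EPSPs
  out <- step_spiking(st, p, n_e = 8, n_i = 0)
  expect_equal(unname(out["spiked"]), 1)
  expect_equal(unname(out["HAP"]), p$k_HAP)
  expect_equal(unname(out["DAP"]), p$k_DAP)
  expect_equal(unname(out["C"]), p$C_rest + p$k_C)
  expect_equal(unname(out["D"]), p$k_D)
  # HAP enforces refractoriness on the next step
  out2 <- step_spiking(out[1:6], p, n_e = 8, n_i = 0)
  expect_equal(unname(out2["spiked"]), 0)
})

test_that("unstimulated decay follows the half-life closed form", {
  p <- spiking_params()
  st <- spiking_state(p)
  st["HAP"] <- 60; st["DAP"] <- 5; st["AHP"] <- 2
  st["C"] <- p$C_rest + 100; st["D"] <- 10
  n <- 10 * p$lambda_HAP
  cur <- st
  for (i in seq_len(n)) cur <- step_spiking(cur[1:6], p, 0, 0)[1:6]
  expect_equal(unname(cur["HAP"]), 60 * 2^(-n / p$lambda_HAP),
               tolerance = 0.01)
  expect_equal(unname(cur["DAP"]), 5 * 2^(-n / p$lambda_DAP),
               tolerance = 0.01)
  expect_equal(unname(cur["C"]) - p$C_rest, 100 * 2^(-n / p$lambda_C),
               tolerance = 0.01)
  expect_equal(unname(cur["D"]), 10 * 2^(-n / p$lambda_D),
               tolerance = 0.01)
})

test_that("mean firing rate is non-decreasing in input rate", {
  for (g in c(8.5, 0)) {
    rates <- sapply(c(100, 300, 600, 900), function(I) {
      mean(sapply(PROP_SEEDS, function(s) {
        mean_rate(simulate_spiking(spiking_params(I_re = I, g_L = g),
                                   300 * 1000, seed = s))
      }))
    })
    expect_true(all(diff(rates) >= 0),
                info = sprintf("g_L = %g, rates: %s", g,
                               paste(round(rates, 2), collapse = " ")))
  }
})

test_that("phasic firing emerges at default input; g_L = 0 fires continuously", {
  tr <- simulate_spiking(spiking_params(), 1000 * 1000, seed = 3)
  aq <- activity_quotient(tr)
  expect_gt(aq, 0.1)
  expect_lt(aq, 0.9)
  bs <- burst_stats(tr)
  expect_gt(bs$n_bursts, 3)
  tr0 <- simulate_spiking(spiking_params(g_L = 0), 1000 * 1000, seed = 3)
  expect_gt(activity_quotient(tr0), 0.9)
})

test_that("spike trains validate their invariants", {
  expect_error(spike_train(c(5, 3), 10), "increasing")
  expect_error(spike_train(c(3, 12), 10), "lie in")
  expect_error(spike_train(1, 0), "positive")
  tr <- spike_train(c(13, 26), 1000)
  expect_s3_class(tr, "spike_train")
})
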