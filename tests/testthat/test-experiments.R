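test_that("config validation fills defaults and reports every violation", {
  v <- validate_config(list())
  expect_length(v$errors, 0)
  expect_equal(v$config$spiking$I_re, 600)
  expect_equal(v$config$secretion$r_max, 1e6)
  # every problem reported, not just the first
  v2 <- validate_config(list(bogus = 1,
                             spiking = list(lambda_HAP = -1, nope = 2),
                             secretion = list(lambda_e = 0)))
  expect_gte(length(v2$errors), 3)
  expect_true(any(grepl("lambda_HAP", v2$errors)))
  expect_true(any(grepl("lambda_e", v2$errors)))
  expect_true(any(grepl("bogus", v2$errors)))
  # non-phasic and no-fatigue switches normalise into the parameter sets
  v3 <- validate_config(list(non_phasic = TRUE, no_fatigue = TRUE))
  expect_length(v3$errors, 0)
  expect_equal(v3$config$spiking$g_L, 0)
  expect_false(v3$config$secretion$fatigue_enabled)
  expect_true(any(grepl("unknown experiment",
                        validate_config(list(experiment = "fig99"))$errors)))
})

test_that("experiments write reproducible outputs with a manifest", {
  d1 <- file.path(tempdir(), "exp1"); d2 <- file.path(tempdir(), "exp2")
  t1 <- run_experiment("fig3_fatigue_bins", list(seed = 4), out_dir = d1)
  t2 <- run_experiment("fig3_fatigue_bins", list(seed = 4), out_dir = d2)
  f1 <- file.path(d1, "fig3_fatigue_bins_bins.csv")
  expect_true(file.exists(f1))
  expect_identical(readLines(f1),
                   readLines(file.path(d2, "fig3_fatigue_bins_bins.csv")))
  m <- jsonlite::read_json(file.path(d1, "fig3_fatigue_bins_manifest.json"))
  expect_equal(m$seed, 4)
  expect_equal(m$spiking$I_re, 600)
  expect_match(m$parameter_digest, "^[0-9a-f]{32}$")
  expect_true(all(diff(t1$bins$secretion_pg) < 0))
  expect_error(run_experiment("fig99"), "unknown experiment")
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("depletion experiment reproduces the store-limited regime", {
  tabs <- run_experiment("fig10_fast_depletion",
                         list(seed = 1, duration_s = 1530),
                         out_dir = tempdir())
  pb <- tabs$per_burst
  fat <- pb[pb$fatigue, ]
  nofat <- pb[!pb$fatigue, ]
  # without fatigue the response tracks the declining store from the start
  ratio <- nofat$secretion_pg[-1] / nofat$r_at_onset[-1]
  expect_lt(diff(range(ratio)) / mean(ratio), 0.1)
  # with fatigue the early response is store-independent by comparison
  early <- fat$secretion_pg[3:5]
  expect_lt(diff(range(early)) / mean(early), 0.02)
})

test_that("YAML configs round-trip into run configurations", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("experiment: fig3_freq_response",
               "seed: 3",
               "secretion:",
               "  r_max: 100000",
               "non_phasic: true"), path)
  cfg <- read_config(path)
  v <- validate_config(cfg)
  expect_length(v$errors, 0)
  expect_equal(v$config$secretion$r_max, 1e5)
  expect_equal(v$config$spiking$g_L, 0)
  unlink(path)
})
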