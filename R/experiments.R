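#' Tune the synaptic input rate for a target mean firing rate
#'
#' Bisection on the (stochastically monotone) input-output curve of the
#' spiking model. Used to generate model spike trains at prescribed mean
#' rates, e.g. for pattern-efficiency comparisons.
#'
#' @param target_hz Desired mean firing rate (Hz).
#' @param params \code{\link{spiking_params}} template.
#' @param duration_s Calibration run length per probe (s).
#' @param seed Seed for the probe runs.
#' @param lo,hi Input-rate bracket (Hz).
#' @param iters Bisection iterations.
#' @return Input rate in Hz.
#' @export
tune_input_rate <- function(target_hz, params = spiking_params(),
                            duration_s = 300, seed = 1,
                            lo = 50, hi = 1500, iters = 8) {
  rate_at <- function(I) {
    p <- params; p$I_re <- I
    mean_rate(simulate_spiking(p, duration_s * 1000, seed = seed))
  }
  for (k in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (rate_at(mid) < target_hz) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

.known_experiments <- c(
  "fig2_burst_recovery", "fig3_freq_response", "fig3_fatigue_bins",
  "fig4_burst_vs_regular", "fig5_pattern_efficiency",
  "fig6_single_cell_sweep", "fig8_population_sweep",
  "fig10_fast_depletion", "fig11_long_depletion",
  "fig12_population_depletion")

#' Validate and normalise a run configuration
#'
#' Fills defaults (the standard single-cell parameter tables), applies
#' overrides, and reports every violation rather than stopping at the
#' first. Unknown keys are rejected.
#'
#' @param config Named list, e.g. parsed from a YAML file: optional
#'   elements \code{experiment}, \code{seed}, \code{duration_s},
#'   \code{no_fatigue}, \code{non_phasic}, \code{out_dir}, and named
#'   override lists \code{spiking}, \code{secretion}, \code{population},
#'   \code{protocol}.
#' @return List with elements \code{config} (normalised: full
#'   \code{spiking_params}, \code{secretion_params}, etc.) and
#'   \code{errors} (character vector; empty when valid).
#' @export
validate_config <- function(config = list()) {
  errors <- character()
  known_top <- c("experiment", "seed", "duration_s", "no_fatigue",
                 "non_phasic", "out_dir", "spiking", "secretion",
                 "population", "protocol")
  unknown <- setdiff(names(config), known_top)
  if (length(unknown))
    errors <- c(errors, paste0("unknown config key(s): ",
                               paste(unknown, collapse = ", ")))

  check_overrides <- function(ov, builder, label) {
    ok <- names(formals(builder))
    bad <- setdiff(names(ov), ok)
    if (length(bad)) {
      errors <<- c(errors, paste0("unknown ", label, " parameter(s): ",
                                  paste(bad, collapse = ", ")))
      ov <- ov[intersect(names(ov), ok)]
    }
    tryCatch(do.call(builder, ov),
             error = function(e) {
               errors <<- c(errors, paste0(label, ": ", conditionMessage(e)))
               do.call(builder, list())
             })
  }
  sp <- check_overrides(config$spiking %||% list(), spiking_params,
                        "spiking")
  se <- check_overrides(config$secretion %||% list(), secretion_params,
                        "secretion")
  if (isTRUE(config$non_phasic)) sp$g_L <- 0
  if (isTRUE(config$no_fatigue)) se <- set_fatigue(se, FALSE)

  pop_defaults <- list(n_cells = 100, I_pop = 460, sigma = 0.5,
                       scale_to = 9000)
  pop <- utils::modifyList(pop_defaults, config$population %||% list())
  bad_pop <- setdiff(names(pop), c(names(pop_defaults), "seed"))
  if (length(bad_pop))
    errors <- c(errors, paste0("unknown population parameter(s): ",
                               paste(bad_pop, collapse = ", ")))

  proto_defaults <- list(kind = "regular", frequency_hz = 13,
                         n_pulses = NULL, burst_s = 72, silence_s = 30,
                         total_s = NULL)
  proto <- utils::modifyList(proto_defaults, config$protocol %||% list())
  if (!proto$kind %in% c("regular", "burst_train", "fixed_pulse_count",
                         "model_generated"))
    errors <- c(errors, paste0("unknown protocol kind: ", proto$kind))

  if (!is.null(config$experiment) &&
      !config$experiment %in% .known_experiments)
    errors <- c(errors, paste0("unknown experiment: ", config$experiment,
                               " (known: ",
                               paste(.known_experiments, collapse = ", "),
                               ")"))
  seed <- config$seed %||% 1
  if (!is.numeric(seed) || length(seed) != 1)
    errors <- c(errors, "seed must be a single number")

  list(config = list(experiment = config$experiment,
                     seed = seed,
                     duration_s = config$duration_s,
                     out_dir = config$out_dir %||% ".",
                     spiking = sp, secretion = se,
                     population = pop, protocol = proto),
       errors = errors)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a named experiment
#'
#' Config-driven drivers reproducing the package's figure-level protocols:
#' burst recovery, secretion frequency response, fatigue bins, burst vs
#' regular stimulation, pattern efficiency, single-cell and population
#' input sweeps, and accelerated/long-term store depletion. Each run writes
#' its result tables as CSV plus a JSON manifest (inputs, seed, parameter
#' digest) sufficient to reproduce it, and returns the tables invisibly.
#'
#' Long protocols default to scaled-down durations; set
#' \code{config$duration_s} for full-length runs.
#'
#' @param name Experiment name; one of
#'   \code{fig2_burst_recovery, fig3_freq_response, fig3_fatigue_bins,
#'   fig4_burst_vs_regular, fig5_pattern_efficiency, fig6_single_cell_sweep,
#'   fig8_population_sweep, fig10_fast_depletion, fig11_long_depletion,
#'   fig12_population_depletion}.
#' @param config Named list of overrides (see \code{\link{validate_config}}).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of data frames (also written as CSV).
#' @export
run_experiment <- function(name, config = list(), out_dir = NULL) {
  config$experiment <- name
  v <- validate_config(config)
  if (length(v$errors))
    stop("invalid configuration:\n  ", paste(v$errors, collapse = "\n  "))
  cfg <- v$config
  out_dir <- out_dir %||% cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  set.seed(cfg$seed)
  tables <- switch(
    name,
    fig2_burst_recovery = .exp_burst_recovery(cfg),
    fig3_freq_response = .exp_freq_response(cfg),
    fig3_fatigue_bins = .exp_fatigue_bins(cfg),
    fig4_burst_vs_regular = .exp_burst_vs_regular(cfg),
    fig5_pattern_efficiency = .exp_pattern_efficiency(cfg),
    fig6_single_cell_sweep = .exp_single_cell_sweep(cfg),
    fig8_population_sweep = .exp_population_sweep(cfg),
    fig10_fast_depletion = .exp_fast_depletion(cfg),
    fig11_long_depletion = .exp_long_depletion(cfg),
    fig12_population_depletion = .exp_population_depletion(cfg))

  for (nm in names(tables))
    utils::write.csv(tables[[nm]],
                     file.path(out_dir, paste0(name, "_", nm, ".csv")),
                     row.names = FALSE, quote = FALSE)

  par_file <- tempfile()
  writeLines(c(deparse(cfg$spiking[order(names(cfg$spiking))]),
               deparse(cfg$secretion[order(names(cfg$secretion))])),
             par_file)
  manifest <- list(experiment = name, seed = cfg$seed,
                   duration_s = cfg$duration_s,
                   parameter_digest = unname(tools::md5sum(par_file)),
                   spiking = cfg$spiking[seq_along(cfg$spiking)],
                   secretion = cfg$secretion[seq_along(cfg$secretion)],
                   outputs = paste0(name, "_", names(tables), ".csv"))
  unlink(par_file)
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0(name, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(tables)
}

.exp_burst_recovery <- function(cfg) {
  tr <- burst_train(13, 40, 20, 100)
  ts <- simulate_secretion(tr, cfg$secretion, record_every = 100L)
  w <- binned_sums(ts, 10)
  list(timeseries = as.data.frame(ts)[
    c("time_ms", "b", "c", "e", "x", "p", "r", "v")],
    summary = data.frame(window_s = 10 * seq_along(w), secretion_pg = w))
}

.exp_freq_response <- function(cfg) {
  fr <- frequency_response(cfg$secretion, 1:60)
  list(response = fr,
       summary = data.frame(peak_hz = fr$freq_hz[which.max(fr$pg_per_spike)]))
}

.exp_fatigue_bins <- function(cfg) {
  tr <- regular_train(13, duration_s = 72)
  ts <- simulate_secretion(tr, cfg$secretion, record_every = 100L)
  b <- binned_sums(ts, 18)
  list(bins = data.frame(bin = seq_along(b), start_s = 18 * (seq_along(b) - 1),
                         secretion_pg = b))
}

.exp_burst_vs_regular <- function(cfg) {
  # model-generated phasic activity; take a 32-s window from a burst onset
  tr <- simulate_spiking(cfg$spiking, 600 * 1000, seed = cfg$seed)
  bs <- burst_stats(tr)
  if (bs$n_bursts == 0) stop("no bursts found; increase duration or input")
  t_s <- tr$times / 1000
  breaks <- which(diff(t_s) >= 0.5)
  starts_idx <- c(1L, breaks + 1L)
  lens <- c(breaks, length(t_s)) - starts_idx + 1L
  onset <- tr$times[starts_idx[which.max(lens)]]
  win <- tr$times[tr$times >= onset & tr$times < onset + 32000] - onset
  patterned <- spike_train(win, 32000)
  pair <- matched_mean_rate_pair(patterned)
  tail_s <- secretion_tail_s(cfg$secretion)
  run1 <- function(t) {
    t2 <- spike_train(t$times, t$duration_ms + tail_s * 1000)
    ts <- simulate_secretion(t2, cfg$secretion, record_every = 100L)
    binned_sums(ts, 10)[1:3]
  }
  list(summary = data.frame(
    window_s = c(10, 20, 30),
    regular_pg = run1(pair$regular),
    patterned_pg = run1(pair$patterned),
    mean_rate_hz = mean_rate(patterned)))
}

.exp_pattern_efficiency <- function(cfg) {
  dur_s <- cfg$duration_s %||% 900
  rates <- 1:8
  sp_np <- cfg$spiking; sp_np$g_L <- 0
  rows <- lapply(rates, function(r) {
    I_ph <- tune_input_rate(r, cfg$spiking, seed = cfg$seed)
    I_np <- tune_input_rate(r, sp_np, seed = cfg$seed)
    p1 <- cfg$spiking; p1$I_re <- I_ph
    p2 <- sp_np; p2$I_re <- I_np
    tr_ph <- simulate_spiking(p1, dur_s * 1000, seed = cfg$seed + 100)
    tr_np <- simulate_spiking(p2, dur_s * 1000, seed = cfg$seed + 200)
    tr_rg <- regular_train(r, duration_s = dur_s)
    tot <- function(tr) attr(simulate_secretion(
      tr, cfg$secretion, record_every = 1000L), "total_secreted")
    data.frame(target_hz = r,
               phasic_hz = mean_rate(tr_ph), nonphasic_hz = mean_rate(tr_np),
               phasic_pg = tot(tr_ph), nonphasic_pg = tot(tr_np),
               regular_pg = tot(tr_rg))
  })
  res <- do.call(rbind, rows)
  list(efficiency = res,
       summary = data.frame(
         phasic_optimum_hz = res$phasic_hz[which.max(res$phasic_pg)]))
}

.exp_single_cell_sweep <- function(cfg) {
  dur_s <- cfg$duration_s %||% 300
  sp <- population_spec(n_cells = 1, I_pop = 0, sigma = 0, scale_to = 1,
                        seed = cfg$seed)
  sw <- input_sweep(seq(100, 1000, by = 100), sp, cfg$spiking,
                    cfg$secretion, duration_s = dur_s)
  list(sweep = sw)
}

.exp_population_sweep <- function(cfg) {
  dur_s <- cfg$duration_s %||% 300
  n <- cfg$population$n_cells %||% 100
  grid <- seq(100, 1000, by = 100)
  run_pop <- function(sigma) {
    sp <- population_spec(n_cells = n, I_pop = 0, sigma = sigma,
                          scale_to = cfg$population$scale_to,
                          seed = cfg$seed)
    sw <- input_sweep(grid, sp, cfg$spiking, cfg$secretion,
                      duration_s = dur_s)
    sw$sigma <- sigma
    sw
  }
  het <- run_pop(cfg$population$sigma)
  hom <- run_pop(0)
  r2 <- function(sw) summary(stats::lm(total_secretion_pg ~ I_pop,
                                       data = sw))$r.squared
  list(heterogeneous = het, homogeneous = hom,
       summary = data.frame(r2_heterogeneous = r2(het),
                            r2_homogeneous = r2(hom)))
}

.per_burst_table <- function(ts, burst_s, silence_s, total_s, r_init) {
  cyc <- burst_s + silence_s
  nb <- floor(total_s / cyc)
  rec_s <- attr(ts, "record_ms") / 1000
  # row i holds state at time i * rec_s; time 0 is the initial state
  cum_at <- function(t_s) {
    v <- ts$cum_x[pmax(1L, pmin(nrow(ts), round(t_s / rec_s)))]
    v[t_s <= 0] <- 0
    v
  }
  r_at <- function(t_s) {
    v <- ts$r[pmax(1L, pmin(nrow(ts), round(t_s / rec_s)))]
    v[t_s <= 0] <- r_init
    v
  }
  onset <- (seq_len(nb) - 1) * cyc
  data.frame(burst = seq_len(nb), onset_s = onset,
             secretion_pg = cum_at(onset + burst_s) - cum_at(onset),
             r_at_onset = r_at(onset))
}

.exp_fast_depletion <- function(cfg) {
  total_s <- cfg$duration_s %||% 3600
  se <- cfg$secretion
  se$r_max <- 1e5
  tr <- burst_train(13, 72, 30, total_s)
  out <- lapply(c(TRUE, FALSE), function(fat) {
    ts <- simulate_secretion(tr, set_fatigue(se, fat),
                             init = secretion_state(se),
                             record_every = 100L)
    tab <- .per_burst_table(ts, 72, 30, total_s, se$r_max)
    tab$fatigue <- fat
    tab
  })
  list(per_burst = do.call(rbind, out))
}

.exp_long_depletion <- function(cfg) {
  total_s <- cfg$duration_s %||% 86400
  tr <- simulate_spiking(cfg$spiking, total_s * 1000, seed = cfg$seed)
  ts <- simulate_secretion(tr, cfg$secretion, record_every = 1000L)
  hours <- binned_sums(ts, 3600)
  list(hourly = data.frame(hour = seq_along(hours), secretion_pg = hours),
       summary = data.frame(mean_rate_hz = mean_rate(tr),
                            final_r = attr(ts, "final_state")[["r"]]))
}

.exp_population_depletion <- function(cfg) {
  total_s <- cfg$duration_s %||% 86400
  sp <- population_spec(n_cells = cfg$population$n_cells,
                        I_pop = cfg$population$I_pop %||% 400,
                        sigma = cfg$population$sigma,
                        scale_to = cfg$population$scale_to,
                        seed = cfg$seed)
  res <- simulate_population(sp, cfg$spiking, cfg$secretion,
                             duration_s = total_s)
  list(cells = res$cells,
       summed = data.frame(time_s = seq_along(res$x_sum) *
                             res$record_ms / 1000,
                           x_sum = res$x_sum, v_sum = res$v_sum))
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file path.
#' @return Parsed configuration list (not yet validated).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}
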