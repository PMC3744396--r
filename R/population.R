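#' Sample synaptic input densities
#'
#' Per-cell synaptic density multipliers drawn from a lognormal
#' distribution whose underlying normal has mean 0 and standard deviation
#' \code{sigma}, so the median multiplier is 1.
#'
#' @param n Number of cells.
#' @param sigma Spread of the underlying normal (default 0.5).
#' @param seed Optional seed.
#' @return Numeric vector of positive multipliers.
#' @export
sample_input_densities <- function(n, sigma = 0.5, seed = NULL) {
  if (n < 1) stop("n must be at least 1")
  if (sigma < 0) stop("sigma must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  exp(stats::rnorm(n, 0, sigma))
}

#' Population specification
#'
#' @param n_cells Number of simulated cells.
#' @param I_pop Population synaptic input rate (Hz); each cell receives
#'   \code{I_re = I_pop * I_syn}.
#' @param sigma Lognormal spread of the per-cell densities; 0 gives a
#'   homogeneous population.
#' @param scale_to Full-population size the summed output is scaled to
#'   (default 9000 magnocellular neurons).
#' @param seed Master seed; cell i is simulated with seed
#'   \code{seed + i} and the densities with \code{seed}.
#' @param I_syn Optional explicit density multipliers (overrides sampling).
#' @return Object of class \code{population_spec}.
#' @export
population_spec <- function(n_cells = 100, I_pop = 460, sigma = 0.5,
                            scale_to = 9000, seed = 1, I_syn = NULL) {
  if (n_cells < 1) stop("n_cells must be at least 1")
  if (I_pop < 0) stop("I_pop must be non-negative")
  if (!is.null(I_syn)) {
    if (length(I_syn) != n_cells) stop("I_syn length must equal n_cells")
    if (any(I_syn <= 0)) stop("I_syn must be positive")
  }
  structure(list(n_cells = n_cells, I_pop = I_pop, sigma = sigma,
                 scale_to = scale_to, seed = seed, I_syn = I_syn),
            class = "population_spec")
}

#' Simulate a heterogeneous cell population
#'
#' Simulates \code{n_cells} independent neurons, each with synaptic input
#' rate \code{I_pop * I_syn[i]} and its own derived seed
#' (\code{seed + i}), optionally coupling each spike train to the secretion
#' model. The summed secretion-rate series is scaled by
#' \code{scale_to / n_cells} to represent the full population.
#'
#' @param spec \code{\link{population_spec}}.
#' @param spiking \code{\link{spiking_params}} template; each cell
#'   overrides \code{I_re}.
#' @param secretion \code{\link{secretion_params}} or \code{NULL} to
#'   skip secretion (spiking statistics only).
#' @param duration_s Simulated time per cell (s).
#' @param record_every Recording stride for the summed series (ms).
#' @param silence_threshold_s,min_burst_spikes Burst-detector settings used
#'   for per-cell classification (see \code{\link{burst_stats}}).
#' @return Object of class \code{population_result}: list with
#'   \code{cells} (data frame: cell, I_syn, I_re, n_spikes, mean_rate_hz,
#'   activity_quotient, phasic, total_secretion_pg), \code{x_sum} (scaled
#'   summed secretion rate, pg/s, sampled every \code{record_every} ms),
#'   \code{v_sum} (plasma concentration of the summed signal), \code{spec},
#'   \code{duration_s}.
#' @export
simulate_population <- function(spec, spiking = spiking_params(),
                                secretion = secretion_params(),
                                duration_s = 2000, record_every = 1000L,
                                silence_threshold_s = 0.5,
                                min_burst_spikes = 5) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n_cells
  I_syn <- spec$I_syn
  if (is.null(I_syn)) {
    I_syn <- if (spec$sigma > 0)
      sample_input_densities(n, spec$sigma, seed = spec$seed)
    else rep(1, n)
  }
  dur_ms <- duration_s * 1000
  with_secretion <- !is.null(secretion)
  x_sum <- NULL
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    p_i <- spiking
    p_i$I_re <- spec$I_pop * I_syn[i]
    tr <- simulate_spiking(p_i, dur_ms, seed = spec$seed + i)
    bs <- burst_stats(tr, silence_threshold_s, min_burst_spikes)
    tot <- NA_real_
    if (with_secretion) {
      ts <- simulate_secretion(tr, secretion,
                               record_every = as.integer(record_every))
      tot <- attr(ts, "total_secreted")
      if (is.null(x_sum)) x_sum <- ts$x else x_sum <- x_sum + ts$x
    }
    cells[[i]] <- data.frame(
      cell = i, I_syn = I_syn[i], I_re = p_i$I_re,
      n_spikes = length(tr$times), mean_rate_hz = mean_rate(tr),
      activity_quotient = bs$activity_quotient,
      phasic = bs$activity_quotient > 0.1 & bs$activity_quotient < 0.9,
      total_secretion_pg = tot)
  }
  cells <- do.call(rbind, cells)
  scale <- spec$scale_to / n
  v_sum <- NULL
  if (with_secretion) {
    x_sum <- x_sum * scale
    v_sum <- plasma_concentration(x_sum, dt_ms = record_every,
                                  lambda_v = secretion$lambda_v)
  }
  structure(list(cells = cells, x_sum = x_sum, v_sum = v_sum,
                 record_ms = record_every, spec = spec,
                 duration_s = duration_s, scale = scale),
            class = "population_result")
}

#' @export
print.population_result <- function(x, ...) {
  ph <- x$cells$phasic
  cat(sprintf(
    "Population: %d cells at I_pop = %g Hz for %g s\n",
    nrow(x$cells), x$spec$I_pop, x$duration_s))
  cat(sprintf("  fully phasic: %d; phasic mean rate %.2f Hz (sd %.2f)\n",
              sum(ph),
              mean(x$cells$mean_rate_hz[ph]),
              stats::sd(x$cells$mean_rate_hz[ph])))
  if (!is.null(x$x_sum))
    cat(sprintf("  summed secretion (scaled to %d cells): %.3g pg\n",
                x$spec$scale_to,
                sum(x$x_sum) * x$record_ms / 1000))
  invisible(x)
}

#' Input-rate sweep
#'
#' Simulates a population (or single cell) at each of several population
#' input rates and tabulates the mean firing rate, total scaled secretion
#' and plasma-concentration quartiles, as used for the input-response and
#' linearisation analyses.
#'
#' @param I_pop_values Input rates to probe (Hz), at least two.
#' @param spec_template \code{\link{population_spec}} whose \code{I_pop} is
#'   replaced at each step. Densities are resampled per sweep point from
#'   the same master seed, so homogeneous/heterogeneous comparisons see
#'   matched noise.
#' @param spiking,secretion Model parameters.
#' @param duration_s Duration per cell (s).
#' @param discard_s Initial transient excluded from the v quartiles.
#' @return Data frame with one row per input rate: \code{I_pop},
#'   \code{mean_rate_hz}, \code{total_secretion_pg}, \code{v_q25},
#'   \code{v_q50}, \code{v_q75}.
#' @export
input_sweep <- function(I_pop_values, spec_template = population_spec(),
                        spiking = spiking_params(),
                        secretion = secretion_params(),
                        duration_s = 300, discard_s = 60) {
  if (length(I_pop_values) < 2) stop("give at least two input rates")
  rows <- lapply(I_pop_values, function(I) {
    sp <- spec_template
    sp$I_pop <- I
    res <- simulate_population(sp, spiking, secretion,
                               duration_s = duration_s)
    keep <- seq_along(res$x_sum) * res$record_ms / 1000 > discard_s
    v <- res$v_sum[keep]
    data.frame(I_pop = I,
               mean_rate_hz = mean(res$cells$mean_rate_hz),
               total_secretion_pg = sum(res$x_sum) * res$record_ms / 1000,
               v_q25 = stats::quantile(v, 0.25, names = FALSE),
               v_q50 = stats::quantile(v, 0.50, names = FALSE),
               v_q75 = stats::quantile(v, 0.75, names = FALSE))
  })
  do.call(rbind, rows)
}
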