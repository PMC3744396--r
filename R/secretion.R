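#' Calcium entry per spike
#'
#' Spike-evoked calcium entry at the terminal: proportional to total spike
#' broadening \code{b + b_base} and attenuated by two inverted Hill
#' functions of the cytosolic (\code{c}, slow fatigue) and submembrane
#' (\code{e}, fast feedback) calcium variables. With fatigue disabled the
#' cytosolic term is clamped to 1.
#'
#' @param b,c,e Current values of the broadening and calcium variables
#'   (non-negative).
#' @param params \code{\link{secretion_params}}.
#' @return Calcium entry (dimensionless), in \code{[0, b + b_base]}.
#' @examples
#' ca_entry(0, 0, 0, secretion_params())       # b_base = 0.5
#' ca_entry(0, 0.07, 0, secretion_params())    # half-inhibited: 0.25
#' @export
ca_entry <- function(b, c, e, params) {
  stopifnot(inherits(params, "secretion_params"))
  if (any(b < 0) || any(c < 0) || any(e < 0))
    stop("b, c, e must be non-negative")
  c_inh <- if (params$fatigue_enabled)
    params$c_theta^params$c_n / (c^params$c_n + params$c_theta^params$c_n)
  else rep(1, length(c))
  e_inh <- params$e_theta^params$e_n /
    (e^params$e_n + params$e_theta^params$e_n)
  (b + params$b_base) * c_inh * e_inh
}

#' Default initial secretion state
#'
#' All variables start at zero except cytosolic calcium (\code{c = 0.03})
#' and the full pools (\code{p = p_max}, \code{r = r_max}).
#'
#' @param params \code{\link{secretion_params}}.
#' @return Named numeric vector \code{b, c, e, p, r, v}.
#' @export
secretion_state <- function(params = secretion_params()) {
  c(b = 0, c = 0.03, e = 0, p = params$p_max, r = params$r_max, v = 0)
}

#' Simulate stimulus-secretion coupling
#'
#' Drives the single-compartment secretion model with a spike train,
#' integrating with a fixed-step scheme (default 1 ms): decaying variables
#' are advanced by exact exponential factors and the pool, store and plasma
#' compartments by forward Euler. On a spike step, calcium entry is
#' evaluated from the pre-increment values of \code{b}, \code{c}, \code{e}.
#'
#' @param train \code{\link{spike_train}}.
#' @param params \code{\link{secretion_params}}.
#' @param init Initial state from \code{\link{secretion_state}}.
#' @param dt_ms Integration step in ms (default 1; smaller values exist for
#'   convergence checks).
#' @param record_every Record every k-th step (default 1). The recorded
#'   \code{cum_x} column is exact regardless of decimation, so windowed
#'   secretion sums can always be recovered exactly.
#' @return A \code{secretion_series}: data frame with columns
#'   \code{time_ms, b, c, e, x, p, r, v, cum_x} and attributes
#'   \code{dt_ms}, \code{record_ms}, \code{params}, \code{n_spikes},
#'   \code{total_secreted}, \code{total_refill}, \code{final_state}.
#' @examples
#' tr <- regular_train(13, n_pulses = 156)
#' ts <- simulate_secretion(tr, secretion_params())
#' max(ts$b) + 0.5  # plateau of total broadening
#' @export
simulate_secretion <- function(train, params = secretion_params(),
                               init = secretion_state(params),
                               dt_ms = 1, record_every = 1L) {
  stopifnot(inherits(train, "spike_train"),
            inherits(params, "secretion_params"))
  if (dt_ms <= 0 || dt_ms > 1) stop("dt_ms must be in (0, 1]")
  if (length(train$times) && (min(train$times) < 0 ||
                              max(train$times) >= train$duration_ms))
    stop("spike times outside [0, duration)")
  nm <- c("b", "c", "e", "p", "r", "v")
  if (!all(nm %in% names(init))) stop("init must have elements ",
                                      paste(nm, collapse = ", "))
  res <- .sim_secretion_cpp(as.integer(train$times), train$duration_ms,
                            .secretion_par_vec(params),
                            params$fatigue_enabled,
                            as.numeric(init[nm]), dt_ms,
                            as.integer(record_every))
  rec <- res$records
  colnames(rec) <- c("time_ms", "b", "c", "e", "x", "p", "r", "v", "cum_x")
  out <- as.data.frame(rec)
  final <- res$final
  names(final) <- nm
  structure(out,
            dt_ms = dt_ms,
            record_ms = dt_ms * record_every,
            params = params,
            n_spikes = length(train$times),
            total_secreted = res$total_secreted,
            total_refill = res$total_refill,
            final_state = final,
            class = c("secretion_series", "data.frame"))
}

#' @export
print.secretion_series <- function(x, ...) {
  cat(sprintf(
    "Secretion series: %.1f s at %g-ms steps (%d spikes)\n",
    nrow(x) * attr(x, "record_ms") / 1000, attr(x, "dt_ms"),
    attr(x, "n_spikes")))
  cat(sprintf("  total secreted %.2f pg; final p = %.0f, r = %.0f pg\n",
              attr(x, "total_secreted"),
              attr(x, "final_state")[["p"]], attr(x, "final_state")[["r"]]))
  invisible(x)
}

#' @export
plot.secretion_series <- function(x, channels = c("b", "e", "c", "x"), ...) {
  op <- par(mfrow = c(length(channels), 1), mar = c(2.5, 4, 0.5, 0.5))
  on.exit(par(op))
  for (ch in channels)
    plot(x$time_ms / 1000, x[[ch]], type = "l", xlab = "time (s)",
         ylab = ch, ...)
  invisible(x)
}

#' Plasma concentration from a secretion-rate series
#'
#' Integrates \code{dv/dt = x - v / tau_v} by forward Euler at the series
#' resolution, where \code{tau_v = lambda_v / ln 2} (s).
#'
#' @param x Numeric vector of secretion rates (pg/s), sampled every
#'   \code{dt_ms} ms.
#' @param dt_ms Sampling interval of \code{x} in ms.
#' @param lambda_v Plasma half-life in seconds.
#' @param v0 Initial concentration.
#' @return Numeric vector of plasma concentrations, same length as \code{x}.
#' @export
plasma_concentration <- function(x, dt_ms = 1, lambda_v = 120, v0 = 0) {
  if (lambda_v <= 0) stop("lambda_v must be positive")
  tau_s <- lambda_v / log(2)
  dt_s <- dt_ms / 1000
  # v[t] = v[t-1] + (x[t] - v[t-1]/tau) * dt  ==  a*v[t-1] + dt*x[t]
  a <- 1 - dt_s / tau_s
  v <- stats::filter(dt_s * x, a, method = "recursive", init = v0)
  pmax(as.numeric(v), 0)
}

#' Write a secretion series to CSV
#'
#' @param series A \code{secretion_series}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_secretion_series <- function(series, path) {
  utils::write.csv(
    as.data.frame(series)[c("time_ms", "b", "c", "e", "x", "p", "r", "v")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
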