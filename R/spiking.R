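#' Poisson synaptic drive
#'
#' Draws per-millisecond counts of excitatory and inhibitory synaptic events
#' from independent Poisson processes with rates \code{I_re} and
#' \code{I_re * I_ratio}. Uses R's global random number generator; call
#' \code{set.seed()} (or pass \code{seed} to \code{\link{simulate_spiking}})
#' for reproducibility.
#'
#' @param params \code{\link{spiking_params}}.
#' @param duration_ms Duration in ms (one draw pair per 1-ms step).
#' @return Integer matrix with columns \code{e} and \code{i}.
#' @export
synaptic_drive <- function(params, duration_ms) {
  stopifnot(inherits(params, "spiking_params"))
  if (duration_ms <= 0) stop("duration_ms must be positive")
  if (params$I_re < 0 || params$I_ratio < 0) stop("rates must be non-negative")
  n <- as.integer(duration_ms)
  mu_e <- params$I_re / 1000
  mu_i <- params$I_re * params$I_ratio / 1000
  cbind(e = if (mu_e > 0) stats::rpois(n, mu_e) else integer(n),
        i = if (mu_i > 0) stats::rpois(n, mu_i) else integer(n))
}

#' Simulate the spiking model
#'
#' Runs the modified integrate-and-fire model at a fixed 1-ms step under
#' Poisson synaptic bombardment and returns the emitted spike train. The
#' same \code{(params, duration_ms, seed)} always yields an identical train.
#'
#' Within a step, all activity variables decay first, synaptic events are
#' applied, the membrane potential is assembled and tested against
#' threshold, and per-spike increments (HAP, DAP, calcium, dynorphin, AHP)
#' take effect from the following step. At most one spike per step.
#'
#' @param params \code{\link{spiking_params}}.
#' @param duration_ms Duration in ms.
#' @param seed Optional integer seed applied via \code{set.seed()}.
#' @param events Optional pre-drawn event matrix from
#'   \code{\link{synaptic_drive}}; when supplied the internal Poisson draws
#'   are skipped and the run is fully deterministic.
#' @return A \code{\link{spike_train}}.
#' @examples
#' train <- simulate_spiking(spiking_params(), duration_ms = 10000, seed = 1)
#' mean_rate(train)
#' @export
simulate_spiking <- function(params, duration_ms, seed = NULL,
                             events = NULL) {
  stopifnot(inherits(params, "spiking_params"))
  if (duration_ms < 1) stop("duration_ms must be at least 1 ms")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(events)) {
    ev_e <- integer(0); ev_i <- integer(0)
  } else {
    if (nrow(events) < duration_ms)
      stop("events matrix shorter than duration")
    ev_e <- as.integer(events[, 1]); ev_i <- as.integer(events[, 2])
  }
  times <- .sim_spiking_cpp(as.numeric(duration_ms),
                            .spiking_par_vec(params), ev_e, ev_i)
  spike_train(times, duration_ms)
}

#' Single spiking-model step
#'
#' Advances the spiking state by one 1-ms step given event counts for that
#' step. Mainly useful for inspecting the membrane trajectory and for
#' validating the update order.
#'
#' @param state Named numeric vector with elements \code{syn}, \code{HAP},
#'   \code{DAP}, \code{AHP}, \code{C}, \code{D}.
#' @param params \code{\link{spiking_params}}.
#' @param n_e,n_i Excitatory and inhibitory event counts for this step.
#' @return Named vector: updated state plus \code{V} (membrane potential at
#'   the threshold test) and \code{spiked} (0/1).
#' @export
step_spiking <- function(state, params, n_e = 0, n_i = 0) {
  stopifnot(inherits(params, "spiking_params"))
  nm <- c("syn", "HAP", "DAP", "AHP", "C", "D")
  if (!all(nm %in% names(state))) stop("state must have elements ",
                                       paste(nm, collapse = ", "))
  out <- .step_spiking_cpp(as.numeric(state[nm]),
                           .spiking_par_vec(params), n_e, n_i)
  names(out) <- c(nm, "V", "spiked")
  out
}

#' Initial spiking state
#'
#' @param params \code{\link{spiking_params}}.
#' @return Named numeric vector: quiescent state (calcium at rest, all
#'   afterpotentials zero).
#' @export
spiking_state <- function(params = spiking_params()) {
  c(syn = 0, HAP = 0, DAP = 0, AHP = 0, C = params$C_rest, D = 0)
}
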