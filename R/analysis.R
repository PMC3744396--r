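#' Mean firing rate
#'
#' @param train A \code{\link{spike_train}}.
#' @return Spikes per second (Hz).
#' @export
mean_rate <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  if (train$duration_ms <= 0) stop("zero-duration train")
  length(train$times) / (train$duration_ms / 1000)
}

#' Secretion per spike
#'
#' Total secreted mass divided by spike count. The series should extend
#' beyond the last spike long enough for release to decay back to baseline
#' (about 10 submembrane-calcium half-lives plus 5 cytosolic half-lives,
#' roughly 101 s at default parameters); \code{\link{frequency_response}}
#' arranges this automatically.
#'
#' @param series A \code{secretion_series}.
#' @param train The driving \code{\link{spike_train}}.
#' @return pg per spike.
#' @export
secretion_per_spike <- function(series, train) {
  stopifnot(inherits(series, "secretion_series"),
            inherits(train, "spike_train"))
  n <- length(train$times)
  if (n == 0) stop("train has no spikes")
  attr(series, "total_secreted") / n
}

#' Secretion tail duration
#'
#' Silent time to append after a stimulation train so that the release
#' transient has decayed: \code{10 * lambda_e + 5 * lambda_c} (in seconds).
#'
#' @param params \code{\link{secretion_params}}.
#' @return Tail duration in seconds.
#' @export
secretion_tail_s <- function(params = secretion_params()) {
  (10 * params$lambda_e + 5 * params$lambda_c) / 1000
}

#' Windowed secretion totals
#'
#' Sums secreted mass over consecutive non-overlapping windows starting at
#' t = 0, using the exact cumulative-secretion channel. A partial final
#' window is discarded.
#'
#' @param series A \code{secretion_series}.
#' @param window_s Window length in seconds.
#' @return Numeric vector of per-window totals (pg).
#' @export
binned_sums <- function(series, window_s) {
  stopifnot(inherits(series, "secretion_series"))
  if (window_s <= 0) stop("window must be positive")
  rec_ms <- attr(series, "record_ms")
  per <- round(window_s * 1000 / rec_ms)
  if (per < 1 || per > nrow(series)) {
    warning("window longer than series")
    return(numeric(0))
  }
  idx <- seq(per, nrow(series), by = per)
  diff(c(0, series$cum_x[idx]))
}

#' Moving-average smoothing
#'
#' Centered moving average with edges truncated to the available support,
#' which preserves the series mean.
#'
#' @param x Numeric vector sampled every \code{dt_ms} ms.
#' @param window_s Smoothing window in seconds (default 1).
#' @param dt_ms Sampling interval in ms.
#' @return Smoothed numeric vector, same length as \code{x}.
#' @export
smooth_series <- function(x, window_s = 1, dt_ms = 1) {
  w <- round(window_s * 1000 / dt_ms)
  if (w < 1) stop("window must be at least one sample")
  if (w == 1) return(x)
  half <- w %/% 2
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Burst statistics and activity quotient
#'
#' Detects bursts as maximal runs of spikes whose inter-spike gaps all stay
#' below \code{silence_threshold_s} and that contain at least
#' \code{min_burst_spikes} spikes. The activity quotient (AQ) is total
#' burst time over total time; cells with AQ in (0.1, 0.9) are
#' conventionally called fully phasic. Detector defaults were calibrated
#' against the heterogeneous-population firing statistics.
#'
#' @param train A \code{\link{spike_train}}.
#' @param silence_threshold_s Gap (s) that terminates a burst.
#' @param min_burst_spikes Minimum spikes for a run to count as a burst.
#' @return Object of class \code{burst_stats}: list with
#'   \code{burst_durations_s}, \code{silence_durations_s},
#'   \code{intraburst_rates_hz}, \code{activity_quotient}, \code{n_bursts}.
#' @export
burst_stats <- function(train, silence_threshold_s = 0.5,
                        min_burst_spikes = 5) {
  stopifnot(inherits(train, "spike_train"))
  t_s <- train$times / 1000
  dur_s <- train$duration_ms / 1000
  empty <- list(burst_durations_s = numeric(0),
                silence_durations_s = numeric(0),
                intraburst_rates_hz = numeric(0),
                activity_quotient = 0, n_bursts = 0L)
  if (length(t_s) < min_burst_spikes)
    return(structure(empty, class = "burst_stats"))
  breaks <- which(diff(t_s) >= silence_threshold_s)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(t_s))
  keep <- (ends - starts + 1L) >= min_burst_spikes
  starts <- starts[keep]; ends <- ends[keep]
  if (!length(starts)) return(structure(empty, class = "burst_stats"))
  bd <- t_s[ends] - t_s[starts]
  sil <- if (length(starts) > 1)
    t_s[starts[-1]] - t_s[ends[-length(ends)]] else numeric(0)
  structure(list(
    burst_durations_s = bd,
    silence_durations_s = sil,
    intraburst_rates_hz = (ends - starts + 1L) / pmax(bd, 1e-9),
    activity_quotient = sum(bd) / dur_s,
    n_bursts = length(starts)), class = "burst_stats")
}

#' @export
print.burst_stats <- function(x, ...) {
  cat(sprintf("Bursts: %d, AQ = %.2f", x$n_bursts, x$activity_quotient))
  if (x$n_bursts)
    cat(sprintf(", mean burst %.1f s, mean silence %.1f s, intraburst %.1f Hz",
                mean(x$burst_durations_s),
                if (length(x$silence_durations_s))
                  mean(x$silence_durations_s) else NA,
                mean(x$intraburst_rates_hz)))
  cat("\n")
  invisible(x)
}

#' Activity quotient
#'
#' Convenience wrapper around \code{\link{burst_stats}}.
#'
#' @inheritParams burst_stats
#' @return AQ in [0, 1].
#' @export
activity_quotient <- function(train, silence_threshold_s = 0.5,
                              min_burst_spikes = 5) {
  burst_stats(train, silence_threshold_s, min_burst_spikes)$activity_quotient
}

#' Frequency-response of secretion per spike
#'
#' For each stimulation frequency, applies a fixed number of regular pulses
#' to the secretion model from the default initial state, integrates the
#' released mass including the post-train decay tail, and divides by the
#' pulse count. Deterministic.
#'
#' @param params \code{\link{secretion_params}}.
#' @param frequencies_hz Frequencies to probe (Hz).
#' @param n_pulses Pulses per train (default 156).
#' @return Data frame with columns \code{freq_hz}, \code{pg_per_spike}.
#' @examples
#' \donttest{
#' fr <- frequency_response(secretion_params(), 1:60)
#' fr$freq_hz[which.max(fr$pg_per_spike)]
#' }
#' @export
frequency_response <- function(params = secretion_params(),
                               frequencies_hz = 1:60, n_pulses = 156) {
  if (length(frequencies_hz) < 2) stop("give at least two frequencies")
  tail_s <- secretion_tail_s(params)
  pg <- vapply(frequencies_hz, function(f) {
    tr <- regular_train(f, n_pulses = n_pulses, tail_s = tail_s)
    ts <- simulate_secretion(tr, params, record_every = 1000L)
    secretion_per_spike(ts, tr)
  }, numeric(1))
  data.frame(freq_hz = frequencies_hz, pg_per_spike = pg)
}
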