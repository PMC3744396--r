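#' Regular stimulation train
#'
#' Equally spaced pulses at a fixed frequency. The first pulse falls one
#' full interval after t = 0, so a 13-Hz, 1-s train has exactly 13 pulses.
#' Times are snapped down to the 1-ms simulation grid; a pulse landing
#' exactly at the total duration is moved onto the final grid step, so a
#' duration-limited train always has \code{floor(frequency * duration)}
#' pulses.
#'
#' @param frequency_hz Pulse frequency (Hz); the implied interval must be
#'   at least 1 ms.
#' @param n_pulses Number of pulses (give this or \code{duration_s}).
#' @param duration_s Total duration in seconds.
#' @param tail_s Extra silent time appended after the last pulse (s).
#' @return A \code{\link{spike_train}}.
#' @examples
#' regular_train(13, n_pulses = 156)   # spans 12 s
#' regular_train(13, duration_s = 72)  # 936 pulses
#' @export
regular_train <- function(frequency_hz, n_pulses = NULL, duration_s = NULL,
                          tail_s = 0) {
  if (frequency_hz <= 0) stop("frequency must be positive")
  interval <- 1000 / frequency_hz
  if (interval < 1) stop("frequency implies an interval below 1 ms")
  if (is.null(n_pulses) && is.null(duration_s))
    stop("give n_pulses or duration_s")
  if (is.null(n_pulses)) {
    total_ms <- duration_s * 1000
    times <- floor(interval * seq_len(floor(frequency_hz * duration_s + 1e-9)))
    # a pulse landing exactly on the end of the grid is kept on the last step
    times[times >= total_ms] <- total_ms - 1
    times <- times[times < total_ms]
  } else {
    times <- floor(interval * seq_len(n_pulses))
    total_ms <- times[length(times)] + 1
    if (!is.null(duration_s)) total_ms <- max(total_ms, duration_s * 1000)
  }
  spike_train(unique(times), total_ms + tail_s * 1000)
}

#' Burst-patterned stimulation train
#'
#' Repeating blocks of a regular intraburst train followed by silence,
#' truncated at the total duration.
#'
#' @param intraburst_hz Within-burst pulse frequency (Hz).
#' @param burst_s Burst duration (s).
#' @param silence_s Silence duration (s); 0 recovers a regular train.
#' @param total_s Total duration (s).
#' @return A \code{\link{spike_train}}.
#' @examples
#' burst_train(13, 40, 20, 100)  # bursts at [0,40) and [60,100)
#' @export
burst_train <- function(intraburst_hz, burst_s, silence_s, total_s) {
  if (burst_s <= 0 || total_s <= 0 || silence_s < 0)
    stop("durations must be positive (silence may be zero)")
  block_ms <- (burst_s + silence_s) * 1000
  total_ms <- total_s * 1000
  interval <- 1000 / intraburst_hz
  if (interval < 1) stop("frequency implies an interval below 1 ms")
  within <- floor(interval * (seq_len(floor(intraburst_hz * burst_s)) - 1))
  within <- within[within < burst_s * 1000]
  starts <- seq(0, total_ms - 1, by = block_ms)
  times <- as.vector(outer(within, starts, "+"))
  times <- sort(unique(times[times < total_ms]))
  spike_train(times, total_ms)
}

#' Regular train matched to a patterned template
#'
#' Builds a regular train with the same pulse count and duration as a
#' patterned (e.g. model-generated phasic) template, so the two members
#' have equal mean rates to within one pulse.
#'
#' @param template A non-empty \code{\link{spike_train}}.
#' @return List with elements \code{regular} and \code{patterned}.
#' @export
matched_mean_rate_pair <- function(template) {
  stopifnot(inherits(template, "spike_train"))
  n <- length(template$times)
  if (n == 0) stop("template train is empty")
  dur_ms <- template$duration_ms
  reg <- regular_train(n / (dur_ms / 1000), duration_s = dur_ms / 1000)
  list(regular = reg, patterned = template)
}
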