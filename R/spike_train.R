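#' Spike train
#'
#' An ordered set of spike times on the 1-ms simulation grid.
#'
#' @param times Numeric vector of spike times in ms, strictly increasing.
#' @param duration_ms Total simulated/observed time in ms.
#' @return An object of class \code{spike_train}.
#' @export
spike_train <- function(times, duration_ms) {
  times <- as.numeric(times)
  if (!is.finite(duration_ms) || duration_ms <= 0)
    stop("duration_ms must be positive")
  if (length(times)) {
    if (any(!is.finite(times))) stop("spike times must be finite")
    if (is.unsorted(times, strictly = TRUE))
      stop("spike times must be strictly increasing")
    if (times[1] < 0 || times[length(times)] > duration_ms)
      stop("spike times must lie in [0, duration_ms]")
  }
  structure(list(times = times, duration_ms = as.numeric(duration_ms)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train: %d spikes over %.1f s (mean rate %.2f Hz)\n",
              length(x$times), x$duration_ms / 1000, mean_rate(x)))
  invisible(x)
}

#' @export
plot.spike_train <- function(x, ...) {
  plot(x$times / 1000, rep(1, length(x$times)), type = "h",
       xlab = "time (s)", ylab = "", yaxt = "n", ylim = c(0, 1),
       xlim = c(0, x$duration_ms / 1000), ...)
  invisible(x)
}

#' Write a spike train to CSV
#'
#' Single-column CSV with header \code{time_ms}, one spike time per row.
#'
#' @param train A \code{spike_train}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_spike_train <- function(train, path) {
  stopifnot(inherits(train, "spike_train"))
  df <- data.frame(time_ms = train$times)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spike train from CSV
#'
#' Expects the format written by \code{\link{write_spike_train}}. Malformed
#' or unsorted rows are reported with their line numbers.
#'
#' @param path Input file path.
#' @param duration_ms Total duration; defaults to the last spike time
#'   rounded up to the next second (1000 ms minimum).
#' @return A \code{spike_train}.
#' @export
read_spike_train <- function(path, duration_ms = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (!length(lines) || trimws(lines[1]) != "time_ms")
    stop("expected header 'time_ms' in ", path)
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  times <- suppressWarnings(as.numeric(body))
  bad <- which(!is.finite(times))
  if (length(bad))
    stop("malformed spike time at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path)
  if (length(times) > 1) {
    viol <- which(diff(times) <= 0)
    if (length(viol))
      stop("spike times not strictly increasing at line(s) ",
           paste(viol + 2L, collapse = ", "), " of ", path)
  }
  if (is.null(duration_ms))
    duration_ms <- max(1000, if (length(times)) 1000 * ceiling(
      times[length(times)] / 1000) else 1000)
  spike_train(times, duration_ms)
}
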