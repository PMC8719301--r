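#' Spike train container
#'
#' @param times spike times in ms, non-decreasing, on the simulation grid.
#'   Ties are permitted in Poisson trains only, where they represent
#'   simultaneous deliveries (multiplicity > 1) after snapping a
#'   continuous-time realization to the grid.
#' @param label one of `"CS"`, `"US"`, `"NOISE"`.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times, label = c("CS", "US", "NOISE")) {
  label <- match.arg(label)
  stopifnot(is.numeric(times), !is.unsorted(times))
  structure(list(times = as.numeric(times), label = label),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train %s: %d spikes%s>\n", x$label, length(x$times),
              if (length(x$times)) sprintf(" in [%g, %g] ms",
                                           min(x$times), max(x$times)) else ""))
  invisible(x)
}

#' Deterministic regular spike train (CS / US generator)
#'
#' Conditioned and unconditioned stimuli are regular trains at 100 spikes/s.
#' Phase convention: the first spike falls one full interspike interval
#' after `start`, the last at or before `stop`, so a 300 ms window at
#' 100 spikes/s carries exactly 30 spikes and a 20 ms window exactly 2.
#' All times are snapped to the `dt` grid.
#'
#' @param rate firing rate, spikes/s (> 0).
#' @param start,stop window bounds, ms (`start < stop`).
#' @param dt simulation step, ms.
#' @param label train label, default `"CS"`.
#' @return A [spike_train()].
#' @examples
#' make_regular_train(100, 0, 300)   # spikes at 10, 20, ..., 300 ms
#' @export
make_regular_train <- function(rate, start, stop, dt = 0.1, label = "CS") {
  stopifnot(rate > 0, start < stop, dt > 0)
  interval <- 1000 / rate
  if (interval < dt) stop("interspike interval smaller than the time step")
  if (start + interval > stop) {
    return(spike_train(numeric(0), label))
  }
  times <- seq(start + interval, stop, by = interval)
  times <- round(times / dt) * dt
  times <- times[times <= stop + 1e-9]
  spike_train(times, label)
}

#' Poisson spike train (noise generator)
#'
#' Homogeneous Poisson process on `[start, stop]`, reproducible from a seed.
#' The spike count is drawn from the exact Poisson law with mean
#' `rate * (stop - start) / 1000`, times are placed uniformly and snapped to
#' the `dt` grid; snapped times may coincide (simultaneous deliveries), so
#' the train is non-decreasing rather than strictly increasing. Used for
#' the intrinsic-noise drive of the deep cerebellar nuclei (rate 2,500
#' spikes/s, 1 ms to 2,500 ms, one independent source per nucleus neuron).
#'
#' @param rate mean firing rate, spikes/s (`>= 0`).
#' @param start,stop window bounds, ms.
#' @param dt simulation step, ms.
#' @param rng_seed optional integer; when supplied the draw is made in a
#'   local RNG scope seeded with it, leaving the global stream untouched.
#'   When `NULL` the current RNG stream is consumed (this is how a subject's
#'   single seeded generator drives all of its noise).
#' @return A [spike_train()] with label `"NOISE"`.
#' @examples
#' tr <- make_poisson_train(2500, 1, 2500, rng_seed = 42)
#' length(tr$times)  # ~ 6247 on average
#' @export
make_poisson_train <- function(rate, start, stop, dt = 0.1, rng_seed = NULL) {
  stopifnot(rate >= 0, start <= stop, dt > 0)
  draw <- function() {
    n <- stats::rpois(1, rate * (stop - start) / 1000)
    sort(stats::runif(n, start, stop))
  }
  times <- if (is.null(rng_seed)) draw() else withr::with_seed(rng_seed, draw())
  spike_train(sort(round(times / dt) * dt), "NOISE")
}

#' Export a spike train as two-column text
#'
#' Writes `source_id` and `time_ms` columns, tab-separated with a header.
#'
#' @param train a [spike_train()].
#' @param source_id identifier written in the first column.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_spike_train <- function(train, source_id, path) {
  df <- data.frame(source_id = source_id, time_ms = train$times)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
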