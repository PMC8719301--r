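#' Group-specific read-out windows
#'
#' The conditioned-response rate is computed over `[0, 450]` ms for the
#' control group and `[0, 400]` ms for the ASD group; peak latency over
#' `[0, 550]` and `[0, 450]` ms respectively. The shorter ASD windows track
#' the earlier ASD response so the read-outs capture CS-related activity
#' rather than noise.
#'
#' @param group `"control"` or `"asd"`.
#' @return A list with `cr` and `pl` windows (ms).
#' @export
analysis_windows <- function(group = c("control", "asd")) {
  group <- match.arg(group)
  if (group == "control") list(cr = c(0, 450), pl = c(0, 550))
  else list(cr = c(0, 400), pl = c(0, 450))
}

#' Population firing-rate trace
#'
#' Rectangular binning with no smoothing: per-bin rate equals the spike
#' count in the bin divided by the number of neurons and the bin width,
#' in spikes/s. Bins are half-open `[left, right)`.
#'
#' @param spike_times numeric vector of spike times, ms (pooled over the
#'   population).
#' @param n_neurons population size (must be positive).
#' @param window `c(start, end)` ms; `bin_width` must divide its length.
#' @param bin_width bin width, ms (default 10).
#' @return A `rate_trace`: tibble with `bin_center` (ms) and `rate`
#'   (spikes/s), with the bin width and population size as attributes.
#' @examples
#' population_rate(rep(5, 10), n_neurons = 10, window = c(0, 10))
#' @export
population_rate <- function(spike_times, n_neurons, window, bin_width = 10) {
  if (n_neurons <= 0) stop("population_rate needs a positive neuron count")
  stopifnot(length(window) == 2, window[2] > window[1])
  n_bins <- (window[2] - window[1]) / bin_width
  if (abs(n_bins - round(n_bins)) > 1e-9) {
    stop("bin_width must divide the window length")
  }
  n_bins <- as.integer(round(n_bins))
  edges <- window[1] + bin_width * (0:n_bins)
  idx <- findInterval(spike_times, edges, rightmost.closed = FALSE)
  idx <- idx[idx >= 1 & idx <= n_bins &
               spike_times >= window[1] & spike_times < window[2]]
  counts <- tabulate(idx, nbins = n_bins)
  trace <- tibble::tibble(
    bin_center = edges[-length(edges)] + bin_width / 2,
    rate = counts / (n_neurons * bin_width) * 1000
  )
  attr(trace, "bin_width") <- bin_width
  attr(trace, "n_neurons") <- n_neurons
  class(trace) <- c("rate_trace", class(trace))
  trace
}

subset_trace <- function(trace, window) {
  keep <- trace$bin_center > window[1] & trace$bin_center < window[2]
  if (!any(keep)) stop("trace does not cover the requested window")
  trace[keep, ]
}

#' Conditioned-response rate
#'
#' The ratio statistic `100 * mean(rate) / max(rate)` over the read-out
#' window of the probe motor-cortex trace, in percent. Scale-invariant by
#' construction; an all-zero trace returns 0 by convention.
#'
#' @param trace a [population_rate()] trace covering the window.
#' @param window `c(start, end)` ms.
#' @return CR rate in `[0, 100]`.
#' @export
cr_rate <- function(trace, window) {
  tr <- subset_trace(trace, window)
  mx <- max(tr$rate)
  if (mx == 0) return(0)
  100 * mean(tr$rate) / mx
}

#' Peak latency of the conditioned response
#'
#' Time at which the motor-cortex rate attains its in-window maximum,
#' averaged over all bins achieving that maximum (ties contribute the mean
#' of their bin centers; a unique maximum degenerates to its own center).
#' An all-zero trace has no peak and returns `NA` (excluded from group
#' averages).
#'
#' @inheritParams cr_rate
#' @return latency in ms, or `NA_real_`.
#' @export
peak_latency <- function(trace, window) {
  tr <- subset_trace(trace, window)
  mx <- max(tr$rate)
  if (mx == 0) return(NA_real_)
  mean(tr$bin_center[tr$rate == mx])
}

#' Dentate-nucleus activity statistics
#'
#' In-window maximum of the pooled (motor + cognitive) dentate rate trace
#' and its tie-averaged time.
#'
#' @inheritParams cr_rate
#' @return A list with `max_fr` (spikes/s) and `peak_time` (ms, `NA` when
#'   the trace is flat zero).
#' @export
dn_stats <- function(trace, window) {
  tr <- subset_trace(trace, window)
  mx <- max(tr$rate)
  list(
    max_fr = mx,
    peak_time = if (mx == 0) NA_real_ else mean(tr$bin_center[tr$rate == mx])
  )
}
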