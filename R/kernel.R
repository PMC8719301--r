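#' Parameters of the cerebellar eligibility kernel
#'
#' The granule-to-Purkinje LTD rule weighs past parallel-fibre spikes with a
#' temporal kernel before each inferior-olive (teaching) spike. Two variants
#' exist, differing only in the translation `c` along the time axis: the
#' *motor* kernel (`c = 0.1` s, peak about 150 ms before the olive spike)
#' gates learning in the granule-Purkinje-dentate-M1 pathway, the *cognitive*
#' kernel (`c = 0.2` s, peak about 250 ms before) gates the pathway routed
#' through medial prefrontal cortex.
#'
#' @param pathway `"motor"` or `"cognitive"`.
#' @return An object of class `kernel_params`: a list with fields `a`
#'   (amplitude, 15), `b` (exponent, 1.8), `d_exp` (sine exponent, 0.75;
#'   named to avoid collision with the connection-delay symbol), `f`
#'   (scale, 1.3) and `c` (translation in seconds).
#' @examples
#' kp <- kernel_params("motor")
#' kernel_value(-0.15, kp)
#' @export
kernel_params <- function(pathway = c("motor", "cognitive")) {
  pathway <- match.arg(pathway)
  structure(
    list(
      a = 15, b = 1.8, d_exp = 0.75, f = 1.3,
      c = if (pathway == "motor") 0.1 else 0.2,
      pathway = pathway
    ),
    class = "kernel_params"
  )
}

#' Evaluate the eligibility kernel
#'
#' The kernel is a single positive lobe on the pre-olive-spike side of the
#' time axis,
#' \deqn{K(t) = a \exp(-|(t+c)a|^{b}/f)\,(-\sin((t+c)e))^{d}}
#' with \eqn{e} Napier's constant, defined where \eqn{-\pi/e < t + c < 0} and
#' zero elsewhere. Time is measured in seconds relative to the inferior-olive
#' spike at \eqn{t = 0}; meaningful lags are negative (past parallel-fibre
#' activity).
#'
#' @param t numeric vector of lags in seconds (typically `<= 0`).
#' @param params a [kernel_params()] object.
#' @return numeric vector of kernel values (dimensionless weights, `>= 0`).
#' @export
kernel_value <- function(t, params) {
  stopifnot(inherits(params, "kernel_params"))
  u <- t + params$c
  out <- numeric(length(u))
  ok <- is.finite(u) & u < 0 & u > -pi / exp(1)
  if (any(ok)) {
    uu <- u[ok]
    out[ok] <- params$a *
      exp(-abs(uu * params$a)^params$b / params$f) *
      (-sin(uu * exp(1)))^params$d_exp
  }
  out
}

#' Locate the kernel peak numerically
#'
#' Grid argmax of [kernel_value()] over a window of lags, at the simulation
#' resolution. Used both to calibrate the kernel reading (the motor and
#' cognitive peaks must fall at the published ~150 ms and ~250 ms lags) and
#' by the `kernel-check` command-line verb.
#'
#' @param params a [kernel_params()] object.
#' @param dt grid resolution in ms (default 0.1).
#' @param window lag window in seconds, default `c(-0.5, 0)`.
#' @return A list with `lag_s` (argmax, seconds), `lag_ms` (same in ms,
#'   negative), and `value` (kernel value at the peak).
#' @export
kernel_peak <- function(params, dt = 0.1, window = c(-0.5, 0)) {
  stopifnot(length(window) == 2, window[1] < window[2], dt > 0)
  grid <- seq(window[1], window[2], by = dt / 1000)
  v <- kernel_value(grid, params)
  i <- which.max(v)
  list(lag_s = grid[i], lag_ms = grid[i] * 1000, value = v[i])
}

# Lookup table of kernel values on the simulation grid, indexed by lag step.
# Entry k + 1 holds K(-k * dt / 1000); used by the C++ engine so the LTD
# convolution is a table lookup per buffered spike.
kernel_lut <- function(params, dt, max_lag_ms = 700) {
  lags <- -seq(0, max_lag_ms, by = dt) / 1000
  kernel_value(lags, params)
}
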