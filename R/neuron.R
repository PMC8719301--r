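#' Leaky integrate-and-fire neuron parameters
#'
#' Parameters of the current-based LIF neuron with exponential-shaped
#' postsynaptic currents used throughout the model. Defaults are the
#' documented defaults of this neuron type in the reference spiking
#' simulator; with them the rheobase (smallest constant current that makes
#' an isolated neuron fire) is
#' \eqn{I_{rh} = C_m (V_{th} - E_L) / \tau_m = 375} pA, so the 370 pA bias
#' used for granule, olive and dentate cells is weakly subthreshold and the
#' 380 pA Purkinje bias is weakly suprathreshold (tonic ~22 spikes/s).
#'
#' @param C_m membrane capacitance, pF.
#' @param tau_m membrane time constant, ms.
#' @param E_L resting (leak reversal) potential, mV.
#' @param V_th spike threshold, mV.
#' @param V_reset post-spike reset potential, mV.
#' @param t_ref absolute refractory period, ms.
#' @param tau_syn_ex,tau_syn_in decay time constants of the excitatory and
#'   inhibitory synaptic currents, ms.
#' @param I_e constant bias current, pA.
#' @return An object of class `neuron_params` (named list).
#' @examples
#' neuron_params(I_e = 370)
#' @export
neuron_params <- function(C_m = 250, tau_m = 10, E_L = -70, V_th = -55,
                          V_reset = -70, t_ref = 2,
                          tau_syn_ex = 2, tau_syn_in = 2, I_e = 0) {
  stopifnot(tau_m > 0, tau_syn_ex > 0, tau_syn_in > 0, t_ref >= 0,
            V_reset <= V_th, C_m > 0)
  structure(
    list(C_m = C_m, tau_m = tau_m, E_L = E_L, V_th = V_th,
         V_reset = V_reset, t_ref = t_ref, tau_syn_ex = tau_syn_ex,
         tau_syn_in = tau_syn_in, I_e = I_e),
    class = "neuron_params"
  )
}

# Exact per-step propagator of the linear subsystem
#   dV/dt  = -(V - E_L)/tau_m + (I_e + i_ex + i_in)/C_m
#   di/dt  = -i/tau_syn
# P22 propagates V, P21e/P21i inject the synaptic currents into V, de/di
# decay the currents. Precomputed once per (params, dt).
lif_propagator <- function(params, dt) {
  p <- params
  em <- exp(-dt / p$tau_m)
  prop_syn <- function(tau_s) {
    es <- exp(-dt / tau_s)
    if (abs(tau_s - p$tau_m) < 1e-12) {
      # degenerate tau_s == tau_m limit
      dt * em / p$C_m
    } else {
      (p$tau_m * tau_s) / (p$C_m * (p$tau_m - tau_s)) * (em - es)
    }
  }
  list(
    em = em,
    de = exp(-dt / p$tau_syn_ex),
    di = exp(-dt / p$tau_syn_in),
    P21e = prop_syn(p$tau_syn_ex),
    P21i = prop_syn(p$tau_syn_in),
    V_drive = (p$E_L + p$I_e * p$tau_m / p$C_m) * (1 - em)
  )
}

#' Initial state of a homogeneous LIF population
#'
#' @param n number of neurons.
#' @param params a [neuron_params()] object.
#' @param t starting time, ms.
#' @return An object of class `population_state`: per-neuron membrane
#'   potential `V_m` (mV, starts at `E_L`), synaptic currents `i_syn_ex`
#'   (`>= 0`) and `i_syn_in` (`<= 0`) in pA, refractory countdown
#'   `refr_remaining` (ms) and current time `t` (ms).
#' @export
population_state <- function(n, params, t = 0) {
  stopifnot(n >= 1)
  structure(
    list(V_m = rep(params$E_L, n), i_syn_ex = numeric(n),
         i_syn_in = numeric(n), refr_remaining = numeric(n), t = t, n = n),
    class = "population_state"
  )
}

#' Advance a LIF population by one time step
#'
#' Applies the exact exponential propagator of the subthreshold dynamics
#' (no integration error for the linear subsystem), detects threshold
#' crossings at end of step, resets and clamps spiking neurons for the
#' refractory period, and books arriving current pulses into the matching
#' synaptic channel (excitatory for positive weights, inhibitory for
#' negative) so they drive the membrane from the next step on. A pure
#' function of its inputs: identical state and pulses give bit-identical
#' results.
#'
#' @param state a [population_state()].
#' @param params the population's [neuron_params()].
#' @param dt time step, ms (must be positive).
#' @param pulses arriving current pulses delivered in this step: a data
#'   frame with columns `neuron` (1-based index) and `weight` (pA; the
#'   postsynaptic-current increment per presynaptic spike, signed), or
#'   `NULL`.
#' @return A list with the updated `state` and `spikes`, a tibble with
#'   columns `neuron_id` and `t_spike` (ms, a multiple of `dt`).
#' @examples
#' p <- neuron_params(I_e = 380)
#' st <- population_state(1, p)
#' out <- step_population(st, p, dt = 0.1)
#' @export
step_population <- function(state, params, dt, pulses = NULL) {
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) {
    stop("`dt` must be a single positive number")
  }
  prop <- lif_propagator(params, dt)
  refr <- state$refr_remaining > 0
  V <- state$V_m
  V[!refr] <- V[!refr] * prop$em + prop$V_drive +
    state$i_syn_ex[!refr] * prop$P21e + state$i_syn_in[!refr] * prop$P21i
  V[refr] <- params$V_reset
  state$refr_remaining[refr] <- pmax(state$refr_remaining[refr] - dt, 0)
  state$i_syn_ex <- state$i_syn_ex * prop$de
  state$i_syn_in <- state$i_syn_in * prop$di
  t_now <- state$t + dt

  fired <- which(!refr & V >= params$V_th)
  V[fired] <- params$V_reset
  state$refr_remaining[fired] <- params$t_ref
  state$V_m <- V
  state$t <- t_now

  if (!is.null(pulses) && nrow(pulses) > 0) {
    if (any(pulses$neuron < 1 | pulses$neuron > state$n)) {
      stop("pulse addressed to a nonexistent neuron id")
    }
    ex <- pulses$weight > 0
    if (any(ex)) {
      add <- tapply(pulses$weight[ex], pulses$neuron[ex], sum)
      idx <- as.integer(names(add))
      state$i_syn_ex[idx] <- state$i_syn_ex[idx] + as.numeric(add)
    }
    if (any(!ex)) {
      add <- tapply(pulses$weight[!ex], pulses$neuron[!ex], sum)
      idx <- as.integer(names(add))
      state$i_syn_in[idx] <- state$i_syn_in[idx] + as.numeric(add)
    }
  }

  list(
    state = state,
    spikes = tibble::tibble(neuron_id = fired, t_spike = rep(t_now, length(fired)))
  )
}

#' Closed-form subthreshold membrane trajectory
#'
#' For a neuron receiving only its bias current, the membrane relaxes
#' exponentially towards \eqn{E_L + I_e \tau_m / C_m}:
#' \deqn{V(t) = E_L + I_e\tau_m/C_m + (V_0 - E_L - I_e\tau_m/C_m)e^{-t/\tau_m}.}
#' Serves as the independent oracle for the stepped propagator.
#'
#' @param params a [neuron_params()] object.
#' @param V0 initial membrane potential, mV.
#' @param t time since start, ms (vectorised).
#' @return membrane potential in mV.
#' @examples
#' subthreshold_closed_form(neuron_params(I_e = 370), V0 = -70, t = 10)
#' @export
subthreshold_closed_form <- function(params, V0, t) {
  vinf <- params$E_L + params$I_e * params$tau_m / params$C_m
  vinf + (V0 - vinf) * exp(-t / params$tau_m)
}
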