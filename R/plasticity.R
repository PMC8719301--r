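#' Plastic state of a granule-to-Purkinje projection
#'
#' Holds the per-synapse weight matrix, the per-granule-cell history of
#' parallel-fibre spikes within the current trial, the non-associative LTP
#' rate, and the Purkinje "activity" window used by both learning branches.
#' This R-level state mirrors exactly what the compiled session engine does
#' and serves as its unit-testable reference.
#'
#' @param n_gr,n_pc population sizes.
#' @param w0 initial weight (pA) on every synapse.
#' @param kernel a [kernel_params()] object (motor or cognitive).
#' @param alpha LTP learning rate (weight increment per parallel-fibre spike
#'   arriving at an active Purkinje cell), default 0.05.
#' @param pc_activity_window ms; a Purkinje cell counts as active if it
#'   spiked within this window before the event, default 50 ms.
#' @return An object of class `gr_pc_state`.
#' @export
gr_pc_state <- function(n_gr, n_pc, w0, kernel, alpha = 0.05,
                        pc_activity_window = 50) {
  stopifnot(inherits(kernel, "kernel_params"), w0 >= 0)
  structure(
    list(
      W = matrix(w0, n_gr, n_pc),
      buffers = replicate(n_gr, numeric(0), simplify = FALSE),
      alpha = alpha,
      pc_activity_window = pc_activity_window,
      kernel = kernel
    ),
    class = "gr_pc_state"
  )
}

#' Record a parallel-fibre spike in the trial buffer
#'
#' @param state a [gr_pc_state()].
#' @param gr granule-cell index (vectorised).
#' @param t spike time, ms.
#' @return the updated state.
#' @export
record_gr_spike <- function(state, gr, t) {
  for (g in gr) state$buffers[[g]] <- c(state$buffers[[g]], t)
  state
}

#' Clear the trial spike buffers
#'
#' Called at each trial boundary so LTD integrates only the current trial's
#' conditioned-stimulus train.
#'
#' @param state a [gr_pc_state()].
#' @return the updated state.
#' @export
reset_trial_buffers <- function(state) {
  state$buffers <- replicate(length(state$buffers), numeric(0),
                             simplify = FALSE)
  state
}

#' Associative LTD at an inferior-olive (teaching) spike
#'
#' When an olive spike reaches Purkinje cell `j` at time `t_io`, every
#' synapse onto an active `j` is depressed by the discrete convolution of
#' the eligibility kernel with that granule cell's buffered spike train:
#' \deqn{\Delta w_{ij} = -\sum_s K(s - t_{IO})}
#' (lags in seconds), clamped so weights never become negative.
#'
#' @param state a [gr_pc_state()].
#' @param t_io olive-spike arrival time at the Purkinje layer, ms.
#' @param pc_active logical vector, one flag per Purkinje cell.
#' @return the updated state.
#' @export
ltd_at_io_spike <- function(state, t_io, pc_active) {
  stopifnot(length(pc_active) == ncol(state$W))
  if (!any(pc_active)) return(state)
  elig <- vapply(
    state$buffers,
    function(b) if (length(b)) sum(kernel_value((b - t_io) / 1000, state$kernel)) else 0,
    numeric(1)
  )
  state$W[, pc_active] <- pmax(state$W[, pc_active] - elig, 0)
  state
}

#' Non-associative LTP at a parallel-fibre spike
#'
#' Each granule-cell spike arriving at an active Purkinje cell potentiates
#' that synapse by `alpha`, except in a step where an olive spike reaches
#' the same Purkinje cell (the LTD branch is exclusive).
#'
#' @param state a [gr_pc_state()].
#' @param gr granule-cell index whose spike arrived.
#' @param pc_active logical vector, one flag per Purkinje cell.
#' @param io_coincident logical vector (or single flag): Purkinje cells
#'   receiving an olive spike in the same step, excluded from LTP.
#' @return the updated state.
#' @export
ltp_at_gr_spike <- function(state, gr, pc_active, io_coincident = FALSE) {
  stopifnot(length(pc_active) == ncol(state$W))
  eligible <- pc_active & !io_coincident
  if (any(eligible)) {
    state$W[gr, eligible] <- state$W[gr, eligible] + state$alpha
  }
  state
}

#' Plastic state of the prefrontal-to-motor projection
#'
#' @param n_mpfc,n_m1 population sizes.
#' @param beta,gamma subject-specific potentiation (> 0) and depression
#'   (< 0) increments.
#' @param w0 initial weight, pA.
#' @param window coincidence window, ms (fixed at 40 ms: a prefrontal spike
#'   within this window before a motor spike is credited with causing it).
#' @param w_cap upper weight clamp, pA.
#' @return An object of class `mpfc_m1_state`.
#' @export
mpfc_m1_state <- function(n_mpfc, n_m1, beta, gamma, w0 = 0.1, window = 40,
                          w_cap = 100) {
  stopifnot(beta > 0, gamma < 0, w0 >= 0)
  structure(
    list(
      W = matrix(w0, n_mpfc, n_m1),
      last_mpfc = rep(-Inf, n_mpfc),
      beta = beta, gamma = gamma, window = window, w_cap = w_cap
    ),
    class = "mpfc_m1_state"
  )
}

#' Record a prefrontal spike
#'
#' @param state an [mpfc_m1_state()].
#' @param i prefrontal neuron index (vectorised).
#' @param t spike time, ms.
#' @return the updated state.
#' @export
record_mpfc_spike <- function(state, i, t) {
  state$last_mpfc[i] <- t
  state
}

#' Coincidence plasticity at a motor-cortex spike
#'
#' When motor neuron `j` spikes at `t_m1`, every afferent prefrontal cell
#' that spiked within the preceding coincidence window potentiates its
#' synapse by `beta`; every other afferent depresses it by `gamma`
#' (`gamma < 0`). Weights are clamped to `[0, w_cap]`.
#'
#' @param state an [mpfc_m1_state()].
#' @param t_m1 motor-neuron spike time, ms.
#' @param m1 motor neuron index.
#' @return the updated state.
#' @export
mpfc_m1_update <- function(state, t_m1, m1) {
  recent <- (t_m1 - state$last_mpfc) <= state$window & state$last_mpfc <= t_m1
  dw <- ifelse(recent, state$beta, state$gamma)
  state$W[, m1] <- pmin(pmax(state$W[, m1] + dw, 0), state$w_cap)
  state
}
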