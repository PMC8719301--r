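# Shared fixtures. The full-scale two-group experiment (15 + 15 subjects,
# 10 sessions, dt = 0.1 ms) is expensive, so it is simulated once and shared
# by every test that needs it.
.fixture_env <- new.env(parent = emptyenv())

default_experiment <- function() {
  if (is.null(.fixture_env$experiment)) {
    .fixture_env$experiment <- run_experiment()
  }
  .fixture_env$experiment
}

# Step an isolated single LIF neuron for `n_steps`, returning the membrane
# trajectory and spike times. Independent reference path used against the
# compiled engine and the closed form.
run_single_neuron <- function(params, n_steps, dt) {
  st <- population_state(1, params)
  V <- numeric(n_steps)
  spikes <- numeric(0)
  for (i in seq_len(n_steps)) {
    out <- step_population(st, params, dt)
    st <- out$state
    V[i] <- st$V_m
    if (nrow(out$spikes)) spikes <- c(spikes, out$spikes$t_spike)
  }
  list(V = V, t = dt * seq_len(n_steps), spikes = spikes, state = st)
}

# Independent oracle: exact two-sided Mann-Whitney p by enumeration of all
# rank assignments (untied samples).
exact_mw <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- rank(c(x, y))
  u_obs <- sum(pooled[seq_len(n1)]) - n1 * (n1 + 1) / 2
  all_u <- apply(utils::combn(n1 + n2, n1), 2, function(idx) {
    sum(seq_len(n1 + n2)[idx]) - n1 * (n1 + 1) / 2
  })
  lo <- min(u_obs, n1 * n2 - u_obs)
  mean(all_u <= lo | all_u >= n1 * n2 - lo)
}

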