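test_that("stepped subthreshold dynamics match the closed form exactly", {
  p <- neuron_params(I_e = 370)
  out <- run_single_neuron(p, n_steps = 2000, dt = 0.1)
  expected <- subthreshold_closed_form(p, V0 = p$E_L, t = out$t)
  expect_lt(max(abs((out$V - expected) / expected)), 1e-6)
  expect_length(out$spikes, 0)

  # relaxation target: E_L + I_e * tau_m / C_m = -70 + 14.8 mV
  expect_equal(tail(out$V, 1), -70 + 370 * 10 / 250, tolerance = 1e-6)
  # monotone approach from rest
  expect_true(all(diff(out$V) > -1e-12))
})

test_that("closed form honours its boundary conditions", {
  p <- neuron_params(I_e = 370)
  expect_identical(subthreshold_closed_form(p, V0 = -62, t = 0), -62)
  p0 <- neuron_params(I_e = 0)
  expect_equal(subthreshold_closed_form(p0, V0 = -55, t = 1e6), p0$E_L)
  expect_equal(subthreshold_closed_form(p, V0 = -70, t = 10),
               -70 + 14.8 * (1 - exp(-1)))
})

test_that("rheobase sits at 375 pA under the default parameters", {
  for (ie in c(0, 370, 374.9)) {
    out <- run_single_neuron(neuron_params(I_e = ie), 25000, 0.1)
    expect_length(out$spikes, 0)
  }
  # 380 pA: tonic firing at the closed-form LIF period
  p <- neuron_params(I_e = 380)
  out <- run_single_neuron(p, 10000, 0.1)
  expect_gt(length(out$spikes), 10)
  dv <- p$I_e * p$tau_m / p$C_m
  isi_expected <- p$t_ref + p$tau_m * log(dv / (dv - (p$V_th - p$E_L)))
  isis <- diff(out$spikes)
  expect_true(all(abs(isis - isi_expected) <= 0.1 + 1e-9))
})

test_that("halving the step leaves driven spike times within one coarse step", {
  p <- neuron_params(I_e = 380)
  coarse <- run_single_neuron(p, 5000, 0.1)$spikes
  fine <- run_single_neuron(p, 10000, 0.05)$spikes
  n <- min(length(coarse), length(fine))
  expect_gt(n, 5)
  # each threshold crossing is resolved to within one coarse step: the
  # first spike and every interspike interval agree at that tolerance
  expect_lt(abs(coarse[1] - fine[1]), 0.1 + 1e-9)
  expect_true(all(abs(diff(coarse[1:n]) - diff(fine[1:n])) <= 0.1 + 1e-9))
})

test_that("arriving pulses route to the signed synaptic channel", {
  p <- neuron_params(I_e = 0)
  st <- population_state(3, p)
  out <- step_population(st, p, 0.1,
                         pulses = data.frame(neuron = c(1, 2), weight = c(200, -200)))
  st <- out$state
  expect_equal(st$i_syn_ex, c(200, 0, 0))
  expect_equal(st$i_syn_in, c(0, -200, 0))
  # next step: neuron 1 depolarises, neuron 2 hyperpolarises, neuron 3 rests
  st2 <- step_population(st, p, 0.1)$state
  expect_gt(st2$V_m[1], p$E_L)
  expect_lt(st2$V_m[2], p$E_L)
  expect_equal(st2$V_m[3], p$E_L)
  # a strong pulse elicits exactly one spike followed by refractory clamping
  stf <- population_state(1, neuron_params(I_e = 370))
  for (i in 1:50) stf <- step_population(stf, neuron_params(I_e = 370), 0.1)$state
  out <- step_population(stf, neuron_params(I_e = 370), 0.1,
                         pulses = data.frame(neuron = 1, weight = 5000))
  got_spike <- FALSE
  stf <- out$state
  for (i in 1:10) {
    out <- step_population(stf, neuron_params(I_e = 370), 0.1)
    stf <- out$state
    if (nrow(out$spikes)) got_spike <- TRUE
  }
  expect_true(got_spike)
  expect_equal(stf$V_m[1], -70)  # clamped at V_reset during refractoriness
})

test_that("step_population rejects bad input", {
  p <- neuron_params()
  st <- population_state(2, p)
  expect_error(step_population(st, p, dt = 0), "positive")
  expect_error(step_population(st, p, dt = -0.1), "positive")
  expect_error(step_population(st, p, 0.1,
                               pulses = data.frame(neuron = 5, weight = 1)),
               "nonexistent")
  expect_error(neuron_params(V_th = -70, V_reset = -55))
  expect_error(neuron_params(tau_m = -1))
})

test_that("stepping is a pure function of state and inputs", {
  p <- neuron_params(I_e = 380)
  st <- population_state(4, p)
  pulses <- data.frame(neuron = c(1, 3), weight = c(300, -120))
  a <- step_population(st, p, 0.1, pulses)
  b <- step_population(st, p, 0.1, pulses)
  expect_identical(a, b)
})

test_that("compiled engine reproduces the R stepper's tonic Purkinje spikes", {
  # Purkinje cells receive no input before the first CS volley reaches them
  # (CS delay 100 ms + granule relay), so their early spikes are pure
  # 380 pA tonic firing, comparable against the R reference path.
  net <- build_subject("control", seed = 77)
  ses <- run_session(net, rng_seed = 1, learn = FALSE)
  eng <- sort(unique(ses$spikes$time_ms[ses$spikes$population == "PCm" &
                                          ses$spikes$time_ms <= 105]))
  ref <- run_single_neuron(neuron_params(I_e = 380), 1050, 0.1)$spikes
  ref <- ref[ref <= 105]
  expect_equal(eng, ref)
})
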