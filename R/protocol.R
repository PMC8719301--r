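#' Layout of one conditioning session
#'
#' A session spans 2,500 ms of simulated time and holds a CS-only test
#' probe followed by three paired trials. The probe presents the
#' conditioned stimulus over `[0, 300]` ms with a measurement epoch to
#' 550 ms (wide enough for the widest read-out window); the paired trials
#' start at 500, 1,150 and 1,800 ms in 650 ms envelopes (300 ms CS plus
#' 350 ms recovery, back-to-back). Each paired trial carries a 300 ms CS
#' whose final 20 ms overlap the US, so the US onset sits 280 ms after CS
#' onset and the two stimuli co-terminate.
#'
#' @param dt simulation step, ms.
#' @return An object of class `session_plan`: `probe` (CS window and
#'   measurement epoch), `trials` (a tibble of CS/US windows with the
#'   `paired` flag) and `total_duration` (2,500 ms).
#' @examples
#' make_session_plan()$trials
#' @export
make_session_plan <- function(dt = 0.1) {
  onsets <- c(500, 1150, 1800)
  trials <- tibble::tibble(
    cs_onset = onsets,
    cs_offset = onsets + 300,
    us_onset = onsets + 280,
    us_offset = onsets + 300,
    paired = TRUE
  )
  structure(
    list(
      probe = list(cs_onset = 0, cs_offset = 300, measure_end = 550),
      trials = trials,
      total_duration = 2500,
      dt = dt
    ),
    class = "session_plan"
  )
}

# Engine population order and 0-based indices
POP_INDEX <- stats::setNames(0:9, POP_NAMES)

# Assemble the full engine configuration for one session.
build_engine_cfg <- function(network, plan, noise_trains, learn, record_gr) {
  dt <- network$dt
  n_steps <- as.integer(round(plan$total_duration / dt))
  sizes <- network$populations$size
  p <- network$params
  pars <- matrix(0, nrow = 10, ncol = 9)
  for (i in seq_len(10)) {
    pars[i, ] <- c(p$C_m, p$tau_m, p$E_L, p$V_th, p$V_reset, p$t_ref,
                   p$tau_syn_ex, p$tau_syn_in, network$populations$I_e[i])
  }
  conn <- network$connections
  get_conn <- function(src, tgt) conn[conn$source == src & conn$target == tgt, ]
  to_steps <- function(ms) as.integer(round(ms / dt))

  # static scalar all-to-all projections handled by count rings
  statics <- list(c("IOm", "DNm"), c("IOc", "DNc"), c("PCm", "DNm"),
                  c("PCc", "DNc"), c("DNm", "M1"), c("DNc", "mPFC"))
  proj_src <- integer(0); proj_tgt <- integer(0)
  proj_w <- numeric(0); proj_delay <- integer(0)
  for (st in statics) {
    row <- get_conn(st[1], st[2])
    proj_src <- c(proj_src, POP_INDEX[[st[1]]])
    proj_tgt <- c(proj_tgt, POP_INDEX[[st[2]]])
    proj_w <- c(proj_w, row$weight)
    proj_delay <- c(proj_delay, to_steps(row$delay))
  }

  # deterministic stimulus trains, shifted by each projection's delay
  cs_times <- c(
    make_regular_train(100, plan$probe$cs_onset, plan$probe$cs_offset, dt)$times,
    unlist(purrr::map2(plan$trials$cs_onset, plan$trials$cs_offset,
                       function(a, b) make_regular_train(100, a, b, dt)$times))
  )
  paired <- plan$trials[plan$trials$paired, ]
  us_times <- unlist(purrr::map2(paired$us_onset, paired$us_offset,
                                 function(a, b) make_regular_train(100, a, b, dt, "US")$times))
  dropped_stim <- 0L
  stim <- list()
  add_stim <- function(times, src, tgt) {
    row <- get_conn(src, tgt)
    steps <- to_steps(times) + to_steps(row$delay)
    keep <- steps <= n_steps
    dropped_stim <<- dropped_stim + sum(!keep)
    stim[[length(stim) + 1]] <<- list(pop = POP_INDEX[[tgt]], w = row$weight,
                                      steps = as.integer(steps[keep]))
  }
  for (tgt in c("GRm", "GRc", "DNm", "DNc")) add_stim(cs_times, "CS", tgt)
  if (length(us_times)) for (tgt in c("IOm", "IOc")) add_stim(us_times, "US", tgt)

  # per-dentate-neuron noise
  off <- cumsum(c(0, sizes))
  noise_tgt <- integer(0); noise_step <- integer(0)
  dn_pops <- c("DNm", "DNc")
  k <- 0
  for (pp in dn_pops) {
    base <- off[POP_INDEX[[pp]] + 1]
    for (i in seq_len(sizes[POP_INDEX[[pp]] + 1])) {
      k <- k + 1
      steps <- to_steps(noise_trains[[k]]$times)
      keep <- steps >= 1 & steps <= n_steps
      noise_tgt <- c(noise_tgt, rep(base + i - 1L, sum(keep)))
      noise_step <- c(noise_step, steps[keep])
    }
  }
  ord <- order(noise_step)

  first_trial_step <- to_steps(min(plan$trials$cs_onset))
  list(
    sizes = as.integer(sizes), pars = pars, dt = dt, n_steps = n_steps,
    proj_src = as.integer(proj_src), proj_tgt = as.integer(proj_tgt),
    proj_w = proj_w, proj_delay = as.integer(proj_delay),
    grm = POP_INDEX[["GRm"]], grc = POP_INDEX[["GRc"]],
    iom = POP_INDEX[["IOm"]], ioc = POP_INDEX[["IOc"]],
    pcm = POP_INDEX[["PCm"]], pcc = POP_INDEX[["PCc"]],
    mpfc = POP_INDEX[["mPFC"]], m1 = POP_INDEX[["M1"]],
    d_gr_pc = to_steps(get_conn("GRm", "PCm")$delay),
    d_io_pc = to_steps(get_conn("IOm", "PCm")$delay),
    d_mpfc_m1 = to_steps(get_conn("mPFC", "M1")$delay),
    w_io_pc = get_conn("IOm", "PCm")$weight,
    W1m = network$W_grm_pcm, W1c = network$W_grc_pcc, W2 = network$W_mpfc_m1,
    alpha = 0.05, beta = network$subject$beta, gamma = network$subject$gamma,
    w_cap = 50,
    pc_window_steps = to_steps(50), mpfc_window_steps = to_steps(40),
    lut_m = kernel_lut(kernel_params("motor"), dt),
    lut_c = kernel_lut(kernel_params("cognitive"), dt),
    trial_boundary_steps = to_steps(plan$trials$cs_onset),
    plast_start_step = if (learn) first_trial_step else n_steps + 1L,
    stim = stim,
    noise_tgt = noise_tgt[ord], noise_step = noise_step[ord],
    noise_w = network$subject$w_noise_dn,
    record_gr = record_gr,
    dropped_stim = dropped_stim
  )
}

#' Run one conditioning session
#'
#' Simulates the CS-only probe (plasticity frozen, so the conditioned
#' response is a pure read-out of the weights carried into the session) and
#' the three paired CS-US trials (plasticity active), then computes the
#' probe read-outs. Plastic weights persist into the returned network.
#'
#' @param network a [build_subject()] network (possibly carrying weights
#'   from earlier sessions).
#' @param plan a [make_session_plan()].
#' @param rng_seed optional integer seeding the session's noise draw; when
#'   `NULL` the current RNG stream is consumed.
#' @param learn logical; `FALSE` freezes plasticity for the whole session
#'   (probe-only experiments).
#' @param keep_spikes `"small"` (default) returns all spikes except the
#'   granule layers, `"all"` everything, `"none"` drops the archive.
#' @return An object of class `debc_session`: `metrics` (one-row tibble
#'   with `cr_rate`, `peak_latency`, `dn_max_fr`, `dn_peak_time`, mean
#'   plastic weights and the dropped-event diagnostic), `spikes` (tibble
#'   `population`, `neuron_id`, `time_ms`), and `network` (weights
#'   updated).
#' @export
run_session <- function(network, plan = make_session_plan(network$dt),
                        rng_seed = NULL, learn = TRUE,
                        keep_spikes = c("small", "all", "none")) {
  keep_spikes <- match.arg(keep_spikes)
  stopifnot(inherits(network, "debc_network"), inherits(plan, "session_plan"))
  if (max(plan$trials$cs_offset) > plan$total_duration) {
    stop("session plan exceeds the simulated duration")
  }
  n_dn <- sum(network$populations$size[network$populations$name %in% c("DNm", "DNc")])
  draw_noise <- function() {
    purrr::map(seq_len(n_dn), function(i) {
      make_poisson_train(2500, 1, plan$total_duration, network$dt)
    })
  }
  noise <- if (is.null(rng_seed)) draw_noise() else withr::with_seed(rng_seed, draw_noise())

  cfg <- build_engine_cfg(network, plan, noise, learn,
                          record_gr = keep_spikes == "all")
  out <- run_session_cpp(cfg)

  dt <- network$dt
  spk <- purrr::map2_dfr(out$spikes, POP_NAMES, function(s, nm) {
    tibble::tibble(population = nm, neuron_id = s$id + 1L,
                   time_ms = s$step * dt)
  })

  windows <- analysis_windows(network$group)
  probe_end <- plan$probe$measure_end
  m1_n <- network$populations$size[network$populations$name == "M1"]
  m1_times <- spk$time_ms[spk$population == "M1" & spk$time_ms <= probe_end]
  m1_trace <- population_rate(m1_times, m1_n, c(0, probe_end), 10)
  dn_n <- sum(network$populations$size[network$populations$name %in% c("DNm", "DNc")])
  dn_times <- spk$time_ms[spk$population %in% c("DNm", "DNc") &
                            spk$time_ms <= probe_end]
  dn_trace <- population_rate(dn_times, dn_n, c(0, probe_end), 10)
  dn <- dn_stats(dn_trace, windows$pl)

  network$W_grm_pcm <- out$W1m
  network$W_grc_pcc <- out$W1c
  network$W_mpfc_m1 <- out$W2

  metrics <- tibble::tibble(
    cr_rate = cr_rate(m1_trace, windows$cr),
    peak_latency = peak_latency(m1_trace, windows$pl),
    dn_max_fr = dn$max_fr,
    dn_peak_time = dn$peak_time,
    w_grm_pcm = mean(out$W1m),
    w_grc_pcc = mean(out$W1c),
    w_mpfc_m1 = mean(out$W2),
    dropped_events = out$dropped + cfg$dropped_stim
  )
  if (keep_spikes == "none") spk <- spk[0, ]
  structure(list(metrics = metrics, spikes = spk, network = network),
            class = "debc_session")
}

#' @export
print.debc_session <- function(x, ...) {
  cat("<debc_session>\n")
  print(x$metrics)
  invisible(x)
}

#' Train one simulated subject
#'
#' Runs consecutive sessions with persistent plastic state: each session is
#' simulated as its own 2,500 ms run (membrane state re-initialised, noise
#' freshly drawn from the subject's stream) while the plastic weight
#' matrices carry over, so training is logically continuous. The subject's
#' seed reproduces everything: parameter draws first, then each session's
#' noise, off one RNG stream.
#'
#' @param group `"control"` or `"asd"`.
#' @param seed integer subject seed.
#' @param n_sessions number of training sessions (default 10).
#' @param dt simulation step, ms.
#' @param keep_spikes passed to [run_session()]; default drops archives to
#'   keep training objects small.
#' @return An object of class `debc_training`: `sessions` (tibble of
#'   per-session metrics), `network` (final state), `group`, `seed`.
#' @examples
#' \donttest{
#' tr <- run_training("control", seed = 1, n_sessions = 2, dt = 1)
#' tr$sessions
#' }
#' @export
run_training <- function(group, seed, n_sessions = 10, dt = 0.1,
                         keep_spikes = "none") {
  withr::with_seed(seed, {
    net <- build_subject_impl(match.arg(group, c("control", "asd")), seed, dt)
    plan <- make_session_plan(dt)
    sessions <- vector("list", n_sessions)
    for (s in seq_len(n_sessions)) {
      res <- run_session(net, plan, learn = TRUE, keep_spikes = keep_spikes)
      net <- res$network
      sessions[[s]] <- dplyr::mutate(res$metrics, session = s,
                                     .before = 1)
    }
    structure(
      list(sessions = dplyr::bind_rows(sessions), network = net,
           group = net$group, seed = seed),
      class = "debc_training"
    )
  })
}

#' @export
print.debc_training <- function(x, ...) {
  cat(sprintf("<debc_training %s, seed %d, %d sessions>\n",
              x$group, x$seed, nrow(x$sessions)))
  print(x$sessions)
  invisible(x)
}

#' @rdname run_training
#' @param x a `debc_training` object.
#' @param ... unused.
#' @method tidy debc_training
#' @export
tidy.debc_training <- function(x, ...) {
  dplyr::mutate(x$sessions, group = x$group, seed = x$seed, .before = 1)
}

#' Dump per-session spikes as columnar text
#'
#' @param session a [run_session()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_session_spikes <- function(session, path) {
  utils::write.table(session$spikes, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
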