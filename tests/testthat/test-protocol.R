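test_that("session layout fits a probe plus three back-to-back paired trials", {
  plan <- make_session_plan()
  expect_equal(nrow(plan$trials), 3)
  expect_true(all(plan$trials$paired))
  expect_equal(plan$trials$cs_onset[2], 1150)
  expect_equal(plan$trials$cs_offset[2], 1450)
  expect_equal(plan$trials$us_onset[2], 1430)
  expect_equal(plan$trials$us_offset[2], 1450)
  # 300 ms CS with 20 ms final US overlap: US starts 280 ms after CS
  expect_true(all(plan$trials$us_onset - plan$trials$cs_onset == 280))
  expect_true(all(plan$trials$us_offset == plan$trials$cs_offset))
  expect_lte(max(plan$trials$cs_offset), plan$total_duration)
  expect_equal(plan$probe$cs_onset, 0)
  expect_equal(plan$probe$cs_offset, 300)
})

test_that("the probe is US-free and plasticity-frozen", {
  net <- build_subject("control", seed = 41, dt = 1)
  ses <- run_session(net, make_session_plan(1), rng_seed = 1)
  io <- ses$spikes$time_ms[ses$spikes$population %in% c("IOm", "IOc")]
  # no olive spikes before the first paired trial's US can arrive
  expect_true(all(io > 550))
  # a fully frozen (probe-like) run leaves every plastic weight untouched
  frozen <- run_session(net, make_session_plan(1), rng_seed = 1, learn = FALSE)
  expect_identical(frozen$network$W_grm_pcm, net$W_grm_pcm)
  expect_identical(frozen$network$W_grc_pcc, net$W_grc_pcc)
  expect_identical(frozen$network$W_mpfc_m1, net$W_mpfc_m1)
  # whereas the training run depressed the parallel-fibre weights
  expect_lt(mean(ses$network$W_grm_pcm), mean(net$W_grm_pcm))
})

test_that("sessions are deterministic at fixed network and seed", {
  net <- build_subject("asd", seed = 42, dt = 1)
  a <- run_session(net, rng_seed = 7)
  b <- run_session(net, rng_seed = 7)
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$network$W_mpfc_m1, b$network$W_mpfc_m1)
})

test_that("training runs ten sessions with persistent, non-increasing LTD", {
  tr <- run_training("control", seed = 51, dt = 1)
  expect_equal(nrow(tr$sessions), 10)
  expect_equal(tr$sessions$session, 1:10)
  # parallel-fibre depression: mean motor weight never increases across
  # sessions and ends at or below its starting point
  expect_true(all(diff(tr$sessions$w_grm_pcm) <= 1e-9))
  expect_lte(tr$sessions$w_grm_pcm[10], tr$sessions$w_grm_pcm[1])
  expect_true(all(tr$sessions$w_grm_pcm >= 0))
  expect_true(all(tr$sessions$w_grc_pcc >= 0))
  # acquisition: the CS-only probe CR grows from session 1 to session 10
  expect_gt(tr$sessions$cr_rate[10], tr$sessions$cr_rate[1])
  expect_true(all(tr$sessions$cr_rate >= 0 & tr$sessions$cr_rate <= 100))
  # determinism end-to-end
  tr2 <- run_training("control", seed = 51, dt = 1)
  expect_identical(tr$sessions, tr2$sessions)
  # tidy() exposes the per-session read-outs
  td <- tidy(tr)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$group[1], "control")
})

test_that("CS-only presentations after acquisition drive extinction", {
  withr::with_seed(61, {
    net <- build_subject("control", seed = 61, dt = 1)
    plan <- make_session_plan(1)
    for (s in 1:3) net <- run_session(net, plan)$network
    acquired_m <- mean(net$W_grm_pcm)
    acquired_c <- mean(net$W_grc_pcc)
    # unpaired trials: CS alone, no teaching signal -> LTP only
    plan$trials$paired <- FALSE
    ext <- run_session(net, plan)$network
    expect_gte(mean(ext$W_grm_pcm), acquired_m)
    expect_gte(mean(ext$W_grc_pcc), acquired_c)
    expect_gt(mean(ext$W_grm_pcm) + mean(ext$W_grc_pcc),
              acquired_m + acquired_c)
  })
})

test_that("deliveries scheduled past the session end are counted, not lost", {
  net <- build_subject("control", seed = 71, dt = 1)
  plan <- make_session_plan(1)
  # push the last trial against the session wall so its delayed cortical
  # volleys (100 ms projections) overshoot the 2,500 ms boundary
  plan$trials$cs_onset[3] <- 2200
  plan$trials$cs_offset[3] <- 2500
  plan$trials$us_onset[3] <- 2480
  plan$trials$us_offset[3] <- 2500
  ses <- run_session(net, plan, rng_seed = 5)
  expect_gt(ses$metrics$dropped_events, 0)
  # the default layout drops nothing
  ses0 <- run_session(net, make_session_plan(1), rng_seed = 5)
  expect_equal(ses0$metrics$dropped_events, 0)
})

test_that("session spike archives export as columnar text", {
  net <- build_subject("control", seed = 81, dt = 1)
  ses <- run_session(net, rng_seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  export_session_spikes(ses, path)
  got <- read.delim(path)
  expect_equal(names(got), c("population", "neuron_id", "time_ms"))
  expect_gt(nrow(got), 100)
})
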