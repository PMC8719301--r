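pop_size <- function(net, name) {
  net$populations$size[net$populations$name == name]
}

test_that("control and ASD subjects carry the published cell counts", {
  ctl <- build_subject("control", seed = 3)
  asd <- build_subject("asd", seed = 3)
  expect_equal(pop_size(ctl, "PCm") + pop_size(ctl, "PCc"), 48)
  expect_equal(pop_size(asd, "PCm") + pop_size(asd, "PCc"), 30)
  for (net in list(ctl, asd)) {
    expect_equal(pop_size(net, "GRm") + pop_size(net, "GRc"), 1536)
    expect_equal(pop_size(net, "IOm") + pop_size(net, "IOc"), 48)
    expect_equal(pop_size(net, "DNm") + pop_size(net, "DNc"), 24)
  }
  expect_error(build_subject("typical", seed = 1))
})

test_that("published weights, currents and delays are wired verbatim", {
  net <- build_subject("control", seed = 9)
  w <- function(s, t) net$connections$weight[net$connections$source == s &
                                               net$connections$target == t]
  d <- function(s, t) net$connections$delay[net$connections$source == s &
                                              net$connections$target == t]
  expect_equal(w("CS", "GRm"), 500)
  expect_equal(w("CS", "DNm"), 500)
  expect_equal(w("US", "IOm"), 100)
  expect_equal(w("IOm", "PCm"), -500)
  expect_equal(w("IOm", "DNm"), 60)
  expect_equal(w("PCm", "DNm"), -7)
  expect_equal(w("DNm", "M1"), 100)
  expect_equal(w("DNc", "mPFC"), 50)
  ie <- function(p) net$populations$I_e[net$populations$name == p]
  expect_equal(ie("GRm"), 370); expect_equal(ie("PCm"), 380)
  expect_equal(ie("IOm"), 370); expect_equal(ie("DNm"), 370)
  # hyper-connectable projections at 100 ms in control, 50 ms in ASD
  asd <- build_subject("asd", seed = 9)
  da <- function(s, t) asd$connections$delay[asd$connections$source == s &
                                               asd$connections$target == t]
  for (pr in list(c("CS", "GRm"), c("CS", "GRc"), c("CS", "DNm"),
                  c("CS", "DNc"), c("US", "IOm"), c("US", "IOc"),
                  c("DNm", "M1"))) {
    expect_equal(d(pr[1], pr[2]), 100)
    expect_equal(da(pr[1], pr[2]), 50)
  }
  # everything else at the minimal synaptic delay
  expect_equal(d("GRm", "PCm"), 1)
  expect_equal(d("IOm", "PCm"), 1)
  expect_equal(d("DNc", "mPFC"), 1)
  expect_equal(d("mPFC", "M1"), 1)
  # initial plastic weights
  expect_true(all(net$W_grm_pcm == 5))
  expect_true(all(net$W_grc_pcc == 20))
  expect_true(all(net$W_mpfc_m1 == 0.1))
})

test_that("groups differ only in Purkinje counts and the six delays", {
  ctl <- build_subject("control", seed = 21)
  asd <- build_subject("asd", seed = 21)
  # same sampled subject parameters at the same seed
  expect_equal(ctl$subject[c("w_noise_dn", "I_e_M1", "I_e_mPFC", "beta", "gamma")],
               asd$subject[c("w_noise_dn", "I_e_M1", "I_e_mPFC", "beta", "gamma")])
  pops <- dplyr::full_join(ctl$populations, asd$populations, by = "name")
  differing <- pops$name[pops$size.x != pops$size.y]
  expect_setequal(differing, c("PCm", "PCc"))
  expect_equal(pops$I_e.x, pops$I_e.y)
  cc <- dplyr::full_join(ctl$connections, asd$connections,
                         by = c("source", "target"))
  expect_equal(cc$weight.x, cc$weight.y)
  changed <- paste0(cc$source, "->", cc$target)[cc$delay.x != cc$delay.y]
  expect_setequal(changed, c("CS->GRm", "CS->GRc", "CS->DNm", "CS->DNc",
                             "US->IOm", "US->IOc", "DNm->M1"))
})

test_that("subject parameter draws stay inside their uniform ranges", {
  for (s in 1:25) {
    cfg <- subject_config("control", seed = s)
    expect_true(cfg$w_noise_dn >= 0.1 && cfg$w_noise_dn <= 0.5)
    expect_true(cfg$I_e_M1 >= 300 && cfg$I_e_M1 <= 365)
    expect_true(cfg$I_e_mPFC >= 300 && cfg$I_e_mPFC <= 365)
    expect_true(cfg$beta >= 0.2 && cfg$beta <= 0.5)
    expect_true(cfg$gamma >= -0.035 && cfg$gamma <= -0.015)
  }
  # identical (group, seed) reproduces the subject exactly
  expect_identical(build_subject("asd", seed = 5), build_subject("asd", seed = 5))
})

test_that("one-to-one maps pair low indices and leave surplus sources", {
  full <- one_to_one_map(24, 24)
  expect_equal(nrow(full), 24)
  expect_equal(full$source, full$target)
  part <- one_to_one_map(24, 15)
  expect_equal(nrow(part), 15)
  expect_equal(part$source, 1:15)
  expect_equal(nrow(one_to_one_map(24, 0)), 0)
  expect_error(one_to_one_map(15, 24), "exceeds")
})

test_that("synapse counts follow the projection topology", {
  s <- network_summary(build_subject("control", seed = 2))
  n <- function(src, tgt) s$n_synapses[s$source == src & s$target == tgt]
  expect_equal(n("GRm", "PCm"), 768 * 24)
  expect_equal(n("IOm", "PCm"), 24)        # one-to-one
  expect_equal(n("PCm", "DNm"), 24 * 12)
  expect_equal(n("CS", "GRm"), 768)        # one logical source, fanned out
  sa <- network_summary(build_subject("asd", seed = 2))
  na <- function(src, tgt) sa$n_synapses[sa$source == src & sa$target == tgt]
  expect_equal(na("GRm", "PCm"), 768 * 15)
  expect_equal(na("IOm", "PCm"), 15)       # 9 olive cells left unpaired
})

test_that("configuration values round-trip through serialisation", {
  net <- build_subject("asd", seed = 13)
  path <- withr::local_tempfile(fileext = ".cfg")
  write_network_config(net, path)
  got <- read_network_config(path)
  expect_identical(got$group, "asd")
  for (i in seq_len(nrow(net$connections))) {
    key <- sprintf("w.%s.%s", net$connections$source[i], net$connections$target[i])
    expect_identical(got[[key]], net$connections$weight[i])
    key <- sprintf("d.%s.%s", net$connections$source[i], net$connections$target[i])
    expect_identical(got[[key]], net$connections$delay[i])
  }
  expect_identical(got$subject.I_e_M1, net$subject$I_e_M1)
  expect_identical(got$subject.beta, net$subject$beta)
  expect_identical(got$subject.gamma, net$subject$gamma)
})
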