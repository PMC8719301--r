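# Architecture constants. Two parallel cerebellar-cortical pathways (motor
# "m": GRm-PCm-DNm-M1; cognitive "c": GRc-PCc-DNc-mPFC-M1), each holding half
# of 1536 granule (GR), 48 inferior-olive (IO), 48 Purkinje (PC) and 24
# dentate (DN) cells. Cortical populations are not sized in the source
# architecture; 24 neurons each keeps them on the scale of the other small
# populations.
POP_NAMES <- c("GRm", "GRc", "IOm", "IOc", "PCm", "PCc",
               "DNm", "DNc", "mPFC", "M1")

pop_sizes <- function(group) {
  pc <- if (group == "control") 24L else 15L
  c(GRm = 768L, GRc = 768L, IOm = 24L, IOc = 24L, PCm = pc, PCc = pc,
    DNm = 12L, DNc = 12L, mPFC = 24L, M1 = 24L)
}

# Bias currents (pA); M1/mPFC are sampled per subject.
POP_IE <- c(GRm = 370, GRc = 370, IOm = 370, IOc = 370, PCm = 380, PCc = 380,
            DNm = 370, DNc = 370, mPFC = NA, M1 = NA)

# Projections hyper-connected in the ASD condition (delay 100 -> 50 ms).
HYPER_PROJECTIONS <- c("CS->GRm", "CS->GRc", "CS->DNm", "CS->DNc",
                       "US->IOm", "US->IOc", "DNm->M1")

#' Static and plastic projection table
#'
#' One row per projection with its weight (pA postsynaptic-current increment
#' per presynaptic spike; negative values target the inhibitory channel),
#' transmission delay (ms), topology, plasticity flag and eligibility-kernel
#' assignment. The six cerebello-cortical sensory/motor projections carry a
#' 100 ms delay in the control condition and 50 ms under the ASD
#' hyper-connectivity manipulation; every other projection uses the minimal
#' 1 ms synaptic delay. Plastic weights (GR->PC, mPFC->M1) are initial
#' values.
#'
#' @param group `"control"` or `"asd"`.
#' @return A tibble with columns `source`, `target`, `weight`, `delay`,
#'   `topology`, `plastic`, `kernel`.
#' @export
connection_table <- function(group = c("control", "asd")) {
  group <- match.arg(group)
  hyper <- if (group == "control") 100 else 50
  con <- function(source, target, weight, delay, topology = "all_to_all",
                  plastic = FALSE, kernel = "none") {
    tibble::tibble(source = source, target = target, weight = weight,
                   delay = delay, topology = topology, plastic = plastic,
                   kernel = kernel)
  }
  dplyr::bind_rows(
    con("CS",   "GRm",  500, hyper),
    con("CS",   "GRc",  500, hyper),
    con("CS",   "DNm",  500, hyper),
    con("CS",   "DNc",  500, hyper),
    con("US",   "IOm",  100, hyper),
    con("US",   "IOc",  100, hyper),
    con("IOm",  "PCm", -500, 1, topology = "one_to_one"),
    con("IOc",  "PCc", -500, 1, topology = "one_to_one"),
    con("IOm",  "DNm",   60, 1),
    con("IOc",  "DNc",   60, 1),
    con("PCm",  "DNm",   -7, 1),
    con("PCc",  "DNc",   -7, 1),
    con("DNm",  "M1",   100, hyper),
    con("DNc",  "mPFC",  50, 1),
    con("GRm",  "PCm",    5, 1, plastic = TRUE, kernel = "motor"),
    con("GRc",  "PCc",   20, 1, plastic = TRUE, kernel = "cognitive"),
    con("mPFC", "M1",   0.1, 1, plastic = TRUE),
    con("Noise", "DNm",  NA, 1, topology = "one_to_one"),
    con("Noise", "DNc",  NA, 1, topology = "one_to_one")
  )
}

#' Per-subject sampled parameters
#'
#' Each simulated child draws, from a uniform distribution, its
#' noise-to-dentate weight (`w_noise_dn`, pA in [0.1, 0.5]), cortical bias
#' currents (`I_e_M1`, `I_e_mPFC`, pA in [300, 365]) and the
#' prefrontal-motor plasticity rates (`beta` in [0.2, 0.5], `gamma` in
#' [-0.035, -0.015]). The draw consumes the subject's single seeded RNG
#' stream, which subsequently drives the noise trains, so one integer
#' reproduces a subject end-to-end.
#'
#' @param group `"control"` or `"asd"`.
#' @param seed optional integer; when supplied the draw happens in a local
#'   RNG scope seeded with it.
#' @return A list of class `subject_config`.
#' @export
subject_config <- function(group = c("control", "asd"), seed = NULL) {
  group <- match.arg(group)
  draw <- function() {
    list(
      group = group,
      seed = seed,
      w_noise_dn = stats::runif(1, 0.1, 0.5),
      I_e_M1 = stats::runif(1, 300, 365),
      I_e_mPFC = stats::runif(1, 300, 365),
      beta = stats::runif(1, 0.2, 0.5),
      gamma = stats::runif(1, -0.035, -0.015)
    )
  }
  cfg <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  structure(cfg, class = "subject_config")
}

#' Index pairing for a one-to-one projection
#'
#' Pairs source neuron `i` with target neuron `i`. When the target
#' population is smaller (the reduced Purkinje population of the ASD
#' condition, 15 cells facing 24 olive cells), the lowest-index source cells
#' take the pairs and the surplus sources remain unpaired (olive cells keep
#' only their projection to the dentate nuclei).
#'
#' @param n_source,n_target population sizes; `n_target <= n_source`.
#' @return A tibble with columns `source` and `target` (1-based indices).
#' @examples
#' one_to_one_map(24, 15)
#' @export
one_to_one_map <- function(n_source, n_target) {
  stopifnot(n_source >= 0, n_target >= 0)
  if (n_target > n_source) stop("n_target exceeds n_source")
  if (n_target == 0) {
    return(tibble::tibble(source = integer(), target = integer()))
  }
  tibble::tibble(source = seq_len(n_target), target = seq_len(n_target))
}

#' Build one simulated subject's network
#'
#' Wires the complete control or ASD network: populations with their sizes
#' and bias currents, the projection table, the per-subject sampled
#' parameters, and the three plastic weight matrices at their initial
#' values (GRm->PCm 5 pA, GRc->PCc 20 pA, mPFC->M1 0.1 pA everywhere).
#' The ASD condition differs from control only in the Purkinje population
#' size (15 per pathway instead of 24) and in the six hyper-connected delays
#' (50 ms instead of 100 ms).
#'
#' @param group `"control"` or `"asd"`.
#' @param seed integer seed reproducing the subject (parameter draws; when
#'   training, also its noise).
#' @param dt simulation step, ms.
#' @return An object of class `debc_network`.
#' @examples
#' net <- build_subject("control", seed = 1)
#' sum(net$populations$size[net$populations$name %in% c("PCm", "PCc")])
#' @export
build_subject <- function(group = c("control", "asd"), seed, dt = 0.1) {
  group <- match.arg(group)
  withr::with_seed(seed, build_subject_impl(group, seed, dt))
}

# Samples from the *current* RNG stream; run_training() relies on this to
# keep parameter draws and noise on one per-subject stream.
build_subject_impl <- function(group, seed, dt) {
  cfg <- subject_config(group)
  cfg$seed <- seed
  sizes <- pop_sizes(group)
  ie <- POP_IE
  ie["M1"] <- cfg$I_e_M1
  ie["mPFC"] <- cfg$I_e_mPFC
  populations <- tibble::tibble(
    name = POP_NAMES,
    size = unname(sizes[POP_NAMES]),
    I_e = unname(ie[POP_NAMES])
  )
  connections <- connection_table(group)
  connections$weight[connections$source == "Noise"] <- cfg$w_noise_dn
  structure(
    list(
      group = group,
      dt = dt,
      populations = populations,
      connections = connections,
      params = neuron_params(),
      W_grm_pcm = matrix(5, nrow = sizes[["GRm"]], ncol = sizes[["PCm"]]),
      W_grc_pcc = matrix(20, nrow = sizes[["GRc"]], ncol = sizes[["PCc"]]),
      W_mpfc_m1 = matrix(0.1, nrow = sizes[["mPFC"]], ncol = sizes[["M1"]]),
      subject = cfg
    ),
    class = "debc_network"
  )
}

#' @export
print.debc_network <- function(x, ...) {
  cat(sprintf("<debc_network %s subject, seed %s, %d neurons, dt %g ms>\n",
              x$group, x$subject$seed, sum(x$populations$size), x$dt))
  invisible(x)
}

#' Summarise a network as one row per projection
#'
#' @param network a [build_subject()] network.
#' @return A tibble: the projection table plus the realised synapse count
#'   (`|source| * |target|` for all-to-all, `min(|source|, |target|)` for
#'   one-to-one; stimulus and noise sources count one source each per
#'   target rule).
#' @export
network_summary <- function(network) {
  sizes <- stats::setNames(network$populations$size, network$populations$name)
  n_src <- function(s, tgt) {
    if (s %in% names(sizes)) sizes[[s]] else if (s == "Noise") sizes[[tgt]] else 1L
  }
  dplyr::mutate(
    network$connections,
    n_synapses = purrr::map2_int(
      .data$source, .data$target,
      function(s, t) {
        ns <- n_src(s, t); nt <- sizes[[t]]
        row <- network$connections[network$connections$source == s &
                                     network$connections$target == t, ]
        if (row$topology[1] == "one_to_one") as.integer(min(ns, nt))
        else as.integer(ns * nt)
      }
    )
  )
}

#' Serialise / restore a subject configuration
#'
#' Writes a human-readable `key = value` file holding the group, the full
#' projection table values and the subject's sampled parameters at full
#' double precision, and reads it back. Every weight, current and delay
#' value round-trips unchanged.
#'
#' @param network a [build_subject()] network.
#' @param path file path.
#' @return `write_network_config()` returns `path` invisibly;
#'   `read_network_config()` returns a named list of numeric values plus
#'   `group`.
#' @export
write_network_config <- function(network, path) {
  kv <- c(
    sprintf("group = %s", network$group),
    sprintf("dt = %.17g", network$dt),
    sprintf("pop.%s.size = %d", network$populations$name,
            network$populations$size),
    sprintf("pop.%s.I_e = %.17g", network$populations$name,
            network$populations$I_e),
    sprintf("w.%s.%s = %.17g", network$connections$source,
            network$connections$target, network$connections$weight),
    sprintf("d.%s.%s = %.17g", network$connections$source,
            network$connections$target, network$connections$delay),
    sprintf("subject.%s = %.17g",
            c("w_noise_dn", "I_e_M1", "I_e_mPFC", "beta", "gamma"),
            c(network$subject$w_noise_dn, network$subject$I_e_M1,
              network$subject$I_e_mPFC, network$subject$beta,
              network$subject$gamma))
  )
  writeLines(kv, path)
  invisible(path)
}

#' @rdname write_network_config
#' @export
read_network_config <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, " = ", fixed = TRUE)
  keys <- vapply(parts, `[`, "", 1)
  vals <- vapply(parts, `[`, "", 2)
  out <- as.list(suppressWarnings(as.numeric(vals)))
  names(out) <- keys
  out$group <- vals[keys == "group"]
  out
}
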