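// Discrete-time simulation of one 2,500 ms conditioning session.
//
// All ten populations are leaky integrate-and-fire neurons with exponential
// postsynaptic currents, advanced with the exact per-step propagator of the
// linear subsystem (no integration error below threshold). Spikes are
// detected at end of step; delayed deliveries travel through per-projection
// ring buffers. The two plasticity rules (eligibility-kernel LTD / fixed-rate
// LTP at granule->Purkinje, coincidence potentiation at prefrontal->motor)
// are applied event-wise, exactly as the R-level reference operations do.
//
// The engine draws no random numbers: noise trains are generated in R and
// passed in as event lists, so a session is a pure function of its inputs.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <climits>
using namespace Rcpp;

struct PopProp {
  double em, de, di, P21e, P21i, Vdrive, Vth, Vreset;
  int ref_steps;
};

static inline void add_current(std::vector<double>& iex,
                               std::vector<double>& iin,
                               int idx, double w) {
  if (w >= 0) iex[idx] += w; else iin[idx] += w;
}

// [[Rcpp::export]]
List run_session_cpp(List cfg) {
  const IntegerVector sizes = cfg["sizes"];
  const NumericMatrix pars = cfg["pars"];   // rows: pops; cols: C_m, tau_m,
                                            // E_L, V_th, V_reset, t_ref,
                                            // tau_e, tau_i, I_e
  const double dt = cfg["dt"];
  const int n_steps = cfg["n_steps"];
  const int n_pop = sizes.size();

  // population offsets into the flat neuron arrays
  std::vector<int> off(n_pop + 1, 0);
  for (int p = 0; p < n_pop; ++p) off[p + 1] = off[p] + sizes[p];
  const int n_tot = off[n_pop];

  std::vector<PopProp> prop(n_pop);
  std::vector<double> EL(n_pop);
  for (int p = 0; p < n_pop; ++p) {
    const double C = pars(p, 0), tm = pars(p, 1), el = pars(p, 2);
    const double vth = pars(p, 3), vre = pars(p, 4), tref = pars(p, 5);
    const double te = pars(p, 6), ti = pars(p, 7), ie = pars(p, 8);
    PopProp pp;
    pp.em = std::exp(-dt / tm);
    pp.de = std::exp(-dt / te);
    pp.di = std::exp(-dt / ti);
    pp.P21e = (std::fabs(te - tm) < 1e-12)
      ? dt * pp.em / C : (tm * te) / (C * (tm - te)) * (pp.em - std::exp(-dt / te));
    pp.P21i = (std::fabs(ti - tm) < 1e-12)
      ? dt * pp.em / C : (tm * ti) / (C * (tm - ti)) * (pp.em - std::exp(-dt / ti));
    pp.Vdrive = (el + ie * tm / C) * (1.0 - pp.em);
    pp.Vth = vth; pp.Vreset = vre;
    pp.ref_steps = (int) std::lround(tref / dt);
    prop[p] = pp;
    EL[p] = el;
  }

  // neuron state
  std::vector<double> V(n_tot), iex(n_tot, 0.0), iin(n_tot, 0.0);
  std::vector<int> refr(n_tot, 0);
  for (int p = 0; p < n_pop; ++p)
    for (int i = off[p]; i < off[p + 1]; ++i) V[i] = EL[p];

  // static scalar projections (all-to-all): counts ring
  const IntegerVector proj_src = cfg["proj_src"], proj_tgt = cfg["proj_tgt"];
  const NumericVector proj_w = cfg["proj_w"];
  const IntegerVector proj_delay = cfg["proj_delay"];
  const int n_proj = proj_src.size();

  // special populations
  const int GRM = cfg["grm"], GRC = cfg["grc"], IOM = cfg["iom"],
            IOC = cfg["ioc"], PCM = cfg["pcm"], PCC = cfg["pcc"],
            MPFC = cfg["mpfc"], M1 = cfg["m1"];
  const int d_gr_pc = cfg["d_gr_pc"], d_io_pc = cfg["d_io_pc"],
            d_mpfc_m1 = cfg["d_mpfc_m1"];
  const double w_io_pc = cfg["w_io_pc"];

  int ring_len = std::max(std::max(d_gr_pc, d_io_pc), d_mpfc_m1);
  for (int k = 0; k < n_proj; ++k) ring_len = std::max(ring_len, proj_delay[k]);
  ring_len += 2;

  std::vector<std::vector<int>> ring_cnt(n_proj, std::vector<int>(ring_len, 0));
  std::vector<std::vector<int>> ring_grm(ring_len), ring_grc(ring_len),
      ring_iom(ring_len), ring_ioc(ring_len), ring_mpfc(ring_len);

  // plastic weights (cloned: caller's matrices stay untouched)
  NumericMatrix W1m = clone(as<NumericMatrix>(cfg["W1m"]));
  NumericMatrix W1c = clone(as<NumericMatrix>(cfg["W1c"]));
  NumericMatrix W2 = clone(as<NumericMatrix>(cfg["W2"]));
  const double alpha = cfg["alpha"], beta = cfg["beta"],
               gamma = cfg["gamma"], w_cap = cfg["w_cap"];
  const int pc_win = cfg["pc_window_steps"], m1_win = cfg["mpfc_window_steps"];
  const NumericVector lut_m = cfg["lut_m"], lut_c = cfg["lut_c"];
  const int plast_start = cfg["plast_start_step"];
  const IntegerVector boundaries = cfg["trial_boundary_steps"];

  // stimulus arrivals: list of list(pop, w, steps) with steps sorted
  const List stim = cfg["stim"];
  const int n_stim = stim.size();
  std::vector<int> stim_pop(n_stim), stim_ptr(n_stim, 0);
  std::vector<double> stim_w(n_stim);
  std::vector<IntegerVector> stim_steps(n_stim);
  for (int k = 0; k < n_stim; ++k) {
    List e = stim[k];
    stim_pop[k] = as<int>(e["pop"]);
    stim_w[k] = as<double>(e["w"]);
    stim_steps[k] = as<IntegerVector>(e["steps"]);
  }

  // noise events (sorted by step): flat target index + step
  const IntegerVector noise_tgt = cfg["noise_tgt"];   // flat neuron index
  const IntegerVector noise_step = cfg["noise_step"];
  const double noise_w = cfg["noise_w"];
  int noise_ptr = 0;
  const int n_noise = noise_step.size();

  // spike-history buffers (granule arrival steps, current trial)
  const int n_grm = sizes[GRM], n_grc = sizes[GRC];
  const int n_pcm = sizes[PCM], n_pcc = sizes[PCC];
  const int n_mpfc = sizes[MPFC], n_m1 = sizes[M1];
  std::vector<std::vector<int>> buf_m(n_grm), buf_c(n_grc);
  std::vector<int> last_pcm(n_pcm, INT_MIN / 2), last_pcc(n_pcc, INT_MIN / 2);
  std::vector<int> last_mpfc(n_mpfc, INT_MIN / 2);
  std::vector<int> io_mark_m(n_pcm, -1), io_mark_c(n_pcc, -1);

  // lazy per-step eligibility
  std::vector<double> elig_m(n_grm, 0.0), elig_c(n_grc, 0.0);
  int elig_m_step = -1, elig_c_step = -1;
  const int lut_len_m = lut_m.size(), lut_len_c = lut_c.size();

  const bool record_gr = cfg["record_gr"];
  std::vector<std::vector<int>> sp_id(n_pop), sp_step(n_pop);
  std::vector<int> step_spikes;       // scratch: flat ids spiking this step
  std::vector<int> pop_count(n_pop);  // spikes per pop this step
  long long dropped = 0;
  int bptr = 0;

  for (int s = 1; s <= n_steps; ++s) {
    const int slot = s % ring_len;
    const bool plast_on = s >= plast_start;

    // trial boundary: clear parallel-fibre history
    while (bptr < boundaries.size() && boundaries[bptr] == s) {
      for (auto& b : buf_m) b.clear();
      for (auto& b : buf_c) b.clear();
      ++bptr;
    }

    // 1. membrane update + 2. threshold detection
    step_spikes.clear();
    std::fill(pop_count.begin(), pop_count.end(), 0);
    for (int p = 0; p < n_pop; ++p) {
      const PopProp& pp = prop[p];
      for (int i = off[p]; i < off[p + 1]; ++i) {
        if (refr[i] > 0) {
          --refr[i];
          V[i] = pp.Vreset;
        } else {
          V[i] = V[i] * pp.em + pp.Vdrive + iex[i] * pp.P21e + iin[i] * pp.P21i;
          if (V[i] >= pp.Vth) {
            V[i] = pp.Vreset;
            refr[i] = pp.ref_steps;
            step_spikes.push_back(i);
            ++pop_count[p];
          }
        }
        iex[i] *= pp.de;
        iin[i] *= pp.di;
      }
    }

    // 3. per-spike bookkeeping (records, scheduling, spike-driven plasticity)
    for (int flat : step_spikes) {
      int p = 0;
      while (off[p + 1] <= flat) ++p;
      const int id = flat - off[p];
      if (record_gr || (p != GRM && p != GRC)) {
        sp_id[p].push_back(id);
        sp_step[p].push_back(s);
      }
      if (p == GRM || p == GRC) {
        const int arr = s + d_gr_pc;
        if (arr > n_steps) { ++dropped; continue; }
        (p == GRM ? ring_grm : ring_grc)[arr % ring_len].push_back(id);
      } else if (p == IOM || p == IOC) {
        const int n_pc = (p == IOM) ? n_pcm : n_pcc;
        if (id < n_pc) {  // surplus olive cells have no Purkinje partner
          const int arr = s + d_io_pc;
          if (arr > n_steps) ++dropped;
          else (p == IOM ? ring_iom : ring_ioc)[arr % ring_len].push_back(id);
        }
      } else if (p == PCM) {
        last_pcm[id] = s;
      } else if (p == PCC) {
        last_pcc[id] = s;
      } else if (p == MPFC) {
        last_mpfc[id] = s;
        const int arr = s + d_mpfc_m1;
        if (arr > n_steps) ++dropped;
        else ring_mpfc[arr % ring_len].push_back(id);
      } else if (p == M1 && plast_on) {
        // coincidence rule: prefrontal spike within the window before this
        // motor spike potentiates, otherwise depresses
        for (int i = 0; i < n_mpfc; ++i) {
          double w = W2(i, id) + ((s - last_mpfc[i]) <= m1_win ? beta : gamma);
          W2(i, id) = w < 0.0 ? 0.0 : (w > w_cap ? w_cap : w);
        }
      }
    }
    // static scalar projections: schedule by per-population spike counts
    for (int k = 0; k < n_proj; ++k) {
      const int c = pop_count[proj_src[k]];
      if (c) {
        const int arr = s + proj_delay[k];
        if (arr > n_steps) dropped += c;
        else ring_cnt[k][arr % ring_len] += c;
      }
    }

    // 4a. stimulus arrivals
    for (int k = 0; k < n_stim; ++k) {
      const IntegerVector& st = stim_steps[k];
      int& ptr = stim_ptr[k];
      while (ptr < st.size() && st[ptr] == s) {
        const int p = stim_pop[k];
        const double w = stim_w[k];
        for (int i = off[p]; i < off[p + 1]; ++i) add_current(iex, iin, i, w);
        ++ptr;
      }
    }
    // 4b. noise arrivals (one independent source per dentate neuron)
    while (noise_ptr < n_noise && noise_step[noise_ptr] == s) {
      iex[noise_tgt[noise_ptr]] += noise_w;
      ++noise_ptr;
    }
    // 4c. static projection deliveries
    for (int k = 0; k < n_proj; ++k) {
      int& c = ring_cnt[k][slot];
      if (c) {
        const int p = proj_tgt[k];
        const double w = proj_w[k] * c;
        for (int i = off[p]; i < off[p + 1]; ++i) add_current(iex, iin, i, w);
        c = 0;
      }
    }
    // 4d. olive -> Purkinje (one-to-one): current + associative LTD
    for (int path = 0; path < 2; ++path) {
      std::vector<int>& ring = (path == 0 ? ring_iom : ring_ioc)[slot];
      if (ring.empty()) continue;
      const int pcp = path == 0 ? PCM : PCC;
      std::vector<int>& last_pc = path == 0 ? last_pcm : last_pcc;
      std::vector<int>& io_mark = path == 0 ? io_mark_m : io_mark_c;
      NumericMatrix& W = path == 0 ? W1m : W1c;
      for (int j : ring) {
        iin[off[pcp] + j] += w_io_pc;
        io_mark[j] = s;
        if (plast_on && s - last_pc[j] <= pc_win) {
          // depression by the kernel-convolved parallel-fibre history
          std::vector<double>& elig = path == 0 ? elig_m : elig_c;
          int& tag = path == 0 ? elig_m_step : elig_c_step;
          const NumericVector& lut = path == 0 ? lut_m : lut_c;
          const int lut_len = path == 0 ? lut_len_m : lut_len_c;
          std::vector<std::vector<int>>& buf = path == 0 ? buf_m : buf_c;
          const int n_gr = path == 0 ? n_grm : n_grc;
          if (tag != s) {
            for (int g = 0; g < n_gr; ++g) {
              double e = 0.0;
              for (int b : buf[g]) {
                const int lag = s - b;
                if (lag >= 0 && lag < lut_len) e += lut[lag];
              }
              elig[g] = e;
            }
            tag = s;
          }
          for (int g = 0; g < (path == 0 ? n_grm : n_grc); ++g) {
            double w = W(g, j) - elig[g];
            W(g, j) = w < 0.0 ? 0.0 : w;
          }
        }
      }
      ring.clear();
    }
    // 4e. granule -> Purkinje deliveries: current, history, LTP
    for (int path = 0; path < 2; ++path) {
      std::vector<int>& ring = (path == 0 ? ring_grm : ring_grc)[slot];
      if (ring.empty()) continue;
      const int pcp = path == 0 ? PCM : PCC;
      const int n_pc = path == 0 ? n_pcm : n_pcc;
      std::vector<int>& last_pc = path == 0 ? last_pcm : last_pcc;
      std::vector<int>& io_mark = path == 0 ? io_mark_m : io_mark_c;
      std::vector<std::vector<int>>& buf = path == 0 ? buf_m : buf_c;
      NumericMatrix& W = path == 0 ? W1m : W1c;
      for (int g : ring) {
        buf[g].push_back(s);
        for (int j = 0; j < n_pc; ++j) {
          iex[off[pcp] + j] += W(g, j);
          if (plast_on && s - last_pc[j] <= pc_win && io_mark[j] != s) {
            W(g, j) += alpha;   // non-associative LTP, olive-exclusive
          }
        }
      }
      ring.clear();
    }
    // 4f. prefrontal -> motor deliveries (plastic weights)
    {
      std::vector<int>& ring = ring_mpfc[slot];
      for (int i : ring)
        for (int j = 0; j < n_m1; ++j) iex[off[M1] + j] += W2(i, j);
      ring.clear();
    }
  }

  List spikes(n_pop);
  for (int p = 0; p < n_pop; ++p) {
    spikes[p] = List::create(_["id"] = wrap(sp_id[p]),
                             _["step"] = wrap(sp_step[p]));
  }
  return List::create(
    _["spikes"] = spikes,
    _["W1m"] = W1m, _["W1c"] = W1c, _["W2"] = W2,
    _["dropped"] = (double) dropped
  );
}
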