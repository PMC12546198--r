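// Core integrator for the thalamocortical microcircuit.
//
// Forward-Euler co-integration of Izhikevich membrane dynamics and
// Tsodyks-Markram short-term plasticity. Each neuron owns one TM synapse
// state describing its outgoing postsynaptic current (PSC); postsynaptic
// drive is a weighted sum of presynaptic PSC traces read from a ring
// buffer at the projection delay. Single-threaded and driven entirely by
// the R RNG, so runs are bitwise reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export(name = ".tcm_simulate_cpp")]]
List tcm_simulate_cpp(const arma::vec& a, const arma::vec& b,
                      const arma::vec& c, const arma::vec& d,
                      const arma::vec& vpeak, const arma::vec& ibias,
                      const arma::vec& U, const arma::vec& tau_f,
                      const arma::vec& tau_d, const arma::vec& tau_s,
                      const arma::vec& A,
                      const arma::mat& W,
                      const arma::imat& delay_steps,   // n_pop x n_pop (target row, source col)
                      const arma::ivec& pop_offset,    // 0-based start of each population
                      const arma::ivec& pop_size,
                      double xi_sd, double zeta_sd,
                      double dt, int n_steps,
                      const arma::vec& dbs_wave,       // length n_steps (current units)
                      const arma::uvec& dbs_mask,      // 0/1 per neuron
                      const arma::ivec& record_idx,    // 0-based neuron ids, may be empty
                      const int record_stride,         // keep every k-th sample
                      const arma::vec& v0, const arma::vec& u0)
{
  const int n = (int) a.n_elem;
  const int n_pop = (int) pop_size.n_elem;
  if ((int) dbs_wave.n_elem != n_steps)
    stop("DBS waveform length does not match the number of steps");

  // TM decay factors (exact exponentials between spikes)
  arma::vec ef = arma::exp(-dt / tau_f);
  arma::vec ed = arma::exp(-dt / tau_d);
  arma::vec es = arma::exp(-dt / tau_s);

  // states
  arma::vec v = v0, u = u0;
  arma::vec us(n, arma::fill::zeros);        // TM utilisation
  arma::vec xs(n, arma::fill::ones);         // TM resources
  arma::vec Is(n, arma::fill::zeros);        // per-neuron PSC

  // delay ring buffer: one column per time slot
  int maxdel = delay_steps.max();
  if (maxdel < 1) maxdel = 1;
  const int L = maxdel + 1;
  arma::mat psc_hist(n, L, arma::fill::zeros);

  arma::mat psc_pop(n_steps, n_pop, arma::fill::zeros);
  const int n_rec = (int) record_idx.n_elem;
  const int stride = record_stride < 1 ? 1 : record_stride;
  arma::mat v_rec;
  if (n_rec > 0) v_rec.set_size((n_steps + stride - 1) / stride, n_rec);

  std::vector<int> sp_step;
  std::vector<int> sp_id;
  sp_step.reserve(1 << 16);
  sp_id.reserve(1 << 16);

  arma::vec syn(n), psc_del(n), xi(n), zeta(n), vdisp(n);

  for (int t = 0; t < n_steps; ++t) {
    const int cur = t % L;

    // 1. spike-free TM decay
    us %= ef;
    xs = 1.0 - (1.0 - xs) % ed;
    Is %= es;

    // 2. synaptic drive: per target population, weighted sum of delayed PSCs
    for (int j = 0; j < n_pop; ++j) {
      if (pop_size[j] == 0) continue;
      for (int jp = 0; jp < n_pop; ++jp) {
        if (pop_size[jp] == 0) continue;
        int slot = (cur - (int) delay_steps(j, jp) % L + L) % L;
        psc_del.subvec(pop_offset[jp], pop_offset[jp] + pop_size[jp] - 1) =
          psc_hist(arma::span(pop_offset[jp], pop_offset[jp] + pop_size[jp] - 1),
                   arma::span(slot, slot));
      }
      syn.subvec(pop_offset[j], pop_offset[j] + pop_size[j] - 1) =
        W.rows(pop_offset[j], pop_offset[j] + pop_size[j] - 1) * psc_del;
    }

    // 3. noise draws (fixed order and count per step for reproducibility)
    for (int i = 0; i < n; ++i) xi[i] = norm_rand() * xi_sd;
    for (int i = 0; i < n; ++i) zeta[i] = norm_rand() * zeta_sd;

    // 4. Euler update of (v, u) from the previous state
    const double stim = dbs_wave[t];
    for (int i = 0; i < n; ++i) {
      double vin = v[i];
      double inp = ibias[i] + syn[i] + xi[i];
      if (stim != 0.0 && dbs_mask[i]) inp += stim;
      v[i] = vin + dt * (0.04 * vin * vin + 5.0 * vin + 140.0 - u[i] + inp);
      u[i] = u[i] + dt * a[i] * (b[i] * vin - u[i]);
    }

    // 5. noisy-threshold reset + TM jump on the neuron's outgoing synapse
    for (int i = 0; i < n; ++i) {
      double thr = vpeak[i] + zeta[i];
      if (v[i] >= thr) {
        vdisp[i] = thr;            // clamp recorded amplitude at the cutoff
        sp_step.push_back(t);
        sp_id.push_back(i);
        v[i] = c[i];
        u[i] += d[i];
        us[i] += U[i] * (1.0 - us[i]);
        double dI = A[i] * us[i] * xs[i];
        xs[i] -= us[i] * xs[i];
        Is[i] += dI;
      } else {
        vdisp[i] = v[i];
      }
    }

    // 6. record + publish PSCs for delayed readout
    psc_hist.col(cur) = Is;
    for (int j = 0; j < n_pop; ++j) {
      if (pop_size[j] == 0) continue;
      psc_pop(t, j) = arma::accu(Is.subvec(pop_offset[j],
                                           pop_offset[j] + pop_size[j] - 1));
    }
    if (n_rec > 0 && t % stride == 0)
      for (int k = 0; k < n_rec; ++k) v_rec(t / stride, k) = vdisp[record_idx[k]];

    if ((t & 1023) == 0 && !v.is_finite())
      stop("non-finite membrane state at t = %f ms", t * dt);
  }
  if (!v.is_finite())
    stop("non-finite membrane state at end of run");

  return List::create(
    _["spike_step"] = IntegerVector(sp_step.begin(), sp_step.end()),
    _["spike_id"]   = IntegerVector(sp_id.begin(), sp_id.end()),
    _["psc_pop"]    = psc_pop,
    _["v_rec"]      = v_rec);
}
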