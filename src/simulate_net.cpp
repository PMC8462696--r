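// Fixed-step simulation of networks of leaky integrate-and-fire neurons
// with double-exponential conductance synapses.
//
// Units: time ms, voltage mV, conductance uS, current nA, capacitance nF.
//
// Each synaptic connection keeps two decay traces per presynaptic neuron
// (xD, xR); their difference reproduces exp(-t/tauD) - exp(-t/tauR)
// exactly on the step grid, so the per-step cost is two scalings, a
// sparse mat-vec and a vector update.  Spikes emitted at step n increment
// the traces at the end of step n and therefore influence currents from
// step n+1 onward.
//
// The membrane is advanced with exponential Euler (conductances held
// constant over the step):  V <- V_inf + (V - V_inf) exp(-g_tot dt / C),
// V_inf = (g_leak E_leak + sum_s g_s E_s + i_app + noise) / g_tot.
// This is unconditionally stable -- required because saturated
// presynaptic populations can push summed conductances to O(100) uS,
// where the effective membrane time constant C/g_tot drops far below any
// usable dt -- and it confines V to the span of the reversal potentials.
#include <RcppArmadillo.h>
using namespace Rcpp;

// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
List lif_simulate_cpp(List pops, List conns, List ext, double duration,
                      double dt, LogicalVector record_v, int v_stride) {
  const int n_pop = pops.size();
  const int n_conn = conns.size();
  const int n_steps = (int) std::round(duration / dt);

  std::vector<int> pop_n(n_pop);
  std::vector<bool> is_src(n_pop);
  std::vector<double> Cm(n_pop), gl(n_pop), El(n_pop), Vth(n_pop),
      Vre(n_pop), noise(n_pop);
  std::vector<arma::vec> iapp(n_pop), V(n_pop);
  std::vector<arma::uvec> fired(n_pop);   // spikes emitted at previous step
  std::vector<std::vector<double>> sp_t(n_pop);
  std::vector<std::vector<int>> sp_id(n_pop);

  for (int p = 0; p < n_pop; ++p) {
    List pp = pops[p];
    pop_n[p] = as<int>(pp["n"]);
    is_src[p] = as<bool>(pp["source"]);
    if (!is_src[p]) {
      Cm[p] = as<double>(pp["C"]);
      gl[p] = as<double>(pp["g_leak"]);
      El[p] = as<double>(pp["E_leak"]);
      Vth[p] = as<double>(pp["V_thresh"]);
      Vre[p] = as<double>(pp["V_reset"]);
      noise[p] = as<double>(pp["noise"]);
      iapp[p] = as<arma::vec>(pp["i_app"]);
      V[p] = as<arma::vec>(pp["V0"]);
    }
    fired[p] = arma::uvec();
  }

  // external (source-population) spikes, pre-binned by step
  std::vector<std::vector<int>> src_step(n_pop), src_id(n_pop);
  std::vector<size_t> src_ptr(n_pop, 0);
  for (int p = 0; p < n_pop; ++p) {
    if (!is_src[p]) continue;
    List ee = ext[p];
    IntegerVector nid = ee["neuron"];
    NumericVector tim = ee["time"];
    std::vector<std::pair<int,int>> ev(nid.size());
    for (int k = 0; k < nid.size(); ++k) {
      int st = (int) std::round(tim[k] / dt);
      if (st < 0) st = 0;
      if (st >= n_steps) st = n_steps - 1;
      ev[k] = std::make_pair(st, nid[k] - 1);
    }
    std::sort(ev.begin(), ev.end());
    src_step[p].resize(ev.size());
    src_id[p].resize(ev.size());
    for (size_t k = 0; k < ev.size(); ++k) {
      src_step[p][k] = ev[k].first;
      src_id[p][k] = ev[k].second;
    }
  }

  // connections
  std::vector<int> c_pre(n_conn), c_post(n_conn);
  std::vector<double> c_g(n_conn), c_E(n_conn), c_dD(n_conn), c_dR(n_conn);
  std::vector<arma::sp_mat> c_Wt(n_conn);       // transposed: n_post x n_pre
  std::vector<arma::vec> c_xD(n_conn), c_xR(n_conn), c_rg(n_conn);
  std::vector<bool> c_has_rg(n_conn);
  for (int c = 0; c < n_conn; ++c) {
    List cc = conns[c];
    c_pre[c] = as<int>(cc["pre"]) - 1;
    c_post[c] = as<int>(cc["post"]) - 1;
    c_g[c] = as<double>(cc["g_syn"]);
    c_E[c] = as<double>(cc["E_syn"]);
    double tauD = as<double>(cc["tau_D"]), tauR = as<double>(cc["tau_R"]);
    c_dD[c] = std::exp(-dt / tauD);
    c_dR[c] = std::exp(-dt / tauR);
    arma::sp_mat W = as<arma::sp_mat>(cc["W"]);
    c_Wt[c] = W.t();
    c_xD[c] = arma::zeros<arma::vec>(pop_n[c_pre[c]]);
    c_xR[c] = arma::zeros<arma::vec>(pop_n[c_pre[c]]);
    SEXP rg = cc["row_gain"];
    c_has_rg[c] = !Rf_isNull(rg);
    if (c_has_rg[c]) c_rg[c] = as<arma::vec>(cc["row_gain"]);
  }

  // voltage recording
  std::vector<arma::mat> vtr(n_pop);
  for (int p = 0; p < n_pop; ++p)
    if (record_v[p] && !is_src[p]) {
      vtr[p] = arma::mat(pop_n[p], n_steps / v_stride + 1);
      vtr[p].col(0) = V[p];
    }

  std::vector<arma::vec> gsum(n_pop), gesum(n_pop);
  for (int p = 0; p < n_pop; ++p)
    if (!is_src[p]) {
      gsum[p] = arma::zeros<arma::vec>(pop_n[p]);
      gesum[p] = arma::zeros<arma::vec>(pop_n[p]);
    }

  RNGScope scope;

  for (int step = 0; step < n_steps; ++step) {
    double t_now = (step + 1) * dt;  // state after this step refers to t_now

    // 1. decay traces, then inject spikes emitted at the previous step
    for (int c = 0; c < n_conn; ++c) {
      c_xD[c] *= c_dD[c];
      c_xR[c] *= c_dR[c];
      const arma::uvec &f = fired[c_pre[c]];
      for (arma::uword k = 0; k < f.n_elem; ++k) {
        c_xD[c][f[k]] += 1.0;
        c_xR[c][f[k]] += 1.0;
      }
    }

    // 2. source spikes scheduled for this step
    for (int p = 0; p < n_pop; ++p) {
      if (!is_src[p]) continue;
      std::vector<arma::uword> now;
      size_t &ptr = src_ptr[p];
      while (ptr < src_step[p].size() && src_step[p][ptr] == step) {
        now.push_back((arma::uword) src_id[p][ptr]);
        sp_t[p].push_back(t_now);
        sp_id[p].push_back(src_id[p][ptr] + 1);
        ++ptr;
      }
      fired[p] = arma::uvec(now);
    }

    // 3. synaptic conductances per postsynaptic population
    for (int p = 0; p < n_pop; ++p)
      if (!is_src[p]) { gsum[p].zeros(); gesum[p].zeros(); }
    for (int c = 0; c < n_conn; ++c) {
      int p = c_post[c];
      if (is_src[p]) continue;
      arma::vec k = c_xD[c] - c_xR[c];
      if (c_has_rg[c]) k %= c_rg[c];
      arma::vec gv = c_g[c] * (c_Wt[c] * k);
      gsum[p] += gv;
      gesum[p] += gv * c_E[c];
    }

    // 4. exponential-Euler membrane update + threshold / reset
    for (int p = 0; p < n_pop; ++p) {
      if (is_src[p]) continue;
      arma::vec gtot = gsum[p] + gl[p];
      arma::vec inum = gesum[p] + gl[p] * El[p] + iapp[p];
      if (noise[p] > 0)
        for (int i = 0; i < pop_n[p]; ++i) inum[i] += noise[p] * norm_rand();
      for (int i = 0; i < pop_n[p]; ++i) {
        double vinf = inum[i] / gtot[i];
        V[p][i] = vinf + (V[p][i] - vinf) * std::exp(-gtot[i] * dt / Cm[p]);
      }
      arma::uvec f = arma::find(V[p] > Vth[p]);
      for (arma::uword k = 0; k < f.n_elem; ++k) {
        sp_t[p].push_back(t_now);
        sp_id[p].push_back((int) f[k] + 1);
        V[p][f[k]] = Vre[p];
      }
      fired[p] = f;
      if (!V[p].is_finite())
        stop("non-finite membrane potential (population %d, t = %.3f ms); "
             "check parameters and dt", p + 1, t_now);
      if (record_v[p] && (step + 1) % v_stride == 0)
        vtr[p].col((step + 1) / v_stride) = V[p];
    }
  }

  List spikes(n_pop), volts(n_pop);
  for (int p = 0; p < n_pop; ++p) {
    spikes[p] = DataFrame::create(_["neuron"] = wrap(sp_id[p]),
                                  _["time"] = wrap(sp_t[p]));
    if (record_v[p] && !is_src[p]) volts[p] = wrap(vtr[p]);
  }
  return List::create(_["spikes"] = spikes, _["voltages"] = volts,
                      _["n_steps"] = n_steps);
}
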