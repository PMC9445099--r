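// Core stepping loop of the stochastic spatial branching simulator.
//
// The R wrapper (simulate_organoid) owns configuration, perturbation
// schedules and tree snapshots; this routine advances the branch state
// over a contiguous block of fixed time steps and accumulates per-branch
// samples, organoid summaries, tip tracks and event logs. All random
// draws use R's RNG, so runs are reproducible from set.seed() alone.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct SimState {
  int n;
  int dim;
  std::vector<int> parent;
  std::vector<double> birth, length, volume, width, last_div;
  std::vector<int> terminal, broken, arrested;
  std::vector<double> dir; // n x dim, row-major
  std::vector<double> tip; // n x dim, row-major
  bool record_nodes;
  std::vector<std::vector<double>> nodes; // per branch, flattened rows
};

void push_node(SimState &st, int i) {
  for (int c = 0; c < st.dim; ++c) st.nodes[i].push_back(st.tip[i * st.dim + c]);
}

// random unit vector perpendicular to row i of dir
void random_perp(const SimState &st, int i, double *out) {
  const double *d = &st.dir[i * st.dim];
  if (st.dim == 2) {
    double s = (unif_rand() < 0.5) ? -1.0 : 1.0;
    out[0] = -s * d[1];
    out[1] = s * d[0];
    return;
  }
  double r[3], proj = 0.0;
  for (int c = 0; c < 3; ++c) r[c] = norm_rand();
  for (int c = 0; c < 3; ++c) proj += r[c] * d[c];
  double nrm2 = 0.0;
  for (int c = 0; c < 3; ++c) {
    out[c] = r[c] - proj * d[c];
    nrm2 += out[c] * out[c];
  }
  if (nrm2 < 1e-18) { // degenerate draw: deterministic fallback
    double b[3] = {0, 0, 0};
    b[(std::fabs(d[0]) < 0.9) ? 0 : 1] = 1.0;
    proj = 0.0;
    for (int c = 0; c < 3; ++c) proj += b[c] * d[c];
    nrm2 = 0.0;
    for (int c = 0; c < 3; ++c) {
      out[c] = b[c] - proj * d[c];
      nrm2 += out[c] * out[c];
    }
  }
  double nrm = std::sqrt(nrm2);
  for (int c = 0; c < 3; ++c) out[c] /= nrm;
}

SimState state_from_list(List s) {
  SimState st;
  st.n = as<int>(s["n"]);
  st.dim = as<int>(s["dim"]);
  st.parent = as<std::vector<int>>(s["parent"]);
  st.birth = as<std::vector<double>>(s["birth"]);
  st.length = as<std::vector<double>>(s["length"]);
  st.volume = as<std::vector<double>>(s["volume"]);
  st.width = as<std::vector<double>>(s["width"]);
  st.last_div = as<std::vector<double>>(s["last_div"]);
  st.terminal = as<std::vector<int>>(s["terminal"]);
  st.broken = as<std::vector<int>>(s["broken"]);
  st.arrested = as<std::vector<int>>(s["arrested"]);
  st.dir = as<std::vector<double>>(s["dir"]);
  st.tip = as<std::vector<double>>(s["tip"]);
  st.record_nodes = as<bool>(s["record_nodes"]);
  if (st.record_nodes) {
    List nd = s["nodes"];
    st.nodes.resize(st.n);
    for (int i = 0; i < st.n; ++i)
      st.nodes[i] = as<std::vector<double>>(nd[i]);
  }
  return st;
}

List state_to_list(const SimState &st) {
  List out = List::create(
      _["n"] = st.n, _["dim"] = st.dim, _["parent"] = st.parent,
      _["birth"] = st.birth, _["length"] = st.length,
      _["volume"] = st.volume, _["width"] = st.width,
      _["last_div"] = st.last_div, _["terminal"] = st.terminal,
      _["broken"] = st.broken, _["arrested"] = st.arrested,
      _["dir"] = st.dir, _["tip"] = st.tip,
      _["record_nodes"] = st.record_nodes);
  if (st.record_nodes) {
    List nd(st.n);
    for (int i = 0; i < st.n; ++i) nd[i] = st.nodes[i];
    out["nodes"] = nd;
  }
  return out;
}

} // namespace

// [[Rcpp::export(name = ".sim_chunk")]]
List sim_chunk(List state, List par, List cfg, int k0, int k1,
               IntegerVector sample_steps, IntegerVector track_steps) {
  SimState st = state_from_list(state);

  const double v0 = as<double>(par["v0"]);
  const double kb = as<double>(par["kb"]);
  const double kd0 = as<double>(par["kd0"]);
  const double w0 = as<double>(par["w0"]);
  const double l_init = as<double>(par["l_init"]);
  const double w_min = as<double>(par["w_min"]);

  const double dt = as<double>(cfg["dt"]);
  const double dtheta = as<double>(cfg["dtheta"]);
  const double theta_b = as<double>(cfg["theta_b"]);
  const int n_tip = as<int>(cfg["n_tip_cells"]);
  const bool coupled = as<bool>(cfg["couple_branching_to_division"]);
  const bool split_mother = as<bool>(cfg["split_mother_volume"]);
  const double sad = as<double>(cfg["sad"]); // <0 disables
  const int node_every = as<int>(cfg["node_every"]);
  const int dim = st.dim;

  const double ang_sd = std::sqrt(dtheta * dt);
  const double p_branch = 1.0 - std::exp(-kb * dt);

  // record accumulators
  std::vector<double> s_time, s_birth, s_width, s_vol, s_len;
  std::vector<int> s_id, s_parent, s_term, s_broken;
  std::vector<double> sum_rows; // 7 values per sampled time
  std::vector<double> tr_time, tr_len;
  std::vector<int> tr_id;
  std::vector<double> ev_time, ev_lastdiv, dv_time;
  std::vector<int> ev_id, dv_id;

  std::size_t samp_ptr = 0, track_ptr = 0;
  // skip past pointers below k0
  while (samp_ptr < (std::size_t)sample_steps.size() &&
         sample_steps[samp_ptr] <= k0)
    ++samp_ptr;
  while (track_ptr < (std::size_t)track_steps.size() &&
         track_steps[track_ptr] <= k0)
    ++track_ptr;

  RNGScope rng;

  for (int k = k0 + 1; k <= k1; ++k) {
    const double t_new = k * dt;

    // 1. elongation with angular diffusion of the tip direction
    if (v0 > 0) {
      for (int i = 0; i < st.n; ++i) {
        if (!(st.terminal[i] && !st.broken[i] && !st.arrested[i])) continue;
        double *d = &st.dir[i * dim];
        if (dtheta > 0) {
          double ang = norm_rand() * ang_sd;
          double perp[3];
          random_perp(st, i, perp);
          double ca = std::cos(ang), sa = std::sin(ang), nrm2 = 0.0;
          for (int c = 0; c < dim; ++c) {
            d[c] = ca * d[c] + sa * perp[c];
            nrm2 += d[c] * d[c];
          }
          double nrm = std::sqrt(nrm2);
          for (int c = 0; c < dim; ++c) d[c] /= nrm;
        }
        for (int c = 0; c < dim; ++c) st.tip[i * dim + c] += v0 * dt * d[c];
        st.length[i] += v0 * dt;
        if (st.record_nodes && (k % node_every == 0)) push_node(st, i);
      }
    }

    // 2. volumetric growth under the width feedback; 3. rupture
    for (int i = 0; i < st.n; ++i) {
      if (st.broken[i]) continue;
      double kd = kd0 * std::max(0.0, 1.0 - st.width[i] / w0);
      st.volume[i] *= std::exp(kd * dt);
      st.width[i] = std::sqrt(4.0 * st.volume[i] / (M_PI * st.length[i]));
      if (st.width[i] < w_min) st.broken[i] = 1;
    }

    // 4. self-avoidance (optional): arrest tips near other centerlines
    if (sad > 0 && st.record_nodes && (k % node_every == 0)) {
      for (int i = 0; i < st.n; ++i) {
        if (!(st.terminal[i] && !st.broken[i] && !st.arrested[i])) continue;
        const double *tp = &st.tip[i * dim];
        bool hit = false;
        for (int j = 0; j < st.n && !hit; ++j) {
          if (j == i || st.parent[i] == j + 1) continue;
          const std::vector<double> &nd = st.nodes[j];
          for (std::size_t r = 0; r + dim <= nd.size(); r += dim) {
            double d2 = 0.0;
            for (int c = 0; c < dim; ++c) {
              double dx = nd[r + c] - tp[c];
              d2 += dx * dx;
            }
            if (d2 < sad * sad) { hit = true; break; }
          }
        }
        if (hit) st.arrested[i] = 1;
      }
    }

    // 5. tip-compartment divisions and branching
    const int n_before = st.n;
    for (int i = 0; i < n_before; ++i) {
      if (!(st.terminal[i] && !st.broken[i] && !st.arrested[i])) continue;
      double kd = kd0 * std::max(0.0, 1.0 - st.width[i] / w0);
      double p_div = 1.0 - std::exp(-n_tip * kd * dt);
      bool div = unif_rand() < p_div;
      if (div) {
        st.last_div[i] = t_new;
        dv_time.push_back(t_new);
        dv_id.push_back(i + 1);
      }
      double u_br = unif_rand();
      bool br;
      if (coupled) {
        // thinning: conditional probability given a division, so the
        // per-step marginal equals the Poisson probability exactly
        double p_cond = (p_div > 0) ? std::min(1.0, p_branch / p_div) : 0.0;
        br = div && (u_br < p_cond);
      } else {
        br = u_br < p_branch;
      }
      if (!br) continue;

      // branching event: mother i -> two daughters at +/- theta_b
      if (st.record_nodes) push_node(st, i);
      double perp[3];
      random_perp(st, i, perp);
      double w = st.width[i];
      double vol = 0.25 * M_PI * w * w * l_init;
      if (split_mother) {
        double take = std::min(2.0 * vol, 0.5 * st.volume[i]);
        st.volume[i] -= take;
        st.width[i] = std::sqrt(4.0 * st.volume[i] / (M_PI * st.length[i]));
        vol = take / 2.0;
        w = std::sqrt(4.0 * vol / (M_PI * l_init));
      }
      const double *dm = &st.dir[i * dim];
      double dmother[3], tipm[3];
      for (int c = 0; c < dim; ++c) {
        dmother[c] = dm[c];
        tipm[c] = st.tip[i * dim + c];
      }
      for (int s = 0; s < 2; ++s) {
        double ang = (s == 0) ? theta_b : -theta_b;
        double ca = std::cos(ang), sa = std::sin(ang);
        st.parent.push_back(i + 1);
        st.birth.push_back(t_new);
        st.length.push_back(l_init);
        st.volume.push_back(vol);
        st.width.push_back(w);
        st.terminal.push_back(1);
        st.broken.push_back(0);
        st.arrested.push_back(0);
        st.last_div.push_back(NA_REAL);
        for (int c = 0; c < dim; ++c) {
          double dc = ca * dmother[c] + sa * perp[c];
          st.dir.push_back(dc);
          st.tip.push_back(tipm[c] + l_init * dc);
        }
        if (st.record_nodes) {
          std::vector<double> nd;
          for (int c = 0; c < dim; ++c) nd.push_back(tipm[c]);
          int j = (int)st.parent.size() - 1;
          for (int c = 0; c < dim; ++c)
            nd.push_back(st.tip[j * dim + c]);
          st.nodes.push_back(nd);
        }
        ++st.n;
      }
      st.terminal[i] = 0;
      ev_time.push_back(t_new);
      ev_id.push_back(i + 1);
      ev_lastdiv.push_back(st.last_div[i]);
    }

    // sanity: finite state
    for (int i = 0; i < st.n; ++i) {
      if (!std::isfinite(st.width[i]) || !std::isfinite(st.length[i]))
        stop("simulation produced a non-finite state at step %d (t = %g)",
             k, t_new);
    }

    // sampling
    if (samp_ptr < (std::size_t)sample_steps.size() &&
        sample_steps[samp_ptr] == k) {
      ++samp_ptr;
      double tot_len = 0, tot_vol = 0;
      int n_term = 0, n_brk = 0;
      for (int i = 0; i < st.n; ++i) {
        s_time.push_back(t_new);
        s_id.push_back(i + 1);
        s_parent.push_back(st.parent[i]);
        s_birth.push_back(st.birth[i]);
        s_width.push_back(st.width[i]);
        s_vol.push_back(st.volume[i]);
        s_len.push_back(st.length[i]);
        s_term.push_back(st.terminal[i]);
        s_broken.push_back(st.broken[i]);
        tot_len += st.length[i];
        tot_vol += st.volume[i];
        n_term += st.terminal[i];
        n_brk += st.broken[i];
      }
      double row[7] = {t_new, (double)st.n, (double)n_term,
                       (double)(st.n - n_term), (double)n_brk, tot_len,
                       tot_vol};
      sum_rows.insert(sum_rows.end(), row, row + 7);
    }
    if (track_ptr < (std::size_t)track_steps.size() &&
        track_steps[track_ptr] == k) {
      ++track_ptr;
      for (int i = 0; i < st.n; ++i) {
        if (st.terminal[i] && !st.broken[i] && !st.arrested[i]) {
          tr_id.push_back(i + 1);
          tr_time.push_back(t_new);
          tr_len.push_back(st.length[i]);
        }
      }
    }
  }

  return List::create(
      _["state"] = state_to_list(st),
      _["samples"] = List::create(
          _["time"] = s_time, _["branch_id"] = s_id,
          _["parent_id"] = s_parent, _["birth_time"] = s_birth,
          _["width"] = s_width, _["volume"] = s_vol, _["length"] = s_len,
          _["terminal"] = s_term, _["broken"] = s_broken),
      _["summary"] = sum_rows,
      _["tracks"] = List::create(_["branch_id"] = tr_id,
                                 _["time"] = tr_time,
                                 _["path_length"] = tr_len),
      _["events"] = List::create(_["time"] = ev_time,
                                 _["branch_id"] = ev_id,
                                 _["last_division_time"] = ev_lastdiv),
      _["divisions"] = List::create(_["time"] = dv_time,
                                    _["branch_id"] = dv_id));
}
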