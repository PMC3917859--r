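// Coupled monodomain sheet + Purkinje cable stepper.
//
// Explicit operator-splitting update of the two-variable excitable model on a
// 2D sheet (5-point Laplacian, no-flux boundaries) and on a 1D cable network
// (graph Laplacian weighted by 1/len^2), with resistive PMJ current exchange
// between the two. Online threshold-crossing activation detection (-20 mV
// upward crossing, 50 ms blanking, -60 mV diastolic validity) matches the
// R-level detector.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct CellPar {
  double tin, tout, topen, tclose, ugate, facil;
};

static CellPar unpack(const NumericVector& p) {
  CellPar c;
  c.tin = p[0]; c.tout = p[1]; c.topen = p[2];
  c.tclose = p[3]; c.ugate = p[4]; c.facil = p[5];
  return c;
}

// [[Rcpp::export]]
List cpp_simulate(List model, List state, List run) {
  const int nx = as<int>(model["nx"]);
  const int ny = as<int>(model["ny"]);
  const double dx = as<double>(model["dx"]);
  const double Ds = as<double>(model["d_sheet"]);
  const double Dc = as<double>(model["d_cable"]);
  const IntegerVector edge_i = model["edge_i"];
  const IntegerVector edge_j = model["edge_j"];
  const NumericVector edge_w = model["edge_w"];
  const int ncab = as<int>(model["n_cable"]);
  const CellPar myo = unpack(model["myo"]);
  const CellPar pk  = unpack(model["pk"]);
  const double v_rest = as<double>(model["v_rest"]);
  const double v_span = as<double>(model["v_span"]);
  const IntegerVector pmj_term = model["pmj_term"];
  const IntegerVector pmj_myo  = model["pmj_myo"];
  const IntegerVector pmj_off  = model["pmj_off"];
  const NumericVector pmj_R    = model["pmj_r"];
  const NumericVector pmj_load = model["pmj_load"];
  const double conv = as<double>(model["current_conversion"]);
  const double cap_scale = as<double>(model["terminal_capacitance_scale"]);
  const int npmj = pmj_term.size();

  const int nsheet = nx * ny;
  std::vector<double> us = as<std::vector<double> >(state["u_s"]);
  std::vector<double> hs = as<std::vector<double> >(state["h_s"]);
  std::vector<double> uc = as<std::vector<double> >(state["u_c"]);
  std::vector<double> hc = as<std::vector<double> >(state["h_c"]);
  if ((int)us.size() != nsheet || (int)uc.size() != ncab)
    stop("state size mismatch");

  const double dt = as<double>(run["dt"]);
  const double t0 = as<double>(run["t0"]);
  const long n_steps = (long)as<double>(run["n_steps"]);
  const NumericMatrix stims = run["stims"];          // rows: t_on t_off amp domain
  const List stim_nodes = run["stim_nodes"];         // 0-based node ids per stim
  const int frame_every = as<int>(run["frame_every"]); // in steps; 0 = off
  const double frame_t_start = as<double>(run["frame_t_start"]);
  const int trace_every = as<int>(run["trace_every"]);
  const IntegerVector trace_cable = run["trace_cable"];
  const IntegerVector trace_sheet = run["trace_sheet"];
  const double act_thresh = as<double>(run["act_thresh_mv"]);
  const double act_start  = as<double>(run["act_start_mv"]);
  const double blank_ms   = as<double>(run["blank_ms"]);
  const bool early_stop   = as<bool>(run["early_stop"]);
  const bool record_sheet_acts = as<bool>(run["record_sheet_acts"]);
  const int cable_substeps = as<int>(run["cable_substeps"]);

  const double u_th = (act_thresh - v_rest) / v_span;  // -20 mV -> 0.565
  const double u_lo = (act_start - v_rest) / v_span;   // -60 mV -> 0.217
  const double u_hi_ab = (100.0 - v_rest) / v_span;    // |V| > 100 mV aborts
  const double u_lo_ab = (-100.0 - v_rest) / v_span;
  const double quiet_u = 0.005;

  // latest stimulus end, for the early-stop guard
  double last_stim_off = t0;
  for (int s = 0; s < stims.nrow(); ++s)
    if (stims(s, 1) > last_stim_off) last_stim_off = stims(s, 1);

  std::vector<double> us_new(nsheet), uc_new(ncab), lap_c(ncab);
  std::vector<char> below_s(nsheet), below_c(ncab);
  std::vector<double> last_s(nsheet, -1e9), last_c(ncab, -1e9);
  for (int i = 0; i < nsheet; ++i) below_s[i] = us[i] <= u_lo;
  for (int i = 0; i < ncab; ++i)   below_c[i] = uc[i] <= u_lo;

  std::vector<int> act_s_node, act_c_node;
  std::vector<double> act_s_time, act_c_time;
  act_s_node.reserve(1 << 16);
  act_c_node.reserve(1 << 12);

  int n_frames_max = frame_every > 0 ? (int)(n_steps / frame_every) + 2 : 0;
  NumericMatrix frames(frame_every > 0 ? nsheet : 1, std::max(n_frames_max, 1));
  std::vector<double> frame_times;
  int fi = 0;

  int n_tr_max = trace_every > 0 ? (int)(n_steps / trace_every) + 2 : 0;
  int ntrc = trace_cable.size(), ntrs = trace_sheet.size();
  NumericMatrix tr_c(std::max(ntrc, 1), std::max(n_tr_max, 1));
  NumericMatrix tr_s(std::max(ntrs, 1), std::max(n_tr_max, 1));
  std::vector<double> trace_times;
  int ti = 0;

  bool aborted = false, stopped = false;
  std::string abort_msg;
  double t_end = t0;
  const double dx2 = dx * dx;

  for (long step = 0; step < n_steps; ++step) {
    const double t = t0 + step * dt;
    const double t_new = t + dt;

    // ---- sheet: reaction + diffusion ----
    double umax = 0.0;
    for (int j = 0; j < ny; ++j) {
      const int jm = (j == 0) ? 0 : j - 1;
      const int jp = (j == ny - 1) ? ny - 1 : j + 1;
      for (int i = 0; i < nx; ++i) {
        const int p = i + nx * j;
        const int im = (i == 0) ? p : p - 1;
        const int ip = (i == nx - 1) ? p : p + 1;
        const double u = us[p], h = hs[p];
        const double lap = us[im] + us[ip] + us[i + nx * jm] + us[i + nx * jp] - 4.0 * u;
        const double du = h * u * u * (1.0 - u) / myo.tin - u / myo.tout
                          + Ds * lap / dx2;
        us_new[p] = u + dt * du;
        if (u < myo.ugate) {
          const double topen = myo.facil > 0.0
            ? myo.topen / (1.0 + myo.facil * (1.0 - h)) : myo.topen;
          hs[p] = h + dt * (1.0 - h) / topen;
        } else {
          hs[p] = h - dt * h / myo.tclose;
        }
        if (u > umax) umax = u;
      }
    }

    // ---- cable: reaction + graph diffusion (sub-stepped: branch nodes
    // tighten the explicit bound to 1/(D * max_i sum_e w_e)) ----
    std::copy(uc.begin(), uc.end(), uc_new.begin());
    const double dtc = dt / cable_substeps;
    for (int sub = 0; sub < cable_substeps; ++sub) {
      std::fill(lap_c.begin(), lap_c.end(), 0.0);
      for (int e = 0; e < edge_i.size(); ++e) {
        const int a = edge_i[e], b = edge_j[e];
        const double f = edge_w[e] * (uc_new[b] - uc_new[a]);
        lap_c[a] += f;
        lap_c[b] -= f;
      }
      for (int i = 0; i < ncab; ++i) {
        const double u = uc_new[i], h = hc[i];
        const double du = h * u * u * (1.0 - u) / pk.tin - u / pk.tout
                          + Dc * lap_c[i];
        uc_new[i] = u + dtc * du;
        if (u < pk.ugate) {
          const double topen = pk.facil > 0.0
            ? pk.topen / (1.0 + pk.facil * (1.0 - h)) : pk.topen;
          hc[i] = h + dtc * (1.0 - h) / topen;
        } else {
          hc[i] = h - dtc * h / pk.tclose;
        }
        if (u > umax) umax = u;
      }
    }

    // ---- PMJ exchange (from pre-step voltages) ----
    for (int q = 0; q < npmj; ++q) {
      const int tnode = pmj_term[q];
      const double vt = v_rest + v_span * uc[tnode];
      double isum = 0.0;
      for (int m = pmj_off[q]; m < pmj_off[q + 1]; ++m) {
        const int mn = pmj_myo[m];
        const double ij = (vt - (v_rest + v_span * us[mn])) / pmj_R[q]; // nA
        us_new[mn] += dt * conv * ij;
        isum += ij;
      }
      uc_new[tnode] -= dt * (conv / cap_scale) * pmj_load[q] * isum;
    }

    // ---- stimuli ----
    for (int s = 0; s < stims.nrow(); ++s) {
      if (t_new >= stims(s, 0) && t < stims(s, 1)) {
        const double amp = stims(s, 2);
        const int domain = (int)stims(s, 3);
        const IntegerVector idx = stim_nodes[s];
        // conductance-like drive toward the excited state (bounded)
        if (domain == 1) {
          for (int k = 0; k < idx.size(); ++k) {
            const int p = idx[k];
            us_new[p] += dt * amp * (1.0 - us_new[p]);
          }
        } else {
          for (int k = 0; k < idx.size(); ++k) {
            const int p = idx[k];
            uc_new[p] += dt * amp * (1.0 - uc_new[p]);
          }
        }
      }
    }

    // ---- activation detection + instability check ----
    for (int p = 0; p < nsheet; ++p) {
      const double un = us_new[p];
      if (un > u_hi_ab || un < u_lo_ab || !std::isfinite(un)) {
        aborted = true;
        abort_msg = "sheet voltage out of [-100, 100] mV: numerical instability";
        break;
      }
      if (us[p] < u_th && un >= u_th && below_s[p] && t_new - last_s[p] >= blank_ms) {
        if (record_sheet_acts) { act_s_node.push_back(p + 1); act_s_time.push_back(t_new); }
        below_s[p] = 0;
        last_s[p] = t_new;
      }
      if (un <= u_lo) below_s[p] = 1;
    }
    if (!aborted) for (int p = 0; p < ncab; ++p) {
      const double un = uc_new[p];
      if (un > u_hi_ab || un < u_lo_ab || !std::isfinite(un)) {
        aborted = true;
        abort_msg = "cable voltage out of [-100, 100] mV: numerical instability";
        break;
      }
      if (uc[p] < u_th && un >= u_th && below_c[p] && t_new - last_c[p] >= blank_ms) {
        act_c_node.push_back(p + 1);
        act_c_time.push_back(t_new);
        below_c[p] = 0;
        last_c[p] = t_new;
      }
      if (un <= u_lo) below_c[p] = 1;
    }

    us.swap(us_new);
    uc.swap(uc_new);
    t_end = t_new;
    if (aborted) break;

    // ---- recording ----
    if (frame_every > 0 && (step + 1) % frame_every == 0 && t_new >= frame_t_start) {
      for (int p = 0; p < nsheet; ++p) frames(p, fi) = v_rest + v_span * us[p];
      frame_times.push_back(t_new);
      ++fi;
    }
    if (trace_every > 0 && (step + 1) % trace_every == 0) {
      for (int k = 0; k < ntrc; ++k) tr_c(k, ti) = v_rest + v_span * uc[trace_cable[k]];
      for (int k = 0; k < ntrs; ++k) tr_s(k, ti) = v_rest + v_span * us[trace_sheet[k]];
      trace_times.push_back(t_new);
      ++ti;
    }

    if (early_stop && t_new > last_stim_off + 10.0 && umax < quiet_u) {
      stopped = true;
      break;
    }
    if (step % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(
    _["u_s"] = NumericVector(us.begin(), us.end()),
    _["h_s"] = NumericVector(hs.begin(), hs.end()),
    _["u_c"] = NumericVector(uc.begin(), uc.end()),
    _["h_c"] = NumericVector(hc.begin(), hc.end()),
    _["t_end"] = t_end,
    _["act_s_node"] = IntegerVector(act_s_node.begin(), act_s_node.end()),
    _["act_s_time"] = NumericVector(act_s_time.begin(), act_s_time.end()),
    _["act_c_node"] = IntegerVector(act_c_node.begin(), act_c_node.end()),
    _["act_c_time"] = NumericVector(act_c_time.begin(), act_c_time.end()),
    _["stopped_early"] = stopped,
    _["aborted"] = aborted,
    _["abort_msg"] = abort_msg);
  if (frame_every > 0) {
    out["frames"] = frames(_, Range(0, std::max(fi - 1, 0)));
    out["frame_times"] = NumericVector(frame_times.begin(), frame_times.end());
  }
  if (trace_every > 0) {
    out["trace_cable_v"] = tr_c(_, Range(0, std::max(ti - 1, 0)));
    out["trace_sheet_v"] = tr_s(_, Range(0, std::max(ti - 1, 0)));
    out["trace_times"] = NumericVector(trace_times.begin(), trace_times.end());
  }
  return out;
}
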