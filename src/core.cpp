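// Core numerical engine: polygon geometry, exploration helpers, and the
// fixed-step (Euler, dt = 0.2 ms) integrator for the adaptive LIF place-cell
// network with supralinear summation, continuous global inhibition, gated
// STDP/anti-STDP, and the spike-force agent.
//
// All randomness is drawn from R's RNG (norm_rand/unif_rand), so set.seed()
// on the R side makes every simulation reproducible.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Geometry: environments are lists of rings (outer boundary first, then
// holes), each ring a closed polygon given as a k x 2 vertex matrix.
// Even-odd (crossing-number) containment over all rings handles holes.
// ---------------------------------------------------------------------------

static bool point_in_rings(double x, double y, const List& rings) {
  bool inside = false;
  for (int r = 0; r < rings.size(); ++r) {
    NumericMatrix ring = rings[r];
    int k = ring.nrow();
    for (int a = 0, b = k - 1; a < k; b = a++) {
      double xa = ring(a, 0), ya = ring(a, 1);
      double xb = ring(b, 0), yb = ring(b, 1);
      if (((ya > y) != (yb > y)) &&
          (x < (xb - xa) * (y - ya) / (yb - ya) + xa))
        inside = !inside;
    }
  }
  return inside;
}

static inline double cross2(double ox, double oy, double ax, double ay,
                            double bx, double by) {
  return (ax - ox) * (by - oy) - (ay - oy) * (bx - ox);
}

// proper segment intersection test (shared endpoints / collinear grazing do
// not count as crossings, which is what wall tests need)
static bool segments_cross(double p1x, double p1y, double p2x, double p2y,
                           double q1x, double q1y, double q2x, double q2y) {
  double d1 = cross2(q1x, q1y, q2x, q2y, p1x, p1y);
  double d2 = cross2(q1x, q1y, q2x, q2y, p2x, p2y);
  double d3 = cross2(p1x, p1y, p2x, p2y, q1x, q1y);
  double d4 = cross2(p1x, p1y, p2x, p2y, q2x, q2y);
  return ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
         ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0));
}

// first wall edge crossed by segment p->pn; returns edge endpoints via out
// params, or false if none
static bool first_wall_hit(double px, double py, double pnx, double pny,
                           const List& rings,
                           double& e1x, double& e1y, double& e2x, double& e2y) {
  for (int r = 0; r < rings.size(); ++r) {
    NumericMatrix ring = rings[r];
    int k = ring.nrow();
    for (int a = 0, b = k - 1; a < k; b = a++) {
      double xa = ring(a, 0), ya = ring(a, 1);
      double xb = ring(b, 0), yb = ring(b, 1);
      if (segments_cross(px, py, pnx, pny, xa, ya, xb, yb)) {
        e1x = xa; e1y = ya; e2x = xb; e2y = yb;
        return true;
      }
    }
  }
  return false;
}

// [[Rcpp::export]]
LogicalVector pip_cpp(NumericMatrix pts, List rings) {
  int n = pts.nrow();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = point_in_rings(pts(i, 0), pts(i, 1), rings);
  return out;
}

// segs: n x 4 (x1 y1 x2 y2); TRUE if the segment crosses any wall edge
// [[Rcpp::export]]
LogicalVector seg_cross_cpp(NumericMatrix segs, List rings) {
  int n = segs.nrow();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    double e1x, e1y, e2x, e2y;
    out[i] = first_wall_hit(segs(i, 0), segs(i, 1), segs(i, 2), segs(i, 3),
                            rings, e1x, e1y, e2x, e2y);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Exploration trajectory: noisy straight line at constant speed whose heading
// decorrelates over `persistence` metres of arc; specular bounce at walls.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix explore_traj_cpp(List rings, double x0, double y0, double theta0,
                               double speed, double persistence,
                               double dt, double t_total) {
  int nstep = (int)std::floor(t_total / dt);
  NumericMatrix out(nstep + 1, 3);
  double x = x0, y = y0, th = theta0;
  // heading diffusion: <cos(dth over arc s)> = exp(-s/persistence)
  double sd_step = std::sqrt(2.0 * speed * dt / persistence);
  out(0, 0) = 0.0; out(0, 1) = x; out(0, 2) = y;
  for (int s = 1; s <= nstep; ++s) {
    th += sd_step * norm_rand();
    double vx = speed * std::cos(th), vy = speed * std::sin(th);
    double xn = x + vx * dt, yn = y + vy * dt;
    double e1x, e1y, e2x, e2y;
    int guard = 0;
    while (first_wall_hit(x, y, xn, yn, rings, e1x, e1y, e2x, e2y) &&
           guard++ < 4) {
      // specular reflection about the wall normal
      double tx = e2x - e1x, ty = e2y - e1y;
      double tn = std::sqrt(tx * tx + ty * ty);
      tx /= tn; ty /= tn;
      double dot = vx * tx + vy * ty;
      double rx = 2.0 * dot * tx - vx, ry = 2.0 * dot * ty - vy;
      th = std::atan2(ry, rx);
      vx = speed * std::cos(th); vy = speed * std::sin(th);
      xn = x + vx * dt; yn = y + vy * dt;
    }
    if (!point_in_rings(xn, yn, rings)) { xn = x; yn = y; th += M_PI; }
    x = xn; y = yn;
    out(s, 0) = s * dt; out(s, 1) = x; out(s, 2) = y;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Exploration spiking: inhomogeneous Poisson emitter, rate proportional to
// the Gaussian sensory drive of each cell at the current trajectory position.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List explore_spikes_cpp(NumericMatrix traj, NumericVector cx, NumericVector cy,
                        double sigma, double rate_max) {
  int nt = traj.nrow(), n = cx.size();
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  double cutoff2 = 9.0 * sigma * sigma;   // 3 sigma: rate < 1.2% of max
  std::vector<double> st; std::vector<int> sid;
  for (int s = 1; s < nt; ++s) {
    double t = traj(s, 0), x = traj(s, 1), y = traj(s, 2);
    double dt = t - traj(s - 1, 0);
    for (int i = 0; i < n; ++i) {
      double dx = cx[i] - x, dy = cy[i] - y;
      double d2 = dx * dx + dy * dy;
      if (d2 > cutoff2) continue;
      double p = rate_max * std::exp(-d2 * inv2s2) * dt;
      if (unif_rand() < p) { st.push_back(t); sid.push_back(i + 1); }
    }
  }
  return List::create(_["t"] = wrap(st), _["id"] = wrap(sid));
}

// Pairwise co-activation potential with exponential |dt| weighting; causal
// (pre before post) pairs weighted 1, anti-causal pairs weighted rho, so the
// net effect is potentiating while retaining direction statistics.
// Returns P with P(i,j) = potential of synapse i (pre) -> j (post), 0-based.
// [[Rcpp::export]]
NumericMatrix accumulate_pairs_cpp(NumericVector st, IntegerVector sid, int n,
                                   double tau, double window, double rho) {
  int ns = st.size();
  NumericMatrix P(n, n);
  for (int a = 0; a < ns; ++a) {
    double ta = st[a]; int i = sid[a];
    for (int b = a + 1; b < ns; ++b) {
      double dtab = st[b] - ta;
      if (dtab > window) break;
      int j = sid[b];
      if (j == i) continue;
      double w = std::exp(-dtab / tau);
      if (dtab == 0.0) {           // simultaneous: causal branch both ways
        P(i, j) += w; P(j, i) += w;
      } else {
        P(i, j) += w;              // a (pre) before b (post): causal
        P(j, i) += rho * w;        // reverse synapse: anti-causal
      }
    }
  }
  return P;
}

// ---------------------------------------------------------------------------
// Main network integrator.
//
// Weight storage: W is a dgCMatrix with rows = postsynaptic, columns =
// presynaptic (entry w[post, pre]), passed as CSC slots Wi/Wp/Wx. Tmap maps
// entries of t(W) (CSC by postsynaptic column, slots Ti/Tp) onto positions in
// Wx so incoming synapses of a spiking cell can be updated in place.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List run_core_cpp(List net, List neuron, List syn, List inhp, List stdp,
                  List drive, List agentp, List ctrl, List rings, List state) {
  // --- network ---
  const int n = as<int>(net["n"]);
  IntegerVector Wi = net["Wi"], Wp = net["Wp"];
  NumericVector Wx = clone(as<NumericVector>(net["Wx"]));
  IntegerVector Ti = net["Ti"], Tp = net["Tp"], Tmap = net["Tmap"];
  NumericVector cx = net["cx"], cy = net["cy"];

  // --- neuron parameters ---
  const double dt       = as<double>(neuron["dt"]);
  const double tau_m    = as<double>(neuron["tau_m"]);
  const double R_m      = as<double>(neuron["R_m"]);
  const double u_r      = as<double>(neuron["u_r"]);
  const double u_th     = as<double>(neuron["threshold"]);
  const double t_ref    = as<double>(neuron["refractory"]);
  const double tau_ca   = as<double>(neuron["tau_ca"]);
  const double dI_ca    = as<double>(neuron["dI_ca"]);
  const double tau_syn  = as<double>(neuron["tau_syn"]);
  const double i_jump   = as<double>(neuron["i_jump"]);
  const double eps_act  = as<double>(neuron["eps_active"]);
  const double noise_sd = as<double>(neuron["noise_sd"]);
  const double syn_delay = neuron.containsElementNamed("syn_delay")
    ? as<double>(neuron["syn_delay"]) : 0.0;

  // --- summation ---
  const bool   supra   = as<bool>(syn["supralinear"]);
  const double a_syn   = as<double>(syn["a_syn"]);
  const double b_syn   = as<double>(syn["b_syn"]);
  const double lin_g   = as<double>(syn["lin_gain"]);

  // --- inhibition ---
  const bool   inh_gate = as<bool>(inhp["gate"]);
  const double inh_tau  = as<double>(inhp["tau_e"]);
  const double inh_a    = as<double>(inhp["a_e"]);
  const double inh_I0   = as<double>(inhp["I_e0"]);
  const double inh_gain = as<double>(inhp["gain"]);

  // --- plasticity ---
  const int    d_pol  = as<int>(stdp["d"]);
  const double eta    = as<double>(stdp["eta"]);
  const double A_plus = as<double>(stdp["A_ji"]);
  const double A_minus= as<double>(stdp["A_ij"]);
  const double tau_w  = as<double>(stdp["tau_w"]);
  const double w_min  = as<double>(stdp["w_min"]);
  const double w_max  = as<double>(stdp["w_max"]);
  const bool   plastic = (d_pol != 0) && (eta != 0.0);

  // --- drive ---
  const int    dmode   = as<int>(drive["mode"]);   // 0 none, 1 agent, 2 path
  const double s_amp   = as<double>(drive["sens_amp"]);
  const double s_sig   = as<double>(drive["sens_sigma"]);
  NumericVector pulse_t0  = drive["pulse_t0"];
  NumericVector pulse_dur = drive["pulse_dur"];
  NumericVector pulse_amp = drive["pulse_amp"];
  IntegerVector pulse_lab = drive["pulse_label"];
  List pulse_members      = drive["pulse_members"];   // 0-based index vectors
  IntegerVector f_step = drive["f_step"];             // sorted ascending
  IntegerVector f_id   = drive["f_id"];               // 0-based
  IntegerVector f_lab  = drive["f_label"];
  NumericMatrix path   = drive["path"];               // mode 2: (x,y) rows
  const double path_dt = as<double>(drive["path_dt"]);

  // --- agent ---
  double ax = 0, ay = 0, avx = 0, avy = 0, mass = 1, damping = 1, a_F = 0;
  double tgx = 0, tgy = 0, capture = 0;
  int rec_every = 1;
  if (dmode == 1) {
    NumericVector a0 = agentp["x0"], v0 = agentp["v0"], tg = agentp["target"];
    ax = a0[0]; ay = a0[1]; avx = v0[0]; avy = v0[1];
    mass    = as<double>(agentp["mass"]);
    damping = as<double>(agentp["damping"]);
    a_F     = as<double>(agentp["a_F"]);
    tgx = tg[0]; tgy = tg[1];
    capture  = as<double>(agentp["capture_radius"]);
    rec_every = as<int>(agentp["record_every"]);
  }

  // --- control ---
  const double t_max   = as<double>(ctrl["t_max"]);
  const int    term    = as<int>(ctrl["term_mode"]); // 0 fixed, 1 quiesc, 2 stop-pos
  const double quiet_w = as<double>(ctrl["quiet_window"]);
  NumericVector stop_pos = ctrl["stop_pos"];
  const double stop_r  = as<double>(ctrl["stop_radius"]);
  const double label_w = as<double>(ctrl["label_window"]);
  const double runaway = as<double>(ctrl["runaway_limit"]);
  const bool   rec_spk = as<bool>(ctrl["record_spikes"]);

  // --- state ---
  NumericVector u   = clone(as<NumericVector>(state["u"]));
  NumericVector ica = clone(as<NumericVector>(state["ica"]));
  NumericVector str = clone(as<NumericVector>(state["syn_trace"]));
  double ie = as<double>(state["ie"]);

  const double e_syn = std::exp(-dt / tau_syn);
  const double e_ca  = std::exp(-dt / tau_ca);
  const double e_w   = std::exp(-dt / tau_w);
  const double e_inh = std::exp(-dt / inh_tau);
  const double inv2s2 = 1.0 / (2.0 * s_sig * s_sig);

  std::vector<double> refr(n, 0.0), trw(n, 0.0), last_sp(n, -1e18);
  std::vector<double> first_sp(n, NA_REAL);
  std::vector<int> nsp(n, 0), lab(n, -1);
  std::vector<double> acc(n), isens(n, 0.0);
  std::vector<int> cnt(n), spiked_now; spiked_now.reserve(256);
  std::vector<char> same_step(n, 0), forced_now(n, 0);
  std::vector<int> forced_lab_now(n, -1);

  std::vector<double> sp_t; std::vector<int> sp_id, sp_lab;
  std::vector<double> tr_t, tr_x, tr_y; std::vector<int> tr_ns;

  const int nstep = (int)std::llround(t_max / dt);
  // synaptic transmission delay: a spike raises the presynaptic trace
  // delay_steps after threshold crossing (minimum one step)
  const int delay_steps = std::max(1, (int)std::llround(syn_delay / dt));
  std::vector< std::vector<int> > pending(delay_steps + 1);
  int fptr = 0, outcome = 0;
  long total_sp = 0;
  double last_global = -1e18;
  bool any_spike = false;
  double t_end = t_max;
  const int npulse = pulse_t0.size();

  for (int step = 0; step < nstep; ++step) {
    double t = step * dt;

    // deliver delayed synaptic jumps scheduled for this step
    {
      std::vector<int>& due = pending[step % (delay_steps + 1)];
      for (size_t z = 0; z < due.size(); ++z) str[due[z]] += i_jump;
      due.clear();
    }

    // decay dynamic variables (exact per-step exponential)
    ie *= e_inh;
    for (int i = 0; i < n; ++i) {
      str[i] *= e_syn; ica[i] *= e_ca; trw[i] *= e_w;
    }

    double i_inh = (inh_gate && ie > inh_I0) ? inh_gain * (ie - inh_I0) : 0.0;

    // synaptic input via active presynaptic traces
    std::memset(acc.data(), 0, n * sizeof(double));
    std::memset(cnt.data(), 0, n * sizeof(int));
    for (int j = 0; j < n; ++j) {
      double sj = str[j];
      if (sj <= eps_act) continue;
      for (int k = Wp[j]; k < Wp[j + 1]; ++k) {
        int post = Wi[k];
        acc[post] += Wx[k] * sj;
        cnt[post] += 1;
      }
    }

    // sensory drive
    if (dmode == 1 || dmode == 2) {
      double px = ax, py = ay;
      if (dmode == 2) {
        int idx = (int)std::floor(t / path_dt);
        if (idx >= path.nrow()) idx = path.nrow() - 1;
        px = path(idx, 0); py = path(idx, 1);
      }
      for (int i = 0; i < n; ++i) {
        double dx = cx[i] - px, dy = cy[i] - py;
        double d2 = dx * dx + dy * dy;
        isens[i] = (d2 < 9.0 * s_sig * s_sig) ? s_amp * std::exp(-d2 * inv2s2)
                                              : 0.0;
      }
    }
    // exciter pulses (target seeding)
    for (int p = 0; p < npulse; ++p) {
      if (t >= pulse_t0[p] && t < pulse_t0[p] + pulse_dur[p]) {
        IntegerVector mem = pulse_members[p];
        for (int q = 0; q < mem.size(); ++q) isens[mem[q]] += pulse_amp[p];
      }
    }

    // forced spikes scheduled for this step
    while (fptr < f_step.size() && f_step[fptr] == step) {
      int i = f_id[fptr];
      if (refr[i] <= 0.0) { forced_now[i] = 1; forced_lab_now[i] = f_lab[fptr]; }
      ++fptr;
    }

    // membrane update + threshold detection
    spiked_now.clear();
    for (int i = 0; i < n; ++i) {
      if (refr[i] > 0.0) {
        refr[i] -= dt;
        u[i] = u_r;
        if (forced_now[i]) forced_now[i] = 0;
        continue;
      }
      double isyn_i = supra
        ? a_syn * std::tanh(b_syn * (double)cnt[i]) * acc[i]
        : lin_g * acc[i];
      double I = isens[i] + isyn_i - i_inh - ica[i];
      if (noise_sd > 0.0) I += noise_sd * norm_rand();
      u[i] += dt / tau_m * (-(u[i] - u_r) + R_m * I);
      if (u[i] >= u_th || forced_now[i]) spiked_now.push_back(i);
      if (dmode == 0 || dmode == 2) isens[i] = 0.0;  // pulses are re-added next step
    }
    if ((dmode == 1) || npulse > 0) {
      // reset isens fully each step in agent/path modes handled above;
      // pulse contributions were added into isens, clear for next step
      std::fill(isens.begin(), isens.end(), 0.0);
    }

    int ns_now = (int)spiked_now.size();
    if (ns_now > 0) {
      any_spike = true; last_global = t; total_sp += ns_now;

      for (int q : spiked_now) same_step[q] = 1;

      for (int q : spiked_now) {
        u[q] = u_r; refr[q] = t_ref; ica[q] += dI_ca; ie += inh_a;
        nsp[q] += 1;
        if (ISNAN(first_sp[q])) first_sp[q] = t;

        // --- label attribution ---
        int lbl = lab[q];
        if (lbl < 0) {
          if (forced_now[q]) {
            lbl = forced_lab_now[q];
          } else {
            // pulse membership within the pulse window (plus short grace)
            for (int p = 0; p < npulse && lbl < 0; ++p) {
              if (t >= pulse_t0[p] && t < pulse_t0[p] + pulse_dur[p] + 0.004) {
                IntegerVector mem = pulse_members[p];
                for (int m = 0; m < mem.size(); ++m)
                  if (mem[m] == q) { lbl = pulse_lab[p]; break; }
              }
            }
            if (lbl < 0) {
              // majority label among recently spiking presynaptic partners
              std::vector<int> labs; std::vector<int> votes;
              for (int k = Tp[q]; k < Tp[q + 1]; ++k) {
                int pre = Ti[k];
                if (lab[pre] >= 0 && t - last_sp[pre] <= label_w) {
                  int found = -1;
                  for (size_t z = 0; z < labs.size(); ++z)
                    if (labs[z] == lab[pre]) { found = (int)z; break; }
                  if (found < 0) { labs.push_back(lab[pre]); votes.push_back(1); }
                  else votes[found] += 1;
                }
              }
              int best = -1, bestv = 0;
              for (size_t z = 0; z < labs.size(); ++z)
                if (votes[z] > bestv || (votes[z] == bestv && labs[z] < best)) {
                  best = labs[z]; bestv = votes[z];
                }
              lbl = best;
            }
          }
          lab[q] = lbl;
        }
        forced_now[q] = 0;

        if (rec_spk) { sp_t.push_back(t); sp_id.push_back(q + 1); sp_lab.push_back(lab[q]); }
      }

      // --- STDP (trace-based online rule, exact for exponential kernels) ---
      if (plastic) {
        for (int q : spiked_now) {
          // q as postsynaptic: causal branch (pre spike at or before post)
          for (int k = Tp[q]; k < Tp[q + 1]; ++k) {
            int pre = Ti[k];
            double pretr = trw[pre] + (same_step[pre] ? 1.0 : 0.0);
            if (pretr > 0.0) {
              int widx = Tmap[k];
              double w = Wx[widx] + d_pol * eta * A_plus * pretr;
              Wx[widx] = w < w_min ? w_min : (w > w_max ? w_max : w);
            }
          }
          // q as presynaptic: anti-causal branch (post spiked strictly before)
          for (int k = Wp[q]; k < Wp[q + 1]; ++k) {
            int post = Wi[k];
            double postr = trw[post];       // excludes same-step posts (s=0 is causal)
            if (postr > 0.0) {
              double w = Wx[k] - d_pol * eta * A_minus * postr;
              Wx[k] = w < w_min ? w_min : (w > w_max ? w_max : w);
            }
          }
        }
      }

      // traces and bookkeeping updated after plasticity
      for (int q : spiked_now) {
        pending[(step + delay_steps) % (delay_steps + 1)].push_back(q);
        trw[q] += 1.0; last_sp[q] = t; same_step[q] = 0;
      }

      // stop-position termination (planning halts when the front reaches the
      // agent's current location)
      if (term == 2) {
        for (int q : spiked_now) {
          double dx = cx[q] - stop_pos[0], dy = cy[q] - stop_pos[1];
          if (dx * dx + dy * dy <= stop_r * stop_r) { outcome = 2; t_end = t; }
        }
      }
    }

    // --- agent dynamics (navigation) ---
    if (dmode == 1) {
      for (int q : spiked_now) {
        avx += (a_F / mass) * (cx[q] - ax);
        avy += (a_F / mass) * (cy[q] - ay);
      }
      double decay = std::exp(-damping / mass * dt);
      avx *= decay; avy *= decay;
      double axn = ax + avx * dt, ayn = ay + avy * dt;
      double e1x, e1y, e2x, e2y;
      if (first_wall_hit(ax, ay, axn, ayn, rings, e1x, e1y, e2x, e2y)) {
        // slide: keep tangential velocity component only
        double tx = e2x - e1x, ty = e2y - e1y;
        double tn = std::sqrt(tx * tx + ty * ty); tx /= tn; ty /= tn;
        double dot = avx * tx + avy * ty;
        avx = dot * tx; avy = dot * ty;
        axn = ax + avx * dt; ayn = ay + avy * dt;
        if (first_wall_hit(ax, ay, axn, ayn, rings, e1x, e1y, e2x, e2y) ||
            !point_in_rings(axn, ayn, rings)) {
          avx = 0; avy = 0; axn = ax; ayn = ay;
        }
      } else if (!point_in_rings(axn, ayn, rings)) {
        avx = 0; avy = 0; axn = ax; ayn = ay;
      }
      ax = axn; ay = ayn;
      if (step % rec_every == 0) {
        tr_t.push_back(t); tr_x.push_back(ax); tr_y.push_back(ay);
        tr_ns.push_back(ns_now);
      }
      double ddx = ax - tgx, ddy = ay - tgy;
      if (std::sqrt(ddx * ddx + ddy * ddy) <= capture) {
        outcome = 3; t_end = t + dt; break;
      }
    }

    // --- termination ---
    if (outcome == 2) break;
    if (total_sp > runaway) { outcome = 5; t_end = t + dt; break; }
    if (term == 1 && any_spike && (t - last_global) > quiet_w &&
        fptr >= f_step.size() && (npulse == 0 || t > max(pulse_t0) + quiet_w)) {
      outcome = 1; t_end = t + dt; break;
    }
    if (dmode == 1 && any_spike && (t - last_global) > quiet_w) {
      outcome = 4; t_end = t + dt; break;
    }
  }

  NumericMatrix traj(tr_t.size(), 4);
  for (size_t z = 0; z < tr_t.size(); ++z) {
    traj(z, 0) = tr_t[z]; traj(z, 1) = tr_x[z]; traj(z, 2) = tr_y[z];
    traj(z, 3) = tr_ns[z];
  }

  return List::create(
    _["spike_t"] = wrap(sp_t), _["spike_id"] = wrap(sp_id),
    _["spike_label"] = wrap(sp_lab),
    _["first_spike"] = wrap(first_sp), _["n_spikes"] = wrap(nsp),
    _["label"] = wrap(lab), _["Wx"] = Wx,
    _["u"] = u, _["ica"] = ica, _["syn_trace"] = str, _["ie"] = ie,
    _["agent_traj"] = traj,
    _["agent_pos"] = NumericVector::create(ax, ay),
    _["agent_vel"] = NumericVector::create(avx, avy),
    _["outcome"] = outcome, _["t_end"] = t_end,
    _["total_spikes"] = (double)total_sp);
}
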