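// Fast inner loop for protocol execution. Mirrors the R-level primitives
// (channel_response, alb_step, mosa_update, attractor_step, grsc_step,
// drsc_step, hebb_cap) step for step, including the order of RNG draws,
// so a run is reproducible across the R and compiled paths.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static const double DEG = M_PI / 180.0;

// positive remainder of x / 360 without fmod
static inline double mod360(double x) {
  return x - 360.0 * std::floor(x / 360.0);
}

// circular linear interpolation of a 1-degree shape table
static inline double samp_shape(const arma::vec& s, double ang) {
  double pos = mod360(ang + 180.0);
  int i0 = (int)std::floor(pos);
  double w = pos - i0;
  i0 %= 360;
  int i1 = (i0 + 1) % 360;
  return s(i0) * (1.0 - w) + s(i1) * w;
}

static inline double wrap180(double x) {
  return mod360(x + 180.0) - 180.0;
}

// thresholded tanh transfer
static inline void transfer(const arma::vec& a, arma::vec& f,
                            double alpha, double beta) {
  const arma::uword n = a.n_elem;
  for (arma::uword i = 0; i < n; ++i) {
    f(i) = (a(i) >= alpha) ? std::tanh(beta * (a(i) - alpha)) : 0.0;
  }
}

// [[Rcpp::export(name = ".cpp_run_phase")]]
List cpp_run_phase(List state, List scene, List pars,
                   arma::vec hd_true, arma::vec omega,
                   double t0, double dt,
                   bool learn, bool feedback, bool full_variant,
                   double jitter_frac, double noise_amp,
                   int log_every, LogicalVector keep_logs) {
  RNGScope rng;

  // --- unpack state -------------------------------------------------------
  arma::vec a_alb = state["a_alb"], f_alb = state["f_alb"];
  arma::vec a_hd = state["a_hd"], f_hd = state["f_hd"];
  arma::vec a_g = state["a_g"], f_g = state["f_g"];
  arma::vec a_d = state["a_d"], f_d = state["f_d"];
  arma::mat W_g2d = state["W_g2d"], W_a2d = state["W_a2d"];
  arma::mat Wsym = state["Wsym"], Wasym = state["Wasym"];
  List W_alb = state["W_alb"];     // per-channel visual->aLB
  List W_v2d = state["W_v2d"];     // per-channel visual->dRSC (direct)
  arma::vec eta_mask = state["eta_mask"];
  arma::vec theta = state["theta"];

  const int n = theta.n_elem;
  const int n_alb = a_alb.n_elem;
  const int T = hd_true.n_elem;

  // --- scenery ------------------------------------------------------------
  // per cue: shape table (360), channel index, centers, dynamics
  List cues = scene["cues"];
  const int n_cues = cues.size();
  IntegerVector cue_chan(n_cues);
  std::vector<arma::vec> cue_shape(n_cues);
  std::vector<arma::vec> cue_centers(n_cues);
  IntegerVector cue_dyn(n_cues); // 0 static 1 rotate 2 teleport 3 window
  NumericVector cue_speed(n_cues), cue_period(n_cues);
  NumericVector cue_ton(n_cues), cue_toff(n_cues);
  for (int c = 0; c < n_cues; ++c) {
    List cu = cues[c];
    cue_chan[c] = as<int>(cu["channel"]);
    cue_shape[c] = as<arma::vec>(cu["shape"]);
    cue_centers[c] = as<arma::vec>(cu["centers"]);
    cue_dyn[c] = as<int>(cu["dyn"]);
    cue_speed[c] = as<double>(cu["speed"]);
    cue_period[c] = as<double>(cu["period"]);
    cue_ton[c] = as<double>(cu["t_on"]);
    cue_toff[c] = as<double>(cu["t_off"]);
  }
  const int n_chan = as<int>(scene["n_channels"]);
  arma::vec bg = as<arma::vec>(scene["bg"]); // background-noise profile (n)
  double target_mean = as<double>(scene["target_mean"]);

  // --- parameters ---------------------------------------------------------
  List pa = pars["alb"], pat = pars["attractor"], pg = pars["grsc"],
       pd = pars["drsc"], pdir = pars["direct"];
  const double alb_tau = pa["tau"], alb_alpha = pa["alpha"],
               alb_beta = pa["beta"], g_alb = pa["g_alb"],
               alb_eta = pa["eta"], alb_zeta = pa["zeta"],
               noise_sd = pa["noise_sd"],
               kick_size = pa["kick_size"], kick_len = pa["kick_len"];
  IntegerVector kick_order = state.containsElementNamed("kick_order")
    ? as<IntegerVector>(state["kick_order"]) : IntegerVector(0);
  int kick_pos = state.containsElementNamed("kick_pos")
    ? as<int>(state["kick_pos"]) : 0;
  int kick_ttl = state.containsElementNamed("kick_ttl")
    ? as<int>(state["kick_ttl"]) : 0;
  double g_vis = pa["g_vis"];
  const double n_ref = pa.containsElementNamed("n_ref")
    ? as<double>(pa["n_ref"]) : (double)n;
  g_vis *= n_ref / n;
  const double at_tau = pat["tau"], at_alpha = pat["alpha"],
               at_beta = pat["beta"], pi_gain = pat["pi_gain"],
               vel_gain = pat["vel_gain"], g_fb = pat["g_fb"],
               g_fb_inh = pat["g_fb_inh"];
  const double g_tau = pg["tau"], g_alpha = pg["alpha"], g_beta = pg["beta"],
               g_in = pg["g_in"], g_inh = pg["g_inh"];
  const double d_tau = pd["tau"], d_alpha = pd["alpha"], d_beta = pd["beta"],
               g_g2d = pd["g_g2d"], g_a2d = pd["g_a2d"], d_inh = pd["g_inh"],
               eta_g2d = pd["eta_g2d"], eta_a2d = pd["eta_a2d"],
               wmax_g2d = pd["wmax_g2d"], wmax_a2d = pd["wmax_a2d"];
  arma::vec g_v2d_raw = as<arma::vec>(pdir["g_v2d"]);
  arma::vec g_v2d(n_chan);
  for (int j = 0; j < n_chan; ++j)
    g_v2d(j) = g_v2d_raw(j % g_v2d_raw.n_elem);
  const double dir_eta = pdir["eta"], dir_wmax = pdir["wmax"];

  // --- logs ---------------------------------------------------------------
  const bool keep_alb = keep_logs[0], keep_hd = keep_logs[1],
             keep_g = keep_logs[2], keep_d = keep_logs[3];
  arma::mat log_alb, log_hd, log_g, log_d;
  if (keep_alb) log_alb.set_size(T, n_alb);
  if (keep_hd) log_hd.set_size(T, n);
  if (keep_g) log_g.set_size(T, n);
  if (keep_d) log_d.set_size(T, n);
  std::vector<double> dec_t, dec_true, dec_hd;

  arma::mat vis(n, n_chan);
  arma::vec drive(n_alb), dvec(n), expected(n);

  // pull the per-channel weight matrices out of the R lists once
  std::vector<arma::mat> Wv_alb(W_alb.size()), Wv_v2d(W_v2d.size());
  for (int j = 0; j < W_alb.size(); ++j) Wv_alb[j] = as<arma::mat>(W_alb[j]);
  for (int j = 0; j < W_v2d.size(); ++j) Wv_v2d[j] = as<arma::mat>(W_v2d[j]);

  for (int k = 0; k < T; ++k) {
    const double t_now = t0 + k * dt;
    const double hd = hd_true(k);

    // advance cue dynamics (RNG order: teleports first, as in advance_cues)
    for (int c = 0; c < n_cues; ++c) {
      if (cue_dyn[c] == 1) {
        for (arma::uword j = 0; j < cue_centers[c].n_elem; ++j)
          cue_centers[c](j) = wrap180(cue_centers[c](j) + cue_speed[c] * dt);
      } else if (cue_dyn[c] == 2) {
        if (std::floor((t_now + dt) / cue_period[c]) >
            std::floor(t_now / cue_period[c])) {
          for (arma::uword j = 0; j < cue_centers[c].n_elem; ++j)
            cue_centers[c](j) = R::runif(-180.0, 180.0);
        }
      }
    }

    // visual channels
    vis.zeros();
    for (int c = 0; c < n_cues; ++c) {
      if (cue_dyn[c] == 3 && !(t_now >= cue_ton[c] && t_now < cue_toff[c]))
        continue;
      const int ch = cue_chan[c];
      for (arma::uword cc = 0; cc < cue_centers[c].n_elem; ++cc) {
        const double off = cue_centers[c](cc) - hd;
        for (int i = 0; i < n; ++i)
          vis(i, ch) += samp_shape(cue_shape[c], theta(i) - off);
      }
    }
    std::vector<bool> active(n_chan);
    for (int j = 0; j < n_chan; ++j)
      active[j] = arma::accu(vis.col(j)) > 0;
    if (noise_amp > 0) vis.each_col() += bg;
    if (jitter_frac > 0) {
      for (int j = 0; j < n_chan; ++j) {
        if (!active[j]) continue;
        double s = arma::accu(vis.col(j));
        arma::vec u(n);
        for (int i = 0; i < n; ++i) u(i) = R::runif(0.0, 1.0);
        vis.col(j) += u * (jitter_frac * s / arma::accu(u));
      }
    }
    int n_act = 0;
    for (int j = 0; j < n_chan; ++j) if (active[j]) ++n_act;
    if (n_act > 0) {
      const double per_mean = target_mean * 3.0 / n_act;
      for (int j = 0; j < n_chan; ++j) {
        if (active[j]) {
          double m = arma::mean(vis.col(j));
          if (m > 0) vis.col(j) *= per_mean / m;
        }
      }
    }
    vis.clamp(0.0, 1.0);

    // aLB layer (full variant) or direct drive
    arma::vec extra;
    if (full_variant) {
      const double fsum = arma::accu(f_alb);
      drive = g_alb * (fsum - f_alb);
      for (int j = 0; j < n_chan; ++j)
        drive += g_vis * (Wv_alb[j] * vis.col(j));
      a_alb += (dt / alb_tau) * (-a_alb + drive);
      if (learn && noise_sd > 0) {
        const double sc = noise_sd * std::sqrt(dt);
        for (int i = 0; i < n_alb; ++i) a_alb(i) += sc * R::norm_rand();
      }
      if (learn && kick_size > 0 && kick_order.size() > 0) {
        if (kick_ttl <= 0) {
          kick_pos = (kick_pos % kick_order.size()) + 1;
          kick_ttl = (int)std::round(kick_len / dt);
        }
        a_alb(kick_order[kick_pos - 1] - 1) += kick_size;
        --kick_ttl;
      }
      transfer(a_alb, f_alb, alb_alpha, alb_beta);
    } else {
      extra.zeros(n);
      for (int j = 0; j < n_chan; ++j)
        extra += g_v2d(j) * (Wv_v2d[j] * vis.col(j));
    }

    // mOSA update on the active rows only (the update carries the f factor)
    if (full_variant && learn) {
      arma::uvec act = arma::find(f_alb > 0);
      if (act.n_elem > 0) {
        arma::vec fa = f_alb(act);
        for (int j = 0; j < n_chan; ++j) {
          arma::mat Wa = Wv_alb[j].rows(act);
          arma::vec exp_v = Wa.t() * fa;
          Wa += alb_eta * (fa * (vis.col(j) - alb_zeta * exp_v).t());
          Wa.transform([](double x) { return x < 0 ? 0.0 : x; });
          Wv_alb[j].rows(act) = Wa;
        }
      }
    }

    // attractor (feedback from previous-step dRSC rates)
    const double om = omega(k) * DEG * pi_gain * vel_gain;
    dvec = Wsym * f_hd + om * (Wasym * f_hd);
    if (feedback) dvec += g_fb * f_d - g_fb_inh * arma::mean(f_d);
    a_hd += (dt / at_tau) * (-a_hd + dvec);
    transfer(a_hd, f_hd, at_alpha, at_beta);

    // gRSC
    const double mg = arma::mean(f_g);
    a_g += (dt / g_tau) * (-a_g + g_in * f_hd - g_inh * mg);
    transfer(a_g, f_g, g_alpha, g_beta);

    // dRSC
    const double md = arma::mean(f_d);
    dvec = g_g2d * (W_g2d * f_g) + g_a2d * (W_a2d * f_alb) - d_inh * md;
    if (!full_variant) dvec += extra;
    a_d += (dt / d_tau) * (-a_d + dvec);
    transfer(a_d, f_d, d_alpha, d_beta);

    // Hebbian plasticity with row norm caps
    if (learn) {
      arma::vec ep = eta_g2d * (eta_mask % f_d);
      arma::uvec act = arma::find(ep > 0);
      if (act.n_elem > 0) {
        arma::mat Wa = W_g2d.rows(act) + ep(act) * f_g.t();
        arma::vec nrm = arma::sqrt(arma::sum(arma::square(Wa), 1));
        for (arma::uword r = 0; r < act.n_elem; ++r)
          if (nrm(r) > wmax_g2d) Wa.row(r) *= wmax_g2d / nrm(r);
        W_g2d.rows(act) = Wa;
      }
      if (full_variant) {
        arma::vec ep2 = eta_a2d * (eta_mask % f_d);
        arma::uvec act2 = arma::find(ep2 > 0);
        if (act2.n_elem > 0) {
          arma::mat Wa = W_a2d.rows(act2) + ep2(act2) * f_alb.t();
          arma::vec nrm = arma::sqrt(arma::sum(arma::square(Wa), 1));
          for (arma::uword r = 0; r < act2.n_elem; ++r)
            if (nrm(r) > wmax_a2d) Wa.row(r) *= wmax_a2d / nrm(r);
          W_a2d.rows(act2) = Wa;
        }
      } else {
        // each per-channel connection matrix is capped separately
        arma::vec ep2 = dir_eta * (eta_mask % f_d);
        arma::uvec act2 = arma::find(ep2 > 0);
        if (act2.n_elem > 0) {
          for (int j = 0; j < n_chan; ++j) {
            arma::mat Wa = Wv_v2d[j].rows(act2) + ep2(act2) * vis.col(j).t();
            arma::vec nrm = arma::sqrt(arma::sum(arma::square(Wa), 1));
            for (arma::uword r = 0; r < act2.n_elem; ++r)
              if (nrm(r) > dir_wmax) Wa.row(r) *= dir_wmax / nrm(r);
            Wv_v2d[j].rows(act2) = Wa;
          }
        }
      }
    }

    // logs
    if (keep_alb) log_alb.row(k) = f_alb.t();
    if (keep_hd) log_hd.row(k) = f_hd.t();
    if (keep_g) log_g.row(k) = f_g.t();
    if (keep_d) log_d.row(k) = f_d.t();
    if (log_every > 0 && ((k + 1) % log_every == 0)) {
      double ssum = 0, csum = 0;
      for (int i = 0; i < n; ++i) {
        ssum += f_hd(i) * std::sin(theta(i) * DEG);
        csum += f_hd(i) * std::cos(theta(i) * DEG);
      }
      dec_t.push_back(t_now);
      dec_true.push_back(hd);
      double res = std::sqrt(ssum * ssum + csum * csum);
      dec_hd.push_back(res < 1e-9 ? NA_REAL
                                  : std::atan2(ssum, csum) / DEG);
    }
  }

  for (int j = 0; j < W_alb.size(); ++j) W_alb[j] = Wv_alb[j];
  for (int j = 0; j < W_v2d.size(); ++j) W_v2d[j] = Wv_v2d[j];

  // final cue centers back to R
  List centers_out(n_cues);
  for (int c = 0; c < n_cues; ++c) centers_out[c] = cue_centers[c];

  List out = List::create(
    _["kick_pos"] = kick_pos, _["kick_ttl"] = kick_ttl,
    _["a_alb"] = a_alb, _["f_alb"] = f_alb,
    _["a_hd"] = a_hd, _["f_hd"] = f_hd,
    _["a_g"] = a_g, _["f_g"] = f_g,
    _["a_d"] = a_d, _["f_d"] = f_d,
    _["W_g2d"] = W_g2d, _["W_a2d"] = W_a2d,
    _["W_alb"] = W_alb, _["W_v2d"] = W_v2d,
    _["cue_centers"] = centers_out,
    _["dec_t"] = dec_t, _["dec_true"] = dec_true, _["dec_hd"] = dec_hd
  );
  if (keep_alb) out["log_alb"] = log_alb;
  if (keep_hd) out["log_hd"] = log_hd;
  if (keep_g) out["log_g"] = log_g;
  if (keep_d) out["log_d"] = log_d;
  return out;
}
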