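#include <Rcpp.h>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Wiener first-passage-time density.
//
// Density of the first hit at the LOWER boundary for a diffusion with unit
// diffusion coefficient, boundary separation a, drift v, relative start w
// (start point z = w*a), evaluated t seconds after accumulation onset.
// Computed from the standardized density f(t/a^2 | 0, 1, w) using whichever
// of the small-time / large-time series needs fewer terms for truncation
// error below eps (Navarro & Fuss style switching rule).
// ---------------------------------------------------------------------------

static double wfpt_std_lower(double tt, double w, double eps) {
  if (tt <= 0.0 || !R_finite(tt)) return 0.0;

  // required number of terms for the large-time series
  double kl;
  if (M_PI * tt * eps < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tt * eps) / (M_PI * M_PI * tt));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tt)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tt));
  }
  // required number of terms for the small-time series
  double ks;
  if (2.0 * std::sqrt(2.0 * M_PI * tt) * eps < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tt * std::log(2.0 * std::sqrt(2.0 * M_PI * tt) * eps));
    ks = std::max(ks, std::sqrt(tt) + 1.0);
  } else {
    ks = 2.0;
  }

  double p = 0.0;
  if (ks < kl) {             // small-time expansion
    int K = (int)std::ceil(ks);
    int lo = (int)(-std::floor((K - 1) / 2.0));
    int hi = (int)(std::ceil((K - 1) / 2.0));
    for (int k = lo; k <= hi; ++k) {
      double wk = w + 2.0 * k;
      p += wk * std::exp(-wk * wk / (2.0 * tt));
    }
    p /= std::sqrt(2.0 * M_PI * tt * tt * tt);
  } else {                   // large-time expansion
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; ++k) {
      p += k * std::exp(-k * k * M_PI * M_PI * tt / 2.0) * std::sin(k * M_PI * w);
    }
    p *= M_PI;
  }
  return p;
}

// full density at rt for the boundary actually hit (upper = 1, lower = 0)
static double wfpt_pdf1(double rt, int upper, double a, double v, double t0,
                        double w, double eps) {
  double t = rt - t0;
  if (!(t > 0.0) || !(a > 0.0) || !(w > 0.0) || !(w < 1.0)) return 0.0;
  double vv = v, ww = w;
  if (upper) { vv = -v; ww = 1.0 - w; }
  double tt = t / (a * a);
  double p = wfpt_std_lower(tt, ww, eps);
  if (p <= 0.0) return 0.0;
  return p * std::exp(-vv * a * ww - vv * vv * t / 2.0) / (a * a);
}

static double wfpt_logpdf1(double rt, int upper, double a, double v, double t0,
                           double w, double eps) {
  double t = rt - t0;
  if (!(t > 0.0) || !(a > 0.05) || !(w > 1e-4) || !(w < 1.0 - 1e-4) ||
      !R_finite(a) || !R_finite(v) || !R_finite(t0))
    return R_NegInf;
  double vv = v, ww = w;
  if (upper) { vv = -v; ww = 1.0 - w; }
  double tt = t / (a * a);
  double p = wfpt_std_lower(tt, ww, eps);
  if (p <= 0.0) return R_NegInf;
  return std::log(p) - vv * a * ww - vv * vv * t / 2.0 - 2.0 * std::log(a);
}

// [[Rcpp::export]]
NumericVector wfpt_pdf_cpp(NumericVector rt, int upper, double a, double v,
                           double t0, double w, double eps) {
  int n = rt.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = wfpt_pdf1(rt[i], upper, a, v, t0, w, eps);
  return out;
}

// force a particular expansion (0 = small-time, 1 = large-time); used to
// verify that both series agree in their overlap region
// [[Rcpp::export]]
NumericVector wfpt_pdf_series_cpp(NumericVector rt, int upper, double a,
                                  double v, double t0, double w, int which_series,
                                  int n_terms) {
  int n = rt.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double t = rt[i] - t0;
    if (!(t > 0.0)) { out[i] = 0.0; continue; }
    double vv = v, ww = w;
    if (upper) { vv = -v; ww = 1.0 - w; }
    double tt = t / (a * a);
    double p = 0.0;
    if (which_series == 0) {
      for (int k = -n_terms; k <= n_terms; ++k) {
        double wk = ww + 2.0 * k;
        p += wk * std::exp(-wk * wk / (2.0 * tt));
      }
      p /= std::sqrt(2.0 * M_PI * tt * tt * tt);
    } else {
      for (int k = 1; k <= n_terms; ++k)
        p += k * std::exp(-k * k * M_PI * M_PI * tt / 2.0) * std::sin(k * M_PI * ww);
      p *= M_PI;
    }
    out[i] = p * std::exp(-vv * a * ww - vv * vv * t / 2.0) / (a * a);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Euler-Maruyama simulator (dt in seconds, unit diffusion coefficient).
// Returns rt (including t0) and boundary hit (1 upper, 0 lower, NA if the
// process had not terminated by max_t, i.e. an omission).
// Uses R's RNG so results are reproducible under set.seed().
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List sample_ddm_cpp(NumericVector a, NumericVector v, NumericVector t0,
                    NumericVector w, NumericVector max_t, double dt) {
  int n = a.size();
  NumericVector rt(n);
  IntegerVector boundary(n);
  double sdt = std::sqrt(dt);
  for (int i = 0; i < n; ++i) {
    double x = w[i] * a[i];
    double tmax = max_t[i] - t0[i];
    double t = 0.0;
    int hit = NA_INTEGER;
    while (t < tmax) {
      double x_new = x + v[i] * dt + sdt * R::norm_rand();
      t += dt;
      if (x_new >= a[i]) { hit = 1; break; }
      if (x_new <= 0.0)  { hit = 0; break; }
      // Brownian-bridge probability of an unobserved within-step crossing;
      // without this, missed excursions bias RTs upward by O(sqrt(dt))
      double p_up = std::exp(-2.0 * (a[i] - x) * (a[i] - x_new) / dt);
      double p_lo = std::exp(-2.0 * x * x_new / dt);
      double u = R::unif_rand();
      if (u < p_up) { hit = 1; break; }
      if (u < p_up + p_lo) { hit = 0; break; }
      x = x_new;
    }
    if (hit == NA_INTEGER) {
      rt[i] = NA_REAL;
      boundary[i] = NA_INTEGER;
    } else {
      rt[i] = t0[i] + t;
      boundary[i] = hit;
    }
  }
  return List::create(_["rt"] = rt, _["boundary"] = boundary);
}

// ---------------------------------------------------------------------------
// Hierarchical DDM sampler.
//
// Trial-level linear predictors with identity link:
//   a_i = ua[subj_i] + Xa[i, ] %*% ba        (Xa excludes the intercept)
//   v_i = uv[subj_i] + Xv[i, ] %*% bv
//   t_i = ut[subj_i] + Xt[i, ] %*% bt
//   w_i = plogis(uwl[subj_i])  or 0.5 when bias is disabled
// Subject intercepts are exchangeable draws from group normals
// (mu_a, sg_a), ...; fixed effects have N(0, prior_b_sd^2) priors; group
// means have normal priors and group SDs half-normal priors.
//
// Updates: per-subject joint random-walk blocks, per-coefficient random
// walks for fixed effects, conjugate Gibbs for group means, log-scale
// random walk for group SDs. Proposal scales adapt during burn-in.
// ---------------------------------------------------------------------------

struct AdaptScale {
  double ls;      // log scale multiplier
  int it;
  AdaptScale() : ls(0.0), it(0) {}
  void adapt(double alpha, double target) {
    ++it;
    ls += (alpha - target) / std::pow((double)it, 0.6);
    if (ls > 4.0) ls = 4.0;
    if (ls < -8.0) ls = -8.0;
  }
  double scale() const { return std::exp(ls); }
};

// [[Rcpp::export]]
List hddm_mcmc_cpp(NumericVector rt, IntegerVector resp, IntegerVector subj,
                   int J, NumericMatrix Xa, NumericMatrix Xv, NumericMatrix Xt,
                   bool include_bias, int n_iter, int n_burn,
                   NumericVector init_ua, NumericVector init_uv,
                   NumericVector init_ut, NumericVector init_uwl,
                   List prior, double eps) {
  int n = rt.size();
  int pa = Xa.ncol(), pv = Xv.ncol(), pt = Xt.ncol();

  // priors
  double pm_a = as<double>(prior["mu_a_mean"]), ps_a = as<double>(prior["mu_a_sd"]);
  double pm_v = as<double>(prior["mu_v_mean"]), ps_v = as<double>(prior["mu_v_sd"]);
  double pm_t = as<double>(prior["mu_t_mean"]), ps_t = as<double>(prior["mu_t_sd"]);
  double hs_a = as<double>(prior["sg_a_scale"]);
  double hs_v = as<double>(prior["sg_v_scale"]);
  double hs_t = as<double>(prior["sg_t_scale"]);
  double b_sd = as<double>(prior["b_sd"]);
  double hs_w = include_bias ? as<double>(prior["sg_w_scale"]) : 0.5;

  // state
  std::vector<double> ua(init_ua.begin(), init_ua.end());
  std::vector<double> uv(init_uv.begin(), init_uv.end());
  std::vector<double> ut(init_ut.begin(), init_ut.end());
  std::vector<double> uwl(init_uwl.begin(), init_uwl.end());
  std::vector<double> ba(pa, 0.0), bv(pv, 0.0), bt(pt, 0.0);
  double mu_a = 0, sg_a = 0.4, mu_v = 0, sg_v = 0.4, mu_t = 0, sg_t = 0.1;
  double mu_w = 0.0, sg_w = 0.3;
  for (int j = 0; j < J; ++j) { mu_a += ua[j]; mu_v += uv[j]; mu_t += ut[j]; }
  mu_a /= J; mu_v /= J; mu_t /= J;

  // trial caches
  std::vector<double> av(n), vv(n), tv(n), wv(n), ll(n);
  std::vector<std::vector<int> > sidx(J);
  for (int i = 0; i < n; ++i) sidx[subj[i]].push_back(i);

  auto lin = [&](int i) {
    double a = ua[subj[i]], v = uv[subj[i]], t0 = ut[subj[i]];
    for (int k = 0; k < pa; ++k) a += Xa(i, k) * ba[k];
    for (int k = 0; k < pv; ++k) v += Xv(i, k) * bv[k];
    for (int k = 0; k < pt; ++k) t0 += Xt(i, k) * bt[k];
    av[i] = a; vv[i] = v; tv[i] = t0;
    wv[i] = include_bias ? 1.0 / (1.0 + std::exp(-uwl[subj[i]])) : 0.5;
  };
  for (int i = 0; i < n; ++i) {
    lin(i);
    ll[i] = wfpt_logpdf1(rt[i], resp[i], av[i], vv[i], tv[i], wv[i], eps);
  }

  std::vector<AdaptScale> sc_subj(J);
  std::vector<AdaptScale> sc_ba(pa), sc_bv(pv), sc_bt(pt);
  AdaptScale sc_sga, sc_sgv, sc_sgt, sc_sgw;

  int n_keep = n_iter - n_burn;
  int ncol_out = 6 + pa + pv + pt + (include_bias ? 2 : 0) + 3 * J;
  NumericMatrix draws(n_keep, ncol_out);

  // scratch for proposals
  std::vector<double> av2(n), vv2(n), tv2(n), ll2(n);

  for (int it = 0; it < n_iter; ++it) {
    bool adapting = it < n_burn;

    // --- subject blocks ---------------------------------------------------
    for (int j = 0; j < J; ++j) {
      double s = sc_subj[j].scale();
      double dua = R::norm_rand() * 0.12 * s;
      double duv = R::norm_rand() * 0.18 * s;
      double dut = R::norm_rand() * 0.02 * s;
      double duw = include_bias ? R::norm_rand() * 0.15 * s : 0.0;
      double wnew = include_bias ? 1.0 / (1.0 + std::exp(-(uwl[j] + duw))) : 0.5;
      double dl = 0.0;
      for (size_t q = 0; q < sidx[j].size(); ++q) {
        int i = sidx[j][q];
        double lnew = wfpt_logpdf1(rt[i], resp[i], av[i] + dua, vv[i] + duv,
                                   tv[i] + dut, wnew, eps);
        ll2[i] = lnew;
        dl += lnew - ll[i];
        if (!R_finite(dl)) break;
      }
      if (R_finite(dl)) {
        dl += R::dnorm(ua[j] + dua, mu_a, sg_a, 1) - R::dnorm(ua[j], mu_a, sg_a, 1);
        dl += R::dnorm(uv[j] + duv, mu_v, sg_v, 1) - R::dnorm(uv[j], mu_v, sg_v, 1);
        dl += R::dnorm(ut[j] + dut, mu_t, sg_t, 1) - R::dnorm(ut[j], mu_t, sg_t, 1);
        if (include_bias)
          dl += R::dnorm(uwl[j] + duw, mu_w, sg_w, 1) - R::dnorm(uwl[j], mu_w, sg_w, 1);
      }
      double alpha = R_finite(dl) ? std::min(1.0, std::exp(dl)) : 0.0;
      if (R::unif_rand() < alpha) {
        ua[j] += dua; uv[j] += duv; ut[j] += dut;
        if (include_bias) uwl[j] += duw;
        for (size_t q = 0; q < sidx[j].size(); ++q) {
          int i = sidx[j][q];
          av[i] += dua; vv[i] += duv; tv[i] += dut; wv[i] = wnew; ll[i] = ll2[i];
        }
      }
      if (adapting) sc_subj[j].adapt(alpha, 0.25);
    }

    // --- fixed effects ----------------------------------------------------
    auto update_beta = [&](std::vector<double>& b, NumericMatrix& X, int k,
                           AdaptScale& sc, int which) {
      double db = R::norm_rand() * 0.05 * sc.scale();
      double dl = 0.0;
      for (int i = 0; i < n; ++i) {
        double a = av[i], v = vv[i], t0 = tv[i];
        if (which == 0) a += db * X(i, k);
        else if (which == 1) v += db * X(i, k);
        else t0 += db * X(i, k);
        double lnew = wfpt_logpdf1(rt[i], resp[i], a, v, t0, wv[i], eps);
        ll2[i] = lnew;
        dl += lnew - ll[i];
        if (dl < -50.0 && !R_finite(lnew)) break;
      }
      if (R_finite(dl))
        dl += R::dnorm(b[k] + db, 0.0, b_sd, 1) - R::dnorm(b[k], 0.0, b_sd, 1);
      double alpha = R_finite(dl) ? std::min(1.0, std::exp(dl)) : 0.0;
      if (R::unif_rand() < alpha) {
        b[k] += db;
        for (int i = 0; i < n; ++i) {
          if (which == 0) av[i] += db * X(i, k);
          else if (which == 1) vv[i] += db * X(i, k);
          else tv[i] += db * X(i, k);
          ll[i] = ll2[i];
        }
      }
      if (adapting) sc.adapt(alpha, 0.35);
    };
    for (int k = 0; k < pa; ++k) update_beta(ba, Xa, k, sc_ba[k], 0);
    for (int k = 0; k < pv; ++k) update_beta(bv, Xv, k, sc_bv[k], 1);
    for (int k = 0; k < pt; ++k) update_beta(bt, Xt, k, sc_bt[k], 2);

    // --- group means (conjugate) and SDs (log random walk) ----------------
    auto update_group = [&](std::vector<double>& u, double& mu, double& sg,
                            double pm, double ps, double hscale, AdaptScale& sc) {
      double sum = 0.0;
      for (int j = 0; j < J; ++j) sum += u[j];
      double prec = J / (sg * sg) + 1.0 / (ps * ps);
      double mean = (sum / (sg * sg) + pm / (ps * ps)) / prec;
      mu = mean + R::norm_rand() / std::sqrt(prec);

      double lsg = std::log(sg);
      double lsg2 = lsg + R::norm_rand() * 0.25 * sc.scale();
      double sg2 = std::exp(lsg2);
      double dl = 0.0;
      for (int j = 0; j < J; ++j)
        dl += R::dnorm(u[j], mu, sg2, 1) - R::dnorm(u[j], mu, sg, 1);
      // half-normal prior plus log-scale Jacobian
      dl += -(sg2 * sg2 - sg * sg) / (2.0 * hscale * hscale) + (lsg2 - lsg);
      double alpha = R_finite(dl) ? std::min(1.0, std::exp(dl)) : 0.0;
      if (R::unif_rand() < alpha) sg = sg2;
      if (adapting) sc.adapt(alpha, 0.35);
    };
    update_group(ua, mu_a, sg_a, pm_a, ps_a, hs_a, sc_sga);
    update_group(uv, mu_v, sg_v, pm_v, ps_v, hs_v, sc_sgv);
    update_group(ut, mu_t, sg_t, pm_t, ps_t, hs_t, sc_sgt);
    if (include_bias) update_group(uwl, mu_w, sg_w, 0.0, 1.0, hs_w, sc_sgw);

    // --- record -----------------------------------------------------------
    if (it >= n_burn) {
      int r = it - n_burn, c = 0;
      draws(r, c++) = mu_a; draws(r, c++) = sg_a;
      draws(r, c++) = mu_v; draws(r, c++) = sg_v;
      draws(r, c++) = mu_t; draws(r, c++) = sg_t;
      for (int k = 0; k < pa; ++k) draws(r, c++) = ba[k];
      for (int k = 0; k < pv; ++k) draws(r, c++) = bv[k];
      for (int k = 0; k < pt; ++k) draws(r, c++) = bt[k];
      if (include_bias) { draws(r, c++) = mu_w; draws(r, c++) = sg_w; }
      for (int j = 0; j < J; ++j) draws(r, c++) = ua[j];
      for (int j = 0; j < J; ++j) draws(r, c++) = uv[j];
      for (int j = 0; j < J; ++j) draws(r, c++) = ut[j];
    }
  }

  return List::create(_["draws"] = draws, _["pa"] = pa, _["pv"] = pv,
                      _["pt"] = pt, _["include_bias"] = include_bias);
}
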