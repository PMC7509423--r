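// Compiled core of the PV-RNN: batched forward generation and exact BPTT.
// Layout convention inside C++: cubes are (B, dim, T); the R wrappers
// translate to the documented (T, B, dim) cache layout.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double SLOG_MIN = std::log(1e-6);
static const double SLOG_MAX = std::log(1e3);

struct Layer {
  int d_dim, z_dim, parent;  // parent: index into layer vector, -1 = none
  double tau;
  arma::mat Wdd, Wdz, Wtd, Wpm, Wps, Wqm, Wqs;
  arma::rowvec b, bpm, bps, bqm, bqs;
};

static std::vector<Layer> unpack_layers(const List& layers, const List& params) {
  int L = layers.size();
  std::vector<Layer> out(L);
  for (int i = 0; i < L; ++i) {
    List lc = layers[i];
    List pp = params[i];
    Layer& ly = out[i];
    ly.d_dim = as<int>(lc["d_dim"]);
    ly.z_dim = as<int>(lc["z_dim"]);
    ly.tau = as<double>(lc["tau"]);
    ly.parent = as<int>(lc["parent"]);
    ly.Wdd = as<arma::mat>(pp["Wdd"]);
    ly.Wdz = as<arma::mat>(pp["Wdz"]);
    if (!Rf_isNull(pp["Wtd"])) ly.Wtd = as<arma::mat>(pp["Wtd"]);
    ly.b = as<arma::rowvec>(pp["b"]);
    ly.Wpm = as<arma::mat>(pp["Wpm"]); ly.bpm = as<arma::rowvec>(pp["bpm"]);
    ly.Wps = as<arma::mat>(pp["Wps"]); ly.bps = as<arma::rowvec>(pp["bps"]);
    ly.Wqm = as<arma::mat>(pp["Wqm"]); ly.bqm = as<arma::rowvec>(pp["bqm"]);
    ly.Wqs = as<arma::mat>(pp["Wqs"]); ly.bqs = as<arma::rowvec>(pp["bqs"]);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_pvrnn_forward(List layers, List params, List heads, int T, int B,
                       bool posterior, List a_mu, List a_sg, List eps,
                       List d0, List h0, bool unit_prior_start,
                       int p_layer, int l_layer) {
  std::vector<Layer> ly = unpack_layers(layers, params);
  int L = ly.size();
  List hp = heads["p"], hl = heads["l"];
  arma::mat WpH = as<arma::mat>(hp["W"]);
  arma::rowvec bpH = as<arma::rowvec>(hp["b"]);
  arma::mat WlH = as<arma::mat>(hl["W"]);
  arma::rowvec blH = as<arma::rowvec>(hl["b"]);

  std::vector<arma::cube> d(L), h(L), z(L), mu_p(L), sg_p(L), mu_q(L), sg_q(L),
      msk_p(L), msk_q(L);
  std::vector<arma::mat> kl(L);
  std::vector<arma::cube> am(L), as_(L), ep(L);
  for (int i = 0; i < L; ++i) {
    d[i].zeros(B, ly[i].d_dim, T + 1);
    h[i].zeros(B, ly[i].d_dim, T + 1);
    d[i].slice(0) = as<arma::mat>(d0[i]);
    h[i].slice(0) = as<arma::mat>(h0[i]);
    z[i].zeros(B, ly[i].z_dim, T);
    mu_p[i].zeros(B, ly[i].z_dim, T);
    sg_p[i].ones(B, ly[i].z_dim, T);
    mu_q[i].zeros(B, ly[i].z_dim, T);
    sg_q[i].ones(B, ly[i].z_dim, T);
    msk_p[i].ones(B, ly[i].z_dim, T);
    msk_q[i].ones(B, ly[i].z_dim, T);
    kl[i].zeros(T, B);
    if (posterior) {
      am[i] = as<arma::cube>(a_mu[i]);
      as_[i] = as<arma::cube>(a_sg[i]);
    }
    ep[i] = as<arma::cube>(eps[i]);
  }
  arma::cube pout(B, WpH.n_cols, T), lout(B, WlH.n_cols, T);

  for (int t = 0; t < T; ++t) {
    bool unitp = (t == 0 && unit_prior_start);
    for (int i = 0; i < L; ++i) {
      const arma::mat& dp = d[i].slice(t);
      arma::mat mp, sp, mq, sq, zt;
      if (unitp) {
        mp.zeros(B, ly[i].z_dim);
        sp.ones(B, ly[i].z_dim);
      } else {
        arma::mat pre_m = dp * ly[i].Wpm; pre_m.each_row() += ly[i].bpm;
        arma::mat pre_s = dp * ly[i].Wps; pre_s.each_row() += ly[i].bps;
        msk_p[i].slice(t) = arma::conv_to<arma::mat>::from(
            (pre_s >= SLOG_MIN) % (pre_s <= SLOG_MAX));
        mp = arma::tanh(pre_m);
        sp = arma::exp(arma::clamp(pre_s, SLOG_MIN, SLOG_MAX));
      }
      mu_p[i].slice(t) = mp; sg_p[i].slice(t) = sp;
      if (posterior) {
        arma::mat pre_m = dp * ly[i].Wqm; pre_m.each_row() += ly[i].bqm;
        pre_m += am[i].slice(t);
        arma::mat pre_s = dp * ly[i].Wqs; pre_s.each_row() += ly[i].bqs;
        pre_s += as_[i].slice(t);
        msk_q[i].slice(t) = arma::conv_to<arma::mat>::from(
            (pre_s >= SLOG_MIN) % (pre_s <= SLOG_MAX));
        mq = arma::tanh(pre_m);
        sq = arma::exp(arma::clamp(pre_s, SLOG_MIN, SLOG_MAX));
        mu_q[i].slice(t) = mq; sg_q[i].slice(t) = sq;
        zt = mq + sq % ep[i].slice(t);
        arma::mat el = arma::log(sp / sq) +
            (arma::square(mp - mq) + arma::square(sq)) /
            (2.0 * arma::square(sp)) - 0.5;
        kl[i].row(t) = arma::sum(el, 1).t();
      } else {
        zt = mp + sp % ep[i].slice(t);
      }
      z[i].slice(t) = zt;
      arma::mat u = dp * ly[i].Wdd + zt * ly[i].Wdz;
      if (ly[i].parent >= 0) u += d[ly[i].parent].slice(t + 1) * ly[i].Wtd;
      u.each_row() += ly[i].b;
      arma::mat ht = (1.0 - 1.0 / ly[i].tau) * h[i].slice(t) + u / ly[i].tau;
      h[i].slice(t + 1) = ht;
      d[i].slice(t + 1) = arma::tanh(ht);
    }
    arma::mat pv = d[p_layer].slice(t + 1) * WpH; pv.each_row() += bpH;
    arma::mat lv = d[l_layer].slice(t + 1) * WlH; lv.each_row() += blH;
    pout.slice(t) = arma::tanh(pv);
    lout.slice(t) = arma::tanh(lv);
  }

  List per(L);
  for (int i = 0; i < L; ++i) {
    per[i] = List::create(_["d"] = d[i], _["h"] = h[i], _["z"] = z[i],
                          _["mu_p"] = mu_p[i], _["sg_p"] = sg_p[i],
                          _["mu_q"] = mu_q[i], _["sg_q"] = sg_q[i],
                          _["msk_p"] = msk_p[i], _["msk_q"] = msk_q[i],
                          _["kl"] = kl[i]);
  }
  return List::create(_["layers"] = per, _["p"] = pout, _["l"] = lout);
}

// [[Rcpp::export]]
List cpp_pvrnn_backward(List layers, List params, List heads, List cache,
                        arma::cube pbar, arma::cube lbar, arma::mat kw,
                        bool unit_prior_start, bool want_params, bool want_a,
                        int p_layer, int l_layer, double Rp, double Rl) {
  std::vector<Layer> ly = unpack_layers(layers, params);
  int L = ly.size();
  List hp = heads["p"], hl = heads["l"];
  arma::mat WpH = as<arma::mat>(hp["W"]);
  arma::mat WlH = as<arma::mat>(hl["W"]);
  List per = cache["layers"];
  arma::cube pout = as<arma::cube>(cache["p"]);
  arma::cube lout = as<arma::cube>(cache["l"]);
  int T = pout.n_slices, B = pout.n_rows;

  std::vector<arma::cube> d(L), z(L), mu_p(L), sg_p(L), mu_q(L), sg_q(L),
      msk_p(L), msk_q(L), ep(L);
  for (int i = 0; i < L; ++i) {
    List ci = per[i];
    d[i] = as<arma::cube>(ci["d"]);
    z[i] = as<arma::cube>(ci["z"]);
    mu_p[i] = as<arma::cube>(ci["mu_p"]); sg_p[i] = as<arma::cube>(ci["sg_p"]);
    mu_q[i] = as<arma::cube>(ci["mu_q"]); sg_q[i] = as<arma::cube>(ci["sg_q"]);
    msk_p[i] = as<arma::cube>(ci["msk_p"]); msk_q[i] = as<arma::cube>(ci["msk_q"]);
    ep[i] = as<arma::cube>(ci["eps"]);
  }

  // gradient accumulators
  std::vector<Layer> g(L);
  for (int i = 0; i < L; ++i) {
    g[i].Wdd.zeros(arma::size(ly[i].Wdd));
    g[i].Wdz.zeros(arma::size(ly[i].Wdz));
    if (ly[i].parent >= 0) g[i].Wtd.zeros(arma::size(ly[i].Wtd));
    g[i].b.zeros(ly[i].d_dim);
    g[i].Wpm.zeros(arma::size(ly[i].Wpm)); g[i].bpm.zeros(ly[i].z_dim);
    g[i].Wps.zeros(arma::size(ly[i].Wps)); g[i].bps.zeros(ly[i].z_dim);
    g[i].Wqm.zeros(arma::size(ly[i].Wqm)); g[i].bqm.zeros(ly[i].z_dim);
    g[i].Wqs.zeros(arma::size(ly[i].Wqs)); g[i].bqs.zeros(ly[i].z_dim);
  }
  arma::mat gWpH(arma::size(WpH), arma::fill::zeros);
  arma::rowvec gbpH(WpH.n_cols, arma::fill::zeros);
  arma::mat gWlH(arma::size(WlH), arma::fill::zeros);
  arma::rowvec gblH(WlH.n_cols, arma::fill::zeros);
  std::vector<arma::cube> ga_mu(L), ga_sg(L);
  if (want_a)
    for (int i = 0; i < L; ++i) {
      ga_mu[i].zeros(B, ly[i].z_dim, T);
      ga_sg[i].zeros(B, ly[i].z_dim, T);
    }

  std::vector<arma::mat> Gd_carry(L), Gh_carry(L), Gd_same(L);
  for (int i = 0; i < L; ++i) {
    Gd_carry[i].zeros(B, ly[i].d_dim);
    Gh_carry[i].zeros(B, ly[i].d_dim);
    Gd_same[i].zeros(B, ly[i].d_dim);
  }

  // reverse topological order: children before parents
  std::vector<int> rev(L);
  {
    std::vector<int> depth(L, 0);
    for (int i = 0; i < L; ++i)
      for (int j = i; ly[j].parent >= 0; j = ly[j].parent) depth[i]++;
    std::vector<std::pair<int, int>> ord;
    for (int i = 0; i < L; ++i) ord.push_back({-depth[i], i});
    std::sort(ord.begin(), ord.end());
    for (int i = 0; i < L; ++i) rev[i] = ord[i].second;
  }

  for (int t = T - 1; t >= 0; --t) {
    bool unitp = (t == 0 && unit_prior_start);
    arma::mat p_t = pout.slice(t), l_t = lout.slice(t);
    arma::mat Gp_pre = ((p_t - pbar.slice(t)) / Rp) % (1.0 - arma::square(p_t));
    arma::mat Gl_pre = ((l_t - lbar.slice(t)) / Rl) % (1.0 - arma::square(l_t));
    if (want_params) {
      gWpH += d[p_layer].slice(t + 1).t() * Gp_pre;
      gbpH += arma::sum(Gp_pre, 0);
      gWlH += d[l_layer].slice(t + 1).t() * Gl_pre;
      gblH += arma::sum(Gl_pre, 0);
    }
    Gd_same[p_layer] += Gp_pre * WpH.t();
    Gd_same[l_layer] += Gl_pre * WlH.t();
    for (int ri = 0; ri < (int)rev.size(); ++ri) {
      int i = rev[ri];
      const arma::mat d_t = d[i].slice(t + 1);
      const arma::mat dprev = d[i].slice(t);
      arma::mat Gd = Gd_carry[i] + Gd_same[i];
      arma::mat Gh = Gd % (1.0 - arma::square(d_t)) + Gh_carry[i];
      arma::mat Gu = Gh / ly[i].tau;
      const arma::mat z_t = z[i].slice(t);
      if (want_params) {
        g[i].Wdd += dprev.t() * Gu;
        g[i].Wdz += z_t.t() * Gu;
        g[i].b += arma::sum(Gu, 0);
      }
      if (ly[i].parent >= 0) {
        if (want_params) g[i].Wtd += d[ly[i].parent].slice(t + 1).t() * Gu;
        Gd_same[ly[i].parent] += Gu * ly[i].Wtd.t();
      }
      arma::mat Gz = Gu * ly[i].Wdz.t();
      const arma::mat mq = mu_q[i].slice(t), sq = sg_q[i].slice(t);
      const arma::mat mp = mu_p[i].slice(t), sp = sg_p[i].slice(t);
      double kwt = kw(t, i);
      arma::mat sp2 = arma::square(sp);
      arma::mat Gmu_q = kwt * (mq - mp) / sp2 + Gz;
      arma::mat Gsg_q = kwt * (-1.0 / sq + sq / sp2) + Gz % ep[i].slice(t);
      arma::mat Gqm_pre = Gmu_q % (1.0 - arma::square(mq));
      arma::mat Gqs_pre = Gsg_q % sq % msk_q[i].slice(t);
      if (want_params) {
        g[i].Wqm += dprev.t() * Gqm_pre;
        g[i].bqm += arma::sum(Gqm_pre, 0);
        g[i].Wqs += dprev.t() * Gqs_pre;
        g[i].bqs += arma::sum(Gqs_pre, 0);
      }
      if (want_a) {
        ga_mu[i].slice(t) = Gqm_pre;
        ga_sg[i].slice(t) = Gqs_pre;
      }
      arma::mat Gdprev = Gu * ly[i].Wdd.t() + Gqm_pre * ly[i].Wqm.t() +
          Gqs_pre * ly[i].Wqs.t();
      if (!unitp) {
        arma::mat Gmu_p = kwt * (mp - mq) / sp2;
        arma::mat Gsg_p = kwt * (1.0 / sp -
            (arma::square(mp - mq) + arma::square(sq)) / (sp2 % sp));
        arma::mat Gpm_pre = Gmu_p % (1.0 - arma::square(mp));
        arma::mat Gps_pre = Gsg_p % sp % msk_p[i].slice(t);
        if (want_params) {
          g[i].Wpm += dprev.t() * Gpm_pre;
          g[i].bpm += arma::sum(Gpm_pre, 0);
          g[i].Wps += dprev.t() * Gps_pre;
          g[i].bps += arma::sum(Gps_pre, 0);
        }
        Gdprev += Gpm_pre * ly[i].Wpm.t() + Gps_pre * ly[i].Wps.t();
      }
      Gd_carry[i] = Gdprev;
      Gh_carry[i] = Gh * (1.0 - 1.0 / ly[i].tau);
      Gd_same[i].zeros();
    }
  }

  List out;
  if (want_params) {
    List gp(L);
    for (int i = 0; i < L; ++i) {
      gp[i] = List::create(
          _["Wdd"] = g[i].Wdd, _["Wdz"] = g[i].Wdz,
          _["Wtd"] = (ly[i].parent >= 0) ? wrap(g[i].Wtd) : R_NilValue,
          _["b"] = g[i].b,
          _["Wpm"] = g[i].Wpm, _["bpm"] = g[i].bpm,
          _["Wps"] = g[i].Wps, _["bps"] = g[i].bps,
          _["Wqm"] = g[i].Wqm, _["bqm"] = g[i].bqm,
          _["Wqs"] = g[i].Wqs, _["bqs"] = g[i].bqs);
    }
    out["params"] = gp;
    out["heads"] = List::create(
        _["p"] = List::create(_["W"] = gWpH, _["b"] = gbpH),
        _["l"] = List::create(_["W"] = gWlH, _["b"] = gblH));
  }
  if (want_a) {
    List ga(L);
    for (int i = 0; i < L; ++i)
      ga[i] = List::create(_["a_mu"] = ga_mu[i], _["a_sigma"] = ga_sg[i]);
    out["a"] = ga;
  }
  return out;
}
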