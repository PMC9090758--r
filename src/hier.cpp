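#include <RcppArmadillo.h>
#include "lba_kernel.h"
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Full DE-MCMC sweep loop of the hierarchical LBA. Chains carry all
// subject-level parameter vectors (sampling scale) plus the group-level
// (mu, log sigma). Per sweep: a DE crossover of every subject block
// conditional on the chain's group state, an exact Gibbs refresh of the
// group conditionals (conjugate normal for mu; independence MH from the
// likelihood-conjugate inverse-gamma for sigma under its Exponential
// prior), interweaved non-centered rescaling moves on a random subset of
// parameters, and, during burn-in only, whole-chain cyclic migration.
// All randomness comes from R's RNG, so runs are reproducible from
// set.seed() on the R side.

struct SubjData {
  arma::vec rt;
  arma::ivec cond;
  arma::ivec correct;
};

struct ParMap {
  // 0-based column indices into the sampling-scale vector
  arma::ivec vt, vf, b;  // length 4 each (per condition)
  int a, t0, sv;
};

static double subj_loglik(const double *x, const ParMap &pm,
                          const SubjData &dat) {
  double A = std::exp(x[pm.a]);
  double t0 = std::exp(x[pm.t0]);
  double sv = std::exp(x[pm.sv]);
  double b4[4], vt4[4], vf4[4], den_t4[4], den_f4[4];
  for (int c = 0; c < 4; ++c) {
    b4[c] = A + std::exp(x[pm.b[c]]);
    vt4[c] = x[pm.vt[c]];
    vf4[c] = x[pm.vf[c]];
    den_t4[c] = lba::trunc_denom(vt4[c], sv);
    den_f4[c] = lba::trunc_denom(vf4[c], 1.0);
  }
  double s = 0.0;
  int nt = dat.rt.n_elem;
  for (int i = 0; i < nt; ++i)
    s += lba::trial_logdens_d(dat.rt[i], dat.cond[i], dat.correct[i], A, b4,
                              t0, sv, vt4, vf4, den_t4, den_f4);
  return s;
}

static void subj_pointwise(const double *x, const ParMap &pm,
                           const SubjData &dat, double *out) {
  double A = std::exp(x[pm.a]);
  double t0 = std::exp(x[pm.t0]);
  double sv = std::exp(x[pm.sv]);
  double b4[4], vt4[4], vf4[4];
  for (int c = 0; c < 4; ++c) {
    b4[c] = A + std::exp(x[pm.b[c]]);
    vt4[c] = x[pm.vt[c]];
    vf4[c] = x[pm.vf[c]];
  }
  int nt = dat.rt.n_elem;
  for (int i = 0; i < nt; ++i)
    out[i] = lba::trial_logdens(dat.rt[i], dat.cond[i], dat.correct[i], A,
                                b4, t0, sv, vt4, vf4);
}

// Single-subject log-likelihood for one sampling-scale vector (fast path
// for the fixed-effects optimizer; avoids the R-level block expansion).
// [[Rcpp::export]]
double cpp_subj_loglik_one(const arma::vec &x, const List &parmap_r,
                           const arma::vec &rt, const arma::ivec &cond,
                           const arma::ivec &correct) {
  ParMap pm;
  pm.vt = as<arma::ivec>(parmap_r["vt"]);
  pm.vf = as<arma::ivec>(parmap_r["vf"]);
  pm.b = as<arma::ivec>(parmap_r["b"]);
  pm.a = as<int>(parmap_r["a"]);
  pm.t0 = as<int>(parmap_r["t0"]);
  pm.sv = as<int>(parmap_r["sv"]);
  SubjData dat;
  dat.rt = rt; dat.cond = cond; dat.correct = correct;
  return subj_loglik(x.memptr(), pm, dat);
}

// distinct partners j, k != i
static inline void pick_partners(int nc, int i, int &j, int &k) {
  j = (int)(unif_rand() * (nc - 1));
  if (j >= i) ++j;
  k = (int)(unif_rand() * (nc - 2));
  int a = i < j ? i : j, b = i < j ? j : i;
  if (k >= a) ++k;
  if (k >= b) ++k;
}

// [[Rcpp::export]]
List cpp_hier_sampler(const List &trials_r, const arma::mat &init,
                      const List &parmap_r, const arma::vec &mu_mean,
                      const arma::vec &mu_sd, double rate, int n_chains,
                      int burnin, int samples, int thin, double mig_prob,
                      double jitter, int n_interweave, bool store_loglik,
                      double init_jitter, int n_full, int n_scale) {
  const int S = trials_r.size();
  const int d = init.n_cols;
  const int nc = n_chains;

  std::vector<SubjData> dat(S);
  arma::ivec n_tr(S);
  for (int s = 0; s < S; ++s) {
    List tr = trials_r[s];
    dat[s].rt = as<arma::vec>(tr["rt"]);
    dat[s].cond = as<arma::ivec>(tr["cond"]);
    dat[s].correct = as<arma::ivec>(tr["correct"]);
    n_tr[s] = dat[s].rt.n_elem;
  }
  ParMap pm;
  pm.vt = as<arma::ivec>(parmap_r["vt"]);
  pm.vf = as<arma::ivec>(parmap_r["vf"]);
  pm.b = as<arma::ivec>(parmap_r["b"]);
  pm.a = as<int>(parmap_r["a"]);
  pm.t0 = as<int>(parmap_r["t0"]);
  pm.sv = as<int>(parmap_r["sv"]);

  // state: X[c](S x d), mu (nc x d), ls (nc x d), cached loglik L (nc x S)
  std::vector<arma::mat> X(nc, arma::mat(S, d));
  arma::mat mu(nc, d), ls(nc, d), L(nc, S);
  arma::vec xprop(d), xcur(d);
  for (int c = 0; c < nc; ++c) {
    for (int s = 0; s < S; ++s)
      for (int k = 0; k < d; ++k)
        X[c](s, k) = init(s, k) + norm_rand() * init_jitter;
    for (int k = 0; k < d; ++k) {
      double m = arma::mean(init.col(k));
      double sdev = arma::stddev(init.col(k));
      if (!(sdev > 0.1)) sdev = 0.1;
      mu(c, k) = m + norm_rand() * init_jitter;
      ls(c, k) = std::log(sdev) + norm_rand() * init_jitter;
    }
    for (int s = 0; s < S; ++s) {
      for (int p = 0; p < d; ++p) xcur[p] = X[c](s, p);
      L(c, s) = subj_loglik(xcur.memptr(), pm, dat[s]);
    }
  }

  double gamma_subj = 2.38 / std::sqrt(2.0 * d);
  double gamma_nc = 2.38 / std::sqrt(2.0 * 2.0);
  double scale_step = 0.05;
  double gamma_full = 2.38 / std::sqrt(2.0 * 2.0 * d);
  long acc_subj = 0, try_subj = 0, acc_grp = 0, try_grp = 0;
  long acc_iw = 0, try_iw = 0, acc_sc = 0, try_sc = 0;
  long acc_fl = 0, try_fl = 0;
  long win_subj = 0, winTry_subj = 0, win_iw = 0, winTry_iw = 0;
  long win_sc = 0, winTry_sc = 0, win_fl = 0, winTry_fl = 0;

  // coordinates touched by the scaling move
  std::set<int> mset, sset;
  for (int c = 0; c < 4; ++c) { mset.insert(pm.vt[c]); mset.insert(pm.vf[c]); }
  for (int c = 0; c < 4; ++c) sset.insert(pm.b[c]);
  sset.insert(pm.a); sset.insert(pm.sv);
  arma::ivec mult_idx(mset.size()), shift_idx(sset.size());
  { int q = 0; for (int v : mset) mult_idx[q++] = v; }
  { int q = 0; for (int v : sset) shift_idx[q++] = v; }

  const int n_store = samples / thin;
  const int total_tr = arma::accu(n_tr);
  arma::cube Gdraws(n_store, nc, 2 * d);
  NumericVector Sdraws(n_store * nc * S * d);
  arma::mat PW;
  if (store_loglik) PW.set_size(n_store * nc, total_tr);
  arma::ivec tr_off(S + 1);
  tr_off[0] = 0;
  for (int s = 0; s < S; ++s) tr_off[s + 1] = tr_off[s] + n_tr[s];

  std::vector<double> pwbuf;
  int stored = 0;
  const int n_sweeps = burnin + samples;

  for (int it = 1; it <= n_sweeps; ++it) {
    const bool in_burnin = it <= burnin;

    // ---- subject-level DE crossover
    for (int s = 0; s < S; ++s) {
      for (int c = 0; c < nc; ++c) {
        int j, k;
        pick_partners(nc, c, j, k);
        double lp_cur = L(c, s);
        double lp_prop_prior = 0.0, lp_cur_prior = 0.0;
        for (int p = 0; p < d; ++p) {
          double sig = std::exp(ls(c, p));
          xcur[p] = X[c](s, p);
          xprop[p] = xcur[p] + gamma_subj * (X[j](s, p) - X[k](s, p)) +
            (jitter > 0 ? (unif_rand() * 2.0 - 1.0) * jitter : 0.0);
          lp_cur_prior += R::dnorm(xcur[p], mu(c, p), sig, 1);
          lp_prop_prior += R::dnorm(xprop[p], mu(c, p), sig, 1);
        }
        double ll_prop = subj_loglik(xprop.memptr(), pm, dat[s]);
        double lhr = (ll_prop + lp_prop_prior) - (lp_cur + lp_cur_prior);
        ++try_subj; ++winTry_subj;
        if (std::isfinite(lhr) && std::log(unif_rand()) < lhr) {
          for (int p = 0; p < d; ++p) X[c](s, p) = xprop[p];
          L(c, s) = ll_prop;
          ++acc_subj; ++win_subj;
        }
      }
    }

    // ---- group-level Gibbs (two scans)
    for (int rep = 0; rep < 2; ++rep) {
      for (int c = 0; c < nc; ++c) {
        for (int k = 0; k < d; ++k) {
          double sig2 = std::exp(2.0 * ls(c, k));
          double xbar = arma::mean(X[c].col(k));
          double prec = S / sig2 + 1.0 / (mu_sd[k] * mu_sd[k]);
          double pmean = (S * xbar / sig2 +
                          mu_mean[k] / (mu_sd[k] * mu_sd[k])) / prec;
          mu(c, k) = pmean + norm_rand() / std::sqrt(prec);
          double b2 = 0.0;
          for (int s = 0; s < S; ++s) {
            double dd = X[c](s, k) - mu(c, k);
            b2 += dd * dd;
          }
          b2 *= 0.5;
          // proposal sigma^2 ~ InvGamma(S/2, b2)
          double prop_s2 = b2 / R::rgamma(S / 2.0, 1.0);
          double ls_p = 0.5 * std::log(prop_s2);
          double sig_p = std::exp(ls_p);
          double sig_c = std::exp(ls(c, k));
          double s2_c = sig_c * sig_c;
          auto lr = [&](double lsv, double sigv, double s2) {
            return (-S * lsv - b2 / s2 - rate * sigv + lsv) -
                   (-(S / 2.0 + 1.0) * std::log(s2) - b2 / s2 +
                    std::log(2.0 * s2));
          };
          double lacc = lr(ls_p, sig_p, prop_s2) - lr(ls(c, k), sig_c, s2_c);
          ++try_grp;
          if (std::log(unif_rand()) < lacc) {
            ls(c, k) = ls_p;
            ++acc_grp;
          }
        }
      }
    }

    // ---- full-vector non-centered DE moves: propose the whole group
    // state (mu, log sigma) along chain-difference directions with all
    // standardized subject deviations held fixed; chain differences
    // align with the posterior's own correlations, which carries the
    // state along soft ridges (A-B-t0 trade-offs) that componentwise
    // moves cannot traverse
    for (int rep = 0; rep < n_full; ++rep) {
      for (int c = 0; c < nc; ++c) {
        int j, kk;
        pick_partners(nc, c, j, kk);
        arma::vec mu_p(d), ls_p(d), sig_p(d), sig_c(d);
        for (int k = 0; k < d; ++k) {
          mu_p[k] = mu(c, k) + gamma_full * (mu(j, k) - mu(kk, k)) +
            (unif_rand() * 2.0 - 1.0) * jitter;
          double lsv = ls(c, k) + gamma_full * (ls(j, k) - ls(kk, k)) +
            (unif_rand() * 2.0 - 1.0) * jitter;
          if (lsv > 20.0) lsv = 20.0;
          if (lsv < -20.0) lsv = -20.0;
          ls_p[k] = lsv;
          sig_p[k] = std::exp(lsv);
          sig_c[k] = std::exp(ls(c, k));
        }
        double ll_tot = 0.0;
        arma::vec ll_new(S);
        arma::mat Xp_s(S, d);
        for (int s = 0; s < S; ++s) {
          for (int p = 0; p < d; ++p) {
            double eta = (X[c](s, p) - mu(c, p)) / sig_c[p];
            xcur[p] = mu_p[p] + sig_p[p] * eta;
          }
          Xp_s.row(s) = xcur.t();
          ll_new[s] = subj_loglik(xcur.memptr(), pm, dat[s]);
          ll_tot += ll_new[s];
        }
        double pr_cur = 0.0, pr_p = 0.0;
        for (int k = 0; k < d; ++k) {
          pr_cur += R::dnorm(mu(c, k), mu_mean[k], mu_sd[k], 1) -
            rate * sig_c[k] + ls(c, k);
          pr_p += R::dnorm(mu_p[k], mu_mean[k], mu_sd[k], 1) -
            rate * sig_p[k] + ls_p[k];
        }
        double lhr = (ll_tot + pr_p) - (arma::accu(L.row(c)) + pr_cur);
        ++try_fl; ++winTry_fl;
        if (std::isfinite(lhr) && std::log(unif_rand()) < lhr) {
          mu.row(c) = mu_p.t();
          ls.row(c) = ls_p.t();
          X[c] = Xp_s;
          L.row(c) = ll_new.t();
          ++acc_fl; ++win_fl;
        }
      }
    }

    // ---- interweaved non-centered moves on random parameters
    for (int rep = 0; rep < n_interweave; ++rep) {
      int k = (int)(unif_rand() * d);
      if (k >= d) k = d - 1;
      for (int c = 0; c < nc; ++c) {
        int j, kk;
        pick_partners(nc, c, j, kk);
        double mu_p = mu(c, k) + gamma_nc * (mu(j, k) - mu(kk, k)) +
          (unif_rand() * 2.0 - 1.0) * jitter;
        double ls_p = ls(c, k) + gamma_nc * (ls(j, k) - ls(kk, k)) +
          (unif_rand() * 2.0 - 1.0) * jitter;
        if (ls_p > 20.0) ls_p = 20.0;
        if (ls_p < -20.0) ls_p = -20.0;
        double sig_c = std::exp(ls(c, k)), sig_p = std::exp(ls_p);
        // rescale every subject's k-th parameter, keeping eta fixed
        double ll_new_tot = 0.0;
        arma::vec ll_new(S);
        arma::vec xk_new(S);
        bool ok = true;
        for (int s = 0; s < S && ok; ++s) {
          double eta = (X[c](s, k) - mu(c, k)) / sig_c;
          xk_new[s] = mu_p + sig_p * eta;
          for (int p = 0; p < d; ++p)
            xcur[p] = (p == k) ? xk_new[s] : X[c](s, p);
          ll_new[s] = subj_loglik(xcur.memptr(), pm, dat[s]);
          ll_new_tot += ll_new[s];
          if (!std::isfinite(ll_new[s])) ok = false;
        }
        double prior_cur = R::dnorm(mu(c, k), mu_mean[k], mu_sd[k], 1) +
          (-rate * sig_c + std::log(rate) + ls(c, k));
        double prior_p = R::dnorm(mu_p, mu_mean[k], mu_sd[k], 1) +
          (-rate * sig_p + std::log(rate) + ls_p);
        double lp_cur = arma::accu(L.row(c)) + prior_cur;
        double lhr = ll_new_tot + prior_p - lp_cur;
        ++try_iw; ++winTry_iw;
        if (ok && std::isfinite(lhr) && std::log(unif_rand()) < lhr) {
          mu(c, k) = mu_p;
          ls(c, k) = ls_p;
          for (int s = 0; s < S; ++s) {
            X[c](s, k) = xk_new[s];
            L(c, s) = ll_new[s];
          }
          ++acc_iw; ++win_iw;
        }
      }
    }

    // ---- joint rescaling move along the LBA's soft scaling ridge:
    // multiply every drift (subject level and group means/SDs) by c and
    // shift the log-scale magnitude parameters (A, B, sv) by log c,
    // leaving t0 fixed. RT distributions are nearly invariant under
    // this map (the mismatch SD fixed at 1 breaks it only through
    // error trials), so the posterior has a long soft ridge that
    // ordinary componentwise moves traverse extremely slowly.
    for (int rep = 0; rep < n_scale; ++rep) {
      for (int c = 0; c < nc; ++c) {
        double lc = (unif_rand() * 2.0 - 1.0) * scale_step;
        double fac = std::exp(lc);
        // proposed group state
        arma::vec mu_p = mu.row(c).t(), ls_p = ls.row(c).t();
        for (int q = 0; q < (int)mult_idx.n_elem; ++q) {
          mu_p[mult_idx[q]] *= fac;
          ls_p[mult_idx[q]] += lc;       // sigma of drifts scales too
        }
        for (int q = 0; q < (int)shift_idx.n_elem; ++q)
          mu_p[shift_idx[q]] += lc;
        double ll_tot = 0.0;
        arma::vec ll_new(S);
        arma::mat Xp_s(S, d);
        for (int s = 0; s < S; ++s) {
          for (int p = 0; p < d; ++p) xcur[p] = X[c](s, p);
          for (int q = 0; q < (int)mult_idx.n_elem; ++q)
            xcur[mult_idx[q]] *= fac;
          for (int q = 0; q < (int)shift_idx.n_elem; ++q)
            xcur[shift_idx[q]] += lc;
          Xp_s.row(s) = xcur.t();
          ll_new[s] = subj_loglik(xcur.memptr(), pm, dat[s]);
          ll_tot += ll_new[s];
        }
        // priors under current and proposed states
        double pr_cur = 0.0, pr_p = 0.0;
        for (int k = 0; k < d; ++k) {
          double sig_c = std::exp(ls(c, k)), sig_pp = std::exp(ls_p[k]);
          for (int s = 0; s < S; ++s) {
            pr_cur += R::dnorm(X[c](s, k), mu(c, k), sig_c, 1);
            pr_p += R::dnorm(Xp_s(s, k), mu_p[k], sig_pp, 1);
          }
          pr_cur += R::dnorm(mu(c, k), mu_mean[k], mu_sd[k], 1) -
            rate * sig_c + ls(c, k);
          pr_p += R::dnorm(mu_p[k], mu_mean[k], mu_sd[k], 1) -
            rate * sig_pp + ls_p[k];
        }
        // Jacobian: multiplied coordinates are the subject drifts and
        // the group drift means (log-scale shifts contribute nothing)
        double n_mult = (double)mult_idx.n_elem * (S + 1);
        double lhr = (ll_tot + pr_p) - (arma::accu(L.row(c)) + pr_cur) +
          n_mult * lc;
        ++try_sc; ++winTry_sc;
        if (std::isfinite(lhr) && std::log(unif_rand()) < lhr) {
          mu.row(c) = mu_p.t();
          ls.row(c) = ls_p.t();
          X[c] = Xp_s;
          L.row(c) = ll_new.t();
          ++acc_sc; ++win_sc;
        }
      }
    }

    // ---- whole-chain cyclic migration during burn-in
    if (in_burnin && unif_rand() < mig_prob) {
      arma::vec lp_tot(nc);
      for (int c = 0; c < nc; ++c) {
        double ps = 0.0;
        for (int k = 0; k < d; ++k) {
          double sig = std::exp(ls(c, k));
          for (int s = 0; s < S; ++s)
            ps += R::dnorm(X[c](s, k), mu(c, k), sig, 1);
          ps += R::dnorm(mu(c, k), mu_mean[k], mu_sd[k], 1) -
            rate * sig + std::log(rate) + ls(c, k);
        }
        lp_tot[c] = arma::accu(L.row(c)) + ps;
      }
      int m = 1 + (int)(unif_rand() * nc);
      if (m > nc) m = nc;
      if (m > 1) {
        arma::ivec sel(m);
        // sample m distinct chains
        std::vector<int> pool(nc);
        for (int c = 0; c < nc; ++c) pool[c] = c;
        for (int t = 0; t < m; ++t) {
          int pick = t + (int)(unif_rand() * (nc - t));
          std::swap(pool[t], pool[pick]);
          sel[t] = pool[t];
        }
        // receiver sel[t] takes the state of donor sel[(t-1+m) % m]
        std::vector<arma::mat> donorX(m);
        arma::mat donorMu(m, d), donorLs(m, d), donorL(m, S);
        arma::vec donorLp(m);
        for (int t = 0; t < m; ++t) {
          int dn = sel[(t - 1 + m) % m];
          donorX[t] = X[dn];
          donorMu.row(t) = mu.row(dn);
          donorLs.row(t) = ls.row(dn);
          donorL.row(t) = L.row(dn);
          donorLp[t] = lp_tot[dn];
        }
        for (int t = 0; t < m; ++t) {
          int rc = sel[t];
          if (std::log(unif_rand()) < donorLp[t] - lp_tot[rc]) {
            X[rc] = donorX[t];
            mu.row(rc) = donorMu.row(t);
            ls.row(rc) = donorLs.row(t);
            L.row(rc) = donorL.row(t);
          }
        }
      }
    }

    // ---- burn-in adaptation of the DE scales
    if (in_burnin && it % 50 == 0) {
      double r1 = winTry_subj ? (double)win_subj / winTry_subj : 0.25;
      if (r1 > 0.35) gamma_subj *= 1.15;
      else if (r1 < 0.15) gamma_subj *= 0.85;
      double r2 = winTry_iw ? (double)win_iw / winTry_iw : 0.25;
      if (r2 > 0.35) gamma_nc *= 1.15;
      else if (r2 < 0.15) gamma_nc *= 0.85;
      double r3 = winTry_sc ? (double)win_sc / winTry_sc : 0.25;
      if (r3 > 0.35) scale_step *= 1.15;
      else if (r3 < 0.15) scale_step *= 0.85;
      double r4 = winTry_fl ? (double)win_fl / winTry_fl : 0.25;
      if (r4 > 0.35) gamma_full *= 1.15;
      else if (r4 < 0.15) gamma_full *= 0.85;
      win_subj = winTry_subj = win_iw = winTry_iw = 0;
      win_sc = winTry_sc = win_fl = winTry_fl = 0;
    }

    // ---- storage
    if (!in_burnin && (it - burnin) % thin == 0) {
      for (int c = 0; c < nc; ++c) {
        for (int k = 0; k < d; ++k) {
          Gdraws(stored, c, k) = mu(c, k);
          Gdraws(stored, c, d + k) = ls(c, k);
        }
        for (int s = 0; s < S; ++s)
          for (int k = 0; k < d; ++k)
            Sdraws[stored + n_store * (c + nc * ((long)s + (long)S * k))] =
              X[c](s, k);
        if (store_loglik) {
          int row = stored * nc + c;
          for (int s = 0; s < S; ++s) {
            pwbuf.resize(n_tr[s]);
            for (int p = 0; p < d; ++p) xcur[p] = X[c](s, p);
            subj_pointwise(xcur.memptr(), pm, dat[s], pwbuf.data());
            for (int i = 0; i < n_tr[s]; ++i)
              PW(row, tr_off[s] + i) = pwbuf[i];
          }
        }
      }
      ++stored;
    }
  }

  List out = List::create(
    Named("group") = Gdraws,
    Named("subjects") = Sdraws,
    Named("acceptance") = NumericVector::create(
      Named("subject") = try_subj ? (double)acc_subj / try_subj : NA_REAL,
      Named("group") = try_grp ? (double)acc_grp / try_grp : NA_REAL,
      Named("interweave") = try_iw ? (double)acc_iw / try_iw : NA_REAL,
      Named("scale") = try_sc ? (double)acc_sc / try_sc : NA_REAL,
      Named("full_nc") = try_fl ? (double)acc_fl / try_fl : NA_REAL));
  if (store_loglik) out["pointwise"] = PW;
  return out;
}
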