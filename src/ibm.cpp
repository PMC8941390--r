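// Individual-based eco-genetic simulator.
//
// Discrete-time (default 1 day) stochastic simulation of the same
// bioenergetics as the deterministic engine, for a finite volume V:
// individuals carry diploid multi-locus genotypes for the niche trait x
// (sum of allelic values) and the assortative-mating trait a (mean of
// allelic values, bounded in [-1, 1]). Event order within a step is fixed
// for reproducibility: feeding/growth, resource update, mortality,
// spawning with mate choice. All randomness comes from the R RNG, so runs
// are bit-reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Params {
  double m_b, m_mat, m_shift, q, A_max, h, n, alpha, k, p_met;
  double eps_egg, mu0, mort_exp, xi, delta, V;
  double m_asym, psi_exp, kappa;
  bool alloc_smooth;
  int shift_mode; // 0 discrete, 1 gradual, 2 broadening
  double shift_steep;
  std::vector<double> theta, tau, R_max;
};

struct Genetics {
  int Fx, Fa;
  double nu, sigma, sigma_a, sigma_m;
};

static inline double mate_weight(double a, double dx, double sigma_m) {
  if (a == 0.0) return 1.0;
  double z = a * a * dx * dx / (2.0 * sigma_m * sigma_m);
  if (a > 0.0) return std::exp(-z);
  return (1.0 - std::exp(-z)) + 1e-3;  // disassortative, uniform floor
}

// fraction of adult net energy to reproduction
static inline double psi_frac(double m, const Params& P) {
  if (!P.alloc_smooth) return P.kappa;
  double gate = 1.0 / (1.0 + std::pow(m / P.m_mat, -P.psi_exp));
  double psi = gate * std::pow(m / P.m_asym, 1.0 - P.n);
  return psi > 1.0 ? 1.0 : psi;
}

// [[Rcpp::export]]
NumericVector cpp_mate_weights(double a, NumericVector dx, double sigma_m) {
  NumericVector w(dx.size());
  for (int i = 0; i < dx.size(); ++i) w[i] = mate_weight(a, dx[i], sigma_m);
  return w;
}

static void inherit(std::vector<double>& child, const double* mom,
                    const double* dad, int F, double nu, double sigma,
                    bool bounded) {
  // per locus: one allele drawn uniformly from each parent's two; each
  // inherited allele mutates with probability nu by a Gaussian step
  for (int l = 0; l < F; ++l) {
    double from_mom = mom[2 * l + (unif_rand() < 0.5 ? 0 : 1)];
    double from_dad = dad[2 * l + (unif_rand() < 0.5 ? 0 : 1)];
    if (unif_rand() < nu) from_mom += norm_rand() * sigma;
    if (unif_rand() < nu) from_dad += norm_rand() * sigma;
    if (bounded) {
      if (from_mom > 1) from_mom = 1; else if (from_mom < -1) from_mom = -1;
      if (from_dad > 1) from_dad = 1; else if (from_dad < -1) from_dad = -1;
    }
    child[2 * l] = from_mom;
    child[2 * l + 1] = from_dad;
  }
}

// [[Rcpp::export]]
List cpp_make_offspring(NumericVector mom_x, NumericVector dad_x,
                        NumericVector mom_a, NumericVector dad_a,
                        int Fx, int Fa, double nu, double sigma,
                        double sigma_a) {
  std::vector<double> cx(2 * Fx), ca(2 * Fa);
  inherit(cx, REAL(mom_x), REAL(dad_x), Fx, nu, sigma, false);
  inherit(ca, REAL(mom_a), REAL(dad_a), Fa, nu, sigma_a, true);
  return List::create(_["x_alleles"] = NumericVector(cx.begin(), cx.end()),
                      _["a_alleles"] = NumericVector(ca.begin(), ca.end()));
}

struct Pop {
  std::vector<double> m, buf, x, a;
  std::vector<double> ax;      // x alleles, flat n * 2Fx
  std::vector<double> aa;      // a alleles, flat n * 2Fa
  std::vector<double> att;     // cached attack coefficients, flat n * nR
  std::vector<int> id;
  int n() const { return (int)m.size(); }
};

static void cache_attack(Pop& pop, int i, const Params& P) {
  int nR = (int)P.theta.size();
  for (int j = 0; j < nR; ++j) {
    double t = P.tau[j];
    double v;
    if (!std::isfinite(t)) v = P.A_max;
    else {
      double d = pop.x[i] - P.theta[j];
      v = P.A_max * std::exp(-d * d / (2.0 * t * t));
    }
    pop.att[(size_t)i * nR + j] = v;
  }
}

static void remove_individual(Pop& pop, int i, int Fx2, int Fa2, int nR) {
  int last = pop.n() - 1;
  if (i != last) {
    pop.m[i] = pop.m[last]; pop.buf[i] = pop.buf[last];
    pop.x[i] = pop.x[last]; pop.a[i] = pop.a[last];
    pop.id[i] = pop.id[last];
    for (int l = 0; l < Fx2; ++l)
      pop.ax[(size_t)i * Fx2 + l] = pop.ax[(size_t)last * Fx2 + l];
    for (int l = 0; l < Fa2; ++l)
      pop.aa[(size_t)i * Fa2 + l] = pop.aa[(size_t)last * Fa2 + l];
    for (int j = 0; j < nR; ++j)
      pop.att[(size_t)i * nR + j] = pop.att[(size_t)last * nR + j];
  }
  pop.m.pop_back(); pop.buf.pop_back(); pop.x.pop_back(); pop.a.pop_back();
  pop.id.pop_back();
  pop.ax.resize((size_t)pop.n() * Fx2);
  pop.aa.resize((size_t)pop.n() * Fa2);
  pop.att.resize((size_t)pop.n() * nR);
}

// [[Rcpp::export]]
List cpp_run_ibm(List pars, List gen, List state, double t_max, double dt,
                 double record_every, bool snapshot_mature_only,
                 int candidate_cap, int mating_log) {
  Params P;
  P.m_b = pars["m_b"]; P.m_mat = pars["m_mat"]; P.m_shift = pars["m_shift"];
  P.q = pars["q"]; P.A_max = pars["A_max"]; P.h = pars["h"];
  P.n = pars["n_intake"]; P.alpha = pars["alpha"]; P.k = pars["k_met"];
  P.p_met = pars["p_met"]; P.eps_egg = pars["eps_egg"];
  P.mu0 = pars["mu_0"]; P.mort_exp = pars["mort_exp"];
  P.xi = pars["xi_starv"]; P.delta = pars["delta"]; P.V = gen["V"];
  P.m_asym = pars["m_asym"]; P.psi_exp = pars["psi_exp"];
  P.kappa = pars["kappa_repro"];
  P.alloc_smooth = as<std::string>(pars["allocation"]) == "smooth";
  std::string sm = as<std::string>(pars["shift_mode"]);
  P.shift_mode = sm == "discrete" ? 0 : (sm == "gradual" ? 1 : 2);
  P.shift_steep = pars["shift_steep"];
  P.theta = as<std::vector<double> >(pars["theta"]);
  P.tau = as<std::vector<double> >(pars["tau"]);
  P.R_max = as<std::vector<double> >(pars["R_max"]);
  int nR = (int)P.theta.size();
  if (nR > 16) stop("at most 15 species-specific resources supported");

  Genetics G;
  G.Fx = gen["F_x"]; G.Fa = gen["F_a"];
  G.nu = gen["nu"]; G.sigma = gen["sigma"]; G.sigma_m = gen["sigma_m"];
  G.sigma_a = gen.containsElementNamed("sigma_a") ?
    as<double>(gen["sigma_a"]) : G.sigma;
  int Fx2 = 2 * G.Fx, Fa2 = 2 * G.Fa;

  Pop pop;
  {
    NumericVector m0 = state["m"], buf0 = state["buffer"];
    NumericMatrix ax0 = state["x_alleles"], aa0 = state["a_alleles"];
    IntegerVector id0 = state["id"];
    int n0 = m0.size();
    pop.m.assign(m0.begin(), m0.end());
    pop.buf.assign(buf0.begin(), buf0.end());
    pop.id.assign(id0.begin(), id0.end());
    pop.x.resize(n0); pop.a.resize(n0);
    pop.ax.resize((size_t)n0 * Fx2); pop.aa.resize((size_t)n0 * Fa2);
    pop.att.resize((size_t)n0 * nR);
    for (int i = 0; i < n0; ++i) {
      double sx = 0;
      for (int l = 0; l < Fx2; ++l) {
        pop.ax[(size_t)i * Fx2 + l] = ax0(i, l);
        sx += ax0(i, l);
      }
      double sa = 0;
      for (int l = 0; l < Fa2; ++l) {
        pop.aa[(size_t)i * Fa2 + l] = aa0(i, l);
        sa += aa0(i, l);
      }
      pop.x[i] = sx;
      pop.a[i] = sa / Fa2;
      cache_attack(pop, i, P);
    }
  }
  std::vector<double> R = as<std::vector<double> >(state["resources"]);
  double t = state["time"];
  int next_id = state["next_id"];
  double t_end = t + t_max;
  double cost = P.m_b / P.eps_egg;   // buffer debit per offspring

  // records
  std::vector<double> sn_t, sn_m, sn_x, sn_a; std::vector<int> sn_id;
  std::vector<double> se_t, se_meana, se_meanx; std::vector<int> se_n, se_nmat;
  std::vector<double> se_R; // flat nR per record
  std::vector<double> mt_t, mt_xm, mt_xf; std::vector<int> mt_mom, mt_dad, mt_noff;

  std::vector<double> mu_dt;        // per-step death probabilities
  std::vector<int> mature_idx, cand;
  std::vector<double> wts;
  bool extinct = false;
  double next_record = t;           // record at t0, then every record_every

  long step_count = 0;
  double eps_t = dt * 1e-6;
  while (t < t_end - eps_t) {
    // ---- record before the step if due
    if (record_every > 0 && t >= next_record - eps_t) {
      next_record += record_every;
      int nmat = 0; double suma = 0, sumx = 0;
      for (int i = 0; i < pop.n(); ++i) {
        if (pop.m[i] >= P.m_mat) ++nmat;
        suma += pop.a[i]; sumx += pop.x[i];
        if (!snapshot_mature_only || pop.m[i] >= P.m_mat) {
          sn_t.push_back(t); sn_id.push_back(pop.id[i]);
          sn_m.push_back(pop.m[i]); sn_x.push_back(pop.x[i]);
          sn_a.push_back(pop.a[i]);
        }
      }
      se_t.push_back(t); se_n.push_back(pop.n()); se_nmat.push_back(nmat);
      se_meana.push_back(pop.n() ? suma / pop.n() : NA_REAL);
      se_meanx.push_back(pop.n() ? sumx / pop.n() : NA_REAL);
      for (int j = 0; j < nR; ++j) se_R.push_back(R[j]);
    }
    // an empty population flags extinction but the resources keep
    // relaxing toward carrying capacity (semi-chemostat)
    if (pop.n() == 0) extinct = true;

    // ---- 1. feeding, growth / buffer filling; collect grazing
    int n = pop.n();
    mu_dt.assign(n, 0.0);
    std::vector<double> uptake(nR, 0.0);
    for (int i = 0; i < n; ++i) {
      double m = pop.m[i];
      // diet weights
      double ws, wc;
      if (P.shift_mode == 1 && P.m_shift > 0 && std::isfinite(P.m_shift)) {
        ws = 1.0 / (1.0 + std::pow(m / P.m_shift, P.shift_steep));
        wc = 1.0 - ws;
      } else {
        wc = (m >= P.m_shift) ? 1.0 : 0.0;
        ws = (P.shift_mode == 2) ? 1.0 : 1.0 - wc;
      }
      const double* att = &pop.att[(size_t)i * nR];
      double mq = std::pow(m, P.q);
      double E = 0;
      double Ej[16];
      for (int j = 0; j < nR; ++j) {
        double w = (j == 0) ? ws : wc;
        Ej[j] = w * att[j] * mq * R[j];
        E += Ej[j];
      }
      double hmn = P.h * std::pow(m, P.n);
      double f = E > 0 ? E / (E + hmn) : 0.0;
      for (int j = 0; j < nR; ++j) uptake[j] += Ej[j] * (1.0 - f);
      double Enet = P.alpha * f * hmn - P.k * std::pow(m, P.p_met);
      double deficit = Enet < 0 ? -Enet : 0.0;
      if (Enet > 0) {
        if (m >= P.m_mat) {
          double psi = psi_frac(m, P);
          pop.buf[i] += psi * Enet * dt;
          pop.m[i] = m + (1.0 - psi) * Enet * dt;
        } else {
          // explicit growth with sub-stepping at small sizes (frozen f)
          double rel = Enet * dt / m;
          int nsub = rel > 0.1 ? (int)std::ceil(rel / 0.1) : 1;
          if (nsub > 64) nsub = 64;
          double hsub = dt / nsub, mm = m;
          for (int s = 0; s < nsub; ++s) {
            double g = P.alpha * f * P.h * std::pow(mm, P.n) -
                       P.k * std::pow(mm, P.p_met);
            if (g < 0) g = 0;
            if (mm >= P.m_mat) {
              double psi = psi_frac(mm, P);
              pop.buf[i] += psi * g * hsub;
              mm += (1.0 - psi) * g * hsub;
            } else mm += g * hsub;
          }
          pop.m[i] = mm;
        }
      }
      double mu = P.mu0 * std::pow(m, P.mort_exp) + P.xi * deficit / m;
      mu_dt[i] = 1.0 - std::exp(-mu * dt);
    }

    // ---- 2. semi-chemostat resource update (grazing scaled by 1/V)
    for (int j = 0; j < nR; ++j) {
      R[j] += dt * (P.delta * (P.R_max[j] - R[j]) - uptake[j] / P.V);
      if (R[j] < 0) R[j] = 0;
    }

    // ---- 3. mortality
    for (int i = pop.n() - 1; i >= 0; --i) {
      if (unif_rand() < mu_dt[i]) remove_individual(pop, i, Fx2, Fa2, nR);
    }

    // ---- 4. spawning: mothers with a full buffer choose a father
    mature_idx.clear();
    for (int i = 0; i < pop.n(); ++i)
      if (pop.m[i] >= P.m_mat) mature_idx.push_back(i);
    int n_before_spawn = pop.n();  // newborns do not act this step
    for (int ii = 0; ii < (int)mature_idx.size(); ++ii) {
      int i = mature_idx[ii];
      if (i >= n_before_spawn) continue;
      if (pop.buf[i] < cost) continue;
      int n_off = (int)std::floor(pop.buf[i] / cost);
      // candidate fathers: mature individuals other than the mother
      cand.clear();
      for (int jj = 0; jj < (int)mature_idx.size(); ++jj)
        if (mature_idx[jj] != i) cand.push_back(mature_idx[jj]);
      if (cand.empty()) continue;   // mating skipped, buffer retained
      if (candidate_cap > 0 && (int)cand.size() > candidate_cap) {
        // uniform subsample with replacement (documented config option)
        for (int c = 0; c < candidate_cap; ++c) {
          int pick = (int)(unif_rand() * cand.size());
          if (pick >= (int)cand.size()) pick = cand.size() - 1;
          cand[c] = cand[pick];
        }
        cand.resize(candidate_cap);
      }
      wts.resize(cand.size());
      double wsum = 0;
      for (size_t c = 0; c < cand.size(); ++c) {
        wts[c] = mate_weight(pop.a[i], pop.x[i] - pop.x[cand[c]], G.sigma_m);
        wsum += wts[c];
      }
      if (wsum <= 0) continue;
      double u = unif_rand() * wsum;
      size_t c = 0;
      for (; c + 1 < cand.size(); ++c) {
        u -= wts[c];
        if (u <= 0) break;
      }
      int dad = cand[c];
      pop.buf[i] -= n_off * cost;
      if (mating_log) {
        mt_t.push_back(t); mt_mom.push_back(pop.id[i]);
        mt_dad.push_back(pop.id[dad]);
        mt_xm.push_back(pop.x[i]); mt_xf.push_back(pop.x[dad]);
        mt_noff.push_back(n_off);
      }
      for (int o = 0; o < n_off; ++o) {
        std::vector<double> cx(Fx2), ca(Fa2);
        inherit(cx, &pop.ax[(size_t)i * Fx2], &pop.ax[(size_t)dad * Fx2],
                G.Fx, G.nu, G.sigma, false);
        inherit(ca, &pop.aa[(size_t)i * Fa2], &pop.aa[(size_t)dad * Fa2],
                G.Fa, G.nu, G.sigma_a, true);
        pop.m.push_back(P.m_b); pop.buf.push_back(0.0);
        pop.id.push_back(next_id++);
        double sx = 0, sa = 0;
        for (int l = 0; l < Fx2; ++l) sx += cx[l];
        for (int l = 0; l < Fa2; ++l) sa += ca[l];
        pop.x.push_back(sx); pop.a.push_back(sa / Fa2);
        pop.ax.insert(pop.ax.end(), cx.begin(), cx.end());
        pop.aa.insert(pop.aa.end(), ca.begin(), ca.end());
        pop.att.resize(pop.att.size() + nR);
        cache_attack(pop, pop.n() - 1, P);
      }
    }

    t += dt;
    ++step_count;
    if (step_count % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  // final state (alleles back to matrices)
  int n = pop.n();
  NumericMatrix axm(n, Fx2), aam(n, Fa2);
  for (int i = 0; i < n; ++i) {
    for (int l = 0; l < Fx2; ++l) axm(i, l) = pop.ax[(size_t)i * Fx2 + l];
    for (int l = 0; l < Fa2; ++l) aam(i, l) = pop.aa[(size_t)i * Fa2 + l];
  }
  List fin = List::create(
    _["m"] = NumericVector(pop.m.begin(), pop.m.end()),
    _["buffer"] = NumericVector(pop.buf.begin(), pop.buf.end()),
    _["x_alleles"] = axm, _["a_alleles"] = aam,
    _["id"] = IntegerVector(pop.id.begin(), pop.id.end()),
    _["x"] = NumericVector(pop.x.begin(), pop.x.end()),
    _["a"] = NumericVector(pop.a.begin(), pop.a.end()),
    _["resources"] = NumericVector(R.begin(), R.end()),
    _["time"] = t, _["next_id"] = next_id);

  NumericMatrix seR((int)se_t.size(), nR);
  for (int r = 0; r < (int)se_t.size(); ++r)
    for (int j = 0; j < nR; ++j) seR(r, j) = se_R[(size_t)r * nR + j];

  return List::create(
    _["final_state"] = fin,
    _["extinct"] = extinct,
    _["snap_t"] = NumericVector(sn_t.begin(), sn_t.end()),
    _["snap_id"] = IntegerVector(sn_id.begin(), sn_id.end()),
    _["snap_m"] = NumericVector(sn_m.begin(), sn_m.end()),
    _["snap_x"] = NumericVector(sn_x.begin(), sn_x.end()),
    _["snap_a"] = NumericVector(sn_a.begin(), sn_a.end()),
    _["series_t"] = NumericVector(se_t.begin(), se_t.end()),
    _["series_n"] = IntegerVector(se_n.begin(), se_n.end()),
    _["series_nmat"] = IntegerVector(se_nmat.begin(), se_nmat.end()),
    _["series_mean_a"] = NumericVector(se_meana.begin(), se_meana.end()),
    _["series_mean_x"] = NumericVector(se_meanx.begin(), se_meanx.end()),
    _["series_R"] = seR,
    _["mate_t"] = NumericVector(mt_t.begin(), mt_t.end()),
    _["mate_mother"] = IntegerVector(mt_mom.begin(), mt_mom.end()),
    _["mate_father"] = IntegerVector(mt_dad.begin(), mt_dad.end()),
    _["mate_x_mother"] = NumericVector(mt_xm.begin(), mt_xm.end()),
    _["mate_x_father"] = NumericVector(mt_xf.begin(), mt_xf.end()),
    _["mate_n_off"] = IntegerVector(mt_noff.begin(), mt_noff.end()));
}
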