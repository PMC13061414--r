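// Production engine for the cooperative-breeding division-of-labour model.
//
// The engine executes the five-step breeding cycle (reproduce -> dispersal ->
// task choice & help -> survival -> breeder replacement -> ageing) on a
// struct-of-arrays population with slot reuse.  All randomness goes through
// R's RNG (unif_rand / norm_rand / R::rpois) in a fixed draw order --- the
// "engine contract" --- so that the per-individual pure-R reference
// implementation in R/reference-engine.R reproduces the exact same states
// bit for bit under the same seed.  Any change to draw order here must be
// mirrored there.
//
// Draw-order contract (one cycle):
//   1. Reproduction: territories in index order; per breeder one rpois(K);
//      per offspring, loci in order (alpha, beta, beta_0, beta_R, gamma_0,
//      gamma_R, neutral): one uniform, plus one normal when it mutates.
//   2. Dispersal: territories in index order, subordinates in list order:
//      one uniform (disperse?).  Then pool = old floaters ++ new dispersers,
//      in order: one uniform (join?), plus one uniform (territory) on join.
//      GA-only: philopatric newborns collected territory/list order; their
//      territory labels Fisher-Yates shuffled (top-down, one uniform per
//      swap); each is then moved (remove + append) to its shuffled label.
//   3. Task choice: territories in index order, subordinates in list order:
//      one uniform against T evaluated at R = age (work cost not yet paid).
//   4. Survival: group sizes frozen at step start; territories in index
//      order, breeder first then subordinates in list order, then floaters
//      in pool order: one uniform each.
//   5. Vacancies: territories in index order; per vacant territory one
//      rpois(f*N_f/N_b) then one uniform per bidder drawn without
//      replacement from the remaining unbid pool; one uniform for the
//      dominance-weighted (or uniform fallback) winner draw.
//   6. Ageing consumes no randomness.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Locus order used for inheritance/mutation (engine contract):
// 0 alpha, 1 beta, 2 beta_0, 3 beta_R, 4 gamma_0, 5 gamma_R, 6 neutral
#define N_LOCI 7

#define TASK_NONE 0
#define TASK_DEFENSE 1
#define TASK_WORK 2

#define BM_KS_ONLY 1
#define BM_GA_ONLY 2
#define BM_KS_GA 3

#define FM_DOL 1
#define FM_NO_DOL 2

#define DN_SCALAR 1
#define DN_RANK 2

struct Params {
  double y_h, x_h, x_n, x_0, m, f, k_m, k_h, k_0, mu, sigma_mu;
  int N_b;
  int benefit_mode, fecundity_mode, dispersal_norm;
};

struct Tally {
  int atrisk_b, surv_b, atrisk_s, surv_s, atrisk_f, surv_f;
  Tally() : atrisk_b(0), surv_b(0), atrisk_s(0), surv_s(0),
            atrisk_f(0), surv_f(0) {}
};

struct Pop {
  std::vector<double> gene[N_LOCI];
  std::vector<double> help;     // max(0, alpha), cached at birth
  std::vector<int> age;         // cycles survived; newborns have age 1
  std::vector<int> task;        // this cycle's task
  std::vector<char> natal;      // newborn still in natal group (within-cycle)
  std::vector<int> breeder;     // per territory: slot index or -1
  std::vector< std::vector<int> > subs; // per territory, stable order
  std::vector<int> floaters;    // pool order
  std::vector<double> prev_def, prev_work; // previous cycle's help sums
  std::vector<int> free_slots;

  int new_slot() {
    if (!free_slots.empty()) {
      int s = free_slots.back();
      free_slots.pop_back();
      return s;
    }
    for (int l = 0; l < N_LOCI; ++l) gene[l].push_back(0.0);
    help.push_back(0.0);
    age.push_back(0);
    task.push_back(TASK_NONE);
    natal.push_back(0);
    return (int) help.size() - 1;
  }

  int n_subs() const {
    int n = 0;
    for (size_t g = 0; g < subs.size(); ++g) n += (int) subs[g].size();
    return n;
  }
  int n_breeders() const {
    int n = 0;
    for (size_t g = 0; g < breeder.size(); ++g) if (breeder[g] >= 0) ++n;
    return n;
  }
  int pop_size() const {
    return n_breeders() + n_subs() + (int) floaters.size();
  }
};

static inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// Dispersal propensity; dominance entering the rank norm is the individual's
// current age (work costs are paid later in the cycle and not carried over).
static inline double disp_D(const Pop &P, const Params &par, int i) {
  if (par.dispersal_norm == DN_SCALAR) return clamp01(P.gene[1][i]);
  double R = (double) P.age[i];
  return 1.0 / (1.0 + std::exp(P.gene[3][i] * R - P.gene[2][i]));
}

static inline double task_T(const Pop &P, int i, double R) {
  return 1.0 / (1.0 + std::exp(P.gene[5][i] * R - P.gene[4][i]));
}

// Division-of-labour cap: each task's cumulative help is truncated at the
// balanced split plus slack k_m; identity in the unconstrained mode.
static inline void effective_help(double sd, double sw, const Params &par,
                                  double &ed, double &ew) {
  if (par.fecundity_mode == FM_NO_DOL) { ed = sd; ew = sw; return; }
  double hmax = (sd + sw) / 2.0 + par.k_m;
  ed = sd > hmax ? hmax : sd;
  ew = sw > hmax ? hmax : sw;
}

static inline double fecundity_K(double ed, double ew, const Params &par) {
  double S = ed + ew;
  return par.k_0 + par.k_h * S / (1.0 + S);
}

// Dominance value with this cycle's work cost.
static inline double dominance_R(const Pop &P, const Params &par, int i) {
  double hw = (P.task[i] == TASK_WORK) ? P.help[i] : 0.0;
  double R = (double) P.age[i] - par.y_h * hw;
  return R < 0.0 ? 0.0 : R;
}

static void step1_reproduce(Pop &P, const Params &par) {
  for (int g = 0; g < par.N_b; ++g) {
    int b = P.breeder[g];
    if (b < 0) continue;
    double ed, ew;
    effective_help(P.prev_def[g], P.prev_work[g], par, ed, ew);
    double K = fecundity_K(ed, ew, par);
    int n_off = (int) R::rpois(K);
    for (int j = 0; j < n_off; ++j) {
      int s = P.new_slot();
      for (int l = 0; l < N_LOCI; ++l) {
        double v = P.gene[l][b];
        double u = unif_rand();
        if (u < par.mu) {
          v += norm_rand() * par.sigma_mu;
          // the dispersal gene maps identically onto a closed probability,
          // so both boundaries would be absorbing under expression-only
          // clamping; it is truncated at the gene.  All other loci
          // (including the helping gene, whose 0 boundary is one-sided)
          // are unbounded, with bounds applied at expression.
          if (l == 1) v = clamp01(v);
        }
        P.gene[l][s] = v;
      }
      P.help[s] = P.gene[0][s] > 0.0 ? P.gene[0][s] : 0.0;
      P.age[s] = 1;
      P.task[s] = TASK_NONE;
      P.natal[s] = 1;
      P.subs[g].push_back(s);
    }
  }
}

static void step2_dispersal(Pop &P, const Params &par) {
  std::vector<int> newf;
  for (int g = 0; g < par.N_b; ++g) {
    std::vector<int> keep;
    keep.reserve(P.subs[g].size());
    for (size_t k = 0; k < P.subs[g].size(); ++k) {
      int s = P.subs[g][k];
      double D = disp_D(P, par, s);
      double u = unif_rand();
      if (u < D) {
        P.natal[s] = 0;
        newf.push_back(s);
      } else {
        keep.push_back(s);
      }
    }
    P.subs[g].swap(keep);
  }
  // Floaters (old pool first, then fresh dispersers) may join a random group
  std::vector<int> pool;
  pool.reserve(P.floaters.size() + newf.size());
  pool.insert(pool.end(), P.floaters.begin(), P.floaters.end());
  pool.insert(pool.end(), newf.begin(), newf.end());
  P.floaters.clear();
  for (size_t k = 0; k < pool.size(); ++k) {
    int s = pool[k];
    double D = disp_D(P, par, s);
    double u = unif_rand();
    if (u < 1.0 - D) {
      int g2 = (int) (unif_rand() * par.N_b);
      if (g2 >= par.N_b) g2 = par.N_b - 1;
      P.natal[s] = 0;
      P.subs[g2].push_back(s);
    } else {
      P.floaters.push_back(s);
    }
  }
  // Group-augmentation-only manipulation: cross-foster philopatric newborns
  if (par.benefit_mode == BM_GA_ONLY) {
    std::vector<int> kids;
    std::vector<int> labels;
    for (int g = 0; g < par.N_b; ++g) {
      for (size_t k = 0; k < P.subs[g].size(); ++k) {
        int s = P.subs[g][k];
        if (P.age[s] == 1 && P.natal[s]) {
          kids.push_back(s);
          labels.push_back(g);
        }
      }
    }
    int n = (int) kids.size();
    if (n >= 2) {
      for (int i = n - 1; i >= 1; --i) {
        int j = (int) (unif_rand() * (i + 1));
        if (j > i) j = i;
        int tmp = labels[i];
        labels[i] = labels[j];
        labels[j] = tmp;
      }
    }
    if (n >= 1) {
      std::vector<char> moving(P.help.size(), 0);
      for (int k = 0; k < n; ++k) moving[kids[k]] = 1;
      for (int g = 0; g < par.N_b; ++g) {
        std::vector<int> keep;
        keep.reserve(P.subs[g].size());
        for (size_t k = 0; k < P.subs[g].size(); ++k)
          if (!moving[P.subs[g][k]]) keep.push_back(P.subs[g][k]);
        P.subs[g].swap(keep);
      }
      for (int k = 0; k < n; ++k) P.subs[labels[k]].push_back(kids[k]);
    }
  }
}

static void step3_help(Pop &P, const Params &par) {
  for (int g = 0; g < par.N_b; ++g) {
    double cd = 0.0, cw = 0.0;
    for (size_t k = 0; k < P.subs[g].size(); ++k) {
      int s = P.subs[g][k];
      double R = (double) P.age[s]; // work cost not yet paid for the draw
      double T = task_T(P, s, R);
      double u = unif_rand();
      if (u < T) {
        P.task[s] = TASK_DEFENSE;
        cd += P.help[s];
      } else {
        P.task[s] = TASK_WORK;
        cw += P.help[s];
      }
    }
    // these sums feed next cycle's reproduction (non-cumulative)
    P.prev_def[g] = cd;
    P.prev_work[g] = cw;
  }
}

static void step4_survival(Pop &P, const Params &par, Tally &t) {
  // group sizes frozen at the start of the step, same value for all members
  std::vector<int> Ng(par.N_b);
  for (int g = 0; g < par.N_b; ++g)
    Ng[g] = (P.breeder[g] >= 0 ? 1 : 0) + (int) P.subs[g].size();
  double one_m = 1.0 - par.m;
  for (int g = 0; g < par.N_b; ++g) {
    int b = P.breeder[g];
    if (b >= 0) {
      double S = one_m / (1.0 + std::exp(-par.x_0 - par.x_n * Ng[g]));
      double u = unif_rand();
      ++t.atrisk_b;
      if (u < S) {
        ++t.surv_b;
      } else {
        P.breeder[g] = -1;
        P.free_slots.push_back(b);
      }
    }
    std::vector<int> keep;
    keep.reserve(P.subs[g].size());
    for (size_t k = 0; k < P.subs[g].size(); ++k) {
      int s = P.subs[g][k];
      double hd = (P.task[s] == TASK_DEFENSE) ? P.help[s] : 0.0;
      double S = one_m /
        (1.0 + std::exp(-par.x_0 + par.x_h * hd - par.x_n * Ng[g]));
      double u = unif_rand();
      ++t.atrisk_s;
      if (u < S) {
        ++t.surv_s;
        keep.push_back(s);
      } else {
        P.free_slots.push_back(s);
      }
    }
    P.subs[g].swap(keep);
  }
  double SF = one_m / (1.0 + std::exp(-par.x_0));
  std::vector<int> keepf;
  keepf.reserve(P.floaters.size());
  for (size_t k = 0; k < P.floaters.size(); ++k) {
    int s = P.floaters[k];
    double u = unif_rand();
    ++t.atrisk_f;
    if (u < SF) {
      ++t.surv_f;
      keepf.push_back(s);
    } else {
      P.free_slots.push_back(s);
    }
  }
  P.floaters.swap(keepf);
}

static void step5_vacancies(Pop &P, const Params &par) {
  int Nf = (int) P.floaters.size();
  double lambda = par.N_b > 0 ? par.f * (double) Nf / (double) par.N_b : 0.0;
  std::vector<int> avail = P.floaters; // unbid pool, order preserved
  for (int g = 0; g < par.N_b; ++g) {
    if (P.breeder[g] >= 0) continue;
    int nb = (int) R::rpois(lambda);
    if (nb > (int) avail.size()) nb = (int) avail.size();
    std::vector<int> bidders;
    bidders.reserve(nb);
    for (int j = 0; j < nb; ++j) {
      int idx = (int) (unif_rand() * avail.size());
      if (idx >= (int) avail.size()) idx = (int) avail.size() - 1;
      bidders.push_back(avail[idx]);
      avail.erase(avail.begin() + idx);
    }
    int ncand = (int) P.subs[g].size() + (int) bidders.size();
    if (ncand == 0) continue;
    std::vector<int> cand;
    cand.reserve(ncand);
    cand.insert(cand.end(), P.subs[g].begin(), P.subs[g].end());
    cand.insert(cand.end(), bidders.begin(), bidders.end());
    std::vector<double> w(ncand);
    double tot = 0.0;
    for (int k = 0; k < ncand; ++k) {
      w[k] = dominance_R(P, par, cand[k]);
      tot += w[k];
    }
    int win;
    if (tot <= 0.0) { // all-zero dominance: uniform lottery
      double u = unif_rand();
      win = (int) (u * ncand);
      if (win >= ncand) win = ncand - 1;
    } else {
      double u = unif_rand() * tot;
      double acc = 0.0;
      win = ncand - 1;
      for (int k = 0; k < ncand; ++k) {
        acc += w[k];
        if (u < acc) { win = k; break; }
      }
    }
    int s = cand[win];
    P.breeder[g] = s;
    if (win < (int) P.subs[g].size()) {
      P.subs[g].erase(P.subs[g].begin() + win);
    } else {
      for (size_t k = 0; k < P.floaters.size(); ++k)
        if (P.floaters[k] == s) {
          P.floaters.erase(P.floaters.begin() + k);
          break;
        }
    }
  }
}

static void step6_age(Pop &P, const Params &par) {
  for (int g = 0; g < par.N_b; ++g) {
    int b = P.breeder[g];
    if (b >= 0) { ++P.age[b]; P.task[b] = TASK_NONE; P.natal[b] = 0; }
    for (size_t k = 0; k < P.subs[g].size(); ++k) {
      int s = P.subs[g][k];
      ++P.age[s];
      P.task[s] = TASK_NONE;
      P.natal[s] = 0;
    }
  }
  for (size_t k = 0; k < P.floaters.size(); ++k) {
    int s = P.floaters[k];
    ++P.age[s];
    P.task[s] = TASK_NONE;
    P.natal[s] = 0;
  }
}

// ---- summary record -------------------------------------------------------

#define N_REC_COLS 31

static void summarize_row(const Pop &P, const Params &par, const Tally &t,
                          int cycle, double *row) {
  int nb = P.n_breeders();
  int ns = P.n_subs();
  int nf = (int) P.floaters.size();
  int ntot = nb + ns + nf;

  // allele moments over all alive individuals (population SD)
  double sum[N_LOCI] = {0}, ssq[N_LOCI] = {0};
  double sum_disp = 0.0, sum_help = 0.0, sum_T = 0.0;
  double sum_rank_help = 0.0, sum_rank_float = 0.0;
  // relatedness accumulators: x = breeder neutral, y = helper neutral
  double rx = 0.0, ry = 0.0, rxx = 0.0, rxy = 0.0;
  int rn = 0;

  for (int g = 0; g < par.N_b; ++g) {
    int b = P.breeder[g];
    if (b >= 0)
      for (int l = 0; l < N_LOCI; ++l) {
        sum[l] += P.gene[l][b];
        ssq[l] += P.gene[l][b] * P.gene[l][b];
      }
    for (size_t k = 0; k < P.subs[g].size(); ++k) {
      int s = P.subs[g][k];
      for (int l = 0; l < N_LOCI; ++l) {
        sum[l] += P.gene[l][s];
        ssq[l] += P.gene[l][s] * P.gene[l][s];
      }
      sum_disp += disp_D(P, par, s);
      sum_help += P.help[s];
      sum_T += task_T(P, s, (double) P.age[s]);
      sum_rank_help += dominance_R(P, par, s);
      if (b >= 0) {
        double x = P.gene[6][b], y = P.gene[6][s];
        rx += x; ry += y; rxx += x * x; rxy += x * y;
        ++rn;
      }
    }
  }
  for (size_t k = 0; k < P.floaters.size(); ++k) {
    int s = P.floaters[k];
    for (int l = 0; l < N_LOCI; ++l) {
      sum[l] += P.gene[l][s];
      ssq[l] += P.gene[l][s] * P.gene[l][s];
    }
    sum_disp += disp_D(P, par, s);
    sum_rank_float += dominance_R(P, par, s);
  }

  double gs_sum = 0.0, gs_ssq = 0.0;
  int nocc = 0;
  for (int g = 0; g < par.N_b; ++g) {
    if (P.breeder[g] < 0) continue;
    double N = 1.0 + (double) P.subs[g].size();
    gs_sum += N;
    gs_ssq += N * N;
    ++nocc;
  }

  int c = 0;
  row[c++] = (double) cycle;
  row[c++] = (double) ntot;
  row[c++] = (double) nb;
  row[c++] = (double) ns;
  row[c++] = (double) nf;
  for (int l = 0; l < N_LOCI; ++l) {
    if (ntot > 0) {
      double mn = sum[l] / ntot;
      double v = ssq[l] / ntot - mn * mn;
      row[c++] = mn;
      row[c++] = v > 0.0 ? std::sqrt(v) : 0.0;
    } else {
      row[c++] = NA_REAL;
      row[c++] = NA_REAL;
    }
  }
  row[c++] = (ns + nf) > 0 ? sum_disp / (ns + nf) : NA_REAL;
  row[c++] = ns > 0 ? sum_help / ns : NA_REAL;
  row[c++] = ns > 0 ? sum_T / ns : NA_REAL;
  if (nocc > 0) {
    double mn = gs_sum / nocc;
    double v = gs_ssq / nocc - mn * mn;
    row[c++] = mn;
    row[c++] = v > 0.0 ? std::sqrt(v) : 0.0;
  } else {
    row[c++] = NA_REAL;
    row[c++] = NA_REAL;
  }
  row[c++] = (double) nocc;
  int atr = t.atrisk_b + t.atrisk_s + t.atrisk_f;
  int srv = t.surv_b + t.surv_s + t.surv_f;
  row[c++] = atr > 0 ? (double) srv / atr : NA_REAL;
  row[c++] = t.atrisk_b > 0 ? (double) t.surv_b / t.atrisk_b : NA_REAL;
  row[c++] = t.atrisk_s > 0 ? (double) t.surv_s / t.atrisk_s : NA_REAL;
  row[c++] = t.atrisk_f > 0 ? (double) t.surv_f / t.atrisk_f : NA_REAL;
  if (ns > 0 && nf > 0 && sum_rank_float > 0.0) {
    row[c++] = (sum_rank_help / ns) / (sum_rank_float / nf);
  } else {
    row[c++] = NA_REAL;
  }
  if (rn >= 2) {
    double den = rn * rxx - rx * rx;
    row[c++] = den > 0.0 ? (rn * rxy - rx * ry) / den : NA_REAL;
  } else {
    row[c++] = NA_REAL;
  }
}

// ---- R interface ----------------------------------------------------------

static Params parse_params(List params) {
  Params p;
  p.y_h = as<double>(params["y_h"]);
  p.x_h = as<double>(params["x_h"]);
  p.x_n = as<double>(params["x_n"]);
  p.x_0 = as<double>(params["x_0"]);
  p.m = as<double>(params["m"]);
  p.f = as<double>(params["f"]);
  p.k_m = as<double>(params["k_m"]);
  p.k_h = as<double>(params["k_h"]);
  p.k_0 = as<double>(params["k_0"]);
  p.mu = as<double>(params["mu"]);
  p.sigma_mu = as<double>(params["sigma_mu"]);
  p.N_b = as<int>(params["N_b"]);
  p.benefit_mode = as<int>(params["benefit_mode_code"]);
  p.fecundity_mode = as<int>(params["fecundity_mode_code"]);
  p.dispersal_norm = as<int>(params["dispersal_norm_code"]);
  return p;
}

static Pop parse_state(List state, const Params &par) {
  Pop P;
  List ind = state["ind"];
  NumericVector alpha = ind["alpha"], beta = ind["beta"],
    beta_0 = ind["beta_0"], beta_R = ind["beta_R"], gamma_0 = ind["gamma_0"],
    gamma_R = ind["gamma_R"], neutral = ind["neutral"];
  IntegerVector age = ind["age"], task = ind["task"];
  int n = alpha.size();
  for (int l = 0; l < N_LOCI; ++l) P.gene[l].resize(n);
  P.help.resize(n);
  P.age.resize(n);
  P.task.resize(n);
  P.natal.assign(n, 0);
  for (int i = 0; i < n; ++i) {
    P.gene[0][i] = alpha[i];
    P.gene[1][i] = beta[i];
    P.gene[2][i] = beta_0[i];
    P.gene[3][i] = beta_R[i];
    P.gene[4][i] = gamma_0[i];
    P.gene[5][i] = gamma_R[i];
    P.gene[6][i] = neutral[i];
    P.help[i] = alpha[i] > 0.0 ? alpha[i] : 0.0;
    P.age[i] = age[i];
    P.task[i] = task[i];
  }
  IntegerVector breeder = state["breeder"];
  P.breeder.resize(par.N_b);
  for (int g = 0; g < par.N_b; ++g)
    P.breeder[g] = breeder[g] == NA_INTEGER ? -1 : breeder[g] - 1;
  List subs = state["subs"];
  P.subs.resize(par.N_b);
  for (int g = 0; g < par.N_b; ++g) {
    IntegerVector sg = subs[g];
    P.subs[g].resize(sg.size());
    for (int k = 0; k < sg.size(); ++k) P.subs[g][k] = sg[k] - 1;
  }
  IntegerVector fl = state["floaters"];
  P.floaters.resize(fl.size());
  for (int k = 0; k < fl.size(); ++k) P.floaters[k] = fl[k] - 1;
  NumericVector pd = state["prev_def"], pw = state["prev_work"];
  P.prev_def.assign(pd.begin(), pd.end());
  P.prev_work.assign(pw.begin(), pw.end());
  return P;
}

// Pack into canonical order: territory by territory (breeder, then
// subordinates in list order), then floaters in pool order.
static List pack_state(const Pop &P, const Params &par, int cycle) {
  int n = P.pop_size();
  NumericVector alpha(n), beta(n), beta_0(n), beta_R(n), gamma_0(n),
    gamma_R(n), neutral(n);
  IntegerVector age(n), task(n), role(n), group(n);
  IntegerVector breeder(par.N_b);
  List subs(par.N_b);
  IntegerVector floaters(P.floaters.size());
  int idx = 0;
  for (int g = 0; g < par.N_b; ++g) {
    int b = P.breeder[g];
    if (b >= 0) {
      alpha[idx] = P.gene[0][b]; beta[idx] = P.gene[1][b];
      beta_0[idx] = P.gene[2][b]; beta_R[idx] = P.gene[3][b];
      gamma_0[idx] = P.gene[4][b]; gamma_R[idx] = P.gene[5][b];
      neutral[idx] = P.gene[6][b];
      age[idx] = P.age[b]; task[idx] = P.task[b];
      role[idx] = 0; group[idx] = g + 1;
      breeder[g] = idx + 1;
      ++idx;
    } else {
      breeder[g] = NA_INTEGER;
    }
    IntegerVector sg(P.subs[g].size());
    for (size_t k = 0; k < P.subs[g].size(); ++k) {
      int s = P.subs[g][k];
      alpha[idx] = P.gene[0][s]; beta[idx] = P.gene[1][s];
      beta_0[idx] = P.gene[2][s]; beta_R[idx] = P.gene[3][s];
      gamma_0[idx] = P.gene[4][s]; gamma_R[idx] = P.gene[5][s];
      neutral[idx] = P.gene[6][s];
      age[idx] = P.age[s]; task[idx] = P.task[s];
      role[idx] = 1; group[idx] = g + 1;
      sg[k] = idx + 1;
      ++idx;
    }
    subs[g] = sg;
  }
  for (size_t k = 0; k < P.floaters.size(); ++k) {
    int s = P.floaters[k];
    alpha[idx] = P.gene[0][s]; beta[idx] = P.gene[1][s];
    beta_0[idx] = P.gene[2][s]; beta_R[idx] = P.gene[3][s];
    gamma_0[idx] = P.gene[4][s]; gamma_R[idx] = P.gene[5][s];
    neutral[idx] = P.gene[6][s];
    age[idx] = P.age[s]; task[idx] = P.task[s];
    role[idx] = 2; group[idx] = NA_INTEGER;
    floaters[k] = idx + 1;
    ++idx;
  }
  DataFrame ind = DataFrame::create(
    _["alpha"] = alpha, _["beta"] = beta, _["beta_0"] = beta_0,
    _["beta_R"] = beta_R, _["gamma_0"] = gamma_0, _["gamma_R"] = gamma_R,
    _["neutral"] = neutral, _["age"] = age, _["role"] = role,
    _["group"] = group, _["task"] = task);
  return List::create(
    _["ind"] = ind, _["breeder"] = breeder, _["subs"] = subs,
    _["floaters"] = floaters,
    _["prev_def"] = NumericVector(P.prev_def.begin(), P.prev_def.end()),
    _["prev_work"] = NumericVector(P.prev_work.begin(), P.prev_work.end()),
    _["cycle"] = cycle);
}

// [[Rcpp::export]]
List cpp_simulate(List state, List params, int n_cycles, int thin) {
  Params par = parse_params(params);
  Pop P = parse_state(state, par);
  int start = as<int>(state["cycle"]);
  int end = start + n_cycles;
  int extinct = NA_INTEGER;

  std::vector<double> rec;
  rec.reserve((size_t) (n_cycles / (thin > 0 ? thin : 1) + 2) * N_REC_COLS);
  double row[N_REC_COLS];
  int nrec = 0;

  for (int c = start + 1; c <= end; ++c) {
    Tally t;
    step1_reproduce(P, par);
    step2_dispersal(P, par);
    step3_help(P, par);
    step4_survival(P, par, t);
    step5_vacancies(P, par);
    if (P.pop_size() == 0) {
      extinct = c;
      summarize_row(P, par, t, c, row);
      rec.insert(rec.end(), row, row + N_REC_COLS);
      ++nrec;
      step6_age(P, par);
      break;
    }
    if ((thin > 0 && c % thin == 0) || c == end) {
      summarize_row(P, par, t, c, row);
      rec.insert(rec.end(), row, row + N_REC_COLS);
      ++nrec;
    }
    step6_age(P, par);
    if (c % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  int final_cycle = extinct == NA_INTEGER ? end : extinct;

  NumericMatrix records(nrec, N_REC_COLS);
  for (int i = 0; i < nrec; ++i)
    for (int j = 0; j < N_REC_COLS; ++j)
      records(i, j) = rec[(size_t) i * N_REC_COLS + j];

  return List::create(
    _["state"] = pack_state(P, par, final_cycle),
    _["records"] = records,
    _["extinct_cycle"] = extinct == NA_INTEGER ? R_NilValue
                                               : wrap(extinct));
}
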