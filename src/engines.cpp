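// Simulation engines for Fisher's geometric model under the two
// experimental demographies:
//  - mutation accumulation (MA): single-cell bottleneck every `cycle_gens`
//    generations of doubling growth, selection during growth;
//  - fitness recovery: constant-size Wright-Fisher dynamics on genotype
//    classes at large Ne.
// All randomness goes through R's RNG so set.seed() governs replay.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Kimura's fixation probability (1 - e^{-2s}) / (1 - e^{-2 Ne s}),
// continuous at s = 0 (limit 1/Ne), evaluated in log space for strongly
// deleterious mutations so it underflows to 0 instead of overflowing.
// [[Rcpp::export]]
double survival_probability_cpp(double s, double Ne) {
  if (std::fabs(s) < 1e-12) return 1.0 / Ne;
  double a = -2.0 * s;       // exponent of the numerator's expm1
  double b = -2.0 * Ne * s;  // exponent of the denominator's expm1
  if (s > 0) {
    // a, b < 0: both expm1 in (-1, 0), no overflow
    return std::expm1(a) / std::expm1(b);
  }
  // s < 0: a, b > 0 and b = Ne * a may overflow
  if (b > 700.0) {
    double log_num = (a > 700.0) ? a : std::log(std::expm1(a));
    double lp = log_num - b;  // log expm1(b) ~ b for b > 700
    return (lp < -745.0) ? 0.0 : std::exp(lp);
  }
  return std::expm1(a) / std::expm1(b);
}

static inline double psurv(double s, double Ne) {
  return survival_probability_cpp(s, Ne);
}

// ---------------------------------------------------------------------------
// Fast MA engine: follow the bottlenecked lineage only. Candidate mutations
// arise Poisson(U * cycle_gens) per cycle; with selection on, each candidate
// is retained with probability min(1, Ne * psurv(s, Ne)) -- the drift filter
// (neutral candidates are always retained since Ne * (1/Ne) = 1); with
// selection off every candidate is retained.
// ---------------------------------------------------------------------------

struct Lineage {
  std::vector<double> x;
  double logw;
  int n_mut;
};

static void fast_cycle(Lineage &lin, int n, double U, double sigma,
                       int cycle_gens, double Ne, bool selection_on) {
  int k = (int) R::rpois(U * cycle_gens);
  std::vector<double> d(n);
  for (int j = 0; j < k; ++j) {
    double dot = 0.0, ss = 0.0;
    for (int i = 0; i < n; ++i) {
      d[i] = R::rnorm(0.0, sigma);
      dot += lin.x[i] * d[i];
      ss += d[i] * d[i];
    }
    double s = -2.0 * dot - ss;
    bool accept = true;
    if (selection_on) {
      double p = Ne * psurv(s, Ne);
      if (p < 1.0) accept = (R::unif_rand() < p);
    }
    if (accept) {
      for (int i = 0; i < n; ++i) lin.x[i] += d[i];
      lin.logw += s;
      lin.n_mut += 1;
    }
  }
}

// [[Rcpp::export]]
List cpp_ma_fast(int n, double U, double sigma, int n_lines, int n_cycles,
                 int cycle_gens, double Ne, bool selection_on,
                 IntegerVector record_cycles) {
  int K = record_cycles.size();
  NumericMatrix fitness(n_lines, K);
  IntegerMatrix n_mut(n_lines, K);
  for (int l = 0; l < n_lines; ++l) {
    Lineage lin{std::vector<double>(n, 0.0), 0.0, 0};
    int rec = 0;
    for (int c = 1; c <= n_cycles; ++c) {
      fast_cycle(lin, n, U, sigma, cycle_gens, Ne, selection_on);
      if (rec < K && record_cycles[rec] == c) {
        fitness(l, rec) = std::exp(lin.logw);
        n_mut(l, rec) = lin.n_mut;
        ++rec;
      }
    }
  }
  return List::create(_["fitness"] = fitness, _["n_mutations"] = n_mut);
}

// One fast-engine cycle from an explicit founder phenotype.
// [[Rcpp::export]]
List cpp_ma_cycle_fast(NumericVector x0, double U, double sigma,
                       int cycle_gens, double Ne, bool selection_on) {
  int n = x0.size();
  Lineage lin{std::vector<double>(x0.begin(), x0.end()), 0.0, 0};
  double lw0 = 0.0;
  for (int i = 0; i < n; ++i) lw0 -= x0[i] * x0[i];
  lin.logw = lw0;
  fast_cycle(lin, n, U, sigma, cycle_gens, Ne, selection_on);
  return List::create(_["x"] = NumericVector(lin.x.begin(), lin.x.end()),
                      _["n_mutations"] = lin.n_mut,
                      _["log_fitness"] = lin.logw);
}

// ---------------------------------------------------------------------------
// Exact MA engine: genotype-class representation of the doubling growth
// phase. Each generation the population size doubles; offspring are
// assigned to classes by multinomial sampling with weights count * fitness
// (selection on) or count (selection off); new mutations arise
// Poisson(U * N_t), each founding a size-1 class. At cycle end one cell is
// sampled uniformly as the next founder. Exponential cost in cycle_gens:
// meant for reduced designs (e.g. cycle_gens = 10) used to validate the
// fast engine.
// ---------------------------------------------------------------------------

struct ClassPop {
  std::vector<double> xs;      // phenotypes, stride n
  std::vector<double> counts;
  std::vector<double> logw;
  std::vector<int> n_mut;
  int n;

  size_t size() const { return counts.size(); }
  void push(const double *x, double count, double lw, int nm) {
    xs.insert(xs.end(), x, x + n);
    counts.push_back(count);
    logw.push_back(lw);
    n_mut.push_back(nm);
  }
  void compact() {
    size_t j = 0;
    for (size_t i = 0; i < counts.size(); ++i) {
      if (counts[i] > 0) {
        if (i != j) {
          std::copy(xs.begin() + i * n, xs.begin() + (i + 1) * n,
                    xs.begin() + j * n);
          counts[j] = counts[i];
          logw[j] = logw[i];
          n_mut[j] = n_mut[i];
        }
        ++j;
      }
    }
    xs.resize(j * n);
    counts.resize(j);
    logw.resize(j);
    n_mut.resize(j);
  }
};

// Multinomial resampling of `total` offspring with weights w (conditional
// binomial method); overwrites pop.counts.
static void multinomial_resample(ClassPop &pop, double total,
                                 const std::vector<double> &w) {
  double wrem = 0.0;
  for (double wi : w) wrem += wi;
  double remaining = total;
  size_t K = pop.size();
  for (size_t i = 0; i < K; ++i) {
    if (remaining <= 0 || wrem <= 0) { pop.counts[i] = 0; continue; }
    double p = w[i] / wrem;
    double c = (i == K - 1) ? remaining
                            : R::rbinom(remaining, p > 1.0 ? 1.0 : p);
    pop.counts[i] = c;
    remaining -= c;
    wrem -= w[i];
  }
}

// Per-class mutation events: each individual mutates Poisson(U) times; each
// event moves one cell into a new size-1 class displaced by a fresh draw.
static void mutate_classes(ClassPop &pop, double U, double sigma) {
  size_t K = pop.size();  // new classes appended after the loop bound
  std::vector<double> d(pop.n);
  for (size_t i = 0; i < K; ++i) {
    if (pop.counts[i] <= 0) continue;
    int m = (int) R::rpois(U * pop.counts[i]);
    if (m > pop.counts[i]) m = (int) pop.counts[i];
    for (int e = 0; e < m; ++e) {
      const double *xp = &pop.xs[i * pop.n];
      double dot = 0.0, ss = 0.0;
      for (int t = 0; t < pop.n; ++t) {
        d[t] = R::rnorm(0.0, sigma);
        dot += xp[t] * d[t];
        ss += d[t] * d[t];
      }
      double s = -2.0 * dot - ss;
      std::vector<double> xnew(pop.n);
      for (int t = 0; t < pop.n; ++t) xnew[t] = xp[t] + d[t];
      pop.counts[i] -= 1;
      pop.push(xnew.data(), 1.0, pop.logw[i] + s, pop.n_mut[i] + 1);
    }
  }
  pop.compact();
}

// Sample one individual uniformly (proportional to class counts).
static size_t sample_individual(const ClassPop &pop) {
  double tot = 0.0;
  for (double c : pop.counts) tot += c;
  double u = R::unif_rand() * tot;
  double acc = 0.0;
  for (size_t i = 0; i < pop.size(); ++i) {
    acc += pop.counts[i];
    if (u <= acc) return i;
  }
  return pop.size() - 1;
}

static void exact_cycle(Lineage &lin, int n, double U, double sigma,
                        int cycle_gens, bool selection_on) {
  ClassPop pop;
  pop.n = n;
  pop.push(lin.x.data(), 1.0, lin.logw, lin.n_mut);
  double Ntot = 1.0;
  std::vector<double> w;
  for (int g = 0; g < cycle_gens; ++g) {
    Ntot *= 2.0;
    w.resize(pop.size());
    for (size_t i = 0; i < pop.size(); ++i)
      w[i] = pop.counts[i] * (selection_on ? std::exp(pop.logw[i]) : 1.0);
    multinomial_resample(pop, Ntot, w);
    pop.compact();
    mutate_classes(pop, U, sigma);
  }
  size_t j = sample_individual(pop);
  lin.x.assign(pop.xs.begin() + j * n, pop.xs.begin() + (j + 1) * n);
  lin.logw = pop.logw[j];
  lin.n_mut = pop.n_mut[j];
}

// [[Rcpp::export]]
List cpp_ma_exact(int n, double U, double sigma, int n_lines, int n_cycles,
                  int cycle_gens, bool selection_on,
                  IntegerVector record_cycles) {
  int K = record_cycles.size();
  NumericMatrix fitness(n_lines, K);
  IntegerMatrix n_mut(n_lines, K);
  for (int l = 0; l < n_lines; ++l) {
    Lineage lin{std::vector<double>(n, 0.0), 0.0, 0};
    int rec = 0;
    for (int c = 1; c <= n_cycles; ++c) {
      exact_cycle(lin, n, U, sigma, cycle_gens, selection_on);
      if (rec < K && record_cycles[rec] == c) {
        fitness(l, rec) = std::exp(lin.logw);
        n_mut(l, rec) = lin.n_mut;
        ++rec;
      }
    }
  }
  return List::create(_["fitness"] = fitness, _["n_mutations"] = n_mut);
}

// [[Rcpp::export]]
List cpp_ma_cycle_exact(NumericVector x0, double U, double sigma,
                        int cycle_gens, bool selection_on) {
  int n = x0.size();
  Lineage lin{std::vector<double>(x0.begin(), x0.end()), 0.0, 0};
  double lw0 = 0.0;
  for (int i = 0; i < n; ++i) lw0 -= x0[i] * x0[i];
  lin.logw = lw0;
  exact_cycle(lin, n, U, sigma, cycle_gens, selection_on);
  return List::create(_["x"] = NumericVector(lin.x.begin(), lin.x.end()),
                      _["n_mutations"] = lin.n_mut,
                      _["log_fitness"] = lin.logw);
}

// ---------------------------------------------------------------------------
// Exact recovery engine: constant-size Wright-Fisher on genotype classes.
// Each generation offspring are multinomially assigned with weights
// count * fitness, then Poisson mutation seeds new size-1 classes. Records
// population mean fitness at the requested generations.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_recovery_exact(NumericVector x0, double U, double sigma,
                                 double Ne, int total_gens,
                                 IntegerVector checkpoints) {
  int n = x0.size();
  ClassPop pop;
  pop.n = n;
  double lw0 = 0.0;
  for (int i = 0; i < n; ++i) lw0 -= x0[i] * x0[i];
  {
    std::vector<double> x(x0.begin(), x0.end());
    pop.push(x.data(), Ne, lw0, 0);
  }
  int K = checkpoints.size();
  NumericVector meanw(K);
  int rec = 0;
  std::vector<double> w;
  for (int g = 1; g <= total_gens; ++g) {
    w.resize(pop.size());
    for (size_t i = 0; i < pop.size(); ++i)
      w[i] = pop.counts[i] * std::exp(pop.logw[i]);
    multinomial_resample(pop, Ne, w);
    pop.compact();
    mutate_classes(pop, U, sigma);
    if (rec < K && checkpoints[rec] == g) {
      double acc = 0.0;
      for (size_t i = 0; i < pop.size(); ++i)
        acc += pop.counts[i] * std::exp(pop.logw[i]);
      meanw[rec] = acc / Ne;
      ++rec;
    }
  }
  return meanw;
}

// ---------------------------------------------------------------------------
// Fast recovery engine: deterministic class frequencies plus stochastic
// establishment. At Ne = 3e5 drift only matters while a lineage is rare, so
// each generation a pilot sample of candidate mutations estimates the
// establishment rate U * Ne * mean(psurv(s, Ne)); Poisson-many establishers
// are drawn, assigned to pilot candidates proportional to psurv, and seeded
// at frequency 1/(Ne * psurv) (the expected size of a lineage conditioned on
// escaping drift), after which selection acts deterministically. Candidates
// that cannot escape drift (s <= 0 at large Ne) enter deterministically as
// frequency-weighted classes carrying the segregating deleterious load.
// Class fitness is cached at creation; duplicated establishers of the same
// pilot candidate are merged into one class. Validated against the exact
// engine in the test suite.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_recovery_fast(NumericVector x0, double U, double sigma,
                                double Ne, int total_gens,
                                IntegerVector checkpoints,
                                int n_pilot = 32, int n_load = 8,
                                double seed_freq_cap = 1e-3) {
  int n = x0.size();
  std::vector<double> xs(x0.begin(), x0.end());
  std::vector<double> logw(1), w(1), freq(1, 1.0);
  double lw0 = 0.0;
  for (int i = 0; i < n; ++i) lw0 -= x0[i] * x0[i];
  logw[0] = lw0;
  w[0] = std::exp(lw0);

  int K = checkpoints.size();
  NumericVector meanw(K);
  int rec = 0;

  std::vector<double> cum, pd(n * n_pilot), ps(n_pilot), pq(n_pilot), pcum(n_pilot);
  std::vector<int> ppar(n_pilot), pmult(n_pilot);
  // below any establishment seed (>= 1/Ne) and any load seed (U / n_load
  // with U >= 1e-4 in practice); decayed classes are dropped quickly
  const double prune = 0.5 / Ne;

  std::vector<double> xbuf;
  auto add_class = [&](size_t parent, const double *d, double s, double f0) {
    if (f0 > freq[parent]) f0 = freq[parent];
    if (f0 <= 0) return;
    freq[parent] -= f0;
    // copy before push_back: growing xs invalidates pointers into it
    xbuf.assign(xs.begin() + parent * n, xs.begin() + (parent + 1) * n);
    for (int t = 0; t < n; ++t) xs.push_back(xbuf[t] + d[t]);
    double lw = logw[parent] + s;
    logw.push_back(lw);
    w.push_back(std::exp(lw));
    freq.push_back(f0);
  };

  for (int g = 1; g <= total_gens; ++g) {
    size_t Kc = freq.size();
    // deterministic selection step on frequencies
    double wbar = 0.0;
    for (size_t i = 0; i < Kc; ++i) wbar += freq[i] * w[i];
    for (size_t i = 0; i < Kc; ++i) freq[i] *= w[i] / wbar;
    // prune effectively-extinct classes, renormalize
    {
      size_t j = 0;
      double tot = 0.0;
      for (size_t i = 0; i < Kc; ++i) {
        if (freq[i] > prune) {
          if (i != j) {
            std::copy(xs.begin() + i * n, xs.begin() + (i + 1) * n,
                      xs.begin() + j * n);
            freq[j] = freq[i];
            logw[j] = logw[i];
            w[j] = w[i];
          }
          tot += freq[j];
          ++j;
        }
      }
      xs.resize(j * n);
      freq.resize(j);
      logw.resize(j);
      w.resize(j);
      for (size_t i = 0; i < j; ++i) freq[i] /= tot;
      Kc = j;
    }

    if (U > 0) {
      // pilot candidates: random parent (by frequency), random displacement
      cum.resize(Kc);
      double acc = 0.0;
      for (size_t i = 0; i < Kc; ++i) { acc += freq[i]; cum[i] = acc; }
      double qsum = 0.0;
      for (int p = 0; p < n_pilot; ++p) {
        double u = R::unif_rand() * acc;
        size_t j = std::lower_bound(cum.begin(), cum.end(), u) - cum.begin();
        if (j >= Kc) j = Kc - 1;
        ppar[p] = (int) j;
        const double *xp = &xs[j * n];
        double dot = 0.0, ss = 0.0;
        for (int t = 0; t < n; ++t) {
          double dt = R::rnorm(0.0, sigma);
          pd[p * n + t] = dt;
          dot += xp[t] * dt;
          ss += dt * dt;
        }
        ps[p] = -2.0 * dot - ss;
        pq[p] = psurv(ps[p], Ne);
        qsum += pq[p];
        pcum[p] = qsum;
      }
      // deterministic deleterious load from the first n_load pilots
      for (int p = 0; p < n_load; ++p) {
        if (ps[p] > 0) continue;
        add_class((size_t) ppar[p], &pd[p * n], ps[p], U / n_load);
      }
      // stochastic establishment of drift-escaping mutations
      double qbar = qsum / n_pilot;
      int m = (qbar > 0) ? (int) R::rpois(U * Ne * qbar) : 0;
      if (m > 0) {
        std::fill(pmult.begin(), pmult.end(), 0);
        for (int e = 0; e < m; ++e) {
          double u = R::unif_rand() * qsum;
          int p = (int) (std::lower_bound(pcum.begin(), pcum.end(), u) -
                         pcum.begin());
          if (p >= n_pilot) p = n_pilot - 1;
          pmult[p] += 1;
        }
        for (int p = 0; p < n_pilot; ++p) {
          if (pmult[p] == 0) continue;
          double f0 = pmult[p] / (Ne * pq[p]);
          if (f0 > seed_freq_cap * pmult[p]) f0 = seed_freq_cap * pmult[p];
          add_class((size_t) ppar[p], &pd[p * n], ps[p], f0);
        }
      }
    }

    if (rec < K && checkpoints[rec] == g) {
      double acc = 0.0, tot = 0.0;
      for (size_t i = 0; i < freq.size(); ++i) {
        acc += freq[i] * w[i];
        tot += freq[i];
      }
      meanw[rec] = acc / tot;
      ++rec;
    }
  }
  return meanw;
}
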