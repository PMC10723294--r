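// Two-locus diploid Wright-Fisher core.
//
// Haplotype codes (shared with the R side): 0 = AB, 1 = aB, 2 = Ab, 3 = ab.
// B-carrying haplotypes are codes 0 and 1; A-carrying are 0 and 2.
// The 10 unordered genotypes are the pairs (i <= j) in the canonical order
// below.  The population state is the vector of genotype counts; one
// generation is a single multinomial draw of N_next offspring from the
// exact offspring distribution (each gamete comes from an independently
// chosen, fitness-weighted parent, so the offspring genotype is the
// unordered pair of two iid draws from the marginal gamete distribution).

#include <Rcpp.h>
using namespace Rcpp;

static const int GI[10] = {0, 0, 0, 0, 1, 1, 1, 2, 2, 3};
static const int GJ[10] = {0, 1, 2, 3, 1, 2, 3, 2, 3, 3};

static inline bool carries_B(int h) { return h < 2; }
static inline bool carries_A(int h) { return h % 2 == 0; }
static inline int hap_of(bool A, bool B) { return (B ? 0 : 2) + (A ? 0 : 1); }

// Gamete distribution contribution for one choice of template strand t
// (weight w): the A-locus allele always comes from the template; with
// probability G the B-locus allele is replaced by the homolog's.
static void add_template(double w, int t, int o, double G, double* out) {
  bool A = carries_A(t);
  out[hap_of(A, carries_B(t))] += w * (1.0 - G);
  out[hap_of(A, carries_B(o))] += w * G;
}

static void gamete_table(double G, double gam[10][4]) {
  for (int g = 0; g < 10; g++) {
    for (int a = 0; a < 4; a++) gam[g][a] = 0.0;
    add_template(0.5, GI[g], GJ[g], G, gam[g]);
    add_template(0.5, GJ[g], GI[g], G, gam[g]);
  }
}

static void fitness_table(double s_prime, double h, double w[10]) {
  double by_nB[3] = {1.0, 1.0 + h * s_prime, 1.0 + s_prime};
  for (int g = 0; g < 10; g++)
    w[g] = by_nB[(carries_B(GI[g]) ? 1 : 0) + (carries_B(GJ[g]) ? 1 : 0)];
}

// Fitness-weighted marginal gamete distribution q[4] for genotype counts n.
static void gamete_marginal(const double* n, const double w[10],
                            const double gam[10][4], double q[4]) {
  double W = 0.0;
  for (int a = 0; a < 4; a++) q[a] = 0.0;
  for (int g = 0; g < 10; g++) {
    if (n[g] <= 0) continue;
    double wg = n[g] * w[g];
    W += wg;
    for (int a = 0; a < 4; a++) q[a] += wg * gam[g][a];
  }
  if (W <= 0) stop("all fitness weights are zero");
  for (int a = 0; a < 4; a++) q[a] /= W;
}

// Exact offspring genotype distribution for the current state; exported for
// cross-checking against the pure-R reference implementation.
// [[Rcpp::export]]
NumericVector cpp_offspring_probs(NumericVector counts, double s_prime,
                                  double h, double G) {
  if (counts.size() != 10) stop("counts must have length 10");
  double gam[10][4], w[10], q[4];
  gamete_table(G, gam);
  fitness_table(s_prime, h, w);
  gamete_marginal(REAL(counts), w, gam, q);
  NumericVector p(10);
  for (int g = 0; g < 10; g++)
    p[g] = q[GI[g]] * q[GJ[g]] * (GI[g] == GJ[g] ? 1.0 : 2.0);
  return p;
}

// One forward replicate.  `sizes` gives the diploid size trajectory from
// the onset generation (sizes[0], the initial population) down to the
// present (sizes[T]); step k draws sizes[k] offspring.  With `condition`
// the state and clock are reset to the onset whenever the beneficial
// allele is lost (the RNG stream continues).  Terminates at fixation of B
// or on reaching the present.
// [[Rcpp::export]]
List cpp_run_replicate(IntegerVector sizes, double s_prime, double h,
                       double G, bool condition, double restart_cap,
                       bool record_trajectory = false) {
  int T = sizes.size() - 1;
  if (T < 1) stop("size trajectory must span at least one generation");
  if (G < 0 || G >= 1) stop("G must be in [0, 1)");
  double gam[10][4], w[10], q[4], p[10];
  gamete_table(G, gam);
  fitness_table(s_prime, h, w);

  double n[10];
  int counts[10];
  const int IDX_ABab = 3, IDX_abab = 9;  // (AB,ab) and (ab,ab)
  auto reset = [&](void) {
    for (int g = 0; g < 10; g++) n[g] = 0.0;
    n[IDX_ABab] = 1.0;
    n[IDX_abab] = sizes[0] - 1.0;
  };
  if (sizes[0] < 2) stop("initial population size must be >= 2");
  reset();

  // per-generation haplotype counts of the returned attempt (row 0 =
  // onset state); truncated to the attempt's length on return
  NumericMatrix traj;
  auto log_row = [&](int row) {
    if (!record_trajectory) return;
    for (int a = 0; a < 4; a++) traj(row, a) = 0.0;
    for (int g = 0; g < 10; g++) {
      traj(row, GI[g]) += n[g];
      traj(row, GJ[g]) += n[g];
    }
  };
  if (record_trajectory) {
    traj = NumericMatrix(T + 1, 4);
    log_row(0);
  }

  double restarts = 0.0;
  bool fixed = false, lost = false;
  int k = 0;  // steps completed in the current attempt
  while (k < T) {
    int Nn = sizes[k + 1];
    gamete_marginal(n, w, gam, q);
    for (int g = 0; g < 10; g++)
      p[g] = q[GI[g]] * q[GJ[g]] * (GI[g] == GJ[g] ? 1.0 : 2.0);
    rmultinom(Nn, p, 10, counts);
    for (int g = 0; g < 10; g++) n[g] = counts[g];
    k++;
    log_row(k);
    double b = 0.0;
    for (int g = 0; g < 10; g++)
      b += n[g] * ((carries_B(GI[g]) ? 1 : 0) + (carries_B(GJ[g]) ? 1 : 0));
    if (b == 0.0) {
      if (!condition) { lost = true; break; }
      restarts += 1.0;
      if (restarts > restart_cap)
        stop("restart cap (%g) exceeded at s'=%g h=%g G=%g N0=%d",
             restart_cap, s_prime, h, G, (int)sizes[0]);
      reset();
      k = 0;
      log_row(0);
      continue;
    }
    if (b == 2.0 * Nn) { fixed = true; break; }
  }

  double hap[4] = {0, 0, 0, 0};
  double Nfin = 0.0;
  for (int g = 0; g < 10; g++) {
    hap[GI[g]] += n[g];
    hap[GJ[g]] += n[g];
    Nfin += n[g];
  }
  double bcount = hap[0] + hap[1];
  List out = List::create(
      _["fixed"] = fixed, _["lost"] = lost, _["gens_elapsed"] = k,
      _["restarts"] = restarts, _["N_final"] = Nfin,
      _["pop_counts"] = NumericVector::create(hap[0], hap[1], hap[2], hap[3]),
      _["p_f"] = bcount / (2.0 * Nfin));
  if (record_trajectory)
    out["trajectory"] = traj(Range(0, k), Range(0, 3));
  return out;
}
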