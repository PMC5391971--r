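// Core samplers and forward simulator. All randomness goes through R's RNG
// (unif_rand / norm_rand / R::r*), so set.seed() on the R side makes every
// exported routine deterministic.
#include <RcppArmadillo.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// truncated normal
// ---------------------------------------------------------------------------

// One-sided Robert (1995) exponential-rejection draw from N(0,1) | x in (a, b),
// used when a is deep in the upper tail where inverse-CDF loses precision.
static double rtail_upper(double a, double b) {
  double alpha = 0.5 * (a + std::sqrt(a * a + 4.0));
  for (int it = 0; it < 100000; ++it) {
    double z = a - std::log(unif_rand()) / alpha;
    double d = z - alpha;
    if (unif_rand() <= std::exp(-0.5 * d * d) && z < b) return z;
  }
  return a; // unreachable in practice
}

// N(0,1) truncated to (a, b); a may be -Inf, b may be +Inf, a < b.
static double rtnorm_std(double a, double b) {
  const double TAIL = 6.0;
  if (a > TAIL) return rtail_upper(a, b);
  if (b < -TAIL) return -rtail_upper(-b, -a);
  double Fa = R_finite(a) ? R::pnorm(a, 0.0, 1.0, 1, 0) : 0.0;
  double Fb = R_finite(b) ? R::pnorm(b, 0.0, 1.0, 1, 0) : 1.0;
  if (Fb - Fa > 1e-12) {
    double u = Fa + unif_rand() * (Fb - Fa);
    double x = R::qnorm(u, 0.0, 1.0, 1, 0);
    if (x < a) x = a;
    if (x > b) x = b;
    return x;
  }
  // interval mass too small for inverse CDF: fall back to tail rejection
  if (a >= 0.0) return rtail_upper(a, b);
  return -rtail_upper(-b, -a);
}

static double rtnorm1(double mean, double sd, double lower, double upper) {
  double a = R_finite(lower) ? (lower - mean) / sd : R_NegInf;
  double b = R_finite(upper) ? (upper - mean) / sd : R_PosInf;
  return mean + sd * rtnorm_std(a, b);
}

// [[Rcpp::export]]
NumericVector cpp_rtnorm(int n, double mean, double sd, double lower, double upper) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rtnorm1(mean, sd, lower, upper);
  return out;
}

// ---------------------------------------------------------------------------
// Wishart / inverse-Wishart (2x2, Bartlett) and the conditional sampler for
// a residual covariance with the (2,2) element fixed at 1
// ---------------------------------------------------------------------------

// W ~ Wishart_2(V, df) via Bartlett decomposition; V must be PD, df > 1.
static arma::mat22 rwish2(const arma::mat22& V, double df) {
  arma::mat22 L = arma::chol(arma::mat(V), "lower");
  double a11 = std::sqrt(R::rchisq(df));
  double a21 = norm_rand();
  double a22 = std::sqrt(R::rchisq(df - 1.0));
  arma::mat22 A;
  A(0, 0) = a11; A(0, 1) = 0.0; A(1, 0) = a21; A(1, 1) = a22;
  arma::mat22 LA = L * A;
  return LA * LA.t();
}

// G ~ IW_2(V, df): G = W^{-1}, W ~ Wishart_2(V, df).
static arma::mat22 riw2_draw(const arma::mat22& V, double df) {
  arma::mat22 W = rwish2(V, df);
  double det = W(0, 0) * W(1, 1) - W(0, 1) * W(1, 0);
  arma::mat22 G;
  G(0, 0) = W(1, 1) / det; G(1, 1) = W(0, 0) / det;
  G(0, 1) = -W(0, 1) / det; G(1, 0) = G(0, 1);
  return G;
}

// 1-dimensional inverse Wishart: 1 / (s * chisq(df)), s = Wishart scale.
static double riw1_draw(double s, double df) {
  return 1.0 / (s * R::rchisq(df));
}

// Conditional inverse-Wishart draw of a 2x2 residual covariance given its
// (2,2) element fixed at 1 (Korsgaard-type algorithm). V is the Wishart scale
// of the corresponding unconditional IW_2(V, df).
static arma::mat22 korsgaard_draw(const arma::mat22& V, double df) {
  double V11 = V(0, 0), V12 = V(0, 1), V22 = V(1, 1);
  double x1 = V11 * R::rchisq(df);
  double V221 = V22 - V12 * V12 / V11;
  double x2 = R::rnorm(V12 / V11, std::sqrt(V221 / x1));
  arma::mat22 Re;
  Re(0, 0) = 1.0 / x1 + x2 * x2;
  Re(0, 1) = -x2; Re(1, 0) = -x2;
  Re(1, 1) = 1.0;
  return Re;
}

// [[Rcpp::export]]
NumericMatrix cpp_riw2(NumericMatrix scale, double df, int ndraws) {
  arma::mat22 V;
  V(0, 0) = scale(0, 0); V(0, 1) = scale(0, 1);
  V(1, 0) = scale(1, 0); V(1, 1) = scale(1, 1);
  NumericMatrix out(ndraws, 3);
  for (int i = 0; i < ndraws; ++i) {
    arma::mat22 G = riw2_draw(V, df);
    out(i, 0) = G(0, 0); out(i, 1) = G(0, 1); out(i, 2) = G(1, 1);
  }
  colnames(out) = CharacterVector::create("v11", "v12", "v22");
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_korsgaard(NumericMatrix scale, double df, int ndraws) {
  arma::mat22 V;
  V(0, 0) = scale(0, 0); V(0, 1) = scale(0, 1);
  V(1, 0) = scale(1, 0); V(1, 1) = scale(1, 1);
  NumericMatrix out(ndraws, 2);
  for (int i = 0; i < ndraws; ++i) {
    arma::mat22 Re = korsgaard_draw(V, df);
    out(i, 0) = Re(0, 0); out(i, 1) = Re(0, 1);
  }
  colnames(out) = CharacterVector::create("t11", "t12");
  return out;
}

// ---------------------------------------------------------------------------
// SNP-pair inclusion Bayes factor (slab integrated out)
// ---------------------------------------------------------------------------
//
// With the SNP's contribution added back into residuals e*, and
// v = (z'e*_1, z'e*_2)', b = Re^{-1} v, Omega = (z'z) Re^{-1} + G0^{-1},
// the marginal-likelihood ratio slab/spike is
//   BF = |G0|^{-1/2} |Omega|^{-1/2} exp( b' Omega^{-1} b / 2 ),
// and (g1, g2) | delta = 1 ~ N(Omega^{-1} b, Omega^{-1}).

static double log_bf_biv(double czz, double v1, double v2,
                         const arma::mat22& G0, const arma::mat22& Re,
                         double* mu1, double* mu2,
                         double* Om11, double* Om12, double* Om22) {
  double detRe = Re(0, 0) * Re(1, 1) - Re(0, 1) * Re(0, 1);
  double w11 = Re(1, 1) / detRe, w22 = Re(0, 0) / detRe, w12 = -Re(0, 1) / detRe;
  double detG = G0(0, 0) * G0(1, 1) - G0(0, 1) * G0(0, 1);
  double gi11 = G0(1, 1) / detG, gi22 = G0(0, 0) / detG, gi12 = -G0(0, 1) / detG;
  double b1 = w11 * v1 + w12 * v2;
  double b2 = w12 * v1 + w22 * v2;
  double o11 = czz * w11 + gi11;
  double o12 = czz * w12 + gi12;
  double o22 = czz * w22 + gi22;
  double detO = o11 * o22 - o12 * o12;
  double quad = (o22 * b1 * b1 - 2.0 * o12 * b1 * b2 + o11 * b2 * b2) / detO;
  if (mu1) {
    *mu1 = (o22 * b1 - o12 * b2) / detO;
    *mu2 = (o11 * b2 - o12 * b1) / detO;
    *Om11 = o11; *Om12 = o12; *Om22 = o22;
  }
  return -0.5 * (std::log(detG) + std::log(detO)) + 0.5 * quad;
}

static double log_bf_uni(double czz, double v, double sg2, double se2,
                         double* mu, double* om) {
  double b = v / se2;
  double o = czz / se2 + 1.0 / sg2;
  if (mu) { *mu = b / o; *om = o; }
  return -0.5 * (std::log(sg2) + std::log(o)) + 0.5 * b * b / o;
}

// [[Rcpp::export]]
double cpp_snp_log_bf(double czz, double v1, double v2,
                      NumericMatrix G0, NumericMatrix Re) {
  arma::mat22 G, R;
  G(0, 0) = G0(0, 0); G(0, 1) = G0(0, 1); G(1, 0) = G0(1, 0); G(1, 1) = G0(1, 1);
  R(0, 0) = Re(0, 0); R(0, 1) = Re(0, 1); R(1, 0) = Re(1, 0); R(1, 1) = Re(1, 1);
  return log_bf_biv(czz, v1, v2, G, R, nullptr, nullptr, nullptr, nullptr, nullptr);
}

// [[Rcpp::export]]
double cpp_snp_log_bf_single(double czz, double v, double sg2, double se2) {
  return log_bf_uni(czz, v, sg2, se2, nullptr, nullptr);
}

// ---------------------------------------------------------------------------
// forward simulator: meiosis with Haldane recombination + allele-flip mutation
// ---------------------------------------------------------------------------
//
// Haplotypes are stored as an L x (2N) integer matrix of 0/1 allele states;
// individual i owns columns 2i and 2i+1. rec[l] is the recombination fraction
// between locus l-1 and l (0.5 at chromosome starts, ignored at l = 0).

static void make_gamete(const int* h0, const int* h1, int L,
                        const double* rec, double mu, int* out,
                        std::vector<int>& idx) {
  int cur = (unif_rand() < 0.5) ? 0 : 1;
  const int* H[2] = { h0, h1 };
  for (int l = 0; l < L; ++l) {
    if (l > 0 && rec[l] > 0.0 && unif_rand() < rec[l]) cur ^= 1;
    out[l] = H[cur][l];
  }
  if (mu > 0.0) {
    int k = (int) R::rbinom((double) L, mu);
    if (k > 0) {
      // k distinct positions via partial Fisher-Yates, undone afterwards
      std::vector<int> swaps(k);
      for (int j = 0; j < k; ++j) {
        int r = j + (int) (unif_rand() * (L - j));
        if (r >= L) r = L - 1;
        swaps[j] = r;
        std::swap(idx[j], idx[r]);
        out[idx[j]] ^= 1;
      }
      for (int j = k - 1; j >= 0; --j) std::swap(idx[j], idx[swaps[j]]);
    }
  }
}

static void rand_perm(std::vector<int>& v) {
  for (int i = (int) v.size() - 1; i > 0; --i) {
    int j = (int) (unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(v[i], v[j]);
  }
}

// Historical random-mating population: n_ind individuals (first half male),
// all loci start monomorphic (allele 0); each generation pairs the sexes at
// random, one male + one female offspring per pair. Returns L x (2 n_ind).
// [[Rcpp::export]]
IntegerMatrix cpp_sim_history(int n_ind, int n_gen, NumericVector rec, double mu) {
  if (n_ind < 2 || n_ind % 2 != 0) stop("historical population size must be even and >= 2");
  if (n_gen < 0) stop("number of historical generations must be >= 0");
  int L = rec.size();
  int nmate = n_ind / 2;
  std::vector<int> A((size_t) L * 2 * n_ind, 0), B((size_t) L * 2 * n_ind, 0);
  std::vector<int> idx(L);
  for (int l = 0; l < L; ++l) idx[l] = l;
  std::vector<int> males(nmate), females(nmate);
  const double* rp = rec.begin();
  int* cur = A.data();
  int* nxt = B.data();
  for (int g = 0; g < n_gen; ++g) {
    for (int i = 0; i < nmate; ++i) { males[i] = i; females[i] = nmate + i; }
    rand_perm(males);
    rand_perm(females);
    for (int m = 0; m < nmate; ++m) {
      int s = males[m], d = females[m];
      const int* s0 = cur + (size_t) L * (2 * s);
      const int* s1 = cur + (size_t) L * (2 * s + 1);
      const int* d0 = cur + (size_t) L * (2 * d);
      const int* d1 = cur + (size_t) L * (2 * d + 1);
      // one male offspring (index m), one female offspring (index nmate + m)
      int off[2] = { m, nmate + m };
      for (int o = 0; o < 2; ++o) {
        int* c0 = nxt + (size_t) L * (2 * off[o]);
        int* c1 = nxt + (size_t) L * (2 * off[o] + 1);
        make_gamete(s0, s1, L, rp, mu, c0, idx);
        make_gamete(d0, d1, L, rp, mu, c1, idx);
      }
    }
    std::swap(cur, nxt);
  }
  IntegerMatrix out(L, 2 * n_ind);
  std::copy(cur, cur + (size_t) L * 2 * n_ind, out.begin());
  return out;
}

// Breed one offspring cohort from parent haplotypes H (L x 2Np) given 0-based
// parent indices; returns L x (2 n_off) with sire gamete first.
// [[Rcpp::export]]
IntegerMatrix cpp_breed(IntegerMatrix H, IntegerVector sire, IntegerVector dam,
                        NumericVector rec, double mu) {
  int L = H.nrow();
  if (rec.size() != L) stop("rec length must equal locus count");
  int np = H.ncol() / 2;
  int n_off = sire.size();
  if (dam.size() != n_off) stop("sire and dam vectors must have equal length");
  IntegerMatrix out(L, 2 * n_off);
  std::vector<int> idx(L);
  for (int l = 0; l < L; ++l) idx[l] = l;
  const double* rp = rec.begin();
  for (int o = 0; o < n_off; ++o) {
    int s = sire[o], d = dam[o];
    if (s < 0 || s >= np || d < 0 || d >= np) stop("pedigree inconsistency: parent index out of range");
    make_gamete(&H(0, 2 * s), &H(0, 2 * s + 1), L, rp, mu, &out(0, 2 * o), idx);
    make_gamete(&H(0, 2 * d), &H(0, 2 * d + 1), L, rp, mu, &out(0, 2 * o + 1), idx);
  }
  return out;
}

// Dosage (0/1/2) matrix, individuals x loci, from an L x 2N haplotype matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_dosage(IntegerMatrix H) {
  int L = H.nrow();
  int n = H.ncol() / 2;
  IntegerMatrix out(n, L);
  for (int i = 0; i < n; ++i) {
    const int* h0 = &H(0, 2 * i);
    const int* h1 = &H(0, 2 * i + 1);
    for (int l = 0; l < L; ++l) out(i, l) = h0[l] + h1[l];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Gibbs chain
// ---------------------------------------------------------------------------

static arma::mat22 as_mat22(SEXP m_) {
  NumericMatrix m(m_);
  arma::mat22 o;
  o(0, 0) = m(0, 0); o(0, 1) = m(0, 1); o(1, 0) = m(1, 0); o(1, 1) = m(1, 1);
  return o;
}

static NumericMatrix from_mat22(const arma::mat22& m) {
  NumericMatrix o(2, 2);
  o(0, 0) = m(0, 0); o(0, 1) = m(0, 1); o(1, 0) = m(1, 0); o(1, 1) = m(1, 1);
  return o;
}

// mode: 0 = single continuous trait (BayesCpi), 1 = single binary trait
// (BayesTCpi, residual variance fixed at 1), 2 = bivariate linear-threshold
// (LT-BayesCpi). Z must arrive column-centered; monomorphic columns (zero
// variance) are permanently excluded from the mixture.
// [[Rcpp::export]]
List cpp_run_chain(NumericVector y1_, IntegerVector y2_,
                   NumericMatrix X1_, NumericMatrix X2_, NumericMatrix Z_,
                   int mode, List prior,
                   int n_cycles, int burn_in, int thin,
                   bool df_all, bool constrain_zero_cov,
                   List init, bool check_invariants, double fixed_pi) {
  const bool T1 = (mode != 1);
  const bool T2 = (mode != 0);
  const int n = Z_.nrow();
  const int q = Z_.ncol();
  if (n_cycles <= burn_in) stop("burn_in must be smaller than n_cycles");
  if (thin < 1) stop("thinning must be >= 1");

  arma::mat Z(Z_.begin(), n, q, false);
  arma::vec y1 = T1 ? as<arma::vec>(y1_) : arma::vec(n, arma::fill::zeros);
  arma::ivec y2 = T2 ? as<arma::ivec>(y2_) : arma::ivec(n, arma::fill::zeros);
  arma::mat X1 = as<arma::mat>(X1_);
  arma::mat X2 = as<arma::mat>(X2_);
  const int p1 = T1 ? X1.n_cols : 0;
  const int p2 = T2 ? X2.n_cols : 0;

  // priors
  double vg = as<double>(prior["v_g"]);
  double ve = as<double>(prior["v_e"]);
  arma::mat22 Vginv = as_mat22(prior["V_g_inv"]);
  arma::mat22 Veinv = as_mat22(prior["V_e_inv"]);
  double beta_lo = as<double>(prior["beta_min"]);
  double beta_hi = as<double>(prior["beta_max"]);

  // state
  arma::vec b1 = as<arma::vec>(init["beta1"]);
  arma::vec b2 = as<arma::vec>(init["beta2"]);
  arma::vec g1 = as<arma::vec>(init["g1"]);
  arma::vec g2 = as<arma::vec>(init["g2"]);
  arma::ivec delta = as<arma::ivec>(init["delta"]);
  arma::vec liab = as<arma::vec>(init["liability"]);
  arma::mat22 G0 = as_mat22(init["G0"]);
  arma::mat22 Re = as_mat22(init["Re"]);
  double pi = as<double>(init["pi"]);

  // precomputations
  arma::vec czz(q);
  std::vector<bool> mono(q);
  int q_eff = 0;
  for (int j = 0; j < q; ++j) {
    czz[j] = arma::dot(Z.col(j), Z.col(j));
    mono[j] = (czz[j] < 1e-10);
    if (!mono[j]) ++q_eff;
  }
  if (q_eff == 0) stop("all SNPs are monomorphic in the training data");

  // residuals
  arma::vec e1(n, arma::fill::zeros), e2(n, arma::fill::zeros);
  auto refresh_resid = [&]() {
    if (T1) e1 = y1 - X1 * b1 - Z * g1;
    if (T2) e2 = liab - X2 * b2 - Z * g2;
  };
  refresh_resid();

  // accumulators
  const int n_keep = (n_cycles - burn_in + thin - 1) / thin;
  arma::vec sg1(q, arma::fill::zeros), sg2(q, arma::fill::zeros), sdelta(q, arma::fill::zeros);
  arma::vec sb1(std::max(p1, 1), arma::fill::zeros), sb2(std::max(p2, 1), arma::fill::zeros);
  arma::mat22 sG0(arma::fill::zeros), sRe(arma::fill::zeros);
  double spi = 0.0;
  NumericMatrix traces(n_keep, 9);
  colnames(traces) = CharacterVector::create(
    "cycle", "pi", "sigma2_g1", "sigma_g12", "sigma2_g2",
    "sigma2_e1", "sigma_e12", "sigma2_e2", "n_included");
  int kept = 0, n_fallback = 0;

  for (int cyc = 0; cyc < n_cycles; ++cyc) {
    // -- liabilities -------------------------------------------------------
    if (T2) {
      double se11 = Re(0, 0), se12 = Re(0, 1), se22 = Re(1, 1);
      double slope = T1 ? se12 / se11 : 0.0;
      double cvar = se22 - (T1 ? se12 * se12 / se11 : 0.0);
      if (!(cvar > 0.0)) stop("non-positive conditional liability variance (Re not PD) at cycle %d", cyc + 1);
      double csd = std::sqrt(cvar);
      for (int i = 0; i < n; ++i) {
        double fitted = liab[i] - e2[i];
        double m = fitted + (T1 ? slope * e1[i] : 0.0);
        double lnew = (y2[i] == 1) ? rtnorm1(m, csd, 0.0, R_PosInf)
                                   : rtnorm1(m, csd, R_NegInf, 0.0);
        liab[i] = lnew;
        e2[i] = lnew - fitted;
      }
    }

    // -- fixed effects -----------------------------------------------------
    double detRe = Re(0, 0) * Re(1, 1) - Re(0, 1) * Re(0, 1);
    double w11 = Re(1, 1) / detRe, w22 = Re(0, 0) / detRe, w12 = -Re(0, 1) / detRe;
    if (T1) {
      for (int c = 0; c < p1; ++c) {
        arma::vec x = X1.col(c);
        double xx = arma::dot(x, x);
        if (xx <= 0.0) continue; // degenerate column: skipped
        e1 += x * b1[c];
        double v = arma::dot(x, e1);
        double m, var;
        if (T2) { m = (v + (w12 / w11) * arma::dot(x, e2)) / xx; var = 1.0 / (w11 * xx); }
        else    { m = v / xx; var = Re(0, 0) / xx; }
        double th = rtnorm1(m, std::sqrt(var), beta_lo, beta_hi);
        b1[c] = th;
        e1 -= x * th;
      }
    }
    if (T2) {
      for (int c = 0; c < p2; ++c) {
        arma::vec x = X2.col(c);
        double xx = arma::dot(x, x);
        if (xx <= 0.0) continue;
        e2 += x * b2[c];
        double v = arma::dot(x, e2);
        double m, var;
        if (T1) { m = (v + (w12 / w22) * arma::dot(x, e1)) / xx; var = 1.0 / (w22 * xx); }
        else    { m = v / xx; var = Re(1, 1) / xx; }
        double th = rtnorm1(m, std::sqrt(var), beta_lo, beta_hi);
        b2[c] = th;
        e2 -= x * th;
      }
    }

    // -- SNP effects (shared inclusion indicator, slab integrated out) -----
    double log_prior_odds = std::log((1.0 - pi) / pi);
    if (mode == 2) {
      for (int j = 0; j < q; ++j) {
        if (mono[j]) continue;
        double v1 = arma::dot(Z.col(j), e1) + czz[j] * g1[j];
        double v2 = arma::dot(Z.col(j), e2) + czz[j] * g2[j];
        double mu1, mu2, o11, o12, o22;
        double lbf = log_bf_biv(czz[j], v1, v2, G0, Re, &mu1, &mu2, &o11, &o12, &o22);
        double lodds = log_prior_odds + lbf;
        double p_in = 1.0 / (1.0 + std::exp(-lodds));
        if (unif_rand() < p_in) {
          // alpha = mu + L'^{-1} z, Omega = L L'
          double l11 = std::sqrt(o11), l21 = o12 / l11;
          double l22 = std::sqrt(o22 - l21 * l21);
          double z1v = norm_rand(), z2v = norm_rand();
          double a2 = z2v / l22;
          double a1 = (z1v - l21 * a2) / l11;
          double n1 = mu1 + a1, n2 = mu2 + a2;
          e1 -= Z.col(j) * (n1 - g1[j]);
          e2 -= Z.col(j) * (n2 - g2[j]);
          g1[j] = n1; g2[j] = n2; delta[j] = 1;
        } else if (delta[j] == 1) {
          e1 += Z.col(j) * g1[j];
          e2 += Z.col(j) * g2[j];
          g1[j] = 0.0; g2[j] = 0.0; delta[j] = 0;
        }
      }
    } else {
      const int a = (mode == 0) ? 0 : 1;
      arma::vec& e = (a == 0) ? e1 : e2;
      arma::vec& g = (a == 0) ? g1 : g2;
      double sg2v = G0(a, a), se2v = Re(a, a);
      for (int j = 0; j < q; ++j) {
        if (mono[j]) continue;
        double v = arma::dot(Z.col(j), e) + czz[j] * g[j];
        double mu, om;
        double lbf = log_bf_uni(czz[j], v, sg2v, se2v, &mu, &om);
        double p_in = 1.0 / (1.0 + std::exp(-(log_prior_odds + lbf)));
        if (unif_rand() < p_in) {
          double nv = mu + norm_rand() / std::sqrt(om);
          e -= Z.col(j) * (nv - g[j]);
          g[j] = nv; delta[j] = 1;
        } else if (delta[j] == 1) {
          e += Z.col(j) * g[j];
          g[j] = 0.0; delta[j] = 0;
        }
      }
    }

    // -- G0 ----------------------------------------------------------------
    int m1 = 0;
    arma::mat22 Sg(arma::fill::zeros);
    for (int j = 0; j < q; ++j) {
      if (delta[j]) {
        ++m1;
        Sg(0, 0) += g1[j] * g1[j];
        Sg(0, 1) += g1[j] * g2[j];
        Sg(1, 1) += g2[j] * g2[j];
      }
    }
    Sg(1, 0) = Sg(0, 1);
    double dfG = vg + (df_all ? (double) q_eff : (double) m1);
    if (mode == 2) {
      if (constrain_zero_cov) {
        double df_use = dfG;
        double s11 = Vginv(0, 0) + Sg(0, 0), s22 = Vginv(1, 1) + Sg(1, 1);
        if (df_use < 1.0 || s11 < 1e-12 || s22 < 1e-12) {
          s11 += 1e-6; s22 += 1e-6; df_use = std::max(df_use, 4.0); ++n_fallback;
        }
        G0(0, 0) = riw1_draw(1.0 / s11, df_use);
        G0(1, 1) = riw1_draw(1.0 / s22, df_use);
        G0(0, 1) = 0.0; G0(1, 0) = 0.0;
      } else {
        arma::mat22 S = Vginv + Sg;
        double df_use = dfG;
        bool fb = (df_use <= 1.5);
        arma::mat22 Si;
        if (!fb) {
          double det = S(0, 0) * S(1, 1) - S(0, 1) * S(0, 1);
          fb = !(det > 1e-300) || S(0, 0) <= 0.0;
        }
        if (fb) {
          S(0, 0) += 1e-6; S(1, 1) += 1e-6;
          df_use = std::max(df_use, 4.0);
          ++n_fallback;
        }
        double det = S(0, 0) * S(1, 1) - S(0, 1) * S(0, 1);
        Si(0, 0) = S(1, 1) / det; Si(1, 1) = S(0, 0) / det;
        Si(0, 1) = -S(0, 1) / det; Si(1, 0) = Si(0, 1);
        G0 = riw2_draw(Si, df_use);
      }
    } else {
      const int a = (mode == 0) ? 0 : 1;
      double s = Vginv(a, a) + Sg(a, a);
      double df_use = dfG;
      if (df_use < 1.0 || s < 1e-12) { s += 1e-6; df_use = std::max(df_use, 4.0); ++n_fallback; }
      G0(a, a) = riw1_draw(1.0 / s, df_use);
    }

    // -- Re ----------------------------------------------------------------
    if (mode == 0) {
      double s = Veinv(0, 0) + arma::dot(e1, e1);
      Re(0, 0) = riw1_draw(1.0 / s, ve + n);
    } else if (mode == 2) {
      arma::mat22 Se;
      Se(0, 0) = arma::dot(e1, e1);
      Se(0, 1) = arma::dot(e1, e2);
      Se(1, 0) = Se(0, 1);
      Se(1, 1) = arma::dot(e2, e2);
      arma::mat22 S = Veinv + Se;
      double dfE = ve + n;
      if (constrain_zero_cov) {
        Re(0, 0) = riw1_draw(1.0 / S(0, 0), dfE);
        Re(0, 1) = 0.0; Re(1, 0) = 0.0; Re(1, 1) = 1.0;
      } else {
        double det = S(0, 0) * S(1, 1) - S(0, 1) * S(0, 1);
        if (!(det > 1e-300)) stop("singular residual cross-product at cycle %d", cyc + 1);
        arma::mat22 V;
        V(0, 0) = S(1, 1) / det; V(1, 1) = S(0, 0) / det;
        V(0, 1) = -S(0, 1) / det; V(1, 0) = V(0, 1);
        Re = korsgaard_draw(V, dfE);
      }
    } // mode 1: Re = 1 fixed

    // -- pi ----------------------------------------------------------------
    if (fixed_pi >= 0.0) pi = fixed_pi;
    else pi = R::rbeta((double) (q_eff - m1) + 1.0, (double) m1 + 1.0);

    // (thresholds: binary trait has its single threshold fixed at 0)

    // -- guards ------------------------------------------------------------
    if (!R_finite(pi) || !G0.is_finite() || !Re.is_finite())
      stop("non-finite sampler state at cycle %d", cyc + 1);

    if (check_invariants) {
      for (int j = 0; j < q; ++j)
        if (delta[j] == 0 && (g1[j] != 0.0 || g2[j] != 0.0))
          stop("invariant violation: delta=0 with nonzero effect at cycle %d", cyc + 1);
      if (T1 && Re(0, 0) <= 0.0) stop("invariant violation: Re not PD at cycle %d", cyc + 1);
      if (mode == 2 && Re(0, 0) * Re(1, 1) - Re(0, 1) * Re(0, 1) <= 0.0)
        stop("invariant violation: Re not PD at cycle %d", cyc + 1);
      arma::vec r1 = e1, r2 = e2;
      refresh_resid();
      if (T1 && arma::abs(r1 - e1).max() > 1e-8)
        stop("residual bookkeeping drift (trait 1) at cycle %d", cyc + 1);
      if (T2 && arma::abs(r2 - e2).max() > 1e-8)
        stop("residual bookkeeping drift (trait 2) at cycle %d", cyc + 1);
    } else if ((cyc + 1) % 2000 == 0) {
      refresh_resid();
    }

    // -- record ------------------------------------------------------------
    if (cyc >= burn_in && (cyc - burn_in) % thin == 0) {
      sg1 += g1; sg2 += g2;
      for (int j = 0; j < q; ++j) sdelta[j] += delta[j];
      if (p1) sb1 += b1;
      if (p2) sb2 += b2;
      sG0 += G0; sRe += Re; spi += pi;
      traces(kept, 0) = cyc + 1;
      traces(kept, 1) = pi;
      traces(kept, 2) = G0(0, 0); traces(kept, 3) = G0(0, 1); traces(kept, 4) = G0(1, 1);
      traces(kept, 5) = Re(0, 0); traces(kept, 6) = Re(0, 1); traces(kept, 7) = Re(1, 1);
      traces(kept, 8) = m1;
      ++kept;
    }
  }

  double K = (double) kept;
  arma::vec mg1 = sg1 / K, mg2 = sg2 / K, mdel = sdelta / K;
  arma::vec mb1 = sb1 / K, mb2 = sb2 / K;
  List state = List::create(
    _["beta1"] = NumericVector(b1.begin(), b1.end()),
    _["beta2"] = NumericVector(b2.begin(), b2.end()),
    _["g1"] = NumericVector(g1.begin(), g1.end()),
    _["g2"] = NumericVector(g2.begin(), g2.end()),
    _["delta"] = IntegerVector(delta.begin(), delta.end()),
    _["liability"] = NumericVector(liab.begin(), liab.end()),
    _["G0"] = from_mat22(G0),
    _["Re"] = from_mat22(Re),
    _["pi"] = pi);
  return List::create(
    _["g1_hat"] = NumericVector(mg1.begin(), mg1.end()),
    _["g2_hat"] = NumericVector(mg2.begin(), mg2.end()),
    _["inclusion"] = NumericVector(mdel.begin(), mdel.end()),
    _["beta1_hat"] = NumericVector(mb1.begin(), mb1.end()),
    _["beta2_hat"] = NumericVector(mb2.begin(), mb2.end()),
    _["pi_hat"] = spi / K,
    _["G0_hat"] = from_mat22(sG0 / K),
    _["Re_hat"] = from_mat22(sRe / K),
    _["traces"] = traces,
    _["n_kept"] = kept,
    _["monomorphic"] = LogicalVector(mono.begin(), mono.end()),
    _["q_eff"] = q_eff,
    _["n_fallback"] = n_fallback,
    _["e1"] = NumericVector(e1.begin(), e1.end()),
    _["e2"] = NumericVector(e2.begin(), e2.end()),
    _["state"] = state);
}
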