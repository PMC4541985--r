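// Gibbs samplers for the Gaussian animal model on a full-sib
// pseudo-pedigree (one unrelated sire/dam pair per family, no inbreeding).
//
// Under that pedigree the additive values of phenotyped offspring decompose
// exactly as a_i = g_f(i) + m_i with g_f ~ N(0, Va/2) (family / parental
// average) and m_i ~ N(0, Va/2) (Mendelian sampling), independent across
// families and individuals.  The samplers work in this representation; it
// is equivalent to the A-matrix formulation (full sibs share Cov = Va/2,
// unrelated individuals share none) and keeps every conditional scalar or
// 2x2, so even million-iteration chains run in seconds.
//
// Variance priors are scaled inverse chi-squared (univariate) and inverse
// Wishart (bivariate genetic covariance), with a low degree of belief and
// scale set from the observed phenotypic variance split equally among the
// additive, replicate and residual components.  Normal draws come from an
// internal xoshiro256+ stream seeded from R's RNG, so set.seed() in R
// fixes the chains; chi-squared draws use R's RNG directly.

#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Fast normal draws: xoshiro256+ seeded from R's RNG (so set.seed() in R
// fixes the chain), with Box-Muller.  R's own rnorm (inversion) would
// dominate the samplers' run time at these chain lengths.
namespace fastrng {

static uint64_t s[4];
static double spare;
static bool has_spare = false;

static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

inline void seed_from_R() {
  uint64_t x = (uint64_t)(R::unif_rand() * 4294967296.0) ^
               ((uint64_t)(R::unif_rand() * 4294967296.0) << 32);
  for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  has_spare = false;
}

static inline uint64_t rotl(uint64_t x, int k) {
  return (x << k) | (x >> (64 - k));
}

static inline uint64_t next() {
  uint64_t result = s[0] + s[3];
  uint64_t t = s[1] << 17;
  s[2] ^= s[0];
  s[3] ^= s[1];
  s[1] ^= s[2];
  s[0] ^= s[3];
  s[2] ^= t;
  s[3] = rotl(s[3], 45);
  return result;
}

static inline double runif01() {
  return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

inline double rnorm() {
  if (has_spare) {
    has_spare = false;
    return spare;
  }
  double u1 = runif01(), u2 = runif01();
  double rad = std::sqrt(-2.0 * std::log(u1));
  double ang = 6.283185307179586476925286766559 * u2;
  spare = rad * std::sin(ang);
  has_spare = true;
  return rad * std::cos(ang);
}

inline double rnorm(double mean, double sd) { return mean + sd * rnorm(); }

}  // namespace fastrng

static inline double rinvchisq(double nu, double scale) {
  // scaled inverse chi-squared: scale / chisq_nu
  return scale / R::rchisq(nu);
}

// [[Rcpp::export(name = ".gibbs_univariate")]]
List gibbs_univariate(NumericVector y, IntegerVector fam, IntegerVector rep,
                      int n_fam, int n_rep, double V0a, double V0r,
                      double V0e, double nu, int n_iter, int burn_in,
                      int thin) {
  const int n = y.size();
  const int n_keep = (n_iter - burn_in) / thin;
  fastrng::seed_from_R();
  NumericVector g(n_fam), m(n), r(n_rep);
  std::vector<int> fam_n(n_fam, 0), rep_n(n_rep, 0);
  for (int i = 0; i < n; ++i) {
    fam_n[fam[i]]++;
    rep_n[rep[i]]++;
  }
  double mu = mean(y);
  double s2a = V0a, s2r = V0r, s2e = V0e;

  NumericVector out_va(n_keep), out_vr(n_keep), out_ve(n_keep),
      out_h2(n_keep), out_mu(n_keep);
  std::vector<double> fsum(n_fam), rsum(n_rep), gd(n_fam), rd(n_rep), e(n);
  int kept = 0;

  // maintained residual e_i = y_i - mu - g[fam] - m_i - r[rep]
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu - g[fam[i]] - m[i] - r[rep[i]];
  double acc = 0.0;
  for (int i = 0; i < n; ++i) acc += e[i];

  for (int it = 0; it < n_iter; ++it) {
    if ((it & 8191) == 8191) {  // periodic refresh against fp drift
      acc = 0.0;
      for (int i = 0; i < n; ++i) {
        e[i] = y[i] - mu - g[fam[i]] - m[i] - r[rep[i]];
        acc += e[i];
      }
    }

    // mu | rest ~ N(mu + mean(e), s2e/n)
    double mu_new = fastrng::rnorm(mu + acc / n, std::sqrt(s2e / n));
    double mu_d = mu_new - mu;
    mu = mu_new;

    // family effects g_f ~ N(0, s2a/2); fold the mu shift into e here
    std::fill(fsum.begin(), fsum.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      e[i] -= mu_d;
      fsum[fam[i]] += e[i];
    }
    double ssg = 0.0;
    for (int f = 0; f < n_fam; ++f) {
      double prec = fam_n[f] / s2e + 2.0 / s2a;
      double tot = fsum[f] + fam_n[f] * g[f];
      double g_new = fastrng::rnorm(tot / s2e / prec, std::sqrt(1.0 / prec));
      gd[f] = g_new - g[f];
      g[f] = g_new;
      ssg += g_new * g_new;
    }

    // Mendelian deviations m_i ~ N(0, s2a/2), then replicate sums
    double ssm = 0.0;
    {
      double prec = 1.0 / s2e + 2.0 / s2a;
      double sd = std::sqrt(1.0 / prec);
      double wt = 1.0 / (s2e * prec);
      std::fill(rsum.begin(), rsum.end(), 0.0);
      for (int i = 0; i < n; ++i) {
        double val = e[i] - gd[fam[i]] + m[i];  // y - mu - g - r
        double m_new = fastrng::rnorm(val * wt, sd);
        m[i] = m_new;
        ssm += m_new * m_new;
        e[i] = val - m_new;
        rsum[rep[i]] += e[i];
      }
    }

    // replicate effects
    double ssr = 0.0;
    for (int k = 0; k < n_rep; ++k) {
      double prec = rep_n[k] / s2e + 1.0 / s2r;
      double tot = rsum[k] + rep_n[k] * r[k];
      double r_new = fastrng::rnorm(tot / s2e / prec, std::sqrt(1.0 / prec));
      rd[k] = r_new - r[k];
      r[k] = r_new;
      ssr += r_new * r_new;
    }
    double sse = 0.0;
    acc = 0.0;
    for (int i = 0; i < n; ++i) {
      e[i] -= rd[rep[i]];
      sse += e[i] * e[i];
      acc += e[i];
    }

    s2a = rinvchisq(nu + n_fam + n, nu * V0a + 2.0 * (ssg + ssm));
    s2r = rinvchisq(nu + n_rep, nu * V0r + ssr);
    s2e = rinvchisq(nu + n, nu * V0e + sse);

    if (it >= burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      out_va[kept] = s2a;
      out_vr[kept] = s2r;
      out_ve[kept] = s2e;
      out_h2[kept] = s2a / (s2a + s2r + s2e);
      out_mu[kept] = mu;
      ++kept;
    }
  }
  return List::create(_["V_A"] = out_va, _["V_rep"] = out_vr,
                      _["V_res"] = out_ve, _["h2"] = out_h2,
                      _["mu"] = out_mu);
}

// Sample a 2x2 inverse-Wishart IW(S, df) via the Bartlett decomposition of
// the Wishart of the inverse scale.
static void rinvwishart2(const double S[3], double df, double G[3]) {
  // S = (S11, S12, S22); invert S
  double det = S[0] * S[2] - S[1] * S[1];
  double Si11 = S[2] / det, Si12 = -S[1] / det, Si22 = S[0] / det;
  // chol of S^{-1} (lower): L
  double L11 = std::sqrt(Si11);
  double L21 = Si12 / L11;
  double L22 = std::sqrt(Si22 - L21 * L21);
  // Bartlett: A lower with chi / normal entries
  double a11 = std::sqrt(R::rchisq(df));
  double a21 = fastrng::rnorm(0.0, 1.0);
  double a22 = std::sqrt(R::rchisq(df - 1.0));
  // T = L * A (lower); W = T T'
  double T11 = L11 * a11;
  double T21 = L21 * a11 + L22 * a21;
  double T22 = L22 * a22;
  double W11 = T11 * T11;
  double W12 = T11 * T21;
  double W22 = T21 * T21 + T22 * T22;
  // G = W^{-1}
  double detW = W11 * W22 - W12 * W12;
  G[0] = W22 / detW;
  G[1] = -W12 / detW;
  G[2] = W11 / detW;
}

// [[Rcpp::export(name = ".gibbs_bivariate")]]
List gibbs_bivariate(NumericVector y, IntegerVector trait, IntegerVector fam,
                     IntegerVector rep, IntegerVector rep_trait, int n_fam,
                     int n_rep, NumericVector V0a, NumericVector V0r,
                     NumericVector V0e, double nu_g, double nu, int n_iter,
                     int burn_in, int thin) {
  const int n = y.size();
  const int n_keep = (n_iter - burn_in) / thin;
  fastrng::seed_from_R();

  NumericMatrix g(n_fam, 2);      // family (parental-average) effects
  NumericMatrix m(n, 2);          // Mendelian deviations, both traits
  NumericVector r(n_rep);         // replicate effects (each rep = one trait)
  double mu[2];
  double s2r[2], s2e[2];
  double G[3];                    // (G11, G12, G22), Va = diag
  double S0[3];

  std::vector<int> rep_n(n_rep, 0);
  std::vector<int> fam_n0(n_fam, 0), fam_n1(n_fam, 0);
  std::vector<double> ybar(2, 0.0);
  std::vector<int> ntr(2, 0);
  for (int i = 0; i < n; ++i) {
    rep_n[rep[i]]++;
    if (trait[i] == 0) fam_n0[fam[i]]++; else fam_n1[fam[i]]++;
    ybar[trait[i]] += y[i];
    ntr[trait[i]]++;
  }
  for (int t = 0; t < 2; ++t) mu[t] = ybar[t] / std::max(1, ntr[t]);
  G[0] = V0a[0];
  G[1] = 0.0;
  G[2] = V0a[1];
  S0[0] = nu_g * V0a[0];
  S0[1] = 0.0;
  S0[2] = nu_g * V0a[1];
  s2r[0] = V0r[0]; s2r[1] = V0r[1];
  s2e[0] = V0e[0]; s2e[1] = V0e[1];

  NumericMatrix out(n_keep, 11);
  int kept = 0;
  std::vector<double> fsum0(n_fam), fsum1(n_fam), rsum(n_rep);

  for (int it = 0; it < n_iter; ++it) {
    // trait means
    double acc0 = 0.0, acc1 = 0.0;
    for (int i = 0; i < n; ++i) {
      double e = y[i] - g(fam[i], trait[i]) - m(i, trait[i]) - r[rep[i]];
      if (trait[i] == 0) acc0 += e; else acc1 += e;
    }
    if (ntr[0] > 0) mu[0] = fastrng::rnorm(acc0 / ntr[0], std::sqrt(s2e[0] / ntr[0]));
    if (ntr[1] > 0) mu[1] = fastrng::rnorm(acc1 / ntr[1], std::sqrt(s2e[1] / ntr[1]));

    // family effects: bivariate normal, prior N(0, G/2)
    double detG = G[0] * G[2] - G[1] * G[1];
    if (detG < 1e-12 * (G[0] * G[2] + 1e-300)) {
      detG = 1e-12 * (G[0] * G[2] + 1e-300);
    }
    double Gi11 = 2.0 * G[2] / detG, Gi12 = -2.0 * G[1] / detG,
           Gi22 = 2.0 * G[0] / detG;  // (G/2)^{-1}
    std::fill(fsum0.begin(), fsum0.end(), 0.0);
    std::fill(fsum1.begin(), fsum1.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      double e = y[i] - mu[trait[i]] - m(i, trait[i]) - r[rep[i]];
      if (trait[i] == 0) fsum0[fam[i]] += e; else fsum1[fam[i]] += e;
    }
    for (int f = 0; f < n_fam; ++f) {
      double P11 = Gi11 + fam_n0[f] / s2e[0];
      double P12 = Gi12;
      double P22 = Gi22 + fam_n1[f] / s2e[1];
      double b1 = fsum0[f] / s2e[0];
      double b2 = fsum1[f] / s2e[1];
      double detP = P11 * P22 - P12 * P12;
      double m1 = (P22 * b1 - P12 * b2) / detP;
      double m2 = (P11 * b2 - P12 * b1) / detP;
      // sample from N(mean, P^{-1}) via chol of P^{-1}
      double C11 = P22 / detP, C12 = -P12 / detP, C22 = P11 / detP;
      double l11 = std::sqrt(C11);
      double l21 = C12 / l11;
      double l22 = std::sqrt(std::max(C22 - l21 * l21, 0.0));
      double z1 = fastrng::rnorm(0.0, 1.0), z2 = fastrng::rnorm(0.0, 1.0);
      g(f, 0) = m1 + l11 * z1;
      g(f, 1) = m2 + l21 * z1 + l22 * z2;
    }

    // Mendelian deviations: observed coordinate from its full conditional,
    // unobserved coordinate from the prior conditional given the observed
    for (int i = 0; i < n; ++i) {
      int t = trait[i], u = 1 - t;
      double Gtt = (t == 0) ? G[0] : G[2];
      double Guu = (t == 0) ? G[2] : G[0];
      double Gtu = G[1];
      double e = y[i] - mu[t] - g(fam[i], t) - r[rep[i]];
      double condv = (Gtt - Gtu * Gtu / std::max(Guu, 1e-300)) / 2.0;
      condv = std::max(condv, 1e-300);
      double condm = (Gtu / std::max(Guu, 1e-300)) * m(i, u);
      double prec = 1.0 / condv + 1.0 / s2e[t];
      double mm = (condm / condv + e / s2e[t]) / prec;
      m(i, t) = fastrng::rnorm(mm, std::sqrt(1.0 / prec));
      double condvu = (Guu - Gtu * Gtu / std::max(Gtt, 1e-300)) / 2.0;
      condvu = std::max(condvu, 1e-300);
      m(i, u) = fastrng::rnorm((Gtu / std::max(Gtt, 1e-300)) * m(i, t),
                         std::sqrt(condvu));
    }

    // replicate effects (each replicate group belongs to one trait)
    std::fill(rsum.begin(), rsum.end(), 0.0);
    for (int i = 0; i < n; ++i)
      rsum[rep[i]] += y[i] - mu[trait[i]] - g(fam[i], trait[i]) - m(i, trait[i]);
    for (int k = 0; k < n_rep; ++k) {
      int t = rep_trait[k];
      double prec = rep_n[k] / s2e[t] + 1.0 / s2r[t];
      r[k] = fastrng::rnorm(rsum[k] / s2e[t] / prec, std::sqrt(1.0 / prec));
    }

    // genetic covariance matrix: inverse Wishart
    double S11 = S0[0], S12 = S0[1], S22 = S0[2];
    for (int f = 0; f < n_fam; ++f) {
      S11 += 2.0 * g(f, 0) * g(f, 0);
      S12 += 2.0 * g(f, 0) * g(f, 1);
      S22 += 2.0 * g(f, 1) * g(f, 1);
    }
    for (int i = 0; i < n; ++i) {
      S11 += 2.0 * m(i, 0) * m(i, 0);
      S12 += 2.0 * m(i, 0) * m(i, 1);
      S22 += 2.0 * m(i, 1) * m(i, 1);
    }
    double S[3] = {S11, S12, S22};
    rinvwishart2(S, nu_g + n_fam + n, G);

    // replicate and residual variances per trait
    double ssr0 = 0.0, ssr1 = 0.0;
    int nr0 = 0, nr1 = 0;
    for (int k = 0; k < n_rep; ++k) {
      if (rep_trait[k] == 0) { ssr0 += r[k] * r[k]; nr0++; }
      else { ssr1 += r[k] * r[k]; nr1++; }
    }
    s2r[0] = rinvchisq(nu + nr0, nu * V0r[0] + ssr0);
    s2r[1] = rinvchisq(nu + nr1, nu * V0r[1] + ssr1);
    double sse0 = 0.0, sse1 = 0.0;
    for (int i = 0; i < n; ++i) {
      double e = y[i] - mu[trait[i]] - g(fam[i], trait[i]) - m(i, trait[i]) - r[rep[i]];
      if (trait[i] == 0) sse0 += e * e; else sse1 += e * e;
    }
    s2e[0] = rinvchisq(nu + ntr[0], nu * V0e[0] + sse0);
    s2e[1] = rinvchisq(nu + ntr[1], nu * V0e[1] + sse1);

    if (it >= burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      out(kept, 0) = G[0];
      out(kept, 1) = G[2];
      out(kept, 2) = G[1];
      out(kept, 3) = G[1] / std::sqrt(G[0] * G[2]);
      out(kept, 4) = s2r[0];
      out(kept, 5) = s2r[1];
      out(kept, 6) = s2e[0];
      out(kept, 7) = s2e[1];
      out(kept, 8) = G[0] / (G[0] + s2r[0] + s2e[0]);
      out(kept, 9) = G[2] / (G[2] + s2r[1] + s2e[1]);
      out(kept, 10) = 0.0;
      ++kept;
    }
  }
  colnames(out) = CharacterVector::create(
      "V_A_1", "V_A_2", "cov_A", "r_G", "V_rep_1", "V_rep_2", "V_res_1",
      "V_res_2", "h2_1", "h2_2", "spare");
  return List::create(_["samples"] = out);
}
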