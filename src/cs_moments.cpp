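// Compound-symmetry truncated-normal kernels for the EM E-step.
//
// With a random intercept every marginal covariance is sigma2*I + psi*J,
// a family closed under Gaussian conditioning and under the Tallis moment
// recursion; all rectangle probabilities reduce to one-dimensional
// integrals over the shared factor (fixed Gauss-Hermite rule) with exact
// closed forms in dimensions one and two. These kernels are evaluated for
// every individual, component and EM iteration, hence compiled.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double TWOPI = 6.283185307179586476925286766559;

// Gauss-Legendre rules used by the bivariate routine (Genz's TVPACK sets)
static const double BVN_W1[3] = {0.1713244923791705, 0.3607615730481384,
                                 0.4679139345726904};
static const double BVN_X1[3] = {-0.9324695142031522, -0.6612093864662647,
                                 -0.2386191860831970};
static const double BVN_W2[6] = {0.04717533638651177, 0.1069393259953183,
                                 0.1600783285433464, 0.2031674267230659,
                                 0.2334925365383547, 0.2491470458134029};
static const double BVN_X2[6] = {-0.9815606342467191, -0.9041172563704750,
                                 -0.7699026741943050, -0.5873179542866171,
                                 -0.3678314989981802, -0.1252334085114692};
static const double BVN_W3[10] = {0.01761400713915212, 0.04060142980038694,
                                  0.06267204833410906, 0.08327674157670475,
                                  0.1019301198172404, 0.1181945319615184,
                                  0.1316886384491766, 0.1420961093183821,
                                  0.1491729864726037, 0.1527533871307259};
static const double BVN_X3[10] = {-0.9931285991850949, -0.9639719272779138,
                                  -0.9122344282513259, -0.8391169718222188,
                                  -0.7463319064601508, -0.6360536807265150,
                                  -0.5108670019508271, -0.3737060887154196,
                                  -0.2277858511416451, -0.07652652113349733};

static inline double phid(double x) {
  return R::pnorm(x, 0.0, 1.0, 1, 0);
}
static inline double lphid(double x) {
  return R::pnorm(x, 0.0, 1.0, 1, 1);
}

// standard bivariate normal P(X <= h, Y <= k), correlation rho
// (Drezner-Wesolowsky / Genz); absolute accuracy ~1e-15
static double pbvn_cpp(double h, double k, double rho) {
  if (rho > 1) rho = 1;
  if (rho < -1) rho = -1;
  const double *w, *x;
  int lg;
  double ar = std::fabs(rho);
  if (ar < 0.3) { w = BVN_W1; x = BVN_X1; lg = 3; }
  else if (ar < 0.75) { w = BVN_W2; x = BVN_X2; lg = 6; }
  else { w = BVN_W3; x = BVN_X3; lg = 10; }

  double a = -h, b = -k;          // survival form P(X > a, Y > b)
  double hk = a * b, bvn = 0.0;
  if (ar < 0.925) {
    if (ar > 0) {
      double hs = (a * a + b * b) / 2.0, asr = std::asin(rho);
      for (int i = 0; i < lg; i++) {
        for (int is = -1; is <= 1; is += 2) {
          double sn = std::sin(asr * (is * x[i] + 1.0) / 2.0);
          bvn += w[i] * std::exp((sn * hk - hs) / (1.0 - sn * sn));
        }
      }
      bvn *= asr / (2.0 * TWOPI);
    }
    bvn += phid(-a) * phid(-b);
  } else {
    if (rho < 0) { b = -b; hk = -hk; }
    if (ar < 1) {
      double as1 = (1.0 - rho) * (1.0 + rho), aa = std::sqrt(as1);
      double bs = (a - b) * (a - b);
      double cc = (4.0 - hk) / 8.0, dd = (12.0 - hk) / 16.0;
      double asr = -(bs / as1 + hk) / 2.0;
      if (asr > -100.0) {
        bvn = aa * std::exp(asr) *
          (1.0 - cc * (bs - as1) * (1.0 - dd * bs / 5.0) / 3.0 +
           cc * dd * as1 * as1 / 5.0);
      }
      if (-hk < 100.0) {
        double bb = std::sqrt(bs);
        bvn -= std::exp(-hk / 2.0) * std::sqrt(TWOPI) * phid(-bb / aa) *
          bb * (1.0 - cc * bs * (1.0 - dd * bs / 5.0) / 3.0);
      }
      aa /= 2.0;
      for (int i = 0; i < lg; i++) {
        for (int is = -1; is <= 1; is += 2) {
          double xs = aa * (is * x[i] + 1.0);
          xs *= xs;
          double rs = std::sqrt(1.0 - xs);
          double asr2 = -(bs / xs + hk) / 2.0;
          if (asr2 > -100.0) {
            bvn += aa * w[i] * std::exp(asr2) *
              (std::exp(-hk * (1.0 - rs) / (2.0 * (1.0 + rs))) / rs -
               (1.0 + cc * xs * (1.0 + dd * xs)));
          }
        }
      }
      bvn = -bvn / TWOPI;
    }
    if (rho > 0) {
      bvn += phid(-std::max(a, b));
    } else {
      bvn = -bvn;
      if (b > a) bvn += phid(b) - phid(a);
    }
  }
  if (bvn < 0) bvn = 0;
  if (bvn > 1) bvn = 1;
  return bvn;
}

// log P(X <= u) for X ~ N(m, s2*I + psi*J), all limits finite.
// ghx / ghlw: probabilists' Gauss-Hermite nodes and log-weights.
static double cs_logcdf_c(const double *u, const double *m, int d,
                          double s2, double psi,
                          const double *ghx, const double *ghlw, int K) {
  double s = std::sqrt(s2);
  if (psi <= 0) {
    double t = 0;
    for (int j = 0; j < d; j++) t += lphid((u[j] - m[j]) / s);
    return t;
  }
  double sd = std::sqrt(s2 + psi);
  if (d == 1) return lphid((u[0] - m[0]) / sd);
  if (d == 2) {
    double p = pbvn_cpp((u[0] - m[0]) / sd, (u[1] - m[1]) / sd,
                        psi / (s2 + psi));
    return std::log(p > 0 ? p : 1e-320);
  }
  double sp = std::sqrt(psi);
  double mx = -INFINITY;
  std::vector<double> lt(K);
  for (int z = 0; z < K; z++) {
    double t = ghlw[z];
    double shift = sp * ghx[z];
    for (int j = 0; j < d; j++) t += lphid((u[j] - m[j] - shift) / s);
    lt[z] = t;
    if (t > mx) mx = t;
  }
  double acc = 0;
  for (int z = 0; z < K; z++) acc += std::exp(lt[z] - mx);
  return mx + std::log(acc);
}

// [[Rcpp::export(name = ".cs_logcdf_cpp")]]
double cs_logcdf_cpp(NumericVector upper, NumericVector mean,
                     double sigma2, double psi,
                     NumericVector ghx, NumericVector ghlw) {
  return cs_logcdf_c(upper.begin(), mean.begin(), upper.size(),
                     sigma2, psi, ghx.begin(), ghlw.begin(), ghx.size());
}

// Tallis-type truncated moments of X ~ N(mean, sigma2*I + psi*J)
// restricted to {X <= upper}; all limits finite, d >= 1.
// Returns mean, cov, log_mass and ok = FALSE when the region mass is
// below mass_floor.
// [[Rcpp::export(name = ".cs_trunc_moments_cpp")]]
List cs_trunc_moments_cpp(NumericVector upper, NumericVector mean,
                          double sigma2, double psi, double mass_floor,
                          NumericVector ghx, NumericVector ghlw) {
  int d = upper.size();
  int K = ghx.size();
  double sig_d = sigma2 + psi;

  double log_alpha = cs_logcdf_c(upper.begin(), mean.begin(), d, sigma2,
                                 psi, ghx.begin(), ghlw.begin(), K);
  if (log_alpha < std::log(mass_floor)) {
    return List::create(_["ok"] = false, _["log_mass"] = log_alpha);
  }
  double alpha = std::exp(log_alpha);

  if (d == 1) {
    double sd = std::sqrt(sig_d);
    double z = (upper[0] - mean[0]) / sd;
    double h = std::exp(R::dnorm(z, 0.0, 1.0, 1) - lphid(z));
    double mu_t = mean[0] - sd * h;
    double var_t = sig_d * (1.0 - z * h - h * h);
    if (var_t < 0) var_t = 0;
    NumericMatrix cv(1, 1);
    cv(0, 0) = var_t;
    return List::create(_["ok"] = true,
                        _["mean"] = NumericVector::create(mu_t),
                        _["cov"] = cv, _["log_mass"] = log_alpha);
  }

  std::vector<double> u(d);
  for (int j = 0; j < d; j++) u[j] = upper[j] - mean[j];

  double c1 = psi / sig_d;
  double psi1 = psi * sigma2 / sig_d;
  double sig_d1 = sigma2 + psi1;
  double c2 = psi1 / sig_d1;
  double psi2 = psi1 * sigma2 / sig_d1;

  // F_k = phi(u_k; sig_d) * P(rest <= limits | X_k = u_k)
  std::vector<double> Fk(d), rest(d - 1), restm(d - 1);
  double sdm = std::sqrt(sig_d);
  for (int k = 0; k < d; k++) {
    double fk = R::dnorm(u[k], 0.0, sdm, 0);
    if (fk <= 0) { Fk[k] = 0; continue; }
    int idx = 0;
    for (int j = 0; j < d; j++) {
      if (j != k) { rest[idx] = u[j]; restm[idx] = c1 * u[k]; idx++; }
    }
    Fk[k] = fk * std::exp(cs_logcdf_c(rest.data(), restm.data(), d - 1,
                                      sigma2, psi1, ghx.begin(),
                                      ghlw.begin(), K));
  }

  // F_kq = phi2(u_k, u_q) * P(rest | X_k = u_k, X_q = u_q)
  std::vector<double> F2(d * d, 0.0);
  double det2 = sig_d * sig_d - psi * psi;
  std::vector<double> rest2(d > 2 ? d - 2 : 1), rest2m(d > 2 ? d - 2 : 1);
  for (int k = 0; k < d - 1; k++) {
    for (int q = k + 1; q < d; q++) {
      double qf = (u[k] * u[k] * sig_d - 2.0 * u[k] * u[q] * psi +
                   u[q] * u[q] * sig_d) / det2;
      double f2 = std::exp(-0.5 * qf) / (TWOPI * std::sqrt(det2));
      if (f2 > 0) {
        if (d == 2) {
          F2[k * d + q] = f2;
        } else {
          double shift = c1 * u[k] + c2 * (u[q] - c1 * u[k]);
          int idx = 0;
          for (int j = 0; j < d; j++) {
            if (j != k && j != q) {
              rest2[idx] = u[j]; rest2m[idx] = shift; idx++;
            }
          }
          F2[k * d + q] = f2 *
            std::exp(cs_logcdf_c(rest2.data(), rest2m.data(), d - 2,
                                 sigma2, psi2, ghx.begin(), ghlw.begin(),
                                 K));
        }
        F2[q * d + k] = F2[k * d + q];
      }
    }
  }

  // first moment: mu_c = -Sigma Fk / alpha, Sigma = sigma2 I + psi J
  double sFk = 0;
  for (int k = 0; k < d; k++) sFk += Fk[k];
  NumericVector mu_out(d);
  std::vector<double> mu_c(d);
  for (int i = 0; i < d; i++) {
    mu_c[i] = -(sigma2 * Fk[i] + psi * sFk) / alpha;
    mu_out[i] = mean[i] + mu_c[i];
  }

  // second moment via the vectorised Tallis terms:
  //   M = Sigma + T1 + T2,
  //   T1[i,j] = -sum_k Sig[i,k] Sig[j,k] (u_k Fk_k / sig_d) / alpha
  //   T2[i,j] =  sum_k Sig[i,k] V[j,k] / alpha with
  //   V[j,k]  =  sum_q Sig[j,q] F2[k,q] - Sig[j,k] * c_k / sig_d,
  //   c_k     =  sum_q Sig[k,q] F2[k,q]
  auto Sig = [&](int i, int j) { return i == j ? sig_d : psi; };
  std::vector<double> ukFk(d), ck(d), rowF2(d);
  for (int k = 0; k < d; k++) {
    ukFk[k] = u[k] * Fk[k];
    double a1 = 0, a2 = 0;
    for (int q = 0; q < d; q++) {
      a1 += Sig(k, q) * F2[k * d + q];
      a2 += F2[k * d + q];
    }
    ck[k] = a1;
    rowF2[k] = a2;
  }
  NumericMatrix cov(d, d);
  for (int i = 0; i < d; i++) {
    for (int j = i; j < d; j++) {
      double t1 = 0, t2 = 0;
      for (int k = 0; k < d; k++) {
        t1 += Sig(i, k) * Sig(j, k) * ukFk[k] / sig_d;
        // A[j,k] = sum_q Sig[j,q] F2[k,q]
        double Ajk = sigma2 * F2[k * d + j] + psi * rowF2[k];
        t2 += Sig(i, k) * (Ajk - Sig(j, k) * ck[k] / sig_d);
      }
      double M = Sig(i, j) - t1 / alpha + t2 / alpha;
      double cc = M - mu_c[i] * mu_c[j];
      cov(i, j) = cc;
      cov(j, i) = cc;
    }
  }
  return List::create(_["ok"] = true, _["mean"] = mu_out,
                      _["cov"] = cov, _["log_mass"] = log_alpha);
}
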