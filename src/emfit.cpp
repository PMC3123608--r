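#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Per-marker EM iteration loop.  A1 (n1 x 6) holds compat(m) * P(sib data |
// m) for units without an IBD dimension, A2 (n2 x 18, j-major blocks of 6)
// the sib-pair analogue; pi1 / pi2 the origin priors.  Everything else is
// the mating-type probability vector under p_k and the z mixture.
// Mirrors the R reference implementation in em.R (emEStep / emMStep).

static inline void mt_probs(double p, double* mt) {
  double q = 1.0 - p;
  mt[0] = q * q * q * q;
  mt[1] = 4.0 * p * q * q * q;
  mt[2] = 2.0 * p * p * q * q;
  mt[3] = 4.0 * p * p * q * q;
  mt[4] = 4.0 * p * p * p * q;
  mt[5] = p * p * p * p;
}

static const double P_LO = 1e-6, P_HI = 1.0 - 1e-6;
static const double MT_A[6] = {0, 1, 2, 2, 3, 4};

// [[Rcpp::export(name = ".emFitCpp")]]
List em_fit_cpp(NumericMatrix A1, NumericMatrix A2, NumericMatrix pi1,
                NumericMatrix pi2, NumericVector p0, NumericVector z0,
                double tol, int maxIter, bool freezeZ) {
  const int n1 = A1.nrow(), n2 = A2.nrow(), K = p0.size();
  std::vector<double> p(K), z(3);
  for (int k = 0; k < K; ++k)
    p[k] = std::min(std::max(p0[k], P_LO), P_HI);
  for (int j = 0; j < 3; ++j) z[j] = z0[j];
  const bool updateZ = n2 > 0 && !freezeZ;

  std::vector<double> mt(6), tot1(n1), tot2(n2);
  std::vector<double> Sp(K), Nk(K), Sz(3);
  std::vector<double> loglikTrace;
  bool converged = false;
  int iter = 0;

  // scratch: per-k row aggregates
  std::vector<double> V1((size_t)n1 * K), S1((size_t)n1 * K);
  std::vector<double> V2((size_t)n2 * K), S2((size_t)n2 * K);
  std::vector<double> PJ((size_t)n2 * 3 * K);

  while (true) {
    ++iter;
    std::fill(tot1.begin(), tot1.end(), 0.0);
    std::fill(tot2.begin(), tot2.end(), 0.0);
    for (int k = 0; k < K; ++k) {
      mt_probs(p[k], mt.data());
      for (int i = 0; i < n1; ++i) {
        double v = 0, s = 0;
        for (int m = 0; m < 6; ++m) {
          double x = A1(i, m) * mt[m];
          v += x;
          s += x * MT_A[m];
        }
        V1[(size_t)k * n1 + i] = pi1(i, k) * v;
        S1[(size_t)k * n1 + i] = pi1(i, k) * s;
        tot1[i] += pi1(i, k) * v;
      }
      for (int i = 0; i < n2; ++i) {
        double v = 0, s = 0;
        for (int j = 0; j < 3; ++j) {
          double vj = 0, sj = 0;
          for (int m = 0; m < 6; ++m) {
            double x = A2(i, 6 * j + m) * mt[m];
            vj += x;
            sj += x * MT_A[m];
          }
          PJ[((size_t)k * 3 + j) * n2 + i] = pi2(i, k) * z[j] * vj;
          v += z[j] * vj;
          s += z[j] * sj;
        }
        V2[(size_t)k * n2 + i] = pi2(i, k) * v;
        S2[(size_t)k * n2 + i] = pi2(i, k) * s;
        tot2[i] += pi2(i, k) * v;
      }
    }
    double ll = 0;
    for (int i = 0; i < n1; ++i) {
      if (tot1[i] <= 0) stop("zero posterior mass for a family");
      ll += std::log(tot1[i]);
    }
    for (int i = 0; i < n2; ++i) {
      if (tot2[i] <= 0) stop("zero posterior mass for a family");
      ll += std::log(tot2[i]);
    }
    loglikTrace.push_back(ll);

    std::fill(Sp.begin(), Sp.end(), 0.0);
    std::fill(Nk.begin(), Nk.end(), 0.0);
    std::fill(Sz.begin(), Sz.end(), 0.0);
    for (int k = 0; k < K; ++k) {
      for (int i = 0; i < n1; ++i) {
        Sp[k] += S1[(size_t)k * n1 + i] / tot1[i];
        Nk[k] += V1[(size_t)k * n1 + i] / tot1[i];
      }
      for (int i = 0; i < n2; ++i) {
        Sp[k] += S2[(size_t)k * n2 + i] / tot2[i];
        Nk[k] += V2[(size_t)k * n2 + i] / tot2[i];
        for (int j = 0; j < 3; ++j)
          Sz[j] += PJ[((size_t)k * 3 + j) * n2 + i] / tot2[i];
      }
    }
    double delta = 0;
    for (int k = 0; k < K; ++k) {
      double pn = Nk[k] > 0 ? Sp[k] / (4.0 * Nk[k]) : p[k];
      pn = std::min(std::max(pn, P_LO), P_HI);
      delta = std::max(delta, std::fabs(pn - p[k]));
      p[k] = pn;
    }
    if (updateZ) {
      double szTot = Sz[0] + Sz[1] + Sz[2];
      if (szTot > 0)
        for (int j = 0; j < 3; ++j) {
          double zn = Sz[j] / szTot;
          delta = std::max(delta, std::fabs(zn - z[j]));
          z[j] = zn;
        }
    }
    if (delta < tol) { converged = true; break; }
    if (iter >= maxIter) break;
  }

  // posterior outputs at the final parameters
  NumericVector expE1(n1), expE2(n2);
  NumericMatrix origin1(n1, K), origin2(n2, K);
  std::fill(tot1.begin(), tot1.end(), 0.0);
  std::fill(tot2.begin(), tot2.end(), 0.0);
  std::vector<double> E1(n1, 0.0), E2(n2, 0.0);
  for (int k = 0; k < K; ++k) {
    mt_probs(p[k], mt.data());
    for (int i = 0; i < n1; ++i) {
      double v = 0, e = 0;
      for (int m = 0; m < 6; ++m) {
        double x = A1(i, m) * mt[m];
        v += x;
        e += x * 0.5 * MT_A[m];
      }
      origin1(i, k) = pi1(i, k) * v;
      E1[i] += pi1(i, k) * e;
      tot1[i] += pi1(i, k) * v;
    }
    for (int i = 0; i < n2; ++i) {
      double v = 0, e = 0;
      for (int j = 0; j < 3; ++j)
        for (int m = 0; m < 6; ++m) {
          double x = A2(i, 6 * j + m) * mt[m] * z[j];
          v += x;
          e += x * 0.5 * MT_A[m];
        }
      origin2(i, k) = pi2(i, k) * v;
      E2[i] += pi2(i, k) * e;
      tot2[i] += pi2(i, k) * v;
    }
  }
  for (int i = 0; i < n1; ++i) {
    expE1[i] = E1[i] / tot1[i];
    for (int k = 0; k < K; ++k) origin1(i, k) /= tot1[i];
  }
  for (int i = 0; i < n2; ++i) {
    expE2[i] = E2[i] / tot2[i];
    for (int k = 0; k < K; ++k) origin2(i, k) /= tot2[i];
  }

  return List::create(
      _["p"] = NumericVector(p.begin(), p.end()),
      _["z"] = NumericVector(z.begin(), z.end()),
      _["nIterations"] = iter, _["converged"] = converged,
      _["loglikTrace"] = NumericVector(loglikTrace.begin(),
                                       loglikTrace.end()),
      _["expE1"] = expE1, _["expE2"] = expE2,
      _["origin1"] = origin1, _["origin2"] = origin2);
}
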