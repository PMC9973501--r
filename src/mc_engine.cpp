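// Metropolis Monte Carlo engine for the two-state nucleosome bead-spring
// chromatin polymer. Energy terms are evaluated incrementally per trial
// move; a from-scratch recomputation is recorded at every retained sample
// so the R side can audit the incremental bookkeeping.
//
// RNG: R's own generator (unif_rand), so trajectories are reproducible
// from set.seed() on the R side.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Par {
  int n;
  double sigma2, epsLJ, kSpring, q0, mu, epsS, epsW;
  double rCut2, wcaCut2, maxDisp;
  bool chainAdj;
};

inline double wca(double r2, const Par &p) {
  if (r2 >= p.wcaCut2) return 0.0;
  double s6 = p.sigma2 / r2;
  s6 = s6 * s6 * s6;
  return 4.0 * p.epsLJ * (s6 * s6 - s6) + p.epsLJ;
}

inline double dist2(const std::vector<double> &x, const std::vector<double> &y,
                    const std::vector<double> &z, int i, int j) {
  double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
  return dx * dx + dy * dy + dz * dz;
}

inline double pairEps(const std::vector<int> &sib, int i, int j,
                      const Par &p) {
  return (sib[i] && sib[j]) ? p.epsS : p.epsW;
}

// full Eq.-style recomputation (audit path)
double fullEnergy(const std::vector<double> &x, const std::vector<double> &y,
                  const std::vector<double> &z, const std::vector<int> &rho,
                  const std::vector<int> &sib, const Par &p) {
  double e = 0.0;
  for (int i = 0; i + 1 < p.n; ++i) {
    double q = std::sqrt(dist2(x, y, z, i, i + 1)) - p.q0;
    e += 0.5 * p.kSpring * q * q;
  }
  for (int i = 0; i < p.n; ++i) {
    if (rho[i]) e += p.mu;
    for (int j = i + 1; j < p.n; ++j) {
      double r2 = dist2(x, y, z, i, j);
      e += wca(r2, p);
      if (rho[i] && rho[j] && r2 < p.rCut2 && (p.chainAdj || j - i > 1))
        e -= pairEps(sib, i, j, p);
    }
  }
  return e;
}

int weakContacts(const std::vector<double> &x, const std::vector<double> &y,
                 const std::vector<double> &z, const std::vector<int> &rho,
                 const std::vector<int> &sib, const Par &p) {
  int k = 0;
  for (int i = 0; i < p.n; ++i) {
    if (!rho[i]) continue;
    for (int j = i + 1; j < p.n; ++j) {
      if (!rho[j]) continue;
      if (!p.chainAdj && j - i <= 1) continue;
      if (sib[i] && sib[j]) continue;
      if (dist2(x, y, z, i, j) < p.rCut2) ++k;
    }
  }
  return k;
}

double radiusGyr(const std::vector<double> &x, const std::vector<double> &y,
                 const std::vector<double> &z, int n) {
  double cx = 0, cy = 0, cz = 0;
  for (int i = 0; i < n; ++i) { cx += x[i]; cy += y[i]; cz += z[i]; }
  cx /= n; cy /= n; cz /= n;
  double s = 0;
  for (int i = 0; i < n; ++i) {
    double dx = x[i] - cx, dy = y[i] - cy, dz = z[i] - cz;
    s += dx * dx + dy * dy + dz * dz;
  }
  return std::sqrt(s / n);
}

inline int randIndex(int n) {
  int i = (int)(unif_rand() * n);
  return (i >= n) ? n - 1 : i;
}

inline bool accept(double dE) {
  return dE <= 0.0 || unif_rand() < std::exp(-dE);
}

// contact-energy magnitude between bead i (at xi,yi,zi, assumed bound)
// and all currently bound partners
double contactSum(const std::vector<double> &x, const std::vector<double> &y,
                  const std::vector<double> &z, const std::vector<int> &rho,
                  const std::vector<int> &sib, const Par &p, int i,
                  double xi, double yi, double zi) {
  double s = 0.0;
  for (int j = 0; j < p.n; ++j) {
    double dx = xi - x[j];
    if (dx * dx >= p.rCut2) continue;  // r >= |dx|
    if (j == i || !rho[j]) continue;
    if (!p.chainAdj && std::abs(j - i) <= 1) continue;
    double dy = yi - y[j], dz = zi - z[j];
    if (dx * dx + dy * dy + dz * dz < p.rCut2) s += pairEps(sib, i, j, p);
  }
  return s;
}

}  // namespace

// [[Rcpp::export(name = ".mcRunCpp")]]
List mcRunCpp(NumericMatrix pos0, IntegerVector rho0, IntegerVector sibIdx,
              List par, int nEquil, int nSample, int stride,
              bool keepFrames) {
  Par p;
  p.n = pos0.nrow();
  double sigma = as<double>(par["sigma"]);
  p.sigma2 = sigma * sigma;
  p.epsLJ = as<double>(par["epsLJ"]);
  p.kSpring = as<double>(par["kSpring"]);
  p.q0 = as<double>(par["q0"]);
  p.mu = as<double>(par["mu"]);
  p.epsS = as<double>(par["epsS"]);
  p.epsW = as<double>(par["epsW"]);
  double rCut = as<double>(par["rCut"]);
  p.rCut2 = rCut * rCut;
  p.wcaCut2 = std::pow(2.0, 1.0 / 3.0) * p.sigma2;  // (2^{1/6} sigma)^2
  p.maxDisp = as<double>(par["maxDisp"]);
  p.chainAdj = as<bool>(par["includeChainAdjacent"]);
  const bool hasContact = (p.epsS != 0.0 || p.epsW != 0.0);
  const double coincide2 = 1e-12 * p.sigma2;  // reject r < 1e-6 sigma
  const double wcaCut = std::sqrt(p.wcaCut2);
  const double rCutLen = std::sqrt(p.rCut2);
  // a pair whose old x-separation exceeds every cutoff plus the largest
  // possible single-move displacement cannot change any energy term
  const double cutMax = hasContact ? std::max(wcaCut, rCutLen) : wcaCut;
  const double farCut = cutMax + 1.7320508075688772 * p.maxDisp;

  std::vector<double> x(p.n), y(p.n), z(p.n);
  std::vector<int> rho(p.n), sib(p.n, 0);
  for (int i = 0; i < p.n; ++i) {
    x[i] = pos0(i, 0); y[i] = pos0(i, 1); z[i] = pos0(i, 2);
    rho[i] = rho0[i];
  }
  for (int k = 0; k < sibIdx.size(); ++k) sib[sibIdx[k] - 1] = 1;

  double E = fullEnergy(x, y, z, rho, sib, p);

  int nKept = nSample / stride;
  IntegerMatrix rhoSamp(nKept, p.n);
  NumericVector rgSamp(nKept), eSamp(nKept), eCheck(nKept);
  IntegerVector weakSamp(nKept);
  NumericVector frames =
      keepFrames ? NumericVector(Dimension(nKept, p.n, 3)) : NumericVector(0);

  long totalSteps = (long)nEquil + nSample;
  int kept = 0;
  for (long step = 1; step <= totalSteps; ++step) {
    for (int t = 0; t < p.n; ++t) {
      // --- displacement trial ---
      {
        int i = randIndex(p.n);
        double nx = x[i] + p.maxDisp * (2.0 * unif_rand() - 1.0);
        double ny = y[i] + p.maxDisp * (2.0 * unif_rand() - 1.0);
        double nz = z[i] + p.maxDisp * (2.0 * unif_rand() - 1.0);
        bool clash = false;
        double dE = 0.0;
        const double xi = x[i], yi = y[i], zi = z[i];
        const bool doContact = hasContact && rho[i];
        for (int j = 0; j < p.n; ++j) {
          if (j == i) continue;
          const double xj = x[j];
          if (xj - xi > farCut || xi - xj > farCut) continue;
          double dxn = nx - xj, dyn = ny - y[j], dzn = nz - z[j];
          double r2n = dxn * dxn + dyn * dyn + dzn * dzn;
          if (r2n < coincide2) { clash = true; break; }
          double dxo = xi - xj, dyo = yi - y[j], dzo = zi - z[j];
          double r2o = dxo * dxo + dyo * dyo + dzo * dzo;
          dE += wca(r2n, p) - wca(r2o, p);
          if (doContact && rho[j] && (p.chainAdj || std::abs(j - i) > 1)) {
            bool inNew = r2n < p.rCut2, inOld = r2o < p.rCut2;
            if (inNew != inOld) {
              double e = pairEps(sib, i, j, p);
              dE += inNew ? -e : e;
            }
          }
        }
        if (!clash) {
          if (i > 0) {
            double qo = std::sqrt(dist2(x, y, z, i, i - 1)) - p.q0;
            double dxn = nx - x[i - 1], dyn = ny - y[i - 1],
                   dzn = nz - z[i - 1];
            double qn =
                std::sqrt(dxn * dxn + dyn * dyn + dzn * dzn) - p.q0;
            dE += 0.5 * p.kSpring * (qn * qn - qo * qo);
          }
          if (i + 1 < p.n) {
            double qo = std::sqrt(dist2(x, y, z, i, i + 1)) - p.q0;
            double dxn = nx - x[i + 1], dyn = ny - y[i + 1],
                   dzn = nz - z[i + 1];
            double qn =
                std::sqrt(dxn * dxn + dyn * dyn + dzn * dzn) - p.q0;
            dE += 0.5 * p.kSpring * (qn * qn - qo * qo);
          }
          if (accept(dE)) {
            x[i] = nx; y[i] = ny; z[i] = nz;
            E += dE;
          }
        }
      }
      // --- nucleosome flip trial ---
      {
        int i = randIndex(p.n);
        double gain = rho[i] ? -1.0 : 1.0;  // change in rho_i
        double dE = gain * p.mu;
        if (hasContact)
          dE -= gain * contactSum(x, y, z, rho, sib, p, i, x[i], y[i], z[i]);
        if (accept(dE)) {
          rho[i] = 1 - rho[i];
          E += dE;
        }
      }
    }
    if (step > nEquil) {
      long s = step - nEquil;
      if (s % stride == 0 && kept < nKept) {
        for (int i = 0; i < p.n; ++i) rhoSamp(kept, i) = rho[i];
        rgSamp[kept] = radiusGyr(x, y, z, p.n);
        weakSamp[kept] = weakContacts(x, y, z, rho, sib, p);
        eSamp[kept] = E;
        eCheck[kept] = fullEnergy(x, y, z, rho, sib, p);
        if (keepFrames) {
          for (int i = 0; i < p.n; ++i) {
            frames[kept + nKept * i] = x[i];
            frames[kept + nKept * (i + p.n)] = y[i];
            frames[kept + nKept * (i + 2 * p.n)] = z[i];
          }
        }
        ++kept;
      }
    }
    if (step % 512 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix finalPos(p.n, 3);
  IntegerVector finalRho(p.n);
  for (int i = 0; i < p.n; ++i) {
    finalPos(i, 0) = x[i]; finalPos(i, 1) = y[i]; finalPos(i, 2) = z[i];
    finalRho[i] = rho[i];
  }
  return List::create(
      _["rho"] = rhoSamp, _["rg"] = rgSamp, _["nWeak"] = weakSamp,
      _["energy"] = eSamp, _["energyCheck"] = eCheck,
      _["frames"] = frames, _["finalPos"] = finalPos,
      _["finalRho"] = finalRho);
}
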