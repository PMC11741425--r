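// Deterministic / stochastic evolution of the joint A-repeat and B-string
// length distributions under substitution and indel transition rules.
//
// Bins are unit lengths 1..LB (C index i = L - 1).  All per-process
// expected count changes are computed from the pre-step state and applied
// simultaneously (Jacobi update).  Gains above the boundary reflect onto
// the boundary bin.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// process ids (rows of the flux matrices)
enum Proc {
  P_SUB_LEN = 0, P_SUB_SHO, P_SUB_FIS, P_SUB_FUS, P_EXP, P_CON,
  P_INS_FIS, P_BDEL_FUS, P_CRE_A1, P_DES_A1, P_B_INS, P_B_DEL,
  N_PROC
};

struct Rates {
  double muLen, muSho, muFis, muFus, muCre, muDes, bIns, bDel, b1Del;
  std::vector<double> eps, kap, iot;
};

struct Work {
  int LB;
  // detail: per-process rows [p * LB + i]; otherwise every process
  // accumulates into row 0 (stride 0), which is all the evolve loop needs
  int stride;
  std::vector<double> finA, foutA, finB, foutB;
  std::vector<double> h, convA, convB, suf; // scratch
  explicit Work(int LB_, bool detail) : LB(LB_),
    stride(detail ? LB_ : 0),
    finA(N_PROC * LB_), foutA(N_PROC * LB_),
    finB(N_PROC * LB_), foutB(N_PROC * LB_),
    h(2 * LB_), convA(2 * LB_), convB(2 * LB_), suf(2 * LB_ + 2) {}
  int rows() const { return stride ? N_PROC : 1; }
  void zero() {
    size_t used = (size_t)rows() * LB;
    std::fill(finA.begin(), finA.begin() + used, 0.0);
    std::fill(foutA.begin(), foutA.begin() + used, 0.0);
    std::fill(finB.begin(), finB.begin() + used, 0.0);
    std::fill(foutB.begin(), foutB.begin() + used, 0.0);
  }
};

// Occupancy-weighted ordered-pair length convolution of N with itself
// (weights below 1e-15 of the total contribute nothing detectable to the
// per-bin fluxes and are skipped).
static void pair_conv(const double* N, int LB, std::vector<double>& conv) {
  std::fill(conv.begin(), conv.end(), 0.0);
  double S = 0.0;
  for (int i = 0; i < LB; ++i) S += N[i];
  if (S <= 0.0) return;
  double invS = 1.0 / S;
  for (int i = 0; i < LB; ++i) {
    double wi = N[i] * invS;
    if (wi < 1e-15) continue;
    for (int j = 0; j < LB; ++j) {
      double wj = N[j] * invS;
      if (wj >= 1e-15) conv[i + j] += wi * wj;
    }
  }
}

// Fusion of two strings sampled from N (occupancy-weighted ordered
// pairs, precomputed in conv); target unit length = j + k + 1 + offset
// for unit lengths j, k.
// offset = 1: substitution fusion / A1-loss (the mutated unit joins the
// product); offset = 0: single-unit deletion fusion.
// mode 0: remove the expected fractions at the sampled pair;
// mode 1: remove two counts evenly from all bins the product could have
//         drawn from (the per-event phrasing of the update rule).
static void fuse(const double* N, const std::vector<double>& conv,
                 double* fin, double* fout, double E,
                 int offset, int mode, int LB, Work& w,
                 const double* fN) {
  if (E <= 0.0) return;
  double S = 0.0;
  for (int i = 0; i < LB; ++i) S += N[i];
  if (S <= 0.0) return;
  double invS = 1.0 / S;
  for (int t = 0; t <= 2 * (LB - 1); ++t) {
    if (conv[t] == 0.0) continue;
    int tgt = t + 1 + offset;            // c-index of product bin
    if (tgt > LB - 1) tgt = LB - 1;      // reflective boundary
    fin[tgt] += E * conv[t];
  }
  if (mode == 0) {
    for (int i = 0; i < LB; ++i)
      fout[i] += 2.0 * E * N[i] * invS * (fN ? fN[i] : 1.0);
  } else {
    // product from t removes two counts evenly over bins 1..t+1 (units)
    std::vector<double>& suf = w.suf;
    int T = 2 * (LB - 1);
    suf[T + 1] = 0.0;
    for (int t = T; t >= 0; --t)
      suf[t] = suf[t + 1] + 2.0 * E * conv[t] / (double)(t + 1);
    for (int b = 0; b < LB && b <= T; ++b) fout[b] += suf[b];
  }
}

// fA / fB: optional per-source-bin event scaling (the super-linear
// limiter); null means no scaling.
static void step_core(const double* A, const double* B, const Rates& R,
                      double s, int fusionMode, Work& w,
                      const double* fA, const double* fB) {
  const int LB = w.LB;
  const int stride = w.stride;
  w.zero();
  double* finA = w.finA.data();  double* foutA = w.foutA.data();
  double* finB = w.finB.data();  double* foutB = w.foutB.data();
  std::vector<double>& h = w.h;
  std::vector<double>& suf = w.suf;

  // --- lengthening substitutions -----------------------------------------
  // Target: the two boundary-adjacent B units per repeat, restricted to
  // those in the A-B-B trinucleotide context that defines the measured
  // rate; a boundary B unit belonging to a length-1 B string sits in the
  // A-B-A fusion context instead, so the per-repeat target of two is
  // scaled by the fraction of B-string ends with another B inside.
  {
    double SB = 0.0, SB2 = 0.0;
    for (int i = 0; i < LB; ++i) SB += B[i];
    for (int i = 1; i < LB; ++i) SB2 += B[i];
    double avail = SB > 0.0 ? SB2 / SB : 0.0;
    double* fo = foutA + P_SUB_LEN * stride;
    double* fi = finA + P_SUB_LEN * stride;
    double E = 0.0;
    for (int i = 0; i < LB; ++i) {
      double e = s * 2.0 * R.muLen * avail * A[i] * (fA ? fA[i] : 1.0);
      if (e == 0.0) continue;
      fo[i] += e;
      fi[i + 1 > LB - 1 ? LB - 1 : i + 1] += e;
      E += e;
    }
    // mirrored B-string shortening, allocated over bins l >= 2
    if (E > 0.0) {
      if (SB2 > 0.0) {
        double* bo = foutB + P_SUB_LEN * stride;
        double* bi = finB + P_SUB_LEN * stride;
        for (int i = 1; i < LB; ++i) {
          double e = E * B[i] / SB2;
          bo[i] += e;
          bi[i - 1] += e;
        }
      }
    }
  }

  // --- shortening substitutions: target size 2 per repeat (L >= 2) -----
  {
    double* fo = foutA + P_SUB_SHO * stride;
    double* fi = finA + P_SUB_SHO * stride;
    double E = 0.0;
    for (int i = 1; i < LB; ++i) {
      double e = s * 2.0 * R.muSho * A[i] * (fA ? fA[i] : 1.0);
      if (e == 0.0) continue;
      fo[i] += e;
      fi[i - 1] += e;
      E += e;
    }
    // mirrored B-string lengthening over all occupied B bins
    if (E > 0.0) {
      double SB = 0.0;
      for (int i = 0; i < LB; ++i) SB += B[i];
      if (SB > 0.0) {
        double* bo = foutB + P_SUB_SHO * stride;
        double* bi = finB + P_SUB_SHO * stride;
        for (int i = 0; i < LB; ++i) {
          double e = E * B[i] / SB;
          if (e == 0.0) continue;
          bo[i] += e;
          bi[i + 1 > LB - 1 ? LB - 1 : i + 1] += e;
        }
      }
    }
  }

  // --- fission substitutions: target size L - 2 per repeat -------------
  {
    double* fo = foutA + P_SUB_FIS * stride;
    double* fi = finA + P_SUB_FIS * stride;
    double E = 0.0;
    std::fill(h.begin(), h.begin() + LB, 0.0);
    for (int i = 2; i < LB; ++i) {          // L >= 3
      double e = s * R.muFis * (double)(i - 1) * A[i] * (fA ? fA[i] : 1.0);
      if (e == 0.0) continue;
      fo[i] += e;
      h[i] = 2.0 * e / (double)(i - 1);     // even spread over bins <= L-2
      E += e;
    }
    if (E > 0.0) {
      suf[LB] = 0.0;
      for (int i = LB - 1; i >= 0; --i) suf[i] = suf[i + 1] + h[i];
      for (int b = 0; b + 2 < LB; ++b) fi[b] += suf[b + 2];
      finB[P_SUB_FIS * stride + 0] += E;        // interrupting unit becomes a B1
    }
  }

  // --- fusion substitutions: proportional to the B1 count --------------
  if ((R.muFus > 0.0 || R.b1Del > 0.0) && B[0] > 0.0)
    pair_conv(A, LB, w.convA);
  {
    double E = s * R.muFus * B[0] * (fB ? fB[0] : 1.0);
    fuse(A, w.convA, finA + P_SUB_FUS * stride, foutA + P_SUB_FUS * stride,
         E, 1, fusionMode, LB, w, fA);
    foutB[P_SUB_FUS * stride + 0] += E;
  }

  // --- expansions: per-repeat target size L ----------------------------
  {
    double* fo = foutA + P_EXP * stride;
    double* fi = finA + P_EXP * stride;
    for (int i = 0; i < LB; ++i) {
      double e = s * R.eps[i] * (double)(i + 1) * A[i] * (fA ? fA[i] : 1.0);
      if (e == 0.0) continue;
      fo[i] += e;
      fi[i + 1 > LB - 1 ? LB - 1 : i + 1] += e;
    }
  }

  // --- contractions: per-repeat target size L (L >= 2) ------------------
  {
    double* fo = foutA + P_CON * stride;
    double* fi = finA + P_CON * stride;
    for (int i = 1; i < LB; ++i) {
      double e = s * R.kap[i] * (double)(i + 1) * A[i] * (fA ? fA[i] : 1.0);
      if (e == 0.0) continue;
      fo[i] += e;
      fi[i - 1] += e;
    }
  }

  // --- non-motif insertion fission: per-repeat target size L (L >= 2) ---
  {
    double* fo = foutA + P_INS_FIS * stride;
    double* fi = finA + P_INS_FIS * stride;
    double E = 0.0;
    std::fill(h.begin(), h.begin() + LB, 0.0);
    for (int i = 1; i < LB; ++i) {
      double e = s * R.iot[i] * (double)(i + 1) * A[i] * (fA ? fA[i] : 1.0);
      if (e == 0.0) continue;
      fo[i] += e;
      h[i] = 2.0 * e / (double)i;           // even spread over bins <= L-1
      E += e;
    }
    if (E > 0.0) {
      suf[LB] = 0.0;
      for (int i = LB - 1; i >= 0; --i) suf[i] = suf[i + 1] + h[i];
      for (int b = 0; b + 1 < LB; ++b) fi[b] += suf[b + 1];
      finB[P_INS_FIS * stride + 0] += E;
    }
  }

  // --- B1-deletion fusion ----------------------------------------------
  {
    double E = s * R.b1Del * B[0] * (fB ? fB[0] : 1.0);
    fuse(A, w.convA, finA + P_BDEL_FUS * stride, foutA + P_BDEL_FUS * stride,
         E, 0, fusionMode, LB, w, fA);
    foutB[P_BDEL_FUS * stride + 0] += E;
  }

  // --- A1 creation (B-string fission) ------------------------------------
  {
    double* fo = foutB + P_CRE_A1 * stride;
    double* fi = finB + P_CRE_A1 * stride;
    double E = 0.0;
    std::fill(h.begin(), h.begin() + LB, 0.0);
    for (int i = 2; i < LB; ++i) {          // B string of length >= 3
      double e = s * R.muCre * (double)(i - 1) * B[i] * (fB ? fB[i] : 1.0);
      if (e == 0.0) continue;
      fo[i] += e;
      h[i] = 2.0 * e / (double)(i - 1);
      E += e;
    }
    if (E > 0.0) {
      suf[LB] = 0.0;
      for (int i = LB - 1; i >= 0; --i) suf[i] = suf[i + 1] + h[i];
      for (int b = 0; b + 2 < LB; ++b) fi[b] += suf[b + 2];
      finA[P_CRE_A1 * stride + 0] += E;
    }
  }

  // --- A1 loss (B-string fusion) -----------------------------------------
  {
    double E = s * R.muDes * A[0] * (fA ? fA[0] : 1.0);
    if (E > 0.0) pair_conv(B, LB, w.convB);
    fuse(B, w.convB, finB + P_DES_A1 * stride, foutB + P_DES_A1 * stride,
         E, 1, fusionMode, LB, w, fB);
    foutA[P_DES_A1 * stride + 0] += E;
  }

  // --- B insertions / deletions (length-independent per-unit rates) -----
  {
    double* fo = foutB + P_B_INS * stride;
    double* fi = finB + P_B_INS * stride;
    for (int i = 0; i < LB; ++i) {
      double e = s * R.bIns * (double)(i + 1) * B[i] * (fB ? fB[i] : 1.0);
      if (e == 0.0) continue;
      fo[i] += e;
      fi[i + 1 > LB - 1 ? LB - 1 : i + 1] += e;
    }
  }
  {
    double* fo = foutB + P_B_DEL * stride;
    double* fi = finB + P_B_DEL * stride;
    for (int i = 1; i < LB; ++i) {
      double e = s * R.bDel * (double)(i + 1) * B[i] * (fB ? fB[i] : 1.0);
      if (e == 0.0) continue;
      fo[i] += e;
      fi[i - 1] += e;
    }
  }
}

// One step with the super-linear limiter: when a bin's total outflux
// exceeds half its stock (possible only outside the linear-mutation
// bound, i.e. during high-r burn-in stages), all event magnitudes
// sourced from that bin are scaled down proportionally and the step is
// recomputed.  Inside the linear regime no bin trips the limiter and the
// single unscaled pass is used bit-for-bit.
static bool limited_step(const double* A, const double* B, const Rates& R,
                         double s, int fusionMode, Work& w,
                         std::vector<double>& fA, std::vector<double>& fB) {
  const int LB = w.LB;
  step_core(A, B, R, s, fusionMode, w, nullptr, nullptr);
  const int nr = w.rows();
  bool limit = false;
  for (int i = 0; i < LB; ++i) {
    double outA = 0, outB = 0;
    for (int p = 0; p < nr; ++p) {
      outA += w.foutA[p * LB + i];
      outB += w.foutB[p * LB + i];
    }
    if (outA > 0.5 * A[i]) { limit = true; break; }
    if (outB > 0.5 * B[i]) { limit = true; break; }
  }
  if (!limit) return false;
  fA.assign(LB, 1.0);
  fB.assign(LB, 1.0);
  for (int i = 0; i < LB; ++i) {
    double outA = 0, outB = 0;
    for (int p = 0; p < nr; ++p) {
      outA += w.foutA[p * LB + i];
      outB += w.foutB[p * LB + i];
    }
    if (outA > 0.5 * A[i]) fA[i] = 0.5 * A[i] / outA;
    if (outB > 0.5 * B[i]) fB[i] = 0.5 * B[i] / outB;
  }
  step_core(A, B, R, s, fusionMode, w, fA.data(), fB.data());
  return true;
}

static Rates parse_rates(const List& rates, int LB) {
  Rates R;
  R.muLen = as<double>(rates["lengthen"]);
  R.muSho = as<double>(rates["shorten"]);
  R.muFis = as<double>(rates["fission"]);
  R.muFus = as<double>(rates["fusion"]);
  R.muCre = as<double>(rates["createA1"]);
  R.muDes = as<double>(rates["destroyA1"]);
  R.bIns = as<double>(rates["bInsert"]);
  R.bDel = as<double>(rates["bDelete"]);
  R.b1Del = as<double>(rates["b1DeleteFusion"]);
  R.eps = as<std::vector<double> >(rates["expansion"]);
  R.kap = as<std::vector<double> >(rates["contraction"]);
  R.iot = as<std::vector<double> >(rates["insertion"]);
  if ((int)R.eps.size() != LB || (int)R.kap.size() != LB ||
      (int)R.iot.size() != LB)
    stop("rate curves must have length LBoundary");
  return R;
}

// Apply one aggregated step.  Returns updated state and the per-process
// flux matrices (rows = processes, cols = length bins).
// [[Rcpp::export]]
List kernel_step_cpp(NumericVector countsA, NumericVector countsB,
                     List rates, double scale, int fusionMode,
                     bool stochastic, bool clampNegative) {
  const int LB = countsA.size();
  if (countsB.size() != LB) stop("countsA and countsB must match");
  Rates R = parse_rates(rates, LB);
  Work w(LB, true);
  std::vector<double> fA, fB;
  if (clampNegative || stochastic)
    limited_step(REAL(countsA), REAL(countsB), R, scale, fusionMode, w,
                 fA, fB);
  else
    step_core(REAL(countsA), REAL(countsB), R, scale, fusionMode, w,
              nullptr, nullptr);

  NumericVector newA(LB), newB(LB);
  for (int i = 0; i < LB; ++i) {
    double inA = 0, outA = 0, inB = 0, outB = 0;
    for (int p = 0; p < N_PROC; ++p) {
      inA += w.finA[p * LB + i];  outA += w.foutA[p * LB + i];
      inB += w.finB[p * LB + i];  outB += w.foutB[p * LB + i];
    }
    double a, b;
    if (stochastic) {
      a = countsA[i] - R::rpois(outA) + R::rpois(inA);
      b = countsB[i] - R::rpois(outB) + R::rpois(inB);
      if (a < 0) a = 0;
      if (b < 0) b = 0;
    } else {
      a = countsA[i] - outA + inA;
      b = countsB[i] - outB + inB;
      if (a < 0 || b < 0) {
        if (!clampNegative)
          stop("negative count produced at bin %d: linear-mutation bound violated", i + 1);
        if (a < 0) a = 0;
        if (b < 0) b = 0;
      }
    }
    newA[i] = a;
    newB[i] = b;
  }
  auto mat = [&](std::vector<double>& v) {
    NumericMatrix m(N_PROC, LB);
    for (int p = 0; p < N_PROC; ++p)
      for (int i = 0; i < LB; ++i) m(p, i) = v[p * LB + i];
    return m;
  };
  return List::create(_["countsA"] = newA, _["countsB"] = newB,
                      _["fluxInA"] = mat(w.finA), _["fluxOutA"] = mat(w.foutA),
                      _["fluxInB"] = mat(w.finB), _["fluxOutB"] = mat(w.foutB));
}

// Progressive-schedule evolution.  rExp / nIter give the stages (rates are
// multiplied by 10^rExp[k] for nIter[k] iterations); a boundary-bin count
// above boundaryTrigger advances to the next stage.  Snapshots of the
// state are recorded every snapshotEvery generations (0 = none).
// [[Rcpp::export]]
List kernel_evolve_cpp(NumericVector countsA, NumericVector countsB,
                       List rates, IntegerVector rExp, NumericVector nIter,
                       double boundaryTrigger, int fusionMode,
                       bool stochastic, double snapshotEvery,
                       double gen0) {
  const int LB = countsA.size();
  Rates R = parse_rates(rates, LB);
  Work w(LB, false);
  std::vector<double> A(REAL(countsA), REAL(countsA) + LB);
  std::vector<double> B(REAL(countsB), REAL(countsB) + LB);
  double gen = gen0;
  double nextSnap = snapshotEvery > 0
    ? (std::floor(gen / snapshotEvery) + 1.0) * snapshotEvery : -1.0;
  std::vector<double> snaps;      // gen, A..., B... per row
  int nSnaps = 0;
  bool triggered = false;
  std::vector<double> fA, fB;

  for (int k = 0; k < rExp.size(); ++k) {
    double s = std::pow(10.0, (double)rExp[k]);
    double iters = nIter[k];
    for (double it = 0; it < iters; ++it) {
      limited_step(A.data(), B.data(), R, s, fusionMode, w, fA, fB);
      double totA = 0.0;
      for (int i = 0; i < LB; ++i) {
        double inA = w.finA[i], outA = w.foutA[i];
        double inB = w.finB[i], outB = w.foutB[i];
        double a, b;
        if (stochastic) {
          a = A[i] - R::rpois(outA) + R::rpois(inA);
          b = B[i] - R::rpois(outB) + R::rpois(inB);
        } else {
          a = A[i] - outA + inA;
          b = B[i] - outB + inB;
        }
        A[i] = a < 0 ? 0 : a;
        B[i] = b < 0 ? 0 : b;
        totA += A[i];
      }
      gen += s;
      if (snapshotEvery > 0 && gen >= nextSnap && nSnaps < 5000) {
        snaps.push_back(gen);
        snaps.insert(snaps.end(), A.begin(), A.end());
        snaps.insert(snaps.end(), B.begin(), B.end());
        ++nSnaps;
        nextSnap = (std::floor(gen / snapshotEvery) + 1.0) * snapshotEvery;
      }
      if (A[LB - 1] > boundaryTrigger) { triggered = true; break; }
      if (!std::isfinite(totA) || totA > 1e300) { triggered = true; break; }
    }
  }

  NumericMatrix snapMat(nSnaps, 1 + 2 * LB);
  for (int r = 0; r < nSnaps; ++r)
    for (int c = 0; c < 1 + 2 * LB; ++c)
      snapMat(r, c) = snaps[(size_t)r * (1 + 2 * LB) + c];
  return List::create(
    _["countsA"] = NumericVector(A.begin(), A.end()),
    _["countsB"] = NumericVector(B.begin(), B.end()),
    _["generation"] = gen,
    _["boundaryFlag"] = !(A[LB - 1] < 1000.0),
    _["triggered"] = triggered,
    _["snapshots"] = snapMat);
}
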