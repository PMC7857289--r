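// Steady-state solver for the branched anthocyanin pathway model.
//
// The network has a cascade structure that the solver exploits:
//   (1) influx v_in = v_CHS(PCoA) is a constant of the model (PCoA fixed);
//   (2) cha and nar are consumed by single-substrate enzymes, so their
//       steady-state values follow from inverting the Michaelis-Menten law;
//   (3) the dihydroflavonols (DHK, DHQ, DHM) form a 3-species nonlinear core
//       coupled through substrate competition at F3'5'H, DFR and FLS,
//       solved by damped Newton with an analytic Jacobian and a
//       pseudo-transient integration fallback;
//   (4) the leucoanthocyanidins (LCP, LCC, LCD) compete only for ANS with
//       known input fluxes, which admits a closed form;
//   (5) each end product equals its branch flux divided by ksink.
//
// Parameter vector layout (length 40), fixed by the R side:
//  0 k_CHS_PCoA   1 Km_CHS_PCoA   2 CHSt
//  3 k_CHI_cha    4 Km_CHI_cha    5 CHIt
//  6 k_F3H_nar    7 Km_F3H_nar    8 F3Ht
//  9 k_F3pH_DHK  10 Km_F3pH_DHK  11 F3pHt
// 12 k_F35pH_DHK 13 Km_F35pH_DHK 14 k_F35pH_DHQ 15 Km_F35pH_DHQ 16 F35pHt
// 17 k_DFR_DHK   18 Km_DFR_DHK   19 k_DFR_DHQ   20 Km_DFR_DHQ
// 21 k_DFR_DHM   22 Km_DFR_DHM   23 DFRt
// 24 k_FLS_DHK   25 Km_FLS_DHK   26 k_FLS_DHQ   27 Km_FLS_DHQ
// 28 k_FLS_DHM   29 Km_FLS_DHM   30 FLSt
// 31 k_ANS_LCP   32 Km_ANS_LCP   33 k_ANS_LCC   34 Km_ANS_LCC
// 35 k_ANS_LCD   36 Km_ANS_LCD   37 ANSt
// 38 PCoA        39 ksink
//
// Status codes: 0 ok; 1 upstream capacity infeasible (CHI/F3H Vmax <= v_in);
// 2 dihydroflavonol core did not converge; 3 ANS capacity infeasible.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct CorePars {
  double VmP, KmP;                         // F3'H on DHK
  bool twoSub;                             // F3'5'H acts on DHK as well as DHQ
  double A35K, Km35K, A35Q, Km35Q;         // F3'5'H (A = Et * kcat)
  double AdK, KmdK, AdQ, KmdQ, AdM, KmdM;  // DFR
  double AfK, KmfK, AfQ, KmfQ, AfM, KmfM;  // FLS
  double vin;
};

struct CoreFlux {
  double vP, v35K, v35Q, vdK, vdQ, vdM, vfK, vfQ, vfM;
};

inline void core_fluxes(const CorePars& P, const double c[3], CoreFlux& F) {
  const double u35K = P.twoSub ? c[0] / P.Km35K : 0.0;
  const double u35Q = c[1] / P.Km35Q;
  const double D35 = 1.0 + u35K + u35Q;
  F.v35K = P.twoSub ? P.A35K * u35K / D35 : 0.0;
  F.v35Q = P.A35Q * u35Q / D35;

  const double udK = c[0] / P.KmdK, udQ = c[1] / P.KmdQ, udM = c[2] / P.KmdM;
  const double Dd = 1.0 + udK + udQ + udM;
  F.vdK = P.AdK * udK / Dd;
  F.vdQ = P.AdQ * udQ / Dd;
  F.vdM = P.AdM * udM / Dd;

  const double ufK = c[0] / P.KmfK, ufQ = c[1] / P.KmfQ, ufM = c[2] / P.KmfM;
  const double Df = 1.0 + ufK + ufQ + ufM;
  F.vfK = P.AfK * ufK / Df;
  F.vfQ = P.AfQ * ufQ / Df;
  F.vfM = P.AfM * ufM / Df;

  F.vP = P.VmP * c[0] / (P.KmP + c[0]);
}

inline void core_residual(const CorePars& P, const double c[3], double f[3],
                          CoreFlux& F) {
  core_fluxes(P, c, F);
  f[0] = P.vin - F.vP - F.v35K - F.vdK - F.vfK;
  f[1] = F.vP - F.v35Q - F.vdQ - F.vfQ;
  f[2] = F.v35K + F.v35Q - F.vdM - F.vfM;
}

// d/dc_l of v_i = A_i * (c_i/Km_i) / D, D = 1 + sum_j c_j/Km_j
inline double dcomp(double A, double u_i, double Km_l, double D, bool diag) {
  return (A / Km_l) * ((diag ? D : 0.0) - u_i) / (D * D);
}

void core_jacobian(const CorePars& P, const double c[3], double J[3][3]) {
  const double u35K = P.twoSub ? c[0] / P.Km35K : 0.0;
  const double u35Q = c[1] / P.Km35Q;
  const double D35 = 1.0 + u35K + u35Q;
  const double udK = c[0] / P.KmdK, udQ = c[1] / P.KmdQ, udM = c[2] / P.KmdM;
  const double Dd = 1.0 + udK + udQ + udM;
  const double ufK = c[0] / P.KmfK, ufQ = c[1] / P.KmfQ, ufM = c[2] / P.KmfM;
  const double Df = 1.0 + ufK + ufQ + ufM;

  const double dP0 = P.VmP * P.KmP / ((P.KmP + c[0]) * (P.KmP + c[0]));

  // F3'5'H derivatives (substrates DHK [optional] and DHQ)
  double d35K[3] = {0, 0, 0}, d35Q[3] = {0, 0, 0};
  if (P.twoSub) {
    d35K[0] = dcomp(P.A35K, u35K, P.Km35K, D35, true);
    d35K[1] = dcomp(P.A35K, u35K, P.Km35Q, D35, false);
    d35Q[0] = dcomp(P.A35Q, u35Q, P.Km35K, D35, false);
  }
  d35Q[1] = dcomp(P.A35Q, u35Q, P.Km35Q, D35, true);

  const double KmD[3] = {P.KmdK, P.KmdQ, P.KmdM};
  const double uD[3] = {udK, udQ, udM};
  const double AD[3] = {P.AdK, P.AdQ, P.AdM};
  const double KmF[3] = {P.KmfK, P.KmfQ, P.KmfM};
  const double uF[3] = {ufK, ufQ, ufM};
  const double AF[3] = {P.AfK, P.AfQ, P.AfM};

  double dD[3][3], dF[3][3];
  for (int i = 0; i < 3; ++i)
    for (int l = 0; l < 3; ++l) {
      dD[i][l] = dcomp(AD[i], uD[i], KmD[l], Dd, i == l);
      dF[i][l] = dcomp(AF[i], uF[i], KmF[l], Df, i == l);
    }

  for (int l = 0; l < 3; ++l) {
    const double dPl = (l == 0) ? dP0 : 0.0;
    J[0][l] = -dPl - d35K[l] - dD[0][l] - dF[0][l];
    J[1][l] = dPl - d35Q[l] - dD[1][l] - dF[1][l];
    J[2][l] = d35K[l] + d35Q[l] - dD[2][l] - dF[2][l];
  }
}

bool solve3(const double A[3][3], const double b[3], double x[3]) {
  const double det = A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1]) -
                     A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0]) +
                     A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
  if (!std::isfinite(det) || std::fabs(det) < 1e-300) return false;
  x[0] = (b[0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1]) -
          A[0][1] * (b[1] * A[2][2] - A[1][2] * b[2]) +
          A[0][2] * (b[1] * A[2][1] - A[1][1] * b[2])) / det;
  x[1] = (A[0][0] * (b[1] * A[2][2] - A[1][2] * b[2]) -
          b[0] * (A[1][0] * A[2][2] - A[1][2] * A[2][0]) +
          A[0][2] * (A[1][0] * b[2] - b[1] * A[2][0])) / det;
  x[2] = (A[0][0] * (A[1][1] * b[2] - b[1] * A[2][1]) -
          A[0][1] * (A[1][0] * b[2] - b[1] * A[2][0]) +
          b[0] * (A[1][0] * A[2][1] - A[1][1] * A[2][0])) / det;
  return std::isfinite(x[0]) && std::isfinite(x[1]) && std::isfinite(x[2]);
}

inline double norm_inf(const double f[3]) {
  double m = std::fabs(f[0]);
  if (std::fabs(f[1]) > m) m = std::fabs(f[1]);
  if (std::fabs(f[2]) > m) m = std::fabs(f[2]);
  return m;
}

bool newton_core(const CorePars& P, double c[3], double tol, int maxit) {
  double f[3];
  CoreFlux F;
  core_residual(P, c, f, F);
  double nrm = norm_inf(f);
  for (int it = 0; it < maxit && nrm > tol; ++it) {
    double J[3][3], dx[3];
    core_jacobian(P, c, J);
    const double b[3] = {-f[0], -f[1], -f[2]};
    if (!solve3(J, b, dx)) return false;
    double t = 1.0;
    bool ok = false;
    for (int h = 0; h < 50; ++h, t *= 0.5) {
      double ct[3];
      for (int i = 0; i < 3; ++i) {
        ct[i] = c[i] + t * dx[i];
        if (ct[i] < 0.0) ct[i] = c[i] * 0.1;  // keep iterates feasible
      }
      double ft[3];
      core_residual(P, ct, ft, F);
      const double nt = norm_inf(ft);
      if (std::isfinite(nt) && nt < nrm) {
        c[0] = ct[0]; c[1] = ct[1]; c[2] = ct[2];
        f[0] = ft[0]; f[1] = ft[1]; f[2] = ft[2];
        nrm = nt;
        ok = true;
        break;
      }
    }
    if (!ok) return false;
  }
  return nrm <= tol;
}

// Relaxation to the attracting steady state by explicit midpoint stepping
// with an adaptive step bound; used when Newton stalls far from the root.
bool pseudo_transient_core(const CorePars& P, double c[3], double tol) {
  double f[3];
  CoreFlux F;
  double dt = 1e-3;
  for (long step = 0; step < 200000; ++step) {
    core_residual(P, c, f, F);
    if (norm_inf(f) <= tol) return true;
    // adapt dt so relative change per step stays moderate
    double rel = 0.0;
    for (int i = 0; i < 3; ++i) {
      const double r = std::fabs(dt * f[i]) / (c[i] + 1e-8);
      if (r > rel) rel = r;
    }
    if (rel > 0.25) { dt *= 0.5; continue; }
    double cm[3], fm[3];
    for (int i = 0; i < 3; ++i) cm[i] = std::max(c[i] + 0.5 * dt * f[i], 0.0);
    core_residual(P, cm, fm, F);
    for (int i = 0; i < 3; ++i) {
      c[i] += dt * fm[i];
      if (c[i] < 0.0) c[i] = 0.0;
      if (c[i] > 1e9) return false;  // divergence: no finite steady state
    }
    dt = std::min(dt * 1.05, 1e3);
    // give Newton a chance to finish from the improved iterate
    if ((step & 1023) == 1023) {
      double ctry[3] = {c[0], c[1], c[2]};
      if (newton_core(P, ctry, tol, 30)) {
        c[0] = ctry[0]; c[1] = ctry[1]; c[2] = ctry[2];
        return true;
      }
    }
  }
  return false;
}

// Invert v = Vmax * S / (Km + S) for S at a prescribed flux.
// Returns -1 when Vmax <= flux (no steady state: the species accumulates).
inline double invert_mm(double Vmax, double Km, double flux) {
  if (flux <= 0.0) return 0.0;
  if (!(Vmax > flux)) return -1.0;
  return flux * Km / (Vmax - flux);
}

}  // namespace

// Linear chain: influx propagates unchanged; each intermediate from
// inverting its consuming MM law; pel = influx / ksink.
// Parameter layout (17): k/Km/Et for CHS, CHI, F3H, DFR, ANS; PCoA; ksink.
// [[Rcpp::export(name = ".c_steady_state_linear")]]
List c_steady_state_linear(NumericVector p) {
  if (p.size() != 17) stop("parameter vector must have length 17");
  NumericVector conc(6);
  const double PCoA = p[15], ksink = p[16];
  const double vin = p[2] * p[0] * PCoA / (p[1] + PCoA);
  conc[0] = PCoA;
  bool ok = true;
  for (int i = 0; i < 4 && ok; ++i) {
    const double s = invert_mm(p[3 * (i + 1) + 2] * p[3 * (i + 1)],
                               p[3 * (i + 1) + 1], vin);
    if (s < 0.0) ok = false; else conc[1 + i] = s;
  }
  if (ok) conc[5] = vin / ksink;
  else for (int i = 1; i < 6; ++i) conc[i] = NA_REAL;
  return List::create(_["converged"] = ok, _["status"] = ok ? 0 : 1,
                      _["conc"] = conc, _["vin"] = vin);
}

// [[Rcpp::export(name = ".c_steady_state_full")]]
List c_steady_state_full(NumericVector p, bool two_sub = true,
                         Nullable<NumericVector> core_guess = R_NilValue,
                         double tol = 1e-10) {
  if (p.size() != 40) stop("parameter vector must have length 40");
  NumericVector conc(15);
  NumericVector flux(21);
  int status = 0;

  const double PCoA = p[38], ksink = p[39];
  const double vin = p[2] * p[0] * PCoA / (p[1] + PCoA);
  const double atol = tol * std::max(1.0, vin);
  conc[0] = PCoA;
  flux[0] = vin;

  double cha = 0.0, nar = 0.0, core[3] = {0.0, 0.0, 0.0};
  CoreFlux F = {0, 0, 0, 0, 0, 0, 0, 0, 0};
  double lc[3] = {0.0, 0.0, 0.0};

  if (vin > 0.0) {
    cha = invert_mm(p[5] * p[3], p[4], vin);
    nar = invert_mm(p[8] * p[6], p[7], vin);
    if (cha < 0.0 || nar < 0.0) status = 1;

    if (status == 0) {
      CorePars P;
      P.VmP = p[11] * p[9]; P.KmP = p[10];
      P.twoSub = two_sub;
      P.A35K = p[16] * p[12]; P.Km35K = p[13];
      P.A35Q = p[16] * p[14]; P.Km35Q = p[15];
      P.AdK = p[23] * p[17]; P.KmdK = p[18];
      P.AdQ = p[23] * p[19]; P.KmdQ = p[20];
      P.AdM = p[23] * p[21]; P.KmdM = p[22];
      P.AfK = p[30] * p[24]; P.KmfK = p[25];
      P.AfQ = p[30] * p[26]; P.KmfQ = p[27];
      P.AfM = p[30] * p[28]; P.KmfM = p[29];
      P.vin = vin;

      if (core_guess.isNotNull()) {
        NumericVector g(core_guess);
        if (g.size() == 3 && g[0] >= 0 && g[1] >= 0 && g[2] >= 0) {
          core[0] = g[0]; core[1] = g[1]; core[2] = g[2];
        }
      }
      if (core[0] <= 0 && core[1] <= 0 && core[2] <= 0) {
        const double c0 = std::max(vin, 1e-6);
        core[0] = c0; core[1] = c0; core[2] = c0;
      }
      bool ok = newton_core(P, core, atol, 200);
      if (!ok) {
        core[0] = std::max(vin, 1e-6); core[1] = core[0]; core[2] = core[0];
        ok = pseudo_transient_core(P, core, atol) ||
             newton_core(P, core, atol, 200);
      }
      if (!ok) {
        status = 2;
      } else {
        core_residual(P, core, /*unused*/ lc, F);  // refresh fluxes
        lc[0] = lc[1] = lc[2] = 0.0;
        // ANS layer: competitive consumption at prescribed input fluxes
        const double J[3] = {F.vdK, F.vdQ, F.vdM};
        const double Aa[3] = {p[37] * p[31], p[37] * p[33], p[37] * p[35]};
        const double Kma[3] = {p[32], p[34], p[36]};
        double A = 0.0;
        for (int i = 0; i < 3; ++i) {
          if (J[i] > 0.0) {
            if (Aa[i] <= 0.0) { status = 3; break; }
            A += J[i] / Aa[i];
          }
        }
        if (status == 0 && A >= 1.0) status = 3;
        if (status == 0) {
          const double U = A / (1.0 - A);
          for (int i = 0; i < 3; ++i)
            lc[i] = (J[i] > 0.0) ? Kma[i] * J[i] * (1.0 + U) / Aa[i] : 0.0;
        }
      }
    }
  }

  conc[1] = cha; conc[2] = nar;
  conc[3] = core[0]; conc[4] = core[1]; conc[5] = core[2];
  conc[6] = lc[0]; conc[7] = lc[1]; conc[8] = lc[2];

  if (status == 0) {
    flux[1] = vin;            // CHI
    flux[2] = vin;            // F3H
    flux[3] = F.vP;           // F3'H
    flux[4] = F.v35K;         // F3'5'H on DHK
    flux[5] = F.v35Q;         // F3'5'H on DHQ
    flux[6] = F.vdK; flux[7] = F.vdQ; flux[8] = F.vdM;    // DFR
    flux[9] = F.vfK; flux[10] = F.vfQ; flux[11] = F.vfM;  // FLS
    flux[12] = F.vdK; flux[13] = F.vdQ; flux[14] = F.vdM; // ANS = DFR input
    conc[9] = F.vdK / ksink;   // pel
    conc[10] = F.vdQ / ksink;  // cya
    conc[11] = F.vdM / ksink;  // del
    conc[12] = F.vfK / ksink;  // kam
    conc[13] = F.vfQ / ksink;  // que
    conc[14] = F.vfM / ksink;  // myr
    for (int i = 0; i < 6; ++i) flux[15 + i] = ksink * conc[9 + i];
  } else {
    for (int i = 1; i < 15; ++i) conc[i] = NA_REAL;
    for (int i = 1; i < 21; ++i) flux[i] = NA_REAL;
  }

  return List::create(_["converged"] = (status == 0), _["status"] = status,
                      _["conc"] = conc, _["flux"] = flux, _["vin"] = vin);
}
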