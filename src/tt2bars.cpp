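// Dual-population (phosphorylated / non-phosphorylated) extension of the
// Ten Tusscher-Panfilov 2006 epicardial human ventricular myocyte model,
// with integrators for single cells, voltage clamp, and monodomain tissue.
//
// Units: mV, ms, mM, pA/pF (fluxes mM/ms), cm, cm^2/ms for diffusivity.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>
using namespace Rcpp;

// ---------------------------------------------------------------- constants
static const double Rgas = 8314.472;
static const double Frd  = 96485.3415;
static const double Tmp  = 310.0;
static const double RTF  = Rgas * Tmp / Frd;   // ~26.7 mV
static const double invRTF = 1.0 / RTF;

static const double Ko  = 5.4, Cao = 2.0, Nao = 140.0;
static const double Vc  = 0.016404, Vsr = 0.001094, Vss = 0.00005468;
static const double Bufc = 0.2,  Kbufc_c = 0.001;
static const double Bufsr = 10.0, Kbufsr = 0.3;
static const double Bufss = 0.4,  Kbufss = 0.00025;
static const double Vmaxup = 0.006375, Kup = 0.00025;
static const double Vrel = 0.102, k1p = 0.15, k2p = 0.045, k3c = 0.060,
                    k4c = 0.005, ECsr = 1.5, maxsr = 2.5, minsr = 1.0;
static const double Vleak = 0.00036, VxferC = 0.0038;
static const double CAP = 0.185;                // uF, TT2 cell capacitance
static const double GNa = 14.838, GK1 = 5.405, Gto = 0.294, GKr = 0.153,
                    GKs = 0.392, GCaL = 0.0000398, GbNa = 0.00029,
                    GbCa = 0.000592, GpCa = 0.1238, KpCa = 0.0005,
                    GpK = 0.0146;
static const double pKNa = 0.03, PNaK = 2.724, KmK = 1.0, KmNa = 40.0;
static const double kNaCa = 1000.0, KmNai = 87.5, KmCa = 1.38, ksat = 0.1,
                    gam = 0.35, aNaCa = 2.5;

// state layout
enum { iV = 0, iNai, iKi, iCai, iCaSS, iCaSR,
       im, ih, ij, ixr1, ixr2, ixs, ir, is_, id, if_, if2, ifca, iRb,
       ihP, ijP, idP, ifP, if2P, ixsP, iRbP, NSTATE };

// alpha (phosphorylation fraction) layout
enum { aNA = 0, aCAL, aKS, aPK, aNAK, aREL, aUP, aXFER, aBUFC, NTGT };

// voltage-gate layout for lookup tables
enum { gm = 0, gh, gj, gxr1, gxr2, gxs, gr, gs, gd, gf, gf2,
       ghP, gjP, gdP, gfP, gf2P, gxsP, NGATE };

struct Mods {
  double gNa_scale, h_shift, gCaL_scale, dff2_shift, dtau_speedup,
         ftau_slowdown, gKs_scale, xs_shift, xs_rate_scale, kmNa_scale,
         gpK_scale, pK_shift, gRel_scale, ryr_open_scale, ryr_close_scale,
         vXfer_scale, kUp_scale, vmaxUp_scale, kBufc_scale;
};

static Mods mods_from_list(List m) {
  Mods p;
  p.gNa_scale      = as<double>(m["gNa_scale"]);
  p.h_shift        = as<double>(m["h_shift"]);
  p.gCaL_scale     = as<double>(m["gCaL_scale"]);
  p.dff2_shift     = as<double>(m["dff2_shift"]);
  p.dtau_speedup   = as<double>(m["dtau_speedup"]);
  p.ftau_slowdown  = as<double>(m["ftau_slowdown"]);
  p.gKs_scale      = as<double>(m["gKs_scale"]);
  p.xs_shift       = as<double>(m["xs_shift"]);
  p.xs_rate_scale  = as<double>(m["xs_rate_scale"]);
  p.kmNa_scale     = as<double>(m["kmNa_scale"]);
  p.gpK_scale      = as<double>(m["gpK_scale"]);
  p.pK_shift       = as<double>(m["pK_shift"]);
  p.gRel_scale     = as<double>(m["gRel_scale"]);
  p.ryr_open_scale = as<double>(m["ryr_open_scale"]);
  p.ryr_close_scale= as<double>(m["ryr_close_scale"]);
  p.vXfer_scale    = as<double>(m["vXfer_scale"]);
  p.kUp_scale      = as<double>(m["kUp_scale"]);
  p.vmaxUp_scale   = as<double>(m["vmaxUp_scale"]);
  p.kBufc_scale    = as<double>(m["kBufc_scale"]);
  return p;
}

// ---------------------------------------------- baseline TT2 gate functions
// each fills ginf and tau for one voltage gate
static inline void rate_m(double V, double &ginf, double &tau) {
  double a = 1.0 / (1.0 + exp((-60.0 - V) / 5.0));
  double b = 0.1 / (1.0 + exp((V + 35.0) / 5.0)) +
             0.1 / (1.0 + exp((V - 50.0) / 200.0));
  double mi = 1.0 / (1.0 + exp((-56.86 - V) / 9.03));
  ginf = mi * mi; tau = a * b;
}
static inline void rate_h(double V, double &ginf, double &tau) {
  double hi = 1.0 / (1.0 + exp((V + 71.55) / 7.43));
  ginf = hi * hi;
  double a, b;
  if (V >= -40.0) { a = 0.0; b = 0.77 / (0.13 * (1.0 + exp(-(V + 10.66) / 11.1))); }
  else { a = 0.057 * exp(-(V + 80.0) / 6.8);
         b = 2.7 * exp(0.079 * V) + 3.1e5 * exp(0.3485 * V); }
  tau = 1.0 / (a + b);
}
static inline void rate_j(double V, double &ginf, double &tau) {
  double ji = 1.0 / (1.0 + exp((V + 71.55) / 7.43));
  ginf = ji * ji;
  double a, b;
  if (V >= -40.0) { a = 0.0;
    b = 0.6 * exp(0.057 * V) / (1.0 + exp(-0.1 * (V + 32.0))); }
  else {
    a = (-2.5428e4 * exp(0.2444 * V) - 6.948e-6 * exp(-0.04391 * V)) *
        (V + 37.78) / (1.0 + exp(0.311 * (V + 79.23)));
    b = 0.02424 * exp(-0.01052 * V) / (1.0 + exp(-0.1378 * (V + 40.14)));
  }
  tau = 1.0 / (a + b);
}
static inline void rate_xr1(double V, double &ginf, double &tau) {
  ginf = 1.0 / (1.0 + exp((-26.0 - V) / 7.0));
  double a = 450.0 / (1.0 + exp((-45.0 - V) / 10.0));
  double b = 6.0 / (1.0 + exp((V + 30.0) / 11.5));
  tau = a * b;
}
static inline void rate_xr2(double V, double &ginf, double &tau) {
  ginf = 1.0 / (1.0 + exp((V + 88.0) / 24.0));
  double a = 3.0 / (1.0 + exp((-60.0 - V) / 20.0));
  double b = 1.12 / (1.0 + exp((V - 60.0) / 20.0));
  tau = a * b;
}
static inline void rate_xs(double V, double &ginf, double &tau) {
  ginf = 1.0 / (1.0 + exp((-5.0 - V) / 14.0));
  double a = 1400.0 / sqrt(1.0 + exp((5.0 - V) / 6.0));
  double b = 1.0 / (1.0 + exp((V - 35.0) / 15.0));
  tau = a * b + 80.0;
}
static inline void rate_r(double V, double &ginf, double &tau) {
  ginf = 1.0 / (1.0 + exp((20.0 - V) / 6.0));
  tau = 9.5 * exp(-(V + 40.0) * (V + 40.0) / 1800.0) + 0.8;
}
static inline void rate_s(double V, double &ginf, double &tau) {   // epicardial
  ginf = 1.0 / (1.0 + exp((V + 20.0) / 5.0));
  tau = 85.0 * exp(-(V + 45.0) * (V + 45.0) / 320.0) +
        5.0 / (1.0 + exp((V - 20.0) / 5.0)) + 3.0;
}
static inline void rate_d(double V, double &ginf, double &tau) {
  ginf = 1.0 / (1.0 + exp((-8.0 - V) / 7.5));
  double a = 1.4 / (1.0 + exp((-35.0 - V) / 13.0)) + 0.25;
  double b = 1.4 / (1.0 + exp((V + 5.0) / 5.0));
  double c = 1.0 / (1.0 + exp((50.0 - V) / 20.0));
  tau = a * b + c;
}
static inline void rate_f(double V, double &ginf, double &tau) {
  ginf = 1.0 / (1.0 + exp((V + 20.0) / 7.0));
  double a = 1102.5 * exp(-(V + 27.0) * (V + 27.0) / 225.0);
  double b = 200.0 / (1.0 + exp((13.0 - V) / 10.0));
  double c = 180.0 / (1.0 + exp((V + 30.0) / 10.0)) + 20.0;
  tau = a + b + c;
}
static inline void rate_f2(double V, double &ginf, double &tau) {
  ginf = 0.67 / (1.0 + exp((V + 35.0) / 7.0)) + 0.33;
  // time constant as in the authors' released code (and openCARP), which
  // differs from the printed formulation
  double a = 562.0 * exp(-(V + 27.0) * (V + 27.0) / 240.0);
  double b = 31.0 / (1.0 + exp((25.0 - V) / 10.0));
  double c = 80.0 / (1.0 + exp((V + 30.0) / 10.0));
  tau = a + b + c;
}

// all 17 gate (ginf, tau) pairs, phosphorylated copies included
static void all_gate_rates(double V, const Mods &md,
                           double *ginf, double *tau) {
  rate_m (V, ginf[gm],  tau[gm]);
  rate_h (V, ginf[gh],  tau[gh]);
  rate_j (V, ginf[gj],  tau[gj]);
  rate_xr1(V, ginf[gxr1], tau[gxr1]);
  rate_xr2(V, ginf[gxr2], tau[gxr2]);
  rate_xs(V, ginf[gxs], tau[gxs]);
  rate_r (V, ginf[gr],  tau[gr]);
  rate_s (V, ginf[gs],  tau[gs]);
  rate_d (V, ginf[gd],  tau[gd]);
  rate_f (V, ginf[gf],  tau[gf]);
  rate_f2(V, ginf[gf2], tau[gf2]);
  // phosphorylated INa: fast inactivation gate h shifted by h_shift
  // (leftward < 0); slow inactivation j is not modified, its P copy
  // evolves with baseline kinetics
  double Vh = V - md.h_shift;
  rate_h (Vh, ginf[ghP], tau[ghP]);
  rate_j (V, ginf[gjP], tau[gjP]);
  // phosphorylated ICaL gates: shifted by dff2_shift, tau blended
  double Vd = V - md.dff2_shift;
  rate_d (Vd, ginf[gdP], tau[gdP]);
  rate_f (Vd, ginf[gfP], tau[gfP]);
  rate_f2(Vd, ginf[gf2P], tau[gf2P]);
  // activation speedup near threshold (V < 0), smooth 5 mV blend
  double wlo = 1.0 / (1.0 + exp(V / 5.0));
  tau[gdP] *= (1.0 - wlo * (1.0 - 1.0 / md.dtau_speedup));
  // inactivation slowdown at strongly positive V (> +20), smooth blend
  double whi = 1.0 / (1.0 + exp(-(V - 20.0) / 5.0));
  double slow = 1.0 + whi * (md.ftau_slowdown - 1.0);
  tau[gfP]  *= slow;
  tau[gf2P] *= slow;
  // phosphorylated IKs activation: shifted and faster
  double Vx = V - md.xs_shift;
  rate_xs(Vx, ginf[gxsP], tau[gxsP]);
  tau[gxsP] /= md.xs_rate_scale;
}

// voltage-only current factors (tabulated)
struct VFac {
  double icalA, icalB;      // ICaL = G * gates * (A*CaSS - B)
  double nacaC1, nacaC2;    // INaCa = C1*Nai^3 - C2*Cai
  double nakF;              // INaK = F * Nai/(Nai+KmNa)
  double pkS, pkSP;         // IpK = S*(V-EK) [GpK folded in]
};

static void vfac_at(double V, const Mods &md, VFac &f) {
  double vf = 2.0 * (V - 15.0) * invRTF;
  if (fabs(vf) < 1e-7) vf = (vf >= 0 ? 1e-7 : -1e-7);
  double e2 = exp(vf);
  double pref = 4.0 * (V - 15.0) * Frd * invRTF / (e2 - 1.0);
  f.icalA = pref * 0.25 * e2;
  f.icalB = pref * Cao;
  double eg  = exp(gam * V * invRTF);
  double eg1 = exp((gam - 1.0) * V * invRTF);
  double den = (KmNai * KmNai * KmNai + Nao * Nao * Nao) * (KmCa + Cao) *
               (1.0 + ksat * eg1);
  f.nacaC1 = kNaCa * eg * Cao / den;
  f.nacaC2 = kNaCa * eg1 * Nao * Nao * Nao * aNaCa / den;
  f.nakF = PNaK * Ko / ((Ko + KmK) *
           (1.0 + 0.1245 * exp(-0.1 * V * invRTF) + 0.0353 * exp(-V * invRTF)));
  f.pkS  = GpK / (1.0 + exp((25.0 - V) / 5.98));
  double Vp = V - md.pK_shift;
  f.pkSP = md.gpK_scale * GpK / (1.0 + exp((25.0 - Vp) / 5.98));
}

static inline double xk1_inf(double VEK) {
  double a = 0.1 / (1.0 + exp(0.06 * (VEK - 200.0)));
  double b = (3.0 * exp(0.0002 * (VEK + 100.0)) + exp(0.1 * (VEK - 10.0))) /
             (1.0 + exp(-0.5 * VEK));
  return a / (a + b);
}

// ------------------------------------------------------------ lookup tables
struct LUT {
  double vmin, dv, inv_dv; int n;
  // per V node: NGATE ginf, NGATE rush-larsen factor exp(-dt/tau), 7 VFac
  std::vector<double> tab;        // n x ncol, ncol = 2*NGATE + 7
  double ekmin, ekdv, ekinv; int ekn;
  std::vector<double> ektab;      // xk1_inf on V-EK grid
  int ncol;
  void build(const Mods &md, double dt) {
    vmin = -150.0; dv = 0.02; n = (int)(300.0 / dv) + 1; inv_dv = 1.0 / dv;
    ncol = 2 * NGATE + 7;
    tab.assign((size_t)n * ncol, 0.0);
    double ginf[NGATE], tau[NGATE];
    for (int i = 0; i < n; ++i) {
      double V = vmin + i * dv;
      all_gate_rates(V, md, ginf, tau);
      double *row = &tab[(size_t)i * ncol];
      for (int g = 0; g < NGATE; ++g) {
        row[g] = ginf[g];
        row[NGATE + g] = exp(-dt / tau[g]);
      }
      VFac f; vfac_at(V, md, f);
      row[2*NGATE + 0] = f.icalA;  row[2*NGATE + 1] = f.icalB;
      row[2*NGATE + 2] = f.nacaC1; row[2*NGATE + 3] = f.nacaC2;
      row[2*NGATE + 4] = f.nakF;
      row[2*NGATE + 5] = f.pkS;    row[2*NGATE + 6] = f.pkSP;
    }
    ekmin = -200.0; ekdv = 0.02; ekn = (int)(400.0 / ekdv) + 1; ekinv = 1.0 / ekdv;
    ektab.resize(ekn);
    for (int i = 0; i < ekn; ++i) ektab[i] = xk1_inf(ekmin + i * ekdv);
  }
};

// ------------------------------------------------- full right-hand side
// direct (non-tabulated) evaluation; fills currents vector too.
// currents layout (see R side): 38 entries
enum { cINa_NP=0, cINa_P, cINa, cICaL_NP, cICaL_P, cICaL, cIKs_NP, cIKs_P,
       cIKs, cIpK_NP, cIpK_P, cIpK, cINaK_NP, cINaK_P, cINaK, cIrel_NP,
       cIrel_P, cIrel, cIup_NP, cIup_P, cIup, cIxfer_NP, cIxfer_P, cIxfer,
       cIKr, cIto, cIK1, cINaCa, cIpCa, cIbNa, cIbCa, cIleak, cItot,
       cKbufc_eff, NCUR };

static void rhs_direct(const double *y, const double *alpha, const Mods &md,
                       bool bars, double istim, double gks_mult, double gkr_mult,
                       double *dy, double *cur) {
  const double V = y[iV], Nai = y[iNai], Ki = y[iKi], Cai = y[iCai],
               CaSS = y[iCaSS], CaSR = y[iCaSR];
  double aa[NTGT];
  for (int t = 0; t < NTGT; ++t) aa[t] = bars ? alpha[t] : 0.0;

  double EK  = RTF * log(Ko / Ki);
  double ENa = RTF * log(Nao / Nai);
  double EKs = RTF * log((Ko + pKNa * Nao) / (Ki + pKNa * Nai));
  double ECa = 0.5 * RTF * log(Cao / Cai);

  VFac f; vfac_at(V, md, f);

  // INa
  double m3 = y[im] * y[im] * y[im];
  double INa_NP = GNa * m3 * y[ih] * y[ij] * (V - ENa);
  double INa_P  = md.gNa_scale * GNa * m3 * y[ihP] * y[ijP] * (V - ENa);
  double INa = INa_NP + aa[aNA] * (INa_P - INa_NP);

  // ICaL
  double drv = f.icalA * CaSS - f.icalB;
  double ICaL_NP = GCaL * y[id] * y[if_] * y[if2] * y[ifca] * drv;
  double ICaL_P  = md.gCaL_scale * GCaL * y[idP] * y[ifP] * y[if2P] * y[ifca] * drv;
  double ICaL = ICaL_NP + aa[aCAL] * (ICaL_P - ICaL_NP);

  // IKs
  double IKs_NP = GKs * y[ixs] * y[ixs] * (V - EKs) * gks_mult;
  double IKs_P  = md.gKs_scale * GKs * y[ixsP] * y[ixsP] * (V - EKs) * gks_mult;
  double IKs = IKs_NP + aa[aKS] * (IKs_P - IKs_NP);

  // IKr, Ito, IK1
  double IKr = gkr_mult * GKr * sqrt(Ko / 5.4) * y[ixr1] * y[ixr2] * (V - EK);
  double Ito = Gto * y[ir] * y[is_] * (V - EK);
  double IK1 = GK1 * sqrt(Ko / 5.4) * xk1_inf(V - EK) * (V - EK);

  // INaK
  double INaK_NP = f.nakF * Nai / (Nai + KmNa);
  double INaK_P  = f.nakF * Nai / (Nai + md.kmNa_scale * KmNa);
  double INaK = INaK_NP + aa[aNAK] * (INaK_P - INaK_NP);

  // INaCa, IpCa, IpK, background
  double INaCa = f.nacaC1 * Nai * Nai * Nai - f.nacaC2 * Cai;
  double IpCa  = GpCa * Cai / (Cai + KpCa);
  double IpK_NP = f.pkS  * (V - EK);
  double IpK_P  = f.pkSP * (V - EK);
  double IpK = IpK_NP + aa[aPK] * (IpK_P - IpK_NP);
  double IbNa = GbNa * (V - ENa);
  double IbCa = GbCa * (V - ECa);

  double Itot = INa + ICaL + IKs + IKr + Ito + IK1 + INaK + INaCa +
                IpCa + IpK + IbNa + IbCa;

  // SR release (RyR), uptake, leak, transfer
  double kcasr = maxsr - (maxsr - minsr) / (1.0 + (ECsr / CaSR) * (ECsr / CaSR));
  double k1 = k1p / kcasr, k2 = k2p * kcasr;
  double O_NP = k1 * CaSS * CaSS * y[iRb] /
                (k3c + k1 * CaSS * CaSS);
  double Irel_NP = Vrel * O_NP * (CaSR - CaSS);
  double k1P = md.ryr_open_scale * k1, k2P = md.ryr_close_scale * k2;
  double O_P = k1P * CaSS * CaSS * y[iRbP] / (k3c + k1P * CaSS * CaSS);
  double Irel_P = md.gRel_scale * Vrel * O_P * (CaSR - CaSS);
  double Irel = Irel_NP + aa[aREL] * (Irel_P - Irel_NP);

  double Iup_NP = Vmaxup / (1.0 + (Kup * Kup) / (Cai * Cai));
  double KupP = md.kUp_scale * Kup;
  double Iup_P = md.vmaxUp_scale * Vmaxup /
                 (1.0 + (KupP * KupP) / (Cai * Cai));
  double Iup = Iup_NP + aa[aUP] * (Iup_P - Iup_NP);

  double Ileak = Vleak * (CaSR - Cai);
  double Ixfer_NP = VxferC * (CaSS - Cai);
  double Ixfer_P  = md.vXfer_scale * VxferC * (CaSS - Cai);
  double Ixfer = Ixfer_NP + aa[aXFER] * (Ixfer_P - Ixfer_NP);

  // gate derivatives
  double ginf[NGATE], tau[NGATE];
  all_gate_rates(V, md, ginf, tau);
  static const int gstate[NGATE] = { im, ih, ij, ixr1, ixr2, ixs, ir, is_,
                                     id, if_, if2, ihP, ijP, idP, ifP, if2P, ixsP };
  for (int g = 0; g < NGATE; ++g)
    dy[gstate[g]] = (ginf[g] - y[gstate[g]]) / tau[g];

  double fcai = 0.6 / (1.0 + (CaSS / 0.05) * (CaSS / 0.05)) + 0.4;
  double fctau = 80.0 / (1.0 + (CaSS / 0.05) * (CaSS / 0.05)) + 2.0;
  dy[ifca] = (fcai - y[ifca]) / fctau;

  dy[iRb]  = -k2  * CaSS * y[iRb]  + k4c * (1.0 - y[iRb]);
  dy[iRbP] = -k2P * CaSS * y[iRbP] + k4c * (1.0 - y[iRbP]);

  // concentrations
  double KbufcEff = Kbufc_c * (1.0 + aa[aBUFC] * (md.kBufc_scale - 1.0));
  double bc = 1.0 / (1.0 + Bufc * KbufcEff /
              ((Cai + KbufcEff) * (Cai + KbufcEff)));
  double bsr = 1.0 / (1.0 + Bufsr * Kbufsr / ((CaSR + Kbufsr) * (CaSR + Kbufsr)));
  double bss = 1.0 / (1.0 + Bufss * Kbufss / ((CaSS + Kbufss) * (CaSS + Kbufss)));
  double inv2VcF = CAP / (2.0 * Vc * Frd);
  dy[iCai] = bc * (-(IbCa + IpCa - 2.0 * INaCa) * inv2VcF +
                   (Ileak - Iup) * Vsr / Vc + Ixfer);
  dy[iCaSR] = bsr * (Iup - Irel - Ileak);
  dy[iCaSS] = bss * (-ICaL * CAP / (2.0 * Vss * Frd) +
                     Irel * Vsr / Vss - Ixfer * Vc / Vss);
  double invVcF = CAP / (Vc * Frd);
  dy[iNai] = -(INa + IbNa + 3.0 * INaK + 3.0 * INaCa) * invVcF;
  dy[iKi]  = -(IK1 + Ito + IKr + IKs + IpK - 2.0 * INaK - istim) * invVcF;

  dy[iV] = -Itot + istim;

  if (cur) {
    cur[cINa_NP]=INa_NP;   cur[cINa_P]=INa_P;   cur[cINa]=INa;
    cur[cICaL_NP]=ICaL_NP; cur[cICaL_P]=ICaL_P; cur[cICaL]=ICaL;
    cur[cIKs_NP]=IKs_NP;   cur[cIKs_P]=IKs_P;   cur[cIKs]=IKs;
    cur[cIpK_NP]=IpK_NP;   cur[cIpK_P]=IpK_P;   cur[cIpK]=IpK;
    cur[cINaK_NP]=INaK_NP; cur[cINaK_P]=INaK_P; cur[cINaK]=INaK;
    cur[cIrel_NP]=Irel_NP; cur[cIrel_P]=Irel_P; cur[cIrel]=Irel;
    cur[cIup_NP]=Iup_NP;   cur[cIup_P]=Iup_P;   cur[cIup]=Iup;
    cur[cIxfer_NP]=Ixfer_NP; cur[cIxfer_P]=Ixfer_P; cur[cIxfer]=Ixfer;
    cur[cIKr]=IKr; cur[cIto]=Ito; cur[cIK1]=IK1; cur[cINaCa]=INaCa;
    cur[cIpCa]=IpCa; cur[cIbNa]=IbNa; cur[cIbCa]=IbCa; cur[cIleak]=Ileak;
    cur[cItot]=Itot; cur[cKbufc_eff]=KbufcEff;
  }
}

// ------------------------------------------- tabulated Rush-Larsen stepper
// advances one node by dt; gates Rush-Larsen from LUT, fcass/Rbar exact
// exponential, concentrations and V forward Euler. istim adds to dV/dt,
// clampV >= -500 means V is clamped (no V update). Returns Itot.
static inline double step_node(double *y, const double *alpha, const Mods &md,
                               bool bars, const LUT &L, double dt,
                               double istim, bool clampV,
                               double gks_mult, double gkr_mult) {
  const double V = y[iV], Nai = y[iNai], Ki = y[iKi], Cai = y[iCai],
               CaSS = y[iCaSS], CaSR = y[iCaSR];
  double aa[NTGT];
  for (int t = 0; t < NTGT; ++t) aa[t] = bars ? alpha[t] : 0.0;

  // table lookup (linear interpolation)
  double u = (V - L.vmin) * L.inv_dv;
  int i0 = (int)u; if (i0 < 0) i0 = 0; if (i0 > L.n - 2) i0 = L.n - 2;
  double w = u - i0;
  const double *r0 = &L.tab[(size_t)i0 * L.ncol];
  const double *r1 = r0 + L.ncol;
  #define LK(c) (r0[c] + w * (r1[c] - r0[c]))

  double EK  = RTF * log(Ko / Ki);
  double ENa = RTF * log(Nao / Nai);
  double EKs = RTF * log((Ko + pKNa * Nao) / (Ki + pKNa * Nai));
  double ECa = 0.5 * RTF * log(Cao / Cai);

  double m3 = y[im] * y[im] * y[im];
  double INa_NP = GNa * m3 * y[ih] * y[ij] * (V - ENa);
  double INa_P  = md.gNa_scale * GNa * m3 * y[ihP] * y[ijP] * (V - ENa);
  double INa = INa_NP + aa[aNA] * (INa_P - INa_NP);

  double drv = LK(2*NGATE + 0) * CaSS - LK(2*NGATE + 1);
  double ICaL_NP = GCaL * y[id] * y[if_] * y[if2] * y[ifca] * drv;
  double ICaL_P  = md.gCaL_scale * GCaL * y[idP] * y[ifP] * y[if2P] * y[ifca] * drv;
  double ICaL = ICaL_NP + aa[aCAL] * (ICaL_P - ICaL_NP);

  double IKs_NP = GKs * y[ixs] * y[ixs] * (V - EKs) * gks_mult;
  double IKs_P  = md.gKs_scale * GKs * y[ixsP] * y[ixsP] * (V - EKs) * gks_mult;
  double IKs = IKs_NP + aa[aKS] * (IKs_P - IKs_NP);

  double IKr = gkr_mult * GKr * sqrt(Ko / 5.4) * y[ixr1] * y[ixr2] * (V - EK);
  double Ito = Gto * y[ir] * y[is_] * (V - EK);

  double ue = (V - EK - L.ekmin) * L.ekinv;
  int e0 = (int)ue; if (e0 < 0) e0 = 0; if (e0 > L.ekn - 2) e0 = L.ekn - 2;
  double we = ue - e0;
  double xk1 = L.ektab[e0] + we * (L.ektab[e0 + 1] - L.ektab[e0]);
  double IK1 = GK1 * sqrt(Ko / 5.4) * xk1 * (V - EK);

  double nakF = LK(2*NGATE + 4);
  double INaK_NP = nakF * Nai / (Nai + KmNa);
  double INaK_P  = nakF * Nai / (Nai + md.kmNa_scale * KmNa);
  double INaK = INaK_NP + aa[aNAK] * (INaK_P - INaK_NP);

  double INaCa = LK(2*NGATE + 2) * Nai * Nai * Nai - LK(2*NGATE + 3) * Cai;
  double IpCa  = GpCa * Cai / (Cai + KpCa);
  double IpK_NP = LK(2*NGATE + 5) * (V - EK);
  double IpK_P  = LK(2*NGATE + 6) * (V - EK);
  double IpK = IpK_NP + aa[aPK] * (IpK_P - IpK_NP);
  double IbNa = GbNa * (V - ENa);
  double IbCa = GbCa * (V - ECa);

  double Itot = INa + ICaL + IKs + IKr + Ito + IK1 + INaK + INaCa +
                IpCa + IpK + IbNa + IbCa;

  double kcasr = maxsr - (maxsr - minsr) / (1.0 + (ECsr / CaSR) * (ECsr / CaSR));
  double k1 = k1p / kcasr, k2 = k2p * kcasr;
  double O_NP = k1 * CaSS * CaSS * y[iRb] / (k3c + k1 * CaSS * CaSS);
  double Irel_NP = Vrel * O_NP * (CaSR - CaSS);
  double k1P = md.ryr_open_scale * k1, k2P = md.ryr_close_scale * k2;
  double O_P = k1P * CaSS * CaSS * y[iRbP] / (k3c + k1P * CaSS * CaSS);
  double Irel_P = md.gRel_scale * Vrel * O_P * (CaSR - CaSS);
  double Irel = Irel_NP + aa[aREL] * (Irel_P - Irel_NP);

  double Iup_NP = Vmaxup / (1.0 + (Kup * Kup) / (Cai * Cai));
  double KupP = md.kUp_scale * Kup;
  double Iup_P = md.vmaxUp_scale * Vmaxup /
                 (1.0 + (KupP * KupP) / (Cai * Cai));
  double Iup = Iup_NP + aa[aUP] * (Iup_P - Iup_NP);

  double Ileak = Vleak * (CaSR - Cai);
  double Ixfer_NP = VxferC * (CaSS - Cai);
  double Ixfer_P  = md.vXfer_scale * VxferC * (CaSS - Cai);
  double Ixfer = Ixfer_NP + aa[aXFER] * (Ixfer_P - Ixfer_NP);

  // gates: Rush-Larsen with tabulated factors
  static const int gstate[NGATE] = { im, ih, ij, ixr1, ixr2, ixs, ir, is_,
                                     id, if_, if2, ihP, ijP, idP, ifP, if2P, ixsP };
  for (int g = 0; g < NGATE; ++g) {
    double gi = LK(g), rl = LK(NGATE + g);
    y[gstate[g]] = gi + (y[gstate[g]] - gi) * rl;
  }
  #undef LK

  double csq = (CaSS / 0.05) * (CaSS / 0.05);
  double fcai = 0.6 / (1.0 + csq) + 0.4;
  double fctau = 80.0 / (1.0 + csq) + 2.0;
  y[ifca] = fcai + (y[ifca] - fcai) * exp(-dt / fctau);

  // Rbar: linear ODE, exact exponential update
  double rb_rate = k2 * CaSS + k4c;
  double rb_inf  = k4c / rb_rate;
  y[iRb] = rb_inf + (y[iRb] - rb_inf) * exp(-dt * rb_rate);
  double rbP_rate = k2P * CaSS + k4c;
  double rbP_inf  = k4c / rbP_rate;
  y[iRbP] = rbP_inf + (y[iRbP] - rbP_inf) * exp(-dt * rbP_rate);

  double KbufcEff = Kbufc_c * (1.0 + aa[aBUFC] * (md.kBufc_scale - 1.0));
  double bc = 1.0 / (1.0 + Bufc * KbufcEff /
              ((Cai + KbufcEff) * (Cai + KbufcEff)));
  double bsr = 1.0 / (1.0 + Bufsr * Kbufsr / ((CaSR + Kbufsr) * (CaSR + Kbufsr)));
  double bss = 1.0 / (1.0 + Bufss * Kbufss / ((CaSS + Kbufss) * (CaSS + Kbufss)));
  double inv2VcF = CAP / (2.0 * Vc * Frd);
  y[iCai]  += dt * bc * (-(IbCa + IpCa - 2.0 * INaCa) * inv2VcF +
                         (Ileak - Iup) * Vsr / Vc + Ixfer);
  y[iCaSR] += dt * bsr * (Iup - Irel - Ileak);
  y[iCaSS] += dt * bss * (-ICaL * CAP / (2.0 * Vss * Frd) +
                          Irel * Vsr / Vss - Ixfer * Vc / Vss);
  double invVcF = CAP / (Vc * Frd);
  y[iNai] += dt * (-(INa + IbNa + 3.0 * INaK + 3.0 * INaCa) * invVcF);
  y[iKi]  += dt * (-(IK1 + Ito + IKr + IKs + IpK - 2.0 * INaK - istim) * invVcF);

  if (!clampV) y[iV] += dt * (-Itot + istim);
  return Itot;
}

static void check_state(const double *y, double t) {
  if (!R_finite(y[iV]) || fabs(y[iV]) > 200.0)
    stop("numerical blow-up at t = %.3f ms (Vm = %g mV)", t, y[iV]);
}

// ------------------------------------------------------------- R interface

// [[Rcpp::export]]
NumericVector cpp_default_state() {
  NumericVector y(NSTATE);
  y[iV] = -86.2; y[iNai] = 7.67; y[iKi] = 138.3;
  y[iCai] = 0.00007; y[iCaSS] = 0.00007; y[iCaSR] = 1.3;
  y[im] = 0.0; y[ih] = 0.75; y[ij] = 0.75;
  y[ixr1] = 0.0; y[ixr2] = 1.0; y[ixs] = 0.0;
  y[ir] = 0.0; y[is_] = 1.0;
  y[id] = 0.0; y[if_] = 1.0; y[if2] = 1.0; y[ifca] = 1.0; y[iRb] = 1.0;
  y[ihP] = 0.75; y[ijP] = 0.75; y[idP] = 0.0; y[ifP] = 1.0; y[if2P] = 1.0;
  y[ixsP] = 0.0; y[iRbP] = 1.0;
  return y;
}

// [[Rcpp::export]]
List cpp_rhs(NumericVector state, NumericVector alpha, List mods,
             bool bars, double istim) {
  Mods md = mods_from_list(mods);
  std::vector<double> dy(NSTATE), cur(NCUR);
  rhs_direct(REAL(state), REAL(alpha), md, bars, istim, 1.0, 1.0,
             dy.data(), cur.data());
  return List::create(_["deriv"] = NumericVector(dy.begin(), dy.end()),
                      _["currents"] = NumericVector(cur.begin(), cur.end()));
}

// free-running integration with an explicit stimulus schedule
// [[Rcpp::export]]
List cpp_integrate(NumericVector state0, NumericVector alpha, List mods,
                   bool bars, double dt, double duration,
                   NumericVector stim_onsets, double stim_amp,
                   double stim_dur, double record_dt) {
  Mods md = mods_from_list(mods);
  LUT L; L.build(md, dt);
  std::vector<double> y(REAL(state0), REAL(state0) + NSTATE);
  long nstep = (long)llround(duration / dt);
  int rev = std::max(1, (int)llround(record_dt / dt));
  long nrec = nstep / rev + 1;
  NumericMatrix states((int)nrec, NSTATE);
  NumericMatrix curm((int)nrec, NCUR);
  NumericVector tt((int)nrec);
  std::vector<double> dy(NSTATE), cur(NCUR);
  int irec = 0;
  size_t ns = stim_onsets.size(); size_t snext = 0;
  for (long k = 0; k <= nstep; ++k) {
    double t = k * dt;
    double istim = 0.0;
    while (snext < ns && t >= stim_onsets[snext] + stim_dur) ++snext;
    if (snext < ns && t >= stim_onsets[snext] && t < stim_onsets[snext] + stim_dur)
      istim = stim_amp;
    if (k % rev == 0 && irec < nrec) {
      rhs_direct(y.data(), REAL(alpha), md, bars, istim, 1.0, 1.0,
                 dy.data(), cur.data());
      tt[irec] = t;
      for (int s = 0; s < NSTATE; ++s) states(irec, s) = y[s];
      for (int c = 0; c < NCUR; ++c) curm(irec, c) = cur[c];
      ++irec;
    }
    if (k == nstep) break;
    step_node(y.data(), REAL(alpha), md, bars, L, dt, istim, false, 1.0, 1.0);
    if ((k & 1023) == 0) check_state(y.data(), t);
  }
  return List::create(_["time"] = tt, _["states"] = states,
                      _["currents"] = curm,
                      _["final_state"] = NumericVector(y.begin(), y.end()));
}

// paced run with per-beat feature extraction and optional early convergence
// [[Rcpp::export]]
List cpp_pace(NumericVector state0, NumericVector alpha, List mods, bool bars,
              double pcl, int nbeats, double amp, double pulse_ms, double dt,
              bool early_exit, double conv_tol, int conv_beats,
              double record_dt) {
  Mods md = mods_from_list(mods);
  LUT L; L.build(md, dt);
  std::vector<double> y(REAL(state0), REAL(state0) + NSTATE);
  long steps_per_beat = (long)llround(pcl / dt);

  std::vector<double> apd(nbeats, NA_REAL), vpk(nbeats), vdia(nbeats),
      dvmax(nbeats), tact(nbeats), camin(nbeats), camax(nbeats),
      inamin(nbeats), icalmin(nbeats), iksmax(nbeats), tplat(nbeats, NA_REAL);
  std::vector<int> captured(nbeats, 0);

  int nconv = 0, beats_run = 0;
  bool converged = false;
  std::vector<double> ystart(NSTATE);   // state at start of final beat

  for (int b = 0; b < nbeats; ++b) {
    beats_run = b + 1;
    std::memcpy(ystart.data(), y.data(), sizeof(double) * NSTATE);
    double Vdias = y[iV];
    double vpeak = -1e9, dvm = -1e9, t_dvm = 0.0, tpk = 0.0;
    double cmin = 1e9, cmax = -1e9, inam = 1e9, icalm = 1e9, iksm = -1e9;
    double apd90 = NA_REAL, vplat = NA_REAL;
    bool crossed = false;
    double Vprev = y[iV];
    for (long k = 0; k < steps_per_beat; ++k) {
      double t = k * dt;
      double istim = (t < pulse_ms) ? amp : 0.0;
      double Itot = step_node(y.data(), REAL(alpha), md, bars, L, dt, istim,
                              false, 1.0, 1.0);
      (void)Itot;
      double Vn = y[iV];
      double dv = (Vn - Vprev) / dt;
      if (dv > dvm) { dvm = dv; t_dvm = t; }
      if (Vn > vpeak) { vpeak = Vn; tpk = t; }
      if (y[iCai] < cmin) cmin = y[iCai];
      if (y[iCai] > cmax) cmax = y[iCai];
      // track current extrema (cheap re-evaluation of the three of interest)
      {
        double ENa = RTF * log(Nao / y[iNai]);
        double m3 = y[im] * y[im] * y[im];
        double iNaNP = GNa * m3 * y[ih] * y[ij] * (Vn - ENa);
        double iNaP  = md.gNa_scale * GNa * m3 * y[ihP] * y[ijP] * (Vn - ENa);
        double a0 = bars ? alpha[aNA] : 0.0;
        double iNa = iNaNP + a0 * (iNaP - iNaNP);
        if (iNa < inam) inam = iNa;
        VFac fv; vfac_at(Vn, md, fv);
        double drvv = fv.icalA * y[iCaSS] - fv.icalB;
        double iCaLNP = GCaL * y[id] * y[if_] * y[if2] * y[ifca] * drvv;
        double iCaLP  = md.gCaL_scale * GCaL * y[idP] * y[ifP] * y[if2P] *
                        y[ifca] * drvv;
        double a1 = bars ? alpha[aCAL] : 0.0;
        double iCaL = iCaLNP + a1 * (iCaLP - iCaLNP);
        if (iCaL < icalm) icalm = iCaL;
        double EKs = RTF * log((Ko + pKNa * Nao) / (y[iKi] + pKNa * y[iNai]));
        double iKsNP = GKs * y[ixs] * y[ixs] * (Vn - EKs);
        double iKsP  = md.gKs_scale * GKs * y[ixsP] * y[ixsP] * (Vn - EKs);
        double a2 = bars ? alpha[aKS] : 0.0;
        double iKsv = iKsNP + a2 * (iKsP - iKsNP);
        if (iKsv > iksm) iksm = iKsv;
      }
      // APD90: first downward crossing of the 90%-repolarization level
      if (!crossed && vpeak > 0.0 && t > tpk) {
        double v90 = vpeak - 0.9 * (vpeak - Vdias);
        if (Vprev > v90 && Vn <= v90) {
          double frac = (Vprev - v90) / (Vprev - Vn);
          apd90 = (t - dt + frac * dt) - t_dvm;
          crossed = true;
        }
      }
      // plateau sample 100 ms after activation
      if (!R_finite(vplat) && vpeak > 0.0 && t >= t_dvm + 100.0) vplat = Vn;
      Vprev = Vn;
      if ((k & 2047) == 0) check_state(y.data(), b * pcl + t);
    }
    captured[b] = (vpeak > 0.0 && R_finite(apd90)) ? 1 : 0;
    apd[b] = apd90; vpk[b] = vpeak; vdia[b] = Vdias; dvmax[b] = dvm;
    tact[b] = t_dvm; camin[b] = cmin; camax[b] = cmax;
    inamin[b] = inam; icalmin[b] = icalm; iksmax[b] = iksm;
    tplat[b] = vplat;

    if (early_exit && b > 0 && captured[b] && captured[b - 1] &&
        R_finite(apd[b]) && R_finite(apd[b - 1])) {
      double da = fabs(apd[b] - apd[b - 1]) / apd[b];
      double ca_b = camax[b] - camin[b], ca_p = camax[b - 1] - camin[b - 1];
      double dc = fabs(ca_b - ca_p) / std::max(ca_b, 1e-12);
      if (da < conv_tol && dc < conv_tol) ++nconv; else nconv = 0;
      if (nconv >= conv_beats) { converged = true; break; }
    }
  }

  // re-run the final beat from its start state with full recording
  List trace;
  {
    std::vector<double> yy(ystart);
    long rev = std::max(1L, (long)llround(record_dt / dt));
    long nrec = steps_per_beat / rev + 1;
    NumericVector tt((int)nrec);
    NumericMatrix st((int)nrec, NSTATE), cm((int)nrec, NCUR);
    std::vector<double> dy(NSTATE), cur(NCUR);
    int irec = 0;
    for (long k = 0; k <= steps_per_beat; ++k) {
      double t = k * dt;
      double istim = (t < pulse_ms) ? amp : 0.0;
      if (k % rev == 0 && irec < nrec) {
        rhs_direct(yy.data(), REAL(alpha), md, bars, istim, 1.0, 1.0,
                   dy.data(), cur.data());
        tt[irec] = t;
        for (int s = 0; s < NSTATE; ++s) st(irec, s) = yy[s];
        for (int c = 0; c < NCUR; ++c) cm(irec, c) = cur[c];
        ++irec;
      }
      if (k == steps_per_beat) break;
      step_node(yy.data(), REAL(alpha), md, bars, L, dt, istim, false, 1.0, 1.0);
    }
    trace = List::create(_["time"] = tt, _["states"] = st, _["currents"] = cm);
  }

  int nb = beats_run;
  auto take = [nb](std::vector<double> &v) {
    return NumericVector(v.begin(), v.begin() + nb); };
  IntegerVector capv(captured.begin(), captured.begin() + nb);
  return List::create(
    _["beats"] = DataFrame::create(
      _["apd90"] = take(apd), _["peak_vm"] = take(vpk),
      _["resting_vm"] = take(vdia), _["max_upstroke"] = take(dvmax),
      _["t_act"] = take(tact), _["cai_min"] = take(camin),
      _["cai_max"] = take(camax), _["ina_min"] = take(inamin),
      _["ical_min"] = take(icalmin), _["iks_max"] = take(iksmax),
      _["plateau_vm"] = take(tplat), _["captured"] = capv),
    _["final_state"] = NumericVector(y.begin(), y.end()),
    _["converged"] = converged, _["n_beats"] = beats_run,
    _["trace"] = trace);
}

// voltage-clamp run: V follows a piecewise-constant schedule
// [[Rcpp::export]]
List cpp_clamp(NumericVector state0, NumericVector alpha, List mods, bool bars,
               NumericVector seg_vm, NumericVector seg_ms, double dt,
               double record_dt) {
  Mods md = mods_from_list(mods);
  LUT L; L.build(md, dt);
  std::vector<double> y(REAL(state0), REAL(state0) + NSTATE);
  double duration = 0.0;
  for (double d : seg_ms) duration += d;
  long nstep = (long)llround(duration / dt);
  long rev = std::max(1L, (long)llround(record_dt / dt));
  long nrec = nstep / rev + 1;
  NumericVector tt((int)nrec);
  NumericMatrix st((int)nrec, NSTATE), cm((int)nrec, NCUR);
  std::vector<double> dy(NSTATE), cur(NCUR);
  int irec = 0, iseg = 0;
  double seg_end = seg_ms[0];
  y[iV] = seg_vm[0];
  for (long k = 0; k <= nstep; ++k) {
    double t = k * dt;
    while (iseg < seg_vm.size() - 1 && t >= seg_end) {
      ++iseg; seg_end += seg_ms[iseg];
    }
    y[iV] = seg_vm[iseg];
    if (k % rev == 0 && irec < nrec) {
      rhs_direct(y.data(), REAL(alpha), md, bars, 0.0, 1.0, 1.0,
                 dy.data(), cur.data());
      tt[irec] = t;
      for (int s = 0; s < NSTATE; ++s) st(irec, s) = y[s];
      for (int c = 0; c < NCUR; ++c) cm(irec, c) = cur[c];
      ++irec;
    }
    if (k == nstep) break;
    step_node(y.data(), REAL(alpha), md, bars, L, dt, 0.0, true, 1.0, 1.0);
  }
  return List::create(_["time"] = tt, _["states"] = st, _["currents"] = cm,
                      _["final_state"] = NumericVector(y.begin(), y.end()));
}

// ---------------------------------------------------------- tissue solver
// explicit monodomain on an nx x ny grid (ny = 1 gives a cable).
// states: nnodes x NSTATE matrix (column-major, R layout).
// alpha_tab: K x NTGT; alpha_idx: per-node row index (0-based) into alpha_tab.
// stimuli: list of lists(nodes (0-based int vec), onset, period, npulses,
//          dur, amp).
// Records: coarse Vm frames every frame_dt, fine Vm traces for probe nodes
// every trace_dt, and per-node activation times (upstroke crossings of
// -20 mV, up to 40 per node).
// [[Rcpp::export]]
List cpp_tissue(NumericMatrix states, IntegerVector alpha_idx,
                NumericMatrix alpha_tab, List mods, bool bars,
                int nx, int ny, double dx_cm, double Dl, double Dt,
                List stimuli, double dt, double duration,
                double frame_dt, IntegerVector probe_nodes, double trace_dt,
                NumericVector gks_mult, NumericVector gkr_mult) {
  Mods md = mods_from_list(mods);
  LUT L; L.build(md, dt);
  const int nn = nx * ny;
  if (states.nrow() != nn) stop("state matrix does not match grid size");
  std::vector<double> Y((size_t)nn * NSTATE);
  for (int s = 0; s < NSTATE; ++s)
    for (int i = 0; i < nn; ++i) Y[(size_t)i * NSTATE + s] = states(i, s);

  // stimulus bookkeeping
  struct Stim { std::vector<int> nodes; double onset, period, dur, amp; int np; };
  std::vector<Stim> ss;
  for (int i = 0; i < stimuli.size(); ++i) {
    List s = stimuli[i];
    Stim st;
    IntegerVector nd = s["nodes"];
    st.nodes.assign(nd.begin(), nd.end());
    st.onset = as<double>(s["onset"]); st.period = as<double>(s["period"]);
    st.np = as<int>(s["npulses"]); st.dur = as<double>(s["dur"]);
    st.amp = as<double>(s["amp"]);
    ss.push_back(st);
  }

  const double rx = Dl * dt / (dx_cm * dx_cm);
  const double ry = Dt * dt / (dx_cm * dx_cm);

  long nstep = (long)llround(duration / dt);
  long frev = std::max(1L, (long)llround(frame_dt / dt));
  long nframe = nstep / frev + 1;
  NumericMatrix frames((int)nframe, nn);   // row = frame, col = node
  NumericVector ftime((int)nframe);
  long trev = std::max(1L, (long)llround(trace_dt / dt));
  long ntr = nstep / trev + 1;
  int npb = probe_nodes.size();
  NumericMatrix ptr((int)ntr, npb);
  NumericVector pttime((int)ntr);

  const int MAXACT = 60;
  std::vector<double> act((size_t)nn * MAXACT, NA_REAL);
  std::vector<int> nact(nn, 0);
  std::vector<double> Vold(nn), istim(nn, 0.0), Vnew(nn);

  int ifr = 0, itr = 0;
  for (long k = 0; k <= nstep; ++k) {
    double t = k * dt;
    if (k % frev == 0 && ifr < nframe) {
      ftime[ifr] = t;
      for (int i = 0; i < nn; ++i) frames(ifr, i) = Y[(size_t)i * NSTATE + iV];
      ++ifr;
    }
    if (k % trev == 0 && itr < ntr) {
      pttime[itr] = t;
      for (int p = 0; p < npb; ++p)
        ptr(itr, p) = Y[(size_t)probe_nodes[p] * NSTATE + iV];
      ++itr;
    }
    if (k == nstep) break;

    std::fill(istim.begin(), istim.end(), 0.0);
    for (auto &st : ss) {
      double rel = t - st.onset;
      if (rel < 0) continue;
      double ph = (st.period > 0)
        ? rel - st.period * floor(rel / st.period) : rel;
      int pulse = (st.period > 0) ? (int)(rel / st.period) : 0;
      if (pulse < st.np && ph < st.dur)
        for (int nd : st.nodes) istim[nd] += st.amp;
    }

    for (int i = 0; i < nn; ++i) Vold[i] = Y[(size_t)i * NSTATE + iV];

    // reaction step (per-node ionic update, V updated by -Itot + istim)
    for (int i = 0; i < nn; ++i) {
      double *y = &Y[(size_t)i * NSTATE];
      step_node(y, &alpha_tab(alpha_idx[i], 0), md, bars, L, dt, istim[i],
                false, gks_mult[i], gkr_mult[i]);
    }
    // diffusion step on Vold (Lie splitting), zero-flux boundaries
    for (int jy = 0; jy < ny; ++jy) {
      for (int jx = 0; jx < nx; ++jx) {
        int i = jy * nx + jx;
        double v = Vold[i];
        double vxm = (jx > 0)      ? Vold[i - 1]  : Vold[i + 1];
        double vxp = (jx < nx - 1) ? Vold[i + 1]  : Vold[i - 1];
        double lap = rx * (vxm + vxp - 2.0 * v);
        if (ny > 1) {
          double vym = (jy > 0)      ? Vold[i - nx] : Vold[i + nx];
          double vyp = (jy < ny - 1) ? Vold[i + nx] : Vold[i - nx];
          lap += ry * (vym + vyp - 2.0 * v);
        }
        Y[(size_t)i * NSTATE + iV] += lap;
      }
    }
    // activation detection: upward crossing of -20 mV
    for (int i = 0; i < nn; ++i) {
      double vn = Y[(size_t)i * NSTATE + iV];
      if (Vold[i] < -20.0 && vn >= -20.0 && nact[i] < MAXACT) {
        double frac = (-20.0 - Vold[i]) / (vn - Vold[i]);
        act[(size_t)i * MAXACT + nact[i]] = t + frac * dt;
        ++nact[i];
      }
      if (!R_finite(vn) || fabs(vn) > 200.0)
        stop("tissue numerical blow-up at t = %.2f ms, node %d", t, i);
    }
  }

  NumericMatrix out_states(nn, NSTATE);
  for (int s = 0; s < NSTATE; ++s)
    for (int i = 0; i < nn; ++i) out_states(i, s) = Y[(size_t)i * NSTATE + s];
  NumericMatrix actm(nn, MAXACT);
  for (int i = 0; i < nn; ++i)
    for (int a = 0; a < MAXACT; ++a) actm(i, a) = act[(size_t)i * MAXACT + a];
  return List::create(_["frames"] = frames, _["frame_time"] = ftime,
                      _["probe_vm"] = ptr, _["probe_time"] = pttime,
                      _["final_states"] = out_states,
                      _["activations"] = actm,
                      _["n_activations"] = IntegerVector(nact.begin(), nact.end()));
}

// [[Rcpp::export]]
CharacterVector cpp_state_names() {
  return CharacterVector::create("Vm","Nai","Ki","Cai","CaSS","CaSR",
    "m","h","j","xr1","xr2","xs","r","s","d","f","f2","fCaSS","Rbar",
    "h_P","j_P","d_P","f_P","f2_P","xs_P","Rbar_P");
}

// [[Rcpp::export]]
CharacterVector cpp_current_names() {
  return CharacterVector::create(
    "INa_NP","INa_P","INa","ICaL_NP","ICaL_P","ICaL","IKs_NP","IKs_P","IKs",
    "IpK_NP","IpK_P","IpK","INaK_NP","INaK_P","INaK","Irel_NP","Irel_P","Irel",
    "Iup_NP","Iup_P","Iup","Ixfer_NP","Ixfer_P","Ixfer",
    "IKr","Ito","IK1","INaCa","IpCa","IbNa","IbCa","Ileak","Itot","Kbufc_eff");
}
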