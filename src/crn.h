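// Courtemanche-Ramirez-Nattel (CRN) human atrial action potential model.
// Transcribed from the CellML curation of courtemanche_ramirez_nattel_1998
// (model units: mV, ms, mM, pA; conductances in nS/pF scaled by Cm = 100 pF).
// [Na+]i and [K+]i are held fixed, so E_Na and E_K are compile-time constants.
#ifndef FIBROSCAPE_CRN_H
#define FIBROSCAPE_CRN_H

#include <cmath>

namespace crn {

// state vector layout (19 entries per node)
enum StateIndex {
  IV = 0,
  IM, IH, IJ,          // fast Na+ gates
  IOA, IOI,            // transient outward gates
  IUA, IUI,            // ultrarapid delayed rectifier gates
  IXR, IXS,            // rapid / slow delayed rectifier gates
  ID, IF, IFCA,        // L-type Ca2+ gates
  IU, IVG, IW,         // Ca2+ release (SR) gates
  ICAI, ICAUP, ICAREL, // Ca2+ concentrations (myoplasm, NSR, JSR)
  NSTATE
};
const int NGATE = 15;     // gates occupy indices IM..IW
const int GATE0 = IM;

// physical constants and cell geometry
const double Rgas = 8.3143;      // J/(mol K)
const double Temp = 310.0;       // K
const double Frdy = 96.4867;     // C/mmol
const double Cm = 100.0;         // pF
const double Vcell = 20100.0;    // um^3
const double Vi = 13668.0;
const double Vup = 1109.52;
const double Vrel = 96.48;

// external / clamped ionic concentrations (mM)
const double Ko = 5.4;
const double Nao = 140.0;
const double Cao = 1.8;
const double Nai_fixed = 11.17;
const double Ki_fixed = 139.0;

// maximum conductances (nS/pF) and current parameters
const double gNa = 7.8;
const double gK1 = 0.09;
const double gto = 0.1652;
const double gKr = 0.029411765;
const double gKs = 0.12941176;
const double gCaL = 0.12375;
const double gbCa = 0.001131;
const double gbNa = 0.0006744375;
const double INaK_max = 0.59933874; // pA/pF
const double KmNai = 10.0;
const double KmKo = 1.5;
const double INaCa_max = 1600.0;    // pA/pF
const double KmNa = 87.5;
const double KmCa = 1.38;
const double ksat = 0.1;
const double gama = 0.35;
const double IpCa_max = 0.275;      // pA/pF

// Ca handling
const double Krel = 30.0;       // 1/ms
const double Iup_max = 0.005;   // mM/ms
const double Kup = 0.00092;     // mM
const double Caup_max = 15.0;   // mM
const double CMDN_max = 0.05;
const double TRPN_max = 0.07;
const double CSQN_max = 10.0;
const double Km_CMDN = 0.00238;
const double Km_TRPN = 0.0005;
const double Km_CSQN = 0.8;
const double tau_tr = 180.0;
const double tau_fca = 2.0;
const double tau_u = 8.0;
const double KQ10 = 3.0;

const double RTF = Rgas * Temp / Frdy; // ~26.71 mV
const double FRT = 1.0 / RTF;

inline double E_Na() { return RTF * std::log(Nao / Nai_fixed); }
inline double E_K()  { return RTF * std::log(Ko / Ki_fixed); }

// variant scalings applied to maximum conductances only
struct Scales {
  double gto, gCaL, gKur, gK1;
  Scales() : gto(1.0), gCaL(1.0), gKur(1.0), gK1(1.0) {}
};

struct Deriv {
  double inf[NGATE];
  double tau[NGATE];
  double dCai, dCaup, dCarel;
  double Iion; // total membrane current, pA
};

// published resting state of the model
inline void initial_state(double* s) {
  s[IV] = -81.18;
  s[IM] = 0.002908; s[IH] = 0.9649; s[IJ] = 0.9775;
  s[IOA] = 0.03043; s[IOI] = 0.9992;
  s[IUA] = 0.004966; s[IUI] = 0.9986;
  s[IXR] = 3.296e-5; s[IXS] = 0.01869;
  s[ID] = 1.367e-4; s[IF] = 0.9996; s[IFCA] = 0.7755;
  s[IU] = 0.0; s[IVG] = 1.0; s[IW] = 0.9992;
  s[ICAI] = 1.013e-4; s[ICAUP] = 1.488; s[ICAREL] = 1.488;
}

// gate steady states and time constants at voltage V (the 12 V-dependent
// gates); d->inf/tau entries for fCa, u, v are filled by eval() since they
// depend on Ca2+ state.
inline void voltage_rates(double V, Deriv* d) {
  double a, b;

  // I_Na gates (Luo-Rudy style formulation used by CRN)
  a = (std::fabs(V + 47.13) < 1e-10) ? 3.2
      : 0.32 * (V + 47.13) / (1.0 - std::exp(-0.1 * (V + 47.13)));
  b = 0.08 * std::exp(-V / 11.0);
  d->inf[IM - GATE0] = a / (a + b);
  d->tau[IM - GATE0] = 1.0 / (a + b);

  if (V >= -40.0) {
    a = 0.0;
    b = 1.0 / (0.13 * (1.0 + std::exp((V + 10.66) / -11.1)));
  } else {
    a = 0.135 * std::exp((V + 80.0) / -6.8);
    b = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
  }
  d->inf[IH - GATE0] = a / (a + b);
  d->tau[IH - GATE0] = 1.0 / (a + b);

  if (V >= -40.0) {
    a = 0.0;
    b = 0.3 * std::exp(-2.535e-7 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  } else {
    a = (-1.2714e5 * std::exp(0.2444 * V) - 3.474e-5 * std::exp(-0.04391 * V)) *
        (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    b = 0.1212 * std::exp(-0.01052 * V) / (1.0 + std::exp(-0.1378 * (V + 40.14)));
  }
  d->inf[IJ - GATE0] = a / (a + b);
  d->tau[IJ - GATE0] = 1.0 / (a + b);

  // I_to gates
  a = 0.65 / (std::exp(-(V + 10.0) / 8.5) + std::exp(-(V - 30.0) / 59.0));
  b = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
  d->tau[IOA - GATE0] = 1.0 / ((a + b) * KQ10);
  d->inf[IOA - GATE0] = 1.0 / (1.0 + std::exp(-(V + 20.47) / 17.54));
  // I_Kur activation shares the oa rate expressions
  d->tau[IUA - GATE0] = d->tau[IOA - GATE0];
  d->inf[IUA - GATE0] = 1.0 / (1.0 + std::exp(-(V + 30.3) / 9.6));

  a = 1.0 / (18.53 + std::exp((V + 113.7) / 10.95));
  b = 1.0 / (35.56 + std::exp(-(V + 1.26) / 7.44));
  d->tau[IOI - GATE0] = 1.0 / ((a + b) * KQ10);
  d->inf[IOI - GATE0] = 1.0 / (1.0 + std::exp((V + 43.1) / 5.3));

  a = 1.0 / (21.0 + std::exp(-(V - 185.0) / 28.0));
  b = std::exp((V - 158.0) / 16.0);
  d->tau[IUI - GATE0] = 1.0 / ((a + b) * KQ10);
  d->inf[IUI - GATE0] = 1.0 / (1.0 + std::exp((V - 99.45) / 27.48));

  // I_Kr activation
  a = (std::fabs(V + 14.1) < 1e-10) ? 0.0015
      : 0.0003 * (V + 14.1) / (1.0 - std::exp(-(V + 14.1) / 5.0));
  b = (std::fabs(V - 3.3328) < 1e-10) ? 3.7836118e-4
      : 7.3898e-5 * (V - 3.3328) / (std::exp((V - 3.3328) / 5.1237) - 1.0);
  d->tau[IXR - GATE0] = 1.0 / (a + b);
  d->inf[IXR - GATE0] = 1.0 / (1.0 + std::exp(-(V + 14.1) / 6.5));

  // I_Ks activation
  a = (std::fabs(V - 19.9) < 1e-10) ? 0.00068
      : 4e-5 * (V - 19.9) / (1.0 - std::exp(-(V - 19.9) / 17.0));
  b = (std::fabs(V - 19.9) < 1e-10) ? 0.000315
      : 3.5e-5 * (V - 19.9) / (std::exp((V - 19.9) / 9.0) - 1.0);
  d->tau[IXS - GATE0] = 0.5 / (a + b);
  d->inf[IXS - GATE0] = std::pow(1.0 + std::exp(-(V - 19.9) / 12.7), -0.5);

  // I_CaL gates
  {
    double e1 = std::exp(-(V + 10.0) / 6.24);
    d->tau[ID - GATE0] = (std::fabs(V + 10.0) < 1e-10)
        ? 4.579 / (1.0 + e1)
        : (1.0 - e1) / (0.035 * (V + 10.0) * (1.0 + e1));
    d->inf[ID - GATE0] = 1.0 / (1.0 + std::exp(-(V + 10.0) / 8.0));
  }
  d->tau[IF - GATE0] =
      9.0 / (0.0197 * std::exp(-0.0337 * 0.0337 * (V + 10.0) * (V + 10.0)) + 0.02);
  d->inf[IF - GATE0] = 1.0 / (1.0 + std::exp((V + 28.0) / 6.9));

  // SR release w gate
  {
    double e2 = std::exp(-(V - 7.9) / 5.0);
    d->tau[IW - GATE0] = (std::fabs(V - 7.9) < 1e-10)
        ? 6.0 * 0.2 / 1.3
        : 6.0 * (1.0 - e2) / ((1.0 + 0.3 * e2) * (V - 7.9));
    d->inf[IW - GATE0] = 1.0 - 1.0 / (1.0 + std::exp(-(V - 40.0) / 17.0));
  }
}

// full model evaluation at a state: fills gate rates, concentration
// derivatives and the total ionic current (pA).
inline void eval(const double* s, const Scales& sc, Deriv* d) {
  const double V = s[IV];
  const double Cai = s[ICAI], Caup = s[ICAUP], Carel = s[ICAREL];

  voltage_rates(V, d);

  const double ENa = E_Na();
  const double EK = E_K();
  const double ECa = 0.5 * RTF * std::log(Cao / Cai);

  const double iNa = Cm * gNa * s[IM] * s[IM] * s[IM] * s[IH] * s[IJ] * (V - ENa);
  const double iK1 = Cm * sc.gK1 * gK1 * (V - EK) / (1.0 + std::exp(0.07 * (V + 80.0)));
  const double ito = Cm * sc.gto * gto * s[IOA] * s[IOA] * s[IOA] * s[IOI] * (V - EK);
  const double gKur = 0.005 + 0.05 / (1.0 + std::exp(-(V - 15.0) / 13.0));
  const double iKur = Cm * sc.gKur * gKur * s[IUA] * s[IUA] * s[IUA] * s[IUI] * (V - EK);
  const double iKr = Cm * gKr * s[IXR] * (V - EK) / (1.0 + std::exp((V + 15.0) / 22.4));
  const double iKs = Cm * gKs * s[IXS] * s[IXS] * (V - EK);
  const double iCaL = Cm * sc.gCaL * gCaL * s[ID] * s[IF] * s[IFCA] * (V - 65.0);

  const double sigma = (std::exp(Nao / 67.3) - 1.0) / 7.0;
  const double fNaK = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * FRT * V) +
                             0.0365 * sigma * std::exp(-FRT * V));
  const double iNaK = Cm * INaK_max * fNaK *
      (1.0 / (1.0 + std::pow(KmNai / Nai_fixed, 1.5))) * (Ko / (Ko + KmKo));

  const double expA = std::exp(gama * FRT * V);
  const double expB = std::exp((gama - 1.0) * FRT * V);
  const double iNaCa = Cm * INaCa_max *
      (expA * Nai_fixed * Nai_fixed * Nai_fixed * Cao -
       expB * Nao * Nao * Nao * Cai) /
      ((KmNa * KmNa * KmNa + Nao * Nao * Nao) * (KmCa + Cao) *
       (1.0 + ksat * expB));

  const double ibNa = Cm * gbNa * (V - ENa);
  const double ibCa = Cm * gbCa * (V - ECa);
  const double ipCa = Cm * IpCa_max * Cai / (0.0005 + Cai);

  d->Iion = iNa + iK1 + ito + iKur + iKr + iKs + iCaL + ipCa + iNaK + iNaCa +
            ibNa + ibCa;

  // SR fluxes and Ca-dependent gates
  const double irel = Krel * s[IU] * s[IU] * s[IVG] * s[IW] * (Carel - Cai);
  const double itr = (Caup - Carel) / tau_tr;
  const double iup = Iup_max / (1.0 + Kup / Cai);
  const double iupleak = Iup_max * Caup / Caup_max;

  const double Fn = 1e3 * (1e-15 * Vrel * irel -
                           (1e-15 / (2.0 * Frdy)) * (0.5 * iCaL - 0.2 * iNaCa));
  const double sigm1 = 1.0 / (1.0 + std::exp(-(Fn - 3.4175e-13) / 13.67e-16));
  d->inf[IU - GATE0] = sigm1;
  d->tau[IU - GATE0] = tau_u;
  d->inf[IVG - GATE0] = 1.0 - 1.0 / (1.0 + std::exp(-(Fn - 6.835e-14) / 13.67e-16));
  d->tau[IVG - GATE0] = 1.91 + 2.09 * sigm1;
  d->inf[IFCA - GATE0] = 1.0 / (1.0 + Cai / 0.00035);
  d->tau[IFCA - GATE0] = tau_fca;

  const double B1 = (2.0 * iNaCa - (ipCa + iCaL + ibCa)) / (2.0 * Vi * Frdy) +
                    (Vup * (iupleak - iup) + irel * Vrel) / Vi;
  const double B2 = 1.0 + TRPN_max * Km_TRPN / ((Cai + Km_TRPN) * (Cai + Km_TRPN)) +
                    CMDN_max * Km_CMDN / ((Cai + Km_CMDN) * (Cai + Km_CMDN));
  d->dCai = B1 / B2;
  d->dCaup = iup - (iupleak + itr * Vrel / Vup);
  d->dCarel = (itr - irel) /
              (1.0 + CSQN_max * Km_CSQN / ((Carel + Km_CSQN) * (Carel + Km_CSQN)));
}

// One Rush-Larsen / forward-Euler step of an isolated cell.
// I_stim in pA (negative = depolarizing); dV/dt = -(I_ion + I_stim)/Cm.
inline void step(double* s, const Scales& sc, double dt, double istim) {
  Deriv d;
  eval(s, sc, &d);
  for (int g = 0; g < NGATE; ++g) {
    double x = s[GATE0 + g];
    s[GATE0 + g] = d.inf[g] + (x - d.inf[g]) * std::exp(-dt / d.tau[g]);
  }
  s[ICAI] += dt * d.dCai;
  s[ICAUP] += dt * d.dCaup;
  s[ICAREL] += dt * d.dCarel;
  s[IV] += -dt * (d.Iion + istim) / Cm;
}

} // namespace crn

#endif
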