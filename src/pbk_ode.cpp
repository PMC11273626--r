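// Two-compound (parent + metabolite) flow-limited PBK model and an
// adaptive Dormand-Prince 5(4) integrator.
//
// State vector (amounts in umol):
//   0  AGL   gut-lumen parent (absorbable pool)
//   1  AL    liver parent            11 ML   liver metabolite
//   2  AK    kidney parent           12 MK   kidney metabolite
//   3  AF    fat parent              13 MF   fat metabolite
//   4  AR    richly perfused parent  14 MR   richly perfused metabolite
//   5  AS    slowly perfused parent  15 MS   slowly perfused metabolite
//   6  AB    blood parent            16 MB   blood metabolite
//   7  Abile cumulative biliary excretion of parent
//   8  Aur   cumulative urinary excretion of parent
//   9  Aform cumulative parent converted to metabolite (umol, equimolar)
//   10 Agluc cumulative parent glucuronidated
//   17 Mur   cumulative urinary excretion of metabolite
//   18 Mcl   cumulative hepatic clearance of metabolite
//
// Parameter vector layout (see R/pbk.R pbk_param_vector):
//   0-5   VL VK VF VR VS VB        (L)
//   6-10  QL QK QF QR QS           (L/h)
//   11    ka  (1/h)   12 kb (1/h)  13 GFRtot (L/h)
//   14    fup_p  15 bpr_p
//   16-20 PL PK PF PR PS  (tissue:blood, parent)
//   21-22 Vmax,Km rhein formation (umol/h, uM)
//   23-28 Vmax,Km AEG1..AEG3
//   29    fup_m  30 bpr_m
//   31-35 PL PK PF PR PS  (tissue:blood, metabolite)
//   36    CLint metabolite (L/h)

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int NSTATE = 19;

static inline double mm(double vmax, double km, double c) {
  return vmax * c / (km + c);
}

static void pbk_rhs(const double* p, const double* y, double* dy) {
  const double VL = p[0], VK = p[1], VF = p[2], VR = p[3], VS = p[4], VB = p[5];
  const double QL = p[6], QK = p[7], QF = p[8], QR = p[9], QS = p[10];
  const double QC = QL + QK + QF + QR + QS;
  const double ka = p[11], kb = p[12], gfr = p[13];
  const double fup_p = p[14], bpr_p = p[15];
  const double *Pp = p + 16;             // parent tissue:blood PCs
  const double fup_m = p[29], bpr_m = p[30];
  const double *Pm = p + 31;             // metabolite tissue:blood PCs
  const double clint_m = p[36];

  // parent concentrations (uM)
  const double CBp  = y[6] / VB;
  const double CVLp = y[1] / (VL * Pp[0]);
  const double CVKp = y[2] / (VK * Pp[1]);
  const double CVFp = y[3] / (VF * Pp[2]);
  const double CVRp = y[4] / (VR * Pp[3]);
  const double CVSp = y[5] / (VS * Pp[4]);

  const double v_rh = mm(p[21], p[22], CVLp);
  const double v_g  = mm(p[23], p[24], CVLp) + mm(p[25], p[26], CVLp)
                    + mm(p[27], p[28], CVLp);
  const double renal_p = gfr * fup_p * CBp / bpr_p;

  dy[0] = -ka * y[0];
  dy[1] = ka * y[0] + QL * (CBp - CVLp) - kb * y[1] - v_rh - v_g;
  dy[2] = QK * (CBp - CVKp) - renal_p;
  dy[3] = QF * (CBp - CVFp);
  dy[4] = QR * (CBp - CVRp);
  dy[5] = QS * (CBp - CVSp);
  dy[6] = QL * CVLp + QK * CVKp + QF * CVFp + QR * CVRp + QS * CVSp - QC * CBp;
  dy[7] = kb * y[1];
  dy[8] = renal_p;
  dy[9] = v_rh;
  dy[10] = v_g;

  // metabolite
  const double CBm  = y[16] / VB;
  const double CVLm = y[11] / (VL * Pm[0]);
  const double CVKm = y[12] / (VK * Pm[1]);
  const double CVFm = y[13] / (VF * Pm[2]);
  const double CVRm = y[14] / (VR * Pm[3]);
  const double CVSm = y[15] / (VS * Pm[4]);
  const double met_cl = clint_m * CVLm;
  const double renal_m = gfr * fup_m * CBm / bpr_m;

  dy[11] = v_rh + QL * (CBm - CVLm) - met_cl;
  dy[12] = QK * (CBm - CVKm) - renal_m;
  dy[13] = QF * (CBm - CVFm);
  dy[14] = QR * (CBm - CVRm);
  dy[15] = QS * (CBm - CVSm);
  dy[16] = QL * CVLm + QK * CVKm + QF * CVFm + QR * CVRm + QS * CVSm - QC * CBm;
  dy[17] = renal_m;
  dy[18] = met_cl;
}

// Dormand-Prince 5(4) coefficients
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
static const double e1 = 35.0 / 384 - 5179.0 / 57600,
                    e3 = 500.0 / 1113 - 7571.0 / 16695,
                    e4 = 125.0 / 192 - 393.0 / 640,
                    e5 = -2187.0 / 6784 + 92097.0 / 339200,
                    e6 = 11.0 / 84 - 187.0 / 2100,
                    e7 = -1.0 / 40;

// [[Rcpp::export]]
NumericMatrix pbk_integrate_cpp(NumericVector params, NumericVector state0,
                                NumericVector t_out, double rtol, double atol,
                                double hmax) {
  const int nt = t_out.size();
  NumericMatrix out(nt, NSTATE);
  const double* p = params.begin();
  double y[NSTATE], ynew[NSTATE], yerr[NSTATE], ytmp[NSTATE];
  double k1[NSTATE], k2[NSTATE], k3[NSTATE], k4[NSTATE], k5[NSTATE],
         k6[NSTATE], k7[NSTATE];
  for (int i = 0; i < NSTATE; ++i) y[i] = state0[i];

  double t = t_out[0];
  for (int i = 0; i < NSTATE; ++i) out(0, i) = y[i];

  double h = std::min(hmax, 1e-3);
  pbk_rhs(p, y, k1);                       // FSAL seed
  long n_step = 0;
  const long max_steps = 50000000L;

  for (int io = 1; io < nt; ++io) {
    const double t_end = t_out[io];
    while (t < t_end) {
      if (++n_step > max_steps) stop("PBK integrator exceeded step limit");
      if (h > t_end - t) h = t_end - t;

      for (int i = 0; i < NSTATE; ++i) ytmp[i] = y[i] + h * a21 * k1[i];
      pbk_rhs(p, ytmp, k2);
      for (int i = 0; i < NSTATE; ++i)
        ytmp[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
      pbk_rhs(p, ytmp, k3);
      for (int i = 0; i < NSTATE; ++i)
        ytmp[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
      pbk_rhs(p, ytmp, k4);
      for (int i = 0; i < NSTATE; ++i)
        ytmp[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i]
                              + a54 * k4[i]);
      pbk_rhs(p, ytmp, k5);
      for (int i = 0; i < NSTATE; ++i)
        ytmp[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i]
                              + a64 * k4[i] + a65 * k5[i]);
      pbk_rhs(p, ytmp, k6);
      for (int i = 0; i < NSTATE; ++i)
        ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i]
                              + b5 * k5[i] + b6 * k6[i]);
      pbk_rhs(p, ynew, k7);
      for (int i = 0; i < NSTATE; ++i)
        yerr[i] = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i]
                       + e6 * k6[i] + e7 * k7[i]);

      double err = 0.0;
      for (int i = 0; i < NSTATE; ++i) {
        double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
        double r = yerr[i] / sc;
        err += r * r;
      }
      err = std::sqrt(err / NSTATE);

      if (err <= 1.0) {                    // accept
        t += h;
        for (int i = 0; i < NSTATE; ++i) { y[i] = ynew[i]; k1[i] = k7[i]; }
      }
      double fac = 0.9 * std::pow(err > 1e-30 ? err : 1e-30, -0.2);
      fac = std::min(5.0, std::max(0.2, fac));
      h = std::min(h * fac, hmax);
      if (h < 1e-14) stop("PBK integrator step size underflow");
    }
    for (int i = 0; i < NSTATE; ++i) out(io, i) = y[i];
  }
  return out;
}
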