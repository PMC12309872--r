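// Bloch-equation core for the PCASL pulse train.
//
// A single spin moves through the labeling plane at constant through-plane
// velocity.  Each RF interval consists of a Hann-windowed slice-selective
// pulse (gradient g_max) discretized into short hard-pulse steps, followed by
// a rectangular rewinder gradient lobe whose area sets the interval-mean
// gradient, over which precession and relaxation are applied analytically.
// Vessel-encoding transverse blips enter as an instantaneous per-interval
// z-rotation of the spin by the encoding phase theta (sign alternating for
// the bipolar scheme); RF pulse phases follow the 0/pi alternating schedule
// so that theta = 0 reproduces the nonselective control condition and
// theta = pi the nonselective label condition.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double GAMMA = 2.0 * M_PI * 42.577e6; // rad / s / T

static inline void rotate_about(double M[3], double wx, double wy, double wz,
                                double dt) {
  // Precession dM/dt = gamma M x B, with w = gamma*B: rotation of M about
  // the unit axis of w by angle -|w|*dt.
  double w = std::sqrt(wx * wx + wy * wy + wz * wz);
  if (w * dt < 1e-14) return;
  double nx = wx / w, ny = wy / w, nz = wz / w;
  double a = -w * dt;
  double ca = std::cos(a), sa = std::sin(a);
  double dot = nx * M[0] + ny * M[1] + nz * M[2];
  double cx = ny * M[2] - nz * M[1];
  double cy = nz * M[0] - nx * M[2];
  double cz = nx * M[1] - ny * M[0];
  double Mx = M[0] * ca + cx * sa + nx * dot * (1.0 - ca);
  double My = M[1] * ca + cy * sa + ny * dot * (1.0 - ca);
  double Mz = M[2] * ca + cz * sa + nz * dot * (1.0 - ca);
  M[0] = Mx; M[1] = My; M[2] = Mz;
}

static inline void rotate_z(double M[3], double angle) {
  double ca = std::cos(angle), sa = std::sin(angle);
  double Mx = M[0] * ca - M[1] * sa;
  double My = M[0] * sa + M[1] * ca;
  M[0] = Mx; M[1] = My;
}

static inline void relax(double M[3], double dt, double t1, double t2) {
  double e2 = std::exp(-dt / t2);
  double e1 = std::exp(-dt / t1);
  M[0] *= e2;
  M[1] *= e2;
  M[2] = 1.0 + (M[2] - 1.0) * e1;
}

// [[Rcpp::export(name = ".pcasl_spin_cpp")]]
List pcasl_spin_cpp(double g_max_T_m, double g_rew_T_m, double rf_dur_s,
                    double rf_int_s, double flip_rad, double t1_s, double t2_s,
                    double v_m_s, double off_hz, double z0_m, double z1_m,
                    double dt_s, int phase_mode, double enc_theta,
                    int enc_bipolar, bool history) {
  if (v_m_s <= 0) stop("velocity must be positive");
  if (dt_s >= rf_dur_s) stop("time step must be smaller than the RF duration");
  if (rf_dur_s >= rf_int_s) stop("RF duration must be shorter than the RF interval");

  int nsteps = (int)std::ceil(rf_dur_s / dt_s);
  double dtr = rf_dur_s / nsteps;
  double b1peak = 2.0 * flip_rad / (GAMMA * rf_dur_s); // Hann integral = peak*dur/2
  double gap = rf_int_s - rf_dur_s;

  double M[3] = {0.0, 0.0, 1.0};
  double t = 0.0, z = z0_m;
  long n = 0;
  double max_norm = 1.0;

  std::vector<double> h_t, h_mx, h_my, h_mz, h_z;
  if (history) {
    h_t.push_back(0.0); h_mx.push_back(0.0); h_my.push_back(0.0);
    h_mz.push_back(1.0); h_z.push_back(z0_m);
  }

  while (z < z1_m) {
    double phi = (phase_mode == 1 && (n % 2 == 1)) ? M_PI : 0.0;
    for (int s = 0; s < nsteps; s++) {
      double tt = (s + 0.5) * dtr;
      double b1 = b1peak * 0.5 * (1.0 - std::cos(2.0 * M_PI * tt / rf_dur_s));
      double zm = z + v_m_s * tt;
      double wx = GAMMA * b1 * std::cos(phi);
      double wy = GAMMA * b1 * std::sin(phi);
      double wz = GAMMA * g_max_T_m * zm + 2.0 * M_PI * off_hz;
      rotate_about(M, wx, wy, wz, dtr);
      relax(M, dtr, t1_s, t2_s);
      double nm = std::sqrt(M[0] * M[0] + M[1] * M[1] + M[2] * M[2]);
      if (nm > max_norm) max_norm = nm;
      if (history) {
        h_t.push_back(t + (s + 1.0) * dtr);
        h_mx.push_back(M[0]); h_my.push_back(M[1]); h_mz.push_back(M[2]);
        h_z.push_back(z + (s + 1.0) * dtr * v_m_s);
      }
    }
    // inter-pulse gap: rewinder gradient + off-resonance, analytic precession
    double zs = z + v_m_s * rf_dur_s;
    double phase = GAMMA * g_rew_T_m * (zs * gap + 0.5 * v_m_s * gap * gap) +
                   2.0 * M_PI * off_hz * gap;
    rotate_z(M, -phase);
    if (enc_theta != 0.0) {
      double th = enc_theta;
      if (enc_bipolar == 1 && (n % 2 == 1)) th = -th;
      rotate_z(M, th);
    }
    relax(M, gap, t1_s, t2_s);
    t += rf_int_s;
    z = z0_m + v_m_s * t;
    n++;
    if (history) {
      h_t.push_back(t); h_mx.push_back(M[0]); h_my.push_back(M[1]);
      h_mz.push_back(M[2]); h_z.push_back(z);
    }
  }

  double t_cross = -z0_m / v_m_s;
  List out = List::create(
      _["mx"] = M[0], _["my"] = M[1], _["mz"] = M[2],
      _["t_cross"] = t_cross, _["t_end"] = t,
      _["n_pulses"] = (double)n, _["max_norm"] = max_norm);
  if (history) {
    out["history"] = DataFrame::create(
        _["t_s"] = h_t, _["z_m"] = h_z,
        _["mx"] = h_mx, _["my"] = h_my, _["mz"] = h_mz);
  }
  return out;
}
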