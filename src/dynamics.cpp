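// Forward-dynamic right-hand side for the six-body lumbar spine model.
//
// The model is loaded once per integration via dyn_set_model() into a
// translation-unit-static structure; dyn_rhs() then evaluates the
// Newton-Euler derivatives for the free bodies. State layout per free
// body: position (3, m), unit quaternion (4, w-x-y-z), linear velocity
// (3, m/s), world angular velocity (3, rad/s).
//
// Units are SI throughout; disc curves are tabulated in degrees/Nm and
// mm/N and converted at evaluation time.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Curve {
  std::vector<double> x, y, m;
  double eval(double v) const {
    const int n = static_cast<int>(x.size());
    if (v <= x[0]) return y[0] + m[0] * (v - x[0]);
    if (v >= x[n - 1]) return y[n - 1] + m[n - 1] * (v - x[n - 1]);
    int i = 0;
    while (i < n - 2 && v > x[i + 1]) ++i;
    const double h = x[i + 1] - x[i];
    const double t = (v - x[i]) / h;
    const double t1 = 1.0 - t;
    const double h00 = (1.0 + 2.0 * t) * t1 * t1;
    const double h10 = t * t1 * t1;
    const double h01 = t * t * (3.0 - 2.0 * t);
    const double h11 = t * t * (t - 1.0);
    return h00 * y[i] + h10 * h * m[i] + h01 * y[i + 1] + h11 * h * m[i + 1];
  }
};

struct ModelData {
  int nb = 0;
  std::vector<int> free_flag;    // per body
  std::vector<int> slot;         // body -> free slot or -1
  int n_free = 0;
  std::vector<double> mass;      // per body
  std::vector<double> inertia;   // 9 per body (body frame)
  std::vector<double> pose0;     // 7 per body (p, q)

  int n_lig = 0;
  std::vector<int> lig_a, lig_b;
  std::vector<double> lig_pa, lig_pb, lig_L0, lig_k, lig_eps_t, lig_shape;

  int n_facet = 0;
  std::vector<int> fc_ca, fc_cr;
  std::vector<double> fc_pt, fc_n, fc_probes, fc_k, fc_d0, fc_cd;

  int n_bush = 0;
  std::vector<int> bu_ca, bu_cr;
  std::vector<double> bu_uca, bu_ucr, bu_Aca, bu_Acr, bu_crot, bu_ctrans;
  double rot_scale = 1.0;
  Curve cFE, cLB, cAR, cAP, cML, cSI;

  // protocol
  int load_body = 0;
  int axis_bushing = 0;
  double moment = 0.0;       // Nm, flexion positive
  double vforce = 0.0;       // N, world -Z
  double t_ramp_end = 1.0;   // s
  double damp_mult = 1.0;
  int vforce_ramped = 0;     // ramp the vertical force with the moment?
  bool loaded = false;
};

ModelData M;

const double RAD2DEG = 57.29577951308232;

inline void quat_to_R(const double *q, double *R) {
  double w = q[0], x = q[1], y = q[2], z = q[3];
  const double nrm = std::sqrt(w * w + x * x + y * y + z * z);
  w /= nrm; x /= nrm; y /= nrm; z /= nrm;
  R[0] = 1 - 2 * (y * y + z * z); R[3] = 2 * (x * y - w * z); R[6] = 2 * (x * z + w * y);
  R[1] = 2 * (x * y + w * z);     R[4] = 1 - 2 * (x * x + z * z); R[7] = 2 * (y * z - w * x);
  R[2] = 2 * (x * z - w * y);     R[5] = 2 * (y * z + w * x);     R[8] = 1 - 2 * (x * x + y * y);
}
// column-major 3x3: R[col*3 + row]

inline void matvec(const double *R, const double *v, double *out) {
  out[0] = R[0] * v[0] + R[3] * v[1] + R[6] * v[2];
  out[1] = R[1] * v[0] + R[4] * v[1] + R[7] * v[2];
  out[2] = R[2] * v[0] + R[5] * v[1] + R[8] * v[2];
}

inline void mattvec(const double *R, const double *v, double *out) {
  out[0] = R[0] * v[0] + R[1] * v[1] + R[2] * v[2];
  out[1] = R[3] * v[0] + R[4] * v[1] + R[5] * v[2];
  out[2] = R[6] * v[0] + R[7] * v[1] + R[8] * v[2];
}

inline void cross(const double *a, const double *b, double *out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

// A * B for column-major 3x3
inline void matmat(const double *A, const double *B, double *out) {
  for (int c = 0; c < 3; ++c) {
    matvec(A, B + 3 * c, out + 3 * c);
  }
}

inline double lig_force(double eps, double k, double eps_t, double p) {
  if (eps <= 0.0) return 0.0;
  if (eps < eps_t) return k * eps_t / p * std::pow(eps / eps_t, p);
  return k * eps_t / p + k * (eps - eps_t);
}

inline double penalty(double depth, double k, double d0) {
  if (depth <= 0.0) return 0.0;
  if (depth < d0) return k * depth * depth / (2.0 * d0);
  return k * (depth - d0 / 2.0);
}

std::vector<double> as_vec(SEXP s) {
  NumericVector v(s);
  return std::vector<double>(v.begin(), v.end());
}
std::vector<int> as_ivec(SEXP s) {
  IntegerVector v(s);
  return std::vector<int>(v.begin(), v.end());
}
Curve as_curve(List cl) {
  Curve c;
  c.x = as_vec(cl["x"]); c.y = as_vec(cl["y"]); c.m = as_vec(cl["m"]);
  return c;
}

struct BodyKin {
  double p[3], R[9], v[3], w[3];
};

void body_kinematics(const double *y, std::vector<BodyKin> &kin) {
  for (int b = 0; b < M.nb; ++b) {
    BodyKin &K = kin[b];
    const int s = M.slot[b];
    if (s >= 0) {
      const double *yb = y + 13 * s;
      K.p[0] = yb[0]; K.p[1] = yb[1]; K.p[2] = yb[2];
      quat_to_R(yb + 3, K.R);
      K.v[0] = yb[7]; K.v[1] = yb[8]; K.v[2] = yb[9];
      K.w[0] = yb[10]; K.w[1] = yb[11]; K.w[2] = yb[12];
    } else {
      const double *p0 = &M.pose0[7 * b];
      K.p[0] = p0[0]; K.p[1] = p0[1]; K.p[2] = p0[2];
      quat_to_R(p0 + 3, K.R);
      for (int i = 0; i < 3; ++i) { K.v[i] = 0.0; K.w[i] = 0.0; }
    }
  }
}

// accumulate forces/torques (about body origins) for all passive elements
void accumulate_wrenches(double t, const std::vector<BodyKin> &kin,
                         std::vector<double> &F, std::vector<double> &T) {
  const double dm = M.damp_mult;

  // ligaments
  for (int i = 0; i < M.n_lig; ++i) {
    const BodyKin &A = kin[M.lig_a[i]];
    const BodyKin &B = kin[M.lig_b[i]];
    double pa[3], pb[3], ra[3], rb[3];
    matvec(A.R, &M.lig_pa[3 * i], ra);
    matvec(B.R, &M.lig_pb[3 * i], rb);
    for (int k = 0; k < 3; ++k) { pa[k] = A.p[k] + ra[k]; pb[k] = B.p[k] + rb[k]; }
    double d[3] = {pb[0] - pa[0], pb[1] - pa[1], pb[2] - pa[2]};
    const double L = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    if (L <= 0.0) continue;
    const double eps = (L - M.lig_L0[i]) / M.lig_L0[i];
    const double f = lig_force(eps, M.lig_k[i], M.lig_eps_t[i], M.lig_shape[i]);
    if (f <= 0.0) continue;
    const double u[3] = {d[0] / L, d[1] / L, d[2] / L};
    const int a = M.lig_a[i], b = M.lig_b[i];
    double tq[3];
    for (int k = 0; k < 3; ++k) F[3 * a + k] += f * u[k];
    cross(ra, u, tq);
    for (int k = 0; k < 3; ++k) T[3 * a + k] += f * tq[k];
    for (int k = 0; k < 3; ++k) F[3 * b + k] -= f * u[k];
    cross(rb, u, tq);
    for (int k = 0; k < 3; ++k) T[3 * b + k] -= f * tq[k];
  }

  // facet contacts
  for (int i = 0; i < M.n_facet; ++i) {
    const int ca = M.fc_ca[i], cr = M.fc_cr[i];
    const BodyKin &A = kin[ca];   // plane owner (caudal)
    const BodyKin &B = kin[cr];   // probe owner (cranial)
    double pt[3], n[3];
    matvec(A.R, &M.fc_pt[3 * i], pt);
    for (int k = 0; k < 3; ++k) pt[k] += A.p[k];
    matvec(A.R, &M.fc_n[3 * i], n);
    for (int j = 0; j < 9; ++j) {
      double q[3], rq[3];
      matvec(B.R, &M.fc_probes[27 * i + 3 * j], rq);
      for (int k = 0; k < 3; ++k) q[k] = B.p[k] + rq[k];
      double rel[3] = {q[0] - pt[0], q[1] - pt[1], q[2] - pt[2]};
      const double gap = rel[0] * n[0] + rel[1] * n[1] + rel[2] * n[2];
      const double depth = -gap;
      if (depth <= 0.0) continue;
      double f = penalty(depth, M.fc_k[i], M.fc_d0[i]);
      // penetration-rate damping, only while penetrating
      double vq[3], vp[3], wxn[3], tmp[3];
      cross(B.w, rq, tmp);
      for (int k = 0; k < 3; ++k) vq[k] = B.v[k] + tmp[k];
      double rpa[3] = {q[0] - A.p[0], q[1] - A.p[1], q[2] - A.p[2]};
      cross(A.w, rpa, tmp);
      for (int k = 0; k < 3; ++k) vp[k] = A.v[k] + tmp[k];
      cross(A.w, n, wxn);
      double gap_rate = 0.0;
      for (int k = 0; k < 3; ++k) gap_rate += (vq[k] - vp[k]) * n[k] + rel[k] * wxn[k];
      // damping fades in over the smoothing zone so the force is
      // continuous at touchdown
      double wd = depth / M.fc_d0[i];
      if (wd > 1.0) wd = 1.0;
      f -= wd * dm * M.fc_cd[i] * gap_rate;
      if (f <= 0.0) continue;
      double tq[3];
      for (int k = 0; k < 3; ++k) F[3 * cr + k] += f * n[k];
      cross(rq, n, tq);
      for (int k = 0; k < 3; ++k) T[3 * cr + k] += f * tq[k];
      for (int k = 0; k < 3; ++k) F[3 * ca + k] -= f * n[k];
      cross(rpa, n, tq);
      for (int k = 0; k < 3; ++k) T[3 * ca + k] -= f * tq[k];
    }
  }

  // disc bushings
  for (int i = 0; i < M.n_bush; ++i) {
    const int ca = M.bu_ca[i], cr = M.bu_cr[i];
    const BodyKin &A = kin[ca];
    const BodyKin &B = kin[cr];
    // disc frames carried by each body
    double Dca[9], Dcr[9];
    matmat(A.R, &M.bu_Aca[9 * i], Dca);
    matmat(B.R, &M.bu_Acr[9 * i], Dcr);
    // relative rotation R_rel = Dca^T * Dcr, Cardan x-y-z (LB, FE, AR axes
    // ordered AP-x, ML-y, SI-z)
    double Rrel[9];
    for (int c = 0; c < 3; ++c) {
      mattvec(Dca, Dcr + 3 * c, Rrel + 3 * c);
    }
    const double r13 = Rrel[6], r23 = Rrel[7], r33 = Rrel[8];
    const double r12 = Rrel[3], r11 = Rrel[0];
    double sb = r13; if (sb > 1.0) sb = 1.0; if (sb < -1.0) sb = -1.0;
    const double ang_lat = std::atan2(-r23, r33);        // about AP (x)
    const double ang_fe = std::asin(sb);                 // about ML (y)
    const double ang_ax = std::atan2(-r12, r11);         // about SI (z)
    // anchors
    double rca[3], rcr[3], pca[3], pcr[3];
    matvec(A.R, &M.bu_uca[3 * i], rca);
    matvec(B.R, &M.bu_ucr[3 * i], rcr);
    for (int k = 0; k < 3; ++k) { pca[k] = A.p[k] + rca[k]; pcr[k] = B.p[k] + rcr[k]; }
    double dw[3] = {pcr[0] - pca[0], pcr[1] - pca[1], pcr[2] - pca[2]};
    double dd[3];
    mattvec(Dca, dw, dd);   // displacement in disc axes, m
    // relative velocities
    double vca[3], vcr[3], tmp[3];
    cross(A.w, rca, tmp);
    for (int k = 0; k < 3; ++k) vca[k] = A.v[k] + tmp[k];
    cross(B.w, rcr, tmp);
    for (int k = 0; k < 3; ++k) vcr[k] = B.v[k] + tmp[k];
    double dv[3] = {vcr[0] - vca[0], vcr[1] - vca[1], vcr[2] - vca[2]};
    double dvd[3];
    mattvec(Dca, dv, dvd);
    double wrel[3] = {B.w[0] - A.w[0], B.w[1] - A.w[1], B.w[2] - A.w[2]};
    double wd[3];
    mattvec(Dca, wrel, wd);

    // elastic + damping in disc axes (force/moment on cranial body)
    const double fe_deg = ang_fe * RAD2DEG;
    const double lat_deg = ang_lat * RAD2DEG;
    const double ax_deg = ang_ax * RAD2DEG;
    double mom[3];
    mom[1] = -M.rot_scale * M.cFE.eval(fe_deg) - dm * M.bu_crot[3 * i + 0] * wd[1];
    mom[0] = -M.rot_scale * M.cLB.eval(lat_deg) - dm * M.bu_crot[3 * i + 1] * wd[0];
    mom[2] = -M.rot_scale * M.cAR.eval(ax_deg) - dm * M.bu_crot[3 * i + 2] * wd[2];
    double frc[3];
    frc[0] = -M.cAP.eval(dd[0] * 1000.0) - dm * M.bu_ctrans[3 * i + 0] * dvd[0];
    frc[1] = -M.cML.eval(dd[1] * 1000.0) - dm * M.bu_ctrans[3 * i + 1] * dvd[1];
    frc[2] = M.cSI.eval(-dd[2] * 1000.0) - dm * M.bu_ctrans[3 * i + 2] * dvd[2];

    double mom_w[3], frc_w[3];
    matvec(Dca, mom, mom_w);
    matvec(Dca, frc, frc_w);
    // force applied at the midpoint of the two anchors on both bodies
    double pm[3] = {(pca[0] + pcr[0]) / 2.0, (pca[1] + pcr[1]) / 2.0,
                    (pca[2] + pcr[2]) / 2.0};
    double rm_cr[3] = {pm[0] - B.p[0], pm[1] - B.p[1], pm[2] - B.p[2]};
    double rm_ca[3] = {pm[0] - A.p[0], pm[1] - A.p[1], pm[2] - A.p[2]};
    double tq[3];
    for (int k = 0; k < 3; ++k) F[3 * cr + k] += frc_w[k];
    cross(rm_cr, frc_w, tq);
    for (int k = 0; k < 3; ++k) T[3 * cr + k] += tq[k] + mom_w[k];
    for (int k = 0; k < 3; ++k) F[3 * ca + k] -= frc_w[k];
    cross(rm_ca, frc_w, tq);
    for (int k = 0; k < 3; ++k) T[3 * ca + k] -= tq[k] + mom_w[k];
  }

  // applied loads: ramped pure flexion couple + constant vertical force at
  // the cranial-most body
  double ramp = t / M.t_ramp_end;
  if (ramp > 1.0) ramp = 1.0;
  if (ramp < 0.0) ramp = 0.0;
  if (M.moment != 0.0) {
    // flexion axis: instantaneous ML axis of the reference disc frame
    const int i = M.axis_bushing;
    double Dca[9];
    matmat(kin[M.bu_ca[i]].R, &M.bu_Aca[9 * i], Dca);
    for (int k = 0; k < 3; ++k) {
      T[3 * M.load_body + k] += M.moment * ramp * Dca[3 + k];
    }
  }
  F[3 * M.load_body + 2] -= M.vforce * (M.vforce_ramped ? ramp : 1.0);
}

} // namespace

// [[Rcpp::export]]
void dyn_set_model(List ml) {
  M = ModelData();
  M.nb = as<int>(ml["nb"]);
  M.free_flag = as_ivec(ml["free"]);
  M.slot.assign(M.nb, -1);
  int s = 0;
  for (int b = 0; b < M.nb; ++b) {
    if (M.free_flag[b]) M.slot[b] = s++;
  }
  M.n_free = s;
  M.mass = as_vec(ml["mass"]);
  M.inertia = as_vec(ml["inertia"]);
  M.pose0 = as_vec(ml["pose0"]);
  M.n_lig = as<int>(ml["n_lig"]);
  if (M.n_lig > 0) {
    M.lig_a = as_ivec(ml["lig_a"]); M.lig_b = as_ivec(ml["lig_b"]);
    M.lig_pa = as_vec(ml["lig_pa"]); M.lig_pb = as_vec(ml["lig_pb"]);
    M.lig_L0 = as_vec(ml["lig_L0"]); M.lig_k = as_vec(ml["lig_k"]);
    M.lig_eps_t = as_vec(ml["lig_eps_t"]);
    M.lig_shape = as_vec(ml["lig_shape"]);
  }
  M.n_facet = as<int>(ml["n_facet"]);
  if (M.n_facet > 0) {
    M.fc_ca = as_ivec(ml["fc_ca"]); M.fc_cr = as_ivec(ml["fc_cr"]);
    M.fc_pt = as_vec(ml["fc_pt"]); M.fc_n = as_vec(ml["fc_n"]);
    M.fc_probes = as_vec(ml["fc_probes"]);
    M.fc_k = as_vec(ml["fc_k"]); M.fc_d0 = as_vec(ml["fc_d0"]);
    M.fc_cd = as_vec(ml["fc_cd"]);
  }
  M.n_bush = as<int>(ml["n_bush"]);
  if (M.n_bush > 0) {
    M.bu_ca = as_ivec(ml["bu_ca"]); M.bu_cr = as_ivec(ml["bu_cr"]);
    M.bu_uca = as_vec(ml["bu_uca"]); M.bu_ucr = as_vec(ml["bu_ucr"]);
    M.bu_Aca = as_vec(ml["bu_Aca"]); M.bu_Acr = as_vec(ml["bu_Acr"]);
    M.bu_crot = as_vec(ml["bu_crot"]); M.bu_ctrans = as_vec(ml["bu_ctrans"]);
    M.rot_scale = as<double>(ml["rot_scale"]);
    List curves = ml["curves"];
    M.cFE = as_curve(curves["FE"]); M.cLB = as_curve(curves["LB"]);
    M.cAR = as_curve(curves["AR"]); M.cAP = as_curve(curves["AP"]);
    M.cML = as_curve(curves["ML"]); M.cSI = as_curve(curves["SI"]);
  }
  M.loaded = true;
}

// [[Rcpp::export]]
void dyn_set_protocol(int load_body, int axis_bushing, double moment,
                      double vforce, double t_ramp_end, double damp_mult,
                      int vforce_ramped) {
  M.load_body = load_body;
  M.axis_bushing = axis_bushing;
  M.moment = moment;
  M.vforce = vforce;
  M.t_ramp_end = t_ramp_end;
  M.damp_mult = damp_mult;
  M.vforce_ramped = vforce_ramped;
}

// [[Rcpp::export]]
NumericVector dyn_rhs(double t, NumericVector y) {
  if (!M.loaded) stop("dynamics model not loaded");
  const int n = 13 * M.n_free;
  if (y.size() != n) stop("state length mismatch");
  std::vector<BodyKin> kin(M.nb);
  body_kinematics(y.begin(), kin);
  std::vector<double> F(3 * M.nb, 0.0), T(3 * M.nb, 0.0);
  accumulate_wrenches(t, kin, F, T);

  NumericVector dy(n);
  for (int b = 0; b < M.nb; ++b) {
    const int s = M.slot[b];
    if (s < 0) continue;
    const double *yb = y.begin() + 13 * s;
    double *d = dy.begin() + 13 * s;
    // translation
    d[0] = yb[7]; d[1] = yb[8]; d[2] = yb[9];
    const double m = M.mass[b];
    d[7] = F[3 * b + 0] / m;
    d[8] = F[3 * b + 1] / m;
    d[9] = F[3 * b + 2] / m;
    // quaternion kinematics with norm stabilization
    const double qw = yb[3], qx = yb[4], qy = yb[5], qz = yb[6];
    const double wx = yb[10], wy = yb[11], wz = yb[12];
    const double nrm2 = qw * qw + qx * qx + qy * qy + qz * qz;
    const double stab = 1.0 * (1.0 - nrm2);
    d[3] = 0.5 * (-wx * qx - wy * qy - wz * qz) + stab * qw;
    d[4] = 0.5 * (wx * qw + wy * qz - wz * qy) + stab * qx;
    d[5] = 0.5 * (-wx * qz + wy * qw + wz * qx) + stab * qy;
    d[6] = 0.5 * (wx * qy - wy * qx + wz * qw) + stab * qz;
    // Euler equations in the world frame: Iw * dw = T - w x (Iw * w)
    const BodyKin &K = kin[b];
    const double *Ib = &M.inertia[9 * b];
    double IR[9], Iw[9];
    // Iw = R * Ib * R^T
    matmat(K.R, Ib, IR);
    for (int c = 0; c < 3; ++c) {
      // column c of Iw = IR * (row c of R) ... compute Iw = IR * R^T
      double col[3] = {K.R[c], K.R[3 + c], K.R[6 + c]};
      matvec(IR, col, Iw + 3 * c);
    }
    double Iww[3], gyro[3];
    const double w[3] = {wx, wy, wz};
    matvec(Iw, w, Iww);
    cross(w, Iww, gyro);
    double rhs[3] = {T[3 * b + 0] - gyro[0], T[3 * b + 1] - gyro[1],
                     T[3 * b + 2] - gyro[2]};
    // solve 3x3 Iw * dw = rhs (closed-form inverse; Iw SPD)
    const double a11 = Iw[0], a12 = Iw[3], a13 = Iw[6];
    const double a21 = Iw[1], a22 = Iw[4], a23 = Iw[7];
    const double a31 = Iw[2], a32 = Iw[5], a33 = Iw[8];
    const double det = a11 * (a22 * a33 - a23 * a32)
                     - a12 * (a21 * a33 - a23 * a31)
                     + a13 * (a21 * a32 - a22 * a31);
    d[10] = ((a22 * a33 - a23 * a32) * rhs[0] +
             (a13 * a32 - a12 * a33) * rhs[1] +
             (a12 * a23 - a13 * a22) * rhs[2]) / det;
    d[11] = ((a23 * a31 - a21 * a33) * rhs[0] +
             (a11 * a33 - a13 * a31) * rhs[1] +
             (a13 * a21 - a11 * a23) * rhs[2]) / det;
    d[12] = ((a21 * a32 - a22 * a31) * rhs[0] +
             (a12 * a31 - a11 * a32) * rhs[1] +
             (a11 * a22 - a12 * a21) * rhs[2]) / det;
  }
  return dy;
}
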