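#include <Rcpp.h>
using namespace Rcpp;

// Force kernels for the coarse-grained peptidoglycan meshwork and the
// overdamped (Euler-Maruyama) Langevin integrator. Units: nm, s, pN.
// Bonds (glycan segments and peptide cross-links alike) are Hookean with a
// per-bond rest length and stiffness; bending is a discrete worm-like-chain
// angle potential; pressure acts along oriented surface triangles; the old
// cell wall is a rigid cylinder-plus-polar-cap surface with half-harmonic
// exclusion.

namespace {

inline double wall_signed_dist(double x, double y, double z,
                               double R, double Lp,
                               double *nx, double *ny, double *nz) {
  if (z <= Lp) {
    double rho = std::sqrt(x * x + y * y);
    if (rho < 1e-12) { *nx = 1; *ny = 0; *nz = 0; return -R; }
    *nx = x / rho; *ny = y / rho; *nz = 0;
    return rho - R;
  }
  double dz = z - Lp;
  double d = std::sqrt(x * x + y * y + dz * dz);
  if (d < 1e-12) { *nx = 0; *ny = 0; *nz = 1; return -R; }
  *nx = x / d; *ny = y / d; *nz = dz / d;
  return d - R;
}

void add_bond_forces(const double *px, const double *py, const double *pz,
                     const int *a, const int *b, const double *rest,
                     const double *kb, int nb,
                     double *fx, double *fy, double *fz) {
  for (int i = 0; i < nb; ++i) {
    int ia = a[i] - 1, ib = b[i] - 1;
    double dx = px[ib] - px[ia], dy = py[ib] - py[ia], dz = pz[ib] - pz[ia];
    double len = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (len < 1e-12) continue; // coincident beads flagged at the R level
    double f = kb[i] * (len - rest[i]) / len; // attractive when stretched
    fx[ia] += f * dx; fy[ia] += f * dy; fz[ia] += f * dz;
    fx[ib] -= f * dx; fy[ib] -= f * dy; fz[ib] -= f * dz;
  }
}

// discrete WLC bending: energy kb * (1 - cos(phi - phi0)) at the bond angle
// phi formed at bead j by neighbours i and k (straight chain: phi = pi)
void add_bend_forces(const double *px, const double *py, const double *pz,
                     const int *ti, const int *tj, const int *tk,
                     const double *phi0, double kb, int nt,
                     double *fx, double *fy, double *fz) {
  for (int t = 0; t < nt; ++t) {
    int i = ti[t] - 1, j = tj[t] - 1, k = tk[t] - 1;
    double ux = px[i] - px[j], uy = py[i] - py[j], uz = pz[i] - pz[j];
    double wx = px[k] - px[j], wy = py[k] - py[j], wz = pz[k] - pz[j];
    double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
    double nw = std::sqrt(wx * wx + wy * wy + wz * wz);
    if (nu < 1e-12 || nw < 1e-12) continue;
    double c = (ux * wx + uy * wy + uz * wz) / (nu * nw);
    c = std::max(-1.0, std::min(1.0, c));
    double phi = std::acos(c);
    double s = std::sqrt(std::max(1.0 - c * c, 1e-18));
    // dE/dcos(phi) = kb * sin(phi - phi0) * (-1/sin(phi))
    double dEdc = -kb * std::sin(phi - phi0[t]) / s;
    // gradients of cos(phi)
    double gix = wx / (nu * nw) - c * ux / (nu * nu);
    double giy = wy / (nu * nw) - c * uy / (nu * nu);
    double giz = wz / (nu * nw) - c * uz / (nu * nu);
    double gkx = ux / (nu * nw) - c * wx / (nw * nw);
    double gky = uy / (nu * nw) - c * wy / (nw * nw);
    double gkz = uz / (nu * nw) - c * wz / (nw * nw);
    fx[i] -= dEdc * gix; fy[i] -= dEdc * giy; fz[i] -= dEdc * giz;
    fx[k] -= dEdc * gkx; fy[k] -= dEdc * gky; fz[k] -= dEdc * gkz;
    fx[j] += dEdc * (gix + gkx);
    fy[j] += dEdc * (giy + gky);
    fz[j] += dEdc * (giz + gkz);
  }
}

void add_anchor_forces(const double *px, const double *py, const double *pz,
                       const int *bead, const double *ax, const double *ay,
                       const double *az, const double *rest, double k, int na,
                       double *fx, double *fy, double *fz) {
  for (int i = 0; i < na; ++i) {
    int ib = bead[i] - 1;
    double dx = ax[i] - px[ib], dy = ay[i] - py[ib], dz = az[i] - pz[ib];
    double len = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (len < 1e-12) continue;
    double f = k * (len - rest[i]) / len;
    fx[ib] += f * dx; fy[ib] += f * dy; fz[ib] += f * dz;
  }
}

// pressure: each oriented triangle contributes dp * A_vec / 3 to its vertices
void add_pressure_forces(const double *px, const double *py, const double *pz,
                         const int *t1, const int *t2, const int *t3,
                         double dp, int nt,
                         double *fx, double *fy, double *fz) {
  for (int t = 0; t < nt; ++t) {
    int a = t1[t] - 1, b = t2[t] - 1, c = t3[t] - 1;
    double ux = px[b] - px[a], uy = py[b] - py[a], uz = pz[b] - pz[a];
    double vx = px[c] - px[a], vy = py[c] - py[a], vz = pz[c] - pz[a];
    double nx = 0.5 * (uy * vz - uz * vy);
    double ny = 0.5 * (uz * vx - ux * vz);
    double nz = 0.5 * (ux * vy - uy * vx);
    double w = dp / 3.0;
    fx[a] += w * nx; fy[a] += w * ny; fz[a] += w * nz;
    fx[b] += w * nx; fy[b] += w * ny; fz[b] += w * nz;
    fx[c] += w * nx; fy[c] += w * ny; fz[c] += w * nz;
  }
}

void add_wall_forces(const double *px, const double *py, const double *pz,
                     int n, double R, double Lp, double kwall,
                     double *fx, double *fy, double *fz) {
  for (int i = 0; i < n; ++i) {
    double nx, ny, nz;
    double d = wall_signed_dist(px[i], py[i], pz[i], R, Lp, &nx, &ny, &nz);
    if (d > 0) { // penetrated outward through the old wall
      fx[i] -= kwall * d * nx;
      fy[i] -= kwall * d * ny;
      fz[i] -= kwall * d * nz;
    }
  }
}

} // namespace

// [[Rcpp::export]]
NumericMatrix bonds_force_cpp(NumericMatrix pos, IntegerVector a,
                              IntegerVector b, NumericVector rest,
                              NumericVector k) {
  int n = pos.nrow();
  NumericMatrix F(n, 3);
  std::vector<double> px(n), py(n), pz(n), fx(n, 0), fy(n, 0), fz(n, 0);
  for (int i = 0; i < n; ++i) { px[i] = pos(i,0); py[i] = pos(i,1); pz[i] = pos(i,2); }
  add_bond_forces(px.data(), py.data(), pz.data(), a.begin(), b.begin(),
                  rest.begin(), k.begin(), a.size(),
                  fx.data(), fy.data(), fz.data());
  for (int i = 0; i < n; ++i) { F(i,0) = fx[i]; F(i,1) = fy[i]; F(i,2) = fz[i]; }
  return F;
}

// [[Rcpp::export]]
double bonds_energy_cpp(NumericMatrix pos, IntegerVector a, IntegerVector b,
                        NumericVector rest, NumericVector k) {
  double e = 0;
  for (int i = 0; i < a.size(); ++i) {
    int ia = a[i] - 1, ib = b[i] - 1;
    double dx = pos(ib,0) - pos(ia,0);
    double dy = pos(ib,1) - pos(ia,1);
    double dz = pos(ib,2) - pos(ia,2);
    double len = std::sqrt(dx*dx + dy*dy + dz*dz);
    e += 0.5 * k[i] * (len - rest[i]) * (len - rest[i]);
  }
  return e;
}

// [[Rcpp::export]]
NumericMatrix bend_force_cpp(NumericMatrix pos, IntegerMatrix triples,
                             NumericVector phi0, double kb) {
  int n = pos.nrow();
  NumericMatrix F(n, 3);
  std::vector<double> px(n), py(n), pz(n), fx(n, 0), fy(n, 0), fz(n, 0);
  for (int i = 0; i < n; ++i) { px[i] = pos(i,0); py[i] = pos(i,1); pz[i] = pos(i,2); }
  std::vector<int> ti(triples.nrow()), tj(triples.nrow()), tk(triples.nrow());
  for (int t = 0; t < triples.nrow(); ++t) {
    ti[t] = triples(t,0); tj[t] = triples(t,1); tk[t] = triples(t,2);
  }
  add_bend_forces(px.data(), py.data(), pz.data(), ti.data(), tj.data(),
                  tk.data(), phi0.begin(), kb, triples.nrow(),
                  fx.data(), fy.data(), fz.data());
  for (int i = 0; i < n; ++i) { F(i,0) = fx[i]; F(i,1) = fy[i]; F(i,2) = fz[i]; }
  return F;
}

// [[Rcpp::export]]
double bend_energy_cpp(NumericMatrix pos, IntegerMatrix triples,
                       NumericVector phi0, double kb) {
  double e = 0;
  for (int t = 0; t < triples.nrow(); ++t) {
    int i = triples(t,0) - 1, j = triples(t,1) - 1, k = triples(t,2) - 1;
    double ux = pos(i,0) - pos(j,0), uy = pos(i,1) - pos(j,1), uz = pos(i,2) - pos(j,2);
    double wx = pos(k,0) - pos(j,0), wy = pos(k,1) - pos(j,1), wz = pos(k,2) - pos(j,2);
    double nu = std::sqrt(ux*ux + uy*uy + uz*uz);
    double nw = std::sqrt(wx*wx + wy*wy + wz*wz);
    if (nu < 1e-12 || nw < 1e-12) continue;
    double c = std::max(-1.0, std::min(1.0, (ux*wx + uy*wy + uz*wz) / (nu*nw)));
    e += kb * (1.0 - std::cos(std::acos(c) - phi0[t]));
  }
  return e;
}

// [[Rcpp::export]]
NumericMatrix anchor_force_cpp(NumericMatrix pos, IntegerVector bead,
                               NumericMatrix anchor, NumericVector rest,
                               double k) {
  int n = pos.nrow();
  NumericMatrix F(n, 3);
  std::vector<double> px(n), py(n), pz(n), fx(n, 0), fy(n, 0), fz(n, 0);
  for (int i = 0; i < n; ++i) { px[i] = pos(i,0); py[i] = pos(i,1); pz[i] = pos(i,2); }
  std::vector<double> ax(bead.size()), ay(bead.size()), az(bead.size());
  for (int i = 0; i < bead.size(); ++i) {
    ax[i] = anchor(i,0); ay[i] = anchor(i,1); az[i] = anchor(i,2);
  }
  add_anchor_forces(px.data(), py.data(), pz.data(), bead.begin(), ax.data(),
                    ay.data(), az.data(), rest.begin(), k, bead.size(),
                    fx.data(), fy.data(), fz.data());
  for (int i = 0; i < n; ++i) { F(i,0) = fx[i]; F(i,1) = fy[i]; F(i,2) = fz[i]; }
  return F;
}

// [[Rcpp::export]]
double anchor_energy_cpp(NumericMatrix pos, IntegerVector bead,
                         NumericMatrix anchor, NumericVector rest, double k) {
  double e = 0;
  for (int i = 0; i < bead.size(); ++i) {
    int ib = bead[i] - 1;
    double dx = anchor(i,0) - pos(ib,0);
    double dy = anchor(i,1) - pos(ib,1);
    double dz = anchor(i,2) - pos(ib,2);
    double len = std::sqrt(dx*dx + dy*dy + dz*dz);
    e += 0.5 * k * (len - rest[i]) * (len - rest[i]);
  }
  return e;
}

// [[Rcpp::export]]
NumericMatrix pressure_force_cpp(NumericMatrix pos, IntegerMatrix tri,
                                 double dp) {
  int n = pos.nrow();
  NumericMatrix F(n, 3);
  std::vector<double> px(n), py(n), pz(n), fx(n, 0), fy(n, 0), fz(n, 0);
  for (int i = 0; i < n; ++i) { px[i] = pos(i,0); py[i] = pos(i,1); pz[i] = pos(i,2); }
  std::vector<int> t1(tri.nrow()), t2(tri.nrow()), t3(tri.nrow());
  for (int t = 0; t < tri.nrow(); ++t) {
    t1[t] = tri(t,0); t2[t] = tri(t,1); t3[t] = tri(t,2);
  }
  add_pressure_forces(px.data(), py.data(), pz.data(), t1.data(), t2.data(),
                      t3.data(), dp, tri.nrow(), fx.data(), fy.data(), fz.data());
  for (int i = 0; i < n; ++i) { F(i,0) = fx[i]; F(i,1) = fy[i]; F(i,2) = fz[i]; }
  return F;
}

// [[Rcpp::export]]
NumericMatrix wall_force_cpp(NumericMatrix pos, double R, double Lp,
                             double kwall) {
  int n = pos.nrow();
  NumericMatrix F(n, 3);
  std::vector<double> px(n), py(n), pz(n), fx(n, 0), fy(n, 0), fz(n, 0);
  for (int i = 0; i < n; ++i) { px[i] = pos(i,0); py[i] = pos(i,1); pz[i] = pos(i,2); }
  add_wall_forces(px.data(), py.data(), pz.data(), n, R, Lp, kwall,
                  fx.data(), fy.data(), fz.data());
  for (int i = 0; i < n; ++i) { F(i,0) = fx[i]; F(i,1) = fy[i]; F(i,2) = fz[i]; }
  return F;
}

// [[Rcpp::export]]
double wall_energy_cpp(NumericMatrix pos, double R, double Lp, double kwall) {
  double e = 0, nx, ny, nz;
  for (int i = 0; i < pos.nrow(); ++i) {
    double d = wall_signed_dist(pos(i,0), pos(i,1), pos(i,2), R, Lp,
                                &nx, &ny, &nz);
    if (d > 0) e += 0.5 * kwall * d * d;
  }
  return e;
}

// [[Rcpp::export]]
NumericVector wall_distance_cpp(NumericMatrix pos, double R, double Lp) {
  NumericVector d(pos.nrow());
  double nx, ny, nz;
  for (int i = 0; i < pos.nrow(); ++i)
    d[i] = wall_signed_dist(pos(i,0), pos(i,1), pos(i,2), R, Lp, &nx, &ny, &nz);
  return d;
}

// Euler-Maruyama integration of the overdamped Langevin equation,
// zeta dr/dt = F_spring + F_bend + F_pep + F_stoch + F_dp + F_wall.
// Runs nsteps updates in place; aborts if any per-step displacement exceeds
// max_disp (instability guard). Optionally records positions of one bead.
// [[Rcpp::export]]
List relax_cpp(NumericMatrix pos,
               IntegerVector ba, IntegerVector bb, NumericVector brest,
               NumericVector bk,
               IntegerMatrix triples, NumericVector phi0, double kb,
               IntegerVector jbead, NumericMatrix janchor, NumericVector jrest,
               double kjun,
               IntegerMatrix tri, double dp,
               double wallR, double wallLp, double kwall,
               double zeta, double kBT, double dt, int nsteps,
               double max_disp, int sample_bead = 0, int sample_every = 0) {
  int n = pos.nrow();
  std::vector<double> px(n), py(n), pz(n), fx(n), fy(n), fz(n);
  for (int i = 0; i < n; ++i) { px[i] = pos(i,0); py[i] = pos(i,1); pz[i] = pos(i,2); }
  int nb = ba.size(), nt = triples.nrow(), na = jbead.size(), ntri = tri.nrow();
  std::vector<int> ti(nt), tj(nt), tk(nt), t1(ntri), t2(ntri), t3(ntri);
  for (int t = 0; t < nt; ++t) { ti[t]=triples(t,0); tj[t]=triples(t,1); tk[t]=triples(t,2); }
  for (int t = 0; t < ntri; ++t) { t1[t]=tri(t,0); t2[t]=tri(t,1); t3[t]=tri(t,2); }
  std::vector<double> ax(na), ay(na), az(na);
  for (int i = 0; i < na; ++i) { ax[i]=janchor(i,0); ay[i]=janchor(i,1); az[i]=janchor(i,2); }

  double noise_sd = (kBT > 0) ? std::sqrt(2.0 * kBT * zeta / dt) : 0.0;
  double mob = dt / zeta;
  int nsamp = (sample_every > 0) ? nsteps / sample_every : 0;
  NumericMatrix samples(std::max(nsamp, 0), 3);
  int isamp = 0;
  bool ok = true;
  int steps_done = 0;

  for (int s = 0; s < nsteps; ++s) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    add_bond_forces(px.data(), py.data(), pz.data(), ba.begin(), bb.begin(),
                    brest.begin(), bk.begin(), nb, fx.data(), fy.data(), fz.data());
    if (nt > 0)
      add_bend_forces(px.data(), py.data(), pz.data(), ti.data(), tj.data(),
                      tk.data(), phi0.begin(), kb, nt,
                      fx.data(), fy.data(), fz.data());
    if (na > 0)
      add_anchor_forces(px.data(), py.data(), pz.data(), jbead.begin(),
                        ax.data(), ay.data(), az.data(), jrest.begin(), kjun,
                        na, fx.data(), fy.data(), fz.data());
    if (ntri > 0 && dp != 0)
      add_pressure_forces(px.data(), py.data(), pz.data(), t1.data(),
                          t2.data(), t3.data(), dp, ntri,
                          fx.data(), fy.data(), fz.data());
    if (kwall > 0)
      add_wall_forces(px.data(), py.data(), pz.data(), n, wallR, wallLp,
                      kwall, fx.data(), fy.data(), fz.data());
    if (noise_sd > 0) {
      for (int i = 0; i < n; ++i) {
        fx[i] += noise_sd * norm_rand();
        fy[i] += noise_sd * norm_rand();
        fz[i] += noise_sd * norm_rand();
      }
    }
    double worst = 0;
    for (int i = 0; i < n; ++i) {
      double dx = mob * fx[i], dy = mob * fy[i], dz = mob * fz[i];
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 > worst) worst = d2;
      px[i] += dx; py[i] += dy; pz[i] += dz;
    }
    ++steps_done;
    if (std::sqrt(worst) > max_disp) { ok = false; break; }
    if (sample_every > 0 && (s + 1) % sample_every == 0 && isamp < nsamp) {
      samples(isamp, 0) = px[sample_bead - 1];
      samples(isamp, 1) = py[sample_bead - 1];
      samples(isamp, 2) = pz[sample_bead - 1];
      ++isamp;
    }
    if ((s & 0x3FF) == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) { out(i,0)=px[i]; out(i,1)=py[i]; out(i,2)=pz[i]; }
  return List::create(_["pos"] = out, _["ok"] = ok,
                      _["steps"] = steps_done, _["samples"] = samples);
}
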