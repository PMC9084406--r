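// Meridian-plane polarized-light Monte Carlo over a voxelated domain.
//
// Photon packets carry a Stokes vector referenced to the meridian plane
// (the plane through the propagation direction and +z).  Free paths are
// sampled in scattering optical depth and consumed voxel-by-voxel;
// absorption attenuates the packet weight continuously along each
// traversed segment.  At a scattering event the zenith/azimuth pair is
// drawn by rejection from the bivariate polarized phase function
//   P(theta, phi) = s11(theta) I + s12(theta) [Q cos 2phi + U sin 2phi]
// and the Stokes vector is updated by the rotation-matrix-rotation
// composition R(gamma) M(theta) R(phi), all frames handled by explicit
// 3-vector algebra rather than spherical trigonometry.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 v3(double x, double y, double z) { return Vec3{x, y, z}; }
inline Vec3 operator+(Vec3 a, Vec3 b) { return v3(a.x + b.x, a.y + b.y, a.z + b.z); }
inline Vec3 operator-(Vec3 a, Vec3 b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
inline Vec3 operator*(double s, Vec3 a) { return v3(s * a.x, s * a.y, s * a.z); }
inline double dot(Vec3 a, Vec3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline Vec3 cross(Vec3 a, Vec3 b) {
  return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
inline double norm(Vec3 a) { return std::sqrt(dot(a, a)); }
inline Vec3 unit(Vec3 a) { double n = norm(a); return v3(a.x / n, a.y / n, a.z / n); }

struct Stokes {
  double I, Q, U, V;
};

// Mueller rotation of the reference frame by psi about the propagation
// direction (new e_par = cos psi e_par + sin psi e_perp).
inline void rotate_ref(Stokes &s, double cpsi, double spsi) {
  // cos 2psi, sin 2psi from the single-angle values
  double c2 = cpsi * cpsi - spsi * spsi;
  double s2 = 2.0 * spsi * cpsi;
  double Q = s.Q * c2 + s.U * s2;
  double U = -s.Q * s2 + s.U * c2;
  s.Q = Q;
  s.U = U;
}

inline void rotate_ref_angle(Stokes &s, double psi) {
  rotate_ref(s, std::cos(psi), std::sin(psi));
}

// Meridian-plane basis of a direction u: e_par lies in the plane through
// u and +z, perpendicular to u, pointing away from the pole; e_perp
// completes the right-handed triad e_par x e_perp = u.  For u within
// 1e-6 of +/-z the meridian is taken as the x-z plane.
inline void meridian_frame(Vec3 u, Vec3 &epar, Vec3 &eperp) {
  double st2 = u.x * u.x + u.y * u.y;
  if (st2 < 1e-12) {
    epar = v3(1.0, 0.0, 0.0);
  } else {
    epar = unit(v3(u.x * u.z, u.y * u.z, u.z * u.z - 1.0));
  }
  eperp = cross(u, epar);
}

// Frame whose e_par is the projection of the global +x axis onto the
// plane normal to u: the detector reference (Q > 0 along +x).
inline void detector_frame(Vec3 u, Vec3 &epar, Vec3 &eperp) {
  Vec3 xr = v3(1.0 - u.x * u.x, -u.x * u.y, -u.x * u.z);
  double n2 = dot(xr, xr);
  if (n2 < 1e-12) {
    // u along +/-x: fall back to the projection of +z
    xr = v3(-u.z * u.x, -u.z * u.y, 1.0 - u.z * u.z);
  }
  epar = unit(xr);
  eperp = cross(u, epar);
}

// Signed rotation angle about u taking frame (a_par, .) into (b_par, .):
// returns (cos psi, sin psi).
inline void frame_angle(Vec3 u, Vec3 a_par, Vec3 b_par, double &c, double &s) {
  c = dot(a_par, b_par);
  s = dot(cross(a_par, b_par), u);
}

// One scattering update: given direction u, meridian-frame Stokes s,
// sampled (theta, phi) and the four matrix elements at theta, produce
// the new direction and the renormalized meridian-frame Stokes vector.
inline void scatter_apply(Vec3 &u, Stokes &s, double ct, double st,
                          double phi, double s11, double s12, double s33,
                          double s34) {
  Vec3 epar, eperp;
  meridian_frame(u, epar, eperp);
  double cphi = std::cos(phi), sphi = std::sin(phi);
  Vec3 epar_s = cphi * epar + sphi * eperp;   // in the scattering plane
  Vec3 eperp_s = -sphi * epar + cphi * eperp;
  rotate_ref(s, cphi, sphi);                  // R(phi)

  double I = s11 * s.I + s12 * s.Q;           // M(theta)
  double Q = s12 * s.I + s11 * s.Q;
  double U = s33 * s.U + s34 * s.V;
  double V = -s34 * s.U + s33 * s.V;
  s.I = I; s.Q = Q; s.U = U; s.V = V;

  Vec3 u2 = unit(ct * u + st * epar_s);
  Vec3 epar_after = cross(eperp_s, u2);       // e_par stays in the scattering plane

  Vec3 epar2, eperp2;
  meridian_frame(u2, epar2, eperp2);
  double cg, sg;
  frame_angle(u2, epar_after, epar2, cg, sg);
  rotate_ref(s, cg, sg);                      // R(gamma)

  double inv = 1.0 / s.I;
  s.I = 1.0; s.Q *= inv; s.U *= inv; s.V *= inv;
  u = u2;
}

// Sampler for the bivariate polarized phase function
//   P(theta, phi) = s11(theta) I + s12(theta) [Q cos 2phi + U sin 2phi]
// weighted by sin(theta), with theta discretised to the table grid.
// The azimuth integral of the s12 term vanishes, so the exact zenith
// marginal is s11(theta) sin(theta): theta is drawn from the tabulated
// cell-weight CDF (inverse transform, cells being the nearest-index
// rounding regions, cos(theta) uniform within a cell), and the
// azimuth-dependent factor is accepted by rejection against the bound
// s11 + |s12|, which never costs more than two candidates on average.
struct PhaseSampler {
  const double *s11, *s12;  // table values per cell
  const double *cdf;        // cumulative cell weights, last = 1
  const double *edge_mu;    // ng + 1 cell-edge cosines, decreasing
  int ng;
  double envelope;          // max over cells of 1 + |s12|/s11

  // returns the cell index; mu/st are cos/sin of the sampled zenith
  inline int sample(double I, double Q, double U, double &mu, double &st,
                    double &phi, long long &trials, int guard) const {
    int tries = 0;
    for (;;) {
      if (++tries > guard)
        stop("rejection sampler exceeded %d trials: envelope does not bound the phase function",
             guard);
      ++trials;
      double xi = unif_rand();
      int lo = 0, hi = ng - 1;        // first cell with cdf >= xi
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (cdf[mid] < xi) lo = mid + 1; else hi = mid;
      }
      double m_hi = edge_mu[lo], m_lo = edge_mu[lo + 1];
      mu = m_lo + unif_rand() * (m_hi - m_lo);
      phi = 2.0 * M_PI * unif_rand();
      double P = s11[lo] * I +
                 s12[lo] * (Q * std::cos(2.0 * phi) + U * std::sin(2.0 * phi));
      if (unif_rand() * envelope * s11[lo] <= P) {
        if (mu > 1.0) mu = 1.0; else if (mu < -1.0) mu = -1.0;
        st = std::sqrt(1.0 - mu * mu);
        return lo;
      }
    }
  }
};

}  // namespace

// ---------------------------------------------------------------------
// Small exported pieces (unit-testable surfaces of the transport module)
// ---------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_rotate_stokes(NumericVector stokes, double psi) {
  Stokes s{stokes[0], stokes[1], stokes[2], stokes[3]};
  rotate_ref_angle(s, psi);
  return NumericVector::create(s.I, s.Q, s.U, s.V);
}

// [[Rcpp::export]]
NumericVector cpp_update_direction(NumericVector direction, double theta,
                                   double phi) {
  Vec3 u = v3(direction[0], direction[1], direction[2]);
  Vec3 epar, eperp;
  meridian_frame(u, epar, eperp);
  Vec3 epar_s = std::cos(phi) * epar + std::sin(phi) * eperp;
  Vec3 u2 = unit(std::cos(theta) * u + std::sin(theta) * epar_s);
  return NumericVector::create(u2.x, u2.y, u2.z);
}

// [[Rcpp::export]]
List cpp_meridian_frame(NumericVector direction) {
  Vec3 u = v3(direction[0], direction[1], direction[2]);
  Vec3 epar, eperp;
  meridian_frame(u, epar, eperp);
  return List::create(
      _["e_par"] = NumericVector::create(epar.x, epar.y, epar.z),
      _["e_perp"] = NumericVector::create(eperp.x, eperp.y, eperp.z));
}

// [[Rcpp::export]]
List cpp_scatter_update(NumericVector direction, NumericVector stokes,
                        double theta, double phi, double s11, double s12,
                        double s33, double s34) {
  Vec3 u = v3(direction[0], direction[1], direction[2]);
  Stokes s{stokes[0], stokes[1], stokes[2], stokes[3]};
  scatter_apply(u, s, std::cos(theta), std::sin(theta), phi, s11, s12, s33,
                s34);
  return List::create(
      _["direction"] = NumericVector::create(u.x, u.y, u.z),
      _["stokes"] = NumericVector::create(s.I, s.Q, s.U, s.V));
}

// [[Rcpp::export]]
NumericVector cpp_detector_rotate(NumericVector stokes,
                                  NumericVector direction) {
  Vec3 u = v3(direction[0], direction[1], direction[2]);
  Stokes s{stokes[0], stokes[1], stokes[2], stokes[3]};
  Vec3 epar, eperp, dpar, dperp;
  meridian_frame(u, epar, eperp);
  detector_frame(u, dpar, dperp);
  double c, sn;
  frame_angle(u, epar, dpar, c, sn);
  rotate_ref(s, c, sn);
  return NumericVector::create(s.I, s.Q, s.U, s.V);
}

// Sampling of (theta, phi) from the bivariate polarized phase function
// for a meridian-frame Stokes vector and a tabulated matrix: exact
// inverse-CDF draw of theta from its s11 sin(theta) marginal (cdf /
// edge_mu describe the grid cells), rejection on the azimuth factor.
// Returns an n x 2 matrix of (theta, phi) plus the candidate count as
// an attribute.
// [[Rcpp::export]]
NumericMatrix cpp_sample_angles(NumericVector stokes, NumericVector s11,
                                NumericVector s12, NumericVector cdf,
                                NumericVector edge_mu, double envelope,
                                int n, int guard = 1000000) {
  PhaseSampler ps{REAL(s11), REAL(s12), REAL(cdf), REAL(edge_mu),
                  (int)s11.size(), envelope};
  NumericMatrix out(n, 2);
  double I = stokes[0], Q = stokes[1], U = stokes[2];
  long long trials = 0;
  for (int i = 0; i < n; ++i) {
    double mu, st, phi;
    ps.sample(I, Q, U, mu, st, phi, trials, guard);
    out(i, 0) = std::acos(mu);
    out(i, 1) = phi;
  }
  out.attr("trials") = (double)trials;
  return out;
}

// Russian roulette applied independently to n packets of weight w.
// [[Rcpp::export]]
NumericVector cpp_roulette(double w, double w_threshold, double p_survive,
                           int n) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    if (w >= w_threshold) {
      out[i] = w;
    } else {
      out[i] = (unif_rand() < p_survive) ? w / p_survive : 0.0;
    }
  }
  return out;
}

// ---------------------------------------------------------------------
// Voxel traversal
// ---------------------------------------------------------------------

namespace {

struct Domain {
  const int *labels;   // nx*ny*nz, x fastest
  int nx, ny, nz;
  double h;            // cubic voxel edge (mm)
  double Lx, Ly, Lz;
  const double *mua;   // per medium (label k -> index k-1)
  const double *mus;
  bool cyclic_xy;
};

enum EventType { EV_SCATTER = 0, EV_DETECT = 1, EV_TRANSMIT = 2,
                 EV_SIDE = 3, EV_AMBIENT = 4, EV_STUCK = 5 };

const double NUDGE = 1e-9;  // mm, boundary-crossing advance

// periodic wrap of a coordinate into [0, L)
inline double wrap_coord(double x, double L) {
  double r = x - std::floor(x / L) * L;
  return (r >= L) ? 0.0 : r;
}

// March a ray until the scattering optical depth tau is consumed or the
// packet leaves the domain.  Weight is attenuated by exp(-mua l) on each
// segment; deposits land in absorb_grid when provided.
inline EventType trace_to_event(const Domain &d, Vec3 &pos, Vec3 dir,
                                double tau, double &w, int &medium,
                                double *absorb_grid, double &absorbed,
                                double &path_len) {
  for (int iter = 0; iter < 100000000; ++iter) {
    int i = (int)std::floor(pos.x / d.h);
    int j = (int)std::floor(pos.y / d.h);
    int k = (int)std::floor(pos.z / d.h);
    if (k < 0) return EV_DETECT;
    if (k >= d.nz) return EV_TRANSMIT;
    if (i < 0 || i >= d.nx || j < 0 || j >= d.ny) {
      if (!d.cyclic_xy) return EV_SIDE;
      pos.x = wrap_coord(pos.x, d.Lx);
      pos.y = wrap_coord(pos.y, d.Ly);
      continue;
    }
    int lab = d.labels[i + d.nx * (j + (long long)d.ny * k)];
    if (lab == 0) return EV_AMBIENT;
    int med = lab - 1;
    double ms = d.mus[med], ma = d.mua[med];

    // distance to the voxel exit along dir
    double t_exit = HUGE_VAL;
    if (dir.x > 0)      t_exit = std::min(t_exit, ((i + 1) * d.h - pos.x) / dir.x);
    else if (dir.x < 0) t_exit = std::min(t_exit, (i * d.h - pos.x) / dir.x);
    if (dir.y > 0)      t_exit = std::min(t_exit, ((j + 1) * d.h - pos.y) / dir.y);
    else if (dir.y < 0) t_exit = std::min(t_exit, (j * d.h - pos.y) / dir.y);
    if (dir.z > 0)      t_exit = std::min(t_exit, ((k + 1) * d.h - pos.z) / dir.z);
    else if (dir.z < 0) t_exit = std::min(t_exit, (k * d.h - pos.z) / dir.z);
    if (!(t_exit >= 0)) t_exit = 0.0;   // roundoff at a face

    double l;
    bool scatter_here = (ms > 0) && (tau <= ms * t_exit);
    l = scatter_here ? tau / ms : t_exit;

    if (ma > 0 && l > 0) {
      double frac = std::exp(-ma * l);
      double dep = w * (1.0 - frac);
      w *= frac;
      absorbed += dep;
      if (absorb_grid)
        absorb_grid[i + d.nx * (j + (long long)d.ny * k)] += dep;
    }
    pos = pos + l * dir;
    path_len += l;

    if (scatter_here) {
      medium = med;
      return EV_SCATTER;
    }
    tau -= ms * l;
    pos = pos + NUDGE * dir;   // step across the face
    path_len += NUDGE;
  }
  return EV_STUCK;
}

}  // namespace

// Exposed tracer for unit tests: first event for a single ray.
// [[Rcpp::export]]
List cpp_trace_first_event(NumericVector position, NumericVector direction,
                           double tau, IntegerVector labels,
                           IntegerVector dims, double voxel_size,
                           NumericVector mua, NumericVector mus,
                           bool cyclic_xy = false) {
  Domain d;
  d.labels = INTEGER(labels);
  d.nx = dims[0]; d.ny = dims[1]; d.nz = dims[2];
  d.h = voxel_size;
  d.Lx = d.nx * d.h; d.Ly = d.ny * d.h; d.Lz = d.nz * d.h;
  d.mua = REAL(mua); d.mus = REAL(mus);
  d.cyclic_xy = cyclic_xy;
  Vec3 pos = v3(position[0], position[1], position[2]);
  Vec3 dir = unit(v3(direction[0], direction[1], direction[2]));
  double w = 1.0, absorbed = 0.0, path = 0.0;
  int med = -1;
  EventType ev = trace_to_event(d, pos, dir, tau, w, med, nullptr,
                                absorbed, path);
  const char *names[] = {"scatter", "detect", "transmit", "side",
                         "ambient", "stuck"};
  return List::create(
      _["event"] = std::string(names[ev]),
      _["position"] = NumericVector::create(pos.x, pos.y, pos.z),
      _["weight"] = w,
      _["absorbed"] = absorbed,
      _["path_length"] = path,
      _["medium"] = med + 1);
}

// ---------------------------------------------------------------------
// Full simulation loop
// ---------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_run_simulation(IntegerVector labels, IntegerVector dims,
                        double voxel_size, NumericVector mua,
                        NumericVector mus, NumericMatrix s11m,
                        NumericMatrix s12m, NumericMatrix s33m,
                        NumericMatrix s34m, NumericMatrix cdfm,
                        NumericVector edge_mu, NumericVector envelope,
                        int src_type, NumericVector src_pos,
                        NumericVector src_dir, NumericVector src_extent,
                        NumericVector src_stokes, bool cyclic_xy,
                        IntegerVector det_pixels, NumericVector det_origin,
                        NumericVector det_size, double n_photons,
                        double w_threshold, double p_survive,
                        bool save_absorption, int rejection_guard) {
  Domain d;
  d.labels = INTEGER(labels);
  d.nx = dims[0]; d.ny = dims[1]; d.nz = dims[2];
  d.h = voxel_size;
  d.Lx = d.nx * d.h; d.Ly = d.ny * d.h; d.Lz = d.nz * d.h;
  d.mua = REAL(mua); d.mus = REAL(mus);
  d.cyclic_xy = cyclic_xy;

  int ng = s11m.nrow();
  int px = det_pixels[0], py = det_pixels[1];
  double pitch_x = det_size[0] / px, pitch_y = det_size[1] / py;

  std::vector<double> imI((size_t)px * py, 0.0), imQ((size_t)px * py, 0.0),
      imU((size_t)px * py, 0.0), imV((size_t)px * py, 0.0);
  std::vector<double> absorb_grid;
  double *agrid = nullptr;
  if (save_absorption) {
    absorb_grid.assign((size_t)d.nx * d.ny * d.nz, 0.0);
    agrid = absorb_grid.data();
  }

  double totI = 0, totQ = 0, totU = 0, totV = 0;
  double offI = 0;                     // z=0 exits outside the detector extent
  double sum_d = 0, sum_d2 = 0;        // per-photon detected weight moments
  double sum_q2 = 0, sum_u2 = 0, sum_v2 = 0;  // detected Q,U,V second moments
  double transmitted = 0, side_escaped = 0, ambient_escaped = 0;
  double absorbed = 0, killed = 0, boosted = 0;
  double stuck_weight = 0;
  long long n_scatter = 0, n_trials = 0;

  Vec3 u0 = unit(v3(src_dir[0], src_dir[1], src_dir[2]));
  Stokes s0{src_stokes[0], src_stokes[1], src_stokes[2], src_stokes[3]};
  {  // renormalize incident Stokes to I = 1
    double inv = 1.0 / s0.I;
    s0.I = 1.0; s0.Q *= inv; s0.U *= inv; s0.V *= inv;
  }

  long long N = (long long)n_photons;
  for (long long ip = 0; ip < N; ++ip) {
    if ((ip & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    Vec3 pos;
    if (src_type == 0) {
      pos = v3(src_pos[0], src_pos[1], src_pos[2]);
    } else {
      pos = v3(src_pos[0] + unif_rand() * src_extent[0],
               src_pos[1] + unif_rand() * src_extent[1], src_pos[2]);
    }
    Vec3 dir = u0;
    Stokes s = s0;
    double w = 1.0;
    pos = pos + NUDGE * dir;   // nudge inside the first voxel

    bool alive = true;
    double detected_here = 0.0;
    while (alive) {
      double tau = -std::log(unif_rand());
      int med = -1;
      double path = 0.0;
      EventType ev = trace_to_event(d, pos, dir, tau, w, med, agrid,
                                    absorbed, path);
      switch (ev) {
        case EV_SCATTER: {
          const double *t11 = &s11m(0, med), *t12 = &s12m(0, med);
          const double *t33 = &s33m(0, med), *t34 = &s34m(0, med);
          PhaseSampler ps{t11, t12, &cdfm(0, med), REAL(edge_mu), ng,
                          envelope[med]};
          double mu, st, phi;
          int idx = ps.sample(s.I, s.Q, s.U, mu, st, phi, n_trials,
                              rejection_guard);
          ++n_scatter;
          scatter_apply(dir, s, mu, st, phi, t11[idx], t12[idx], t33[idx],
                        t34[idx]);
          if (w < w_threshold) {   // Russian roulette
            if (unif_rand() < p_survive) {
              boosted += w / p_survive - w;
              w /= p_survive;
            } else {
              killed += w;
              alive = false;
            }
          }
          break;
        }
        case EV_DETECT: {
          Vec3 epar, eperp, dpar, dperp;
          meridian_frame(dir, epar, eperp);
          detector_frame(dir, dpar, dperp);
          double c, sn;
          frame_angle(dir, epar, dpar, c, sn);
          Stokes sd = s;
          rotate_ref(sd, c, sn);
          totI += w * sd.I; totQ += w * sd.Q;
          totU += w * sd.U; totV += w * sd.V;
          detected_here = w * sd.I;
          sum_q2 += w * w * sd.Q * sd.Q;
          sum_u2 += w * w * sd.U * sd.U;
          sum_v2 += w * w * sd.V * sd.V;
          int ix = (int)std::floor((pos.x - det_origin[0]) / pitch_x);
          int iy = (int)std::floor((pos.y - det_origin[1]) / pitch_y);
          if (ix >= 0 && ix < px && iy >= 0 && iy < py) {
            size_t pix = (size_t)ix + (size_t)px * iy;
            imI[pix] += w * sd.I; imQ[pix] += w * sd.Q;
            imU[pix] += w * sd.U; imV[pix] += w * sd.V;
          } else {
            offI += w * sd.I;
          }
          alive = false;
          break;
        }
        case EV_TRANSMIT: transmitted += w; alive = false; break;
        case EV_SIDE:     side_escaped += w; alive = false; break;
        case EV_AMBIENT:  ambient_escaped += w; alive = false; break;
        case EV_STUCK:    stuck_weight += w; alive = false; break;
      }
    }
    sum_d += detected_here;
    sum_d2 += detected_here * detected_here;
  }

  NumericMatrix I(px, py), Q(px, py), U(px, py), V(px, py);
  std::copy(imI.begin(), imI.end(), I.begin());
  std::copy(imQ.begin(), imQ.end(), Q.begin());
  std::copy(imU.begin(), imU.end(), U.begin());
  std::copy(imV.begin(), imV.end(), V.begin());

  List out = List::create(
      _["images"] = List::create(_["I"] = I, _["Q"] = Q, _["U"] = U,
                                 _["V"] = V),
      _["totals"] = NumericVector::create(_["I"] = totI, _["Q"] = totQ,
                                          _["U"] = totU, _["V"] = totV),
      _["off_detector_I"] = offI,
      _["sum_detected"] = sum_d,
      _["sum_detected_sq"] = sum_d2,
      _["sum_sq_QUV"] = NumericVector::create(sum_q2, sum_u2, sum_v2),
      _["transmitted"] = transmitted,
      _["side_escaped"] = side_escaped,
      _["ambient_escaped"] = ambient_escaped,
      _["absorbed"] = absorbed,
      _["roulette_killed"] = killed,
      _["roulette_boosted"] = boosted,
      _["stuck_weight"] = stuck_weight,
      _["n_scatter"] = (double)n_scatter,
      _["n_rejection_trials"] = (double)n_trials,
      _["n_photons"] = (double)N);
  if (save_absorption) {
    NumericVector av(absorb_grid.begin(), absorb_grid.end());
    av.attr("dim") = IntegerVector::create(d.nx, d.ny, d.nz);
    out["absorption"] = av;
  }
  return out;
}
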