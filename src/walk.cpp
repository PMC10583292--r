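#include <Rcpp.h>
using namespace Rcpp;

// Random-walk spin ensemble under a sampled gradient waveform.
// Geometries: 0 free, 1 planar (|z| <= R), 2 cylinder (x^2+y^2 <= R^2,
// infinite z), 3 sphere.  Specular reflection with sub-step backtracking;
// phase accrued by trapezoidal integration of -gamma * g.r.
// Uses the R RNG so results follow set.seed().

static inline double dot3(const double *a, const double *b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// reflect a step r -> r + d inside a sphere (dim = 3) or disk in x,y
// (dim = 2) of radius R; modifies r in place
static void reflect_radial(double *r, double *d, double R, int dim) {
  for (int iter = 0; iter < 64; ++iter) {
    double rn[3] = {r[0] + d[0], r[1] + d[1], r[2] + d[2]};
    double rr = 0.0;
    for (int k = 0; k < dim; ++k) rr += rn[k] * rn[k];
    if (rr <= R * R) {
      r[0] = rn[0]; r[1] = rn[1]; r[2] = rn[2];
      return;
    }
    // solve |r + s d| = R for s in (0, 1] within the restricted dims
    double a = 0.0, bq = 0.0, c = -R * R;
    for (int k = 0; k < dim; ++k) {
      a += d[k] * d[k];
      bq += r[k] * d[k];
      c += r[k] * r[k];
    }
    double disc = bq * bq - a * c;
    if (disc < 0.0 || a == 0.0) break;  // numerical corner: give up, clamp
    double s = (-bq + std::sqrt(disc)) / a;
    if (s < 0.0) s = 0.0;
    if (s > 1.0) s = 1.0;
    double contact[3] = {r[0] + s * d[0], r[1] + s * d[1], r[2] + s * d[2]};
    // outward normal at contact (restricted dims only)
    double nrm[3] = {0.0, 0.0, 0.0};
    double nn = 0.0;
    for (int k = 0; k < dim; ++k) { nrm[k] = contact[k]; nn += nrm[k] * nrm[k]; }
    nn = std::sqrt(nn);
    if (nn == 0.0) break;
    for (int k = 0; k < dim; ++k) nrm[k] /= nn;
    double rem[3] = {(1.0 - s) * d[0], (1.0 - s) * d[1], (1.0 - s) * d[2]};
    double rn_dot = 0.0;
    for (int k = 0; k < dim; ++k) rn_dot += rem[k] * nrm[k];
    for (int k = 0; k < dim; ++k) rem[k] -= 2.0 * rn_dot * nrm[k];
    r[0] = contact[0]; r[1] = contact[1]; r[2] = contact[2];
    d[0] = rem[0]; d[1] = rem[1]; d[2] = rem[2];
    double dl = std::sqrt(dot3(d, d));
    if (dl < 1e-18) return;
  }
  // fallback: clamp onto the boundary radially
  double rr = 0.0;
  for (int k = 0; k < dim; ++k) rr += r[k] * r[k];
  rr = std::sqrt(rr);
  if (rr > R && rr > 0.0) {
    double f = R / rr * (1.0 - 1e-12);
    for (int k = 0; k < dim; ++k) r[k] *= f;
  }
}

// fold z into [-R, R] (specular reflection between parallel plates)
static inline double fold_plates(double z, double R) {
  double L = 4.0 * R;  // period of the unfolded coordinate
  double y = z + R;
  y -= L * std::floor(y / L);
  double out = (y <= 2.0 * R) ? (y - R) : (3.0 * R - y);
  return out;
}

// [[Rcpp::export]]
List walk_engine(NumericMatrix g, double dt, double gamma_, int geometry,
                 double radius, double D0, NumericVector vdrift,
                 int n_spins, int n_store_spins, int store_every) {
  const int nt = g.nrow();
  const double step_sd = std::sqrt(2.0 * D0 * dt);
  NumericVector phase(n_spins);
  NumericMatrix pos0(n_spins, 3), pos(n_spins, 3);
  const int n_store_t = (n_store_spins > 0) ?
      (nt + store_every - 1) / store_every : 0;
  NumericVector traj(n_store_spins > 0 ?
      (R_xlen_t)n_store_spins * n_store_t * 3 : 0);

  RNGScope scope;
  for (int s = 0; s < n_spins; ++s) {
    double r[3] = {0.0, 0.0, 0.0};
    // uniform initial positions inside the compartment
    if (geometry == 1) {
      r[2] = (2.0 * unif_rand() - 1.0) * radius;
    } else if (geometry == 2 || geometry == 3) {
      int dim = (geometry == 2) ? 2 : 3;
      for (;;) {
        double rr = 0.0;
        for (int k = 0; k < dim; ++k) {
          r[k] = (2.0 * unif_rand() - 1.0) * radius;
          rr += r[k] * r[k];
        }
        if (rr <= radius * radius) break;
      }
    }
    pos0(s, 0) = r[0]; pos0(s, 1) = r[1]; pos0(s, 2) = r[2];
    double acc = 0.5 * (g(0, 0) * r[0] + g(0, 1) * r[1] + g(0, 2) * r[2]);
    for (int j = 1; j < nt; ++j) {
      double d[3];
      for (int k = 0; k < 3; ++k)
        d[k] = step_sd * norm_rand() + vdrift[k] * dt;
      if (geometry == 0) {
        r[0] += d[0]; r[1] += d[1]; r[2] += d[2];
      } else if (geometry == 1) {
        r[0] += d[0]; r[1] += d[1];
        r[2] = fold_plates(r[2] + d[2], radius);
      } else {
        reflect_radial(r, d, radius, geometry == 2 ? 2 : 3);
      }
      double w = (j == nt - 1) ? 0.5 : 1.0;
      acc += w * (g(j, 0) * r[0] + g(j, 1) * r[1] + g(j, 2) * r[2]);
      if (s < n_store_spins && (j % store_every) == 0) {
        int jt = j / store_every;
        for (int k = 0; k < 3; ++k)
          traj[(R_xlen_t)k * n_store_spins * n_store_t +
               (R_xlen_t)jt * n_store_spins + s] = r[k];
      }
    }
    phase[s] = -gamma_ * acc * dt;
    pos(s, 0) = r[0]; pos(s, 1) = r[1]; pos(s, 2) = r[2];
  }
  List out = List::create(_["phase"] = phase, _["pos0"] = pos0,
                          _["pos"] = pos);
  if (n_store_spins > 0) {
    traj.attr("dim") = IntegerVector::create(n_store_spins, n_store_t, 3);
    out["traj"] = traj;
  }
  return out;
}
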