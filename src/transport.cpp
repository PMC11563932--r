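// Photon-packet Monte Carlo transport on a voxelized material grid.
//
// Conventions: positions in mm, grid corner at the origin, voxel (i,j,k)
// occupies [i*h,(i+1)*h) x ... ; labels index rows of the material matrix.
// Fluence is scored with the track-length estimator (sum of weight x path
// length per voxel, in photon-weight * mm); absorption is handled by weight
// attenuation with the single-scattering albedo at each collision.
//
// Every packet owns an independent counter-based RNG substream derived from
// (seed, packet index), so results do not depend on execution order.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

namespace {

const double TWO_PI = 6.283185307179586476925;

inline uint64_t mix64(uint64_t z) {
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// splitmix64 stream; state seeded per packet.
struct RngStream {
  uint64_t s;
  RngStream(uint64_t seed, uint64_t id) {
    s = mix64(seed * 0x9E3779B97F4A7C15ULL + 0xD1B54A32D192ED03ULL * (id + 1));
    s = mix64(s + 0x9E3779B97F4A7C15ULL);
  }
  inline uint64_t next64() {
    s += 0x9E3779B97F4A7C15ULL;
    return mix64(s);
  }
  // uniform on (0, 1]
  inline double unif() {
    return ((next64() >> 11) + 1) * (1.0 / 9007199254740992.0);
  }
};

struct Mat {
  double mua, mus, g, n;
  bool reduced;
  double mut, albedo;
};

inline void unit3(double* v) {
  double s = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
  v[0] /= s; v[1] /= s; v[2] /= s;
}

// orthonormal basis perpendicular to unit vector d
inline void perp_basis(const double* d, double* u, double* v) {
  if (std::fabs(d[0]) < 0.9) { u[0] = 0; u[1] = -d[2]; u[2] = d[1]; }
  else                       { u[0] = -d[2]; u[1] = 0; u[2] = d[0]; }
  unit3(u);
  v[0] = d[1] * u[2] - d[2] * u[1];
  v[1] = d[2] * u[0] - d[0] * u[2];
  v[2] = d[0] * u[1] - d[1] * u[0];
}

inline double hg_cos(double g, double u) {
  if (std::fabs(g) < 1e-9) return 2.0 * u - 1.0;
  double t = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - t * t) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

// rotate direction by Henyey-Greenstein deflection, uniform azimuth (in place)
inline void hg_spin(double* dir, double g, RngStream& rng) {
  if (g >= 1.0 - 1e-12) return;  // forward limit: pass-through
  double ct = hg_cos(g, rng.unif());
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double phi = TWO_PI * rng.unif();
  double u[3], v[3];
  perp_basis(dir, u, v);
  double cp = std::cos(phi), sp = std::sin(phi);
  for (int a = 0; a < 3; ++a)
    dir[a] = ct * dir[a] + st * (cp * u[a] + sp * v[a]);
  unit3(dir);
}

struct Source {
  int type;  // 0 = isotropic point, 1 = Lambertian disc
  double center[3], normal[3], radius, power;
};

inline void launch_from(const Source& src, RngStream& rng,
                        double* pos, double* dir) {
  if (src.type == 0) {
    pos[0] = src.center[0]; pos[1] = src.center[1]; pos[2] = src.center[2];
    double ct = 2.0 * rng.unif() - 1.0;
    double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
    double phi = TWO_PI * rng.unif();
    dir[0] = st * std::cos(phi); dir[1] = st * std::sin(phi); dir[2] = ct;
  } else {
    double u[3], v[3];
    perp_basis(src.normal, u, v);
    double r = src.radius * std::sqrt(rng.unif());
    double phi = TWO_PI * rng.unif();
    double cp = std::cos(phi), sp = std::sin(phi);
    for (int a = 0; a < 3; ++a)
      pos[a] = src.center[a] + r * (cp * u[a] + sp * v[a]);
    // Lambertian (cosine-weighted) emission about the inward normal
    double ct = std::sqrt(rng.unif());
    double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
    double phi2 = TWO_PI * rng.unif();
    double c2 = std::cos(phi2), s2 = std::sin(phi2);
    for (int a = 0; a < 3; ++a)
      dir[a] = ct * src.normal[a] + st * (c2 * u[a] + s2 * v[a]);
    unit3(dir);
  }
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".mc_simulate_cpp")]]
List mc_simulate_cpp(IntegerVector labels, IntegerVector dim, double voxel_mm,
                     NumericMatrix materials, List sources, double n_packets,
                     double seed, double roulette_threshold,
                     double roulette_survival, bool fresnel, int max_steps) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double h = voxel_mm;
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  if (labels.size() != nvox) stop("label grid size does not match dim");
  const int nmat = materials.nrow();

  std::vector<Mat> mats(nmat);
  for (int m = 0; m < nmat; ++m) {
    Mat& M = mats[m];
    M.mua = materials(m, 0); M.mus = materials(m, 1);
    M.g = materials(m, 2);   M.n = materials(m, 3);
    M.reduced = materials(m, 4) != 0.0;
    M.mut = M.mua + M.mus;
    M.albedo = (M.mut > 0.0) ? M.mus / M.mut : 0.0;
  }

  const int nsrc = sources.size();
  std::vector<Source> srcs(nsrc);
  double total_power = 0.0;
  for (int k = 0; k < nsrc; ++k) {
    List s = sources[k];
    Source& S = srcs[k];
    S.type = as<int>(s["type"]);
    NumericVector c0 = s["center"], nv = s["normal"];
    for (int a = 0; a < 3; ++a) { S.center[a] = c0[a]; S.normal[a] = nv[a]; }
    S.radius = as<double>(s["radius"]);
    S.power = as<double>(s["power"]);
    total_power += S.power;
  }
  if (total_power <= 0) stop("total source power must be positive");

  // packet allocation proportional to power, largest-remainder rounding
  const uint64_t N = (uint64_t)n_packets;
  std::vector<uint64_t> alloc(nsrc, 0);
  {
    std::vector<double> frac(nsrc);
    uint64_t used = 0;
    for (int k = 0; k < nsrc; ++k) {
      double exact = n_packets * srcs[k].power / total_power;
      alloc[k] = (uint64_t)std::floor(exact);
      frac[k] = exact - std::floor(exact);
      used += alloc[k];
    }
    while (used < N) {
      int best = 0;
      for (int k = 1; k < nsrc; ++k) if (frac[k] > frac[best]) best = k;
      alloc[best] += 1; frac[best] = -1.0; ++used;
    }
  }
  std::vector<uint64_t> cum(nsrc + 1, 0);
  for (int k = 0; k < nsrc; ++k) cum[k + 1] = cum[k] + alloc[k];

  NumericVector fluence(nvox);  // photon-weight * mm per voxel
  double launched = 0.0, absorbed = 0.0, escaped = 0.0;
  double roulette_net = 0.0, maxstep_weight = 0.0;
  const double inv_surv = 1.0 / roulette_survival;
  const long seg_cap = 64L * (long)max_steps + 1000000L;
  const uint64_t seed_u = (uint64_t)(int64_t)seed;

  int ksrc = 0;
  for (uint64_t i = 0; i < N; ++i) {
    if ((i & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    while (i >= cum[ksrc + 1]) ++ksrc;
    RngStream rng(seed_u, i);

    double pos[3], dir[3], w = 1.0;
    launch_from(srcs[ksrc], rng, pos, dir);
    launched += 1.0;

    int v[3];
    bool inside = true;
    for (int a = 0; a < 3; ++a) {
      v[a] = (int)std::floor(pos[a] / h);
      if (v[a] < 0 || v[a] >= dim[a]) inside = false;
    }
    if (!inside) { escaped += w; continue; }

    double tau = -std::log(rng.unif());
    long collisions = 0, segments = 0;
    bool alive = true;

    while (alive) {
      if (!(std::isfinite(pos[0]) && std::isfinite(pos[1]) &&
            std::isfinite(pos[2])))
        stop("non-finite packet position (internal transport bug)");
      R_xlen_t idx = (R_xlen_t)v[0] + (R_xlen_t)nx * (v[1] + (R_xlen_t)ny * v[2]);
      int lab = labels[idx] - 1;
      if (lab < 0 || lab >= nmat) stop("voxel label outside material table");
      const Mat& M = mats[lab];

      // distance to nearest voxel face along dir
      int ax = 0, stp = 0;
      double db = R_PosInf;
      for (int a = 0; a < 3; ++a) {
        double t;
        int s;
        if (dir[a] > 1e-12)      { t = ((v[a] + 1) * h - pos[a]) / dir[a]; s = 1; }
        else if (dir[a] < -1e-12){ t = (v[a] * h - pos[a]) / dir[a];       s = -1; }
        else continue;
        if (t < db) { db = t; ax = a; stp = s; }
      }
      if (db < 0) db = 0;

      bool cross;
      if (M.mut <= 0.0) {
        cross = true;  // non-interacting medium: free flight to the face
      } else if (M.mut * db < tau) {
        tau -= M.mut * db;
        cross = true;
      } else {
        cross = false;
      }

      if (cross) {
        fluence[idx] += w * db;
        for (int a = 0; a < 3; ++a) pos[a] += dir[a] * db;
        // snap onto the face to avoid drift
        pos[ax] = (stp > 0 ? (v[ax] + 1) : v[ax]) * h;
        int vnext = v[ax] + stp;
        if (vnext < 0 || vnext >= dim[ax]) { escaped += w; break; }
        if (fresnel) {
          R_xlen_t jdx;
          int vv[3] = { v[0], v[1], v[2] };
          vv[ax] = vnext;
          jdx = (R_xlen_t)vv[0] + (R_xlen_t)nx * (vv[1] + (R_xlen_t)ny * vv[2]);
          int lab2 = labels[jdx] - 1;
          double n1 = M.n, n2 = mats[lab2].n;
          if (n1 != n2) {
            double ci = std::fabs(dir[ax]);
            double eta = n1 / n2;
            double st2 = eta * eta * (1.0 - ci * ci);
            if (st2 >= 1.0) {  // total internal reflection
              dir[ax] = -dir[ax];
              continue;
            }
            double ct = std::sqrt(1.0 - st2);
            double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
            double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
            double R = 0.5 * (rs * rs + rp * rp);
            if (rng.unif() < R) {
              dir[ax] = -dir[ax];
              continue;
            }
            // refract across the axis-aligned face
            double sgn = dir[ax] > 0 ? 1.0 : -1.0;
            for (int a = 0; a < 3; ++a)
              if (a != ax) dir[a] *= eta;
            dir[ax] = sgn * ct;
            unit3(dir);
          }
        }
        v[ax] = vnext;
        if (++segments > seg_cap) { maxstep_weight += w; roulette_net += w; break; }
        continue;
      }

      // collision inside this voxel
      double d = tau / M.mut;
      fluence[idx] += w * d;
      for (int a = 0; a < 3; ++a) pos[a] += dir[a] * d;
      absorbed += w * (M.mua / M.mut);
      w *= M.albedo;
      if (w <= 0.0) break;  // pure absorber
      hg_spin(dir, M.reduced ? 0.0 : M.g, rng);
      if (++collisions >= max_steps) {
        maxstep_weight += w; roulette_net += w; break;
      }
      if (w < roulette_threshold) {
        if (rng.unif() < inv_surv) {
          roulette_net -= w * (roulette_survival - 1.0);
          w *= roulette_survival;
        } else {
          roulette_net += w;
          break;
        }
      }
      tau = -std::log(rng.unif());
    }
  }

  List ledger = List::create(
      _["launched"] = launched, _["absorbed"] = absorbed,
      _["escaped"] = escaped, _["rouletted"] = roulette_net,
      _["max_step_weight"] = maxstep_weight);
  IntegerVector alloc_out(nsrc);
  for (int k = 0; k < nsrc; ++k) alloc_out[k] = (int)alloc[k];
  return List::create(_["fluence"] = fluence, _["ledger"] = ledger,
                      _["packets_per_source"] = alloc_out);
}

//' @noRd
// [[Rcpp::export(name = ".hg_sample_cpp")]]
NumericMatrix hg_sample_cpp(double g, NumericVector incoming, int n,
                            double seed) {
  double d0[3] = { incoming[0], incoming[1], incoming[2] };
  unit3(d0);
  NumericMatrix out(n, 3);
  const uint64_t seed_u = (uint64_t)(int64_t)seed;
  for (int i = 0; i < n; ++i) {
    RngStream rng(seed_u, (uint64_t)i);
    double d[3] = { d0[0], d0[1], d0[2] };
    hg_spin(d, g, rng);
    out(i, 0) = d[0]; out(i, 1) = d[1]; out(i, 2) = d[2];
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".launch_sample_cpp")]]
List launch_sample_cpp(List source, int n, double seed) {
  Source S;
  S.type = as<int>(source["type"]);
  NumericVector c0 = source["center"], nv = source["normal"];
  for (int a = 0; a < 3; ++a) { S.center[a] = c0[a]; S.normal[a] = nv[a]; }
  S.radius = as<double>(source["radius"]);
  S.power = as<double>(source["power"]);
  NumericMatrix pos(n, 3), dir(n, 3);
  const uint64_t seed_u = (uint64_t)(int64_t)seed;
  for (int i = 0; i < n; ++i) {
    RngStream rng(seed_u, (uint64_t)i);
    double p[3], d[3];
    launch_from(S, rng, p, d);
    for (int a = 0; a < 3; ++a) { pos(i, a) = p[a]; dir(i, a) = d[a]; }
  }
  return List::create(_["position"] = pos, _["direction"] = dir,
                      _["weight"] = NumericVector(n, 1.0));
}
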