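// Mesh-based Monte Carlo photon transport kernel.
//
// Weighted photon packets are traced through a conforming tetrahedral mesh
// by straight-segment ray/face traversal.  At each interaction a fraction
// mu_a/mu_t of the packet weight is deposited onto the four nodes of the
// containing element (barycentric shares) into the time gate given by the
// elapsed optical time of flight.  Scattering uses the Henyey-Greenstein
// phase function; the external boundary applies unpolarized Fresnel
// reflection against air (n = 1); low-weight packets undergo Russian
// roulette.  Single-threaded and fully deterministic for a fixed seed.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

const double C_MM_PS = 0.299792458;

// --- xoshiro256++ (seeded via splitmix64) ------------------------------
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in [0, 1)
  double runif() { return (next() >> 11) * 0x1.0p-53; }
  // uniform in (0, 1]   (safe for log)
  double runif_pos() { return ((next() >> 11) + 1) * 0x1.0p-53; }
};

struct Vec3 { double x, y, z; };

inline Vec3 operator+(Vec3 a, Vec3 b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
inline Vec3 operator-(Vec3 a, Vec3 b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline Vec3 operator*(double s, Vec3 a) { return {s * a.x, s * a.y, s * a.z}; }
inline double dot(Vec3 a, Vec3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline Vec3 cross(Vec3 a, Vec3 b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}

inline double hg_cos(double g, double xi) {
  if (g == 0.0) return 2.0 * xi - 1.0;
  double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * xi);
  double c = (1.0 + g * g - tmp * tmp) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

// per-element precomputed geometry
struct ElemGeom {
  int v[4];          // 0-based node indices
  double Minv[9];    // inverse of [v2-v1 | v3-v1 | v4-v1]
  Vec3 fn[4];        // unit outward normal of face opposite local vertex f
  double fd[4];      // plane offset: dot(fn, x) = fd on the face
  Vec3 p0;           // coordinates of vertex v[0] (barycentric origin)
};

}  // namespace

// [[Rcpp::export]]
List mmc_transport_cpp(NumericMatrix nodes, IntegerMatrix elems,
                       IntegerMatrix neighbors, NumericVector src_pos,
                       NumericVector src_dir, int start_elem, double mu_a,
                       double mu_s, double g, double n_refr,
                       double n_photons, double gate_width, int n_gates,
                       double t0, double seed, double rr_threshold,
                       double rr_survive) {
  const int n_nodes = nodes.nrow();
  const int m = elems.nrow();
  const double mu_t = mu_a + mu_s;
  if (mu_t <= 0) stop("mu_a + mu_s must be > 0");
  const double inv_mu_t = 1.0 / mu_t;
  const double albedo = mu_s * inv_mu_t;
  const double absorb_frac = mu_a * inv_mu_t;
  const double t_end = t0 + gate_width * n_gates;
  const double time_per_mm = n_refr / C_MM_PS;

  // --- precompute element geometry -------------------------------------
  std::vector<ElemGeom> geo(m);
  // local faces: face f is opposite local vertex f
  const int face_v[4][3] = {{1, 2, 3}, {0, 2, 3}, {0, 1, 3}, {0, 1, 2}};
  for (int e = 0; e < m; ++e) {
    ElemGeom &G = geo[e];
    for (int k = 0; k < 4; ++k) G.v[k] = elems(e, k) - 1;
    Vec3 p[4];
    for (int k = 0; k < 4; ++k)
      p[k] = {nodes(G.v[k], 0), nodes(G.v[k], 1), nodes(G.v[k], 2)};
    Vec3 a = p[1] - p[0], b = p[2] - p[0], c = p[3] - p[0];
    double det = a.x * (b.y * c.z - b.z * c.y) -
                 b.x * (a.y * c.z - a.z * c.y) +
                 c.x * (a.y * b.z - a.z * b.y);
    if (det == 0) stop("degenerate element %d", e + 1);
    double id = 1.0 / det;
    // inverse of column matrix [a b c]
    G.Minv[0] = (b.y * c.z - b.z * c.y) * id;
    G.Minv[1] = (b.z * c.x - b.x * c.z) * id;
    G.Minv[2] = (b.x * c.y - b.y * c.x) * id;
    G.Minv[3] = (a.z * c.y - a.y * c.z) * id;
    G.Minv[4] = (a.x * c.z - a.z * c.x) * id;
    G.Minv[5] = (a.y * c.x - a.x * c.y) * id;
    G.Minv[6] = (a.y * b.z - a.z * b.y) * id;
    G.Minv[7] = (a.z * b.x - a.x * b.z) * id;
    G.Minv[8] = (a.x * b.y - a.y * b.x) * id;
    for (int f = 0; f < 4; ++f) {
      Vec3 q0 = p[face_v[f][0]], q1 = p[face_v[f][1]], q2 = p[face_v[f][2]];
      Vec3 n = cross(q1 - q0, q2 - q0);
      double nn = std::sqrt(dot(n, n));
      if (nn == 0) stop("degenerate face in element %d", e + 1);
      n = (1.0 / nn) * n;
      // orient away from the opposite vertex
      if (dot(n, p[f] - q0) > 0) n = -1.0 * n;
      G.fn[f] = n;
      G.fd[f] = dot(n, q0);
    }
    G.p0 = p[0];
  }
  // flat copy of the neighbor table (0 = boundary) for the hot loop
  std::vector<int> nb_flat(static_cast<size_t>(m) * 4, 0);
  for (int e = 0; e < m; ++e)
    for (int f = 0; f < 4; ++f) {
      int nb = neighbors(e, f);
      nb_flat[static_cast<size_t>(e) * 4 + f] =
          (nb == NA_INTEGER || nb <= 0) ? 0 : nb;
    }
  // local face index of the shared face as seen from the neighbor
  std::vector<int> nb_face(static_cast<size_t>(m) * 4, -1);
  for (int e = 0; e < m; ++e) {
    for (int f = 0; f < 4; ++f) {
      int nb = neighbors(e, f);
      if (nb == NA_INTEGER || nb <= 0) continue;
      int ne = nb - 1;
      // the neighbor's local face = local index of its vertex not on the face
      for (int k = 0; k < 4; ++k) {
        int vk = geo[ne].v[k];
        bool on_face = false;
        for (int j = 0; j < 3; ++j)
          if (geo[e].v[face_v[f][j]] == vk) { on_face = true; break; }
        if (!on_face) { nb_face[static_cast<size_t>(e) * 4 + f] = k; break; }
      }
    }
  }

  NumericMatrix deposit(n_nodes, n_gates);
  double *dep = REAL(deposit);
  double w_exited = 0, w_killed = 0, w_expired = 0, w_lost = 0,
         w_deposited = 0, w_boosted = 0;
  long long n_interactions = 0, n_crossings = 0;

  Xoshiro rng(static_cast<uint64_t>(seed));
  const long long N = static_cast<long long>(n_photons);
  const Vec3 launch_pos = {src_pos[0], src_pos[1], src_pos[2]};
  const Vec3 launch_dir = {src_dir[0], src_dir[1], src_dir[2]};
  const int el0 = start_elem - 1;
  if (el0 < 0 || el0 >= m) stop("start element out of range");

  const double inv_gate_width = 1.0 / gate_width;

  for (long long ph = 0; ph < N; ++ph) {
    Vec3 pos = launch_pos, dir = launch_dir;
    double w = 1.0, t = 0.0;
    int el = el0, entry_face = -1, zero_steps = 0;
    double rem = -std::log(rng.runif_pos()) * inv_mu_t;
    const ElemGeom *G = &geo[el];

    // signed face state for the current element: ndir = n_f . dir,
    // fdist = fd_f - n_f . pos (>= 0 inside); fdist is updated
    // incrementally as the packet advances, ndir on direction changes.
    double ndir[4], fdist[4];
    for (int f = 0; f < 4; ++f) {
      ndir[f] = dot(G->fn[f], dir);
      fdist[f] = G->fd[f] - dot(G->fn[f], pos);
    }

    for (;;) {
      // fast test: does the sampled step stay inside the element?
      bool crossing = false;
      for (int f = 0; f < 4; ++f)
        if (f != entry_face && ndir[f] > 1e-12 && rem * ndir[f] > fdist[f]) {
          crossing = true;
          break;
        }

      if (!crossing) {
        // interaction inside the element
        ++n_interactions;
        pos = pos + rem * dir;
        for (int f = 0; f < 4; ++f) fdist[f] -= rem * ndir[f];
        t += rem * time_per_mm;
        zero_steps = 0;
        if (t >= t_end) { w_expired += w; break; }
        double dw = w * absorb_frac;
        if (t >= t0) {
          int gate = static_cast<int>((t - t0) * inv_gate_width);
          // barycentric shares of the interaction point
          Vec3 r = pos - G->p0;
          double b1 = G->Minv[0] * r.x + G->Minv[1] * r.y + G->Minv[2] * r.z;
          double b2 = G->Minv[3] * r.x + G->Minv[4] * r.y + G->Minv[5] * r.z;
          double b3 = G->Minv[6] * r.x + G->Minv[7] * r.y + G->Minv[8] * r.z;
          double b0 = 1.0 - b1 - b2 - b3;
          if (b0 < 0) b0 = 0; if (b1 < 0) b1 = 0;
          if (b2 < 0) b2 = 0; if (b3 < 0) b3 = 0;
          double bs = b0 + b1 + b2 + b3;
          if (bs <= 0) { b0 = b1 = b2 = b3 = 0.25; bs = 1.0; }
          double sc = dw / bs;
          double *col = dep + static_cast<size_t>(gate) * n_nodes;
          col[G->v[0]] += sc * b0;
          col[G->v[1]] += sc * b1;
          col[G->v[2]] += sc * b2;
          col[G->v[3]] += sc * b3;
          w_deposited += dw;
        } else {
          w_expired += dw;  // absorbed before the gated window opens
        }
        w *= albedo;
        if (w < rr_threshold) {
          if (rng.runif() < rr_survive) {
            w_boosted += w * (1.0 / rr_survive - 1.0);
            w /= rr_survive;
          } else {
            w_killed += w;
            break;
          }
        }
        // scatter: Henyey-Greenstein polar angle, uniform azimuth
        double ct = hg_cos(g, rng.runif());
        double st = std::sqrt(1.0 - ct * ct);
        double phi = 6.283185307179586476925286766559 * rng.runif();
        double cp = std::cos(phi), sp = std::sin(phi);
        if (std::fabs(dir.z) > 0.99999) {
          dir = {st * cp, st * sp, ct * (dir.z >= 0 ? 1.0 : -1.0)};
        } else {
          double den = std::sqrt(1.0 - dir.z * dir.z);
          Vec3 nd = {st * (dir.x * dir.z * cp - dir.y * sp) / den + dir.x * ct,
                     st * (dir.y * dir.z * cp + dir.x * sp) / den + dir.y * ct,
                     -st * cp * den + dir.z * ct};
          double nn = 1.0 / std::sqrt(dot(nd, nd));
          dir = nn * nd;
        }
        for (int f = 0; f < 4; ++f) ndir[f] = dot(G->fn[f], dir);
        entry_face = -1;
        rem = -std::log(rng.runif_pos()) * inv_mu_t;
      } else {
        // exact exit distance (divisions only on this slower path)
        double tmin = std::numeric_limits<double>::infinity();
        int fexit = -1;
        for (int f = 0; f < 4; ++f) {
          if (f == entry_face || ndir[f] <= 1e-12) continue;
          double tf = fdist[f] / ndir[f];
          if (tf < 0) tf = 0;
          if (tf < tmin) { tmin = tf; fexit = f; }
        }
        if (fexit < 0) {  // inconsistent geometry (should not happen)
          w_lost += w;
          break;
        }
        ++n_crossings;
        pos = pos + tmin * dir;
        rem -= tmin;
        t += tmin * time_per_mm;
        if (t >= t_end) { w_expired += w; break; }
        if (tmin < 1e-12) {
          if (++zero_steps > 256) { w_lost += w; break; }
        } else zero_steps = 0;
        int nb = nb_flat[static_cast<size_t>(el) * 4 + fexit];
        if (nb > 0) {
          entry_face = nb_face[static_cast<size_t>(el) * 4 + fexit];
          el = nb - 1;
          G = &geo[el];
          for (int f = 0; f < 4; ++f) {
            ndir[f] = dot(G->fn[f], dir);
            fdist[f] = G->fd[f] - dot(G->fn[f], pos);
          }
        } else {
          // external boundary: unpolarized Fresnel vs air (n = 1)
          Vec3 nrm = G->fn[fexit];
          double ci = dot(dir, nrm);
          if (ci < 0) ci = 0; if (ci > 1) ci = 1;
          double R;
          if (n_refr == 1.0) {
            R = 0.0;
          } else {
            double si = std::sqrt(1.0 - ci * ci);
            double stt = n_refr * si;  // n2 = 1
            if (stt >= 1.0) {
              R = 1.0;
            } else {
              double ctt = std::sqrt(1.0 - stt * stt);
              double rs = (n_refr * ci - ctt) / (n_refr * ci + ctt);
              double rp = (n_refr * ctt - ci) / (n_refr * ctt + ci);
              R = 0.5 * (rs * rs + rp * rp);
            }
          }
          if (rng.runif() < R) {
            dir = dir - (2.0 * ci) * nrm;
            for (int f = 0; f < 4; ++f) ndir[f] = dot(G->fn[f], dir);
            entry_face = -1;  // normal now opposes dir
          } else {
            w_exited += w;
            break;
          }
        }
      }
    }
    if ((ph & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["deposit"] = deposit, _["deposited"] = w_deposited,
      _["exited"] = w_exited, _["killed"] = w_killed,
      _["expired"] = w_expired, _["lost"] = w_lost,
      _["boosted"] = w_boosted, _["launched"] = static_cast<double>(N),
      _["n_interactions"] = static_cast<double>(n_interactions),
      _["n_crossings"] = static_cast<double>(n_crossings));
}

// Henyey-Greenstein inverse-CDF sampling of the scattering cosine for given
// uniform variates; used by the R-level sampler so tests exercise the same
// formula as the transport kernel.
// [[Rcpp::export]]
NumericVector hg_cosine_cpp(double g, NumericVector xi) {
  NumericVector out(xi.size());
  for (R_xlen_t i = 0; i < xi.size(); ++i) out[i] = hg_cos(g, xi[i]);
  return out;
}
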