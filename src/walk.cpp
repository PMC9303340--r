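// Random-walk engine: segment-triangle intersection, point containment,
// uniform seeding, fixed-step-length walks with specular reflection, and
// on-the-fly accumulation of PGSE lobe position sums.
//
// All randomness is drawn from R's RNG (unif_rand / norm_rand) so that
// set.seed() on the R side gives byte-identical results.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

struct Vec3 {
  double x, y, z;
};

static inline Vec3 v3(double x, double y, double z) { Vec3 v; v.x = x; v.y = y; v.z = z; return v; }
static inline Vec3 sub(const Vec3 &a, const Vec3 &b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline Vec3 add(const Vec3 &a, const Vec3 &b) { return v3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline Vec3 scl(const Vec3 &a, double s) { return v3(a.x * s, a.y * s, a.z * s); }
static inline double dot(const Vec3 &a, const Vec3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double norm3(const Vec3 &a) { return std::sqrt(dot(a, a)); }

struct Tri {
  Vec3 v0, e1, e2; // v0 + barycentric edges
  Vec3 n;          // unit normal
};

static std::vector<Tri> build_tris(const NumericMatrix &verts, const IntegerMatrix &faces) {
  std::vector<Tri> tris(faces.nrow());
  for (int f = 0; f < faces.nrow(); ++f) {
    int i0 = faces(f, 0) - 1, i1 = faces(f, 1) - 1, i2 = faces(f, 2) - 1;
    Vec3 a = v3(verts(i0, 0), verts(i0, 1), verts(i0, 2));
    Vec3 b = v3(verts(i1, 0), verts(i1, 1), verts(i1, 2));
    Vec3 c = v3(verts(i2, 0), verts(i2, 1), verts(i2, 2));
    tris[f].v0 = a;
    tris[f].e1 = sub(b, a);
    tris[f].e2 = sub(c, a);
    Vec3 n = cross(tris[f].e1, tris[f].e2);
    double nn = norm3(n);
    tris[f].n = nn > 0 ? scl(n, 1.0 / nn) : v3(0, 0, 0);
  }
  return tris;
}

// Moller-Trumbore segment/triangle intersection; returns t in (tmin, tmax] or -1.
// A small barycentric slack keeps shared edges leak-free.
static inline double hit_tri(const Tri &T, const Vec3 &o, const Vec3 &d,
                             double tmin, double tmax) {
  const double EPSB = 1e-10;
  Vec3 pvec = cross(d, T.e2);
  double det = dot(T.e1, pvec);
  if (std::fabs(det) < 1e-300) return -1.0;
  double inv = 1.0 / det;
  Vec3 tvec = sub(o, T.v0);
  double u = dot(tvec, pvec) * inv;
  if (u < -EPSB || u > 1.0 + EPSB) return -1.0;
  Vec3 qvec = cross(tvec, T.e1);
  double v = dot(d, qvec) * inv;
  if (v < -EPSB || u + v > 1.0 + EPSB) return -1.0;
  double t = dot(T.e2, qvec) * inv;
  if (t <= tmin || t > tmax) return -1.0;
  return t;
}

// Squared distance from point to triangle (Eberly's region decomposition).
static double dist2_point_tri(const Tri &T, const Vec3 &p) {
  Vec3 D = sub(T.v0, p);
  double a = dot(T.e1, T.e1), b = dot(T.e1, T.e2), c = dot(T.e2, T.e2);
  double d = dot(T.e1, D), e = dot(T.e2, D);
  double det = a * c - b * b, s = b * e - c * d, t = b * d - a * e;
  if (s + t <= det) {
    if (s < 0) {
      if (t < 0) { // region 4
        if (d < 0) { t = 0; s = (-d >= a ? 1 : -d / a); }
        else { s = 0; t = (e >= 0 ? 0 : (-e >= c ? 1 : -e / c)); }
      } else { // region 3
        s = 0; t = (e >= 0 ? 0 : (-e >= c ? 1 : -e / c));
      }
    } else if (t < 0) { // region 5
      t = 0; s = (d >= 0 ? 0 : (-d >= a ? 1 : -d / a));
    } else { // region 0
      double inv = 1.0 / det; s *= inv; t *= inv;
    }
  } else {
    if (s < 0) { // region 2
      double tmp0 = b + d, tmp1 = c + e;
      if (tmp1 > tmp0) {
        double numer = tmp1 - tmp0, denom = a - 2 * b + c;
        s = (numer >= denom ? 1 : numer / denom); t = 1 - s;
      } else { s = 0; t = (tmp1 <= 0 ? 1 : (e >= 0 ? 0 : -e / c)); }
    } else if (t < 0) { // region 6
      double tmp0 = b + e, tmp1 = a + d;
      if (tmp1 > tmp0) {
        double numer = tmp1 - tmp0, denom = a - 2 * b + c;
        t = (numer >= denom ? 1 : numer / denom); s = 1 - t;
      } else { t = 0; s = (tmp1 <= 0 ? 1 : (d >= 0 ? 0 : -d / a)); }
    } else { // region 1
      double numer = c + e - b - d;
      if (numer <= 0) s = 0;
      else { double denom = a - 2 * b + c; s = (numer >= denom ? 1 : numer / denom); }
      t = 1 - s;
    }
  }
  Vec3 q = add(T.v0, add(scl(T.e1, s), scl(T.e2, t)));
  Vec3 diff = sub(q, p);
  return dot(diff, diff);
}

// Parity ray test with jittered retries when a ray grazes an edge/vertex.
static bool inside_one(const std::vector<Tri> &tris, const Vec3 &p) {
  // fixed, deliberately irrational-looking directions
  static const double dirs[8][3] = {
    {0.5340600, 0.7521510, 0.3859240}, {-0.6213309, 0.4417093, 0.6470070},
    {0.2938183, -0.8170213, 0.4962103}, {0.8033118, 0.1192347, -0.5835519},
    {-0.1490372, -0.5127395, -0.8454906}, {0.9301284, -0.3279823, 0.1629112},
    {-0.4421390, 0.8603910, -0.2528100}, {0.1021735, 0.3011827, 0.9480893}};
  for (int trial = 0; trial < 8; ++trial) {
    Vec3 d = v3(dirs[trial][0], dirs[trial][1], dirs[trial][2]);
    int crossings = 0;
    bool degenerate = false;
    for (size_t f = 0; f < tris.size(); ++f) {
      const Tri &T = tris[f];
      Vec3 pvec = cross(d, T.e2);
      double det = dot(T.e1, pvec);
      if (std::fabs(det) < 1e-12) continue;
      double inv = 1.0 / det;
      Vec3 tvec = sub(p, T.v0);
      double u = dot(tvec, pvec) * inv;
      if (u < 0 || u > 1) continue;
      Vec3 qvec = cross(tvec, T.e1);
      double v = dot(d, qvec) * inv;
      if (v < 0 || u + v > 1) continue;
      double t = dot(T.e2, qvec) * inv;
      if (t <= 0) continue;
      double tol_b = 1e-9;
      if (u < tol_b || v < tol_b || u + v > 1 - tol_b) { degenerate = true; break; }
      ++crossings;
    }
    if (!degenerate) return (crossings % 2) == 1;
  }
  return false; // pathological point; treat as outside
}

// [[Rcpp::export]]
LogicalVector cpp_inside_points(NumericMatrix verts, IntegerMatrix faces,
                                NumericMatrix pts, double tol) {
  std::vector<Tri> tris = build_tris(verts, faces);
  int n = pts.nrow();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    Vec3 p = v3(pts(i, 0), pts(i, 1), pts(i, 2));
    bool in = inside_one(tris, p);
    if (!in && tol > 0) {
      double t2 = tol * tol;
      for (size_t f = 0; f < tris.size() && !in; ++f)
        if (dist2_point_tri(tris[f], p) <= t2) in = true;
    }
    out[i] = in;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_seed_spins(NumericMatrix verts, IntegerMatrix faces, int n) {
  std::vector<Tri> tris = build_tris(verts, faces);
  double lo[3], hi[3];
  for (int a = 0; a < 3; ++a) {
    lo[a] = R_PosInf; hi[a] = R_NegInf;
    for (int i = 0; i < verts.nrow(); ++i) {
      lo[a] = std::min(lo[a], verts(i, a));
      hi[a] = std::max(hi[a], verts(i, a));
    }
  }
  NumericMatrix out(n, 3);
  int accepted = 0;
  long attempts = 0;
  while (accepted < n) {
    Vec3 p = v3(lo[0] + unif_rand() * (hi[0] - lo[0]),
                lo[1] + unif_rand() * (hi[1] - lo[1]),
                lo[2] + unif_rand() * (hi[2] - lo[2]));
    ++attempts;
    if (inside_one(tris, p)) {
      out(accepted, 0) = p.x; out(accepted, 1) = p.y; out(accepted, 2) = p.z;
      ++accepted;
    }
    if (attempts > 1000 && accepted < attempts / 100)
      stop("seed_spins: acceptance rate below 1%% (degenerate mesh?)");
  }
  return out;
}

// Advance one spin by one reflected step; returns final position.
// cand/ncand: faces whose plane lies within the step length of the start
// point (every point of the reflected polyline stays within that ball, so
// this candidate set is valid across reflections).
static inline Vec3 advance(const std::vector<Tri> &tris, Vec3 p, Vec3 v,
                           int max_reflect, int *clamped,
                           const int *cand, int ncand) {
  Vec3 p0 = p;
  int last_face = -1;
  for (int r = 0; r <= max_reflect; ++r) {
    double best_t = -1.0;
    int best_f = -1;
    for (int ci = 0; ci < ncand; ++ci) {
      int f = cand[ci];
      if (f == last_face) continue;
      double t = hit_tri(tris[f], p, v, 1e-12, 1.0);
      if (t > 0 && (best_t < 0 || t < best_t)) { best_t = t; best_f = f; }
    }
    if (best_f < 0) return add(p, v);
    if (r == max_reflect) { ++(*clamped); return p0; }
    Vec3 hit = add(p, scl(v, best_t));
    Vec3 rem = scl(v, 1.0 - best_t);
    const Vec3 &n = tris[best_f].n;
    Vec3 refl = sub(rem, scl(n, 2.0 * dot(rem, n)));
    p = hit;
    v = refl;
    last_face = best_f;
    if (norm3(v) < 1e-14) return p;
  }
  return p; // unreachable
}

// Fixed-length random-walk with specular reflection. Accumulates, per spin and
// per PGSE timing, A = sum_{j in lobe1} r_j - sum_{j in lobe2} r_j so that the
// spin phase for gradient amplitude G along unit direction g is
// phi = gamma * G * dt * dot(A, g).
//
// lobes: k x 2 integer matrix, columns (n1 = lobe length in samples,
//        m = first sample of the second lobe); sample j=0 is the start point.
// Returns list(A = N x 3 x k array, positions = N x (n_steps+1) x 3 array or
// NULL, clamped = count of reflection-budget overruns).
// [[Rcpp::export]]
List cpp_walk(NumericMatrix verts, IntegerMatrix faces, NumericMatrix start,
              int n_steps, double step_len, IntegerMatrix lobes,
              bool record, int max_reflect) {
  std::vector<Tri> tris = build_tris(verts, faces);
  int N = start.nrow();
  int K = lobes.nrow();

  // safety ball: steps fully inside it cannot touch a wall
  Vec3 cen = v3(0, 0, 0);
  for (int i = 0; i < verts.nrow(); ++i) {
    cen.x += verts(i, 0); cen.y += verts(i, 1); cen.z += verts(i, 2);
  }
  cen = scl(cen, 1.0 / verts.nrow());
  double r_safe = R_PosInf;
  for (size_t f = 0; f < tris.size(); ++f)
    r_safe = std::min(r_safe, std::sqrt(dist2_point_tri(tris[f], cen)));

  NumericVector A(N * 3 * K);
  A.attr("dim") = IntegerVector::create(N, 3, K);
  NumericVector pos;
  if (record) {
    pos = NumericVector((R_xlen_t)N * (n_steps + 1) * 3);
    pos.attr("dim") = IntegerVector::create(N, n_steps + 1, 3);
  }
  int clamped = 0;

  std::vector<int> n1(K), m(K);
  for (int k = 0; k < K; ++k) { n1[k] = lobes(k, 0); m[k] = lobes(k, 1); }
  std::vector<int> cand(tris.size());

  for (int n = 0; n < N; ++n) {
    Vec3 p = v3(start(n, 0), start(n, 1), start(n, 2));
    for (int j = 0; j <= n_steps; ++j) {
      for (int k = 0; k < K; ++k) {
        double w = 0;
        if (j < n1[k]) w = 1.0;
        else if (j >= m[k] && j < m[k] + n1[k]) w = -1.0;
        if (w != 0) {
          A[n + (R_xlen_t)N * 0 + (R_xlen_t)N * 3 * k] += w * p.x;
          A[n + (R_xlen_t)N * 1 + (R_xlen_t)N * 3 * k] += w * p.y;
          A[n + (R_xlen_t)N * 2 + (R_xlen_t)N * 3 * k] += w * p.z;
        }
      }
      if (record) {
        pos[n + (R_xlen_t)N * j] = p.x;
        pos[n + (R_xlen_t)N * j + (R_xlen_t)N * (n_steps + 1)] = p.y;
        pos[n + (R_xlen_t)N * j + (R_xlen_t)N * (n_steps + 1) * 2] = p.z;
      }
      if (j == n_steps) break;
      // uniform direction on the sphere from three normals
      double gx = norm_rand(), gy = norm_rand(), gz = norm_rand();
      double gn = std::sqrt(gx * gx + gy * gy + gz * gz);
      while (gn < 1e-12) {
        gx = norm_rand(); gy = norm_rand(); gz = norm_rand();
        gn = std::sqrt(gx * gx + gy * gy + gz * gz);
      }
      Vec3 v = v3(step_len * gx / gn, step_len * gy / gn, step_len * gz / gn);
      Vec3 dc = sub(p, cen);
      if (norm3(dc) + step_len < r_safe) { p = add(p, v); continue; }
      // cull faces whose supporting plane is farther than one step length
      int ncand = 0;
      for (int f = 0; f < (int)tris.size(); ++f) {
        double d = dot(tris[f].n, sub(p, tris[f].v0));
        if (std::fabs(d) <= step_len) cand[ncand++] = f;
      }
      if (ncand == 0) p = add(p, v);
      else p = advance(tris, p, v, max_reflect, &clamped, cand.data(), ncand);
    }
  }

  return List::create(_["A"] = A,
                      _["positions"] = record ? (SEXP)pos : R_NilValue,
                      _["clamped"] = clamped);
}
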