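// Small fixed-size linear algebra for the multibody core.
#ifndef MVNAIL_CORE_MATH_H
#define MVNAIL_CORE_MATH_H

#include <cmath>
#include <cstring>
#include <algorithm>
#include <vector>

struct Vec3 {
  double x = 0, y = 0, z = 0;
  Vec3() {}
  Vec3(double a, double b, double c) : x(a), y(b), z(c) {}
  Vec3 operator+(const Vec3& o) const { return {x + o.x, y + o.y, z + o.z}; }
  Vec3 operator-(const Vec3& o) const { return {x - o.x, y - o.y, z - o.z}; }
  Vec3 operator*(double s) const { return {x * s, y * s, z * s}; }
  Vec3 operator-() const { return {-x, -y, -z}; }
  Vec3& operator+=(const Vec3& o) { x += o.x; y += o.y; z += o.z; return *this; }
  Vec3& operator-=(const Vec3& o) { x -= o.x; y -= o.y; z -= o.z; return *this; }
};

inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
          a.x * b.y - a.y * b.x};
}
inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }

// 3x3 matrix, row-major
struct Mat3 {
  double m[9] = {0};
  static Mat3 identity() {
    Mat3 r; r.m[0] = r.m[4] = r.m[8] = 1; return r;
  }
  double& operator()(int i, int j) { return m[3 * i + j]; }
  double operator()(int i, int j) const { return m[3 * i + j]; }
  Vec3 operator*(const Vec3& v) const {
    return {m[0] * v.x + m[1] * v.y + m[2] * v.z,
            m[3] * v.x + m[4] * v.y + m[5] * v.z,
            m[6] * v.x + m[7] * v.y + m[8] * v.z};
  }
  Mat3 operator*(const Mat3& o) const {
    Mat3 r;
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        double s = 0;
        for (int k = 0; k < 3; ++k) s += (*this)(i, k) * o(k, j);
        r(i, j) = s;
      }
    return r;
  }
  Mat3 t() const {
    Mat3 r;
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) r(i, j) = (*this)(j, i);
    return r;
  }
  Vec3 tmul(const Vec3& v) const {   // transpose * v
    return {m[0] * v.x + m[3] * v.y + m[6] * v.z,
            m[1] * v.x + m[4] * v.y + m[7] * v.z,
            m[2] * v.x + m[5] * v.y + m[8] * v.z};
  }
};

// quaternion, scalar first (w, x, y, z)
struct Quat {
  double w = 1, x = 0, y = 0, z = 0;
  Quat() {}
  Quat(double a, double b, double c, double d) : w(a), x(b), y(c), z(d) {}
  void normalize() {
    double n = std::sqrt(w * w + x * x + y * y + z * z);
    w /= n; x /= n; y /= n; z /= n;
  }
};

inline Quat qmul(const Quat& a, const Quat& b) {
  return {a.w * b.w - a.x * b.x - a.y * b.y - a.z * b.z,
          a.w * b.x + a.x * b.w + a.y * b.z - a.z * b.y,
          a.w * b.y - a.x * b.z + a.y * b.w + a.z * b.x,
          a.w * b.z + a.x * b.y - a.y * b.x + a.z * b.w};
}

inline Mat3 qrot(const Quat& q) {
  Mat3 R;
  double w = q.w, x = q.x, y = q.y, z = q.z;
  R(0, 0) = 1 - 2 * (y * y + z * z); R(0, 1) = 2 * (x * y - w * z);
  R(0, 2) = 2 * (x * z + w * y);
  R(1, 0) = 2 * (x * y + w * z); R(1, 1) = 1 - 2 * (x * x + z * z);
  R(1, 2) = 2 * (y * z - w * x);
  R(2, 0) = 2 * (x * z - w * y); R(2, 1) = 2 * (y * z + w * x);
  R(2, 2) = 1 - 2 * (x * x + y * y);
  return R;
}

// rotation vector (axis * angle) of a rotation matrix; safe near identity
inline Vec3 rot_log(const Mat3& R) {
  double c = (R(0, 0) + R(1, 1) + R(2, 2) - 1) / 2;
  c = std::max(-1.0, std::min(1.0, c));
  double th = std::acos(c);
  Vec3 w(R(2, 1) - R(1, 2), R(0, 2) - R(2, 0), R(1, 0) - R(0, 1));
  if (th < 1e-8) return w * 0.5;                 // small angle
  double s = std::sin(th);
  if (s < 1e-8) {                                // near pi: fall back
    // diagonal-dominant axis extraction
    int k = 0;
    if (R(1, 1) > R(0, 0)) k = 1;
    if (R(2, 2) > R(k, k)) k = 2;
    Vec3 a(std::sqrt(std::max(0.0, (R(0, 0) - c) / (1 - c))) ,
           std::sqrt(std::max(0.0, (R(1, 1) - c) / (1 - c))) ,
           std::sqrt(std::max(0.0, (R(2, 2) - c) / (1 - c))));
    // fix signs from off-diagonals
    if (k == 0) { if (R(0, 1) + R(1, 0) < 0) a.y = -a.y;
                  if (R(0, 2) + R(2, 0) < 0) a.z = -a.z; }
    else if (k == 1) { if (R(0, 1) + R(1, 0) < 0) a.x = -a.x;
                       if (R(1, 2) + R(2, 1) < 0) a.z = -a.z; }
    else { if (R(0, 2) + R(2, 0) < 0) a.x = -a.x;
           if (R(1, 2) + R(2, 1) < 0) a.y = -a.y; }
    double n = norm(a); if (n < 1e-12) return {th, 0, 0};
    return a * (th / n);
  }
  return w * (th / (2 * s));
}

inline Quat quat_exp_half(const Vec3& w, double h) {
  // exp(h * w / 2) as a unit quaternion
  Vec3 v = w * (h * 0.5);
  double th = norm(v);
  if (th < 1e-12) return {1, v.x, v.y, v.z};
  double s = std::sin(th) / th;
  return {std::cos(th), v.x * s, v.y * s, v.z * s};
}

// Symmetric banded matrix (lower storage by column) with Cholesky solve.
struct BandMatrix {
  int n = 0, bw = 0;                 // dimension, half bandwidth
  std::vector<double> a;             // a[j * (bw + 1) + k] = A(j + k, j)
  void resize(int n_, int bw_) {
    n = n_; bw = bw_; a.assign((size_t)n * (bw + 1), 0.0);
  }
  void zero() { std::fill(a.begin(), a.end(), 0.0); }
  inline double& at(int i, int j) {  // requires j <= i <= j + bw
    return a[(size_t)j * (bw + 1) + (i - j)];
  }
  inline void add(int i, int j, double v) {
    if (i < j) std::swap(i, j);
    if (i - j <= bw) a[(size_t)j * (bw + 1) + (i - j)] += v;
  }
  // zero row/col k, unit diagonal (for constrained DOF); caller fixes rhs
  void constrain(int k) {
    for (int j = std::max(0, k - bw); j < k; ++j) a[(size_t)j * (bw + 1) + (k - j)] = 0;
    for (int i = 1; i <= bw && k + i < n; ++i) a[(size_t)k * (bw + 1) + i] = 0;
    a[(size_t)k * (bw + 1)] = 1.0;
  }
  // in-place LL^T; returns false if not positive definite
  bool factor() {
    for (int j = 0; j < n; ++j) {
      for (int k = std::max(0, j - bw); k < j; ++k) {
        double ljk = a[(size_t)k * (bw + 1) + (j - k)];
        if (ljk == 0.0) continue;
        int imax = std::min(n - 1, k + bw);
        for (int i = j; i <= imax; ++i)
          a[(size_t)j * (bw + 1) + (i - j)] -= a[(size_t)k * (bw + 1) + (i - k)] * ljk;
      }
      double d = a[(size_t)j * (bw + 1)];
      if (d <= 0) return false;
      d = std::sqrt(d);
      int imax = std::min(n - 1, j + bw);
      for (int i = j; i <= imax; ++i) a[(size_t)j * (bw + 1) + (i - j)] /= d;
    }
    return true;
  }
  void solve(std::vector<double>& b) const {
    for (int j = 0; j < n; ++j) {            // forward: L y = b
      b[j] /= a[(size_t)j * (bw + 1)];
      int imax = std::min(n - 1, j + bw);
      for (int i = j + 1; i <= imax; ++i)
        b[i] -= a[(size_t)j * (bw + 1) + (i - j)] * b[j];
    }
    for (int j = n - 1; j >= 0; --j) {       // backward: L^T x = y
      int imax = std::min(n - 1, j + bw);
      for (int i = j + 1; i <= imax; ++i)
        b[j] -= a[(size_t)j * (bw + 1) + (i - j)] * b[i];
      b[j] /= a[(size_t)j * (bw + 1)];
    }
  }
};

#endif
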