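#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Iterative solver kernel for the adaptive-TV variational flow model.
//
// Per pixel the update blends two diagonally semi-implicit gradient-descent
// steps with weight w_hs on the quadratic (Horn-Schunck) step and 1 - w_hs
// on the epsilon-perturbed TV step. Both steps share the fixed points of
// their Euler-Lagrange systems:
//   quadratic: (Ix u + Iy v + It) Ix - alpha (avg(u) - u) = 0
//   TV:        (Ix u + Iy v + It) Ix - alpha div(grad u / |grad u|_eps) = 0
// Semi-implicit means the terms diagonal in the updated pixel sit in the
// denominator, so the scheme is stable for any step gamma and tends to the
// Jacobi fixed-point iteration as gamma -> Inf.
//
// Conventions: matrices are (row i = y, column j = x); replicate (Neumann)
// borders for the 8-neighbor average; forward-difference gradient /
// backward-difference divergence adjoint pair for the TV term.

static inline int clampi(int a, int lo, int hi) {
  return a < lo ? lo : (a > hi ? hi : a);
}

// weighted 8-neighbor average, clamped borders (1/6 axial, 1/12 diagonal)
static void neighbor_avg(const NumericMatrix& m, NumericMatrix& out) {
  const int h = m.nrow(), w = m.ncol();
  for (int j = 0; j < w; ++j) {
    const int jl = clampi(j - 1, 0, w - 1), jr = clampi(j + 1, 0, w - 1);
    for (int i = 0; i < h; ++i) {
      const int iu = clampi(i - 1, 0, h - 1), id = clampi(i + 1, 0, h - 1);
      out(i, j) = (m(iu, j) + m(id, j) + m(i, jl) + m(i, jr)) / 6.0 +
                  (m(iu, jl) + m(iu, jr) + m(id, jl) + m(id, jr)) / 12.0;
    }
  }
}

// TV curvature pieces for one component: diffusivity g = 1/|grad m|_eps at
// each pixel (forward differences, zero at the far borders), then for each
// pixel the off-diagonal neighbor flux nsum and diagonal coefficient dcoef
// of div(g grad m) = nsum - dcoef * m.
static void tv_terms(const NumericMatrix& m, double eps,
                     NumericMatrix& g, NumericMatrix& nsum,
                     NumericMatrix& dcoef) {
  const int h = m.nrow(), w = m.ncol();
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      const double mx = (j + 1 < w) ? m(i, j + 1) - m(i, j) : 0.0;
      const double my = (i + 1 < h) ? m(i + 1, j) - m(i, j) : 0.0;
      g(i, j) = 1.0 / std::sqrt(mx * mx + my * my + eps);
    }
  }
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      double d = 0.0, s = 0.0;
      if (j + 1 < w) { d += g(i, j); s += g(i, j) * m(i, j + 1); }
      if (j > 0)     { d += g(i, j - 1); s += g(i, j - 1) * m(i, j - 1); }
      if (i + 1 < h) { d += g(i, j); s += g(i, j) * m(i + 1, j); }
      if (i > 0)     { d += g(i - 1, j); s += g(i - 1, j) * m(i - 1, j); }
      nsum(i, j) = s;
      dcoef(i, j) = d;
    }
  }
}

// [[Rcpp::export(name = "flow_iterate_cpp")]]
List flow_iterate_cpp(NumericMatrix Ix, NumericMatrix Iy, NumericMatrix It,
                      NumericMatrix u0, NumericMatrix v0, NumericMatrix w_hs,
                      double alpha, double gamma, double eps,
                      int max_iter, double tol) {
  const int h = Ix.nrow(), w = Ix.ncol();
  NumericMatrix u(clone(u0)), v(clone(v0));
  NumericMatrix ubar(h, w), vbar(h, w);
  NumericMatrix gu(h, w), nu(h, w), du(h, w);
  NumericMatrix gv(h, w), nv(h, w), dv(h, w);
  NumericMatrix un(h, w), vn(h, w);

  bool need_hs = false, need_tv = false;
  for (int j = 0; j < w && !(need_hs && need_tv); ++j)
    for (int i = 0; i < h; ++i) {
      if (w_hs(i, j) > 0.0) need_hs = true;
      if (w_hs(i, j) < 1.0) need_tv = true;
    }

  bool converged = false;
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    if (need_hs) { neighbor_avg(u, ubar); neighbor_avg(v, vbar); }
    if (need_tv) {
      tv_terms(u, eps, gu, nu, du);
      tv_terms(v, eps, gv, nv, dv);
    }
    double delta2 = 0.0, norm2 = 0.0;
    for (int j = 0; j < w; ++j) {
      for (int i = 0; i < h; ++i) {
        const double ix = Ix(i, j), iy = Iy(i, j), it = It(i, j);
        const double uc = u(i, j), vc = v(i, j);
        const double bu = ix * (iy * vc + it);   // data forcing for u
        const double bv = iy * (ix * uc + it);   // data forcing for v
        const double wh = w_hs(i, j), wt = 1.0 - wh;
        double unew = 0.0, vnew = 0.0;
        if (wh > 0.0) {
          unew += wh * (uc + gamma * (alpha * ubar(i, j) - bu)) /
                  (1.0 + gamma * (alpha + ix * ix));
          vnew += wh * (vc + gamma * (alpha * vbar(i, j) - bv)) /
                  (1.0 + gamma * (alpha + iy * iy));
        }
        if (wt > 0.0) {
          unew += wt * (uc + gamma * (alpha * nu(i, j) - bu)) /
                  (1.0 + gamma * (alpha * du(i, j) + ix * ix));
          vnew += wt * (vc + gamma * (alpha * nv(i, j) - bv)) /
                  (1.0 + gamma * (alpha * dv(i, j) + iy * iy));
        }
        const double eu = unew - uc, ev = vnew - vc;
        delta2 += eu * eu + ev * ev;
        norm2 += unew * unew + vnew * vnew;
        un(i, j) = unew;
        vn(i, j) = vnew;
      }
    }
    std::swap(u, un);
    std::swap(v, vn);
    const double rel = std::sqrt(delta2) / (std::sqrt(norm2) + 1e-12);
    if (delta2 == 0.0 || rel < tol) { converged = true; break; }
  }
  if (iter > max_iter) iter = max_iter;

  return List::create(_["u"] = u, _["v"] = v,
                      _["iterations"] = iter,
                      _["converged"] = converged);
}
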