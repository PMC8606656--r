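#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Kernel-weighted sums of one query against the support set.
// Sp/Sm: per-class weight sums; Spx/Spy/Smx/Smy: weighted coordinate sums;
// wmax: largest single kernel weight (used for the denominator floor).
struct Sums {
  double Sp, Spx, Spy, Sm, Smx, Smy, wmax;
};

static inline Sums eval_sums(double qx, double qy, const double* px,
                             const double* py, const int* lab, int n,
                             double inv2h2) {
  Sums s = {0, 0, 0, 0, 0, 0, 0};
  for (int i = 0; i < n; ++i) {
    double dx = qx - px[i], dy = qy - py[i];
    double w = std::exp(-(dx * dx + dy * dy) * inv2h2);
    if (w > s.wmax) s.wmax = w;
    if (lab[i] > 0) {
      s.Sp += w; s.Spx += w * px[i]; s.Spy += w * py[i];
    } else {
      s.Sm += w; s.Smx += w * px[i]; s.Smy += w * py[i];
    }
  }
  return s;
}

// Batch mode seeking. mode 0: dual (supervised mean shift on the signed
// kernel-weight sum; conventional mean shift is the all-positive special
// case). mode 1: density-ratio ascent Sp / (Sm + eps_ratio) by normalized
// gradient steps. Objective values are returned in raw kernel-sum units;
// the R wrapper applies the c_d / (N h^d) scale.
// [[Rcpp::export]]
List seek_batch_cpp(NumericMatrix inits, NumericMatrix pts, IntegerVector lab,
                    double h, int mode, double tol, int max_rounds,
                    double step_shrink, int max_backtracks, double eps_den_rel,
                    double eps_ratio, bool record) {
  const int m = inits.nrow(), n = pts.nrow();
  std::vector<double> px(n), py(n);
  std::vector<int> lb(n);
  for (int i = 0; i < n; ++i) {
    px[i] = pts(i, 0); py[i] = pts(i, 1); lb[i] = lab[i];
  }
  const double inv2h2 = 1.0 / (2.0 * h * h);

  NumericMatrix finals(m, 2);
  NumericVector q_final(m), q_signed_final(m);
  IntegerVector rounds(m), init_sign(m);
  LogicalVector converged(m), failed(m);
  List trajs(record ? m : 0);

  for (int k = 0; k < m; ++k) {
    double x = inits(k, 0), y = inits(k, 1);
    Sums s = eval_sums(x, y, px.data(), py.data(), lb.data(), n, inv2h2);
    double qs = s.Sp - s.Sm;                     // signed quality (raw)
    double qcur = (mode == 1) ? s.Sp / (s.Sm + eps_ratio) : std::fabs(qs);
    init_sign[k] = (qs > 0) - (qs < 0);
    bool conv = false, fail = false;
    int nacc = 0;

    std::vector<double> tx, ty, tq, tqs;
    if (record) {
      tx.push_back(x); ty.push_back(y); tq.push_back(qcur); tqs.push_back(qs);
    }

    while (nacc < max_rounds) {
      if (s.wmax < 1e-300) { conv = true; break; }  // isolated kernel: freeze

      double propx, propy;
      if (mode == 1) {
        // step h^2 * grad(r) / r (gradient ascent on log r): scales with
        // the relative gradient, so a flat guarded ratio gives a
        // vanishing step instead of a fixed-length march
        if (s.Sp < 1e-300) { conv = true; break; }  // no positive support
        double gpx = s.Spx - s.Sp * x, gpy = s.Spy - s.Sp * y;
        double gmx = s.Smx - s.Sm * x, gmy = s.Smy - s.Sm * y;
        double denom = (s.Sm + eps_ratio) * s.Sp;
        propx = (gpx * (s.Sm + eps_ratio) - s.Sp * gmx) / denom;
        propy = (gpy * (s.Sm + eps_ratio) - s.Sp * gmy) / denom;
        double nrm = std::hypot(propx, propy);
        if (nrm < 1e-300) { conv = true; break; }
        if (nrm > h) { propx *= h / nrm; propy *= h / nrm; }  // trust region
      } else if (std::fabs(qs) >= eps_den_rel * s.wmax) {
        // supervised mean-shift step
        propx = (s.Spx - s.Smx) / qs - x;
        propy = (s.Spy - s.Smy) / qs - y;
      } else {
        // balanced-density fallback: normalized gradient step of length tol
        double gx = (s.Spx - s.Sp * x) - (s.Smx - s.Sm * x);
        double gy = (s.Spy - s.Sp * y) - (s.Smy - s.Sm * y);
        double nrm = std::sqrt(gx * gx + gy * gy);
        if (nrm < 1e-300) { conv = true; break; }
        double sgn = (qs >= 0) ? 1.0 : -1.0;
        propx = sgn * tol * gx / nrm; propy = sgn * tol * gy / nrm;
      }

      // backtracking line search on the objective
      double step = 1.0, cx = x, cy = y, qc = qcur, qsc = qs;
      Sums sc = s;
      bool acc = false;
      for (int bt = 0; bt <= max_backtracks; ++bt) {
        cx = x + step * propx; cy = y + step * propy;
        if (!std::isfinite(cx) || !std::isfinite(cy)) { fail = true; break; }
        sc = eval_sums(cx, cy, px.data(), py.data(), lb.data(), n, inv2h2);
        qsc = sc.Sp - sc.Sm;
        qc = (mode == 1) ? sc.Sp / (sc.Sm + eps_ratio) : std::fabs(qsc);
        if (qc > qcur) { acc = true; break; }
        step *= step_shrink;
      }
      if (fail) break;
      if (!acc) { conv = true; break; }           // frozen: no improving step

      double disp = std::hypot(cx - x, cy - y);
      x = cx; y = cy; s = sc; qs = qsc; qcur = qc;
      ++nacc;
      if (record) {
        tx.push_back(x); ty.push_back(y); tq.push_back(qcur); tqs.push_back(qs);
      }
      if (disp < tol) { conv = true; break; }
    }

    finals(k, 0) = x; finals(k, 1) = y;
    q_final[k] = qcur; q_signed_final[k] = qs;
    rounds[k] = nacc; converged[k] = conv; failed[k] = fail;
    if (record) {
      int np = tx.size();
      NumericMatrix pos(np, 2);
      NumericVector qv(np), qsv(np);
      for (int i = 0; i < np; ++i) {
        pos(i, 0) = tx[i]; pos(i, 1) = ty[i]; qv[i] = tq[i]; qsv[i] = tqs[i];
      }
      trajs[k] = List::create(_["positions"] = pos, _["q"] = qv,
                              _["q_signed"] = qsv);
    }
  }

  return List::create(
      _["finals"] = finals, _["q"] = q_final, _["q_signed"] = q_signed_final,
      _["rounds"] = rounds, _["converged"] = converged, _["failed"] = failed,
      _["initial_sign"] = init_sign, _["trajectories"] = trajs);
}

// Raw kernel weight sums of many queries against one support set
// (used for density grids / heat maps).
// [[Rcpp::export]]
NumericVector kde_sum_batch_cpp(NumericMatrix queries, NumericMatrix pts,
                                double h) {
  const int m = queries.nrow(), n = pts.nrow();
  const double inv2h2 = 1.0 / (2.0 * h * h);
  NumericVector out(m);
  for (int k = 0; k < m; ++k) {
    double qx = queries(k, 0), qy = queries(k, 1), acc = 0;
    for (int i = 0; i < n; ++i) {
      double dx = qx - pts(i, 0), dy = qy - pts(i, 1);
      acc += std::exp(-(dx * dx + dy * dy) * inv2h2);
    }
    out[k] = acc;
  }
  return out;
}
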