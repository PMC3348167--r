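// Two-phase revised simplex specialised to basis pursuit:
//
//     minimise sum_j |w_j|   subject to   A w = b,
//
// via the non-negative split w = u - v, u,v >= 0, min sum(u_j + v_j).
// The LP columns are +a_j (for u_j) and -a_j (for v_j); the mirror
// structure is exploited so pricing a window of K' columns costs one
// m-by-K' gemv and yields the reduced costs of both half-columns.
// Partial (windowed) pricing keeps per-iteration cost low; optimality is
// only declared after a full pass over all windows finds no candidate.
// The basis inverse is kept explicitly (m is the number of subjects, a
// few hundred at most) with product-form updates and periodic
// refactorisation.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

const double RC_TOL = 1e-9;   // reduced-cost optimality tolerance
const double PIV_TOL = 1e-9;  // minimum admissible pivot magnitude

// variable encoding: k in [0, K)      -> u_k  (column +a_k)
//                    k in [K, 2K)     -> v_{k-K} (column -a_{k-K})
//                    k in [2K, 2K+m)  -> artificial for row k-2K
inline bool is_art(uword k, uword K) { return k >= 2 * K; }

vec lp_column(const mat& Af, uword k, uword K, uword m) {
  if (is_art(k, K)) {
    vec e(m, fill::zeros);
    e(k - 2 * K) = 1.0;
    return e;
  }
  if (k < K) return Af.col(k);
  return -Af.col(k - K);
}

}  // namespace

// [[Rcpp::export(name = ".bp_simplex_cpp")]]
Rcpp::List bp_simplex(const arma::mat& A, const arma::vec& b,
                      double feas_tol = 1e-7, int max_iter = 200000) {
  const uword m = A.n_rows, K = A.n_cols;
  if (b.n_elem != m) Rcpp::stop("length of b must match rows of A");

  // flip rows so the right-hand side is non-negative
  vec rs = ones<vec>(m);
  for (uword i = 0; i < m; ++i) if (b(i) < 0) rs(i) = -1.0;
  mat Af = A.each_col() % rs;
  vec bf = b % rs;

  uvec basis(m);
  // 0 = nonbasic, 1 = basic, 2 = banned (artificial that left the basis)
  std::vector<unsigned char> state(2 * K + m, 0);
  for (uword i = 0; i < m; ++i) {
    basis(i) = 2 * K + i;
    state[2 * K + i] = 1;
  }
  mat Binv = eye<mat>(m, m);
  vec xB = bf;

  const uword W = std::min<uword>(K, std::max<uword>(256, K / 16));
  const uword n_win = (K + W - 1) / W;
  uword win = 0;

  int phase = 1;
  int iter = 0, since_refactor = 0;
  bool bland = false;
  int degen_run = 0;
  int status = 2;  // 0 optimal, 1 infeasible, 2 iteration limit, 3 numerical

  auto refactor = [&]() {
    mat B(m, m);
    for (uword i = 0; i < m; ++i) B.col(i) = lp_column(Af, basis(i), K, m);
    mat Bi;
    if (!inv(Bi, B)) return false;
    Binv = Bi;
    xB = Binv * bf;
    since_refactor = 0;
    return true;
  };

  while (iter < max_iter) {
    ++iter;

    // phase-dependent basic costs and simplex multipliers
    vec cB(m);
    for (uword i = 0; i < m; ++i) {
      if (phase == 1) cB(i) = is_art(basis(i), K) ? 1.0 : 0.0;
      else            cB(i) = is_art(basis(i), K) ? 0.0 : 1.0;
    }
    vec y = Binv.t() * cB;
    const double c_orig = (phase == 1) ? 0.0 : 1.0;

    // partial pricing: scan windows of columns until one yields a
    // candidate; a full empty pass means the phase is optimal
    sword enter = -1;
    for (uword pass = 0; pass < n_win; ++pass) {
      uword w = (win + pass) % n_win;
      uword lo = w * W, hi = std::min(K, lo + W);
      vec g = Af.cols(lo, hi - 1).t() * y;
      double best = -RC_TOL;
      for (uword j = lo; j < hi; ++j) {
        double gj = g(j - lo);
        if (state[j] == 0) {
          double d = c_orig - gj;
          if (bland) {
            if (d < -RC_TOL && (enter < 0 || (uword)enter > j)) { enter = j; }
          } else if (d < best) { best = d; enter = j; }
        }
        if (state[K + j] == 0) {
          double d = c_orig + gj;
          if (bland) {
            if (d < -RC_TOL && (enter < 0 || (uword)enter > K + j)) { enter = K + j; }
          } else if (d < best) { best = d; enter = K + j; }
        }
      }
      if (enter >= 0) { win = w; break; }
    }

    if (enter < 0) {  // optimal for current phase
      if (phase == 1) {
        double art_sum = 0;
        for (uword i = 0; i < m; ++i)
          if (is_art(basis(i), K)) art_sum += std::abs(xB(i));
        if (art_sum > feas_tol * (1.0 + norm(bf, "inf"))) { status = 1; break; }
        phase = 2;
        bland = false;
        degen_run = 0;
        continue;
      }
      status = 0;
      break;
    }

    vec d = Binv * lp_column(Af, (uword)enter, K, m);

    // Leaving variable. Basic artificials sit at ~0 in phase 2; if the
    // direction touches one, pivot it out at a zero step so it can never
    // re-grow.
    sword leave = -1;
    if (phase == 2) {
      for (uword i = 0; i < m; ++i)
        if (is_art(basis(i), K) && std::abs(d(i)) > PIV_TOL) { leave = i; break; }
    }
    double theta = 0.0;
    if (leave < 0) {
      double best_ratio = datum::inf;
      double best_piv = 0.0;
      for (uword i = 0; i < m; ++i) {
        if (d(i) > PIV_TOL) {
          double ratio = xB(i) / d(i);
          if (ratio < best_ratio - 1e-12 ||
              (ratio < best_ratio + 1e-12 && std::abs(d(i)) > best_piv)) {
            best_ratio = ratio;
            best_piv = std::abs(d(i));
            leave = i;
          }
        }
      }
      if (leave < 0) { status = 3; break; }  // unbounded: numerical breakdown
      theta = std::max(best_ratio, 0.0);
    }

    // anti-cycling: long degenerate runs switch pricing to Bland's rule
    if (theta < 1e-12) {
      if (++degen_run > 2 * (int)(m + K)) bland = true;
    } else {
      degen_run = 0;
      bland = false;
    }

    uword out = basis(leave);
    state[out] = is_art(out, K) ? 2 : 0;
    basis(leave) = (uword)enter;
    state[enter] = 1;

    xB -= theta * d;
    xB(leave) = theta;
    for (uword i = 0; i < m; ++i) if (xB(i) < 0 && xB(i) > -1e-11) xB(i) = 0;

    double piv = d(leave);
    Binv.row(leave) /= piv;
    for (uword i = 0; i < m; ++i) {
      if (i != (uword)leave && std::abs(d(i)) > 0) {
        Binv.row(i) -= d(i) * Binv.row(leave);
      }
    }

    if (++since_refactor >= 64) {
      if (!refactor()) { status = 3; break; }
    }
  }

  vec w(K, fill::zeros);
  vec dual(K, fill::zeros);
  if (status == 0) {
    for (uword i = 0; i < m; ++i) {
      uword k = basis(i);
      if (k < K) w(k) += xB(i);
      else if (k < 2 * K) w(k - K) -= xB(i);
    }
    // dual attractiveness |a_j' y*| at the optimum: 1 on the support,
    // close to 1 for columns that are nearly profitable
    vec cB(m);
    for (uword i = 0; i < m; ++i) cB(i) = is_art(basis(i), K) ? 0.0 : 1.0;
    vec y = Binv.t() * cB;
    dual = abs(Af.t() * y);
  }
  double obj = accu(abs(w));
  return Rcpp::List::create(Rcpp::Named("w") = w,
                            Rcpp::Named("status") = status,
                            Rcpp::Named("objective") = obj,
                            Rcpp::Named("iterations") = iter,
                            Rcpp::Named("dual") = dual);
}
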