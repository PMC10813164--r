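// Iterative TM-score alignment core: gapless-threading seeds, Kabsch
// superposition, and semi-global DP over the TM kernel score matrix.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Proper-rotation Kabsch for row-vector points: mapped A = (A - cA) * R + cB.
static bool kabsch_rows(const arma::mat& A, const arma::mat& B,
                        arma::mat& R, arma::rowvec& cA, arma::rowvec& cB) {
  if (A.n_rows < 3) return false;
  cA = arma::mean(A, 0);
  cB = arma::mean(B, 0);
  arma::mat H = (A.each_row() - cA).t() * (B.each_row() - cB);
  arma::mat U, V;
  arma::vec s;
  if (!arma::svd(U, s, V, H)) return false;
  double d = arma::det(U * V.t()) < 0 ? -1.0 : 1.0;
  arma::mat D = arma::eye(3, 3);
  D(2, 2) = d;
  R = U * D * V.t();
  return true;
}

// Semi-global (free end gaps) Needleman-Wunsch over score matrix S with a
// linear gap penalty; returns matched index pairs (0-based), strictly
// increasing in both indices.
static arma::umat dp_pairs(const arma::mat& S, double gap) {
  const int n = S.n_rows, m = S.n_cols;
  arma::mat M(n + 1, m + 1, arma::fill::zeros);
  arma::Mat<int> tb(n + 1, m + 1, arma::fill::zeros); // 0 stop, 1 diag, 2 up, 3 left
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diag = M(i - 1, j - 1) + S(i - 1, j - 1);
      double up = M(i - 1, j) + gap;
      double left = M(i, j - 1) + gap;
      double best = diag;
      int t = 1;
      if (up > best) { best = up; t = 2; }
      if (left > best) { best = left; t = 3; }
      M(i, j) = best;
      tb(i, j) = t;
    }
  }
  // free trailing gaps: best cell on last row/col
  int bi = n, bj = m;
  double best = M(n, m);
  for (int i = 1; i <= n; ++i)
    if (M(i, m) > best) { best = M(i, m); bi = i; bj = m; }
  for (int j = 1; j <= m; ++j)
    if (M(n, j) > best) { best = M(n, j); bi = n; bj = j; }
  std::vector<std::pair<int, int>> rev;
  int i = bi, j = bj;
  while (i > 0 && j > 0) {
    int t = tb(i, j);
    if (t == 1) {
      rev.push_back(std::make_pair(i - 1, j - 1));
      --i; --j;
    } else if (t == 2) {
      --i;
    } else {
      --j;
    }
  }
  arma::umat out(rev.size(), 2);
  for (size_t k = 0; k < rev.size(); ++k) {
    out(k, 0) = rev[rev.size() - 1 - k].first;
    out(k, 1) = rev[rev.size() - 1 - k].second;
  }
  return out;
}

static double kernel_sum(const arma::mat& A, const arma::mat& B,
                         const arma::umat& pairs, const arma::mat& R,
                         const arma::rowvec& cA, const arma::rowvec& cB,
                         double d0) {
  double s = 0.0;
  for (arma::uword k = 0; k < pairs.n_rows; ++k) {
    arma::rowvec am = (A.row(pairs(k, 0)) - cA) * R + cB;
    double d = arma::norm(am - B.row(pairs(k, 1)), 2);
    s += 1.0 / (1.0 + (d / d0) * (d / d0));
  }
  return s;
}

// [[Rcpp::export(name = ".tm_align_core")]]
List tm_align_core(const arma::mat& A, const arma::mat& B, double d0,
                   double gap = -0.6, int max_iter = 30, int max_shifts = 20) {
  const int la = A.n_rows, lb = B.n_rows;
  const int lmin = std::min(la, lb);
  std::vector<int> lens;
  lens.push_back(std::min(5, lmin));
  lens.push_back(std::max(3, lmin / 2));
  lens.push_back(lmin);
  std::sort(lens.begin(), lens.end());
  lens.erase(std::unique(lens.begin(), lens.end()), lens.end());

  double best_score = -1.0;
  arma::umat best_pairs;
  arma::mat best_R;
  arma::rowvec best_cA, best_cB;

  for (size_t li = 0; li < lens.size(); ++li) {
    int L = lens[li];
    if (L < 3) continue;
    int smin = -(lb - L), smax = la - L;
    int nshift = smax - smin + 1;
    int step = std::max(1, (nshift + max_shifts - 1) / max_shifts);
    for (int s = smin; s <= smax; s += step) {
      int ia = std::max(0, s);
      int ib = ia - s;
      int len = std::min(la - ia, lb - ib);
      len = std::min(len, L);
      if (len < 3) continue;
      arma::mat SA = A.rows(ia, ia + len - 1);
      arma::mat SB = B.rows(ib, ib + len - 1);
      arma::mat R;
      arma::rowvec cA, cB;
      if (!kabsch_rows(SA, SB, R, cA, cB)) continue;

      arma::umat prev;
      arma::umat pairs;
      for (int it = 0; it < max_iter; ++it) {
        arma::mat Am = (A.each_row() - cA) * R;
        Am.each_row() += cB;
        arma::mat S(la, lb);
        for (int i = 0; i < la; ++i)
          for (int j = 0; j < lb; ++j) {
            double d = arma::norm(Am.row(i) - B.row(j), 2);
            S(i, j) = 1.0 / (1.0 + (d / d0) * (d / d0));
          }
        pairs = dp_pairs(S, gap);
        if (pairs.n_rows == 0) break;
        if (prev.n_rows == pairs.n_rows &&
            arma::all(arma::vectorise(prev == pairs)))
          break;
        prev = pairs;
        // refine transform on close pairs
        std::vector<double> dk(pairs.n_rows);
        std::vector<arma::uword> sel;
        for (arma::uword k = 0; k < pairs.n_rows; ++k) {
          dk[k] = arma::norm(Am.row(pairs(k, 0)) - B.row(pairs(k, 1)), 2);
          if (dk[k] < d0) sel.push_back(k);
        }
        if (sel.size() < 3) {
          std::vector<arma::uword> ord(pairs.n_rows);
          for (arma::uword k = 0; k < pairs.n_rows; ++k) ord[k] = k;
          std::sort(ord.begin(), ord.end(),
                    [&](arma::uword x, arma::uword y) { return dk[x] < dk[y]; });
          sel.assign(ord.begin(),
                     ord.begin() + std::min<size_t>(3, ord.size()));
        }
        if (sel.size() < 3) break;
        arma::mat PA(sel.size(), 3), PB(sel.size(), 3);
        for (size_t k = 0; k < sel.size(); ++k) {
          PA.row(k) = A.row(pairs(sel[k], 0));
          PB.row(k) = B.row(pairs(sel[k], 1));
        }
        if (!kabsch_rows(PA, PB, R, cA, cB)) break;
      }
      if (pairs.n_rows == 0) continue;
      double sc = kernel_sum(A, B, pairs, R, cA, cB, d0);
      if (sc > best_score) {
        best_score = sc;
        best_pairs = pairs;
        best_R = R;
        best_cA = cA;
        best_cB = cB;
      }
    }
  }
  if (best_score < 0)
    return List::create(Named("pairs") = IntegerMatrix(0, 2));
  IntegerMatrix pm(best_pairs.n_rows, 2);
  for (arma::uword k = 0; k < best_pairs.n_rows; ++k) {
    pm(k, 0) = best_pairs(k, 0) + 1;
    pm(k, 1) = best_pairs(k, 1) + 1;
  }
  return List::create(Named("pairs") = pm,
                      Named("rotation") = wrap(best_R),
                      Named("centroid_a") = wrap(best_cA),
                      Named("centroid_b") = wrap(best_cB),
                      Named("score") = best_score);
}
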