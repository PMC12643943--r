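// Superposition and TM-score kernels.
//
// These are the inner loops of the structure-comparison module: Kabsch
// superposition, fixed-correspondence TM-score with iterative
// fragment-seeded refinement, cyclic-register (and optional reversal)
// search, and the all-by-all matrix. Compared macrocycles are equal
// length, so the correspondence is an index relabeling, never a
// sequence alignment.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Optimal proper rotation R and centroids such that
// (Y - cY) * R + cX least-squares matches X. Returns squared error sum.
static double kabsch_core(const mat& X, const mat& Y, mat& R,
                          rowvec& cX, rowvec& cY) {
  cX = mean(X, 0);
  cY = mean(Y, 0);
  mat Xc = X.each_row() - cX;
  mat Yc = Y.each_row() - cY;
  mat C = Yc.t() * Xc;          // 3x3 cross-covariance
  mat U, V;
  vec s;
  svd(U, s, V, C);
  double d = det(U * V.t()) < 0 ? -1.0 : 1.0;
  mat D = eye(3, 3);
  D(2, 2) = d;
  R = U * D * V.t();
  double e = accu(square(Xc)) + accu(square(Yc)) -
             2.0 * (s(0) + s(1) + d * s(2));
  return e < 0 ? 0.0 : e;
}

// [[Rcpp::export(name = ".cpp_kabsch")]]
Rcpp::List cpp_kabsch(const arma::mat& X, const arma::mat& Y) {
  mat R;
  rowvec cX, cY;
  kabsch_core(X, Y, R, cX, cY);
  // residual-based rmsd avoids the cancellation error of the
  // singular-value formula near zero
  mat Yt = (Y.each_row() - cY) * R;
  Yt.each_row() += cX;
  double rmsd = std::sqrt(accu(square(X - Yt)) / X.n_rows);
  rowvec t = cX - cY * R;
  return Rcpp::List::create(Rcpp::Named("rotation") = R,
                            Rcpp::Named("translation") = t,
                            Rcpp::Named("rmsd") = rmsd);
}

// TM-score of a fixed correspondence, maximized by iterative
// fragment-seeded superposition refinement: superpose on a seed subset,
// score all residues, refit on the residues currently within the
// distance cutoff, repeat until the subset is stable.
static double tm_fixed(const mat& A, const mat& B, double d0) {
  const uword L = A.n_rows;
  double best = 0.0;
  const double d0sq = d0 * d0;

  std::vector<std::pair<uword, uword>> seeds;
  seeds.push_back({0, L});
  if (L >= 6) {
    seeds.push_back({0, L / 2});
    seeds.push_back({L / 2, L});
    seeds.push_back({L / 4, L / 4 + L / 2});
  }

  for (auto& sd : seeds) {
    uvec sub = regspace<uvec>(sd.first, sd.second - 1);
    for (int it = 0; it < 30; ++it) {
      if (sub.n_elem < 3) break;
      mat R;
      rowvec cX, cY;
      kabsch_core(A.rows(sub), B.rows(sub), R, cX, cY);
      mat Bt = (B.each_row() - cY) * R;
      Bt.each_row() += cX;
      vec dsq = sum(square(A - Bt), 1);
      double sc = accu(1.0 / (1.0 + dsq / d0sq)) / L;
      if (sc > best) best = sc;
      double cut = d0;
      uvec nxt = find(dsq < cut * cut);
      while (nxt.n_elem < 3) {
        cut += 0.5;
        nxt = find(dsq < cut * cut);
      }
      bool same = (nxt.n_elem == sub.n_elem) && arma::all(nxt == sub);
      sub = nxt;
      if (same) break;
    }
  }
  return best;
}

// Search correspondences: cyclic register shifts s (A residue (i+s) mod L
// paired with B residue i) and, optionally, reversal of B's residue
// order. Ties keep the first (lowest shift, unreversed) correspondence.
static void tm_search(const mat& A, const mat& B, double d0,
                      bool cyclic_shift, bool reversal, double& best,
                      int& best_shift, bool& best_rev) {
  const uword L = A.n_rows;
  best = -1.0;
  best_shift = 0;
  best_rev = false;
  int nrev = reversal ? 2 : 1;
  int nshift = cyclic_shift ? (int)L : 1;
  for (int rv = 0; rv < nrev; ++rv) {
    mat Bu = B;
    if (rv == 1) Bu = flipud(B);
    for (int s = 0; s < nshift; ++s) {
      mat As(L, 3);
      for (uword i = 0; i < L; ++i)
        As.row(i) = A.row((i + s) % L);
      double sc = tm_fixed(As, Bu, d0);
      if (sc > best + 1e-12) {
        best = sc;
        best_shift = s;
        best_rev = (rv == 1);
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_tm_score")]]
Rcpp::List cpp_tm_score(const arma::mat& A, const arma::mat& B, double d0,
                        bool cyclic_shift, bool reversal) {
  double best;
  int shift;
  bool rev;
  tm_search(A, B, d0, cyclic_shift, reversal, best, shift, rev);
  return Rcpp::List::create(Rcpp::Named("score") = best,
                            Rcpp::Named("register_shift") = shift,
                            Rcpp::Named("reversed") = rev);
}

// [[Rcpp::export(name = ".cpp_pairwise_tm")]]
arma::mat cpp_pairwise_tm(const Rcpp::List& coords, double d0,
                          bool cyclic_shift, bool reversal) {
  const int n = coords.size();
  std::vector<mat> cs(n);
  for (int i = 0; i < n; ++i)
    cs[i] = Rcpp::as<mat>(coords[i]);
  mat M(n, n, fill::ones);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double best;
      int shift;
      bool rev;
      tm_search(cs[i], cs[j], d0, cyclic_shift, reversal, best, shift, rev);
      M(i, j) = best;
      M(j, i) = best;
    }
  }
  return M;
}
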