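#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Global (Needleman-Wunsch/Gotoh) alignment with affine gaps over an
// arbitrary position-specific score matrix S (la x lb).  A gap of length k
// costs gap_open + (k - 1) * gap_extend; terminal gaps are penalised.
//
// Every consumer of this kernel (residue-residue, residue-profile and
// profile-profile alignment, with or without structural terms) precomputes
// its own S, so one traceback implementation serves the whole package.
//
// Returns list(score, path) where path is an n_steps x 2 integer matrix of
// 1-based indices into the two inputs; 0 marks a gap in that input.
// Traceback tie-break is fixed (match > gap-in-b > gap-in-a) so results are
// deterministic.
// [[Rcpp::export]]
List gotoh_align(NumericMatrix S, double gap_open, double gap_extend) {
  const int la = S.nrow(), lb = S.ncol();
  const double NEG = -1e30;
  const int W = lb + 1;
  std::vector<double> M((la + 1) * W, NEG), X((la + 1) * W, NEG),
      Y((la + 1) * W, NEG);
  // X: gap in b (consumes a); Y: gap in a (consumes b)
  M[0] = 0.0;
  for (int i = 1; i <= la; ++i) X[i * W] = -(gap_open + (i - 1) * gap_extend);
  for (int j = 1; j <= lb; ++j) Y[j] = -(gap_open + (j - 1) * gap_extend);

  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      const int c = i * W + j, d = (i - 1) * W + (j - 1), u = (i - 1) * W + j,
                l = i * W + (j - 1);
      double best = M[d];
      if (X[d] > best) best = X[d];
      if (Y[d] > best) best = Y[d];
      M[c] = (best <= NEG / 2) ? NEG : best + S(i - 1, j - 1);

      double xo = std::max(M[u], Y[u]) - gap_open;
      double xe = X[u] - gap_extend;
      X[c] = xo > xe ? xo : xe;

      double yo = std::max(M[l], X[l]) - gap_open;
      double ye = Y[l] - gap_extend;
      Y[c] = yo > ye ? yo : ye;
    }
  }

  const int end = la * W + lb;
  int state = 0;  // 0 = M, 1 = X, 2 = Y
  double score = M[end];
  if (la == 0 || lb == 0) {
    score = (la == 0 && lb == 0) ? 0.0 : (la == 0 ? Y[end] : X[end]);
    state = (la == 0) ? 2 : 1;
  } else {
    if (X[end] > score) { score = X[end]; state = 1; }
    if (Y[end] > score) { score = Y[end]; state = 2; }
  }

  std::vector<int> ai, bi;
  int i = la, j = lb;
  const double tol = 1e-9;
  while (i > 0 || j > 0) {
    if (i == 0) { ai.push_back(0); bi.push_back(j); --j; continue; }
    if (j == 0) { ai.push_back(i); bi.push_back(0); --i; continue; }
    const int c = i * W + j, d = (i - 1) * W + (j - 1), u = (i - 1) * W + j,
              l = i * W + (j - 1);
    if (state == 0) {
      ai.push_back(i); bi.push_back(j);
      double need = M[c] - S(i - 1, j - 1);
      --i; --j;
      if (std::abs(M[d] - need) < tol) state = 0;
      else if (std::abs(X[d] - need) < tol) state = 1;
      else state = 2;
    } else if (state == 1) {
      ai.push_back(i); bi.push_back(0);
      double cur = X[c];
      --i;
      if (std::abs(M[u] - gap_open - cur) < tol) state = 0;
      else if (std::abs(X[u] - gap_extend - cur) < tol) state = 1;
      else state = 2;  // came from Y with open cost
    } else {
      ai.push_back(0); bi.push_back(j);
      double cur = Y[c];
      --j;
      if (std::abs(M[l] - gap_open - cur) < tol) state = 0;
      else if (std::abs(Y[l] - gap_extend - cur) < tol) state = 2;
      else state = 1;
    }
  }

  const int n = (int)ai.size();
  IntegerMatrix path(n, 2);
  for (int k = 0; k < n; ++k) {
    path(k, 0) = ai[n - 1 - k];
    path(k, 1) = bi[n - 1 - k];
  }
  return List::create(_["score"] = score, _["path"] = path);
}
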