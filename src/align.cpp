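#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh three-state recursion) with optional
// free end gaps ("overlap" mode). A gap of length L costs open + L * extend.
//
// States: M = a[i] aligned to b[j]; X = gap in b (consumes a, "up");
//         Y = gap in a (consumes b, "left").
//
// Traceback is deterministic: among tied predecessors the order of preference
// is diagonal (M), then up (X), then left (Y). The endpoint in overlap mode
// is chosen by scanning the last row left-to-right, then the last column
// top-to-bottom, keeping the first strictly best cell (state order M, X, Y).

static const double NEG_INF = -1e30;
static const double EPS = 1e-9;

// [[Rcpp::export(name = ".align_affine")]]
List align_affine(IntegerVector a, IntegerVector b, NumericMatrix sub,
                  double gap_open, double gap_ext, bool free_ends) {
  const int n = a.size(), m = b.size();
  const double gopen1 = gap_open + gap_ext;  // cost of a length-1 gap

  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);

  M(0, 0) = 0.0;
  X(0, 0) = NEG_INF;
  Y(0, 0) = NEG_INF;
  for (int i = 1; i <= n; ++i) {
    if (free_ends) {
      M(i, 0) = 0.0;           // alignment may start after skipping a[1..i]
      X(i, 0) = NEG_INF;
      Y(i, 0) = NEG_INF;
    } else {
      M(i, 0) = NEG_INF;
      X(i, 0) = -(gap_open + gap_ext * i);
      Y(i, 0) = NEG_INF;
    }
  }
  for (int j = 1; j <= m; ++j) {
    if (free_ends) {
      M(0, j) = 0.0;
      X(0, j) = NEG_INF;
      Y(0, j) = NEG_INF;
    } else {
      M(0, j) = NEG_INF;
      X(0, j) = NEG_INF;
      Y(0, j) = -(gap_open + gap_ext * j);
    }
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = sub(a[i - 1], b[j - 1]);
      double best = M(i - 1, j - 1);
      if (X(i - 1, j - 1) > best) best = X(i - 1, j - 1);
      if (Y(i - 1, j - 1) > best) best = Y(i - 1, j - 1);
      M(i, j) = best + s;

      double xo = M(i - 1, j) - gopen1;
      double xe = X(i - 1, j) - gap_ext;
      X(i, j) = (xo >= xe) ? xo : xe;

      double yo = M(i, j - 1) - gopen1;
      double ye = Y(i, j - 1) - gap_ext;
      Y(i, j) = (yo >= ye) ? yo : ye;
    }
  }

  // endpoint
  int ei = n, ej = m, estate = 0;  // 0 = M, 1 = X, 2 = Y
  double best = NEG_INF;
  if (free_ends) {
    // last row, then last column; state preference M > X > Y
    for (int j = 0; j <= m; ++j) {
      double cand[3] = {M(n, j), X(n, j), Y(n, j)};
      for (int s = 0; s < 3; ++s)
        if (cand[s] > best + EPS) { best = cand[s]; ei = n; ej = j; estate = s; }
    }
    for (int i = 0; i <= n; ++i) {
      double cand[3] = {M(i, m), X(i, m), Y(i, m)};
      for (int s = 0; s < 3; ++s)
        if (cand[s] > best + EPS) { best = cand[s]; ei = i; ej = m; estate = s; }
    }
  } else {
    double cand[3] = {M(n, m), X(n, m), Y(n, m)};
    best = cand[0]; estate = 0;
    for (int s = 1; s < 3; ++s)
      if (cand[s] > best + EPS) { best = cand[s]; estate = s; }
  }

  // traceback
  std::vector<int> qpos, tpos;
  int i = ei, j = ej, state = estate;
  while (true) {
    if (state == 0) {  // M
      if (i == 0 || j == 0) break;  // boundary start cell (overlap) or origin
      qpos.push_back(i - 1);
      tpos.push_back(j - 1);
      double need = M(i, j) - sub(a[i - 1], b[j - 1]);
      // predecessor preference: diagonal M, then up X, then left Y
      if (std::abs(M(i - 1, j - 1) - need) < EPS)      state = 0;
      else if (std::abs(X(i - 1, j - 1) - need) < EPS) state = 1;
      else                                             state = 2;
      --i; --j;
      if (i == 0 && j == 0) break;
      if (state == 0 && (i == 0 || j == 0)) break;
    } else if (state == 1) {  // X: gap in b, move up
      if (i == 0) break;
      if (std::abs(M(i - 1, j) - gopen1 - X(i, j)) < EPS) state = 0;
      --i;
      if (state == 0 && (i == 0 || j == 0)) break;
    } else {  // Y: gap in a, move left
      if (j == 0) break;
      if (std::abs(M(i, j - 1) - gopen1 - Y(i, j)) < EPS) state = 0;
      --j;
      if (state == 0 && (i == 0 || j == 0)) break;
    }
  }

  std::reverse(qpos.begin(), qpos.end());
  std::reverse(tpos.begin(), tpos.end());

  return List::create(_["score"] = best,
                      _["qpos"] = wrap(qpos),   // 0-based query indices
                      _["tpos"] = wrap(tpos));  // 0-based target indices
}

// All-pairs Euclidean distances below are trivial in R; kept there.
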