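// Sparse LDL' factorization, triangular solves, and the Takahashi selected
// inverse used by the AI-REML engine. The input is the upper triangle of a
// symmetric positive-definite matrix in compressed sparse column form,
// already permuted by a fill-reducing ordering. The factorization follows
// the classic up-looking method (elimination tree, then one column of L per
// step); the selected inverse computes the entries of the matrix inverse on
// the pattern of L + D, which is exactly what the REML first derivatives
// need (traces of products of the inverse coefficient matrix with the
// sparse inverse-covariance blocks of the mixed-model equations).

#include <Rcpp.h>
using namespace Rcpp;

// Elimination tree and column counts for the LDL' factor.
// [[Rcpp::export]]
List ldl_symbolic(int n, IntegerVector Ap, IntegerVector Ai) {
  IntegerVector Parent(n), Lnz(n), Flag(n), Lp(n + 1);
  for (int k = 0; k < n; k++) {
    Parent[k] = -1;
    Flag[k] = k;
    Lnz[k] = 0;
    for (int p = Ap[k]; p < Ap[k + 1]; p++) {
      int i = Ai[p];
      if (i < k) {
        for (; Flag[i] != k; i = Parent[i]) {
          if (Parent[i] == -1) Parent[i] = k;
          Lnz[i]++;
          Flag[i] = k;
        }
      }
    }
  }
  Lp[0] = 0;
  for (int k = 0; k < n; k++) Lp[k + 1] = Lp[k] + Lnz[k];
  return List::create(_["Lp"] = Lp, _["Parent"] = Parent);
}

// Numeric factorization with the symbolic structure from ldl_symbolic.
// Returns ok = FALSE when a non-positive pivot is met (matrix not PD).
// [[Rcpp::export]]
List ldl_numeric(int n, IntegerVector Ap, IntegerVector Ai, NumericVector Ax,
                 IntegerVector Lp, IntegerVector Parent) {
  IntegerVector Li(Lp[n]), Lnz(n), Flag(n), Pattern(n);
  NumericVector Lx(Lp[n]), D(n), Y(n);
  for (int k = 0; k < n; k++) {
    Y[k] = 0.0;
    int top = n;
    Flag[k] = k;
    Lnz[k] = 0;
    for (int p = Ap[k]; p < Ap[k + 1]; p++) {
      int i = Ai[p];
      if (i > k) continue;
      Y[i] += Ax[p];
      int len = 0;
      for (; Flag[i] != k; i = Parent[i]) {
        Pattern[len++] = i;
        Flag[i] = k;
      }
      while (len > 0) Pattern[--top] = Pattern[--len];
    }
    D[k] = Y[k];
    Y[k] = 0.0;
    for (; top < n; top++) {
      int i = Pattern[top];
      double yi = Y[i];
      Y[i] = 0.0;
      int p2 = Lp[i] + Lnz[i];
      for (int p = Lp[i]; p < p2; p++) Y[Li[p]] -= Lx[p] * yi;
      double lki = yi / D[i];
      D[k] -= lki * yi;
      Li[p2] = k;
      Lx[p2] = lki;
      Lnz[i]++;
    }
    if (D[k] <= 0.0) {
      return List::create(_["ok"] = false, _["k"] = k);
    }
  }
  return List::create(_["ok"] = true, _["Li"] = Li, _["Lx"] = Lx, _["D"] = D);
}

// Solve (L D L') X = B for multiple right-hand sides (B is overwritten copy).
// [[Rcpp::export]]
NumericMatrix ldl_solve(int n, IntegerVector Lp, IntegerVector Li,
                        NumericVector Lx, NumericVector D, NumericMatrix B) {
  NumericMatrix X = clone(B);
  int nrhs = X.ncol();
  for (int r = 0; r < nrhs; r++) {
    NumericMatrix::Column x = X(_, r);
    for (int j = 0; j < n; j++) {
      double xj = x[j];
      if (xj != 0.0)
        for (int p = Lp[j]; p < Lp[j + 1]; p++) x[Li[p]] -= Lx[p] * xj;
    }
    for (int j = 0; j < n; j++) x[j] /= D[j];
    for (int j = n - 1; j >= 0; j--) {
      double xj = x[j];
      for (int p = Lp[j]; p < Lp[j + 1]; p++) xj -= Lx[p] * x[Li[p]];
      x[j] = xj;
    }
  }
  return X;
}

// Takahashi selected inverse: entries of the inverse of L D L' on the
// pattern of L plus the diagonal, stored lower-triangular CSC with the
// diagonal entry first in every column. Columns are processed from right to
// left; every term in the recurrence stays inside the filled pattern.
// [[Rcpp::export]]
List ldl_takahashi(int n, IntegerVector Lp, IntegerVector Li,
                   NumericVector Lx, NumericVector D) {
  IntegerVector Zp(n + 1), Zi(Lp[n] + n);
  NumericVector Zx(Lp[n] + n);
  Zp[0] = 0;
  for (int j = 0; j < n; j++) {
    Zp[j + 1] = Zp[j] + 1 + (Lp[j + 1] - Lp[j]);
    Zi[Zp[j]] = j;
    for (int p = Lp[j], q = Zp[j] + 1; p < Lp[j + 1]; p++, q++) Zi[q] = Li[p];
  }
  // binary search for entry (row >= col) in column col of Z
  auto zget = [&](int row, int col) -> double {
    int lo = Zp[col], hi = Zp[col + 1] - 1;
    while (lo <= hi) {
      int mid = (lo + hi) / 2;
      if (Zi[mid] == row) return Zx[mid];
      if (Zi[mid] < row) lo = mid + 1; else hi = mid - 1;
    }
    return 0.0;
  };
  for (int j = n - 1; j >= 0; j--) {
    for (int p = Zp[j + 1] - 1; p >= Zp[j]; p--) {
      int i = Zi[p];
      double s = (i == j) ? 1.0 / D[j] : 0.0;
      for (int q = Lp[j]; q < Lp[j + 1]; q++) {
        int k = Li[q];  // k > j
        double zki = (k >= i) ? zget(k, i) : zget(i, k);
        s -= Lx[q] * zki;
      }
      Zx[p] = s;
    }
  }
  return List::create(_["Zp"] = Zp, _["Zi"] = Zi, _["Zx"] = Zx);
}

// Positions (1-based; 0 when absent) of entries (rows[t], cols[t]) with
// rows >= cols in the lower-triangular CSC pattern (Zp, Zi).
// [[Rcpp::export]]
IntegerVector z_positions(IntegerVector Zp, IntegerVector Zi,
                          IntegerVector rows, IntegerVector cols) {
  int m = rows.size();
  IntegerVector out(m);
  for (int t = 0; t < m; t++) {
    int row = rows[t], col = cols[t];
    int lo = Zp[col], hi = Zp[col + 1] - 1, pos = 0;
    while (lo <= hi) {
      int mid = (lo + hi) / 2;
      if (Zi[mid] == row) { pos = mid + 1; break; }
      if (Zi[mid] < row) lo = mid + 1; else hi = mid - 1;
    }
    out[t] = pos;
  }
  return out;
}
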