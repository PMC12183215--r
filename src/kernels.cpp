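#include <Rcpp.h>
using namespace Rcpp;

// Meuwissen-Luo recursion for pedigree inbreeding.
// sire/dam are 1-based indices into a topologically sorted pedigree
// (parents before offspring), 0 = unknown parent.
// [[Rcpp::export(name = ".fped_ml")]]
NumericVector fped_ml(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericVector f(n);
  std::vector<double> d(n), v(n, 0.0);
  for (int i = 0; i < n; ++i) {
    const int s = sire[i], dd = dam[i];
    const double fs = s ? f[s - 1] : 0.0;
    const double fd = dd ? f[dd - 1] : 0.0;
    d[i] = 0.5 - 0.25 * (fs + fd) + 0.25 * ((s == 0) + (dd == 0));
    if (s == 0 || dd == 0) {
      f[i] = 0.0;
      continue;
    }
    // accumulate A_ii = sum v_j^2 d_j over the ancestor closure of i
    v[i] = 1.0;
    double aii = 0.0;
    for (int j = i; j >= 0; --j) {
      const double vj = v[j];
      if (vj == 0.0) continue;
      v[j] = 0.0;
      aii += vj * vj * d[j];
      if (sire[j]) v[sire[j] - 1] += 0.5 * vj;
      if (dam[j])  v[dam[j] - 1]  += 0.5 * vj;
    }
    f[i] = aii - 1.0;
  }
  return f;
}

// Takahashi selected inverse of a sparse SPD matrix given its lower
// Cholesky factor L (C = L L') in compressed sparse column form.
// Returns the entries of C^{-1} on the sparsity pattern of L.
// The pattern of a Cholesky factor is closed under the elimination tree,
// so the recurrences below never reference an entry outside the pattern.
// [[Rcpp::export(name = ".takahashi_inverse")]]
NumericVector takahashi_inverse(IntegerVector Lp, IntegerVector Li,
                                NumericVector Lx, int n) {
  NumericVector Sx(Lx.size());
  const int *lp = INTEGER(Lp.get__()), *li = INTEGER(Li.get__());
  const double *lx = REAL(Lx.get__());
  double *sx = REAL(Sx.get__());
  // acc[i] accumulates sum_k l_kj S[max(i,k), min(i,k)] for i in col j;
  // mark[i] points at i's position inside column j (-1 outside)
  std::vector<double> acc(n, 0.0);
  std::vector<int> mark(n, -1);
  for (int j = n - 1; j >= 0; --j) {
    const int p0 = lp[j], p1 = lp[j + 1];
    if (p0 >= p1 || li[p0] != j)
      stop("Cholesky factor must have an explicit diagonal in every column");
    const double ljj = lx[p0];
    for (int q = p0; q < p1; ++q) mark[li[q]] = q;
    // accumulate over columns b in struct(col j), b > j: every stored
    // S[a, b] with a also in struct(col j) contributes to entries a and b
    for (int q = p0 + 1; q < p1; ++q) {
      const int b = li[q];
      const double lbj = lx[q];
      const int b0 = lp[b], b1 = lp[b + 1];
      for (int r = b0; r < b1; ++r) {
        const int a = li[r];
        const int ma = mark[a];
        if (ma < 0) continue;               // a outside struct(col j)
        const double w = sx[r];
        acc[a] += lbj * w;
        if (a != b) acc[b] += lx[ma] * w;
      }
    }
    for (int q = p1 - 1; q > p0; --q) {
      const int i = li[q];
      sx[q] = -acc[i] / ljj;
    }
    double d = 0.0;
    for (int r = p0 + 1; r < p1; ++r) d += lx[r] * sx[r];
    sx[p0] = 1.0 / (ljj * ljj) - d / ljj;
    for (int q = p0; q < p1; ++q) { mark[li[q]] = -1; acc[li[q]] = 0.0; }
  }
  return Sx;
}

// Fetch entries of the selected inverse by (row, col) pairs (1-based,
// row >= col in the permuted frame); zero when outside the pattern.
// [[Rcpp::export(name = ".sparse_lookup")]]
NumericVector sparse_lookup(IntegerVector Lp, IntegerVector Li,
                            NumericVector Sx, IntegerVector rows,
                            IntegerVector cols) {
  const int m = rows.size();
  NumericVector out(m);
  for (int t = 0; t < m; ++t) {
    const int r = rows[t] - 1, c = cols[t] - 1;
    int lo = Lp[c], hi = Lp[c + 1];
    double val = 0.0;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (Li[mid] < r) lo = mid + 1;
      else if (Li[mid] > r) hi = mid;
      else { val = Sx[mid]; break; }
    }
    out[t] = val;
  }
  return out;
}
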