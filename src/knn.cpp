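#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Distance between two samples over the selected genes, with per-gene
// weights w = 1/sd^2. Standardisation is affine per gene, so only the
// scale enters the Euclidean distance; genes with zero variance get
// weight 0 (they carry no information at that fold).
//
// Neighbour search keeps a running list of the k nearest, ordered by
// (distance, sample index); candidates are visited in ascending index,
// and only a strictly smaller distance displaces an incumbent, which
// realises the documented stable tie-break without a full sort.

struct KNearest {
  int k;
  std::vector<double> d;
  std::vector<int> idx;
  int size;
  explicit KNearest(int k_) : k(k_), d(k_), idx(k_), size(0) {}
  void offer(double dist, int j) {
    int pos;
    if (size < k) {
      pos = size++;
    } else if (dist < d[k - 1]) {
      pos = k - 1;
    } else {
      return;
    }
    while (pos > 0 && dist < d[pos - 1]) {
      d[pos] = d[pos - 1];
      idx[pos] = idx[pos - 1];
      --pos;
    }
    d[pos] = dist;
    idx[pos] = j;
  }
};

static int vote(const KNearest &nn, const IntegerVector &y, int n_class) {
  std::vector<int> counts(n_class, 0);
  for (int i = 0; i < nn.size; ++i) counts[y[nn.idx[i]]]++;
  int best = 0;
  bool tie = false;
  for (int c = 1; c < n_class; ++c) {
    if (counts[c] > counts[best]) { best = c; tie = false; }
    else if (counts[c] == counts[best]) tie = true;
  }
  // ties cannot occur for two classes with odd k; defined anyway:
  // fall back to the label of the single nearest neighbour.
  if (tie) return y[nn.idx[0]];
  return best;
}

// LOOCV predictions for one feature set laid out as an L x n buffer
static void loocv_predict_core(const double *xp, int L, int n,
                               const IntegerVector &y, int k,
                               bool standardize, int n_class, int *pred) {
  std::vector<double> sum(L, 0.0), sumsq(L, 0.0);
  for (int j = 0; j < n; ++j) {
    const double *col = xp + (size_t)j * L;
    for (int g = 0; g < L; ++g) { sum[g] += col[g]; sumsq[g] += col[g] * col[g]; }
  }
  std::vector<double> w(L);
  for (int i = 0; i < n; ++i) {
    const double *xi = xp + (size_t)i * L;
    // per-gene variance over the n-1 samples that remain when i is held out
    for (int g = 0; g < L; ++g) {
      if (!standardize) { w[g] = 1.0; continue; }
      double s = sum[g] - xi[g];
      double ss = sumsq[g] - xi[g] * xi[g];
      double m = s / (n - 1);
      double var = (n >= 3) ? (ss - (n - 1) * m * m) / (n - 2) : 0.0;
      w[g] = (var > 0.0) ? 1.0 / var : 0.0;
    }
    KNearest nn(k);
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double *xj = xp + (size_t)j * L;
      double d = 0.0;
      for (int g = 0; g < L; ++g) {
        double diff = xi[g] - xj[g];
        d += w[g] * diff * diff;
      }
      nn.offer(d, j);
    }
    pred[i] = vote(nn, y, n_class);
  }
}

// [[Rcpp::export]]
IntegerVector loocv_predict_cpp(NumericMatrix X, IntegerVector y, int k,
                                bool standardize) {
  const int L = X.nrow(), n = X.ncol();
  if (k > n - 1) stop("k exceeds the number of training samples");
  int n_class = 0;
  for (int i = 0; i < n; ++i) n_class = std::max(n_class, y[i] + 1);
  IntegerVector pred(n);
  loocv_predict_core(REAL(X), L, n, y, k, standardize, n_class,
                     INTEGER(pred));
  return pred;
}

// Batch LOOCV accuracy for many feature sets over one training matrix.
// V is the full genes x samples matrix; each row of `chrom` holds 1-based
// row indices of one feature set.
// [[Rcpp::export]]
NumericVector loocv_accuracy_batch_cpp(NumericMatrix V, IntegerMatrix chrom,
                                       IntegerVector y, int k,
                                       bool standardize) {
  const int G = V.nrow(), n = V.ncol();
  const int P = chrom.nrow(), L = chrom.ncol();
  if (k > n - 1) stop("k exceeds the number of training samples");
  int n_class = 0;
  for (int i = 0; i < n; ++i) n_class = std::max(n_class, y[i] + 1);
  const double *vp = REAL(V);

  NumericVector out(P);
  std::vector<double> buf((size_t)L * n);
  std::vector<int> pred(n);
  for (int p = 0; p < P; ++p) {
    for (int g = 0; g < L; ++g) {
      int row = chrom(p, g) - 1;
      if (row < 0 || row >= G) stop("chromosome index out of range");
      for (int j = 0; j < n; ++j) buf[(size_t)j * L + g] = vp[(size_t)j * G + row];
    }
    loocv_predict_core(buf.data(), L, n, y, k, standardize, n_class,
                       pred.data());
    int ok = 0;
    for (int i = 0; i < n; ++i) if (pred[i] == y[i]) ok++;
    out[p] = (double)ok / n;
  }
  return out;
}

// [[Rcpp::export]]
double loocv_accuracy_cpp(NumericMatrix X, IntegerVector y, int k,
                          bool standardize) {
  IntegerVector pred = loocv_predict_cpp(X, y, k, standardize);
  const int n = y.size();
  int ok = 0;
  for (int i = 0; i < n; ++i) if (pred[i] == y[i]) ok++;
  return (double)ok / n;
}

// [[Rcpp::export]]
IntegerVector knn_predict_cpp(NumericMatrix X, IntegerVector y,
                              NumericMatrix Q, int k, bool standardize) {
  const int L = X.nrow(), n = X.ncol(), m = Q.ncol();
  if (k > n) stop("k exceeds the number of training samples");
  if (Q.nrow() != L) stop("query and training gene counts differ");
  int n_class = 0;
  for (int i = 0; i < n; ++i) n_class = std::max(n_class, y[i] + 1);
  const double *xp = REAL(X), *qp = REAL(Q);

  std::vector<double> w(L, 1.0);
  if (standardize) {
    for (int g = 0; g < L; ++g) {
      double s = 0.0, ss = 0.0;
      for (int j = 0; j < n; ++j) {
        double v = xp[(size_t)j * L + g];
        s += v; ss += v * v;
      }
      double mu = s / n;
      double var = (n >= 2) ? (ss - n * mu * mu) / (n - 1) : 0.0;
      w[g] = (var > 0.0) ? 1.0 / var : 0.0;
    }
  }

  IntegerVector pred(m);
  for (int q = 0; q < m; ++q) {
    const double *qq = qp + (size_t)q * L;
    KNearest nn(k);
    for (int j = 0; j < n; ++j) {
      const double *xj = xp + (size_t)j * L;
      double d = 0.0;
      for (int g = 0; g < L; ++g) {
        double diff = qq[g] - xj[g];
        d += w[g] * diff * diff;
      }
      nn.offer(d, j);
    }
    pred[q] = vote(nn, y, n_class);
  }
  return pred;
}
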