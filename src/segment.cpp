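#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Optimal piecewise least-squares segmentation of many series sharing one
// design matrix.
//
// Every column of Y is a series observed at the same N time points; X is the
// common N x p design matrix (e.g. intercept + time for a piecewise-linear
// trend, or harmonic sin/cos columns for a piecewise-seasonal model).  For
// each series and each break count k = 0..max_breaks the routine finds, by
// dynamic programming over all admissible segment boundaries, the
// segmentation minimising the total residual sum of squares when each
// segment is fit by OLS on the corresponding rows of X.  Segments must
// contain at least min_seg observations, so break positions lie in
// [min_seg, N - min_seg].  Ties are broken toward the earliest break.
//
// The per-window Gram inverses depend only on X and are precomputed once and
// shared across all series, which is what makes whole-cube processing cheap.
//
// Returns:
//   rss     : npix x (max_breaks+1) matrix, column k+1 = optimal RSS with k breaks
//   breaks  : list of length max_breaks; element k is an npix x k integer
//             matrix of 1-based break positions (last index of each
//             non-final segment), rows sorted increasing.
// [[Rcpp::export(name = ".seg_scan_batch")]]
List seg_scan_batch(const arma::mat& Y, const arma::mat& X,
                    int min_seg, int max_breaks) {
  const int N = X.n_rows;
  const int p = X.n_cols;
  const int npix = Y.n_cols;
  const int K = max_breaks;

  if ((int)Y.n_rows != N) stop("Y and X must have the same number of rows");
  if (min_seg < p + 1) stop("min_seg must exceed the number of regressors");
  if (N < min_seg) stop("series shorter than one minimum segment");

  // cumulative X'X so any window Gram is a difference of two slices
  arma::cube cumXtX(p, p, N + 1, arma::fill::zeros);
  for (int i = 0; i < N; ++i)
    cumXtX.slice(i + 1) = cumXtX.slice(i) + X.row(i).t() * X.row(i);

  // enumerate admissible windows [i, j] (0-based inclusive, length >= min_seg)
  std::vector<int> wstart(N, -1);
  int W = 0;
  for (int i = 0; i + min_seg <= N; ++i) {
    wstart[i] = W;
    W += N - (i + min_seg - 1);
  }
  auto widx = [&](int i, int j) { return wstart[i] + j - (i + min_seg - 1); };

  // flat row-major storage of the per-window Gram inverses
  std::vector<double> winInv((size_t)W * p * p);
  for (int i = 0; i + min_seg <= N; ++i) {
    for (int j = i + min_seg - 1; j < N; ++j) {
      arma::mat G = cumXtX.slice(j + 1) - cumXtX.slice(i);
      arma::mat Gi;
      if (!arma::inv_sympd(Gi, G)) Gi = arma::pinv(G);
      double* dst = &winInv[(size_t)widx(i, j) * p * p];
      for (int a = 0; a < p; ++a)
        for (int b = 0; b < p; ++b) dst[a * p + b] = Gi(a, b);
    }
  }

  arma::mat rss_out(npix, K + 1);
  std::vector<IntegerMatrix> brk_out;
  for (int k = 1; k <= K; ++k) brk_out.push_back(IntegerMatrix(npix, k));

  const double BIG = std::numeric_limits<double>::max() / 4.0;
  arma::vec cost(W);
  arma::mat cumXy(p, N + 1);
  arma::vec cumyy(N + 1);
  arma::mat F(K + 2, N + 1);
  arma::imat arg(K + 2, N + 1);

  std::vector<double> v(p);
  for (int px = 0; px < npix; ++px) {
    // per-series cumulative moments
    cumXy.col(0).zeros();
    cumyy(0) = 0.0;
    for (int i = 0; i < N; ++i) {
      double y = Y(i, px);
      for (int a = 0; a < p; ++a) cumXy(a, i + 1) = cumXy(a, i) + X(i, a) * y;
      cumyy(i + 1) = cumyy(i) + y * y;
    }
    // window costs: rss = y'y - v' G^{-1} v with v = window X'y
    const double* cXy = cumXy.memptr();  // column-major p x (N+1)
    for (int i = 0; i + min_seg <= N; ++i) {
      const double* ci = cXy + (size_t)i * p;
      double* cw = cost.memptr() + wstart[i] - (i + min_seg - 1);
      const double* inv0 = &winInv[(size_t)(wstart[i] -
                                            (i + min_seg - 1)) * p * p];
      for (int j = i + min_seg - 1; j < N; ++j) {
        const double* cj = cXy + (size_t)(j + 1) * p;
        for (int a = 0; a < p; ++a) v[a] = cj[a] - ci[a];
        const double* inv = inv0 + (size_t)j * p * p;
        double quad = 0.0;
        for (int a = 0; a < p; ++a) {
          double s = 0.0;
          const double* row = inv + a * p;
          for (int b = 0; b < p; ++b) s += row[b] * v[b];
          quad += v[a] * s;
        }
        double r = (cumyy(j + 1) - cumyy(i)) - quad;
        cw[j] = r > 0.0 ? r : 0.0;
      }
    }
    // DP over segment counts s = 1..K+1; F(s, j) = best RSS for first j obs
    F.fill(BIG);
    arg.fill(-1);
    for (int j = min_seg; j <= N; ++j) F(1, j) = cost(widx(0, j - 1));
    for (int s = 2; s <= K + 1; ++s) {
      int jlo = s * min_seg;
      // only the final prefix length N is needed at the top level s = K+1,
      // but intermediate s feeds every longer s, so fill the full range
      for (int j = jlo; j <= N; ++j) {
        double best = BIG;
        int bestb = -1;
        for (int b = (s - 1) * min_seg; b <= j - min_seg; ++b) {
          double cand = F(s - 1, b) + cost(widx(b, j - 1));
          if (cand < best) {  // strict: earliest boundary wins ties
            best = cand;
            bestb = b;
          }
        }
        F(s, j) = best;
        arg(s, j) = bestb;
      }
    }
    for (int k = 0; k <= K; ++k) {
      if ((k + 1) * min_seg > N) {
        rss_out(px, k) = NA_REAL;
        if (k >= 1)
          for (int q = 0; q < k; ++q) brk_out[k - 1](px, q) = NA_INTEGER;
        continue;
      }
      rss_out(px, k) = F(k + 1, N);
      if (k >= 1) {
        int j = N;
        for (int s = k + 1; s >= 2; --s) {
          int b = arg(s, j);
          brk_out[k - 1](px, s - 2) = b;  // b is already a 1-based position
          j = b;
        }
      }
    }
  }

  List brks(K);
  for (int k = 1; k <= K; ++k) brks[k - 1] = brk_out[k - 1];
  return List::create(_["rss"] = rss_out, _["breaks"] = brks);
}
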