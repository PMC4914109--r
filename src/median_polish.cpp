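#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// median of a buffer (midpoint convention for even length); scrambles buf
static double med(std::vector<double> &buf) {
  const size_t n = buf.size();
  const size_t h = n / 2;
  std::nth_element(buf.begin(), buf.begin() + h, buf.end());
  double m = buf[h];
  if (n % 2 == 0) {
    double lo = *std::max_element(buf.begin(), buf.begin() + h);
    m = (m + lo) / 2.0;
  }
  return m;
}

// Alternating column/row median sweeps on a column-major nr x nc buffer,
// without effect tracking.  Columns are swept first so that a constant
// added to any sample (column) is removed wholesale in the very first
// sweep, making the residuals exactly invariant to per-sample shifts.
// Convergence: every row and column median of the residuals is <= tol in
// absolute value.  Returns iterations used, negated when not converged.
static int polish_residuals(std::vector<double> &r, int nr, int nc,
                            double tol, int max_iter) {
  std::vector<double> rowbuf(nc), colbuf(nr);
  int iter = 0;
  bool converged = false;
  while (iter < max_iter) {
    ++iter;
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) colbuf[i] = r[i + j * nr];
      double m = med(colbuf);
      for (int i = 0; i < nr; ++i) r[i + j * nr] -= m;
    }
    for (int i = 0; i < nr; ++i) {
      for (int j = 0; j < nc; ++j) rowbuf[j] = r[i + j * nr];
      double m = med(rowbuf);
      for (int j = 0; j < nc; ++j) r[i + j * nr] -= m;
    }
    double mx = 0.0;
    for (int i = 0; i < nr; ++i) {
      for (int j = 0; j < nc; ++j) rowbuf[j] = r[i + j * nr];
      mx = std::max(mx, std::fabs(med(rowbuf)));
    }
    if (mx <= tol) {
      for (int j = 0; j < nc && mx <= tol; ++j) {
        for (int i = 0; i < nr; ++i) colbuf[i] = r[i + j * nr];
        mx = std::max(mx, std::fabs(med(colbuf)));
      }
      if (mx <= tol) { converged = true; break; }
    }
  }
  return converged ? iter : -iter;
}

// Tukey median polish with effect tracking.  The additive identity
//   y = overall + alpha[row] + beta[col] + residual
// holds exactly at every iteration; columns are swept first (see
// polish_residuals) so residuals are exactly invariant to per-sample
// constant shifts; convergence as in polish_residuals.
// [[Rcpp::export(name = ".median_polish_cpp")]]
List median_polish_cpp(NumericMatrix y, double tol, int max_iter) {
  const int nr = y.nrow(), nc = y.ncol();
  NumericMatrix r(clone(y));
  NumericVector alpha(nr), beta(nc);
  double overall = 0.0;
  std::vector<double> rowbuf(nc), colbuf(nr), effbuf;
  bool converged = false;
  int iter = 0;

  while (iter < max_iter) {
    ++iter;
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) colbuf[i] = r(i, j);
      double m = med(colbuf);
      beta[j] += m;
      for (int i = 0; i < nr; ++i) r(i, j) -= m;
    }
    effbuf.assign(alpha.begin(), alpha.end());
    double am = med(effbuf);
    for (int i = 0; i < nr; ++i) alpha[i] -= am;
    overall += am;
    for (int i = 0; i < nr; ++i) {
      for (int j = 0; j < nc; ++j) rowbuf[j] = r(i, j);
      double m = med(rowbuf);
      alpha[i] += m;
      for (int j = 0; j < nc; ++j) r(i, j) -= m;
    }
    effbuf.assign(beta.begin(), beta.end());
    double bm = med(effbuf);
    for (int j = 0; j < nc; ++j) beta[j] -= bm;
    overall += bm;

    double mx = 0.0;
    for (int i = 0; i < nr; ++i) {
      for (int j = 0; j < nc; ++j) rowbuf[j] = r(i, j);
      mx = std::max(mx, std::fabs(med(rowbuf)));
    }
    if (mx <= tol) {
      for (int j = 0; j < nc && mx <= tol; ++j) {
        for (int i = 0; i < nr; ++i) colbuf[i] = r(i, j);
        mx = std::max(mx, std::fabs(med(colbuf)));
      }
      if (mx <= tol) { converged = true; break; }
    }
  }
  return List::create(_["overall"] = overall, _["alpha"] = alpha,
                      _["beta"] = beta, _["residuals"] = r,
                      _["converged"] = converged, _["iterations"] = iter);
}

// Resampled MUF null by sample-label permutation over intact genes.
// `resid` stacks the residual matrices of every gene with `n_probes`
// probes (so it has n_genes * n_probes rows); `gene_start` holds each
// gene's 0-based first row.  A pseudo-gene picks one gene uniformly and a
// random reassignment of its nA + nB sample columns into pseudo-groups,
// then reduces each probe to median(pseudo-A) - median(pseudo-B) and
// scores the prefix (or window) MUF.  Median-polish residuals are
// invariant to column permutation, so under within-gene sample
// exchangeability these draws have exactly the null distribution of the
// observed statistic — no re-fit and no scale estimate is needed.
// Uses R's RNG.
// [[Rcpp::export(name = ".null_mufs_permutation_cpp")]]
NumericVector null_mufs_permutation(NumericMatrix resid,
                                    IntegerVector gene_start, int n_probes,
                                    int nA, int nB, int draws, bool window) {
  const int n_genes = gene_start.size();
  const int nc = nA + nB;
  if (resid.ncol() != nc) stop("residual columns must equal nA + nB");
  NumericVector out(draws);
  std::vector<double> bufA(nA), bufB(nB);
  std::vector<int> idx(nc);
  for (int b = 0; b < draws; ++b) {
    const int g = (int)(unif_rand() * n_genes) % n_genes;
    const int start = gene_start[g];
    for (int j = 0; j < nc; ++j) idx[j] = j;
    for (int j = nc - 1; j > 0; --j) {
      int k = (int)(unif_rand() * (j + 1)) % (j + 1);
      std::swap(idx[j], idx[k]);
    }
    double s = 0.0, mx = 0.0, mn = 0.0, mxabs = 0.0;
    for (int p = 0; p < n_probes; ++p) {
      for (int j = 0; j < nA; ++j) bufA[j] = resid(start + p, idx[j]);
      for (int j = 0; j < nB; ++j) bufB[j] = resid(start + p, idx[nA + j]);
      s += med(bufA) - med(bufB);
      if (s > mx) mx = s;
      if (s < mn) mn = s;
      if (std::fabs(s) > mxabs) mxabs = std::fabs(s);
    }
    out[b] = window ? (mx - mn) : mxabs;
  }
  return out;
}

// Resampling scheme for a pool of residual *differences*: pseudo-gene
// probes draw d values directly (no model re-fit; conservative when the
// pool carries real signal or when the observed d vectors are
// sum-constrained by the per-gene fit).
// [[Rcpp::export(name = ".null_mufs_differences_cpp")]]
NumericVector null_mufs_differences(NumericVector pool, int n_probes,
                                    int draws, bool window) {
  const int len = pool.size();
  NumericVector out(draws);
  for (int b = 0; b < draws; ++b) {
    double s = 0.0, mx = 0.0, mn = 0.0, mxabs = 0.0;
    for (int p = 0; p < n_probes; ++p) {
      s += pool[(int)(unif_rand() * len) % len];
      if (s > mx) mx = s;
      if (s < mn) mn = s;
      if (std::fabs(s) > mxabs) mxabs = std::fabs(s);
    }
    out[b] = window ? (mx - mn) : mxabs;
  }
  return out;
}
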