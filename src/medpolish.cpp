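#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Median of a small buffer (midpoint rule for even n, as stats::median).
static double med(std::vector<double>& buf) {
  const size_t n = buf.size();
  std::vector<double> v(buf);
  const size_t h = n / 2;
  std::nth_element(v.begin(), v.begin() + h, v.end());
  double m = v[h];
  if (n % 2 == 0) {
    double lo = *std::max_element(v.begin(), v.begin() + h);
    m = (m + lo) / 2.0;
  }
  return m;
}

// Tukey median polish of one probe block (k probes x n arrays), following the
// iteration of stats::medpolish: alternate row and column median sweeps until
// the sum of absolute residuals changes by less than eps (relative) or maxiter
// is reached. Returns the array summaries overall + column effect.
static void polish_block(const NumericMatrix& x, const std::vector<int>& rows,
                         int ncol, double eps, int maxiter,
                         double* summary_out, double* resid_out) {
  const int k = (int)rows.size();
  std::vector<double> z((size_t)k * ncol);
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < ncol; ++j)
      z[(size_t)i * ncol + j] = x(rows[i], j);

  std::vector<double> r(k, 0.0), c(ncol, 0.0);
  double t = 0.0, oldsum = 0.0;
  std::vector<double> rowbuf(ncol), colbuf(k);

  for (int iter = 0; iter < maxiter; ++iter) {
    // row sweep
    for (int i = 0; i < k; ++i) {
      for (int j = 0; j < ncol; ++j) rowbuf[j] = z[(size_t)i * ncol + j];
      double d = med(rowbuf);
      for (int j = 0; j < ncol; ++j) z[(size_t)i * ncol + j] -= d;
      r[i] += d;
    }
    { std::vector<double> cb(c); double d = med(cb);
      for (int j = 0; j < ncol; ++j) c[j] -= d; t += d; }
    // column sweep
    for (int j = 0; j < ncol; ++j) {
      for (int i = 0; i < k; ++i) colbuf[i] = z[(size_t)i * ncol + j];
      double d = med(colbuf);
      for (int i = 0; i < k; ++i) z[(size_t)i * ncol + j] -= d;
      c[j] += d;
    }
    { std::vector<double> rb(r); double d = med(rb);
      for (int i = 0; i < k; ++i) r[i] -= d; t += d; }

    double newsum = 0.0;
    for (size_t q = 0; q < z.size(); ++q) newsum += std::fabs(z[q]);
    bool converged = (newsum == 0.0) || (std::fabs(newsum - oldsum) < eps * newsum);
    if (converged) break;
    oldsum = newsum;
  }
  for (int j = 0; j < ncol; ++j) summary_out[j] = t + c[j];
  if (resid_out)
    for (int i = 0; i < k; ++i)
      for (int j = 0; j < ncol; ++j)
        resid_out[(size_t)i * ncol + j] = z[(size_t)i * ncol + j];
}

// [[Rcpp::export(name = ".medpolish_groups")]]
List medpolish_groups(NumericMatrix x, IntegerVector group, int ngroups,
                      double eps, int maxiter, bool residuals) {
  const int ncol = x.ncol(), nrow = x.nrow();
  std::vector<std::vector<int> > rows((size_t)ngroups);
  for (int i = 0; i < nrow; ++i) {
    int g = group[i] - 1;
    if (g < 0 || g >= ngroups) stop("group index out of range");
    rows[g].push_back(i);
  }
  NumericMatrix summaries(ngroups, ncol);
  NumericMatrix resid = residuals ? NumericMatrix(nrow, ncol) : NumericMatrix(0, 0);
  std::vector<double> rbuf;
  for (int g = 0; g < ngroups; ++g) {
    if (rows[g].empty()) {
      for (int j = 0; j < ncol; ++j) summaries(g, j) = NA_REAL;
      continue;
    }
    if (rows[g].size() == 1) {  // single probe: the summary is the probe row
      int i = rows[g][0];
      for (int j = 0; j < ncol; ++j) summaries(g, j) = x(i, j);
      if (residuals) for (int j = 0; j < ncol; ++j) resid(i, j) = 0.0;
      continue;
    }
    rbuf.assign(rows[g].size() * (size_t)ncol, 0.0);
    std::vector<double> sbuf(ncol);
    polish_block(x, rows[g], ncol, eps, maxiter, sbuf.data(),
                 residuals ? rbuf.data() : (double*)0);
    for (int j = 0; j < ncol; ++j) summaries(g, j) = sbuf[j];
    if (residuals)
      for (size_t ii = 0; ii < rows[g].size(); ++ii)
        for (int j = 0; j < ncol; ++j)
          resid(rows[g][ii], j) = rbuf[ii * (size_t)ncol + j];
  }
  return List::create(_["summaries"] = summaries, _["residuals"] = resid);
}
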