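#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Two-sided Mann-Whitney test on complete data.
// Exact null distribution (via pwilcox) when both samples have <= 8
// observations and no ties occur; otherwise normal approximation with
// midranks, tie-corrected variance and continuity correction. U is
// reported for the first sample.
static void mw_core(const std::vector<double>& x, const std::vector<double>& y,
                    double& U, double& p) {
  const int n1 = (int)x.size(), n2 = (int)y.size(), N = n1 + n2;
  std::vector<double> v;
  v.reserve(N);
  v.insert(v.end(), x.begin(), x.end());
  v.insert(v.end(), y.begin(), y.end());
  std::vector<int> ord(N);
  for (int i = 0; i < N; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return v[a] < v[b]; });

  std::vector<double> rank(N);
  bool ties = false;
  double tiesum = 0.0;  // sum over tie groups of t^3 - t
  int i = 0;
  while (i < N) {
    int j = i;
    while (j + 1 < N && v[ord[j + 1]] == v[ord[i]]) ++j;
    const double r = 0.5 * (i + j) + 1.0;  // midrank
    const int t = j - i + 1;
    if (t > 1) {
      ties = true;
      tiesum += (double)t * t * t - t;
    }
    for (int k = i; k <= j; ++k) rank[ord[k]] = r;
    i = j + 1;
  }

  double R1 = 0.0;
  for (int k = 0; k < n1; ++k) R1 += rank[k];
  U = R1 - n1 * (n1 + 1.0) / 2.0;

  if (n1 <= 8 && n2 <= 8 && !ties) {
    const double half = n1 * (double)n2 / 2.0;
    if (U > half) {
      p = 2.0 * ::R::pwilcox(U - 1.0, n1, n2, 0, 0);
    } else {
      p = 2.0 * ::R::pwilcox(U, n1, n2, 1, 0);
    }
    if (p > 1.0) p = 1.0;
    return;
  }

  const double mu = n1 * (double)n2 / 2.0;
  double sigma2 = (n1 * (double)n2 / 12.0) *
    ((N + 1.0) - tiesum / ((double)N * (N - 1.0)));
  if (sigma2 <= 0.0) {  // all observations tied
    p = 1.0;
    return;
  }
  double z = U - mu;
  const double corr = (z > 0) - (z < 0);  // sign
  z = (z - 0.5 * corr) / std::sqrt(sigma2);
  p = 2.0 * ::R::pnorm(-std::fabs(z), 0.0, 1.0, 1, 0);
  if (p > 1.0) p = 1.0;
}

// [[Rcpp::export]]
NumericVector mw_test_cpp(NumericVector x, NumericVector y) {
  std::vector<double> xs, ys;
  for (double xi : x) if (R_finite(xi)) xs.push_back(xi);
  for (double yi : y) if (R_finite(yi)) ys.push_back(yi);
  if (xs.empty() || ys.empty()) stop("both samples need >= 1 observation");
  double U, p;
  mw_core(xs, ys, U, p);
  return NumericVector::create(_["U"] = U, _["p"] = p);
}

static double median_of(std::vector<double>& w) {
  if (w.empty()) return NA_REAL;
  const size_t n = w.size(), h = n / 2;
  std::nth_element(w.begin(), w.begin() + h, w.end());
  double hi = w[h];
  if (n % 2 == 1) return hi;
  std::nth_element(w.begin(), w.begin() + h - 1, w.begin() + h);
  return 0.5 * (hi + w[h - 1]);
}

// Bootstrap Mann-Whitney over all metabolites: per iteration draw
// `resample` rows from each group (with replacement by default), run the
// test per metabolite on observed values only, record (U, p); report
// per-metabolite medians. A metabolite with an empty observed sample in a
// resample contributes p = 1 (conservative) and U = NA to that iteration.
// Uses R's RNG: seed with set.seed() before calling.
// [[Rcpp::export]]
List boot_mw_cpp(NumericMatrix case_m, NumericMatrix ctrl_m, int n_boot,
                 int resample, bool replace, bool keep) {
  const int nx = case_m.nrow(), ny = ctrl_m.nrow(), m = case_m.ncol();
  if (ctrl_m.ncol() != m) stop("metabolite columns differ between groups");
  if (!replace && (resample > nx || resample > ny))
    stop("resample size exceeds a group size (without replacement)");

  NumericMatrix Us, Ps;
  if (keep) {
    Us = NumericMatrix(n_boot, m);
    Ps = NumericMatrix(n_boot, m);
  }
  std::vector<std::vector<double>> pall(m), uall(m);
  for (int j = 0; j < m; ++j) {
    pall[j].reserve(n_boot);
    uall[j].reserve(n_boot);
  }

  std::vector<int> ix(resample), iy(resample);
  std::vector<int> permx(nx), permy(ny);
  std::vector<double> xs, ys;
  xs.reserve(resample);
  ys.reserve(resample);

  for (int b = 0; b < n_boot; ++b) {
    if (replace) {
      for (int k = 0; k < resample; ++k) {
        ix[k] = (int)(unif_rand() * nx) % nx;
        iy[k] = (int)(unif_rand() * ny) % ny;
      }
    } else {
      for (int k = 0; k < nx; ++k) permx[k] = k;
      for (int k = 0; k < ny; ++k) permy[k] = k;
      for (int k = 0; k < resample; ++k) {
        int r = k + (int)(unif_rand() * (nx - k)) % (nx - k ? (nx - k) : 1);
        std::swap(permx[k], permx[r]);
        ix[k] = permx[k];
        r = k + (int)(unif_rand() * (ny - k)) % (ny - k ? (ny - k) : 1);
        std::swap(permy[k], permy[r]);
        iy[k] = permy[k];
      }
    }
    for (int j = 0; j < m; ++j) {
      xs.clear();
      ys.clear();
      for (int k = 0; k < resample; ++k) {
        const double xv = case_m(ix[k], j);
        if (R_finite(xv)) xs.push_back(xv);
        const double yv = ctrl_m(iy[k], j);
        if (R_finite(yv)) ys.push_back(yv);
      }
      double U = NA_REAL, p = 1.0;
      if (!xs.empty() && !ys.empty()) mw_core(xs, ys, U, p);
      pall[j].push_back(p);
      if (!ISNAN(U)) uall[j].push_back(U);
      if (keep) {
        Us(b, j) = U;
        Ps(b, j) = p;
      }
    }
  }

  NumericVector medU(m), medP(m);
  for (int j = 0; j < m; ++j) {
    medU[j] = median_of(uall[j]);
    medP[j] = median_of(pall[j]);
  }
  List out = List::create(_["median_U"] = medU, _["median_p"] = medP);
  if (keep) {
    out["U"] = Us;
    out["p"] = Ps;
  }
  return out;
}
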