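#include <Rcpp.h>
using namespace Rcpp;

// Hartigan & Hartigan's dip statistic of unimodality.
//
// D = min over unimodal CDFs U of sup_x |F_n(x) - U(x)|, computed by the
// greatest-convex-minorant / least-concave-majorant modal-interval scheme:
// iteratively shrink the candidate modal interval [low, high]; the largest
// gap between the GCM and LCM inside the interval forces further shrinking,
// whose price is the deviation of the ECDF from the hulls on the parts cut
// off.  All bookkeeping is in "count" units (ECDF heights 0..n); the result
// is divided by 2n at the end (a band of half the max deviation suffices).
//
// Conventions (x sorted ascending, 1-based index j):
//  - the ECDF occupies heights [j-1, j] at x_j;
//  - the GCM touches (x_j, j-1) (it must stay below the left limits), the
//    LCM touches (x_j, j);
//  - deviation of the ECDF above a GCM chord anchored at touchpoints jb<je:
//      (j - jb + 1) - (x_j - x_jb) * (je - jb)/(x_je - x_jb)
//  - deviation below an LCM chord: (x_j - x_jb)*C - (j - jb - 1).

static double gcm_dev(const NumericVector& x, int jb, int je) {
  // max deviation of ECDF above the GCM chord [jb, je] (1-based, jb < je)
  double dev = 1.0;
  if (je - jb > 1 && x[je - 1] > x[jb - 1]) {
    double C = (double)(je - jb) / (x[je - 1] - x[jb - 1]);
    for (int j = jb + 1; j < je; ++j) {
      double t = (j - jb + 1) - (x[j - 1] - x[jb - 1]) * C;
      if (t > dev) dev = t;
    }
  }
  return dev;
}

static double lcm_dev(const NumericVector& x, int jb, int je) {
  // max deviation of ECDF below the LCM chord [jb, je]
  double dev = 1.0;
  if (je - jb > 1 && x[je - 1] > x[jb - 1]) {
    double C = (double)(je - jb) / (x[je - 1] - x[jb - 1]);
    for (int j = jb + 1; j < je; ++j) {
      double t = (x[j - 1] - x[jb - 1]) * C - (j - jb - 1);
      if (t > dev) dev = t;
    }
  }
  return dev;
}

// [[Rcpp::export(name = ".dip_stat_cpp")]]
double dip_stat_cpp(NumericVector xs) {
  const int n = xs.size();
  if (n < 1) stop("empty sample");
  NumericVector x = clone(xs).sort();
  if (n == 1 || x[n - 1] == x[0]) return 0.0;  // degenerate: point mass
  if (n <= 3) return 1.0 / (2.0 * n);

  // Convex-minorant predecessor links over the whole range: mn[j] is the
  // previous touchpoint of the GCM of points (x_1..x_j); mirrored for mj.
  std::vector<int> mn(n + 1), mj(n + 2);
  mn[1] = 1;
  for (int j = 2; j <= n; ++j) {
    mn[j] = j - 1;
    for (;;) {
      int mnj = mn[j], mnmnj = mn[mnj];
      if (mnj == 1 ||
          (x[j - 1] - x[mnj - 1]) * (mnj - mnmnj) <
              (x[mnj - 1] - x[mnmnj - 1]) * (j - mnj))
        break;
      mn[j] = mnmnj;
    }
  }
  mj[n] = n;
  for (int k = n - 1; k >= 1; --k) {
    mj[k] = k + 1;
    for (;;) {
      int mjk = mj[k], mjmjk = mj[mjk];
      if (mjk == n ||
          (x[k - 1] - x[mjk - 1]) * (mjk - mjmjk) <
              (x[mjk - 1] - x[mjmjk - 1]) * (k - mjk))
        break;
      mj[k] = mjmjk;
    }
  }

  int low = 1, high = n;
  double dip = 1.0;  // count units; lower bound 1/(2n) after scaling

  std::vector<int> gcm, lcm;  // touchpoints, ascending
  for (int iter = 0; iter < 4 * n + 16; ++iter) {
    // touchpoints of the GCM of [low, high], collected high -> low
    gcm.clear();
    for (int j = high; j > low; j = mn[j]) {
      gcm.push_back(j);
      if (mn[j] >= j) stop("internal error: GCM links not decreasing");
    }
    gcm.push_back(low);
    std::reverse(gcm.begin(), gcm.end());
    lcm.clear();
    for (int j = low; j < high; j = mj[j]) {
      lcm.push_back(j);
      if (mj[j] <= j) stop("internal error: LCM links not increasing");
    }
    lcm.push_back(high);

    // largest GCM-LCM gap inside [low, high], with the modal subinterval
    // [new_low, new_high] that brackets it
    double d = 1.0;
    int new_low = low, new_high = high;
    if ((int)gcm.size() > 2 || (int)lcm.size() > 2) {
      // gaps at LCM touchpoints, measured to the GCM chord covering them
      size_t ix = 0;
      for (size_t iv = 1; iv + 1 < lcm.size(); ++iv) {
        int p = lcm[iv];
        while (ix + 1 < gcm.size() && gcm[ix + 1] < p) ++ix;
        int jb = gcm[ix], je = gcm[ix + 1];  // jb <= p <= je
        double C = (double)(je - jb) / (x[je - 1] - x[jb - 1]);
        double gap = (p - jb + 1) - (x[p - 1] - x[jb - 1]) * C;
        if (gap > d) { d = gap; new_low = jb; new_high = p; }
      }
      // gaps at GCM touchpoints, measured to the LCM chord covering them
      size_t iv = 0;
      for (size_t ig = 1; ig + 1 < gcm.size(); ++ig) {
        int p = gcm[ig];
        while (iv + 1 < lcm.size() && lcm[iv + 1] < p) ++iv;
        int jb = lcm[iv], je = lcm[iv + 1];
        double C = (double)(je - jb) / (x[je - 1] - x[jb - 1]);
        double gap = (x[p - 1] - x[jb - 1]) * C - (p - jb - 1);
        if (gap > d) { d = gap; new_low = p; new_high = je; }
      }
    }

    if (d <= dip) break;

    // price of excluding [low, new_low] (GCM side) and [new_high, high]
    double dl = 1.0, du = 1.0;
    for (size_t i = 0; i + 1 < gcm.size() && gcm[i + 1] <= new_low; ++i) {
      double t = gcm_dev(x, gcm[i], gcm[i + 1]);
      if (t > dl) dl = t;
    }
    for (size_t i = 0; i + 1 < lcm.size(); ++i) {
      if (lcm[i] >= new_high) {
        double t = lcm_dev(x, lcm[i], lcm[i + 1]);
        if (t > du) du = t;
      }
    }
    if (dl > dip) dip = dl;
    if (du > dip) dip = du;

    if (new_low == low && new_high == high) break;  // no progress
    low = new_low;
    high = new_high;
  }

  return dip / (2.0 * n);
}

// Dips of n_boot uniform(0,1) samples of size n (bootstrap null for the
// dip test).  Uses R's RNG so results are reproducible via set.seed().
// [[Rcpp::export(name = ".dip_null_cpp")]]
NumericVector dip_null_cpp(int n, int n_boot) {
  NumericVector out(n_boot);
  for (int b = 0; b < n_boot; ++b) {
    NumericVector u = runif(n);
    out[b] = dip_stat_cpp(u);
  }
  return out;
}
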