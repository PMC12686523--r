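// Hartigan & Hartigan's dip statistic: the maximum distance between the
// empirical CDF and the closest unimodal CDF. Computed by the published
// iterative construction: on the current modal interval, build the
// greatest convex minorant (GCM, through the lower step corners
// (x_j, (j-1)/n)) and the least concave majorant (LCM, through the upper
// corners (x_j, j/n)); if their maximal vertical gap d no longer exceeds
// the best one-sided deviation D found so far, stop with dip = D/(2n);
// otherwise record the deviations of the empirical CDF above the GCM left
// of the gap and below the LCM right of it, shrink the modal interval to
// the hull touch points bracketing the gap, and iterate. All internal
// quantities are in count units (multiples of 1/n).

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// lower convex hull indices of (x[j], y0 + j) for j in [lo, hi] (0-based)
static void lower_hull(const std::vector<double> &x, int lo, int hi,
                       double y_off, std::vector<int> &hull) {
  hull.clear();
  for (int j = lo; j <= hi; ++j) {
    double yj = j + y_off;
    while (hull.size() >= 2) {
      int a = hull[hull.size() - 2], b = hull[hull.size() - 1];
      double cross = (x[b] - x[a]) * (yj - (a + y_off)) -
                     (b - a) * (x[j] - x[a]);
      if (cross <= 0) hull.pop_back(); else break;
    }
    hull.push_back(j);
  }
}

// upper concave hull indices of (x[j], y0 + j)
static void upper_hull(const std::vector<double> &x, int lo, int hi,
                       double y_off, std::vector<int> &hull) {
  hull.clear();
  for (int j = lo; j <= hi; ++j) {
    double yj = j + y_off;
    while (hull.size() >= 2) {
      int a = hull[hull.size() - 2], b = hull[hull.size() - 1];
      double cross = (x[b] - x[a]) * (yj - (a + y_off)) -
                     (b - a) * (x[j] - x[a]);
      if (cross >= 0) hull.pop_back(); else break;
    }
    hull.push_back(j);
  }
}

// evaluate the piecewise-linear hull curve at every index in [lo, hi];
// curve[j - lo] = hull value at x[j]. Vertical pieces (tied x) take the
// touch-point value nearer the curve's own side (lower for GCM, upper for
// LCM), which is where the deviations are measured.
static void eval_curve(const std::vector<double> &x,
                       const std::vector<int> &hull, double y_off, int lo,
                       int hi, bool lower, std::vector<double> &curve) {
  curve.assign(hi - lo + 1, 0.0);
  for (size_t s = 0; s + 1 < hull.size(); ++s) {
    int a = hull[s], b = hull[s + 1];
    double ya = a + y_off, yb = b + y_off;
    double dx = x[b] - x[a];
    for (int j = a; j <= b; ++j) {
      double v;
      if (dx > 0)
        v = ya + (yb - ya) * (x[j] - x[a]) / dx;
      else
        v = lower ? ya : yb;
      curve[j - lo] = v;
    }
  }
  if (hull.size() == 1) curve[hull[0] - lo] = hull[0] + y_off;
}

static double dip_sorted(const std::vector<double> &x) {
  const int n = static_cast<int>(x.size()); // 0-based x[0..n-1]
  if (n < 4) stop("dip statistic needs at least 4 observations");
  if (x[n - 1] == x[0])
    stop("dip statistic undefined for a sample with no spread");

  int low = 0, high = n - 1;
  double D = 1.0; // count units; 1/(2n) after final scaling
  std::vector<int> gh, lh;
  std::vector<double> gc, lc;

  for (;;) {
    if (high - low < 1 || x[high] == x[low]) break;
    // GCM through (x_j, j) with F-lower offset 0 (j is 0-based: y = j,
    // i.e. (j+1)-1 counts); LCM through (x_j, j+1)
    lower_hull(x, low, high, 0.0, gh);
    upper_hull(x, low, high, 1.0, lh);
    eval_curve(x, gh, 0.0, low, high, true, gc);
    eval_curve(x, lh, 1.0, low, high, false, lc);

    double d = 0.0;
    int jstar = low;
    for (int j = low; j <= high; ++j) {
      double gap = lc[j - low] - gc[j - low];
      if (gap > d) { d = gap; jstar = j; }
    }
    if (d <= D) break;

    // modal-interval endpoints: hull touch points bracketing the max gap
    int new_low = low, new_high = high;
    for (size_t s = 0; s < gh.size(); ++s)
      if (gh[s] <= jstar) new_low = gh[s];
    for (size_t s = lh.size(); s-- > 0;)
      if (lh[s] >= jstar) new_high = lh[s];

    // deviation of the empirical CDF above the GCM on [low, new_low]
    // (F upper corner y = j + 1) and below the LCM on [new_high, high]
    // (F lower corner y = j)
    double dl = 0.0, du = 0.0;
    for (int j = low; j <= new_low; ++j) {
      double t = (j + 1) - gc[j - low];
      if (t > dl) dl = t;
    }
    for (int j = new_high; j <= high; ++j) {
      double t = lc[j - low] - j;
      if (t > du) du = t;
    }
    double Dnew = dl > du ? dl : du;
    if (Dnew > D) D = Dnew;
    if (new_low == low && new_high == high) break;
    low = new_low;
    high = new_high;
  }
  return D / (2.0 * n);
}

// [[Rcpp::export]]
double dip_stat_cpp(NumericVector x_sorted) {
  int n = x_sorted.size();
  std::vector<double> x(n);
  for (int i = 0; i < n; ++i) {
    x[i] = x_sorted[i];
    if (i > 0 && x[i] < x[i - 1]) stop("input must be sorted");
  }
  return dip_sorted(x);
}

// Null distribution of the dip for sample size n under uniform(0,1);
// driven by R's RNG so set.seed() controls reproducibility.
// [[Rcpp::export]]
NumericVector dip_null_cpp(int n, int n_boot) {
  NumericVector out(n_boot);
  std::vector<double> x(n);
  for (int b = 0; b < n_boot; ++b) {
    for (int i = 0; i < n; ++i) x[i] = unif_rand();
    std::sort(x.begin(), x.end());
    out[b] = dip_sorted(x);
  }
  return out;
}
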