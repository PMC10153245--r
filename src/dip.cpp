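#include <Rcpp.h>
#include <vector>
#include <algorithm>

// Hartigan & Hartigan dip statistic.
//
// Works on the jump midpoints c_i = (2i - 1) / (2n) of the empirical CDF:
// a continuous G with sup|F_n - G| <= d exists iff G passes within
// r = d - 1/(2n) of every (x_i, c_i).  The dip is therefore 1/(2n) + r*,
// where r* is the smallest sup-distance from the midpoints to a
// convex-then-concave (unimodal CDF shaped) curve.  r* is found by the
// classic shrinking modal-interval iteration: compute the greatest convex
// minorant (GCM) and least concave majorant (LCM) of the midpoints on the
// current interval, locate the largest minorant/majorant gap, freeze the
// flanks (their bulge relative to the hulls is what a convex or concave
// fit must absorb, at half the bulge), and recurse into the interval
// around the gap until the interior gap no longer exceeds what the flanks
// already require.

namespace {

// lower convex hull (GCM) vertex indices of points (x[i], c[i]), i in [lo, hi]
std::vector<int> lower_hull(const std::vector<double>& x,
                            const std::vector<double>& c,
                            int lo, int hi) {
    std::vector<int> v;
    for (int i = lo; i <= hi; ++i) {
        while (v.size() >= 2) {
            int a = v[v.size() - 2], b = v[v.size() - 1];
            // keep b iff strictly below chord a -> i
            double cross = (x[b] - x[a]) * (c[i] - c[a]) -
                           (x[i] - x[a]) * (c[b] - c[a]);
            if (cross > 0) break;
            v.pop_back();
        }
        v.push_back(i);
    }
    return v;
}

// upper concave hull (LCM) vertex indices
std::vector<int> upper_hull(const std::vector<double>& x,
                            const std::vector<double>& c,
                            int lo, int hi) {
    std::vector<int> v;
    for (int i = lo; i <= hi; ++i) {
        while (v.size() >= 2) {
            int a = v[v.size() - 2], b = v[v.size() - 1];
            // keep b iff strictly above chord a -> i
            double cross = (x[b] - x[a]) * (c[i] - c[a]) -
                           (x[i] - x[a]) * (c[b] - c[a]);
            if (cross < 0) break;
            v.pop_back();
        }
        v.push_back(i);
    }
    return v;
}

// evaluate the piecewise-linear hull (vertex list v) at x[j]; seg is the
// index into v of the segment start such that x[v[seg]] <= x[j] <= x[v[seg+1]].
// 'top' selects the value used on vertical (tied-x) segments: the upper end
// for the majorant, the lower end for the minorant.
double hull_eval(const std::vector<double>& x, const std::vector<double>& c,
                 const std::vector<int>& v, int seg, int j, bool top) {
    int a = v[seg], b = v[seg + 1];
    if (x[b] == x[a]) return top ? std::max(c[a], c[b]) : std::min(c[a], c[b]);
    double t = (x[j] - x[a]) / (x[b] - x[a]);
    return c[a] + t * (c[b] - c[a]);
}

// segment of hull v whose x-range contains x[j] (first such, scanning left)
int find_seg(const std::vector<double>& x, const std::vector<int>& v, int j) {
    int seg = 0;
    int m = (int) v.size();
    while (seg < m - 2 && x[v[seg + 1]] < x[j]) ++seg;
    // for vertical stacks prefer the segment whose endpoints straddle j by index
    while (seg < m - 2 && x[v[seg + 1]] == x[j] && v[seg + 1] < j) ++seg;
    return seg;
}

} // namespace

// [[Rcpp::export]]
double dip_stat_cpp(Rcpp::NumericVector xs) {
    int n = xs.size();
    if (n < 1) Rcpp::stop("dip statistic needs at least one observation");
    std::vector<double> x(xs.begin(), xs.end());
    std::sort(x.begin(), x.end());
    if (n < 2 || x[0] == x[n - 1]) return 1.0 / (2.0 * n);

    std::vector<double> c(n);
    for (int i = 0; i < n; ++i) c[i] = (2.0 * i + 1.0) / (2.0 * n);

    int low = 0, high = n - 1;
    double r = 0.0;

    for (int iter = 0; iter < 2 * n + 10; ++iter) {
        std::vector<int> g = lower_hull(x, c, low, high);
        std::vector<int> l = upper_hull(x, c, low, high);

        // largest gap LCM - GCM; piecewise linear, so the max sits at a
        // vertex of one of the hulls
        double gap = 0.0;
        bool at_gcm = true;   // is the argmax a GCM vertex?
        int arg = low;        // argmax vertex index (into the sample)
        int other_seg = 0;    // segment of the *other* hull covering it
        for (size_t k = 0; k < g.size(); ++k) {
            int j = g[k];
            int seg = find_seg(x, l, j);
            double d = hull_eval(x, c, l, seg, j, true) - c[j];
            if (d > gap) { gap = d; at_gcm = true; arg = j; other_seg = seg; }
        }
        for (size_t k = 0; k < l.size(); ++k) {
            int u = l[k];
            int seg = find_seg(x, g, u);
            double d = c[u] - hull_eval(x, c, g, seg, u, false);
            if (d > gap) { gap = d; at_gcm = false; arg = u; other_seg = seg; }
        }

        if (gap / 2.0 <= r) break;

        int new_low, new_high;
        if (at_gcm) {            // modal interval: this GCM vertex up to the
            new_low = arg;       // right end of the covering LCM segment
            new_high = l[other_seg + 1];
        } else {                 // left end of covering GCM segment up to
            new_low = g[other_seg];  // this LCM vertex
            new_high = arg;
        }
        if (new_low < low) new_low = low;
        if (new_high > high) new_high = high;

        if (new_low == low && new_high == high) { // no progress: interior gap is final
            if (gap / 2.0 > r) r = gap / 2.0;
            break;
        }

        // freeze the flanks: bulge of midpoints above the GCM on the left,
        // below the LCM on the right; a convex (resp. concave) fit there
        // costs half the bulge
        double dl = 0.0;
        {
            int seg = 0;
            for (int i = low; i <= new_low; ++i) {
                while (seg < (int) g.size() - 2 &&
                       (x[g[seg + 1]] < x[i] ||
                        (x[g[seg + 1]] == x[i] && g[seg + 1] < i))) ++seg;
                double d = c[i] - hull_eval(x, c, g, seg, i, false);
                if (d > dl) dl = d;
            }
        }
        double du = 0.0;
        {
            int seg = 0;
            for (int i = new_high; i <= high; ++i) {
                while (seg < (int) l.size() - 2 &&
                       (x[l[seg + 1]] < x[i] ||
                        (x[l[seg + 1]] == x[i] && l[seg + 1] < i))) ++seg;
                double d = hull_eval(x, c, l, seg, i, true) - c[i];
                if (d > du) du = d;
            }
        }
        if (dl / 2.0 > r) r = dl / 2.0;
        if (du / 2.0 > r) r = du / 2.0;

        low = new_low;
        high = new_high;
        if (low >= high) break;
    }

    return r + 1.0 / (2.0 * n);
}
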