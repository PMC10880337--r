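#include <Rcpp.h>
#include <set>
#include <utility>

// Greedy 1:k nearest-neighbour matching without replacement on propensity
// scores. Exposed units are processed in the order given (caller sorts by
// descending score, ties broken by id); for each, the k nearest available
// controls within the absolute caliper are taken. With strict = true an
// exposed unit that cannot fill all k slots is dropped and its provisionally
// taken controls are returned to the pool. Ties in control distance resolve
// to the lower control index (deterministic).
//
// exposed: scores in processing order; controls: scores (any order; indexed
// 1-based in the result). Returns an ne x k matrix of control indices
// (NA for unfilled slots).
// [[Rcpp::export]]
Rcpp::IntegerMatrix nn_match_cpp(Rcpp::NumericVector exposed,
                                 Rcpp::NumericVector controls,
                                 int ratio, double caliper, bool strict) {
    const int ne = exposed.size(), nc = controls.size();
    typedef std::pair<double, int> P;
    std::set<P> avail;
    for (int j = 0; j < nc; ++j) avail.insert(P(controls[j], j));
    Rcpp::IntegerMatrix out(ne, ratio);
    std::fill(out.begin(), out.end(), NA_INTEGER);

    std::vector<P> taken;
    taken.reserve(ratio);
    for (int e = 0; e < ne; ++e) {
        const double s = exposed[e];
        taken.clear();
        for (int k = 0; k < ratio; ++k) {
            if (avail.empty()) break;
            // nearest available to s: candidates around lower_bound
            std::set<P>::iterator hi = avail.lower_bound(P(s, -1));
            std::set<P>::iterator best = avail.end();
            double bestd = 0.0;
            if (hi != avail.end()) {
                best = hi;
                bestd = hi->first - s;
            }
            if (hi != avail.begin()) {
                std::set<P>::iterator lo = hi;
                --lo;
                double d = s - lo->first;
                // prefer strictly smaller distance; on exact tie keep the
                // lower-index control
                if (best == avail.end() || d < bestd ||
                    (d == bestd && lo->second < best->second)) {
                    best = lo;
                    bestd = d;
                }
            }
            if (best == avail.end() || bestd > caliper) break;
            taken.push_back(*best);
            avail.erase(best);
        }
        if (strict && (int)taken.size() < ratio) {
            // infeasible: release provisional controls, drop this unit
            for (size_t t = 0; t < taken.size(); ++t) avail.insert(taken[t]);
        } else {
            for (size_t t = 0; t < taken.size(); ++t)
                out(e, t) = taken[t].second + 1; // 1-based
        }
    }
    return out;
}
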