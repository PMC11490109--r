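#include <Rcpp.h>
#include <algorithm>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Haplotype matrices are handled site-major here (n_sites rows, one column
// per haplotype) so that segment copies along a chromosome are contiguous.

// Discrete-generation Wright-Fisher forward simulation on a fixed site grid.
// Each offspring haplotype draws two uniform parents, a Poisson number of
// crossover points uniform on the physical map, and a Poisson number of
// site mutations (0<->1 flips). Uses R's RNG, so set.seed() governs it.
// [[Rcpp::export]]
IntegerMatrix wf_evolve_cpp(IntegerMatrix founders, int generations,
                            NumericVector pos, double recomb_rate, double mu) {
    const int L = founders.nrow();
    const int N = founders.ncol();
    if (L != pos.size()) stop("positions must match site count");
    IntegerMatrix cur = clone(founders);
    IntegerMatrix nxt(L, N);
    const double span = (L > 1) ? (pos[L - 1] - pos[0]) : 0.0;
    const double lambda = recomb_rate * span;
    const double mu_total = mu * L;
    std::vector<double> bp;
    const double* p0 = &pos[0];

    for (int g = 0; g < generations; ++g) {
        for (int i = 0; i < N; ++i) {
            int p1 = std::min(N - 1, (int)(unif_rand() * N));
            int p2 = std::min(N - 1, (int)(unif_rand() * N));
            int* child = &nxt(0, i);
            const int* a = &cur(0, p1);
            const int* b = &cur(0, p2);
            int k = (lambda > 0 && p1 != p2) ? (int)R::rpois(lambda) : 0;
            if (k == 0) {
                std::memcpy(child, a, L * sizeof(int));
            } else {
                bp.clear();
                for (int c = 0; c < k; ++c) bp.push_back(pos[0] + unif_rand() * span);
                std::sort(bp.begin(), bp.end());
                int start = 0;
                bool useA = true;
                const int* src = a;
                for (size_t c = 0; c < bp.size(); ++c) {
                    int idx = (int)(std::upper_bound(p0, p0 + L, bp[c]) - p0);
                    if (idx > start)
                        std::memcpy(child + start, src + start, (idx - start) * sizeof(int));
                    start = idx;
                    useA = !useA;
                    src = useA ? a : b;
                }
                if (start < L)
                    std::memcpy(child + start, src + start, (L - start) * sizeof(int));
            }
            if (mu_total > 0) {
                int m = (int)R::rpois(mu_total);
                for (int c = 0; c < m; ++c) {
                    int s = std::min(L - 1, (int)(unif_rand() * L));
                    child[s] ^= 1;
                }
            }
        }
        std::swap(cur, nxt);
        if (g % 64 == 0) Rcpp::checkUserInterrupt();
    }
    return cur;
}

// One-sided integrated EHH for a core variant/allele by incremental
// partition refinement of the carrier set: at each successive variant the
// surviving haplotype groups are split by the allele carried there, and
// EHH = sum_h n_h(n_h-1) / (n_c(n_c-1)). The trapezoid integral over bp
// distance accumulates up to (and including) the first variant where EHH
// drops below `cutoff`; hitting the data boundary first sets `truncated`.
static void ehh_integrate_side(const int* hap, int L, int stride,
                               const NumericVector& pos, int core,
                               const std::vector<int>& carriers, int dir,
                               double cutoff, double* ihh_out, bool* trunc_out) {
    const int nc = (int)carriers.size();
    const double denom = (double)nc * (nc - 1);
    double ihh = 0.0, ehh_prev = 1.0, d_prev = 0.0;
    std::vector<std::vector<int> > groups(1, carriers);
    for (int k = core + dir; k >= 0 && k < L; k += dir) {
        double pairs = 0.0;
        std::vector<std::vector<int> > nxt;
        for (size_t gi = 0; gi < groups.size(); ++gi) {
            std::vector<int> ones, zeros;
            const std::vector<int>& g = groups[gi];
            for (size_t m = 0; m < g.size(); ++m) {
                if (hap[(R_xlen_t)g[m] * stride + k]) ones.push_back(g[m]);
                else zeros.push_back(g[m]);
            }
            if (ones.size() >= 2) {
                pairs += (double)ones.size() * (ones.size() - 1);
                nxt.push_back(ones);
            }
            if (zeros.size() >= 2) {
                pairs += (double)zeros.size() * (zeros.size() - 1);
                nxt.push_back(zeros);
            }
        }
        double ehh = pairs / denom;
        double d = std::abs(pos[k] - pos[core]);
        ihh += (d - d_prev) * (ehh_prev + ehh) / 2.0;
        if (ehh < cutoff) {
            *ihh_out = ihh;
            *trunc_out = false;
            return;
        }
        d_prev = d;
        ehh_prev = ehh;
        groups.swap(nxt);
    }
    *ihh_out = ihh;
    *trunc_out = true; // ran off the data before EHH < cutoff
}

// Per-variant iHH on both allelic backgrounds for all variants passing the
// MAF filter. haps is site-major (L x N). Status codes for dropped scored
// variants: 1 = fewer than 2 carriers on a background, 2 = zero integral.
// [[Rcpp::export]]
List ihs_scan_cpp(IntegerMatrix haps, NumericVector pos,
                  double maf_min, double cutoff) {
    const int L = haps.nrow();
    const int N = haps.ncol();
    const int* H = &haps(0, 0); // column (haplotype) stride = L
    std::vector<int> idx_keep, idx_drop, drop_code;
    std::vector<double> v_daf, v_ihh_d, v_ihh_a;
    std::vector<int> v_trunc;
    std::vector<int> der, anc;

    for (int j = 0; j < L; ++j) {
        int c1 = 0;
        for (int i = 0; i < N; ++i) c1 += H[(R_xlen_t)i * L + j];
        double daf = (double)c1 / N;
        double maf = std::min(daf, 1.0 - daf);
        if (!(maf > maf_min)) continue;
        der.clear();
        anc.clear();
        for (int i = 0; i < N; ++i) {
            if (H[(R_xlen_t)i * L + j]) der.push_back(i);
            else anc.push_back(i);
        }
        if (der.size() < 2 || anc.size() < 2) {
            idx_drop.push_back(j + 1);
            drop_code.push_back(1);
            continue;
        }
        double ihh_d = 0, ihh_a = 0, part;
        bool trunc = false, tr;
        ehh_integrate_side(H, L, L, pos, j, der, -1, cutoff, &part, &tr);
        ihh_d += part; trunc = trunc || tr;
        ehh_integrate_side(H, L, L, pos, j, der, +1, cutoff, &part, &tr);
        ihh_d += part; trunc = trunc || tr;
        ehh_integrate_side(H, L, L, pos, j, anc, -1, cutoff, &part, &tr);
        ihh_a += part; trunc = trunc || tr;
        ehh_integrate_side(H, L, L, pos, j, anc, +1, cutoff, &part, &tr);
        ihh_a += part; trunc = trunc || tr;
        if (ihh_d <= 0 || ihh_a <= 0) {
            idx_drop.push_back(j + 1);
            drop_code.push_back(2);
            continue;
        }
        idx_keep.push_back(j + 1);
        v_daf.push_back(daf);
        v_ihh_d.push_back(ihh_d);
        v_ihh_a.push_back(ihh_a);
        v_trunc.push_back(trunc ? 1 : 0);
        if (j % 4096 == 0) Rcpp::checkUserInterrupt();
    }
    return List::create(
        _["index"] = wrap(idx_keep), _["daf"] = wrap(v_daf),
        _["ihh_derived"] = wrap(v_ihh_d), _["ihh_ancestral"] = wrap(v_ihh_a),
        _["truncated"] = wrap(v_trunc),
        _["dropped_index"] = wrap(idx_drop), _["dropped_code"] = wrap(drop_code));
}
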