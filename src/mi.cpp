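#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Binned mutual information in nats with Miller-Madow bias correction.
// `bins` holds equal-frequency bin codes in 0..nbins-1; rows are genes,
// columns are samples. MM adds (K-1)/(2n) to each plug-in entropy, so the
// MI correction is (kx + ky - kxy - 1)/(2n). Estimates are clamped at 0.

static double marginal_entropy(const int *b, int n, int nbins, int *kout) {
    std::vector<int> cnt(nbins, 0);
    for (int s = 0; s < n; ++s) cnt[b[s]]++;
    double h = 0.0;
    int k = 0;
    for (int c = 0; c < nbins; ++c) {
        if (cnt[c] > 0) {
            double p = (double)cnt[c] / n;
            h -= p * std::log(p);
            ++k;
        }
    }
    *kout = k;
    return h;
}

// joint: scratch counts of size nbins*nbins (zeroed); touched: scratch index list
static double pair_mi(const int *bx, const int *by, int n, int nbins,
                      double hx, int kx, double hy, int ky,
                      std::vector<int> &joint, std::vector<int> &touched) {
    touched.clear();
    for (int s = 0; s < n; ++s) {
        int idx = bx[s] * nbins + by[s];
        if (joint[idx]++ == 0) touched.push_back(idx);
    }
    double hxy = 0.0;
    int kxy = (int)touched.size();
    for (int t = 0; t < kxy; ++t) {
        int idx = touched[t];
        double p = (double)joint[idx] / n;
        hxy -= p * std::log(p);
        joint[idx] = 0;
    }
    double mi = hx + hy - hxy + (double)(kx + ky - kxy - 1) / (2.0 * n);
    return mi > 0.0 ? mi : 0.0;
}

// [[Rcpp::export]]
double mi_pair_cpp(IntegerVector bx, IntegerVector by, int nbins) {
    int n = bx.size();
    int kx, ky;
    double hx = marginal_entropy(&bx[0], n, nbins, &kx);
    double hy = marginal_entropy(&by[0], n, nbins, &ky);
    std::vector<int> joint(nbins * nbins, 0), touched;
    touched.reserve(n);
    return pair_mi(&bx[0], &by[0], n, nbins, hx, kx, hy, ky, joint, touched);
}

// All gene pairs (i < j, row order), emitted in the order
// (1,2),(1,3),...,(1,G),(2,3),... matching R's upper-triangle unrolling.
// [[Rcpp::export]]
NumericVector mi_all_pairs_cpp(IntegerMatrix bins, int nbins) {
    int G = bins.nrow(), n = bins.ncol();
    // row-major copy so each gene's samples are contiguous
    std::vector<int> B((size_t)G * n);
    for (int g = 0; g < G; ++g)
        for (int s = 0; s < n; ++s) B[(size_t)g * n + s] = bins(g, s);
    std::vector<double> hx(G);
    std::vector<int> kx(G);
    for (int g = 0; g < G; ++g)
        hx[g] = marginal_entropy(&B[(size_t)g * n], n, nbins, &kx[g]);
    NumericVector out((R_xlen_t)G * (G - 1) / 2);
    std::vector<int> joint(nbins * nbins, 0), touched;
    touched.reserve(n);
    R_xlen_t e = 0;
    for (int i = 0; i < G - 1; ++i) {
        const int *bi = &B[(size_t)i * n];
        for (int j = i + 1; j < G; ++j) {
            out[e++] = pair_mi(bi, &B[(size_t)j * n], n, nbins,
                               hx[i], kx[i], hx[j], kx[j], joint, touched);
        }
        if (i % 64 == 0) Rcpp::checkUserInterrupt();
    }
    return out;
}

// Pooled permutation null: each draw picks two distinct genes, shuffles the
// sample order of the second, and records the MI. Uses R's RNG so results
// are reproducible under set.seed().
// [[Rcpp::export]]
NumericVector mi_null_cpp(IntegerMatrix bins, int nbins, int nperm) {
    int G = bins.nrow(), n = bins.ncol();
    std::vector<int> B((size_t)G * n);
    for (int g = 0; g < G; ++g)
        for (int s = 0; s < n; ++s) B[(size_t)g * n + s] = bins(g, s);
    std::vector<double> hx(G);
    std::vector<int> kx(G);
    for (int g = 0; g < G; ++g)
        hx[g] = marginal_entropy(&B[(size_t)g * n], n, nbins, &kx[g]);
    NumericVector out(nperm);
    std::vector<int> joint(nbins * nbins, 0), touched, perm(n);
    touched.reserve(n);
    GetRNGstate();
    for (int p = 0; p < nperm; ++p) {
        int i = (int)(unif_rand() * G);
        if (i >= G) i = G - 1;
        int j = (int)(unif_rand() * (G - 1));
        if (j >= G - 1) j = G - 2;
        if (j >= i) ++j;
        const int *bj = &B[(size_t)j * n];
        for (int s = 0; s < n; ++s) perm[s] = bj[s];
        for (int s = n - 1; s > 0; --s) {  // Fisher-Yates
            int t = (int)(unif_rand() * (s + 1));
            if (t > s) t = s;
            std::swap(perm[s], perm[t]);
        }
        out[p] = pair_mi(&B[(size_t)i * n], perm.data(), n, nbins,
                         hx[i], kx[i], hx[j], kx[j], joint, touched);
    }
    PutRNGstate();
    return out;
}
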