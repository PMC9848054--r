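#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

// Deterministic RNG (splitmix64 seeding a xoshiro256**): training is
// bit-reproducible for a fixed seed, independent of R's RNG state.
namespace {

struct Rng {
    uint64_t s[4];
    explicit Rng(uint64_t seed) {
        uint64_t x = seed;
        for (int i = 0; i < 4; ++i) {
            x += 0x9e3779b97f4a7c15ULL;
            uint64_t z = x;
            z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
            z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
            s[i] = z ^ (z >> 31);
        }
    }
    static inline uint64_t rotl(uint64_t x, int k) {
        return (x << k) | (x >> (64 - k));
    }
    inline uint64_t next() {
        uint64_t result = rotl(s[1] * 5, 7) * 9;
        uint64_t t = s[1] << 17;
        s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
        s[2] ^= t; s[3] = rotl(s[3], 45);
        return result;
    }
    inline double unif() {  // in [0, 1)
        return (next() >> 11) * 0x1.0p-53;
    }
    inline int below(int n) { return (int)(unif() * n); }
};

// Vose alias table for O(1) discrete sampling.
struct Alias {
    std::vector<double> prob;
    std::vector<int> alias;
    void build(const std::vector<double>& w) {
        int n = w.size();
        prob.assign(n, 0.0); alias.assign(n, 0);
        double total = 0.0;
        for (double x : w) total += x;
        std::vector<double> p(n);
        for (int i = 0; i < n; ++i) p[i] = w[i] * n / total;
        std::vector<int> small, large;
        small.reserve(n); large.reserve(n);
        for (int i = 0; i < n; ++i) (p[i] < 1.0 ? small : large).push_back(i);
        while (!small.empty() && !large.empty()) {
            int s = small.back(); small.pop_back();
            int l = large.back(); large.pop_back();
            prob[s] = p[s]; alias[s] = l;
            p[l] = p[l] + p[s] - 1.0;
            (p[l] < 1.0 ? small : large).push_back(l);
        }
        while (!large.empty()) { prob[large.back()] = 1.0; large.pop_back(); }
        while (!small.empty()) { prob[small.back()] = 1.0; small.pop_back(); }
    }
    inline int draw(Rng& rng) const {
        int i = rng.below(prob.size());
        return rng.unif() < prob[i] ? i : alias[i];
    }
};

inline double sigmoid(double x) {
    if (x > 30.0) return 1.0;
    if (x < -30.0) return 0.0;
    return 1.0 / (1.0 + std::exp(-x));
}

}  // namespace

// Second-order-proximity embedding trainer: stochastic ascent on
// sigma(u'_j . u_i) for edges drawn proportional to their weight (both
// directions of each undirected edge enter the sampler), with K negative
// draws from a noise distribution proportional to degree^noisePow.
// [[Rcpp::export(name = ".lineTrainCpp", rng = false)]]
Rcpp::List lineTrainCpp(Rcpp::IntegerVector src, Rcpp::IntegerVector dst,
                        Rcpp::NumericVector weight, int nNodes, int dim,
                        int negatives, double totalSamples, double rho0,
                        double noisePow, double seed) {
    const int nEdges = src.size();
    if (dim <= 0) Rcpp::stop("dim must be positive");
    if (totalSamples <= 0) Rcpp::stop("total sample count must be positive");

    // directed edge arrays: both directions of every undirected edge
    std::vector<int> esrc(2 * nEdges), edst(2 * nEdges);
    std::vector<double> ew(2 * nEdges);
    std::vector<double> degree(nNodes, 0.0);
    for (int e = 0; e < nEdges; ++e) {
        int i = src[e], j = dst[e];
        double w = weight[e];
        esrc[2 * e] = i; edst[2 * e] = j; ew[2 * e] = w;
        esrc[2 * e + 1] = j; edst[2 * e + 1] = i; ew[2 * e + 1] = w;
        degree[i] += w; degree[j] += w;
    }
    Alias edgeTable; edgeTable.build(ew);
    std::vector<double> noise(nNodes);
    for (int v = 0; v < nNodes; ++v) noise[v] = std::pow(degree[v], noisePow);
    Alias noiseTable; noiseTable.build(noise);

    Rng rng((uint64_t)seed);
    std::vector<double> u((size_t)nNodes * dim), ctx((size_t)nNodes * dim, 0.0);
    for (size_t k = 0; k < u.size(); ++k)
        u[k] = (rng.unif() - 0.5) / dim;

    const double T = totalSamples;
    std::vector<double> err(dim);
    for (double t = 0; t < T; t += 1.0) {
        double lr = rho0 * (1.0 - t / T);
        if (lr < rho0 * 1e-4) lr = rho0 * 1e-4;
        int e = edgeTable.draw(rng);
        int i = esrc[e], j = edst[e];
        double* ui = &u[(size_t)i * dim];
        std::fill(err.begin(), err.end(), 0.0);
        for (int d = 0; d <= negatives; ++d) {
            int target; double label;
            if (d == 0) { target = j; label = 1.0; }
            else {
                target = noiseTable.draw(rng);
                if (target == j || target == i) continue;
                label = 0.0;
            }
            double* ct = &ctx[(size_t)target * dim];
            double dot = 0.0;
            for (int k = 0; k < dim; ++k) dot += ui[k] * ct[k];
            double g = (label - sigmoid(dot)) * lr;
            for (int k = 0; k < dim; ++k) {
                err[k] += g * ct[k];
                ct[k] += g * ui[k];
            }
        }
        for (int k = 0; k < dim; ++k) ui[k] += err[k];
    }

    Rcpp::NumericMatrix U(nNodes, dim), C(nNodes, dim);
    for (int v = 0; v < nNodes; ++v)
        for (int k = 0; k < dim; ++k) {
            U(v, k) = u[(size_t)v * dim + k];
            C(v, k) = ctx[(size_t)v * dim + k];
        }
    return Rcpp::List::create(Rcpp::Named("u") = U, Rcpp::Named("ctx") = C);
}
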