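#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Stochastic (Eden-type) region growing on a 3D voxel grid.
//
// Starting from `seeds` (1-based linear indices into the volume), voxels are
// added one at a time by drawing uniformly from the current frontier (the
// 6-connected neighbours of the region that lie inside `allowed`), until
// `target` voxels have been added or the frontier is exhausted. Draws use
// R's RNG so growth is reproducible under set.seed(). Returns the 1-based
// linear indices of the grown region (the seeds themselves are included and
// count toward `target` when `includeSeeds` is true; otherwise the seeds act
// only as growth origins, as when oedema is grown as a shell around an
// existing core).
// [[Rcpp::export(name = ".growRegion")]]
IntegerVector growRegion(LogicalVector allowed, IntegerVector dims,
                         IntegerVector seeds, int target,
                         bool includeSeeds = true) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
    std::vector<char> state(nvox, 0); // 0 untouched, 1 in region/blocked, 2 queued
    std::vector<int> frontier;
    std::vector<int> region;
    region.reserve(target > 0 ? target : 1);

    RNGScope scope;

    auto pushNeighbours = [&](int idx0) {
        int k = idx0 / (nx * ny);
        int rem = idx0 - k * nx * ny;
        int j = rem / nx;
        int i = rem - j * nx;
        const int di[6] = {-1, 1, 0, 0, 0, 0};
        const int dj[6] = {0, 0, -1, 1, 0, 0};
        const int dk[6] = {0, 0, 0, 0, -1, 1};
        for (int d = 0; d < 6; ++d) {
            int ii = i + di[d], jj = j + dj[d], kk = k + dk[d];
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
                continue;
            int nb = ii + nx * (jj + (R_xlen_t)ny * kk);
            if (state[nb] == 0 && allowed[nb]) {
                state[nb] = 2;
                frontier.push_back(nb);
            }
        }
    };

    for (int s = 0; s < seeds.size(); ++s) {
        int idx0 = seeds[s] - 1;
        if (idx0 < 0 || idx0 >= nvox) stop("seed index out of range");
        if (state[idx0] == 1) continue;
        state[idx0] = 1;
        if (includeSeeds) {
            if (!allowed[idx0]) stop("seed voxel not inside the allowed mask");
            region.push_back(idx0);
        }
        pushNeighbours(idx0);
    }

    int need = target - (int)region.size();
    while (need > 0 && !frontier.empty()) {
        // swap-pop a uniform random frontier element
        int pick = (int)(unif_rand() * frontier.size());
        if (pick >= (int)frontier.size()) pick = frontier.size() - 1;
        int idx0 = frontier[pick];
        frontier[pick] = frontier.back();
        frontier.pop_back();
        if (state[idx0] == 1) continue;
        state[idx0] = 1;
        region.push_back(idx0);
        --need;
        pushNeighbours(idx0);
    }

    IntegerVector out(region.size());
    for (size_t m = 0; m < region.size(); ++m) out[m] = region[m] + 1;
    return out;
}
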