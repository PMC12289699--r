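#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 13 unique direction offsets covering the 26-neighborhood up to sign.
static const int OFF13[13][3] = {
    {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
    {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1}, {0, 1, 1}, {0, 1, -1},
    {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}};

static inline int idx3(int x, int y, int z, int nx, int ny) {
    return x + nx * (y + ny * z);
}

// lev: 3-D integer array (dim attribute required); 0 marks out-of-region
// voxels, in-region voxels carry quantized levels 1..n_levels. Returns the
// raw (unnormalized) texture count structures:
//   glcm  - n_levels x n_levels symmetric pair counts summed over the 13
//           distance-1 offsets (each unordered pair counted in both orders)
//   glrlm - n_levels x max_run maximal-run counts summed over 13 directions
//   glszm - n_levels x max_zone counts of 26-connected constant-level zones
//   ngtdm_n / ngtdm_s - per-level occurrence counts and summed absolute
//           difference to the mean of in-region 26-neighbors (voxels with no
//           in-region neighbor are skipped)
// [[Rcpp::export]]
List texture_counts_cpp(IntegerVector lev, int n_levels) {
    IntegerVector dim = lev.attr("dim");
    if (dim.size() != 3) stop("level array must be 3-D");
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const int L = n_levels;

    NumericMatrix glcm(L, L);

    // ---- GLCM ----
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
                int l1 = lev[idx3(x, y, z, nx, ny)];
                if (l1 == 0) continue;
                for (int d = 0; d < 13; ++d) {
                    int xx = x + OFF13[d][0], yy = y + OFF13[d][1],
                        zz = z + OFF13[d][2];
                    if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny ||
                        zz >= nz)
                        continue;
                    int l2 = lev[idx3(xx, yy, zz, nx, ny)];
                    if (l2 == 0) continue;
                    glcm(l1 - 1, l2 - 1) += 1.0;
                    glcm(l2 - 1, l1 - 1) += 1.0;
                }
            }

    // ---- GLRLM ----
    int maxdim = nx > ny ? nx : ny;
    if (nz > maxdim) maxdim = nz;
    NumericMatrix glrlm(L, maxdim);
    int max_run_seen = 1;
    for (int d = 0; d < 13; ++d) {
        const int dx = OFF13[d][0], dy = OFF13[d][1], dz = OFF13[d][2];
        for (int z = 0; z < nz; ++z)
            for (int y = 0; y < ny; ++y)
                for (int x = 0; x < nx; ++x) {
                    int l = lev[idx3(x, y, z, nx, ny)];
                    if (l == 0) continue;
                    // start of a maximal run: predecessor absent or different
                    int px = x - dx, py = y - dy, pz = z - dz;
                    if (px >= 0 && py >= 0 && pz >= 0 && px < nx && py < ny &&
                        pz < nz && lev[idx3(px, py, pz, nx, ny)] == l)
                        continue;
                    int len = 1;
                    int cx = x + dx, cy = y + dy, cz = z + dz;
                    while (cx >= 0 && cy >= 0 && cz >= 0 && cx < nx &&
                           cy < ny && cz < nz &&
                           lev[idx3(cx, cy, cz, nx, ny)] == l) {
                        ++len;
                        cx += dx; cy += dy; cz += dz;
                    }
                    glrlm(l - 1, len - 1) += 1.0;
                    if (len > max_run_seen) max_run_seen = len;
                }
    }

    // ---- GLSZM: 26-connected constant-level zones ----
    std::vector<int> zone_level, zone_size;
    {
        std::vector<char> visited((size_t)nx * ny * nz, 0);
        std::vector<int> stack;
        for (int z0 = 0; z0 < nz; ++z0)
            for (int y0 = 0; y0 < ny; ++y0)
                for (int x0 = 0; x0 < nx; ++x0) {
                    int i0 = idx3(x0, y0, z0, nx, ny);
                    int l = lev[i0];
                    if (l == 0 || visited[i0]) continue;
                    int size = 0;
                    stack.clear();
                    stack.push_back(i0);
                    visited[i0] = 1;
                    while (!stack.empty()) {
                        int i = stack.back();
                        stack.pop_back();
                        ++size;
                        int x = i % nx, y = (i / nx) % ny, zz = i / (nx * ny);
                        for (int dz = -1; dz <= 1; ++dz)
                            for (int dy = -1; dy <= 1; ++dy)
                                for (int dx = -1; dx <= 1; ++dx) {
                                    if (!dx && !dy && !dz) continue;
                                    int ax = x + dx, ay = y + dy, az = zz + dz;
                                    if (ax < 0 || ay < 0 || az < 0 ||
                                        ax >= nx || ay >= ny || az >= nz)
                                        continue;
                                    int ai = idx3(ax, ay, az, nx, ny);
                                    if (!visited[ai] && lev[ai] == l) {
                                        visited[ai] = 1;
                                        stack.push_back(ai);
                                    }
                                }
                    }
                    zone_level.push_back(l);
                    zone_size.push_back(size);
                }
    }
    int max_zone = 1;
    for (size_t k = 0; k < zone_size.size(); ++k)
        if (zone_size[k] > max_zone) max_zone = zone_size[k];
    NumericMatrix glszm(L, max_zone);
    for (size_t k = 0; k < zone_level.size(); ++k)
        glszm(zone_level[k] - 1, zone_size[k] - 1) += 1.0;

    // ---- NGTDM ----
    NumericVector ngtdm_n(L), ngtdm_s(L);
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
                int l = lev[idx3(x, y, z, nx, ny)];
                if (l == 0) continue;
                double sum = 0.0;
                int cnt = 0;
                for (int dz = -1; dz <= 1; ++dz)
                    for (int dy = -1; dy <= 1; ++dy)
                        for (int dx = -1; dx <= 1; ++dx) {
                            if (!dx && !dy && !dz) continue;
                            int ax = x + dx, ay = y + dy, az = z + dz;
                            if (ax < 0 || ay < 0 || az < 0 || ax >= nx ||
                                ay >= ny || az >= nz)
                                continue;
                            int ln = lev[idx3(ax, ay, az, nx, ny)];
                            if (ln == 0) continue;
                            sum += ln;
                            ++cnt;
                        }
                if (cnt == 0) continue;  // isolated voxel: no neighborhood
                ngtdm_n[l - 1] += 1.0;
                ngtdm_s[l - 1] += std::fabs((double)l - sum / cnt);
            }

    // trim GLRLM to observed maximum run length
    NumericMatrix glrlm_out(L, max_run_seen);
    for (int i = 0; i < L; ++i)
        for (int j = 0; j < max_run_seen; ++j) glrlm_out(i, j) = glrlm(i, j);

    return List::create(_["glcm"] = glcm, _["glrlm"] = glrlm_out,
                        _["glszm"] = glszm, _["ngtdm_n"] = ngtdm_n,
                        _["ngtdm_s"] = ngtdm_s);
}
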