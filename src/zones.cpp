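#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component zones of equal gray level in a 3D integer array.
// Breadth-first search with 26- or 6-connectivity; every voxel belongs to
// exactly one zone. Returns the gray level and voxel count of each zone.
// [[Rcpp::export(name = ".zone_list_cpp")]]
DataFrame zone_list_cpp(IntegerVector levels, IntegerVector dims,
                        int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  if (levels.size() != n) stop("levels length does not match dims");
  if (connectivity != 26 && connectivity != 6)
    stop("connectivity must be 26 or 6");

  std::vector<int> offx, offy, offz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        if (connectivity == 6 && std::abs(dx) + std::abs(dy) + std::abs(dz) != 1)
          continue;
        offx.push_back(dx); offy.push_back(dy); offz.push_back(dz);
      }
  const int noff = (int)offx.size();

  std::vector<char> seen(n, 0);
  std::vector<int> zone_level, zone_size;
  std::vector<int> queue;
  queue.reserve(n);

  for (int start = 0; start < n; ++start) {
    if (seen[start]) continue;
    const int lev = levels[start];
    int size = 0;
    queue.clear();
    queue.push_back(start);
    seen[start] = 1;
    while (!queue.empty()) {
      int idx = queue.back();
      queue.pop_back();
      ++size;
      int x = idx % nx;
      int y = (idx / nx) % ny;
      int z = idx / (nx * ny);
      for (int k = 0; k < noff; ++k) {
        int xx = x + offx[k], yy = y + offy[k], zz = z + offz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int nidx = xx + nx * (yy + ny * zz);
        if (!seen[nidx] && levels[nidx] == lev) {
          seen[nidx] = 1;
          queue.push_back(nidx);
        }
      }
    }
    zone_level.push_back(lev);
    zone_size.push_back(size);
  }
  return DataFrame::create(_["level"] = wrap(zone_level),
                           _["size"] = wrap(zone_size));
}
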