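#include <Rcpp.h>
using namespace Rcpp;

// Whole-brain searchlight Pearson correlation between two 3D maps.
// For each in-mask center, r is computed over the in-mask voxels of the
// Euclidean sphere of `radius` voxels (center included); spheres are
// clipped at the volume boundary and the mask edge. Centers whose usable
// sphere has fewer than `min_voxels` voxels, or zero variance in either
// map, are returned as NA.
// [[Rcpp::export(name = ".searchlight_core")]]
NumericVector searchlight_core(NumericVector a, NumericVector b,
                               LogicalVector mask, IntegerVector dim,
                               IntegerMatrix offsets, int min_voxels) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  const int m = offsets.nrow();
  NumericVector out(n, NA_REAL);
  std::vector<double> va(m), vb(m);

  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        const int c = x + nx * (y + ny * z);
        if (!mask[c]) continue;
        int k = 0;
        for (int o = 0; o < m; ++o) {
          const int xi = x + offsets(o, 0);
          const int yi = y + offsets(o, 1);
          const int zi = z + offsets(o, 2);
          if (xi < 0 || xi >= nx || yi < 0 || yi >= ny || zi < 0 || zi >= nz)
            continue;
          const int v = xi + nx * (yi + ny * zi);
          if (!mask[v]) continue;
          if (ISNAN(a[v]) || ISNAN(b[v])) continue;
          va[k] = a[v];
          vb[k] = b[v];
          ++k;
        }
        if (k < min_voxels) continue;
        double ma = 0.0, mb = 0.0;
        for (int i = 0; i < k; ++i) { ma += va[i]; mb += vb[i]; }
        ma /= k; mb /= k;
        double sab = 0.0, saa = 0.0, sbb = 0.0;
        for (int i = 0; i < k; ++i) {
          const double da = va[i] - ma, db = vb[i] - mb;
          sab += da * db;
          saa += da * da;
          sbb += db * db;
        }
        if (saa <= 0.0 || sbb <= 0.0) continue;
        out[c] = sab / std::sqrt(saa * sbb);
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}
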