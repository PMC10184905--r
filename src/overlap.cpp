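#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Pairwise overlap relaxation for spherical cells with a uniform-grid
// neighbour search. Each pass displaces every overlapping pair by half the
// overlap along the centre line; positions are clamped to the domain box.
// Coincident centres are separated along a deterministic axis so results
// are reproducible.
// [[Rcpp::export]]
List relax_overlaps_cpp(NumericVector x, NumericVector y, NumericVector z,
                        NumericVector r, NumericVector domain,
                        double tol, int max_pass) {
  const int n = x.size();
  std::vector<double> px(x.begin(), x.end());
  std::vector<double> py(y.begin(), y.end());
  std::vector<double> pz(z.begin(), z.end());
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, r[i]);
  const double bin = std::max(2.0 * rmax, 1e-6);
  const int bx = std::max(1, (int)std::floor(domain[0] / bin));
  const int by = std::max(1, (int)std::floor(domain[1] / bin));
  const int bz = std::max(1, (int)std::floor(domain[2] / bin));
  const double wx = domain[0] / bx, wy = domain[1] / by, wz = domain[2] / bz;

  std::vector<int> head(bx * by * bz), nxt(n);
  double max_ov = 0.0;
  int pass = 0;
  for (pass = 0; pass < max_pass; ++pass) {
    std::fill(head.begin(), head.end(), -1);
    for (int i = 0; i < n; ++i) {
      int cx = std::min(bx - 1, std::max(0, (int)(px[i] / wx)));
      int cy = std::min(by - 1, std::max(0, (int)(py[i] / wy)));
      int cz = std::min(bz - 1, std::max(0, (int)(pz[i] / wz)));
      int c = cx + bx * (cy + by * cz);
      nxt[i] = head[c];
      head[c] = i;
    }
    max_ov = 0.0;
    for (int i = 0; i < n; ++i) {
      int cx = (int)(px[i] / wx), cy = (int)(py[i] / wy), cz = (int)(pz[i] / wz);
      cx = std::min(bx - 1, std::max(0, cx));
      cy = std::min(by - 1, std::max(0, cy));
      cz = std::min(bz - 1, std::max(0, cz));
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = cz + dz; if (zz < 0 || zz >= bz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = cy + dy; if (yy < 0 || yy >= by) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            int xx = cx + dx; if (xx < 0 || xx >= bx) continue;
            for (int j = head[xx + bx * (yy + by * zz)]; j >= 0; j = nxt[j]) {
              if (j <= i) continue;
              double ddx = px[j] - px[i];
              double ddy = py[j] - py[i];
              double ddz = pz[j] - pz[i];
              double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
              double rsum = r[i] + r[j];
              if (d2 >= rsum * rsum) continue;
              double d = std::sqrt(d2);
              double ov = rsum - d;
              if (ov > max_ov) max_ov = ov;
              double ux, uy, uz;
              if (d > 1e-12) {
                ux = ddx / d; uy = ddy / d; uz = ddz / d;
              } else {
                // deterministic separation axis for coincident centres
                int axis = (i + j) % 3;
                ux = axis == 0; uy = axis == 1; uz = axis == 2;
              }
              double s = 0.5 * ov;
              px[i] -= ux * s; py[i] -= uy * s; pz[i] -= uz * s;
              px[j] += ux * s; py[j] += uy * s; pz[j] += uz * s;
              for (int k : {i, j}) {
                px[k] = std::min(domain[0], std::max(0.0, px[k]));
                py[k] = std::min(domain[1], std::max(0.0, py[k]));
                pz[k] = std::min(domain[2], std::max(0.0, pz[k]));
              }
            }
          }
        }
      }
    }
    if (max_ov < tol) { ++pass; break; }
  }
  return List::create(_["x"] = NumericVector(px.begin(), px.end()),
                      _["y"] = NumericVector(py.begin(), py.end()),
                      _["z"] = NumericVector(pz.begin(), pz.end()),
                      _["passes"] = pass, _["max_overlap"] = max_ov);
}
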