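#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a boolean grid by breadth-first search.
// Scan order is the raster order (top-left, rightwards, then down), so
// labels are contiguous 1..NP and deterministic.
// [[Rcpp::export]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  static const int dr8[] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dc8[] = {-1, 0, 1, -1, 1, -1, 0, 1};
  static const int dr4[] = {-1, 1, 0, 0};
  static const int dc4[] = {0, 0, -1, 1};
  const int *dr = (connectivity == 8) ? dr8 : dr4;
  const int *dc = (connectivity == 8) ? dc8 : dc4;
  const int nd = connectivity;
  std::vector<int> qr(static_cast<size_t>(nr) * nc), qc(qr.size());
  int next = 0;
  for (int r0 = 0; r0 < nr; ++r0) {
    for (int c0 = 0; c0 < nc; ++c0) {
      if (!mask(r0, c0) || lab(r0, c0)) continue;
      ++next;
      int head = 0, tail = 0;
      qr[tail] = r0; qc[tail] = c0; ++tail;
      lab(r0, c0) = next;
      while (head < tail) {
        const int r = qr[head], c = qc[head];
        ++head;
        for (int k = 0; k < nd; ++k) {
          const int rr = r + dr[k], cch = c + dc[k];
          if (rr < 0 || rr >= nr || cch < 0 || cch >= nc) continue;
          if (mask(rr, cch) && !lab(rr, cch)) {
            lab(rr, cch) = next;
            qr[tail] = rr; qc[tail] = cch; ++tail;
          }
        }
      }
    }
  }
  return lab;
}

// Per-pixel box-counting masses over the locally connected set.
//
// For every foreground pixel, the 8-connected cluster containing it is
// traced within the window of the largest scheduled box (clipped at the
// image border), and for each box side in `scales` the number of cluster
// pixels inside the centered box is counted. Boxes are clipped at the
// border; masses use the available cells.
// [[Rcpp::export]]
List lcfd_masses(LogicalMatrix mask, IntegerVector scales) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const int ns = scales.size();
  const int smax = scales[ns - 1];
  const int R = (smax - 1) / 2;
  static const int dr8[] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dc8[] = {-1, 0, 1, -1, 1, -1, 0, 1};

  int nfg = 0;
  for (int i = 0; i < nr * nc; ++i) if (mask[i]) ++nfg;

  IntegerVector out_r(nfg), out_c(nfg);
  IntegerMatrix M(nfg, ns);
  std::vector<unsigned char> in_set(static_cast<size_t>(smax) * smax);
  std::vector<int> qr(static_cast<size_t>(smax) * smax), qc(qr.size());

  int idx = 0;
  for (int r0 = 0; r0 < nr; ++r0) {
    for (int c0 = 0; c0 < nc; ++c0) {
      if (!mask(r0, c0)) continue;
      const int rlo = std::max(0, r0 - R), rhi = std::min(nr - 1, r0 + R);
      const int clo = std::max(0, c0 - R), chi = std::min(nc - 1, c0 + R);
      const int wr = rhi - rlo + 1, wc = chi - clo + 1;
      std::fill(in_set.begin(), in_set.begin() + static_cast<size_t>(wr) * wc, 0);
      // BFS over the clipped window, local coordinates (i = row - rlo)
      int head = 0, tail = 0;
      const int i0 = r0 - rlo, j0 = c0 - clo;
      in_set[static_cast<size_t>(i0) * wc + j0] = 1;
      qr[tail] = i0; qc[tail] = j0; ++tail;
      while (head < tail) {
        const int i = qr[head], j = qc[head];
        ++head;
        for (int k = 0; k < 8; ++k) {
          const int ii = i + dr8[k], jj = j + dc8[k];
          if (ii < 0 || ii >= wr || jj < 0 || jj >= wc) continue;
          if (in_set[static_cast<size_t>(ii) * wc + jj]) continue;
          if (mask(rlo + ii, clo + jj)) {
            in_set[static_cast<size_t>(ii) * wc + jj] = 1;
            qr[tail] = ii; qc[tail] = jj; ++tail;
          }
        }
      }
      for (int s = 0; s < ns; ++s) {
        const int rad = (scales[s] - 1) / 2;
        const int bi0 = std::max(i0 - rad, 0), bi1 = std::min(i0 + rad, wr - 1);
        const int bj0 = std::max(j0 - rad, 0), bj1 = std::min(j0 + rad, wc - 1);
        int m = 0;
        for (int i = bi0; i <= bi1; ++i) {
          const unsigned char *row = &in_set[static_cast<size_t>(i) * wc];
          for (int j = bj0; j <= bj1; ++j) m += row[j];
        }
        M(idx, s) = m;
      }
      out_r[idx] = r0 + 1;  // back to R's 1-based indexing
      out_c[idx] = c0 + 1;
      ++idx;
    }
  }
  return List::create(_["row"] = out_r, _["col"] = out_c, _["mass"] = M);
}
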