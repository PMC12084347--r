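#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Minimum-image squared distance in an orthorhombic box.
static inline double mi_d2(double dx, double dy, double dz,
                           double lx, double ly, double lz) {
  dx -= lx * std::round(dx / lx);
  dy -= ly * std::round(dy / ly);
  dz -= lz * std::round(dz / lz);
  return dx * dx + dy * dy + dz * dz;
}

static inline int cell_of(double x, double l, int nc) {
  double w = x - l * std::floor(x / l);  // wrap into [0, l)
  int c = (int)std::floor(w / l * nc);
  if (c >= nc) c = nc - 1;               // guard rounding at the edge
  return c;
}

// Contact counting between two atom sets across frames.
//
// ca, cb : coordinates, dim (na x 3 x nf) and (nb x 3 x nf), Angstrom
// ga, gb : 1-based group id per atom (residue index, molecule index,
//          or atom-class index depending on the caller)
// box    : nf x 3 orthorhombic box edges
// binary : TRUE  -> count, per frame, whether ANY atom pair between the two
//                   groups is within cutoff (contact frequency numerator)
//          FALSE -> count every atom pair event (atomistic contact map)
// symmetric : the two sets are the same atoms; skip identical-group pairs,
//             canonicalise group order, and visit each atom pair once
//
// Returns an nga x ngb matrix of event counts summed over frames.
// [[Rcpp::export]]
NumericMatrix contact_counts_cpp(NumericVector ca, NumericVector cb,
                                 IntegerVector ga, IntegerVector gb,
                                 int nga, int ngb,
                                 NumericMatrix box, double cutoff,
                                 bool binary, bool symmetric) {
  IntegerVector da = ca.attr("dim"), db = cb.attr("dim");
  const int na = da[0], nb = db[0], nf = da[2];
  if (db[2] != nf) stop("coordinate sets disagree on frame count");
  const double cut2 = cutoff * cutoff;
  const double *pa = ca.begin(), *pb = cb.begin();

  NumericMatrix counts(nga, ngb);
  std::vector<int> stamp;                 // frame stamp for binary dedupe
  if (binary) stamp.assign((size_t)nga * ngb, -1);

  std::vector<int> head, nxt(nb);

  for (int f = 0; f < nf; ++f) {
    const double lx = box(f, 0), ly = box(f, 1), lz = box(f, 2);
    const double *fa = pa + (size_t)f * na * 3;
    const double *fb = pb + (size_t)f * nb * 3;

    auto emit = [&](int i, int j) {
      if (symmetric) {
        if (i >= j) return;               // each unordered pair once
        if (ga[i] == gb[j]) return;       // same group (e.g. same residue)
      }
      int g1 = ga[i] - 1, g2 = gb[j] - 1;
      if (symmetric && g1 > g2) std::swap(g1, g2);
      if (binary) {
        size_t k = (size_t)g2 * nga + g1;
        if (stamp[k] == f) return;
        stamp[k] = f;
      }
      counts(g1, g2) += 1.0;
    };

    int ncx = (int)std::floor(lx / cutoff), ncy = (int)std::floor(ly / cutoff),
        ncz = (int)std::floor(lz / cutoff);
    ncx = std::min(ncx, 48); ncy = std::min(ncy, 48); ncz = std::min(ncz, 48);

    if (ncx < 3 || ncy < 3 || ncz < 3) {
      // box too small for a periodic cell grid: all-pairs with min image
      for (int i = 0; i < na; ++i)
        for (int j = 0; j < nb; ++j)
          if (mi_d2(fa[i] - fb[j], fa[i + na] - fb[j + nb],
                    fa[i + 2 * na] - fb[j + 2 * nb], lx, ly, lz) <= cut2)
            emit(i, j);
      continue;
    }

    const int ncells = ncx * ncy * ncz;
    head.assign(ncells, -1);
    for (int j = 0; j < nb; ++j) {
      int cx = cell_of(fb[j], lx, ncx);
      int cy = cell_of(fb[j + nb], ly, ncy);
      int cz = cell_of(fb[j + 2 * nb], lz, ncz);
      int c = (cz * ncy + cy) * ncx + cx;
      nxt[j] = head[c];
      head[c] = j;
    }

    for (int i = 0; i < na; ++i) {
      const double xi = fa[i], yi = fa[i + na], zi = fa[i + 2 * na];
      const int cx = cell_of(xi, lx, ncx);
      const int cy = cell_of(yi, ly, ncy);
      const int cz = cell_of(zi, lz, ncz);
      for (int oz = -1; oz <= 1; ++oz) {
        int wz = (cz + oz + ncz) % ncz;
        for (int oy = -1; oy <= 1; ++oy) {
          int wy = (cy + oy + ncy) % ncy;
          for (int ox = -1; ox <= 1; ++ox) {
            int wx = (cx + ox + ncx) % ncx;
            for (int j = head[(wz * ncy + wy) * ncx + wx]; j != -1; j = nxt[j])
              if (mi_d2(xi - fb[j], yi - fb[j + nb], zi - fb[j + 2 * nb],
                        lx, ly, lz) <= cut2)
                emit(i, j);
          }
        }
      }
    }
  }
  return counts;
}

// 8-connected component labelling of a binary mask (iterative flood fill).
// Returns an integer matrix of labels, 0 = background.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0)) continue;
      ++next;
      lab(r0, c0) = next;
      stack.push_back(c0 * nr + r0);
      while (!stack.empty()) {
        int k = stack.back(); stack.pop_back();
        int r = k % nr, c = k / nr;
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (mask(rr, cc) && !lab(rr, cc)) {
              lab(rr, cc) = next;
              stack.push_back(cc * nr + rr);
            }
          }
        }
      }
    }
  }
  return lab;
}
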