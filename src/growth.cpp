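#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a logical mask.
// connectivity: 4 (edge adjacency) or 8 (edge + corner).
// Returns an integer matrix: 0 outside the mask, 1..k component ids
// assigned in raster scan order of each component's first pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int dr4[] = {-1, 1, 0, 0};
  int dc4[] = {0, 0, -1, 1};
  int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  int dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  int ndir = (connectivity == 8) ? 8 : 4;
  int *dr = (connectivity == 8) ? dr8 : dr4;
  int *dc = (connectivity == 8) ? dc8 : dc4;
  int next = 0;
  std::vector<int> stack;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0) != 0) continue;
      ++next;
      lab(r0, c0) = next;
      stack.clear();
      stack.push_back(r0 + c0 * nr);
      while (!stack.empty()) {
        int cell = stack.back();
        stack.pop_back();
        int r = cell % nr, c = cell / nr;
        for (int d = 0; d < ndir; ++d) {
          int rr = r + dr[d], cc = c + dc[d];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back(rr + cc * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Seeded multi-class region growing with per-class pixel quotas.
//
// footprint:  logical matrix, TRUE where growth is allowed.
// seed_cells: 0-based cell indices (column-major) of the seed pixels.
// seed_class: class id (1..K) for each seed.
// quota:      target pixel count per class (length K, summing to at most
//             the footprint size).
// roughness:  per-class probability in [0,1] of expanding a random
//             frontier entry instead of the oldest one; 0 gives compact
//             near-isotropic patches, values near 1 give ragged
//             Eden-growth boundaries.
//
// Uses R's RNG (honours set.seed). Cells left unassigned after all
// quotas are exhausted (enclosed pockets) are filled from the class of
// an already-assigned neighbour so the footprint is fully covered.
// [[Rcpp::export]]
IntegerMatrix cpp_grow_regions(LogicalMatrix footprint,
                               IntegerVector seed_cells,
                               IntegerVector seed_class,
                               IntegerVector quota,
                               NumericVector roughness) {
  int nr = footprint.nrow(), nc = footprint.ncol();
  int K = quota.size();
  IntegerMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), 0);
  std::vector<int> left(quota.begin(), quota.end());
  std::vector<int> fcell, fclass;
  fcell.reserve(nr * nc);
  fclass.reserve(nr * nc);
  int dr[] = {-1, 1, 0, 0};
  int dc[] = {0, 0, -1, 1};

  for (int i = 0; i < seed_cells.size(); ++i) {
    int cell = seed_cells[i];
    int cls = seed_class[i];
    int r = cell % nr, c = cell / nr;
    if (!footprint(r, c) || out(r, c) != 0 || left[cls - 1] <= 0) continue;
    out(r, c) = cls;
    --left[cls - 1];
    for (int d = 0; d < 4; ++d) {
      int rr = r + dr[d], cc = c + dc[d];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (footprint(rr, cc) && out(rr, cc) == 0) {
        fcell.push_back(rr + cc * nr);
        fclass.push_back(cls);
      }
    }
  }

  size_t head = 0;
  while (head < fcell.size()) {
    // peek at the oldest entry's class to pick the expansion policy
    double rough = roughness[fclass[head] - 1];
    size_t j = head;
    if (rough > 0.0 && unif_rand() < rough) {
      j = head + (size_t)(unif_rand() * (fcell.size() - head));
      if (j >= fcell.size()) j = fcell.size() - 1;
    }
    int cell = fcell[j], cls = fclass[j];
    fcell[j] = fcell[head];
    fclass[j] = fclass[head];
    ++head;
    int r = cell % nr, c = cell / nr;
    if (out(r, c) != 0 || left[cls - 1] <= 0) continue;
    out(r, c) = cls;
    --left[cls - 1];
    for (int d = 0; d < 4; ++d) {
      int rr = r + dr[d], cc = c + dc[d];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (footprint(rr, cc) && out(rr, cc) == 0) {
        fcell.push_back(rr + cc * nr);
        fclass.push_back(cls);
      }
    }
  }

  // Fill stranded pockets from an assigned neighbour, ignoring quotas —
  // but only when the quotas were meant to cover the whole footprint
  // (partial-coverage calls, e.g. footprint blob growth, keep their
  // unassigned cells).
  long fpsize = 0, qtot = 0;
  for (int i = 0; i < nr * nc; ++i) fpsize += footprint[i] ? 1 : 0;
  for (int k = 0; k < K; ++k) qtot += quota[k];
  bool changed = qtot >= fpsize;
  while (changed) {
    changed = false;
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        if (!footprint(r, c) || out(r, c) != 0) continue;
        for (int d = 0; d < 4; ++d) {
          int rr = r + dr[d], cc = c + dc[d];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (out(rr, cc) != 0) {
            out(r, c) = out(rr, cc);
            changed = true;
            break;
          }
        }
      }
    }
  }
  return out;
}
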