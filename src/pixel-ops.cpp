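#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Offsets for 4- and 8-connectivity (row, col).
static const int DR8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
static const int DR4[4] = {-1, 0, 0, 1};
static const int DC4[4] = {0, -1, 1, 0};

// Label connected components of a logical mask. Unlabelled pixels get 0.
// [[Rcpp::export]]
IntegerMatrix label_mask_cpp(LogicalMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  const int n_nbr = (connectivity == 8) ? 8 : 4;
  const int *dr = (connectivity == 8) ? DR8 : DR4;
  const int *dc = (connectivity == 8) ? DC8 : DC4;
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  for (int c0 = 0; c0 < W; ++c0) {
    for (int r0 = 0; r0 < H; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0) != 0) continue;
      ++next;
      lab(r0, c0) = next;
      stack.clear();
      stack.push_back(r0 + c0 * H);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int r = idx % H, c = idx / H;
        for (int k = 0; k < n_nbr; ++k) {
          int rr = r + dr[k], cc = c + dc[k];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back(rr + cc * H);
          }
        }
      }
    }
  }
  return lab;
}

// Label 8-connected components of equal pixel value (plateau labelling).
// [[Rcpp::export]]
IntegerMatrix label_equal_cpp(IntegerMatrix img) {
  const int H = img.nrow(), W = img.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  for (int c0 = 0; c0 < W; ++c0) {
    for (int r0 = 0; r0 < H; ++r0) {
      if (lab(r0, c0) != 0) continue;
      ++next;
      int v = img(r0, c0);
      lab(r0, c0) = next;
      stack.clear();
      stack.push_back(r0 + c0 * H);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int r = idx % H, c = idx / H;
        for (int k = 0; k < 8; ++k) {
          int rr = r + DR8[k], cc = c + DC8[k];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (lab(rr, cc) == 0 && img(rr, cc) == v) {
            lab(rr, cc) = next;
            stack.push_back(rr + cc * H);
          }
        }
      }
    }
  }
  return lab;
}

// Flood from the seed pixels over pixels with value >= floor_val (8-connected);
// return true as soon as a pixel with value > peak_val is reached.
// seed_idx holds 0-based column-major linear indices.
// [[Rcpp::export]]
bool reaches_higher_cpp(IntegerMatrix img, IntegerVector seed_idx,
                        double floor_val, double peak_val) {
  const int H = img.nrow(), W = img.ncol();
  std::vector<bool> seen(static_cast<size_t>(H) * W, false);
  std::vector<int> stack;
  for (int i = 0; i < seed_idx.size(); ++i) {
    int idx = seed_idx[i];
    if (!seen[idx]) {
      seen[idx] = true;
      stack.push_back(idx);
    }
  }
  while (!stack.empty()) {
    int idx = stack.back();
    stack.pop_back();
    int r = idx % H, c = idx / H;
    for (int k = 0; k < 8; ++k) {
      int rr = r + DR8[k], cc = c + DC8[k];
      if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
      int nidx = rr + cc * H;
      if (seen[nidx]) continue;
      double v = img(rr, cc);
      if (v > peak_val) return true;
      if (v >= floor_val) {
        seen[nidx] = true;
        stack.push_back(nidx);
      }
    }
  }
  return false;
}

// Per-pixel max (and min) over the 8-neighbourhood; pixels outside the image
// contribute pad_max / pad_min respectively.
// [[Rcpp::export]]
List neighbour_extrema_cpp(IntegerMatrix img) {
  const int H = img.nrow(), W = img.ncol();
  IntegerMatrix nmax(H, W), nmin(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      int mx = INT_MIN, mn = INT_MAX;
      for (int k = 0; k < 8; ++k) {
        int rr = r + DR8[k], cc = c + DC8[k];
        if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
        int v = img(rr, cc);
        if (v > mx) mx = v;
        if (v < mn) mn = v;
      }
      nmax(r, c) = mx;
      nmin(r, c) = mn;
    }
  }
  return List::create(_["max"] = nmax, _["min"] = nmin);
}
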