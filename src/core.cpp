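// Pixel-level cores: nuclear-stain candidate detection, connected-component
// labelling, and greedy confidence NMS. Kept in C++ because the end-to-end
// slide simulations touch O(1e10) pixels; algorithms mirror the documented
// R-level contracts exactly.
#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>
#include <climits>
#include <algorithm>
#include <functional>
using namespace Rcpp;

static inline double clamp01(double v) {
  return v < 0.0 ? 0.0 : (v > 1.0 ? 1.0 : v);
}

struct UnionFind {
  std::vector<int> parent;
  explicit UnionFind(int n) : parent(n) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int i) {
    while (parent[i] != i) {
      parent[i] = parent[parent[i]];
      i = parent[i];
    }
    return i;
  }
  void unite(int a, int b) {
    a = find(a);
    b = find(b);
    if (a != b) parent[b] = a;
  }
};

// 4-connected component labelling of a binary mask (vector, column-major
// hgt x wid). Returns labels (0 = background, 1..k) for testing against an
// independent labeller.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, int hgt, int wid) {
  const R_xlen_t n = static_cast<R_xlen_t>(hgt) * wid;
  UnionFind uf(static_cast<int>(n));
  const int *m = LOGICAL(mask);
  for (int x = 0; x < wid; ++x) {
    for (int y = 0; y < hgt; ++y) {
      R_xlen_t i = static_cast<R_xlen_t>(x) * hgt + y;
      if (!m[i]) continue;
      if (y > 0 && m[i - 1]) uf.unite((int)i, (int)(i - 1));
      if (x > 0 && m[i - hgt]) uf.unite((int)i, (int)(i - hgt));
    }
  }
  IntegerVector lab(n);
  std::vector<int> remap(n, 0);
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!m[i]) {
      lab[i] = 0;
      continue;
    }
    int r = uf.find((int)i);
    if (remap[r] == 0) remap[r] = ++next;
    lab[i] = remap[r];
  }
  return lab;
}

// Candidate detection on a rectangular region of a slide held as a numeric
// array dim (H, W, 3). rect = c(x0, y0, x1, y1), half-open pixel intervals.
// open_edges = c(left, top, right, bottom): TRUE where the window edge is an
// interior cut (candidates hugging such an edge are suppressed; an
// overlapping neighbour window sees them whole).
// Returns matrix with columns x0, y0, x1, y1, confidence in slide coordinates.
// [[Rcpp::export]]
NumericMatrix detect_region_cpp(NumericVector slide, int H, int W,
                                IntegerVector rect, double scale,
                                LogicalVector open_edges, List opts) {
  const double nuc_thresh = as<double>(opts["nuc_thresh"]);
  const int min_area = as<int>(opts["min_area"]);
  const double link_dist = as<double>(opts["link_frac"]) * scale;
  const double ring_r = as<double>(opts["ring_frac"]) * scale;
  const double pad_min = as<double>(opts["pad_frac"]) * scale;
  const double w_lobe = as<double>(opts["w_lobe"]);
  const double w_area = as<double>(opts["w_area"]);
  const double w_ann = as<double>(opts["w_ann"]);
  const int border_margin = as<int>(opts["border_margin"]);

  const int rx0 = rect[0], ry0 = rect[1], rx1 = rect[2], ry1 = rect[3];
  const int ww = rx1 - rx0, wh = ry1 - ry0;
  const R_xlen_t plane = static_cast<R_xlen_t>(H) * W;
  const double *pr = REAL(slide), *pg = REAL(slide) + plane,
               *pb = REAL(slide) + 2 * plane;

  // nuclear mask over the window
  std::vector<uint8_t> mask(static_cast<size_t>(ww) * wh);
  for (int x = 0; x < ww; ++x) {
    R_xlen_t col = static_cast<R_xlen_t>(x + rx0) * H + ry0;
    size_t mcol = static_cast<size_t>(x) * wh;
    for (int y = 0; y < wh; ++y) {
      R_xlen_t i = col + y;
      double val = (pr[i] + pg[i] + pb[i]) / 3.0;
      mask[mcol + y] = val < nuc_thresh;
    }
  }

  // connected components (4-connectivity), window raster order
  const size_t n = mask.size();
  std::vector<int> parent(n);
  for (size_t i = 0; i < n; ++i) parent[i] = (int)i;
  std::function<int(int)> find = [&](int i) {
    while (parent[i] != i) {
      parent[i] = parent[parent[i]];
      i = parent[i];
    }
    return i;
  };
  for (int x = 0; x < ww; ++x) {
    for (int y = 0; y < wh; ++y) {
      size_t i = static_cast<size_t>(x) * wh + y;
      if (!mask[i]) continue;
      if (y > 0 && mask[i - 1]) {
        int a = find((int)i), b = find((int)(i - 1));
        if (a != b) parent[b] = a;
      }
      if (x > 0 && mask[i - wh]) {
        int a = find((int)i), b = find((int)(i - wh));
        if (a != b) parent[b] = a;
      }
    }
  }
  // accumulate per-root stats
  std::vector<int> comp_id(n, -1);
  std::vector<double> area, sx, sy;
  std::vector<int> bx0, by0, bx1, by1;
  for (int x = 0; x < ww; ++x) {
    for (int y = 0; y < wh; ++y) {
      size_t i = static_cast<size_t>(x) * wh + y;
      if (!mask[i]) continue;
      int r = find((int)i);
      int id = comp_id[r];
      if (id < 0) {
        id = (int)area.size();
        comp_id[r] = id;
        area.push_back(0);
        sx.push_back(0);
        sy.push_back(0);
        bx0.push_back(x);
        by0.push_back(y);
        bx1.push_back(x);
        by1.push_back(y);
      }
      area[id] += 1;
      sx[id] += x;
      sy[id] += y;
      if (x < bx0[id]) bx0[id] = x;
      if (x > bx1[id]) bx1[id] = x;
      if (y < by0[id]) by0[id] = y;
      if (y > by1[id]) by1[id] = y;
    }
  }
  // lobes = components above the speck floor
  std::vector<int> keep;
  for (size_t c = 0; c < area.size(); ++c)
    if (area[c] >= min_area) keep.push_back((int)c);
  const int k = (int)keep.size();
  if (k == 0) return NumericMatrix(0, 5);

  std::vector<double> lcx(k), lcy(k);
  for (int i = 0; i < k; ++i) {
    lcx[i] = sx[keep[i]] / area[keep[i]];
    lcy[i] = sy[keep[i]] / area[keep[i]];
  }
  // single-linkage grouping of lobes by centroid distance
  UnionFind guf(k);
  const double link2 = link_dist * link_dist;
  for (int i = 0; i < k; ++i)
    for (int j = i + 1; j < k; ++j) {
      double dx = lcx[i] - lcx[j], dy = lcy[i] - lcy[j];
      if (dx * dx + dy * dy <= link2) guf.unite(i, j);
    }
  std::vector<int> gid(k, -1);
  int ng = 0;
  for (int i = 0; i < k; ++i) {
    int r = guf.find(i);
    if (gid[r] < 0) gid[r] = ng++;
    gid[i] = gid[r];
  }
  std::vector<int> g_n(ng, 0), g_bx0(ng, INT_MAX), g_by0(ng, INT_MAX),
      g_bx1(ng, INT_MIN), g_by1(ng, INT_MIN);
  std::vector<double> g_area(ng, 0), g_sx(ng, 0), g_sy(ng, 0);
  for (int i = 0; i < k; ++i) {
    int g = gid[guf.find(i)];
    int c = keep[i];
    g_n[g] += 1;
    g_area[g] += area[c];
    g_sx[g] += sx[c];
    g_sy[g] += sy[c];
    g_bx0[g] = std::min(g_bx0[g], bx0[c]);
    g_by0[g] = std::min(g_by0[g], by0[c]);
    g_bx1[g] = std::max(g_bx1[g], bx1[c]);
    g_by1[g] = std::max(g_by1[g], by1[c]);
  }

  const double cell_area = M_PI * scale * scale / 4.0;
  std::vector<double> rx0v, ry0v, rx1v, ry1v, confv;
  for (int g = 0; g < ng; ++g) {
    // lobe-count score: 2-5 lobes favoured (lobulated nucleus cue)
    int nl = g_n[g];
    double ls = nl == 1 ? 0.2 : (nl >= 2 && nl <= 5 ? 1.0 : (nl <= 7 ? 0.5 : 0.2));
    // nuclear-area score: plateau over the plausible lobed-nucleus range
    double ar = g_area[g] / cell_area;
    double as;
    if (ar <= 0.05 || ar >= 0.95)
      as = 0.0;
    else if (ar < 0.09)
      as = (ar - 0.05) / 0.04;
    else if (ar <= 0.60)
      as = 1.0;
    else
      as = (0.95 - ar) / 0.35;
    // cytoplasm annulus: lighter basophilic ring around the nucleus group
    double gcx = g_sx[g] / g_area[g] + rx0, gcy = g_sy[g] / g_area[g] + ry0;
    int hits = 0, tot = 0;
    for (int s = 0; s < 48; ++s) {
      double a = 2.0 * M_PI * s / 48.0;
      int px = (int)std::lround(gcx + ring_r * std::cos(a));
      int py = (int)std::lround(gcy + ring_r * std::sin(a));
      if (px < 0 || px >= W || py < 0 || py >= H) continue;
      R_xlen_t i = static_cast<R_xlen_t>(px) * H + py;
      double val = (pr[i] + pg[i] + pb[i]) / 3.0;
      ++tot;
      if (pb[i] >= pr[i] + 0.02 && val >= 0.55 && val <= 0.92) ++hits;
    }
    double ann = tot == 0 ? 0.0 : std::min(1.0, (double)hits / tot / 0.8);
    double conf = clamp01(w_lobe * ls + w_area * as + w_ann * ann);

    // tight lobe bbox in slide coords, padded to >= pad_min per axis
    double bxa = g_bx0[g] + rx0, bya = g_by0[g] + ry0;
    double bxb = g_bx1[g] + 1 + rx0, byb = g_by1[g] + 1 + ry0;
    double cw = bxb - bxa, ch = byb - bya;
    if (cw < pad_min) {
      double cx = (bxa + bxb) / 2;
      bxa = cx - pad_min / 2;
      bxb = cx + pad_min / 2;
    }
    if (ch < pad_min) {
      double cy = (bya + byb) / 2;
      bya = cy - pad_min / 2;
      byb = cy + pad_min / 2;
    }
    // suppress candidates hugging an interior window cut
    if (open_edges[0] && bxa < rx0 + border_margin) continue;
    if (open_edges[1] && bya < ry0 + border_margin) continue;
    if (open_edges[2] && bxb > rx1 - border_margin) continue;
    if (open_edges[3] && byb > ry1 - border_margin) continue;
    // clip to slide bounds
    bxa = std::max(0.0, bxa);
    bya = std::max(0.0, bya);
    bxb = std::min((double)W, bxb);
    byb = std::min((double)H, byb);
    if (bxb <= bxa || byb <= bya) continue;
    rx0v.push_back(bxa);
    ry0v.push_back(bya);
    rx1v.push_back(bxb);
    ry1v.push_back(byb);
    confv.push_back(conf);
  }
  NumericMatrix out((int)confv.size(), 5);
  for (int i = 0; i < (int)confv.size(); ++i) {
    out(i, 0) = rx0v[i];
    out(i, 1) = ry0v[i];
    out(i, 2) = rx1v[i];
    out(i, 3) = ry1v[i];
    out(i, 4) = confv[i];
  }
  colnames(out) = CharacterVector::create("x0", "y0", "x1", "y1", "confidence");
  return out;
}

// Greedy non-maximum suppression: rows must be sorted by descending
// confidence; keeps a row unless it overlaps an already-kept row with
// IOU >= thr. Returns a logical keep vector.
// [[Rcpp::export]]
LogicalVector nms_keep_cpp(NumericMatrix boxes, double thr) {
  const int n = boxes.nrow();
  LogicalVector keep(n);
  std::vector<int> kept;
  kept.reserve(n);
  for (int i = 0; i < n; ++i) {
    double ax0 = boxes(i, 0), ay0 = boxes(i, 1), ax1 = boxes(i, 2),
           ay1 = boxes(i, 3);
    double aarea = (ax1 - ax0) * (ay1 - ay0);
    bool ok = true;
    for (int j : kept) {
      double bx0 = boxes(j, 0), by0 = boxes(j, 1), bx1 = boxes(j, 2),
             by1 = boxes(j, 3);
      double ix = std::min(ax1, bx1) - std::max(ax0, bx0);
      if (ix <= 0) continue;
      double iy = std::min(ay1, by1) - std::max(ay0, by0);
      if (iy <= 0) continue;
      double inter = ix * iy;
      double uni = aarea + (bx1 - bx0) * (by1 - by0) - inter;
      if (inter / uni >= thr) {
        ok = false;
        break;
      }
    }
    keep[i] = ok;
    if (ok) kept.push_back(i);
  }
  return keep;
}
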