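// Synthetic tile/case planning and rendering core. Planning (rejection
// placement and distractor layout) and rendering live here so that a
// 200-HPF case costs milliseconds; the single-tile R API and the mosaic
// path call the same routines, so a tile generated alone is byte-identical
// to the same tile inside a case mosaic.
#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>
using namespace Rcpp;

// RNG shared with core.cpp (duplicated definition kept local via namespace)
namespace synth {
struct Rng {
  uint64_t s0, s1;
  explicit Rng(uint64_t seed) {
    uint64_t z = seed + 0x9E3779B97F4A7C15ULL;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    s0 = z ^ (z >> 31);
    z = seed + 2 * 0x9E3779B97F4A7C15ULL;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    s1 = z ^ (z >> 31);
    if (s0 == 0 && s1 == 0) s1 = 1;
  }
  uint64_t next() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  double unif(double a, double b) { return a + (b - a) * unif(); }
  // one draw, two independent 32-bit uniforms: cheap triangular noise
  double tri() {
    uint64_t x = next();
    double u1 = (x >> 32) * (1.0 / 4294967296.0);
    double u2 = (x & 0xffffffffULL) * (1.0 / 4294967296.0);
    return u1 + u2 - 1.0;
  }
  int randint(int lo, int hi) { // inclusive
    int v = lo + (int)(unif() * (hi - lo + 1));
    return v > hi ? hi : v;
  }
};

struct Disc {
  double cx, cy, r, col[3];
};

// palette rows (fixed order, supplied from R):
// 0 cytoplasm, 1 nucleus, 2 lymph_rim, 3 lymph_nucleus, 4 rbc, 5 necrotic
static void add_disc(std::vector<Disc> &v, double cx, double cy, double r,
                     const NumericMatrix &pal, int row) {
  Disc d;
  d.cx = cx;
  d.cy = cy;
  d.r = r;
  d.col[0] = pal(row, 0);
  d.col[1] = pal(row, 1);
  d.col[2] = pal(row, 2);
  v.push_back(d);
}

// IOU of two axis-aligned squares of side s
static double square_iou(double s, double dx, double dy) {
  double w = s - std::fabs(dx), h = s - std::fabs(dy);
  if (w <= 0 || h <= 0) return 0.0;
  double inter = w * h;
  return inter / (2 * s * s - inter);
}

// plan one tile: returns false when the tile cannot host target_count
// targets (capacity)
static bool plan_tile(Rng &rng, int tw, int th, int n_targets, double size,
                      int n_lymph, int n_rbc, int n_necro,
                      const NumericMatrix &pal, double min_dist,
                      std::vector<Disc> &discs, std::vector<double> &tx,
                      std::vector<double> &ty) {
  const double u = size / 40.0;
  const double lo_x = size / 2 + 1, hi_x = tw - size / 2 - 1;
  const double lo_y = size / 2 + 1, hi_y = th - size / 2 - 1;
  if (hi_x <= lo_x || hi_y <= lo_y) return false;
  for (int i = 0; i < n_targets; ++i) {
    bool placed = false;
    for (int t = 0; t < 200; ++t) {
      double cx = rng.unif(lo_x, hi_x), cy = rng.unif(lo_y, hi_y);
      bool ok = true;
      for (size_t j = 0; j < tx.size() && ok; ++j) {
        double dx = cx - tx[j], dy = cy - ty[j];
        if (square_iou(size, dx, dy) > 0.3) ok = false;
        if (min_dist > 0 && dx * dx + dy * dy < min_dist * min_dist) ok = false;
      }
      if (ok) {
        tx.push_back(cx);
        ty.push_back(cy);
        placed = true;
        break;
      }
    }
    if (!placed) return false;
  }
  // neutrophils: cytoplasm disc + 2-5 lobes on a ring with separable gaps
  for (size_t i = 0; i < tx.size(); ++i) {
    add_disc(discs, tx[i], ty[i], 19 * u, pal, 0);
    int k = rng.randint(2, 5);
    double rot = rng.unif(0, 2 * M_PI);
    double lobe_r = 4.5 * u;
    double ring = (k == 2) ? 5.25 * u : (10.5 * u) / (2 * std::sin(M_PI / k));
    for (int l = 1; l <= k; ++l) {
      double a = rot + 2 * M_PI * l / k;
      add_disc(discs, tx[i] + ring * std::cos(a), ty[i] + ring * std::sin(a),
               lobe_r, pal, 1);
    }
  }
  // distractors: best effort, kept clear of target cells and of each
  // other (cell bodies do not interpenetrate; adjacent free nuclei would
  // otherwise mimic a lobulated cluster)
  const int counts[3] = {n_lymph, n_rbc, n_necro};
  std::vector<double> dxs, dys;
  for (int kind = 0; kind < 3; ++kind) {
    for (int c = 0; c < counts[kind]; ++c) {
      for (int t = 0; t < 100; ++t) {
        double cx = rng.unif(10 * u, tw - 10 * u);
        double cy = rng.unif(10 * u, th - 10 * u);
        bool clear = true;
        for (size_t j = 0; j < tx.size() && clear; ++j) {
          double dx = cx - tx[j], dy = cy - ty[j];
          if (dx * dx + dy * dy < (26 * u) * (26 * u)) clear = false;
        }
        for (size_t j = 0; j < dxs.size() && clear; ++j) {
          double dx = cx - dxs[j], dy = cy - dys[j];
          if (dx * dx + dy * dy < (28 * u) * (28 * u)) clear = false;
        }
        if (!clear) continue;
        dxs.push_back(cx);
        dys.push_back(cy);
        if (kind == 0) { // lymphocyte: thin rim + single round nucleus
          add_disc(discs, cx, cy, 7.5 * u, pal, 2);
          add_disc(discs, cx, cy, 5.5 * u, pal, 3);
        } else if (kind == 1) { // red blood cell: anucleate pink disc
          add_disc(discs, cx, cy, 7 * u, pal, 4);
        } else { // necrotic fragment: 2-3 tiny dark specks
          int m = rng.randint(2, 3);
          for (int s = 0; s < m; ++s) {
            add_disc(discs, cx + rng.unif(-5 * u, 5 * u),
                     cy + rng.unif(-5 * u, 5 * u), rng.unif(1.5, 2.2) * u,
                     pal, 5);
          }
        }
        break;
      }
    }
  }
  return true;
}

static inline double clamp01(double v) {
  return v < 0.0 ? 0.0 : (v > 1.0 ? 1.0 : v);
}

// render one planned tile into a slide buffer at offset (ox, oy);
// buffer is column-major (H, W, 3)
static void render_into(double *buf, int H, int W, int ox, int oy, int tw,
                        int th, const double *bg,
                        const std::vector<Disc> &discs, double noise_sd,
                        uint64_t noise_seed) {
  const R_xlen_t plane = static_cast<R_xlen_t>(H) * W;
  double *ch[3] = {buf, buf + plane, buf + 2 * plane};
  for (int c = 0; c < 3; ++c) {
    for (int x = 0; x < tw; ++x) {
      double *col = ch[c] + static_cast<R_xlen_t>(ox + x) * H + oy;
      for (int y = 0; y < th; ++y) col[y] = bg[c];
    }
  }
  for (const Disc &d : discs) {
    double r2 = d.r * d.r;
    int xlo = std::max(0, (int)std::floor(d.cx - d.r));
    int xhi = std::min(tw - 1, (int)std::ceil(d.cx + d.r));
    int ylo = std::max(0, (int)std::floor(d.cy - d.r));
    int yhi = std::min(th - 1, (int)std::ceil(d.cy + d.r));
    for (int x = xlo; x <= xhi; ++x) {
      double dx = x - d.cx;
      R_xlen_t col = static_cast<R_xlen_t>(ox + x) * H + oy;
      for (int y = ylo; y <= yhi; ++y) {
        double dy = y - d.cy;
        if (dx * dx + dy * dy <= r2) {
          ch[0][col + y] = d.col[0];
          ch[1][col + y] = d.col[1];
          ch[2][col + y] = d.col[2];
        }
      }
    }
  }
  if (noise_sd > 0) {
    const double k = noise_sd * std::sqrt(6.0);
    Rng rng(noise_seed);
    // column-major over the tile so the stream is layout-independent
    for (int x = 0; x < tw; ++x) {
      R_xlen_t col = static_cast<R_xlen_t>(ox + x) * H + oy;
      for (int y = 0; y < th; ++y) {
        double n = k * rng.tri();
        ch[0][col + y] = clamp01(ch[0][col + y] + n);
        ch[1][col + y] = clamp01(ch[1][col + y] + n);
        ch[2][col + y] = clamp01(ch[2][col + y] + n);
      }
    }
  }
}
} // namespace synth

// Plan + render one tile. Returns list(image, centres) where centres are
// the planted target centres (n x 2).
// [[Rcpp::export]]
List generate_tile_cpp(double seed, double noise_seed, int tile_w, int tile_h,
                       int target_count, double target_size,
                       IntegerVector distractor_counts, NumericMatrix palette,
                       NumericVector background, double noise_sd,
                       double min_dist) {
  synth::Rng rng(static_cast<uint64_t>(seed));
  std::vector<synth::Disc> discs;
  std::vector<double> tx, ty;
  bool ok = synth::plan_tile(rng, tile_w, tile_h, target_count, target_size,
                             distractor_counts[0], distractor_counts[1],
                             distractor_counts[2], palette, min_dist, discs,
                             tx, ty);
  if (!ok)
    stop("tile capacity exceeded: could not place %d targets of size %.0f in %d x %d",
         target_count, target_size, tile_w, tile_h);
  NumericVector img(static_cast<R_xlen_t>(tile_h) * tile_w * 3);
  synth::render_into(REAL(img), tile_h, tile_w, 0, 0, tile_w, tile_h,
                     REAL(background), discs, noise_sd,
                     static_cast<uint64_t>(noise_seed));
  img.attr("dim") = IntegerVector::create(tile_h, tile_w, 3);
  NumericMatrix centres((int)tx.size(), 2);
  for (int i = 0; i < (int)tx.size(); ++i) {
    centres(i, 0) = tx[i];
    centres(i, 1) = ty[i];
  }
  return List::create(_["image"] = img, _["centres"] = centres);
}

// Plan + render a whole case mosaic in one call. seeds/noise_seeds/counts
// have one entry per HPF tile; tiles are laid out in raster order on an
// ncol-wide grid. Returns list(slide, truth, offsets).
// [[Rcpp::export]]
List render_case_cpp(NumericVector seeds, NumericVector noise_seeds,
                     IntegerVector counts, int ncol, int tile_w, int tile_h,
                     double target_size, IntegerVector distractor_counts,
                     NumericMatrix palette, NumericVector background,
                     double noise_sd, double min_dist) {
  const int n = seeds.size();
  const int nrow = (n + ncol - 1) / ncol;
  const int H = nrow * tile_h, W = ncol * tile_w;
  NumericVector slide(static_cast<R_xlen_t>(H) * W * 3);
  // background-fill only the padding cells past the n real tiles (each
  // real tile fills its own cell during rendering)
  const R_xlen_t plane = static_cast<R_xlen_t>(H) * W;
  for (int i = n; i < nrow * ncol; ++i) {
    int ox = (i % ncol) * tile_w, oy = (i / ncol) * tile_h;
    for (int c = 0; c < 3; ++c) {
      double v = background[c];
      double *p = REAL(slide) + c * plane;
      for (int x = 0; x < tile_w; ++x) {
        double *col = p + static_cast<R_xlen_t>(ox + x) * H + oy;
        for (int y = 0; y < tile_h; ++y) col[y] = v;
      }
    }
  }
  std::vector<double> truth_x, truth_y;
  std::vector<int> truth_tile;
  for (int i = 0; i < n; ++i) {
    synth::Rng rng(static_cast<uint64_t>(seeds[i]));
    std::vector<synth::Disc> discs;
    std::vector<double> tx, ty;
    bool ok = synth::plan_tile(rng, tile_w, tile_h, counts[i], target_size,
                               distractor_counts[0], distractor_counts[1],
                               distractor_counts[2], palette, min_dist, discs,
                               tx, ty);
    if (!ok)
      stop("tile capacity exceeded in HPF %d (%d targets)", i + 1, counts[i]);
    int ox = (i % ncol) * tile_w, oy = (i / ncol) * tile_h;
    synth::render_into(REAL(slide), H, W, ox, oy, tile_w, tile_h,
                       REAL(background), discs, noise_sd,
                       static_cast<uint64_t>(noise_seeds[i]));
    for (size_t j = 0; j < tx.size(); ++j) {
      truth_x.push_back(tx[j] + ox);
      truth_y.push_back(ty[j] + oy);
      truth_tile.push_back(i + 1);
    }
  }
  slide.attr("dim") = IntegerVector::create(H, W, 3);
  const int m = (int)truth_x.size();
  NumericMatrix truth(m, 4);
  IntegerVector hpf(m);
  const double half = target_size / 2.0;
  for (int j = 0; j < m; ++j) {
    truth(j, 0) = truth_x[j] - half;
    truth(j, 1) = truth_y[j] - half;
    truth(j, 2) = truth_x[j] + half;
    truth(j, 3) = truth_y[j] + half;
    hpf[j] = truth_tile[j];
  }
  colnames(truth) = CharacterVector::create("x0", "y0", "x1", "y1");
  return List::create(_["slide"] = slide, _["truth"] = truth, _["hpf"] = hpf);
}
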