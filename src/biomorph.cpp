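// Core biomorph development and rasterization pipeline.
//
// Coordinates are exact integers from genotype drawing through segment
// merging; the only floating point enters at rasterization, where pixel
// boundary incidence is still decided by integer arithmetic (the affine
// map to grid units is rational with an integer denominator).

#include <Rcpp.h>
#include <array>
#include <map>
#include <tuple>
#include <vector>
#include <algorithm>
#include <numeric>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

typedef long long ll;

static ll igcd(ll a, ll b) {
  if (a < 0) a = -a;
  if (b < 0) b = -b;
  while (b) { ll t = a % b; a = b; b = t; }
  return a;
}

// ---------------------------------------------------------------------------
// Drawing: recursive development
// ---------------------------------------------------------------------------

struct SegI { ll x0, y0, x1, y1; };

static void vectors_from_genes(const int* g, ll vx[9], ll vy[9]) {
  // index 1..8; g is 0-based g[0]..g[8]
  vx[1] = -g[2]; vy[1] = g[6];
  vx[2] = -g[1]; vy[2] = g[5];
  vx[3] = -g[0]; vy[3] = g[4];
  vx[4] = 0;     vy[4] = g[3];
  vx[5] = g[0];  vy[5] = g[4];
  vx[6] = g[1];  vy[6] = g[5];
  vx[7] = g[2];  vy[7] = g[6];
  vx[8] = 0;     vy[8] = g[7];
}

static void draw_rec(int i, int c, ll x0, ll y0, const ll vx[9], const ll vy[9],
                     std::vector<SegI>& out) {
  if (i == 0) i = 8; else if (i == 9) i = 1;
  ll xn = x0 + (ll)c * vx[i];
  ll yn = y0 + (ll)c * vy[i];
  out.push_back({x0, y0, xn, yn});
  if (c > 1) {
    draw_rec(i - 1, c - 1, xn, yn, vx, vy, out);
    draw_rec(i + 1, c - 1, xn, yn, vx, vy, out);
  }
}

static std::vector<SegI> draw_genotype(const int* g) {
  ll vx[9], vy[9];
  vectors_from_genes(g, vx, vy);
  std::vector<SegI> out;
  int g9 = g[8];
  out.reserve((size_t(1) << g9) - 1);
  draw_rec(4, g9, 0, 0, vx, vy, out);
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_draw(IntegerVector genotype) {
  std::vector<SegI> segs = draw_genotype(INTEGER(genotype));
  IntegerMatrix m(segs.size(), 4);
  for (size_t i = 0; i < segs.size(); ++i) {
    m(i, 0) = segs[i].x0; m(i, 1) = segs[i].y0;
    m(i, 2) = segs[i].x1; m(i, 3) = segs[i].y1;
  }
  colnames(m) = CharacterVector::create("x0", "y0", "x1", "y1");
  return m;
}

// ---------------------------------------------------------------------------
// Merging coincident / overlapping collinear segments
// ---------------------------------------------------------------------------

// Segments are grouped by the (primitive direction, offset) of their
// supporting line; 1D interval union along the line removes duplicated and
// partially overlapping pieces while preserving the covered point set.
// Zero-length segments cover no length and are dropped.
static std::vector<SegI> merge_segments(const std::vector<SegI>& in) {
  typedef std::tuple<ll, ll, ll> LineKey; // ux, uy, c = ux*y0 - uy*x0
  struct LineData {
    ll ux, uy;
    ll refx, refy, refs;             // reference lattice point and its s
    std::vector<std::pair<ll, ll>> iv; // intervals in s units
  };
  std::map<LineKey, LineData> lines;

  for (const SegI& s : in) {
    ll dx = s.x1 - s.x0, dy = s.y1 - s.y0;
    if (dx == 0 && dy == 0) continue;
    ll g = igcd(dx, dy);
    ll ux = dx / g, uy = dy / g;
    if (ux < 0 || (ux == 0 && uy < 0)) { ux = -ux; uy = -uy; }
    ll c = ux * s.y0 - uy * s.x0;
    ll s0 = ux * s.x0 + uy * s.y0;
    ll s1 = ux * s.x1 + uy * s.y1;
    if (s0 > s1) std::swap(s0, s1);
    LineKey key(ux, uy, c);
    auto it = lines.find(key);
    if (it == lines.end()) {
      LineData d;
      d.ux = ux; d.uy = uy;
      d.refx = s.x0; d.refy = s.y0;
      d.refs = ux * s.x0 + uy * s.y0;
      d.iv.push_back({s0, s1});
      lines.emplace(key, d);
    } else {
      it->second.iv.push_back({s0, s1});
    }
  }

  std::vector<SegI> out;
  for (auto& kv : lines) {
    LineData& d = kv.second;
    std::sort(d.iv.begin(), d.iv.end());
    ll norm2 = d.ux * d.ux + d.uy * d.uy;
    size_t i = 0;
    while (i < d.iv.size()) {
      ll a = d.iv[i].first, b = d.iv[i].second;
      size_t j = i + 1;
      while (j < d.iv.size() && d.iv[j].first <= b) {
        b = std::max(b, d.iv[j].second);
        ++j;
      }
      // reconstruct lattice endpoints from s values
      ll ka = (a - d.refs) / norm2, kb = (b - d.refs) / norm2;
      out.push_back({d.refx + ka * d.ux, d.refy + ka * d.uy,
                     d.refx + kb * d.ux, d.refy + kb * d.uy});
      i = j;
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_merge(IntegerMatrix segs) {
  std::vector<SegI> in(segs.nrow());
  for (int i = 0; i < segs.nrow(); ++i)
    in[i] = {segs(i, 0), segs(i, 1), segs(i, 2), segs(i, 3)};
  std::vector<SegI> out = merge_segments(in);
  IntegerMatrix m(out.size(), 4);
  for (size_t i = 0; i < out.size(); ++i) {
    m(i, 0) = out[i].x0; m(i, 1) = out[i].y0;
    m(i, 2) = out[i].x1; m(i, 3) = out[i].y1;
  }
  colnames(m) = CharacterVector::create("x0", "y0", "x1", "y1");
  return m;
}

// ---------------------------------------------------------------------------
// Rasterization
// ---------------------------------------------------------------------------

// Accumulates per-pixel clipped lengths (in pixel-side units) of a merged
// drawing on a G x G grid sized (100+margin_pct)% of the figure's longer
// dimension, figure centered. Storage is row-major with row 0 at the TOP
// (large mathematical y); columns increase with x.
//
// The grid-unit x coordinate of a point is sx = G/2 + NX/Q with
//   NX = (2x - (xmin+xmax)) * G * 100,  Q = 2 * (100+margin_pct) * D,
// both integers (D = longer bounding-box dimension). A segment lies ON a
// pixel boundary iff Q divides the (constant) NX or NY, an exact test.
// NX/NY/Q are reduced by their common gcd before any floating division so
// the computed doubles are identical under integer rescaling of the input.
static std::vector<double> raster_lengths(const std::vector<SegI>& segs,
                                          int G, int margin_pct) {
  std::vector<double> acc((size_t)G * G, 0.0);
  if (segs.empty()) return acc;

  ll xmin = segs[0].x0, xmax = segs[0].x0, ymin = segs[0].y0, ymax = segs[0].y0;
  for (const SegI& s : segs) {
    xmin = std::min({xmin, s.x0, s.x1}); xmax = std::max({xmax, s.x0, s.x1});
    ymin = std::min({ymin, s.y0, s.y1}); ymax = std::max({ymax, s.y0, s.y1});
  }
  ll W = xmax - xmin, H = ymax - ymin, D = std::max(W, H);
  if (D == 0) {
    // degenerate "dot": single pixel at the grid center
    acc[(size_t)(G / 2) * G + (G / 2)] = 1e9; // sentinel, thresholded later
    return acc;
  }
  ll sumx = xmin + xmax, sumy = ymin + ymax;
  ll Q = 2LL * (100 + margin_pct) * D;
  ll mult = (ll)G * 100;

  // reduce the rational transform
  ll gg = Q;
  for (const SegI& s : segs) {
    gg = igcd(gg, (2 * s.x0 - sumx) * mult);
    gg = igcd(gg, (2 * s.x1 - sumx) * mult);
    gg = igcd(gg, (2 * s.y0 - sumy) * mult);
    gg = igcd(gg, (2 * s.y1 - sumy) * mult);
  }
  if (gg == 0) gg = 1;
  ll Qr = Q / gg;
  double half = G / 2.0;

  auto add = [&](double len, int row, int col) {
    if (row < 0) row = 0; if (row >= G) row = G - 1;
    if (col < 0) col = 0; if (col >= G) col = G - 1;
    acc[(size_t)row * G + col] += len;
  };

  for (const SegI& s : segs) {
    ll NX0 = (2 * s.x0 - sumx) * mult / gg, NX1 = (2 * s.x1 - sumx) * mult / gg;
    ll NY0 = (2 * s.y0 - sumy) * mult / gg, NY1 = (2 * s.y1 - sumy) * mult / gg;
    double sx0 = half + (double)NX0 / Qr, sx1 = half + (double)NX1 / Qr;
    double sy0 = half + (double)NY0 / Qr, sy1 = half + (double)NY1 / Qr;

    bool vertical = (NX0 == NX1), horizontal = (NY0 == NY1);
    if (vertical && NX0 % Qr == 0) {
      // lies exactly on the boundary between columns j-1 and j
      ll j = G / 2 + NX0 / Qr;
      double lo = std::min(sy0, sy1), hi = std::max(sy0, sy1);
      for (ll r = (ll)std::floor(lo); r < (ll)std::ceil(hi); ++r) {
        double a = std::max(lo, (double)r), b = std::min(hi, (double)(r + 1));
        if (b <= a) continue;
        int row = G - 1 - (int)r;
        add((b - a) / 2.0, row, (int)j - 1);
        add((b - a) / 2.0, row, (int)j);
      }
      continue;
    }
    if (horizontal && NY0 % Qr == 0) {
      // lies exactly on the boundary between pixel rows at sy = iy
      ll iy = G / 2 + NY0 / Qr;
      int row_above = G - 1 - (int)iy;      // pixels with sy in [iy, iy+1]
      int row_below = G - 1 - (int)(iy - 1); // pixels with sy in [iy-1, iy]
      double lo = std::min(sx0, sx1), hi = std::max(sx0, sx1);
      for (ll ccol = (ll)std::floor(lo); ccol < (ll)std::ceil(hi); ++ccol) {
        double a = std::max(lo, (double)ccol), b = std::min(hi, (double)(ccol + 1));
        if (b <= a) continue;
        add((b - a) / 2.0, row_above, (int)ccol);
        add((b - a) / 2.0, row_below, (int)ccol);
      }
      continue;
    }

    // generic segment: subdivide at every gridline crossing
    double dx = sx1 - sx0, dy = sy1 - sy0;
    double L = std::sqrt(dx * dx + dy * dy);
    std::vector<double> ts;
    ts.push_back(0.0); ts.push_back(1.0);
    if (dx != 0.0) {
      double lo = std::min(sx0, sx1), hi = std::max(sx0, sx1);
      for (ll j = (ll)std::floor(lo) + 1; j <= (ll)std::ceil(hi) - 1; ++j)
        ts.push_back(((double)j - sx0) / dx);
    }
    if (dy != 0.0) {
      double lo = std::min(sy0, sy1), hi = std::max(sy0, sy1);
      for (ll j = (ll)std::floor(lo) + 1; j <= (ll)std::ceil(hi) - 1; ++j)
        ts.push_back(((double)j - sy0) / dy);
    }
    std::sort(ts.begin(), ts.end());
    for (size_t i = 0; i + 1 < ts.size(); ++i) {
      double t0 = ts[i], t1 = ts[i + 1];
      if (t1 <= t0) continue;
      double tm = (t0 + t1) / 2.0;
      int col = (int)std::floor(sx0 + tm * dx);
      int row = G - 1 - (int)std::floor(sy0 + tm * dy);
      add(L * (t1 - t0), row, col);
    }
  }
  return acc;
}

static void threshold_grid(const std::vector<double>& acc, int G,
                           double fill_threshold, double quantum,
                           std::vector<uint8_t>& out) {
  ll thr_units = (ll)std::ceil(fill_threshold / quantum - 1e-9);
  out.assign((size_t)G * G, 0);
  for (size_t i = 0; i < acc.size(); ++i) {
    ll units = (ll)std::llround(acc[i] / quantum);
    out[i] = (units >= thr_units) ? 1 : 0;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_raster_lengths(IntegerMatrix segs, int grid_size,
                                 int margin_pct) {
  std::vector<SegI> in(segs.nrow());
  for (int i = 0; i < segs.nrow(); ++i)
    in[i] = {segs(i, 0), segs(i, 1), segs(i, 2), segs(i, 3)};
  std::vector<double> acc = raster_lengths(in, grid_size, margin_pct);
  NumericMatrix m(grid_size, grid_size);
  for (int r = 0; r < grid_size; ++r)
    for (int c = 0; c < grid_size; ++c)
      m(r, c) = acc[(size_t)r * grid_size + c];
  return m;
}

// [[Rcpp::export]]
IntegerMatrix cpp_rasterize(IntegerMatrix segs, int grid_size, int margin_pct,
                            double fill_threshold, double quantum) {
  std::vector<SegI> in(segs.nrow());
  for (int i = 0; i < segs.nrow(); ++i)
    in[i] = {segs(i, 0), segs(i, 1), segs(i, 2), segs(i, 3)};
  std::vector<double> acc = raster_lengths(in, grid_size, margin_pct);
  std::vector<uint8_t> px;
  threshold_grid(acc, grid_size, fill_threshold, quantum, px);
  IntegerMatrix m(grid_size, grid_size);
  for (int r = 0; r < grid_size; ++r)
    for (int c = 0; c < grid_size; ++c)
      m(r, c) = px[(size_t)r * grid_size + c];
  return m;
}

// ---------------------------------------------------------------------------
// Phenotype keys
// ---------------------------------------------------------------------------

static const char HEXC[] = "0123456789abcdef";

static std::string pack_key(const std::vector<uint8_t>& px) {
  size_t nbytes = (px.size() + 7) / 8;
  std::string hex(nbytes * 2, '0');
  for (size_t b = 0; b < nbytes; ++b) {
    unsigned v = 0;
    for (size_t k = 0; k < 8; ++k) {
      size_t idx = b * 8 + k;
      v = (v << 1) | (idx < px.size() ? px[idx] : 0);
    }
    hex[2 * b] = HEXC[v >> 4];
    hex[2 * b + 1] = HEXC[v & 15];
  }
  return hex;
}

// [[Rcpp::export]]
String cpp_grid_key(IntegerMatrix grid) {
  std::vector<uint8_t> px((size_t)grid.nrow() * grid.ncol());
  size_t idx = 0;
  for (int r = 0; r < grid.nrow(); ++r)
    for (int c = 0; c < grid.ncol(); ++c)
      px[idx++] = grid(r, c) ? 1 : 0;
  return String(pack_key(px));
}

// [[Rcpp::export]]
IntegerMatrix cpp_key_to_grid(std::string key, int grid_size) {
  IntegerMatrix m(grid_size, grid_size);
  size_t nbits = (size_t)grid_size * grid_size;
  for (size_t i = 0; i < nbits; ++i) {
    char ch = key[i / 4];
    unsigned nib = (ch <= '9') ? (unsigned)(ch - '0') : (unsigned)(ch - 'a' + 10);
    unsigned b = (nib >> (3 - (i % 4))) & 1; // bits packed MSB-first
    m(i / grid_size, i % grid_size) = (int)b;
  }
  return m;
}

static std::string key_of_genotype(const int* g, int G, int margin_pct,
                                   double fill_threshold, double quantum) {
  std::vector<SegI> drawn = draw_genotype(g);
  std::vector<SegI> segs = merge_segments(drawn);
  // all segments zero-length: a "dot" phenotype, kept representable by
  // rasterizing the degenerate extent rather than an empty drawing
  if (segs.empty() && !drawn.empty()) segs = drawn;
  std::vector<double> acc = raster_lengths(segs, G, margin_pct);
  std::vector<uint8_t> px;
  threshold_grid(acc, G, fill_threshold, quantum, px);
  return pack_key(px);
}

// [[Rcpp::export]]
String cpp_phenotype_key(IntegerVector genotype, int grid_size, int margin_pct,
                         double fill_threshold, double quantum) {
  return String(key_of_genotype(INTEGER(genotype), grid_size, margin_pct,
                                fill_threshold, quantum));
}

// [[Rcpp::export]]
CharacterVector cpp_phenotype_keys(IntegerMatrix genotypes, int grid_size,
                                   int margin_pct, double fill_threshold,
                                   double quantum) {
  int n = genotypes.nrow();
  CharacterVector out(n);
  int g[9];
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < 9; ++j) g[j] = genotypes(i, j);
    out[i] = key_of_genotype(g, grid_size, margin_pct, fill_threshold, quantum);
    if (i % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// ---------------------------------------------------------------------------
// Odometer enumeration helper: genotypes for a block of 0-based indices
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_genotypes_at(NumericVector idx, IntegerVector mins,
                               IntegerVector sizes) {
  // odometer order over (g1..g9), g1 slowest, g9 fastest
  int n = idx.size();
  IntegerMatrix out(n, 9);
  double strides[9];
  strides[8] = 1;
  for (int j = 7; j >= 0; --j) strides[j] = strides[j + 1] * sizes[j + 1];
  for (int i = 0; i < n; ++i) {
    double rem = idx[i];
    for (int j = 0; j < 9; ++j) {
      double q = std::floor(rem / strides[j]);
      out(i, j) = mins[j] + (int)q;
      rem -= q * strides[j];
    }
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_keys_for_index_range(double from, double to,
                                         IntegerVector mins, IntegerVector sizes,
                                         int grid_size, int margin_pct,
                                         double fill_threshold, double quantum) {
  // keys for 0-based enumeration indices [from, to); avoids materializing
  // the genotype matrix in R for large blocks
  ll n = (ll)(to - from);
  CharacterVector out(n);
  double strides[9];
  strides[8] = 1;
  for (int j = 7; j >= 0; --j) strides[j] = strides[j + 1] * sizes[j + 1];
  int g[9];
  for (ll i = 0; i < n; ++i) {
    double rem = from + (double)i;
    for (int j = 0; j < 9; ++j) {
      double q = std::floor(rem / strides[j]);
      g[j] = mins[j] + (int)q;
      rem -= q * strides[j];
    }
    out[i] = key_of_genotype(g, grid_size, margin_pct, fill_threshold, quantum);
    if (i % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// ---------------------------------------------------------------------------
// Lempel-Ziv 76 phrase count
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
int cpp_lz76(IntegerVector bits) {
  // number of phrases in the LZ76 exhaustive-history factorisation
  int n = bits.size();
  if (n == 0) return 0;
  int i = 0, cnt = 0;
  while (i < n) {
    int l = 1;
    // longest prefix of bits[i..] occurring in bits[0..i+l-2] (self-overlap allowed)
    while (i + l <= n) {
      bool found = false;
      for (int s = 0; s + l <= i + l - 1 && s < i; ++s) {
        bool eq = true;
        for (int k = 0; k < l; ++k)
          if (bits[s + k] != bits[i + k]) { eq = false; break; }
        if (eq) { found = true; break; }
      }
      if (found) ++l; else break;
    }
    cnt += 1;
    i += l;
  }
  return cnt;
}
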