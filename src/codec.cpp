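// Bit-level core of the PIC codec: canvas occupancy, slot scanning,
// self-delimiting record packing, raster construction and column scanning.
// A canvas column is a bit string of length H = 2880*epsilon = 3600*m bits
// (m = 0.8*epsilon, an integer); bit i of a column lives in pixel row
// floor(i/8) as bit (i mod 8) counted from the most significant bit.
#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

static const int THETA_BITS = 11;   // ceil(log2(1801))
static const int BASE_LEN = 2 + THETA_BITS;  // start bit + flag + payload

// smallest w with 2^w >= H; H = 3600*m is never a power of two
static inline int pointer_width(int H) {
  int w = 0;
  while ((1LL << w) < H) ++w;
  return w;
}

static inline bool get_bit(const std::vector<uint64_t> &v, size_t base, int b) {
  return (v[base + (b >> 6)] >> (b & 63)) & 1ULL;
}
static inline void set_bit(std::vector<uint64_t> &v, size_t base, int b) {
  v[base + (b >> 6)] |= (1ULL << (b & 63));
}

// all bits [b, b+l) clear?  caller guarantees b + l - 1 < H (no wrap)
static bool range_free(const std::vector<uint64_t> &occ, size_t base, int b, int l) {
  int w1 = b >> 6, w2 = (b + l - 1) >> 6;
  if (w1 == w2) {
    uint64_t mask = ((l == 64) ? ~0ULL : ((1ULL << l) - 1)) << (b & 63);
    return (occ[base + w1] & mask) == 0;
  }
  uint64_t m1 = ~0ULL << (b & 63);
  if (occ[base + w1] & m1) return false;
  for (int w = w1 + 1; w < w2; ++w)
    if (occ[base + w]) return false;
  int rem = ((b + l - 1) & 63) + 1;
  uint64_t m2 = (rem == 64) ? ~0ULL : ((1ULL << rem) - 1);
  return (occ[base + w2] & m2) == 0;
}

// Scan candidates b = (b_target + i) mod H, i = 0, 1, ..., H-1.  A candidate
// is pointer-free iff it lies inside the azimuth bin [b_target, b_target+m),
// which happens exactly when i < m and no wrap occurred.  Acceptance needs
// the full record (length l, decided per candidate) to fit above the column
// bottom and land on unwritten bits only.
static bool find_slot_core(const std::vector<uint64_t> &occ, size_t base,
                           int H, int m, int w, int b_target,
                           int &b_star, int &p) {
  const int l_free = BASE_LEN, l_ptr = BASE_LEN + w;
  for (int i = 0; i < H; ++i) {
    int bt = b_target + i;
    bool in_bin = (i < m) && (bt < H);
    int b = (bt >= H) ? bt - H : bt;
    int l = in_bin ? l_free : l_ptr;
    if (b + l - 1 >= H) continue;
    if (!range_free(occ, base, b, l)) continue;
    b_star = b;
    if (in_bin) {
      p = -1;
    } else {
      int bprime = b_target + m - 1;  // bit form of y' = y + 0.1*eps - 1/8; < H always
      int pp = (b_star - bprime) % H;
      if (pp < 0) pp += H;
      p = pp;
    }
    return true;
  }
  return false;
}

// write the packed record (start bit, flag, optional pointer, 11-bit theta)
// into the value plane and mark all l bits occupied
static void write_record_bits(std::vector<uint64_t> &val, std::vector<uint64_t> &occ,
                              size_t base, int b, int theta, int p, int w) {
  std::vector<int> bits;
  bits.push_back(1);
  bits.push_back(p >= 0 ? 1 : 0);
  if (p >= 0)
    for (int k = w - 1; k >= 0; --k) bits.push_back((p >> k) & 1);
  for (int k = THETA_BITS - 1; k >= 0; --k) bits.push_back((theta >> k) & 1);
  for (size_t i = 0; i < bits.size(); ++i) {
    if (bits[i]) set_bit(val, base, b + (int)i);
    set_bit(occ, base, b + (int)i);
  }
}

struct Canvas {
  int cols, H, nw;
  std::vector<uint64_t> val, occ;
  long long written;
  Canvas(int cols_, int H_) : cols(cols_), H(H_), nw((H_ + 63) / 64),
      val((size_t)cols_ * nw, 0), occ((size_t)cols_ * nw, 0), written(0) {}
};

// [[Rcpp::export]]
List cpp_encode(IntegerMatrix q, int m) {
  const int n = q.nrow();
  const int H = 3600 * m, w = pointer_width(H);
  int r_star = 0;
  for (int a = 0; a < n; ++a) if (q(a, 0) > r_star) r_star = q(a, 0);
  const int cols = r_star + 1, rows_px = H / 8;

  std::vector<Canvas> canvases;
  IntegerVector img(n), col(n), bit(n), ptr(n), len(n);

  for (int a = 0; a < n; ++a) {
    const int x = q(a, 0), b_target = m * q(a, 1), theta = q(a, 2);
    int b_star = -1, p = -1, ci = -1;
    for (size_t c = 0; c < canvases.size(); ++c) {
      size_t base = (size_t)x * canvases[c].nw;
      if (find_slot_core(canvases[c].occ, base, H, m, w, b_target, b_star, p)) {
        ci = (int)c;
        break;
      }
    }
    if (ci < 0) {
      canvases.emplace_back(cols, H);
      ci = (int)canvases.size() - 1;
      size_t base = (size_t)x * canvases[ci].nw;
      if (!find_slot_core(canvases[ci].occ, base, H, m, w, b_target, b_star, p))
        stop("record does not fit in an empty column (internal error)");
    }
    Canvas &cv = canvases[ci];
    size_t base = (size_t)x * cv.nw;
    int l = (p >= 0) ? BASE_LEN + w : BASE_LEN;
    write_record_bits(cv.val, cv.occ, base, b_star, theta, p, w);
    cv.written += l;
    img[a] = ci; col[a] = x; bit[a] = b_star; ptr[a] = p; len[a] = l;
  }

  List rasters((int)canvases.size());
  NumericVector written((int)canvases.size());
  for (size_t c = 0; c < canvases.size(); ++c) {
    Canvas &cv = canvases[c];
    IntegerMatrix ras(rows_px, cols);
    for (int x = 0; x < cols; ++x) {
      size_t base = (size_t)x * cv.nw;
      for (int j = 0; j < rows_px; ++j) {
        int byte = 0;
        for (int k = 0; k < 8; ++k)
          if (get_bit(cv.val, base, 8 * j + k)) byte |= 1 << (7 - k);
        ras(j, x) = byte;
      }
    }
    rasters[(int)c] = ras;
    written[(int)c] = (double)cv.written;
  }

  return List::create(_["rasters"] = rasters, _["r_star"] = r_star,
                      _["image"] = img, _["column"] = col, _["bit"] = bit,
                      _["pointer"] = ptr, _["length"] = len,
                      _["bits_written"] = written);
}

// Scan one full-size raster: columns left to right, bits top to bottom with
// a cursor; a 1 bit opens a record whose length follows from its second bit,
// a 0 bit advances the cursor by one.
// [[Rcpp::export]]
List cpp_decode_raster(IntegerMatrix raster, int m) {
  const int H = 3600 * m, w = pointer_width(H);
  const int rows_px = raster.nrow(), cols = raster.ncol();
  if (rows_px * 8 != H)
    stop("raster height %d px does not match 360*epsilon = %d", rows_px, H / 8);
  std::vector<int> rcol, rbit, rptr, rtheta;

  for (int x = 0; x < cols; ++x) {
    int b = 0;
    while (b < H) {
      int bitv = (raster(b >> 3, x) >> (7 - (b & 7))) & 1;
      if (!bitv) { ++b; continue; }
      if (b + BASE_LEN - 1 >= H)
        stop("truncated record at column %d bit %d", x, b);
      int flag = (raster((b + 1) >> 3, x) >> (7 - ((b + 1) & 7))) & 1;
      int l = flag ? BASE_LEN + w : BASE_LEN;
      if (b + l - 1 >= H)
        stop("truncated record at column %d bit %d", x, b);
      int pos = b + 2, p = -1;
      if (flag) {
        p = 0;
        for (int k = 0; k < w; ++k, ++pos)
          p = (p << 1) | ((raster(pos >> 3, x) >> (7 - (pos & 7))) & 1);
      }
      int theta = 0;
      for (int k = 0; k < THETA_BITS; ++k, ++pos)
        theta = (theta << 1) | ((raster(pos >> 3, x) >> (7 - (pos & 7))) & 1);
      rcol.push_back(x); rbit.push_back(b); rptr.push_back(p); rtheta.push_back(theta);
      b += l;
    }
  }
  return List::create(_["column"] = wrap(rcol), _["bit"] = wrap(rbit),
                      _["pointer"] = wrap(rptr), _["theta_code"] = wrap(rtheta));
}

// [[Rcpp::export]]
List cpp_find_slot(LogicalVector occupied, int b_target, int m) {
  const int H = occupied.size();
  if (H != 3600 * m) stop("occupancy vector must have length 3600*m");
  const int w = pointer_width(H);
  std::vector<uint64_t> occ((H + 63) / 64, 0);
  for (int b = 0; b < H; ++b)
    if (occupied[b]) set_bit(occ, 0, b);
  int b_star = -1, p = -1;
  if (!find_slot_core(occ, 0, H, m, w, b_target, b_star, p))
    return List::create(_["no_space"] = true);
  return List::create(_["no_space"] = false, _["b_star"] = b_star,
                      _["p"] = (p >= 0) ? IntegerVector::create(p) : IntegerVector(0));
}

// [[Rcpp::export]]
IntegerVector cpp_pack_record(int theta_code, int p, int m) {
  const int H = 3600 * m, w = pointer_width(H);
  if (theta_code < 0 || theta_code > 1800) stop("theta_code out of [0, 1800]");
  if (p == 0 || p >= H) stop("pointer out of range [1, %d)", H);
  std::vector<int> bits;
  bits.push_back(1);
  bits.push_back(p > 0 ? 1 : 0);
  if (p > 0)
    for (int k = w - 1; k >= 0; --k) bits.push_back((p >> k) & 1);
  for (int k = THETA_BITS - 1; k >= 0; --k) bits.push_back((theta_code >> k) & 1);
  return wrap(bits);
}

// [[Rcpp::export]]
List cpp_unpack_record(IntegerVector bits, int m) {
  const int H = 3600 * m, w = pointer_width(H);
  if (bits.size() < 1 || bits[0] != 1) stop("record must start with a 1 bit");
  if (bits.size() < BASE_LEN) stop("truncated record");
  int flag = bits[1], l = flag ? BASE_LEN + w : BASE_LEN;
  if (bits.size() < l) stop("truncated record");
  int pos = 2, p = -1;
  if (flag) {
    p = 0;
    for (int k = 0; k < w; ++k, ++pos) p = (p << 1) | bits[pos];
    if (p < 1) stop("pointer must be positive");
  }
  int theta = 0;
  for (int k = 0; k < THETA_BITS; ++k, ++pos) theta = (theta << 1) | bits[pos];
  if (theta > 1800) stop("theta_code out of [0, 1800]");
  return List::create(_["theta_code"] = theta,
                      _["p"] = (p >= 0) ? IntegerVector::create(p) : IntegerVector(0),
                      _["length"] = l);
}

// LEB128-style varint packing of non-negative (zigzag-mapped) integers
// [[Rcpp::export]]
RawVector cpp_varint_pack(IntegerVector values) {
  std::vector<uint8_t> out;
  out.reserve(values.size() * 2);
  for (int i = 0; i < values.size(); ++i) {
    uint32_t v = (uint32_t)values[i];
    while (v >= 0x80) {
      out.push_back((uint8_t)(v & 0x7F) | 0x80);
      v >>= 7;
    }
    out.push_back((uint8_t)v);
  }
  return RawVector(out.begin(), out.end());
}

// [[Rcpp::export]]
List cpp_varint_unpack(RawVector bytes, int n, int offset) {
  IntegerVector out(n);
  size_t pos = (size_t)offset;
  for (int i = 0; i < n; ++i) {
    uint32_t v = 0;
    int shift = 0;
    for (;;) {
      if (pos >= (size_t)bytes.size()) stop("truncated varint stream");
      uint8_t byte = bytes[pos++];
      v |= (uint32_t)(byte & 0x7F) << shift;
      if (!(byte & 0x80)) break;
      shift += 7;
      if (shift > 28) stop("varint overflow");
    }
    out[i] = (int)v;
  }
  return List::create(_["values"] = out, _["position"] = (int)pos);
}
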