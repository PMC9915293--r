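#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// MSB-first bit packing. Bit i of the stream lives in byte i/8 at bit
// position 7 - i%8. Finalised streams are zero-padded to a byte boundary;
// the exact bit count travels alongside the bytes.

namespace {

struct BitWriter {
  std::vector<uint8_t> buf;
  uint64_t nbits = 0;

  void push_bit(int b) {
    if ((nbits & 7u) == 0) buf.push_back(0);
    if (b) buf.back() |= static_cast<uint8_t>(1u << (7 - (nbits & 7u)));
    ++nbits;
  }
  // value's nb low bits, most-significant first
  void push_bits(uint64_t value, int nb) {
    for (int i = nb - 1; i >= 0; --i) push_bit((value >> i) & 1u);
  }
  void push_ones(uint64_t q) {
    for (uint64_t i = 0; i < q; ++i) push_bit(1);
  }
};

struct BitReader {
  const uint8_t* data;
  uint64_t nbits;
  uint64_t pos = 0;

  BitReader(const uint8_t* d, uint64_t n) : data(d), nbits(n) {}

  int read_bit() {
    if (pos >= nbits) stop("truncated bitstream: read past end at bit %s",
                           std::to_string(pos));
    int b = (data[pos >> 3] >> (7 - (pos & 7u))) & 1u;
    ++pos;
    return b;
  }
  uint64_t read_bits(int nb) {
    uint64_t v = 0;
    for (int i = 0; i < nb; ++i) v = (v << 1) | read_bit();
    return v;
  }
};

inline int64_t map_signed(int64_t e) {
  return e >= 0 ? 2 * e : -2 * e - 1;
}
inline int64_t unmap_signed(int64_t m) {
  return (m & 1) ? -((m + 1) / 2) : m / 2;
}

inline void rice_put(BitWriter& w, int64_t M, int k) {
  uint64_t q = static_cast<uint64_t>(M) >> k;
  w.push_ones(q);
  w.push_bit(0);
  if (k > 0) w.push_bits(static_cast<uint64_t>(M) & ((1ull << k) - 1), k);
}

inline int64_t rice_get(BitReader& r, int k) {
  uint64_t q = 0;
  while (r.read_bit() == 1) ++q;
  uint64_t rem = (k > 0) ? r.read_bits(k) : 0;
  return static_cast<int64_t>((q << k) | rem);
}

// k(n) from the three most recent absolute residuals: integer-floored MAE,
// then floor(log2(.)), 0 below 2, clamped to kmax.
inline int k_from_window(const int64_t w[3], int kmax) {
  int64_t mae = (w[0] + w[1] + w[2]) / 3;
  if (mae <= 1) return 0;
  int k = 0;
  while ((mae >> (k + 1)) > 0) ++k;
  return k > kmax ? kmax : k;
}

// order-p binomial predictor from the four samples preceding index n
inline int64_t predict_at(const int* x, int n, int p) {
  switch (p) {
    case 1: return x[n - 1];
    case 2: return 2LL * x[n - 1] - x[n - 2];
    case 3: return 3LL * x[n - 1] - 3LL * x[n - 2] + x[n - 3];
    default:
      return 4LL * x[n - 1] - 6LL * x[n - 2] + 4LL * x[n - 3] - x[n - 4];
  }
}

inline void errors_at(const int* x, int n, int64_t e[4]) {
  for (int p = 1; p <= 4; ++p) e[p - 1] = x[n] - predict_at(x, n, p);
}

inline int argmin_abs(const int64_t e[4]) {
  int best = 0;
  for (int p = 1; p < 4; ++p)
    if (std::llabs(e[p]) < std::llabs(e[best])) best = p;
  return best + 1;
}

}  // namespace

// [[Rcpp::export(name = ".alp_encode_cpp")]]
List alp_encode_cpp(IntegerVector x, int mode, int kmax, bool trace) {
  const int n = x.size();
  if (n < 5) stop("need at least 5 samples");
  const int* xs = INTEGER(x);

  BitWriter w;
  int64_t win[3] = {0, 0, 0};
  int k = 0;
  int64_t prev_e[4] = {0, 0, 0, 0};
  IntegerVector counts(4);
  IntegerVector tr_order, tr_k, tr_err;
  if (trace) {
    tr_order = IntegerVector(n - 4);
    tr_k = IntegerVector(n - 4);
    tr_err = IntegerVector(n - 4);
  }

  for (int i = 4; i < n; ++i) {
    int64_t e[4];
    errors_at(xs, i, e);
    int p;
    if (mode == 1) {  // side_info: per-sample minimum, order transmitted
      p = argmin_abs(e);
      w.push_bits(static_cast<uint64_t>(p - 1), 2);
    } else {  // causal: previous sample's full error vector decides
      p = (i == 4) ? 2 : argmin_abs(prev_e);
    }
    int64_t err = e[p - 1];
    rice_put(w, map_signed(err), k);
    counts[p - 1] += 1;
    if (trace) {
      tr_order[i - 4] = p;
      tr_k[i - 4] = k;
      tr_err[i - 4] = static_cast<int>(err);
    }
    win[2] = win[1]; win[1] = win[0]; win[0] = std::llabs(err);
    k = k_from_window(win, kmax);
    for (int j = 0; j < 4; ++j) prev_e[j] = e[j];
  }

  RawVector payload(w.buf.size());
  if (!w.buf.empty()) std::copy(w.buf.begin(), w.buf.end(), payload.begin());
  List out = List::create(_["payload"] = payload,
                          _["nbits"] = static_cast<double>(w.nbits),
                          _["order_counts"] = counts);
  if (trace) {
    out["orders"] = tr_order;
    out["ks"] = tr_k;
    out["errors"] = tr_err;
  }
  return out;
}

// [[Rcpp::export(name = ".alp_decode_cpp")]]
List alp_decode_cpp(RawVector payload, double nbits, int n,
                    IntegerVector init, int mode, int kmax, bool trace) {
  if (n < 5) stop("need at least 5 samples");
  if (init.size() != 4) stop("need exactly 4 initial samples");
  IntegerVector x(n);
  for (int i = 0; i < 4; ++i) x[i] = init[i];
  int* xs = INTEGER(x);

  BitReader r(RAW(payload), static_cast<uint64_t>(nbits));
  int64_t win[3] = {0, 0, 0};
  int k = 0;
  int64_t prev_e[4] = {0, 0, 0, 0};
  IntegerVector tr_order, tr_k;
  if (trace) {
    tr_order = IntegerVector(n - 4);
    tr_k = IntegerVector(n - 4);
  }

  for (int i = 4; i < n; ++i) {
    int p;
    if (mode == 1) {
      p = static_cast<int>(r.read_bits(2)) + 1;
    } else {
      p = (i == 4) ? 2 : argmin_abs(prev_e);
    }
    int64_t err = unmap_signed(rice_get(r, k));
    int64_t v = predict_at(xs, i, p) + err;
    if (v < INT32_MIN || v > INT32_MAX) stop("decoded sample out of range");
    xs[i] = static_cast<int>(v);
    if (trace) {
      tr_order[i - 4] = p;
      tr_k[i - 4] = k;
    }
    if (mode != 1) errors_at(xs, i, prev_e);
    win[2] = win[1]; win[1] = win[0]; win[0] = std::llabs(err);
    k = k_from_window(win, kmax);
  }

  List out = List::create(_["samples"] = x,
                          _["bits_read"] = static_cast<double>(r.pos));
  if (trace) {
    out["orders"] = tr_order;
    out["ks"] = tr_k;
  }
  return out;
}

// Bulk Rice coding of a vector of non-negative values, one k per value.
// [[Rcpp::export(name = ".rice_encode_stream_cpp")]]
List rice_encode_stream_cpp(NumericVector M, IntegerVector k) {
  const R_xlen_t n = M.size();
  if (k.size() != n) stop("k must have one entry per value");
  BitWriter w;
  for (R_xlen_t i = 0; i < n; ++i) {
    double m = M[i];
    if (m < 0 || m != std::floor(m)) stop("values must be non-negative integers");
    rice_put(w, static_cast<int64_t>(m), k[i]);
  }
  RawVector payload(w.buf.size());
  if (!w.buf.empty()) std::copy(w.buf.begin(), w.buf.end(), payload.begin());
  return List::create(_["payload"] = payload,
                      _["nbits"] = static_cast<double>(w.nbits));
}

// [[Rcpp::export(name = ".rice_decode_stream_cpp")]]
NumericVector rice_decode_stream_cpp(RawVector payload, double nbits,
                                     IntegerVector k) {
  BitReader r(RAW(payload), static_cast<uint64_t>(nbits));
  NumericVector out(k.size());
  for (R_xlen_t i = 0; i < k.size(); ++i)
    out[i] = static_cast<double>(rice_get(r, k[i]));
  return out;
}
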