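#include <Rcpp.h>
#include <cstring>
#include <cstdint>
#include <string>

using namespace Rcpp;

// Exact 64-bit integer vectors stored as REALSXP bit patterns (one int64 per
// double slot). All values are kept strictly below 2^62 so no bit pattern can
// collide with an IEEE NaN/Inf payload, which R is free to canonicalize.
static const int64_t I64_MAX_SAFE = (int64_t)1 << 62;

static inline int64_t load_i64(double d) {
  int64_t v;
  std::memcpy(&v, &d, sizeof(double));
  return v;
}

static inline double store_i64(int64_t v) {
  double d;
  std::memcpy(&d, &v, sizeof(double));
  return d;
}

static NumericVector wrap_i64(std::vector<int64_t>& v) {
  NumericVector out(v.size());
  for (R_xlen_t i = 0; i < (R_xlen_t)v.size(); ++i) out[i] = store_i64(v[i]);
  out.attr("class") = "i64";
  return out;
}

static inline void check_safe(int64_t v) {
  if (v >= I64_MAX_SAFE || v <= -I64_MAX_SAFE)
    stop("i64 overflow: value exceeds the 2^62 safety bound");
}

// [[Rcpp::export(name = ".i64_from_double")]]
NumericVector i64_from_double(NumericVector x) {
  std::vector<int64_t> v(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double d = x[i];
    if (NumericVector::is_na(d) || d != std::floor(d))
      stop("i64: input must be integral and non-missing (element %d)", (int)(i + 1));
    if (std::abs(d) >= 4611686018427387904.0)  // 2^62 safety bound
      stop("i64: double input %g not exactly representable", d);
    v[i] = (int64_t)d;
    if ((double)v[i] != d)
      stop("i64: double input %g not exactly representable", d);
    check_safe(v[i]);
  }
  return wrap_i64(v);
}

// [[Rcpp::export(name = ".i64_to_double")]]
NumericVector i64_to_double(NumericVector x) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    int64_t v = load_i64(x[i]);
    if (v >= ((int64_t)1 << 53) || v <= -((int64_t)1 << 53))
      stop("i64: value does not fit exactly in a double; keep it as i64");
    out[i] = (double)v;
  }
  return out;
}

// [[Rcpp::export(name = ".i64_add")]]
NumericVector i64_add(NumericVector a, NumericVector b) {
  if (a.size() != b.size()) stop("i64 add: length mismatch");
  std::vector<int64_t> v(a.size());
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    v[i] = load_i64(a[i]) + load_i64(b[i]);
    check_safe(v[i]);
  }
  return wrap_i64(v);
}

// [[Rcpp::export(name = ".i64_mul")]]
NumericVector i64_mul(NumericVector a, NumericVector b) {
  if (a.size() != b.size()) stop("i64 mul: length mismatch");
  std::vector<int64_t> v(a.size());
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    __int128 p = (__int128)load_i64(a[i]) * (__int128)load_i64(b[i]);
    if (p >= (__int128)I64_MAX_SAFE || p <= -(__int128)I64_MAX_SAFE)
      stop("i64 overflow in multiplication");
    v[i] = (int64_t)p;
  }
  return wrap_i64(v);
}

// [[Rcpp::export(name = ".i64_nonzero")]]
IntegerVector i64_nonzero(NumericVector x) {
  std::vector<int> idx;
  for (R_xlen_t i = 0; i < x.size(); ++i)
    if (load_i64(x[i]) != 0) idx.push_back((int)(i + 1));
  return wrap(idx);
}

// [[Rcpp::export(name = ".i64_eq")]]
LogicalVector i64_eq(NumericVector a, NumericVector b) {
  if (a.size() != b.size()) stop("i64 eq: length mismatch");
  LogicalVector out(a.size());
  for (R_xlen_t i = 0; i < a.size(); ++i)
    out[i] = load_i64(a[i]) == load_i64(b[i]);
  return out;
}

// [[Rcpp::export(name = ".i64_zeros")]]
NumericVector i64_zeros(double n) {
  std::vector<int64_t> v((size_t)n, 0);
  return wrap_i64(v);
}

// [[Rcpp::export(name = ".i64_format")]]
CharacterVector i64_format(NumericVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = std::to_string(load_i64(x[i]));
  return out;
}

// Packed impact layout: ((bitmap << 18) + neighborhood) << 2) + frame.
// bitmap < 2^38 (exact as double), neighborhood < 2^18, frame in {0,1,2}.

// [[Rcpp::export(name = ".i64_pack_impact")]]
NumericVector i64_pack_impact(IntegerVector frame, IntegerVector nb, NumericVector bitmap) {
  R_xlen_t n = frame.size();
  if (nb.size() != n || bitmap.size() != n) stop("pack: length mismatch");
  std::vector<int64_t> v(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    int f = frame[i];
    int nbv = nb[i];
    double bm = bitmap[i];
    if (f < 0 || f > 2) stop("pack: coding frame must be 0, 1 or 2");
    if (nbv < 0 || nbv >= (1 << 18)) stop("pack: neighborhood code must be < 2^18");
    if (bm < 0 || bm != std::floor(bm) || bm >= 274877906944.0)  // 2^38
      stop("pack: impact bitmap must be an integer < 2^38");
    v[i] = ((((int64_t)bm << 18) + (int64_t)nbv) << 2) + (int64_t)f;
  }
  return wrap_i64(v);
}

// [[Rcpp::export(name = ".i64_unpack_impact")]]
List i64_unpack_impact(NumericVector x) {
  R_xlen_t n = x.size();
  IntegerVector frame(n), nb(n);
  NumericVector bitmap(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    int64_t v = load_i64(x[i]);
    if (v < 0 || v >= ((int64_t)1 << 58)) stop("unpack: value is not a 58-bit packed impact");
    frame[i] = (int)(v & 3);
    nb[i] = (int)((v >> 2) & ((1 << 18) - 1));
    bitmap[i] = (double)(v >> 20);
  }
  return List::create(_["frame"] = frame, _["neighborhood"] = nb, _["bitmap"] = bitmap);
}

// [[Rcpp::export(name = ".i64_from_string")]]
NumericVector i64_from_string(CharacterVector x) {
  std::vector<int64_t> v(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    std::string s = as<std::string>(x[i]);
    size_t j = 0;
    bool neg = !s.empty() && s[0] == '-';
    if (neg || (!s.empty() && s[0] == '+')) j = 1;
    if (j >= s.size()) stop("i64: cannot parse '%s'", s.c_str());
    int64_t acc = 0;
    for (; j < s.size(); ++j) {
      if (s[j] < '0' || s[j] > '9') stop("i64: cannot parse '%s'", s.c_str());
      acc = acc * 10 + (s[j] - '0');
      check_safe(acc);
    }
    v[i] = neg ? -acc : acc;
  }
  return wrap_i64(v);
}

// [[Rcpp::export(name = ".i64_max_abs")]]
double i64_max_abs(NumericVector x) {
  int64_t m = 0;
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    int64_t v = load_i64(x[i]);
    if (v < 0) v = -v;
    if (v > m) m = v;
  }
  // plain double (used only for range checks; values stay below 2^62)
  return (double)m;
}
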