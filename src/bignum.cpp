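// Multiprecision modular arithmetic over hex-encoded non-negative integers.
// Little-endian 32-bit limbs; division is Knuth algorithm D in base 2^32.
// Sized for Schnorr-group ElGamal: ~31-bit test groups and 2048-bit
// production groups.
#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>

namespace {

typedef std::vector<uint32_t> BN;

void trim(BN& a) {
  while (!a.empty() && a.back() == 0) a.pop_back();
}

BN from_hex(const std::string& s) {
  BN a;
  int end = (int)s.size();
  int start = 0;
  if (end - start >= 2 && s[0] == '0' && (s[1] == 'x' || s[1] == 'X')) start = 2;
  for (int pos = end; pos > start; pos -= 8) {
    int lo = pos - 8 < start ? start : pos - 8;
    uint32_t limb = 0;
    for (int i = lo; i < pos; ++i) {
      char c = s[i];
      uint32_t d;
      if (c >= '0' && c <= '9') d = c - '0';
      else if (c >= 'a' && c <= 'f') d = c - 'a' + 10;
      else if (c >= 'A' && c <= 'F') d = c - 'A' + 10;
      else Rcpp::stop("invalid hex digit in '%s'", s);
      limb = (limb << 4) | d;
    }
    a.push_back(limb);
  }
  trim(a);
  return a;
}

std::string to_hex(const BN& a) {
  if (a.empty()) return "0";
  static const char* hexd = "0123456789abcdef";
  std::string out;
  out.reserve(a.size() * 8);
  bool leading = true;
  for (int i = (int)a.size() - 1; i >= 0; --i) {
    for (int sh = 28; sh >= 0; sh -= 4) {
      uint32_t d = (a[i] >> sh) & 0xf;
      if (leading && d == 0) continue;
      leading = false;
      out.push_back(hexd[d]);
    }
  }
  if (out.empty()) out = "0";
  return out;
}

int cmp(const BN& a, const BN& b) {
  if (a.size() != b.size()) return a.size() < b.size() ? -1 : 1;
  for (int i = (int)a.size() - 1; i >= 0; --i)
    if (a[i] != b[i]) return a[i] < b[i] ? -1 : 1;
  return 0;
}

BN add(const BN& a, const BN& b) {
  BN r;
  size_t n = std::max(a.size(), b.size());
  r.resize(n + 1, 0);
  uint64_t carry = 0;
  for (size_t i = 0; i < n; ++i) {
    uint64_t s = carry;
    if (i < a.size()) s += a[i];
    if (i < b.size()) s += b[i];
    r[i] = (uint32_t)s;
    carry = s >> 32;
  }
  r[n] = (uint32_t)carry;
  trim(r);
  return r;
}

// a - b, requires a >= b
BN sub(const BN& a, const BN& b) {
  BN r(a.size(), 0);
  int64_t borrow = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    int64_t d = (int64_t)a[i] - borrow - (i < b.size() ? (int64_t)b[i] : 0);
    if (d < 0) { d += ((int64_t)1 << 32); borrow = 1; } else borrow = 0;
    r[i] = (uint32_t)d;
  }
  if (borrow) Rcpp::stop("bignum subtraction underflow");
  trim(r);
  return r;
}

BN mul(const BN& a, const BN& b) {
  if (a.empty() || b.empty()) return BN();
  BN r(a.size() + b.size(), 0);
  for (size_t i = 0; i < a.size(); ++i) {
    uint64_t carry = 0;
    uint64_t ai = a[i];
    for (size_t j = 0; j < b.size(); ++j) {
      uint64_t t = ai * b[j] + r[i + j] + carry;
      r[i + j] = (uint32_t)t;
      carry = t >> 32;
    }
    r[i + b.size()] = (uint32_t)carry;
  }
  trim(r);
  return r;
}

int nlz32(uint32_t x) {
  int n = 0;
  if (x == 0) return 32;
  while (!(x & 0x80000000u)) { x <<= 1; ++n; }
  return n;
}

// remainder of u / v (Knuth algorithm D, base 2^32)
BN mod_(const BN& u, const BN& v) {
  if (v.empty()) Rcpp::stop("division by zero modulus");
  if (cmp(u, v) < 0) return u;
  if (v.size() == 1) {
    uint64_t d = v[0], rem = 0;
    for (int i = (int)u.size() - 1; i >= 0; --i)
      rem = ((rem << 32) | u[i]) % d;
    BN r;
    if (rem) r.push_back((uint32_t)rem);
    return r;
  }
  const int n = (int)v.size();
  const int m = (int)u.size();
  const int s = nlz32(v[n - 1]);

  // normalized divisor and dividend (dividend gains one limb)
  std::vector<uint32_t> vn(n), un(m + 1, 0);
  for (int i = n - 1; i > 0; --i)
    vn[i] = s ? (v[i] << s) | (v[i - 1] >> (32 - s)) : v[i];
  vn[0] = v[0] << s;
  un[m] = s ? (u[m - 1] >> (32 - s)) : 0;
  for (int i = m - 1; i > 0; --i)
    un[i] = s ? (u[i] << s) | (u[i - 1] >> (32 - s)) : u[i];
  un[0] = u[0] << s;

  const uint64_t b = ((uint64_t)1 << 32);
  for (int j = m - n; j >= 0; --j) {
    uint64_t num = ((uint64_t)un[j + n] << 32) | un[j + n - 1];
    uint64_t qhat = num / vn[n - 1];
    uint64_t rhat = num % vn[n - 1];
    while (qhat >= b ||
           qhat * vn[n - 2] > ((rhat << 32) | un[j + n - 2])) {
      --qhat;
      rhat += vn[n - 1];
      if (rhat >= b) break;
    }
    // multiply and subtract
    int64_t borrow = 0;
    uint64_t carry = 0;
    for (int i = 0; i < n; ++i) {
      uint64_t p = qhat * vn[i] + carry;
      carry = p >> 32;
      int64_t t = (int64_t)un[i + j] - (int64_t)(uint32_t)p - borrow;
      if (t < 0) { t += (int64_t)b; borrow = 1; } else borrow = 0;
      un[i + j] = (uint32_t)t;
    }
    int64_t t = (int64_t)un[j + n] - (int64_t)carry - borrow;
    if (t < 0) {
      // add back
      un[j + n] = (uint32_t)(t + (int64_t)b);
      uint64_t c2 = 0;
      for (int i = 0; i < n; ++i) {
        uint64_t ss = (uint64_t)un[i + j] + vn[i] + c2;
        un[i + j] = (uint32_t)ss;
        c2 = ss >> 32;
      }
      un[j + n] = (uint32_t)((uint64_t)un[j + n] + c2);
    } else {
      un[j + n] = (uint32_t)t;
    }
  }
  // denormalize remainder
  BN r(n, 0);
  for (int i = 0; i < n - 1; ++i)
    r[i] = s ? (un[i] >> s) | (un[i + 1] << (32 - s)) : un[i];
  r[n - 1] = s ? (un[n - 1] >> s) : un[n - 1];
  trim(r);
  return r;
}

BN mulmod(const BN& a, const BN& b, const BN& m) { return mod_(mul(a, b), m); }

BN modexp(const BN& base, const BN& e, const BN& m) {
  if (m.empty()) Rcpp::stop("division by zero modulus");
  BN one(1, 1);
  if (m.size() == 1 && m[0] == 1) return BN();  // mod 1
  BN result = one;
  BN b0 = mod_(base, m);
  if (e.empty()) return result;
  int topbit = 31;
  while (topbit >= 0 && !((e.back() >> topbit) & 1)) --topbit;
  for (int i = (int)e.size() - 1; i >= 0; --i) {
    int start = (i == (int)e.size() - 1) ? topbit : 31;
    for (int bit = start; bit >= 0; --bit) {
      result = mulmod(result, result, m);
      if ((e[i] >> bit) & 1) result = mulmod(result, b0, m);
    }
  }
  return result;
}

BN get1(const Rcpp::CharacterVector& x, R_xlen_t i) {
  return from_hex(std::string(x[x.size() == 1 ? 0 : i]));
}

// ---- native fast path for moduli below 2^62 (test-mode groups) ----------

bool u64_from_hex(const char* s, uint64_t* out) {
  uint64_t v = 0;
  int n = 0;
  if (s[0] == '0' && (s[1] == 'x' || s[1] == 'X')) s += 2;
  for (; *s; ++s, ++n) {
    char c = *s;
    uint64_t d;
    if (c >= '0' && c <= '9') d = c - '0';
    else if (c >= 'a' && c <= 'f') d = c - 'a' + 10;
    else if (c >= 'A' && c <= 'F') d = c - 'A' + 10;
    else Rcpp::stop("invalid hex digit");
    if (n >= 15) return false;  // may exceed 2^62, fall back to bignum
    v = (v << 4) | d;
  }
  *out = v;
  return true;
}

uint64_t get_u64(const Rcpp::CharacterVector& x, R_xlen_t i) {
  uint64_t v;
  const char* s = CHAR(STRING_ELT(x, x.size() == 1 ? 0 : i));
  if (!u64_from_hex(s, &v)) Rcpp::stop("value exceeds native range");
  return v;
}

bool all_u64 (const Rcpp::CharacterVector& x) {
  uint64_t v;
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    SEXP e = STRING_ELT(x, i);
    if (e == NA_STRING || !u64_from_hex(CHAR(e), &v)) return false;
  }
  return true;
}

std::string u64_to_hex(uint64_t v) {
  char buf[17];
  snprintf(buf, sizeof(buf), "%llx", (unsigned long long)v);
  return std::string(buf);
}

inline uint64_t mulmod_u64(uint64_t a, uint64_t b, uint64_t m) {
  return (uint64_t)(((unsigned __int128)a * b) % m);
}

uint64_t modexp_u64(uint64_t b, uint64_t e, uint64_t m) {
  if (m == 1) return 0;
  uint64_t r = 1;
  b %= m;
  while (e > 0) {
    if (e & 1) r = mulmod_u64(r, b, m);
    b = mulmod_u64(b, b, m);
    e >>= 1;
  }
  return r;
}

}  // namespace

// [[Rcpp::export(name = ".bn_modexp")]]
Rcpp::CharacterVector bn_modexp(Rcpp::CharacterVector base,
                                Rcpp::CharacterVector exp,
                                std::string mod) {
  BN m = from_hex(mod);
  R_xlen_t n = std::max(base.size(), exp.size());
  if (base.size() != n && base.size() != 1)
    Rcpp::stop("incompatible lengths");
  if (exp.size() != n && exp.size() != 1) Rcpp::stop("incompatible lengths");
  Rcpp::CharacterVector out(n);
  uint64_t m64;
  if (u64_from_hex(mod.c_str(), &m64) && all_u64(base) && all_u64(exp)) {
    for (R_xlen_t i = 0; i < n; ++i)
      out[i] = u64_to_hex(modexp_u64(get_u64(base, i), get_u64(exp, i), m64));
    return out;
  }
  if (base.size() == 1 && exp.size() > 1) {
    BN b = from_hex(std::string(base[0]));
    for (R_xlen_t i = 0; i < n; ++i)
      out[i] = to_hex(modexp(b, get1(exp, i), m));
  } else {
    for (R_xlen_t i = 0; i < n; ++i)
      out[i] = to_hex(modexp(get1(base, i), get1(exp, i), m));
  }
  return out;
}

// [[Rcpp::export(name = ".bn_mulmod")]]
Rcpp::CharacterVector bn_mulmod(Rcpp::CharacterVector a,
                                Rcpp::CharacterVector b, std::string mod) {
  BN m = from_hex(mod);
  R_xlen_t n = std::max(a.size(), b.size());
  if ((a.size() != n && a.size() != 1) || (b.size() != n && b.size() != 1))
    Rcpp::stop("incompatible lengths");
  Rcpp::CharacterVector out(n);
  uint64_t m64;
  if (u64_from_hex(mod.c_str(), &m64) && all_u64(a) && all_u64(b)) {
    for (R_xlen_t i = 0; i < n; ++i)
      out[i] = u64_to_hex(mulmod_u64(get_u64(a, i) % m64,
                                     get_u64(b, i) % m64, m64));
    return out;
  }
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = to_hex(mulmod(get1(a, i), get1(b, i), m));
  return out;
}

// [[Rcpp::export(name = ".bn_addmod")]]
Rcpp::CharacterVector bn_addmod(Rcpp::CharacterVector a,
                                Rcpp::CharacterVector b, std::string mod) {
  BN m = from_hex(mod);
  R_xlen_t n = std::max(a.size(), b.size());
  if ((a.size() != n && a.size() != 1) || (b.size() != n && b.size() != 1))
    Rcpp::stop("incompatible lengths");
  Rcpp::CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = to_hex(mod_(add(get1(a, i), get1(b, i)), m));
  return out;
}

// [[Rcpp::export(name = ".bn_mod")]]
Rcpp::CharacterVector bn_mod(Rcpp::CharacterVector a, std::string mod) {
  BN m = from_hex(mod);
  Rcpp::CharacterVector out(a.size());
  for (R_xlen_t i = 0; i < a.size(); ++i)
    out[i] = to_hex(mod_(from_hex(std::string(a[i])), m));
  return out;
}

// [[Rcpp::export(name = ".bn_sub")]]
std::string bn_sub(std::string a, std::string b) {
  return to_hex(sub(from_hex(a), from_hex(b)));
}

// [[Rcpp::export(name = ".bn_cmp")]]
int bn_cmp(std::string a, std::string b) {
  return cmp(from_hex(a), from_hex(b));
}

// [[Rcpp::export(name = ".bn_nbits")]]
int bn_nbits(std::string a) {
  BN x = from_hex(a);
  if (x.empty()) return 0;
  return (int)(x.size() - 1) * 32 + (32 - nlz32(x.back()));
}
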