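// Big-integer backend over OpenSSL's BIGNUM: modular arithmetic for the
// Paillier cryptosystem and DH-style PSI, SHA-256 hashing, exact Levenshtein
// DP, and arithmetic in the 61-bit Mersenne-prime share field (values exceed
// the exact range of R doubles, so they cross the boundary as decimal strings).
#include <Rcpp.h>
#include <openssl/bn.h>
#include <openssl/opensslv.h>
#include <openssl/sha.h>

#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

namespace {

struct BNCtx {
  BN_CTX *ctx;
  BNCtx() : ctx(BN_CTX_new()) {
    if (!ctx) stop("BN_CTX allocation failed");
  }
  ~BNCtx() { BN_CTX_free(ctx); }
};

struct Big {
  BIGNUM *p;
  Big() : p(BN_new()) {
    if (!p) stop("BIGNUM allocation failed");
  }
  explicit Big(const std::string &hex) : p(nullptr) {
    if (!BN_hex2bn(&p, hex.c_str()))
      stop("invalid hex integer: '%s'", hex.c_str());
  }
  ~Big() { BN_free(p); }
  Big(const Big &) = delete;
  Big &operator=(const Big &) = delete;
  std::string hex() const {
    char *s = BN_bn2hex(p);
    std::string out(s);
    OPENSSL_free(s);
    return out;
  }
};

}  // namespace

// [[Rcpp::export]]
std::string cx_bn_arith(std::string a, std::string b, std::string op) {
  BNCtx ctx;
  Big x(a), y(b), r;
  int ok = 0;
  if (op == "add") ok = BN_add(r.p, x.p, y.p);
  else if (op == "sub") ok = BN_sub(r.p, x.p, y.p);
  else if (op == "mul") ok = BN_mul(r.p, x.p, y.p, ctx.ctx);
  else if (op == "div") ok = BN_div(r.p, nullptr, x.p, y.p, ctx.ctx);
  else if (op == "mod") ok = BN_nnmod(r.p, x.p, y.p, ctx.ctx);
  else if (op == "gcd") ok = BN_gcd(r.p, x.p, y.p, ctx.ctx);
  else stop("unknown op '%s'", op.c_str());
  if (!ok) stop("bignum '%s' failed", op.c_str());
  return r.hex();
}

// [[Rcpp::export]]
int cx_bn_cmp(std::string a, std::string b) {
  Big x(a), y(b);
  return BN_cmp(x.p, y.p);
}

// [[Rcpp::export]]
int cx_bn_num_bits(std::string a) {
  Big x(a);
  return BN_num_bits(x.p);
}

// [[Rcpp::export]]
bool cx_bn_is_prime(std::string a) {
  BNCtx ctx;
  Big x(a);
#if OPENSSL_VERSION_NUMBER >= 0x30000000L
  int r = BN_check_prime(x.p, ctx.ctx, nullptr);
#else
  int r = BN_is_prime_ex(x.p, BN_prime_checks, ctx.ctx, nullptr);
#endif
  if (r < 0) stop("primality test failed");
  return r == 1;
}

// [[Rcpp::export]]
std::string cx_bn_mod_inverse(std::string a, std::string m) {
  BNCtx ctx;
  Big x(a), mod(m), r;
  if (!BN_mod_inverse(r.p, x.p, mod.p, ctx.ctx))
    stop("no modular inverse exists");
  return r.hex();
}

// [[Rcpp::export]]
CharacterVector cx_bn_mod_exp(CharacterVector base, CharacterVector exp,
                              std::string mod) {
  BNCtx ctx;
  Big m(mod);
  R_xlen_t n = base.size();
  if (exp.size() != n && exp.size() != 1)
    stop("exponent length must be 1 or match base");
  CharacterVector out(n);
  Big e(as<std::string>(exp[0]));
  for (R_xlen_t i = 0; i < n; ++i) {
    Big b(as<std::string>(base[i])), r;
    if (exp.size() != 1) {
      Big ei(as<std::string>(exp[i]));
      if (!BN_mod_exp(r.p, b.p, ei.p, m.p, ctx.ctx)) stop("mod_exp failed");
    } else {
      if (!BN_mod_exp(r.p, b.p, e.p, m.p, ctx.ctx)) stop("mod_exp failed");
    }
    out[i] = r.hex();
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cx_bn_mod_mul(CharacterVector a, CharacterVector b,
                              std::string mod) {
  BNCtx ctx;
  Big m(mod);
  R_xlen_t n = std::max(a.size(), b.size());
  if ((a.size() != n && a.size() != 1) || (b.size() != n && b.size() != 1))
    stop("lengths must match or be 1");
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    Big x(as<std::string>(a[a.size() == 1 ? 0 : i]));
    Big y(as<std::string>(b[b.size() == 1 ? 0 : i]));
    Big r;
    if (!BN_mod_mul(r.p, x.p, y.p, m.p, ctx.ctx)) stop("mod_mul failed");
    out[i] = r.hex();
  }
  return out;
}

// Product of all elements mod m (homomorphic sum of Paillier ciphertexts).
// [[Rcpp::export]]
std::string cx_bn_mod_prod(CharacterVector a, std::string mod) {
  BNCtx ctx;
  Big m(mod), acc;
  if (!BN_one(acc.p)) stop("mod_prod failed");
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    Big x(as<std::string>(a[i]));
    if (!BN_mod_mul(acc.p, acc.p, x.p, m.p, ctx.ctx)) stop("mod_prod failed");
  }
  return acc.hex();
}

// [[Rcpp::export]]
CharacterVector cx_bn_mod(CharacterVector a, std::string mod) {
  BNCtx ctx;
  Big m(mod);
  CharacterVector out(a.size());
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    Big x(as<std::string>(a[i])), r;
    if (!BN_nnmod(r.p, x.p, m.p, ctx.ctx)) stop("mod failed");
    out[i] = r.hex();
  }
  return out;
}

// c = (1 + m n) r^n mod n^2  (g = n + 1 variant)
// [[Rcpp::export]]
CharacterVector cx_paillier_encrypt(std::string n_hex, std::string nsq_hex,
                                    CharacterVector m, CharacterVector r) {
  BNCtx ctx;
  Big n(n_hex), nsq(nsq_hex);
  R_xlen_t len = m.size();
  if (r.size() != len) stop("message/randomizer length mismatch");
  CharacterVector out(len);
  Big gm, rn, c;
  for (R_xlen_t i = 0; i < len; ++i) {
    Big mi(as<std::string>(m[i])), ri(as<std::string>(r[i]));
    if (BN_is_negative(mi.p) || BN_cmp(mi.p, n.p) >= 0)
      stop("plaintext out of range [0, n)");
    // g^m = 1 + m n (mod n^2)
    if (!BN_mod_mul(gm.p, mi.p, n.p, nsq.p, ctx.ctx)) stop("encrypt failed");
    if (!BN_add_word(gm.p, 1)) stop("encrypt failed");
    if (!BN_mod_exp(rn.p, ri.p, n.p, nsq.p, ctx.ctx)) stop("encrypt failed");
    if (!BN_mod_mul(c.p, gm.p, rn.p, nsq.p, ctx.ctx)) stop("encrypt failed");
    out[i] = c.hex();
  }
  return out;
}

// m = L(c^lambda mod n^2) * mu mod n, with L(u) = (u - 1) / n
// [[Rcpp::export]]
CharacterVector cx_paillier_decrypt(std::string n_hex, std::string nsq_hex,
                                    std::string lambda_hex,
                                    std::string mu_hex, CharacterVector c) {
  BNCtx ctx;
  Big n(n_hex), nsq(nsq_hex), lambda(lambda_hex), mu(mu_hex);
  CharacterVector out(c.size());
  Big u, l, m;
  for (R_xlen_t i = 0; i < c.size(); ++i) {
    Big ci(as<std::string>(c[i]));
    if (!BN_mod_exp(u.p, ci.p, lambda.p, nsq.p, ctx.ctx)) stop("decrypt failed");
    if (!BN_sub_word(u.p, 1)) stop("decrypt failed");
    if (!BN_div(l.p, nullptr, u.p, n.p, ctx.ctx)) stop("decrypt failed");
    if (!BN_mod_mul(m.p, l.p, mu.p, n.p, ctx.ctx)) stop("decrypt failed");
    out[i] = m.hex();
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cx_sha256_hex(CharacterVector x) {
  CharacterVector out(x.size());
  unsigned char digest[SHA256_DIGEST_LENGTH];
  char hex[2 * SHA256_DIGEST_LENGTH + 1];
  static const char *tab = "0123456789ABCDEF";
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    std::string s = as<std::string>(x[i]);
    SHA256(reinterpret_cast<const unsigned char *>(s.data()), s.size(),
           digest);
    for (int j = 0; j < SHA256_DIGEST_LENGTH; ++j) {
      hex[2 * j] = tab[digest[j] >> 4];
      hex[2 * j + 1] = tab[digest[j] & 0x0F];
    }
    hex[2 * SHA256_DIGEST_LENGTH] = '\0';
    out[i] = hex;
  }
  return out;
}

// Exact Levenshtein distance, unit costs, two-row rolling DP.
// [[Rcpp::export]]
int cx_levenshtein(std::string s1, std::string s2) {
  const std::string &a = s1.size() >= s2.size() ? s1 : s2;
  const std::string &b = s1.size() >= s2.size() ? s2 : s1;
  size_t n = b.size();
  std::vector<int> prev(n + 1), cur(n + 1);
  for (size_t j = 0; j <= n; ++j) prev[j] = static_cast<int>(j);
  for (size_t i = 1; i <= a.size(); ++i) {
    cur[0] = static_cast<int>(i);
    char ai = a[i - 1];
    for (size_t j = 1; j <= n; ++j) {
      int sub = prev[j - 1] + (ai != b[j - 1]);
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      cur[j] = std::min(sub, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[n];
}

// ---- Z_p arithmetic for p = 2^61 - 1 (additive secret shares) ----

static const uint64_t F61_P = 2305843009213693951ULL;

static uint64_t f61_parse(const String &s) {
  const char *c = s.get_cstring();
  uint64_t v = 0;
  const char *p = c;
  if (*p == '\0') stop("invalid field element ''");
  for (; *p != '\0'; ++p) {
    if (*p < '0' || *p > '9' || v > F61_P / 10)
      stop("invalid field element '%s'", c);
    v = v * 10 + static_cast<uint64_t>(*p - '0');
  }
  if (v >= F61_P) stop("invalid field element '%s'", c);
  return v;
}

static String f61_fmt(uint64_t v) { return String(std::to_string(v)); }

// [[Rcpp::export]]
CharacterVector cx_f61_add(CharacterVector a, CharacterVector b) {
  R_xlen_t n = std::max(a.size(), b.size());
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t x = f61_parse(a[a.size() == 1 ? 0 : i]);
    uint64_t y = f61_parse(b[b.size() == 1 ? 0 : i]);
    uint64_t s = x + y;  // < 2^62, no overflow
    if (s >= F61_P) s -= F61_P;
    out[i] = f61_fmt(s);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cx_f61_sub(CharacterVector a, CharacterVector b) {
  R_xlen_t n = std::max(a.size(), b.size());
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t x = f61_parse(a[a.size() == 1 ? 0 : i]);
    uint64_t y = f61_parse(b[b.size() == 1 ? 0 : i]);
    out[i] = f61_fmt(x >= y ? x - y : x + (F61_P - y));
  }
  return out;
}

// Interpret consecutive 8-byte big-endian blocks, mask to 61 bits, reduce
// mod p. Bias is a single residue out of 2^61 - negligible for share use.
// [[Rcpp::export]]
CharacterVector cx_f61_from_bytes(RawVector bytes) {
  if (bytes.size() % 8 != 0) stop("byte length must be a multiple of 8");
  R_xlen_t n = bytes.size() / 8;
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t v = 0;
    for (int j = 0; j < 8; ++j) v = (v << 8) | bytes[i * 8 + j];
    v &= (1ULL << 61) - 1;
    if (v >= F61_P) v -= F61_P;
    out[i] = f61_fmt(v);
  }
  return out;
}

// [[Rcpp::export]]
RawVector cx_f61_to_bytes(CharacterVector a) {
  RawVector out(a.size() * 8);
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    uint64_t v = f61_parse(a[i]);
    for (int j = 7; j >= 0; --j) {
      out[i * 8 + j] = static_cast<Rbyte>(v & 0xFF);
      v >>= 8;
    }
  }
  return out;
}
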