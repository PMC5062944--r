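#' Paillier keypair generation
#'
#' Generates an additively homomorphic Paillier keypair in the simplified
#' `g = n + 1` variant: `n = p q` with `p`, `q` equal-size probable primes,
#' private `lambda = lcm(p-1, q-1)` and `mu = lambda^{-1} mod n`. The
#' 80-bit security floor of the benchmark setting maps to a 1024-bit
#' modulus; smaller moduli are refused unless `allow_insecure = TRUE`
#' (fast test keys, loudly insecure). All randomness is drawn from R's
#' RNG, so `set.seed()` makes key generation reproducible.
#'
#' @param bits modulus size in bits (multiple of 16).
#' @param allow_insecure permit `bits < 1024` for fast tests.
#' @return a `paillier_keypair`: list with `pk` (`paillier_public_key`:
#'   `n`, `g`, `n_sq`, `bits`, `fingerprint`) and `sk`
#'   (`paillier_private_key`: `lambda`, `mu`, and the public key).
#' @export
paillier_keygen <- function(bits = 1024, allow_insecure = FALSE) {
  if (bits < 1024 && !allow_insecure)
    abort("bits < 1024 is below the 80-bit security floor; set allow_insecure = TRUE for test keys")
  if (bits %% 16 != 0 || bits < 64) abort("bits must be a multiple of 16, >= 64")
  p <- gen_probable_prime(bits / 2)
  repeat {
    q <- gen_probable_prime(bits / 2)
    if (cx_bn_cmp(p, q) != 0) break
  }
  n <- cx_bn_arith(p, q, "mul")
  stopifnot(cx_bn_num_bits(n) == bits)
  n_sq <- cx_bn_arith(n, n, "mul")
  pm1 <- cx_bn_arith(p, "1", "sub")
  qm1 <- cx_bn_arith(q, "1", "sub")
  g0 <- cx_bn_arith(pm1, qm1, "gcd")
  lambda <- cx_bn_arith(cx_bn_arith(pm1, qm1, "mul"), g0, "div")
  mu <- cx_bn_mod_inverse(cx_bn_arith(lambda, n, "mod"), n)
  pk <- structure(list(
    n = n, g = cx_bn_arith(n, "1", "add"), n_sq = n_sq, bits = bits,
    fingerprint = substr(cx_sha256_hex(n), 1, 16),
    insecure = bits < 1024), class = "paillier_public_key")
  sk <- structure(list(lambda = lambda, mu = mu, pk = pk),
                  class = "paillier_private_key")
  structure(list(pk = pk, sk = sk), class = "paillier_keypair")
}

# Random probable prime: random odd candidate with the top two bits set
# (so products of two such primes have exactly 2x the bit length), then a
# bounded forward search over odd numbers. Miller-Rabin via libcrypto with
# error probability well below 2^-80.
gen_probable_prime <- function(bits) {
  stopifnot(bits %% 8 == 0)
  nbytes <- bits / 8
  repeat {
    b <- rand_bytes(nbytes)
    b[1] <- as.raw(bitwOr(as.integer(b[1]), 0xC0L))
    b[nbytes] <- as.raw(bitwOr(as.integer(b[nbytes]), 0x01L))
    cand <- raw_to_hex(b)
    for (k in 0:299) {
      if (cx_bn_is_prime(cand)) return(cand)
      cand <- cx_bn_arith(cand, "2", "add")
    }
  }
}

#' @exportS3Method base::print
print.paillier_public_key <- function(x, ...) {
  cat(sprintf("<paillier_public_key> %d-bit modulus, fingerprint %s%s\n",
              x$bits, x$fingerprint,
              if (isTRUE(x$insecure)) " [INSECURE TEST KEY]" else ""))
  invisible(x)
}

#' @exportS3Method base::print
print.paillier_private_key <- function(x, ...) {
  cat(sprintf("<paillier_private_key> for %d-bit modulus, fingerprint %s\n",
              x$pk$bits, x$pk$fingerprint))
  invisible(x)
}

as_hex_messages <- function(m, n_hex) {
  h <- if (is.character(m)) toupper(m) else num_to_hex(m)
  out_of_range <- vapply(h, function(x) cx_bn_cmp(x, n_hex) >= 0, logical(1))
  if (any(out_of_range)) abort("plaintext out of range [0, n)")
  h
}

#' Paillier encryption and decryption
#'
#' `paillier_encrypt()` maps each plaintext `m` in `[0, n)` to
#' `(1 + m n) r^n mod n^2` with a fresh uniform randomizer `r`, so two
#' encryptions of the same value differ. `paillier_decrypt()` inverts
#' exactly via `L(c^lambda mod n^2) mu mod n`.
#'
#' @param pk,sk public / private key from [paillier_keygen()].
#' @param m numeric vector of non-negative integers (< 2^53) or hex
#'   strings for larger plaintexts.
#' @param ct a `paillier_ciphertext`.
#' @param as return decrypted values as `"numeric"` (error above 2^53) or
#'   `"hex"`.
#' @return `paillier_encrypt()`: a vectorised `paillier_ciphertext`;
#'   `paillier_decrypt()`: numeric or hex character vector.
#' @export
paillier_encrypt <- function(pk, m) {
  stopifnot(inherits(pk, "paillier_public_key"))
  h <- as_hex_messages(m, pk$n)
  r <- rand_below_nonzero(pk$n, length(h))
  new_ciphertext(cx_paillier_encrypt(pk$n, pk$n_sq, h, r), pk)
}

new_ciphertext <- function(values, pk) {
  structure(list(value = values, fingerprint = pk$fingerprint,
                 bits = pk$bits), class = "paillier_ciphertext")
}

#' @export
length.paillier_ciphertext <- function(x) length(x$value)

#' @exportS3Method base::print
print.paillier_ciphertext <- function(x, ...) {
  cat(sprintf("<paillier_ciphertext> %d value(s) under key %s\n",
              length(x$value), x$fingerprint))
  invisible(x)
}

#' @rdname paillier_encrypt
#' @export
paillier_decrypt <- function(sk, ct, as = c("numeric", "hex")) {
  as <- match.arg(as)
  stopifnot(inherits(sk, "paillier_private_key"),
            inherits(ct, "paillier_ciphertext"))
  check_fingerprint(sk$pk, ct)
  h <- cx_paillier_decrypt(sk$pk$n, sk$pk$n_sq, sk$lambda, sk$mu, ct$value)
  if (as == "hex") h else hex_to_num(h)
}

check_fingerprint <- function(pk, ct) {
  if (!identical(pk$fingerprint, ct$fingerprint))
    abort("ciphertext was produced under a different key")
  invisible(TRUE)
}

#' Homomorphic operations on Paillier ciphertexts
#'
#' Addition of plaintexts is multiplication of ciphertexts modulo `n^2`;
#' multiplication by a non-negative integer scalar is exponentiation:
#' `dec(he_add(c1, c2)) = (m1 + m2) mod n` and
#' `dec(he_scalar_mul(c, k)) = (k m) mod n`. Both are element-wise over
#' vectorised ciphertexts; `he_sum()` folds a whole ciphertext vector into
#' the encryption of the plaintext sum.
#'
#' @param pk the public key the ciphertexts were produced under.
#' @param c1,c2,ct `paillier_ciphertext`s under `pk`.
#' @param k non-negative integer scalar (or vector matching `ct`).
#' @return a `paillier_ciphertext`.
#' @export
he_add <- function(pk, c1, c2) {
  stopifnot(inherits(pk, "paillier_public_key"))
  check_fingerprint(pk, c1); check_fingerprint(pk, c2)
  new_ciphertext(cx_bn_mod_mul(c1$value, c2$value, pk$n_sq), pk)
}

#' @rdname he_add
#' @export
he_scalar_mul <- function(pk, ct, k) {
  stopifnot(inherits(pk, "paillier_public_key"))
  check_fingerprint(pk, ct)
  if (any(k < 0) || any(k != floor(k))) abort("k must be a non-negative integer")
  new_ciphertext(cx_bn_mod_exp(ct$value, num_to_hex(k), pk$n_sq), pk)
}

#' @rdname he_add
#' @export
he_sum <- function(pk, ct) {
  stopifnot(inherits(pk, "paillier_public_key"))
  check_fingerprint(pk, ct)
  new_ciphertext(cx_bn_mod_prod(ct$value, pk$n_sq), pk)
}

#' Didactic demonstration of the unpadded-RSA multiplicative homomorphism
#'
#' Textbook (unpadded) RSA, `E(x) = x^e mod m`, is multiplicatively
#' homomorphic: `E(x1) E(x2) mod m = E(x1 x2)`. This routine generates a
#' throwaway modulus, encrypts `x1`, `x2` and their product, and verifies
#' the identity. It is deliberately insecure (deterministic, unpadded) and
#' exists only to illustrate partial homomorphic encryption with a
#' multiplicative (rather than additive) operation; if `x1 x2 >= m` the
#' identity holds only modulo `m` and the `wrapped` flag is set.
#'
#' @param x1,x2 non-negative integers (numeric below 2^53 or hex strings).
#' @param bits demo modulus size (default 512; no security claim).
#' @return an `rsa_demo` list: `modulus`, `e`, the three ciphertexts,
#'   `identity_holds`, `wrapped`, `insecure = TRUE`.
#' @export
rsa_homomorphism_demo <- function(x1, x2, bits = 512) {
  if (bits %% 16 != 0 || bits < 64) abort("bits must be a multiple of 16, >= 64")
  e <- "10001"
  repeat {
    p <- gen_probable_prime(bits / 2)
    q <- gen_probable_prime(bits / 2)
    if (cx_bn_cmp(p, q) == 0) next
    phi <- cx_bn_arith(cx_bn_arith(p, "1", "sub"),
                       cx_bn_arith(q, "1", "sub"), "mul")
    if (cx_bn_cmp(cx_bn_arith(phi, e, "gcd"), "1") == 0) break
  }
  m <- cx_bn_arith(p, q, "mul")
  h1 <- if (is.character(x1)) toupper(x1) else num_to_hex(x1)
  h2 <- if (is.character(x2)) toupper(x2) else num_to_hex(x2)
  prod_plain <- cx_bn_arith(h1, h2, "mul")
  wrapped <- cx_bn_cmp(prod_plain, m) >= 0
  enc <- function(x) cx_bn_mod_exp(cx_bn_mod(x, m), e, m)
  e1 <- enc(h1); e2 <- enc(h2)
  lhs <- cx_bn_mod_mul(e1, e2, m)
  rhs <- enc(prod_plain)
  structure(list(modulus = m, e = e, e_x1 = e1, e_x2 = e2,
                 product_of_ciphertexts = lhs, e_of_product = rhs,
                 identity_holds = identical(lhs, as.character(rhs)),
                 wrapped = wrapped, insecure = TRUE),
            class = "rsa_demo")
}

#' @exportS3Method base::print
print.rsa_demo <- function(x, ...) {
  cat(sprintf("<rsa_demo> E(x1)E(x2) == E(x1*x2): %s%s  [didactic, INSECURE]\n",
              x$identity_holds, if (x$wrapped) " (product wrapped modulus)" else ""))
  invisible(x)
}
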