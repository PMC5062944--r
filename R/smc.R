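#' The prime field used for additive secret shares
#'
#' Shares live in Z_p with the Mersenne prime `p = 2^61 - 1`. Pooled
#' allele counts never exceed a few thousand, so there is no wraparound;
#' field elements cross function boundaries as decimal strings because a
#' 61-bit integer exceeds the exact range of an R double.
#'
#' @return the field prime as a decimal string.
#' @export
smc_field_prime <- function() "2305843009213693951"

#' Additive secret sharing over the 61-bit Mersenne field
#'
#' `share_split()` splits a non-negative value `v < p` into two shares
#' with `s1` uniform in Z_p and `s2 = (v - s1) mod p`; either share alone
#' is uniformly distributed and reveals nothing about `v`.
#' `share_reconstruct()` returns `v` exactly.
#'
#' @param v non-negative integer (numeric < 2^53 or decimal string).
#' @param p field prime; only the built-in 61-bit Mersenne field is
#'   supported.
#' @param s1,s2 `smc_share` objects over the same prime.
#' @return `share_split()`: list of two `smc_share`s;
#'   `share_reconstruct()`: numeric value.
#' @export
share_split <- function(v, p = smc_field_prime()) {
  if (!identical(p, smc_field_prime()))
    abort("only the built-in 61-bit Mersenne field is supported")
  v_chr <- as_field_elements(v)
  k <- length(v_chr)
  s1 <- cx_f61_from_bytes(rand_bytes(8L * k))
  s2 <- cx_f61_sub(v_chr, s1)
  list(new_share(s1, "1"), new_share(s2, "2"))
}

as_field_elements <- function(v) {
  if (is.character(v)) return(v)
  stopifnot(all(v >= 0), all(v == floor(v)), all(v < 2^53))
  sprintf("%.0f", v)
}

new_share <- function(value, party) {
  structure(list(value = value, p = smc_field_prime(), party = party),
            class = "smc_share")
}

#' @exportS3Method base::print
print.smc_share <- function(x, ...) {
  cat(sprintf("<smc_share> party %s, %d element(s) in Z_(2^61-1)\n",
              x$party, length(x$value)))
  invisible(x)
}

#' @rdname share_split
#' @export
share_reconstruct <- function(s1, s2) {
  stopifnot(inherits(s1, "smc_share"), inherits(s2, "smc_share"))
  if (!identical(s1$p, s2$p)) abort("shares come from different fields")
  as.numeric(cx_f61_add(s1$value, s2$value))
}

local_group_counts <- function(gm, sites) {
  d <- gm$dosage[, sites, drop = FALSE]
  is_case <- gm$label == "case"
  cnt <- function(rows) {
    sub <- d[rows, , drop = FALSE]
    c(colSums(sub, na.rm = TRUE), 2 * colSums(!is.na(sub)))
  }
  # layout: case_alt | case_tot | control_alt | control_tot, each n_sites long
  c(cnt(is_case), cnt(!is_case))
}

#' Two-party secure GWAS on horizontally partitioned case/control data
#'
#' Each institution holds a partition of the cohort (e.g. 100 cases and
#' 100 controls each) over a common SNP site universe. Each party computes
#' its local per-site, per-group integer allele counts, the counts cross
#' the channel only as additive shares over the 61-bit field, and only the
#' pooled per-site sums are reconstructed; both parties then derive the
#' same MAF and chi-square values, exactly equal to the centralized
#' plaintext pipeline on the concatenated matrix. The transcript consists
#' of uniform field elements plus the final masked partial sums.
#'
#' @param gm_a,gm_b the two parties' [genotype_matrix()] partitions;
#'   their site universes must agree (protocol aborts naming any
#'   mismatched sites).
#' @param ch an [channel()] (created if `NULL`).
#' @param p_value include p-values.
#' @param seed optional seed for share randomness.
#' @return list with `stats` (a `gwas_result`, identical at both
#'   parties), `metrics` (a [metrics_report()]), `oracle` (centralized
#'   result) and `channel`.
#' @export
smc_gwas <- function(gm_a, gm_b, ch = NULL, p_value = TRUE, seed = NULL) {
  stopifnot(inherits(gm_a, "genotype_matrix"), inherits(gm_b, "genotype_matrix"))
  sites_a <- colnames(gm_a$dosage); sites_b <- colnames(gm_b$dosage)
  if (!identical(sites_a, sites_b)) {
    bad <- c(setdiff(sites_a, sites_b), setdiff(sites_b, sites_a))
    abort(paste0("site universe mismatch between parties: ",
                 paste(utils::head(bad, 10), collapse = ", ")))
  }
  if (is.null(ch)) ch <- channel()
  with_seed_if(seed, {
    t0 <- proc.time()[["elapsed"]]
    sites <- sites_a
    ca <- local_group_counts(gm_a, sites)  # private to A
    cb <- local_group_counts(gm_b, sites)  # private to B
    # A: cA = a1 + a2; B: cB = b1 + b2 (mod p). A keeps a1, B keeps b2.
    sa <- share_split(ca)
    sb <- share_split(cb)
    # field elements travel in their fixed 8-byte big-endian serialization
    a2 <- sa[[2]]$value
    b1 <- sb[[1]]$value
    ch_send(ch, "A", cx_f61_to_bytes(a2), "share of A's local counts")
    ch_send(ch, "B", cx_f61_to_bytes(b1), "share of B's local counts")
    # A holds a1 + b1, B holds a2 + b2: additive shares of the pooled counts.
    partial_a <- cx_f61_add(sa[[1]]$value, b1)
    partial_b <- cx_f61_add(a2, sb[[2]]$value)
    ch_send(ch, "A", cx_f61_to_bytes(partial_a), "masked partial sum (A)")
    ch_send(ch, "B", cx_f61_to_bytes(partial_b), "masked partial sum (B)")
    pooled <- as.numeric(cx_f61_add(partial_a, partial_b))
    t1 <- proc.time()[["elapsed"]]

    m <- length(sites)
    counts <- counts_from_group_sums(
      sites,
      case_alt = pooled[1:m], case_tot = pooled[m + 1:m],
      control_alt = pooled[2 * m + 1:m], control_tot = pooled[3 * m + 1:m])
    stats <- stats_from_counts(counts, p_value = p_value)
    oracle <- gwas_stats(rbind_genotype_matrix(gm_a, gm_b), p_value = p_value)
    metrics <- metrics_report(
      task = "gwas_smc",
      accuracy_exact = identical_stats(stats, oracle),
      max_deviation = max_stat_deviation(stats, oracle),
      security_bits = 61,
      time_s = list(party_a = (t1 - t0) / 2, party_b = (t1 - t0) / 2),
      storage_bytes = 8 * 2 * length(ca),
      comm_bytes = channel_bytes(ch),
      n = m,
      seed = if (is.null(seed)) NA_integer_ else seed,
      config = list(n_a = nrow(gm_a$dosage), n_b = nrow(gm_b$dosage),
                    n_sites = m))
    list(stats = stats, metrics = metrics, oracle = oracle, channel = ch)
  })
}

# ---- Diffie-Hellman private set intersection cardinality ----

# RFC 3526 group 14: 2048-bit safe prime (p = 2q + 1, q prime); elements
# are mapped into the quadratic-residue subgroup of order q by squaring.
psi_group_prime <- function() {
  paste0(
    "FFFFFFFFFFFFFFFFC90FDAA22168C234C4C6628B80DC1CD129024E088A67CC74",
    "020BBEA63B139B22514A08798E3404DDEF9519B3CD3A431B302B0A6DF25F1437",
    "4FE1356D6D51C245E485B576625E7EC6F44C42E9A637ED6B0BFF5CB6F406B7ED",
    "EE386BFB5A899FA5AE9F24117C4B1FE649286651ECE45B3DC2007CB8A163BF05",
    "98DA48361C55D39A69163FA8FD24CF5F83655D23DCA3AD961C62F356208552BB",
    "9ED529077096966D670C354E4ABC9804F1746C08CA18217C32905E462E36CE3B",
    "E39E772C180E86039B2783A2EC07A28FB5C55DF06F4C52C9DE2BCBF695581718",
    "3995497CEA956AE515D2261898FA051015728E5A8AACAA68FFFFFFFFFFFFFFFF")
}

hash_to_group <- function(keys, p) {
  h <- cx_bn_mod(cx_sha256_hex(keys), p)
  cx_bn_mod_mul(h, h, p)
}

psi_secret <- function(bits = 256) raw_to_hex(rand_bytes(bits / 8))

#' Private set intersection cardinality between two variant sets
#'
#' Classic semi-honest DH-style PSI-CA in the quadratic-residue subgroup
#' of a 2048-bit safe prime: each party hashes each variant key into the
#' group (SHA-256, then squaring), exponentiates with its secret, and
#' exchanges; the counterpart re-exponentiates and returns the first
#' party's elements shuffled. Equal double-exponentiated elements
#' correspond to equal keys, so the number of matches is exactly
#' `|a intersect b|`. Only the set sizes and the cardinality are revealed.
#'
#' @param a,b `variant_set`s held by parties A and B (same key mode).
#' @param ch an [channel()] (created if `NULL`).
#' @param exp_bits secret exponent size in bits (default 256, far above
#'   the 80-bit security floor).
#' @param seed optional seed for secrets and the mandatory shuffle.
#' @return list with `cardinality`, `sizes`, and `channel`.
#' @export
psi_cardinality <- function(a, b, ch = NULL, exp_bits = 256, seed = NULL) {
  stopifnot(inherits(a, "variant_set"), inherits(b, "variant_set"))
  check_same_key_mode(a, b)
  if (is.null(ch)) ch <- channel(retain_limit = 0)
  with_seed_if(seed, {
    p <- psi_group_prime()
    ka <- variant_keys(a); kb <- variant_keys(b)
    ea <- hash_to_group(ka, p)
    eb <- hash_to_group(kb, p)
    if (anyDuplicated(ea) || anyDuplicated(eb))
      abort("hash collision among distinct keys detected (probability ~2^-256)")
    x <- psi_secret(exp_bits)  # A's secret
    y <- psi_secret(exp_bits)  # B's secret
    # A -> B: H(a_i)^x ; B returns them re-exponentiated and SHUFFLED
    xa <- ch_send(ch, "A", cx_bn_mod_exp(ea, x, p), "A's blinded elements")
    xa_y <- ch_send(ch, "B", sample(cx_bn_mod_exp(xa, y, p)),
                    "A's elements re-blinded by B (shuffled)")
    # B -> A: H(b_j)^y ; A re-exponentiates locally
    yb <- ch_send(ch, "B", cx_bn_mod_exp(eb, y, p), "B's blinded elements")
    yb_x <- cx_bn_mod_exp(yb, x, p)
    card <- length(intersect(xa_y, yb_x))
    ch_send(ch, "A", as.numeric(card), "cardinality")
    list(cardinality = card, sizes = c(a = length(ka), b = length(kb)),
         channel = ch)
  })
}

#' Two-party secure genome distance via PSI cardinality
#'
#' Runs [psi_cardinality()] on the two parties' keyed variant sets and
#' lets each party finish `|a| + |b| - 2 |a intersect b|` locally — the
#' Hamming distance, which the set-difference approximation of edit
#' distance equals in cardinality mode. The result equals the plaintext
#' [hamming_distance()] / [approx_edit_distance()] value exactly.
#'
#' @inheritParams psi_cardinality
#' @param kind `"hamming"` or `"edit_approx"` (same value, different
#'   result label).
#' @return list with `result` (tibble: kind, value, sizes, intersection),
#'   `metrics` (a [metrics_report()]) and `channel`.
#' @export
smc_distance <- function(a, b, kind = c("hamming", "edit_approx"), ch = NULL,
                         exp_bits = 256, seed = NULL) {
  kind <- match.arg(kind)
  if (is.null(ch)) ch <- channel(retain_limit = 0)
  t0 <- proc.time()[["elapsed"]]
  psi <- psi_cardinality(a, b, ch = ch, exp_bits = exp_bits, seed = seed)
  value <- length(variant_keys(a)) + length(variant_keys(b)) -
    2L * psi$cardinality
  t1 <- proc.time()[["elapsed"]]
  oracle <- if (kind == "hamming") hamming_distance(a, b) else
    approx_edit_distance(a, b, "cardinality")
  result <- tibble::tibble(
    kind = kind, value = value,
    size_a = psi$sizes[["a"]], size_b = psi$sizes[["b"]],
    intersection = psi$cardinality)
  metrics <- metrics_report(
    task = paste0("dist_", kind, "_smc"),
    accuracy_exact = value == oracle,
    max_deviation = abs(value - oracle),
    security_bits = 80,
    time_s = list(party_a = (t1 - t0) / 2, party_b = (t1 - t0) / 2),
    storage_bytes = 0,
    comm_bytes = channel_bytes(ch),
    n = psi$sizes[["a"]] + psi$sizes[["b"]],
    seed = if (is.null(seed)) NA_integer_ else seed,
    config = list(exp_bits = exp_bits, kind = kind))
  list(result = result, metrics = metrics, channel = ch)
}
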