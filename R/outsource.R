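#' Semi-honest aggregation server for the HE-outsourced GWAS protocol
#'
#' The server holds only the public key and homomorphically sums the
#' per-sample encrypted contributions into per-site, per-group count
#' accumulators. Role separation is enforced by construction: the server
#' object refuses anything that carries private key material, so no code
#' path on the server side can decrypt.
#'
#' @param pk a `paillier_public_key` (a private key or keypair is
#'   rejected).
#' @return an `he_server`.
#' @export
he_server <- function(pk) {
  if (inherits(pk, "paillier_private_key") || inherits(pk, "paillier_keypair"))
    abort("the aggregation server must never receive private key material")
  stopifnot(inherits(pk, "paillier_public_key"))
  env <- new.env(parent = emptyenv())
  env$pk <- pk
  env$stored_bytes <- 0
  structure(env, class = "he_server")
}

ciphertext_bytes <- function(ct) hex_payload_bytes(ct$value)

# Server-side computation: homomorphic sum of each site x group block.
he_server_aggregate <- function(server, enc_alt, enc_tot2, is_case, sites) {
  stopifnot(inherits(server, "he_server"))
  pk <- server$pk
  n_samples <- length(is_case)
  server$stored_bytes <- server$stored_bytes +
    ciphertext_bytes(enc_alt) + ciphertext_bytes(enc_tot2)
  agg_one <- function(values, rows, site_idx) {
    idx <- (site_idx - 1L) * n_samples + which(rows)
    cx_bn_mod_prod(values[idx], pk$n_sq)
  }
  bundle <- purrr::map(seq_along(sites), function(j) {
    list(case_alt = agg_one(enc_alt$value, is_case, j),
         case_tot = agg_one(enc_tot2$value, is_case, j),
         control_alt = agg_one(enc_alt$value, !is_case, j),
         control_tot = agg_one(enc_tot2$value, !is_case, j))
  })
  lapply(c("case_alt", "case_tot", "control_alt", "control_tot"), function(f) {
    new_ciphertext(vapply(bundle, `[[`, character(1), f), pk)
  }) |> stats::setNames(c("case_alt", "case_tot", "control_alt", "control_tot"))
}

#' Secure outsourcing of GWAS statistics under Paillier encryption
#'
#' Implements the outsourcing protocol: the data owner encrypts, for every
#' (sample, site) pair, the alternate-allele dosage and twice the
#' non-missing indicator; a semi-honest server (which never sees the
#' private key) homomorphically sums them into four encrypted allele-count
#' accumulators per site; the owner decrypts only these aggregate counts
#' and finishes MAF and chi-square locally. The result is exactly —
#' bit-identical, since both routes run the same integer-count arithmetic
#' — the plaintext [gwas_stats()] output on the same matrix.
#'
#' @param gm a [genotype_matrix()].
#' @param keypair a `paillier_keypair`; generated fresh when `NULL`.
#' @param bits key size when generating (see [paillier_keygen()]).
#' @param allow_insecure passed to [paillier_keygen()].
#' @param sites optional subset of site ids to analyse.
#' @param p_value include p-values.
#' @param seed optional seed (keys and randomizers).
#' @return list with `stats` (a `gwas_result`), `metrics` (a
#'   [metrics_report()] including ciphertext storage and transfer bytes),
#'   and `oracle` (the plaintext result it was verified against).
#' @export
outsource_gwas <- function(gm, keypair = NULL, bits = 1024,
                           allow_insecure = FALSE, sites = NULL,
                           p_value = TRUE, seed = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  with_seed_if(seed, {
    if (is.null(keypair)) keypair <- paillier_keygen(bits, allow_insecure)
    pk <- keypair$pk
    if (is.null(sites)) sites <- colnames(gm$dosage)
    d <- gm$dosage[, sites, drop = FALSE]
    is_case <- gm$label == "case"
    # overflow guard: aggregate counts are bounded by 2 x samples << n
    stopifnot(cx_bn_cmp(num_to_hex(2 * nrow(d)), pk$n) < 0)

    t0 <- proc.time()[["elapsed"]]
    alt <- as.integer(ifelse(is.na(d), 0L, d))
    tot2 <- as.integer(ifelse(is.na(d), 0L, 2L))
    enc_alt <- paillier_encrypt(pk, alt)
    enc_tot2 <- paillier_encrypt(pk, tot2)
    t1 <- proc.time()[["elapsed"]]

    ch <- channel(retain_limit = 0)
    ch_send(ch, "client", enc_alt$value, "encrypted alt dosages")
    ch_send(ch, "client", enc_tot2$value, "encrypted non-missing indicators (x2)")
    server <- he_server(pk)
    bundle <- he_server_aggregate(server, enc_alt, enc_tot2, is_case, sites)
    t2 <- proc.time()[["elapsed"]]
    for (f in names(bundle)) ch_send(ch, "server", bundle[[f]]$value,
                                     paste0("aggregate ", f))

    dec <- lapply(bundle, function(ct) paillier_decrypt(keypair$sk, ct))
    counts <- counts_from_group_sums(sites, dec$case_alt, dec$case_tot,
                                     dec$control_alt, dec$control_tot)
    stats <- stats_from_counts(counts, p_value = p_value)
    t3 <- proc.time()[["elapsed"]]

    oracle <- gwas_stats(genotype_matrix(d, gm$label), p_value = p_value)
    metrics <- metrics_report(
      task = "gwas_he",
      accuracy_exact = identical_stats(stats, oracle),
      max_deviation = max_stat_deviation(stats, oracle),
      security_bits = if (pk$bits >= 1024) 80 else NA_real_,
      time_s = list(encrypt = t1 - t0, compute = t2 - t1, decrypt = t3 - t2),
      storage_bytes = server$stored_bytes,
      comm_bytes = channel_bytes(ch),
      n = length(sites),
      seed = if (is.null(seed)) NA_integer_ else seed,
      config = list(bits = pk$bits, n_samples = nrow(d), n_sites = length(sites)))
    list(stats = stats, metrics = metrics, oracle = oracle)
  })
}

identical_stats <- function(x, y) {
  isTRUE(all.equal(as.data.frame(x), as.data.frame(y), tolerance = 0)) &&
    identical(x$chi2, y$chi2) && identical(x$maf, y$maf)
}

max_stat_deviation <- function(x, y) {
  dev <- c(abs(x$chi2 - y$chi2), abs(x$maf - y$maf))
  dev <- dev[!is.na(dev)]
  if (length(dev) == 0) 0 else max(dev)
}
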