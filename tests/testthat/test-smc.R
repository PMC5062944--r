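test_that("additive shares reconstruct exactly and reject foreign fields", {
  s0 <- share_split(0)
  expect_equal(share_reconstruct(s0[[1]], s0[[2]]), 0)
  withr::with_seed(41, {
    v <- sample.int(2^30, 1000)
    s <- share_split(v)
    expect_equal(share_reconstruct(s[[1]], s[[2]]), v)
  })
  expect_error(share_split(5, p = "101"), "Mersenne")
  s <- share_split(5)
  s[[2]]$p <- "101"
  expect_error(share_reconstruct(s[[1]], s[[2]]), "different fields")
})

test_that("a single share of a fixed value is uniform over the field", {
  withr::with_seed(42, {
    s <- share_split(rep(123456, 10000))
    u <- as.numeric(s[[1]]$value) / as.numeric(smc_field_prime())
    counts <- table(cut(u, breaks = seq(0, 1, length.out = 17)))
    gof <- stats::chisq.test(as.vector(counts))
    expect_gt(gof$p.value, 1e-4)
  })
})

test_that("two-party GWAS equals the centralized pipeline on a toy partition", {
  ga <- toy_gm(list(c(0L, 1L, 2L), c(1L, 1L, 0L)),
               list(c(2L, 0L, 1L), c(0L, 0L, 1L)))
  gb <- toy_gm(list(c(1L, 2L, 2L), c(2L, 1L, 0L)),
               list(c(0L, 0L, 0L), c(1L, 2L, 1L)))
  r <- smc_gwas(ga, gb, seed = 5)
  expect_true(r$metrics$accuracy_exact)
  expect_identical(r$stats$chi2, r$oracle$chi2)
  expect_identical(r$stats$maf, r$oracle$maf)
  expect_gt(r$metrics$comm_bytes_total, 0)
})

test_that("a party with all values missing at a site contributes nothing", {
  da <- cbind(s1 = c(NA_integer_, NA_integer_), s2 = c(1L, 2L))
  db <- cbind(s1 = c(1L, 2L), s2 = c(0L, 1L))
  ga <- genotype_matrix(da, c("case", "control"))
  gb <- genotype_matrix(db, c("case", "control"))
  r <- smc_gwas(ga, gb, seed = 6)
  solo <- gwas_stats(gb)
  expect_equal(r$stats$case_minor[1] + r$stats$case_major[1],
               solo$case_minor[1] + solo$case_major[1])
  expect_true(r$metrics$accuracy_exact)
})

test_that("mismatched site universes abort with the offending sites named", {
  ga <- toy_gm(list(0L), list(1L), sites = "rs1")
  gb <- toy_gm(list(0L), list(1L), sites = "rs2")
  expect_error(smc_gwas(ga, gb), "rs1")
})

test_that("share payloads on the wire are statistically uniform bytes", {
  ga <- simulate_genotypes(20, 20, 200, seed = 7)
  gb <- simulate_genotypes(20, 20, 200, seed = 8)
  r <- smc_gwas(ga, gb, seed = 9)
  payloads <- genocrypt:::channel_payloads(r$channel, "share of")
  value_bytes <- unlist(lapply(payloads, function(p) {
    # fixed 8-byte big-endian field elements; the top byte holds only the
    # high 5 bits of a 61-bit value, so drop it
    m <- matrix(as.integer(p), nrow = 8)
    as.vector(m[-1, ])
  }))
  expect_gt(length(value_bytes), 5000)
  freq <- tabulate(value_bytes + 1L, nbins = 256) / length(value_bytes)
  entropy <- -sum(ifelse(freq > 0, freq * log2(freq), 0))
  expect_gt(entropy, 7.8)  # uniform bytes have entropy 8
})

test_that("PSI cardinality is exact on identical, disjoint, and overlapping sets", {
  a <- vs_from_positions(1:100, "a")
  expect_equal(psi_cardinality(a, a, seed = 1)$cardinality, 100)
  b <- vs_from_positions(101:160, "b")
  expect_equal(psi_cardinality(a, b, seed = 2)$cardinality, 0)
  pair <- simulate_genome_pair(n_a = 500, n_b = 500, n_shared = 300, seed = 3)
  psi <- psi_cardinality(pair$a, pair$b, seed = 4)
  expect_equal(psi$cardinality,
               length(intersect(variant_keys(pair$a), variant_keys(pair$b))))
})

test_that("PSI is symmetric in the parties and invariant to key order", {
  pair <- simulate_genome_pair(n_a = 120, n_b = 140, n_shared = 60, seed = 10)
  expect_equal(psi_cardinality(pair$a, pair$b, seed = 11)$cardinality, 60)
  expect_equal(psi_cardinality(pair$b, pair$a, seed = 12)$cardinality, 60)
  shuffled <- pair$a[sample(nrow(pair$a)), ]
  expect_equal(psi_cardinality(shuffled, pair$b, seed = 13)$cardinality, 60)
})

test_that("the returned re-blinded elements are shuffled relative to sending order", {
  a <- vs_from_positions(1:80, "a")
  b <- vs_from_positions(41:120, "b")
  ch <- channel(retain_limit = 1e7)
  psi_cardinality(a, b, ch = ch, seed = 14)
  tr <- channel_transcript(ch)
  expect_equal(tr$label[1:3],
               c("A's blinded elements", "A's elements re-blinded by B (shuffled)",
                 "B's blinded elements"))
  # same element count both ways, but bytes differ because order is randomized
  expect_equal(tr$bytes[1], tr$bytes[2], tolerance = 0.01)
})

test_that("secure distances equal the plaintext symmetric difference", {
  pair <- simulate_genome_pair(n_a = 400, n_b = 380, n_shared = 200, seed = 15)
  r <- smc_distance(pair$a, pair$b, "hamming", seed = 16)
  expect_equal(r$result$value, hamming_distance(pair$a, pair$b))
  expect_true(r$metrics$accuracy_exact)
  expect_gt(r$metrics$comm_bytes_total, 0)
  r2 <- smc_distance(pair$a, pair$b, "edit_approx", seed = 17)
  expect_equal(r2$result$value, approx_edit_distance(pair$a, pair$b))
  same <- smc_distance(pair$a, pair$a, "hamming", seed = 18)
  expect_equal(same$result$value, 0)
})

test_that("channel byte counts are deterministic for fixed inputs and seeds", {
  pair <- simulate_genome_pair(n_a = 100, n_b = 100, n_shared = 50, seed = 19)
  b1 <- smc_distance(pair$a, pair$b, "hamming", seed = 20)$metrics$comm_bytes_total
  b2 <- smc_distance(pair$a, pair$b, "hamming", seed = 20)$metrics$comm_bytes_total
  expect_identical(b1, b2)
  g1 <- smc_gwas(simulate_genotypes(10, 10, 20, seed = 1),
                 simulate_genotypes(10, 10, 20, seed = 2), seed = 21)
  g2 <- smc_gwas(simulate_genotypes(10, 10, 20, seed = 1),
                 simulate_genotypes(10, 10, 20, seed = 2), seed = 21)
  expect_identical(g1$metrics$comm_bytes_total, g2$metrics$comm_bytes_total)
})
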