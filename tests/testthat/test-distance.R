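test_that("DP edit distance handles trivial and boundary cases", {
  expect_equal(edit_distance_dp("ACGT", "ACGT"), 0)
  expect_equal(edit_distance_dp("", "ACGTA"), 5)
  expect_equal(edit_distance_dp("ACGTA", ""), 5)
  expect_equal(edit_distance_dp("", ""), 0)
  # prefix pairs: distance equals length difference
  expect_equal(edit_distance_dp("ACGTACGT", "ACGT"), 4)
  expect_error(edit_distance_dp("ACGN", "ACG"), "A, C, G, T")
})

test_that("DP edit distance matches a memoized recursion on random pairs", {
  withr::with_seed(21, {
    for (i in 1:200) {
      a <- random_dna(sample(0:50, 1))
      b <- random_dna(sample(0:50, 1))
      expect_equal(edit_distance_dp(a, b), edit_distance_memo(a, b))
    }
    # spot check against the generalized distance in base R
    for (i in 1:20) {
      a <- random_dna(60); b <- random_dna(60)
      expect_equal(edit_distance_dp(a, b), unname(utils::adist(a, b)[1, 1]))
    }
  })
})

test_that("edit distance satisfies the metric axioms", {
  withr::with_seed(22, {
    for (i in 1:100) {
      x <- random_dna(sample(5:40, 1))
      y <- random_dna(sample(5:40, 1))
      z <- random_dna(sample(5:40, 1))
      dxy <- edit_distance_dp(x, y)
      dyz <- edit_distance_dp(y, z)
      dxz <- edit_distance_dp(x, z)
      expect_equal(dxy, edit_distance_dp(y, x))
      expect_lte(dxz, dxy + dyz)
      expect_identical(edit_distance_dp(x, x), 0L)
    }
  })
})

test_that("hamming distance is the symmetric difference of key sets", {
  a <- vs_from_positions(1:3, "a")
  b <- vs_from_positions(4:7, "b")
  expect_equal(hamming_distance(a, a), 0)
  expect_equal(hamming_distance(a, b), 7)
  withr::with_seed(23, {
    for (i in 1:1000) {
      pa <- sample.int(200, sample(5:50, 1))
      pb <- sample.int(200, sample(5:50, 1))
      va <- vs_from_positions(pa); vb <- vs_from_positions(pb)
      direct <- length(setdiff(paste(pa), paste(pb))) +
        length(setdiff(paste(pb), paste(pa)))
      expect_equal(hamming_distance(va, vb), direct)
    }
  })
})

test_that("planted-overlap pairs give |a|+|b|-2|intersection| exactly", {
  pair <- simulate_genome_pair(n_a = 1000, n_b = 1000, n_shared = 600, seed = 3)
  expect_equal(hamming_distance(pair$a, pair$b), 800)
  expect_equal(approx_edit_distance(pair$a, pair$b), 800)
})

test_that("symmetric-difference distance is a metric on random set triples", {
  withr::with_seed(24, {
    for (i in 1:100) {
      x <- vs_from_positions(sample.int(100, 30))
      y <- vs_from_positions(sample.int(100, 30))
      z <- vs_from_positions(sample.int(100, 30))
      dxy <- hamming_distance(x, y)
      expect_equal(dxy, hamming_distance(y, x))
      expect_lte(abs(hamming_distance(x, z) - hamming_distance(y, z)), dxy)
      expect_identical(hamming_distance(x, x), 0L)
      # cardinality-mode approximation is the same statistic by construction
      expect_identical(approx_edit_distance(x, y), dxy)
    }
  })
})

test_that("key-mode mismatch is a configuration error", {
  a <- variant_set(tibble::tibble(chrom = "1", pos = 1L, ref = "A", alt = "G"),
                   key_mode = "zygosity")
  b <- variant_set(tibble::tibble(chrom = "1", pos = 1L, ref = "A", alt = "G"),
                   key_mode = "site")
  expect_error(hamming_distance(a, b), "key_mode")
  expect_error(approx_edit_distance(a, b), "key_mode")
})

test_that("indel-length weighting charges one edit per base beyond the anchor", {
  mk <- function(ref, alt) variant_set(
    tibble::tibble(chrom = "1", pos = 10L, ref = ref, alt = alt),
    key_mode = "site")
  empty <- variant_set(tibble::tibble(chrom = character(), pos = integer(),
                                      ref = character(), alt = character()),
                       key_mode = "site")
  expect_equal(approx_edit_distance(mk("A", "G"), empty, "indel_length"), 1)
  expect_equal(approx_edit_distance(mk("AC", "A"), empty, "indel_length"), 1)
  expect_equal(approx_edit_distance(mk("ACGT", "A"), empty, "indel_length"), 3)
  expect_equal(approx_edit_distance(mk("A", "ACGT"), empty, "indel_length"), 3)
})

test_that("reconstruct_sequence applies variants right-to-left and validates", {
  ref <- "ACGTACGTAC"
  expect_identical(reconstruct_sequence(ref, tibble::tibble(pos = integer(),
                                                            ref = character(),
                                                            alt = character())),
                   ref)
  one <- reconstruct_sequence(ref, tibble::tibble(pos = 3L, ref = "G", alt = "T"))
  expect_equal(edit_distance_dp(ref, one), 1)
  expect_equal(substr(one, 3, 3), "T")
  # length bookkeeping for an insertion and a deletion
  out <- reconstruct_sequence(ref, tibble::tibble(pos = c(2L, 6L),
                                                  ref = c("C", "CG"),
                                                  alt = c("CTT", "C")))
  expect_equal(nchar(out), nchar(ref) + 2 - 1)
  expect_error(reconstruct_sequence(ref, tibble::tibble(pos = 99L, ref = "A",
                                                        alt = "G")),
               "out of range")
  expect_error(reconstruct_sequence(ref, tibble::tibble(pos = c(3L, 4L),
                                                        ref = c("GT", "T"),
                                                        alt = c("G", "A"))),
               "overlap")
  expect_error(reconstruct_sequence(ref, tibble::tibble(pos = 1L, ref = "G",
                                                        alt = "T")),
               "mismatch")
})

test_that("k spaced SNVs cost exactly k edits, matching the approximation", {
  withr::with_seed(25, {
    ref <- random_dna(2000)
    pos <- seq(10, by = 40, length.out = 25)
    recs <- tibble::tibble(chrom = "seg", pos = pos,
                           ref = vapply(pos, function(p) substr(ref, p, p),
                                        character(1)))
    recs$alt <- vapply(recs$ref, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    mut <- reconstruct_sequence(ref, recs)
    expect_equal(edit_distance_dp(ref, mut), 25)
  })
})

test_that("validate_approximation reports the documented deviation convention", {
  # all-identical pairs: every pair exact, all deviations zero
  same <- constructed_pair(0)
  same$vs_a <- same$vs_b <- list(same$vs_b[[1]])
  same$seq_a <- same$seq_b
  rep20 <- dplyr::bind_rows(lapply(1:20, function(i) same))
  v0 <- validate_approximation(rep20)
  expect_equal(sum(v0$exact), 20)
  expect_true(all(v0$deviation_pct == 0))

  # one colliding site on top of 26 clean SNVs: approximation 28, truth 27,
  # reported as 3.7 % of the true distance
  pair <- constructed_pair(26, colliding = TRUE)
  v <- validate_approximation(pair)
  expect_equal(v$approx, 28)
  expect_equal(v$true, 27)
  expect_false(v$exact)
  expect_equal(v$deviation_pct, 3.7)

  # zero true distance with nonzero approximation: undefined deviation
  odd <- constructed_pair(0)
  odd$seq_a <- odd$seq_b <- odd$ref
  odd$vs_a <- list(vs_from_positions(5))
  odd$vs_b <- list(vs_from_positions(300))
  vodd <- validate_approximation(odd)
  expect_true(is.na(vodd$deviation_pct))
  g <- glance(validate_approximation(pair))
  expect_named(g, c("n_pairs", "n_exact", "max_deviation_pct", "mean_true"))
})
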