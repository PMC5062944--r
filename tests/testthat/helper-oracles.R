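# Independent oracles used across the suite. These deliberately share no
# code with the package implementation.

# Levenshtein by plain memoized recursion (reference for the DP route).
edit_distance_memo <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0) return(j)
    if (j == 0) return(i)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    cost <- if (ca[i] == cb[j]) 0L else 1L
    v <- min(rec(i - 1L, j - 1L) + cost, rec(i - 1L, j) + 1L, rec(i, j - 1L) + 1L)
    memo[[key]] <- v
    v
  }
  rec(length(ca), length(cb))
}

# Pearson chi-square by explicit observed-vs-expected summation.
chi2_observed_expected <- function(a, b, c, d) {
  obs <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  n <- sum(obs)
  exp <- outer(rowSums(obs), colSums(obs)) / n
  sum((obs - exp)^2 / exp)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Tiny genotype matrix from explicit dosage rows.
toy_gm <- function(case_rows, control_rows, sites = NULL) {
  d <- rbind(do.call(rbind, case_rows), do.call(rbind, control_rows))
  if (is.null(sites)) sites <- sprintf("s%d", seq_len(ncol(d)))
  colnames(d) <- sites
  genotype_matrix(d, rep(c("case", "control"),
                         c(length(case_rows), length(control_rows))))
}

# Variant set from bare keys (SNVs on chromosome 1 at the given positions).
vs_from_positions <- function(pos, owner = "g", alt = NULL) {
  ref <- rep("A", length(pos))
  if (is.null(alt)) alt <- rep("G", length(pos))
  variant_set(tibble::tibble(chrom = "1", pos = pos, ref = ref, alt = alt),
              owner = owner, key_mode = "site")
}

# A segment pair whose approximation and true distance are known by
# construction: n_clean spaced private SNVs on side A plus (optionally)
# one position where the two sides carry different alternate alleles,
# which the set difference counts twice but alignment fixes with one
# substitution.
constructed_pair <- function(n_clean, colliding = FALSE, seed = 99) {
  withr::with_seed(seed, {
    L <- 40 * (n_clean + 2)
    ref <- random_dna(L)
    pos <- seq(10, by = 30, length.out = n_clean + 1)
    base_at <- function(p) substr(ref, p, p)
    other <- function(b, avoid = character(0))
      sample(setdiff(c("A", "C", "G", "T"), c(b, avoid)), 1)
    recs_a <- tibble::tibble(
      chrom = "seg", pos = pos[seq_len(n_clean)],
      ref = vapply(pos[seq_len(n_clean)], base_at, character(1)))
    recs_a$alt <- vapply(recs_a$ref, other, character(1))
    recs_b <- recs_a[0, ]
    if (colliding) {
      p <- pos[n_clean + 1]
      b0 <- base_at(p)
      alt_a <- other(b0)
      alt_b <- other(b0, avoid = alt_a)
      recs_a <- rbind(recs_a,
                      tibble::tibble(chrom = "seg", pos = p, ref = b0, alt = alt_a))
      recs_b <- tibble::tibble(chrom = "seg", pos = p, ref = b0, alt = alt_b)
    }
    tibble::tibble(
      pair_id = 1L, ref = ref,
      seq_a = reconstruct_sequence(ref, recs_a),
      seq_b = reconstruct_sequence(ref, recs_b),
      vs_a = list(variant_set(recs_a, owner = "A", key_mode = "site")),
      vs_b = list(variant_set(recs_b, owner = "B", key_mode = "site")))
  })
}
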