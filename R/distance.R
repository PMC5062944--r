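#' Exact Levenshtein edit distance (dynamic programming)
#'
#' Unit-cost substitution/insertion/deletion distance computed with a
#' two-row rolling DP in compiled code. This is the ground-truth oracle
#' against which the set-difference approximation is validated.
#'
#' @param s1,s2 nucleotide strings over A, C, G, T (empty allowed).
#' @return non-negative integer distance.
#' @export
edit_distance_dp <- function(s1, s2) {
  s1 <- check_sequence(s1); s2 <- check_sequence(s2)
  cx_levenshtein(s1, s2)
}

check_sequence <- function(s) {
  stopifnot(is.character(s), length(s) == 1, !is.na(s))
  s <- toupper(s)
  if (!grepl("^[ACGT]*$", s))
    abort("sequence must contain only A, C, G, T")
  s
}

#' Hamming distance between two genomes' keyed variant sets
#'
#' Defined as the size of the symmetric difference of the two variant key
#' sets, `|a| + |b| - 2 |a intersect b|`. Both sets must have been built
#' with the same key mode.
#'
#' @param a,b `variant_set`s.
#' @return non-negative integer.
#' @export
hamming_distance <- function(a, b) {
  stopifnot(inherits(a, "variant_set"), inherits(b, "variant_set"))
  check_same_key_mode(a, b)
  ka <- variant_keys(a); kb <- variant_keys(b)
  length(ka) + length(kb) - 2L * length(intersect(ka, kb))
}

#' Set-difference approximation of edit distance
#'
#' Two genomes represented by their variations from a common reference
#' have an edit distance well approximated by the size of the symmetric
#' difference of their variation sets: shared variants change both
#' sequences identically and cancel, and each private variant costs about
#' one edit. `weighting = "cardinality"` (default) counts each differing
#' key once and coincides with [hamming_distance()]. `weighting =
#' "indel_length"` charges each differing key
#' `max(nchar(ref), nchar(alt)) - lcp` edits (at least 1), where `lcp` is
#' the shared ref/alt prefix length — a refinement for multi-base indels,
#' which cost one edit per base in the true distance.
#'
#' @param a,b `variant_set`s built with the same key mode.
#' @param weighting `"cardinality"` or `"indel_length"`.
#' @return non-negative integer.
#' @export
approx_edit_distance <- function(a, b,
                                 weighting = c("cardinality", "indel_length")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(a, "variant_set"), inherits(b, "variant_set"))
  check_same_key_mode(a, b)
  if (weighting == "cardinality") return(hamming_distance(a, b))
  ka <- variant_keys(a); kb <- variant_keys(b)
  diff_rows <- dplyr::bind_rows(a[!ka %in% kb, ], b[!kb %in% ka, ])
  if (nrow(diff_rows) == 0) return(0L)
  sum(vapply(seq_len(nrow(diff_rows)), function(i) {
    indel_weight(diff_rows$ref[i], diff_rows$alt[i])
  }, integer(1)))
}

indel_weight <- function(ref, alt) {
  lcp <- 0L
  m <- min(nchar(ref), nchar(alt))
  while (lcp < m && substr(ref, lcp + 1, lcp + 1) == substr(alt, lcp + 1, lcp + 1))
    lcp <- lcp + 1L
  max(max(nchar(ref), nchar(alt)) - lcp, 1L)
}

#' Apply VCF-style variants to a reference segment
#'
#' Variants (sorted by position, non-overlapping, within the reference)
#' are applied right to left so earlier positions stay valid. The output
#' length is `nchar(ref) + sum(nchar(alt) - nchar(ref))`.
#'
#' @param ref reference nucleotide string.
#' @param variants data frame with columns `pos`, `ref`, `alt` (1-based,
#'   VCF anchoring: the `ref` field is the substring replaced by `alt`).
#' @return the mutated sequence (character scalar).
#' @export
reconstruct_sequence <- function(ref, variants) {
  ref <- check_sequence(ref)
  variants <- tibble::as_tibble(variants)
  if (nrow(variants) == 0) return(ref)
  variants <- variants[order(variants$pos), ]
  ends <- variants$pos + nchar(variants$ref) - 1L
  if (any(variants$pos < 1L) || any(ends > nchar(ref)))
    abort("variant position out of range of the reference")
  if (nrow(variants) > 1 && any(variants$pos[-1] <= ends[-nrow(variants)]))
    abort("overlapping variants")
  out <- ref
  for (i in rev(seq_len(nrow(variants)))) {
    p <- variants$pos[i]
    mism <- substr(out, p, p + nchar(variants$ref[i]) - 1L)
    if (mism != toupper(variants$ref[i]))
      abort(sprintf("ref allele mismatch at pos %d: expected '%s', found '%s'",
                    p, variants$ref[i], mism))
    out <- paste0(substr(out, 1, p - 1L), toupper(variants$alt[i]),
                  substr(out, p + nchar(variants$ref[i]), nchar(out)))
  }
  out
}

#' Validate the set-difference approximation against the DP oracle
#'
#' For each segment pair, computes the approximate distance from the
#' variant sets and the true Levenshtein distance from the sequences, and
#' reports the per-pair relative deviation `|approx - true| / true` as a
#' percentage (1 decimal), with the count of exactly matched pairs.
#' A pair with true distance 0 but nonzero approximation has undefined
#' deviation (`NA`).
#'
#' @param pairs tibble as produced by [simulate_segment_pairs()]: columns
#'   `seq_a`, `seq_b` (sequences) and `vs_a`, `vs_b` (list columns of
#'   `variant_set`s).
#' @param weighting passed to [approx_edit_distance()].
#' @return an `approx_validation` tibble: `pair_id`, `approx`, `true`,
#'   `exact`, `deviation_pct`.
#' @export
validate_approximation <- function(pairs,
                                   weighting = c("cardinality", "indel_length")) {
  weighting <- match.arg(weighting)
  res <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    ap <- approx_edit_distance(pairs$vs_a[[i]], pairs$vs_b[[i]], weighting)
    tr <- edit_distance_dp(pairs$seq_a[i], pairs$seq_b[i])
    tibble::tibble(
      pair_id = if ("pair_id" %in% names(pairs)) pairs$pair_id[i] else i,
      approx = ap, true = tr, exact = ap == tr,
      deviation_pct = if (tr == 0 && ap > 0) NA_real_ else
        if (tr == 0) 0 else round(abs(ap - tr) / tr * 100, 1))
  })
  structure(res, class = c("approx_validation", class(tibble::tibble())))
}

#' @export
glance.approx_validation <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x),
    n_exact = sum(x$exact),
    max_deviation_pct = if (all(is.na(x$deviation_pct))) NA_real_ else
      max(x$deviation_pct, na.rm = TRUE),
    mean_true = mean(x$true))
}

#' @export
autoplot.approx_validation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$true, y = .data$approx)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$exact), size = 2) +
    ggplot2::labs(x = "true edit distance (DP)",
                  y = "set-difference approximation",
                  title = "Approximate vs true edit distance per segment pair") +
    ggplot2::theme_minimal()
}
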