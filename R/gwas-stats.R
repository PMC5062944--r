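#' Per-site allele count tables
#'
#' For each site, every non-missing sample contributes two alleles to its
#' group: dosage *k* contributes *k* alternate and *2 − k* reference
#' alleles. Missing samples are excluded from that site's denominators.
#' The minor allele is determined on the combined cohort (cases plus
#' controls), so the case and control rows always refer to the same
#' allele.
#'
#' @param gm a [genotype_matrix()].
#' @param sites site ids (default: all). Explicitly requesting a site at
#'   which every sample is missing is an error; in whole-matrix mode such
#'   degenerate sites are returned with zero counts and a warning.
#' @return tibble with one row per site: `site`, `case_minor`,
#'   `case_major`, `control_minor`, `control_major`, `n_total` (total
#'   allele count) and `minor_is_alt`.
#' @export
allele_counts <- function(gm, sites = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  explicit <- !is.null(sites)
  if (is.null(sites)) sites <- colnames(gm$dosage)
  missing_sites <- setdiff(sites, colnames(gm$dosage))
  if (length(missing_sites) > 0)
    abort(paste0("unknown site(s): ", paste(missing_sites, collapse = ", ")))
  if (sum(gm$label == "case") == 0 || sum(gm$label == "control") == 0)
    abort("both case and control groups must be non-empty")
  d <- gm$dosage[, sites, drop = FALSE]
  is_case <- gm$label == "case"
  grp_counts <- function(rows) {
    sub <- d[rows, , drop = FALSE]
    alt <- colSums(sub, na.rm = TRUE)
    tot <- 2L * colSums(!is.na(sub))
    list(alt = alt, tot = tot)
  }
  ca <- grp_counts(is_case)
  co <- grp_counts(!is_case)
  counts_from_group_sums(sites, ca$alt, ca$tot, co$alt, co$tot,
                         error_on_degenerate = explicit)
}

# Shared count->table step: used identically by the plaintext pipeline,
# the HE-outsourced client, and both SMC parties, so that all routes make
# the same minor-allele call and produce bit-identical statistics.
counts_from_group_sums <- function(sites, case_alt, case_tot, control_alt,
                                   control_tot, error_on_degenerate = FALSE) {
  n_tot <- case_tot + control_tot
  degenerate <- n_tot == 0
  if (any(degenerate)) {
    if (error_on_degenerate)
      abort(paste0("degenerate site (all samples missing): ",
                   paste(sites[degenerate], collapse = ", ")))
    warning("site(s) with all samples missing yield zero counts: ",
            paste(sites[degenerate], collapse = ", "), call. = FALSE)
  }
  p_alt <- ifelse(n_tot > 0, (case_alt + control_alt) / n_tot, NA_real_)
  minor_is_alt <- !is.na(p_alt) & p_alt <= 0.5
  tibble::tibble(
    site = sites,
    case_minor = as.integer(ifelse(minor_is_alt, case_alt, case_tot - case_alt)),
    case_major = as.integer(ifelse(minor_is_alt, case_tot - case_alt, case_alt)),
    control_minor = as.integer(ifelse(minor_is_alt, control_alt,
                                      control_tot - control_alt)),
    control_major = as.integer(ifelse(minor_is_alt, control_tot - control_alt,
                                      control_alt)),
    n_total = as.integer(n_tot),
    minor_is_alt = ifelse(degenerate, NA, minor_is_alt))
}

count_cols <- function(t) {
  need <- c("case_minor", "case_major", "control_minor", "control_major")
  if (is.data.frame(t)) {
    miss <- setdiff(need, names(t))
    if (length(miss) > 0)
      abort(paste0("count table lacks column(s): ", paste(miss, collapse = ", ")))
    lapply(t[need], as.numeric)
  } else if (is.numeric(t) && length(t) == 4) {
    as.list(stats::setNames(as.numeric(t), need))
  } else {
    abort("expected a count tibble or a numeric vector (a, b, c, d)")
  }
}

#' Minor allele frequency from an allele count table
#'
#' `maf = min(p, 1 - p)` with `p = (a + c) / N` under the combined-cohort
#' convention, where `a`, `c` are the case and control minor-allele counts
#' and `N` the total allele count. Always in `[0, 0.5]`.
#'
#' @param t a count tibble from [allele_counts()] or a numeric vector
#'   `(a, b, c, d)` = (case minor, case major, control minor, control major).
#' @return numeric vector of frequencies (`NA` for empty tables).
#' @export
maf <- function(t) {
  cc <- count_cols(t)
  n <- cc$case_minor + cc$case_major + cc$control_minor + cc$control_major
  if (length(n) == 1 && n == 0) abort("degenerate table: N = 0")
  p <- ifelse(n > 0, (cc$case_minor + cc$control_minor) / n, NA_real_)
  pmin(p, 1 - p)
}

#' Allelic chi-square statistic (2x2, 1 df, no continuity correction)
#'
#' Pearson chi-square on the 2x2 table of (case/control) x (minor/major)
#' allele counts: `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`. Identical to
#' the observed-vs-expected Pearson sum over the four cells. A zero
#' marginal makes the statistic undefined; it is reported as `NA` with a
#' warning, never silently 0.
#'
#' @inheritParams maf
#' @return numeric vector of chi-square values.
#' @export
chi2_allelic <- function(t) {
  cc <- count_cols(t)
  a <- cc$case_minor; b <- cc$case_major
  c <- cc$control_minor; d <- cc$control_major
  n <- a + b + c + d
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  undefined <- is.na(denom) | denom == 0
  if (any(undefined, na.rm = TRUE))
    warning("chi-square undefined (zero marginal) at ",
            sum(undefined), " site(s); reported as NA", call. = FALSE)
  ifelse(undefined, NA_real_, n * (a * d - b * c)^2 / denom)
}

#' Plaintext GWAS statistics: MAF and allelic chi-square per site
#'
#' The reference pipeline every secure protocol is required to match
#' exactly: allele counting, combined-cohort minor allele call, MAF, and
#' the allelic chi-square statistic, with an optional p-value from the
#' 1-df chi-square survival function.
#'
#' @param gm a [genotype_matrix()].
#' @param p_value include a `p_value` column.
#' @return a `gwas_result` tibble: `site`, the four counts, `maf`, `chi2`,
#'   `df` and optionally `p_value`.
#' @export
gwas_stats <- function(gm, p_value = TRUE) {
  counts <- allele_counts(gm)
  stats_from_counts(counts, p_value = p_value)
}

stats_from_counts <- function(counts, p_value = TRUE) {
  out <- dplyr::mutate(counts,
    maf = maf(counts),
    chi2 = chi2_allelic(counts),
    df = 1L)
  if (p_value)
    out$p_value <- stats::pchisq(out$chi2, df = 1, lower.tail = FALSE)
  structure(out, class = c("gwas_result", class(tibble::tibble())))
}

#' Write a GWAS result table as TSV
#' @param x a `gwas_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gwas_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @export
tidy.gwas_result <- function(x, ...) {
  tibble::as_tibble(unclass(x)[setdiff(names(x), character(0))])
}

#' @export
glance.gwas_result <- function(x, ...) {
  tibble::tibble(
    n_sites = nrow(x),
    n_defined = sum(!is.na(x$chi2)),
    median_maf = stats::median(x$maf, na.rm = TRUE),
    max_chi2 = suppressWarnings(max(x$chi2, na.rm = TRUE)),
    n_sig_05 = if ("p_value" %in% names(x)) sum(x$p_value < 0.05, na.rm = TRUE) else NA_integer_)
}

#' @export
autoplot.gwas_result <- function(object, ...) {
  df <- tibble::tibble(index = seq_len(nrow(object)), chi2 = object$chi2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$chi2)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = stats::qchisq(0.95, 1), linetype = "dashed") +
    ggplot2::labs(x = "SNP site index", y = expression(chi^2),
                  title = "Allelic chi-square by site",
                  subtitle = "dashed: 0.05 critical value (1 df)") +
    ggplot2::theme_minimal()
}
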