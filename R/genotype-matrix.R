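#' Case/control genotype matrices
#'
#' A `genotype_matrix` holds an individuals-by-SNP-sites dosage matrix
#' (values 0, 1, 2 counting alternate alleles, `NA` for missing) together
#' with a case/control label per sample. It is the substrate of the GWAS
#' statistics and of both secure GWAS protocols.
#'
#' @param dosage integer matrix, samples in rows, sites in columns, with
#'   dimnames; values in \{0, 1, 2, NA\}.
#' @param label per-sample group, `"case"` or `"control"`.
#' @return a `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, label) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("S%04d", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("site_%04d", seq_len(ncol(dosage)))
  label <- as.character(label)
  if (length(label) != nrow(dosage))
    abort("one label per sample required")
  if (!all(label %in% c("case", "control")))
    abort(paste0("unknown label(s): ",
                 paste(unique(setdiff(label, c("case", "control"))), collapse = ", ")))
  bad <- !(dosage %in% c(0L, 1L, 2L) | is.na(dosage))
  if (any(bad)) abort("dosage values must be 0, 1, 2 or missing")
  structure(list(dosage = dosage, label = label),
            class = "genotype_matrix")
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples (%d case / %d control) x %d sites; %.3f missing\n",
              nrow(x$dosage), sum(x$label == "case"), sum(x$label == "control"),
              ncol(x$dosage), mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Tidy a genotype matrix into long format
#' @param x a `genotype_matrix`; `...` unused.
#' @return tibble with columns `sample_id`, `label`, `site`, `dosage`.
#' @export
as_tibble.genotype_matrix <- function(x, ...) {
  tibble::tibble(
    sample_id = rep(rownames(x$dosage), times = ncol(x$dosage)),
    label = rep(x$label, times = ncol(x$dosage)),
    site = rep(colnames(x$dosage), each = nrow(x$dosage)),
    dosage = as.integer(x$dosage))
}

#' Row-bind two genotype matrices sharing a site universe
#' @noRd
rbind_genotype_matrix <- function(a, b) {
  if (!identical(colnames(a$dosage), colnames(b$dosage)))
    abort("site universes differ; cannot pool")
  genotype_matrix(rbind(a$dosage, b$dosage), c(a$label, b$label))
}

#' Read a genotype matrix from TSV or VCF
#'
#' The TSV dialect has a header row `sample_id`, `label`, then one column
#' per site id; one row per sample; dosages in \{0,1,2\} with `.` for
#' missing. The VCF route reads a multi-sample VCF's GT fields
#' (`0/0`, `0/1`, `1/1` become dosages 0, 1, 2; `./.` missing) and takes
#' labels from the `labels` argument (VCF has no phenotype column).
#'
#' @param path input file.
#' @param format `"tsv"` or `"vcf"`.
#' @param labels for `format = "vcf"`, a named character vector (or plain
#'   vector in sample order) of `"case"`/`"control"` labels.
#' @return a `genotype_matrix`.
#' @export
read_genotype_matrix <- function(path, format = c("tsv", "vcf"), labels = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
    if (!identical(names(df)[1:2], c("sample_id", "label")))
      abort("TSV must start with columns sample_id, label")
    vals <- as.matrix(df[, -(1:2), drop = FALSE])
    vals[vals == "."] <- NA
    suppressWarnings(storage.mode(vals) <- "integer")
    if (any(!(vals %in% c(0L, 1L, 2L)) & !is.na(vals)))
      abort("dosage outside {0,1,2}")
    rownames(vals) <- df$sample_id
    genotype_matrix(vals, df$label)
  } else {
    v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
    gt <- vcfR::extract.gt(v, element = "GT")
    dos <- apply(gt, c(1, 2), function(g) {
      if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NA_integer_)
      sum(strsplit(g, "[/|]")[[1]] == "1")
    })
    dos <- t(dos)  # samples x sites
    colnames(dos) <- paste(vcfR::getFIX(v)[, "CHROM"], vcfR::getFIX(v)[, "POS"],
                           sep = ":")
    if (is.null(labels)) abort("labels must be supplied for VCF input")
    if (!is.null(names(labels))) labels <- labels[rownames(dos)]
    genotype_matrix(dos, labels)
  }
}

#' Write a genotype matrix in the package's TSV dialect
#' @param gm a `genotype_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(gm, path) {
  vals <- gm$dosage
  out <- cbind(sample_id = rownames(vals), label = gm$label,
               apply(vals, 2, function(col) ifelse(is.na(col), ".", col)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
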