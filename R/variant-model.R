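#' Variant sets: keyed representation of one genome's variants
#'
#' A `variant_set` is a tibble with one row per canonical variant key and
#' columns `chrom`, `pos` (1-based, VCF convention), `ref`, `alt`,
#' `zygosity` (`"het"` or `"hom"`), plus a `key` column that is the
#' canonical tuple the distance operations compare. Two key modes exist:
#'
#' * `"zygosity"` (default): the key is `(chrom, pos, ref, alt, zygosity)`,
#'   so a heterozygous and a homozygous-alternate call at the same site are
#'   different genomic states and count as a difference.
#' * `"site"`: the key is `(chrom, pos, ref, alt)`, for sensitivity
#'   analysis of how much zygosity contributes to a distance.
#'
#' @param records data frame with columns `chrom`, `pos`, `ref`, `alt` and
#'   optionally `zygosity`; alleles are uppercased on construction.
#' @param owner identifier of the genome the variants belong to.
#' @param key_mode `"zygosity"` or `"site"`.
#' @param source provenance string (file path or generator descriptor).
#' @return a `variant_set` tibble.
#' @export
variant_set <- function(records, owner = "genome",
                        key_mode = c("zygosity", "site"),
                        source = "in-memory") {
  key_mode <- match.arg(key_mode)
  records <- tibble::as_tibble(records)
  required <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0)
    abort(paste0("records lack column(s): ", paste(missing_cols, collapse = ", ")))
  if (!"zygosity" %in% names(records)) records$zygosity <- "het"
  records <- dplyr::mutate(records,
    chrom = as.character(.data$chrom),
    pos = as.integer(.data$pos),
    ref = toupper(.data$ref),
    alt = toupper(.data$alt))
  validate_alleles(records)
  records$key <- variant_key(records, key_mode)
  records <- dplyr::distinct(records, .data$key, .keep_all = TRUE)
  new_variant_set(records, owner, key_mode, source)
}

new_variant_set <- function(df, owner, key_mode, source) {
  structure(df,
            class = c("variant_set", class(tibble::tibble()))
            , owner = owner, key_mode = key_mode, source = source)
}

validate_alleles <- function(records) {
  if (any(records$pos < 1L, na.rm = TRUE)) abort("pos must be >= 1")
  if (any(is.na(records$pos))) abort("pos must be an integer position")
  bad <- !grepl("^[ACGT]+$", records$ref) | !grepl("^[ACGT]+$", records$alt)
  if (any(bad))
    abort(paste0("alleles must be non-empty strings over A,C,G,T; offending rows: ",
                 paste(utils::head(which(bad), 5), collapse = ", ")))
  if (any(records$ref == records$alt)) abort("ref and alt must differ")
  invisible(records)
}

variant_key <- function(records, key_mode) {
  base <- paste(records$chrom, records$pos, records$ref, records$alt, sep = ":")
  if (key_mode == "zygosity") paste(base, records$zygosity, sep = ":") else base
}

#' @exportS3Method base::print
print.variant_set <- function(x, ...) {
  cat(sprintf("<variant_set> owner=%s keys=%d key_mode=%s\n",
              attr(x, "owner"), nrow(x), attr(x, "key_mode")))
  NextMethod()
}

#' Extract the canonical keys of a variant set
#' @param vs a `variant_set`.
#' @return character vector of distinct keys.
#' @export
variant_keys <- function(vs) {
  stopifnot(inherits(vs, "variant_set"))
  vs$key
}

key_mode_of <- function(vs) attr(vs, "key_mode")

check_same_key_mode <- function(a, b) {
  if (!identical(key_mode_of(a), key_mode_of(b)))
    abort(sprintf("key_mode mismatch: '%s' vs '%s'",
                  key_mode_of(a), key_mode_of(b)))
  invisible(TRUE)
}

#' Read a single-sample VCF into a variant set
#'
#' Records failing FILTER (anything other than `PASS` or `.`) are dropped;
#' multi-allelic records are split into one key per alternate allele. In
#' `"zygosity"` mode the GT field classifies each retained alternate allele
#' as `"hom"` (both chromosomes carry it) or `"het"`.
#'
#' @param path path to a VCF 4.x file (single sample; GT required for
#'   zygosity-aware keys).
#' @inheritParams variant_set
#' @param owner defaults to the file name.
#' @return a `variant_set`.
#' @export
read_vcf <- function(path, key_mode = c("zygosity", "site"), owner = NULL) {
  key_mode <- match.arg(key_mode)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (is.null(owner)) owner <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  prevalidate_vcf(path)
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0) abort(paste0("VCF contains no variant records: ", path))
  filt <- fix[, "FILTER"]
  keep <- is.na(filt) | filt %in% c("PASS", ".")
  if (!any(keep)) abort("no records pass FILTER")
  gt <- NULL
  if (key_mode == "zygosity") {
    if (ncol(v@gt) < 2)
      abort("zygosity-aware keys require a GT sample column; use key_mode='site'")
    gt <- vcfR::extract.gt(v, element = "GT")[, 1]
  }
  rows <- purrr::map(which(keep), function(i) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    zyg <- rep("het", length(alts))
    if (!is.null(gt)) {
      alleles <- strsplit(gt[i], "[/|]")[[1]]
      zyg <- vapply(seq_along(alts), function(k) {
        if (sum(alleles == as.character(k)) == 2) "hom" else "het"
      }, character(1))
    }
    tibble::tibble(chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
                   ref = fix[i, "REF"], alt = alts, zygosity = zyg)
  })
  variant_set(dplyr::bind_rows(rows), owner = owner, key_mode = key_mode,
              source = path)
}

# Light structural scan so malformed lines are reported by line number
# (the parser itself is tolerant of some malformations).
prevalidate_vcf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  if (length(body) == 0)
    abort(paste0("VCF contains no variant records: ", path))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8)
      abort(sprintf("malformed VCF line %d: expected >= 8 tab-separated fields, got %d",
                    i, length(f)))
    if (is.na(suppressWarnings(as.integer(f[2]))))
      abort(sprintf("malformed VCF line %d: POS '%s' is not an integer", i, f[2]))
  }
  invisible(TRUE)
}

#' Write variant records as a minimal single-sample VCF 4.2 file
#'
#' @param records a `variant_set` or data frame with columns `chrom`,
#'   `pos`, `ref`, `alt` and optionally `zygosity`.
#' @param path output file path.
#' @param sample_name sample column header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, sample_name = NULL) {
  if (is.null(sample_name)) {
    sample_name <- if (inherits(records, "variant_set")) attr(records, "owner") else "SAMPLE"
  }
  df <- tibble::as_tibble(records)
  if (!"zygosity" %in% names(df)) df$zygosity <- "het"
  if (any(is.na(df$chrom) | !nzchar(df$chrom)))
    abort("unsortable chromosome labels: empty or NA chrom")
  chrom_rank <- suppressWarnings(as.numeric(df$chrom))
  ord <- order(is.na(chrom_rank), chrom_rank, df$chrom, df$pos)
  df <- df[ord, ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=genocrypt",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")), con)
  if (nrow(df) > 0) {
    gt <- ifelse(df$zygosity == "hom", "1/1", "0/1")
    writeLines(paste(df$chrom, df$pos, ".", toupper(df$ref), toupper(df$alt),
                     ".", "PASS", ".", "GT", gt, sep = "\t"), con)
  }
  invisible(path)
}

#' Randomly subsample a variant set to n keys
#'
#' Mirrors the benchmark practice of selecting a random subset of variation
#' sites (e.g. 5K or 100K) to form inputs of different sizes. Reproducible
#' for a fixed seed.
#'
#' @param vs a `variant_set`.
#' @param n subset size; must not exceed `nrow(vs)`.
#' @param seed optional integer seed.
#' @return a `variant_set` of exactly `n` keys.
#' @export
select_sites <- function(vs, n, seed = NULL) {
  stopifnot(inherits(vs, "variant_set"))
  if (n > nrow(vs))
    abort(sprintf("requested %d sites but the set has only %d", n, nrow(vs)))
  idx <- with_seed_if(seed, sample.int(nrow(vs), n))
  new_variant_set(vs[sort(idx), ], attr(vs, "owner"), key_mode_of(vs),
                  paste0(attr(vs, "source"), " [subset n=", n, "]"))
}

#' Subsample a paired pair of genomes over a common site universe
#'
#' Selects `n` sites uniformly from the union of the two genomes' sites
#' (`chrom:pos`), then restricts each genome to its variants at the
#' selected sites — both members of the pair see the same site universe.
#'
#' @param a,b `variant_set`s with the same key mode.
#' @param n number of sites to select from the union of sites.
#' @param seed optional integer seed.
#' @return list with elements `a` and `b`.
#' @export
select_sites_pair <- function(a, b, n, seed = NULL) {
  check_same_key_mode(a, b)
  site_a <- paste(a$chrom, a$pos, sep = ":")
  site_b <- paste(b$chrom, b$pos, sep = ":")
  universe <- union(site_a, site_b)
  if (n > length(universe))
    abort(sprintf("requested %d sites but the union has only %d", n,
                  length(universe)))
  chosen <- with_seed_if(seed, sample(universe, n))
  list(
    a = new_variant_set(a[site_a %in% chosen, ], attr(a, "owner"),
                        key_mode_of(a), paste0(attr(a, "source"), " [paired subset]")),
    b = new_variant_set(b[site_b %in% chosen, ], attr(b, "owner"),
                        key_mode_of(b), paste0(attr(b, "source"), " [paired subset]"))
  )
}
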