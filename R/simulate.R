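#' Simulate a case/control genotype panel
#'
#' Emulates the benchmark's GWAS input at configurable scale: by default
#' 200 cases and 200 controls over 311 SNP sites. Per-site population
#' minor-allele frequencies are drawn uniformly from `maf_range`. Controls
#' are sampled, in the default `"pool"` mode, by drawing two haplotypes
#' with replacement from a simulated pool of `2 * haplotype_pool_size`
#' haplotypes — structurally mirroring controls built from the haplotypes
#' of a fixed reference panel of 174 individuals — or i.i.d. binomially in
#' `"iid"` mode (a simpler null, e.g. for calibration studies). Cases are
#' drawn binomially; at the `n_assoc_sites` associated sites the case
#' allele frequency is shifted to the requested allelic odds ratio.
#' Missingness is applied i.i.d. Fully reproducible for a fixed seed.
#'
#' @param n_case,n_control sample counts.
#' @param n_sites SNP site count.
#' @param maf_range interval in (0, 0.5] for population frequencies.
#' @param n_assoc_sites number of truly associated sites.
#' @param odds_ratio allelic odds ratio at associated sites (> 0).
#' @param missing_rate i.i.d. missingness probability in [0, 1).
#' @param haplotype_pool_size individuals in the simulated haplotype pool.
#' @param control_mode `"pool"` or `"iid"`.
#' @param seed optional integer seed.
#' @return a [genotype_matrix()] with a `sim_info` attribute recording
#'   the drawn frequencies, associated site ids, and parameters.
#' @export
simulate_genotypes <- function(n_case = 200, n_control = 200, n_sites = 311,
                               maf_range = c(0.05, 0.5), n_assoc_sites = 0,
                               odds_ratio = 1, missing_rate = 0,
                               haplotype_pool_size = 174,
                               control_mode = c("pool", "iid"), seed = NULL) {
  control_mode <- match.arg(control_mode)
  stopifnot(maf_range[1] > 0, maf_range[2] <= 0.5, maf_range[1] <= maf_range[2],
            n_assoc_sites <= n_sites, missing_rate >= 0, missing_rate < 1)
  if (!is.finite(odds_ratio) || odds_ratio <= 0)
    abort("odds_ratio must be a positive finite number")
  with_seed_if(seed, {
    sites <- sprintf("rs%05d", seq_len(n_sites))
    p0 <- stats::runif(n_sites, maf_range[1], maf_range[2])
    assoc <- sort(sample.int(n_sites, n_assoc_sites))
    odds1 <- odds_ratio * p0 / (1 - p0)
    p1 <- p0
    p1[assoc] <- odds1[assoc] / (1 + odds1[assoc])
    if (any(p1 >= 1)) abort("infeasible odds ratio: case frequency reaches 1")

    cases <- matrix(stats::rbinom(n_case * n_sites, 2, rep(p1, each = n_case)),
                    nrow = n_case)
    controls <- if (control_mode == "iid") {
      matrix(stats::rbinom(n_control * n_sites, 2, rep(p0, each = n_control)),
             nrow = n_control)
    } else {
      n_hap <- 2L * haplotype_pool_size
      pool <- matrix(stats::rbinom(n_hap * n_sites, 1, rep(p0, each = n_hap)),
                     nrow = n_hap)
      i1 <- sample.int(n_hap, n_control, replace = TRUE)
      i2 <- sample.int(n_hap, n_control, replace = TRUE)
      pool[i1, , drop = FALSE] + pool[i2, , drop = FALSE]
    }
    d <- rbind(cases, controls)
    if (missing_rate > 0)
      d[stats::runif(length(d)) < missing_rate] <- NA_integer_
    rownames(d) <- c(sprintf("case_%04d", seq_len(n_case)),
                     sprintf("control_%04d", seq_len(n_control)))
    colnames(d) <- sites
    gm <- genotype_matrix(d, rep(c("case", "control"), c(n_case, n_control)))
    attr(gm, "sim_info") <- list(
      maf = stats::setNames(p0, sites), assoc_sites = sites[assoc],
      odds_ratio = odds_ratio, missing_rate = missing_rate,
      control_mode = control_mode, haplotype_pool_size = haplotype_pool_size,
      seed = seed)
    gm
  })
}

random_alt <- function(ref_base, k) {
  vapply(seq_len(k), function(i)
    sample(setdiff(c("A", "C", "G", "T"), ref_base[i]), 1), character(1))
}

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a pair of genome variant sets with a planted overlap
#'
#' Builds two keyed variant sets of exact target sizes sharing an exact
#' number of keys (a shared core plus private variants per genome),
#' emulating a pair of individual genomes' variation sets at reduced
#' scale. Optionally writes each set as a well-formed single-sample VCF.
#'
#' @param n_a,n_b target set sizes.
#' @param n_shared exact number of shared keys; alternatively give
#'   `overlap`, the Jaccard index `|intersection| / |union|`, from which
#'   `n_shared` is rounded.
#' @param overlap Jaccard overlap in [0, 1] (ignored when `n_shared` is
#'   given).
#' @param site_universe_size positions are drawn without replacement from
#'   `1..site_universe_size` (default `10 * (n_a + n_b)`).
#' @param indel_fraction fraction of non-SNV (1-base indel) keys.
#' @param key_mode passed to [variant_set()].
#' @param dir if non-NULL, write `<owner>.vcf` files here.
#' @param seed optional integer seed.
#' @return list with `a`, `b` (`variant_set`s), `n_shared`, and `paths`
#'   (when `dir` is given).
#' @export
simulate_genome_pair <- function(n_a = 1000, n_b = n_a, n_shared = NULL,
                                 overlap = 0.6, site_universe_size = NULL,
                                 indel_fraction = 0.05,
                                 key_mode = c("zygosity", "site"),
                                 dir = NULL, seed = NULL) {
  key_mode <- match.arg(key_mode)
  if (is.null(n_shared)) {
    stopifnot(overlap >= 0, overlap <= 1)
    n_shared <- round(overlap * (n_a + n_b) / (1 + overlap))
  }
  if (n_shared > min(n_a, n_b))
    abort("n_shared exceeds the smaller set size")
  if (is.null(site_universe_size)) site_universe_size <- 10 * (n_a + n_b)
  n_distinct <- n_a + n_b - n_shared
  if (n_distinct > site_universe_size)
    abort("site universe too small for the requested set sizes")
  with_seed_if(seed, {
    pos <- sample.int(site_universe_size, n_distinct)
    ref <- sample(c("A", "C", "G", "T"), n_distinct, replace = TRUE)
    is_indel <- stats::runif(n_distinct) < indel_fraction
    alt <- random_alt(ref, n_distinct)
    # 1-base indels, VCF-anchored: insertion REF=X ALT=XY, deletion REF=XY ALT=X
    ins <- is_indel & stats::runif(n_distinct) < 0.5
    del <- is_indel & !ins
    alt[ins] <- paste0(ref[ins],
                       sample(c("A", "C", "G", "T"), sum(ins), replace = TRUE))
    extra <- sample(c("A", "C", "G", "T"), sum(del), replace = TRUE)
    ref[del] <- paste0(ref[del], extra)
    alt[del] <- substr(ref[del], 1, 1)
    records <- tibble::tibble(
      chrom = "1", pos = pos, ref = ref, alt = alt,
      zygosity = sample(c("het", "hom"), n_distinct, replace = TRUE))
    shared <- records[seq_len(n_shared), , drop = FALSE]
    priv_a <- records[n_shared + seq_len(n_a - n_shared), , drop = FALSE]
    priv_b <- records[n_shared + (n_a - n_shared) + seq_len(n_b - n_shared), ,
                      drop = FALSE]
    a <- variant_set(dplyr::bind_rows(shared, priv_a), owner = "genomeA",
                     key_mode = key_mode, source = "simulate_genome_pair")
    b <- variant_set(dplyr::bind_rows(shared, priv_b), owner = "genomeB",
                     key_mode = key_mode, source = "simulate_genome_pair")
    stopifnot(nrow(a) == n_a, nrow(b) == n_b)
    paths <- NULL
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      paths <- c(a = file.path(dir, "genomeA.vcf"),
                 b = file.path(dir, "genomeB.vcf"))
      write_vcf(a, paths[["a"]]); write_vcf(b, paths[["b"]])
    }
    list(a = a, b = b, n_shared = n_shared, paths = paths)
  })
}

# k positions in [1, max_pos] with consecutive differences >= gap
spaced_positions <- function(k, max_pos, gap) {
  m <- max_pos - (k - 1) * (gap - 1)
  if (m < k) abort("spacing infeasible: too many variants for the segment length")
  sort(sample.int(m, k)) + (seq_len(k) - 1L) * (gap - 1L)
}

#' Simulate mutated genomic segment pairs for approximation validation
#'
#' Each pair derives from one random reference segment (~5000 nt by
#' default); each side receives its own variants — `snv_fraction` SNVs,
#' the rest short indels with lengths from `indel_length_range` — at
#' positions spaced at least `min_spacing` apart across the union of both
#' sides (two genomes' private variants essentially never hit the same
#' base, and the set-difference approximation targets exactly this
#' low-density regime). The variant sets record exactly what was applied,
#' so [validate_approximation()] can compare the approximation with the
#' DP oracle on the reconstructed sequences.
#'
#' @param n_pairs number of segment pairs (default 20).
#' @param ref_length reference segment length in nucleotides.
#' @param n_variants_range inclusive range for the per-side variant count.
#' @param snv_fraction fraction of SNVs (remainder are indels).
#' @param indel_length_range inclusive indel length range in bases.
#' @param min_spacing minimum gap between variant positions.
#' @param seed optional integer seed.
#' @return tibble: `pair_id`, `ref`, `seq_a`, `seq_b`, list columns
#'   `vs_a`, `vs_b` (site-keyed `variant_set`s), `n_var_a`, `n_var_b`.
#' @export
simulate_segment_pairs <- function(n_pairs = 20, ref_length = 5000,
                                   n_variants_range = c(25, 50),
                                   snv_fraction = 0.9,
                                   indel_length_range = c(1, 1),
                                   min_spacing = 5, seed = NULL) {
  stopifnot(min_spacing >= 1, indel_length_range[1] >= 1,
            n_variants_range[1] >= 0)
  max_indel <- indel_length_range[2]
  if (ref_length <= 2 * n_variants_range[2] * (min_spacing + max_indel))
    abort("ref_length too short for the requested variant density")
  with_seed_if(seed, {
    purrr::map_dfr(seq_len(n_pairs), function(i) {
      ref <- random_bases(ref_length)
      nv_choices <- n_variants_range[1]:n_variants_range[2]
      n_side <- nv_choices[sample.int(length(nv_choices), 2, replace = TRUE)]
      k <- sum(n_side)
      gap <- min_spacing + max_indel
      pos <- if (k > 0) spaced_positions(k, ref_length - max_indel, gap)
             else integer(0)
      side <- sample(rep(c("A", "B"), n_side))
      empty_recs <- tibble::tibble(chrom = character(), pos = integer(),
                                   ref = character(), alt = character())
      recs <- purrr::map_dfr(seq_len(k), function(j) {
        p <- pos[j]
        base <- substr(ref, p, p)
        if (stats::runif(1) < snv_fraction) {
          tibble::tibble(chrom = "seg", pos = p, ref = base,
                         alt = random_alt(base, 1))
        } else {
          len_choices <- indel_length_range[1]:indel_length_range[2]
          len <- len_choices[sample.int(length(len_choices), 1)]
          if (stats::runif(1) < 0.5) {
            tibble::tibble(chrom = "seg", pos = p, ref = base,
                           alt = paste0(base, random_bases(len)))
          } else {
            tibble::tibble(chrom = "seg", pos = p,
                           ref = substr(ref, p, p + len), alt = base)
          }
        }
      })
      if (k == 0) recs <- empty_recs
      build_side <- function(which_side, owner) {
        side_recs <- recs[side == which_side, , drop = FALSE]
        list(seq = reconstruct_sequence(ref, side_recs),
             vs = variant_set(side_recs, owner = owner, key_mode = "site",
                              source = "simulate_segment_pairs"))
      }
      a <- build_side("A", sprintf("pair%02d_A", i))
      b <- build_side("B", sprintf("pair%02d_B", i))
      tibble::tibble(pair_id = i, ref = ref, seq_a = a$seq, seq_b = b$seq,
                     vs_a = list(a$vs), vs_b = list(b$vs),
                     n_var_a = n_side[1], n_var_b = n_side[2])
    })
  })
}
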