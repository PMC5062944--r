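test_that("VCF write/read round trip preserves key sets, including indel alleles", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      n <- sample(5:30, 1)
      pos <- sort(sample.int(10000, n))
      ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
      alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                    character(1))
      # throw in a 2-bp deletion and an insertion
      ref[1] <- "AC"; alt[1] <- "A"
      ref[2] <- "G";  alt[2] <- "GTT"
      vs <- variant_set(
        tibble::tibble(chrom = sample(c("1", "2", "X"), n, replace = TRUE),
                       pos = pos, ref = ref, alt = alt,
                       zygosity = sample(c("het", "hom"), n, replace = TRUE)),
        owner = "sim", key_mode = "zygosity")
      path <- withr::local_tempfile(fileext = ".vcf")
      write_vcf(vs, path)
      back <- read_vcf(path, key_mode = "zygosity")
      expect_setequal(variant_keys(back), variant_keys(vs))
      # indel allele strings survive byte-exact
      del <- back[back$ref == "AC", ]
      expect_identical(del$alt, "A")
    }
  })
})

test_that("multi-allelic records split into one key per alternate allele", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1",
    "1\t200\t.\tC\tT,G\t.\tPASS\t.\tGT\t1/2"), path)
  vs <- read_vcf(path)
  expect_equal(nrow(vs), 3)
  expect_setequal(vs$alt[vs$pos == 200], c("T", "G"))
  # a triallelic 1/2 genotype is heterozygous for both alternates
  expect_true(all(vs$zygosity[vs$pos == 200] == "het"))
  # site-only mode drops zygosity from the key but not the split
  expect_equal(nrow(read_vcf(path, key_mode = "site")), 3)
})

test_that("FILTER handling retains only PASS and '.' records", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1",
    "1\t150\t.\tT\tC\t.\t.\t.\tGT\t1/1",
    "1\t200\t.\tC\tT\t.\tq10\t.\tGT\t0/1"), path)
  vs <- read_vcf(path)
  expect_equal(sort(vs$pos), c(100L, 150L))
})

test_that("malformed and empty VCFs produce informative errors", {
  bad <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "1\t100\tonly-three-fields"), bad)
  expect_error(read_vcf(bad), "line 3")
  empty <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1"),
             empty)
  expect_error(read_vcf(empty), "no variant records")
  expect_error(write_vcf(tibble::tibble(chrom = c("1", NA), pos = c(1L, 2L),
                                        ref = "A", alt = "G"),
                         withr::local_tempfile()),
               "unsortable")
})

test_that("empty record list yields a header-only VCF", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(tibble::tibble(chrom = character(), pos = integer(),
                           ref = character(), alt = character()), path)
  lines <- readLines(path)
  expect_true(all(startsWith(lines, "#")))
  expect_match(lines[1], "fileformat=VCF")
})

test_that("variant_set enforces its invariants", {
  expect_error(variant_set(tibble::tibble(chrom = "1", pos = 0L, ref = "A",
                                          alt = "G")), "pos")
  expect_error(variant_set(tibble::tibble(chrom = "1", pos = 5L, ref = "A",
                                          alt = "A")), "differ")
  expect_error(variant_set(tibble::tibble(chrom = "1", pos = 5L, ref = "",
                                          alt = "G")), "A,C,G,T")
  # duplicate rows collapse to one key; lower-case alleles canonicalize
  vs <- variant_set(tibble::tibble(chrom = "1", pos = c(5L, 5L),
                                   ref = c("a", "A"), alt = c("g", "G")))
  expect_equal(nrow(vs), 1)
  expect_identical(vs$ref, "A")
})

test_that("select_sites is a deterministic, uniform subsample", {
  vs <- vs_from_positions(1:500)
  expect_identical(variant_keys(select_sites(vs, 500, seed = 1)),
                   variant_keys(vs))
  s1 <- select_sites(vs, 50, seed = 42)
  s2 <- select_sites(vs, 50, seed = 42)
  expect_identical(variant_keys(s1), variant_keys(s2))
  expect_true(all(variant_keys(s1) %in% variant_keys(vs)))
  expect_error(select_sites(vs, 501), "only 500")
})

test_that("subset overlap between independent draws matches the hypergeometric law", {
  big <- vs_from_positions(1:100000)
  n <- 5000; N <- 100000
  overlaps <- vapply(1:100, function(i) {
    a <- select_sites(big, n, seed = 2 * i)
    b <- select_sites(big, n, seed = 2 * i + 1)
    length(intersect(variant_keys(a), variant_keys(b)))
  }, numeric(1))
  mu <- n * n / N
  sd1 <- sqrt(n * (n / N) * (1 - n / N) * (N - n) / (N - 1))
  expect_lt(abs(mean(overlaps) - mu), 3 * sd1 / sqrt(100))
  expect_gt(stats::var(overlaps), 0)  # different seeds give different subsets
})

test_that("genotype TSV round trip, missing entries, and validation errors", {
  gm <- toy_gm(list(c(0L, 2L), c(1L, NA)), list(c(2L, 2L), c(0L, 1L)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_tsv(gm, path)
  back <- read_genotype_matrix(path, "tsv")
  expect_identical(back$dosage, gm$dosage)
  expect_identical(back$label, gm$label)
  expect_true(is.na(back$dosage[2, 2]))  # "." becomes MISSING

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tlabel\ts1", "x\tpatient\t1"), bad)
  expect_error(read_genotype_matrix(bad, "tsv"), "label")
  bad2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tlabel\ts1", "x\tcase\t3"), bad2)
  expect_error(read_genotype_matrix(bad2, "tsv"), "dosage")
})

test_that("VCF GT fields map to dosages 0/1/2 with ./. missing", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t1|1\t./.\t0|0"), path)
  gm <- read_genotype_matrix(path, "vcf",
                             labels = c(S1 = "case", S2 = "case", S3 = "control"))
  expect_equal(unname(gm$dosage[, "1:100"]), c(0L, 1L, 2L))
  expect_equal(unname(gm$dosage[, "1:200"]), c(2L, NA, 0L))
})

test_that("paired subsampling applies one site universe to both genomes", {
  pair <- simulate_genome_pair(n_a = 400, n_b = 400, overlap = 0.5, seed = 8)
  sel <- select_sites_pair(pair$a, pair$b, 300, seed = 9)
  sites <- union(paste(sel$a$chrom, sel$a$pos), paste(sel$b$chrom, sel$b$pos))
  expect_lte(length(sites), 300)
  # shared keys at selected sites survive in both members
  shared <- intersect(variant_keys(sel$a), variant_keys(sel$b))
  expect_true(all(shared %in% variant_keys(pair$a)))
  sel2 <- select_sites_pair(pair$a, pair$b, 300, seed = 9)
  expect_identical(variant_keys(sel2$a), variant_keys(sel$a))
})
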