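test_that("read_vcf collapses diploid-coded calls and flags heterozygotes", {
  path <- write_vcf_fixture(c(
    "chloroplast\t100\t.\tA\tG\t.\tPASS\t.\tGT\t1/1\t0/0",
    "chloroplast\t200\t.\tC\tT\t.\tPASS\t.\tGT\t0/1\t1",
    "chloroplast\t300\t.\tT\tTA\t.\tPASS\t.\tGT\t./.\t1|1"
  ))
  g <- suppressMessages(read_vcf(path))
  expect_s3_class(g, "chloro_geno")
  expect_equal(n_sites(g), 3)
  expect_equal(n_samples(g), 2)
  expect_equal(unname(g$calls[1, ]), c(1L, 0L))   # 1/1 -> 1, 0/0 -> 0
  expect_true(is.na(g$calls[2, 1]))               # 0/1 -> missing
  expect_equal(unname(g$calls[2, 2]), 1L)         # haploid 1 kept
  expect_true(is.na(g$calls[3, 1]))               # ./. missing
  expect_equal(unname(g$calls[3, 2]), 1L)         # phased hom collapses
  expect_equal(g$sites$vclass, c("SNP", "SNP", "InDel"))
})

test_that("read_vcf under major-allele mode keeps the first het allele", {
  path <- write_vcf_fixture(
    "chloroplast\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t1/0")
  g <- read_vcf(path, het = "major")
  expect_equal(unname(g$calls[1, ]), c(0L, 1L))
})

test_that("read_vcf errors on empty or sample-free input", {
  bad <- withr::local_tempfile(fileext = ".vcf")
  writeLines("not a vcf at all", bad)
  expect_error(read_vcf(bad))
})

test_that("all-homozygous toy VCF yields a complete matrix", {
  path <- write_vcf_fixture(c(
    "chloroplast\t10\t.\tA\tG\t.\tPASS\t.\tGT\t1\t1",
    "chloroplast\t20\t.\tC\tT\t.\tPASS\t.\tGT\t1\t1",
    "chloroplast\t30\t.\tG\tA\t.\tPASS\t.\tGT\t1\t1"
  ))
  g <- read_vcf(path)
  expect_equal(dim(g$calls), c(3L, 2L))
  expect_false(anyNA(g$calls))
  expect_true(all(g$calls == 1L))
})

test_that("variant classification follows SNP/InDel and Ts/Tv rules", {
  cls <- classify_variants(c("A", "A", "T", "C"),
                           list("G", "T", "TA", "G"))
  expect_equal(cls$vclass, c("SNP", "SNP", "InDel", "SNP"))
  expect_equal(cls$subst,
               c("transition", "transversion", NA, "transversion"))
  # symmetric in ref/alt for the substitution class
  fwd <- classify_variants(c("A", "C"), list("G", "A"))$subst
  rev <- classify_variants(c("G", "A"), list("A", "C"))$subst
  expect_equal(fwd, rev)
  # multiallelic SNP has no biallelic substitution type
  expect_true(is.na(classify_variants("A", list(c("G", "T")))$subst))
  expect_error(classify_variants("N", list("A")), "A,C,G,T")
})

test_that("filter_variants applies strict missingness and MAF boundaries", {
  n <- 200
  # missing rates 0, 0, .25, 0, .5; MAFs .3, .005, .3, .2, .3 (of non-missing)
  calls <- rbind(
    c(rep(1L, 60), rep(0L, 140)),
    c(rep(1L, 1), rep(0L, 199)),
    c(rep(1L, 45), rep(0L, 105), rep(NA_integer_, 50)),
    c(rep(1L, 40), rep(0L, 160)),
    c(rep(1L, 30), rep(0L, 70), rep(NA_integer_, 100))
  )
  g <- toy_geno(calls)
  expect_equal(site_missing_rate(g), c(0, 0, .25, 0, .5))
  expect_equal(site_maf(g), c(.3, .005, .3, .2, .3))
  f <- suppressMessages(filter_variants(g))
  expect_equal(n_sites(f), 2)
  expect_equal(f$sites$pos, g$sites$pos[c(1, 4)])
  counts <- attr(f, "filter_counts")
  expect_equal(unname(counts["retained"] + counts["removed"]), n_sites(g))
  # idempotent
  f2 <- suppressMessages(filter_variants(f))
  expect_equal(f2$sites$pos, f$sites$pos)
  expect_equal(f2$calls, f$calls)
})

test_that("MAF exactly at the cutoff is retained (removal is strict <)", {
  calls <- rbind(c(rep(1L, 1), rep(0L, 99)),   # maf = 0.01 exactly
                 c(rep(1L, 30), rep(0L, 70)))
  g <- toy_geno(calls)
  f <- suppressMessages(filter_variants(g, max_missing = 0.2, min_maf = 0.01))
  expect_equal(n_sites(f), 2)
  # missingness exactly at the cutoff is retained too (removal is strict >)
  calls2 <- rbind(c(rep(1L, 4), rep(0L, 4), NA, NA),
                  c(rep(1L, 5), rep(0L, 5)))
  g2 <- toy_geno(calls2)
  f2 <- suppressMessages(filter_variants(g2, max_missing = 0.2, min_maf = 0.01))
  expect_equal(n_sites(f2), 2)
})

test_that("Ts/Tv ratio counts biallelic SNPs only", {
  g <- toy_geno(rbind(c(0L, 1L), c(0L, 1L), c(0L, 1L), c(0L, 1L)),
                ref = c("A", "C", "A", "T"),
                alts = list("G", "T", "T", "TA"))
  expect_equal(tstv_ratio(g), 2 / 1)  # two transitions, one transversion
  g_ts <- toy_geno(rbind(c(0L, 1L)), ref = "A", alts = list("G"))
  expect_identical(tstv_ratio(g_ts), Inf)
  g_indel <- toy_geno(rbind(c(0L, 1L)), ref = "T", alts = list("TA"))
  expect_error(tstv_ratio(g_indel), "no biallelic SNPs")
})

test_that("region annotation respects 1-based inclusive gene bounds", {
  g <- toy_geno(matrix(c(0L, 1L), 4, 2, byrow = FALSE),
                pos = c(60L, 100L, 150L, 151L))
  genes <- tibble::tibble(start = 50, end = 150)
  a <- annotate_regions(g, genes)
  expect_equal(a$sites$region, c("coding", "coding", "coding", "noncoding"))
  expect_equal(mean(a$sites$region == "coding"), 0.75)
  expect_error(annotate_regions(g, tibble::tibble(start = 10, end = 5)),
               "end < start")
})

test_that("variant density counts polymorphic sites per kb of genome", {
  g <- toy_geno(rbind(c(0L, 1L, 0L), c(1L, 1L, 1L), c(0L, 0L, 1L),
                      c(0L, 0L, 0L), c(0L, 1L, 1L), c(1L, 0L, 1L),
                      c(1L, 1L, 1L)),
                genome_length = 10000L)
  # sites 2, 4 and 7 are monomorphic among the samples -> 4 polymorphic
  expect_equal(variant_density(g), 4 / 10)
  mono <- toy_geno(rbind(c(1L, 1L, 1L)), genome_length = 10000L)
  expect_equal(variant_density(mono), 0)
  expect_error(variant_density(g, samples = character(0)), "empty")
})

test_that("write_vcf / read_vcf round trip preserves the dataset", {
  set.seed(21)
  cfg <- sim_config(groups = tibble::tibble(group = c("a", "b"),
                                            n = c(6L, 5L)),
                    theta = c(a = 4, b = 2), n_fixed_diff = 3L,
                    fixed_pair_a = "a", fixed_pair_b = "b",
                    missing_rate = 0.05, seed = 99L)
  sim <- simulate_structured(cfg)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sim$geno, path)
  g2 <- suppressMessages(read_vcf(path))
  expect_equal(g2$sites$pos, sim$geno$sites$pos)
  expect_equal(g2$sites$ref, sim$geno$sites$ref)
  expect_equal(g2$sites$alts, sim$geno$sites$alts)
  expect_equal(unname(g2$calls), unname(sim$geno$calls))
  expect_equal(colnames(g2$calls), colnames(sim$geno$calls))
})
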