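test_that("genotype tokens are parsed, normalized and validated", {
  panel <- population_panel(c("NA12878", "NA12891"), sex = c("female", "male"))
  geno <- matrix(c("O1/O2", "O2/O1", "bogus", NA),
                 nrow = 2, dimnames = list(c("NA12878", "NA12891"),
                                           c("inv1", "inv2")))
  expect_warning(gt <- genotype_table(geno, panel), "unrecognized")
  expect_equal(gt$geno["NA12878", "inv1"], "O1/O2")
  expect_equal(gt$geno["NA12891", "inv1"], "O1/O2")  # O2/O1 normalized
  expect_true(is.na(gt$geno["NA12878", "inv2"]))     # unknown token
  expect_equal(o2_dosage(gt)["NA12878", "inv1"], 1)
})

test_that("ploidy rules reject impossible calls", {
  panel <- population_panel(c("m1", "f1"), sex = c("male", "female"))
  # diploid call on chrY for a male
  g <- matrix(c("O1/O2", NA), nrow = 2, dimnames = list(c("m1", "f1"), "invY"))
  expect_error(genotype_table(g, panel, c(invY = "chrY")), "diploid call")
  # any call on chrY for a female
  g2 <- matrix(c("O1", "O2"), nrow = 2, dimnames = list(c("m1", "f1"), "invY"))
  expect_error(genotype_table(g2, panel, c(invY = "chrY")), "lacking")
  # hemizygous call for a diploid (female, chrX)
  g3 <- matrix(c("O1", "O2"), nrow = 2, dimnames = list(c("m1", "f1"), "invX"))
  expect_error(genotype_table(g3, panel, c(invX = "chrX")), "hemizygous call")
  # sample missing from the panel
  g4 <- matrix("O1/O1", dimnames = list("ghost", "inv1"))
  expect_error(genotype_table(g4, panel), "absent from panel")
  # valid hemizygous male X passes
  g5 <- matrix(c("O1", "O2/O2"), nrow = 2,
               dimnames = list(c("m1", "f1"), "invX"))
  expect_silent(genotype_table(g5, panel, c(invX = "chrX")))
})

test_that("a large synthetic genotype table round-trips through disk", {
  set.seed(5)
  n <- 551; m <- 45
  panel <- toy_panel(n)
  geno <- matrix(sample(c("O1/O1", "O1/O2", "O2/O2", NA), n * m,
                        replace = TRUE, prob = c(.4, .3, .25, .05)),
                 nrow = n,
                 dimnames = list(panel$sample_id, sprintf("HsInv%04d", 1:m)))
  gt <- genotype_table(geno, panel)
  f <- tempfile(fileext = ".tsv")
  write_genotype_table(gt, f)
  gt2 <- read_genotype_table(f, panel)
  expect_identical(gt2$geno, gt$geno)
})

test_that("population panel files round-trip and trios are validated", {
  panel <- population_panel(
    c("fa", "mo", "kid", "orphan"), sex = c("male", "female", "male", "female"),
    population = "CEU", group = "EUR",
    family_role = c("father", "mother", "child", "child"),
    family_id = c("F1", "F1", "F1", "F9"))
  expect_false(panel$incomplete_trio[3])
  expect_true(panel$incomplete_trio[4])
  f <- tempfile(fileext = ".tsv")
  write_population_panel(panel, f)
  p2 <- read_population_panel(f)
  expect_equal(p2$sample_id, panel$sample_id)
  expect_equal(p2$family_id, panel$family_id)
  expect_error(population_panel(c("a", "a")), "duplicated")
})

test_that("VCF reading keeps phase, drops multiallelics, round-trips", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2", "##contig=<ID=chr1>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS001\tS002",
    "chr1\t101\t.\tA\tG\t.\tPASS\t.\tGT\t0|1\t1|1",
    "chr1\t201\t.\tC\tT,G\t.\tPASS\t.\tGT\t0/1\t0/2",
    "chr1\t301\t.\tG\t<DEL>\t.\tPASS\t.\tGT\t0/1\t0/0",
    "chr1\t401\t.\tT\tC\t.\tPASS\t.\tGT\t0|0\t0|1"), vcf)
  panel <- toy_panel(2)
  vp <- read_variants(vcf, panel)
  expect_equal(attr(vp, "dropped"), 2)          # triallelic + symbolic
  expect_equal(n_variants(vp), 2)
  expect_equal(vp$pos, c(100L, 400L))           # converted to 0-based
  expect_true(all(vp$phased[c("S001", "S002")]))
  expect_equal(vp$alleles[vp$hap_sample == "S001", 1], c(0L, 1L))
  # round-trip of a 100-SNP synthetic panel
  pool <- simulate_neutral_pool(n_samples = 8, n_loci = 4,
                                seq_length = 20000, mu = 5e-6, seed = 9)
  keep <- seq_len(min(100, n_variants(pool)))
  pool <- subset_variants(pool, variants = keep)
  out <- write_variants(pool, tempfile(fileext = ".vcf"))
  back <- read_variants(out)
  expect_equal(back$pos, pool$pos)
  expect_equal(unname(back$alleles), unname(pool$alleles))
})

test_that("samples absent from the panel are dropped with a warning", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2", "##contig=<ID=chr1>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS001\tWHO",
    "chr1\t101\t.\tA\tG\t.\tPASS\t.\tGT\t0|1\t1|1"), vcf)
  expect_warning(vp <- read_variants(vcf, toy_panel(1)), "not in panel")
  expect_equal(unique(vp$hap_sample), "S001")
})

test_that("mendelian check agrees with gamete enumeration on random trios", {
  set.seed(11)
  geno_space <- c("O1/O1", "O1/O2", "O2/O2")
  mk_panel <- function(sexes) population_panel(
    c("fa", "mo", "kid"), sex = sexes, family_role = c("father", "mother", "child"),
    family_id = "F1")
  # autosomal: all 27 configurations
  panel <- mk_panel(c("male", "female", "female"))
  for (f in geno_space) for (m in geno_space) for (k in geno_space) {
    g <- matrix(c(f, m, k), nrow = 3,
                dimnames = list(c("fa", "mo", "kid"), "inv1"))
    gt <- genotype_table(g, panel)
    res <- mendelian_check(gt)
    expect_equal(res$status == "consistent",
                 oracle_mendel(f, m, k, "autosome"),
                 info = paste(f, m, k))
  }
  # chrX with a daughter: father hemizygous
  for (f in c("O1", "O2")) for (m in geno_space) for (k in geno_space) {
    g <- matrix(c(f, m, k), nrow = 3,
                dimnames = list(c("fa", "mo", "kid"), "invX"))
    gt <- genotype_table(g, panel, c(invX = "chrX"))
    res <- mendelian_check(gt)
    expect_equal(res$status == "consistent",
                 oracle_mendel(f, m, k, "X", "female"),
                 info = paste("X", f, m, k))
  }
  # chrX son and chrY son
  panel_m <- mk_panel(c("male", "female", "male"))
  gX <- matrix(c("O1", "O2/O2", "O1"), nrow = 3,
               dimnames = list(c("fa", "mo", "kid"), "invX"))
  expect_equal(mendelian_check(genotype_table(gX, panel_m, c(invX = "chrX")))$status,
               "violation")  # son's X must be maternal
  gY <- matrix(c("O1", NA, "O2"), nrow = 3,
               dimnames = list(c("fa", "mo", "kid"), "invY"))
  expect_equal(mendelian_check(genotype_table(gY, panel_m, c(invY = "chrY")))$status,
               "violation")
  # missing genotype -> untestable, spec's worked examples
  gNA <- matrix(c("O1/O1", NA, "O1/O2"), nrow = 3,
                dimnames = list(c("fa", "mo", "kid"), "inv1"))
  expect_equal(mendelian_check(genotype_table(gNA, panel))$status, "untestable")
})

test_that("inversion records enforce coordinate sanity", {
  inv <- toy_inversion()
  expect_equal(inv$inverted_length, 30000)
  expect_equal(inversion_span(inv, "inner"), c(10000, 40000))
  expect_error(inversion_record("x", "chr1", 100, 90, 200, 210), "start <= end")
  expect_error(inversion_record("x", "chr1", 100, 250, 200, 210), "bp1_end")
})
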