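test_that("r-squared matches direct gamete counting", {
  # perfectly co-segregating haplotypes
  expect_equal(as.numeric(ld_r2(c(1, 1, 0, 0), c(1, 1, 0, 0),
                                method = "haplotype")), 1)
  # statistically independent: all four gametes at expected counts
  x <- c(1, 1, 0, 0); y <- c(1, 0, 1, 0)
  expect_equal(as.numeric(ld_r2(x, y, method = "haplotype")), 0)
  # AB=4, Ab=1, aB=1, ab=4 -> D = 0.15, r2 = 0.36
  x <- c(rep(1, 5), rep(0, 5))
  y <- c(rep(1, 4), 0, 1, rep(0, 4))
  expect_equal(as.numeric(ld_r2(x, y, method = "haplotype")), 0.36)
  # monomorphic -> missing
  expect_true(is.na(ld_r2(rep(1, 5), c(1, 0, 1, 0, 1), method = "haplotype")))
  # genotype-dosage mode reduces to cor^2
  g1 <- c(0, 1, 2, 1, 0, 2); g2 <- c(0, 1, 2, 0, 1, 2)
  expect_equal(as.numeric(ld_r2(g1, g2, method = "genotype")), cor(g1, g2)^2)
})

test_that("tag discovery distinguishes unique from recurrent inversions", {
  cfg <- sim_config(n_samples = c(POP = 25), origin = "unique", age = 4000,
                    Ne = 400, mu = 2e-6, seed = 101)
  sim <- simulate_haplotypes(cfg)
  inv <- toy_inversion()
  tags <- find_tag_variants(sim$genotypes, sim$variants, inv)
  expect_gt(nrow(tags), 0)
  expect_true(any(tags$perfect))
  # recurrent inversion on balanced backgrounds: no perfect tag
  cfg2 <- sim_config(n_samples = c(POP = 25), origin = "recurrent",
                     k_events = 2, Ne = 3000, mu = 2e-6,
                     inv_frequency = 0.4, freq_tol = 0.2, seed = 102)
  sim2 <- simulate_haplotypes(cfg2)
  tags2 <- find_tag_variants(sim2$genotypes, sim2$variants, inv,
                             threshold = 0)
  expect_lt(max(tags2$r2), 1)
  # unattainable threshold -> empty result
  none <- find_tag_variants(sim$genotypes, sim$variants, inv,
                            threshold = 1.01)
  expect_equal(nrow(none), 0)
})

test_that("variant classification matches the spec's worked cases", {
  panel <- toy_panel(6)
  geno <- matrix(c("O1/O1", "O1/O1", "O1/O2", "O1/O2", "O2/O2", "O2/O2"),
                 ncol = 1, dimnames = list(panel$sample_id, "INV1"))
  gt <- genotype_table(geno, panel)
  hapS <- rep(panel$sample_id, each = 2)
  # fixed: O1/O1 -> GG(0), O2/O2 -> AA(1), hets AG
  H <- cbind(c(0, 0, 0, 0, 0, 1, 0, 1, 1, 1, 1, 1))
  vp <- variant_panel(H, "chr1", 100L, hap_sample = hapS)
  expect_equal(classify_variants(gt, vp)$class, "fixed")
  # shared: both alleles among O1/O1 and among O2/O2 samples
  H2 <- cbind(c(0, 0, 1, 1, 0, 0, 0, 0, 0, 0, 1, 1))
  vp2 <- variant_panel(H2, "chr1", 100L, hap_sample = hapS)
  expect_equal(classify_variants(gt, vp2)$class, "shared")
  # heterozygous only in inversion heterozygotes -> unassigned
  H3 <- cbind(c(0, 0, 0, 0, 0, 1, 0, 1, 0, 0, 0, 0))
  vp3 <- variant_panel(H3, "chr1", 100L, hap_sample = hapS)
  expect_equal(classify_variants(gt, vp3)$class, "unassigned")
})

test_that("classification agrees with assignment-enumeration oracle", {
  set.seed(111)
  for (rep in 1:40) {
    n <- sample(4:10, 1)
    panel <- toy_panel(n)
    inv_g <- sample(c("O1/O1", "O1/O2", "O2/O2"), n, replace = TRUE)
    geno <- matrix(inv_g, ncol = 1, dimnames = list(panel$sample_id, "INV1"))
    gt <- genotype_table(geno, panel)
    hap_alleles <- matrix(rbinom(2 * n, 1, 0.45), ncol = 1)
    vp <- variant_panel(hap_alleles, "chr1", 100L,
                        hap_sample = rep(panel$sample_id, each = 2))
    got <- classify_variants(gt, vp)$class
    want <- oracle_classify(inv_g, variant_dosage(vp)[panel$sample_id, 1])
    expect_equal(got, want, info = paste("rep", rep))
  }
})

test_that("windowed shared-fraction profiles summarize classes correctly", {
  inv <- toy_inversion()
  # 3 shared of 10 polymorphic in one flank window -> fraction 0.3
  classes <- data.frame(
    pos = c(seq(41000, 45500, by = 500), 20000),
    class = c(rep("shared", 3), rep("private_O1", 7), "fixed"),
    stringsAsFactors = FALSE)
  prof <- window_shared_profile(classes, inv, window = 10000, step = 5000,
                                flank_span = 10000)
  w <- prof[!prof$inverted_region & prof$start == 40000, ]
  expect_equal(w$n_polymorphic, 10)
  expect_equal(w$shared_fraction, 0.3)
  # whole-region record is first and has negative distance
  expect_true(prof$inverted_region[1])
  expect_lt(prof$distance[1], 0)
  expect_error(window_shared_profile(classes, inv, flank_span = 0), "flank_span")
})

test_that("unique-origin simulations give zero shared fraction inside", {
  cfg <- sim_config(n_samples = c(POP = 20), origin = "unique", age = 4000,
                    Ne = 400, mu = 2e-6, seed = 121)
  sim <- simulate_haplotypes(cfg)
  inv <- toy_inversion()
  cls <- classify_variants(sim$genotypes, exclude_breakpoint_variants(sim$variants, inv))
  prof <- window_shared_profile(cls, inv, flank_span = 10000)
  expect_equal(prof$shared_fraction[prof$inverted_region], 0)
})

test_that("shared fraction rises with flank distance under recombination", {
  set.seed(131)
  agg <- NULL
  for (r in 1:25) {
    cfg <- sim_config(n_samples = c(POP = 12), origin = "unique", age = 4000,
                      Ne = 1000, mu = 2e-6, rho = 1e-7,
                      seq_length = 60000, inversion_span = c(20000, 40000),
                      inv_frequency = 0.4)
    sim <- simulate_haplotypes(cfg)
    inv <- inversion_record("INV1", "chr1", 20000, 20000, 40000, 40000)
    cls <- classify_variants(sim$genotypes, sim$variants)
    prof <- window_shared_profile(cls, inv, window = 4000, step = 2000,
                                  flank_span = 20000)
    fl <- prof[!prof$inverted_region, ]
    agg <- rbind(agg, fl[, c("distance", "shared_fraction")])
  }
  agg <- agg[!is.na(agg$shared_fraction), ]
  means <- tapply(agg$shared_fraction, agg$distance, mean)
  ct <- suppressWarnings(cor.test(as.numeric(names(means)), as.numeric(means),
                                  method = "spearman"))
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.05)
})

test_that("non-recombining flank scan follows the stopping rules", {
  inv <- toy_inversion()
  # no shared variants within 20 kb -> full flank
  cls <- data.frame(pos = c(seq(41000, 59000, by = 2000)),
                    class = "fixed", stringsAsFactors = FALSE)
  fl <- nonrecombining_flank(cls, inv)
  right <- fl[fl$side == "right", ]
  expect_equal(c(right$start, right$end), c(40000, 60000))
  expect_true(is.na(right$stopped_by))
  # first non-exempt shared variant at +7340 stops the scan
  cls2 <- rbind(cls, data.frame(pos = 47340, class = "shared"))
  fl2 <- nonrecombining_flank(cls2, inv)
  right2 <- fl2[fl2$side == "right", ]
  expect_equal(right2$end, 47340)
  expect_equal(right2$stopped_by, 47340)
  # a shared SNP bracketed by fixed variants within 1 kb is exempt
  cls3 <- data.frame(pos = c(47000, 47340, 47800, 52500),
                     class = c("fixed", "shared", "fixed", "shared"))
  fl3 <- nonrecombining_flank(cls3, inv)
  right3 <- fl3[fl3$side == "right", ]
  expect_equal(right3$end, 52500)     # scan passed the exempt SNP
  expect_equal(right3$stopped_by, 52500)
  # left side mirrors the rule
  cls4 <- data.frame(pos = c(1000, 5000), class = c("fixed", "shared"))
  fl4 <- nonrecombining_flank(cls4, inv)
  left4 <- fl4[fl4$side == "left", ]
  expect_equal(c(left4$start, left4$end), c(5000, 10000))
  # optional truncation at the outermost fixed variant
  fl5 <- nonrecombining_flank(cls2, inv, fixed_rule = "outermost")
  expect_equal(fl5$end[fl5$side == "right"], 47001)
})
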