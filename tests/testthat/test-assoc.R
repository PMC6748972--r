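test_that("rank normalization is symmetric, rank-invariant and normal", {
  z <- rank_normalize(c(1, 2, 3))
  expect_equal(z[2], 0)
  expect_equal(z[1], -z[3])
  expect_gt(z[3], 0)
  # any monotone transform of the input yields identical output
  x <- rexp(50)
  expect_equal(rank_normalize(x), rank_normalize(log(x)))
  expect_equal(rank_normalize(x), rank_normalize(x^3))
  expect_error(rank_normalize(rep(1, 10)), "constant")
  expect_error(rank_normalize(c(1, 2)), ">= 3")
  # missing values preserved in place
  xm <- c(5, NA, 1, 3)
  zm <- rank_normalize(xm)
  expect_true(is.na(zm[2]) && !anyNA(zm[-2]))
  # normal scores pass Shapiro-Wilk most of the time at n = 500
  set.seed(601)
  ok <- sum(replicate(100, {
    shapiro.test(rank_normalize(rcauchy(500)))$p.value > 0.05
  }))
  expect_gte(ok, 95)
})

test_that("BH q-values reproduce the direct step-up procedure", {
  set.seed(611)
  for (r in 1:50) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), oracle_bh(p))
  }
})

make_eqtl_fixture <- function(n = 200, n_genes = 40, beta = 1, seed = 1) {
  set.seed(seed)
  panel <- toy_panel(n)
  geno <- matrix(sample(c("O1/O1", "O1/O2", "O2/O2"), n, replace = TRUE,
                        prob = c(.36, .48, .16)),
                 ncol = 1, dimnames = list(panel$sample_id, "INV1"))
  gt <- genotype_table(geno, panel)
  effects <- c(beta, rep(0, n_genes - 1))
  ex <- simulate_expression(gt, effects, noise_sd = 1, baseline = 2,
                            seed = seed + 1)
  tss <- setNames(seq(5000, by = 2000, length.out = n_genes),
                  rownames(ex$expr))
  list(gt = gt, expr = ex$expr, tss = tss, inv = toy_inversion())
}

test_that("targeted eQTL finds planted effects and honours the window", {
  fx <- make_eqtl_fixture(beta = 1, seed = 621)
  res <- inversion_eqtl(fx$gt, fx$expr, fx$tss, fx$inv, n_expr_pcs = 5)
  expect_true(res$significant[res$feature == "gene0001"])
  # distant features are not tested
  tss2 <- fx$tss
  tss2["gene0002"] <- 2e6
  res2 <- inversion_eqtl(fx$gt, fx$expr, tss2, fx$inv, n_expr_pcs = 5)
  expect_false("gene0002" %in% res2$feature)
  # q-values are monotone in p
  expect_true(all(diff(res$q[order(res$p)]) >= -1e-12))
})

test_that("permuted genotypes give no associations (negative control)", {
  set.seed(631)
  zero_runs <- 0
  for (r in 1:100) {
    fx <- make_eqtl_fixture(n = 120, n_genes = 25, beta = 1, seed = 700 + r)
    res <- inversion_eqtl(fx$gt, fx$expr, fx$tss, fx$inv, n_expr_pcs = 5,
                          permute = TRUE, seed = r)
    if (sum(res$significant) == 0) zero_runs <- zero_runs + 1
  }
  # a calibrated pipeline yields zero hits in ~95 of 100 runs; 89 is the
  # 0.1% binomial lower bound at that rate
  expect_gte(zero_runs, 89)
})

test_that("joint lead ranking puts the inversion first only when it wins", {
  inv_stats <- data.frame(feature = c("g1", "g2"), p = c(1e-8, 0.01),
                          effect = c(1, 0.2))
  var_stats <- data.frame(feature = c("g1", "g1", "g2"),
                          variant = c("v1", "v2", "v3"),
                          p = c(1e-6, 0.5, 1e-5), effect = c(0.8, 0.1, 0.5))
  res <- joint_lead_eqtl(inv_stats, var_stats)
  expect_true(res$lead[res$feature == "g1"])
  expect_false(res$lead[res$feature == "g2"])
  # exact tie with a tag SNP: the inversion ranks first by convention
  tie <- joint_lead_eqtl(data.frame(feature = "g", p = 1e-4, effect = 0.5),
                         data.frame(feature = "g", variant = "tag",
                                    p = 1e-4, effect = 0.5))
  expect_true(tie$lead)
  # a feature missing from either table is skipped
  expect_equal(nrow(joint_lead_eqtl(inv_stats,
                                    var_stats[var_stats$feature == "g1", ])), 1)
})

test_that("the inversion leads over imperfectly linked SNPs", {
  set.seed(641)
  hits <- 0
  for (r in 1:50) {
    n <- 150
    dos <- rbinom(n, 2, 0.4)
    y <- rank_normalize(dos + rnorm(n))
    # tag SNP with r2 ~ 0.8: flip some genotypes
    tag <- dos
    flip <- sample(n, 15)
    tag[flip] <- rbinom(15, 2, 0.4)
    p_inv <- summary(lm(y ~ dos))$coefficients[2, 4]
    f_tag <- summary(lm(y ~ tag))$coefficients
    lead <- joint_lead_eqtl(
      data.frame(feature = "g", p = p_inv, effect = 1),
      data.frame(feature = "g", variant = "tag", p = f_tag[2, 4],
                 effect = f_tag[2, 1]))
    if (lead$lead) hits <- hits + 1
  }
  expect_gte(hits, 45)
})

test_that("GWAS locus clustering is greedy, transitive and phenotype-aware", {
  sig <- data.frame(variant = c("A", "B", "C"), chrom = "chr1",
                    pos = c(0, 90e3, 180e3), pvalue = c(1e-9, 1e-7, 1e-5),
                    phenotype = "asthma")
  res <- cluster_gwas_loci(sig)
  expect_equal(nrow(res), 1)                 # chain A-B-C merges transitively
  expect_equal(res$variant, "A")             # minimum-p representative kept
  expect_equal(res$n_signals, 3)
  # same positions, different phenotypes -> separate loci
  sig2 <- data.frame(variant = c("A", "B"), chrom = "chr1", pos = c(0, 50e3),
                     pvalue = c(1e-9, 1e-7), phenotype = c("asthma", "height"))
  expect_equal(nrow(cluster_gwas_loci(sig2)), 2)
  # LD joins distant signals of the same phenotype
  sig3 <- data.frame(variant = c("A", "B"), chrom = "chr1", pos = c(0, 5e6),
                     pvalue = c(1e-9, 1e-7), phenotype = "asthma")
  ld <- function(a, b) 0.95
  expect_equal(nrow(cluster_gwas_loci(sig3, ld = ld)), 1)
})

test_that("GWAS enrichment matches regions and keeps p conventions", {
  set.seed(651)
  vp <- simulate_neutral_pool(n_samples = 30, n_loci = 200,
                              seq_length = 400000, mu = 2e-6, seed = 652)
  inv <- inversion_record("INV1", "chr1", 150000, 150000, 170000, 170000)
  # no observed loci in the region -> p = 1
  far <- data.frame(chrom = "chr1", pos = c(1000, 2000), phenotype = "x")
  r0 <- gwas_enrichment(far, inv, vp, n_null = 200, seed = 653)
  expect_equal(r0$observed, 0)
  expect_equal(r0$p, 1)
  # loci planted uniformly: fold near 1, p not extreme
  set.seed(654)
  loci <- data.frame(chrom = "chr1", pos = sort(runif(300, 0, 4e5)),
                     phenotype = "x")
  r1 <- gwas_enrichment(loci, inv, vp, n_null = 300, seed = 655)
  expect_gt(r1$fold, 0.6); expect_lt(r1$fold, 1.6)
  # an observation above every null count -> p = 1/(n+1)
  stack <- data.frame(chrom = "chr1",
                      pos = runif(400, 130001, 189999), phenotype = "x")
  r2 <- gwas_enrichment(stack, inv, vp, n_null = 300, seed = 656)
  expect_equal(r2$p, (sum(r2$null_counts >= r2$observed) + 1) /
                 (r2$n_null + 1))
  expect_lt(r2$p, 0.05)
  # accepted null regions satisfy the matching criteria by construction
  maf <- minor_freq(vp)
  reg <- c(130000, 190000)
  target <- mean(alt_freq(vp)[vp$pos >= reg[1] & vp$pos < reg[2]])
  expect_lt(abs(r1$null_mean - mean(r1$null_counts)), 1e-12)
})

test_that("uniform planted loci give calibrated enrichment p-values", {
  set.seed(661)
  vp <- simulate_neutral_pool(n_samples = 25, n_loci = 200,
                              seq_length = 400000, mu = 2e-6, seed = 662)
  ps <- replicate(60, {
    loci <- data.frame(chrom = "chr1", pos = runif(1500, 0, 4e5),
                       phenotype = "x")
    inv_pos <- runif(1, 50000, 300000)
    inv <- inversion_record("I", "chr1", inv_pos, inv_pos,
                            inv_pos + 20000, inv_pos + 20000)
    gwas_enrichment(loci, inv, vp, n_null = 150,
                    seed = sample.int(1e6, 1))$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
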