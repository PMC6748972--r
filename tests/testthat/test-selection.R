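test_that("Weir-Cockerham FST matches the variance-component formulas", {
  # p1 = 0.2, p2 = 0.8, 50 diploids each, genotype counts exact
  g1 <- c(rep(0, 32), rep(1, 16), rep(2, 2))
  g2 <- c(rep(2, 32), rep(1, 16), rep(0, 2))
  res <- weir_cockerham_fst(cbind(c(g1, g2)), rep(c("A", "B"), each = 50))
  want <- oracle_wc_fst(p = c(mean(g1) / 2, mean(g2) / 2), n = c(50, 50),
                        h = c(mean(g1 == 1), mean(g2 == 1)))
  expect_equal(res$overall, want, tolerance = 1e-12)
  # two populations fixed for alternative alleles -> FST 1
  fixed <- weir_cockerham_fst(cbind(c(rep(0, 40), rep(2, 40))),
                              rep(c("A", "B"), each = 40))
  expect_equal(fixed$overall, 1)
  # random toy configurations against the direct transcription
  set.seed(501)
  for (r in 1:25) {
    nA <- sample(10:40, 1); nB <- sample(10:40, 1)
    gA <- rbinom(nA, 2, runif(1, 0.2, 0.8))
    gB <- rbinom(nB, 2, runif(1, 0.2, 0.8))
    g <- c(gA, gB)
    if (var(g) == 0) next
    res <- weir_cockerham_fst(cbind(g), rep(c("A", "B"), c(nA, nB)))
    want <- oracle_wc_fst(c(mean(gA) / 2, mean(gB) / 2), c(nA, nB),
                          c(mean(gA == 1), mean(gB == 1)))
    expect_equal(res$per_locus$fst, want, tolerance = 1e-12)
  }
  # monomorphic locus is undefined
  mono <- weir_cockerham_fst(cbind(rep(0, 20)), rep(c("A", "B"), each = 10))
  expect_true(is.na(mono$per_locus$fst))
})

test_that("null FST is centred near zero and haploid loci are supported", {
  set.seed(511)
  p <- runif(40, 0.2, 0.8)
  g <- sapply(p, function(pp) rbinom(100, 2, pp))
  res <- weir_cockerham_fst(g, rep(c("A", "B"), each = 50))
  expect_true(res$overall > -0.02 && res$overall < 0.02)
  # haploid (chrY-like): fixed difference -> 1; common allele -> ~0
  hap <- cbind(c(rep(0, 30), rep(1, 30)))
  expect_equal(weir_cockerham_fst(hap, rep(c("A", "B"), each = 30),
                                  ploidy = 1)$overall, 1)
  hap2 <- cbind(rbinom(200, 1, 0.5))
  r2 <- weir_cockerham_fst(hap2, rep(c("A", "B"), each = 100), ploidy = 1)
  expect_lt(abs(r2$overall), 0.05)
})

test_that("FST percentile classification follows the top-percent rules", {
  null <- seq(0, 0.5, length.out = 1000)
  expect_equal(fst_empirical_pvalue(0.9, null)$class, "strong")
  expect_equal(fst_empirical_pvalue(0.49, null)$class, "weak")
  expect_equal(fst_empirical_pvalue(0.25, null)$class, "none")
  # simulated local adaptation: shifted frequency lands in the top 1%
  set.seed(521)
  null_fst <- vapply(runif(1000, 0.05, 0.95), function(pp) {
    g <- c(rbinom(50, 2, pp), rbinom(50, 2, pp))
    f <- weir_cockerham_fst(cbind(g), rep(c("A", "B"), each = 50))$overall
    if (is.na(f)) 0 else f
  }, numeric(1))
  hits <- 0
  for (r in 1:100) {
    p0 <- runif(1, 0.2, 0.5)
    g_inv <- c(rbinom(50, 2, p0), rbinom(50, 2, p0 + 0.4))
    f_inv <- weir_cockerham_fst(cbind(g_inv), rep(c("A", "B"), each = 50))$overall
    if (fst_empirical_pvalue(f_inv, null_fst)$class == "strong") hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("LSFS linkage classification is exhaustive and exclusive", {
  H <- rbind(c(1, 0, 0, 1), c(1, 0, 1, 1), c(1, 0, 1, 0),
             c(0, 1, 0, 0), c(0, 1, 0, 0))
  haps <- haplotype_set(H, c(10, 20, 30, 40),
                        c("O2", "O2", "O2", "O1", "O1"))
  spec <- lsfs_build(haps, spans = c(0, 50), window = 50)
  # carriers {1,2,3} = focal -> nested; {4,5} disjoint; {2,3} nested;
  # {1,2,4}... col4 carriers {1,2} nested
  expect_equal(sum(spec$xi), 4)
  expect_equal(spec$windows$n_discordant, 0)
  # a discordant variant: carriers {3,4} straddle the focal set
  H2 <- cbind(H, c(0, 0, 1, 1, 0))
  haps2 <- haplotype_set(H2, c(10, 20, 30, 40, 45),
                         c("O2", "O2", "O2", "O1", "O1"))
  spec2 <- lsfs_build(haps2, spans = c(0, 50), window = 50)
  expect_equal(spec2$windows$n_discordant, 1)
  expect_equal(sum(spec2$xi) + spec2$windows$n_discordant,
               spec2$windows$n_variants)
  # under a unique-origin zero-recombination simulation nothing straddles
  cfg <- sim_config(n_samples = c(POP = 15), origin = "unique", age = 4000,
                    Ne = 300, mu = 2e-6, seed = 531)
  sim <- simulate_haplotypes(cfg)
  sp <- lsfs_build(subset_haplotypes(sim$haps, span = c(10000, 40000)),
                   spans = c(10000, 40000))
  expect_equal(sum(sp$windows$n_discordant), 0)
})

test_that("LSFS linear statistic reduces to a count ratio at unit weights", {
  set.seed(541)
  sim <- simulate_haplotypes(sim_config(n_samples = c(POP = 15),
                                        origin = "unique", age = 4000,
                                        Ne = 300, mu = 2e-6, seed = 542))
  haps <- subset_haplotypes(sim$haps, span = c(10000, 40000))
  spec <- lsfs_build(haps, spans = c(10000, 40000))
  bank <- lapply(1:120, function(i) {
    x <- rmultinom(1, sample(5:30, 1), rep(1 / 20, 20))[, 1]
    as.integer(x)
  })
  res <- lsfs_linear_test(spec, bank)
  ok <- res$n_variants > 0 & res$n_variants == rowSums(spec$xi)
  expect_equal(res$T[ok], rep(1, sum(ok)))  # sum(xi)/n = 1 without discordants
  expect_error(lsfs_linear_test(spec, bank[1:50]), ">= 100")
})

test_that("Edgington combination matches the Irwin-Hall closed form", {
  expect_equal(edgington_combine(0.2), 0.2)
  expect_equal(edgington_combine(c(0.5, 0.5)), 0.5)
  expect_equal(edgington_combine(c(0.1, 0.1)), 0.02)
  expect_error(edgington_combine(numeric(0)), "no p-values")
  expect_error(edgington_combine(c(0.5, 1.2)), "0, 1")
  # monotone: increasing any input never decreases the output
  set.seed(551)
  for (r in 1:50) {
    p <- runif(sample(2:6, 1))
    i <- sample(seq_along(p), 1)
    p2 <- p; p2[i] <- min(1, p2[i] + runif(1, 0, 1 - p2[i]))
    expect_gte(edgington_combine(p2), edgington_combine(p) - 1e-12)
  }
  # uniform p-values stay uniform after combination (Irwin-Hall check)
  sims <- replicate(2000, edgington_combine(runif(3)))
  expect_gt(suppressWarnings(ks.test(sims, "punif"))$p.value, 0.01)
})

test_that("NCD statistics match hand computation and window filters", {
  expect_equal(ncd_statistic(c(0.5, 0.5), tf = 0.5), 0)
  expect_equal(ncd_statistic(c(0.1, 0.5), tf = 0.5), sqrt(0.16 / 2),
               tolerance = 1e-12)
  expect_equal(ncd_statistic(0.5, tf = 0.5, fixed_diffs = 1),
               sqrt(0.25 / 2), tolerance = 1e-12)
  expect_error(ncd_statistic(numeric(0), 0.5), "informative")
  # windows below the informative-site minimum are excluded, not zeroed
  pos <- seq(0, 1999, by = 250)           # 8 sites in [0, 2000)
  res <- ncd_windows(pos, rep(0.3, 8), span = c(0, 3000), tf = 0.5)
  expect_true(all(res$start == 0))        # the sparse second window dropped
  expect_equal(unique(res$n_sites), 8)
  # coverage filter removes windows
  res2 <- ncd_windows(pos, rep(0.3, 8), span = c(0, 3000), tf = 0.5,
                      coverage = function(s, e) 0.1)
  expect_equal(nrow(res2), 0)
})

test_that("NCD empirical p-values use the lower tail and (r+1)/(n+1)", {
  bank <- seq(0.1, 0.4, length.out = 2000)
  r <- ncd_empirical_pvalue(0.05, bank)
  expect_equal(r$p, 1 / 2001)
  expect_error(ncd_empirical_pvalue(0.1, bank[1:100]), ">= 1000")
  expect_equal(selection_signal_class(c(a = 0.01, b = 0.02, c = 0.04)),
               "strong")
  expect_equal(selection_signal_class(c(a = 0.01, b = 0.5)), "weak")
  expect_equal(selection_signal_class(c(a = 0.2, b = 0.5)), "none")
})

test_that("balancing-like haplotype structure lowers NCD", {
  # two deep clades at frequency 0.5 push MAFs toward 0.5: NCD(0.5) small
  set.seed(561)
  hits <- 0
  for (r in 1:40) {
    cfg <- sim_config(n_samples = c(POP = 20), origin = "unique",
                      age = 30000, Ne = 300, mu = 1e-6,
                      inv_frequency = 0.5)
    sim <- simulate_haplotypes(cfg)
    maf_bal <- minor_freq(sim$variants)
    neutral <- simulate_neutral_pool(n_samples = 20, n_loci = 2,
                                     seq_length = 50000, mu = 1e-6, Ne = 300)
    v <- ncd_statistic(maf_bal, 0.5) < ncd_statistic(minor_freq(neutral), 0.5)
    hits <- hits + v
  }
  expect_gte(hits, 32)
})
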