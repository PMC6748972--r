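#' Weir-Cockerham F_ST
#'
#' Variance-component estimator of population differentiation for
#' biallelic loci: per-locus components `a` (among populations), `b`
#' (among individuals within populations) and `c` (within individuals),
#' per-locus `FST = a/(a+b+c)` and the multi-locus weighted average
#' `sum(a)/sum(a+b+c)`. Haploid loci (chrY, male chrX) use the haploid
#' moment estimator (mean-square decomposition of allele frequencies,
#' no heterozygosity component).
#'
#' @param dosage samples x loci matrix of alternative-allele dosages
#'   (0/1/2 diploid, 0/1 haploid; `NA` allowed).
#' @param pop population label per sample (>= 2 populations).
#' @param ploidy 1 or 2 (constant across samples; analyze mixed-ploidy
#'   systems in separate calls).
#' @return list with `per_locus` (data frame: `a`, `b`, `c`, `fst`) and
#'   `overall` (multi-locus weighted FST). Monomorphic loci give `NA`.
#' @export
weir_cockerham_fst <- function(dosage, pop, ploidy = 2) {
  dosage <- as.matrix(dosage)
  pop <- as.character(pop)
  stopifnot(nrow(dosage) == length(pop), ploidy %in% c(1, 2))
  pops <- unique(pop)
  if (length(pops) < 2) stopf("need >= 2 populations")
  per <- t(apply(dosage, 2, function(g) {
    if (ploidy == 2) wc_locus_diploid(g, pop, pops) else wc_locus_haploid(g, pop, pops)
  }))
  colnames(per) <- c("a", "b", "c")
  per <- as.data.frame(per)
  per$fst <- per$a / (per$a + per$b + per$c)
  denom <- sum(per$a + per$b + per$c, na.rm = TRUE)
  list(per_locus = per,
       overall = if (denom > 0) sum(per$a, na.rm = TRUE) / denom else NA_real_)
}

wc_locus_diploid <- function(g, pop, pops) {
  ok <- !is.na(g)
  if (!any(ok)) return(c(NA, NA, NA))
  n_i <- vapply(pops, function(p) sum(ok & pop == p), numeric(1))
  use <- n_i > 0
  if (sum(use) < 2) return(c(NA, NA, NA))
  pops <- pops[use]; n_i <- n_i[use]
  p_i <- vapply(pops, function(p) mean(g[ok & pop == p]) / 2, numeric(1))
  h_i <- vapply(pops, function(p) mean(g[ok & pop == p] == 1), numeric(1))
  r <- length(pops)
  nbar <- mean(n_i)
  if (nbar <= 1) return(c(NA, NA, NA))
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  if (pbar <= 0 || pbar >= 1) return(c(NA, NA, NA))
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2
  c(a, b, c_)
}

wc_locus_haploid <- function(g, pop, pops) {
  ok <- !is.na(g)
  if (!any(ok)) return(c(NA, NA, NA))
  n_i <- vapply(pops, function(p) sum(ok & pop == p), numeric(1))
  use <- n_i > 0
  if (sum(use) < 2) return(c(NA, NA, NA))
  pops <- pops[use]; n_i <- n_i[use]
  p_i <- vapply(pops, function(p) mean(g[ok & pop == p]), numeric(1))
  r <- length(pops)
  ntot <- sum(n_i)
  pbar <- sum(n_i * p_i) / ntot
  if (pbar <= 0 || pbar >= 1) return(c(NA, NA, NA))
  nc <- (ntot - sum(n_i^2) / ntot) / (r - 1)
  msp <- sum(n_i * (p_i - pbar)^2) / (r - 1)
  msg <- sum(n_i * p_i * (1 - p_i)) / sum(n_i - 1)
  a <- (msp - msg) / nc
  c(a, msg, 0)
}

#' Empirical percentile of an inversion F_ST within a matched null
#'
#' Compares the inversion F_ST with the F_ST distribution of matched null
#' variants (same individuals, similar frequency, same chromosome type)
#' and classifies the signal: `strong` in the top 1 percent, `weak` in
#' the top 5 percent, `none` otherwise.
#'
#' @param inv_fst inversion F_ST.
#' @param null_fst F_ST values of matched null variants (>= 1000
#'   recommended).
#' @return list with `percentile` (fraction of null values below the
#'   observation), `p_upper` (fraction at or above it) and `class`.
#' @export
fst_empirical_pvalue <- function(inv_fst, null_fst) {
  null_fst <- null_fst[is.finite(null_fst)]
  if (length(null_fst) == 0) stopf("empty null distribution")
  up <- mean(null_fst >= inv_fst)
  cls <- if (up <= 0.01) "strong" else if (up <= 0.05) "weak" else "none"
  list(percentile = mean(null_fst < inv_fst), p_upper = up, class = cls,
       n_null = length(null_fst))
}

#' Build linked-site frequency spectra (LSFS) around a focal allele
#'
#' For non-overlapping windows within the inverted region and its
#' non-recombining flanks, tabulates every variant by (i) its frequency
#' class and (ii) its linkage pattern with the focal (inverted) allele:
#' `nested` when its carrier set is contained in, or contains, the focal
#' carrier set; `disjoint` when the two sets do not intersect; and
#' `discordant` otherwise. Discordant variants are counted but excluded
#' from the spectrum used by the linear tests (under complete crossover
#' suppression a perfect genealogy contains none).
#'
#' @param haps an orientation-labelled [haplotype_set()].
#' @param spans interval(s) (`c(start, end)` or list of) to scan.
#' @param window window width in bases (default 3000, non-overlapping).
#' @param n_bins number of derived/minor-frequency bins for the spectrum.
#' @return an `lsfs` object: `windows` data frame (`start`, `end`,
#'   `n_variants`, `n_discordant`), `xi` matrix (windows x (2 * n_bins)
#'   counts: nested bins then disjoint bins), `focal_freq`.
#' @export
lsfs_build <- function(haps, spans = NULL, window = 3000, n_bins = 10) {
  if (is.null(spans)) spans <- list(c(min(haps$pos), max(haps$pos) + 1L))
  if (!is.list(spans)) spans <- list(spans)
  focal <- which(haps$orientation == "O2")
  n_hap <- nrow(haps$alleles)
  if (length(focal) == 0 || length(focal) == n_hap)
    stopf("focal allele must be polymorphic with assigned orientations")
  wins <- list()
  for (s in spans) {
    st <- seq(s[1], s[2] - 1, by = window)
    for (w in st) wins[[length(wins) + 1]] <- c(w, min(w + window, s[2]))
  }
  xi <- matrix(0L, nrow = length(wins), ncol = 2 * n_bins)
  colnames(xi) <- c(paste0("nested_b", seq_len(n_bins)),
                    paste0("disjoint_b", seq_len(n_bins)))
  meta <- data.frame(start = vapply(wins, `[`, 0, 1),
                     end = vapply(wins, `[`, 0, 2),
                     n_variants = 0L, n_discordant = 0L)
  freq <- variant_class_freq(haps)
  for (k in seq_along(wins)) {
    w <- wins[[k]]
    cols <- which(haps$pos >= w[1] & haps$pos < w[2])
    meta$n_variants[k] <- length(cols)
    for (j in cols) {
      carriers <- which(haps$alleles[, j] == 1L)
      cls <- carrier_topology(carriers, focal)
      if (cls == "discordant") {
        meta$n_discordant[k] <- meta$n_discordant[k] + 1L
        next
      }
      b <- min(n_bins, 1L + floor(freq[j] * n_bins))
      col <- if (cls == "nested") b else n_bins + b
      xi[k, col] <- xi[k, col] + 1L
    }
  }
  structure(list(windows = meta, xi = xi,
                 focal_freq = length(focal) / n_hap, n_bins = n_bins),
            class = "lsfs")
}

carrier_topology <- function(carriers, focal) {
  inter <- length(intersect(carriers, focal))
  if (inter == 0) return("disjoint")
  if (inter == length(carriers) || inter == length(focal)) return("nested")
  "discordant"
}

# derived frequency where the ancestral allele is known, minor otherwise
variant_class_freq <- function(haps) {
  n <- nrow(haps$alleles)
  f_alt <- colMeans(haps$alleles, na.rm = TRUE)
  ifelse(!is.na(haps$ancestral),
         ifelse(haps$ancestral == 0L, f_alt, 1 - f_alt),
         pmin(f_alt, 1 - f_alt))
}

#' Linear LSFS neutrality test with an empirical null bank
#'
#' The test statistic is linear in the spectrum, `T = sum(w * xi) /
#' n_variants`; the weight vector orients the statistic toward the
#' alternative of interest and is estimated empirically (see
#' [estimate_lsfs_weights()]), and the per-window p-value is the upper
#' empirical rank of `T` within a bank of null spectra conditioned on the
#' focal-allele frequency, with the `(r+1)/(n+1)` convention.
#'
#' @param spec an `lsfs` object from [lsfs_build()].
#' @param null_bank list of `xi` count vectors (or an `lsfs` object) from
#'   neutral windows sharing the focal-frequency conditioning (>= 100).
#' @param weights weight vector over spectrum entries; `NULL` for equal
#'   weights (the statistic then reduces to a variant-count ratio).
#' @return data frame: one row per window with `T`, `p`.
#' @export
lsfs_linear_test <- function(spec, null_bank, weights = NULL) {
  bank <- if (inherits(null_bank, "lsfs")) {
    lapply(seq_len(nrow(null_bank$xi)), function(i)
      list(xi = null_bank$xi[i, ], n = null_bank$windows$n_variants[i]))
  } else lapply(null_bank, function(x) list(xi = x, n = sum(x)))
  if (length(bank) < 100) stopf("null bank must contain >= 100 windows")
  w <- weights %||% rep(1, ncol(spec$xi))
  stat <- function(xi, n) if (n > 0) sum(w * xi) / n else NA_real_
  null_T <- vapply(bank, function(b) stat(b$xi, b$n), numeric(1))
  res <- spec$windows[, c("start", "end", "n_variants")]
  res$T <- vapply(seq_len(nrow(spec$xi)), function(k)
    stat(spec$xi[k, ], spec$windows$n_variants[k]), numeric(1))
  res$p <- vapply(res$T, function(t)
    if (is.na(t)) NA_real_ else empirical_p(t, null_T, "upper"), numeric(1))
  res
}

#' Estimate LSFS weights from simulated alternative spectra
#'
#' `w = (E_alt[xi] - E_null[xi]) / SD_null[xi]` per spectrum entry, the
#' standard nearly-optimal linear-test construction with expectations
#' replaced by simulation averages; entries never observed under the null
#' get weight 0.
#'
#' @param null_bank,alt_bank lists of `xi` vectors (or `lsfs` objects)
#'   from neutral and alternative simulations.
#' @return numeric weight vector.
#' @export
estimate_lsfs_weights <- function(null_bank, alt_bank) {
  as_mat <- function(b) {
    if (inherits(b, "lsfs")) b$xi else do.call(rbind, b)
  }
  n0 <- as_mat(null_bank); n1 <- as_mat(alt_bank)
  mu0 <- colMeans(n0); mu1 <- colMeans(n1)
  s0 <- apply(n0, 2, sd)
  w <- (mu1 - mu0) / s0
  w[!is.finite(w)] <- 0
  w
}

#' Combine per-population, per-window LSFS p-values
#'
#' Population p-values of the same window are combined with Edgington's
#' method; the window-level p-values of an inversion are then combined
#' across windows both conservatively (Bonferroni-adjusted minimum) and
#' approximately (Edgington across windows). Both summaries are reported.
#'
#' @param pmat matrix of p-values, populations in rows, windows in
#'   columns (a vector is treated as one population).
#' @return list with `per_window` (combined across populations),
#'   `conservative` and `approximate` inversion-level p-values.
#' @export
lsfs_combine <- function(pmat) {
  if (is.vector(pmat)) pmat <- matrix(pmat, nrow = 1)
  per_window <- apply(pmat, 2, function(p) edgington_combine(p[!is.na(p)]))
  ok <- per_window[!is.na(per_window)]
  list(per_window = per_window,
       conservative = min(1, min(ok) * length(ok)),
       approximate = edgington_combine(ok))
}

#' Edgington's p-value combination
#'
#' Combines independent p-values via the distribution of their sum
#' (Irwin-Hall): `P = sum_{k=0..floor(S)} (-1)^k C(n,k) (S-k)^n / n!`
#' with `S = sum(p)`, capped to `[0, 1]`.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return combined p-value.
#' @examples
#' edgington_combine(c(0.5, 0.5))  # 0.5
#' @export
edgington_combine <- function(pvalues) {
  if (length(pvalues) == 0) stopf("no p-values to combine")
  if (any(pvalues < 0 | pvalues > 1)) stopf("p-values must lie in [0, 1]")
  n <- length(pvalues)
  if (n == 1) return(pvalues)
  S <- sum(pvalues)
  k <- 0:floor(S)
  p <- sum((-1)^k * choose(n, k) * (S - k)^n) / factorial(n)
  min(1, max(0, p))
}

#' Non-central deviation (NCD) statistic
#'
#' Measures how tightly the minor-allele frequencies of a window cluster
#' around a target frequency: `NCD(tf) = sqrt(sum((MAF_i - tf)^2) / n)`,
#' where for NCD2 fixed differences with the outgroup enter as sites with
#' MAF 0. Low values indicate the frequency clustering expected under
#' long-term balancing selection.
#'
#' @param mafs minor-allele frequencies of the window's polymorphic sites.
#' @param tf target frequency (0.3, 0.4 or 0.5 in standard scans).
#' @param fixed_diffs number of fixed differences (NCD2; 0 gives NCD1).
#' @return the NCD value.
#' @examples
#' ncd_statistic(c(0.1, 0.5), tf = 0.5)            # NCD1 = 0.2828
#' ncd_statistic(0.5, tf = 0.5, fixed_diffs = 1)   # NCD2 = 0.3536
#' @export
ncd_statistic <- function(mafs, tf, fixed_diffs = 0) {
  stopifnot(tf > 0, tf <= 0.5, fixed_diffs >= 0)
  n_is <- length(mafs) + fixed_diffs
  if (n_is == 0) stopf("no informative sites")
  sqrt((sum((mafs - tf)^2) + fixed_diffs * tf^2) / n_is)
}

#' NCD statistics in overlapping windows
#'
#' Computes NCD1/NCD2 for each target frequency in overlapping windows
#' (default 2 kb with 1 kb step). Windows with fewer than `min_sites`
#' informative sites or alignment coverage below `min_coverage` are
#' excluded (not set to zero).
#'
#' @param pos variant positions (0-based).
#' @param mafs minor-allele frequencies at `pos`.
#' @param span `c(start, end)` region scanned.
#' @param fixed_pos positions of fixed differences (NCD2); `NULL` for NCD1.
#' @param tf target frequencies (default `c(0.3, 0.4, 0.5)`).
#' @param window,step window width and step in bases.
#' @param min_sites minimum informative sites per window (default 8).
#' @param coverage optional `function(start, end) -> fraction` of the
#'   window covered by outgroup alignment; `min_coverage` the cutoff.
#' @param min_coverage minimum alignment coverage (default 0.167).
#' @return data frame: `start`, `end`, `tf`, `n_sites`, `n_fixed`, `ncd`.
#' @export
ncd_windows <- function(pos, mafs, span, fixed_pos = NULL,
                        tf = c(0.3, 0.4, 0.5), window = 2000, step = 1000,
                        min_sites = 8, coverage = NULL, min_coverage = 1 / 6) {
  starts <- seq(span[1], max(span[1], span[2] - 1), by = step)
  out <- list()
  for (s in starts) {
    e <- min(s + window, span[2])
    if (!is.null(coverage) && coverage(s, e) < min_coverage) next
    sel <- pos >= s & pos < e
    nf <- if (is.null(fixed_pos)) 0L else sum(fixed_pos >= s & fixed_pos < e)
    n_is <- sum(sel) + nf
    if (n_is < min_sites) next
    for (t in tf)
      out[[length(out) + 1]] <- data.frame(
        start = s, end = e, tf = t, n_sites = sum(sel), n_fixed = nf,
        ncd = ncd_statistic(mafs[sel], t, nf))
  }
  if (length(out) == 0)
    return(data.frame(start = numeric(0), end = numeric(0), tf = numeric(0),
                      n_sites = integer(0), n_fixed = integer(0),
                      ncd = numeric(0)))
  do.call(rbind, out)
}

#' Empirical p-value of an inversion NCD against a genome-wide bank
#'
#' The inversion is summarized by its minimum-NCD window (the strongest
#' balancing-like signal) and compared with the null NCD distribution of
#' same-size regions; low NCD is balancing-like, so the p-value is the
#' lower empirical tail with the `(r+1)/(n+1)` convention.
#'
#' @param inv_ncd NCD values of the inversion's windows (one target
#'   frequency at a time).
#' @param bank null NCD values from sampled same-size regions (>= 1000).
#' @return list with `observed` (minimum-window NCD), `p`, `n_bank`.
#' @export
ncd_empirical_pvalue <- function(inv_ncd, bank) {
  bank <- bank[is.finite(bank)]
  if (length(bank) < 1000) stopf("genome bank must contain >= 1000 regions")
  if (length(inv_ncd) == 0 || all(!is.finite(inv_ncd)))
    stopf("no inversion NCD values")
  obs <- min(inv_ncd, na.rm = TRUE)
  list(observed = obs, p = empirical_p(obs, bank, "lower"),
       n_bank = length(bank))
}

#' Classify an NCD (or other per-population) selection signal
#'
#' `strong` when significant in at least three populations, `weak` when
#' significant in at least one, `none` otherwise.
#'
#' @param p_by_pop named vector of per-population p-values.
#' @param alpha significance cutoff (default 0.05).
#' @return `"strong"`, `"weak"` or `"none"`.
#' @export
selection_signal_class <- function(p_by_pop, alpha = 0.05) {
  k <- sum(p_by_pop < alpha, na.rm = TRUE)
  if (k >= 3) "strong" else if (k >= 1) "weak" else "none"
}
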