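#' Rank-based inverse normal transformation
#'
#' Maps a vector through its ranks (ties averaged) to standard normal
#' scores with the Blom offset, `qnorm((rank - 3/8) / (n + 1/4))`, so that
#' outliers cannot drive spurious associations. Missing values are
#' preserved in place.
#'
#' @param values numeric vector with at least 3 non-missing values.
#' @return numeric vector of normal scores (mean ~0, sd ~1).
#' @export
rank_normalize <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 3) stopf("need >= 3 non-missing values")
  if (var(values[ok]) == 0) stopf("constant vector cannot be rank-normalized")
  out <- rep(NA_real_, length(values))
  r <- rank(values[ok], ties.method = "average")
  out[ok] <- qnorm((r - 0.375) / (sum(ok) + 0.25))
  out
}

#' Targeted inversion cis-eQTL analysis
#'
#' Linear regression of expression on the O2-allele dosage of an
#' inversion, for every feature whose transcription start site lies
#' within `window` of the inverted region and which is expressed in at
#' least `min_prevalence` of the samples. Expression is adjusted for the
#' supplied covariates plus `n_expr_pcs` expression principal components
#' (technical confounders), then rank-normalized before testing.
#' Benjamini-Hochberg q-values are computed across all tested features;
#' a permutation mode shuffles the genotypes to provide a negative
#' control.
#'
#' @param gt a [genotype_table()].
#' @param expr features x samples expression matrix (column names are
#'   sample ids).
#' @param tss named numeric vector: TSS position per feature.
#' @param inv a one-row inversion table giving the region tested.
#' @param inversion_id inversion column of `gt`.
#' @param covariates optional data frame of per-sample covariates
#'   (rownames = sample ids), e.g. sex and genotype principal components.
#' @param n_expr_pcs number of expression principal components added to
#'   the covariates (default 10; use 20 for transcript-level data).
#' @param window TSS distance window in bases (default 1 Mb).
#' @param min_prevalence minimum fraction of samples with expression > 0.
#' @param fdr FDR threshold annotated in the output (default 0.05).
#' @param permute permute genotypes (negative control).
#' @param seed seed for the permutation.
#' @return data frame: one row per tested feature with `effect`, `tstat`,
#'   `p`, `q`, `significant`, `tss_distance`, `n`.
#' @export
inversion_eqtl <- function(gt, expr, tss, inv, inversion_id = 1,
                           covariates = NULL, n_expr_pcs = 10,
                           window = 1e6, min_prevalence = 0.2, fdr = 0.05,
                           permute = FALSE, seed = NULL) {
  dos <- o2_dosage(gt)[, inversion_id]
  samples <- intersect(names(dos)[!is.na(dos)], colnames(expr))
  if (length(samples) < 20) stopf("need >= 20 samples with genotype and expression")
  dos <- dos[samples]
  expr <- expr[, samples, drop = FALSE]
  if (permute) {
    if (!is.null(seed)) set.seed(seed)
    dos <- setNames(sample(dos), names(dos))
  }
  span <- inversion_span(inv, "outer")
  dist_to_inv <- function(x) ifelse(x < span[1], span[1] - x,
                                    ifelse(x >= span[2], x - span[2] + 1, 0))
  feats <- rownames(expr)
  feats <- feats[feats %in% names(tss)]
  feats <- feats[dist_to_inv(tss[feats]) <= window]
  prev <- rowMeans(expr[feats, , drop = FALSE] > 0)
  feats <- feats[prev >= min_prevalence]
  if (length(feats) == 0)
    return(data.frame(feature = character(0), effect = numeric(0),
                      tstat = numeric(0), p = numeric(0), q = numeric(0),
                      significant = logical(0), tss_distance = numeric(0),
                      n = integer(0)))
  # covariate matrix: user covariates + expression PCs
  C <- NULL
  if (!is.null(covariates)) {
    C <- as.matrix(covariates[samples, , drop = FALSE])
    keep <- qr(cbind(1, C))$rank - 1
    if (keep < ncol(C)) {
      warnf("dropping rank-deficient covariate column(s)")
      q <- qr(cbind(1, C))
      C <- C[, q$pivot[seq_len(q$rank)][-1] - 1, drop = FALSE]
    }
  }
  if (n_expr_pcs > 0 && length(feats) > 1) {
    pcs <- prcomp(t(expr[feats, , drop = FALSE]), center = TRUE,
                  scale. = FALSE)$x
    k <- min(n_expr_pcs, ncol(pcs), length(samples) - 3)
    C <- cbind(C, pcs[, seq_len(k), drop = FALSE])
  }
  k_cov <- if (is.null(C)) 0L else ncol(C)
  rows <- lapply(feats, function(f) {
    y <- expr[f, ]
    if (!is.null(C)) y <- stats::resid(lm(y ~ C))
    y <- rank_normalize(y)
    fit <- summary(lm(y ~ dos))$coefficients
    if (nrow(fit) < 2)
      return(data.frame(feature = f, effect = NA_real_, tstat = NA_real_,
                        p = NA_real_, tss_distance = dist_to_inv(tss[f]),
                        n = length(y)))
    # degrees of freedom account for the covariates projected out upstream
    df <- length(y) - 2 - k_cov
    data.frame(feature = f, effect = fit[2, 1], tstat = fit[2, 3],
               p = 2 * pt(-abs(fit[2, 3]), df = max(df, 1)),
               tss_distance = unname(dist_to_inv(tss[f])),
               n = length(y))
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$q) & out$q < fdr
  out[order(out$p), c("feature", "effect", "tstat", "p", "q", "significant",
                      "tss_distance", "n")]
}

#' Joint lead-eQTL ranking of an inversion against neighbouring variants
#'
#' For each feature, ranks the inversion and all neighbouring variants by
#' nominal association p-value (ties broken by decreasing absolute effect,
#' then with the inversion first so that a perfectly tied tag SNP does not
#' displace it); the inversion is flagged lead when it ranks first.
#'
#' @param inv_stats data frame from [inversion_eqtl()] (inversion
#'   association per feature).
#' @param variant_stats data frame with columns `feature`, `variant`,
#'   `p`, `effect` (neighbouring-variant associations on the same
#'   samples).
#' @return data frame: `feature`, `inv_rank`, `n_candidates`, `lead`,
#'   `best_variant`, `best_variant_p`.
#' @export
joint_lead_eqtl <- function(inv_stats, variant_stats) {
  feats <- intersect(inv_stats$feature, unique(variant_stats$feature))
  rows <- lapply(feats, function(f) {
    pi <- inv_stats$p[inv_stats$feature == f][1]
    ei <- abs(inv_stats$effect[inv_stats$feature == f][1])
    vs <- variant_stats[variant_stats$feature == f, , drop = FALSE]
    cand <- data.frame(id = c("__inversion__", vs$variant),
                       p = c(pi, vs$p), ae = c(ei, abs(vs$effect)),
                       is_inv = c(TRUE, rep(FALSE, nrow(vs))))
    ord <- order(cand$p, -cand$ae, !cand$is_inv)
    rank_inv <- which(cand$is_inv[ord])
    best_var <- vs[which.min(vs$p), , drop = FALSE]
    data.frame(feature = f, inv_rank = rank_inv,
               n_candidates = nrow(cand), lead = rank_inv == 1,
               best_variant = if (nrow(best_var)) best_var$variant else NA,
               best_variant_p = if (nrow(best_var)) best_var$p else NA)
  })
  do.call(rbind, rows)
}

#' Cluster GWAS signals into non-redundant loci
#'
#' Greedy single-linkage clustering over signals sorted by increasing
#' p-value: a signal joins an existing locus when it shares the phenotype
#' and lies within `locus_span` of any member (or is in high LD,
#' `r2 >= ld_threshold`, with any member when an LD provider is given);
#' the clustering is therefore transitive along chains. Each locus keeps
#' its minimum-p signal as representative.
#'
#' @param signals data frame with columns `variant`, `chrom`, `pos`,
#'   `pvalue`, `phenotype`.
#' @param ld optional `function(variant_a, variant_b) -> r2`.
#' @param locus_span distance criterion in bases (default 100 kb).
#' @param ld_threshold LD criterion (default 0.8).
#' @return data frame of locus representatives with `n_signals` per locus
#'   and a `locus` id column added to a `signals` attribute copy.
#' @export
cluster_gwas_loci <- function(signals, ld = NULL, locus_span = 1e5,
                              ld_threshold = 0.8) {
  sig <- signals[order(signals$pvalue), , drop = FALSE]
  locus <- rep(NA_integer_, nrow(sig))
  nxt <- 0L
  for (i in seq_len(nrow(sig))) {
    joined <- FALSE
    for (l in seq_len(nxt)) {
      members <- which(locus == l)
      if (sig$phenotype[members[1]] != sig$phenotype[i]) next
      same_chr <- sig$chrom[members] == sig$chrom[i]
      near <- any(same_chr & abs(sig$pos[members] - sig$pos[i]) <= locus_span)
      linked <- !is.null(ld) && any(vapply(members, function(m)
        isTRUE(ld(sig$variant[m], sig$variant[i]) >= ld_threshold), TRUE))
      if (near || linked) { locus[i] <- l; joined <- TRUE; break }
    }
    if (!joined) { nxt <- nxt + 1L; locus[i] <- nxt }
  }
  sig$locus <- locus
  reps <- do.call(rbind, lapply(split(sig, sig$locus), function(d) {
    r <- d[which.min(d$pvalue), , drop = FALSE]
    r$n_signals <- nrow(d)
    r
  }))
  rownames(reps) <- NULL
  attr(reps, "signals") <- sig
  reps
}

#' GWAS-signal enrichment within an inversion and its flanks
#'
#' Counts clustered GWAS loci within the inversion region plus `flank`
#' bases on each side, and compares the count with those of `n_null`
#' random same-size regions matched on SNP frequency content (mean SNP
#' frequency within `freq_tol`, and a chi-square test `p > 0.05` on the
#' counts of SNPs with MAF below/at-or-above 0.2), excluding supplied gap
#' intervals. One-tailed empirical p-value with the `(r+1)/(n+1)`
#' convention.
#'
#' @param loci data frame of locus representatives (needs `chrom`,
#'   `pos`).
#' @param inv a one-row inversion table.
#' @param vp a [variant_panel()] providing the SNP background (the
#'   "genome" over which null regions are placed).
#' @param gaps optional data frame of excluded intervals (`start`,
#'   `end`).
#' @param flank flank width in bases (default 20 kb).
#' @param n_null number of accepted null regions (default 1000).
#' @param freq_tol tolerance on the matched mean SNP frequency.
#' @param max_tries sampling attempts before giving up.
#' @param force proceed despite a low acceptance rate.
#' @param seed integer seed.
#' @return an `enrichment_result` list: `observed`, `null_counts`,
#'   `null_mean`, `fold`, `p`, `n_null`, `acceptance_rate`.
#' @export
gwas_enrichment <- function(loci, inv, vp, gaps = NULL, flank = 20000,
                            n_null = 1000, freq_tol = 0.01,
                            max_tries = 200000, force = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  span <- inversion_span(inv, "outer")
  region <- c(span[1] - flank, span[2] + flank)
  L <- region[2] - region[1]
  obs <- sum(loci$pos >= region[1] & loci$pos < region[2])
  maf <- minor_freq(vp)
  freq <- alt_freq(vp)
  in_region <- vp$pos >= region[1] & vp$pos < region[2]
  target_mean <- mean(freq[in_region])
  target_counts <- c(sum(maf[in_region] < 0.2), sum(maf[in_region] >= 0.2))
  gmin <- min(vp$pos); gmax <- max(vp$pos)
  if (gmax - gmin <= L) stopf("variant background shorter than the matched region")
  # prefix sums over position-sorted variants; candidate regions are
  # screened in vectorized batches
  o <- order(vp$pos)
  pos_s <- as.numeric(vp$pos[o])
  cs_freq <- c(0, cumsum(freq[o]))
  cs_low <- c(0, cumsum(maf[o] < 0.2))
  loci_pos <- as.numeric(sort(loci$pos))
  null_counts <- integer(0); tries <- 0L
  batch <- max(1000L, n_null)
  while (length(null_counts) < n_null && tries < max_tries) {
    nb <- min(batch, max_tries - tries)
    tries <- tries + nb
    st <- gmin + floor(runif(nb) * (gmax - gmin - L))
    en <- st + L
    if (!is.null(gaps)) {
      bad <- vapply(seq_len(nb), function(i)
        any(st[i] < gaps$end & en[i] > gaps$start), TRUE)
      st <- st[!bad]; en <- en[!bad]
      if (length(st) == 0) next
    }
    i1 <- findInterval(st - 0.5, pos_s)
    i2 <- findInterval(en - 0.5, pos_s)
    nsnp <- i2 - i1
    ok <- nsnp > 0
    ok[ok] <- abs((cs_freq[i2[ok] + 1] - cs_freq[i1[ok] + 1]) / nsnp[ok] -
                    target_mean) <= freq_tol
    if (!any(ok)) next
    low <- cs_low[i2[ok] + 1] - cs_low[i1[ok] + 1]
    nn <- nsnp[ok]
    p_chi <- vapply(seq_along(low), function(i)
      chisq2x2_p(target_counts, c(low[i], nn[i] - low[i])), numeric(1))
    ok2 <- !is.finite(p_chi) | p_chi > 0.05
    if (!any(ok2)) next
    st_ok <- st[ok][ok2]; en_ok <- en[ok][ok2]
    cnt <- findInterval(en_ok - 0.5, loci_pos) -
      findInterval(st_ok - 0.5, loci_pos)
    null_counts <- c(null_counts, cnt)
  }
  if (length(null_counts) > n_null) null_counts <- null_counts[seq_len(n_null)]
  acc <- length(null_counts) / tries
  if (length(null_counts) < n_null) {
    msg <- sprintf("only %d/%d null regions accepted (rate %.3g)",
                   length(null_counts), n_null, acc)
    if (!force) stopf("%s; relax matching or set force = TRUE", msg)
    warnf(msg)
  }
  r <- sum(null_counts >= obs)
  structure(list(observed = obs, null_counts = null_counts,
                 null_mean = mean(null_counts),
                 fold = if (mean(null_counts) > 0) obs / mean(null_counts) else NA_real_,
                 p = (r + 1) / (length(null_counts) + 1),
                 n_null = length(null_counts), acceptance_rate = acc),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("GWAS enrichment: observed %d loci, null mean %.2f, fold %.2f, p = %.4g (%d null regions)\n",
              x$observed, x$null_mean, x$fold, x$p, x$n_null))
  invisible(x)
}

# Pearson chi-square with Yates correction for a 2x2 table (fast path)
chisq2x2_p <- function(a, b) {
  m <- rbind(a, b)
  n <- sum(m)
  if (n == 0) return(NA_real_)
  e <- outer(rowSums(m), colSums(m)) / n
  if (any(e == 0)) return(NA_real_)
  stat <- sum((abs(m - e) - 0.5)^2 / e)
  pchisq(stat, df = 1, lower.tail = FALSE)
}
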