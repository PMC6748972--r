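#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test for a biallelic locus: given the observed allele
#' counts, the probability of every possible heterozygote count is
#' computed under Hardy-Weinberg proportions and the p-value is the total
#' probability of configurations no more probable than the observed one.
#' Monomorphic loci return 1.
#'
#' @param n_hom1,n_het,n_hom2 genotype counts (reference homozygote,
#'   heterozygote, alternative homozygote).
#' @return exact p-value.
#' @examples
#' hwe_exact_test(25, 50, 25)
#' @export
hwe_exact_test <- function(n_hom1, n_het, n_hom2) {
  stopifnot(n_hom1 >= 0, n_het >= 0, n_hom2 >= 0)
  n <- n_hom1 + n_het + n_hom2
  n_a <- 2 * n_hom2 + n_het            # minor-side allele count (either side)
  if (n == 0) return(1)
  if (n_a == 0 || n_a == 2 * n) return(1)
  nA <- min(n_a, 2 * n - n_a)
  # possible het counts share the parity of the minor allele count
  hets <- seq(nA %% 2, nA, by = 2)
  logp <- vapply(hets, function(h) {
    hom_min <- (nA - h) / 2
    hom_maj <- n - h - hom_min
    lfactorial(n) - lfactorial(hom_min) - lfactorial(h) - lfactorial(hom_maj) +
      h * log(2) + lfactorial(nA) + lfactorial(2 * n - nA) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs_het <- if (n_a <= 2 * n - n_a) n_het else n_het
  sum(p[p <= p[match(obs_het, hets)] * (1 + 1e-12)])
}

#' Ascertainment model for the inversion detection process
#'
#' Describes how inversions (and, in the simulation, SNPs standing in for
#' them) were discovered: the composition of the discovery panel and a
#' detection-probability function. The default detection model is carrier
#' presence — a variant is detectable in proportion to whether any
#' discovery individual carries its non-reference allele — times an
#' optional length factor; it is pluggable so that richer models (e.g.
#' frequency- or size-dependent detection) can be substituted.
#'
#' @param discovery_ids sample ids of the discovery panel.
#' @param detect_fun `function(vp, model) -> numeric` per-variant detection
#'   probability in `[0, 1]`; `NULL` for the carrier-presence default.
#' @param length_factor scalar multiplier applied to all probabilities.
#' @param source `"PEM_panel"` (multi-individual discovery) or
#'   `"assembly_single"` (single-genome discovery).
#' @return an `ascertainment_model` list.
#' @export
ascertainment_model <- function(discovery_ids, detect_fun = NULL,
                                length_factor = 1,
                                source = c("PEM_panel", "assembly_single")) {
  source <- match.arg(source)
  stopifnot(length_factor >= 0, length_factor <= 1)
  structure(list(discovery_ids = discovery_ids, detect_fun = detect_fun,
                 length_factor = length_factor, source = source),
            class = "ascertainment_model")
}

#' Carrier-presence detection probability
#'
#' Default detection model: a variant is detectable (probability 1) when at
#' least one discovery individual carries its non-reference allele, and
#' undetectable otherwise. Evaluated on the discovery-panel genotypes.
#'
#' @param vp a [variant_panel()].
#' @param model an [ascertainment_model()].
#' @return numeric vector of 0/1 detection probabilities.
#' @export
default_detect_prob <- function(vp, model) {
  rows <- vp$hap_sample %in% model$discovery_ids
  if (!any(rows)) stopf("no discovery individuals present in the variant panel")
  carrier <- colSums(vp$alleles[rows, , drop = FALSE], na.rm = TRUE) > 0
  as.numeric(carrier)
}

#' Simulate detection-probability-weighted SNP sampling
#'
#' Step 2 of the two-step ascertainment simulation: from a pool of
#' variants already polymorphic in the discovery panel (step 1, see
#' [simulate_discovery_panel()]), draws `n_sets` variants with probability
#' proportional to the per-variant detection probability.
#'
#' @param vp the step-1 [variant_panel()] pool.
#' @param model an [ascertainment_model()].
#' @param n_sets number of draws (default 10000).
#' @param seed integer seed.
#' @return data frame with one row per draw: `variant` (pool index),
#'   `pos`, `maf`, and a `detection_prob` attribute with the weights used.
#' @export
simulate_detection <- function(vp, model, n_sets = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_variants(vp) == 0) stopf("empty variant pool")
  detect_fun <- model$detect_fun %||% default_detect_prob
  w <- detect_fun(vp, model) * model$length_factor
  if (any(w < 0 | w > 1)) stopf("detection probabilities must be in [0, 1]")
  if (sum(w) == 0) stopf("no variant has positive detection probability")
  idx <- sample.int(n_variants(vp), n_sets, replace = TRUE, prob = w)
  out <- data.frame(variant = idx, pos = vp$pos[idx],
                    maf = minor_freq(vp)[idx])
  attr(out, "detection_prob") <- w
  out
}

#' Empirical test of an observed statistic against matched null samples
#'
#' Two-tailed p-value computed as twice the fraction of null values at
#' least as extreme as the observation (capped at 1); one-sided variants
#' use the single tail.
#'
#' @param observed observed statistic (e.g. mean inversion frequency).
#' @param null_values numeric vector of matched null statistics.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return an `empirical_test` list: `observed`, `p`, `n_null`,
#'   `alternative`, and the null sample.
#' @export
empirical_frequency_test <- function(observed, null_values,
                                     alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  null_values <- null_values[is.finite(null_values)]
  if (length(null_values) == 0) stopf("null sample is empty")
  up <- mean(null_values >= observed)
  lo <- mean(null_values <= observed)
  p <- switch(alternative,
              two.sided = min(1, 2 * min(up, lo)),
              greater = up, less = lo)
  structure(list(observed = observed, p = p, n_null = length(null_values),
                 alternative = alternative, null_values = null_values),
            class = "empirical_test")
}

#' @export
print.empirical_test <- function(x, ...) {
  note <- if (x$p == 0) sprintf(" (< %g)", 2 / x$n_null) else ""
  cat(sprintf("empirical test: observed %.4g, p = %.4g%s (%d null samples, %s)\n",
              x$observed, x$p, note, x$n_null, x$alternative))
  invisible(x)
}

#' Match null variants by frequency (and other strata)
#'
#' Returns the indices of candidate values within `bin` of the target
#' frequency, widening the bin (with a warning) until at least `n_min`
#' matches are found.
#'
#' @param freqs candidate frequencies.
#' @param target target frequency.
#' @param bin half-width of the matching bin (default 0.02).
#' @param n_min minimum number of matches required.
#' @return integer indices into `freqs`.
#' @export
match_by_frequency <- function(freqs, target, bin = 0.02, n_min = 100) {
  b <- bin
  repeat {
    idx <- which(abs(freqs - target) <= b)
    if (length(idx) >= n_min || b >= 0.5) break
    b <- b * 2
  }
  if (b > bin) warnf("frequency bin widened to %.3g to reach %d matches", b, n_min)
  idx
}

#' Robust stepwise regression of inversion frequency on genomic variables
#'
#' M-estimation (Tukey bisquare) with forward selection: at each step the
#' candidate predictor with the smallest robust-test p-value is added if
#' below `alpha`; selection stops when no candidate qualifies. Predictors
#' can be log-transformed; collinear candidates are skipped with a
#' warning. Variance explained is reported as a robust pseudo R-squared,
#' one minus the squared ratio of the residual M-scale to the M-scale of
#' the centred response.
#'
#' @param response numeric response (DAF or MAF per inversion).
#' @param predictors data frame of candidate predictors.
#' @param transform named character vector over predictors, values
#'   `"identity"` or `"log"`.
#' @param alpha entry threshold for the robust-test p-value.
#' @return list with `selected` (predictor names in entry order),
#'   `coefficients`, `pvalues` (robust t-test of each retained term),
#'   `r_squared` (robust pseudo R-squared) and the fitted `MASS::rlm`
#'   model (`NULL` when nothing was selected).
#' @export
robust_regression_stepwise <- function(response, predictors,
                                       transform = NULL, alpha = 0.05) {
  stopifnot(is.data.frame(predictors), length(response) == nrow(predictors))
  if (length(response) < 5 * 1) stopf("need >= 5 observations")
  X <- predictors
  for (v in names(X)) {
    tr <- transform[v] %||% "identity"
    if (!is.na(tr) && tr == "log") {
      if (any(X[[v]] <= 0, na.rm = TRUE))
        stopf("log transform requested for non-positive predictor %s", v)
      X[[v]] <- log(X[[v]])
    }
  }
  selected <- character(0)
  candidates <- names(X)
  dat <- data.frame(.y = response, X, check.names = FALSE)
  fit <- NULL
  repeat {
    best_p <- Inf; best_v <- NULL; best_fit <- NULL
    for (v in candidates) {
      form <- stats::reformulate(c(selected, sprintf("`%s`", v)), response = ".y")
      mm <- stats::model.matrix(form, dat)
      if (qr(mm)$rank < ncol(mm)) {
        warnf("predictor %s collinear with current model; skipped", v)
        next
      }
      f <- tryCatch(MASS::rlm(form, data = dat, psi = MASS::psi.bisquare,
                              maxit = 100), error = function(e) NULL)
      if (is.null(f)) next
      p <- rlm_term_p(f)[length(coef(f))]
      if (is.finite(p) && p < best_p) { best_p <- p; best_v <- v; best_fit <- f }
    }
    if (is.null(best_v) || best_p >= alpha) break
    selected <- c(selected, best_v)
    candidates <- setdiff(candidates, best_v)
    fit <- best_fit
    if (length(candidates) == 0) break
  }
  if (is.null(fit))
    return(list(selected = character(0), coefficients = numeric(0),
                pvalues = numeric(0), r_squared = 0, model = NULL))
  s_res <- fit$s
  null_fit <- MASS::rlm(.y ~ 1, data = dat, psi = MASS::psi.bisquare,
                        maxit = 100)
  r2 <- max(0, min(1, 1 - (s_res / null_fit$s)^2))
  list(selected = selected, coefficients = coef(fit),
       pvalues = rlm_term_p(fit), r_squared = r2, model = fit)
}

# robust Wald-type p-values for rlm coefficients
rlm_term_p <- function(fit) {
  sm <- summary(fit)$coefficients
  tval <- sm[, "t value"]
  df <- length(fit$residuals) - nrow(sm)
  2 * pt(-abs(tval), df = max(df, 1))
}
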