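#' Infer the ancestral orientation from outgroup observations
#'
#' Combines orientation calls in outgroup species (archaic hominins,
#' chimpanzee, gorilla, orangutan, macaque) into a consensus ancestral
#' state for the human lineage. Species polymorphic for the region are
#' uninformative about direction (a segregating inversion in an outgroup
#' indicates recurrence, not ancestry) and are excluded; among informative
#' species the majority state is taken, with ties (and the absence of any
#' informative species) returned as `unknown`. This is the
#' parsimony-motivated rule under which two agreeing deeper outgroups
#' outvote a single discordant closer one.
#'
#' @param obs data frame with columns `species` and `call`
#'   (`O1`, `O2`, `polymorphic`, `untested`); one row per
#'   species/individual/assembly observation.
#' @return `"O1"`, `"O2"` or `"unknown"`.
#' @examples
#' infer_ancestral(data.frame(species = c("chimpanzee", "gorilla"),
#'                            call = c("O1", "O1")))  # "O1"
#' @export
infer_ancestral <- function(obs) {
  stopifnot(all(c("species", "call") %in% names(obs)))
  ok <- obs$call %in% c("O1", "O2")
  if (!any(ok)) return("unknown")
  # one vote per species: a species with conflicting individuals is
  # effectively polymorphic, hence uninformative
  per_sp <- tapply(obs$call[ok], obs$species[ok], function(x)
    if (length(unique(x)) == 1) x[1] else NA_character_)
  per_sp <- per_sp[!is.na(per_sp)]
  if (length(per_sp) == 0) return("unknown")
  tab <- table(per_sp)
  if (length(tab) == 1) return(names(tab))
  if (tab["O1"] == tab["O2"]) return("unknown")
  names(which.max(tab))
}

#' Pairwise nucleotide diversity within and between orientations
#'
#' Mean pairwise Hamming differences per accessible site, computed within
#' each orientation class and between classes, over the inverted region
#' and any non-recombining flank supplied as `span` intervals. Indel and
#' breakpoint-interval exclusion is expected upstream (supply a SNP-only
#' haplotype set).
#'
#' @param haps an orientation-labelled [haplotype_set()].
#' @param span a `c(start, end)` interval or a list of such intervals;
#'   `NULL` uses all sites.
#' @param use_mask restrict to accessible sites.
#' @param site_total number of surveyed bases the per-site means are
#'   scaled by. Defaults to the physical width of `span` when given
#'   (variant columns are then taken to be the segregating subset of a
#'   fully surveyed interval) and to the number of columns otherwise
#'   (the matrix is then taken to hold every surveyed site).
#' @return list with `pi_between`, `pi_within_O1`, `pi_within_O2`
#'   (per-site means; `NA` when a class has fewer than 2 haplotypes) and
#'   `n_sites` (the denominator used).
#' @export
pairwise_diversity <- function(haps, span = NULL, use_mask = FALSE,
                               site_total = NULL) {
  keep <- rep(TRUE, ncol(haps$alleles))
  if (!is.null(span)) {
    if (!is.list(span)) span <- list(span)
    keep <- Reduce(`|`, lapply(span, function(s)
      haps$pos >= s[1] & haps$pos < s[2]))
  }
  if (use_mask) keep <- keep & haps$accessible
  H <- haps$alleles[, keep, drop = FALSE]
  n_sites <- site_total %||%
    (if (!is.null(span)) sum(vapply(span, function(s) s[2] - s[1], 0))
     else ncol(H))
  i1 <- which(haps$orientation == "O1")
  i2 <- which(haps$orientation == "O2")
  if (length(i1) == 0 || length(i2) == 0)
    stopf("both orientations must be represented")
  D <- hamming_distance(H)
  mean_pairs <- function(idx) {
    if (length(idx) < 2) return(NA_real_)
    mean(D[idx, idx][upper.tri(D[idx, idx])])
  }
  list(pi_between = mean(D[i1, i2, drop = FALSE]) / n_sites,
       pi_within_O1 = mean_pairs(i1) / n_sites,
       pi_within_O2 = mean_pairs(i2) / n_sites,
       n_sites = n_sites)
}

#' Divergence-based inversion age estimate
#'
#' The net divergence between orientation classes,
#' `pi_between - max(pi_within)`, accrues at `2 * rate` per site since the
#' origin of the derived arrangement (mutations accumulate on both the
#' inverted and the non-inverted lineage), and subtracting the larger
#' within-class diversity corrects for the diversity segregating in the
#' ancestral background at the time of origin. The age is therefore
#' `(pi_between - max(pi_within)) / (2 * rate)`, reported separately for
#' each substitution rate supplied. Non-positive net divergence yields a
#' non-positive age flagged `undetermined` (never silently clipped).
#'
#' @param div output of [pairwise_diversity()].
#' @param rates named numeric vector of substitution rates per site.
#' @param rate_unit `"per_year"` (ages in years) or `"per_generation"`
#'   (ages converted to years via `generation_time`).
#' @param generation_time years per generation (default 29).
#' @return data frame with one row per rate: `rate`, `age_years`,
#'   `age_generations`, `undetermined`.
#' @export
estimate_age <- function(div, rates, rate_unit = c("per_year", "per_generation"),
                         generation_time = 29) {
  rate_unit <- match.arg(rate_unit)
  stopifnot(all(rates > 0))
  wmax <- max(div$pi_within_O1, div$pi_within_O2, na.rm = TRUE)
  net <- div$pi_between - wmax
  age <- net / (2 * rates)
  if (rate_unit == "per_year") {
    years <- age; gens <- age / generation_time
  } else {
    gens <- age; years <- age * generation_time
  }
  data.frame(rate_name = names(rates) %||% paste0("rate", seq_along(rates)),
             rate = as.numeric(rates), age_years = as.numeric(years),
             age_generations = as.numeric(gens),
             undetermined = net <= 0, stringsAsFactors = FALSE)
}

#' Bootstrap confidence interval for the inversion age
#'
#' Resamples individuals (not haplotypes) with replacement, recomputes the
#' divergence-based age for every resample and returns percentile 95
#' percent intervals per substitution rate. Resamples in which one
#' orientation class disappears are skipped and counted.
#'
#' @param haps an orientation-labelled [haplotype_set()].
#' @param span interval(s) passed to [pairwise_diversity()].
#' @param rates named numeric vector of substitution rates per site.
#' @param n_boot number of bootstrap resamples (>= 100).
#' @param rate_unit,generation_time see [estimate_age()].
#' @param site_total surveyed-base denominator, see [pairwise_diversity()].
#' @param conf_level confidence level (default 0.95).
#' @param seed integer seed.
#' @return data frame with one row per rate: point estimate, `lower`,
#'   `upper` (years) and `n_skipped` degenerate resamples.
#' @export
bootstrap_age_ci <- function(haps, span = NULL, rates, n_boot = 1000,
                             rate_unit = "per_year", generation_time = 29,
                             conf_level = 0.95, site_total = NULL,
                             seed = NULL) {
  if (n_boot < 100) stopf("n_boot must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  samples <- unique(haps$sample_id)
  rows_of <- split(seq_len(nrow(haps$alleles)), haps$sample_id)
  div0 <- pairwise_diversity(haps, span, site_total = site_total)
  point <- estimate_age(div0, rates, rate_unit, generation_time)
  # the pairwise distance matrix is fixed; resampling only re-indexes it
  keep <- rep(TRUE, ncol(haps$alleles))
  if (!is.null(span)) {
    spl <- if (!is.list(span)) list(span) else span
    keep <- Reduce(`|`, lapply(spl, function(s)
      haps$pos >= s[1] & haps$pos < s[2]))
  }
  D <- hamming_distance(haps$alleles[, keep, drop = FALSE])
  n_sites <- div0$n_sites
  boot <- matrix(NA_real_, nrow = n_boot, ncol = length(rates))
  skipped <- 0L
  for (b in seq_len(n_boot)) {
    draw <- sample(samples, length(samples), replace = TRUE)
    idx <- unlist(rows_of[draw], use.names = FALSE)
    ori <- haps$orientation[idx]
    i1 <- idx[ori == "O1"]; i2 <- idx[ori == "O2"]
    if (length(i1) < 2 || length(i2) < 2) {
      skipped <- skipped + 1L
      next
    }
    # duplicated individuals contribute pairs like any bootstrap draw
    w1 <- mean(D[i1, i1][upper.tri(matrix(0, length(i1), length(i1)))]) / n_sites
    w2 <- mean(D[i2, i2][upper.tri(matrix(0, length(i2), length(i2)))]) / n_sites
    pb <- mean(D[i1, i2]) / n_sites
    div_b <- list(pi_between = pb, pi_within_O1 = w1, pi_within_O2 = w2,
                  n_sites = n_sites)
    boot[b, ] <- estimate_age(div_b, rates, rate_unit,
                              generation_time)$age_years
  }
  alpha <- (1 - conf_level) / 2
  data.frame(rate_name = point$rate_name, rate = point$rate,
             age_years = point$age_years,
             lower = apply(boot, 2, quantile, alpha, na.rm = TRUE),
             upper = apply(boot, 2, quantile, 1 - alpha, na.rm = TRUE),
             n_skipped = skipped, stringsAsFactors = FALSE)
}
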