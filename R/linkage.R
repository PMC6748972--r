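#' Linkage disequilibrium (r squared) between an inversion and a variant
#'
#' With phased 0/1 haplotype vectors the textbook haplotype measure
#' `r2 = D^2 / (pA pa pB pb)` is computed by direct gamete counting. With
#' genotype dosages the composite genotype-correlation-squared is used,
#' which is phase-free and reduces to the haplotype measure under
#' Hardy-Weinberg equilibrium. Missing observations are removed pairwise.
#'
#' @param x,y numeric vectors: 0/1 alleles per haplotype
#'   (`method = "haplotype"`) or allele dosages per sample
#'   (`method = "genotype"`).
#' @param method `"haplotype"` or `"genotype"`.
#' @return r squared in `[0, 1]`, with attribute `method`; `NA` when either
#'   vector is monomorphic or fewer than 2 complete observations remain.
#' @examples
#' ld_r2(c(1, 1, 0, 0), c(1, 1, 0, 0), method = "haplotype")  # 1
#' @export
ld_r2 <- function(x, y, method = c("haplotype", "genotype")) {
  method <- match.arg(method)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) return(structure(NA_real_, method = method))
  if (var(x) == 0 || var(y) == 0) return(structure(NA_real_, method = method))
  r2 <- if (method == "haplotype") {
    pA <- mean(x); pB <- mean(y)
    D <- mean(x * y) - pA * pB
    D^2 / (pA * (1 - pA) * pB * (1 - pB))
  } else {
    cor(x, y)^2
  }
  structure(min(1, r2), method = method)
}

#' Find inversion tag variants
#'
#' Computes r squared between the inversion O2 dosage and every variant
#' within a window around the inverted region, per stratum of samples
#' (all samples together, plus any population groupings supplied), and
#' returns variants above the tagging threshold ranked by r squared.
#' Perfect tags (`r2 = 1`) are flagged; these are the variants usable for
#' direct orientation imputation on phased haplotypes.
#'
#' @param gt a [genotype_table()].
#' @param vp a [variant_panel()] over the same samples.
#' @param inv a one-row inversion table ([inversion_record()]).
#' @param inversion_id inversion column of `gt` to use.
#' @param window flank width in bases scanned on each side of the region.
#' @param threshold minimum r squared for a tag (default 0.8).
#' @param strata optional named list of sample-id vectors; a stratum
#'   `"all"` with every shared sample is always included.
#' @return data frame with columns `stratum`, `pos`, `r2`, `perfect`,
#'   sorted by stratum and decreasing r squared.
#' @export
find_tag_variants <- function(gt, vp, inv, inversion_id = 1, window = 200000,
                              threshold = 0.8, strata = NULL) {
  stopifnot(window >= 0)
  span <- inversion_span(inv, "outer")
  keep <- vp$pos >= span[1] - window & vp$pos < span[2] + window
  out <- list()
  dos_inv <- o2_dosage(gt)[, inversion_id]
  dos_var <- variant_dosage(vp)
  common <- intersect(names(dos_inv), rownames(dos_var))
  strata <- c(list(all = common), strata)
  for (s in names(strata)) {
    ids <- intersect(strata[[s]], common)
    for (j in which(keep)) {
      r2 <- ld_r2(dos_inv[ids], dos_var[ids, j], method = "genotype")
      if (!is.na(r2) && r2 >= threshold - 1e-12)
        out[[length(out) + 1]] <- data.frame(
          stratum = s, pos = vp$pos[j], r2 = as.numeric(r2),
          perfect = r2 > 1 - 1e-9, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(stratum = character(0), pos = integer(0),
                      r2 = numeric(0), perfect = logical(0)))
  res <- do.call(rbind, out)
  res[order(res$stratum, -res$r2, res$pos), , drop = FALSE]
}

#' Drop variants inside breakpoint intervals
#'
#' Variants within either breakpoint interval (and hence within the
#' breakpoint IRs) are excluded before classification, since genotype
#' calls there are unreliable.
#'
#' @param vp a [variant_panel()].
#' @param inv a one-row inversion table.
#' @return the filtered [variant_panel()].
#' @export
exclude_breakpoint_variants <- function(vp, inv) {
  bad <- (vp$pos >= inv$bp1_start & vp$pos < inv$bp1_end) |
    (vp$pos >= inv$bp2_start & vp$pos < inv$bp2_end)
  subset_variants(vp, variants = !bad)
}

#' Classify variants by their distribution across inversion orientations
#'
#' Each variant is labelled `fixed` (perfectly associated with orientation,
#' `r2 = 1`), `shared` (unambiguously polymorphic on both orientations),
#' `private_O1` / `private_O2` (polymorphic on one orientation only) or
#' `unassigned`. Orientation assignment of alleles uses only inversion
#' homozygotes and hemizygotes, whose chromosomes carry a known
#' orientation, unless `haps` supplies phased haplotypes with orientation
#' labels, in which case all labelled haplotypes are used.
#'
#' @details Without phased haplotypes, an allele is credited to an
#' orientation only when the assignment is forced by the genotypes: all
#' alleles of inversion homozygotes/hemizygotes belong to their single
#' orientation, and a variant-homozygous call in an inversion heterozygote
#' places that allele on both orientations. Variant-heterozygous calls in
#' inversion heterozygotes are ambiguous and contribute no evidence.
#'
#' @param gt a [genotype_table()].
#' @param vp a [variant_panel()] over the same samples.
#' @param inversion_id inversion column of `gt` to classify against.
#' @param haps optional orientation-labelled [haplotype_set()] whose
#'   variant columns match `vp` positions.
#' @param use_mask restrict to variants with `accessible = TRUE`.
#' @return data frame with columns `pos`, `class`, `r2`, and evidence
#'   counts `n_O1_ref`, `n_O1_alt`, `n_O2_ref`, `n_O2_alt`.
#' @export
classify_variants <- function(gt, vp, inversion_id = 1, haps = NULL,
                              use_mask = FALSE) {
  if (use_mask) vp <- subset_variants(vp, variants = vp$accessible)
  dos_inv <- o2_dosage(gt)[, inversion_id]
  dos_var <- variant_dosage(vp)
  common <- intersect(names(dos_inv), rownames(dos_var))
  if (!is.null(haps)) {
    ori <- haps$orientation
    H <- haps$alleles
    pos <- haps$pos
    m <- ncol(H)
    i1 <- ori == "O1"; i2 <- ori == "O2"
    ev <- function(j) {
      a1 <- H[i1, j]; a2 <- H[i2, j]
      c(sum(a1 == 0L, na.rm = TRUE), sum(a1 == 1L, na.rm = TRUE),
        sum(a2 == 0L, na.rm = TRUE), sum(a2 == 1L, na.rm = TRUE))
    }
  } else {
    pos <- vp$pos
    m <- ncol(vp$alleles)
    g <- setNames(gt$geno[, inversion_id], rownames(gt$geno))[common]
    dv <- dos_var[common, , drop = FALSE]
    nh <- vapply(common, function(s) sum(vp$hap_sample == s), 0L)
    ev <- function(j) {
      n <- c(0L, 0L, 0L, 0L)  # O1_ref, O1_alt, O2_ref, O2_alt
      for (k in seq_along(common)) {
        gi <- g[k]; d <- dv[k, j]
        if (is.na(gi) || is.na(d)) next
        if (gi %in% c("O1/O1", "O1")) {           # all alleles on O1
          n[1] <- n[1] + (nh[k] - d); n[2] <- n[2] + d
        } else if (gi %in% c("O2/O2", "O2")) {
          n[3] <- n[3] + (nh[k] - d); n[4] <- n[4] + d
        } else if (gi == "O1/O2") {
          if (d == 0) { n[1] <- n[1] + 1L; n[3] <- n[3] + 1L }
          if (d == 2) { n[2] <- n[2] + 1L; n[4] <- n[4] + 1L }
          # d == 1 is ambiguous: no evidence
        }
      }
      n
    }
  }
  cls <- character(m); r2v <- numeric(m)
  nev <- matrix(0L, nrow = m, ncol = 4)
  for (j in seq_len(m)) {
    r2 <- ld_r2(dos_inv[common], dos_var[common, j], method = "genotype")
    r2v[j] <- as.numeric(r2)
    n <- ev(j)
    nev[j, ] <- n
    poly1 <- n[1] > 0 && n[2] > 0
    poly2 <- n[3] > 0 && n[4] > 0
    cls[j] <- if (!is.na(r2) && r2 > 1 - 1e-9) "fixed"
    else if (poly1 && poly2) "shared"
    else if (poly1 && (n[3] + n[4]) > 0) "private_O1"
    else if (poly2 && (n[1] + n[2]) > 0) "private_O2"
    else "unassigned"
  }
  data.frame(pos = pos, class = cls, r2 = r2v, n_O1_ref = nev[, 1],
             n_O1_alt = nev[, 2], n_O2_ref = nev[, 3], n_O2_alt = nev[, 4],
             stringsAsFactors = FALSE)
}

#' Windowed shared/fixed variant profile around an inversion
#'
#' Summarizes the output of [classify_variants()] as one record for the
#' whole inverted region plus sliding windows over both flanks: the
#' fraction of shared and fixed variants among the polymorphic variants of
#' each window, and the signed distance of the window centre to the
#' nearest breakpoint (negative inside the inversion).
#'
#' @param classes data frame from [classify_variants()].
#' @param inv a one-row inversion table.
#' @param window window width in bases (default 10 kb).
#' @param step step size in bases (default 5 kb).
#' @param flank_span flank width profiled on each side (bases).
#' @return data frame with columns `start`, `end`, `distance`,
#'   `n_polymorphic`, `shared_fraction`, `fixed_fraction` and a logical
#'   `inverted_region` marking the whole-region record.
#' @export
window_shared_profile <- function(classes, inv, window = 10000, step = 5000,
                                  flank_span = 20000) {
  if (flank_span <= 0) stopf("flank_span must be > 0")
  span <- inversion_span(inv, "inner")
  win <- list(c(span[1], span[2]))  # whole inverted region first
  left_edge <- inv$bp1_start
  s <- left_edge - window
  while (s + window > left_edge - flank_span) {
    win[[length(win) + 1]] <- c(max(left_edge - flank_span, s), min(left_edge, s + window))
    s <- s - step
    if (s + window <= left_edge - flank_span) break
  }
  s <- inv$bp2_end
  while (s < inv$bp2_end + flank_span) {
    win[[length(win) + 1]] <- c(s, min(inv$bp2_end + flank_span, s + window))
    s <- s + step
  }
  rows <- lapply(seq_along(win), function(i) {
    w <- win[[i]]
    centre <- mean(w)
    inside <- centre >= inv$bp1_end && centre < inv$bp2_start
    dist_bp <- min(abs(centre - inv$bp1_end), abs(centre - inv$bp2_start),
                   abs(centre - inv$bp1_start), abs(centre - inv$bp2_end))
    sel <- classes$pos >= w[1] & classes$pos < w[2]
    n <- sum(sel)
    data.frame(start = w[1], end = w[2],
               distance = if (inside) -dist_bp else dist_bp,
               n_polymorphic = n,
               shared_fraction = if (n > 0) mean(classes$class[sel] == "shared") else NA_real_,
               fixed_fraction = if (n > 0) mean(classes$class[sel] == "fixed") else NA_real_,
               inverted_region = i == 1)
  })
  do.call(rbind, rows)
}

#' Define non-recombining flanking regions of an inversion
#'
#' Scans outward from each breakpoint, up to `max_span`, and stops before
#' the first reliable shared variant compatible with a crossing-over
#' event. An isolated shared variant bracketed by fixed or private
#' variants within `bracket` bases on both sides is treated as
#' gene-conversion evidence rather than crossover evidence and the scan
#' continues past it. Optionally the flank is truncated at the outermost
#' fixed variant inside the stopping point.
#'
#' @param classes data frame from [classify_variants()].
#' @param inv a one-row inversion table.
#' @param max_span maximum flank extent in bases (default 20 kb).
#' @param bracket bracketing distance for the gene-conversion exemption.
#' @param fixed_rule `"stop"` (flank runs to the stopping point),
#'   `"outermost"` (truncate at the outermost fixed variant inside the
#'   stopping point) or `"fraction"` (shortest extent containing at least
#'   90 percent of the fixed variants inside the stopping point).
#' @param reliable optional predicate `function(classes) logical` marking
#'   which shared variants count as reliable crossover evidence; defaults
#'   to all shared variants.
#' @return data frame with one row per side (`left`, `right`): `start`,
#'   `end` (0-based half-open; empty interval when length 0) and
#'   `stopped_by` (position of the shared variant that stopped the scan,
#'   `NA` when the scan ran to `max_span`).
#' @export
nonrecombining_flank <- function(classes, inv, max_span = 20000,
                                 bracket = 1000,
                                 fixed_rule = c("stop", "outermost", "fraction"),
                                 reliable = NULL) {
  fixed_rule <- match.arg(fixed_rule)
  rel <- if (is.null(reliable)) rep(TRUE, nrow(classes)) else reliable(classes)
  anchored <- classes$class %in% c("fixed", "private_O1", "private_O2")
  scan_side <- function(from, dir) {
    lim <- from + dir * max_span
    sel <- if (dir > 0) classes$pos >= from & classes$pos < lim
           else classes$pos < from & classes$pos >= lim
    idx <- which(sel)
    idx <- idx[order(dir * classes$pos[idx])]  # outward order
    stop_pos <- NA_integer_
    for (i in idx) {
      if (classes$class[i] != "shared" || !rel[i]) next
      # gene-conversion exemption: isolated shared variant bracketed by
      # orientation-anchored variants within `bracket` on both sides
      near <- abs(classes$pos - classes$pos[i]) <= bracket &
        classes$pos != classes$pos[i]
      has_shared_near <- any(near & classes$class == "shared" & rel)
      br_in <- any(near & anchored &
                     (dir > 0) == (classes$pos < classes$pos[i]))
      br_out <- any(near & anchored &
                      (dir > 0) == (classes$pos > classes$pos[i]))
      if (!has_shared_near && br_in && br_out) next
      stop_pos <- classes$pos[i]
      break
    }
    end_pos <- if (is.na(stop_pos)) lim else stop_pos
    # optional truncation to the fixed variants inside the stopping point
    if (fixed_rule != "stop") {
      infl <- if (dir > 0) classes$pos >= from & classes$pos < end_pos
              else classes$pos < from & classes$pos > end_pos
      fx <- classes$pos[infl & classes$class == "fixed"]
      if (length(fx) > 0) {
        if (fixed_rule == "outermost") {
          end_pos <- if (dir > 0) max(fx) + 1L else min(fx)
        } else {
          fx <- fx[order(dir * fx)]
          k <- ceiling(0.9 * length(fx))
          end_pos <- if (dir > 0) fx[k] + 1L else fx[k]
        }
      } else end_pos <- from
    }
    c(min(from, end_pos), max(from, end_pos), stop_pos)
  }
  left <- scan_side(inv$bp1_start, -1)
  right <- scan_side(inv$bp2_end, +1)
  data.frame(side = c("left", "right"),
             start = c(left[1], right[1]), end = c(left[2], right[2]),
             stopped_by = c(left[3], right[3]))
}
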