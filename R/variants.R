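#' Biallelic variant panel
#'
#' Holds biallelic variants as an allele matrix with one row per haplotype
#' (two per diploid sample, one per hemizygote) and one column per variant.
#' Allele 0 is the reference allele, 1 the alternative. For unphased diploid
#' samples the two rows carry the alleles in arbitrary order and `phased`
#' is `FALSE` for that sample; analyses that need phase must restrict to
#' phased samples or to homozygotes.
#'
#' @param alleles integer matrix (haplotypes x variants) of 0/1/`NA`.
#' @param chrom chromosome name(s), length 1 or one per variant.
#' @param pos 0-based positions, strictly increasing within a chromosome.
#' @param ref,alt reference / alternative allele strings.
#' @param hap_sample sample id of each haplotype row.
#' @param phased named logical, one per sample.
#' @param accessible logical accessibility-mask flag per variant.
#' @param ancestral integer 0/1/`NA` per variant: which allele is ancestral.
#' @return a `variant_panel` object.
#' @export
variant_panel <- function(alleles, chrom, pos, ref = NULL, alt = NULL,
                          hap_sample, phased = NULL, accessible = NULL,
                          ancestral = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  m <- ncol(alleles)
  chrom <- rep_len(as.character(chrom), m)
  pos <- as.integer(pos)
  if (length(pos) != m) stopf("pos length != number of variant columns")
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (length(p) > 1 && any(diff(p) <= 0))
      stopf("positions must be strictly increasing within chromosome %s", ch)
  }
  if (any(!is.na(alleles) & !alleles %in% c(0L, 1L)))
    stopf("allele matrix must be 0/1/NA (biallelic only)")
  hap_sample <- as.character(hap_sample)
  if (length(hap_sample) != nrow(alleles))
    stopf("hap_sample length != number of haplotype rows")
  samples <- unique(hap_sample)
  if (is.null(phased)) phased <- setNames(rep(TRUE, length(samples)), samples)
  structure(list(
    alleles = alleles, chrom = chrom, pos = pos,
    ref = ref %||% rep("A", m), alt = alt %||% rep("T", m),
    hap_sample = hap_sample, phased = phased,
    accessible = accessible %||% rep(TRUE, m),
    ancestral = ancestral %||% rep(NA_integer_, m)),
    class = "variant_panel")
}

#' @export
print.variant_panel <- function(x, ...) {
  cat(sprintf("variant_panel: %d variants x %d haplotypes (%d samples)\n",
              ncol(x$alleles), nrow(x$alleles), length(unique(x$hap_sample))))
  invisible(x)
}

#' Number of variants / samples of a variant panel
#' @param vp a [variant_panel()].
#' @export
n_variants <- function(vp) ncol(vp$alleles)

#' Alternative-allele frequencies of a variant panel
#' @param vp a [variant_panel()].
#' @return numeric vector of alt-allele frequencies (pairwise-complete).
#' @export
alt_freq <- function(vp) colMeans(vp$alleles, na.rm = TRUE)

#' Minor-allele frequencies of a variant panel
#' @param vp a [variant_panel()].
#' @export
minor_freq <- function(vp) pmin(alt_freq(vp), 1 - alt_freq(vp))

#' Per-sample alternative-allele dosage matrix
#' @param vp a [variant_panel()].
#' @return samples x variants numeric matrix.
#' @export
variant_dosage <- function(vp) {
  samples <- unique(vp$hap_sample)
  out <- matrix(NA_real_, nrow = length(samples), ncol = ncol(vp$alleles),
                dimnames = list(samples, NULL))
  for (s in samples)
    out[s, ] <- colSums(vp$alleles[vp$hap_sample == s, , drop = FALSE])
  out
}

#' Subset a variant panel
#'
#' @param vp a [variant_panel()].
#' @param variants logical or integer index over variants (optional).
#' @param samples character vector of sample ids to keep (optional).
#' @return a [variant_panel()].
#' @export
subset_variants <- function(vp, variants = NULL, samples = NULL) {
  keep_v <- if (is.null(variants)) seq_len(ncol(vp$alleles)) else variants
  keep_h <- if (is.null(samples)) seq_len(nrow(vp$alleles)) else
    which(vp$hap_sample %in% samples)
  variant_panel(vp$alleles[keep_h, keep_v, drop = FALSE],
                vp$chrom[keep_v], vp$pos[keep_v], vp$ref[keep_v],
                vp$alt[keep_v], vp$hap_sample[keep_h],
                vp$phased[intersect(names(vp$phased), unique(vp$hap_sample[keep_h]))],
                vp$accessible[keep_v], vp$ancestral[keep_v])
}

#' Read biallelic variants from a VCF file
#'
#' Parses a VCF (plain or bgzipped) into a [variant_panel()]. Multiallelic
#' and symbolic-allele records are dropped (their count is reported in the
#' `dropped` attribute), VCF 1-based positions are converted to 0-based,
#' and phase flags (`|` vs `/`) are preserved per sample. Samples absent
#' from the panel are dropped with a warning.
#'
#' @param path VCF file path.
#' @param panel optional [population_panel()]; if given, VCF samples are
#'   restricted to panel samples and ploidy is taken from the panel.
#' @param region optional `list(chrom=, start=, end=)`, 0-based half-open.
#' @return a [variant_panel()] with attribute `dropped` (count of excluded
#'   multiallelic/symbolic records).
#' @export
read_variants <- function(path, panel = NULL, region = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0) stopf("VCF contains no records: %s", path)
  alt <- fix[, "ALT"]
  biallelic <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    !grepl("[][<>]", alt)
  dropped <- sum(!biallelic)
  gtm <- vcfR::extract.gt(v, element = "GT")
  keep <- which(biallelic)
  chrom <- fix[keep, "CHROM"]
  pos <- as.integer(fix[keep, "POS"]) - 1L   # to 0-based
  if (!is.null(region)) {
    inr <- chrom == region$chrom & pos >= region$start & pos < region$end
    keep <- keep[inr]; chrom <- chrom[inr]; pos <- pos[inr]
  }
  gtm <- gtm[keep, , drop = FALSE]
  vcf_samples <- colnames(gtm)
  if (!is.null(panel)) {
    extra <- setdiff(vcf_samples, panel$sample_id)
    if (length(extra) > 0) {
      warnf("%d VCF sample(s) not in panel dropped", length(extra))
      gtm <- gtm[, setdiff(vcf_samples, extra), drop = FALSE]
      vcf_samples <- colnames(gtm)
    }
  }
  if (ncol(gtm) == 0) stopf("no samples left after panel restriction")
  # split genotype strings into per-haplotype alleles
  alleles <- list(); hap_sample <- character(); phased <- logical()
  for (s in vcf_samples) {
    g <- gtm[, s]
    ph <- all(grepl("|", g[!is.na(g)], fixed = TRUE)) && any(!is.na(g))
    parts <- strsplit(ifelse(is.na(g), ".", g), "[/|]")
    pl <- max(lengths(parts))
    for (k in seq_len(pl)) {
      a <- vapply(parts, function(p) if (length(p) >= k) p[k] else ".", "")
      ai <- suppressWarnings(as.integer(a))
      alleles[[length(alleles) + 1]] <- ai
      hap_sample <- c(hap_sample, s)
    }
    phased[s] <- ph
  }
  amat <- do.call(rbind, alleles)
  vp <- variant_panel(amat, chrom, pos, fix[keep, "REF"], fix[keep, "ALT"],
                      hap_sample, phased)
  attr(vp, "dropped") <- dropped
  vp
}

#' Write a variant panel as VCF
#'
#' Writes phased (`|`) or unphased (`/`) diploid genotypes, or haploid
#' genotypes for single-haplotype samples, as a bgzipped VCF.
#'
#' @param vp a [variant_panel()].
#' @param path output path (a `.gz` suffix is appended by the writer if
#'   absent).
#' @return the path actually written, invisibly.
#' @export
write_variants <- function(vp, path) {
  samples <- unique(vp$hap_sample)
  m <- ncol(vp$alleles)
  gt <- matrix(NA_character_, nrow = m, ncol = length(samples),
               dimnames = list(NULL, samples))
  for (s in samples) {
    rows <- which(vp$hap_sample == s)
    sep <- if (isTRUE(vp$phased[s])) "|" else "/"
    sub <- vp$alleles[rows, , drop = FALSE]
    sub_chr <- matrix(as.character(sub), nrow = length(rows))
    sub_chr[is.na(sub_chr)] <- "."
    gt[, s] <- apply(sub_chr, 2, paste, collapse = sep)
  }
  fix <- cbind(CHROM = vp$chrom, POS = as.character(vp$pos + 1L),
               ID = rep(".", m), REF = vp$ref, ALT = vp$alt,
               QUAL = rep(".", m), FILTER = rep("PASS", m),
               INFO = rep(".", m))
  meta <- c("##fileformat=VCFv4.2",
            paste0("##contig=<ID=", unique(vp$chrom), ">"),
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  out <- methods::new(methods::getClass("vcfR", where = asNamespace("vcfR")),
                      meta = meta, fix = fix,
                      gt = cbind(FORMAT = rep("GT", m), gt))
  vcfR::write.vcf(out, file = if (grepl("\\.gz$", path)) path else paste0(path, ".gz"))
  invisible(if (grepl("\\.gz$", path)) path else paste0(path, ".gz"))
}

#' Phased haplotype set
#'
#' A matrix of 0/1 alleles with one row per haplotype, each haplotype
#' annotated with its sample, population and inversion orientation
#' (`O1`/`O2`/`unknown`). Orientation labels are set either by perfect-tag
#' assignment or by restriction to inversion homozygotes/hemizygotes
#' (see [assign_orientation()]).
#'
#' @param alleles haplotypes x variants 0/1 matrix.
#' @param pos 0-based variant positions.
#' @param orientation per-haplotype orientation label.
#' @param sample_id per-haplotype sample id.
#' @param population optional per-haplotype population label.
#' @param accessible optional logical mask per variant.
#' @param ancestral optional 0/1 ancestral allele per variant.
#' @return a `haplotype_set` object.
#' @export
haplotype_set <- function(alleles, pos, orientation = NULL, sample_id = NULL,
                          population = NULL, accessible = NULL,
                          ancestral = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  n <- nrow(alleles)
  orientation <- orientation %||% rep("unknown", n)
  if (!all(orientation %in% c("O1", "O2", "unknown")))
    stopf("orientation labels must be O1/O2/unknown")
  structure(list(
    alleles = alleles, pos = as.integer(pos),
    orientation = as.character(orientation),
    sample_id = as.character(sample_id %||% paste0("hap", seq_len(n))),
    population = as.character(population %||% rep("POP", n)),
    accessible = accessible %||% rep(TRUE, ncol(alleles)),
    ancestral = ancestral %||% rep(NA_integer_, ncol(alleles))),
    class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("haplotype_set: %d haplotypes x %d variants (O1: %d, O2: %d, unknown: %d)\n",
              nrow(x$alleles), ncol(x$alleles), sum(x$orientation == "O1"),
              sum(x$orientation == "O2"), sum(x$orientation == "unknown")))
  invisible(x)
}

#' Restrict a haplotype set to a genomic span and/or accessible sites
#'
#' @param haps a [haplotype_set()].
#' @param span `c(start, end)` 0-based half-open, or `NULL` for all sites.
#' @param use_mask drop sites with `accessible == FALSE`.
#' @return a [haplotype_set()].
#' @export
subset_haplotypes <- function(haps, span = NULL, use_mask = FALSE) {
  keep <- rep(TRUE, ncol(haps$alleles))
  if (!is.null(span)) keep <- keep & haps$pos >= span[1] & haps$pos < span[2]
  if (use_mask) keep <- keep & haps$accessible
  haplotype_set(haps$alleles[, keep, drop = FALSE], haps$pos[keep],
                haps$orientation, haps$sample_id, haps$population,
                haps$accessible[keep], haps$ancestral[keep])
}
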