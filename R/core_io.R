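#' Population panel
#'
#' A population panel describes the samples of a genotyping study: sex,
#' population (e.g. YRI), continental group and family structure. It is the
#' reference against which genotype tables and variant panels are validated,
#' and drives ploidy rules (chrX male hemizygosity, chrY) throughout the
#' package.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param sex one of `"male"`, `"female"`, `"unknown"` per sample.
#' @param population population label per sample (e.g. `"YRI"`).
#' @param group continental group per sample: `"AFR"`, `"EUR"`, `"SAS"`,
#'   `"EAS"` or `"other"`.
#' @param family_role `"unrelated"`, `"father"`, `"mother"` or `"child"`.
#' @param family_id optional family identifier (required for trio members).
#' @return A `population_panel` data frame. Children whose parents are not
#'   both present in the panel are flagged in the `incomplete_trio` column.
#' @examples
#' population_panel(c("a", "b"), c("male", "female"), "YRI", "AFR")
#' @export
population_panel <- function(sample_id, sex = "unknown", population = "POP",
                             group = "other", family_role = "unrelated",
                             family_id = NA_character_) {
  n <- length(sample_id)
  df <- data.frame(
    sample_id = as.character(sample_id),
    sex = rep_len(as.character(sex), n),
    population = rep_len(as.character(population), n),
    group = rep_len(as.character(group), n),
    family_role = rep_len(as.character(family_role), n),
    family_id = rep_len(as.character(family_id), n),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$sample_id))
    stopf("duplicated sample ids in panel: %s",
          paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  bad <- !df$sex %in% c("male", "female", "unknown")
  if (any(bad)) stopf("invalid sex values: %s", paste(unique(df$sex[bad]), collapse = ", "))
  bad <- !df$group %in% c("AFR", "EUR", "SAS", "EAS", "other")
  if (any(bad)) stopf("invalid group values: %s", paste(unique(df$group[bad]), collapse = ", "))
  bad <- !df$family_role %in% c("unrelated", "father", "mother", "child")
  if (any(bad)) stopf("invalid family roles: %s", paste(unique(df$family_role[bad]), collapse = ", "))
  # children need both parents in the same family, otherwise flagged
  df$incomplete_trio <- FALSE
  kids <- which(df$family_role == "child")
  for (i in kids) {
    fam <- df$family_id[i]
    ok <- !is.na(fam) &&
      any(df$family_role == "father" & df$family_id == fam, na.rm = TRUE) &&
      any(df$family_role == "mother" & df$family_id == fam, na.rm = TRUE)
    df$incomplete_trio[i] <- !ok
  }
  class(df) <- c("population_panel", "data.frame")
  df
}

#' Read / write a population panel file
#'
#' Tab-delimited with a header line; columns `sample_id`, `sex`,
#' `population`, `group`, `family_role`, `family_id` (the last two optional).
#'
#' @param path file path.
#' @return `read_population_panel()` returns a [population_panel()];
#'   `write_population_panel()` returns `path` invisibly.
#' @export
read_population_panel <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = c("NA", "", "."))
  population_panel(df$sample_id, df$sex %||% "unknown",
                   df$population %||% "POP", df$group %||% "other",
                   df$family_role %||% "unrelated",
                   df$family_id %||% NA_character_)
}

#' @rdname read_population_panel
#' @param panel a [population_panel()].
#' @export
write_population_panel <- function(panel, path) {
  write.table(panel[, c("sample_id", "sex", "population", "group",
                        "family_role", "family_id")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Inversion records
#'
#' An inversion is described by its two breakpoint intervals (0-based
#' half-open), the generating mechanism (`NH` for non-homologous, `NAHR` for
#' inverted-repeat mediated), the length of the breakpoint inverted repeats,
#' and the known ancestral orientation if any. The inverted span can be
#' taken as the inner interval between breakpoints (default) or the outer
#' interval including the breakpoint repeats; both conventions are exposed
#' because breakpoint intervals are often only localized to a region.
#'
#' @param inversion_id inversion identifier.
#' @param chromosome chromosome name.
#' @param bp1_start,bp1_end,bp2_start,bp2_end breakpoint intervals, 0-based
#'   half-open, with `bp1_end <= bp2_start`.
#' @param mechanism `"NH"` or `"NAHR"`.
#' @param ir_length inverted-repeat length in bases (0 for NH inversions).
#' @param genetic_length optional genetic length in 4Ner units.
#' @param ancestral ancestral orientation: `"O1"`, `"O2"` or `"unknown"`.
#' @return a one-row `inversion_table` data frame; rows can be combined
#'   with `rbind`.
#' @export
inversion_record <- function(inversion_id, chromosome, bp1_start, bp1_end,
                             bp2_start, bp2_end, mechanism = c("NH", "NAHR"),
                             ir_length = 0, genetic_length = NA_real_,
                             ancestral = c("unknown", "O1", "O2")) {
  mechanism <- match.arg(mechanism)
  ancestral <- match.arg(ancestral)
  if (bp1_start > bp1_end || bp2_start > bp2_end)
    stopf("breakpoint intervals must have start <= end")
  if (bp1_end > bp2_start)
    stopf("bp1_end must be <= bp2_start (%s)", inversion_id)
  if (ir_length < 0) stopf("ir_length must be >= 0")
  df <- data.frame(inversion_id = inversion_id, chromosome = chromosome,
                   bp1_start = bp1_start, bp1_end = bp1_end,
                   bp2_start = bp2_start, bp2_end = bp2_end,
                   mechanism = mechanism, ir_length = ir_length,
                   inverted_length = bp2_start - bp1_end,
                   genetic_length = genetic_length, ancestral = ancestral,
                   stringsAsFactors = FALSE)
  class(df) <- c("inversion_table", "data.frame")
  df
}

#' Inverted span of an inversion record
#'
#' @param inv a one-row inversion table.
#' @param convention `"inner"` (between breakpoint intervals, excludes the
#'   IRs) or `"outer"` (includes the breakpoint intervals).
#' @return `c(start, end)`, 0-based half-open.
#' @export
inversion_span <- function(inv, convention = c("inner", "outer")) {
  convention <- match.arg(convention)
  if (convention == "inner") c(inv$bp1_end, inv$bp2_start)
  else c(inv$bp1_start, inv$bp2_end)
}

valid_genotype_tokens <- c("O1/O1", "O1/O2", "O2/O2", "O1", "O2")

normalize_genotype_token <- function(x) {
  x <- trimws(x)
  x[x %in% c("O2/O1")] <- "O1/O2"
  x[x %in% c("", ".", "./.", "NA", "missing")] <- NA_character_
  x
}

#' Inversion genotype table
#'
#' Orientation genotypes of samples at a set of inversions. The two
#' orientations of each inversion are called `O1` (reference orientation)
#' and `O2`; diploid calls are `"O1/O1"`, `"O1/O2"`, `"O2/O2"`, hemizygous
#' calls (chrY, chrX males) are `"O1"` or `"O2"`, and missing data `NA`.
#'
#' @param geno character matrix, samples in rows (rownames = sample ids),
#'   inversions in columns (colnames = inversion ids).
#' @param panel a [population_panel()] covering all samples.
#' @param chromosome named character vector mapping inversion ids to
#'   chromosome names (used for ploidy validation); defaults to autosomes.
#' @return a `genotype_table` object.
#' @export
genotype_table <- function(geno, panel, chromosome = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "character"
  if (is.null(rownames(geno)) || is.null(colnames(geno)))
    stopf("genotype matrix needs sample rownames and inversion colnames")
  missing_samples <- setdiff(rownames(geno), panel$sample_id)
  if (length(missing_samples) > 0)
    stopf("samples absent from panel: %s", paste(missing_samples, collapse = ", "))
  geno[] <- normalize_genotype_token(geno)
  unknown <- !is.na(geno) & !geno %in% valid_genotype_tokens
  if (any(unknown)) {
    warnf("%d unrecognized genotype token(s) set to missing", sum(unknown))
    geno[unknown] <- NA_character_
  }
  if (is.null(chromosome))
    chromosome <- setNames(rep("autosome", ncol(geno)), colnames(geno))
  chromosome <- chromosome[colnames(geno)]
  sex <- setNames(panel$sex, panel$sample_id)[rownames(geno)]
  for (j in seq_len(ncol(geno))) {
    pl <- expected_ploidy(chromosome[j], sex)
    g <- geno[, j]
    ndip <- !is.na(g) & g %in% c("O1/O1", "O1/O2", "O2/O2")
    nhap <- !is.na(g) & g %in% c("O1", "O2")
    if (any(ndip & pl == 1))
      stopf("diploid call for hemizygous sample(s) at %s: %s", colnames(geno)[j],
            paste(head(rownames(geno)[ndip & pl == 1], 3), collapse = ", "))
    if (any((ndip | nhap) & pl == 0))
      stopf("call present for sample(s) lacking %s", colnames(geno)[j])
    if (any(nhap & pl == 2))
      stopf("hemizygous call for diploid sample(s) at %s", colnames(geno)[j])
  }
  structure(list(geno = geno, chromosome = chromosome, panel = panel),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d samples x %d inversions (%.1f%% missing)\n",
              nrow(x$geno), ncol(x$geno), 100 * mean(is.na(x$geno))))
  invisible(x)
}

#' O2-allele dosage of a genotype table
#'
#' @param gt a [genotype_table()].
#' @return numeric matrix of O2-allele counts (0/1/2 for diploid, 0/1 for
#'   hemizygous calls, `NA` for missing).
#' @export
o2_dosage <- function(gt) {
  map <- c("O1/O1" = 0, "O1/O2" = 1, "O2/O2" = 2, "O1" = 0, "O2" = 1)
  d <- matrix(map[gt$geno], nrow = nrow(gt$geno),
              dimnames = dimnames(gt$geno))
  d
}

#' Read / write an inversion genotype table
#'
#' Tab-delimited; header row of inversion ids, first column the sample id,
#' one row per sample.
#'
#' @param path file path.
#' @param panel a [population_panel()].
#' @param chromosome optional named chromosome map, see [genotype_table()].
#' @return a [genotype_table()].
#' @export
read_genotype_table <- function(path, panel, chromosome = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE, na.strings = c("NA", "", "."))
  geno <- as.matrix(df[, -1, drop = FALSE])
  rownames(geno) <- df[[1]]
  genotype_table(geno, panel, chromosome)
}

#' @rdname read_genotype_table
#' @param gt a [genotype_table()].
#' @export
write_genotype_table <- function(gt, path) {
  df <- data.frame(sample_id = rownames(gt$geno), gt$geno,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Mendelian-consistency check of inversion genotypes in trios
#'
#' For every complete father-mother-child trio in the panel and every
#' inversion, checks whether the child genotype is compatible with at least
#' one legal transmission of parental alleles, honouring chrX/chrY ploidy
#' (sons receive the X allele from the mother only; daughters one X allele
#' from each parent; chrY passes father to son). Missing genotypes make a
#' trio untestable for that inversion rather than raising an error.
#'
#' @param gt a [genotype_table()].
#' @param panel a [population_panel()] with family annotations.
#' @return data frame with one row per trio x inversion and a `status`
#'   column in `consistent`, `violation`, `untestable`.
#' @export
mendelian_check <- function(gt, panel = gt$panel) {
  fams <- unique(na.omit(panel$family_id[panel$family_role == "child"]))
  trios <- list()
  for (fam in fams) {
    f <- panel$sample_id[panel$family_role == "father" & panel$family_id %in% fam]
    m <- panel$sample_id[panel$family_role == "mother" & panel$family_id %in% fam]
    kids <- panel$sample_id[panel$family_role == "child" & panel$family_id %in% fam]
    if (length(f) == 1 && length(m) == 1)
      for (k in kids) trios[[length(trios) + 1]] <- c(fam, f, m, k)
  }
  if (length(trios) == 0) stopf("panel contains no complete trio")
  sex <- setNames(panel$sex, panel$sample_id)
  out <- list()
  for (tr in trios) {
    fam <- tr[1]; f <- tr[2]; m <- tr[3]; k <- tr[4]
    for (inv in colnames(gt$geno)) {
      g <- gt$geno[c(f, m, k), inv]
      type <- chrom_type(gt$chromosome[inv])
      # only the transmitting parents are required: chrY needs no mother,
      # a son's chrX needs no father
      need <- c(father = !(type == "Y" && sex[k] != "male") &&
                  !(type == "X" && sex[k] == "male"),
                mother = type != "Y")
      if (type == "Y" && sex[k] != "male") {
        next  # daughters carry no chrY locus; nothing to test
      }
      status <- if (is.na(g[3]) || (need["father"] && is.na(g[1])) ||
                    (need["mother"] && is.na(g[2]))) "untestable" else {
        ok <- transmission_consistent(g[1], g[2], g[3], type, sex[k])
        if (ok) "consistent" else "violation"
      }
      out[[length(out) + 1]] <- data.frame(
        family_id = fam, father = f, mother = m, child = k,
        inversion_id = inv, status = status, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

geno_alleles <- function(g) strsplit(g, "/", fixed = TRUE)[[1]]

# enumerate all legal gamete combinations for one trio genotype configuration
transmission_consistent <- function(father, mother, child, type, child_sex) {
  fa <- geno_alleles(father); mo <- geno_alleles(mother); ch <- geno_alleles(child)
  if (type == "Y") {
    if (child_sex != "male") return(TRUE)        # daughters carry no Y locus
    return(length(ch) == 1 && ch %in% fa)
  }
  if (type == "X") {
    if (child_sex == "male")                     # sons: maternal X only
      return(length(ch) == 1 && any(vapply(mo, function(a) a == ch, TRUE)))
    # daughters: one paternal (his single X) + one maternal allele
    for (ma in mo) {
      if (setequal_multiset(ch, c(fa[1], ma))) return(TRUE)
    }
    return(FALSE)
  }
  for (pa in fa) for (ma in mo)
    if (setequal_multiset(ch, c(pa, ma))) return(TRUE)
  FALSE
}

setequal_multiset <- function(a, b) identical(sort(a), sort(b))
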