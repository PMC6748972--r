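#' @keywords internal
"_PACKAGE"

#' @importFrom stats as.dendrogram as.dist chisq.test coef cor cutree dist
#'   hclust ks.test lm median na.omit p.adjust pchisq pnorm poisson.test
#'   prcomp pt qnorm quantile rbinom reorder rexp rnorm rpois runif sd
#'   setNames var
#' @importFrom utils head read.table write.table combn
#' @importFrom methods new getClass
NULL

# chromosome classification used for ploidy rules
chrom_type <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom))
  ifelse(x %in% c("Y", "y"), "Y", ifelse(x %in% c("X", "x"), "X", "autosome"))
}

# expected ploidy of a sample for a chromosome; 0 = locus absent (female chrY)
expected_ploidy <- function(chrom, sex) {
  type <- chrom_type(chrom)
  if (type == "autosome") return(rep(2L, length(sex)))
  if (type == "X") return(ifelse(sex == "male", 1L, 2L))
  ifelse(sex == "male", 1L, 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# empirical p-value with the (r+1)/(n+1) convention used for bank-based tests
empirical_p <- function(obs, null, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  null <- null[is.finite(null)]
  r <- if (tail == "upper") sum(null >= obs) else sum(null <= obs)
  (r + 1) / (length(null) + 1)
}
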