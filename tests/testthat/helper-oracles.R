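# Independent brute-force oracles used across test files. These are kept
# deliberately naive (full enumeration, direct formula evaluation) and
# separate from the package implementations they check.

# --- Mendelian transmission oracle: enumerate every gamete combination ----
oracle_mendel <- function(father, mother, child, type = "autosome",
                          child_sex = "female") {
  split_g <- function(g) strsplit(g, "/", fixed = TRUE)[[1]]
  fa <- split_g(father); mo <- split_g(mother); ch <- split_g(child)
  cand <- list()
  if (type == "Y") {
    if (child_sex != "male") return(TRUE)
    cand <- lapply(fa, function(a) a)
  } else if (type == "X" && child_sex == "male") {
    cand <- lapply(mo, function(a) a)
  } else if (type == "X") {
    for (m in mo) cand[[length(cand) + 1]] <- c(fa[1], m)
  } else {
    for (f in fa) for (m in mo) cand[[length(cand) + 1]] <- c(f, m)
  }
  any(vapply(cand, function(g) identical(sort(g), sort(ch)), TRUE))
}

# --- exhaustive Fitch oracle: minimum over all internal labelings --------
oracle_parsimony <- function(tree, tip_states, root_state = NULL) {
  n <- length(tree$tip.label)
  n_int <- tree$Nnode
  states <- c("O1", "O2")
  tipv <- unname(tip_states[tree$tip.label])
  best <- Inf
  for (mask in 0:(2^n_int - 1)) {
    lab <- states[1 + bitwAnd(bitwShiftR(mask, 0:(n_int - 1)), 1L)]
    if (!is.null(root_state) && lab[1] != root_state) next
    node_state <- c(tipv, lab)
    changes <- sum(node_state[tree$edge[, 1]] != node_state[tree$edge[, 2]])
    best <- min(best, changes)
  }
  best
}

# --- exact HWE enumeration oracle (direct multinomial probabilities) -----
oracle_hwe <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  nA <- 2 * n_hom1 + n_het
  na <- 2 * n_hom2 + n_het
  if (nA == 0 || na == 0) return(1)
  nmin <- min(nA, na)
  hets <- seq(nmin %% 2, nmin, by = 2)
  pr <- sapply(hets, function(h) {
    h1 <- (nA - h) / 2; h2 <- (na - h) / 2
    if (h1 < 0 || h2 < 0 || round(h1) != h1) return(0)
    exp(lfactorial(n) - lfactorial(h1) - lfactorial(h) - lfactorial(h2) +
          h * log(2) + lfactorial(nA) + lfactorial(na) - lfactorial(2 * n))
  })
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[match(n_het, hets)] * (1 + 1e-12)])
}

# --- Weir & Cockerham variance components, direct transcription ----------
oracle_wc_fst <- function(p, n, h) {
  r <- length(p)
  nbar <- sum(n) / r
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}

# --- direct BH step-up procedure -----------------------------------------
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

# --- enumeration oracle for variant classification -----------------------
# enumerates every allele-to-orientation assignment consistent with the
# genotypes; labels follow the unambiguous-evidence convention
oracle_classify <- function(inv_geno, var_dosage, nh = 2) {
  n <- length(inv_geno)
  per_sample <- lapply(seq_len(n), function(i) {
    g <- inv_geno[i]; d <- var_dosage[i]
    if (is.na(g) || is.na(d)) return(list())
    ors <- if (g == "O1/O2") c("O1", "O2") else
      rep(sub("/.*", "", g), if (grepl("/", g)) 2 else 1)
    k <- length(ors)
    alleles_sets <- if (d == 0) list(rep(0L, k))
    else if (d == k) list(rep(1L, k))
    else unique(combinat_perms(c(rep(1L, d), rep(0L, k - d))))
    lapply(alleles_sets, function(a) data.frame(ori = ors, allele = a))
  })
  per_sample <- per_sample[lengths(per_sample) > 0]
  if (length(per_sample) == 0) return("unassigned")
  combos <- Reduce(function(acc, opts) {
    out <- list()
    for (a in acc) for (o in opts) out[[length(out) + 1]] <- rbind(a, o)
    out
  }, per_sample[-1], init = per_sample[[1]])
  seen <- lapply(combos, function(d) {
    c(o1r = any(d$ori == "O1" & d$allele == 0),
      o1a = any(d$ori == "O1" & d$allele == 1),
      o2r = any(d$ori == "O2" & d$allele == 0),
      o2a = any(d$ori == "O2" & d$allele == 1))
  })
  always <- Reduce(`&`, seen)
  poly1 <- always["o1r"] && always["o1a"]
  poly2 <- always["o2r"] && always["o2a"]
  dos_inv <- c("O1/O1" = 0, "O1/O2" = 1, "O2/O2" = 2, "O1" = 0, "O2" = 1)[inv_geno]
  ok <- !is.na(dos_inv) & !is.na(var_dosage)
  r2 <- if (sum(ok) > 1 && var(dos_inv[ok]) > 0 && var(var_dosage[ok]) > 0)
    cor(dos_inv[ok], var_dosage[ok])^2 else NA
  if (!is.na(r2) && r2 > 1 - 1e-9) "fixed"
  else if (poly1 && poly2) "shared"
  else if (poly1 && (always["o2r"] || always["o2a"])) "private_O1"
  else if (poly2 && (always["o1r"] || always["o1a"])) "private_O2"
  else "unassigned"
}

combinat_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    rest <- combinat_perms(x[-i])
    for (r in rest) out[[length(out) + 1]] <- c(x[i], r)
  }
  unique(out)
}

# --- shared fixtures ------------------------------------------------------
toy_panel <- function(n, sex = "unknown", population = "POP", group = "other") {
  population_panel(sprintf("S%03d", seq_len(n)), sex = sex,
                   population = population, group = group)
}

toy_inversion <- function(bp1 = c(10000, 10000), bp2 = c(40000, 40000),
                          chromosome = "chr1", ...) {
  inversion_record("INV1", chromosome, bp1[1], bp1[2], bp2[1], bp2[2], ...)
}
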