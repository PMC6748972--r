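#' Simulation configuration
#'
#' Bundles the parameters of the synthetic haplotype generator. The
#' generator emulates a panel of phased haplotypes carrying a polymorphic
#' inversion: within the inversion span, crossing-over between opposite
#' orientation classes is fully suppressed (the zero-exchange limit implied
#' by unbalanced gametes in heterokaryotypes), and the inverted allele
#' traces back either to a single origin event of a requested age
#' (`origin = "unique"`) or to `k` independent origin events on distinct
#' haplotype backgrounds (`origin = "recurrent"`).
#'
#' @param n_samples named integer vector of diploid sample counts per
#'   population (a single unnamed count is treated as one population).
#' @param ploidy haplotypes per sample (2 = diploid, 1 = hemizygous panel).
#' @param seq_length sequence length in bases.
#' @param mu neutral mutation rate per site per generation.
#' @param rho crossover rate per site per generation (applies to flanking
#'   sequence only; exchange between orientation classes inside the
#'   inversion span is suppressed by construction).
#' @param Ne effective population size (per orientation class background).
#' @param inversion_span `c(start, end)` of the inverted segment, 0-based
#'   half-open, within `[0, seq_length)`.
#' @param inv_frequency target frequency of the inverted (O2) allele.
#' @param origin `"unique"` or `"recurrent"`.
#' @param age origin age in generations (unique-origin mode).
#' @param k_events number of independent origin events (recurrent mode).
#' @param gene_conversion expected number of gene-conversion tracts copied
#'   between opposite-orientation haplotypes inside the inversion span
#'   (total over the panel); default 0.
#' @param gc_tract gene-conversion tract length in bases.
#' @param freq_tol tolerance on the realized O2 frequency (recurrent mode).
#' @param chromosome chromosome name given to emitted variants.
#' @param seed integer seed; every stochastic step is governed by it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_samples = c(POP = 50), ploidy = 2, seq_length = 50000,
                       mu = 1e-6, rho = 0, Ne = 1000,
                       inversion_span = c(10000, 40000), inv_frequency = 0.3,
                       origin = c("unique", "recurrent"), age = 4000,
                       k_events = 2, gene_conversion = 0, gc_tract = 200,
                       freq_tol = 0.1, chromosome = "chr1", seed = NULL) {
  origin <- match.arg(origin)
  if (is.null(names(n_samples))) names(n_samples) <- paste0("POP", seq_along(n_samples))
  stopifnot(mu >= 0, rho >= 0, Ne > 0, gene_conversion >= 0,
            inv_frequency > 0, inv_frequency < 1, k_events >= 1,
            inversion_span[1] >= 0, inversion_span[2] <= seq_length,
            inversion_span[1] < inversion_span[2])
  structure(list(n_samples = n_samples, ploidy = ploidy,
                 seq_length = seq_length, mu = mu, rho = rho, Ne = Ne,
                 inversion_span = inversion_span,
                 inv_frequency = inv_frequency, origin = origin, age = age,
                 k_events = k_events, gene_conversion = gene_conversion,
                 gc_tract = gc_tract, freq_tol = freq_tol,
                 chromosome = chromosome, seed = seed),
            class = "sim_config")
}

# ---- Kingman coalescent with per-lineage entry times -----------------------
# Returns parent pointers and node times (generations, backwards from 0).
# Tips are nodes 1..n, internal nodes n+1..2n-1 in coalescence order.
coalescent_genealogy <- function(entry_times, Ne) {
  n <- length(entry_times)
  if (n == 1)
    return(list(parent = NA_integer_, node_time = entry_times, n_tips = 1L,
                root = 1L))
  node_time <- c(entry_times, rep(NA_real_, n - 1))
  parent <- rep(NA_integer_, 2 * n - 1)
  pending <- order(entry_times)
  active <- integer(0)
  t <- 0
  next_node <- n + 1L
  while (length(active) > 1 || length(pending) > 0) {
    k <- length(active)
    tnext <- if (k >= 2) t + rexp(1, rate = k * (k - 1) / 2 / (2 * Ne)) else Inf
    if (length(pending) > 0 && entry_times[pending[1]] <= tnext) {
      t <- max(t, entry_times[pending[1]])
      active <- c(active, pending[1])
      pending <- pending[-1]
    } else {
      t <- tnext
      pair <- sample(active, 2)
      node_time[next_node] <- t
      parent[pair] <- next_node
      active <- c(setdiff(active, pair), next_node)
      next_node <- next_node + 1L
    }
  }
  list(parent = parent, node_time = node_time, n_tips = n,
       root = 2L * n - 1L)
}

# descendant tip sets for every node (list indexed by node id)
genealogy_descendants <- function(gen) {
  n_nodes <- length(gen$parent)
  ord <- order(gen$node_time)
  # accumulate bottom-up: process nodes in increasing time, pushing into parent
  acc <- vector("list", n_nodes)
  for (v in seq_len(n_nodes)) acc[[v]] <- integer(0)
  for (i in seq_len(gen$n_tips)) acc[[i]] <- i
  for (v in ord) {
    p <- gen$parent[v]
    if (!is.na(p)) acc[[p]] <- c(acc[[p]], acc[[v]])
  }
  acc
}

# drop mutations on a genealogy: Poisson per branch, uniform positions
drop_mutations <- function(gen, mu, span) {
  L <- span[2] - span[1]
  desc <- genealogy_descendants(gen)
  carriers <- list()
  pos <- integer(0)
  for (v in seq_along(gen$parent)) {
    p <- gen$parent[v]
    if (is.na(p)) next
    len <- gen$node_time[p] - gen$node_time[v]
    nm <- rpois(1, mu * L * len)
    if (nm > 0) {
      pos <- c(pos, span[1] + sample.int(L, nm, replace = TRUE) - 1L)
      carriers <- c(carriers, rep(list(desc[[v]]), nm))
    }
  }
  if (length(pos) == 0)
    return(list(pos = integer(0), carriers = list()))
  # infinite-sites approximation: resolve positional collisions by jitter
  dup <- duplicated(pos)
  while (any(dup)) {
    pos[dup] <- span[1] + sample.int(L, sum(dup), replace = TRUE) - 1L
    dup <- duplicated(pos)
  }
  o <- order(pos)
  list(pos = pos[o], carriers = carriers[o])
}

# Fitch small-parsimony count on a coalescent genealogy (binary states)
genealogy_parsimony <- function(gen, tip_states) {
  n_nodes <- length(gen$parent)
  sets <- vector("list", n_nodes)
  for (i in seq_len(gen$n_tips)) sets[[i]] <- tip_states[i]
  changes <- 0
  kids <- split(seq_len(n_nodes)[!is.na(gen$parent)],
                gen$parent[!is.na(gen$parent)])
  for (v in order(gen$node_time)) {
    ch <- kids[[as.character(v)]]
    if (is.null(ch)) next
    s <- Reduce(intersect, lapply(ch, function(c) sets[[c]]))
    if (length(s) == 0) {
      s <- Reduce(union, lapply(ch, function(c) sets[[c]]))
      changes <- changes + 1
    }
    sets[[v]] <- s
  }
  changes
}

# one linked genealogy for the inversion + per-segment flank genealogies
simulate_one_replicate <- function(cfg) {
  n_hap <- sum(cfg$n_samples) * cfg$ploidy
  span <- cfg$inversion_span
  if (cfg$origin == "unique") {
    n2 <- max(1L, round(cfg$inv_frequency * n_hap))
    if (n2 >= n_hap) stopf("inv_frequency too high for %d haplotypes", n_hap)
    n1 <- n_hap - n2
    # O2 class: coalescent conditioned to find its common ancestor more
    # recently than the origin
    g2 <- NULL
    for (try in 1:500) {
      cand <- coalescent_genealogy(rep(0, n2), cfg$Ne)
      if (n2 == 1 || max(cand$node_time, na.rm = TRUE) <= cfg$age) {
        g2 <- cand; break
      }
    }
    if (is.null(g2))
      stopf("could not condition O2 genealogy on age %g; use smaller Ne or larger age",
            cfg$age)
    # O1 class plus the ancestral lineage of the O2 clade entering at `age`
    g1 <- coalescent_genealogy(c(rep(0, n1), cfg$age), cfg$Ne)
    gen <- merge_origin_genealogy(g1, g2, n1, n2)
    orientation <- c(rep("O1", n1), rep("O2", n2))
    events <- data.frame(event = 1L, time = cfg$age,
                         n_carriers = n2, stringsAsFactors = FALSE)
    event_carriers <- list(seq(n1 + 1L, n_hap))
  } else {
    k <- cfg$k_events
    gen <- NULL
    for (try in 1:1000) {
      cand <- coalescent_genealogy(rep(0, n_hap), cfg$Ne)
      desc <- genealogy_descendants(cand)
      edges <- which(!is.na(cand$parent))
      sizes <- lengths(desc[edges])
      ok_edges <- edges[sizes < n_hap]
      if (length(ok_edges) < k) next
      pick <- sample(ok_edges, k)
      sets <- desc[pick]
      disjoint <- length(unlist(sets)) == length(unique(unlist(sets)))
      if (!disjoint) next
      carriers <- sort(unique(unlist(sets)))
      freq <- length(carriers) / n_hap
      if (abs(freq - cfg$inv_frequency) > cfg$freq_tol) next
      states <- rep("O1", n_hap); states[carriers] <- "O2"
      if (genealogy_parsimony(cand, states) != k) next
      gen <- cand
      orientation <- states
      event_carriers <- lapply(sets, sort)
      events <- data.frame(event = seq_len(k),
                           time = cand$node_time[cand$parent[pick]] -
                             (cand$node_time[cand$parent[pick]] -
                              cand$node_time[pick]) / 2,
                           n_carriers = lengths(sets))
      break
    }
    if (is.null(gen))
      stopf("could not place %d recurrent origin events at frequency %.2f +- %.2f; use a larger sample or wider freq_tol",
            k, cfg$inv_frequency, cfg$freq_tol)
  }
  list(gen = gen, orientation = orientation, events = events,
       event_carriers = event_carriers, n_hap = n_hap)
}

# graft the O2 clade (g2) onto the O1-side genealogy (g1) whose extra
# "tip" n1+1 is the O2 ancestral lineage entering at the origin time
merge_origin_genealogy <- function(g1, g2, n1, n2) {
  n <- n1 + n2
  parent <- rep(NA_integer_, 2 * n - 1)
  node_time <- rep(NA_real_, 2 * n - 1)
  # maps: g1 nodes -> global; the pseudo-tip n1+1 maps to g2's root
  n_nodes1 <- length(g1$parent)
  map1 <- integer(n_nodes1)
  map1[seq_len(n1)] <- seq_len(n1)
  n_int2 <- if (n2 > 1) n2 - 1L else 0L
  int1_global <- n + n_int2 + seq_len(n_nodes1 - (n1 + 1L))
  if (n_nodes1 > n1 + 1L) map1[(n1 + 2L):n_nodes1] <- int1_global
  map2 <- integer(length(g2$parent))
  map2[seq_len(n2)] <- n1 + seq_len(n2)
  if (n_int2 > 0) map2[(n2 + 1L):(2L * n2 - 1L)] <- n + seq_len(n_int2)
  map1[n1 + 1L] <- map2[g2$root]
  for (v in seq_len(n_nodes1)) {
    g <- map1[v]
    if (v != n1 + 1L) node_time[g] <- g1$node_time[v]
    if (!is.na(g1$parent[v])) parent[g] <- map1[g1$parent[v]]
  }
  for (v in seq_along(g2$parent)) {
    g <- map2[v]
    node_time[g] <- g2$node_time[v]
    if (!is.na(g2$parent[v])) parent[g] <- map2[g2$parent[v]]
  }
  list(parent = parent, node_time = node_time, n_tips = n,
       root = map1[g1$root])
}

#' Simulate a phased haplotype panel carrying a polymorphic inversion
#'
#' Generates coalescent-style haplotypes under the configured origin model
#' (see [sim_config()]), together with the matching [variant_panel()],
#' inversion [genotype_table()] and a ground-truth record for recovery
#' tests. Within the inversion span the orientation classes never exchange
#' material by crossing-over; the only exchange mechanism is gene
#' conversion, applied as short tract copies between random
#' opposite-orientation haplotypes. Flanking sequence recombines away from
#' the inversion genealogy: each flank segment keeps the inversion-linked
#' genealogy with probability `exp(-4 Ne rho d)` at distance `d` from the
#' breakpoint, and otherwise receives an independent neutral genealogy, so
#' linkage to the inversion decays with distance.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `haps` ([haplotype_set()] carrying the true
#'   orientation labels), `variants` ([variant_panel()]), `genotypes`
#'   ([genotype_table()]), `panel` ([population_panel()]) and `truth`
#'   (origin events with carrier sets, true age, true perfect-tag variants,
#'   gene-conversion tracts applied).
#' @export
simulate_haplotypes <- function(cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  rep <- simulate_one_replicate(cfg)
  gen <- rep$gen; n_hap <- rep$n_hap
  span <- cfg$inversion_span
  # Within the inversion span the two orientation classes never exchange
  # material, but same-orientation chromosomes do recombine: with rho > 0
  # (unique-origin mode) the span is split into ~4*Ne*rho*L blocks, each
  # with an independent class-structured genealogy sharing the same
  # orientation membership and origin time.
  muts_pos <- integer(0); muts_car <- list()
  n_blocks <- if (cfg$origin == "unique" && cfg$rho > 0)
    max(1L, round(4 * cfg$Ne * cfg$rho * (span[2] - span[1]))) else 1L
  block_bounds <- round(seq(span[1], span[2], length.out = n_blocks + 1))
  for (b in seq_len(n_blocks)) {
    bgen <- if (b == 1) gen else simulate_one_replicate(cfg)$gen
    mm <- drop_mutations(bgen, cfg$mu,
                         c(block_bounds[b], block_bounds[b + 1]))
    muts_pos <- c(muts_pos, mm$pos); muts_car <- c(muts_car, mm$carriers)
  }
  # flanks: 1-kb segments that stay linked to the inversion genealogy
  # with probability exp(-4 Ne rho d)
  segs <- flank_segments(cfg)
  for (sg in segs) {
    p_link <- if (cfg$rho == 0) 1 else exp(-4 * cfg$Ne * cfg$rho * sg$dist)
    use_gen <- if (runif(1) < p_link) gen else
      coalescent_genealogy(rep(0, n_hap), cfg$Ne)
    mm <- drop_mutations(use_gen, cfg$mu, c(sg$start, sg$end))
    muts_pos <- c(muts_pos, mm$pos); muts_car <- c(muts_car, mm$carriers)
  }
  o <- order(muts_pos)
  muts_pos <- muts_pos[o]; muts_car <- muts_car[o]
  H <- matrix(0L, nrow = n_hap, ncol = length(muts_pos))
  for (j in seq_along(muts_car)) H[muts_car[[j]], j] <- 1L
  # gene conversion: short tracts copied between opposite orientations
  gc_tracts <- data.frame(donor = integer(0), recipient = integer(0),
                          start = integer(0), end = integer(0))
  n_gc <- if (cfg$gene_conversion > 0) rpois(1, cfg$gene_conversion) else 0
  if (n_gc > 0) {
    o1 <- which(rep$orientation == "O1"); o2 <- which(rep$orientation == "O2")
    for (e in seq_len(n_gc)) {
      if (runif(1) < 0.5) { d <- sample(o1, 1); r <- sample(o2, 1) }
      else { d <- sample(o2, 1); r <- sample(o1, 1) }
      st <- span[1] + sample.int(max(1L, span[2] - span[1] - cfg$gc_tract), 1) - 1L
      en <- st + cfg$gc_tract
      cols <- which(muts_pos >= st & muts_pos < en)
      if (length(cols) > 0) H[r, cols] <- H[d, cols]
      gc_tracts <- rbind(gc_tracts, data.frame(donor = d, recipient = r,
                                               start = st, end = en))
    }
  }
  # drop sites monomorphic after gene conversion
  ac <- colSums(H)
  seg <- ac > 0 & ac < n_hap
  H <- H[, seg, drop = FALSE]; muts_pos <- muts_pos[seg]
  # sample bookkeeping
  pops <- rep(names(cfg$n_samples), cfg$n_samples)
  sample_id <- sprintf("S%04d", seq_len(sum(cfg$n_samples)))
  hap_sample <- rep(sample_id, each = cfg$ploidy)
  hap_pop <- rep(pops, each = cfg$ploidy)
  grp <- ifelse(names(cfg$n_samples) %in% c("AFR", "EUR", "SAS", "EAS"),
                names(cfg$n_samples), "other")
  panel <- population_panel(sample_id, sex = "unknown", population = pops,
                            group = rep(grp, cfg$n_samples))
  haps <- haplotype_set(H, muts_pos, orientation = rep$orientation,
                        sample_id = hap_sample, population = hap_pop,
                        ancestral = rep(0L, ncol(H)))
  vp <- variant_panel(H, cfg$chromosome, muts_pos, hap_sample = hap_sample,
                      ancestral = rep(0L, ncol(H)))
  geno <- orientation_to_genotypes(rep$orientation, hap_sample, cfg$ploidy)
  gt <- genotype_table(matrix(geno, ncol = 1,
                              dimnames = list(sample_id, "INV1")),
                       panel, c(INV1 = cfg$chromosome))
  o2set <- which(rep$orientation == "O2")
  tag_true <- which(vapply(seq_len(ncol(H)), function(j)
    setequal(which(H[, j] == 1L), o2set) ||
      setequal(which(H[, j] == 0L), o2set), TRUE))
  truth <- structure(list(origin = rep$events,
                          event_carriers = rep$event_carriers,
                          age = if (cfg$origin == "unique") cfg$age else NA_real_,
                          orientation = rep$orientation,
                          tag_variants = muts_pos[tag_true],
                          gc_tracts = gc_tracts,
                          frequency = length(o2set) / n_hap),
                     class = "truth_record")
  list(haps = haps, variants = vp, genotypes = gt, panel = panel,
       truth = truth)
}

flank_segments <- function(cfg, seg_len = 1000) {
  span <- cfg$inversion_span
  segs <- list()
  add <- function(st, en, dist) {
    if (en > st) segs[[length(segs) + 1]] <<- list(start = st, end = en,
                                                   dist = dist)
  }
  pos <- span[1]
  while (pos > 0) {
    st <- max(0, pos - seg_len)
    add(st, pos, span[1] - pos + seg_len / 2)
    pos <- st
  }
  pos <- span[2]
  while (pos < cfg$seq_length) {
    en <- min(cfg$seq_length, pos + seg_len)
    add(pos, en, pos - span[2] + seg_len / 2)
    pos <- en
  }
  segs
}

orientation_to_genotypes <- function(orientation, hap_sample, ploidy) {
  samples <- unique(hap_sample)
  vapply(samples, function(s) {
    ors <- sort(orientation[hap_sample == s])
    if (length(ors) == 1) ors else paste(ors, collapse = "/")
  }, "")
}

#' Simulate a neutral SNP pool (no inversion)
#'
#' A constant-size coalescent panel of `n_loci` unlinked loci (independent
#' genealogies laid end to end), emulating a genome-wide SNP pool; the
#' site-frequency spectrum of the emitted variants follows the neutral
#' 1/i expectation, and the many independent genealogies keep the
#' realized spectrum close to it.
#'
#' @param n_samples number of diploid samples.
#' @param n_loci number of unlinked loci.
#' @param seq_length total sequence length in bases (split across loci).
#' @param mu,Ne as in [sim_config()].
#' @param chromosome chromosome name.
#' @param seed integer seed.
#' @return a [variant_panel()].
#' @export
simulate_neutral_pool <- function(n_samples = 500, n_loci = 50,
                                  seq_length = 50000, mu = 1e-6, Ne = 10000,
                                  chromosome = "chr1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_hap <- 2L * n_samples
  L <- floor(seq_length / n_loci)
  all_pos <- integer(0); all_car <- list()
  for (l in seq_len(n_loci)) {
    gen <- coalescent_genealogy(rep(0, n_hap), Ne)
    mm <- drop_mutations(gen, mu, c((l - 1L) * L, l * L))
    all_pos <- c(all_pos, mm$pos)
    all_car <- c(all_car, mm$carriers)
  }
  H <- matrix(0L, nrow = n_hap, ncol = length(all_pos))
  for (j in seq_along(all_car)) H[all_car[[j]], j] <- 1L
  sample_id <- sprintf("S%04d", seq_len(n_samples))
  variant_panel(H, chromosome, all_pos,
                hap_sample = rep(sample_id, each = 2),
                ancestral = rep(0L, ncol(H)))
}

#' Simulate the discovery step of an ascertainment process
#'
#' Keeps the variants that are polymorphic within a discovery subset of
#' individuals (both alleles observed among their haplotypes), mirroring
#' variant discovery in a small sequencing panel before wide genotyping.
#'
#' @param vp a [variant_panel()].
#' @param discovery_ids sample ids forming the discovery panel.
#' @return the ascertained [variant_panel()], with a `detection_prob`
#'   attribute holding, per retained variant, the analytic probability that
#'   a random panel of the same haplotype count would have discovered it
#'   (computed from the pool allele frequency).
#' @export
simulate_discovery_panel <- function(vp, discovery_ids) {
  if (length(discovery_ids) == 0) stopf("empty discovery panel")
  missing <- setdiff(discovery_ids, unique(vp$hap_sample))
  if (length(missing) > 0)
    stopf("discovery individuals absent from panel: %s",
          paste(missing, collapse = ", "))
  rows <- vp$hap_sample %in% discovery_ids
  sub <- vp$alleles[rows, , drop = FALSE]
  nalt <- colSums(sub, na.rm = TRUE)
  nobs <- colSums(!is.na(sub))
  keep <- nalt > 0 & nalt < nobs
  out <- subset_variants(vp, variants = keep)
  m <- sum(rows)
  p <- alt_freq(vp)[keep]
  attr(out, "detection_prob") <- 1 - p^m - (1 - p)^m
  out
}

#' Simulate a Y-chromosome genealogy with placed inversion events
#'
#' Draws a random rooted coalescent tree and places `k_events` orientation
#' flips on distinct, non-nested branches such that the minimum-change
#' (small parsimony) reconstruction of the tip states equals `k_events`.
#'
#' @param n_tips number of chromosomes (tips).
#' @param k_events number of inversion events to place (0 allowed).
#' @param scale multiplier applied to the coalescent branch lengths to
#'   express them in generations.
#' @param seed integer seed.
#' @return list with `tree` (an [ape::phylo] with branch lengths in
#'   generations), `tip_states` (named `O1`/`O2` vector, ancestral state
#'   `O1`) and `truth` (flipped clades per event).
#' @export
simulate_ytree <- function(n_tips, k_events, scale = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_tips >= 3, k_events >= 0)
  for (try in 1:500) {
    tree <- ape::rcoal(n_tips)
    tree$edge.length <- tree$edge.length * scale
    states <- setNames(rep("O1", n_tips), tree$tip.label)
    if (k_events == 0)
      return(list(tree = tree, tip_states = states,
                  truth = list(k = 0L, clades = list())))
    tipsets <- lapply(seq_len(nrow(tree$edge)), function(i)
      phylo_tips_below(tree, tree$edge[i, 2]))
    cand <- which(lengths(tipsets) < n_tips)
    if (length(cand) < k_events) next
    pick <- sample(cand, k_events)
    sets <- tipsets[pick]
    if (length(unlist(sets)) != length(unique(unlist(sets)))) next
    flipped <- unlist(sets)
    states[flipped] <- "O2"
    if (fitch_parsimony_events(tree, states) != k_events) {
      states[flipped] <- "O1"; next
    }
    return(list(tree = tree, tip_states = states,
                truth = list(k = as.integer(k_events),
                             clades = lapply(sets, function(s) tree$tip.label[s]))))
  }
  stopf("could not place %d non-nested events on a %d-tip tree", k_events, n_tips)
}

phylo_tips_below <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(node)
  out <- integer(0); stack <- node
  while (length(stack) > 0) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    ch <- tree$edge[tree$edge[, 1] == v, 2]
    out <- c(out, ch[ch <= n])
    stack <- c(stack, ch[ch > n])
  }
  sort(out)
}

#' Simulate an expression matrix with a planted inversion-genotype effect
#'
#' `expression = baseline + effect x O2-dosage + N(0, sd)` per gene.
#'
#' @param gt a [genotype_table()] (its first inversion column is used).
#' @param effect numeric vector of per-gene effect sizes.
#' @param noise_sd Gaussian noise standard deviation.
#' @param baseline per-gene baseline (recycled; default 0).
#' @param seed integer seed.
#' @return list with `expr` (genes x samples matrix) and `truth`
#'   (per-gene effects).
#' @export
simulate_expression <- function(gt, effect, noise_sd = 1, baseline = 0,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(is.finite(effect)))
  dos <- o2_dosage(gt)[, 1]
  n_genes <- length(effect)
  baseline <- rep_len(baseline, n_genes)
  expr <- matrix(rnorm(n_genes * length(dos), sd = noise_sd),
                 nrow = n_genes,
                 dimnames = list(sprintf("gene%04d", seq_len(n_genes)),
                                 names(dos)))
  expr <- expr + baseline + outer(effect, dos)
  list(expr = expr,
       truth = data.frame(gene = rownames(expr), effect = effect,
                          stringsAsFactors = FALSE))
}
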