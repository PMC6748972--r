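#' Assign inversion orientation to phased haplotypes
#'
#' Labels each haplotype `O1`/`O2` from the allele it carries at a perfect
#' tag variant (`r2 = 1`). Where no perfect tag is available, only the
#' haplotypes of inversion homozygotes or hemizygotes are labelled (their
#' orientation is unambiguous); all other haplotypes stay `unknown`.
#' Haplotypes with conflicting perfect-tag alleles are flagged and left
#' unlabelled.
#'
#' @param haps a [haplotype_set()] (phased).
#' @param gt a [genotype_table()] over the same samples.
#' @param tags optional data frame from [find_tag_variants()]; only rows
#'   with `perfect = TRUE` are used. `NULL` for the homozygote-only path.
#' @param inversion_id inversion column of `gt`.
#' @return the [haplotype_set()] with `orientation` filled in and a
#'   `conflicts` attribute (indices of tag-conflicted haplotypes).
#' @export
assign_orientation <- function(haps, gt, tags = NULL, inversion_id = 1) {
  n <- nrow(haps$alleles)
  ori <- rep("unknown", n)
  conflicts <- integer(0)
  g <- setNames(gt$geno[, inversion_id], rownames(gt$geno))
  perfect <- if (!is.null(tags)) tags[tags$perfect, , drop = FALSE] else NULL
  if (!is.null(perfect) && nrow(perfect) > 0) {
    cols <- match(unique(perfect$pos), haps$pos)
    cols <- cols[!is.na(cols)]
    if (length(cols) > 0) {
      # orient each tag: which allele travels with O2, read off homozygotes
      dos <- o2_dosage(gt)[, inversion_id]
      for (i in seq_len(n)) {
        votes <- character(0)
        s <- haps$sample_id[i]
        for (j in cols) {
          a <- haps$alleles[i, j]
          if (is.na(a)) next
          # allele/orientation pairing from samples with known genotypes
          o2_allele <- tag_o2_allele(haps, j, g)
          if (is.na(o2_allele)) next
          votes <- c(votes, if (a == o2_allele) "O2" else "O1")
        }
        if (length(votes) == 0) next
        if (length(unique(votes)) > 1) conflicts <- c(conflicts, i)
        else ori[i] <- votes[1]
      }
    }
  }
  # homozygote/hemizygote restriction for anything still unknown
  for (i in which(ori == "unknown")) {
    gi <- g[haps$sample_id[i]]
    if (is.na(gi)) next
    if (gi %in% c("O1/O1", "O1")) ori[i] <- "O1"
    if (gi %in% c("O2/O2", "O2")) ori[i] <- "O2"
  }
  ori[conflicts] <- "unknown"
  out <- haplotype_set(haps$alleles, haps$pos, ori, haps$sample_id,
                       haps$population, haps$accessible, haps$ancestral)
  attr(out, "conflicts") <- unique(conflicts)
  out
}

# which variant allele rides on O2 chromosomes, from unambiguous samples
tag_o2_allele <- function(haps, col, g) {
  ori_known <- g[haps$sample_id]
  a <- haps$alleles[, col]
  on_o2 <- unique(a[!is.na(ori_known) & ori_known %in% c("O2/O2", "O2") & !is.na(a)])
  on_o1 <- unique(a[!is.na(ori_known) & ori_known %in% c("O1/O1", "O1") & !is.na(a)])
  if (length(on_o2) == 1 && length(on_o1) == 1 && on_o2 != on_o1) return(on_o2)
  NA_integer_
}

#' Hierarchical clustering of haplotypes (iHPlot backbone)
#'
#' Clusters haplotypes by Hamming distance over accessible variants with
#' complete or average linkage. Haplotypes are first put into a canonical
#' order (lexicographic over alleles) so that the clustering, its leaf
#' order and all downstream event counts are invariant to the input row
#' permutation.
#'
#' @param haps a [haplotype_set()], typically orientation-labelled.
#' @param linkage_method `"complete"` or `"average"`.
#' @param use_mask restrict to accessible variants.
#' @return a `haplotype_clustering` object: the `hclust` tree, the pairwise
#'   distance matrix, leaf order and per-leaf orientation/population/sample
#'   annotations.
#' @export
cluster_haplotypes <- function(haps, linkage_method = c("complete", "average"),
                               use_mask = FALSE) {
  linkage_method <- match.arg(linkage_method)
  H <- haps$alleles
  if (use_mask) H <- H[, haps$accessible, drop = FALSE]
  if (nrow(H) < 3) stopf("need at least 3 haplotypes")
  if (ncol(H) < 1) stopf("need at least 1 variant")
  key <- apply(H, 1, paste, collapse = "")
  ord <- order(key, seq_len(nrow(H)))
  H <- H[ord, , drop = FALSE]
  D <- hamming_distance(H)
  labels <- paste0(haps$sample_id[ord], "_h", ord)
  dimnames(D) <- list(labels, labels)
  hc <- hclust(as.dist(D), method = linkage_method)
  structure(list(
    hclust = hc, dist = D, input_order = ord,
    leaf_order = hc$order,
    labels = labels,
    alleles = H,
    orientation = haps$orientation[ord],
    population = haps$population[ord],
    sample_id = haps$sample_id[ord]),
    class = "haplotype_clustering")
}

#' @export
print.haplotype_clustering <- function(x, ...) {
  cat(sprintf("haplotype_clustering: %d haplotypes, %d variants, %s linkage\n",
              nrow(x$alleles), ncol(x$alleles), x$hclust$method))
  invisible(x)
}

# pairwise Hamming distances of a 0/1 matrix (NA-tolerant)
hamming_distance <- function(H) {
  H1 <- H; H1[is.na(H1)] <- 0L
  H0 <- 1L - H; H0[is.na(H0)] <- 0L
  D <- H1 %*% t(H0) + H0 %*% t(H1)
  diag(D) <- 0
  (D + t(D)) / 2
}

#' Minimum recurrence-event estimate from a haplotype clustering
#'
#' Counts the minimum number of orientation state changes needed on the
#' clustering dendrogram (small parsimony) and reports `changes - 1` as
#' the number of recurrence events beyond the original inversion. Before
#' counting, putative phasing errors are removed: a labelled haplotype
#' from an inversion-heterozygous sample lying within `max_error_diff`
#' Hamming distance of an opposite-orientation haplotype is reassigned to
#' that orientation. Supporting clusters (maximal same-orientation clades
#' under one most-parsimonious reconstruction) are reported with their
#' sizes; clusters below `min_support` haplotypes are flagged.
#'
#' @param clust a [cluster_haplotypes()] result.
#' @param min_support minimum haplotypes per supporting cluster before it
#'   is flagged as weakly supported.
#' @param max_error_diff Hamming radius of the phasing-error rule.
#' @param min_separation same-orientation state-change clusters whose
#'   minimum Hamming distance is below this threshold are treated as one
#'   event (they do not differ enough to support independent origins);
#'   default 20 variants. The threshold is reported, never silently
#'   applied.
#' @param by_group optionally a named list of population sets; the event
#'   count is recomputed restricted to each set (e.g. African vs
#'   non-African populations).
#' @return a `recurrence_estimate` list: `events`, `changes` (raw
#'   dendrogram parsimony count), `clusters` (data frame with orientation,
#'   size, event id after merging, flagged), `reassigned` (indices),
#'   `min_separation`, and `group_events` when `by_group` is given.
#' @export
estimate_recurrence <- function(clust, min_support = 1, max_error_diff = 2,
                                min_separation = 20, by_group = NULL) {
  ori <- clust$orientation
  labeled <- which(ori %in% c("O1", "O2"))
  if (length(labeled) == 0) stopf("no orientation-labelled haplotypes")
  # phasing-error pruning: haplotypes of heterozygous samples only
  het_samples <- names(which(tapply(ori, clust$sample_id, function(o)
    all(c("O1", "O2") %in% o))))
  reassigned <- integer(0)
  ori2 <- ori
  for (i in labeled) {
    if (!clust$sample_id[i] %in% het_samples) next
    opp <- which(ori == setdiff(c("O1", "O2"), ori[i]))
    opp <- setdiff(opp, i)
    if (length(opp) == 0) next
    if (min(clust$dist[i, opp]) <= max_error_diff) {
      ori2[i] <- setdiff(c("O1", "O2"), ori[i])
      reassigned <- c(reassigned, i)
    }
  }
  res <- dendrogram_parsimony(clust, ori2)
  clusters <- res$clusters
  clusters$event <- merge_close_clusters(clusters, clust$dist, min_separation)
  # distinct cluster groups minus the ancestral-state group minus the
  # original inversion
  n_eff <- length(unique(clusters$event))
  events <- max(0L, n_eff - 2L)
  clusters$flagged <- clusters$size < min_support
  out <- list(events = events, changes = res$changes, clusters = clusters,
              reassigned = reassigned, orientation_used = ori2,
              min_separation = min_separation)
  if (!is.null(by_group)) {
    out$group_events <- vapply(by_group, function(pops) {
      keep <- clust$population %in% pops & ori2 %in% c("O1", "O2")
      if (sum(keep) < 3) return(NA_integer_)
      sub <- haplotype_set(clust$alleles[keep, , drop = FALSE],
                           seq_len(ncol(clust$alleles)),
                           ori2[keep], clust$sample_id[keep],
                           clust$population[keep])
      sc <- cluster_haplotypes(sub, clust$hclust$method)
      r <- dendrogram_parsimony(sc, sc$orientation)
      cl <- r$clusters
      cl$event <- merge_close_clusters(cl, sc$dist, min_separation)
      as.integer(max(0L, length(unique(cl$event)) - 2L))
    }, integer(1))
  }
  class(out) <- "recurrence_estimate"
  out
}

#' @export
print.recurrence_estimate <- function(x, ...) {
  cat(sprintf("recurrence_estimate: %d state change(s) on the dendrogram -> %d event(s) beyond the original inversion; %d haplotype(s) reassigned as phasing errors\n",
              x$changes, x$events, length(x$reassigned)))
  invisible(x)
}

# Fitch small parsimony on the hclust dendrogram; returns the change count
# and the maximal same-orientation clades of one MP reconstruction, with
# member labels so that clusters can be compared by Hamming distance
dendrogram_parsimony <- function(clust, ori) {
  tree <- ape::as.phylo(clust$hclust)
  keep <- clust$labels[ori %in% c("O1", "O2")]
  states <- setNames(ori[ori %in% c("O1", "O2")], keep)
  if (length(keep) < 2) return(list(changes = 0L,
                                    clusters = data.frame(orientation = unique(states),
                                                          size = length(keep),
                                                          members = I(list(keep)))))
  if (length(keep) < length(clust$labels))
    tree <- ape::keep.tip(tree, keep)
  fp <- fitch_reconstruction(tree, states)
  clusters <- fitch_clusters(tree, states, fp)
  list(changes = fp$changes, clusters = clusters)
}

# single-linkage merge of same-orientation clusters closer than the
# separation threshold; returns an event id per cluster row
merge_close_clusters <- function(clusters, dist, min_separation) {
  n <- nrow(clusters)
  id <- seq_len(n)
  if (n < 2 || min_separation <= 0) return(id)
  find <- function(i) { while (id[i] != i) i <- id[i] <- id[id[i]]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (clusters$orientation[i] != clusters$orientation[j]) next
    mi <- clusters$members[[i]]; mj <- clusters$members[[j]]
    if (min(dist[mi, mj]) < min_separation) id[find(j)] <- find(i)
  }
  vapply(seq_len(n), find, integer(1))
}

#' Minimum inversion state changes on a phylogenetic tree (Fitch parsimony)
#'
#' Standard two-pass small parsimony for binary orientation states on a
#' rooted (binary or multifurcating) tree. Tips without a state are
#' dropped with a warning. With `root_state` given, the count is
#' conditioned on that ancestral orientation at the root.
#'
#' @param tree an [ape::phylo] rooted tree.
#' @param tip_states named character vector (`O1`/`O2`) over tip labels.
#' @param root_state optional `"O1"` or `"O2"`.
#' @return integer minimum number of state changes.
#' @examples
#' tr <- ape::read.tree(text = "((a,b),(c,d));")
#' fitch_parsimony_events(tr, c(a = "O2", b = "O2", c = "O1", d = "O1"))  # 1
#' @export
fitch_parsimony_events <- function(tree, tip_states, root_state = NULL) {
  if (is.null(tree) || length(tree$tip.label) == 0) stopf("empty tree")
  miss <- setdiff(tree$tip.label, names(tip_states))
  nastate <- names(tip_states)[is.na(tip_states)]
  drop <- union(miss, intersect(nastate, tree$tip.label))
  if (length(drop) > 0) {
    warnf("%d tip(s) without state dropped", length(drop))
    if (length(drop) >= length(tree$tip.label) - 1)
      stopf("fewer than 2 stated tips remain")
    tree <- ape::drop.tip(tree, drop)
  }
  states <- tip_states[tree$tip.label]
  fp <- fitch_reconstruction(tree, states)
  changes <- if (is.null(root_state)) fp$changes
  else fp$root_cost[root_state]
  as.integer(changes)
}

# small-parsimony dynamic programme (unit costs) over an ape phylo;
# handles multifurcations; exact per-state root costs allow conditioning
fitch_reconstruction <- function(tree, states) {
  n <- length(tree$tip.label)
  n_nodes <- n + tree$Nnode
  st <- c("O1", "O2")
  cost <- matrix(Inf, nrow = n_nodes, ncol = 2, dimnames = list(NULL, st))
  for (i in seq_len(n)) cost[i, unname(states[tree$tip.label[i]])] <- 0
  post <- n + rank_nodes_postorder(tree)
  for (v in post) {
    ch <- tree$edge[tree$edge[, 1] == v, 2]
    for (s in 1:2) {
      tot <- 0
      for (c2 in ch) tot <- tot + min(cost[c2, s], cost[c2, 3 - s] + 1)
      cost[v, s] <- tot
    }
  }
  root <- n + 1L
  root_cost <- cost[root, ]
  list(changes = as.integer(min(root_cost)), cost = cost,
       root_cost = root_cost,
       root_set = st[root_cost == min(root_cost)])
}

# internal nodes in child-before-parent order, as offsets from n
rank_nodes_postorder <- function(tree) {
  n <- length(tree$tip.label)
  ord <- integer(0)
  visit <- function(v) {
    ch <- tree$edge[tree$edge[, 1] == v, 2]
    for (c in ch) if (c > n) visit(c)
    ord <<- c(ord, v - n)
  }
  visit(n + 1L)
  ord
}

# one MP assignment (root preference O1) -> maximal same-state clades
fitch_clusters <- function(tree, states, fp) {
  n <- length(tree$tip.label)
  n_nodes <- n + tree$Nnode
  st <- c("O1", "O2")
  assign <- character(n_nodes)
  root <- n + 1L
  assign[root] <- if ("O1" %in% fp$root_set) "O1" else fp$root_set[1]
  pre <- rev(n + rank_nodes_postorder(tree))
  for (v in pre) {
    ch <- tree$edge[tree$edge[, 1] == v, 2]
    ps <- match(assign[v], st)
    for (c in ch) {
      # keep the parent state on ties (minimizes apparent clusters)
      keep <- fp$cost[c, ps] <= fp$cost[c, 3 - ps] + 1
      assign[c] <- if (keep) st[ps] else st[3 - ps]
    }
  }
  # cluster roots: nodes whose state differs from parent (plus tree root)
  parent <- rep(NA_integer_, n_nodes)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  cl_roots <- c(root, which(!is.na(parent) & assign != assign[parent]))
  rows <- lapply(cl_roots, function(v) {
    tips <- if (v <= n) v else phylo_tips_below(tree, v)
    # only tips not claimed by a deeper cluster root
    deeper <- setdiff(cl_roots, v)
    claimed <- unlist(lapply(deeper, function(w) {
      tw <- if (w <= n) w else phylo_tips_below(tree, w)
      if (all(tw %in% tips) && length(tw) < length(tips)) tw else integer(0)
    }))
    own <- setdiff(tips, claimed)
    data.frame(orientation = assign[v], size = length(own),
               members = I(list(tree$tip.label[own])))
  })
  out <- do.call(rbind, rows)
  out[out$size > 0, , drop = FALSE]
}

#' Inversion (re-)inversion rate from events on a genealogy
#'
#' `rate = events / total branch length in generations`, with an exact
#' Poisson confidence interval on the event count.
#'
#' @param events non-negative integer event count.
#' @param total_branch_generations total branch length of the genealogy in
#'   generations.
#' @param conf_level confidence level for the Poisson interval.
#' @return list with `rate` (per generation), `ci` (length 2) and the
#'   inputs.
#' @export
inversion_rate <- function(events, total_branch_generations,
                           conf_level = 0.95) {
  if (total_branch_generations <= 0) stopf("total branch length must be > 0")
  stopifnot(events >= 0)
  ci <- poisson.test(events, conf.level = conf_level)$conf.int /
    total_branch_generations
  list(rate = events / total_branch_generations, ci = as.numeric(ci),
       events = events, total_branch_generations = total_branch_generations)
}

#' Render an integrated haplotype plot (iHPlot)
#'
#' Draws the haplotype dendrogram, the pairwise distance heatmap, the
#' allele matrix (one column per polymorphic position) and orientation /
#' population side bars in a single deterministic layout, to the current
#' device or to a PNG/PDF file chosen by the `out` extension.
#'
#' @param clust a [cluster_haplotypes()] result.
#' @param out optional output path (`.png` or `.pdf`).
#' @param width,height device size in inches.
#' @return the leaf order used, invisibly.
#' @export
render_ihplot <- function(clust, out = NULL, width = 8, height = 6) {
  if (!is.null(out)) {
    if (grepl("\\.png$", out)) grDevices::png(out, width = width, height = height,
                                              units = "in", res = 120)
    else grDevices::pdf(out, width = width, height = height)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  ord <- clust$leaf_order
  n <- length(ord)
  op <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(op), add = TRUE)
  graphics::layout(matrix(c(1, 2, 3, 4), nrow = 1),
                   widths = c(1.2, 0.25, 1.4, 1.4))
  graphics::par(mar = c(2, 0.5, 2, 0))
  graphics::plot(as.dendrogram(clust$hclust), horiz = TRUE, leaflab = "none",
                 main = "dendrogram")
  # orientation + population bars
  ocol <- c(O1 = "#1f78b4", O2 = "#e31a1c", unknown = "grey70")
  pcol <- grDevices::rainbow(length(unique(clust$population)))
  names(pcol) <- unique(clust$population)
  graphics::par(mar = c(2, 0.1, 2, 0.1))
  graphics::image(t(matrix(seq_len(n))), col = NA, axes = FALSE, main = "")
  graphics::rect(0, (seq_len(n) - 1) / n, 0.5, seq_len(n) / n,
                 col = ocol[clust$orientation[ord]], border = NA)
  graphics::rect(0.5, (seq_len(n) - 1) / n, 1, seq_len(n) / n,
                 col = pcol[clust$population[ord]], border = NA)
  graphics::par(mar = c(2, 0.5, 2, 0.5))
  graphics::image(t(clust$alleles[ord, , drop = FALSE]),
                  col = c("#f0f0f0", "#252525"), axes = FALSE,
                  main = "alleles")
  graphics::image(clust$dist[ord, ord],
                  col = grDevices::hcl.colors(25, "YlOrRd", rev = TRUE),
                  axes = FALSE, main = "distance")
  invisible(ord)
}
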