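#' Neighbour-joining tree from a dissimilarity matrix
#'
#' Standard neighbour-joining agglomeration on the genome dissimilarity
#' matrix. Negative branch-length estimates, which NJ can produce on
#' non-additive data, are clamped to zero.
#'
#' @param D symmetric dissimilarity matrix with genome ids as dimnames (e.g.
#'   from [distance_matrix()]).
#' @return Unrooted `phylo` tree.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 4)
    stop("need at least 4 taxa for neighbour joining; ",
         "build the tree directly for fewer")
  tr <- ape::nj(D)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Delete-half jackknife resamples of an occurrence matrix
#'
#' Resamples units (matrix rows), not genomes: each sample keeps
#' `floor(fraction * U)` units drawn without replacement, preserving the
#' original row order.
#'
#' @param m `occurrence_matrix`.
#' @param n_samples number of jackknife samples.
#' @param fraction fraction of units kept per sample, in (0, 1).
#' @param seed integer seed; the sample sequence is reproducible.
#' @return List of `occurrence_matrix` objects.
#' @export
jackknife_samples <- function(m, n_samples = 100, fraction = 0.5, seed = 1) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  if (nrow(m) < 2) stop("need at least 2 units to resample")
  keep <- floor(fraction * nrow(m))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  lapply(seq_len(n_samples), function(i) {
    idx <- sort(sample.int(nrow(m), keep))
    occurrence_matrix(unclass(m)[idx, , drop = FALSE],
                      level = attr(m, "level"), genomes = attr(m, "genomes"))
  })
}

#' Majority-rule consensus of a tree ensemble
#'
#' Bipartitions appearing in more than half the trees are always retained;
#' with `extended = TRUE` (the default) remaining bipartitions are added
#' greedily in order of decreasing frequency whenever compatible with the
#' splits already accepted (the extended majority rule of PHYLIP CONSENSE).
#'
#' @param trees list (or `multiPhylo`) of trees on the same leaf set.
#' @param extended add compatible minority splits greedily.
#' @return Unrooted consensus `phylo` with per-split support frequencies in
#'   `$node.label` (internal nodes).
#' @export
majority_rule_consensus <- function(trees, extended = TRUE) {
  trees <- .as_multiphylo(trees)
  labs <- sort(trees[[1]]$tip.label)
  for (tr in trees)
    if (!identical(sort(tr$tip.label), labs))
      stop("trees do not share a common leaf set")
  if (extended) phangorn::allCompat(trees)
  else ape::consensus(trees, p = 0.5)
}

#' Per-split support of a tree against an ensemble
#'
#' @param tree reference topology.
#' @param trees ensemble of trees on the same leaves.
#' @return Numeric vector, one frequency in `[0, 1]` per internal node of
#'   `tree` (unrooted split support).
#' @export
split_support <- function(tree, trees) {
  trees <- .as_multiphylo(trees)
  ape::prop.clades(tree, trees, rooted = FALSE) / length(trees)
}

.as_multiphylo <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!inherits(trees, "multiPhylo")) class(trees) <- "multiPhylo"
  if (length(trees) < 1) stop("empty tree ensemble")
  trees
}

#' Least-squares (Fitch-Margoliash) branch lengths on a fixed topology
#'
#' Fits branch lengths minimising \eqn{\sum_{i<j} w_{ij} (d_{ij} - p_{ij})^2}
#' where \eqn{p_{ij}} is the tree path length and \eqn{w_{ij} = 1/d_{ij}^2}
#' (the Fitch-Margoliash weighting). Pairs with \eqn{d_{ij} = 0} receive the
#' largest finite weight. Negative solutions are clamped to zero.
#'
#' @param topology `phylo` whose tips match the taxa of `D`. Fitted on the
#'   unrooted form (a degree-2 root makes its two edges unidentifiable from
#'   path lengths).
#' @param D symmetric distance matrix with matching dimnames.
#' @return `topology` with fitted `edge.length`.
#' @export
fit_branch_lengths_ls <- function(topology, D) {
  D <- as.matrix(D)
  if (!setequal(topology$tip.label, rownames(D)))
    stop("topology leaves and distance-matrix taxa differ")
  tr <- ape::unroot(topology)   # a degree-2 root has unidentifiable edges
  ntip <- ape::Ntip(tr)
  nedge <- nrow(tr$edge)
  root <- ntip + 1L
  parent <- integer(ntip + tr$Nnode); pedge <- integer(ntip + tr$Nnode)
  parent[tr$edge[, 2]] <- tr$edge[, 1]
  pedge[tr$edge[, 2]] <- seq_len(nedge)
  # per-tip incidence of edges on the path to the (arbitrary) root
  inc <- matrix(FALSE, ntip, nedge)
  for (i in seq_len(ntip)) {
    v <- i
    while (v != root) { inc[i, pedge[v]] <- TRUE; v <- parent[v] }
  }
  pairs <- utils::combn(ntip, 2)
  A <- (inc[pairs[1, ], , drop = FALSE] != inc[pairs[2, ], , drop = FALSE]) + 0
  d <- D[cbind(tr$tip.label[pairs[1, ]], tr$tip.label[pairs[2, ]])]
  w <- ifelse(d > 0, 1 / d^2, NA)
  if (all(is.na(w))) w[] <- 1 else w[is.na(w)] <- max(w, na.rm = TRUE)
  fit <- stats::lm.wfit(A, d, w)
  len <- fit$coefficients
  len[is.na(len) | len < 0] <- 0
  tr$edge.length <- unname(len)
  tr
}

#' Wagner-parsimony branch lengths on a fixed topology
#'
#' For each unit, treats presence/absence as an unweighted symmetric binary
#' character and computes, for every branch, the expected number of state
#' transitions on that branch averaged uniformly over \emph{all} most
#' parsimonious reconstructions, by exact dynamic-programming MPR counting.
#' Branch lengths are these expectations summed over units; their total
#' equals the parsimony score summed over units.
#'
#' @param topology `phylo`; leaves must match the genomes of `m`.
#' @param m `occurrence_matrix`.
#' @return `topology` with `edge.length` set to expected transition counts.
#' @export
parsimony_branch_lengths <- function(topology, m) {
  if (!setequal(topology$tip.label, colnames(m)))
    stop("topology leaves and occurrence-matrix genomes differ")
  tr <- topology
  el <- numeric(nrow(tr$edge))
  for (u in seq_len(nrow(m)))
    el <- el + .mpr_expected_transitions(tr, unclass(m)[u, tr$tip.label])
  tr$edge.length <- el
  tr
}

# Expected transitions per edge for one binary character, averaged uniformly
# over all most parsimonious reconstructions (Sankoff DP + outside counts).
.mpr_expected_transitions <- function(tr, profile) {
  ntip <- ape::Ntip(tr)
  nnode <- ntip + tr$Nnode
  kids <- .children_list(tr)
  po <- .postorder_nodes(tr)
  cost <- matrix(Inf, nnode, 2)     # min subtree cost given node state {0,1}
  nmpr <- matrix(0, nnode, 2)       # number of optimal subtree reconstructions
  for (i in seq_len(ntip)) {
    s <- profile[i] + 1L
    cost[i, s] <- 0; nmpr[i, s] <- 1
  }
  # child messages: m_u(s) = min_t cost(u,t) + 1{s!=t}; n_u(s) = sum of nmpr over argmin
  msg_cost <- vector("list", nnode); msg_n <- vector("list", nnode)
  for (v in po) {
    cv <- c(0, 0); nv <- c(1, 1)
    for (u in kids[[v]]) {
      mc <- numeric(2); mn <- numeric(2)
      for (s in 1:2) {
        tot <- cost[u, ] + as.numeric(c(s != 1, s != 2))
        mc[s] <- min(tot)
        mn[s] <- sum(nmpr[u, tot == mc[s]])
      }
      msg_cost[[u]] <- mc; msg_n[[u]] <- mn
      cv <- cv + mc; nv <- nv * mn
    }
    cost[v, ] <- cv; nmpr[v, ] <- nv
  }
  root <- ntip + 1L
  best <- min(cost[root, ])
  total <- sum(nmpr[root, cost[root, ] == best])
  if (total == 0) return(numeric(nrow(tr$edge)))
  # outside counts: number of full MPRs restricted outside subtree(v) with v = s
  outc <- matrix(0, nnode, 2)
  outc[root, ] <- ifelse(cost[root, ] == best, 1, 0)
  pre <- rev(po)
  for (v in pre) {
    for (u in kids[[v]]) {
      sibn <- rep(1, 2)
      for (w in kids[[v]]) if (w != u) sibn <- sibn * msg_n[[w]]
      for (s in 1:2) {
        if (outc[v, s] == 0) next
        for (t in 1:2) {
          if (cost[u, t] + (s != t) == msg_cost[[u]][s])
            outc[u, t] <- outc[u, t] + outc[v, s] * sibn[s]
        }
      }
    }
  }
  # expected transitions per edge = sum over discordant optimal (s,t) joints
  ex <- numeric(nrow(tr$edge))
  for (e in seq_len(nrow(tr$edge))) {
    v <- tr$edge[e, 1]; u <- tr$edge[e, 2]
    sibn <- rep(1, 2)
    for (w in kids[[v]]) if (w != u) sibn <- sibn * msg_n[[w]]
    cnt <- 0
    for (s in 1:2) {
      if (outc[v, s] == 0) next
      for (t in 1:2) {
        if (s != t && cost[u, t] + 1 == msg_cost[[u]][s])
          cnt <- cnt + outc[v, s] * sibn[s] * nmpr[u, t]
      }
    }
    ex[e] <- cnt / total
  }
  ex
}

.children_list <- function(tr) {
  nnode <- ape::Ntip(tr) + tr$Nnode
  kids <- vector("list", nnode)
  for (e in seq_len(nrow(tr$edge)))
    kids[[tr$edge[e, 1]]] <- c(kids[[tr$edge[e, 1]]], tr$edge[e, 2])
  kids
}

# internal nodes in postorder (children before parents)
.postorder_nodes <- function(tr) {
  po <- ape::reorder.phylo(tr, "postorder")$edge[, 1]
  unique(po)
}
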