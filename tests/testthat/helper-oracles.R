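# Independent oracles used across the suite. These deliberately avoid the
# package's dynamic programmes: exhaustive enumeration over internal-state
# assignments, direct per-pair tallies, and closed forms.

# exhaustive gain/loss parsimony: enumerate all internal state assignments,
# score S = L + g*G with an absent ancestor above the root, optionally cap
# the number of gains inside `euk` nodes
brute_gainloss <- function(tree, profile, g, euk = NULL, cap = Inf) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  ages <- node_ages(tree)
  par <- integer(nn); par[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ntip + 1L
  internal <- (ntip + 1L):nn
  k <- length(internal)
  grid <- as.matrix(expand.grid(rep(list(0:1), k)))
  S <- matrix(0L, nrow(grid), nn)
  S[, internal] <- grid
  S[, 1:ntip] <- matrix(profile, nrow(grid), ntip, byrow = TRUE)
  cost <- g * S[, root]
  gain_age <- ifelse(S[, root] == 1, ages[root], -Inf)
  n_euk_gains <- if (is.null(euk)) rep(0L, nrow(grid)) else
    integer(nrow(grid))
  for (v in seq_len(nn)) {
    if (v == root) next
    p <- par[v]
    up <- S[, p] == 0 & S[, v] == 1
    dn <- S[, p] == 1 & S[, v] == 0
    cost <- cost + g * up + dn
    gain_age <- pmax(gain_age, ifelse(up, ages[v], -Inf))
    if (!is.null(euk) && euk[v]) n_euk_gains <- n_euk_gains + up
  }
  keep <- n_euk_gains <= cap
  cost <- cost[keep]; gain_age <- gain_age[keep]
  best <- min(cost)
  opt <- abs(cost - best) < 1e-9
  list(cost = best, maxage = max(gain_age[opt]), minage = min(gain_age[opt]))
}

# expected per-edge transitions of one binary character averaged over all
# most parsimonious reconstructions, by enumeration
brute_wagner <- function(tree, profile) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  internal <- (ntip + 1L):nn
  grid <- as.matrix(expand.grid(rep(list(0:1), length(internal))))
  best <- Inf; acc <- NULL; cnt <- 0
  for (r in seq_len(nrow(grid))) {
    st <- integer(nn); st[internal] <- grid[r, ]; st[1:ntip] <- profile
    ch <- as.numeric(st[tree$edge[, 1]] != st[tree$edge[, 2]])
    cost <- sum(ch)
    if (cost < best - 1e-12) { best <- cost; acc <- ch; cnt <- 1 }
    else if (cost < best + 1e-12) { acc <- acc + ch; cnt <- cnt + 1 }
  }
  acc / cnt
}

# eukaryote indicator vector for a trifurcation-rooted tree
euk_indicator <- function(tree) {
  sk <- attr(tree, "superkingdoms")
  ntip <- ape::Ntip(tree)
  euk <- rep(FALSE, ntip + tree$Nnode)
  root_kids <- tree$edge[tree$edge[, 1] == ntip + 1L, 2]
  for (k in root_kids) {
    tips <- if (k <= ntip) k else {
      d <- foldage:::.descendants(tree, k); d[d <= ntip]
    }
    if (all(sk[tree$tip.label[tips]] == "Eukarya"))
      euk[c(k, if (k > ntip) foldage:::.descendants(tree, k))] <- TRUE
  }
  euk
}

random_profile <- function(ntip, p = 0.5) {
  prof <- stats::rbinom(ntip, 1, p)
  if (!any(prof == 1)) prof[sample.int(ntip, 1)] <- 1L
  prof
}

# worked greek key / jelly roll sheet topologies
greek_key_fixture <- function(mirror = FALSE, parallel_pair = FALSE) {
  pos <- if (mirror) c(4L, 1L, 2L, 3L) else c(1L, 4L, 3L, 2L)
  ori <- rep("antiparallel", 3)
  if (parallel_pair) ori[2] <- "parallel"
  s <- data.frame(sheet_id = "A", strand_id = paste0("s", 1:4),
                  sequence_order = 1:4, spatial_position = pos,
                  stringsAsFactors = FALSE)
  ord <- order(s$spatial_position)
  list(strands = s,
       pairings = data.frame(sheet_id = "A",
                             strand_a = s$strand_id[ord][-4],
                             strand_b = s$strand_id[ord][-1],
                             orientation = ori, stringsAsFactors = FALSE))
}

jelly_roll_fixture <- function(parallel_wrap = FALSE) {
  s <- data.frame(sheet_id = "A", strand_id = paste0("s", 1:6),
                  sequence_order = 1:6,
                  spatial_position = c(1L, 2L, 5L, 4L, 3L, 6L),
                  stringsAsFactors = FALSE)
  ord <- order(s$spatial_position)
  ori <- rep("antiparallel", 5)
  if (parallel_wrap) ori[c(1, 5)] <- "parallel"
  list(strands = s,
       pairings = data.frame(sheet_id = "A",
                             strand_a = s$strand_id[ord][-6],
                             strand_b = s$strand_id[ord][-1],
                             orientation = ori, stringsAsFactors = FALSE))
}

random_rotation_matrix <- function() {
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
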