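#' Random three-superkingdom species tree
#'
#' Generates a rooted species tree with Archaea, Bacteria and Eukarya as
#' three clades under a trifurcating root (the last universal common
#' ancestor), random clade topologies and exponential branch lengths, then
#' normalizes node heights so the root has age 1 and the leaves age 0.
#'
#' @param n_leaves named integer vector: leaves per superkingdom.
#' @param seed integer seed.
#' @param rate rate of the exponential branch-length distribution.
#' @return Height-normalized `phylo` with attribute `superkingdoms` (named
#'   leaf -> superkingdom vector).
#' @export
random_tree <- function(n_leaves = c(Archaea = 4, Bacteria = 4, Eukarya = 4),
                        seed = 1, rate = 1) {
  stopifnot(all(c("Archaea", "Bacteria", "Eukarya") %in% names(n_leaves)),
            sum(n_leaves) >= 4)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  prefix <- c(Archaea = "arc", Bacteria = "bac", Eukarya = "euk")
  clade_nwk <- function(sk) {
    n <- n_leaves[[sk]]
    labs <- sprintf("%s_%02d", prefix[[sk]], seq_len(n))
    if (n == 1) return(sprintf("%s:%.6f", labs, stats::rexp(1, rate)))
    tr <- ape::rtree(n, tip.label = labs,
                     br = function(k) stats::rexp(k, rate))
    sub <- sub(";$", "", ape::write.tree(tr))
    sprintf("%s:%.6f", sub, stats::rexp(1, rate))
  }
  nwk <- sprintf("(%s,%s,%s);", clade_nwk("Archaea"), clade_nwk("Bacteria"),
                 clade_nwk("Eukarya"))
  tree <- ape::read.tree(text = nwk)
  tree <- normalize_heights(tree)
  sk <- sub("_.*", "", tree$tip.label)
  sk <- c(arc = "Archaea", bac = "Bacteria", euk = "Eukarya")[sk]
  names(sk) <- tree$tip.label
  attr(tree, "superkingdoms") <- sk
  tree
}

#' Simulate occurrence profiles with known birth nodes
#'
#' Each unit is born at a node of the tree and inherited by every descendant;
#' each branch below the birth node loses the unit with probability
#' `loss_rate` (loss is absorbing — no regain except by explicit lateral
#' transfer); each branch outside the present clade acquires it laterally
#' with probability `hgt_rate`; finally each leaf state flips with
#' probability `fp_rate` (0 to 1) or `fn_rate` (1 to 0), emulating annotation
#' noise. Units ending all-absent are re-drawn (their age would be
#' undefined); the re-draw count is reported.
#'
#' @param tree height-normalized tree from [random_tree()].
#' @param n_units number of units to simulate.
#' @param birth_node_distribution `"uniform_nodes"` (every node equally
#'   likely) or `"branch_length_weighted"` (probability proportional to the
#'   parent branch length; the root gets the mean branch length as weight).
#' @param loss_rate,hgt_rate per-branch event probabilities in `[0, 1)`.
#' @param fp_rate,fn_rate per-leaf annotation flip probabilities in `[0, 1)`.
#' @param seed integer seed.
#' @return List: `matrix` (`occurrence_matrix`, units x genomes), `truth`
#'   (data.frame unit_id, birth_node, true_age, n_losses, n_hgt, n_flipped),
#'   `events` (per-unit lists of loss/hgt branches and flipped leaves),
#'   `redraws`.
#' @export
simulate_profiles <- function(tree, n_units = 500,
                              birth_node_distribution = c(
                                "uniform_nodes", "branch_length_weighted"),
                              loss_rate = 0, hgt_rate = 0,
                              fp_rate = 0, fn_rate = 0, seed = 1) {
  birth_node_distribution <- match.arg(birth_node_distribution)
  for (r in c(loss_rate, hgt_rate, fp_rate, fn_rate))
    if (r < 0 || r >= 1) stop("rates must lie in [0, 1)")
  ages <- node_ages(tree)
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  kids <- .children_list(tree)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  w <- rep(1, nnode)
  if (birth_node_distribution == "branch_length_weighted") {
    w <- numeric(nnode)
    w[tree$edge[, 2]] <- tree$edge.length
    w[root] <- mean(tree$edge.length)
  }
  desc_cache <- lapply(seq_len(nnode), function(v)
    if (v <= ntip) integer(0) else .descendants(tree, v))
  below <- function(v) if (v <= ntip) v else
    desc_cache[[v]][desc_cache[[v]] <= ntip]

  prof <- matrix(0L, n_units, ntip,
                 dimnames = list(sprintf("sf%04d", seq_len(n_units)),
                                 tree$tip.label))
  truth <- data.frame(unit_id = rownames(prof), birth_node = NA_integer_,
                      true_age = NA_real_, n_losses = 0L, n_hgt = 0L,
                      n_flipped = 0L, stringsAsFactors = FALSE)
  events <- vector("list", n_units)
  redraws <- 0L
  for (u in seq_len(n_units)) {
    repeat {
      b <- sample.int(nnode, 1, prob = w)
      losses <- integer(0); hgts <- integer(0)
      present <- logical(ntip)
      # vertical descent with absorbing branch loss
      spread <- function(v) {
        if (v <= ntip) { present[v] <<- TRUE; return(invisible()) }
        for (ch in kids[[v]]) {
          if (stats::runif(1) < loss_rate) losses <<- c(losses, ch)
          else spread(ch)
        }
      }
      spread(b)
      # lateral transfer on branches outside the birth clade
      clade <- c(b, desc_cache[[b]])
      outside <- setdiff(seq_len(nnode)[-root], clade)
      for (v in outside) if (stats::runif(1) < hgt_rate) {
        hgts <- c(hgts, v)
        present[below(v)] <- TRUE
      }
      # annotation noise
      flip_up <- which(!present & stats::runif(ntip) < fp_rate)
      flip_dn <- which(present & stats::runif(ntip) < fn_rate)
      present[flip_up] <- TRUE
      present[flip_dn] <- FALSE
      if (any(present)) break
      redraws <- redraws + 1L
    }
    prof[u, ] <- as.integer(present)
    truth$birth_node[u] <- b
    truth$true_age[u] <- ages[b]
    truth$n_losses[u] <- length(losses)
    truth$n_hgt[u] <- length(hgts)
    truth$n_flipped[u] <- length(flip_up) + length(flip_dn)
    events[[u]] <- list(loss_branches = losses, hgt_branches = hgts,
                        flipped_leaves = tree$tip.label[c(flip_up, flip_dn)])
  }
  sk <- attr(tree, "superkingdoms")
  genomes <- if (!is.null(sk))
    genome_table(tree$tip.label, unname(sk[tree$tip.label])) else NULL
  list(matrix = occurrence_matrix(prof, level = "superfamily",
                                  genomes = genomes),
       truth = truth, events = events, redraws = redraws)
}

#' Synthetic GO-style annotations with planted enrichment
#'
#' Annotates superfamilies with terms by independent Bernoulli draws: a term
#' planted on a group is assigned with probability `rate_in` inside the group
#' and `rate_out` elsewhere.
#'
#' @param superfamilies character vector of superfamily ids.
#' @param groups named character vector superfamily -> group.
#' @param planted data.frame with columns `term`, `group`, `rate_in`,
#'   `rate_out`.
#' @param seed integer seed.
#' @return data.frame (superfamily_id, term_id).
#' @export
synthetic_go <- function(superfamilies, groups, planted, seed = 1) {
  stopifnot(all(c("term", "group", "rate_in", "rate_out") %in% names(planted)))
  if (any(planted$rate_in < 0 | planted$rate_in > 1 |
            planted$rate_out < 0 | planted$rate_out > 1))
    stop("rates must lie in [0, 1]")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(planted))) {
    pr <- ifelse(!is.na(groups[superfamilies]) &
                   groups[superfamilies] == planted$group[i],
                 planted$rate_in[i], planted$rate_out[i])
    hit <- stats::runif(length(superfamilies)) < pr
    if (any(hit))
      rows[[length(rows) + 1L]] <-
        data.frame(superfamily_id = superfamilies[hit],
                   term_id = planted$term[i], stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(superfamily_id = character(0), term_id = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
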