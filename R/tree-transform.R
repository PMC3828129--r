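#' Root a species tree
#'
#' Two rooting modes. `"trifurcation"` places the root at the internal node
#' joining the three superkingdom clades (Archaea, Bacteria, Eukarya), so the
#' root has exactly three children; it requires every superkingdom to be
#' monophyletic in the unrooted tree. `"outgroup"` roots on the pendant edge
#' of a named leaf.
#'
#' @param tree unrooted `phylo`.
#' @param mode `"trifurcation"` or `"outgroup"`.
#' @param superkingdoms named character vector leaf -> superkingdom
#'   (required for trifurcation mode).
#' @param outgroup_id leaf label (required for outgroup mode).
#' @return Rooted `phylo` (trifurcating root in trifurcation mode).
#' @export
root_tree <- function(tree, mode = c("trifurcation", "outgroup"),
                      superkingdoms = NULL, outgroup_id = NULL) {
  mode <- match.arg(mode)
  if (ape::Ntip(tree) > 2) tree <- ape::unroot(tree)
  if (mode == "outgroup") {
    if (is.null(outgroup_id) || !outgroup_id %in% tree$tip.label)
      stop("outgroup_id must name a leaf of the tree")
    return(ape::root(tree, outgroup = outgroup_id, resolve.root = TRUE))
  }
  if (is.null(superkingdoms)) stop("trifurcation mode needs superkingdom metadata")
  sk <- superkingdoms[tree$tip.label]
  if (anyNA(sk)) stop("leaves without superkingdom: ",
                      paste(tree$tip.label[is.na(sk)], collapse = ", "))
  groups <- split(tree$tip.label, sk)
  if (length(groups) != 3)
    stop("trifurcation rooting needs all three superkingdoms present")
  bad <- names(groups)[!vapply(groups, function(g) .has_split(tree, g), TRUE)]
  if (length(bad))
    stop("superkingdom(s) not monophyletic: ",
         paste(sprintf("%s {%s}", bad,
                       vapply(groups[bad], paste, "", collapse = ",")),
               collapse = "; "))
  center <- .trifurcation_node(tree, groups)
  root <- ape::Ntip(tree) + 1L
  rooted <- if (center == root) tree else
    ape::root(tree, node = center, resolve.root = FALSE)
  root <- ape::Ntip(rooted) + 1L
  kids <- .children_list(rooted)[[root]]
  clades <- lapply(kids, function(k) .tips_below(rooted, k))
  ok <- length(kids) == 3 &&
    setequal(vapply(lapply(clades, sort), paste, "", collapse = "|"),
             vapply(lapply(groups, sort), paste, "", collapse = "|"))
  if (!ok)
    stop("could not locate the superkingdom trifurcation node")
  rooted
}

# node where the three superkingdom subtrees meet: for each group the
# separating edge's endpoint on the far side from the group
.trifurcation_node <- function(tree, groups) {
  n <- ape::Ntip(tree)
  idx <- lapply(groups, match, table = tree$tip.label)
  parent <- integer(n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  cand <- integer(0)
  for (g in idx) {
    found <- NA_integer_
    for (v in seq_len(n + tree$Nnode)) {
      if (v == n + 1L) next
      below <- .tips_below_idx(tree, v)
      if (setequal(below, g)) { found <- parent[v]; break }
      if (setequal(setdiff(seq_len(n), below), g)) { found <- v; break }
    }
    if (is.na(found))
      stop("could not locate the superkingdom trifurcation node")
    cand <- c(cand, found)
  }
  if (length(unique(cand)) != 1L)
    stop("could not locate the superkingdom trifurcation node")
  cand[1]
}

# does the unrooted tree contain a split separating `tips` from the rest?
.has_split <- function(tree, tips) {
  n <- ape::Ntip(tree)
  if (length(tips) %in% c(1L, n - 1L, n)) return(TRUE)
  idx <- match(tips, tree$tip.label)
  all_tips <- seq_len(n)
  for (v in (n + 1L):(n + tree$Nnode)) {
    below <- .tips_below_idx(tree, v)
    if (setequal(below, idx) || setequal(setdiff(all_tips, below), idx))
      return(TRUE)
  }
  FALSE
}

.tips_below_idx <- function(tree, node) {
  n <- ape::Ntip(tree)
  if (node <= n) return(node)
  kids <- .children_list(tree)
  out <- integer(0); stack <- node
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (v <= n) out <- c(out, v) else stack <- c(stack, kids[[v]])
  }
  out
}

.tips_below <- function(tree, node) tree$tip.label[.tips_below_idx(tree, node)]

#' Normalized node ages on a rooted tree
#'
#' The age of a node is its maximum path length to any descendant leaf,
#' divided by the tree height (the maximum root-to-leaf path length). Every
#' leaf therefore has age exactly 0 and the root exactly 1, also on
#' non-ultrametric trees; ages decrease from root to leaves along every path.
#'
#' @param tree rooted `phylo` with non-negative branch lengths.
#' @return `tree` with a `node.age` component: numeric vector indexed by node
#'   id (tips `1..Ntip`, then internal nodes).
#' @export
normalize_heights <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  h <- numeric(nnode)               # max distance to a descendant leaf
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    v <- po$edge[e, 1]; u <- po$edge[e, 2]
    h[v] <- max(h[v], h[u] + po$edge.length[e])
  }
  root <- ntip + 1L
  if (h[root] == 0) {
    warning("all branch lengths zero; internal ages set to 1")
    age <- c(rep(0, ntip), rep(1, tree$Nnode))
  } else {
    age <- h / h[root]
    age[seq_len(ntip)] <- 0
    age[root] <- 1
  }
  tree$node.age <- age
  tree
}

#' Node ages of a height-normalized tree
#'
#' @param tree `phylo` processed by [normalize_heights()].
#' @return Numeric vector of ages indexed by node id.
#' @export
node_ages <- function(tree) {
  if (is.null(tree$node.age))
    stop("tree has no node ages; run normalize_heights() first")
  tree$node.age
}
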