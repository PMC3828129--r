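#' Maximum-parsimony gain/loss scenario for one occurrence profile
#'
#' Finds the minimum-cost scenario of gain and loss events on the tree
#' explaining the presence/absence profile at the leaves, with score
#' `S = L + g * G` (`L` losses, `G` gains, `g` the gain weight), by a
#' Sankoff-style dynamic programme over states \{absent, present\}. The
#' hypothetical ancestor above the root is absent, so a present root incurs
#' one gain at the root. Among co-optimal scenarios, the one maximising the
#' age of the earliest (oldest) gain is returned by default; set
#' `tie_break = "youngest"` to minimise it instead and so measure the
#' sensitivity of the dating to this choice.
#'
#' @param tree rooted `phylo` with node ages (see [normalize_heights()]).
#' @param profile 0/1 vector over leaves, named by tip label (unnamed vectors
#'   are taken in `tree$tip.label` order). At least one presence.
#' @param g positive gain weight (cost of a gain relative to a loss).
#' @param tie_break `"oldest"` or `"youngest"`: which co-optimal scenario to
#'   report.
#' @return An `age_scenario` list: `gains` and `losses` (node ids), `cost`,
#'   `age` (normalized age of the earliest gain), `earliest_gain_node`,
#'   `model`, `g`.
#' @export
mp_scenario <- function(tree, profile, g = 1,
                        tie_break = c("oldest", "youngest")) {
  .gainloss_scenario(tree, profile, g, match.arg(tie_break),
                     euk_nodes = NULL, model = "mp")
}

#' Fusion-parsimony scenario: at most one gain on the Eukaryotic subtree
#'
#' Maximum parsimony constrained so that at most one gain event occurs inside
#' the Eukaryotic clade (Dollo behaviour there); gains at the root and in the
#' Bacterial/Archaeal subtrees are unconstrained. Implemented by a
#' state-augmented dynamic programme tracking the Eukaryotic gain budget.
#'
#' @inheritParams mp_scenario
#' @param superkingdoms named character vector leaf -> superkingdom, used to
#'   locate the Eukaryotic child clade of the root.
#' @return An `age_scenario` (see [mp_scenario()]).
#' @export
fusion_scenario <- function(tree, profile, g = 1, superkingdoms,
                            tie_break = c("oldest", "youngest")) {
  if (missing(superkingdoms) || is.null(superkingdoms))
    stop("fusion parsimony needs superkingdom annotation of the leaves")
  sk <- superkingdoms[tree$tip.label]
  if (anyNA(sk)) stop("leaves without superkingdom annotation")
  root <- ape::Ntip(tree) + 1L
  kids <- .children_list(tree)[[root]]
  euk_root <- NULL
  for (k in kids)
    if (all(sk[match(.tips_below(tree, k), tree$tip.label)] == "Eukarya"))
      euk_root <- k
  if (is.null(euk_root))
    stop("no purely Eukaryotic child clade of the root; ",
         "root the tree at the superkingdom trifurcation first")
  euk <- rep(FALSE, ape::Ntip(tree) + tree$Nnode)
  euk[c(euk_root, .descendants(tree, euk_root))] <- TRUE
  .gainloss_scenario(tree, profile, g, match.arg(tie_break),
                     euk_nodes = euk, model = "fusion")
}

#' Dollo-parsimony age of an occurrence profile
#'
#' A single gain is placed at the most recent common ancestor of all present
#' leaves; losses are the minimal set of maximal absent subtrees below it.
#'
#' @inheritParams mp_scenario
#' @return An `age_scenario` with a singleton `gains` set; `cost` is
#'   `|losses| + g`.
#' @export
dollo_age <- function(tree, profile, g = 1) {
  tree <- .ensure_ages(tree)
  p <- .check_profile(tree, profile)
  present <- which(p == 1L)
  mrca <- if (length(present) == 1L) present else
    ape::getMRCA(tree, tree$tip.label[present])
  kids <- .children_list(tree)
  ntip <- ape::Ntip(tree)
  has_present <- logical(ntip + tree$Nnode)
  has_present[present] <- TRUE
  for (v in .postorder_nodes(tree))
    has_present[v] <- any(has_present[kids[[v]]])
  # maximal absent subtrees strictly below the MRCA
  losses <- integer(0)
  if (mrca > ntip) {
    stack <- kids[[mrca]]
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (!has_present[v]) losses <- c(losses, v)
      else if (v > ntip) stack <- c(stack, kids[[v]])
    }
  }
  ages <- node_ages(tree)
  structure(list(model = "dollo", g = g,
                 gains = unname(mrca), losses = sort(losses),
                 cost = length(losses) + g,
                 age = unname(ages[mrca]), earliest_gain_node = unname(mrca)),
            class = "age_scenario")
}

#' Age of a gain/loss scenario
#'
#' The normalized age of the earliest event: the maximum node age over the
#' scenario's gain nodes.
#'
#' @param scenario an `age_scenario`.
#' @param tree the height-normalized tree the scenario was computed on.
#' @return Age in `[0, 1]`.
#' @export
age_from_scenario <- function(scenario, tree) {
  if (!length(scenario$gains)) stop("scenario has no gain events")
  max(node_ages(tree)[scenario$gains])
}

#' Assign age-group labels
#'
#' Ancient superfamilies have age exactly 1 (within `tol`); new-born ones
#' have age at or below the cutoff; everything else is middle-aged. With
#' `auto_cutoff = TRUE` the cutoff is chosen to make the new-born and ancient
#' groups as close in size as possible, the criterion used to pick the
#' published cutoff.
#'
#' @param ages named numeric vector of ages in `[0, 1]`.
#' @param cutoff new-born age cutoff, in (0, 1).
#' @param auto_cutoff choose the cutoff equalizing group sizes instead.
#' @param tol absolute tolerance for the ancient (age = 1) test.
#' @return data.frame with `unit_id`, `age`, `group` and attribute `cutoff`.
#' @export
assign_age_groups <- function(ages, cutoff = 0.1, auto_cutoff = FALSE,
                              tol = 1e-9) {
  if (any(ages < -tol | ages > 1 + tol)) stop("ages must lie in [0, 1]")
  ancient <- abs(ages - 1) <= tol
  if (auto_cutoff) {
    cand <- sort(unique(ages[!ancient]))
    cand <- cand[cand < 1]
    if (!length(cand)) cand <- 0.5
    n_new <- vapply(cand, function(cv) sum(ages[!ancient] <= cv + tol), 0L)
    best <- cand[which.min(abs(n_new - sum(ancient)))]
    if (best <= 0) {
      nxt <- cand[cand > 0]
      best <- if (length(nxt)) min(nxt) / 2 else 0.5
    }
    cutoff <- best
  }
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must be in (0, 1)")
  group <- ifelse(ancient, "ancient",
                  ifelse(ages <= cutoff + tol, "newborn", "middle"))
  out <- data.frame(unit_id = if (is.null(names(ages)))
    as.character(seq_along(ages)) else names(ages),
    age = unname(ages), group = group, stringsAsFactors = FALSE)
  attr(out, "cutoff") <- cutoff
  out
}

#' Age estimates across a range of gain weights
#'
#' Recomputes maximum-parsimony ages for every unit at each gain weight and
#' reports the Spearman rank correlation between every pair of weights, the
#' robustness summary used to show that dating is stable under up to
#' ten-fold gain/loss asymmetry.
#'
#' @param tree height-normalized rooted `phylo`.
#' @param m `occurrence_matrix` over the tree's leaves.
#' @param g_values positive gain weights to sweep.
#' @param tie_break passed to [mp_scenario()].
#' @return List with `ages` (units x weights matrix) and `spearman`
#'   (weights x weights correlation matrix).
#' @export
gain_weight_sweep <- function(tree, m,
                              g_values = c(0.1, 0.2, 0.5, 1, 2, 5, 10),
                              tie_break = "oldest") {
  if (any(g_values <= 0)) stop("gain weights must be positive")
  tree <- .ensure_ages(tree)
  ages <- matrix(NA_real_, nrow(m), length(g_values),
                 dimnames = list(rownames(m), as.character(g_values)))
  for (u in seq_len(nrow(m))) {
    prof <- unclass(m)[u, ]
    if (!any(prof == 1)) next
    for (j in seq_along(g_values))
      ages[u, j] <- mp_scenario(tree, prof, g = g_values[j],
                                tie_break = tie_break)$age
  }
  keep <- stats::complete.cases(ages)
  list(ages = ages,
       spearman = stats::cor(ages[keep, , drop = FALSE], method = "spearman"))
}

#' @export
print.age_scenario <- function(x, ...) {
  cat(sprintf("%s parsimony scenario (g = %g): cost %.3g, age %.4f\n",
              x$model, x$g, x$cost, x$age))
  cat(sprintf("  gains at nodes {%s}; losses at nodes {%s}\n",
              paste(x$gains, collapse = ","),
              paste(x$losses, collapse = ",")))
  invisible(x)
}

# ---- internal gain/loss DP ------------------------------------------------

.ensure_ages <- function(tree) {
  if (is.null(tree$node.age)) tree <- normalize_heights(tree) else tree
}

.check_profile <- function(tree, profile) {
  if (!is.null(names(profile))) {
    if (!setequal(names(profile), tree$tip.label))
      stop("profile names do not match the tree's leaves")
    profile <- profile[tree$tip.label]
  } else if (length(profile) != ape::Ntip(tree))
    stop("profile length does not match the number of leaves")
  p <- as.integer(profile)
  if (!all(p %in% 0:1)) stop("profile must be binary")
  if (!any(p == 1L)) stop("unit unobserved; age undefined")
  p
}

.descendants <- function(tree, node) {
  kids <- .children_list(tree)
  out <- integer(0); stack <- kids[[node]]
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    out <- c(out, v)
    if (v > ape::Ntip(tree)) stack <- c(stack, kids[[v]])
  }
  out
}

# Sankoff DP over states {1 = absent, 2 = present}, optional Eukaryotic gain
# budget (at-most-one), lexicographic (cost, earliest-gain age) optimisation.
.gainloss_scenario <- function(tree, profile, g, tie_break, euk_nodes, model) {
  tree <- .ensure_ages(tree)
  p <- .check_profile(tree, profile)
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  ages <- node_ages(tree)
  kids <- .children_list(tree)
  kmax <- if (is.null(euk_nodes)) 0L else 1L
  euk <- if (is.null(euk_nodes)) rep(FALSE, nnode) else euk_nodes
  tc <- matrix(c(0, 1, g, 0), 2, 2)   # tc[s, t]: cost of s -> t on an edge
  # tie value = the subtree's (optimised) earliest-gain age, -Inf if no gain;
  # the scenario age is a max over subtrees, so values combine by max and the
  # tie-break only chooses among co-optimal options per child
  better <- if (tie_break == "oldest") function(a, b) a > b else
    function(a, b) a < b

  cost <- array(Inf, c(nnode, 2, kmax + 1))
  tval <- array(-Inf, c(nnode, 2, kmax + 1))
  for (i in seq_len(ntip)) cost[i, p[i] + 1L, ] <- 0

  # best transition into child w given parent state s and budget k2
  opt_child <- function(w, s, k2) {
    best <- list(cost = Inf, tval = -Inf, t = NA, ksub = NA)
    for (t in 1:2) {
      gainflag <- as.integer(s == 1L && t == 2L && euk[w])
      ksub <- k2 - gainflag
      if (ksub < 0) next
      cc <- tc[s, t] + cost[w, t, ksub + 1]
      if (!is.finite(cc)) next
      tv <- tval[w, t, ksub + 1]
      if (s == 1L && t == 2L) tv <- max(tv, ages[w])
      if (cc < best$cost - 1e-12 ||
          (cc < best$cost + 1e-12 &&
           (!is.finite(best$cost) || better(tv, best$tval)))) {
        best <- list(cost = cc, tval = tv, t = t, ksub = ksub)
      }
    }
    best
  }

  # combine children of node v in state s under budget k: all children at
  # budget 0, or (k = 1) exactly one child at budget 1
  combine <- function(v, s, k) {
    ch <- kids[[v]]
    o0 <- lapply(ch, opt_child, s = s, k2 = 0L)
    c0 <- vapply(o0, `[[`, 0, "cost")
    base_cost <- sum(c0)
    base_tval <- if (length(ch)) max(vapply(o0, `[[`, 0, "tval")) else -Inf
    best <- list(cost = base_cost, tval = base_tval, alloc = rep(0L, length(ch)))
    if (k >= 1L) {
      for (j in seq_along(ch)) {
        o1 <- opt_child(ch[j], s, 1L)
        cc <- sum(c0[-j]) + o1$cost
        if (!is.finite(cc)) next
        others <- vapply(o0[-j], `[[`, 0, "tval")
        tv <- max(c(o1$tval, others, -Inf))
        if (cc < best$cost - 1e-12 ||
            (cc < best$cost + 1e-12 && better(tv, best$tval))) {
          alloc <- rep(0L, length(ch)); alloc[j] <- 1L
          best <- list(cost = cc, tval = tv, alloc = alloc)
        }
      }
    }
    best
  }

  for (v in .postorder_nodes(tree)) {
    for (s in 1:2) for (k in 0:kmax) {
      cb <- combine(v, s, k)
      cost[v, s, k + 1] <- cb$cost
      tval[v, s, k + 1] <- cb$tval
    }
  }

  root <- ntip + 1L
  top <- opt_child(root, 1L, kmax)      # ancestor above the root is absent
  if (!is.finite(top$cost)) stop("no feasible scenario")   # cannot happen

  gains <- integer(0); losses <- integer(0)
  assign_node <- function(v, s_parent, t, k2) {
    if (s_parent == 1L && t == 2L) gains <<- c(gains, v)
    if (s_parent == 2L && t == 1L) losses <<- c(losses, v)
    if (v <= ntip) return(invisible())
    gainflag <- as.integer(s_parent == 1L && t == 2L && euk[v])
    cb <- combine(v, t, k2 - gainflag)
    ch <- kids[[v]]
    for (j in seq_along(ch)) {
      o <- opt_child(ch[j], t, cb$alloc[j])
      assign_node(ch[j], t, o$t, cb$alloc[j])
    }
    invisible()
  }
  assign_node(root, 1L, top$t, kmax)

  gains <- sort(gains); losses <- sort(losses)
  age <- max(ages[gains])
  structure(list(model = model, g = g, gains = gains, losses = losses,
                 cost = top$cost, age = age,
                 earliest_gain_node = gains[which.max(ages[gains])],
                 tie_break = tie_break),
            class = "age_scenario")
}
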