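test_that("neighbour joining recovers additive topologies and clamps lengths", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(5:12, 1)
    tr <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    est <- neighbor_joining(ape::cophenetic.phylo(tr))
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(est))), 0)
    expect_true(all(est$edge.length >= 0))
  }
  D3 <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(D3) <- 0
  expect_error(neighbor_joining(D3), "at least 4 taxa")

  # four-point structure: AB|CD split recovered
  tr4 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  est4 <- neighbor_joining(ape::cophenetic.phylo(tr4))
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr4), ape::unroot(est4))), 0)
})

test_that("jackknife resampling halves the units reproducibly", {
  set.seed(12)
  m <- occurrence_matrix(matrix(rbinom(1000, 1, 0.5), 100, 10,
                                dimnames = list(sprintf("u%03d", 1:100),
                                                paste0("g", 1:10))))
  s1 <- jackknife_samples(m, n_samples = 100, seed = 42)
  expect_length(s1, 100)
  expect_true(all(vapply(s1, nrow, 0L) == 50))
  s2 <- jackknife_samples(m, n_samples = 100, seed = 42)
  expect_identical(lapply(s1, rownames), lapply(s2, rownames))
  expect_error(jackknife_samples(m, fraction = 1.2), "fraction")

  # each unit appears in about half the samples (binomial bounds)
  counts <- table(unlist(lapply(s1, rownames)))
  expect_true(all(counts >= qbinom(1e-6, 100, 0.5) &
                    counts <= qbinom(1e-6, 100, 0.5, lower.tail = FALSE)))
})

test_that("extended majority-rule consensus keeps majority and compatible splits", {
  set.seed(13)
  base <- ape::rtree(6)
  ten <- rep(list(base), 10)
  cons <- majority_rule_consensus(ten)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(base), ape::unroot(cons))), 0)
  expect_true(all(split_support(cons, ten) == 1, na.rm = TRUE))

  # majority split survives a minority alternative
  t1 <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  t2 <- ape::read.tree(text = "((A,C),(B,(D,E)));")
  cons2 <- majority_rule_consensus(c(t1, t1, t2))
  part <- ape::prop.part(cons2)
  labs <- attr(part, "labels")
  splits <- lapply(part, function(p) sort(labs[p]))
  expect_true(any(vapply(splits, identical, TRUE, c("A", "B"))) ||
                any(vapply(splits, identical, TRUE, c("C", "D", "E"))))

  # random ensembles: all consensus splits pairwise compatible
  for (rep in 1:5) {
    trees <- ape::rmtree(9, 7)
    cc <- majority_rule_consensus(trees)
    part <- ape::prop.part(cc)
    n <- length(attr(part, "labels"))
    sets <- lapply(part, function(p) p)
    for (i in seq_along(sets)) for (j in seq_along(sets)) {
      if (i >= j) next
      A <- sets[[i]]; B <- sets[[j]]
      compatible <- length(intersect(A, B)) == 0 || all(A %in% B) ||
        all(B %in% A) || length(union(A, B)) == n
      expect_true(compatible)
    }
  }

  bad <- c(ape::rtree(5), ape::rtree(6))
  expect_error(majority_rule_consensus(bad), "leaf set")
})

test_that("least-squares branch lengths reproduce additive distances", {
  set.seed(14)
  tr <- ape::rtree(8, br = function(k) runif(k, 0.2, 1))
  D <- ape::cophenetic.phylo(tr)
  fit <- fit_branch_lengths_ls(ape::unroot(tr), D)
  expect_equal(ape::cophenetic.phylo(fit)[rownames(D), colnames(D)], D,
               tolerance = 1e-8)

  # star topology with equal distances 2d: every leaf branch is d
  star <- ape::read.tree(text = "(a,b,c,d,e)r;")
  Ds <- matrix(1.4, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(Ds) <- 0
  fs <- fit_branch_lengths_ls(star, Ds)
  expect_equal(fs$edge.length, rep(0.7, 5))

  # perturbed distances: fitted objective no worse than the true lengths
  Dp <- D + matrix(runif(64, -0.05, 0.05), 8, 8)
  Dp <- (Dp + t(Dp)) / 2; diag(Dp) <- 0
  fitp <- fit_branch_lengths_ls(ape::unroot(tr), Dp)
  obj <- function(t2) {
    P <- ape::cophenetic.phylo(t2)[rownames(Dp), colnames(Dp)]
    w <- ifelse(Dp > 0, 1 / Dp^2, 0)
    sum((w * (Dp - P)^2)[upper.tri(Dp)])
  }
  expect_lte(obj(fitp), obj(ape::unroot(tr)) + 1e-8)
})

test_that("Wagner branch lengths equal MPR-averaged transition counts", {
  set.seed(15)
  for (i in 1:10) {
    tr <- ape::rtree(sample(4:7, 1))
    m <- matrix(rbinom(ape::Ntip(tr) * 6, 1, 0.5), 6, ape::Ntip(tr),
                dimnames = list(paste0("u", 1:6), tr$tip.label))
    pb <- parsimony_branch_lengths(tr, occurrence_matrix(m))
    expected <- Reduce(`+`, lapply(1:6, function(u)
      brute_wagner(tr, m[u, tr$tip.label])))
    expect_equal(pb$edge.length, expected, tolerance = 1e-9)

    # conservation: total branch length equals the summed parsimony score
    ph <- phangorn::phyDat(t(m), type = "USER", levels = 0:1)
    expect_equal(sum(pb$edge.length), phangorn::parsimony(tr, ph),
                 tolerance = 1e-9)
  }

  # trivial profiles
  tr <- ape::rtree(4)
  all1 <- occurrence_matrix(matrix(1L, 1, 4,
                                   dimnames = list("u", tr$tip.label)))
  expect_true(all(parsimony_branch_lengths(tr, all1)$edge.length == 0))
  single <- matrix(0L, 1, 4, dimnames = list("u", tr$tip.label))
  single[1, 2] <- 1L
  pb1 <- parsimony_branch_lengths(tr, occurrence_matrix(single))
  leaf_edge <- which(tr$edge[, 2] == 2)
  expect_equal(pb1$edge.length[leaf_edge], 1)
  expect_equal(sum(pb1$edge.length), 1)
})

test_that("rooting finds the superkingdom trifurcation or the outgroup edge", {
  tr <- random_tree(c(Archaea = 3, Bacteria = 4, Eukarya = 4), seed = 21)
  sk <- attr(tr, "superkingdoms")
  unr <- ape::unroot(tr)
  rooted <- root_tree(unr, "trifurcation", superkingdoms = sk)
  root <- ape::Ntip(rooted) + 1L
  expect_identical(sum(rooted$edge[, 1] == root), 3L)

  og <- root_tree(unr, "outgroup", outgroup_id = "arc_01")
  root_kids <- og$edge[og$edge[, 1] == ape::Ntip(og) + 1L, 2]
  expect_true(match("arc_01", og$tip.label) %in% root_kids)

  # a mixed clade is rejected with the offending superkingdom named
  sk_bad <- sk
  sk_bad["arc_01"] <- "Eukarya"
  expect_error(root_tree(unr, "trifurcation", superkingdoms = sk_bad),
               "not monophyletic")
})

test_that("height normalization pins leaves to 0, root to 1, monotone on paths", {
  tr <- ape::read.tree(text = "((a:1,b:3):1,(c:2,(d:1,e:1):2):1);")
  nt <- normalize_heights(tr)
  ages <- node_ages(nt)
  ntip <- ape::Ntip(nt)
  expect_true(all(ages[1:ntip] == 0))
  expect_equal(ages[ntip + 1L], 1)
  # hand-computed max-descendant-path ratios (tree height 4: root->b and
  # root->d/e both span 4)
  expect_equal(unname(ages[ntip + 2L]), 3 / 4)   # clade (a,b): depth of b
  expect_equal(unname(ages[ntip + 3L]), 3 / 4)   # clade (c,(d,e)): via d/e
  expect_equal(unname(ages[ntip + 4L]), 1 / 4)   # clade (d,e)

  # invariant to uniform rescaling; antitone parent >= child
  tr2 <- tr; tr2$edge.length <- tr$edge.length * 7.3
  expect_equal(node_ages(normalize_heights(tr2)), ages)
  for (e in seq_len(nrow(nt$edge)))
    expect_gte(ages[nt$edge[e, 1]], ages[nt$edge[e, 2]])

  zero <- tr; zero$edge.length[] <- 0
  expect_warning(nz <- normalize_heights(zero), "zero")
  expect_true(all(node_ages(nz)[1:ntip] == 0))
})
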