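test_that("maximum parsimony handles the canonical profiles", {
  tr <- random_tree(c(Archaea = 3, Bacteria = 3, Eukarya = 3), seed = 31)
  ntip <- ape::Ntip(tr)
  all_present <- stats::setNames(rep(1L, ntip), tr$tip.label)
  for (g in c(0.5, 1, 3)) {
    s <- mp_scenario(tr, all_present, g)
    expect_identical(s$gains, ntip + 1L)
    expect_equal(s$cost, g)
    expect_equal(s$age, 1)
  }
  single <- stats::setNames(rep(0L, ntip), tr$tip.label)
  single["bac_02"] <- 1L
  s1 <- mp_scenario(tr, single, g = 1)
  expect_identical(s1$gains, match("bac_02", tr$tip.label))
  expect_equal(s1$cost, 1)
  expect_equal(s1$age, 0)
  expect_error(mp_scenario(tr, single * 0L), "unobserved")
})

test_that("MP and fusion costs and dated ages equal exhaustive enumeration", {
  set.seed(32)
  shapes <- list(c(2, 3, 3), c(3, 3, 3), c(2, 4, 3))
  for (i in 1:20) {
    nl <- shapes[[1 + i %% length(shapes)]]
    tr <- random_tree(c(Archaea = nl[1], Bacteria = nl[2], Eukarya = nl[3]),
                      seed = 300 + i)
    euk <- euk_indicator(tr)
    sk <- attr(tr, "superkingdoms")
    prof <- random_profile(ape::Ntip(tr))
    names(prof) <- tr$tip.label
    for (g in c(0.5, 1, 2)) {
      s <- mp_scenario(tr, prof, g)
      o <- brute_gainloss(tr, unname(prof), g)
      expect_equal(s$cost, o$cost, tolerance = 1e-9)
      expect_equal(s$age, o$maxage, tolerance = 1e-9)
      expect_equal(mp_scenario(tr, prof, g, tie_break = "youngest")$age,
                   o$minage, tolerance = 1e-9)
      sf <- fusion_scenario(tr, prof, g, superkingdoms = sk)
      of <- brute_gainloss(tr, unname(prof), g, euk = euk, cap = 1)
      expect_equal(sf$cost, of$cost, tolerance = 1e-9)
      expect_equal(sf$age, of$maxage, tolerance = 1e-9)
      expect_gte(sf$cost, s$cost - 1e-9)
    }
  }
})

test_that("scenario event sets reproduce the leaf profile they explain", {
  set.seed(33)
  tr <- random_tree(c(Archaea = 3, Bacteria = 4, Eukarya = 4), seed = 34)
  ntip <- ape::Ntip(tr)
  par <- integer(ntip + tr$Nnode)
  par[tr$edge[, 2]] <- tr$edge[, 1]
  replay <- function(s) {
    state <- integer(ntip + tr$Nnode)
    # preorder: parents before children
    pre <- c(ntip + 1L, rev(ape::reorder.phylo(tr, "postorder")$edge[, 2]))
    for (v in pre) {
      inherit <- if (v == ntip + 1L) 0L else state[par[v]]
      state[v] <- inherit
      if (v %in% s$gains) state[v] <- 1L
      if (v %in% s$losses) state[v] <- 0L
    }
    state[1:ntip]
  }
  for (i in 1:25) {
    prof <- random_profile(ntip)
    names(prof) <- tr$tip.label
    for (g in c(0.5, 2)) {
      s <- mp_scenario(tr, prof, g)
      expect_identical(replay(s), unname(prof))
      expect_equal(s$cost, length(s$losses) + g * length(s$gains))
    }
    d <- dollo_age(tr, prof)
    expect_identical(replay(d), unname(prof))
  }
})

test_that("Dollo places one gain at the MRCA with maximal absent subtrees", {
  tr <- random_tree(c(Archaea = 3, Bacteria = 4, Eukarya = 4), seed = 35)
  ntip <- ape::Ntip(tr)
  ages <- node_ages(tr)
  set.seed(36)
  for (i in 1:30) {
    prof <- random_profile(ntip, p = 0.4)
    names(prof) <- tr$tip.label
    d <- dollo_age(tr, prof)
    expect_length(d$gains, 1)
    present <- which(prof[tr$tip.label] == 1L)
    mrca <- if (length(present) == 1) present else
      ape::getMRCA(tr, tr$tip.label[present])
    expect_identical(d$gains, unname(mrca))
    expect_equal(d$age, unname(ages[mrca]))
    # losses are maximal absent subtrees: disjoint, absent, parents not absent
    for (l in d$losses) {
      tips_l <- if (l <= ntip) l else {
        dd <- foldage:::.descendants(tr, l); dd[dd <= ntip]
      }
      expect_true(all(prof[tr$tip.label[tips_l]] == 0L))
    }
  }
  # spanning two root children dates to the root; single leaf to age 0
  prof <- stats::setNames(rep(0L, ntip), tr$tip.label)
  prof[c("arc_01", "euk_01")] <- 1L
  expect_equal(dollo_age(tr, prof)$age, 1)
  prof2 <- stats::setNames(rep(0L, ntip), tr$tip.label)
  prof2["euk_02"] <- 1L
  expect_equal(dollo_age(tr, prof2)$age, 0)
})

test_that("model relations: MP below Dollo, equality at large gain weight", {
  tr <- random_tree(c(Archaea = 3, Bacteria = 4, Eukarya = 4), seed = 37)
  sk <- attr(tr, "superkingdoms")
  ntip <- ape::Ntip(tr)
  set.seed(38)
  for (i in 1:30) {
    prof <- random_profile(ntip, p = 0.4)
    names(prof) <- tr$tip.label
    d <- dollo_age(tr, prof)
    for (g in c(0.2, 1, 5)) {
      s <- mp_scenario(tr, prof, g)
      expect_lte(s$age, d$age + 1e-12)
    }
    gbig <- nrow(tr$edge) + 1     # exceeds any possible loss count
    sb <- mp_scenario(tr, prof, gbig)
    expect_identical(sb$gains, d$gains)
    expect_equal(sb$age, d$age)
    # fusion equals MP when no Eukaryotic presence
    prof_noe <- prof
    prof_noe[grep("^euk", names(prof_noe))] <- 0L
    if (any(prof_noe == 1L)) {
      expect_equal(fusion_scenario(tr, prof_noe, 1, superkingdoms = sk)$cost,
                   mp_scenario(tr, prof_noe, 1)$cost)
    }
  }
  # fusion active: two distant Eukaryotic leaves at small g
  prof <- stats::setNames(rep(0L, ntip), tr$tip.label)
  euks <- grep("^euk", tr$tip.label, value = TRUE)
  prof[euks[c(1, length(euks))]] <- 1L
  s <- mp_scenario(tr, prof, g = 0.1)
  f <- fusion_scenario(tr, prof, g = 0.1, superkingdoms = sk)
  euk <- euk_indicator(tr)
  expect_lte(sum(euk[f$gains]), 1)
  expect_gte(f$cost, s$cost)
})

test_that("age groups split at the cutoff with an equal-size auto option", {
  ages <- c(u1 = 1.0, u2 = 0.05, u3 = 0.5)
  grp <- assign_age_groups(ages, cutoff = 0.1)
  expect_identical(grp$group, c("ancient", "newborn", "middle"))
  expect_error(assign_age_groups(ages, cutoff = 1.2), "cutoff")

  # monotone: the newborn set grows with the cutoff
  set.seed(39)
  a <- c(rep(1, 20), runif(80))
  n_new <- vapply(c(0.05, 0.1, 0.2, 0.4),
                  function(cv) sum(assign_age_groups(a, cv)$group == "newborn"),
                  0L)
  expect_true(all(diff(n_new) >= 0))
  # counting oracle
  for (cv in c(0.1, 0.3)) {
    g <- assign_age_groups(a, cv)
    expect_identical(sum(g$group == "ancient"), sum(a == 1))
    expect_identical(sum(g$group == "newborn"), sum(a <= cv & a != 1))
  }
  # auto cutoff balances newborn against ancient counts
  auto <- assign_age_groups(a, auto_cutoff = TRUE)
  n_anc <- sum(auto$group == "ancient")
  n_nb <- sum(auto$group == "newborn")
  others <- vapply(sort(unique(a[a < 1])), function(cv)
    abs(sum(a <= cv & a < 1) - n_anc), 0)
  expect_equal(abs(n_nb - n_anc), min(others))
})

test_that("gain-weight sweep is monotone and strongly self-correlated", {
  tr <- random_tree(c(Archaea = 3, Bacteria = 3, Eukarya = 3), seed = 40)
  sim <- simulate_profiles(tr, n_units = 40, loss_rate = 0.15, seed = 41)
  sw <- gain_weight_sweep(tr, sim$matrix, g_values = c(0.1, 0.5, 1, 2, 10))
  expect_true(all(apply(sw$ages, 1, function(x) all(diff(x) >= -1e-12))))
  expect_true(isSymmetric(sw$spearman))
  expect_true(all(diag(sw$spearman) == 1))
  # brute-force optima at each g
  set.seed(42)
  for (u in sample(nrow(sw$ages), 5)) {
    prof <- unclass(sim$matrix)[u, tr$tip.label]
    for (g in c(0.1, 1, 10))
      expect_equal(mp_scenario(tr, prof, g)$age,
                   brute_gainloss(tr, unname(prof), g)$maxage)
  }
  # single-leaf profiles are newborn at every g
  single <- matrix(0L, 1, ape::Ntip(tr),
                   dimnames = list("u", tr$tip.label))
  single[1, 3] <- 1L
  sw1 <- gain_weight_sweep(tr, occurrence_matrix(single),
                           g_values = c(0.1, 1, 10))
  expect_true(all(sw1$ages == 0))
  expect_error(gain_weight_sweep(tr, sim$matrix, g_values = c(-1, 1)),
               "positive")
})
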