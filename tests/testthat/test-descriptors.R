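test_that("radius of gyration matches closed forms and rigid invariance", {
  theta <- seq(0, 2 * pi, length.out = 13)[-13]
  circ <- cbind(4.5 * cos(theta), 4.5 * sin(theta), 0)
  circ <- circ + rep(c(3, -2, 7), each = nrow(circ))
  expect_equal(radius_of_gyration(circ), 4.5)
  two <- rbind(c(0, 0, 0), c(2 * 1.7, 0, 0))
  expect_equal(radius_of_gyration(two), 1.7)
  expect_error(radius_of_gyration(matrix(0, 1, 3)), "2 points")

  set.seed(51)
  pts <- matrix(rnorm(150, sd = 5), 50, 3)
  direct <- sqrt(mean(rowSums(sweep(pts, 2, colMeans(pts))^2)))
  expect_equal(radius_of_gyration(pts), direct)
  for (i in 1:10) {
    R <- random_rotation_matrix()
    moved <- pts %*% R + rep(rnorm(3, sd = 20), each = 50)
    expect_equal(radius_of_gyration(moved), radius_of_gyration(pts),
                 tolerance = 1e-9)
    expect_identical(contact_counts(moved), contact_counts(pts))
  }
})

test_that("contact counting follows the distance and separation thresholds", {
  chain <- cbind(3.8 * (0:29), 0, 0)
  cc <- contact_counts(chain, dist_threshold = 8, min_separation = 5)
  expect_identical(cc[["nonlocal"]], 0L)
  tri <- rbind(c(0, 0, 0), c(5, 0, 0), c(2.5, 5 * sqrt(3) / 2, 0))
  expect_identical(contact_counts(tri, 8, 1)[["total"]], 3L)
  expect_error(contact_counts(tri, -1, 5), "positive")

  set.seed(52)
  cloud <- matrix(rnorm(120, sd = 4), 40, 3)
  cc2 <- contact_counts(cloud, 8, 5)
  tot <- nl <- 0L
  for (i in 1:39) for (j in (i + 1):40) {
    d <- sqrt(sum((cloud[i, ] - cloud[j, ])^2))
    if (d <= 8) {
      tot <- tot + 1L
      if (j - i >= 5) nl <- nl + 1L
    }
  }
  expect_identical(cc2, c(total = tot, nonlocal = nl))
})

test_that("normalised contact and burial descriptors are simple ratios", {
  set.seed(53)
  cloud <- matrix(rnorm(90, sd = 3.5), 30, 3)
  rg <- radius_of_gyration(cloud)
  nl <- contact_counts(cloud, 8, 5)[["nonlocal"]]
  expect_equal(nonlocal_contacts_norm(cloud), nl / rg)
  # doubling the scale shrinks contacts and doubles Rg
  expect_lte(nonlocal_contacts_norm(cloud * 2),
             nonlocal_contacts_norm(cloud) / 2 + 1e-12)

  expo <- c(runif(30, 0, 6.9), runif(70, 7.1, 100))[sample(100)]
  coords <- matrix(rnorm(300, sd = 5), 100, 3)
  rg100 <- radius_of_gyration(coords)
  expect_equal(buried_fraction_norm(expo, coords, 7),
               (sum(expo < 7) / 100) / rg100)
  expect_equal(buried_fraction_norm(expo, coords, 7, normalize = "count"),
               sum(expo < 7) / rg100)
  expect_equal(buried_fraction_norm(rep(100, 30),
                                    matrix(rnorm(90), 30, 3), 7), 0)
  expo_na <- expo; expo_na[c(3, 17)] <- NA
  expect_error(buried_fraction_norm(expo_na, coords, 7), "3, 17")
})

test_that("hydrophobicity averages the OMH scale", {
  sc <- omh_scale()
  expect_equal(hydrophobicity(strrep("W", 12)), sc[["W"]])
  expect_equal(hydrophobicity("AC"), (sc[["A"]] + sc[["C"]]) / 2)
  set.seed(54)
  s <- paste(sample(names(sc), 100, replace = TRUE), collapse = "")
  expect_equal(hydrophobicity(s),
               sum(sc[strsplit(s, "")[[1]]]) / 100)
  expect_error(hydrophobicity("AXA"), "X")
  expect_equal(hydrophobicity("AXA", unknown = "mean"),
               (2 * sc[["A"]] + mean(sc)) / 3)
})

test_that("strand direction labels follow content and majority thresholds", {
  pair_anti <- data.frame(strand_a = "s1", strand_b = "s2",
                          orientation = "antiparallel")
  all_helix <- rep("helix", 20)
  expect_identical(strand_direction_label(all_helix, rep(NA, 20), pair_anti),
                   "not_applicable")
  ss <- c(rep("strand", 4), rep("coil", 2), rep("strand", 4))
  sid <- c(rep("s1", 4), NA, NA, rep("s2", 4))
  expect_identical(strand_direction_label(ss, sid, pair_anti), "antiparallel")
  # 60/40 mix at threshold 0.7 is mixed
  pairs_mixed <- data.frame(strand_a = c("s1", "s2"), strand_b = c("s2", "s3"),
                            orientation = c("parallel", "antiparallel"))
  ss2 <- rep("strand", 10)
  sid2 <- c(rep("s1", 3), rep("s2", 4), rep("s3", 3))
  expect_identical(
    strand_direction_label(ss2, sid2, pairs_mixed, majority_threshold = 0.7),
    "mixed")
})

test_that("disulphide classes implement the dual counting criterion", {
  expect_identical(disulphide_class(c(TRUE, TRUE, FALSE)), "with")
  expect_identical(disulphide_class(rep(FALSE, 4)), "without")
  expect_identical(disulphide_class(c(TRUE, FALSE, FALSE, FALSE)), "ambiguous")
})

test_that("amino-acid propensities centre at 1 and detect planted enrichment", {
  set.seed(55)
  aas <- names(omh_scale())
  whole <- paste(sample(aas, 2000, replace = TRUE), collapse = "")
  ident <- amino_acid_propensities(list(all = whole), background = whole)
  expect_true(all(abs(ident$propensity[ident$n_aa > 0] - 1) < 1e-12))

  polyA <- list(grp = strrep("A", 50))
  bg <- c(whole, strrep("A", 50))
  pa <- amino_acid_propensities(polyA, background = bg)
  expect_gt(pa$propensity[pa$aa == "A"], 1)

  # planted 1.3-fold Cys enrichment, 50,000 residues per group: Cys at
  # 0.065 in group A and 0.035 in B, so the pooled frequency stays 0.05
  pA <- stats::setNames(rep((1 - 0.065) / 19, 20), aas); pA["C"] <- 0.065
  pB <- stats::setNames(rep((1 - 0.035) / 19, 20), aas); pB["C"] <- 0.035
  gA <- paste(sample(aas, 50000, replace = TRUE, prob = pA), collapse = "")
  gB <- paste(sample(aas, 50000, replace = TRUE, prob = pB), collapse = "")
  res <- amino_acid_propensities(list(A = gA, B = gB))
  pcys <- res$propensity[res$aa == "C" & res$group == "A"]
  expect_gt(pcys, 1.25)
  expect_lt(pcys, 1.35)
  # sign consistency: enrichment in one group implies depletion in the other
  for (aa in c("C")) {
    pa_ <- res$propensity[res$aa == aa & res$group == "A"]
    pb_ <- res$propensity[res$aa == aa & res$group == "B"]
    expect_true((pa_ - 1) * (pb_ - 1) <= 0)
  }
  # conservation over the partition
  agg <- vapply(split(res, res$aa), function(df)
    sum(df$N_group / df$N * df$propensity), 0)
  expect_true(all(abs(agg - 1) < 1e-9))
})

test_that("superfamily summaries average domains and vote on labels", {
  rec <- data.frame(domain_id = c("d1", "d2", "d3"),
                    superfamily_id = "sf1",
                    length = c(100, 200, 150),
                    rg = c(10, 12, 11),
                    nonlocal_contacts_norm = c(1, 2, 3),
                    buried_norm = c(0.01, 0.02, 0.03),
                    hydrophobicity = c(-0.1, 0.1, 0),
                    strand_label = c("parallel", "parallel", "antiparallel"),
                    has_disulphide = c(TRUE, TRUE, FALSE))
  s <- summarize_superfamily(rec)
  expect_equal(s$mean_length, 150)
  expect_identical(s$strand_label, "parallel")
  expect_identical(s$disulphide_class, "with")
  one <- summarize_superfamily(rec[1, ])
  expect_equal(one$mean_length, 100)
  expect_identical(one$strand_label, "parallel")
  tie <- rec[1:2, ]; tie$strand_label <- c("parallel", "antiparallel")
  expect_identical(summarize_superfamily(tie)$strand_label, "mixed")
})

test_that("PDB and annotation files round-trip through the readers", {
  plan <- data.frame(ss_element = c("helix", "coil", "strand", "coil",
                                    "strand"),
                     length = c(10, 3, 5, 3, 5))
  dom <- synthetic_domain(plan, seed = 56, n_disulphides = 1)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_ca_pdb(dom, pdb)
  back <- read_ca_pdb(pdb)
  expect_equal(back$coords, dom$ca_coords, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_identical(back$sequence, dom$sequence)

  ann <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(dom$annotations, ann)
  back_ann <- read_annotations(ann)
  expect_equal(back_ann$relative_exposure, dom$annotations$relative_exposure,
               tolerance = 1e-9)
  expect_identical(back_ann$ss_element, dom$annotations$ss_element)
  expect_identical(back_ann$disulphide_partner,
                   dom$annotations$disulphide_partner)

  topo <- withr::local_tempfile(fileext = ".tsv")
  write_topology(dom$topology, topo)
  back_topo <- read_topology(topo)
  expect_identical(back_topo$strands$spatial_position,
                   dom$topology$strands$spatial_position)
  expect_identical(back_topo$pairings$orientation,
                   dom$topology$pairings$orientation)

  # descriptor records survive a TSV round-trip
  rec <- domain_descriptors(dom)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(rec, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  rec2 <- utils::read.delim(tsv, stringsAsFactors = FALSE)
  expect_equal(rec2$rg, rec$rg, tolerance = 1e-9)
  expect_identical(rec2$strand_label, rec$strand_label)
})
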