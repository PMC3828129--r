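#!/usr/bin/env Rscript
# Stage 2: build the eight species trees per genome set — the backbone
# topology with Wagner-parsimony branch lengths, and neighbour-joining
# jackknife-consensus trees for Jaccard and Bray-Curtis distances, each at
# superfamily and fold level.
#
# Reads stage-1 outputs; writes results/tree_<method>.<level>.nwk

library(foldage)

cfg <- default_config(seed = 1)
tree <- ape::read.tree("results/tree_true.nwk")
attr(tree, "superkingdoms") <-
  with(read_genomes("results/genomes.tsv"),
       setNames(superkingdom, genome_id))
tree <- normalize_heights(tree)
sk <- attr(tree, "superkingdoms")

mats <- list(superfamily = read_occurrence("results/occurrence_superfamily.tsv",
                                           "superfamily"),
             fold = read_occurrence("results/occurrence_fold.tsv", "fold"))

recipes <- tree_recipes()
for (i in seq_len(nrow(recipes))) {
  method <- recipes$method[i]; level <- recipes$level[i]
  m <- mats[[level]]
  tr <- switch(
    method,
    backbone_parsimony = ,
    parsimony_topology = normalize_heights(parsimony_branch_lengths(tree, m)),
    nj_jaccard = ,
    nj_braycurtis = {
      metric <- sub("nj_", "", method)
      samples <- jackknife_samples(m, n_samples = cfg$n_jackknife,
                                   seed = cfg$seed + i)
      njs <- lapply(samples, function(s)
        neighbor_joining(distance_matrix(s, metric)))
      cons <- majority_rule_consensus(njs, extended = TRUE)
      fitted <- fit_branch_lengths_ls(cons, distance_matrix(m, metric))
      rooted <- tryCatch(
        root_tree(fitted, "trifurcation", superkingdoms = sk),
        error = function(e) root_tree(fitted, "outgroup",
                                      outgroup_id = names(sk)[sk == "Archaea"][1]))
      normalize_heights(rooted)
    })
  out <- sprintf("results/tree_%s.%s.nwk", method, level)
  ape::write.tree(tr, out)
  cat(sprintf("%-22s %-12s -> %s (height-normalized, %d tips)\n",
              method, level, out, ape::Ntip(tr)))
}
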