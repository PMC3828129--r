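#!/usr/bin/env Rscript
# Stage 3: estimate superfamily ages on every tree with maximum parsimony
# (gain weight 1), plus Dollo and fusion ages on the backbone tree, the
# gain-weight sweep, the inter-tree Spearman concordance matrix, and the
# age-group assignment.
#
# Writes: results/ages.tsv, results/concordance.tsv, results/age_groups.tsv,
#         results/gain_weight_sweep.tsv

library(foldage)

cfg <- default_config(seed = 1)
m <- read_occurrence("results/occurrence_superfamily.tsv", "superfamily")
genomes <- read_genomes("results/genomes.tsv")
sk <- setNames(genomes$superkingdom, genomes$genome_id)
truth <- read.delim("results/truth.tsv")

tree_files <- Sys.glob("results/tree_*.nwk")
tree_files <- tree_files[!grepl("tree_true", tree_files)]
trees <- lapply(tree_files, function(f) normalize_heights(ape::read.tree(f)))
names(trees) <- sub("^tree_", "", sub("\\.nwk$", "", basename(tree_files)))

sf_ids <- rownames(m)
age_mat <- matrix(NA_real_, length(sf_ids), length(trees),
                  dimnames = list(sf_ids, names(trees)))
for (j in seq_along(trees)) {
  tr <- trees[[j]]
  prof_m <- unclass(m)[, tr$tip.label, drop = FALSE]
  for (u in seq_along(sf_ids))
    age_mat[u, j] <- mp_scenario(tr, prof_m[u, ], g = cfg$gain_weight)$age
}

backbone <- trees[["backbone_parsimony.superfamily"]]
attr(backbone, "superkingdoms") <- sk
prof_b <- unclass(m)[, backbone$tip.label, drop = FALSE]
dollo <- vapply(seq_along(sf_ids), function(u)
  dollo_age(backbone, prof_b[u, ])$age, 0)
fusion <- vapply(seq_along(sf_ids), function(u)
  fusion_scenario(backbone, prof_b[u, ], superkingdoms = sk)$age, 0)

ages <- data.frame(unit_id = sf_ids, age_mat, dollo = dollo,
                   fusion = fusion, true_age = truth$true_age,
                   check.names = FALSE)
write.table(ages, "results/ages.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

conc <- concordance(cbind(age_mat, dollo = dollo, fusion = fusion,
                          truth = truth$true_age))
write.table(round(conc, 4), "results/concordance.tsv", sep = "\t",
            quote = FALSE)
cat("age concordance across trees/models (Spearman):\n")
cat(sprintf("  min off-diagonal %.3f; truth vs backbone MP %.3f\n",
            min(conc[upper.tri(conc)]),
            conc["truth", "backbone_parsimony.superfamily"]))

groups <- assign_age_groups(
  setNames(age_mat[, "backbone_parsimony.superfamily"], sf_ids),
  cutoff = cfg$cutoff)
write.table(groups, "results/age_groups.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
tab <- table(groups$group)
cat(sprintf("groups at cutoff %.2f: %s\n", attr(groups, "cutoff"),
            paste(names(tab), tab, sep = "=", collapse = ", ")))

sweep <- gain_weight_sweep(backbone, m)
write.table(data.frame(unit_id = rownames(sweep$ages), sweep$ages,
                       check.names = FALSE),
            "results/gain_weight_sweep.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("gain-weight sweep %s: min pairwise Spearman %.3f\n",
            paste(colnames(sweep$ages), collapse = "/"),
            min(sweep$spearman)))
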