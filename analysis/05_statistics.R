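#!/usr/bin/env Rscript
# Stage 5: contrast new-born against ancient superfamilies — descriptor
# Mann-Whitney tests, amino-acid propensities, GO-style hypergeometric
# enrichment with planted terms, percentile curves of the age
# distributions, the motif-set age contrast, and the structure-versus-
# function comparison.
#
# Writes: results/descriptor_contrasts.tsv, results/propensities.tsv,
#         results/enrichment.tsv, results/percentile_curves.tsv,
#         results/motif_age_contrast.txt, results/structure_vs_function.txt

library(foldage)

cfg <- default_config(seed = 1)
groups <- read.delim("results/age_groups.tsv")
summaries <- read.delim("results/superfamily_summaries.tsv")
descriptors <- read.delim("results/descriptors.tsv")
motifs <- read.delim("results/motif_sets.tsv")
group_of <- setNames(groups$group, groups$unit_id)
ages <- setNames(groups$age, groups$unit_id)

## descriptor contrasts: ancient vs new-born superfamilies -----------------
grp <- group_of[summaries$superfamily_id]
anc <- summaries[grp == "ancient", ]
nb <- summaries[grp == "newborn", ]
vars <- c("mean_length", "mean_nonlocal_norm", "mean_buried_norm",
          "mean_hydrophobicity")
contrasts <- do.call(rbind, lapply(vars, function(v) {
  mw <- mann_whitney_ties(anc[[v]], nb[[v]])
  data.frame(descriptor = v, n_ancient = nrow(anc), n_newborn = nrow(nb),
             U = mw$U, z = mw$z, p_two_sided = mw$p_two_sided)
}))
write.table(contrasts, "results/descriptor_contrasts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("ancient vs new-born descriptor contrasts:\n")
print(contrasts, row.names = FALSE)

## amino-acid propensities by age group ------------------------------------
seqs <- read.delim("results/sequences.tsv")
seq_of <- setNames(seqs$sequence, seqs$superfamily_id)
seqs_by_group <- lapply(split(groups$unit_id, group_of[groups$unit_id]),
                        function(ids) unname(seq_of[ids]))
prop <- amino_acid_propensities(seqs_by_group,
                                background = unname(seq_of))
write.table(prop, "results/propensities.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("propensities: %d cells, %d significant after Bonferroni\n",
            nrow(prop), sum(prop$significant)))

## GO-style enrichment by age group ----------------------------------------
planted <- data.frame(term = sprintf("GO:%07d", seq_len(cfg$n_go_terms)),
                      group = rep(c("ancient", "newborn"),
                                  length.out = cfg$n_go_terms),
                      rate_in = cfg$go_rate_in, rate_out = cfg$go_rate_out)
ann <- synthetic_go(groups$unit_id, group_of, planted, seed = cfg$seed + 5)
enrich <- hypergeometric_enrichment(
  ann, data.frame(superfamily_id = groups$unit_id, group = groups$group),
  universe = groups$unit_id, alpha = cfg$alpha)
write.table(enrich, "results/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("enrichment: %d of %d planted terms recovered (Bonferroni m=%d)\n",
            sum(enrich$significant), cfg$n_go_terms, enrich$m[1]))

## percentile curves of the age distributions ------------------------------
curves <- percentile_curves(groups$age, groups$group)
write.table(curves, "results/percentile_curves.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

## motif-set age contrast ---------------------------------------------------
gk_ages <- ages[motifs$superfamily_id[motifs$set == "greek_key"]]
jr_ages <- ages[motifs$superfamily_id[motifs$set == "jelly_roll"]]
sink("results/motif_age_contrast.txt")
if (length(gk_ages) >= 2 && length(jr_ages) >= 2) {
  mw <- mann_whitney_ties(gk_ages, jr_ages)
  cat(sprintf("greek key (n=%d, median %.3f) vs jelly roll (n=%d, median %.3f)\n",
              length(gk_ages), median(gk_ages),
              length(jr_ages), median(jr_ages)))
  cat(sprintf("Mann-Whitney U=%.1f z=%.3f p(two-sided)=%.4g\n",
              mw$U, mw$z, mw$p_two_sided))
} else cat("too few motif superfamilies for a contrast\n")
sink()
cat(readLines("results/motif_age_contrast.txt"), sep = "\n")

## structure versus function -----------------------------------------------
lab <- setNames(summaries$strand_label, summaries$superfamily_id)
svf <- structure_vs_function_contrast(ages, lab, ann)
sink("results/structure_vs_function.txt")
cat(sprintf("structural contrast (parallel vs antiparallel): z=%.3f p=%.4g\n",
            svf$structural$z, svf$structural$p_two_sided))
if (!is.null(svf$functional))
  cat(sprintf("functional contrast: z=%.3f p=%.4g (overlap %d)\n",
              svf$functional$z, svf$functional$p_two_sided,
              svf$overlap_count))
if (!is.null(svf$unique_annotation))
  cat(sprintf("unique-annotation contrast: z=%.3f p=%.4g\n",
              svf$unique_annotation$z, svf$unique_annotation$p_two_sided))
cat(sprintf("enriched terms: %d parallel, %d antiparallel\n",
            length(svf$parallel_terms), length(svf$antiparallel_terms)))
sink()
cat(readLines("results/structure_vs_function.txt"), sep = "\n")
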