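#!/usr/bin/env Rscript
# Stage 3: within-population diversity, pairwise Phi-ST with permutation
# tests, AMOVA over populations and cohorts, and the UPGMA population tree
# on net distances.

library(mtphylogeo)

seed <- 1L
tab <- read_hap_table("results/tables/haplotype_table.tsv")
cohort_df <- utils::read.delim("results/data/cohorts.tsv")
cohorts <- stats::setNames(cohort_df$cohort, cohort_df$population)
haln <- hap_alignment(tab)
dc <- pairwise_diff_matrix(haln)

div <- diversity_table(tab, dc, haln)
utils::write.table(div, "results/tables/diversity.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("Within-population diversity (h = haplotype diversity, pi = nucleotide diversity):\n")
print(div[, c("population", "n", "k", "h", "mean_pairwise", "pi")],
      row.names = FALSE, digits = 3)

fst <- pairwise_fst(tab, dc, n_perm = 1023, seed = seed)
out <- unclass(fst$fst)
out[upper.tri(out)] <- fst$p[upper.tri(fst$p)]
utils::write.table(data.frame(population = rownames(out), out,
                              check.names = FALSE),
                   "results/tables/fst.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
cat("\nPairwise Phi-ST written (lower triangle; permutation p above diagonal)\n")

am1 <- amova(tab, dc)
am2 <- amova(tab, dc, strata = cohorts)
cat(sprintf("AMOVA: %.1f%% of variation among populations, %.1f%% among cohorts\n",
            am1$table$percent[1], am2$table$percent[1]))
utils::write.table(rbind(cbind(grouping = "populations", am1$table),
                         cbind(grouping = "cohorts", am2$table)),
                   "results/tables/amova.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

net <- net_population_distance(tab, dc)
write_dist_matrix(net, "results/tables/net_distances.tsv")
upgma <- build_upgma(net)
write_tree(upgma, "results/tables/upgma_populations.nwk")
cat("UPGMA population tree on net distances written\n")
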