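#!/usr/bin/env Rscript
# Locus validation statistics on simulated assays: bisulfite clone matrices
# for a hypermethylated candidate (case clones at high methylation) analyzed
# with per-clone Mann-Whitney and per-CpG Fisher tests, and a qPCR plate
# quantified by the comparative ddCt method with dual reference genes.
suppressMessages(library(dmrcap))

seed <- 20130905

# bisulfite clones: 10 CpGs, 3 subjects x 8 clones per group
ctrl <- simulate_bisulfite_clones(rep(0.15, 10), n_clones = 24,
                                  seed = child_seed(seed, "bis_ctrl"))
pilo <- simulate_bisulfite_clones(rep(0.75, 10), n_clones = 24,
                                  seed = child_seed(seed, "bis_pilo"))
s_ctrl <- clone_methylation_summary(ctrl)
s_pilo <- clone_methylation_summary(pilo)
mw <- mannwhitney_group_test(s_pilo$per_clone, s_ctrl$per_clone)
fis <- percpg_fisher(pilo, ctrl, adjust = TRUE)

cat("per-clone methylation: CTRL", signif(mean(s_ctrl$per_clone), 3),
    "PILO", signif(mean(s_pilo$per_clone), 3), "\n")
cat("Mann-Whitney U:", mw$U, "two-sided p:", signif(mw$p, 3), "\n")
cat("CpG sites with Fisher p < 0.05:", sum(fis$p < 0.05), "of", nrow(fis), "\n")
writeLines(c("CTRL clones:", lollipop_text(ctrl), "", "PILO clones:",
             lollipop_text(pilo)), "results/clone_lollipops.txt")
write.table(fis, "results/percpg_fisher.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# qPCR: candidate repressed 4-fold in the case group
rel <- c(C1 = 1, C2 = 1, C3 = 1, C4 = 1, C5 = 1,
         P1 = 0.25, P2 = 0.25, P3 = 0.25, P4 = 0.25)
grp <- setNames(rep(c("CTRL", "PILO"), c(5, 4)), names(rel))
plate <- simulate_qpcr_plate(rel, grp, ct_noise_sd = 0.15, n_replicates = 3,
                             seed = child_seed(seed, "qpcr"))
rq <- ddct_relative_expression(plate, control_group = "CTRL")
print(rq$group_summary, row.names = FALSE)
tt <- group_mean_tests(rq$per_sample$rq, rq$per_sample$group, "ttest")
cat("unpaired two-tailed t test on RQ: t =", signif(tt$statistic, 3),
    "p =", signif(tt$p, 3), "\n")
write.table(rq$per_sample, "results/qpcr_rq.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
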