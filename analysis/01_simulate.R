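#!/usr/bin/env Rscript
# Build the synthetic study: a toy genome with genes and CpG islands, a
# group-structured methylation landscape (hyper/hypo effects concentrated on
# CGIs and gene bodies, last chromosome spared), methyl-capture tags for a
# 5-control vs 4-case cohort, and expression counts inversely coupled to
# gene-body methylation. Writes BED/TSV inputs for the later stages.
suppressMessages(library(dmrcap))

seed <- 20130905
out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genome <- generate_toy_genome(n_chroms = 3, chrom_length = 2e6, n_genes = 150,
                              n_cgis = 150, seed = child_seed(seed, "genome"))
landscape <- random_landscape(genome, n_effects = 60, feature_weight = 0.8,
                              seed = child_seed(seed, "landscape"))
cfg <- simulation_config(seed = child_seed(seed, "tags"),
                         n_samples = c(CTRL = 5, PILO = 4), depth = 2e5)

tags <- simulate_capture_tags(genome, landscape, cfg)
expr <- simulate_expression_counts(genome, landscape, cfg)

dir.create("scratch/simulated", recursive = TRUE, showWarnings = FALSE)
write_tag_bed(tags, "scratch/simulated/tags.bed")  # bulk intermediate
write_intervals(genome$cgis[, c("chrom", "start", "end")],
                file.path(out, "cgis.bed"))
write_gene_table(genome$genes, genome$exons, file.path(out, "genes.txt"))
write_count_matrix(expr, file.path(out, "expression_counts.tsv"),
                   id_col = "gene_id")
writeLines(yaml::as.yaml(list(
  seed = seed, n_samples = as.list(cfg$n_samples), depth = cfg$depth,
  duplicate_rate = cfg$duplicate_rate, nb_dispersion = cfg$nb_dispersion,
  coupling = cfg$coupling,
  groups = as.list(attr(tags, "groups")))),
  file.path(out, "config.yaml"))
saveRDS(list(genome = genome, landscape = landscape, cfg = cfg),
        "scratch/simulated_state.rds")

cat("samples:", paste(names(attr(tags, "groups")), collapse = " "), "\n")
cat("tags:", nrow(tags), "| genes:", nrow(genome$genes),
    "| planted effects:", length(unique(landscape$effects$effect_id)), "\n")
cat("wrote", length(list.files(out)), "files to", out, "\n")
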