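#!/usr/bin/env Rscript
# Stage 1 — synthetic study generation.
#
# Generates the full synthetic study under the default conditions: a
# five-superpopulation reference panel (300 genomes, 8,000 variants in
# 10-variant LD blocks), GWAS summary statistics whose genetic variance is
# concentrated in four neurotransmitter pathways (h2 = 0.5), and a
# 320-subject cohort (~205 psychosis cases with SZ/SA/BP labels) carrying a
# 12-measure endophenotype battery with three planted biotypes, follow-up
# BPRS for a case subset, and injected genotype-QC defects. All downstream
# stages consume only the text files written here.

library(ppgs)

seed <- 20260926L
out <- "results"
dir.create(out, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
study <- simulate_study(cfg)

write_vcf(study$panel, file.path(out, "panel.vcf"))
write_vcf(study$cohort$genotypes, file.path(out, "cohort.vcf"))
write_sumstats(study$sumstats, file.path(out, "sumstats.tsv"))
write_gmt(study$pathways, file.path(out, "pathways.gmt"))
write_annotation(study$annotation, file.path(out, "genes.tsv"))
write_pheno(study$cohort$pheno, file.path(out, "pheno.tsv"))
data.table::fwrite(data.frame(sample_id = study$panel$sample_ids,
                              population = study$pop_labels),
                   file.path(out, "panel_populations.tsv"), sep = "\t")
truth <- study$truth
jsonlite::write_json(
  list(causal_ids = truth$causal_ids,
       true_beta = as.list(truth$true_beta[truth$true_beta != 0]),
       liability = truth$liability, status = truth$status,
       pop_labels = truth$pop_labels, true_cluster = truth$true_cluster,
       responder = truth$responder,
       related_pairs = truth$related_pairs,
       defect_variants = truth$defect_variants),
  file.path(out, "ground_truth.json"), auto_unbox = TRUE, digits = NA,
  null = "null")

ph <- study$cohort$pheno
cat(sprintf("cohort: %d subjects (%d cases / %d controls)\n",
            nrow(ph), sum(ph$status), sum(!ph$status)))
print(table(ph$diagnosis))
cat(sprintf("causal variants: %d of %d; planted related pairs: %d\n",
            length(truth$causal_ids), nrow(study$sumstats),
            NROW(truth$related_pairs)))
cat("inputs written under", out, "\n")
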