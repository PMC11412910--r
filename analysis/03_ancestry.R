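#!/usr/bin/env Rscript
# Stage 3 — ancestry principal components.
#
# Fits a PCA on the reference panel (GRM-standardized dosages restricted to
# post-QC variants), projects the cohort onto it, and assigns each subject
# the nearest reference superpopulation centroid in 20-dimensional PC space.
# Separately fits a 10-component PCA within the cohort itself — those are the
# components later regressed out of every polygenic score to control
# stratification.

library(ppgs)

out <- "results"
panel <- read_vcf(file.path(out, "panel.vcf"))
pops <- read_pheno(file.path(out, "panel_populations.tsv"))
g <- read_vcf(file.path(out, "cohort_qc.vcf"))
truth <- jsonlite::read_json(file.path(out, "ground_truth.json"),
                             simplifyVector = TRUE)

panel_qc <- subset_genotypes(panel, variants = panel$variants$id %in%
                               g$variants$id)
ref_pca <- fit_reference_pca(panel_qc, k = 20)
proj <- project_samples(ref_pca, g)
centroids <- population_centroids(ref_pca$scores, pops$population)
assigned <- assign_superpopulation(proj, centroids)

study_pca <- fit_reference_pca(g, k = 10)
tab <- data.frame(sample_id = g$sample_ids, assigned_pop = assigned,
                  study_pca$scores, check.names = FALSE)
data.table::fwrite(tab, file.path(out, "ancestry.tsv"), sep = "\t")

true_pop <- truth$pop_labels[match(g$sample_ids,
                                   sprintf("subj%04d", seq_along(truth$pop_labels)))]
acc <- mean(assigned == true_pop)
cat(sprintf("superpopulation assignment accuracy vs ground truth: %.3f\n", acc))
print(table(assigned = assigned, truth = true_pop))
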