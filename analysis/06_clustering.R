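#!/usr/bin/env Rscript
# Stage 6 — endophenotype biotyping and the cluster-vs-diagnosis comparison.
#
# Derives and z-normalizes the case endophenotype battery (cognitive-control
# measures within scanner), selects the cluster number on complete cases via
# the five-index ensemble, clusters every case with > 50% observed variables
# by missing-tolerant k-means, classifies treatment response from BPRS
# (> 20% decrease after rescaling 24 -> 0), tests cluster enrichment for
# response and diagnosis, and compares, per score, linear models against
# cluster vs diagnosis (BP and the low-pathology cluster as references).

library(ppgs)

out <- "results"
seed <- 20260926L
pheno <- read_pheno(file.path(out, "pheno.tsv"))
scores_tab <- read_pheno(file.path(out, "scores.tsv"))

endo <- normalize_endophenotypes(derive_endophenotypes(pheno))
em <- as.matrix(endo[, endo_battery()])
rownames(em) <- endo$sample_id

complete <- em[complete.cases(em), , drop = FALSE]
sel <- select_k(complete, seed = seed)
cat(sprintf("cluster-number votes (n = %d complete cases):\n", nrow(complete)))
print(sel$votes)
cat("selected k:", sel$k, "\n")

km <- kmeans_missing(em, sel$k, seed = seed)
cat(sprintf("k-means on %d cases with > 50%% observed variables\n",
            sum(km$included)))
data.table::fwrite(
  data.frame(sample_id = rownames(em), included = km$included,
             cluster = km$assignment[match(rownames(em), names(km$assignment))],
             n_observed = rowSums(!is.na(em))),
  file.path(out, "clusters.tsv"), sep = "\t")

resp <- classify_response(pheno$bprs_baseline, pheno$bprs_followup)
cl_of <- km$assignment[match(pheno$sample_id, names(km$assignment))]
enr_resp <- cluster_enrichment(cl_of, resp$responder)
cat(sprintf("\nresponse x cluster (%s p = %.3f):\n", enr_resp$method, enr_resp$p))
print(enr_resp$table)
diag_cases <- pheno$diagnosis[match(names(km$assignment), pheno$sample_id)]
enr_diag <- cluster_enrichment(km$assignment, diag_cases)
cat(sprintf("\ndiagnosis x cluster (%s p = %.3f):\n", enr_diag$method, enr_diag$p))
print(enr_diag$table)

score_names <- unique(scores_tab$pathway)
score_cases <- lapply(score_names, function(nm) {
  s <- scores_tab[scores_tab$pathway == nm, ]
  s$residualized[match(names(km$assignment), s$sample_id)]
})
names(score_cases) <- make.names(score_names)
cmp <- compare_models(score_cases, as.character(km$assignment), diag_cases,
                      cluster_ref = as.character(sel$k))
data.table::fwrite(cmp$comparison, file.path(out, "model_comparison.tsv"),
                   sep = "\t")
data.table::fwrite(cmp$coefficients, file.path(out, "model_coefficients.tsv"),
                   sep = "\t")
cat("\nBIC by model (lower is better):\n")
print(reshape(cmp$comparison[, c("score", "model", "BIC")],
              idvar = "score", timevar = "model", direction = "wide"),
      row.names = FALSE, digits = 1)

# cluster profile table (mirrors a cluster-by-measure mean profile figure)
prof <- aggregate(em[km$included, ],
                  by = list(cluster = km$assignment), FUN = mean, na.rm = TRUE)
data.table::fwrite(prof, file.path(out, "cluster_profiles.tsv"), sep = "\t")
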