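#!/usr/bin/env Rscript
# Stage 4 — polygenic scoring and the permuted-null pathway test.
#
# Greedy LD clumping at r^2 = 0.7 within 250 kb (no p-value filter), then the
# genome-wide clump-and-score PGS and the four pathway-restricted pPGS
# (glutamate, GABA, dopamine, serotonin). Every score is residualized on the
# first 10 within-cohort genetic PCs. Each pathway's case-status association
# is then referred to 10,000 length-matched random gene sets scored the same
# way — the competitive permuted-null test.

library(ppgs)

out <- "results"
seed <- 20260926L
g <- read_vcf(file.path(out, "cohort_qc.vcf"))
panel <- read_vcf(file.path(out, "panel.vcf"))
ss <- read_sumstats(file.path(out, "sumstats.tsv"))
pathways <- read_gmt(file.path(out, "pathways.gmt"))
annotation <- read_annotation(file.path(out, "genes.tsv"))
pheno <- read_pheno(file.path(out, "pheno.tsv"))
pheno <- pheno[match(g$sample_ids, pheno$sample_id), ]
pcs <- as.matrix(read_pheno(file.path(out, "ancestry.tsv"))[, paste0("PC", 1:10)])

clumped <- ld_clump(ss, panel, r2_threshold = 0.7, window_kb = 250)
clumped <- intersect(clumped, g$variants$id)
cat(sprintf("clumping kept %d of %d variants\n", length(clumped), nrow(ss)))

scores <- c(list(pgs = compute_score(g, ss, clumped, label = "genome-wide",
                                     clump_r2 = 0.7)),
            lapply(names(pathways), function(nm)
              pathway_score(g, ss, annotation, pathways[[nm]], clumped,
                            label = nm, clump_r2 = 0.7)))
names(scores) <- c("pgs", names(pathways))
scores <- lapply(scores, residualize_score_set, pcs = pcs, n_pcs = 10)

tab <- do.call(rbind, lapply(scores, function(s) data.frame(
  sample_id = g$sample_ids, pathway = s$pathway, raw = s$score,
  residualized = s$residualized, n_snps = s$n_snps)))
data.table::fwrite(tab, file.path(out, "scores.tsv"), sep = "\t")

nulls <- lapply(names(pathways), function(nm) {
  pathway_null_test(g, ss, annotation, pathways[[nm]], clumped,
                    status = pheno$status, n_null = 10000,
                    seed = seed + match(nm, names(pathways)), pcs = pcs)
})
names(nulls) <- names(pathways)
ntab <- data.frame(pathway = names(nulls),
                   n_genes = vapply(nulls, `[[`, 0, "set_size"),
                   observed_z = vapply(nulls, `[[`, 0, "observed"),
                   competitive_p = vapply(nulls, `[[`, 0, "p"))
data.table::fwrite(ntab, file.path(out, "pathway_null_tests.tsv"), sep = "\t")
print(ntab, row.names = FALSE)
cat("per-score SNP counts:",
    paste(names(scores), vapply(scores, `[[`, 0L, "n_snps"), collapse = ", "),
    "\n")
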