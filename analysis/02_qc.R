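#!/usr/bin/env Rscript
# Stage 2 — genotype quality control.
#
# Applies the variant/sample filter chain to the cohort genotypes: variant
# missingness > 5%, case/control differential missingness (Fisher exact
# p < 0.001), exact Hardy-Weinberg p < 1e-6, relatedness (2x KING-robust
# kinship >= 0.2, one member of each related pair excluded at random), and
# imputation quality (INFO < 0.7 or empirical INFO < 0.8). Writes the
# filtered VCF and the per-step QC report.

library(ppgs)

out <- "results"
g <- read_vcf(file.path(out, "cohort.vcf"))
pheno <- read_pheno(file.path(out, "pheno.tsv"))
stopifnot(identical(g$sample_ids, pheno$sample_id))

qc <- run_qc(g, pheno$status, seed = 20260926L)
write_vcf(qc$genotypes, file.path(out, "cohort_qc.vcf"))
write_qc_report(qc$report, file.path(out, "qc_report"))

print(as.data.frame(qc$report)[, c("step", "n_variants_removed",
                                   "n_samples_removed")])
ini <- attr(qc$report, "initial"); fin <- attr(qc$report, "final")
cat(sprintf("%d -> %d variants, %d -> %d samples\n",
            ini["variants"], fin["variants"], ini["samples"], fin["samples"]))
if (nrow(qc$related$pairs)) {
  cat("related pairs detected:\n")
  print(qc$related$pairs)
}
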