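test_that("generator is seed-deterministic and respects dosage bounds", {
  s1 <- simulate_study(tiny_config(seed = 7))
  s2 <- simulate_study(tiny_config(seed = 7))
  expect_identical(s1$cohort$genotypes$dosage, s2$cohort$genotypes$dosage)
  expect_identical(s1$panel$dosage, s2$panel$dosage)
  expect_identical(s1$cohort$pheno, s2$cohort$pheno)
  expect_identical(s1$sumstats, s2$sumstats)
  d <- s1$cohort$genotypes$dosage
  expect_true(all(d[!is.na(d)] >= 0 & d[!is.na(d)] <= 2))
})

test_that("no-drift limit gives shared population frequencies", {
  cfg <- tiny_config(seed = 2, fst_drift = 1e-4, n_variants = 1000)
  ref <- simulate_reference_panel(cfg)
  pf <- ref$panel$pop_freqs
  expect_lt(mean(abs(pf[, 1] - pf[, 2])), 0.01)
  cfg2 <- tiny_config(seed = 2, fst_drift = 0.1, n_variants = 1000)
  pf2 <- simulate_reference_panel(cfg2)$panel$pop_freqs
  expect_gt(mean(abs(pf2[, 1] - pf2[, 2])), mean(abs(pf[, 1] - pf[, 2])))
})

test_that("within_block_r = 0 yields uncorrelated genotypes within blocks", {
  set.seed(4)
  d <- ppgs:::sim_block_genotypes(1000, runif(50, 0.2, 0.8), 0, 10)
  offdiag <- numeric(0)
  for (b in 0:4) {
    r <- cor(d[, b * 10 + 1:10])
    offdiag <- c(offdiag, abs(r[upper.tri(r)]))
  }
  expect_lt(mean(offdiag), 0.1)
})

test_that("within-block genotype correlation approximates the requested r", {
  set.seed(5)
  d <- ppgs:::sim_block_genotypes(2000, rep(0.5, 10), 0.9, 10)
  r <- cor(d)
  expect_equal(mean(r[upper.tri(r)]), 0.9, tolerance = 0.05)
})

test_that("gene annotation respects length bounds and pathway overlap", {
  cfg <- tiny_config(seed = 3, n_genes = 500,
                     gene_length_distribution = c(1000, 50000))
  ann <- simulate_gene_annotation(cfg)
  expect_true(all(ann$annotation$length >= 1000 &
                    ann$annotation$length <= 50000))
  expect_true(all(ann$annotation$start < ann$annotation$end))
  # non-overlapping placement
  expect_true(all(diff(ann$annotation$start) >=
                    ann$annotation$length[-nrow(ann$annotation)]))

  cfg0 <- tiny_config(seed = 3)
  for (nm in names(cfg0$pathways)) cfg0$pathways[[nm]]$overlap_fraction <- 0
  p0 <- simulate_gene_annotation(cfg0)$pathways
  for (i in 1:3) for (j in (i + 1):4)
    expect_length(intersect(p0[[i]], p0[[j]]), 0)

  cfg1 <- tiny_config(seed = 3)
  for (nm in names(cfg1$pathways)) cfg1$pathways[[nm]]$overlap_fraction <- 1
  p1 <- simulate_gene_annotation(cfg1)$pathways
  expect_identical(p1$glutamate, p1$GABA)
  expect_identical(p1$glutamate, p1$serotonin)

  cfg_bad <- tiny_config(seed = 3)
  cfg_bad$pathways$glutamate$n_genes <- 1000
  expect_error(ppgs:::validate_sim_config(cfg_bad), "larger than gene universe")
})

test_that("summary statistics honor heritability and pathway shares", {
  null_cfg <- tiny_config(seed = 4, h2_liability = 0,
                          pathway_effect_share = c(glutamate = 0))
  ref <- simulate_reference_panel(null_cfg)
  ann <- simulate_gene_annotation(null_cfg)
  ss0 <- simulate_sumstats(ref$panel, ann$annotation, ann$pathways, null_cfg)
  expect_true(all(ss0$truth$true_beta == 0))
  expect_true(all(ss0$sumstats$p > 0 & ss0$sumstats$p <= 1))

  bad <- tiny_config(seed = 4)
  bad$h2_liability <- 0
  expect_error(simulate_sumstats(ref$panel, ann$annotation, ann$pathways, bad),
               "incompatible")

  conc <- tiny_config(seed = 4, pathway_effect_share = c(glutamate = 1))
  ssc <- simulate_sumstats(ref$panel, ann$annotation, ann$pathways, conc)
  glu_snps <- snps_in_genes(ssc$sumstats, ann$annotation, ann$pathways$glutamate)
  expect_true(all(ssc$truth$causal_ids %in% glu_snps))
})

test_that("true genetic variance matches the configured liability h2", {
  # minimal population structure so the liability decomposition dominates
  cfg <- sim_config(seed = 1, n_populations = 2, n_samples_per_pop = 1000,
                    n_variants = 20000, fst_drift = 0.001, n_genes = 2000,
                    n_cohort = 2000,
                    qc_defect_rates = c(variant_missing = 0, hwe_violation = 0,
                                        related_pairs = 0, low_info = 0))
  study <- simulate_study(cfg)
  xc <- sweep(study$cohort$genotypes$dosage, 2, 2 * study$sumstats$frq)
  gv <- as.vector(xc %*% study$truth$true_beta)
  ratio <- var(gv) / var(study$truth$liability)
  expect_lt(abs(ratio - 0.5), 0.02)
})

test_that("case rate tracks the prevalence threshold", {
  study <- tiny_study()
  n <- nrow(study$cohort$pheno)
  target <- 1 - tiny_config()$prevalence_threshold
  k <- sum(study$cohort$pheno$status)
  expect_gte(k, qbinom(0.005, n, target))
  expect_lte(k, qbinom(0.995, n, target))
})

test_that("zero defect rates leave QC with nothing to remove", {
  # at the default study scale (8000 variants) the kinship null sits well
  # below the relatedness threshold; smaller panels are too noisy for it.
  # drift is kept low because pooled-ancestry HWE testing legitimately
  # rejects Wahlund-extreme variants in a strongly structured cohort
  cfg <- tiny_config(seed = 9, n_variants = 8000, fst_drift = 0.01,
                     qc_defect_rates = c(variant_missing = 0, hwe_violation = 0,
                                         related_pairs = 0, low_info = 0))
  study <- simulate_study(cfg)
  qc <- run_qc(study$cohort$genotypes, study$cohort$pheno$status)
  expect_equal(sum(qc$report$n_variants_removed), 0)
  expect_equal(sum(qc$report$n_samples_removed), 0)
})

test_that("null heritability keeps score-status association at OR ~ 1", {
  covered <- logical(100)
  pvals <- numeric(100)
  for (s in seq_len(100)) {
    cfg <- tiny_config(seed = 1000 + s, h2_liability = 0,
                       pathway_effect_share = c(glutamate = 0),
                       n_variants = 300, n_genes = 60, n_cohort = 150,
                       n_samples_per_pop = 25,
                       cluster_archetypes = matrix(0, 3, 12))
    study <- simulate_study(cfg)
    df <- study$cohort$pheno
    sc <- compute_score(study$cohort$genotypes, study$sumstats,
                        study$sumstats$id)
    df$score <- sc$score
    r <- fit_association(df, assoc_spec("status", "binary", "score"))
    covered[s] <- r$or_ci[1] <= 1 && r$or_ci[2] >= 1
    pvals[s] <- r$p
  }
  expect_gte(mean(covered), 0.90)
  # nominal rejection rate at alpha = 0.05 (99.8% binomial band for n = 100)
  expect_gte(mean(pvals < 0.05), 0.005)
  expect_lte(mean(pvals < 0.05), 0.12)
})

test_that("planted archetypes are recovered by downstream k-means", {
  study <- tiny_study()
  norm <- normalize_endophenotypes(derive_endophenotypes(study$cohort$pheno))
  em <- as.matrix(norm[, endo_battery()])
  rownames(em) <- norm$sample_id
  km <- kmeans_missing(em, 3, seed = 11)
  truth <- study$truth$true_cluster[match(names(km$assignment),
                                          study$cohort$pheno$sample_id)]
  expect_gt(ari(km$assignment, truth), 0.8)
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(tiny_config(within_block_r = 1.2), "within_block_r")
  expect_error(tiny_config(fst_drift = -0.1), "fst_drift")
  expect_error(tiny_config(endo_missing_rate = 2), "endo_missing_rate")
  expect_error(tiny_config(pathway_effect_share = c(glutamate = 0.7, GABA = 0.6)),
               "pathway_effect_share")
  expect_error(tiny_config(prevalence_threshold = 0), "prevalence_threshold")
})

test_that("round-trip through the text writers preserves the data", {
  study <- tiny_study()
  dir <- withr::local_tempdir()
  g <- subset_genotypes(study$cohort$genotypes, samples = 1:20, variants = 1:50)
  write_vcf(g, file.path(dir, "g.vcf"))
  g2 <- read_vcf(file.path(dir, "g.vcf"))
  expect_equal(g2$dosage, g$dosage, tolerance = 1e-6)
  expect_identical(g2$hardcall, g$hardcall)
  expect_equal(g2$info, g$info, tolerance = 1e-3)

  write_sumstats(study$sumstats, file.path(dir, "ss.tsv"))
  ss2 <- read_sumstats(file.path(dir, "ss.tsv"))
  expect_equal(ss2$beta, study$sumstats$beta)
  expect_identical(ss2$id, study$sumstats$id)

  write_gmt(study$pathways, file.path(dir, "p.gmt"))
  expect_identical(read_gmt(file.path(dir, "p.gmt")), study$pathways)

  write_annotation(study$annotation, file.path(dir, "a.tsv"))
  a2 <- read_annotation(file.path(dir, "a.tsv"))
  expect_equal(a2$start, study$annotation$start)
  expect_identical(a2$gene_id, study$annotation$gene_id)
})
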