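mk_ref <- function(dosage, pos = seq_len(ncol(dosage)) * 1000) {
  m <- ncol(dosage)
  variants <- data.frame(id = sprintf("v%d", 1:m), chrom = "1", pos = pos,
                         ref = "A", alt = "C",
                         frq = pmin(pmax(colMeans(dosage) / 2, 0.01), 0.99),
                         stringsAsFactors = FALSE)
  genotype_data(dosage, variants, sprintf("s%d", seq_len(nrow(dosage))),
                hardcall = round(dosage))
}

test_that("greedy clumping follows the hand-traced example", {
  set.seed(41)
  n <- 400
  x1 <- rbinom(n, 2, 0.5)
  # r2(1,2) high: copy with small perturbation; r2(1,3) low
  x2 <- x1; flip <- sample(n, 8); x2[flip] <- rbinom(8, 2, 0.5)
  x3 <- rbinom(n, 2, 0.5)
  ref <- mk_ref(cbind(x1, x2, x3))
  expect_gt(cor(x1, x2)^2, 0.9)
  expect_lt(cor(x1, x3)^2, 0.1)
  ss <- data.frame(id = c("v1", "v2", "v3"), chrom = "1",
                   pos = ref$variants$pos, a1 = "C", a2 = "A",
                   beta = c(0.3, 0.2, 0.1), p = c(1e-8, 1e-5, 1e-3),
                   frq = ref$variants$frq)
  expect_identical(ld_clump(ss, ref, r2_threshold = 0.7, window_kb = 250),
                   c("v1", "v3"))
  # single variant trivially retained
  expect_identical(ld_clump(ss[1, ], ref), "v1")
  # all pairwise r2 below threshold: everything survives (order by p)
  expect_setequal(ld_clump(ss, ref, r2_threshold = 0.99), c("v1", "v2", "v3"))
})

test_that("greedy clumping equals the brute-force reference on random instances", {
  for (s in 1:200) {
    inst <- random_clump_instance(4000 + s)
    r2 <- suppressWarnings(cor(inst$g$dosage))^2
    r2[is.na(r2)] <- 0
    attr(r2, "thr") <- 0.5
    expect_identical(ld_clump(inst$ss, inst$g, r2_threshold = 0.5,
                              window_kb = 100),
                     brute_clump(inst$ss, r2, 100 * 1000))
  }
})

test_that("raising the clumping r2 threshold never shrinks the retained set", {
  study <- tiny_study()
  sizes <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(r2)
    length(ld_clump(study$sumstats, study$panel, r2_threshold = r2)), 0)
  expect_true(all(diff(sizes) >= 0))
})

test_that("gene-window membership uses half-open interval boundaries", {
  ann <- data.frame(gene_id = "g1", chrom = "1", start = 1000, end = 2000,
                    length = 1000)
  ss <- data.frame(id = c("a", "b", "c", "d"), chrom = "1",
                   pos = c(1000, 1999, 2000, 999))
  expect_setequal(snps_in_genes(ss, ann, "g1"), c("a", "b"))
  expect_setequal(snps_in_genes(ss, ann, "g1", window_bp = 1),
                  c("a", "b", "c", "d"))
  expect_length(snps_in_genes(ss, ann, character(0)), 0)
  ss_bad <- transform(ss, chrom = "chr9")
  expect_error(snps_in_genes(ss_bad, ann, "g1"), "chromosome")
})

test_that("scores follow the additive dosage rule with frequency imputation", {
  d <- matrix(c(2, 0, NA, 1), 2, 2)
  ref <- mk_ref(d)
  ss <- data.frame(id = c("v1", "v2"), chrom = "1", pos = c(1000, 2000),
                   a1 = "C", a2 = "A", beta = c(0.5, 0.4), p = c(0.5, 0.5),
                   frq = c(0.5, 0.25))
  s1 <- compute_score(ref, ss, "v1")
  expect_equal(unname(s1$score), c(1.0, 0.0))
  # missing dosage contributes beta * 2 * frq = 0.4 * 0.5 = 0.2
  s2 <- compute_score(ref, ss, "v2")
  expect_equal(unname(s2$score[1]), 0.2)
  # zero betas give zero scores; doubling betas doubles scores
  ss0 <- transform(ss, beta = 0)
  expect_true(all(compute_score(ref, ss0, c("v1", "v2"))$score == 0))
  ss2x <- transform(ss, beta = beta * 2)
  expect_equal(compute_score(ref, ss2x, c("v1", "v2"))$score,
               2 * compute_score(ref, ss, c("v1", "v2"))$score)
})

test_that("allele flips with complemented dosage leave scores unchanged", {
  study <- tiny_study()
  ids <- study$sumstats$id[1:50]
  base <- compute_score(study$cohort$genotypes, study$sumstats, ids)
  ss_flip <- study$sumstats
  flip <- ss_flip$id %in% ids[1:25]
  tmp <- ss_flip$a1[flip]
  ss_flip$a1[flip] <- ss_flip$a2[flip]
  ss_flip$a2[flip] <- tmp
  ss_flip$beta[flip] <- -ss_flip$beta[flip]
  ss_flip$frq[flip] <- 1 - ss_flip$frq[flip]
  flipped <- compute_score(study$cohort$genotypes, ss_flip, ids)
  # a polygenic score's location is representation-dependent (flipping the
  # effect allele shifts every score by 2*beta); centered scores are invariant
  expect_equal(flipped$score - mean(flipped$score),
               base$score - mean(base$score), tolerance = 1e-12)
  expect_equal(diff(range(flipped$score - base$score)), 0, tolerance = 1e-12)
})

test_that("strand-ambiguous variants are excluded with a count", {
  d <- matrix(rbinom(40, 2, 0.5), 20, 2)
  ref <- mk_ref(d)
  ref$variants$ref <- c("A", "A"); ref$variants$alt <- c("T", "C")
  ss <- data.frame(id = c("v1", "v2"), chrom = "1", pos = c(1000, 2000),
                   a1 = c("T", "C"), a2 = c("A", "A"), beta = c(1, 1),
                   p = 0.5, frq = 0.5)
  out <- compute_score(ref, ss, c("v1", "v2"))
  expect_equal(out$n_snps, 1)
  expect_equal(out$n_ambiguous_excluded, 1)
})

test_that("disjoint pathways partitioning the SNPs sum to the genome-wide score", {
  study <- tiny_study()
  clumped <- ld_clump(study$sumstats, study$panel)
  # synthetic annotation: four disjoint gene blocks tiling the chromosome
  maxpos <- max(study$sumstats$pos) + 1
  cuts <- round(seq(0, maxpos, length.out = 5))
  ann <- data.frame(gene_id = paste0("tile", 1:4), chrom = "1",
                    start = cuts[1:4], end = cuts[2:5],
                    length = diff(cuts))
  g <- study$cohort$genotypes
  gw <- compute_score(g, study$sumstats, intersect(clumped, g$variants$id))
  parts <- lapply(1:4, function(i)
    pathway_score(g, study$sumstats, ann, paste0("tile", i),
                  intersect(clumped, g$variants$id), label = paste0("tile", i)))
  expect_equal(Reduce(`+`, lapply(parts, `[[`, "score")), gw$score,
               tolerance = 1e-12)
  expect_equal(sum(vapply(parts, `[[`, 0, "n_snps")), gw$n_snps)
  # a pathway covering every gene reproduces the genome-wide score
  full <- pathway_score(g, study$sumstats, ann, paste0("tile", 1:4),
                        intersect(clumped, g$variants$id))
  expect_equal(full$score, gw$score)
  expect_error(pathway_score(g, study$sumstats, ann, "tile1",
                             character(0), label = "empty"), "no clumped")
})

test_that("length-weighted null sets follow their sampling law", {
  ann_eq <- data.frame(gene_id = sprintf("g%02d", 1:20), chrom = "1",
                       start = 0:19 * 100, end = 0:19 * 100 + 50, length = 50)
  sets <- sample_null_gene_sets(ann_eq, set_size = 5, n_sets = 10000, seed = 2)
  freq <- table(factor(unlist(sets), levels = ann_eq$gene_id)) / 10000
  expected <- 5 / 20
  sd3 <- 3 * sqrt(expected * (1 - expected) / 10000)
  expect_true(all(abs(freq - expected) < sd3 + 0.01))
  # 9:1 length ratio, sets of size one
  ann2 <- data.frame(gene_id = c("long", "short"), chrom = "1",
                     start = c(0, 10000), end = c(9000, 11000),
                     length = c(9000, 1000))
  s2 <- sample_null_gene_sets(ann2, 1, 10000, seed = 3)
  expect_lt(abs(mean(unlist(s2) == "long") - 0.90), 0.01)
  # full-universe sets and the size guard
  s3 <- sample_null_gene_sets(ann_eq, 20, 5, seed = 4)
  expect_true(all(vapply(s3, function(s) setequal(s, ann_eq$gene_id), TRUE)))
  expect_error(sample_null_gene_sets(ann_eq, 21, 5), "exceeds")
  expect_identical(sample_null_gene_sets(ann_eq, 5, 50, seed = 9),
                   sample_null_gene_sets(ann_eq, 5, 50, seed = 9))
})

test_that("competitive p follows the add-one empirical rule", {
  nulls <- rnorm(10000)
  expect_equal(competitive_p(max(nulls) + 1, nulls), 1 / 10001)
  expect_equal(competitive_p(min(nulls) - 1, nulls), 1)
  expect_lt(abs(competitive_p(median(nulls), nulls) - 0.5), 1 / sqrt(10000))
  expect_equal(competitive_p(min(nulls) - 1, nulls, direction = "less"),
               1 / 10001)
  expect_error(competitive_p(NaN, nulls), "NaN")
  expect_error(competitive_p(1, numeric(0)), "empty")
})

test_that("a pathway carrying all genetic variance shows the strongest signal", {
  wins <- 0L
  n_seeds <- 12
  for (s in seq_len(n_seeds)) {
    cfg <- tiny_config(seed = 6000 + s,
                       pathway_effect_share = c(glutamate = 0.6),
                       n_cohort = 240)
    study <- simulate_study(cfg)
    g <- study$cohort$genotypes
    clumped <- intersect(ld_clump(study$sumstats, study$panel), g$variants$id)
    z <- vapply(names(study$pathways), function(nm) {
      sc <- pathway_score(g, study$sumstats, study$annotation,
                          study$pathways[[nm]], clumped, label = nm)
      abs(score_status_z(sc$score, study$cohort$pheno$status))
    }, 0)
    wins <- wins + (names(which.max(z)) == "glutamate")
  }
  expect_gte(wins / n_seeds, 0.9)
})
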