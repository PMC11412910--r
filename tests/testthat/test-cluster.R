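test_that("endophenotype derivation follows the instrument rules", {
  expect_equal(range_midpoint(c(6, 8)), 7.0)
  expect_equal(range_midpoint(c(4, 4, 9)), 6.5)
  expect_true(is.na(range_midpoint(numeric(0))))

  pheno <- data.frame(sample_id = c("a", "b"), status = c(1, 1),
                      diagnosis = "SZ", scanner = "scannerA",
                      gsf_values = c("6;8", ""), grf_values = c("4;4;9", "5"),
                      stringsAsFactors = FALSE)
  for (nm in setdiff(endo_battery(), c("gsf", "grf", "ymrs")))
    pheno[[nm]] <- c(0.5, -0.5)
  items <- matrix(2L, 2, 11, dimnames = list(NULL, sprintf("ymrs_item_%d", 1:11)))
  pheno <- cbind(pheno, items)
  tab <- derive_endophenotypes(pheno)
  expect_equal(tab$gsf, c(7.0, NA))
  expect_equal(tab$grf, c(6.5, 5))
  # 10 items x 2 after removing item 8
  expect_equal(tab$ymrs, c(20, 20))
  expect_identical(names(tab), c("sample_id", "diagnosis", "scanner",
                                 endo_battery()))
})

test_that("normalization gives unit z-scores within every stratum", {
  tab <- data.frame(sample_id = sprintf("s%d", 1:6), diagnosis = "SZ",
                    scanner = rep(c("scannerA", "scannerB"), each = 3),
                    stringsAsFactors = FALSE)
  for (nm in endo_battery()) tab[[nm]] <- c(1, 2, 3, 10, 20, 30)
  out <- normalize_endophenotypes(tab)
  # plain variables: z over all six values; scanner-stratified: per stratum
  expect_equal(out$dprime_context, c(-1, 0, 1, -1, 0, 1))
  for (sc in c("scannerA", "scannerB"))
    expect_lt(abs(mean(out$dlpfc_beta[out$scanner == sc])), 1e-12)
  expect_lt(abs(mean(out$gaf)), 1e-12)
  expect_equal(sd(out$gaf), 1, tolerance = 1e-12)
  # idempotent on already-standardized (non-stratified) input
  out2 <- normalize_endophenotypes(out, scanner_stratified = character(0))
  expect_equal(out2$gaf, out$gaf, tolerance = 1e-12)
  # zero-variance stratum turns missing with a warning
  tab$gaf <- 1
  expect_warning(normalize_endophenotypes(tab), "zero-variance")
})

test_that("the index ensemble finds exact cluster structure unanimously", {
  pts <- matrix(c(0, 0, 10, 0, 5, 9), 3, 2, byrow = TRUE)
  x <- pts[rep(1:3, each = 20), ]
  sel <- select_k(x, seed = 3)
  expect_equal(sel$k, 3)
  expect_true(all(sel$votes == 3))
  sel2 <- select_k(x, seed = 3)
  expect_identical(sel$votes, sel2$votes)
})

test_that("a single Gaussian falls back to the k = 2 boundary", {
  set.seed(61)
  x <- matrix(rnorm(120 * 5), 120, 5)
  sel <- select_k(x, seed = 4)
  expect_equal(sel$k, 2)
})

test_that("three planted archetypes are selected and recovered with missing data", {
  pb <- planted_battery(n_per = 30, miss = 0, seed = 62)
  sel <- select_k(pb$x, seed = 5)
  expect_equal(sel$k, 3)
  pbm <- planted_battery(n_per = 40, miss = 0.2, seed = 63)
  km <- kmeans_missing(pbm$x, 3, seed = 6)
  expect_gt(ari(km$assignment, pbm$labels[km$included]), 0.8)
})

test_that("missing-tolerant k-means reduces to standard k-means when complete", {
  pb <- planted_battery(n_per = 25, miss = 0, seed = 64)
  km <- kmeans_missing(pb$x, 3, seed = 7, restarts = 25)
  ref <- kmeans(pb$x, 3, nstart = 50)
  expect_equal(ari(km$assignment, ref$cluster), 1)
  expect_equal(km$total_cost, ref$tot.withinss, tolerance = 1e-8)
})

test_that("the 50% data rule and degenerate inputs are enforced", {
  pb <- planted_battery(n_per = 10, seed = 65)
  x <- pb$x
  x[1, 1:6] <- NA   # exactly 50% observed: excluded (> 50% required)
  x[2, 1:5] <- NA   # 7/12 observed: included
  km <- kmeans_missing(x, 3, seed = 8)
  expect_false(km$included[1])
  expect_true(km$included[2])
  expect_error(kmeans_missing(pb$x[1:2, ], 3, seed = 1), "exceeds")
  # a case with one observed variable sitting on a centroid joins that cluster
  centers <- matrix(c(0, 0, 0, 10, 10, 10), 2, 3, byrow = TRUE)
  base <- centers[rep(1:2, each = 20), ] + matrix(rnorm(120, 0, 0.1), 40)
  probe <- c(10, NA, NA)
  xx <- rbind(base, probe)
  rownames(xx) <- sprintf("r%02d", 1:41)
  km2 <- kmeans_missing(xx, 2, seed = 9, min_observed = 0)
  expect_equal(unname(km2$assignment["r41"]),
               unname(km2$assignment["r40"]))  # r40 is a known cluster-2 point
})

test_that("treatment response uses the rescaled strict 20% rule", {
  out <- classify_response(c(44, 40, 34, 26, NA), c(36, 40, 32, 25, 30))
  expect_identical(out$responder, c(TRUE, FALSE, FALSE, NA, NA))
  # rescaled baseline 10, follow-up 8: exactly 20%, strictly no
  expect_false(classify_response(34, 32)$responder)
  expect_identical(out$excluded_reason[4], "rescaled baseline < 5")
  expect_identical(out$excluded_reason[5], "missing BPRS")
  expect_error(classify_response(20, 30), "minimum")
})

test_that("model comparison prefers the generating factor", {
  set.seed(66)
  n <- 180
  cl <- sample(as.character(1:3), n, replace = TRUE)
  dg <- sample(c("SZ", "SA", "BP"), n, replace = TRUE)
  # identical labelings give identical single-factor fits
  cmp_same <- compare_models(list(s = rnorm(n)), cl,
                             c("3" = "BP", "1" = "SZ", "2" = "SA")[cl],
                             diagnosis_ref = "BP")
  tab <- cmp_same$comparison
  expect_equal(tab$BIC[tab$model == "cluster"], tab$BIC[tab$model == "diagnosis"],
               tolerance = 1e-9)
  expect_equal(tab$adj_r2[tab$model == "cluster"],
               tab$adj_r2[tab$model == "diagnosis"], tolerance = 1e-9)

  # scores generated from cluster means: cluster model wins by BIC
  wins <- 0L
  for (s in 1:200) {
    set.seed(700 + s)
    cl_s <- sample(as.character(1:3), n, replace = TRUE)
    dg_s <- sample(c("SZ", "SA", "BP"), n, replace = TRUE)
    score <- c("1" = -1, "2" = 0, "3" = 1)[cl_s] + rnorm(n)
    cmp <- compare_models(list(s = score), cl_s, dg_s)
    t2 <- cmp$comparison
    wins <- wins + (t2$BIC[t2$model == "cluster"] < t2$BIC[t2$model == "diagnosis"])
  }
  expect_gte(wins / 200, 0.95)

  # null scores: combined-model CIs cover zero at ~95%
  cover <- numeric(0)
  for (s in 1:200) {
    set.seed(900 + s)
    cl_s <- sample(as.character(1:3), n, replace = TRUE)
    dg_s <- sample(c("SZ", "SA", "BP"), n, replace = TRUE)
    cmp <- compare_models(list(s = rnorm(n)), cl_s, dg_s)
    co <- cmp$coefficients
    co <- co[co$term != "(Intercept)", ]
    cover <- c(cover, co$ci_low <= 0 & co$ci_high >= 0)
  }
  expect_gt(mean(cover), 0.92)
  expect_lt(mean(cover), 0.98)
  expect_error(compare_models(list(s = rnorm(10)), rep("1", 10),
                              rep(c("SZ", "BP"), 5)), "constant")
})

test_that("cluster enrichment matches hypergeometric enumeration", {
  eq <- cluster_enrichment(rep(c(1, 2), each = 20),
                           rep(c(TRUE, FALSE), 20))
  expect_gt(eq$p, 0.99)
  # (10,0) vs (0,10): two-sided exact p = 2 / C(20,10)
  out <- cluster_enrichment(rep(c(1, 2), each = 10),
                            rep(c(TRUE, FALSE), each = 10))
  expect_equal(out$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_identical(out$method, "fisher")
  expect_error(cluster_enrichment(rep(1, 10), rep(c(TRUE, FALSE), 5)),
               "levels")
})
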