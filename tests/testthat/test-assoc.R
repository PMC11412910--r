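test_that("a perfectly predictive continuous association is recovered exactly", {
  set.seed(51)
  d <- data.frame(y = rnorm(50))
  d$x <- d$y
  r <- suppressWarnings(fit_association(d, assoc_spec("y", "continuous", "x")))
  expect_equal(r$beta_std, 1.0, tolerance = 1e-10)
  expect_equal(r$r2_adj, 1.0, tolerance = 1e-10)
  expect_true(r$ci[1] <= r$beta && r$beta <= r$ci[2])
})

test_that("standardized effects are invariant to predictor rescaling", {
  set.seed(52)
  d <- data.frame(x = rnorm(300))
  d$status <- rbinom(300, 1, plogis(0.3 * d$x))
  d$y <- 0.4 * d$x + rnorm(300)
  for (c in c(0.001, 1, 250)) {
    d$xs <- d$x * c
    rb <- fit_association(d, assoc_spec("status", "binary", "xs"))
    rc <- fit_association(d, assoc_spec("y", "continuous", "xs"))
    if (c == 0.001) { base_b <- rb; base_c <- rc }
    expect_equal(rb$or, base_b$or, tolerance = 1e-9)
    expect_equal(rb$p, base_b$p, tolerance = 1e-9)
    expect_equal(rc$beta, base_c$beta, tolerance = 1e-9)
  }
})

test_that("association p-values are uniform under the null", {
  set.seed(53)
  pvals <- vapply(1:200, function(i) {
    d <- data.frame(x = rnorm(300), status = rbinom(300, 1, 0.5))
    fit_association(d, assoc_spec("status", "binary", "x"))$p
  }, 0)
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("guard rails reject degenerate designs", {
  d <- data.frame(y = rep(1, 20), x = rnorm(20), z = rnorm(20))
  expect_error(fit_association(d, assoc_spec("y", "continuous", "x")),
               "constant")
  d2 <- data.frame(y = rnorm(20), x = rnorm(20))
  d2$x2 <- d2$x
  expect_error(fit_association(d2, assoc_spec("y", "continuous", "x",
                                              covariates = "x2")),
               "collinear|rank")
  expect_error(assoc_spec("y", "binary", "x", covariates = "y"), "outcome")
})

test_that("Nagelkerke R2 matches direct formula arithmetic", {
  # n = 4 toy whose likelihoods are known in closed form: the balanced null
  # has ll = 4 log(1/2) = -2.7726; a predictor that perfectly separates two
  # observations and leaves two at 1/2 has ll -> 2 log(1/2) = -1.3863
  y <- c(0, 0, 1, 1); x <- c(-1, 0, 0, 1)
  full <- suppressWarnings(glm(y ~ x, family = binomial()))
  null <- glm(y ~ 1, family = binomial())
  expect_equal(as.numeric(logLik(null)), -2.7726, tolerance = 1e-4)
  expect_equal(as.numeric(logLik(full)), -1.3863, tolerance = 1e-3)
  ll_null <- -2.7726; ll_full <- -1.3863
  expected <- (1 - exp((2 / 4) * (ll_null - ll_full))) /
    (1 - exp((2 / 4) * ll_null))  # = 0.5 / 0.75 by independent arithmetic
  expect_equal(expected, 0.5 / 0.75, tolerance = 1e-4)
  expect_equal(nagelkerke_r2(full, null), expected, tolerance = 1e-3)
  # identical models give zero; swapped models are a fit failure
  expect_equal(nagelkerke_r2(null, null), 0)
  expect_error(nagelkerke_r2(null, full), "fit failure")
  null5 <- glm(c(y, 1) ~ 1, family = binomial())
  expect_error(nagelkerke_r2(full, null5), "subsets")
  # near-perfect separation drives the value toward 1
  set.seed(54)
  x <- c(rnorm(50, -4), rnorm(50, 4))
  y <- as.integer(x > 0)
  full <- suppressWarnings(glm(y ~ x, family = binomial()))
  null <- glm(y ~ 1, family = binomial())
  expect_gte(nagelkerke_r2(full, null), 0.99)
})

test_that("Cook's rule excludes a gross outlier but spares clean data", {
  set.seed(55)
  x <- rnorm(200); y <- 0.5 * x + rnorm(200)
  x[1] <- 10; y[1] <- -30  # high-leverage gross outlier
  d <- data.frame(x = x, y = y)
  r <- fit_association(d, assoc_spec("y", "continuous", "x"))
  expect_equal(r$n_outliers, 1)
  expect_equal(r$n, 199)
  for (s in 1:10) {
    set.seed(100 + s)
    dc <- data.frame(x = rnorm(200))
    dc$y <- 0.3 * dc$x + rnorm(200)
    rc <- fit_association(dc, assoc_spec("y", "continuous", "x"))
    expect_equal(rc$n_outliers, 0)
  }
  # duplicating an existing point leaves it retained
  dd <- rbind(dc, dc[1, ])
  fit <- lm(y ~ x, dd)
  expect_length(cooks_outliers(fit)$excluded, 0)
})

test_that("Galwey effective tests match hand eigen arithmetic and its bounds", {
  expect_equal(galwey_meff(diag(5)), 5, tolerance = 1e-12)
  expect_equal(galwey_meff(matrix(1, 4, 4)), 1, tolerance = 1e-6)
  r <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(galwey_meff(r), (sqrt(1.5) + sqrt(0.5))^2 / 2, tolerance = 1e-12)
  expect_equal(galwey_meff(r), 1.8660, tolerance = 1e-4)
  expect_error(galwey_meff(matrix(c(1, 0.2, 0.5, 1), 2)), "symmetric")
  set.seed(56)
  for (i in 1:25) {
    m <- sample(2:12, 1)
    x <- matrix(rnorm(40 * m), 40, m)
    cm <- cor(x)
    meff <- galwey_meff(cm)
    expect_gte(meff, 1)
    expect_lte(meff, m + 1e-9)
  }
  expect_lt(galwey_meff(cor(matrix(rnorm(30 * 4), 30, 4))), 4)
})

test_that("the effective test budget reproduces the corrected-test arithmetic", {
  expect_identical(effective_test_budget(5, 12, 1), 61)
  expect_identical(effective_test_budget(1, 1, 0), 1)
  expect_identical(effective_test_budget(6, 17, 0), 102)
  # rounding is half-up before the product
  expect_identical(effective_test_budget(4.6, 11.5, 1), 61)
})

test_that("BH step-up matches the hand trace and controls FDR", {
  out <- bh_fdr(c(0.01, 0.02, 0.04, 0.9), q = 0.10)
  expect_identical(out$discovery, c(TRUE, TRUE, TRUE, FALSE))
  expect_false(any(bh_fdr(rep(1, 6))$discovery))
  expect_true(bh_fdr(0.05, q = 0.10)$discovery)
  # agreement with p.adjust when no budget override is used
  set.seed(57)
  p <- runif(15)^2
  expect_equal(bh_fdr(p)$q_values, p.adjust(p, "BH"), tolerance = 1e-12)
  # m_override makes the correction strictly harsher for a shorter list
  p2 <- c(0.001, 0.004, 0.2)
  expect_true(all(bh_fdr(p2, m_override = 61)$q_values >=
                    bh_fdr(p2)$q_values))
  # empirical FDR under independent nulls stays at or below q (+2 SE)
  set.seed(58)
  fdp <- vapply(1:1000, function(i) {
    p_null <- runif(12)
    p_alt <- pmin(rbeta(8, 0.05, 1), 1)
    res <- bh_fdr(c(p_null, p_alt), q = 0.10)
    disc <- which(res$discovery)
    if (!length(disc)) return(0)
    mean(disc <= 12)
  }, 0)
  se <- sd(fdp) / sqrt(length(fdp))
  expect_lte(mean(fdp), 0.10 + 2 * se)
})
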