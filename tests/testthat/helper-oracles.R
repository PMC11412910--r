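# Independent brute-force oracles and shared small fixtures.

tiny_config <- function(seed = 1, ...) {
  base <- list(
    n_populations = 3, n_samples_per_pop = 40, n_variants = 600,
    n_genes = 120,
    pathways = list(glutamate = list(n_genes = 15, overlap_fraction = 0.1),
                    GABA = list(n_genes = 15, overlap_fraction = 0.1),
                    dopamine = list(n_genes = 15, overlap_fraction = 0.1),
                    serotonin = list(n_genes = 15, overlap_fraction = 0.1)),
    n_cohort = 200, seed = seed
  )
  do.call(sim_config, utils::modifyList(base, list(...)))
}

tiny_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_study(tiny_config())
    cache
  }
})

# exact HWE p by direct enumeration with choose()-based multinomial weights
brute_hwe <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_a <- 2 * n_aa + n_ab
  rare <- min(n_a, 2 * n - n_a)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  w <- vapply(hets, function(h) {
    ra <- (rare - h) / 2
    choose(n, ra) * choose(n - ra, h) * 2^h
  }, 0)
  pr <- w / sum(w)
  obs <- pr[hets == n_ab]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

# two-sided Fisher exact p via hypergeometric tail enumeration
brute_fisher <- function(m_case, n_case, m_ctrl, n_ctrl) {
  M <- m_case + m_ctrl
  dens <- stats::dhyper(0:M, n_case, n_ctrl, M)
  obs <- dens[m_case + 1]
  sum(dens[dens <= obs * (1 + 1e-7)])
}

# reference clumping: precomputed r2 matrix, explicit survivor bookkeeping
brute_clump <- function(ss, r2mat, window_bp) {
  alive <- rep(TRUE, nrow(ss))
  kept <- character(0)
  repeat {
    cand <- which(alive)
    if (!length(cand)) break
    o <- cand[order(ss$p[cand], ss$pos[cand], ss$id[cand])][1]
    kept <- c(kept, ss$id[o])
    alive[o] <- FALSE
    prune <- alive & ss$chrom == ss$chrom[o] &
      abs(ss$pos - ss$pos[o]) <= window_bp & r2mat[o, ] >= attr(r2mat, "thr")
    alive[prune] <- FALSE
  }
  kept
}

random_clump_instance <- function(seed) {
  set.seed(seed)
  m <- sample(2:50, 1)
  n <- 60
  dos <- matrix(rbinom(n * m, 2, runif(m, 0.1, 0.9)[rep(1:m, each = n)]), n, m)
  # plant some LD by copying columns with noise
  for (j in seq_len(m)) {
    if (j > 1 && runif(1) < 0.4) {
      src <- sample(j - 1, 1)
      flip <- runif(n) < 0.1
      dos[, j] <- ifelse(flip, rbinom(n, 2, 0.5), dos[, src])
    }
  }
  pos <- sort(sample.int(5e5, m))
  variants <- data.frame(id = sprintf("v%02d", 1:m), chrom = "1", pos = pos,
                         ref = "A", alt = "C",
                         frq = pmin(pmax(colMeans(dos) / 2, 0.01), 0.99),
                         stringsAsFactors = FALSE)
  g <- genotype_data(dos, variants, sprintf("s%02d", 1:n), hardcall = dos)
  ss <- data.frame(id = variants$id, chrom = "1", pos = pos,
                   a1 = "C", a2 = "A", beta = rnorm(m),
                   p = runif(m), frq = variants$frq, stringsAsFactors = FALSE)
  list(g = g, ss = ss)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# planted three-cluster battery matrix for clustering tests
planted_battery <- function(n_per = 30, miss = 0, seed = 1, sep = NULL) {
  set.seed(seed)
  arch <- default_archetypes()
  if (!is.null(sep)) arch <- arch / max(abs(arch)) * sep
  lab <- rep(1:3, each = n_per)
  x <- arch[lab, ] + matrix(rnorm(3 * n_per * ncol(arch)), 3 * n_per)
  if (miss > 0) x[matrix(runif(length(x)) < miss, nrow(x))] <- NA
  rownames(x) <- sprintf("c%03d", seq_len(nrow(x)))
  list(x = x, labels = lab)
}
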