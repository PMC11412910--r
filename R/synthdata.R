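#' Simulation configuration for the synthetic psychosis cohort
#'
#' Builds a validated configuration for the synthetic-data generator. The
#' defaults describe the study conditions the pipeline is exercised under: a
#' five-superpopulation reference panel with block LD, a 320-subject cohort
#' ascertained to 205 cases / 115 controls (SZ:SA:BP = 118:39:48), liability
#' heritability 0.5 with genetic variance concentrated in four
#' neurotransmitter pathways, a 12-measure endophenotype battery with three
#' planted archetypes separated by ~2 within-cluster SDs, and low rates of
#' injected genotype-QC defects.
#'
#' @param n_populations number of source populations (>= 2).
#' @param n_samples_per_pop reference-panel samples per population.
#' @param n_variants number of biallelic variants on the single simulated
#'   chromosome.
#' @param ld_block_size variants per LD block.
#' @param within_block_r latent (copula) correlation within an LD block,
#'   in [0, 1).
#' @param fst_drift Balding-Nichols drift parameter in (0, 1); 0 is accepted
#'   as the no-drift limit.
#' @param n_genes number of non-overlapping genes placed on the chromosome.
#' @param gene_length_distribution `c(min_bp, max_bp)` for gene lengths.
#' @param pathways named list; each element `list(n_genes=, overlap_fraction=)`.
#' @param h2_liability narrow-sense liability heritability in [0, 1].
#' @param pathway_effect_share named numeric: fraction of genetic variance
#'   placed in each pathway's genes; must sum to <= 1.
#' @param prevalence_threshold liability quantile below which a subject is a
#'   control; case fraction is `1 - prevalence_threshold`.
#' @param n_cohort cohort size.
#' @param diagnosis_weights unnormalized sampling weights for SZ/SA/BP among
#'   cases.
#' @param cluster_archetypes numeric matrix (archetypes x endophenotypes) of
#'   per-cluster endophenotype means on the z scale.
#' @param endo_missing_rate per-entry MCAR missingness for case
#'   endophenotypes.
#' @param endo_pathway_effects data.frame(endo, pathway, beta): standardized
#'   effect of each pathway genetic value on an endophenotype.
#' @param responder_rate base treatment-response rate among cases with
#'   follow-up data.
#' @param bprs_obs_rate fraction of cases with baseline/follow-up BPRS.
#' @param qc_defect_rates named numeric: `variant_missing`, `hwe_violation`,
#'   `related_pairs`, `low_info`, all in [0, 1].
#' @param gwas_n effective GWAS sample size controlling summary-statistic
#'   estimation noise.
#' @param seed integer seed; every generator draw derives from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_populations = 5,
                       n_samples_per_pop = 60,
                       n_variants = 8000,
                       ld_block_size = 10,
                       within_block_r = 0.9,
                       fst_drift = 0.05,
                       n_genes = 400,
                       gene_length_distribution = c(2000, 50000),
                       pathways = list(
                         glutamate = list(n_genes = 40, overlap_fraction = 0.1),
                         GABA      = list(n_genes = 40, overlap_fraction = 0.1),
                         dopamine  = list(n_genes = 40, overlap_fraction = 0.1),
                         serotonin = list(n_genes = 40, overlap_fraction = 0.1)
                       ),
                       h2_liability = 0.5,
                       pathway_effect_share = c(glutamate = 0.25, GABA = 0.20,
                                                dopamine = 0.10, serotonin = 0.05),
                       prevalence_threshold = 0.36,
                       n_cohort = 320,
                       diagnosis_weights = c(SZ = 118, SA = 39, BP = 48),
                       cluster_archetypes = default_archetypes(),
                       endo_missing_rate = 0.07,
                       endo_pathway_effects = default_endo_effects(),
                       responder_rate = 35 / 63,
                       bprs_obs_rate = 63 / 205,
                       qc_defect_rates = c(variant_missing = 0.02,
                                           hwe_violation = 0.01,
                                           related_pairs = 0.01,
                                           low_info = 0.02),
                       gwas_n = 1e5,
                       seed = 1L) {
  cfg <- list(n_populations = n_populations,
              n_samples_per_pop = n_samples_per_pop,
              n_variants = n_variants, ld_block_size = ld_block_size,
              within_block_r = within_block_r, fst_drift = fst_drift,
              n_genes = n_genes,
              gene_length_distribution = gene_length_distribution,
              pathways = pathways, h2_liability = h2_liability,
              pathway_effect_share = pathway_effect_share,
              prevalence_threshold = prevalence_threshold,
              n_cohort = n_cohort, diagnosis_weights = diagnosis_weights,
              cluster_archetypes = cluster_archetypes,
              endo_missing_rate = endo_missing_rate,
              endo_pathway_effects = endo_pathway_effects,
              responder_rate = responder_rate, bprs_obs_rate = bprs_obs_rate,
              qc_defect_rates = qc_defect_rates, gwas_n = gwas_n,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Default endophenotype battery names
#' @return Character vector of the 12 battery measures.
#' @export
endo_battery <- function() {
  c("reality_distortion", "poverty_symptoms", "disorganization",
    "gaf", "gsf", "grf", "ymrs", "sans_total", "saps_total",
    "dprime_context", "dlpfc_beta", "spc_beta")
}

#' Default cluster archetypes
#'
#' Three endophenotype archetypes on the z scale: (1) mania / reality
#' distortion / disorganization with moderate cognitive-control impairment,
#' (2) poverty symptoms with poor social/role functioning and the strongest
#' cognitive-control deficits, (3) low pathology. Higher = worse for symptom
#' scales, higher = better for functioning and cognitive measures. The
#' pattern matrix is rescaled so the minimum pairwise centroid separation
#' equals two within-cluster standard deviations in the full battery metric
#' (within-cluster SD = sqrt(n_measures) under unit per-measure noise).
#' @return 3 x 12 numeric matrix with endophenotype column names.
#' @export
default_archetypes <- function() {
  m <- rbind(
    c(1.8, 0.0, 1.8, -0.8,  0.0,  0.0, 2.0, 0.0, 1.5, -0.8, -0.8, -0.8),
    c(0.0, 2.0, 0.5, -1.5, -1.8, -1.8, 0.0, 1.8, 0.0, -1.8, -1.8, -1.8),
    c(0.0, 0.0, 0.0,  0.0,  0.0,  0.0, 0.0, 0.0, 0.0,  0.0,  0.0,  0.0)
  )
  min_sep <- min(stats::dist(m))
  m <- m * 2 * sqrt(ncol(m)) / min_sep
  colnames(m) <- endo_battery()
  m
}

#' Default pathway-to-endophenotype effects
#'
#' Standardized effects of pathway genetic values on case endophenotypes:
#' dopamine load lowers global and role functioning; glutamate load lowers
#' cognitive-control performance and task-evoked DLPFC/SPC activation.
#' @return data.frame with columns endo, pathway, beta.
#' @export
default_endo_effects <- function() {
  data.frame(
    endo    = c("gaf", "grf", "dprime_context", "dlpfc_beta", "spc_beta"),
    pathway = c("dopamine", "dopamine", "glutamate", "glutamate", "glutamate"),
    beta    = c(-0.20, -0.20, -0.20, -0.25, -0.20),
    stringsAsFactors = FALSE
  )
}

validate_sim_config <- function(cfg) {
  bad <- function(field, msg) stop("invalid sim_config field '", field, "': ", msg,
                                   call. = FALSE)
  chk_rate <- function(x, field) {
    if (!is.numeric(x) || any(is.na(x)) || any(x < 0 | x > 1)) bad(field, "must be in [0, 1]")
  }
  if (cfg$n_populations < 1) bad("n_populations", "must be >= 1")
  if (cfg$n_variants < 1) bad("n_variants", "must be >= 1")
  if (cfg$ld_block_size < 1) bad("ld_block_size", "must be >= 1")
  if (cfg$within_block_r < 0 || cfg$within_block_r >= 1)
    bad("within_block_r", "must be in [0, 1)")
  if (cfg$fst_drift < 0 || cfg$fst_drift >= 1) bad("fst_drift", "must be in [0, 1)")
  if (length(cfg$gene_length_distribution) != 2 ||
      cfg$gene_length_distribution[1] > cfg$gene_length_distribution[2] ||
      cfg$gene_length_distribution[1] < 1)
    bad("gene_length_distribution", "must be (min_bp, max_bp) with 1 <= min <= max")
  chk_rate(cfg$h2_liability, "h2_liability")
  chk_rate(cfg$pathway_effect_share, "pathway_effect_share")
  if (sum(cfg$pathway_effect_share) > 1 + 1e-12)
    bad("pathway_effect_share", "shares must sum to <= 1")
  if (!all(names(cfg$pathway_effect_share) %in% names(cfg$pathways)))
    bad("pathway_effect_share", "names must be a subset of pathway names")
  if (cfg$prevalence_threshold <= 0 || cfg$prevalence_threshold >= 1)
    bad("prevalence_threshold", "must be in (0, 1)")
  if (!is.matrix(cfg$cluster_archetypes) || nrow(cfg$cluster_archetypes) < 1)
    bad("cluster_archetypes", "must be a matrix with >= 1 row")
  chk_rate(cfg$endo_missing_rate, "endo_missing_rate")
  chk_rate(cfg$qc_defect_rates, "qc_defect_rates")
  if (!all(c("variant_missing", "hwe_violation", "related_pairs", "low_info")
           %in% names(cfg$qc_defect_rates)))
    bad("qc_defect_rates", "must name variant_missing, hwe_violation, related_pairs, low_info")
  chk_rate(cfg$responder_rate, "responder_rate")
  chk_rate(cfg$bprs_obs_rate, "bprs_obs_rate")
  for (p in cfg$pathways) {
    if (p$n_genes > cfg$n_genes) bad("pathways", "pathway larger than gene universe")
    chk_rate(p$overlap_fraction, "pathways$overlap_fraction")
  }
  invisible(cfg)
}

pop_label_set <- function(k) {
  std <- c("AFR", "AMR", "EAS", "EUR", "SAS")
  if (k <= 5) std[seq_len(k)] else c(std, sprintf("POP%d", 6:k))
}

# Cohort superpopulation mix, loosely matching a US early-psychosis catchment.
pop_cohort_weights <- function(k) {
  std <- c(AFR = 0.24, AMR = 0.09, EAS = 0.13, EUR = 0.50, SAS = 0.04)
  if (k <= 5) {
    w <- std[seq_len(k)]
  } else {
    w <- c(std, rep(0.02, k - 5))
  }
  w / sum(w)
}

chrom_length <- function(cfg) {
  max(ceiling(cfg$n_genes * mean(cfg$gene_length_distribution) * 1.3),
      cfg$n_variants * 10L)
}

# Block-correlated genotypes via a Gaussian copula: two latent haplotype
# fields with equicorrelation inside consecutive blocks, thresholded at the
# population allele frequency. The latent correlation is inflated by the
# tetrachoric map rho = sin(pi * r / 2) so the realized genotype correlation
# approximates the requested r at mid frequencies (thresholding attenuates
# latent correlation; without the correction r = 0.7 blocks land near
# genotype r^2 of 0.3 and LD clumping never fires).
sim_block_genotypes <- function(n, p, r, block_size) {
  m <- length(p)
  n_blocks <- ceiling(m / block_size)
  block_of <- rep(seq_len(n_blocks), each = block_size)[seq_len(m)]
  rho <- sin(pi * r / 2)
  thr <- matrix(stats::qnorm(p), n, m, byrow = TRUE)
  hap <- function() {
    u <- matrix(stats::rnorm(n * n_blocks), n, n_blocks)
    z <- sqrt(rho) * u[, block_of, drop = FALSE] +
      sqrt(1 - rho) * matrix(stats::rnorm(n * m), n, m)
    (z < thr) * 1L
  }
  hap() + hap()
}

#' Simulate a multi-population reference panel
#'
#' Draws per-population allele frequencies by Balding-Nichols drift from
#' shared ancestral frequencies and generates hard-call genotypes with
#' block-diagonal LD (Gaussian copula, equicorrelated within consecutive
#' blocks of `ld_block_size` variants).
#'
#' @param cfg a [sim_config()].
#' @return list with `panel` (a [genotype_data()] carrying `pop_freqs` for
#'   later cohort draws) and `pop_labels` (per-sample population).
#' @export
simulate_reference_panel <- function(cfg) {
  validate_sim_config(cfg)
  if (cfg$n_populations < 2)
    stop("invalid sim_config field 'n_populations': reference panel needs >= 2 populations")
  set.seed(cfg$seed)
  m <- cfg$n_variants
  p0 <- stats::runif(m, 0.05, 0.95)
  f <- cfg$fst_drift
  labs <- pop_label_set(cfg$n_populations)
  pop_freqs <- sapply(labs, function(l) {
    if (f == 0) p0 else {
      pk <- stats::rbeta(m, p0 * (1 - f) / f, (1 - p0) * (1 - f) / f)
      pmin(pmax(pk, 1e-4), 1 - 1e-4)
    }
  })
  pos <- sort(sample.int(chrom_length(cfg), m))
  pairs <- rbind(c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
                 c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))
  al <- pairs[sample.int(nrow(pairs), m, replace = TRUE), , drop = FALSE]
  n <- cfg$n_samples_per_pop
  dos <- do.call(rbind, lapply(seq_along(labs), function(k) {
    sim_block_genotypes(n, pop_freqs[, k], cfg$within_block_r, cfg$ld_block_size)
  }))
  pop_labels <- rep(labs, each = n)
  variants <- data.frame(
    id = sprintf("snp%05d", seq_len(m)), chrom = "1", pos = pos,
    ref = al[, 1], alt = al[, 2],
    frq = colMeans(dos) / 2, stringsAsFactors = FALSE
  )
  panel <- genotype_data(dos, variants,
                         sample_ids = sprintf("ref%04d", seq_len(nrow(dos))),
                         hardcall = dos,
                         info = rep(1, m), emp_info = rep(1, m))
  panel$pop_freqs <- pop_freqs
  list(panel = panel, pop_labels = pop_labels)
}

#' Simulate gene annotation and pathway gene sets
#'
#' Places `n_genes` non-overlapping genes on the simulated chromosome
#' (0-based half-open intervals) and draws named pathways of the configured
#' sizes. `overlap_fraction` of each pathway is taken from a common shared
#' pool, so pathways may share genes (overlap 0 gives pairwise-disjoint sets,
#' overlap 1 with equal sizes gives identical sets).
#'
#' @param cfg a [sim_config()].
#' @return list with `annotation` (data.frame gene_id, chrom, start, end,
#'   length) and `pathways` (named list of gene-id vectors).
#' @export
simulate_gene_annotation <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed + 1L)
  rng <- cfg$gene_length_distribution
  lens <- floor(stats::runif(cfg$n_genes, rng[1], rng[2] + 1))
  L <- chrom_length(cfg)
  slack <- L - sum(lens)
  if (slack < cfg$n_genes)
    stop("genes do not fit on the simulated chromosome without overlap")
  g <- stats::runif(cfg$n_genes + 1)
  gaps <- floor(slack * g / sum(g))
  starts <- cumsum(gaps[seq_len(cfg$n_genes)]) +
    c(0, cumsum(lens[-cfg$n_genes]))
  annotation <- data.frame(
    gene_id = sprintf("gene%04d", seq_len(cfg$n_genes)),
    chrom = "1", start = starts, end = starts + lens,
    length = lens, stringsAsFactors = FALSE
  )
  n_shared <- vapply(cfg$pathways,
                     function(p) round(p$overlap_fraction * p$n_genes), 0)
  shared_pool <- sample(annotation$gene_id, max(c(n_shared, 0)))
  exclusive_pool <- setdiff(annotation$gene_id, shared_pool)
  pathways <- list()
  for (nm in names(cfg$pathways)) {
    k <- n_shared[[nm]]
    n_excl <- cfg$pathways[[nm]]$n_genes - k
    if (n_excl > length(exclusive_pool))
      stop("pathway '", nm, "' larger than remaining gene universe")
    excl <- if (n_excl > 0) sample(exclusive_pool, n_excl) else character(0)
    exclusive_pool <- setdiff(exclusive_pool, excl)
    pathways[[nm]] <- sort(c(shared_pool[seq_len(k)], excl))
  }
  list(annotation = annotation, pathways = pathways)
}

#' Simulate GWAS summary statistics with pathway-concentrated effects
#'
#' True liability-scale effects are drawn so the configured share of genetic
#' variance (measured empirically on the reference panel) lies in SNPs inside
#' each pathway's genes; total genetic variance is rescaled to
#' `h2_liability`. Reported betas add estimation noise at the configured GWAS
#' sample size; p-values are consistent with reported beta/SE.
#'
#' @param panel reference [genotype_data()] from [simulate_reference_panel()].
#' @param annotation,pathways from [simulate_gene_annotation()].
#' @param cfg a [sim_config()].
#' @return list with `sumstats` (data.frame id, chrom, pos, a1, a2, beta, se,
#'   p, frq; a1 is the effect allele = alt) and `truth` (causal ids, true
#'   betas, per-pathway causal components).
#' @export
simulate_sumstats <- function(panel, annotation, pathways, cfg) {
  validate_sim_config(cfg)
  shares <- cfg$pathway_effect_share
  if (cfg$h2_liability == 0 && any(shares > 0))
    stop("h2_liability = 0 is incompatible with nonzero pathway_effect_share")
  set.seed(cfg$seed + 2L)
  v <- panel$variants
  m <- nrow(v)
  true_beta <- numeric(m)
  xc <- sweep(panel$dosage, 2, colMeans(panel$dosage))
  components <- list()
  assigned <- logical(m)
  h2 <- cfg$h2_liability
  if (h2 > 0) {
    for (nm in names(pathways)) {
      share <- if (nm %in% names(shares)) shares[[nm]] else 0
      idx <- setdiff(which(v$id %in% snps_in_genes(v, annotation, pathways[[nm]])),
                     which(assigned))
      if (share > 0 && length(idx) == 0)
        stop("pathway '", nm, "' has no SNPs to carry its effect share")
      b <- stats::rnorm(length(idx))
      if (share > 0 && length(idx) > 0) {
        gv <- xc[, idx, drop = FALSE] %*% b
        b <- b * sqrt(share * h2 / max(stats::var(as.vector(gv)), 1e-12))
      } else b <- b * 0
      true_beta[idx] <- b
      assigned[idx] <- TRUE
      components[[nm]] <- list(idx = idx)
    }
    bg_share <- 1 - sum(shares)
    bg_pool <- which(!assigned)
    n_bg <- round(0.2 * length(bg_pool))
    if (bg_share > 0 && n_bg > 0) {
      idx <- sort(sample(bg_pool, n_bg))
      b <- stats::rnorm(length(idx))
      gv <- xc[, idx, drop = FALSE] %*% b
      b <- b * sqrt(bg_share * h2 / max(stats::var(as.vector(gv)), 1e-12))
      true_beta[idx] <- b
      components[["background"]] <- list(idx = idx)
    }
    # pin the empirical panel heritability exactly at h2
    g_tot <- as.vector(xc %*% true_beta)
    sc <- sqrt(h2 / max(stats::var(g_tot), 1e-12))
    true_beta <- true_beta * sc
  }
  se <- 1 / sqrt(2 * pmax(v$frq * (1 - v$frq), 1e-4) * cfg$gwas_n)
  beta_hat <- true_beta + stats::rnorm(m, 0, se)
  z <- beta_hat / se
  p <- pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
  sumstats <- data.frame(id = v$id, chrom = v$chrom, pos = v$pos,
                         a1 = v$alt, a2 = v$ref,
                         beta = beta_hat, se = se, p = p, frq = v$frq,
                         stringsAsFactors = FALSE)
  truth <- list(causal_ids = v$id[true_beta != 0],
                true_beta = stats::setNames(true_beta, v$id),
                components = lapply(components, function(cp)
                  list(ids = v$id[cp$idx])),
                h2_liability = h2)
  list(sumstats = sumstats, truth = truth)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulate the phenotyped study cohort with injected QC defects
#'
#' Draws cohort genotypes from the panel's population process (cohort
#' superpopulation mix weighted like a diverse catchment), computes
#' liability = genetic value + Gaussian environment, thresholds it at the
#' configured quantile for case status, assigns SZ/SA/BP diagnoses among
#' cases, generates the 12-measure endophenotype battery from the planted
#' cluster archetypes plus scaled pathway genetic contributions, masks
#' endophenotypes MCAR, generates baseline/follow-up BPRS for a subset of
#' cases (response probability tied to dopamine pathway load), and injects
#' genotype-QC defects: variant missingness above the QC threshold,
#' heterozygote-free HWE violations, near-duplicate related pairs, and
#' low-INFO variants.
#'
#' @param panel reference panel list from [simulate_reference_panel()].
#' @param ss output of [simulate_sumstats()].
#' @param annotation_pathways output of [simulate_gene_annotation()].
#' @param cfg a [sim_config()].
#' @return list with `genotypes` ([genotype_data()]), `pheno` (data.frame),
#'   and `truth` (ground-truth list extending the sumstats truth).
#' @export
simulate_cohort <- function(panel, ss, annotation_pathways, cfg) {
  validate_sim_config(cfg)
  if (nrow(cfg$cluster_archetypes) >= 1 &&
      ncol(cfg$cluster_archetypes) != length(endo_battery()))
    stop("cluster_archetypes must have ", length(endo_battery()),
         " columns (one per endophenotype)")
  set.seed(cfg$seed + 3L)
  g_panel <- panel$panel
  pf <- g_panel$pop_freqs
  labs <- colnames(pf)
  n <- cfg$n_cohort
  pops <- sample(labs, n, replace = TRUE, prob = pop_cohort_weights(length(labs)))
  m <- nrow(g_panel$variants)
  dos <- matrix(0L, n, m)
  for (k in seq_along(labs)) {
    idx <- which(pops == labs[k])
    if (length(idx))
      dos[idx, ] <- sim_block_genotypes(length(idx), pf[, k],
                                        cfg$within_block_r, cfg$ld_block_size)
  }
  true_beta <- ss$truth$true_beta
  xc <- sweep(dos, 2, 2 * ss$sumstats$frq)
  gvalue <- as.vector(xc %*% true_beta)
  h2 <- cfg$h2_liability
  liab <- gvalue + stats::rnorm(n, 0, sqrt(max(1 - h2, 0)))
  thr <- stats::qnorm(cfg$prevalence_threshold, mean(liab), stats::sd(liab))
  status <- as.integer(liab > thr)
  n_case <- sum(status)
  diag <- rep("CTRL", n)
  dw <- cfg$diagnosis_weights
  diag[status == 1] <- sample(names(dw), n_case, replace = TRUE, prob = dw / sum(dw))

  sex <- ifelse(stats::runif(n) < ifelse(status == 1, 0.77, 0.58), "M", "F")
  age <- round(stats::rnorm(n, 19.7, 4.1), 1)
  race <- sample(c("Black", "Asian", "White", "Other"), n, TRUE,
                 prob = c(0.11, 0.13, 0.60, 0.16))
  ethnicity <- sample(c("Hispanic", "NonHispanic", "Unknown"), n, TRUE,
                      prob = c(0.21, 0.77, 0.02))
  scanner <- sample(c("scannerA", "scannerB"), n, TRUE)

  # per-pathway genetic values in the cohort, standardized
  comp_z <- sapply(names(annotation_pathways$pathways), function(nm) {
    ids <- ss$truth$components[[nm]]$ids
    if (is.null(ids) || !length(ids)) return(rep(0, n))
    j <- match(ids, g_panel$variants$id)
    gv <- as.vector(xc[, j, drop = FALSE] %*% true_beta[ids])
    if (stats::sd(gv) > 0) as.vector(scale(gv)) else gv
  })

  ncl <- nrow(cfg$cluster_archetypes)
  true_cluster <- rep(NA_integer_, n)
  true_cluster[status == 1] <- sample.int(ncl, n_case, replace = TRUE)
  d <- length(endo_battery())
  endo <- matrix(NA_real_, n, d, dimnames = list(NULL, endo_battery()))
  ci <- which(status == 1)
  endo[ci, ] <- cfg$cluster_archetypes[true_cluster[ci], , drop = FALSE] +
    matrix(stats::rnorm(n_case * d), n_case, d)
  ef <- cfg$endo_pathway_effects
  if (!is.null(ef) && nrow(ef)) {
    for (r in seq_len(nrow(ef))) {
      if (!ef$pathway[r] %in% colnames(comp_z)) next
      endo[ci, ef$endo[r]] <- endo[ci, ef$endo[r]] +
        ef$beta[r] * comp_z[ci, ef$pathway[r]]
    }
  }
  endo[ci, ][stats::runif(n_case * d) < cfg$endo_missing_rate] <- NA

  # raw instrument fields so derive_endophenotypes() has work to do
  gsf_target <- clamp(round(2 * (7 + 1.5 * endo[, "gsf"])) / 2, 1, 10)
  grf_target <- clamp(round(2 * (7 + 1.5 * endo[, "grf"])) / 2, 1, 10)
  spread <- sample(0:1, n, replace = TRUE)
  pack_meas <- function(target, spread) {
    vapply(seq_along(target), function(i) {
      if (is.na(target[i])) return("")
      lo <- max(target[i] - spread[i], 1); hi <- min(target[i] + spread[i], 10)
      mid <- (lo + hi) / 2  # (max+min)/2 recovers this exactly
      paste(c(lo, mid, hi), collapse = ";")
    }, "")
  }
  gsf_values <- pack_meas(gsf_target, spread)
  grf_values <- pack_meas(grf_target, spread)
  ymrs_total <- clamp(round(10 + 4 * endo[, "ymrs"]), 0, 40)
  ymrs_items <- matrix(NA_integer_, n, 11,
                       dimnames = list(NULL, sprintf("ymrs_item_%d", 1:11)))
  ok <- which(!is.na(ymrs_total))
  for (i in ok) {
    tot <- ymrs_total[i]
    base <- tot %/% 10
    extra <- tot %% 10
    it <- rep(base, 10)
    if (extra > 0) it[seq_len(extra)] <- it[seq_len(extra)] + 1L
    ymrs_items[i, ] <- append(it, sample(0:4, 1), after = 7)  # item 8 = content
  }

  # BPRS baseline / follow-up for a case subset; response tied to dopamine load
  bprs_baseline <- rep(NA_integer_, n)
  bprs_followup <- rep(NA_integer_, n)
  responder_truth <- rep(NA, n)
  n_bprs <- round(cfg$bprs_obs_rate * n_case)
  bi <- if (n_bprs > 0) sample(ci, n_bprs) else integer(0)
  if (length(bi)) {
    dopa <- if ("dopamine" %in% colnames(comp_z)) comp_z[bi, "dopamine"] else rep(0, length(bi))
    pr <- stats::plogis(stats::qlogis(cfg$responder_rate) + 0.5 * dopa)
    resp <- stats::runif(length(bi)) < pr
    base_rs <- sample(10:45, length(bi), replace = TRUE)
    fu_rs <- integer(length(bi))
    drop_f <- stats::runif(length(bi), 0.25, 0.60)
    hold_f <- stats::runif(length(bi), -0.20, 0.15)
    fu_rs[resp] <- pmax(floor(base_rs[resp] * (1 - drop_f[resp])), 0)
    fu_rs[!resp] <- ceiling(base_rs[!resp] * (1 - hold_f[!resp]))
    bprs_baseline[bi] <- base_rs + 24L
    bprs_followup[bi] <- fu_rs + 24L
    responder_truth[bi] <- resp
  }

  # ---- QC defect injection (disjoint variant sets) ----
  rates <- cfg$qc_defect_rates
  hard <- dos
  pool <- seq_len(m)
  n_vm <- round(rates[["variant_missing"]] * m)
  vm_idx <- if (n_vm > 0) sort(sample(pool, n_vm)) else integer(0)
  pool <- setdiff(pool, vm_idx)
  n_hwe <- round(rates[["hwe_violation"]] * m)
  hwe_pool <- intersect(pool, which(g_panel$variants$frq > 0.2 &
                                      g_panel$variants$frq < 0.8))
  hwe_idx <- if (n_hwe > 0) sort(sample(hwe_pool, min(n_hwe, length(hwe_pool)))) else integer(0)
  pool <- setdiff(pool, hwe_idx)
  n_li <- round(rates[["low_info"]] * m)
  li_idx <- if (n_li > 0) sort(sample(pool, n_li)) else integer(0)

  n_rel <- round(rates[["related_pairs"]] * n)
  related_pairs <- NULL
  if (n_rel > 0) {
    picks <- sample.int(n, 2 * n_rel)
    related_pairs <- matrix(picks, ncol = 2, byrow = TRUE)
    for (r in seq_len(n_rel)) {
      a <- related_pairs[r, 1]; b <- related_pairs[r, 2]
      dup <- dos[a, ]
      flip <- which(stats::runif(m) < 0.02)
      dup[flip] <- stats::rbinom(length(flip), 2, g_panel$variants$frq[flip])
      dos[b, ] <- dup
      hard[b, ] <- dup
    }
  }
  for (j in hwe_idx) {
    p <- g_panel$variants$frq[j]
    gval <- 2L * stats::rbinom(n, 1, p)  # no heterozygotes
    dos[, j] <- gval; hard[, j] <- gval
  }
  storage.mode(dos) <- "double"
  for (j in vm_idx) {
    miss <- stats::runif(n) < stats::runif(1, 0.07, 0.15)
    dos[miss, j] <- NA; hard[miss, j] <- NA
  }
  info <- stats::runif(m, 0.85, 1)
  emp_info <- stats::runif(m, 0.9, 1)
  if (length(li_idx)) {
    half <- seq_along(li_idx) %% 2 == 0
    info[li_idx[half]] <- stats::runif(sum(half), 0.3, 0.69)
    emp_info[li_idx[!half]] <- stats::runif(sum(!half), 0.3, 0.79)
  }

  sample_ids <- sprintf("subj%04d", seq_len(n))
  pheno <- data.frame(sample_id = sample_ids, status = status,
                      diagnosis = diag, sex = sex, age = age, race = race,
                      ethnicity = ethnicity, scanner = scanner,
                      stringsAsFactors = FALSE)
  pass <- setdiff(endo_battery(), c("gsf", "grf", "ymrs"))
  pheno[pass] <- endo[, pass]
  pheno$gsf_values <- gsf_values
  pheno$grf_values <- grf_values
  pheno <- cbind(pheno, as.data.frame(ymrs_items))
  pheno$bprs_baseline <- bprs_baseline
  pheno$bprs_followup <- bprs_followup

  geno <- genotype_data(dos, g_panel$variants, sample_ids,
                        hardcall = hard, info = info, emp_info = emp_info)
  geno$pop_freqs <- pf
  truth <- ss$truth
  truth$liability <- liab
  truth$status <- status
  truth$pop_labels <- pops
  truth$true_cluster <- true_cluster
  truth$responder <- responder_truth
  truth$related_pairs <- if (!is.null(related_pairs))
    matrix(sample_ids[related_pairs], ncol = 2) else NULL
  truth$defect_variants <- list(
    variant_missing = g_panel$variants$id[vm_idx],
    hwe_violation = g_panel$variants$id[hwe_idx],
    low_info = g_panel$variants$id[li_idx]
  )
  list(genotypes = geno, pheno = pheno, truth = truth)
}

#' Run the full generator
#'
#' Convenience wrapper: reference panel, gene annotation + pathways, summary
#' statistics, and phenotyped cohort from one configuration.
#'
#' @param cfg a [sim_config()].
#' @return list with `panel`, `pop_labels`, `annotation`, `pathways`,
#'   `sumstats`, `cohort` (genotypes/pheno), and `truth`.
#' @export
simulate_study <- function(cfg) {
  ref <- simulate_reference_panel(cfg)
  ann <- simulate_gene_annotation(cfg)
  ss <- simulate_sumstats(ref$panel, ann$annotation, ann$pathways, cfg)
  coh <- simulate_cohort(ref, ss, ann, cfg)
  list(panel = ref$panel, pop_labels = ref$pop_labels,
       annotation = ann$annotation, pathways = ann$pathways,
       sumstats = ss$sumstats, cohort = coh[c("genotypes", "pheno")],
       truth = coh$truth)
}
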