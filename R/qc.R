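#' Remove variants with excess missingness
#'
#' Retains variants whose missing-call fraction is at most `max_missing`
#' (boundary kept; the removal rule is strictly greater, matching a "> 5%
#' removed" convention). Variant order is preserved.
#'
#' @param g [genotype_data()].
#' @param max_missing maximum tolerated missing fraction (default 0.05).
#' @return Filtered [genotype_data()].
#' @export
filter_variant_missingness <- function(g, max_missing = 0.05) {
  stopifnot(max_missing >= 0, max_missing <= 1)
  if (!nrow(g$variants) || !length(g$sample_ids)) stop("empty genotype data")
  miss <- colMeans(is.na(g$dosage))
  subset_genotypes(g, variants = miss <= max_missing)
}

#' Flag samples with excess missingness
#'
#' Flags (does not remove) samples whose fraction of missing variants exceeds
#' `max_missing`; removal is the caller's choice.
#'
#' @param g [genotype_data()].
#' @param max_missing threshold (default 0.01).
#' @return Named logical vector, TRUE = flagged.
#' @export
check_sample_missingness <- function(g, max_missing = 0.01) {
  miss <- rowMeans(is.na(g$dosage))
  stats::setNames(miss > max_missing, g$sample_ids)
}

#' Differential (case/control) missingness test
#'
#' For each variant, a two-sided Fisher exact test on the 2x2 table of
#' missing/observed by case/control.
#'
#' @param g [genotype_data()].
#' @param case_status 0/1 vector, one per sample.
#' @return Numeric vector of p-values, one per variant (1 when the variant
#'   has no missingness).
#' @export
test_differential_missingness <- function(g, case_status) {
  case_status <- as.integer(case_status)
  if (length(unique(case_status)) < 2)
    stop("both cases and controls are required for the differential test")
  is_case <- case_status == 1
  n_ca <- sum(is_case); n_co <- sum(!is_case)
  miss <- is.na(g$dosage)
  m_ca <- colSums(miss[is_case, , drop = FALSE])
  m_co <- colSums(miss[!is_case, , drop = FALSE])
  vapply(seq_along(m_ca), function(j) {
    if (m_ca[j] + m_co[j] == 0) return(1)
    stats::fisher.test(matrix(c(m_ca[j], n_ca - m_ca[j],
                                m_co[j], n_co - m_co[j]), 2))$p.value
  }, 0)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact two-sided HWE p-value per variant by full enumeration of
#' heterozygote counts conditional on the observed allele counts
#' (Wigginton-style): p = sum of probabilities of all heterozygote counts
#' whose conditional probability does not exceed the observed one. Computed
#' from hard-call genotypes; missing calls are dropped per variant.
#'
#' @param g [genotype_data()] with `hardcall` populated, or a 3-column matrix
#'   of genotype counts (AA, Aa, aa).
#' @return Numeric vector of p-values (1 for monomorphic variants; NA with a
#'   warning for dosage-only variants).
#' @export
test_hwe <- function(g) {
  if (inherits(g, "genotype_data")) {
    if (is.null(g$hardcall)) {
      warning("hard-call genotypes unavailable; HWE test skipped")
      return(rep(NA_real_, nrow(g$variants)))
    }
    hc <- g$hardcall
    counts <- t(vapply(seq_len(ncol(hc)), function(j) {
      x <- hc[, j]
      c(sum(x == 0, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
        sum(x == 2, na.rm = TRUE))
    }, numeric(3)))
  } else counts <- as.matrix(g)
  apply(counts, 1, function(cc) hwe_exact_p(cc[1], cc[2], cc[3]))
}

#' Exact HWE p for one genotype table
#'
#' @param n_aa,n_ab,n_bb genotype counts (major hom, het, minor hom order is
#'   irrelevant).
#' @return Two-sided exact p-value.
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  rare <- min(n_a, n_b)
  if (rare == 0) return(1)  # monomorphic: single possible table
  # heterozygote count shares parity with the rare-allele count
  hets <- seq(rare %% 2, rare, by = 2)
  # log conditional probability of each heterozygote count given allele counts
  lp <- vapply(hets, function(h) {
    ra <- (rare - h) / 2          # rare homozygotes
    ca <- (n - h - ra)            # common homozygotes
    lgamma(n + 1) - lgamma(ra + 1) - lgamma(ca + 1) - lgamma(h + 1) +
      h * log(2) - (lgamma(2 * n + 1) - lgamma(n_a + 1) - lgamma(n_b + 1))
  }, 0)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- which(hets == n_ab)
  min(1, sum(pr[pr <= pr[obs] * (1 + 1e-12)]))
}

#' Find related sample pairs
#'
#' Pairwise relatedness over a thinned subset of at most `max_variants`
#' evenly spaced variants. With hard calls available the statistic is twice
#' the KING-robust kinship estimator,
#' 2 * (N_het,het - 2 N_opposite-hom) / (N_het_i + N_het_j),
#' which is 1 for duplicate genomes, ~0.5 for first-degree relatives, ~0 for
#' unrelated pairs, and — unlike genome-wide dosage correlation — is not
#' inflated by shared ancestry in a structured cohort. Dosage-only data fall
#' back to mean-centered dosage correlation. Pairs at or above `threshold`
#' are reported and one member of each related component is retained, the
#' rest marked for exclusion by a seeded RNG.
#'
#' @param g [genotype_data()].
#' @param threshold relatedness above which a pair is called related
#'   (default 0.2, i.e. closer than second degree).
#' @param max_variants thinning bound (default 5000).
#' @param seed seed for the random choice of excluded members.
#' @return list(pairs = data.frame(sample1, sample2, r), exclude = character
#'   vector of sample ids).
#' @export
find_related_pairs <- function(g, threshold = 0.2, max_variants = 5000,
                               seed = 1L) {
  if (length(g$sample_ids) < 2)
    return(list(pairs = data.frame(sample1 = character(0),
                                   sample2 = character(0), r = numeric(0)),
                exclude = character(0)))
  m <- nrow(g$variants)
  keep <- if (m > max_variants)
    round(seq(1, m, length.out = max_variants)) else seq_len(m)
  if (!is.null(g$hardcall)) {
    hc <- g$hardcall[, keep, drop = FALSE]
    obs <- (!is.na(hc)) * 1
    het <- (hc == 1); het[is.na(het)] <- FALSE; het <- het * 1
    aa <- (hc == 0); aa[is.na(aa)] <- FALSE; aa <- aa * 1
    bb <- (hc == 2); bb[is.na(bb)] <- FALSE; bb <- bb * 1
    n_hh <- tcrossprod(het)
    n_opp <- tcrossprod(aa, bb); n_opp <- n_opp + t(n_opp)
    n_het_pair <- tcrossprod(het, obs) + tcrossprod(obs, het)
    r <- 2 * (n_hh - 2 * n_opp) / pmax(n_het_pair, 1)
  } else {
    xs <- g$dosage[, keep, drop = FALSE]
    xs <- sweep(xs, 2, colMeans(xs, na.rm = TRUE))
    xs[is.na(xs)] <- 0
    r <- suppressWarnings(stats::cor(t(xs)))
    r[is.na(r)] <- 0
  }
  diag(r) <- 0
  idx <- which(r >= threshold & upper.tri(r), arr.ind = TRUE)
  pairs <- data.frame(sample1 = g$sample_ids[idx[, 1]],
                      sample2 = g$sample_ids[idx[, 2]],
                      r = r[idx], stringsAsFactors = FALSE)
  exclude <- character(0)
  if (nrow(pairs)) {
    set.seed(seed)
    remaining <- pairs
    while (nrow(remaining)) {
      drop <- if (stats::runif(1) < 0.5) remaining$sample1[1] else remaining$sample2[1]
      exclude <- c(exclude, drop)
      remaining <- remaining[remaining$sample1 != drop &
                               remaining$sample2 != drop, , drop = FALSE]
    }
  }
  list(pairs = pairs, exclude = exclude)
}

#' Remove variants with poor imputation quality
#'
#' Retains variants with INFO >= `min_info` and empirical INFO >=
#' `min_emp_info` (boundaries kept; removal is strictly below, matching an
#' "INFO < 0.7 removed" convention).
#'
#' @param g [genotype_data()] with `info` and `emp_info` populated.
#' @param min_info,min_emp_info thresholds (defaults 0.7 and 0.8).
#' @return Filtered [genotype_data()].
#' @export
filter_info <- function(g, min_info = 0.7, min_emp_info = 0.8) {
  if (is.null(g$info)) stop("genotype data lacks the 'info' field")
  if (is.null(g$emp_info)) stop("genotype data lacks the 'emp_info' field")
  subset_genotypes(g, variants = g$info >= min_info & g$emp_info >= min_emp_info)
}

#' Run the full genotype QC chain
#'
#' Applies, in order: variant missingness, differential case/control
#' missingness, exact HWE, relatedness exclusion, INFO filters. Each step's
#' removals and parameters are recorded in an auditable report. A sex-check
#' no-op step is recorded for completeness (the synthetic data is
#' autosomal-only).
#'
#' @param g [genotype_data()].
#' @param case_status 0/1 per sample.
#' @param max_missing variant missingness threshold (default 0.05).
#' @param diff_missing_p differential-missingness removal p (default 0.001).
#' @param hwe_p HWE removal p (default 1e-6).
#' @param relatedness_threshold correlation threshold (default 0.2).
#' @param min_info,min_emp_info INFO thresholds (defaults 0.7, 0.8).
#' @param sample_missing sample-missingness flag threshold (default 0.01).
#' @param seed seed for the related-pair exclusion draw.
#' @return list(genotypes = filtered [genotype_data()], report = `qc_report`
#'   data.frame with step, n_variants_removed, n_samples_removed, parameters).
#' @export
run_qc <- function(g, case_status, max_missing = 0.05, diff_missing_p = 0.001,
                   hwe_p = 1e-6, relatedness_threshold = 0.2,
                   min_info = 0.7, min_emp_info = 0.8,
                   sample_missing = 0.01, seed = 1L) {
  steps <- list()
  note <- function(name, nv, ns, par) {
    steps[[length(steps) + 1]] <<- data.frame(
      step = name, n_variants_removed = nv, n_samples_removed = ns,
      parameters = par, stringsAsFactors = FALSE)
  }
  n0v <- nrow(g$variants); n0s <- length(g$sample_ids)

  g1 <- filter_variant_missingness(g, max_missing)
  note("variant_missingness", n0v - nrow(g1$variants), 0,
       sprintf("max_missing=%g", max_missing))

  flags <- check_sample_missingness(g1, sample_missing)
  note("sample_missingness_flags", 0, 0,
       sprintf("max_missing=%g; flagged=%d (not removed)", sample_missing,
               sum(flags)))

  p_dm <- test_differential_missingness(g1, case_status)
  g2 <- subset_genotypes(g1, variants = p_dm >= diff_missing_p)
  note("differential_missingness", nrow(g1$variants) - nrow(g2$variants), 0,
       sprintf("p<%g (Fisher exact)", diff_missing_p))

  p_hwe <- test_hwe(g2)
  keep_hwe <- is.na(p_hwe) | p_hwe >= hwe_p
  g3 <- subset_genotypes(g2, variants = keep_hwe)
  note("hwe", nrow(g2$variants) - nrow(g3$variants), 0,
       sprintf("exact p<%g%s", hwe_p,
               if (anyNA(p_hwe)) "; dosage-only variants skipped" else ""))

  rel <- find_related_pairs(g3, relatedness_threshold, seed = seed)
  keep_s <- !(g3$sample_ids %in% rel$exclude)
  g4 <- subset_genotypes(g3, samples = keep_s)
  case_status <- case_status[keep_s]
  note("relatedness", 0, sum(!keep_s),
       sprintf("dosage correlation>=%g; %d pairs", relatedness_threshold,
               nrow(rel$pairs)))

  g5 <- filter_info(g4, min_info, min_emp_info)
  note("info", nrow(g4$variants) - nrow(g5$variants), 0,
       sprintf("info>=%g & emp_info>=%g", min_info, min_emp_info))

  note("sex_check", 0, 0, "no-op (autosomal-only data)")

  report <- do.call(rbind, steps)
  attr(report, "initial") <- c(variants = n0v, samples = n0s)
  attr(report, "final") <- c(variants = nrow(g5$variants),
                             samples = length(g5$sample_ids))
  class(report) <- c("qc_report", class(report))
  list(genotypes = g5, report = report, sample_flags = flags,
       related = rel, case_status = case_status)
}
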