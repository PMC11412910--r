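#' Greedy LD clumping
#'
#' Standard clump-and-score variant selection: repeatedly take the most
#' significant unclaimed variant as an index SNP and claim every unclaimed
#' variant within `window_kb` whose dosage r-squared with the index is at or
#' above `r2_threshold`. P-value ties are broken by ascending position, then
#' id, so the result is deterministic.
#'
#' @param ss summary-statistics data.frame (`id`, `chrom`, `pos`, `p`).
#' @param ref reference [genotype_data()] supplying LD (Pearson r^2 of
#'   dosages).
#' @param r2_threshold clumping r^2 in (0, 1]; variants at or above it are
#'   claimed.
#' @param window_kb clumping window half-width in kilobases.
#' @return Character vector of retained (index) variant ids, in the order
#'   they were selected.
#' @export
ld_clump <- function(ss, ref, r2_threshold = 0.7, window_kb = 250) {
  stopifnot(r2_threshold > 0, r2_threshold <= 1)
  in_ref <- ss$id %in% ref$variants$id
  if (!all(in_ref)) {
    warning(sum(!in_ref), " summary-statistic variants absent from the ",
            "reference panel were skipped")
    ss <- ss[in_ref, , drop = FALSE]
  }
  if (!nrow(ss)) return(character(0))
  ord <- order(ss$p, ss$pos, ss$id)
  ss <- ss[ord, , drop = FALSE]
  dos <- ref$dosage[, match(ss$id, ref$variants$id), drop = FALSE]
  # standardize once (missing reference dosages mean-imputed) so each pairwise
  # r^2 is a crossprod instead of a cor() call
  mu <- colMeans(dos, na.rm = TRUE)
  dos <- sweep(dos, 2, mu)
  dos[is.na(dos)] <- 0
  sdv <- sqrt(colSums(dos^2))
  sdv[sdv == 0] <- Inf
  dos <- sweep(dos, 2, sdv, `/`)
  window <- window_kb * 1000
  # per chromosome, a position-sorted index so window neighbours are a
  # contiguous slice instead of a full scan per index SNP
  pos_order <- order(ss$chrom, ss$pos)
  chrom_sorted <- ss$chrom[pos_order]
  rows_by_chr <- split(seq_along(pos_order), chrom_sorted)
  pos_by_chr <- split(ss$pos[pos_order], chrom_sorted)
  claimed <- logical(nrow(ss))
  is_index <- logical(nrow(ss))
  for (i in seq_len(nrow(ss))) {
    if (claimed[i]) next
    claimed[i] <- TRUE
    is_index[i] <- TRUE
    chr <- ss$chrom[i]
    lo <- findInterval(ss$pos[i] - window - 1, pos_by_chr[[chr]]) + 1
    hi <- findInterval(ss$pos[i] + window, pos_by_chr[[chr]])
    if (hi < lo) next
    cand <- pos_order[rows_by_chr[[chr]][lo:hi]]
    cand <- cand[!claimed[cand]]
    if (!length(cand)) next
    r2 <- as.vector(crossprod(dos[, cand, drop = FALSE], dos[, i]))^2
    claimed[cand[r2 >= r2_threshold]] <- TRUE
  }
  ss$id[is_index]
}

#' Variants falling in a set of genes
#'
#' Returns the variants whose position lies in `[start - window_bp,
#' end + window_bp)` of any listed gene (left-closed, right-open, matching
#' the annotation's half-open intervals). Duplicates are collapsed.
#'
#' @param ss data.frame with `id`, `chrom`, `pos`.
#' @param annotation gene annotation data.frame (`gene_id`, `chrom`, `start`,
#'   `end`).
#' @param genes character vector of gene ids.
#' @param window_bp symmetric padding around gene bodies (default 0).
#' @return Character vector of variant ids.
#' @export
snps_in_genes <- function(ss, annotation, genes, window_bp = 0) {
  ann <- annotation[annotation$gene_id %in% genes, , drop = FALSE]
  if (!nrow(ann)) return(character(0))
  unmatched <- setdiff(unique(ann$chrom), unique(ss$chrom))
  if (length(unmatched) && !any(ss$chrom %in% ann$chrom))
    stop("chromosome names in annotation not found in variants: ",
         paste(unmatched, collapse = ", "))
  hit <- rep(FALSE, nrow(ss))
  for (chr in unique(ann$chrom)) {
    a <- ann[ann$chrom == chr, , drop = FALSE]
    vi <- which(ss$chrom == chr)
    if (!length(vi)) next
    pos <- ss$pos[vi]
    for (g in seq_len(nrow(a))) {
      hit[vi[pos >= a$start[g] - window_bp & pos < a$end[g] + window_bp]] <- TRUE
    }
  }
  unique(ss$id[hit])
}

#' Compute a polygenic score
#'
#' score_i = sum over variants of beta_v x effect-allele dosage_iv. Effect
#' alleles are reconciled against the genotype data's alt allele: when the
#' summary-statistic effect allele equals the genotype ref allele the dosage
#' is complemented (2 - d). Strand-ambiguous variants (A/T, C/G) that cannot
#' be reconciled are excluded and counted. Missing dosages are imputed as
#' 2 x effect-allele frequency from the summary statistics. No p-value filter
#' is applied.
#'
#' @param g [genotype_data()].
#' @param ss summary statistics (`id`, `a1` effect allele, `a2`, `beta`,
#'   `frq`).
#' @param variant_ids variants to score (must be in both `g` and `ss`).
#' @param label score name recorded in the result (default "genome-wide").
#' @param clump_r2 provenance: clumping r^2 that produced `variant_ids`.
#' @return A `score_set` list: `score` (named per sample), `n_snps`,
#'   `n_ambiguous_excluded`, `pathway`, `clump_r2`, `residualized` (NULL
#'   until [residualize_scores()] is applied).
#' @export
compute_score <- function(g, ss, variant_ids, label = "genome-wide",
                          clump_r2 = NA_real_) {
  gi <- match(variant_ids, g$variants$id)
  si <- match(variant_ids, ss$id)
  if (anyNA(gi) || anyNA(si))
    stop("variant ids missing from genotypes or summary statistics")
  a1 <- ss$a1[si]; a2 <- ss$a2[si]
  ref <- g$variants$ref[gi]; alt <- g$variants$alt[gi]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ambiguous <- a1 == comp[a2]
  aligned <- a1 == alt & a2 == ref
  flipped <- a1 == ref & a2 == alt
  usable <- !ambiguous & (aligned | flipped)
  n_amb <- sum(ambiguous | !(aligned | flipped))
  if (!any(usable)) stop("no usable variants after allele reconciliation")
  gi <- gi[usable]; si <- si[usable]; flipped <- flipped[usable]
  d <- g$dosage[, gi, drop = FALSE]
  frq <- ss$frq[si]
  # impute missing to expected effect-allele dosage
  for (j in which(colSums(is.na(d)) > 0)) {
    fj <- if (flipped[j]) 1 - frq[j] else frq[j]
    # frq is the effect-allele frequency; on the genotype (alt) scale that is
    # 1 - frq for flipped variants
    d[is.na(d[, j]), j] <- 2 * fj
  }
  if (any(flipped)) d[, flipped] <- 2 - d[, flipped, drop = FALSE]
  score <- as.vector(d %*% ss$beta[si])
  names(score) <- g$sample_ids
  structure(list(score = score, residualized = NULL,
                 n_snps = sum(usable), n_ambiguous_excluded = n_amb,
                 pathway = label, clump_r2 = clump_r2),
            class = "score_set")
}

#' @export
print.score_set <- function(x, ...) {
  cat("score_set [", x$pathway, "]: ", length(x$score), " samples, ",
      x$n_snps, " SNPs", if (!is.na(x$clump_r2)) paste0(", clump r2 ", x$clump_r2),
      "\n", sep = "")
  invisible(x)
}

#' Pathway-restricted polygenic score
#'
#' Scores the intersection of the clumped index variants with the variants
#' inside the pathway's genes (no p-value filter).
#'
#' @param g,ss as in [compute_score()].
#' @param annotation gene annotation.
#' @param pathway_genes character vector of gene ids.
#' @param clumped_ids index variants from [ld_clump()] on the same `ss`.
#' @param label pathway name for provenance.
#' @param window_bp gene-boundary padding passed to [snps_in_genes()].
#' @param clump_r2 provenance field.
#' @return A `score_set`.
#' @export
pathway_score <- function(g, ss, annotation, pathway_genes, clumped_ids,
                          label = "pathway", window_bp = 0,
                          clump_r2 = NA_real_) {
  in_genes <- snps_in_genes(ss, annotation, pathway_genes, window_bp)
  ids <- intersect(clumped_ids, in_genes)
  if (!length(ids))
    stop("pathway '", label, "': no clumped variants fall in its genes")
  compute_score(g, ss, ids, label = label, clump_r2 = clump_r2)
}

#' Length-weighted null gene sets
#'
#' Draws `n_sets` gene sets of `set_size` genes without replacement, each by
#' sequential weighted sampling with inclusion weight proportional to gene
#' length (base R's weighted `sample()` algorithm). Seed-deterministic.
#'
#' @param annotation gene annotation with `gene_id` and `length`.
#' @param set_size genes per null set.
#' @param n_sets number of null sets (default 10000).
#' @param seed integer seed.
#' @return List of character vectors of gene ids.
#' @export
sample_null_gene_sets <- function(annotation, set_size, n_sets = 10000,
                                  seed = 1L) {
  if (set_size > nrow(annotation))
    stop("set_size (", set_size, ") exceeds the gene universe (",
         nrow(annotation), ")")
  set.seed(seed)
  ids <- annotation$gene_id
  w <- annotation$length
  lapply(seq_len(n_sets), function(i) sample(ids, set_size, prob = w))
}

#' Empirical competitive p-value
#'
#' p = (1 + #\{null >= observed\}) / (1 + N) for `direction = "greater"`;
#' mirrored for `"less"`.
#'
#' @param observed_stat scalar statistic for the tested gene set.
#' @param null_stats statistics of the null gene sets.
#' @param direction "greater" (enrichment raises the statistic) or "less".
#' @return Empirical p in (0, 1].
#' @export
competitive_p <- function(observed_stat, null_stats,
                          direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (!length(null_stats)) stop("null_stats is empty")
  if (is.na(observed_stat) || anyNA(null_stats))
    stop("NaN/NA statistics passed to competitive_p")
  hits <- if (direction == "greater") sum(null_stats >= observed_stat)
  else sum(null_stats <= observed_stat)
  (1 + hits) / (1 + length(null_stats))
}

#' Case-status association statistic for a matrix of scores
#'
#' Point-biserial z statistic of each score column against binary case
#' status: z = r * sqrt(n - 2) / sqrt(1 - r^2). Asymptotically equivalent to
#' the Wald z of a score-only logistic model but vectorizable over thousands
#' of null gene-set scores. `method = "logistic_z"` fits the logistic model
#' per column instead.
#'
#' @param scores numeric matrix (samples x score columns) or vector.
#' @param status 0/1 case status.
#' @param method "corr_z" (default) or "logistic_z".
#' @return Numeric vector of z statistics, one per column.
#' @export
score_status_z <- function(scores, status, method = c("corr_z", "logistic_z")) {
  method <- match.arg(method)
  scores <- as.matrix(scores)
  if (method == "logistic_z") {
    return(apply(scores, 2, function(s) {
      fit <- stats::glm(status ~ scale(s), family = stats::binomial())
      summary(fit)$coefficients[2, "z value"]
    }))
  }
  n <- length(status)
  r <- suppressWarnings(as.vector(stats::cor(status, scores)))
  r[is.na(r)] <- 0
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  r * sqrt(n - 2) / sqrt(1 - r^2)
}

#' Scores for many gene sets at once
#'
#' Computes the pathway score for each gene set in `sets` over the clumped
#' variants, via a sparse gene-to-SNP incidence product, so 10,001 sets cost
#' one matrix multiply. Overlapping genes are handled exactly (a SNP covered
#' by two genes of a set contributes once).
#'
#' @param g,ss,annotation as in [pathway_score()].
#' @param sets list of gene-id vectors.
#' @param clumped_ids index variants from [ld_clump()].
#' @param window_bp gene padding.
#' @return Numeric matrix, samples x sets.
#' @export
score_gene_sets <- function(g, ss, annotation, sets, clumped_ids,
                            window_bp = 0) {
  ids <- intersect(clumped_ids, ss$id)
  ids <- ids[ids %in% g$variants$id]
  gi <- match(ids, g$variants$id)
  si <- match(ids, ss$id)
  d <- g$dosage[, gi, drop = FALSE]
  frq <- ss$frq[si]
  for (j in which(colSums(is.na(d)) > 0)) d[is.na(d[, j]), j] <- 2 * frq[j]
  contrib <- sweep(d, 2, ss$beta[si], `*`)  # samples x snps
  # snp x gene incidence over the clumped variants
  snp_gene <- lapply(annotation$gene_id, function(gid) {
    match(intersect(snps_in_genes(ss[si, , drop = FALSE], annotation, gid,
                                  window_bp), ids), ids)
  })
  ii <- unlist(snp_gene)
  jj <- rep(seq_along(snp_gene), lengths(snp_gene))
  incid <- Matrix::sparseMatrix(i = ii, j = jj,
                                dims = c(length(ids), nrow(annotation)),
                                x = 1)
  set_ind <- Matrix::sparseMatrix(
    i = unlist(lapply(sets, function(s) match(s, annotation$gene_id))),
    j = rep(seq_along(sets), lengths(sets)),
    dims = c(nrow(annotation), length(sets)), x = 1)
  memb <- (incid %*% set_ind) > 0  # snp x set
  as.matrix(contrib %*% memb)
}

#' Competitive permuted-null pathway test
#'
#' Tests whether a pathway score's case-status association exceeds what
#' length-matched random gene sets achieve: draws `n_null` null sets with
#' gene-inclusion probability proportional to gene length, scores each over
#' the same clumped variants, optionally residualizes every score on the
#' supplied PCs, computes the case-status z statistic for all, and returns
#' the empirical competitive p.
#'
#' @param g,ss,annotation as in [pathway_score()].
#' @param pathway_genes tested gene set.
#' @param clumped_ids index variants from [ld_clump()].
#' @param status 0/1 case status.
#' @param n_null number of null gene sets (default 10000).
#' @param seed seed for null-set sampling.
#' @param pcs optional matrix of principal components; when supplied, every
#'   score (observed and null) is residualized on them first.
#' @param statistic passed to [score_status_z()].
#' @param direction tail for [competitive_p()].
#' @param window_bp gene padding.
#' @return list(p, observed, nulls, n_null, set_size).
#' @export
pathway_null_test <- function(g, ss, annotation, pathway_genes, clumped_ids,
                              status, n_null = 10000, seed = 1L, pcs = NULL,
                              statistic = "corr_z", direction = "greater",
                              window_bp = 0) {
  set_size <- length(intersect(pathway_genes, annotation$gene_id))
  nulls <- sample_null_gene_sets(annotation, set_size, n_null, seed = seed)
  sc <- score_gene_sets(g, ss, annotation, c(list(pathway_genes), nulls),
                        clumped_ids, window_bp)
  if (!is.null(pcs)) sc <- apply(sc, 2, residualize_scores, pcs = pcs)
  z <- score_status_z(sc, status, method = statistic)
  list(p = competitive_p(z[1], z[-1], direction = direction),
       observed = z[1], nulls = z[-1], n_null = n_null, set_size = set_size)
}
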