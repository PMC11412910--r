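#' Fit a reference-panel PCA model
#'
#' PCA of reference dosages standardized GRM-style: center by 2*p-hat and
#' scale by sqrt(2*p-hat*(1-p-hat)) with reference allele frequencies.
#' Monomorphic variants are dropped from the model. Means, scales and
#' loadings are retained so study samples can be projected later.
#'
#' @param panel reference [genotype_data()] (missing dosages are mean-imputed
#'   before the decomposition).
#' @param k number of components (default 20).
#' @return A `pc_model`: `variant_ids`, `center`, `scale`, `loadings`
#'   (variants x k, column-orthonormal), `scores` (reference samples x k),
#'   `sdev`, `k`.
#' @export
fit_reference_pca <- function(panel, k = 20) {
  x <- panel$dosage
  p <- colMeans(x, na.rm = TRUE) / 2
  keep <- which(p > 0 & p < 1)
  if (!length(keep)) stop("panel has zero genetic variance; PCA undefined")
  x <- x[, keep, drop = FALSE]
  p <- p[keep]
  ctr <- 2 * p
  scl <- sqrt(2 * p * (1 - p))
  xs <- sweep(sweep(x, 2, ctr), 2, scl, `/`)
  xs[is.na(xs)] <- 0
  if (k > min(dim(xs))) stop("k = ", k, " exceeds the rank bound min(",
                             nrow(xs), ", ", ncol(xs), ")")
  sv <- svd(xs, nu = k, nv = k)
  if (sv$d[1] < 1e-10) stop("panel has zero genetic variance; PCA undefined")
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- panel$sample_ids
  loadings <- sv$v
  dimnames(loadings) <- list(panel$variants$id[keep], paste0("PC", seq_len(k)))
  structure(list(variant_ids = panel$variants$id[keep],
                 center = ctr, scale = scl, loadings = loadings,
                 scores = scores, sdev = sv$d[seq_len(k)] / sqrt(nrow(xs) - 1),
                 k = k),
            class = "pc_model")
}

#' Project samples onto a fitted PC model
#'
#' Standardizes study dosages with the reference means/scales (missing
#' dosages are imputed to the reference mean, i.e. standardized zero) and
#' multiplies by the loadings.
#'
#' @param m a `pc_model` from [fit_reference_pca()].
#' @param g [genotype_data()] to project.
#' @param min_overlap minimum fraction of model variants that must be present
#'   in `g` (default 0.95).
#' @return Matrix of PC scores, samples x k.
#' @export
project_samples <- function(m, g, min_overlap = 0.95) {
  idx <- match(m$variant_ids, g$variants$id)
  overlap <- mean(!is.na(idx))
  if (overlap < min_overlap)
    stop(sprintf("variant overlap with PC model is %.3f (< %.3f required)",
                 overlap, min_overlap))
  present <- which(!is.na(idx))
  xs <- matrix(0, nrow(g$dosage), length(m$variant_ids),
               dimnames = list(g$sample_ids, m$variant_ids))
  xs[, present] <- sweep(sweep(g$dosage[, idx[present], drop = FALSE],
                               2, m$center[present]),
                         2, m$scale[present], `/`)
  xs[is.na(xs)] <- 0
  out <- xs %*% m$loadings
  colnames(out) <- paste0("PC", seq_len(m$k))
  out
}

#' Superpopulation centroids in PC space
#'
#' @param scores reference PC scores (samples x k).
#' @param labels per-sample superpopulation labels.
#' @param fun centroid summary (`mean` default; `median` available).
#' @return Matrix of centroids, one row per label, in PC space.
#' @export
population_centroids <- function(scores, labels, fun = mean) {
  labs <- sort(unique(labels))
  cen <- t(vapply(labs, function(l)
    apply(scores[labels == l, , drop = FALSE], 2, fun),
    numeric(ncol(scores))))
  rownames(cen) <- labs
  cen
}

#' Nearest-centroid superpopulation assignment
#'
#' Assigns each sample the label of the nearest centroid by Euclidean
#' distance in PC space; exact ties are broken lexicographically by label.
#'
#' @param scores sample PC scores (samples x k).
#' @param centroids matrix of centroids with labelled rows (same k columns).
#' @return Character vector of labels, one per sample.
#' @export
assign_superpopulation <- function(scores, centroids) {
  if (is.null(centroids) || nrow(centroids) == 0) stop("empty centroid set")
  if (ncol(scores) != ncol(centroids))
    stop("score dimension ", ncol(scores), " does not match centroid dimension ",
         ncol(centroids))
  ord <- order(rownames(centroids))
  centroids <- centroids[ord, , drop = FALSE]
  d2 <- outer(rowSums(scores^2), rep(1, nrow(centroids))) -
    2 * scores %*% t(centroids) +
    outer(rep(1, nrow(scores)), rowSums(centroids^2))
  rownames(centroids)[apply(d2, 1, which.min)]
}

#' Residualize a score on principal components
#'
#' Regresses the score on an intercept plus the first `n_pcs` PCs and returns
#' the least-squares residuals; by construction the residuals are
#' uncorrelated with every PC used.
#'
#' @param score numeric vector.
#' @param pcs matrix of principal components (samples x >= n_pcs).
#' @param n_pcs number of leading PCs to regress out (default 10, capped at
#'   the number of supplied columns).
#' @return Residual score vector (names preserved).
#' @export
residualize_scores <- function(score, pcs, n_pcs = 10) {
  pcs <- as.matrix(pcs)
  n_pcs <- min(n_pcs, ncol(pcs))
  x <- cbind(1, pcs[, seq_len(n_pcs), drop = FALSE])
  if (nrow(x) <= n_pcs + 1)
    stop("need more samples (", nrow(x), ") than PCs + 1 (", n_pcs + 1, ")")
  qx <- qr(x)
  if (qx$rank < ncol(x)) stop("collinear principal components")
  res <- stats::setNames(as.vector(qr.resid(qx, score)), names(score))
  res
}

#' Residualize a score_set in place
#'
#' @param ss a `score_set` from [compute_score()].
#' @param pcs,n_pcs as in [residualize_scores()].
#' @return The `score_set` with its `residualized` field filled.
#' @export
residualize_score_set <- function(ss, pcs, n_pcs = 10) {
  ss$residualized <- residualize_scores(ss$score, pcs, n_pcs)
  ss
}
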