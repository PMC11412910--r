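#' Midpoint of the past-year range
#'
#' Functioning scales measured at multiple time points are summarized as the
#' average of the highest and lowest values observed.
#'
#' @param values numeric vector of measurements (possibly empty).
#' @return (max + min) / 2, or NA for zero measurements.
#' @export
range_midpoint <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) return(NA_real_)
  (max(values) + min(values)) / 2
}

#' Derive the endophenotype battery from raw phenotype records
#'
#' Builds the per-case clustering battery: GSF and GRF are each the
#' (max + min)/2 midpoint of the past-year measurements (stored as
#' semicolon-separated `gsf_values` / `grf_values` strings); the YMRS total
#' excludes item 8 ("Content"), which probes positive psychotic symptoms and
#' would skew mania scores in schizophrenia; the remaining battery measures
#' are passed through. Only cases (status == 1) are returned.
#'
#' @param pheno phenotype data.frame from the generator or a phenotype TSV:
#'   needs `sample_id`, `status`, `diagnosis`, `scanner`, the pass-through
#'   battery columns, `gsf_values`, `grf_values`, and `ymrs_item_1` ..
#'   `ymrs_item_11`.
#' @return data.frame: sample_id, diagnosis, scanner, then the 12 battery
#'   columns ([endo_battery()] order).
#' @export
derive_endophenotypes <- function(pheno) {
  cases <- pheno[pheno$status == 1, , drop = FALSE]
  parse_vals <- function(s) {
    if (is.na(s) || !nzchar(s)) return(numeric(0))
    as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  }
  gsf <- vapply(cases$gsf_values, function(s) range_midpoint(parse_vals(s)), 0,
                USE.NAMES = FALSE)
  grf <- vapply(cases$grf_values, function(s) range_midpoint(parse_vals(s)), 0,
                USE.NAMES = FALSE)
  items <- as.matrix(cases[, sprintf("ymrs_item_%d", 1:11), drop = FALSE])
  ymrs <- rowSums(items[, -8, drop = FALSE])
  out <- data.frame(sample_id = cases$sample_id, diagnosis = cases$diagnosis,
                    scanner = cases$scanner, stringsAsFactors = FALSE)
  for (nm in endo_battery()) {
    out[[nm]] <- switch(nm, gsf = gsf, grf = grf, ymrs = ymrs, cases[[nm]])
  }
  out
}

#' Z-score normalize the endophenotype battery within cases
#'
#' Centers and scales each battery variable to mean 0, SD 1 (sample SD)
#' within cases; variables listed in `scanner_stratified` (the
#' cognitive-control measures) are normalized within cases sharing the same
#' scanner/protocol. Missing entries stay missing; a zero-variance stratum
#' has its values set missing with a warning.
#'
#' @param tab endophenotype table from [derive_endophenotypes()].
#' @param scanner_stratified variables normalized within scanner strata.
#' @param vars battery columns to normalize (default [endo_battery()]).
#' @return The table with normalized battery columns.
#' @export
normalize_endophenotypes <- function(tab,
                                     scanner_stratified = c("dprime_context",
                                                            "dlpfc_beta",
                                                            "spc_beta"),
                                     vars = endo_battery()) {
  zscore <- function(x) {
    s <- stats::sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) {
      warning("zero-variance stratum; values set missing")
      return(rep(NA_real_, length(x)))
    }
    (x - mean(x, na.rm = TRUE)) / s
  }
  for (nm in vars) {
    if (nm %in% scanner_stratified) {
      for (sc in unique(tab$scanner)) {
        i <- tab$scanner == sc
        tab[[nm]][i] <- zscore(tab[[nm]][i])
      }
    } else tab[[nm]] <- zscore(tab[[nm]])
  }
  tab
}

km_safe <- function(x, k, nstart, iter.max = 30) {
  stats::kmeans(x, k, nstart = nstart, iter.max = iter.max)
}

#' Select the number of clusters by an index ensemble
#'
#' Runs k-means over `k_range` on complete-case data and lets each index vote
#' for its optimum: average silhouette width and Calinski-Harabasz (maximize),
#' Davies-Bouldin (minimize), the gap statistic (first-SE-max rule via
#' `cluster::clusGap`), and Hartigan's rule (smallest k with H(k) <= 10, else
#' the k minimizing H). Majority vote wins; ties go to the smaller k. On data
#' with fewer distinct rows than `max(k_range)` the range is capped at the
#' number of distinct rows.
#'
#' @param data complete-case numeric matrix (cases x variables).
#' @param k_range candidate cluster counts (default 2:8).
#' @param indices subset of `c("silhouette","ch","db","gap","hartigan")`.
#' @param seed RNG seed (k-means restarts and gap bootstrap).
#' @param nstart k-means restarts per k.
#' @param gap_b bootstrap references for the gap statistic.
#' @return list(k, votes, index_values).
#' @export
select_k <- function(data, k_range = 2:8,
                     indices = c("silhouette", "ch", "db", "gap", "hartigan"),
                     seed = 1L, nstart = 25, gap_b = 25) {
  x <- as.matrix(data)
  if (anyNA(x)) stop("select_k needs complete-case data")
  if (length(indices) < 2) stop("index ensemble needs >= 2 indices")
  n_distinct <- nrow(unique(x))
  k_range <- k_range[k_range <= n_distinct]
  if (!length(k_range) || nrow(x) < max(k_range))
    stop("complete-case subset smaller than the largest candidate k")
  set.seed(seed)
  fits <- lapply(k_range, function(k) km_safe(x, k, nstart))
  names(fits) <- k_range
  n <- nrow(x)
  dmat <- stats::dist(x)
  gmean <- colMeans(x)

  sil <- vapply(seq_along(k_range), function(i)
    mean(cluster::silhouette(fits[[i]]$cluster, dmat)[, 3]), 0)
  ch <- vapply(seq_along(k_range), function(i) {
    f <- fits[[i]]; k <- k_range[i]
    b <- sum(f$size * rowSums(sweep(f$centers, 2, gmean)^2))
    w <- f$tot.withinss
    if (w == 0) Inf else (b / (k - 1)) / (w / (n - k))
  }, 0)
  db <- vapply(seq_along(k_range), function(i) {
    f <- fits[[i]]; k <- k_range[i]
    s <- vapply(seq_len(k), function(c) {
      pts <- x[f$cluster == c, , drop = FALSE]
      sqrt(mean(rowSums(sweep(pts, 2, f$centers[c, ])^2)))
    }, 0)
    cd <- as.matrix(stats::dist(f$centers))
    mean(vapply(seq_len(k), function(c) {
      r <- (s[c] + s[-c]) / cd[c, -c]
      max(r[is.finite(r)], 0)
    }, 0))
  }, 0)

  votes <- c()
  val <- list(silhouette = sil, ch = ch, db = db)
  if ("silhouette" %in% indices)
    votes["silhouette"] <- k_range[which.max(sil)]
  if ("ch" %in% indices) votes["ch"] <- k_range[which.max(ch)]
  if ("db" %in% indices) votes["db"] <- k_range[which.min(db)]
  degenerate <- FALSE
  if ("gap" %in% indices) {
    gp <- tryCatch(
      cluster::clusGap(x, FUN = function(xx, kk) km_safe(xx, kk, nstart),
                       K.max = max(k_range), B = gap_b, verbose = FALSE),
      error = function(e) NULL)
    if (!is.null(gp)) {
      tabg <- gp$Tab
      kg <- if (all(is.finite(tabg[, "gap"]))) {
        cluster::maxSE(tabg[, "gap"], tabg[, "SE.sim"], method = "firstSEmax")
      } else which.max(tabg[, "gap"])
      # the gap statistic is the only ensemble member with a null reference
      # model; k = 1 from it means "no cluster structure" and the selection
      # degenerates to the boundary of the candidate range
      degenerate <- kg == 1
      votes["gap"] <- min(max(kg, min(k_range)), max(k_range))
      val$gap <- tabg[, "gap"]
    }
  }
  if ("hartigan" %in% indices) {
    wk <- vapply(fits, function(f) f$tot.withinss, 0)
    w_next <- c(wk[-1], NA)
    kmax1 <- max(k_range) + 1
    w_next[length(w_next)] <- if (kmax1 <= n_distinct)
      km_safe(x, kmax1, nstart)$tot.withinss else 0
    h <- ifelse(wk == 0, 0,
                ifelse(w_next == 0, Inf,
                       (wk / w_next - 1) * (n - k_range - 1)))
    h[wk == 0] <- 0
    ok <- which(h <= 10)
    # no k meeting the criterion = no evidence of structure: smallest k
    votes["hartigan"] <- if (length(ok)) k_range[min(ok)] else min(k_range)
    val$hartigan <- h
  }
  tv <- table(votes)
  winners <- as.integer(names(tv)[tv == max(tv)])
  list(k = if (degenerate) min(k_range) else min(winners),
       votes = votes, index_values = val, degenerate = degenerate)
}

scaled_missing_dist <- function(x0, obs, centers) {
  # squared Euclidean over observed dims, rescaled by total/observed dims
  n <- nrow(x0); k <- nrow(centers); d <- ncol(x0)
  D <- matrix(0, n, k)
  for (j in seq_len(k)) {
    diff <- sweep(x0, 2, centers[j, ])
    diff[!obs] <- 0
    D[, j] <- rowSums(diff^2)
  }
  D * (d / rowSums(obs))
}

#' K-means tolerant of missing endophenotypes
#'
#' K-means where the case-to-centroid distance is the squared Euclidean over
#' the case's observed variables, rescaled by (total variables / observed
#' variables); centroids are updated from observed entries only. Cases with
#' at most 50% of variables observed are excluded and flagged. Initialization
#' is k-means++ under the same distance, with the best of `restarts` seeded
#' starts kept by total cost. Reduces exactly to standard k-means on complete
#' data.
#'
#' @param data numeric matrix (cases x variables), NAs allowed.
#' @param k number of clusters.
#' @param seed RNG seed.
#' @param restarts number of initializations (default 50).
#' @param max_iter Lloyd iteration cap per start.
#' @param min_observed minimum fraction of observed variables for inclusion
#'   (strictly greater; default 0.5; set 0 to cluster every case with at
#'   least one observed value).
#' @return A `cluster_result`: k, `assignment` (named, included cases only),
#'   `included` (logical per input row), `centers`, `total_cost`, `seed`.
#' @export
kmeans_missing <- function(data, k, seed = 1L, restarts = 50, max_iter = 100,
                           min_observed = 0.5) {
  x <- as.matrix(data)
  obs <- !is.na(x)
  included <- rowMeans(obs) > min_observed
  xi <- x[included, , drop = FALSE]
  oi <- obs[included, , drop = FALSE]
  n <- nrow(xi)
  if (k > n) stop("k = ", k, " exceeds the ", n, " included cases")
  x0 <- xi; x0[!oi] <- 0
  colmu <- colSums(x0) / pmax(colSums(oi), 1)

  one_run <- function() {
    # k-means++ seeding under the scaled distance
    centers <- matrix(NA_real_, k, ncol(xi))
    fill <- function(i) ifelse(oi[i, ], xi[i, ], colmu)
    centers[1, ] <- fill(sample.int(n, 1))
    if (k > 1) for (j in 2:k) {
      D <- scaled_missing_dist(x0, oi, centers[seq_len(j - 1), , drop = FALSE])
      dmin <- apply(D, 1, min)
      if (sum(dmin) == 0) pick <- sample.int(n, 1)
      else pick <- sample.int(n, 1, prob = dmin)
      centers[j, ] <- fill(pick)
    }
    assign <- rep(0L, n)
    for (it in seq_len(max_iter)) {
      D <- scaled_missing_dist(x0, oi, centers)
      new_assign <- max.col(-D, ties.method = "first")
      if (all(new_assign == assign)) break
      assign <- new_assign
      for (c in seq_len(k)) {
        rows <- which(assign == c)
        if (!length(rows)) next
        cnt <- colSums(oi[rows, , drop = FALSE])
        mu <- colSums(x0[rows, , drop = FALSE]) / pmax(cnt, 1)
        centers[c, ] <- ifelse(cnt > 0, mu, centers[c, ])
      }
    }
    D <- scaled_missing_dist(x0, oi, centers)
    cost <- sum(D[cbind(seq_len(n), assign)])
    list(assign = assign, centers = centers, cost = cost)
  }

  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(seed + r)
    run <- one_run()
    if (is.null(best) || run$cost < best$cost) best <- run
  }
  assignment <- best$assign
  names(assignment) <- rownames(x)[included]
  structure(list(k = k, assignment = assignment, included = included,
                 centers = best$centers, total_cost = best$cost, seed = seed),
            class = "cluster_result")
}

#' Classify treatment response from BPRS
#'
#' Both scores are rescaled by subtracting the instrument minimum of 24 so
#' the lowest possible score maps to 0; a subject is a responder iff the
#' rescaled decrease exceeds 20% of the rescaled baseline, strictly. Records
#' with rescaled baseline below 5 lack the resolution to detect a 20%
#' improvement and are excluded with a reason.
#'
#' @param baseline_bprs_raw,followup_bprs_raw raw BPRS totals (minimum 24).
#' @return data.frame(responder, excluded_reason); responder is NA for
#'   excluded or incomplete records.
#' @export
classify_response <- function(baseline_bprs_raw, followup_bprs_raw) {
  if (any(stats::na.omit(c(baseline_bprs_raw, followup_bprs_raw)) < 24))
    stop("BPRS totals below the instrument minimum of 24")
  b <- baseline_bprs_raw - 24
  f <- followup_bprs_raw - 24
  responder <- rep(NA, length(b))
  reason <- rep(NA_character_, length(b))
  missing <- is.na(b) | is.na(f)
  reason[missing] <- "missing BPRS"
  low <- !missing & b < 5
  reason[low] <- "rescaled baseline < 5"
  ok <- !missing & !low
  responder[ok] <- (b[ok] - f[ok]) / b[ok] > 0.20
  data.frame(responder = responder, excluded_reason = reason,
             stringsAsFactors = FALSE)
}

#' Compare cluster-based and diagnosis-based genetic models
#'
#' For each score, fits three linear models: score ~ cluster + covariates,
#' score ~ diagnosis + covariates, and score ~ cluster + diagnosis +
#' covariates, with BP and Cluster 3 (or the supplied references) as
#' reference levels, and reports BIC and adjusted R-squared per model plus
#' per-level coefficients with Wald 95% CIs for the combined model.
#'
#' @param scores named list (or data.frame) of per-case score vectors.
#' @param clusters cluster label per case.
#' @param diagnosis diagnosis label per case.
#' @param covariates data.frame of covariates per case (may be NULL).
#' @param cluster_ref,diagnosis_ref reference levels (defaults "3", "BP").
#' @return list(comparison = data.frame(score, model, BIC, adj_r2),
#'   coefficients = data.frame of combined-model terms).
#' @export
compare_models <- function(scores, clusters, diagnosis, covariates = NULL,
                           cluster_ref = "3", diagnosis_ref = "BP") {
  if (length(unique(clusters)) < 2) stop("cluster labels are constant")
  if (length(unique(diagnosis)) < 2) stop("diagnosis labels are constant")
  scores <- as.data.frame(scores)
  df0 <- data.frame(
    cluster = stats::relevel(factor(clusters), ref = cluster_ref),
    diagnosis = stats::relevel(factor(diagnosis), ref = diagnosis_ref))
  if (!is.null(covariates)) df0 <- cbind(df0, covariates)
  cov_rhs <- if (!is.null(covariates) && ncol(covariates))
    paste("+", paste(names(covariates), collapse = " + ")) else ""
  rows <- list(); coefs <- list()
  for (nm in names(scores)) {
    d <- df0
    d$.score <- as.vector(scale(scores[[nm]]))
    fits <- list(
      cluster = stats::lm(stats::as.formula(paste(".score ~ cluster", cov_rhs)), d),
      diagnosis = stats::lm(stats::as.formula(paste(".score ~ diagnosis", cov_rhs)), d),
      combined = stats::lm(stats::as.formula(paste(".score ~ cluster + diagnosis", cov_rhs)), d)
    )
    for (mn in names(fits)) {
      rows[[length(rows) + 1]] <- data.frame(
        score = nm, model = mn, BIC = stats::BIC(fits[[mn]]),
        adj_r2 = summary(fits[[mn]])$adj.r.squared, stringsAsFactors = FALSE)
    }
    sm <- summary(fits$combined)$coefficients
    zc <- stats::qnorm(0.975)
    coefs[[length(coefs) + 1]] <- data.frame(
      score = nm, term = rownames(sm), beta = sm[, 1], se = sm[, 2],
      ci_low = sm[, 1] - zc * sm[, 2], ci_high = sm[, 1] + zc * sm[, 2],
      p = sm[, 4], stringsAsFactors = FALSE, row.names = NULL)
  }
  list(comparison = do.call(rbind, rows),
       coefficients = do.call(rbind, coefs))
}

#' Cluster-by-category enrichment test
#'
#' Cross-tabulates cluster membership against a categorical label (diagnosis
#' or treatment response) and tests independence with Fisher's exact test
#' (network enumeration); falls back to a chi-square test, flagged, when the
#' exact computation is infeasible.
#'
#' @param clusters cluster label per case.
#' @param categorical second categorical label per case.
#' @return list(table, p, method).
#' @export
cluster_enrichment <- function(clusters, categorical) {
  keep <- !is.na(clusters) & !is.na(categorical)
  tab <- table(cluster = clusters[keep], category = categorical[keep])
  if (!all(dim(tab) >= 2))
    stop("enrichment test needs >= 2 levels on each axis")
  ft <- tryCatch(stats::fisher.test(tab, workspace = 2e7),
                 error = function(e) NULL)
  if (!is.null(ft)) return(list(table = tab, p = ft$p.value, method = "fisher"))
  cs <- suppressWarnings(stats::chisq.test(tab))
  list(table = tab, p = cs$p.value, method = "chisq (exact test infeasible)")
}
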