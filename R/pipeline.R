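pipeline_stages <- c("synth", "qc", "ancestry", "scoring", "assoc", "cluster")

known_config_keys <- list(
  seed = "integer", out_dir = "character", synth = "list",
  qc = "list", scoring = "list", assoc = "list", cluster = "list",
  n_pcs = "numeric", ancestry_pcs = "numeric"
)

config_defaults <- function() {
  list(
    n_pcs = 10, ancestry_pcs = 20,
    qc = list(max_missing = 0.05, diff_missing_p = 0.001, hwe_p = 1e-6,
              relatedness_threshold = 0.2, min_info = 0.7, min_emp_info = 0.8),
    scoring = list(r2 = 0.7, window_kb = 250, n_null = 10000, window_bp = 0),
    assoc = list(fdr_q = 0.10),
    cluster = list(k_range = 2:8, restarts = 50)
  )
}

#' Validate a pipeline configuration
#'
#' Reads a YAML (or JSON) run configuration, rejects unknown keys and
#' out-of-range values (all violations listed at once), and fills defaults:
#' clump r-squared 0.7 / window 250 kb, FDR q 0.10, 10 PCs for score
#' residualization, 20 PCs for ancestry assignment, 10,000 null gene sets.
#' `seed` is mandatory.
#'
#' @param path YAML/JSON config file, or a list already in memory.
#' @return A validated `run_config` list.
#' @export
validate_config <- function(path) {
  cfg <- if (is.list(path)) path
  else if (grepl("[.]json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  errs <- character(0)
  unknown <- setdiff(names(cfg), names(known_config_keys))
  if (length(unknown))
    errs <- c(errs, paste("unknown config keys:", paste(unknown, collapse = ", ")))
  if (is.null(cfg$seed)) errs <- c(errs, "seed is mandatory")
  else if (!is.numeric(cfg$seed)) errs <- c(errs, "seed must be an integer")
  def <- config_defaults()
  for (blk in c("qc", "scoring", "assoc", "cluster")) {
    given <- cfg[[blk]]
    if (!is.null(given)) {
      bad <- setdiff(names(given), names(def[[blk]]))
      if (length(bad))
        errs <- c(errs, paste0("unknown ", blk, " keys: ",
                               paste(bad, collapse = ", ")))
    }
    cfg[[blk]] <- utils::modifyList(def[[blk]], given %||% list())
  }
  for (k in c("n_pcs", "ancestry_pcs"))
    cfg[[k]] <- cfg[[k]] %||% def[[k]]
  r2 <- cfg$scoring$r2
  if (!is.null(r2) && (!is.numeric(r2) || r2 <= 0 || r2 > 1))
    errs <- c(errs, "scoring$r2 must be in (0, 1]")
  q <- cfg$assoc$fdr_q
  if (!is.numeric(q) || q <= 0 || q >= 1)
    errs <- c(errs, "assoc$fdr_q must be in (0, 1)")
  synth <- cfg$synth %||% list()
  if (!is.null(synth$pathways) && anyDuplicated(names(synth$pathways)))
    errs <- c(errs, "duplicate pathway names in synth$pathways")
  if (length(errs)) stop("invalid configuration:\n  - ",
                         paste(errs, collapse = "\n  - "), call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stage seed fan-out
#'
#' Derives a deterministic per-stage seed from the global seed by a stable
#' hash of the stage name, so re-running a subset of stages reproduces the
#' full run's draws.
#'
#' @param seed global integer seed.
#' @param stage stage name.
#' @return Integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes the six stages in order — synthetic data generation, genotype QC,
#' ancestry PCs + assignment, clump-and-score (p)PGS with permuted-null
#' pathway tests, covariate-adjusted association with the Galwey/BH
#' correction machinery, and endophenotype clustering with the
#' cluster-versus-diagnosis model comparison — writing tidy TSV/JSON results
#' and a provenance manifest under `cfg$out_dir`. Any stage failure aborts
#' with the manifest recording partial progress.
#'
#' @param cfg a validated `run_config` (see [validate_config()]).
#' @return list(manifest, results) where `results` holds the in-memory stage
#'   outputs.
#' @export
run_all <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- validate_config(cfg)
  out_dir <- cfg$out_dir %||% tempfile("ppgs_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("ppgs")),
                   config_hash = digest_obj(unclass(cfg)), stages = list())
  res <- list()
  t_all <- Sys.time()
  run_stage <- function(name, fun) {
    t0 <- Sys.time()
    warns <- character(0)
    out <- withCallingHandlers(
      tryCatch(fun(), error = function(e) {
        manifest$stages[[name]] <<- list(status = "failed",
                                         error = conditionMessage(e))
        jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA, force = TRUE)
        stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
      }),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w)); invokeRestart("muffleWarning")
      })
    manifest$stages[[name]] <<- list(
      status = "completed",
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3),
      warnings = warns,
      outputs = stage_checksums(out_dir, name))
    out
  }
  wtsv <- function(x, name) {
    data.table::fwrite(x, file.path(out_dir, name), sep = "\t")
  }

  # ---- synth ----
  res$study <- run_stage("synth", function() {
    scfg <- do.call(sim_config, utils::modifyList(
      list(seed = stage_seed(cfg$seed, "synth")), cfg$synth %||% list()))
    study <- simulate_study(scfg)
    write_sumstats(study$sumstats, file.path(out_dir, "synth_sumstats.tsv"))
    write_gmt(study$pathways, file.path(out_dir, "synth_pathways.gmt"))
    write_annotation(study$annotation, file.path(out_dir, "synth_genes.tsv"))
    write_pheno(study$cohort$pheno, file.path(out_dir, "synth_pheno.tsv"))
    study
  })
  study <- res$study
  pheno <- study$cohort$pheno

  # ---- qc ----
  res$qc <- run_stage("qc", function() {
    qc <- do.call(run_qc, c(list(g = study$cohort$genotypes,
                                 case_status = pheno$status,
                                 seed = stage_seed(cfg$seed, "qc")),
                            cfg$qc))
    write_qc_report(qc$report, file.path(out_dir, "qc_report"))
    qc
  })
  g <- res$qc$genotypes
  pheno <- pheno[pheno$sample_id %in% g$sample_ids, , drop = FALSE]

  # ---- ancestry ----
  res$ancestry <- run_stage("ancestry", function() {
    panel_qc <- subset_genotypes(study$panel,
                                 variants = study$panel$variants$id %in%
                                   g$variants$id)
    ref_pca <- fit_reference_pca(panel_qc, k = cfg$ancestry_pcs)
    proj <- project_samples(ref_pca, g)
    cent <- population_centroids(ref_pca$scores, study$pop_labels)
    assigned <- assign_superpopulation(proj, cent)
    study_pca <- fit_reference_pca(g, k = cfg$n_pcs)
    tab <- data.frame(sample_id = g$sample_ids, assigned_pop = assigned,
                      study_pca$scores, check.names = FALSE)
    wtsv(tab, "ancestry.tsv")
    list(ref_pca = ref_pca, projection = proj, assigned = assigned,
         study_pcs = study_pca$scores)
  })
  pcs <- res$ancestry$study_pcs

  # ---- scoring ----
  res$scoring <- run_stage("scoring", function() {
    sc <- cfg$scoring
    clumped <- ld_clump(study$sumstats, study$panel,
                        r2_threshold = sc$r2, window_kb = sc$window_kb)
    scores <- list(
      pgs = compute_score(g, study$sumstats, intersect(clumped, g$variants$id),
                          label = "genome-wide", clump_r2 = sc$r2))
    for (nm in names(study$pathways)) {
      scores[[nm]] <- pathway_score(g, study$sumstats, study$annotation,
                                    study$pathways[[nm]],
                                    intersect(clumped, g$variants$id),
                                    label = nm, window_bp = sc$window_bp,
                                    clump_r2 = sc$r2)
    }
    scores <- lapply(scores, residualize_score_set, pcs = pcs,
                     n_pcs = cfg$n_pcs)
    null_tests <- lapply(names(study$pathways), function(nm) {
      pathway_null_test(g, study$sumstats, study$annotation,
                        study$pathways[[nm]],
                        intersect(clumped, g$variants$id),
                        status = pheno$status, n_null = sc$n_null,
                        seed = stage_seed(cfg$seed, paste0("null_", nm)),
                        pcs = pcs, window_bp = sc$window_bp)
    })
    names(null_tests) <- names(study$pathways)
    tab <- do.call(rbind, lapply(scores, function(s) data.frame(
      sample_id = g$sample_ids, pathway = s$pathway, raw = s$score,
      residualized = s$residualized, n_snps = s$n_snps)))
    wtsv(tab, "scores.tsv")
    wtsv(data.frame(pathway = names(null_tests),
                    observed_z = vapply(null_tests, `[[`, 0, "observed"),
                    competitive_p = vapply(null_tests, `[[`, 0, "p"),
                    n_null = sc$n_null), "pathway_null_tests.tsv")
    list(clumped = clumped, scores = scores, null_tests = null_tests)
  })
  scores <- res$scoring$scores

  # ---- assoc ----
  res$assoc <- run_stage("assoc", function() {
    df <- pheno
    for (nm in names(scores)) df[[paste0("score_", nm)]] <- scores[[nm]]$residualized
    endo <- derive_endophenotypes(pheno)
    base_cov <- c("sex", "age", "race", "ethnicity")
    rows <- list()
    # case status by each score
    for (nm in names(scores)) {
      r <- fit_association(df, assoc_spec("status", "binary",
                                          paste0("score_", nm), base_cov))
      rows[[length(rows) + 1]] <- data.frame(
        outcome = "status", predictor = nm, n = r$n, beta = r$beta,
        or = r$or, ci_low = r$or_ci[1], ci_high = r$or_ci[2], p = r$p,
        r2_nagelkerke = r$r2_nagelkerke)
    }
    # endophenotypes by each score, within cases
    cases <- merge(df, endo[, c("sample_id", setdiff(endo_battery(), names(df)))],
                   by = "sample_id")
    scanner_vars <- c("dprime_context", "dlpfc_beta", "spc_beta")
    for (nm in names(scores)) {
      for (ph in endo_battery()) {
        covs <- c(base_cov, "diagnosis",
                  if (ph %in% scanner_vars) "scanner",
                  if (nm != "pgs") "score_pgs")
        r <- tryCatch(
          fit_association(cases, assoc_spec(ph, "continuous",
                                            paste0("score_", nm), covs,
                                            subset = "cases-only")),
          error = function(e) NULL)
        if (is.null(r)) next
        rows[[length(rows) + 1]] <- data.frame(
          outcome = ph, predictor = nm, n = r$n, beta = r$beta,
          or = NA, ci_low = r$ci[1], ci_high = r$ci[2], p = r$p,
          r2_nagelkerke = NA)
      }
    }
    tab <- do.call(rbind, rows)
    score_mat <- sapply(scores, function(s) s$residualized)
    case_rows <- pheno$status == 1
    meff_s <- galwey_meff(pairwise_corr(score_mat[case_rows, , drop = FALSE]))
    endo_mat <- as.matrix(endo[, endo_battery()])
    meff_e <- galwey_meff(pairwise_corr(endo_mat))
    budget <- effective_test_budget(meff_s, meff_e, extra_tests = 1)
    endo_rows <- tab$outcome != "status"
    fdr <- bh_fdr(tab$p[endo_rows], q = cfg$assoc$fdr_q, m_override = budget)
    tab$q <- NA_real_; tab$discovery <- NA
    tab$q[endo_rows] <- fdr$q_values
    tab$discovery[endo_rows] <- fdr$discovery
    wtsv(tab, "associations.tsv")
    jsonlite::write_json(
      list(meff_scores = meff_s, meff_endophenotypes = meff_e,
           effective_test_budget = budget),
      file.path(out_dir, "testing_budget.json"), auto_unbox = TRUE, digits = NA)
    list(table = tab, meff_scores = meff_s, meff_endophenotypes = meff_e,
         budget = budget, endo = endo)
  })

  # ---- cluster ----
  res$cluster <- run_stage("cluster", function() {
    endo <- normalize_endophenotypes(res$assoc$endo)
    em <- as.matrix(endo[, endo_battery()])
    rownames(em) <- endo$sample_id
    complete <- em[stats::complete.cases(em), , drop = FALSE]
    sel <- select_k(complete, k_range = cfg$cluster$k_range,
                    seed = stage_seed(cfg$seed, "select_k"))
    km <- kmeans_missing(em, sel$k, seed = stage_seed(cfg$seed, "kmeans"),
                         restarts = cfg$cluster$restarts)
    resp <- classify_response(pheno$bprs_baseline, pheno$bprs_followup)
    cl_of <- km$assignment[match(pheno$sample_id, names(km$assignment))]
    enr_resp <- tryCatch(cluster_enrichment(cl_of, resp$responder),
                         error = function(e) NULL)
    diag_cases <- pheno$diagnosis[match(names(km$assignment), pheno$sample_id)]
    enr_diag <- cluster_enrichment(km$assignment, diag_cases)
    score_cases <- lapply(scores, function(s)
      s$residualized[match(names(km$assignment), names(s$residualized))])
    cmp <- compare_models(score_cases, as.character(km$assignment), diag_cases,
                          cluster_ref = as.character(sel$k))
    wtsv(data.frame(sample_id = rownames(em),
                    included = km$included,
                    cluster = km$assignment[match(rownames(em),
                                                  names(km$assignment))],
                    n_observed_vars = rowSums(!is.na(em))), "clusters.tsv")
    wtsv(data.frame(index = names(sel$votes), k_vote = as.integer(sel$votes)),
         "cluster_votes.tsv")
    wtsv(cmp$comparison, "model_comparison.tsv")
    list(selected_k = sel, clusters = km, response = resp,
         enrichment_response = enr_resp, enrichment_diagnosis = enr_diag,
         model_comparison = cmp)
  })

  manifest$total_seconds <- round(as.numeric(difftime(Sys.time(), t_all,
                                                      units = "secs")), 2)
  manifest$out_dir <- out_dir
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  list(manifest = manifest, results = res, out_dir = out_dir)
}

digest_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, force = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

stage_checksums <- function(out_dir, stage) {
  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!grepl("manifest[.]json$", files)]
  if (!length(files)) return(list())
  as.list(tools::md5sum(files))
}
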