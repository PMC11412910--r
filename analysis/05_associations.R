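#!/usr/bin/env Rscript
# Stage 5 — covariate-adjusted association and multiple-testing correction.
#
# Case status is regressed on each residualized score (logistic, per-SD odds
# ratios, Nagelkerke R^2) adjusting for sex, age, race and ethnicity. Within
# cases, every endophenotype is regressed on each score adjusting
# additionally for diagnosis (and scanner for cognitive-control measures;
# overall PGS is a covariate in pPGS models). The endophenotype p-values are
# BH-corrected at q = 0.10 against the Galwey effective-test budget computed
# from the observed score and endophenotype correlation structure.

library(ppgs)

out <- "results"
pheno <- read_pheno(file.path(out, "pheno.tsv"))
scores_tab <- read_pheno(file.path(out, "scores.tsv"))
score_names <- unique(scores_tab$pathway)
df <- pheno[pheno$sample_id %in% unique(scores_tab$sample_id), ]
col_of <- function(nm) paste0("score_", make.names(nm))
for (nm in score_names) {
  s <- scores_tab[scores_tab$pathway == nm, ]
  df[[col_of(nm)]] <- s$residualized[match(df$sample_id, s$sample_id)]
}

endo <- derive_endophenotypes(df)
cases <- merge(df, endo[, c("sample_id", c("gsf", "grf", "ymrs"))],
               by = "sample_id")
base_cov <- c("sex", "age", "race", "ethnicity")
scanner_vars <- c("dprime_context", "dlpfc_beta", "spc_beta")

rows <- list()
for (nm in score_names) {
  r <- fit_association(df, assoc_spec("status", "binary", col_of(nm), base_cov))
  rows[[length(rows) + 1]] <- data.frame(
    outcome = "status", predictor = nm, n = r$n, beta = r$beta, or = r$or,
    ci_low = r$or_ci[1], ci_high = r$or_ci[2], p = r$p,
    r2_nagelkerke = r$r2_nagelkerke)
  for (ph in endo_battery()) {
    covs <- c(base_cov, "diagnosis",
              if (ph %in% scanner_vars) "scanner",
              if (nm != "genome-wide") col_of("genome-wide"))
    r <- tryCatch(fit_association(
      cases, assoc_spec(ph, "continuous", col_of(nm), covs,
                        subset = "cases-only")), error = function(e) NULL)
    if (is.null(r)) next
    rows[[length(rows) + 1]] <- data.frame(
      outcome = ph, predictor = nm, n = r$n, beta = r$beta, or = NA,
      ci_low = r$ci[1], ci_high = r$ci[2], p = r$p, r2_nagelkerke = NA)
  }
}
tab <- do.call(rbind, rows)

case_rows <- df$status == 1
score_mat <- as.matrix(df[case_rows, col_of(score_names)])
meff_s <- galwey_meff(pairwise_corr(score_mat))
meff_e <- galwey_meff(pairwise_corr(as.matrix(endo[, endo_battery()])))
budget <- effective_test_budget(meff_s, meff_e, extra_tests = 1)
endo_rows <- tab$outcome != "status"
fdr <- bh_fdr(tab$p[endo_rows], q = 0.10, m_override = budget)
tab$q <- NA_real_; tab$discovery <- NA
tab$q[endo_rows] <- fdr$q_values
tab$discovery[endo_rows] <- fdr$discovery

data.table::fwrite(tab, file.path(out, "associations.tsv"), sep = "\t")
jsonlite::write_json(list(meff_scores = meff_s, meff_endophenotypes = meff_e,
                          effective_test_budget = budget),
                     file.path(out, "testing_budget.json"),
                     auto_unbox = TRUE, digits = NA)

cat(sprintf("effective tests: %.2f scores x %.2f endophenotypes -> budget %d\n",
            meff_s, meff_e, budget))
cat("\ncase-status associations:\n")
print(tab[tab$outcome == "status",
          c("predictor", "or", "ci_low", "ci_high", "p", "r2_nagelkerke")],
      row.names = FALSE, digits = 3)
cat("\nFDR discoveries among endophenotype tests:\n")
print(tab[endo_rows & tab$discovery,
          c("outcome", "predictor", "beta", "p", "q")],
      row.names = FALSE, digits = 3)
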