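#' Write genotypes as VCF 4.2 with dosage FORMAT
#'
#' Emits GT (from hard calls, unphased) and DS (dosage) per sample, and the
#' per-variant imputation quality as `INFO=<score>;EMPINFO=<score>` in the
#' INFO column.
#'
#' @param g [genotype_data()].
#' @param path output file (uncompressed .vcf).
#' @export
write_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation INFO score\">",
    "##INFO=<ID=EMPINFO,Number=1,Type=Float,Description=\"Empirical INFO score\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alt-allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$sample_ids), collapse = "\t")), con)
  info <- sprintf("INFO=%.4g;EMPINFO=%.4g",
                  if (is.null(g$info)) rep(1, nrow(g$variants)) else g$info,
                  if (is.null(g$emp_info)) rep(1, nrow(g$variants)) else g$emp_info)
  gt_code <- c("0/0", "0/1", "1/1")
  hc <- if (is.null(g$hardcall)) round(g$dosage) else g$hardcall
  lines <- vapply(seq_len(nrow(g$variants)), function(j) {
    v <- g$variants[j, ]
    gt <- ifelse(is.na(hc[, j]), "./.", gt_code[hc[, j] + 1])
    ds <- ifelse(is.na(g$dosage[, j]), ".", formatC(g$dosage[, j], format = "g"))
    paste(c(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", info[j],
            "GT:DS", paste(gt, ds, sep = ":")), collapse = "\t")
  }, "")
  writeLines(lines, con)
  invisible(path)
}

#' Read a dosage VCF written by [write_vcf()] (or any VCF with a DS field)
#'
#' @param path VCF file.
#' @return A [genotype_data()]; INFO/EMPINFO fields are recovered when
#'   present, hard calls from GT.
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  gt <- vcfR::extract.gt(v, element = "GT")
  hc <- matrix(NA_integer_, nrow(gt), ncol(gt))
  hc[gt %in% c("0/0", "0|0")] <- 0L
  hc[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  hc[gt %in% c("1/1", "1|1")] <- 2L
  info <- suppressWarnings(as.numeric(vcfR::extract.info(v, "INFO")))
  emp <- suppressWarnings(as.numeric(vcfR::extract.info(v, "EMPINFO")))
  dsm <- t(ds)
  variants <- data.frame(id = fx$ID, chrom = fx$CHROM,
                         pos = as.integer(fx$POS), ref = fx$REF, alt = fx$ALT,
                         frq = colMeans(dsm, na.rm = TRUE) / 2,
                         stringsAsFactors = FALSE)
  genotype_data(dsm, variants, sample_ids = colnames(ds),
                hardcall = t(hc), info = info, emp_info = emp)
}

#' Write summary statistics as TSV (SNP CHR BP A1 A2 BETA P FRQ [SE])
#' @param ss summary-statistics data.frame.
#' @param path output file.
#' @export
write_sumstats <- function(ss, path) {
  out <- data.frame(SNP = ss$id, CHR = ss$chrom, BP = ss$pos, A1 = ss$a1,
                    A2 = ss$a2, BETA = ss$beta, P = ss$p, FRQ = ss$frq,
                    SE = ss$se)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a summary-statistics TSV written by [write_sumstats()]
#' @param path input file.
#' @return data.frame with internal column names.
#' @export
read_sumstats <- function(path) {
  x <- data.table::fread(path, data.table = FALSE)
  out <- data.frame(id = x$SNP, chrom = as.character(x$CHR), pos = x$BP,
                    a1 = x$A1, a2 = x$A2, beta = x$BETA, p = x$P, frq = x$FRQ,
                    stringsAsFactors = FALSE)
  if ("SE" %in% names(x)) out$se <- x$SE
  out
}

#' Write pathways as GMT
#' @param pathways named list of gene-id vectors.
#' @param path output file.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(names(pathways), function(nm)
    paste(c(nm, "synthetic pathway", pathways[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT file into a named list of gene sets
#' @param path GMT file.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE))
    return(fgsea::gmtPathways(path))
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  stats::setNames(lapply(lines, function(l) l[-(1:2)]),
                  vapply(lines, `[`, "", 1))
}

#' Write gene annotation as BED-like TSV (0-based half-open)
#' @param annotation data.frame gene_id, chrom, start, end.
#' @param path output file.
#' @export
write_annotation <- function(annotation, path) {
  data.table::fwrite(annotation[, c("chrom", "start", "end", "gene_id")],
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a BED-like gene annotation TSV
#' @param path input file.
#' @return data.frame gene_id, chrom, start, end, length.
#' @export
read_annotation <- function(path) {
  x <- data.table::fread(path, data.table = FALSE, header = FALSE,
                         col.names = c("chrom", "start", "end", "gene_id"))
  data.frame(gene_id = x$gene_id, chrom = as.character(x$chrom),
             start = x$start, end = x$end, length = x$end - x$start,
             stringsAsFactors = FALSE)
}

#' Write / read the phenotype table as TSV
#' @param pheno phenotype data.frame.
#' @param path file path.
#' @export
write_pheno <- function(pheno, path) {
  data.table::fwrite(pheno, path, sep = "\t")
  invisible(path)
}

#' @rdname write_pheno
#' @export
read_pheno <- function(path) {
  data.table::fread(path, data.table = FALSE)
}

#' Write the QC report as TSV + JSON
#' @param report `qc_report` from [run_qc()].
#' @param stem output path without extension.
#' @export
write_qc_report <- function(report, stem) {
  data.table::fwrite(as.data.frame(report), paste0(stem, ".tsv"), sep = "\t")
  jsonlite::write_json(list(steps = as.data.frame(report),
                            initial = as.list(attr(report, "initial")),
                            final = as.list(attr(report, "final"))),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}
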