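#' Genotype container
#'
#' A light S3 container for a sample x variant dosage matrix plus variant
#' metadata. Dosages are on the 0..2 scale (NA = missing); `hardcall` holds
#' integer genotype calls where available (here: always, the generator emits
#' hard calls). `info` and `emp_info` are per-variant imputation-quality
#' scores in [0, 1].
#'
#' @param dosage numeric matrix, samples x variants, values in [0, 2] or NA.
#' @param variants data.frame with columns `id`, `chrom`, `pos` (1-based,
#'   strictly increasing within chromosome), `ref`, `alt`, `frq`
#'   (effect/alt-allele frequency).
#' @param sample_ids character vector, one per dosage row.
#' @param hardcall optional integer matrix of 0/1/2 calls (NA = missing).
#' @param info,emp_info optional per-variant quality scores.
#' @return An object of class `genotype_data`.
#' @export
genotype_data <- function(dosage, variants, sample_ids,
                          hardcall = NULL, info = NULL, emp_info = NULL) {
  dosage <- as.matrix(dosage)
  stopifnot(is.data.frame(variants),
            all(c("id", "chrom", "pos", "ref", "alt", "frq") %in% names(variants)))
  if (nrow(dosage) != length(sample_ids))
    stop("dosage has ", nrow(dosage), " rows but ", length(sample_ids), " sample ids")
  if (ncol(dosage) != nrow(variants))
    stop("dosage has ", ncol(dosage), " columns but ", nrow(variants), " variant records")
  if (anyDuplicated(variants$id)) stop("duplicate variant ids")
  if (!all(is.na(dosage)) && length(dosage)) {
    rng <- range(dosage, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 2) stop("dosages outside [0, 2]")
  }
  for (chr in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == chr]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions not strictly increasing on chromosome ", chr)
  }
  if (any(variants$frq < 0 | variants$frq > 1, na.rm = TRUE))
    stop("allele frequencies outside [0, 1]")
  dimnames(dosage) <- list(sample_ids, variants$id)
  if (!is.null(hardcall)) dimnames(hardcall) <- dimnames(dosage)
  structure(list(dosage = dosage, variants = variants,
                 sample_ids = sample_ids, hardcall = hardcall,
                 info = info, emp_info = emp_info),
            class = "genotype_data")
}

#' @export
print.genotype_data <- function(x, ...) {
  cat("genotype_data:", length(x$sample_ids), "samples x",
      nrow(x$variants), "variants\n")
  cat("  missing dosages:", sum(is.na(x$dosage)), "\n")
  invisible(x)
}

#' @export
dim.genotype_data <- function(x) dim(x$dosage)

#' Subset a genotype_data object
#'
#' @param g a `genotype_data` object.
#' @param samples logical/integer/character index of samples to keep.
#' @param variants logical/integer/character index of variants to keep.
#' @return A `genotype_data` with the selected rows/columns; variant order is
#'   preserved as in the original object.
#' @export
subset_genotypes <- function(g, samples = NULL, variants = NULL) {
  si <- if (is.null(samples)) seq_along(g$sample_ids) else samples
  if (is.character(si)) si <- match(si, g$sample_ids)
  vi <- if (is.null(variants)) seq_len(nrow(g$variants)) else variants
  if (is.character(vi)) vi <- match(vi, g$variants$id)
  if (is.logical(vi)) vi <- which(vi)
  if (is.logical(si)) si <- which(si)
  genotype_data(
    dosage = g$dosage[si, vi, drop = FALSE],
    variants = g$variants[vi, , drop = FALSE],
    sample_ids = g$sample_ids[si],
    hardcall = if (!is.null(g$hardcall)) g$hardcall[si, vi, drop = FALSE],
    info = g$info[vi], emp_info = g$emp_info[vi]
  )
}
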