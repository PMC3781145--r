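#' Construct a case-control SNP dataset
#'
#' The single data container of the pipeline: a samples-by-SNPs genotype
#' matrix coded as minor-allele counts (0/1/2, `NA` = missing call), a sample
#' table (phenotype, disease subtype, covariates) and a SNP annotation table.
#' Genotype 0 is the homozygote of the most frequent allele in controls, so
#' odds ratios computed downstream are referenced to that genotype.
#'
#' @param genotypes integer matrix, samples x SNPs, entries in `{0, 1, 2, NA}`.
#' @param samples data.frame with columns `sample_id`, `phenotype` (0 =
#'   control, 1 = case), `subtype` (one of `control`, `cPTC`, `fvPTC`,
#'   `otherPTC`, `FTC`), `age` (years, `NA` allowed), `sex` (`female`/`male`),
#'   `country`.
#' @param snps data.frame with columns `snp_id`, `gene`, `allele_major`,
#'   `allele_minor` and optionally `functional_note`. Alleles are single
#'   characters and must differ within a SNP.
#' @return An object of class `snp_dataset`.
#' @export
snp_dataset <- function(genotypes, samples, snps) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)

  need_s <- c("sample_id", "phenotype", "subtype", "age", "sex", "country")
  miss <- setdiff(need_s, names(samples))
  if (length(miss)) stop("samples table lacks columns: ", paste(miss, collapse = ", "))
  need_m <- c("snp_id", "allele_major", "allele_minor")
  miss <- setdiff(need_m, names(snps))
  if (length(miss)) stop("snps table lacks columns: ", paste(miss, collapse = ", "))
  if (!"gene" %in% names(snps)) snps$gene <- NA_character_
  if (!"functional_note" %in% names(snps)) snps$functional_note <- NA_character_

  if (nrow(genotypes) != nrow(samples))
    stop("genotype rows (", nrow(genotypes), ") != samples (", nrow(samples), ")")
  if (ncol(genotypes) != nrow(snps))
    stop("genotype columns (", ncol(genotypes), ") != SNPs (", nrow(snps), ")")
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id")
  if (anyDuplicated(snps$snp_id)) stop("duplicate snp_id")
  bad <- genotypes[!is.na(genotypes) & !(genotypes %in% 0:2)]
  if (length(bad)) stop("genotype entries outside {0, 1, 2, NA}")
  if (any(snps$allele_major == snps$allele_minor))
    stop("allele_major must differ from allele_minor")
  if (!all(samples$subtype %in% .SUBTYPES))
    stop("unknown subtype label; expected one of ", paste(.SUBTYPES, collapse = ", "))
  if (!all(samples$phenotype %in% c(0L, 1L)))
    stop("phenotype must be 0 (control) or 1 (case)")
  if (any((samples$phenotype == 0L) != (samples$subtype == "control")))
    stop("phenotype 0 must coincide with subtype 'control'")

  samples$phenotype <- as.integer(samples$phenotype)
  rownames(genotypes) <- samples$sample_id
  colnames(genotypes) <- snps$snp_id
  structure(list(genotypes = genotypes, samples = samples, snps = snps),
            class = "snp_dataset")
}

#' @export
print.snp_dataset <- function(x, ...) {
  cat(sprintf("<snp_dataset> %d samples (%d cases / %d controls) x %d SNPs\n",
              nrow(x$genotypes), sum(x$samples$phenotype == 1L),
              sum(x$samples$phenotype == 0L), ncol(x$genotypes)))
  tab <- table(x$samples$subtype)
  cat("  subtypes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.snp_dataset <- function(x) dim(x$genotypes)

# resolve a snp_id (or integer index) to a column index
snp_index <- function(dataset, snp) {
  if (is.numeric(snp)) {
    idx <- as.integer(snp)
    if (any(idx < 1L | idx > ncol(dataset$genotypes))) stop("SNP index out of range")
    return(idx)
  }
  idx <- match(snp, dataset$snps$snp_id)
  if (anyNA(idx)) stop("unknown snp_id: ", paste(snp[is.na(idx)], collapse = ", "))
  idx
}

# resolve a sample filter to a logical vector
sample_filter <- function(dataset, group) {
  s <- dataset$samples
  if (is.null(group) || identical(group, "all")) return(rep(TRUE, nrow(s)))
  if (is.logical(group)) {
    stopifnot(length(group) == nrow(s))
    return(group)
  }
  if (identical(group, "controls")) return(s$phenotype == 0L)
  if (identical(group, "cases")) return(s$phenotype == 1L)
  if (all(group %in% .SUBTYPES)) return(s$subtype %in% group)
  stop("cannot interpret sample group: ", paste(group, collapse = ", "))
}

#' Minor allele frequency of a SNP within a sample group
#'
#' Missing genotypes are excluded from numerator and denominator. Because the
#' coding anchors the minor allele to the full control series at load time,
#' the value over controls is at most 0.5 (ties allowed).
#'
#' @param dataset an [snp_dataset].
#' @param snp snp_id or column index.
#' @param group `"all"`, `"controls"`, `"cases"`, a vector of subtype labels,
#'   or a logical sample mask.
#' @return frequency in `[0, 1]`.
#' @export
minor_allele_freq <- function(dataset, snp, group = "all") {
  j <- snp_index(dataset, snp)
  stopifnot(length(j) == 1L)
  g <- dataset$genotypes[sample_filter(dataset, group), j]
  g <- g[!is.na(g)]
  if (!length(g)) stop("all genotypes missing in the requested group")
  sum(g) / (2 * length(g))
}

#' Restrict a dataset to controls plus selected case subtypes
#'
#' All controls are kept; cases are kept only if their subtype belongs to
#' `case_group`. The genotype coding is NOT re-derived: the minor allele
#' stays anchored to the full control series, so discovery and replication
#' stay on a common coding.
#'
#' @param dataset an [snp_dataset].
#' @param case_group nonempty character vector of case subtypes, e.g.
#'   `c("cPTC")` or `c("cPTC", "fvPTC", "otherPTC")` for PTC overall.
#' @return the restricted [snp_dataset].
#' @export
stratify <- function(dataset, case_group) {
  if (!length(case_group)) stop("case_group must be nonempty")
  bad <- setdiff(case_group, setdiff(.SUBTYPES, "control"))
  if (length(bad)) stop("not a case subtype: ", paste(bad, collapse = ", "))
  keep <- dataset$samples$phenotype == 0L | dataset$samples$subtype %in% case_group
  if (!any(dataset$samples$phenotype == 1L & keep))
    stop("no cases remain after stratification")
  snp_dataset(dataset$genotypes[keep, , drop = FALSE],
              dataset$samples[keep, , drop = FALSE],
              dataset$snps)
}

#' Concatenate two datasets sharing a SNP panel
#'
#' Used for the combined (pooled-stage) analysis. Both datasets must carry
#' identical SNP panels with identical allele coding; a `stage` column is
#' added to the sample table so it can be used as a covariate.
#'
#' @param x,y [snp_dataset] objects on the same panel.
#' @param stage_labels length-2 character labels stored in the `stage` column.
#' @return pooled [snp_dataset] with a `stage` sample column.
#' @export
combine_datasets <- function(x, y, stage_labels = c("I", "II")) {
  if (!identical(x$snps$snp_id, y$snps$snp_id))
    stop("SNP panels differ")
  if (!identical(x$snps$allele_major, y$snps$allele_major) ||
      !identical(x$snps$allele_minor, y$snps$allele_minor))
    stop("allele coding differs between datasets")
  sx <- x$samples; sy <- y$samples
  if (is.null(sx$stage)) sx$stage <- stage_labels[1]
  sy$stage <- stage_labels[2]
  if (anyDuplicated(c(sx$sample_id, sy$sample_id))) {
    sx$sample_id <- paste0(stage_labels[1], ".", sx$sample_id)
    sy$sample_id <- paste0(stage_labels[2], ".", sy$sample_id)
  }
  common <- intersect(names(sx), names(sy))
  out <- snp_dataset(rbind(x$genotypes, y$genotypes),
                     rbind(sx[common], sy[common]), x$snps)
  out
}

# canonical unordered pair key
pair_key <- function(snp1, snp2) paste(sort(c(snp1, snp2)), collapse = "|")
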