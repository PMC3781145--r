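#' Read a PLINK text fileset (.ped/.map)
#'
#' Whitespace-delimited PLINK text dialect: each .ped row is FID IID PAT MAT
#' SEX PHENO followed by two allele characters per SNP; "0" denotes a missing
#' allele and phenotype is 1 = control, 2 = case. Genotypes are recoded to
#' minor-allele counts with the minor allele determined from controls (ties
#' at 0.5 broken towards the lexicographically smaller allele character).
#'
#' @param ped_path path to the .ped file.
#' @param map_path path to the .map file (columns: chrom, snp_id, cM, bp).
#' @param samples optional sample table (as in [snp_dataset]) overriding the
#'   .ped phenotype/sex fields; matched by sample_id (= IID). When absent,
#'   subtype is `control`/`otherPTC` by phenotype, sex 1 = male, 2 = female,
#'   and age/country are `NA`.
#' @return an [snp_dataset].
#' @export
read_plink <- function(ped_path, map_path, samples = NULL) {
  map <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(map) < 4) stop(".map must have 4 columns (chrom, snp_id, cM, bp)")
  snp_ids <- as.character(map[[2]])
  m <- length(snp_ids)

  ped <- read.table(ped_path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (ncol(ped) != 6 + 2 * m)
    stop(".ped has ", ncol(ped), " fields; expected ", 6 + 2 * m,
         " for ", m, " SNPs")
  n <- nrow(ped)
  pheno_raw <- ped[[6]]
  if (!all(pheno_raw %in% c("1", "2")))
    stop("PLINK phenotype must be 1 (control) or 2 (case)")
  phenotype <- as.integer(pheno_raw == "2")

  a1 <- as.matrix(ped[, 6 + 2 * seq_len(m) - 1, drop = FALSE])
  a2 <- as.matrix(ped[, 6 + 2 * seq_len(m), drop = FALSE])
  ok <- c("A", "C", "G", "T", "0")
  if (!all(a1 %in% ok) || !all(a2 %in% ok))
    stop("allele characters must be A, C, G, T or 0")
  half_missing <- (a1 == "0") != (a2 == "0")
  if (any(half_missing)) stop("half-missing genotype (one allele '0')")

  geno <- matrix(NA_integer_, n, m)
  allele_major <- allele_minor <- character(m)
  is_control <- phenotype == 0L
  for (j in seq_len(m)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    obs <- c(x1[x1 != "0"], x2[x2 != "0"])
    alleles <- sort(unique(obs))
    if (length(alleles) > 2)
      stop("SNP ", snp_ids[j], " has >2 distinct alleles")
    if (length(alleles) == 0) alleles <- c("A", "C")  # fully missing SNP
    if (length(alleles) == 1) alleles <- c(alleles, setdiff(c("A", "C"), alleles)[1])
    # minor allele from controls; lexicographic tie-break at 0.5
    ctl <- c(x1[is_control], x2[is_control])
    ctl <- ctl[ctl != "0"]
    n2 <- sum(ctl == alleles[2])
    f2 <- if (length(ctl)) n2 / length(ctl) else 0
    minor <- if (f2 < 0.5) alleles[2] else if (f2 > 0.5) alleles[1] else alleles[1]
    major <- setdiff(alleles, minor)
    cnt <- (x1 == minor) + (x2 == minor)
    cnt[x1 == "0"] <- NA_integer_
    geno[, j] <- as.integer(cnt)
    allele_major[j] <- major; allele_minor[j] <- minor
  }

  sample_id <- as.character(ped[[2]])
  if (is.null(samples)) {
    sex <- c("male", "female", NA)[match(ped[[5]], c("1", "2"))]
    samples <- data.frame(
      sample_id = sample_id, phenotype = phenotype,
      subtype = ifelse(phenotype == 1L, "otherPTC", "control"),
      age = NA_real_, sex = sex, country = NA_character_,
      stringsAsFactors = FALSE)
  } else {
    idx <- match(sample_id, samples$sample_id)
    if (anyNA(idx)) stop("sample in .ped missing from sample table")
    samples <- samples[idx, , drop = FALSE]
    if (!all(samples$phenotype == phenotype))
      stop("phenotype mismatch between .ped and sample table")
  }
  snps <- data.frame(snp_id = snp_ids, gene = NA_character_,
                     allele_major = allele_major, allele_minor = allele_minor,
                     stringsAsFactors = FALSE)
  snp_dataset(geno, samples, snps)
}

#' Write a dataset as PLINK text (.ped/.map)
#'
#' @param dataset an [snp_dataset].
#' @param ped_path,map_path output paths.
#' @export
write_plink <- function(dataset, ped_path, map_path) {
  g <- dataset$genotypes
  n <- nrow(g); m <- ncol(g)
  maj <- dataset$snps$allele_major; min_ <- dataset$snps$allele_minor
  al <- matrix("0", n, 2 * m)
  for (j in seq_len(m)) {
    gj <- g[, j]
    a1 <- ifelse(is.na(gj), "0", ifelse(gj >= 1, min_[j], maj[j]))
    a2 <- ifelse(is.na(gj), "0", ifelse(gj == 2, min_[j], maj[j]))
    al[, 2 * j - 1] <- a1; al[, 2 * j] <- a2
  }
  s <- dataset$samples
  sex <- ifelse(is.na(s$sex), "0", ifelse(s$sex == "male", "1", "2"))
  lead <- cbind(s$sample_id, s$sample_id, "0", "0", sex,
                as.character(s$phenotype + 1L))
  write.table(cbind(lead, al), ped_path, quote = FALSE, sep = " ",
              row.names = FALSE, col.names = FALSE)
  map <- data.frame(chrom = 1L, snp_id = dataset$snps$snp_id, cm = 0, bp = seq_len(m))
  write.table(map, map_path, quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(dataset)
}

#' Read the tabular dialect (genotype CSV + sample CSV)
#'
#' The genotype file is samples x SNPs with a leading `sample_id` column and
#' one column per SNP holding minor-allele counts 0/1/2 (`NA` = missing).
#' The sample file carries `sample_id, phenotype, subtype, age, sex, country`.
#' Rows are aligned by `sample_id`; the 0/1/2 coding is taken as supplied.
#' The dialect carries no allele letters, so placeholder alleles A (major) /
#' B (minor) are stored.
#'
#' @param genotype_csv,sample_csv file paths.
#' @return an [snp_dataset].
#' @export
read_tabular <- function(genotype_csv, sample_csv) {
  gt <- utils::read.csv(genotype_csv, stringsAsFactors = FALSE,
                        check.names = FALSE)
  if (names(gt)[1] != "sample_id") stop("genotype file must start with sample_id")
  sm <- utils::read.csv(sample_csv, stringsAsFactors = FALSE)
  if (!setequal(gt$sample_id, sm$sample_id))
    stop("sample_id sets differ between genotype and sample files")
  sm <- sm[match(gt$sample_id, sm$sample_id), , drop = FALSE]
  geno <- as.matrix(gt[, -1, drop = FALSE])
  bad <- geno[!is.na(geno) & !(geno %in% 0:2)]
  if (length(bad)) stop("genotype token outside {0,1,2,NA}: ", bad[1])
  storage.mode(geno) <- "integer"
  snps <- data.frame(snp_id = colnames(geno), gene = NA_character_,
                     allele_major = "A", allele_minor = "B",
                     stringsAsFactors = FALSE)
  snp_dataset(geno, sm, snps)
}

#' Write a dataset in the tabular dialect
#'
#' @param dataset an [snp_dataset].
#' @param genotype_csv,sample_csv output paths.
#' @export
write_tabular <- function(dataset, genotype_csv, sample_csv) {
  gt <- data.frame(sample_id = dataset$samples$sample_id,
                   dataset$genotypes, check.names = FALSE)
  utils::write.csv(gt, genotype_csv, row.names = FALSE, quote = FALSE, na = "NA")
  cols <- c("sample_id", "phenotype", "subtype", "age", "sex", "country")
  extra <- setdiff(names(dataset$samples), cols)
  utils::write.csv(dataset$samples[c(cols, extra)], sample_csv,
                   row.names = FALSE, quote = FALSE, na = "NA")
  invisible(dataset)
}
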