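#' Label two-locus genotype cells by case:control ratio
#'
#' The classic MDR dimensionality reduction: a cell is "high" risk when its
#' case:control ratio reaches the threshold `T` (a cell with cases but no
#' controls is high); otherwise "low". Empty cells are labeled low.
#'
#' @param cases,controls 3x3 matrices of cell counts (rows = first SNP
#'   minor-allele count 0..2, columns = second SNP).
#' @param T case:control ratio cutoff (> 0), conventionally the sample's
#'   overall case:control ratio.
#' @return 3x3 character matrix of `"high"`/`"low"`.
#' @export
mdr_label_cells <- function(cases, controls, T) {
  stopifnot(T > 0)
  if (any(cases < 0) || any(controls < 0)) stop("negative cell count")
  lab <- matrix("low", 3, 3)
  high <- ifelse(controls == 0, cases > 0, cases / controls >= T)
  lab[high] <- "high"
  lab
}

#' Balanced accuracy of an MDR cell labeling
#'
#' Classifies every sample by its cell's label (high = predicted case) and
#' returns (sensitivity + specificity) / 2 over samples with both genotypes
#' observed.
#'
#' @param labels 3x3 `"high"`/`"low"` matrix as from [mdr_label_cells].
#' @param g1,g2 genotype vectors (0/1/2, `NA` = missing).
#' @param pheno 0/1 phenotype vector.
#' @return balanced accuracy in `[0, 1]`.
#' @export
mdr_balanced_accuracy <- function(labels, g1, g2, pheno) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]; pheno <- pheno[ok]
  if (!any(pheno == 1) || !any(pheno == 0))
    stop("evaluation split needs both cases and controls")
  pred <- labels[cbind(g1 + 1L, g2 + 1L)] == "high"
  sens <- mean(pred[pheno == 1])
  spec <- mean(!pred[pheno == 0])
  (sens + spec) / 2
}

# stratified fold assignment (0-based), deterministic given the RNG state
stratified_folds <- function(pheno, n_folds) {
  fold <- integer(length(pheno))
  for (cls in c(0L, 1L)) {
    idx <- which(pheno == cls)
    fold[idx] <- (sample(seq_along(idx)) - 1L) %% n_folds
  }
  fold
}

#' Exhaustive cross-validated MDR scan over SNP pairs
#'
#' For every SNP pair, stratified `n_folds`-fold cross-validation: within
#' each training fold cells are labeled with `T` = training case:control
#' ratio, and the labeling is scored by balanced accuracy (BA) on the held
#' fold. Pairs are ranked by mean testing BA; cross-validation consistency
#' (CVC) counts the folds in which the pair had the best training BA (ties
#' to the lexicographically first pair). Samples missing either genotype are
#' excluded for that pair only. Deterministic given `seed`. MDR is
#' covariate-naive by construction.
#'
#' @param dataset an [snp_dataset].
#' @param case_group optional case-subtype restriction (see [stratify]).
#' @param pairs optional 2-column matrix/data.frame of snp_ids (default: all
#'   pairs).
#' @param n_folds folds (>= 2), default 10.
#' @param seed integer seed for the fold assignment.
#' @return data.frame of class `mdr_scan`: snp1, snp2, mean train/test BA,
#'   cvc; ranked by mean test BA. Fold assignment and per-fold thresholds
#'   are kept in attributes.
#' @export
mdr_scan <- function(dataset, case_group = NULL, pairs = NULL, n_folds = 10,
                     seed = NULL) {
  stopifnot(n_folds >= 2)
  d <- if (is.null(case_group)) dataset else stratify(dataset, case_group)
  if (nrow(d$genotypes) < n_folds) stop("fewer samples than folds")
  if (!is.null(seed)) set.seed(seed)
  pheno <- d$samples$phenotype
  fold <- stratified_folds(pheno, n_folds)

  ids <- d$snps$snp_id
  if (is.null(pairs)) {
    cmb <- combn(length(ids), 2)
    pa <- cmb[1, ]; pb <- cmb[2, ]
  } else {
    pairs <- as.matrix(pairs)
    pa <- snp_index(d, pairs[, 1]); pb <- snp_index(d, pairs[, 2])
    swap <- pa > pb
    tmp <- pa[swap]; pa[swap] <- pb[swap]; pb[swap] <- tmp
  }
  geno <- d$genotypes
  geno[is.na(geno)] <- -1L
  res <- .cpp_mdr_scan(geno, pheno, fold, as.integer(n_folds),
                       as.integer(pa - 1L), as.integer(pb - 1L))
  train_ba <- res$train_ba; test_ba <- res$test_ba
  # CVC: per fold, first pair attaining the max training BA
  best <- apply(train_ba, 2, which.max)
  cvc <- tabulate(best, nbins = length(pa))
  out <- data.frame(snp1 = ids[pa], snp2 = ids[pb],
                    mean_train_ba = rowMeans(train_ba, na.rm = TRUE),
                    mean_test_ba = rowMeans(test_ba, na.rm = TRUE),
                    cvc = cvc, stringsAsFactors = FALSE)
  out <- out[order(-out$mean_test_ba, out$snp1, out$snp2), ]
  rownames(out) <- NULL
  attr(out, "n_folds") <- n_folds
  attr(out, "fold") <- fold
  attr(out, "case_group") <- case_group
  class(out) <- c("mdr_scan", "data.frame")
  out
}

#' Fit the final MDR model for one pair on the full data
#'
#' Labels the 3x3 grid using the whole analysis sample at `T` = overall
#' case:control ratio; the conventional report of the selected model.
#'
#' @inheritParams mdr_scan
#' @param pair character vector of two snp_ids.
#' @param T optional ratio cutoff (default: overall case:control ratio).
#' @return list with `pair`, `grid_labels`, `threshold_T`, `train_ba`.
#' @export
mdr_fit_pair <- function(dataset, pair, case_group = NULL, T = NULL) {
  d <- if (is.null(case_group)) dataset else stratify(dataset, case_group)
  j <- snp_index(d, pair)
  g1 <- d$genotypes[, j[1]]; g2 <- d$genotypes[, j[2]]
  pheno <- d$samples$phenotype
  ok <- !is.na(g1) & !is.na(g2)
  if (is.null(T)) T <- sum(pheno == 1) / sum(pheno == 0)
  tab <- function(cls) {
    m <- matrix(0, 3, 3)
    t0 <- table(factor(g1[ok & pheno == cls], levels = 0:2),
                factor(g2[ok & pheno == cls], levels = 0:2))
    m[] <- as.numeric(t0); m
  }
  cases <- tab(1L); controls <- tab(0L)
  labels <- mdr_label_cells(cases, controls, T)
  list(pair = pair, grid_labels = labels, threshold_T = T,
       train_ba = mdr_balanced_accuracy(labels, g1, g2, pheno))
}

#' Flag MDR-detected pairs for the consensus rule
#'
#' A pair is flagged when (i) its cross-validation consistency reaches
#' `cvc_min` of the folds and (ii) its mean testing BA exceeds the
#' `1 - alpha` quantile of a permutation null of the scan's top testing BA
#' (phenotype labels permuted, fold assignment kept, full rescan per
#' permutation). This numeric convention stands in for selection criteria
#' that MDR applications report only graphically.
#'
#' @param dataset the dataset the scan was run on (after any
#'   stratification).
#' @param scan an `mdr_scan` result.
#' @param case_group case-subtype restriction used for the scan.
#' @param cvc_min minimum CVC (default 6 of 10 folds).
#' @param n_perm permutations for the top-BA null (default 100).
#' @param alpha tail probability for the null threshold (default 0.05).
#' @param seed integer seed for the permutations.
#' @return character vector of flagged pair keys (`"snp1|snp2"`), with the
#'   null threshold in attribute `ba_threshold`.
#' @export
mdr_flag <- function(dataset, scan, case_group = NULL, cvc_min = 6,
                     n_perm = 100, alpha = 0.05, seed = NULL) {
  d <- if (is.null(case_group)) dataset else stratify(dataset, case_group)
  if (!is.null(seed)) set.seed(seed)
  pheno <- d$samples$phenotype
  fold <- attr(scan, "fold")
  n_folds <- attr(scan, "n_folds")
  pa <- snp_index(d, scan$snp1); pb <- snp_index(d, scan$snp2)
  swap <- pa > pb
  tmp <- pa[swap]; pa[swap] <- pb[swap]; pb[swap] <- tmp
  geno <- d$genotypes
  geno[is.na(geno)] <- -1L
  null_top <- vapply(seq_len(n_perm), function(b) {
    pp <- sample(pheno)
    r <- .cpp_mdr_scan(geno, pp, fold, as.integer(n_folds),
                       as.integer(pa - 1L), as.integer(pb - 1L))
    max(rowMeans(r$test_ba, na.rm = TRUE))
  }, 0)
  thr <- as.numeric(quantile(null_top, 1 - alpha, type = 7))
  sel <- scan$cvc >= cvc_min & scan$mean_test_ba > thr
  keys <- mapply(pair_key, scan$snp1[sel], scan$snp2[sel], USE.NAMES = FALSE)
  structure(as.character(keys), ba_threshold = thr)
}
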