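# ---- shared assembly of the MB-MDR regression inputs -----------------------

# Build the per-pair analysis pieces: design matrix base (intercept +
# covariates [+ log-additive codings of both SNPs when adjust_marginal]),
# the 0..8 cell index (row-major 3*g1+g2) and the phenotype, over samples
# complete for the pair and covariates.
mbmdr_inputs <- function(dataset, pair, covariates, adjust_marginal) {
  j <- snp_index(dataset, pair)
  if (j[1] == j[2]) stop("pair must name two distinct SNPs")
  g1 <- dataset$genotypes[, j[1]]; g2 <- dataset$genotypes[, j[2]]
  s <- dataset$samples
  ok <- !is.na(g1) & !is.na(g2)
  cv_df <- NULL
  if (length(covariates)) {
    cv_df <- s[covariates]
    for (cv in covariates) {
      if (!cv %in% names(s)) stop("unknown covariate: ", cv)
      ok <- ok & !is.na(s[[cv]])
    }
  }
  g1 <- g1[ok]; g2 <- g2[ok]
  y <- s$phenotype[ok]
  X <- matrix(1, length(y), 1)
  if (length(covariates)) {
    cv_df <- cv_df[ok, , drop = FALSE]
    for (cv in covariates) {
      v <- cv_df[[cv]]
      if (is.character(v) || is.factor(v)) {
        v <- droplevels(factor(v))
        if (nlevels(v) >= 2)
          X <- cbind(X, model.matrix(~v)[, -1, drop = FALSE])
      } else {
        X <- cbind(X, as.numeric(v))
      }
    }
  }
  if (adjust_marginal) {
    if (length(unique(g1)) > 1) X <- cbind(X, as.numeric(g1))
    if (length(unique(g2)) > 1) X <- cbind(X, as.numeric(g2))
  }
  # drop linearly dependent adjustment columns (e.g. a stage indicator that
  # coincides with country) so the cell fits stay full rank
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  list(X = X, y = as.numeric(y), cell = as.integer(3L * g1 + g2),
       keep = ok, n = length(y))
}

label_chr <- function(code) c("O", "H", "L")[code + 1L]

#' MB-MDR risk categorization of a SNP pair
#'
#' Assigns each of the nine two-SNP genotype combinations to a risk
#' category: per cell, a logistic regression of case status on the
#' cell-membership indicator plus covariates (plus the log-additive codings
#' of both SNPs when `adjust_marginal`, so purely additive SNP pairs do not
#' masquerade as interactions) is fit; the cell is `H` (high risk) when the
#' coefficient is positive with p < `alpha_cell`, `L` when negative with
#' p < `alpha_cell`, otherwise `O` (neutral). Cells with fewer than
#' `min_cell` samples, or whose test fails to converge or separates, stay
#' `O`.
#'
#' @param dataset an [snp_dataset] (already stratified to the case group of
#'   interest).
#' @param pair character vector of two distinct snp_ids.
#' @param covariates covariate columns of the sample table (e.g.
#'   `c("age", "sex", "country")`).
#' @param adjust_marginal adjust the cell tests and statistic for the two
#'   SNPs' marginal log-additive effects (default `TRUE`).
#' @param alpha_cell per-cell significance threshold (default 0.1).
#' @param min_cell minimum cell occupancy (default 10).
#' @return object of class `risk_categorization`: `pair`, `labels` (3x3
#'   `H`/`L`/`O`, rows = first SNP minor-allele count), `cell_tests`
#'   (sign, p, n per cell), `alleles`, `provenance = "discovery"` and the
#'   settings needed to recompute the statistic.
#' @export
mbmdr_categorize <- function(dataset, pair, covariates = NULL,
                             adjust_marginal = TRUE, alpha_cell = 0.1,
                             min_cell = 10) {
  stopifnot(alpha_cell > 0, alpha_cell <= 1, min_cell >= 0)
  inp <- mbmdr_inputs(dataset, pair, covariates, adjust_marginal)
  ev <- .cpp_mbmdr_eval(inp$X, inp$cell, inp$y, alpha_cell,
                        as.integer(min_cell))
  labels <- matrix(label_chr(ev$labels), 3, 3, byrow = TRUE,
                   dimnames = list(paste0(pair[1], "=", 0:2),
                                   paste0(pair[2], "=", 0:2)))
  cell_tests <- data.frame(
    cell = paste0(rep(0:2, each = 3), rep(0:2, 3)),
    sign = ev$sign, p = ev$p, n_in_cell = ev$n_cell,
    label = label_chr(ev$labels), stringsAsFactors = FALSE)
  j <- snp_index(dataset, pair)
  structure(list(pair = pair, labels = labels, cell_tests = cell_tests,
                 alleles = dataset$snps[j, c("snp_id", "allele_major",
                                             "allele_minor")],
                 provenance = "discovery",
                 settings = list(covariates = covariates,
                                 adjust_marginal = adjust_marginal,
                                 alpha_cell = alpha_cell,
                                 min_cell = min_cell)),
            class = "risk_categorization")
}

#' @export
print.risk_categorization <- function(x, ...) {
  cat(sprintf("<risk_categorization> %s x %s (%s)\n", x$pair[1], x$pair[2],
              x$provenance))
  print(x$labels)
  invisible(x)
}

# H/L sample-membership indicators implied by a categorization
membership_from_labels <- function(labels, cell) {
  lab_vec <- as.vector(t(labels))      # row-major, cell = 3*g1+g2
  lab_cell <- lab_vec[cell + 1L]
  list(h = as.numeric(lab_cell == "H"), l = as.numeric(lab_cell == "L"),
       has_h = any(lab_cell == "H") && !all(lab_cell == "H"),
       has_l = any(lab_cell == "L") && !all(lab_cell == "L"))
}

#' MB-MDR association statistic for a categorized pair
#'
#' `W_H` is the squared Wald statistic of the H-membership indicator (H
#' cells versus all others) in a covariate-adjusted logistic fit; `W_L`
#' analogously for L. The pair's statistic is `W = max(W_H, W_L)`, with an
#' absent or degenerate category contributing `-Inf`; when every cell is
#' neutral the statistic is `NA` (reported as "not available" downstream).
#'
#' @param dataset an [snp_dataset] (the data to evaluate on; may differ from
#'   the data that produced `categorization`, as in the replication stage).
#' @param categorization a `risk_categorization`.
#' @param covariates covariates for the Wald fits (default: the ones stored
#'   in the categorization).
#' @return `W` (nonnegative) or `NA`; attributes `W_H`, `W_L`, `n_used`.
#' @export
mbmdr_statistic <- function(dataset, categorization, covariates = NULL) {
  st <- categorization$settings
  covariates <- covariates %||% st$covariates
  inp <- mbmdr_inputs(dataset, categorization$pair, covariates,
                      st$adjust_marginal)
  mem <- membership_from_labels(categorization$labels, inp$cell)
  if (!mem$has_h && !mem$has_l)
    return(structure(NA_real_, W_H = -Inf, W_L = -Inf, n_used = inp$n))
  y1 <- matrix(inp$y, ncol = 1)
  wh <- if (mem$has_h) .cpp_fixed_w(inp$X, mem$h, mem$l, y1, TRUE, FALSE)[1] else -Inf
  wl <- if (mem$has_l) .cpp_fixed_w(inp$X, mem$h, mem$l, y1, FALSE, TRUE)[1] else -Inf
  if (is.na(wh)) wh <- -Inf
  if (is.na(wl)) wl <- -Inf
  W <- max(wh, wl)
  structure(if (is.finite(W)) W else NA_real_, W_H = wh, W_L = wl,
            n_used = inp$n)
}

# interaction_result constructor shared by the detectors and the pipeline
interaction_result <- function(pair, W, perm_p, n_perm, categorization,
                               stage, detectors = character(),
                               replicated = NA) {
  structure(list(pair = pair, statistic_W = W, perm_p = perm_p,
                 n_permutations = n_perm, categorization = categorization,
                 stage = stage, detectors_flagging = detectors,
                 replicated = replicated),
            class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf("<interaction_result %s> %s x %s: W = %s, perm p = %s (B = %d)\n",
              x$stage, x$pair[1], x$pair[2],
              ifelse(is.na(x$statistic_W), "NA", sprintf("%.3f", x$statistic_W)),
              ifelse(is.na(x$perm_p), "NA", format(x$perm_p, digits = 3)),
              x$n_permutations))
  invisible(x)
}

# generate a B x n matrix of permuted phenotypes (columns... rows) for the
# given y; each row of the returned matrix is one permutation
perm_matrix <- function(y, B) {
  n <- length(y)
  t(vapply(seq_len(B), function(b) y[sample.int(n)], numeric(n)))
}

#' Permutation p-value of the MB-MDR statistic for one pair
#'
#' The observed `W` comes from a fresh categorization + statistic. For each
#' permutation, case/control labels are shuffled (covariates stay attached
#' to their samples), and the categorization and statistic are recomputed
#' from scratch; `perm_p = (1 + #\{W_perm >= W_obs\}) / (B + 1)`. With
#' `exact = TRUE` (small samples) all distinct case/control assignments are
#' enumerated instead and `perm_p = #\{W >= W_obs\} / #assignments` (the
#' observed assignment is one of them). An all-neutral observed
#' categorization yields `perm_p = NA`.
#'
#' @inheritParams mbmdr_categorize
#' @param B number of permutations (ignored when `exact`).
#' @param seed integer seed.
#' @param exact enumerate all distinct phenotype assignments.
#' @return an `interaction_result` (stage `"discovery"`).
#' @export
mbmdr_permutation_p <- function(dataset, pair, covariates = NULL, B = 999,
                                seed = NULL, adjust_marginal = TRUE,
                                alpha_cell = 0.1, min_cell = 10,
                                exact = FALSE) {
  if (!exact && B < 1) stop("B must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  cat_obs <- mbmdr_categorize(dataset, pair, covariates, adjust_marginal,
                              alpha_cell, min_cell)
  W_obs <- mbmdr_statistic(dataset, cat_obs, covariates)
  inp <- mbmdr_inputs(dataset, pair, covariates, adjust_marginal)

  if (is.na(W_obs))
    return(interaction_result(pair, NA_real_, NA_real_,
                              if (exact) 0L else as.integer(B),
                              cat_obs, "discovery"))
  if (exact) {
    n1 <- sum(inp$y == 1)
    combos <- combn(inp$n, n1)
    Y <- matrix(0, inp$n, ncol(combos))
    for (k in seq_len(ncol(combos))) Y[combos[, k], k] <- 1
    Wp <- .cpp_mbmdr_perm(inp$X, inp$cell, Y, alpha_cell, as.integer(min_cell))
    Wp[is.na(Wp)] <- -Inf
    p <- sum(Wp >= as.numeric(W_obs) - 1e-12) / ncol(combos)
    return(interaction_result(pair, as.numeric(W_obs), p,
                              as.integer(ncol(combos)), cat_obs, "discovery"))
  }
  Y <- t(perm_matrix(inp$y, B))
  Wp <- .cpp_mbmdr_perm(inp$X, inp$cell, Y, alpha_cell, as.integer(min_cell))
  Wp[is.na(Wp)] <- -Inf
  p <- (1 + sum(Wp >= as.numeric(W_obs) - 1e-12)) / (B + 1)
  interaction_result(pair, as.numeric(W_obs), p, as.integer(B), cat_obs,
                     "discovery")
}

#' Two-tier MB-MDR scan over SNP pairs
#'
#' Computes the observed statistic `W` for every pair, then spends the
#' permutation budget only on pairs whose `W` reaches the
#' `screen_quantile` of the observed `W` distribution (two-tier design that
#' keeps exhaustive candidate-panel scans tractable). Ranked by permutation
#' p, then `W`; pairs outside the screen follow, ranked by `W`; all-neutral
#' pairs (`W = NA`) come last. Deterministic given `seed`.
#'
#' @inheritParams mbmdr_permutation_p
#' @param pairs optional 2-column matrix of snp_ids (default all pairs).
#' @param B_screen permutations per screened pair (default 999).
#' @param screen_quantile quantile of finite `W` values above which pairs
#'   are permuted (default 0.98); set 0 to permute every pair.
#' @return data.frame of class `mbmdr_scan` with snp1, snp2, `W`, `perm_p`,
#'   `n_perm`, `labels` (9-character H/L/O string, row-major by minor-allele
#'   counts), `n_used`; scan settings in attributes.
#' @export
mbmdr_scan <- function(dataset, pairs = NULL, covariates = NULL,
                       B_screen = 999, seed = NULL, adjust_marginal = TRUE,
                       alpha_cell = 0.1, min_cell = 10,
                       screen_quantile = 0.98) {
  if (!is.null(seed)) set.seed(seed)
  ids <- dataset$snps$snp_id
  if (is.null(pairs)) {
    cmb <- combn(length(ids), 2)
    pairs <- cbind(ids[cmb[1, ]], ids[cmb[2, ]])
  } else {
    pairs <- as.matrix(pairs)
  }
  P <- nrow(pairs)
  W <- numeric(P); labels <- character(P); n_used <- integer(P)
  cats <- vector("list", P)
  for (k in seq_len(P)) {
    ct <- mbmdr_categorize(dataset, pairs[k, ], covariates, adjust_marginal,
                           alpha_cell, min_cell)
    w <- mbmdr_statistic(dataset, ct, covariates)
    W[k] <- as.numeric(w)
    n_used[k] <- attr(w, "n_used")
    labels[k] <- paste(as.vector(t(ct$labels)), collapse = "")
    cats[[k]] <- ct
  }
  perm_p <- rep(NA_real_, P); n_perm <- integer(P)
  finite <- which(!is.na(W))
  if (length(finite)) {
    thr <- quantile(W[finite], screen_quantile, type = 7)
    screened <- finite[W[finite] >= thr]
    for (k in screened) {
      inp <- mbmdr_inputs(dataset, pairs[k, ], covariates, adjust_marginal)
      Y <- t(perm_matrix(inp$y, B_screen))
      Wp <- .cpp_mbmdr_perm(inp$X, inp$cell, Y, alpha_cell,
                            as.integer(min_cell))
      Wp[is.na(Wp)] <- -Inf
      perm_p[k] <- (1 + sum(Wp >= W[k] - 1e-12)) / (B_screen + 1)
      n_perm[k] <- B_screen
    }
  }
  out <- data.frame(snp1 = pairs[, 1], snp2 = pairs[, 2], W = W,
                    perm_p = perm_p, n_perm = n_perm, labels = labels,
                    n_used = n_used, stringsAsFactors = FALSE)
  out <- out[order(ifelse(is.na(out$perm_p), 2, 1),    # permuted first
                   out$perm_p, -ifelse(is.na(out$W), -Inf, out$W)), ]
  rownames(out) <- NULL
  attr(out, "settings") <- list(covariates = covariates,
                                adjust_marginal = adjust_marginal,
                                alpha_cell = alpha_cell, min_cell = min_cell,
                                B_screen = B_screen,
                                screen_quantile = screen_quantile)
  class(out) <- c("mbmdr_scan", "data.frame")
  out
}

#' Flag MB-MDR-detected pairs for the consensus rule
#'
#' Pairs with a screening-stage permutation p below `alpha` (default 0.05).
#'
#' @param scan an `mbmdr_scan` result.
#' @param alpha flagging threshold on the permutation p.
#' @return character vector of flagged pair keys (`"snp1|snp2"`).
#' @export
mbmdr_flag <- function(scan, alpha = 0.05) {
  sel <- !is.na(scan$perm_p) & scan$perm_p < alpha
  as.character(mapply(pair_key, scan$snp1[sel], scan$snp2[sel],
                      USE.NAMES = FALSE))
}
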