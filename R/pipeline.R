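#' Consensus selection of interaction candidates across detectors
#'
#' A SNP pair is selected for replication only when flagged by at least
#' `k_required` of the interaction-detection methods. Order-independent and
#' idempotent.
#'
#' @param detector_outputs named list: detector name -> character vector of
#'   flagged pair keys (`"snp1|snp2"`, sorted snp_ids joined by `|`).
#' @param k_required minimum number of flagging detectors (default 3, the
#'   usual rule with a five-detector battery; use 2 when only the two
#'   built-in detectors run).
#' @return data.frame with `pair`, `detectors_flagging`, `n_flagging`,
#'   `selected`.
#' @export
consensus_select <- function(detector_outputs, k_required = 3) {
  stopifnot(length(detector_outputs) >= 1, k_required >= 1)
  if (k_required > length(detector_outputs))
    stop("k_required (", k_required, ") exceeds number of detectors (",
         length(detector_outputs), ")")
  all_pairs <- sort(unique(unlist(detector_outputs, use.names = FALSE)))
  if (!length(all_pairs))
    return(data.frame(pair = character(), detectors_flagging = character(),
                      n_flagging = integer(), selected = logical(),
                      stringsAsFactors = FALSE))
  flags <- vapply(all_pairs, function(p)
    sum(vapply(detector_outputs, function(d) p %in% d, TRUE)), 0L)
  dets <- vapply(all_pairs, function(p)
    paste(sort(names(detector_outputs)[vapply(detector_outputs,
                                              function(d) p %in% d, TRUE)]),
          collapse = ","), "")
  out <- data.frame(pair = all_pairs, detectors_flagging = dets,
                    n_flagging = as.integer(flags),
                    selected = flags >= k_required,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$n_flagging, out$pair), , drop = FALSE]
}

#' Replicate an interaction by category forcing
#'
#' The replication-stage test: the discovery-stage H/L/O grid is applied
#' unchanged to the independent series (no re-categorization), the MB-MDR
#' statistic `W` is computed for the forced memberships with the requested
#' covariates, and a permutation p-value is obtained by shuffling phenotype
#' labels while keeping the forced grid fixed. The interaction is
#' `replicated` when the permutation p is below `alpha` (0.05 by
#' convention; stage 2 is a single pre-specified test per pair).
#'
#' @param replication_data an [snp_dataset] for the independent series
#'   (already stratified to the discovery case group); must carry the SNP
#'   pair with the same allele coding as discovery.
#' @param fixed_cat the discovery-stage `risk_categorization`.
#' @param covariates covariates for the replication fits (e.g.
#'   `c("age", "sex", "country")`); defaults to the discovery settings.
#' @param B permutations (default 999).
#' @param seed integer seed.
#' @param alpha replication threshold on the permutation p.
#' @return an `interaction_result` with stage `"replication"`, a
#'   `replicated` flag, and the forced categorization (provenance
#'   `"fixed"`).
#' @export
replicate_interaction <- function(replication_data, fixed_cat,
                                  covariates = NULL, B = 999, seed = NULL,
                                  alpha = 0.05) {
  stopifnot(inherits(fixed_cat, "risk_categorization"), B >= 1)
  j <- snp_index(replication_data, fixed_cat$pair)
  al <- replication_data$snps[j, c("snp_id", "allele_major", "allele_minor")]
  if (!identical(unname(as.matrix(al)), unname(as.matrix(fixed_cat$alleles))))
    stop("allele coding mismatch between discovery and replication for pair ",
         pair_key(fixed_cat$pair[1], fixed_cat$pair[2]))
  if (!is.null(seed)) set.seed(seed)
  st <- fixed_cat$settings
  covariates <- covariates %||% st$covariates
  forced <- fixed_cat
  forced$provenance <- "fixed"
  forced$settings$covariates <- covariates

  W_obs <- mbmdr_statistic(replication_data, forced, covariates)
  if (is.na(W_obs))
    return(interaction_result(fixed_cat$pair, NA_real_, NA_real_,
                              as.integer(B), forced, "replication",
                              replicated = NA))
  inp <- mbmdr_inputs(replication_data, fixed_cat$pair, covariates,
                      st$adjust_marginal)
  mem <- membership_from_labels(forced$labels, inp$cell)
  Y <- t(perm_matrix(inp$y, B))
  Wp <- .cpp_fixed_w(inp$X, mem$h, mem$l, Y, mem$has_h, mem$has_l)
  Wp[is.na(Wp)] <- -Inf
  p <- (1 + sum(Wp >= as.numeric(W_obs) - 1e-12)) / (B + 1)
  interaction_result(fixed_cat$pair, as.numeric(W_obs), p, as.integer(B),
                     forced, "replication", replicated = p < alpha)
}

#' Combined-stage analysis of a replicated interaction
#'
#' Pools the stage datasets (adding a `stage` indicator to the covariates),
#' re-categorizes the pair on the pooled data and computes a permutation p
#' at a large budget, as done for replicated pairs once both series are
#' available.
#'
#' @param datasets list of two or more [snp_dataset]s on the same panel,
#'   already stratified to the case group.
#' @param pair character vector of two snp_ids.
#' @param covariates covariates in addition to the automatic stage
#'   indicator.
#' @param B_large permutation budget (e.g. `1e5` for confirmatory values;
#'   default 9999).
#' @param seed integer seed.
#' @inheritParams mbmdr_categorize
#' @return an `interaction_result` with stage `"combined"`.
#' @export
combined_analysis <- function(datasets, pair, covariates = NULL,
                              B_large = 9999, seed = NULL,
                              adjust_marginal = TRUE, alpha_cell = 0.1,
                              min_cell = 10) {
  stopifnot(length(datasets) >= 2)
  pooled <- datasets[[1]]
  lab <- c("I", "II", "III", "IV")
  for (k in 2:length(datasets))
    pooled <- combine_datasets(pooled, datasets[[k]],
                               stage_labels = c(if (k == 2) lab[1] else "pool",
                                                lab[k]))
  covs <- unique(c(covariates, "stage"))
  res <- mbmdr_permutation_p(pooled, pair, covs, B = B_large, seed = seed,
                             adjust_marginal = adjust_marginal,
                             alpha_cell = alpha_cell, min_cell = min_cell)
  res$stage <- "combined"
  res
}

#' Run the full two-stage interaction study
#'
#' Orchestrates the study design end to end for each case group: discovery
#' scans with the built-in detectors (MDR, covariate-naive; MB-MDR,
#' covariate- and marginal-adjusted) plus any plug-in detectors, consensus
#' selection (>= `k_required` detectors), category-forced replication of
#' each selected pair on the independent series, and a combined pooled
#' analysis for pairs that replicate. Deterministic given `seed`.
#'
#' @param discovery,replication [snp_dataset]s sharing the SNP panel and
#'   allele coding.
#' @param case_groups named list of case-subtype vectors analyzed in turn,
#'   e.g. `list(PTC = c("cPTC","fvPTC","otherPTC"), cPTC = "cPTC")`.
#' @param covariates covariates for MB-MDR fits (MDR is covariate-naive).
#' @param k_required consensus threshold; must not exceed the number of
#'   detectors (2 built-ins + plug-ins). Checked before any computation.
#' @param extra_detectors named list of plug-in detectors: functions
#'   `f(dataset)` returning flagged pair keys (`"snp1|snp2"`); stands in
#'   for external tools with their own selection logic.
#' @param B_screen,B_replication,B_combined permutation budgets for the
#'   discovery screen, the replication tests and the combined analysis.
#' @param mdr_n_perm permutations for the MDR flagging null.
#' @param screen_quantile MB-MDR screening quantile (see [mbmdr_scan]).
#' @param alpha_replication replication threshold (default 0.05).
#' @param seed master seed; stage seeds are derived deterministically.
#' @return list of class `two_stage_report`, one entry per case group, each
#'   holding the scans, consensus table, replication and combined results.
#' @export
run_two_stage <- function(discovery, replication,
                          case_groups = list(PTC = .PTC_SUBTYPES,
                                             cPTC = "cPTC"),
                          covariates = NULL, k_required = 2,
                          extra_detectors = NULL, B_screen = 999,
                          B_replication = 999, B_combined = 9999,
                          mdr_n_perm = 100, screen_quantile = 0.98,
                          alpha_replication = 0.05, seed = 1L) {
  n_detectors <- 2L + length(extra_detectors)
  if (k_required > n_detectors)
    stop("k_required (", k_required, ") exceeds number of detectors (",
         n_detectors, ")")
  if (!identical(discovery$snps$snp_id, replication$snps$snp_id))
    stop("discovery and replication SNP panels differ")

  reports <- list()
  for (gname in names(case_groups)) {
    grp <- case_groups[[gname]]
    disc <- stratify(discovery, grp)
    repl <- stratify(replication, grp)

    s_mdr <- seed; s_mdrflag <- seed + 1000L
    s_mbmdr <- seed + 2000L; s_repl <- seed + 3000L; s_comb <- seed + 4000L

    scan_mdr <- mdr_scan(disc, seed = s_mdr)
    flag_mdr <- mdr_flag(disc, scan_mdr, n_perm = mdr_n_perm,
                         seed = s_mdrflag)
    scan_mb <- mbmdr_scan(disc, covariates = covariates, B_screen = B_screen,
                          seed = s_mbmdr, screen_quantile = screen_quantile)
    flag_mb <- mbmdr_flag(scan_mb)
    flags <- list(MDR = as.character(flag_mdr), MBMDR = flag_mb)
    if (length(extra_detectors))
      for (dn in names(extra_detectors))
        flags[[dn]] <- as.character(extra_detectors[[dn]](disc))

    consensus <- consensus_select(flags, k_required)
    selected <- consensus$pair[consensus$selected]

    repl_results <- list(); comb_results <- list()
    for (pk in selected) {
      pr <- strsplit(pk, "|", fixed = TRUE)[[1]]
      ct <- mbmdr_categorize(disc, pr, covariates,
                             adjust_marginal = attr(scan_mb, "settings")$adjust_marginal,
                             alpha_cell = attr(scan_mb, "settings")$alpha_cell,
                             min_cell = attr(scan_mb, "settings")$min_cell)
      rr <- replicate_interaction(repl, ct, covariates, B = B_replication,
                                  seed = s_repl, alpha = alpha_replication)
      repl_results[[pk]] <- rr
      if (isTRUE(rr$replicated))
        comb_results[[pk]] <- combined_analysis(list(disc, repl), pr,
                                                covariates, B_combined,
                                                seed = s_comb)
    }
    reports[[gname]] <- list(case_group = grp,
                             mdr_scan = scan_mdr, mdr_flagged = flag_mdr,
                             mbmdr_scan = scan_mb, mbmdr_flagged = flag_mb,
                             consensus = consensus,
                             replication = repl_results,
                             combined = comb_results,
                             seed = seed)
  }
  class(reports) <- "two_stage_report"
  reports
}

#' @export
print.two_stage_report <- function(x, ...) {
  for (gname in names(x)) {
    r <- x[[gname]]
    cat(sprintf("== case group %s (%s) ==\n", gname,
                paste(r$case_group, collapse = "+")))
    cat(sprintf("  detectors flagged: MDR %d, MB-MDR %d pairs\n",
                length(r$mdr_flagged), length(r$mbmdr_flagged)))
    nsel <- sum(r$consensus$selected)
    cat(sprintf("  consensus-selected pairs: %d\n", nsel))
    for (pk in names(r$replication)) {
      rr <- r$replication[[pk]]
      cat(sprintf("  %s: replication perm p = %s -> %s\n", pk,
                  format(rr$perm_p, digits = 3),
                  if (isTRUE(rr$replicated)) "REPLICATED" else "not replicated"))
      if (pk %in% names(r$combined))
        cat(sprintf("    combined perm p = %s (B = %d)\n",
                    format(r$combined[[pk]]$perm_p, digits = 3),
                    r$combined[[pk]]$n_permutations))
    }
  }
  invisible(x)
}

#' Summarize an interaction scan as a report table
#'
#' Collects the top of an MB-MDR scan with gene annotations and the
#' per-detector flags, in the layout of a two-locus interaction report
#' (MB-MDR p column uses `NA` when every cell was neutral).
#'
#' @param scan an `mbmdr_scan`.
#' @param dataset the scanned [snp_dataset] (for gene annotations).
#' @param flags named list of detector flag vectors (pair keys).
#' @param top number of rows to keep.
#' @return data.frame.
#' @export
interaction_report <- function(scan, dataset, flags = list(), top = 20) {
  n <- min(top, nrow(scan))
  out <- scan[seq_len(n), , drop = FALSE]
  gene_of <- function(s) dataset$snps$gene[match(s, dataset$snps$snp_id)]
  out$gene1 <- gene_of(out$snp1); out$gene2 <- gene_of(out$snp2)
  keys <- mapply(pair_key, out$snp1, out$snp2, USE.NAMES = FALSE)
  for (dn in names(flags))
    out[[paste0("flag_", dn)]] <- keys %in% flags[[dn]]
  out
}
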