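#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test on the heterozygote count given the allele counts
#' (Fisher-style, as applied to control genotypes in candidate-gene panels):
#' the p-value is the summed probability of every heterozygote configuration
#' no more probable than the one observed. Computed by the standard
#' probability recurrence over heterozygote counts.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (major homozygote, heterozygote,
#'   minor homozygote).
#' @return p-value in `(0, 1]`.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (n_AA < 0 || n_Aa < 0 || n_aa < 0) stop("negative genotype count")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("empty genotype table")
  nr <- 2 * min(n_AA, n_aa) + n_Aa    # rare allele count
  if (nr == 0) return(1.0)            # monomorphic: single configuration
  # heterozygote support: parity of nr, max = min(nr, 2n - nr)
  hmax <- min(nr, 2L * n - nr)
  hmin <- nr %% 2L
  hs <- seq.int(hmin, hmax, by = 2L)
  # unnormalized recurrence: P(h+2)/P(h) = 4*nAA(h)*naa(h) / ((h+2)*(h+1))
  logp <- numeric(length(hs))
  for (k in seq_along(hs)[-1]) {
    h <- hs[k - 1]
    nAA <- (2L * n - nr - h) / 2L
    naa <- (nr - h) / 2L
    logp[k] <- logp[k - 1] + log(4 * nAA * naa) - log((h + 2) * (h + 1))
  }
  logp <- logp - max(logp)
  p <- exp(logp); p <- p / sum(p)
  obs <- which(hs == n_Aa)
  # relative slack so exact probability ties land on the same side
  min(1, sum(p[p <= p[obs] * (1 + 1e-7)]))
}

# genotype coding for the logistic models
code_genotype <- function(g, model) {
  switch(model,
         dominant = as.numeric(g >= 1),
         recessive = as.numeric(g == 2),
         logadditive = as.numeric(g),
         codominant = NULL,
         stop("unknown genetic model: ", model))
}

# assemble the complete-case analysis frame for one SNP
assoc_frame <- function(dataset, snp_id, covariates, case_group) {
  d <- if (is.null(case_group)) dataset else stratify(dataset, case_group)
  j <- snp_index(d, snp_id)
  df <- data.frame(y = d$samples$phenotype, g = d$genotypes[, j])
  for (cv in covariates) {
    if (!cv %in% names(d$samples)) stop("unknown covariate: ", cv)
    v <- d$samples[[cv]]
    if (is.character(v)) v <- factor(v)
    df[[cv]] <- v
  }
  df <- df[complete.cases(df), , drop = FALSE]
  # drop single-level factor covariates (e.g. one country)
  for (cv in covariates)
    if (is.factor(df[[cv]]) && nlevels(droplevels(df[[cv]])) < 2)
      df[[cv]] <- NULL
  df
}

#' Fit one genetic model for one SNP
#'
#' Unconditional logistic regression of case status on a genotype coding
#' plus covariates; the reference group is the homozygote of the most
#' frequent control allele (genotype 0). OR = exp(coefficient), 95% CI from
#' coefficient +/- 1.96 SE, p from the Wald statistic. Samples missing the
#' genotype or any covariate are dropped for this SNP only.
#'
#' @param dataset an [snp_dataset].
#' @param snp_id SNP to test.
#' @param model `"dominant"`, `"recessive"`, `"logadditive"` or
#'   `"codominant"` (two indicators; the reported OR is the homozygote one,
#'   the heterozygote OR is returned in `or_het`).
#' @param covariates character vector of sample-table columns (e.g.
#'   `c("age", "sex")`).
#' @param case_group optional case-subtype restriction (see [stratify]).
#' @return list of class `assoc_result` with `snp_id`, `model`, `or_point`,
#'   `ci95`, `wald_p`, `covariates_used`, `n_used`, `aic`, `p_type`.
#' @export
fit_genetic_model <- function(dataset, snp_id, model = "logadditive",
                              covariates = NULL, case_group = NULL) {
  df <- assoc_frame(dataset, snp_id, covariates, case_group)
  if (length(unique(df$g)) < 2) stop("SNP ", snp_id, " monomorphic in analysis subset")
  if (model == "codominant") {
    df$g1 <- as.numeric(df$g == 1); df$g2 <- as.numeric(df$g == 2)
    rhs <- c("g1", "g2", setdiff(names(df), c("y", "g", "g1", "g2")))
  } else {
    df$x <- code_genotype(df$g, model)
    if (length(unique(df$x)) < 2)
      stop("SNP ", snp_id, " monomorphic under ", model, " coding")
    rhs <- c("x", setdiff(names(df), c("y", "g", "x")))
  }
  fml <- stats::as.formula(paste("y ~", paste(rhs, collapse = " + ")))
  fit <- glm(fml, family = binomial(), data = df,
             control = stats::glm.control(epsilon = 1e-12, maxit = 50))
  if (!fit$converged) stop("logistic fit did not converge for ", snp_id)
  co <- summary(fit)$coefficients
  term <- if (model == "codominant") "g2" else "x"
  b <- co[term, 1]; se <- co[term, 2]
  if (abs(b) > 15 || se > 50)
    stop("separation detected for ", snp_id, " under ", model, " coding")
  res <- list(snp_id = snp_id, model = model,
              or_point = exp(b),
              ci95 = exp(b + c(-1.96, 1.96) * se),
              wald_p = co[term, 4],
              covariates_used = intersect(covariates, names(df)),
              n_used = nrow(df), aic = AIC(fit), p_type = "single-model")
  if (model == "codominant")
    res$or_het <- exp(co["g1", 1])
  class(res) <- "assoc_result"
  res
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("%s [%s] OR = %.3f (95%% CI %.3f-%.3f), Wald p = %.3g (%s, n = %d)\n",
              x$snp_id, x$model, x$or_point, x$ci95[1], x$ci95[2], x$wald_p,
              x$p_type, x$n_used))
  invisible(x)
}

#' Select the best-fitting genetic model for a SNP
#'
#' Fits the dominant, recessive and log-additive codings and returns the fit
#' with the smallest AIC (ties broken in that fixed order; the codominant
#' model is excluded from selection but available via [fit_genetic_model]).
#' The returned p-value is post-selection and labeled `"model-selected"`:
#' under the null it is anti-conservative and must not be read as calibrated.
#'
#' @inheritParams fit_genetic_model
#' @return an `assoc_result` (see [fit_genetic_model]).
#' @export
select_best_model <- function(dataset, snp_id, covariates = NULL,
                              case_group = NULL) {
  fits <- lapply(c("dominant", "recessive", "logadditive"), function(mod)
    fit_genetic_model(dataset, snp_id, mod, covariates, case_group))
  aics <- vapply(fits, `[[`, 0, "aic")
  best <- fits[[which.min(aics)]]   # which.min keeps the first on ties
  best$p_type <- "model-selected"
  best
}

#' Per-SNP association scan with model selection
#'
#' Applies [select_best_model] to every polymorphic SNP in a case group and
#' collects a table shaped like the usual candidate-panel report (best
#' model, OR, CI, Wald p, control/case MAF).
#'
#' @inheritParams fit_genetic_model
#' @param hwe_controls add a column with the exact HWE p in controls.
#' @return data.frame, one row per testable SNP.
#' @export
single_snp_scan <- function(dataset, covariates = NULL, case_group = NULL,
                            hwe_controls = TRUE) {
  d <- if (is.null(case_group)) dataset else stratify(dataset, case_group)
  rows <- lapply(dataset$snps$snp_id, function(s) {
    res <- tryCatch(select_best_model(dataset, s, covariates, case_group),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    hwe <- NA_real_
    if (hwe_controls) {
      g <- d$genotypes[d$samples$phenotype == 0L, snp_index(d, s)]
      g <- g[!is.na(g)]
      hwe <- hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
    }
    data.frame(snp_id = s, gene = dataset$snps$gene[snp_index(dataset, s)],
               model = res$model,
               maf_controls = minor_allele_freq(d, s, "controls"),
               maf_cases = minor_allele_freq(d, s, "cases"),
               or = res$or_point, ci_lo = res$ci95[1], ci_hi = res$ci95[2],
               wald_p = res$wald_p, p_type = res$p_type,
               hwe_p_controls = hwe, n_used = res$n_used,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- multinomial logistic machinery for the subtype-heterogeneity test ----

# negative log-likelihood and gradient of a baseline-category multinomial
# logit with per-category covariate coefficients and either per-category or
# shared genotype slope. theta layout: k blocks of (intercept+covariates),
# then genotype slopes (k or 1).
mlogit_nll <- function(theta, Z, gx, ycat, k, shared) {
  p <- ncol(Z)
  G <- matrix(theta[seq_len(k * p)], p, k)
  bg <- if (shared) rep(theta[k * p + 1], k) else theta[k * p + seq_len(k)]
  eta <- Z %*% G + outer(gx, bg)           # n x k
  M <- pmax(apply(eta, 1, max), 0)
  lse <- M + log(exp(-M) + rowSums(exp(eta - M)))
  ll <- -sum(lse)
  case <- ycat > 0L
  ll <- ll + sum(eta[cbind(which(case), ycat[case])])
  -ll
}

mlogit_grad <- function(theta, Z, gx, ycat, k, shared) {
  p <- ncol(Z)
  G <- matrix(theta[seq_len(k * p)], p, k)
  bg <- if (shared) rep(theta[k * p + 1], k) else theta[k * p + seq_len(k)]
  eta <- Z %*% G + outer(gx, bg)
  M <- pmax(apply(eta, 1, max), 0)
  den <- exp(-M) + rowSums(exp(eta - M))
  P <- exp(eta - M) / den                  # n x k category probabilities
  Y <- matrix(0, nrow(Z), k)
  case <- ycat > 0L
  Y[cbind(which(case), ycat[case])] <- 1
  R <- Y - P
  gG <- -crossprod(Z, R)                   # p x k
  gb <- -crossprod(R, gx)                  # k x 1
  if (shared) c(as.vector(gG), sum(gb)) else c(as.vector(gG), as.vector(gb))
}

fit_mlogit <- function(Z, gx, ycat, k, shared, start = NULL) {
  p <- ncol(Z)
  npar <- k * p + if (shared) 1L else k
  if (is.null(start)) start <- rep(0, npar)
  fit <- optim(start, mlogit_nll, mlogit_grad, Z = Z, gx = gx, ycat = ycat,
               k = k, shared = shared, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  if (fit$convergence != 0) warning("multinomial fit convergence code ",
                                    fit$convergence)
  fit
}

#' Likelihood-ratio test of per-allele OR heterogeneity across case subtypes
#'
#' Polytomous (baseline-category) logistic model over control plus the
#' requested case subtypes, with per-allele (minor-allele count) genotype
#' coding and covariate adjustment. The LR statistic contrasts
#' subtype-specific genotype coefficients against one shared coefficient and
#' is referred to chi-square with (k - 1) df for k subtypes.
#'
#' @param dataset an [snp_dataset].
#' @param snp_id SNP to test.
#' @param covariates covariate columns, as in [fit_genetic_model].
#' @param subtypes character vector (>= 2) of case subtypes to contrast;
#'   each must have at least one case.
#' @return list with `p`, `lr_stat`, `df`, `coef_by_subtype`.
#' @export
heterogeneity_lr_test <- function(dataset, snp_id, covariates = NULL,
                                  subtypes = c("cPTC", "fvPTC")) {
  subtypes <- unique(subtypes)
  if (length(subtypes) < 2) stop("need at least two case subtypes")
  cnt <- table(factor(dataset$samples$subtype, levels = subtypes))
  if (any(cnt == 0))
    stop("subtype with zero cases: ",
         paste(names(cnt)[cnt == 0], collapse = ", "))
  keep <- dataset$samples$phenotype == 0L | dataset$samples$subtype %in% subtypes
  d <- snp_dataset(dataset$genotypes[keep, , drop = FALSE],
                   dataset$samples[keep, , drop = FALSE], dataset$snps)
  j <- snp_index(d, snp_id)
  df <- data.frame(y = d$samples$phenotype, g = d$genotypes[, j],
                   subtype = d$samples$subtype)
  for (cv in covariates %||% character()) {
    v <- d$samples[[cv]]
    if (is.null(v)) stop("unknown covariate: ", cv)
    if (is.character(v)) v <- factor(v)
    df[[cv]] <- v
  }
  df <- df[complete.cases(df), , drop = FALSE]
  for (cv in covariates %||% character())
    if (is.factor(df[[cv]]) && nlevels(droplevels(df[[cv]])) < 2)
      df[[cv]] <- NULL
  k <- length(subtypes)
  ycat <- ifelse(df$y == 0L, 0L, match(df$subtype, subtypes))
  ycat <- as.integer(ycat)
  covs <- setdiff(names(df), c("y", "g", "subtype"))
  Z <- if (length(covs))
    model.matrix(stats::as.formula(paste("~", paste(covs, collapse = "+"))), df)
  else matrix(1, nrow(df), 1)
  g <- as.numeric(df$g)

  f0 <- fit_mlogit(Z, g, ycat, k, shared = TRUE)
  # start the free fit from the shared solution to guarantee nesting
  p <- ncol(Z)
  start1 <- c(f0$par[seq_len(k * p)], rep(f0$par[k * p + 1], k))
  f1 <- fit_mlogit(Z, g, ycat, k, shared = FALSE, start = start1)
  lr <- max(0, 2 * (f0$value - f1$value))
  list(p = pchisq(lr, df = k - 1, lower.tail = FALSE),
       lr_stat = lr, df = k - 1,
       coef_by_subtype = setNames(f1$par[k * p + seq_len(k)], subtypes),
       shared_coef = f0$par[k * p + 1])
}
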