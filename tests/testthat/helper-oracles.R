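# Independent oracles and fixture builders shared across the suite.

# --- HWE enumeration oracle -------------------------------------------------
# Exact conditional distribution of the heterozygote count given allele
# totals, via log-factorial closed form (independent of the package's
# recurrence): P(nAB | n, nA) = n! / (nAA! nAB! nBB!) * 2^nAB / C(2n, nA).
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nr <- 2 * min(n_AA, n_aa) + n_Aa
  if (nr == 0) return(1.0)
  hmax <- min(nr, 2 * n - nr)
  hs <- seq(nr %% 2, hmax, by = 2)
  logp <- vapply(hs, function(h) {
    nAA <- (2 * n - nr - h) / 2
    naa <- (nr - h) / 2
    lfactorial(n) - lfactorial(nAA) - lfactorial(h) - lfactorial(naa) +
      h * log(2) - (lchoose(2 * n, nr))
  }, 0)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- which(hs == n_Aa)
  min(1, sum(p[p <= p[obs] * (1 + 1e-7)]))
}

# --- logistic oracles -------------------------------------------------------
# closed-form Wald pieces of a 2x2 logistic fit (exposure indicator only)
wald_2x2 <- function(a, b, c, d) {
  # a = exposed cases, b = exposed controls, c = unexposed cases, d = unexp ctl
  beta <- log((a * d) / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = exp(beta), beta = beta, se = se, z = beta / se,
       p = 2 * pnorm(-abs(beta / se)))
}

# hand-rolled IRLS, independent of both stats::glm and the compiled path
irls_oracle <- function(X, y, maxit = 60, tol = 1e-12) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    XtWX <- crossprod(X, X * w)
    bnew <- solve(XtWX, crossprod(X, w * z))
    if (max(abs(bnew - beta)) < tol) { beta <- bnew; break }
    beta <- bnew
  }
  eta <- drop(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  XtWX <- crossprod(X, X * pmax(mu * (1 - mu), 1e-12))
  list(beta = drop(beta), se = sqrt(diag(solve(XtWX))))
}

# --- fixture builders -------------------------------------------------------
make_samples <- function(phenotype, subtype = NULL, age = 50, sex = "female",
                         country = "ES") {
  n <- length(phenotype)
  if (is.null(subtype)) subtype <- ifelse(phenotype == 1, "cPTC", "control")
  data.frame(sample_id = sprintf("S%04d", seq_len(n)),
             phenotype = phenotype, subtype = subtype,
             age = rep_len(age, n), sex = rep_len(sex, n),
             country = rep_len(country, n), stringsAsFactors = FALSE)
}

make_snps <- function(ids) {
  data.frame(snp_id = ids, gene = paste0("G", seq_along(ids)),
             allele_major = "A", allele_minor = "G", stringsAsFactors = FALSE)
}

# small deterministic dataset: geno as matrix, default one SNP per column
toy_dataset <- function(geno, phenotype, ...) {
  geno <- as.matrix(geno)
  if (is.null(colnames(geno))) colnames(geno) <- sprintf("rs%02d", seq_len(ncol(geno)))
  snp_dataset(geno, make_samples(phenotype, ...), make_snps(colnames(geno)))
}

# dataset with counts in a dominant-coded 2x2 layout:
# cases: exposed/unexposed, controls: exposed/unexposed (exposed = geno 1)
dataset_2x2 <- function(case_exp, case_unexp, ctl_exp, ctl_unexp) {
  g <- c(rep(1L, case_exp), rep(0L, case_unexp),
         rep(1L, ctl_exp), rep(0L, ctl_unexp))
  y <- c(rep(1L, case_exp + case_unexp), rep(0L, ctl_exp + ctl_unexp))
  toy_dataset(matrix(g, ncol = 1), y)
}

# standard planted-interaction study pieces used by several files
planted_mafs <- function(n_snps = 50, seed = 2024) {
  set.seed(seed)
  mafs <- setNames(runif(n_snps, 0.1, 0.5), sprintf("SNP%03d", seq_len(n_snps)))
  mafs[c("SNP001", "SNP002")] <- 0.3
  mafs
}

planted_model <- function(mafs, cell_log_or = 1.2)
  pure_epistasis_model(c("SNP001", "SNP002"), cell_log_or, "corner", mafs)

# reference categorization + statistic using stats::glm, independent of the
# compiled IRLS path
mbmdr_glm_oracle <- function(d, pair, alpha_cell = 0.1, min_cell = 10,
                             adjust_marginal = FALSE) {
  g1 <- d$genotypes[, pair[1]]; g2 <- d$genotypes[, pair[2]]
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]; y <- d$samples$phenotype[ok]
  cell <- 3 * g1 + g2
  lab <- rep("O", 9)
  for (c in 0:8) {
    nc <- sum(cell == c)
    if (nc < min_cell || nc == 0 || nc == length(y)) next
    ind <- as.numeric(cell == c)
    df <- data.frame(y = y, ind = ind, g1 = g1, g2 = g2)
    fml <- if (adjust_marginal) y ~ ind + g1 + g2 else y ~ ind
    fit <- suppressWarnings(glm(fml, binomial(), df,
                                control = stats::glm.control(epsilon = 1e-12)))
    co <- summary(fit)$coefficients
    if (!"ind" %in% rownames(co)) next
    b <- co["ind", 1]; p <- co["ind", 4]
    if (abs(b) > 15) next
    if (p < alpha_cell) lab[c + 1] <- if (b > 0) "H" else "L"
  }
  ws <- sapply(c("H", "L"), function(which) {
    ind <- as.numeric(lab[cell + 1] == which)
    if (sum(ind) == 0 || sum(ind) == length(y)) return(-Inf)
    df <- data.frame(y = y, ind = ind, g1 = g1, g2 = g2)
    fml <- if (adjust_marginal) y ~ ind + g1 + g2 else y ~ ind
    fit <- suppressWarnings(glm(fml, binomial(), df,
                                control = stats::glm.control(epsilon = 1e-12)))
    co <- summary(fit)$coefficients
    if (abs(co["ind", 1]) > 15) return(-Inf)
    (co["ind", 1] / co["ind", 2])^2
  })
  W <- max(ws)
  list(labels = lab, W = if (is.finite(W)) W else NA_real_)
}

# closed-form MB-MDR statistic for the unadjusted case: the 2x2 logistic MLE
# is the cross-product ratio, separation is exactly a zero margin count.
# Mirrors the declared edge conventions (separated or degenerate cell -> O,
# separated or degenerate category fit -> -Inf) by construction.
mbmdr_exact_oracle <- function(g1, g2, y, alpha_cell = 1) {
  cell <- 3 * g1 + g2
  n <- length(y)
  lab <- rep("O", 9)
  for (c in 0:8) {
    a <- sum(y == 1 & cell == c); b <- sum(y == 0 & cell == c)
    cc <- sum(y == 1 & cell != c); dd <- sum(y == 0 & cell != c)
    if (min(a, b, cc, dd) == 0) next
    o <- wald_2x2(a, b, cc, dd)
    if (o$p < alpha_cell && o$beta != 0)
      lab[c + 1] <- if (o$beta > 0) "H" else "L"
  }
  ws <- vapply(c("H", "L"), function(wh) {
    ind <- lab[cell + 1] == wh
    a <- sum(y == 1 & ind); b <- sum(y == 0 & ind)
    cc <- sum(y == 1 & !ind); dd <- sum(y == 0 & !ind)
    if (min(a, b, cc, dd) == 0) return(-Inf)
    wald_2x2(a, b, cc, dd)$z^2
  }, 0)
  W <- max(ws)
  list(labels = lab, W = if (is.finite(W)) W else NA_real_)
}

# exact permutation p over all distinct case assignments, via the oracle
mbmdr_exact_perm_oracle <- function(g1, g2, y, alpha_cell = 1) {
  W_obs <- mbmdr_exact_oracle(g1, g2, y, alpha_cell)$W
  if (is.na(W_obs)) return(list(W = NA_real_, p = NA_real_))
  combos <- combn(length(y), sum(y))
  Ws <- apply(combos, 2, function(idx) {
    yy <- rep(0L, length(y)); yy[idx] <- 1L
    w <- mbmdr_exact_oracle(g1, g2, yy, alpha_cell)$W
    if (is.na(w)) -Inf else w
  })
  list(W = W_obs, p = sum(Ws >= W_obs - 1e-9) / ncol(combos))
}
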