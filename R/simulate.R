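#' Penetrance model for the case-control simulator
#'
#' Disease risk follows a logistic model on genotypes and covariates:
#' baseline log-odds, optional per-SNP genetic effects (dominant, recessive
#' or log-additive coding with a log odds ratio), an optional 3x3 grid of
#' log-odds offsets attached to one designated SNP pair (the epistatic
#' component), and optional covariate effects.
#'
#' @param baseline_logit baseline log-odds of disease (default -2.5, about
#'   7.6% population risk).
#' @param snp_effects `NULL` or data.frame with columns `snp_id`, `coding`
#'   (`"dominant"`, `"recessive"` or `"additive"`) and `log_or`.
#' @param epistatic_cells `NULL` or `list(pair = c(id1, id2), offsets = 3x3
#'   numeric matrix)` of log-odds offsets indexed by minor-allele counts
#'   (row = first SNP, column = second SNP, counts 0..2).
#' @param covariate_effects `NULL` or named numeric vector with any of
#'   `age` (per year, age centered at 47), `sex` (female vs male) and
#'   `country` (second level vs first).
#' @return object of class `penetrance_model`.
#' @export
penetrance_model <- function(baseline_logit = -2.5, snp_effects = NULL,
                             epistatic_cells = NULL, covariate_effects = NULL) {
  stopifnot(is.numeric(baseline_logit), is.finite(baseline_logit))
  if (!is.null(snp_effects)) {
    snp_effects <- as.data.frame(snp_effects, stringsAsFactors = FALSE)
    stopifnot(all(c("snp_id", "coding", "log_or") %in% names(snp_effects)),
              all(snp_effects$coding %in% c("dominant", "recessive", "additive")),
              all(is.finite(snp_effects$log_or)))
  }
  if (!is.null(epistatic_cells)) {
    stopifnot(is.list(epistatic_cells),
              length(epistatic_cells$pair) == 2,
              epistatic_cells$pair[1] != epistatic_cells$pair[2],
              is.matrix(epistatic_cells$offsets),
              all(dim(epistatic_cells$offsets) == c(3, 3)),
              all(is.finite(epistatic_cells$offsets)))
  }
  if (!is.null(covariate_effects)) {
    stopifnot(is.numeric(covariate_effects),
              all(names(covariate_effects) %in% c("age", "sex", "country")))
  }
  structure(list(baseline_logit = baseline_logit, snp_effects = snp_effects,
                 epistatic_cells = epistatic_cells,
                 covariate_effects = covariate_effects),
            class = "penetrance_model")
}

#' Simulation configuration
#'
#' Defaults mirror a discovery series of 609 cases / 525 controls with the
#' case-subtype mix of the thyroid-carcinoma study design the pipeline
#' targets (cPTC 304, fvPTC 146, other/unspecified PTC 90, FTC 69), age
#' about Normal(47, 12) truncated to [18, 90], 82% female, and a single
#' country by default.
#'
#' @param n_cases,n_controls sample sizes.
#' @param mafs named vector of minor allele frequencies in `(0, 0.5]` (names
#'   become snp_ids; unnamed vectors get `SNP001...`).
#' @param model a [penetrance_model].
#' @param case_subtype_mix named proportions over case subtypes (must sum
#'   to 1).
#' @param missing_rate proportion of genotype calls set missing, in `[0, 1)`.
#' @param age_mean,age_sd,age_range,p_female,country_levels,country_probs
#'   covariate generator settings.
#' @param subtype_models optional named list of [penetrance_model]s keyed by
#'   subtype: cases of those subtypes are drawn under their own model (used
#'   to plant subtype-specific interactions); remaining cases and all
#'   controls use `model`.
#' @param max_draws rejection-sampling cap on population draws.
#' @param seed integer seed making the draw reproducible.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_cases = 609, n_controls = 525, mafs, model,
                       case_subtype_mix = c(cPTC = 304, fvPTC = 146,
                                            otherPTC = 90, FTC = 69) / 609,
                       missing_rate = 0, age_mean = 47, age_sd = 12,
                       age_range = c(18, 90), p_female = 0.82,
                       country_levels = "ES", country_probs = 1,
                       subtype_models = NULL, max_draws = 2e6, seed = 1L) {
  stopifnot(n_cases >= 1, n_controls >= 1,
            all(mafs >= 0 & mafs <= 0.5),
            inherits(model, "penetrance_model"),
            missing_rate >= 0, missing_rate < 1,
            abs(sum(case_subtype_mix) - 1) < 1e-8,
            all(names(case_subtype_mix) %in% setdiff(.SUBTYPES, "control")),
            length(country_levels) == length(country_probs))
  if (is.null(names(mafs)))
    names(mafs) <- sprintf("SNP%03d", seq_along(mafs))
  if (!is.null(subtype_models))
    stopifnot(all(names(subtype_models) %in% names(case_subtype_mix)),
              all(vapply(subtype_models, inherits, TRUE, "penetrance_model")))
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls), mafs = mafs,
                 model = model, case_subtype_mix = case_subtype_mix,
                 missing_rate = missing_rate, age_mean = age_mean,
                 age_sd = age_sd, age_range = age_range, p_female = p_female,
                 country_levels = country_levels,
                 country_probs = country_probs / sum(country_probs),
                 subtype_models = subtype_models,
                 max_draws = max_draws, seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw independent HWE genotypes
#'
#' Each SNP is drawn independently with genotype probabilities
#' ((1-p)^2, 2p(1-p), p^2); no linkage disequilibrium is generated.
#'
#' @param mafs vector of minor allele frequencies in `[0, 0.5]`.
#' @param n number of individuals.
#' @param seed optional integer seed.
#' @return integer matrix n x length(mafs) of minor-allele counts.
#' @export
simulate_genotypes <- function(mafs, n, seed = NULL) {
  stopifnot(all(mafs >= 0 & mafs <= 0.5), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  m <- length(mafs)
  g <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    p <- mafs[j]
    g[, j] <- sample.int(3L, n, replace = TRUE,
                         prob = c((1 - p)^2, 2 * p * (1 - p), p^2)) - 1L
  }
  if (!is.null(names(mafs))) colnames(g) <- names(mafs)
  g
}

# disease probability for a genotype matrix + sample covariates under a model
disease_prob <- function(model, geno, samples = NULL) {
  eta <- rep(model$baseline_logit, nrow(geno))
  se <- model$snp_effects
  if (!is.null(se)) {
    for (r in seq_len(nrow(se))) {
      g <- geno[, se$snp_id[r]]
      x <- switch(se$coding[r],
                  dominant = as.numeric(g >= 1),
                  recessive = as.numeric(g == 2),
                  additive = as.numeric(g))
      eta <- eta + se$log_or[r] * x
    }
  }
  ec <- model$epistatic_cells
  if (!is.null(ec)) {
    g1 <- geno[, ec$pair[1]]; g2 <- geno[, ec$pair[2]]
    eta <- eta + ec$offsets[cbind(g1 + 1L, g2 + 1L)]
  }
  ce <- model$covariate_effects
  if (!is.null(ce) && !is.null(samples)) {
    if (!is.na(ce["age"]) && "age" %in% names(samples))
      eta <- eta + ce[["age"]] * (samples$age - 47)
    if (!is.na(ce["sex"]) && "sex" %in% names(samples))
      eta <- eta + ce[["sex"]] * as.numeric(samples$sex == "female")
    if (!is.na(ce["country"]) && "country" %in% names(samples)) {
      lev <- unique(samples$country)
      if (length(lev) > 1)
        eta <- eta + ce[["country"]] * as.numeric(samples$country == lev[2])
    }
  }
  plogis(eta)
}

# draw covariates for a batch of individuals
draw_covariates <- function(cfg, n) {
  age <- rnorm(n, cfg$age_mean, cfg$age_sd)
  age <- pmin(pmax(age, cfg$age_range[1]), cfg$age_range[2])
  sex <- ifelse(runif(n) < cfg$p_female, "female", "male")
  country <- if (length(cfg$country_levels) == 1L)
    rep(cfg$country_levels, n)
  else
    cfg$country_levels[sample.int(length(cfg$country_levels), n,
                                  replace = TRUE, prob = cfg$country_probs)]
  data.frame(age = round(age, 1), sex = sex, country = country,
             stringsAsFactors = FALSE)
}

# rejection-sample `n_needed` individuals with the given disease status
rejection_sample <- function(cfg, model, n_needed, diseased) {
  geno_acc <- NULL; cov_acc <- NULL
  drawn <- 0L
  batch <- max(1000L, 4L * n_needed)
  while (is.null(geno_acc) || nrow(geno_acc) < n_needed) {
    if (drawn > cfg$max_draws)
      stop("rejection sampling exceeded max_draws (", cfg$max_draws,
           "); disease prevalence too extreme for the requested sizes")
    g <- simulate_genotypes(cfg$mafs, batch)
    cv <- draw_covariates(cfg, batch)
    p <- disease_prob(model, g, cv)
    keep <- if (diseased) runif(batch) < p else runif(batch) >= p
    drawn <- drawn + batch
    geno_acc <- rbind(geno_acc, g[keep, , drop = FALSE])
    cov_acc <- rbind(cov_acc, cv[keep, , drop = FALSE])
  }
  list(geno = geno_acc[seq_len(n_needed), , drop = FALSE],
       cov = cov_acc[seq_len(n_needed), , drop = FALSE])
}

#' Simulate a case-control dataset under a penetrance model
#'
#' Individuals are rejection-sampled from the population model (HWE
#' genotypes, covariates, logistic penetrance) until exactly `n_cases`
#' diseased and `n_controls` non-diseased individuals are collected. Case
#' subtypes are filled by quota from `case_subtype_mix`; when
#' `subtype_models` names a subtype, its cases are drawn under that model
#' instead (all controls always come from the base model). Missing calls are
#' then injected uniformly at random. Fully reproducible from `seed`.
#'
#' @param config a [sim_config].
#' @return an [snp_dataset].
#' @export
simulate_case_control <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  mix <- config$case_subtype_mix
  quota <- floor(mix * config$n_cases)
  rem <- config$n_cases - sum(quota)
  if (rem > 0) {
    o <- order(mix * config$n_cases - quota, decreasing = TRUE)
    quota[o[seq_len(rem)]] <- quota[o[seq_len(rem)]] + 1L
  }
  quota <- quota[quota > 0]

  parts <- list()
  for (s in names(quota)) {
    mod <- config$subtype_models[[s]] %||% config$model
    smp <- rejection_sample(config, mod, quota[[s]], diseased = TRUE)
    smp$cov$subtype <- s
    smp$cov$phenotype <- 1L
    parts[[s]] <- smp
  }
  ctl <- rejection_sample(config, config$model, config$n_controls,
                          diseased = FALSE)
  ctl$cov$subtype <- "control"
  ctl$cov$phenotype <- 0L
  parts$control <- ctl

  geno <- do.call(rbind, lapply(parts, `[[`, "geno"))
  samp <- do.call(rbind, lapply(parts, `[[`, "cov"))
  n <- nrow(geno)
  samp$sample_id <- sprintf("S%05d", seq_len(n))
  rownames(samp) <- NULL

  if (config$missing_rate > 0) {
    mask <- runif(length(geno)) < config$missing_rate
    geno[mask] <- NA_integer_
  }

  snps <- data.frame(snp_id = names(config$mafs), gene = NA_character_,
                     allele_major = "A", allele_minor = "G",
                     stringsAsFactors = FALSE)
  snp_dataset(geno,
              samp[c("sample_id", "phenotype", "subtype", "age", "sex", "country")],
              snps)
}

#' Build a purely epistatic two-SNP penetrance model
#'
#' Attaches a 3x3 grid of log-odds offsets to one SNP pair such that the
#' pair interacts while each SNP's genotype-specific marginal penetrances
#' (averaged over the partner's HWE genotype distribution) are exactly
#' equal, i.e. every single-SNP marginal odds ratio is 1.
#'
#' Patterns:
#' * `"corner"`: the four carrier-by-carrier cells (both minor-allele
#'   counts >= 1) receive `cell_log_or`; compensating offsets on the
#'   remaining margin cells and the origin cell are solved numerically
#'   against the HWE cell weights so the marginals equalize. Within the
#'   one-parameter family of balanced solutions the margin cells are kept
#'   as close to baseline as possible, which makes the balancing push the
#'   origin (non-carrier/non-carrier) cell up toward the corner's risk --
#'   an XOR-flavored shape that is intrinsic to marginally neutral
#'   carrier-block epistasis.
#' * `"checkerboard"`: offsets alternate `+cell_log_or` / `-cell_log_or` by
#'   cell parity (an XOR-type model); marginals are exactly balanced by
#'   symmetry at MAF 0.5 and approximately otherwise.
#'
#' @param pair character of the two snp_ids.
#' @param cell_log_or log odds ratio carried by the pattern cells.
#' @param pattern `"corner"` or `"checkerboard"`.
#' @param mafs minor allele frequencies of the two SNPs (length 2, or a
#'   named vector containing them).
#' @param baseline_logit baseline log-odds of disease.
#' @return a [penetrance_model] with `epistatic_cells` set.
#' @export
pure_epistasis_model <- function(pair, cell_log_or,
                                 pattern = c("corner", "checkerboard"),
                                 mafs, baseline_logit = -2.5) {
  pattern <- match.arg(pattern)
  stopifnot(length(pair) == 2, pair[1] != pair[2], is.finite(cell_log_or))
  if (!is.null(names(mafs)) && all(pair %in% names(mafs)))
    mafs <- mafs[pair]
  stopifnot(length(mafs) == 2, all(mafs > 0 & mafs <= 0.5))

  if (pattern == "checkerboard") {
    off <- outer(0:2, 0:2, function(i, j) cell_log_or * (-1)^(i + j))
  } else {
    off <- solve_corner_offsets(cell_log_or, mafs, baseline_logit)
  }
  penetrance_model(baseline_logit = baseline_logit,
                   epistatic_cells = list(pair = pair, offsets = off))
}

# Solve compensating offsets for the carrier-block corner pattern.
# Cell groups: block (gA>=1 & gB>=1) = delta; row-comp (gA>=1, gB=0) = aA;
# col-comp (gA=0, gB>=1) = aB; origin (0,0) = cc. The four marginal
# conditions (rows in/out of the block, columns in/out) share a common
# marginal penetrance K, solved by a 1-d root search.
solve_corner_offsets <- function(delta, mafs, b0) {
  if (delta == 0) return(matrix(0, 3, 3))
  wA <- c((1 - mafs[1])^2, 2 * mafs[1] * (1 - mafs[1]), mafs[1]^2)
  wB <- c((1 - mafs[2])^2, 2 * mafs[2] * (1 - mafs[2]), mafs[2]^2)
  uA <- wA[2] + wA[3]; vA <- 1 - uA
  uB <- wB[2] + wB[3]; vB <- 1 - uB
  fd <- plogis(b0 + delta)

  eps <- 1e-12
  faA <- function(K) (K - uB * fd) / vB
  faB <- function(K) (K - uA * fd) / vA
  gfun <- function(K) {
    fa <- faA(K); fb <- faB(K)
    fc1 <- (K - uB * fb) / vB
    fc2 <- (K - uA * fa) / vA
    fc1 - fc2
  }
  feasible <- function(K) {
    fa <- faA(K); fb <- faB(K)
    if (fa <= eps || fa >= 1 - eps || fb <= eps || fb >= 1 - eps) return(FALSE)
    fc <- (K - uB * fb) / vB
    fc > eps && fc < 1 - eps
  }

  offsets_at <- function(K) {
    aA <- unname(qlogis(faA(K)) - b0)
    aB <- unname(qlogis(faB(K)) - b0)
    cc <- unname(qlogis((K - uB * plogis(b0 + aB)) / vB) - b0)
    c(aA = aA, aB = aB, cc = cc)
  }
  lo <- max(eps, uB * fd, uA * fd) + 1e-9
  hi <- min(1 - eps, uB * fd + vB, uA * fd + vA) - 1e-9
  if (hi <= lo) stop("marginal equalization infeasible for this cell_log_or/MAFs")
  Ks <- seq(lo, hi, length.out = 2001)
  ok <- vapply(Ks, feasible, TRUE)
  if (!any(ok)) stop("marginal equalization infeasible for this cell_log_or/MAFs")
  Ks <- Ks[ok]
  gv <- vapply(Ks, gfun, 0)
  # one-parameter solution family: anchor the margin cells (carrier x
  # non-carrier) as close to the baseline as the balance allows, so the
  # corner block stays the elevated-risk region
  margin_obj <- function(K) { o <- offsets_at(K); o[["aA"]]^2 + o[["aB"]]^2 }
  if (max(abs(gv)) < 1e-12) {
    K <- stats::optimize(margin_obj, range(Ks), tol = 1e-12)$minimum
  } else {
    sgn <- sign(gv)
    flip <- which(diff(sgn) != 0)
    if (!length(flip))
      stop("marginal equalization infeasible for this cell_log_or/MAFs")
    roots <- vapply(flip, function(i)
      uniroot(gfun, c(Ks[i], Ks[i + 1]), tol = 1e-14)$root, 0)
    K <- roots[which.min(vapply(roots, margin_obj, 0))]
  }
  off3 <- offsets_at(K)
  aA <- off3[["aA"]]; aB <- off3[["aB"]]; cc <- off3[["cc"]]
  off <- matrix(cc, 3, 3)
  off[2:3, 2:3] <- delta
  off[2:3, 1] <- aA
  off[1, 2:3] <- aB
  off[1, 1] <- cc

  # exact enumeration check of the construction
  pen <- plogis(b0 + off)
  margA <- as.vector(pen %*% wB)
  margB <- as.vector(t(pen) %*% wA)
  if (max(abs(margA - margA[1])) > 1e-8 || max(abs(margB - margB[1])) > 1e-8)
    stop("internal: marginal equalization failed to converge")
  off
}

#' Exact genotype-marginal penetrances of a two-SNP model
#'
#' Enumerates the nine HWE-weighted cells of the model's epistatic pair and
#' returns, for each SNP, the disease probability by genotype (averaged over
#' the partner SNP). Equal entries mean marginal odds ratio 1. Used to
#' verify pure-epistasis constructions.
#'
#' @param model a [penetrance_model] with `epistatic_cells`.
#' @param mafs minor allele frequencies of the pair (length 2).
#' @return list with numeric length-3 vectors `snp1` and `snp2`.
#' @export
marginal_penetrances <- function(model, mafs) {
  ec <- model$epistatic_cells
  if (is.null(ec)) stop("model has no epistatic component")
  wA <- c((1 - mafs[1])^2, 2 * mafs[1] * (1 - mafs[1]), mafs[1]^2)
  wB <- c((1 - mafs[2])^2, 2 * mafs[2] * (1 - mafs[2]), mafs[2]^2)
  pen <- plogis(model$baseline_logit + ec$offsets)
  list(snp1 = as.vector(pen %*% wB), snp2 = as.vector(t(pen) %*% wA))
}
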