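test_that("hwe_exact_test matches enumeration on canonical tables", {
  # modal configuration: every configuration is in the tail sum
  expect_equal(hwe_exact_test(25, 50, 25), 1.0)
  # monomorphic: single possible configuration
  expect_equal(hwe_exact_test(0, 0, 40), 1.0)
  expect_equal(hwe_exact_test(10, 0, 0), 1.0)
  expect_error(hwe_exact_test(0, 0, 0), "empty")
  # frozen value from the enumeration oracle for a het-deficient table
  expect_equal(hwe_exact_test(21, 18, 61), hwe_oracle(21, 18, 61),
               tolerance = 1e-10)
  expect_error(hwe_exact_test(-1, 5, 5), "negative")
})

test_that("hwe_exact_test equals the enumeration oracle on random tables", {
  set.seed(88)
  for (i in 1:200) {
    n <- sample(2:300, 1)
    nAA <- sample(0:n, 1)
    nAa <- sample(0:(n - nAA), 1)
    naa <- n - nAA - nAa
    expect_equal(hwe_exact_test(nAA, nAa, naa), hwe_oracle(nAA, nAa, naa),
                 tolerance = 1e-10)
  }
})

test_that("unadjusted dominant fit reproduces the cross-product OR", {
  d <- dataset_2x2(30, 70, 20, 80)
  fit <- fit_genetic_model(d, "rs01", "dominant")
  expect_equal(fit$or_point, (30 * 80) / (70 * 20), tolerance = 1e-8)
  # phenotype independent of genotype -> OR 1
  d0 <- dataset_2x2(25, 75, 25, 75)
  fit0 <- fit_genetic_model(d0, "rs01", "dominant")
  expect_equal(fit0$or_point, 1.0, tolerance = 1e-8)
  expect_true(fit0$ci95[1] <= fit0$or_point & fit0$or_point <= fit0$ci95[2])
})

test_that("covariate-adjusted fit matches an independent IRLS oracle", {
  set.seed(42)
  n <- 800
  g <- simulate_genotypes(0.3, n)
  age <- rnorm(n, 50, 10)
  sex <- sample(c("female", "male"), n, replace = TRUE)
  eta <- -0.5 + 0.4 * g + 0.02 * (age - 50) + 0.3 * (sex == "female")
  y <- rbinom(n, 1, plogis(eta))
  d <- snp_dataset(matrix(g, ncol = 1, dimnames = list(NULL, "rs1")),
                   make_samples(y, age = age, sex = sex),
                   make_snps("rs1"))
  fit <- fit_genetic_model(d, "rs1", "logadditive", covariates = c("age", "sex"))
  X <- cbind(1, g, age, as.numeric(sex == "male"))
  or <- irls_oracle(X, y)
  expect_equal(log(fit$or_point), unname(or$beta[2]), tolerance = 1e-6)
  expect_equal(fit$n_used, n)
})

test_that("monomorphic SNPs and separation are reported as errors", {
  d <- toy_dataset(matrix(0L, 40, 1), rep(c(1L, 0L), 20))
  expect_error(fit_genetic_model(d, "rs01", "dominant"), "monomorphic")
  # perfect separation
  g <- c(rep(1L, 20), rep(0L, 20))
  y <- c(rep(1L, 20), rep(0L, 20))
  ds <- toy_dataset(matrix(g, ncol = 1), y)
  suppressWarnings(expect_error(fit_genetic_model(ds, "rs01", "dominant"),
                                "separation"))
})

test_that("select_best_model recovers a planted recessive model", {
  hits <- 0L
  for (r in 1:60) {
    set.seed(5000 + r)
    g <- simulate_genotypes(0.4, 2000)
    y <- rbinom(2000, 1, plogis(-0.7 + log(2.5) * (g == 2)))
    d <- toy_dataset(matrix(g, ncol = 1), y)
    res <- select_best_model(d, "rs01")
    if (res$model == "recessive") hits <- hits + 1L
    expect_identical(res$p_type, "model-selected")
  }
  expect_gte(hits / 60, 0.9)
})

test_that("AIC ties fall back to the fixed dominant-first order", {
  # with only genotypes 0 and 2 present, the dominant, recessive and
  # log-additive codings produce the same binary split, so all three AICs
  # tie exactly and the fixed order returns dominant
  set.seed(9)
  g <- sample(c(0L, 2L), 400, replace = TRUE)
  y <- rbinom(400, 1, plogis(-0.3 + 0.3 * (g == 2)))
  d <- toy_dataset(matrix(g, ncol = 1), y)
  fd <- fit_genetic_model(d, "rs01", "dominant")
  fr <- fit_genetic_model(d, "rs01", "recessive")
  fl <- fit_genetic_model(d, "rs01", "logadditive")
  expect_equal(fd$aic, fr$aic, tolerance = 1e-10)
  expect_equal(fd$aic, fl$aic, tolerance = 1e-10)
  expect_identical(select_best_model(d, "rs01")$model, "dominant")
})

test_that("heterogeneity LR test is null-calibrated and detects planted
           subtype-specific effects", {
  # identical genotype effect across subtypes: LR near 0, p near 1 at large n
  set.seed(31)
  n <- 3000
  g <- simulate_genotypes(0.3, 3 * n)
  eta <- -0.4 + 0.5 * g
  y <- rbinom(3 * n, 1, plogis(eta))
  sub <- ifelse(y == 1, sample(c("cPTC", "fvPTC"), 3 * n, replace = TRUE),
                "control")
  d <- toy_dataset(matrix(g, ncol = 1), y, subtype = sub)
  ht <- heterogeneity_lr_test(d, "rs01", subtypes = c("cPTC", "fvPTC"))
  expect_lt(ht$lr_stat, 6)
  expect_gt(ht$p, 0.01)

  # planted per-allele ORs 2.3 vs 1.0 (a fvPTC-specific pattern)
  pows <- vapply(1:40, function(r) {
    set.seed(7000 + r)
    nc <- 300; n1 <- 150; n2 <- 150
    gc <- simulate_genotypes(0.3, nc)
    # case genotype distributions under per-allele enrichment
    draw_cases <- function(n, or) {
      w <- c(0.49, 0.42, 0.09) * or^(0:2)
      sample(0:2, n, replace = TRUE, prob = w / sum(w))
    }
    g1 <- draw_cases(n1, 2.3); g2 <- draw_cases(n2, 1.0)
    g <- c(gc, g1, g2)
    y <- c(rep(0L, nc), rep(1L, n1 + n2))
    sub <- c(rep("control", nc), rep("fvPTC", n1), rep("cPTC", n2))
    d <- toy_dataset(matrix(as.integer(g), ncol = 1), y, subtype = sub)
    heterogeneity_lr_test(d, "rs01", subtypes = c("fvPTC", "cPTC"))$p
  }, 0)
  expect_lt(median(pows), 0.05)

  expect_error(heterogeneity_lr_test(d, "rs01", subtypes = "cPTC"),
               "at least two")
  expect_error(heterogeneity_lr_test(d, "rs01", subtypes = c("cPTC", "FTC")),
               "zero cases")
})

test_that("free-slope multinomial fit matches nnet::multinom's likelihood", {
  set.seed(77)
  n <- 600
  g <- drop(simulate_genotypes(0.3, n))
  lin1 <- -0.6 + 0.6 * g; lin2 <- -0.9 + 0.1 * g
  pr <- cbind(1, exp(lin1), exp(lin2)); pr <- pr / rowSums(pr)
  cls <- apply(pr, 1, function(p) sample(0:2, 1, prob = p))
  y <- as.integer(cls > 0)
  sub <- c("control", "cPTC", "fvPTC")[cls + 1]
  d <- toy_dataset(matrix(g, ncol = 1), y, subtype = sub)
  ht <- heterogeneity_lr_test(d, "rs01", subtypes = c("cPTC", "fvPTC"))
  # independent maximum-likelihood route for the unconstrained model
  mn <- nnet::multinom(factor(cls) ~ g, trace = FALSE, reltol = 1e-12)
  co <- coef(mn)
  expect_equal(sort(unname(ht$coef_by_subtype)), sort(unname(co[, "g"])),
               tolerance = 1e-4)
})

test_that("single_snp_scan reports a table with HWE and MAF columns", {
  set.seed(61)
  mafs <- c(rs1 = 0.3, rs2 = 0.2)
  cfg <- sim_config(150, 150, mafs = mafs,
                    model = penetrance_model(
                      snp_effects = data.frame(snp_id = "rs1",
                                               coding = "additive",
                                               log_or = log(1.8))),
                    seed = 3)
  d <- simulate_case_control(cfg)
  tab <- single_snp_scan(d, case_group = c("cPTC", "fvPTC", "otherPTC"))
  expect_identical(nrow(tab), 2L)
  expect_true(all(c("model", "or", "wald_p", "hwe_p_controls") %in% names(tab)))
  expect_true(all(tab$p_type == "model-selected"))
  expect_true(all(tab$maf_controls <= 0.5))
})
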