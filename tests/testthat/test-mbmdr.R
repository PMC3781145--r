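pair_key_mb <- function(a, b) paste(sort(c(a, b)), collapse = "|")

test_that("categorization always emits nine labels from {H, L, O}", {
  set.seed(52)
  mafs <- c(a = 0.3, b = 0.4, c = 0.15)
  cfg <- sim_config(120, 140, mafs = mafs, model = penetrance_model(),
                    missing_rate = 0.05, seed = 6)
  d <- simulate_case_control(cfg)
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    ct <- mbmdr_categorize(d, pair, alpha_cell = 0.5, min_cell = 0)
    expect_identical(dim(ct$labels), c(3L, 3L))
    expect_identical(length(ct$labels), 9L)
    expect_true(all(ct$labels %in% c("H", "L", "O")))
    expect_identical(nrow(ct$cell_tests), 9L)
  }
  expect_error(mbmdr_categorize(d, c("a", "a")), "distinct")
})

test_that("null data produce all-neutral grids and NA statistics", {
  set.seed(53)
  cfg <- sim_config(400, 400, mafs = c(x = 0.3, y = 0.3),
                    model = penetrance_model(), seed = 54)
  d <- simulate_case_control(cfg)
  ct <- mbmdr_categorize(d, c("x", "y"), alpha_cell = 1e-6)
  expect_true(all(ct$labels == "O"))
  expect_true(is.na(mbmdr_statistic(d, ct)))
  r <- mbmdr_permutation_p(d, c("x", "y"), B = 19, alpha_cell = 1e-6)
  expect_true(is.na(r$perm_p))
  # empty cells are forced neutral by the occupancy rule
  ct2 <- mbmdr_categorize(d, c("x", "y"), alpha_cell = 1, min_cell = 1e6)
  expect_true(all(ct2$labels == "O"))
})

test_that("cell Wald statistics match the closed-form 2x2 logistic fit", {
  set.seed(57)
  for (rep in 1:40) {
    n <- 400
    g1 <- drop(simulate_genotypes(0.35, n)); g2 <- drop(simulate_genotypes(0.3, n))
    y <- rbinom(n, 1, 0.45)
    d <- toy_dataset(cbind(a = g1, b = g2), as.integer(y))
    ct <- mbmdr_categorize(d, c("a", "b"), alpha_cell = 1, min_cell = 0,
                           adjust_marginal = FALSE)
    cell <- 3 * g1 + g2
    for (c in 0:8) {
      nc <- sum(cell == c)
      if (nc == 0 || nc == n) next
      a <- sum(y == 1 & cell == c); b <- sum(y == 0 & cell == c)
      cc <- sum(y == 1 & cell != c); dd <- sum(y == 0 & cell != c)
      if (min(a, b, cc, dd) == 0) next
      o <- wald_2x2(a, b, cc, dd)
      row <- ct$cell_tests[c + 1, ]
      expect_equal(row$p, o$p, tolerance = 1e-6)
      expect_identical(row$sign > 0, o$beta > 0)
    }
  }
})

test_that("categorization and statistic agree with the glm oracle", {
  set.seed(59)
  mafs <- c(SNP001 = 0.35, SNP002 = 0.35, N1 = 0.25)
  mod <- planted_model(mafs)
  cfg <- sim_config(350, 350, mafs = mafs, model = mod, seed = 60)
  d <- simulate_case_control(cfg)
  ct <- mbmdr_categorize(d, c("SNP001", "SNP002"), adjust_marginal = FALSE)
  w <- mbmdr_statistic(d, ct)
  o <- mbmdr_glm_oracle(d, c("SNP001", "SNP002"))
  expect_identical(as.vector(t(ct$labels)), o$labels)
  expect_equal(as.numeric(w), o$W, tolerance = 1e-6)
})

test_that("planted high-risk combinations are labeled H, never inverted", {
  # the balanced corner model elevates the carrier-by-carrier block and the
  # origin cell and depresses the margins; the categorization must recover
  # that geometry: H labels only in the elevated region (its well-populated
  # het-het cell H in the majority of replicates), L labels only on margins,
  # and the sparse minor-minor corner never mislabeled L
  elevated <- rbind(c(TRUE, FALSE, FALSE),
                    c(FALSE, TRUE, TRUE),
                    c(FALSE, TRUE, TRUE))
  h_hethet <- 0L
  for (r in 1:20) {
    mafs <- c(SNP001 = 0.35, SNP002 = 0.35)
    mod <- planted_model(mafs)
    cfg <- sim_config(609, 525, mafs = mafs, model = mod, seed = 900 + r)
    d <- simulate_case_control(cfg)
    L <- mbmdr_categorize(d, c("SNP001", "SNP002"))$labels
    expect_true(all(L[elevated] != "L"))
    expect_true(all(L[!elevated] != "H"))
    h_hethet <- h_hethet + (L[2, 2] == "H")
  }
  expect_gt(h_hethet / 20, 0.5)
})

test_that("permutation p is exact, deterministic and floor-bounded", {
  # W_obs above every permuted statistic gives the add-one floor
  mafs <- c(SNP001 = 0.4, SNP002 = 0.4)
  mod <- planted_model(mafs, cell_log_or = 2)
  cfg <- sim_config(400, 400, mafs = mafs, model = mod, seed = 71)
  d <- simulate_case_control(cfg)
  r <- mbmdr_permutation_p(d, c("SNP001", "SNP002"), B = 199, seed = 8)
  expect_gte(r$perm_p, 1 / 200)
  expect_lte(r$perm_p, 1)
  r2 <- mbmdr_permutation_p(d, c("SNP001", "SNP002"), B = 199, seed = 8)
  expect_identical(r$perm_p, r2$perm_p)
  expect_identical(r$n_permutations, 199L)
  expect_error(mbmdr_permutation_p(d, c("SNP001", "SNP002"), B = 0), "B")
})

test_that("exact permutation p equals full enumeration on tiny samples", {
  # n = 8 grouped into three occupied cells: all C(8,4) = 70 phenotype
  # assignments are enumerated independently by the closed-form oracle
  g1 <- c(0L, 0L, 0L, 1L, 1L, 1L, 2L, 2L)
  g2 <- c(0L, 0L, 0L, 1L, 1L, 1L, 2L, 2L)
  y <- c(1L, 1L, 0L, 0L, 1L, 0L, 1L, 0L)
  d <- toy_dataset(cbind(s1 = g1, s2 = g2), y)
  r <- mbmdr_permutation_p(d, c("s1", "s2"), alpha_cell = 1, min_cell = 0,
                           adjust_marginal = FALSE, exact = TRUE)
  o <- mbmdr_exact_perm_oracle(g1, g2, y, alpha_cell = 1)
  expect_false(is.na(o$W))
  expect_equal(r$statistic_W, o$W, tolerance = 1e-6)
  expect_equal(r$perm_p, o$p)
})

test_that("perm p is invariant to swapping case and control labels", {
  mafs <- c(SNP001 = 0.35, SNP002 = 0.35)
  mod <- planted_model(mafs)
  cfg <- sim_config(150, 150, mafs = mafs, model = mod, seed = 81)
  d <- simulate_case_control(cfg)
  d_swap <- d
  d_swap$samples$phenotype <- 1L - d$samples$phenotype
  d_swap$samples$subtype <- ifelse(d_swap$samples$phenotype == 1L, "cPTC",
                                   "control")
  r1 <- mbmdr_permutation_p(d, c("SNP001", "SNP002"), B = 99, seed = 5,
                            adjust_marginal = FALSE)
  r2 <- mbmdr_permutation_p(d_swap, c("SNP001", "SNP002"), B = 99, seed = 5,
                            adjust_marginal = FALSE)
  expect_equal(r1$statistic_W, r2$statistic_W, tolerance = 1e-8)
  expect_identical(r1$perm_p, r2$perm_p)
})

test_that("marginal adjustment keeps purely additive pairs at the null level", {
  # both SNPs act log-additively with no cell interaction: the adjusted
  # detector must reject at ~alpha
  B <- 60
  rej <- vapply(1:120, function(r) {
    set.seed(4000 + r)
    n <- 500
    g1 <- drop(simulate_genotypes(0.3, n)); g2 <- drop(simulate_genotypes(0.3, n))
    y <- rbinom(n, 1, plogis(-0.4 + 0.5 * g1 + 0.5 * g2))
    if (length(unique(y)) < 2) return(NA)
    d <- toy_dataset(cbind(a = g1, b = g2), as.integer(y))
    res <- mbmdr_permutation_p(d, c("a", "b"), B = B, seed = r,
                               adjust_marginal = TRUE)
    !is.na(res$perm_p) && res$perm_p < 0.05
  }, TRUE)
  rate <- mean(rej, na.rm = TRUE)
  expect_gte(rate, 0.0)
  expect_lte(rate, 0.10)
})

test_that("scan ranks the planted pair first and handles single pairs", {
  mafs <- planted_mafs(12)
  mod <- planted_model(mafs)
  cfg <- sim_config(500, 450, mafs = mafs, model = mod, seed = 91)
  d <- simulate_case_control(cfg)
  sc <- mbmdr_scan(d, B_screen = 99, seed = 92, screen_quantile = 0.95)
  expect_identical(pair_key_mb(sc$snp1[1], sc$snp2[1]), "SNP001|SNP002")
  expect_true("SNP001|SNP002" %in% mbmdr_flag(sc))
  # single-pair scan
  sc1 <- mbmdr_scan(d, pairs = rbind(c("SNP001", "SNP002")), B_screen = 49,
                    seed = 93, screen_quantile = 0)
  expect_identical(nrow(sc1), 1L)
  expect_false(is.na(sc1$perm_p[1]))
  # determinism
  sc2 <- mbmdr_scan(d, B_screen = 99, seed = 92, screen_quantile = 0.95)
  expect_equal(sc$perm_p, sc2$perm_p)
})
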