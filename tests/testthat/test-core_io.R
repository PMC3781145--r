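test_that("snp_dataset validates its invariants", {
  geno <- matrix(c(0L, 1L, 2L, NA), 2, 2)
  d <- toy_dataset(geno, c(1L, 0L))
  expect_s3_class(d, "snp_dataset")
  expect_identical(dim(d), c(2L, 2L))

  expect_error(toy_dataset(matrix(3L, 2, 1), c(1L, 0L)), "outside")
  expect_error(snp_dataset(geno, make_samples(c(1L, 0L)), make_snps("one")),
               "columns")
  s <- make_samples(c(1L, 0L)); s$subtype <- c("control", "control")
  expect_error(snp_dataset(geno, s, make_snps(c("a", "b"))), "coincide")
  m <- make_snps(c("a", "b")); m$allele_minor <- "A"
  expect_error(snp_dataset(geno, make_samples(c(1L, 0L)), m), "differ")
})

test_that("read_plink recodes to minor-allele counts anchored in controls", {
  ped <- tempfile(fileext = ".ped"); map <- tempfile(fileext = ".map")
  # case is A/A, control is G/G: G is the control-major allele, so the case
  # counts two copies of the minor allele
  writeLines(c("F1 S1 0 0 1 2 A A",
               "F2 S2 0 0 2 1 G G"), ped)
  writeLines("1\trs1\t0\t1", map)
  d <- read_plink(ped, map)
  expect_identical(unname(d$genotypes[, 1]), c(2L, 0L))
  expect_identical(d$snps$allele_major, "G")
  expect_identical(d$snps$allele_minor, "A")
  expect_identical(d$samples$phenotype, c(1L, 0L))

  # missing allele pair "0 0"
  writeLines(c("F1 S1 0 0 1 2 A A",
               "F2 S2 0 0 2 1 0 0",
               "F3 S3 0 0 2 1 G G"), ped)
  d2 <- read_plink(ped, map)
  expect_identical(unname(d2$genotypes[, 1]), c(2L, NA, 0L))

  # three distinct alleles is an error
  writeLines(c("F1 S1 0 0 1 2 A C",
               "F2 S2 0 0 2 1 G G"), ped)
  expect_error(read_plink(ped, map), ">2 distinct alleles")

  # ped/map SNP count mismatch
  writeLines(c("1\trs1\t0\t1", "1\trs2\t0\t2"), map)
  writeLines(c("F1 S1 0 0 1 2 A A", "F2 S2 0 0 2 1 G G"), ped)
  expect_error(read_plink(ped, map), "expected")
})

test_that("read_tabular aligns samples and rejects bad tokens", {
  gfile <- tempfile(fileext = ".csv"); sfile <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,rs1,rs2", "S1,0,1", "S2,2,NA", "S3,1,0"), gfile)
  writeLines(c("sample_id,phenotype,subtype,age,sex,country",
               "S3,0,control,44,male,ES",
               "S1,1,cPTC,51,female,ES",
               "S2,0,control,63,female,ES"), sfile)
  d <- read_tabular(gfile, sfile)
  expect_identical(nrow(d$genotypes), 3L)
  # aligned by sample_id, genotype file order wins
  expect_identical(d$samples$sample_id, c("S1", "S2", "S3"))
  expect_identical(unname(d$genotypes["S2", ]), c(2L, NA))

  writeLines(c("sample_id,phenotype,subtype,age,sex,country",
               "S1,1,cPTC,51,female,ES",
               "S2,0,control,63,female,ES"), sfile)
  expect_error(read_tabular(gfile, sfile), "sample_id sets differ")

  writeLines(c("sample_id,rs1", "S1,3", "S2,0", "S3,1"), gfile)
  writeLines(c("sample_id,phenotype,subtype,age,sex,country",
               "S1,1,cPTC,51,female,ES", "S2,0,control,63,female,ES",
               "S3,0,control,44,male,ES"), sfile)
  expect_error(read_tabular(gfile, sfile), "outside")
})

test_that("datasets round-trip through both dialects identically", {
  set.seed(11)
  mafs <- setNames(runif(8, 0.1, 0.4), sprintf("SNP%03d", 1:8))
  cfg <- sim_config(40, 50, mafs = mafs, model = penetrance_model(),
                    missing_rate = 0.05, seed = 99)
  d <- simulate_case_control(cfg)

  gfile <- tempfile(fileext = ".csv"); sfile <- tempfile(fileext = ".csv")
  write_tabular(d, gfile, sfile)
  d2 <- read_tabular(gfile, sfile)
  expect_identical(unname(d2$genotypes), unname(d$genotypes))
  expect_identical(d2$samples$phenotype, d$samples$phenotype)
  expect_identical(d2$samples$subtype, d$samples$subtype)
  expect_equal(d2$samples$age, d$samples$age)

  ped <- tempfile(fileext = ".ped"); map <- tempfile(fileext = ".map")
  write_plink(d, ped, map)
  d3 <- read_plink(ped, map, samples = d$samples)
  expect_identical(unname(d3$genotypes), unname(d$genotypes))
  expect_identical(d3$samples$sex, d$samples$sex)

  # equivalent content through the two dialects gives identical genotypes
  expect_identical(unname(d3$genotypes), unname(d2$genotypes))
})

test_that("minor_allele_freq counts alleles with pairwise missing exclusion", {
  d <- toy_dataset(matrix(c(0L, 1L, 2L), 3, 1), c(1L, 0L, 0L))
  expect_equal(minor_allele_freq(d, "rs01"), 0.5)
  d2 <- toy_dataset(matrix(0L, 3, 1), c(1L, 0L, 0L))
  expect_equal(minor_allele_freq(d2, "rs01"), 0)
  d3 <- toy_dataset(matrix(c(2L, 2L, NA), 3, 1), c(1L, 0L, 0L))
  expect_equal(minor_allele_freq(d3, "rs01"), 1)
  d4 <- toy_dataset(matrix(c(NA, NA, 2L), 3, 1), c(0L, 0L, 1L))
  expect_error(minor_allele_freq(d4, "rs01", "controls"), "missing")
  # control MAF <= 0.5 by construction of the plink coding
  set.seed(5)
  cfg <- sim_config(30, 60, mafs = c(a = 0.45, b = 0.2),
                    model = penetrance_model(), seed = 17)
  d5 <- simulate_case_control(cfg)
  ped <- tempfile(); map <- tempfile()
  write_plink(d5, ped, map)
  d6 <- read_plink(ped, map)
  expect_true(all(vapply(d6$snps$snp_id, function(s)
    minor_allele_freq(d6, s, "controls"), 0) <= 0.5))
})

test_that("stratify keeps controls plus requested subtypes, coding anchored", {
  set.seed(21)
  cfg <- sim_config(60, 40, mafs = c(x = 0.3, y = 0.25),
                    model = penetrance_model(), seed = 31)
  d <- simulate_case_control(cfg)
  dc <- stratify(d, "cPTC")
  expect_true(all(dc$samples$subtype %in% c("control", "cPTC")))
  expect_identical(sum(dc$samples$phenotype == 0L),
                   sum(d$samples$phenotype == 0L))
  # PTC overall excludes FTC
  dp <- stratify(d, c("cPTC", "fvPTC", "otherPTC"))
  expect_false("FTC" %in% dp$samples$subtype)
  expect_identical(dp$snps, d$snps)  # coding untouched
  expect_error(stratify(d, character()), "nonempty")
  expect_error(stratify(d, "control"), "not a case subtype")
})
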