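test_that("segregation types follow the parental genotype configuration", {
  expect_equal(classify_segregation("0/1", "0/0"), "AB_X_AA")
  expect_equal(classify_segregation("0/1", "1/1"), "AB_X_AA")
  expect_equal(classify_segregation("0/0", "0/1"), "AA_X_AB")
  expect_equal(classify_segregation("1/1", "0/1"), "AA_X_AB")
  expect_equal(classify_segregation("0/1", "0/1"), "other")
  expect_equal(classify_segregation("0/0", "1/1"), "other")
  expect_equal(classify_segregation("./.", "0/1"), "other")
  # vectorised
  expect_equal(classify_segregation(c("0/1", "0/0"), c("0/0", "0/1")),
               c("AB_X_AA", "AA_X_AB"))
})

test_that("1:1 segregation chi-square matches an independent implementation", {
  t1 <- test_segregation_ratio(50, 50)
  expect_equal(t1$chisq, 0)
  expect_equal(t1$p, 1)
  t2 <- test_segregation_ratio(70, 30)
  expect_equal(t2$chisq, 16)
  expect_equal(t2$p, 6.334248366623988e-05, tolerance = 1e-10)  # scipy chi2.sf
  t3 <- test_segregation_ratio(60, 50)
  expect_equal(t3$chisq, 100 / 110, tolerance = 1e-12)
  expect_equal(t3$p, 0.34035574238519883, tolerance = 1e-10)
  expect_gt(t3$p, 0.01)  # kept at the default threshold
  expect_error(test_segregation_ratio(0, 0), "zero")
})

test_that("missingness and segregation filters use the documented rules", {
  n <- 257
  mk_calls <- function(n_miss, n_het = NULL) {
    n_obs <- n - n_miss
    if (is.null(n_het)) n_het <- round(n_obs / 2)
    c(rep(1L, n_het), rep(0L, n_obs - n_het), rep(NA_integer_, n_miss))
  }
  calls <- rbind(mk_calls(52),             # 52/257 = 20.2% missing: removed
                 mk_calls(51),             # 51/257 = 19.8%: kept
                 mk_calls(0, n_het = 180), # distorted 180:77: removed
                 mk_calls(0))              # clean: kept
  ds <- make_dataset(calls, seg_types = rep("AB_X_AA", 4))
  out <- apply_filters(ds)
  expect_equal(out$report$n_missing_removed, 1)
  expect_equal(out$report$n_segratio_removed, 1)
  expect_equal(out$dataset$markers$id, c("m002", "m004"))
  # seg-type "other" markers are dropped
  ds2 <- make_dataset(calls[4, , drop = FALSE], seg_types = "other")
  expect_warning(out2 <- apply_filters(ds2), "all markers removed")
  expect_equal(out2$report$n_uninformative, 1)
})

test_that("filtering is idempotent and warns when nothing survives", {
  set.seed(5)
  cfg <- sim_config(n_progeny = 60,
                    chromosomes = data.frame(name = "Chr01",
                                             length_bp = 5e6,
                                             length_morgan = 0.8),
                    missing_rate = 0.1, seed = 5)
  ds <- simulate_population(cfg)$dataset
  once <- apply_filters(ds)
  twice <- apply_filters(once$dataset)
  expect_identical(twice$dataset$calls, once$dataset$calls)
  expect_equal(twice$report$n_missing_removed +
                 twice$report$n_segratio_removed, 0)
  # all-distorted dataset: everything removed, with a warning
  bad <- make_dataset(matrix(1L, 2, 50), seg_types = rep("AB_X_AA", 2))
  expect_warning(apply_filters(bad), "all markers removed")
})

test_that("markers without distortion mostly survive the 1:1 filter", {
  cfg <- sim_config(n_progeny = 200,
                    chromosomes = data.frame(name = c("Chr01", "Chr02"),
                                             length_bp = 2e7,
                                             length_morgan = 3),
                    missing_rate = 0.1, seed = 13)
  ds <- simulate_population(cfg)$dataset
  out <- apply_filters(ds)
  surv <- out$report$n_kept / out$report$n_input
  expect_gte(surv, 0.98)  # chi-square type-I at alpha = 0.01
})

test_that("the distortion option produces markers the 1:1 filter removes", {
  cfg <- sim_config(n_progeny = 250,
                    chromosomes = data.frame(name = "Chr01",
                                             length_bp = 5e6,
                                             length_morgan = 0.75),
                    missing_rate = 0,
                    distortion = c(Chr01_T003_f = 0.85), seed = 17)
  ds <- simulate_population(cfg)$dataset
  out <- apply_filters(ds)
  expect_false("Chr01_T003_f" %in% out$dataset$markers$id)
  expect_gte(out$report$n_segratio_removed, 1)
})

test_that("VCF import applies the depth and quality thresholds", {
  vcf <- write_fixture_vcf(tempfile(fileext = ".vcf"))
  expect_message(ds <- read_genotypes(vcf, female = "mom", male = "dad"),
                 "multiallelic")
  expect_equal(nrow(ds$markers), 3)
  expect_equal(ds$markers$seg_type, c("AB_X_AA", "AA_X_AB", "other"))
  # s1: p1 good het kept; p2 het DP=2 below the het depth floor; p3 hom ok
  expect_equal(unname(ds$calls["s1", ]), c(1L, NA, 0L))
  # s2: p1 hom DP=4 below the hom floor; p2 het GQ=30 fails strict > 30;
  # p3 hom-alt is mendelian-inconsistent with a hom-ref parent
  expect_equal(unname(ds$calls["s2", ]), c(NA_integer_, NA, NA))
})

test_that("chromosome sizes TSV reader handles headers", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tlength_bp", "Chr01\t1000000", "Chr02\t2000000"), f)
  cs <- read_chrom_sizes(f)
  expect_equal(cs$length_bp, c(1e6, 2e6))
  writeLines(c("Chr01\t1000000"), f)
  expect_equal(read_chrom_sizes(f)$chrom, "Chr01")
})
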