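test_that("phase inference canonicalises counts with ties going to coupling", {
  ph <- infer_phase(c(48, 2, 3, 47))
  expect_equal(ph$phase, "coupling")
  expect_equal(ph$counts, c(48, 2, 3, 47))
  expect_false(ph$unlinked)

  ph2 <- infer_phase(c(2, 48, 47, 3))
  expect_equal(ph2$phase, "repulsion")
  expect_equal(ph2$counts, c(48, 2, 3, 47))

  ph3 <- infer_phase(c(25, 25, 25, 25))
  expect_equal(ph3$phase, "coupling")
  expect_true(ph3$unlinked)
  expect_equal(estimate_rate(ph3$counts), 0.5)

  expect_error(infer_phase(c(0, 0, 0, 0)), "zero")
})

test_that("rate MLE equals the recombinant fraction and matches the grid oracle", {
  expect_equal(estimate_rate(c(48, 2, 3, 47)), 0.05)
  expect_equal(estimate_rate(c(50, 0, 0, 50)), 0)
  expect_equal(estimate_rate(c(40, 10, 10, 40)), 0.2)
  set.seed(71)
  for (i in 1:25) {
    cnt <- infer_phase(simulate_count_table(
      sample(50:500, 1), r = runif(1, 0.01, 0.45),
      phase = sample(c("coupling", "repulsion"), 1)))$counts
    expect_lt(abs(estimate_rate(cnt) - oracle_grid_rate(cnt)), 1e-4 + 1e-12)
  }
})

test_that("rate-equality LR test reproduces closed-form worked examples", {
  same <- lr_equal_rates(c(48, 2, 3, 47), c(48, 2, 3, 47))
  expect_equal(same$lr, 0)
  expect_equal(same$p, 1)

  lt <- lr_equal_rates(c(90, 5, 5, 100), c(80, 20, 20, 80))
  expect_equal(lt$r_f, 0.05)
  expect_equal(lt$r_m, 0.2)
  expect_equal(lt$r_pooled, 0.125)
  expect_equal(lt$lr, 21.84906, tolerance = 1e-6)
  expect_equal(lt$p, 2.949607e-06, tolerance = 1e-5)

  bound <- lr_equal_rates(c(50, 0, 0, 50), c(50, 0, 0, 50))
  expect_equal(bound$lr, 0)  # 0 log 0 convention at the boundary
})

test_that("LR statistic scales linearly under count-table scaling", {
  set.seed(72)
  for (i in 1:10) {
    cf <- infer_phase(simulate_count_table(200, r = runif(1, .02, .4)))$counts
    cm <- infer_phase(simulate_count_table(300, r = runif(1, .02, .4)))$counts
    k <- sample(2:6, 1)
    expect_equal(lr_equal_rates(k * cf, k * cm)$lr,
                 k * lr_equal_rates(cf, cm)$lr, tolerance = 1e-9)
  }
})

test_that("interval scan excludes missing pairs and flags degenerate rows", {
  # two tags = four markers: f1 m1 | f2 m2; 30 progeny
  set.seed(73)
  n <- 30
  f1 <- rep(c(1L, 0L), each = n / 2)
  f2 <- f1; f2[1:2] <- 0L              # two female recombinants
  m1 <- rep(c(1L, 0L), n / 2)
  m2 <- m1; m2[5] <- 1L - m2[5]        # one male recombinant
  m2[1] <- NA                          # one progeny dropped pairwise
  calls <- rbind(f1, m1, f2, m2)
  ds <- make_dataset(calls, pos = c(1e5, 1.001e5, 3e5, 3.001e5),
                     seg_types = c("AB_X_AA", "AA_X_AB",
                                   "AB_X_AA", "AA_X_AB"))
  tags <- pair_snps_into_tags(ds)
  ints <- build_intervals(select_spaced_tags(tags))
  res <- scan_intervals(ds, ints)
  expect_equal(nrow(res), 1)
  expect_equal(res$n_f, 30)
  expect_equal(res$n_m, 29)  # pairwise-complete exclusion
  expect_equal(res$r_f, 2 / 30)
  expect_false(res$no_test)

  # all male calls missing: flagged, no test
  calls2 <- calls
  calls2[2, ] <- NA_integer_
  calls2[4, ] <- NA_integer_
  ds2 <- make_dataset(calls2, pos = c(1e5, 1.001e5, 3e5, 3.001e5),
                      seg_types = c("AB_X_AA", "AA_X_AB",
                                    "AB_X_AA", "AA_X_AB"))
  res2 <- scan_intervals(ds2, ints)
  expect_true(res2$no_test)
  expect_true(is.na(res2$p))
})

test_that("region finder groups runs and matches a brute-force scanner", {
  res <- data.frame(chrom = "Chr01",
                    left_pos = seq(1e5, by = 2e5, length.out = 4),
                    right_pos = seq(3e5, by = 2e5, length.out = 4),
                    p = c(0.04, 0.03, 0.20, 0.01))
  out <- find_significant_regions(res, alpha = 0.05)
  expect_equal(nrow(out$regions), 1)
  expect_equal(out$regions$n_intervals, 2)
  expect_equal(nrow(out$singletons), 1)
  expect_equal(out$singletons$first_row, 4)

  res$p <- c(0.5, 0.6, 0.7, 0.9)
  out2 <- find_significant_regions(res, alpha = 0.05)
  expect_null(out2$regions)
  expect_null(out2$singletons)

  res$p <- c(0.01, 0.02, 0.03, 0.8)
  out3 <- find_significant_regions(res, alpha = 0.05)
  expect_equal(out3$regions$n_intervals, 3)

  # random p sequences across chromosomes vs the brute-force run scanner
  set.seed(74)
  for (rep in 1:20) {
    k <- sample(10:60, 1)
    rr <- data.frame(chrom = sort(sample(paste0("Chr0", 1:3), k,
                                         replace = TRUE)),
                     left_pos = 1, right_pos = 2,
                     p = round(runif(k), 2))
    got <- find_significant_regions(rr, alpha = 0.3)
    runs <- oracle_region_runs(rr$chrom, rr$p, 0.3)
    expect_equal(sum(got$regions$n_intervals %||% 0) +
                   nrow(got$singletons %||% data.frame()),
                 sum(runs$len))
    expect_equal(nrow(got$regions %||% data.frame()),
                 sum(runs$len >= 2))
  }
})

test_that("paired rank test on chromosome means has the exact tail", {
  set.seed(75)
  # 19 chromosomes, every female mean above the male mean
  mk <- function(i, rf, rm) data.frame(
    chrom = sprintf("Chr%02d", i), left_pos = 1, right_pos = 2,
    r_f = rf, r_m = rm, p = 0.5)
  res <- do.call(rbind, lapply(1:19, function(i)
    mk(i, 0.05 + i / 1000 + 0.02, 0.05 + runif(1, 0, 0.01))))
  cmp <- compare_rates(res, level = "chromosome")
  expect_equal(cmp$test$p.value, 2 / 2^19, tolerance = 1e-9)
  expect_equal(nrow(cmp$summary), 19)

  # identical vectors: degenerate, p = 1
  res2 <- do.call(rbind, lapply(1:3, function(i) mk(i, 0.05, 0.05)))
  expect_warning(cmp2 <- compare_rates(res2, level = "chromosome"),
                 "zero")
  expect_equal(cmp2$test$p.value, 1)

  expect_error(compare_rates(mk(1, .1, .2), level = "chromosome"),
               ">= 2 chromosomes")
})

test_that("rate estimates are unbiased on simulated intervals", {
  set.seed(76)
  r_hats <- replicate(400, {
    cnt <- infer_phase(simulate_count_table(250, r = 0.08,
                                            phase = sample(c("coupling",
                                                             "repulsion"),
                                                           1)))$counts
    estimate_rate(cnt)
  })
  expect_lt(abs(mean(r_hats) - 0.08), 0.005)
})
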