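test_that("three-point class tabulation uses the canonical ordering", {
  a <- c(1L, 1L, 0L, 0L, NA)
  b <- c(1L, 0L, 1L, 0L, 1L)
  c_ <- c(1L, 0L, 0L, 1L, 1L)
  # (H,H,H)=1, (H,O,O)=4, (O,H,O)=6, (O,O,H)=7; NA progeny dropped
  expect_equal(three_point_counts(a, b, c_),
               c(1L, 0L, 0L, 1L, 0L, 1L, 1L, 0L))
})

test_that("CoC MLEs reproduce the closed-form worked examples", {
  e1 <- estimate_coc(c(36, 4, 1, 9, 9, 1, 4, 36))
  expect_equal(e1$r1_hat, 0.2)
  expect_equal(e1$r2_hat, 0.1)
  expect_equal(e1$coc_hat, 1)

  e2 <- estimate_coc(c(30, 2, 4, 10, 8, 4, 2, 40))
  expect_equal(e2$r1_hat, 0.26)
  expect_equal(e2$r2_hat, 0.12)
  expect_equal(e2$coc_hat, 8 / 3.12, tolerance = 1e-12)

  e3 <- estimate_coc(c(40, 6, 0, 12, 12, 0, 6, 24))
  expect_equal(e3$r1_hat, 0.24)
  expect_equal(e3$r2_hat, 0.12)
  expect_equal(e3$coc_hat, 0)

  # a zero marginal rate leaves the CoC undefined
  e4 <- estimate_coc(c(50, 0, 0, 0, 0, 0, 0, 50))
  expect_true(is.na(e4$coc_hat))
})

test_that("interference LR test matches the numeric-maximization oracle", {
  ind <- lr_interference(c(36, 4, 1, 9, 9, 1, 4, 36))
  expect_equal(ind$lr, 0)
  expect_equal(ind$p, 1)
  expect_equal(ind$direction, "none")

  neg <- lr_interference(c(30, 2, 4, 10, 8, 4, 2, 40))
  expect_equal(neg$lr, 10.16648, tolerance = 1e-5)
  expect_equal(neg$p, 0.00143017, tolerance = 1e-4)
  expect_equal(neg$direction, "negative")

  pos <- lr_interference(c(40, 6, 0, 12, 12, 0, 6, 24))
  expect_equal(pos$coc_hat, 0)
  expect_gt(pos$lr, 0)
  expect_equal(pos$direction, "positive")

  set.seed(81)
  for (i in 1:30) {
    tb <- random_three_point_table()
    ph <- resolve_phase_case(tb$counts)
    if (ph$ambiguous) next
    est <- estimate_coc(ph$counts)
    if (is.na(est$coc_hat)) next
    num <- oracle_numeric_coc(ph$counts)
    expect_lt(max(abs(c(est$r1_hat, est$r2_hat, est$coc_hat) - num)), 1e-4)
    lt <- lr_interference(ph$counts)
    expect_gte(lt$lr, 0)
    # implied class frequencies at the MLE sum to 1 and stay in [0, 1]
    pr <- radxo:::three_point_probs(est$r1_hat, est$r2_hat, est$coc_hat)
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    expect_true(all(pr >= 0 & pr <= 1))
  }
})

test_that("phase cases map to the documented single-marker relabellings", {
  set.seed(82)
  base <- simulate_count_table(800, r1 = 0.2, r2 = 0.15, coc = 1.3)
  cc <- resolve_phase_case(base)
  expect_equal(cc$phase_case, 1)
  expect_equal(cc$counts, base)  # identity permutation

  perm <- function(cnt, flip) radxo:::permute_counts(cnt, flip)
  # repulsion in pair 1-2 (marker 1 relabelled): classes 1<->5, 2<->6, ...
  rc <- resolve_phase_case(perm(base, c(TRUE, FALSE, FALSE)))
  expect_equal(rc$phase_case, 2)
  expect_equal(rc$counts, base)
  # repulsion in pair 2-3 only
  cr <- resolve_phase_case(perm(base, c(FALSE, FALSE, TRUE)))
  expect_equal(cr$phase_case, 3)
  expect_equal(cr$counts, base)
  # both pairs repulsion (marker 2 relabelled): classes 1<->3, 2<->4, ...
  rr <- resolve_phase_case(perm(base, c(FALSE, TRUE, FALSE)))
  expect_equal(rr$phase_case, 4)
  expect_equal(rr$counts, base)
  expect_equal(perm(base, c(FALSE, TRUE, FALSE)),
               base[c(3, 4, 1, 2, 7, 8, 5, 6)])
})

test_that("estimates are invariant to any single-marker relabelling", {
  set.seed(83)
  for (i in 1:20) {
    tb <- random_three_point_table(c(200, 900))
    ref <- lr_interference(resolve_phase_case(tb$counts)$counts)
    flip <- sample(c(TRUE, FALSE), 3, replace = TRUE)
    obs <- radxo:::permute_counts(tb$counts, flip)
    got <- lr_interference(resolve_phase_case(obs)$counts)
    expect_identical(got$r1_hat, ref$r1_hat)
    expect_identical(got$r2_hat, ref$r2_hat)
    expect_identical(got$coc_hat, ref$coc_hat)
    expect_identical(got$lr, ref$lr)
  }
})

test_that("canonicalised counts maximise the coupling likelihood", {
  set.seed(84)
  flips <- list(c(FALSE, FALSE, FALSE), c(TRUE, FALSE, FALSE),
                c(FALSE, TRUE, FALSE), c(FALSE, FALSE, TRUE))
  for (i in 1:10) {
    tb <- random_three_point_table(c(300, 900))
    obs <- radxo:::permute_counts(tb$counts,
                                  sample(c(TRUE, FALSE), 3, replace = TRUE))
    chosen <- resolve_phase_case(obs)$counts
    ll_at_mle <- function(cnt) {
      e <- estimate_coc(cnt)
      if (is.na(e$coc_hat)) return(-Inf)
      oracle_ll3(cnt, e$r1_hat, e$r2_hat, e$coc_hat)
    }
    best <- max(vapply(flips, function(f)
      ll_at_mle(radxo:::permute_counts(obs, f)), numeric(1)))
    expect_equal(ll_at_mle(chosen), best, tolerance = 1e-9)
  }
})

test_that("MIL chaining is greedy with overlap-by-one triples", {
  pos <- c(0, 0.3, 0.6, 1.2, 1.8) * 1e6
  out <- select_mil_triples(pos, 0.5e6)
  expect_equal(out$chain, c(1L, 3L, 4L, 5L))
  expect_equal(nrow(out$triples), 2)
  expect_equal(out$triples[1, ], c(1L, 3L, 4L))
  expect_equal(out$triples[2, ], c(3L, 4L, 5L))

  expect_equal(nrow(select_mil_triples(c(1e5, 9e5), 5e5)$triples), 0)
  expect_equal(nrow(select_mil_triples(pos, 6e6)$triples), 0)
})

test_that("MIL scan recovers simulated interference directions", {
  chroms <- data.frame(name = c("Chr01", "Chr02"), length_bp = 2e7,
                       length_morgan = 3)
  cfg <- sim_config(n_progeny = 220, chromosomes = chroms,
                    nu_female = 0.3, nu_male = 1,
                    tag_spacing_bp = 5e5, missing_rate = 0, seed = 85)
  sim <- simulate_population(cfg)
  scan <- mil_scan(sim$dataset, mils = 0.5e6)
  s <- scan$summary
  fem <- s[s$parent == "female", ]
  expect_gt(fem$n_sig, 0)
  expect_gt(fem$n_coc_gt1, fem$n_coc_lt1)  # nu < 1: negative interference
  expect_true(all(!is.na(scan$triples$coc_hat)))
  expect_true(all(scan$triples$pos3 > scan$triples$pos1))
  # per-triple spans respect the MIL
  expect_true(all(scan$triples$pos2 - scan$triples$pos1 >= 0.5e6))
  expect_true(all(scan$triples$pos3 - scan$triples$pos2 >= 0.5e6))
})

test_that("an empty marker set yields an all-zero scan summary", {
  ds <- make_dataset(matrix(0L, 2, 4), seg_types = c("other", "other"))
  scan <- mil_scan(ds, chrom_sizes = data.frame(chrom = "Chr01",
                                                length_bp = 1e7),
                   mils = c(0.5e6, 1e6))
  expect_null(scan$triples)
  expect_true(all(scan$summary$n_pairs == 0))
  expect_true(all(scan$summary$coverage == 0))
})
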