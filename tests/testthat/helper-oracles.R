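`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent oracles used across tests: brute-force maximization of the
# multinomial likelihoods, checked against the closed-form estimators.

# two-point log-likelihood kernel under coupling (constants dropped)
oracle_ll2 <- function(counts, r) {
  par <- counts[1] + counts[4]
  rec <- counts[2] + counts[3]
  (if (par == 0) 0 else par * log(1 - r)) +
    (if (rec == 0) 0 else rec * log(r))
}

# two-point log-likelihood evaluated over a grid vector (0 log 0 := 0)
oracle_ll2_grid <- function(counts, grid) {
  par <- counts[1] + counts[4]
  rec <- counts[2] + counts[3]
  ll <- (if (par == 0) 0 else par * log(1 - grid)) +
    (if (rec == 0) 0 else rec * log(grid))
  ll[!is.finite(ll)] <- -1e300
  ll
}

# grid argmax of the two-point likelihood at step 1e-4
oracle_grid_rate <- function(counts, step = 1e-4) {
  grid <- seq(0, 0.5, by = step)
  grid[which.max(oracle_ll2_grid(counts, grid))]
}

# grid argmax of the pooled (null) two-point likelihood
oracle_grid_pooled <- function(counts_f, counts_m, step = 1e-4) {
  grid <- seq(0, 0.5, by = step)
  grid[which.max(oracle_ll2_grid(counts_f, grid) +
                   oracle_ll2_grid(counts_m, grid))]
}

# three-point log-likelihood kernel (coupling-coupling, constants dropped)
oracle_ll3 <- function(counts, r1, r2, coc) {
  p11 <- r1 * r2 * coc
  pr <- c(1 - r1 - r2 + p11, r2 - p11, r1 - p11, p11)
  grp <- c(counts[1] + counts[8], counts[2] + counts[7],
           counts[4] + counts[5], counts[3] + counts[6])
  sum(ifelse(grp == 0, 0, grp * log(pmax(pr, 1e-300))))
}

# numeric maximization of the three-point likelihood over (r1, r2, C):
# smooth logit reparameterization (feasible by construction) plus
# restarted Nelder-Mead
oracle_numeric_coc <- function(counts) {
  tomodel <- function(th) {
    r1 <- 0.5 * stats::plogis(th[1])
    r2 <- 0.5 * stats::plogis(th[2])
    # feasibility: p01, p10 >= 0 bound C above by 1/r1 and 1/r2; with
    # r1 + r2 < 1 the p00 >= 0 constraint is never active
    cmax <- min(1 / r1, 1 / r2)
    c(r1, r2, cmax * stats::plogis(th[3]))
  }
  obj <- function(th) {
    p <- tomodel(th)
    -oracle_ll3(counts, p[1], p[2], p[3])
  }
  th <- c(0, 0, 0)
  for (k in 1:4)
    th <- stats::optim(th, obj, method = "Nelder-Mead",
                       control = list(maxit = 3000, reltol = 1e-15))$par
  p <- tomodel(th)
  names(p) <- c("r1", "r2", "coc")
  p
}

# brute-force run scanner for significant regions: for each maximal run of
# consecutive p < alpha rows within a chromosome, report its length
oracle_region_runs <- function(chrom, p, alpha) {
  out <- list()
  for (ch in unique(chrom)) {
    s <- p[chrom == ch] < alpha
    i <- 1
    while (i <= length(s)) {
      if (s[i]) {
        j <- i
        while (j < length(s) && s[j + 1]) j <- j + 1
        out[[length(out) + 1]] <- data.frame(chrom = ch, len = j - i + 1)
        i <- j + 1
      } else i <- i + 1
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(chrom = character(), len = integer())
}

# draw a random valid (r1, r2, C) triple and a multinomial table from it
random_three_point_table <- function(n_range = c(100, 2000)) {
  r1 <- stats::runif(1, 0.02, 0.45)
  r2 <- stats::runif(1, 0.02, 0.45)
  cmax <- min(1 / r1, 1 / r2, (1 - r1 - r2) / (r1 * r2) + 1)
  coc <- stats::runif(1, 0.05, min(cmax * 0.95, 3))
  n <- sample(seq(n_range[1], n_range[2]), 1)
  list(r1 = r1, r2 = r2, coc = coc, n = n,
       counts = simulate_count_table(n, r1 = r1, r2 = r2, coc = coc))
}
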