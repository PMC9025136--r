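## Stationary gamma-renewal model of chiasma formation.
##
## Chiasmata on the four-strand bundle form a stationary renewal process on
## the genetic scale, with inter-chiasma distances ~ Gamma(shape = nu,
## rate = 2 nu) Morgans (mean 1/2, i.e. two chiasmata per Morgan on the
## bundle).  Each chiasma involves a given chromatid with probability 1/2,
## independently, so a transmitted chromatid sees on average one crossover
## per Morgan.  nu = 1 gives a Poisson process (no interference); nu > 1 a
## more regular process (positive interference); nu < 1 a clustered one
## (negative interference).

#' Equilibrium (stationary residual) CDF of the chiasma process
#'
#' Distribution of the distance from an arbitrary genome position to the next
#' chiasma when the gamma-renewal chiasma process is in equilibrium.  For a
#' renewal process with inter-arrival CDF `F` and mean `mu`, the residual CDF
#' is `(1/mu) * integral_0^x (1 - F(u)) du`; for Gamma(nu, 2*nu) this reduces
#' to `2*x*(1 - pgamma(x, nu, 2*nu)) + pgamma(x, nu + 1, 2*nu)`.
#'
#' @param x Distance in Morgans (vectorised, >= 0).
#' @param nu Interference strength (gamma shape), > 0.
#' @return `P(next chiasma within x)`, in \[0, 1\].
#' @keywords internal
stationary_gamma_cdf <- function(x, nu) {
  stopifnot(is.numeric(x), length(nu) == 1L, is.finite(nu), nu > 0)
  out <- numeric(length(x))
  pos <- !is.na(x) & x > 0
  xp <- x[pos]
  out[pos] <- 2 * xp * stats::pgamma(xp, shape = nu, rate = 2 * nu,
                                     lower.tail = FALSE) +
    stats::pgamma(xp, shape = nu + 1, rate = 2 * nu)
  out[is.na(x)] <- NA_real_
  pmin(out, 1)
}

## Draw the distance to the first chiasma under stationarity (inverse CDF by
## root-finding; exact up to uniroot tolerance).
rstationary_first <- function(n, nu) {
  u <- stats::runif(n)
  ## generous bracket: residual distribution has mean (nu+1)/(4 nu) <= ~5.25
  ## for nu >= 0.05; expand upper bound until it covers the quantile
  vapply(u, function(ui) {
    hi <- 2
    while (stationary_gamma_cdf(hi, nu) < ui) hi <- hi * 2
    stats::uniroot(function(x) stationary_gamma_cdf(x, nu) - ui,
                   lower = 0, upper = hi, tol = 1e-10)$root
  }, numeric(1))
}

#' Simulate crossover positions on one transmitted chromatid
#'
#' Draws chiasma positions on (0, L) from the stationary gamma-renewal
#' process (inter-chiasma distances Gamma(nu, 2*nu) Morgans; first chiasma
#' from the equilibrium residual distribution), then keeps each chiasma on
#' the observed chromatid independently with probability 1/2.
#'
#' @param genetic_length Chromosome genetic length L in Morgans, > 0.
#' @param nu Interference strength, > 0.  `nu = 1` reduces to a homogeneous
#'   Poisson process of rate 1 crossover per Morgan on the chromatid.
#' @return Strictly increasing numeric vector of crossover positions in
#'   Morgans (possibly empty).
#' @examples
#' set.seed(1)
#' simulate_chromatid_crossovers(2, nu = 1)
#' @export
simulate_chromatid_crossovers <- function(genetic_length, nu) {
  if (!is.numeric(genetic_length) || length(genetic_length) != 1L ||
      !is.finite(genetic_length) || genetic_length <= 0) {
    stop("`genetic_length` must be a single positive number (Morgans)")
  }
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) || nu <= 0) {
    stop("`nu` must be a single positive number")
  }
  pos <- rstationary_first(1L, nu)
  if (pos >= genetic_length) return(numeric(0))
  xs <- pos
  ## mean inter-chiasma distance is 1/2, draw increments in blocks
  while (pos < genetic_length) {
    k <- max(8L, ceiling(2.5 * (genetic_length - pos)))
    inc <- stats::rgamma(k, shape = nu, rate = 2 * nu)
    pts <- pos + cumsum(inc)
    xs <- c(xs, pts[pts < genetic_length])
    pos <- pts[k]
  }
  xs <- xs[xs < genetic_length]
  xs[stats::runif(length(xs)) < 0.5]
}

#' Model-implied recombination fraction over a genetic interval
#'
#' Under the thinned stationary gamma-renewal model the transmitted chromatid
#' shows an odd crossover count in an interval of genetic length `d` with
#' probability `F_e(d)/2`, where `F_e` is the equilibrium chiasma CDF
#' ([stationary_gamma_cdf()]): given at least one chiasma, the thinned count
#' is odd with probability exactly 1/2.  For `nu = 1` this is Haldane's
#' `(1 - exp(-2 d)) / 2`.
#'
#' @param d Genetic interval length(s) in Morgans.
#' @param nu Interference strength, > 0.
#' @return Recombination fraction(s) in \[0, 0.5\].
#' @export
gamma_model_rf <- function(d, nu) {
  stationary_gamma_cdf(d, nu) / 2
}

#' Model-implied coefficient of coincidence for two adjacent intervals
#'
#' The chromatid shows a crossover (odd thinned count) in both of two
#' adjacent intervals with probability `P(k1 >= 1, k2 >= 1) / 4` where the
#' `k` are chiasma counts, giving
#' `CoC = (F_e(d1) + F_e(d2) - F_e(d1 + d2)) / (F_e(d1) * F_e(d2))`.
#' Equals 1 for every `d1, d2` when `nu = 1`.
#'
#' @param d1,d2 Genetic lengths (Morgans) of the two adjacent intervals.
#' @param nu Interference strength, > 0.
#' @return CoC value(s) >= 0.
#' @export
gamma_model_coc <- function(d1, d2, nu) {
  f1 <- stationary_gamma_cdf(d1, nu)
  f2 <- stationary_gamma_cdf(d2, nu)
  f12 <- stationary_gamma_cdf(d1 + d2, nu)
  (f1 + f2 - f12) / (f1 * f2)
}
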