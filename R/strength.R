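## Interference strength from reconstructed crossover events.  Crossovers on
## a transmitted chromatid are modelled as a stationary gamma-renewal
## chiasma process (inter-chiasma distances Gamma(nu, 2 nu) Morgans) thinned
## by 1/2; nu = 1 is no interference, nu > 1 positive, nu < 1 negative.
## Because each chiasma is observed independently with probability 1/2, the
## distance between consecutive observed crossovers is a 2^-k-weighted
## mixture of Gamma(k nu, 2 nu) convolutions, and the terms at the
## chromosome ends use the stationary residual / censoring forms.  All terms
## are closed-form in the gamma CDF.

MAX_SKIP <- 27L  # truncate the 2^-k mixture once the weight drops below 1e-8

## mixture densities/tails for the thinned stationary renewal process;
## all arguments in Morgans, vectorised over x
thinned_terms <- function(nu) {
  k <- seq_len(MAX_SKIP)
  w <- 0.5^k
  list(
    ## density of the distance between consecutive observed COs
    f_gap = function(x) {
      s <- 0
      for (i in k) s <- s + w[i] * stats::dgamma(x, shape = i * nu,
                                                 rate = 2 * nu)
      s
    },
    ## density of the first observed CO from the chromosome start
    ## (stationary k-th arrival density: 2 * (F_(k-1)nu - F_knu))
    f_first = function(x) {
      s <- 0
      for (i in k) {
        lo <- if (i == 1L) 1
              else stats::pgamma(x, shape = (i - 1L) * nu, rate = 2 * nu)
        s <- s + w[i] * 2 * (lo - stats::pgamma(x, shape = i * nu,
                                                rate = 2 * nu))
      }
      s
    },
    ## P(no further observed CO within distance t of the last one)
    s_gap = function(t) {
      s <- 1
      for (i in k) s <- s - w[i] * stats::pgamma(t, shape = i * nu,
                                                 rate = 2 * nu)
      pmax(s, 0)
    },
    ## P(no observed CO at all on a chromosome of length L)
    p_none = function(L) {
      ## integral of F_a over (0, L): L F_a(L) - (a / rate) F_(a+1)(L)
      intF <- function(a) {
        if (a == 0) return(L)
        L * stats::pgamma(L, shape = a, rate = 2 * nu) -
          a / (2 * nu) * stats::pgamma(L, shape = a + 1, rate = 2 * nu)
      }
      s <- 1
      for (i in k)
        s <- s - w[i] * 2 * (intF((i - 1L) * nu) - intF(i * nu))
      max(s, .Machine$double.xmin)
    })
}

#' Fit the gamma interference-strength parameter to crossover events
#'
#' Maximises, over `nu` in `[0.05, 20]`, the likelihood of the observed
#' crossover locations per meiosis under the thinned stationary
#' gamma-renewal model.  Meioses with no crossover contribute the
#' no-event (censoring) probability.
#'
#' @param events List with one numeric vector per meiosis: crossover
#'   positions in Morgans within `(0, genetic_length)` (empty vectors
#'   allowed).
#' @param genetic_length Chromosome genetic length in Morgans, > 0.
#' @return Object of class `gamma_fit`: `nu_hat`, `se`, `ci` (Wald 95%),
#'   `loglik`, `loglik_nu1`, `n_meioses`, `n_events`, `boundary` (`TRUE`
#'   when the optimiser hit a bound).  `NULL` (with a message) when there
#'   are no events at all, in which case `nu` is unidentifiable.
#' @examples
#' set.seed(1)
#' ev <- replicate(200, simulate_chromatid_crossovers(2, nu = 1),
#'                 simplify = FALSE)
#' fit_gamma_nu(ev, 2)
#' @export
fit_gamma_nu <- function(events, genetic_length) {
  stopifnot(is.list(events), length(events) >= 1L,
            is.numeric(genetic_length), genetic_length > 0)
  L <- genetic_length
  events <- lapply(events, sort)
  if (any(unlist(events) <= 0 | unlist(events) >= L))
    stop("crossover positions must lie strictly inside (0, genetic_length)")
  n_ev <- vapply(events, length, integer(1))
  if (sum(n_ev) == 0L) {
    message("no crossover events: nu unidentifiable, fit skipped")
    return(NULL)
  }
  firsts <- vapply(events[n_ev > 0L], `[`, numeric(1), 1L)
  lasts <- L - vapply(events[n_ev > 0L], function(x) x[length(x)],
                      numeric(1))
  gaps <- unlist(lapply(events[n_ev > 1L], diff))
  n0 <- sum(n_ev == 0L)

  negll <- function(nu) {
    tm <- thinned_terms(nu)
    ll <- sum(log(tm$f_first(firsts))) + sum(log(tm$s_gap(lasts))) +
      n0 * log(tm$p_none(L))
    if (length(gaps)) ll <- ll + sum(log(tm$f_gap(gaps)))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  opt <- stats::optimize(negll, interval = c(0.05, 20), tol = 1e-6)
  nu_hat <- opt$minimum
  ll_hat <- -opt$objective
  ll_1 <- -negll(1)
  if (ll_1 > ll_hat) {  # optimiser tolerance safeguard
    nu_hat <- 1
    ll_hat <- ll_1
  }
  boundary <- nu_hat < 0.05 + 1e-3 || nu_hat > 20 - 1e-2
  ## observed-information SE by central second difference
  h <- 1e-3 * nu_hat
  d2 <- (negll(nu_hat + h) - 2 * negll(nu_hat) + negll(nu_hat - h)) / h^2
  se <- if (is.finite(d2) && d2 > 0) 1 / sqrt(d2) else NA_real_
  structure(list(nu_hat = nu_hat, se = se,
                 ci = c(nu_hat - 1.96 * se, nu_hat + 1.96 * se),
                 loglik = ll_hat, loglik_nu1 = ll_1,
                 n_meioses = length(events), n_events = sum(n_ev),
                 boundary = boundary),
            class = "gamma_fit")
}

#' @exportS3Method base::print
print.gamma_fit <- function(x, ...) {
  cat(sprintf(
    "gamma_fit: nu_hat = %.3f (se %.3f), %d events / %d meioses%s\n",
    x$nu_hat, x$se, x$n_events, x$n_meioses,
    if (x$boundary) " [at bound]" else ""))
  invisible(x)
}

#' Call crossover events from a transmitted-allele signal
#'
#' One event per sign change between consecutive non-missing markers;
#' missing markers are skipped, so an event next to missing data is
#' localised to the wider bracket.  The event is placed at the bracket
#' midpoint.
#'
#' @param alleles 0/1 vector of phase-canonicalised transmitted alleles
#'   (`NA` = missing).
#' @param positions Marker positions (same length; any monotone scale).
#' @return Data frame with `left`, `right`, `mid` per event (0 rows when
#'   fewer than 2 markers are non-missing).
#' @examples
#' call_crossovers(c(0, 0, 0, 1, 1), 1:5)         # one event at 3.5
#' call_crossovers(c(0, NA, 1), c(1, 2, 3))       # bracketed (1, 3)
#' @export
call_crossovers <- function(alleles, positions) {
  stopifnot(length(alleles) == length(positions),
            !is.unsorted(positions))
  ok <- !is.na(alleles)
  a <- alleles[ok]; p <- positions[ok]
  if (length(a) < 2L)
    return(data.frame(left = numeric(0), right = numeric(0),
                      mid = numeric(0)))
  sw <- which(diff(a) != 0L)
  data.frame(left = p[sw], right = p[sw + 1L],
             mid = (p[sw] + p[sw + 1L]) / 2)
}

#' Cumulative genetic positions from adjacent recombination fractions
#'
#' Marker `k` is placed at the running sum of the adjacent-interval
#' `r_hat` values (small-interval additive approximation; intervals at the
#' tag spacing used here are short enough that mapping-function corrections
#' are negligible).
#'
#' @param r_adjacent Adjacent-interval recombination fractions, each in
#'   \[0, 0.5\]; an interval at exactly 0.5 is genetically unbounded and
#'   triggers a warning.
#' @return Numeric vector of marker positions in Morgans (first marker at
#'   0), length `length(r_adjacent) + 1`.
#' @examples
#' genetic_scale(c(0.05, 0.05, 0.10))  # 0, 0.05, 0.10, 0.20
#' @export
genetic_scale <- function(r_adjacent) {
  stopifnot(all(r_adjacent >= 0), all(r_adjacent <= 0.5))
  if (any(r_adjacent == 0.5))
    warning("interval with r_hat = 0.5: genetic distance unbounded, ",
            "position capped at 0.5 Morgans")
  c(0, cumsum(r_adjacent))
}

## chain-canonicalise one parent's markers on one chromosome: flip het/hom
## per marker so adjacent pairs are all in coupling; returns flipped calls
## and the adjacent r_hat vector
canonicalize_chromosome <- function(calls) {
  k <- nrow(calls)
  flip <- integer(k)
  r_adj <- numeric(k - 1L)
  for (j in seq_len(k - 1L)) {
    cnt <- two_point_counts(abs(calls[j, ] - flip[j]), calls[j + 1L, ])
    if (sum(cnt) == 0L) {
      flip[j + 1L] <- flip[j]
      r_adj[j] <- NA_real_
      next
    }
    ph <- infer_phase(cnt)
    ## pair compared flipped-j against raw-(j+1), so the flip for j+1 is
    ## simply whether that pair is in repulsion
    flip[j + 1L] <- as.integer(ph$phase == "repulsion")
    r_adj[j] <- estimate_rate(ph$counts)
  }
  flipped <- abs(calls - flip)  # row-wise flip via recycling over columns
  list(calls = flipped, r_adj = r_adj, flip = flip)
}

#' Reconstruct crossovers and fit interference strength per chromosome
#'
#' For each parent and chromosome: that parent's informative SNPs (tag SNPs
#' when `tags` is given) are phase-canonicalised by chaining two-point phase
#' inference along the chromosome; adjacent `r_hat` values build the
#' genetic scale; crossovers are called per progeny as transmitted-allele
#' sign changes and placed at genetic bracket midpoints; and
#' [fit_gamma_nu()] is fitted to the per-meiosis event lists.
#'
#' @param dataset A filtered [genotype_dataset()].
#' @param tags Optional tag data frame; restricts markers to tag SNPs.
#' @param min_markers Minimum informative markers per chromosome (default 3).
#' @param event_placement Genetic position given to each event for the fit:
#'   `"uniform"` (default) draws it uniformly within the flanking-marker
#'   bracket, which avoids the spurious regularity (inflated `nu_hat`) that
#'   deterministic midpoint placement induces by forbidding short
#'   inter-event distances; `"midpoint"` uses the bracket midpoint.
#'   Reproducible given the session RNG seed.
#' @return List: `fits` (data frame per parent x chromosome with `nu_hat`,
#'   `se`, `n_meioses`, `n_events`, `loglik`, `boundary`, `genetic_length`)
#'   and `events` (data frame of all called events with genetic and
#'   physical midpoints).
#' @export
estimate_interference_strength <- function(dataset, tags = NULL,
                                           min_markers = 3L,
                                           event_placement = c("uniform",
                                                               "midpoint")) {
  event_placement <- match.arg(event_placement)
  stopifnot(inherits(dataset, "genotype_dataset"))
  m <- dataset$markers
  if (!is.null(tags)) m <- m[m$id %in% c(tags$id_f, tags$id_m), ,
                             drop = FALSE]
  fits <- list(); events_out <- list()
  for (parent in c("female", "male")) {
    seg <- if (parent == "female") "AB_X_AA" else "AA_X_AB"
    for (chrom in unique(m$chrom)) {
      mm <- m[m$chrom == chrom & m$seg_type == seg, , drop = FALSE]
      mm <- mm[order(mm$pos), , drop = FALSE]
      if (nrow(mm) < min_markers) next
      calls <- dataset$calls[mm$id, , drop = FALSE]
      canon <- canonicalize_chromosome(calls)
      r_adj <- canon$r_adj
      if (anyNA(r_adj)) next
      gpos <- genetic_scale(pmin(r_adj, 0.4999))
      L <- gpos[length(gpos)]
      if (L <= 0) next
      ev <- vector("list", ncol(calls))
      for (i in seq_len(ncol(calls))) {
        al <- canon$calls[, i]
        if (sum(!is.na(al)) < 2L) { ev[[i]] <- NA; next }
        evg <- call_crossovers(al, gpos)
        evb <- call_crossovers(al, mm$pos)
        ev[[i]] <- if (event_placement == "uniform" && nrow(evg))
          sort(stats::runif(nrow(evg), evg$left, evg$right)) else evg$mid
        if (nrow(evg))
          events_out[[length(events_out) + 1L]] <- data.frame(
            progeny = colnames(calls)[i], parent = parent, chrom = chrom,
            mid_morgan = evg$mid, left_bp = evb$left, right_bp = evb$right,
            mid_bp = evb$mid)
      }
      ev <- ev[!vapply(ev, function(x) length(x) == 1L && all(is.na(x)),
                       logical(1))]
      if (length(ev) == 0L) next
      ## keep events strictly inside (0, L) for the renewal likelihood
      ev <- lapply(ev, function(x) x[x > 1e-9 & x < L - 1e-9])
      fit <- fit_gamma_nu(ev, L)
      if (is.null(fit)) next
      fits[[length(fits) + 1L]] <- data.frame(
        parent = parent, chrom = chrom, nu_hat = fit$nu_hat, se = fit$se,
        n_meioses = fit$n_meioses, n_events = fit$n_events,
        loglik = fit$loglik, boundary = fit$boundary, genetic_length = L)
    }
  }
  list(fits = if (length(fits)) do.call(rbind, fits) else NULL,
       events = if (length(events_out)) do.call(rbind, events_out)
                else NULL)
}

#' Paired t test comparing per-chromosome interference strengths
#'
#' @param nu_f,nu_m Equal-length vectors of per-chromosome `nu_hat` for the
#'   female and male parent (>= 2 chromosomes).
#' @return List: `mean_f`, `mean_m`, `t`, `df`, `p` (two-sided paired t).
#'   A zero-variance difference vector is handled in closed form with a
#'   warning (t = 0 and p = 1 when identical, |t| = Inf and p = 0 for a
#'   constant non-zero difference).
#' @examples
#' compare_strength(c(0.5, 0.55, 0.6), c(0.6, 0.66, 0.72))
#' @export
compare_strength <- function(nu_f, nu_m) {
  stopifnot(length(nu_f) == length(nu_m), length(nu_f) >= 2L,
            all(is.finite(nu_f)), all(is.finite(nu_m)))
  d <- nu_f - nu_m
  if (stats::sd(d) == 0) {
    warning("zero variance of paired differences: degenerate t test")
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(list(mean_f = mean(nu_f), mean_m = mean(nu_m), t = t_stat,
                df = length(d) - 1L,
                p = if (mean(d) == 0) 1 else 0))
  }
  tt <- stats::t.test(nu_f, nu_m, paired = TRUE)
  list(mean_f = mean(nu_f), mean_m = mean(nu_m),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}
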