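## Two-point pseudo-testcross analysis: linkage-phase inference, sex-specific
## crossover-rate MLEs and the likelihood-ratio test of female = male rate
## per interval.
##
## For two same-type SNPs the progeny fall in four classes, ordered
## (het,het), (het,hom), (hom,het), (hom,hom) with counts n1..n4.  Under
## coupling the multinomial class probabilities are ((1-r)/2, r/2, r/2,
## (1-r)/2); repulsion is the same model with classes 1<->2 and 3<->4
## swapped.  The rate MLE under coupling is r_hat = (n2 + n3) / n.

#' Tabulate two-point genotype-class counts
#'
#' @param a,b Call vectors at the two SNPs (1 = het, 0 = hom, `NA`
#'   missing); progeny missing at either SNP are dropped pairwise.
#' @return Integer vector `c(n11, n12, n13, n14)` in canonical class order.
#' @export
two_point_counts <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  c(sum(a == 1L & b == 1L), sum(a == 1L & b == 0L),
    sum(a == 0L & b == 1L), sum(a == 0L & b == 0L))
}

#' Infer the linkage phase of a two-point count table
#'
#' Coupling if the would-be recombinant classes (2, 3) are the minority —
#' equivalently, maximum likelihood over the two phases; ties go to
#' coupling.  Under repulsion the classes are relabelled (1<->2, 3<->4) so
#' the canonical counts satisfy the coupling likelihood with `r_hat <= 0.5`.
#'
#' @param counts Integer vector `c(n11, n12, n13, n14)`.
#' @return List: `phase` (`"coupling"`/`"repulsion"`), `counts` (canonical),
#'   `unlinked` (`TRUE` when `r_hat = 0.5`).
#' @examples
#' infer_phase(c(48, 2, 3, 47))   # coupling, unchanged
#' infer_phase(c(2, 48, 47, 3))   # repulsion, canonical c(48, 2, 3, 47)
#' @export
infer_phase <- function(counts) {
  stopifnot(length(counts) == 4L, all(counts >= 0))
  n <- sum(counts)
  if (n == 0L) stop("phase undefined: zero informative progeny")
  rec <- (counts[2L] + counts[3L]) / n
  if (rec <= 0.5) {
    list(phase = "coupling", counts = counts, unlinked = rec == 0.5)
  } else {
    list(phase = "repulsion", counts = counts[c(2L, 1L, 4L, 3L)],
         unlinked = FALSE)
  }
}

#' Crossover-rate MLE from canonical two-point counts
#'
#' @param counts Phase-canonicalised counts (see [infer_phase()]).
#' @return `r_hat = (n12 + n13) / n`, in \[0, 0.5\].
#' @examples
#' estimate_rate(c(48, 2, 3, 47))  # 0.05
#' @export
estimate_rate <- function(counts) {
  stopifnot(length(counts) == 4L, all(counts >= 0), sum(counts) > 0)
  (counts[2L] + counts[3L]) / sum(counts)
}

## multinomial two-point log-likelihood kernel (constants dropped),
## with 0*log(0) := 0
ll_two_point <- function(counts, r) {
  par <- counts[1L] + counts[4L]
  rec <- counts[2L] + counts[3L]
  xlogy(par, 1 - r) + xlogy(rec, r)
}

xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))

#' Likelihood-ratio test for equal female and male crossover rates
#'
#' Full model: separate rates `r_f`, `r_m` (MLEs from [estimate_rate()]).
#' Null: a common rate with pooled MLE
#' `(n12 + n13 + n22 + n23) / (n1 + n2)`.  The statistic
#' `LR = 2 [l(r_f) + l(r_m) - l(r_pooled)]` is referred to a chi-square
#' distribution with one degree of freedom; boundary estimates use the
#' `0 log 0 = 0` convention.
#'
#' @param counts_f,counts_m Canonical two-point counts for the female- and
#'   male-informative SNP pairs.
#' @return List: `r_f`, `r_m`, `r_pooled`, `lr`, `p`.
#' @examples
#' lr_equal_rates(c(90, 5, 5, 100), c(80, 20, 20, 80))  # lr ~ 21.85
#' @export
lr_equal_rates <- function(counts_f, counts_m) {
  n1 <- sum(counts_f); n2 <- sum(counts_m)
  stopifnot(n1 > 0, n2 > 0)
  r_f <- estimate_rate(counts_f)
  r_m <- estimate_rate(counts_m)
  r0 <- (counts_f[2L] + counts_f[3L] + counts_m[2L] + counts_m[3L]) /
    (n1 + n2)
  lr <- 2 * (ll_two_point(counts_f, r_f) + ll_two_point(counts_m, r_m) -
               ll_two_point(counts_f, r0) - ll_two_point(counts_m, r0))
  lr <- max(lr, 0)
  list(r_f = r_f, r_m = r_m, r_pooled = r0, lr = lr,
       p = stats::pchisq(lr, df = 1, lower.tail = FALSE))
}

#' Scan all tag intervals for sex-specific rates and rate differences
#'
#' For each interval the female SNP pair is the two flanking tags'
#' `AB_X_AA` SNPs and the male pair their `AA_X_AB` SNPs.  Phase is
#' inferred per pair, rates estimated, and the equality LR test applied.
#' Progeny missing at either SNP of a pair are excluded pairwise; intervals
#' with fewer than `min_n` informative progeny on either side are flagged
#' `low_n` but still reported; intervals where one side has no data get
#' `NA` results.
#'
#' @param dataset A filtered [genotype_dataset()].
#' @param intervals Interval data frame from [build_intervals()].
#' @param alpha_levels Two significance levels flagged in the output.
#' @param min_n Informative-progeny floor for the `low_n` flag.
#' @return Data frame, one row per interval: counts, `r_f`, `r_m`, phases,
#'   `lr`, `p`, `sig05`, `sig01`, `low_n`.
#' @export
scan_intervals <- function(dataset, intervals,
                           alpha_levels = c(0.05, 0.01), min_n = 20L) {
  stopifnot(inherits(dataset, "genotype_dataset"), is.data.frame(intervals))
  calls <- dataset$calls
  res <- intervals
  k <- nrow(intervals)
  res$n_f <- res$n_m <- NA_integer_
  res$r_f <- res$r_m <- res$lr <- res$p <- NA_real_
  res$phase_f <- res$phase_m <- NA_character_
  res$low_n <- res$no_test <- FALSE
  for (i in seq_len(k)) {
    cf <- two_point_counts(calls[intervals$left_id_f[i], ],
                           calls[intervals$right_id_f[i], ])
    cm <- two_point_counts(calls[intervals$left_id_m[i], ],
                           calls[intervals$right_id_m[i], ])
    res$n_f[i] <- sum(cf); res$n_m[i] <- sum(cm)
    if (sum(cf) == 0L || sum(cm) == 0L) {
      res$no_test[i] <- TRUE
      next
    }
    phf <- infer_phase(cf); phm <- infer_phase(cm)
    res$phase_f[i] <- phf$phase; res$phase_m[i] <- phm$phase
    lt <- lr_equal_rates(phf$counts, phm$counts)
    res$r_f[i] <- lt$r_f; res$r_m[i] <- lt$r_m
    res$lr[i] <- lt$lr; res$p[i] <- lt$p
    res$low_n[i] <- sum(cf) < min_n || sum(cm) < min_n
  }
  res$sig05 <- !is.na(res$p) & res$p < alpha_levels[1L]
  res$sig01 <- !is.na(res$p) & res$p < alpha_levels[2L]
  res
}

#' Group successive significant intervals into regions
#'
#' A region is a maximal run of two or more consecutive intervals (sharing a
#' boundary tag, i.e. adjacent rows on the same chromosome) each significant
#' at `alpha`; isolated significant intervals are reported separately.
#'
#' @param results Output of [scan_intervals()], ordered by chromosome and
#'   position.
#' @param alpha Significance level applied to column `p`.
#' @return List of data frames `regions` (chrom, start/end interval rows,
#'   `left_pos`, `right_pos`, `n_intervals`) and `singletons`.
#' @export
find_significant_regions <- function(results, alpha = 0.05) {
  stopifnot(is.data.frame(results), all(c("chrom", "p") %in% names(results)))
  sig <- !is.na(results$p) & results$p < alpha
  regions <- list(); singles <- list()
  for (chrom in unique(results$chrom)) {
    idx <- which(results$chrom == chrom)
    s <- sig[idx]
    if (!any(s)) next
    r <- rle(s)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      rows <- idx[starts[j]:ends[j]]
      rec <- data.frame(chrom = chrom,
                        first_row = rows[1L], last_row = rows[length(rows)],
                        left_pos = results$left_pos[rows[1L]],
                        right_pos = results$right_pos[rows[length(rows)]],
                        n_intervals = length(rows))
      if (length(rows) >= 2L) regions[[length(regions) + 1L]] <- rec
      else singles[[length(singles) + 1L]] <- rec
    }
  }
  list(regions = if (length(regions)) do.call(rbind, regions) else NULL,
       singletons = if (length(singles)) do.call(rbind, singles) else NULL)
}

#' Per-chromosome rate summary and paired rank test of female vs male
#'
#' Summarises interval rate estimates per chromosome (mean and range per
#' parent) and applies a two-sided Wilcoxon signed-rank test to the paired
#' female/male values: chromosome means (`level = "chromosome"`, the
#' genome-wide comparison over >= 2 chromosomes; exact distribution used for
#' up to 25 untied pairs) or individual intervals (`level = "interval"`).
#'
#' @param results Output of [scan_intervals()].
#' @param level Pairing unit for the signed-rank test.
#' @return List: `summary` (per-chromosome data frame), `test`
#'   (`htest` from [stats::wilcox.test()]), `level`.
#' @export
compare_rates <- function(results, level = c("chromosome", "interval")) {
  level <- match.arg(level)
  ok <- !is.na(results$r_f) & !is.na(results$r_m)
  rr <- results[ok, , drop = FALSE]
  summ <- do.call(rbind, lapply(split(rr, rr$chrom), function(d) {
    data.frame(chrom = d$chrom[1L], n_intervals = nrow(d),
               mean_r_f = mean(d$r_f), min_r_f = min(d$r_f),
               max_r_f = max(d$r_f),
               mean_r_m = mean(d$r_m), min_r_m = min(d$r_m),
               max_r_m = max(d$r_m))
  }))
  rownames(summ) <- NULL
  if (level == "chromosome") {
    if (nrow(summ) < 2L)
      stop("chromosome-level comparison needs >= 2 chromosomes")
    x <- summ$mean_r_f; y <- summ$mean_r_m
  } else {
    x <- rr$r_f; y <- rr$r_m
  }
  if (all(x == y)) {
    warning("all paired differences are zero")
    test <- list(statistic = c(V = NA_real_), p.value = 1,
                 method = "Wilcoxon signed rank test (degenerate)")
    class(test) <- "htest"
  } else {
    test <- suppressWarnings(
      stats::wilcox.test(x, y, paired = TRUE,
                         exact = length(x) <= 25 && level == "chromosome"))
  }
  list(summary = summ, test = test, level = level)
}
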