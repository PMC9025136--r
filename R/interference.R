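## Three-point coefficient-of-coincidence analysis.  Over two adjacent
## intervals with CO rates r1, r2 and coincidence C, the joint crossover
## frequencies are r11 = r1 r2 C (double), r10 = r1 - r11, r01 = r2 - r11,
## r00 = 1 - r1 - r2 + r11, and the eight progeny genotype classes at three
## same-type SNPs (coupling-coupling phases) have probabilities r../2 with
## the parental classes (H,H,H) and (O,O,O) at r00/2, etc.  C = 1 means no
## interference, C < 1 positive, C > 1 negative interference.

#' Tabulate three-point genotype-class counts
#'
#' Classes are in lexicographic order with het before hom:
#' 1 = (H,H,H), 2 = (H,H,O), 3 = (H,O,H), 4 = (H,O,O), 5 = (O,H,H),
#' 6 = (O,H,O), 7 = (O,O,H), 8 = (O,O,O).  Progeny missing at any of the
#' three SNPs are dropped.
#'
#' @param a,b,c Call vectors at the three SNPs (1 het, 0 hom, `NA` missing).
#' @return Integer vector of length 8.
#' @export
three_point_counts <- function(a, b, c) {
  ok <- !is.na(a) & !is.na(b) & !is.na(c)
  idx <- 4L * (1L - a[ok]) + 2L * (1L - b[ok]) + (1L - c[ok]) + 1L
  tabulate(idx, nbins = 8L)
}

#' Resolve the linkage-phase case of a marker triple
#'
#' The phase of each sub-pair (markers 1-2 and 2-3) is inferred by
#' [infer_phase()]; the four combinations map to a het/hom relabelling of a
#' single marker that reduces the counts to the canonical
#' coupling-coupling form: CC = identity, RC (first pair repulsion) = flip
#' marker 1, CR = flip marker 3, RR = flip marker 2.
#'
#' @param counts Integer vector of 8 three-point class counts.
#' @return List: `phase_case` (1 = CC, 2 = RC, 3 = CR, 4 = RR), `phases`
#'   (the two sub-pair phases), `counts` (canonical), `flip` (logical
#'   length-3: which markers were relabelled), `ambiguous` (`TRUE` when a
#'   sub-pair is uninformative, `r_hat = 0.5`).
#' @export
resolve_phase_case <- function(counts) {
  stopifnot(length(counts) == 8L, all(counts >= 0), sum(counts) > 0)
  c12 <- counts_subpair(counts, 1L, 2L)
  c23 <- counts_subpair(counts, 2L, 3L)
  ph12 <- infer_phase(c12)
  ph23 <- infer_phase(c23)
  rep12 <- ph12$phase == "repulsion"
  rep23 <- ph23$phase == "repulsion"
  flip <- if (!rep12 && !rep23) c(FALSE, FALSE, FALSE)
          else if (rep12 && !rep23) c(TRUE, FALSE, FALSE)
          else if (!rep12 && rep23) c(FALSE, FALSE, TRUE)
          else c(FALSE, TRUE, FALSE)
  phase_case <- c(1L, 2L, 3L, 4L)[1L + rep12 + 2L * rep23]  # CC,RC,CR,RR
  list(phase_case = phase_case,
       phases = c(ph12$phase, ph23$phase),
       counts = permute_counts(counts, flip),
       flip = flip,
       ambiguous = ph12$unlinked || ph23$unlinked)
}

## two-point counts of a sub-pair from the 8 three-point classes
counts_subpair <- function(counts, i, j) {
  bits <- cbind((0:7) %/% 4L, ((0:7) %/% 2L) %% 2L, (0:7) %% 2L)
  idx <- 2L * bits[, i] + bits[, j] + 1L  # (H,H)=1,(H,O)=2,(O,H)=3,(O,O)=4
  as.integer(tapply(counts, idx, sum))
}

## relabel het/hom at flipped markers
permute_counts <- function(counts, flip) {
  bits <- cbind((0:7) %/% 4L, ((0:7) %/% 2L) %% 2L, (0:7) %% 2L)
  newbits <- bits
  for (j in which(flip)) newbits[, j] <- 1L - bits[, j]
  idx <- drop(newbits %*% c(4L, 2L, 1L)) + 1L
  out <- integer(8L)
  out[idx] <- counts
  out
}

#' Interval CO rates and coefficient of coincidence from canonical counts
#'
#' Closed-form MLEs: `r1_hat = (n3+n4+n5+n6)/n`, `r2_hat = (n2+n3+n6+n7)/n`
#' and `coc_hat = (n3+n6) / (n * r1_hat * r2_hat)` (the doubles are classes
#' 3 and 6).
#'
#' @param counts Canonical (coupling-coupling) three-point counts.
#' @return List: `r1_hat`, `r2_hat`, `coc_hat` (`NA` when either rate is 0).
#' @examples
#' estimate_coc(c(36, 4, 1, 9, 9, 1, 4, 36))  # r1 0.2, r2 0.1, C 1
#' @export
estimate_coc <- function(counts) {
  stopifnot(length(counts) == 8L, all(counts >= 0))
  n <- sum(counts)
  if (n == 0L) stop("empty count table")
  r1 <- (counts[3L] + counts[4L] + counts[5L] + counts[6L]) / n
  r2 <- (counts[2L] + counts[3L] + counts[6L] + counts[7L]) / n
  coc <- if (r1 == 0 || r2 == 0) NA_real_
         else (counts[3L] + counts[6L]) / (n * r1 * r2)
  list(r1_hat = r1, r2_hat = r2, coc_hat = coc)
}

## three-point log-likelihood kernel over the four crossover groups
ll_three_point <- function(counts, r1, r2, coc) {
  p11 <- r1 * r2 * coc
  grp <- c(counts[1L] + counts[8L],  # no CO
           counts[2L] + counts[7L],  # CO in 2nd interval only
           counts[4L] + counts[5L],  # CO in 1st interval only
           counts[3L] + counts[6L])  # double CO
  pr <- c(1 - r1 - r2 + p11, r2 - p11, r1 - p11, p11)
  if (min(pr) < -1e-12) return(-Inf)
  sum(xlogy(grp, pmax(pr, 0)))
}

#' Likelihood-ratio test for crossover interference
#'
#' Compares the full model (free `C`, MLE from [estimate_coc()]) with the
#' no-interference null `C = 1` (interval rates refit at their marginal
#' MLEs, which coincide with the full-model ones).  `LR` is referred to a
#' chi-square distribution with one degree of freedom; the direction is
#' `"negative"` for significant `C > 1`, `"positive"` for significant
#' `C < 1`, `"none"` otherwise.
#'
#' @param counts Canonical three-point counts.
#' @param alpha Significance level for the direction call.
#' @return List: `r1_hat`, `r2_hat`, `coc_hat`, `lr`, `p`, `direction`.
#' @examples
#' lr_interference(c(30, 2, 4, 10, 8, 4, 2, 40))  # lr ~ 10.17, negative
#' @export
lr_interference <- function(counts, alpha = 0.05) {
  est <- estimate_coc(counts)
  if (is.na(est$coc_hat)) {
    return(c(est, list(lr = NA_real_, p = NA_real_, direction = "none")))
  }
  lr <- 2 * (ll_three_point(counts, est$r1_hat, est$r2_hat, est$coc_hat) -
               ll_three_point(counts, est$r1_hat, est$r2_hat, 1))
  lr <- max(lr, 0)
  p <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
  direction <- if (p < alpha && est$coc_hat > 1) "negative"
               else if (p < alpha && est$coc_hat < 1) "positive"
               else "none"
  c(est, list(lr = lr, p = p, direction = direction))
}

#' Chain markers at a minimum interval length and form triples
#'
#' Greedy left-to-right walk: the first marker is anchored, then each next
#' marker must lie at least `mil_bp` beyond the previous selected one.
#' Consecutive triples overlap by one interval (triple `k` uses chained
#' markers `k, k+1, k+2`).
#'
#' @param positions Sorted marker positions (bp) on one chromosome.
#' @param mil_bp Minimum interval length in bp (`>=`).
#' @return List: `chain` (indices into `positions` of the chained markers),
#'   `triples` (integer matrix, one row per triple, columns the three
#'   chained-marker indices); both empty when fewer than 3 markers chain.
#' @export
select_mil_triples <- function(positions, mil_bp) {
  stopifnot(!is.unsorted(positions), mil_bp > 0)
  chain <- integer(0)
  last <- -Inf
  for (k in seq_along(positions)) {
    if (!is.finite(last) || positions[k] - last >= mil_bp) {
      chain <- c(chain, k)
      last <- positions[k]
    }
  }
  if (length(chain) < 3L)
    return(list(chain = chain,
                triples = matrix(integer(0), ncol = 3L)))
  i <- seq_len(length(chain) - 2L)
  list(chain = chain,
       triples = cbind(chain[i], chain[i + 1L], chain[i + 2L]))
}

#' Genome-wide minimum-interval-length interference scan
#'
#' For each parent and each minimum interval length (MIL), that parent's
#' informative SNPs are chained per chromosome ([select_mil_triples()]);
#' each marker triple is phase-resolved, its CoC estimated and the
#' interference LR test applied.  The summary counts significant pairs of
#' adjacent intervals (NPCI) split by CoC > 1 / < 1, their genome coverage
#' (union of the triple spans over the genome size), and the pairs
#' significant in both parents at physically overlapping spans (split by
#' agreeing direction).
#'
#' @param dataset A filtered [genotype_dataset()].
#' @param chrom_sizes Data frame `chrom`, `length_bp` (defaults to the
#'   dataset's own, if present).
#' @param mils MIL grid in bp (default 0.5, 1, 2, 3, 4, 5 Mb).
#' @param alpha Significance level of the interference test.
#' @param tags Optional tag data frame ([pair_snps_into_tags()]); when
#'   given, only tag SNPs are used.
#' @return List: `triples` (per-triple results across parents and MILs) and
#'   `summary` (per parent x MIL: `n_pairs`, `n_sig`, `n_coc_gt1`,
#'   `n_coc_lt1`, `coverage`, plus `common_*` columns on the female rows).
#' @export
mil_scan <- function(dataset, chrom_sizes = NULL,
                     mils = c(0.5, 1, 2, 3, 4, 5) * 1e6,
                     alpha = 0.05, tags = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (is.null(chrom_sizes)) chrom_sizes <- dataset$chrom_sizes
  if (is.null(chrom_sizes)) stop("chrom_sizes required")
  m <- dataset$markers
  if (!is.null(tags)) {
    keep <- m$id %in% c(tags$id_f, tags$id_m)
    m <- m[keep, , drop = FALSE]
  }
  res <- list(); summ <- list()
  for (mil in mils) {
    per_parent <- list()
    for (parent in c("female", "male")) {
      seg <- if (parent == "female") "AB_X_AA" else "AA_X_AB"
      rows <- list()
      for (chrom in unique(m$chrom)) {
        mm <- m[m$chrom == chrom & m$seg_type == seg, , drop = FALSE]
        mm <- mm[order(mm$pos), , drop = FALSE]
        if (nrow(mm) < 3L) next
        tri <- select_mil_triples(mm$pos, mil)$triples
        if (nrow(tri) == 0L) next
        for (k in seq_len(nrow(tri))) {
          ids <- mm$id[tri[k, ]]
          cnt <- three_point_counts(dataset$calls[ids[1L], ],
                                    dataset$calls[ids[2L], ],
                                    dataset$calls[ids[3L], ])
          if (sum(cnt) == 0L) next
          ph <- resolve_phase_case(cnt)
          if (ph$ambiguous) next
          lt <- lr_interference(ph$counts, alpha)
          rows[[length(rows) + 1L]] <- data.frame(
            parent = parent, mil_bp = mil, chrom = chrom,
            pos1 = mm$pos[tri[k, 1L]], pos2 = mm$pos[tri[k, 2L]],
            pos3 = mm$pos[tri[k, 3L]],
            r1_hat = lt$r1_hat, r2_hat = lt$r2_hat,
            coc_hat = lt$coc_hat, lr = lt$lr, p = lt$p,
            phase_case = ph$phase_case, direction = lt$direction)
        }
      }
      per_parent[[parent]] <-
        if (length(rows)) do.call(rbind, rows) else NULL
    }
    res[[length(res) + 1L]] <- do.call(rbind, per_parent)
    summ[[length(summ) + 1L]] <-
      summarize_mil(per_parent, mil, chrom_sizes, alpha)
  }
  triples <- do.call(rbind, res)
  rownames(triples) <- NULL
  list(triples = triples, summary = do.call(rbind, summ))
}

summarize_mil <- function(per_parent, mil, chrom_sizes, alpha) {
  sig_spans <- list()
  out <- list()
  for (parent in c("female", "male")) {
    d <- per_parent[[parent]]
    if (is.null(d)) {
      out[[parent]] <- data.frame(
        parent = parent, mil_bp = mil, n_pairs = 0L, n_sig = 0L,
        n_coc_gt1 = 0L, n_coc_lt1 = 0L, coverage = 0,
        common_pairs = NA_integer_, common_gt1 = NA_integer_,
        common_lt1 = NA_integer_, common_coverage = NA_real_)
      sig_spans[[parent]] <- NULL
      next
    }
    sig <- !is.na(d$p) & d$p < alpha
    spans <- data.frame(chrom = d$chrom[sig], start = d$pos1[sig],
                        end = d$pos3[sig],
                        direction = d$direction[sig])
    sig_spans[[parent]] <- spans
    out[[parent]] <- data.frame(
      parent = parent, mil_bp = mil, n_pairs = nrow(d), n_sig = sum(sig),
      n_coc_gt1 = sum(sig & d$coc_hat > 1),
      n_coc_lt1 = sum(sig & d$coc_hat < 1),
      coverage = genome_coverage(spans, chrom_sizes),
      common_pairs = NA_integer_, common_gt1 = NA_integer_,
      common_lt1 = NA_integer_, common_coverage = NA_real_)
  }
  ## common pairs: female significant spans overlapping a male one
  sf <- sig_spans$female; sm <- sig_spans$male
  if (!is.null(sf) && !is.null(sm) && nrow(sf) && nrow(sm)) {
    n_common <- 0L; n_gt1 <- 0L; n_lt1 <- 0L
    inter <- list()
    for (chrom in unique(sf$chrom)) {
      a <- sf[sf$chrom == chrom, ]; b <- sm[sm$chrom == chrom, ]
      if (!nrow(a) || !nrow(b)) next
      ia <- IRanges::IRanges(round(a$start), round(a$end))
      ib <- IRanges::IRanges(round(b$start), round(b$end))
      hit <- IRanges::findOverlaps(ia, ib)
      qh <- unique(S4Vectors::queryHits(hit))
      n_common <- n_common + length(qh)
      for (q in qh) {
        subj <- S4Vectors::subjectHits(hit)[S4Vectors::queryHits(hit) == q]
        if (a$direction[q] == "negative" &&
            any(b$direction[subj] == "negative")) n_gt1 <- n_gt1 + 1L
        if (a$direction[q] == "positive" &&
            any(b$direction[subj] == "positive")) n_lt1 <- n_lt1 + 1L
      }
      ov <- IRanges::intersect(IRanges::reduce(ia), IRanges::reduce(ib))
      if (length(ov))
        inter[[chrom]] <- data.frame(
          chrom = chrom, start = IRanges::start(ov),
          end = IRanges::end(ov))
    }
    cover <- if (length(inter))
      genome_coverage(do.call(rbind, inter), chrom_sizes) else 0
    out$female$common_pairs <- n_common
    out$female$common_gt1 <- n_gt1
    out$female$common_lt1 <- n_lt1
    out$female$common_coverage <- cover
  }
  do.call(rbind, out)
}
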