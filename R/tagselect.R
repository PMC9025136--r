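## RAD-tag construction and spacing.  A tag pairs one female-informative
## (ab x aa) SNP with one male-informative (aa x ab) SNP lying within the
## intra-tag distance limit; adjacent selected tags must be separated by
## more than the inter-tag gap so crossovers in the interval are observable
## in a population of a few hundred progeny.

#' Pair opposite-segregation SNPs into RAD tags
#'
#' Within each chromosome, SNPs of type `AB_X_AA` are matched to SNPs of
#' type `AA_X_AB` lying closer than `max_intra_bp`; when several candidates
#' exist the closest pair is taken, and each SNP is used in at most one tag.
#'
#' @param dataset A (filtered) [genotype_dataset()].
#' @param max_intra_bp Maximum intra-tag SNP distance (strict `<`), default
#'   1 kb.
#' @return Data frame of tags: `chrom`, `tag_pos` (midpoint, bp), `id_f`,
#'   `pos_f`, `id_m`, `pos_m`, sorted by chromosome and position.
#' @export
pair_snps_into_tags <- function(dataset, max_intra_bp = 1000) {
  stopifnot(inherits(dataset, "genotype_dataset"), max_intra_bp > 0)
  m <- dataset$markers
  out <- list()
  for (chrom in unique(m$chrom)) {
    f <- m[m$chrom == chrom & m$seg_type == "AB_X_AA", ]
    g <- m[m$chrom == chrom & m$seg_type == "AA_X_AB", ]
    if (nrow(f) == 0L || nrow(g) == 0L) next
    ## all candidate pairs within the limit, closest first
    cand <- expand.grid(i = seq_len(nrow(f)), j = seq_len(nrow(g)))
    cand$dist <- abs(f$pos[cand$i] - g$pos[cand$j])
    cand <- cand[cand$dist < max_intra_bp, , drop = FALSE]
    cand <- cand[order(cand$dist, cand$i, cand$j), , drop = FALSE]
    used_f <- logical(nrow(f)); used_g <- logical(nrow(g))
    sel <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      i <- cand$i[k]; j <- cand$j[k]
      if (!used_f[i] && !used_g[j]) {
        used_f[i] <- TRUE; used_g[j] <- TRUE; sel[k] <- TRUE
      }
    }
    cand <- cand[sel, , drop = FALSE]
    if (nrow(cand) == 0L) next
    out[[chrom]] <- data.frame(
      chrom = chrom,
      tag_pos = (f$pos[cand$i] + g$pos[cand$j]) / 2,
      id_f = f$id[cand$i], pos_f = f$pos[cand$i],
      id_m = g$id[cand$j], pos_m = g$pos[cand$j])
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(), tag_pos = numeric(),
                      id_f = character(), pos_f = numeric(),
                      id_m = character(), pos_m = numeric()))
  tags <- do.call(rbind, out)
  tags <- tags[order(tags$chrom, tags$tag_pos), ]
  rownames(tags) <- NULL
  tags
}

#' Select spaced tags by a greedy left-to-right walk
#'
#' The first tag on each chromosome is anchored; thereafter the earliest tag
#' lying strictly more than `min_gap_bp` beyond the last selected one is
#' taken.
#'
#' @param tags Tag data frame from [pair_snps_into_tags()] (sorted by
#'   chromosome and position).
#' @param min_gap_bp Minimum inter-tag distance (strict `>`), default 100 kb.
#' @return The selected subset of `tags`.
#' @export
select_spaced_tags <- function(tags, min_gap_bp = 1e5) {
  stopifnot(is.data.frame(tags), min_gap_bp >= 0)
  if (nrow(tags) == 0L) return(tags)
  keep <- logical(nrow(tags))
  for (chrom in unique(tags$chrom)) {
    idx <- which(tags$chrom == chrom)
    pos <- tags$tag_pos[idx]
    stopifnot(!is.unsorted(pos))
    last <- -Inf
    for (k in seq_along(idx)) {
      if (pos[k] - last > min_gap_bp || !is.finite(last)) {
        keep[idx[k]] <- TRUE
        last <- pos[k]
      }
    }
  }
  out <- tags[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build adjacent-tag intervals
#'
#' `k` selected tags on a chromosome define `k - 1` analysis intervals, each
#' spanned by the two flanking tags.
#'
#' @param tags Selected tag data frame (sorted).
#' @return Data frame of intervals: `chrom`, `left_pos`, `right_pos`
#'   (tag midpoints, bp) and the flanking tags' SNP ids/positions
#'   (`*_f`, `*_m` for the female- and male-informative SNPs).
#' @export
build_intervals <- function(tags) {
  stopifnot(is.data.frame(tags))
  out <- list()
  for (chrom in unique(tags$chrom)) {
    tt <- tags[tags$chrom == chrom, , drop = FALSE]
    k <- nrow(tt)
    if (k < 2L) next
    i <- seq_len(k - 1L)
    out[[chrom]] <- data.frame(
      chrom = chrom,
      left_pos = tt$tag_pos[i], right_pos = tt$tag_pos[i + 1L],
      left_id_f = tt$id_f[i], right_id_f = tt$id_f[i + 1L],
      left_id_m = tt$id_m[i], right_id_m = tt$id_m[i + 1L])
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(), left_pos = numeric(),
                      right_pos = numeric(), left_id_f = character(),
                      right_id_f = character(), left_id_m = character(),
                      right_id_m = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fraction of the genome covered by a set of regions
#'
#' Overlapping or touching regions are merged (union) before summing, so the
#' result is invariant to input order and to splitting regions into touching
#' pieces.
#'
#' @param regions Data frame with `chrom`, `start`, `end` (bp, 1-based
#'   inclusive).
#' @param chrom_sizes Data frame with `chrom`, `length_bp`; only these
#'   chromosomes count towards the denominator.
#' @return Covered fraction in \[0, 1\].
#' @examples
#' sizes <- data.frame(chrom = "c1", length_bp = 1e7)
#' genome_coverage(data.frame(chrom = "c1", start = 1e6, end = 3e6),
#'                 sizes)
#' @export
genome_coverage <- function(regions, chrom_sizes) {
  stopifnot(is.data.frame(chrom_sizes),
            all(c("chrom", "length_bp") %in% names(chrom_sizes)))
  if (is.null(regions) || nrow(regions) == 0L) return(0)
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)),
            all(regions$end >= regions$start))
  if (!all(regions$chrom %in% chrom_sizes$chrom))
    stop("region on unknown chromosome")
  len <- chrom_sizes$length_bp[match(regions$chrom, chrom_sizes$chrom)]
  if (any(regions$end > len) || any(regions$start < 1))
    stop("region outside chromosome bounds")
  covered <- 0
  for (chrom in unique(regions$chrom)) {
    rr <- regions[regions$chrom == chrom, ]
    ir <- IRanges::reduce(IRanges::IRanges(start = round(rr$start),
                                           end = round(rr$end)))
    covered <- covered + sum(IRanges::width(ir))
  }
  covered / sum(chrom_sizes$length_bp)
}
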