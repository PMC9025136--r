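## Genotype input, segregation-type classification and marker-level filters.
##
## In the F1 pseudo-testcross design only two SNP configurations are
## informative, and each for exactly one parent: ab x aa (female het, male
## hom; segregates 1:1 through the female) and aa x ab (the mirror).  Calls
## are coded relative to the informative parent: 1 = het, 0 = hom (progeny
## equals the homozygous parent), NA = missing.

GT_HET <- c("0/1", "1/0", "0|1", "1|0")
GT_HOM_REF <- c("0/0", "0|0")
GT_HOM_ALT <- c("1/1", "1|1")

#' Classify the segregation type of a SNP from its parental genotypes
#'
#' @param female_gt,male_gt Character vectors of VCF-style genotypes
#'   (`"0/1"`, `"0/0"`, `"1/1"`, phased variants accepted).
#' @return Character vector: `"AB_X_AA"` (female-informative het x hom),
#'   `"AA_X_AB"` (male-informative hom x het), `"other"` otherwise
#'   (including a missing parental genotype, which is unclassifiable).
#' @examples
#' classify_segregation("0/1", "0/0")  # "AB_X_AA"
#' classify_segregation("1/1", "0/1")  # "AA_X_AB"
#' classify_segregation("0/1", "0/1")  # "other"
#' @export
classify_segregation <- function(female_gt, male_gt) {
  f_het <- female_gt %in% GT_HET
  m_het <- male_gt %in% GT_HET
  f_hom <- female_gt %in% c(GT_HOM_REF, GT_HOM_ALT)
  m_hom <- male_gt %in% c(GT_HOM_REF, GT_HOM_ALT)
  out <- rep("other", length(female_gt))
  out[f_het & m_hom] <- "AB_X_AA"
  out[f_hom & m_het] <- "AA_X_AB"
  out
}

#' Chi-square test of the 1:1 Mendelian segregation ratio
#'
#' The pseudo-testcross expectation at an informative SNP is an equal number
#' of het and hom progeny.  The statistic is the one-degree-of-freedom
#' goodness-of-fit chi-square `(n_het - n_hom)^2 / (n_het + n_hom)` without
#' continuity correction.
#'
#' @param n_het,n_hom Non-negative counts (vectorised).
#' @return List with numeric vectors `chisq` and `p`.
#' @examples
#' test_segregation_ratio(50, 50)  # chisq 0, p 1
#' test_segregation_ratio(70, 30)  # chisq 16
#' @export
test_segregation_ratio <- function(n_het, n_hom) {
  tot <- n_het + n_hom
  if (any(tot <= 0)) stop("segregation test undefined for zero total count")
  chisq <- (n_het - n_hom)^2 / tot
  list(chisq = chisq,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Marker filter thresholds
#'
#' Defaults follow the genotyping protocol the package targets: keep markers
#' whose het:hom ratio is compatible with 1:1 at the 0.01 level, drop markers
#' with more than 20% missing progeny calls, and (at VCF import) require
#' read depth >= 3 plus genotype quality > 30 for a het call and depth >= 5
#' for a hom call.
#'
#' @param seg_ratio_alpha Significance floor of the 1:1 test; markers with
#'   `p >= seg_ratio_alpha` are kept.
#' @param max_missing Maximum tolerated missing fraction; strictly more is
#'   removed.
#' @param min_dp_het,min_dp_hom Minimum read depth for het / hom calls.
#' @param min_gq Genotype quality floor for het calls (strict `>`).
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(seg_ratio_alpha = 0.01, max_missing = 0.20,
                          min_dp_het = 3, min_dp_hom = 5, min_gq = 30) {
  stopifnot(seg_ratio_alpha >= 0, seg_ratio_alpha <= 1,
            max_missing >= 0, max_missing <= 1,
            min_dp_het >= 0, min_dp_hom >= 0, min_gq >= 0)
  structure(list(seg_ratio_alpha = seg_ratio_alpha,
                 max_missing = max_missing,
                 min_dp_het = min_dp_het, min_dp_hom = min_dp_hom,
                 min_gq = min_gq),
            class = "filter_config")
}

#' Apply marker-level filters to a genotype dataset
#'
#' Removes, in order: SNPs of segregation type `"other"` (uninformative in
#' the pseudo-testcross design), SNPs with a missing-call fraction strictly
#' above `max_missing`, and SNPs whose het:hom counts deviate from 1:1
#' (`p < seg_ratio_alpha` in [test_segregation_ratio()]).  Filtering is
#' idempotent.
#'
#' @param dataset A [genotype_dataset()].
#' @param config A [filter_config()].
#' @return List with the filtered `dataset` and a one-row data frame
#'   `report` counting removals per rule.
#' @export
apply_filters <- function(dataset, config = filter_config()) {
  stopifnot(inherits(dataset, "genotype_dataset"),
            inherits(config, "filter_config"))
  if (nrow(dataset$markers) == 0L) stop("empty dataset")
  calls <- dataset$calls
  keep <- dataset$markers$seg_type != "other"
  n_other <- sum(!keep)

  miss_frac <- rowMeans(is.na(calls))
  bad_miss <- keep & miss_frac > config$max_missing
  keep <- keep & !bad_miss

  n_het <- rowSums(calls == 1L, na.rm = TRUE)
  n_hom <- rowSums(calls == 0L, na.rm = TRUE)
  tot <- n_het + n_hom
  p_seg <- rep(NA_real_, length(tot))
  ok <- tot > 0
  p_seg[ok] <- test_segregation_ratio(n_het[ok], n_hom[ok])$p
  bad_seg <- keep & (!ok | p_seg < config$seg_ratio_alpha)
  keep <- keep & !bad_seg

  if (!any(keep)) warning("all markers removed by filtering")
  report <- data.frame(n_input = nrow(dataset$markers),
                       n_uninformative = n_other,
                       n_missing_removed = sum(bad_miss),
                       n_segratio_removed = sum(bad_seg),
                       n_kept = sum(keep))
  list(dataset = genotype_dataset(dataset$markers[keep, , drop = FALSE],
                                  calls[keep, , drop = FALSE],
                                  chrom_sizes = dataset$chrom_sizes),
       report = report)
}

#' Read progeny + parental genotypes from VCF or the simplified TSV dialect
#'
#' VCF (v4.x): one marker per biallelic site (multiallelic sites are skipped
#' with a message); parents are identified by sample name; segregation types
#' come from the parental GT fields; progeny calls are coded het/hom relative
#' to the informative parent, and calls failing the depth/quality thresholds
#' of `config` (when the DP/GQ FORMAT fields are present) are set missing.
#' Progeny genotypes incompatible with the cross (e.g. hom-alt when the
#' homozygous parent is ref) are also set missing.
#'
#' TSV: columns `chrom`, `pos`, `id`, `seg_type`, then one column per
#' individual with values `het`/`hom`/`missing` (the format written by
#' [write_genotypes_tsv()]).
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @param female,male Parent sample names (VCF only).
#' @param config A [filter_config()] supplying DP/GQ thresholds (VCF only).
#' @return A [genotype_dataset()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv"),
                           female = "female", male = "male",
                           config = filter_config()) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  }
  if (format == "vcf")
    read_genotypes_vcf(path, female, male, config)
  else
    read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path, female, male, config) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(vcf)
  if (any(!bi)) {
    message(sum(!bi), " multiallelic site(s) skipped")
    vcf <- vcf[bi, ]
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  if (!all(c(female, male) %in% samples))
    stop("parent samples not found in VCF: ", female, ", ", male)
  has_fmt <- function(el) {
    any(grepl(paste0("(^|:)", el, "(:|$)"), vcf@gt[, "FORMAT"]))
  }
  dp <- if (has_fmt("DP"))
    vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE) else NULL
  gq <- if (has_fmt("GQ"))
    vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE) else NULL

  seg <- classify_segregation(gt[, female], gt[, male])
  fix <- vcfR::getFIX(vcf)
  markers <- data.frame(chrom = fix[, "CHROM"],
                        pos = as.integer(fix[, "POS"]),
                        id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                                    paste0(fix[, "CHROM"], ":", fix[, "POS"]),
                                    fix[, "ID"]),
                        seg_type = seg)
  prog <- setdiff(samples, c(female, male))
  gtp <- gt[, prog, drop = FALSE]
  hom_parent_gt <- ifelse(seg == "AB_X_AA", gt[, male], gt[, female])
  hom_is_ref <- hom_parent_gt %in% GT_HOM_REF

  calls <- matrix(NA_integer_, nrow(markers), length(prog),
                  dimnames = list(markers$id, prog))
  is_het <- matrix(gtp %in% GT_HET, nrow(markers))
  is_ref <- matrix(gtp %in% GT_HOM_REF, nrow(markers))
  is_alt <- matrix(gtp %in% GT_HOM_ALT, nrow(markers))
  calls[is_het] <- 1L
  calls[is_ref & hom_is_ref] <- 0L
  calls[is_alt & !hom_is_ref] <- 0L

  if (!is.null(dp)) {
    dpp <- dp[, prog, drop = FALSE]
    low <- (calls == 1L & (is.na(dpp) | dpp < config$min_dp_het)) |
           (calls == 0L & (is.na(dpp) | dpp < config$min_dp_hom))
    calls[low] <- NA_integer_
  }
  if (!is.null(gq)) {
    gqp <- gq[, prog, drop = FALSE]
    low <- calls == 1L & (is.na(gqp) | gqp <= config$min_gq)
    calls[low] <- NA_integer_
  }
  genotype_dataset(markers, calls)
}

read_genotypes_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "id", "seg_type")
  if (!all(need %in% names(df)))
    stop("TSV genotype file must have columns: ",
         paste(need, collapse = ", "))
  ind <- setdiff(names(df), need)
  vals <- as.matrix(df[, ind, drop = FALSE])
  bad <- !vals %in% c("het", "hom", "missing")
  if (any(bad))
    stop("invalid genotype token(s) in TSV (expected het/hom/missing), ",
         "first at row ", which(bad)[1] %% nrow(vals))
  calls <- matrix(NA_integer_, nrow(df), length(ind),
                  dimnames = list(df$id, ind))
  calls[vals == "het"] <- 1L
  calls[vals == "hom"] <- 0L
  genotype_dataset(df[, need], calls)
}

#' Write a genotype dataset as the simplified TSV dialect
#'
#' @param dataset A [genotype_dataset()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(dataset, path) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  vals <- matrix("missing", nrow(dataset$calls), ncol(dataset$calls))
  vals[dataset$calls == 1L] <- "het"
  vals[dataset$calls == 0L] <- "hom"
  colnames(vals) <- colnames(dataset$calls)
  out <- cbind(dataset$markers[c("chrom", "pos", "id", "seg_type")],
               as.data.frame(vals, optional = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a genotype dataset as VCF v4.2
#'
#' Parents appear as the first two samples (`female`, `male`) with the GT
#' field only; positions are 1-based.  Calls are decoded back to VCF
#' genotypes relative to the informative parent (hom parent is REF).
#'
#' @param dataset A [genotype_dataset()].
#' @param path Output file (plain text).
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(dataset, path) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  m <- dataset$markers
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=radxo_simulate",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  if (!is.null(dataset$chrom_sizes)) {
    writeLines(sprintf("##contig=<ID=%s,length=%d>",
                       dataset$chrom_sizes$chrom,
                       as.integer(dataset$chrom_sizes$length_bp)), con)
  }
  prog <- colnames(dataset$calls)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "female", "male", prog),
                   collapse = "\t"), con)
  fgt <- ifelse(m$seg_type == "AB_X_AA", "0/1",
                ifelse(m$seg_type == "AA_X_AB", "0/0", "./."))
  mgt <- ifelse(m$seg_type == "AA_X_AB", "0/1",
                ifelse(m$seg_type == "AB_X_AA", "0/0", "./."))
  cgt <- matrix("./.", nrow(m), length(prog))
  cgt[dataset$calls == 1L] <- "0/1"
  cgt[dataset$calls == 0L] <- "0/0"
  lines <- paste(m$chrom, m$pos, m$id, "A", "T", ".", "PASS", ".", "GT",
                 fgt, mgt, sep = "\t")
  lines <- paste(lines, apply(cgt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read chromosome sizes from a two-column TSV
#'
#' @param path TSV with columns `chrom` and `length_bp` (header optional if
#'   in that order).
#' @return Data frame with `chrom`, `length_bp`.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          header = FALSE)
  if (identical(tolower(as.character(df[1, 1])), "chrom")) {
    names(df) <- as.character(unlist(df[1, ]))
    df <- df[-1, , drop = FALSE]
  } else names(df) <- c("chrom", "length_bp")[seq_len(ncol(df))]
  data.frame(chrom = as.character(df$chrom),
             length_bp = as.numeric(df$length_bp))
}
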