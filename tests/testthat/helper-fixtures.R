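# Small in-code fixtures.

# dataset with explicit call vectors; markers alternate f/m types when
# seg_types not given
make_dataset <- function(calls, chrom = "Chr01", pos = NULL,
                         seg_types = NULL, chrom_sizes = NULL) {
  k <- nrow(calls)
  if (is.null(pos)) pos <- seq(1e5, by = 1e5, length.out = k)
  if (is.null(seg_types))
    seg_types <- rep(c("AB_X_AA", "AA_X_AB"), length.out = k)
  markers <- data.frame(chrom = rep(chrom, length.out = k), pos = pos,
                        id = sprintf("m%03d", seq_len(k)),
                        seg_type = seg_types)
  genotype_dataset(markers, calls, chrom_sizes = chrom_sizes)
}

# a small VCF with DP/GQ fields exercising the import thresholds
write_fixture_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Quality">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "mom", "dad", "p1", "p2", "p3"), collapse = "\t"),
    # female-informative site; p1 good het, p2 het with DP=2 (below floor),
    # p3 good hom-ref
    paste(c("Chr01", "1000", "s1", "A", "T", ".", "PASS", ".", "GT:DP:GQ",
            "0/1:20:99", "0/0:20:99", "0/1:10:99", "0/1:2:99",
            "0/0:10:99"), collapse = "\t"),
    # male-informative site; p1 hom with DP=4 (below hom floor of 5),
    # p2 het with GQ=30 (not > 30), p3 mendelian-inconsistent hom-alt
    paste(c("Chr01", "2000", "s2", "G", "C", ".", "PASS", ".", "GT:DP:GQ",
            "0/0:20:99", "0/1:20:99", "0/0:4:99", "0/1:10:30",
            "1/1:10:99"), collapse = "\t"),
    # both parents het: uninformative
    paste(c("Chr01", "3000", "s3", "A", "G", ".", "PASS", ".", "GT:DP:GQ",
            "0/1:20:99", "0/1:20:99", "0/1:10:99", "0/0:10:99",
            "0/0:10:99"), collapse = "\t"),
    # multiallelic: skipped
    paste(c("Chr01", "4000", "s4", "A", "G,T", ".", "PASS", ".", "GT:DP:GQ",
            "0/1:20:99", "0/0:20:99", "0/1:10:99", "0/2:10:99",
            "0/0:10:99"), collapse = "\t"))
  writeLines(lines, path)
  path
}
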