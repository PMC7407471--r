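# shared fixtures, built in code at test time

# minimal VarScan-style VCF with GT:DP:RD genotype fields.
# records: list of lists(chrom, pos, ref, alt, cells = character vector
# "GT:DP:RD" per sample); cells may use "." for missing subfields.
write_test_vcf <- function(path, samples, records) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
    "##FORMAT=<ID=RD,Number=1,Type=Integer,Description=\"Reference Depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic Depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  rows <- vapply(records, function(r) {
    fmt <- if (is.null(r$fmt)) "GT:DP:RD" else r$fmt
    paste(c(r$chrom, r$pos, ".", r$ref, r$alt, ".", "PASS", ".", fmt,
            r$cells), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  path
}

# naive dosage-probability slices (list of matrices with rownames) for
# simulated background markers, ready for assoc_scan / permutation_maxima
naive_slices <- function(DP, RD, ids, params = dosage_params()) {
  lapply(seq_len(ncol(DP)), function(j) {
    M <- polyscan:::.naive_probs_matrix(DP[, j], RD[, j], params)
    rownames(M) <- ids
    M
  })
}

# GEV sampler by inverse-CDF through the package quantile function
rgev_sample <- function(n, loc, scale, shape) {
  u <- runif(n)
  vapply(u, function(ui)
    gev_quantile(list(loc = loc, scale = scale, shape = shape), 1 - ui),
    numeric(1))
}
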