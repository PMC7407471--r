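#' Read-count tables for dosage-probability genotyping
#'
#' A `read_count_table` holds, for a set of individuals and biallelic SNP
#' markers, the total read depth (DP) and reference-allele read depth (RD)
#' extracted from a VCF, plus per-marker metadata. Missing genotype cells are
#' `NA` in both matrices (DP and RD always share one missingness mask).
#'
#' @param DP,RD integer matrices, individuals x markers; `NA` marks missing.
#' @param individual_ids,marker_ids character vectors naming rows/columns.
#' @param marker_meta data.frame with one row per marker: columns `chrom`,
#'   `pos` (1-based), and optionally `homologous_group` (integer or `NA`).
#'
#' @return An object of class `read_count_table`: a list with elements
#'   `DP`, `RD`, `individual_ids`, `marker_ids`, `marker_meta`.
#' @export
read_count_table <- function(DP, RD, individual_ids = rownames(DP),
                             marker_ids = colnames(DP), marker_meta = NULL) {
  DP <- as.matrix(DP)
  RD <- as.matrix(RD)
  if (!all(dim(DP) == dim(RD)))
    stop("DP and RD must have identical dimensions")
  if (is.null(individual_ids))
    individual_ids <- paste0("ind", seq_len(nrow(DP)))
  if (is.null(marker_ids))
    marker_ids <- paste0("m", seq_len(ncol(DP)))
  ## unify the missingness mask: a cell lacking either field is missing
  miss <- is.na(DP) | is.na(RD)
  DP[miss] <- NA_integer_
  RD[miss] <- NA_integer_
  ok <- !miss
  if (any(RD[ok] > DP[ok], na.rm = TRUE))
    stop("RD must not exceed DP in any unmasked cell")
  if (any(DP[ok] < 0) || any(RD[ok] < 0))
    stop("read depths must be non-negative")
  if (is.null(marker_meta)) {
    m <- length(marker_ids)
    marker_meta <- data.frame(chrom = rep(NA_character_, m),
                              pos = rep(NA_integer_, m),
                              homologous_group = rep(NA_integer_, m),
                              row.names = marker_ids,
                              stringsAsFactors = FALSE)
  }
  if (is.null(marker_meta$homologous_group))
    marker_meta$homologous_group <- NA_integer_
  dimnames(DP) <- dimnames(RD) <- list(individual_ids, marker_ids)
  structure(list(DP = DP, RD = RD,
                 individual_ids = individual_ids,
                 marker_ids = marker_ids,
                 marker_meta = marker_meta),
            class = "read_count_table")
}

#' @export
print.read_count_table <- function(x, ...) {
  miss <- mean(is.na(x$DP))
  cat(sprintf("read_count_table: %d individuals x %d markers (%.1f%% missing)\n",
              nrow(x$DP), ncol(x$DP), 100 * miss))
  invisible(x)
}

#' @export
dim.read_count_table <- function(x) dim(x$DP)

#' Extract DP/RD count matrices from a VCF file
#'
#' Reads per-genotype depth fields from a VCF (plain or bgzipped) as emitted
#' by VarScan-style callers. Only biallelic SNP records are retained;
#' multi-allelic and indel records are skipped with a warning. The
#' reference-read field may be a scalar FORMAT field (VarScan `RD`) or, when
#' absent, the first element of an allele-depth list field (`AD`).
#'
#' @param path path to a VCF file.
#' @param dp_field FORMAT field holding total depth (default `"DP"`).
#' @param rd_field FORMAT field holding reference depth (default `"RD"`);
#'   if missing from the file, `"AD"` is tried and its first element used.
#' @param verbose log which extraction path was used.
#' @return A [read_count_table] with one column per retained SNP.
#' @export
read_vcf_counts <- function(path, dp_field = "DP", rd_field = "RD",
                            verbose = TRUE) {
  if (!file.exists(path)) stop("cannot read VCF file: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(alt) & !grepl(",", alt) & nchar(ref) == 1L & nchar(alt) == 1L
  n_skip <- sum(!snp)
  if (n_skip > 0)
    warning(sprintf("skipped %d non-biallelic-SNP record(s)", n_skip))
  if (!any(snp)) stop("no biallelic SNP records in ", path)

  fmt <- unique(unlist(strsplit(unname(vcf@gt[, "FORMAT"]), ":", fixed = TRUE)))
  if (!dp_field %in% fmt)
    stop("FORMAT field '", dp_field, "' absent from every record")
  dp <- vcfR::extract.gt(vcf, element = dp_field, as.numeric = TRUE)

  if (rd_field %in% fmt) {
    rd <- vcfR::extract.gt(vcf, element = rd_field, as.numeric = TRUE)
    if (verbose) message("reference depths taken from scalar field '",
                         rd_field, "'")
  } else if ("AD" %in% fmt) {
    ad <- vcfR::extract.gt(vcf, element = "AD")
    rd <- suppressWarnings(
      apply(ad, 2, function(s) as.numeric(sub(",.*$", "", s))))
    if (is.null(dim(rd))) rd <- matrix(rd, nrow = nrow(ad),
                                       dimnames = dimnames(ad))
    dimnames(rd) <- dimnames(ad)
    if (verbose) message("reference depths derived from AD[1] (field '",
                         rd_field, "' absent)")
  } else {
    stop("FORMAT field '", rd_field, "' (and fallback 'AD') absent from ",
         "every record")
  }

  keep <- which(snp)
  ids <- fix[keep, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste(fix[keep, "CHROM"], fix[keep, "POS"],
                     sep = "_")[noid]
  ids <- make.unique(ids)
  meta <- data.frame(chrom = fix[keep, "CHROM"],
                     pos = as.integer(fix[keep, "POS"]),
                     homologous_group = NA_integer_,
                     row.names = ids, stringsAsFactors = FALSE)
  ## vcfR returns markers x individuals; transpose to individuals x markers
  DP <- t(dp[keep, , drop = FALSE])
  RD <- t(rd[keep, , drop = FALSE])
  colnames(DP) <- colnames(RD) <- ids
  read_count_table(DP, RD, individual_ids = rownames(DP),
                   marker_ids = ids, marker_meta = meta)
}

#' Mask genotypes outside a read-depth window
#'
#' Individual genotype cells with DP below `min_dp` or above `max_dp` become
#' missing (strict inequalities: DP equal to either bound is retained). The
#' matrix shape is unchanged; cells are only ever masked, never unmasked.
#'
#' @param table a [read_count_table].
#' @param min_dp,max_dp depth window (defaults 10 and 300).
#' @return The filtered [read_count_table].
#' @export
filter_depth <- function(table, min_dp = 10, max_dp = 300) {
  stopifnot(inherits(table, "read_count_table"), min_dp <= max_dp)
  bad <- !is.na(table$DP) & (table$DP < min_dp | table$DP > max_dp)
  table$DP[bad] <- NA_integer_
  table$RD[bad] <- NA_integer_
  table
}

#' Drop markers with too many missing genotypes
#'
#' Removes marker columns whose missing fraction exceeds `max_missing`
#' (strictly; a marker at exactly the threshold is retained). Column order of
#' survivors is preserved.
#'
#' @param table a [read_count_table].
#' @param max_missing maximum tolerated missing fraction, default 0.5.
#' @return The filtered [read_count_table] (possibly with zero markers).
#' @export
filter_missing <- function(table, max_missing = 0.5) {
  stopifnot(inherits(table, "read_count_table"),
            max_missing >= 0, max_missing <= 1)
  frac <- colMeans(is.na(table$DP))
  keep <- frac <= max_missing
  subset_markers(table, which(keep))
}

## keep a subset of marker columns, preserving order
subset_markers <- function(table, idx) {
  table$DP <- table$DP[, idx, drop = FALSE]
  table$RD <- table$RD[, idx, drop = FALSE]
  table$marker_ids <- table$marker_ids[idx]
  table$marker_meta <- table$marker_meta[idx, , drop = FALSE]
  table
}

#' Attach homologous-group annotation to markers
#'
#' Joins an external marker-to-group table (as produced by linkage analysis)
#' by exact marker ID. Unmatched markers keep group `NA` and still appear in
#' downstream scans.
#'
#' @param table a [read_count_table].
#' @param groups data.frame with columns `marker_id` and `group` (integers,
#'   e.g. 1-15 homologous linkage groups).
#' @return The annotated [read_count_table].
#' @export
set_homologous_groups <- function(table, groups) {
  stopifnot(inherits(table, "read_count_table"),
            all(c("marker_id", "group") %in% names(groups)))
  m <- match(table$marker_ids, groups$marker_id)
  table$marker_meta$homologous_group <- as.integer(groups$group[m])
  table
}

#' Dump DP/RD matrices to TSV (debugging aid)
#'
#' @param table a [read_count_table].
#' @param dp_path,rd_path output file paths.
#' @return invisibly, the table.
#' @export
write_counts_tsv <- function(table, dp_path, rd_path) {
  write.table(table$DP, dp_path, sep = "\t", quote = FALSE, na = "NA")
  write.table(table$RD, rd_path, sep = "\t", quote = FALSE, na = "NA")
  invisible(table)
}
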