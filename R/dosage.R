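#' Dosage-model parameters
#'
#' Parameters of the binomial allele-dosage model: ploidy K and a small error
#' probability e that pulls the expected reference-read fractions away from 0
#' and 1 at the homozygous dosages, giving the expected fractions
#' r = \{0/K + e, 1/K, ..., (K-1)/K, K/K - e\}. Only the endpoint fractions
#' are adjusted.
#'
#' @param ploidy even integer, number of chromosome copies (default 6).
#' @param e error probability adjusting the endpoint fractions
#'   (default 0.001).
#' @return An object of class `dosage_params` with elements `ploidy`, `e`
#'   and the fraction vector `r` (length ploidy + 1).
#' @export
dosage_params <- function(ploidy = 6, e = 0.001) {
  stopifnot(ploidy >= 2, e >= 0, e < 1 / ploidy)
  r <- (0:ploidy) / ploidy
  r[1] <- r[1] + e
  r[ploidy + 1] <- r[ploidy + 1] - e
  structure(list(ploidy = as.integer(ploidy), e = e, r = r),
            class = "dosage_params")
}

#' Relative dosage probabilities for one genotype
#'
#' For observed reference/total read counts (RD, DP) the probability of each
#' allele dosage d in 0..K is proportional to the binomial likelihood
#' r_d^RD (1 - r_d)^(DP - RD); the binomial coefficient is common to all
#' dosages and cancels in the normalisation. Computed in log space, so large
#' depths do not underflow.
#'
#' @param DP total read depth (>= 1).
#' @param RD reference-allele read depth, 0 <= RD <= DP.
#' @param params a [dosage_params] object.
#' @return Numeric vector of length ploidy + 1 summing to 1; element d + 1
#'   is the relative probability of dosage d.
#' @export
naive_dosage_probs <- function(DP, RD, params = dosage_params()) {
  if (RD > DP) stop("RD exceeds DP")
  if (DP < 1) stop("DP must be >= 1")
  lp <- RD * log(params$r) + (DP - RD) * log1p(-params$r)
  lp <- lp - max(lp)
  p <- exp(lp)
  p / sum(p)
}

#' Dosage-probability array for a read-count table
#'
#' Applies the binomial dosage model cell-wise to every marker, producing a
#' 3-dimensional array individuals x (ploidy + 1) x markers. Missing genotype
#' cells become all-`NA` rows of the corresponding marker slice.
#'
#' @param table a [read_count_table].
#' @param params a [dosage_params].
#' @return A `dosage_array`: numeric array with `dim = c(n_individuals,
#'   ploidy + 1, n_markers)`, dimnames individual / dosage (as "0".."K") /
#'   marker, attributes `ploidy` and `e`.
#' @export
dosage_probs <- function(table, params = dosage_params()) {
  stopifnot(inherits(table, "read_count_table"))
  K <- params$ploidy
  n <- nrow(table$DP); m <- ncol(table$DP)
  dp <- as.vector(table$DP); rd <- as.vector(table$RD)
  ok <- !is.na(dp) & dp >= 1
  ## vectorised log-likelihood over all unmasked cells at once
  lp <- matrix(NA_real_, n * m, K + 1)
  if (any(ok)) {
    for (d in 0:K) {
      lp[ok, d + 1] <- rd[ok] * log(params$r[d + 1]) +
        (dp[ok] - rd[ok]) * log1p(-params$r[d + 1])
    }
    mx <- apply(lp[ok, , drop = FALSE], 1, max)
    pr <- exp(lp[ok, , drop = FALSE] - mx)
    lp[ok, ] <- pr / rowSums(pr)
  }
  ## lp rows are cells in (individual, marker) column-major order;
  ## reshape to individuals x dosage x markers
  arr <- aperm(array(lp, dim = c(n, m, K + 1)), c(1, 3, 2))
  dimnames(arr) <- list(table$individual_ids, as.character(0:K),
                        table$marker_ids)
  structure(arr, ploidy = K, e = params$e, class = "dosage_array")
}

#' @export
print.dosage_array <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "dosage_array: %d individuals x %d dosage classes x %d markers (ploidy %d)\n",
    d[1], d[2], d[3], attr(x, "ploidy")))
  invisible(x)
}

## accept either one marker slice (matrix n x K+1) or a full dosage_array
.marker_slices <- function(M) {
  if (is.matrix(M)) return(list(M))
  stopifnot(length(dim(M)) == 3)
  lapply(seq_len(dim(M)[3]), function(j) M[, , j, drop = TRUE])
}

#' Expected (continuous) allele dosage
#'
#' The probability-weighted dosage x_i = sum_d RPr[i, d] * d, a real value in
#' \[0, K\]; this is the "continuous" genotype encoding. Masked rows give `NA`.
#'
#' @param M a single-marker probability matrix (individuals x K+1) or a
#'   `dosage_array`.
#' @return A numeric vector (single marker) or individuals x markers matrix.
#' @export
continuous_dosage <- function(M) {
  v <- function(mat) as.vector(mat %*% (seq_len(ncol(mat)) - 1))
  if (is.matrix(M)) return(v(M))
  out <- sapply(.marker_slices(M), v)
  dimnames(out) <- dimnames(M)[c(1, 3)]
  out
}

#' Hard dosage calls (argmax)
#'
#' Per individual, the dosage with the highest relative probability. Exact
#' ties are broken toward the lower dosage and counted in the `ties`
#' attribute of the result.
#'
#' @inheritParams continuous_dosage
#' @return Integer vector/matrix of calls in 0..K with attribute `ties`.
#' @export
call_dosage <- function(M) {
  f <- function(mat) {
    calls <- rep(NA_integer_, nrow(mat))
    ties <- 0L
    ok <- which(!is.na(mat[, 1]))
    for (i in ok) {
      w <- which(mat[i, ] == max(mat[i, ]))
      if (length(w) > 1L) ties <- ties + 1L
      calls[i] <- w[1L] - 1L
    }
    list(calls = calls, ties = ties)
  }
  if (is.matrix(M)) {
    r <- f(M)
    return(structure(r$calls, ties = r$ties))
  }
  rs <- lapply(.marker_slices(M), f)
  out <- sapply(rs, `[[`, "calls")
  dimnames(out) <- dimnames(M)[c(1, 3)]
  structure(out, ties = sum(vapply(rs, `[[`, integer(1), "ties")))
}

#' Major genotype frequency of a marker
#'
#' The largest column mean of the dosage-probability matrix over unmasked
#' individuals: the (probability-weighted) fraction of individuals in the
#' most common dosage class. Near 1 flags a (near-)monomorphic marker. With
#' `hard_calls = TRUE` the frequency is computed from argmax calls instead.
#'
#' @inheritParams continuous_dosage
#' @param hard_calls use hard argmax calls rather than probability mass.
#' @return Numeric scalar (single marker) or vector over markers; `NA` when
#'   every row is masked.
#' @export
major_genotype_frequency <- function(M, hard_calls = FALSE) {
  f <- function(mat) {
    ok <- !is.na(mat[, 1])
    if (!any(ok)) return(NA_real_)
    if (hard_calls) {
      cl <- call_dosage(mat)
      return(max(tabulate(cl[ok] + 1L, nbins = ncol(mat))) / sum(ok))
    }
    max(colMeans(mat[ok, , drop = FALSE]))
  }
  if (is.matrix(M)) return(f(M))
  out <- vapply(.marker_slices(M), f, numeric(1))
  names(out) <- dimnames(M)[[3]]
  out
}

#' Drop near-monomorphic markers by major genotype frequency
#'
#' Removes markers whose MGF strictly exceeds `threshold` (a marker at
#' exactly the threshold is retained), as well as markers whose rows are all
#' masked.
#'
#' @param M a `dosage_array`.
#' @param threshold MGF cutoff in (0, 1\], default 0.95.
#' @param hard_calls passed to [major_genotype_frequency].
#' @return The filtered `dosage_array`; dropped marker ids in attribute
#'   `dropped`.
#' @export
filter_mgf <- function(M, threshold = 0.95, hard_calls = FALSE) {
  stopifnot(length(dim(M)) == 3, threshold > 0, threshold <= 1)
  mgf <- major_genotype_frequency(M, hard_calls = hard_calls)
  keep <- !is.na(mgf) & mgf <= threshold
  out <- M[, , keep, drop = FALSE]
  attributes(out) <- c(attributes(out),
                       list(ploidy = attr(M, "ploidy"), e = attr(M, "e")))
  class(out) <- "dosage_array"
  attr(out, "dropped") <- dimnames(M)[[3]][!keep]
  out
}

#' Export one marker's dosage matrix as TSV
#'
#' Layout: one row per individual with columns ID, DP, RD and the relative
#' probability of each dosage class.
#'
#' @param table a [read_count_table].
#' @param M the matching `dosage_array`.
#' @param marker marker id or index.
#' @param path output TSV path.
#' @return invisibly, the exported data.frame.
#' @export
write_dosage_tsv <- function(table, M, marker, path) {
  j <- if (is.character(marker)) match(marker, table$marker_ids) else marker
  sl <- M[, , j, drop = TRUE]
  df <- data.frame(ID = table$individual_ids,
                   DP = table$DP[, j], RD = table$RD[, j],
                   round(sl, 4), check.names = FALSE)
  names(df)[-(1:3)] <- paste0("RPr", 0:(ncol(sl) - 1))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(df)
}
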