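#' Likelihood-ratio test for one marker design
#'
#' Fits a null (intercept-only) and a full (intercept + design) generalized
#' linear model — Gaussian with identity link for continuous traits,
#' binomial with logit link for binary traits — and computes the
#' likelihood-ratio statistic as the drop in deviance. In the default
#' `"unscaled"` mode the Gaussian deviance difference is used unscaled, exactly
#' as produced by `glm()`/`pchisq()`; because genome-wide significance is
#' calibrated by permutation this is valid despite being scale-dependent.
#' Mode `"scaled"` divides by the full-model dispersion estimate, giving the
#' usual scale-free statistic.
#'
#' @param y numeric response; for binary traits values in \{0, 1\}.
#' @param X design matrix (rows aligned with `y`); constant columns are
#'   pruned automatically.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param mode `"unscaled"` (the raw Gaussian deviance difference) or `"scaled"`.
#' @return List with `lrt_stat`, `df`, `pvalue`, `neglog10p`, `flag`
#'   (`NA`, `"untestable"`, `"constant_phenotype"` or `"separation"`).
#' @export
fit_glm_lrt <- function(y, X, trait_type = c("continuous", "binary"),
                        mode = c("unscaled", "scaled")) {
  trait_type <- match.arg(trait_type)
  mode <- match.arg(mode)
  X <- as.matrix(X)
  ## prune constant (zero-variance) columns: untestable degrees of freedom
  if (ncol(X) > 0) {
    sds <- apply(X, 2, function(col) max(col) - min(col))
    X <- X[, sds > 1e-12, drop = FALSE]
  }
  untestable <- list(lrt_stat = 0, df = 0L, pvalue = 1, neglog10p = 0,
                     flag = "untestable")
  if (ncol(X) == 0) return(untestable)
  if (max(y) - min(y) < 1e-12) {
    r <- untestable; r$flag <- "constant_phenotype"; return(r)
  }
  fam <- if (trait_type == "continuous") gaussian() else binomial()
  fit <- suppressWarnings(
    glm.fit(cbind(`(Intercept)` = 1, X), y, family = fam,
            control = glm.control(maxit = 100, epsilon = 1e-8)))
  df <- fit$rank - 1L
  if (df < 1L) return(untestable)
  stat <- fit$null.deviance - fit$deviance
  flag <- NA_character_
  if (!is.finite(stat)) {
    stat <- 0; flag <- "nonfinite_deviance"
  }
  stat <- max(stat, 0)
  if (mode == "scaled" && trait_type == "continuous") {
    disp <- fit$deviance / fit$df.residual
    if (disp <= 0 || !is.finite(disp)) {
      flag <- "zero_dispersion"
    } else stat <- stat / disp
  }
  if (trait_type == "binary") {
    mu <- fit$fitted.values
    if (any(mu < 1e-8 | mu > 1 - 1e-8)) flag <- "separation"
  }
  lten <- -pchisq(stat, df, lower.tail = FALSE, log.p = TRUE) / log(10)
  list(lrt_stat = stat, df = df, pvalue = 10^(-lten), neglog10p = lten,
       flag = flag)
}

#' Continuous-dosage genotype encoding
#'
#' One design column: the expected allele dosage of each individual
#' ([continuous_dosage]). Masked individuals give `NA` rows.
#'
#' @param M single-marker dosage-probability matrix (individuals x K+1).
#' @return One-column design matrix.
#' @export
encode_continuous <- function(M) {
  matrix(continuous_dosage(M), ncol = 1,
         dimnames = list(rownames(M), "dosage"))
}

#' Dosage-matrix (Dogmat) genotype encoding
#'
#' Uses the dosage-probability matrix itself as the design block: dosage
#' classes with (near-)zero total probability mass are dropped, then the
#' class with the largest mass is dropped as the reference to break the
#' rows-sum-to-one collinearity with the intercept. Markers with fewer than
#' two populated classes are untestable.
#'
#' @param M single-marker dosage-probability matrix (individuals x K+1).
#' @param tol mass threshold below which a dosage class counts as absent.
#' @return Design matrix with one column per retained dosage class, or
#'   `NULL` when the marker is untestable.
#' @export
encode_dogmat <- function(M, tol = 1e-8) {
  ok <- !is.na(M[, 1])
  s <- colSums(M[ok, , drop = FALSE])
  present <- which(s > tol)
  if (length(present) < 2) return(NULL)
  drop_ref <- present[which.max(s[present])]
  keep <- setdiff(present, drop_ref)
  M[, keep, drop = FALSE]
}

.encode_marker <- function(M, encoding) {
  if (encoding == "continuous") encode_continuous(M) else encode_dogmat(M)
}

#' Genome-wide marker-phenotype association scan
#'
#' Tests every marker for association with a phenotype by the GLM
#' likelihood-ratio test ([fit_glm_lrt]) under the chosen genotype encoding.
#' Individuals are matched by ID; at each marker, individuals with a masked
#' genotype or missing phenotype are excluded pairwise.
#'
#' @param dosage a `dosage_array` from [dosage_probs] (rownames = individual
#'   ids), or a named list of single-marker probability matrices.
#' @param phenotype named numeric vector (names = individual ids), e.g. from
#'   [read_phenotype].
#' @param trait_type `"continuous"` or `"binary"`; default taken from the
#'   phenotype's `trait_type` attribute, else `"continuous"`.
#' @param encoding `"continuous"` or `"dogmat"`.
#' @param marker_meta optional data.frame (rownames = marker ids) with
#'   `chrom`, `pos`, `homologous_group`, as in a [read_count_table].
#' @param mode LRT mode, see [fit_glm_lrt].
#' @return An object of class `assoc_scan`: list with `results` (one row per
#'   marker: marker_id, chrom, pos, homologous_group, encoding, n_used,
#'   lrt_stat, df, pvalue, neglog10p, flag), `encoding`, `trait_type`,
#'   `mode`, `n_individuals`.
#' @seealso [perm_gev_threshold] for genome-wide significance thresholds.
#' @export
assoc_scan <- function(dosage, phenotype, trait_type = NULL,
                       encoding = c("continuous", "dogmat"),
                       marker_meta = NULL, mode = c("unscaled", "scaled")) {
  encoding <- match.arg(encoding)
  mode <- match.arg(mode)
  if (is.null(trait_type))
    trait_type <- attr(phenotype, "trait_type") %||% "continuous"
  slices <- if (is.list(dosage)) dosage else {
    s <- .marker_slices(dosage)
    names(s) <- dimnames(dosage)[[3]]
    s
  }
  ind <- rownames(slices[[1]])
  if (is.null(ind) || is.null(names(phenotype)))
    stop("both genotypes and phenotype must carry individual ids")
  ids <- intersect(ind, names(phenotype)[!is.na(phenotype)])
  if (length(ids) == 0) stop("no overlapping individuals between genotypes ",
                             "and phenotype")
  y_all <- phenotype[ids]

  res <- vector("list", length(slices))
  for (j in seq_along(slices)) {
    M <- slices[[j]][ids, , drop = FALSE]
    use <- !is.na(M[, 1])
    X <- .encode_marker(M, encoding)
    if (is.null(X)) {
      r <- list(lrt_stat = 0, df = 0L, pvalue = 1, neglog10p = 0,
                flag = "untestable")
    } else {
      r <- fit_glm_lrt(y_all[use], X[use, , drop = FALSE], trait_type, mode)
    }
    r$n_used <- sum(use)
    res[[j]] <- r
  }
  mids <- names(slices) %||% paste0("m", seq_along(slices))
  meta_of <- function(col, default) {
    if (!is.null(marker_meta) && col %in% names(marker_meta)) {
      marker_meta[mids, col]
    } else rep(default, length(mids))
  }
  results <- data.frame(
    marker_id = mids,
    chrom = meta_of("chrom", NA_character_),
    pos = meta_of("pos", NA_integer_),
    homologous_group = meta_of("homologous_group", NA_integer_),
    encoding = encoding,
    n_used = vapply(res, `[[`, numeric(1), "n_used"),
    lrt_stat = vapply(res, `[[`, numeric(1), "lrt_stat"),
    df = vapply(res, `[[`, numeric(1), "df"),
    pvalue = vapply(res, `[[`, numeric(1), "pvalue"),
    neglog10p = vapply(res, `[[`, numeric(1), "neglog10p"),
    flag = vapply(res, function(r) as.character(r$flag), character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(results = results, encoding = encoding,
                 trait_type = trait_type, mode = mode,
                 n_individuals = length(ids), call = match.call()),
            class = "assoc_scan")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.assoc_scan <- function(x, ...) {
  cat(sprintf(
    "assoc_scan: %d markers, %d individuals, %s encoding, %s trait (%s LRT)\n",
    nrow(x$results), x$n_individuals, x$encoding, x$trait_type, x$mode))
  top <- x$results[order(-x$results$neglog10p), ][1, ]
  cat(sprintf("  top hit: %s  -log10(p) = %.2f\n",
              top$marker_id, top$neglog10p))
  invisible(x)
}

#' @export
summary.assoc_scan <- function(object, n_top = 10, ...) {
  r <- object$results
  testable <- is.na(r$flag) | r$flag == "NA"
  cat(sprintf("Association scan (%s encoding, %s trait)\n",
              object$encoding, object$trait_type))
  cat(sprintf("  markers: %d tested, %d flagged\n",
              sum(testable), sum(!testable)))
  cat(sprintf("  individuals: %d\n", object$n_individuals))
  cat("\nTop markers:\n")
  print(r[order(-r$neglog10p), ][seq_len(min(n_top, nrow(r))),
        c("marker_id", "chrom", "pos", "n_used", "lrt_stat", "df",
          "neglog10p")], row.names = FALSE)
  invisible(object)
}

#' Manhattan-style plot of an association scan
#'
#' Markers are grouped along the x axis by homologous linkage group when
#' annotated (else by chromosome/scaffold, else plotted in input order) and
#' coloured alternately; an optional genome-wide threshold is drawn as a
#' horizontal line.
#'
#' @param x an `assoc_scan` object.
#' @param threshold optional -log10(p) threshold (e.g. from
#'   [perm_gev_threshold]).
#' @param ... further arguments passed to [graphics::plot].
#' @export
plot.assoc_scan <- function(x, threshold = NULL, ...) {
  r <- x$results
  grp <- r$homologous_group
  if (all(is.na(grp))) grp <- r$chrom
  if (all(is.na(grp))) grp <- rep(1L, nrow(r))
  grp <- factor(grp, exclude = NULL)
  ord <- order(grp, r$pos, na.last = TRUE)
  r <- r[ord, ]; grp <- grp[ord]
  col <- c("#374e8e", "#8aa0d1")[1 + (as.integer(grp) %% 2)]
  plot(seq_len(nrow(r)), r$neglog10p, pch = 20, col = col,
       xlab = "marker (grouped)", ylab = expression(-log[10](italic(p))),
       ...)
  if (!is.null(threshold)) abline(h = threshold, col = "red", lwd = 1.5)
  invisible(x)
}

#' Write scan results as TSV
#'
#' @param scan an `assoc_scan` object.
#' @param path output file.
#' @export
write_scan_tsv <- function(scan, path) {
  write.table(scan$results, path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(scan)
}

## Fast Gaussian LRT engine for permutation scans.
## For each marker design X_j (rows = its usable individuals), the unscaled
## deviance drop RSS0 - RSS1 equals ||Q_j' y_j||^2 where Q_j is an
## orthonormal basis of the column-centred design (centred columns are
## orthogonal to the intercept). Precomputing Q_j makes each permutation a
## single crossprod. Exactly equals the glm() route (tested).
.gaussian_marker_basis <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  qrx <- qr(Xc)
  if (qrx$rank == 0) return(NULL)
  qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]
}

## designs: list of per-marker lists(list(rows = integer idx, Q = basis));
## Y: n x n_perm matrix of (permuted) phenotypes. Returns markers x n_perm
## matrix of -log10 p-values. mode = "unscaled" uses the raw deviance drop
## ||Q'y||^2; mode = "scaled" divides by the full-model dispersion
## (RSS1 / (n - df - 1)), matching fit_glm_lrt.
.gaussian_engine_neglog10p <- function(designs, Y, mode = "unscaled") {
  out <- matrix(0, length(designs), ncol(Y))
  for (j in seq_along(designs)) {
    d <- designs[[j]]
    if (is.null(d)) next
    Yj <- Y[d$rows, , drop = FALSE]
    df <- ncol(d$Q)
    stat <- colSums(crossprod(d$Q, Yj)^2)
    if (mode == "scaled") {
      nj <- length(d$rows)
      rss0 <- colSums(Yj^2) - nj * colMeans(Yj)^2
      disp <- (rss0 - stat) / (nj - df - 1)
      stat <- ifelse(disp > 0, stat / disp, 0)
    }
    out[j, ] <- -pchisq(stat, df, lower.tail = FALSE,
                        log.p = TRUE) / log(10)
  }
  out
}

## build per-marker bases for the engine; returns list parallel to slices,
## NULL where untestable
.build_marker_designs <- function(slices, ids, encoding) {
  lapply(slices, function(M) {
    M <- M[ids, , drop = FALSE]
    use <- which(!is.na(M[, 1]))
    if (length(use) < 3) return(NULL)
    X <- .encode_marker(M, encoding)
    if (is.null(X)) return(NULL)
    Q <- .gaussian_marker_basis(X[use, , drop = FALSE])
    if (is.null(Q)) return(NULL)
    list(rows = use, Q = Q)
  })
}
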