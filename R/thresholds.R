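#' Per-permutation maxima of the association scan
#'
#' Permutes the phenotype vector across individuals (genotypes untouched —
#' with no covariates this is the exchangeable null), reruns the scan for
#' each replicate and records the genome-wide maximum -log10(p). Markers
#' that are untestable under the encoding are excluded, consistently with
#' the observed scan. For continuous traits in `"unscaled"` mode the scan uses
#' a vectorised projection engine that reproduces the `glm()` statistics
#' exactly; binary traits refit logistic models per replicate.
#'
#' Per-replicate seeds are derived from `seed` by a counter, so individual
#' replicates are reproducible independently of each other.
#'
#' @inheritParams assoc_scan
#' @param n_perm number of permutation replicates (default 1000; fewer than
#'   50 triggers a warning since the extreme-value fit becomes unstable).
#' @param seed integer master seed.
#' @return Numeric vector of length `n_perm` of per-replicate maxima, with
#'   attribute `seed`.
#' @export
permutation_maxima <- function(dosage, phenotype, trait_type = NULL,
                               encoding = c("continuous", "dogmat"),
                               n_perm = 1000, seed = 1,
                               mode = c("unscaled", "scaled")) {
  encoding <- match.arg(encoding)
  mode <- match.arg(mode)
  if (n_perm < 50)
    warning("n_perm < 50: generalized-extreme-value fit will be unstable")
  if (is.null(trait_type))
    trait_type <- attr(phenotype, "trait_type") %||% "continuous"
  slices <- if (is.list(dosage)) dosage else .marker_slices(dosage)
  ind <- rownames(slices[[1]])
  ids <- intersect(ind, names(phenotype)[!is.na(phenotype)])
  if (length(ids) == 0) stop("no overlapping individuals")
  y <- unname(phenotype[ids])
  n <- length(y)
  if (max(y) - min(y) < 1e-12) {
    warning("constant phenotype: permutation maxima are degenerate")
    return(structure(rep(0, n_perm), seed = seed))
  }
  perms <- vapply(seq_len(n_perm), function(k) {
    set.seed(seed + k)
    sample.int(n)
  }, integer(n))

  if (trait_type == "continuous") {
    designs <- .build_marker_designs(slices, ids, encoding)
    keep <- !vapply(designs, is.null, logical(1))
    if (!any(keep)) stop("no testable markers")
    Y <- matrix(y[perms], n, n_perm)
    nl <- .gaussian_engine_neglog10p(designs[keep], Y, mode = mode)
    mx <- apply(nl, 2, max)
  } else {
    mx <- numeric(n_perm)
    for (k in seq_len(n_perm)) {
      yp <- stats::setNames(y[perms[, k]], ids)
      sc <- assoc_scan(slices, yp, trait_type = trait_type,
                       encoding = encoding, mode = mode)
      r <- sc$results
      ok <- is.na(r$flag) | r$flag %in% c("separation")
      mx[k] <- max(r$neglog10p[ok])
    }
  }
  structure(mx, seed = seed)
}

## negative log-likelihood of the GEV (location mu, scale sigma, shape xi);
## shape > 0 is the heavy-tailed Frechet branch. Gumbel limit at |xi| ~ 0.
.gev_nll <- function(par, x) {
  mu <- par[1]; sigma <- exp(par[2]); xi <- par[3]
  z <- (x - mu) / sigma
  if (abs(xi) < 1e-9) {
    return(length(x) * log(sigma) + sum(z) + sum(exp(-z)))
  }
  t <- 1 + xi * z
  if (any(t <= 0)) return(Inf)
  length(x) * log(sigma) + (1 + 1 / xi) * sum(log(t)) + sum(t^(-1 / xi))
}

#' Maximum-likelihood fit of a generalized extreme-value distribution
#'
#' Fits location, scale and shape by direct numerical maximum likelihood
#' (Nelder-Mead on (loc, log scale, shape), initialised at Gumbel moment
#' estimates). Shape > 0 is the heavy-tailed (Frechet) branch. On
#' non-convergence or degenerate input the fit is marked unconverged and
#' downstream thresholds fall back to empirical quantiles with a warning.
#'
#' @param maxima numeric vector of block maxima (e.g. permutation maxima);
#'   at least 50 finite values with positive variance are required for a
#'   trustworthy fit.
#' @return List with `loc`, `scale`, `shape`, `loglik`, `converged`.
#' @export
fit_gev <- function(maxima) {
  x <- maxima[is.finite(maxima)]
  if (length(x) < 50 || stats::sd(x) < 1e-12) {
    warning("fewer than 50 finite maxima or zero variance: GEV fit ",
            "unavailable, falling back to empirical quantiles")
    return(list(loc = NA_real_, scale = NA_real_, shape = NA_real_,
                loglik = NA_real_, converged = FALSE))
  }
  s0 <- stats::sd(x) * sqrt(6) / pi
  m0 <- mean(x) - 0.5772156649 * s0
  opt <- stats::optim(c(m0, log(s0), 0.1), .gev_nll, x = x,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  if (opt$convergence != 0 || !is.finite(opt$value)) {
    warning("GEV maximum-likelihood fit did not converge; thresholds will ",
            "use empirical quantiles")
    return(list(loc = NA_real_, scale = NA_real_, shape = NA_real_,
                loglik = NA_real_, converged = FALSE))
  }
  list(loc = opt$par[1], scale = exp(opt$par[2]), shape = opt$par[3],
       loglik = -opt$value, converged = TRUE)
}

#' Upper-tail quantile of a fitted GEV
#'
#' Returns the 1 - alpha quantile:
#' loc + scale/shape * ((-ln(1 - alpha))^(-shape) - 1) for shape != 0, with
#' the Gumbel limit loc - scale * ln(-ln(1 - alpha)) at shape = 0.
#'
#' @param params list with `loc`, `scale`, `shape` (e.g. from [fit_gev]).
#' @param alpha genome-wide type-I error rate, in (0, 1).
#' @return The threshold on the -log10(p) scale.
#' @export
gev_quantile <- function(params, alpha) {
  stopifnot(alpha > 0, alpha < 1)
  ll <- -log(1 - alpha)
  with(params, {
    if (abs(shape) < 1e-9) loc - scale * log(ll)
    else loc + scale / shape * (ll^(-shape) - 1)
  })
}

#' Genome-wide significance thresholds by permutation and GEV tail fit
#'
#' Runs [permutation_maxima], fits a GEV to the maxima by maximum likelihood
#' ([fit_gev]) and extracts -log10(p) thresholds at the requested
#' genome-wide alpha levels. A small number of permutations tends to
#' underestimate thresholds; the extreme-value model uses the whole maxima
#' sample rather than only the empirical tail, which is why it is preferred
#' over raw quantiles.
#'
#' @inheritParams permutation_maxima
#' @param alphas genome-wide significance levels (default 0.10, 0.05, 0.01).
#' @return Object of class `gev_threshold`: list with `n_perm`, `maxima`,
#'   `loc`, `scale`, `shape`, `converged`, `thresholds` (named by alpha),
#'   `alphas`, `seed`, `encoding`, `trait_type`.
#' @export
perm_gev_threshold <- function(dosage, phenotype, trait_type = NULL,
                               encoding = c("continuous", "dogmat"),
                               n_perm = 1000, alphas = c(0.10, 0.05, 0.01),
                               seed = 1, mode = c("unscaled", "scaled")) {
  encoding <- match.arg(encoding)
  mode <- match.arg(mode)
  if (is.null(trait_type))
    trait_type <- attr(phenotype, "trait_type") %||% "continuous"
  mx <- permutation_maxima(dosage, phenotype, trait_type, encoding,
                           n_perm = n_perm, seed = seed, mode = mode)
  fit <- fit_gev(mx)
  thr <- if (fit$converged) {
    vapply(alphas, function(a) gev_quantile(fit, a), numeric(1))
  } else {
    vapply(alphas, function(a) unname(stats::quantile(mx, 1 - a)),
           numeric(1))
  }
  names(thr) <- paste0(format(100 * alphas, trim = TRUE), "%")
  structure(list(n_perm = n_perm, maxima = as.numeric(mx),
                 loc = fit$loc, scale = fit$scale, shape = fit$shape,
                 converged = fit$converged, thresholds = thr,
                 alphas = alphas, seed = seed, encoding = encoding,
                 trait_type = trait_type),
            class = "gev_threshold")
}

#' @export
print.gev_threshold <- function(x, ...) {
  cat(sprintf(
    "gev_threshold: %d permutations (%s encoding, %s trait), seed %d\n",
    x$n_perm, x$encoding, x$trait_type, x$seed))
  if (x$converged) {
    cat(sprintf("  GEV fit: loc = %.3f, scale = %.3f, shape = %.3f\n",
                x$loc, x$scale, x$shape))
  } else cat("  GEV fit unavailable; empirical quantiles reported\n")
  cat("  -log10(p) thresholds:\n")
  for (i in seq_along(x$thresholds))
    cat(sprintf("    alpha %4.2f : %.3f\n", x$alphas[i], x$thresholds[i]))
  invisible(x)
}

#' Write a threshold report as TSV
#'
#' One row per alpha level, with the GEV parameters, replicate count and
#' seed alongside the -log10(p) threshold.
#'
#' @param x a `gev_threshold` object.
#' @param path output file.
#' @export
write_threshold_tsv <- function(x, path) {
  df <- data.frame(encoding = x$encoding, trait = x$trait_type,
                   n_perm = x$n_perm, loc = x$loc, scale = x$scale,
                   shape = x$shape, alpha = x$alphas,
                   threshold = unname(x$thresholds), seed = x$seed)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(x)
}
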