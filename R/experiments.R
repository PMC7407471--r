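## one-hot probability matrix for known true dosages
.one_hot_probs <- function(dosages, K, ids = NULL) {
  M <- matrix(0, length(dosages), K + 1,
              dimnames = list(ids, as.character(0:K)))
  M[cbind(seq_along(dosages), dosages + 1)] <- 1
  M
}

## naive probability matrix for depth vectors (vectorised over individuals)
.naive_probs_matrix <- function(DP, RD, params, ids = NULL) {
  K <- params$ploidy
  lp <- sapply(0:K, function(d)
    RD * log(params$r[d + 1]) + (DP - RD) * log1p(-params$r[d + 1]))
  lp <- lp - apply(lp, 1, max)
  p <- exp(lp)
  p <- p / rowSums(p)
  dimnames(p) <- list(ids, as.character(0:K))
  p
}

## estimate a single marker's dosage-probability matrix under an estimator
.estimate_marker <- function(DP, RD, estimator, prior, params, seq_error) {
  switch(estimator,
    naive = .naive_probs_matrix(DP, RD, params),
    noise_aware = {
      np <- estimate_noise_params(DP, RD, prior, seq_error = seq_error)
      noise_aware_posterior(DP, RD, prior, bias = np$bias, od = np$od,
                            seq_error = seq_error)
    },
    stop("unknown estimator: ", estimator))
}

#' Dosage-call accuracy experiment
#'
#' For each condition (marker segregation type x read depth x noise setting
#' x estimator), repeatedly simulates an S1 population's true dosages and
#' read counts, estimates the dosage-probability matrix, calls dosages by
#' argmax, and scores the proportion of individuals called correctly.
#' The noise setting `TRUE` uses allelic bias 0.5 with overdispersion 0.05;
#' `FALSE` uses bias 1 with overdispersion 0. The noise-aware estimator
#' uses the population segregation prior and grid-estimated noise
#' parameters; the naive estimator is the plain binomial model.
#'
#' @param conditions data.frame with columns `marker_type` (SS/DD/TT),
#'   `depth`, `noise` (logical), `estimator` ("naive"/"noise_aware").
#'   Default: the full naive grid over SS/DD/TT x 20/40/100 x noise on/off.
#' @param R replicates per condition (default 100).
#' @param n individuals per replicate (default 100).
#' @param seed integer seed.
#' @param ploidy,e,seq_error dosage-model settings.
#' @return data.frame: one row per condition with `accuracy` (mean
#'   proportion correct), `se` (sd/sqrt(R)) and `R`.
#' @export
accuracy_experiment <- function(conditions = NULL, R = 100, n = 100,
                                seed = 1, ploidy = 6, e = 0.001,
                                seq_error = 0.001) {
  if (is.null(conditions)) {
    conditions <- expand.grid(marker_type = c("SS", "DD", "TT"),
                              depth = c(20, 40, 100),
                              noise = c(FALSE, TRUE),
                              estimator = "naive",
                              stringsAsFactors = FALSE)
  }
  params <- dosage_params(ploidy, e)
  set.seed(seed)
  out <- conditions
  out$accuracy <- out$se <- NA_real_
  out$R <- R
  for (ci in seq_len(nrow(conditions))) {
    cd <- conditions[ci, ]
    cfg <- sim_config(ploidy = ploidy, n_individuals = n,
                      marker_type = cd$marker_type, depth = cd$depth,
                      bias = if (cd$noise) 0.5 else 1,
                      od = if (cd$noise) 0.05 else 0,
                      seq_error = seq_error, n_background_markers = 0)
    prior <- offspring_dosage_distribution(ploidy,
                                           .type_dosage[cd$marker_type])
    acc <- numeric(R)
    for (rep in seq_len(R)) {
      truth <- sample(0:ploidy, n, replace = TRUE, prob = prior)
      rc <- simulate_read_counts(truth, cfg)
      M <- .estimate_marker(rc$DP, rc$RD, cd$estimator, prior, params,
                            seq_error)
      acc[rep] <- mean(call_dosage(M) == truth)
    }
    out$accuracy[ci] <- mean(acc)
    out$se[ci] <- stats::sd(acc) / sqrt(R)
  }
  out
}

#' Association-power experiment
#'
#' For each condition, the genome-wide threshold is calibrated once from a
#' simulated null background-marker panel (permutation + GEV at the given
#' alpha), then `R` replicate populations are simulated: linked causal
#' gene and marker, phenotype at the configured PVE, read counts and dosage
#' estimation for the focal marker, and the GLM likelihood-ratio test under
#' the condition's encoding. Power is the fraction of replicates whose
#' focal-marker -log10(p) exceeds the threshold.
#'
#' @param conditions data.frame with columns `marker_type`, `gene_type`,
#'   `effect_model`, `pve`, `distance_cM`, `depth`, `noise` (logical),
#'   `estimator` ("true"/"naive"/"noise_aware"), `encoding`
#'   ("continuous"/"dogmat").
#' @param R replicates per condition (default 100).
#' @param n individuals (default 248).
#' @param n_background background markers for threshold calibration
#'   (default 500).
#' @param n_perm permutation replicates for the threshold (default 200,
#'   the reduced desk-scale setting; 1000 matches the full design).
#' @param alpha genome-wide significance level (default 0.05).
#' @param seed integer seed.
#' @param ploidy,e,seq_error dosage-model settings.
#' @param lambda_mode crossover-rate reading, see [sim_config].
#' @param mode LRT mode (see [fit_glm_lrt]); default `"scaled"`, because
#'   cross-condition power comparisons need a statistic whose permutation
#'   threshold does not inherit the calibration phenotype's variance scale.
#' @return data.frame: the conditions plus `power`, `se`, `threshold`, `R`.
#' @export
power_experiment <- function(conditions, R = 100, n = 248,
                             n_background = 500, n_perm = 200,
                             alpha = 0.05, seed = 1, ploidy = 6,
                             e = 0.001, seq_error = 0.001,
                             lambda_mode = c("morgan", "literal"),
                             mode = c("scaled", "unscaled")) {
  lambda_mode <- match.arg(lambda_mode)
  mode <- match.arg(mode)
  params <- dosage_params(ploidy, e)
  out <- conditions
  out$power <- out$se <- out$threshold <- NA_real_
  out$R <- R
  for (ci in seq_len(nrow(conditions))) {
    cd <- conditions[ci, ]
    cfg <- sim_config(ploidy = ploidy, n_individuals = n,
                      marker_type = cd$marker_type,
                      gene_type = cd$gene_type,
                      distance_cM = cd$distance_cM, depth = cd$depth,
                      lambda_mode = lambda_mode,
                      bias = if (cd$noise) 0.5 else 1,
                      od = if (cd$noise) 0.05 else 0,
                      seq_error = seq_error,
                      effect_model = cd$effect_model, pve = cd$pve,
                      n_background_markers = n_background)
    prior_by_type <- lapply(.type_dosage, function(l)
      offspring_dosage_distribution(ploidy, l))

    ## threshold: one calibration population per condition. Retry a few
    ## seeds if the drawn gene happens to be monomorphic in genetic value
    ## (possible for rare classes, e.g. simplex-dominant TT genes).
    pop0 <- NULL
    for (try in 0:19) {
      pop0 <- tryCatch(simulate_population(cfg, seed = seed + 131 * ci + try),
                       error = function(err) NULL)
      if (!is.null(pop0)) break
    }
    if (is.null(pop0)) stop("could not draw a polymorphic calibration ",
                            "population for condition ", ci)
    bg <- pop0$background
    slices <- lapply(seq_len(ncol(bg$DP)), function(j) {
      M <- if (cd$estimator == "true") {
        .one_hot_probs(bg$dosages[, j], ploidy)
      } else {
        .estimate_marker(bg$DP[, j], bg$RD[, j], cd$estimator,
                         prior_by_type[[bg$types[j]]], params, seq_error)
      }
      rownames(M) <- pop0$individual_ids
      M
    })
    thr <- perm_gev_threshold(slices, pop0$phenotype,
                              encoding = cd$encoding, n_perm = n_perm,
                              alphas = alpha, seed = seed + 131 * ci,
                              mode = mode)
    threshold <- unname(thr$thresholds[1])

    ## replicates: focal marker only
    hits <- logical(R)
    prior <- prior_by_type[[cd$marker_type]]
    for (rep in seq_len(R)) {
      set.seed(seed + 131 * ci + 7919 * rep)
      pair <- simulate_linked_pair(cfg)
      ## a gene monomorphic in genetic value is undetectable by design:
      ## the phenotype is then pure environmental noise and the replicate
      ## counts as an ordinary (almost surely failed) detection attempt
      y <- tryCatch(simulate_phenotype(pair$gene, cfg),
                    error = function(err) rnorm(length(pair$gene)))
      M <- if (cd$estimator == "true") {
        .one_hot_probs(pair$marker, ploidy)
      } else {
        rc <- simulate_read_counts(pair$marker, cfg)
        .estimate_marker(rc$DP, rc$RD, cd$estimator, prior, params,
                         seq_error)
      }
      X <- .encode_marker(M, cd$encoding)
      if (is.null(X)) next
      r <- fit_glm_lrt(as.numeric(y), X, trait_type = "continuous",
                       mode = mode)
      hits[rep] <- r$neglog10p > threshold
    }
    p <- mean(hits)
    out$power[ci] <- p
    out$se[ci] <- sqrt(p * (1 - p) / R)
    out$threshold[ci] <- threshold
  }
  out
}

#' Run the full mapping pipeline on VCF + phenotype files
#'
#' The complete chain: read depth fields from the VCF, apply the
#' per-genotype depth window and per-marker missingness filters, compute
#' dosage-probability matrices, drop near-monomorphic markers by MGF, scan
#' for association under the chosen encoding, and calibrate the genome-wide
#' threshold by permutation + GEV. Deterministic given `seed`.
#'
#' @param vcf_path VCF with per-genotype DP and RD (or AD) fields.
#' @param phenotype_path TSV `id<TAB>value`.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param encoding `"continuous"` or `"dogmat"`.
#' @param n_perm permutation replicates (default 1000).
#' @param seed integer seed.
#' @param out_dir optional directory; when given, writes `scan.tsv`,
#'   `thresholds.tsv` and `manhattan.png`.
#' @param min_dp,max_dp,max_missing,mgf_threshold filter settings
#'   (defaults 10, 300, 0.5, 0.95).
#' @param ploidy,e dosage-model settings.
#' @param alphas genome-wide alpha levels.
#' @return List with `scan` (an `assoc_scan`), `threshold`
#'   (a `gev_threshold`), `table` (the filtered [read_count_table]) and
#'   `dosage` (the filtered `dosage_array`).
#' @export
run_real_pipeline <- function(vcf_path, phenotype_path,
                              trait_type = c("continuous", "binary"),
                              encoding = c("continuous", "dogmat"),
                              n_perm = 1000, seed = 1, out_dir = NULL,
                              min_dp = 10, max_dp = 300, max_missing = 0.5,
                              mgf_threshold = 0.95, ploidy = 6, e = 0.001,
                              alphas = c(0.10, 0.05, 0.01)) {
  trait_type <- match.arg(trait_type)
  encoding <- match.arg(encoding)
  stage <- function(what, expr) {
    tryCatch(expr, error = function(err)
      stop(what, ": ", conditionMessage(err), call. = FALSE))
  }
  tbl <- stage("reading VCF", read_vcf_counts(vcf_path, verbose = FALSE))
  tbl <- stage("depth filter", filter_depth(tbl, min_dp, max_dp))
  tbl <- stage("missingness filter", filter_missing(tbl, max_missing))
  if (length(tbl$marker_ids) == 0) stop("no markers survive the filters")
  pheno <- stage("reading phenotype",
                 read_phenotype(phenotype_path, trait_type))
  M <- stage("dosage estimation", dosage_probs(tbl, dosage_params(ploidy, e)))
  M <- stage("MGF filter", filter_mgf(M, mgf_threshold))
  if (dim(M)[3] == 0) stop("no markers survive the MGF filter")
  meta <- tbl$marker_meta[dimnames(M)[[3]], , drop = FALSE]
  scan <- stage("association scan",
                assoc_scan(M, pheno, trait_type = trait_type,
                           encoding = encoding, marker_meta = meta))
  thr <- stage("permutation thresholds",
               perm_gev_threshold(M, pheno, trait_type = trait_type,
                                  encoding = encoding, n_perm = n_perm,
                                  alphas = alphas, seed = seed))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_scan_tsv(scan, file.path(out_dir, "scan.tsv"))
    write_threshold_tsv(thr, file.path(out_dir, "thresholds.tsv"))
    grDevices::png(file.path(out_dir, "manhattan.png"), width = 900,
                   height = 400)
    plot(scan, threshold = thr$thresholds[match(0.05, thr$alphas)],
         main = basename(vcf_path))
    grDevices::dev.off()
  }
  list(scan = scan, threshold = thr, table = tbl, dosage = M)
}
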