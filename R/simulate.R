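#' Gamete dosage distribution under polysomic inheritance
#'
#' Random bivalent-equivalent chromosome segregation without double
#' reduction: a gamete receives K/2 of the K homologs uniformly at random,
#' so the number of reference alleles transmitted is hypergeometric,
#' P(k) = C(l, k) C(K - l, K/2 - k) / C(K, K/2) for parental dosage l.
#'
#' @param K even ploidy.
#' @param parent_dosage parental reference-allele dosage, 0..K.
#' @return Named probability vector over gamete dosages 0..K/2.
#' @export
gamete_dosage_distribution <- function(K, parent_dosage) {
  if (K %% 2 != 0) stop("ploidy must be even")
  stopifnot(parent_dosage >= 0, parent_dosage <= K)
  k <- 0:(K / 2)
  p <- dhyper(k, parent_dosage, K - parent_dosage, K / 2)
  names(p) <- k
  p
}

#' Offspring dosage distribution for S1/F1 populations
#'
#' Convolution of the two parents' independent gamete distributions; a
#' selfed (S1) parent contributes two independent meioses of the same
#' genotype, so pass the same dosage twice.
#'
#' @param K even ploidy.
#' @param parent1_dosage,parent2_dosage parental dosages, 0..K.
#' @return Named probability vector over offspring dosages 0..K.
#' @export
offspring_dosage_distribution <- function(K, parent1_dosage,
                                          parent2_dosage = parent1_dosage) {
  g1 <- gamete_dosage_distribution(K, parent1_dosage)
  g2 <- gamete_dosage_distribution(K, parent2_dosage)
  p <- as.vector(convolve(g1, rev(g2), type = "open"))
  p[p < 0] <- 0                      # fft round-off
  p <- p / sum(p)
  names(p) <- 0:K
  p
}

.type_dosage <- c(SS = 1L, DD = 2L, TT = 3L)

#' Simulation configuration
#'
#' Bundles the study conditions for the single-locus simulator: an
#' autohexaploid S1 (selfed) or F1 (biparental) population; marker and
#' causal-gene segregation types SS/DD/TT (both parents simplex, duplex or
#' triplex); marker-gene map distance with Poisson crossovers; a fixed or
#' resampled read-depth model; beta-binomial read noise (allelic bias,
#' overdispersion, sequencing error); and a single-locus genetic effect
#' (additive, simplex-dominant or diploidized-additive) at a controlled
#' proportion of phenotypic variance explained.
#'
#' @param ploidy even ploidy (default 6, autohexaploid).
#' @param population `"S1"` or `"F1"`.
#' @param n_individuals population size (default 248, a typical selfed
#'   mapping population).
#' @param marker_type,gene_type `"SS"`, `"DD"` or `"TT"` (parental dosage
#'   1, 2, 3).
#' @param distance_cM marker-gene genetic distance, >= 0.
#' @param lambda_mode `"morgan"` (Poisson crossover mean = cM / 100 per
#'   meiosis, the standard genetic reading of map distance) or `"literal"`
#'   (mean = the cM value itself; at 5 cM this implies five expected
#'   crossovers per meiosis, i.e. near-free recombination).
#' @param depth fixed read depth (scalar, e.g. 20/40/100) or an integer
#'   vector resampled with replacement as an empirical depth distribution.
#' @param bias,od,seq_error read-noise parameters (see [ref_fraction_xi];
#'   defaults 1, 0, 0.001 = no bias, no overdispersion).
#' @param effect_model `"Add"`, `"SimDom"` or `"DipAdd"`.
#' @param pve proportion of phenotypic variance explained by the gene,
#'   in (0, 1).
#' @param trait_type `"continuous"` or `"binary"`.
#' @param n_background_markers unlinked null markers for threshold
#'   calibration (default 500).
#' @param background_mix SS/DD/TT mixture for background marker types.
#' @param seed optional integer seed stored with the config.
#' @return Object of class `sim_config` (a list of the above).
#' @export
sim_config <- function(ploidy = 6, population = c("S1", "F1"),
                       n_individuals = 248,
                       marker_type = c("SS", "DD", "TT"),
                       gene_type = marker_type,
                       distance_cM = 0,
                       lambda_mode = c("morgan", "literal"),
                       depth = 40, bias = 1, od = 0, seq_error = 0.001,
                       effect_model = c("Add", "SimDom", "DipAdd"),
                       pve = 0.2,
                       trait_type = c("continuous", "binary"),
                       n_background_markers = 500,
                       background_mix = c(SS = 0.6, DD = 0.3, TT = 0.1),
                       seed = NULL) {
  population <- match.arg(population)
  marker_type <- match.arg(marker_type)
  gene_type <- match.arg(gene_type, c("SS", "DD", "TT"))
  lambda_mode <- match.arg(lambda_mode)
  effect_model <- match.arg(effect_model)
  trait_type <- match.arg(trait_type)
  stopifnot(ploidy %% 2 == 0, n_individuals >= 2, distance_cM >= 0,
            pve > 0, pve < 1, od >= 0, od < 1, bias > 0,
            all(depth >= 1), n_background_markers >= 0)
  structure(list(ploidy = as.integer(ploidy), population = population,
                 n_individuals = as.integer(n_individuals),
                 marker_type = marker_type, gene_type = gene_type,
                 distance_cM = distance_cM, lambda_mode = lambda_mode,
                 depth = depth, bias = bias, od = od,
                 seq_error = seq_error, effect_model = effect_model,
                 pve = pve, trait_type = trait_type,
                 n_background_markers = as.integer(n_background_markers),
                 background_mix = background_mix / sum(background_mix),
                 seed = seed),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %s, ploidy %d, n = %d, marker %s / gene %s at %.1f cM (%s)\n",
    x$population, x$ploidy, x$n_individuals, x$marker_type, x$gene_type,
    x$distance_cM, x$lambda_mode))
  cat(sprintf(
    "  depth %s, bias %.2f, od %.3f; effect %s, PVE %.2f, %s trait\n",
    paste(range(x$depth), collapse = "-"), x$bias, x$od, x$effect_model,
    x$pve, x$trait_type))
  invisible(x)
}

## Parental phase in maximal coupling: gene reference alleles occupy
## homologs 1..lg; marker reference alleles are stacked onto the gene-ref
## homologs first, so every gene-ref homolog carries a marker-ref allele
## whenever counts permit. The most favourable phase: power loss under
## mismatched segregation types is then due to the segregation itself.
.parent_phase <- function(K, gene_dosage, marker_dosage) {
  G <- as.integer(seq_len(K) <= gene_dosage)
  M <- integer(K)
  take <- min(marker_dosage, gene_dosage)
  if (take > 0) M[seq_len(take)] <- 1L
  rest <- marker_dosage - take
  if (rest > 0) M[gene_dosage + seq_len(rest)] <- 1L
  list(G = G, M = M)
}

## one meiosis: Poisson(lambda) crossovers, each swapping the gene-side
## allele between two homologs chosen without replacement, then a gamete of
## K/2 homologs drawn without replacement. Returns c(marker, gene) dosage.
.meiosis <- function(phase, K, lambda) {
  G <- phase$G
  if (lambda > 0) {
    nx <- rpois(1, lambda)
    for (i in seq_len(nx)) {
      hw <- sample.int(K, 2)
      G[hw] <- G[c(hw[2], hw[1])]
    }
  }
  idx <- sample.int(K, K / 2)
  c(sum(phase$M[idx]), sum(G[idx]))
}

#' Simulate a linked marker-gene dosage pair
#'
#' Generates true allele dosages for a causal gene and a linked marker in an
#' S1 or F1 population. Per meiosis the number of crossovers between the two
#' loci is Poisson with mean equal to the map distance (in cM in the default
#' literal mode; `"morgan"` mode uses cM/100); each crossover exchanges the
#' gene-side allele between two random homologs before the gamete is drawn.
#' Parent phases are built in maximal coupling (see [sim_config]). At
#' distance 0 with matched types, marker and gene dosages co-segregate
#' exactly; the marginal dosage law at any distance is
#' [offspring_dosage_distribution].
#'
#' @param config a [sim_config].
#' @param n number of individuals (default from config).
#' @return List with integer vectors `gene`, `marker` (dosages 0..K) and
#'   `crossovers` (total crossover count per individual).
#' @export
simulate_linked_pair <- function(config, n = config$n_individuals) {
  K <- config$ploidy
  lambda <- if (config$lambda_mode == "literal") config$distance_cM
            else config$distance_cM / 100
  p1 <- .parent_phase(K, .type_dosage[config$gene_type],
                      .type_dosage[config$marker_type])
  p2 <- if (config$population == "S1") p1
        else .parent_phase(K, .type_dosage[config$gene_type],
                           .type_dosage[config$marker_type])
  gene <- marker <- integer(n)
  for (i in seq_len(n)) {
    a <- .meiosis(p1, K, lambda)
    b <- .meiosis(p2, K, lambda)
    marker[i] <- a[1] + b[1]
    gene[i] <- a[2] + b[2]
  }
  list(gene = gene, marker = marker)
}

#' Simulate read counts for true dosages
#'
#' Total depths come from the configured depth model (fixed value or
#' empirical resampling); reference-read counts are beta-binomial with mean
#' [ref_fraction_xi]`(d/K, bias, seq_error)` and overdispersion `od`
#' (binomial when `od = 0`). The same mean-fraction formula is used by
#' [noise_aware_posterior], so simulator and estimator share one noise
#' model.
#'
#' @param dosages integer vector of true dosages 0..K.
#' @param config a [sim_config].
#' @return List with integer vectors `DP` and `RD`.
#' @export
simulate_read_counts <- function(dosages, config) {
  K <- config$ploidy
  n <- length(dosages)
  DP <- if (length(config$depth) == 1L) rep(as.integer(config$depth), n)
        else sample(as.integer(config$depth), n, replace = TRUE)
  xi <- ref_fraction_xi((0:K) / K, config$bias, config$seq_error)[dosages + 1]
  if (config$od == 0) {
    RD <- rbinom(n, DP, xi)
  } else {
    a <- xi * (1 - config$od) / config$od
    b <- (1 - xi) * (1 - config$od) / config$od
    p <- numeric(n)
    pos <- xi > 0 & xi < 1
    p[pos] <- rbeta(sum(pos), a[pos], b[pos])
    p[xi >= 1] <- 1
    RD <- rbinom(n, DP, p)
  }
  list(DP = DP, RD = RD)
}

#' Genetic value of a dosage under an effect model
#'
#' Additive (`"Add"`): effect proportional to dosage, g = d/K.
#' Simplex-dominant (`"SimDom"`): all dosage-carrying genotypes equal one
#' homozygote, g = 0 at d = 0 and 1 otherwise. Diploidized-additive
#' (`"DipAdd"`): all heterozygotes equivalent and exactly halfway between
#' the homozygotes, g = 0, 1/2, 1 at d = 0, 1..K-1, K. Values lie in
#' \[0, 1\]; since heritability is scale-free this normalisation is
#' harmless.
#'
#' @param d integer dosage(s) in 0..K.
#' @param model `"Add"`, `"SimDom"` or `"DipAdd"`.
#' @param K ploidy (default 6).
#' @return Numeric genetic value(s).
#' @export
genetic_effect <- function(d, model = c("Add", "SimDom", "DipAdd"), K = 6) {
  model <- match.arg(model)
  stopifnot(all(d >= 0), all(d <= K))
  switch(model,
         Add = d / K,
         SimDom = as.numeric(d >= 1),
         DipAdd = ifelse(d == 0, 0, ifelse(d == K, 1, 0.5)))
}

#' Simulate a phenotype at a controlled PVE
#'
#' Continuous traits: y = g + e with e ~ Normal(0, s2) and
#' s2 = Var(g) (1 - PVE) / PVE computed from the realized sample variance
#' of the genetic values, so the expected variance ratio equals the target
#' PVE by construction. Binary traits (an extension, clearly labelled as
#' such): y = 1 with probability logistic(a + b g), where b matches the
#' target PVE on the latent logistic scale
#' (b^2 Var(g) / (b^2 Var(g) + pi^2/3) = PVE) and a centres the prevalence
#' near 1/2.
#'
#' @param gene_dosages integer vector of true causal-gene dosages.
#' @param config a [sim_config].
#' @return Named list-free numeric vector `y` with attributes `g` (genetic
#'   values) and `sigma2` (residual variance, continuous traits).
#' @export
simulate_phenotype <- function(gene_dosages, config) {
  g <- genetic_effect(gene_dosages, config$effect_model, config$ploidy)
  vg <- stats::var(g)
  if (!is.finite(vg) || vg < 1e-12)
    stop("constant genetic values: PVE undefined")
  n <- length(g)
  if (config$trait_type == "continuous") {
    s2 <- vg * (1 - config$pve) / config$pve
    y <- g + rnorm(n, 0, sqrt(s2))
  } else {
    b <- sqrt((pi^2 / 3) * config$pve / ((1 - config$pve) * vg))
    a <- -b * mean(g)
    y <- rbinom(n, 1, stats::plogis(a + b * g))
    s2 <- pi^2 / 3
  }
  structure(y, g = g, sigma2 = s2)
}

#' Simulate unlinked background markers
#'
#' Draws `n_background_markers` markers independent of the phenotype, with
#' segregation types sampled from the configured SS/DD/TT mixture, dosages
#' i.i.d. from the corresponding offspring distribution, and read counts
#' from [simulate_read_counts]. These play the role of the genome-wide
#' null marker set when calibrating permutation thresholds.
#'
#' @param config a [sim_config].
#' @return List with `types` (character vector), `dosages`, `DP`, `RD`
#'   (integer matrices individuals x markers).
#' @export
simulate_background_markers <- function(config) {
  m <- config$n_background_markers
  n <- config$n_individuals
  K <- config$ploidy
  types <- sample(names(config$background_mix), m, replace = TRUE,
                  prob = config$background_mix)
  dos <- matrix(0L, n, m)
  DP <- RD <- matrix(0L, n, m)
  pops <- if (config$population == "S1") {
    lapply(.type_dosage, function(l) offspring_dosage_distribution(K, l))
  } else {
    lapply(.type_dosage, function(l) offspring_dosage_distribution(K, l, l))
  }
  for (j in seq_len(m)) {
    p <- pops[[types[j]]]
    dos[, j] <- sample(0:K, n, replace = TRUE, prob = p)
    rc <- simulate_read_counts(dos[, j], config)
    DP[, j] <- rc$DP
    RD[, j] <- rc$RD
  }
  ids <- sprintf("bg%04d", seq_len(m))
  colnames(dos) <- colnames(DP) <- colnames(RD) <- ids
  list(types = stats::setNames(types, ids), dosages = dos, DP = DP, RD = RD)
}

#' Simulate a complete single-locus mapping population
#'
#' Master generator: draws the linked causal-gene/marker dosage pair, the
#' focal marker's read counts, a phenotype at the configured PVE, and an
#' unlinked background marker panel. Fully reproducible given
#' `config$seed` (or the `seed` argument).
#'
#' @param config a [sim_config].
#' @param seed integer seed; overrides `config$seed` when given.
#' @return Object of class `sim_population`: list with `config`,
#'   `individual_ids`, `gene_dosages`, `marker_dosages`, `marker_DP`,
#'   `marker_RD`, `phenotype` (named vector with `trait_type` attribute),
#'   `g`, `sigma2`, `background` (see [simulate_background_markers]).
#' @export
simulate_population <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_individuals
  pair <- simulate_linked_pair(config)
  rc <- simulate_read_counts(pair$marker, config)
  y <- simulate_phenotype(pair$gene, config)
  bg <- if (config$n_background_markers > 0)
    simulate_background_markers(config) else NULL
  ids <- sprintf("sim%04d", seq_len(n))
  pheno <- stats::setNames(as.numeric(y), ids)
  attr(pheno, "trait_type") <- config$trait_type
  structure(list(config = config, individual_ids = ids,
                 gene_dosages = pair$gene, marker_dosages = pair$marker,
                 marker_DP = rc$DP, marker_RD = rc$RD,
                 phenotype = pheno, g = attr(y, "g"),
                 sigma2 = attr(y, "sigma2"), background = bg,
                 seed = seed),
            class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  print(x$config)
  cat(sprintf("  %d background markers; realized Var(g)/Var(y) = %.3f\n",
              x$config$n_background_markers,
              stats::var(x$g) / stats::var(as.numeric(x$phenotype))))
  invisible(x)
}

#' @export
summary.sim_population <- function(object, ...) {
  print(object)
  cat("  gene dosage table:\n")
  print(table(factor(object$gene_dosages, levels = 0:object$config$ploidy)))
  invisible(object)
}

#' Convert a simulated population to a read-count table
#'
#' Bundles the focal marker (first column, id `"focal"`) and the background
#' markers into a [read_count_table] ready for the standard pipeline.
#'
#' @param pop a `sim_population`.
#' @return A [read_count_table].
#' @export
sim_counts_table <- function(pop) {
  DP <- cbind(focal = pop$marker_DP, pop$background$DP)
  RD <- cbind(focal = pop$marker_RD, pop$background$RD)
  rownames(DP) <- rownames(RD) <- pop$individual_ids
  read_count_table(DP, RD)
}

#' Write a simulated population as VCF + phenotype + truth files
#'
#' Emits a minimal VCF v4.2 with per-genotype `GT:DP:RD` fields (the focal
#' marker first, then background markers), a two-column phenotype TSV
#' (`id<TAB>value`) and a truth TSV with the true dosages and genetic
#' values for evaluation.
#'
#' @param pop a `sim_population`.
#' @param vcf_path,pheno_path,truth_path output file paths (`NULL` skips).
#' @return invisibly, `pop`.
#' @export
write_sim_vcf <- function(pop, vcf_path, pheno_path = NULL,
                          truth_path = NULL) {
  tbl <- sim_counts_table(pop)
  n <- nrow(tbl$DP); m <- ncol(tbl$DP)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=polyscan-simulator",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
           "##FORMAT=<ID=RD,Number=1,Type=Integer,Description=\"Reference Depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", tbl$individual_ids), collapse = "\t"))
  rows <- vapply(seq_len(m), function(j) {
    gt <- sprintf("./.:%d:%d", tbl$DP[, j], tbl$RD[, j])
    paste(c("sim1", j * 100, tbl$marker_ids[j], "A", "G", ".", "PASS",
            ".", "GT:DP:RD", gt), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), vcf_path)
  if (!is.null(pheno_path)) {
    df <- data.frame(id = pop$individual_ids,
                     value = as.numeric(pop$phenotype))
    write.table(df, pheno_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(truth_path)) {
    df <- data.frame(id = pop$individual_ids,
                     gene_dosage = pop$gene_dosages,
                     marker_dosage = pop$marker_dosages,
                     g = pop$g)
    write.table(df, truth_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(pop)
}

#' Read a phenotype TSV
#'
#' Expects a header line `id<TAB>value` and one row per individual. The
#' trait type is declared, not inferred.
#'
#' @param path phenotype file.
#' @param trait_type `"continuous"` or `"binary"`.
#' @return Named numeric vector with attribute `trait_type`.
#' @export
read_phenotype <- function(path, trait_type = c("continuous", "binary")) {
  trait_type <- match.arg(trait_type)
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (!all(c("id", "value") %in% names(df)))
    stop("phenotype file must have columns 'id' and 'value'")
  if (trait_type == "binary" && !all(df$value %in% c(0, 1)))
    stop("binary trait values must be 0 or 1")
  y <- stats::setNames(as.numeric(df$value), as.character(df$id))
  attr(y, "trait_type") <- trait_type
  y
}
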