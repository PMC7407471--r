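---
title: "Dosage-probability association mapping in autopolyploids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dosage-probability association mapping in autopolyploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyscan)
```

## The problem

In an autohexaploid such as sweet potato, a biallelic SNP has seven possible
genotypes — reference-allele dosages 0 through 6. Genotyping-by-sequencing
reads are a binomial-like sample of the two alleles, so distinguishing, say,
dosage 3 (expected reference fraction 1/2) from dosage 4 (2/3) requires deep
coverage: around 100 reads per genotype for reliable calls, while affordable
ddRAD-seq experiments typically deliver 20–40. polyscan implements a mapping
strategy that does not require dosage calls at all: each genotype is carried
through the analysis as a probability distribution over dosages, and
association tests consume those probabilities directly.

## Dosage probabilities

For a genotype with total depth $DP$ and reference-read depth $RD$, the
likelihood of dosage $d \in \{0,\dots,K\}$ (ploidy $K$) is binomial with
success probability $r_d$, the expected reference-read fraction. To absorb
stray errors at the homozygous classes the endpoint fractions are nudged
inward by an error probability $e$:
$r = \{0/K + e,\; 1/K,\; \dots,\; (K-1)/K,\; K/K - e\}$, with $e = 0.001$ by
default. The relative probability of each dosage is the normalised
likelihood; the binomial coefficient cancels. All of this is computed in log
space, so depths in the hundreds do not underflow. `naive_dosage_probs()`
returns one such vector; `dosage_probs()` maps a whole read-count table to
an individuals × (K+1) × markers array.

Data-quality filters follow common practice for this data type: genotypes
with $DP < 10$ or $DP > 300$ are masked (strict inequalities), markers with
a missing fraction above 0.5 are dropped, and markers whose major genotype
frequency — the largest column mean of the probability matrix — exceeds 0.95
are removed as likely monomorphs. The MGF is probability-weighted by
default; a hard-call variant (`hard_calls = TRUE`) exists for sensitivity
checks, and the two agree whenever calls are confident.

A second estimator, `noise_aware_posterior()`, extends the binomial model
with the two noise components that dominate real reduced-representation
data: allelic bias $h$ (unequal detectability of the two alleles) and
overdispersion $\rho$ (extra-binomial variance between samples). The
expected reference fraction becomes
$\xi(p) = f / (h\,(1-f) + f)$ with $f = p(1-\epsilon) + (1-p)\epsilon$ and
$\epsilon$ the per-read sequencing error, and read counts are beta-binomial
with mean $\xi$ and overdispersion $\rho$. The posterior combines this
likelihood with the expected segregation ratio of the population as a prior.
$(h, \rho)$ are estimated per marker by maximising the marginal likelihood
over a fixed grid (15 log-spaced bias values in [0.25, 2]; 12
overdispersion values in [0, 0.2]). This is a deliberately simple,
transparent estimator: it does not iterate over markers, share information
between them, or model parental genotypes, and its resolution is bounded by
the grid. The same $\xi$ formula drives the read-count simulator, so the
simulator and the estimator share one noise model by construction.

## Association tests

Two genotype encodings feed a generalized linear model (Gaussian identity
link for continuous traits, binomial logit for binary ones):

* **Continuous** — the expected dosage $x_i = \sum_d \Pr(d)\, d$, a single
  regressor. Optimal when the effect is close to linear in dosage.
* **Dogmat** — the dosage-probability matrix itself as a multi-column
  regressor block. Dosage classes with (near-)zero total mass are dropped,
  then the largest class is dropped as the reference to break the
  rows-sum-to-one collinearity with the intercept; the test's degrees of
  freedom equal the retained columns. This encoding is agnostic about the
  genetic architecture.

Each marker is tested by the likelihood-ratio statistic, the drop in
deviance between the intercept-only and the full model, referred to a
chi-square. For Gaussian traits the default (`mode = "unscaled"`) uses the raw
deviance difference, which is scale-dependent; that is harmless for a single
scan because genome-wide significance is calibrated by permutation of the
same statistic. A `"scaled"` mode divides by the full-model dispersion
estimate, giving the usual scale-free statistic; it is exactly invariant to
affine rescaling of the phenotype. Missing genotypes are excluded pairwise
per marker; `n_used` records the effective sample size. No kinship or
structure covariate is used — the intended populations are single
biparental/selfed families.

## Genome-wide thresholds

The phenotype vector is permuted across individuals (with no covariates
this is the exchangeable null), the scan is rerun, and the maximum
$-\log_{10} p$ is recorded per replicate — 1000 replicates by default.
Because small replicate counts underestimate extreme quantiles, a
generalized extreme-value distribution is fitted to the maxima by maximum
likelihood and thresholds are read off its quantile function,
$q_{1-\alpha} = \mu + \sigma/\xi\,[(-\ln(1-\alpha))^{-\xi} - 1]$ (Gumbel
limit at $\xi = 0$). Non-convergence falls back to empirical quantiles with
a prominent warning. A reduced 200-replicate mode is used in the package's
own simulation studies; the full 1000 matches the intended analysis
setting. Per-replicate permutations derive their seeds from the master seed
by a counter, so runs are reproducible and individual replicates can be
regenerated independently. For Gaussian traits the permutation scan uses a
vectorised projection identity ($\mathrm{RSS}_0 - \mathrm{RSS}_1 =
\lVert Q^\top y \rVert^2$ for an orthonormal basis $Q$ of the centred
design), which the test suite verifies against the per-marker `glm()` route
to machine precision.

## The simulator

`sim_config()` + `simulate_population()` generate the study conditions the
package's claims are tested under:

* **Segregation.** Polysomic inheritance with strict random bivalent-like
  segregation and no double reduction: a gamete receives $K/2$ of the $K$
  homologs uniformly at random, so transmitted dosages are hypergeometric
  (`gamete_dosage_distribution()`), and offspring dosages are the
  convolution of two independent gametes. Marker types SS/DD/TT mean both
  parents carry dosage 1, 2 or 3.
* **Linkage.** The marker and the causal gene sit on the same homolog set
  in *maximal coupling*: marker reference alleles are stacked onto the
  homologs carrying gene reference alleles whenever counts permit. This is
  the most favourable phase, so any power loss observed under mismatched
  segregation types is attributable to the segregation itself, not to
  adverse phase. Per meiosis, the number of crossovers between the loci is
  Poisson; each crossover exchanges the gene-side allele between two
  homologs drawn without replacement.
* **Crossover rate.** The package reads a map distance of $d$ cM as a
  Poisson mean of $d/100$ per meiosis (`lambda_mode = "morgan"`), the
  standard definition of genetic distance. The alternative literal reading
  (`"literal"`, mean $= d$) is available as a switch but makes a 5 cM
  marker essentially unlinked under this crossover mechanism — five
  expected exchanges per meiosis shuffle the homologs almost completely —
  which would contradict the well-established observation that markers a
  few cM from a causal gene retain most of their detection power. Both
  modes preserve the marginal segregation ratios exactly (tested by
  goodness-of-fit at n = 10,000).
* **Reads.** Depths are fixed (20/40/100) or resampled from a supplied
  empirical distribution; reference counts are beta-binomial via the shared
  $\xi$ formula. The two canonical noise settings are clean (bias 1,
  od 0) and noisy (bias 0.5, od 0.05), with sequencing error 0.001
  throughout.
* **Phenotypes.** Genetic values $g(d)$ follow one of three architectures —
  additive ($d/K$), simplex-dominant ($\mathbb{1}[d \ge 1]$), diploidized
  additive (0, 1/2, 1 at $d = 0$, intermediate, $K$) — normalised to
  $[0, 1]$, which is harmless because heritability is scale-free. For a
  target PVE the environmental variance is set analytically from the
  realised sample variance of $g$: $\sigma^2 = \mathrm{Var}(g)\,
  (1-\mathrm{PVE})/\mathrm{PVE}$. Binary traits are a clearly labelled
  extension: $\Pr(y = 1) = \mathrm{logistic}(a + bg)$ with $b$ matching
  the target PVE on the latent logistic scale ($\pi^2/3$ residual
  variance) and $a$ centring prevalence at 1/2.
* **Background markers.** Unlinked null markers with types drawn from a
  0.6/0.3/0.1 SS/DD/TT mixture stand in for the genome-wide marker panel
  when calibrating permutation thresholds in simulation studies.

Population defaults (n = 248 individuals, S1) mirror a typical selfed
hexaploid mapping population of the size this strategy targets.

## Experiment design choices

`accuracy_experiment()` scores the proportion of individuals whose argmax
dosage call matches the truth, over 100 replicates of n = 100 by default.
`power_experiment()` calibrates one permutation-GEV threshold per condition
from a simulated background panel (500 markers, 200 permutations in the
desk-scale default) and then scores the fraction of 100–200 replicate
populations whose focal marker exceeds it.

Two choices here deserve explanation:

* **Scaled LRT for power studies.** Cross-condition power comparisons need
  a statistic whose null distribution does not depend on the phenotype's
  variance scale. The raw (unscaled) Gaussian deviance difference scales
  with $\mathrm{Var}(y)$, so a once-per-condition threshold inherits the
  calibration draw's scale and, for Dogmat, interacts with the per-marker
  degrees of freedom; the resulting condition-level noise is of the same
  order as the effects being compared. `power_experiment()` therefore uses
  the dispersion-scaled statistic by default; single-scan analyses keep
  the raw statistic as their default, where permutation calibration makes
  it valid.
* **Mid-range panels.** At n = 248 a tightly linked causal marker is
  detected essentially always under easy conditions (simplex marker, depth
  40, no noise), leaving no room to resolve orderings. The package's own
  acceptance checks therefore use the harder panels of the design space —
  duplex/triplex markers, depth 20, noisy reads, the Dogmat encoding — so
  that power sits mid-range and monotonicity margins are measurable. The
  distance curve uses 0/30/75 cM for the same reason: with the
  homolog-exchange crossover mechanism, each exchange disrupts coupling
  only partially, so the decay per cM is gentler than a chromatid-level
  model would give and wider spacing is needed for clearly separated
  powers.

## Known limitations

* The noise-parameter grid bounds the noise-aware estimator's resolution;
  in particular, duplex-marker accuracy under strong bias plateaus between
  depth 40 and 100 because the bias grid step, not sampling noise, becomes
  the binding error.
* Under the Dogmat encoding with noisy low-depth reads, the noise-aware
  posterior yields consistently *higher* power than the naive binomial
  probabilities. The two estimators are statistically indistinguishable
  under the continuous encoding, which is the equivalence the package
  asserts; users comparing estimators under Dogmat should expect a real
  difference in this simulator's regime.
* A triplex-by-triplex simplex-dominant gene is monomorphic in genetic
  value in roughly half of n = 248 populations (the nulliplex class has
  frequency 1/400), so its detection power is dominated by segregation
  luck; such replicates are treated as pure-noise phenotypes.
* The simulator models a single causal locus, one marker, and an unlinked
  background panel: no multi-QTL genomes, no linkage maps, no preferential
  pairing or double reduction, no kinship structure. Passing tests
  demonstrate the statistical machinery under polysomic segregation and
  beta-binomial reads; they do not certify behaviour on populations with
  structure, relatedness gradients, or allopolyploid pairing.

## A worked miniature

```{r example, eval = FALSE}
cfg <- sim_config(n_individuals = 250, marker_type = "SS",
                  effect_model = "SimDom", pve = 0.3, depth = 40,
                  n_background_markers = 300, seed = 42)
pop <- simulate_population(cfg)
tbl <- sim_counts_table(pop)
M <- filter_mgf(dosage_probs(filter_missing(filter_depth(tbl))))
scan <- assoc_scan(M, pop$phenotype, encoding = "dogmat")
thr <- perm_gev_threshold(M, pop$phenotype, encoding = "dogmat",
                          n_perm = 200, seed = 42)
summary(scan)
print(thr)
plot(scan, threshold = thr$thresholds["5%"])
```
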