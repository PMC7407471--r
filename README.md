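# polyscan

Association mapping for autopolyploid populations genotyped by low-coverage
sequencing, built around **allele-dosage probabilities** instead of hard
dosage calls.

## Why

In an autohexaploid (K = 6, e.g. sweet potato), a biallelic SNP has seven
genotypes — reference-allele dosages 0..6 — and distinguishing adjacent
dosages from sequencing read counts reliably needs ~100× coverage, while
typical ddRAD-seq/GBS experiments deliver 20–40×. Hard dosage calls from
such data are wrong too often to support linkage or QTL analysis. polyscan
instead propagates, for every genotype, the full probability distribution
over dosages into the association test, so shallow data still contribute
what information they carry.

## The model

For total depth DP and reference-read depth RD at a marker, the relative
probability of dosage d is the normalised binomial likelihood

    Pr(d) ∝ r_d^RD (1 − r_d)^(DP−RD),
    r = {0/K + e, 1/K, …, (K−1)/K, K/K − e},  e = 0.001,

computed per individual (`naive_dosage_probs`, `dosage_probs`). A
noise-aware variant (`noise_aware_posterior`) replaces the binomial with a
beta-binomial whose mean ξ(d/K) warps the expected reference fraction by an
allelic-bias factor and whose overdispersion captures extra-binomial
variance; bias and overdispersion are estimated per marker by grid marginal
likelihood under the population's segregation prior.

Marker–phenotype association is a GLM likelihood-ratio test
(`assoc_scan`) under two genotype encodings: **Continuous** (the expected
dosage Σ_d Pr(d)·d as a single regressor) and **Dogmat** (the probability
matrix itself as a multi-column regressor block). Genome-wide significance
comes from phenotype permutation with a generalized-extreme-value model
fitted to the per-permutation maxima of −log10(p)
(`perm_gev_threshold`). A polysomic S1/F1 simulator — hypergeometric
gametes, Poisson crossovers, beta-binomial reads, additive /
simplex-dominant / diploidized-additive genetic effects at controlled
PVE — drives the package's accuracy and power studies
(`simulate_population`, `accuracy_experiment`, `power_experiment`).

## Worked example

Simulate a 250-individual selfed hexaploid population with one planted
simplex-dominant gene (PVE 0.3) and 300 unlinked background markers, then
map it from the emitted VCF:

```r
library(polyscan)

cfg <- sim_config(n_individuals = 250, marker_type = "SS",
                  effect_model = "SimDom", pve = 0.3, depth = 40,
                  n_background_markers = 300, seed = 501)
pop <- simulate_population(cfg)
write_sim_vcf(pop, "sim.vcf", "phenotype.tsv")

res <- run_real_pipeline("sim.vcf", "phenotype.tsv",
                         trait_type = "continuous",
                         encoding = "continuous",
                         n_perm = 200, seed = 501, out_dir = "out")
print(res$threshold)
#> gev_threshold: 200 permutations (continuous encoding, continuous trait), seed 501
#>   GEV fit: loc = 1.848, scale = 0.306, shape = 0.087
#>   -log10(p) thresholds:
#>     alpha 0.10 : 2.608
#>     alpha 0.05 : 2.885
#>     alpha 0.01 : 3.579
print(res$scan)
#> assoc_scan: 301 markers, 250 individuals, continuous encoding, continuous trait (unscaled LRT)
#>   top hit: focal  -log10(p) = 8.29
```

The planted marker (`focal`) towers over the permutation-calibrated 5%
genome-wide threshold; the thresholds here are on the unscaled-deviance
scale of the default LRT mode, which the permutation calibration makes
valid (see the methods vignette for the scaled alternative). `out/`
contains the scan TSV, the threshold report and a Manhattan-style plot
grouped by homologous linkage group when annotation is supplied
(`set_homologous_groups`).

The same pipeline runs from the shell:

```sh
exec/polyscan simulate --n 250 --marker-type SS --effect SimDom --pve 0.3 \
    --depth 40 --n-background 300 --seed 501 --out-dir simdata
exec/polyscan scan --vcf simdata/simulated.vcf --pheno simdata/phenotype.tsv \
    --trait continuous --encoding continuous --n-perm 200 --seed 501 --out-dir out
```

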