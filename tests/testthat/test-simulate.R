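test_that("gamete dosage distributions match hand enumeration", {
  expect_equal(unname(gamete_dosage_distribution(6, 1)),
               c(1 / 2, 1 / 2, 0, 0))
  expect_equal(unname(gamete_dosage_distribution(6, 3)),
               c(1, 9, 9, 1) / 20)
  expect_equal(unname(gamete_dosage_distribution(6, 0)), c(1, 0, 0, 0))
  expect_equal(unname(gamete_dosage_distribution(6, 6)), c(0, 0, 0, 1))
  expect_error(gamete_dosage_distribution(5, 1), "even")
})

test_that("offspring distributions are gamete convolutions", {
  ## selfed simplex: 1:2:1 on dosages 0..2
  expect_equal(unname(offspring_dosage_distribution(6, 1)),
               c(1 / 4, 1 / 2, 1 / 4, 0, 0, 0, 0), tolerance = 1e-12)
  ## selfed triplex: convolution of {1,9,9,1}/20 with itself
  tt <- offspring_dosage_distribution(6, 3)
  expect_equal(unname(tt[1]), 1 / 400, tolerance = 1e-12)
  expect_equal(unname(tt[4]), 164 / 400, tolerance = 1e-12)
  expect_equal(sum(tt), 1, tolerance = 1e-12)
  ## fixed homozygote
  expect_equal(unname(offspring_dosage_distribution(6, 0)),
               c(1, rep(0, 6)), tolerance = 1e-12)
})

test_that("complete linkage in maximal coupling co-segregates exactly", {
  cfg <- sim_config(n_individuals = 300, marker_type = "DD",
                    gene_type = "DD", distance_cM = 0,
                    n_background_markers = 0)
  set.seed(41)
  pair <- simulate_linked_pair(cfg)
  expect_identical(pair$marker, pair$gene)
})

test_that("many crossovers decouple marker from gene", {
  cfg <- sim_config(n_individuals = 10000, marker_type = "SS",
                    distance_cM = 80, lambda_mode = "literal",
                    n_background_markers = 0)
  set.seed(42)
  pair <- simulate_linked_pair(cfg)
  expect_lt(abs(cor(pair$marker, pair$gene)), 0.05)
})

test_that("marker marginals survive recombination", {
  cfg <- sim_config(n_individuals = 10000, marker_type = "TT",
                    gene_type = "TT", distance_cM = 30,
                    n_background_markers = 0)
  set.seed(43)
  pair <- simulate_linked_pair(cfg)
  expected <- offspring_dosage_distribution(6, 3)
  obs <- tabulate(pair$marker + 1L, nbins = 7)
  gof <- suppressWarnings(chisq.test(obs, p = expected))
  expect_gt(gof$p.value, 0.001)
  ## gene marginal too
  obs_g <- tabulate(pair$gene + 1L, nbins = 7)
  gof_g <- suppressWarnings(chisq.test(obs_g, p = expected))
  expect_gt(gof_g$p.value, 0.001)
})

test_that("read counts follow the configured noise model", {
  ## clean homozygote at zero sequencing error: all reads are reference
  cfg <- sim_config(n_individuals = 500, depth = 40, bias = 1, od = 0,
                    seq_error = 0, n_background_markers = 0)
  set.seed(44)
  rc <- simulate_read_counts(rep(6L, 500), cfg)
  expect_true(all(rc$RD == rc$DP))
  ## balanced heterozygote mean fraction 1/2
  rc3 <- simulate_read_counts(rep(3L, 1e5), sim_config(
    n_individuals = 1e5, depth = 40, bias = 1, od = 0, seq_error = 0,
    n_background_markers = 0))
  expect_equal(mean(rc3$RD / rc3$DP), 0.5, tolerance = 0.005)
  ## empirical depth model resamples the supplied histogram
  cfg_emp <- sim_config(n_individuals = 200, depth = c(20L, 40L, 100L),
                        n_background_markers = 0)
  rc_emp <- simulate_read_counts(rep(2L, 200), cfg_emp)
  expect_true(all(rc_emp$DP %in% c(20L, 40L, 100L)))
})

test_that("genetic effect models encode the three architectures", {
  expect_equal(genetic_effect(3, "Add"), 0.5)
  expect_equal(genetic_effect(0:6, "Add"), (0:6) / 6)
  expect_equal(genetic_effect(3, "SimDom"), 1)
  expect_equal(genetic_effect(0, "SimDom"), 0)
  expect_equal(genetic_effect(5, "DipAdd"), 0.5)
  expect_equal(genetic_effect(6, "DipAdd"), 1)
  expect_equal(genetic_effect(0, "DipAdd"), 0)
})

test_that("phenotypes hit the target variance ratio", {
  cfg <- sim_config(n_individuals = 5000, marker_type = "DD", pve = 0.2,
                    n_background_markers = 0)
  set.seed(45)
  dos <- sample(0:6, 5000, TRUE, offspring_dosage_distribution(6, 2))
  y <- simulate_phenotype(dos, cfg)
  g <- attr(y, "g")
  ## residual variance follows sigma2 = Var(g) (1 - PVE) / PVE exactly
  expect_equal(attr(y, "sigma2"), var(g) * 0.8 / 0.2, tolerance = 1e-12)
  expect_equal(var(g) / var(as.numeric(y)), 0.2, tolerance = 0.02)
  ## near-unit heritability returns the genetic values themselves
  cfg99 <- sim_config(n_individuals = 5000, pve = 0.999,
                      n_background_markers = 0)
  y99 <- simulate_phenotype(dos, cfg99)
  expect_equal(as.numeric(y99), g, tolerance = 0.1)
  ## constant genetic values are an error
  expect_error(simulate_phenotype(rep(3L, 100), cfg), "PVE")
})

test_that("binary phenotypes are a labelled logistic extension", {
  cfg <- sim_config(n_individuals = 4000, trait_type = "binary", pve = 0.3,
                    n_background_markers = 0)
  set.seed(46)
  dos <- sample(0:2, 4000, TRUE, c(0.25, 0.5, 0.25))
  y <- simulate_phenotype(dos, cfg)
  expect_true(all(y %in% c(0, 1)))
  expect_equal(mean(y), 0.5, tolerance = 0.05)   # centred prevalence
  ## carriers are enriched for 1
  expect_gt(mean(y[dos == 2]), mean(y[dos == 0]))
})

test_that("background markers are reproducible and pass the MGF filter", {
  cfg <- sim_config(n_individuals = 100, n_background_markers = 200,
                    depth = 40, seed = 8)
  set.seed(8); a <- simulate_background_markers(cfg)
  set.seed(8); b <- simulate_background_markers(cfg)
  expect_identical(a, b)
  ## type mixture close to 0.6 / 0.3 / 0.1
  frac <- table(factor(a$types, c("SS", "DD", "TT"))) / 200
  expect_true(all(abs(frac - c(0.6, 0.3, 0.1)) < 3 * sqrt(0.6 * 0.4 / 200)))
  ## no synthetic marker is near-monomorphic under segregation
  tbl <- read_count_table(a$DP, a$RD,
                          individual_ids = sprintf("i%03d", 1:100))
  M <- dosage_probs(tbl)
  expect_equal(dim(filter_mgf(M))[3], 200L)
})

test_that("whole populations are reproducible from the seed", {
  cfg <- sim_config(n_individuals = 40, n_background_markers = 10,
                    marker_type = "SS", pve = 0.3, seed = 99)
  p1 <- simulate_population(cfg)
  p2 <- simulate_population(cfg)
  expect_identical(p1$marker_RD, p2$marker_RD)
  expect_identical(as.numeric(p1$phenotype), as.numeric(p2$phenotype))
  expect_identical(p1$background$RD, p2$background$RD)
})
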