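test_that("Gaussian LRT matches the hand-worked residual sums", {
  ## y = (0,1,1,2), x = (0,0,1,1): RSS0 = 2, RSS1 = 1, stat = 1, df = 1
  r <- fit_glm_lrt(c(0, 1, 1, 2), matrix(c(0, 0, 1, 1)), "continuous")
  expect_equal(r$lrt_stat, 1)
  expect_equal(r$df, 1L)
  expect_equal(r$pvalue, pchisq(1, 1, lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(r$pvalue, 0.3173, tolerance = 1e-4)
  expect_equal(r$neglog10p, -log10(r$pvalue))
})

test_that("binary trait with equal group rates gives a null test", {
  r <- fit_glm_lrt(c(0, 1, 0, 1), matrix(c(0, 0, 1, 1)), "binary")
  expect_equal(r$lrt_stat, 0, tolerance = 1e-10)
  expect_equal(r$pvalue, 1, tolerance = 1e-6)
})

test_that("degenerate designs and constant phenotypes are flagged", {
  r <- fit_glm_lrt(c(0, 1, 1, 2), matrix(1, 4, 1), "continuous")
  expect_equal(r$flag, "untestable")
  expect_equal(r$pvalue, 1)
  expect_equal(r$df, 0L)
  r2 <- fit_glm_lrt(rep(2, 6), matrix(rnorm(6)), "continuous")
  expect_equal(r2$flag, "constant_phenotype")
  expect_equal(r2$pvalue, 1)
})

test_that("scaled mode is exactly invariant to affine phenotype rescaling", {
  set.seed(21)
  y <- rnorm(40); x <- matrix(rnorm(40))
  a <- fit_glm_lrt(y, x, "continuous", mode = "scaled")
  b <- fit_glm_lrt(5 * y - 3, x, "continuous", mode = "scaled")
  expect_equal(a$pvalue, b$pvalue, tolerance = 1e-10)
  ## unscaled mode scales with the response (the documented dispersion caveat)
  ap <- fit_glm_lrt(y, x, "continuous", mode = "unscaled")
  bp <- fit_glm_lrt(5 * y, x, "continuous", mode = "unscaled")
  expect_equal(bp$lrt_stat, 25 * ap$lrt_stat, tolerance = 1e-8)
})

test_that("dogmat encoding drops empty classes and the reference class", {
  ## simplex-type marker: only dosages 0..2 occur (1:2:1)
  dos <- rep(c(0L, 1L, 1L, 2L), 10)
  M <- matrix(0, 40, 7); M[cbind(1:40, dos + 1)] <- 1
  X <- encode_dogmat(M)
  expect_equal(ncol(X), 2L)                 # 3 classes minus the largest
  expect_false("1" %in% colnames(X))        # dosage 1 is the largest class
  ## monomorphic marker untestable
  M3 <- matrix(0, 10, 7); M3[, 4] <- 1
  expect_null(encode_dogmat(M3))
  ## all seven classes present: K columns remain
  M7 <- diag(7)[rep(1:7, 2), ]
  expect_equal(ncol(encode_dogmat(M7)), 6L)
})

test_that("scan aligns ids, accounts n_used pairwise and flags untestables", {
  set.seed(22)
  ids <- sprintf("i%02d", 1:30)
  M1 <- polyscan:::.naive_probs_matrix(rep(40, 30), rbinom(30, 40, 0.3),
                                       dosage_params())
  rownames(M1) <- ids
  M2 <- M1; M2[1:4, ] <- NA                 # 4 masked genotypes
  Mmono <- matrix(0, 30, 7); Mmono[, 4] <- 1; rownames(Mmono) <- ids
  y <- setNames(rnorm(30), ids)
  sc <- assoc_scan(list(a = M1, b = M2, mono = Mmono), y,
                   encoding = "dogmat")
  expect_equal(sc$results$n_used, c(30, 26, 30))
  expect_equal(sc$results$flag[3], "untestable")
  ## duplicated marker gives identical statistics
  sc2 <- assoc_scan(list(a = M1, a2 = M1), y, encoding = "continuous")
  expect_equal(sc2$results$lrt_stat[1], sc2$results$lrt_stat[2])
  ## disjoint ids is an error
  y2 <- setNames(rnorm(5), paste0("other", 1:5))
  expect_error(assoc_scan(list(a = M1), y2, encoding = "continuous"),
               "overlap")
})

test_that("null scan p-values are approximately uniform", {
  set.seed(23)
  n <- 120; m <- 500
  ids <- sprintf("i%03d", 1:n)
  DP <- matrix(40L, n, m)
  RD <- matrix(rbinom(n * m, 40, rep(runif(m, 0.2, 0.8), each = n)), n, m)
  slices <- naive_slices(DP, RD, ids)
  y <- setNames(rnorm(n), ids)
  sc <- assoc_scan(slices, y, encoding = "continuous", mode = "scaled")
  ks <- suppressWarnings(ks.test(sc$results$pvalue, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("projection engine reproduces the glm route in both modes", {
  set.seed(24)
  n <- 50
  ids <- sprintf("i%02d", 1:n)
  DP <- matrix(30L, n, 6)
  RD <- matrix(rbinom(n * 6, 30, 0.4), n, 6)
  slices <- naive_slices(DP, RD, ids)
  slices[[2]][c(3, 9), ] <- NA              # missingness in one marker
  y <- rnorm(n)
  Y <- cbind(y, y[sample(n)], y[sample(n)])
  for (enc in c("continuous", "dogmat")) for (md in c("unscaled", "scaled")) {
    designs <- polyscan:::.build_marker_designs(slices, ids, enc)
    keep <- !vapply(designs, is.null, logical(1))
    nl <- polyscan:::.gaussian_engine_neglog10p(designs[keep], Y, mode = md)
    for (k in 1:3) {
      yk <- setNames(Y[, k], ids)
      sc <- assoc_scan(slices, yk, encoding = enc, mode = md)
      expect_equal(unname(nl[, k]),
                   sc$results$neglog10p[keep], tolerance = 1e-8)
    }
  }
})

test_that("binary traits run through the logistic path", {
  set.seed(25)
  n <- 80
  ids <- sprintf("i%02d", 1:n)
  dos <- sample(0:2, n, TRUE, c(0.25, 0.5, 0.25))
  rc <- simulate_read_counts(dos, sim_config(n_individuals = n, depth = 40,
                                             n_background_markers = 0))
  M <- polyscan:::.naive_probs_matrix(rc$DP, rc$RD, dosage_params())
  rownames(M) <- ids
  y <- setNames(rbinom(n, 1, plogis(-1 + dos)), ids)
  attr(y, "trait_type") <- "binary"
  sc <- assoc_scan(list(m = M), y, encoding = "continuous")
  expect_equal(sc$trait_type, "binary")
  expect_true(sc$results$pvalue > 0 && sc$results$pvalue <= 1)
})
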