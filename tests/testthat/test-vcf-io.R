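test_that("DP/RD fields are copied faithfully from a VCF", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(f, c("S1", "S2"), list(
    list(chrom = "sc1", pos = 100, ref = "A", alt = "G",
         cells = c("0/1:12:4", "1/1:30:30"))))
  tbl <- read_vcf_counts(f, verbose = FALSE)
  expect_s3_class(tbl, "read_count_table")
  expect_equal(dim(tbl), c(2L, 1L))
  expect_equal(unname(tbl$DP[, 1]), c(12, 30))
  expect_equal(unname(tbl$RD[, 1]), c(4, 30))
  expect_equal(tbl$marker_meta$pos, 100L)
})

test_that("cells lacking a depth field are masked, others kept", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(f, c("S1", "S2"), list(
    list(chrom = "sc1", pos = 100, ref = "A", alt = "G",
         cells = c("0/1:12:.", "1/1:30:30"))))
  tbl <- read_vcf_counts(f, verbose = FALSE)
  expect_true(is.na(tbl$DP[1, 1]))   # shared mask with RD
  expect_true(is.na(tbl$RD[1, 1]))
  expect_equal(unname(tbl$DP[2, 1]), 30)
})

test_that("non-biallelic-SNP records are skipped with a warning", {
  f <- withr::local_tempfile(fileext = ".vcf")
  recs <- lapply(1:4, function(i)
    list(chrom = "sc1", pos = i * 10, ref = "A", alt = "G",
         cells = c("0/1:10:5", "0/1:10:5")))
  recs[[5]] <- list(chrom = "sc1", pos = 99, ref = "A", alt = "G,T",
                    cells = c("0/1:10:5", "0/1:10:5"))
  expect_warning(tbl <- read_vcf_counts(f <- write_test_vcf(f, c("S1", "S2"),
                                                            recs),
                                        verbose = FALSE),
                 "skipped 1")
  expect_equal(ncol(tbl$DP), 4L)
})

test_that("reference depths fall back to AD[1] when RD is absent", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(f, c("S1", "S2"), list(
    list(chrom = "sc1", pos = 7, ref = "C", alt = "T", fmt = "GT:DP:AD",
         cells = c("0/1:12:4,8", "1/1:30:30,0"))))
  expect_message(tbl <- read_vcf_counts(f), "AD")
  expect_equal(unname(tbl$RD[, 1]), c(4, 30))
  ## and a hard error when neither field exists anywhere
  write_test_vcf(f, "S1", list(
    list(chrom = "sc1", pos = 7, ref = "C", alt = "T", fmt = "GT:DP",
         cells = "0/1:12")))
  expect_error(read_vcf_counts(f, verbose = FALSE), "RD")
})

test_that("depth filter masks strictly outside [10, 300] and only masks", {
  DP <- matrix(c(9, 10, 300, 301, 50, NA), 2, 3)
  RD <- matrix(c(4, 5, 100, 200, 25, NA), 2, 3)
  tbl <- read_count_table(DP, RD)
  out <- filter_depth(tbl)
  expect_true(is.na(out$DP[1, 1]))            # 9  < 10  -> masked
  expect_equal(unname(out$DP[2, 1]), 10)      # boundary retained
  expect_equal(unname(out$DP[1, 2]), 300)     # boundary retained
  expect_true(is.na(out$DP[2, 2]))            # 301 > 300 -> masked
  expect_equal(dim(out), dim(tbl))            # shape unchanged
  expect_true(all(is.na(out$DP[is.na(tbl$DP)])))  # never unmasks
  ## all-in-range table passes unchanged
  tbl2 <- read_count_table(matrix(50, 3, 2), matrix(20, 3, 2))
  expect_identical(filter_depth(tbl2)$DP, tbl2$DP)
})

test_that("missingness filter drops markers strictly above the threshold", {
  DP <- cbind(a = c(NA, NA, NA, 10, 10),   # 60% missing -> dropped
              b = c(NA, NA, 10, 10, NA),   # 60% missing -> dropped
              c = c(NA, NA, 10, 10, 10),   # 40% -> kept
              d = c(10, 10, 10, 10, 10))
  tbl <- read_count_table(DP, pmin(DP, 5))
  out <- filter_missing(tbl, 0.5)
  expect_equal(out$marker_ids, c("c", "d"))  # order preserved
  ## exactly-at-threshold marker retained
  DP2 <- cbind(e = c(NA, NA, 10, 10), f = c(10, 10, 10, 10))
  out2 <- filter_missing(read_count_table(DP2, pmin(DP2, 3)), 0.5)
  expect_equal(out2$marker_ids, c("e", "f"))
  ## no missing cells: identity
  expect_equal(filter_missing(tbl)$DP[, "d"], tbl$DP[, "d"])
})

test_that("write + re-read of simulator output is idempotent on DP/RD", {
  cfg <- sim_config(n_individuals = 12, n_background_markers = 5,
                    depth = 40, seed = 7)
  pop <- simulate_population(cfg)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_sim_vcf(pop, f)
  tbl <- read_vcf_counts(f, verbose = FALSE)
  ref <- sim_counts_table(pop)
  expect_equal(unname(tbl$DP), unname(ref$DP))
  expect_equal(unname(tbl$RD), unname(ref$RD))
  ## round again
  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_counts_tsv(tbl, withr::local_tempfile(), withr::local_tempfile())
  expect_equal(unname(read_vcf_counts(f, verbose = FALSE)$RD),
               unname(tbl$RD))
})

test_that("filters leave every unmasked cell within bounds", {
  set.seed(42)
  for (i in 1:5) {
    DP <- matrix(rpois(60, 60), 10, 6)
    RD <- matrix(rbinom(60, as.vector(DP), 0.4), 10, 6)
    DP[sample(60, 8)] <- NA
    tbl <- filter_missing(filter_depth(read_count_table(DP, RD)), 0.5)
    ok <- !is.na(tbl$DP)
    expect_true(all(tbl$DP[ok] >= 10 & tbl$DP[ok] <= 300))
    expect_true(all(tbl$RD[ok] >= 0 & tbl$RD[ok] <= tbl$DP[ok]))
    expect_identical(is.na(tbl$DP), is.na(tbl$RD))
  }
})

test_that("homologous-group annotation joins by exact id", {
  tbl <- read_count_table(matrix(20, 2, 3), matrix(8, 2, 3),
                          marker_ids = c("m1", "m2", "m3"))
  tbl <- set_homologous_groups(tbl, data.frame(marker_id = c("m3", "m1"),
                                               group = c(7L, 2L)))
  expect_equal(tbl$marker_meta$homologous_group, c(2L, NA, 7L))
})
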