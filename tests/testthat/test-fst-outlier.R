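test_that("SNP filters drop high-missingness and low-MAF markers, idempotently", {
  set.seed(61)
  geno <- matrix(rbinom(20 * 50, 1, 0.4), 20, 50,
                 dimnames = list(paste0("m", 1:20), paste0("i", 1:50)))
  geno[1, 1:3] <- NA                      # 6% missing -> removed
  geno[2, ] <- c(1, rep(0, 49))           # MAF 0.02 -> kept
  geno[3, ] <- rep(0:1, c(50, 0)); geno[3, 1] <- 1  # duplicate of MAF 0.02
  geno[4, ] <- rep(0, 50)                  # MAF 0 -> removed
  filt <- filter_snps(geno)
  ex <- attr(filt, "exclusions")
  expect_true("m1" %in% ex$marker[ex$reason == "missing"])
  expect_true("m4" %in% ex$marker[ex$reason == "maf"])
  expect_false("m2" %in% ex$marker)
  expect_identical(dim(filter_snps(filt)), dim(filt))  # idempotent

  # MAF exactly at the threshold is excluded (<= rule)
  g2 <- matrix(rbinom(2 * 100, 1, 0.5), 2, 100)
  g2[1, ] <- c(1, rep(0, 99))  # MAF 0.01
  expect_equal(nrow(filter_snps(g2)), 1L)

  expect_error(filter_snps(matrix(0L, 2, 10)), "all markers removed")
})

test_that("a panel built with engineered failures mimics the 131 -> 112 filter", {
  panel <- generate_snp_panel(131, n1 = 30, n2 = 30, target_fst = 0.2,
                              n_fail_missing = 10, n_fail_maf = 9, seed = 4)
  filt <- filter_snps(panel$geno)
  expect_equal(nrow(filt), 112L)
  expect_equal(nrow(attr(filt, "exclusions")), 19L)
})

test_that("the island-model cloud is seeded and centered near the target FST", {
  cl1 <- simulate_fdist_cloud(3000, c(30, 30), target_fst = 0.2,
                              n_demes = 100, seed = 7)
  cl2 <- simulate_fdist_cloud(3000, c(30, 30), target_fst = 0.2,
                              n_demes = 100, seed = 7)
  expect_identical(cl1$fst, cl2$fst)
  expect_true(all(cl1$He >= 0 & cl1$He <= 1, na.rm = TRUE))
  # multilocus mean within the documented +-0.03 band of the target
  expect_lt(abs(mean(cl1$fst, na.rm = TRUE) - 0.2), 0.03)

  expect_error(simulate_fdist_cloud(10, target_fst = 0), "target mean FST")
})

test_that("envelope classification flags extremes and degenerates sensibly", {
  set.seed(8)
  cloud <- simulate_fdist_cloud(8000, c(30, 30), 0.2, 100, seed = 8)
  obs <- cloud[sample.int(nrow(cloud), 300), ]
  cls <- envelope_and_classify(obs, cloud, ci = 0.99)
  expect_true(all(cls$class %in% c("neutral", "directional", "balancing")))

  # marker far above the cloud at its He
  hot <- data.frame(marker = "hot", He = 0.4, fst = 0.999)
  obs2 <- rbind(obs[, c("He", "fst")], hot[, c("He", "fst")])
  cls2 <- envelope_and_classify(obs2, cloud, ci = 0.99)
  expect_equal(cls2$class[nrow(cls2)], "directional")

  # ci = 1 degenerates to the cloud min/max: nothing inside support flagged
  cls3 <- envelope_and_classify(obs, cloud, ci = 1)
  expect_true(all(cls3$class %in% c("neutral", "unclassified")))

  # raising ci never flags more markers
  n95 <- sum(envelope_and_classify(obs, cloud, ci = 0.95)$class != "neutral")
  n99 <- sum(cls$class != "neutral")
  expect_lte(n99, n95)

  # He outside the cloud support: unclassified with warning
  far <- data.frame(He = 2, fst = 0.1)
  expect_warning(cf <- envelope_and_classify(rbind(obs[, c("He", "fst")], far),
                                             cloud),
                 "unclassified")
  expect_equal(cf$class[nrow(cf)], "unclassified")
})

test_that("forced-mean iteration re-centers and converges", {
  set.seed(9)
  cloud <- simulate_fdist_cloud(4000, c(30, 30), 0.15, 100, seed = 9)
  panel <- generate_snp_panel(120, 30, 30, target_fst = 0.15, seed = 10)
  obs <- snp_he_fst(panel$geno, panel$pops)
  # spike a few strong outliers so the forced mean moves
  obs$fst[1:4] <- 0.95
  res <- envelope_and_classify(obs, cloud, ci = 0.99, forced_mean = TRUE,
                               seed = 20)
  expect_true(attr(res, "n_iter") >= 1)
  expect_true(all(c("class", "lower", "upper") %in% names(res)))
})

test_that("genotype matrices round-trip through TSV", {
  panel <- generate_snp_panel(15, 6, 6, 0.2, seed = 3)
  f <- tempfile(fileext = ".tsv")
  write_snp_matrix(panel$geno, f)
  back <- read_snp_matrix(f)
  expect_equal(unname(back), unname(panel$geno))
  expect_equal(rownames(back), rownames(panel$geno))
})
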