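test_that("site counts classify monomorphic, singleton and tri-allelic sites", {
  mono <- mk_aln(rep("ACGTACGTAC", 4))
  sc <- site_counts(mono)
  expect_equal(sc[c("V", "eta", "S", "Pi_sites")],
               list(V = 0L, eta = 0L, S = 0L, Pi_sites = 0L))

  one <- mk_aln(c("AAAA", "AAAA", "AAAA", "TAAA"))
  sc <- site_counts(one)
  expect_equal(sc[c("V", "eta", "S", "Pi_sites")],
               list(V = 1L, eta = 1L, S = 1L, Pi_sites = 0L))

  tri <- mk_aln(c("AAAA", "AAAA", "TAAA", "GAAA"))
  sc <- site_counts(tri)
  expect_equal(sc[c("V", "eta", "S", "Pi_sites")],
               list(V = 1L, eta = 2L, S = 1L, Pi_sites = 0L))

  # two alleles each twice: parsimony informative, not singleton
  pi2 <- mk_aln(c("AAAA", "AAAA", "TAAA", "TAAA"))
  sc <- site_counts(pi2)
  expect_equal(sc[c("V", "S", "Pi_sites")], list(V = 1L, S = 0L, Pi_sites = 1L))
})

test_that("nucleotide diversity matches hand-computed pairwise sums", {
  ident <- mk_aln(rep("ACGTACGTAC", 3))
  expect_equal(nucleotide_diversity(ident), 0)

  # n = 4, L = 10, pairwise differences sum to 7
  a <- mk_aln(c("AAAAAAAAAA", "TAAAAAAAAA", "TTAAAAAAAA", "TTAAAAAAAA"))
  expect_equal(nucleotide_diversity(a), 7 / 60)
  expect_equal(nucleotide_diversity(a), brute_pi(a))
})

test_that("Watterson theta uses the exact harmonic sum", {
  mono <- mk_aln(rep("ACGTACGTAC", 4))
  expect_equal(watterson_theta(mono), 0)

  # n = 4, S = 3, L = 10
  a <- mk_aln(c("AAAAAAAAAA", "TAAAAAAAAA", "ATAAAAAAAA", "AATAAAAAAA"))
  expect_equal(watterson_theta(a), 3 / ((1 + 1/2 + 1/3) * 10))

  # n = 2 limit: a_n = 1
  b <- mk_aln(c("AAAAAAAAAA", "TTAAAAAAAA"))
  expect_equal(watterson_theta(b), 2 / 10)
})

test_that("haplotype statistics match the unbiased estimator", {
  ident <- mk_aln(rep("ACGT", 4))
  expect_equal(haplotype_stats(ident), list(H = 1L, Hd = 0))

  two <- mk_aln(c("AAAA", "AAAA", "TTTT", "TTTT"))
  hp <- haplotype_stats(two)
  expect_equal(hp$H, 2L)
  expect_equal(hp$Hd, (4 / 3) * (1 - 0.5))

  four <- mk_aln(c("AAAA", "TAAA", "ATAA", "AATA"))
  expect_equal(haplotype_stats(four)$Hd, 1)
})

test_that("estimators agree with brute-force oracles on random alignments", {
  set.seed(101)
  for (rep in 1:300) {
    aln <- rand_aln(sample(2:8, 1), sample(5:30, 1),
                    p_gap = sample(c(0, 0.08), 1))
    if (ncol(brute_usable(aln)) == 0) next
    expect_equal(nucleotide_diversity(aln), brute_pi(aln), tolerance = 1e-12)
    expect_equal(watterson_theta(aln), brute_theta(aln), tolerance = 1e-12)
    expect_equal(watterson_theta(aln, type = "eta"),
                 brute_theta(aln, type = "eta"), tolerance = 1e-12)
    sc <- site_counts(aln); bc <- brute_counts(aln)
    expect_identical(c(sc$V, sc$eta, sc$S, sc$Pi_sites),
                     as.integer(c(bc$V, bc$eta, bc$S, bc$Pi)))
    hp <- haplotype_stats(aln); bh <- brute_hd(aln)
    expect_equal(hp$H, unname(bh$H))
    expect_equal(hp$Hd, unname(bh$Hd), tolerance = 1e-12)
    expect_true(hp$Hd >= 0 && hp$Hd <= 1)
  }
})

test_that("loss-of-diversity statistics reproduce printed-scale arithmetic", {
  # mean whole-sequence diversities of the wild/domesticated summary table
  expect_equal(round(loss_of_diversity(5.39e-3, 2.70e-3)$L, 2), 0.50)
  # mean coding-region Watterson estimates
  expect_equal(round(loss_of_diversity(3.09e-3, 1.77e-3)$L, 2), 0.43)

  x <- c(0.5, 1, 2)
  ld <- loss_of_diversity(x, x)
  expect_equal(ld$L, 0)
  expect_equal(ld$L1, 0)

  # loci monomorphic in the wild are excluded from L1, kept in L
  ld <- loss_of_diversity(c(0, 1), c(0, 0.5))
  expect_equal(ld$n_excluded, 1L)
  expect_equal(ld$L1, 0.5)
  expect_equal(ld$L, 0.5)

  expect_error(loss_of_diversity(c(0, 0), c(0, 0)), "undefined")
})

test_that("dataset summary table aggregates per the table conventions", {
  ds <- tiny_dataset()
  tab <- summarize_dataset(ds, "whole", "MW")
  foot <- tab[tab$locus == "overall", ]
  expect_equal(foot$V, sum(tab$V[tab$locus != "overall"]))
  expect_equal(foot$snp_freq, foot$V / foot$L)

  # monomorphic single locus
  mono <- bean_dataset(
    list(m1 = mk_aln(rep("ACGTACGT", 4), "m1")), list(),
    setNames(rep("MW", 4), paste0("s", 1:4)))
  tm <- summarize_dataset(mono, "whole", "MW")
  foot <- tm[tm$locus == "overall", ]
  expect_equal(foot$V, 0L)
  expect_equal(foot$H, 1)
  expect_equal(foot$pi, 0)
})

test_that("variable sites add over a region partition", {
  set.seed(21)
  cfg <- generator_config(n_loci = 8, length_range = c(150, 400),
                          p_unannotated = 0, seed = 21)
  ds <- generate_dataset(cfg)
  wh <- summarize_dataset(ds, "whole", "MW")
  co <- summarize_dataset(ds, "coding", "MW")
  nc <- summarize_dataset(ds, "noncoding", "MW")
  for (id in names(ds$loci)) {
    v_w <- wh$V[wh$locus == id]
    v_c <- co$V[co$locus == id]
    v_n <- nc$V[nc$locus == id]
    expect_equal(v_w, sum(v_c, v_n))  # empty slices contribute nothing
  }
})
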