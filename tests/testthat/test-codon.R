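test_that("site-level synonymous/nonsynonymous classification follows the code table", {
  # GGG vs GGA at codon position 3: Gly/Gly
  a <- mk_aln(c("GGG", "GGG", "GGA"))
  expect_equal(classify_site_syn_nonsyn(a, 3), "synonymous")

  # TCT vs TTT at position 2: Ser -> Phe
  b <- mk_aln(c("TCT", "TCT", "TTT"))
  expect_equal(classify_site_syn_nonsyn(b, 2), "nonsynonymous")

  # ATG vs ACG at position 2: Met -> Thr
  d <- mk_aln(c("ATG", "ACG"))
  expect_equal(classify_site_syn_nonsyn(d, 2), "nonsynonymous")

  expect_equal(classify_site_syn_nonsyn(b, 1), "invariant")

  # codon overlapping a masked column is excluded
  g <- mk_aln(c("TC-", "TTT"))
  expect_equal(classify_site_syn_nonsyn(g, 2), "excluded")

  # frame offset shifts codon boundaries
  e <- mk_aln(c("ATCTA", "ATTTA"))  # frame 1: codon = columns 2..4
  expect_equal(classify_site_syn_nonsyn(e, 3, frame_offset = 1L),
               "nonsynonymous")
})

test_that("syn/nonsyn change counts accumulate per variable site", {
  aln <- mk_aln(c("ATGTCTGGA", "ATGTCTGGA", "ATGTTTGGG", "ATGTCTGGG"))
  cc <- count_syn_nonsyn(aln, frame_offset = 0L)
  expect_equal(cc$syn, 1L)     # GGA/GGG third position
  expect_equal(cc$nonsyn, 1L)  # TCT/TTT serine -> phenylalanine
})

test_that("polymorphism partition classifies shared and private mutations", {
  w <- mk_aln(c("AAAA", "TAAA", "AAAA"), "g")
  d <- mk_aln(c("AAAA", "TAAA"), "g")
  pp <- partition_polymorphisms(w, d)
  expect_equal(pp$SM, 1L)  # A/T segregating in both

  d2 <- mk_aln(c("AAAA", "AAAA"), "g")
  pp <- partition_polymorphisms(w, d2)
  expect_equal(pp$P_MW, 1L)
  expect_equal(pp$SM + pp$P_MD, 0L)

  w2 <- mk_aln(c("AAAA", "AAAA"), "g")
  d3 <- mk_aln(c("AAAA", "TAAA"), "g")
  pp <- partition_polymorphisms(w2, d3)
  expect_equal(pp$P_MD, 1L)

  # tri-allelic: A/T shared, third allele G private to the wild sample
  w3 <- mk_aln(c("AAAA", "TAAA", "GAAA"), "g")
  d4 <- mk_aln(c("AAAA", "TAAA"), "g")
  pp <- partition_polymorphisms(w3, d4)
  expect_equal(pp$SM, 1L)
  expect_equal(pp$P_MW, 1L)
})

test_that("partition conserves the pooled mutation count over relevant sites", {
  set.seed(31)
  for (rep in 1:40) {
    w <- rand_aln(sample(3:6, 1), 20, p_gap = 0.03, id = "g")
    d <- rand_aln(sample(3:6, 1), 20, p_gap = 0.03, id = "g")
    pp <- partition_polymorphisms(w, d)
    # oracle: pooled eta restricted to sites variable within >= 1 population
    pm <- rbind(w$mat, d$mat)
    keep <- apply(pm, 2, function(col) all(col %in% c("A", "C", "G", "T")))
    eta_rel <- 0L
    for (s in which(keep)) {
      cw <- table(w$mat[, s]); cd <- table(d$mat[, s])
      if (length(cw) < 2 && length(cd) < 2) next
      eta_rel <- eta_rel + length(table(pm[, s])) - 1L
    }
    expect_equal(pp$SM + pp$P_MW + pp$P_MD, eta_rel)
  }
})

test_that("private replacement report finds derived MD variants", {
  mk_ds <- function(md2_codon = "TCT", out_codon = "TCT") {
    seqs <- c(mw1 = paste0("ATG", "TCT", "GGA"), mw2 = paste0("ATG", "TCT", "GGA"),
              md1 = paste0("ATG", "TTT", "GGA"),
              md2 = paste0("ATG", md2_codon, "GGA"),
              aw1 = paste0("ATG", "TCT", "GGA"),
              pd1 = paste0("ATG", out_codon, "GGA"))
    manifest <- setNames(c("MW", "MW", "MD", "MD", "AW", "OUT_PD"), names(seqs))
    ann <- region_annotation("g1", data.frame(start = 0L, end = 9L,
                                              class = "exon"))
    bean_dataset(list(g1 = mk_aln(seqs, "g1")), list(g1 = ann), manifest)
  }
  rep1 <- private_replacement_report(mk_ds())
  expect_equal(nrow(rep1), 1L)
  expect_equal(rep1$variant_codon, "TTT")
  expect_equal(rep1$variant_aa, "F")
  expect_equal(rep1$background_aa, "S")
  expect_true(rep1$derived)
  expect_equal(rep1$MD, 1L)

  # variant also carried by a wild accession: not private, no record
  ds2 <- mk_ds()
  ds2$loci$g1$mat["mw1", 5] <- "T"
  expect_equal(nrow(private_replacement_report(ds2)), 0L)

  # outgroup carries the variant state: private but not flagged derived
  rep3 <- private_replacement_report(mk_ds(out_codon = "TTT"))
  rep3 <- rep3[rep3$variant_aa == "F", ]
  expect_equal(rep3$MD, 1L)
  expect_false(rep3$derived)
})

test_that("Nei-Gojobori dN/dS matches closed forms and the pathway oracle", {
  ident <- mk_aln(c("ATGTCTGGA", "ATGTCTGGA"))
  ng <- nei_gojobori_dn_ds(ident, n_boot = 0)
  expect_equal(ng$dN, 0)
  expect_equal(ng$dS, 0)

  # single synonymous difference over three glycine codons, R = 1:
  # pS = (1/3) over 3 synonymous sites, dS = -(3/4) log(5/9)
  pair <- mk_aln(c("GGGGGGGGG", "GGAGGGGGG"))
  ng <- nei_gojobori_dn_ds(pair, n_boot = 0)
  expect_equal(ng$dS, -0.75 * log(5 / 9), tolerance = 1e-12)
  expect_equal(ng$dN, 0)

  # two differences within one codon average over both mutational pathways
  two <- rbind("TTT", "GGT")
  b <- brute_ng(two)
  ng2 <- nei_gojobori_dn_ds(codon_matrix_to_aln(two), n_boot = 0)
  expect_equal(ng2$dN, b$dN, tolerance = 1e-12)
  expect_equal(ng2$dS, b$dS, tolerance = 1e-12)

  expect_error(nei_gojobori_dn_ds(mk_aln(c("ATGTAAGGA", "ATGTAAGGA"))),
               "stop codon")
})

test_that("dN/dS agrees with the enumeration oracle on random codon alignments", {
  set.seed(47)
  for (rep in 1:200) {
    cm <- rand_codon_aln(n = sample(2:4, 1), n_codons = sample(2:5, 1))
    R <- sample(c(0.5, 1, 2), 1)
    b <- brute_ng(cm, R)
    ng <- nei_gojobori_dn_ds(codon_matrix_to_aln(cm), R = R, n_boot = 0)
    expect_equal(ng$pS, b$pS, tolerance = 1e-12)
    expect_equal(ng$pN, b$pN, tolerance = 1e-12)
    if (!is.na(b$dS)) expect_equal(ng$dS, b$dS, tolerance = 1e-12)
    if (!is.na(b$dN)) expect_equal(ng$dN, b$dN, tolerance = 1e-12)
  }
})

test_that("bootstrap SEs are seeded and shrink with codon count", {
  cm_small <- rand_codon_aln(4, 10)
  aln_small <- codon_matrix_to_aln(cm_small)
  a <- nei_gojobori_dn_ds(aln_small, n_boot = 300, seed = 5)
  b <- nei_gojobori_dn_ds(aln_small, n_boot = 300, seed = 5)
  expect_identical(a$se_dS, b$se_dS)

  set.seed(8)
  ses <- sapply(c(8, 128), function(nc) {
    cm <- rand_codon_aln(4, nc)
    nei_gojobori_dn_ds(codon_matrix_to_aln(cm), n_boot = 200, seed = 1)$se_dS
  })
  expect_gt(ses[1], ses[2])  # roughly 1/sqrt(codons)
})

test_that("paired signed-rank test matches exact enumeration", {
  und <- paired_wilcoxon_dnds(c(1, 2, 3), c(1, 2, 3))
  expect_true(is.na(und$p_value))
  expect_equal(und$n_pairs, 0L)

  # differences {+1,+2,+3}: one-sided exact P = 1/8
  r <- paired_wilcoxon_dnds(c(2, 4, 6), c(1, 2, 3), alternative = "greater")
  expect_equal(r$p_value, 1 / 8)

  # antisymmetric differences: two-sided exact P = 1
  r2 <- paired_wilcoxon_dnds(c(1, -1, 2, -2), c(0, 0, 0, 0))
  expect_equal(r2$p_value, 1)

  set.seed(13)
  for (rep in 1:25) {
    n <- sample(3:9, 1)
    x <- sample(seq(0.5, 50, by = 0.5), n)  # distinct magnitudes, no ties
    y <- sample(seq(51, 100, by = 0.5), n) * sample(c(-1, 1), n, replace = TRUE)
    d <- x - y
    for (alt in c("greater", "two.sided")) {
      r <- paired_wilcoxon_dnds(x, y, alternative = alt)
      expect_equal(r$p_value, brute_signed_rank_p(d, alt), tolerance = 1e-12)
    }
  }
})

test_that("rank-sum test matches exact enumeration", {
  same <- ranksum_diversity_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)

  # complete separation with n = m = 4: two-sided exact P = 2/70
  r <- ranksum_diversity_test(c(1, 2, 3, 4), c(5, 6, 7, 8))
  expect_equal(r$p_value, 2 / 70)

  expect_error(ranksum_diversity_test(numeric(0), 1:3), "non-empty")

  set.seed(17)
  for (rep in 1:25) {
    x <- sample(1:100, sample(3:5, 1))
    y <- sample(101:200, sample(3:5, 1)) - sample(0:150, 1)
    if (length(intersect(x, y))) next
    r <- ranksum_diversity_test(x, y)
    expect_equal(r$p_value, brute_ranksum_p(x, y), tolerance = 1e-12)
  }
})

test_that("binomial private-coding test sums the exact tail", {
  # P(X >= 8), X ~ Bin(12, 1/2) = 794/4096
  expect_equal(binomial_private_coding_test(8, 4, 6, 6), 794 / 4096)
  # zero observed: tail probability 1
  expect_equal(binomial_private_coding_test(0, 5, 3, 7), 1)
  # degenerate p0 = 1
  expect_equal(binomial_private_coding_test(5, 0, 4, 0), 1)
  # length standardization reweights the null proportion
  p_std <- binomial_private_coding_test(8, 4, 6, 6,
                                        null_mode = "length_standardized",
                                        mw_lengths = c(100, 300),
                                        md_lengths = c(100, 300))
  p0 <- (6 / 100 * 100) / (6 / 100 * 100 + 6 / 300 * 300)
  expect_equal(p_std, pbinom(7, 12, p0, lower.tail = FALSE))
  expect_error(binomial_private_coding_test(0, 0, 1, 1), "focal")
})
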