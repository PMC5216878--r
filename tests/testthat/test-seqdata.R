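test_that("FASTA reading validates shape and alphabet, tolerates comments/CRLF", {
  f <- write_tmp_fasta(c("# comment line", ">a1", "ACGT", ">a2", "acgt"))
  aln <- read_alignment(f, "L1")
  expect_s3_class(aln, "locus_alignment")
  expect_equal(dim(aln), c(2L, 4L))
  expect_equal(unname(aln$mat[2, ]), c("A", "C", "G", "T"))  # uppercased

  f2 <- write_tmp_fasta(c(">a1\r", "ACGT\r", ">a2\r", "ACGTA\r"))
  expect_error(read_alignment(f2), "alignment error")

  f3 <- write_tmp_fasta(c(">a1", "ACXT", ">a2", "ACGT"))
  expect_error(read_alignment(f3), "illegal")
})

test_that("alignment write/read round-trips", {
  aln <- rand_aln(5, 40, p_gap = 0.05)
  f <- tempfile(fileext = ".fasta")
  write_alignment(aln, f)
  back <- read_alignment(f, aln$locus_id)
  expect_identical(back$mat, aln$mat)
})

test_that("manifest reading enforces labels and uniqueness", {
  f <- tempfile()
  writeLines(c("acc1\tMW", "acc2\tMD"), f)
  expect_equal(read_manifest(f), c(acc1 = "MW", acc2 = "MD"))

  writeLines(c("acc1\tMW", "acc1\tMD"), f)
  expect_error(read_manifest(f), "duplicate")

  writeLines(c("acc1\tWILD"), f)
  expect_error(read_manifest(f), "unknown population label")

  m <- c(a = "MW", b = "MD", c = "OUT_PC")
  f2 <- tempfile()
  write_manifest(m, f2)
  expect_equal(read_manifest(f2), m)
})

test_that("annotations convert 1-based inclusive input and validate intervals", {
  f <- tempfile()
  writeLines(c("locus_id\tstart\tend\tclass\tframe", "g1\t1\t6\texon\t0"), f)
  ann <- read_annotations(f, lengths = c(g1 = 10L))[["g1"]]
  expect_equal(ann$intervals$start, 0L)
  expect_equal(ann$intervals$end, 6L)

  writeLines(c("locus_id\tstart\tend\tclass\tframe",
               "g1\t1\t6\texon\t0", "g1\t5\t8\tintron\t0"), f)
  expect_error(read_annotations(f), "overlap")

  writeLines(c("locus_id\tstart\tend\tclass\tframe", "g1\t8\t12\tintron\t0"), f)
  expect_error(read_annotations(f, lengths = c(g1 = 10L)), "beyond locus length")

  anns <- list(g1 = region_annotation("g1", data.frame(
    start = c(0L, 6L), end = c(6L, 10L), class = c("exon", "intron"))))
  f2 <- tempfile()
  write_annotations(anns, f2)
  back <- read_annotations(f2, lengths = c(g1 = 10L))
  expect_equal(back$g1$intervals, anns$g1$intervals)
})

test_that("slice_region extracts classes and signals empty regions", {
  aln <- rand_aln(4, 10)
  ann <- region_annotation(aln$locus_id, data.frame(
    start = c(0L, 6L), end = c(6L, 10L), class = c("exon", "intron")))
  ex <- slice_region(aln, ann, "exon")
  expect_equal(ncol(ex$mat), 6L)
  expect_identical(ex$mat, aln$mat[, 1:6])
  expect_equal(attr(ex, "frame_offset"), 0L)

  expect_null(slice_region(aln, ann, "utr5"))

  all_cl <- slice_region(aln, ann, c("exon", "intron", "utr5", "utr3"))
  expect_equal(ncol(all_cl$mat), 10L)
})

test_that("slicing a class partition reconstructs all annotated columns", {
  set.seed(4)
  for (rep in 1:20) {
    aln <- rand_aln(3, 60)
    k <- sample(2:4, 1)
    cuts <- sort(sample(5:55, k - 1))
    ends <- c(cuts, 60L)
    starts <- c(0L, cuts)
    classes <- sample(c("exon", "intron", "utr5", "utr3"), k, replace = TRUE)
    ann <- region_annotation(aln$locus_id,
                             data.frame(start = starts, end = ends,
                                        class = classes))
    total <- 0L
    for (cl in unique(classes)) {
      sl <- slice_region(aln, ann, cl)
      total <- total + ncol(sl$mat)
    }
    expect_equal(total, 60L)
    whole <- slice_region(aln, ann, unique(classes))
    expect_equal(ncol(whole$mat), 60L)
  }
})

test_that("usable_sites is a complete-deletion mask over the chosen subset", {
  seqs <- c(a = "ACGTAC", b = "AC-TAC", c = "ACGTNC")
  aln <- mk_aln(seqs)
  expect_equal(usable_sites(aln), c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE))
  # gap/N carriers excluded from the subset leave the column usable
  expect_true(all(usable_sites(aln, "a")))
  expect_equal(usable_sites(aln, c("a", "b")),
               c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
})

test_that("enlarging the accession subset never turns a column usable", {
  set.seed(9)
  for (rep in 1:20) {
    aln <- rand_aln(6, 30, p_gap = 0.1)
    accs <- rownames(aln$mat)
    small <- sample(accs, 3)
    big <- union(small, sample(accs, 2))
    m_small <- usable_sites(aln, small)
    m_big <- usable_sites(aln, big)
    expect_true(all(m_big <= m_small))
  }
})

test_that("datasets validate membership and round-trip through a directory", {
  ds <- tiny_dataset()
  expect_equal(pop_accessions(ds, "MW"), c("mw1", "mw2", "mw3"))
  expect_error(bean_dataset(ds$loci, ds$annotations,
                            ds$manifest[-1]), "missing from manifest")

  d <- tempfile()
  attr(ds, "truth") <- list(swept_loci = "g1", seed = 7L)
  write_dataset(ds, d)
  back <- read_dataset(d)
  expect_identical(back$loci$g1$mat, ds$loci$g1$mat)
  expect_equal(back$annotations$g1$intervals, ds$annotations$g1$intervals)
  expect_equal(back$manifest, ds$manifest)
  expect_equal(attr(back, "truth")$swept_loci, "g1")
})
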