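# Small hand-built datasets shared across tests.

tiny_dataset <- function() {
  # locus "g1": 12 bp, exon (1..6, frame 0) + intron (7..12)
  seqs <- c(mw1 = "ATGTCTAAGGTC", mw2 = "ATGTCTAAGGTC",
            mw3 = "ATGTCTATGGTC", md1 = "ATGTTTAAGGTC",
            md2 = "ATGTTTAAGGTC", md3 = "ATGTCTAAGGTC")
  aln <- mk_aln(seqs, "g1")
  ann <- region_annotation("g1", data.frame(
    start = c(0L, 6L), end = c(6L, 12L), class = c("exon", "intron")),
    frame_offset = 0L, length = 12L)
  manifest <- setNames(c("MW", "MW", "MW", "MD", "MD", "MD"), names(seqs))
  bean_dataset(list(g1 = aln), list(g1 = ann), manifest)
}

write_tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}
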