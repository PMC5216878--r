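# Synthetic-data generator: desk-scale wild/domesticated sequence panels
# with known truth, emulating a multi-locus amplicon resequencing design
# (49 loci of 150-900 bp, 19 wild + 20 domesticated haploid inbred
# sequences, exon/intron mosaic structure, a domestication bottleneck, and
# optional injected sweeps).
#
# Sweeps are emulated demographically, with two ingredients and no explicit
# selection coefficient: (i) diversity loss - the domesticated bottleneck
# size and the post-domestication domesticated size are both scaled by the
# retention fraction; (ii) differentiation boost - the swept fragment's
# domesticated lineages stay isolated from the wild pool back to the
# configured merge time (default: the ancestral pool split), mimicking the
# fixation by hitchhiking of a rare, deeply diverged standing haplotype.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Generator configuration
#'
#' @param n_loci number of loci (default 49).
#' @param length_range locus length range in bp (default 150-900).
#' @param n_wild,n_dom haploid sample sizes (defaults 19 and 20).
#' @param model truth demography, a [demographic_model()] (two-population
#'   wild/domesticated reduction is used for the sequences).
#' @param mu_exon,mu_intron mutation rates per site per generation
#'   (defaults 1e-9 and 1e-8; the exon rate is 10-fold lower).
#' @param sweep_loci indices of swept loci (subset of `1:n_loci`).
#' @param sweep_retention post-domestication diversity retention fraction
#'   in `(0, 1]` for swept loci (small = strong sweep).
#' @param sweep_merge_time differentiation boost: backward merge time of the
#'   swept domesticated lineages into the wild pool, in generations;
#'   `NULL` (default) anchors it at the model's pool-split time `T_ANC`,
#'   emulating a sweep that fixed a rare standing haplotype of maximal
#'   within-species divergence. Use the model's `T_BMD` for no boost.
#' @param p_unannotated fraction of loci without structure information.
#' @param seed RNG seed.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_loci = 49L, length_range = c(150L, 900L),
                             n_wild = 19L, n_dom = 20L,
                             model = demographic_model(1L),
                             mu_exon = 1e-9, mu_intron = 1e-8,
                             sweep_loci = integer(0), sweep_retention = 0.05,
                             sweep_merge_time = NULL,
                             p_unannotated = 4 / 49, seed = 1L) {
  stopifnot(n_loci >= 1L, length_range[1L] >= 30L,
            length_range[2L] >= length_range[1L],
            all(sweep_loci %in% seq_len(n_loci)),
            sweep_retention > 0, sweep_retention <= 1)
  if (is.null(sweep_merge_time)) sweep_merge_time <- model$params$T_ANC
  stopifnot(sweep_merge_time >= model$params$T_BMD,
            sweep_merge_time <= model$params$T_ANC)
  structure(list(n_loci = as.integer(n_loci),
                 length_range = as.integer(length_range),
                 n_wild = as.integer(n_wild), n_dom = as.integer(n_dom),
                 model = model, mu_exon = mu_exon, mu_intron = mu_intron,
                 sweep_loci = as.integer(sweep_loci),
                 sweep_retention = sweep_retention,
                 sweep_merge_time = sweep_merge_time,
                 p_unannotated = p_unannotated, seed = as.integer(seed)),
            class = "generator_config")
}

# Random exon/intron/UTR mosaic for a locus of length L; NULL = unannotated.
# Mimics an amplicon panel designed to span gene structures: most loci mix
# coding and noncoding sequence, with the noncoding share drawn around the
# roughly half-and-half split of such panels; a few loci are purely
# noncoding (UTR/intron-only amplicons).
.random_structure <- function(L, unannotated) {
  if (unannotated) return(NULL)
  split_len <- function(total, k) {
    w <- runif(k, 0.6, 1.4)
    lens <- floor(total * w / sum(w))
    lens[1L] <- lens[1L] + total - sum(lens)
    lens
  }
  if (runif(1L) < 0.1) {                    # purely noncoding locus
    classes <- sample(c("intron", "utr5", "utr3"), sample(1:2, 1L))
    lens <- split_len(L, length(classes))
  } else {
    n_exons <- sample.int(max(1L, min(3L, L %/% 150L + 1L)), 1L)
    has_utr5 <- runif(1L) < 0.2
    has_utr3 <- runif(1L) < 0.3
    if (n_exons == 1L && !has_utr5 && !has_utr3) has_utr3 <- TRUE
    classes <- c(if (has_utr5) "utr5",
                 head(rep(c("exon", "intron"), n_exons), 2L * n_exons - 1L),
                 if (has_utr3) "utr3")
    nc_share <- runif(1L, 0.3, 0.7)
    is_exon <- classes == "exon"
    lens <- integer(length(classes))
    lens[is_exon] <- split_len(round((1 - nc_share) * L), sum(is_exon))
    lens[!is_exon] <- split_len(L - sum(lens[is_exon]), sum(!is_exon))
  }
  if (any(lens < 25L)) return(.random_structure(L, unannotated))
  ends <- cumsum(lens)
  data.frame(start = c(0L, head(ends, -1L)), end = ends, class = classes,
             stringsAsFactors = FALSE)
}

# reference sequence respecting the exon reading frame (no internal stops)
.reference_sequence <- function(L, structure) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, L, replace = TRUE)
  if (is.null(structure)) return(ref)
  exon_cols <- unlist(Map(function(s, e) seq.int(s + 1L, e),
                          structure$start[structure$class == "exon"],
                          structure$end[structure$class == "exon"]))
  if (is.null(exon_cols) || length(exon_cols) < 3L) return(ref)
  nc <- length(exon_cols) %/% 3L
  codons <- setdiff(names(GENCODE), STOP_CODONS)
  drawn <- sample(codons, nc, replace = TRUE)
  ref[exon_cols[seq_len(3L * nc)]] <- unlist(strsplit(drawn, ""))
  ref
}

# exon column index (within locus) -> codon column triple, or NULL
.exon_codon_cols <- function(exon_cols, col) {
  pos <- match(col, exon_cols)
  phase <- (pos - 1L) %% 3L
  s <- pos - phase
  if (s + 2L > length(exon_cols)) return(NULL)
  exon_cols[s:(s + 2L)]
}

#' Generate a synthetic dataset with known truth
#'
#' Neutral loci are simulated under the configured demography; exon
#' mutations that would create an internal stop codon in the reference
#' frame are rejection-resampled; swept loci re-run the coalescent with the
#' domesticated bottleneck intensified by the retention fraction. The
#' attached truth record (`attr(ds, "truth")`) lists the swept loci and all
#' generating parameters; identical seeds give identical datasets.
#'
#' @param config a [generator_config()].
#' @return a [bean_dataset()] with a `truth` attribute.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  accs <- c(sprintf("mw%02d", seq_len(config$n_wild)),
            sprintf("md%02d", seq_len(config$n_dom)))
  manifest <- setNames(rep(c("MW", "MD"), c(config$n_wild, config$n_dom)), accs)
  sweep_model <- local({
    p <- config$model$params
    p$N_MD <- p$N_MD * config$sweep_retention
    p$I_MD <- p$I_MD * config$sweep_retention
    p$T_BMD <- config$sweep_merge_time    # differentiation boost
    p$M_WD <- 0; p$M_DW <- 0   # directional selection repels introgression
    demographic_model(config$model$model_id, p,
                      growth_steps = config$model$growth_steps)
  })
  loci <- list(); anns <- list()
  n_unann <- round(config$p_unannotated * config$n_loci)
  # swept loci must be annotated: an unannotated gene is invisible to the
  # exon/intron fragment scan by construction
  unann <- sample(setdiff(seq_len(config$n_loci), config$sweep_loci),
                  min(n_unann, config$n_loci - length(config$sweep_loci)))
  for (li in seq_len(config$n_loci)) {
    id <- sprintf("locus%02d", li)
    L <- sample(seq.int(config$length_range[1L], config$length_range[2L]), 1L)
    structure_df <- .random_structure(L, li %in% unann)
    ref <- .reference_sequence(L, structure_df)
    mu_col <- rep(config$mu_intron, L)
    exon_cols <- integer(0)
    if (!is.null(structure_df)) {
      exon_cols <- unlist(Map(function(s, e) seq.int(s + 1L, e),
                              structure_df$start[structure_df$class == "exon"],
                              structure_df$end[structure_df$class == "exon"]))
      if (length(exon_cols)) mu_col[exon_cols] <- config$mu_exon
    }
    mod <- if (li %in% config$sweep_loci) sweep_model else config$model
    be <- build_epochs(mod, c("MW", "MD"))
    sample_demes <- rep(0:1, c(config$n_wild, config$n_dom))
    tree <- .sim_tree_cpp(sample_demes, be$epochs, 2L)
    n_mut <- rpois(length(tree$length), tree$length * sum(mu_col))
    mat <- matrix(rep(ref, each = length(accs)), nrow = length(accs),
                  dimnames = list(accs, NULL))
    total <- sum(n_mut)
    if (total > 0L) {
      leaves <- .edge_leaves_cpp(tree$child, tree$parent,
                                 length(tree$node_time), tree$n_samples)
      # infinite sites per column: each mutated column used once
      cols <- sample.int(L, min(total, L), prob = mu_col)
      ci <- 1L
      for (e in seq_along(n_mut)) {
        if (n_mut[e] == 0L) next
        for (k in seq_len(n_mut[e])) {
          if (ci > length(cols)) break
          col <- cols[ci]; ci <- ci + 1L
          alts <- setdiff(c("A", "C", "G", "T"), ref[col])
          if (col %in% exon_cols) {
            trip <- .exon_codon_cols(exon_cols, col)
            if (!is.null(trip)) {
              ok <- vapply(alts, function(b) {
                cd <- ref[trip]; cd[match(col, trip)] <- b
                !(paste0(cd, collapse = "") %in% STOP_CODONS)
              }, TRUE)
              alts <- alts[ok]
              if (!length(alts)) next   # stop-avoidance rejection
            }
          }
          mat[leaves[[e]], col] <- sample(alts, 1L)
        }
      }
    }
    loci[[id]] <- locus_alignment(id, mat)
    if (!is.null(structure_df))
      anns[[id]] <- region_annotation(id, structure_df, frame_offset = 0L,
                                      length = L)
  }
  ds <- bean_dataset(loci, anns, manifest)
  attr(ds, "truth") <- list(
    seed = config$seed, n_loci = config$n_loci,
    swept_loci = sprintf("locus%02d", config$sweep_loci),
    sweep_retention = config$sweep_retention,
    sweep_merge_time = config$sweep_merge_time,
    model_id = config$model$model_id, params = config$model$params,
    mu_exon = config$mu_exon, mu_intron = config$mu_intron,
    n_wild = config$n_wild, n_dom = config$n_dom)
  ds
}

#' Synthetic biallelic SNP panel from an island model
#'
#' Markers are sampled from the symmetric island coalescent used by the
#' FDIST null (two sampled demes). Optionally a block of markers is made to
#' fail the standard panel filters (missingness > 5% or MAF at the 0.01
#' boundary), to mimic the pre-filter state of a genotyping panel.
#'
#' @param n_markers total markers.
#' @param n1,n2 haploid sample sizes of the two demes.
#' @param target_fst island-model mean FST used to solve the migration
#'   rate.
#' @param n_demes island count (default 100).
#' @param n_fail_missing,n_fail_maf markers engineered to fail the
#'   missingness / MAF filter.
#' @param seed RNG seed.
#' @return list with `geno` (markers x individuals 0/1/NA matrix) and
#'   `pops` (individual population labels).
#' @export
generate_snp_panel <- function(n_markers, n1 = 30L, n2 = 30L,
                               target_fst = 0.2, n_demes = 100L,
                               n_fail_missing = 0L, n_fail_maf = 0L,
                               seed = 1L) {
  stopifnot(n_fail_missing + n_fail_maf <= n_markers)
  set.seed(seed)
  m <- .calibrate_island_m(target_fst, c(n1, n2), n_demes)
  n <- n1 + n2
  geno <- matrix(NA_integer_, n_markers, n,
                 dimnames = list(sprintf("snp%03d", seq_len(n_markers)),
                                 c(sprintf("w%03d", seq_len(n1)),
                                   sprintf("d%03d", seq_len(n2)))))
  need <- n_markers
  got <- 0L
  while (got < n_markers) {
    cts <- .sim_island_snps_cpp(2L * (need - got), n1, n2, n_demes, m, 1)
    for (r in seq_len(nrow(cts))) {
      tot <- cts[r, 1L] + cts[r, 2L]
      if (tot == 0L || tot == n) next           # safety; cannot happen
      got <- got + 1L
      x <- integer(n)
      x[sample.int(n1, cts[r, 1L])] <- 1L
      x[n1 + sample.int(n2, cts[r, 2L])] <- 1L
      geno[got, ] <- x
      if (got == n_markers) break
    }
  }
  fail_rows <- sample.int(n_markers, n_fail_missing + n_fail_maf)
  miss_rows <- fail_rows[seq_len(n_fail_missing)]
  maf_rows <- setdiff(fail_rows, miss_rows)
  for (r in miss_rows)
    geno[r, sample.int(n, ceiling(0.06 * n))] <- NA_integer_
  # below-threshold MAF: with desk-scale sample sizes this means a
  # monomorphic genotyped marker (MAF <= 0.01 requires <= n/100 carriers)
  for (r in maf_rows) geno[r, ] <- 0L
  list(geno = geno,
       pops = setNames(rep(c("MW", "MD"), c(n1, n2)), colnames(geno)))
}

#' Hand-built worked fixtures
#'
#' Returns (a) tiny alignments exercising every estimator branch
#' (monomorphic, singleton, tri-allelic, gapped, codon replacement cases)
#' and (b) the machine-readable transcriptions of the published summary
#' tables shipped under `extdata` (see [load_printed_tables()]).
#'
#' @param what `"all"`, `"alignments"` or `"tables"`.
#' @return named list.
#' @export
make_worked_fixtures <- function(what = "all") {
  if (!what %in% c("all", "alignments", "tables"))
    stop("unknown fixture bundle: ", what)
  mk <- function(id, seqs) {
    locus_alignment(id, matrix(unlist(strsplit(seqs, "")),
                               nrow = length(seqs), byrow = TRUE,
                               dimnames = list(names(seqs), NULL)))
  }
  alns <- list(
    monomorphic = mk("mono", c(a1 = "ACGTACGTAC", a2 = "ACGTACGTAC",
                               a3 = "ACGTACGTAC", a4 = "ACGTACGTAC")),
    singleton = mk("single", c(a1 = "ACGTACGTAC", a2 = "ACGTACGTAC",
                               a3 = "ACGTACGTAC", a4 = "ACGTACTTAC")),
    triallelic = mk("tri", c(a1 = "AAAA", a2 = "AAAA", a3 = "TAAA",
                             a4 = "GAAA")),
    gapped = mk("gap", c(a1 = "AC-TACGTAC", a2 = "ACGTACGTAC",
                         a3 = "ACGTACGTNC", a4 = "ACGTACGTAC")),
    # DNAJ-like serine->phenylalanine replacement: background TCT, one
    # variant TTT at codon 2
    replacement = mk("dnaj", c(w1 = "ATGTCTGGA", w2 = "ATGTCTGGA",
                               d1 = "ATGTCTGGA", d2 = "ATGTTTGGA")))
  if (what == "alignments") return(alns)
  tabs <- load_printed_tables()
  if (what == "tables") return(tabs)
  c(list(alignments = alns), tabs)
}
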