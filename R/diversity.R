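# Per-locus, per-region diversity estimators and loss-of-diversity summaries.
#
# All estimators use complete deletion by default: sites carrying a gap or N
# in any analyzed accession are dropped (indels are never counted as
# polymorphisms). theta_W is computed from segregating sites by default; an
# eta-based variant is provided since total mutation counts are reported
# separately.

# allele counts (A,C,G,T) per column of a character matrix
.allele_counts <- function(m) {
  L <- ncol(m)
  cnt <- matrix(0L, nrow = 4L, ncol = L, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (b in rownames(cnt)) cnt[b, ] <- colSums(m == b)
  cnt
}

# resolve (accessions, mask) into the analyzed sub-matrix of usable columns
.usable_matrix <- function(aln, accessions = NULL, mask = NULL) {
  a <- if (is.null(accessions)) aln else aln_subset(aln, accessions)
  if (is.null(mask)) mask <- usable_sites(a)
  if (length(mask) != ncol(a$mat)) stop("mask length != alignment length")
  a$mat[, mask, drop = FALSE]
}

#' Site-pattern counts (V, eta, S, parsimony-informative)
#'
#' `V` is the number of variable sites, `eta` the total number of mutations
#' (k observed alleles at a site contribute k-1), `S` the singleton variable
#' sites (every non-major allele occurs exactly once), and `Pi_sites` the
#' parsimony-informative sites (>= 2 alleles each with count >= 2).
#'
#' @param aln a [locus_alignment()].
#' @param accessions optional accession subset.
#' @param mask optional usable-site mask (default complete deletion on the
#'   subset).
#' @return list with `V`, `eta`, `S`, `Pi_sites`, `L` (usable sites), `n`.
#' @export
site_counts <- function(aln, accessions = NULL, mask = NULL) {
  m <- .usable_matrix(aln, accessions, mask)
  if (nrow(m) < 2L) stop("need >= 2 sequences")
  cnt <- .allele_counts(m)
  k <- colSums(cnt > 0L)
  srt <- apply(cnt, 2L, sort, decreasing = TRUE)
  variable <- k >= 2L
  list(V = as.integer(sum(variable)),
       eta = as.integer(sum(pmax(k - 1L, 0L))),
       S = as.integer(sum(variable & srt[2L, ] == 1L)),
       Pi_sites = as.integer(sum(srt[2L, ] >= 2L)),
       L = ncol(m), n = nrow(m))
}

#' Nucleotide diversity (pi per site)
#'
#' Average pairwise difference per usable site. With
#' `deletion = "pairwise"` each pair is compared over its own gap-free
#' columns and per-pair per-site distances are averaged.
#'
#' @inheritParams site_counts
#' @param deletion `"complete"` (default) or `"pairwise"`.
#' @return pi per site; `NA` when no usable site exists.
#' @export
nucleotide_diversity <- function(aln, accessions = NULL, mask = NULL,
                                 deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  a <- if (is.null(accessions)) aln else aln_subset(aln, accessions)
  n <- nrow(a$mat)
  if (n < 2L) stop("need >= 2 sequences")
  if (deletion == "pairwise") {
    ok <- a$mat %in% c("A", "C", "G", "T")
    dim(ok) <- dim(a$mat)
    tot <- 0; npair <- 0L
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      both <- ok[i, ] & ok[j, ]
      Lij <- sum(both)
      if (Lij > 0L) {
        tot <- tot + sum(a$mat[i, both] != a$mat[j, both]) / Lij
        npair <- npair + 1L
      }
    }
    if (npair == 0L) return(NA_real_)
    return(tot / npair)
  }
  m <- .usable_matrix(a, NULL, mask)
  L <- ncol(m)
  if (L == 0L) return(NA_real_)
  cnt <- .allele_counts(m)
  pairs_diff <- choose(n, 2L) - colSums(choose(cnt, 2L))
  sum(pairs_diff) / (choose(n, 2L) * L)
}

#' Watterson's theta per site
#'
#' `theta = S* / (a_n * L)` with `a_n = sum(1/i, i = 1..n-1)`; `S*` is the
#' number of segregating sites by default, or eta with `type = "eta"`.
#'
#' @inheritParams site_counts
#' @param type `"S"` (segregating sites, default) or `"eta"`.
#' @export
watterson_theta <- function(aln, accessions = NULL, mask = NULL,
                            type = c("S", "eta")) {
  type <- match.arg(type)
  sc <- site_counts(aln, accessions, mask)
  if (sc$L == 0L) return(NA_real_)
  a_n <- sum(1 / seq_len(sc$n - 1L))
  (if (type == "S") sc$V else sc$eta) / (a_n * sc$L)
}

#' Haplotype count and diversity
#'
#' Haplotypes are distinct row strings over usable sites; `Hd` uses Nei's
#' unbiased estimator `(n/(n-1)) * (1 - sum(p_k^2))`.
#'
#' @inheritParams site_counts
#' @return list with `H` and `Hd`.
#' @export
haplotype_stats <- function(aln, accessions = NULL, mask = NULL) {
  m <- .usable_matrix(aln, accessions, mask)
  n <- nrow(m)
  if (n < 2L) stop("need >= 2 sequences")
  hap <- apply(m, 1L, paste0, collapse = "")
  p <- as.numeric(table(hap)) / n
  # clamp the unbiased estimator against floating-point overshoot at Hd = 1
  list(H = length(p), Hd = min(1, max(0, n / (n - 1) * (1 - sum(p^2)))))
}

#' Loss of diversity between paired per-locus estimates
#'
#' `L = 1 - mean(dom)/mean(wild)` uses the across-locus means; the
#' per-locus variant `L1` averages `1 - dom_i/wild_i` over loci with
#' `wild_i > 0` (loci monomorphic in the wild are excluded from `L1` and
#' their count reported; they still contribute zeros to the mean-based L).
#'
#' @param wild,dom per-locus estimate vectors aligned by locus.
#' @return list with `L`, `L1`, `n_excluded`.
#' @export
loss_of_diversity <- function(wild, dom) {
  stopifnot(length(wild) == length(dom))
  keep <- !is.na(wild) & !is.na(dom)
  wild <- wild[keep]; dom <- dom[keep]
  if (!length(wild) || mean(wild) == 0)
    stop("loss of diversity undefined: wild diversity is zero everywhere")
  pos <- wild > 0
  list(L = 1 - mean(dom) / mean(wild),
       L1 = mean(1 - dom[pos] / wild[pos]),
       n_excluded = sum(!pos))
}

# map a region keyword to annotation classes; NULL means whole sequence
.region_classes <- function(region) {
  switch(region,
         whole = NULL,
         coding = "exon",
         noncoding = c("intron", "utr5", "utr3"),
         intron = "intron",
         utr5 = "utr5",
         utr3 = "utr3",
         stop("unknown region: ", region))
}

# slice one locus of a dataset to a region keyword; NULL when the region is
# structurally absent (or the locus lacks an annotation and region != whole)
.dataset_slice <- function(dataset, locus_id, region) {
  aln <- dataset$loci[[locus_id]]
  classes <- .region_classes(region)
  if (is.null(classes)) return(aln)
  ann <- dataset$annotations[[locus_id]]
  if (is.null(ann)) return(NULL)
  slice_region(aln, ann, classes)
}

#' Per-locus diversity table with aggregate footer
#'
#' One row per locus for the chosen region and population, plus a footer row
#' (`locus = "overall"`) aggregating like a printed summary table: means for
#' `n`, `H`, `Hd`, `pi`, `thetaW`; sums for `V`, `eta`, `S`, `Pi`, `Syn`,
#' `Nonsyn`; footer SNP frequency is `sum(V)/sum(L)`. Loci without the
#' region (or without annotation, for region != "whole") are skipped.
#'
#' @param dataset a [bean_dataset()].
#' @param region one of `whole, coding, noncoding, intron, utr5, utr3`.
#' @param population population label selecting accessions.
#' @param theta_type passed to [watterson_theta()].
#' @return data.frame, last row the footer.
#' @export
summarize_dataset <- function(dataset, region = "whole", population = "MW",
                              theta_type = "S") {
  accs <- pop_accessions(dataset, population)
  if (!length(accs)) stop("no accessions with label ", population)
  rows <- list()
  for (id in names(dataset$loci)) {
    sl <- .dataset_slice(dataset, id, region)
    if (is.null(sl)) next
    keep <- intersect(rownames(sl$mat), accs)
    if (length(keep) < 2L) next
    sub <- aln_subset(sl, keep)
    mask <- usable_sites(sub)
    sc <- site_counts(sub, mask = mask)
    hp <- haplotype_stats(sub, mask = mask)
    pi <- nucleotide_diversity(sub, mask = mask)
    th <- watterson_theta(sub, mask = mask, type = theta_type)
    syn <- nonsyn <- NA_integer_
    if (region == "coding") {
      fr <- attr(sl, "frame_offset")
      cc <- count_syn_nonsyn(sub, frame_offset = fr, mask = mask)
      syn <- cc$syn; nonsyn <- cc$nonsyn
    }
    rows[[id]] <- data.frame(
      locus = id, region = region, n = sc$n, L = sc$L, V = sc$V, eta = sc$eta,
      S = sc$S, Pi = sc$Pi_sites, Syn = syn, Nonsyn = nonsyn, H = hp$H,
      Hd = hp$Hd, pi = ifelse(is.na(pi), 0, pi), thetaW = ifelse(is.na(th), 0, th),
      snp_freq = ifelse(sc$L > 0, sc$V / sc$L, NA_real_),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no analyzable locus for region ", region)
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  footer <- data.frame(
    locus = "overall", region = region, n = mean(tab$n), L = sum(tab$L),
    V = sum(tab$V), eta = sum(tab$eta), S = sum(tab$S), Pi = sum(tab$Pi),
    Syn = if (all(is.na(tab$Syn))) NA_integer_ else sum(tab$Syn, na.rm = TRUE),
    Nonsyn = if (all(is.na(tab$Nonsyn))) NA_integer_ else
      sum(tab$Nonsyn, na.rm = TRUE),
    H = mean(tab$H), Hd = mean(tab$Hd), pi = mean(tab$pi),
    thetaW = mean(tab$thetaW), snp_freq = sum(tab$V) / sum(tab$L),
    stringsAsFactors = FALSE)
  rbind(tab, footer)
}

#' Write a diversity table as TSV
#' @param tab result of [summarize_dataset()].
#' @param path output file.
#' @export
write_diversity_table <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
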