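# Hudson FST with permutation testing and two-level AMOVA.

# per-column allele counts for a subset given a pooled matrix
.hudson_from_counts <- function(cnt1, cnt2, n1, n2) {
  # mean within- and between-population pairwise differences per site
  hw1 <- sum(choose(n1, 2) - colSums(choose(cnt1, 2))) / choose(n1, 2)
  hw2 <- sum(choose(n2, 2) - colSums(choose(cnt2, 2))) / choose(n2, 2)
  hb <- sum(n1 * n2 - colSums(cnt1 * cnt2)) / (n1 * n2)
  if (hb == 0) return(NA_real_)
  1 - ((hw1 + hw2) / 2) / hb
}

#' Hudson's FST between two populations
#'
#' `FST = 1 - Hw/Hb` with `Hw` the mean within-population pairwise
#' difference per site (the two populations weighted equally) and `Hb` the
#' mean between-population pairwise difference. Computed on the
#' complete-deletion mask of the pooled accessions. Monomorphic pooled data
#' give `NA` (the "na" cells of a per-locus report); slightly negative
#' estimates are reported as computed.
#'
#' @param aln1,aln2 [locus_alignment()]s over the same column space.
#' @param mask optional mask (default: complete deletion over the union).
#' @return FST estimate or `NA`.
#' @export
hudson_fst <- function(aln1, aln2, mask = NULL) {
  if (ncol(aln1$mat) != ncol(aln2$mat))
    stop("alignments must share one column space")
  if (nrow(aln1$mat) < 2L || nrow(aln2$mat) < 2L)
    stop("each population needs >= 2 sequences")
  pooled <- rbind(aln1$mat, aln2$mat)
  if (is.null(mask)) mask <- colSums(pooled == "-" | pooled == "N") == 0L
  m1 <- aln1$mat[, mask, drop = FALSE]
  m2 <- aln2$mat[, mask, drop = FALSE]
  if (!ncol(m1)) return(NA_real_)
  .hudson_from_counts(.allele_counts(m1), .allele_counts(m2),
                      nrow(m1), nrow(m2))
}

#' Permutation test for Hudson's FST
#'
#' Population labels are shuffled with group sizes fixed;
#' `p = (1 + #(FST_perm >= FST_obs)) / (n_perm + 1)` (add-one estimator, so
#' p is never exactly 0 at finite replicates).
#'
#' @param aln pooled [locus_alignment()].
#' @param labels two-level factor/character vector aligned with rows.
#' @param n_perm number of label permutations (default 1000).
#' @param seed RNG seed.
#' @return list with `fst`, `p_perm`, `n_perm`.
#' @export
fst_permutation_test <- function(aln, labels, n_perm = 1000L, seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) != 2L) stop("exactly two populations required")
  mask <- usable_sites(aln)
  m <- aln$mat[, mask, drop = FALSE]
  idx1 <- which(labels == lv[1L])
  n1 <- length(idx1); n2 <- nrow(m) - n1
  if (n1 < 2L || n2 < 2L) stop("each population needs >= 2 sequences")
  cnt_all <- .allele_counts(m)
  fst_of <- function(i1) {
    c1 <- .allele_counts(m[i1, , drop = FALSE])
    .hudson_from_counts(c1, cnt_all - c1, n1, n2)
  }
  obs <- fst_of(idx1)
  if (is.na(obs)) stop("observed FST undefined (monomorphic pooled data)")
  set.seed(seed)
  ge <- 0L
  for (b in seq_len(n_perm)) {
    f <- fst_of(sample.int(nrow(m), n1))
    if (!is.na(f) && f >= obs) ge <- ge + 1L
  }
  list(fst = obs, p_perm = (1 + ge) / (n_perm + 1), n_perm = n_perm)
}

# AMOVA variance components from a pairwise-difference matrix
# (squared Euclidean distance = number of differences, the haplotypic
# convention) and group labels.
.amova_from_D <- function(D, labels) {
  labels <- as.character(labels)
  N <- nrow(D)
  grp <- split(seq_len(N), labels)
  P <- length(grp)
  if (P < 2L) stop("need >= 2 populations")
  ssd_of <- function(idx) {
    if (length(idx) < 2L) return(0)
    sum(D[idx, idx][upper.tri(D[idx, idx])]) / length(idx)
  }
  ssd_total <- sum(D[upper.tri(D)]) / N
  ssd_within <- sum(vapply(grp, ssd_of, 0))
  ssd_among <- ssd_total - ssd_within
  df_among <- P - 1L
  df_within <- N - P
  ms_among <- ssd_among / df_among
  ms_within <- if (df_within > 0) ssd_within / df_within else 0
  n_sizes <- lengths(grp)
  n_prime <- (N - sum(n_sizes^2) / N) / df_among
  sigma_within <- ms_within
  sigma_among <- (ms_among - ms_within) / n_prime
  denom <- sigma_among + sigma_within
  phi <- if (denom == 0) NA_real_ else sigma_among / denom
  list(sigma_among = sigma_among, sigma_within = sigma_within, phi_st = phi)
}

# hamming distance matrix over usable columns
.pairwise_diff_matrix <- function(m) {
  n <- nrow(m)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n))
    D[i, j] <- D[j, i] <- sum(m[i, ] != m[j, ])
  D
}

#' Two-level AMOVA (Phi_ST) on haplotype pairwise differences
#'
#' Excoffier-style variance decomposition with the number of pairwise
#' differences as the squared molecular distance; significance by label
#' permutation.
#'
#' @param aln pooled [locus_alignment()] (complete-deletion mask applied).
#' @param labels population labels aligned with rows (>= 2 populations,
#'   each with >= 2 sequences).
#' @param n_perm permutations for the p-value (0 = skip).
#' @param seed RNG seed.
#' @return list with `sigma_among`, `sigma_within`, `phi_st`, `p_perm`.
#' @export
amova_two_level <- function(aln, labels, n_perm = 999L, seed = 1L) {
  mask <- usable_sites(aln)
  m <- aln$mat[, mask, drop = FALSE]
  if (any(table(labels) < 2L)) stop("each population needs >= 2 sequences")
  D <- .pairwise_diff_matrix(m)
  obs <- .amova_from_D(D, labels)
  p <- NA_real_
  if (n_perm > 0L && !is.na(obs$phi_st)) {
    set.seed(seed)
    ge <- 0L
    for (b in seq_len(n_perm)) {
      ph <- .amova_from_D(D, sample(labels))$phi_st
      if (!is.na(ph) && ph >= obs$phi_st) ge <- ge + 1L
    }
    p <- (1 + ge) / (n_perm + 1)
  }
  c(obs, list(p_perm = p, n_perm = n_perm))
}

#' Per-locus FST report across a dataset
#'
#' Table of Hudson FST with permutation p and shared/private mutation
#' counts for each locus and region (whole/coding/noncoding), using the
#' sentinel conventions of a per-region report: `NA` fst for loci
#' monomorphic across both populations ("na"), rows skipped for
#' structurally absent regions ("/"). The footer row carries the mean FST
#' over defined entries and the column sums of the mutation counts.
#'
#' @param dataset a [bean_dataset()].
#' @param wild,dom population labels to contrast.
#' @param n_perm permutations per locus (0 = skip p-values).
#' @param seed RNG seed.
#' @return data.frame with columns `locus, region, fst, p_perm, SM, P_MW,
#'   P_MD`.
#' @export
fst_report <- function(dataset, wild = "MW", dom = "MD", n_perm = 1000L,
                       seed = 1L) {
  wacc <- pop_accessions(dataset, wild)
  dacc <- pop_accessions(dataset, dom)
  rows <- list()
  for (id in names(dataset$loci)) {
    ann <- dataset$annotations[[id]]
    regions <- if (is.null(ann)) "whole" else c("whole", "coding", "noncoding")
    for (rg in regions) {
      sl <- .dataset_slice(dataset, id, rg)
      if (is.null(sl)) next
      w <- aln_subset(sl, intersect(rownames(sl$mat), wacc))
      d <- aln_subset(sl, intersect(rownames(sl$mat), dacc))
      fst <- hudson_fst(w, d)
      pp <- NA_real_
      if (!is.na(fst) && n_perm > 0L) {
        pooled <- locus_alignment(id, rbind(w$mat, d$mat))
        lab <- rep(c(wild, dom), c(nrow(w$mat), nrow(d$mat)))
        pp <- fst_permutation_test(pooled, lab, n_perm, seed)$p_perm
      }
      part <- .partition_sites(w$mat, d$mat)
      rows[[length(rows) + 1L]] <- data.frame(
        locus = id, region = rg, fst = fst, p_perm = pp,
        SM = part$SM, P_MW = part$P_MW, P_MD = part$P_MD,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  footer <- do.call(rbind, lapply(split(tab, tab$region), function(d)
    data.frame(locus = "overall", region = d$region[1L],
               fst = mean(d$fst, na.rm = TRUE), p_perm = NA_real_,
               SM = sum(d$SM), P_MW = sum(d$P_MW), P_MD = sum(d$P_MD),
               stringsAsFactors = FALSE)))
  out <- rbind(tab, footer)
  rownames(out) <- NULL
  out
}
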