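# Shared/private polymorphism partitioning, synonymous/nonsynonymous
# classification, private-replacement reporting, and modified Nei-Gojobori
# dN/dS with Jukes-Cantor correction.

GENCODE <- Biostrings::GENETIC_CODE  # standard nuclear code, named by codon

.is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
  (a == "C" & b == "T") | (a == "T" & b == "C")
}

.translate_codon <- function(codon) unname(GENCODE[codon])

# codon column indices for exon position i (1-based), given frame offset;
# NULL when the position falls in a leading/trailing partial codon
.codon_span <- function(i, frame_offset, L) {
  phase <- (i - 1L - frame_offset) %% 3L
  s <- i - phase
  if (s < 1L || s + 2L > L) return(NULL)
  seq.int(s, s + 2L)
}

#' Classify one exon site as synonymous or nonsynonymous
#'
#' Uses the observed whole-haplotype codons: the site is `synonymous` if
#' every pair of observed codons differing at that site encodes the same
#' amino acid, `nonsynonymous` if every such pair changes the amino acid,
#' and `mixed` if both occur (tri-allelic sites). `invariant` is returned
#' for sites with a single codon state at that position, and `excluded` when
#' the codon is incomplete or overlaps an unusable column.
#'
#' @param aln exon-slice [locus_alignment()] (columns are exon positions).
#' @param site 1-based exon position.
#' @param frame_offset phase of exon position 1 (0-2).
#' @param mask optional usable-site mask for the exon slice.
#' @return single string.
#' @export
classify_site_syn_nonsyn <- function(aln, site, frame_offset = 0L, mask = NULL) {
  m <- aln$mat
  if (is.null(mask)) mask <- usable_sites(aln)
  span <- .codon_span(site, frame_offset, ncol(m))
  if (is.null(span) || !all(mask[span])) return("excluded")
  codons <- unique(apply(m[, span, drop = FALSE], 1L, paste0, collapse = ""))
  off <- site - span[1L] + 1L
  base_at <- substr(codons, off, off)
  if (length(unique(base_at)) < 2L) return("invariant")
  syn <- FALSE; nonsyn <- FALSE
  for (i in seq_along(codons)[-length(codons)])
    for (j in seq.int(i + 1L, length(codons))) {
      if (substr(codons[i], off, off) == substr(codons[j], off, off)) next
      if (.translate_codon(codons[i]) == .translate_codon(codons[j]))
        syn <- TRUE else nonsyn <- TRUE
    }
  if (syn && nonsyn) "mixed" else if (syn) "synonymous" else "nonsynonymous"
}

#' Count synonymous and nonsynonymous changes in an exon slice
#'
#' Each variable usable site inside a complete codon contributes its
#' mutation count (observed alleles minus one) to the synonymous or
#' nonsynonymous tally; `mixed` sites count as nonsynonymous (any
#' amino-acid change at the site).
#'
#' @inheritParams classify_site_syn_nonsyn
#' @return list with `syn`, `nonsyn`, `n_excluded_sites`.
#' @export
count_syn_nonsyn <- function(aln, frame_offset = 0L, mask = NULL) {
  if (is.na(frame_offset)) frame_offset <- 0L
  m <- aln$mat
  if (is.null(mask)) mask <- usable_sites(aln)
  cnt <- .allele_counts(m[, mask, drop = FALSE])
  usable_idx <- which(mask)
  k <- colSums(cnt > 0L)
  syn <- 0L; nonsyn <- 0L; excl <- 0L
  for (jj in which(k >= 2L)) {
    site <- usable_idx[jj]
    cls <- classify_site_syn_nonsyn(aln, site, frame_offset, mask)
    if (cls == "excluded") { excl <- excl + 1L; next }
    if (cls == "synonymous") syn <- syn + (k[jj] - 1L)
    else if (cls %in% c("nonsynonymous", "mixed")) nonsyn <- nonsyn + (k[jj] - 1L)
  }
  list(syn = syn, nonsyn = nonsyn, n_excluded_sites = excl)
}

# per-site mutation partition between two row subsets of one sliced
# alignment; returns per-allele categories
.partition_sites <- function(m_wild, m_dom) {
  stopifnot(ncol(m_wild) == ncol(m_dom))
  pooled <- rbind(m_wild, m_dom)
  mask <- colSums(pooled == "-" | pooled == "N") == 0L
  SM <- 0L; PMW <- 0L; PMD <- 0L
  detail <- list()
  for (s in which(mask)) {
    cw <- table(factor(m_wild[, s], levels = c("A", "C", "G", "T")))
    cd <- table(factor(m_dom[, s], levels = c("A", "C", "G", "T")))
    ct <- cw + cd
    seg_w <- sum(cw > 0L) >= 2L
    seg_d <- sum(cd > 0L) >= 2L
    if (!seg_w && !seg_d) next  # monomorphic in both (or pure fixed difference)
    alleles <- names(ct)[ct > 0L]
    major <- alleles[which.max(ct[alleles])]
    for (x in setdiff(alleles, major)) {
      sx_w <- cw[x] > 0L && seg_w
      sx_d <- cd[x] > 0L && seg_d
      cat_x <- if (sx_w && sx_d) "SM"
               else if (sx_w) "P_MW"
               else if (sx_d) "P_MD"
               else if (cw[x] > 0L) "P_MW" else "P_MD"
      if (cat_x == "SM") SM <- SM + 1L
      else if (cat_x == "P_MW") PMW <- PMW + 1L
      else PMD <- PMD + 1L
      detail[[length(detail) + 1L]] <- data.frame(site = s, allele = x,
                                                  category = cat_x,
                                                  stringsAsFactors = FALSE)
    }
  }
  list(SM = SM, P_MW = PMW, P_MD = PMD, L = sum(mask),
       detail = if (length(detail)) do.call(rbind, detail) else
         data.frame(site = integer(), allele = character(),
                    category = character()))
}

#' Partition polymorphisms into shared and private mutations
#'
#' For each region class, every mutation (allele beyond the most frequent
#' at a site, counted on the pooled complete-deletion mask) is classified as
#' shared (`SM`, segregating in both populations), private to the wild
#' population (`P_MW`) or private to the domesticated population (`P_MD`).
#' Sites monomorphic within both populations are skipped. In the coding
#' region, mutations are further split into synonymous and nonsynonymous
#' (site-level classification; `mixed` counts as nonsynonymous).
#'
#' @param aln_wild,aln_dom [locus_alignment()]s over the same column space
#'   (same locus, two accession subsets).
#' @param ann optional [region_annotation()]; without it only the
#'   whole-sequence row is produced.
#' @return data.frame with columns `region, L, SM, P_MW, P_MD, syn_SM,
#'   syn_P_MW, syn_P_MD, nonsyn_SM, nonsyn_P_MW, nonsyn_P_MD` (syn columns
#'   are NA outside coding); regions absent from the annotation are skipped.
#' @export
partition_polymorphisms <- function(aln_wild, aln_dom, ann = NULL) {
  if (ncol(aln_wild$mat) != ncol(aln_dom$mat))
    stop("alignments must share one column space")
  regions <- if (is.null(ann)) "whole" else c("whole", "coding", "noncoding")
  rows <- list()
  for (rg in regions) {
    if (rg == "whole") {
      sw <- aln_wild; sd_ <- aln_dom; fr <- NA_integer_
    } else {
      classes <- .region_classes(rg)
      sw <- slice_region(aln_wild, ann, classes)
      sd_ <- slice_region(aln_dom, ann, classes)
      if (is.null(sw)) next
      fr <- attr(sw, "frame_offset")
    }
    pp <- .partition_sites(sw$mat, sd_$mat)
    syn <- rep(NA_integer_, 3L); nonsyn <- rep(NA_integer_, 3L)
    if (rg == "coding" && !is.na(fr)) {
      syn[] <- 0L; nonsyn[] <- 0L
      pooled <- locus_alignment(sw$locus_id, rbind(sw$mat, sd_$mat))
      pmask <- usable_sites(pooled)
      if (nrow(pp$detail)) for (r in seq_len(nrow(pp$detail))) {
        cls <- classify_site_syn_nonsyn(pooled, pp$detail$site[r], fr, pmask)
        idx <- match(pp$detail$category[r], c("SM", "P_MW", "P_MD"))
        if (cls == "synonymous") syn[idx] <- syn[idx] + 1L
        else if (cls %in% c("nonsynonymous", "mixed"))
          nonsyn[idx] <- nonsyn[idx] + 1L
      }
    }
    rows[[rg]] <- data.frame(
      region = rg, L = pp$L, SM = pp$SM, P_MW = pp$P_MW, P_MD = pp$P_MD,
      syn_SM = syn[1L], syn_P_MW = syn[2L], syn_P_MD = syn[3L],
      nonsyn_SM = nonsyn[1L], nonsyn_P_MW = nonsyn[2L], nonsyn_P_MD = nonsyn[3L],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Report nonsynonymous variants private to one population
#'
#' Scans the coding regions of every annotated locus for amino-acid variants
#' carried only by accessions of the focal population, and records carrier
#' counts in all populations (including outgroups). A record is flagged
#' `derived` when every other population, outgroups included, carries only
#' the non-focal amino-acid state.
#'
#' @param dataset a [bean_dataset()].
#' @param focal population carrying the candidate variants (default `"MD"`).
#' @return data.frame, one row per private replacement variant: locus, codon
#'   number, variant codon/amino acid, background codon/amino acid, carrier
#'   accessions, per-population variant carrier counts, `derived` flag.
#' @export
private_replacement_report <- function(dataset, focal = "MD") {
  pops <- intersect(POP_LABELS, unique(dataset$manifest))
  rows <- list()
  for (id in names(dataset$annotations)) {
    sl <- .dataset_slice(dataset, id, "coding")
    if (is.null(sl)) next
    fr <- attr(sl, "frame_offset"); if (is.na(fr)) fr <- 0L
    mask <- usable_sites(sl)
    L <- ncol(sl$mat)
    starts <- seq.int(fr + 1L, L - 2L, by = 3L)
    for (s in starts) {
      span <- s:(s + 2L)
      if (!all(mask[span])) next
      codons <- apply(sl$mat[, span, drop = FALSE], 1L, paste0, collapse = "")
      aas <- setNames(.translate_codon(codons), names(codons))
      if (length(unique(aas)) < 2L) next
      pop_of <- dataset$manifest[names(codons)]
      outgroups <- c("OUT_PD", "OUT_PC")
      ingroup <- setdiff(pops, outgroups)
      for (aa in unique(aas)) {
        carriers <- names(codons)[aas == aa]
        # private to the focal population among the ingroup; outgroup
        # carriers are allowed (they void the derived flag below)
        if (!any(pop_of[carriers] == focal)) next
        if (!all(pop_of[carriers] %in% c(focal, outgroups))) next
        others <- names(codons)[aas != aa]
        other_aas <- unique(aas[others])
        counts <- vapply(pops, function(p) sum(pop_of[carriers] == p), 0L)
        rows[[length(rows) + 1L]] <- data.frame(
          locus = id, codon_number = (s - fr - 1L) %/% 3L + 1L,
          variant_codon = paste(unique(codons[carriers]), collapse = "/"),
          variant_aa = aa,
          background_codon = paste(unique(codons[others]), collapse = "/"),
          background_aa = paste(other_aas, collapse = "/"),
          carriers = paste(carriers, collapse = ","),
          t(counts),
          derived = length(other_aas) == 1L &&
            all(pop_of[carriers] == focal) &&
            all(setdiff(pops, focal) %in% unique(pop_of[others])),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(locus = character(), codon_number = integer(),
                      variant_codon = character(), variant_aa = character(),
                      background_codon = character(),
                      background_aa = character(), carriers = character(),
                      derived = logical()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- modified Nei-Gojobori ------------------------------------------------

# R-weighted synonymous site fraction per position of one codon
.ng_sites_codon <- function(codon, R) {
  bases <- c("A", "C", "G", "T")
  aa0 <- .translate_codon(codon)
  s <- numeric(3L)
  for (p in 1:3) {
    b0 <- substr(codon, p, p)
    wsum <- 0; wsyn <- 0
    for (b in setdiff(bases, b0)) {
      alt <- codon
      substr(alt, p, p) <- b
      if (.translate_codon(alt) == "*") next  # mutations to stops excluded
      w <- if (.is_transition(b0, b)) R else 1
      wsum <- wsum + w
      if (.translate_codon(alt) == aa0) wsyn <- wsyn + w
    }
    s[p] <- if (wsum > 0) wsyn / wsum else 0
  }
  sum(s)  # synonymous sites in this codon; nonsynonymous = 3 - this
}

# pathway-averaged (sd, nd) for one codon pair; intermediate stop codons
# invalidate a pathway (fallback: all pathways if none survives)
.ng_diff_pair <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  d <- length(pos)
  if (d == 0L) return(c(sd = 0, nd = 0))
  perms <- switch(d, list(1L), list(c(1L, 2L), c(2L, 1L)),
                  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  path_counts <- function(order_idx, allow_stops) {
    cur <- c1; sd_ <- 0; nd_ <- 0
    for (k in order_idx) {
      p <- pos[k]
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (!allow_stops && .translate_codon(nxt) == "*" && nxt != c2) return(NULL)
      if (.translate_codon(cur) == .translate_codon(nxt)) sd_ <- sd_ + 1
      else nd_ <- nd_ + 1
      cur <- nxt
    }
    c(sd = sd_, nd = nd_)
  }
  res <- Filter(Negate(is.null), lapply(perms, path_counts, allow_stops = FALSE))
  if (!length(res)) res <- lapply(perms, path_counts, allow_stops = TRUE)
  cm <- do.call(rbind, res)
  c(sd = mean(cm[, "sd"]), nd = mean(cm[, "nd"]))
}

#' Modified Nei-Gojobori dN/dS with Jukes-Cantor correction
#'
#' Pathway-counted synonymous/nonsynonymous differences and
#' transition/transversion-weighted site counts (weight `R` on transitions;
#' `R = 1` reduces to the original proportional method), averaged over all
#' sequence pairs; proportions are corrected with
#' `d = -(3/4) log(1 - 4p/3)`. Standard errors come from a seeded bootstrap
#' over codons.
#'
#' @param aln [locus_alignment()] of an exon slice, or a character matrix of
#'   aligned sequences; columns are trimmed to complete codons after
#'   removing codons that overlap unusable columns.
#' @param frame_offset phase of column 1 (0-2).
#' @param R transition/transversion ratio for site counting (default 1).
#' @param n_boot bootstrap replicates over codons for the SEs (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return list with `dN`, `dS`, `se_dN`, `se_dS`, `pN`, `pS`, `n_codons`,
#'   `R`, and `jc_undefined` (TRUE when a p-distance reaches 3/4 so the
#'   correction has no value; the corresponding d is NA, never clipped).
#' @export
nei_gojobori_dn_ds <- function(aln, frame_offset = 0L, R = 1, n_boot = 1000L,
                               seed = 1L) {
  m <- if (inherits(aln, "locus_alignment")) aln$mat else aln
  if (nrow(m) < 2L) stop("need >= 2 sequences")
  mask <- colSums(m == "-" | m == "N") == 0L
  L <- ncol(m)
  starts <- seq.int(frame_offset + 1L, L - 2L, by = 3L)
  starts <- starts[vapply(starts, function(s) all(mask[s:(s + 2L)]), TRUE)]
  if (!length(starts)) stop("no complete usable codon")
  codon_mat <- vapply(starts, function(s)
    apply(m[, s:(s + 2L), drop = FALSE], 1L, paste0, collapse = ""),
    character(nrow(m)))
  if (is.null(dim(codon_mat))) codon_mat <- matrix(codon_mat, nrow = nrow(m))
  if (any(.translate_codon(as.vector(codon_mat)) == "*"))
    stop("internal stop codon in coding sequence")
  n <- nrow(m); nc <- length(starts)
  site_s <- apply(codon_mat, c(1L, 2L), .ng_sites_codon, R = R)
  pair_idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  np <- nrow(pair_idx)
  # per pair x codon contributions
  Sd <- matrix(0, np, nc); Nd <- matrix(0, np, nc)
  Ss <- matrix(0, np, nc); Ns <- matrix(0, np, nc)
  for (p in seq_len(np)) {
    i <- pair_idx[p, 2L]; j <- pair_idx[p, 1L]  # upper.tri: row < col
    for (cdx in seq_len(nc)) {
      dd <- .ng_diff_pair(codon_mat[i, cdx], codon_mat[j, cdx])
      Sd[p, cdx] <- dd["sd"]; Nd[p, cdx] <- dd["nd"]
      s_ <- (site_s[i, cdx] + site_s[j, cdx]) / 2
      Ss[p, cdx] <- s_; Ns[p, cdx] <- 3 - s_
    }
  }
  jc <- function(p) ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
  est <- function(cols) {
    pS <- mean(rowSums(Sd[, cols, drop = FALSE])) /
          mean(rowSums(Ss[, cols, drop = FALSE]))
    pN <- mean(rowSums(Nd[, cols, drop = FALSE])) /
          mean(rowSums(Ns[, cols, drop = FALSE]))
    c(dS = jc(pS), dN = jc(pN), pS = pS, pN = pN)
  }
  e0 <- est(seq_len(nc))
  boot <- matrix(NA_real_, n_boot, 2L)
  if (n_boot > 0L) {
    set.seed(seed)
    for (b in seq_len(n_boot)) {
      eb <- est(sample.int(nc, nc, replace = TRUE))
      boot[b, ] <- eb[c("dN", "dS")]
    }
  }
  list(dN = unname(e0["dN"]), dS = unname(e0["dS"]),
       se_dN = if (n_boot > 0) sd(boot[, 1L], na.rm = TRUE) else NA_real_,
       se_dS = if (n_boot > 0) sd(boot[, 2L], na.rm = TRUE) else NA_real_,
       pN = unname(e0["pN"]), pS = unname(e0["pS"]),
       n_codons = nc, R = R,
       jc_undefined = any(is.na(e0[c("dN", "dS")]) & e0[c("pN", "pS")] >= 0.75))
}

# ---- nonparametric tests --------------------------------------------------

#' Paired Wilcoxon signed-rank test on per-locus estimates
#'
#' Zero differences are discarded (Wilcoxon's original convention). The
#' exact null distribution is used for up to 25 informative pairs: via the
#' standard signed-rank distribution when the magnitudes are untied, and by
#' full enumeration of sign assignments (average ranks) when ties are
#' present and at most 14 pairs remain; the normal approximation with
#' continuity correction is used otherwise.
#'
#' @param x,y paired per-locus vectors (e.g. dN per locus in two
#'   populations).
#' @param alternative `"two.sided"`, `"greater"` (x > y) or `"less"`.
#' @return list with `statistic` (V), `p_value`, `n_pairs` (informative);
#'   statistic and p are NA when no informative pair exists.
#' @export
paired_wilcoxon_dnds <- function(x, y, alternative = "two.sided") {
  stopifnot(length(x) == length(y))
  alternative <- match.arg(alternative, c("two.sided", "greater", "less"))
  d <- x - y
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (!n) return(list(statistic = NA_real_, p_value = NA_real_, n_pairs = 0L))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  tied <- anyDuplicated(abs(d)) > 0L
  if (n <= 25L && !tied) {
    wt <- wilcox.test(d, alternative = alternative, exact = TRUE)
    return(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                n_pairs = n))
  }
  if (n <= 14L) {
    # enumerate all 2^n sign assignments with average ranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vs <- as.vector(signs %*% r)
    ge <- mean(vs >= v); le <- mean(vs <= v)
    p <- switch(alternative, greater = ge, less = le,
                two.sided = min(1, 2 * min(ge, le)))
    return(list(statistic = v, p_value = p, n_pairs = n))
  }
  wt <- suppressWarnings(wilcox.test(d, alternative = alternative,
                                     exact = FALSE, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value, n_pairs = n)
}

#' Two-sample rank-sum test on per-locus diversity estimates
#'
#' Wilcoxon rank-sum (equivalent to a two-group Kruskal-Wallis). The exact
#' tail is computed for small samples — by the standard distribution when
#' untied, by full enumeration of group assignments (average ranks) when
#' ties are present and `choose(n+m, n) <= 50000` — and by the
#' tie-corrected normal approximation otherwise.
#'
#' @param x,y independent per-locus vectors.
#' @param alternative `"two.sided"`, `"greater"` (x tends larger) or
#'   `"less"`.
#' @return list with `statistic` (W) and `p_value`.
#' @export
ranksum_diversity_test <- function(x, y, alternative = "two.sided") {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  alternative <- match.arg(alternative, c("two.sided", "greater", "less"))
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  tied <- anyDuplicated(c(x, y)) > 0L
  if (!tied && n <= 25L && m <= 25L) {
    wt <- wilcox.test(x, y, alternative = alternative, exact = TRUE)
    return(list(statistic = unname(wt$statistic), p_value = wt$p.value))
  }
  if (tied && choose(n + m, n) <= 50000) {
    combs <- utils::combn(n + m, n)
    ws <- apply(combs, 2L, function(idx) sum(r[idx])) - n * (n + 1) / 2
    ge <- mean(ws >= w); le <- mean(ws <= w)
    p <- switch(alternative, greater = ge, less = le,
                two.sided = min(1, 2 * min(ge, le)))
    return(list(statistic = w, p_value = p))
  }
  wt <- suppressWarnings(wilcox.test(x, y, alternative = alternative,
                                     exact = FALSE, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Binomial test for excess private coding mutations
#'
#' One-sided `P(X >= observed)` with `X ~ Binomial(n, p0)`, where `n` is the
#' total number of private mutations in the focal population (coding +
#' noncoding) and the null proportion `p0` comes from the other population's
#' private mutations: the raw coding fraction (`raw_count`, the literal
#' null), or per-bp private rates weighted by the focal population's
#' analyzed region lengths (`length_standardized`).
#'
#' @param md_coding,md_noncoding private mutation counts in the focal
#'   population.
#' @param mw_coding,mw_noncoding private mutation counts in the reference
#'   population.
#' @param null_mode `"raw_count"` or `"length_standardized"`.
#' @param mw_lengths,md_lengths numeric length-2 vectors
#'   `c(coding, noncoding)` in bp; required for the standardized mode.
#' @return one-sided p-value.
#' @export
binomial_private_coding_test <- function(md_coding, md_noncoding,
                                         mw_coding, mw_noncoding,
                                         null_mode = c("raw_count",
                                                       "length_standardized"),
                                         mw_lengths = NULL, md_lengths = NULL) {
  null_mode <- match.arg(null_mode)
  n <- md_coding + md_noncoding
  if (n < 1L) stop("no private mutations in the focal population")
  if (null_mode == "raw_count") {
    tot <- mw_coding + mw_noncoding
    if (tot == 0) stop("null proportion undefined: no private reference mutations")
    p0 <- mw_coding / tot
  } else {
    if (is.null(mw_lengths) || is.null(md_lengths))
      stop("length_standardized mode needs mw_lengths and md_lengths")
    r <- c(mw_coding, mw_noncoding) / mw_lengths
    w <- r * md_lengths
    if (sum(w) == 0) stop("null proportion undefined")
    p0 <- w[1L] / sum(w)
  }
  pbinom(md_coding - 1L, n, p0, lower.tail = FALSE)
}
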