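# FDIST-style FST-outlier detection for biallelic SNP panels: island-model
# coalescent cloud of (He, FST) pairs, per-heterozygosity quantile
# envelope, and classification of markers as neutral, directional
# (FST above the envelope) or balancing (below).

# island-model migration rate giving expected FST (haploid pairwise-time
# derivation: FST = 1 / (1 + 2 m N d/(d-1)) with N = 1 coalescent units)
.island_migration_rate <- function(target_fst, n_demes, N = 1) {
  if (target_fst <= 0 || target_fst >= 1)
    stop("target mean FST must be in (0, 1)")
  (n_demes - 1) * (1 - target_fst) / (2 * N * n_demes * target_fst)
}

# refine the island migration rate by pilot simulation so the realized
# mean per-locus FST hits the target (uses the current RNG stream)
.calibrate_island_m <- function(target_fst, sample_sizes, n_demes,
                                k_pilot = 5000L) {
  m <- .island_migration_rate(target_fst, n_demes)
  for (it in 1:6) {
    cts <- .sim_island_snps_cpp(k_pilot, sample_sizes[1L], sample_sizes[2L],
                                n_demes, m, 1)
    fhat <- mean(.wc_fst(cts[, 1L], cts[, 2L], sample_sizes[1L],
                         sample_sizes[2L]), na.rm = TRUE)
    if (abs(fhat - target_fst) <= 0.01) break
    # F = 1/(1 + c m)  =>  c = (1/F - 1)/m, re-solve for the target
    cc <- (1 / max(fhat, 1e-6) - 1) / m
    m <- (1 / target_fst - 1) / cc
  }
  m
}

# Weir-Cockerham-style FST for haploid two-population counts
.wc_fst <- function(c1, c2, n1, n2) {
  p1 <- c1 / n1; p2 <- c2 / n2
  nbar_tot <- n1 + n2
  pbar <- (c1 + c2) / nbar_tot
  msa <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / 1
  msw <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (nbar_tot - 2)
  n_c <- (nbar_tot - (n1^2 + n2^2) / nbar_tot) / 1
  denom <- msa + (n_c - 1) * msw
  ifelse(denom == 0, NA_real_, (msa - msw) / denom)
}

# unbiased pooled expected heterozygosity
.pooled_he <- function(c1, c2, n1, n2) {
  n <- n1 + n2
  p <- (c1 + c2) / n
  n / (n - 1) * (1 - p^2 - (1 - p)^2)
}

#' Filter a SNP genotype matrix
#'
#' Removes markers with more than `max_missing` missing calls or a minor
#' allele frequency at or below `min_maf` (computed over non-missing
#' calls). Filtering is idempotent.
#'
#' @param geno markers x individuals matrix of 0/1/NA haploid calls.
#' @param max_missing maximum missing fraction (default 0.05).
#' @param min_maf MAF threshold; markers with MAF `<=` this are dropped
#'   (default 0.01).
#' @return filtered matrix with attribute `exclusions` (data.frame of
#'   removed markers and reasons).
#' @export
filter_snps <- function(geno, max_missing = 0.05, min_maf = 0.01) {
  stopifnot(is.matrix(geno))
  miss <- rowMeans(is.na(geno))
  p <- rowMeans(geno, na.rm = TRUE)
  maf <- pmin(p, 1 - p)
  drop_miss <- miss > max_missing
  drop_maf <- !drop_miss & maf <= min_maf
  keep <- !(drop_miss | drop_maf)
  if (!any(keep)) stop("all markers removed by the filters")
  out <- geno[keep, , drop = FALSE]
  ids <- rownames(geno) %||% as.character(seq_len(nrow(geno)))
  attr(out, "exclusions") <- data.frame(
    marker = ids[!keep],
    reason = ifelse(drop_miss[!keep], "missing", "maf"),
    stringsAsFactors = FALSE)
  out
}

#' Per-marker He and FST for a two-population panel
#'
#' @param geno markers x individuals 0/1/NA matrix.
#' @param pops individual population labels (two levels), aligned with
#'   columns.
#' @return data.frame `marker, He, fst`.
#' @export
snp_he_fst <- function(geno, pops) {
  pops <- as.character(pops)
  lv <- unique(pops)
  if (length(lv) != 2L) stop("exactly two populations required")
  i1 <- pops == lv[1L]; i2 <- pops == lv[2L]
  n1 <- rowSums(!is.na(geno[, i1, drop = FALSE]))
  n2 <- rowSums(!is.na(geno[, i2, drop = FALSE]))
  c1 <- rowSums(geno[, i1, drop = FALSE], na.rm = TRUE)
  c2 <- rowSums(geno[, i2, drop = FALSE], na.rm = TRUE)
  data.frame(marker = rownames(geno) %||% as.character(seq_len(nrow(geno))),
             He = .pooled_he(c1, c2, n1, n2),
             fst = .wc_fst(c1, c2, n1, n2),
             stringsAsFactors = FALSE)
}

#' Simulate an FDIST null cloud of (He, FST) pairs
#'
#' Symmetric island-model coalescent (default 100 demes, two sampled), one
#' biallelic mutation per locus placed uniformly on the genealogy (the
#' biallelic approximation of an infinite-alleles run); the migration rate
#' is solved from the island-model expectation so the cloud is centered on
#' the target mean FST.
#'
#' @param n_sims simulated loci (default 50000).
#' @param sample_sizes haploid sample sizes of the two sampled demes.
#' @param target_fst desired mean FST in (0,1).
#' @param n_demes island count (default 100).
#' @param seed RNG seed.
#' @param calibrate solve the migration rate so the realized cloud mean FST
#'   matches the target (default TRUE): the closed-form island expectation
#'   is only a starting value, since SNP ascertainment (one segregating
#'   mutation per locus) and the finite-sample estimator shift the realized
#'   mean; pilot clouds refine `m` by secant steps until the pilot mean is
#'   within 0.01 of the target.
#' @return data.frame `He, fst` with attributes `target_fst`, `m`,
#'   `n_demes`, `sample_sizes`.
#' @export
simulate_fdist_cloud <- function(n_sims = 50000L, sample_sizes = c(30L, 30L),
                                 target_fst = 0.2, n_demes = 100L, seed = 1L,
                                 calibrate = TRUE) {
  if (n_sims < 1L) stop("n_sims must be >= 1")
  m <- .island_migration_rate(target_fst, n_demes)
  set.seed(seed)
  cloud_of <- function(m, k) {
    cts <- .sim_island_snps_cpp(k, sample_sizes[1L], sample_sizes[2L],
                                n_demes, m, 1)
    data.frame(
      He = .pooled_he(cts[, 1L], cts[, 2L], sample_sizes[1L], sample_sizes[2L]),
      fst = .wc_fst(cts[, 1L], cts[, 2L], sample_sizes[1L], sample_sizes[2L]))
  }
  if (calibrate)
    m <- .calibrate_island_m(target_fst, sample_sizes, n_demes,
                             k_pilot = min(5000L, n_sims))
  out <- cloud_of(m, n_sims)
  attr(out, "target_fst") <- target_fst
  attr(out, "m") <- m
  attr(out, "n_demes") <- n_demes
  attr(out, "sample_sizes") <- sample_sizes
  out
}

# quantile envelope over equal-count He bins (piecewise-constant per bin;
# at ci = 1 it degenerates exactly to the per-bin cloud min/max)
.fst_envelope <- function(cloud, ci = 0.99, n_bins = 20L) {
  ok <- !is.na(cloud$fst)
  he <- cloud$He[ok]; fst <- cloud$fst[ok]
  qs <- unique(quantile(he, probs = seq(0, 1, length.out = n_bins + 1L)))
  idx <- findInterval(he, qs, rightmost.closed = TRUE)  # same rule as classify
  lo_p <- (1 - ci) / 2; hi_p <- 1 - lo_p
  bin <- factor(idx, levels = seq_len(length(qs) - 1L))
  lo <- as.numeric(tapply(fst, bin, quantile, probs = lo_p, names = FALSE))
  hi <- as.numeric(tapply(fst, bin, quantile, probs = hi_p, names = FALSE))
  lo[is.na(lo)] <- -Inf; hi[is.na(hi)] <- Inf  # empty bins classify nothing
  list(breaks = as.numeric(qs), lo = lo, hi = hi,
       he_range = range(he), ci = ci)
}

.classify_with_envelope <- function(obs, env) {
  nb <- length(env$breaks) - 1L
  idx <- findInterval(obs$He, env$breaks, rightmost.closed = TRUE)
  outside <- idx < 1L | idx > nb | is.na(obs$He)
  idx[outside] <- 1L
  lower <- env$lo[idx]; upper <- env$hi[idx]
  cls <- rep("neutral", nrow(obs))
  cls[which(obs$fst > upper)] <- "directional"
  cls[which(obs$fst < lower)] <- "balancing"
  cls[outside | is.na(obs$fst)] <- "unclassified"
  lower[outside] <- NA_real_; upper[outside] <- NA_real_
  list(class = cls, lower = lower, upper = upper)
}

#' Classify markers against an FDIST envelope
#'
#' Empirical per-He-bin quantiles of the simulated cloud are interpolated
#' into lower/upper envelope curves at confidence `ci`; markers above the
#' upper curve are called `directional`, below the lower curve
#' `balancing`. With `forced_mean = TRUE` the procedure iterates: current
#' outliers are dropped, the mean FST of the remainder re-estimated, the
#' cloud re-simulated at that target and markers reclassified (at most
#' `max_iter` rounds or until the outlier set stabilizes).
#'
#' @param obs data.frame from [snp_he_fst()] (filtered markers).
#' @param cloud simulated cloud from [simulate_fdist_cloud()]; with
#'   `forced_mean` it is re-simulated internally with the cloud's own
#'   settings.
#' @param ci confidence level of the envelope (default 0.99).
#' @param forced_mean iterate with outliers removed (default FALSE).
#' @param n_bins He bins for the envelope (default 20).
#' @param max_iter forced-mean iteration cap (default 5).
#' @param seed seed for forced-mean re-simulation.
#' @return `obs` with columns `class`, `lower`, `upper`; attributes
#'   `ci`, `target_fst`, `n_iter`. Markers with He outside the cloud
#'   support are `unclassified` (with a warning).
#' @export
envelope_and_classify <- function(obs, cloud, ci = 0.99, forced_mean = FALSE,
                                  n_bins = 20L, max_iter = 5L, seed = 1L) {
  env <- .fst_envelope(cloud, ci, n_bins)
  res <- .classify_with_envelope(obs, env)
  n_iter <- 0L
  if (forced_mean) {
    n_sims <- nrow(cloud)
    ss <- attr(cloud, "sample_sizes") %||% c(30L, 30L)
    nd <- attr(cloud, "n_demes") %||% 100L
    prev <- res$class
    for (it in seq_len(max_iter)) {
      keep <- prev == "neutral"
      if (!any(keep)) break
      target <- mean(obs$fst[keep], na.rm = TRUE)
      if (target <= 0 || target >= 1) break
      cloud <- simulate_fdist_cloud(n_sims, ss, target, nd, seed + it)
      env <- .fst_envelope(cloud, ci, n_bins)
      res <- .classify_with_envelope(obs, env)
      n_iter <- it
      if (identical(res$class, prev)) break
      prev <- res$class
    }
  }
  if (any(res$class == "unclassified"))
    warning(sum(res$class == "unclassified"),
            " marker(s) outside the cloud support left unclassified")
  out <- obs
  out$class <- res$class
  out$lower <- res$lower
  out$upper <- res$upper
  attr(out, "ci") <- ci
  attr(out, "target_fst") <- attr(cloud, "target_fst")
  attr(out, "n_iter") <- n_iter
  out
}

#' Read / write SNP genotype TSVs
#'
#' Markers x individuals table of 0/1/NA haploid calls, first column the
#' marker id, header row the individual ids.
#'
#' @param path TSV file.
#' @export
read_snp_matrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   row.names = 1L, check.names = FALSE)
  as.matrix(df)
}

#' @rdname read_snp_matrix
#' @param geno genotype matrix.
#' @export
write_snp_matrix <- function(geno, path) {
  write.table(cbind(marker = rownames(geno), as.data.frame(geno)), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
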