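# Composite selection-index scan against a coalescent null.
#
# Per polymorphic fragment (exonic or intronic portion of a gene) three
# statistics are computed between the wild and domesticated samples: a
# molecular FST (two-population AMOVA Phi), the branch-length statistic
# -log(1 - FST), and the standardized diversity difference
# (pi_w - pi_d)/(pi_w + pi_d). Each is z-scored with constants estimated
# from the observed fragment panel (per fragment class) and the three
# z-scores are summed into the selection index. The same constants are
# applied to coalescent simulations under the demographic null, so observed
# and simulated indices share one scale; the empirical p is the fraction of
# simulated indices exceeding the observed one, corrected by
# Benjamini-Hochberg across fragments.

# ---- coalescent simulation wrappers ---------------------------------------

#' Simulate one neutral fragment under a demographic model
#'
#' Runs the structured coalescent and returns the binary (0/1) haplotype
#' matrix of the sampled wild and domesticated sequences under the
#' infinite-sites model.
#'
#' @param model a [demographic_model()].
#' @param n_wild,n_dom haploid sample sizes (defaults 19 and 20).
#' @param length fragment length in bp.
#' @param mu mutation rate per site per generation.
#' @param populations demes to sample from, in row-block order.
#' @return integer matrix with `n_wild + n_dom` rows; 0 columns when the
#'   fragment is monomorphic.
#' @export
sim_fragment <- function(model, n_wild = 19L, n_dom = 20L, length = 500L,
                         mu = 1e-8, populations = c("MW", "MD")) {
  be <- build_epochs(model, populations)
  sample_demes <- rep(match(populations, be$demes) - 1L, c(n_wild, n_dom))
  .sim_binary_sites_cpp(as.integer(sample_demes), be$epochs,
                        length(be$demes), mu * length)
}

#' Simulate a genealogy under a demographic model
#'
#' Lower-level access to the coalescent engine; returns the edge list
#' (0-based node ids, samples first) with node times in generations.
#'
#' @inheritParams sim_fragment
#' @param sample_sizes named integer vector, e.g. `c(MW = 19, MD = 20)`.
#' @export
sim_genealogy <- function(model, sample_sizes = c(MW = 19L, MD = 20L)) {
  be <- build_epochs(model, names(sample_sizes))
  sample_demes <- rep(match(names(sample_sizes), be$demes) - 1L, sample_sizes)
  .sim_tree_cpp(as.integer(sample_demes), be$epochs, length(be$demes))
}

# ---- component statistics -------------------------------------------------

# pairwise-difference matrix from a binary matrix
.binary_diff_matrix <- function(X) {
  k <- rowSums(X)
  G <- tcrossprod(X)
  outer(k, k, "+") - 2 * G
}

# mean pairwise difference within a set of rows of a diff matrix
.mean_pairwise <- function(D, idx) {
  if (length(idx) < 2L) return(NA_real_)
  mean(D[idx, idx][upper.tri(D[idx, idx])])
}

# branch-length clamp: FST estimates at/near 1 (common on one- or two-SNP
# fragments) would otherwise send -log(1 - FST) to arbitrarily large values
# and let a single noisy estimate dominate the composite index
.BRANCH_EPS <- 0.01

# component statistics from a pairwise-difference matrix
.components_from_D <- function(D, n1) {
  n <- nrow(D)
  labels <- rep(c("w", "d"), c(n1, n - n1))
  phi <- .amova_from_D(D, labels)$phi_st
  if (is.na(phi)) phi <- 0
  fst_cl <- min(max(phi, 0), 1 - .BRANCH_EPS)
  pw <- .mean_pairwise(D, seq_len(n1))
  pd <- .mean_pairwise(D, seq.int(n1 + 1L, n))
  delta <- if ((pw + pd) > 0) (pw - pd) / (pw + pd) else 0
  c(fst_mol = phi, branch_len = -log(1 - fst_cl), delta_div = delta)
}

#' Component statistics of the selection index
#'
#' @param frag_wild,frag_dom fragment alignments for the two populations:
#'   [locus_alignment()]s sharing a column space, or 0/1 matrices from
#'   [sim_fragment()] split by rows.
#' @return named vector `(fst_mol, branch_len, delta_div)`, or `NULL` when
#'   the pooled fragment is monomorphic (excluded from the scan).
#' @export
component_stats <- function(frag_wild, frag_dom) {
  if (inherits(frag_wild, "locus_alignment")) {
    pooled <- rbind(frag_wild$mat, frag_dom$mat)
    mask <- colSums(pooled == "-" | pooled == "N") == 0L
    m <- pooled[, mask, drop = FALSE]
    if (!ncol(m) || all(apply(m, 2L, function(x) length(unique(x))) == 1L))
      return(NULL)
    D <- .pairwise_diff_matrix(m)
    n1 <- nrow(frag_wild$mat)
  } else {
    X <- rbind(frag_wild, frag_dom)
    if (!ncol(X)) return(NULL)
    D <- .binary_diff_matrix(X)
    n1 <- nrow(frag_wild)
  }
  if (all(D == 0)) return(NULL)
  .components_from_D(D, n1)
}

#' Selection index from normalized components
#'
#' Each component column is z-scored with the supplied constants and the
#' three z-scores are summed. A zero standard deviation silences that
#' component.
#'
#' @param components matrix/data.frame with columns `fst_mol, branch_len,
#'   delta_div`.
#' @param center,scale length-3 constants (means and sds per component); by
#'   default estimated from `components` itself.
#' @return numeric index per row, with the constants as attributes.
#' @export
selection_index <- function(components, center = NULL, scale = NULL) {
  X <- as.matrix(components[, c("fst_mol", "branch_len", "delta_div")])
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) scale <- apply(X, 2L, sd)
  Z <- sweep(X, 2L, center)
  Z <- sweep(Z, 2L, ifelse(scale > 0, scale, Inf), "/")
  idx <- rowSums(Z)
  attr(idx, "center") <- center
  attr(idx, "scale") <- scale
  idx
}

#' Empirical p-value against a simulated null
#'
#' The literal estimator `#(null > observed) / length(null)`; the add-one
#' variant `(1 + #)/(n + 1)` is available.
#'
#' @param observed observed index (vectorized).
#' @param null vector of simulated null indices.
#' @param add_one use the add-one estimator (default FALSE).
#' @export
empirical_p <- function(observed, null, add_one = FALSE) {
  if (!length(null)) stop("null vector is empty")
  cnt <- vapply(observed, function(o) sum(null > o), 0)
  if (add_one) (1 + cnt) / (length(null) + 1) else cnt / length(null)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} (m p_(j) / j)`, capped at 1; stable under ties.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  m <- sum(ok)
  if (m == 0L) return(out)
  pv <- p[ok]
  o <- order(pv)
  q_sorted <- rev(cummin(rev(pmin(1, m * pv[o] / seq_len(m)))))
  qq <- numeric(m)
  qq[o] <- q_sorted
  out[ok] <- qq
  out
}

#' Simulate the null distribution of the selection index
#'
#' Per replicate: demographic parameters are drawn from their priors, a
#' fragment length is drawn from the observed class-specific length
#' multiset, a mutation rate from the class prior, a neutral coalescent is
#' run under the wild/domesticated demography, and the component statistics
#' are computed on the simulated sample. Monomorphic replicates are
#' recorded and excluded, mirroring the rule that only polymorphic
#' fragments are analyzed.
#'
#' @param model a [demographic_model()] (base parameters).
#' @param priors prior set over demographic parameters; use
#'   [fixed_priors()] for a known-truth null.
#' @param n_sims number of replicates.
#' @param lengths observed fragment lengths for the class (sampled with
#'   replacement).
#' @param mu_prior mutation-rate spec for the class (see
#'   [mutation_rate_priors()]).
#' @param n_wild,n_dom sample sizes.
#' @param seed RNG seed.
#' @return list of class `null_distribution`: `components` (matrix over
#'   polymorphic replicates), `n_sims`, `n_polymorphic`, `n_rejected`,
#'   `seed`.
#' @export
simulate_null <- function(model, priors, n_sims, lengths,
                          mu_prior = list(dist = "fixed", value = 1e-8),
                          n_wild = 19L, n_dom = 20L, seed = 1L) {
  if (n_sims < 1L) stop("n_sims must be >= 1")
  if (!length(lengths)) stop("need observed fragment lengths")
  set.seed(seed)
  comp <- matrix(NA_real_, n_sims, 3L,
                 dimnames = list(NULL, c("fst_mol", "branch_len", "delta_div")))
  n_rej <- 0L
  for (b in seq_len(n_sims)) {
    dp <- sample_model_params(priors, base = model$params)
    n_rej <- n_rej + dp$n_rejected
    mod_b <- demographic_model(model$model_id, dp$params,
                               growth_steps = model$growth_steps)
    L <- sample(lengths, 1L)
    mu <- .draw_prior(mu_prior)
    X <- sim_fragment(mod_b, n_wild, n_dom, L, mu)
    cs <- component_stats(X[seq_len(n_wild), , drop = FALSE],
                          X[seq.int(n_wild + 1L, n_wild + n_dom), , drop = FALSE])
    if (!is.null(cs)) comp[b, ] <- cs
  }
  poly <- !is.na(comp[, 1L])
  structure(list(components = comp[poly, , drop = FALSE],
                 n_sims = n_sims, n_polymorphic = sum(poly),
                 n_rejected = n_rej, seed = seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %d sims, %d polymorphic (seed %d)\n",
              x$n_sims, x$n_polymorphic, x$seed))
  invisible(x)
}

# observed fragments of a dataset: one exonic + one intronic (all noncoding
# classes) fragment per annotated gene
.observed_fragments <- function(dataset, wild, dom) {
  wacc <- pop_accessions(dataset, wild)
  dacc <- pop_accessions(dataset, dom)
  frags <- list()
  for (id in names(dataset$annotations)) {
    for (cls in c("exonic", "intronic")) {
      rg <- if (cls == "exonic") "coding" else "noncoding"
      sl <- .dataset_slice(dataset, id, rg)
      if (is.null(sl)) next
      w <- aln_subset(sl, intersect(rownames(sl$mat), wacc))
      d <- aln_subset(sl, intersect(rownames(sl$mat), dacc))
      pooled <- rbind(w$mat, d$mat)
      mask <- colSums(pooled == "-" | pooled == "N") == 0L
      frags[[length(frags) + 1L]] <- list(
        gene = id, class = cls, length = sum(mask),
        components = component_stats(w, d))
    }
  }
  frags
}

#' Selection scan of a wild/domesticated dataset
#'
#' Splits each annotated gene into its exonic and intronic fragments,
#' excludes monomorphic fragments, computes the composite selection index
#' per fragment, tests it against `n_sims` coalescent replicates of the
#' demographic null per fragment class, and flags fragments with
#' Benjamini-Hochberg q below `fdr`. A gene is flagged when at least one of
#' its fragments is.
#'
#' @param dataset annotated [bean_dataset()].
#' @param model a [demographic_model()].
#' @param priors demographic prior set; default pins the model's own
#'   parameters ([fixed_priors()]).
#' @param n_sims null replicates per fragment class.
#' @param fdr FDR threshold (default 0.05).
#' @param seed RNG seed (governs the null simulations).
#' @param wild,dom population labels.
#' @param mu_priors per-class mutation-rate specs
#'   ([mutation_rate_priors()]).
#' @return list of class `scan_result`: `fragments` (data.frame: gene,
#'   class, length, components, index, p_raw, q_bh, flagged), `genes`
#'   (rollup), `null` (per class), `model_id`, `n_excluded_monomorphic`.
#' @export
scan_selection <- function(dataset, model, priors = NULL, n_sims = 1000L,
                           fdr = 0.05, seed = 1L, wild = "MW", dom = "MD",
                           mu_priors = mutation_rate_priors()) {
  if (is.null(priors)) priors <- fixed_priors(model$params)
  n_wild <- length(pop_accessions(dataset, wild))
  n_dom <- length(pop_accessions(dataset, dom))
  frags <- .observed_fragments(dataset, wild, dom)
  if (!length(frags)) {
    warning("no annotated fragments to scan")
    return(structure(list(fragments = NULL, genes = NULL), class = "scan_result"))
  }
  poly <- !vapply(frags, function(f) is.null(f$components), TRUE)
  n_mono_frag <- sum(!poly)
  genes_all <- unique(vapply(frags, `[[`, "", "gene"))
  genes_poly <- unique(vapply(frags[poly], `[[`, "", "gene"))
  frags <- frags[poly]
  if (!length(frags)) {
    warning("all fragments monomorphic; nothing to scan")
    return(structure(list(fragments = NULL, genes = NULL), class = "scan_result"))
  }
  tab <- data.frame(
    gene = vapply(frags, `[[`, "", "gene"),
    class = vapply(frags, `[[`, "", "class"),
    length = vapply(frags, `[[`, 0, "length"),
    do.call(rbind, lapply(frags, `[[`, "components")),
    stringsAsFactors = FALSE)
  # a class with a single polymorphic fragment cannot supply normalization
  # constants; such fragments are untestable and dropped with a warning
  few <- names(which(table(tab$class) < 2L))
  if (length(few)) {
    warning("dropping ", sum(tab$class %in% few), " fragment(s) of class ",
            paste(few, collapse = ", "),
            ": not enough fragments to estimate normalization constants")
    tab <- tab[!tab$class %in% few, , drop = FALSE]
    if (!nrow(tab)) {
      warning("no testable fragments remain")
      return(structure(list(fragments = NULL, genes = NULL),
                       class = "scan_result"))
    }
  }
  nulls <- list()
  tab$index <- NA_real_
  tab$p_raw <- NA_real_
  for (cls in unique(tab$class)) {
    sel <- tab$class == cls
    comp_obs <- tab[sel, c("fst_mol", "branch_len", "delta_div")]
    idx_obs <- selection_index(comp_obs)
    center <- attr(idx_obs, "center"); scale <- attr(idx_obs, "scale")
    nd <- simulate_null(model, priors, n_sims, lengths = tab$length[sel],
                        mu_prior = mu_priors[[cls]], n_wild = n_wild,
                        n_dom = n_dom,
                        seed = seed + match(cls, c("exonic", "intronic")))
    if (!nrow(nd$components))
      stop("all null replicates monomorphic for class ", cls,
           "; increase the mutation rate or fragment lengths")
    idx_null <- selection_index(nd$components, center, scale)
    tab$index[sel] <- as.numeric(idx_obs)
    tab$p_raw[sel] <- empirical_p(as.numeric(idx_obs), as.numeric(idx_null))
    nulls[[cls]] <- nd
  }
  tab$q_bh <- bh_adjust(tab$p_raw)
  tab$flagged <- tab$q_bh < fdr
  genes <- do.call(rbind, lapply(split(tab, tab$gene), function(d)
    data.frame(gene = d$gene[1L], n_fragments = nrow(d),
               min_q = min(d$q_bh), flagged = any(d$flagged),
               stringsAsFactors = FALSE)))
  rownames(genes) <- NULL
  structure(list(fragments = tab, genes = genes, null = nulls,
                 model_id = model$model_id, fdr = fdr, seed = seed,
                 n_excluded_monomorphic_genes =
                   length(setdiff(genes_all, genes_poly)),
                 n_excluded_monomorphic_fragments = n_mono_frag),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  if (is.null(x$fragments)) { cat("<scan_result> empty\n"); return(invisible(x)) }
  cat(sprintf("<scan_result> Model %d: %d fragments, %d genes, %d flagged genes (FDR %g)\n",
              x$model_id, nrow(x$fragments), nrow(x$genes),
              sum(x$genes$flagged), x$fdr))
  invisible(x)
}

#' Write scan tables as TSV
#' @param scan a `scan_result`.
#' @param frag_path,gene_path output files (NULL = skip).
#' @export
write_scan_result <- function(scan, frag_path = NULL, gene_path = NULL) {
  if (!is.null(frag_path))
    write.table(scan$fragments, frag_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(gene_path))
    write.table(scan$genes, gene_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(scan)
}
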