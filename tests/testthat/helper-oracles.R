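# Independent brute-force oracles used to verify the estimators. These are
# deliberately naive (per-pair loops, explicit enumerations) and share no
# code with the package implementations.

GEN_CODE <- Biostrings::GENETIC_CODE

mk_aln <- function(seqs, id = "test") {
  locus_alignment(id, matrix(unlist(strsplit(seqs, "")),
                             nrow = length(seqs), byrow = TRUE,
                             dimnames = list(names(seqs) %||%
                                               paste0("s", seq_along(seqs)),
                                             NULL)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

rand_aln <- function(n, L, p_gap = 0, p_var = 0.5, id = "rand") {
  ref <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  m <- matrix(rep(ref, each = n), nrow = n,
              dimnames = list(paste0("s", seq_len(n)), NULL))
  for (j in seq_len(L)) {
    if (runif(1) < p_var) {
      k <- sample.int(n, sample.int(max(1, n - 1), 1))
      m[k, j] <- sample(c("A", "C", "G", "T"), 1)
    }
  }
  if (p_gap > 0) {
    idx <- which(runif(n * L) < p_gap)
    m[idx] <- sample(c("-", "N"), length(idx), replace = TRUE)
  }
  locus_alignment(id, m)
}

# complete-deletion usable matrix
brute_usable <- function(aln) {
  m <- aln$mat
  keep <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  m[, keep, drop = FALSE]
}

brute_pi <- function(aln) {
  m <- brute_usable(aln)
  n <- nrow(m); L <- ncol(m)
  if (L == 0) return(NA_real_)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(m[i, ] != m[j, ])
  tot / (choose(n, 2) * L)
}

brute_counts <- function(aln) {
  m <- brute_usable(aln)
  V <- eta <- S <- Pi <- 0
  for (j in seq_len(ncol(m))) {
    tab <- sort(table(m[, j]), decreasing = TRUE)
    if (length(tab) >= 2) {
      V <- V + 1
      eta <- eta + length(tab) - 1
      if (all(tab[-1] == 1)) S <- S + 1
      if (sum(tab >= 2) >= 2) Pi <- Pi + 1
    }
  }
  list(V = V, eta = eta, S = S, Pi = Pi, L = ncol(m))
}

brute_theta <- function(aln, type = "S") {
  m <- brute_usable(aln)
  cc <- brute_counts(aln)
  if (cc$L == 0) return(NA_real_)
  a_n <- sum(1 / seq_len(nrow(m) - 1))
  (if (type == "S") cc$V else cc$eta) / (a_n * cc$L)
}

brute_hd <- function(aln) {
  m <- brute_usable(aln)
  n <- nrow(m)
  hap <- apply(m, 1, paste0, collapse = "")
  p <- table(hap) / n
  list(H = length(p), Hd = n / (n - 1) * (1 - sum(p^2)))
}

brute_hudson <- function(aln1, aln2) {
  pm <- rbind(aln1$mat, aln2$mat)
  rownames(pm) <- paste0("r", seq_len(nrow(pm)))
  keep <- apply(pm, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  m1 <- aln1$mat[, keep, drop = FALSE]; m2 <- aln2$mat[, keep, drop = FALSE]
  n1 <- nrow(m1); n2 <- nrow(m2); L <- ncol(m1)
  pairsum <- function(m) {
    tot <- 0
    for (i in 1:(nrow(m) - 1)) for (j in (i + 1):nrow(m))
      tot <- tot + sum(m[i, ] != m[j, ])
    tot
  }
  hw1 <- pairsum(m1) / choose(n1, 2)
  hw2 <- pairsum(m2) / choose(n2, 2)
  hb <- 0
  for (i in 1:n1) for (j in 1:n2) hb <- hb + sum(m1[i, ] != m2[j, ])
  hb <- hb / (n1 * n2)
  if (hb == 0) return(NA_real_)
  1 - ((hw1 + hw2) / 2) / hb
}

# AMOVA variance components straight from the sums-of-squares definitions
brute_amova_phi <- function(D, labels) {
  N <- nrow(D); grp <- split(seq_len(N), labels); P <- length(grp)
  ssd <- function(idx) {
    s <- 0
    if (length(idx) >= 2)
      for (i in 1:(length(idx) - 1)) for (j in (i + 1):length(idx))
        s <- s + D[idx[i], idx[j]]
    s / length(idx)
  }
  sst <- ssd(seq_len(N)); ssw <- sum(sapply(grp, ssd))
  msa <- (sst - ssw) / (P - 1); msw <- ssw / (N - P)
  n0 <- (N - sum(lengths(grp)^2) / N) / (P - 1)
  sa <- (msa - msw) / n0
  if (sa + msw == 0) return(NA_real_)
  sa / (sa + msw)
}

# exact BH step-up from the definition (find largest k with p_(k) <= k a/m,
# computed for every alpha via the q-value definition)
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- sapply(i:m, function(j) m * p[o][j] / j)
    q[o[i]] <- min(1, min(vals))
  }
  q
}

# exact signed-rank tail by enumerating all sign assignments
brute_signed_rank_p <- function(d, alternative = "greater") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  vs <- as.matrix(signs) %*% r
  switch(alternative,
         greater = mean(vs >= v_obs),
         less = mean(vs <= v_obs),
         two.sided = min(1, 2 * min(mean(vs >= v_obs), mean(vs <= v_obs))))
}

# exact rank-sum tail by enumerating all group assignments
brute_ranksum_p <- function(x, y, alternative = "two.sided") {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(n + m, n)
  ws <- apply(combs, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  switch(alternative,
         greater = mean(ws >= w_obs),
         less = mean(ws <= w_obs),
         two.sided = min(1, 2 * min(mean(ws >= w_obs), mean(ws <= w_obs))))
}

# ---- Nei-Gojobori oracle --------------------------------------------------

ngo_translate <- function(codon) unname(GEN_CODE[codon])
ngo_is_ts <- function(a, b) paste0(sort(c(a, b)), collapse = "") %in% c("AG", "CT")

# R-weighted synonymous-site count of one codon (stop targets excluded)
ngo_sites <- function(codon, R) {
  s <- 0
  for (p in 1:3) {
    b0 <- substr(codon, p, p)
    wt <- ws <- 0
    for (b in setdiff(c("A", "C", "G", "T"), b0)) {
      alt <- codon; substr(alt, p, p) <- b
      if (ngo_translate(alt) == "*") next
      w <- ifelse(ngo_is_ts(b0, b), R, 1)
      wt <- wt + w
      if (ngo_translate(alt) == ngo_translate(codon)) ws <- ws + w
    }
    if (wt > 0) s <- s + ws / wt
  }
  s
}

# pathway enumeration for one codon pair; paths through stops dropped
ngo_diff <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(0, 0))
  perms <- if (length(pos) == 1) list(pos)
           else if (length(pos) == 2) list(pos, rev(pos))
           else unname(lapply(asplit(rbind(
             c(1,2,3),c(1,3,2),c(2,1,3),c(2,3,1),c(3,1,2),c(3,2,1)), 1),
             function(o) pos[o]))
  walk <- function(order_pos, strict) {
    cur <- c1; sd <- nd <- 0
    for (p in order_pos) {
      nxt <- cur; substr(nxt, p, p) <- substr(c2, p, p)
      if (strict && ngo_translate(nxt) == "*" && nxt != c2) return(NULL)
      if (ngo_translate(cur) == ngo_translate(nxt)) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- Filter(Negate(is.null), lapply(perms, walk, strict = TRUE))
  if (!length(res)) res <- lapply(perms, walk, strict = FALSE)
  colMeans(do.call(rbind, res))
}

brute_ng <- function(codon_rows, R = 1) {
  # codon_rows: character matrix of codon strings (rows = sequences)
  n <- nrow(codon_rows); nc <- ncol(codon_rows)
  SdT <- NdT <- SsT <- NsT <- 0; np <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    np <- np + 1
    for (k in seq_len(nc)) {
      d <- ngo_diff(codon_rows[i, k], codon_rows[j, k])
      SdT <- SdT + d[1]; NdT <- NdT + d[2]
      s <- (ngo_sites(codon_rows[i, k], R) + ngo_sites(codon_rows[j, k], R)) / 2
      SsT <- SsT + s; NsT <- NsT + 3 - s
    }
  }
  pS <- (SdT / np) / (SsT / np); pN <- (NdT / np) / (NsT / np)
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(dS = jc(pS), dN = jc(pN), pS = pS, pN = pN)
}

rand_codon_aln <- function(n, n_codons) {
  codons <- setdiff(names(GEN_CODE), c("TAA", "TAG", "TGA"))
  ref <- sample(codons, n_codons, replace = TRUE)
  m <- matrix(rep(ref, each = n), nrow = n)
  for (k in seq_len(n_codons)) for (i in seq_len(n)) {
    if (runif(1) < 0.4) {
      repeat {
        cd <- ref[k]
        p <- sample(1:3, 1)
        substr(cd, p, p) <- sample(c("A", "C", "G", "T"), 1)
        if (ngo_translate(cd) != "*") break
      }
      m[i, k] <- cd
    }
  }
  m
}

codon_matrix_to_aln <- function(codon_rows, id = "cds") {
  seqs <- apply(codon_rows, 1, paste0, collapse = "")
  mk_aln(setNames(seqs, paste0("s", seq_len(nrow(codon_rows)))), id)
}
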