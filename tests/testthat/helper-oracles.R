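# Independent oracle implementations, deliberately written as literal,
# scalar transcriptions so they share no code path with the package.

# Weir & Cockerham (1984) theta for two samples of dosages, one locus at a
# time, combined by ratio-of-sums.
oracle_wc_fst <- function(da, db) {
  num <- 0
  den <- 0
  for (l in seq_len(ncol(da))) {
    xa <- da[, l][!is.na(da[, l])]
    xb <- db[, l][!is.na(db[, l])]
    n1 <- length(xa); n2 <- length(xb)
    if (n1 < 2 || n2 < 2) next
    p1 <- sum(xa) / (2 * n1); p2 <- sum(xb) / (2 * n2)
    h1 <- mean(xa == 1); h2 <- mean(xb == 1)
    r <- 2
    nbar <- (n1 + n2) / 2
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- nbar / nc * (s2 - 1 / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
      (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    if (a + b + cc == 0) next
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# Tajima's D from a complete-call dosage matrix: textbook constants coded
# afresh from the 1989 definitions.
oracle_tajima_d <- function(dos) {
  n <- 2 * nrow(dos)
  freqs <- colMeans(dos) / 2
  seg <- freqs > 0 & freqs < 1
  S <- sum(seg)
  pi_hat <- 0
  for (l in which(seg)) {
    k <- sum(dos[, l])                       # alt alleles among n chromosomes
    pi_hat <- pi_hat + k * (n - k) / choose(n, 2)
  }
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Average pairwise difference per site by enumerating all chromosome pairs.
oracle_pairwise_pi <- function(dos, surveyed_bp) {
  total <- 0
  for (l in seq_len(ncol(dos))) {
    x <- dos[, l][!is.na(dos[, l])]
    chroms <- unlist(lapply(x, function(d) c(rep(1, d), rep(0, 2 - d))))
    n <- length(chroms)
    diffs <- 0
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) diffs <- diffs + (chroms[i] != chroms[j])
    }
    total <- total + diffs / choose(n, 2)
  }
  total / surveyed_bp
}

# Exact Mantel p by enumerating every joint row/column permutation of b.
oracle_mantel_exact <- function(ma, mb, tail = "greater") {
  va <- ma[lower.tri(ma)]
  r_obs <- cor(va, mb[lower.tri(mb)])
  perms <- gtools_permutations(nrow(ma))
  rs <- apply(perms, 1, function(ix) {
    mp <- mb[ix, ix]
    cor(va, mp[lower.tri(mp)])
  })
  if (tail == "greater") mean(rs >= r_obs - 1e-12)
  else mean(abs(rs) >= abs(r_obs) - 1e-12)
}

# All permutations of 1..n as a matrix (lexicographic recursion).
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(first) {
    rest <- matrix(setdiff(seq_len(n), first)[sub], nrow(sub))
    cbind(first, rest)
  }))
}

# Random symmetric zero-diagonal matrix.
random_dist <- function(n, labels = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- runif(n * (n - 1) / 2)
  m <- m + t(m)
  if (is.null(labels)) labels <- paste0("P", seq_len(n))
  dimnames(m) <- list(labels, labels)
  m
}

# Small genotype fixture helper.
tiny_geno <- function(dosage_rows, pops) {
  genotype_matrix(do.call(rbind, dosage_rows), pops)
}
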