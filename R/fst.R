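#' Weir-Cockerham F_ST between two populations
#'
#' Multi-locus theta of Weir & Cockerham (1984), the moment estimator of the
#' fixation index built from three per-locus variance components: `a`
#' (among populations), `b` (among individuals within populations) and `c`
#' (within individuals, i.e. heterozygosity). Loci are combined by
#' ratio-of-sums, `sum(a) / sum(a + b + c)`, the standard small-sample
#' choice; loci monomorphic in the pair contribute nothing and are skipped.
#' Only the two populations' own samples enter the estimate. Values may be
#' slightly negative through sampling noise and are reported as computed.
#'
#' @param g A [genotype_matrix()].
#' @param pop_a,pop_b Population labels.
#' @return A single F_ST estimate (at most 1, possibly negative).
#' @export
wc_fst_pair <- function(g, pop_a, pop_b) {
  comp <- wc_components(pop_dosages(g, pop_a), pop_dosages(g, pop_b))
  num <- sum(comp$a)
  den <- sum(comp$a + comp$b + comp$c)
  if (length(comp$a) == 0 || den == 0) {
    abort(sprintf(
      "F_ST undefined for pair (%s, %s): no jointly polymorphic SNP (denominator zero).",
      pop_a, pop_b
    ))
  }
  num / den
}

# Per-locus W&C (1984) components for two samples of dosages.
# Vectorized over loci; returns components only for loci where both
# populations have >= 2 calls and a + b + c != 0.
wc_components <- function(da, db) {
  na <- colSums(!is.na(da))
  nb <- colSums(!is.na(db))
  ok <- na >= 2 & nb >= 2
  if (!any(ok)) abort("No SNP with at least two called genotypes in both populations.")
  na <- na[ok]; nb <- nb[ok]
  da <- da[, ok, drop = FALSE]; db <- db[, ok, drop = FALSE]
  pa <- colSums(da, na.rm = TRUE) / (2 * na)
  pb <- colSums(db, na.rm = TRUE) / (2 * nb)
  ha <- colSums(da == 1L, na.rm = TRUE) / na
  hb <- colSums(db == 1L, na.rm = TRUE) / nb

  r <- 2
  nbar <- (na + nb) / r
  nc <- (r * nbar - (na^2 + nb^2) / (r * nbar)) / (r - 1)
  pbar <- (na * pa + nb * pb) / (r * nbar)
  s2 <- (na * (pa - pbar)^2 + nb * (pb - pbar)^2) / ((r - 1) * nbar)
  hbar <- (na * ha + nb * hb) / (r * nbar)

  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2

  keep <- (a + b + cc) != 0
  list(a = a[keep], b = b[keep], c = cc[keep])
}

#' Pairwise F_ST matrix over all populations
#'
#' @param g A [genotype_matrix()] with at least two populations.
#' @return A `fst_matrix` (a [pop_dist()]) with `min`, `max` and `mean` of
#'   the off-diagonal estimates attached; see [glance.fst_matrix()].
#' @examples
#' sim <- simulate_study(sim_config(n_snps = 500, seed = 1))
#' f <- fst_matrix(sim$genotypes)
#' glance(f)
#' @export
fst_matrix <- function(g) {
  pops <- populations(g)
  if (length(pops) < 2) abort("Need at least two populations for F_ST.")
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (pair in combn(pops, 2, simplify = FALSE)) {
    est <- wc_fst_pair(g, pair[1], pair[2])
    m[pair[1], pair[2]] <- est
    m[pair[2], pair[1]] <- est
  }
  out <- pop_dist(m, measure = "F_ST")
  class(out) <- c("fst_matrix", class(out))
  off <- lower_triangle(out)
  attr(out, "summary") <- tibble(
    n_pairs = length(off), min = min(off), max = max(off), mean = mean(off)
  )
  out
}

#' @rdname fst_matrix
#' @param x A `fst_matrix`.
#' @param ... Unused.
#' @export
glance.fst_matrix <- function(x, ...) attr(x, "summary")

#' Linearized genetic distance F_ST / (1 - F_ST)
#'
#' Rousset's linearization used for isolation-by-distance regressions; a
#' strictly increasing map, so negative estimates pass through unchanged.
#'
#' @param f A `fst_matrix` or [pop_dist()] of F_ST values, all below 1.
#' @return A [pop_dist()] of linearized values.
#' @export
linearize_fst <- function(f) {
  m <- as.matrix(f)
  if (any(m >= 1)) abort("Cannot linearize: F_ST value of 1 maps to infinity.")
  pop_dist(m / (1 - m), measure = "F_ST/(1-F_ST)")
}

#' Wright island-model migrant estimate
#'
#' `Nm = (1 - F_ST) / (4 F_ST)`, the effective number of migrants per
#' generation implied by an island model at equilibrium.
#'
#' @param fst F_ST value(s) in (0, 1].
#' @return Migrants per generation, same length as `fst`.
#' @export
nm_from_fst <- function(fst) {
  if (any(fst <= 0)) {
    abort("Nm is undefined (infinite) for F_ST <= 0.")
  }
  (1 - fst) / (4 * fst)
}
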