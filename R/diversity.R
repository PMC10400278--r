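#' Per-population genetic diversity indices
#'
#' Six standard indices summarised per population from a filtered SNP panel:
#' observed heterozygosity Ho, expected heterozygosity He (1 - p^2 - q^2),
#' unbiased Nei gene diversity (He scaled by 2n/(2n-1)), polymorphism
#' information content (Botstein's PIC, for a biallelic marker
#' 1 - p^2 - q^2 - 2 p^2 q^2), nucleotide diversity per surveyed base, and
#' Tajima's D. Per-SNP values use within-population allele frequencies from
#' non-missing calls; SNPs are those polymorphic in the whole panel (no
#' per-population re-ascertainment), matching panel-level PLINK-style
#' reporting.
#'
#' @name diversity
NULL

div_pop_stats <- function(g, pop) {
  d <- pop_dosages(g, pop)
  n <- colSums(!is.na(d))
  usable <- n > 0
  if (!any(usable)) abort(sprintf("No callable SNPs in population '%s'.", pop))
  p <- colSums(d, na.rm = TRUE) / (2 * n)
  list(d = d, n = n, p = p, usable = usable)
}

#' Observed heterozygosity
#'
#' Mean over SNPs of the fraction of called genotypes that are heterozygous.
#'
#' @param g A [genotype_matrix()].
#' @param pop Population label.
#' @return A single fraction in \[0, 1\].
#' @export
observed_het <- function(g, pop) {
  s <- div_pop_stats(g, pop)
  het <- colSums(s$d == 1L, na.rm = TRUE)[s$usable] / s$n[s$usable]
  mean(het)
}

#' Expected heterozygosity
#'
#' Mean over SNPs of `1 - p^2 - q^2` from within-population allele
#' frequencies.
#'
#' @inheritParams observed_het
#' @return A single fraction in \[0, 0.5\] for biallelic SNPs.
#' @export
expected_het <- function(g, pop) {
  s <- div_pop_stats(g, pop)
  p <- s$p[s$usable]
  mean(2 * p * (1 - p))
}

#' Nei unbiased gene diversity
#'
#' Per SNP `(2n / (2n - 1)) * (1 - p^2 - q^2)` with `n` the called genotype
#' count, averaged over SNPs; the small-sample unbiased version of expected
#' heterozygosity.
#'
#' @inheritParams observed_het
#' @return A single fraction.
#' @export
nei_diversity <- function(g, pop) {
  s <- div_pop_stats(g, pop)
  p <- s$p[s$usable]
  n <- s$n[s$usable]
  mean(2 * n / (2 * n - 1) * 2 * p * (1 - p))
}

#' Polymorphism information content
#'
#' Botstein's PIC for a biallelic marker, `1 - (p^2 + q^2) - 2 p^2 q^2`,
#' averaged over SNPs.
#'
#' @inheritParams observed_het
#' @return A single fraction; always at most the expected heterozygosity.
#' @export
pic <- function(g, pop) {
  s <- div_pop_stats(g, pop)
  p <- s$p[s$usable]
  q <- 1 - p
  mean(1 - (p^2 + q^2) - 2 * p^2 * q^2)
}

#' Nucleotide diversity per surveyed base
#'
#' Sum over SNPs of the unbiased per-site heterozygosity
#' `(2n/(2n-1)) * 2 p (1 - p)`, divided by the total number of surveyed
#' bases. Reduced-representation panels survey far more monomorphic than
#' polymorphic bases, so a per-site value is only meaningful against the
#' surveyed length, which must be supplied.
#'
#' @inheritParams observed_het
#' @param surveyed_bp Total surveyed sequence length in base pairs; must be
#'   at least the number of SNPs.
#' @return Dimensionless per-site diversity.
#' @export
theta_pi <- function(g, pop, surveyed_bp) {
  if (missing(surveyed_bp) || is.null(surveyed_bp)) {
    abort(paste(
      "`surveyed_bp` is required: nucleotide diversity is reported per",
      "surveyed base, so the total surveyed length must be given."
    ))
  }
  if (surveyed_bp < ncol(g$dosages)) {
    abort("`surveyed_bp` cannot be smaller than the number of SNPs.")
  }
  s <- div_pop_stats(g, pop)
  p <- s$p[s$usable]
  n <- s$n[s$usable]
  sum(2 * n / (2 * n - 1) * 2 * p * (1 - p)) / surveyed_bp
}

tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D from genotype dosages
#'
#' The classical normalized difference between pi-based and segregating-site
#' estimates of the population mutation rate, computed from unphased
#' dosages. A single chromosome count is required by the constants, so
#' `n_chr` is twice the (floored) median per-SNP call count in the
#' population; SNPs called in fewer than 80% of that median are excluded
#' from the segregating-site count. Per segregating site the pairwise
#' heterozygosity contribution is `2 p (1 - p) * n_chr / (n_chr - 1)`.
#'
#' @inheritParams observed_het
#' @return Dimensionless D statistic.
#' @export
tajimas_d <- function(g, pop) {
  s <- div_pop_stats(g, pop)
  med <- floor(median(s$n[s$usable]))
  n_chr <- 2 * med
  if (n_chr < 4) abort("Tajima's D needs at least 4 sampled chromosomes.")
  keep <- s$usable & s$n >= 0.8 * med
  p <- s$p[keep]
  seg <- p > 0 & p < 1
  S <- sum(seg)
  if (S == 0) abort("Tajima's D undefined: no segregating sites in population.")
  pi_total <- sum(2 * p[seg] * (1 - p[seg])) * n_chr / (n_chr - 1)
  k <- tajima_constants(n_chr)
  (pi_total - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Diversity summary table for all populations
#'
#' @param g A [genotype_matrix()].
#' @param surveyed_bp Surveyed length for [theta_pi()]; when `NULL` the
#'   `theta_pi` column is omitted.
#' @return A tibble with one row per population and columns `population`,
#'   `n`, `ho`, `he`, `nei`, `pic`, `theta_pi` (optional), `tajima_d`.
#' @examples
#' sim <- simulate_study(sim_config(n_snps = 200, seed = 1))
#' diversity_table(sim$genotypes, surveyed_bp = 1e5)
#' @export
diversity_table <- function(g, surveyed_bp = NULL) {
  stopifnot(inherits(g, "geno_mat"))
  list_rbind(map(populations(g), function(pop) {
    row <- tibble(
      population = pop,
      n = sum(g$populations == pop),
      ho = observed_het(g, pop),
      he = expected_het(g, pop),
      nei = nei_diversity(g, pop),
      pic = pic(g, pop),
      tajima_d = tryCatch(tajimas_d(g, pop), error = function(e) NA_real_)
    )
    if (!is.null(surveyed_bp)) {
      row <- mutate(row,
        theta_pi = theta_pi(g, pop, surveyed_bp),
        .before = "tajima_d"
      )
    }
    row
  }))
}
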