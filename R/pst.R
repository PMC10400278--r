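#' One-way ANOVA variance components
#'
#' Model II (random-effects) one-way ANOVA decomposition of a trait into
#' between-group and within-group variance components, the classical
#' Sokal-Rohlf moment estimators: `MS_within` estimates the within
#' component directly and `(MS_between - MS_within) / n0` estimates the
#' between component, with `n0 = (N - sum(n_i^2)/N) / (k - 1)` the
#' effective per-group sample size for unequal group sizes. A negative
#' between-component estimate is truncated to zero so downstream P_ST stays
#' in \[0, 1\].
#'
#' @param values Numeric vector of trait values.
#' @param groups Group (population) labels, same length as `values`.
#'   Missing trait values are dropped with their labels.
#' @return A one-row tibble: `k`, `n_total`, `n0`, `ms_between`,
#'   `ms_within`, `sigma2_b`, `sigma2_w`.
#' @examples
#' anova_components(c(1, 2, 3, 4, 5, 6), rep(c("A", "B"), each = 3))
#' @export
anova_components <- function(values, groups) {
  keep <- !is.na(values)
  values <- values[keep]
  groups <- as.character(groups[keep])
  ni <- table(groups)
  if (length(ni) < 2) abort("Need at least two groups.")
  if (any(ni < 2)) {
    abort(sprintf(
      "Group(s) with fewer than two values: %s",
      paste(names(ni)[ni < 2], collapse = ", ")
    ))
  }
  k <- length(ni)
  N <- length(values)
  gm <- tapply(values, groups, mean)
  grand <- mean(values)
  ssb <- sum(as.numeric(ni) * (gm - grand)^2)
  ssw <- sum((values - gm[groups])^2)
  ms_between <- ssb / (k - 1)
  ms_within <- ssw / (N - k)
  if (ms_within == 0) abort("Zero within-group variance: components undefined.")
  n0 <- (N - sum(as.numeric(ni)^2) / N) / (k - 1)
  tibble(
    k = k, n_total = N, n0 = n0,
    ms_between = ms_between, ms_within = ms_within,
    sigma2_b = max(0, (ms_between - ms_within) / n0),
    sigma2_w = ms_within
  )
}

check_c_h2 <- function(c, h2) {
  if (any(c <= 0)) abort("`c` must be positive.")
  if (any(h2 <= 0) || any(h2 > 1)) abort("`h2` must lie in (0, 1].")
}

#' P_ST from variance components
#'
#' The phenotypic analogue of Q_ST for wild-caught individuals:
#' `P_ST = c * sigma2_B / (c * sigma2_B + 2 * h2 * sigma2_W)`, where `c` is
#' the proportion of the between-population variance assumed additive
#' genetic and `h2` the narrow-sense heritability within populations. With
#' the conventional assumptions of no environmental variance between
#' samples (`c = 1`) and `h2 = 0.5` this reduces to the between proportion
#' `sigma2_B / (sigma2_B + sigma2_W)`.
#'
#' @param sigma2_b,sigma2_w Between- and within-population variance
#'   components (e.g. from [anova_components()]); vectors recycle.
#' @param c Additive proportion of between-population variance, positive
#'   (values above 1 are admitted for critical-c reasoning).
#' @param h2 Within-population heritability in (0, 1].
#' @return P_ST value(s) in \[0, 1\] (0 when `sigma2_b` is 0).
#' @export
pst_value <- function(sigma2_b, sigma2_w, c = 1, h2 = 0.5) {
  check_c_h2(c, h2)
  ifelse(sigma2_b == 0, 0,
         c * sigma2_b / (c * sigma2_b + 2 * h2 * sigma2_w))
}

#' Pairwise P_ST for every trait and population pair
#'
#' For each trait and each unordered pair of populations, variance
#' components come from a two-group ANOVA on that pair only (mirroring the
#' pairwise-F_ST construction), then P_ST is evaluated at (`c`, `h2`).
#' Missing trait values are dropped per trait.
#'
#' @param traits A data frame with a `population` column and one numeric
#'   column per trait (any other non-numeric columns are ignored).
#' @param c,h2 Passed to [pst_value()].
#' @return A tibble with one row per trait x pair: `trait`, `pop_a`,
#'   `pop_b`, the ANOVA components, and `pst`.
#' @examples
#' sim <- simulate_study(sim_config(n_snps = 50, n_traits = 3, seed = 1))
#' pairwise_pst(sim$traits)
#' @export
pairwise_pst <- function(traits, c = 1, h2 = 0.5) {
  check_c_h2(c, h2)
  traits <- as_tibble(traits)
  if (!"population" %in% names(traits)) {
    abort("`traits` must contain a `population` column.")
  }
  trait_names <- names(traits)[vapply(traits, is.numeric, logical(1))]
  if (length(trait_names) == 0) abort("No numeric trait columns found.")
  pops <- sort(unique(traits$population))
  if (length(pops) < 2) abort("Need at least two populations.")
  pairs <- combn(pops, 2, simplify = FALSE)
  grid <- tidyr::expand_grid(trait = trait_names, pair = pairs)
  out <- pmap(grid, function(trait, pair) {
    keep <- traits$population %in% pair
    comp <- tryCatch(
      anova_components(traits[[trait]][keep], traits$population[keep]),
      error = function(e) {
        abort(sprintf("Trait '%s', pair (%s, %s): %s",
                      trait, pair[1], pair[2], conditionMessage(e)))
      }
    )
    mutate(comp, trait = trait, pop_a = pair[1], pop_b = pair[2],
           .before = 1)
  })
  out <- list_rbind(out)
  mutate(out, c = c, h2 = h2,
         pst = pst_value(.data$sigma2_b, .data$sigma2_w, c = c, h2 = h2))
}

#' Global (all-population) P_ST per trait
#'
#' Same construction as [pairwise_pst()] but with a single k-group ANOVA
#' over all populations, for reference alongside the pairwise values.
#'
#' @inheritParams pairwise_pst
#' @return A tibble with one row per trait.
#' @export
global_pst <- function(traits, c = 1, h2 = 0.5) {
  check_c_h2(c, h2)
  traits <- as_tibble(traits)
  trait_names <- names(traits)[vapply(traits, is.numeric, logical(1))]
  out <- map(trait_names, function(trait) {
    comp <- anova_components(traits[[trait]], traits$population)
    mutate(comp, trait = trait, .before = 1)
  })
  out <- list_rbind(out)
  mutate(out, c = c, h2 = h2,
         pst = pst_value(.data$sigma2_b, .data$sigma2_w, c = c, h2 = h2))
}

#' P_ST / F_ST ratios per trait and population pair
#'
#' Joins pairwise P_ST values with the matching pairwise F_ST and reports
#' their ratio; pairs with non-positive F_ST yield `NA` with
#' `undefined = TRUE` rather than a misleading ratio.
#'
#' @param pst_tbl Result of [pairwise_pst()].
#' @param fst A `fst_matrix` from [fst_matrix()].
#' @return `pst_tbl` with columns `fst`, `ratio`, `undefined` added.
#' @export
pst_fst_ratio <- function(pst_tbl, fst) {
  fst_tbl <- tidy(fst) |> dplyr::rename(fst = "value")
  missing_pops <- setdiff(
    unique(c(pst_tbl$pop_a, pst_tbl$pop_b)), labels(fst)
  )
  if (length(missing_pops) > 0) {
    abort(sprintf("Populations absent from the F_ST matrix: %s",
                  paste(missing_pops, collapse = ", ")))
  }
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  fst_lookup <- setNames(fst_tbl$fst, key(fst_tbl$pop_a, fst_tbl$pop_b))
  out <- mutate(pst_tbl, fst = unname(fst_lookup[key(.data$pop_a, .data$pop_b)]))
  mutate(out,
    undefined = .data$fst <= 0,
    ratio = ifelse(.data$undefined, NA_real_, .data$pst / .data$fst)
  )
}

#' Critical c: the additive proportion at which P_ST equals F_ST
#'
#' Solves `P_ST(c) = fst` for `c` in closed form:
#' `c_crit = 2 * h2 * sigma2_W * fst / (sigma2_B * (1 - fst))`. Traits whose
#' plausible `c` exceeds this value show more divergence than neutral
#' expectation; a small `c_crit` makes the selection inference robust.
#'
#' @param sigma2_b,sigma2_w Variance components; `sigma2_b` must be
#'   positive.
#' @param fst Neutral differentiation in (0, 1).
#' @param h2 Heritability in (0, 1].
#' @return The critical `c` (may exceed 1).
#' @export
critical_c <- function(sigma2_b, sigma2_w, fst, h2 = 1) {
  if (any(sigma2_b <= 0)) {
    abort("Critical c undefined: no between-population variance.")
  }
  if (any(fst <= 0 | fst >= 1)) abort("`fst` must lie in (0, 1).")
  check_c_h2(1, h2)
  2 * h2 * sigma2_w * fst / (sigma2_b * (1 - fst))
}

#' Heritability sensitivity of the P_ST > F_ST conclusion
#'
#' Re-evaluates every trait x pair P_ST over a grid of heritabilities at
#' `c = 1` (no environmental variance between samples) and reports, per
#' grid point, the fraction of cells whose P_ST exceeds the matching
#' pairwise F_ST. Because P_ST is nonincreasing in `h2`, the fraction is
#' nonincreasing along the grid; a fraction still high at `h2 = 1` is the
#' conservative end of the inference.
#'
#' @param pst_tbl Result of [pairwise_pst()] (components are reused; the
#'   grid re-evaluates P_ST from them).
#' @param fst A `fst_matrix`.
#' @param h2_grid Heritability grid in (0, 1].
#' @return A tibble: `h2`, `n_cells`, `n_exceed`, `frac_exceed`.
#' @export
h2_sensitivity <- function(pst_tbl, fst, h2_grid = c(0.25, 0.5, 0.75, 1)) {
  check_c_h2(1, h2_grid)
  with_fst <- pst_fst_ratio(pst_tbl, fst)
  list_rbind(map(h2_grid, function(h2) {
    p <- pst_value(with_fst$sigma2_b, with_fst$sigma2_w, c = 1, h2 = h2)
    tibble(
      h2 = h2,
      n_cells = length(p),
      n_exceed = sum(p > with_fst$fst),
      frac_exceed = mean(p > with_fst$fst)
    )
  }))
}

#' Welch t-test of pairwise P_ST against pairwise F_ST, per trait
#'
#' For each trait, compares its pairwise P_ST values with the pairwise
#' F_ST values by a two-sample Welch t-test; both the two-sided p and the
#' one-sided p for the alternative "P_ST exceeds F_ST" are reported, the
#' one-sided test being the divergent-selection hypothesis. With
#' `pooled = TRUE` a single study-level test of all trait-by-pair P_ST
#' values against the pairwise F_ST values is returned instead — the
#' comparison a violin plot of per-trait P_ST distributions with the F_ST
#' values overlaid depicts.
#'
#' @param pst_tbl Result of [pairwise_pst()].
#' @param fst A `fst_matrix`.
#' @param pooled Pool all traits into one test (default `FALSE`: one row
#'   per trait).
#' @return A tibble per trait (or one row with trait `"(all)"`): `t`,
#'   `df`, `p_two_sided`, `p_greater`, `mean_pst`, `mean_fst`.
#' @export
pst_vs_fst_test <- function(pst_tbl, fst, pooled = FALSE) {
  fst_vals <- lower_triangle(fst)
  if (length(fst_vals) < 2) abort("Need at least two population pairs.")
  welch_row <- function(trait, pst_vals) {
    two <- t.test(pst_vals, fst_vals)
    one <- t.test(pst_vals, fst_vals, alternative = "greater")
    tibble(
      trait = trait,
      t = unname(two$statistic), df = unname(two$parameter),
      p_two_sided = two$p.value, p_greater = one$p.value,
      mean_pst = mean(pst_vals), mean_fst = mean(fst_vals)
    )
  }
  if (pooled) {
    return(welch_row("(all)", pst_tbl$pst))
  }
  groups <- split(pst_tbl$pst, pst_tbl$trait)
  groups <- groups[unique(pst_tbl$trait)]
  list_rbind(map2(names(groups), groups, welch_row))
}

#' Violin-style comparison plot of pairwise P_ST against F_ST
#'
#' @param pst_tbl Result of [pairwise_pst()].
#' @param fst A `fst_matrix`; its pairwise values are drawn as points over
#'   each trait's P_ST distribution.
#' @return A ggplot object.
#' @export
plot_pst_fst <- function(pst_tbl, fst) {
  fst_vals <- lower_triangle(fst)
  fst_df <- tidyr::expand_grid(trait = unique(pst_tbl$trait), fst = fst_vals)
  ggplot2::ggplot(pst_tbl, ggplot2::aes(.data$trait, .data$pst)) +
    ggplot2::geom_violin(fill = "grey85", colour = NA, scale = "width") +
    ggplot2::geom_jitter(width = 0.08, size = 0.8, alpha = 0.7) +
    ggplot2::geom_point(
      data = fst_df, ggplot2::aes(y = .data$fst),
      shape = 17, colour = "black", size = 1.6
    ) +
    ggplot2::labs(x = NULL, y = expression(P[ST] ~ "(triangles:" ~ F[ST] * ")")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
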