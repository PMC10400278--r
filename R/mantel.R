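#' Mantel permutation test between two distance matrices
#'
#' The Mantel statistic is the Pearson correlation over the n(n-1)/2
#' lower-triangle entries of two aligned population distance matrices. Its
#' null distribution is obtained by jointly permuting the rows and columns
#' of the second matrix; the p-value counts permuted statistics at least as
#' extreme as the observed one, with the observed arrangement included as
#' one permutation so p is never zero:
#' `p = (count + 1) / (n_perm + 1)`. With `exact = TRUE` all n! label
#' permutations (identity included) are enumerated instead and the p-value
#' is the exact fraction of permutations at least as extreme — feasible
#' for small n and the gold standard the sampled p approximates.
#'
#' @param a,b [pop_dist()] objects (or symmetric labelled matrices) over
#'   the same populations in the same order.
#' @param n_perm Number of random permutations (default 9999).
#' @param tail `"greater"` (default; the isolation-model hypothesis
#'   "closer means more similar" is one-sided) or `"two_sided"`.
#' @param seed Optional integer seed for reproducible permutations.
#' @param exact Enumerate all permutations (n <= 8 enforced) instead of
#'   sampling.
#' @return A `mantel_test` object; see [tidy.mantel_test()].
#' @examples
#' sim <- simulate_study(sim_config(n_snps = 50, seed = 4))
#' d_geo <- geo_distance_matrix(sim$sites)
#' d_alt <- scalar_distance_matrix(sim$sites, "altitude")
#' mantel(d_geo, d_alt, n_perm = 99, seed = 1)
#' @export
mantel <- function(a, b, n_perm = 9999, tail = c("greater", "two_sided"),
                   seed = NULL, exact = FALSE) {
  tail <- match.arg(tail)
  if (inherits(a, "pop_dist") && inherits(b, "pop_dist")) check_aligned(a, b)
  ma <- as.matrix(a)
  mb <- as.matrix(b)
  if (nrow(ma) < 3) abort("Mantel test needs at least three populations.")
  if (n_perm < 1) abort("`n_perm` must be at least 1.")
  va <- ma[lower.tri(ma)]
  if (sd(va) == 0 || sd(mb[lower.tri(mb)]) == 0) {
    abort("Zero variance in a distance matrix: Mantel r undefined.")
  }
  r_obs <- cor(va, mb[lower.tri(mb)])
  n <- nrow(ma)
  perm_r <- function(ix) {
    mp <- mb[ix, ix]
    cor(va, mp[lower.tri(mp)])
  }
  if (exact) {
    if (n > 8) abort("`exact = TRUE` supported only for n <= 8 populations.")
    perms <- all_permutations(n)
    r_perm <- vapply(perms, perm_r, numeric(1))
    count <- switch(tail,
      greater = sum(r_perm >= r_obs - 1e-12),
      two_sided = sum(abs(r_perm) >= abs(r_obs) - 1e-12)
    )
    p <- count / length(perms)
    n_perm <- length(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    r_perm <- vapply(seq_len(n_perm), function(i) perm_r(sample.int(n)),
                     numeric(1))
    count <- switch(tail,
      greater = sum(r_perm >= r_obs),
      two_sided = sum(abs(r_perm) >= abs(r_obs))
    )
    p <- (count + 1) / (n_perm + 1)
  }
  structure(
    list(
      r = r_obs, p = p, n_perm = n_perm,
      tail = tail, n = n, seed = seed, partial = FALSE, exact = exact,
      names = c(measure_of(a), measure_of(b))
    ),
    class = "mantel_test"
  )
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1)
  out <- vector("list", n * length(sub))
  k <- 0
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1
      out[[k]] <- append(p, n, after = pos - 1)
    }
  }
  out
}

measure_of <- function(x) if (inherits(x, "pop_dist")) x$measure else "matrix"

#' Partial Mantel test controlling for a third matrix
#'
#' Both matrices are residualized on the control matrix by simple linear
#' regression over their lower triangles; the partial Mantel r is the
#' Pearson correlation of the residuals. Permutations jointly permute the
#' rows/columns of the residualized second matrix.
#'
#' @inheritParams mantel
#' @param control [pop_dist()] to partial out, aligned with `a` and `b`.
#' @return A `mantel_test` object with `partial = TRUE`.
#' @export
partial_mantel <- function(a, b, control, n_perm = 9999,
                           tail = c("greater", "two_sided"), seed = NULL) {
  tail <- match.arg(tail)
  if (inherits(a, "pop_dist") && inherits(control, "pop_dist")) {
    check_aligned(a, control)
  }
  if (inherits(a, "pop_dist") && inherits(b, "pop_dist")) check_aligned(a, b)
  ma <- as.matrix(a); mb <- as.matrix(b); mc <- as.matrix(control)
  n <- nrow(ma)
  if (n < 4) abort("Partial Mantel needs at least four populations.")
  tri <- lower.tri(ma)
  vc <- mc[tri]
  ra <- stats::resid(lm(ma[tri] ~ vc))
  rb <- stats::resid(lm(mb[tri] ~ vc))
  # a matrix explained exactly by the control leaves only float noise:
  # nothing to correlate
  if (sd(ra) < 1e-10 * max(sd(ma[tri]), 1)) ra <- ra * 0
  if (sd(rb) < 1e-10 * max(sd(mb[tri]), 1)) rb <- rb * 0
  degenerate <- sd(ra) == 0 || sd(rb) == 0
  r_obs <- if (degenerate) 0 else cor(ra, rb)
  # residuals placed back into matrix form for joint row/column permutation
  rb_mat <- matrix(0, n, n)
  rb_mat[tri] <- rb
  rb_mat <- rb_mat + t(rb_mat)
  if (!is.null(seed)) set.seed(seed)
  r_perm <- if (degenerate) {
    rep(0, n_perm)
  } else {
    vapply(seq_len(n_perm), function(i) {
      ix <- sample.int(n)
      mp <- rb_mat[ix, ix]
      cor(ra, mp[lower.tri(mp)])
    }, numeric(1))
  }
  count <- switch(tail,
    greater = sum(r_perm >= r_obs),
    two_sided = sum(abs(r_perm) >= abs(r_obs))
  )
  structure(
    list(
      r = r_obs, p = (count + 1) / (n_perm + 1), n_perm = n_perm,
      tail = tail, n = n, seed = seed, partial = TRUE,
      names = c(measure_of(a), measure_of(b), measure_of(control))
    ),
    class = "mantel_test"
  )
}

#' @export
print.mantel_test <- function(x, ...) {
  kind <- if (x$partial) "partial Mantel" else "Mantel"
  cat(sprintf(
    "%s test (%s vs %s%s): r = %.4f, p = %.4g (%d permutations, tail = %s)\n",
    kind, x$names[1], x$names[2],
    if (x$partial) paste0(" | ", x$names[3]) else "",
    x$r, x$p, x$n_perm, x$tail
  ))
  invisible(x)
}

#' One-row tibble of a Mantel test result
#'
#' @param x A `mantel_test`.
#' @param ... Unused.
#' @return Tibble with `r`, `p`, `n`, `n_perm`, `tail`, `partial`.
#' @export
tidy.mantel_test <- function(x, ...) {
  tibble(
    matrix_a = x$names[1], matrix_b = x$names[2],
    control = if (x$partial) x$names[3] else NA_character_,
    r = x$r, p = x$p, n = x$n, n_perm = x$n_perm,
    tail = x$tail, partial = x$partial
  )
}

#' @export
glance.mantel_test <- function(x, ...) tidy(x)

#' Ordinary least squares between two distance matrices
#'
#' Simple linear regression of the lower triangle of `y` on the lower
#' triangle of `x`; the descriptive companion to [mantel()] (inference on
#' distance matrices should use the permutation test, not the regression's
#' nominal p-values, because pairs are not independent).
#'
#' @param y,x Aligned [pop_dist()] objects.
#' @return Tibble with `slope`, `intercept`, `r_squared`, `n_pairs`.
#' @export
matrix_regression <- function(y, x) {
  if (inherits(y, "pop_dist") && inherits(x, "pop_dist")) check_aligned(y, x)
  my <- as.matrix(y); mx <- as.matrix(x)
  if (nrow(my) < 3) abort("Need at least three populations.")
  vy <- my[lower.tri(my)]
  vx <- mx[lower.tri(mx)]
  if (sd(vx) == 0) abort("Zero variance in predictor distances.")
  fit <- suppressWarnings(lm(vy ~ vx))
  tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = if (sd(vy) == 0) 0 else
      suppressWarnings(summary(fit)$r.squared),
    n_pairs = length(vy)
  )
}
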