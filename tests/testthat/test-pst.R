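test_that("variance components reproduce the hand-computed ANOVA table", {
  comp <- anova_components(c(1, 2, 3, 4, 5, 6), rep(c("A", "B"), each = 3))
  expect_equal(comp$ms_between, 13.5)
  expect_equal(comp$ms_within, 1)
  expect_equal(comp$n0, 3)
  expect_equal(comp$sigma2_b, 25 / 6)
  expect_equal(comp$sigma2_w, 1)

  # identical groups: between component truncates to zero
  comp0 <- anova_components(c(1, 2, 3, 1, 2, 3), rep(c("A", "B"), each = 3))
  expect_equal(comp0$sigma2_b, 0)

  # balanced designs: n0 equals the common group size
  set.seed(8)
  compb <- anova_components(rnorm(40), rep(letters[1:4], each = 10))
  expect_equal(compb$n0, 10)
  # unbalanced: n0 between min and max group size
  compu <- anova_components(rnorm(30), rep(letters[1:3], c(5, 10, 15)))
  expect_gt(compu$n0, 5)
  expect_lt(compu$n0, 15)

  expect_error(anova_components(c(1, 2, 3), c("A", "A", "B")), "B")
  expect_error(
    anova_components(c(1, 1, 2, 2), rep(c("A", "B"), each = 2)),
    "Zero within-group"
  )
})

test_that("the P_ST formula obeys its closed-form identities", {
  expect_equal(pst_value(2, 1, c = 1, h2 = 0.5), 2 / 3)
  expect_equal(pst_value(0, 5, c = 1, h2 = 0.5), 0)
  # sigma2_b = sigma2_w and c = h2 cancel to 1/3 for any shared value
  for (v in c(0.25, 0.5, 1)) {
    expect_equal(pst_value(3, 3, c = v, h2 = v), 1 / 3)
  }
  # scale invariance: multiplying the trait scales both components by s^2
  set.seed(1)
  for (i in 1:20) {
    s2b <- runif(1, 0, 5); s2w <- runif(1, 0.1, 5); s <- runif(1, 0.1, 10)
    expect_equal(pst_value(s2b, s2w), pst_value(s^2 * s2b, s^2 * s2w))
  }
  # monotone in c, antitone in h2
  cs <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(pst_value(1.3, 0.7, c = cs, h2 = 0.5)) > 0))
  h2s <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(pst_value(1.3, 0.7, c = 1, h2 = h2s)) < 0))

  expect_error(pst_value(1, 1, c = 0), "positive")
  expect_error(pst_value(1, 1, h2 = 1.5), "h2")
})

test_that("pairwise P_ST detects saturation and null divergence", {
  # null: no between-population variance
  simn <- simulate_traits(sim_config(n_per_pop = 30, n_traits = 6,
                                     sigma2_b = 0, sigma2_w = 1, seed = 13))
  pn <- pairwise_pst(simn$traits)
  # two-group between-MS has 1 df, so isolated cells can spike; the bulk
  # must sit at zero
  expect_lt(median(pn$pst), 0.05)
  expect_gt(mean(pn$pst < 0.1), 0.9)

  # saturation: two populations 10 SD apart
  tr <- tibble::tibble(
    population = rep(c("A", "B"), each = 20),
    y = c(rnorm(20, 0, 1), rnorm(20, 10, 1))
  )
  ps <- pairwise_pst(tr)
  expect_gt(ps$pst, 0.9)
})

test_that("mean estimated P_ST matches an exact chi-square sampling oracle", {
  # With k groups of n, MS_between ~ (s2w + n0 s2b) * chisq(k-1)/(k-1) and
  # MS_within ~ s2w * chisq(N-k)/(N-k); pushing those draws through the
  # component and P_ST formulas is an implementation-independent oracle for
  # E[P_ST-hat], which Jensen attenuation keeps below the plug-in truth.
  oracle_mean_pst <- function(k, n, s2b, s2w, reps = 20000, seed = 1) {
    set.seed(seed)
    msb <- (s2w + n * s2b) * stats::rchisq(reps, k - 1) / (k - 1)
    msw <- s2w * stats::rchisq(reps, k * n - k) / (k * n - k)
    sb <- pmax(0, (msb - msw) / n)
    mean(ifelse(sb == 0, 0, sb / (sb + msw)))
  }
  # NOTE: the simulator realizes sigma2_b exactly across populations, so the
  # between-MS noncentrality is fixed, not chi-square. For k = 2 the pair
  # contrast delta = b_i - b_j still varies across the 10 pairs of 5
  # populations; the matching oracle draws scaled contrasts.
  oracle_mean_pairwise_pst <- function(n_pops, n, s2b, s2w,
                                       reps = 5000, seed = 2) {
    set.seed(seed)
    out <- replicate(reps, {
      b <- rnorm(n_pops)
      b <- (b - mean(b)) / sd(b) * sqrt(s2b)
      pairs <- combn(n_pops, 2)
      deltas <- (b[pairs[1, ]] - b[pairs[2, ]])
      # two-group MSB = n * delta^2 / 2 plus within noise on group means
      msw <- s2w * stats::rchisq(ncol(pairs), 2 * n - 2) / (2 * n - 2)
      mean_noise <- stats::rnorm(ncol(pairs), 0, sqrt(2 * s2w / n))
      msb <- n * (deltas + mean_noise)^2 / 2
      sb <- pmax(0, (msb - msw) / n)
      mean(ifelse(sb == 0, 0, sb / (sb + msw)))
    })
    mean(out)
  }
  means <- vapply(1:20, function(s) {
    tr <- simulate_traits(sim_config(n_pops = 5, n_per_pop = 50,
                                     n_traits = 22, sigma2_b = 1,
                                     sigma2_w = 1, seed = 400 + s))
    mean(pairwise_pst(tr$traits)$pst)
  }, numeric(1))
  expect_equal(mean(means),
               oracle_mean_pairwise_pst(5, 50, 1, 1),
               tolerance = 0.05)
})

test_that("P_ST/F_ST ratios flag non-positive denominators", {
  pst_tbl <- tibble::tibble(
    trait = "t", pop_a = c("A", "A", "B"), pop_b = c("B", "C", "C"),
    sigma2_b = 1, sigma2_w = 1, pst = c(0.1, 0.5, 0.3)
  )
  fm <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  fm["A", "B"] <- fm["B", "A"] <- 0.1
  fm["A", "C"] <- fm["C", "A"] <- 0.1
  fm["B", "C"] <- fm["C", "B"] <- 0
  f <- pop_dist(fm, measure = "F_ST")
  class(f) <- c("fst_matrix", class(f))
  out <- pst_fst_ratio(pst_tbl, f)
  expect_equal(out$ratio[1], 1)    # pst 0.1 / fst 0.1
  expect_equal(out$ratio[2], 5)    # pst 0.5 / fst 0.1
  expect_true(is.na(out$ratio[3]) && out$undefined[3])

  bad <- dplyr::mutate(pst_tbl, pop_b = c("B", "C", "Z"))
  expect_error(pst_fst_ratio(bad, f), "absent")
})

test_that("critical c solves P_ST(c) = F_ST exactly", {
  expect_equal(critical_c(1, 1, fst = 0.5, h2 = 1), 2)
  expect_equal(pst_value(1, 1, c = 2, h2 = 1), 0.5)
  expect_equal(critical_c(4, 1, fst = 0.2, h2 = 1), 0.125)
  # limit: c_crit -> 0 as fst -> 0
  expect_lt(critical_c(1, 1, fst = 1e-9, h2 = 1), 1e-8)

  set.seed(5)
  for (i in 1:25) {
    s2b <- runif(1, 0.05, 4); s2w <- runif(1, 0.05, 4)
    fst <- runif(1, 0.01, 0.95); h2 <- runif(1, 0.05, 1)
    cc <- critical_c(s2b, s2w, fst, h2)
    expect_equal(pst_value(s2b, s2w, c = cc, h2 = h2), fst,
                 tolerance = 1e-12)
  }
  expect_error(critical_c(0, 1, 0.1), "no between-population variance")
})

test_that("the exceedance fraction is nonincreasing in heritability", {
  # divergent-selection fixture: between variance far above the neutral
  # expectation sigma2_w * F/(1-F) ~ 0.14, so even close population pairs
  # separate
  sim <- simulate_study(sim_config(n_snps = 600, n_per_pop = 16,
                                   n_traits = 22, sigma2_b = 25,
                                   sigma2_w = 1, target_f = 0.124,
                                   seed = 19))
  f <- fst_matrix(sim$genotypes)
  p <- pairwise_pst(sim$traits)
  sens <- h2_sensitivity(p, f, c(0.25, 0.5, 0.75, 1))
  expect_equal(nrow(sens), 4)
  expect_true(all(diff(sens$frac_exceed) <= 0))
  # strongly divergent traits exceed F_ST at every heritability
  expect_gt(min(sens$frac_exceed), 0.9)

  # no between-population variance: nothing exceeds
  sim0 <- simulate_traits(sim_config(n_per_pop = 16, n_traits = 4,
                                     sigma2_b = 0, seed = 23))
  p0 <- pairwise_pst(sim0$traits)
  sens0 <- h2_sensitivity(p0, f, c(0.5, 1))
  expect_true(all(sens0$frac_exceed < 0.2))
})

test_that("Welch comparison of P_ST and F_ST matches hand arithmetic", {
  pst_tbl <- tibble::tibble(
    trait = "t", pop_a = "A", pop_b = "B",
    sigma2_b = 1, sigma2_w = 1, pst = c(0.2, 0.4, 0.6)
  )
  fm <- random_dist(3, labels = c("A", "B", "C"), seed = 1)
  fm[lower.tri(fm)] <- c(0.1, 0.2, 0.3)
  fm <- fm * 0
  fm[lower.tri(fm)] <- c(0.1, 0.2, 0.3)
  fm <- fm + t(fm)
  f <- pop_dist(fm, measure = "F_ST")
  class(f) <- c("fst_matrix", class(f))

  out <- pst_vs_fst_test(pst_tbl, f)
  # hand Welch: means 0.4 / 0.2, variances 0.04 / 0.01, n = 3 each
  se <- sqrt(0.04 / 3 + 0.01 / 3)
  t_hand <- (0.4 - 0.2) / se
  df_hand <- (0.04 / 3 + 0.01 / 3)^2 /
    ((0.04 / 3)^2 / 2 + (0.01 / 3)^2 / 2)
  expect_equal(out$t, t_hand, tolerance = 1e-12)
  expect_equal(out$df, df_hand, tolerance = 1e-12)

  # identical samples: t = 0, two-sided p = 1
  pst_eq <- dplyr::mutate(pst_tbl, pst = c(0.1, 0.2, 0.3))
  out_eq <- pst_vs_fst_test(pst_eq, f)
  expect_equal(out_eq$t, 0)
  expect_equal(out_eq$p_two_sided, 1)

  # separated samples are extremely significant
  pst_hi <- dplyr::mutate(pst_tbl, pst = c(0.9, 0.91, 0.9))
  expect_lt(pst_vs_fst_test(pst_hi, f)$p_greater, 0.01)

  # pooled mode returns a single study-level row
  pooled <- pst_vs_fst_test(pst_tbl, f, pooled = TRUE)
  expect_equal(nrow(pooled), 1)
  expect_equal(pooled$trait, "(all)")
})
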