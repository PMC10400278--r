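test_that("coordinate strings parse under the decimal-fraction dialect", {
  # minutes above 59 only make sense as a decimal fraction written in pairs
  expect_equal(parse_coordinate("24°90′30″ N"), 24.9030)
  expect_equal(parse_coordinate("0°00′00″ N"), 0)
  expect_equal(parse_coordinate("99°03′15″ E"), 99.0315)
  expect_equal(parse_coordinate("12°30′00″ S"), -12.30)
  expect_equal(parse_coordinate("45°05′05″ W"), -45.0505)
  expect_error(parse_coordinate("not a coordinate"), "Cannot parse")
})

test_that("great-circle distances agree with a law-of-cosines oracle", {
  sites <- tibble::tibble(
    population = c("A", "B"),
    longitude = c(10, 10), latitude = c(20, 20)
  )
  expect_equal(as.matrix(geo_distance_matrix(sites))["A", "B"], 0)

  anti <- tibble::tibble(
    population = c("A", "B"),
    longitude = c(0, 180), latitude = c(0, 0)
  )
  expect_equal(as.matrix(geo_distance_matrix(anti))["A", "B"],
               pi * 6371, tolerance = 1e-6)

  ref <- reference_sites()
  d <- geo_distance_matrix(ref)
  # independent great-circle formula (spherical law of cosines)
  slc <- function(lon1, lat1, lon2, lat2) {
    to_rad <- pi / 180
    6371 * acos(pmin(1,
      sin(lat1 * to_rad) * sin(lat2 * to_rad) +
        cos(lat1 * to_rad) * cos(lat2 * to_rad) *
          cos((lon2 - lon1) * to_rad)
    ))
  }
  dq <- ref[ref$population == "DQ", ]
  als <- ref[ref$population == "ALS", ]
  expect_equal(
    as.matrix(d)["DQ", "ALS"],
    slc(dq$longitude, dq$latitude, als$longitude, als$latitude),
    tolerance = 0.1 / 400
  )

  # triangle inequality on random triples
  set.seed(14)
  rnd <- tibble::tibble(
    population = paste0("S", 1:6),
    longitude = runif(6, -170, 170), latitude = runif(6, -80, 80)
  )
  m <- as.matrix(geo_distance_matrix(rnd))
  for (tri in combn(6, 3, simplify = FALSE)) {
    i <- tri[1]; j <- tri[2]; k <- tri[3]
    expect_lte(m[i, j], m[i, k] + m[k, j] + 1e-9)
  }
})

test_that("scalar distances are absolute differences", {
  ref <- reference_sites()
  d <- scalar_distance_matrix(ref, "altitude")
  expect_equal(as.matrix(d)["DQ", "ALS"], 3459 - 2183)
  m <- as.matrix(d)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 5))
  expect_error(
    scalar_distance_matrix(dplyr::mutate(ref, altitude = NA), "altitude"),
    "Missing values"
  )
})

test_that("Pearson climate distances match the direct formula", {
  # identical profiles -> 0; opposite-direction profiles -> 2
  set.seed(41)
  prof <- rnorm(19)
  other <- rnorm(19)
  bc2 <- tibble::tibble(population = c("A", "B", "C"))
  for (i in 1:19) bc2[[paste0("bio", i)]] <- c(prof[i], prof[i], other[i])
  d <- pearson_distance_matrix(bc2, "all")
  expect_equal(as.matrix(d)["A", "B"], 0, tolerance = 1e-12)

  set.seed(6)
  bc <- tibble::tibble(population = paste0("S", 1:5))
  for (i in 1:19) bc[[paste0("bio", i)]] <- rnorm(5, mean = i, sd = i / 2)
  d_all <- pearson_distance_matrix(bc, "all")
  z <- scale(as.matrix(bc[, paste0("bio", 1:19)]))
  rownames(z) <- bc$population
  brute <- 1 - cor(t(z))
  expect_equal(as.matrix(d_all), brute[labels(d_all), labels(d_all)],
               tolerance = 1e-12)
  expect_true(all(as.matrix(d_all) >= 0 & as.matrix(d_all) <= 2))

  # temperature subset uses bio1-11 only
  d_temp <- pearson_distance_matrix(bc, "temperature")
  z_t <- scale(as.matrix(bc[, paste0("bio", 1:11)]))
  expect_equal(as.matrix(d_temp)["S1", "S2"],
               1 - cor(z_t[1, ], z_t[2, ]), tolerance = 1e-12)

  bc_flat <- dplyr::mutate(bc, bio3 = 1)
  expect_error(pearson_distance_matrix(bc_flat, "all"), "Zero variance")
})

test_that("diversity-environment correlations reproduce the published table", {
  out <- diversity_env_correlation(reference_diversity(), reference_sites())
  cell <- function(i, v) out[out$index == i & out$variable == v, ]
  expect_equal(round(cell("he", "temperature")$r2, 3), 0.842)
  expect_equal(round(cell("he", "altitude")$r2, 3), 0.576)
  expect_equal(round(cell("ho", "temperature")$r2, 3), 0.708)
  expect_equal(round(cell("nei", "altitude")$r2, 3), 0.566)
  # n = 5 populations -> t with 3 df
  expect_true(all(out$n == 5))
  expect_lt(cell("he", "temperature")$p_value, 0.05)
  expect_gt(cell("he", "altitude")$p_value, 0.05)

  # exact linear relation gives r2 = 1
  div_lin <- tibble::tibble(population = paste0("P", 1:4),
                            idx = c(1, 2, 3, 4))
  sites_lin <- tibble::tibble(
    population = paste0("P", 1:4),
    altitude = c(10, 20, 30, 40), temperature = c(4, 3, 2, 1),
    latitude = c(1, 5, 2, 8)
  )
  out_lin <- diversity_env_correlation(div_lin, sites_lin)
  expect_equal(out_lin$r2[out_lin$variable == "altitude"], 1)

  # affine invariance: km vs m altitude changes nothing
  sites_km <- dplyr::mutate(reference_sites(), altitude = altitude / 1000)
  out_km <- diversity_env_correlation(reference_diversity(), sites_km)
  expect_equal(out_km$r2, out$r2, tolerance = 1e-12)
})

test_that("trait ANOVA with LSD letters matches a hand-computed fixture", {
  tr <- tibble::tibble(
    population = rep(c("A", "B", "C"), each = 3),
    y = c(1, 2, 3, 4, 5, 6, 10, 11, 12)
  )
  res <- trait_anova_lsd(tr)
  # hand ANOVA: group means 2, 5, 11; grand 6; SSB = 3*(16+1+25) = 126
  # SSW = 6 (each group var 1, 2 df); MSB = 63, MSW = 1, F = 63
  expect_equal(res$tests$statistic, 63, tolerance = 1e-12)
  expect_equal(res$tests$df_between, 2)
  expect_equal(res$tests$df_within, 6)
  expect_equal(res$tests$p_value, pf(63, 2, 6, lower.tail = FALSE),
               tolerance = 1e-12)
  # LSD: all pairwise |t| = diff / sqrt(1 * (1/3 + 1/3)) with 6 df;
  # smallest diff 3 -> t = 3.67 -> p < .05, so all groups differ
  lt <- res$letters$letter
  expect_equal(length(unique(lt)), 3)

  # identical distributions share a letter
  tr_same <- tibble::tibble(
    population = rep(c("A", "B"), each = 4),
    y = rep(c(1, 2, 3, 4), 2)
  )
  res_same <- trait_anova_lsd(tr_same)
  expect_equal(res_same$letters$letter, c("a", "a"))

  # a 10-SD-shifted group earns its own letter
  set.seed(10)
  tr_shift <- tibble::tibble(
    population = rep(c("A", "B", "C"), each = 10),
    y = c(rnorm(10), rnorm(10), rnorm(10, 10))
  )
  res_shift <- trait_anova_lsd(tr_shift)
  lets <- setNames(res_shift$letters$letter, res_shift$letters$population)
  expect_true(lets["C"] != lets["A"])
  expect_true(lets["C"] != lets["B"])
})

test_that("LSD letters agree with the pairwise significance graph", {
  set.seed(33)
  for (rep in 1:5) {
    k <- sample(3:6, 1)
    tr <- tibble::tibble(
      population = rep(LETTERS[1:k], each = 8),
      y = unlist(lapply(seq_len(k), function(i) rnorm(8, sample(0:4, 1))))
    )
    res <- trait_anova_lsd(tr)
    lets <- setNames(res$letters$letter, res$letters$population)
    # recompute pairwise LSD decisions directly
    fit <- aov(y ~ population, data = tr)
    msw <- anova(fit)[["Mean Sq"]][2]
    dfw <- anova(fit)[["Df"]][2]
    means <- tapply(tr$y, tr$population, mean)
    for (pair in combn(names(means), 2, simplify = FALSE)) {
      tval <- (means[pair[1]] - means[pair[2]]) /
        sqrt(msw * (1 / 8 + 1 / 8))
      sig <- 2 * pt(-abs(tval), dfw) < 0.05
      share <- any(strsplit(lets[pair[1]], "")[[1]] %in%
                     strsplit(lets[pair[2]], "")[[1]])
      expect_equal(!share, unname(sig))
    }
  }
})
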