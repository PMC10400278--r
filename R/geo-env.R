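#' Parse a printed coordinate string to decimal degrees
#'
#' Site coordinates in regional field studies are often printed as
#' `D°MM'SS"` strings whose "minutes" and "seconds" are really the decimal
#' fraction written in pairs of digits (values above 59 give the dialect
#' away, e.g. `24°90'30"`). This parser therefore reads `D°ab'cd"` as the
#' decimal number `D.abcd`, with the sign taken from the hemisphere letter
#' (S and W negative).
#'
#' @param text Coordinate string(s), e.g. `"28°35'14\" N"`. The prime and
#'   double-prime may be typographic or ASCII.
#' @return Decimal degrees, same length as `text`.
#' @examples
#' parse_coordinate("24°90′30″ N")
#' @export
parse_coordinate <- function(text) {
  vapply(text, function(s) {
    s0 <- trimws(s)
    pat <- paste0(
      "^(\\d+)°(\\d+)[′’']+(\\d+)[″”\"]*\\s*([NSEW])$"
    )
    m <- regmatches(s0, regexec(pat, s0, perl = TRUE))[[1]]
    if (length(m) == 0) abort(sprintf("Cannot parse coordinate '%s'.", s))
    deg <- as.numeric(m[2])
    frac <- as.numeric(paste0("0.", sprintf("%02d", as.numeric(m[3])),
                              sprintf("%02d", as.numeric(m[4]))))
    sign <- if (m[5] %in% c("S", "W")) -1 else 1
    sign * (deg + frac)
  }, numeric(1), USE.NAMES = FALSE)
}

check_sites <- function(sites, cols) {
  sites <- as_tibble(sites)
  need <- c("population", cols)
  miss <- setdiff(need, names(sites))
  if (length(miss) > 0) {
    abort(sprintf("Site table is missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  for (cl in cols) {
    if (anyNA(sites[[cl]])) abort(sprintf("Missing values in site column '%s'.", cl))
  }
  arrange(sites, .data$population)
}

#' Great-circle distance matrix between sites (km)
#'
#' Haversine distances on a sphere of radius 6371 km between the sites'
#' longitude/latitude.
#'
#' @param sites Data frame with columns `population`, `longitude`,
#'   `latitude` (decimal degrees).
#' @return A [pop_dist()] in kilometres, populations in sorted label order.
#' @export
geo_distance_matrix <- function(sites) {
  sites <- check_sites(sites, c("longitude", "latitude"))
  if (any(abs(sites$latitude) > 90) || any(abs(sites$longitude) > 180)) {
    abort("Coordinates out of range: latitude in [-90, 90], longitude in [-180, 180].")
  }
  xy <- as.matrix(sites[, c("longitude", "latitude")])
  n <- nrow(xy)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    m[i, ] <- geosphere::distHaversine(xy[i, ], xy, r = 6371000) / 1000
  }
  m <- (m + t(m)) / 2
  diag(m) <- 0
  pop_dist(m, labels = sites$population, measure = "geographic (km)")
}

#' Absolute-difference distance matrix for a scalar site variable
#'
#' @param sites Data frame with a `population` column and the requested
#'   variable.
#' @param variable Column name, e.g. `"altitude"` or `"temperature"`.
#' @return A [pop_dist()] of `|x_i - x_j|`.
#' @export
scalar_distance_matrix <- function(sites, variable) {
  sites <- check_sites(sites, variable)
  x <- sites[[variable]]
  pop_dist(abs(outer(x, x, "-")), labels = sites$population,
           measure = paste0("|Δ ", variable, "|"))
}

#' Pearson distance between sites' climate profiles
#'
#' Each site is described by a vector of bioclimatic variables (BIO1-BIO19
#' convention: BIO1-BIO11 temperature-related, BIO12-BIO19
#' precipitation-related). Variables are z-scored across sites so scales
#' contribute equally, then the distance between two sites is
#' `1 - r` with `r` the Pearson correlation of their standardized profiles
#' (range \[0, 2\]).
#'
#' @param bioclim Data frame with a `population` column and numeric
#'   bioclim columns named `bio1` ... `bio19` (case-insensitive).
#' @param variable_set `"all"` (BIO1-19), `"temperature"` (BIO1-11) or
#'   `"precipitation"` (BIO12-19).
#' @return A [pop_dist()].
#' @export
pearson_distance_matrix <- function(bioclim,
                                    variable_set = c("all", "temperature",
                                                     "precipitation")) {
  variable_set <- match.arg(variable_set)
  bioclim <- as_tibble(bioclim)
  names(bioclim) <- tolower(names(bioclim))
  bioclim <- check_sites(
    bioclim,
    paste0("bio", switch(variable_set,
      all = 1:19, temperature = 1:11, precipitation = 12:19
    ))
  )
  cols <- paste0("bio", switch(variable_set,
    all = 1:19, temperature = 1:11, precipitation = 12:19
  ))
  x <- as.matrix(bioclim[, cols])
  sdev <- apply(x, 2, sd)
  if (any(sdev == 0)) {
    abort(sprintf("Zero variance across sites in: %s",
                  paste(cols[sdev == 0], collapse = ", ")))
  }
  z <- scale(x)
  if (ncol(z) < 2) abort("Need at least two climate variables.")
  r <- cor(t(z))
  pop_dist(1 - r, labels = bioclim$population,
           measure = paste0("1 - r (", variable_set, " bioclim)"))
}

#' Correlations between diversity indices and site covariates
#'
#' For every diversity index and each of altitude, annual mean temperature
#' and latitude, the squared Pearson correlation across populations and its
#' two-sided p-value from the t distribution with n - 2 degrees of
#' freedom. Squared correlation is reported because with a handful of sites
#' the sign is fragile but the strength of association is the quantity of
#' interest; r^2 is invariant to affine rescaling of either variable (so
#' metres versus kilometres of altitude is immaterial).
#'
#' @param div A diversity table ([diversity_table()] or any data frame
#'   with a `population` column and numeric index columns).
#' @param sites Data frame with columns `population`, `altitude`,
#'   `temperature`, `latitude`.
#' @return A tibble: `index`, `variable`, `r`, `r2`, `p_value`, `n`.
#' @examples
#' diversity_env_correlation(reference_diversity(), reference_sites())
#' @export
diversity_env_correlation <- function(div, sites) {
  div <- as_tibble(div)
  sites <- check_sites(sites, c("altitude", "temperature", "latitude"))
  if (nrow(sites) < 3) abort("Need at least three populations for correlation.")
  div <- arrange(div, .data$population)
  if (!all(div$population == sites$population)) {
    abort("Diversity and site tables must describe the same populations.")
  }
  idx_cols <- setdiff(
    names(div)[vapply(div, is.numeric, logical(1))], c("n")
  )
  grid <- tidyr::expand_grid(
    index = idx_cols,
    variable = c("altitude", "temperature", "latitude")
  )
  list_rbind(pmap(grid, function(index, variable) {
    x <- div[[index]]
    y <- sites[[variable]]
    if (sd(x) == 0 || sd(y) == 0) {
      abort(sprintf("Constant column: cannot correlate %s with %s.",
                    index, variable))
    }
    ct <- cor.test(x, y)
    tibble(
      index = index, variable = variable,
      r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
      p_value = ct$p.value, n = length(x)
    )
  }))
}

#' Per-trait one-way ANOVA with LSD post-hoc letters
#'
#' Classic group-difference screen for morphometric tables: per trait a
#' one-way ANOVA over populations, then Fisher's least-significant-
#' difference pairwise t-tests on the pooled within mean square (N - k
#' degrees of freedom, deliberately uncorrected — that is what LSD means)
#' summarised as a compact letter display at `alpha`: populations sharing
#' no letter differ significantly.
#'
#' @param traits Data frame with a `population` column and numeric trait
#'   columns.
#' @param alpha Significance level for the letter display (default 0.05).
#' @return A list of class `trait_anova` with elements `tests` (tibble:
#'   trait, df_between, df_within, statistic, p_value) and `letters`
#'   (tibble: trait, population, mean, letter).
#' @export
trait_anova_lsd <- function(traits, alpha = 0.05) {
  traits <- as_tibble(traits)
  if (!"population" %in% names(traits)) {
    abort("`traits` must contain a `population` column.")
  }
  trait_names <- names(traits)[vapply(traits, is.numeric, logical(1))]
  tests <- list()
  letters_tbl <- list()
  for (tr in trait_names) {
    keep <- !is.na(traits[[tr]])
    y <- traits[[tr]][keep]
    gp <- factor(traits$population[keep])
    if (nlevels(gp) < 2 || any(table(gp) < 2)) {
      abort(sprintf("Trait '%s': need >= 2 groups with >= 2 values each.", tr))
    }
    fit <- aov(y ~ gp)
    at <- anova(fit)
    msw <- at[["Mean Sq"]][2]
    dfw <- at[["Df"]][2]
    tests[[tr]] <- tibble(
      trait = tr, df_between = at[["Df"]][1], df_within = dfw,
      statistic = at[["F value"]][1], p_value = at[["Pr(>F)"]][1]
    )
    ni <- table(gp)
    means <- tapply(y, gp, mean)
    pops <- names(means)
    npop <- length(pops)
    differs <- matrix(FALSE, npop, npop, dimnames = list(pops, pops))
    for (pair in combn(pops, 2, simplify = FALSE)) {
      se <- sqrt(msw * (1 / ni[pair[1]] + 1 / ni[pair[2]]))
      tval <- (means[pair[1]] - means[pair[2]]) / se
      p <- 2 * pt(-abs(tval), dfw)
      differs[pair[1], pair[2]] <- differs[pair[2], pair[1]] <- p < alpha
    }
    letters_tbl[[tr]] <- tibble(
      trait = tr, population = pops, mean = as.numeric(means),
      letter = unname(compact_letters(differs))
    )
  }
  structure(
    list(tests = list_rbind(tests), letters = list_rbind(letters_tbl),
         alpha = alpha),
    class = "trait_anova"
  )
}

# Insert-and-absorb compact letter display from a logical "significantly
# different" matrix. Groups sharing a letter are not significantly different.
compact_letters <- function(differs) {
  pops <- rownames(differs)
  # letter sets: list of character vectors (members of each letter class)
  sets <- list(pops)
  for (pair in combn(pops, 2, simplify = FALSE)) {
    if (!differs[pair[1], pair[2]]) next
    for (si in seq_along(sets)) {
      s <- sets[[si]]
      if (all(pair %in% s)) {
        # split this set: duplicate without each offender
        sets[[si]] <- setdiff(s, pair[1])
        sets <- c(sets, list(setdiff(s, pair[2])))
      }
    }
    # absorb sets contained in others
    keep <- rep(TRUE, length(sets))
    for (i in seq_along(sets)) {
      for (j in seq_along(sets)) {
        if (i != j && keep[j] && all(sets[[i]] %in% sets[[j]]) &&
            (length(sets[[i]]) < length(sets[[j]]) ||
             (length(sets[[i]]) == length(sets[[j]]) && i > j))) {
          keep[i] <- FALSE
        }
      }
    }
    sets <- sets[keep]
  }
  sets <- sets[order(vapply(sets, function(s) match(s[1], pops), numeric(1)))]
  out <- vapply(pops, function(p) {
    paste0(letters[which(vapply(sets, function(s) p %in% s, logical(1)))],
           collapse = "")
  }, character(1))
  out
}

#' @export
print.trait_anova <- function(x, ...) {
  cat(sprintf("<trait_anova> %d traits, alpha = %g\n",
              nrow(x$tests), x$alpha))
  print(x$tests, n = 10)
  invisible(x)
}

#' @rdname trait_anova_lsd
#' @param x A `trait_anova` object.
#' @param ... Unused.
#' @export
tidy.trait_anova <- function(x, ...) x$tests

#' Group-means plot with LSD letters
#'
#' @param object A `trait_anova` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trait_anova <- function(object, ...) {
  ggplot2::ggplot(object$letters,
                  ggplot2::aes(.data$population, .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_text(ggplot2::aes(label = .data$letter), vjust = -0.4,
                       size = 3) +
    ggplot2::facet_wrap(~trait, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "group mean") +
    ggplot2::theme_minimal()
}
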