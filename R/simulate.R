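#' Configuration for the synthetic study generator
#'
#' Defines a five-population study design with known ground truth: SNP
#' genotypes under the Balding-Nichols model at a chosen differentiation
#' level, normally distributed traits with chosen between/within variance
#' components, and a site table with a monotone altitude-temperature
#' gradient. Defaults emulate the motivating field design: 5 montane
#' populations of about 32 diploid individuals, thousands of biallelic
#' reduced-representation SNPs, 22 morphometric traits, altitudes spanning
#' 2183-3459 m against annual mean temperatures 19.7-4.7 degrees C.
#'
#' @param n_pops Number of populations (default 5).
#' @param n_per_pop Diploid individuals per population (default 32).
#' @param n_snps Number of biallelic SNPs (default 10000).
#' @param target_f Balding-Nichols differentiation parameter F in \[0, 1);
#'   default 0.124, a moderate montane-rodent level.
#' @param ancestral_maf_range Range of the uniform ancestral allele
#'   frequency (default c(0.05, 0.95)).
#' @param missing_rate Fraction of genotype calls set missing uniformly at
#'   random (default 0.05), exercising pairwise-complete estimators.
#' @param n_traits Number of traits (default 22).
#' @param sigma2_b,sigma2_w Between/within-population trait variance
#'   components, scalars or per-trait vectors (defaults 0 and 1: a
#'   drift-free null unless between variance is requested).
#' @param trait_c,trait_h2 Bookkeeping values of the additive proportion
#'   and heritability at which the generator records the implied true
#'   P_ST (defaults 1 and 0.5).
#' @param altitude_range,temperature_range Site gradient endpoints
#'   (defaults 2183-3459 m and 19.7-4.7 degrees C, temperature declining
#'   as altitude rises).
#' @param temperature_noise_sd SD of noise added to the linear
#'   altitude-temperature relation (default 0).
#' @param geo_step_km Spacing of sites along a south-north line (default
#'   120 km).
#' @param seed Integer seed; all randomness in [simulate_study()] flows
#'   from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_pops = 5, n_per_pop = 32, n_snps = 10000,
                       target_f = 0.124,
                       ancestral_maf_range = c(0.05, 0.95),
                       missing_rate = 0.05,
                       n_traits = 22, sigma2_b = 0, sigma2_w = 1,
                       trait_c = 1, trait_h2 = 0.5,
                       altitude_range = c(3459, 2183),
                       temperature_range = c(4.7, 19.7),
                       temperature_noise_sd = 0,
                       geo_step_km = 120, seed = 1) {
  if (n_pops < 2 || n_per_pop < 2 || n_snps < 1) {
    abort("Counts too small: need >= 2 populations, >= 2 individuals, >= 1 SNP.")
  }
  if (target_f < 0 || target_f >= 1) abort("`target_f` must lie in [0, 1).")
  if (any(sigma2_b < 0) || any(sigma2_w < 0)) {
    abort("Trait variance components must be non-negative.")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("`missing_rate` must lie in [0, 1).")
  }
  structure(as.list(environment()), class = "sim_config")
}

# Independent sub-seeds per component so modules can be regenerated in
# isolation without disturbing each other's streams.
split_seed <- function(seed, offset) (seed * 7919L + offset) %% .Machine$integer.max

#' Simulate SNP genotypes under the Balding-Nichols model
#'
#' Per SNP an ancestral frequency p is drawn uniformly in
#' `ancestral_maf_range`; each population's frequency is
#' `Beta(p (1-F)/F, (1-p)(1-F)/F)` (variance `F p (1-p)` around p), and
#' individual dosages are Binomial(2, p_pop): Hardy-Weinberg within
#' populations, differentiation F between them. `F = 0` degenerates to all
#' populations sharing p. SNPs are unlinked.
#'
#' @param cfg A [sim_config()].
#' @return List with `genotypes` (a [genotype_matrix()]) and `truth`
#'   (tibble of per-SNP ancestral and population frequencies plus
#'   `target_f`).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(split_seed(cfg$seed, 1L))
  pops <- pop_names(cfg$n_pops)
  p_anc <- runif(cfg$n_snps, cfg$ancestral_maf_range[1],
                 cfg$ancestral_maf_range[2])
  f <- cfg$target_f
  pop_freq <- vapply(seq_len(cfg$n_pops), function(i) {
    if (f == 0) {
      p_anc
    } else {
      rbeta(cfg$n_snps, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
    }
  }, numeric(cfg$n_snps))
  colnames(pop_freq) <- pops
  n_ind <- cfg$n_pops * cfg$n_per_pop
  dosages <- matrix(NA_integer_, n_ind, cfg$n_snps)
  row <- 0
  for (i in seq_len(cfg$n_pops)) {
    block <- matrix(
      rbinom(cfg$n_per_pop * cfg$n_snps, 2, rep(pop_freq[, i],
                                                each = cfg$n_per_pop)),
      nrow = cfg$n_per_pop
    )
    dosages[row + seq_len(cfg$n_per_pop), ] <- block
    row <- row + cfg$n_per_pop
  }
  if (cfg$missing_rate > 0) {
    drop <- runif(length(dosages)) < cfg$missing_rate
    dosages[drop] <- NA_integer_
  }
  rownames(dosages) <- paste0(rep(pops, each = cfg$n_per_pop), "_",
                              rep(seq_len(cfg$n_per_pop), cfg$n_pops))
  colnames(dosages) <- paste0("snp", seq_len(cfg$n_snps))
  truth <- as_tibble(pop_freq) |>
    mutate(snp = colnames(dosages), p_ancestral = p_anc,
           target_f = f, .before = 1)
  list(
    genotypes = genotype_matrix(
      dosages, rep(pops, each = cfg$n_per_pop)
    ),
    truth = truth
  )
}

pop_names <- function(n) sprintf("P%02d", seq_len(n))

#' Simulate quantitative traits with known variance components
#'
#' Each trait value is `mu_t + b_pop + e_ind` with population effects drawn
#' from a Normal and then centred and rescaled so their realized sample
#' variance across populations equals `sigma2_b` exactly, and residuals
#' `e_ind ~ N(0, sigma2_w)`. The rescaling makes the truth record exact:
#' with only a handful of populations, raw Normal draws would leave
#' chi-square noise of the same order as the target in the realized
#' between-population variance, and the recorded "true P_ST" —
#' `c sigma2_b / (c sigma2_b + 2 h2 sigma2_w)` at the config's
#' (`trait_c`, `trait_h2`) — would describe no particular data set. The
#' random relative configuration of the population effects is retained.
#' Trait baselines `mu_t` are arbitrary positive constants; P_ST is
#' location- and scale-invariant so they are cosmetic.
#'
#' @param cfg A [sim_config()].
#' @return List with `traits` (tibble: individual, population, trait
#'   columns t01, t02, ...) and `truth` (tibble: trait, sigma2_b,
#'   sigma2_w, true_pst, and per-population effects).
#' @export
simulate_traits <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(split_seed(cfg$seed, 2L))
  pops <- pop_names(cfg$n_pops)
  s2b <- rep_len(cfg$sigma2_b, cfg$n_traits)
  s2w <- rep_len(cfg$sigma2_w, cfg$n_traits)
  trait_names <- sprintf("t%02d", seq_len(cfg$n_traits))
  mu <- 10 + seq_len(cfg$n_traits)
  n_ind <- cfg$n_pops * cfg$n_per_pop
  values <- matrix(NA_real_, n_ind, cfg$n_traits,
                   dimnames = list(NULL, trait_names))
  b_pop <- matrix(NA_real_, cfg$n_pops, cfg$n_traits,
                  dimnames = list(pops, trait_names))
  pop_of <- rep(pops, each = cfg$n_per_pop)
  for (t in seq_len(cfg$n_traits)) {
    if (s2b[t] == 0) {
      b <- rep(0, cfg$n_pops)
    } else {
      b <- rnorm(cfg$n_pops)
      b <- (b - mean(b)) / sd(b) * sqrt(s2b[t])
    }
    b_pop[, t] <- b
    values[, t] <- mu[t] + b[match(pop_of, pops)] +
      rnorm(n_ind, 0, sqrt(s2w[t]))
  }
  traits <- as_tibble(values) |>
    mutate(
      individual = paste0(pop_of, "_", rep(seq_len(cfg$n_per_pop),
                                           cfg$n_pops)),
      population = pop_of, .before = 1
    )
  truth <- tibble(
    trait = trait_names, sigma2_b = s2b, sigma2_w = s2w,
    true_pst = pst_value(s2b, s2w, c = cfg$trait_c, h2 = cfg$trait_h2)
  )
  list(traits = traits, truth = truth,
       population_effects = as_tibble(b_pop, rownames = "population"))
}

#' Simulate a site table with an altitude-temperature gradient
#'
#' Sites sit on a south-north line `geo_step_km` apart; altitudes are
#' equally spaced over `altitude_range` and annual mean temperature is
#' linear in altitude (plus optional noise), mirroring montane sampling
#' designs where temperature declines with elevation.
#'
#' @param cfg A [sim_config()].
#' @return A tibble: `population`, `longitude`, `latitude`, `altitude`,
#'   `temperature`, `precipitation`.
#' @export
simulate_sites <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(split_seed(cfg$seed, 3L))
  pops <- pop_names(cfg$n_pops)
  altitude <- seq(cfg$altitude_range[1], cfg$altitude_range[2],
                  length.out = cfg$n_pops)
  slope <- diff(cfg$temperature_range) / diff(cfg$altitude_range)
  temperature <- cfg$temperature_range[1] +
    slope * (altitude - cfg$altitude_range[1]) +
    rnorm(cfg$n_pops, 0, cfg$temperature_noise_sd)
  lat_step <- cfg$geo_step_km / 111.2  # km per degree latitude
  tibble(
    population = pops,
    longitude = 100 + 0.1 * seq_len(cfg$n_pops),
    latitude = 28 - lat_step * (seq_len(cfg$n_pops) - 1),
    altitude = altitude,
    temperature = temperature,
    precipitation = 600 + 40 * seq_len(cfg$n_pops)
  )
}

#' Simulate a complete synthetic study
#'
#' Runs [simulate_genotypes()], [simulate_traits()] and
#' [simulate_sites()] from one seed.
#'
#' @param cfg A [sim_config()].
#' @return List with `genotypes`, `traits`, `sites`, and `truth` (list of
#'   the genotype and trait truth records).
#' @examples
#' sim <- simulate_study(sim_config(n_snps = 100, seed = 42))
#' sim$genotypes
#' @export
simulate_study <- function(cfg = sim_config()) {
  geno <- simulate_genotypes(cfg)
  tr <- simulate_traits(cfg)
  sites <- simulate_sites(cfg)
  list(
    genotypes = geno$genotypes,
    traits = tr$traits,
    sites = sites,
    truth = list(genotypes = geno$truth, traits = tr$truth,
                 population_effects = tr$population_effects,
                 config = cfg)
  )
}

#' Write a synthetic study to disk as plain-text fixtures
#'
#' Writes the genotype TSV, population map, trait TSV, site TSV and a
#' truth JSON (target F and per-trait true P_ST) into a directory; a
#' bundle re-read through [read_genotypes()] reproduces the dosage matrix
#' exactly, and equal seeds give byte-identical files.
#'
#' @param sim Result of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genotypes = file.path(dir, "genotypes.tsv"),
    popmap = file.path(dir, "popmap.tsv"),
    traits = file.path(dir, "traits.tsv"),
    sites = file.path(dir, "sites.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_genotypes(sim$genotypes, paths["genotypes"], paths["popmap"])
  readr::write_tsv(sim$traits, paths["traits"])
  readr::write_tsv(sim$sites, paths["sites"])
  jsonlite::write_json(
    list(
      target_f = sim$truth$config$target_f,
      seed = sim$truth$config$seed,
      traits = sim$truth$traits
    ),
    paths["truth"], auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}
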