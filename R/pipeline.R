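#' Analysis configuration
#'
#' Bundles every tunable parameter of [run_divergence_pipeline()] with the
#' field-standard defaults: SNPs kept at call rate >= 0.8 and pooled
#' MAF >= 0.05; P_ST evaluated at c = 1 (no environmental variance between
#' samples) and within-population heritability 0.5, with sensitivity over
#' h2 in {0.25, 0.5, 0.75, 1}; Mantel tests one-sided with 9999
#' permutations.
#'
#' @param min_presence,min_maf SNP filter thresholds (see [filter_snps()]).
#' @param c,h2 P_ST evaluation point (see [pst_value()]).
#' @param h2_grid Heritability grid for [h2_sensitivity()].
#' @param n_perm,tail Mantel permutation settings (see [mantel()]).
#' @param surveyed_bp Surveyed length for [theta_pi()]; `NULL` omits it.
#' @param seed Seed for the permutation tests.
#' @return A `divergence_config` list.
#' @export
divergence_config <- function(min_presence = 0.8, min_maf = 0.05,
                              c = 1, h2 = 0.5,
                              h2_grid = c(0.25, 0.5, 0.75, 1),
                              n_perm = 9999, tail = "greater",
                              surveyed_bp = NULL, seed = 1) {
  check_c_h2(c, h2)
  check_c_h2(1, h2_grid)
  structure(as.list(environment()), class = "divergence_config")
}

#' Run the full divergence analysis
#'
#' Executes the whole pipeline on a genotype matrix, trait table and site
#' table: SNP filtering, per-population diversity, pairwise
#' Weir-Cockerham F_ST (raw and linearized), pairwise P_ST with
#' P_ST/F_ST ratios, Welch tests, heritability sensitivity and critical
#' c, geographic/altitude/temperature (and optionally bioclim Pearson)
#' distance matrices, diversity-environment correlations, per-trait
#' ANOVA + LSD letters, and the Mantel suite of genetic distance against
#' each environmental distance.
#'
#' @param genotypes A [genotype_matrix()].
#' @param traits Trait tibble with a `population` column (optional:
#'   `NULL` runs the genetic-only stages).
#' @param sites Site tibble (`population`, `longitude`, `latitude`,
#'   `altitude`, `temperature`, ...; optional).
#' @param bioclim Optional site-by-bioclim tibble for
#'   [pearson_distance_matrix()].
#' @param config A [divergence_config()].
#' @param out_dir Optional directory: when given, every result table is
#'   also written as TSV plus a `report.json` of headline numbers.
#' @return A list of result tables (class `divergence_report`):
#'   `diversity`, `fst`, `fst_linear`, `fst_summary`, `pst`, `ratios`,
#'   `pst_fst_test`, `h2_sensitivity`, `critical_c`, `trait_anova`,
#'   `distances`, `env_correlation`, `mantel`.
#' @examples
#' sim <- simulate_study(sim_config(n_snps = 300, sigma2_b = 1, seed = 7))
#' rep <- run_divergence_pipeline(
#'   sim$genotypes, sim$traits, sim$sites,
#'   config = divergence_config(n_perm = 99)
#' )
#' rep$fst_summary
#' @export
run_divergence_pipeline <- function(genotypes, traits = NULL, sites = NULL,
                                    bioclim = NULL,
                                    config = divergence_config(),
                                    out_dir = NULL) {
  stopifnot(inherits(config, "divergence_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  out <- list(config = config)

  g <- stage("filter_snps",
             filter_snps(genotypes, config$min_presence, config$min_maf))
  inform(sprintf("SNP filter: %d of %d SNPs retained.",
                 ncol(g$dosages), ncol(genotypes$dosages)))
  out$diversity <- stage("diversity", diversity_table(g, config$surveyed_bp))
  fst <- stage("fst", fst_matrix(g))
  out$fst <- fst
  out$fst_linear <- stage("linearize_fst", linearize_fst(fst))
  out$fst_summary <- glance(fst)

  if (!is.null(traits)) {
    pst_tbl <- stage("pairwise_pst",
                     pairwise_pst(traits, c = config$c, h2 = config$h2))
    out$pst <- pst_tbl
    out$ratios <- stage("pst_fst_ratio", pst_fst_ratio(pst_tbl, fst))
    out$pst_fst_test <- stage("pst_vs_fst_test", pst_vs_fst_test(pst_tbl, fst))
    out$h2_sensitivity <- stage(
      "h2_sensitivity", h2_sensitivity(pst_tbl, fst, config$h2_grid)
    )
    out$critical_c <- stage("critical_c",
      out$ratios |>
        filter(.data$sigma2_b > 0, .data$fst > 0, .data$fst < 1) |>
        mutate(c_crit = critical_c(.data$sigma2_b, .data$sigma2_w,
                                   .data$fst, h2 = 1)) |>
        select("trait", "pop_a", "pop_b", "sigma2_b", "sigma2_w",
               "fst", "c_crit")
    )
    out$trait_anova <- stage("trait_anova_lsd", trait_anova_lsd(traits))
  }

  if (!is.null(sites)) {
    sites <- arrange(as_tibble(sites), .data$population)
    dists <- list(
      geographic = stage("geo_distance", geo_distance_matrix(sites)),
      altitude = stage("altitude_distance",
                       scalar_distance_matrix(sites, "altitude")),
      temperature = stage("temperature_distance",
                          scalar_distance_matrix(sites, "temperature"))
    )
    if (!is.null(bioclim)) {
      dists$climate <- stage("climate_distance",
                             pearson_distance_matrix(bioclim, "all"))
      dists$temperature_bioclim <- stage(
        "temperature_bioclim", pearson_distance_matrix(bioclim, "temperature")
      )
      dists$precipitation_bioclim <- stage(
        "precipitation_bioclim",
        pearson_distance_matrix(bioclim, "precipitation")
      )
    }
    out$distances <- dists
    if ("temperature" %in% names(sites) && "altitude" %in% names(sites)) {
      out$env_correlation <- stage(
        "diversity_env_correlation",
        diversity_env_correlation(
          select(out$diversity, -dplyr::any_of(c("theta_pi", "tajima_d"))),
          sites
        )
      )
    }
    gen_mats <- list(fst = fst, fst_linear = out$fst_linear)
    out$mantel <- stage("mantel_suite", list_rbind(imap(
      gen_mats,
      function(gm, gname) list_rbind(imap(dists, function(dm, dname) {
        res <- mantel(gm, dm, n_perm = config$n_perm,
                      tail = config$tail, seed = config$seed)
        mutate(tidy(res), genetic = gname, distance = dname, .before = 1)
      }))
    )))
  }

  class(out) <- "divergence_report"
  if (!is.null(out_dir)) write_report(out, out_dir)
  out
}

#' @export
print.divergence_report <- function(x, ...) {
  cat("<divergence_report> sections:",
      paste(setdiff(names(x), "config"), collapse = ", "), "\n")
  if (!is.null(x$fst_summary)) {
    cat(sprintf("F_ST: min %.3f, max %.3f, mean %.3f over %d pairs\n",
                x$fst_summary$min, x$fst_summary$max, x$fst_summary$mean,
                x$fst_summary$n_pairs))
  }
  invisible(x)
}

write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) {
    readr::write_tsv(x, file.path(dir, paste0(name, ".tsv")))
  }
  wr(report$diversity, "diversity")
  wr(as_tibble(as.matrix(report$fst), rownames = "population"), "fst_matrix")
  wr(as_tibble(as.matrix(report$fst_linear), rownames = "population"),
     "fst_linearized")
  if (!is.null(report$pst)) {
    wr(report$pst, "pst_pairwise")
    wr(report$ratios, "pst_fst_ratio")
    wr(report$pst_fst_test, "pst_fst_test")
    wr(report$h2_sensitivity, "h2_sensitivity")
    wr(report$critical_c, "critical_c")
    wr(report$trait_anova$tests, "trait_anova")
    wr(report$trait_anova$letters, "trait_anova_letters")
  }
  if (!is.null(report$env_correlation)) wr(report$env_correlation,
                                           "env_correlations")
  if (!is.null(report$mantel)) wr(report$mantel, "mantel_results")
  headline <- list(
    fst = as.list(report$fst_summary),
    pst = if (!is.null(report$pst)) {
      list(mean = mean(report$pst$pst), median = median(report$pst$pst))
    },
    mantel = if (!is.null(report$mantel)) report$mantel
  )
  jsonlite::write_json(headline, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Reproduce the reference study's diversity-environment worked example
#'
#' Recomputes the 18 squared Pearson correlations (6 diversity indices x
#' altitude/temperature/latitude) from the packaged per-population index
#' values and site covariates, and compares them with the published
#' values. Cells published from indices printed at too coarse a precision
#' (the nucleotide-diversity row, 3 significant figures) cannot round-trip
#' exactly and are flagged by `reproducible`.
#'
#' @param tolerance Absolute difference (after rounding to 3 decimals)
#'   within which a cell counts as matched (default 0.002).
#' @return A tibble: `index`, `variable`, `r2`, `p_value`,
#'   `r2_published`, `significant`, `matches`, `sig_matches`,
#'   `reproducible`.
#' @examples
#' ex <- run_reference_example()
#' sum(ex$matches[ex$reproducible])
#' @export
run_reference_example <- function(tolerance = 0.002) {
  div <- reference_diversity()
  sites <- reference_sites()
  computed <- diversity_env_correlation(div, sites)
  published <- reference_env_r2()
  out <- left_join(computed, published, by = c("index", "variable"))
  mutate(out,
    matches = abs(round(.data$r2, 3) - .data$r2_published) <= tolerance + 1e-9,
    sig_matches = (.data$p_value < 0.05) == .data$significant,
    reproducible = .data$index != "theta_pi"
  )
}
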