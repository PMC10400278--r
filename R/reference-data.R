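#' Published site records for the five montane vole populations
#'
#' Sampling-site covariates for the five *Eothenomys miletus* populations
#' in the Hengduan Mountains whose published diversity summaries ship with
#' the package: coordinates (printed strings and their decimal-degree
#' parse), altitude (m), annual mean temperature (degrees C) and annual
#' precipitation (mm). These drive the worked example in
#' [run_reference_example()].
#'
#' @return A tibble with columns `population` (region code), `site_name`,
#'   `n`, `longitude`, `latitude`, `altitude`, `temperature`,
#'   `precipitation`.
#' @examples
#' reference_sites()
#' @export
reference_sites <- function() {
  path <- system.file("extdata", "miletus_sites.tsv", package = "pstfst")
  raw <- readr::read_tsv(path, col_types = readr::cols(
    population = "c", region = "c", n = "i", longitude_text = "c",
    latitude_text = "c", altitude = "d", temperature = "d",
    precipitation = "d"
  ))
  tibble(
    population = raw$region,
    site_name = raw$population,
    n = raw$n,
    longitude = parse_coordinate(raw$longitude_text),
    latitude = parse_coordinate(raw$latitude_text),
    altitude = raw$altitude,
    temperature = raw$temperature,
    precipitation = raw$precipitation
  )
}

#' Published per-population diversity indices for the reference study
#'
#' Six genetic diversity indices (nucleotide diversity, Tajima's D,
#' observed and expected heterozygosity, Nei gene diversity, PIC) for the
#' five populations of [reference_sites()], as printed in the source
#' study's summary table.
#'
#' @return A tibble with one row per population, columns `population`,
#'   `theta_pi`, `tajima_d`, `ho`, `he`, `nei`, `pic`.
#' @export
reference_diversity <- function() {
  path <- system.file("extdata", "miletus_diversity.tsv", package = "pstfst")
  raw <- readr::read_tsv(path, col_types = readr::cols(index = "c",
                                                       .default = "d"))
  long <- tidyr::pivot_longer(raw, -"index", names_to = "population")
  tidyr::pivot_wider(long, names_from = "index") |>
    arrange(.data$population)
}

#' Published diversity-environment r-squared values for the reference study
#'
#' The squared Pearson correlations (and their significance flags at
#' p = 0.05) between each diversity index and altitude, annual mean
#' temperature and latitude, as printed in the source study. Used to
#' validate [run_reference_example()].
#'
#' @return A tibble: `index`, `variable`, `r2_published`, `significant`.
#' @export
reference_env_r2 <- function() {
  path <- system.file("extdata", "miletus_diversity_env_r2.tsv",
                      package = "pstfst")
  raw <- readr::read_tsv(path, col_types = readr::cols(
    index = "c", altitude_r2 = "d", altitude_sig = "c",
    temperature_r2 = "d", temperature_sig = "c",
    latitude_r2 = "d", latitude_sig = "c"
  ))
  list_rbind(map(c("altitude", "temperature", "latitude"), function(v) {
    tibble(
      index = raw$index, variable = v,
      r2_published = raw[[paste0(v, "_r2")]],
      significant = raw[[paste0(v, "_sig")]] == "sig"
    )
  }))
}
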