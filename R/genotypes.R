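#' Genotype matrix with population labels
#'
#' Constructs the container used by every genetic estimator in the package:
#' an individuals-by-SNPs matrix of allele dosages (0, 1, 2 copies of the
#' alternate allele; `NA` for a missing call) together with a population
#' label per individual. Estimators treat missing calls as pairwise-complete
#' and never impute.
#'
#' @param dosages Integer matrix, individuals in rows, SNPs in columns.
#'   Entries must be 0, 1, 2 or `NA`. Row names are individual ids, column
#'   names SNP ids (generated when absent).
#' @param populations Character vector of population labels, one per row of
#'   `dosages`, or a named vector keyed by individual id.
#' @return An object of class `geno_mat`.
#' @examples
#' g <- genotype_matrix(rbind(a = c(0, 1), b = c(2, NA)), c(a = "P1", b = "P2"))
#' g
#' @export
genotype_matrix <- function(dosages, populations) {
  dosages <- as.matrix(dosages)
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- paste0("ind", seq_len(nrow(dosages)))
  }
  if (is.null(colnames(dosages))) {
    colnames(dosages) <- paste0("snp", seq_len(ncol(dosages)))
  }
  if (anyDuplicated(colnames(dosages))) {
    abort("SNP ids must be unique.")
  }
  bad <- !is.na(dosages) & !dosages %in% c(0L, 1L, 2L)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "Invalid dosage at individual '%s', SNP '%s': dosages must be 0, 1, 2 or NA.",
      rownames(dosages)[idx[1]], colnames(dosages)[idx[2]]
    ))
  }
  storage.mode(dosages) <- "integer"
  if (!is.null(names(populations))) {
    missing_pop <- setdiff(rownames(dosages), names(populations))
    if (length(missing_pop) > 0) {
      abort(sprintf(
        "No population label for individual(s): %s",
        paste(missing_pop, collapse = ", ")
      ))
    }
    populations <- populations[rownames(dosages)]
  } else if (length(populations) != nrow(dosages)) {
    abort("`populations` must have one label per individual.")
  }
  populations <- as.character(populations)
  if (anyNA(populations)) abort("Every individual needs a population label.")
  names(populations) <- rownames(dosages)
  structure(
    list(dosages = dosages, populations = populations),
    class = "geno_mat"
  )
}

#' @export
print.geno_mat <- function(x, ...) {
  pops <- table(x$populations)
  cat(sprintf(
    "<geno_mat> %d individuals x %d SNPs (%.1f%% missing)\n",
    nrow(x$dosages), ncol(x$dosages),
    100 * mean(is.na(x$dosages))
  ))
  cat("populations:",
      paste(sprintf("%s (n=%d)", names(pops), pops), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.geno_mat <- function(x) dim(x$dosages)

#' Population labels of a genotype matrix
#' @param g A [genotype_matrix()].
#' @return Character vector of distinct population labels, sorted.
#' @export
populations <- function(g) sort(unique(g$populations))

#' Subset a genotype matrix to one population
#' @param g A [genotype_matrix()].
#' @param pop Population label.
#' @return Integer dosage matrix for that population's individuals.
#' @keywords internal
pop_dosages <- function(g, pop) {
  keep <- g$populations == pop
  if (!any(keep)) abort(sprintf("Unknown population '%s'.", pop))
  g$dosages[keep, , drop = FALSE]
}

#' Long-format view of a genotype matrix
#'
#' @param x A [genotype_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `individual`, `population`, `snp`, `dosage`.
#' @export
tidy.geno_mat <- function(x, ...) {
  tibble(
    individual = rep(rownames(x$dosages), times = ncol(x$dosages)),
    population = rep(unname(x$populations), times = ncol(x$dosages)),
    snp = rep(colnames(x$dosages), each = nrow(x$dosages)),
    dosage = as.integer(x$dosages)
  )
}

#' Read a genotype matrix from TSV or VCF
#'
#' The TSV dialect is: header row of SNP ids, first column the individual id,
#' remaining cells allele dosages 0/1/2 or `NA`. VCF input (4.x, `GT` field)
#' is converted to alternate-allele dosage; half-calls and missing genotypes
#' become `NA`; records with more than one alternate allele are skipped with
#' a message reporting the count.
#'
#' @param path Path to the genotype TSV or VCF (may be bgzipped for VCF).
#' @param popmap_path Path to a two-column TSV (individual id, population
#'   label) with a header. Individuals present in the genotype file but
#'   absent from the population map are an error.
#' @param format `"tsv"` or `"vcf"`; guessed from the file extension by
#'   default.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, popmap_path,
                           format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (!file.exists(path)) abort(sprintf("Genotype file not found: %s", path))
  popmap <- read_popmap(popmap_path)
  dosages <- switch(format,
    tsv = read_genotype_tsv(path),
    vcf = read_genotype_vcf(path)
  )
  unmapped <- setdiff(rownames(dosages), names(popmap))
  if (length(unmapped) > 0) {
    abort(sprintf(
      "Individual(s) missing from population map: %s",
      paste(unmapped, collapse = ", ")
    ))
  }
  genotype_matrix(dosages, popmap[rownames(dosages)])
}

read_popmap <- function(path) {
  if (!file.exists(path)) abort(sprintf("Population map not found: %s", path))
  pm <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  if (ncol(pm) < 2) abort("Population map needs two columns: individual, population.")
  setNames(as.character(pm[[2]]), as.character(pm[[1]]))
}

read_genotype_tsv <- function(path) {
  tab <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = "c"),
    na = c("NA", "")
  )
  ids <- as.character(tab[[1]])
  cells <- as.matrix(tab[, -1, drop = FALSE])
  parsed <- suppressWarnings(matrix(
    as.integer(cells),
    nrow = nrow(cells),
    dimnames = list(ids, colnames(cells))
  ))
  bad <- which(is.na(parsed) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "Malformed genotype cell '%s' at row '%s', column '%s' in %s.",
      cells[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
      colnames(cells)[bad[1, 2]], path
    ))
  }
  parsed
}

read_genotype_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(vcf)
  multi <- grepl(",", alt) | is.na(alt) | alt == "."
  if (any(multi)) {
    inform(sprintf(
      "Skipped %d non-biallelic VCF record(s).", sum(multi)
    ))
    vcf <- vcf[!multi, ]
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ids <- vcfR::getID(vcf)
  if (is.null(ids) || anyNA(ids) || anyDuplicated(ids)) {
    ids <- paste(vcfR::getCHROM(vcf), vcfR::getPOS(vcf), sep = "_")
  }
  dos <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt),
                dimnames = list(colnames(gt), ids))
  for (j in seq_len(nrow(gt))) {
    v <- gt[j, ]
    d <- rep(NA_integer_, length(v))
    ok <- !is.na(v) & grepl("^[0-9]+[|/][0-9]+$", v)
    parts <- strsplit(v[ok], "[|/]")
    d[ok] <- vapply(parts, function(p) sum(p == "1"), integer(1))
    dos[, j] <- d
  }
  dos
}

#' Write a genotype matrix (and population map) as TSV
#'
#' Inverse of [read_genotypes()]'s TSV dialect: a round trip reproduces the
#' dosage matrix exactly.
#'
#' @param g A [genotype_matrix()].
#' @param path Output path for the genotype TSV.
#' @param popmap_path Optional output path for the population map TSV.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, popmap_path = NULL) {
  tab <- as_tibble(g$dosages, rownames = "individual")
  readr::write_tsv(tab, path, na = "NA")
  if (!is.null(popmap_path)) {
    readr::write_tsv(
      tibble(individual = rownames(g$dosages),
             population = unname(g$populations)),
      popmap_path
    )
  }
  invisible(path)
}

#' Filter SNPs on call rate and minor allele frequency
#'
#' Mirrors the reduced-representation SNP panel filter used in wild-population
#' studies: a SNP is kept when its call rate over all individuals is at least
#' `min_presence` and its pooled minor-allele frequency (computed from
#' non-missing calls across all populations) is at least `min_maf`. Both
#' boundaries are inclusive, so a SNP exactly at 80% presence or 5% MAF
#' survives. Column order is preserved.
#'
#' @param g A [genotype_matrix()].
#' @param min_presence Minimum fraction of individuals with a called
#'   genotype (default 0.8).
#' @param min_maf Minimum pooled minor-allele frequency (default 0.05).
#' @return A filtered [genotype_matrix()].
#' @export
filter_snps <- function(g, min_presence = 0.8, min_maf = 0.05) {
  stopifnot(inherits(g, "geno_mat"))
  if (min_presence < 0 || min_presence > 1 || min_maf < 0 || min_maf > 1) {
    abort("`min_presence` and `min_maf` must lie in [0, 1].")
  }
  d <- g$dosages
  called <- colSums(!is.na(d))
  presence <- called / nrow(d)
  p <- colSums(d, na.rm = TRUE) / (2 * pmax(called, 1L))
  maf <- pmin(p, 1 - p)
  keep <- presence >= min_presence & maf >= min_maf & called > 0
  if (!any(keep)) {
    abort("Empty panel: every SNP was removed by the presence/MAF filter.")
  }
  genotype_matrix(d[, keep, drop = FALSE], g$populations)
}

#' Alternate-allele frequencies per SNP
#'
#' Frequency is the dosage sum over non-missing calls divided by twice the
#' number of calls. With `by_population = TRUE` the frequency is computed
#' within each population; a population with no calls at a SNP yields `NA`.
#'
#' @param g A [genotype_matrix()].
#' @param by_population Compute per-population frequencies instead of pooled.
#' @return A tibble with columns `snp`, `n_called`, `freq` and, when
#'   `by_population = TRUE`, `population`.
#' @export
allele_freqs <- function(g, by_population = FALSE) {
  stopifnot(inherits(g, "geno_mat"))
  one <- function(d, pop = NULL) {
    called <- unname(colSums(!is.na(d)))
    freq <- ifelse(called > 0,
                   unname(colSums(d, na.rm = TRUE)) / (2 * called), NA_real_)
    out <- tibble(snp = colnames(d), n_called = as.integer(called), freq = freq)
    if (!is.null(pop)) out <- mutate(out, population = pop, .before = 1)
    out
  }
  if (!by_population) {
    return(one(g$dosages))
  }
  list_rbind(map(populations(g), function(p) one(pop_dosages(g, p), p)))
}
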