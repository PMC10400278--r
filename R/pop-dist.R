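#' Symmetric population distance matrix
#'
#' Light wrapper holding a symmetric matrix with zero diagonal, labelled by
#' population. Used for every pairwise quantity in the package (F_ST,
#' geographic, environmental and trait distances), so Mantel-type tests can
#' accept any of them interchangeably.
#'
#' @param values Symmetric numeric matrix with zero diagonal.
#' @param labels Population labels (defaults to `rownames(values)`).
#' @param measure Short name of what the distances are (used in printing
#'   and plots).
#' @return An object of class `pop_dist`.
#' @export
pop_dist <- function(values, labels = rownames(values), measure = "distance") {
  values <- as.matrix(values)
  if (is.null(labels)) abort("Distance matrix needs population labels.")
  if (nrow(values) != ncol(values) || nrow(values) != length(labels)) {
    abort("Distance matrix must be square and match its labels.")
  }
  if (max(abs(values - t(values)), na.rm = TRUE) > 1e-8) {
    abort("Distance matrix must be symmetric.")
  }
  if (any(abs(diag(values)) > 1e-12)) {
    abort("Distance matrix must have a zero diagonal.")
  }
  values <- (values + t(values)) / 2
  diag(values) <- 0
  dimnames(values) <- list(labels, labels)
  structure(list(values = values, measure = measure), class = "pop_dist")
}

#' @export
print.pop_dist <- function(x, digits = 4, ...) {
  cat(sprintf("<pop_dist: %s> %d populations\n", x$measure, nrow(x$values)))
  print(round(x$values, digits))
  invisible(x)
}

#' @export
as.matrix.pop_dist <- function(x, ...) x$values

#' @export
labels.pop_dist <- function(object, ...) rownames(object$values)

#' Lower-triangle vectorization of a distance matrix
#'
#' Pairs are emitted in column-major lower-triangle order over
#' lexicographically interpretable label order as stored; all matrix tests in
#' the package vectorize the same way so entries align across matrices.
#'
#' @param d A [pop_dist()] or symmetric matrix.
#' @return Numeric vector of the n(n-1)/2 lower-triangle entries.
#' @export
lower_triangle <- function(d) {
  m <- as.matrix(d)
  m[lower.tri(m)]
}

#' Pairwise long format of a distance matrix
#'
#' @param x A [pop_dist()].
#' @param ... Unused.
#' @return Tibble with columns `pop_a`, `pop_b`, `value` (unordered pairs,
#'   each once).
#' @export
tidy.pop_dist <- function(x, ...) {
  m <- x$values
  idx <- which(lower.tri(m), arr.ind = TRUE)
  tibble(
    pop_a = rownames(m)[idx[, 2]],
    pop_b = rownames(m)[idx[, 1]],
    value = m[idx]
  )
}

#' Heat-map of a population distance matrix
#'
#' @param object A [pop_dist()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pop_dist <- function(object, ...) {
  df <- tidyr::expand_grid(
    pop_a = rownames(object$values),
    pop_b = colnames(object$values)
  )
  df$value <- as.vector(t(object$values))
  ggplot2::ggplot(df, ggplot2::aes(.data$pop_a, .data$pop_b,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = signif(.data$value, 3)),
                       size = 3) +
    ggplot2::scale_fill_viridis_c(name = object$measure) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

check_aligned <- function(a, b) {
  la <- labels(a)
  lb <- labels(b)
  if (length(la) != length(lb) || !all(la == lb)) {
    abort("Distance matrices must share the same populations in the same order.")
  }
}
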