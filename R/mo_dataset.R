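#' Multi-output dataset in stacked (long) form
#'
#' Holds the shared currency of all surrogate models: inputs `X`,
#' observations `y`, and a per-row output-surface label. The stacked form
#' accommodates ragged replicate counts (1-6 repeats per location in the
#' amplification data).
#'
#' @param X N x D input matrix (vectors become one column).
#' @param y numeric vector of N observations.
#' @param surface per-row surface label (character/factor/integer); coerced
#'   to character.
#' @param surface_labels optional full set of surface labels, so surfaces
#'   with zero observations (new competitors) can be declared.
#' @return object of class `mo_dataset` with fields `X`, `y`, `surface`
#'   (character), `surface_labels`, `P`.
#' @export
mo_dataset <- function(X, y, surface, surface_labels = NULL) {
  X <- as_matrix_input(X)
  y <- as.numeric(y)
  surface <- as.character(surface)
  if (nrow(X) != length(y) || length(y) != length(surface)) {
    stop("X, y and surface must have matching lengths", call. = FALSE)
  }
  if (length(y) && (!all(is.finite(y)) || !all(is.finite(X)))) {
    stop("non-finite values in inputs or observations", call. = FALSE)
  }
  if (is.null(surface_labels)) surface_labels <- unique(surface)
  surface_labels <- as.character(surface_labels)
  if (!all(surface %in% surface_labels)) {
    stop("surface labels found in rows that are absent from surface_labels", call. = FALSE)
  }
  structure(list(X = X, y = y, surface = surface,
                 surface_labels = surface_labels,
                 P = length(surface_labels)),
            class = "mo_dataset")
}

#' @export
print.mo_dataset <- function(x, ...) {
  n_obs <- table(factor(x$surface, levels = x$surface_labels))
  cat("Multi-output dataset:", length(x$y), "rows,", ncol(x$X), "input dims,",
      x$P, "surfaces (", sum(n_obs > 0), "with data )\n")
  invisible(x)
}

# rows belonging to one surface
mo_rows <- function(data, label) which(data$surface == label)

# subset a mo_dataset by row index, keeping the declared label set
mo_subset <- function(data, idx) {
  mo_dataset(data$X[idx, , drop = FALSE], data$y[idx], data$surface[idx],
             surface_labels = data$surface_labels)
}

# append rows to a mo_dataset
mo_append <- function(data, X, y, surface) {
  mo_dataset(rbind(data$X, as_matrix_input(X)), c(data$y, y),
             c(data$surface, as.character(surface)),
             surface_labels = union(data$surface_labels, as.character(surface)))
}
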