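## Labeled receptor-by-odorant matrices with an observed mask.

#' Receptor-by-odorant affinity matrix
#'
#' Container for an `N x M` nonnegative affinity matrix `K` with unique
#' receptor and odorant labels and an observed mask (`FALSE` marks a missing
#' measurement, in the style of consolidated odorant-response datasets).
#' Where `K > 0`, the effective threshold concentration is `1/K`.
#'
#' @param values `N x M` numeric matrix; observed entries must be
#'   nonnegative and finite.
#' @param receptor_labels,odorant_labels Unique label vectors; default to
#'   dimnames of `values` or generated labels.
#' @param observed Logical matrix of the same shape (`TRUE` = measured).
#'   `NA` entries in `values` are marked unobserved automatically.
#' @return Object of class `affinity_matrix`: list with `values`,
#'   `observed`; labels live in `dimnames(values)`.
#' @export
affinity_matrix <- function(values, receptor_labels = NULL,
                            odorant_labels = NULL, observed = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  receptor_labels <- receptor_labels %||% rownames(values) %||%
    paste0("OR", seq_len(nrow(values)))
  odorant_labels <- odorant_labels %||% colnames(values) %||%
    paste0("odor", seq_len(ncol(values)))
  if (length(receptor_labels) != nrow(values) ||
      length(odorant_labels) != ncol(values))
    stop("label lengths do not match matrix dimensions", call. = FALSE)
  if (anyDuplicated(receptor_labels) || anyDuplicated(odorant_labels))
    stop("receptor and odorant labels must be unique", call. = FALSE)
  if (is.null(observed)) observed <- !is.na(values)
  observed <- as.matrix(observed) & !is.na(values)
  if (!identical(dim(observed), dim(values)))
    stop("observed mask shape does not match values", call. = FALSE)
  obs_vals <- values[observed]
  if (any(!is.finite(obs_vals)) || any(obs_vals < 0))
    stop("observed affinities must be finite and nonnegative", call. = FALSE)
  values[!observed] <- NA_real_
  dimnames(values) <- list(receptor_labels, odorant_labels)
  dimnames(observed) <- dimnames(values)
  structure(list(values = values, observed = observed),
            class = "affinity_matrix")
}

#' Normalized odorant-response matrix
#'
#' An [affinity_matrix()] whose observed entries are normalized responses in
#' `[0, 1]` (the form in which consolidated fly receptor-response data is
#' distributed). Used by the primacy-matrix and overlap analyses.
#'
#' @inheritParams affinity_matrix
#' @return Object of class `c("odor_response_matrix", "affinity_matrix")`.
#' @export
odor_response_matrix <- function(values, receptor_labels = NULL,
                                 odorant_labels = NULL, observed = NULL) {
  A <- affinity_matrix(values, receptor_labels, odorant_labels, observed)
  if (any(A$values[A$observed] > 1 + 1e-12))
    stop("observed responses must lie in [0, 1]", call. = FALSE)
  class(A) <- c("odor_response_matrix", class(A))
  A
}

#' @export
print.affinity_matrix <- function(x, ...) {
  cat(sprintf("%s: %d receptors x %d odorants, %.1f%% observed\n",
              if (inherits(x, "odor_response_matrix"))
                "Odorant response matrix" else "Affinity matrix",
              nrow(x$values), ncol(x$values), 100 * mean(x$observed)))
  invisible(x)
}

#' @export
dim.affinity_matrix <- function(x) dim(x$values)

#' Threshold concentrations of an affinity matrix
#'
#' `1/K` entrywise, defined only where `K > 0` is observed (other entries
#' are `NA`): the concentration at which each receptor reaches
#' half-activation for each odorant.
#'
#' @param A An [affinity_matrix()].
#' @return Numeric matrix of threshold concentrations.
#' @export
threshold_concentration <- function(A) {
  stopifnot(inherits(A, "affinity_matrix"))
  out <- A$values
  out[!A$observed | !(out > 0)] <- NA_real_
  1 / out
}

#' Low-rank factorization of an affinity matrix
#'
#' Holds the factorization `K = R Q` of an affinity matrix into receptor
#' points `R` (`N x D`) in a D-dimensional space of odorant properties and
#' property loadings `Q` (`D x M`). `D` is an assumption about the intrinsic
#' dimensionality of the odor space, not a fitted quantity.
#'
#' @param R `N x D` receptor-factor matrix.
#' @param Q `D x M` property-loading matrix.
#' @return Object of class `low_rank_model` with elements `R`, `Q`, `D`.
#' @export
low_rank_model <- function(R, Q) {
  R <- as.matrix(R); Q <- as.matrix(Q)
  if (ncol(R) != nrow(Q))
    stop("ncol(R) must equal nrow(Q)", call. = FALSE)
  D <- ncol(R)
  if (D > min(nrow(R), ncol(Q)))
    stop("dimension D exceeds min(N, M); not a low-rank model", call. = FALSE)
  structure(list(R = R, Q = Q, D = D), class = "low_rank_model")
}

#' @export
print.low_rank_model <- function(x, ...) {
  cat(sprintf("Low-rank affinity model: %d receptors x %d odorants, D = %d\n",
              nrow(x$R), ncol(x$Q), x$D))
  invisible(x)
}
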