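## Mass-action receptor activation and primacy sets.
##
## A receptor r responds to odorant o with affinity K_ro (units: inverse
## concentration). For a pure odorant at concentration c the activation
## fraction f satisfies f/(1 - f) = K c, and for a mixture with concentration
## vector c it satisfies f/(1 - f) = K_r . c. In a low-dimensional odor space
## K = R Q, so the same law reads f/(1 - f) = R_r . (Q c).

#' Activation of a single receptor by a pure odorant
#'
#' Mass-action activation fraction `f = Kc / (1 + Kc)`. At the threshold
#' concentration `c = 1/K` the receptor is exactly half activated, which is
#' why the affinity can be read as the inverse of the effective threshold
#' concentration.
#'
#' @param K Nonnegative affinity (inverse concentration units). Vectorized.
#' @param c Nonnegative concentration. Vectorized.
#' @return Activation fraction(s) in `[0, 1)`.
#' @examples
#' activate_single(5, 0)        # 0
#' activate_single(3, 1 / 3)    # 0.5 at the threshold concentration
#' @export
activate_single <- function(K, c) {
  stop_if_negative(K, "affinity K")
  stop_if_negative(c, "concentration c")
  s <- K * c
  s / (1 + s)
}

#' Mixture concentration with direction/norm decomposition
#'
#' Represents a mixture as its concentration vector `c`, its Euclidean norm,
#' and the unit direction `q = c / ||c||`. The direction determines *which*
#' receptors are most activated; the norm only determines *how many*.
#'
#' @param c Nonnegative concentration vector (one entry per odorant).
#' @return A list of class `mixture_concentration` with elements `c`, `norm`
#'   and `q` (`q` is `NULL` for the zero mixture).
#' @export
mixture_concentration <- function(c) {
  stop_if_negative(c, "concentration vector")
  nrm <- sqrt(sum(c^2))
  structure(
    list(c = as.numeric(c), norm = nrm,
         q = if (nrm > 0) as.numeric(c) / nrm else NULL),
    class = "mixture_concentration"
  )
}

#' @export
print.mixture_concentration <- function(x, ...) {
  cat("Mixture of", length(x$c), "odorants, total concentration (L2)",
      format(x$norm), "\n")
  invisible(x)
}

#' Activation of one receptor by an odorant mixture
#'
#' Mass-action activation for a mixture: `f = s / (1 + s)` with
#' `s = K_r . c`. In the low-rank factorization `K = R Q` the same quantity
#' is `s = R_r . (Q c)`; pass the receptor's property-affinity row as
#' `affinity` together with `loadings = Q` to use that form. The two call
#' forms agree whenever `K_r = R_r Q`.
#'
#' @param affinity Affinity row `K_r` (length M), or the property-space row
#'   `R_r` (length D) when `loadings` is supplied.
#' @param conc Nonnegative concentration vector (length M), or a
#'   [mixture_concentration()].
#' @param loadings Optional `D x M` property-loading matrix `Q`.
#' @return Activation fraction in `[0, 1)`.
#' @export
activate_mixture <- function(affinity, conc, loadings = NULL) {
  if (inherits(conc, "mixture_concentration")) conc <- conc$c
  stop_if_negative(conc, "concentration vector")
  affinity <- as.numeric(affinity)
  if (is.null(loadings)) {
    if (length(affinity) != length(conc))
      stop("affinity row and concentration vector have different lengths",
           call. = FALSE)
    s <- sum(affinity * conc)
  } else {
    loadings <- as.matrix(loadings)
    if (length(affinity) != nrow(loadings))
      stop("receptor row length does not match nrow(loadings)", call. = FALSE)
    if (ncol(loadings) != length(conc))
      stop("ncol(loadings) does not match the concentration vector",
           call. = FALSE)
    s <- sum(affinity * drop(loadings %*% conc))
  }
  if (s < 0)
    stop("effective affinity K_r . c is negative; not a valid mass-action ",
         "activation", call. = FALSE)
  s / (1 + s)
}

#' Project a concentration vector into property space
#'
#' Computes the property-space concentration `q~ = Q c`: the concentrations
#' of the D latent odorant properties carried by the mixture `c`.
#'
#' @param Q `D x M` property-loading matrix.
#' @param c Concentration vector of length M.
#' @return Numeric vector of length D.
#' @export
property_concentration <- function(Q, c) {
  Q <- as.matrix(Q)
  if (ncol(Q) != length(c))
    stop("ncol(Q) does not match length(c)", call. = FALSE)
  drop(Q %*% as.numeric(c))
}

#' Activation profile of a receptor ensemble
#'
#' Evaluates the mixture activation of every receptor in an affinity matrix.
#' Activation calls require complete affinity rows: any unobserved entry is
#' an error, because the mass-action sum is undefined with missing terms
#' (masked data is handled only by the primacy-matrix route).
#'
#' @param A An [affinity_matrix()].
#' @param conc Concentration vector (length = number of odorants) or
#'   [mixture_concentration()].
#' @param theta Activation threshold in (0, 1); default 1/2.
#' @return Object of class `activation_profile`: list with `f` (named
#'   activations) and `theta`.
#' @export
activation_profile <- function(A, conc, theta = 0.5) {
  stopifnot(inherits(A, "affinity_matrix"))
  if (!all(A$observed))
    stop("affinity matrix has unobserved entries; activation requires ",
         "complete affinity rows", call. = FALSE)
  if (inherits(conc, "mixture_concentration")) conc <- conc$c
  stop_if_negative(conc, "concentration vector")
  if (length(conc) != ncol(A$values))
    stop("concentration vector length does not match the number of odorants",
         call. = FALSE)
  check_theta(theta)
  s <- drop(A$values %*% conc)
  f <- s / (1 + s)
  names(f) <- rownames(A$values)
  structure(list(f = f, theta = theta), class = "activation_profile")
}

#' @export
print.activation_profile <- function(x, ...) {
  cat("Activation profile over", length(x$f), "receptors (theta =",
      format(x$theta), ")\n")
  cat("  active:", length(active_set(x)), "receptors\n")
  invisible(x)
}

check_theta <- function(theta) {
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0 || theta >= 1)
    stop("theta must lie strictly between 0 and 1", call. = FALSE)
  invisible(theta)
}

#' Active receptor set
#'
#' Indices of receptors whose activation strictly exceeds the threshold.
#' The boundary value `f == theta` counts as inactive, so a silent ensemble
#' at zero concentration is unambiguously empty. Along a fixed mixture
#' direction, active sets are nested: raising the total concentration never
#' deactivates a receptor.
#'
#' @param f Numeric activation vector, or an [activation_profile()].
#' @param theta Activation threshold in (0, 1); ignored when `f` carries its
#'   own threshold.
#' @return Integer vector of active receptor indices (ascending).
#' @export
active_set <- function(f, theta = 0.5) {
  if (inherits(f, "activation_profile")) {
    theta <- f$theta
    f <- f$f
  }
  check_theta(theta)
  which(as.numeric(f) > theta)
}

#' Primacy set of a mixture direction
#'
#' The `p` receptors activated at the lowest total concentration of the
#' mixture with direction `q`: exactly the `p` rows of `points` with the
#' largest projection onto `q`. The activation threshold plays no role —
#' the ranking of threshold-crossing concentrations equals the ranking of
#' projections for any common threshold.
#'
#' Ties at the p-th rank are broken toward the lowest receptor index and the
#' result carries a `tied` attribute (a measure-zero event for continuous
#' affinities, but made deterministic here).
#'
#' @param points `N x D` matrix of receptor affinity points (rows of `K` or,
#'   in property space, rows of `R`).
#' @param q Mixture direction of length D (any nonzero vector; internally
#'   normalized, since the projection ranking is scale-invariant).
#' @param p Primacy number, `1 <= p <= N`.
#' @return Sorted integer vector of `p` receptor indices, with attribute
#'   `tied` (logical).
#' @export
primacy_set <- function(points, q, p) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (!is.numeric(p) || length(p) != 1L || p < 1 || p > n || p != round(p))
    stop("p must be an integer in [1, nrow(points)]", call. = FALSE)
  q <- as.numeric(q)
  if (length(q) != ncol(points))
    stop("direction q has wrong length", call. = FALSE)
  nq <- sqrt(sum(q^2))
  if (!is.finite(nq) || nq == 0) stop("q must be a nonzero vector", call. = FALSE)
  proj <- drop(points %*% (q / nq))
  ord <- order(-proj, seq_len(n))
  sel <- ord[seq_len(p)]
  tied <- p < n && isTRUE(proj[ord[p]] == proj[ord[p + 1L]])
  structure(sort(sel), tied = tied)
}
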