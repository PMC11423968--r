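## The primacy hull: the simplicial complex of all primacy sets obtained by
## sweeping mixture directions q through the receptor point cloud. Each
## primacy set of size p is a (p-1)-simplex on the receptor vertices; the
## hull collects the distinct simplexes over all directions.

#' Number of n-vertex faces of a (p-1)-simplex
#'
#' The binomial count `p! / (n! (p-n)!)` of n-point faces ("subprime
#' simplexes") contained in a primacy simplex with `p` vertices. A
#' tetrahedron (`p = 4`) has 4 triangles and 6 edges.
#'
#' @param n Face size (number of vertices), `1 <= n <= p`. Vectorized.
#' @param p Primacy number (vertices of the simplex). Vectorized.
#' @return Exact integer-valued count(s).
#' @examples
#' face_count(3, 4)  # 4 triangles in a tetrahedron
#' face_count(2, 4)  # 6 edges
#' @export
face_count <- function(n, p) {
  if (any(n < 1) || any(p < 1) || any(n != round(n)) || any(p != round(p)))
    stop("n and p must be positive integers", call. = FALSE)
  if (any(n > p)) stop("n must not exceed p", call. = FALSE)
  round(choose(p, n))
}

#' Faces of a simplex
#'
#' All n-vertex faces (n-subsets) of a simplex given by its sorted vertex
#' indices. There are exactly `face_count(n, length(vertices))` of them.
#'
#' @param vertices Integer vector of distinct vertex indices.
#' @param n Face size, `1 <= n <= length(vertices)`.
#' @return List of sorted integer vectors, one per face.
#' @export
simplex_faces <- function(vertices, n) {
  vertices <- sort(as.integer(vertices))
  if (anyDuplicated(vertices)) stop("vertices must be distinct", call. = FALSE)
  p <- length(vertices)
  if (n < 1 || n > p || n != round(n))
    stop("n must be an integer in [1, length(vertices)]", call. = FALSE)
  m <- utils::combn(vertices, n)
  lapply(seq_len(ncol(m)), function(j) m[, j])
}

## Order-free exact key for a set of indices in 1..n_total (n_total <= 52
## uses an exact power-of-two sum; larger falls back to sorted strings).
simplex_keys <- function(idx_matrix, n_total) {
  if (n_total <= 52) {
    rowSums(matrix(2^(idx_matrix - 1), nrow = nrow(idx_matrix)))
  } else {
    apply(idx_matrix, 1L, function(r) paste(sort(r), collapse = ","))
  }
}

new_primacy_hull <- function(simplices, support, p, n_receptors, dimension,
                             sweep_meta) {
  structure(
    list(simplices = simplices, support = as.integer(support), p = as.integer(p),
         n_receptors = as.integer(n_receptors), dimension = as.integer(dimension),
         sweep_meta = sweep_meta),
    class = "primacy_hull"
  )
}

## Sample unit directions (columns) from the unit sphere or its nonnegative
## orthant. Gaussian draws are consumed per-direction so that prefixes of a
## larger sample coincide with a smaller sample under the same seed.
sample_directions <- function(n, D, cone) {
  M <- matrix(stats::rnorm(D * n), nrow = D, ncol = n)
  if (cone == "nonnegative_orthant") M <- abs(M)
  nrm <- sqrt(colSums(M^2))
  nrm[nrm == 0] <- 1
  sweep(M, 2L, nrm, "/")
}

#' Build a primacy hull by a Monte-Carlo directional sweep
#'
#' Samples unit mixture directions `q`, computes the primacy set (top-`p`
#' projections) for each, and collects the distinct simplexes with the
#' number of sampled directions supporting each. With enough directions the
#' result converges to the full primacy hull; with nested samples (same
#' seed, growing `n_directions`) hulls grow monotonically.
#'
#' The default cone is the nonnegative orthant, appropriate when `points`
#' are raw affinities (mixture concentrations are nonnegative). Use
#' `"full_sphere"` for property-space points whose loadings may carry signs.
#'
#' @param points `N x D` matrix of receptor points.
#' @param p Primacy number.
#' @param n_directions Number of sampled directions.
#' @param cone `"nonnegative_orthant"` or `"full_sphere"`.
#' @param seed Optional integer seed for the direction sample.
#' @param extra_directions Optional `D x k` matrix of additional directions
#'   to include in the sweep (e.g. the property vectors of known odorants,
#'   so their primacy sets are hull simplexes by construction).
#' @return Object of class `primacy_hull`.
#' @seealso [build_hull_exact_2d()] for the exact two-dimensional sweep.
#' @export
build_hull <- function(points, p, n_directions = 20000,
                       cone = c("nonnegative_orthant", "full_sphere"),
                       seed = NULL, extra_directions = NULL) {
  cone <- match.arg(cone)
  points <- as.matrix(points)
  N <- nrow(points); D <- ncol(points)
  if (p < 1 || p > N || p != round(p))
    stop("p must be an integer in [1, N]", call. = FALSE)
  if (n_directions < 1) stop("n_directions must be >= 1", call. = FALSE)
  if (N > 1 && all(abs(sweep(points, 2L, points[1L, ], "-")) < 1e-300))
    stop("degenerate points: all receptors identical, every direction ties",
         call. = FALSE)
  dirs <- with_seed(seed, sample_directions(n_directions, D, cone))
  n_extra <- 0L
  if (!is.null(extra_directions)) {
    extra_directions <- as.matrix(extra_directions)
    stopifnot(nrow(extra_directions) == D)
    nrm <- sqrt(colSums(extra_directions^2))
    dirs <- cbind(dirs, sweep(extra_directions, 2L, pmax(nrm, 1e-300), "/"))
    n_extra <- ncol(extra_directions)
  }
  proj <- crossprod(dirs, t(points))          # (directions) x N
  idx <- matrix(0L, nrow = nrow(proj), ncol = p)
  for (k in seq_len(p)) {
    top <- max.col(proj, ties.method = "first")
    idx[, k] <- top
    proj[cbind(seq_len(nrow(proj)), top)] <- -Inf
  }
  keys <- simplex_keys(idx, N)
  uk <- unique(keys)
  first <- match(uk, keys)
  simplices <- lapply(first, function(i) sort(idx[i, ]))
  support <- tabulate(match(keys, uk), nbins = length(uk))
  ord <- order(vapply(simplices, paste, "", collapse = ","))
  new_primacy_hull(
    simplices[ord], support[ord], p, N, D,
    sweep_meta = list(method = "monte_carlo", n_directions = n_directions,
                      cone = cone, seed = seed, n_extra = n_extra)
  )
}

#' Exact primacy hull in two dimensions
#'
#' The projection ranking of 2D points changes only at directions orthogonal
#' to a pairwise difference vector. Enumerating these O(N^2) critical angles
#' and evaluating one direction inside each angular interval yields the
#' exact hull, independent of any sampling; this is the oracle against which
#' the Monte-Carlo sweep converges.
#'
#' @param points `N x 2` matrix of receptor points; no two rows identical.
#' @param p Primacy number.
#' @param cone `"nonnegative_orthant"` (angles in `[0, pi/2]`) or
#'   `"full_sphere"` (the full circle).
#' @return Object of class `primacy_hull`; `support` counts the angular
#'   intervals realizing each simplex.
#' @export
build_hull_exact_2d <- function(points, p,
                                cone = c("nonnegative_orthant", "full_sphere")) {
  cone <- match.arg(cone)
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("points must be N x 2", call. = FALSE)
  N <- nrow(points)
  if (p < 1 || p > N || p != round(p))
    stop("p must be an integer in [1, N]", call. = FALSE)
  d2 <- as.matrix(stats::dist(points))
  if (any(d2[upper.tri(d2)] == 0))
    stop("duplicate points are not allowed in the exact 2D sweep",
         call. = FALSE)
  crit <- numeric(0)
  if (N > 1) {
    pr <- utils::combn(N, 2L)
    dvec <- points[pr[1L, ], , drop = FALSE] - points[pr[2L, ], , drop = FALSE]
    a <- atan2(dvec[, 2L], dvec[, 1L]) + pi / 2
    crit <- c(a, a + pi) %% (2 * pi)
  }
  if (cone == "nonnegative_orthant") {
    crit <- crit[crit > 0 & crit < pi / 2]
    angles <- sort(unique(c(0, crit, pi / 2)))
    eval_at <- unique(c(angles, (angles[-length(angles)] + angles[-1L]) / 2))
  } else {
    angles <- sort(unique(crit))
    if (length(angles) == 0L) {
      eval_at <- 0
    } else {
      mids <- (angles + c(angles[-1L], angles[1L] + 2 * pi)) / 2
      eval_at <- mids %% (2 * pi)
    }
  }
  sets <- lapply(eval_at, function(a)
    as.integer(primacy_set(points, c(cos(a), sin(a)), p)))
  idx <- do.call(rbind, sets)
  keys <- simplex_keys(idx, N)
  uk <- unique(keys)
  first <- match(uk, keys)
  simplices <- lapply(first, function(i) sort(idx[i, ]))
  support <- tabulate(match(keys, uk), nbins = length(uk))
  ord <- order(vapply(simplices, paste, "", collapse = ","))
  new_primacy_hull(
    simplices[ord], support[ord], p, N, 2L,
    sweep_meta = list(method = "exact_2d", cone = cone,
                      n_intervals = length(eval_at))
  )
}

#' @export
print.primacy_hull <- function(x, ...) {
  cat(sprintf(
    "Primacy hull: p = %d, %d receptors (D = %d), %d simplexes, %d hull vertices\n",
    x$p, x$n_receptors, x$dimension, length(x$simplices),
    length(hull_membership(x)$members)))
  cat("  sweep:", x$sweep_meta$method,
      if (!is.null(x$sweep_meta$n_directions))
        paste0("(", x$sweep_meta$n_directions, " directions, ",
               x$sweep_meta$cone, ")") else paste0("(", x$sweep_meta$cone, ")"),
      "\n")
  invisible(x)
}

#' @export
summary.primacy_hull <- function(object, ...) {
  mem <- hull_membership(object)
  cat(sprintf("Primacy hull with %d (%d-1)-simplexes over %d receptors\n",
              length(object$simplices), object$p, object$n_receptors))
  cat(sprintf("  hull vertices: %d; predicted pseudogenized: %d\n",
              length(mem$members), length(mem$non_members)))
  if (length(mem$non_members))
    cat("  non-members:", paste(mem$non_members, collapse = " "), "\n")
  invisible(mem)
}

#' Hull membership and predicted pseudogenization
#'
#' Partitions the receptor indices into hull vertices (members of at least
#' one primacy set) and non-members. Under the primacy model, receptors
#' outside the hull never encode any odor identity and are predicted to be
#' lost from the genome (pseudogenized).
#'
#' @param hull A `primacy_hull`.
#' @return List with integer vectors `members` and `non_members`.
#' @export
hull_membership <- function(hull) {
  stopifnot(inherits(hull, "primacy_hull"))
  members <- sort(unique(unlist(hull$simplices)))
  list(members = members,
       non_members = setdiff(seq_len(hull$n_receptors), members))
}

#' Subprime complex: all n-vertex faces of a hull
#'
#' The union, over all hull simplexes, of their n-vertex faces. These
#' "subprime" simplexes are the proposed unit of representation for
#' individual higher-center neurons (each Kenyon cell / cortical cell reads
#' out one face rather than a whole primacy simplex).
#'
#' @param hull A `primacy_hull`.
#' @param n Face size, `1 <= n <= p`.
#' @return List of sorted integer vectors (distinct faces).
#' @export
subprime_complex <- function(hull, n) {
  stopifnot(inherits(hull, "primacy_hull"))
  if (n < 1 || n > hull$p || n != round(n))
    stop("n must be an integer in [1, p]", call. = FALSE)
  fl <- unlist(lapply(hull$simplices, function(v)
    simplex_faces(v, n)), recursive = FALSE)
  idx <- do.call(rbind, fl)
  keys <- simplex_keys(idx, hull$n_receptors)
  fl[match(unique(keys), keys)]
}

#' Plot a 2D primacy hull
#'
#' Draws the receptor points and, for `p >= 2`, the edges of every hull
#' simplex; hull vertices are filled, predicted-pseudogenized receptors are
#' open circles.
#'
#' @param x A `primacy_hull` built from 2D points.
#' @param points The `N x 2` point matrix the hull was built from.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.primacy_hull <- function(x, points, ...) {
  points <- as.matrix(points)
  if (ncol(points) != 2L)
    stop("plotting requires the original N x 2 point matrix", call. = FALSE)
  mem <- hull_membership(x)
  graphics::plot(points, pch = ifelse(seq_len(nrow(points)) %in% mem$members,
                                      19, 1),
                 xlab = expression(K[X]), ylab = expression(K[Y]), ...)
  if (x$p >= 2) {
    for (s in x$simplices) {
      e <- utils::combn(s, 2L)
      graphics::segments(points[e[1L, ], 1L], points[e[1L, ], 2L],
                         points[e[2L, ], 1L], points[e[2L, ], 2L],
                         col = "red3")
    }
  }
  invisible(x)
}

#' Serialize a primacy hull to JSON
#'
#' Writes `p`, `n_receptors`, `dimension`, the simplex vertex lists
#' (1-based indices), their support counts and the sweep metadata.
#'
#' @param hull A `primacy_hull`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hull_json <- function(hull, path) {
  stopifnot(inherits(hull, "primacy_hull"))
  obj <- list(p = hull$p, n_receptors = hull$n_receptors,
              dimension = hull$dimension,
              simplices = lapply(hull$simplices, as.integer),
              support = hull$support,
              sweep_meta = hull$sweep_meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a primacy hull from JSON
#'
#' @param path File written by [write_hull_json()].
#' @return A `primacy_hull`.
#' @export
read_hull_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  simplices <- obj$simplices
  if (is.matrix(simplices)) {
    simplices <- lapply(seq_len(nrow(simplices)), function(i)
      as.integer(simplices[i, ]))
  } else {
    simplices <- lapply(simplices, as.integer)
  }
  new_primacy_hull(simplices, obj$support, obj$p, obj$n_receptors,
                   obj$dimension, as.list(obj$sweep_meta))
}
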