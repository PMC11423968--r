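## Surrogate worlds with planted primacy structure: low-dimensional receptor
## points, a primacy hull, a masked odorant-response matrix, and one or two
## connectivity matrices whose KCs sample faces of hull simplexes. Used to
## validate the analysis pipeline against known ground truth and to build
## matched negative controls.

#' Configuration for a surrogate world
#'
#' Defaults are the fly-scale study conditions: 51 glomerulus/receptor
#' channels, 156 odorants, 1800 KCs with 6 claws each, primacy number 5.
#' The odor-space dimension `D = 4` and the noise/missingness rates are the
#' generator's own calibration choices (documented in the methods
#' vignette).
#'
#' @param n_receptors Number of receptor/glomerulus channels.
#' @param dimension Intrinsic odor-space dimension D.
#' @param p Primacy number.
#' @param n_odorants Number of odorants in the response matrix.
#' @param n_kc Number of Kenyon cells.
#' @param claws_per_kc Claws (glomerular inputs) per KC; must not exceed `p`.
#' @param claw_noise_fraction Probability a claw is rewired to a uniformly
#'   random glomerulus.
#' @param missing_rate Bernoulli missingness rate of the response matrix
#'   (or give a template mask to [surrogate_world()]).
#' @param affinity_noise Gaussian noise s.d. added to the noise-free
#'   receptor-odorant projections before clipping/rescaling.
#' @param n_directions Monte-Carlo sweep size for the planted hull.
#' @param seed Integer seed; all stage seeds derive from it.
#' @return A list of class `world_config`.
#' @export
world_config <- function(n_receptors = 51, dimension = 4, p = 5,
                         n_odorants = 156, n_kc = 1800, claws_per_kc = 6,
                         claw_noise_fraction = 0.2, missing_rate = 0.3,
                         affinity_noise = 0.2, n_directions = 2000,
                         seed = NULL) {
  stopifnot(p <= n_receptors, claws_per_kc <= p,
            claw_noise_fraction >= 0, claw_noise_fraction <= 1,
            missing_rate >= 0, missing_rate <= 1, affinity_noise >= 0,
            n_receptors >= dimension + 1)
  structure(as.list(environment()), class = "world_config")
}

#' Sample receptor points in property space
#'
#' Receptor points are drawn i.i.d. normal with unit spread, mean-shifted
#' into the positive orthant (`mean = 3`) so that projections onto
#' nonnegative mixture directions are valid nonnegative affinities.
#'
#' @param n_receptors,dimension Matrix shape (`N x D`), `N >= D + 1`.
#' @param seed Optional seed.
#' @param mean Mean shift of each coordinate.
#' @return `N x D` numeric matrix.
#' @export
sample_receptors <- function(n_receptors, dimension, seed = NULL, mean = 3) {
  stopifnot(n_receptors >= dimension + 1)
  with_seed(seed,
    matrix(stats::rnorm(n_receptors * dimension, mean = mean),
           nrow = n_receptors, ncol = dimension))
}

#' Surrogate masked odorant-response matrix
#'
#' Draws odorant property columns `Q` as unit vectors in the nonnegative
#' orthant (the same cone used for hull construction, so planted primacy
#' sets are hull simplexes), forms the noise-free low-rank responses
#' `R %*% Q`, adds Gaussian noise, clips at zero, rescales to `[0, 1]`, and
#' applies the missing mask (a supplied template mask, or i.i.d. Bernoulli).
#'
#' @param points `N x D` receptor matrix.
#' @param n_odorants Number of odorant columns.
#' @param affinity_noise Gaussian noise s.d. (raw projection scale).
#' @param missing Either a single Bernoulli missing rate in `[0, 1]` or a
#'   logical template mask (`TRUE` = observed) of shape `N x n_odorants`.
#' @param seed Optional seed.
#' @return List: `response` (an [odor_response_matrix()]), `Q` (`D x M`
#'   unit property columns), `truth` (noise-free value matrix, unmasked).
#' @export
make_affinity <- function(points, n_odorants, affinity_noise = 0.2,
                          missing = 0.3, seed = NULL) {
  points <- as.matrix(points)
  N <- nrow(points); D <- ncol(points)
  with_seed(seed, {
    Q <- sample_directions(n_odorants, D, "nonnegative_orthant")
    truth <- points %*% Q
    raw <- pmax(truth + stats::rnorm(N * n_odorants, sd = affinity_noise), 0)
    vals <- raw / max(raw)
    if (is.matrix(missing)) {
      stopifnot(identical(dim(missing), dim(vals)))
      obs <- as.matrix(missing)
    } else {
      stopifnot(missing >= 0, missing <= 1)
      obs <- matrix(stats::runif(N * n_odorants) >= missing, N, n_odorants)
    }
    vals[!obs] <- NA_real_
    resp <- odor_response_matrix(vals,
                                 receptor_labels = rownames(points) %||%
                                   paste0("OR", seq_len(N)),
                                 odorant_labels = paste0("odor",
                                                         seq_len(n_odorants)))
    list(response = resp, Q = Q, truth = truth)
  })
}

#' Surrogate connectivity sampling hull faces
#'
#' Each KC picks a hull simplex (probability proportional to its sweep
#' support), then a uniform `n`-subset of its vertices (a subprime face) as
#' its claw set. With probability `claw_noise_fraction` each claw is
#' rewired to a uniformly random glomerulus; duplicate claws arising from
#' rewiring are redrawn so every KC keeps exactly `n` distinct claws.
#'
#' @param hull A `primacy_hull`.
#' @param n_kc Number of KCs.
#' @param claws_per_kc Claws per KC, `<= p`.
#' @param claw_noise_fraction Rewiring probability per claw.
#' @param seed Optional seed.
#' @param glom_labels Optional glomerulus labels (length `n_receptors`).
#' @return A [connectivity_matrix()]; attribute `simplex_id` records each
#'   KC's generating simplex.
#' @export
make_connectivity <- function(hull, n_kc, claws_per_kc,
                              claw_noise_fraction = 0, seed = NULL,
                              glom_labels = NULL) {
  stopifnot(inherits(hull, "primacy_hull"))
  if (claws_per_kc > hull$p) stop("claws_per_kc exceeds p", call. = FALSE)
  if (length(hull$simplices) == 0L) stop("empty hull", call. = FALSE)
  N <- hull$n_receptors
  with_seed(seed, {
    sid <- sample.int(length(hull$simplices), n_kc, replace = TRUE,
                      prob = hull$support)
    b <- matrix(0L, n_kc, N)
    for (i in seq_len(n_kc)) {
      v <- hull$simplices[[sid[i]]]
      claws <- if (claws_per_kc < length(v))
        v[sample.int(length(v), claws_per_kc)] else v
      if (claw_noise_fraction > 0) {
        rew <- stats::runif(claws_per_kc) < claw_noise_fraction
        for (j in which(rew)) {
          repeat {
            cand <- sample.int(N, 1L)
            if (!(cand %in% claws[-j])) { claws[j] <- cand; break }
          }
        }
      }
      b[i, claws] <- 1L
    }
    out <- connectivity_matrix(
      b, kc_labels = paste0("KC", seq_len(n_kc)),
      glom_labels = glom_labels %||% paste0("OR", seq_len(N)))
    attr(out, "simplex_id") <- sid
    out
  })
}

#' Generate a surrogate world with a planted primacy hull
#'
#' Builds the full planted-truth bundle: receptor points, the primacy hull
#' swept over the nonnegative orthant (with every odorant's property vector
#' included in the sweep, so each planted primacy set is a hull simplex by
#' construction), a masked response matrix, the noise-free primacy truth,
#' and one or two KC connectivity matrices sampling hull faces.
#'
#' @param config A [world_config()]; or pass individual fields via `...`.
#' @param ... Overrides for [world_config()] fields.
#' @param template_mask Optional logical observed-mask to copy instead of
#'   Bernoulli missingness.
#' @param two_animals If `TRUE`, generate an independent second animal
#'   (same hull, fresh KC sample).
#' @return Object of class `surrogate_world`: list with `points`, `hull`,
#'   `affinity` (response matrix), `Q`, `truth_primacy` (a
#'   [primacy_matrix()] built from the noise-free projections),
#'   `connectivity` (and `connectivity_b` if requested), `config`, and
#'   `ground_truth` ("planted").
#' @export
surrogate_world <- function(config = world_config(), ...,
                            template_mask = NULL, two_animals = FALSE) {
  dots <- list(...)
  if (length(dots)) config <- do.call(world_config,
                                      utils::modifyList(unclass(config), dots))
  cf <- config
  points <- sample_receptors(cf$n_receptors, cf$dimension,
                             seed = derive_seed(cf$seed, 1L))
  aff <- make_affinity(points, cf$n_odorants, cf$affinity_noise,
                       missing = template_mask %||% cf$missing_rate,
                       seed = derive_seed(cf$seed, 2L))
  hull <- build_hull(points, cf$p, n_directions = cf$n_directions,
                     cone = "nonnegative_orthant",
                     seed = derive_seed(cf$seed, 3L),
                     extra_directions = aff$Q)
  ## noise-free primacy truth: top-p projections per odorant direction
  truth_ind <- matrix(FALSE, cf$n_receptors, cf$n_odorants,
                      dimnames = dimnames(aff$response$values))
  for (j in seq_len(cf$n_odorants))
    truth_ind[primacy_set(points, aff$Q[, j], cf$p), j] <- TRUE
  truth_primacy <- structure(
    list(indicator = truth_ind, p = as.integer(cf$p),
         dropped = character(0), tied = character(0)),
    class = "primacy_matrix")
  conn <- make_connectivity(hull, cf$n_kc, cf$claws_per_kc,
                            cf$claw_noise_fraction,
                            seed = derive_seed(cf$seed, 4L),
                            glom_labels = rownames(aff$response$values))
  world <- structure(
    list(points = points, hull = hull, affinity = aff$response, Q = aff$Q,
         truth_primacy = truth_primacy, connectivity = conn,
         connectivity_b = NULL, config = cf, ground_truth = "planted"),
    class = "surrogate_world")
  if (two_animals)
    world$connectivity_b <- make_second_animal(world,
                                               seed = derive_seed(cf$seed, 5L))
  world
}

#' @export
print.surrogate_world <- function(x, ...) {
  cf <- x$config
  cat(sprintf(
    "Surrogate world (%s): N = %d receptors, D = %d, p = %d, %d odorants\n",
    x$ground_truth, cf$n_receptors, cf$dimension, cf$p, cf$n_odorants))
  cat(sprintf("  hull: %d simplexes; KCs: %d x %d claws (noise %.0f%%); missing %.0f%%\n",
              length(x$hull$simplices), cf$n_kc, cf$claws_per_kc,
              100 * cf$claw_noise_fraction, 100 * (1 - mean(x$affinity$observed))))
  if (!is.null(x$connectivity_b)) cat("  second animal present\n")
  invisible(x)
}

#' Second animal sharing the planted hull
#'
#' Draws an independent KC population from the same hull (fresh sample,
#' same glomerulus labels, its own KC labels) with the stated rewiring
#' noise — the generative premise behind cross-animal conservation of
#' connectivity structure.
#'
#' @param world A `surrogate_world`.
#' @param rewire_fraction Claw rewiring probability; defaults to the
#'   world's `claw_noise_fraction`.
#' @param seed Optional seed.
#' @return A [connectivity_matrix()].
#' @export
make_second_animal <- function(world, rewire_fraction = NULL, seed = NULL) {
  stopifnot(inherits(world, "surrogate_world"))
  cf <- world$config
  out <- make_connectivity(world$hull, cf$n_kc, cf$claws_per_kc,
                           rewire_fraction %||% cf$claw_noise_fraction,
                           seed = seed,
                           glom_labels = colnames(world$connectivity$binary))
  rownames(out$binary) <- paste0("KCb", seq_len(nrow(out$binary)))
  out
}

#' Matched null world
#'
#' Copy of a surrogate world whose connectivity is replaced by its
#' degree-preserving shuffle; hull and affinity are untouched. The shuffle
#' destroys the claw/primacy-set association while keeping all degrees, so
#' enrichment analyses on the null world should find nothing.
#'
#' @param world A `surrogate_world`.
#' @param seed Optional seed for the shuffle.
#' @return A `surrogate_world` with `ground_truth = "null"`; the config
#'   records both the generator seed and the shuffle seed.
#' @export
make_null_world <- function(world, seed = NULL) {
  stopifnot(inherits(world, "surrogate_world"))
  world$connectivity <- shuffle_degree_preserving(world$connectivity,
                                                  seed = seed)
  if (!is.null(world$connectivity_b))
    world$connectivity_b <- shuffle_degree_preserving(
      world$connectivity_b, seed = derive_seed(seed, 1L))
  world$ground_truth <- "null"
  world$config$shuffle_seed <- seed
  world
}
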