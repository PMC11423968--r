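## Shared fixture builders. Everything is generated in code under fixed
## seeds; no stored data.

## Random binary KC x glomerulus matrix with no empty rows/columns.
random_binary_matrix <- function(n_kc, n_glom, fill = 0.2) {
  repeat {
    m <- matrix(rbinom(n_kc * n_glom, 1L, fill), n_kc, n_glom)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) break
  }
  dimnames(m) <- list(paste0("KC", seq_len(n_kc)), paste0("G", seq_len(n_glom)))
  m
}

## Small planted world used across modules (fast to generate).
small_world <- function(seed, n_kc = 300, claw_noise = 0.2, ...) {
  surrogate_world(world_config(
    n_receptors = 30, dimension = 4, p = 5, n_odorants = 60,
    n_kc = n_kc, claws_per_kc = 5, claw_noise_fraction = claw_noise,
    missing_rate = 0.3, n_directions = 1000, seed = seed, ...))
}

## Indices (1-based) of convex-hull extreme points via an independent
## oracle: grDevices::chull in 2D, scipy's ConvexHull (qhull) in 3D.
convex_hull_vertices <- function(points) {
  if (ncol(points) == 2L) return(sort(grDevices::chull(points)))
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  utils::write.table(points, f, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  out <- system2("python", c("-c", shQuote(paste0(
    "import numpy, sys\n",
    "from scipy.spatial import ConvexHull\n",
    "p = numpy.loadtxt(sys.argv[1], delimiter=',')\n",
    "print(' '.join(map(str, sorted(ConvexHull(p).vertices))))")), f),
    stdout = TRUE)
  sort(as.integer(strsplit(tail(out, 1L), " ")[[1]]) + 1L)
}

## Hand-built hull with given simplices (support 1 each).
new_hull_for_test <- function(simplices, p, n) {
  structure(
    list(simplices = lapply(simplices, as.integer),
         support = rep(1L, length(simplices)), p = as.integer(p),
         n_receptors = as.integer(n), dimension = 2L,
         sweep_meta = list(method = "manual")),
    class = "primacy_hull")
}

## Canonical form of a simplex list for set comparison.
simplex_set <- function(hull) {
  sort(vapply(hull$simplices, paste, "", collapse = "-"))
}
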