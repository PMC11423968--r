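## Glomerulus-to-Kenyon-cell connectivity analysis: binarization, Pearson
## similarity between glomeruli, cross-animal correlation of similarity
## matrices with a permutation test, degree-preserving nulls, PCA / Isomap
## embeddings and cross-animal Procrustes alignment.

#' Binary Kenyon-cell-by-glomerulus connectivity matrix
#'
#' @param binary `n_KC x n_glom` 0/1 matrix (logical or numeric).
#' @param kc_labels,glom_labels Labels; glomerulus labels must be unique.
#'   Default to dimnames or generated labels.
#' @param weights Optional matching matrix of synapse counts.
#' @return Object of class `connectivity_matrix` with elements `binary`
#'   (integer 0/1 matrix, labeled) and `weights` (or `NULL`).
#' @export
connectivity_matrix <- function(binary, kc_labels = NULL, glom_labels = NULL,
                                weights = NULL) {
  binary <- as.matrix(binary)
  storage.mode(binary) <- "integer"
  if (any(is.na(binary)) || any(binary != 0L & binary != 1L))
    stop("binary connectivity must contain only 0 and 1", call. = FALSE)
  kc_labels <- kc_labels %||% rownames(binary) %||%
    paste0("KC", seq_len(nrow(binary)))
  glom_labels <- glom_labels %||% colnames(binary) %||%
    paste0("G", seq_len(ncol(binary)))
  if (anyDuplicated(glom_labels))
    stop("glomerulus labels must be unique", call. = FALSE)
  dimnames(binary) <- list(kc_labels, glom_labels)
  if (!is.null(weights)) {
    weights <- as.matrix(weights)
    if (!identical(dim(weights), dim(binary)))
      stop("weights shape does not match binary", call. = FALSE)
    dimnames(weights) <- dimnames(binary)
  }
  structure(list(binary = binary, weights = weights),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("Connectivity: %d KCs x %d glomeruli, %d connections (%.2f claws/KC)\n",
              nrow(x$binary), ncol(x$binary), sum(x$binary),
              mean(rowSums(x$binary))))
  invisible(x)
}

#' @export
dim.connectivity_matrix <- function(x) dim(x$binary)

#' Binarize a synapse-count matrix
#'
#' Marks a connection wherever the synapse count reaches `threshold`
#' (default 1: any synapse counts). KCs left without claws and glomeruli
#' left without targets are dropped and reported via a message.
#'
#' @param weights `n_KC x n_glom` nonnegative integer matrix.
#' @param threshold Minimum synapse count for a connection.
#' @return A [connectivity_matrix()] (with the retained `weights` attached);
#'   dropped labels are recorded in attribute `dropped`.
#' @export
binarize <- function(weights, threshold = 1) {
  weights <- as.matrix(weights)
  stop_if_negative(weights, "synapse counts")
  if (threshold < 1) stop("threshold must be a positive integer", call. = FALSE)
  b <- (weights >= threshold) * 1L
  if (sum(b) == 0L)
    stop("empty matrix: no entry reaches the binarization threshold",
         call. = FALSE)
  keep_r <- rowSums(b) > 0L
  keep_c <- colSums(b) > 0L
  dropped <- list(
    kcs = rownames(b)[!keep_r] %||% which(!keep_r),
    glomeruli = colnames(b)[!keep_c] %||% which(!keep_c)
  )
  if (!all(keep_r))
    message("binarize: dropping ", sum(!keep_r), " KC(s) with no claws")
  if (!all(keep_c))
    message("binarize: dropping ", sum(!keep_c), " unconnected glomerulus/i")
  out <- connectivity_matrix(b[keep_r, keep_c, drop = FALSE],
                             weights = weights[keep_r, keep_c, drop = FALSE])
  attr(out, "threshold") <- threshold
  attr(out, "dropped") <- dropped
  out
}

## Pearson correlation between the columns of m, dropping constant columns
## (undefined correlation) with a warning. Shared by the connectivity and
## primacy similarity computations.
similarity_kernel <- function(m, what = "column") {
  if (nrow(m) < 2L) stop("need at least two rows to correlate", call. = FALSE)
  keep <- apply(m, 2L, function(v) stats::var(v) > 0)
  if (!all(keep))
    warning("dropping ", sum(!keep), " constant ", what, "(s): ",
            paste(colnames(m)[!keep], collapse = ", "), call. = FALSE)
  if (sum(keep) < 2L)
    stop("fewer than two non-constant ", what, "s; similarity undefined",
         call. = FALSE)
  stats::cor(m[, keep, drop = FALSE])
}

#' Glomerulus-glomerulus connectivity similarity
#'
#' Pearson correlation between every pair of glomeruli in terms of their
#' binary projection patterns onto the KC population. Constant glomerulus
#' columns (connected to all KCs or none) are dropped with a warning.
#'
#' @param C A [connectivity_matrix()] or binary matrix (KCs x glomeruli).
#' @return Symmetric correlation matrix with unit diagonal, labeled by
#'   glomerulus.
#' @export
glom_similarity <- function(C) {
  m <- if (inherits(C, "connectivity_matrix")) C$binary else as.matrix(C)
  similarity_kernel(m * 1.0, "glomerulus column")
}

#' Correlation of two similarity matrices with a permutation test
#'
#' Pearson correlation over the strictly-upper-triangle entries of two
#' label-aligned similarity matrices, with a Mantel-style permutation test:
#' the labels of the second matrix are permuted jointly on rows and columns,
#' and the permutation p-value carries the +1 correction.
#'
#' @param S1,S2 Symmetric similarity matrices with shared label dimnames;
#'   aligned on the intersection of labels (at least 3 required).
#' @param n_perm Number of label permutations.
#' @param seed Optional seed for the permutations.
#' @param alternative `"greater"` (conservation implies positive
#'   correlation) or `"two.sided"`.
#' @return List of class `offdiag_cor`: `r`, `p_value`, `n_labels`,
#'   `n_perm`, `alternative`, `perm_r` (the null correlations).
#' @export
offdiag_correlation <- function(S1, S2, n_perm = 999, seed = NULL,
                                alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  S1 <- as.matrix(S1); S2 <- as.matrix(S2)
  shared <- intersect(rownames(S1), rownames(S2))
  if (length(shared) < 3L)
    stop("need at least 3 shared labels", call. = FALSE)
  S1 <- S1[shared, shared]; S2 <- S2[shared, shared]
  ut <- upper.tri(S1)
  r <- stats::cor(S1[ut], S2[ut])
  n <- length(shared)
  perm_r <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    pp <- sample.int(n)
    stats::cor(S1[ut], S2[pp, pp][ut])
  }, 0.0))
  p <- switch(alternative,
    greater = (1 + sum(perm_r >= r)) / (n_perm + 1),
    two.sided = (1 + sum(abs(perm_r) >= abs(r))) / (n_perm + 1)
  )
  structure(list(r = r, p_value = p, n_labels = n, n_perm = n_perm,
                 alternative = alternative, perm_r = perm_r),
            class = "offdiag_cor")
}

#' @export
print.offdiag_cor <- function(x, ...) {
  cat(sprintf(
    "Off-diagonal similarity correlation: r = %.3f over %d labels (p = %.4g, %s, %d permutations)\n",
    x$r, x$n_labels, x$p_value, x$alternative, x$n_perm))
  invisible(x)
}

#' Degree-preserving shuffle of a binary connectivity matrix
#'
#' Randomizes a binary matrix by a checkerboard-swap Markov chain: two
#' 1-entries are proposed uniformly at random and, when they span a
#' `[[1,0],[0,1]]` / `[[0,1],[1,0]]` 2x2 submatrix, the checkerboard is
#' swapped for the other pattern. Accepted swaps keep every KC in-degree
#' (row sum) and glomerulus out-degree (column sum) exactly; rejected
#' proposals keep the chain aperiodic. Matrices whose margins admit a
#' unique fill are returned unchanged. Margins are asserted on every call.
#'
#' @param C A [connectivity_matrix()] or binary 0/1 matrix.
#' @param n_steps Number of proposed swaps. The default scales the proposal
#'   count so that the *expected number of accepted swaps* is about 10x the
#'   number of ones (an edge-pair proposal succeeds with probability
#'   roughly `(1 - d)^2` at fill density `d`), so sparse and dense
#'   matrices mix comparably.
#' @param seed Optional seed.
#' @return Same type as `C`, with identical row and column sums.
#' @export
shuffle_degree_preserving <- function(C, n_steps = NULL, seed = NULL) {
  m <- if (inherits(C, "connectivity_matrix")) C$binary else {
    x <- as.matrix(C); storage.mode(x) <- "integer"; x
  }
  if (any(m != 0L & m != 1L)) stop("matrix must be binary", call. = FALSE)
  if (is.null(n_steps)) {
    ones <- sum(m)
    d <- ones / length(m)
    accept <- max(0.05, (1 - d)^2)   # edge-pair acceptance rate, floored
    n_steps <- min(ceiling(10 * ones / accept), 5e7)
  }
  sh <- with_seed(seed, checkerboard_swap_cpp(m, as.integer(n_steps)))
  dimnames(sh) <- dimnames(m)
  stopifnot(identical(rowSums(sh), rowSums(m)),
            identical(colSums(sh), colSums(m)))
  if (inherits(C, "connectivity_matrix"))
    connectivity_matrix(sh)
  else sh
}

new_embedding <- function(coords, ve, method, k = NULL, seed = NULL) {
  structure(list(coords = coords, variance_explained = ve, method = method,
                 k = k, seed = seed),
            class = "odor_embedding")
}

#' @export
print.odor_embedding <- function(x, ...) {
  cat(sprintf("%s embedding: %d points in %d dimension(s)%s\n",
              toupper(x$method), nrow(x$coords), ncol(x$coords),
              if (!is.null(x$k)) sprintf(" (k = %d neighbors)", x$k) else ""))
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = " "),
      "\n")
  invisible(x)
}

#' Linear (PCA) embedding of a similarity matrix
#'
#' Treats each row of the similarity matrix as that glomerulus's feature
#' vector, mean-centers the columns and projects onto the top `d` principal
#' components. `variance_explained` is the eigenvalue fraction per retained
#' dimension (nonincreasing).
#'
#' @param S Similarity (or any feature) matrix, rows = objects to embed.
#' @param d Embedding dimension, `d < nrow(S)`.
#' @return An embedding object with labeled `coords` (`n x d`) and
#'   `variance_explained` (length `d`).
#' @export
pca_embed <- function(S, d = 2) {
  S <- as.matrix(S)
  if (d >= nrow(S)) stop("d must be smaller than the number of rows",
                         call. = FALSE)
  pc <- stats::prcomp(S, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  coords <- pc$x[, seq_len(d), drop = FALSE]
  rownames(coords) <- rownames(S)
  new_embedding(coords, ve[seq_len(d)], "pca")
}

## Symmetrized k-nearest-neighbor graph on a distance matrix; edge weights
## are the distances. Returns an igraph graph.
knn_graph <- function(Dm, k) {
  n <- nrow(Dm)
  adj <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(Dm[i, ])[-1L][seq_len(k)]
    adj[i, nb] <- Dm[i, nb]
  }
  adj <- pmax(adj, t(adj))  # union symmetrization
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                      weighted = TRUE)
}

smallest_connecting_k <- function(Dm) {
  n <- nrow(Dm)
  for (k in seq_len(n - 1L)) {
    if (igraph::components(knn_graph(Dm, k))$no == 1L) return(k)
  }
  n - 1L
}

#' Nonlinear (Isomap) embedding of a similarity matrix
#'
#' Classical Isomap on the rows of `S`: Euclidean distances between rows, a
#' symmetrized k-nearest-neighbor graph, shortest-path geodesic distances,
#' and classical multidimensional scaling of the geodesics.
#' `variance_explained` is the positive-eigenvalue fraction of the geodesic
#' Gram matrix per dimension.
#'
#' @param S Similarity (feature) matrix, rows = objects.
#' @param d Embedding dimension.
#' @param k Neighbor count, or `"auto"` for the smallest `k` whose neighbor
#'   graph is connected. A disconnected graph for a user-supplied `k` is an
#'   error naming the smallest connecting `k`.
#' @return An embedding object (`coords`, `variance_explained`, `k`).
#' @export
isomap_embed <- function(S, d = 2, k = "auto") {
  S <- as.matrix(S)
  n <- nrow(S)
  if (d >= n) stop("d must be smaller than the number of rows", call. = FALSE)
  Dm <- as.matrix(stats::dist(S))
  k_min <- smallest_connecting_k(Dm)
  if (identical(k, "auto")) {
    k <- k_min
  } else {
    k <- as.integer(k)
    if (k < 1 || k > n - 1L) stop("k out of range", call. = FALSE)
    if (k < k_min)
      stop("k-nearest-neighbor graph is disconnected; smallest connecting k is ",
           k_min, call. = FALSE)
  }
  g <- knn_graph(Dm, k)
  geo <- igraph::distances(g)
  mds <- stats::cmdscale(geo, k = d, eig = TRUE)
  coords <- mds$points
  if (ncol(coords) < d)  # degenerate geometry: pad with zero coordinates
    coords <- cbind(coords, matrix(0, n, d - ncol(coords)))
  rownames(coords) <- rownames(S)
  pos <- pmax(mds$eig, 0)
  ve <- (pos / sum(pos))[seq_len(d)]
  new_embedding(coords, ve, "isomap", k = k)
}

#' Cross-animal embedding deviation (Procrustes RMSD)
#'
#' Aligns the second embedding to the first over their shared labels by
#' translation (centroid matching) and an orthogonal transformation
#' (rotation and reflection, no scaling: a common scale across animals is
#' part of what conservation means, and embedding sign/orientation is
#' arbitrary), then reports the root-mean-square deviation and the
#' per-label residual distances.
#'
#' @param E1,E2 Embedding objects or coordinate matrices with row labels.
#' @return List of class `embedding_rmsd`: `rmsd`, named `residuals`,
#'   `n_shared`.
#' @export
embedding_rmsd <- function(E1, E2) {
  A <- if (inherits(E1, "odor_embedding")) E1$coords else as.matrix(E1)
  B <- if (inherits(E2, "odor_embedding")) E2$coords else as.matrix(E2)
  if (ncol(A) != ncol(B)) stop("embedding dimensions differ", call. = FALSE)
  shared <- intersect(rownames(A), rownames(B))
  if (length(shared) < 3L) stop("need at least 3 shared labels", call. = FALSE)
  A <- scale(A[shared, , drop = FALSE], scale = FALSE)
  B <- scale(B[shared, , drop = FALSE], scale = FALSE)
  sv <- svd(crossprod(B, A))
  R <- sv$u %*% t(sv$v)           # orthogonal map (reflections allowed)
  resid2 <- rowSums((A - B %*% R)^2)
  structure(list(rmsd = sqrt(mean(resid2)),
                 residuals = stats::setNames(sqrt(resid2), shared),
                 n_shared = length(shared)),
            class = "embedding_rmsd")
}

#' @export
print.embedding_rmsd <- function(x, ...) {
  cat(sprintf("Embedding RMSD over %d shared labels: %.3f\n",
              x$n_shared, x$rmsd))
  invisible(x)
}

#' Per-dimension significance of embedding variance against a null
#'
#' Builds a degree-preserving shuffle ensemble of the connectivity matrix,
#' re-runs similarity + embedding on each shuffle, and reports for each
#' dimension the empirical probability (with +1 pseudocount) that a shuffle
#' explains at least as much variance as the data.
#'
#' @param C A [connectivity_matrix()].
#' @param d_max Number of leading dimensions to test.
#' @param n_shuffles Ensemble size.
#' @param method `"pca"` or `"isomap"`.
#' @param seed Optional seed for the ensemble.
#' @param ... Passed to the embedding function (e.g. `k` for Isomap).
#' @return List of class `dimension_significance`: `p_values` (length
#'   `d_max`), `observed` variance fractions, `null` (`n_shuffles x d_max`
#'   matrix), `method`, `n_shuffles`.
#' @export
dimension_significance <- function(C, d_max = 2, n_shuffles = 100,
                                   method = c("pca", "isomap"), seed = NULL,
                                   ...) {
  method <- match.arg(method)
  stopifnot(inherits(C, "connectivity_matrix"))
  if (n_shuffles < 1) stop("empty shuffle ensemble", call. = FALSE)
  embed_fun <- switch(method, pca = pca_embed, isomap = isomap_embed)
  obs <- embed_fun(glom_similarity(C), d = d_max, ...)$variance_explained
  null_ve <- with_seed(seed, {
    t(vapply(seq_len(n_shuffles), function(i) {
      Cs <- shuffle_degree_preserving(C)
      suppressWarnings(
        embed_fun(glom_similarity(Cs), d = d_max, ...)$variance_explained)
    }, numeric(d_max)))
  })
  p <- vapply(seq_len(d_max), function(dd)
    (1 + sum(null_ve[, dd] >= obs[dd])) / (n_shuffles + 1), 0.0)
  structure(list(p_values = p, observed = obs, null = null_ve,
                 method = method, n_shuffles = n_shuffles),
            class = "dimension_significance")
}

#' @export
print.dimension_significance <- function(x, ...) {
  cat(sprintf("Per-dimension variance significance (%s, %d shuffles)\n",
              toupper(x$method), x$n_shuffles))
  for (dd in seq_along(x$p_values))
    cat(sprintf("  dim %d: observed %.1f%% vs null %.1f%%, p = %.4g\n",
                dd, 100 * x$observed[dd], 100 * mean(x$null[, dd]),
                x$p_values[dd]))
  invisible(x)
}

#' Cross-animal RMSD against a degree-preserving null
#'
#' Embeds both animals' similarity matrices, computes the aligned RMSD, and
#' compares the per-glomerulus residuals with those obtained after
#' degree-preserving shuffles of the second animal's connectivity
#' (two-sample t-test on residuals, as the distributional summary of
#' whether glomeruli sit closer across animals than chance allows).
#'
#' @param C1,C2 [connectivity_matrix()] objects for the two animals.
#' @param d Embedding dimension (2 reproduces the planar comparison).
#' @param method `"pca"` or `"isomap"`.
#' @param n_shuffles Shuffle ensemble size.
#' @param seed Optional seed.
#' @param ... Passed to the embedding function.
#' @return List of class `rmsd_test`: `rmsd`, `null_rmsd` (vector),
#'   `t_test` (htest), `residuals`, `null_residuals`.
#' @export
embedding_rmsd_test <- function(C1, C2, d = 2, method = c("pca", "isomap"),
                                n_shuffles = 100, seed = NULL, ...) {
  method <- match.arg(method)
  embed_fun <- switch(method, pca = pca_embed, isomap = isomap_embed)
  E1 <- embed_fun(glom_similarity(C1), d = d, ...)
  E2 <- embed_fun(glom_similarity(C2), d = d, ...)
  obs <- embedding_rmsd(E1, E2)
  null_out <- with_seed(seed, {
    lapply(seq_len(n_shuffles), function(i) {
      Cs <- shuffle_degree_preserving(C2)
      Es <- suppressWarnings(embed_fun(glom_similarity(Cs), d = d, ...))
      embedding_rmsd(E1, Es)
    })
  })
  null_rmsd <- vapply(null_out, `[[`, 0.0, "rmsd")
  null_resid <- unlist(lapply(null_out, `[[`, "residuals"))
  tt <- stats::t.test(obs$residuals, null_resid, alternative = "less")
  structure(list(rmsd = obs$rmsd, null_rmsd = null_rmsd, t_test = tt,
                 residuals = obs$residuals, null_residuals = null_resid,
                 method = method),
            class = "rmsd_test")
}

#' @export
print.rmsd_test <- function(x, ...) {
  cat(sprintf("%s 2D alignment: RMSD = %.3f vs shuffled %.3f (t-test p = %.3g)\n",
              toupper(x$method), x$rmsd, mean(x$null_rmsd),
              x$t_test$p.value))
  invisible(x)
}
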