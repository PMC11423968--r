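test_that("binarization thresholds synapse counts and prunes empty channels", {
  w <- rbind(c(3, 0), c(1, 2))
  expect_equal(unname(binarize(w, 1)$binary), rbind(c(1L, 0L), c(1L, 1L)))
  expect_equal(unname(binarize(w, 2)$binary), rbind(c(1L, 0L), c(0L, 1L)))
  expect_error(binarize(w, 4), "empty matrix")
  expect_error(binarize(rbind(c(-1, 2)), 1), "nonnegative")
  w2 <- rbind(c(2, 0, 0), c(3, 0, 1))
  expect_message(b2 <- binarize(w2, 2), "glomerulus")
  expect_equal(dim(b2$binary), c(2L, 1L))
})

test_that("glomerulus similarity is the Pearson correlation of projection columns", {
  m <- cbind(a = c(1, 0, 1, 0), b = c(1, 0, 1, 0), c = c(0, 1, 0, 1))
  S <- glom_similarity(m)
  expect_equal(S["a", "b"], 1)
  expect_equal(S["a", "c"], -1)
  expect_equal(diag(S), c(a = 1, b = 1, c = 1))
  # brute-force covariance / sd oracle on a random binary matrix
  set.seed(31)
  mb <- random_binary_matrix(20, 6, 0.4)
  S2 <- glom_similarity(mb)
  i <- "G2"; j <- "G5"
  x <- mb[, i]; y <- mb[, j]
  brute <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(S2[i, j], brute)
  expect_warning(
    glom_similarity(cbind(a = c(1, 1, 1), b = c(1, 0, 0), c = c(0, 1, 0))),
    "constant")
})

test_that("off-diagonal correlation and its permutation test behave", {
  set.seed(33)
  C <- connectivity_matrix(random_binary_matrix(40, 8, 0.3))
  S <- glom_similarity(C)
  self <- offdiag_correlation(S, S, n_perm = 99, seed = 1)
  expect_equal(self$r, 1)
  expect_lt(self$p_value, 0.05)
  # hand-sized oracle: direct formula over the 6 upper-triangle pairs
  S1 <- matrix(c(1, .2, .3, .4, .2, 1, .5, .6, .3, .5, 1, .7, .4, .6, .7, 1), 4,
               dimnames = list(letters[1:4], letters[1:4]))
  S2 <- matrix(c(1, .1, .6, .2, .1, 1, .3, .9, .6, .3, 1, .2, .2, .9, .2, 1), 4,
               dimnames = list(letters[1:4], letters[1:4]))
  got <- offdiag_correlation(S1, S2, n_perm = 9, seed = 2)$r
  expect_equal(got, cor(S1[upper.tri(S1)], S2[upper.tri(S2)]))
  # label permutation destroys the correlation in expectation
  set.seed(34)
  rs <- replicate(30, {
    pp <- sample(nrow(S))
    Sp <- S[pp, pp]; dimnames(Sp) <- dimnames(S)
    offdiag_correlation(S, Sp, n_perm = 1, seed = NULL)$r
  })
  expect_lt(abs(mean(rs)), 0.15)
  expect_error(offdiag_correlation(S1[1:2, 1:2], S2[1:2, 1:2]), "3 shared")
})

test_that("off-diagonal permutation test agrees with an independent Mantel implementation", {
  set.seed(35)
  C1 <- connectivity_matrix(random_binary_matrix(60, 10, 0.3))
  C2 <- connectivity_matrix(random_binary_matrix(60, 10, 0.3))
  S1 <- glom_similarity(C1); S2 <- glom_similarity(C2)
  ours <- offdiag_correlation(S1, S2, n_perm = 199, seed = 3)
  vg <- vegan::mantel(as.dist(1 - S1), as.dist(1 - S2), permutations = 199)
  expect_equal(ours$r, vg$statistic, tolerance = 1e-12)
  expect_lt(abs(ours$p_value - vg$signif), 0.15)
})

test_that("degree-preserving shuffles keep margins exactly and mix states", {
  set.seed(37)
  for (i in 1:100) {
    m <- matrix(rbinom(12 * 6, 1, runif(1, 0.2, 0.8)), 12, 6)
    sh <- shuffle_degree_preserving(m, seed = i)
    expect_identical(rowSums(sh), rowSums(m))
    expect_identical(colSums(sh), colSums(m))
  }
  ones <- matrix(1L, 3, 3)
  expect_identical(unname(shuffle_degree_preserving(ones, seed = 1)), ones)
  # 2x2 identity: both admissible matrices are reached across seeds
  id2 <- diag(1L, 2)
  reached <- vapply(1:40, function(s)
    paste(shuffle_degree_preserving(id2, n_steps = 3, seed = s),
          collapse = ""), "")
  expect_setequal(unique(reached), c("1001", "0110"))
  # deterministic given seed
  m <- random_binary_matrix(30, 8)
  expect_identical(shuffle_degree_preserving(m, seed = 11),
                   shuffle_degree_preserving(m, seed = 11))
})

test_that("PCA embedding matches an independent eigendecomposition", {
  set.seed(39)
  # exact low-rank data: two dimensions carry all the variance
  base <- matrix(rnorm(20), 10, 2)
  X <- base %*% matrix(rnorm(2 * 10), 2, 10)
  rownames(X) <- paste0("G", 1:10)
  e <- pca_embed(X, 2)
  expect_equal(sum(e$variance_explained), 1, tolerance = 1e-9)
  # duplicated rows embed identically
  X2 <- rbind(X, X[1, , drop = FALSE]); rownames(X2)[11] <- "dup"
  e2 <- pca_embed(X2, 2)
  expect_equal(unname(e2$coords["dup", ]), unname(e2$coords["G1", ]))
  # oracle: eigendecomposition of the centered covariance
  Y <- matrix(rnorm(100), 10, 10); rownames(Y) <- paste0("G", 1:10)
  eo <- pca_embed(Y, 3)
  Yc <- scale(Y, scale = FALSE)
  ev <- eigen(crossprod(Yc) / (nrow(Y) - 1), symmetric = TRUE)
  expect_equal(eo$variance_explained,
               (ev$values / sum(ev$values))[1:3], tolerance = 1e-9)
  for (d in 1:3)
    expect_equal(abs(unname(eo$coords[, d])),
                 unname(abs(drop(Yc %*% ev$vectors[, d]))), tolerance = 1e-9)
  expect_error(pca_embed(Y, 10), "smaller")
})

test_that("Isomap reduces to PCA on flat data and unrolls curved data", {
  set.seed(43)
  # 1D arc embedded in 5D: one geodesic dimension dominates
  t <- seq(0, 3 * pi / 2, length.out = 40)
  arc <- cbind(cos(t), sin(t), 0.01 * matrix(rnorm(40 * 3), 40, 3))
  rownames(arc) <- paste0("P", 1:40)
  ei <- isomap_embed(arc, 2, k = 3)
  expect_gt(ei$variance_explained[1], 0.9)
  # complete neighbor graph on linear data: geodesic = Euclidean = PCA
  X <- matrix(rnorm(12 * 4), 12, 4) %*% matrix(rnorm(4 * 8), 4, 8)
  rownames(X) <- paste0("G", 1:12)
  ep <- pca_embed(X, 2)
  ec <- isomap_embed(X, 2, k = 11)
  al <- embedding_rmsd(ep, ec)
  expect_lt(al$rmsd, 1e-6)
  # disconnected graph errors and names the smallest connecting k
  two <- rbind(matrix(rnorm(10, 0), 5, 2), matrix(rnorm(10, 50), 5, 2))
  rownames(two) <- paste0("G", 1:10)
  expect_error(isomap_embed(two, 1, k = 2), "smallest connecting k is 5")
})

test_that("Procrustes RMSD is blind to rotation/reflection and tracks noise", {
  set.seed(45)
  A <- matrix(rnorm(20), 10, 2); rownames(A) <- paste0("G", 1:10)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rot <- A %*% R; rownames(rot) <- rownames(A)
  expect_lt(embedding_rmsd(A, rot)$rmsd, 1e-12)
  refl <- A %*% diag(c(1, -1)); rownames(refl) <- rownames(A)
  expect_lt(embedding_rmsd(A, refl)$rmsd, 1e-12)
  # isotropic per-coordinate noise sigma gives rmsd ~ sigma * sqrt(2) in 2D
  sigma <- 0.05
  rmsds <- replicate(40, {
    B <- A + matrix(rnorm(20, sd = sigma), 10, 2)
    rownames(B) <- rownames(A)
    embedding_rmsd(A, B)$rmsd
  })
  expect_equal(mean(rmsds), sigma * sqrt(2), tolerance = 0.15)
  expect_error(embedding_rmsd(A[1:2, ], A[1:2, ]), "3 shared")
})

test_that("dimension significance separates planted structure from shuffles", {
  w <- small_world(seed = 61, n_kc = 250)
  ds <- dimension_significance(w$connectivity, d_max = 4, n_shuffles = 60,
                               method = "pca", seed = 8)
  expect_length(ds$p_values, 4L)
  expect_true(all(ds$p_values >= 1 / 61 & ds$p_values <= 1))
  # hull structure concentrates variance in the leading dimensions
  expect_lt(ds$p_values[1], 0.05)
  expect_error(dimension_significance(w$connectivity, 2, n_shuffles = 0),
               "empty")
})
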