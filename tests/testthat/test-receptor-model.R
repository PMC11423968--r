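test_that("single-odorant activation follows the mass-action law", {
  expect_identical(activate_single(5, 0), 0)
  expect_equal(activate_single(2, 3), 6 / 7)  # invert f/(1-f) = 6
  # half-activation at the threshold concentration c = 1/K
  set.seed(41)
  K <- 10^runif(50, -3, 3)
  expect_equal(activate_single(K, 1 / K), rep(0.5, 50), tolerance = 1e-15)
  # strictly increasing in c for K > 0
  cs <- sort(runif(20))
  expect_true(all(diff(activate_single(3, cs)) > 0))
  expect_error(activate_single(-1, 2), "nonnegative")
  expect_error(activate_single(1, -2), "nonnegative")
})

test_that("mixture activation sums component drives and matches the low-rank form", {
  expect_equal(activate_mixture(c(2, 1), c(1, 1)), 0.75)  # s = 3
  expect_identical(activate_mixture(c(5, 7, 2), c(0, 0, 0)), 0)
  expect_equal(activate_mixture(c(1, 0), c(4, 9), loadings = diag(2)), 0.8)
  expect_error(activate_mixture(c(1, 2), c(1, 2, 3)), "length")
  expect_error(activate_mixture(c(1, 2), c(-1, 2)), "nonnegative")
  expect_error(activate_mixture(c(1, 2), c(1, 2, 3), loadings = diag(2)),
               "loadings")
  # K = R Q makes the two call forms agree to numerical tolerance
  set.seed(7)
  for (i in 1:20) {
    R <- matrix(abs(rnorm(4 * 3)), 4, 3)
    Q <- matrix(abs(rnorm(3 * 6)), 3, 6)
    K <- R %*% Q
    conc <- runif(6)
    r <- sample(4, 1)
    expect_equal(activate_mixture(K[r, ], conc),
                 activate_mixture(R[r, ], conc, loadings = Q),
                 tolerance = 1e-12)
  }
})

test_that("property-space concentration is the matrix-vector product", {
  expect_equal(property_concentration(diag(3), c(1, 2, 3)), c(1, 2, 3))
  expect_equal(property_concentration(matrix(1, 1, 3), c(1, 2, 3)), 6)
  set.seed(3)
  Q <- matrix(rnorm(12), 3, 4)
  cc <- runif(4)
  brute <- vapply(1:3, function(d) sum(Q[d, ] * cc), 0.0)
  expect_equal(property_concentration(Q, cc), brute)
  expect_error(property_concentration(Q, 1:3), "match")
})

test_that("active sets use strict threshold crossing and nest with concentration", {
  expect_identical(active_set(c(0.9, 0.4), 0.5), 1L)
  expect_identical(active_set(rep(0.5, 4), 0.5), integer(0))  # boundary inactive
  expect_error(active_set(c(0.1), 0), "between 0 and 1")
  # nestedness: doubling the concentration never deactivates a receptor
  set.seed(11)
  for (i in 1:100) {
    K <- matrix(abs(rnorm(8 * 3)), 8, 3)
    q <- abs(rnorm(3))
    c1 <- q * runif(1, 0.1, 2)
    f1 <- vapply(1:8, function(r) activate_mixture(K[r, ], c1), 0.0)
    f2 <- vapply(1:8, function(r) activate_mixture(K[r, ], 2 * c1), 0.0)
    expect_true(all(active_set(f1) %in% active_set(f2)))
  }
})

test_that("activation profiles require complete affinity rows", {
  A <- affinity_matrix(matrix(c(1, 2, 3, 4), 2, 2))
  pr <- activation_profile(A, c(1, 0))
  expect_equal(unname(pr$f), c(1 / 2, 2 / 3))
  Am <- affinity_matrix(matrix(c(1, NA, 3, 4), 2, 2))
  expect_error(activation_profile(Am, c(1, 0)), "unobserved")
})

test_that("primacy sets are the top-p projections with deterministic ties", {
  pts <- rbind(c(3, 1), c(1, 3), c(2, 2))
  expect_identical(as.integer(primacy_set(pts, c(1, 0), 2)), c(1L, 3L))
  expect_identical(as.integer(primacy_set(pts, c(0.3, 0.7), 3)), 1:3)
  pts2 <- rbind(c(3, 1), c(1, 2), c(2, 2))
  s <- primacy_set(pts2, c(1, 1) / sqrt(2), 2)  # projections 4, 3, 4
  expect_identical(as.integer(s), c(1L, 3L))
  # tie exactly at the p-th rank is flagged and broken toward low index
  pts3 <- rbind(c(2, 0), c(1, 0), c(1, 0), c(0, 1))
  s3 <- primacy_set(pts3, c(1, 0), 2)
  expect_identical(as.integer(s3), c(1L, 2L))
  expect_true(attr(s3, "tied"))
  expect_error(primacy_set(pts, c(0, 0), 2), "nonzero")
  expect_error(primacy_set(pts, c(1, 0), 4), "p must be")
})

test_that("primacy sets match threshold-crossing order for any threshold", {
  # the p receptors whose mass-action curves cross theta at the lowest
  # total concentration (found by root-finding on activate_mixture, an
  # independent route) equal primacy_set, for small and large theta alike
  set.seed(23)
  for (i in 1:30) {
    K <- matrix(abs(rnorm(8 * 3, mean = 1)), 8, 3)
    q <- abs(rnorm(3)); q <- q / sqrt(sum(q^2))
    for (theta in c(0.1, 0.5, 0.9)) {
      cross <- vapply(1:8, function(r) {
        stats::uniroot(function(cc) activate_mixture(K[r, ], q * cc) - theta,
                       c(1e-9, 1e9), tol = 1e-12)$root
      }, 0.0)
      first3 <- sort(order(cross)[1:3])
      expect_identical(first3, as.integer(primacy_set(K, q, 3)))
    }
  }
})
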