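test_that("face counts are exact binomials with the usual identities", {
  expect_identical(face_count(3, 4), 4)
  expect_identical(face_count(2, 4), 6)
  expect_identical(face_count(8, 16), 12870)
  expect_identical(face_count(4, 4), 1)
  for (p in c(3, 5, 9))
    expect_equal(sum(face_count(1:p, p)), 2^p - 1)
  expect_error(face_count(5, 4), "exceed")
  expect_error(face_count(0, 4), "positive")
})

test_that("simplex faces enumerate all n-subsets", {
  expect_equal(simplex_faces(c(1, 2, 3), 2),
               list(c(1L, 2L), c(1L, 3L), c(2L, 3L)))
  expect_length(simplex_faces(c(0, 4, 7, 9) + 1L, 3), 4L)
  set.seed(5)
  for (i in 1:10) {
    p <- sample(3:7, 1)
    v <- sort(sample(50, p))
    n <- sample(p, 1)
    fl <- simplex_faces(v, n)
    expect_length(fl, face_count(n, p))
    expect_false(anyDuplicated(vapply(fl, paste, "", collapse = "-")) > 0)
  }
  expect_error(simplex_faces(c(1, 1, 2), 2), "distinct")
})

test_that("the directional sweep finds all simplexes of small configurations", {
  # 3 non-collinear points, p = 2: every pair is extremal in some direction
  tri <- rbind(c(0, 0), c(1, 0), c(0.4, 1))
  h <- build_hull(tri, 2, n_directions = 5000, cone = "full_sphere", seed = 1)
  expect_setequal(simplex_set(h), c("1-2", "1-3", "2-3"))
  # p = 1: hull vertices are exactly the convex-hull extreme points
  set.seed(9)
  pts <- matrix(rnorm(24), 12, 2)
  h1 <- build_hull(pts, 1, n_directions = 20000, cone = "full_sphere", seed = 2)
  expect_identical(hull_membership(h1)$members, convex_hull_vertices(pts))
  # centroid of an equilateral triangle joins every p = 2 primacy set
  eq <- rbind(c(cos(pi / 2), sin(pi / 2)),
              c(cos(pi / 2 + 2 * pi / 3), sin(pi / 2 + 2 * pi / 3)),
              c(cos(pi / 2 + 4 * pi / 3), sin(pi / 2 + 4 * pi / 3)),
              c(0, 0))
  h2 <- build_hull(eq, 2, n_directions = 5000, cone = "full_sphere", seed = 3)
  expect_true(4L %in% hull_membership(h2)$members)
  expect_error(build_hull(rbind(c(1, 1), c(1, 1)), 1, 100), "degenerate")
})

test_that("hulls grow monotonically with nested direction samples", {
  set.seed(13)
  pts <- matrix(rnorm(30), 15, 2)
  for (p in c(1, 2)) {
    h_small <- build_hull(pts, p, n_directions = 200, seed = 5)
    h_big <- build_hull(pts, p, n_directions = 2000, seed = 5)
    expect_true(all(simplex_set(h_small) %in% simplex_set(h_big)))
  }
})

test_that("the exact 2D sweep agrees with brute-force and handles edge cases", {
  seg <- rbind(c(0, 0), c(1, 2))
  hs <- build_hull_exact_2d(seg, 2, cone = "full_sphere")
  expect_equal(hs$simplices, list(c(1L, 2L)))
  # unit square, p = 2: exactly the four sides (diagonals are never top-2)
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  hsq <- build_hull_exact_2d(sq, 2, cone = "full_sphere")
  expect_setequal(simplex_set(hsq), c("1-2", "2-3", "3-4", "1-4"))
  # Monte-Carlo convergence to the exact sweep, both cones
  set.seed(17)
  pts <- matrix(rnorm(20, sd = 2), 10, 2)
  for (cone in c("full_sphere", "nonnegative_orthant")) {
    ex <- build_hull_exact_2d(pts, 2, cone = cone)
    mc <- build_hull(pts, 2, n_directions = 50000, cone = cone, seed = 19)
    expect_identical(simplex_set(mc), simplex_set(ex))
  }
  expect_error(build_hull_exact_2d(rbind(c(1, 1), c(1, 1)), 1), "duplicate")
})

test_that("hull membership separates encoding receptors from pseudogenization candidates", {
  tri_c <- rbind(c(1, 0), c(-0.5, 0.87), c(-0.5, -0.87), c(0, 0))
  h1 <- build_hull(tri_c, 1, n_directions = 2000, cone = "full_sphere", seed = 1)
  mem <- hull_membership(h1)
  expect_identical(mem$members, 1:3)
  expect_identical(mem$non_members, 4L)   # interior point never wins top-1
  h_all <- build_hull(tri_c, 4, n_directions = 100, cone = "full_sphere", seed = 1)
  expect_length(hull_membership(h_all)$non_members, 0L)
})

test_that("subprime complexes merge faces across simplexes", {
  one <- new_hull_for_test(list(c(1L, 2L, 3L, 4L)), p = 4, n = 10)
  expect_length(subprime_complex(one, 2), face_count(2, 4))
  expect_equal(subprime_complex(one, 4), list(c(1L, 2L, 3L, 4L)))
  # two simplexes sharing p-1 vertices share exactly one (p-1)-face
  two <- new_hull_for_test(list(c(1L, 2L, 3L), c(1L, 2L, 4L)), p = 3, n = 10)
  expect_length(subprime_complex(two, 2), 2 * face_count(2, 3) - 1)
  expect_error(subprime_complex(two, 4), "\\[1, p\\]")
})

test_that("hull JSON serialization round-trips", {
  set.seed(21)
  h <- build_hull(matrix(rnorm(20), 10, 2), 3, n_directions = 500, seed = 3)
  f <- tempfile(fileext = ".json")
  write_hull_json(h, f)
  h2 <- read_hull_json(f)
  expect_identical(h2$simplices, h$simplices)
  expect_identical(h2$support, h$support)
  expect_identical(h2$p, h$p)
  expect_identical(h2$n_receptors, h$n_receptors)
})
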