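test_that("primacy matrices mark the top-p observed responders per odorant", {
  vals <- cbind(o1 = c(0.9, 0.5, 0.1, NA), o2 = c(0.2, NA, NA, 0.3))
  rownames(vals) <- paste0("OR", 1:4)
  A <- odor_response_matrix(vals)
  P <- primacy_matrix(A, p = 2, min_observed = 2)
  expect_equal(unname(P$indicator[, "o1"]), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(colSums(P$indicator), c(o1 = 2L, o2 = 2L))
  # drop rule: fewer observed entries than required
  expect_message(P2 <- primacy_matrix(A, p = 3, min_observed = 3), "dropping")
  expect_identical(P2$dropped, "o2")
  expect_error(primacy_matrix(A, p = 5), "exceeds")
  # random masked matrix vs brute-force top-p selection
  set.seed(51)
  m <- matrix(runif(30 * 12), 30, 12,
              dimnames = list(paste0("OR", 1:30), paste0("od", 1:12)))
  m[sample(length(m), 100)] <- NA
  Ar <- odor_response_matrix(m)
  Pr <- primacy_matrix(Ar, p = 5)
  expect_true(all(colSums(Pr$indicator) == 5L))
  for (j in colnames(Pr$indicator)) {
    v <- m[, j]
    brute <- names(sort(v[!is.na(v)], decreasing = TRUE))[1:5]
    expect_setequal(rownames(Pr$indicator)[Pr$indicator[, j]], brute)
  }
})

test_that("primacy similarity correlates shared membership", {
  ind <- rbind(a = c(TRUE, FALSE, TRUE, FALSE),
               b = c(TRUE, FALSE, TRUE, FALSE),
               c = c(FALSE, TRUE, FALSE, TRUE))
  P <- structure(list(indicator = ind, p = 1L, dropped = character(0),
                      tied = character(0)), class = "primacy_matrix")
  S <- primacy_similarity(P)
  expect_equal(S["a", "b"], 1)
  expect_equal(S["a", "c"], -1)
  # brute-force correlation oracle
  set.seed(53)
  ind2 <- matrix(runif(8 * 10) < 0.4, 8, 10,
                 dimnames = list(paste0("OR", 1:8), NULL))
  P2 <- structure(list(indicator = ind2, p = 3L, dropped = character(0),
                       tied = character(0)), class = "primacy_matrix")
  S2 <- suppressWarnings(primacy_similarity(P2))
  pair <- intersect(rownames(S2), c("OR1", "OR5"))
  if (length(pair) == 2L)
    expect_equal(S2[pair[1], pair[2]],
                 cor(ind2[pair[1], ] * 1, ind2[pair[2], ] * 1))
})

test_that("overlap tables equal set-intersection counts", {
  bin <- rbind(KC1 = c(1, 1, 1, 0, 0), KC2 = c(0, 1, 0, 0, 1))
  colnames(bin) <- paste0("OR", 1:5)
  C <- connectivity_matrix(bin)
  ind <- matrix(FALSE, 5, 2, dimnames = list(paste0("OR", 1:5), c("o1", "o2")))
  ind[c(2, 3, 5), "o1"] <- TRUE   # primacy set {2,3,5}
  ind[4, "o2"] <- TRUE            # disjoint from KC1
  P <- structure(list(indicator = ind, p = 3L, dropped = character(0),
                      tied = character(0)), class = "primacy_matrix")
  ot <- overlap_table(C, P)
  expect_identical(ot$counts["KC1", "o1"], 2L)  # claws {1,2,3} vs {2,3,5}
  expect_identical(ot$counts["KC1", "o2"], 0L)
  # randomized brute force over all (KC, odorant) pairs
  set.seed(55)
  Cb <- connectivity_matrix(random_binary_matrix(15, 10, 0.3))
  colnames(Cb$binary) <- paste0("OR", 1:10)
  ind2 <- matrix(runif(10 * 7) < 0.3, 10, 7,
                 dimnames = list(paste0("OR", 1:10), paste0("od", 1:7)))
  P2 <- structure(list(indicator = ind2, p = 3L, dropped = character(0),
                       tied = character(0)), class = "primacy_matrix")
  ot2 <- overlap_table(Cb, P2)
  for (i in 1:15) for (j in 1:7) {
    claws <- which(Cb$binary[i, ] == 1L)
    pset <- which(ind2[, j])
    expect_identical(ot2$counts[i, j], length(intersect(claws, pset)))
  }
})

test_that("top-k selection at k = 1 picks the per-odorant maximum overlap", {
  w <- small_world(seed = 57, n_kc = 150)
  e1 <- topk_enrichment(w$connectivity, w$affinity, k = 1, p = 5,
                        n_shuffles = 20, seed = 1)
  ot <- overlap_table(w$connectivity, primacy_matrix(w$affinity, p = 5))
  gkc <- apply(ot$counts, 2L, max)
  full <- tabulate(gkc + 1L, nbins = 6L)  # degrees 0..5
  sel <- e1$p == 5
  expect_equal(e1$observed[sel], full[e1$degree[sel] + 1L])
  # every degree the data occupies appears among the retained cells
  expect_true(all((which(full > 0) - 1L) %in% e1$degree[sel]))
})

test_that("enrichment is a controlled null on hull-free random worlds", {
  # type-I control: KC wiring independent of the response matrix
  set.seed(59)
  n_sig <- vapply(1:50, function(i) {
    C <- connectivity_matrix(random_binary_matrix(100, 20, 5 / 20))
    colnames(C$binary) <- paste0("OR", 1:20)
    m <- matrix(runif(20 * 30), 20, 30,
                dimnames = list(paste0("OR", 1:20), paste0("od", 1:30)))
    m[runif(length(m)) < 0.3] <- NA
    A <- odor_response_matrix(m)
    e <- topk_enrichment(C, A, k = 10, p = 1:5, n_shuffles = 100, seed = i)
    sum(e$q_value < 0.05)
  }, 0L)
  # fraction of replicate worlds with any false positive stays near the
  # nominal FDR (binomial slack on 50 replicates)
  expect_lte(mean(n_sig > 0), 0.05 + 3 * sqrt(0.05 * 0.95 / 50))
})

test_that("BH adjustment follows the step-up rule", {
  r <- bh_fdr(c(0.01, 0.02, 0.03, 0.04), alpha = 0.05)
  expect_identical(r$rejected, 1:4)
  expect_equal(r$q_values, rep(0.04, 4))
  r1 <- bh_fdr(0.04)
  expect_identical(r1$rejected, 1L)
  expect_equal(r1$q_values, 0.04)
  expect_identical(bh_fdr(rep(1, 5))$rejected, integer(0))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_equal(bh_fdr(c(0.03, 0.4, 0.01))$q_values,
               p.adjust(c(0.03, 0.4, 0.01), "BH"))
})

test_that("glomerulus relabeling keeps only single-receptor channels", {
  S <- diag(1, 3); dimnames(S) <- list(c("DA1", "DM2", "VA7"),
                                       c("DA1", "DM2", "VA7"))
  map <- data.frame(glomerulus = c("DA1", "DM2", "VA7", "VA7"),
                    or = c("Or67d", "Or22a", "Or46aA", "Or46aB"))
  S2 <- relabel_glomeruli(S, map)
  expect_identical(rownames(S2), c("Or67d", "Or22a"))  # VA7 is multi-OR
  expect_error(relabel_glomeruli(S, data.frame(g = 1)), "columns")
})
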