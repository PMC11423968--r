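## Comparing receptor-odorant response data with glomerulus-KC connectivity:
## top-p "primacy" indicator matrices, similarity of primacy profiles vs
## connectivity profiles, KC-by-odorant overlap counts, and enrichment of
## top-ranked overlaps against a degree-preserving null with BH FDR control.

#' Primacy matrix from an odorant-response table
#'
#' For each odorant, marks the `p` receptors with the strongest observed
#' responses (an approximation to the primacy set computable from masked
#' data). Missing responses never rank; odorants with fewer than
#' `min_observed` measured receptors are dropped and recorded, rather than
#' imputed. Ties at rank `p` are broken by receptor order and flagged.
#'
#' @param A An [odor_response_matrix()] / [affinity_matrix()].
#' @param p Primacy number (default 5).
#' @param min_observed Minimum observed entries to retain an odorant;
#'   default `max(p, 8)`.
#' @return Object of class `primacy_matrix`: list with `indicator`
#'   (logical `n_OR x n_retained`), `p`, `dropped` (labels), `tied`
#'   (labels of columns with a rank-p tie). Every retained column sums to
#'   exactly `p`.
#' @export
primacy_matrix <- function(A, p = 5, min_observed = max(p, 8)) {
  stopifnot(inherits(A, "affinity_matrix"))
  vals <- A$values
  n_or <- nrow(vals)
  if (p < 1 || p != round(p)) stop("p must be a positive integer", call. = FALSE)
  if (p > n_or) stop("p exceeds the number of receptors", call. = FALSE)
  n_obs <- colSums(A$observed)
  keep <- n_obs >= max(min_observed, p)
  dropped <- colnames(vals)[!keep]
  if (length(dropped))
    message("primacy_matrix: dropping ", length(dropped),
            " odorant(s) with < ", max(min_observed, p), " observed entries")
  ind <- matrix(FALSE, n_or, sum(keep),
                dimnames = list(rownames(vals), colnames(vals)[keep]))
  tied <- character(0)
  for (j in which(keep)) {
    v <- vals[, j]
    obs <- which(A$observed[, j])
    ord <- obs[order(-v[obs], obs)]
    sel <- ord[seq_len(p)]
    if (length(ord) > p && v[ord[p]] == v[ord[p + 1L]])
      tied <- c(tied, colnames(vals)[j])
    ind[sel, colnames(vals)[j]] <- TRUE
  }
  structure(list(indicator = ind, p = as.integer(p), dropped = dropped,
                 tied = tied),
            class = "primacy_matrix")
}

#' @export
print.primacy_matrix <- function(x, ...) {
  cat(sprintf("Primacy matrix (p = %d): %d receptors x %d retained odorants",
              x$p, nrow(x$indicator), ncol(x$indicator)))
  if (length(x$dropped)) cat(sprintf(" (%d dropped)", length(x$dropped)))
  cat("\n")
  invisible(x)
}

#' Receptor-receptor similarity of primacy membership
#'
#' Pearson correlation between receptors' primacy-indicator rows across the
#' retained odorants: receptors that tend to be primary for the same
#' odorants correlate positively. Receptors that are never (or always)
#' primary are constant and are dropped with a warning.
#'
#' @param P A [primacy_matrix()].
#' @return Symmetric correlation matrix labeled by receptor.
#' @export
primacy_similarity <- function(P) {
  stopifnot(inherits(P, "primacy_matrix"))
  if (ncol(P$indicator) < 2L)
    stop("need at least 2 retained odorants", call. = FALSE)
  similarity_kernel(t(P$indicator) * 1.0, "receptor row")
}

#' Map glomerulus labels to their receptor labels
#'
#' Applies a two-column glomerulus-to-receptor table to a
#' glomerulus-labeled similarity matrix, keeping only glomeruli that
#' receive a single receptor input (multi-receptor glomeruli have no
#' unambiguous affinity row and are excluded).
#'
#' @param S Similarity matrix with glomerulus dimnames.
#' @param glom_or_map Data frame with columns `glomerulus` and `or`.
#' @return The matrix restricted to single-receptor glomeruli, relabeled by
#'   receptor.
#' @export
relabel_glomeruli <- function(S, glom_or_map) {
  glom_or_map <- as.data.frame(glom_or_map)
  if (!all(c("glomerulus", "or") %in% names(glom_or_map)))
    stop("glom_or_map needs columns 'glomerulus' and 'or'", call. = FALSE)
  tab <- table(glom_or_map$glomerulus)
  single <- names(tab)[tab == 1L]
  map <- glom_or_map[glom_or_map$glomerulus %in% single, ]
  keep <- intersect(rownames(S), map$glomerulus)
  if (length(keep) == 0L) stop("no single-receptor glomeruli shared with S",
                               call. = FALSE)
  S <- S[keep, keep, drop = FALSE]
  ors <- map$or[match(keep, map$glomerulus)]
  dimnames(S) <- list(ors, ors)
  S
}

#' Correlate connectivity similarity with primacy similarity
#'
#' Tests whether receptors that project to similar KC populations are also
#' primary for similar odorants: the off-diagonal correlation between the
#' connectivity similarity matrix (restricted to single-receptor glomeruli
#' and relabeled by receptor) and the primacy similarity matrix, with a
#' label-permutation p-value.
#'
#' @param S_conn Glomerulus similarity matrix from [glom_similarity()].
#' @param S_prim Receptor similarity matrix from [primacy_similarity()].
#' @param glom_or_map Optional glomerulus-to-receptor table (see
#'   [relabel_glomeruli()]); omit if `S_conn` is already receptor-labeled.
#' @inheritParams offdiag_correlation
#' @return An `offdiag_cor` object (`r`, `p_value`, ...).
#' @export
connectivity_vs_primacy <- function(S_conn, S_prim, glom_or_map = NULL,
                                    n_perm = 999, seed = NULL,
                                    alternative = "greater") {
  if (!is.null(glom_or_map)) S_conn <- relabel_glomeruli(S_conn, glom_or_map)
  offdiag_correlation(S_conn, S_prim, n_perm = n_perm, seed = seed,
                      alternative = alternative)
}

## Align a connectivity matrix's glomerulus columns with a primacy matrix's
## receptor rows (optionally through the glomerulus-to-receptor map).
## Returns list(C = numeric KC x shared, P = numeric shared x odorants).
align_conn_primacy <- function(C, P, glom_or_map = NULL) {
  stopifnot(inherits(C, "connectivity_matrix"), inherits(P, "primacy_matrix"))
  cb <- C$binary
  if (!is.null(glom_or_map)) {
    glom_or_map <- as.data.frame(glom_or_map)
    tab <- table(glom_or_map$glomerulus)
    map <- glom_or_map[glom_or_map$glomerulus %in% names(tab)[tab == 1L], ]
    keep <- intersect(colnames(cb), map$glomerulus)
    cb <- cb[, keep, drop = FALSE]
    colnames(cb) <- map$or[match(keep, map$glomerulus)]
  }
  shared <- intersect(colnames(cb), rownames(P$indicator))
  if (length(shared) == 0L)
    stop("no shared receptor labels between connectivity and primacy matrix",
         call. = FALSE)
  list(C = cb[, shared, drop = FALSE] * 1.0,
       P = P$indicator[shared, , drop = FALSE] * 1.0)
}

#' Overlap counts between KC claws and primacy sets
#'
#' The matrix product of the binary connectivity and primacy matrices along
#' the shared receptor dimension: entry (KC, odorant) counts how many of the
#' KC's claws land on receptors in that odorant's primacy set.
#'
#' @param C A [connectivity_matrix()].
#' @param P A [primacy_matrix()].
#' @param glom_or_map Optional glomerulus-to-receptor table.
#' @return Object of class `overlap_table`: integer `counts`
#'   (`n_KC x n_odorant`) plus `p` and the number of shared receptors.
#' @export
overlap_table <- function(C, P, glom_or_map = NULL) {
  al <- align_conn_primacy(C, P, glom_or_map)
  counts <- al$C %*% al$P
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, p = P$p, n_shared = ncol(al$C)),
            class = "overlap_table")
}

#' @export
print.overlap_table <- function(x, ...) {
  cat(sprintf("Overlap table: %d KCs x %d odorants (p = %d, %d shared receptors)\n",
              nrow(x$counts), ncol(x$counts), x$p, x$n_shared))
  invisible(x)
}

## Histogram of the k largest overlap counts per odorant by overlap degree
## 0..max_deg. Exactly k KCs per odorant: the selected multiset of overlap
## values is determined by the counts alone (KC-order tie-breaking affects
## which cells are picked, never which values), so the histogram can be
## read off the per-odorant degree histograms, walking degrees high to low
## and taking up to k entries per odorant. Fully vectorized.
topk_degree_hist <- function(counts, k, max_deg) {
  H <- vapply(max_deg:0, function(d) colSums(counts == d),
              numeric(ncol(counts)))            # odorants x degrees (desc)
  if (is.null(dim(H))) H <- matrix(H, nrow = 1L)
  cum_before <- t(apply(H, 1L, cumsum)) - H
  take <- pmin(H, pmax(k - cum_before, 0))
  rev(colSums(take))
}

#' Enrichment of top-ranked KC/primacy-set overlaps
#'
#' For each primacy number in `p`, ranks the KCs per odorant by their
#' overlap with the odorant's primacy set, keeps the top `k` (`k = 1` is
#' the "grandmother-KC" case), and histograms those overlaps by degree.
#' The same histograms are recomputed on degree-preserving shuffles of the
#' connectivity matrix; per (p, degree) cell the result reports the
#' observed minus mean-null count, a two-sided empirical p-value (the
#' fraction of shuffles deviating from the null mean at least as far as
#' the observation, with a +1 pseudocount), and Benjamini-Hochberg
#' q-values across the full (p x degree) grid.
#'
#' @param C A [connectivity_matrix()].
#' @param A An [odor_response_matrix()], or a single [primacy_matrix()].
#' @param k KCs retained per odorant (1 = grandmother cell; 10 and 50 probe
#'   population readout).
#' @param p Vector of primacy numbers to sweep (default 1:8).
#' @param n_shuffles Size of the shuffle null (>= 100 recommended).
#' @param glom_or_map Optional glomerulus-to-receptor table.
#' @param min_observed Passed to [primacy_matrix()].
#' @param seed Optional seed for the shuffles.
#' @return Object of class `overlap_enrichment`: a long data frame with
#'   columns `p`, `degree`, `observed`, `null_mean`, `diff`, `p_value`,
#'   `q_value`, plus attributes `k`, `n_shuffles`, `seed`. Impossible
#'   cells (degree above `p`) and vacuous cells (occupied by neither data
#'   nor null) are omitted; only testable cells enter the BH family.
#' @export
topk_enrichment <- function(C, A, k = 10, p = 1:8, n_shuffles = 200,
                            glom_or_map = NULL, min_observed = NULL,
                            seed = NULL) {
  stopifnot(inherits(C, "connectivity_matrix"))
  if (k < 1 || k > nrow(C$binary))
    stop("k must be between 1 and the number of KCs", call. = FALSE)
  if (inherits(A, "primacy_matrix")) {
    p <- A$p
    plist <- list(A)
  } else {
    plist <- lapply(p, function(pp)
      primacy_matrix(A, p = pp,
                     min_observed = min_observed %||% max(pp, 8)))
  }
  al <- lapply(plist, function(P) align_conn_primacy(C, P, glom_or_map))
  Cb <- al[[1L]]$C                       # shared columns identical across p
  max_deg <- max(p)
  obs <- lapply(seq_along(p), function(i)
    topk_degree_hist(al[[i]]$C %*% al[[i]]$P, k, max_deg))
  ## null histograms: one shuffle of C reused across the whole p sweep
  nulls <- array(0, c(max_deg + 1L, length(p), n_shuffles))
  with_seed(seed, {
    for (s in seq_len(n_shuffles)) {
      Cs <- shuffle_degree_preserving(Cb)
      for (i in seq_along(p))
        nulls[, i, s] <- topk_degree_hist(Cs %*% al[[i]]$P, k, max_deg)
    }
  })
  null_mean <- apply(nulls, c(1L, 2L), mean)
  ## two-sided empirical p: deviation from the null mean, +1 pseudocount
  pv <- matrix(0, max_deg + 1L, length(p))
  for (i in seq_along(p)) {
    dev_obs <- abs(obs[[i]] - null_mean[, i])
    dev_null <- abs(nulls[, i, , drop = FALSE] - null_mean[, i])
    pv[, i] <- (1 + rowSums(dev_null[, 1L, ] >= dev_obs)) / (n_shuffles + 1)
  }
  out <- data.frame(
    p = rep(p, each = max_deg + 1L),
    degree = rep(0:max_deg, times = length(p)),
    observed = unlist(obs),
    null_mean = as.vector(null_mean),
    p_value = as.vector(pv)
  )
  ## degrees above p are impossible for that primacy number, and cells
  ## occupied by neither the data nor any shuffle carry no testable
  ## hypothesis: both are excluded from the table and the BH family
  out <- out[out$degree <= out$p, ]
  out <- out[out$observed > 0 | out$null_mean > 0, ]
  out$diff <- out$observed - out$null_mean
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[, c("p", "degree", "observed", "null_mean", "diff",
                 "p_value", "q_value")]
  rownames(out) <- NULL
  structure(out, k = k, n_shuffles = n_shuffles, seed = seed,
            class = c("overlap_enrichment", "data.frame"))
}

#' @export
print.overlap_enrichment <- function(x, ...) {
  cat(sprintf("Overlap enrichment: top-%d KCs per odorant, %d shuffles\n",
              attr(x, "k"), attr(x, "n_shuffles")))
  sig <- x[x$q_value < 0.05, , drop = FALSE]
  cat(sprintf("  %d of %d (p, degree) cells significant at FDR < 0.05\n",
              nrow(sig), nrow(x)))
  NextMethod()
}

#' Plot an overlap-enrichment grid
#'
#' Displays the observed-minus-null difference per (primacy number, overlap
#' degree) cell, marking cells significant at FDR < 0.05.
#'
#' @param x An `overlap_enrichment` result.
#' @param ... Passed to [graphics::image()].
#' @export
plot.overlap_enrichment <- function(x, ...) {
  ps <- sort(unique(x$p)); ds <- sort(unique(x$degree))
  z <- matrix(NA_real_, length(ds), length(ps),
              dimnames = list(ds, ps))
  z[cbind(match(x$degree, ds), match(x$p, ps))] <- x$diff
  lim <- max(abs(z), na.rm = TRUE)
  graphics::image(ds, ps, z, zlim = c(-lim, lim),
                  col = grDevices::hcl.colors(64, "Blue-Red 2"),
                  xlab = "overlap degree", ylab = "primacy number p", ...)
  sig <- x[x$q_value < 0.05, , drop = FALSE]
  if (nrow(sig)) graphics::points(sig$degree, sig$p, pch = 0, cex = 2)
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values via [stats::p.adjust()] plus the rejection set at level
#' `alpha` (reject where `q <= alpha`, equivalently the classical step-up
#' rule).
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return List with `q_values` and integer `rejected` indices.
#' @export
bh_fdr <- function(p_values, alpha = 0.05) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  q <- stats::p.adjust(p_values, method = "BH")
  list(q_values = q, rejected = which(q <= alpha))
}
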