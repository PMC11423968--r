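## Readers and writers for the interchange formats (labeled delimited
## matrices with "NA" for missing, edge lists, hull JSON) and the
## end-to-end pipeline driver behind the command-line wrapper.

#' Read a labeled delimited matrix
#'
#' Expects a header row of column labels and a first column of row labels;
#' the missing token (default `"NA"`) marks unobserved entries. Ragged
#' rows, duplicate labels and non-numeric cells are errors.
#'
#' @param path Input file.
#' @param delim Field delimiter (tab default).
#' @param missing_token Token for missing values.
#' @return List with `values` (numeric matrix, `NA` where missing),
#'   `observed` (logical matrix), `row_labels`, `col_labels`.
#' @export
read_labeled_matrix <- function(path, delim = "\t", missing_token = "NA") {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("file has no data rows: ", path, call. = FALSE)
  parts <- strsplit(lines, delim, fixed = TRUE)
  widths <- lengths(parts)
  if (any(widths != widths[1L]))
    stop("ragged rows in ", path, call. = FALSE)
  col_labels <- parts[[1L]][-1L]
  body <- parts[-1L]
  row_labels <- vapply(body, `[[`, "", 1L)
  if (anyDuplicated(row_labels) || anyDuplicated(col_labels))
    stop("duplicate row or column labels in ", path, call. = FALSE)
  cells <- t(vapply(body, function(r) r[-1L], character(length(col_labels))))
  if (length(col_labels) == 1L) cells <- matrix(cells, ncol = 1L)
  observed <- cells != missing_token
  values <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- observed & is.na(values)
  if (any(bad))
    stop("non-numeric cell(s) other than the missing token in ", path,
         call. = FALSE)
  values[!observed] <- NA_real_
  dimnames(values) <- dimnames(observed) <- list(row_labels, col_labels)
  list(values = values, observed = observed,
       row_labels = row_labels, col_labels = col_labels)
}

#' Write a labeled delimited matrix
#'
#' Inverse of [read_labeled_matrix()]: header row of column labels, first
#' column of row labels, `NA` entries written as the missing token.
#'
#' @param values Numeric (or 0/1) matrix with dimnames.
#' @param path Output file.
#' @param delim Field delimiter.
#' @param missing_token Token written for `NA`.
#' @return `path`, invisibly.
#' @export
write_labeled_matrix <- function(values, path, delim = "\t",
                                 missing_token = "NA") {
  values <- as.matrix(values)
  ch <- format(values, trim = TRUE, digits = 15)
  ch[is.na(values)] <- missing_token
  header <- paste(c("", colnames(values)), collapse = delim)
  rows <- vapply(seq_len(nrow(values)), function(i)
    paste(c(rownames(values)[i], ch[i, ]), collapse = delim), "")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read an affinity / response matrix file
#'
#' @inheritParams read_labeled_matrix
#' @param normalized If `TRUE` (default) return an
#'   [odor_response_matrix()] (values validated to `[0, 1]`); otherwise an
#'   [affinity_matrix()].
#' @return An affinity-type object (receptors x odorants).
#' @export
read_affinity <- function(path, delim = "\t", missing_token = "NA",
                          normalized = TRUE) {
  m <- read_labeled_matrix(path, delim, missing_token)
  ctor <- if (normalized) odor_response_matrix else affinity_matrix
  ctor(m$values, m$row_labels, m$col_labels, m$observed)
}

#' Read a connectivity matrix file
#'
#' Labeled delimited matrix with rows = KCs and columns = glomeruli;
#' entries are synapse counts (or already 0/1), binarized at `threshold`.
#'
#' @inheritParams read_labeled_matrix
#' @param threshold Binarization threshold (see [binarize()]).
#' @return A [connectivity_matrix()].
#' @export
read_connectivity <- function(path, delim = "\t", threshold = 1) {
  m <- read_labeled_matrix(path, delim)
  if (any(is.na(m$values)))
    stop("connectivity matrix may not contain missing entries", call. = FALSE)
  binarize(m$values, threshold = threshold)
}

#' Read a connectivity edge list
#'
#' Three delimited columns `kc_id`, `glomerulus`, `weight` (a header line
#' is detected and skipped if its third field is non-numeric). Duplicate
#' edges are summed, then the matrix is binarized at `threshold`.
#'
#' @inheritParams read_connectivity
#' @return A [connectivity_matrix()].
#' @export
read_edge_list <- function(path, delim = "\t", threshold = 1) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty edge list: ", path, call. = FALSE)
  parts <- strsplit(lines, delim, fixed = TRUE)
  if (any(lengths(parts) != 3L))
    stop("malformed edge list row(s): expected 3 columns", call. = FALSE)
  first_w <- suppressWarnings(as.numeric(parts[[1L]][3L]))
  if (is.na(first_w)) parts <- parts[-1L]
  if (length(parts) == 0L) stop("empty edge list: ", path, call. = FALSE)
  kc <- vapply(parts, `[[`, "", 1L)
  gl <- vapply(parts, `[[`, "", 2L)
  w <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  if (any(is.na(w))) stop("non-numeric edge weight(s)", call. = FALSE)
  stop_if_negative(w, "edge weights")
  kc_f <- factor(kc, levels = unique(kc))
  gl_f <- factor(gl, levels = unique(gl))
  weights <- matrix(0, nlevels(kc_f), nlevels(gl_f),
                    dimnames = list(levels(kc_f), levels(gl_f)))
  for (i in seq_along(w))
    weights[kc[i], gl[i]] <- weights[kc[i], gl[i]] + w[i]
  binarize(weights, threshold = threshold)
}

#' Read a flat key=value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Numeric-looking
#' values are converted.
#'
#' @param path Configuration file.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L)) stop("malformed config line(s)", call. = FALSE)
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  out <- lapply(vals, function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  })
  stats::setNames(out, keys)
}

#' Write a surrogate world to a directory
#'
#' Writes `affinity.tsv` (missing as `NA`), `mask.tsv`, `connectivity_A.tsv`
#' (and `_B` when present), `hull.json`, `truth.json` (planted primacy sets
#' per odorant) and `config.json`.
#'
#' @param world A [surrogate_world()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "surrogate_world"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_labeled_matrix(world$affinity$values, file.path(dir, "affinity.tsv"))
  write_labeled_matrix(world$affinity$observed * 1L, file.path(dir, "mask.tsv"))
  write_labeled_matrix(world$connectivity$binary,
                       file.path(dir, "connectivity_A.tsv"))
  if (!is.null(world$connectivity_b))
    write_labeled_matrix(world$connectivity_b$binary,
                         file.path(dir, "connectivity_B.tsv"))
  write_hull_json(world$hull, file.path(dir, "hull.json"))
  truth <- apply(world$truth_primacy$indicator, 2L, which, simplify = FALSE)
  jsonlite::write_json(
    list(ground_truth = world$ground_truth,
         primacy_sets = lapply(truth, as.integer)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(world$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Run an analysis pipeline end to end
#'
#' Drives the package's analyses from a flat configuration, writing result
#' tables and a metadata log to an output directory. Subcommands:
#' \describe{
#'   \item{simulate}{Generate a surrogate world ([surrogate_world()]) and
#'     write it out.}
#'   \item{hull}{Build a primacy hull from a points matrix file.}
#'   \item{conn-compare}{Cross-animal comparison of two connectivity files:
#'     similarity matrices, off-diagonal correlation with permutation test
#'     and a shuffled control, PCA/Isomap embeddings with per-dimension
#'     significance, and aligned-embedding RMSD.}
#'   \item{affinity-compare}{Correlate connectivity similarity with primacy
#'     similarity from a response-matrix file.}
#'   \item{enrich}{Top-k overlap enrichment of a connectivity file against
#'     a response-matrix file.}
#' }
#' Every stochastic stage consumes a sub-seed derived from `seed`, and the
#' metadata log (`metadata.json`) records the seeds, parameters and all
#' dropped items. Identical config + seed reproduce identical outputs.
#'
#' @param config Named list (or path to a `key = value` file) with at least
#'   `subcommand`; input paths (`connectivity_a`, `connectivity_b`,
#'   `affinity`, `points`, `glom_or_map`) and parameters (`p`, `k`,
#'   `dimension`, `n_shuffles`, `n_perm`, `n_directions`, `threshold`,
#'   `isomap_k`, `cone`) as the subcommand needs.
#' @param out Output directory.
#' @param seed Global integer seed.
#' @return The results (list), invisibly; files are written under `out`.
#' @export
run_pipeline <- function(config, out, seed = 1) {
  if (is.character(config) && length(config) == 1L)
    config <- read_config(config)
  sub <- config$subcommand %||% stop("config lacks 'subcommand'", call. = FALSE)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  meta <- list(subcommand = sub, seed = seed, parameters = config,
               dropped = list())
  res <- switch(
    sub,
    "simulate" = {
      cf_args <- config[intersect(names(config), names(formals(world_config)))]
      cf <- do.call(world_config, c(cf_args, list(seed = seed)))
      ta <- isTRUE(config$two_animals) || isTRUE(config$two_animals == 1)
      world <- surrogate_world(cf, two_animals = ta)
      write_world(world, out)
      list(world = world)
    },
    "hull" = {
      pts <- read_labeled_matrix(config$points)$values
      hull <- build_hull(pts, p = config$p %||% 5,
                         n_directions = config$n_directions %||% 20000,
                         cone = config$cone %||% "nonnegative_orthant",
                         seed = derive_seed(seed, 1L))
      write_hull_json(hull, file.path(out, "hull.json"))
      mem <- hull_membership(hull)
      jsonlite::write_json(mem, file.path(out, "membership.json"),
                           digits = NA)
      list(hull = hull, membership = mem)
    },
    "conn-compare" = {
      thr <- config$threshold %||% 1
      C1 <- read_connectivity(config$connectivity_a, threshold = thr)
      C2 <- read_connectivity(config$connectivity_b, threshold = thr)
      S1 <- glom_similarity(C1); S2 <- glom_similarity(C2)
      n_perm <- config$n_perm %||% 999
      n_shuf <- config$n_shuffles %||% 100
      d <- config$dimension %||% 2
      cmp <- offdiag_correlation(S1, S2, n_perm = n_perm,
                                 seed = derive_seed(seed, 1L))
      C2s <- shuffle_degree_preserving(C2, seed = derive_seed(seed, 2L))
      cmp_shuf <- offdiag_correlation(S1,
                                      suppressWarnings(glom_similarity(C2s)),
                                      n_perm = n_perm,
                                      seed = derive_seed(seed, 3L))
      sig_pca <- dimension_significance(C1, d_max = d, n_shuffles = n_shuf,
                                        method = "pca",
                                        seed = derive_seed(seed, 4L))
      sig_iso <- dimension_significance(C1, d_max = d, n_shuffles = n_shuf,
                                        method = "isomap",
                                        seed = derive_seed(seed, 5L))
      rmsd_pca <- embedding_rmsd_test(C1, C2, d = d, method = "pca",
                                      n_shuffles = n_shuf,
                                      seed = derive_seed(seed, 6L))
      rmsd_iso <- embedding_rmsd_test(C1, C2, d = d, method = "isomap",
                                      n_shuffles = n_shuf,
                                      seed = derive_seed(seed, 7L))
      write_labeled_matrix(S1, file.path(out, "similarity_A.tsv"))
      write_labeled_matrix(S2, file.path(out, "similarity_B.tsv"))
      stats_out <- list(
        offdiag_r = cmp$r, offdiag_p = cmp$p_value,
        offdiag_r_shuffled = cmp_shuf$r, offdiag_p_shuffled = cmp_shuf$p_value,
        pca_variance = sig_pca$observed, pca_dim_p = sig_pca$p_values,
        isomap_variance = sig_iso$observed, isomap_dim_p = sig_iso$p_values,
        pca_rmsd = rmsd_pca$rmsd, pca_rmsd_null = mean(rmsd_pca$null_rmsd),
        pca_rmsd_p = rmsd_pca$t_test$p.value,
        isomap_rmsd = rmsd_iso$rmsd,
        isomap_rmsd_null = mean(rmsd_iso$null_rmsd),
        isomap_rmsd_p = rmsd_iso$t_test$p.value)
      jsonlite::write_json(stats_out, file.path(out, "conn_compare.json"),
                           auto_unbox = TRUE, digits = NA)
      list(correlation = cmp, correlation_shuffled = cmp_shuf,
           pca = sig_pca, isomap = sig_iso,
           rmsd_pca = rmsd_pca, rmsd_isomap = rmsd_iso)
    },
    "affinity-compare" = {
      C <- read_connectivity(config$connectivity_a,
                             threshold = config$threshold %||% 1)
      A <- read_affinity(config$affinity)
      map <- if (!is.null(config$glom_or_map))
        utils::read.delim(config$glom_or_map, stringsAsFactors = FALSE)
      P <- primacy_matrix(A, p = config$p %||% 5)
      cmp <- connectivity_vs_primacy(
        suppressWarnings(glom_similarity(C)),
        suppressWarnings(primacy_similarity(P)),
        glom_or_map = map, n_perm = config$n_perm %||% 999,
        seed = derive_seed(seed, 1L))
      meta$dropped$odorants <- P$dropped
      jsonlite::write_json(list(r = cmp$r, p_value = cmp$p_value,
                                n_labels = cmp$n_labels),
                           file.path(out, "affinity_compare.json"),
                           auto_unbox = TRUE, digits = NA)
      list(correlation = cmp, primacy = P)
    },
    "enrich" = {
      C <- read_connectivity(config$connectivity_a,
                             threshold = config$threshold %||% 1)
      A <- read_affinity(config$affinity)
      map <- if (!is.null(config$glom_or_map))
        utils::read.delim(config$glom_or_map, stringsAsFactors = FALSE)
      p_max <- config$p_max %||% 8
      enr <- topk_enrichment(C, A, k = config$k %||% 10,
                             p = seq_len(p_max),
                             n_shuffles = config$n_shuffles %||% 200,
                             glom_or_map = map,
                             seed = derive_seed(seed, 1L))
      utils::write.table(as.data.frame(enr),
                         file.path(out, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(enrichment = enr)
    },
    stop("unknown subcommand: ", sub, call. = FALSE)
  )
  jsonlite::write_json(meta, file.path(out, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  invisible(res)
}
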