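#' Curate a matrisome collection by category-scoped exclusion
#'
#' Removes the given genes (typically cytokines and chemokines) from the
#' named category only — by default Secreted Factors — leaving every other
#' category untouched, so that e.g. a symbol shared with Glycoproteins is
#' retained there.
#'
#' @param collection A [gene_set_collection()].
#' @param exclusions Character vector of gene symbols to remove.
#' @param category Category label to curate (default "Secreted Factors").
#' @return The curated collection; per-set removal counts are messaged.
#' @export
curate_matrisome <- function(collection, exclusions,
                             category = "Secreted Factors") {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (!length(exclusions)) return(collection)
  exclusions <- unique(as.character(exclusions))
  present <- exclusions %in% unlist(collection$sets, use.names = FALSE)
  if (any(!present))
    warning("exclusion gene(s) absent from every set: ",
            paste(exclusions[!present], collapse = ", "))
  target <- names(collection$sets)[collection$categories == category]
  for (nm in target) {
    before <- length(collection$sets[[nm]])
    collection$sets[[nm]] <- setdiff(collection$sets[[nm]], exclusions)
    removed <- before - length(collection$sets[[nm]])
    if (removed)
      message(sprintf("curate_matrisome: removed %d gene(s) from '%s'",
                      removed, nm))
    if (!length(collection$sets[[nm]]))
      stop("curation emptied set '", nm, "'")
  }
  collection
}

#' Rank genes within each cell
#'
#' Ranks every cell's genes in descending order of raw counts (rank 1 =
#' highest expression); since downstream AUC scores depend only on ranks,
#' no normalisation is needed. Ties — including the all-zero bulk of a
#' sparse cell — are broken by a seeded random permutation, so the same
#' seed reproduces the same ranking.
#'
#' @param em An [expression_matrix()].
#' @param seed Integer seed for tie-breaking.
#' @return Integer matrix of ranks, genes x cells.
#' @export
rank_genes_per_cell <- function(em, seed = 1L) {
  stopifnot(inherits(em, "expression_matrix"))
  m <- as.matrix(em$counts)
  set.seed(seed)
  r <- apply(m, 2L, function(x) rank(-x, ties.method = "random"))
  rownames(r) <- rownames(m)
  colnames(r) <- colnames(m)
  r
}

#' Recovery-curve AUC enrichment score for one ranking
#'
#' The per-cell gene-set enrichment statistic: walk down the expression
#' ranking to the top `top_fraction` of genes and accumulate the recovery
#' curve f(k) = number of set members at rank <= k. The score is the curve
#' area divided by its maximum possible area,
#' \eqn{\sum_{k=1}^{m} \min(k, |set|)}, with m = ceiling(top_fraction * G),
#' giving a value in \[0, 1\]. The default threshold is the top 10% of the
#' ranking (raised from the conventional 5%).
#'
#' @param ranking Named integer vector of ranks for one cell (1 = highest).
#' @param set Character vector of gene symbols.
#' @param top_fraction Fraction of the ranking used (default 0.10).
#' @return AUC score in \[0, 1\]; 0 with a warning when the set does not
#'   intersect the gene universe.
#' @examples
#' r <- setNames(1:10, paste0("g", 1:10))
#' auc_score(r, c("g1", "g3"), top_fraction = 0.5)   # 8/9
#' @export
auc_score <- function(ranking, set, top_fraction = 0.10) {
  if (top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must lie in (0, 1]")
  G <- length(ranking)
  m <- ceiling(top_fraction * G)
  rk <- ranking[names(ranking) %in% set]
  n_set <- length(rk)
  if (n_set == 0L) {
    warning("gene set does not intersect the gene universe; score 0")
    return(0)
  }
  hits <- rk[rk <= m]
  raw <- sum(m - hits + 1L)
  k <- seq_len(m)
  max_raw <- sum(pmin(k, n_set))
  raw / max_raw
}

#' AUC scores for every cell and every set
#'
#' @param em An [expression_matrix()].
#' @param collection A [gene_set_collection()].
#' @param top_fraction Fraction of the ranking used (default 0.10).
#' @param seed Seed for rank tie-breaking.
#' @param ranking Optional precomputed ranking matrix from
#'   [rank_genes_per_cell()] (overrides `em`/`seed` ranking).
#' @return Object of class `auc_score_table`: data.frame with columns
#'   `cell`, `set`, `score` and attribute `top_fraction`.
#' @export
auc_scores <- function(em, collection, top_fraction = 0.10, seed = 1L,
                       ranking = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (is.null(ranking)) ranking <- rank_genes_per_cell(em, seed)
  G <- nrow(ranking)
  m <- ceiling(top_fraction * G)
  k <- seq_len(m)
  out <- list()
  for (nm in names(collection$sets)) {
    idx <- rownames(ranking) %in% collection$sets[[nm]]
    n_set <- sum(idx)
    if (n_set == 0L) {
      warning("set '", nm, "' does not intersect the gene universe")
      sc <- rep(0, ncol(ranking))
    } else {
      max_raw <- sum(pmin(k, n_set))
      sub <- ranking[idx, , drop = FALSE]
      contrib <- (m - sub + 1L) * (sub <= m)
      sc <- colSums(contrib) / max_raw
    }
    out[[nm]] <- data.frame(cell = colnames(ranking), set = nm, score = sc,
                            row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("auc_score_table", "data.frame"),
            top_fraction = top_fraction)
}

#' Summarise AUC scores per cluster
#'
#' Boxplot-convention summary per (cluster, set): sample size, quartiles,
#' mean, and whiskers extending to the most extreme values within 1.5 IQR
#' of the hinges. Clusters with no cells are omitted.
#'
#' @param scores An [auc_scores()] table.
#' @param cells Cell metadata data.frame with columns `cell` and `cluster`.
#' @return data.frame with one row per (cluster, set).
#' @export
summarize_by_cluster <- function(scores, cells) {
  cl <- cells$cluster[match(scores$cell, cells$cell)]
  if (anyNA(cl))
    stop("every scored cell needs a cluster label")
  out <- list()
  for (key in split(seq_len(nrow(scores)),
                    list(cluster = cl, set = scores$set), drop = TRUE)) {
    x <- scores$score[key]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    lo <- min(x[x >= q[1] - 1.5 * iqr])
    hi <- max(x[x <= q[3] + 1.5 * iqr])
    out[[length(out) + 1L]] <- data.frame(
      cluster = cl[key[1L]], set = scores$set[key[1L]], n = length(x),
      mean = mean(x), q1 = q[1], median = q[2], q3 = q[3],
      whisker_lo = lo, whisker_hi = hi)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$set, res$cluster), ]
}
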