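#' Sum-pseudobulk a single-cell matrix by sample and cluster
#'
#' Collapses raw counts to one column per (sample, cluster) pair by
#' summation, the replicate unit for negative-binomial differential
#' expression. Cells with an empty or missing cluster label are excluded
#' (their count is messaged).
#'
#' @param em An [expression_matrix()].
#' @return List of class `pseudobulk`: `counts` (gene x group matrix) and
#'   `groups` (data.frame `sample`, `cluster`, `condition` per column).
#' @export
pseudobulk_sum <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  cl <- as.character(em$cells$cluster)
  labelled <- !is.na(cl) & nzchar(cl)
  if (any(!labelled))
    message(sprintf("pseudobulk_sum: excluded %d unlabelled cell(s)",
                    sum(!labelled)))
  cells <- em$cells[labelled, , drop = FALSE]
  counts <- em$counts[, labelled, drop = FALSE]
  key <- paste(cells$sample, cells$cluster, sep = "||")
  f <- factor(key, levels = unique(key))
  ind <- Matrix::fac2sparse(f)
  pb <- as.matrix(Matrix::tcrossprod(counts, ind))
  meta <- cells[!duplicated(key), c("sample", "cluster", "condition"),
                drop = FALSE]
  rownames(meta) <- NULL
  colnames(pb) <- paste(meta$sample, meta$cluster, sep = "||")
  structure(list(counts = pb, groups = meta), class = "pseudobulk")
}

#' Pseudobulk negative-binomial differential expression
#'
#' Condition contrast within one cluster on sum-pseudobulked raw counts,
#' via the edgeR pipeline: TMM library-size normalisation, trended/tagwise
#' dispersion estimation, negative-binomial GLM fit and likelihood-ratio
#' test, with p values taken from the LRT and Benjamini-Hochberg adjustment
#' within the cluster.
#'
#' @param pb A [pseudobulk_sum()] result.
#' @param cluster Cluster label to test.
#' @param conditions Optional character vector of the two condition levels,
#'   ordered (contrast is level 2 vs level 1); defaults to sorted unique
#'   conditions.
#' @return data.frame of DEG records: `gene`, `cluster`, `comparison`,
#'   `log2FC`, `pval`, `padj`, `method = "pseudobulk_nb"`.
#' @export
dea_pseudobulk_nb <- function(pb, cluster, conditions = NULL) {
  stopifnot(inherits(pb, "pseudobulk"))
  sel <- pb$groups$cluster == cluster
  if (!any(sel)) stop("no pseudobulk columns for cluster '", cluster, "'")
  counts <- pb$counts[, sel, drop = FALSE]
  cond <- pb$groups$condition[sel]
  if (is.null(conditions)) conditions <- sort(unique(cond))
  if (length(conditions) != 2L)
    stop("need exactly two conditions, got: ",
         paste(unique(cond), collapse = ", "))
  tab <- table(factor(cond, levels = conditions))
  if (any(tab < 2L))
    stop(sprintf("cluster '%s': condition '%s' has %d sample(s); need >= 2",
                 cluster, names(tab)[which.min(tab)], min(tab)))
  grp <- factor(cond, levels = conditions)
  y <- edgeR::DGEList(counts = counts, group = grp)
  y <- edgeR::calcNormFactors(y)
  design <- stats::model.matrix(~grp)
  y <- edgeR::estimateDisp(y, design)
  fit <- edgeR::glmFit(y, design)
  lrt <- edgeR::glmLRT(fit, coef = 2L)
  tt <- lrt$table
  data.frame(gene = rownames(tt), cluster = cluster,
             comparison = paste(conditions[2L], "vs", conditions[1L]),
             log2FC = tt$logFC, pval = tt$PValue,
             padj = stats::p.adjust(tt$PValue, method = "BH"),
             method = "pseudobulk_nb", row.names = NULL)
}

# log-normalised expression: log(1 + count * 1e4 / cell_total)
log_normalize <- function(counts, scale = 1e4) {
  tot <- Matrix::colSums(counts)
  tot[tot == 0] <- 1
  m <- as.matrix(counts)
  log1p(sweep(m, 2L, scale / tot, "*"))
}

#' Hurdle-model single-cell differential expression
#'
#' Two-part hurdle test per gene on log-normalised expression
#' (log(1 + count * 1e4 / cell total)): a binomial likelihood-ratio test on
#' the detection rate plus a Gaussian likelihood-ratio test on the positive
#' values, combined as a chi-square with degrees of freedom equal to the
#' number of contributing parts. When a gene is detected in no cell of one
#' group the continuous part is dropped (df reduced). The reported log2FC
#' is the difference of mean log-normalised expression between conditions,
#' in log2 units.
#'
#' @param em An [expression_matrix()].
#' @param cluster Cluster label to test (NULL for all cells).
#' @param conditions Optional ordered pair of condition levels (contrast is
#'   level 2 vs level 1).
#' @return data.frame of DEG records with `method = "hurdle"`.
#' @export
dea_hurdle <- function(em, cluster = NULL, conditions = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  keep <- if (is.null(cluster)) rep(TRUE, ncol(em$counts)) else
    em$cells$cluster == cluster
  if (!any(keep)) stop("no cells in cluster '", cluster, "'")
  cond <- em$cells$condition[keep]
  if (is.null(conditions)) conditions <- sort(unique(cond))
  if (length(conditions) != 2L) stop("need exactly two conditions")
  ln <- log_normalize(em$counts[, keep, drop = FALSE])
  ga <- cond == conditions[1L]; gb <- cond == conditions[2L]
  n_a <- sum(ga); n_b <- sum(gb)
  res <- lapply(seq_len(nrow(ln)), function(i) {
    x <- ln[i, ]
    det <- x > 0
    a_a <- sum(det[ga]); a_b <- sum(det[gb])
    lfc <- (mean(x[gb]) - mean(x[ga])) / log(2)
    if (a_a + a_b == 0L)
      return(data.frame(gene = rownames(ln)[i], log2FC = 0, pval = 1,
                        df = 0L))
    # discrete part: binomial G-test of detection rate
    lr_disc <- {
      p_pool <- (a_a + a_b) / (n_a + n_b)
      ll <- function(a, n, p) {
        out <- 0
        if (a > 0) out <- out + a * log(p)
        if (n - a > 0) out <- out + (n - a) * log(1 - p)
        out
      }
      p_a <- a_a / n_a; p_b <- a_b / n_b
      2 * (ll(a_a, n_a, p_a) + ll(a_b, n_b, p_b) -
             ll(a_a, n_a, p_pool) - ll(a_b, n_b, p_pool))
    }
    stat <- lr_disc; df <- 1L
    # continuous part: Gaussian LR on positive values, needs both groups
    xa <- x[ga & det]; xb <- x[gb & det]
    if (length(xa) >= 1L && length(xb) >= 1L &&
        length(xa) + length(xb) >= 3L) {
      pool <- c(xa, xb)
      rss1 <- sum((xa - mean(xa))^2) + sum((xb - mean(xb))^2)
      rss0 <- sum((pool - mean(pool))^2)
      if (rss1 > 0 && rss0 > 0) {
        stat <- stat + length(pool) * log(rss0 / rss1)
        df <- df + 1L
      } else if (rss0 > rss1) {   # perfect within-group fit, real shift
        stat <- stat + 1e6
        df <- df + 1L
      }
    }
    data.frame(gene = rownames(ln)[i], log2FC = lfc,
               pval = stats::pchisq(stat, df = df, lower.tail = FALSE),
               df = df)
  })
  out <- do.call(rbind, res)
  data.frame(gene = out$gene,
             cluster = if (is.null(cluster)) NA_character_ else cluster,
             comparison = paste(conditions[2L], "vs", conditions[1L]),
             log2FC = out$log2FC, pval = out$pval,
             padj = stats::p.adjust(out$pval, method = "BH"),
             method = "hurdle", row.names = NULL)
}

#' One-vs-rest cluster marker detection
#'
#' Wilcoxon rank-sum marker test per cluster on log-normalised expression,
#' restricted to genes detected in at least `min_pct` of in-cluster cells
#' and with an average log2 fold change of at least `min_log2fc` versus all
#' other cells; BH adjustment within each cluster.
#'
#' @param em An [expression_matrix()].
#' @param min_pct Minimum in-cluster detection fraction (default 0.25).
#' @param min_log2fc Minimum absolute log2 fold change (default 0.25).
#' @return data.frame of marker records with `method = "wilcoxon"`, ordered
#'   within cluster by increasing p value.
#' @export
find_cluster_markers <- function(em, min_pct = 0.25, min_log2fc = 0.25) {
  stopifnot(inherits(em, "expression_matrix"))
  cl <- as.character(em$cells$cluster)
  clusters <- sort(unique(cl[!is.na(cl) & nzchar(cl)]))
  if (length(clusters) < 2L) stop("need at least 2 clusters")
  ln <- log_normalize(em$counts)
  out <- list()
  for (k in clusters) {
    inb <- cl == k
    pct_in <- rowMeans(ln[, inb, drop = FALSE] > 0)
    lfc <- (rowMeans(ln[, inb, drop = FALSE]) -
              rowMeans(ln[, !inb, drop = FALSE])) / log(2)
    pass <- pct_in >= min_pct & abs(lfc) >= min_log2fc
    if (!any(pass)) next
    idx <- which(pass)
    pv <- vapply(idx, function(i) {
      stats::wilcox.test(ln[i, inb], ln[i, !inb], exact = FALSE)$p.value
    }, 0)
    rec <- data.frame(gene = rownames(ln)[idx], cluster = k,
                      comparison = paste(k, "vs rest"),
                      log2FC = lfc[idx], pct_in = pct_in[idx],
                      pval = pv,
                      padj = stats::p.adjust(pv, method = "BH"),
                      method = "wilcoxon", row.names = NULL)
    out[[k]] <- rec[order(rec$pval), ]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Differential-expression score
#'
#' The prioritisation score `|(-log10(pval)) * log2FC|`: rather than a hard
#' significance call, genes are placed on a spectrum of differential
#' expression combining evidence strength and effect size. The score is
#' symmetric in the sign of the fold change and monotone in both
#' `-log10(p)` and `|log2FC|`. Zero p values are clamped to the smallest
#' positive double.
#'
#' @param pval Raw p value(s) in (0, 1].
#' @param log2FC Log2 fold change(s).
#' @return Non-negative score(s).
#' @examples
#' de_score(0.01, 2)     # 4
#' de_score(1e-4, -3)    # 12
#' @export
de_score <- function(pval, log2FC) {
  if (any(!is.finite(log2FC))) stop("log2FC must be finite")
  if (any(pval < 0 | pval > 1, na.rm = TRUE))
    stop("pval must lie in [0, 1]")
  clamped <- pval == 0
  if (any(clamped, na.rm = TRUE)) {
    message(sprintf("de_score: clamped %d zero p value(s)",
                    sum(clamped, na.rm = TRUE)))
    pval[clamped] <- .Machine$double.xmin
  }
  abs(-log10(pval) * log2FC)
}

#' Three-metric target prioritisation
#'
#' Ranks matrisome DEGs by (1) overlap between the two human DEA methods
#' (significant by both, with the same fold-change sign), (2) conservation
#' of the expression pattern in the mouse arthritis-model data
#' (case-insensitive symbol match, same sign, significant by at least one
#' method), and (3) the differential-expression score
#' `|(-log10(pval)) * log2FC|`. Genes are ordered by tier — triple overlap
#' (both flags), then one flag, then none — with the mean de_score across
#' human methods as the within-tier key.
#'
#' @param human_degs data.frame of DEG records from the two human methods
#'   (rbind of [dea_pseudobulk_nb()] and [dea_hurdle()] output for the same
#'   comparison).
#' @param mouse_degs data.frame of DEG records for the mouse data (any
#'   method), or NULL when no mouse data are available.
#' @param matrisome A [gene_set_collection()]; only its genes are ranked.
#' @param sig_padj Adjusted-p significance threshold (default 0.05).
#' @param sig_log2fc Minimum absolute log2FC for significance
#'   (default 0.25).
#' @param top_n Keep the top N targets per cluster (default Inf).
#' @return data.frame of class `prioritized_targets` with columns `gene`,
#'   `cluster`, `de_score`, `method_overlap`, `species_conserved`,
#'   `triple_overlap`, `tier`, `rank` (within cluster).
#' @export
prioritize_targets <- function(human_degs, mouse_degs, matrisome,
                               sig_padj = 0.05, sig_log2fc = 0.25,
                               top_n = Inf) {
  stopifnot(inherits(matrisome, "gene_set_collection"))
  matg <- toupper(unique(unlist(matrisome$sets, use.names = FALSE)))
  hd <- human_degs[toupper(human_degs$gene) %in% matg, , drop = FALSE]
  if (!nrow(hd))
    stop("no human DEG overlaps the matrisome collection")
  hd$sig <- hd$padj < sig_padj & abs(hd$log2FC) >= sig_log2fc
  hd$score <- de_score(hd$pval, hd$log2FC)
  if (!is.null(mouse_degs)) {
    mouse_degs$sig <- mouse_degs$padj < sig_padj &
      abs(mouse_degs$log2FC) >= sig_log2fc
    msig <- mouse_degs[mouse_degs$sig, , drop = FALSE]
  } else {
    msig <- NULL
  }
  methods_all <- unique(hd$method)
  out <- list()
  for (key in split(seq_len(nrow(hd)),
                    list(gene = hd$gene, cluster = hd$cluster),
                    drop = TRUE)) {
    rec <- hd[key, , drop = FALSE]
    sig <- rec[rec$sig, , drop = FALSE]
    method_overlap <- length(methods_all) >= 2L &&
      all(methods_all %in% sig$method) &&
      length(unique(sign(sig$log2FC))) == 1L
    sgn <- if (nrow(sig)) sign(sig$log2FC[1L]) else
      sign(rec$log2FC[which.max(rec$score)])
    species_conserved <- FALSE
    if (!is.null(msig) && nrow(msig) && nrow(sig)) {
      mm <- msig[toupper(msig$gene) == toupper(rec$gene[1L]), ,
                 drop = FALSE]
      species_conserved <- any(sign(mm$log2FC) == sgn)
    }
    out[[length(out) + 1L]] <- data.frame(
      gene = rec$gene[1L], cluster = rec$cluster[1L],
      de_score = mean(rec$score),
      method_overlap = method_overlap,
      species_conserved = species_conserved,
      triple_overlap = method_overlap && species_conserved)
  }
  res <- do.call(rbind, out)
  res$tier <- res$method_overlap + res$species_conserved
  res <- res[order(res$cluster, -res$tier, -res$de_score), ]
  res$rank <- stats::ave(seq_len(nrow(res)), res$cluster,
                         FUN = seq_along)
  res <- res[res$rank <= top_n, , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("prioritized_targets", "data.frame"))
}

#' Cross-disease cassette overlap
#'
#' Venn-style overlap between two diseases' DEG lists, computed per stratum
#' (lining / sub-lining) and direction (up / down): the shared cassette is
#' the intersection, and the disease-unique sets are the set differences.
#' The three sets are pairwise disjoint and union to the two input lists.
#'
#' @param degs_a,degs_b Nested named lists: stratum -> direction -> character
#'   vector of gene symbols (e.g. `list(lining = list(up = ..., down =
#'   ...))`). Both inputs must share the same strata and directions.
#' @return data.frame of class `cassette_result` with one row per
#'   (stratum, direction): counts `n_shared`, `n_unique_a`, `n_unique_b`
#'   and list-columns `shared`, `unique_a`, `unique_b`.
#' @export
cassette_overlap <- function(degs_a, degs_b) {
  strata <- names(degs_a)
  if (!setequal(strata, names(degs_b)))
    stop("the two DEG lists must cover the same strata")
  rows <- list()
  for (st in strata) {
    dirs <- names(degs_a[[st]])
    if (!setequal(dirs, names(degs_b[[st]])))
      stop("stratum '", st, "': directions differ between inputs")
    for (dr in dirs) {
      a <- unique(degs_a[[st]][[dr]]); b <- unique(degs_b[[st]][[dr]])
      sh <- sort(intersect(a, b))
      ua <- sort(setdiff(a, b)); ub <- sort(setdiff(b, a))
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = st, direction = dr,
        n_shared = length(sh), n_unique_a = length(ua),
        n_unique_b = length(ub))
      rows[[length(rows)]]$shared <- list(sh)
      rows[[length(rows)]]$unique_a <- list(ua)
      rows[[length(rows)]]$unique_b <- list(ub)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  structure(res, class = c("cassette_result", "data.frame"))
}
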