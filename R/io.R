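#' Gene-set collections with matrisome categories
#'
#' A `gene_set_collection` is a named list of unique gene symbols per set,
#' together with a category label per set (e.g. the matrisome divisions:
#' Collagens, Glycoproteins, Proteoglycans, ECM-affiliated Proteins,
#' ECM Regulators, Secreted Factors).
#'
#' @param sets Named list of character vectors of gene symbols.
#' @param categories Character vector of category labels, one per set.
#'   Defaults to the set names.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, categories = names(sets)) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("every gene set must be named")
  if (anyDuplicated(names(sets)))
    stop("duplicate set names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets <- lapply(sets, function(g) unique(as.character(g[nzchar(g)])))
  empty <- names(sets)[lengths(sets) == 0L]
  if (length(empty))
    stop("empty gene set(s): ", paste(empty, collapse = ", "))
  categories <- as.character(categories)
  if (length(categories) != length(sets))
    stop("need one category label per set")
  names(categories) <- names(sets)
  structure(list(sets = sets, categories = categories),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection with %d sets\n", length(x$sets)))
  for (nm in names(x$sets))
    cat(sprintf("  %-28s [%s] %d genes\n", nm, x$categories[[nm]],
                length(x$sets[[nm]])))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read gene sets from GMT or a two-column table
#'
#' GMT lines are `name<TAB>description<TAB>gene1<TAB>gene2...`; the
#' description field is kept as the category label. The table format needs
#' columns `gene` and `category`; each category becomes one set. Gene
#' symbols are case-preserved and de-duplicated within a set.
#'
#' @param path Path to the file.
#' @param format `"gmt"` or `"table"`.
#' @return A [gene_set_collection()].
#' @export
read_gene_sets <- function(path, format = c("gmt", "table")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("gene set file not found: ", path)
  if (format == "gmt") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 3L)
    if (length(bad))
      stop("malformed GMT line(s) (need name, description, >=1 gene): line ",
           paste(bad, collapse = ", "))
    nms <- vapply(parts, `[[`, "", 1L)
    cats <- vapply(parts, `[[`, "", 2L)
    sets <- lapply(parts, function(p) p[-(1:2)])
    names(sets) <- nms
    gene_set_collection(sets, cats)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE)
    if (!all(c("gene", "category") %in% names(tab)))
      stop("table format requires columns 'gene' and 'category'")
    sets <- split(tab$gene, tab$category)
    gene_set_collection(sets, names(sets))
  }
}

#' Write gene sets to GMT or a two-column table
#'
#' @param collection A [gene_set_collection()].
#' @param path Output file path.
#' @param format `"gmt"` or `"table"`.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(collection, path, format = c("gmt", "table")) {
  format <- match.arg(format)
  stopifnot(inherits(collection, "gene_set_collection"))
  if (format == "gmt") {
    lines <- vapply(names(collection$sets), function(nm) {
      paste(c(nm, collection$categories[[nm]], collection$sets[[nm]]),
            collapse = "\t")
    }, "")
    writeLines(lines, path)
  } else {
    tab <- do.call(rbind, lapply(names(collection$sets), function(nm) {
      data.frame(gene = collection$sets[[nm]],
                 category = collection$categories[[nm]])
    }))
    utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Single-cell expression container
#'
#' Bundles a sparse genes-by-cells count matrix with per-cell metadata
#' (`cell`, `sample`, `condition`, `cluster`). Counts must be non-negative;
#' duplicate gene symbols are aggregated by summation.
#'
#' @param counts Matrix or sparse `dgCMatrix`, genes in rows, cells in
#'   columns, with dimnames.
#' @param cells data.frame with one row per cell and columns `sample`,
#'   `condition`, `cluster` (cluster may contain empty strings / NA for
#'   unassigned cells).
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(counts, cells) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene rownames and cell colnames")
  if (any(counts@x < 0))
    stop("negative counts are not allowed")
  req <- c("sample", "condition", "cluster")
  if (!all(req %in% names(cells)))
    stop("cell metadata must have columns: ", paste(req, collapse = ", "))
  if (nrow(cells) != ncol(counts))
    stop(sprintf("cell metadata rows (%d) do not match matrix columns (%d)",
                 nrow(cells), ncol(counts)))
  if (is.null(cells$cell)) cells$cell <- colnames(counts)
  if (anyDuplicated(rownames(counts))) {
    dup <- unique(rownames(counts)[duplicated(rownames(counts))])
    message(sprintf("aggregating %d duplicated gene symbol(s) by sum: %s",
                    length(dup), paste(utils::head(dup, 5), collapse = ", ")))
    agg <- Matrix::fac2sparse(factor(rownames(counts),
                                     levels = unique(rownames(counts))))
    counts <- methods::as(agg %*% counts, "CsparseMatrix")
  }
  structure(list(counts = counts, cells = cells),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d cells (%d samples, %d clusters)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cells$sample)),
              length(unique(stats::na.omit(x$cells$cluster)))))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$counts)

#' Read an expression matrix from MatrixMarket + metadata TSVs
#'
#' @param matrix_path MTX (MatrixMarket coordinate) file, genes x cells.
#' @param genes_path TSV with a `gene` column (or single unnamed column),
#'   one row per matrix row.
#' @param cells_path TSV with columns `sample`, `condition`, `cluster` (and
#'   optionally `cell`), one row per matrix column.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(matrix_path, genes_path, cells_path) {
  m <- Matrix::readMM(matrix_path)
  genes <- utils::read.delim(genes_path, stringsAsFactors = FALSE)
  cells <- utils::read.delim(cells_path, stringsAsFactors = FALSE)
  gcol <- if ("gene" %in% names(genes)) genes$gene else genes[[1L]]
  if (nrow(genes) != nrow(m) || nrow(cells) != ncol(m))
    stop(sprintf(
      "dimension mismatch: matrix is %d x %d but found %d genes, %d cells",
      nrow(m), ncol(m), nrow(genes), nrow(cells)))
  if (any(m@x < 0)) stop("negative counts in ", matrix_path)
  rownames(m) <- gcol
  colnames(m) <- if ("cell" %in% names(cells)) cells$cell else
    paste0("cell", seq_len(ncol(m)))
  expression_matrix(m, cells)
}

#' Write an expression matrix to MTX + metadata TSVs
#'
#' @param em An [expression_matrix()].
#' @param matrix_path,genes_path,cells_path Output paths.
#' @return `matrix_path`, invisibly.
#' @export
write_expression_matrix <- function(em, matrix_path, genes_path, cells_path) {
  stopifnot(inherits(em, "expression_matrix"))
  Matrix::writeMM(em$counts, matrix_path)
  utils::write.table(data.frame(gene = rownames(em$counts)), genes_path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(em$cells, cells_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(matrix_path)
}

#' Read an identified-peptide table against its protein FASTA
#'
#' Validates that every peptide's claimed coordinates reproduce its sequence
#' from the protein, erroring on the first offending record. Quantification
#' columns (any column starting `abundance_` or `spectral_`) are preserved;
#' both kinds may coexist and the analysis mode is chosen downstream.
#'
#' @param path TSV with columns `accession`, `start`, `end`, `sequence` plus
#'   quantification columns.
#' @param fasta_path Protein FASTA containing every accession in the table.
#' @return A data.frame of peptide records with attribute `"proteins"`
#'   holding the named character vector of protein sequences.
#' @export
read_peptide_table <- function(path, fasta_path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  req <- c("accession", "start", "end", "sequence")
  if (!all(req %in% names(tab)))
    stop("peptide table needs columns: ", paste(req, collapse = ", "))
  aa <- Biostrings::readAAStringSet(fasta_path)
  prots <- stats::setNames(as.character(aa),
                           vapply(strsplit(names(aa), "\\s+"), `[[`, "", 1L))
  miss <- setdiff(unique(tab$accession), names(prots))
  if (length(miss))
    stop("accession(s) missing from FASTA: ", paste(miss, collapse = ", "))
  for (i in seq_len(nrow(tab))) {
    seq <- prots[[tab$accession[i]]]
    s <- tab$start[i]; e <- tab$end[i]
    if (s < 1L || e > nchar(seq) || s > e)
      stop(sprintf("peptide %s (%s %d-%d): coordinates out of range",
                   tab$sequence[i], tab$accession[i], s, e))
    sub <- substr(seq, s, e)
    if (sub != tab$sequence[i])
      stop(sprintf(
        "peptide %s (%s %d-%d) does not match protein substring %s",
        tab$sequence[i], tab$accession[i], s, e, sub))
  }
  attr(tab, "proteins") <- prots
  tab
}

#' Write a peptide table
#'
#' @param peptides Peptide data.frame (e.g. from [read_peptide_table()] or
#'   [simulate_degradome()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(peptides, path) {
  utils::write.table(peptides, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a region set to GeoJSON
#'
#' Emits an RFC 7946 FeatureCollection of Polygon features with properties
#' `label` (rich / poor / perivascular) and `area_um2`. Coordinates are in
#' micrometres (Cartesian, arbitrary origin). Self-intersecting polygons are
#' rejected.
#'
#' @param regions A [region_set()].
#' @param path Output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  stopifnot(inherits(regions, "region_set"))
  feats <- lapply(seq_along(regions$polygons), function(i) {
    poly <- regions$polygons[[i]]
    if (polygon_self_intersects(poly))
      stop(sprintf("region %d (%s) is self-intersecting", i,
                   regions$labels[i]))
    ring <- rbind(poly, poly[1L, , drop = FALSE])
    list(
      type = "Feature",
      properties = list(label = regions$labels[i],
                        area_um2 = regions$areas[i]),
      geometry = list(type = "Polygon",
                      coordinates = list(unname(
                        lapply(seq_len(nrow(ring)),
                               function(j) as.numeric(ring[j, 1:2]))))))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a region set from GeoJSON
#'
#' @param path A `.geojson` file written by [write_regions()].
#' @return A [region_set()].
#' @export
read_regions <- function(path) {
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection"))
    stop("not a GeoJSON FeatureCollection: ", path)
  polys <- list(); labels <- character(0); areas <- numeric(0)
  for (ft in fc$features) {
    ring <- ft$geometry$coordinates[[1L]]
    xy <- do.call(rbind, lapply(ring, function(p)
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
    xy <- xy[-nrow(xy), , drop = FALSE]   # drop closing vertex
    colnames(xy) <- c("x", "y")
    polys[[length(polys) + 1L]] <- xy
    labels <- c(labels, ft$properties$label)
    areas <- c(areas, as.numeric(ft$properties$area_um2))
  }
  region_set(polys, labels, areas)
}
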