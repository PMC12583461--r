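# Synthetic-data generators. Every generator is a pure function of
# (spec, seed): the same pair reproduces byte-identical outputs, and the
# returned ground truth is sufficient to score the downstream stage.

#' Specification for the single-cell count simulator
#'
#' Describes a cluster-structured negative-binomial scRNA-seq experiment
#' over two conditions, with optional planted matrisome programs (a gene
#' set upregulated by a multiplier in one cluster) and planted
#' condition-DEGs, some of which are shared with a second "species"
#' replica. The negative binomial is parameterised by mean and dispersion
#' (variance = mu + mu^2 * dispersion).
#'
#' @param n_clusters Number of cell clusters.
#' @param cells_per_cluster Cells per cluster per sample.
#' @param n_genes Gene universe size.
#' @param n_samples_per_condition Biological replicates per condition.
#' @param conditions Two condition labels; planted DEG fold changes apply
#'   to the second relative to the first.
#' @param nb_mean Baseline mean count scale; per-gene means are drawn from
#'   a gamma distribution with this mean.
#' @param nb_dispersion NB dispersion (> 0).
#' @param planted_program NULL, or `list(cluster =, genes =, multiplier =)`
#'   boosting the gene set's mean in one cluster.
#' @param planted_degs NULL, or data.frame with columns `gene`, `cluster`,
#'   `log2FC`, `shared` (logical: also planted, same sign, in the second
#'   species).
#' @return Object of class `sc_sim_spec`.
#' @export
sc_sim_spec <- function(n_clusters = 4L, cells_per_cluster = 25L,
                        n_genes = 2000L, n_samples_per_condition = 4L,
                        conditions = c("remission", "active"),
                        nb_mean = 2, nb_dispersion = 0.4,
                        planted_program = NULL, planted_degs = NULL) {
  stopifnot(n_clusters >= 1L, cells_per_cluster >= 1L, n_genes >= 1L,
            n_samples_per_condition >= 1L, length(conditions) == 2L,
            nb_mean > 0, nb_dispersion > 0)
  genes <- sprintf("G%04d", seq_len(n_genes))
  if (!is.null(planted_program)) {
    stopifnot(all(c("cluster", "genes", "multiplier") %in%
                    names(planted_program)))
    if (!all(planted_program$genes %in% genes))
      stop("planted program genes outside the gene universe")
    if (planted_program$multiplier <= 0)
      stop("program multiplier must be > 0")
  }
  if (!is.null(planted_degs)) {
    stopifnot(all(c("gene", "cluster", "log2FC", "shared") %in%
                    names(planted_degs)))
    if (!all(planted_degs$gene %in% genes))
      stop("planted DEGs outside the gene universe")
    if (any(!is.finite(planted_degs$log2FC)))
      stop("planted log2FC must be finite")
  }
  structure(list(n_clusters = n_clusters,
                 cells_per_cluster = cells_per_cluster,
                 n_genes = n_genes, genes = genes,
                 n_samples_per_condition = n_samples_per_condition,
                 conditions = conditions, nb_mean = nb_mean,
                 nb_dispersion = nb_dispersion,
                 planted_program = planted_program,
                 planted_degs = planted_degs),
            class = "sc_sim_spec")
}

# mouse-style title-case symbols for the species replica
title_case_symbol <- function(x) {
  paste0(toupper(substr(x, 1L, 1L)), tolower(substr(x, 2L, nchar(x))))
}

#' Simulate cluster-structured single-cell counts
#'
#' Draws negative-binomial counts per gene, cluster, sample and condition,
#' applies the planted program multiplier and planted DEG fold changes,
#' and emits a paired second-species matrix in which the shared planted
#' DEGs carry the same fold-change sign (gene symbols title-cased, as for
#' mouse). Ground truth lists every planted effect.
#'
#' @param spec An [sc_sim_spec()].
#' @param seed Integer seed.
#' @return List with elements `human` (an [expression_matrix()]), `mouse`
#'   (ditto, title-case symbols) and `truth` (list with `program` and
#'   `degs`).
#' @export
simulate_sc_counts <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "sc_sim_spec"))
  set.seed(seed)
  gene_mean <- stats::rgamma(spec$n_genes, shape = 1.5,
                             scale = spec$nb_mean / 1.5) + 0.05
  names(gene_mean) <- spec$genes
  clusters <- sprintf("C%d", seq_len(spec$n_clusters))
  build <- function(species) {
    cols <- list(); meta <- list()
    for (ci in seq_along(spec$conditions)) {
      cond <- spec$conditions[ci]
      for (s in seq_len(spec$n_samples_per_condition)) {
        samp <- sprintf("%s_%s_s%d", species, cond, s)
        for (cl in clusters) {
          mu <- gene_mean
          if (!is.null(spec$planted_program) &&
              spec$planted_program$cluster == cl)
            mu[spec$planted_program$genes] <-
              mu[spec$planted_program$genes] *
              spec$planted_program$multiplier
          if (ci == 2L && !is.null(spec$planted_degs)) {
            pd <- spec$planted_degs
            if (species == "mouse") pd <- pd[pd$shared, , drop = FALSE]
            pd <- pd[pd$cluster == cl, , drop = FALSE]
            if (nrow(pd))
              mu[pd$gene] <- mu[pd$gene] * 2^pd$log2FC
          }
          n <- spec$cells_per_cluster
          cnt <- matrix(stats::rnbinom(spec$n_genes * n,
                                       mu = rep(mu, n),
                                       size = 1 / spec$nb_dispersion),
                        nrow = spec$n_genes)
          cols[[length(cols) + 1L]] <- cnt
          meta[[length(meta) + 1L]] <- data.frame(
            sample = samp, condition = cond, cluster = cl,
            n = n)
        }
      }
    }
    counts <- do.call(cbind, cols)
    rownames(counts) <- if (species == "mouse")
      title_case_symbol(spec$genes) else spec$genes
    md <- do.call(rbind, meta)
    cells <- data.frame(
      cell = sprintf("%s_cell%06d", species, seq_len(ncol(counts))),
      sample = rep(md$sample, md$n),
      condition = rep(md$condition, md$n),
      cluster = rep(md$cluster, md$n))
    colnames(counts) <- cells$cell
    expression_matrix(counts, cells)
  }
  human <- build("human")
  mouse <- build("mouse")
  truth <- list(program = spec$planted_program, degs = spec$planted_degs,
                conditions = spec$conditions)
  list(human = human, mouse = mouse, truth = truth)
}

#' Specification for the degradome simulator
#'
#' Describes proteins, planted endogenous cleavage sites, and
#' condition-dependent cleavage rates for generating identified-peptide
#' tables with both fully tryptic and semi-tryptic records. Planted sites
#' must not coincide with tryptic cleavage sites (the ground truth would
#' be ambiguous) and must lie beyond the protein N-terminal exclusion
#' window.
#'
#' @param proteins Named character vector of sequences; defaults to the
#'   packaged synthetic toy collagen-like chains.
#' @param endogenous_cleavage_sites Named list (accession -> integer
#'   positions in \[3, length-1\]); defaults to three evenly spaced
#'   non-tryptic positions per protein.
#' @param cleavage_rate_by_condition Named probabilities per condition
#'   (default `c(RA = 0.4, OA = 0.1)`).
#' @param abundance_meanlog,abundance_sdlog Log-normal abundance
#'   parameters (default meanlog 10, sdlog 0.5).
#' @param spectral_poisson_mean Mean tryptic spectral count (default 20).
#' @param n_samples_per_condition Samples per condition (default 5).
#' @param missed_cleavages Digest depth for the tryptic background
#'   (default 2).
#' @return Object of class `degradome_sim_spec`.
#' @export
degradome_sim_spec <- function(proteins = NULL,
                               endogenous_cleavage_sites = NULL,
                               cleavage_rate_by_condition =
                                 c(RA = 0.4, OA = 0.1),
                               abundance_meanlog = 10,
                               abundance_sdlog = 0.5,
                               spectral_poisson_mean = 20,
                               n_samples_per_condition = 5L,
                               missed_cleavages = 2L) {
  if (is.null(proteins)) {
    fa <- system.file("extdata", "toy_collagen_synthetic.fasta",
                      package = "matriturn")
    aa <- Biostrings::readAAStringSet(fa)
    proteins <- stats::setNames(
      as.character(aa),
      vapply(strsplit(names(aa), "\\s+"), `[[`, "", 1L))
  }
  if (any(cleavage_rate_by_condition < 0 |
            cleavage_rate_by_condition > 1))
    stop("cleavage rates must lie in [0, 1]")
  if (is.null(names(cleavage_rate_by_condition)))
    stop("cleavage rates must be named by condition")
  if (is.null(endogenous_cleavage_sites)) {
    endogenous_cleavage_sites <- lapply(proteins, function(seq) {
      res <- strsplit(seq, "")[[1L]]
      tryptic <- cleavage_sites(res)
      cand <- setdiff(seq(3L, nchar(seq) - 1L), tryptic)
      cand[round(seq(1L, length(cand), length.out = 3L))]
    })
  }
  for (acc in names(endogenous_cleavage_sites)) {
    if (!acc %in% names(proteins)) stop("unknown accession: ", acc)
    seq <- proteins[[acc]]
    pos <- endogenous_cleavage_sites[[acc]]
    if (any(pos < 3L | pos > nchar(seq) - 1L))
      stop("planted sites for ", acc, " must lie in [3, length-1]")
    tryptic <- cleavage_sites(strsplit(seq, "")[[1L]])
    amb <- intersect(pos, tryptic)
    if (length(amb))
      stop("planted site(s) coincide with tryptic sites in ", acc, ": ",
           paste(amb, collapse = ", "), " (ambiguous ground truth)")
  }
  structure(list(proteins = proteins,
                 endogenous_cleavage_sites = endogenous_cleavage_sites,
                 cleavage_rate_by_condition = cleavage_rate_by_condition,
                 abundance_meanlog = abundance_meanlog,
                 abundance_sdlog = abundance_sdlog,
                 spectral_poisson_mean = spectral_poisson_mean,
                 n_samples_per_condition = n_samples_per_condition,
                 missed_cleavages = missed_cleavages),
            class = "degradome_sim_spec")
}

#' Simulate an identified-peptide table with planted degradation
#'
#' Emits the fully tryptic digest of every protein (log-normal abundances,
#' Poisson spectral counts) plus one semi-tryptic peptide per planted
#' endogenous cleavage site, running from the residue after the site to
#' the next tryptic boundary. Semi-tryptic signal is condition-dependent:
#' spectral counts are Poisson with mean scaled by the condition's
#' cleavage rate, and abundances are drawn from the tryptic log-normal
#' scaled by the same rate (missing when the count is zero).
#'
#' @param spec A [degradome_sim_spec()].
#' @param seed Integer seed.
#' @return List with `peptides` (data.frame with `accession`, `start`,
#'   `end`, `sequence` and `abundance_*` / `spectral_*` columns; attribute
#'   `"proteins"`) and `truth` (planted sites and rates).
#' @export
simulate_degradome <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "degradome_sim_spec"))
  set.seed(seed)
  conds <- names(spec$cleavage_rate_by_condition)
  samples <- unlist(lapply(conds, function(cd)
    sprintf("%s_%d", cd, seq_len(spec$n_samples_per_condition))))
  samp_cond <- stats::setNames(rep(conds,
                                   each = spec$n_samples_per_condition),
                               samples)
  rows <- list()
  for (acc in names(spec$proteins)) {
    seq <- spec$proteins[[acc]]
    dig <- digest_protein(seq, spec$missed_cleavages)
    dig$accession <- acc
    dig$is_semi <- FALSE
    sites <- spec$endogenous_cleavage_sites[[acc]]
    bounds <- c(cleavage_sites(strsplit(seq, "")[[1L]]), nchar(seq))
    semi <- lapply(sites, function(p) {
      e <- min(bounds[bounds > p])
      data.frame(start = p + 1L, end = e,
                 sequence = substr(seq, p + 1L, e), n_missed = 0L,
                 accession = acc, is_semi = TRUE)
    })
    rows[[acc]] <- rbind(dig, do.call(rbind, semi))
  }
  pep <- do.call(rbind, rows)
  rownames(pep) <- NULL
  n <- nrow(pep)
  for (s in samples) {
    rate <- spec$cleavage_rate_by_condition[[samp_cond[[s]]]]
    lam <- ifelse(pep$is_semi, spec$spectral_poisson_mean * rate,
                  spec$spectral_poisson_mean)
    cnt <- stats::rpois(n, lam)
    ab <- stats::rlnorm(n, spec$abundance_meanlog, spec$abundance_sdlog) *
      ifelse(pep$is_semi, rate, 1)
    ab[pep$is_semi & cnt == 0L] <- NA_real_
    pep[[paste0("spectral_", s)]] <- cnt
    pep[[paste0("abundance_", s)]] <- ab
  }
  truth <- list(sites = spec$endogenous_cleavage_sites,
                rates = spec$cleavage_rate_by_condition,
                sample_condition = samp_cond,
                semi_index = which(pep$is_semi))
  out <- pep[, c("accession", "start", "end", "sequence",
                 grep("^(spectral|abundance)_", names(pep),
                      value = TRUE))]
  attr(out, "proteins") <- spec$proteins
  list(peptides = out, truth = truth)
}

#' Specification for the tissue simulator
#'
#' Describes a square tissue field with vessels, fibre-poor "dark zone"
#' discs around a fraction of the vessels, an inhomogeneous fibre point
#' process (dense outside dark zones, thinned inside), and cell phenotypes
#' with optional placement preference toward fibre-rich or fibre-poor
#' tissue. Defaults are chosen to mimic imaged synovial sections at desk
#' scale: a 600 um field, 5 vessels, 120 um dark zones around 80% of them,
#' 0.003 fibres/um^2 in rich tissue with 5% thinning inside dark zones,
#' and 1200 cells over four phenotypes.
#'
#' @param field_size_um Side of the square field (default 600).
#' @param n_vessels Number of vessels (default 5).
#' @param dark_zone_vessel_fraction Fraction of vessels nucleating a dark
#'   zone (default 0.8).
#' @param dark_zone_radius_um Dark-zone disc radius (default 120).
#' @param fibre_intensity_rich Fibre intensity outside dark zones
#'   (fibres/um^2, default 0.003).
#' @param fibre_thinning Fibre retention probability inside dark zones
#'   (default 0.05; the poor intensity is rich * thinning).
#' @param cell_counts_by_type Named integer vector (default 300 cells for
#'   each of monocyte, macrophage, tcell, bcell).
#' @param placement_preference Named list phenotype -> `list(zone =
#'   "rich"|"poor"|"uniform", odds = ...)`; unlisted phenotypes are
#'   uniform. Odds ratios must be > 0.
#' @param mask_resolution_um_per_px Fibre-mask raster resolution
#'   (default 2).
#' @return Object of class `tissue_sim_spec`.
#' @export
tissue_sim_spec <- function(field_size_um = 600, n_vessels = 5L,
                            dark_zone_vessel_fraction = 0.8,
                            dark_zone_radius_um = 120,
                            fibre_intensity_rich = 0.003,
                            fibre_thinning = 0.05,
                            cell_counts_by_type =
                              c(monocyte = 300L, macrophage = 300L,
                                tcell = 300L, bcell = 300L),
                            placement_preference = list(),
                            mask_resolution_um_per_px = 2) {
  stopifnot(field_size_um > 0, n_vessels >= 1L,
            dark_zone_vessel_fraction >= 0,
            dark_zone_vessel_fraction <= 1,
            dark_zone_radius_um > 0, fibre_intensity_rich >= 0,
            fibre_thinning >= 0, fibre_thinning <= 1,
            all(cell_counts_by_type >= 0),
            mask_resolution_um_per_px > 0)
  for (p in placement_preference) {
    stopifnot(p$zone %in% c("rich", "poor", "uniform"), p$odds > 0)
  }
  structure(list(field_size_um = field_size_um, n_vessels = n_vessels,
                 dark_zone_vessel_fraction = dark_zone_vessel_fraction,
                 dark_zone_radius_um = dark_zone_radius_um,
                 fibre_intensity_rich = fibre_intensity_rich,
                 fibre_thinning = fibre_thinning,
                 cell_counts_by_type = cell_counts_by_type,
                 placement_preference = placement_preference,
                 mask_resolution_um_per_px = mask_resolution_um_per_px),
            class = "tissue_sim_spec")
}

#' Simulate a tissue section point pattern
#'
#' Vessels are uniform in the field; dark zones are discs around the first
#' `round(fraction * n_vessels)` vessels. Fibres follow an inhomogeneous
#' Poisson process (homogeneous at the rich intensity, thinned inside dark
#' zones), cells are placed by rejection sampling honouring each
#' phenotype's placement odds, and the mask rasterises fibre presence.
#'
#' @param spec A [tissue_sim_spec()].
#' @param seed Integer seed.
#' @return List with `scene` (a [spatial_scene()]) and `truth` (dark-zone
#'   centres/radius, per-cell true zone, preferences).
#' @export
simulate_tissue <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "tissue_sim_spec"))
  set.seed(seed)
  L <- spec$field_size_um
  vessels <- data.frame(x = stats::runif(spec$n_vessels, 0, L),
                        y = stats::runif(spec$n_vessels, 0, L))
  n_dark <- round(spec$dark_zone_vessel_fraction * spec$n_vessels)
  dark <- vessels[seq_len(n_dark), , drop = FALSE]
  in_dark <- function(x, y) {
    if (nrow(dark) == 0L) return(rep(FALSE, length(x)))
    hit <- rep(FALSE, length(x))
    for (i in seq_len(nrow(dark)))
      hit <- hit | ((x - dark$x[i])^2 + (y - dark$y[i])^2 <=
                      spec$dark_zone_radius_um^2)
    hit
  }
  n_f <- stats::rpois(1L, spec$fibre_intensity_rich * L^2)
  fx <- stats::runif(n_f, 0, L); fy <- stats::runif(n_f, 0, L)
  dk <- in_dark(fx, fy)
  keep <- !dk | stats::runif(n_f) < spec$fibre_thinning
  fibres <- data.frame(x = fx[keep], y = fy[keep], marker = "COL6A1")
  cells <- list()
  for (ph in names(spec$cell_counts_by_type)) {
    n <- spec$cell_counts_by_type[[ph]]
    if (n == 0L) next
    pref <- spec$placement_preference[[ph]]
    if (is.null(pref)) pref <- list(zone = "uniform", odds = 1)
    got <- 0L; xs <- numeric(0); ys <- numeric(0)
    while (got < n) {
      m <- max(2L * (n - got), 50L)
      cx <- stats::runif(m, 0, L); cy <- stats::runif(m, 0, L)
      if (pref$zone == "uniform") {
        acc <- rep(TRUE, m)
      } else {
        zone <- ifelse(in_dark(cx, cy), "poor", "rich")
        w <- ifelse(zone == pref$zone, pref$odds, 1)
        acc <- stats::runif(m) < w / max(pref$odds, 1)
      }
      xs <- c(xs, cx[acc]); ys <- c(ys, cy[acc])
      got <- length(xs)
    }
    cells[[ph]] <- data.frame(x = xs[seq_len(n)], y = ys[seq_len(n)],
                              phenotype = ph)
  }
  cells <- do.call(rbind, cells)
  rownames(cells) <- NULL
  res <- spec$mask_resolution_um_per_px
  npx <- ceiling(L / res)
  mask <- matrix(FALSE, nrow = npx, ncol = npx)
  if (nrow(fibres)) {
    j <- pmin(npx, pmax(1L, ceiling(fibres$x / res)))
    i <- pmin(npx, pmax(1L, ceiling(fibres$y / res)))
    mask[cbind(i, j)] <- TRUE
  }
  scene <- spatial_scene(fibres, cells, vessels, mask = mask,
                         um_per_px = res, bounds = c(0, 0, L, L))
  truth <- list(dark_centres = dark,
                dark_radius_um = spec$dark_zone_radius_um,
                cell_zone = ifelse(in_dark(cells$x, cells$y), "poor",
                                   "rich"),
                preferences = spec$placement_preference)
  list(scene = scene, truth = truth)
}

#' Simulate a block-structured protein abundance matrix
#'
#' Proteins within a block share a latent per-sample factor; observed
#' values are the factor plus Gaussian noise, so within-block Pearson
#' correlations approach 1 as `noise_sd` shrinks (r ~ 1 / (1 +
#' noise_sd^2)) while between-block correlations are centred on zero.
#'
#' @param n_proteins Number of proteins.
#' @param blocks Either the number of (equal) blocks or a vector of block
#'   labels of length `n_proteins`.
#' @param noise_sd Noise standard deviation (default 0.2).
#' @param n_samples Number of samples (default 10).
#' @param seed Integer seed.
#' @return List with `abundance` (matrix, proteins x samples) and `truth`
#'   (named block labels).
#' @export
simulate_abundance_matrix <- function(n_proteins = 60L, blocks = 2L,
                                      noise_sd = 0.2, n_samples = 10L,
                                      seed = 1L) {
  stopifnot(n_proteins >= 1L, n_samples >= 3L, noise_sd >= 0)
  if (length(blocks) == 1L)
    blocks <- sort(rep(seq_len(blocks), length.out = n_proteins))
  if (length(blocks) != n_proteins)
    stop("blocks must partition the proteins")
  set.seed(seed)
  ids <- sprintf("P%03d", seq_len(n_proteins))
  ub <- unique(blocks)
  z <- matrix(stats::rnorm(length(ub) * n_samples), nrow = length(ub),
              dimnames = list(ub, NULL))
  m <- z[match(blocks, ub), , drop = FALSE] +
    matrix(stats::rnorm(n_proteins * n_samples, sd = noise_sd),
           nrow = n_proteins)
  rownames(m) <- ids
  colnames(m) <- sprintf("s%02d", seq_len(n_samples))
  list(abundance = m, truth = stats::setNames(blocks, ids))
}
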