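#' In-silico trypsin digestion
#'
#' Cleaves after lysine (K) or arginine (R), by default suppressing cleavage
#' when the following residue is proline (the specificity used by standard
#' search engines). Returns every fully tryptic peptide spanning at most
#' `missed_cleavages` internal cleavage sites, with 1-based inclusive
#' coordinates.
#'
#' @param sequence Protein sequence (single string, 20-letter alphabet).
#' @param missed_cleavages Maximum internal missed cleavage sites
#'   (default 2).
#' @param proline_rule Suppress cleavage before proline (default TRUE).
#' @return data.frame with columns `start`, `end`, `sequence`, `n_missed`.
#' @examples
#' digest_protein("MAKRGYKPWR")   # 6 peptides at <=2 missed cleavages
#' @export
digest_protein <- function(sequence, missed_cleavages = 2L,
                           proline_rule = TRUE) {
  sequence <- toupper(as.character(sequence))
  n <- nchar(sequence)
  if (n == 0L) stop("empty protein sequence")
  if (missed_cleavages < 0L) stop("missed_cleavages must be >= 0")
  res <- strsplit(sequence, "")[[1L]]
  sites <- cleavage_sites(res, proline_rule)       # cleave after these
  bounds <- unique(c(0L, sites, n))
  nfrag <- length(bounds) - 1L
  i <- rep(seq_len(nfrag), each = as.integer(missed_cleavages) + 1L)
  j <- i + rep(0L:as.integer(missed_cleavages), times = nfrag)
  ok <- j <= nfrag
  i <- i[ok]; j <- j[ok]
  s <- bounds[i] + 1L
  e <- bounds[j + 1L]
  data.frame(start = s, end = e,
             sequence = substring(sequence, s, e),
             n_missed = j - i)
}

# indices i such that trypsin cleaves between residue i and i+1
cleavage_sites <- function(res, proline_rule = TRUE) {
  n <- length(res)
  if (n < 2L) return(integer(0))
  i <- which(res[-n] %in% c("K", "R"))
  if (proline_rule) i <- i[res[i + 1L] != "P"]
  i
}

#' Classify peptide termini against trypsin specificity
#'
#' A terminus conforms if it is a protein terminus (N-terminal start at or
#' before `nterm_exclusion_limit`, accommodating initiator-methionine loss)
#' or sits at a tryptic cleavage site (preceded by K/R and, under the
#' proline rule, not starting with P; symmetrically for the C-terminus).
#' Peptides with both termini conforming are `full`y tryptic, with exactly
#' one conforming are `semi`-tryptic — the hallmark of endogenous protease
#' activity — and with neither are `non`-tryptic. For semi-tryptic peptides
#' the endogenous cleavage position is the residue index on the N-terminal
#' side of the broken bond: `start - 1` for a nonconforming N-terminus,
#' `end` for a nonconforming C-terminus.
#'
#' @param peptides data.frame with columns `accession`, `start`, `end` (and
#'   optionally `sequence`, validated if present).
#' @param proteins Named character vector of protein sequences.
#' @param nterm_exclusion_limit Start positions at or below this count as
#'   the protein N-terminus (default 2).
#' @param proline_rule Apply the no-cleavage-before-proline rule
#'   (default TRUE).
#' @return The input data.frame with added columns `tryptic_class`
#'   (`full`/`semi`/`non`), `nonconforming_terminus` (`none`/`N`/`C`) and
#'   `cleavage_pos` (NA unless semi-tryptic).
#' @export
classify_peptides <- function(peptides, proteins,
                              nterm_exclusion_limit = 2L,
                              proline_rule = TRUE) {
  stopifnot(all(c("accession", "start", "end") %in% names(peptides)))
  miss <- setdiff(unique(peptides$accession), names(proteins))
  if (length(miss))
    stop("unknown accession(s): ", paste(miss, collapse = ", "))
  n <- nrow(peptides)
  cls <- character(n); ncf <- character(n); pos <- rep(NA_integer_, n)
  res_by_acc <- lapply(proteins[unique(peptides$accession)],
                       function(s) strsplit(s, "")[[1L]])
  lens <- lengths(res_by_acc)
  for (acc in names(res_by_acc)) {
    res <- res_by_acc[[acc]]; L <- lens[[acc]]
    idx <- which(peptides$accession == acc)
    s <- peptides$start[idx]; e <- peptides$end[idx]
    if (any(s < 1L | e > L | s > e))
      stop(sprintf("peptide coordinates out of range for %s", acc))
    prev <- ifelse(s > 1L, res[pmax(s - 1L, 1L)], "")
    first <- res[s]; last <- res[e]
    after <- ifelse(e < L, res[pmin(e + 1L, L)], "")
    n_ok <- s <= nterm_exclusion_limit |
      (prev %in% c("K", "R") & (!proline_rule | first != "P"))
    c_ok <- e == L |
      (last %in% c("K", "R") & (!proline_rule | after != "P"))
    cls[idx] <- ifelse(n_ok & c_ok, "full",
                       ifelse(n_ok | c_ok, "semi", "non"))
    ncf[idx] <- ifelse(n_ok & c_ok, "none",
                       ifelse(!n_ok & c_ok, "N",
                              ifelse(n_ok & !c_ok, "C", "none")))
    pos[idx] <- ifelse(cls[idx] == "semi",
                       ifelse(ncf[idx] == "N", s - 1L, e), NA_integer_)
  }
  peptides$tryptic_class <- cls
  peptides$nonconforming_terminus <- ncf
  peptides$cleavage_pos <- pos
  peptides
}

#' Median-subtraction normalisation
#'
#' Log-transforms abundances and subtracts the per-sample median, so that
#' every sample's post-normalisation median is zero. Missing values are
#' ignored in the median; zero or negative abundances are errors.
#'
#' @param abundance Numeric matrix or data.frame, features in rows, samples
#'   in columns.
#' @param log_base Base of the log transform (default 2).
#' @return Matrix of normalised log-abundances.
#' @export
median_normalize <- function(abundance, log_base = 2) {
  m <- as.matrix(abundance)
  if (any(m[!is.na(m)] <= 0))
    stop("abundances must be strictly positive where present")
  lm <- log(m, base = log_base)
  meds <- apply(lm, 2L, stats::median, na.rm = TRUE)
  if (any(is.na(meds))) {
    bad <- colnames(m)[is.na(meds)]
    if (is.null(bad)) bad <- which(is.na(meds))
    stop("sample(s) with all values missing: ", paste(bad, collapse = ", "))
  }
  sweep(lm, 2L, meds, "-")
}

#' Semi-tryptic to tryptic degradation ratios
#'
#' The degradation statistic: after removing protein N-terminal peptides
#' (start at or below `nterm_exclusion_limit`), semi-tryptic signal is
#' referenced to the fully tryptic signal of the same protein group. In
#' `abundance` mode each semi-tryptic peptide yields one ratio — its mean
#' abundance divided by the mean tryptic abundance of the group (one dot per
#' peptide); in `spectral` mode the group ratio is the total semi-tryptic
#' spectral count over the total tryptic count. A higher ratio indicates
#' more endogenous degradation. Both statistics are invariant to global
#' abundance scaling.
#'
#' @param peptides Classified peptide data.frame (see [classify_peptides()])
#'   with `abundance_*` and/or `spectral_*` sample columns.
#' @param mode `"abundance"` or `"spectral"`.
#' @param groups Optional named map accession -> group id (e.g. collapsing
#'   collagen VI chains); defaults to one group per accession.
#' @param sample_condition Optional named map sample -> condition; ratios
#'   are then computed per condition. Sample names are the suffixes of the
#'   quantification columns.
#' @param nterm_exclusion_limit Drop peptides starting at or below this
#'   residue (default 2).
#' @return List of class `degradation_profile` with elements `per_peptide`
#'   (abundance mode; one ratio per semi-tryptic peptide and condition),
#'   `spectral` (spectral mode; one ratio per group and condition) and
#'   `tryptic_mean` (per group/condition denominator used).
#' @export
semitryptic_ratio <- function(peptides, mode = c("abundance", "spectral"),
                              groups = NULL, sample_condition = NULL,
                              nterm_exclusion_limit = 2L) {
  mode <- match.arg(mode)
  stopifnot("tryptic_class" %in% names(peptides))
  prefix <- if (mode == "abundance") "abundance_" else "spectral_"
  qcols <- grep(paste0("^", prefix), names(peptides), value = TRUE)
  if (!length(qcols))
    stop("no ", sub("_$", "", prefix), " columns in peptide table")
  samples <- sub(prefix, "", qcols)
  if (is.null(sample_condition))
    sample_condition <- stats::setNames(rep("all", length(samples)), samples)
  conds <- unique(sample_condition[samples])
  keep <- peptides$start > nterm_exclusion_limit
  dropped <- sum(!keep)
  if (dropped) message(sprintf("removed %d protein N-terminal peptide(s)",
                               dropped))
  pep <- peptides[keep, , drop = FALSE]
  if (is.null(groups))
    groups <- stats::setNames(unique(pep$accession), unique(pep$accession))
  pep$group <- unname(groups[pep$accession])
  per_pep <- list(); spectral <- list(); trymean <- list()
  for (g in unique(pep$group)) {
    gp <- pep[pep$group == g, , drop = FALSE]
    tr <- gp[gp$tryptic_class == "full", , drop = FALSE]
    se <- gp[gp$tryptic_class == "semi", , drop = FALSE]
    if (nrow(tr) == 0L)
      stop("group '", g, "' has no fully tryptic peptides after exclusions")
    for (cd in conds) {
      cs <- samples[sample_condition[samples] == cd]
      cc <- paste0(prefix, cs)
      if (mode == "abundance") {
        tmat <- as.matrix(tr[, cc, drop = FALSE])
        tmean <- mean(tmat, na.rm = TRUE)
        trymean[[length(trymean) + 1L]] <-
          data.frame(group = g, condition = cd, tryptic_mean = tmean)
        if (nrow(se)) {
          smean <- rowMeans(as.matrix(se[, cc, drop = FALSE]), na.rm = TRUE)
          per_pep[[length(per_pep) + 1L]] <- data.frame(
            group = g, condition = cd, accession = se$accession,
            start = se$start, end = se$end, sequence = se$sequence,
            ratio = smean / tmean)
        }
      } else {
        tsum <- sum(as.matrix(tr[, cc, drop = FALSE]), na.rm = TRUE)
        ssum <- if (nrow(se))
          sum(as.matrix(se[, cc, drop = FALSE]), na.rm = TRUE) else 0
        if (tsum == 0)
          stop("group '", g, "' has zero tryptic spectral counts in ", cd)
        spectral[[length(spectral) + 1L]] <- data.frame(
          group = g, condition = cd, semi_counts = ssum,
          tryptic_counts = tsum, ratio = ssum / tsum)
      }
    }
  }
  structure(list(
    mode = mode,
    per_peptide = if (length(per_pep)) do.call(rbind, per_pep) else
      data.frame(group = character(0), condition = character(0),
                 accession = character(0), start = integer(0),
                 end = integer(0), sequence = character(0),
                 ratio = numeric(0)),
    spectral = if (length(spectral)) do.call(rbind, spectral) else NULL,
    tryptic_mean = if (length(trymean)) do.call(rbind, trymean) else NULL),
    class = "degradation_profile")
}

#' Map endogenous cleavage sites onto protein sections
#'
#' Assigns each semi-tryptic peptide's endogenous cleavage position to a
#' fixed-width amino-acid section (bin `ceiling(pos / bin_width)`), tiling
#' the protein from residue 1 to its length. The default width is 50 aa for
#' chains shorter than 1500 residues and 100 aa otherwise, matching typical
#' collagen-chain map resolutions.
#'
#' @param peptides Classified peptide data.frame; only semi-tryptic records
#'   contribute.
#' @param sequence The protein sequence (string).
#' @param bin_width Section width in residues, or NULL for the default rule.
#' @param differential Optional per-peptide statistics from
#'   [differential_peptides()]; supplies the mean differential direction per
#'   bin (matched by `accession`, `start`, `end`).
#' @param accession Accession to map (default: the unique accession in
#'   `peptides`).
#' @return Object of class `cleavage_map`: data.frame of bins (`bin`,
#'   `bin_start`, `bin_end`, `count`, `mean_direction`) with attributes
#'   `accession` and `bin_width`.
#' @export
map_cleavage_bins <- function(peptides, sequence, bin_width = NULL,
                              differential = NULL, accession = NULL) {
  L <- nchar(sequence)
  if (is.null(bin_width)) bin_width <- if (L < 1500L) 50L else 100L
  if (is.null(accession)) {
    accession <- unique(peptides$accession)
    if (length(accession) != 1L)
      stop("supply 'accession' when the table covers several proteins")
  }
  semi <- peptides[peptides$accession == accession &
                     peptides$tryptic_class == "semi", , drop = FALSE]
  nb <- ceiling(L / bin_width)
  bins <- data.frame(
    bin = seq_len(nb),
    bin_start = (seq_len(nb) - 1L) * bin_width + 1L,
    bin_end = pmin(seq_len(nb) * bin_width, L),
    count = 0L, mean_direction = NA_real_)
  if (nrow(semi)) {
    b <- ceiling(semi$cleavage_pos / bin_width)
    tb <- table(factor(b, levels = seq_len(nb)))
    bins$count <- as.integer(tb)
    if (!is.null(differential)) {
      key <- paste(semi$accession, semi$start, semi$end)
      dkey <- paste(differential$accession, differential$start,
                    differential$end)
      dirv <- differential$direction[match(key, dkey)]
      md <- tapply(dirv, factor(b, levels = seq_len(nb)),
                   mean, na.rm = TRUE)
      bins$mean_direction <- as.numeric(md)
    }
  }
  structure(bins, class = c("cleavage_map", "data.frame"),
            accession = accession, bin_width = bin_width,
            protein_length = L)
}

#' Overlay predicted protease susceptibility on a cleavage map
#'
#' Adds, per section, the number of positions whose predicted cleavage
#' susceptibility (e.g. MMP2/9) reaches the cutoff, and flags sections where
#' observed endogenous cleavage co-occurs with at least one predicted site.
#'
#' @param map A [map_cleavage_bins()] result.
#' @param track data.frame with columns `position` and `score` (scores in
#'   \[0, 1\]).
#' @param cutoff Susceptibility cutoff (default 0.75).
#' @return The map with added columns `predicted` and `flagged`.
#' @export
susceptibility_overlay <- function(map, track, cutoff = 0.75) {
  stopifnot(inherits(map, "cleavage_map"))
  L <- attr(map, "protein_length")
  if (nrow(track) && (any(track$position < 1L) || any(track$position > L)))
    stop("susceptibility positions outside protein [1, ", L, "]")
  bw <- attr(map, "bin_width")
  hit <- track$position[track$score >= cutoff]
  tb <- table(factor(ceiling(hit / bw), levels = map$bin))
  map$predicted <- as.integer(tb)
  map$flagged <- map$count > 0L & map$predicted > 0L
  map
}

#' Differential peptide abundance between two groups
#'
#' Per-peptide two-sided Welch t-test on normalised abundances, as used to
#' call RA- versus OA-elevated peptides. Peptides with fewer than two usable
#' values in either group are skipped (recorded in attribute `"skipped"`).
#'
#' @param normalised Matrix of normalised log-abundances (peptides x
#'   samples), e.g. from [median_normalize()].
#' @param groups Factor/character vector of length `ncol(normalised)` with
#'   exactly two levels.
#' @param alpha Significance level for the `significant` flag (default
#'   0.05).
#' @return data.frame with `peptide`, group means, `direction` (sign of
#'   first-level minus second-level mean), `t`, `pval`, `significant`.
#' @export
differential_peptides <- function(normalised, groups, alpha = 0.05) {
  m <- as.matrix(normalised)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("need exactly two groups")
  if (length(groups) != ncol(m))
    stop("groups length must match number of samples")
  ga <- levels(groups)[1L]; gb <- levels(groups)[2L]
  ids <- rownames(m); if (is.null(ids)) ids <- as.character(seq_len(nrow(m)))
  res <- vector("list", nrow(m)); skipped <- character(0)
  for (i in seq_len(nrow(m))) {
    xa <- m[i, groups == ga]; xa <- xa[!is.na(xa)]
    xb <- m[i, groups == gb]; xb <- xb[!is.na(xb)]
    if (length(xa) < 2L || length(xb) < 2L) {
      skipped <- c(skipped, ids[i]); next
    }
    d <- mean(xa) - mean(xb)
    if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
      tt <- list(statistic = if (d == 0) 0 else sign(d) * Inf,
                 p.value = if (d == 0) 1 else 0)
    } else {
      tt <- stats::t.test(xa, xb, var.equal = FALSE)
    }
    res[[i]] <- data.frame(peptide = ids[i], mean_a = mean(xa),
                           mean_b = mean(xb),
                           direction = sign(d),
                           t = unname(tt$statistic), pval = tt$p.value)
  }
  if (length(skipped))
    message(sprintf("skipped %d peptide(s) with <2 usable samples",
                    length(skipped)))
  out <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(peptide = character(0), mean_a = numeric(0),
                      mean_b = numeric(0), direction = numeric(0),
                      t = numeric(0), pval = numeric(0))
  out$significant <- out$pval < alpha
  attr(out, "skipped") <- skipped
  attr(out, "groups") <- c(ga, gb)
  out
}

#' Protein correlation network with Louvain communities
#'
#' Builds the abundance-correlation network: proteins are nodes, and an
#' edge joins two proteins when the Pearson correlation of their abundance
#' profiles exceeds the threshold (one-sided, r > threshold — anticorrelated
#' pairs are not linked). Communities come from Louvain modularity
#' optimisation at the given resolution, with isolated proteins as
#' singleton communities. Community labels are canonicalised by each
#' community's alphabetically smallest member, so output is deterministic.
#'
#' @param abundance Matrix, proteins in rows, samples (>= 3) in columns.
#' @param r_threshold Edge threshold on Pearson r (default 0.85).
#' @param resolution Louvain resolution parameter (default 0.5).
#' @param seed Integer seed for the community search (default 1).
#' @return List of class `correlation_network`: `edges` (data.frame `a`,
#'   `b`, `r`), `communities` (named character: protein -> community
#'   label), `excluded` (zero-variance proteins).
#' @export
correlation_network <- function(abundance, r_threshold = 0.85,
                                resolution = 0.5, seed = 1L) {
  m <- as.matrix(abundance)
  if (ncol(m) < 3L) stop("need at least 3 samples")
  ids <- rownames(m); if (is.null(ids)) ids <- paste0("p", seq_len(nrow(m)))
  v <- apply(m, 1L, stats::var, na.rm = TRUE)
  excluded <- ids[!is.finite(v) | v == 0]
  if (length(excluded))
    message(sprintf("excluded %d zero-variance protein(s)",
                    length(excluded)))
  keep <- !(ids %in% excluded)
  mk <- m[keep, , drop = FALSE]; idk <- ids[keep]
  edges <- data.frame(a = character(0), b = character(0), r = numeric(0))
  if (nrow(mk) >= 2L) {
    cm <- stats::cor(t(mk))
    iu <- which(upper.tri(cm) & cm > r_threshold, arr.ind = TRUE)
    if (nrow(iu))
      edges <- data.frame(a = idk[iu[, 1L]], b = idk[iu[, 2L]],
                          r = cm[iu])
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = idk))
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(comm)
  # canonical label: smallest member name of each community
  lab <- tapply(names(memb), as.integer(memb), function(x) min(x))
  communities <- stats::setNames(unname(lab[as.character(memb)]),
                                 names(memb))
  structure(list(edges = edges, communities = communities,
                 excluded = excluded, r_threshold = r_threshold,
                 resolution = resolution),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf(
    "correlation_network: %d proteins, %d edges (r > %.2f), %d communities\n",
    length(x$communities), nrow(x$edges), x$r_threshold,
    length(unique(x$communities))))
  invisible(x)
}
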