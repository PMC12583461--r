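#' Cross-disease remission cassette gene lists
#'
#' The matrisome gene cassettes shared between synovial fibroblasts of RA
#' patients in sustained remission and capsule fibroblasts of resolving
#' frozen shoulder: 10 remission-upregulated and 13 remission-downregulated
#' genes in the lining layer, and 6 upregulated and 7 downregulated genes
#' in the sub-lining. These are the reference lists used by the packaged
#' cassette-overlap fixtures.
#'
#' @return Nested named list: stratum (`lining`, `sublining`) -> direction
#'   (`up`, `down`) -> character vector of gene symbols.
#' @examples
#' lengths(remission_cassettes()$lining)   # up 10, down 13
#' @export
remission_cassettes <- function() {
  list(
    lining = list(
      up = c("FGL2", "HTRA4", "IGFBP5", "IGFBP6", "LTBP4", "PDGFD",
             "PRG4", "S100A6", "SEMA3E", "SPARCL1"),
      down = c("ADAMTS2", "ADAMTS6", "COL14A1", "COL1A1", "COL1A2",
               "COL3A1", "IGFBP7", "MMP2", "MMP3", "SERPINE2", "SMOC1",
               "TIMP1", "TNFAIP6")),
    sublining = list(
      up = c("CILP", "FGFBP2", "FGL2", "LTBP4", "MGP", "TNXB"),
      down = c("COL1A1", "COL3A1", "COL5A2", "ELN", "IGF1", "SERPINE2",
               "SPARC")))
}

#' Packaged cassette-overlap fixture
#'
#' Builds the pair of per-stratum, per-direction DEG lists used as the
#' worked example for [cassette_overlap()]: each disease's list embeds the
#' shared remission cassette of [remission_cassettes()] plus fillers unique
#' to that disease, so the intersection sizes are exactly the cassette
#' sizes (10 / 13 / 6 / 7). The frozen-shoulder filler for lining-up
#' includes the resolution-specific neutrophil/monocyte chemokines CXCL1,
#' CXCL2, CXCL3 and CXCL8.
#'
#' @param n_filler Number of synthetic filler genes per list (default 5).
#' @return List with elements `ra` and `fs`, each a nested stratum ->
#'   direction -> gene vector suitable for [cassette_overlap()].
#' @export
cassette_fixture <- function(n_filler = 5L) {
  cass <- remission_cassettes()
  filler <- function(tag, n) sprintf("%s_FILLER%02d", tag, seq_len(n))
  fs_extra <- list(lining_up = c("CXCL1", "CXCL2", "CXCL3", "CXCL8"))
  ra <- list(); fs <- list()
  for (st in names(cass)) {
    ra[[st]] <- list(); fs[[st]] <- list()
    for (dr in names(cass[[st]])) {
      tag <- toupper(paste(st, dr, sep = "_"))
      ra[[st]][[dr]] <- c(cass[[st]][[dr]],
                          filler(paste0("RA_", tag), n_filler))
      extra <- if (st == "lining" && dr == "up")
        fs_extra$lining_up else character(0)
      fs[[st]][[dr]] <- c(cass[[st]][[dr]], extra,
                          filler(paste0("FS_", tag), n_filler))
    }
  }
  list(ra = ra, fs = fs)
}
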