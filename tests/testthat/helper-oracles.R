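# Independent brute-force oracles used across the suite. Each recomputes
# the quantity from first principles, without touching the implementation
# path it checks.

# two-sided Fisher exact p by exhaustive hypergeometric enumeration over
# all tables with the observed margins (tables as [[a, b], [c, d]])
fisher_oracle_p <- function(a, b, c, d) {
  m <- a + b          # row-1 total
  n <- c + d          # row-2 total
  k <- a + c          # column-1 total
  support <- max(0L, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(dens[dens <= obs * (1 + 1e-7)])
}

# Benjamini-Hochberg from the definition: sort, p * n / rank, enforce
# monotonicity from the largest rank down, cap at 1, restore order
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  if (n >= 2L)
    for (i in (n - 1L):1L) adj[i] <- min(adj[i], adj[i + 1L])
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# recovery-curve AUC by literal step-by-step summation
auc_oracle <- function(ranking, set, top_fraction) {
  G <- length(ranking)
  m <- ceiling(top_fraction * G)
  members <- names(ranking)[names(ranking) %in% set]
  n_set <- length(members)
  if (n_set == 0L) return(0)
  raw <- 0; max_raw <- 0
  for (k in seq_len(m)) {
    raw <- raw + sum(ranking[members] <= k)
    max_raw <- max_raw + min(k, n_set)
  }
  raw / max_raw
}

# tryptic digest by brute-force enumeration of all substrings whose
# termini are cleavage boundaries and which span <= mc internal sites
digest_oracle <- function(sequence, mc, proline_rule = TRUE) {
  res <- strsplit(sequence, "")[[1L]]
  n <- length(res)
  sites <- which(res[-n] %in% c("K", "R"))
  if (proline_rule) sites <- sites[res[sites + 1L] != "P"]
  starts <- c(1L, sites + 1L)
  ends <- c(sites, n)
  out <- list()
  for (s in starts) {
    for (e in ends[ends >= s]) {
      internal <- sum(sites > s - 1L & sites < e)
      if (internal <= mc)
        out[[length(out) + 1L]] <- data.frame(
          start = s, end = e,
          sequence = paste(res[s:e], collapse = ""),
          n_missed = internal)
    }
  }
  df <- do.call(rbind, out)
  df[order(df$start, df$end), ]
}

# random protein sequence with K/R enrichment for digestion tests
random_protein <- function(len, kr_prob = 0.15) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "L", "M", "N", "P",
          "Q", "S", "T", "V", "W", "Y")
  paste(ifelse(stats::runif(len) < kr_prob,
               sample(c("K", "R"), len, replace = TRUE),
               sample(aa, len, replace = TRUE)), collapse = "")
}

# small deterministic expression matrix for plumbing tests
tiny_em <- function() {
  counts <- matrix(c(5, 3, 3, 0,
                     1, 0, 2, 4,
                     0, 0, 0, 0,
                     2, 2, 1, 1,
                     9, 1, 0, 3), nrow = 5, byrow = TRUE,
                   dimnames = list(paste0("g", 1:5), paste0("c", 1:4)))
  cells <- data.frame(cell = paste0("c", 1:4),
                      sample = c("s1", "s1", "s2", "s2"),
                      condition = c("A", "A", "B", "B"),
                      cluster = c("k1", "k1", "k2", "k2"))
  expression_matrix(counts, cells)
}
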