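test_that("trypsin digestion follows K/R specificity with the proline rule", {
  d <- digest_protein("MAKRGYKPWR", missed_cleavages = 2)
  expect_setequal(d$sequence,
                  c("MAK", "R", "GYKPWR", "MAKR", "RGYKPWR", "MAKRGYKPWR"))
  expect_equal(nrow(d), 6L)
  # no K/R -> whole protein
  expect_equal(digest_protein("MAGGWQ")$sequence, "MAGGWQ")
  # K before P is not a cleavage site
  expect_false(any(digest_protein("MAKPGW", 0)$end == 3))
  expect_error(digest_protein(""), "empty")
})

test_that("digestion matches brute-force enumeration on random sequences", {
  set.seed(7)
  for (i in 1:40) {
    seq <- random_protein(sample(5:60, 1))
    mc <- sample(0:2, 1)
    got <- digest_protein(seq, mc)
    got <- got[order(got$start, got$end), ]
    want <- digest_oracle(seq, mc)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$sequence, want$sequence)
    expect_equal(got$n_missed, want$n_missed)
  }
})

test_that("terminus classification identifies full/semi/non peptides", {
  prot <- c(P1 = "MAKRGYKPWR")
  pep <- data.frame(accession = "P1",
                    start = c(5, 6, 1),
                    end = c(10, 10, 6))
  out <- classify_peptides(pep, prot)
  expect_equal(out$tryptic_class, c("full", "semi", "semi"))
  expect_equal(out$nonconforming_terminus, c("none", "N", "C"))
  expect_equal(out$cleavage_pos, c(NA, 5L, 6L))
})

test_that("every digest product classifies as fully tryptic", {
  set.seed(11)
  for (i in 1:20) {
    seq <- random_protein(sample(10:60, 1))
    d <- digest_protein(seq, 2)
    d$accession <- "X"
    cls <- classify_peptides(d, c(X = seq))
    expect_true(all(cls$tryptic_class == "full"))
  }
})

test_that("median subtraction centres every sample at zero", {
  m <- cbind(s1 = c(1, 10, 100), s2 = c(2, 20, 200))
  norm <- median_normalize(m, log_base = 10)
  expect_equal(unname(norm[, "s1"]), c(-1, 0, 1))
  expect_equal(unname(apply(norm, 2, median)), c(0, 0))
  # global scaling cancels
  expect_equal(median_normalize(m * 7, log_base = 10), norm)
  expect_error(median_normalize(cbind(c(0, 1))), "positive")
  expect_error(median_normalize(cbind(a = c(1, 2), b = c(NA, NA))),
               "missing")
})

test_that("semi-tryptic ratios follow the per-peptide and spectral rules", {
  # group with tryptic abundances {4, 6} and semi abundances {5, 10}
  pep <- data.frame(
    accession = "P1", start = c(10, 20, 30, 40), end = c(15, 25, 35, 45),
    sequence = c("T1", "T2", "S1", "S2"),
    tryptic_class = c("full", "full", "semi", "semi"),
    abundance_a = c(4, 6, 5, 10), spectral_a = c(3, 5, 2, 6))
  prof <- semitryptic_ratio(pep, mode = "abundance")
  expect_equal(sort(prof$per_peptide$ratio), c(1, 2))
  # scale invariance
  pep2 <- pep; pep2$abundance_a <- pep2$abundance_a * 13
  expect_equal(semitryptic_ratio(pep2, "abundance")$per_peptide$ratio,
               prof$per_peptide$ratio)
  sp <- semitryptic_ratio(pep, mode = "spectral")
  expect_equal(sp$spectral$ratio, 8 / 8)
  # no semi-tryptic peptides -> empty list, spectral ratio 0
  pep3 <- pep[pep$tryptic_class == "full", ]
  expect_equal(nrow(semitryptic_ratio(pep3, "abundance")$per_peptide), 0L)
  expect_equal(semitryptic_ratio(pep3, "spectral")$spectral$ratio, 0)
  # N-terminal peptides are removed before anything else
  pep4 <- pep; pep4$start[1:2] <- c(1, 2)
  expect_error(suppressMessages(semitryptic_ratio(pep4, "abundance")),
               "no fully tryptic")
})

test_that("cleavage positions map to tiling bins with count conservation", {
  seq <- paste(rep("A", 220), collapse = "")
  pep <- data.frame(accession = "P1", start = c(121, 2, 60),
                    end = c(130, 10, 70),
                    tryptic_class = "semi",
                    cleavage_pos = c(120L, 1L, 59L))
  map <- map_cleavage_bins(pep, seq, bin_width = 50)
  expect_equal(map$count[map$bin == 3], 1L)   # site 120 -> bin 3 (101-150)
  expect_equal(map$count[map$bin == 1], 1L)   # site 1 -> bin 1
  expect_equal(sum(map$count), 3L)
  # bins tile [1, length] with no gaps or overlaps
  expect_equal(map$bin_start, c(1, 51, 101, 151, 201))
  expect_equal(map$bin_end, c(50, 100, 150, 200, 220))
  expect_equal(map$bin_start[-1], map$bin_end[-5] + 1)
  # default width rule: short chains 50, long chains 100
  expect_equal(attr(map_cleavage_bins(pep, seq), "bin_width"), 50L)
  long <- paste(rep("A", 1600), collapse = "")
  expect_equal(attr(map_cleavage_bins(pep[1, ], long), "bin_width"), 100L)
})

test_that("susceptibility overlay counts predicted sites at the cutoff", {
  seq <- paste(rep("A", 200), collapse = "")
  pep <- data.frame(accession = "P1", start = 121, end = 130,
                    tryptic_class = "semi", cleavage_pos = 120L)
  map <- map_cleavage_bins(pep, seq, bin_width = 50)
  track <- data.frame(position = c(120, 10, 130), score = c(0.8, 0.4, 0.75))
  ov <- susceptibility_overlay(map, track, cutoff = 0.75)
  expect_equal(ov$predicted, c(0L, 0L, 2L, 0L))
  expect_true(ov$flagged[3])
  # all-zero track and boundary cutoff
  z <- susceptibility_overlay(map, data.frame(position = 1, score = 0))
  expect_equal(sum(z$predicted), 0L)
  hi <- susceptibility_overlay(map, track, cutoff = 1.0)
  expect_equal(sum(hi$predicted), 0L)
  expect_error(susceptibility_overlay(map,
                                      data.frame(position = 999,
                                                 score = 1)), "outside")
})

test_that("differential peptide tests behave under null, shift and swap", {
  m <- rbind(p1 = c(1, 2, 3, 3, 2, 1))
  g <- c("a", "a", "a", "b", "b", "b")
  r <- differential_peptides(m, g)
  expect_equal(r$t, 0)
  expect_equal(r$pval, 1)
  # planted 3-SD shifts are detected in most seeds
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    x <- matrix(rnorm(10), nrow = 1,
                dimnames = list("p", NULL))
    x[1, 6:10] <- x[1, 6:10] + 3
    differential_peptides(x, rep(c("a", "b"), each = 5))$pval < 0.05
  }, TRUE)
  expect_gte(sum(hits), 18)
  # swapping labels flips direction, keeps p
  set.seed(1)
  x <- matrix(rnorm(12), nrow = 2)
  ga <- rep(c("a", "b"), each = 3)
  r1 <- differential_peptides(x, ga)
  r2 <- differential_peptides(x, rev(ga))
  expect_equal(r1$pval, r2$pval)
  expect_equal(r1$direction, -r2$direction)
})

test_that("correlation networks apply the one-sided r threshold", {
  set.seed(3)
  base <- rnorm(10)
  m <- rbind(a = base, b = base,                    # r = 1 -> edge
             c = -base,                             # r = -1 -> no edge
             d = rnorm(10))                         # noise
  net <- correlation_network(m, r_threshold = 0.85)
  expect_equal(nrow(net$edges), 1L)
  expect_setequal(c(net$edges$a, net$edges$b), c("a", "b"))
  # zero-variance proteins are excluded with a message
  m2 <- rbind(m, e = rep(1, 10))
  expect_message(net2 <- correlation_network(m2), "zero-variance")
  expect_equal(net2$excluded, "e")
  # noise-free blocks are recovered as exactly two communities
  sim <- simulate_abundance_matrix(n_proteins = 20, blocks = 2,
                                   noise_sd = 0, seed = 5)
  net3 <- correlation_network(sim$abundance)
  expect_equal(length(unique(net3$communities)), 2L)
  expect_equal(unname(table(net3$communities)[unique(net3$communities)]),
               unname(table(sim$truth)))
})
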