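test_that("pseudobulk summation conserves counts and drops unlabelled cells", {
  em <- tiny_em()
  pb <- pseudobulk_sum(em)
  expect_equal(unname(pb$counts["g1", ]), c(8, 3))
  expect_equal(sum(pb$counts), sum(em$counts))
  # unlabelled cells are excluded with a message
  em$cells$cluster[4] <- ""
  expect_message(pb2 <- pseudobulk_sum(em), "1 unlabelled")
  expect_equal(sum(pb2$counts), sum(em$counts[, 1:3]))
})

test_that("pseudobulk NB test is null on identical replicated profiles", {
  profile <- c(g1 = 40, g2 = 10, g3 = 100, g4 = 5)
  counts <- matrix(rep(profile, 8), nrow = 4,
                   dimnames = list(names(profile), paste0("c", 1:8)))
  cells <- data.frame(cell = paste0("c", 1:8),
                      sample = paste0("s", 1:8),
                      condition = rep(c("A", "B"), each = 4),
                      cluster = "k1")
  pb <- pseudobulk_sum(expression_matrix(counts, cells))
  # identical profiles leave zero residual variance; the dispersion
  # moderation step warns about exactly that degeneracy
  deg <- suppressWarnings(dea_pseudobulk_nb(pb, "k1"))
  expect_true(all(deg$pval > 0.999))
  expect_true(all(abs(deg$log2FC) < 1e-6))
  # a condition with fewer than two samples is an error
  cells2 <- cells; cells2$condition <- c("A", rep("B", 7))
  pb2 <- pseudobulk_sum(expression_matrix(counts, cells2))
  expect_error(dea_pseudobulk_nb(pb2, "k1"), ">= 2")
})

test_that("pseudobulk NB test recovers planted fold changes", {
  hits <- vapply(1:10, function(s) {
    spec <- sc_sim_spec(n_clusters = 1, cells_per_cluster = 20,
                        n_genes = 400, n_samples_per_condition = 4,
                        nb_mean = 3,
                        planted_degs = data.frame(gene = "G0007",
                                                  cluster = "C1",
                                                  log2FC = 2,
                                                  shared = TRUE))
    sim <- simulate_sc_counts(spec, seed = s)
    deg <- dea_pseudobulk_nb(pseudobulk_sum(sim$human), "C1")
    deg$padj[deg$gene == "G0007"] < 0.05
  }, TRUE)
  expect_gte(sum(hits), 8)
})

test_that("hurdle test handles degenerate genes and permutation nulls", {
  spec <- sc_sim_spec(n_clusters = 1, cells_per_cluster = 50,
                      n_genes = 500, n_samples_per_condition = 2)
  sim <- simulate_sc_counts(spec, seed = 17)
  em <- sim$human
  # permutation null: conditions carry no signal by construction
  deg <- dea_hurdle(em, "C1")
  ks <- stats::ks.test(deg$pval[deg$pval < 1], "punif")
  expect_gt(ks$p.value, 0.01)
  # an all-zero gene gets p = 1
  em$counts["G0001", ] <- 0
  deg2 <- dea_hurdle(em, "C1")
  expect_equal(deg2$pval[deg2$gene == "G0001"], 1)
})

test_that("hurdle test detects a planted detection-rate shift", {
  set.seed(5)
  n <- 200
  counts <- matrix(rpois(400 * 2 * n, 1), nrow = 400,
                   dimnames = list(sprintf("G%04d", 1:400),
                                   sprintf("c%d", 1:(2 * n))))
  grp <- rep(c("ctl", "sti"), each = n)
  # gene detected in ~20% of controls vs ~80% of stimulated cells
  counts["G0005", ] <- c(rbinom(n, 1, 0.2), rbinom(n, 1, 0.8)) *
    (1 + rpois(2 * n, 2))
  cells <- data.frame(cell = colnames(counts), sample = grp,
                      condition = grp, cluster = "k")
  deg <- dea_hurdle(expression_matrix(counts, cells), "k")
  expect_lt(deg$pval[deg$gene == "G0005"], 0.001)
})

test_that("marker detection applies the 25% detection and log2FC filters", {
  set.seed(31)
  n_genes <- 60
  counts <- matrix(rpois(n_genes * 60, 2), nrow = n_genes,
                   dimnames = list(sprintf("G%04d", 1:n_genes),
                                   sprintf("c%d", 1:60)))
  cl <- rep(c("k1", "k2"), each = 30)
  # marker candidate detected in only 10% of in-cluster cells
  counts["G0001", ] <- 0
  counts["G0001", which(cl == "k1")[1:3]] <- 50
  # strong planted marker for k2
  counts["G0002", cl == "k2"] <- counts["G0002", cl == "k2"] + 30
  cells <- data.frame(cell = colnames(counts), sample = "s",
                      condition = "A", cluster = cl)
  mk <- find_cluster_markers(expression_matrix(counts, cells))
  expect_false("G0001" %in% mk$gene[mk$cluster == "k1"])
  expect_equal(mk$gene[mk$cluster == "k2"][1], "G0002")
  expect_true(all(mk$pct_in >= 0.25))
  expect_true(all(abs(mk$log2FC) >= 0.25))
})

test_that("the de_score formula is reproduced with sign symmetry", {
  expect_equal(de_score(0.01, 2), 4)
  expect_equal(de_score(1e-4, -3), 12)
  expect_equal(de_score(1, 5), 0)
  expect_equal(de_score(0.01, -2), de_score(0.01, 2))
  # monotone in both |log2FC| and -log10(p)
  expect_gt(de_score(0.01, 3), de_score(0.01, 2))
  expect_gt(de_score(0.001, 2), de_score(0.01, 2))
  expect_message(s <- de_score(0, 1), "clamped")
  expect_true(is.finite(s) && s > 0)
  expect_error(de_score(0.5, Inf), "finite")
})

test_that("target prioritisation enforces sign rules and tier precedence", {
  matg <- gene_set_collection(list(Collagens = c("COL6A1", "COL1A1",
                                                 "MMP2")))
  mk <- function(gene, method, lfc, padj, pval = padj / 2)
    data.frame(gene = gene, cluster = "k1", comparison = "x vs y",
               log2FC = lfc, pval = pval, padj = padj, method = method)
  # COL6A1: significant by both methods, same sign, modest score (triple
  # with mouse); COL1A1: both methods but opposite signs; MMP2: one
  # method only, huge score
  human <- rbind(
    mk("COL6A1", "pseudobulk_nb", 1.0, 0.01),
    mk("COL6A1", "hurdle", 1.2, 0.02),
    mk("COL1A1", "pseudobulk_nb", 1.0, 0.01),
    mk("COL1A1", "hurdle", -1.0, 0.01),
    mk("MMP2", "pseudobulk_nb", 4, 1e-6),
    mk("MMP2", "hurdle", 0.1, 0.9))
  mouse <- mk("Col6a1", "hurdle", 0.8, 0.01)
  tg <- prioritize_targets(human, mouse, matg)
  expect_true(tg$triple_overlap[tg$gene == "COL6A1"])
  expect_false(tg$method_overlap[tg$gene == "COL1A1"])
  expect_false(tg$triple_overlap[tg$gene == "MMP2"])
  # tier precedence: triple-overlap COL6A1 outranks high-score MMP2
  expect_lt(tg$rank[tg$gene == "COL6A1"], tg$rank[tg$gene == "MMP2"])
  expect_gt(tg$de_score[tg$gene == "MMP2"],
            tg$de_score[tg$gene == "COL6A1"])
  expect_error(prioritize_targets(mk("ZZZ1", "hurdle", 1, 0.01), NULL,
                                  matg), "matrisome")
})

test_that("planted cross-species DEGs are recovered as triple overlaps", {
  hits <- vapply(1:10, function(s) {
    spec <- sc_sim_spec(n_clusters = 1, cells_per_cluster = 40,
                        n_genes = 300, n_samples_per_condition = 4,
                        nb_mean = 3,
                        planted_degs = data.frame(gene = "G0010",
                                                  cluster = "C1",
                                                  log2FC = 2.5,
                                                  shared = TRUE))
    sim <- simulate_sc_counts(spec, seed = 100 + s)
    h1 <- dea_pseudobulk_nb(pseudobulk_sum(sim$human), "C1")
    h2 <- dea_hurdle(sim$human, "C1")
    m1 <- dea_hurdle(sim$mouse, "C1")
    matg <- gene_set_collection(list(M = sprintf("G%04d", 1:50)))
    tg <- prioritize_targets(rbind(h1, h2), m1, matg)
    isTRUE(tg$triple_overlap[tg$gene == "G0010"])
  }, TRUE)
  expect_gte(sum(hits), 9)
})

test_that("cassette overlap partitions gene lists and hits the fixture", {
  fix <- cassette_fixture()
  cs <- cassette_overlap(fix$ra, fix$fs)
  key <- paste(cs$stratum, cs$direction)
  expect_equal(cs$n_shared[key == "lining up"], 10L)
  expect_equal(cs$n_shared[key == "lining down"], 13L)
  expect_equal(cs$n_shared[key == "sublining up"], 6L)
  expect_equal(cs$n_shared[key == "sublining down"], 7L)
  # the three parts are disjoint and union to A and B
  for (i in seq_len(nrow(cs))) {
    sh <- cs$shared[[i]]; ua <- cs$unique_a[[i]]; ub <- cs$unique_b[[i]]
    expect_length(intersect(sh, ua), 0L)
    expect_length(intersect(sh, ub), 0L)
    expect_length(intersect(ua, ub), 0L)
  }
  # set-algebra example
  r <- cassette_overlap(list(l = list(up = c("x", "y", "z"))),
                        list(l = list(up = c("y", "z", "w"))))
  expect_equal(r$shared[[1]], c("y", "z"))
  expect_equal(r$unique_a[[1]], "x")
  expect_equal(r$unique_b[[1]], "w")
  # disjoint lists share nothing
  r2 <- cassette_overlap(list(l = list(up = "a")),
                         list(l = list(up = "b")))
  expect_equal(r2$n_shared, 0L)
})
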