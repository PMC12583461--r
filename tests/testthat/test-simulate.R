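test_that("generators are pure functions of spec and seed", {
  spec <- sc_sim_spec(n_clusters = 2, cells_per_cluster = 5, n_genes = 50,
                      n_samples_per_condition = 2)
  s1 <- simulate_sc_counts(spec, seed = 42)
  s2 <- simulate_sc_counts(spec, seed = 42)
  expect_identical(as.matrix(s1$human$counts), as.matrix(s2$human$counts))
  expect_identical(as.matrix(s1$mouse$counts), as.matrix(s2$mouse$counts))
  d1 <- simulate_degradome(degradome_sim_spec(), 7)
  d2 <- simulate_degradome(degradome_sim_spec(), 7)
  expect_identical(d1$peptides, d2$peptides)
  t1 <- simulate_tissue(tissue_sim_spec(), 7)
  t2 <- simulate_tissue(tissue_sim_spec(), 7)
  expect_identical(t1$scene$fibres, t2$scene$fibres)
  expect_identical(t1$scene$cells, t2$scene$cells)
  a1 <- simulate_abundance_matrix(seed = 3)
  a2 <- simulate_abundance_matrix(seed = 3)
  expect_identical(a1$abundance, a2$abundance)
})

test_that("single-cell spec validation catches planting errors", {
  expect_error(sc_sim_spec(planted_degs = data.frame(gene = "NOPE",
                                                     cluster = "C1",
                                                     log2FC = 1,
                                                     shared = TRUE)),
               "universe")
  expect_error(sc_sim_spec(n_genes = 10,
                           planted_program = list(cluster = "C1",
                                                  genes = "G0001",
                                                  multiplier = 0)),
               "> 0")
  expect_error(sc_sim_spec(nb_dispersion = 0))
})

test_that("null single-cell simulations carry no condition signal", {
  spec <- sc_sim_spec(n_clusters = 1, cells_per_cluster = 20,
                      n_genes = 1000, n_samples_per_condition = 3)
  sim <- simulate_sc_counts(spec, seed = 19)
  deg <- dea_pseudobulk_nb(pseudobulk_sum(sim$human), "C1")
  ks <- stats::ks.test(deg$pval, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("the mouse replica shares planted DEG signs", {
  spec <- sc_sim_spec(n_clusters = 1, cells_per_cluster = 60,
                      n_genes = 100, n_samples_per_condition = 3,
                      nb_mean = 5,
                      planted_degs = data.frame(
                        gene = c("G0001", "G0002"), cluster = "C1",
                        log2FC = 3, shared = c(TRUE, FALSE)))
  sim <- simulate_sc_counts(spec, seed = 23)
  meanfc <- function(em, g) {
    ln <- rowMeans(as.matrix(em$counts[, em$cells$condition == "active"]))
    lr <- rowMeans(as.matrix(em$counts[, em$cells$condition ==
                                         "remission"]))
    log2((ln[g] + 0.1) / (lr[g] + 0.1))
  }
  expect_gt(meanfc(sim$human, "G0001"), 1)
  expect_gt(meanfc(sim$mouse, "G0001"), 1)       # shared: planted
  expect_lt(abs(meanfc(sim$mouse, "G0002")), 1)  # unshared: absent
})

test_that("degradome simulation plants only unambiguous semi-tryptic sites", {
  spec <- degradome_sim_spec()
  sim <- simulate_degradome(spec, 3)
  cls <- suppressMessages(
    classify_peptides(sim$peptides, attr(sim$peptides, "proteins")))
  semi <- cls[cls$tryptic_class == "semi", ]
  for (acc in unique(semi$accession)) {
    expect_true(all(semi$cleavage_pos[semi$accession == acc] %in%
                      spec$endogenous_cleavage_sites[[acc]]))
  }
  # zero cleavage rates leave no semi-tryptic spectral signal
  spec0 <- degradome_sim_spec(cleavage_rate_by_condition = c(RA = 0,
                                                            OA = 0))
  sim0 <- simulate_degradome(spec0, 3)
  cls0 <- suppressMessages(
    classify_peptides(sim0$peptides, attr(sim0$peptides, "proteins")))
  sp0 <- as.matrix(cls0[cls0$tryptic_class == "semi",
                        grep("^spectral_", names(cls0))])
  expect_equal(sum(sp0), 0)
  # planting on a tryptic site is rejected as ambiguous
  prot <- c(P1 = "MAAAKGGGGRWWWW")
  expect_error(degradome_sim_spec(proteins = prot,
                                  endogenous_cleavage_sites =
                                    list(P1 = 5L)),
               "ambiguous")
})

test_that("tissue simulation honours counts, bounds and homogeneity", {
  spec <- tissue_sim_spec(cell_counts_by_type = c(mono = 40L, t = 25L))
  sim <- simulate_tissue(spec, 5)
  expect_equal(nrow(sim$scene$cells), 65L)
  expect_equal(as.integer(table(sim$scene$cells$phenotype)[c("mono", "t")]),
               c(40L, 25L))
  b <- sim$scene$bounds
  expect_true(all(sim$scene$fibres$x >= b[1] & sim$scene$fibres$x <= b[3]))
  # without dark zones the fibre pattern is homogeneous (quadrat test)
  spec0 <- tissue_sim_spec(dark_zone_vessel_fraction = 0)
  sim0 <- simulate_tissue(spec0, 9)
  f <- sim0$scene$fibres
  qx <- cut(f$x, seq(0, 600, by = 150))
  qy <- cut(f$y, seq(0, 600, by = 150))
  cs <- stats::chisq.test(as.vector(table(qx, qy)),
                          p = rep(1 / 16, 16))
  expect_gt(cs$p.value, 0.01)
  # dark zones thin the fibre pattern around their vessels
  sim1 <- simulate_tissue(tissue_sim_spec(), 9)
  dk <- sim1$truth$dark_centres
  rr <- sim1$truth$dark_radius_um
  in_disc <- function(x, y) rowSums(outer(x, dk$x, "-")^2 +
                                      outer(y, dk$y, "-")^2 <= rr^2) > 0
  indark <- in_disc(sim1$scene$fibres$x, sim1$scene$fibres$y)
  # dark-area fraction of the field, by grid
  gr <- expand.grid(x = seq(2.5, 597.5, by = 5), y = seq(2.5, 597.5, by = 5))
  frac_dark <- mean(in_disc(gr$x, gr$y))
  expect_lt(mean(indark), frac_dark / 4)
})

test_that("block abundance matrices induce within-block correlation", {
  sim <- simulate_abundance_matrix(n_proteins = 10, blocks = 2,
                                   noise_sd = 0.1, n_samples = 20,
                                   seed = 2)
  cm <- cor(t(sim$abundance))
  same <- outer(sim$truth, sim$truth, "==")
  diag(same) <- NA
  expect_gt(min(cm[which(same)]), 0.85)
  expect_lt(max(abs(cm[which(!same)])), 0.85)
  # a single protein yields an empty edge set
  one <- simulate_abundance_matrix(n_proteins = 1, blocks = 1, seed = 1)
  net <- correlation_network(one$abundance)
  expect_equal(nrow(net$edges), 0L)
  expect_length(net$communities, 1L)
})
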