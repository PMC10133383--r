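test_that("simulated layers are standardized and reproducible under a seed", {
  st <- simulate_climate_stack(1, 50, 50, autocorr_length = 0, seed = 7)
  expect_equal(sd(as.vector(st$values[, , 1])), 1, tolerance = 0.1)
  expect_equal(mean(as.vector(st$values[, , 1])), 0, tolerance = 1e-10)
  st2 <- simulate_climate_stack(1, 50, 50, autocorr_length = 0, seed = 7)
  expect_identical(st$values, st2$values)  # bit-reproducible
})

test_that("target correlation is honored at the stated accuracy", {
  r1 <- matrix(c(1, 1, 1, 1), 2)
  st <- simulate_climate_stack(2, 60, 60, autocorr_length = 4,
                               target_corr = r1, seed = 3)
  expect_gte(cor(as.vector(st$values[, , 1]), as.vector(st$values[, , 2])),
             0.99)
  st0 <- simulate_climate_stack(2, 200, 200, autocorr_length = 4,
                                target_corr = diag(2), seed = 3)
  expect_lt(abs(cor(as.vector(st0$values[, , 1]),
                    as.vector(st0$values[, , 2]))), 0.1)
  bad <- matrix(c(1, 2, 2, 1), 2)  # not PSD
  expect_error(simulate_climate_stack(2, 20, 20, target_corr = bad),
               "positive semi-definite")
})

test_that("occurrence sampling follows the niche and respects edge cases", {
  st <- tiny_stack(seed = 7)
  same <- list(A = niche_params(c(1, 1, 0), 0.5),
               B = niche_params(c(1, 1, 0), 0.5))
  occ <- simulate_occurrences(st, same, 200, seed = 2)
  envA <- cell_values(st, cell_from_xy(st, occ$A$x, occ$A$y))
  envB <- cell_values(st, cell_from_xy(st, occ$B$x, occ$B$y))
  # identical niches: mean environments differ by < 0.2 sd in every layer
  expect_true(all(abs(colMeans(envA) - colMeans(envB)) < 0.2))
  # divergent-preset geometry (optima 4 tolerances apart in two layers):
  # < 5% histogram overlap along the axis connecting the optima
  apart <- list(A = niche_params(c(-0.5, -0.5, 0), 0.5),
                B = niche_params(c(1.5, 1.5, 0), 0.5))
  occ2 <- simulate_occurrences(st, apart, 200, seed = 2)
  proj <- c(1, 1, 0) / sqrt(2)
  e1 <- cell_values(st, cell_from_xy(st, occ2$A$x, occ2$A$y)) %*% proj
  e2 <- cell_values(st, cell_from_xy(st, occ2$B$x, occ2$B$y)) %*% proj
  brk <- seq(min(e1, e2) - 1e-9, max(e1, e2) + 1e-9, length.out = 30)
  h1 <- hist(e1, breaks = brk, plot = FALSE)$counts / 200
  h2 <- hist(e2, breaks = brk, plot = FALSE)$counts / 200
  expect_lt(sum(pmin(h1, h2)), 0.05)
  one <- simulate_occurrences(st, same["A"], 1, seed = 5)
  expect_equal(nrow(one$A), 1L)
  # all-zero suitability over mask errors with the lineage name
  expect_error(
    simulate_occurrences(st, list(Z = niche_params(c(50, 0, 0), 0.01)), 5,
                         seed = 1),
    "Z")
})

test_that("cell occupancy converges to normalized suitability", {
  st <- tiny_stack(seed = 11, n_layers = 1, nrow = 10, ncol = 10)
  nic <- niche_params(0, 1)
  suit <- as.vector(t(niche_suitability(st, nic)))
  p <- suit / sum(suit)
  occ <- simulate_occurrences(st, list(A = nic), 10000, seed = 3)$A
  cells <- cell_from_xy(st, occ$x, occ$y)
  obs <- tabulate(cells, nbins = 100)
  # chi-square goodness of fit not rejected at alpha = 0.01
  keep <- p > 0
  chi <- sum((obs[keep] - 10000 * p[keep])^2 / (10000 * p[keep]))
  expect_gt(stats::pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE), 0.01)
})

test_that("F-model alignments behave at the panmixia and drift extremes", {
  spec0 <- divergence_spec(list("A", "B"), F = 0)
  al0 <- simulate_locus_alignments(spec0, n_individuals_per_lineage = 10,
                                   n_loci = 500, sites_per_locus = 10,
                                   prop_variable = 0.3, seed = 4)
  sets <- extract_snp_sets(al0, n_sets = 1, seed = 1)
  g <- sets[[1]]$genotypes
  lin <- sets[[1]]$individuals$lineage
  pA <- colMeans(g[lin == "A", ], na.rm = TRUE) / 2
  pB <- colMeans(g[lin == "B", ], na.rm = TRUE) / 2
  # panmixia: the mean (signed) frequency difference is ~0 across loci
  expect_lt(abs(mean(pA - pB)), 0.05)
  spec5 <- divergence_spec(list("A", list("B", "C")), F = 0.5)
  al5 <- simulate_locus_alignments(spec5, n_individuals_per_lineage = 10,
                                   n_loci = 500, sites_per_locus = 10,
                                   prop_variable = 0.3, seed = 4)
  fst <- hudson_fst(extract_snp_sets(al5, n_sets = 1, seed = 1)[[1]])
  expect_gt(fst, 0.2)
})

test_that("F parameter is recovered within 0.1 at 1000 loci", {
  for (f_true in c(0.1, 0.3)) {
    sp <- divergence_spec(list("A", "B"), F = f_true)
    al <- simulate_locus_alignments(sp, n_individuals_per_lineage = 15,
                                    n_loci = 1000, sites_per_locus = 5,
                                    prop_variable = 0.5, seed = 21)
    fst <- hudson_fst(extract_snp_sets(al, n_sets = 1, seed = 2)[[1]])
    expect_equal(fst, f_true, tolerance = 0.1)
  }
})

test_that("completeness controls per-individual locus presence", {
  sp <- divergence_spec(list("A", "B"), F = 0.2)
  al <- simulate_locus_alignments(sp, n_individuals_per_lineage = 5,
                                  n_loci = 50, sites_per_locus = 8,
                                  completeness = 1.0, seed = 9)
  expect_true(all(vapply(al$loci, nrow, integer(1)) == 20L))  # 10 ind x 2 hap
  expect_error(simulate_locus_alignments(sp, completeness = 0), "completeness")
})

test_that("FASTA round-trip preserves alignments and phase suffixes", {
  sp <- divergence_spec(list("A", "B"), F = 0.3)
  al <- simulate_locus_alignments(sp, n_individuals_per_lineage = 3,
                                  n_loci = 4, sites_per_locus = 12, seed = 2)
  d <- withr::local_tempdir()
  write_locus_alignments(al, d)
  al2 <- read_locus_alignments(d)
  expect_equal(names(al2$loci), names(al$loci))
  expect_identical(al2$loci[[1]], al$loci[[1]])
  expect_true(all(grepl("/[01]$", rownames(al2$loci[[2]]))))
})

test_that("trait tables have the stated shape and positivity", {
  tt <- simulate_trait_table(10, 25, n_lineages = 3, seed = 6)
  expect_equal(dim(tt), c(30L, 26L))  # lineage column + 25 traits
  expect_true(all(tt[, -1] > 0))
  tt2 <- simulate_trait_table(10, 25, n_lineages = 3, seed = 6)
  expect_identical(tt, tt2)
})

test_that("lineage_shift drives downstream PCA separation", {
  flat <- simulate_trait_table(10, 25, n_lineages = 3, lineage_shift = 0,
                               seed = 31)
  sep <- simulate_trait_table(10, 25, n_lineages = 3, lineage_shift = 5,
                              seed = 31)
  sil <- function(tt) {
    sc <- embed_pca(tt[, -1], log_transform = TRUE)$scores[, 1:2]
    cohesiondelim:::mean_silhouette(sc, tt$lineage)
  }
  expect_lt(sil(flat), 0.2)
  expect_gt(sil(sep), 0.5)
})
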