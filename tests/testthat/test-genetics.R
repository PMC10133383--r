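make_aligns <- function(loci, lineages) {
  # build a locus_alignment_set from a list of haplotype-character matrices
  inds <- data.frame(
    individual = names(lineages), lineage = unname(lineages),
    stringsAsFactors = FALSE)
  structure(list(loci = loci, individuals = inds, completeness = 1,
                 provenance = list()), class = "locus_alignment_set")
}

test_that("SNP extraction drops invariant loci and fixes single-site loci", {
  lin <- c(i1 = "A", i2 = "B")
  inv <- matrix("A", 4, 5,
                dimnames = list(c("i1/0", "i1/1", "i2/0", "i2/1"), NULL))
  one <- inv
  one[, 3] <- c("A", "A", "G", "G")  # exactly one biallelic site
  aligns <- make_aligns(list(locus_a = inv, locus_b = one), lin)
  sets <- extract_snp_sets(aligns, n_sets = 5, seed = 1)
  expect_length(sets, 5)
  for (s in sets) {
    expect_equal(colnames(s$genotypes), "locus_b")
    expect_equal(unname(s$chosen_sites), 3L)  # same site in all 5 sets
    expect_equal(unname(s$genotypes["i1", ]), 0L)
    expect_equal(unname(s$genotypes["i2", ]), 2L)
  }
  # all-invariant input errors
  expect_error(extract_snp_sets(make_aligns(list(x = inv), lin)),
               "no locus")
})

test_that("sites with gaps or ambiguity codes are excluded", {
  lin <- c(i1 = "A", i2 = "B")
  m <- matrix("C", 4, 3,
              dimnames = list(c("i1/0", "i1/1", "i2/0", "i2/1"), NULL))
  m[, 1] <- c("C", "C", "T", "-")   # gap segregating -> excluded
  m[, 2] <- c("C", "N", "T", "T")   # ambiguity -> excluded
  m[, 3] <- c("C", "T", "T", "T")   # clean biallelic
  sets <- extract_snp_sets(make_aligns(list(l = m), lin), n_sets = 2, seed = 1)
  expect_equal(unname(sets[[1]]$chosen_sites), 3L)
  # multi-allelic excluded entirely
  m2 <- m
  m2[, 3] <- c("A", "C", "G", "G")
  expect_error(extract_snp_sets(make_aligns(list(l = m2[, 3, drop = FALSE]),
                                            lin)),
               "no locus")
})

test_that("missing individuals yield NA genotypes", {
  lin <- c(i1 = "A", i2 = "A", i3 = "B")
  m <- matrix(c("A", "A", "G", "G"), 4, 2,
              dimnames = list(c("i1/0", "i1/1", "i3/0", "i3/1"), NULL))
  sets <- extract_snp_sets(make_aligns(list(l = m), lin), n_sets = 1, seed = 3)
  expect_true(is.na(sets[[1]]$genotypes["i2", "l"]))
})

test_that("one-hot encoding has the stated shape and codes", {
  g <- matrix(c(2L, NA, 0L, 1L), 2, 2,
              dimnames = list(c("i1", "i2"), c("l1", "l2")))
  snp <- structure(list(set_id = 1L, genotypes = g,
                        individuals = data.frame(individual = c("i1", "i2"),
                                                 lineage = c("A", "B"))),
                   class = "snp_matrix")
  enc <- one_hot(snp)
  expect_equal(dim(enc), c(2L, 6L))
  expect_equal(unname(enc["i1", 1:3]), c(0, 0, 1))  # genotype 2
  expect_equal(unname(enc["i2", 1:3]), c(0, 0, 0))  # missing -> zero triplet
  expect_equal(unname(enc["i2", 4:6]), c(0, 1, 0))  # genotype 1
  snp$genotypes[1, 1] <- 7L
  expect_error(one_hot(snp), "i1.*l1")
})

test_that("VAE training reduces the loss and is seed-reproducible", {
  set.seed(5)
  enc <- matrix(rbinom(12 * 30, 1, 0.5), 12, 30)
  rownames(enc) <- paste0("i", 1:12)
  emb <- embed_vae(enc, n_replicates = 2, epochs = 60, seed = 9)
  expect_lt(emb$loss, emb$trajectory[1])  # final < initial
  expect_true(all(emb$sd > 0))
  expect_equal(nrow(emb$mu), 12L)
  emb2 <- embed_vae(enc, n_replicates = 2, epochs = 60, seed = 9)
  expect_identical(emb$mu, emb2$mu)  # latent geometry reproducible
  expect_error(embed_vae(enc[1:3, ]), "at least 4")
})

test_that("an overfit VAE round-trips tiny genotype matrices", {
  # 2 individuals x 3 loci, maximally distinct genotypes
  g <- matrix(c(0L, 2L, 2L, 0L, 1L, 0L), 2, 3,
              dimnames = list(c("i1", "i2"), paste0("l", 1:3)))
  snp <- structure(list(set_id = 1L, genotypes = g,
                        individuals = data.frame(individual = c("i1", "i2"),
                                                 lineage = c("A", "B"))),
                   class = "snp_matrix")
  enc <- one_hot(snp)
  # below the public API's 4-individual floor, so drive the trainer directly
  run <- cohesiondelim:::vae_train(enc, epochs = 2500, seed = 4, h1 = 32)
  recon <- cohesiondelim:::vae_decode(run$par, run$mu)
  # decode the argmax genotype per locus and compare
  for (i in 1:2) for (l in 1:3) {
    trip <- recon[i, (3 * (l - 1) + 1):(3 * l)]
    expect_equal(which.max(trip) - 1L, unname(g[i, l]))
  }
})

test_that("PCA matches the analytic variance split and an eigen oracle", {
  set.seed(11)
  x <- cbind(rnorm(4000, sd = 2), rnorm(4000, sd = 1))
  p <- embed_pca(x, scale. = FALSE)
  expect_equal(p$variance_fraction[1], 0.8, tolerance = 0.03)
  # eigen oracle on a small matrix
  y <- matrix(rnorm(60), 12, 5)
  p2 <- embed_pca(y, scale. = FALSE)
  ev <- eigen(cov(y))
  scores_oracle <- scale(y, center = TRUE, scale = FALSE) %*% ev$vectors
  for (j in 1:5)
    expect_equal(abs(p2$scores[, j]), abs(scores_oracle[, j]),
                 tolerance = 1e-9, ignore_attr = TRUE)
  # row-order invariance (up to the same reordering)
  perm <- sample(12)
  p3 <- embed_pca(y[perm, ], scale. = FALSE)
  expect_equal(p3$scores, p2$scores[perm, ], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("PCA handles trait tables, log transform, and constant columns", {
  tt <- simulate_trait_table(10, 25, n_lineages = 3, seed = 13)
  p <- embed_pca(tt, log_transform = TRUE)
  expect_equal(nrow(p$scores), 30L)
  expect_equal(ncol(p$scores), 25L)
  expect_equal(sum(p$variance_fraction), 1)
  bad <- tt; bad$trait1 <- -bad$trait1
  expect_error(embed_pca(bad, log_transform = TRUE), "positive")
  cst <- cbind(tt[, 2:4], fixed = 1)
  expect_warning(p2 <- embed_pca(cst), "constant")
  expect_equal(p2$dropped, "fixed")
  # deterministic sign: largest-magnitude loading positive
  expect_true(all(apply(p$loadings, 2,
                        function(v) v[which.max(abs(v))] > 0)))
})

test_that("clustering verdicts follow the stated thresholds", {
  far <- rbind(matrix(rnorm(20, 0, 0.05), 10, 2),
               matrix(rnorm(20, 10, 0.05), 10, 2))
  labels <- rep(c("A", "B"), each = 10)
  a <- assess_clustering(far, labels)
  expect_equal(a$verdict, "separate")
  expect_gt(a$silhouette, 0.9)
  expect_equal(a$ari, 1)
  blob <- matrix(rnorm(40), 20, 2)
  a2 <- assess_clustering(blob, sample(labels))
  expect_equal(a2$verdict, "overlapping")
  expect_lt(abs(a2$ari), 0.5)
  expect_equal(a2$silhouette_threshold, 0.35)
  expect_equal(a2$ari_threshold, 0.9)
  expect_error(assess_clustering(blob, rep("A", 20)), "two distinct")
})

test_that("adjusted Rand index matches hand-computed values", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  # hand-computed: partitions {1,1,1,2} vs {1,2,2,2} on n = 4
  # contingency: [[1,2],[0,1]]; sum_ij C2 = 1; a = C(3,2)+C(1,2) = 3;
  # b = 3; exp = 9/6 = 1.5; max = 3 -> ARI = (1-1.5)/(3-1.5) = -1/3
  expect_equal(adjusted_rand_index(c(1, 1, 1, 2), c(1, 2, 2, 2)), -1 / 3)
  expect_error(adjusted_rand_index(1:3, 1:4), "equal length")
})

test_that("SNP-set replicate verdicts agree under strong drift", {
  sp <- divergence_spec(list("A", "B"), F = 0.5)
  al <- simulate_locus_alignments(sp, n_individuals_per_lineage = 8,
                                  n_loci = 120, sites_per_locus = 12,
                                  prop_variable = 0.3, completeness = 0.9,
                                  seed = 15)
  sets <- extract_snp_sets(al, n_sets = 5, seed = 16)
  labels <- sets[[1]]$individuals$lineage
  # PCA embedding per set keeps this fast; verdicts should agree >= 4/5
  verdicts <- vapply(sets, function(s) {
    # constant one-hot columns (monomorphic within the sample) drop with a
    # warning by design; silence it here
    sc <- suppressWarnings(embed_pca(one_hot(s), scale. = FALSE))$scores[, 1:2]
    assess_clustering(sc, labels)$verdict
  }, character(1))
  expect_gte(max(table(verdicts)), 4)
})
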