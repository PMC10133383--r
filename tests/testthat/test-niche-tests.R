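test_that("Schoener's D matches the analytic cases and a brute-force loop", {
  u <- matrix(1 / 36, 6, 6)
  expect_equal(schoener_d(surface_from_raw(u), surface_from_raw(u)), 1)
  a <- matrix(0, 6, 6); a[1, 1] <- 1
  b <- matrix(0, 6, 6); b[6, 6] <- 1
  expect_equal(schoener_d(surface_from_raw(a), surface_from_raw(b)), 0)
  # two cells: (1, 0) vs (0.5, 0.5) -> 0.5
  p <- matrix(c(1, 0), 1); q <- matrix(c(0.5, 0.5), 1)
  expect_equal(schoener_d(surface_from_raw(p), surface_from_raw(q)), 0.5)
  # brute-force oracle on random surfaces
  set.seed(101)
  for (i in 1:100) {
    ra <- matrix(rexp(25), 5); ra <- ra / sum(ra)
    rb <- matrix(rexp(25), 5); rb <- rb / sum(rb)
    d <- schoener_d(surface_from_raw(ra), surface_from_raw(rb))
    brute <- 0
    for (r in 1:5) for (cc in 1:5) brute <- brute + abs(ra[r, cc] - rb[r, cc])
    expect_equal(d, 1 - brute / 2, tolerance = 1e-12)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, schoener_d(surface_from_raw(rb), surface_from_raw(ra)))
  }
  expect_error(schoener_d(surface_from_raw(u), surface_from_raw(p)),
               "different grids")
})

test_that("D is invariant under integer grid refinement", {
  set.seed(7)
  ra <- matrix(rexp(16), 4); ra <- ra / sum(ra)
  rb <- matrix(rexp(16), 4); rb <- rb / sum(rb)
  refine <- function(m, k) m[rep(1:4, each = k), rep(1:4, each = k)] / k^2
  d1 <- schoener_d(surface_from_raw(ra), surface_from_raw(rb))
  d3 <- schoener_d(surface_from_raw(refine(ra, 3)),
                   surface_from_raw(refine(rb, 3)))
  expect_equal(d1, d3, tolerance = 1e-12)
})

test_that("equivalency test flags separated niches and not identical ones", {
  st <- tiny_stack(seed = 53)
  cfg <- light_config("L", 1)
  apart <- simulate_occurrences(
    st, list(A = niche_params(c(-1, -1, 0), 0.5),
             B = niche_params(c(1, 1, 0), 0.5)), c(40, 55), seed = 3)
  eq <- equivalency_test(apart$A, apart$B, st, cfg, n_reps = 99, seed = 11)
  expect_equal(eq$outcome, "not equivalent")
  expect_lt(eq$p_lower, 0.05)
  expect_equal(length(eq$null), 99L)
  expect_true(all(eq$null >= 0 & eq$null <= 1))
  same <- simulate_occurrences(
    st, list(A = niche_params(c(1, 1, 0), 0.5),
             B = niche_params(c(1, 1, 0), 0.5)), c(40, 55), seed = 4)
  eq2 <- equivalency_test(same$A, same$B, st, cfg, n_reps = 99, seed = 12)
  expect_gt(eq2$p_lower, 0.05)
  expect_error(equivalency_test(same$A, same$B, st, cfg, n_reps = 9),
               "at least 19")
})

test_that("equivalency test is reproducible under a fixed seed", {
  st <- tiny_stack(seed = 59, nrow = 30, ncol = 30)
  occ <- simulate_occurrences(
    st, list(A = niche_params(c(1, 1, 0), 0.5),
             B = niche_params(c(1, 1, 0), 0.5)), c(20, 25), seed = 5)
  cfg <- light_config("L", 1, 900)
  e1 <- equivalency_test(occ$A, occ$B, st, cfg, n_reps = 19, seed = 21)
  e2 <- equivalency_test(occ$A, occ$B, st, cfg, n_reps = 19, seed = 21)
  expect_identical(e1$observed, e2$observed)
  expect_identical(e1$null, e2$null)
})

test_that("similarity null built from B's own occupied cells is not significant", {
  st <- tiny_stack(seed = 61)
  cfg <- light_config("LQ", 0.5)
  occ <- simulate_occurrences(
    st, list(A = niche_params(c(1, 1, 0), 0.5),
             B = niche_params(c(1, 1, 0), 0.5)), c(40, 55), seed = 6)
  fa <- fit_sdm(occ$A, st, cfg, seed = 7)
  fb <- fit_sdm(occ$B, st, cfg, seed = 7)
  # region = exactly B's occupied cells: pseudo-occurrences are
  # distributionally identical to the real ones, so "not significant"
  # should dominate
  reg <- background_region("custom", attr(fb$presences, "cells"),
                           lineage = "B")
  outs <- vapply(1:5, function(i) {
    similarity_test(fa$surface, fb$surface, reg, st, cfg, n_reps = 99,
                    seed = 30 + i,
                    n_pseudo = nrow(fb$presences) - 5)$outcome
  }, character(1))
  expect_gte(sum(outs == "not significant"), 3)
})

test_that("similarity test validates region size and replicate count", {
  st <- tiny_stack(seed = 67, nrow = 20, ncol = 20)
  occ <- simulate_occurrences(st, list(A = niche_params(c(1, 1, 0), 0.5),
                                       B = niche_params(c(1, 1, 0), 0.5)),
                              c(15, 15), seed = 8)
  cfg <- light_config("L", 1, 400)
  fa <- fit_sdm(occ$A, st, cfg, seed = 9)
  fb <- fit_sdm(occ$B, st, cfg, seed = 9)
  small <- background_region("custom", 1:3)
  expect_error(similarity_test(fa$surface, fb$surface, small, st, cfg,
                               n_reps = 99, seed = 1), "smaller than")
  big <- background_region("custom", valid_cells(st))
  expect_error(similarity_test(fa$surface, fb$surface, big, st, cfg,
                               n_reps = 9, seed = 1), "at least 39")
})

test_that("the pairwise battery has the documented result structure", {
  st <- tiny_stack(seed = 71, nrow = 40, ncol = 40)
  occ <- simulate_occurrences(st, list(A = niche_params(c(1, 1, 0), 0.5),
                                       B = niche_params(c(1, 1, 0), 0.5)),
                              c(25, 30), seed = 10)
  cfg <- light_config("LQ", 0.5, 1600)
  bat <- run_pairwise_battery(occ, st, cfg,
                              methods = c("mcp", "thresh50"),
                              n_reps = 39, seed = 31)
  tab <- bat$table
  # 2 lineages, 2 methods: 1 equivalency + 4 similarity rows
  expect_equal(sum(tab$kind == "equivalency"), 1L)
  expect_equal(sum(tab$kind == "similarity"), 4L)
  expect_equal(unique(tab$comparison), "A to B")
  expect_setequal(unique(tab$method[tab$kind == "similarity"]),
                  c("mcp", "thresh50"))
  bat2 <- run_pairwise_battery(occ, st, cfg,
                               methods = c("mcp", "thresh50"),
                               n_reps = 39, seed = 31)
  expect_identical(bat$table, bat2$table)  # fixed seed, identical table
})

test_that("merged lineages run through the battery like atomic ones", {
  st <- tiny_stack(seed = 73, nrow = 40, ncol = 40)
  occ <- simulate_occurrences(
    st, list(North = niche_params(c(-1, -0.5, 0), 0.5),
             Central = niche_params(c(0.8, 0.4, 0), 0.5),
             South = niche_params(c(1.2, 0.8, 0), 0.5)),
    c(20, 25, 30), seed = 11)
  merged <- list(
    North = occ$North,
    `Central+South` = merge_occurrences(occ$Central, occ$South))
  expect_equal(merged$`Central+South`$lineage[1], "Central+South")
  bat <- run_pairwise_battery(merged, st, light_config("L", 1, 1600),
                              methods = "mcp", n_reps = 39, seed = 41)
  expect_equal(unique(bat$table$comparison), "North to Central+South")
})
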