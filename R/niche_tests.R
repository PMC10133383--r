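# Niche overlap and the two randomization tests of ecological
# interchangeability: the equivalency (identity) test, which pools and
# repartitions occurrences, and the background-similarity test, which
# compares observed overlap to overlap with models fit to random draws from
# a lineage's available background.

#' Schoener's D niche overlap
#'
#' `D = 1 - 0.5 * sum_i |p_A,i - p_B,i|` over non-missing cells of the raw
#' (sum-to-one) suitability views; ranges from 0 (no overlap) to 1 (complete
#' overlap) and is symmetric.
#'
#' @param a,b [suitability_surface][predict_surface]s on the same grid and
#'   mask.
#' @return the overlap D in \[0, 1\].
#' @export
schoener_d <- function(a, b) {
  if (a$nrow != b$nrow || a$ncol != b$ncol)
    stop("surfaces are on different grids")
  if (!identical(which(is.na(a$raw)), which(is.na(b$raw))))
    stop("surfaces have different missing-value masks")
  1 - 0.5 * sum(abs(a$raw - b$raw), na.rm = TRUE)
}

# D between two raw vectors over the same valid cells.
schoener_d_vec <- function(ra, rb) 1 - 0.5 * sum(abs(ra - rb))

# Common result container.
niche_test_result <- function(kind, direction, observed, null, n_reps, alpha,
                              seed, outcome, p_lower, p_upper = NA_real_,
                              method = NA_character_) {
  structure(list(kind = kind, direction = direction, observed = observed,
                 null = null, p_lower = p_lower, p_upper = p_upper,
                 outcome = outcome, n_reps = n_reps, alpha = alpha,
                 seed = seed, method = method),
            class = "niche_test")
}

#' @export
print.niche_test <- function(x, ...) {
  cat(sprintf("<niche_test:%s> %s  D = %.4f  p_lower = %.4f  -> %s\n",
              x$kind, x$direction, x$observed, x$p_lower, x$outcome))
  invisible(x)
}

#' Niche equivalency (identity) test
#'
#' One-tailed randomization test of whether two lineages' niches are
#' identical. The observed D comes from SDMs fit to each lineage's thinned
#' occurrences over a shared background. Each replicate pools all occurrence
#' records, repartitions them at random into the original sample sizes, refits
#' both SDMs with the observed models' selected feature class and
#' regularization multiplier (full reselection with
#' `config$reselect_per_rep = TRUE`), and records D. Niches are declared not
#' identical when the observed D falls significantly below the null
#' (`p_lower < alpha`).
#'
#' @param occ_a,occ_b [occurrence_set]s.
#' @param stack a [climate_stack].
#' @param config an [sdm_config].
#' @param n_reps permutation replicates (>= 19).
#' @param alpha one-tailed significance level.
#' @param seed integer seed.
#' @return a `niche_test` (kind `"equivalency"`); the fitted observed
#'   surfaces are attached as the `fits` attribute.
#' @export
equivalency_test <- function(occ_a, occ_b, stack, config = sdm_config(),
                             n_reps = 99, alpha = 0.05, seed = 1) {
  if (n_reps < 19) stop("n_reps must be at least 19")
  bg_n <- min(config$n_background, length(valid_cells(stack)))
  background <- sample_background(stack, bg_n, seed = derive_seed(seed, 0))
  fit_a <- fit_sdm(occ_a, stack, config, background = background)
  fit_b <- fit_sdm(occ_b, stack, config, background = background)
  observed <- schoener_d(fit_a$surface, fit_b$surface)
  pa <- fit_a$presences
  pb <- fit_b$presences
  n_a <- nrow(pa)
  n_b <- nrow(pb)
  pool_xy <- rbind(cbind(pa$x, pa$y), cbind(pb$x, pb$y))
  bounds <- apply(cell_values(stack, background$cell), 2, range)
  engines <- rep_engines(stack, config, bounds,
                         c(fit_a$model$fc, fit_b$model$fc))
  null <- with_seed(derive_seed(seed, 1), {
    vapply(seq_len(n_reps), function(r) {
      idx <- sample(n_a + n_b, n_a)
      d_ab <- lapply(list(idx, setdiff(seq_len(n_a + n_b), idx)), function(ii) {
        xy <- pool_xy[ii, , drop = FALSE]
        occ <- occurrence_set("rep", xy[, 1], xy[, 2])
        suppressWarnings(thin_occurrences(occ, stack))
      })
      m1 <- rep_fit(attr(d_ab[[1]], "cells"), background$cell, engines,
                    config, fit_a$model)
      m2 <- rep_fit(attr(d_ab[[2]], "cells"), background$cell, engines,
                    config, fit_b$model)
      schoener_d_vec(m1$raw_valid, m2$raw_valid)
    }, numeric(1))
  })
  p_lower <- (1 + sum(null <= observed)) / (n_reps + 1)
  outcome <- if (p_lower < alpha) "not equivalent" else "not significant"
  res <- niche_test_result("equivalency",
                           paste0(pa$lineage[1], "-vs-", pb$lineage[1]),
                           observed, null, n_reps, alpha, seed, outcome,
                           p_lower)
  attr(res, "fits") <- list(a = fit_a, b = fit_b)
  res
}

# Engine cache shared by replicate fits: one design per needed feature class.
rep_engines <- function(stack, config, bounds, fcs) {
  fcs <- unique(if (config$reselect_per_rep) config$fc else fcs)
  stats::setNames(lapply(fcs, function(fc)
    sdm_engine(stack, fc, config$hinge_knots, bounds)), fcs)
}

# One replicate fit: either reuse the observed model's fc/rm or redo full
# candidate selection.
rep_fit <- function(pres_cells, bg_cells, engines, config, observed_model) {
  if (!config$reselect_per_rep) {
    return(fit_model_engine(pres_cells, bg_cells,
                            engines[[observed_model$fc]], observed_model$rm))
  }
  cands <- list()
  for (fc in names(engines))
    for (rm in config$rm)
      cands[[length(cands) + 1]] <-
        fit_model_engine(pres_cells, bg_cells, engines[[fc]], rm)
  select_model(cands)
}

#' Niche background-similarity test
#'
#' Two-tailed randomization test of whether the overlap between lineage A's
#' SDM and lineage B's SDM is more similar (niche conservatism) or more
#' different (niche divergence) than expected given the environment available
#' to B. Each replicate draws `n_pseudo` cells uniformly without replacement
#' from B's background region, fits an SDM to those pseudo-occurrences with
#' B's selected feature class and regularization multiplier, and records its
#' D against A's observed surface. The observed D is compared with the
#' `alpha_per_tail` and `1 - alpha_per_tail` null quantiles.
#'
#' @param surface_a lineage A's observed [suitability_surface][predict_surface].
#' @param surface_b lineage B's observed surface (its model supplies the
#'   replicate fc/rm and the default `n_pseudo`).
#' @param region_b lineage B's [background_region].
#' @param stack a [climate_stack].
#' @param config an [sdm_config].
#' @param n_reps randomization replicates (>= 39).
#' @param alpha_per_tail per-tail significance level (default 0.025).
#' @param seed integer seed.
#' @param n_pseudo pseudo-occurrence count per replicate; defaults to B's
#'   thinned occurrence count.
#' @param background optional pre-sampled background points.
#' @return a `niche_test` (kind `"similarity"`) whose `direction` reads
#'   `"<A>-vs-background:<B>"` and whose `method` records the region type.
#' @export
similarity_test <- function(surface_a, surface_b, region_b, stack,
                            config = sdm_config(), n_reps = 99,
                            alpha_per_tail = 0.025, seed = 1,
                            n_pseudo = NULL, background = NULL) {
  if (n_reps < 39) stop("n_reps must be at least 39")
  n_pseudo <- n_pseudo %||% surface_b$model$n
  if (length(region_b$cells) < n_pseudo)
    stop(sprintf("background region (%d cells) smaller than n_pseudo = %d",
                 length(region_b$cells), n_pseudo))
  observed <- schoener_d(surface_a, surface_b)
  if (is.null(background)) {
    bg_n <- min(config$n_background, length(valid_cells(stack)))
    background <- sample_background(stack, bg_n, seed = derive_seed(seed, 0))
  }
  bounds <- apply(cell_values(stack, background$cell), 2, range)
  engines <- rep_engines(stack, config, bounds, surface_b$model$fc)
  vc <- valid_cells(stack)
  raw_a <- as.vector(t(surface_a$raw))[vc]
  null <- with_seed(derive_seed(seed, 1), {
    vapply(seq_len(n_reps), function(r) {
      cells <- sample(region_b$cells, n_pseudo)
      m <- rep_fit(cells, background$cell, engines, config, surface_b$model)
      schoener_d_vec(raw_a, m$raw_valid)
    }, numeric(1))
  })
  p_lower <- (1 + sum(null <= observed)) / (n_reps + 1)
  p_upper <- (1 + sum(null >= observed)) / (n_reps + 1)
  lo <- stats::quantile(null, alpha_per_tail, names = FALSE)
  hi <- stats::quantile(null, 1 - alpha_per_tail, names = FALSE)
  outcome <- if (observed > hi) "conservatism"
             else if (observed < lo) "divergence"
             else "not significant"
  a_lab <- surface_a$model$lineage %||% "A"
  b_lab <- region_b$lineage %||% "B"
  niche_test_result("similarity",
                    paste0(a_lab, "-vs-background:", b_lab),
                    observed, null, n_reps, alpha_per_tail, seed, outcome,
                    p_lower, p_upper, method = region_b$method)
}

#' Run the full pairwise niche-test battery
#'
#' For every unordered lineage pair: Schoener's D, one equivalency test, and
#' — for each background-region method — similarity tests in both directions.
#' Merged lineages are supported by passing merged occurrence sets (see
#' [merge_occurrences]).
#'
#' @param occs named list of [occurrence_set]s (>= 2).
#' @param stack a [climate_stack].
#' @param config an [sdm_config].
#' @param methods background-region methods, a subset of
#'   `c("mcp", "thresh50", "thresh75")`.
#' @param n_reps replicates for both tests.
#' @param alpha equivalency significance level.
#' @param alpha_per_tail similarity per-tail level.
#' @param seed integer seed.
#' @param pairs optional list of character pairs of lineage names; default
#'   all unordered pairs.
#' @return a list with `results` (nested per pair) and `table` — a long
#'   data frame with one row per test (comparison, n_a, n_b, D, kind,
#'   direction, method, p_lower, outcome).
#' @export
run_pairwise_battery <- function(occs, stack, config = sdm_config(),
                                 methods = c("mcp", "thresh50", "thresh75"),
                                 n_reps = 99, alpha = 0.05,
                                 alpha_per_tail = 0.025, seed = 1,
                                 pairs = NULL) {
  if (length(occs) < 2) stop("need at least two lineages")
  if (is.null(pairs))
    pairs <- utils::combn(names(occs), 2, simplify = FALSE)
  results <- list()
  rows <- list()
  for (pi in seq_along(pairs)) {
    pr <- pairs[[pi]]
    pseed <- derive_seed(seed, pi)
    eq <- equivalency_test(occs[[pr[1]]], occs[[pr[2]]], stack, config,
                           n_reps = n_reps, alpha = alpha, seed = pseed)
    fits <- attr(eq, "fits")
    n_a <- nrow(fits$a$presences)
    n_b <- nrow(fits$b$presences)
    comp <- paste(pr, collapse = " to ")
    rows[[length(rows) + 1]] <- data.frame(
      comparison = comp, n_a = n_a, n_b = n_b, D = eq$observed,
      kind = "equivalency", direction = eq$direction, method = NA_character_,
      p_lower = eq$p_lower, outcome = eq$outcome, stringsAsFactors = FALSE)
    sims <- list()
    sides <- list(c("a", "b"), c("b", "a"))
    for (mth in methods) {
      for (sd_i in seq_along(sides)) {
        first <- sides[[sd_i]][1]
        second <- sides[[sd_i]][2]
        occ_2 <- occs[[pr[if (second == "a") 1 else 2]]]
        region <- switch(mth,
          mcp = mcp_region(occ_2, stack),
          thresh50 = threshold_region(fits[[second]]$surface, 0.5),
          thresh75 = threshold_region(fits[[second]]$surface, 0.75),
          stop("unknown background method: ", mth))
        sim <- similarity_test(fits[[first]]$surface, fits[[second]]$surface,
                               region, stack, config, n_reps = n_reps,
                               alpha_per_tail = alpha_per_tail,
                               seed = derive_seed(pseed, 10 + 2 * match(mth, methods) + sd_i),
                               background = fits[[first]]$background)
        sims[[paste(mth, sd_i, sep = "_")]] <- sim
        rows[[length(rows) + 1]] <- data.frame(
          comparison = comp, n_a = n_a, n_b = n_b, D = sim$observed,
          kind = "similarity", direction = sim$direction, method = mth,
          p_lower = sim$p_lower, outcome = sim$outcome,
          stringsAsFactors = FALSE)
      }
    }
    results[[comp]] <- list(equivalency = eq, similarity = sims,
                            overlap = eq$observed, fits = fits)
  }
  list(results = results, table = do.call(rbind, rows))
}
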