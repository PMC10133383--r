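# Presence-background maximum-entropy-style SDMs.
#
# The model is the Gibbs distribution over grid cells
#   q_i(beta) = exp(beta . f(x_i)) / sum_j exp(beta . f(x_j)),
# fit by maximizing the average presence log-likelihood under q (with the
# partition function estimated over a background sample) minus an L1 penalty
# rm * sum_j lambda_j |beta_j|, with per-feature weights
# lambda_j = max(sqrt(s2_j / n), 1e-3) (s2_j = presence sample variance of
# feature j, n = presence count) — the MaxEnt convention of tying the penalty
# to the sampling uncertainty of each feature's presence mean.

#' Candidate-grid configuration for SDM fitting
#'
#' @param fc character vector of feature-class codes, subsets of
#'   `{L, Q, P, H}` (linear, quadratic, product, hinge). The default grid of 6
#'   classes x 5 regularization multipliers yields 30 candidate models.
#' @param rm numeric vector of regularization multipliers (> 0).
#' @param n_background background sample size (capped at the number of
#'   non-missing cells).
#' @param hinge_knots hinge knots per layer and direction.
#' @param reselect_per_rep logical: refit the full candidate grid inside every
#'   randomization replicate (slow) instead of reusing the observed models'
#'   selected fc/rm.
#' @return an `sdm_config` list.
#' @export
sdm_config <- function(fc = c("L", "LQ", "H", "LQH", "LQP", "LQPH"),
                       rm = c(0.5, 1, 2, 3, 4),
                       n_background = 10000, hinge_knots = 4,
                       reselect_per_rep = FALSE) {
  if (any(rm <= 0)) stop("regularization multipliers must be > 0")
  structure(list(fc = fc, rm = rm, n_background = n_background,
                 hinge_knots = hinge_knots,
                 reselect_per_rep = reselect_per_rep), class = "sdm_config")
}

#' Thin occurrences to one record per grid cell
#'
#' The first record (input order) in each cell is retained; records falling
#' on masked or out-of-grid cells are dropped and counted in the
#' `n_dropped_masked` attribute.
#'
#' @param occ an [occurrence_set].
#' @param stack the [climate_stack] defining the cell grid.
#' @return the thinned `occurrence_set` with attributes `cells` (cell index
#'   per retained record) and `n_dropped_masked`.
#' @export
thin_occurrences <- function(occ, stack) {
  cells <- cell_from_xy(stack, occ$x, occ$y)
  on_grid <- !is.na(cells)
  valid <- on_grid
  valid[on_grid] <- t(stack$mask)[cells[on_grid]]
  n_masked <- sum(!valid)
  if (n_masked > 0)
    warning(sprintf("%d record(s) on masked or out-of-grid cells dropped",
                    n_masked))
  keep <- valid & !duplicated(cells)
  if (!any(keep)) stop("no occurrence records remain after thinning")
  out <- occ[keep, , drop = FALSE]
  class(out) <- class(occ)
  attr(out, "cells") <- cells[keep]
  attr(out, "n_dropped_masked") <- n_masked
  attr(out, "note") <- attr(occ, "note")
  out
}

#' Sample background cells
#'
#' Uniform draw without replacement from the non-missing cells of the stack
#' (within `region` if given); if `n` exceeds the available cells the draw
#' falls back to sampling with replacement and is flagged.
#'
#' @param stack a [climate_stack].
#' @param n number of background points (>= 1).
#' @param region optional [background_region] restricting the draw.
#' @param seed integer seed.
#' @return data frame with columns `cell`, `x`, `y` and attribute
#'   `with_replacement`.
#' @export
sample_background <- function(stack, n, region = NULL, seed = 1) {
  stopifnot(n >= 1)
  cells <- if (is.null(region)) valid_cells(stack) else region$cells
  if (!length(cells)) stop("background region is empty")
  with_replacement <- n > length(cells)
  draw <- with_seed(seed, {
    if (with_replacement) sample(cells, n, replace = TRUE)
    else if (n == length(cells)) cells
    else sample(cells, n)
  })
  ctr <- xy_from_cell(stack, draw)
  out <- data.frame(cell = draw, x = ctr[, 1], y = ctr[, 2])
  attr(out, "with_replacement") <- with_replacement
  out
}

#' Build a maximum-entropy feature matrix
#'
#' Layers must already be min-max normalized to \[0, 1\] using background
#' bounds. Transform blocks appear in L, Q, P, H order; within each block
#' layers follow stack order. Hinge features are forward
#' (`max(0, x - k) / (1 - k)`) and reverse (`max(0, k - x) / k`) at
#' `hinge_knots` evenly spaced interior knots per layer.
#'
#' @param env points x layers matrix of normalized layer values.
#' @param fc feature-class code (string over `{L, Q, P, H}`).
#' @param hinge_knots hinge knots per layer per direction.
#' @return the feature matrix with deterministic column names.
#' @export
build_features <- function(env, fc, hinge_knots = 4) {
  codes <- strsplit(fc, "")[[1]]
  if (!all(codes %in% c("L", "Q", "P", "H")))
    stop("unknown feature class code in '", fc, "'")
  env <- as.matrix(env)
  nms <- colnames(env) %||% paste0("layer", seq_len(ncol(env)))
  blocks <- list()
  if ("L" %in% codes) {
    b <- env
    colnames(b) <- paste0("L_", nms)
    blocks$L <- b
  }
  if ("Q" %in% codes) {
    b <- env^2
    colnames(b) <- paste0("Q_", nms)
    blocks$Q <- b
  }
  if ("P" %in% codes && ncol(env) >= 2) {
    prs <- utils::combn(ncol(env), 2)
    b <- env[, prs[1, ], drop = FALSE] * env[, prs[2, ], drop = FALSE]
    colnames(b) <- paste0("P_", nms[prs[1, ]], "_x_", nms[prs[2, ]])
    blocks$P <- b
  }
  if ("H" %in% codes) {
    knots <- seq_len(hinge_knots) / (hinge_knots + 1)
    hb <- list()
    for (j in seq_len(ncol(env))) {
      for (k in knots)
        hb[[length(hb) + 1]] <- structure(pmax(0, env[, j] - k) / (1 - k),
                                          nm = sprintf("H_%s_fwd_%.3f", nms[j], k))
      for (k in knots)
        hb[[length(hb) + 1]] <- structure(pmax(0, k - env[, j]) / k,
                                          nm = sprintf("H_%s_rev_%.3f", nms[j], k))
    }
    b <- do.call(cbind, lapply(hb, as.numeric))
    colnames(b) <- vapply(hb, attr, character(1), "nm")
    blocks$H <- b
  }
  out <- do.call(cbind, blocks[intersect(c("L", "Q", "P", "H"), names(blocks))])
  if (is.null(out)) out <- matrix(numeric(0), nrow = nrow(env), ncol = 0)
  out
}

# min-max normalize env values into [0,1] using stated bounds, clamping.
normalize_env <- function(env, bounds) {
  env <- as.matrix(env)
  for (j in seq_len(ncol(env))) {
    rng <- bounds[, j]
    span <- max(rng[2] - rng[1], 1e-12)
    env[, j] <- pmin(pmax((env[, j] - rng[1]) / span, 0), 1)
  }
  env
}

# Proximal-gradient (FISTA) fit of the L1-penalized Gibbs likelihood.
# Xp: presence features; Xb: background features. Returns beta and
# convergence flag. Objective minimized:
#   f(beta) = -mean_p(Xp beta) + log(mean_b exp(Xb beta)) + rm*sum(lambda|beta|)
maxent_solve <- function(Xp, Xb, rm, lambda, max_iter = 500, tol = 1e-6) {
  p <- ncol(Xp)
  beta <- numeric(p)
  if (p == 0) return(list(beta = beta, converged = TRUE, iter = 0))
  fbar <- colMeans(Xp)
  smooth_obj <- function(b) {
    eta <- Xb %*% b
    m <- max(eta)
    -sum(fbar * b) + m + log(mean(exp(eta - m)))
  }
  grad <- function(b) {
    eta <- as.vector(Xb %*% b)
    w <- exp(eta - max(eta))
    w <- w / sum(w)
    as.vector(crossprod(Xb, w)) - fbar
  }
  pen <- function(b) rm * sum(lambda * abs(b))
  step <- 1
  obj_old <- smooth_obj(beta) + pen(beta)
  y <- beta
  t_acc <- 1
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    g <- grad(y)
    fy <- smooth_obj(y)
    # backtracking line search on the smooth part
    repeat {
      beta_new <- soft_threshold(y - step * g, step * rm * lambda)
      d <- beta_new - y
      lhs <- smooth_obj(beta_new)
      if (lhs <= fy + sum(g * d) + sum(d^2) / (2 * step) + 1e-12) break
      step <- step / 2
      if (step < 1e-12) break
    }
    t_new <- (1 + sqrt(1 + 4 * t_acc^2)) / 2
    y <- beta_new + ((t_acc - 1) / t_new) * (beta_new - beta)
    beta <- beta_new
    t_acc <- t_new
    obj <- smooth_obj(beta) + pen(beta)
    if (abs(obj_old - obj) < tol * max(1, abs(obj_old))) {
      converged <- TRUE
      break
    }
    obj_old <- obj
    step <- step * 1.5  # allow the step to grow back
  }
  list(beta = beta, converged = converged, iter = iter)
}

#' Fit one presence-background SDM
#'
#' Fits the L1-penalized Gibbs model for a single feature class and
#' regularization multiplier, then predicts the full raw suitability surface
#' and computes its AICc (see Details in the package vignette). Convergence is
#' declared when the relative change in the penalized objective drops below
#' `1e-6` (at most 500 iterations); non-converged models are flagged and
#' excluded from selection.
#'
#' @param presences a thinned [occurrence_set] (see [thin_occurrences]).
#' @param background a background-point data frame from [sample_background].
#' @param stack the [climate_stack].
#' @param fc feature-class code.
#' @param rm regularization multiplier (> 0).
#' @param hinge_knots hinge knots per layer per direction.
#' @return an `sdm_model`: coefficients, feature metadata, normalization
#'   bounds, `k` (nonzero coefficients), `n`, log-likelihood, `aicc`,
#'   `converged`, `valid`.
#' @export
fit_model <- function(presences, background, stack, fc, rm,
                      hinge_knots = 4) {
  pres_cells <- attr(presences, "cells")
  if (is.null(pres_cells)) {
    presences <- thin_occurrences(presences, stack)
    pres_cells <- attr(presences, "cells")
  }
  env_bg <- cell_values(stack, background$cell)
  bounds <- apply(env_bg, 2, range)
  engine <- sdm_engine(stack, fc, hinge_knots, bounds)
  fit_model_engine(pres_cells, background$cell, engine, rm,
                   lineage = presences$lineage[1])
}

# Precomputed design over the full grid for one (stack, fc, bounds): full-grid
# feature matrix restricted to valid cells, with a cell -> row lookup.
sdm_engine <- function(stack, fc, hinge_knots, bounds) {
  vc <- valid_cells(stack)
  envf <- normalize_env(cell_values(stack, vc), bounds)
  Xfull <- build_features(envf, fc, hinge_knots)
  lookup <- integer(stack$nrow * stack$ncol)
  lookup[vc] <- seq_along(vc)
  list(stack = stack, fc = fc, hinge_knots = hinge_knots, bounds = bounds,
       valid = vc, Xfull = Xfull, lookup = lookup)
}

# Core fit given an engine; cells are row-major indices into the grid.
fit_model_engine <- function(pres_cells, bg_cells, engine, rm,
                             lineage = NA_character_) {
  Xp <- engine$Xfull[engine$lookup[pres_cells], , drop = FALSE]
  Xb <- engine$Xfull[engine$lookup[bg_cells], , drop = FALSE]
  n <- nrow(Xp)
  s2 <- apply(Xp, 2, stats::var)
  s2[!is.finite(s2)] <- 0
  lambda <- pmax(sqrt(s2 / n), 1e-3)
  sol <- maxent_solve(Xp, Xb, rm, lambda)
  beta <- sol$beta
  names(beta) <- colnames(engine$Xfull)
  k <- sum(abs(beta) > 1e-8)
  # raw surface over valid cells, normalized to sum 1
  eta <- as.vector(engine$Xfull %*% beta)
  raw <- exp(eta - max(eta))
  raw <- raw / sum(raw)
  ll <- sum(log(raw[engine$lookup[pres_cells]]))
  valid_aicc <- n - k - 1 > 0
  aicc <- if (valid_aicc) 2 * k - 2 * ll + 2 * k * (k + 1) / (n - k - 1)
          else NA_real_
  structure(list(lineage = lineage, fc = engine$fc, rm = rm,
                 hinge_knots = engine$hinge_knots, beta = beta,
                 bounds = engine$bounds, layer_names = engine$stack$layer_names,
                 k = k, n = n, loglik = ll, aicc = aicc,
                 valid = valid_aicc && sol$converged,
                 converged = sol$converged, iter = sol$iter,
                 presence_cells = pres_cells, raw_valid = raw),
            class = "sdm_model")
}

#' @export
print.sdm_model <- function(x, ...) {
  cat(sprintf("<sdm_model> fc=%s rm=%g k=%d n=%d lnL=%.3f AICc=%s%s\n",
              x$fc, x$rm, x$k, x$n, x$loglik,
              ifelse(is.na(x$aicc), "invalid", sprintf("%.2f", x$aicc)),
              if (!x$converged) " [not converged]" else ""))
  invisible(x)
}

#' AICc of a fitted SDM
#'
#' `AICc = 2k - 2 lnL + 2k(k+1)/(n-k-1)` with lnL the sum of log raw
#' (sum-to-one) suitabilities at the thinned presence cells and k the count of
#' nonzero coefficients; invalid (NA) when `n - k - 1 <= 0`.
#'
#' @param model an `sdm_model`.
#' @param surface optional [suitability_surface] to recompute the likelihood
#'   from (defaults to the model's stored raw surface).
#' @return the AICc value (NA if invalid).
#' @export
evaluate_aicc <- function(model, surface = NULL) {
  if (!is.null(surface)) {
    raw <- as.vector(t(surface$raw))[model$presence_cells]
    if (anyNA(raw)) stop("presence on a missing cell")
    ll <- sum(log(raw))
  } else {
    ll <- model$loglik
  }
  k <- model$k
  n <- model$n
  if (n - k - 1 <= 0) return(NA_real_)
  2 * k - 2 * ll + 2 * k * (k + 1) / (n - k - 1)
}

#' Select the minimum-AICc model from a candidate list
#'
#' Only valid, converged candidates compete. Ties are broken by smaller `k`,
#' then smaller `rm`, then lexicographic feature-class code. The full
#' candidate table (fc, rm, k, lnL, AICc, delta AICc) is attached as the
#' `selection_table` attribute of the winner.
#'
#' @param candidates list of `sdm_model`s.
#' @return the selected `sdm_model`.
#' @export
select_model <- function(candidates) {
  if (!length(candidates)) stop("no candidate models")
  tab <- data.frame(
    fc = vapply(candidates, `[[`, character(1), "fc"),
    rm = vapply(candidates, `[[`, numeric(1), "rm"),
    k = vapply(candidates, `[[`, numeric(1), "k"),
    loglik = vapply(candidates, `[[`, numeric(1), "loglik"),
    aicc = vapply(candidates, `[[`, numeric(1), "aicc"),
    valid = vapply(candidates, `[[`, logical(1), "valid"))
  ok <- which(tab$valid & is.finite(tab$aicc))
  if (!length(ok)) stop("all candidate models are invalid")
  ord <- ok[order(tab$aicc[ok], tab$k[ok], tab$rm[ok], tab$fc[ok])]
  best <- candidates[[ord[1]]]
  tab$delta_aicc <- tab$aicc - tab$aicc[ord[1]]
  attr(best, "selection_table") <- tab
  best
}

#' Predict the suitability surface of a fitted model
#'
#' The raw view is `exp(beta . f(cell))` normalized to sum 1 over non-missing
#' cells (the operand of Schoener's D). The logistic display view follows the
#' MaxEnt convention `c r / (1 + c r)` with `c = exp(H)`, H the Shannon
#' entropy of the raw distribution (for a uniform surface this reduces to
#' `c` = number of non-missing cells); habitat-suitability thresholds such as
#' 0.5 / 0.75 are taken on this view.
#'
#' @param model an `sdm_model`.
#' @param stack the [climate_stack] to predict over (layer names must cover
#'   the model's).
#' @return a `suitability_surface`: matrices `raw` and `logistic` (grid
#'   shape), the calibration constant `c`, and the generating `model`.
#' @export
predict_surface <- function(model, stack) {
  missing_layers <- setdiff(model$layer_names, stack$layer_names)
  if (length(missing_layers))
    stop("stack lacks layer(s): ", paste(missing_layers, collapse = ", "))
  vc <- valid_cells(stack)
  env <- cell_values(stack, vc)[, model$layer_names, drop = FALSE]
  X <- build_features(normalize_env(env, model$bounds), model$fc,
                      model$hinge_knots)
  eta <- as.vector(X %*% model$beta)
  raw_v <- exp(eta - max(eta))
  raw_v <- raw_v / sum(raw_v)
  raw <- matrix(NA_real_, stack$nrow, stack$ncol)
  t_raw <- t(raw)
  t_raw[vc] <- raw_v
  raw <- t(t_raw)
  # entropy calibration: c = exp(H) of the raw distribution
  pos <- raw_v > 0
  h <- -sum(raw_v[pos] * log(raw_v[pos]))
  cc <- exp(h)
  if (!is.finite(cc) || cc <= 0) cc <- length(vc)
  logistic <- cc * raw / (1 + cc * raw)
  structure(list(raw = raw, logistic = logistic, c = cc, model = model,
                 nrow = stack$nrow, ncol = stack$ncol,
                 mask = stack$mask),
            class = "suitability_surface")
}

#' @export
print.suitability_surface <- function(x, ...) {
  cat(sprintf("<suitability_surface> %d x %d, raw sum = %.6f, logistic max = %.3f\n",
              x$nrow, x$ncol, sum(x$raw, na.rm = TRUE),
              max(x$logistic, na.rm = TRUE)))
  invisible(x)
}

#' Fit, select, and predict an SDM for one lineage
#'
#' The full workflow operation: thin the occurrences, sample a shared
#' background, fit the fc x rm candidate grid (default 6 x 5 = 30 models),
#' select by AICc, and predict the suitability surface.
#'
#' @param occ an [occurrence_set].
#' @param stack a [climate_stack].
#' @param config an [sdm_config].
#' @param seed integer seed (controls the background draw).
#' @param background optional pre-sampled background (shared across lineages
#'   in comparative analyses).
#' @return a list with `model` (selected, carrying the `selection_table`
#'   attribute), `surface`, `background`, and `presences` (thinned).
#' @export
fit_sdm <- function(occ, stack, config = sdm_config(), seed = 1,
                    background = NULL) {
  presences <- thin_occurrences(occ, stack)
  if (is.null(background)) {
    nb <- min(config$n_background, length(valid_cells(stack)))
    background <- sample_background(stack, nb, seed = seed)
  }
  env_bg <- cell_values(stack, background$cell)
  bounds <- apply(env_bg, 2, range)
  candidates <- list()
  for (fc in config$fc) {
    engine <- sdm_engine(stack, fc, config$hinge_knots, bounds)
    for (rm in config$rm) {
      candidates[[length(candidates) + 1]] <-
        fit_model_engine(attr(presences, "cells"), background$cell, engine,
                         rm, lineage = presences$lineage[1])
    }
  }
  model <- select_model(candidates)
  surface <- predict_surface(model, stack)
  list(model = model, surface = surface, background = background,
       presences = presences)
}
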