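# Synthetic-data generators: spatially autocorrelated climate fields,
# Gaussian-niche occurrence sampling, F-model locus alignments, and
# correlated morphometric trait tables. Every generator is deterministic
# under a fixed seed and attaches provenance (parameters + seed).

#' Gaussian niche parameters
#'
#' Describes one lineage's climatic niche as an axis-aligned Gaussian in layer
#' space: suitability of a cell with layer values x is
#' `max_suitability * prod_k exp(-(x_k - optimum_k)^2 / (2 tolerance_k^2))`,
#' always in \[0, 1\].
#'
#' @param optimum numeric vector of per-layer optima (layer units).
#' @param tolerance numeric vector (recycled) of per-layer niche breadths
#'   (standard deviations, layer units); strictly positive.
#' @param max_suitability peak suitability in (0, 1\].
#' @return a `niche_params` object.
#' @export
niche_params <- function(optimum, tolerance, max_suitability = 1) {
  tolerance <- rep_len(tolerance, length(optimum))
  if (any(tolerance <= 0)) stop("tolerances must be > 0")
  if (max_suitability <= 0 || max_suitability > 1)
    stop("max_suitability must be in (0, 1]")
  structure(list(optimum = optimum, tolerance = tolerance,
                 max_suitability = max_suitability), class = "niche_params")
}

#' Suitability of every grid cell under a Gaussian niche
#'
#' @param stack a [climate_stack].
#' @param niche a [niche_params] whose length matches the layer count.
#' @return a matrix (grid shape) of suitabilities in \[0, 1\], `NA` on masked
#'   cells.
#' @export
niche_suitability <- function(stack, niche) {
  if (length(niche$optimum) != n_layers(stack))
    stop("niche dimensionality must match the number of layers")
  s <- matrix(niche$max_suitability, stack$nrow, stack$ncol)
  for (k in seq_len(n_layers(stack))) {
    s <- s * exp(-(stack$values[, , k] - niche$optimum[k])^2 /
                   (2 * niche$tolerance[k]^2))
  }
  s[!stack$mask] <- NA_real_
  s
}

#' Simulate a stack of autocorrelated, optionally correlated climate layers
#'
#' Each layer is a Gaussian random field built by smoothing white noise with a
#' Gaussian kernel of scale `autocorr_length` (in cells), then standardized to
#' mean 0, sd 1. If `target_corr` is given, the layers are first empirically
#' whitened and then mixed through a symmetric square root of the target
#' matrix, so the realized inter-layer Pearson correlations match the target
#' (exactly, up to degeneracies introduced by rank deficiency).
#'
#' @param n_layers number of layers (>= 1).
#' @param nrow,ncol grid dimensions.
#' @param autocorr_length Gaussian smoothing scale in cells; 0 = white noise.
#' @param target_corr optional positive semi-definite layer correlation
#'   matrix.
#' @param seed integer seed.
#' @return a [climate_stack] with a `provenance` attribute.
#' @export
simulate_climate_stack <- function(n_layers, nrow = 50, ncol = 50,
                                   autocorr_length = 5, target_corr = NULL,
                                   seed = 1) {
  stopifnot(n_layers >= 1, autocorr_length >= 0)
  if (!is.null(target_corr)) {
    target_corr <- as.matrix(target_corr)
    if (!isTRUE(all.equal(target_corr, t(target_corr), tolerance = 1e-8)))
      stop("target_corr must be symmetric")
    ev <- eigen(target_corr, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop("target_corr must be positive semi-definite")
    if (nrow(target_corr) != n_layers)
      stop("target_corr dimension must equal n_layers")
  }
  fields <- with_seed(seed, {
    lapply(seq_len(n_layers), function(k) {
      f <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
      smooth_field(f, autocorr_length)
    })
  })
  z <- vapply(fields, function(f) {
    v <- as.vector(f)
    (v - mean(v)) / stats::sd(v)
  }, numeric(nrow * ncol))
  if (!is.null(target_corr) && n_layers > 1) {
    # empirical whitening, then mixing by the symmetric sqrt of the target
    cz <- stats::cov(z)
    ei <- eigen(cz, symmetric = TRUE)
    w <- ei$vectors %*% diag(1 / sqrt(pmax(ei$values, 1e-12))) %*% t(ei$vectors)
    zt <- eigen(target_corr, symmetric = TRUE)
    a <- zt$vectors %*% diag(sqrt(pmax(zt$values, 0))) %*% t(zt$vectors)
    z <- (z %*% w) %*% a
    z <- scale(z)
  }
  vals <- lapply(seq_len(n_layers), function(k) matrix(z[, k], nrow, ncol))
  out <- climate_stack(vals)
  attr(out, "provenance") <- list(generator = "simulate_climate_stack",
                                  n_layers = n_layers, nrow = nrow,
                                  ncol = ncol,
                                  autocorr_length = autocorr_length,
                                  target_corr = target_corr, seed = seed)
  out
}

# Separable Gaussian smoothing of a matrix field (reflection-free: weights
# renormalized at edges through the row-stochastic smoothing matrices).
smooth_field <- function(f, len) {
  if (len <= 0) return(f)
  smat <- function(n) {
    d <- outer(seq_len(n), seq_len(n), function(i, j) (i - j)^2)
    w <- exp(-d / (2 * len^2))
    w / rowSums(w)
  }
  smat(nrow(f)) %*% f %*% t(smat(ncol(f)))
}

#' Sample occurrence records from a suitability-weighted grid
#'
#' Cells are drawn (with replacement) with probability proportional to the
#' lineage's Gaussian-niche suitability, optionally restricted to a cell
#' mask; coordinates are cell centers jittered uniformly within the cell.
#' Lineages given identical niches and masks are statistically exchangeable —
#' the null world of the ecological-interchangeability tests.
#'
#' @param stack a [climate_stack].
#' @param niches named list of [niche_params], one per lineage.
#' @param n_per_lineage integer vector (recycled) of record counts.
#' @param region_mask optional named list of integer cell-index vectors
#'   restricting each lineage's available cells.
#' @param seed integer seed.
#' @return a named list of `occurrence_set` data frames (columns
#'   `lineage`, `x`, `y`) with lineage and provenance attributes.
#' @export
simulate_occurrences <- function(stack, niches, n_per_lineage, region_mask = NULL,
                                 seed = 1) {
  if (is.null(names(niches)))
    names(niches) <- paste0("lineage", seq_along(niches))
  n_per_lineage <- rep_len(n_per_lineage, length(niches))
  if (any(n_per_lineage < 1)) stop("n_per_lineage must be >= 1")
  vc <- valid_cells(stack)
  out <- with_seed(seed, {
    lapply(seq_along(niches), function(i) {
      nm <- names(niches)[i]
      suit <- niche_suitability(stack, niches[[i]])
      cells <- vc
      if (!is.null(region_mask) && !is.null(region_mask[[nm]]))
        cells <- intersect(cells, region_mask[[nm]])
      w <- as.vector(t(suit))[cells]
      if (all(w == 0) || !length(cells))
        stop(sprintf("lineage '%s' has zero suitability over its mask", nm))
      draw <- sample(cells, n_per_lineage[i], replace = TRUE, prob = w)
      ctr <- xy_from_cell(stack, draw)
      jit <- stack$cellsize * (matrix(stats::runif(2 * length(draw)),
                                      ncol = 2) - 0.5)
      occurrence_set(nm, ctr[, 1] + jit[, 1], ctr[, 2] + jit[, 2],
                     note = "simulated")
    })
  })
  names(out) <- names(niches)
  attr(out, "provenance") <- list(generator = "simulate_occurrences",
                                  n_per_lineage = n_per_lineage, seed = seed)
  out
}

#' Occurrence record set
#'
#' @param lineage lineage label.
#' @param x,y record coordinates (finite).
#' @param note free-text provenance note.
#' @return a data frame of class `occurrence_set` with columns
#'   `lineage`, `x`, `y`.
#' @export
occurrence_set <- function(lineage, x, y, note = "") {
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("occurrence coordinates must be finite")
  structure(data.frame(lineage = lineage, x = x, y = y,
                       stringsAsFactors = FALSE),
            class = c("occurrence_set", "data.frame"), note = note)
}

#' Pool several occurrence sets into one labelled set
#'
#' Used for merged lineages (e.g. "Central+South") in pairwise comparisons.
#'
#' @param ... occurrence sets.
#' @param label label of the merged set; defaults to the `+`-joined labels.
#' @return an `occurrence_set`.
#' @export
merge_occurrences <- function(..., label = NULL) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !is.data.frame(sets[[1]]))
    sets <- sets[[1]]
  lab <- label %||% paste(unique(unlist(lapply(sets, function(s) s$lineage))),
                          collapse = "+")
  occurrence_set(lab, unlist(lapply(sets, `[[`, "x")),
                 unlist(lapply(sets, `[[`, "y")), note = "merged")
}

#' Lineage divergence specification for the F-model
#'
#' Lineage history is a rooted tree given as nested pairs of lineage names,
#' e.g. `list(list("A", "B"), "C")`. Along every branch, each SNP's allele
#' frequency drifts from its parent value p to a
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` draw (mean p, variance `F p (1-p)`);
#' `F = 0` is exact panmixia (frequency inherited unchanged).
#'
#' @param tree nested-pair lineage tree (character leaves).
#' @param F drift parameter in \[0, 1): a single value applied to every
#'   branch, or a vector consumed in preorder (parent-before-child,
#'   left-to-right) branch order.
#' @param ancestral_range range of the Uniform distribution of ancestral
#'   allele frequencies.
#' @return a `divergence_spec` object with element `lineages` (leaf labels).
#' @export
divergence_spec <- function(tree, F = 0.2, ancestral_range = c(0.1, 0.9)) {
  if (any(F < 0 | F >= 1)) stop("F must be in [0, 1)")
  leaves <- unlist(tree)
  if (anyDuplicated(leaves)) stop("lineage names must be unique")
  structure(list(tree = tree, F = F, ancestral_range = ancestral_range,
                 lineages = leaves), class = "divergence_spec")
}

# Recursively drift an allele frequency down the tree; returns a named vector
# of leaf frequencies. `env$i` walks the per-branch F vector in preorder.
drift_tree <- function(node, p, Fvec, env) {
  if (is.character(node) && length(node) == 1) {
    out <- p
    names(out) <- node
    return(out)
  }
  res <- list()
  for (child in node) {
    f <- Fvec[min(env$i, length(Fvec))]
    env$i <- env$i + 1
    q <- if (f == 0) p else
      stats::rbeta(1, p * (1 - f) / f, (1 - p) * (1 - f) / f)
    res[[length(res) + 1]] <- drift_tree(child, q, Fvec, env)
  }
  unlist(res)
}

#' Simulate phased per-locus alignments under the F-model
#'
#' Generates a set of loci for individuals of the lineages in `spec`. Variable
#' site frequencies follow the F-model down the lineage tree; haplotype
#' alleles are Bernoulli draws from the lineage frequency; invariant sites are
#' identical across all haplotypes. Two haplotype sequences are emitted per
#' individual (phase suffixes `/0`, `/1`); an individual is present at a locus
#' with probability `completeness`, and both haplotypes drop together
#' (capture dropout is per library).
#'
#' @param spec a [divergence_spec].
#' @param n_individuals_per_lineage individuals per lineage.
#' @param n_loci number of loci.
#' @param sites_per_locus alignment length per locus.
#' @param prop_variable fraction of sites that are variable.
#' @param completeness probability in (0, 1\] that an individual is present at
#'   a locus.
#' @param seed integer seed.
#' @return a `locus_alignment_set`: list with `loci` (named list of character
#'   matrices, haplotypes x sites), `individuals` (data frame individual,
#'   lineage), `completeness`, and provenance.
#' @export
simulate_locus_alignments <- function(spec, n_individuals_per_lineage = 10,
                                      n_loci = 100, sites_per_locus = 40,
                                      prop_variable = 0.15, completeness = 1.0,
                                      seed = 1) {
  if (completeness <= 0 || completeness > 1)
    stop("completeness must be in (0, 1]")
  lineages <- spec$lineages
  inds <- data.frame(
    individual = paste0(rep(lineages, each = n_individuals_per_lineage), "_",
                        sequence(rep(n_individuals_per_lineage, length(lineages)))),
    lineage = rep(lineages, each = n_individuals_per_lineage),
    stringsAsFactors = FALSE)
  hap_names <- paste0(rep(inds$individual, each = 2), "/", 0:1)
  hap_lineage <- rep(inds$lineage, each = 2)
  bases <- c("A", "C", "G", "T")
  n_var <- max(0L, round(prop_variable * sites_per_locus))
  loci <- with_seed(seed, {
    lapply(seq_len(n_loci), function(l) {
      present <- stats::runif(nrow(inds)) <= completeness
      hap_present <- rep(present, each = 2)
      if (!any(hap_present)) present[sample(nrow(inds), 1)] <- TRUE
      hap_present <- rep(present, each = 2)
      aln <- matrix("", nrow = sum(hap_present), ncol = sites_per_locus,
                    dimnames = list(hap_names[hap_present], NULL))
      cons <- sample(bases, sites_per_locus, replace = TRUE)
      for (s in seq_len(sites_per_locus)) aln[, s] <- cons[s]
      if (n_var > 0) {
        var_sites <- sample(sites_per_locus, n_var)
        lin_here <- hap_lineage[hap_present]
        for (s in var_sites) {
          p <- stats::runif(1, spec$ancestral_range[1], spec$ancestral_range[2])
          env <- new.env()
          env$i <- 1L
          freqs <- drift_tree(spec$tree, p, spec$F, env)
          pair <- sample(bases, 2)
          alle <- stats::rbinom(length(lin_here), 1, freqs[lin_here])
          aln[, s] <- pair[alle + 1]
        }
      }
      aln
    })
  })
  names(loci) <- sprintf("locus_%04d", seq_len(n_loci))
  structure(list(loci = loci, individuals = inds, completeness = completeness,
                 provenance = list(generator = "simulate_locus_alignments",
                                   spec = spec,
                                   n_individuals_per_lineage = n_individuals_per_lineage,
                                   n_loci = n_loci,
                                   sites_per_locus = sites_per_locus,
                                   prop_variable = prop_variable,
                                   completeness = completeness, seed = seed)),
            class = "locus_alignment_set")
}

#' Write / read a locus alignment set as per-locus FASTA
#'
#' One uncompressed FASTA per locus under `dir/loci/`, haplotype names carry
#' `/0` and `/1` phase suffixes; individual-to-lineage mapping goes to
#' `individuals.csv`.
#'
#' @param aligns a `locus_alignment_set`.
#' @param dir output / input directory.
#' @return `write_locus_alignments` returns `dir` invisibly;
#'   `read_locus_alignments` a `locus_alignment_set`.
#' @export
write_locus_alignments <- function(aligns, dir) {
  locidir <- file.path(dir, "loci")
  dir.create(locidir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(aligns$loci)) {
    m <- aligns$loci[[nm]]
    seqs <- Biostrings::DNAStringSet(apply(m, 1, paste, collapse = ""))
    names(seqs) <- rownames(m)
    Biostrings::writeXStringSet(seqs, file.path(locidir, paste0(nm, ".fasta")))
  }
  utils::write.csv(aligns$individuals, file.path(dir, "individuals.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_locus_alignments
#' @export
read_locus_alignments <- function(dir) {
  files <- sort(list.files(file.path(dir, "loci"), pattern = "\\.fasta$",
                           full.names = TRUE))
  if (!length(files)) stop("no FASTA files under ", file.path(dir, "loci"))
  loci <- lapply(files, function(f) {
    seqs <- Biostrings::readDNAStringSet(f)
    m <- do.call(rbind, strsplit(as.character(seqs), ""))
    rownames(m) <- names(seqs)
    m
  })
  names(loci) <- sub("\\.fasta$", "", basename(files))
  ind_file <- file.path(dir, "individuals.csv")
  inds <- if (file.exists(ind_file)) {
    utils::read.csv(ind_file, stringsAsFactors = FALSE)
  } else {
    ids <- unique(sub("/[01]$", "", unlist(lapply(loci, rownames))))
    data.frame(individual = ids, lineage = NA_character_,
               stringsAsFactors = FALSE)
  }
  structure(list(loci = loci, individuals = inds, completeness = NA_real_,
                 provenance = list(generator = "read_locus_alignments",
                                   dir = dir)),
            class = "locus_alignment_set")
}

#' Simulate a morphometric trait table
#'
#' Strictly positive continuous traits generated log-normally, correlated
#' within individuals through a shared allometric size factor.
#' `lineage_shift = 0` reproduces the fully overlapping morphology regime
#' typical of morphologically homogeneous taxa; larger values displace the
#' lineages' mean body size, in units of the within-lineage standard
#' deviation of the size factor (the axis a morphometric PCA's first
#' component captures).
#'
#' @param n_per_lineage individuals per lineage.
#' @param n_traits number of traits (default 25).
#' @param n_lineages number of lineages.
#' @param lineage_shift between-lineage mean separation, residual-sd units.
#' @param seed integer seed.
#' @return a data frame: column `lineage` plus `n_traits` positive trait
#'   columns, one row per individual.
#' @export
simulate_trait_table <- function(n_per_lineage = 10, n_traits = 25,
                                 n_lineages = 3, lineage_shift = 0, seed = 1) {
  with_seed(seed, {
    n <- n_per_lineage * n_lineages
    lineage <- rep(paste0("lineage", seq_len(n_lineages)),
                   each = n_per_lineage)
    mu <- stats::runif(n_traits, 0.5, 2)        # log-scale trait baselines
    load <- stats::runif(n_traits, 0.5, 1.5)    # size-factor loadings
    size_sd <- 0.3
    sigma <- 0.1                                 # residual sd, log scale
    size_mean <- (as.integer(factor(lineage)) - 1) * lineage_shift * size_sd
    size <- stats::rnorm(n, size_mean, size_sd)
    logx <- matrix(mu, n, n_traits, byrow = TRUE) +
      outer(size, load) +
      matrix(stats::rnorm(n * n_traits, 0, sigma), n, n_traits)
    out <- data.frame(lineage = lineage, exp(logx), stringsAsFactors = FALSE)
    names(out)[-1] <- paste0("trait", seq_len(n_traits))
    attr(out, "provenance") <- list(generator = "simulate_trait_table",
                                    n_per_lineage = n_per_lineage,
                                    n_traits = n_traits,
                                    n_lineages = n_lineages,
                                    lineage_shift = lineage_shift, seed = seed)
    out
  })
}

#' Generate a complete synthetic study under a named preset
#'
#' Presets state whole worlds: `"null"` — two lineages with identical niches
#' and panmictic loci (`F = 0`); `"divergent"` — two lineages with optima four
#' tolerances apart and strong drift (`F = 0.5`); `"three-lineage"` — the
#' three-lineage configuration (North-like split deeper than the other two)
#' with `F = 0.5` and partially separated niches.
#'
#' @param preset one of `"null"`, `"divergent"`, `"three-lineage"`.
#' @param seed integer seed.
#' @param out optional directory: when given, rasters (TSV), occurrences
#'   (CSV), per-locus FASTA, traits (CSV) and a YAML manifest of the true
#'   parameters are written there.
#' @return a list with `stack`, `occurrences`, `alignments`, `traits`,
#'   `niches`, `divergence`, and `manifest`.
#' @export
simulate_preset <- function(preset = c("null", "divergent", "three-lineage"),
                            seed = 1, out = NULL) {
  preset <- match.arg(preset)
  stack <- simulate_climate_stack(3, 50, 50, autocorr_length = 5,
                                  seed = derive_seed(seed, 1))
  tol <- 0.5  # narrow-range endemic: suitable habitat is a small fraction
  cfg <- switch(preset,
    "null" = list(
      niches = list(A = niche_params(c(1, 1, 0), tol),
                    B = niche_params(c(1, 1, 0), tol)),
      n_occ = c(40, 55),
      div = divergence_spec(list("A", "B"), F = 0),
      trait_shift = 0),
    "divergent" = list(  # optima four tolerances apart in two layers
      niches = list(A = niche_params(c(-0.5, -0.5, 0), tol),
                    B = niche_params(c(1.5, 1.5, 0), tol)),
      n_occ = c(40, 55),
      div = divergence_spec(list("A", "B"), F = 0.5),
      trait_shift = 5),
    "three-lineage" = list(
      niches = list(North = niche_params(c(-1, -0.5, 0), tol),
                    Central = niche_params(c(0.8, 0.4, 0), tol),
                    South = niche_params(c(1.2, 0.8, 0), tol)),
      n_occ = c(29, 42, 55),
      div = divergence_spec(list("North", list("Central", "South")), F = 0.5),
      trait_shift = 0))
  occ <- simulate_occurrences(stack, cfg$niches, cfg$n_occ,
                              seed = derive_seed(seed, 2))
  aligns <- simulate_locus_alignments(cfg$div, n_individuals_per_lineage = 10,
                                      n_loci = 500, sites_per_locus = 40,
                                      prop_variable = 0.15, completeness = 0.9,
                                      seed = derive_seed(seed, 3))
  traits <- simulate_trait_table(10, 25, n_lineages = length(cfg$niches),
                                 lineage_shift = cfg$trait_shift,
                                 seed = derive_seed(seed, 4))
  manifest <- list(preset = preset, seed = seed,
                   lineages = names(cfg$niches), n_occ = cfg$n_occ,
                   niche_optima = lapply(cfg$niches, `[[`, "optimum"),
                   niche_tolerance = lapply(cfg$niches, `[[`, "tolerance"),
                   F = cfg$div$F, trait_shift = cfg$trait_shift,
                   n_loci = 500, completeness = 0.9)
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write_stack(stack, file.path(out, "stack"))
    utils::write.csv(do.call(rbind, occ), file.path(out, "occurrences.csv"),
                     row.names = FALSE)
    write_locus_alignments(aligns, out)
    utils::write.csv(traits, file.path(out, "traits.csv"), row.names = FALSE)
    yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  }
  list(stack = stack, occurrences = occ, alignments = aligns, traits = traits,
       niches = cfg$niches, divergence = cfg$div, manifest = manifest)
}

#' Hudson-style F_ST between lineages from a SNP matrix
#'
#' Ratio-of-averages Hudson estimator computed from per-lineage allele
#' frequencies across loci; for a pair of daughter populations drifted
#' independently from a shared ancestor with drift parameter F, its
#' expectation is F, which makes it the parameter-recovery check for the
#' F-model generator.
#'
#' @param snp a [snp_matrix].
#' @param pair optional character pair of lineages; default: mean over all
#'   pairs.
#' @return a single F_ST estimate.
#' @export
hudson_fst <- function(snp, pair = NULL) {
  lin <- snp$individuals$lineage
  pairs <- if (is.null(pair)) utils::combn(unique(lin), 2, simplify = FALSE)
           else list(pair)
  ests <- vapply(pairs, function(pr) {
    g1 <- snp$genotypes[lin == pr[1], , drop = FALSE]
    g2 <- snp$genotypes[lin == pr[2], , drop = FALSE]
    n1 <- 2 * colSums(!is.na(g1))
    n2 <- 2 * colSums(!is.na(g2))
    p1 <- colSums(g1, na.rm = TRUE) / n1
    p2 <- colSums(g2, na.rm = TRUE) / n2
    ok <- n1 > 2 & n2 > 2
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    sum(num[ok]) / sum(den[ok])
  }, numeric(1))
  mean(ests)
}
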