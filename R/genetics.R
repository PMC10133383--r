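# Molecular and morphological clustering evidence for genetic
# exchangeability: replicate single-SNP-per-locus matrices, one-hot genotype
# encoding, a small variational autoencoder trained by hand (no external
# deep-learning backend), trait PCA, and a quantitative cluster-separation
# verdict.

#' Extract replicate single-SNP-per-locus matrices
#'
#' Per locus, variable biallelic sites are identified; a site is excluded if
#' any non-ACGT character (gap, N, ambiguity code) occurs at it, or if it is
#' not exactly biallelic among the haplotypes carrying the locus. Per
#' replicate set one qualifying site is chosen uniformly at random; loci with
#' no qualifying site are dropped from all sets. Genotypes are haplotype
#' allele sums (0/1/2, counting the alphabetically later allele), missing
#' where an individual lacks the locus.
#'
#' @param aligns a `locus_alignment_set`.
#' @param n_sets number of replicate SNP sets (default 5, for SNP-set
#'   sensitivity checks).
#' @param seed integer seed.
#' @return a list of `snp_matrix` objects, each with `genotypes`
#'   (individuals x loci, 0/1/2/NA), `individuals`, `chosen_sites`, and
#'   `set_id`.
#' @export
extract_snp_sets <- function(aligns, n_sets = 5, seed = 1) {
  inds <- aligns$individuals
  qual <- lapply(aligns$loci, function(aln) {
    ok <- integer(0)
    for (s in seq_len(ncol(aln))) {
      chars <- aln[, s]
      if (any(!chars %in% c("A", "C", "G", "T"))) next
      alleles <- unique(chars)
      if (length(alleles) == 2) ok <- c(ok, s)
    }
    ok
  })
  keep <- names(qual)[lengths(qual) > 0]
  if (!length(keep)) stop("no locus has a qualifying biallelic site")
  with_seed(seed, {
    lapply(seq_len(n_sets), function(set) {
      sites <- vapply(keep, function(l) {
        s <- qual[[l]]
        if (length(s) == 1) s else sample(s, 1)
      }, integer(1))
      g <- matrix(NA_integer_, nrow(inds), length(keep),
                  dimnames = list(inds$individual, keep))
      for (li in seq_along(keep)) {
        aln <- aligns$loci[[keep[li]]]
        col <- aln[, sites[li]]
        alleles <- sort(unique(col))
        hap_ind <- sub("/[01]$", "", rownames(aln))
        allele01 <- as.integer(col == alleles[2])
        sums <- tapply(allele01, hap_ind, sum)
        g[names(sums), li] <- as.integer(sums)
      }
      structure(list(set_id = set, genotypes = g, individuals = inds,
                     chosen_sites = sites, seed = seed),
                class = "snp_matrix")
    })
  })
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf("<snp_matrix> set %d: %d individuals x %d loci (%.1f%% missing)\n",
              x$set_id, nrow(x$genotypes), ncol(x$genotypes),
              100 * mean(is.na(x$genotypes))))
  invisible(x)
}

#' One-hot encode a genotype matrix
#'
#' Each locus becomes three indicator columns for genotypes 0/1/2; a missing
#' genotype becomes an all-zero triplet. Columns follow locus order then
#' genotype order; rows follow individual order.
#'
#' @param snp a `snp_matrix`.
#' @return a numeric individuals x (3 * loci) matrix.
#' @export
one_hot <- function(snp) {
  g <- snp$genotypes
  bad <- which(!is.na(g) & !(g %in% 0:2), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("unexpected genotype code at individual '%s', locus '%s'",
                 rownames(g)[bad[1, 1]], colnames(g)[bad[1, 2]]))
  n <- nrow(g)
  m <- ncol(g)
  out <- matrix(0, n, 3 * m)
  for (j in seq_len(m)) {
    for (lev in 0:2) {
      out[, 3 * (j - 1) + lev + 1] <- as.numeric(!is.na(g[, j]) & g[, j] == lev)
    }
  }
  rownames(out) <- rownames(g)
  colnames(out) <- paste0(rep(colnames(g), each = 3), "_g", rep(0:2, m))
  out
}

# ---------------------------------------------------------------------------
# Variational autoencoder, implemented directly (manual backprop + Adam).
# Architecture: input d -> h1 -> h2 -> 2-D Gaussian latent (mu, log-variance)
# -> h2 -> h1 -> d logits; ELU activations; loss = Bernoulli reconstruction
# cross-entropy + KL divergence to the standard normal prior.

elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
elu_grad <- function(x, act) ifelse(x > 0, 1, act + 1)

vae_init <- function(d, h1, h2, latent = 2) {
  glorot <- function(nin, nout)
    matrix(stats::rnorm(nin * nout, 0, sqrt(2 / (nin + nout))), nin, nout)
  list(W1 = glorot(d, h1), b1 = numeric(h1),
       W2 = glorot(h1, h2), b2 = numeric(h2),
       Wm = glorot(h2, latent), bm = numeric(latent),
       Ws = glorot(h2, latent), bs = numeric(latent),
       W4 = glorot(latent, h2), b4 = numeric(h2),
       W5 = glorot(h2, h1), b5 = numeric(h1),
       W6 = glorot(h1, d), b6 = numeric(d))
}

addb <- function(m, b) sweep(m, 2, b, "+")

vae_train <- function(X, epochs = 500, lr = 1e-3, h1 = NULL, h2 = 16,
                      seed = 1) {
  n <- nrow(X)
  d <- ncol(X)
  h1 <- h1 %||% max(32, round(d / 10))
  with_seed(seed, {
    par <- vae_init(d, h1, h2)
    adam_m <- lapply(par, function(p) p * 0)
    adam_v <- lapply(par, function(p) p * 0)
    b1a <- 0.9; b2a <- 0.999; eps <- 1e-8
    trajectory <- numeric(epochs)
    tstep <- 0
    for (ep in seq_len(epochs)) {
      # forward
      a1 <- addb(X %*% par$W1, par$b1); y1 <- elu(a1)
      a2 <- addb(y1 %*% par$W2, par$b2); y2 <- elu(a2)
      mu <- addb(y2 %*% par$Wm, par$bm)
      lv <- pmin(pmax(addb(y2 %*% par$Ws, par$bs), -10), 10)
      epsz <- matrix(stats::rnorm(n * ncol(mu)), n)
      z <- mu + epsz * exp(0.5 * lv)
      a4 <- addb(z %*% par$W4, par$b4); y4 <- elu(a4)
      a5 <- addb(y4 %*% par$W5, par$b5); y5 <- elu(a5)
      logits <- addb(y5 %*% par$W6, par$b6)
      # loss (mean per individual)
      recon <- sum(log1p(exp(-abs(logits))) + pmax(logits, 0) - X * logits) / n
      kl <- -0.5 * sum(1 + lv - mu^2 - exp(lv)) / n
      loss <- recon + kl
      trajectory[ep] <- loss
      if (!is.finite(loss)) return(list(loss = Inf, trajectory = trajectory))
      # backward
      dlogits <- (stats::plogis(logits) - X) / n
      gW6 <- crossprod(y5, dlogits); gb6 <- colSums(dlogits)
      dy5 <- dlogits %*% t(par$W6)
      da5 <- dy5 * elu_grad(a5, y5)
      gW5 <- crossprod(y4, da5); gb5 <- colSums(da5)
      dy4 <- da5 %*% t(par$W5)
      da4 <- dy4 * elu_grad(a4, y4)
      gW4 <- crossprod(z, da4); gb4 <- colSums(da4)
      dz <- da4 %*% t(par$W4)
      dmu <- dz + mu / n
      dlv <- dz * epsz * 0.5 * exp(0.5 * lv) + 0.5 * (exp(lv) - 1) / n
      gWm <- crossprod(y2, dmu); gbm <- colSums(dmu)
      gWs <- crossprod(y2, dlv); gbs <- colSums(dlv)
      dy2 <- dmu %*% t(par$Wm) + dlv %*% t(par$Ws)
      da2 <- dy2 * elu_grad(a2, y2)
      gW2 <- crossprod(y1, da2); gb2 <- colSums(da2)
      dy1 <- da2 %*% t(par$W2)
      da1 <- dy1 * elu_grad(a1, y1)
      gW1 <- crossprod(X, da1); gb1 <- colSums(da1)
      grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                    Wm = gWm, bm = gbm, Ws = gWs, bs = gbs,
                    W4 = gW4, b4 = gb4, W5 = gW5, b5 = gb5,
                    W6 = gW6, b6 = gb6)
      tstep <- tstep + 1
      for (nm in names(par)) {
        adam_m[[nm]] <- b1a * adam_m[[nm]] + (1 - b1a) * grads[[nm]]
        adam_v[[nm]] <- b2a * adam_v[[nm]] + (1 - b2a) * grads[[nm]]^2
        mhat <- adam_m[[nm]] / (1 - b1a^tstep)
        vhat <- adam_v[[nm]] / (1 - b2a^tstep)
        par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    # deterministic final encoding
    a1 <- addb(X %*% par$W1, par$b1); y1 <- elu(a1)
    a2 <- addb(y1 %*% par$W2, par$b2); y2 <- elu(a2)
    mu <- addb(y2 %*% par$Wm, par$bm)
    lv <- pmin(pmax(addb(y2 %*% par$Ws, par$bs), -10), 10)
    list(loss = trajectory[epochs], trajectory = trajectory, par = par,
         mu = mu, sd = exp(0.5 * lv))
  })
}

# Decode latent coordinates back to reconstruction probabilities.
vae_decode <- function(par, z) {
  y4 <- elu(addb(z %*% par$W4, par$b4))
  y5 <- elu(addb(y4 %*% par$W5, par$b5))
  stats::plogis(addb(y5 %*% par$W6, par$b6))
}

#' Embed a one-hot genotype matrix with a variational autoencoder
#'
#' Trains `n_replicates` VAEs with distinct derived seeds and returns the
#' replicate with the lowest final loss (replicates whose loss diverges are
#' discarded with a warning). The architecture default — hidden widths
#' `max(32, d/10)` and 16 around a 2-D Gaussian latent, ELU activations,
#' full-batch Adam at learning rate 1e-3 for 500 epochs — targets the
#' few-dozen-individuals regime typical of phylogeographic sampling.
#'
#' @param encoded numeric matrix from [one_hot] (>= 4 rows).
#' @param n_replicates training replicates (default 3).
#' @param epochs training epochs.
#' @param seed integer seed.
#' @param lr,h1,h2 optimizer and architecture overrides.
#' @return a `latent_embedding`: `mu` and `sd` (individuals x 2), `loss`,
#'   `replicate` (index of the winning replicate), `trajectory`, the decoder
#'   weights, and `seed`.
#' @export
embed_vae <- function(encoded, n_replicates = 3, epochs = 500, seed = 1,
                      lr = 1e-3, h1 = NULL, h2 = 16) {
  if (nrow(encoded) < 4) stop("need at least 4 individuals")
  runs <- lapply(seq_len(n_replicates), function(r)
    vae_train(encoded, epochs = epochs, lr = lr, h1 = h1, h2 = h2,
              seed = derive_seed(seed, r)))
  finite <- vapply(runs, function(r) is.finite(r$loss), logical(1))
  if (any(!finite))
    warning(sprintf("%d replicate(s) discarded for non-finite loss",
                    sum(!finite)))
  if (!any(finite)) stop("all VAE replicates diverged")
  best <- which(finite)[which.min(vapply(runs[finite], `[[`, numeric(1),
                                         "loss"))]
  run <- runs[[best]]
  structure(list(mu = run$mu, sd = run$sd, loss = run$loss,
                 replicate = best, trajectory = run$trajectory,
                 par = run$par, seed = seed,
                 individuals = rownames(encoded)),
            class = "latent_embedding")
}

#' @export
print.latent_embedding <- function(x, ...) {
  cat(sprintf("<latent_embedding> %d individuals, final loss %.3f (replicate %d)\n",
              nrow(x$mu), x$loss, x$replicate))
  invisible(x)
}

#' Principal component embedding
#'
#' Thin wrapper around an eigendecomposition-backed PCA for trait tables and
#' genotype matrices: optional log transform (for strictly positive traits),
#' mean imputation of missing values, constant columns dropped with a
#' warning, column centering and unit scaling, and a deterministic sign
#' convention (the largest-magnitude loading of each component is positive).
#'
#' @param table numeric matrix or data frame (non-numeric columns dropped).
#' @param log_transform log-transform the values first (requires positives).
#' @param scale. unit-scale columns (default TRUE).
#' @return a list with `scores`, `loadings`, `variance_fraction`, and
#'   `dropped` (names of constant columns).
#' @export
embed_pca <- function(table, log_transform = FALSE, scale. = TRUE) {
  x <- as.matrix(as.data.frame(table)[vapply(as.data.frame(table),
                                             is.numeric, logical(1))])
  if (log_transform) {
    if (any(x <= 0, na.rm = TRUE))
      stop("log transform requires strictly positive values")
    x <- log(x)
  }
  # mean imputation
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- mean(x[, j], na.rm = TRUE)
  }
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped)) {
    warning("dropping constant column(s): ", paste(dropped, collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = scale.)
  # sign convention
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  list(scores = pc$x, loadings = pc$rotation,
       variance_fraction = pc$sdev^2 / sum(pc$sdev^2), dropped = dropped)
}

#' Quantify cluster separation of an embedding
#'
#' Operationalizes the visual "separate vs overlapping clusters" judgment:
#' the verdict is `"separate"` iff the mean silhouette width of the lineage
#' labels is at least `silhouette_threshold` AND the adjusted Rand index of
#' k-means (k = number of labels) against the labels is at least
#' `ari_threshold`. Pairwise verdicts are computed the same way on each label
#' pair's subset.
#'
#' @param embedding a `latent_embedding`, or a numeric coordinate matrix
#'   (e.g. the first PCA scores).
#' @param labels lineage labels, one per row (>= 2 distinct).
#' @param silhouette_threshold minimum mean silhouette for separation.
#' @param ari_threshold minimum adjusted Rand index for separation.
#' @param seed seed for the k-means starts.
#' @return a `cluster_assessment`: `silhouette`, `ari`, `verdict`,
#'   `pairwise` (data frame of per-pair verdicts), and the thresholds used.
#' @export
assess_clustering <- function(embedding, labels, silhouette_threshold = 0.35,
                              ari_threshold = 0.9, seed = 1) {
  x <- if (inherits(embedding, "latent_embedding")) embedding$mu
       else as.matrix(embedding)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("need at least two distinct labels")
  if (nrow(x) != length(labels)) stop("one label per embedding row required")
  one <- function(xx, ll) {
    sil <- mean_silhouette(xx, ll)
    km <- with_seed(seed, stats::kmeans(xx, centers = length(unique(ll)),
                                        nstart = 25))
    ari <- adjusted_rand_index(km$cluster, ll)
    list(silhouette = sil, ari = ari,
         verdict = if (sil >= silhouette_threshold && ari >= ari_threshold)
           "separate" else "overlapping")
  }
  overall <- one(x, labels)
  prs <- utils::combn(sort(unique(labels)), 2, simplify = FALSE)
  pairwise <- do.call(rbind, lapply(prs, function(pr) {
    sel <- labels %in% pr
    r <- one(x[sel, , drop = FALSE], labels[sel])
    data.frame(a = pr[1], b = pr[2], silhouette = r$silhouette, ari = r$ari,
               verdict = r$verdict, stringsAsFactors = FALSE)
  }))
  structure(list(silhouette = overall$silhouette, ari = overall$ari,
                 verdict = overall$verdict, pairwise = pairwise,
                 silhouette_threshold = silhouette_threshold,
                 ari_threshold = ari_threshold),
            class = "cluster_assessment")
}

#' @export
print.cluster_assessment <- function(x, ...) {
  cat(sprintf("<cluster_assessment> %s (silhouette %.3f >= %.2f: %s; ARI %.3f >= %.2f: %s)\n",
              x$verdict, x$silhouette, x$silhouette_threshold,
              x$silhouette >= x$silhouette_threshold,
              x$ari, x$ari_threshold, x$ari >= x$ari_threshold))
  invisible(x)
}
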