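# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so pipeline functions do not perturb user RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a child seed from a parent seed and a stream index, kept within the
# 32-bit integer range R requires.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1103L + as.double(index) * 7919L) %% 2147483647)
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Adjusted Rand index between two labelings
#'
#' Closed-form computation from the contingency table; used to quantify
#' agreement between an unsupervised partition (e.g. k-means on a latent
#' embedding) and a priori lineage labels.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return a single number in \[-1, 1\]; 1 means identical partitions, values
#'   near 0 mean chance-level agreement.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sum_ij <- sum_comb(tab)
  sum_a <- sum_comb(rowSums(tab))
  sum_b <- sum_comb(colSums(tab))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Mean silhouette width of `labels` on rows of the coordinate matrix `x`.
mean_silhouette <- function(x, labels) {
  f <- as.integer(factor(labels))
  if (length(unique(f)) < 2) stop("silhouette needs at least two labels")
  sil <- cluster::silhouette(f, stats::dist(x))
  mean(sil[, "sil_width"])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
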