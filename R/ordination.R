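#' Square-root transform of a composition table
#'
#' Elementwise square root of the proportions, the standard
#' variance-stabilising transform applied before Bray-Curtis ordination of
#' proportional count tables. No renormalisation is performed.
#'
#' @param comp a `composition_table` (or plain numeric matrix).
#' @return The transformed table, same class and dimnames.
#' @export
sqrt_transform <- function(comp) {
  stopifnot(is.numeric(comp), all(comp >= 0))
  out <- sqrt(comp)
  attributes(out) <- attributes(comp)
  out
}

#' Bray-Curtis dissimilarity
#'
#' BC(x, y) = sum(|x - y|) / sum(x + y) for non-negative abundance vectors:
#' 0 for identical samples, 1 for samples with disjoint support.
#'
#' @param x,y non-negative numeric vectors of equal length.
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (any(x < 0) || any(y < 0)) stop("inputs must be non-negative", call. = FALSE)
  denom <- sum(x + y)
  if (denom == 0) stop("both vectors are all-zero", call. = FALSE)
  sum(abs(x - y)) / denom
}

#' Pairwise Bray-Curtis distance matrix for a composition table
#'
#' @param comp matrix with taxa as rows and samples as columns (a
#'   `composition_table`), typically [sqrt_transform()]ed first.
#' @return Symmetric `dist`-compatible square matrix of class
#'   `distance_matrix` with zero diagonal and sample ids as dimnames.
#' @export
bray_curtis_matrix <- function(comp) {
  stopifnot(is.numeric(comp), ncol(comp) >= 2L)
  ids <- colnames(comp) %||% as.character(seq_len(ncol(comp)))
  n <- ncol(comp)
  dm <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      dm[i, j] <- dm[j, i] <- bray_curtis(comp[, i], comp[, j])
    }
  }
  structure(dm, class = c("distance_matrix", "matrix"))
}

# Pseudo-F for a one-way design on a distance matrix (Anderson's direct
# formulation from sums of squared distances).
pseudo_f <- function(d2, groups) {
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1L) {
      sub <- d2[idx, idx]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  a <- length(unique(groups))
  ss_among <- ss_total - ss_within
  (ss_among / (a - 1)) / (ss_within / (n - a))
}

#' Permutational multivariate analysis of variance (one-way)
#'
#' Partitions the total sum of squared dissimilarities among and within
#' groups directly on the distance matrix and tests the pseudo-F statistic by
#' permuting sample labels. The p-value uses the add-one convention
#' p = (1 + #[F_perm >= F_obs]) / (1 + n_perm), so its floor is
#' 1 / (n_perm + 1). Degenerate matrices with zero within-group variation on
#' every permutation are reported with p = 1.
#'
#' @param dm square symmetric dissimilarity matrix (e.g.
#'   [bray_curtis_matrix()]).
#' @param labels group label per sample; at least 2 groups with >= 2 samples
#'   each.
#' @param n_perm number of label permutations.
#' @param seed integer seed making the permutation stream reproducible.
#' @return An object of class `permanova`: list with `f`, `p_value`,
#'   `n_perm`, `labels`, `seed`, `ss_among`, `ss_within`, `df`.
#' @export
permanova <- function(dm, labels, n_perm = 999L, seed = 1L) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  stopifnot(ncol(dm) == n, length(labels) == n, n_perm >= 1L)
  labels <- as.character(labels)
  sizes <- table(labels)
  if (length(sizes) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(sizes < 2L)) {
    stop("every group needs at least 2 samples", call. = FALSE)
  }
  d2 <- dm^2
  f_obs <- pseudo_f(d2, labels)
  a <- length(sizes)
  if (!is.finite(f_obs)) {
    # all-equal distances: no within variation anywhere, test is vacuous
    return(structure(list(f = f_obs, p_value = 1, n_perm = n_perm,
                          labels = labels, seed = seed,
                          df = c(among = a - 1L, within = n - a)),
                     class = "permanova"))
  }
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(k) {
      fp <- pseudo_f(d2, labels[sample.int(n)])
      is.finite(fp) && fp >= f_obs
    }, logical(1)))
  })
  structure(
    list(f = f_obs, p_value = (1 + hits) / (1 + n_perm), n_perm = n_perm,
         labels = labels, seed = seed,
         df = c(among = a - 1L, within = n - a)),
    class = "permanova"
  )
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g (df %d, %d), p = %.4g (%d permutations)\n",
              x$f, x$df[["among"]], x$df[["within"]], x$p_value, x$n_perm))
  invisible(x)
}

#' Pairwise PERMANOVA over all group pairs with BH correction
#'
#' Runs [permanova()] on every pair of groups and adjusts the p-values across
#' all pairs with [bh_adjust()].
#'
#' @inheritParams permanova
#' @return data.frame with columns `group1`, `group2`, `f`, `p_value`,
#'   `p_adjusted`.
#' @export
pairwise_permanova <- function(dm, labels, n_perm = 999L, seed = 1L) {
  dm <- as.matrix(dm)
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  pairs <- utils::combn(groups, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1L, k]; g2 <- pairs[2L, k]
    idx <- labels %in% c(g1, g2)
    res <- permanova(dm[idx, idx, drop = FALSE], labels[idx], n_perm,
                     seed = seed + k)
    data.frame(group1 = g1, group2 = g2, f = res$f, p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p_value)
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up FDR adjustment: order the p-values, scale the i-th order
#' statistic by m/i, enforce monotonicity from the largest down, cap at 1.
#'
#' @param pvals numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(pvals) {
  stopifnot(is.numeric(pvals), all(pvals >= 0 & pvals <= 1))
  m <- length(pvals)
  if (m <= 1L) return(pvals)
  o <- order(pvals, decreasing = TRUE)
  ro <- order(o)
  scaled <- pvals[o] * m / (m:1)
  pmin(1, cummin(scaled))[ro]
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Embeds the samples in `k` dimensions minimising Kruskal stress-1, with
#' multiple seeded random restarts. Numerical optimisation is delegated to
#' \code{vegan::metaMDS}; stress is reported on the 0-1 scale.
#'
#' @param dm square symmetric dissimilarity matrix.
#' @param k embedding dimension, default 2.
#' @param seed integer seed; results are reproducible given the seed.
#' @param trymax maximum random restarts.
#' @return List with `points` (samples x k coordinate matrix) and `stress`.
#' @export
nmds <- function(dm, k = 2L, seed = 1L, trymax = 40L) {
  dm <- as.matrix(dm)
  stopifnot(nrow(dm) == ncol(dm), k >= 1L)
  fit <- with_seed(seed, {
    vegan::metaMDS(stats::as.dist(dm), k = k, trymax = trymax, trace = 0,
                   autotransform = FALSE, wascores = FALSE)
  })
  pts <- fit$points
  rownames(pts) <- rownames(dm)
  list(points = pts, stress = fit$stress)
}

#' Write a distance matrix as square TSV
#'
#' @param dm square dissimilarity matrix with sample ids as dimnames.
#' @param path output path; first column holds the sample ids.
#' @return The matrix invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  dm <- as.matrix(dm)
  df <- data.frame(sample_id = rownames(dm), dm, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dm)
}
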