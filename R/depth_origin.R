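#' Per-gene depth-of-origin probabilities from catalog coverage
#'
#' For every gene, the probability that a sequence matching it originated at
#' a given depth is the ratio of the gene's catalog coverage at that depth to
#' its total coverage across depths. Genes with zero coverage at every depth
#' carry no depth information and are flagged for the unassigned bucket
#' rather than being dropped.
#'
#' By default each depth column of the catalog coverage is first rescaled to
#' unit sum, so that unevenly sequenced depths do not dominate the ratios;
#' set `renormalize_depths = FALSE` to use the stored coverage as is.
#'
#' @param catalog a [gene_catalog()].
#' @param renormalize_depths scale each depth column to sum to 1 before
#'   forming the ratios? Default `TRUE`.
#' @return An object of class `origin_probabilities`: list with `P` (gene x
#'   depth matrix, positive rows summing to 1), `unassigned_genes` (character
#'   vector of zero-coverage genes) and `depths`.
#' @export
origin_probabilities <- function(catalog, renormalize_depths = TRUE) {
  stopifnot(inherits(catalog, "gene_catalog"))
  cov <- catalog$coverage
  if (renormalize_depths) {
    cs <- colSums(cov)
    pos <- cs > 0
    cov[, pos] <- sweep(cov[, pos, drop = FALSE], 2L, cs[pos], "/")
  }
  tot <- rowSums(cov)
  flagged <- rownames(cov)[tot == 0]
  P <- cov
  ok <- tot > 0
  P[ok, ] <- cov[ok, , drop = FALSE] / tot[ok]
  structure(
    list(P = P, unassigned_genes = flagged, depths = catalog$depths),
    class = "origin_probabilities"
  )
}

#' @export
print.origin_probabilities <- function(x, ...) {
  cat(sprintf("origin_probabilities: %d genes x %d depths, %d unassigned\n",
              nrow(x$P), length(x$depths), length(x$unassigned_genes)))
  invisible(x)
}

#' Attribute a sample's coverage to probable depths of origin
#'
#' Multiplies each gene's depth-origin probabilities by the gene's normalised
#' coverage in the sample, yielding the portion of sample coverage that
#' likely originated at each depth, then aggregates the portions by taxonomic
#' domain. Coverage on flagged genes (zero catalog coverage) and on genes
#' absent from the catalog accumulates into an explicit `unassigned` bucket,
#' so the portioned masses plus the unassigned mass always equal the total
#' normalised sample coverage.
#'
#' @param table a [sample_coverage()].
#' @param probs an [origin_probabilities()] built from `catalog`.
#' @param catalog the same [gene_catalog()].
#' @param use_proportions attribute normalised per-gene proportions (default,
#'   total mass 1) or raw counts (`FALSE`)?
#' @return An object of class `depth_origin`: list with `sample_id`,
#'   `portioned` (depth x domain matrix of coverage mass), `unassigned`
#'   (scalar mass) and `total`.
#' @export
attribute_sample <- function(table, probs, catalog, use_proportions = TRUE) {
  stopifnot(inherits(table, "sample_coverage"),
            inherits(probs, "origin_probabilities"),
            inherits(catalog, "gene_catalog"))
  mass <- if (use_proportions) normalize_counts(table) else table$counts
  doms <- exodna_domains()
  nd <- length(probs$depths)
  portioned <- matrix(0, nrow = nd, ncol = length(doms),
                      dimnames = list(as.character(probs$depths), doms))
  idx <- match(names(mass), rownames(probs$P))
  absent <- is.na(idx)
  if (any(absent & mass > 0)) {
    message(sprintf("sample '%s': %g mass on genes absent from catalog treated as unassigned",
                    table$sample_id, sum(mass[absent])))
  }
  flagged <- names(mass) %in% probs$unassigned_genes
  unassigned <- sum(mass[absent | flagged])

  keep <- !absent & !flagged & mass > 0
  if (any(keep)) {
    gid <- names(mass)[keep]
    dom <- catalog$annotations$domain[match(gid, catalog$annotations$gene_id)]
    dom[is.na(dom)] <- "unknown"
    Pm <- probs$P[idx[keep], , drop = FALSE] * mass[keep]
    for (d in doms) {
      sel <- dom == d
      if (any(sel)) portioned[, d] <- colSums(Pm[sel, , drop = FALSE])
    }
  }
  structure(
    list(sample_id = table$sample_id, portioned = portioned,
         unassigned = unassigned, total = sum(mass),
         depths = probs$depths),
    class = "depth_origin"
  )
}

#' @export
print.depth_origin <- function(x, ...) {
  cat(sprintf("depth_origin '%s': total mass %g, unassigned %.4f (%.1f%%)\n",
              x$sample_id, x$total, x$unassigned,
              100 * x$unassigned / x$total))
  by_depth <- rowSums(x$portioned)
  top <- utils::head(sort(by_depth, decreasing = TRUE), 5L)
  cat("  top depths (m):",
      paste(sprintf("%s=%.3f", names(top), top), collapse = " "), "\n")
  invisible(x)
}

#' Default water-column depth zones
#'
#' Contiguous half-open `[lo, hi)` intervals covering the water column and
#' named after the classic zones: upper euphotic (surface to just below the
#' 75 m sampling depth), the deep chlorophyll maximum band, upper mesopelagic,
#' lower mesopelagic (through the 1,000 m sampling depth), and deep. Being
#' contiguous, they conserve total attributed mass under [bin_origins()].
#'
#' @return A data.frame with columns `bin`, `lo`, `hi`.
#' @export
default_depth_bins <- function() {
  data.frame(
    bin = c("upper_euphotic", "dcm_band", "upper_mesopelagic",
            "lower_mesopelagic", "deep"),
    lo = c(0, 100, 200, 500, 1001),
    hi = c(100, 200, 500, 1001, Inf),
    stringsAsFactors = FALSE
  )
}

#' Sum attributed mass into named depth intervals
#'
#' Aggregates the (depth, domain) portions of a [attribute_sample()] result
#' into named half-open `[lo, hi)` depth intervals; the unassigned bucket is
#' carried through as its own bin. With contiguous bins (the default), the
#' binned masses conserve the sample total.
#'
#' @param result a `depth_origin`.
#' @param bins data.frame with columns `bin`, `lo`, `hi` (half-open
#'   `[lo, hi)`); default [default_depth_bins()].
#' @return A data.frame with columns `bin`, `domain`, `mass`, including an
#'   `unassigned` row.
#' @export
bin_origins <- function(result, bins = default_depth_bins()) {
  stopifnot(inherits(result, "depth_origin"),
            all(c("bin", "lo", "hi") %in% names(bins)))
  if (any(bins$hi <= bins$lo)) stop("bins must have hi > lo", call. = FALSE)
  out <- list()
  for (i in seq_len(nrow(bins))) {
    sel <- result$depths >= bins$lo[i] & result$depths < bins$hi[i]
    m <- colSums(result$portioned[sel, , drop = FALSE])
    out[[i]] <- data.frame(bin = bins$bin[i], domain = names(m),
                           mass = unname(m), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rbind(out, data.frame(bin = "unassigned", domain = "unassigned",
                        mass = result$unassigned, stringsAsFactors = FALSE))
}

#' Fraction of depth-assigned mass originating in the euphotic zone
#'
#' The proportion of a sample's depth-attributed coverage originating within
#' the sunlit 0-200 m layer (the 200 m boundary depth is counted as
#' euphotic). Reported both over the depth-assigned mass only and with the
#' unassigned bucket included in the denominator.
#'
#' @param result a `depth_origin`.
#' @param max_depth euphotic lower boundary in metres, default 200.
#' @return List with `assigned_only` and `including_unassigned` proportions.
#' @export
euphotic_fraction <- function(result, max_depth = 200) {
  stopifnot(inherits(result, "depth_origin"))
  by_depth <- rowSums(result$portioned)
  assigned <- sum(by_depth)
  if (assigned <= 0) stop("no depth-assigned mass", call. = FALSE)
  eu <- sum(by_depth[result$depths <= max_depth])
  list(assigned_only = eu / assigned,
       including_unassigned = eu / (assigned + result$unassigned))
}

#' Export a depth-origin result as tidy TSV
#'
#' @param result a `depth_origin`.
#' @param path output path. One row per (depth, domain) plus an unassigned row.
#' @return The result invisibly.
#' @export
write_depth_origin <- function(result, path) {
  stopifnot(inherits(result, "depth_origin"))
  df <- expand.grid(depth = result$depths,
                    domain = colnames(result$portioned),
                    stringsAsFactors = FALSE)
  df$sample_id <- result$sample_id
  df$mass <- as.vector(result$portioned)
  df <- df[, c("sample_id", "depth", "domain", "mass")]
  df <- rbind(df, data.frame(sample_id = result$sample_id, depth = NA,
                             domain = "unassigned", mass = result$unassigned))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(result)
}
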