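#' Simulate a depth-resolved gene catalog
#'
#' Builds a synthetic reference catalog with the statistical structure the
#' depth-of-origin attribution assumes: taxa with depth-localised abundance
#' profiles (Dirichlet-distributed over the depth grid), genes assigned to
#' taxa, and a gene-by-depth coverage matrix. A configurable fraction of
#' genes are depth-exclusive markers — coverage at exactly one depth — which
#' make mixtures of depth origins identifiable; a configurable fraction carry
#' no taxonomy (domain `"unknown"`) to emulate unannotated sequences. Each
#' depth column of the coverage matrix is scaled to sum to 1, emulating a
#' per-depth normalised reference survey.
#'
#' @param n_genes number of genes (>= `n_taxa`).
#' @param n_taxa number of taxa; each gene belongs to exactly one.
#' @param depth_grid strictly increasing depths in metres within 0-4000.
#' @param depth_exclusive_frac fraction of genes restricted to a single depth
#'   (`round(n_genes * depth_exclusive_frac)` genes).
#' @param seed integer seed; all randomness flows from it.
#' @param unknown_frac fraction of genes left unannotated (domain "unknown").
#' @param alpha Dirichlet concentration for taxon depth profiles; small values
#'   give patchy, depth-localised taxa.
#' @param viral_frac fraction of taxa that are viral; the remaining taxa are
#'   split among the cellular domains.
#' @param tag_frac fraction of taxa that carry an ecotype/host tag (drawn
#'   from `tags`).
#' @param tags candidate tag labels.
#' @return A [gene_catalog()]. Determinstic given `seed`.
#' @export
make_catalog <- function(n_genes, n_taxa, depth_grid,
                         depth_exclusive_frac = 0.2, seed = 1L,
                         unknown_frac = 0.25, alpha = 0.3,
                         viral_frac = 0.3, tag_frac = 0.2,
                         tags = c("HL", "LL")) {
  stopifnot(n_genes >= 1L, n_taxa >= 1L, n_genes >= n_taxa)
  if (length(depth_grid) < 1L) stop("empty depth grid", call. = FALSE)
  if (is.unsorted(depth_grid, strictly = TRUE)) {
    stop("depth_grid must be strictly increasing", call. = FALSE)
  }
  if (any(depth_grid < 0 | depth_grid > 4000)) {
    stop("depths must lie within 0-4000 m", call. = FALSE)
  }
  if (depth_exclusive_frac < 0 || depth_exclusive_frac > 1) {
    stop("depth_exclusive_frac must be in [0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    nd <- length(depth_grid)
    # taxon depth profiles: Dirichlet(alpha) rows via normalised gammas
    prof <- matrix(stats::rgamma(n_taxa * nd, shape = alpha, rate = 1),
                   nrow = n_taxa)
    # guard against all-zero rows at tiny alpha
    zero <- rowSums(prof) == 0
    prof[zero, ] <- 1
    prof <- prof / rowSums(prof)

    cellular <- c("bacteria", "archaea", "eukaryote")
    taxon_domain <- ifelse(stats::runif(n_taxa) < viral_frac, "virus",
                           sample(cellular, n_taxa, replace = TRUE,
                                  prob = c(0.7, 0.15, 0.15)))
    taxon_family <- sprintf("family_%02d", seq_len(n_taxa))
    taxon_tag <- ifelse(stats::runif(n_taxa) < tag_frac,
                        sample(tags, n_taxa, replace = TRUE), NA_character_)

    gene_taxon <- c(seq_len(n_taxa),
                    sample.int(n_taxa, n_genes - n_taxa, replace = TRUE))
    n_excl <- round(n_genes * depth_exclusive_frac)
    is_excl <- rep(FALSE, n_genes)
    if (n_excl > 0) is_excl[sample.int(n_genes, n_excl)] <- TRUE

    cov <- matrix(0, nrow = n_genes, ncol = nd)
    for (g in seq_len(n_genes)) {
      p <- prof[gene_taxon[g], ]
      if (is_excl[g]) {
        d <- sample.int(nd, 1L, prob = p)
        cov[g, d] <- stats::rgamma(1L, shape = 2, rate = 2)
      } else {
        cov[g, ] <- p * stats::rgamma(1L, shape = 2, rate = 2)
      }
    }
    # per-depth normalisation: each depth column sums to 1 (zero columns stay 0)
    cs <- colSums(cov)
    pos <- cs > 0
    cov[, pos] <- sweep(cov[, pos, drop = FALSE], 2L, cs[pos], "/")

    gene_id <- sprintf("gene_%05d", seq_len(n_genes))
    dimnames(cov) <- list(gene_id, as.character(depth_grid))

    unknown <- stats::runif(n_genes) < unknown_frac
    ann <- data.frame(
      gene_id = gene_id,
      domain = ifelse(unknown, "unknown", taxon_domain[gene_taxon]),
      family = ifelse(unknown, NA_character_, taxon_family[gene_taxon]),
      tag = ifelse(unknown, NA_character_, taxon_tag[gene_taxon]),
      stringsAsFactors = FALSE
    )
    gene_catalog(ann, cov)
  })
}

#' Specification of a synthetic sample as a mixture over depth origins
#'
#' Encodes the hypothesis that a sample's DNA is a mixture of material
#' produced at different depths: non-negative mixing weights over catalog
#' depths (summing to 1), a sequencing effort (`read_depth` multinomial
#' trials), and the sample's own metadata.
#'
#' @param sample_id sample identifier.
#' @param fraction_type one of [exodna_fractions()].
#' @param collection_depth collection depth in metres.
#' @param weights named numeric vector: names are depths (m), values are
#'   non-negative mixing weights summing to 1 (tolerance 1e-9).
#' @param read_depth positive integer count of multinomial trials.
#' @param seed integer seed for [make_sample()].
#' @return An object of class `mixture_spec`.
#' @export
mixture_spec <- function(sample_id, fraction_type, collection_depth, weights,
                         read_depth, seed = 1L) {
  fraction_type <- match.arg(fraction_type, exodna_fractions())
  if (is.null(names(weights))) stop("weights must be named by depth", call. = FALSE)
  w <- as.numeric(weights)
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  if (abs(sum(w) - 1) > 1e-9) stop("weights must sum to 1", call. = FALSE)
  if (read_depth < 1) stop("read_depth must be >= 1", call. = FALSE)
  structure(
    list(sample_id = as.character(sample_id), fraction_type = fraction_type,
         collection_depth = collection_depth,
         weights = stats::setNames(w, names(weights)),
         read_depth = as.integer(read_depth), seed = as.integer(seed)),
    class = "mixture_spec"
  )
}

#' Simulate a sample count table from a catalog and a mixture over depths
#'
#' The expected per-gene coverage is the catalog coverage matrix applied to
#' the mixing weights (a weighted sum of depth columns); realised counts are
#' one multinomial draw of `read_depth` trials from that expectation, so
#' totals equal the sequencing effort exactly and the count proportions
#' converge to the expectation as the effort grows.
#'
#' @param catalog a [gene_catalog()].
#' @param spec a [mixture_spec()]; every weighted depth must exist in the
#'   catalog depth grid.
#' @return A [sample_coverage()], deterministic given `spec$seed`.
#' @export
make_sample <- function(catalog, spec) {
  stopifnot(inherits(catalog, "gene_catalog"), inherits(spec, "mixture_spec"))
  wd <- as.numeric(names(spec$weights))
  missing <- setdiff(wd, catalog$depths)
  if (length(missing)) {
    stop("weights on depth(s) absent from catalog: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cols <- match(wd, catalog$depths)
  expectation <- as.numeric(catalog$coverage[, cols, drop = FALSE] %*% spec$weights)
  if (sum(expectation) <= 0) {
    stop("mixture expectation is identically zero", call. = FALSE)
  }
  counts <- with_seed(spec$seed,
                      as.numeric(stats::rmultinom(1L, spec$read_depth,
                                                  prob = expectation)))
  names(counts) <- rownames(catalog$coverage)
  sample_coverage(spec$sample_id, spec$fraction_type, spec$collection_depth,
                  counts)
}

#' Expected per-gene coverage of a mixture (noiseless oracle)
#'
#' The exact expectation [make_sample()] samples from, normalised to sum
#' to 1. Useful as ground truth in identifiability checks.
#'
#' @inheritParams make_sample
#' @return Named numeric vector of expected per-gene proportions.
#' @export
mixture_expectation <- function(catalog, spec) {
  cols <- match(as.numeric(names(spec$weights)), catalog$depths)
  if (anyNA(cols)) stop("weights on depth(s) absent from catalog", call. = FALSE)
  e <- as.numeric(catalog$coverage[, cols, drop = FALSE] %*% spec$weights)
  stats::setNames(e / sum(e), rownames(catalog$coverage))
}

#' Simulate a capillary-electrophoresis electropherogram
#'
#' Generates a fragment-size trace as a mixture of Gaussian peaks on the
#' log10(bp) axis (CE sizing is approximately log-linear) plus an
#' exponential-decay degradation smear toward small fragments, sampled on a
#' log-spaced size grid spanning the 75-50,000 bp sizing range. Component
#' densities are expressed per bp so that trapezoidal integration on the
#' linear size axis recovers the requested mass fractions.
#'
#' @param peaks list of peaks, each `c(center_bp, width_log10, mass_fraction)`
#'   (or a 3-column matrix); centers within 75-50,000 bp.
#' @param smear_fraction mass fraction of the degradation smear; peak mass
#'   fractions plus `smear_fraction` must sum to 1.
#' @param n_points number of log-spaced sample sizes (>= 10).
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @param smear_scale exponential decay scale of the smear, bp.
#' @param noise_sd standard deviation of additive Gaussian noise, as a
#'   fraction of the maximum clean signal; negative excursions are clipped
#'   at 0. Default 0 (clean trace).
#' @return An [electropherogram()].
#' @export
make_electropherogram <- function(peaks, smear_fraction = 0, n_points = 1000L,
                                  seed = 1L, smear_scale = 2000,
                                  noise_sd = 0) {
  if (is.matrix(peaks)) peaks <- split(peaks, row(peaks))
  peaks <- lapply(peaks, as.numeric)
  stopifnot(all(vapply(peaks, length, integer(1)) == 3L) || length(peaks) == 0L)
  centers <- vapply(peaks, `[`, numeric(1), 1L)
  widths <- vapply(peaks, `[`, numeric(1), 2L)
  masses <- vapply(peaks, `[`, numeric(1), 3L)
  if (length(centers) && any(centers < 75 | centers > 50000)) {
    stop("peak centers must lie within 75-50,000 bp", call. = FALSE)
  }
  if (length(widths) && any(widths <= 0)) {
    stop("peak widths must be positive", call. = FALSE)
  }
  if (abs(sum(masses) + smear_fraction - 1) > 1e-9) {
    stop("peak mass fractions plus smear_fraction must sum to 1", call. = FALSE)
  }
  stopifnot(n_points >= 10L)
  size <- 10^seq(log10(75), log10(50000), length.out = n_points)
  dens <- numeric(n_points)
  for (i in seq_along(centers)) {
    # Gaussian in log10(bp), converted to a per-bp density
    dens <- dens + masses[i] *
      stats::dnorm(log10(size), mean = log10(centers[i]), sd = widths[i]) /
      (size * log(10))
  }
  if (smear_fraction > 0) {
    dens <- dens + smear_fraction *
      stats::dexp(size - 75, rate = 1 / smear_scale)
  }
  if (noise_sd > 0) {
    dens <- with_seed(seed, {
      pmax(0, dens + stats::rnorm(n_points, sd = noise_sd * max(dens)))
    })
  }
  electropherogram(size, dens)
}
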