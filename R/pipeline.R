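#' Demo run configuration
#'
#' A self-contained configuration for [run_pipeline()] that simulates a small
#' depth-resolved catalog, a panel of exocellular DNA samples (vesicle, virus,
#' free) plus cellular references across the water column, and a set of
#' electropherogram traces, then runs every downstream stage. Mirrors the
#' structure of a YAML config file (see [read_run_config()]).
#'
#' @param seed master integer seed; every stage seed is derived from it.
#' @return A named list, a valid `run_pipeline()` config.
#' @export
demo_config <- function(seed = 42L) {
  depths <- c(5, 75, 125, 250, 500, 1000)
  mk <- function(id, type, cd, w, s_off) {
    list(sample_id = id, fraction_type = type, collection_depth = cd,
         weights = w, read_depth = 200000L, seed = seed + s_off)
  }
  list(
    seed = seed,
    simulate = list(
      n_genes = 600L, n_taxa = 15L, depth_grid = depths,
      depth_exclusive_frac = 0.3, unknown_frac = 0.25,
      samples = list(
        mk("free_75",    "free",    75,   list(`5` = 0.3, `75` = 0.55, `125` = 0.15), 1L),
        mk("free_125",   "free",    125,  list(`75` = 0.3, `125` = 0.6, `250` = 0.1), 2L),
        mk("free_500",   "free",    500,  list(`75` = 0.5, `125` = 0.17, `500` = 0.33), 3L),
        mk("free_1000",  "free",    1000, list(`75` = 0.35, `125` = 0.11, `500` = 0.2, `1000` = 0.34), 4L),
        mk("ves_75",     "vesicle", 75,   list(`5` = 0.2, `75` = 0.7, `125` = 0.1), 5L),
        mk("ves_125",    "vesicle", 125,  list(`75` = 0.25, `125` = 0.65, `250` = 0.1), 6L),
        mk("ves_500",    "vesicle", 500,  list(`75` = 0.4, `500` = 0.6), 7L),
        mk("vir_75",     "virus",   75,   list(`5` = 0.15, `75` = 0.8, `125` = 0.05), 8L),
        mk("vir_125",    "virus",   125,  list(`125` = 0.9, `250` = 0.1), 9L),
        mk("vir_500",    "virus",   500,  list(`250` = 0.2, `500` = 0.8), 10L),
        mk("cell_75",    "cellular", 75,  list(`75` = 1.0), 11L),
        mk("cell_125",   "cellular", 125, list(`125` = 1.0), 12L),
        mk("cell_500",   "cellular", 500, list(`500` = 1.0), 13L),
        mk("cell_1000",  "cellular", 1000, list(`1000` = 1.0), 14L)
      ),
      traces = list(
        list(trace_id = "free_75", peaks = list(c(8000, 0.06, 0.75), c(400, 0.10, 0.15)),
             smear_fraction = 0.10),
        list(trace_id = "free_500", peaks = list(c(5000, 0.25, 0.45), c(300, 0.15, 0.30)),
             smear_fraction = 0.25),
        list(trace_id = "free_1000", peaks = list(c(3000, 0.35, 0.35), c(250, 0.20, 0.30)),
             smear_fraction = 0.35)
      )
    ),
    bins = default_depth_bins(),
    cutoffs = list(major_taxon = 0.005, lmw_bp = 1000, hmw_cap_bp = 40000,
                   peak_distinct_bp = 5000, peak_broad_bp = 10000),
    flux = list(F_ref = 4000, z_ref = 175, b = 0.86, layer_m = 100,
                stocks = list(`500` = 0.10, `1000` = 0.10)),
    n_perm = 199L
  )
}

#' Read a YAML run configuration
#'
#' @param path YAML file with the same structure as [demo_config()].
#' @return A config list for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (!is.list(cfg)) stop("config must be a list", call. = FALSE)
  if (is.null(cfg$seed)) stop("config needs a `seed`", call. = FALSE)
  if (is.null(cfg$simulate) && is.null(cfg$paths)) {
    stop("config needs either `simulate` or `paths`", call. = FALSE)
  }
  co <- cfg$cutoffs
  if (!is.null(co)) {
    vals <- unlist(co)
    if (any(vals <= 0)) stop("cutoffs must be positive", call. = FALSE)
    if (!is.null(co$lmw_bp) && !is.null(co$hmw_cap_bp) &&
        co$lmw_bp >= co$hmw_cap_bp) {
      stop("cutoffs must be ordered: lmw_bp < hmw_cap_bp", call. = FALSE)
    }
    if (!is.null(co$peak_distinct_bp) && !is.null(co$peak_broad_bp) &&
        co$peak_distinct_bp > co$peak_broad_bp) {
      stop("cutoffs must be ordered: peak_distinct_bp <= peak_broad_bp",
           call. = FALSE)
    }
  }
  invisible(cfg)
}

load_inputs <- function(cfg) {
  if (!is.null(cfg$simulate)) {
    sm <- cfg$simulate
    catalog <- make_catalog(
      n_genes = sm$n_genes, n_taxa = sm$n_taxa,
      depth_grid = as.numeric(sm$depth_grid),
      depth_exclusive_frac = sm$depth_exclusive_frac %||% 0.2,
      seed = cfg$seed,
      unknown_frac = sm$unknown_frac %||% 0.25
    )
    samples <- lapply(sm$samples, function(s) {
      w <- unlist(s$weights)
      spec <- mixture_spec(s$sample_id, s$fraction_type, s$collection_depth,
                           stats::setNames(as.numeric(w), names(w)),
                           s$read_depth, seed = s$seed)
      make_sample(catalog, spec)
    })
    traces <- lapply(sm$traces %||% list(), function(t) {
      make_electropherogram(t$peaks, t$smear_fraction %||% 0,
                            seed = cfg$seed)
    })
    names(traces) <- vapply(sm$traces %||% list(), `[[`, character(1), "trace_id")
  } else {
    catalog <- read_catalog(cfg$paths$catalog_annotations,
                            cfg$paths$catalog_coverage)
    samples <- lapply(cfg$paths$samples, read_count_table)
    traces <- lapply(cfg$paths$traces %||% character(0), read_trace)
    names(traces) <- basename(unlist(cfg$paths$traces %||% character(0)))
  }
  list(catalog = catalog, samples = samples, traces = traces)
}

#' Run the full exocellular DNA analysis pipeline
#'
#' Orchestrates the stages end to end from one configuration: obtain inputs
#' (simulated or read from disk), compute composition tables, attribute
#' samples to depths of origin and bin them, evaluate the export-flux model,
#' compute size-spectrum metrics for any traces, and compare fractions by
#' Bray-Curtis / PERMANOVA / NMDS. All outputs are plain TSV plus a JSON run
#' manifest recording seeds and parameters; given fixed seeds, two runs
#' produce byte-identical outputs. Stages whose inputs are absent (e.g. no
#' traces) are skipped with a notice.
#'
#' @param config a config list (see [demo_config()]) or path to a YAML file.
#' @param outdir output directory, created if needed.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, outdir) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  validate_config(cfg)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  inputs <- load_inputs(cfg)
  catalog <- inputs$catalog
  samples <- inputs$samples
  note("inputs: %d genes, %d samples, %d traces",
       nrow(catalog$coverage), length(samples), length(inputs$traces))

  # --- compose ---------------------------------------------------------------
  dom <- domain_composition(samples, catalog)
  fam <- family_composition(samples, catalog, annotated_only = TRUE)
  write_composition(dom, file.path(outdir, "composition_domain.tsv"))
  write_composition(fam, file.path(outdir, "composition_family.tsv"))
  cutoff <- cfg$cutoffs$major_taxon %||% 0.005
  writeLines(major_taxa(fam, cutoff), file.path(outdir, "major_families.txt"))
  note("compose: %d families, %d major at >%g", nrow(fam),
       length(major_taxa(fam, cutoff)), cutoff)

  # --- attribute -------------------------------------------------------------
  probs <- origin_probabilities(catalog)
  bins <- if (is.data.frame(cfg$bins)) cfg$bins else
    if (!is.null(cfg$bins)) do.call(rbind, lapply(cfg$bins, as.data.frame)) else
      default_depth_bins()
  attributions <- lapply(samples, attribute_sample, probs = probs,
                         catalog = catalog)
  binned <- do.call(rbind, lapply(attributions, function(r) {
    b <- bin_origins(r, bins)
    b$sample_id <- r$sample_id
    b[, c("sample_id", "bin", "domain", "mass")]
  }))
  utils::write.table(binned, file.path(outdir, "attribution_binned.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  eu <- do.call(rbind, lapply(attributions, function(r) {
    e <- euphotic_fraction(r)
    data.frame(sample_id = r$sample_id,
               euphotic_assigned = e$assigned_only,
               euphotic_incl_unassigned = e$including_unassigned,
               unassigned = r$unassigned)
  }))
  utils::write.table(eu, file.path(outdir, "euphotic_fractions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("attribute: %d samples attributed over %d depths", length(attributions),
       length(probs$depths))

  # --- flux ------------------------------------------------------------------
  if (!is.null(cfg$flux)) {
    fx <- cfg$flux
    model <- flux_model(fx$F_ref, fx$z_ref %||% 175, fx$b %||% 0.86)
    st <- stock_profile(as.numeric(names(fx$stocks)),
                        as.numeric(unlist(fx$stocks)),
                        layer_m = fx$layer_m %||% 100)
    zs <- st$depth[st$depth >= model$z_ref]
    flux_tab <- data.frame(
      depth = zs,
      flux = martin_flux(zs, model),
      supply_ratio_pct = vapply(zs, flux_supply_ratio, numeric(1),
                                model = model, stocks = st)
    )
    utils::write.table(flux_tab, file.path(outdir, "flux_supply.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("flux: evaluated at %d depths", nrow(flux_tab))
  } else {
    note("flux: no flux config supplied, stage skipped")
  }

  # --- sizespec --------------------------------------------------------------
  if (length(inputs$traces)) {
    co <- cfg$cutoffs %||% list()
    bandf <- do.call(rbind, lapply(names(inputs$traces), function(id) {
      data.frame(trace_id = id, t(band_fractions(inputs$traces[[id]])))
    }))
    utils::write.table(bandf, file.path(outdir, "size_band_fractions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pk <- do.call(rbind, lapply(names(inputs$traces), function(id) {
      p <- detect_peaks(normalize_trace(inputs$traces[[id]]),
                        distinct_bp = co$peak_distinct_bp %||% 5000,
                        broad_bp = co$peak_broad_bp %||% 10000)
      if (nrow(p)) cbind(trace_id = id, p) else NULL
    }))
    if (!is.null(pk)) {
      utils::write.table(pk, file.path(outdir, "size_peaks.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    note("sizespec: %d traces measured", length(inputs$traces))
  } else {
    note("sizespec: no traces supplied, stage skipped")
  }

  # --- compare ---------------------------------------------------------------
  comp_sqrt <- sqrt_transform(fam)
  dmat <- bray_curtis_matrix(comp_sqrt)
  write_distance_matrix(dmat, file.path(outdir, "bray_curtis.tsv"))
  groups <- vapply(samples, `[[`, character(1), "fraction_type")
  names(groups) <- vapply(samples, `[[`, character(1), "sample_id")
  sizes <- table(groups)
  testable <- names(sizes)[sizes >= 2L]
  if (length(testable) >= 2L) {
    keep <- groups %in% testable
    pp <- pairwise_permanova(dmat[keep, keep, drop = FALSE], groups[keep],
                             n_perm = cfg$n_perm %||% 999L, seed = cfg$seed)
    utils::write.table(pp, file.path(outdir, "permanova_pairwise.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("compare: %d pairwise PERMANOVA tests", nrow(pp))
  } else {
    pp <- NULL
    note("compare: fewer than two groups with >=2 samples, PERMANOVA skipped")
  }
  ord <- nmds(dmat, k = 2L, seed = cfg$seed)
  coords <- data.frame(sample_id = rownames(ord$points), ord$points,
                       fraction = groups[rownames(ord$points)])
  utils::write.table(coords, file.path(outdir, "nmds_coordinates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("compare: NMDS stress %.4f", ord$stress)

  manifest <- list(
    seed = cfg$seed,
    cutoffs = cfg$cutoffs,
    flux = cfg$flux,
    n_perm = cfg$n_perm %||% 999L,
    n_genes = nrow(catalog$coverage),
    samples = names(groups),
    nmds_stress = ord$stress,
    log = log_lines
  )
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(catalog = catalog, samples = samples,
                 compositions = list(domain = dom, family = fam),
                 attributions = attributions, permanova = pp,
                 nmds = ord, manifest = manifest))
}
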