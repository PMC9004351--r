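#' Per-sample gene count table
#'
#' A `sample_coverage` holds the mapped gene counts for one metagenomic
#' sample — one of the exocellular DNA fractions (vesicle, virus, free) or a
#' cellular reference sample — together with its metadata: which fraction it
#' is and the depth (m) it was collected from. Counts come from upstream read
#' mapping against the reference catalog and are non-negative; at least one
#' count must be positive for the table to be usable downstream.
#'
#' @param sample_id sample identifier.
#' @param fraction_type one of `"vesicle"`, `"virus"`, `"free"`, `"cellular"`.
#' @param collection_depth collection depth in metres.
#' @param counts named numeric vector, names are gene ids, values are
#'   non-negative counts.
#' @return An object of class `sample_coverage`.
#' @export
sample_coverage <- function(sample_id, fraction_type, collection_depth, counts) {
  fraction_type <- match.arg(fraction_type, exodna_fractions())
  stop_if_not_scalar_number(collection_depth, "collection_depth")
  if (is.null(names(counts)) || any(names(counts) == "")) {
    stop("counts must be named by gene_id", call. = FALSE)
  }
  if (anyDuplicated(names(counts))) {
    dup <- names(counts)[duplicated(names(counts))][1L]
    stop(sprintf("duplicate gene_id in counts: '%s'", dup), call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  structure(
    list(sample_id = as.character(sample_id), fraction_type = fraction_type,
         collection_depth = as.numeric(collection_depth),
         counts = stats::setNames(as.numeric(counts), names(counts))),
    class = "sample_coverage"
  )
}

#' @export
print.sample_coverage <- function(x, ...) {
  cat(sprintf(
    "sample_coverage '%s' (%s, %g m): %d genes, %g total counts\n",
    x$sample_id, x$fraction_type, x$collection_depth,
    length(x$counts), sum(x$counts)
  ))
  invisible(x)
}

#' Exocellular DNA fraction labels
#'
#' @return The four sample fraction types: the three exocellular pools plus
#'   `"cellular"` for particulate reference communities.
#' @export
exodna_fractions <- function() c("vesicle", "virus", "free", "cellular")

#' Read / write a sample count table as TSV plus a JSON metadata sidecar
#'
#' The count table is a two-column TSV (`gene_id`, `count`); sample metadata
#' (`sample_id`, `fraction_type`, `collection_depth`) lives in a JSON sidecar
#' at `<path>.meta.json`. Write-then-read is an identity.
#'
#' @param table a [sample_coverage()].
#' @param path TSV path; the sidecar is derived from it.
#' @return `read_count_table()` returns a `sample_coverage`;
#'   `write_count_table()` returns the table invisibly.
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "sample_coverage"))
  df <- data.frame(gene_id = names(table$counts), count = unname(table$counts))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(sample_id = table$sample_id, fraction_type = table$fraction_type,
               collection_depth = table$collection_depth)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(table)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "numeric"))
  if (!identical(names(df), c("gene_id", "count"))) {
    stop("count table must have header: gene_id<TAB>count", call. = FALSE)
  }
  if (anyDuplicated(df$gene_id)) {
    dup <- df$gene_id[duplicated(df$gene_id)][1L]
    stop(sprintf("duplicate gene_id in count table: '%s'", dup), call. = FALSE)
  }
  if (any(df$count < 0)) stop("negative counts in count table", call. = FALSE)
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path)) {
    stop("missing metadata sidecar: ", meta_path, call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  counts <- stats::setNames(df$count, df$gene_id)
  sample_coverage(meta$sample_id, meta$fraction_type, meta$collection_depth,
                  counts)
}

#' Normalize gene counts to proportions of mapped genes
#'
#' Each gene count is divided by the total mapped count of the sample, the
#' standard per-sample normalisation before any composition or attribution
#' step.
#'
#' @param table a [sample_coverage()].
#' @return Named numeric vector of per-gene proportions summing to 1.
#' @export
normalize_counts <- function(table) {
  stopifnot(inherits(table, "sample_coverage"))
  total <- sum(table$counts)
  if (total <= 0) stop("cannot normalize an all-zero count table", call. = FALSE)
  table$counts / total
}

# --- composition tables -----------------------------------------------------

new_composition_table <- function(values, level, universe) {
  structure(values, class = c("composition_table", class(values)),
            level = level, universe = universe)
}

#' @export
print.composition_table <- function(x, ...) {
  cat(sprintf("composition_table (%s level): %d taxa x %d samples\n",
              attr(x, "level"), nrow(x), ncol(x)))
  print(unclass(x), ...)
  invisible(x)
}

as_table_list <- function(tables) {
  if (inherits(tables, "sample_coverage")) tables <- list(tables)
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, logical(1), "sample_coverage")))
  ids <- vapply(tables, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) stop("duplicate sample ids", call. = FALSE)
  stats::setNames(tables, ids)
}

# Map each gene of a sample onto a label; genes absent from the catalog get
# NA. Returns a data.frame of (label, count).
gene_labels <- function(table, catalog, what = c("domain", "family", "tag")) {
  what <- match.arg(what)
  idx <- match(names(table$counts), catalog$annotations$gene_id)
  lab <- catalog$annotations[[what]][idx]
  data.frame(label = lab, count = unname(table$counts),
             stringsAsFactors = FALSE)
}

#' Domain-level composition, unannotated sequences included
#'
#' Computes the proportion of each sample's mapped counts falling on genes
#' annotated as bacteria, archaea, eukaryote or virus, with everything else —
#' genes in the catalog lacking a taxonomy as well as genes absent from the
#' catalog — reported explicitly as `"unknown"`. The denominator is all
#' mapped counts, so the five proportions sum to 1 per sample (the semantics
#' of a domain pie chart with an unannotated wedge).
#'
#' @param tables a [sample_coverage()] or a list of them.
#' @param catalog a [gene_catalog()].
#' @return A `composition_table` matrix: 5 domains x samples.
#' @export
domain_composition <- function(tables, catalog) {
  tables <- as_table_list(tables)
  doms <- exodna_domains()
  cols <- vapply(tables, function(tb) {
    gl <- gene_labels(tb, catalog, "domain")
    absent <- sum(gl$count[is.na(gl$label)])
    if (absent > 0) {
      message(sprintf("sample '%s': %g counts on genes absent from catalog folded into 'unknown'",
                      tb$sample_id, absent))
    }
    gl$label[is.na(gl$label)] <- "unknown"
    tot <- sum(gl$count)
    if (tot <= 0) stop("all-zero sample: ", tb$sample_id, call. = FALSE)
    vapply(doms, function(d) sum(gl$count[gl$label == d]), numeric(1)) / tot
  }, numeric(length(doms)))
  cols <- matrix(cols, nrow = length(doms),
                 dimnames = list(doms, names(tables)))
  new_composition_table(cols, "domain", doms)
}

#' Family-level composition
#'
#' Proportion of counts assigned to each taxonomic family. With
#' `annotated_only = TRUE` (the default) the denominator is restricted to
#' counts on family-annotated genes, matching how family-level percentages of
#' annotated sequences are usually reported; with `annotated_only = FALSE`
#' the denominator is all mapped counts and an `"(unannotated)"` row absorbs
#' the rest so columns still sum to 1.
#'
#' @inheritParams domain_composition
#' @param annotated_only restrict the denominator to family-annotated counts?
#' @return A `composition_table` matrix: families x samples.
#' @export
family_composition <- function(tables, catalog, annotated_only = TRUE) {
  tables <- as_table_list(tables)
  fams <- sort(unique(stats::na.omit(catalog$annotations$family)))
  rows <- if (annotated_only) fams else c(fams, "(unannotated)")
  cols <- vapply(tables, function(tb) {
    gl <- gene_labels(tb, catalog, "family")
    tallies <- vapply(fams, function(f) {
      sum(gl$count[!is.na(gl$label) & gl$label == f])
    }, numeric(1))
    if (annotated_only) {
      denom <- sum(tallies)
      if (denom <= 0) stop("no family-annotated counts in sample: ",
                           tb$sample_id, call. = FALSE)
      tallies / denom
    } else {
      tot <- sum(gl$count)
      c(tallies, tot - sum(tallies)) / tot
    }
  }, numeric(length(rows)))
  cols <- matrix(cols, nrow = length(rows),
                 dimnames = list(rows, names(tables)))
  new_composition_table(cols, "family", rows)
}

#' Composition over an ecotype / host-tag universe
#'
#' Proportions over a declared set of gene tags, e.g. high-light (HL) versus
#' low-light (LL) Prochlorococcus ecotypes, or known-host groups of viral
#' genes. The denominator is the counts carrying any tag in the universe, so
#' columns sum to 1 over the universe.
#'
#' @inheritParams domain_composition
#' @param tag_universe character vector of tags defining the composition rows.
#' @return A `composition_table` matrix: tags x samples.
#' @export
tag_composition <- function(tables, catalog, tag_universe) {
  stopifnot(is.character(tag_universe), length(tag_universe) >= 1L)
  tables <- as_table_list(tables)
  cols <- vapply(tables, function(tb) {
    gl <- gene_labels(tb, catalog, "tag")
    keep <- !is.na(gl$label) & gl$label %in% tag_universe
    denom <- sum(gl$count[keep])
    if (denom <= 0) stop("no counts carry a tag from the universe in sample: ",
                         tb$sample_id, call. = FALSE)
    vapply(tag_universe, function(t) sum(gl$count[keep & gl$label == t]),
           numeric(1)) / denom
  }, numeric(length(tag_universe)))
  cols <- matrix(cols, nrow = length(tag_universe),
                 dimnames = list(tag_universe, names(tables)))
  new_composition_table(cols, "tag", tag_universe)
}

#' Major taxa by abundance cutoff
#'
#' Returns the taxa whose proportion strictly exceeds `cutoff` in at least
#' one sample — the usual ">0.5% in any sample" rule for deciding which
#' families are abundant enough to display. The comparison is strict, so a
#' taxon sitting exactly at the cutoff everywhere is excluded, and raising
#' the cutoff can only shrink the set.
#'
#' @param comp a `composition_table`.
#' @param cutoff proportion threshold, default 0.005 (0.5%).
#' @return Character vector of taxa (row names of `comp`).
#' @export
major_taxa <- function(comp, cutoff = 0.005) {
  stopifnot(inherits(comp, "composition_table"))
  stop_if_not_scalar_number(cutoff, "cutoff")
  keep <- apply(unclass(comp) > cutoff, 1L, any)
  rownames(comp)[keep]
}

#' Export a composition table as wide-format TSV
#'
#' @param comp a `composition_table`.
#' @param path output path.
#' @return The composition invisibly.
#' @export
write_composition <- function(comp, path) {
  stopifnot(inherits(comp, "composition_table"))
  df <- data.frame(taxon = rownames(comp), unclass(comp), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(comp)
}
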