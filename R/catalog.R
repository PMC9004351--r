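#' Depth-resolved reference gene catalog
#'
#' A `gene_catalog` bundles per-gene taxonomy annotations with a gene-by-depth
#' coverage matrix, the reference against which exocellular DNA samples are
#' attributed to probable depths of origin. It mirrors the structure of a
#' depth-resolved marine gene catalog spanning the upper 4,000 m of the water
#' column: every gene carries a domain call (or `"unknown"` when unannotated),
#' an optional family, an optional ecotype/host tag, and a non-negative
#' coverage value at each catalog depth.
#'
#' @param annotations data.frame with columns `gene_id`, `domain`, `family`,
#'   `tag`. `gene_id` must be unique; `domain` must be one of
#'   `r paste0('"', exodna_domains(), '"', collapse = ", ")`; `family` and
#'   `tag` may be `NA`.
#' @param coverage numeric matrix, one row per gene (rownames = `gene_id`),
#'   one column per depth; column names are depths in metres, strictly
#'   increasing; all entries non-negative and finite.
#'
#' @return An object of class `gene_catalog`: a list with elements
#'   `annotations` and `coverage` plus a numeric `depths` vector.
#' @seealso [make_catalog()] to simulate one, [read_catalog()] /
#'   [write_catalog()] for TSV round-trips, [origin_probabilities()].
#' @export
gene_catalog <- function(annotations, coverage) {
  stopifnot(is.data.frame(annotations), is.matrix(coverage))
  req <- c("gene_id", "domain", "family", "tag")
  if (!all(req %in% names(annotations))) {
    stop("annotations must have columns gene_id, domain, family, tag", call. = FALSE)
  }
  annotations <- annotations[, req]
  annotations$gene_id <- as.character(annotations$gene_id)
  annotations$domain <- as.character(annotations$domain)
  annotations$family <- as.character(annotations$family)
  annotations$tag <- as.character(annotations$tag)
  if (anyDuplicated(annotations$gene_id)) {
    dup <- annotations$gene_id[duplicated(annotations$gene_id)][1L]
    stop(sprintf("duplicate gene_id in catalog: '%s'", dup), call. = FALSE)
  }
  bad <- setdiff(unique(annotations$domain), exodna_domains())
  if (length(bad)) {
    stop("unknown domain value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(rownames(coverage))) rownames(coverage) <- annotations$gene_id
  if (!identical(rownames(coverage), annotations$gene_id)) {
    stop("coverage rownames must match annotations$gene_id in order", call. = FALSE)
  }
  depths <- suppressWarnings(as.numeric(colnames(coverage)))
  if (is.null(colnames(coverage)) || anyNA(depths)) {
    stop("coverage column names must be numeric depths in metres", call. = FALSE)
  }
  if (is.unsorted(depths, strictly = TRUE)) {
    stop("catalog depths must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(coverage)) || any(coverage < 0)) {
    stop("coverage must be finite and non-negative", call. = FALSE)
  }
  structure(
    list(annotations = annotations, coverage = coverage, depths = depths),
    class = "gene_catalog"
  )
}

#' The five taxonomic domains used for aggregation
#'
#' Domain-level composition and depth-origin aggregation use a fixed universe
#' of five categories: the three cellular domains, viruses, and `"unknown"`
#' for unannotated sequences.
#'
#' @return Character vector of the five domain labels.
#' @export
exodna_domains <- function() {
  c("bacteria", "archaea", "eukaryote", "virus", "unknown")
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat(sprintf(
    "gene_catalog: %d genes x %d depths (%g-%g m)\n",
    nrow(x$coverage), length(x$depths), min(x$depths), max(x$depths)
  ))
  tab <- table(factor(x$annotations$domain, levels = exodna_domains()))
  cat("  domains:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Read / write a gene catalog as a pair of TSV files
#'
#' The on-disk representation is two plain TSVs: an annotation table
#' (`gene_id`, `domain`, `family`, `tag`; empty fields for missing family/tag)
#' and a coverage table (`gene_id` followed by one column per depth, with
#' depths in metres as column headers).
#'
#' @param catalog a [gene_catalog()].
#' @param annotations_path,coverage_path file paths for the two TSVs.
#' @return `write_catalog()` returns the catalog invisibly; `read_catalog()`
#'   returns a `gene_catalog`. Write-then-read is an identity on the catalog
#'   contents.
#' @export
write_catalog <- function(catalog, annotations_path, coverage_path) {
  stopifnot(inherits(catalog, "gene_catalog"))
  ann <- catalog$annotations
  ann$family[is.na(ann$family)] <- ""
  ann$tag[is.na(ann$tag)] <- ""
  utils::write.table(ann, annotations_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cov <- data.frame(gene_id = rownames(catalog$coverage), catalog$coverage,
                    check.names = FALSE)
  utils::write.table(cov, coverage_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(catalog)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(annotations_path, coverage_path) {
  ann <- utils::read.table(annotations_path, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = NULL)
  ann$family[ann$family == ""] <- NA_character_
  ann$tag[ann$tag == ""] <- NA_character_
  cov <- utils::read.table(coverage_path, sep = "\t", header = TRUE,
                           check.names = FALSE)
  mat <- as.matrix(cov[, -1L, drop = FALSE])
  rownames(mat) <- as.character(cov$gene_id)
  gene_catalog(ann, mat)
}
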