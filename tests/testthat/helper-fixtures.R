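# Hand-built tiny catalog over 3 depths with known annotations. Coverage
# columns each sum to 1 so the default per-depth renormalisation is a no-op.
tiny_catalog <- function() {
  ann <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "g5"),
    domain = c("bacteria", "bacteria", "virus", "unknown", "archaea"),
    family = c("Pelagibacteraceae", "Prochlorococcus", "Myoviridae", NA, NA),
    tag = c(NA, "HL", "pelagibacter_phage", NA, NA),
    stringsAsFactors = FALSE
  )
  cov <- rbind(
    g1 = c(0.25, 0.75, 0.00),
    g2 = c(0.25, 0.00, 0.50),
    g3 = c(0.50, 0.25, 0.25),
    g4 = c(0.00, 0.00, 0.25),
    g5 = c(0.00, 0.00, 0.00)  # zero coverage -> unassigned
  )
  colnames(cov) <- c("75", "500", "1000")
  gene_catalog(ann, cov)
}

tiny_sample <- function(counts = c(g1 = 10, g2 = 20, g3 = 40, g4 = 20, g5 = 10),
                        fraction = "free", depth = 500) {
  sample_coverage("toy", fraction, depth, counts)
}

random_sample <- function(catalog, seed, read_depth = 5e4, fraction = "free",
                          depth = 500) {
  depths <- catalog$depths
  w <- with_seed_local(seed, {
    v <- stats::runif(length(depths))
    v / sum(v)
  })
  spec <- mixture_spec(paste0("s", seed), fraction, depth,
                       stats::setNames(w, depths), read_depth, seed = seed)
  make_sample(catalog, spec)
}

# run expr under a fixed seed, restoring the caller's RNG state
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Independent brute-force pseudo-F from first principles (double loops).
brute_pseudo_f <- function(dm, groups) {
  n <- nrow(dm)
  ss_t <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) ss_t <- ss_t + dm[i, j]^2
  ss_t <- ss_t / n
  ss_w <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    s <- 0
    if (length(idx) > 1) {
      for (a in seq_len(length(idx) - 1)) for (b in (a + 1):length(idx)) {
        s <- s + dm[idx[a], idx[b]]^2
      }
    }
    ss_w <- ss_w + s / length(idx)
  }
  a <- length(unique(groups))
  ((ss_t - ss_w) / (a - 1)) / (ss_w / (n - a))
}

# Closed-form mass of a log10-Gaussian peak inside [lo, hi) bp.
log_gauss_mass <- function(center, width_log10, lo, hi) {
  stats::pnorm((log10(hi) - log10(center)) / width_log10) -
    stats::pnorm((log10(lo) - log10(center)) / width_log10)
}
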