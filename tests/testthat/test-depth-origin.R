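test_that("origin probabilities are coverage ratios with zero rows flagged", {
  cat <- tiny_catalog()  # columns already unit-sum, so renormalisation is a no-op
  pr <- origin_probabilities(cat)
  expect_equal(unname(pr$P["g1", ]), c(0.25, 0.75, 0))
  expect_identical(pr$unassigned_genes, "g5")

  # the ratio definition, with stored coverage used as is
  ann <- data.frame(gene_id = "g", domain = "bacteria", family = NA, tag = NA)
  cov <- matrix(c(2, 6, 0), 1, dimnames = list("g", c("75", "500", "1000")))
  pr2 <- origin_probabilities(gene_catalog(ann, cov),
                              renormalize_depths = FALSE)
  expect_equal(unname(pr2$P["g", ]), c(0.25, 0.75, 0))

  # random catalogs: every positive row sums to 1
  for (seed in 1:5) {
    rc <- make_catalog(80, 5, c(5, 75, 500, 1000), seed = seed)
    P <- origin_probabilities(rc)$P
    pos <- rowSums(P) > 0
    expect_equal(unname(rowSums(P[pos, ])), rep(1, sum(pos)),
                 tolerance = 1e-12)
  }
})

test_that("attribution portions coverage by probability and conserves mass", {
  cat <- tiny_catalog()
  pr <- origin_probabilities(cat)

  # gene at 8% of sample coverage with P = (0.25, 0.75, 0) -> (0.02, 0.06, 0)
  s <- sample_coverage("p", "free", 500, c(g1 = 8, g3 = 92))
  r <- attribute_sample(s, pr, cat)
  expect_equal(unname(r$portioned[, "bacteria"]), c(0.02, 0.06, 0))
  expect_equal(sum(r$portioned) + r$unassigned, r$total, tolerance = 1e-12)

  # a sample holding only flagged genes is entirely unassigned
  s0 <- sample_coverage("u", "free", 500, c(g5 = 100))
  r0 <- attribute_sample(s0, pr, cat)
  expect_equal(r0$unassigned, 1)
  expect_equal(sum(r0$portioned), 0)

  # genes absent from the catalog go to unassigned with a notice
  s1 <- sample_coverage("a", "free", 500, c(g1 = 50, ghost = 50))
  expect_message(r1 <- attribute_sample(s1, pr, cat), "unassigned")
  expect_equal(r1$unassigned, 0.5)

  # linearity on raw counts: attribution of a sum = sum of attributions
  sa <- sample_coverage("sa", "free", 75, c(g1 = 10, g2 = 5, g3 = 20))
  sb <- sample_coverage("sb", "free", 75, c(g1 = 2, g2 = 30, g4 = 8))
  sum_counts <- c(g1 = 12, g2 = 35, g3 = 20, g4 = 8)
  sc <- sample_coverage("sc", "free", 75, sum_counts)
  ra <- attribute_sample(sa, pr, cat, use_proportions = FALSE)
  rb <- attribute_sample(sb, pr, cat, use_proportions = FALSE)
  rc <- attribute_sample(sc, pr, cat, use_proportions = FALSE)
  expect_equal(rc$portioned, ra$portioned + rb$portioned, tolerance = 1e-12)
})

test_that("depth-exclusive marker catalogs make mixtures identifiable", {
  depths <- c(75, 500)
  cat <- make_catalog(200, 6, depths, depth_exclusive_frac = 1, seed = 6)
  pr <- origin_probabilities(cat)
  spec <- mixture_spec("m", "free", 500, c(`75` = 0.7, `500` = 0.3),
                       read_depth = 1e6, seed = 21)

  # noiseless oracle: attributing the exact expectation recovers the weights
  expct <- mixture_expectation(cat, spec)
  s_exact <- sample_coverage("exact", "free", 500, expct[expct > 0])
  r_exact <- attribute_sample(s_exact, pr, cat)
  expect_equal(unname(rowSums(r_exact$portioned)), c(0.7, 0.3),
               tolerance = 1e-9)

  # finite sequencing effort: within 3 binomial SD
  s <- make_sample(cat, spec)
  r <- attribute_sample(s, pr, cat)
  sd3 <- 3 * sqrt(0.7 * 0.3 / 1e6)
  expect_lt(abs(rowSums(r$portioned)[["75"]] - 0.7), sd3)

  # degenerate depth-uniform catalog: attribution is uniform no matter the mix
  ann <- data.frame(gene_id = paste0("g", 1:4), domain = "bacteria",
                    family = "f", tag = NA)
  cov <- matrix(0.25, 4, 3,
                dimnames = list(paste0("g", 1:4), c("75", "500", "1000")))
  ucat <- gene_catalog(ann, cov)
  upr <- origin_probabilities(ucat)
  us <- sample_coverage("u", "free", 75, c(g1 = 90, g2 = 5, g3 = 3, g4 = 2))
  ur <- attribute_sample(us, upr, ucat)
  expect_equal(unname(rowSums(ur$portioned)), rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("depth binning conserves mass and matches an interval tally", {
  cat <- tiny_catalog()
  pr <- origin_probabilities(cat)

  # all mass at 75 m -> upper euphotic holds the total
  s75 <- sample_coverage("e", "free", 75, c(g2 = 100))  # g2: 75 and 1000
  r <- attribute_sample(sample_coverage("e", "free", 75, c(g1 = 100)), pr, cat)
  b <- bin_origins(r)
  expect_equal(sum(b$mass[b$bin == "upper_euphotic"]), 0.25)
  expect_equal(sum(b$mass[b$bin == "lower_mesopelagic"]), 0.75)
  expect_equal(sum(b$mass), r$total, tolerance = 1e-12)

  # 50/50 at 125 and 500 m -> DCM band 0.5, lower mesopelagic 0.5
  ann <- data.frame(gene_id = c("a", "b"), domain = "bacteria",
                    family = NA, tag = NA)
  cov <- matrix(c(1, 0, 0, 1), 2, dimnames = list(c("a", "b"), c("125", "500")))
  cat2 <- gene_catalog(ann, cov)
  r2 <- attribute_sample(sample_coverage("d", "free", 125, c(a = 50, b = 50)),
                         origin_probabilities(cat2), cat2)
  b2 <- bin_origins(r2)
  expect_equal(sum(b2$mass[b2$bin == "dcm_band"]), 0.5)
  expect_equal(sum(b2$mass[b2$bin == "lower_mesopelagic"]), 0.5)

  # random results match a brute-force interval tally
  big <- make_catalog(100, 5, c(5, 75, 125, 250, 500, 770, 1000, 2000),
                      seed = 8)
  bpr <- origin_probabilities(big)
  rr <- attribute_sample(random_sample(big, 13), bpr, big)
  bins <- default_depth_bins()
  bb <- bin_origins(rr, bins)
  by_depth <- rowSums(rr$portioned)
  for (i in seq_len(nrow(bins))) {
    sel <- rr$depths >= bins$lo[i] & rr$depths < bins$hi[i]
    expect_equal(sum(bb$mass[bb$bin == bins$bin[i]]), sum(by_depth[sel]),
                 tolerance = 1e-12)
  }
  expect_equal(sum(bb$mass), rr$total, tolerance = 1e-9)
})

test_that("euphotic fraction is the 0-200 m share of assigned mass", {
  ann <- data.frame(gene_id = c("a", "b"), domain = "bacteria",
                    family = NA, tag = NA)
  cov <- matrix(c(1, 0, 0, 1), 2, dimnames = list(c("a", "b"), c("75", "500")))
  cat <- gene_catalog(ann, cov)
  pr <- origin_probabilities(cat)

  r_all <- attribute_sample(sample_coverage("x", "free", 125, c(a = 10)),
                            pr, cat)
  expect_equal(euphotic_fraction(r_all)$assigned_only, 1)

  r_half <- attribute_sample(sample_coverage("y", "free", 125,
                                             c(a = 50, b = 50)), pr, cat)
  e <- euphotic_fraction(r_half)
  expect_equal(e$assigned_only, 0.5)
  expect_equal(e$including_unassigned, 0.5)

  # synthetic mixture with 0.67 euphotic mass is recovered
  depths <- c(75, 125, 500)
  mark <- make_catalog(300, 6, depths, depth_exclusive_frac = 1, seed = 10)
  spec <- mixture_spec("m", "free", 500,
                       c(`75` = 0.37, `125` = 0.30, `500` = 0.33),
                       read_depth = 1e6, seed = 14)
  rm <- attribute_sample(make_sample(mark, spec),
                         origin_probabilities(mark), mark)
  expect_equal(euphotic_fraction(rm)$assigned_only, 0.67, tolerance = 0.02)
})
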