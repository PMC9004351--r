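test_that("square-root transform is elementwise with fixed points", {
  m <- matrix(c(0.25, 0, 1, 0.5), 2, 2)
  expect_equal(sqrt_transform(m), sqrt(m))
  expect_equal(sqrt_transform(m)[1, 1], 0.5)
  expect_equal(sqrt_transform(matrix(c(0, 1), 1)), matrix(c(0, 1), 1))
  with_seed_local(2, {
    r <- matrix(stats::runif(30), 5, 6)
    expect_equal(sqrt_transform(r), sqrt(r), tolerance = 1e-15)
  })
  expect_error(sqrt_transform(matrix(-1)), "non-negative|>= 0")
})

test_that("Bray-Curtis matches its definition and vegan", {
  expect_equal(bray_curtis(c(0.2, 0.3, 0.5), c(0.5, 0.3, 0.2)), 0.3)
  expect_equal(bray_curtis(1:5, 1:5), 0)
  expect_equal(bray_curtis(c(1, 0, 2), c(0, 3, 0)), 1)  # disjoint supports
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(bray_curtis(c(-1, 1), c(1, 1)), "non-negative")

  with_seed_local(4, {
    comp <- matrix(stats::runif(40), 8, 5,
                   dimnames = list(NULL, paste0("s", 1:5)))
    dm <- bray_curtis_matrix(comp)
    expect_equal(as.vector(stats::as.dist(dm)),
                 as.vector(vegan::vegdist(t(comp), method = "bray")),
                 tolerance = 1e-12)
    expect_true(all(dm >= 0 & dm <= 1))
    expect_equal(dm, t(dm))
    expect_equal(diag(dm), stats::setNames(rep(0, 5), paste0("s", 1:5)))
  })
})

test_that("PERMANOVA pseudo-F matches brute force and vegan's adonis", {
  with_seed_local(7, {
    comp <- matrix(stats::runif(60), 10, 6,
                   dimnames = list(NULL, paste0("s", 1:6)))
    dm <- bray_curtis_matrix(comp)
    labels <- rep(c("a", "b"), each = 3)

    res <- permanova(dm, labels, n_perm = 99, seed = 1)
    expect_equal(res$f, brute_pseudo_f(dm, labels), tolerance = 1e-12)

    # exhaustive enumeration over all 20 balanced assignments
    combos <- utils::combn(6, 3)
    fs <- apply(combos, 2, function(idx) {
      lab <- rep("b", 6); lab[idx] <- "a"
      brute_pseudo_f(dm, lab)
    })
    expect_true(any(abs(fs - res$f) < 1e-12))
    # every enumerated labelling agrees with the package statistic
    for (k in seq_len(ncol(combos))) {
      lab <- rep("b", 6); lab[combos[, k]] <- "a"
      expect_equal(permanova(dm, lab, n_perm = 1, seed = 1)$f,
                   fs[k], tolerance = 1e-12)
    }

    # cross-check against vegan on a larger balanced design
    comp2 <- matrix(stats::runif(140), 10, 14)
    comp2[, 1:7] <- comp2[, 1:7] + 0.4
    dm2 <- bray_curtis_matrix(comp2)
    lab2 <- rep(c("x", "y"), each = 7)
    ad <- vegan::adonis2(stats::as.dist(dm2) ~ g,
                         data = data.frame(g = lab2), permutations = 99)
    expect_equal(permanova(dm2, lab2, n_perm = 9, seed = 2)$f, ad$F[1],
                 tolerance = 1e-10)
  })
})

test_that("PERMANOVA p-values behave at the extremes and under the seed", {
  # two far-separated clusters attain the minimum p = 1/(n_perm + 1); the 8+8
  # design makes a partition-preserving permutation (the only way to tie the
  # observed F) vanishingly unlikely in 199 draws
  with_seed_local(31, {
    comp <- cbind(matrix(c(10, 0, 0, 0) + abs(stats::rnorm(32, sd = 0.01)), 4, 8),
                  matrix(c(0, 0, 0, 10) + abs(stats::rnorm(32, sd = 0.01)), 4, 8))
  })
  colnames(comp) <- paste0("s", 1:16)
  dm <- bray_curtis_matrix(comp)
  labels <- rep(c("a", "b"), each = 8)
  res <- permanova(dm, labels, n_perm = 199, seed = 3)
  expect_equal(res$p_value, 1 / 200)

  # determinism under the seed
  res2 <- permanova(dm, labels, n_perm = 199, seed = 3)
  expect_identical(res$p_value, res2$p_value)

  # degenerate all-equal distances report p = 1
  deq <- matrix(1, 6, 6) - diag(6)
  dimnames(deq) <- list(paste0("s", 1:6), paste0("s", 1:6))
  expect_equal(permanova(deq, rep(c("a", "b"), 3), n_perm = 49)$p_value, 1)

  expect_error(permanova(dm, rep("a", 16)), "at least 2 groups")
  expect_error(permanova(dm, c("a", rep("b", 15))), "at least 2 samples")
})

test_that("Benjamini-Hochberg adjustment is the classic step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 4)), rep(1, 4))
  with_seed_local(9, {
    for (i in 1:5) {
      p <- stats::runif(12)
      adj <- bh_adjust(p)
      expect_equal(adj, stats::p.adjust(p, method = "BH"), tolerance = 1e-15)
      expect_true(all(adj >= p - 1e-15))
      expect_true(all(adj <= 1))
    }
  })
})

test_that("pairwise PERMANOVA covers every pair and BH-adjusts across pairs", {
  with_seed_local(11, {
    comp <- matrix(stats::runif(120), 10, 12)
    comp[, 1:4] <- comp[, 1:4] + 1
    colnames(comp) <- paste0("s", 1:12)
    dm <- bray_curtis_matrix(comp)
    labels <- rep(c("a", "b", "c"), each = 4)
    pp <- pairwise_permanova(dm, labels, n_perm = 99, seed = 5)
    expect_equal(nrow(pp), 3L)
    expect_setequal(paste(pp$group1, pp$group2),
                    c("a b", "a c", "b c"))
    expect_equal(pp$p_adjusted, bh_adjust(pp$p_value))
  })
})

test_that("NMDS embeds recoverable geometries with near-zero stress", {
  # 3 equidistant points embed exactly in the plane
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(letters[1:3], letters[1:3])
  fit3 <- nmds(d3, k = 2, seed = 1)
  expect_lt(fit3$stress, 1e-3)

  # distances generated from points already in the plane are recovered
  with_seed_local(6, {
    pts <- matrix(stats::rnorm(16), 8, 2)
    dm <- as.matrix(stats::dist(pts))
    dimnames(dm) <- list(paste0("s", 1:8), paste0("s", 1:8))
    fit <- nmds(dm, k = 2, seed = 2)
    expect_lt(fit$stress, 0.01)
    # deterministic under the seed
    fit_again <- nmds(dm, k = 2, seed = 2)
    expect_equal(fit$points, fit_again$points, tolerance = 1e-12)
  })

  # duplicated samples land on near-coincident coordinates
  with_seed_local(8, {
    comp <- matrix(stats::runif(50), 10, 5)
    comp <- cbind(comp, comp[, 5])
    colnames(comp) <- paste0("s", 1:6)
    dm <- bray_curtis_matrix(comp)
    fit <- nmds(dm, k = 2, seed = 3)
    dup <- sqrt(sum((fit$points["s5", ] - fit$points["s6", ])^2))
    spread <- mean(stats::dist(fit$points))
    expect_lt(dup, 0.05 * spread)
  })
})
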