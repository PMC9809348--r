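naive_grm <- function(panel) {
  x <- panel$genotypes
  p <- colMeans(x, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  x <- x[, keep, drop = FALSE]; p <- p[keep]
  n <- nrow(x)
  g <- matrix(NA_real_, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    acc <- 0; m <- 0
    for (i in seq_along(p)) {
      if (is.na(x[j, i]) || is.na(x[k, i])) next
      acc <- acc + (x[j, i] - 2 * p[i]) * (x[k, i] - 2 * p[i]) /
        (2 * p[i] * (1 - p[i]))
      m <- m + 1
    }
    g[j, k] <- acc / m
  }
  g
}

naive_pdist <- function(panel) {
  x <- panel$genotypes
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    if (j == k) next
    shared <- !is.na(x[j, ]) & !is.na(x[k, ])
    d[j, k] <- sum(abs(x[j, shared] - x[k, shared])) / (2 * sum(shared))
  }
  d
}

test_that("GRM matches the naive double-loop estimator under missingness", {
  set.seed(51)
  p <- random_panel(10, 60, missing_rate = 0.15)
  g <- compute_grm(p)
  expect_equal(unname(g$matrix), naive_grm(p), tolerance = 1e-12)
  expect_equal(g$matrix, t(g$matrix))
})

test_that("identical samples have off-diagonal GRM equal to their diagonal", {
  g0 <- c(0, 1, 2, 0, 2, 1, 1, 0)
  sites <- lapply(seq_along(g0), function(i) c(g0[i], g0[i], sample(0:2, 3,
                                                                    TRUE)))
  set.seed(52)
  p <- toy_panel(sites)
  g <- compute_grm(p)
  expect_equal(g$matrix[1, 2], g$matrix[1, 1], tolerance = 1e-12)
})

test_that("a sample pair sharing no called site is flagged undefined", {
  sites <- list(c(0, NA, 1), c(2, NA, 0), c(NA, 1, 2), c(NA, 2, 1))
  p <- toy_panel(sites)
  expect_warning(g <- compute_grm(p), "no called")
  expect_true(is.nan(g$matrix[1, 2]))
})

test_that("PCA of the identity GRM gives unit eigenvalues; eigenvalue sum equals trace", {
  g <- diag(5)
  dimnames(g) <- list(letters[1:5], letters[1:5])
  pc <- grm_pca(g, k = 2)
  expect_equal(pc$values, rep(1, 5))

  set.seed(53)
  p <- random_panel(12, 80, missing_rate = 0.05)
  grm <- compute_grm(p)
  pc <- grm_pca(grm, k = 3)
  expect_equal(sum(pc$values), sum(diag(grm$matrix)), tolerance = 1e-9)
  expect_error(grm_pca(grm, k = 12), "smaller")
})

test_that("PC1 of a two-block GRM separates the blocks by sign", {
  b <- 0.8
  g <- rbind(cbind(matrix(b, 4, 4), matrix(-b, 4, 4)),
             cbind(matrix(-b, 4, 4), matrix(b, 4, 4)))
  diag(g) <- 1
  dimnames(g) <- list(letters[1:8], letters[1:8])
  pc <- grm_pca(g, k = 1)
  s <- sign(pc$scores[, 1])
  expect_true(all(s[1:4] == s[1]) && all(s[5:8] == -s[1]))
})

test_that("p-distance matches per-allele brute force; endpoints are exact", {
  p_same <- toy_panel(list(c(1, 1), c(2, 2), c(0, 0)))
  expect_equal(p_distance(p_same)[1, 2], 0)
  p_opp <- toy_panel(list(c(0, 2), c(2, 0), c(0, 2)))
  expect_equal(p_distance(p_opp)[1, 2], 1)

  set.seed(54)
  p <- random_panel(8, 50, missing_rate = 0.2)
  d <- p_distance(p)
  expect_equal(unname(as.matrix(d))[seq_len(8), seq_len(8)], naive_pdist(p),
               tolerance = 1e-12)
  expect_true(all(d >= 0 & d <= 1))

  no_share <- toy_panel(list(c(0, NA), c(NA, 1)))
  expect_error(p_distance(no_share), "no called site")
})

test_that("NJ recovers a known 4-taxon additive tree exactly", {
  t0 <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:4);")
  d0 <- cophenetic(t0)
  tr <- neighbor_joining(d0)
  expect_setequal(tr$tip.label, c("A", "B", "C", "D"))
  expect_equal(cophenetic(tr)[rownames(d0), colnames(d0)], d0,
               tolerance = 1e-12)
  # topology: A,B form a cherry
  expect_true(is_group_monophyletic(tr, c("A", "B")))
})

test_that("three taxa resolve by the closed-form star formulas", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("X", "Y", "Z"), c("X", "Y", "Z")))
  tr <- neighbor_joining(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["X"]], 1)  # (3+4-5)/2
  expect_equal(bl[["Y"]], 2)  # (3+5-4)/2
  expect_equal(bl[["Z"]], 3)  # (4+5-3)/2
})

test_that("NJ reproduces random additive matrices and agrees with ape's NJ", {
  set.seed(55)
  for (i in 1:25) {
    n <- sample(4:8, 1)
    t0 <- ape::rtree(n, rooted = FALSE)
    t0$edge.length <- runif(nrow(t0$edge), 0.05, 2)
    d0 <- cophenetic(t0)
    tr <- neighbor_joining(d0)
    expect_equal(cophenetic(tr)[rownames(d0), colnames(d0)], d0,
                 tolerance = 1e-9)
    # independent cross-check: same topology as ape's implementation
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr),
                                           ape::unroot(ape::nj(d0)))), 0)
  }
})

test_that("NJ rejects malformed matrices and clamps negative branch lengths", {
  d <- matrix(runif(16), 4)
  expect_error(neighbor_joining(d), "symmetric")
  d2 <- matrix(c(0, 1, 1, 0), 2)
  expect_error(neighbor_joining(d2), "at least 3")
  # strongly non-additive matrix: all branch lengths still >= 0
  set.seed(56)
  m <- matrix(0, 6, 6)
  m[upper.tri(m)] <- runif(15, 0.1, 1)
  m <- m + t(m)
  dimnames(m) <- list(letters[1:6], letters[1:6])
  tr <- neighbor_joining(m)
  expect_true(all(tr$edge.length >= 0))
})

test_that("breed samples are monophyletic in the NJ tree of a drifted panel", {
  sc <- simulation_scenario(n_sites = 800, n_planted_per_breed = 0,
                            fst = 0.2, missing_rate = 0.05, seed = 57)
  sim <- simulate_panel(sc)
  tr <- neighbor_joining(p_distance(sim$panel))
  for (b in breeds(sim$popmap))
    expect_true(is_group_monophyletic(tr, breed_samples(sim$popmap, b)),
                info = b)
})
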