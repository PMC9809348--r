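#' Genetic relationship matrix (GCTA estimator)
#'
#' For samples j, k and polymorphic sites i with allele frequency p_i
#' estimated from the whole panel (all breeds pooled), the relationship is
#' the average of `(x_ij - 2 p_i) (x_ik - 2 p_i) / (2 p_i (1 - p_i))` over
#' the sites where both genotypes are called (pairwise-complete
#' missingness handling). Monomorphic and fully missing sites are skipped.
#'
#' @param panel a [genotype_panel()] with at least 2 samples.
#' @return list of class `grm`: `matrix` (n x n, symmetric; `NaN` where a
#'   pair shares no called site), `n_pairs` (per-pair site counts),
#'   `samples`, `n_sites_used`.
#' @export
compute_grm <- function(panel) {
  if (n_samples(panel) < 2L) stop("GRM needs at least 2 samples")
  x <- panel$genotypes  # samples x variants
  p <- colMeans(x, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic sites")
  x <- x[, poly, drop = FALSE]
  p <- p[poly]
  z <- sweep(x, 2L, 2 * p, "-")
  z <- sweep(z, 2L, sqrt(2 * p * (1 - p)), "/")
  called <- !is.na(z)
  z[!called] <- 0
  num <- z %*% t(z)
  m <- called %*% t(called)
  g <- num / m  # NaN where m == 0
  dimnames(g) <- list(panel$samples, panel$samples)
  if (any(m == 0))
    warning("sample pair(s) share no called polymorphic site; ",
            "GRM entries undefined (NaN)")
  structure(list(matrix = g, n_pairs = m, samples = panel$samples,
                 n_sites_used = sum(poly)),
            class = "grm")
}

#' Principal components of a genetic relationship matrix
#'
#' Eigendecomposition of the GRM; sample coordinates are the eigenvectors
#' scaled by the square root of their eigenvalue (set to zero for
#' non-positive eigenvalues).
#'
#' @param grm a `grm` from [compute_grm()] or a symmetric numeric matrix.
#' @param k number of components to keep; must be below the sample count.
#' @return list of class `grm_pca`: `values` (all eigenvalues, descending),
#'   `vectors` (n x k), `scores` (n x k coordinates), `samples`.
#' @export
grm_pca <- function(grm, k = 2L) {
  g <- if (inherits(grm, "grm")) grm$matrix else grm
  if (!all(is.finite(g))) stop("non-finite GRM entries")
  if (k >= nrow(g)) stop("k must be smaller than the sample count")
  e <- eigen(g, symmetric = TRUE)
  vec <- e$vectors[, seq_len(k), drop = FALSE]
  lam <- e$values[seq_len(k)]
  sc <- sweep(vec, 2L, sqrt(pmax(lam, 0)), "*")
  rn <- rownames(g)
  dimnames(vec) <- dimnames(sc) <- list(rn, paste0("PC", seq_len(k)))
  structure(list(values = e$values, vectors = vec, scores = sc,
                 samples = rn),
            class = "grm_pca")
}

#' Pairwise p-distance matrix
#'
#' For samples j, k the p-distance is the proportion of differing alleles
#' over the sites called in both: `sum_i |x_ij - x_ik| / (2 M')` with `M'`
#' the number of shared called sites. Values lie in `[0, 1]`.
#'
#' @param panel a [genotype_panel()] with at least 2 samples.
#' @return symmetric numeric matrix with zero diagonal and sample dimnames;
#'   attribute `n_shared` holds the per-pair shared-site counts. A pair
#'   with zero shared called sites is an error.
#' @export
p_distance <- function(panel) {
  if (n_samples(panel) < 2L) stop("p-distance needs at least 2 samples")
  x <- panel$genotypes
  called <- !is.na(x)
  ind <- lapply(0:2, function(g) {
    m <- (x == g) & called
    m[is.na(m)] <- FALSE
    storage.mode(m) <- "numeric"
    m
  })
  # sum_i |x_j - x_k| = sum over genotype pairs |g-h| * co-occurrence
  absdiff <- ind[[1]] %*% t(ind[[2]]) + ind[[2]] %*% t(ind[[1]]) +
    2 * (ind[[1]] %*% t(ind[[3]]) + ind[[3]] %*% t(ind[[1]])) +
    ind[[2]] %*% t(ind[[3]]) + ind[[3]] %*% t(ind[[2]])
  storage.mode(called) <- "numeric"
  shared <- called %*% t(called)
  if (any(shared == 0))
    stop("sample pair(s) share no called site; p-distance undefined")
  d <- absdiff / (2 * shared)
  diag(d) <- 0
  dimnames(d) <- list(panel$samples, panel$samples)
  attr(d, "n_shared") <- shared
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: repeatedly joins the pair minimizing
#' `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)`, with the standard
#' branch-length formulas. A negative branch length at a join is clamped to
#' zero and the deficit moved to the sister branch, preserving the joined
#' pair's path length. The result is unrooted (final trifurcation).
#'
#' @param dist symmetric numeric matrix with zero diagonal, finite entries
#'   and at least 3 labelled taxa.
#' @return an [ape::phylo] tree whose leaves are the matrix labels.
#' @export
neighbor_joining <- function(dist) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  if (!all(is.finite(d))) stop("non-finite distances")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix not symmetric")
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  if (anyDuplicated(labs)) stop("duplicate taxon labels")
  node <- labs  # Newick fragment per active node
  active <- seq_len(n)
  fmt <- function(x) sprintf("%.15g", x)
  while (length(active) > 3L) {
    m <- length(active)
    dd <- d[active, active, drop = FALSE]
    r <- rowSums(dd)
    q <- (m - 2) * dd - outer(r, r, "+")
    diag(q) <- Inf
    ij <- which(q == min(q), arr.ind = TRUE)[1L, ]  # row-major first minimum
    i <- ij[[1L]]; j <- ij[[2L]]
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    dij <- dd[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- dij - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_lab <- paste0("(", node[active[i]], ":", fmt(li), ",",
                      node[active[j]], ":", fmt(lj), ")")
    # distances from the new node u to every remaining k
    du <- (dd[i, ] + dd[j, ] - dij) / 2
    ai <- active[i]; aj <- active[j]
    d[ai, active] <- du
    d[active, ai] <- du
    d[ai, ai] <- 0
    node[ai] <- new_lab
    active <- active[-j]
  }
  a <- active
  da <- d[a, a]
  l1 <- (da[1, 2] + da[1, 3] - da[2, 3]) / 2
  l2 <- (da[1, 2] + da[2, 3] - da[1, 3]) / 2
  l3 <- (da[1, 3] + da[2, 3] - da[1, 2]) / 2
  ls <- pmax(c(l1, l2, l3), 0)
  txt <- paste0("(", node[a[1]], ":", fmt(ls[1]), ",",
                node[a[2]], ":", fmt(ls[2]), ",",
                node[a[3]], ":", fmt(ls[3]), ");")
  ape::read.tree(text = txt)
}

#' Leaf monophyly of a group in an unrooted tree
#'
#' A group of leaves is monophyletic (as a bipartition of an unrooted tree)
#' when some edge splits the leaf set exactly into the group and its
#' complement.
#'
#' @param tree an [ape::phylo].
#' @param group character vector of leaf labels.
#' @return `TRUE` or `FALSE`.
#' @export
is_group_monophyletic <- function(tree, group) {
  tips <- tree$tip.label
  group <- intersect(group, tips)
  if (length(group) <= 1L || length(group) == length(tips)) return(TRUE)
  parts <- ape::prop.part(tree)
  target <- sort(match(group, tips))
  comp <- sort(setdiff(seq_along(tips), target))
  any(vapply(parts, function(p)
    identical(sort(p), target) || identical(sort(p), comp), logical(1)))
}
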