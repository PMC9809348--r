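#' QC thresholds
#'
#' Default thresholds follow common WGS practice for multi-breed panels:
#' sites with minor allele frequency below 0.05 or an exact
#' Hardy-Weinberg-equilibrium p-value below 1e-6 are removed.
#'
#' @param maf_min minimum minor allele frequency in `[0, 0.5]`; sites with
#'   MAF strictly below this are removed.
#' @param hwe_p_min minimum HWE exact p-value in `(0, 1)`; sites strictly
#'   below are removed.
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(maf_min = 0.05, hwe_p_min = 1e-6) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, hwe_p_min > 0, hwe_p_min < 1)
  structure(list(maf_min = maf_min, hwe_p_min = hwe_p_min),
            class = "qc_thresholds")
}

#' Genotype tallies at one site
#'
#' @param panel a [genotype_panel()].
#' @param variant_index 1-based variant index.
#' @return named integer vector `(n_hom_ref, n_het, n_hom_alt, n_missing)`
#'   summing to the sample count.
#' @export
site_counts <- function(panel, variant_index) {
  if (variant_index < 1L || variant_index > n_variants(panel))
    stop("variant index out of range: ", variant_index)
  g <- panel$genotypes[, variant_index]
  c(n_hom_ref = sum(g == 0L, na.rm = TRUE),
    n_het     = sum(g == 1L, na.rm = TRUE),
    n_hom_alt = sum(g == 2L, na.rm = TRUE),
    n_missing = sum(is.na(g)))
}

# all-sites tallies, samples pooled: 4 x n_variants matrix
site_counts_all <- function(panel) {
  g <- panel$genotypes
  rbind(n_hom_ref = colSums(g == 0L, na.rm = TRUE),
        n_het     = colSums(g == 1L, na.rm = TRUE),
        n_hom_alt = colSums(g == 2L, na.rm = TRUE),
        n_missing = colSums(is.na(g)))
}

#' Minor allele frequency from site counts
#'
#' @param counts vector as from [site_counts()].
#' @return the minor allele frequency, or `NA` when no genotype is called
#'   (undefined, not an error).
#' @export
minor_allele_frequency <- function(counts) {
  n_called <- counts[["n_hom_ref"]] + counts[["n_het"]] + counts[["n_hom_alt"]]
  if (n_called == 0L) return(NA_real_)
  alt_freq <- (counts[["n_het"]] + 2 * counts[["n_hom_alt"]]) / (2 * n_called)
  min(alt_freq, 1 - alt_freq)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact conditional test: given the observed allele counts, the
#' p-value is the sum of the probabilities of all heterozygote counts whose
#' conditional probability does not exceed that of the observed
#' configuration. Computed by the standard probability-ratio recurrence over
#' heterozygote counts. A monomorphic site has a single possible
#' configuration and p = 1.
#'
#' @param counts vector as from [site_counts()].
#' @param midp if `TRUE`, use the mid-p variant (half weight on the observed
#'   configuration). Off by default.
#' @return p-value in `(0, 1]`.
#' @export
hwe_exact_p <- function(counts, midp = FALSE) {
  n_aa <- counts[["n_hom_ref"]]; n_ab <- counts[["n_het"]]
  n_bb <- counts[["n_hom_alt"]]
  n <- n_aa + n_ab + n_bb
  if (n < 1L) stop("zero called genotypes: HWE test undefined")
  n_a <- 2L * n_aa + n_ab
  n_b <- 2L * n_bb + n_ab
  rare <- min(n_a, n_b)
  if (rare == 0L) return(1)
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  probs <- numeric(length(hets))
  # ratio recurrence: P(h+2)/P(h) = 4 * hom_rare(h) * hom_common(h) /
  #                                 ((h+1)(h+2)); start mid-range for
  # numerical headroom, then normalize.
  start <- which.min(abs(hets - 2 * n_a * n_b / (n_a + n_b)))
  probs[start] <- 1
  h <- hets[start]
  if (start < length(hets)) {
    for (k in seq(start, length(hets) - 1L)) {
      h <- hets[k]
      hom_r <- (rare - h) / 2
      hom_c <- (max(n_a, n_b) - h) / 2
      probs[k + 1L] <- probs[k] * 4 * hom_r * hom_c / ((h + 1) * (h + 2))
    }
  }
  if (start > 1L) {
    for (k in seq(start, 2L)) {
      h <- hets[k]
      hom_r <- (rare - h) / 2
      hom_c <- (max(n_a, n_b) - h) / 2
      probs[k - 1L] <- probs[k] * h * (h - 1) / (4 * (hom_r + 1) * (hom_c + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_ab, hets)]
  if (is.na(p_obs)) stop("heterozygote count inconsistent with allele counts")
  sel <- probs <= p_obs * (1 + 1e-10)
  p <- sum(probs[sel])
  if (midp) p <- p - 0.5 * p_obs
  min(p, 1)
}

#' Apply MAF and HWE quality-control filters to a panel
#'
#' Filters are computed on the whole panel, all breeds pooled. A site is
#' removed when its MAF is undefined (no called genotypes) or strictly below
#' `maf_min`, or — among sites passing the MAF filter — when its exact HWE
#' p-value is strictly below `hwe_p_min`. Boundary values are kept.
#' The operation is idempotent.
#'
#' @param panel a [genotype_panel()].
#' @param thresholds a [qc_thresholds()].
#' @return list with elements `panel` (filtered) and `report` (data.frame
#'   with id, chrom, pos, maf, hwe_p, kept, reason).
#' @export
apply_qc <- function(panel, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  m <- n_variants(panel)
  counts <- site_counts_all(panel)
  n_called <- counts["n_hom_ref", ] + counts["n_het", ] + counts["n_hom_alt", ]
  alt_freq <- ifelse(n_called > 0,
                     (counts["n_het", ] + 2 * counts["n_hom_alt", ]) /
                       (2 * pmax(n_called, 1L)), NA_real_)
  maf <- pmin(alt_freq, 1 - alt_freq)
  hwe <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    if (n_called[i] > 0)
      hwe[i] <- hwe_exact_p(counts[, i])
  }
  fail_maf <- is.na(maf) | maf < thresholds$maf_min
  fail_hwe <- !fail_maf & !is.na(hwe) & hwe < thresholds$hwe_p_min
  kept <- !fail_maf & !fail_hwe
  reason <- rep("", m)
  reason[fail_maf] <- "maf"
  reason[fail_hwe] <- "hwe"
  report <- data.frame(id = panel$variants$id, chrom = panel$variants$chrom,
                       pos = panel$variants$pos, maf = maf, hwe_p = hwe,
                       kept = kept, reason = reason,
                       stringsAsFactors = FALSE)
  list(panel = subset_panel(panel, variants = kept), report = report)
}
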