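#' Construct a genotype panel
#'
#' A genotype panel holds diploid genotypes for a set of samples at a set of
#' biallelic SNVs, as counts of the alternative allele: 0 (hom ref), 1 (het),
#' 2 (hom alt), or `NA` for a missing call. Variant metadata follows VCF
#' conventions (1-based positions, uppercase single-base REF/ALT).
#'
#' @param genotypes integer matrix, samples in rows, variants in columns;
#'   entries in `{0, 1, 2, NA}`.
#' @param variants data.frame with columns `chrom`, `pos`, `id`, `ref`, `alt`;
#'   one row per column of `genotypes`. Within a chromosome positions must be
#'   non-decreasing. Missing ids are `"."`.
#' @param samples character vector of unique sample names, one per row.
#' @return An object of class `genotype_panel`: a list with elements
#'   `genotypes`, `variants`, `samples`.
#' @examples
#' g <- matrix(c(0L, 1L, 2L), nrow = 3,
#'             dimnames = list(c("a", "b", "c"), NULL))
#' v <- data.frame(chrom = "1", pos = 100L, id = ".", ref = "A", alt = "T")
#' genotype_panel(g, v, c("a", "b", "c"))
#' @export
genotype_panel <- function(genotypes, variants, samples) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  stopifnot(is.data.frame(variants))
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(req %in% names(variants)))
    stop("variants must have columns: ", paste(req, collapse = ", "))
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  variants$id <- as.character(variants$id)
  variants$ref <- toupper(as.character(variants$ref))
  variants$alt <- toupper(as.character(variants$alt))
  rownames(variants) <- NULL
  samples <- as.character(samples)
  obj <- structure(list(genotypes = genotypes, variants = variants,
                        samples = samples),
                   class = "genotype_panel")
  validate_panel(obj)
  obj
}

validate_panel <- function(x) {
  g <- x$genotypes
  if (nrow(g) != length(x$samples))
    stop("genotype matrix has ", nrow(g), " rows but ", length(x$samples),
         " samples")
  if (ncol(g) != nrow(x$variants))
    stop("genotype matrix has ", ncol(g), " columns but ", nrow(x$variants),
         " variants")
  if (anyDuplicated(x$samples))
    stop("duplicate sample names")
  bad <- !(g %in% c(0L, 1L, 2L)) & !is.na(g)
  if (any(bad))
    stop("genotype entries must be 0, 1, 2 or NA")
  v <- x$variants
  if (nrow(v)) {
    if (any(is.na(v$pos)) || any(v$pos < 1L))
      stop("variant positions must be >= 1")
    if (any(v$ref == v$alt))
      stop("ref and alt alleles must differ")
    if (any(nchar(v$ref) != 1L) || any(nchar(v$alt) != 1L))
      stop("ref and alt must be single bases (SNV-only panel)")
    ooo <- unlist(lapply(split(v$pos, v$chrom), function(p) any(diff(p) < 0)))
    if (any(ooo))
      stop("positions must be non-decreasing within each chromosome")
  }
  invisible(x)
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", length(x$samples), "samples x",
      nrow(x$variants), "variants\n")
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  chromosomes: %s\n  missing genotype rate: %.3f\n",
              paste(unique(x$variants$chrom), collapse = ", "), miss))
  invisible(x)
}

#' Number of samples / variants in a panel
#' @param panel a `genotype_panel`.
#' @return integer count.
#' @export
n_samples <- function(panel) length(panel$samples)

#' @rdname n_samples
#' @export
n_variants <- function(panel) nrow(panel$variants)

#' Variant keys of a panel
#'
#' The identity of a variant for overlaps and truth lookups is the
#' `chrom:pos:ref:alt` tuple; ids (e.g. rs numbers) are not used as keys.
#'
#' @param x a `genotype_panel` or a data.frame with columns
#'   `chrom`, `pos`, `ref`, `alt`.
#' @return character vector of keys.
#' @export
variant_keys <- function(x) {
  v <- if (inherits(x, "genotype_panel")) x$variants else x
  paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
}

#' Subset a panel
#'
#' @param panel a `genotype_panel`.
#' @param variants integer or logical index over variants (optional).
#' @param samples character names, integer or logical index over samples
#'   (optional).
#' @return a `genotype_panel`.
#' @export
subset_panel <- function(panel, variants = NULL, samples = NULL) {
  g <- panel$genotypes
  v <- panel$variants
  s <- panel$samples
  if (!is.null(variants)) {
    g <- g[, variants, drop = FALSE]
    v <- v[variants, , drop = FALSE]
  }
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, s)
    g <- g[samples, , drop = FALSE]
    s <- s[samples]
  }
  genotype_panel(g, v, s)
}

#' Drop samples from a panel
#'
#' Removes named samples before analysis, e.g. individuals found to be
#' admixed by an external structure analysis.
#'
#' @param panel a `genotype_panel`.
#' @param drop character vector of sample names to remove.
#' @return a `genotype_panel` without the dropped samples.
#' @export
drop_samples <- function(panel, drop) {
  unknown <- setdiff(drop, panel$samples)
  if (length(unknown))
    stop("samples not in panel: ", paste(unknown, collapse = ", "))
  keep <- !(panel$samples %in% drop)
  subset_panel(panel, samples = keep)
}

#' Construct a population map
#'
#' Assigns every sample to exactly one breed label.
#'
#' @param samples character vector of sample names.
#' @param breeds character vector of breed labels, parallel to `samples`.
#' @return a named character vector of class `pop_map` (names are samples,
#'   values are breed labels).
#' @export
pop_map <- function(samples, breeds) {
  samples <- as.character(samples)
  breeds <- as.character(breeds)
  if (length(samples) != length(breeds))
    stop("samples and breeds must have equal length")
  if (anyDuplicated(samples))
    stop("duplicate sample in population map: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (any(is.na(breeds)) || any(breeds == ""))
    stop("every sample needs a non-empty breed label")
  structure(stats::setNames(breeds, samples), class = "pop_map")
}

#' @export
print.pop_map <- function(x, ...) {
  tab <- table(unclass(x))
  cat("pop_map:", length(x), "samples,", length(tab), "breeds\n")
  print(tab)
  invisible(x)
}

#' Breed labels of a population map
#' @param popmap a `pop_map`.
#' @return sorted character vector of distinct breed labels.
#' @export
breeds <- function(popmap) sort(unique(as.character(unclass(popmap))))

#' Samples belonging to given breeds
#' @param popmap a `pop_map`.
#' @param which_breeds character vector of breed labels.
#' @return character vector of sample names.
#' @export
breed_samples <- function(popmap, which_breeds) {
  unknown <- setdiff(which_breeds, breeds(popmap))
  if (length(unknown))
    stop("unknown breed label: ", paste(unknown, collapse = ", "))
  names(popmap)[unclass(popmap) %in% which_breeds]
}

check_popmap_covers <- function(popmap, panel) {
  missing <- setdiff(panel$samples, names(popmap))
  if (length(missing))
    stop("unassigned sample: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}
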