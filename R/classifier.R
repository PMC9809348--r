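#' Configuration for breed-specific classification
#'
#' A variant is breed-specific for the target (object) breed when one allele
#' exceeds the threshold frequency in the target population while the
#' complementary allele exceeds the same threshold in the pooled background
#' populations. Both orientations are tested; with a threshold above 0.5 at
#' most one can hold. The comparison is strict (`>`), so a frequency exactly
#' equal to the threshold does not qualify.
#'
#' @param target_breed breed label of the object population.
#' @param background_breeds character vector of breed labels pooled as the
#'   background (reference) population; must not contain the target.
#' @param threshold frequency threshold in `(0.5, 1]`; default 0.9.
#' @param exclude_from_background breeds deliberately left out of the
#'   background (e.g. a wild ancestor whose alleles overlap the target's);
#'   recorded for provenance and checked for consistency.
#' @return list of class `breed_specific_config`.
#' @export
breed_specific_config <- function(target_breed, background_breeds,
                                  threshold = 0.9,
                                  exclude_from_background = character(0)) {
  stopifnot(length(target_breed) == 1L, length(background_breeds) >= 1L)
  if (target_breed %in% background_breeds)
    stop("target breed cannot be in the background")
  if (any(exclude_from_background %in% background_breeds))
    stop("excluded breeds cannot be in the background")
  if (!(threshold > 0.5 && threshold <= 1))
    stop("threshold must be in (0.5, 1]")
  structure(list(target_breed = target_breed,
                 background_breeds = sort(unique(background_breeds)),
                 threshold = threshold,
                 exclude_from_background = sort(unique(exclude_from_background))),
            class = "breed_specific_config")
}

#' Allele frequency of a set of breeds at one or all sites
#'
#' The denominator is the number of called (non-missing) alleles of the
#' samples belonging to the named breeds; missing genotypes contribute
#' neither allele.
#'
#' @param panel a [genotype_panel()].
#' @param popmap a [pop_map()] covering the panel samples.
#' @param breeds_set character vector of breed labels (pooled).
#' @param variant_index 1-based variant index, or `NULL` for all sites.
#' @return list with `alt_freq` (numeric; `NA` where zero alleles are
#'   called) and `n_called` (called allele count), each scalar when
#'   `variant_index` is given and vectors over sites otherwise.
#' @export
population_allele_freq <- function(panel, popmap, breeds_set,
                                   variant_index = NULL) {
  check_popmap_covers(popmap, panel)
  if (length(breeds_set) == 0L) stop("empty breed set")
  ss <- breed_samples(popmap, breeds_set)
  ss <- intersect(ss, panel$samples)
  g <- panel$genotypes[match(ss, panel$samples), , drop = FALSE]
  if (!is.null(variant_index)) g <- g[, variant_index, drop = FALSE]
  alt <- colSums(g, na.rm = TRUE)
  called <- 2L * colSums(!is.na(g))
  freq <- ifelse(called > 0L, alt / pmax(called, 1L), NA_real_)
  if (!is.null(variant_index))
    list(alt_freq = freq[[1L]], n_called = called[[1L]])
  else
    list(alt_freq = unname(freq), n_called = unname(called))
}

#' Classify every site of a panel for one target breed
#'
#' Applies the allele-frequency criterion in both orientations at every
#' site: alt-specific (object alt frequency and background ref frequency
#' both above threshold) and ref-specific (the reverse). A site where either
#' side's frequency is undefined (no called alleles) is never specific.
#' Sites where fewer than half of a population's alleles are called are
#' flagged `low_confidence` but still classified.
#'
#' @param panel a [genotype_panel()].
#' @param popmap a [pop_map()].
#' @param config a [breed_specific_config()].
#' @return list of class `breed_specific_calls` with elements
#'   `calls` (data.frame: chrom, pos, id, ref, alt, target_breed,
#'   specific_allele, object_freq, background_freq, object_called,
#'   background_called, low_confidence, is_specific) and `summary`
#'   (n_sites, n_specific, n_alt_specific, n_ref_specific, per_chrom table).
#'   For non-specific sites `object_freq`/`background_freq` report the
#'   alt orientation (object alt, background ref).
#' @export
classify_panel <- function(panel, popmap, config) {
  stopifnot(inherits(config, "breed_specific_config"))
  check_popmap_covers(popmap, panel)
  all_b <- breeds(popmap)
  unknown <- setdiff(c(config$target_breed, config$background_breeds), all_b)
  if (length(unknown))
    stop("breed not present in population map: ",
         paste(unknown, collapse = ", "))
  t <- config$threshold
  obj <- population_allele_freq(panel, popmap, config$target_breed)
  bg <- population_allele_freq(panel, popmap, config$background_breeds)
  obj_total <- 2L * length(breed_samples(popmap, config$target_breed))
  bg_total <- 2L * length(breed_samples(popmap, config$background_breeds))

  obj_alt <- obj$alt_freq; bg_alt <- bg$alt_freq
  defined <- !is.na(obj_alt) & !is.na(bg_alt)
  alt_spec <- defined & obj_alt > t & (1 - bg_alt) > t
  ref_spec <- defined & (1 - obj_alt) > t & bg_alt > t
  is_spec <- alt_spec | ref_spec

  spec_allele <- rep(NA_character_, n_variants(panel))
  spec_allele[alt_spec] <- "alt"
  spec_allele[ref_spec] <- "ref"

  object_freq <- obj_alt
  background_freq <- 1 - bg_alt
  object_freq[ref_spec] <- 1 - obj_alt[ref_spec]
  background_freq[ref_spec] <- bg_alt[ref_spec]

  low_conf <- obj$n_called < obj_total / 2 | bg$n_called < bg_total / 2

  v <- panel$variants
  calls <- data.frame(chrom = v$chrom, pos = v$pos, id = v$id, ref = v$ref,
                      alt = v$alt, target_breed = config$target_breed,
                      specific_allele = spec_allele,
                      object_freq = object_freq,
                      background_freq = background_freq,
                      object_called = obj$n_called,
                      background_called = bg$n_called,
                      low_confidence = low_conf,
                      is_specific = is_spec,
                      stringsAsFactors = FALSE)
  per_chrom <- table(factor(v$chrom[is_spec], levels = unique(v$chrom)))
  structure(list(calls = calls,
                 summary = list(n_sites = nrow(calls),
                                n_specific = sum(is_spec),
                                n_alt_specific = sum(alt_spec),
                                n_ref_specific = sum(ref_spec),
                                per_chrom = per_chrom),
                 config = config),
            class = "breed_specific_calls")
}

#' @export
print.breed_specific_calls <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "breed_specific_calls for %s: %d/%d sites specific (%d alt, %d ref)\n",
    x$config$target_breed, s$n_specific, s$n_sites, s$n_alt_specific,
    s$n_ref_specific))
  invisible(x)
}

#' Classify a single site
#'
#' @inheritParams classify_panel
#' @param variant_index 1-based variant index.
#' @return one-row data.frame as in [classify_panel()]'s `calls`.
#' @export
classify_site <- function(panel, popmap, config, variant_index) {
  if (variant_index < 1L || variant_index > n_variants(panel))
    stop("variant index out of range: ", variant_index)
  sub <- subset_panel(panel, variants = variant_index)
  classify_panel(sub, popmap, config)$calls
}

#' Build the per-breed configurations with the wild-ancestor exclusion
#'
#' For each native target breed the background is every breed except the
#' target and the wild ancestor (whose alleles may overlap the natives'
#' through recent common ancestry); for the wild breed itself the background
#' is every other breed.
#'
#' @param all_breeds character vector of all breed labels in the panel.
#' @param wild_breed label of the wild ancestral breed.
#' @param natives character vector of native breed labels (excluding the
#'   wild breed).
#' @param threshold frequency threshold, default 0.9.
#' @return named list of [breed_specific_config()], one per native plus one
#'   for the wild breed.
#' @export
native_breed_configs <- function(all_breeds, wild_breed, natives,
                                 threshold = 0.9) {
  all_breeds <- unique(all_breeds)
  if (!wild_breed %in% all_breeds) stop("wild breed not in breed set")
  if (!all(natives %in% all_breeds)) stop("native breeds must be in breed set")
  if (wild_breed %in% natives) stop("wild breed cannot be listed as native")
  cfgs <- lapply(natives, function(b)
    breed_specific_config(b, setdiff(all_breeds, c(b, wild_breed)),
                          threshold = threshold,
                          exclude_from_background = wild_breed))
  cfgs <- c(cfgs, list(breed_specific_config(
    wild_breed, setdiff(all_breeds, wild_breed), threshold = threshold)))
  stats::setNames(cfgs, c(natives, wild_breed))
}

#' Venn region counts over per-breed specific-call sets
#'
#' Variants are keyed by the `chrom:pos:ref:alt` tuple. Returns the count of
#' every exclusive membership region; the region counts sum to the size of
#' the union.
#'
#' @param calls_by_breed named list; each element either a
#'   `breed_specific_calls` object or a calls data.frame (rows with
#'   `is_specific == TRUE` are used when the column is present).
#' @return data.frame with columns `region` (breed labels joined by `&`)
#'   and `count`, plus attribute `union_size`.
#' @export
overlap_sets <- function(calls_by_breed) {
  if (is.null(names(calls_by_breed))) stop("calls_by_breed must be named")
  key_sets <- lapply(calls_by_breed, function(x) {
    df <- if (inherits(x, "breed_specific_calls")) x$calls else x
    if ("is_specific" %in% names(df)) df <- df[df$is_specific, , drop = FALSE]
    unique(variant_keys(df))
  })
  labs <- names(key_sets)
  all_keys <- unique(unlist(key_sets))
  memb <- vapply(key_sets, function(s) all_keys %in% s,
                 logical(length(all_keys)))
  if (length(all_keys) == 1L) memb <- matrix(memb, nrow = 1L,
                                             dimnames = list(NULL, labs))
  if (length(all_keys) == 0L)
    memb <- matrix(logical(0), ncol = length(labs),
                   dimnames = list(NULL, labs))
  patt <- expand.grid(rep(list(c(FALSE, TRUE)), length(labs)))[-1L, ,
                                                               drop = FALSE]
  names(patt) <- labs
  region <- apply(patt, 1L, function(p) paste(labs[as.logical(p)],
                                              collapse = "&"))
  count <- apply(patt, 1L, function(p)
    sum(apply(memb, 1L, function(row) all(row == as.logical(p)))))
  if (length(all_keys) == 0L) count <- rep(0L, nrow(patt))
  out <- data.frame(region = region, count = as.integer(count),
                    stringsAsFactors = FALSE)
  attr(out, "union_size") <- length(all_keys)
  out
}
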