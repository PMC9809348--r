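#' Per-chromosome SNP summary
#'
#' Counts SNPs (and, given annotations, nonsynonymous SNPs split into
#' rs-tagged and novel) per chromosome and summarizes the distance between
#' adjacent SNPs. Positions are sorted internally, so input record order
#' does not matter. The distance SD is the sample standard deviation
#' (divide by n-1); a chromosome with fewer than 2 SNPs has undefined
#' distance statistics. A variant is rs-tagged when its id matches
#' `^rs[0-9]+$`.
#'
#' @param panel a [genotype_panel()].
#' @param annotations optional annotation data.frame from
#'   [annotate_variants()] covering the panel's variants; without it the
#'   nsSNP columns are `NA`.
#' @return data.frame with one row per chromosome: `chrom`, `n_snps`,
#'   `n_nssnps`, `n_rs_tagged_nssnps`, `n_novel_nssnps`,
#'   `mean_adjacent_distance`, `sd_adjacent_distance`.
#' @export
summarize_by_chrom <- function(panel, annotations = NULL) {
  v <- panel$variants
  is_rs <- grepl("^rs[0-9]+$", v$id)
  is_ns <- rep(NA, nrow(v))
  if (!is.null(annotations)) {
    idx <- match(variant_keys(v), paste(annotations$chrom, annotations$pos,
                                        annotations$ref, annotations$alt,
                                        sep = ":"))
    if (anyNA(idx)) stop("annotations do not cover all panel variants")
    is_ns <- annotations$consequence[idx] %in% NS_CONSEQUENCES
  }
  chroms <- unique(v$chrom)
  rows <- lapply(chroms, function(ch) {
    sel <- v$chrom == ch
    p <- sort(v$pos[sel])
    dd <- if (length(p) >= 2L) diff(p) else numeric(0)
    n_ns <- if (is.null(annotations)) NA_integer_ else sum(is_ns[sel])
    n_rs_ns <- if (is.null(annotations)) NA_integer_
               else sum(is_ns[sel] & is_rs[sel])
    data.frame(chrom = ch, n_snps = sum(sel), n_nssnps = n_ns,
               n_rs_tagged_nssnps = n_rs_ns,
               n_novel_nssnps = if (is.null(annotations)) NA_integer_
                                else n_ns - n_rs_ns,
               mean_adjacent_distance = if (length(dd)) mean(dd) else NA_real_,
               sd_adjacent_distance = if (length(dd) >= 2L) stats::sd(dd)
                                      else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Provenance manifest of a pipeline run
#'
#' Records the configuration, seeds, package and R versions, and md5
#' checksums of the listed output files, as a JSON-serializable list.
#' Two runs of the same configuration differ only in the `timestamp` field.
#'
#' @param config named list of run parameters (thresholds, scenario
#'   settings, ...).
#' @param seeds named or unnamed vector/list of the seeds used.
#' @param files optional character vector of output file paths to checksum.
#' @return list of class `run_manifest`.
#' @export
run_manifest <- function(config, seeds, files = character(0)) {
  checksums <- list()
  if (length(files)) {
    missing <- files[!file.exists(files)]
    if (length(missing))
      stop("cannot checksum missing file(s): ",
           paste(missing, collapse = ", "))
    sums <- tools::md5sum(files)
    checksums <- as.list(stats::setNames(unname(sums), basename(files)))
  }
  structure(list(
    tool = "breedmark",
    version = as.character(utils::packageVersion("breedmark")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    seeds = as.list(seeds),
    checksums = checksums), class = "run_manifest")
}

#' Validate the structure of a run manifest
#' @param manifest a `run_manifest` (or a list read back from JSON).
#' @return `TRUE`, invisibly; error when a required field is missing.
#' @export
validate_manifest <- function(manifest) {
  req <- c("tool", "version", "r_version", "timestamp", "config", "seeds",
           "checksums")
  missing <- setdiff(req, names(manifest))
  if (length(missing))
    stop("manifest missing field(s): ", paste(missing, collapse = ", "))
  if (!identical(manifest$tool, "breedmark")) stop("manifest tool mismatch")
  invisible(TRUE)
}

#' Write a run manifest as JSON
#' @param manifest a `run_manifest`.
#' @param path output file path.
#' @param strip_timestamp drop the timestamp field (useful when comparing
#'   manifests across runs).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path, strip_timestamp = FALSE) {
  x <- unclass(manifest)
  if (strip_timestamp) x$timestamp <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
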