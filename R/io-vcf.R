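#' Read a multi-sample VCF into a genotype panel
#'
#' Parses a VCF 4.x file (via vcfR) and converts the GT field of each sample
#' into alternative-allele dosages. Only the GT FORMAT field is used; other
#' FORMAT fields are ignored. Phased (`|`) and unphased (`/`) separators are
#' treated identically. A genotype with one missing allele (e.g. `./1`) is
#' conservatively treated as fully missing. Any GT that is not diploid is a
#' hard error.
#'
#' @param path path to an (uncompressed or bgzipped) VCF file.
#' @param snv_only if `TRUE` (default), multiallelic records and records whose
#'   REF or ALT is not a single base are dropped; the number of exclusions is
#'   recorded in the `dropped` attribute of the result.
#' @return a [genotype_panel()] with attribute `dropped`, a list with counts
#'   `multiallelic`, `not_snv`, `n_input` and `n_kept`
#'   (`n_kept + multiallelic + not_snv == n_input` when `snv_only`).
#' @export
read_vcf <- function(path, snv_only = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  fix <- vcf@fix  # always a matrix, unlike getFIX() on single-record files
  if (is.null(fix) || nrow(vcf@gt) == 0L && nrow(fix) > 0L)
    stop("VCF has records but no genotype columns: ", path)
  n_input <- nrow(fix)
  n_header <- length(vcf@meta) + 1L  # meta lines plus the #CHROM line
  if (n_input > 0L) {
    fmt <- vcf@gt[, 1L]
    has_gt <- vapply(strsplit(fmt, ":", fixed = TRUE),
                     function(f) "GT" %in% f, logical(1))
    if (any(!has_gt)) {
      line <- n_header + which(!has_gt)[1L]
      stop("record without GT field at line ", line, " of ", path)
    }
  }
  samples <- colnames(vcf@gt)[-1L]
  if (is.null(samples)) samples <- character(0)

  chrom <- as.character(fix[, "CHROM"])
  pos <- as.integer(fix[, "POS"])
  id <- as.character(fix[, "ID"]); id[is.na(id)] <- "."
  ref <- toupper(as.character(fix[, "REF"]))
  alt <- toupper(as.character(fix[, "ALT"]))

  keep <- rep(TRUE, n_input)
  dropped <- list(multiallelic = 0L, not_snv = 0L,
                  n_input = n_input, n_kept = n_input)
  if (snv_only && n_input > 0L) {
    multi <- grepl(",", alt, fixed = TRUE)
    not_snv <- !multi & (nchar(ref) != 1L | nchar(alt) != 1L |
                           !ref %in% c("A", "C", "G", "T") |
                           !alt %in% c("A", "C", "G", "T"))
    keep <- !multi & !not_snv
    dropped$multiallelic <- sum(multi)
    dropped$not_snv <- sum(not_snv)
    dropped$n_kept <- sum(keep)
  }

  if (n_input > 0L && length(samples) > 0L) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    gt <- matrix(as.character(gt), nrow = nrow(fix),
                 dimnames = list(NULL, samples))
  } else {
    gt <- matrix(character(0), nrow = n_input, ncol = length(samples),
                 dimnames = list(NULL, samples))
  }
  gt <- gt[keep, , drop = FALSE]

  geno <- gt_to_dosage(gt, path)
  panel <- genotype_panel(t(geno),
                          data.frame(chrom = chrom[keep], pos = pos[keep],
                                     id = id[keep], ref = ref[keep],
                                     alt = alt[keep],
                                     stringsAsFactors = FALSE),
                          samples)
  attr(panel, "dropped") <- dropped
  panel
}

# GT string matrix (variants x samples) -> integer dosage matrix.
# Strictly diploid; half-calls become NA.
gt_to_dosage <- function(gt, path = "<vcf>") {
  u <- unique(as.character(gt))
  u <- u[!is.na(u)]
  val <- vapply(u, function(s) {
    a <- strsplit(s, "[/|]")[[1]]
    if (length(a) != 2L)
      stop("non-diploid genotype '", s, "' in ", path, call. = FALSE)
    if (any(a == ".")) return(NA_integer_)
    ai <- suppressWarnings(as.integer(a))
    if (any(is.na(ai)) || any(ai < 0L) || any(ai > 1L))
      stop("unsupported allele index in genotype '", s, "' in ", path,
           call. = FALSE)
    sum(ai)
  }, integer(1))
  out <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                dimnames = dimnames(gt))
  idx <- match(as.character(gt), u)
  out[] <- val[idx]
  out
}

#' Write a genotype panel as VCF 4.2
#'
#' Emits a minimal VCF with the GT FORMAT field only: dosage 0 becomes
#' `0/0`, 1 becomes `0/1`, 2 becomes `1/1` and a missing call `./.`.
#' The output round-trips through [read_vcf()].
#'
#' @param panel a [genotype_panel()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  validate_panel(panel)
  v <- panel$variants
  gt_codes <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=breedmark",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples), collapse = "\t"))
  con <- file(path, open = "wb")  # "wb": byte-identical across platforms
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (nrow(v)) {
    g <- panel$genotypes  # samples x variants
    gt <- matrix(gt_codes[g + 1L], nrow = nrow(g))
    gt[is.na(g)] <- "./."
    body_gt <- apply(gt, 2, paste, collapse = "\t")
    lines <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", ".", ".", "GT",
                   body_gt, sep = "\t")
    if (length(panel$samples) == 0L)
      lines <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", ".", ".", "GT",
                     sep = "\t")
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Read a population map file
#'
#' A population map is two whitespace- or tab-separated columns:
#' sample name, breed label. Every panel sample must appear exactly once;
#' samples in the map that the panel does not know are an error.
#'
#' @param path path to the map file.
#' @param samples character vector of panel sample names the map must cover.
#' @return a [pop_map()].
#' @export
read_popmap <- function(path, samples) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("sample", "breed"),
                           colClasses = "character")
  dup <- tab$sample[duplicated(tab$sample)]
  if (length(dup))
    stop("duplicate sample in population map: ",
         paste(unique(dup), collapse = ", "))
  unknown <- setdiff(tab$sample, samples)
  if (length(unknown))
    stop("unknown sample in population map: ",
         paste(unknown, collapse = ", "))
  unassigned <- setdiff(samples, tab$sample)
  if (length(unassigned))
    stop("unassigned sample: ", paste(unassigned, collapse = ", "))
  idx <- match(samples, tab$sample)
  pop_map(samples, tab$breed[idx])
}

#' Write a population map file
#' @param popmap a [pop_map()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(popmap, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(popmap), unclass(popmap), sep = "\t"), con,
             sep = "\n")
  invisible(path)
}
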