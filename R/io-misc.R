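#' Write a tree in Newick format
#'
#' @param tree an [ape::phylo] tree with labelled leaves and branch lengths.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  labs <- tree$tip.label
  if (any(is.na(labs)) || any(labs == ""))
    stop("every leaf must be labelled")
  if (anyDuplicated(labs))
    stop("duplicate leaf labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch lengths")
  txt <- ape::write.tree(tree, digits = 15)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(txt, con, sep = "\n")
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' GMT is tab-separated: set id, description, then one gene per field.
#'
#' @param path path to a GMT file.
#' @return named list of character gene vectors; the `description` attribute
#'   of each element carries the second GMT column.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("GMT line with fewer than 3 fields")
    genes <- unique(f[-(1:2)])
    attr(genes, "description") <- f[2]
    genes
  })
  ids <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  if (anyDuplicated(ids)) stop("duplicate gene-set id in GMT")
  stats::setNames(out, ids)
}

#' Write gene sets to a GMT file
#' @param sets named list of character gene vectors; each element may carry a
#'   `description` attribute (defaults to the set name).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("gene sets must be named")
  lines <- vapply(names(sets), function(id) {
    genes <- sets[[id]]
    desc <- attr(genes, "description")
    if (is.null(desc)) desc <- id
    paste(c(id, desc, genes), collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Write a square distance matrix in PHYLIP format
#' @param dist symmetric numeric matrix with dimnames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phylip_dist <- function(dist, path) {
  stopifnot(is.matrix(dist), nrow(dist) == ncol(dist))
  labs <- rownames(dist)
  lines <- c(sprintf("%5d", nrow(dist)),
             vapply(seq_len(nrow(dist)), function(i)
               paste(c(sprintf("%-10s", labs[i]),
                       sprintf("%.9f", dist[i, ])), collapse = " "),
               character(1)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

# Deterministic TSV writer shared by the report-style outputs.
write_tsv_plain <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) ifelse(is.na(x), NA,
                                                sprintf("%.10g", x)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", eol = "\n")
  invisible(path)
}

#' Write breed-specific calls as TSV
#' @param calls a calls data.frame from [classify_panel()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) write_tsv_plain(calls, path)

#' Write a QC report as TSV
#' @param report the report data.frame from [apply_qc()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) write_tsv_plain(report, path)

#' Write eigenvalues and eigenvectors in GCTA-compatible layout
#'
#' Produces `<prefix>.eigenval` (one eigenvalue per line) and
#' `<prefix>.eigenvec` (family id, sample id, then one column per PC).
#'
#' @param pca_result result of [grm_pca()].
#' @param prefix output path prefix.
#' @return the two paths, invisibly.
#' @export
write_eigen <- function(pca_result, prefix) {
  pv <- paste0(prefix, ".eigenval")
  con <- file(pv, open = "wb")
  writeLines(sprintf("%.10g", pca_result$values), con, sep = "\n")
  close(con)
  pe <- paste0(prefix, ".eigenvec")
  sc <- pca_result$scores
  lines <- vapply(seq_len(nrow(sc)), function(i)
    paste(c(rownames(sc)[i], rownames(sc)[i],
            sprintf("%.10g", sc[i, ])), collapse = "\t"), character(1))
  con <- file(pe, open = "wb")
  writeLines(lines, con, sep = "\n")
  close(con)
  invisible(c(pv, pe))
}
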