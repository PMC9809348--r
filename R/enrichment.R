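check_table <- function(count, list_total, pop_hits, pop_total) {
  stopifnot(length(count) == 1L, length(list_total) == 1L,
            length(pop_hits) == 1L, length(pop_total) == 1L)
  if (pop_total < 1L) stop("empty background")
  if (list_total > pop_total || pop_hits > pop_total)
    stop("list or set larger than background")
  if (count > min(list_total, pop_hits))
    stop("overlap exceeds list or set size")
  if (count < max(0L, list_total + pop_hits - pop_total))
    stop("overlap below the minimum forced by the margins")
  invisible(TRUE)
}

#' Upper-tail hypergeometric probability of a gene-list overlap
#'
#' Probability of observing at least `count` genes of the set in a list of
#' `list_total` genes drawn from a background of `pop_total` genes of which
#' `pop_hits` belong to the set.
#'
#' @param count observed overlap (list and set).
#' @param list_total size of the gene list.
#' @param pop_hits set size within the background.
#' @param pop_total background (universe) size.
#' @return `P[X >= count]` in `(0, 1]`.
#' @export
hypergeom_upper_tail <- function(count, list_total, pop_hits, pop_total) {
  check_table(count, list_total, pop_hits, pop_total)
  stats::phyper(count - 1, pop_hits, pop_total - pop_hits, list_total,
                lower.tail = FALSE)
}

#' EASE score (conservative hypergeometric variant)
#'
#' The upper-tail hypergeometric probability computed with one gene removed
#' from the overlap (`count - 1`), penalizing single-gene overlaps: an
#' overlap of 1 always scores 1. Always at least as large as the plain
#' hypergeometric p-value.
#'
#' @inheritParams hypergeom_upper_tail
#' @return probability in `(0, 1]`.
#' @export
ease_p <- function(count, list_total, pop_hits, pop_total) {
  if (count < 1L) stop("EASE score requires an overlap of at least 1")
  check_table(count, list_total, pop_hits, pop_total)
  stats::phyper(count - 2, pop_hits, pop_total - pop_hits, list_total,
                lower.tail = FALSE)
}

#' Gene-set over-representation of a gene list
#'
#' One test per gene set with a non-empty overlap: overlap count, fold
#' enrichment `(count / list_total) / (pop_hits / pop_total)`, upper-tail
#' hypergeometric p-value and the EASE variant. Results are ranked by
#' p-value. Raw p-values are reported by default; Benjamini-Hochberg
#' adjustment is optional.
#'
#' @param gene_list character vector of genes of interest; must be a subset
#'   of `background`.
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param background character vector: the gene universe.
#' @param adjust if `TRUE`, add a Benjamini-Hochberg `p_adjust` column
#'   (computed over the tested sets).
#' @return data.frame with columns term_id, term_name, count, list_total,
#'   pop_hits, pop_total, fold_enrichment, p_value, ease_p, genes
#'   (comma-separated overlap), ordered by increasing p_value.
#' @export
enrich <- function(gene_list, gene_sets, background, adjust = FALSE) {
  background <- unique(background)
  if (!length(background)) stop("empty background")
  gene_list <- unique(gene_list)
  outside <- setdiff(gene_list, background)
  if (length(outside))
    stop("gene list not contained in background: ",
         paste(utils::head(outside, 5L), collapse = ", "))
  pop_total <- length(background)
  list_total <- length(gene_list)
  rows <- lapply(names(gene_sets), function(id) {
    set <- intersect(gene_sets[[id]], background)
    hit <- intersect(gene_list, set)
    if (!length(hit)) return(NULL)
    count <- length(hit); pop_hits <- length(set)
    desc <- attr(gene_sets[[id]], "description")
    data.frame(term_id = id,
               term_name = if (is.null(desc)) id else desc,
               count = count, list_total = list_total,
               pop_hits = pop_hits, pop_total = pop_total,
               fold_enrichment = (count / list_total) /
                 (pop_hits / pop_total),
               p_value = hypergeom_upper_tail(count, list_total, pop_hits,
                                              pop_total),
               ease_p = ease_p(count, list_total, pop_hits, pop_total),
               genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(term_id = character(0), term_name = character(0),
                      count = integer(0), list_total = integer(0),
                      pop_hits = integer(0), pop_total = integer(0),
                      fold_enrichment = numeric(0), p_value = numeric(0),
                      ease_p = numeric(0), genes = character(0),
                      stringsAsFactors = FALSE)
  if (adjust && nrow(out))
    out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
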