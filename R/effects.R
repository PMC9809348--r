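AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", `F` = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "Ter")

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Load gene models from GFF3 and a reference FASTA
#'
#' Builds one coding model per gene from the GFF3's CDS features. CDS
#' features are attributed to transcripts through their `Parent` (or
#' `transcript_id`) attribute and transcripts to genes through the
#' mRNA/transcript features' `Parent` (or a `gene_id` attribute); per gene
#' the transcript with the longest total CDS is kept. Models whose total CDS
#' length is not divisible by 3 are skipped with a warning, as are models on
#' chromosomes absent from the FASTA.
#'
#' @param gff_path path to a GFF3 file with CDS features.
#' @param fasta_path path to the reference FASTA.
#' @return list of class `gene_model_set` with elements `models` (list of
#'   gene models: `gene_id`, `transcript_id`, `chrom`, `strand`, `cds`
#'   data.frame of 1-based inclusive start/end sorted by position,
#'   `cds_len`) and `reference` (a `DNAStringSet`).
#' @export
load_gene_models <- function(gff_path, fasta_path) {
  ref <- Biostrings::readDNAStringSet(fasta_path)
  names(ref) <- sub("\\s.*$", "", names(ref))
  gff <- rtracklayer::import(gff_path, format = "gff3")
  models <- build_gene_models(gff, ref)
  structure(list(models = models, reference = ref),
            class = "gene_model_set")
}

build_gene_models <- function(gff, ref) {
  type <- as.character(gff$type)
  cds <- gff[type == "CDS"]
  if (length(cds) == 0L) stop("no CDS features in GFF3")
  first_chr <- function(x) vapply(x, function(e)
    if (length(e)) as.character(e[[1L]]) else NA_character_, character(1))
  parent <- if (!is.null(cds$Parent)) first_chr(as.list(cds$Parent))
            else rep(NA_character_, length(cds))
  if (all(is.na(parent)) && !is.null(cds$transcript_id))
    parent <- as.character(cds$transcript_id)
  if (any(is.na(parent)))
    stop("CDS features without Parent/transcript attribution")
  # transcript -> gene through mRNA/transcript features
  tx <- gff[type %in% c("mRNA", "transcript")]
  tx_gene <- character(0)
  if (length(tx)) {
    tg <- if (!is.null(tx$Parent)) first_chr(as.list(tx$Parent))
          else rep(NA_character_, length(tx))
    tx_gene <- stats::setNames(tg, as.character(tx$ID))
  }
  gene_of <- function(txid) {
    g <- tx_gene[txid]
    ifelse(is.na(g), txid, g)
  }
  models <- list()
  for (txid in unique(parent)) {
    sel <- parent == txid
    chrom <- unique(as.character(GenomicRanges::seqnames(cds[sel])))
    strand <- unique(as.character(GenomicRanges::strand(cds[sel])))
    if (length(chrom) != 1L || length(strand) != 1L) {
      warning("transcript ", txid, " spans chromosomes/strands; skipped")
      next
    }
    iv <- data.frame(start = GenomicRanges::start(cds[sel]),
                     end = GenomicRanges::end(cds[sel]))
    iv <- iv[order(iv$start), , drop = FALSE]
    rownames(iv) <- NULL
    if (nrow(iv) > 1L && any(iv$start[-1L] <= iv$end[-nrow(iv)])) {
      warning("overlapping CDS intervals in transcript ", txid, "; skipped")
      next
    }
    len <- sum(iv$end - iv$start + 1L)
    if (len %% 3L != 0L) {
      warning("CDS length of transcript ", txid,
              " not divisible by 3; model skipped")
      next
    }
    if (!chrom %in% names(ref)) {
      warning("chromosome ", chrom, " of transcript ", txid,
              " absent from FASTA; model skipped")
      next
    }
    models[[txid]] <- list(gene_id = unname(gene_of(txid)),
                           transcript_id = txid, chrom = chrom,
                           strand = strand, cds = iv, cds_len = len)
  }
  if (!length(models)) stop("no usable gene models")
  # longest CDS per gene
  genes <- vapply(models, `[[`, character(1), "gene_id")
  lens <- vapply(models, `[[`, integer(1), "cds_len")
  keep <- unlist(lapply(split(seq_along(models), genes), function(ix)
    ix[which.max(lens[ix])]), use.names = FALSE)
  unname(models[sort(keep)])
}

# concatenated CDS sequence of a model, 5'->3' in coding orientation
cds_sequence <- function(model, ref) {
  chrom_seq <- ref[[model$chrom]]
  parts <- lapply(seq_len(nrow(model$cds)), function(i)
    Biostrings::subseq(chrom_seq, model$cds$start[i], model$cds$end[i]))
  s <- do.call(Biostrings::xscat, parts)
  if (model$strand == "-") s <- Biostrings::reverseComplement(s)
  s
}

# 1-based offset of genomic position within the coding sequence, or NA
cds_offset <- function(model, pos) {
  iv <- model$cds
  cum <- c(0L, cumsum(iv$end - iv$start + 1L))
  hit <- which(pos >= iv$start & pos <= iv$end)
  if (!length(hit)) return(NA_integer_)
  off_fwd <- cum[hit] + (pos - iv$start[hit] + 1L)
  if (model$strand == "-") model$cds_len - off_fwd + 1L else off_fwd
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Annotate the coding consequence of one SNV
#'
#' Locates the variant within the gene models, extracts the affected codon
#' strand-aware, substitutes the alternative base (complemented for minus
#' strand genes) and translates both codons with the standard genetic code.
#' The reference base at the position must match the variant's REF allele.
#'
#' @param variant one-row data.frame (or list) with `chrom`, `pos`, `ref`,
#'   `alt`.
#' @param models a `gene_model_set` from [load_gene_models()] (or its
#'   `models` element).
#' @param reference a `DNAStringSet`; defaults to the set bundled in
#'   `models`.
#' @return one-row data.frame: `chrom`, `pos`, `ref`, `alt`, `gene_id`,
#'   `consequence` (one of intergenic, non_coding_gene_region, synonymous,
#'   nonsynonymous, stop_gained, stop_lost), `codon_change` (e.g.
#'   `"AGT>TGT"`), `aa_change` (e.g. `"Ser>Cys"`), `aa_position`.
#' @export
annotate_variant <- function(variant, models, reference = NULL) {
  if (inherits(models, "gene_model_set")) {
    if (is.null(reference)) reference <- models$reference
    models <- models$models
  }
  if (is.null(reference)) stop("a reference DNAStringSet is required")
  chrom <- as.character(variant$chrom); pos <- as.integer(variant$pos)
  ref_a <- toupper(as.character(variant$ref))
  alt_a <- toupper(as.character(variant$alt))
  if (nchar(ref_a) != 1L || nchar(alt_a) != 1L)
    stop("annotate_variant handles single-base SNVs only")
  if (chrom %in% names(reference)) {
    genome_base <- as.character(Biostrings::subseq(reference[[chrom]],
                                                   pos, pos))
    if (genome_base != ref_a)
      stop("reference mismatch at ", chrom, ":", pos, " (VCF REF ", ref_a,
           ", genome ", genome_base, ")")
  }
  out <- data.frame(chrom = chrom, pos = pos, ref = ref_a, alt = alt_a,
                    gene_id = NA_character_, consequence = "intergenic",
                    codon_change = NA_character_, aa_change = NA_character_,
                    aa_position = NA_integer_, stringsAsFactors = FALSE)
  for (m in models) {
    if (m$chrom != chrom) next
    span <- c(min(m$cds$start), max(m$cds$end))
    if (pos < span[1] || pos > span[2]) next
    off <- cds_offset(m, pos)
    if (is.na(off)) {
      out$gene_id <- m$gene_id
      out$consequence <- "non_coding_gene_region"
      next  # keep looking for a model whose CDS contains the site
    }
    cds <- as.character(cds_sequence(m, reference))
    codon_i <- (off - 1L) %/% 3L + 1L
    within <- off - 3L * (codon_i - 1L)
    ref_codon <- substr(cds, 3L * codon_i - 2L, 3L * codon_i)
    sub_base <- if (m$strand == "-") COMPLEMENT[[alt_a]] else alt_a
    alt_codon <- ref_codon
    substr(alt_codon, within, within) <- sub_base
    aa_ref <- translate_codon(ref_codon)
    aa_alt <- translate_codon(alt_codon)
    cons <- if (aa_ref == aa_alt) "synonymous"
            else if (aa_alt == "*") "stop_gained"
            else if (aa_ref == "*") "stop_lost"
            else "nonsynonymous"
    out$gene_id <- m$gene_id
    out$consequence <- cons
    out$codon_change <- paste0(ref_codon, ">", alt_codon)
    out$aa_change <- paste0(AA3[[aa_ref]], ">", AA3[[aa_alt]])
    out$aa_position <- codon_i
    break
  }
  out
}

#' Annotate every variant of a panel (or variant table)
#'
#' @param x a [genotype_panel()] or a variants data.frame.
#' @param models a `gene_model_set` from [load_gene_models()].
#' @return data.frame with one annotation row per variant, in input order
#'   (see [annotate_variant()] for columns).
#' @export
annotate_variants <- function(x, models) {
  v <- if (inherits(x, "genotype_panel")) x$variants else x
  rows <- lapply(seq_len(nrow(v)), function(i)
    annotate_variant(v[i, , drop = FALSE], models))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

CODING_CONSEQUENCES <- c("synonymous", "nonsynonymous", "stop_gained",
                         "stop_lost")
NS_CONSEQUENCES <- c("nonsynonymous", "stop_gained", "stop_lost")

#' Restrict breed-specific calls to nonsynonymous sites
#'
#' Keeps the calls whose consequence changes the protein (nonsynonymous,
#' stop gained or stop lost). Every call variant must be covered by the
#' annotation table.
#'
#' @param calls a `breed_specific_calls` object or calls data.frame (rows
#'   with `is_specific == TRUE` are used when the column is present).
#' @param annotations annotation data.frame from [annotate_variants()].
#' @return the filtered calls data.frame with annotation columns appended;
#'   attribute `n_by_consequence` tabulates the retained categories.
#' @export
breed_specific_nssnps <- function(calls, annotations) {
  df <- if (inherits(calls, "breed_specific_calls")) calls$calls else calls
  if ("is_specific" %in% names(df)) df <- df[df$is_specific, , drop = FALSE]
  key_c <- paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  key_a <- paste(annotations$chrom, annotations$pos, annotations$ref,
                 annotations$alt, sep = ":")
  idx <- match(key_c, key_a)
  if (anyNA(idx))
    stop("unannotated variant(s): ",
         paste(utils::head(key_c[is.na(idx)], 5L), collapse = ", "))
  ann <- annotations[idx, c("gene_id", "consequence", "codon_change",
                            "aa_change", "aa_position"), drop = FALSE]
  out <- cbind(df, ann)
  rownames(out) <- NULL
  out <- out[out$consequence %in% NS_CONSEQUENCES, , drop = FALSE]
  attr(out, "n_by_consequence") <-
    table(factor(out$consequence, levels = NS_CONSEQUENCES))
  out
}

#' Genes hit by breed-specific calls
#'
#' Two modes mirror different downstream uses: `"nssnp"` collects genes
#' whose coding sequence carries a protein-changing breed-specific SNP;
#' `"all"` collects genes whose bounds contain any breed-specific SNP
#' (coding or not).
#'
#' @param calls a `breed_specific_calls` object or calls data.frame.
#' @param annotations annotation data.frame from [annotate_variants()].
#' @param mode `"nssnp"` (default) or `"all"`.
#' @return character vector of unique gene ids, sorted.
#' @export
genes_hit <- function(calls, annotations, mode = c("nssnp", "all")) {
  mode <- match.arg(mode)
  df <- if (inherits(calls, "breed_specific_calls")) calls$calls else calls
  if ("is_specific" %in% names(df)) df <- df[df$is_specific, , drop = FALSE]
  if (!nrow(df)) return(character(0))
  key_c <- paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  key_a <- paste(annotations$chrom, annotations$pos, annotations$ref,
                 annotations$alt, sep = ":")
  idx <- match(key_c, key_a)
  if (anyNA(idx))
    stop("unannotated variant(s): ",
         paste(utils::head(key_c[is.na(idx)], 5L), collapse = ", "))
  ann <- annotations[idx, , drop = FALSE]
  keep <- if (mode == "nssnp") ann$consequence %in% NS_CONSEQUENCES
          else !is.na(ann$gene_id)
  sort(unique(ann$gene_id[keep & !is.na(ann$gene_id)]))
}
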