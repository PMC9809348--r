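#' Default multi-breed sample design
#'
#' Eight breeds with per-breed sample sizes typical of a multi-breed pig
#' WGS panel: three Korean populations (Jeju native pig JNP, Korean native
#' pig KNP, Korean wild boar KWB) and five other breeds.
#'
#' @return data.frame with columns `label` and `n`.
#' @export
default_breed_design <- function() {
  data.frame(label = c("BKS", "DUR", "JNP", "KNP", "KWB", "LDR", "YKS",
                       "YMP"),
             n = c(10L, 20L, 20L, 6L, 10L, 13L, 15L, 12L),
             stringsAsFactors = FALSE)
}

#' Describe a simulation scenario
#'
#' Background sites drift apart between breeds under the Balding-Nichols
#' model: an ancestral frequency `p0 ~ Uniform(0.05, 0.95)` and per-breed
#' frequencies `Beta(p0 (1-fst)/fst, (1-p0)(1-fst)/fst)` (variance
#' `p0 (1-p0) fst`); `fst = 0` means no drift (all breeds share `p0`).
#' Planted sites override the drifted frequencies: the target breed gets
#' `planted_object_freq` and every other breed `planted_background_freq`,
#' the cleanest constructible truth for breed-specific discovery. Genotypes
#' are Binomial(2, p) within breed (Hardy-Weinberg within breed), with
#' i.i.d. missingness and optional allele-level admixture.
#'
#' @param breeds data.frame with columns `label`, `n`; default
#'   [default_breed_design()].
#' @param n_sites number of background (drifted) sites.
#' @param fst drift parameter in `[0, 1)`.
#' @param planted_targets breeds that receive planted private alleles;
#'   plantings are disjoint across targets.
#' @param n_planted_per_breed planted sites per target breed.
#' @param planted_object_freq allele frequency of the planted allele in the
#'   target breed (default fixation).
#' @param planted_background_freq its frequency in every other breed
#'   (default absence).
#' @param missing_rate i.i.d. genotype missingness in `[0, 1)`.
#' @param admixture optional data.frame `sample`, `donor`, `fraction`:
#'   each allele of the sample is drawn from the donor breed's frequency
#'   with the given probability.
#' @param rs_fraction fraction of variants given an rs-style id (the rest
#'   get `"."`), exercising the tagged-vs-novel split.
#' @param n_chroms,chrom_length coordinate space when no genome is supplied
#'   to [simulate_panel()].
#' @param seed integer seed; everything the generator emits is reproducible
#'   from it.
#' @return list of class `sim_scenario`.
#' @export
simulation_scenario <- function(breeds = default_breed_design(),
                                n_sites = 10000L,
                                fst = 0.2,
                                planted_targets = c("JNP", "KNP", "KWB"),
                                n_planted_per_breed = 50L,
                                planted_object_freq = 1.0,
                                planted_background_freq = 0.0,
                                missing_rate = 0.05,
                                admixture = NULL,
                                rs_fraction = 0.5,
                                n_chroms = 18L,
                                chrom_length = 1000000L,
                                seed = 1L) {
  stopifnot(is.data.frame(breeds), all(c("label", "n") %in% names(breeds)),
            all(breeds$n >= 1L), !anyDuplicated(breeds$label))
  if (fst < 0 || fst >= 1) stop("fst must be in [0, 1)")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (planted_object_freq < 0 || planted_object_freq > 1 ||
      planted_background_freq < 0 || planted_background_freq > 1)
    stop("planted frequencies must be in [0, 1]")
  if (rs_fraction < 0 || rs_fraction > 1)
    stop("rs_fraction must be in [0, 1]")
  if (!all(planted_targets %in% breeds$label))
    stop("planted targets must be breeds of the design")
  if (!is.null(admixture))
    stopifnot(all(c("sample", "donor", "fraction") %in% names(admixture)))
  structure(list(breeds = breeds, n_sites = as.integer(n_sites), fst = fst,
                 planted_targets = planted_targets,
                 n_planted_per_breed = as.integer(n_planted_per_breed),
                 planted_object_freq = planted_object_freq,
                 planted_background_freq = planted_background_freq,
                 missing_rate = missing_rate, admixture = admixture,
                 rs_fraction = rs_fraction, n_chroms = as.integer(n_chroms),
                 chrom_length = as.integer(chrom_length),
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Simulate a multi-breed genotype panel with planted truth
#'
#' See [simulation_scenario()] for the generating model. When a genome from
#' [simulate_genome()] is supplied, variant positions are drawn on its
#' chromosomes and REF alleles match its sequence, so the panel can be
#' annotated against it.
#'
#' @param scenario a [simulation_scenario()].
#' @param genome optional `sim_genome` from [simulate_genome()].
#' @return list with `panel` (a [genotype_panel()]), `popmap` (a
#'   [pop_map()]) and `truth` (class `synthetic_truth`: `planted`
#'   data.frame with key, chrom, pos, ref, alt, target_breed, category;
#'   `p0`; `true_freqs` breed-by-site matrix; `scenario`).
#' @export
simulate_panel <- function(scenario, genome = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(scenario$seed)
  br <- scenario$breeds
  samples <- unlist(lapply(seq_len(nrow(br)), function(i)
    sprintf("%s_%02d", br$label[i], seq_len(br$n[i]))))
  breed_of <- rep(br$label, br$n)
  popmap <- pop_map(samples, breed_of)

  n_planted <- scenario$n_planted_per_breed * length(scenario$planted_targets)
  m <- scenario$n_sites + n_planted

  if (is.null(genome)) {
    chroms <- as.character(seq_len(scenario$n_chroms))
    chr_len <- stats::setNames(rep(scenario$chrom_length,
                                   scenario$n_chroms), chroms)
  } else {
    stopifnot(inherits(genome, "sim_genome"))
    chroms <- names(genome$sequences)
    chr_len <- stats::setNames(Biostrings::width(genome$sequences), chroms)
  }
  site_chrom <- sample(chroms, m, replace = TRUE,
                       prob = chr_len / sum(chr_len))
  pos <- integer(m)
  for (ch in chroms) {
    ix <- which(site_chrom == ch)
    if (length(ix) > chr_len[[ch]])
      stop("chromosome ", ch, " too short for the requested site count")
    pos[ix] <- sample.int(chr_len[[ch]], length(ix), replace = FALSE)
  }
  ord <- order(match(site_chrom, chroms), pos)
  site_chrom <- site_chrom[ord]; pos <- pos[ord]

  bases <- c("A", "C", "G", "T")
  if (is.null(genome)) {
    ref <- sample(bases, m, replace = TRUE)
  } else {
    ref <- vapply(seq_len(m), function(i)
      as.character(Biostrings::subseq(genome$sequences[[site_chrom[i]]],
                                      pos[i], pos[i])), character(1))
  }
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1),
                USE.NAMES = FALSE)

  id <- rep(".", m)
  n_rs <- round(scenario$rs_fraction * m)
  if (n_rs > 0) {
    rs_ix <- sample.int(m, n_rs)
    id[rs_ix] <- paste0("rs", sample.int(99999999L, n_rs))
  }

  # ancestral and per-breed allele frequencies
  p0 <- stats::runif(m, 0.05, 0.95)
  nb <- nrow(br)
  P <- matrix(NA_real_, nrow = nb, ncol = m,
              dimnames = list(br$label, NULL))
  for (b in seq_len(nb)) {
    P[b, ] <- if (scenario$fst == 0) p0
              else stats::rbeta(m, p0 * (1 - scenario$fst) / scenario$fst,
                                (1 - p0) * (1 - scenario$fst) / scenario$fst)
  }

  planted <- NULL
  if (n_planted > 0) {
    planted_ix <- sample.int(m, n_planted)
    tgt <- rep(scenario$planted_targets, each = scenario$n_planted_per_breed)
    for (k in seq_along(planted_ix)) {
      s <- planted_ix[k]
      P[, s] <- scenario$planted_background_freq
      P[tgt[k], s] <- scenario$planted_object_freq
    }
    planted <- data.frame(chrom = site_chrom[planted_ix],
                          pos = pos[planted_ix], ref = ref[planted_ix],
                          alt = alt[planted_ix], target_breed = tgt,
                          category = NA_character_,
                          object_freq = scenario$planted_object_freq,
                          background_freq = scenario$planted_background_freq,
                          stringsAsFactors = FALSE)
  } else {
    planted <- data.frame(chrom = character(0), pos = integer(0),
                          ref = character(0), alt = character(0),
                          target_breed = character(0),
                          category = character(0),
                          object_freq = numeric(0),
                          background_freq = numeric(0),
                          stringsAsFactors = FALSE)
  }

  breed_idx <- match(breed_of, br$label)
  g <- matrix(NA_integer_, nrow = length(samples), ncol = m)
  adm <- scenario$admixture
  for (s in seq_along(samples)) {
    q <- P[breed_idx[s], ]
    if (!is.null(adm) && samples[s] %in% adm$sample) {
      a <- adm[adm$sample == samples[s], , drop = FALSE][1L, ]
      q <- (1 - a$fraction) * q + a$fraction * P[a$donor, ]
    }
    g[s, ] <- stats::rbinom(m, 2L, q)
  }
  if (scenario$missing_rate > 0) {
    miss <- matrix(stats::runif(length(g)) < scenario$missing_rate,
                   nrow = nrow(g))
    g[miss] <- NA_integer_
  }

  variants <- data.frame(chrom = site_chrom, pos = pos, id = id, ref = ref,
                         alt = alt, stringsAsFactors = FALSE)
  panel <- genotype_panel(g, variants, samples)
  key <- paste(planted$chrom, planted$pos, planted$ref, planted$alt,
               sep = ":")
  planted <- cbind(data.frame(key = key, stringsAsFactors = FALSE), planted)
  colnames(P) <- variant_keys(panel)
  truth <- structure(list(planted = planted, p0 = p0, true_freqs = P,
                          scenario = scenario),
                     class = "synthetic_truth")
  list(panel = panel, popmap = popmap, truth = truth)
}

#' Simulate a toy annotated genome
#'
#' Random chromosomes carrying non-overlapping single-exon protein-coding
#' genes on both strands. Each gene is a valid ORF: ATG, random sense
#' codons, one stop codon; total length divisible by 3.
#'
#' @param n_genes total number of genes, distributed evenly over the
#'   chromosomes.
#' @param gene_length CDS length in bp (divisible by 3, at least 9).
#' @param chrom_length chromosome length in bp.
#' @param n_chroms number of chromosomes (named `"1"`, `"2"`, ...).
#' @param seed integer seed.
#' @return list of class `sim_genome`: `sequences` (`DNAStringSet`),
#'   `models` (gene models as in [load_gene_models()]), `genes`
#'   (data.frame gene_id, chrom, start, end, strand).
#' @export
simulate_genome <- function(n_genes = 30L, gene_length = 300L,
                            chrom_length = 20000L, n_chroms = 3L,
                            seed = 1L) {
  if (gene_length %% 3L != 0L || gene_length < 9L)
    stop("gene_length must be divisible by 3 and at least 9")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  stops <- c("TAA", "TAG", "TGA")
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- setdiff(codons, stops)
  per_chrom <- diff(round(seq(0, n_genes, length.out = n_chroms + 1L)))
  seqs <- character(n_chroms)
  genes <- list()
  models <- list()
  gid <- 0L
  for (c_i in seq_len(n_chroms)) {
    k <- per_chrom[c_i]
    slot <- if (k > 0) chrom_length %/% k else chrom_length
    if (k > 0 && slot < gene_length + 20L)
      stop("genes do not fit on chromosome ", c_i)
    s <- sample(bases, chrom_length, replace = TRUE)
    for (g_i in seq_len(k)) {
      gid <- gid + 1L
      start <- (g_i - 1L) * slot +
        sample.int(slot - gene_length - 10L, 1L) + 5L
      end <- start + gene_length - 1L
      orf <- c("ATG", sample(sense, gene_length / 3L - 2L, replace = TRUE),
               sample(stops, 1L))
      orf <- paste(orf, collapse = "")
      strand <- sample(c("+", "-"), 1L)
      insert <- if (strand == "-")
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(orf)))
      else orf
      s[start:end] <- strsplit(insert, "")[[1L]]
      gene_id <- sprintf("g%03d", gid)
      genes[[gid]] <- data.frame(gene_id = gene_id,
                                 chrom = as.character(c_i), start = start,
                                 end = end, strand = strand,
                                 stringsAsFactors = FALSE)
      models[[gid]] <- list(gene_id = gene_id,
                            transcript_id = sprintf("t%03d", gid),
                            chrom = as.character(c_i), strand = strand,
                            cds = data.frame(start = start, end = end),
                            cds_len = gene_length)
    }
    seqs[c_i] <- paste(s, collapse = "")
  }
  sequences <- Biostrings::DNAStringSet(seqs)
  names(sequences) <- as.character(seq_len(n_chroms))
  structure(list(sequences = sequences, models = models,
                 genes = do.call(rbind, genes)),
            class = "sim_genome")
}

#' Write a simulated genome as FASTA + GFF3
#'
#' @param genome a `sim_genome` from [simulate_genome()].
#' @param fasta_path,gff_path output file paths.
#' @return the two paths, invisibly.
#' @export
write_genome <- function(genome, fasta_path, gff_path) {
  stopifnot(inherits(genome, "sim_genome"))
  Biostrings::writeXStringSet(genome$sequences, fasta_path)
  g <- genome$genes
  feat <- function(type, ID, Parent) {
    gr <- GenomicRanges::GRanges(g$chrom,
                                 IRanges::IRanges(g$start, g$end),
                                 strand = g$strand)
    gr$source <- "breedmark_sim"; gr$type <- type
    gr$ID <- ID
    gr$Parent <- Parent
    gr
  }
  tid <- sub("^g", "t", g$gene_id)
  gr <- c(feat("gene", g$gene_id, NA_character_),
          feat("mRNA", tid, g$gene_id),
          feat("CDS", paste0("cds_", tid), tid))
  gr$phase <- ifelse(as.character(gr$type) == "CDS", 0L, NA_integer_)
  suppressWarnings(rtracklayer::export(gr, gff_path, format = "gff3"))
  invisible(c(fasta_path, gff_path))
}

as_model_set <- function(genome) {
  structure(list(models = genome$models, reference = genome$sequences),
            class = "gene_model_set")
}

#' Relocate planted sites onto verified coding/intergenic positions
#'
#' Moves each planted breed-specific site of a simulated panel to a genomic
#' position with a verified consequence: a requested fraction to positions
#' where the chosen ALT allele is nonsynonymous (verified by translation),
#' the remainder to verified synonymous codon positions or to intergenic
#' positions. The truth table records each site's category. Genotype
#' columns are carried along unchanged; the panel is re-sorted by position.
#'
#' @param panel a [genotype_panel()] simulated against `genome`.
#' @param truth the matching `synthetic_truth`.
#' @param genome the `sim_genome` the panel was simulated on.
#' @param fraction_nonsynonymous fraction of planted sites per target breed
#'   placed at nonsynonymous positions.
#' @param remainder `"synonymous"` or `"intergenic"`: where the rest go.
#' @param seed integer seed for the placement draws.
#' @return list with updated `panel` and `truth`.
#' @export
place_planted_variants <- function(panel, truth, genome,
                                   fraction_nonsynonymous = 1.0,
                                   remainder = c("synonymous", "intergenic"),
                                   seed = truth$scenario$seed + 1L) {
  stopifnot(inherits(genome, "sim_genome"))
  remainder <- match.arg(remainder)
  if (fraction_nonsynonymous < 0 || fraction_nonsynonymous > 1)
    stop("fraction_nonsynonymous must be in [0, 1]")
  set.seed(seed)
  ms <- as_model_set(genome)
  used <- new.env(parent = emptyenv())
  for (k in variant_keys(panel)) {
    ck <- sub("^([^:]+:[0-9]+):.*$", "\\1", k)
    assign(ck, TRUE, envir = used)
  }
  pl <- truth$planted
  keys_old <- pl$key
  v <- panel$variants
  old_idx <- match(keys_old, variant_keys(panel))
  if (anyNA(old_idx)) stop("planted keys missing from panel")

  n <- nrow(pl)
  want_ns <- logical(n)
  for (b in unique(pl$target_breed)) {
    ix <- which(pl$target_breed == b)
    k_ns <- round(fraction_nonsynonymous * length(ix))
    want_ns[ix[seq_len(k_ns)]] <- TRUE
  }

  pick_coding <- function(target_cons) {
    for (try in seq_len(1000L)) {
      mdl <- genome$models[[sample.int(length(genome$models), 1L)]]
      n_codons <- mdl$cds_len %/% 3L
      codon_i <- sample.int(n_codons - 2L, 1L) + 1L  # avoid start/stop
      within <- if (target_cons == "synonymous") 3L
                else sample.int(3L, 1L)
      off <- 3L * (codon_i - 1L) + within
      gpos <- if (mdl$strand == "+") mdl$cds$start[1L] + off - 1L
              else mdl$cds$end[1L] - off + 1L
      ck <- paste0(mdl$chrom, ":", gpos)
      if (exists(ck, envir = used)) next
      refb <- as.character(Biostrings::subseq(
        genome$sequences[[mdl$chrom]], gpos, gpos))
      for (altb in sample(setdiff(c("A", "C", "G", "T"), refb))) {
        ann <- annotate_variant(list(chrom = mdl$chrom, pos = gpos,
                                     ref = refb, alt = altb), ms)
        if (ann$consequence == target_cons) {
          assign(ck, TRUE, envir = used)
          return(list(chrom = mdl$chrom, pos = gpos, ref = refb,
                      alt = altb))
        }
      }
    }
    stop("could not place a ", target_cons, " site; genome too small")
  }
  pick_intergenic <- function() {
    spans <- genome$genes
    for (try in seq_len(1000L)) {
      ch <- sample(names(genome$sequences), 1L)
      gpos <- sample.int(Biostrings::width(
        genome$sequences[names(genome$sequences) == ch]), 1L)
      inside <- any(spans$chrom == ch & gpos >= spans$start &
                      gpos <= spans$end)
      ck <- paste0(ch, ":", gpos)
      if (inside || exists(ck, envir = used)) next
      refb <- as.character(Biostrings::subseq(
        genome$sequences[[ch]], gpos, gpos))
      altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
      assign(ck, TRUE, envir = used)
      return(list(chrom = ch, pos = gpos, ref = refb, alt = altb))
    }
    stop("could not place an intergenic site")
  }

  for (r in seq_len(n)) {
    target_cons <- if (want_ns[r]) "nonsynonymous"
                   else if (remainder == "synonymous") "synonymous"
                   else "intergenic"
    site <- if (target_cons == "intergenic") pick_intergenic()
            else pick_coding(target_cons)
    i <- old_idx[r]
    v$chrom[i] <- site$chrom; v$pos[i] <- site$pos
    v$ref[i] <- site$ref; v$alt[i] <- site$alt
    pl$chrom[r] <- site$chrom; pl$pos[r] <- site$pos
    pl$ref[r] <- site$ref; pl$alt[r] <- site$alt
    pl$category[r] <- target_cons
  }
  ord <- order(match(v$chrom, names(genome$sequences)), v$pos)
  new_panel <- genotype_panel(panel$genotypes[, ord, drop = FALSE],
                              v[ord, , drop = FALSE], panel$samples)
  pl$key <- paste(pl$chrom, pl$pos, pl$ref, pl$alt, sep = ":")
  tf <- truth$true_freqs[, ord, drop = FALSE]
  colnames(tf) <- variant_keys(new_panel)
  new_truth <- structure(list(planted = pl, p0 = truth$p0[ord],
                              true_freqs = tf, scenario = truth$scenario),
                         class = "synthetic_truth")
  list(panel = new_panel, truth = new_truth)
}

#' Build toy gene sets with one planted enriched set
#'
#' Emits GMT-style gene sets over the simulated genome's genes: one set
#' containing the given genes of interest (the planted enrichment) plus
#' random decoy sets drawn from the remaining genes.
#'
#' @param genome a `sim_genome`.
#' @param enriched_genes character vector of gene ids concentrated in the
#'   planted set.
#' @param n_decoy_sets number of random decoy sets.
#' @param set_size size of each decoy set.
#' @param seed integer seed.
#' @return named list of gene vectors (GMT-compatible; see [write_gmt()]);
#'   the planted set is named `"planted_set"`.
#' @export
make_gene_sets <- function(genome, enriched_genes, n_decoy_sets = 10L,
                           set_size = 8L, seed = 1L) {
  stopifnot(inherits(genome, "sim_genome"))
  all_genes <- genome$genes$gene_id
  if (!all(enriched_genes %in% all_genes))
    stop("enriched genes must exist in the genome")
  set.seed(seed)
  rest <- setdiff(all_genes, enriched_genes)
  sets <- list(planted_set = unique(enriched_genes))
  attr(sets$planted_set, "description") <- "planted enriched set"
  for (i in seq_len(n_decoy_sets)) {
    nm <- sprintf("decoy_%02d", i)
    sets[[nm]] <- sample(rest, min(set_size, length(rest)))
    attr(sets[[nm]], "description") <- nm
  }
  sets
}
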