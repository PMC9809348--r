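# one + strand and one - strand single-exon gene on a tiny chromosome,
# built base by base so expected codons are known exactly
tiny_genome <- function() {
  # + strand gene at 11..22: ATG AGT CTT TAA  (Met Ser Leu stop)
  plus <- "ATGAGTCTTTAA"
  # - strand gene at 31..42 encoding ATG TGC AAA TGA on the minus strand
  minus_cds <- "ATGTGCAAATGA"
  minus_genomic <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(minus_cds)))
  seq <- paste0(strrep("C", 10), plus, strrep("C", 8), minus_genomic,
                strrep("C", 10))
  sequences <- Biostrings::DNAStringSet(seq)
  names(sequences) <- "1"
  models <- list(
    list(gene_id = "gplus", transcript_id = "tplus", chrom = "1",
         strand = "+", cds = data.frame(start = 11L, end = 22L),
         cds_len = 12L),
    list(gene_id = "gminus", transcript_id = "tminus", chrom = "1",
         strand = "-", cds = data.frame(start = 31L, end = 42L),
         cds_len = 12L))
  structure(list(sequences = sequences, models = models,
                 genes = data.frame(gene_id = c("gplus", "gminus"),
                                    chrom = "1", start = c(11L, 31L),
                                    end = c(22L, 42L),
                                    strand = c("+", "-"))),
            class = "sim_genome")
}

model_set <- function(genome) {
  structure(list(models = genome$models, reference = genome$sequences),
            class = "gene_model_set")
}

test_that("known codon substitutions classify correctly on the plus strand", {
  ms <- model_set(tiny_genome())
  # AGT codon (positions 14-16), middle base G->C gives ACT: Ser>Thr
  a <- annotate_variant(list(chrom = "1", pos = 15, ref = "G", alt = "C"), ms)
  expect_equal(a$consequence, "nonsynonymous")
  expect_equal(a$codon_change, "AGT>ACT")
  expect_equal(a$aa_change, "Ser>Thr")
  expect_equal(a$aa_position, 2L)
  # AGT first base A->T gives TGT: Ser>Cys
  a <- annotate_variant(list(chrom = "1", pos = 14, ref = "A", alt = "T"), ms)
  expect_equal(a$consequence, "nonsynonymous")
  expect_equal(a$aa_change, "Ser>Cys")
  # CTT third base T->C gives CTC: Leu>Leu (wobble)
  a <- annotate_variant(list(chrom = "1", pos = 19, ref = "T", alt = "C"), ms)
  expect_equal(a$consequence, "synonymous")
  expect_equal(a$codon_change, "CTT>CTC")
  expect_equal(a$aa_change, "Leu>Leu")
  # AGT middle G->A gives AAT... stop gain instead: CTT -> taa? Use
  # TAA stop loss: last codon TAA first base T->C gives CAA: Ter>Gln
  a <- annotate_variant(list(chrom = "1", pos = 20, ref = "T", alt = "C"), ms)
  expect_equal(a$consequence, "stop_lost")
  expect_equal(a$aa_change, "Ter>Gln")
})

test_that("minus strand genes are annotated via the reverse complement", {
  g <- tiny_genome()
  ms <- model_set(g)
  # minus-strand CDS = ATG TGC AAA TGA; codon 2 TGC (Cys); its first coding
  # base sits at genomic position end - 3 = 39; genomic base is the
  # complement of T, i.e. A
  refb <- as.character(Biostrings::subseq(g$sequences[["1"]], 39, 39))
  expect_equal(refb, "A")
  # substituting genomic A->T puts A at coding position 4: TGC->AGC Cys>Ser
  a <- annotate_variant(list(chrom = "1", pos = 39, ref = "A", alt = "T"), ms)
  expect_equal(a$gene_id, "gminus")
  expect_equal(a$consequence, "nonsynonymous")
  expect_equal(a$codon_change, "TGC>AGC")
  expect_equal(a$aa_change, "Cys>Ser")
})

test_that("intergenic sites and reference mismatches are handled", {
  ms <- model_set(tiny_genome())
  a <- annotate_variant(list(chrom = "1", pos = 3, ref = "C", alt = "T"), ms)
  expect_equal(a$consequence, "intergenic")
  expect_true(is.na(a$gene_id))
  expect_error(
    annotate_variant(list(chrom = "1", pos = 15, ref = "T", alt = "C"), ms),
    "reference mismatch at 1:15")
})

test_that("gene models load from written GFF3 + FASTA and translate cleanly", {
  g <- simulate_genome(n_genes = 12, gene_length = 90, chrom_length = 4000,
                       n_chroms = 2, seed = 31)
  fa <- tempfile(fileext = ".fa"); gff <- tempfile(fileext = ".gff3")
  write_genome(g, fa, gff)
  expect_no_warning(ms <- load_gene_models(gff, fa))
  expect_length(ms$models, 12)
  for (m in ms$models) {
    expect_equal(m$cds_len %% 3L, 0L)
    cds <- breedmark:::cds_sequence(m, ms$reference)
    prot <- as.character(Biostrings::translate(cds))
    # valid ORF: starts with Met, single terminal stop
    expect_match(prot, "^M[^*]*\\*$")
  }
  # strands must agree with the generator's record
  strands <- vapply(ms$models, `[[`, character(1), "strand")
  expect_setequal(unique(strands), c("+", "-"))
})

test_that("transcript with CDS length not divisible by 3 is skipped with a warning", {
  g <- tiny_genome()
  fa <- tempfile(fileext = ".fa"); gff <- tempfile(fileext = ".gff3")
  g$genes <- rbind(g$genes,
                   data.frame(gene_id = "gbad", chrom = "1", start = 50L,
                              end = 59L, strand = "+"))
  write_genome(g, fa, gff)
  expect_warning(ms <- load_gene_models(gff, fa), "not divisible by 3")
  expect_length(ms$models, 2)
})

test_that("codon-local classification equals whole-protein translation (oracle)", {
  set.seed(32)
  g <- simulate_genome(n_genes = 20, gene_length = 150, chrom_length = 6000,
                       n_chroms = 2, seed = 32)
  ms <- model_set(g)
  bases <- c("A", "C", "G", "T")
  n_checked <- 0
  while (n_checked < 200) {
    m <- g$models[[sample.int(length(g$models), 1)]]
    pos <- sample(m$cds$start:m$cds$end, 1)
    refb <- as.character(Biostrings::subseq(g$sequences[[m$chrom]], pos, pos))
    altb <- sample(setdiff(bases, refb), 1)
    got <- annotate_variant(list(chrom = m$chrom, pos = pos, ref = refb,
                                 alt = altb), ms)
    want <- protein_diff_oracle(m, g$sequences, pos, altb)
    expect_equal(got$consequence, want,
                 info = sprintf("%s:%d %s>%s (%s strand)", m$chrom, pos,
                                refb, altb, m$strand))
    n_checked <- n_checked + 1
  }
})

test_that("every variant receives exactly one annotation row (conservation)", {
  set.seed(33)
  g <- simulate_genome(n_genes = 8, gene_length = 90, chrom_length = 3000,
                       n_chroms = 2, seed = 33)
  sc <- simulation_scenario(n_sites = 60, n_planted_per_breed = 5,
                            missing_rate = 0, seed = 33)
  sim <- simulate_panel(sc, genome = g)
  ann <- annotate_variants(sim$panel, model_set(g))
  expect_equal(nrow(ann), n_variants(sim$panel))
  expect_true(all(ann$consequence %in%
                    c("intergenic", "non_coding_gene_region", "synonymous",
                      "nonsynonymous", "stop_gained", "stop_lost")))
})

test_that("breed-specific nsSNP filtering follows planted truth", {
  g <- simulate_genome(n_genes = 16, gene_length = 120, chrom_length = 5000,
                       n_chroms = 2, seed = 34)
  sc <- simulation_scenario(n_sites = 150, n_planted_per_breed = 10,
                            missing_rate = 0, seed = 34)
  sim <- simulate_panel(sc, genome = g)
  pp <- place_planted_variants(sim$panel, sim$truth, g,
                               fraction_nonsynonymous = 0.5)
  ann <- annotate_variants(pp$panel, model_set(g))
  cfgs <- native_breed_configs(breeds(sim$popmap), "KWB", c("JNP", "KNP"))
  for (b in c("JNP", "KNP", "KWB")) {
    calls <- classify_panel(pp$panel, sim$popmap, cfgs[[b]])
    ns <- breed_specific_nssnps(calls, ann)
    truth_b <- pp$truth$planted[pp$truth$planted$target_breed == b, ]
    want <- truth_b$key[truth_b$category == "nonsynonymous"]
    # incidental drift-specific sites may add extras; all planted ns sites
    # must be present and no planted synonymous site may appear
    expect_true(all(want %in% variant_keys(ns)))
    expect_false(any(truth_b$key[truth_b$category == "synonymous"] %in%
                       variant_keys(ns)))
  }
  expect_equal(nrow(breed_specific_nssnps(
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0)), ann)), 0L)
})

test_that("genes_hit de-duplicates and respects its mode", {
  ms <- model_set(tiny_genome())
  calls <- data.frame(chrom = "1", pos = c(14L, 15L, 3L),
                      ref = c("A", "G", "C"), alt = c("T", "C", "T"),
                      stringsAsFactors = FALSE)
  ann <- annotate_variants(calls, ms)
  expect_equal(genes_hit(calls, ann, mode = "nssnp"), "gplus")
  expect_equal(genes_hit(calls, ann, mode = "all"), "gplus")
  inter <- calls[3, , drop = FALSE]
  expect_equal(genes_hit(inter, annotate_variants(inter, ms),
                         mode = "nssnp"), character(0))
  expect_error(genes_hit(calls, ann[1:2, ], mode = "all"), "unannotated")
})
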