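# Independent oracles and fixture builders. These deliberately avoid the
# code paths they check: brute-force enumeration, direct log-factorial
# formulas, whole-protein translation.

# --- panel builders ---------------------------------------------------------

# per-site genotype vectors (length n_samples, NA for missing) -> panel
toy_panel <- function(sites, samples = NULL, chrom = "1") {
  m <- length(sites)
  n <- length(sites[[1]])
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(n))
  g <- do.call(cbind, lapply(sites, as.integer))
  refalt <- c("A", "C", "G", "T")
  variants <- data.frame(chrom = chrom, pos = seq_len(m) * 100L, id = ".",
                         ref = refalt[(seq_len(m) - 1L) %% 4L + 1L],
                         alt = refalt[seq_len(m) %% 4L + 1L],
                         stringsAsFactors = FALSE)
  genotype_panel(g, variants, samples)
}

random_panel <- function(n_samples, n_sites, missing_rate = 0.1,
                         n_chrom = 2L) {
  g <- matrix(sample(0:2, n_samples * n_sites, replace = TRUE),
              nrow = n_samples)
  g[matrix(runif(length(g)) < missing_rate, nrow = n_samples)] <- NA_integer_
  chrom <- sort(sample(as.character(seq_len(n_chrom)), n_sites,
                       replace = TRUE))
  pos <- unlist(lapply(split(seq_len(n_sites), chrom), function(ix)
    sort(sample.int(1e6L, length(ix)))), use.names = FALSE)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L),
                character(1), USE.NAMES = FALSE)
  id <- ifelse(runif(n_sites) < 0.3,
               paste0("rs", sample.int(1e7L, n_sites)), ".")
  genotype_panel(g, data.frame(chrom = chrom, pos = pos, id = id, ref = ref,
                               alt = alt, stringsAsFactors = FALSE),
                 sprintf("s%03d", seq_len(n_samples)))
}

# breed-structured panel from a named list: breed -> list of per-site
# genotype vectors; all breeds must list the same number of sites
breed_panel <- function(by_breed) {
  breed_labels <- names(by_breed)
  n_per <- vapply(by_breed, function(b) length(b[[1]]), integer(1))
  m <- length(by_breed[[1]])
  sites <- lapply(seq_len(m), function(s)
    unlist(lapply(by_breed, function(b) b[[s]]), use.names = FALSE))
  samples <- unlist(lapply(breed_labels, function(b)
    sprintf("%s_%d", b, seq_len(n_per[[b]]))), use.names = FALSE)
  panel <- toy_panel(sites, samples)
  popmap <- pop_map(samples, rep(breed_labels, n_per))
  list(panel = panel, popmap = popmap)
}

# sample one element of a vector (avoids R's scalar-range sample() trap)
sample1 <- function(v) v[sample.int(length(v), 1L)]

# --- statistical oracles ----------------------------------------------------

# exact HWE p-value by direct enumeration of all heterozygote counts
# conditional on the allele counts (log-factorial multinomial formula)
hwe_enum_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2L * n_aa + n_ab
  n_b <- 2L * n - n_a
  rare <- min(n_a, n_b)
  if (rare == 0L) return(1)
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  logp <- vapply(hets, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- (max(n_a, n_b) - h) / 2
    lfactorial(n) - lfactorial(hom_r) - lfactorial(h) - lfactorial(hom_c) +
      h * log(2) + lfactorial(n_a) + lfactorial(n_b) - lfactorial(2 * n)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_ab, hets)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-10)]))
}

# upper-tail hypergeometric by explicit summation of PMF terms
hyper_sum_p <- function(count, list_total, pop_hits, pop_total) {
  js <- count:min(list_total, pop_hits)
  sum(exp(lchoose(pop_hits, js) + lchoose(pop_total - pop_hits,
                                          list_total - js) -
            lchoose(pop_total, list_total)))
}

# allele frequency by flat per-allele enumeration
allele_freq_enum <- function(genos) {
  alleles <- unlist(lapply(genos, function(g) {
    if (is.na(g)) character(0)
    else c(rep("alt", g), rep("ref", 2L - g))
  }))
  if (!length(alleles)) return(list(freq = NA_real_, n = 0L))
  list(freq = mean(alleles == "alt"), n = length(alleles))
}

# --- effects oracle ---------------------------------------------------------

# classify a coding SNV by full-CDS substitution and whole-protein
# translation (independent of the codon-local path)
protein_diff_oracle <- function(model, reference, pos, alt) {
  chrom_seq <- reference[[model$chrom]]
  parts <- lapply(seq_len(nrow(model$cds)), function(i)
    as.character(Biostrings::subseq(chrom_seq, model$cds$start[i],
                                    model$cds$end[i])))
  cds <- paste(parts, collapse = "")
  cum <- c(0L, cumsum(model$cds$end - model$cds$start + 1L))
  hit <- which(pos >= model$cds$start & pos <= model$cds$end)
  off <- cum[hit] + pos - model$cds$start[hit] + 1L
  alt_cds <- cds
  substr(alt_cds, off, off) <- alt
  to_prot <- function(s) {
    if (model$strand == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    as.character(Biostrings::translate(Biostrings::DNAString(s),
                                       no.init.codon = TRUE))
  }
  p_ref <- to_prot(cds)
  p_alt <- to_prot(alt_cds)
  if (p_ref == p_alt) return("synonymous")
  d <- which(strsplit(p_ref, "")[[1]] != strsplit(p_alt, "")[[1]])
  aa_ref <- substr(p_ref, d, d)
  aa_alt <- substr(p_alt, d, d)
  if (aa_alt == "*") "stop_gained"
  else if (aa_ref == "*") "stop_lost"
  else "nonsynonymous"
}
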