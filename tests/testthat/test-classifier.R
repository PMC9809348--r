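two_breed <- function(obj, bg) {
  breed_panel(list(OBJ = list(obj), BG = list(bg)))
}

test_that("population allele frequency excludes missing alleles from the denominator", {
  bp <- breed_panel(list(A = list(c(2, 2, 2)), B = list(c(0, 1, NA))))
  expect_equal(population_allele_freq(bp$panel, bp$popmap, "A", 1),
               list(alt_freq = 1.0, n_called = 6L))
  expect_equal(population_allele_freq(bp$panel, bp$popmap, "B", 1),
               list(alt_freq = 1 / 4, n_called = 4L))
  expect_error(population_allele_freq(bp$panel, bp$popmap, "ZZ", 1),
               "unknown breed")

  set.seed(21)
  for (i in 1:15) {
    genos <- sample(c(0:2, NA), 12, replace = TRUE)
    bp <- breed_panel(list(A = list(genos[1:7]), B = list(genos[8:12])))
    got <- population_allele_freq(bp$panel, bp$popmap, "A", 1)
    oracle <- allele_freq_enum(genos[1:7])
    expect_equal(got$n_called, oracle$n)
    if (oracle$n == 0) expect_true(is.na(got$alt_freq))
    else expect_equal(got$alt_freq, oracle$freq)
  }
})

test_that("both orientations classify and the 0.9 boundary is strict", {
  cfg <- breed_specific_config("OBJ", "BG", threshold = 0.9)
  # object fixed alt, background fixed ref
  bp <- two_breed(rep(2, 5), rep(0, 10))
  call <- classify_site(bp$panel, bp$popmap, cfg, 1)
  expect_true(call$is_specific)
  expect_equal(call$specific_allele, "alt")
  expect_equal(call$object_freq, 1.0)
  expect_equal(call$background_freq, 1.0)

  # vice versa: object fixed ref, background fixed alt
  bp <- two_breed(rep(0, 5), rep(2, 10))
  call <- classify_site(bp$panel, bp$popmap, cfg, 1)
  expect_true(call$is_specific)
  expect_equal(call$specific_allele, "ref")

  # object alt frequency exactly 0.9 -> not specific (strict >)
  bp <- two_breed(c(rep(2, 4), 1), rep(0, 10))  # 9/10 alleles alt
  call <- classify_site(bp$panel, bp$popmap, cfg, 1)
  expect_equal(call$object_freq, 0.9)
  expect_false(call$is_specific)

  # undefined object frequency -> never specific
  bp <- two_breed(rep(NA, 5), rep(0, 10))
  call <- classify_site(bp$panel, bp$popmap, cfg, 1)
  expect_false(call$is_specific)
  expect_true(call$low_confidence)
})

test_that("with 6 diploid samples the >0.9 rule equals the >=11-of-12-alleles integer rule", {
  cfg <- breed_specific_config("OBJ", "BG", threshold = 0.9)
  for (alt_alleles in 0:12) {
    genos <- c(rep(2, alt_alleles %/% 2), rep(1, alt_alleles %% 2))
    genos <- c(genos, rep(0, 6 - length(genos)))
    bp <- two_breed(genos, rep(0, 10))
    call <- classify_site(bp$panel, bp$popmap, cfg, 1)
    expect_equal(call$is_specific, alt_alleles >= 11,
                 info = paste("alt alleles:", alt_alleles))
  }
})

test_that("no site is simultaneously ref- and alt-specific above threshold 0.5 (property)", {
  set.seed(22)
  cfg <- breed_specific_config("A", "B", threshold = 0.6)
  for (i in 1:10) {
    g <- matrix(sample(c(0:2, NA), 12 * 30, replace = TRUE,
                       prob = c(.4, .1, .4, .1)), nrow = 12)
    bp <- breed_panel(list(
      A = lapply(seq_len(30), function(s) g[1:5, s]),
      B = lapply(seq_len(30), function(s) g[6:12, s])))
    res <- classify_panel(bp$panel, bp$popmap, cfg)
    expect_equal(res$summary$n_alt_specific + res$summary$n_ref_specific,
                 res$summary$n_specific)
    oa <- population_allele_freq(bp$panel, bp$popmap, "A")$alt_freq
    ba <- population_allele_freq(bp$panel, bp$popmap, "B")$alt_freq
    alt_spec <- !is.na(oa) & !is.na(ba) & oa > 0.6 & (1 - ba) > 0.6
    ref_spec <- !is.na(oa) & !is.na(ba) & (1 - oa) > 0.6 & ba > 0.6
    expect_false(any(alt_spec & ref_spec))
    expect_equal(res$calls$is_specific, alt_spec | ref_spec)
  }
})

test_that("removing a majority-allele background sample never revokes specificity (property)", {
  set.seed(23)
  cfg <- breed_specific_config("OBJ", "BG")
  for (i in 1:20) {
    obj <- sample(0:2, 6, replace = TRUE, prob = c(.05, .05, .9))
    bg <- sample(0:2, 12, replace = TRUE, prob = c(.95, .03, .02))
    bp <- two_breed(obj, bg)
    before <- classify_site(bp$panel, bp$popmap, cfg, 1)
    if (!before$is_specific) next
    maj_hom <- which(bg == if (before$specific_allele == "alt") 0 else 2)
    if (!length(maj_hom)) next
    bg2 <- bg
    bg2[maj_hom[1]] <- NA
    bp2 <- two_breed(obj, bg2)
    after <- classify_site(bp2$panel, bp2$popmap, cfg, 1)
    expect_true(after$is_specific)
  }
})

test_that("native breed configurations exclude the wild ancestor from native backgrounds", {
  all8 <- c("JNP", "KNP", "KWB", "BKS", "DUR", "LDR", "YKS", "YMP")
  cfgs <- native_breed_configs(all8, wild_breed = "KWB",
                               natives = c("JNP", "KNP"))
  expect_setequal(cfgs$JNP$background_breeds,
                  c("KNP", "BKS", "DUR", "LDR", "YKS", "YMP"))
  expect_setequal(cfgs$KNP$background_breeds,
                  c("JNP", "BKS", "DUR", "LDR", "YKS", "YMP"))
  expect_setequal(cfgs$KWB$background_breeds,
                  c("JNP", "KNP", "BKS", "DUR", "LDR", "YKS", "YMP"))
  expect_equal(cfgs$JNP$exclude_from_background, "KWB")
  expect_error(native_breed_configs(all8, "KWB", c("JNP", "KWB")),
               "native")
  expect_error(breed_specific_config("A", c("A", "B")), "target")
  expect_error(breed_specific_config("A", "B", threshold = 0.5),
               "threshold")
})

test_that("Venn region counts follow set algebra", {
  mk <- function(keys) {
    if (!length(keys)) return(data.frame(chrom = character(0),
                                         pos = integer(0),
                                         ref = character(0),
                                         alt = character(0)))
    parts <- do.call(rbind, strsplit(keys, ":"))
    data.frame(chrom = parts[, 1], pos = as.integer(parts[, 2]),
               ref = parts[, 3], alt = parts[, 4],
               stringsAsFactors = FALSE)
  }
  k <- function(i) sprintf("1:%d:A:T", i)
  ov <- overlap_sets(list(X = mk(k(1:4)), Y = mk(k(3:6))))
  counts <- setNames(ov$count, ov$region)
  expect_equal(counts[["X"]], 2L)
  expect_equal(counts[["Y"]], 2L)
  expect_equal(counts[["X&Y"]], 2L)
  expect_equal(attr(ov, "union_size"), 6L)
  expect_equal(sum(ov$count), attr(ov, "union_size"))

  # identical lists: everything in the intersection
  ov2 <- overlap_sets(list(X = mk(k(1:5)), Y = mk(k(1:5))))
  expect_equal(setNames(ov2$count, ov2$region)[["X&Y"]], 5L)

  # random 3-way vs brute-force set algebra
  set.seed(24)
  for (i in 1:5) {
    sets <- lapply(1:3, function(j) sample(k(1:30), sample(5:20, 1)))
    names(sets) <- c("A", "B", "C")
    ov3 <- overlap_sets(lapply(sets, mk))
    counts <- setNames(ov3$count, ov3$region)
    inA <- k(1:30) %in% sets$A; inB <- k(1:30) %in% sets$B
    inC <- k(1:30) %in% sets$C
    expect_equal(counts[["A&B&C"]], sum(inA & inB & inC))
    expect_equal(counts[["A&B"]], sum(inA & inB & !inC))
    expect_equal(counts[["A"]], sum(inA & !inB & !inC))
    expect_equal(sum(ov3$count), sum(inA | inB | inC))
  }
})
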