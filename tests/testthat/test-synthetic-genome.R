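# generator: divergence structure, determinism, annotation conservation, reads

test_that("invalid specs fail naming the offending field", {
  expect_error(genome_spec(duplicated_subgenome = "ZZ"), "duplicated_subgenome")
  expect_error(genome_spec(haplotype_divergence = 0.8), "haplotype_divergence")
  expect_error(genome_spec(subgenome_divergence = c(S1 = 0.9, S2 = 0.01,
                                                    R3 = 0.01, R4 = 0.01)),
               "subgenome_divergence")
  expect_error(genome_spec(centromere_fraction = 0.6), "centromere_fraction")
  expect_error(genome_spec(cenltr_monomer_length = 1000), "cenltr_monomer_length")
})

test_that("haplotype and subgenome divergences land in the stated bands", {
  b <- small_bundle()
  # h1/h2 identity 0.995 +/- 0.001 over non-repeat (arm) space
  for (lg in c(1, 4)) {
    id <- arm_identity(b, paste0("Rca", lg, "_S1_h1"), paste0("Rca", lg, "_S1_h2"))
    expect_gt(id, 0.994)
    expect_lt(id, 0.996)
  }
  # distinct subgenomes within the 93-98.5% band
  pairs <- list(c("Rca1_S1_h1", "Rca1_S2"), c("Rca1_S2", "Rca1_R3"),
                c("Rca1_R3", "Rca1_R4"), c("Rca1_S1_h1", "Rca1_R4"))
  for (p in pairs) {
    id <- arm_identity(b, p[1], p[2])
    expect_gt(id, 0.93)
    expect_lt(id, 0.985)
  }
})

test_that("zero divergence gives identical chromosome copies", {
  spec <- genome_spec(seed = 3, chromosome_length = 2e4, n_sco_loci = 0,
                      haplotype_divergence = 0,
                      subgenome_divergence = c(S1 = 0, S2 = 0, R3 = 0, R4 = 0),
                      centromere_plan = list(S1 = "CANR4", S2 = "CANR4",
                                             R3 = "CANR4", R4 = "CANR4"),
                      linkage_groups = 2L)
  b <- generate_pentaploid(spec)
  # identical arms across all five copies of a linkage group (centromere
  # content is drawn per copy and may differ)
  arms <- vapply(grep("^Rca1_", names(b$sequences), value = TRUE), function(ch)
    substring(as.character(b$sequences[[ch]]), 1, 9000), character(1))
  expect_true(all(arms == arms[1]))
})

test_that("the same seed reproduces the bundle, reads and tracks bit-identically", {
  spec <- small_spec(seed = 19)
  b1 <- generate_pentaploid(spec)
  b2 <- generate_pentaploid(spec)
  expect_identical(as.character(b1$sequences), as.character(b2$sequences))
  expect_identical(b1$repeats, b2$repeats)
  expect_identical(b1$truth, b2$truth)
  r1 <- generate_reads(b1, "bivalent", coverage = 5, seed = 4)
  r2 <- generate_reads(b2, "bivalent", coverage = 5, seed = 4)
  expect_identical(r1, r2)
  t1 <- generate_chip_tracks(b1, window_size = 2000, seed = 6)
  t2 <- generate_chip_tracks(b2, window_size = 2000, seed = 6)
  expect_identical(t1, t2)
})

test_that("truth composition is conserved in the emitted annotation", {
  b <- small_bundle()
  ct <- b$truth$centromere_truth
  for (i in seq_len(nrow(ct))) {
    feats <- b$repeats[b$repeats$chrom == ct$chrom[i], ]
    expect_equal(sum(feats$end[feats$family == "ATHILA"] -
                       feats$start0[feats$family == "ATHILA"]), ct$athila_bp[i])
    expect_equal(sum(feats$end[feats$family == "CANR4"] -
                       feats$start0[feats$family == "CANR4"]), ct$canr4_bp[i])
  }
  # every truth interval lies inside its chromosome; SCO truth has 5
  # placements per locus, all in one linkage group
  expect_true(all(ct$start0 >= 0 & ct$end <= b$spec$chromosome_length))
  st <- b$truth$sco_truth
  per_locus <- split(st, st$locus_id)
  expect_true(all(vapply(per_locus, nrow, integer(1)) == 5L))
  expect_true(all(vapply(per_locus, function(df)
    length(unique(df$linkage_group)) == 1L, logical(1))))
})

test_that("ATHILA LTR pairs diverge as their planted age implies", {
  b <- small_bundle()
  pairs <- ltr_pairs_from_bundle(b)
  tr <- b$truth$ltr_truth
  ix <- match(pairs$element_id, tr$element_id)
  expect_false(anyNA(ix))
  r <- b$spec$ltr_rate
  # expected differing sites under JC69 on two branches of length r*T
  p_exp <- 0.75 * (1 - exp(-8 * r * tr$age_years[ix] / 3))
  mean_m <- pairs$aligned_length * p_exp
  tol <- 4 * sqrt(mean_m)   # ~Poisson(2 r T L) spread
  expect_true(all(abs(pairs$mismatches - mean_m) <= pmax(tol, 5)))
})

test_that("read sources honour their selectors", {
  b <- small_bundle()
  # pollen: bivalent subgenome only
  rb <- generate_reads(b, "bivalent", coverage = 2, seed = 3)
  expect_true(all(b$genome_map$subgenome[match(rb$chrom, b$genome_map$chrom)] == "S1"))
  # error-free reads are exact substrings of their source
  r0 <- generate_reads(b, "bivalent", coverage = 0.5, error_rate = 0, seed = 5)
  idx <- seq(1, nrow(r0), length.out = 25)
  for (i in idx) {
    expect_identical(r0$seq[i],
                     substring(as.character(b$sequences[[r0$chrom[i]]]),
                               r0$start0[i] + 1, r0$end[i]))
  }
  # empty selector errors
  expect_error(generate_reads(b, "dosage", dosage = NULL), "dosage")
  expect_error(generate_reads(b, "dosage", dosage = c(S1 = 0, S2 = 0, R3 = 0, R4 = 0)),
               "empty")
})

test_that("dosage-mode reads scale with subgenome copy number", {
  b <- small_bundle()
  reads <- generate_reads(b, "dosage", dosage = c(S1 = 1, S2 = 1, R3 = 1, R4 = 2),
                          coverage = 30, seed = 9)
  sg <- b$genome_map$subgenome[match(reads$chrom, b$genome_map$chrom)]
  bases <- tapply(reads$end - reads$start0, sg, sum)
  ratio <- bases[["R4"]] / bases[["S2"]]
  expect_gte(ratio, 1.8)
  expect_lte(ratio, 2.2)
  # realized coverage within 10% of requested at >= 20x
  cov_s2 <- bases[["S2"]] / (7 * b$spec$chromosome_length)
  expect_lt(abs(cov_s2 - 30) / 30, 0.1)
})

test_that("ChIP tracks are exact in noiseless mode and composition-coupled by default", {
  b <- small_bundle()
  tr <- generate_chip_tracks(b, window_size = 2500, snr = 8, noise_sd = 0,
                             canr4_boost = 0, seed = 2)
  enr <- enrichment_track(tr$cenh3, tr$h3, normalize = "none",
                          pseudocount = 1e-9)
  ct <- b$truth$centromere_truth
  ix <- match(enr$chrom, ct$chrom)
  inside <- enr$start0 >= ct$start0[ix] & enr$end <= ct$end[ix]
  outside <- enr$end <= ct$start0[ix] | enr$start0 >= ct$end[ix]
  expect_true(all(abs(enr$value[inside] - 3) < 1e-6))
  expect_true(all(abs(enr$value[outside]) < 1e-6))
  # raw CENH3/H3 ratio >= snr/2 inside, ~1 outside
  ratio <- tr$cenh3$value / tr$h3$value
  expect_true(all(ratio[inside] >= 4))
  expect_true(all(abs(ratio[outside] - 1) < 1e-6))
  # composition coupling: CANR4 centromeres carry more CENH3 mass than ATHILA
  trc <- generate_chip_tracks(b, window_size = 2500, snr = 8, noise_sd = 0,
                              seed = 2)
  mass <- function(cls) {
    sel <- ct$class == cls
    mean(vapply(which(sel), function(i) {
      w <- trc$cenh3$chrom == ct$chrom[i] & trc$cenh3$start0 >= ct$start0[i] &
        trc$cenh3$end <= ct$end[i]
      sum(trc$cenh3$value[w])
    }, numeric(1)))
  }
  expect_gt(mass("CANR4-based"), mass("ATHILA-based"))
  expect_error(generate_chip_tracks(b, snr = 0.5), "snr")
})
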