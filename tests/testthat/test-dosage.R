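# hybrid dosage: windowed coverage, copy-number calls, parent-unique SNPs

test_that("windowed coverage is exact mean depth with half-open windows", {
  lens <- c(chrA = 2500L)
  # one 150 bp read fully inside the first 1 kb window
  aln <- data.frame(chrom = "chrA", start0 = 100L, end = 250L)
  tr <- window_coverage(aln, lens, window_size = 1000L)
  expect_equal(tr$depth, c(150 / 1000, 0, 0))
  expect_equal(tr$start0, c(0L, 1000L, 2000L))
  expect_equal(tr$end, c(1000L, 2000L, 2500L))   # last window short
  # empty alignments: all zeros
  tr0 <- window_coverage(aln[0, ], lens, window_size = 1000L)
  expect_equal(tr0$depth, c(0, 0, 0))
  # unsorted input errors
  bad <- data.frame(chrom = "chrA", start0 = c(500L, 100L), end = c(650L, 250L))
  expect_error(window_coverage(bad, lens, 1000L), "unsorted")
})

test_that("windowed coverage conserves total mapped bases", {
  b <- small_bundle()
  reads <- generate_reads(b, "bivalent", coverage = 3, error_rate = 0, seed = 12)
  reads <- reads[order(reads$chrom, reads$start0), ]
  chroms <- unique(reads$chrom)
  lens <- stats::setNames(rep(b$spec$chromosome_length, length(chroms)), chroms)
  tr <- window_coverage(reads, lens, window_size = 5000L)
  expect_equal(sum(tr$depth * (tr$end - tr$start0)),
               sum(reads$end - reads$start0))
  # uniform simulation: genome-wide mean within 5% of requested
  expect_lt(abs(mean(tr$depth) - 3) / 3, 0.05)
})

test_that("dosage calling rounds median ratios against the 1x baseline", {
  map <- data.frame(chrom = paste0("c", 1:4),
                    subgenome = c("S1", "S2", "R3", "R4"), length = 1000L)
  mk_track <- function(depths) {
    do.call(rbind, lapply(seq_along(depths), function(i)
      data.frame(chrom = map$chrom[i], start0 = seq(0, 900, 100),
                 end = seq(100, 1000, 100), depth = depths[i])))
  }
  call <- call_dosage(mk_track(c(30, 30, 30, 60)), map, baseline = c("S2", "R3"))
  expect_equal(stats::setNames(call$copy_number, call$subgenome),
               c(R3 = 1L, R4 = 2L, S1 = 1L, S2 = 1L))
  expect_true(all(call$confident))
  # all equal: all 1
  expect_true(all(call_dosage(mk_track(rep(25, 4)), map,
                              baseline = "S2")$copy_number == 1L))
  # zero baseline errors
  expect_error(call_dosage(mk_track(c(30, 0, 0, 60)), map,
                           baseline = c("S2", "R3")), "baseline")
  # off-integer ratio loses confidence
  call2 <- call_dosage(mk_track(c(30, 30, 30, 45)), map, baseline = c("S2", "R3"))
  expect_false(call2$confident[call2$subgenome == "R4"])
})

test_that("parent-unique SNPs follow symmetric-difference semantics", {
  p1 <- data.frame(chrom = "c1", pos0 = c(10L, 20L, 30L), ref = "A",
                   alt = c("T", "G", "C"))
  p2 <- data.frame(chrom = "c1", pos0 = c(20L, 40L), ref = "A", alt = c("G", "T"))
  u <- parent_unique_snps(p1, p2, labels = c("mother", "father"))
  expect_equal(u$pos0[u$parent == "mother"], c(10L, 30L))
  expect_equal(u$pos0[u$parent == "father"], 40L)
  # identical sets: empty
  expect_equal(nrow(parent_unique_snps(p1, p1)), 0L)
  # disjoint sets: everything retained
  expect_equal(nrow(parent_unique_snps(p1, data.frame(chrom = "c2", pos0 = 1L,
                                                      ref = "A", alt = "G"))), 4L)
  # symmetric under parent swap
  u2 <- parent_unique_snps(p2, p1, labels = c("father", "mother"))
  key <- function(df) sort(paste(df$chrom, df$pos0, df$alt, df$parent))
  expect_equal(key(u), key(u2))
  # conflicting alleles at one position within a parent: flagged, warned
  p3 <- data.frame(chrom = "c1", pos0 = c(5L, 5L), ref = "A", alt = c("T", "G"))
  expect_warning(u3 <- parent_unique_snps(p3, p2), "multi-allelic")
  expect_true(all(u3$multi_allelic[u3$pos0 == 5L]))
})

test_that("SNP contribution counts observed parent-unique alleles", {
  snps <- data.frame(chrom = "c1", pos0 = c(10L, 20L, 30L), ref = "A",
                     alt = c("T", "G", "C"),
                     parent = c("mother", "mother", "father"))
  reads <- data.frame(chrom = "c1", start0 = c(0L, 0L, 15L),
                      end = c(50L, 50L, 60L),
                      seq = c(paste(rep("T", 50), collapse = ""),
                              paste(rep("T", 50), collapse = ""),
                              paste(rep("A", 45), collapse = "")))
  pu <- pileup_at(reads, snps[, c("chrom", "pos0")])
  rep_ <- snp_contribution(pu, snps, min_depth = 1L)
  m <- rep_[rep_$parent == "mother", ]
  expect_equal(m$observed, 1L)   # T at pos 10 observed; G at 20 not
  expect_equal(m$fraction, 0.5)
  f <- rep_[rep_$parent == "father", ]
  expect_equal(f$observed, 0L)
  expect_error(snp_contribution(pu, snps[0, ]), "empty")
  # depth below threshold everywhere: error
  expect_error(snp_contribution(pu[0, ], snps), "depth")
})

test_that("a clone of one parent shows full/zero parental fractions", {
  b <- small_bundle()
  chrom <- "Rca1_S1_h1"
  # plant private SNPs: mother's differ from the reference on h1, father's on S2
  sqs <- as.character(b$sequences[[chrom]])
  pos <- c(1000L, 3000L, 5000L, 7000L)
  other <- function(x) chartr("ACGT", "CGTA", x)
  mother <- data.frame(chrom = chrom, pos0 = pos,
                       ref = substring(sqs, pos + 1, pos + 1),
                       alt = other(substring(sqs, pos + 1, pos + 1)))
  father <- data.frame(chrom = chrom, pos0 = pos + 200L,
                       ref = substring(sqs, pos + 201, pos + 201),
                       alt = other(substring(sqs, pos + 201, pos + 201)))
  u <- parent_unique_snps(mother, father, labels = c("mother", "father"))
  # hybrid = clone of mother: reads carry the mother alt at her positions
  mseq <- strsplit(sqs, "")[[1]]
  mseq[pos + 1] <- mother$alt
  reads <- data.frame(chrom = chrom,
                      start0 = rep(pos - 50L, each = 3) + c(-20L, 0L, 20L))
  reads$end <- reads$start0 + 120L
  reads$seq <- substring(paste(mseq, collapse = ""), reads$start0 + 1, reads$end)
  reads2 <- reads
  reads2$start0 <- reads$start0 + 200L
  reads2$end <- reads$end + 200L
  reads2$seq <- substring(paste(mseq, collapse = ""), reads2$start0 + 1, reads2$end)
  pu <- pileup_at(rbind(reads, reads2), u[, c("chrom", "pos0")])
  rep_ <- snp_contribution(pu, u, min_depth = 1L)
  expect_equal(rep_$fraction[rep_$parent == "mother"], 1)
  expect_equal(rep_$fraction[rep_$parent == "father"], 0)
})

test_that("hybrid coverage recovers the planted dosage for both crosses", {
  b <- small_bundle()
  # canina (S1-bivalent) mother x rubiginosa (R4) father
  d1 <- predict_hybrid_dosage(canina_karyotype(), rubiginosa_karyotype())
  r1 <- run_hybrid_dosage(b, d1, window_size = 5000L, seed = 51)
  expect_equal(stats::setNames(r1$call$copy_number, r1$call$subgenome),
               c(R3 = 1L, R4 = 2L, S1 = 1L, S2 = 1L))
  expect_true(all(r1$call$confident))
  # reciprocal cross: rubiginosa mother x corymbifera (S1) father
  d2 <- predict_hybrid_dosage(rubiginosa_karyotype(), corymbifera_karyotype())
  r2 <- run_hybrid_dosage(b, d2, window_size = 5000L, seed = 52)
  expect_equal(stats::setNames(r2$call$copy_number, r2$call$subgenome),
               c(R3 = 1L, R4 = 1L, S1 = 2L, S2 = 1L))
})
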