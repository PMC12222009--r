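# centromere calling, composition classes, regression, metaplots, methylation

mk_track <- function(values, chrom = "c1", win = 1000L) {
  n <- length(values)
  data.frame(chrom = chrom, start0 = seq(0L, by = win, length.out = n),
             end = seq(win, by = win, length.out = n), value = values)
}

test_that("enrichment track is the normalized windowed log2 ratio", {
  a <- mk_track(rep(4, 10)); b <- mk_track(rep(4, 10))
  expect_equal(enrichment_track(a, b)$value, rep(0, 10))
  # 8-fold region gives value 3 with negligible pseudocount, no normalization
  a2 <- mk_track(c(rep(1, 8), 8, 8))
  b2 <- mk_track(rep(1, 10))
  e <- enrichment_track(a2, b2, pseudocount = 1e-9, normalize = "none")
  expect_equal(e$value[9:10], c(3, 3), tolerance = 1e-6)
  # window mismatch errors
  expect_error(enrichment_track(a2[1:5, ], b2), "mismatch")
})

test_that("centromere calling spans merged peak runs around the argmax", {
  # single noiseless block (5% of the chromosome): interval recovered exactly
  v <- c(rep(0, 50), rep(3, 5), rep(0, 45))
  cc <- call_centromere(mk_track(v), k = 2, merge_gap = 3000L)
  expect_true(cc$found)
  expect_equal(cc$start0, 50000L)
  expect_equal(cc$end, 55000L)
  expect_equal(cc$cenh3_abundance, 15)
  # two peaks separated by less than merge_gap: one interval 5' to 3'
  v2 <- c(rep(0, 10), 3, 3, 0, 0, 3, 3, rep(0, 10))
  cc2 <- call_centromere(mk_track(v2), k = 1, merge_gap = 3000L)
  expect_equal(cc2$start0, 10000L)
  expect_equal(cc2$end, 16000L)
  # beyond merge_gap: only the cluster holding the global max
  v3 <- c(rep(0, 10), 3, 3.5, rep(0, 8), 3, rep(0, 10))
  cc3 <- call_centromere(mk_track(v3), k = 1, merge_gap = 2000L)
  expect_equal(cc3$start0, 10000L)
  expect_equal(cc3$end, 12000L)
  # flat track: no centromere, reported not fatal
  cc4 <- call_centromere(mk_track(rep(0, 30)))
  expect_false(cc4$found)
  expect_true(is.na(cc4$start0))
})

test_that("the called interval always contains the enrichment argmax", {
  set.seed(99)
  for (i in 1:20) {
    v <- rnorm(60)
    v[25:30] <- v[25:30] + runif(1, 3, 8)
    cc <- call_centromere(mk_track(v), k = 2, merge_gap = 5000L)
    if (!cc$found) next
    expect_gte(cc$max_position, cc$start0)
    expect_lt(cc$max_position, cc$end)
  }
})

test_that("repeat composition clips and merges annotation", {
  iv <- data.frame(chrom = "c1", start0 = 100000L, end = 700000L,
                   length = 600000L, found = TRUE)
  reps <- data.frame(chrom = "c1",
                     start0 = c(150000L, 650000L, 10000L),
                     end = c(650000L, 750000L, 20000L),
                     family = c("CANR4", "ATHILA", "cenLTR1"))
  out <- repeat_composition(iv, reps)
  expect_equal(out$canr4_bp, 500000L)
  expect_equal(out$athila_bp, 50000L)   # half-overlapping feature clipped
  expect_equal(out$cenltr_bp, 0L)       # outside the interval
  # splitting a feature does not change the result
  reps_split <- rbind(reps,
                      data.frame(chrom = "c1", start0 = 150000L, end = 400000L,
                                 family = "CANR4"))
  expect_equal(repeat_composition(iv, reps_split)$canr4_bp, 500000L)
})

test_that("classification follows the satellite/array/retrotransposon rule", {
  prof <- data.frame(chrom = "c1", length = 1000000L, canr4_bp = 800000L,
                     athila_bp = 0L, cenltr_bp = 0L)
  expect_equal(classify_centromere(prof)$class, "CANR4-based")
  # the cenLTR1 array case: no CANR4, 235 kb array
  prof2 <- data.frame(chrom = "c1", length = 1000000L, canr4_bp = 0L,
                      athila_bp = 100000L, cenltr_bp = 235000L)
  expect_equal(classify_centromere(prof2)$class, "cenLTR-based")
  prof3 <- data.frame(chrom = "c1", length = 1000000L, canr4_bp = 0L,
                      athila_bp = 300000L, cenltr_bp = 0L)
  expect_equal(classify_centromere(prof3)$class, "ATHILA-based")
  prof4 <- data.frame(chrom = "c1", length = 1000000L, canr4_bp = 10L,
                      athila_bp = 10L, cenltr_bp = 0L)
  expect_equal(classify_centromere(prof4)$class, "mixed")
  expect_error(classify_centromere(transform(prof, length = 0L)), "zero-length")
})

test_that("the CANR4/CENH3 regression matches closed forms on constructed data", {
  # exactly collinear points
  col <- data.frame(canr4_bp = 1:10 * 1000, cenh3_abundance = 5 + 2 * (1:10))
  r <- canr4_cenh3_regression(col)
  expect_equal(r$r_squared, 1)
  expect_equal(r$spearman_rho, 1)
  expect_equal(r$slope, 2 / 1000)
  # strictly decreasing relation
  dec <- data.frame(canr4_bp = 1:10, cenh3_abundance = exp(-(1:10)))
  expect_equal(canr4_cenh3_regression(dec)$spearman_rho, -1)
  # constant predictor: undefined, reported as missing
  con <- data.frame(canr4_bp = rep(7, 5), cenh3_abundance = rnorm(5))
  expect_message(rc <- canr4_cenh3_regression(con), "constant")
  expect_true(is.na(rc$r_squared))
  expect_error(canr4_cenh3_regression(col[1:2, ]), "at least 3")
})

test_that("regression equals the normal-equations oracle to 1e-9", {
  b <- cen_bundle()
  res <- run_centromere_analysis(b, seed = 12)
  p <- res$profiles
  x <- p$canr4_bp; y <- p$cenh3_abundance
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  yhat <- X %*% beta
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  expect_equal(res$regression$intercept, beta[1], tolerance = 1e-9)
  expect_equal(res$regression$slope, beta[2], tolerance = 1e-9)
  expect_equal(res$regression$r_squared, r2, tolerance = 1e-9)
})

test_that("metaplots scale arms to [0,1] and mirror symmetric signals", {
  map <- data.frame(chrom = "c1", subgenome = "S1", length = 60000L)
  cc <- data.frame(chrom = "c1", start0 = 28000L, end = 32000L,
                   max_position = 30000L, found = TRUE)
  # constant signal scales to 1 everywhere
  mp <- metaplot(list(sig = mk_track(rep(4, 60))), cc, map, n_bins = 10)
  expect_true(all(mp$profile$value == 1))
  expect_true(all(mp$profile$coord >= 0 & mp$profile$coord <= 1))
  # signal symmetric about the centromere: mirroring is exact, increasing
  v <- c(seq(0, 1, length.out = 30), rev(seq(0, 1, length.out = 30)))
  mp2 <- metaplot(list(sig = mk_track(v)), cc, map, n_bins = 10)
  expect_equal(nrow(mp2$profile), 10L)
  expect_true(all(diff(mp2$profile$value) >= 0))
  # proximity view restricted to the last 10%
  expect_true(all(mp2$proximity$coord >= 0.9))
  expect_error(metaplot(list(s = mk_track(v)), cc, map, n_bins = 1), "n_bins")
  # chromosomes without a call are skipped with a warning
  tr2 <- rbind(mk_track(v), mk_track(v, chrom = "c2"))
  map2 <- rbind(map, data.frame(chrom = "c2", subgenome = "S2", length = 60000L))
  expect_warning(metaplot(list(s = tr2), cc, map2, n_bins = 10), "skipped")
})

test_that("generator CENH3 proximity profile rises toward the centromere", {
  b <- small_bundle()
  res <- run_centromere_analysis(b, window_size = 2500L, merge_gap = 10000L,
                                 min_array = 2000L, seed = 13)
  mp <- metaplot(list(cenh3 = res$enrichment), res$profiles, b$genome_map,
                 n_bins = 20)
  for (sg in unique(mp$profile$subgenome)) {
    prox <- mp$profile[mp$profile$subgenome == sg, ]
    # enrichment peaks in the centromere-adjacent bin and dominates the arm
    expect_equal(prox$bin[which.max(prox$value)], 20L)
    expect_gt(prox$value[prox$bin == 20], max(prox$value[prox$bin <= 16]))
  }
})

test_that("methylation summary computes per-context window percentages", {
  m <- data.frame(chrom = "c1", start0 = c(0L, 1000L, 2000L),
                  end = c(1000L, 2000L, 3000L), context = "CpG",
                  meth = c(200L, 1L, 0L), total = c(200L, 4L, 0L))
  m <- rbind(m, transform(m, context = "CHG"), transform(m, context = "CHH"))
  out <- methylation_summary(m, c(c1 = 3000L), window_size = 1000L)
  cpg <- out[out$context == "CpG", ]
  expect_equal(cpg$pct, c(100, 25, NA))
  # generator: CpG dips inside CANR4 arrays relative to chromosome arms
  b <- small_bundle()
  tracks <- generate_chip_tracks(b, window_size = 1000L, seed = 14)
  ms <- methylation_summary(tracks$methylation, b$genome_map, 1000L)
  ct <- b$truth$centromere_truth
  canr4 <- b$repeats[b$repeats$family == "CANR4", ]
  cpg <- ms[ms$context == "CpG" & !is.na(ms$pct), ]
  in_canr4 <- mapply(function(ch, s, e) any(canr4$chrom == ch & canr4$start0 <= s &
                                              canr4$end >= e),
                     cpg$chrom, cpg$start0, cpg$end)
  ix <- match(cpg$chrom, ct$chrom)
  in_cen <- cpg$start0 >= ct$start0[ix] & cpg$end <= ct$end[ix]
  expect_lt(mean(cpg$pct[in_canr4]), mean(cpg$pct[!in_cen]))
})
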