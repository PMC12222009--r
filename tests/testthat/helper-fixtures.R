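# shared fixtures, built once per test run and cached

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# desk-scale spec: 50 kb chromosomes, 3 SCO loci per linkage group
small_spec <- function(seed = 7L, ...) {
  genome_spec(seed = seed, chromosome_length = 5e4, n_sco_loci = 3L, ...)
}

small_bundle <- function() {
  cached("small_bundle", function() generate_pentaploid(small_spec()))
}

# default-scale bundle for the centromere suite (1 Mb chromosomes, no loci)
cen_bundle <- function() {
  cached("cen_bundle", function()
    generate_pentaploid(genome_spec(seed = 11L, chromosome_length = 1e6,
                                    n_sco_loci = 0L)))
}

# brute-force placement oracle: every start position where the query matches
# the subject chromosome with at most max_mm mismatches (substitution-only)
brute_force_placements <- function(query, sequences, max_mm) {
  out <- list()
  qv <- utf8ToInt(query)
  L <- length(qv)
  for (ch in names(sequences)) {
    sv <- utf8ToInt(as.character(sequences[[ch]]))
    n <- length(sv) - L + 1L
    if (n < 1L) next
    for (s0 in 0:(n - 1L)) {
      mm <- sum(qv != sv[(s0 + 1L):(s0 + L)])
      if (mm <= max_mm)
        out[[length(out) + 1L]] <- data.frame(chrom = ch, start0 = s0,
                                              mismatches = mm,
                                              stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, c(out, make.row.names = FALSE))
}

# ungapped identity between two chromosomes over the chromosome arms
# (non-centromeric space) of a bundle
arm_identity <- function(bundle, chrom_a, chrom_b) {
  ct <- bundle$truth$centromere_truth
  a <- utf8ToInt(as.character(bundle$sequences[[chrom_a]]))
  b <- utf8ToInt(as.character(bundle$sequences[[chrom_b]]))
  cen <- ct[ct$chrom == chrom_a, ]
  arm <- c(seq_len(cen$start0), seq(cen$end + 1L, length(a)))
  mean(a[arm] == b[arm])
}
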