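#' @title Synthetic pentaploid genome generator
#'
#' @description
#' Builds seeded dogrose-like pentaploid genome bundles with the statistical
#' structure the downstream analyses assume: 7 linkage groups x 5 chromosome
#' copies, one subgenome present as two near-identical haplotypes (h1/h2,
#' ~99.5% identity) and three divergent single-copy subgenomes (95-98% pairwise
#' identity), centromeres built from CANR4 tandem arrays, ATHILA
#' retrotransposons (paired LTRs mutated according to a planted insertion age)
#' or cenLTR tandem arrays, and single-copy orthologue (SCO) loci placed once
#' per chromosome copy. Ground truth (bivalent subgenome, centromere intervals
#' and classes, LTR ages, locus coordinates, read provenance) is emitted
#' alongside so every inference can be tested against what was planted.
#'
#' @name synthetic-genome
NULL

DNA_BASES4 <- c("A", "C", "G", "T")

rand_dna <- function(n) {
  sample(DNA_BASES4, n, replace = TRUE)
}

# substitute a Binomial(L, rate) number of positions, new base uniform among
# the other three (i.i.d. substitution model, no indels)
mutate_dna <- function(x, rate) {
  if (rate <= 0) return(x)
  n <- stats::rbinom(1L, length(x), rate)
  if (n == 0L) return(x)
  pos <- sample.int(length(x), n)
  cur <- match(x[pos], DNA_BASES4)
  x[pos] <- DNA_BASES4[(cur - 1L + sample.int(3L, n, replace = TRUE)) %% 4L + 1L]
  x
}

# evolve a sequence along one JC69 branch of length K substitutions/site:
# each site differs from the ancestor with probability (3/4)(1 - exp(-4K/3))
jc_evolve <- function(x, branch_k) {
  p_change <- 0.75 * (1 - exp(-4 * branch_k / 3))
  mutate_dna_prob(x, p_change)
}

# per-site substitution with exact probability p (not the Binomial shortcut)
mutate_dna_prob <- function(x, p) {
  if (p <= 0) return(x)
  hit <- which(stats::runif(length(x)) < p)
  if (length(hit) == 0L) return(x)
  cur <- match(x[hit], DNA_BASES4)
  x[hit] <- DNA_BASES4[(cur - 1L + sample.int(3L, length(hit), replace = TRUE)) %% 4L + 1L]
  x
}

# 22-bp CANR4 FISH probe embedded in a synthetic ~160 bp monomer stand-in
# (the real monomer is not published; the probe guarantees detectability)
CANR4_PROBE <- "ACCCTAGAAGCAAGAAGTTTGG"

default_canr4_monomer <- function(length = 160L, seed_offset = 104729L) {
  # deterministic filler independent of the caller's RNG stream
  filler_pool <- strsplit("GATCCATGGTACGTTAGCCTAGGATCGCTAAGCTTGGCCAATTCGGATCA", "")[[1]]
  n_fill <- length - nchar(CANR4_PROBE)
  fill <- filler_pool[(seq_len(n_fill) * 7L + seed_offset) %% length(filler_pool) + 1L]
  paste0(paste(fill[seq_len(floor(n_fill / 2))], collapse = ""),
         CANR4_PROBE,
         paste(fill[seq(floor(n_fill / 2) + 1L, n_fill)], collapse = ""))
}

default_centromere_plan <- function(subgenomes, duplicated, n_lg) {
  # bivalent subgenome: ATHILA-based centromeres; permanent univalents S2/R3:
  # CANR4 satellite-based; R4 mostly ATHILA with one cenLTR tandem-array
  # centromere (Rca1_R4-like) when R4 is a univalent
  plan <- list()
  for (sg in subgenomes) {
    cls <- if (sg == duplicated) rep("ATHILA", n_lg)
           else if (startsWith(sg, "S") || sg == "R3") rep("CANR4", n_lg)
           else c("cenLTR", rep("ATHILA", n_lg - 1L))
    plan[[sg]] <- cls
  }
  plan
}

#' Specification of a synthetic pentaploid genome
#'
#' Defaults state the emulated world: 7 linkage groups, one duplicated
#' subgenome at 99.5% haplotype identity, three single-copy subgenomes whose
#' pairwise identities fall in the 95-98% band, ~10% of each chromosome
#' occupied by the centromere, ATHILA insertions dated around 0.7 Ma on the
#' bivalent subgenome and 1.2 Ma on univalents (rate 1.3e-8 subs/site/year),
#' and cenLTR monomers within the observed 1,425-2,596 bp monomer range.
#' Chromosomes default to 1 Mb (vs ~70 Mb real) so analyses run at desk scale.
#'
#' @param seed integer seed; all randomness in the bundle flows from it.
#' @param linkage_groups number of linkage groups (basic number x).
#' @param chromosome_length chromosome length in bp.
#' @param subgenome_labels ordered subgenome labels.
#' @param duplicated_subgenome the bivalent-forming (duplicated) subgenome.
#' @param haplotype_divergence pairwise substitution fraction between h1/h2.
#' @param subgenome_divergence named per-subgenome substitution fraction from
#'   the common ancestor sequence.
#' @param n_sco_loci SCO loci per linkage group.
#' @param sco_length locus length in bp.
#' @param centromere_fraction fraction of the chromosome occupied by the
#'   centromere.
#' @param centromere_plan per-subgenome vector of centromere classes
#'   ("CANR4", "ATHILA", "cenLTR"), one per linkage group.
#' @param canr4_monomer CANR4 satellite monomer sequence (contains the 22-bp
#'   probe by default).
#' @param athila_ltr_length,athila_internal_length ATHILA element geometry.
#' @param cenltr_monomer_length cenLTR monomer length (1,425-2,596 bp).
#' @param ltr_age_ma named insertion ages (Ma): `bivalent` applies to the
#'   duplicated subgenome, `univalent` to the rest.
#' @param ltr_rate substitution rate per site per year used to mutate LTRs.
#' @return A validated `genome_spec` object.
#' @export
genome_spec <- function(seed = 1L,
                        linkage_groups = 7L,
                        chromosome_length = 1e6,
                        subgenome_labels = c("S1", "S2", "R3", "R4"),
                        duplicated_subgenome = "S1",
                        haplotype_divergence = 0.005,
                        subgenome_divergence = c(S1 = 0.010, S2 = 0.017,
                                                 R3 = 0.022, R4 = 0.026),
                        n_sco_loci = 4L,
                        sco_length = 500L,
                        centromere_fraction = 0.10,
                        centromere_plan = NULL,
                        canr4_monomer = default_canr4_monomer(),
                        athila_ltr_length = 400L,
                        athila_internal_length = 800L,
                        cenltr_monomer_length = 1800L,
                        ltr_age_ma = c(bivalent = 0.7, univalent = 1.2),
                        ltr_rate = 1.3e-8) {
  if (!duplicated_subgenome %in% subgenome_labels)
    stop("invalid spec field 'duplicated_subgenome': '", duplicated_subgenome,
         "' is not in subgenome_labels")
  if (haplotype_divergence < 0 || haplotype_divergence >= 0.75)
    stop("invalid spec field 'haplotype_divergence': must be in [0, 0.75)")
  if (is.null(names(subgenome_divergence)) ||
      !setequal(names(subgenome_divergence), subgenome_labels))
    stop("invalid spec field 'subgenome_divergence': must be named by subgenome_labels")
  if (any(subgenome_divergence < 0 | subgenome_divergence >= 0.75))
    stop("invalid spec field 'subgenome_divergence': values must be in [0, 0.75)")
  cen_len <- round(centromere_fraction * chromosome_length)
  if (chromosome_length <= 2 * cen_len)
    stop("invalid spec field 'centromere_fraction': chromosome_length must exceed ",
         "twice the centromere length")
  if (cenltr_monomer_length < 1425L || cenltr_monomer_length > 2596L)
    stop("invalid spec field 'cenltr_monomer_length': must lie in [1425, 2596]")
  if (is.null(centromere_plan))
    centromere_plan <- default_centromere_plan(subgenome_labels,
                                               duplicated_subgenome,
                                               linkage_groups)
  for (sg in subgenome_labels) {
    cls <- centromere_plan[[sg]]
    if (is.null(cls)) stop("invalid spec field 'centromere_plan': missing ", sg)
    if (length(cls) == 1L) centromere_plan[[sg]] <- rep(cls, linkage_groups)
    if (!all(centromere_plan[[sg]] %in% c("CANR4", "ATHILA", "cenLTR")))
      stop("invalid spec field 'centromere_plan': unknown class for ", sg)
  }
  structure(list(
    seed = as.integer(seed),
    linkage_groups = as.integer(linkage_groups),
    chromosome_length = as.integer(chromosome_length),
    subgenome_labels = subgenome_labels,
    duplicated_subgenome = duplicated_subgenome,
    haplotype_divergence = haplotype_divergence,
    subgenome_divergence = subgenome_divergence[subgenome_labels],
    n_sco_loci = as.integer(n_sco_loci),
    sco_length = as.integer(sco_length),
    centromere_fraction = centromere_fraction,
    centromere_length = as.integer(cen_len),
    centromere_plan = centromere_plan,
    canr4_monomer = canr4_monomer,
    athila_ltr_length = as.integer(athila_ltr_length),
    athila_internal_length = as.integer(athila_internal_length),
    cenltr_monomer_length = as.integer(cenltr_monomer_length),
    ltr_age_ma = ltr_age_ma,
    ltr_rate = ltr_rate), class = "genome_spec")
}

# --- centromere content builders -------------------------------------------
# each returns list(seq = char vector of length cen_len,
#                   features = data.frame(family, start0, end, element_id),
#                   ltr_truth = data.frame or NULL)

build_canr4_centromere <- function(spec, cen_len) {
  mono <- strsplit(spec$canr4_monomer, "")[[1]]
  frac <- stats::runif(1, 0.55, 0.95)
  n_mono <- max(1L, floor(frac * cen_len / length(mono)))
  arr_len <- n_mono * length(mono)
  arr <- rep(mono, n_mono)
  pad <- cen_len - arr_len
  lead <- floor(pad / 2)
  seq <- c(rand_dna(lead), arr, rand_dna(pad - lead))
  list(seq = seq,
       features = data.frame(family = "CANR4", start0 = lead,
                             end = lead + arr_len,
                             element_id = NA_character_,
                             stringsAsFactors = FALSE),
       ltr_truth = NULL)
}

# one ATHILA element: [LTR5][internal][LTR3]; both LTRs evolve independently
# from the element's own LTR sequence for `age_years`, so their divergence
# carries the planted insertion age (K = 2 * rate * T under JC69)
make_athila_element <- function(spec, ltr_template, int_template, age_years) {
  ltr0 <- mutate_dna(ltr_template, 0.02)        # individualize the insertion
  int0 <- mutate_dna(int_template, 0.02)
  branch_k <- spec$ltr_rate * age_years
  ltr5 <- jc_evolve(ltr0, branch_k)
  ltr3 <- jc_evolve(ltr0, branch_k)
  list(seq = c(ltr5, int0, ltr3), ltr5 = ltr5, ltr3 = ltr3)
}

build_athila_centromere <- function(spec, cen_len, ltr_template, int_template,
                                    age_ma, chrom_name) {
  L_ltr <- spec$athila_ltr_length
  elem_len <- 2L * L_ltr + spec$athila_internal_length
  parts <- list(); feats <- list(); truth <- list()
  off <- 0L; k <- 0L
  # retrotransposon-based centromeres still carry a minor satellite fraction
  mono <- strsplit(spec$canr4_monomer, "")[[1]]
  n_mono <- floor(stats::runif(1, 0.02, 0.10) * cen_len / length(mono))
  if (n_mono >= 1L) {
    arr_len <- n_mono * length(mono)
    parts[[1L]] <- rep(mono, n_mono)
    feats[[1L]] <- data.frame(family = "CANR4", start0 = 0L, end = arr_len,
                              element_id = NA_character_,
                              stringsAsFactors = FALSE)
    off <- arr_len
  }
  n_elem <- max(1L, floor(0.7 * (cen_len - off) / elem_len))
  gap <- floor((cen_len - off - n_elem * elem_len) / (n_elem + 1L))
  for (i in seq_len(n_elem)) {
    parts[[length(parts) + 1L]] <- rand_dna(gap); off <- off + gap
    age_years <- age_ma * 1e6 * stats::runif(1, 0.8, 1.2)
    el <- make_athila_element(spec, ltr_template, int_template, age_years)
    eid <- paste0(chrom_name, "_ATH", i)
    feats[[length(feats) + 1L]] <- data.frame(
      family = c("ATHILA", "ATHILA_LTR", "ATHILA_LTR"),
      start0 = c(off, off, off + elem_len - L_ltr),
      end = c(off + elem_len, off + L_ltr, off + elem_len),
      element_id = eid, stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(
      element_id = eid, age_years = age_years, ltr_length = L_ltr,
      stringsAsFactors = FALSE)
    parts[[length(parts) + 1L]] <- el$seq; off <- off + elem_len
    k <- k + 1L
  }
  parts[[length(parts) + 1L]] <- rand_dna(cen_len - off)
  list(seq = unlist(parts),
       features = do.call(rbind, feats),
       ltr_truth = do.call(rbind, truth))
}

build_cenltr_centromere <- function(spec, cen_len, ltr_template, int_template,
                                    chrom_name) {
  # tandem array whose monomer derives from an ATHILA LTR (>75% similarity),
  # padded to the configured monomer length
  mono_ltr <- mutate_dna(ltr_template, 0.10)
  mono <- c(mono_ltr, rand_dna(spec$cenltr_monomer_length - length(mono_ltr)))
  n_mono <- max(1L, floor(0.7 * cen_len / length(mono)))
  arr_len <- n_mono * length(mono)
  arr <- rep(mono, n_mono)
  feats <- data.frame(family = "cenLTR1", start0 = 0L, end = arr_len,
                      element_id = NA_character_, stringsAsFactors = FALSE)
  pad <- cen_len - arr_len
  elem_len <- 2L * spec$athila_ltr_length + spec$athila_internal_length
  ltr_truth <- NULL
  parts <- list(arr)
  off <- arr_len
  if (pad >= elem_len + 20L) {
    age_years <- 1.2e6 * stats::runif(1, 0.8, 1.2)
    el <- make_athila_element(spec, ltr_template, int_template, age_years)
    eid <- paste0(chrom_name, "_ATH1")
    gap <- floor((pad - elem_len) / 2)
    parts[[2L]] <- rand_dna(gap)
    parts[[3L]] <- el$seq
    feats <- rbind(feats, data.frame(
      family = c("ATHILA", "ATHILA_LTR", "ATHILA_LTR"),
      start0 = c(off + gap, off + gap, off + gap + elem_len - spec$athila_ltr_length),
      end = c(off + gap + elem_len, off + gap + spec$athila_ltr_length,
              off + gap + elem_len),
      element_id = eid, stringsAsFactors = FALSE))
    ltr_truth <- data.frame(element_id = eid, age_years = age_years,
                            ltr_length = spec$athila_ltr_length,
                            stringsAsFactors = FALSE)
    off <- off + gap + elem_len
  }
  parts[[length(parts) + 1L]] <- rand_dna(cen_len - off)
  list(seq = unlist(parts), features = feats, ltr_truth = ltr_truth)
}

#' Generate a synthetic pentaploid genome bundle
#'
#' Emits 5 x linkage_groups chromosome sequences named
#' `Rca<LG>_<subgenome>[_<hap>]`, a chromosome/genome map, repeat and SCO
#' annotations (0-based half-open), SCO target reference sequences (the
#' ancestral locus sequences), and the ground-truth tables used by the test
#' oracles. Identical spec (including seed) gives byte-identical output.
#'
#' @param spec a [genome_spec()].
#' @return A `genome_bundle`: list with elements `sequences`
#'   (`Biostrings::DNAStringSet`), `genome_map` (data.frame: chrom,
#'   linkage_group, subgenome, haplotype, length), `repeats` (data.frame:
#'   chrom, start0, end, family, element_id), `sco_targets` (`DNAStringSet`),
#'   `truth` (list: bivalent_subgenome, centromere_truth, sco_truth,
#'   ltr_truth) and `spec`.
#' @export
generate_pentaploid <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, generate_pentaploid_impl(spec))
}

generate_pentaploid_impl <- function(spec) {
  L <- spec$chromosome_length
  cen_len <- spec$centromere_length
  arm1 <- floor((L - cen_len) / 2)
  arm2 <- L - cen_len - arm1
  dup <- spec$duplicated_subgenome

  ltr_template <- rand_dna(spec$athila_ltr_length)
  int_template <- rand_dna(spec$athila_internal_length)

  seqs <- list(); map <- list(); reps <- list()
  cen_truth <- list(); sco_truth <- list(); ltr_truth <- list()
  targets <- list()

  for (lg in seq_len(spec$linkage_groups)) {
    anc1 <- rand_dna(arm1)
    anc2 <- rand_dna(arm2)

    # SCO loci at fixed ancestor coordinates; identical across copies because
    # the divergence model is substitution-only
    n_loci <- spec$n_sco_loci
    locus_pos <- integer(0)
    if (n_loci > 0L) {
      usable <- arm1 - spec$sco_length - 2000L
      slots <- floor(seq(1000L, 1000L + usable,
                         length.out = max(n_loci, 2L)))[seq_len(n_loci)]
      locus_pos <- as.integer(slots)  # start0 on the chromosome (arm 1)
      for (i in seq_len(n_loci)) {
        lid <- sprintf("SCO_LG%d_%02d", lg, i)
        targets[[lid]] <- paste(anc1[(locus_pos[i] + 1L):(locus_pos[i] + spec$sco_length)],
                                collapse = "")
      }
    }

    for (sg in spec$subgenome_labels) {
      d <- spec$subgenome_divergence[[sg]]
      base1 <- mutate_dna(anc1, d)
      base2 <- mutate_dna(anc2, d)
      haps <- if (sg == dup) c("h1", "h2") else NA_character_
      for (hap in haps) {
        chrom <- paste0("Rca", lg, "_", sg,
                        if (!is.na(hap)) paste0("_", hap) else "")
        a1 <- if (!is.na(hap)) mutate_dna(base1, spec$haplotype_divergence / 2) else base1
        a2 <- if (!is.na(hap)) mutate_dna(base2, spec$haplotype_divergence / 2) else base2

        cls <- spec$centromere_plan[[sg]][lg]
        age_ma <- if (sg == dup) spec$ltr_age_ma[["bivalent"]] else spec$ltr_age_ma[["univalent"]]
        cen <- switch(cls,
          CANR4 = build_canr4_centromere(spec, cen_len),
          ATHILA = build_athila_centromere(spec, cen_len, ltr_template,
                                           int_template, age_ma, chrom),
          cenLTR = build_cenltr_centromere(spec, cen_len, ltr_template,
                                           int_template, chrom))

        seqs[[chrom]] <- paste(c(a1, cen$seq, a2), collapse = "")
        map[[chrom]] <- data.frame(chrom = chrom, linkage_group = lg,
                                   subgenome = sg, haplotype = hap,
                                   length = L, stringsAsFactors = FALSE)
        feats <- cen$features
        feats$start0 <- feats$start0 + arm1
        feats$end <- feats$end + arm1
        feats <- cbind(chrom = chrom, feats, stringsAsFactors = FALSE)
        reps[[chrom]] <- feats
        if (!is.null(cen$ltr_truth)) {
          lt <- cen$ltr_truth
          lt$chrom <- chrom
          lt$subgenome <- sg
          ltr_truth[[length(ltr_truth) + 1L]] <- lt
        }
        fam_bp <- function(f) {
          x <- feats[feats$family == f, , drop = FALSE]
          if (nrow(x) == 0L) 0L else sum(x$end - x$start0)
        }
        cen_truth[[chrom]] <- data.frame(
          chrom = chrom, start0 = arm1, end = arm1 + cen_len,
          class = paste0(switch(cls, CANR4 = "CANR4", ATHILA = "ATHILA",
                                cenLTR = "cenLTR"), "-based"),
          canr4_bp = fam_bp("CANR4"), athila_bp = fam_bp("ATHILA"),
          cenltr_bp = fam_bp("cenLTR1"), stringsAsFactors = FALSE)
        if (n_loci > 0L) {
          sco_truth[[length(sco_truth) + 1L]] <- data.frame(
            locus_id = sprintf("SCO_LG%d_%02d", lg, seq_len(n_loci)),
            chrom = chrom, linkage_group = lg, subgenome = sg, haplotype = hap,
            start0 = locus_pos, end = locus_pos + spec$sco_length,
            stringsAsFactors = FALSE)
        }
      }
    }
  }

  sequences <- Biostrings::DNAStringSet(unlist(seqs))
  sco_truth <- if (length(sco_truth)) do.call(rbind, sco_truth) else NULL
  structure(list(
    sequences = sequences,
    genome_map = do.call(rbind, c(map, make.row.names = FALSE)),
    repeats = do.call(rbind, c(reps, make.row.names = FALSE)),
    sco_targets = Biostrings::DNAStringSet(unlist(targets)),
    truth = list(
      bivalent_subgenome = dup,
      centromere_truth = do.call(rbind, c(cen_truth, make.row.names = FALSE)),
      sco_truth = sco_truth,
      ltr_truth = if (length(ltr_truth)) do.call(rbind, c(ltr_truth, make.row.names = FALSE)) else NULL),
    spec = spec), class = "genome_bundle")
}

#' @export
print.genome_bundle <- function(x, ...) {
  cat(sprintf("<genome_bundle> %d chromosomes x %d bp, bivalent = %s\n",
              length(x$sequences), x$spec$chromosome_length,
              x$truth$bivalent_subgenome))
  invisible(x)
}

#' Simulate sequencing reads from a bundle
#'
#' Uniform fragment starts, substitution-only errors. Sources:
#' \describe{
#'   \item{genome}{every chromosome, one copy each.}
#'   \item{bivalent}{only the two haplotypes of the bivalent subgenome —
#'     emulates pollen, which carries no univalents.}
#'   \item{sco_targets}{target-enrichment pollen reads: restricted to the SCO
#'     locus intervals on the bivalent-subgenome chromosomes.}
#'   \item{dosage}{one representative chromosome per subgenome (h1 for the
#'     duplicated one), sampled proportionally to a per-subgenome copy-number
#'     vector — emulates hybrid whole-genome reads.}
#' }
#'
#' @param bundle a `genome_bundle`.
#' @param source one of "genome", "bivalent", "sco_targets", "dosage".
#' @param dosage named integer vector (subgenome -> copy number), required for
#'   `source = "dosage"`.
#' @param coverage requested fold coverage per source copy.
#' @param read_length read length in bp.
#' @param error_rate per-base substitution error rate.
#' @param seed integer seed.
#' @return A `read_set`: data.frame with read_id, chrom, start0, end, seq;
#'   this table doubles as the read-level ground truth.
#' @export
generate_reads <- function(bundle, source = c("genome", "bivalent",
                                              "sco_targets", "dosage"),
                           dosage = NULL, coverage = 20, read_length = 150L,
                           error_rate = 0.002, seed = 1L) {
  source <- match.arg(source)
  stopifnot(coverage > 0, read_length < bundle$spec$chromosome_length)
  map <- bundle$genome_map
  biv <- bundle$truth$bivalent_subgenome
  with_seed(seed, {
    if (source == "sco_targets") {
      st <- bundle$truth$sco_truth
      if (is.null(st)) stop("bundle has no SCO loci")
      st <- st[st$subgenome == biv, , drop = FALSE]
      pool <- data.frame(chrom = st$chrom, start0 = st$start0, end = st$end,
                         weight = 1, stringsAsFactors = FALSE)
    } else {
      chroms <- switch(source,
        genome = map$chrom,
        bivalent = map$chrom[map$subgenome == biv],
        dosage = {
          if (is.null(dosage) || is.null(names(dosage)))
            stop("dosage mode needs a named per-subgenome copy-number vector")
          reps <- map[is.na(map$haplotype) | map$haplotype == "h1", , drop = FALSE]
          reps$chrom[reps$subgenome %in% names(dosage)[dosage > 0]]
        })
      if (length(chroms) == 0L) stop("empty read source selector")
      pool <- data.frame(chrom = chroms, start0 = 0L,
                         end = map$length[match(chroms, map$chrom)],
                         weight = 1, stringsAsFactors = FALSE)
      if (source == "dosage") {
        sg <- map$subgenome[match(pool$chrom, map$chrom)]
        pool$weight <- as.numeric(dosage[sg])
      }
    }
    out <- vector("list", nrow(pool))
    for (i in seq_len(nrow(pool))) {
      chrom <- pool$chrom[i]
      span <- pool$end[i] - pool$start0[i]
      n_reads <- round(coverage * pool$weight[i] * span / read_length)
      if (n_reads == 0L) next
      lo <- max(0L, pool$start0[i] - read_length + 50L)
      hi <- min(bundle$spec$chromosome_length, pool$end[i] + read_length - 50L) -
        read_length
      starts <- lo + floor(stats::runif(n_reads) * (hi - lo + 1L))
      seqs <- substring(as.character(bundle$sequences[[chrom]]),
                        starts + 1L, starts + read_length)
      if (error_rate > 0) {
        n_err <- stats::rbinom(n_reads, read_length, error_rate)
        for (j in which(n_err > 0L)) {
          v <- strsplit(seqs[j], "")[[1]]
          pos <- sample.int(read_length, n_err[j])
          cur <- match(v[pos], DNA_BASES4)
          v[pos] <- DNA_BASES4[(cur - 1L + sample.int(3L, n_err[j], TRUE)) %% 4L + 1L]
          seqs[j] <- paste(v, collapse = "")
        }
      }
      out[[i]] <- data.frame(chrom = chrom, start0 = starts,
                             end = starts + read_length, seq = seqs,
                             stringsAsFactors = FALSE)
    }
    reads <- do.call(rbind, c(out[!vapply(out, is.null, logical(1))],
                              make.row.names = FALSE))
    reads <- cbind(read_id = sprintf("read_%06d", seq_len(nrow(reads))), reads,
                   stringsAsFactors = FALSE)
    class(reads) <- c("read_set", class(reads))
    reads
  })
}

#' Simulate CENH3/H3 ChIP tracks and a methylation table
#'
#' H3 is flat at 1; CENH3 is 1 outside truth centromeres and `snr`-fold
#' enriched inside. CANR4- and cenLTR-based centromeres receive extra CENH3
#' mass (`canr4_boost` scales with the CANR4 fraction; cenLTR arrays are the
#' most enriched, as observed for the cenLTR1 centromere), mirroring the
#' positive CANR4-size/CENH3-abundance association. Both tracks get
#' multiplicative log-normal noise of sd `noise_sd`. The methylation table
#' carries per-window CpG/CHG/CHH methylated/total cytosine counts, elevated
#' at centromeres with a dip inside CANR4 arrays.
#'
#' @param bundle a `genome_bundle`.
#' @param window_size track window in bp.
#' @param snr CENH3 enrichment fold inside centromeres (> 1).
#' @param noise_sd sd of the log-normal multiplicative noise (0 = noiseless).
#' @param canr4_boost extra enrichment per unit CANR4 fraction (0 disables
#'   composition coupling, making log2(CENH3/H3) = log2(snr) exactly inside
#'   every centromere in noiseless mode).
#' @param seed integer seed.
#' @return List with `cenh3` and `h3` track data.frames (chrom, start0, end,
#'   value) and `methylation` (chrom, start0, end, context, meth, total, pct).
#' @export
generate_chip_tracks <- function(bundle, window_size = 10000L, snr = 8,
                                 noise_sd = 0.05, canr4_boost = 2.5,
                                 seed = 1L) {
  stopifnot(snr > 1)
  ct <- bundle$truth$centromere_truth
  if (is.null(ct) || nrow(ct) == 0L) stop("bundle truth has no centromere intervals")
  map <- bundle$genome_map
  with_seed(seed, {
    cen_tracks <- list(); h3_tracks <- list(); meth <- list()
    for (i in seq_len(nrow(map))) {
      chrom <- map$chrom[i]
      L <- map$length[i]
      starts <- seq(0L, L - 1L, by = window_size)
      ends <- pmin(starts + window_size, L)
      tr <- ct[ct$chrom == chrom, , drop = FALSE]
      ov <- pmax(0, pmin(ends, tr$end) - pmax(starts, tr$start0)) / (ends - starts)
      cfrac <- tr$canr4_bp / (tr$end - tr$start0)
      # cenLTR arrays are strongly CENH3-enriched despite lacking CANR4 —
      # comparable to a mid-sized satellite centromere, not above the largest
      enrich <- if (tr$class == "cenLTR-based") snr * (1 + canr4_boost * 0.6)
                else snr * (1 + canr4_boost * cfrac)
      cenh3 <- 1 + (enrich - 1) * ov
      h3 <- rep(1, length(starts))
      if (noise_sd > 0) {
        cenh3 <- cenh3 * exp(stats::rnorm(length(cenh3), 0, noise_sd))
        h3 <- h3 * exp(stats::rnorm(length(h3), 0, noise_sd))
      }
      cen_tracks[[chrom]] <- data.frame(chrom = chrom, start0 = starts,
                                        end = ends, value = cenh3,
                                        stringsAsFactors = FALSE)
      h3_tracks[[chrom]] <- data.frame(chrom = chrom, start0 = starts,
                                       end = ends, value = h3,
                                       stringsAsFactors = FALSE)
      # methylation: baseline per context, centromere gain, CANR4-array dip
      canr4 <- bundle$repeats[bundle$repeats$chrom == chrom &
                                bundle$repeats$family == "CANR4", , drop = FALSE]
      ov_canr4 <- if (nrow(canr4)) {
        pmax(0, pmin(ends, canr4$end[1]) - pmax(starts, canr4$start0[1])) /
          (ends - starts)
      } else rep(0, length(starts))
      for (ctx in c("CpG", "CHG", "CHH")) {
        base <- c(CpG = 60, CHG = 35, CHH = 8)[[ctx]]
        gain <- c(CpG = 22, CHG = 20, CHH = 4)[[ctx]]
        dip <- c(CpG = 25, CHG = 10, CHH = 2)[[ctx]]
        pct <- base + gain * ov - dip * ov_canr4
        if (noise_sd > 0) pct <- pct + stats::rnorm(length(pct), 0, 2)
        pct <- pmin(100, pmax(0, pct))
        total <- 200L
        meth[[paste0(chrom, "_", ctx)]] <- data.frame(
          chrom = chrom, start0 = starts, end = ends, context = ctx,
          meth = as.integer(round(pct / 100 * total)), total = total,
          stringsAsFactors = FALSE)
      }
    }
    list(cenh3 = do.call(rbind, c(cen_tracks, make.row.names = FALSE)),
         h3 = do.call(rbind, c(h3_tracks, make.row.names = FALSE)),
         methylation = do.call(rbind, c(meth, make.row.names = FALSE)))
  })
}

#' Simulate a cohort of LTR pairs with a planted insertion age
#'
#' Each element gets a random ancestral LTR; its 5' and 3' copies then evolve
#' independently for `age_years` under JC69 at `rate` substitutions/site/year,
#' so the expected pairwise divergence is K = 2 * rate * age. Used to test
#' that [date_insertion()] recovers planted ages.
#'
#' @param n number of elements.
#' @param age_years planted insertion age in years.
#' @param ltr_length LTR length in bp.
#' @param rate substitution rate per site per year.
#' @param subgenome label attached to the cohort.
#' @param seed integer seed.
#' @return Data.frame of LTR pairs: element_id, subgenome, ltr5, ltr3,
#'   aligned_length, mismatches, p_distance.
#' @export
simulate_ltr_pairs <- function(n, age_years, ltr_length = 400L, rate = 1.3e-8,
                               subgenome = "S1", seed = 1L) {
  with_seed(seed, {
    branch_k <- rate * age_years
    out <- lapply(seq_len(n), function(i) {
      anc <- rand_dna(ltr_length)
      a <- jc_evolve(anc, branch_k)
      b <- jc_evolve(anc, branch_k)
      m <- sum(a != b)
      data.frame(element_id = sprintf("%s_elem%04d", subgenome, i),
                 subgenome = subgenome,
                 ltr5 = paste(a, collapse = ""), ltr3 = paste(b, collapse = ""),
                 aligned_length = ltr_length, mismatches = m,
                 p_distance = m / ltr_length, stringsAsFactors = FALSE)
    })
    do.call(rbind, c(out, make.row.names = FALSE))
  })
}

#' Extract annotated LTR pairs from a bundle
#'
#' Pulls the two `ATHILA_LTR` features of every ATHILA insertion out of the
#' genome sequence and counts mismatches (the copies are equal length; no
#' gaps in the substitution-only world).
#'
#' @param bundle a `genome_bundle`.
#' @return Data.frame of LTR pairs as in [simulate_ltr_pairs()].
#' @export
ltr_pairs_from_bundle <- function(bundle) {
  feats <- bundle$repeats[bundle$repeats$family == "ATHILA_LTR", , drop = FALSE]
  if (nrow(feats) == 0L) return(NULL)
  out <- lapply(split(feats, feats$element_id), function(df) {
    df <- df[order(df$start0), , drop = FALSE]
    stopifnot(nrow(df) == 2L)
    s <- as.character(bundle$sequences[[df$chrom[1]]])
    a <- substring(s, df$start0[1] + 1L, df$end[1])
    b <- substring(s, df$start0[2] + 1L, df$end[2])
    va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
    m <- sum(va != vb)
    sg <- bundle$genome_map$subgenome[match(df$chrom[1], bundle$genome_map$chrom)]
    data.frame(element_id = df$element_id[1], subgenome = sg,
               ltr5 = a, ltr3 = b, aligned_length = length(va),
               mismatches = m, p_distance = m / length(va),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res[order(res$element_id), , drop = FALSE]
}
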