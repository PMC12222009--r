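#' @title Hybrid subgenome dosage and parental contribution
#'
#' @description
#' A dogrose hybrid inherits one copy of every maternal subgenome through the
#' 4x egg plus one copy of the paternal bivalent subgenome through the 1x
#' pollen. Its subgenome dosage is therefore readable from windowed read
#' coverage: the subgenome contributed by both parents shows doubled depth.
#' Parent-unique SNPs provide an orthogonal check on which parents actually
#' contributed.
#'
#' @name hybrid-dosage
NULL

#' Windowed mean read depth
#'
#' Tiles each chromosome with half-open windows of `window_size` bp (the last
#' window may be short) and reports the mean per-base depth of the supplied
#' alignments per window.
#'
#' @param alignments data.frame with chrom, start0, end (sorted by start
#'   within chromosome).
#' @param chrom_lengths named integer vector of chromosome lengths (or a
#'   genome_map data.frame with chrom and length columns).
#' @param window_size window size in bp.
#' @return A `coverage_track` data.frame: chrom, start0, end, depth.
#' @export
window_coverage <- function(alignments, chrom_lengths, window_size = 100000L) {
  stopifnot(window_size > 0)
  if (is.data.frame(chrom_lengths))
    chrom_lengths <- stats::setNames(chrom_lengths$length, chrom_lengths$chrom)
  for (ch in unique(alignments$chrom)) {
    if (is.unsorted(alignments$start0[alignments$chrom == ch]))
      stop("unsorted input: alignments on ", ch, " are not position-sorted")
  }
  out <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    starts <- seq(0L, L - 1L, by = window_size)
    ends <- pmin(starts + window_size, L)
    df <- alignments[alignments$chrom == ch, , drop = FALSE]
    if (nrow(df) == 0L) {
      depth <- rep(0, length(starts))
    } else {
      cov <- IRanges::coverage(IRanges::IRanges(pmax(1L, df$start0 + 1L),
                                                pmin(L, df$end)), width = L)
      v <- IRanges::Views(cov, starts + 1L, ends)
      depth <- IRanges::viewMeans(v)
    }
    data.frame(chrom = ch, start0 = starts, end = ends, depth = as.numeric(depth),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  class(res) <- c("coverage_track", class(res))
  res
}

#' Call per-subgenome copy number from windowed coverage
#'
#' The baseline depth is the median window depth over the subgenomes assumed
#' present in one copy; each subgenome's copy number is the nearest integer of
#' its median-depth ratio to that baseline. Windows overlapping repeat
#' annotation by more than `repeat_overlap` are excluded from the medians
#' (centromeric repeats attract multi-mapping artefacts). A subgenome is
#' flagged low-confidence when its ratio is farther than `tolerance` from the
#' nearest integer. The track should cover one representative chromosome per
#' subgenome (the dosage reference).
#'
#' @param track a `coverage_track`.
#' @param genome_map data.frame: chrom, subgenome (and more).
#' @param baseline character vector of subgenomes assumed 1x.
#' @param repeats optional repeat annotation data.frame (chrom, start0, end).
#' @param repeat_overlap overlap fraction above which a window is masked.
#' @param tolerance maximum |ratio - nearest integer| for a confident call.
#' @return A `dosage_call`: data.frame per subgenome with modal (median)
#'   depth, ratio, copy_number and confident flag; baseline depth as an
#'   attribute.
#' @export
call_dosage <- function(track, genome_map, baseline, repeats = NULL,
                        repeat_overlap = 0.5, tolerance = 0.25) {
  stopifnot(all(baseline %in% genome_map$subgenome))
  tr <- track
  tr$subgenome <- genome_map$subgenome[match(tr$chrom, genome_map$chrom)]
  tr <- tr[!is.na(tr$subgenome), , drop = FALSE]
  if (!is.null(repeats) && nrow(repeats) > 0L) {
    masked <- logical(nrow(tr))
    for (ch in unique(tr$chrom)) {
      wi <- which(tr$chrom == ch)
      rp <- repeats[repeats$chrom == ch, , drop = FALSE]
      if (nrow(rp) == 0L) next
      rp_ir <- IRanges::reduce(IRanges::IRanges(rp$start0 + 1L, rp$end))
      win_ir <- IRanges::IRanges(tr$start0[wi] + 1L, tr$end[wi])
      hits <- IRanges::findOverlaps(win_ir, rp_ir)
      if (length(hits) > 0L) {
        ovw <- IRanges::width(IRanges::pintersect(
          win_ir[S4Vectors::queryHits(hits)], rp_ir[S4Vectors::subjectHits(hits)]))
        ovl_by_win <- tapply(ovw, S4Vectors::queryHits(hits), sum)
        idx <- as.integer(names(ovl_by_win))
        frac <- ovl_by_win / IRanges::width(win_ir[idx])
        masked[wi[idx[frac > repeat_overlap]]] <- TRUE
      }
    }
    tr <- tr[!masked, , drop = FALSE]
  }
  med <- tapply(tr$depth, tr$subgenome, stats::median)
  base_depth <- stats::median(tr$depth[tr$subgenome %in% baseline])
  if (!is.finite(base_depth) || base_depth <= 0)
    stop("zero baseline depth: cannot normalize dosage")
  ratio <- as.numeric(med) / base_depth
  cn <- as.integer(round(ratio))
  res <- data.frame(subgenome = names(med), modal_depth = as.numeric(med),
                    ratio = ratio, copy_number = cn,
                    confident = abs(ratio - cn) <= tolerance,
                    stringsAsFactors = FALSE)
  attr(res, "baseline_depth") <- base_depth
  class(res) <- c("dosage_call", class(res))
  res
}

#' Parent-unique SNPs
#'
#' Symmetric-difference semantics on (chrom, pos0, alt): a record is retained
#' iff its position+allele combination occurs in exactly one parent.
#' Duplicate positions with conflicting alleles within one parent are kept
#' with a `multi_allelic` flag and a warning.
#'
#' @param parent1,parent2 data.frames with chrom, pos0, ref, alt.
#' @param labels parent labels attached to the output.
#' @return Data.frame: chrom, pos0, ref, alt, parent, multi_allelic.
#' @export
parent_unique_snps <- function(parent1, parent2, labels = c("parent1", "parent2")) {
  prep <- function(df, lab) {
    if (is.null(df) || nrow(df) == 0L)
      return(data.frame(chrom = character(0), pos0 = integer(0),
                        ref = character(0), alt = character(0),
                        parent = character(0), multi_allelic = logical(0),
                        stringsAsFactors = FALSE))
    df <- df[, c("chrom", "pos0", "ref", "alt")]
    df$parent <- lab
    pos_key <- paste(df$chrom, df$pos0)
    df$multi_allelic <- pos_key %in% pos_key[duplicated(pos_key)]
    if (any(df$multi_allelic))
      warning("parent ", lab, ": ", sum(df$multi_allelic),
              " records at multi-allelic positions kept with a flag")
    df
  }
  p1 <- prep(parent1, labels[1])
  p2 <- prep(parent2, labels[2])
  k1 <- paste(p1$chrom, p1$pos0, p1$alt)
  k2 <- paste(p2$chrom, p2$pos0, p2$alt)
  out <- rbind(p1[!(k1 %in% k2), , drop = FALSE],
               p2[!(k2 %in% k1), , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Pileup of read bases at given positions
#'
#' @param reads data.frame: chrom, start0, end, seq.
#' @param positions data.frame: chrom, pos0.
#' @return Data.frame: chrom, pos0, base, count (one row per observed base).
#' @export
pileup_at <- function(reads, positions) {
  out <- list()
  for (ch in unique(positions$chrom)) {
    ps <- positions[positions$chrom == ch, , drop = FALSE]
    rd <- reads[reads$chrom == ch, , drop = FALSE]
    if (nrow(rd) == 0L) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(ps$pos0 + 1L, ps$pos0 + 1L),
      IRanges::IRanges(rd$start0 + 1L, rd$end))
    if (length(hits) == 0L) next
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    base <- substring(rd$seq[si], ps$pos0[qi] - rd$start0[si] + 1L,
                      ps$pos0[qi] - rd$start0[si] + 1L)
    tab <- stats::aggregate(list(count = base),
                            by = list(pos0 = ps$pos0[qi], base = base), length)
    out[[ch]] <- data.frame(chrom = ch, pos0 = tab$pos0, base = tab$base,
                            count = tab$count, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(0), pos0 = integer(0),
                      base = character(0), count = integer(0)))
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Parental SNP contribution in a hybrid
#'
#' A parent-unique allele counts as observed when at least one hybrid read
#' carries it at a position covered by at least `min_depth` reads. Reports the
#' observed fraction of each parent's unique alleles.
#'
#' @param pileup data.frame: chrom, pos0, base, count (e.g. [pileup_at()]).
#' @param snps parent-unique SNP set from [parent_unique_snps()].
#' @param min_depth minimum total depth for a position to be assessable.
#' @return Data.frame per parent: observed, assessable, total, fraction
#'   (observed / assessable).
#' @export
snp_contribution <- function(pileup, snps, min_depth = 1L) {
  stopifnot(min_depth >= 1L)
  if (is.null(snps) || nrow(snps) == 0L) stop("empty SNP set")
  if (is.null(pileup) || nrow(pileup) == 0L)
    stop("no SNP position reaches the minimum depth (", min_depth, ")")
  depth <- stats::aggregate(list(depth = pileup$count),
                            by = list(chrom = pileup$chrom, pos0 = pileup$pos0),
                            sum)
  key_d <- paste(depth$chrom, depth$pos0)
  key_s <- paste(snps$chrom, snps$pos0)
  snps$depth <- depth$depth[match(key_s, key_d)]
  snps$depth[is.na(snps$depth)] <- 0L
  if (all(snps$depth < min_depth))
    stop("no SNP position reaches the minimum depth (", min_depth, ")")
  key_p <- paste(pileup$chrom, pileup$pos0, pileup$base)
  snps$observed <- snps$depth >= min_depth &
    paste(snps$chrom, snps$pos0, snps$alt) %in% key_p[pileup$count >= 1L]
  out <- do.call(rbind, lapply(split(snps, snps$parent), function(df) {
    assessable <- sum(df$depth >= min_depth)
    data.frame(parent = df$parent[1], observed = sum(df$observed),
               assessable = assessable, total = nrow(df),
               fraction = if (assessable > 0) sum(df$observed) / assessable else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Simple majority SNP caller against a reference
#'
#' Pileup majority caller (depth >= `min_depth`, allele fraction >=
#' `min_af`): reports positions where the majority non-reference base passes
#' both thresholds.
#'
#' @param reads data.frame: chrom, start0, end, seq.
#' @param sequences `DNAStringSet` reference.
#' @param positions optional data.frame (chrom, pos0) restricting the scan;
#'   scanning whole chromosomes is only sensible at toy scale.
#' @param min_depth,min_af calling thresholds.
#' @return Data.frame: chrom, pos0, ref, alt, depth, af.
#' @export
call_snps <- function(reads, sequences, positions = NULL, min_depth = 5L,
                      min_af = 0.1) {
  if (is.null(positions)) {
    positions <- do.call(rbind, lapply(unique(reads$chrom), function(ch) {
      data.frame(chrom = ch,
                 pos0 = seq_len(Biostrings::width(sequences)[match(ch, names(sequences))]) - 1L)
    }))
  }
  pu <- pileup_at(reads, positions)
  if (nrow(pu) == 0L) return(NULL)
  out <- list()
  for (ch in unique(pu$chrom)) {
    df <- pu[pu$chrom == ch, , drop = FALSE]
    refseq <- as.character(sequences[[ch]])
    depth <- tapply(df$count, df$pos0, sum)
    for (p in unique(df$pos0)) {
      ref <- substring(refseq, p + 1L, p + 1L)
      dd <- df[df$pos0 == p & df$base != ref, , drop = FALSE]
      if (nrow(dd) == 0L) next
      best <- dd[which.max(dd$count), , drop = FALSE]
      tot <- depth[[as.character(p)]]
      if (tot >= min_depth && best$count / tot >= min_af)
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, pos0 = p, ref = ref, alt = best$base, depth = tot,
          af = best$count / tot, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(NULL)
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res[order(res$chrom, res$pos0), , drop = FALSE]
}

#' End-to-end hybrid dosage pipeline on a synthetic bundle
#'
#' Simulates hybrid whole-genome reads with a given per-subgenome dosage,
#' computes windowed coverage over the dosage reference (one representative
#' chromosome per subgenome) and calls copy numbers against a 1x baseline.
#'
#' @param bundle a `genome_bundle`.
#' @param dosage named per-subgenome copy numbers (e.g. the output of
#'   [predict_hybrid_dosage()]).
#' @param baseline subgenomes assumed 1x (defaults to those with dosage 1).
#' @param coverage per-copy fold coverage.
#' @param window_size coverage window in bp.
#' @param seed seed for the read simulation.
#' @return List: call (`dosage_call`), track, reads.
#' @export
run_hybrid_dosage <- function(bundle, dosage, baseline = NULL, coverage = 20,
                              window_size = 10000L, seed = 1L) {
  reads <- generate_reads(bundle, source = "dosage", dosage = dosage,
                          coverage = coverage, seed = seed)
  reads <- reads[order(reads$chrom, reads$start0), , drop = FALSE]
  map <- bundle$genome_map
  refs <- map[is.na(map$haplotype) | map$haplotype == "h1", , drop = FALSE]
  refs <- refs[refs$subgenome %in% names(dosage)[dosage > 0], , drop = FALSE]
  track <- window_coverage(reads, stats::setNames(refs$length, refs$chrom),
                           window_size = window_size)
  if (is.null(baseline)) baseline <- names(dosage)[dosage == 1L]
  call <- call_dosage(track, map, baseline = baseline,
                      repeats = bundle$repeats)
  list(call = call, track = track, reads = reads)
}
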