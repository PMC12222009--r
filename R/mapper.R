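#' @title Minimal seeded k-mer mapper
#'
#' @description
#' A deliberately small substitution-only mapper sufficient for synthetic
#' reads and locus sequences: exact k-mer seeds anchor candidate placements
#' (one `matchPDict` call over the concatenated subject), which are then
#' scored by direct mismatch counting (no indels, matching the generator's
#' divergence model). It stands in for an external aligner so the SCO
#' filtering/counting/decision logic can be tested end to end; real SAM
#' alignments can be supplied instead via [read_sam_minimal()].
#'
#' @name kmer-mapper
NULL

# mismatch count between two equal-length strings (C-speed via utf8ToInt)
count_mismatches <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# seed table for a set of query strings: constant-width k-mers at n evenly
# spaced offsets (1-based offsets into the query)
seed_table <- function(qchar, k, n_seeds) {
  out <- lapply(seq_along(qchar), function(i) {
    qlen <- nchar(qchar[i])
    if (qlen < k) return(NULL)
    offs <- unique(as.integer(floor(seq(1L, qlen - k + 1L,
                                        length.out = min(n_seeds, qlen - k + 1L)))))
    data.frame(qi = i, off = offs, seed = substring(qchar[i], offs, offs + k - 1L),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Map query sequences onto a genome
#'
#' For each query, exact `k`-mer seeds taken at `n_seeds` evenly spaced
#' offsets propose candidate placements (seed hit position minus seed
#' offset); each candidate is scored by mismatch count over the full query
#' length. Placements with identity below `1 - max_mismatch_frac` are
#' dropped. The best placement becomes the primary hit; remaining placements
#' within `alt_identity_drop` of the primary identity are reported as
#' alternative placements (the XA-style alternatives the SCO filter
#' consumes), weaker ones stay in the full hit table only.
#'
#' @param query `Biostrings::DNAStringSet` or named character vector.
#' @param subject `Biostrings::DNAStringSet` of chromosomes.
#' @param k seed length.
#' @param n_seeds number of seed offsets per query.
#' @param max_mismatch_frac maximum mismatch fraction for a reported placement.
#' @param alt_identity_drop identity window below the primary within which a
#'   placement counts as an alternative.
#' @return List with `hits` (data.frame: query_id, chrom, start0, end,
#'   mismatches, identity, is_primary, is_alt) and `records` (one row per
#'   mapped query: id, chrom, pos0, mapq, alt_count, alt_list).
#' @export
map_sequences <- function(query, subject, k = 17L, n_seeds = 12L,
                          max_mismatch_frac = 0.10, alt_identity_drop = 0.01) {
  qchar <- if (methods::is(query, "DNAStringSet")) as.character(query)
           else as.character(query)
  if (is.null(names(qchar))) names(qchar) <- paste0("q", seq_along(qchar))
  schar <- as.character(subject)
  subj_names <- names(subject)
  widths <- nchar(schar)
  # concatenate with N spacers so seeds cannot bridge chromosomes
  spacer <- strrep("N", k)
  concat <- paste(schar, collapse = spacer)
  offsets <- cumsum(c(0L, utils::head(widths + k, -1L)))  # 0-based chrom starts

  seeds <- seed_table(unname(qchar), k, n_seeds)
  if (is.null(seeds) || nrow(seeds) == 0L)
    return(list(hits = NULL, records = NULL))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds$seed))
  m <- Biostrings::matchPDict(pd, Biostrings::DNAString(concat))
  starts <- BiocGenerics::start(m)

  hit_rows <- list(); rec_rows <- list()
  n_hits_per_seed <- lengths(starts)
  seed_idx <- rep.int(seq_len(nrow(seeds)), n_hits_per_seed)
  if (length(seed_idx) == 0L) return(list(hits = NULL, records = NULL))
  gpos <- unlist(starts, use.names = FALSE)              # 1-based in concat
  sj <- findInterval(gpos, offsets + 1L)
  cand <- data.frame(qi = seeds$qi[seed_idx], sj = sj,
                     start0 = gpos - 1L - offsets[sj] - (seeds$off[seed_idx] - 1L))
  cand <- unique(cand)
  qlen <- nchar(qchar)[cand$qi]
  cand <- cand[cand$start0 >= 0L & cand$start0 + qlen <= widths[cand$sj], ,
               drop = FALSE]
  if (nrow(cand) == 0L) return(list(hits = NULL, records = NULL))

  for (qi in unique(cand$qi)) {
    df <- cand[cand$qi == qi, , drop = FALSE]
    q <- qchar[[qi]]
    L <- nchar(q)
    gfrom <- offsets[df$sj] + df$start0 + 1L
    mm <- vapply(seq_len(nrow(df)), function(i)
      count_mismatches(q, substring(concat, gfrom[i], gfrom[i] + L - 1L)),
      integer(1))
    res <- data.frame(query_id = names(qchar)[qi], chrom = subj_names[df$sj],
                      start0 = df$start0, end = df$start0 + L,
                      mismatches = mm, identity = 1 - mm / L,
                      stringsAsFactors = FALSE)
    res <- res[res$identity >= 1 - max_mismatch_frac, , drop = FALSE]
    if (nrow(res) == 0L) next
    res <- res[order(-res$identity, res$chrom, res$start0), , drop = FALSE]
    res$is_primary <- seq_len(nrow(res)) == 1L
    res$is_alt <- !res$is_primary &
      res$identity >= res$identity[1] - alt_identity_drop
    hit_rows[[length(hit_rows) + 1L]] <- res
    alts <- res[res$is_alt, , drop = FALSE]
    rec_rows[[length(rec_rows) + 1L]] <- data.frame(
      id = names(qchar)[qi], chrom = res$chrom[1], pos0 = res$start0[1],
      mapq = if (nrow(alts) == 0L) 60L else 20L,
      alt_count = nrow(alts),
      alt_list = if (nrow(alts) == 0L) "" else
        paste(paste0(alts$chrom, ",", alts$start0), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  list(hits = if (length(hit_rows)) do.call(rbind, c(hit_rows, make.row.names = FALSE)) else NULL,
       records = if (length(rec_rows)) do.call(rbind, c(rec_rows, make.row.names = FALSE)) else NULL)
}

#' Assign reads to SCO target loci
#'
#' Fast exact-seed assignment of short reads to a small set of target locus
#' references: two constant-width seeds per read (start and middle) are
#' looked up in a k-mer table of the targets; the first consistent placement
#' below the mismatch ceiling wins. Reads whose seeds all carry
#' errors/divergence stay unassigned (dropped), which only thins coverage.
#'
#' @param reads a `read_set` data.frame (read_id, seq).
#' @param targets `DNAStringSet` of locus references.
#' @param k seed width.
#' @param max_mismatch_frac mismatch ceiling for accepting an assignment
#'   (checked over the read/target overlap).
#' @return Data.frame: read_id, locus_id, offset0 (read start on the target,
#'   may be negative for reads overhanging the locus start), seq; or NULL.
#' @export
map_reads_to_targets <- function(reads, targets, k = 25L,
                                 max_mismatch_frac = 0.10) {
  stopifnot(nrow(reads) > 0L, length(targets) > 0L)
  tchar <- stats::setNames(as.character(targets), names(targets))
  # k-mer lookup table over all targets
  km <- lapply(seq_along(tchar), function(ti) {
    L <- nchar(tchar[ti])
    if (L < k) return(NULL)
    pos <- seq_len(L - k + 1L)
    data.frame(ti = ti, pos1 = pos, kmer = substring(tchar[ti], pos, pos + k - 1L),
               stringsAsFactors = FALSE)
  })
  km <- do.call(rbind, km)
  rl <- nchar(reads$seq)
  soffs <- cbind(1L, pmax(1L, floor(rl / 2) - floor(k / 2)))
  assigned_ti <- rep(NA_integer_, nrow(reads))
  assigned_off <- rep(NA_integer_, nrow(reads))
  for (col in 1:2) {
    todo <- which(is.na(assigned_ti) & rl >= k)
    if (length(todo) == 0L) break
    soff <- soffs[todo, col]
    seed <- substring(reads$seq[todo], soff, soff + k - 1L)
    hit <- match(seed, km$kmer)                 # first occurrence wins
    ok <- !is.na(hit)
    assigned_ti[todo[ok]] <- km$ti[hit[ok]]
    assigned_off[todo[ok]] <- km$pos1[hit[ok]] - soff[ok]  # 0-based
  }
  keep <- which(!is.na(assigned_ti))
  if (length(keep) == 0L) return(NULL)
  out <- data.frame(read_id = reads$read_id[keep],
                    locus_id = names(tchar)[assigned_ti[keep]],
                    offset0 = assigned_off[keep],
                    seq = reads$seq[keep], stringsAsFactors = FALSE)
  # verify under the mismatch ceiling on the overlapping span
  tl <- nchar(tchar)[assigned_ti[keep]]
  from <- pmax(0L, out$offset0)
  to <- pmin(tl, out$offset0 + nchar(out$seq))
  rseq <- substring(out$seq, from - out$offset0 + 1L, to - out$offset0)
  tseq <- substring(tchar[assigned_ti[keep]], from + 1L, to)
  ok <- vapply(seq_len(nrow(out)), function(i) {
    span <- to[i] - from[i]
    span >= k && count_mismatches(rseq[i], tseq[i]) <= max_mismatch_frac * span
  }, logical(1))
  out <- out[ok, , drop = FALSE]
  if (nrow(out) == 0L) NULL else out
}
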