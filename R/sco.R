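#' @title Pollen SCO inference of the bivalent-forming subgenome
#'
#' @description
#' Pollen of a pentaploid dogrose carries only the bivalent-forming subgenome,
#' so single-copy orthologue (SCO) loci sequenced from pollen map
#' overwhelmingly onto that subgenome's chromosome pair. The procedure:
#' keep loci that are genome-wide single copy (exactly one hit per chromosome
#' copy, all in one linkage group), build per-locus pollen consensus
#' sequences, map them back, retain mappings with exactly one alternative
#' placement (the second haplotype of a bivalent pair), count hits per
#' chromosome and call the subgenome with the dominant count.
#'
#' @name sco-inference
NULL

#' Genome-wide single-copy filter for SCO loci
#'
#' A locus is retained iff it has exactly as many hits as there are
#' chromosome copies per linkage group (5 in a pentaploid), with exactly one
#' hit per subgenome/haplotype combination, and all hits within one linkage
#' group.
#'
#' @param hits data.frame of genomic hits with columns locus_id, chrom, and
#'   optionally linkage_group/subgenome/haplotype (joined from `genome_map`
#'   when absent).
#' @param genome_map data.frame: chrom, linkage_group, subgenome, haplotype.
#' @return Character vector of retained locus ids.
#' @export
filter_genomic_single_copy <- function(hits, genome_map) {
  if (nrow(hits) == 0L) return(character(0))
  idx <- match(hits$chrom, genome_map$chrom)
  if (anyNA(idx))
    stop("hit on chromosome absent from the genome map: ",
         paste(unique(hits$chrom[is.na(idx)]), collapse = ", "))
  hits$linkage_group <- genome_map$linkage_group[idx]
  copy_key <- paste0(genome_map$subgenome,
                     ifelse(is.na(genome_map$haplotype), "",
                            paste0("_", genome_map$haplotype)))
  hits$copy <- copy_key[idx]
  n_copies <- length(unique(copy_key))
  keep <- vapply(split(hits, hits$locus_id), function(df) {
    nrow(df) == n_copies &&
      length(unique(df$linkage_group)) == 1L &&
      !anyDuplicated(df$copy) &&
      length(unique(df$copy)) == n_copies
  }, logical(1))
  sort(names(keep)[keep])
}

#' Filter alignment records by alternative-placement count
#'
#' The default rule retains records with exactly one alternative placement —
#' the signature of a locus hitting both near-identical haplotypes of a
#' bivalent pair (primary on one, single XA alternative on the other).
#'
#' @param records data.frame with an `alt_count` column.
#' @param rule one of `"==1"`, `"<=1"`, `"any"`.
#' @return The retained rows of `records`.
#' @export
filter_alt_hits <- function(records, rule = c("==1", "<=1", "any")) {
  rule <- match.arg(rule)
  if (is.null(records) || nrow(records) == 0L) return(records)
  keep <- switch(rule,
                 "==1" = records$alt_count == 1L,
                 "<=1" = records$alt_count <= 1L,
                 "any" = rep(TRUE, nrow(records)))
  records[keep, , drop = FALSE]
}

#' Build per-locus sample-specific consensus sequences
#'
#' Majority-vote substitution consensus: at positions covered by at least
#' `min_depth` reads the majority base replaces the reference base; positions
#' below depth keep the reference. Length is preserved (substitution-only).
#' Loci with no assigned reads are skipped with a warning.
#'
#' @param assignments data.frame from [map_reads_to_targets()]: read_id,
#'   locus_id, offset0, seq.
#' @param targets `DNAStringSet` of locus reference sequences.
#' @param min_depth minimum depth to emit a substituted base.
#' @return Named `DNAStringSet` of consensus sequences (one per covered locus).
#' @export
build_consensus_reference <- function(assignments, targets, min_depth = 5L) {
  stopifnot(min_depth >= 1L)
  covered <- intersect(names(targets), unique(assignments$locus_id))
  missing <- setdiff(names(targets), covered)
  if (length(missing))
    warning("skipping ", length(missing), " locus/loci with empty pileup: ",
            paste(utils::head(missing, 5), collapse = ", "),
            if (length(missing) > 5) " ...")
  out <- lapply(covered, function(lid) {
    ref <- strsplit(as.character(targets[[lid]]), "")[[1]]
    L <- length(ref)
    df <- assignments[assignments$locus_id == lid, , drop = FALSE]
    counts <- matrix(0L, nrow = 4L, ncol = L)
    for (i in seq_len(nrow(df))) {
      off <- df$offset0[i]
      v <- strsplit(df$seq[i], "")[[1]]
      pos <- off + seq_along(v)          # 1-based target positions
      inb <- pos >= 1L & pos <= L
      b <- match(v[inb], DNA_BASES4)
      p <- pos[inb]
      ok <- !is.na(b)
      tab <- tabulate((p[ok] - 1L) * 4L + b[ok], nbins = 4L * L)
      counts <- counts + matrix(tab, nrow = 4L)
    }
    depth <- colSums(counts)
    maj <- max.col(t(counts), ties.method = "first")
    cons <- ref
    sub <- depth >= min_depth
    cons[sub] <- DNA_BASES4[maj[sub]]
    paste(cons, collapse = "")
  })
  names(out) <- covered
  Biostrings::DNAStringSet(unlist(out))
}

#' Count filtered SCO hits per chromosome
#'
#' @param records filtered alignment records (one primary placement per
#'   locus/read) with columns id, chrom.
#' @param genome_map data.frame: chrom, linkage_group, subgenome, haplotype.
#' @param taxon optional sample label carried into the table.
#' @return An `sco_hit_table`: list with `per_chromosome` (chrom,
#'   linkage_group, subgenome, haplotype, count — zero-filled over the whole
#'   map), `pair_means` (per haplotype pair: linkage_group, subgenome,
#'   mean_count), `total` and `taxon`.
#' @export
count_hits <- function(records, genome_map, taxon = NA_character_) {
  if (!is.null(records) && nrow(records) > 0L &&
      !all(records$chrom %in% genome_map$chrom))
    stop("record on unannotated chromosome: ",
         paste(setdiff(unique(records$chrom), genome_map$chrom), collapse = ", "))
  counts <- table(factor(if (is.null(records)) character(0) else records$chrom,
                         levels = genome_map$chrom))
  per_chrom <- data.frame(genome_map[, c("chrom", "linkage_group", "subgenome",
                                         "haplotype")],
                          count = as.integer(counts), stringsAsFactors = FALSE)
  pairs <- per_chrom[!is.na(per_chrom$haplotype), , drop = FALSE]
  pair_means <- if (nrow(pairs)) {
    agg <- stats::aggregate(count ~ linkage_group + subgenome, data = pairs,
                            FUN = mean)
    names(agg)[names(agg) == "count"] <- "mean_count"
    agg
  } else NULL
  structure(list(per_chromosome = per_chrom, pair_means = pair_means,
                 total = sum(per_chrom$count), taxon = taxon),
            class = "sco_hit_table")
}

#' @export
print.sco_hit_table <- function(x, ...) {
  cat(sprintf("<sco_hit_table> %d hits%s\n", x$total,
              if (is.na(x$taxon)) "" else paste0(" (", x$taxon, ")")))
  agg <- tapply(x$per_chromosome$count, x$per_chromosome$subgenome, sum)
  print(agg)
  invisible(x)
}

#' Call the bivalent-forming subgenome from an SCO hit table
#'
#' Haplotype counts are summed within each subgenome; the winner is the
#' subgenome with the maximal aggregate count. The call is `confident` when
#' the winner-minus-runner-up margin (as a fraction of the total) reaches
#' `margin_threshold`, otherwise `ambiguous`. Ties break lexicographically
#' and are always ambiguous.
#'
#' @param table an `sco_hit_table`.
#' @param margin_threshold minimum margin fraction for a confident call.
#' @return A `bivalent_call`: list(subgenome, support, margin, status, counts).
#' @export
assign_bivalent_subgenome <- function(table, margin_threshold = 0.5) {
  stopifnot(inherits(table, "sco_hit_table"))
  agg <- tapply(table$per_chromosome$count, table$per_chromosome$subgenome, sum)
  agg <- agg[order(-agg, names(agg))]
  total <- sum(agg)
  if (total == 0L) stop("no informative hits: all chromosome counts are zero")
  support <- unname(agg[1] / total)
  margin <- unname((agg[1] - if (length(agg) > 1L) agg[2] else 0) / total)
  status <- if (margin >= margin_threshold) "confident" else "ambiguous"
  structure(list(subgenome = names(agg)[1], support = support, margin = margin,
                 status = status, counts = agg),
            class = "bivalent_call")
}

#' @export
print.bivalent_call <- function(x, ...) {
  cat(sprintf("<bivalent_call> %s (%s): support %.2f, margin %.2f\n",
              x$subgenome, x$status, x$support, x$margin))
  invisible(x)
}

#' End-to-end pollen SCO pipeline on a synthetic bundle
#'
#' simulate pollen target-enrichment reads -> assign to SCO targets -> build
#' consensus -> genome-wide single-copy filter (on the targets) -> map
#' consensus back to the genome -> retain single-alternative records -> count
#' -> call the bivalent subgenome.
#'
#' @param bundle a `genome_bundle`.
#' @param coverage pollen read coverage over the loci.
#' @param read_length,error_rate read simulation parameters.
#' @param alt_rule alternative-hit retention rule (see [filter_alt_hits()]).
#' @param margin_threshold see [assign_bivalent_subgenome()].
#' @param min_depth consensus depth threshold.
#' @param seed seed for the read simulation.
#' @return List: call (`bivalent_call`), table (`sco_hit_table`), retained
#'   locus ids, records (filtered alignment records), consensus.
#' @export
run_pollen_bivalent <- function(bundle, coverage = 20, read_length = 150L,
                                error_rate = 0.002, alt_rule = "==1",
                                margin_threshold = 0.5, min_depth = 5L,
                                seed = 1L) {
  reads <- generate_reads(bundle, source = "sco_targets", coverage = coverage,
                          read_length = read_length, error_rate = error_rate,
                          seed = seed)
  assignments <- map_reads_to_targets(reads, bundle$sco_targets)
  if (is.null(assignments)) stop("no pollen reads could be assigned to targets")
  consensus <- build_consensus_reference(assignments, bundle$sco_targets,
                                         min_depth = min_depth)
  genomic <- map_sequences(bundle$sco_targets, bundle$sequences)
  retained <- filter_genomic_single_copy(
    data.frame(locus_id = genomic$hits$query_id, chrom = genomic$hits$chrom,
               stringsAsFactors = FALSE),
    bundle$genome_map)
  consensus <- consensus[names(consensus) %in% retained]
  if (length(consensus) == 0L) stop("no single-copy locus with pollen coverage")
  back <- map_sequences(consensus, bundle$sequences)
  records <- filter_alt_hits(back$records, rule = alt_rule)
  table <- count_hits(records, bundle$genome_map,
                      taxon = bundle$spec$duplicated_subgenome)
  call <- assign_bivalent_subgenome(table, margin_threshold = margin_threshold)
  list(call = call, table = table, retained_loci = retained,
       records = records, consensus = consensus)
}

#' Export per-subgenome concatenated locus sequences
#'
#' Concatenates retained locus sequences per chromosome copy in a fixed locus
#' order, for external phylogenetic tree building.
#'
#' @param bundle a `genome_bundle`.
#' @param locus_ids loci to include, in the order to concatenate.
#' @return Named `DNAStringSet`, one entry per chromosome copy.
#' @export
concatenate_sco_loci <- function(bundle, locus_ids) {
  st <- bundle$truth$sco_truth
  st <- st[st$locus_id %in% locus_ids, , drop = FALSE]
  st <- st[order(match(st$locus_id, locus_ids)), , drop = FALSE]
  out <- vapply(split(st, st$chrom), function(df) {
    paste(substring(as.character(bundle$sequences[[df$chrom[1]]]),
                    df$start0 + 1L, df$end), collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(out)
}
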