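#' @title Format readers and writers
#'
#' @description
#' Boundary layer between the package's internal conventions (0-based
#' half-open intervals everywhere) and the standard on-disk formats: FASTA /
#' FASTQ (Biostrings), GFF3 / BED / bedGraph (rtracklayer; GFF3 is 1-based
#' inclusive and converted at the boundary), a minimal SAM table with
#' XA-style alternative placements, a minimal VCF, TSV tables and JSON.
#'
#' @name format-io
NULL

#' Write / read sequencing reads as FASTQ
#'
#' @param reads a `read_set` data.frame (read_id, seq).
#' @param file path.
#' @return `read_fastq` returns a data.frame with read_id and seq.
#' @export
write_fastq <- function(reads, file) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  q <- Biostrings::BStringSet(vapply(nchar(reads$seq), function(n)
    paste(rep("I", n), collapse = ""), character(1)))
  Biostrings::writeXStringSet(x, file, format = "fastq", qualities = q)
  invisible(file)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(file) {
  x <- Biostrings::readDNAStringSet(file, format = "fastq")
  data.frame(read_id = names(x), seq = as.character(x),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write / read repeat and locus annotation as GFF3
#'
#' Internal 0-based half-open intervals become 1-based inclusive GFF3
#' coordinates on write and are converted back on read. The repeat family is
#' carried in a `family` attribute.
#'
#' @param features data.frame: chrom, start0, end, family, element_id.
#' @param file path.
#' @return `read_gff3` returns the features data.frame.
#' @export
write_gff3 <- function(features, file) {
  gr <- GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(features$start0 + 1L, features$end))
  S4Vectors::mcols(gr)$source <- "caninakit"
  S4Vectors::mcols(gr)$type <- "repeat_region"
  S4Vectors::mcols(gr)$family <- features$family
  S4Vectors::mcols(gr)$element_id <- features$element_id
  rtracklayer::export(gr, file, format = "gff3")
  invisible(file)
}

#' @rdname write_gff3
#' @export
read_gff3 <- function(file) {
  gr <- rtracklayer::import(file, format = "gff3")
  eid <- as.character(S4Vectors::mcols(gr)$element_id)
  eid[!is.na(eid) & eid == "NA"] <- NA_character_
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start0 = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             family = S4Vectors::mcols(gr)$family,
             element_id = eid, stringsAsFactors = FALSE, row.names = NULL)
}

#' Write / read a windowed signal track as bedGraph
#'
#' @param track data.frame: chrom, start0, end, value (or depth).
#' @param file path.
#' @return `read_bedgraph` returns a track data.frame (chrom, start0, end,
#'   value).
#' @export
write_bedgraph <- function(track, file) {
  val <- if (!is.null(track$value)) track$value else track$depth
  gr <- GenomicRanges::GRanges(track$chrom,
                               IRanges::IRanges(track$start0 + 1L, track$end),
                               score = val)
  rtracklayer::export(gr, file, format = "bedGraph")
  invisible(file)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(file) {
  gr <- rtracklayer::import(file, format = "bedGraph")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start0 = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             value = S4Vectors::mcols(gr)$score,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write / read intervals as BED (0-based half-open)
#'
#' @param intervals data.frame: chrom, start0, end and optionally name.
#' @param file path.
#' @return `read_bed` returns a data.frame (chrom, start0, end, name).
#' @export
write_bed <- function(intervals, file) {
  df <- data.frame(intervals$chrom, intervals$start0, intervals$end,
                   if (!is.null(intervals$name)) intervals$name else
                     if (!is.null(intervals$class)) intervals$class else ".")
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(file)
}

#' @rdname write_bed
#' @export
read_bed <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start0", "end")
  if (ncol(df) >= 4L) names(df)[4] <- "name"
  df
}

#' Write / read minimal SAM with XA-style alternative placements
#'
#' Columns written: QNAME FLAG RNAME POS MAPQ CIGAR RNEXT PNEXT TLEN SEQ QUAL
#' plus an `XA:Z:chrom,+pos,<len>M,0;...` tag for alternative placements.
#' POS is 1-based on disk, 0-based (`pos0`) in memory.
#'
#' @param records alignment records data.frame (id, chrom, pos0, mapq,
#'   alt_count, alt_list; optional seq).
#' @param file path.
#' @param chrom_lengths named lengths for the @SQ header.
#' @return `read_sam_minimal` returns an alignment records data.frame.
#' @export
write_sam_minimal <- function(records, file, chrom_lengths = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  if (!is.null(chrom_lengths))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                       as.integer(chrom_lengths)), con)
  seqs <- if (!is.null(records$seq)) records$seq else rep("*", nrow(records))
  lens <- ifelse(seqs == "*", 0L, nchar(seqs))
  cigar <- ifelse(lens > 0L, paste0(lens, "M"), "*")
  for (i in seq_len(nrow(records))) {
    fields <- c(records$id[i], 0L, records$chrom[i], records$pos0[i] + 1L,
                records$mapq[i], cigar[i], "*", 0L, 0L, seqs[i], "*")
    if (records$alt_count[i] > 0L) {
      alts <- strsplit(records$alt_list[i], ";", fixed = TRUE)[[1]]
      xa <- paste(vapply(alts, function(a) {
        cp <- strsplit(a, ",", fixed = TRUE)[[1]]
        paste0(cp[1], ",+", as.integer(cp[2]) + 1L, ",", cigar[i], ",0")
      }, character(1)), collapse = ";")
      fields <- c(fields, paste0("XA:Z:", xa, ";"))
    }
    writeLines(paste(fields, collapse = "\t"), con)
  }
  invisible(file)
}

#' @rdname write_sam_minimal
#' @export
read_sam_minimal <- function(file) {
  lines <- readLines(file)
  lines <- lines[!startsWith(lines, "@")]
  out <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L)
      stop("malformed SAM record (", file, " line ", i, "): fewer than 11 fields")
    xa <- grep("^XA:Z:", f[-(1:11)], value = TRUE)
    alt_list <- ""
    alt_count <- 0L
    if (length(xa) == 1L) {
      alts <- strsplit(sub("^XA:Z:", "", xa), ";", fixed = TRUE)[[1]]
      alts <- alts[nzchar(alts)]
      parsed <- vapply(alts, function(a) {
        cp <- strsplit(a, ",", fixed = TRUE)[[1]]
        paste0(cp[1], ",", abs(as.integer(cp[2])) - 1L)
      }, character(1))
      alt_list <- paste(parsed, collapse = ";")
      alt_count <- length(parsed)
    }
    data.frame(id = f[1], chrom = f[3], pos0 = as.integer(f[4]) - 1L,
               mapq = as.integer(f[5]), alt_count = alt_count,
               alt_list = alt_list,
               seq = if (f[10] != "*") f[10] else NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Write / read a minimal VCF (CHROM POS REF ALT)
#'
#' POS is 1-based on disk, `pos0` in memory.
#'
#' @param variants data.frame: chrom, pos0, ref, alt.
#' @param file path.
#' @return `read_vcf_minimal` returns a variants data.frame.
#' @export
write_vcf_minimal <- function(variants, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", variants$chrom,
                     variants$pos0 + 1L, variants$ref, variants$alt), con)
  invisible(file)
}

#' @rdname write_vcf_minimal
#' @export
read_vcf_minimal <- function(file) {
  lines <- readLines(file)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(0), pos0 = integer(0),
                      ref = character(0), alt = character(0)))
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) < 5L)
  if (length(bad))
    stop("malformed VCF record (", file, " line ", bad[1], "): fewer than 5 fields")
  data.frame(chrom = vapply(f, `[`, "", 1),
             pos0 = as.integer(vapply(f, `[`, "", 2)) - 1L,
             ref = vapply(f, `[`, "", 4), alt = vapply(f, `[`, "", 5),
             stringsAsFactors = FALSE)
}

#' Write / read the chromosome genome map as TSV
#'
#' @param genome_map data.frame: chrom, linkage_group, subgenome, haplotype,
#'   length.
#' @param file path.
#' @return `read_genome_map` returns the data.frame.
#' @export
write_genome_map <- function(genome_map, file) {
  utils::write.table(genome_map, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_genome_map
#' @export
read_genome_map <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (anyDuplicated(df$chrom)) stop("genome map has duplicate chromosome names")
  df
}

#' Read a table of LTR pairs from FASTA
#'
#' Expects two records per element named `<element_id>_ltr5` and
#' `<element_id>_ltr3`; mismatches are counted over gap-free columns (gap
#' columns in pre-aligned input are excluded).
#'
#' @param file FASTA path.
#' @return LTR pair data.frame as in [simulate_ltr_pairs()].
#' @export
read_ltr_pairs <- function(file) {
  x <- Biostrings::readBStringSet(file)
  ids <- sub("_ltr[53]$", "", names(x))
  out <- lapply(split(seq_along(x), ids), function(ix) {
    if (length(ix) != 2L)
      stop("element ", ids[ix[1]], " does not have exactly two LTR records")
    a <- strsplit(as.character(x[[ix[1]]]), "")[[1]]
    b <- strsplit(as.character(x[[ix[2]]]), "")[[1]]
    if (length(a) != length(b))
      stop("element ", ids[ix[1]], ": LTR sequences differ in length; align first")
    keep <- a != "-" & b != "-"
    m <- sum(a[keep] != b[keep])
    L <- sum(keep)
    data.frame(element_id = ids[ix[1]], subgenome = NA_character_,
               ltr5 = paste(a[keep], collapse = ""),
               ltr3 = paste(b[keep], collapse = ""),
               aligned_length = L, mismatches = m, p_distance = m / L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Write a genome bundle to a directory
#'
#' Emits genome.fa, sco_targets.fa, repeats.gff3, genome_map.tsv,
#' centromere_truth.bed and truth.json. Writing the same bundle twice gives
#' byte-identical files.
#'
#' @param bundle a `genome_bundle`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(bundle$sequences, file.path(dir, "genome.fa"))
  Biostrings::writeXStringSet(bundle$sco_targets,
                              file.path(dir, "sco_targets.fa"))
  write_gff3(bundle$repeats, file.path(dir, "repeats.gff3"))
  write_genome_map(bundle$genome_map, file.path(dir, "genome_map.tsv"))
  ct <- bundle$truth$centromere_truth
  write_bed(data.frame(chrom = ct$chrom, start0 = ct$start0, end = ct$end,
                       name = ct$class), file.path(dir, "centromere_truth.bed"))
  jsonlite::write_json(bundle$truth[c("bivalent_subgenome", "centromere_truth",
                                      "sco_truth", "ltr_truth")],
                       file.path(dir, "truth.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
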