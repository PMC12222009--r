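#' @title Centromere annotation and bimodal composition analysis
#'
#' @description
#' Functional centromeres are annotated from CENH3 ChIP enrichment over an H3
#' control: per chromosome, windows whose log2(CENH3/H3) exceeds mean + k*sd
#' form peaks; the centromere is the interval spanning the merged peak cluster
#' that contains the chromosome-wide enrichment maximum. Repeat composition
#' (CANR4 satellite, ATHILA retrotransposon, cenLTR tandem arrays, in bp)
#' classifies each centromere into the bimodal types observed in dogroses:
#' satellite-based centromeres on permanent univalents versus
#' retrotransposon-based centromeres on bivalent-forming chromosomes. CANR4
#' content is regressed on CENH3 abundance, and telomere-to-centromere scaled
#' metaplots summarize signals per subgenome.
#'
#' @name centromere-analysis
NULL

#' log2(CENH3/H3) enrichment track
#'
#' Both tracks are first coverage-normalized (scaled to equal total mass,
#' i.e. each divided by its mean) unless `normalize = "none"`, then the
#' windowed log2 ratio with a pseudocount is computed.
#'
#' @param cenh3,h3 track data.frames (chrom, start0, end, value) on identical
#'   windows.
#' @param pseudocount positive pseudocount added to both tracks.
#' @param normalize "mass" (default) or "none".
#' @return Track data.frame (chrom, start0, end, value) of log2 ratios.
#' @export
enrichment_track <- function(cenh3, h3, pseudocount = 1e-3,
                             normalize = c("mass", "none")) {
  normalize <- match.arg(normalize)
  stopifnot(pseudocount > 0)
  if (nrow(cenh3) != nrow(h3) ||
      !all(cenh3$chrom == h3$chrom & cenh3$start0 == h3$start0 &
             cenh3$end == h3$end))
    stop("window mismatch between CENH3 and H3 tracks")
  a <- cenh3$value
  b <- h3$value
  if (normalize == "mass") {
    a <- a / mean(a)
    b <- b / mean(b)
  }
  data.frame(chrom = cenh3$chrom, start0 = cenh3$start0, end = cenh3$end,
             value = log2((a + pseudocount) / (b + pseudocount)),
             stringsAsFactors = FALSE)
}

#' Call centromere intervals from an enrichment track
#'
#' Per chromosome: peaks are maximal runs of windows with value >= mean +
#' k*sd (chromosome-wise); runs closer than `merge_gap` are merged; the
#' centromere spans from the first to the last peak of the merged cluster
#' containing the global enrichment maximum. CENH3 abundance is the sum of
#' enrichment values over the interval (positive-only by default; see
#' `abundance`).
#'
#' @param track log2-ratio track data.frame.
#' @param k threshold multiplier on the chromosome-wise sd.
#' @param merge_gap peak runs closer than this many bp are merged.
#' @param abundance "positive" sums only positive log2 values, "raw" sums all.
#' @return Data.frame, one row per chromosome: chrom, start0, end, length,
#'   cenh3_abundance, max_position, found (FALSE rows carry NA interval).
#' @export
call_centromere <- function(track, k = 2, merge_gap = 100000L,
                            abundance = c("positive", "raw")) {
  abundance <- match.arg(abundance)
  out <- lapply(split(track, track$chrom), function(df) {
    df <- df[order(df$start0), , drop = FALSE]
    s <- stats::sd(df$value)
    thr <- mean(df$value) + k * s
    hot <- df$value >= thr
    if (!any(hot) || !is.finite(thr) || s == 0) {
      return(data.frame(chrom = df$chrom[1], start0 = NA_integer_,
                        end = NA_integer_, length = NA_integer_,
                        cenh3_abundance = NA_real_, max_position = NA_integer_,
                        found = FALSE, stringsAsFactors = FALSE))
    }
    r <- rle(hot)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    runs <- data.frame(si = starts_i[r$values], ei = ends_i[r$values])
    runs$start0 <- df$start0[runs$si]
    runs$end <- df$end[runs$ei]
    # merge runs separated by < merge_gap
    cluster <- cumsum(c(1L, as.integer(runs$start0[-1] - runs$end[-nrow(runs)] >=
                                         merge_gap)))
    merged <- do.call(rbind, lapply(split(runs, cluster), function(rr) {
      data.frame(start0 = min(rr$start0), end = max(rr$end))
    }))
    imax <- which.max(df$value)
    max_mid <- (df$start0[imax] + df$end[imax]) / 2
    pick <- which(merged$start0 <= max_mid & max_mid <= merged$end)
    if (length(pick) == 0L)  # argmax window below threshold: nearest cluster
      pick <- which.min(pmin(abs(merged$start0 - max_mid),
                             abs(merged$end - max_mid)))
    iv <- merged[pick[1], , drop = FALSE]
    inside <- df$start0 >= iv$start0 & df$end <= iv$end
    ab <- if (abundance == "positive") sum(pmax(df$value[inside], 0))
          else sum(df$value[inside])
    data.frame(chrom = df$chrom[1], start0 = iv$start0, end = iv$end,
               length = iv$end - iv$start0, cenh3_abundance = ab,
               max_position = df$start0[imax], found = TRUE,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res[order(res$chrom), , drop = FALSE]
}

#' Repeat composition of centromere intervals
#'
#' Per-family bp = total length of annotation within the interval, after
#' merging overlapping same-family features (so feature splitting does not
#' change the result). cenLTR1-4 families are pooled into `cenltr_bp`.
#'
#' @param intervals centromere calls ([call_centromere()] output or any
#'   data.frame with chrom, start0, end).
#' @param repeats repeat annotation data.frame (chrom, start0, end, family).
#' @return The input intervals with canr4_bp, athila_bp, cenltr_bp, other_bp
#'   columns added (ATHILA_LTR features are part of ATHILA elements and are
#'   not double-counted).
#' @export
repeat_composition <- function(intervals, repeats) {
  fam_of <- function(f) {
    ifelse(f == "CANR4", "canr4",
           ifelse(f == "ATHILA", "athila",
                  ifelse(grepl("^cenLTR", f), "cenltr",
                         ifelse(f == "ATHILA_LTR", "skip", "other"))))
  }
  reps <- repeats
  reps$group <- fam_of(reps$family)
  reps <- reps[reps$group != "skip", , drop = FALSE]
  for (col in c("canr4_bp", "athila_bp", "cenltr_bp", "other_bp"))
    intervals[[col]] <- 0L
  for (i in seq_len(nrow(intervals))) {
    if (is.na(intervals$start0[i])) next
    iv <- IRanges::IRanges(intervals$start0[i] + 1L, intervals$end[i])
    rp <- reps[reps$chrom == intervals$chrom[i], , drop = FALSE]
    for (g in unique(rp$group)) {
      rr <- rp[rp$group == g, , drop = FALSE]
      merged <- IRanges::reduce(IRanges::IRanges(rr$start0 + 1L, rr$end))
      bp <- sum(IRanges::width(IRanges::intersect(merged, iv)))
      intervals[[paste0(g, "_bp")]][i] <- bp
    }
  }
  intervals
}

#' Classify a centromere by repeat composition
#'
#' Rule: CANR4-based if canr4_bp/length >= `f_sat`; else cenLTR-based if
#' cenltr_bp >= `min_array`; else ATHILA-based if athila_bp/length >= `f_te`;
#' else mixed.
#'
#' @param profile data.frame with length, canr4_bp, athila_bp, cenltr_bp
#'   columns (from [repeat_composition()]).
#' @param f_sat CANR4 fraction threshold.
#' @param min_array minimum cenLTR array bp.
#' @param f_te ATHILA fraction threshold.
#' @return The profile with a `class` column added.
#' @export
classify_centromere <- function(profile, f_sat = 0.3, min_array = 50000L,
                                f_te = 0.2) {
  if (any(!is.na(profile$length) & profile$length == 0))
    stop("zero-length centromere interval")
  profile$class <- ifelse(is.na(profile$length), NA_character_,
    ifelse(profile$canr4_bp / profile$length >= f_sat, "CANR4-based",
      ifelse(profile$cenltr_bp >= min_array, "cenLTR-based",
        ifelse(profile$athila_bp / profile$length >= f_te, "ATHILA-based",
               "mixed"))))
  attr(profile, "thresholds") <- c(f_sat = f_sat, min_array = min_array,
                                   f_te = f_te)
  profile
}

#' Linear regression of CENH3 abundance on CANR4 content
#'
#' Ordinary least squares of `cenh3_abundance` on `canr4_bp` across
#' centromeres, with the Spearman rank correlation.
#'
#' @param profiles data.frame with canr4_bp and cenh3_abundance (n >= 3 rows).
#' @return List: slope, intercept, r_squared, spearman_rho, n. A constant
#'   predictor yields NA r_squared with a message.
#' @export
canr4_cenh3_regression <- function(profiles) {
  df <- profiles[!is.na(profiles$cenh3_abundance), , drop = FALSE]
  if (nrow(df) < 3L) stop("need at least 3 centromeres for the regression")
  if (stats::sd(df$canr4_bp) == 0) {
    message("constant CANR4 predictor: regression undefined")
    return(list(slope = NA_real_, intercept = NA_real_, r_squared = NA_real_,
                spearman_rho = NA_real_, n = nrow(df)))
  }
  fit <- stats::lm(cenh3_abundance ~ canr4_bp, data = df)
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((df$cenh3_abundance - mean(df$cenh3_abundance))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       spearman_rho = stats::cor(df$canr4_bp, df$cenh3_abundance,
                                 method = "spearman"),
       n = nrow(df))
}

#' Telomere-to-centromere scaled metaplot
#'
#' Every chromosome arm is scaled to [0, 1] (telomere = 0, centromere = 1,
#' centromere position = enrichment argmax), binned, p- and q-arm values
#' averaged (mirroring), then averaged across the chromosomes of each
#' subgenome. Signals are min-max scaled to [0, 1] using the global extremes
#' across all subgenomes, except tracks flagged as methylation (raw
#' percentages retained). The proximity view keeps bins with scaled
#' coordinate >= 1 - `proximity_fraction`.
#'
#' @param tracks named list of track data.frames (chrom, start0, end, value).
#' @param centromeres [call_centromere()] output (uses max_position).
#' @param genome_map data.frame: chrom, subgenome, length.
#' @param n_bins number of bins along the scaled arm (>= 2).
#' @param proximity_fraction proximity view width (default final 10%).
#' @param methylation_signals names of tracks to leave on their raw scale.
#' @param spar optional `smooth.spline` parameter; smoothing adds a
#'   `value_smooth` column and never alters `value`.
#' @return List: `profile` (signal, subgenome, bin, coord, value
#'   [, value_smooth]), `proximity` (restricted view), `scaling` (per-signal
#'   global min/max used).
#' @export
metaplot <- function(tracks, centromeres, genome_map, n_bins = 50L,
                     proximity_fraction = 0.10, methylation_signals = NULL,
                     spar = NULL) {
  if (n_bins < 2L) stop("n_bins must be at least 2")
  if (is.data.frame(tracks)) tracks <- list(signal = tracks)
  cen <- centromeres[centromeres$found %||% TRUE, , drop = FALSE]
  rows <- list()
  for (sig in names(tracks)) {
    tr <- tracks[[sig]]
    for (ch in unique(tr$chrom)) {
      ci <- which(cen$chrom == ch)
      if (length(ci) == 0L || is.na(cen$max_position[ci])) {
        warning("no centromere call for ", ch, "; chromosome skipped")
        next
      }
      cpos <- cen$max_position[ci]
      L <- genome_map$length[match(ch, genome_map$chrom)]
      df <- tr[tr$chrom == ch, , drop = FALSE]
      mid <- (df$start0 + df$end) / 2
      p <- mid <= cpos
      coord <- ifelse(p, mid / cpos, (L - mid) / (L - cpos))
      bin <- pmin(n_bins, pmax(1L, ceiling(coord * n_bins)))
      arm <- ifelse(p, "p", "q")
      agg <- stats::aggregate(list(value = df$value),
                              by = list(arm = arm, bin = bin), mean)
      # mirror: average the two arms per bin
      agg2 <- stats::aggregate(list(value = agg$value),
                               by = list(bin = agg$bin), mean)
      rows[[length(rows) + 1L]] <- data.frame(
        signal = sig, chrom = ch,
        subgenome = genome_map$subgenome[match(ch, genome_map$chrom)],
        bin = agg2$bin, value = agg2$value, stringsAsFactors = FALSE)
    }
  }
  long <- do.call(rbind, c(rows, make.row.names = FALSE))
  prof <- stats::aggregate(list(value = long$value),
                           by = list(signal = long$signal,
                                     subgenome = long$subgenome,
                                     bin = long$bin), mean)
  prof$coord <- (prof$bin - 0.5) / n_bins
  scaling <- list()
  for (sig in unique(prof$signal)) {
    sel <- prof$signal == sig
    lo <- min(prof$value[sel]); hi <- max(prof$value[sel])
    scaling[[sig]] <- c(min = lo, max = hi)
    if (!sig %in% methylation_signals) {
      prof$value[sel] <- if (hi > lo) (prof$value[sel] - lo) / (hi - lo) else
        rep(1, sum(sel))
    }
  }
  if (!is.null(spar)) {
    prof$value_smooth <- prof$value
    for (key in unique(paste(prof$signal, prof$subgenome))) {
      sel <- paste(prof$signal, prof$subgenome) == key
      if (sum(sel) >= 4L)
        prof$value_smooth[sel] <- stats::predict(
          stats::smooth.spline(prof$coord[sel], prof$value[sel], spar = spar),
          prof$coord[sel])$y
    }
  }
  prof <- prof[order(prof$signal, prof$subgenome, prof$bin), , drop = FALSE]
  rownames(prof) <- NULL
  list(profile = prof,
       proximity = prof[prof$coord >= 1 - proximity_fraction, , drop = FALSE],
       scaling = scaling)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Windowed methylation percentages per context
#'
#' Aggregates a methylation call table (counts of methylated and total
#' cytosine calls) into windows: per-window percentage = 100 * methylated /
#' total per context. Windows with no cytosine calls are NA, not zero.
#'
#' @param methylation data.frame: chrom, start0, end, context, meth, total.
#' @param chrom_lengths named lengths (or genome_map data.frame).
#' @param window_size output window size in bp (input rows are assigned to
#'   the window containing their start).
#' @return Data.frame: chrom, start0, end, context, pct.
#' @export
methylation_summary <- function(methylation, chrom_lengths,
                                window_size = 50000L) {
  stopifnot(all(methylation$context %in% c("CpG", "CHG", "CHH")))
  if (is.data.frame(chrom_lengths))
    chrom_lengths <- stats::setNames(chrom_lengths$length, chrom_lengths$chrom)
  m <- methylation
  m$win <- floor(m$start0 / window_size)
  agg <- stats::aggregate(cbind(meth, total) ~ chrom + context + win, data = m,
                          FUN = sum)
  out <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    starts <- seq(0L, L - 1L, by = window_size)
    do.call(rbind, lapply(c("CpG", "CHG", "CHH"), function(ctx) {
      a <- agg[agg$chrom == ch & agg$context == ctx, , drop = FALSE]
      idx <- match(floor(starts / window_size), a$win)
      pct <- ifelse(!is.na(idx) & a$total[idx] > 0,
                    100 * a$meth[idx] / a$total[idx], NA_real_)
      data.frame(chrom = ch, start0 = starts,
                 end = pmin(starts + window_size, L), context = ctx, pct = pct,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' End-to-end centromere pipeline on a synthetic bundle
#'
#' Simulated CENH3/H3 tracks -> enrichment -> centromere calls -> repeat
#' composition -> classification -> CANR4/CENH3 regression.
#'
#' @param bundle a `genome_bundle`.
#' @param window_size ChIP track window in bp.
#' @param snr,noise_sd,canr4_boost see [generate_chip_tracks()].
#' @param k,merge_gap see [call_centromere()].
#' @param f_sat,min_array,f_te see [classify_centromere()].
#' @param seed seed for the track simulation.
#' @return List: profiles (classified centromere table), regression, tracks,
#'   enrichment.
#' @export
run_centromere_analysis <- function(bundle, window_size = 10000L, snr = 8,
                                    noise_sd = 0.05, canr4_boost = 2.5,
                                    k = 2, merge_gap = 100000L, f_sat = 0.3,
                                    min_array = 50000L, f_te = 0.2, seed = 1L) {
  tracks <- generate_chip_tracks(bundle, window_size = window_size, snr = snr,
                                 noise_sd = noise_sd,
                                 canr4_boost = canr4_boost, seed = seed)
  enr <- enrichment_track(tracks$cenh3, tracks$h3)
  calls <- call_centromere(enr, k = k, merge_gap = merge_gap)
  prof <- repeat_composition(calls, bundle$repeats)
  prof <- classify_centromere(prof, f_sat = f_sat, min_array = min_array,
                              f_te = f_te)
  reg <- canr4_cenh3_regression(prof)
  list(profiles = prof, regression = reg, tracks = tracks, enrichment = enr)
}
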