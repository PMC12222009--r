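#' @title Canina meiosis model
#'
#' @description
#' Pentaploid dogroses (2n = 5x = 35) reproduce sexually through an asymmetric
#' meiosis: in every one of the 7 linkage groups one subgenome is present as two
#' near-identical haplotypes that pair as a bivalent, while the remaining three
#' subgenome copies stay unpaired (univalents). Bivalent chromosomes segregate
#' into both pollen and egg; univalents are transmitted through the egg only.
#' The male gamete therefore carries 7 chromosomes (1x) and the female gamete
#' 28 (4x), restoring 35 at fertilization.
#'
#' These functions encode that model as operations on `karyotype` and `gamete`
#' objects and derive its quantitative predictions (gamete sizes, seed-tissue
#' ploidies, hybrid dosage vectors, multi-generation stability).
#'
#' @name meiosis-model
NULL

# run expr with a private RNG stream, restoring the caller's .Random.seed
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Construct a karyotype
#'
#' A karyotype is the chromosome-copy composition of an individual: one row per
#' chromosome copy, tagged by linkage group, subgenome and (for the duplicated
#' subgenome) haplotype. The bivalent-forming subgenome is derived, not
#' declared: it is the subgenome present exactly twice in every linkage group.
#'
#' @param copies data.frame with columns `linkage_group` (integer),
#'   `subgenome` (character), `haplotype` (character or NA for single-copy
#'   subgenomes) and optionally `copy_id` (unique identifier used to track
#'   identity-by-descent across generations; generated when absent).
#' @param taxon label for the individual/taxon.
#' @param basic_number basic chromosome number x (7 for Rosa).
#' @return An object of class `karyotype`.
#' @export
karyotype <- function(copies, taxon = "unnamed", basic_number = 7L) {
  stopifnot(is.data.frame(copies),
            all(c("linkage_group", "subgenome") %in% names(copies)))
  copies$linkage_group <- as.integer(copies$linkage_group)
  if (is.null(copies$haplotype)) copies$haplotype <- NA_character_
  if (is.null(copies$copy_id)) {
    copies$copy_id <- paste0("LG", copies$linkage_group, "_", copies$subgenome,
                             ifelse(is.na(copies$haplotype), "",
                                    paste0("_", copies$haplotype)))
  }
  if (anyDuplicated(copies$copy_id))
    stop("copy_id values must be unique")
  lgs <- sort(unique(copies$linkage_group))
  per_lg <- table(copies$linkage_group)
  if (length(unique(per_lg)) != 1L)
    stop("every linkage group must carry the same number of chromosome copies")
  obj <- structure(
    list(taxon = taxon,
         copies = copies[order(copies$linkage_group, copies$subgenome,
                               copies$haplotype), , drop = FALSE],
         basic_number = as.integer(basic_number),
         bivalent_subgenome = NA_character_),
    class = "karyotype")
  obj$bivalent_subgenome <- tryCatch(bivalent_subgenome(obj),
                                     error = function(e) NA_character_)
  obj
}

#' Bivalent-forming subgenome of a karyotype
#'
#' @param k a `karyotype`.
#' @return The label of the subgenome present exactly twice in each linkage
#'   group. Errors with "no bivalent partner" when no subgenome is duplicated
#'   in every linkage group, or when several are.
#' @export
bivalent_subgenome <- function(k) {
  stopifnot(inherits(k, "karyotype"))
  cands <- lapply(split(k$copies, k$copies$linkage_group), function(df) {
    tab <- table(df$subgenome)
    names(tab)[tab == 2L]
  })
  common <- Reduce(intersect, cands)
  if (length(common) == 0L)
    stop("no bivalent partner: no subgenome is present twice in every linkage group")
  if (length(common) > 1L)
    stop("ambiguous bivalent subgenome: ", paste(common, collapse = ", "))
  common
}

#' @export
print.karyotype <- function(x, ...) {
  tab <- table(x$copies$subgenome)
  cat(sprintf("<karyotype> %s: %d copies (%d LG x %.0f), bivalent = %s\n",
              x$taxon, nrow(x$copies), length(unique(x$copies$linkage_group)),
              nrow(x$copies) / length(unique(x$copies$linkage_group)),
              x$bivalent_subgenome))
  print(tab)
  invisible(x)
}

#' Preset pentaploid and diploid karyotypes
#'
#' `pentaploid_karyotype()` builds a 35-chromosome karyotype (7 linkage groups,
#' subgenomes S1/S2/R3/R4 with one subgenome duplicated as haplotypes h1/h2).
#' `canina_karyotype()` duplicates S1 (R. canina, subsect. Caninae) and
#' `rubiginosa_karyotype()` duplicates R4 (R. rubiginosa, subsect. Rubigineae).
#' `diploid_karyotype()` builds a standard 14-chromosome diploid.
#'
#' @param subgenomes ordered subgenome labels.
#' @param duplicated label of the subgenome present as two haplotypes.
#' @param n_lg number of linkage groups.
#' @param taxon taxon label.
#' @return A `karyotype`.
#' @export
pentaploid_karyotype <- function(duplicated = "S1",
                                 subgenomes = c("S1", "S2", "R3", "R4"),
                                 n_lg = 7L, taxon = duplicated) {
  if (!duplicated %in% subgenomes)
    stop("duplicated subgenome '", duplicated, "' not among subgenome labels")
  rows <- do.call(rbind, lapply(seq_len(n_lg), function(lg) {
    data.frame(
      linkage_group = lg,
      subgenome = c(duplicated, duplicated, setdiff(subgenomes, duplicated)),
      haplotype = c("h1", "h2", rep(NA_character_, length(subgenomes) - 1L)),
      stringsAsFactors = FALSE)
  }))
  karyotype(rows, taxon = taxon)
}

#' @rdname pentaploid_karyotype
#' @export
canina_karyotype <- function() pentaploid_karyotype("S1", taxon = "R. canina")

#' @rdname pentaploid_karyotype
#' @export
rubiginosa_karyotype <- function() pentaploid_karyotype("R4", taxon = "R. rubiginosa")

#' @rdname pentaploid_karyotype
#' @export
corymbifera_karyotype <- function() pentaploid_karyotype("S1", taxon = "R. corymbifera")

#' @rdname pentaploid_karyotype
#' @export
diploid_karyotype <- function(n_lg = 7L, taxon = "diploid") {
  rows <- do.call(rbind, lapply(seq_len(n_lg), function(lg) {
    data.frame(linkage_group = lg, subgenome = c("A", "A"),
               haplotype = c("h1", "h2"), stringsAsFactors = FALSE)
  }))
  karyotype(rows, taxon = taxon)
}

new_gamete <- function(sex, copies, n_lg) {
  structure(list(sex = sex, copies = copies,
                 ploidy_x = as.integer(nrow(copies) / n_lg)),
            class = "gamete")
}

#' @export
print.gamete <- function(x, ...) {
  cat(sprintf("<gamete> %s, %d chromosomes (%dx)\n", x$sex, nrow(x$copies),
              x$ploidy_x))
  invisible(x)
}

#' Male (pollen) meiosis
#'
#' Only bivalent chromosomes enter pollen: per linkage group one of the two
#' bivalent haplotypes is drawn independently and uniformly; univalents never
#' appear. For a pentaploid the result is a 7-chromosome (1x) gamete.
#'
#' @param k a `karyotype` with a defined bivalent subgenome.
#' @param seed integer seed for the haplotype draws (NULL = current RNG).
#' @return A `gamete` with `sex = "male"`.
#' @export
male_meiosis <- function(k, seed = NULL) {
  biv <- bivalent_subgenome(k)
  n_lg <- length(unique(k$copies$linkage_group))
  with_seed(seed, {
    picked <- lapply(split(k$copies, k$copies$linkage_group), function(df) {
      pair <- df[df$subgenome == biv, , drop = FALSE]
      pair[sample.int(2L, 1L), , drop = FALSE]
    })
    new_gamete("male", do.call(rbind, c(picked, make.row.names = FALSE)), n_lg)
  })
}

#' Female (egg) meiosis
#'
#' The egg receives one bivalent haplotype per linkage group (seeded uniform
#' choice) plus every univalent chromosome. For a pentaploid this yields a
#' 28-chromosome (4x) gamete; for a diploid the female case equals the male.
#'
#' @inheritParams male_meiosis
#' @return A `gamete` with `sex = "female"`.
#' @export
female_meiosis <- function(k, seed = NULL) {
  biv <- bivalent_subgenome(k)
  n_lg <- length(unique(k$copies$linkage_group))
  with_seed(seed, {
    picked <- lapply(split(k$copies, k$copies$linkage_group), function(df) {
      pair <- df[df$subgenome == biv, , drop = FALSE]
      uni <- df[df$subgenome != biv, , drop = FALSE]
      rbind(pair[sample.int(2L, 1L), , drop = FALSE], uni)
    })
    new_gamete("female", do.call(rbind, c(picked, make.row.names = FALSE)), n_lg)
  })
}

#' Fertilization
#'
#' Fuses a female and a male gamete into the offspring karyotype. A pentaploid
#' cross (4x egg + 1x sperm) restores 35 chromosomes; the offspring's bivalent
#' subgenome is whichever subgenome ends up present twice per linkage group.
#'
#' @param egg a female `gamete`.
#' @param sperm a male `gamete`.
#' @param taxon label for the offspring.
#' @return A `karyotype`.
#' @export
fertilize <- function(egg, sperm, taxon = "offspring") {
  stopifnot(inherits(egg, "gamete"), inherits(sperm, "gamete"))
  if (egg$sex != "female" || sperm$sex != "male")
    stop("fertilize() needs a female egg and a male sperm gamete")
  if (!setequal(unique(egg$copies$linkage_group),
                unique(sperm$copies$linkage_group)))
    stop("incompatible gametes: different linkage-group universes")
  copies <- rbind(egg$copies, sperm$copies)
  # disambiguate copy ids when egg and sperm carry the same haplotype
  copies$copy_id <- make.unique(copies$copy_id, sep = ".dup")
  karyotype(copies, taxon = taxon)
}

#' Seed-tissue ploidies and the endosperm/embryo ratio
#'
#' Double fertilization: the embryo arises from egg + sperm, the endosperm from
#' the two polar nuclei (2 x egg ploidy) + one sperm. For a pentaploid dogrose
#' (4x egg, 1x sperm) this predicts a 9x endosperm over a 5x embryo, ratio 1.8;
#' for a diploid (1x + 1x) a 3x/2x ratio of 1.5.
#'
#' @param egg female `gamete` (or its ploidy as an integer).
#' @param sperm male `gamete` (or its ploidy as an integer).
#' @return A list with `embryo_ploidy_x`, `endosperm_ploidy_x` and `ratio`.
#' @export
endosperm_ploidy <- function(egg, sperm) {
  e <- if (inherits(egg, "gamete")) egg$ploidy_x else as.integer(egg)
  s <- if (inherits(sperm, "gamete")) sperm$ploidy_x else as.integer(sperm)
  if (e <= 0L || s <= 0L)
    stop("gamete ploidies must be positive")
  list(embryo_ploidy_x = e + s,
       endosperm_ploidy_x = 2L * e + s,
       ratio = (2 * e + s) / (e + s))
}

#' Predicted subgenome dosage of a hybrid
#'
#' The egg contributes one copy of each maternal subgenome; the sperm adds one
#' copy of the paternal bivalent subgenome. A canina (bivalent S1) mother
#' crossed with a rubiginosa (bivalent R4) father therefore yields
#' \{S1:1, S2:1, R3:1, R4:2\}.
#'
#' @param mother,father `karyotype` objects with defined bivalent subgenomes.
#' @return Named integer vector of per-subgenome copy numbers (sums to the
#'   offspring ploidy).
#' @export
predict_hybrid_dosage <- function(mother, father) {
  m_sub <- sort(unique(mother$copies$subgenome))
  dose <- stats::setNames(rep(1L, length(m_sub)), m_sub)
  pat <- bivalent_subgenome(father)
  if (pat %in% names(dose)) dose[pat] <- dose[pat] + 1L
  else dose <- c(dose, stats::setNames(1L, pat))[order(c(m_sub, pat))]
  dose
}

#' Multi-generation selfing trajectory
#'
#' Repeated selfing under Canina meiosis is a fixed point of the subgenome
#' composition: every generation is pentaploid with identical counts, and the
#' univalent copies are identical-by-descent to the founder's (they pass only
#' through the egg and never recombine).
#'
#' @param founder pentaploid `karyotype`.
#' @param n_generations number of selfed generations to simulate.
#' @param seed integer seed.
#' @return List of `karyotype` objects of length `n_generations`.
#' @export
simulate_generations <- function(founder, n_generations, seed = NULL) {
  stopifnot(n_generations >= 1L)
  with_seed(seed, {
    out <- vector("list", n_generations)
    k <- founder
    for (g in seq_len(n_generations)) {
      egg <- female_meiosis(k)
      sperm <- male_meiosis(k)
      k <- fertilize(egg, sperm, taxon = paste0(founder$taxon, "_G", g))
      # drop fertilize()'s dedup suffix so descent tracking stays by id
      k$copies$copy_id <- sub("\\.dup[0-9]*$", "", k$copies$copy_id)
      out[[g]] <- k
    }
    out
  })
}

#' Summarise subgenome copy counts
#'
#' @param k a `karyotype` or `gamete`.
#' @return Named integer vector: chromosome copies per subgenome.
#' @export
subgenome_counts <- function(k) {
  copies <- if (inherits(k, "karyotype") || inherits(k, "gamete")) k$copies else k
  tab <- table(copies$subgenome)
  stats::setNames(as.integer(tab), names(tab))
}
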