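#' @title Umbrella pipeline runner
#' @name pipeline
NULL

#' Run one of the headline analyses end to end
#'
#' Chains the generator and the analysis modules for one of the three
#' headline questions: which subgenome forms bivalents (pollen SCO mapping),
#' what subgenome dosage a hybrid carries (windowed coverage), and how
#' centromere composition partitions into satellite- versus
#' retrotransposon-based classes. All randomness flows from `config$seed`;
#' re-running with the same config is bit-identical.
#'
#' @param analysis one of "pollen-bivalent", "hybrid-dosage",
#'   "centromere-bimodality".
#' @param config list understood keys: `seed` (required), `spec` (a
#'   [genome_spec()]; built from `seed` with defaults when absent), `dosage`
#'   (named vector, hybrid analysis), `coverage`, `window_size`, `alt_rule`,
#'   `margin_threshold`, `k`, `merge_gap`, `snr`, `noise_sd`.
#' @param out optional output directory; when given, a machine-readable
#'   `summary.json` (with the config echoed) and the key tables are written.
#' @return The analysis result list, invisibly when `out` is given.
#' @export
run_pipeline <- function(analysis = c("pollen-bivalent", "hybrid-dosage",
                                      "centromere-bimodality"),
                         config = list(seed = 1L), out = NULL) {
  analysis <- match.arg(analysis)
  if (is.null(config$seed)) stop("config$seed is required")
  spec <- config$spec
  if (is.null(spec)) spec <- genome_spec(seed = config$seed)
  bundle <- generate_pentaploid(spec)
  cfg <- function(key, default) if (is.null(config[[key]])) default else config[[key]]

  result <- switch(analysis,
    "pollen-bivalent" = {
      res <- run_pollen_bivalent(
        bundle, coverage = cfg("coverage", 20),
        alt_rule = cfg("alt_rule", "==1"),
        margin_threshold = cfg("margin_threshold", 0.5),
        seed = config$seed + 1L)
      res$summary <- list(analysis = analysis,
                          bivalent_subgenome = res$call$subgenome,
                          status = res$call$status,
                          support = res$call$support,
                          truth = bundle$truth$bivalent_subgenome)
      res
    },
    "hybrid-dosage" = {
      dosage <- cfg("dosage", c(S1 = 1L, S2 = 1L, R3 = 1L, R4 = 2L))
      res <- run_hybrid_dosage(bundle, dosage,
                               coverage = cfg("coverage", 20),
                               window_size = cfg("window_size", 10000L),
                               seed = config$seed + 1L)
      res$summary <- list(analysis = analysis,
                          dosage = as.list(stats::setNames(
                            res$call$copy_number, res$call$subgenome)),
                          requested = as.list(dosage))
      res
    },
    "centromere-bimodality" = {
      res <- run_centromere_analysis(
        bundle, window_size = cfg("window_size", 10000L),
        snr = cfg("snr", 8), noise_sd = cfg("noise_sd", 0.05),
        k = cfg("k", 2), merge_gap = cfg("merge_gap", 100000L),
        seed = config$seed + 1L)
      res$summary <- list(analysis = analysis,
                          classes = as.list(table(res$profiles$class)),
                          spearman_rho = res$regression$spearman_rho,
                          r_squared = res$regression$r_squared)
      res
    })
  result$config <- config

  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    echo <- config[setdiff(names(config), "spec")]
    jsonlite::write_json(c(result$summary, list(config = echo)),
                         file.path(out, "summary.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    if (analysis == "hybrid-dosage")
      write_bedgraph(result$track, file.path(out, "coverage.bedGraph"))
    if (analysis == "centromere-bimodality") {
      utils::write.table(result$profiles, file.path(out, "centromeres.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (analysis == "pollen-bivalent") {
      utils::write.table(result$table$per_chromosome,
                         file.path(out, "sco_hits.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    return(invisible(result))
  }
  result
}
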