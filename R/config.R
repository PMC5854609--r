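#' Run configuration
#'
#' Bundles the analysis constants used across the pipeline. The defaults are
#' the study's printed operating points: a 500 nM inclusive binding-affinity
#' cutoff, mutant 9-mers and 10-mers, the mean-plus-3-standard-deviations
#' ELISpot positivity rule, removal of clonotypes supported by a single read,
#' and a repertoire limit of detection of 10 cells per million (1e-5).
#'
#' @param seed integer seed; every randomized routine that receives this
#'   config derives its stream from it. Required — there is no wall-clock
#'   default, so runs are reproducible by construction.
#' @param affinity_threshold_nm inclusive IC50 cutoff in nM (default 500).
#' @param peptide_lengths integer vector of peptide lengths to enumerate,
#'   each in 8..11 (default `c(9L, 10L)`).
#' @param min_reads_per_clonotype clonotypes with fewer pooled reads are
#'   discarded (default 2, i.e. singletons removed).
#' @param lod_fraction repertoire limit of detection as a read fraction
#'   (default 1e-5 = 0.001%).
#' @param elispot_sd_multiplier multiplier on the negative-control standard
#'   deviation in the ELISpot call (default 3).
#' @return A list with class `neotrack_config`.
#' @export
run_config <- function(seed,
                       affinity_threshold_nm = 500,
                       peptide_lengths = c(9L, 10L),
                       min_reads_per_clonotype = 2L,
                       lod_fraction = 1e-5,
                       elispot_sd_multiplier = 3) {
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is required: randomized runs must be explicitly seeded.")
  }
  seed <- as.integer(seed)
  cfg <- list(
    seed = seed,
    affinity_threshold_nm = affinity_threshold_nm,
    peptide_lengths = as.integer(sort(unique(peptide_lengths))),
    min_reads_per_clonotype = as.integer(min_reads_per_clonotype),
    lod_fraction = lod_fraction,
    elispot_sd_multiplier = elispot_sd_multiplier
  )
  validate_config(cfg)
  structure(cfg, class = "neotrack_config")
}

validate_config <- function(cfg) {
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1)
  for (fld in c("affinity_threshold_nm", "min_reads_per_clonotype",
                "lod_fraction", "elispot_sd_multiplier")) {
    if (!is.numeric(cfg[[fld]]) || length(cfg[[fld]]) != 1 || cfg[[fld]] <= 0) {
      abort(paste0("config field `", fld, "` must be a single positive number"))
    }
  }
  if (!all(cfg$peptide_lengths %in% 8:11)) {
    abort("`peptide_lengths` must be a subset of 8..11")
  }
  invisible(cfg)
}

#' Read / write a run configuration as YAML
#'
#' @param path file path to a YAML key/value file.
#' @return `read_run_config()` returns a `neotrack_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param config a `neotrack_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Limit of detection expressed as a percentage
#'
#' Converts a detectable-cell count per assayed total into percent, e.g. the
#' repertoire assay's validated floor of 10 cells in 1,000,000 is 0.001%.
#'
#' @param cells detectable cells (default 10).
#' @param total total cells assayed (default 1e6).
#' @return A single number, percent.
#' @export
lod_percent <- function(cells = 10, total = 1e6) {
  stopifnot(cells > 0, total > 0, cells <= total)
  100 * cells / total
}
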