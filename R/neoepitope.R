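#' Enumerate candidate mutant peptides around somatic missense mutations
#'
#' For every mutation and every requested length L, emits each L-mer window of
#' the protein that lies fully inside the sequence and covers the mutated
#' position, with the altered residue substituted; the wild-type counterpart
#' is the unsubstituted window. Windows truncated by the protein ends are
#' omitted (fixed-length predictors take full-length peptides only), so an
#' interior mutation yields L windows per length — 9 + 10 = 19 candidates at
#' the default lengths. Peptides whose window contains 'X' are excluded as
#' unsynthesizable and tallied in [rejections()].
#'
#' @param mutations tibble with `patient_id`, `gene`, `protein_id`,
#'   `position` (1-based), `ref_aa`, `alt_aa` and optionally `label`
#'   (built if absent).
#' @param proteome tibble with `protein_id`, `sequence`. Every mutation is
#'   cross-checked: the protein residue at `position` must equal `ref_aa`.
#' @param lengths integer vector of peptide lengths, each in 8..11.
#' @return A tibble of candidates: `patient_id`, `gene`, `label`,
#'   `protein_id`, `position`, `ref_aa`, `alt_aa`, `length`, `start`,
#'   `mut_offset` (1-based position of the altered residue within the
#'   peptide), `mutant_seq`, `wt_seq`.
#' @export
enumerate_mutant_peptides <- function(mutations, proteome, lengths = c(9L, 10L)) {
  stopifnot(all(lengths %in% 8:11))
  lengths <- as.integer(sort(unique(lengths)))
  if (!"label" %in% names(mutations)) {
    mutations <- mutate(mutations, label = paste0(
      .data$gene, "_", .data$ref_aa, .data$position, .data$alt_aa))
  }
  check_mutations(mutations, proteome)
  m <- left_join(mutations, proteome, by = "protein_id")

  one <- function(sequence, position, ref_aa, alt_aa, L) {
    n <- nchar(sequence)
    s0 <- max(1L, position - L + 1L)
    s1 <- min(position, n - L + 1L)
    if (s1 < s0) return(NULL)
    starts <- s0:s1
    wt <- substring(sequence, starts, starts + L - 1L)
    off <- position - starts + 1L
    mut <- wt
    substr(mut, off, off) <- alt_aa
    tibble(length = L, start = starts, mut_offset = off,
           mutant_seq = mut, wt_seq = wt)
  }

  res <- purrr::pmap(
    list(m$sequence, m$position, m$ref_aa, m$alt_aa, seq_len(nrow(m))),
    function(sequence, position, ref_aa, alt_aa, i) {
      windows <- purrr::map(lengths, function(L)
        one(sequence, position, ref_aa, alt_aa, L))
      windows <- bind_rows(windows)
      if (nrow(windows) == 0) return(NULL)
      bind_cols_meta(m[i, ], windows)
    })
  proto <- tibble(patient_id = character(), gene = character(),
                  label = character(), protein_id = character(),
                  position = integer(), ref_aa = character(),
                  alt_aa = character(), length = integer(),
                  start = integer(), mut_offset = integer(),
                  mutant_seq = character(), wt_seq = character())
  out <- bind_rows(proto, res)

  has_x <- stringr::str_detect(out$wt_seq, "X") |
    stringr::str_detect(out$mutant_seq, "X")
  rej <- NULL
  if (any(has_x)) {
    rej <- out[has_x, ] |> mutate(reason = "contains 'X' (unsynthesizable)")
    out <- out[!has_x, ]
  }
  structure(out, rejections = rej)
}

bind_cols_meta <- function(mrow, windows) {
  meta <- mrow[rep(1L, nrow(windows)),
               c("patient_id", "gene", "label", "protein_id",
                 "position", "ref_aa", "alt_aa")]
  dplyr::bind_cols(meta, windows)
}

#' Collapse candidates to unique mutant/wild-type peptide pairs
#'
#' Mutant peptides are pooled per patient for synthesis: each unique
#' `(patient_id, mutant_seq)` is kept once, with every source mutation label
#' preserved in a list column. Mutant and wild-type members of a pair always
#' differ (at exactly the mutated offset), which is asserted.
#'
#' @param candidates tibble from [enumerate_mutant_peptides()].
#' @return A tibble: `patient_id`, `mutant_seq`, `wt_seq`, `length`,
#'   `mut_offset`, `sources` (list of labels), `n_sources`.
#' @export
pair_wildtype <- function(candidates) {
  stopifnot(all(candidates$mutant_seq != candidates$wt_seq))
  candidates |>
    group_by(.data$patient_id, .data$mutant_seq) |>
    summarise(wt_seq = first(.data$wt_seq),
              length = first(.data$length),
              mut_offset = first(.data$mut_offset),
              sources = list(unique(.data$label)),
              n_sources = length(unique(.data$label)),
              .groups = "drop")
}

#' Filter candidate peptides by predicted HLA-I binding affinity
#'
#' Joins candidates to per-allele IC50 predictions, restricts to each
#' patient's own HLA alleles, and retains pairs with `ic50_nm <= threshold`
#' — the bound is inclusive, matching the study's "<= 500 nM" rule. Output
#' is sorted by ascending IC50. Candidates with no prediction on any of the
#' patient's alleles are tallied in [rejections()] as unpredicted.
#'
#' @param candidates tibble from [enumerate_mutant_peptides()].
#' @param predictions tibble with `peptide`, `allele`, `ic50_nm`.
#' @param patient_alleles tibble with `patient_id`, `allele` (or a character
#'   vector of alleles applied to every patient).
#' @param threshold_nm inclusive IC50 cutoff in nM.
#' @return A tibble of retained `(candidate, allele, ic50_nm)` rows.
#' @export
apply_affinity_filter <- function(candidates, predictions, patient_alleles,
                                  threshold_nm = 500) {
  if (is.character(patient_alleles)) {
    patient_alleles <- tidyr::crossing(
      patient_id = unique(candidates$patient_id),
      allele = patient_alleles)
  }
  if (nrow(patient_alleles) == 0) {
    abort("`patient_alleles` is empty: each patient needs at least one HLA allele")
  }
  scored <- candidates |>
    inner_join(predictions, by = c(mutant_seq = "peptide"),
               relationship = "many-to-many") |>
    semi_join(patient_alleles, by = c("patient_id", "allele"))
  unpred <- anti_join(candidates,
                      distinct(scored, .data$patient_id, .data$mutant_seq,
                               .data$label),
                      by = c("patient_id", "mutant_seq", "label"))
  rej <- NULL
  if (nrow(unpred) > 0) {
    rej <- mutate(unpred, reason = "no prediction on any patient allele")
  }
  out <- scored |>
    filter(.data$ic50_nm <= threshold_nm) |>
    arrange(.data$ic50_nm)
  structure(out, rejections = rej)
}

#' Per-patient predicted neo-epitope load
#'
#' Counts retained candidates per patient after the affinity filter, both as
#' unique mutant peptide sequences and as (peptide, allele) pairs — the two
#' readings of a "predicted neo-epitope". Patients with no retained peptide
#' are reported with count 0 when listed in `patients`.
#'
#' @param filtered tibble from [apply_affinity_filter()].
#' @param patients optional character vector of all patients to report
#'   (zero-count patients included).
#' @return A tibble: `patient_id`, `n_peptides`, `n_peptide_allele_pairs`.
#' @seealso [load_summary()]
#' @export
predicted_load <- function(filtered, patients = NULL) {
  counts <- filtered |>
    group_by(.data$patient_id) |>
    summarise(n_peptides = n_distinct(.data$mutant_seq),
              n_peptide_allele_pairs = n_distinct(
                paste(.data$mutant_seq, .data$allele)),
              .groups = "drop")
  if (!is.null(patients)) {
    counts <- tibble(patient_id = unique(patients)) |>
      left_join(counts, by = "patient_id") |>
      mutate(across(c("n_peptides", "n_peptide_allele_pairs"),
                    ~ dplyr::coalesce(.x, 0L)))
  }
  arrange(counts, .data$patient_id)
}

#' @rdname predicted_load
#' @param load tibble from `predicted_load()`.
#' @export
load_summary <- function(load) {
  tibble(
    n_patients = nrow(load),
    total_peptides = sum(load$n_peptides),
    total_peptide_allele_pairs = sum(load$n_peptide_allele_pairs),
    min_per_patient = if (nrow(load)) min(load$n_peptides) else NA_integer_,
    max_per_patient = if (nrow(load)) max(load$n_peptides) else NA_integer_,
    median_per_patient = if (nrow(load)) median(load$n_peptides) else NA_real_
  )
}
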