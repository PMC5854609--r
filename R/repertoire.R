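# TCR repertoire construction: translate amplicon reads, pool nucleotide
# variants coding for the same receptor protein, drop singletons, and track
# specific clonotypes across compartments.

#' Translate TCR amplicon reads and remove out-of-frame sequences
#'
#' Each nucleotide sequence is translated in reading frame 1 with the
#' standard genetic code (amplicons are primer-anchored, so the frame is
#' known). A read is out-of-frame when its length is not a multiple of 3 or
#' its translation contains a stop codon; such reads are removed and
#' tallied. Reads with characters outside A/C/G/T are rejected under their
#' own tally. With `frame_rescue = TRUE` the three forward frames are tried
#' and the first stop-free one kept (for unanchored input).
#'
#' @param reads tibble with `sequence_nt`, `read_count` and any annotation
#'   columns (`chain`, `compartment`, `v_segment`, `j_segment`).
#' @param frame_rescue try all three forward frames (default FALSE).
#' @return The in-frame reads with a `protein_seq` column added; the tally
#'   of removed reads is in `accounting()` (columns `category`, `n_rows`,
#'   `reads`).
#' @export
translate_and_filter <- function(reads, frame_rescue = FALSE) {
  if (nrow(reads) == 0) abort("read table is empty")
  seq <- toupper(reads$sequence_nt)
  invalid <- stringr::str_detect(seq, "[^ACGT]")
  prot <- rep(NA_character_, length(seq))
  ok <- !invalid
  if (frame_rescue) {
    prot[ok] <- purrr::map_chr(seq[ok], rescue_translate)
  } else {
    in3 <- ok & nchar(seq) %% 3 == 0
    prot[in3] <- translate_nt(seq[in3])
    prot[ok & !in3] <- NA_character_
  }
  has_stop <- !is.na(prot) & stringr::str_detect(prot, stringr::fixed("*"))
  prot[has_stop] <- NA_character_
  out_frame <- ok & is.na(prot)
  retained <- ok & !is.na(prot)

  tallies <- tibble(
    category = c("retained", "out_of_frame", "invalid_character"),
    n_rows = c(sum(retained), sum(out_frame), sum(invalid)),
    reads = c(sum(reads$read_count[retained]),
              sum(reads$read_count[out_frame]),
              sum(reads$read_count[invalid]))
  )
  out <- reads[retained, ] |> mutate(protein_seq = prot[retained])
  structure(out, accounting = tallies)
}

translate_nt <- function(seq) {
  if (length(seq) == 0) return(character(0))
  as.character(Biostrings::translate(Biostrings::DNAStringSet(seq),
                                     no.init.codon = TRUE))
}

rescue_translate <- function(s) {
  for (off in 0:2) {
    sub <- substr(s, 1 + off, nchar(s))
    sub <- substr(sub, 1, (nchar(sub) %/% 3) * 3)
    if (nchar(sub) < 3) next
    p <- translate_nt(sub)
    if (!stringr::str_detect(p, stringr::fixed("*"))) return(p)
  }
  NA_character_
}

#' Build a clonotype table from translated reads
#'
#' Reads coding for the same receptor protein sequence are pooled (their
#' counts summed) within each compartment and chain; clonotypes whose
#' pooled count falls below `min_reads` are removed — the default of 2
#' applies the study's rule that receptors supported by a single read are
#' not considered, after pooling. Frequencies are computed over retained
#' reads. Ordering is deterministic: descending read count, then
#' lexicographic protein sequence. V/J annotations of a pooled clonotype
#' are taken from its most abundant read.
#'
#' @param translated tibble from [translate_and_filter()] (needs
#'   `protein_seq`, `read_count`; `compartment`/`chain` define groups).
#' @param min_reads minimum pooled reads to retain a clonotype (default 2).
#' @return A clonotype tibble with `read_count`, `frequency`, `rank` per
#'   compartment/chain; per-group read accounting in `accounting()`.
#' @export
build_clonotypes <- function(translated, min_reads = 2L) {
  group_cols <- intersect(c("compartment", "chain"), names(translated))
  ann_cols <- intersect(c("v_segment", "j_segment"), names(translated))
  pooled <- translated |>
    arrange(desc(.data$read_count)) |>
    group_by(across(all_of(c(group_cols, "protein_seq")))) |>
    summarise(across(all_of(ann_cols), first),
              read_count = sum(.data$read_count), .groups = "drop")
  grouped <- pooled |> group_by(across(all_of(group_cols)))
  acct <- grouped |>
    summarise(
      total_reads_in = sum(.data$read_count),
      reads_discarded_singleton = sum(.data$read_count[
        .data$read_count < min_reads]),
      .groups = "drop") |>
    mutate(reads_retained = .data$total_reads_in -
             .data$reads_discarded_singleton)
  out <- grouped |>
    filter(.data$read_count >= min_reads) |>
    mutate(frequency = .data$read_count / sum(.data$read_count)) |>
    arrange(desc(.data$read_count), .data$protein_seq, .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    ungroup()
  structure(out, accounting = acct)
}

#' Track specific clonotypes across bulk compartments
#'
#' For each specific clonotype — typically sequenced from multimer-sorted
#' cells — and each bulk compartment, reports presence, frequency, and rank
#' (position after ordering by descending read count with lexicographic
#' tie-break). Absences are interpreted against the assay's limit of
#' detection: when a compartment is too shallow for `lod_fraction` to be
#' observable (1 / retained reads > lod_fraction), the absence is flagged
#' `below_lod`; otherwise the clonotype is genuinely absent above the LOD.
#' A present clonotype sitting under `lod_fraction` is also flagged.
#'
#' @param specific tibble keyed by `chain`, `protein_seq` (a
#'   `clonotype_id` column, if present, is carried through).
#' @param bulk clonotype tibble from [build_clonotypes()] with a
#'   `compartment` column.
#' @param lod_fraction limit of detection as a read fraction (default 1e-5,
#'   i.e. 0.001%).
#' @return A tibble with one row per (specific clonotype, compartment):
#'   `present`, `frequency`, `rank`, `compartment_reads`, `below_lod`,
#'   `note`.
#' @export
track_clonotypes <- function(specific, bulk, lod_fraction = 1e-5) {
  require_columns(specific, c("chain", "protein_seq"), "specific clonotypes")
  key_cols <- intersect(c("clonotype_id", "chain", "protein_seq"),
                        names(specific))
  compartments <- sort(unique(bulk$compartment))
  if (length(compartments) == 0) {
    warn("bulk repertoire is empty: tracking is uninformative")
  }
  depth <- bulk |>
    group_by(.data$compartment) |>
    summarise(compartment_reads = sum(.data$read_count), .groups = "drop")
  hits <- bulk |>
    select("compartment", "chain", "protein_seq", "frequency", "rank") |>
    semi_join(specific, by = c("chain", "protein_seq"))
  out <- tidyr::crossing(distinct(specific[key_cols]),
                         compartment = compartments) |>
    left_join(hits, by = c("chain", "protein_seq", "compartment")) |>
    left_join(depth, by = "compartment") |>
    mutate(
      present = !is.na(.data$frequency),
      frequency = dplyr::coalesce(.data$frequency, 0),
      depth_blind = 1 / .data$compartment_reads > lod_fraction,
      below_lod = if_else(.data$present,
                          .data$frequency < lod_fraction,
                          .data$depth_blind),
      note = dplyr::case_when(
        .data$present & !.data$below_lod ~ "present",
        .data$present ~ "present below LOD",
        .data$depth_blind ~ "absent; depth insufficient for LOD",
        TRUE ~ "absent above LOD")
    ) |>
    select(-"depth_blind") |>
    arrange(across(all_of(key_cols)), .data$compartment)
  out
}

#' V-J segment usage of a repertoire
#'
#' Sums clonotype frequencies over each (V segment, J segment) pair and
#' attaches the chromosomal order index of each segment from the reference,
#' ready for a Manhattan-style recombination plot. Clonotypes lacking a
#' segment annotation are excluded and their summed frequency reported in
#' `accounting()`; an annotated segment missing from the reference is an
#' error naming the segment.
#'
#' @param clonotypes clonotype tibble with `v_segment`, `j_segment`,
#'   `frequency` (one compartment, or a `compartment` column to group by).
#' @param segments reference tibble with `class` ("V"/"J"), `segment`,
#'   `order_index` (unique within a class).
#' @return Long tibble: `v_segment`, `j_segment`, `v_order`, `j_order`,
#'   `frequency`.
#' @export
vj_usage <- function(clonotypes, segments) {
  require_columns(segments, c("class", "segment", "order_index"),
                  "segment reference")
  for (cl in c("V", "J")) {
    idx <- segments$order_index[segments$class == cl]
    if (anyDuplicated(idx)) {
      abort(paste0("duplicate order_index in segment class ", cl))
    }
  }
  vref <- filter(segments, .data$class == "V")
  jref <- filter(segments, .data$class == "J")
  group_cols <- intersect("compartment", names(clonotypes))

  annotated <- filter(clonotypes, !is.na(.data$v_segment),
                      !is.na(.data$j_segment))
  missing_v <- setdiff(annotated$v_segment, vref$segment)
  missing_j <- setdiff(annotated$j_segment, jref$segment)
  if (length(missing_v) + length(missing_j) > 0) {
    abort(paste0("segment(s) absent from reference: ",
                 paste(c(missing_v, missing_j), collapse = ", ")))
  }
  unannotated <- clonotypes |>
    filter(is.na(.data$v_segment) | is.na(.data$j_segment)) |>
    group_by(across(all_of(group_cols))) |>
    summarise(unannotated_frequency = sum(.data$frequency), .groups = "drop")

  out <- annotated |>
    group_by(across(all_of(c(group_cols, "v_segment", "j_segment")))) |>
    summarise(frequency = sum(.data$frequency), .groups = "drop") |>
    left_join(select(vref, v_segment = "segment", v_order = "order_index"),
              by = "v_segment") |>
    left_join(select(jref, j_segment = "segment", j_order = "order_index"),
              by = "j_segment") |>
    arrange(across(all_of(group_cols)), .data$v_order, .data$j_order)
  structure(out, accounting = unannotated)
}

#' @rdname vj_usage
#' @param usage long tibble from `vj_usage()` (a single compartment).
#' @return `vj_matrix()`: a numeric matrix, V segments in chromosomal order
#'   as rows, J segments as columns.
#' @export
vj_matrix <- function(usage) {
  if ("compartment" %in% names(usage) &&
      n_distinct(usage$compartment) > 1) {
    abort("vj_matrix() takes a single compartment")
  }
  v <- usage |> distinct(.data$v_segment, .data$v_order) |> arrange(.data$v_order)
  j <- usage |> distinct(.data$j_segment, .data$j_order) |> arrange(.data$j_order)
  m <- matrix(0, nrow(v), nrow(j), dimnames = list(v$v_segment, j$j_segment))
  m[cbind(match(usage$v_segment, v$v_segment),
          match(usage$j_segment, j$j_segment))] <- usage$frequency
  m
}

#' Descriptive diversity summary of a repertoire
#'
#' @param clonotypes clonotype tibble from [build_clonotypes()].
#' @param top_n how many top clonotype frequencies to report (default 10).
#' @return One row per compartment: `n_clonotypes`, `total_reads`,
#'   `dominance` (top clonotype frequency) and `top_frequencies`
#'   (list column).
#' @export
diversity_summary <- function(clonotypes, top_n = 10L) {
  group_cols <- intersect(c("compartment", "chain"), names(clonotypes))
  clonotypes |>
    group_by(across(all_of(group_cols))) |>
    summarise(
      n_clonotypes = n(),
      total_reads = sum(.data$read_count),
      dominance = if (n() > 0) max(.data$frequency) else NA_real_,
      top_frequencies = list(sort(.data$frequency, decreasing = TRUE)[
        seq_len(min(top_n, n()))]),
      .groups = "drop")
}
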