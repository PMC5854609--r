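# Readers and writers for the external formats the pipeline touches.
# TSV dialect throughout: tab-separated, UTF-8, header row required,
# '#'-prefixed comment lines ignored. Protein coordinates are 1-based,
# matching mutation labels like L75F.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' Read a proteome FASTA
#'
#' One record per FASTA entry; the protein identifier is the first
#' whitespace-delimited token of the header. Sequences are upper-cased and
#' must use the 20 standard residues plus 'X'.
#'
#' @param path FASTA file path.
#' @return A tibble with columns `protein_id`, `sequence`.
#' @export
read_proteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) abort(paste0("empty FASTA file: ", path))
  ids <- stringr::str_split_i(names(aa), "\\s+", 1)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(paste0("duplicate protein_id in proteome: ",
                 paste(dup, collapse = ", ")))
  }
  seqs <- toupper(as.character(aa))
  bad <- stringr::str_detect(seqs, paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"))
  if (any(bad)) {
    abort(paste0("non-standard residues in protein(s): ",
                 paste(ids[bad], collapse = ", ")))
  }
  if (any(nchar(seqs) == 0)) {
    abort(paste0("empty sequence for protein(s): ",
                 paste(ids[nchar(seqs) == 0], collapse = ", ")))
  }
  tibble(protein_id = ids, sequence = unname(seqs))
}

#' @rdname read_proteome
#' @param proteome tibble with `protein_id`, `sequence`.
#' @export
write_proteome_fasta <- function(proteome, path) {
  aa <- Biostrings::AAStringSet(setNames(proteome$sequence, proteome$protein_id))
  Biostrings::writeXStringSet(aa, path, width = 60)
  invisible(path)
}

read_neotrack_tsv <- function(path, col_types) {
  readr::read_tsv(path, comment = "#", col_types = col_types,
                  progress = FALSE, lazy = FALSE)
}

require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    abort(paste0(what, " is missing column(s): ", paste(miss, collapse = ", ")))
  }
  invisible(df)
}

#' Read a somatic missense mutation table
#'
#' Expects tab-separated columns `patient_id`, `gene`, `protein_id`,
#' `position` (1-based), `ref_aa`, `alt_aa`. Rows where `ref_aa == alt_aa`
#' (synonymous) are rejected with a message and recorded in
#' [rejections()]. A label of the form `gene_refPOSalt` (e.g. `HHAT_L75F`)
#' is built for each retained row. If `proteome` is supplied, positions and
#' reference residues are cross-checked and mismatches are an error.
#'
#' @param path TSV file path.
#' @param proteome optional proteome tibble for cross-checking.
#' @return A tibble of mutations with a `label` column; rejected rows in
#'   `rejections()`.
#' @export
read_mutation_table <- function(path, proteome = NULL) {
  df <- read_neotrack_tsv(path, readr::cols(
    patient_id = readr::col_character(),
    gene = readr::col_character(),
    protein_id = readr::col_character(),
    position = readr::col_integer(),
    ref_aa = readr::col_character(),
    alt_aa = readr::col_character()
  ))
  require_columns(df, c("patient_id", "gene", "protein_id", "position",
                        "ref_aa", "alt_aa"), "mutation table")
  if (any(is.na(df$position)) || any(df$position < 1)) {
    abort("mutation positions must be 1-based positive integers")
  }
  syn <- df$ref_aa == df$alt_aa
  rej <- NULL
  if (any(syn)) {
    rej <- df[syn, ] |> mutate(reason = "synonymous (ref_aa == alt_aa)")
    inform(paste0("rejected ", sum(syn),
                  " synonymous row(s) (ref_aa == alt_aa)"))
    df <- df[!syn, ]
  }
  df <- df |> mutate(label = paste0(.data$gene, "_", .data$ref_aa,
                                    .data$position, .data$alt_aa))
  if (!is.null(proteome)) check_mutations(df, proteome)
  structure(df, rejections = rej)
}

# Cross-check a mutation table against a proteome: position in range and
# reference residue matching. Errors identify the offending protein/position.
check_mutations <- function(mutations, proteome) {
  m <- left_join(mutations, proteome, by = "protein_id")
  if (any(is.na(m$sequence))) {
    abort(paste0("protein_id not in proteome: ",
                 paste(unique(m$protein_id[is.na(m$sequence)]), collapse = ", ")))
  }
  out_of_range <- m$position > nchar(m$sequence)
  if (any(out_of_range)) {
    bad <- m[which(out_of_range)[1], ]
    abort(paste0("mutation position ", bad$position,
                 " outside protein ", bad$protein_id,
                 " (length ", nchar(bad$sequence), ")"))
  }
  at <- substr(m$sequence, m$position, m$position)
  mismatch <- at != m$ref_aa
  if (any(mismatch)) {
    bad <- m[which(mismatch)[1], ]
    abort(paste0("reference residue mismatch for ", bad$protein_id,
                 " position ", bad$position, ": protein has ",
                 substr(bad$sequence, bad$position, bad$position),
                 ", mutation table says ", bad$ref_aa))
  }
  invisible(mutations)
}

#' @rdname read_mutation_table
#' @param mutations tibble as returned by `read_mutation_table()`.
#' @export
write_mutation_table <- function(mutations, path) {
  readr::write_tsv(select(mutations, "patient_id", "gene", "protein_id",
                          "position", "ref_aa", "alt_aa"), path)
  invisible(path)
}

#' Read a per-peptide per-allele predicted binding affinity table
#'
#' Columns `peptide`, `allele`, `ic50_nm` (nM, strictly positive).
#'
#' @param path TSV file path.
#' @return A tibble.
#' @export
read_affinity_table <- function(path) {
  df <- read_neotrack_tsv(path, readr::cols(
    peptide = readr::col_character(),
    allele = readr::col_character(),
    ic50_nm = readr::col_character()
  ))
  require_columns(df, c("peptide", "allele", "ic50_nm"), "affinity table")
  ic50 <- suppressWarnings(as.numeric(df$ic50_nm))
  if (any(is.na(ic50))) {
    abort(paste0("non-numeric ic50_nm value(s): ",
                 paste(head(unique(df$ic50_nm[is.na(ic50)]), 3), collapse = ", ")))
  }
  if (any(ic50 <= 0)) abort("ic50_nm values must be strictly positive")
  mutate(df, ic50_nm = ic50)
}

#' @rdname read_affinity_table
#' @param affinities tibble with `peptide`, `allele`, `ic50_nm`.
#' @export
write_affinity_table <- function(affinities, path) {
  readr::write_tsv(select(affinities, "peptide", "allele", "ic50_nm"), path)
  invisible(path)
}

#' Read a TCR amplicon read table
#'
#' Columns `sequence_nt`, `read_count` (>= 1), `chain` (`alpha`/`beta`),
#' `compartment`, and optionally `v_segment`, `j_segment`.
#'
#' @param path TSV file path.
#' @return A tibble of reads.
#' @export
read_repertoire_table <- function(path) {
  df <- read_neotrack_tsv(path, readr::cols(
    sequence_nt = readr::col_character(),
    read_count = readr::col_integer(),
    chain = readr::col_character(),
    compartment = readr::col_character(),
    .default = readr::col_character()
  ))
  require_columns(df, c("sequence_nt", "read_count", "chain", "compartment"),
                  "repertoire table")
  if (any(is.na(df$read_count)) || any(df$read_count < 1)) {
    abort("read_count must be an integer >= 1 for every row")
  }
  if (!all(df$chain %in% c("alpha", "beta"))) {
    abort("chain must be 'alpha' or 'beta'")
  }
  df
}

#' @rdname read_repertoire_table
#' @param reads tibble of reads.
#' @export
write_repertoire_table <- function(reads, path) {
  keep <- intersect(c("sequence_nt", "read_count", "chain", "compartment",
                      "v_segment", "j_segment"), names(reads))
  readr::write_tsv(select(reads, all_of(keep)), path)
  invisible(path)
}

#' Read assay tables
#'
#' ELISpot: `patient_id`, `compartment`, `condition`, `replicate`, `spots`,
#' `cells_per_well`. ICS: `patient_id`, `condition`, `ifng`, `tnfa`, `il2`,
#' `event_count`. Dose-response: `series_id`, `concentration`, `unit`,
#' `response`. Killing: `assay_id`, `experimental`, `spontaneous`, `total`.
#'
#' @param path TSV file path.
#' @return A tibble.
#' @export
read_elispot_table <- function(path) {
  df <- read_neotrack_tsv(path, readr::cols(
    spots = readr::col_double(), replicate = readr::col_integer(),
    cells_per_well = readr::col_integer(), .default = readr::col_character()
  ))
  require_columns(df, c("condition", "replicate", "spots"), "ELISpot table")
  if (any(df$spots < 0)) abort("spot counts must be non-negative")
  df
}

#' @rdname read_elispot_table
#' @export
read_ics_table <- function(path) {
  df <- read_neotrack_tsv(path, readr::cols(
    ifng = readr::col_logical(), tnfa = readr::col_logical(),
    il2 = readr::col_logical(), event_count = readr::col_integer(),
    .default = readr::col_character()
  ))
  require_columns(df, c("condition", "ifng", "tnfa", "il2", "event_count"),
                  "ICS table")
  if (any(df$event_count < 0)) abort("event counts must be non-negative")
  df
}

#' @rdname read_elispot_table
#' @export
read_dose_response_table <- function(path) {
  df <- read_neotrack_tsv(path, readr::cols(
    concentration = readr::col_double(), response = readr::col_double(),
    .default = readr::col_character()
  ))
  require_columns(df, c("series_id", "concentration", "unit", "response"),
                  "dose-response table")
  if (any(df$concentration <= 0)) abort("concentrations must be positive")
  df
}

#' @rdname read_elispot_table
#' @export
read_killing_table <- function(path) {
  df <- read_neotrack_tsv(path, readr::cols(
    experimental = readr::col_double(), spontaneous = readr::col_double(),
    total = readr::col_double(), .default = readr::col_character()
  ))
  require_columns(df, c("experimental", "spontaneous", "total"),
                  "killing table")
  df
}

#' @rdname read_elispot_table
#' @param table a tibble as read by the matching reader.
#' @export
write_assay_table <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}

#' Write / read a JSON results report
#'
#' Reports are plain lists of scalars, vectors and data frames; the schema
#' carries a version tag and, when present in the report, the seed used, so
#' every result is traceable to its configuration.
#'
#' @param report a named list.
#' @param path output JSON path.
#' @return `write_report()` returns `path` invisibly; `read_report()` the
#'   report list.
#' @export
write_report <- function(report, path) {
  stopifnot(is.list(report))
  report$schema_version <- report$schema_version %||% "1.0"
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null", na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
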