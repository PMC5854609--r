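# Small in-code fixtures shared across tests.

toy_proteome <- function() {
  hhat <- paste(rep("ACDEFGHIKL", 20), collapse = "") # 200 aa
  substr(hhat, 75, 75) <- "L" # so the worked mutation is L75F
  tibble::tibble(
    protein_id = c("HHAT_PROT", "TOY_PROT"),
    sequence = c(hhat, "ACDEFGHIKLMNPQRSTVWY"))
}

toy_mutation <- function(patient_id = "P1", gene = "HHAT",
                         protein_id = "HHAT_PROT", position = 75L,
                         ref_aa = NULL, alt_aa = "F") {
  prot <- toy_proteome()
  seq <- prot$sequence[prot$protein_id == protein_id]
  ref <- ref_aa %||% substr(seq, position, position)
  tibble::tibble(patient_id = patient_id, gene = gene,
                 protein_id = protein_id, position = position,
                 ref_aa = ref, alt_aa = alt_aa)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_4pl_series <- function(ec50, hill = 1, lower = 0, upper = 100,
                            concentrations = 10^seq(-3, 3, length.out = 8),
                            noise_sd = 0, unit = "ug/mL") {
  mu <- lower + (upper - lower) /
    (1 + 10^(hill * (log10(ec50) - log10(concentrations))))
  resp <- mu
  if (noise_sd > 0) {
    resp <- pmax(0, mu * (1 + stats::rnorm(length(mu), 0, noise_sd)))
  }
  tibble::tibble(concentration = concentrations, response = resp, unit = unit)
}

elispot_plate <- function(neg = c(10, 12, 14), conditions = list(),
                          patient_id = NULL) {
  rows <- list(tibble::tibble(condition = "No Ag",
                              replicate = seq_along(neg), spots = neg))
  for (nm in names(conditions)) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      condition = nm, replicate = seq_along(conditions[[nm]]),
      spots = conditions[[nm]])
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(patient_id)) out$patient_id <- patient_id
  out
}
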