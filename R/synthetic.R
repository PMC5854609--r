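# Synthetic cohort generator. Emulates the statistical structure the
# analysis assumes -- a ~19-patient cohort with 10-129 somatic missense
# mutations each, a minority of candidate peptides passing the 500 nM
# filter, ELISpot plates with planted responders, 4PL dose-response series
# with known EC50s, and multi-compartment TCR repertoires with specific
# clonotypes spiked at controlled frequencies -- so every pipeline stage is
# testable without any external data. Nothing here attempts biological
# realism of HLA binding; the toy affinity model is an arbitrary fixed
# scoring scheme.

AA20 <- setdiff(AA_ALPHABET, "X")

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the study conditions: 19 patients, 10-129 mutations per
#' patient, 6 HLA-I alleles per patient, 9/10-mer enumeration with a 500 nM
#' filter, triplicate ELISpot wells with a "No Ag" negative and PHA
#' viability control, dose-response series spanning 8 decades, and
#' repertoires of 1e5 reads per compartment with specific clonotypes spiked
#' at frequencies spanning 1e-6 to 1e-2 around the 1e-5 limit of detection.
#'
#' @param seed integer seed (required); all generators derive their random
#'   streams from it.
#' @param n_patients cohort size (default 19).
#' @param mutation_range inclusive bounds on per-patient missense mutation
#'   counts (default 10-129).
#' @param mutation_distribution `"uniform"` (integer-uniform over
#'   `mutation_range`) or `"lognormal"` (discretized, median 69, clipped to
#'   the range).
#' @param n_proteins,protein_length_range synthetic proteome shape.
#' @param x_rate per-residue rate of 'X' in the proteome, exercising the
#'   unsynthesizable-peptide exclusion (default 0.002).
#' @param alleles_per_patient HLA-I alleles drawn per patient (default 6).
#' @param peptide_lengths,affinity_threshold_nm,lod_fraction,
#'   min_reads_per_clonotype,elispot_sd_multiplier analysis constants, as
#'   in [run_config()].
#' @param elispot list: `neg_mean`, `dispersion` (negative-binomial size
#'   of negative and null wells), `effect` (responder mean shift in spots;
#'   validated responses in this assay class sit far above background, so
#'   the default is a strong 150-spot shift), `responder_dispersion`
#'   (responder wells are proportionally less dispersed), `replicates`,
#'   `n_null_conditions`, `cells_per_well`.
#' @param responders list: `n_pbl` responding patients, `n_til`, and
#'   `max_per_patient` validated epitopes per responder; one epitope is
#'   planted in both compartments, the rest are compartment-exclusive.
#' @param ec50 list: `n_pbl`/`n_til` clones, `log10_range` of PBL true
#'   EC50s (ug/mL), `til_shift` in log10 (TILs more avid), `noise`
#'   (multiplicative), `hill`, `upper`.
#' @param killing list: planted `lysis` fractions, `spontaneous`, `total`
#'   counts.
#' @param repertoire list: `reads` per compartment, `n_background`
#'   clonotypes, `zipf_s`, `syn_rate` (synonymous-variant injection),
#'   `oof_fraction` (out-of-frame reads), `n_singletons`, `n_invalid`,
#'   and `spikes` (tibble: clonotype_id, PBL, tumor, TIL planted
#'   frequencies).
#' @return A list with class `neotrack_cohort_config`.
#' @export
cohort_config <- function(seed,
                          n_patients = 19L,
                          mutation_range = c(10L, 129L),
                          mutation_distribution = c("uniform", "lognormal"),
                          n_proteins = 250L,
                          protein_length_range = c(150L, 600L),
                          x_rate = 0.002,
                          alleles_per_patient = 6L,
                          peptide_lengths = c(9L, 10L),
                          affinity_threshold_nm = 500,
                          lod_fraction = 1e-5,
                          min_reads_per_clonotype = 2L,
                          elispot_sd_multiplier = 3,
                          elispot = list(),
                          responders = list(),
                          ec50 = list(),
                          killing = list(),
                          repertoire = list()) {
  if (missing(seed) || is.null(seed)) abort("`seed` is required")
  mutation_distribution <- match.arg(mutation_distribution)
  elispot <- utils::modifyList(list(
    neg_mean = 8, dispersion = 4, effect = 150, responder_dispersion = 25,
    replicates = 3L,
    n_null_conditions = 2L, cells_per_well = 200000L), elispot)
  responders <- utils::modifyList(list(
    n_pbl = 6L, n_til = 4L, max_per_patient = 3L), responders)
  ec50 <- utils::modifyList(list(
    n_pbl = 6L, n_til = 6L, log10_range = c(-2, 0), til_shift = -1,
    noise = 0.1, hill = 1, upper = 100), ec50)
  killing <- utils::modifyList(list(
    lysis = c(0.2, 0.5, 0.8), spontaneous = 100, total = 1000), killing)
  repertoire <- utils::modifyList(list(
    reads = 100000L, sorted_reads = 20000L, n_background = 600L,
    n_pool = 1500L, zipf_s = 1, syn_rate = 0.2, oof_fraction = 0.05,
    n_singletons = 20L, n_invalid = 2L,
    spikes = tibble(
      clonotype_id = c("spike_til_tumor", "spike_pbl_tumor",
                       "spike_shared", "spike_trace"),
      PBL = c(0, 5e-3, 1e-4, 1e-6),
      tumor = c(1e-2, 1e-2, 1e-4, 0),
      TIL = c(5e-2, 0, 1e-4, 0))), repertoire)
  cfg <- list(seed = as.integer(seed), n_patients = as.integer(n_patients),
              mutation_range = as.integer(mutation_range),
              mutation_distribution = mutation_distribution,
              n_proteins = as.integer(n_proteins),
              protein_length_range = as.integer(protein_length_range),
              x_rate = x_rate,
              alleles_per_patient = as.integer(alleles_per_patient),
              peptide_lengths = as.integer(peptide_lengths),
              affinity_threshold_nm = affinity_threshold_nm,
              lod_fraction = lod_fraction,
              min_reads_per_clonotype = as.integer(min_reads_per_clonotype),
              elispot_sd_multiplier = elispot_sd_multiplier,
              elispot = elispot, responders = responders, ec50 = ec50,
              killing = killing, repertoire = repertoire)
  stopifnot(cfg$mutation_range[1] >= 1,
            cfg$mutation_range[2] >= cfg$mutation_range[1],
            all(cfg$peptide_lengths %in% 8:11),
            all(unlist(cfg$repertoire$spikes[, c("PBL", "tumor", "TIL")]) >= 0),
            all(unlist(cfg$repertoire$spikes[, c("PBL", "tumor", "TIL")]) < 1))
  structure(cfg, class = "neotrack_cohort_config")
}

HLA_POOL <- c("HLA-A*01:01", "HLA-A*02:01", "HLA-A*03:01", "HLA-A*11:01",
              "HLA-A*24:02", "HLA-B*07:02", "HLA-B*08:01", "HLA-B*15:01",
              "HLA-B*35:01", "HLA-C*04:01", "HLA-C*07:01", "HLA-C*07:02")

#' Deterministic toy peptide-MHC affinity model
#'
#' Maps each (peptide, allele) pair to a reproducible IC50-like value in nM
#' via a fixed per-allele position-specific residue score; the same pair
#' always yields the same value, independent of any global random seed, and
#' values span both sides of 500 nM (roughly 1% of 9/10-mers score at or
#' under 500 nM per allele). This is an arbitrary, non-biological scoring
#' scheme that stands where an external binding predictor's output table
#' would enter the pipeline; it predicts nothing about real HLA binding.
#'
#' @param peptides character vector of 8-11-mer peptides.
#' @param alleles character vector of allele names; every peptide is scored
#'   on every allele.
#' @return A tibble: `peptide`, `allele`, `ic50_nm`.
#' @export
toy_affinity <- function(peptides, alleles) {
  purrr::map(alleles, function(al) {
    tibble(peptide = peptides, allele = al,
           ic50_nm = toy_affinity_score(peptides, al))
  }) |> bind_rows()
}

toy_affinity_score <- function(peptides, allele) {
  lens <- nchar(peptides)
  out <- numeric(length(peptides))
  for (L in unique(lens)) {
    W <- toy_weight_matrix(allele, L)
    pep <- peptides[lens == L]
    idx <- matrix(match(unlist(strsplit(pep, "", fixed = TRUE)), AA20),
                  ncol = L, byrow = TRUE)
    z <- numeric(length(pep))
    for (p in seq_len(L)) z <- z + W[idx[, p], p]
    # log10 IC50 = 4.4 + 0.25 z; z ~ N(0, sqrt(L)) over random peptides
    out[lens == L] <- pmin(5e5, pmax(0.01, 10^(4.4 + 0.25 * z)))
  }
  out
}

toy_weight_matrix <- function(allele, L) {
  key <- sum(utf8ToInt(allele) * seq_along(utf8ToInt(allele))) * 131L + L
  withr::with_seed(key %% .Machine$integer.max, {
    matrix(rnorm(20 * L), nrow = 20, ncol = L, dimnames = list(AA20, NULL))
  })
}

#' Generate a synthetic patient cohort
#'
#' Builds a random proteome, per-patient somatic missense mutations (counts
#' drawn from the configured distribution over 10-129), per-patient HLA-I
#' allele sets, a toy-model affinity table covering every candidate mutant
#' peptide, the evaluation roster (all patients for blood; tumor material
#' for 14 of 19), and a truth record of every planted quantity: binders
#' passing the 500 nM filter (computed by an independent scan of the
#' affinity table, not by the pipeline's filter), and the planted responder
#' set per compartment.
#'
#' @param config a [cohort_config()].
#' @return A list of class `neotrack_cohort`: `proteome`, `mutations`,
#'   `patient_alleles`, `affinities`, `roster`, `truth`, `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "neotrack_cohort_config"))
  withr::with_seed(config$seed, {
    proteome <- random_proteome(config)
    patients <- sprintf("PT%02d", seq_len(config$n_patients))
    n_mut <- draw_mutation_counts(config)
    mutations <- purrr::map2(patients, n_mut,
                             ~ random_mutations(.x, .y, proteome)) |>
      bind_rows()
    patient_alleles <- purrr::map(patients, function(p) {
      tibble(patient_id = p,
             allele = sample(HLA_POOL, config$alleles_per_patient))
    }) |> bind_rows()

    candidates <- enumerate_mutant_peptides(mutations, proteome,
                                            config$peptide_lengths)
    affinities <- toy_affinity(
      sort(unique(c(candidates$mutant_seq, candidates$wt_seq))), HLA_POOL)

    truth_binders <- scan_binders(candidates, affinities, patient_alleles,
                                  config$affinity_threshold_nm)
    n_til_eval <- min(14L, config$n_patients)
    roster <- bind_rows(
      tibble(patient_id = patients, compartment = "PBL"),
      tibble(patient_id = patients[seq_len(n_til_eval)],
             compartment = "TIL_conventional"),
      tibble(patient_id = patients[seq_len(n_til_eval)],
             compartment = "TIL_primed"))
    responders <- plant_responders(truth_binders, patients,
                                   patients[seq_len(n_til_eval)],
                                   config$responders)

    structure(list(
      proteome = proteome, mutations = mutations,
      patient_alleles = patient_alleles, affinities = affinities,
      roster = roster,
      truth = list(seed = config$seed,
                   mutation_counts = tibble(patient_id = patients,
                                            mutational_load = n_mut),
                   binders = truth_binders, responders = responders),
      config = config), class = "neotrack_cohort")
  })
}

random_proteome <- function(config) {
  lens <- sample(config$protein_length_range[1]:config$protein_length_range[2],
                 config$n_proteins, replace = TRUE)
  seqs <- purrr::map_chr(lens, function(L) {
    aa <- sample(AA20, L, replace = TRUE)
    nx <- rbinom(1, L, config$x_rate)
    if (nx > 0) aa[sample(L, nx)] <- "X"
    paste(aa, collapse = "")
  })
  tibble(protein_id = sprintf("PROT%04d", seq_len(config$n_proteins)),
         sequence = seqs)
}

draw_mutation_counts <- function(config) {
  lo <- config$mutation_range[1]; hi <- config$mutation_range[2]
  if (config$mutation_distribution == "uniform") {
    sample(lo:hi, config$n_patients, replace = TRUE)
  } else {
    # discretized lognormal, median 69, clipped to the configured range
    pmin(hi, pmax(lo, round(exp(rnorm(config$n_patients, log(69), 0.5)))))
  }
}

random_mutations <- function(patient, n, proteome) {
  pick <- sample(nrow(proteome), n, replace = TRUE)
  pos <- purrr::map_int(pick, ~ sample(nchar(proteome$sequence[.x]), 1))
  ref <- substr(proteome$sequence[pick], pos, pos)
  # avoid mutating an 'X' residue and pick a different residue as alt
  while (any(ref == "X")) {
    redo <- ref == "X"
    pos[redo] <- purrr::map_int(pick[redo],
                                ~ sample(nchar(proteome$sequence[.x]), 1))
    ref <- substr(proteome$sequence[pick], pos, pos)
  }
  alt <- purrr::map_chr(ref, ~ sample(setdiff(AA20, .x), 1))
  tibble(patient_id = patient,
         gene = sub("PROT", "GENE", proteome$protein_id[pick]),
         protein_id = proteome$protein_id[pick],
         position = pos, ref_aa = ref, alt_aa = alt) |>
    distinct(.data$protein_id, .data$position, .keep_all = TRUE) |>
    mutate(label = paste0(.data$gene, "_", .data$ref_aa, .data$position,
                          .data$alt_aa))
}

# Truth-side binder scan, written in base R on purpose: a flat lookup over
# (patient, peptide, allele) rows that the pipeline's join-based filter is
# cross-checked against.
scan_binders <- function(candidates, affinities, patient_alleles, threshold) {
  aff <- setNames(affinities$ic50_nm,
                  paste(affinities$peptide, affinities$allele))
  rows <- list()
  for (p in unique(candidates$patient_id)) {
    cand <- candidates[candidates$patient_id == p, ]
    als <- patient_alleles$allele[patient_alleles$patient_id == p]
    for (al in als) {
      ic <- unname(aff[paste(cand$mutant_seq, al)])
      keep <- !is.na(ic) & ic <= threshold
      if (any(keep)) {
        rows[[length(rows) + 1]] <- tibble(
          patient_id = p, label = cand$label[keep],
          mutant_seq = cand$mutant_seq[keep], allele = al,
          ic50_nm = ic[keep])
      }
    }
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) return(out)
  distinct(out) |> arrange(.data$patient_id, .data$ic50_nm)
}

plant_responders <- function(binders, pbl_roster, til_roster, rcfg) {
  per_patient <- binders |>
    distinct(.data$patient_id, .data$label) |>
    group_by(.data$patient_id) |> summarise(n = n(), .groups = "drop")
  eligible_pbl <- intersect(pbl_roster, per_patient$patient_id)
  pbl_pat <- sample(eligible_pbl, min(rcfg$n_pbl, length(eligible_pbl)))
  pick_epitopes <- function(p, k) {
    labs <- unique(binders$label[binders$patient_id == p])
    sample(labs, min(k, length(labs)))
  }
  pbl <- purrr::map(pbl_pat, function(p) {
    tibble(patient_id = p,
           label = pick_epitopes(p, sample(rcfg$max_per_patient, 1)),
           compartment = "PBL")
  }) |> bind_rows()

  # TIL responders: one patient (and one epitope) shared with the PBL set,
  # the remainder exclusive to TILs
  shared_pool <- intersect(pbl_pat, til_roster)
  shared_pat <- if (length(shared_pool)) sample(shared_pool, 1) else character(0)
  other_pool <- setdiff(intersect(til_roster, per_patient$patient_id),
                        shared_pat)
  til_pat <- c(shared_pat,
               sample(other_pool, min(rcfg$n_til - length(shared_pat),
                                      length(other_pool))))
  til <- purrr::map(til_pat, function(p) {
    if (p %in% shared_pat) {
      labs <- sample(pbl$label[pbl$patient_id == p], 1)
    } else {
      avoid <- pbl$label[pbl$patient_id == p]
      pool <- setdiff(unique(binders$label[binders$patient_id == p]), avoid)
      labs <- sample(pool, min(sample(2, 1), length(pool)))
    }
    tibble(patient_id = p, label = labs, compartment = "TIL_conventional")
  }) |> bind_rows()
  bind_rows(pbl, til) |> arrange(.data$patient_id, .data$label)
}

#' Generate synthetic functional assay tables for a cohort
#'
#' ELISpot plates (triplicate wells, "No Ag" negative and PHA viability
#' controls, negative-binomial counts, planted responders shifted by the
#' configured effect), orthogonal validation records for every planted
#' responder, a stimulated/unstimulated ICS event-table pair with a planted
#' triple-producer-dominant profile, 4PL dose-response series with known
#' EC50s (TIL clones planted one decade more avid than PBL clones), and
#' chromium-release counts with planted lysis fractions.
#'
#' @param cohort a `neotrack_cohort` from [simulate_cohort()].
#' @return A list: `elispot`, `validations`, `ics` (list of
#'   stimulated/unstimulated tibbles), `dose_response`, `killing`, `truth`.
#' @export
simulate_assays <- function(cohort) {
  cfg <- cohort$config
  withr::with_seed(cfg$seed + 1L, {
    el <- simulate_elispot(cohort, cfg)
    validations <- cohort$truth$responders |>
      mutate(assay = if_else(runif(n()) < 0.5, "multimer", "ICS")) |>
      select("patient_id", "label", "assay")
    # guarantee some double-validated responses
    extra <- cohort$truth$responders |>
      slice_head(n = max(1, nrow(cohort$truth$responders) %/% 3)) |>
      mutate(assay = "multimer") |>
      select("patient_id", "label", "assay")
    validations <- distinct(bind_rows(validations, extra))
    ics <- simulate_ics()
    dr <- simulate_dose_response(cfg)
    kill <- tibble(assay_id = sprintf("K%02d", seq_along(cfg$killing$lysis)),
                   experimental = cfg$killing$spontaneous +
                     cfg$killing$lysis *
                     (cfg$killing$total - cfg$killing$spontaneous),
                   spontaneous = cfg$killing$spontaneous,
                   total = cfg$killing$total)
    list(elispot = el, validations = validations, ics = ics$tables,
         dose_response = dr$series, killing = kill,
         truth = list(responders = cohort$truth$responders,
                      ics_profile = ics$truth, ec50 = dr$truth,
                      lysis = cfg$killing$lysis))
  })
}

simulate_elispot <- function(cohort, cfg) {
  ecfg <- cfg$elispot
  resp <- cohort$truth$responders
  compartments <- c("PBL", "TIL_conventional")
  purrr::map(compartments, function(cmp) {
    roster <- unique(cohort$roster$patient_id[
      cohort$roster$compartment == cmp])
    purrr::map(roster, function(p) {
      planted <- resp$label[resp$patient_id == p & resp$compartment == cmp]
      binder_labels <- unique(cohort$truth$binders$label[
        cohort$truth$binders$patient_id == p])
      nulls <- head(setdiff(binder_labels, planted), ecfg$n_null_conditions)
      conds <- c(planted, nulls, "No Ag", "PHA")
      mu <- c(rep(ecfg$neg_mean + ecfg$effect, length(planted)),
              rep(ecfg$neg_mean, length(nulls) + 1), 500)
      disp <- c(rep(ecfg$responder_dispersion, length(planted)),
                rep(ecfg$dispersion, length(nulls) + 1), 50)
      purrr::map2(conds, seq_along(conds), function(cd, i) {
        tibble(patient_id = p, compartment = cmp, condition = cd,
               replicate = seq_len(ecfg$replicates),
               spots = rnbinom(ecfg$replicates, mu = mu[i], size = disp[i]),
               cells_per_well = ecfg$cells_per_well)
      }) |> bind_rows()
    }) |> bind_rows()
  }) |> bind_rows()
}

simulate_ics <- function(total = 20000L) {
  # planted excess frequencies over the 7 non-empty cytokine combinations
  # (triple-producer dominant), on top of a shared background
  combos <- tidyr::expand_grid(ifng = c(TRUE, FALSE), tnfa = c(TRUE, FALSE),
                               il2 = c(TRUE, FALSE)) |>
    filter(.data$ifng | .data$tnfa | .data$il2)
  planted <- c(0.45, 0.20, 0.12, 0.05, 0.10, 0.05, 0.03) # sums to 1
  names(planted) <- combo_label(combos$ifng, combos$tnfa, combos$il2)
  bg_frac <- c(rep(0.001, 7))
  response_mass <- 0.02
  stim_frac <- bg_frac + response_mass * planted
  make_table <- function(frac) {
    n_pos <- round(frac * total)
    bind_rows(
      mutate(combos, event_count = n_pos),
      tibble(ifng = FALSE, tnfa = FALSE, il2 = FALSE,
             event_count = total - sum(n_pos)))
  }
  list(tables = list(stimulated = make_table(stim_frac),
                     unstimulated = make_table(bg_frac)),
       truth = tibble(combination = names(planted), frequency = planted))
}

simulate_dose_response <- function(cfg) {
  ecfg <- cfg$ec50
  concentrations <- 30 / 10^(0:8) # 30 ug/mL down to 3e-7 ug/mL (0.3 pg/mL)
  groups <- c(rep("PBL", ecfg$n_pbl), rep("TIL", ecfg$n_til))
  le <- runif(length(groups), ecfg$log10_range[1], ecfg$log10_range[2]) +
    ifelse(groups == "TIL", ecfg$til_shift, 0)
  truth <- tibble(series_id = sprintf("DR%02d", seq_along(groups)),
                  group = groups, true_ec50 = 10^le)
  series <- purrr::pmap(truth, function(series_id, group, true_ec50) {
    mu <- fourpl(log10(concentrations), 0, ecfg$upper, ecfg$hill,
                 log10(true_ec50))
    tibble(series_id = series_id, group = group,
           concentration = concentrations, unit = "ug/mL",
           response = pmax(0, mu * (1 + rnorm(length(mu), 0, ecfg$noise))))
  }) |> bind_rows()
  list(series = series, truth = truth)
}

SENSE_CODONS <- {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

#' Generate synthetic multi-compartment TCR repertoires
#'
#' Builds bulk beta-chain repertoires for blood (PBL), tumor and expanded
#' TIL compartments plus a multimer-sorted sample, each sampled
#' multinomially at the configured depth from a Zipf-distributed background
#' clonotype pool with specific clonotypes spiked at planted per-compartment
#' frequencies — including deliberate absences that reproduce the
#' blood/tumor/TIL discordance patterns. Synonymous nucleotide variants of
#' the same clonotype are injected to exercise protein-level pooling, along
#' with out-of-frame reads, invalid-character reads and singleton reads at
#' configured rates. A spike whose expected read count is below one read
#' triggers a classed warning (`neotrack_spike_below_depth`): it may
#' legitimately vanish from the sample.
#'
#' @param config a [cohort_config()].
#' @return A list: `reads` (all compartments), `segments` (V/J reference
#'   with chromosomal order), `specific` (sorted-sample clonotypes keyed by
#'   chain and protein sequence), `truth` (planted spike frequencies and
#'   injection rates).
#' @export
simulate_repertoires <- function(config) {
  rcfg <- config$repertoire
  withr::with_seed(config$seed + 2L, {
    segments <- bind_rows(
      tibble(class = "V", segment = sprintf("TRBV%d", 1:12),
             order_index = sample(12)),
      tibble(class = "J", segment = sprintf("TRBJ%d", 1:6),
             order_index = sample(6)))
    pool <- clonotype_pool(rcfg$n_pool, segments)
    spikes <- rcfg$spikes
    spike_pool <- clonotype_pool(nrow(spikes), segments, prefix = "SPK")
    spike_pool$clonotype_id <- spikes$clonotype_id

    compartments <- c("PBL", "tumor", "TIL")
    reads <- purrr::map(compartments, function(cmp) {
      sample_compartment(cmp, spikes[[cmp]], spike_pool, pool, rcfg)
    }) |> bind_rows()
    # sorted sample: the TIL-dominant spikes plus a little background
    sorted_freq <- c(0.7, 0, 0.25, 0)
    reads <- bind_rows(reads,
                       sample_compartment("sorted", sorted_freq, spike_pool,
                                          pool, utils::modifyList(
                                            rcfg, list(reads = rcfg$sorted_reads,
                                                       n_background = 50L,
                                                       oof_fraction = 0.02,
                                                       n_singletons = 2L,
                                                       n_invalid = 0L))))
    specific <- spike_pool |>
      mutate(protein_seq = translate_nt(.data$sequence_nt)) |>
      select("clonotype_id", "chain", "protein_seq")
    truth <- list(
      spikes = tidyr::pivot_longer(
        bind_cols(spikes, tibble(sorted = sorted_freq)),
        c("PBL", "tumor", "TIL", "sorted"),
        names_to = "compartment", values_to = "frequency"),
      oof_fraction = rcfg$oof_fraction,
      syn_rate = rcfg$syn_rate, n_singletons = rcfg$n_singletons)
    list(reads = reads, segments = segments, specific = specific,
         truth = truth)
  })
}

clonotype_pool <- function(n, segments, prefix = "BG") {
  vseg <- segments$segment[segments$class == "V"]
  jseg <- segments$segment[segments$class == "J"]
  seqs <- character(0)
  while (length(unique(seqs)) < n) {  # resample until protein-unique
    lens <- sample(12:17, n - length(seqs), replace = TRUE)
    seqs <- c(seqs, purrr::map_chr(lens, function(L)
      paste(sample(SENSE_CODONS, L, replace = TRUE), collapse = "")))
    seqs <- seqs[!duplicated(translate_nt(seqs))]
  }
  tibble(clonotype_id = sprintf("%s%04d", prefix, seq_len(n)),
         sequence_nt = seqs[seq_len(n)], chain = "beta",
         v_segment = sample(vseg, n, replace = TRUE),
         j_segment = sample(jseg, n, replace = TRUE))
}

sample_compartment <- function(cmp, spike_freq, spike_pool, pool, rcfg) {
  n_total <- rcfg$reads
  n_oof <- rbinom(1, n_total, rcfg$oof_fraction)
  n_invalid_reads <- rcfg$n_invalid * 3L
  n_singletons <- rcfg$n_singletons
  n_inframe <- n_total - n_oof - n_invalid_reads - n_singletons

  low <- spike_freq > 0 & spike_freq * n_inframe < 1
  if (any(low)) {
    warn(paste0("spike(s) ", paste(spike_pool$clonotype_id[low], collapse = ", "),
                " in ", cmp, " planted below one expected read; ",
                "they may legitimately vanish"),
         class = "neotrack_spike_below_depth")
  }
  bg <- pool[sample(nrow(pool), rcfg$n_background), ]
  bg_freq <- (1 / seq_len(nrow(bg))^rcfg$zipf_s)
  bg_freq <- bg_freq / sum(bg_freq) * (1 - sum(spike_freq))
  members <- bind_rows(spike_pool, bg)
  freq <- c(spike_freq, bg_freq)
  counts <- as.integer(rmultinom(1, n_inframe, freq))
  keep <- counts > 0
  members <- members[keep, ]; counts <- counts[keep]

  rows <- tibble(sequence_nt = members$sequence_nt, read_count = counts,
                 chain = members$chain, compartment = cmp,
                 v_segment = members$v_segment,
                 j_segment = members$j_segment)
  rows <- inject_synonymous(rows, rcfg$syn_rate)

  oof <- oof_reads(n_oof, cmp)
  singletons <- clonotype_pool(n_singletons, tibble(
    class = c("V", "J"), segment = c(members$v_segment[1], members$j_segment[1]),
    order_index = c(1L, 1L)), prefix = paste0("SG", substr(cmp, 1, 2))) |>
    mutate(read_count = 1L, compartment = cmp) |>
    select("sequence_nt", "read_count", "chain", "compartment",
           "v_segment", "j_segment")
  invalid <- if (rcfg$n_invalid > 0) {
    tibble(sequence_nt = replicate(rcfg$n_invalid, paste0(
      paste(sample(SENSE_CODONS, 5, replace = TRUE), collapse = ""), "NNN")),
      read_count = 3L, chain = "beta", compartment = cmp,
      v_segment = NA_character_, j_segment = NA_character_)
  } else NULL
  bind_rows(rows, oof, singletons, invalid)
}

inject_synonymous <- function(rows, syn_rate) {
  big <- which(rows$read_count >= 10 & runif(nrow(rows)) < syn_rate)
  if (length(big) == 0) return(rows)
  variants <- purrr::map(big, function(i) {
    var_nt <- synonymous_variant(rows$sequence_nt[i])
    if (is.na(var_nt)) return(NULL)
    share <- rbinom(1, rows$read_count[i] - 1, 0.3)
    if (share == 0) return(NULL)
    v <- rows[i, ]; v$sequence_nt <- var_nt; v$read_count <- share
    v
  })
  rows$read_count[big] <- rows$read_count[big] -
    purrr::map_int(variants, ~ if (is.null(.x)) 0L else .x$read_count)
  bind_rows(rows, bind_rows(variants))
}

synonymous_variant <- function(nt) {
  gc <- Biostrings::GENETIC_CODE
  codons <- substring(nt, seq(1, nchar(nt), 3), seq(3, nchar(nt), 3))
  for (i in sample(seq_along(codons))) {
    alts <- setdiff(names(gc)[gc == gc[[codons[i]]]], codons[i])
    if (length(alts) > 0) {
      codons[i] <- sample(alts, 1)
      return(paste(codons, collapse = ""))
    }
  }
  NA_character_
}

oof_reads <- function(n_oof, cmp, n_seqs = 30L) {
  if (n_oof == 0) return(NULL)
  n_seqs <- min(n_seqs, n_oof)
  seqs <- purrr::map_chr(seq_len(n_seqs), function(i) {
    body <- paste(sample(SENSE_CODONS, 10, replace = TRUE), collapse = "")
    if (i %% 2 == 0) {
      paste0(substr(body, 1, 15), "TAA", substr(body, 16, 30)) # internal stop
    } else {
      substr(body, 1, 28) # length not a multiple of 3
    }
  })
  counts <- as.integer(rmultinom(1, n_oof, rep(1 / n_seqs, n_seqs)))
  keep <- counts > 0
  tibble(sequence_nt = seqs[keep], read_count = counts[keep],
         chain = "beta", compartment = cmp,
         v_segment = NA_character_, j_segment = NA_character_)
}

#' Write a synthetic cohort to disk in the pipeline's input formats
#'
#' Emits `proteome.fasta`, `mutations.tsv`, `affinities.tsv`,
#' `patient_alleles.tsv`, `roster.tsv` and `truth.json` under `dir`.
#'
#' @param cohort a `neotrack_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_proteome_fasta(cohort$proteome, file.path(dir, "proteome.fasta"))
  write_mutation_table(cohort$mutations, file.path(dir, "mutations.tsv"))
  write_affinity_table(cohort$affinities, file.path(dir, "affinities.tsv"))
  readr::write_tsv(cohort$patient_alleles,
                   file.path(dir, "patient_alleles.tsv"))
  readr::write_tsv(cohort$roster, file.path(dir, "roster.tsv"))
  write_report(list(seed = cohort$truth$seed,
                    mutation_counts = cohort$truth$mutation_counts,
                    binders = cohort$truth$binders,
                    responders = cohort$truth$responders),
               file.path(dir, "truth.json"))
  invisible(dir)
}
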