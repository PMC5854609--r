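test_that("cohort generation is deterministic under a fixed seed", {
  cfg <- cohort_config(seed = 123, n_patients = 4L, n_proteins = 40L)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_equal(c1$proteome, c2$proteome)
  expect_equal(c1$mutations, c2$mutations)
  expect_equal(c1$affinities, c2$affinities)
  expect_equal(c1$truth$responders, c2$truth$responders)
})

test_that("per-patient mutation counts honor the configured 10-129 bounds", {
  cfg <- cohort_config(seed = 5)
  co <- simulate_cohort(cfg)
  counts <- co$truth$mutation_counts$mutational_load
  expect_length(counts, 19)
  expect_true(all(counts >= 10 & counts <= 129))

  cfg_ln <- cohort_config(seed = 5, mutation_distribution = "lognormal",
                          n_patients = 30L)
  co_ln <- simulate_cohort(cfg_ln)
  expect_true(all(co_ln$truth$mutation_counts$mutational_load >= 10))
  expect_true(all(co_ln$truth$mutation_counts$mutational_load <= 129))
})

test_that("the toy affinity model is deterministic and spans the 500 nM cut", {
  peps <- c("ACDEFGHIK", "LMNPQRSTVW", "YACDEFGHI")
  a1 <- toy_affinity(peps, c("HLA-A*02:01", "HLA-B*07:02"))
  a2 <- toy_affinity(rev(peps), c("HLA-B*07:02", "HLA-A*02:01"))
  merged <- dplyr::inner_join(a1, a2, by = c("peptide", "allele"))
  expect_equal(merged$ic50_nm.x, merged$ic50_nm.y)
  expect_true(all(a1$ic50_nm > 0))

  withr::local_seed(2)
  many <- toy_affinity(replicate(400, random_protein_seq(9)), "HLA-A*02:01")
  frac <- mean(many$ic50_nm <= 500)
  expect_gt(frac, 0)   # some binders
  expect_lt(frac, 0.2) # a minority
})

test_that("the truth binder list equals the pipeline's affinity filter output", {
  cfg <- cohort_config(seed = 77, n_patients = 5L)
  co <- simulate_cohort(cfg)
  cand <- enumerate_mutant_peptides(co$mutations, co$proteome,
                                    cfg$peptide_lengths)
  hits <- apply_affinity_filter(cand, co$affinities, co$patient_alleles,
                                cfg$affinity_threshold_nm)
  got <- dplyr::arrange(
    dplyr::distinct(tibble::as_tibble(hits)[, c("patient_id", "mutant_seq",
                                                "allele", "ic50_nm")]),
    patient_id, mutant_seq, allele)
  want <- dplyr::arrange(
    dplyr::distinct(co$truth$binders[, c("patient_id", "mutant_seq",
                                         "allele", "ic50_nm")]),
    patient_id, mutant_seq, allele)
  expect_equal(as.data.frame(got), as.data.frame(want))
})

test_that("planted responders sit on the roster and among the binders", {
  co <- simulate_cohort(cohort_config(seed = 41))
  resp <- co$truth$responders
  expect_true(all(resp$patient_id %in% co$roster$patient_id))
  expect_true(all(paste(resp$patient_id, resp$label) %in%
                    paste(co$truth$binders$patient_id,
                          co$truth$binders$label)))
  # compartment-sharing: exactly one epitope planted in both compartments
  shared <- dplyr::count(resp, patient_id, label) |>
    dplyr::filter(n > 1)
  expect_equal(nrow(shared), 1)
})

test_that("assay generation matches its planted truths at zero noise", {
  cfg <- cohort_config(seed = 6, n_patients = 5L,
                       ec50 = list(noise = 0, n_pbl = 2L, n_til = 2L))
  co <- simulate_cohort(cfg)
  as <- simulate_assays(co)
  # killing counts invert exactly to the planted lysis fractions
  lys <- specific_lysis(as$killing)
  expect_equal(lys$lysis_pct, 100 * cfg$killing$lysis)
  # noise-free dose-response series invert to the planted EC50s
  for (sid in as$truth$ec50$series_id) {
    f <- fit_ec50(as$dose_response[as$dose_response$series_id == sid, ],
                  n_bootstrap = 0)
    truth <- as$truth$ec50$true_ec50[as$truth$ec50$series_id == sid]
    expect_equal(f$estimate$ec50, truth, tolerance = 1e-5)
  }
})

test_that("a zero responder effect makes responder wells exchangeable with nulls", {
  cfg <- cohort_config(seed = 9, n_patients = 6L,
                       elispot = list(effect = 0, responder_dispersion = 4))
  co <- simulate_cohort(cfg)
  as <- simulate_assays(co)
  resp_wells <- dplyr::semi_join(
    as$elispot,
    dplyr::mutate(co$truth$responders,
                  condition = label,
                  compartment = compartment),
    by = c("patient_id", "condition", "compartment"))
  neg_wells <- dplyr::filter(as$elispot, condition == "No Ag")
  # same negative-binomial law: compare means loosely (null effect)
  expect_lt(abs(mean(resp_wells$spots) - mean(neg_wells$spots)),
            3 * sd(neg_wells$spots) / sqrt(nrow(resp_wells)) * 2 + 2)
})

test_that("repertoire injection rates are recovered within binomial error", {
  cfg <- cohort_config(seed = 13)
  rp <- suppressWarnings(simulate_repertoires(cfg))
  tf <- translate_and_filter(rp$reads)
  acct_all <- accounting(tf)

  pbl_reads <- dplyr::filter(rp$reads, compartment == "PBL")
  tf_pbl <- translate_and_filter(pbl_reads)
  acct <- accounting(tf_pbl)
  n_tot <- sum(pbl_reads$read_count)
  oof_frac <- acct$reads[acct$category == "out_of_frame"] / n_tot
  p <- cfg$repertoire$oof_fraction
  se <- sqrt(p * (1 - p) / n_tot)
  expect_lt(abs(oof_frac - p), 4 * se)

  # spiked clonotypes at >= 2/depth recovered within 3 binomial SEs
  cl <- build_clonotypes(tf, cfg$min_reads_per_clonotype)
  for (i in seq_len(nrow(rp$truth$spikes))) {
    sp <- rp$truth$spikes[i, ]
    if (sp$frequency * 1e5 < 2) next
    prot <- rp$specific$protein_seq[rp$specific$clonotype_id ==
                                      sp$clonotype_id]
    got <- cl$frequency[cl$compartment == sp$compartment &
                          cl$protein_seq == prot]
    depth <- sum(cl$read_count[cl$compartment == sp$compartment])
    se_sp <- sqrt(sp$frequency * (1 - sp$frequency) / depth)
    expect_equal(length(got), 1)
    expect_lt(abs(got - sp$frequency), 3 * se_sp + 1e-9)
  }
})

test_that("a spike planted below one expected read warns with its class", {
  cfg <- cohort_config(seed = 25)
  expect_warning(simulate_repertoires(cfg),
                 class = "neotrack_spike_below_depth")
})

test_that("written cohorts are re-read identically by the io layer", {
  cfg <- cohort_config(seed = 55, n_patients = 3L, n_proteins = 30L)
  co <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  prot <- read_proteome(file.path(dir, "proteome.fasta"))
  expect_equal(as.data.frame(prot), as.data.frame(co$proteome))
  mut <- read_mutation_table(file.path(dir, "mutations.tsv"), prot)
  expect_equal(as.data.frame(mut[, names(co$mutations)]),
               as.data.frame(co$mutations))
  aff <- read_affinity_table(file.path(dir, "affinities.tsv"))
  expect_equal(as.data.frame(aff), as.data.frame(co$affinities))
  truth <- read_report(file.path(dir, "truth.json"))
  expect_equal(truth$seed, 55)
  expect_equal(tibble::as_tibble(truth$responders),
               co$truth$responders)
})
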