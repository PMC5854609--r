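test_that("an interior mutation yields 9 nine-mers and 10 ten-mers", {
  cand <- enumerate_mutant_peptides(toy_mutation(), toy_proteome(),
                                    c(9L, 10L))
  expect_equal(nrow(cand), 19)
  expect_equal(sum(cand$length == 9), 9)
  expect_equal(sum(cand$length == 10), 10)
  # every candidate contains the altered residue at its recorded offset
  expect_true(all(substr(cand$mutant_seq, cand$mut_offset,
                         cand$mut_offset) == "F"))
  expect_true(all(substr(cand$wt_seq, cand$mut_offset,
                         cand$mut_offset) == "L"))
  expect_equal(cand$label[1], "HHAT_L75F")
})

test_that("a mutation at position 1 gives a single window with offset 1", {
  mut <- toy_mutation(protein_id = "TOY_PROT", gene = "TOY", position = 1L,
                      alt_aa = "G")
  cand <- enumerate_mutant_peptides(mut, toy_proteome(), 9L)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$mut_offset, 1L)
  expect_equal(cand$start, 1L)
})

test_that("enumeration equals the brute-force window oracle on the 20-aa toy protein", {
  mut <- toy_mutation(protein_id = "TOY_PROT", gene = "TOY", position = 9L,
                      alt_aa = "R") # K9R
  cand <- enumerate_mutant_peptides(mut, toy_proteome(), c(9L, 10L))
  oracle <- oracle_windows(toy_proteome()$sequence[2], 9, "R", c(9L, 10L))
  got <- as.data.frame(cand[order(cand$length, cand$start),
                            c("length", "start", "mut_offset",
                              "mutant_seq", "wt_seq")])
  rownames(got) <- rownames(oracle) <- NULL
  expect_equal(got, oracle)
})

test_that("window counts follow the boundary law against the oracle on random proteins", {
  withr::local_seed(101)
  for (i in 1:200) {
    n <- sample(8:60, 1)
    seq <- random_protein_seq(n)
    pos <- sample(n, 1)
    ref <- substr(seq, pos, pos)
    alt <- sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], ref), 1)
    lengths <- sort(sample(8:11, sample(1:3, 1)))
    prot <- tibble::tibble(protein_id = "P", sequence = seq)
    mut <- tibble::tibble(patient_id = "pt", gene = "G", protein_id = "P",
                          position = pos, ref_aa = ref, alt_aa = alt)
    cand <- enumerate_mutant_peptides(mut, prot, lengths)
    oracle <- oracle_windows(seq, pos, alt, lengths)
    expect_equal(nrow(cand), nrow(oracle))
    expect_setequal(cand$mutant_seq, oracle$mutant_seq)
    for (L in lengths) {
      expect_equal(sum(cand$length == L),
                   max(0, min(pos, L, n - pos + 1, n - L + 1)))
    }
    # exactly one differing residue per pair
    d <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
                cand$mutant_seq, cand$wt_seq)
    expect_true(all(d == 1))
  }
})

test_that("windows containing X are excluded and tallied", {
  prot <- tibble::tibble(protein_id = "P",
                         sequence = "ACDEFGHIKXMNPQRSTVWYACDEF")
  mut <- tibble::tibble(patient_id = "pt", gene = "G", protein_id = "P",
                        position = 15L, ref_aa = "R", alt_aa = "K")
  cand <- enumerate_mutant_peptides(mut, prot, 9L)
  expect_true(all(!grepl("X", cand$mutant_seq)))
  rej <- rejections(cand)
  expect_gt(nrow(rej), 0)
  expect_true(all(grepl("X", rej$wt_seq)))
  # accepted + rejected covers every full window over the mutation
  expect_equal(nrow(cand) + nrow(rej), 9)
})

test_that("a mismatching reference residue is an error naming the site", {
  mut <- toy_mutation(ref_aa = "W")
  expect_error(enumerate_mutant_peptides(mut, toy_proteome()),
               "HHAT_PROT.*75")
})

test_that("pair_wildtype pools duplicate mutant peptides and keeps provenance", {
  # two mutations at the same site with the same alt yield identical windows
  m1 <- toy_mutation(gene = "G1")
  m2 <- toy_mutation(gene = "G2")
  cand <- enumerate_mutant_peptides(dplyr::bind_rows(m1, m2), toy_proteome())
  pairs <- pair_wildtype(cand)
  expect_equal(nrow(pairs), 19)
  expect_true(all(pairs$n_sources == 2))
  expect_setequal(pairs$sources[[1]], c("G1_L75F", "G2_L75F"))

  single <- pair_wildtype(enumerate_mutant_peptides(m1, toy_proteome()))
  expect_equal(nrow(single), 19)
  expect_true(all(single$mutant_seq != single$wt_seq))
})

test_that("the affinity filter keeps the 500 nM boundary inclusively", {
  cand <- enumerate_mutant_peptides(toy_mutation(), toy_proteome(), 9L)
  pred <- tibble::tibble(peptide = cand$mutant_seq[1:3],
                         allele = "HLA-A*02:01",
                         ic50_nm = c(500, 500.1, 12))
  hits <- apply_affinity_filter(cand, pred,
                                tibble::tibble(patient_id = "P1",
                                               allele = "HLA-A*02:01"),
                                threshold_nm = 500)
  expect_setequal(hits$ic50_nm, c(12, 500))
  expect_equal(hits$ic50_nm, sort(hits$ic50_nm)) # ascending IC50
  # unpredicted candidates are tallied, not dropped silently
  expect_equal(nrow(rejections(hits)), nrow(cand) - 3)
  expect_error(
    apply_affinity_filter(cand, pred,
                          tibble::tibble(patient_id = character(),
                                         allele = character())),
    "empty")
})

test_that("the filter is restricted to the patient's own alleles", {
  cand <- enumerate_mutant_peptides(toy_mutation(), toy_proteome(), 9L)
  pred <- tibble::tibble(peptide = cand$mutant_seq[1],
                         allele = c("HLA-A*02:01", "HLA-B*07:02"),
                         ic50_nm = c(10, 20))
  hits <- apply_affinity_filter(cand, pred,
                                tibble::tibble(patient_id = "P1",
                                               allele = "HLA-B*07:02"))
  expect_equal(hits$allele, "HLA-B*07:02")
})

test_that("raising the threshold never removes a retained pair", {
  withr::local_seed(7)
  cand <- enumerate_mutant_peptides(toy_mutation(), toy_proteome())
  pred <- toy_affinity(unique(cand$mutant_seq), c("HLA-A*02:01", "HLA-B*07:02"))
  alleles <- tibble::tibble(patient_id = "P1",
                            allele = c("HLA-A*02:01", "HLA-B*07:02"))
  prev <- NULL
  for (thr in c(50, 500, 5000, 50000)) {
    hits <- apply_affinity_filter(cand, pred, alleles, thr)
    key <- paste(hits$mutant_seq, hits$allele)
    if (!is.null(prev)) expect_true(all(prev %in% key))
    prev <- key
  }
})

test_that("predicted_load counts unique peptides per patient and keeps zeros", {
  cand <- enumerate_mutant_peptides(toy_mutation(), toy_proteome(), 9L)
  pred <- tibble::tibble(peptide = cand$mutant_seq[1], allele = "A",
                         ic50_nm = 10)
  hits <- apply_affinity_filter(cand, pred, c("A"))
  load <- predicted_load(hits, patients = c("P1", "P2"))
  expect_equal(load$n_peptides, c(1L, 0L))
  s <- load_summary(load)
  expect_equal(s$total_peptides, 1L)
  expect_equal(c(s$min_per_patient, s$max_per_patient), c(0L, 1L))

  # row-order invariance
  hits_rev <- hits[rev(seq_len(nrow(hits))), ]
  expect_equal(predicted_load(hits_rev, patients = c("P1", "P2")), load)
})
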