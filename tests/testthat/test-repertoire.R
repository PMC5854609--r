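read_row <- function(nt, n = 2L, compartment = "PBL", chain = "beta") {
  tibble::tibble(sequence_nt = nt, read_count = as.integer(n),
                 chain = chain, compartment = compartment)
}

test_that("translation uses frame 1 and filters out-of-frame reads", {
  reads <- dplyr::bind_rows(
    read_row("ATGGCT", 3),        # MA, in frame
    read_row("ATGTAAGCT", 4),     # internal stop
    read_row("ATGGCTA", 5),       # length 7
    read_row("ATGNNT", 6))        # invalid characters
  tf <- translate_and_filter(reads)
  expect_equal(tf$protein_seq, "MA")
  acct <- accounting(tf)
  expect_equal(acct$reads[acct$category == "retained"], 3)
  expect_equal(acct$reads[acct$category == "out_of_frame"], 9)
  expect_equal(acct$reads[acct$category == "invalid_character"], 6)
  # conservation at the translation step
  expect_equal(sum(acct$reads), sum(reads$read_count))
})

test_that("frame rescue recovers a shifted reading frame when asked", {
  stopped <- "TAAATGGCT" # frame 1: TAA stop; frame 2: AAA TGG -> KW
  expect_equal(nrow(translate_and_filter(read_row(stopped))), 0)
  rescued <- translate_and_filter(read_row(stopped), frame_rescue = TRUE)
  expect_equal(rescued$protein_seq, "KW")
})

test_that("clonotypes pool synonymous variants and drop singletons", {
  reads <- dplyr::bind_rows(
    read_row("TTAGCT", 3),  # LA
    read_row("CTGGCC", 4),  # LA via synonymous codons
    read_row("ATGAAA", 1))  # MK singleton
  tf <- translate_and_filter(reads)
  cl <- build_clonotypes(tf, min_reads = 2)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$protein_seq, "LA")
  expect_equal(cl$read_count, 7L)
  expect_equal(cl$frequency, 1)
  acct <- accounting(cl)
  expect_equal(acct$reads_discarded_singleton, 1L)
  expect_equal(acct$total_reads_in, 8L)
})

test_that("clonotype building equals a brute-force group-by on random reads", {
  withr::local_seed(14)
  codons <- neotrack:::SENSE_CODONS
  for (i in 1:20) {
    n <- sample(30:80, 1)
    nts <- vapply(seq_len(n), function(j)
      paste(sample(codons, sample(2:4, 1), replace = TRUE), collapse = ""),
      character(1))
    reads <- read_row(nts, n = sample(1:6, n, replace = TRUE))
    tf <- translate_and_filter(reads)
    cl <- build_clonotypes(tf, min_reads = 2)
    oracle <- oracle_clonotypes(tf$protein_seq, tf$read_count, 2)
    expect_equal(as.data.frame(cl[, c("protein_seq", "read_count",
                                      "frequency")]),
                 oracle, ignore_attr = TRUE)
  }
})

test_that("pooling is idempotent on its own output", {
  withr::local_seed(15)
  codons <- neotrack:::SENSE_CODONS
  nts <- replicate(40, paste(sample(codons, 3, replace = TRUE),
                             collapse = ""))
  reads <- read_row(nts, n = sample(1:5, 40, replace = TRUE))
  cl <- build_clonotypes(translate_and_filter(reads), min_reads = 2)
  again <- build_clonotypes(cl, min_reads = 2)
  expect_equal(as.data.frame(again), as.data.frame(cl),
               ignore_attr = TRUE)
})

test_that("ordering is deterministic: descending count then lexicographic", {
  reads <- dplyr::bind_rows(
    read_row("GCTGCT", 5), # AA
    read_row("TGTTGT", 5), # CC ties with AA
    read_row("GATGAT", 9)) # DD dominates
  cl <- build_clonotypes(translate_and_filter(reads), min_reads = 2)
  expect_equal(cl$protein_seq, c("DD", "AA", "CC"))
  expect_equal(cl$rank, 1:3)
})

test_that("tracking flags absence relative to the detection limit", {
  bulk <- build_clonotypes(translate_and_filter(dplyr::bind_rows(
    read_row("GCTGCT", 30000, "tumor"),
    read_row("GATGAT", 20000, "tumor"))), min_reads = 2)
  specific <- tibble::tibble(clonotype_id = "s1", chain = "beta",
                             protein_seq = "ATGGCT-missing")
  tr <- track_clonotypes(specific, bulk, lod_fraction = 1e-5)
  expect_false(tr$present)
  expect_equal(tr$frequency, 0)
  # 5e4 reads cannot resolve a 1e-5 frequency: absence is excused by depth
  expect_true(tr$below_lod)

  tr2 <- track_clonotypes(specific, bulk, lod_fraction = 2e-5)
  expect_false(tr2$below_lod)
  expect_equal(tr2$note, "absent above LOD")
})

test_that("tracking reproduces spiked ranks and discordance patterns", {
  cfg <- cohort_config(seed = 31)
  rp <- suppressWarnings(simulate_repertoires(cfg))
  tf <- translate_and_filter(rp$reads)
  cl <- build_clonotypes(tf, cfg$min_reads_per_clonotype)
  bulk <- dplyr::filter(cl, compartment != "sorted")
  # desk-scale LOD: two reads out of ~1e5
  tr <- track_clonotypes(rp$specific, bulk, lod_fraction = 2e-5)

  # rank of a present clonotype equals its position in a brute-force sort
  present <- dplyr::filter(tr, present)
  for (i in seq_len(nrow(present))) {
    cmp <- present$compartment[i]
    sub <- dplyr::filter(bulk, compartment == cmp)
    ord <- order(-sub$read_count, sub$protein_seq)
    expect_equal(present$rank[i],
                 which(sub$protein_seq[ord] == present$protein_seq[i]))
  }

  # planted discordance: TIL+tumor clone absent from blood, blood+tumor
  # clone absent from TIL cultures
  wide <- tidyr::pivot_wider(tr[, c("clonotype_id", "compartment", "present")],
                             names_from = "compartment",
                             values_from = "present")
  tt <- dplyr::filter(wide, clonotype_id == "spike_til_tumor")
  expect_true(tt$TIL && tt$tumor && !tt$PBL)
  pt <- dplyr::filter(wide, clonotype_id == "spike_pbl_tumor")
  expect_true(pt$PBL && pt$tumor && !pt$TIL)

  # row-order invariance of tracking
  tr_shuf <- track_clonotypes(rp$specific,
                              bulk[sample(nrow(bulk)), ],
                              lod_fraction = 2e-5)
  expect_equal(tr_shuf, tr)
})

test_that("V-J usage sums frequencies at chromosomal order with conservation", {
  segs <- tibble::tibble(class = c("V", "V", "J", "J"),
                         segment = c("TRBV1", "TRBV2", "TRBJ1", "TRBJ2"),
                         order_index = c(2L, 1L, 1L, 2L))
  one <- tibble::tibble(protein_seq = "AA", v_segment = "TRBV1",
                        j_segment = "TRBJ1", read_count = 10L,
                        frequency = 1)
  u <- vj_usage(one, segs)
  expect_equal(u$frequency, 1)
  m <- vj_matrix(u)
  expect_equal(sum(m), 1)
  expect_equal(dimnames(m), list("TRBV1", "TRBJ1"))

  expect_error(vj_usage(dplyr::mutate(one, v_segment = "TRBV99"), segs),
               "TRBV99")
  expect_error(vj_usage(one, dplyr::mutate(segs, order_index = 1L)),
               "duplicate")

  # unannotated clonotypes tallied, matrix total = annotated fraction
  mixed <- dplyr::bind_rows(one |> dplyr::mutate(frequency = 0.6),
                            tibble::tibble(protein_seq = "CC",
                                           v_segment = NA, j_segment = NA,
                                           read_count = 5L, frequency = 0.4))
  u2 <- vj_usage(mixed, segs)
  expect_equal(sum(u2$frequency), 0.6)
  expect_equal(accounting(u2)$unannotated_frequency, 0.4)
})

test_that("V-usage marginals equal direct per-segment summation", {
  withr::local_seed(44)
  cfg <- cohort_config(seed = 44)
  rp <- suppressWarnings(simulate_repertoires(cfg))
  cl <- build_clonotypes(translate_and_filter(rp$reads), 2)
  pbl <- dplyr::filter(cl, compartment == "PBL")
  u <- vj_usage(pbl, rp$segments)
  marg <- u |> dplyr::group_by(v_segment) |>
    dplyr::summarise(frequency = sum(frequency))
  ann <- dplyr::filter(pbl, !is.na(v_segment), !is.na(j_segment))
  want <- tapply(ann$frequency, ann$v_segment, sum)
  expect_equal(marg$frequency, as.numeric(want[marg$v_segment]))
})

test_that("diversity summary reports counts and equal-clone frequencies", {
  empty <- build_clonotypes(
    translate_and_filter(read_row("ATGGCT", 1)), min_reads = 2)
  expect_equal(nrow(empty), 0)
  d0 <- diversity_summary(empty)
  expect_equal(nrow(d0), 0)

  codons <- neotrack:::SENSE_CODONS
  withr::local_seed(9)
  nts <- character(0)
  while (length(nts) < 100) {
    cand <- replicate(150, paste(sample(codons, 4), collapse = ""))
    nts <- c(nts, cand)
    # keep one nucleotide sequence per distinct protein
    nts <- nts[!duplicated(vapply(nts, function(x)
      as.character(Biostrings::translate(Biostrings::DNAString(x))),
      character(1)))]
  }
  reads <- read_row(nts[1:100], n = 10L)
  cl <- build_clonotypes(translate_and_filter(reads), 2)
  d <- diversity_summary(cl)
  expect_equal(d$n_clonotypes, 100L)
  expect_equal(d$dominance, 0.01)
  expect_true(all(abs(d$top_frequencies[[1]] - 0.01) < 1e-12))
})
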