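# Independent oracles used by unit and acceptance tests. These deliberately
# avoid the package's own code paths: brute-force enumeration, direct
# arithmetic, exhaustive counting.

# Slide every window of every requested length over the protein and keep
# those covering the mutated position; substitute the altered residue.
oracle_windows <- function(sequence, position, alt_aa, lengths) {
  out <- list()
  n <- nchar(sequence)
  for (L in lengths) {
    if (L > n) next
    for (s in 1:(n - L + 1)) {
      e <- s + L - 1
      if (s <= position && position <= e) {
        wt <- substr(sequence, s, e)
        mut <- wt
        substr(mut, position - s + 1, position - s + 1) <- alt_aa
        out[[length(out) + 1]] <- data.frame(
          length = L, start = s, mut_offset = position - s + 1,
          mutant_seq = mut, wt_seq = wt, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(length = integer(), start = integer(),
                      mut_offset = integer(), mutant_seq = character(),
                      wt_seq = character()))
  }
  df <- do.call(rbind, out)
  df[order(df$length, df$start), ]
}

# Direct application of the ELISpot positivity rule to one plate.
oracle_elispot_decision <- function(cond_spots, neg_spots, multiplier = 3) {
  mean(cond_spots) > mean(neg_spots) + multiplier * sd(neg_spots)
}

# Least-squares grid search for the 4PL EC50 on a dense (log10 EC50, hill)
# lattice, asymptotes solved in closed form from the normal equations at
# every lattice point. Dense enough that its optimum approximates the
# global least-squares solution, making it an independent check of the
# package's grid-plus-refinement fitter.
oracle_grid_ec50 <- function(concentration, response,
                             n_le = 241,
                             hills = 10^seq(log10(0.05), log10(20),
                                            length.out = 48)) {
  lx <- log10(concentration)
  y <- response
  les <- seq(min(lx) - 1, max(lx) + 1, length.out = n_le)
  LE <- rep(les, times = length(hills))
  HH <- rep(hills, each = n_le)
  n <- length(lx)
  m <- length(LE)
  FF <- 1 / (1 + 10^(matrix(HH, n, m, byrow = TRUE) *
                       (matrix(LE, n, m, byrow = TRUE) - matrix(lx, n, m))))
  Sf <- colSums(FF)
  Sff <- colSums(FF^2)
  Sfy <- colSums(FF * y)
  Sy <- sum(y)
  den <- n * Sff - Sf^2
  b <- (n * Sfy - Sf * Sy) / den
  a <- (Sy - b * Sf) / n
  R <- matrix(y, n, m) - sweep(FF, 2, b, "*") -
    matrix(a, n, m, byrow = TRUE)
  sse <- colSums(R^2)
  sse[!is.finite(b) | b <= 0 | abs(den) < 1e-12] <- Inf
  10^LE[which.min(sse)]
}

# Two-sided Fisher p by full enumeration over all tables with the observed
# margins, probabilities from choose() directly.
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  n <- r1 + r2
  ks <- max(0, c1 - r2):min(r1, c1)
  prob <- choose(r1, ks) * choose(r2, c1 - ks) / choose(n, c1)
  p_obs <- choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
}

# Exact two-sided Mann-Whitney p by enumeration over all assignments of the
# pooled ranks to the first group.
oracle_mann_whitney_p <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  n1 <- length(x)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  all_idx <- utils::combn(length(pooled), n1)
  us <- apply(all_idx, 2, u_of)
  mu <- n1 * length(y) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Group reads by translated protein with base R only.
oracle_clonotypes <- function(protein_seq, read_count, min_reads = 2) {
  agg <- tapply(read_count, protein_seq, sum)
  agg <- agg[agg >= min_reads]
  agg <- agg[order(-agg, names(agg))]
  data.frame(protein_seq = names(agg), read_count = as.integer(agg),
             frequency = as.numeric(agg / sum(agg)),
             stringsAsFactors = FALSE)
}

random_protein_seq <- function(n, alphabet = setdiff(strsplit(
  "ACDEFGHIKLMNPQRSTVWY", "")[[1]], character(0))) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
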