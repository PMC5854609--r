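# Cohort-level aggregation: validated response tables, per-compartment
# prevalence, the PBL/TIL discordance landscape, and association statistics.

RESPONSE_COMPARTMENTS <- c("PBL", "TIL_conventional", "TIL_primed")

#' Assemble validated neo-epitope responses from assay calls
#'
#' A neo-epitope response is recorded for a (patient, peptide) when at
#' least one compartment is ELISpot-positive and — under the default
#' two-step rule — at least one orthogonal assay (multimer staining or
#' ICS) confirms it. Set `require_orthogonal = FALSE` for exploratory
#' ELISpot-only calling.
#'
#' @param calls tibble from [call_elispot()] with `patient_id`,
#'   `compartment` (one of PBL / TIL_conventional / TIL_primed),
#'   `condition` (neo-epitope label) and `positive`.
#' @param validations tibble with `patient_id`, `label`, `assay`
#'   (`"multimer"` or `"ICS"`).
#' @param require_orthogonal require an orthogonal validation
#'   (default TRUE).
#' @return A tibble with one row per responding (patient, neo-epitope):
#'   logical columns `pbl`, `til_conventional`, `til_primed`, list column
#'   `assays`, and `validated`.
#' @export
build_responses <- function(calls, validations = NULL,
                            require_orthogonal = TRUE) {
  require_columns(calls, c("patient_id", "compartment", "condition",
                           "positive"), "ELISpot calls")
  pos <- calls |>
    filter(.data$role == "test", !is.na(.data$positive), .data$positive)
  if (nrow(pos) == 0) {
    return(tibble(patient_id = character(), label = character(),
                  pbl = logical(), til_conventional = logical(),
                  til_primed = logical(), assays = list(),
                  validated = logical()))
  }
  flags <- pos |>
    distinct(.data$patient_id, label = .data$condition, .data$compartment) |>
    mutate(compartment = tolower(.data$compartment)) |>
    mutate(flag = TRUE) |>
    tidyr::pivot_wider(names_from = "compartment", values_from = "flag",
                       values_fill = FALSE)
  for (cmp in tolower(RESPONSE_COMPARTMENTS)) {
    if (!cmp %in% names(flags)) flags[[cmp]] <- FALSE
  }
  if (is.null(validations)) {
    validations <- tibble(patient_id = character(), label = character(),
                          assay = character())
  }
  val <- validations |>
    group_by(.data$patient_id, .data$label) |>
    summarise(orthogonal = list(sort(unique(.data$assay))), .groups = "drop")
  out <- flags |>
    left_join(val, by = c("patient_id", "label")) |>
    mutate(
      assays = purrr::map(.data$orthogonal,
                          ~ c("ELISpot", .x %||% character(0))),
      validated = purrr::map_lgl(.data$orthogonal, ~ length(.x %||% c()) > 0)
    ) |>
    select("patient_id", "label", pbl = "pbl",
           til_conventional = "til_conventional",
           til_primed = "til_primed", "assays", "validated")
  if (require_orthogonal) out <- filter(out, .data$validated)
  arrange(out, .data$patient_id, .data$label)
}

#' Per-compartment prevalence of neo-epitope responses
#'
#' Fraction of evaluated patients with at least one validated response in
#' each compartment. Denominators come from the roster of evaluated
#' patients — they differ by compartment when, e.g., tumor material was
#' unavailable for some patients — never from the response list.
#'
#' @param responses tibble from [build_responses()].
#' @param roster tibble with `patient_id`, `compartment` listing every
#'   patient evaluated in each compartment.
#' @return One row per compartment: `n_evaluated`, `n_responders`,
#'   `fraction`.
#' @export
summarize_prevalence <- function(responses, roster) {
  require_columns(roster, c("patient_id", "compartment"), "roster")
  unknown <- setdiff(responses$patient_id, roster$patient_id)
  if (length(unknown) > 0) {
    abort(paste0("response for patient(s) not on the roster: ",
                 paste(unknown, collapse = ", ")))
  }
  long <- responses |>
    tidyr::pivot_longer(all_of(tolower(RESPONSE_COMPARTMENTS)),
                        names_to = "compartment", values_to = "positive") |>
    filter(.data$positive)
  roster |>
    mutate(compartment = tolower(.data$compartment)) |>
    group_by(.data$compartment) |>
    summarise(n_evaluated = n_distinct(.data$patient_id), .groups = "drop") |>
    left_join(long |>
                group_by(.data$compartment) |>
                summarise(n_responders = n_distinct(.data$patient_id),
                          .groups = "drop"),
              by = "compartment") |>
    mutate(n_responders = dplyr::coalesce(.data$n_responders, 0L),
           fraction = .data$n_responders / .data$n_evaluated)
}

#' Classify each neo-epitope response by compartment discordance
#'
#' Labels every validated response as detected in both PBL and TIL, in
#' PBLs only, in TILs only, or in neither — the compartment-sharing
#' landscape. The conventional-TIL landscape uses IL-2-expanded TILs only;
#' the primed variant also counts peptide-primed TIL cultures as TIL
#' detection.
#'
#' @param responses tibble from [build_responses()].
#' @return The input with `category` and `category_primed` columns; use
#'   [discordance_counts()] for the per-category tallies.
#' @export
discordance_landscape <- function(responses) {
  categ <- function(pbl, til) {
    dplyr::case_when(pbl & til ~ "both", pbl ~ "PBL-only",
                     til ~ "TIL-only", TRUE ~ "none")
  }
  responses |>
    mutate(
      category = categ(.data$pbl, .data$til_conventional),
      category_primed = categ(.data$pbl,
                              .data$til_conventional | .data$til_primed))
}

#' @rdname discordance_landscape
#' @param landscape tibble from `discordance_landscape()`.
#' @param variant `"conventional"` or `"primed"`.
#' @return `discordance_counts()`: one row per category with `n`, plus the
#'   exclusive total (PBL-only + TIL-only).
#' @export
discordance_counts <- function(landscape, variant = c("conventional", "primed")) {
  variant <- match.arg(variant)
  col <- if (variant == "conventional") "category" else "category_primed"
  counts <- landscape |>
    count(category = .data[[col]]) |>
    tidyr::complete(category = c("both", "PBL-only", "TIL-only", "none"),
                    fill = list(n = 0L))
  exclusive <- sum(counts$n[counts$category %in% c("PBL-only", "TIL-only")])
  structure(counts, exclusive = exclusive)
}

#' Fisher's exact test for a 2x2 contingency table
#'
#' Two-sided p-value by the point-probability method: the hypergeometric
#' probabilities of all tables with the observed margins that are no more
#' probable than the observed table are summed (the convention of most
#' statistical software; probabilities are compared with a 1e-7 relative
#' tolerance so floating-point ties count). The conditional maximum
#' likelihood odds ratio is reported. A table with an empty row or column
#' margin carries no information: p = 1 and the odds ratio is flagged
#' undefined.
#'
#' @param table a 2x2 matrix, or a length-4 vector `c(a, b, c, d)` filled
#'   row-wise.
#' @param odds_ratio compute the conditional-MLE odds ratio (default TRUE;
#'   disable in tight loops that only need the p-value).
#' @return A one-row tibble: `p_value`, `odds_ratio`, `method`,
#'   `degenerate`.
#' @export
fisher_exact <- function(table, odds_ratio = TRUE) {
  if (is.data.frame(table)) table <- as.matrix(table)
  if (!is.matrix(table)) table <- matrix(table, 2, 2, byrow = TRUE)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0),
            all(table == round(table)))
  a <- table[1, 1]
  r1 <- sum(table[1, ]); r2 <- sum(table[2, ])
  c1 <- sum(table[, 1]); c2 <- sum(table[, 2])
  if (min(r1, r2, c1, c2) == 0) {
    return(fisher_row(1, NA_real_, TRUE))
  }
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- if (odds_ratio) unname(stats::fisher.test(table)$estimate) else NA_real_
  fisher_row(p, or, FALSE)
}

fisher_row <- function(p, or, degenerate) {
  tibble::new_tibble(list(p_value = p, odds_ratio = or,
                          method = "fisher_point_probability",
                          degenerate = degenerate), nrow = 1L)
}

#' Association between mutational load and predicted neo-epitope load
#'
#' Ordinary least-squares regression of the per-patient predicted
#' neo-epitope count on the non-synonymous mutational load, with the
#' two-sided t-test on the slope and a seeded permutation p-value (labels
#' of the response permuted) reported alongside.
#'
#' @param loads tibble with one row per patient and numeric columns
#'   `mutational_load` and `neoepitope_load`.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @return A one-row tibble: `n`, `slope`, `se`, `t`, `p_value`,
#'   `p_permutation`, `r_squared`.
#' @export
load_association <- function(loads, n_perm = 999, seed = NULL) {
  require_columns(loads, c("mutational_load", "neoepitope_load"),
                  "load table")
  x <- loads$mutational_load
  y <- loads$neoepitope_load
  if (length(x) < 3) abort("load association needs at least 3 patients")
  if (sd(x) == 0) abort("mutational load has zero variance")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  slope <- sm$coefficients["x", "Estimate"]
  perm <- function() {
    vx <- sum((x - mean(x))^2)
    purrr::map_dbl(seq_len(n_perm), function(i) {
      yp <- sample(y)
      sum((x - mean(x)) * (yp - mean(yp))) / vx
    })
  }
  b_perm <- if (is.null(seed)) perm() else withr::with_seed(seed, perm())
  p_perm <- (1 + sum(abs(b_perm) >= abs(slope))) / (n_perm + 1)
  tibble(n = length(x), slope = slope,
         se = sm$coefficients["x", "Std. Error"],
         t = sm$coefficients["x", "t value"],
         p_value = sm$coefficients["x", "Pr(>|t|)"],
         p_permutation = p_perm, r_squared = sm$r.squared)
}
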