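#' Call T-cell responses from ELISpot replicate spot counts
#'
#' A condition is positive when its mean spot count exceeds the negative
#' control ("No Ag") mean plus `multiplier` times the negative control's
#' standard deviation — the study's 3-SD rule. The standard deviation is the
#' sample (n-1) estimate; with a zero-variance negative the rule degenerates
#' to a strict `mean > neg_mean` comparison. The viability control (PHA) is
#' excluded from calling but reported. Conditions with fewer than two
#' replicates still receive a call, flagged `low_replicates`.
#'
#' @param plates long tibble with columns `condition` and `spots` (one row
#'   per well); optional `patient_id` / `compartment` columns define
#'   independent plates, each with its own negative control.
#' @param negative_label condition label of the negative control
#'   (default `"No Ag"`).
#' @param multiplier SD multiplier in the threshold (default 3).
#' @param viability_label condition reported but excluded from calling
#'   (default `"PHA"`).
#' @return A tibble with one row per condition: `n_replicates`,
#'   `mean_spots`, `neg_mean`, `neg_sd`, `threshold`, `positive` (NA for
#'   controls), `role`, `low_replicates`.
#' @export
call_elispot <- function(plates, negative_label = "No Ag", multiplier = 3,
                         viability_label = "PHA") {
  group_cols <- intersect(c("patient_id", "compartment"), names(plates))
  neg <- plates |>
    filter(.data$condition == negative_label) |>
    group_by(across(all_of(group_cols))) |>
    summarise(neg_n = n(), neg_mean = mean(.data$spots),
              neg_sd = sd(.data$spots), .groups = "drop")
  plate_ids <- distinct(plates, across(all_of(group_cols)))
  if (nrow(neg) < nrow(plate_ids)) {
    abort(paste0("plate(s) without a negative control condition '",
                 negative_label, "'"))
  }
  if (any(neg$neg_n < 2)) {
    abort(paste0("negative control '", negative_label,
                 "' needs >= 2 replicates on every plate"))
  }
  calls <- plates |>
    group_by(across(all_of(c(group_cols, "condition")))) |>
    summarise(n_replicates = n(), mean_spots = mean(.data$spots),
              .groups = "drop")
  calls <- if (length(group_cols) > 0) {
    left_join(calls, neg, by = group_cols)
  } else {
    dplyr::cross_join(calls, neg)
  }
  calls <- calls |>
    mutate(
      threshold = .data$neg_mean + multiplier * .data$neg_sd,
      role = dplyr::case_when(
        .data$condition == negative_label ~ "negative_control",
        .data$condition == viability_label ~ "viability_control",
        TRUE ~ "test"),
      positive = if_else(.data$role == "test",
                         .data$mean_spots > .data$threshold, NA),
      low_replicates = .data$n_replicates < 2
    ) |>
    select(-"neg_n")
  if (any(calls$low_replicates)) {
    warn(paste0(sum(calls$low_replicates),
                " condition(s) called from fewer than 2 replicates"))
  }
  calls
}
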