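# Polyfunctionality decomposition of intracellular cytokine staining (ICS)
# over the fixed cytokine set {IFNg, TNFa, IL-2}.

CYTOKINES <- c("ifng", "tnfa", "il2")

#' Decompose ICS polyfunctionality into cytokine-combination frequencies
#'
#' Events (cells) are classified by which of IFNg, TNFa and IL-2 they
#' produce. For each of the 7 non-empty combinations the unstimulated
#' ("No Ag") fraction is subtracted from the stimulated fraction, negative
#' differences are floored at zero, and the result is renormalized to sum
#' to 1 over the 7 combinations. If nothing survives background
#' subtraction the summary is flagged empty.
#'
#' @param stimulated,unstimulated tibbles with logical columns `ifng`,
#'   `tnfa`, `il2` and optionally `event_count` (aggregated combination
#'   counts; defaults to one event per row).
#' @return A tibble with one row per non-empty combination: the three
#'   cytokine flags, `combination`, `n_cytokines`, `frequency`. Attributes:
#'   `empty` (logical), `total_events` (stimulated well),
#'   `producer_summary` (frequency mass of triple/double/single producers).
#' @export
decompose_polyfunctionality <- function(stimulated, unstimulated) {
  stim <- combo_fractions(stimulated)
  unstim <- combo_fractions(unstimulated)
  out <- stim |>
    left_join(select(unstim, all_of(CYTOKINES), bg_fraction = "fraction"),
              by = CYTOKINES) |>
    filter(.data$n_cytokines > 0) |>
    mutate(excess = pmax(.data$fraction - .data$bg_fraction, 0))
  total <- sum(out$excess)
  empty <- total <= 0
  out <- out |>
    mutate(frequency = if (empty) 0 else .data$excess / total) |>
    select(all_of(CYTOKINES), "combination", "n_cytokines", "frequency")
  producers <- out |>
    group_by(.data$n_cytokines) |>
    summarise(frequency = sum(.data$frequency), .groups = "drop")
  structure(out, empty = empty,
            total_events = attr(stim, "total_events"),
            producer_summary = producers)
}

combo_fractions <- function(events) {
  for (cy in CYTOKINES) {
    if (!cy %in% names(events)) abort(paste0("missing cytokine column: ", cy))
  }
  if (!"event_count" %in% names(events)) {
    events <- mutate(events, event_count = 1L)
  }
  total <- sum(events$event_count)
  if (total == 0) abort("event table has zero events")
  grid <- tidyr::expand_grid(ifng = c(TRUE, FALSE), tnfa = c(TRUE, FALSE),
                             il2 = c(TRUE, FALSE))
  fr <- events |>
    mutate(across(all_of(CYTOKINES), as.logical)) |>
    group_by(across(all_of(CYTOKINES))) |>
    summarise(n = sum(.data$event_count), .groups = "drop")
  out <- grid |>
    left_join(fr, by = CYTOKINES) |>
    mutate(n = dplyr::coalesce(.data$n, 0L),
           fraction = .data$n / total,
           n_cytokines = .data$ifng + .data$tnfa + .data$il2,
           combination = combo_label(.data$ifng, .data$tnfa, .data$il2)) |>
    arrange(desc(.data$n_cytokines), .data$combination)
  structure(out, total_events = total)
}

combo_label <- function(ifng, tnfa, il2) {
  lab <- function(i, t, l) {
    parts <- c("IFNg", "TNFa", "IL2")[c(i, t, l)]
    if (length(parts) == 0) "none" else paste(parts, collapse = "+")
  }
  purrr::pmap_chr(list(ifng, tnfa, il2), lab)
}
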