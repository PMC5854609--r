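#' Percent specific lysis from chromium-release counts
#'
#' Computes 100 * (experimental - spontaneous) / (total - spontaneous) for
#' each assay row. The denominator must be positive (total release strictly
#' above spontaneous). Values outside [0, 100] are possible with noisy
#' counts and are kept but flagged `out_of_range`.
#'
#' @param assays tibble with numeric columns `experimental`, `spontaneous`,
#'   `total` (counts); other columns are carried through.
#' @return The input with `lysis_pct` and `out_of_range` columns added.
#' @export
specific_lysis <- function(assays) {
  require_columns(assays, c("experimental", "spontaneous", "total"),
                  "killing assay table")
  bad <- assays$total <= assays$spontaneous
  if (any(bad)) {
    abort(paste0("total release must exceed spontaneous release (row ",
                 which(bad)[1], ": total ", assays$total[which(bad)[1]],
                 ", spontaneous ", assays$spontaneous[which(bad)[1]], ")"))
  }
  out <- assays |>
    mutate(lysis_pct = 100 * (.data$experimental - .data$spontaneous) /
             (.data$total - .data$spontaneous),
           out_of_range = .data$lysis_pct < 0 | .data$lysis_pct > 100)
  if (any(out$out_of_range)) {
    warn(paste0(sum(out$out_of_range),
                " lysis value(s) outside [0, 100] (measurement noise)"))
  }
  out
}
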