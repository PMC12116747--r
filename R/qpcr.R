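# Relative distal-PAS usage from isoform-specific RT-qPCR Ct values.

#' Relative dPAS usage from CDS / distal primer Ct values
#'
#' Implements the ddCt design for isoform-specific 3' UTR quantification:
#' one primer pair targets the CDS (total transcripts, the internal
#' reference), the other targets sequence immediately upstream of the
#' distal PAS (long-3'-UTR transcripts only). Per condition,
#' `dCt = mean Ct(distal) - mean Ct(CDS)`; relative usage is
#' `2^-(dCt - dCt_reference)`, so the reference condition is exactly 1 by
#' construction and a one-cycle drop in dCt doubles the usage. Replicates
#' are averaged on the Ct scale and their SD is propagated to the usage
#' scale by the delta method (amplification efficiency fixed at 2).
#'
#' @param ct Tibble of Ct records: columns `condition`, `primer`
#'   (`"CDS"` or `"distal"`), `ct` (one row per replicate well).
#' @param reference_condition Condition whose usage defines 1.
#' @return A tibble per condition: `condition`, `delta_ct`,
#'   `delta_delta_ct`, `rel_usage`, `se` (delta-method standard error of
#'   `rel_usage`; `NA` with single replicates).
#' @export
dpas_usage <- function(ct, reference_condition) {
  required <- c("condition", "primer", "ct")
  missing <- setdiff(required, names(ct))
  if (length(missing) > 0) {
    abort(sprintf("`ct` lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  if (any(ct$ct <= 0)) abort("Ct values must be positive cycle numbers")
  if (!all(ct$primer %in% c("CDS", "distal"))) {
    abort("`primer` must be 'CDS' or 'distal'")
  }
  if (!reference_condition %in% ct$condition) {
    abort(sprintf("reference condition '%s' absent from `ct`",
                  reference_condition))
  }
  per <- ct %>%
    group_by(.data$condition, .data$primer) %>%
    summarise(mean_ct = mean(.data$ct),
              var_mean = ifelse(n() > 1, stats::var(.data$ct) / n(), NA_real_),
              .groups = "drop")
  incomplete <- per %>%
    count(.data$condition) %>%
    filter(.data$n < 2)
  if (nrow(incomplete) > 0) {
    abort(sprintf("condition '%s' is missing a primer set (needs CDS and distal)",
                  incomplete$condition[1]))
  }
  dct <- per %>%
    tidyr::pivot_wider(id_cols = "condition", names_from = "primer",
                       values_from = c("mean_ct", "var_mean")) %>%
    mutate(delta_ct = .data$mean_ct_distal - .data$mean_ct_CDS,
           var_delta = .data$var_mean_distal + .data$var_mean_CDS)
  ref <- dct$delta_ct[dct$condition == reference_condition]
  dct %>%
    mutate(delta_delta_ct = .data$delta_ct - ref,
           rel_usage = 2^(-.data$delta_delta_ct),
           se = log(2) * .data$rel_usage * sqrt(.data$var_delta)) %>%
    select("condition", "delta_ct", "delta_delta_ct", "rel_usage", "se")
}
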