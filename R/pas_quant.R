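# Per-sample TPM normalisation and low-signal site filtering.

#' Compute tags-per-million for every poly(A) site
#'
#' TPM is computed per sample as `count / total_count * 1e6`, where the
#' denominator is the sample's total counted 3'-end reads *before* any site
#' exclusion, so each sample's TPM column sums to exactly one million prior
#' to filtering.
#'
#' @param sites Site table with populated counts.
#' @return The site table with a (re)computed `tpm` column.
#' @export
compute_tpm <- function(sites) {
  validate_sites(sites)
  if (nrow(sites) == 0) return(mutate(sites, tpm = numeric(0)))
  totals <- sites %>%
    group_by(.data$sample) %>%
    summarise(total = sum(.data$count), .groups = "drop")
  zero <- totals$sample[totals$total == 0]
  if (length(zero) > 0) {
    abort(sprintf("sample(s) with zero total count: %s",
                  paste(zero, collapse = ", ")))
  }
  sites %>%
    left_join(totals, by = "sample") %>%
    mutate(tpm = .data$count / .data$total * 1e6) %>%
    select(-"total")
}

#' Remove sites below a TPM threshold
#'
#' A site row is removed for a sample iff its TPM is strictly below
#' `threshold` in that sample (a site at exactly the threshold is retained);
#' a site that survives in no sample disappears entirely. Filtering is
#' idempotent and monotone in the threshold.
#'
#' @param sites Site table with `tpm` computed (see [compute_tpm()]).
#' @param threshold Minimum TPM to keep a site in a sample (default 1).
#' @return The filtered site table.
#' @export
filter_low_tpm <- function(sites, threshold = 1) {
  if (threshold < 0) abort("`threshold` must be >= 0")
  validate_sites(sites, need_tpm = TRUE)
  filter(sites, .data$tpm >= threshold)
}
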