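# Distal poly(A)-site usage index (PDUI) and marker-stratified cohort
# comparison.

#' Pick the proximal and distal PAC of each gene
#'
#' For genes carrying at least two gene-assigned consensus PACs, the two
#' PACs with the highest combined (all-sample) TPM are selected; the one
#' whose summit is nearer the gene's stop codon in transcript orientation is
#' the proximal PAC (pPAS), the farther one the distal PAC (dPAS). Genes
#' with fewer than two PACs are excluded with a message.
#'
#' @param consensus Gene-assigned consensus table (see [assign_to_genes()]).
#' @param utrs UTR table from [three_prime_utrs()] (or a feature table from
#'   [read_gtf()], from which UTRs are derived).
#' @param quiet Suppress the exclusion message.
#' @return A tibble with one row per gene and role: `gene_id`, `role`
#'   (`proximal`/`distal`), `consensus_id`, `summit`, `stop_dist` (nt from
#'   the stop codon in transcript orientation).
#' @export
assign_proximal_distal <- function(consensus, utrs, quiet = FALSE) {
  if (!"gene_id" %in% names(consensus)) {
    abort("`consensus` has no gene_id column; run assign_to_genes() first")
  }
  if (!"stop_pos" %in% names(utrs)) utrs <- three_prime_utrs(utrs, quiet = TRUE)
  stops <- distinct(utrs, .data$gene_id, .data$strand, .data$stop_pos)

  per_pac <- consensus %>%
    filter(!.data$gene_id %in% c("intergenic", "ambiguous")) %>%
    group_by(.data$gene_id, .data$consensus_id, .data$strand, .data$summit) %>%
    summarise(total_tpm = sum(.data$tpm), .groups = "drop") %>%
    inner_join(stops, by = c("gene_id", "strand")) %>%
    mutate(stop_dist = ifelse(.data$strand == "+",
                              .data$summit - .data$stop_pos,
                              .data$stop_pos - .data$summit))

  n_by_gene <- count(per_pac, .data$gene_id)
  excluded <- n_by_gene$gene_id[n_by_gene$n < 2]
  if (length(excluded) > 0 && !quiet) {
    inform(sprintf("%d gene(s) with < 2 PACs excluded from PDUI", length(excluded)))
  }

  kept <- filter(per_pac, !.data$gene_id %in% excluded)
  if (nrow(kept) == 0) {
    return(tibble(gene_id = character(), role = character(),
                  consensus_id = character(), summit = integer(),
                  stop_dist = numeric()))
  }
  kept %>%
    group_by(.data$gene_id) %>%
    arrange(dplyr::desc(.data$total_tpm), .data$stop_dist, .by_group = TRUE) %>%
    slice(1:2) %>%
    arrange(.data$stop_dist, .by_group = TRUE) %>%
    mutate(role = c("proximal", "distal")) %>%
    ungroup() %>%
    select("gene_id", "role", "consensus_id", "summit", "stop_dist")
}

#' Distal poly(A)-site usage index
#'
#' `PDUI = distal / (proximal + distal)`: 0 when only the proximal site is
#' used, 1 when only the distal site is used. When both abundances are zero
#' the index is undefined and `NA` is returned (never 0). Vectorised; the
#' index is invariant under common scaling of both abundances.
#'
#' @param proximal,distal Non-negative abundances (TPM) of the proximal and
#'   distal isoform.
#' @return PDUI values in \[0, 1\] (or `NA`).
#' @export
compute_pdui <- function(proximal, distal) {
  if (any(proximal < 0, na.rm = TRUE) || any(distal < 0, na.rm = TRUE)) {
    abort("abundances must be non-negative")
  }
  total <- proximal + distal
  ifelse(total > 0, distal / total, NA_real_)
}

#' Per-gene, per-sample PDUI table
#'
#' Joins a proximal/distal assignment with the per-sample consensus TPMs
#' and computes the PDUI record for every (gene, sample).
#'
#' @param assignment Output of [assign_proximal_distal()].
#' @param consensus Long consensus table with per-sample TPM.
#' @return A tibble: `gene_id`, `sample`, `proximal_tpm`, `distal_tpm`,
#'   `pdui`.
#' @export
pdui_table <- function(assignment, consensus) {
  assignment %>%
    select("gene_id", "role", "consensus_id") %>%
    inner_join(select(consensus, "consensus_id", "sample", "tpm"),
               by = "consensus_id") %>%
    tidyr::pivot_wider(id_cols = c("gene_id", "sample"),
                       names_from = "role", values_from = "tpm",
                       values_fill = 0) %>%
    mutate(pdui = compute_pdui(.data$proximal, .data$distal)) %>%
    rename(proximal_tpm = "proximal", distal_tpm = "distal") %>%
    arrange(.data$gene_id, .data$sample)
}

#' Marker-stratified PDUI comparison
#'
#' Splits the cohort at the median expression of a marker gene (samples at
#' or below the median go to the `low` group, so ties resolve
#' deterministically), averages PDUI within groups, and compares the groups
#' with a two-sided Mann-Whitney U test. By default the comparison units are
#' per-sample mean PDUIs (`units = "sample"`), which are independent
#' observations; `units = "gene"` instead compares per-gene group means,
#' which mirrors averaging gene-by-gene but shares each gene's baseline
#' between the groups and is therefore conservative.
#'
#' @param pdui PDUI matrix: either wide (a `gene_id` column plus one column
#'   per sample) or long (`gene_id`, `sample`, `pdui`).
#' @param marker_expression Marker expression per sample: a tibble with
#'   `sample` and `expression` columns, or a named numeric vector.
#' @param marker Marker gene name (annotation only, e.g. `"LDHA"`).
#' @param units `"sample"` (default) or `"gene"` comparison units.
#' @return An `apa_stratified` object; see [tidy()], [glance()],
#'   [autoplot()] methods.
#' @export
stratify_and_compare <- function(pdui, marker_expression, marker = "marker",
                                 units = c("sample", "gene")) {
  units <- match.arg(units)
  long <- if (all(c("gene_id", "sample", "pdui") %in% names(pdui))) {
    as_tibble(pdui)
  } else {
    tidyr::pivot_longer(pdui, -"gene_id", names_to = "sample",
                        values_to = "pdui")
  }
  expr <- if (is.numeric(marker_expression)) {
    tibble(sample = names(marker_expression),
           expression = unname(marker_expression))
  } else {
    as_tibble(marker_expression)[, c("sample", "expression")]
  }
  expr <- filter(expr, .data$sample %in% unique(long$sample))
  if (n_distinct(expr$expression) == 1) {
    abort("all marker values identical: no median split possible")
  }
  med <- median(expr$expression)
  expr$group <- ifelse(expr$expression <= med, "low", "high")
  sizes <- table(expr$group)
  if (length(sizes) < 2 || any(sizes < 2)) {
    abort("need at least 2 samples per group after the median split")
  }
  long <- inner_join(long, expr, by = "sample")

  if (units == "sample") {
    unit_vals <- long %>%
      group_by(.data$sample, .data$group) %>%
      summarise(value = mean(.data$pdui, na.rm = TRUE), .groups = "drop")
  } else {
    unit_vals <- long %>%
      group_by(.data$gene_id, .data$group) %>%
      summarise(value = mean(.data$pdui, na.rm = TRUE), .groups = "drop") %>%
      rename(sample = "gene_id")
  }
  hi <- unit_vals$value[unit_vals$group == "high"]
  lo <- unit_vals$value[unit_vals$group == "low"]
  wt <- suppressWarnings(wilcox.test(hi, lo, alternative = "two.sided"))
  p_value <- wt$p.value
  if (is.nan(p_value)) p_value <- 1   # fully tied groups: no evidence of shift
  out <- list(
    marker = marker, units = units, median = med,
    groups = expr, unit_values = unit_vals,
    mean_high = mean(hi, na.rm = TRUE), mean_low = mean(lo, na.rm = TRUE),
    n_high = length(hi), n_low = length(lo),
    statistic = unname(wt$statistic), p_value = p_value)
  class(out) <- "apa_stratified"
  out
}

#' @export
print.apa_stratified <- function(x, ...) {
  cat(sprintf("Stratified PDUI comparison (%s-wise) on marker %s\n",
              x$units, x$marker))
  cat(sprintf("  high (n=%d) mean PDUI %.4f vs low (n=%d) mean PDUI %.4f\n",
              x$n_high, x$mean_high, x$n_low, x$mean_low))
  cat(sprintf("  Mann-Whitney U = %.1f, two-sided p = %.3g\n",
              x$statistic, x$p_value))
  invisible(x)
}

#' @method tidy apa_stratified
#' @export
tidy.apa_stratified <- function(x, ...) {
  x$unit_values %>%
    group_by(.data$group) %>%
    summarise(n = n(), mean_pdui = mean(.data$value, na.rm = TRUE),
              median_pdui = median(.data$value, na.rm = TRUE),
              .groups = "drop") %>%
    mutate(marker = x$marker, .before = 1)
}

#' @method glance apa_stratified
#' @export
glance.apa_stratified <- function(x, ...) {
  tibble(marker = x$marker, units = x$units,
         n_high = x$n_high, n_low = x$n_low,
         mean_high = x$mean_high, mean_low = x$mean_low,
         delta_pdui = x$mean_high - x$mean_low,
         statistic = x$statistic, p_value = x$p_value)
}
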