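# Clustering of poly(A) sites into PACs within samples, weak-singleton
# removal, cross-sample consensus construction and gene assignment.

#' Cluster poly(A) sites into PACs
#'
#' Single-linkage sweep within each (sample, chrom, strand) group: sorted
#' sites belong to one PAC iff every adjacent positional gap is at most
#' `max_gap` nucleotides (24 by default, so positions 100 and 124 share a
#' PAC while 100 and 125 do not). Output order is deterministic by
#' coordinate.
#'
#' @param sites TPM-filtered site table (see [filter_low_tpm()]).
#' @param max_gap Maximum adjacent gap within a PAC, in nt.
#' @return A PAC table: `pac_id`, `sample`, `chrom`, `strand`, `start`,
#'   `end` (0-based half-open span of member positions), `n_sites`, `tpm`
#'   (sum of member TPM), `summit` (position of the max-TPM member;
#'   leftmost on ties).
#' @export
cluster_sites <- function(sites, max_gap = 24) {
  validate_sites(sites, need_tpm = TRUE)
  if (max_gap < 0) abort("`max_gap` must be >= 0")
  empty <- tibble(pac_id = character(), sample = character(),
                  chrom = character(), strand = character(),
                  start = integer(), end = integer(), n_sites = integer(),
                  tpm = numeric(), summit = integer())
  if (nrow(sites) == 0) return(empty)
  sites %>%
    arrange(.data$sample, .data$chrom, .data$strand, .data$position) %>%
    group_by(.data$sample, .data$chrom, .data$strand) %>%
    mutate(.gap = .data$position - lag(.data$position),
           .new = is.na(.data$.gap) | .data$.gap > max_gap,
           .cluster = cumsum(.data$.new)) %>%
    group_by(.data$sample, .data$chrom, .data$strand, .data$.cluster) %>%
    summarise(start = min(.data$position),
              end = max(.data$position) + 1L,
              n_sites = n(),
              summit = .data$position[which.max(.data$tpm)],
              tpm = sum(.data$tpm),
              .groups = "drop") %>%
    arrange(.data$sample, .data$chrom, .data$strand, .data$start) %>%
    mutate(pac_id = sprintf("%s:%s:%s:%d", .data$sample, .data$chrom,
                            .data$strand, .data$.cluster)) %>%
    select("pac_id", "sample", "chrom", "strand", "start", "end",
           "n_sites", "tpm", "summit")
}

#' Remove weak single-site PACs
#'
#' A PAC is dropped iff it contains exactly one site and that site's TPM is
#' strictly below `min_tpm` (default 3) in the PAC's sample. Multi-site PACs
#' are never removed by this rule, whatever their TPM.
#'
#' @param pacs PAC table from [cluster_sites()].
#' @param min_tpm Singleton TPM threshold.
#' @return The filtered PAC table.
#' @export
filter_singleton_pacs <- function(pacs, min_tpm = 3) {
  filter(pacs, !(.data$n_sites == 1L & .data$tpm < min_tpm))
}

#' Build cross-sample consensus PACs
#'
#' Per-sample PACs with TPM strictly above `min_tpm` (default 5) are pooled
#' across samples and chained by single linkage on summit-to-summit distance
#' at most `max_distance` nt (default 500) within each (chrom, strand).
#' A PAC detected in any sample may seed a consensus
#' (`require_all_samples = TRUE` restricts to consensus PACs with a
#' contribution from every sample). Each consensus records one row per
#' sample with that sample's aggregate TPM (0 where it contributed nothing).
#'
#' @param pacs PAC table pooled over samples (after
#'   [filter_singleton_pacs()]).
#' @param max_distance Maximum summit distance chaining two PACs.
#' @param min_tpm Strict per-sample TPM threshold for a PAC to enter.
#' @param require_all_samples Keep only consensus PACs detected in every
#'   sample.
#' @return A long consensus table: `consensus_id`, `chrom`, `strand`,
#'   `start`, `end`, `summit` (summit of the strongest contributing PAC),
#'   `n_pacs`, `sample`, `tpm`.
#' @export
build_consensus <- function(pacs, max_distance = 500, min_tpm = 5,
                            require_all_samples = FALSE) {
  stopifnot(is.data.frame(pacs))
  all_samples <- unique(pacs$sample)
  eligible <- filter(pacs, .data$tpm > min_tpm)
  empty <- tibble(consensus_id = character(), chrom = character(),
                  strand = character(), start = integer(), end = integer(),
                  summit = integer(), n_pacs = integer(),
                  sample = character(), tpm = numeric())
  if (nrow(eligible) == 0) return(empty)

  grouped <- eligible %>%
    arrange(.data$chrom, .data$strand, .data$summit, .data$start) %>%
    group_by(.data$chrom, .data$strand) %>%
    mutate(.gap = .data$summit - lag(.data$summit),
           .new = is.na(.data$.gap) | .data$.gap > max_distance,
           .cluster = cumsum(.data$.new)) %>%
    ungroup()

  cons <- grouped %>%
    group_by(.data$chrom, .data$strand, .data$.cluster) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              summit = .data$summit[which.max(.data$tpm)],
              n_pacs = n(),
              data = {
                s <- .data$sample; tp <- .data$tpm
                list(tibble(sample = s, tpm = tp))
              },
              .groups = "drop") %>%
    arrange(.data$chrom, .data$strand, .data$start) %>%
    mutate(consensus_id = sprintf("cons_%04d", row_number()))

  base <- select(cons, "consensus_id", "chrom", "strand", "start", "end",
                 "summit", "n_pacs")
  tpms <- cons %>%
    select("consensus_id", "data") %>%
    tidyr::unnest("data") %>%
    group_by(.data$consensus_id, .data$sample) %>%
    summarise(tpm = sum(.data$tpm), .groups = "drop")
  out <- tidyr::crossing(base, sample = all_samples) %>%
    left_join(tpms, by = c("consensus_id", "sample")) %>%
    mutate(tpm = tidyr::replace_na(.data$tpm, 0)) %>%
    arrange(.data$chrom, .data$strand, .data$start, .data$sample)

  if (require_all_samples) {
    out <- out %>%
      group_by(.data$consensus_id) %>%
      filter(all(.data$tpm > 0)) %>%
      ungroup()
  }
  select(out, "consensus_id", "chrom", "strand", "start", "end", "summit",
         "n_pacs", "sample", "tpm")
}

#' Assign consensus PACs to genes
#'
#' A consensus PAC is assigned to the gene whose merged 3' UTR — extended
#' downstream by `margin` nt (default 1 kb) to catch unannotated distal
#' sites — overlaps its interval on the same strand. When several genes
#' overlap, the gene whose stop codon is nearest the consensus summit wins;
#' an exact tie is labelled `"ambiguous"`, no overlap `"intergenic"`.
#'
#' @param consensus Consensus table from [build_consensus()].
#' @param genes Feature table from [read_gtf()] (or a UTR table from
#'   [three_prime_utrs()]).
#' @param margin Downstream extension of each UTR, in nt.
#' @return The consensus table with a `gene_id` column.
#' @export
assign_to_genes <- function(consensus, genes, margin = 1000) {
  utr <- if (all(c("stop_pos") %in% names(genes))) genes else
    three_prime_utrs(genes, quiet = TRUE)
  ivals <- distinct(consensus, .data$consensus_id, .data$chrom,
                    .data$strand, .data$start, .data$end, .data$summit)
  if (nrow(utr) == 0 || nrow(ivals) == 0) {
    return(mutate(consensus, gene_id = "intergenic"))
  }
  ext_start <- ifelse(utr$strand == "+", utr$start, pmax(0L, utr$start - margin))
  ext_end <- ifelse(utr$strand == "+", utr$end + margin, utr$end)
  utr_gr <- GenomicRanges::GRanges(utr$chrom,
                                   IRanges::IRanges(ext_start + 1L, ext_end),
                                   strand = utr$strand)
  pac_gr <- GenomicRanges::GRanges(ivals$chrom,
                                   IRanges::IRanges(ivals$start + 1L, ivals$end),
                                   strand = ivals$strand)
  hits <- GenomicRanges::findOverlaps(pac_gr, utr_gr)
  if (length(hits) == 0) {
    ivals$gene_id <- "intergenic"
    return(left_join(consensus, select(ivals, "consensus_id", "gene_id"),
                     by = "consensus_id"))
  }
  assignment <- tibble(
    idx = S4Vectors::queryHits(hits),
    gene_id = utr$gene_id[S4Vectors::subjectHits(hits)],
    stop_dist = abs(ivals$summit[S4Vectors::queryHits(hits)] -
                      utr$stop_pos[S4Vectors::subjectHits(hits)])) %>%
    distinct(.data$idx, .data$gene_id, .keep_all = TRUE) %>%
    group_by(.data$idx) %>%
    summarise(gene_id = if (n() == 1) .data$gene_id else {
      nearest <- .data$gene_id[.data$stop_dist == min(.data$stop_dist)]
      if (length(unique(nearest)) > 1) "ambiguous" else nearest[1]
    }, .groups = "drop")
  ivals$gene_id <- "intergenic"
  ivals$gene_id[assignment$idx] <- assignment$gene_id
  left_join(consensus,
            select(ivals, "consensus_id", "gene_id"),
            by = "consensus_id")
}
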