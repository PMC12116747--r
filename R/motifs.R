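# Polyadenylation-signal hexamer and UGUA upstream-element scanning,
# genomic context annotation of PACs, and the proximal-PAS mutagenesis
# utility. Motifs are stated in the RNA alphabet; DNA input is transcribed
# internally and both alphabets are accepted everywhere.

#' The scanned polyadenylation-signal hexamer set
#'
#' The canonical signal AAUAAA, its major variant AUUAAA, and the ten
#' common single-base variants observed at human cleavage sites.
#'
#' @return A character vector of 12 RNA hexamers.
#' @export
pas_hexamers <- function() {
  c("AAUAAA", "AUUAAA", "UAUAAA", "AGUAAA", "AAGAAA", "AAUAUA",
    "AAUACA", "CAUAAA", "GAUAAA", "AAUGAA", "UUUAAA", "ACUAAA")
}

# Extract the transcript-oriented window [pas - window, pas] (inclusive of
# the cleavage base) as an RNA string; truncates at sequence boundaries.
upstream_window <- function(sequence, pas_position, window, strand,
                            quiet = FALSE) {
  seq_str <- as_sequence_string(sequence)
  len <- nchar(seq_str)
  if (pas_position < 0 || pas_position >= len) {
    abort("`pas_position` outside the sequence")
  }
  if (strand == "+") {
    lo <- pas_position - window
    truncated <- lo < 0
    lo <- max(0L, lo)
    win <- substr(seq_str, lo + 1L, pas_position + 1L)
  } else {
    hi <- pas_position + window
    truncated <- hi >= len
    hi <- min(len - 1L, hi)
    win <- reverse_complement(substr(seq_str, pas_position + 1L, hi + 1L))
  }
  if (truncated && !quiet) {
    inform("scan window extends past the sequence boundary: truncated")
  }
  to_rna(win)
}

scan_motifs <- function(sequence, pas_position, window, strand, motifs,
                        quiet = FALSE) {
  if (window < 1) abort("`window` must be >= 1")
  if (!strand %in% STRANDS) abort("`strand` must be '+' or '-'")
  win <- upstream_window(sequence, pas_position, window, strand, quiet = quiet)
  L <- nchar(win)
  hits <- purrr::map_dfr(to_rna(motifs), function(m) {
    starts <- stringr::str_locate_all(win, stringr::fixed(m))[[1]][, "start"]
    if (length(starts) == 0) return(NULL)
    tibble(motif = m, offset = as.integer(starts) - L)
  })
  if (nrow(hits) == 0) {
    return(tibble(motif = character(), offset = integer(),
                  position = integer(), strand = character()))
  }
  hits %>%
    mutate(position = if (strand == "+") pas_position + .data$offset
                      else pas_position - .data$offset,
           strand = strand) %>%
    arrange(dplyr::desc(.data$offset), .data$motif)   # nearest to the PAS first
}

#' Scan for polyadenylation-signal hexamers upstream of a cleavage site
#'
#' Finds all occurrences of the configured hexamer set within `window` nt
#' upstream of the cleavage position, in transcript orientation (on the `-`
#' strand the reverse complement is scanned). Offsets follow the convention:
#' offset of the motif's first base relative to the cleavage position,
#' negative upstream, so the canonical signal typically sits near -21.
#' Hits are returned nearest-to-PAS first.
#'
#' @param sequence Chromosome or region sequence (character string,
#'   `DNAString`/`RNAString`, or length-1 `XStringSet`); DNA or RNA
#'   alphabet.
#' @param pas_position 0-based position of the cleavage base on `sequence`.
#' @param window Upstream scan window in nt (default 50; the canonical
#'   signal sits 10-30 nt upstream).
#' @param strand Transcript strand of the PAS.
#' @param motifs Hexamer set to scan (default [pas_hexamers()]).
#' @param quiet Suppress the boundary-truncation message.
#' @return A tibble of hits: `motif` (RNA alphabet), `offset`, `position`
#'   (0-based genomic position of the motif's first transcript base),
#'   `strand`.
#' @export
scan_pas_hexamers <- function(sequence, pas_position, window = 50,
                              strand = "+", motifs = pas_hexamers(),
                              quiet = FALSE) {
  scan_motifs(sequence, pas_position, window, strand, motifs, quiet = quiet)
}

#' Scan for UGUA upstream elements
#'
#' Finds all UGUA occurrences (the CFIm / NUDT21-CPSF6 binding element)
#' upstream of a cleavage position, with the same conventions as
#' [scan_pas_hexamers()]. Scanning the proximal and the distal PAS of one
#' gene with the same window makes their upstream element content directly
#' comparable.
#'
#' @inheritParams scan_pas_hexamers
#' @export
scan_ugua <- function(sequence, pas_position, window = 50, strand = "+",
                      quiet = FALSE) {
  scan_motifs(sequence, pas_position, window, strand, "UGUA", quiet = quiet)
}

#' Annotate PACs with genomic context
#'
#' Labels every PAC with the highest-precedence overlapping annotation
#' class: `3UTR` > `CDS-exon` > `intron` > `downstream-1kb` > `intergenic`.
#' 3' UTRs are derived from the gene models ([three_prime_utrs()]); introns
#' are the gaps between a transcript's exons; `downstream-1kb` covers the
#' kilobase past each gene's 3' end on the gene's strand.
#'
#' @param pacs PAC or consensus table (`chrom`, `start`, `end`, `strand`).
#' @param genes Feature table from [read_gtf()].
#' @param downstream Width of the downstream window, nt.
#' @return `pacs` with a `context` column; the per-class frequency table is
#'   available via [context_frequencies()].
#' @export
annotate_context <- function(pacs, genes, downstream = 1000) {
  mk_gr <- function(d) {
    GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start + 1L, d$end),
                           strand = d$strand)
  }
  pac_gr <- mk_gr(pacs)

  utr <- three_prime_utrs(genes, quiet = TRUE)
  cds <- filter(genes, .data$type == "CDS")
  exons <- filter(genes, .data$type == "exon")
  introns <- exons %>%
    group_by(.data$gene_id, .data$transcript_id, .data$chrom, .data$strand) %>%
    group_modify(function(d, key) {
      if (nrow(d) < 2) return(tibble(start = integer(), end = integer()))
      ir <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
      gaps <- IRanges::gaps(ir, start = min(IRanges::start(ir)),
                            end = max(IRanges::end(ir)))
      tibble(start = IRanges::start(gaps) - 1L, end = IRanges::end(gaps))
    }) %>% ungroup()
  gene_span <- exons %>%
    group_by(.data$gene_id, .data$chrom, .data$strand) %>%
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  down <- gene_span %>%
    mutate(s = ifelse(.data$strand == "+", .data$end,
                      pmax(0L, .data$start - downstream)),
           e = ifelse(.data$strand == "+", .data$end + downstream,
                      .data$start)) %>%
    select("chrom", "strand", start = "s", end = "e") %>%
    filter(.data$start < .data$end)

  layers <- list(`3UTR` = utr, `CDS-exon` = cds, intron = introns,
                 `downstream-1kb` = down)
  context <- rep("intergenic", nrow(pacs))
  unset <- rep(TRUE, nrow(pacs))
  for (label in names(layers)) {
    layer <- layers[[label]]
    if (nrow(layer) == 0) next
    ov <- GenomicRanges::findOverlaps(pac_gr, mk_gr(layer))
    hit <- unique(S4Vectors::queryHits(ov))
    context[unset & seq_along(context) %in% hit] <- label
    unset <- unset & !(seq_along(context) %in% hit)
  }
  mutate(pacs, context = factor(context, levels = c(names(layers), "intergenic")))
}

#' Context frequency table
#'
#' @param annotated Output of [annotate_context()].
#' @return A tibble: `context`, `n`, `fraction`.
#' @export
context_frequencies <- function(annotated) {
  annotated %>%
    count(.data$context, .drop = FALSE) %>%
    mutate(fraction = .data$n / sum(.data$n))
}

#' Mutate a proximal polyadenylation signal to CCCCCC
#'
#' Replaces a recognised signal hexamer at the given interval with CCCCCC
#' (the standard loss-of-function edit used to force distal-site usage in
#' reporter constructs), leaving every other base unchanged. The sequence
#' length is invariant. If the interval does not contain a recognised
#' hexamer the edit is refused.
#'
#' @param sequence Sequence containing the signal (character,
#'   DNA or RNA alphabet).
#' @param interval 0-based half-open `c(start, end)` of the hexamer
#'   (length 6).
#' @param motifs Recognised hexamer set (default [pas_hexamers()]).
#' @return A list: `sequence` (edited, in the input alphabet), `edit`
#'   (tibble: `start`, `end`, `original`, `replacement`).
#' @export
mutate_proximal_pas <- function(sequence, interval, motifs = pas_hexamers()) {
  seq_str <- as_sequence_string(sequence)
  if (length(interval) != 2 || interval[2] - interval[1] != 6) {
    abort("`interval` must be a 0-based half-open hexamer interval (length 6)")
  }
  if (interval[1] < 0 || interval[2] > nchar(seq_str)) {
    abort("`interval` outside the sequence")
  }
  original <- substr(seq_str, interval[1] + 1L, interval[2])
  if (!to_rna(original) %in% to_rna(motifs)) {
    abort(sprintf("no recognised polyadenylation signal at [%d, %d): found %s",
                  interval[1], interval[2], original))
  }
  replacement <- "CCCCCC"
  edited <- paste0(substr(seq_str, 1, interval[1]), replacement,
                   substr(seq_str, interval[2] + 1L, nchar(seq_str)))
  list(sequence = edited,
       edit = tibble(start = interval[1], end = interval[2],
                     original = original, replacement = replacement))
}
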