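# Readers and writers for the external formats the pipeline touches:
# GTF gene models, BAM alignments, per-position 3'-end site tables, BED.
# Coordinates are converted to 0-based half-open on the way in and back to
# each format's native convention on the way out.

#' Read gene models from a GTF file
#'
#' Imports exon and CDS features and returns them as a tidy feature table,
#' one row per (transcript, feature interval), with coordinates converted to
#' 0-based half-open. 3' UTRs are not stored in the table; they are derived
#' from the exon/CDS structure by [three_prime_utrs()], so annotations that
#' do not mark UTR features explicitly are handled identically to those that
#' do.
#'
#' @param path Path to a GTF file (Ensembl-dialect `gene_id`/`transcript_id`
#'   attributes).
#' @return A tibble with columns `gene_id`, `transcript_id`, `type`
#'   (`exon` or `CDS`), `chrom`, `start`, `end` (0-based half-open), `strand`.
#' @seealso [three_prime_utrs()], [annotate_context()]
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) abort(sprintf("annotation file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- body[nfield != 9]
  if (length(bad) > 0) {
    abort(sprintf("malformed GTF record at line %d of %s: expected 9 tab-separated fields",
                  bad[1], path))
  }
  noattr <- body[!grepl("gene_id", lines[body], fixed = TRUE)]
  if (length(noattr) > 0) {
    abort(sprintf("malformed GTF attribute column at line %d of %s: no gene_id",
                  noattr[1], path))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type %in% c("exon", "CDS")]
  tx <- as.character(gr$transcript_id)
  tibble(
    gene_id = as.character(gr$gene_id),
    transcript_id = ifelse(is.na(tx), as.character(gr$gene_id), tx),
    type = as.character(gr$type),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  ) %>% arrange(.data$chrom, .data$start, .data$transcript_id, .data$type)
}

#' Derive merged 3' UTR intervals per gene
#'
#' The 3' UTR of a transcript is its exonic span downstream of the CDS end
#' (in transcript orientation). Transcript UTRs are merged per gene; the
#' reported stop-codon boundary is the 5'-most UTR boundary across
#' transcripts. Transcripts without an annotated CDS contribute no UTR and
#' are reported via a message.
#'
#' @param features Feature table from [read_gtf()] (or the simulator).
#' @param quiet Suppress the message about genes lacking a CDS.
#' @return A tibble with one row per merged UTR interval: `gene_id`, `chrom`,
#'   `strand`, `start`, `end` (0-based half-open), `stop_pos` (stop-codon
#'   boundary: the UTR-proximal CDS edge in genomic coordinates).
#' @export
three_prime_utrs <- function(features, quiet = FALSE) {
  stopifnot(is.data.frame(features))
  empty <- tibble(gene_id = character(), chrom = character(),
                  strand = character(), start = integer(), end = integer(),
                  stop_pos = integer())
  if (nrow(features) == 0) return(empty)

  per_tx <- features %>%
    group_by(.data$gene_id, .data$transcript_id, .data$chrom, .data$strand) %>%
    summarise(
      cds_min = suppressWarnings(min(.data$start[.data$type == "CDS"])),
      cds_max = suppressWarnings(max(.data$end[.data$type == "CDS"])),
      exon_start = list(.data$start[.data$type == "exon"]),
      exon_end = list(.data$end[.data$type == "exon"]),
      .groups = "drop"
    )
  no_cds <- !is.finite(per_tx$cds_min)
  if (any(no_cds) && !quiet) {
    inform(sprintf("%d transcript(s) without CDS: no 3' UTR emitted (%s)",
                   sum(no_cds),
                   paste(head(unique(per_tx$gene_id[no_cds]), 3), collapse = ", ")))
  }
  per_tx <- per_tx[!no_cds, , drop = FALSE]
  if (nrow(per_tx) == 0) return(empty)

  utr_rows <- purrr::pmap_dfr(per_tx, function(gene_id, transcript_id, chrom,
                                                strand, cds_min, cds_max,
                                                exon_start, exon_end) {
    if (strand == "+") {
      s <- pmax(exon_start, cds_max); e <- exon_end; stop_pos <- cds_max
    } else {
      s <- exon_start; e <- pmin(exon_end, cds_min); stop_pos <- cds_min
    }
    keep <- s < e
    if (!any(keep)) return(NULL)
    tibble(gene_id = gene_id, chrom = chrom, strand = strand,
           start = as.integer(s[keep]), end = as.integer(e[keep]),
           stop_pos = as.integer(stop_pos))
  })
  if (nrow(utr_rows) == 0) return(empty)

  utr_rows %>%
    group_by(.data$gene_id, .data$chrom, .data$strand) %>%
    group_modify(function(d, key) {
      ir <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
      # 5'-most stop boundary gives the longest annotated UTR
      stop_pos <- if (key$strand == "+") min(d$stop_pos) else max(d$stop_pos)
      tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir),
             stop_pos = stop_pos)
    }) %>%
    ungroup() %>%
    select("gene_id", "chrom", "strand", "start", "end", "stop_pos") %>%
    arrange(.data$chrom, .data$start)
}

#' Write a feature table as GTF
#'
#' Inverse of [read_gtf()] for exon/CDS feature tables; coordinates are
#' serialised 1-based closed per the GTF convention.
#'
#' @param features Feature table (`gene_id`, `transcript_id`, `type`,
#'   `chrom`, `start`, `end`, `strand`; 0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(features, path) {
  stopifnot(all(c("gene_id", "transcript_id", "type", "chrom", "start",
                  "end", "strand") %in% names(features)))
  lines <- sprintf(
    "%s\tapashift\t%s\t%d\t%d\t.\t%s\t%s\tgene_id \"%s\"; transcript_id \"%s\";",
    features$chrom, features$type, features$start + 1L, features$end,
    features$strand, ifelse(features$type == "CDS", "0", "."),
    features$gene_id, features$transcript_id)
  writeLines(lines, path)
  invisible(path)
}

#' Extract read 3'-end positions from a BAM file
#'
#' Counts one tag per primary alignment at the 3'-terminal *aligned* base of
#' the read on its transcriptional strand (soft-clipped bases are never
#' counted). For `strandedness = "reverse"` (dUTP-style libraries, the
#' default) the transcriptional strand is the opposite of the alignment
#' strand; for `"forward"` they coincide. Secondary, supplementary and
#' unmapped records are skipped, as are alignments below `min_mapq` (default
#' 10, so multi-mappers with near-zero MAPQ do not create spurious sites).
#' For paired-end data only the first mate is counted. Duplicate reads are
#' counted individually unless `collapse_umi = TRUE`, in which case reads
#' sharing (position, strand, UMI tag) collapse to one tag.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM file.
#' @param sample Sample identifier recorded in the output.
#' @param strandedness `"reverse"` or `"forward"` library orientation.
#' @param min_mapq Minimum mapping quality; lower alignments are dropped.
#' @param collapse_umi Collapse reads by (position, UMI)?
#' @param umi_tag BAM tag holding the UMI (default `"UB"`).
#' @return A site table: `chrom`, `position` (0-based), `strand`, `sample`,
#'   `count`.
#' @export
extract_three_prime_ends <- function(bam, sample,
                                     strandedness = c("reverse", "forward"),
                                     min_mapq = 10, collapse_umi = FALSE,
                                     umi_tag = "UB") {
  strandedness <- match.arg(strandedness)
  if (!file.exists(bam)) abort(sprintf("alignment file not found: %s", bam))
  idx <- c(paste0(bam, ".bai"), sub("\\.bam$", ".bai", bam))
  if (!any(file.exists(idx))) {
    abort(sprintf("missing BAM index for %s (expected %s)", bam, idx[1]))
  }
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE),
    mapqFilter = min_mapq,
    what = "flag",
    tag = if (collapse_umi) umi_tag else character(0))
  ga <- GenomicAlignments::readGAlignments(Rsamtools::BamFile(bam), param = param)
  flag <- S4Vectors::mcols(ga)$flag
  paired <- bitwAnd(flag, 1L) > 0L
  first_mate <- bitwAnd(flag, 64L) > 0L
  keep <- !paired | first_mate
  ga <- ga[keep]
  if (length(ga) == 0) {
    return(tibble(chrom = character(), position = integer(),
                  strand = character(), sample = character(),
                  count = integer()))
  }
  aln_strand <- as.character(GenomicRanges::strand(ga))
  ts <- if (strandedness == "forward") aln_strand else
    ifelse(aln_strand == "+", "-", "+")
  pos <- ifelse(ts == "+",
                GenomicAlignments::end(ga) - 1L,
                GenomicAlignments::start(ga) - 1L)
  d <- tibble(chrom = as.character(GenomicRanges::seqnames(ga)),
              position = as.integer(pos), strand = ts)
  if (collapse_umi) {
    umi <- S4Vectors::mcols(ga)[[umi_tag]][keep]
    d$umi <- ifelse(is.na(umi), paste0("read", seq_len(nrow(d))), umi)
    d <- distinct(d, .data$chrom, .data$position, .data$strand, .data$umi)
  }
  d %>%
    count(.data$chrom, .data$position, .data$strand, name = "count") %>%
    mutate(sample = sample, count = as.integer(.data$count)) %>%
    select("chrom", "position", "strand", "sample", "count") %>%
    arrange(.data$chrom, .data$position, .data$strand)
}

#' Write / read a site table as TSV
#'
#' The TSV carries the columns `chrom`, `position`, `strand`, `sample`,
#' `count`, `tpm` with positions serialised 1-based; `read_site_table()`
#' converts back to the internal 0-based convention, so a write/read
#' round-trip is lossless.
#'
#' @param sites Site table (0-based positions).
#' @param path File path.
#' @return `write_site_table()` returns `path` invisibly; `read_site_table()`
#'   returns the site table.
#' @export
write_site_table <- function(sites, path) {
  validate_sites(sites)
  out <- sites
  if (!"tpm" %in% names(out)) out$tpm <- NA_real_
  out <- out %>%
    mutate(position = .data$position + 1L) %>%
    select("chrom", "position", "strand", "sample", "count", "tpm")
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_site_table
#' @export
read_site_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("site table not found: %s", path))
  d <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), position = readr::col_integer(),
    strand = readr::col_character(), sample = readr::col_character(),
    count = readr::col_double(), tpm = readr::col_double()))
  if (nrow(d) > 0) {
    bad <- which(d$count < 0 | d$count != floor(d$count))
    if (length(bad) > 0) {
      abort(sprintf("invalid count in %s at data row %d", path, bad[1]))
    }
    if (!all(d$strand %in% STRANDS)) {
      abort(sprintf("invalid strand value in %s", path))
    }
  }
  d %>%
    mutate(position = as.integer(.data$position) - 1L,
           count = as.integer(.data$count)) %>%
    select("chrom", "position", "strand", "sample", "count", "tpm")
}

#' Write PACs or consensus PACs as BED6+
#'
#' Native 0-based half-open BED with `name` = cluster id, `score` = total
#' TPM (capped at 1000 per the BED spec), plus any remaining columns
#' appended after the strand field.
#'
#' @param pacs PAC or consensus table with `chrom`, `start`, `end`, `strand`,
#'   an id column (`pac_id` or `consensus_id`) and `tpm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pac_bed <- function(pacs, path) {
  id_col <- intersect(c("consensus_id", "pac_id", "id"), names(pacs))[1]
  if (is.na(id_col)) abort("`pacs` needs a pac_id or consensus_id column")
  bed <- tibble(
    chrom = pacs$chrom, start = pacs$start, end = pacs$end,
    name = pacs[[id_col]],
    score = round(pmin(pacs$tpm, 1000)),
    strand = pacs$strand)
  extra <- setdiff(names(pacs), c("chrom", "start", "end", "strand", id_col, "tpm"))
  for (col in extra) bed[[col]] <- pacs[[col]]
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
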