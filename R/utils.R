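# Shared validators and small helpers.

STRANDS <- c("+", "-")

# Site tables are the package's central currency: one row per
# (chrom, position, strand, sample), position = 0-based coordinate of the
# read's 3'-terminal aligned base.
validate_sites <- function(sites, need_tpm = FALSE, arg = "sites") {
  required <- c("chrom", "position", "strand", "sample", "count")
  if (need_tpm) required <- c(required, "tpm")
  missing <- setdiff(required, names(sites))
  if (length(missing) > 0) {
    abort(sprintf("`%s` lacks required column(s): %s", arg,
                  paste(missing, collapse = ", ")))
  }
  if (nrow(sites) == 0) return(invisible(sites))
  if (!all(sites$strand %in% STRANDS)) {
    abort(sprintf("`%s`: strand must be one of '+', '-'", arg))
  }
  bad <- which(sites$count < 0 | sites$count != floor(sites$count))
  if (length(bad) > 0) {
    abort(sprintf("`%s`: counts must be non-negative integers (row %d)",
                  arg, bad[1]))
  }
  if (need_tpm && any(sites$tpm < 0, na.rm = TRUE)) {
    abort(sprintf("`%s`: tpm must be non-negative", arg))
  }
  invisible(sites)
}

validate_interval <- function(start, end, arg = "interval") {
  if (any(start >= end)) {
    abort(sprintf("`%s`: start must be < end (0-based half-open)", arg))
  }
  invisible(NULL)
}

# DNA/RNA alphabet helpers: motifs are stated in the RNA alphabet, genomes
# usually arrive as DNA; both are accepted everywhere.
to_rna <- function(x) chartr("Tt", "Uu", toupper(x))
to_dna <- function(x) chartr("Uu", "Tt", toupper(x))

reverse_complement <- function(x) {
  x <- to_dna(x)
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

as_sequence_string <- function(sequence) {
  if (inherits(sequence, c("DNAString", "RNAString", "BString"))) {
    return(as.character(sequence))
  }
  if (inherits(sequence, c("DNAStringSet", "RNAStringSet"))) {
    if (length(sequence) != 1) {
      abort("`sequence` must be a single sequence")
    }
    return(as.character(sequence[[1]]))
  }
  if (is.character(sequence) && length(sequence) == 1) return(sequence)
  abort("`sequence` must be a single character string or Biostrings sequence")
}
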