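# Seeded synthetic-data generator: two-PAS genes with a condition-dependent
# distal-usage shift, negative-binomial 3'-end counts and Gaussian read-end
# jitter, emitting the same annotation / genome / site-table formats the
# rest of the pipeline consumes, together with the planted ground truth.

#' Parameters of the synthetic PAS-seq generator
#'
#' Defaults describe the simulated study conditions: 200 two-PAS genes at a
#' mean depth of 500 3'-end reads per gene and condition, 15% of genes
#' shifting distal usage by `delta` = 0.3 between control and treatment
#' (70% of shifts toward lengthening, the typical shape under a
#' CFIm-activating stimulus), proximal-to-distal PAS spacing of 300 nt so
#' both sites fall inside one 500-nt consensus PAC, read-end jitter of
#' sd 8 nt so each PAS yields a multi-site cluster, and negative-binomial
#' counts with size 20 (overdispersion between technical- and
#' biological-replicate levels for a single-library comparison).
#'
#' @param n_genes Number of simulated genes.
#' @param fraction_shifted Fraction of genes with a true usage shift.
#' @param fraction_lengthened_among_shifted Fraction of shifted genes whose
#'   distal usage increases in the treatment.
#' @param delta Distal-usage shift between conditions, in \[0, 1\].
#' @param depth Mean 3'-end reads per gene and condition.
#' @param dispersion Negative-binomial size parameter (larger = closer to
#'   Poisson).
#' @param pas_spacing Distance between the proximal and distal PAS, nt.
#' @param site_jitter_sd Gaussian sd of read 3'-end scatter around each
#'   PAS, nt.
#' @param ugua_fraction Fraction of genes with a UGUA element planted
#'   upstream of the distal PAS only (the CFIm-responsive pattern).
#' @param seed Integer seed; identical seeds give bit-identical outputs.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_genes = 200, fraction_shifted = 0.15,
                           fraction_lengthened_among_shifted = 0.7,
                           delta = 0.3, depth = 500, dispersion = 20,
                           pas_spacing = 300, site_jitter_sd = 8,
                           ugua_fraction = 0.5, seed = 1) {
  fr <- c(fraction_shifted, fraction_lengthened_among_shifted, ugua_fraction)
  if (any(fr < 0 | fr > 1)) abort("fractions must lie in [0, 1]")
  if (delta < 0 || delta > 1) abort("`delta` must lie in [0, 1]")
  if (depth <= 0) abort("`depth` must be > 0")
  if (dispersion <= 0) abort("`dispersion` must be > 0")
  if (pas_spacing < 1) abort("`pas_spacing` must be >= 1")
  if (site_jitter_sd < 0) abort("`site_jitter_sd` must be >= 0")
  spec <- list(n_genes = as.integer(n_genes),
               fraction_shifted = fraction_shifted,
               fraction_lengthened_among_shifted = fraction_lengthened_among_shifted,
               delta = delta, depth = depth, dispersion = dispersion,
               pas_spacing = as.integer(pas_spacing),
               site_jitter_sd = site_jitter_sd,
               ugua_fraction = ugua_fraction, seed = as.integer(seed))
  class(spec) <- "synthetic_spec"
  spec
}

# Fixed gene architecture of the simulator.
SIM_CDS_LEN <- 300L       # single CDS exon
SIM_PPAS_OFFSET <- 150L   # stop codon to proximal PAS, nt
SIM_UTR_TAIL <- 80L       # bases retained past the distal cleavage site
SIM_GAP <- 1200L          # intergenic spacing, > consensus chain distance
SIM_CHROM <- "chrS"

sim_gene_layout <- function(spec) {
  L <- SIM_CDS_LEN + SIM_PPAS_OFFSET + spec$pas_spacing + SIM_UTR_TAIL + 1L
  step <- L + SIM_GAP
  g <- SIM_GAP + (seq_len(spec$n_genes) - 1L) * step
  strand <- rep(c("+", "-"), length.out = spec$n_genes)
  plus <- strand == "+"
  stop_pos <- ifelse(plus, g + SIM_CDS_LEN, g + L - SIM_CDS_LEN)
  p_pas <- ifelse(plus, stop_pos + SIM_PPAS_OFFSET, stop_pos - 1L - SIM_PPAS_OFFSET)
  d_pas <- ifelse(plus, p_pas + spec$pas_spacing, p_pas - spec$pas_spacing)
  tibble(gene_id = sprintf("gene%04d", seq_len(spec$n_genes)),
         chrom = SIM_CHROM, strand = strand,
         gene_start = as.integer(g), gene_end = as.integer(g + L),
         stop_pos = as.integer(stop_pos),
         p_pas = as.integer(p_pas), d_pas = as.integer(d_pas))
}

# Write `motif` (DNA) so that its transcript-oriented first base sits at
# `offset` (negative = upstream) relative to the cleavage base `pas`,
# within a gene-local character string starting at genomic `block_start`.
plant_motif <- function(block, block_start, pas, offset, motif, strand) {
  n <- nchar(motif)
  gstart <- if (strand == "+") pas + offset else pas - offset - (n - 1L)
  written <- if (strand == "+") motif else reverse_complement(motif)
  local <- gstart - block_start
  substr(block, local + 1L, local + n) <- written
  block
}

#' Simulate a two-condition PAS-seq dataset with known ground truth
#'
#' For every gene, a proximal and a distal PAS are placed `pas_spacing` nt
#' apart in a synthetic 3' UTR, with the canonical AAUAAA signal planted 21
#' nt upstream of each cleavage site and a UGUA element planted 40 nt
#' upstream of the distal PAS only, for a random `ugua_fraction` subset of
#' genes. The control condition draws its distal usage
#' `pi0 ~ Uniform(0.2, 0.8)`; the treatment uses `pi0 + delta` (lengthened
#' genes), `pi0 - delta` (shortened) or `pi0` (null), clipped to \[0, 1\]
#' with a message when clipping occurs. Per-PAS read counts are negative
#' binomial with mean `depth * usage`, and each read's 3' end is scattered
#' around its PAS with integer-rounded Gaussian jitter.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Optional output directory; when given, `annotation.gtf`,
#'   `genome.fa`, `sites.tsv` and `truth.tsv` are written there.
#' @param quiet Suppress the clipping message.
#' @return A list: `sites` (site table for samples `control` and
#'   `treatment`), `features` (gene-model feature table as [read_gtf()]
#'   returns), `genome` (a `DNAStringSet`), `truth` (per-gene tibble:
#'   `gene_id`, `strand`, `p_pas`, `d_pas`, `pi0`, `pi1`, `label`,
#'   `ugua_planted`), `spec`, and `paths` when `dir` is given.
#' @export
simulate_apa_dataset <- function(spec = synthetic_spec(), dir = NULL,
                                 quiet = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    genes <- sim_gene_layout(spec)
    n <- nrow(genes)

    # planted truth
    n_shifted <- round(n * spec$fraction_shifted)
    n_len <- round(n_shifted * spec$fraction_lengthened_among_shifted)
    shifted <- sample(n, n_shifted)
    label <- rep("null", n)
    label[shifted[seq_len(n_len)]] <- "lengthened"
    if (n_shifted > n_len) {
      label[shifted[(n_len + 1):n_shifted]] <- "shortened"
    }
    ugua <- rep(FALSE, n)
    ugua[sample(n, round(n * spec$ugua_fraction))] <- TRUE
    pi0 <- runif(n, 0.2, 0.8)
    pi1_raw <- pi0 + ifelse(label == "lengthened", spec$delta,
                            ifelse(label == "shortened", -spec$delta, 0))
    n_clipped <- sum(pi1_raw < 0 | pi1_raw > 1)
    if (n_clipped > 0 && !quiet) {
      inform(sprintf("%d treatment usage value(s) clipped into [0, 1]", n_clipped))
    }
    pi1 <- pmin(1, pmax(0, pi1_raw))

    # genome: per-gene blocks (gene body + downstream gap) with planted motifs
    step <- genes$gene_end[1] - genes$gene_start[1] + SIM_GAP
    blocks <- character(n + 1L)
    blocks[1] <- paste(sample(c("A", "C", "G", "T"), SIM_GAP, replace = TRUE),
                       collapse = "")
    for (i in seq_len(n)) {
      blk <- paste(sample(c("A", "C", "G", "T"), step, replace = TRUE),
                   collapse = "")
      bs <- genes$gene_start[i]
      st <- genes$strand[i]
      blk <- plant_motif(blk, bs, genes$p_pas[i], -21L, "AATAAA", st)
      blk <- plant_motif(blk, bs, genes$d_pas[i], -21L, "AATAAA", st)
      if (ugua[i]) blk <- plant_motif(blk, bs, genes$d_pas[i], -40L, "TGTA", st)
      blocks[i + 1L] <- blk
    }
    chrom_seq <- paste(blocks, collapse = "")
    genome <- Biostrings::DNAStringSet(setNames(chrom_seq, SIM_CHROM))

    # counts: NB totals per PAS, Gaussian read-end jitter
    usage <- list(control = pi0, treatment = pi1)
    sites <- purrr::map_dfr(names(usage), function(cond) {
      pi <- usage[[cond]]
      n_d <- rnbinom(n, mu = spec$depth * pi, size = spec$dispersion)
      n_p <- rnbinom(n, mu = spec$depth * (1 - pi), size = spec$dispersion)
      pas <- c(rep(genes$p_pas, n_p), rep(genes$d_pas, n_d))
      strand <- c(rep(genes$strand, n_p), rep(genes$strand, n_d))
      pos <- pas + as.integer(round(rnorm(length(pas), 0, spec$site_jitter_sd)))
      pos <- pmin(pmax(pos, 0L), nchar(chrom_seq) - 1L)
      tibble(chrom = SIM_CHROM, position = pos, strand = strand) %>%
        count(.data$chrom, .data$position, .data$strand, name = "count") %>%
        mutate(sample = cond, count = as.integer(.data$count))
    }) %>%
      select("chrom", "position", "strand", "sample", "count") %>%
      arrange(.data$sample, .data$chrom, .data$position, .data$strand)

    features <- bind_rows(
      genes %>% mutate(type = "exon", start = .data$gene_start,
                       end = .data$gene_end),
      genes %>% mutate(type = "CDS",
                       start = ifelse(.data$strand == "+", .data$gene_start,
                                      .data$gene_end - SIM_CDS_LEN),
                       end = ifelse(.data$strand == "+",
                                    .data$gene_start + SIM_CDS_LEN,
                                    .data$gene_end))) %>%
      mutate(transcript_id = paste0(.data$gene_id, ".t1")) %>%
      select("gene_id", "transcript_id", "type", "chrom", "start", "end",
             "strand") %>%
      arrange(.data$start, .data$transcript_id, .data$type)

    truth <- genes %>%
      select("gene_id", "chrom", "strand", "stop_pos", "p_pas", "d_pas") %>%
      mutate(pi0 = pi0, pi1 = pi1, label = label, ugua_planted = ugua)

    out <- list(sites = sites, features = features, genome = genome,
                truth = truth, spec = spec)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      paths <- list(annotation = file.path(dir, "annotation.gtf"),
                    genome = file.path(dir, "genome.fa"),
                    sites = file.path(dir, "sites.tsv"),
                    truth = file.path(dir, "truth.tsv"))
      write_gtf(features, paths$annotation)
      Biostrings::writeXStringSet(genome, paths$genome)
      write_site_table(sites, paths$sites)
      readr::write_tsv(truth, paths$truth)
      out$paths <- paths
    }
    out
  })
}

#' Simulate a cohort PDUI matrix with a marker-linked usage shift
#'
#' Emulates a tumour-cohort PDUI resource: marker-gene expression is
#' log-normal across samples; samples above the median marker expression
#' have every gene's PDUI shifted by `marker_effect` on the logit scale
#' (positive effect = higher distal usage in marker-high samples), on top
#' of per-gene baselines `Uniform(0.2, 0.8)` and per-observation logit
#' noise.
#'
#' @param n_samples Number of samples (>= 4).
#' @param n_genes Number of genes.
#' @param marker_effect Logit-scale PDUI shift in marker-high samples.
#' @param seed Integer seed.
#' @param noise_sd Logit-scale sd of per-observation noise.
#' @return A list: `pdui` (wide tibble, `gene_id` plus one column per
#'   sample), `marker` (tibble `sample`, `expression`), `truth` (baselines
#'   and the high-group sample ids).
#' @export
simulate_cohort_pdui <- function(n_samples = 48, n_genes = 200,
                                 marker_effect = 1, seed = 1,
                                 noise_sd = 0.5) {
  if (n_samples < 4) abort("`n_samples` must be >= 4")
  withr::with_seed(as.integer(seed), {
    samples <- sprintf("S%03d", seq_len(n_samples))
    expression <- rlnorm(n_samples, meanlog = 2, sdlog = 0.5)
    high <- expression > median(expression)
    base <- runif(n_genes, 0.2, 0.8)
    logit <- outer(qlogis(base), ifelse(high, marker_effect, 0), "+") +
      matrix(rnorm(n_genes * n_samples, 0, noise_sd), n_genes, n_samples)
    pdui <- as_tibble(setNames(as.data.frame(plogis(logit)), samples)) %>%
      mutate(gene_id = sprintf("gene%04d", seq_len(n_genes)), .before = 1)
    list(pdui = pdui,
         marker = tibble(sample = samples, expression = expression),
         truth = list(base_pdui = base, high_samples = samples[high],
                      marker_effect = marker_effect))
  })
}
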