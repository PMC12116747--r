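# Hexamer / UGUA scanning, context annotation and the signal mutagenesis
# utility.

test_that("hexamer scanning reports nearest-first hits with first-base offsets", {
  # AAUAAA with its first base 20 nt upstream of the cleavage site
  seq <- paste0(strrep("C", 30), "AATAAA", strrep("C", 14), "G")
  pas <- nchar(seq) - 1L
  hits <- scan_pas_hexamers(seq, pas, window = 40)
  expect_equal(hits$motif, "AAUAAA")
  expect_equal(hits$offset, -20L)
  expect_equal(hits$position, pas - 20L)

  expect_equal(nrow(scan_pas_hexamers(strrep("C", 100), 80)), 0)

  # two signals: the nearer one (AUUAAA at -18) comes first
  s2 <- strrep("C", 61)
  substr(s2, 60 - 40 + 1, 60 - 40 + 6) <- "AATAAA"   # first base at offset -40
  substr(s2, 60 - 18 + 1, 60 - 18 + 6) <- "ATTAAA"   # first base at offset -18
  h2 <- scan_pas_hexamers(s2, 60L, window = 50)
  expect_equal(h2$motif, c("AUUAAA", "AAUAAA"))
  expect_equal(h2$offset, c(-18L, -40L))
})

test_that("UGUA scanning matches the worked example and boundary truncation", {
  hits <- scan_ugua("AATGTAAA", 7L, window = 7)
  expect_equal(hits$motif, "UGUA")
  expect_equal(hits$offset, -5L)

  expect_equal(nrow(scan_ugua(strrep("A", 50), 40L, window = 30)), 0)
  expect_message(scan_ugua("AATGTAAA", 7L, window = 20), "truncated")
})

test_that("scanning is strand-consistent under reverse complementation", {
  withr::local_seed(13)
  for (i in 1:20) {
    n <- 120
    fwd <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                 collapse = "")
    pas <- sample(60:100, 1)
    rev <- paste(rev(strsplit(chartr("ACGT", "TGCA", fwd), "")[[1]]),
                 collapse = "")
    pas_rev <- n - 1L - pas
    h_f <- scan_pas_hexamers(fwd, pas, window = 50, strand = "+", quiet = TRUE)
    h_r <- scan_pas_hexamers(rev, pas_rev, window = 50, strand = "-",
                             quiet = TRUE)
    expect_equal(h_f$motif, h_r$motif)
    expect_equal(h_f$offset, h_r$offset)
  }
})

test_that("context labels follow the precedence chain", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  attrs <- 'gene_id "g1"; transcript_id "g1.t";'
  # two-exon gene: exons [0,1000) + [2000,3500), CDS [0,1000)+[2000,2500)
  writeLines(c(
    sprintf("chr1\tt\texon\t1\t1000\t.\t+\t.\t%s", attrs),
    sprintf("chr1\tt\texon\t2001\t3500\t.\t+\t.\t%s", attrs),
    sprintf("chr1\tt\tCDS\t1\t1000\t.\t+\t0\t%s", attrs),
    sprintf("chr1\tt\tCDS\t2001\t2500\t.\t+\t0\t%s", attrs)), gtf)
  genes <- read_gtf(gtf)
  pac <- function(start, end) {
    tibble::tibble(pac_id = "p", chrom = "chr1", strand = "+",
                   start = start, end = end, tpm = 10)
  }
  lab <- function(p) as.character(annotate_context(p, genes)$context)
  expect_equal(lab(pac(2600L, 2620L)), "3UTR")
  expect_equal(lab(pac(500L, 520L)), "CDS-exon")
  expect_equal(lab(pac(1500L, 1520L)), "intron")
  expect_equal(lab(pac(3600L, 3620L)), "downstream-1kb")
  expect_equal(lab(pac(9000L, 9020L)), "intergenic")
  # straddling UTR and intron: UTR wins by precedence
  expect_equal(lab(pac(1900L, 2600L)), "3UTR")

  freq <- context_frequencies(annotate_context(pac(2600L, 2620L), genes))
  expect_equal(sum(freq$n), 1)
  expect_equal(freq$n[freq$context == "3UTR"], 1)
})

test_that("context frequencies track feature footprint for uniform PACs", {
  # single-exon gene occupying [0, 4000): CDS [0,2000), UTR [2000,4000),
  # downstream [4000,5000), intergenic [5000,10000)
  gtf <- withr::local_tempfile(fileext = ".gtf")
  attrs <- 'gene_id "g1"; transcript_id "g1.t";'
  writeLines(c(sprintf("chr1\tt\texon\t1\t4000\t.\t+\t.\t%s", attrs),
               sprintf("chr1\tt\tCDS\t1\t2000\t.\t+\t0\t%s", attrs)), gtf)
  genes <- read_gtf(gtf)
  withr::local_seed(17)
  starts <- sample(0:9998, 4000, replace = TRUE)
  pacs <- tibble::tibble(pac_id = sprintf("p%d", seq_along(starts)),
                         chrom = "chr1", strand = "+", start = starts,
                         end = starts + 1L, tpm = 1)
  freq <- context_frequencies(annotate_context(pacs, genes))
  got <- stats::setNames(freq$fraction, as.character(freq$context))
  expect_equal(unname(got["3UTR"]), 0.2, tolerance = 0.12)
  expect_equal(unname(got["CDS-exon"]), 0.2, tolerance = 0.12)
  expect_equal(unname(got["downstream-1kb"]), 0.1, tolerance = 0.2)
  expect_equal(unname(got["intergenic"]), 0.5, tolerance = 0.1)
})

test_that("proximal-signal mutagenesis swaps the hexamer for CCCCCC only", {
  seq <- paste0("GGG", "ATTAAA", "GGGTTT")
  out <- mutate_proximal_pas(seq, c(3L, 9L))
  expect_equal(out$sequence, "GGGCCCCCCGGGTTT")
  expect_equal(nchar(out$sequence), nchar(seq))     # length invariant
  expect_equal(out$edit$original, "ATTAAA")
  # RNA input stays RNA-alphabet compatible
  rna <- mutate_proximal_pas("GGAUUAAAGG", c(2L, 8L))
  expect_equal(substr(rna$sequence, 3, 8), "CCCCCC")
  # an unrecognised interval is refused
  expect_error(mutate_proximal_pas("GGAAAAAAGG", c(2L, 8L)), "recognised")
})

test_that("planted signals in simulated genomes peak at the planted offset", {
  sim <- simulate_apa_dataset(synthetic_spec(n_genes = 40, seed = 5),
                              quiet = TRUE)
  chrom <- as.character(sim$genome[[1]])
  offs <- purrr::map_int(seq_len(nrow(sim$truth)), function(i) {
    g <- sim$truth[i, ]
    h <- scan_pas_hexamers(chrom, g$d_pas, window = 50, strand = g$strand,
                           motifs = "AAUAAA", quiet = TRUE)
    if (nrow(h) == 0) NA_integer_ else h$offset[1]
  })
  # the modal nearest-hit offset is the planted -21
  expect_equal(as.integer(names(sort(table(offs), decreasing = TRUE))[1]), -21L)
  expect_gt(mean(offs == -21, na.rm = TRUE), 0.8)

  # UGUA planted upstream of the dPAS only for the flagged subset
  ug <- sim$truth[sim$truth$ugua_planted, ][1, ]
  hits <- scan_ugua(chrom, ug$d_pas, window = 45, strand = ug$strand,
                    quiet = TRUE)
  expect_true(-40L %in% hits$offset)
})
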