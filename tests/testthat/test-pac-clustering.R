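# PAC clustering sweeps, singleton filtering, consensus construction and
# gene assignment.

tpm_sites <- function(position, ...) {
  compute_tpm(make_sites(position, ...))
}

test_that("adjacent-gap sweep reproduces the worked examples and boundaries", {
  pacs <- cluster_sites(tpm_sites(c(100, 110, 130, 160)))
  expect_equal(nrow(pacs), 2)
  expect_equal(pacs$start, c(100L, 160L))
  expect_equal(pacs$end, c(131L, 161L))
  expect_equal(pacs$n_sites, c(3L, 1L))

  expect_equal(nrow(cluster_sites(tpm_sites(50))), 1)              # singleton
  expect_equal(nrow(cluster_sites(tpm_sites(c(100, 124)))), 1)     # gap 24: one PAC
  expect_equal(nrow(cluster_sites(tpm_sites(c(100, 125)))), 2)     # gap 25: two
  expect_equal(nrow(cluster_sites(tpm_sites(integer(0))[0, ])), 0)
})

test_that("sweep clustering matches the transitive-closure oracle and its gap laws", {
  skip_if_not_installed("igraph")
  withr::local_seed(7)
  for (i in 1:60) {
    n <- sample(200, 1)
    pos <- sort(sample(2000, n))
    gap <- sample(c(1, 10, 24, 50), 1)
    got <- cluster_sites(tpm_sites(pos), max_gap = gap)
    want <- canonical_partition(oracle_cluster(pos, gap))
    expect_equal(nrow(got), length(want))
    expect_equal(got$start, vapply(want, min, numeric(1)))
    expect_equal(got$end - 1L, vapply(want, max, numeric(1)))
    # maximal-gap property: intra-PAC gaps <= gap, inter-PAC gaps > gap
    if (nrow(got) > 1) {
      expect_true(all(got$start[-1] - got$end[-nrow(got)] + 1L > gap))
    }
    # idempotence on singleton summits
    again <- cluster_sites(tpm_sites(got$summit), max_gap = 0)
    expect_equal(nrow(again), nrow(got))
  }
})

test_that("summit is the max-TPM member and PAC TPM conserves member TPM", {
  sites <- tpm_sites(c(10, 20, 30), count = c(5L, 50L, 10L))
  pac <- cluster_sites(sites)
  expect_equal(pac$summit, 20L)
  expect_equal(pac$tpm, sum(sites$tpm))
})

test_that("only weak singletons are removed by the singleton filter", {
  pacs <- tibble::tibble(pac_id = c("a", "b", "c"), sample = "s1",
                         chrom = "chr1", strand = "+",
                         start = c(1L, 50L, 100L), end = c(2L, 51L, 120L),
                         n_sites = c(1L, 1L, 2L), tpm = c(2.9, 3.0, 1.5),
                         summit = c(1L, 50L, 100L))
  kept <- filter_singleton_pacs(pacs)
  expect_equal(kept$pac_id, c("b", "c"))   # tpm 3.0 retained, multi-site retained
})

test_that("consensus chains PAC summits across samples within the distance", {
  pacs <- dplyr::bind_rows(
    cluster_sites(tpm_sites(1000, sample = "s1", count = 8L)),
    cluster_sites(tpm_sites(1280, sample = "s2", count = 9L)))
  # counts are each sample's only reads, so TPM = 1e6 >> threshold
  one <- build_consensus(pacs)
  expect_equal(dplyr::n_distinct(one$consensus_id), 1)
  expect_equal(sort(unique(one$sample)), c("s1", "s2"))

  far <- dplyr::bind_rows(
    cluster_sites(tpm_sites(1000, sample = "s1")),
    cluster_sites(tpm_sites(1600, sample = "s2")))
  expect_equal(dplyr::n_distinct(build_consensus(far)$consensus_id), 2)
})

test_that("the consensus TPM threshold is strict and TPM is conserved", {
  pacs <- tibble::tibble(pac_id = c("p1", "p2", "p3"),
                         sample = c("s1", "s1", "s2"),
                         chrom = "chr1", strand = "+",
                         start = c(100L, 140L, 150L), end = c(110L, 145L, 160L),
                         n_sites = 2L, tpm = c(5.0, 8.5, 9.25),
                         summit = c(105L, 141L, 155L))
  cons <- build_consensus(pacs, max_distance = 500, min_tpm = 5)
  # the tpm-5.0 PAC is excluded (strict >), the others chain into one consensus
  expect_equal(dplyr::n_distinct(cons$consensus_id), 1)
  expect_equal(cons$tpm[cons$sample == "s1"], 8.5)
  expect_equal(cons$tpm[cons$sample == "s2"], 9.25)
})

test_that("gene assignment uses strand-matched UTR overlap, margins and stop distance", {
  gtf <- write_toy_gtf(withr::local_tempfile(fileext = ".gtf"), tibble::tibble(
    gene_id = c("gA", "gB"), tx_id = c("gA.t", "gB.t"), chrom = "chr1",
    strand = "+", exon_start = c(0L, 1800L), exon_end = c(2000L, 4000L),
    cds_start = c(0L, 1800L), cds_end = c(1000L, 3000L)))
  genes <- read_gtf(gtf)
  cons <- function(start, end, summit) {
    tibble::tibble(consensus_id = "c1", chrom = "chr1", strand = "+",
                   start = start, end = end, summit = summit,
                   n_pacs = 1L, sample = "s1", tpm = 10)
  }
  # inside gA's UTR [1000, 2000)
  expect_equal(unique(assign_to_genes(cons(1100L, 1120L, 1110L), genes)$gene_id), "gA")
  # 800 nt past gB's UTR end: caught with the 1 kb margin, not with 500
  past <- cons(4800L, 4820L, 4810L)
  expect_equal(unique(assign_to_genes(past, genes, margin = 1000)$gene_id), "gB")
  expect_equal(unique(assign_to_genes(past, genes, margin = 500)$gene_id), "intergenic")
  # overlapping both genes (gA's margin-extended UTR and gB's UTR):
  # the nearer stop codon wins (gB stop at 3000, 10 nt from the summit)
  both <- cons(2950L, 3050L, 2990L)
  expect_equal(unique(assign_to_genes(both, genes)$gene_id), "gB")
})
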