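# Signal profiles, the shifting score, the count-weighted KS test, calls
# and gene summaries.

two_sample_sites <- function(pos_a, count_a, pos_b, count_b, strand = "+") {
  dplyr::bind_rows(
    make_sites(pos_a, sample = "ctrl", count = count_a, strand = strand),
    make_sites(pos_b, sample = "trt", count = count_b, strand = strand)) |>
    compute_tpm()
}

toy_consensus <- function(start, end, strand = "+", id = "c1") {
  tibble::tibble(consensus_id = id, chrom = "chr1", strand = strand,
                 start = start, end = end, summit = start, n_pacs = 2L,
                 sample = rep(c("ctrl", "trt"), each = length(start)),
                 tpm = 50)
}

test_that("profiles are strand-ordered, normalised, and skip one-sided PACs", {
  sites <- two_sample_sites(c(10, 20), c(3L, 1L), c(10, 20), c(1L, 1L))
  prof <- pac_signal_profiles(toy_consensus(5L, 30L), sites, "ctrl", "trt")
  expect_equal(prof$position[order(prof$rank)], c(10L, 20L))
  expect_equal(prof$p_a[order(prof$rank)], c(0.75, 0.25))
  expect_equal(sum(prof$p_b), 1)

  minus <- two_sample_sites(c(10, 20), c(3L, 1L), c(10, 20), c(1L, 1L),
                            strand = "-")
  prof_m <- pac_signal_profiles(toy_consensus(5L, 30L, strand = "-"),
                                minus, "ctrl", "trt")
  expect_equal(prof_m$position[order(prof_m$rank)], c(20L, 10L))

  lone <- dplyr::bind_rows(
    make_sites(10, sample = "ctrl", count = 5L),
    make_sites(900, sample = "trt", count = 5L)) |> compute_tpm()
  expect_message(
    prof_s <- pac_signal_profiles(toy_consensus(5L, 30L), lone, "ctrl", "trt"),
    "skipped")
  expect_equal(nrow(prof_s), 0)
  expect_equal(attr(prof_s, "skipped")$reason, "no signal in trt")
})

test_that("the shifting score honours its overlap contract", {
  p <- c(0.2, 0.5, 0.3)
  expect_identical(shifting_score(p, p), -1)                       # identical
  expect_equal(shifting_score(c(1, 0), c(0, 1)), 1)                # disjoint
  expect_equal(shifting_score(c(0.5, 0.5, 0), c(0, 0.5, 0.5)), 0)  # half overlap
  expect_error(shifting_score(c(0.5, 0.4), c(0.5, 0.5)), "sum to 1")
  expect_error(shifting_score(c(1), c(0.5, 0.5)), "equal length")
})

test_that("score is symmetric and bounded on random profile pairs", {
  withr::local_seed(3)
  for (i in 1:200) {
    k <- sample(2:30, 1)
    pa <- runif(k); pa <- pa / sum(pa)
    pb <- runif(k); pb <- pb / sum(pb)
    s <- shifting_score(pa, pb)
    expect_gte(s, -1); expect_lte(s, 1)
    expect_equal(shifting_score(pb, pa), s)   # label swap leaves S unchanged
    # brute-force overlap cross-check
    expect_equal(s, 1 - 2 * sum(mapply(min, pa, pb)))
  }
})

test_that("KS statistic matches hand-computed cumulatives and the contract", {
  ident <- ks_test_pac(c(3L, 7L), c(3L, 7L))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)

  disjoint <- ks_test_pac(c(10L, 0L), c(0L, 10L))
  expect_equal(disjoint$statistic, 1)

  # A = (5,5), B = (2,8): cumulative 0.5 vs 0.2 -> D = 0.3
  worked <- ks_test_pac(c(5L, 5L), c(2L, 8L))
  expect_equal(worked$statistic, 0.3)
  expect_equal(worked$n_eff, 5)
  expect_equal(worked$method, "exact")

  expect_error(ks_test_pac(c(0L, 0L), c(1L, 2L)), "at least one read")
  # swapping the samples leaves D and p unchanged
  expect_equal(ks_test_pac(c(2L, 8L), c(5L, 5L))$p_value, worked$p_value)
})

test_that("exact and asymptotic KS tails agree with a permutation oracle", {
  withr::local_seed(11)
  for (i in 1:25) {
    k <- sample(3:8, 1)
    ca <- as.integer(rmultinom(1, sample(8:40, 1), runif(k)))
    cb <- as.integer(rmultinom(1, sample(8:40, 1), runif(k)))
    if (sum(ca) == 0 || sum(cb) == 0) next
    got <- ks_test_pac(ca, cb)
    oracle <- oracle_ks_perm(ca, cb, B = 2000)
    expect_equal(got$statistic, oracle$d)
    se <- sqrt(oracle$p * (1 - oracle$p) / 2000)
    expect_lt(abs(got$p_value - oracle$p), 4 * se + 0.02)
  }
  # large counts take the asymptotic route and stay near the exact tail
  big <- ks_test_pac(c(300L, 200L), c(200L, 300L))
  expect_equal(big$method, "asymptotic")
  exact <- ks_test_pac(c(300L, 200L), c(200L, 300L), exact = TRUE)
  expect_lt(abs(big$p_value - exact$p_value), 0.01)
})

test_that("significance calls implement the published rule layers", {
  results <- tibble::tibble(
    consensus_id = c("a", "b", "c", "d"),
    score = c(0.2, -0.1, 0.4, 0.3),
    p = c(0.0005, 0.0001, 0.016, 0.002),
    tpm_a = c(10, 20, 30, 3), tpm_b = c(12, 25, 35, 40),
    dist_frac_a = c(0.2, 0.5, 0.3, 0.2), dist_frac_b = c(0.7, 0.2, 0.6, 0.9))
  called <- call_significant(results, alpha = 0.01, min_tpm = 5)
  expect_equal(called$q, p.adjust(results$p, "BH"))
  # a: S>0, q<=0.01, TPM ok -> significant
  expect_true(called$significant[called$consensus_id == "a"])
  # b: q fine but S<0 -> detected, not significant
  expect_true(called$detected[called$consensus_id == "b"])
  expect_false(called$significant[called$consensus_id == "b"])
  # c: q above alpha -> nothing
  expect_false(called$detected[called$consensus_id == "c"])
  expect_equal(called$direction[called$consensus_id == "c"], "none")
  # d: TPM 3 in sample A fails the strict > 5 pair condition
  expect_false(called$detected[called$consensus_id == "d"])
})

test_that("direction compares distal fractions around the pooled median", {
  prof <- tibble::tibble(
    consensus_id = "c1", position = c(10L, 20L), rank = 1:2,
    count_a = c(8L, 2L), count_b = c(3L, 7L),
    tpm_a = c(8, 2), tpm_b = c(3, 7),
    p_a = c(0.8, 0.2), p_b = c(0.3, 0.7))
  d <- classify_direction(prof)
  expect_equal(d$dist_frac_a, 0.2)
  expect_equal(d$dist_frac_b, 0.7)
  expect_equal(d$direction, "lengthened")

  # swapping the sample labels flips the call
  swapped <- dplyr::mutate(prof,
                           p_a = c(0.3, 0.7), p_b = c(0.8, 0.2),
                           tpm_a = c(3, 7), tpm_b = c(8, 2),
                           count_a = c(3L, 7L), count_b = c(8L, 2L))
  d2 <- classify_direction(swapped)
  expect_equal(d2$direction, "shortened")
  expect_equal(c(d2$dist_frac_a, d2$dist_frac_b), c(0.7, 0.2))
})

test_that("an FDX1-like two-PAS gene under treatment is called lengthened", {
  # proximal-heavy control, distal-heavy treatment across two site clusters
  sites <- two_sample_sites(
    c(100:102, 400:402), c(40L, 45L, 35L, 10L, 12L, 8L),
    c(100:102, 400:402), c(12L, 15L, 10L, 40L, 42L, 38L))
  cons <- toy_consensus(90L, 410L)
  res <- apa_shift_test(cons, sites, "ctrl", "trt", quiet = TRUE)
  expect_true(res$detected)
  expect_equal(res$direction, "lengthened")
  expect_lt(res$q, 0.01)
})

test_that("gene summaries pick the lowest-q PAC and count directions", {
  res <- tibble::tibble(
    consensus_id = c("c1", "c2", "c3", "c4", "c5"),
    gene_id = c("g1", "g1", "g2", "g3", "g4"),
    score = 0.1, ks_d = 0.5,
    p = c(0.001, 0.04, 0.001, 0.001, 0.001),
    q = c(0.001, 0.04, 0.001, 0.001, 0.001),
    tpm_a = 10, tpm_b = 10,
    dist_frac_a = c(0.1, 0.8, 0.1, 0.1, 0.8),
    dist_frac_b = c(0.8, 0.1, 0.9, 0.9, 0.1),
    detected = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    significant = FALSE,
    direction = c("lengthened", "shortened", "lengthened", "lengthened", "none"))
  class(res) <- c("apa_shift_result", class(res))
  g <- summarize_genes(res)
  expect_equal(nrow(g), 4)
  g1 <- g[g$gene_id == "g1", ]
  expect_equal(g1$consensus_id, "c1")       # lowest q wins
  expect_equal(g1$direction, "lengthened")
  expect_true(g1$discordant)                # its PACs disagree
  counts <- attr(g, "counts")
  expect_equal(counts$n_lengthened, 3)
  expect_equal(counts$prop_lengthened, 3 / 3)  # the shortened g1 PAC lost to c1
  expect_equal(nrow(summarize_genes(res[0, ])), 0)
})
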