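# Fixtures built in code and independent brute-force oracles used across
# the suite.

make_sites <- function(position, sample = "s1", count = 10L, chrom = "chr1",
                       strand = "+", tpm = NULL) {
  d <- tibble::tibble(chrom = chrom, position = as.integer(position),
                      strand = strand, sample = sample,
                      count = as.integer(count))
  if (!is.null(tpm)) d$tpm <- tpm
  d
}

# One-gene-per-strand toy annotation writer (1-based GTF on disk).
write_toy_gtf <- function(path, genes) {
  lines <- unlist(lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', g$gene_id, g$tx_id)
    c(sprintf("%s\ttest\texon\t%d\t%d\t.\t%s\t.\t%s",
              g$chrom, g$exon_start + 1L, g$exon_end, g$strand, attrs),
      sprintf("%s\ttest\tCDS\t%d\t%d\t.\t%s\t0\t%s",
              g$chrom, g$cds_start + 1L, g$cds_end, g$strand, attrs))
  }))
  writeLines(lines, path)
  path
}

# Synthetic alignment fixture: SAM written in code, converted to an indexed
# BAM via Rsamtools. Read layout is chosen so every extraction rule
# (terminal base, strand mirror, soft-clip, MAPQ, secondary) is exercised.
make_test_bam <- function(dir = tempdir()) {
  sam <- file.path(dir, "toy.sam")
  seq50 <- strrep("A", 50)
  lines <- c(
    "@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:chrT\tLN:10000",
    # forward alignment [100,150) 0-based
    sprintf("r1\t0\tchrT\t101\t60\t50M\t*\t0\t0\t%s\t*", seq50),
    # reverse alignment [100,150)
    sprintf("r2\t16\tchrT\t101\t60\t50M\t*\t0\t0\t%s\t*", seq50),
    # 3' soft-clip of 5: aligned span [200,245)
    sprintf("r3\t0\tchrT\t201\t60\t45M5S\t*\t0\t0\t%s\t*", seq50),
    # low MAPQ: dropped at min_mapq 10
    sprintf("r4\t0\tchrT\t301\t3\t50M\t*\t0\t0\t%s\t*", seq50),
    # secondary alignment: always dropped
    sprintf("r5\t256\tchrT\t401\t60\t50M\t*\t0\t0\t%s\t*", seq50))
  writeLines(lines, sam)
  bam <- suppressMessages(Rsamtools::asBam(sam, file.path(dir, "toy"),
                                           overwrite = TRUE))
  bam
}

# O(n^2) transitive-closure clustering oracle: sites i, j are linked iff
# |pos_i - pos_j| <= gap; clusters are the connected components.
oracle_cluster <- function(positions, gap) {
  n <- length(positions)
  if (n == 0) return(list())
  adj <- abs(outer(positions, positions, "-")) <= gap
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  unname(lapply(split(positions, comp), sort))
}

canonical_partition <- function(groups) {
  groups <- lapply(groups, sort)
  groups[order(vapply(groups, min, numeric(1)))]
}

# Monte-Carlo permutation oracle for the two-sample KS test on per-position
# counts (label permutation of the pooled reads).
oracle_ks_perm <- function(counts_a, counts_b, B = 2000) {
  k <- length(counts_a)
  pooled <- rep(seq_len(k), counts_a + counts_b)
  n_a <- sum(counts_a); n_b <- sum(counts_b)
  dstat <- function(a_idx) {
    ta <- tabulate(pooled[a_idx], k)
    tb <- tabulate(pooled[-a_idx], k)
    max(abs(cumsum(ta) / n_a - cumsum(tb) / n_b))
  }
  f_a <- cumsum(counts_a) / n_a
  f_b <- cumsum(counts_b) / n_b
  obs <- max(abs(f_a - f_b))
  ds <- replicate(B, dstat(sample(length(pooled), n_a)))
  list(d = obs, p = mean(ds >= obs - 1e-12))
}

# Exact enumeration oracle for the two-sided Mann-Whitney U test
# (tie-free inputs, n <= 8 per group).
oracle_mann_whitney <- function(x, y) {
  pooled <- c(x, y)
  n_x <- length(x)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n_x * (n_x + 1) / 2
  }
  u_obs <- u_of(seq_len(n_x))
  all_idx <- utils::combn(length(pooled), n_x)
  us <- apply(all_idx, 2, u_of)
  u_max <- n_x * length(y)
  u_low <- min(u_obs, u_max - u_obs)
  p <- mean(us <= u_low) + mean(us >= u_max - u_low)
  list(u = u_obs, p = min(1, p))
}

# Brute-force interval union over integer positions (0-based half-open).
oracle_union <- function(starts, ends) {
  pos <- sort(unique(unlist(mapply(seq, starts, ends - 1L, SIMPLIFY = FALSE))))
  if (length(pos) == 0) return(tibble::tibble(start = integer(), end = integer()))
  brk <- c(0, which(diff(pos) > 1), length(pos))
  tibble::tibble(start = pos[head(brk, -1) + 1],
                 end = pos[brk[-1]] + 1L)
}
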