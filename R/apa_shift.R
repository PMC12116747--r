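# Differential PAS usage between two samples: per-PAC signal profiles,
# the overlap-based shifting score, a count-weighted two-sample
# Kolmogorov-Smirnov test, FDR control and direction calls.

#' Paired per-position signal profiles for consensus PACs
#'
#' For each consensus PAC, collects the member-site TPM of the two compared
#' samples at every position inside the consensus interval, ordered 5' to 3'
#' along the transcript strand, and normalises each sample's vector to sum
#' to one. PACs with zero signal in either sample cannot be tested; they are
#' skipped and recorded in the `"skipped"` attribute (with a message unless
#' `quiet = TRUE`).
#'
#' @param consensus Consensus table from [build_consensus()] (optionally
#'   gene-assigned).
#' @param sites Site table with TPM, covering both samples.
#' @param sample_a,sample_b Sample identifiers: A is the control/reference,
#'   B the treatment.
#' @param quiet Suppress the skip message.
#' @return A tibble with one row per (consensus PAC, position):
#'   `consensus_id`, `gene_id` (if present on `consensus`), `position`,
#'   `rank` (1 = 5'-most), `count_a`, `count_b`, `tpm_a`, `tpm_b`, `p_a`,
#'   `p_b`. Attribute `"skipped"` lists untestable PACs and the reason;
#'   attribute `"samples"` names the pair.
#' @export
pac_signal_profiles <- function(consensus, sites, sample_a, sample_b,
                                quiet = FALSE) {
  validate_sites(sites, need_tpm = TRUE)
  for (s in c(sample_a, sample_b)) {
    if (!s %in% sites$sample) abort(sprintf("sample '%s' absent from `sites`", s))
  }
  cols <- c("consensus_id", "chrom", "strand", "start", "end",
            intersect("gene_id", names(consensus)))
  cons <- distinct(consensus[, cols])

  sub <- filter(sites, .data$sample %in% c(sample_a, sample_b))
  cons_gr <- GenomicRanges::GRanges(cons$chrom,
                                    IRanges::IRanges(cons$start + 1L, cons$end),
                                    strand = cons$strand)
  site_gr <- GenomicRanges::GRanges(sub$chrom,
                                    IRanges::IRanges(sub$position + 1L,
                                                     sub$position + 1L),
                                    strand = sub$strand)
  hits <- GenomicRanges::findOverlaps(site_gr, cons_gr, select = "first")
  sub <- sub[!is.na(hits), , drop = FALSE]
  sub$consensus_id <- cons$consensus_id[hits[!is.na(hits)]]

  wide <- sub %>%
    select("consensus_id", "position", "sample", "count", "tpm") %>%
    tidyr::pivot_wider(names_from = "sample",
                       values_from = c("count", "tpm"),
                       values_fill = 0, values_fn = sum)
  for (col in paste0(rep(c("count_", "tpm_"), each = 2),
                     c(sample_a, sample_b))) {
    if (!col %in% names(wide)) wide[[col]] <- 0
  }
  wide <- wide %>%
    rename(count_a = dplyr::all_of(paste0("count_", sample_a)),
           count_b = dplyr::all_of(paste0("count_", sample_b)),
           tpm_a = dplyr::all_of(paste0("tpm_", sample_a)),
           tpm_b = dplyr::all_of(paste0("tpm_", sample_b))) %>%
    left_join(select(cons, -"start", -"end", -"chrom"), by = "consensus_id") %>%
    mutate(.ord = ifelse(.data$strand == "+", .data$position, -.data$position)) %>%
    arrange(.data$consensus_id, .data$.ord) %>%
    group_by(.data$consensus_id) %>%
    mutate(rank = row_number(),
           .sum_a = sum(.data$tpm_a), .sum_b = sum(.data$tpm_b)) %>%
    ungroup()

  skipped <- wide %>%
    filter(.data$.sum_a == 0 | .data$.sum_b == 0) %>%
    distinct(.data$consensus_id, .data$.sum_a, .data$.sum_b) %>%
    mutate(reason = ifelse(.data$.sum_a == 0 & .data$.sum_b == 0,
                           "no signal in either sample",
                           ifelse(.data$.sum_a == 0,
                                  sprintf("no signal in %s", sample_a),
                                  sprintf("no signal in %s", sample_b)))) %>%
    select("consensus_id", "reason")
  untested <- setdiff(cons$consensus_id, wide$consensus_id)
  if (length(untested) > 0) {
    skipped <- bind_rows(skipped, tibble(consensus_id = untested,
                                         reason = "no member sites"))
  }
  if (nrow(skipped) > 0 && !quiet) {
    inform(sprintf("%d consensus PAC(s) skipped (zero signal in a sample)",
                   nrow(skipped)))
  }

  out <- wide %>%
    filter(.data$.sum_a > 0 & .data$.sum_b > 0) %>%
    mutate(p_a = .data$tpm_a / .data$.sum_a,
           p_b = .data$tpm_b / .data$.sum_b) %>%
    select(dplyr::any_of(c("consensus_id", "gene_id")), "position", "rank",
           "count_a", "count_b", "tpm_a", "tpm_b", "p_a", "p_b")
  attr(out, "skipped") <- skipped
  attr(out, "samples") <- c(a = sample_a, b = sample_b)
  out
}

#' Overlap-based shifting score
#'
#' Quantifies spatial separation of two normalised per-position signal
#' profiles as `S = 1 - 2 * sum(pmin(pA, pB))`. `S` is -1 for identical
#' profiles, +1 for disjoint supports, and crosses zero exactly when half
#' the signal mass overlaps, so a positive score means the majority of the
#' 3'-end signal mass has moved. The score is symmetric in its arguments;
#' direction is assigned separately (see [classify_direction()]).
#'
#' @param p_a,p_b Normalised per-position signal masses on a common ordered
#'   position set (each must sum to 1 within 1e-6).
#' @return The score, a scalar in \[-1, 1\].
#' @export
shifting_score <- function(p_a, p_b) {
  if (length(p_a) != length(p_b)) abort("profiles must have equal length")
  if (abs(sum(p_a) - 1) > 1e-6 || abs(sum(p_b) - 1) > 1e-6) {
    abort("profiles must each sum to 1 (normalise first)")
  }
  1 - 2 * sum(pmin(p_a, p_b))
}

# Asymptotic two-sided Kolmogorov tail Q(lambda) = 2 sum (-1)^(k-1) exp(-2 k^2 lambda^2)
kolmogorov_tail <- function(lambda) {
  if (lambda < 0.05) return(1)
  k <- seq_len(101)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(1, max(0, p))
}

#' Count-weighted two-sample Kolmogorov-Smirnov test for one PAC
#'
#' Treats the per-position integer 3'-end counts of each sample as a
#' discrete empirical distribution over the ordered positions and computes
#' `D`, the maximum absolute difference of the two count-weighted empirical
#' cumulative distributions. The p-value comes from the asymptotic
#' Kolmogorov distribution evaluated at `sqrt(n_eff) * D` with effective
#' size `n_eff = n_a * n_b / (n_a + n_b)`; for small problems
#' (`n_eff < exact_limit`, default 50) the exact conditional permutation
#' distribution accounting for ties is used instead
#' ([stats::psmirnov()]). Ties are ubiquitous at single-base resolution,
#' which makes the asymptotic tail conservative.
#'
#' @param counts_a,counts_b Integer per-position counts for the two samples,
#'   aligned on the same ordered position set.
#' @param exact Use the exact tail? Default (`NULL`) decides by `n_eff`.
#' @param exact_limit `n_eff` below which the exact tail is used.
#' @return A list with `statistic` (D), `p_value`, `n_a`, `n_b`, `n_eff`,
#'   `method`.
#' @export
ks_test_pac <- function(counts_a, counts_b, exact = NULL, exact_limit = 50) {
  if (length(counts_a) != length(counts_b)) {
    abort("count vectors must have equal length")
  }
  if (any(c(counts_a, counts_b) < 0)) abort("counts must be non-negative")
  n_a <- sum(counts_a); n_b <- sum(counts_b)
  if (n_a == 0 || n_b == 0) abort("each sample needs at least one read")
  f_a <- cumsum(counts_a) / n_a
  f_b <- cumsum(counts_b) / n_b
  d <- max(abs(f_a - f_b))
  n_eff <- n_a * n_b / (n_a + n_b)
  use_exact <- exact %||% (n_eff < exact_limit)
  if (use_exact) {
    pooled <- rep(seq_along(counts_a), times = counts_a + counts_b)
    p <- stats::psmirnov(d, sizes = c(n_a, n_b), z = pooled,
                         two.sided = TRUE, exact = TRUE, lower.tail = FALSE)
    method <- "exact"
  } else {
    p <- kolmogorov_tail(sqrt(n_eff) * d)
    method <- "asymptotic"
  }
  list(statistic = d, p_value = min(1, max(p, 0)), n_a = n_a, n_b = n_b,
       n_eff = n_eff, method = method)
}

#' Classify the direction of a usage shift
#'
#' For each PAC, locates the signal-weighted median position of the pooled
#' (both-sample average) profile, 5' to 3', and compares the two samples'
#' distal signal fractions — the mass strictly 3' of that median. The
#' treatment is called `lengthened` when its distal fraction exceeds the
#' control's, `shortened` when lower, `none` on an exact tie. Anchoring the
#' median on the pooled signal makes the boundary identical for both
#' samples, so swapping the sample labels exactly flips the call.
#'
#' @param profiles Profile table from [pac_signal_profiles()].
#' @return A tibble: `consensus_id`, `dist_frac_a`, `dist_frac_b`,
#'   `direction`.
#' @export
classify_direction <- function(profiles) {
  stopifnot(all(c("consensus_id", "rank", "p_a", "p_b") %in% names(profiles)))
  profiles %>%
    arrange(.data$consensus_id, .data$rank) %>%
    group_by(.data$consensus_id) %>%
    summarise(
      dist_frac_a = {
        m <- which(cumsum((.data$p_a + .data$p_b) / 2) >= 0.5)[1]
        sum(.data$p_a[.data$rank > .data$rank[m]])
      },
      dist_frac_b = {
        m <- which(cumsum((.data$p_a + .data$p_b) / 2) >= 0.5)[1]
        sum(.data$p_b[.data$rank > .data$rank[m]])
      },
      .groups = "drop") %>%
    mutate(direction = dplyr::case_when(
      .data$dist_frac_b > .data$dist_frac_a ~ "lengthened",
      .data$dist_frac_b < .data$dist_frac_a ~ "shortened",
      TRUE ~ "none"))
}

#' FDR control and significance calls for shift results
#'
#' Adjusts the per-PAC KS p-values by Benjamini-Hochberg over all tested
#' PACs of the comparison and annotates three layers of calls:
#' `detected` — statistical detection, `q <= alpha` and consensus TPM
#' strictly above `min_tpm` in both samples; `significant` — the published
#' call rule, additionally requiring shifting score `> 0` (majority-mass
#' separation); `direction` — lengthened/shortened for detected PACs,
#' `"none"` otherwise.
#'
#' @param results Per-PAC result table with columns `score`, `p`, `tpm_a`,
#'   `tpm_b`, `dist_frac_a`, `dist_frac_b` (see [apa_shift_test()]).
#' @param alpha FDR level (default 0.01).
#' @param min_tpm Strict consensus TPM threshold applied to both samples.
#' @return `results` with `q`, `detected`, `significant`, `direction`
#'   columns.
#' @export
call_significant <- function(results, alpha = 0.01, min_tpm = 5) {
  if (nrow(results) == 0) {
    return(mutate(results, q = numeric(0), detected = logical(0),
                  significant = logical(0), direction = character(0)))
  }
  raw <- dplyr::case_when(
    results$dist_frac_b > results$dist_frac_a ~ "lengthened",
    results$dist_frac_b < results$dist_frac_a ~ "shortened",
    TRUE ~ "none")
  out <- results %>%
    mutate(q = p.adjust(.data$p, method = "BH"),
           detected = .data$q <= alpha & pmin(.data$tpm_a, .data$tpm_b) > min_tpm,
           significant = .data$detected & .data$score > 0,
           direction = ifelse(.data$detected, raw, "none"))
  attr(out, "alpha") <- alpha
  attr(out, "min_tpm") <- min_tpm
  out
}

#' Test all consensus PACs for differential PAS usage between two samples
#'
#' Orchestrates [pac_signal_profiles()], [shifting_score()] (or a drop-in
#' replacement via `score_fun`), [ks_test_pac()], [classify_direction()] and
#' [call_significant()] over every testable consensus PAC.
#'
#' @inheritParams pac_signal_profiles
#' @inheritParams call_significant
#' @param score_fun Scoring plug-in with the signature of
#'   [shifting_score()].
#' @param quiet Suppress progress messages.
#' @return An `apa_shift_result` tibble, one row per tested PAC:
#'   `consensus_id`, `gene_id` (when gene-assigned), `score`, `ks_d`, `p`,
#'   `q`, `tpm_a`, `tpm_b`, `dist_frac_a`, `dist_frac_b`, `detected`,
#'   `significant`, `direction`. Attributes: `"samples"`, `"skipped"`.
#' @export
apa_shift_test <- function(consensus, sites, sample_a, sample_b,
                           alpha = 0.01, min_tpm = 5,
                           score_fun = shifting_score, quiet = FALSE) {
  profiles <- pac_signal_profiles(consensus, sites, sample_a, sample_b,
                                  quiet = quiet)
  tpms <- consensus %>%
    filter(.data$sample %in% c(sample_a, sample_b)) %>%
    select("consensus_id", "sample", "tpm") %>%
    tidyr::pivot_wider(names_from = "sample", values_from = "tpm",
                       values_fill = 0) %>%
    rename(tpm_a = dplyr::all_of(sample_a), tpm_b = dplyr::all_of(sample_b))

  has_gene <- "gene_id" %in% names(profiles)
  parts <- split(as.data.frame(profiles), profiles$consensus_id)
  rows <- purrr::map_dfr(parts, function(d) {
    d <- d[order(d$rank), , drop = FALSE]
    ks <- ks_test_pac(d$count_a, d$count_b)
    tibble(consensus_id = d$consensus_id[1],
           gene_id = if (has_gene) d$gene_id[1] else NA_character_,
           score = score_fun(d$p_a, d$p_b),
           ks_d = ks$statistic, p = ks$p_value)
  })
  if (nrow(rows) == 0) {
    out <- tibble(consensus_id = character(), gene_id = character(),
                  score = numeric(), ks_d = numeric(), p = numeric(),
                  q = numeric(), tpm_a = numeric(), tpm_b = numeric(),
                  dist_frac_a = numeric(), dist_frac_b = numeric(),
                  detected = logical(), significant = logical(),
                  direction = character())
  } else {
    out <- rows %>%
      left_join(classify_direction(profiles), by = "consensus_id") %>%
      left_join(tpms, by = "consensus_id") %>%
      call_significant(alpha = alpha, min_tpm = min_tpm) %>%
      arrange(.data$q, .data$p)
  }
  if (!has_gene) out$gene_id <- NULL
  class(out) <- c("apa_shift_result", class(out))
  attr(out, "samples") <- c(a = sample_a, b = sample_b)
  attr(out, "skipped") <- attr(profiles, "skipped")
  attr(out, "alpha") <- alpha
  attr(out, "min_tpm") <- min_tpm
  out
}

#' Summarise shift results per gene
#'
#' Collapses PAC-level shift results to one row per gene, carrying the
#' best (lowest-q) PAC's call. Genes whose detected PACs disagree on
#' direction are flagged `discordant`. Lengthened/shortened gene counts and
#' the lengthened fraction are stored in the `"counts"` attribute (also
#' available through [glance()]).
#'
#' @param results An `apa_shift_result` with gene assignment.
#' @return A tibble with one row per gene: `gene_id`, `consensus_id` (best
#'   PAC), `score`, `q`, `detected`, `significant`, `direction`,
#'   `dist_frac_a`, `dist_frac_b`, `n_pacs_tested`, `discordant`.
#' @export
summarize_genes <- function(results) {
  if (!"gene_id" %in% names(results)) {
    abort("`results` has no gene_id column; run assign_to_genes() upstream")
  }
  genes <- results %>%
    as_tibble() %>%
    filter(!.data$gene_id %in% c("intergenic", "ambiguous"), !is.na(.data$gene_id)) %>%
    group_by(.data$gene_id) %>%
    mutate(n_pacs_tested = n(),
           discordant = n_distinct(
             .data$direction[.data$detected & .data$direction != "none"]) > 1) %>%
    arrange(.data$q, .data$p, .data$consensus_id, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    select("gene_id", "consensus_id", "score", "q", "detected",
           "significant", "direction", "dist_frac_a", "dist_frac_b",
           "n_pacs_tested", "discordant") %>%
    arrange(.data$q)
  n_len <- sum(genes$direction == "lengthened")
  n_sho <- sum(genes$direction == "shortened")
  attr(genes, "counts") <- tibble(
    n_genes = nrow(genes), n_lengthened = n_len, n_shortened = n_sho,
    prop_lengthened = if (n_len + n_sho > 0) n_len / (n_len + n_sho) else NA_real_)
  genes
}

#' @method tidy apa_shift_result
#' @export
tidy.apa_shift_result <- function(x, ...) {
  out <- as_tibble(x)
  attr(out, "skipped") <- NULL
  attr(out, "samples") <- NULL
  out
}

#' @method glance apa_shift_result
#' @export
glance.apa_shift_result <- function(x, ...) {
  n_len <- sum(x$direction == "lengthened")
  n_sho <- sum(x$direction == "shortened")
  tibble(
    n_tested = nrow(x),
    n_skipped = nrow(attr(x, "skipped") %||% tibble()),
    n_detected = sum(x$detected),
    n_significant = sum(x$significant),
    n_lengthened = n_len,
    n_shortened = n_sho,
    prop_lengthened = if (n_len + n_sho > 0) n_len / (n_len + n_sho) else NA_real_,
    alpha = attr(x, "alpha") %||% NA_real_)
}
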