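#' Per-gene association summary statistics of a SNP universe
#'
#' Collapses a per-SNP table to the per-gene quantities the gene-set
#' simulations aggregate: SNP count, minimum p, and counts of SNPs below each
#' threshold. Precomputing this once makes each of the 100,000-scale
#' simulations an O(set size) sum.
#'
#' @param snps Tibble (gene_id, p), one row per SNP.
#' @param thresholds Numeric thresholds (default 0.05 and 0.005).
#' @return A tibble (gene_id, n_snps, min_p, n_lt_05, n_lt_005, ...).
#' @export
gene_snp_stats <- function(snps, thresholds = c(0.05, 0.005)) {
  out <- snps %>%
    group_by(.data$gene_id) %>%
    summarise(n_snps = n(), min_p = min(.data$p), .groups = "drop")
  for (a in thresholds) {
    tag <- paste0("n_lt_", sub("^0\\.", "", format(a, scientific = FALSE)))
    cnt <- snps %>%
      group_by(.data$gene_id) %>%
      summarise(x = sum(.data$p < a), .groups = "drop")
    out[[tag]] <- cnt$x[match(out$gene_id, cnt$gene_id)]
  }
  out
}

#' Observed gene-set summary
#'
#' The summary of an observed gene set over a per-SNP table: total SNP count,
#' minimum p, and SNPs below each threshold.
#'
#' @param snps Tibble (gene_id, p).
#' @param gene_set Character vector of gene ids.
#' @param thresholds Numeric thresholds.
#' @return A one-row tibble (snp_count, min_p, n_lt_05, n_lt_005).
#' @export
observed_set_summary <- function(snps, gene_set,
                                 thresholds = c(0.05, 0.005)) {
  sub <- filter(snps, .data$gene_id %in% gene_set)
  row <- tibble(snp_count = nrow(sub),
                min_p = if (nrow(sub) == 0) NA_real_ else min(sub$p))
  for (a in thresholds) {
    tag <- paste0("n_lt_", sub("^0\\.", "", format(a, scientific = FALSE)))
    row[[tag]] <- sum(sub$p < a)
  }
  row
}

#' Simulate random same-size gene sets from a GWAS universe
#'
#' Each simulation draws `set_size` genes uniformly without replacement from
#' the universe and records the SNP count, minimum p-value, and SNPs below
#' each threshold of the drawn set. Draws are independent across simulations
#' and driven by a single seeded generator per run.
#'
#' @param gene_stats Per-gene statistics from [gene_snp_stats()] (or a
#'   per-SNP tibble, which is collapsed first).
#' @param set_size Number of genes per simulated set.
#' @param n_sims Number of simulations.
#' @param rng_seed Integer seed.
#' @return A tibble of `n_sims` rows (snp_count, min_p, n_lt_05, n_lt_005).
#' @export
simulate_gene_sets <- function(gene_stats, set_size, n_sims, rng_seed = 1) {
  if (!"n_snps" %in% names(gene_stats)) {
    gene_stats <- gene_snp_stats(gene_stats)
  }
  n_univ <- nrow(gene_stats)
  if (set_size > n_univ) {
    abort(sprintf("set_size (%d) exceeds the universe size (%d).",
                  set_size, n_univ))
  }
  set.seed(stage_seed(rng_seed, "gene_set_sims"))
  cnt_cols <- grep("^n_lt_", names(gene_stats), value = TRUE)
  n_snps <- gene_stats$n_snps
  min_p <- gene_stats$min_p
  cnts <- as.matrix(gene_stats[, cnt_cols, drop = FALSE])

  draws <- vapply(seq_len(n_sims),
                  function(i) sample.int(n_univ, set_size),
                  integer(set_size))
  draws <- matrix(draws, nrow = set_size)
  out <- tibble(
    snp_count = colSums(matrix(n_snps[draws], nrow = set_size)),
    min_p = apply(matrix(min_p[draws], nrow = set_size), 2, min)
  )
  for (j in seq_along(cnt_cols)) {
    out[[cnt_cols[j]]] <-
      colSums(matrix(cnts[, j][draws], nrow = set_size))
  }
  out
}

#' SNP-count bias filter over simulated gene sets
#'
#' Because genes vary greatly in size and SNP density, random gene sets can
#' have systematically different total SNP counts than the observed set,
#' biasing enrichment comparisons. Simulations are ranked by descending SNP
#' count; for each threshold K in the grid (ascending), the top K are
#' retained and the observed SNP count is tested for two-sided empirical
#' compatibility with the retained counts: the mid-tie fraction of retained
#' counts above the observed (counting ties half) must lie in
#' \[0.025, 0.975\], so the observed must sit inside the central 95% of the
#' retained counts rather than beyond either tail. The smallest compatible K
#' wins; if none is compatible the full set is returned with an
#' incompatibility flag.
#'
#' @param sims Simulation tibble from [simulate_gene_sets()].
#' @param observed_snp_count Observed total SNP count.
#' @param K_grid Integer thresholds to try, in ascending order; the default
#'   grid includes the 500 and 10,000 used in practice on real GWAS
#'   universes.
#' @return A list: `sims` (the retained simulations), `K` (integer or
#'   `"all"`), `compatible` (logical), `frac_ge` (diagnostic fraction at the
#'   chosen K).
#' @export
snp_count_match_filter <- function(sims, observed_snp_count,
                                   K_grid = c(500, 1000, 2000, 5000, 10000,
                                              20000, 50000)) {
  if (nrow(sims) == 0) abort("`sims` must be nonempty.")
  sims_sorted <- arrange(sims, dplyr::desc(.data$snp_count))
  K_grid <- sort(K_grid[K_grid <= nrow(sims_sorted)])
  frac_above <- function(counts) {
    (sum(counts > observed_snp_count) +
       0.5 * sum(counts == observed_snp_count)) / length(counts)
  }
  for (K in K_grid) {
    top <- sims_sorted[seq_len(K), ]
    fr <- frac_above(top$snp_count)
    if (fr >= 0.025 && fr <= 0.975) {
      return(list(sims = top, K = as.integer(K), compatible = TRUE,
                  frac_ge = fr))
    }
  }
  fr <- frac_above(sims_sorted$snp_count)
  list(sims = sims_sorted, K = "all",
       compatible = fr >= 0.025 && fr <= 0.975, frac_ge = fr)
}

#' Plus-one empirical p-value
#'
#' p = (r + 1) / n, where r counts simulated values as or more extreme than
#' the observed in the stated direction ("ge" for counts, "le" for minimum
#' p-values), capped at 1. Never 0; bounded below by 1/n.
#'
#' @param observed Observed scalar.
#' @param sim_values Nonempty numeric vector of simulated values.
#' @param direction `"ge"` (larger more extreme) or `"le"`.
#' @return A probability in (0, 1].
#' @examples
#' empirical_p(10, rep(1, 999), "ge")
#' @export
empirical_p <- function(observed, sim_values, direction = c("ge", "le")) {
  direction <- match.arg(direction)
  if (length(sim_values) == 0) abort("`sim_values` must be nonempty.")
  r <- if (direction == "ge") sum(sim_values >= observed)
       else sum(sim_values <= observed)
  min(1, (r + 1) / length(sim_values))
}

metric_directions <- c(snp_count = "ge", min_p = "le",
                       n_lt_05 = "ge", n_lt_005 = "ge")

#' Enrichment report over categories and metrics
#'
#' For each selection category, draws same-size random gene sets from the
#' GWAS universe and reports the plus-one empirical p-value of every summary
#' metric (SNP count, minimum p, SNPs below 0.05 and below 0.005), both over
#' all simulations and over the SNP-count-matched subset chosen by
#' [snp_count_match_filter()] per category.
#'
#' @param category_sets Named list of character vectors: gene ids per
#'   category label (e.g. `"1"`, `"2"`, `"3"`, `"All"`).
#' @param observed_snps Per-SNP tibble (gene_id, p) the observed summaries
#'   are computed from.
#' @param universe_snps Per-SNP tibble (gene_id, p) of the GWAS universe, or
#'   a precomputed [gene_snp_stats()] table.
#' @param n_sims Simulations per category (the full-replication scale is
#'   100,000; tests run smaller).
#' @param rng_seed Integer seed.
#' @param K_grid Passed to [snp_count_match_filter()].
#' @return A tibble (category, metric, observed, filter, filter_K,
#'   n_sims_used, snp_count_compatible, empirical_p) with one row per
#'   category x metric x filter (`"none"` = all simulations,
#'   `"snp_count_matched"` = the top-K subset, where K may be `"all"` if no
#'   grid value was compatible), of class `enrichment_report`.
#' @export
enrichment_report <- function(category_sets, observed_snps, universe_snps,
                              n_sims = 2000, rng_seed = 1,
                              K_grid = c(500, 1000, 2000, 5000, 10000,
                                         20000, 50000)) {
  stats <- if ("n_snps" %in% names(universe_snps)) universe_snps
           else gene_snp_stats(universe_snps)
  rows <- purrr::imap_dfr(category_sets, function(genes, lab) {
    obs <- observed_set_summary(observed_snps, genes)
    sims <- simulate_gene_sets(stats, set_size = length(genes),
                               n_sims = n_sims,
                               rng_seed = stage_seed(rng_seed, lab))
    flt <- snp_count_match_filter(sims, obs$snp_count, K_grid = K_grid)
    purrr::map_dfr(names(metric_directions), function(m) {
      dir <- metric_directions[[m]]
      tibble(
        category = lab,
        metric = m,
        observed = obs[[m]],
        filter = c("none", "snp_count_matched"),
        filter_K = c("all", as.character(flt$K)),
        n_sims_used = c(nrow(sims), nrow(flt$sims)),
        snp_count_compatible = c(NA, flt$compatible),
        empirical_p = c(empirical_p(obs[[m]], sims[[m]], dir),
                        empirical_p(obs[[m]], flt$sims[[m]], dir))
      )
    })
  })
  class(rows) <- c("enrichment_report", class(rows))
  rows
}
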