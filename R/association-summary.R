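#' Map SNPs to genes by genomic interval
#'
#' Assigns each SNP to every gene whose 0-based half-open interval
#' \[start, end) contains its position. SNPs that already carry a non-missing
#' `gene_id` keep it unchanged; SNPs mapping to no gene are dropped with a
#' message stating the count. A SNP inside two overlapping genes yields two
#' rows.
#'
#' @param snps Tibble (snp_id, chrom, pos, p, optionally gene_id).
#' @param genes Tibble (gene_id, chrom, start, end).
#' @return A tibble (snp_id, chrom, pos, gene_id, p).
#' @export
map_snps_to_genes <- function(snps, genes) {
  pre <- tibble()
  todo <- snps
  if ("gene_id" %in% names(snps)) {
    pre <- filter(snps, !is.na(.data$gene_id))
    todo <- filter(snps, is.na(.data$gene_id))
  }
  if (nrow(todo) > 0) {
    bad <- setdiff(unique(todo$chrom), unique(genes$chrom))
    if (length(bad) > 0) {
      abort(paste0("SNP chromosome label(s) absent from the gene table: ",
                   paste(bad, collapse = ", ")))
    }
    mapped <- purrr::map_dfr(split(todo, todo$chrom), function(s) {
      g <- filter(genes, .data$chrom == s$chrom[1])
      # 0-based half-open [start, end) -> 1-based closed [start+1, end]
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(s$pos + 1, s$pos + 1),
        IRanges::IRanges(g$start + 1, g$end)
      )
      s[S4Vectors::queryHits(hits), ] %>%
        mutate(gene_id = g$gene_id[S4Vectors::subjectHits(hits)])
    })
    n_drop <- length(setdiff(todo$snp_id, mapped$snp_id))
    if (n_drop > 0) {
      message(sprintf("%d SNP(s) mapped to no gene and were dropped.", n_drop))
    }
    todo <- mapped
  }
  bind_rows(pre, todo) %>%
    select("snp_id", "chrom", "pos", "gene_id", "p") %>%
    arrange(.data$chrom, .data$pos, .data$gene_id)
}

#' Transmission-disequilibrium stand-in test
#'
#' A simplified family-based association test over case-parent trios, used
#' only as synthetic plumbing for end-to-end runs; it is *not* equivalent to
#' the haplotype-aware pedigree disequilibrium test (PDTPHASE) used in real
#' analyses. For each SNP it counts transmissions `b` and non-transmissions
#' `c` of the risk allele (coded "2") from heterozygous parents, forms the
#' McNemar-type statistic (b - c)^2 / (b + c), and takes the p-value from the
#' 1-df chi-square upper tail; b + c = 0 gives p = 1. Trios with a Mendelian
#' inconsistency at a SNP are skipped at that SNP and counted.
#'
#' @param ped,map Tibbles as returned by [sim_trios()] / [read_ped_map()].
#' @return A tibble (snp_id, b, c, statistic, p, n_inconsistent) with the
#'   note attribute `"method"` set to `"tdt_standin (not PDTPHASE)"`.
#' @export
tdt_standin <- function(ped, map) {
  child <- ped$phenotype == 2L
  fam <- ped$fam_id
  res <- purrr::map_dfr(seq_len(nrow(map)), function(j) {
    a1 <- ped[[paste0(map$snp_id[j], "_a1")]]
    a2 <- ped[[paste0(map$snp_id[j], "_a2")]]
    b <- 0L; cc <- 0L; bad <- 0L
    for (f in unique(fam)) {
      rows <- which(fam == f)
      ch <- rows[child[rows]]
      pa <- setdiff(rows, ch)
      if (length(ch) != 1 || length(pa) != 2) next
      cg <- sort(c(a1[ch], a2[ch]))
      pg <- list(sort(c(a1[pa[1]], a2[pa[1]])), sort(c(a1[pa[2]], a2[pa[2]])))
      # Mendelian check: the child genotype must be composable from one
      # allele of each parent
      ok <- FALSE
      for (x in pg[[1]]) for (y in pg[[2]]) {
        if (identical(sort(c(x, y)), cg)) ok <- TRUE
      }
      if (!ok) { bad <- bad + 1L; next }
      for (k in 1:2) {
        par <- pg[[k]]; other <- pg[[3 - k]]
        if (par[1] == par[2]) next          # homozygous parent: uninformative
        # transmitted allele from this het parent given the child genotype
        trans <- NA_integer_
        if (cg[1] == cg[2]) {
          trans <- cg[1]
        } else if (other[1] == other[2]) {
          trans <- setdiff(cg, other[1])
          if (length(trans) == 0) trans <- other[1]
          trans <- trans[1]
        } else {
          # both parents het, child het: one transmitted each allele
          trans <- if (k == 1) 2L else 1L
        }
        if (trans == 2L) b <- b + 1L else cc <- cc + 1L
      }
    }
    stat <- if (b + cc == 0) 0 else (b - cc)^2 / (b + cc)
    p <- if (b + cc == 0) 1 else pchisq(stat, df = 1, lower.tail = FALSE)
    tibble(snp_id = map$snp_id[j], b = b, c = cc, statistic = stat, p = p,
           n_inconsistent = bad)
  })
  attr(res, "method") <- "tdt_standin (not PDTPHASE)"
  res
}

#' Summarize association results by selection category
#'
#' Builds the per-category summary table: gene and SNP counts, mean and
#' minimum p-value, and observed vs. expected numbers of SNPs below each
#' threshold (expected = n_snps * alpha, displayed rounded half away from
#' zero to one decimal). Rows are produced for categories 1, 2, 3, the
#' unions 1+2 (all hypothesis genes) and 1+3 (all rank-selected genes), and
#' "All". SNPs shared by overlapping genes are counted once per gene row but
#' deduplicated by snp_id within union and "All" rows.
#'
#' @param snp_results Tibble (snp_id, gene_id, p) of per-SNP association
#'   results mapped to genes.
#' @param selection Selection tibble (gene_id, category) from
#'   [assign_categories()].
#' @param thresholds Numeric thresholds for the observed/expected counts.
#' @return A tibble with one row per category label ("1", "2", "3", "1+2",
#'   "1+3", "All") and columns n_genes, n_snps, mean_p, min_p, then per
#'   threshold obs_lt_<a>, exp_lt_<a>, exp_lt_<a>_display.
#' @export
summarize_categories <- function(snp_results, selection,
                                 thresholds = c(0.05, 0.005)) {
  snp_cat <- snp_results %>%
    dplyr::inner_join(select(selection, "gene_id", "category"), by = "gene_id")
  labels <- list(`1` = 1L, `2` = 2L, `3` = 3L, `1+2` = c(1L, 2L),
                 `1+3` = c(1L, 3L), All = c(1L, 2L, 3L))
  purrr::imap_dfr(labels, function(cats, lab) {
    sub <- filter(snp_cat, .data$category %in% cats)
    if (length(cats) > 1) sub <- distinct(sub, .data$snp_id, .keep_all = TRUE)
    n_snps <- nrow(sub)
    row <- tibble(
      category = lab,
      n_genes = dplyr::n_distinct(sub$gene_id),
      n_snps = n_snps,
      mean_p = if (n_snps == 0) NA_real_ else mean(sub$p),
      min_p = if (n_snps == 0) NA_real_ else min(sub$p)
    )
    for (a in thresholds) {
      tag <- sub("^0\\.", "", format(a, scientific = FALSE))
      row[[paste0("obs_lt_", tag)]] <- sum(sub$p < a)
      row[[paste0("exp_lt_", tag)]] <- n_snps * a
      row[[paste0("exp_lt_", tag, "_display")]] <- round_half_away(n_snps * a, 1)
    }
    row
  })
}

#' Per-gene minimum p-value report
#'
#' One row per gene carrying its category, evidence rank, SNP count and
#' minimum p-value, filtered to genes whose best SNP beats the reporting
#' threshold and sorted by ascending minimum p (ties broken by gene id).
#'
#' @param snp_results Tibble (snp_id, gene_id, p).
#' @param selection Selection tibble (gene_id, category).
#' @param ranking Optional ranking tibble (gene_id, rank).
#' @param threshold Reporting threshold on the per-gene minimum p
#'   (default 0.01).
#' @return A tibble (gene_id, category, rank, n_snps, min_p).
#' @export
gene_min_p_table <- function(snp_results, selection, ranking = NULL,
                             threshold = 0.01) {
  out <- snp_results %>%
    group_by(.data$gene_id) %>%
    summarise(n_snps = n(), min_p = min(.data$p), .groups = "drop") %>%
    left_join(select(selection, "gene_id", "category"), by = "gene_id")
  if (!is.null(ranking)) {
    out <- left_join(out, select(ranking, "gene_id", "rank"), by = "gene_id")
  } else {
    out$rank <- NA_integer_
  }
  out %>%
    filter(.data$min_p < threshold) %>%
    arrange(.data$min_p, .data$gene_id) %>%
    select("gene_id", "category", "rank", "n_snps", "min_p")
}

#' Experiment-wide multiple-testing adjustment
#'
#' Bonferroni (min(1, N p)) and Benjamini-Hochberg q-values over all tested
#' SNPs.
#'
#' @param snp_results Tibble with a `p` column.
#' @return The input with `p_bonferroni` and `q_bh` columns added.
#' @export
adjust_experimentwide <- function(snp_results) {
  snp_results %>%
    mutate(p_bonferroni = pmin(1, length(.data$p) * .data$p),
           q_bh = bh_qvalues(.data$p))
}

#' Genomic inflation factor
#'
#' lambda = median of the observed 1-df chi-square association statistics
#' divided by the null median of the 1-df chi-square distribution
#' (qchisq(0.5, 1), about 0.4549). P-values are converted to chi-square
#' quantiles first; a lambda near 1 indicates no systematic inflation.
#'
#' @param p P-values, or `NULL` if `chisq` is given.
#' @param chisq 1-df chi-square statistics (alternative input).
#' @return The scalar inflation factor.
#' @examples
#' genomic_lambda(runif(1e4))
#' @export
genomic_lambda <- function(p = NULL, chisq = NULL) {
  if (is.null(chisq)) {
    if (is.null(p) || length(p) == 0) abort("Supply `p` or `chisq`.")
    assert_probabilities(p, "p")
    chisq <- qchisq(p, df = 1, lower.tail = FALSE)
  }
  if (length(chisq) == 0) abort("Supply a nonempty statistic vector.")
  median(chisq) / qchisq(0.5, df = 1)
}
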