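test_that("SNP-to-gene mapping respects half-open intervals and overlaps", {
  genes <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chr1",
                          start = c(50, 100), end = c(150, 250))
  snps <- tibble::tibble(snp_id = paste0("s", 1:4), chrom = "chr1",
                         pos = c(100, 150, 249, 300),
                         gene_id = NA_character_, p = c(0.1, 0.2, 0.3, 0.4))
  expect_message(m <- map_snps_to_genes(snps, genes), "1 SNP")
  # pos 100 is inside both [50,150) and [100,250): two rows
  expect_equal(sort(m$gene_id[m$snp_id == "s1"]), c("g1", "g2"))
  # pos 150 is outside [50,150) (half-open) but inside g2
  expect_equal(m$gene_id[m$snp_id == "s2"], "g2")
  expect_false("s4" %in% m$snp_id)   # unmapped, dropped

  # explicit gene ids are kept untouched
  pre <- dplyr::mutate(snps, gene_id = "g9")
  expect_equal(unique(map_snps_to_genes(pre, genes)$gene_id), "g9")

  bad <- dplyr::mutate(snps, chrom = "chrX")
  expect_error(map_snps_to_genes(bad, genes), "chrX")
})

test_that("transmission stand-in counts b/c and calibrates at the null", {
  cfg <- sim_config(n_genes = 40, n_linkage_regions = 2, genome_length = 2e7,
                    mean_snps_per_gene = 4, frac_associated_genes = 0,
                    n_trios = 80, rng_seed = 17)
  u <- sim_gene_universe(cfg)
  snps <- sim_association(u$genes, cfg)[1:150, ]
  tr <- sim_trios(snps, u$genes, cfg)
  res <- tdt_standin(tr$ped, tr$map)
  expect_equal(nrow(res), 150)
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_true(all(res$n_inconsistent == 0))
  # statistic arithmetic: (b - c)^2 / (b + c), p = 1 when b = c
  i <- which(res$b == res$c)[1]
  if (!is.na(i)) expect_equal(res$p[i], 1)
  expect_equal(res$statistic, (res$b - res$c)^2 / pmax(1, res$b + res$c))
  # null type-I rate within 2 binomial sd of 0.05
  rate <- mean(res$p < 0.05)
  expect_lt(abs(rate - 0.05), 2 * sqrt(0.05 * 0.95 / nrow(res)))
  expect_match(attr(res, "method"), "not PDTPHASE")
})

test_that("planted transmission distortion is detected at causal SNPs", {
  cfg <- sim_config(n_genes = 10, n_linkage_regions = 2, genome_length = 1e7,
                    mean_snps_per_gene = 2, frac_associated_genes = 0.5,
                    effect_size = 3, n_trios = 200, rng_seed = 23)
  u <- sim_gene_universe(cfg)
  snps <- sim_association(u$genes, cfg)
  tr <- sim_trios(snps, u$genes, cfg)
  res <- tdt_standin(tr$ped, tr$map)
  causal <- snps |>
    dplyr::semi_join(dplyr::filter(u$genes, is_associated), by = "gene_id") |>
    dplyr::group_by(gene_id) |> dplyr::slice(1) |> dplyr::pull(snp_id)
  expect_lt(stats::median(res$p[res$snp_id %in% causal]),
            stats::median(res$p[!res$snp_id %in% causal]))
  expect_true(all(res$b[res$snp_id %in% causal] >
                    res$c[res$snp_id %in% causal]))
})

test_that("category summaries reproduce observed/expected count structure", {
  set.seed(9)
  selection <- tibble::tibble(gene_id = sprintf("g%02d", 1:30),
                              category = rep(1:3, each = 10))
  snps <- tibble::tibble(
    snp_id = sprintf("s%04d", 1:3000),
    gene_id = sample(selection$gene_id, 3000, replace = TRUE),
    p = runif(3000))
  tab <- summarize_categories(snps, selection)
  expect_equal(tab$category, c("1", "2", "3", "1+2", "1+3", "All"))
  one <- function(lab, col) tab[[col]][tab$category == lab]
  # union rows add up (no overlapping genes here, so no deduplication)
  expect_equal(one("1+2", "n_snps"), one("1", "n_snps") + one("2", "n_snps"))
  expect_equal(one("All", "obs_lt_05"),
               one("1", "obs_lt_05") + one("2", "obs_lt_05") +
                 one("3", "obs_lt_05"))
  expect_equal(tab$exp_lt_05, tab$n_snps * 0.05)
  expect_true(all(tab$obs_lt_005 <= tab$obs_lt_05))
  # uniform null: observed ~ expected
  expect_lt(abs(one("All", "obs_lt_05") / one("All", "n_snps") - 0.05),
            3 * sqrt(0.05 * 0.95 / one("All", "n_snps")))

  # a SNP in two genes of different categories is deduplicated in unions
  sel2 <- tibble::tibble(gene_id = c("a", "b"), category = c(1L, 2L))
  snp2 <- tibble::tibble(snp_id = "s1", gene_id = c("a", "b"), p = 0.01)
  t2 <- summarize_categories(snp2, sel2)
  expect_equal(t2$n_snps[t2$category == "1+2"], 1L)
  expect_equal(t2$n_snps[t2$category == "1"] + t2$n_snps[t2$category == "2"],
               2L)
  # zero-SNP category flagged with NA mean, not an error
  expect_true(is.na(t2$mean_p[t2$category == "3"]))
})

test_that("per-gene minimum-p report filters, sorts and breaks ties by id", {
  snps <- tibble::tibble(
    snp_id = paste0("s", 1:6),
    gene_id = c("gB", "gB", "gA", "gC", "gC", "gD"),
    p = c(0.002, 0.5, 0.005, 0.005, 0.9, 0.5))
  sel <- tibble::tibble(gene_id = c("gA", "gB", "gC", "gD"),
                        category = c(1L, 2L, 3L, 1L))
  rk <- tibble::tibble(gene_id = c("gA", "gB", "gC", "gD"), rank = 1:4)
  tab <- gene_min_p_table(snps, sel, rk, threshold = 0.01)
  expect_equal(tab$gene_id, c("gB", "gA", "gC"))  # gA/gC tie -> id order
  expect_equal(tab$n_snps, c(2L, 1L, 2L))
  expect_false("gD" %in% tab$gene_id)
})

test_that("experiment-wide adjustment clips Bonferroni and orders q-values", {
  n <- 3725
  set.seed(10)
  snps <- tibble::tibble(snp_id = seq_len(n), p = runif(n))
  snps$p[1] <- 0.000536           # best observed p at this experiment size
  adj <- adjust_experimentwide(snps)
  expect_equal(adj$p_bonferroni[1], 1)          # 3725 * 0.000536 > 1 -> clip
  expect_equal(adjust_experimentwide(tibble::tibble(p = 0.05))$p_bonferroni,
               0.05)
  expect_true(all(diff(adj$q_bh[order(adj$p)]) >= 0))
})

test_that("genomic inflation factor is 1 at the null and scales linearly", {
  m1 <- stats::qchisq(0.5, df = 1)
  expect_equal(genomic_lambda(chisq = rep(m1, 5)), 1.0)
  expect_equal(genomic_lambda(chisq = rep(2 * m1, 5)), 2.0)
  set.seed(12)
  expect_lt(abs(genomic_lambda(p = runif(1e5)) - 1), 0.02)
  expect_error(genomic_lambda(), "Supply")
})
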