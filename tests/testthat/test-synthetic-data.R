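test_that("gene universe respects counts, placement and planted labels", {
  cfg <- sim_config(n_genes = 3819, rng_seed = 2)
  u <- sim_gene_universe(cfg)
  expect_equal(nrow(u$genes), 3819)
  expect_true(all(u$genes$start < u$genes$end))
  expect_true(all(u$genes$snp_count >= 1))
  expect_true(all(u$regions$max_npl >= 2.0))

  # non-overlap within a chromosome
  by_chr <- split(u$genes, u$genes$chrom)
  for (g in by_chr) {
    g <- g[order(g$start), ]
    expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }

  # every gene inside exactly one linkage region
  n_regions_containing <- vapply(seq_len(nrow(u$genes)), function(i) {
    sum(u$regions$chrom == u$genes$chrom[i] &
          u$regions$start <= u$genes$start[i] &
          u$regions$end >= u$genes$end[i])
  }, integer(1))
  expect_true(all(n_regions_containing == 1))

  # planted-truth fractions
  expect_equal(sum(u$genes$is_associated), round(0.05 * 3819))
  cfg0 <- sim_config(n_genes = 200, frac_associated_genes = 0, rng_seed = 2)
  expect_false(any(sim_gene_universe(cfg0)$genes$is_associated))
})

test_that("identical configs give identical outputs across all generators", {
  run <- function() {
    cfg <- sim_config(n_genes = 80, n_linkage_regions = 4,
                      genome_length = 3e7, ppi_n_edges = 300,
                      gwas_n_genes = 200, gwas_mean_snps = 5,
                      frac_associated_genes = 0.2, rng_seed = 99)
    simulate_inputs(cfg)
  }
  a <- run()
  b <- run()
  expect_identical(a, b)
})

test_that("placement fails loudly when the genome is too small", {
  cfg <- sim_config(n_genes = 500, n_linkage_regions = 2, genome_length = 1e6)
  expect_error(sim_gene_universe(cfg), "too small")
})

test_that("null expression p-values are uniform and planted ones are not", {
  cfg <- sim_config(n_genes = 3819, frac_associated_genes = 0, rng_seed = 5)
  u <- sim_gene_universe(cfg)
  ev <- sim_evidence(u$genes, cfg)
  ks <- suppressWarnings(stats::ks.test(ev$expression$p, "punif"))
  expect_gt(ks$p.value, 0.01)

  cfga <- sim_config(n_genes = 2000, frac_associated_genes = 0.5,
                     rng_seed = 5)
  ua <- sim_gene_universe(cfga)
  eva <- sim_evidence(ua$genes, cfga)
  expect_lt(mean(eva$expression$p[ua$genes$is_associated]),
            mean(eva$expression$p[!ua$genes$is_associated]))
})

test_that("evidence generator validates seed genes and saturates literature", {
  inp <- tiny_world()
  cfg_bad <- sim_config(n_genes = 120, n_linkage_regions = 6,
                        genome_length = 4e7,
                        ppi_seed_genes = c("G00001", "NOT_A_GENE"))
  u <- sim_gene_universe(cfg_bad)
  expect_error(sim_evidence(u$genes, cfg_bad), "NOT_A_GENE")

  cfg_sat <- sim_config(n_genes = 120, n_linkage_regions = 6,
                        genome_length = 4e7, frac_associated_genes = 0.3,
                        lit_hit_p_assoc = 1, rng_seed = 4)
  us <- sim_gene_universe(cfg_sat)
  evs <- sim_evidence(us$genes, cfg_sat)
  score <- literature_category_score(evs$literature)
  assoc <- us$genes$gene_id[us$genes$is_associated]
  expect_true(all(score$lit_categories[score$gene_id %in% assoc] == 5))
})

test_that("PPI rewiring places associated genes closer to the seeds", {
  base <- list(n_genes = 600, n_linkage_regions = 6, genome_length = 1e8,
               ppi_n_edges = 1200, frac_associated_genes = 0.3, rng_seed = 21)
  cfg0 <- do.call(sim_config, c(base, list(ppi_rewire_prob = 0)))
  cfg1 <- do.call(sim_config, c(base, list(ppi_rewire_prob = 1)))
  u <- sim_gene_universe(cfg0)  # same seed -> same universe for both configs
  seeds <- u$genes$gene_id[1:3]
  steps_for <- function(cfg) {
    ev <- sim_evidence(u$genes, cfg)
    st <- ppi_min_steps(ev$ppi, seeds, gene_ids = u$genes$gene_id)
    split(st$steps[is.finite(st$steps)],
          u$genes$is_associated[is.finite(st$steps)])
  }
  s1 <- steps_for(cfg1)
  # with certain rewiring every associated gene sits one step from a seed
  expect_true(all(s1$`TRUE` <= 1))
  s0 <- steps_for(cfg0)
  # with no rewiring the step distributions are indistinguishable
  wt <- suppressWarnings(stats::wilcox.test(s0$`TRUE`, s0$`FALSE`))
  expect_gt(wt$p.value, 0.01)
})

test_that("association results conserve SNP counts and calibrate at the null", {
  inp <- tiny_world()
  expect_equal(nrow(inp$snps), sum(inp$genes$snp_count))
  expect_setequal(unique(inp$snps$gene_id), inp$genes$gene_id)
  in_gene <- inp$snps$pos >= inp$genes$start[match(inp$snps$gene_id,
                                                  inp$genes$gene_id)] &
    inp$snps$pos < inp$genes$end[match(inp$snps$gene_id, inp$genes$gene_id)]
  expect_true(all(in_gene))

  # effect_size = 1 is the null: rejection rate ~ alpha within 3 binomial sd
  cfg <- sim_config(n_genes = 400, n_linkage_regions = 8, genome_length = 1e8,
                    mean_snps_per_gene = 10, frac_associated_genes = 0.5,
                    effect_size = 1, rng_seed = 31)
  u <- sim_gene_universe(cfg)
  snps <- sim_association(u$genes, cfg)
  n <- nrow(snps)
  frac <- mean(snps$p < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / n))
})

test_that("GWAS universes are null-calibrated, long-tailed and conserved", {
  cfg <- sim_config(gwas_n_genes = 2000, gwas_mean_snps = 20, rng_seed = 13)
  gw <- sim_gwas_universe(cfg)
  expect_length(gw$studies, 3)
  s1 <- gw$studies$study1
  # no planted effect: z-statistics standard normal
  z <- s1$beta / s1$se
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)))
  expect_lt(abs(stats::sd(z) - 1), 0.05)
  # conservation of the gene -> SNP-count map
  expect_equal(sum(gw$gene_snp_counts$n_snps), nrow(s1))
  cnt <- gw$gene_snp_counts$n_snps
  expect_gt(max(cnt) / stats::median(cnt), 5)  # long tail

  # noise off: betas identical across studies (all zero here)
  gw0 <- sim_gwas_universe(cfg, noise = FALSE)
  expect_identical(gw0$studies$study1$beta, gw0$studies$study2$beta)
})

test_that("written inputs round-trip through the TSV/PED interfaces", {
  inp <- tiny_world()
  cfg <- sim_config(n_genes = 120, n_linkage_regions = 6, genome_length = 4e7,
                    mean_snps_per_gene = 6, frac_associated_genes = 0.1,
                    frac_neurodev = 0.15, n_trios = 10, rng_seed = 11)
  inp$trios <- sim_trios(inp$snps[1:5, ], inp$genes, cfg)
  dir <- withr::local_tempdir()
  write_synthetic_inputs(inp, dir)
  expect_true(all(file.exists(file.path(
    dir, c("genes.tsv", "regions.bed", "expression.tsv", "ppi.tsv",
           "literature.tsv", "go.tsv", "snps.tsv", "gwas_study1.tsv",
           "trios.ped", "trios.map")))))
  genes2 <- read_input_tsv(file.path(dir, "genes.tsv"))
  expect_equal(nrow(genes2), nrow(inp$genes))
  tr <- read_ped_map(file.path(dir, "trios.ped"), file.path(dir, "trios.map"))
  expect_equal(dim(tr$ped), dim(inp$trios$ped))
  expect_equal(tr$map$snp_id, inp$trios$map$snp_id)
})
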