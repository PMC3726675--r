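#' Generate the gene universe under linkage peaks
#'
#' Lays out `n_genes` non-overlapping genes inside `n_linkage_regions`
#' linkage regions (each region a contiguous genomic segment with a maximum
#' nonparametric-linkage score of at least 2.0, with boundaries emulating the
#' NPL 1.0 flanks). Coordinates are 0-based half-open throughout the package.
#' Per-gene tag-SNP counts are Poisson(`mean_snps_per_gene`) truncated below
#' at 1. A fraction `frac_neurodev` of genes receives the neurodevelopment GO
#' label and `frac_associated_genes` carry planted association signal;
#' `concentrate_assoc_in_neurodev` draws the associated genes from the
#' labelled set first.
#'
#' @param config A [sim_config()].
#' @return A list with two tibbles: `genes` (gene_id, chrom, start, end,
#'   snp_count, is_neurodev, is_associated) and `regions` (chrom, start, end,
#'   max_npl).
#' @examples
#' u <- sim_gene_universe(sim_config(n_genes = 100, rng_seed = 7))
#' nrow(u$genes)
#' @export
sim_gene_universe <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(stage_seed(config$rng_seed, "gene_universe"))

  n <- config$n_genes
  k <- config$n_linkage_regions
  gene_id <- sprintf("G%05d", seq_len(n))
  # near-even contiguous assignment of genes to regions
  region_of <- sort(rep_len(seq_len(k), n))
  gene_len <- round(runif(n, 5e3, 5e4))
  gap <- round(runif(n, 1e3, 2e4))

  n_chr <- min(k, 22L)
  region_chr_idx <- rep_len(seq_len(n_chr), k)
  chrom_len <- floor(config$genome_length / n_chr)

  region_pad <- 1e4          # NPL-1.0 flank emulation on each side
  inter_region_gap <- 5e4

  starts <- ends <- numeric(n)
  region_start <- region_end <- numeric(k)
  cursor <- setNames(rep(0, n_chr), seq_len(n_chr))
  for (r in seq_len(k)) {
    ci <- region_chr_idx[r]
    idx <- which(region_of == r)
    pos <- cursor[[ci]] + inter_region_gap + region_pad
    region_start[r] <- cursor[[ci]] + inter_region_gap
    for (i in idx) {
      pos <- pos + gap[i]
      starts[i] <- pos
      ends[i] <- pos + gene_len[i]
      pos <- ends[i]
    }
    region_end[r] <- pos + region_pad
    cursor[[ci]] <- region_end[r]
    if (cursor[[ci]] > chrom_len) {
      abort(paste0(
        "Gene placement failed: genome_length ", config$genome_length,
        " bp is too small to place ", n, " genes in ", k,
        " regions. Increase `genome_length` or reduce `n_genes`."
      ))
    }
  }

  n_nd <- round(config$frac_neurodev * n)
  is_neurodev <- logical(n)
  is_neurodev[sample.int(n, n_nd)] <- TRUE
  n_assoc <- round(config$frac_associated_genes * n)
  is_associated <- logical(n)
  if (n_assoc > 0) {
    if (config$concentrate_assoc_in_neurodev) {
      nd <- which(is_neurodev)
      take_nd <- nd[sample.int(length(nd), min(n_assoc, length(nd)))]
      rest <- setdiff(seq_len(n), nd)
      extra <- n_assoc - length(take_nd)
      take <- c(take_nd, if (extra > 0) rest[sample.int(length(rest), extra)])
    } else {
      take <- sample.int(n, n_assoc)
    }
    is_associated[take] <- TRUE
  }

  genes <- tibble(
    gene_id = gene_id,
    chrom = paste0("chr", region_chr_idx[region_of]),
    start = starts,
    end = ends,
    snp_count = pmax(1L, rpois(n, config$mean_snps_per_gene)),
    is_neurodev = is_neurodev,
    is_associated = is_associated
  )
  regions <- tibble(
    chrom = paste0("chr", region_chr_idx),
    start = region_start,
    end = region_end,
    max_npl = round(runif(k, 2.0, 4.5), 2)
  )
  list(genes = genes, regions = regions)
}

#' Non-centrality parameter implied by an odds ratio in a trio design
#'
#' For a transmission test over `n_trios` trios with on average one
#' heterozygous parent each, the transmission probability of the risk allele
#' is OR/(1+OR) and the 1-df chi-square statistic has non-centrality
#' approximately n_trios * ((OR-1)/(OR+1))^2.
#'
#' @keywords internal
tdt_ncp <- function(effect_size, n_trios) {
  n_trios * ((effect_size - 1) / (effect_size + 1))^2
}

#' Generate the three evidence domains
#'
#' Emits the prior-information inputs of the ranking stage: a per-gene
#' expression meta-analysis p-value table (Uniform(0,1) for null genes,
#' Beta(a, 1) with a < 1 for associated genes), a protein-protein interaction
#' edge list containing all seed genes with associated genes preferentially
#' wired next to the seeds, a 0/1 literature hit matrix over term categories
#' with elevated hit probability for associated genes, and a GO-style
#' annotation table carrying "nervous system development" for labelled genes.
#'
#' @param genes Gene tibble from [sim_gene_universe()].
#' @param config A [sim_config()].
#' @return A list of tibbles: `expression` (gene_id, p), `ppi` (gene_a,
#'   gene_b), `literature` (gene_id plus one 0/1 column per category),
#'   `go` (gene_id, term).
#' @export
sim_evidence <- function(genes, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(genes) == 0) abort("`genes` must be nonempty.")
  set.seed(stage_seed(config$rng_seed, "evidence"))

  ids <- genes$gene_id
  seeds <- config$ppi_seed_genes
  if (is.null(seeds)) seeds <- ids[seq_len(min(3, length(ids)))]
  missing <- setdiff(seeds, ids)
  if (length(missing) > 0) {
    abort(paste0("PPI seed gene(s) absent from the gene universe: ",
                 paste(missing, collapse = ", ")))
  }

  n <- length(ids)
  p_expr <- runif(n)
  p_expr[genes$is_associated] <-
    rbeta(sum(genes$is_associated), config$expr_beta_a, 1)
  expression <- tibble(gene_id = ids, p = p_expr)

  # random background graph; every seed gets at least one incident edge
  m <- config$ppi_n_edges
  a <- sample(ids, m, replace = TRUE)
  b <- sample(ids, m, replace = TRUE)
  keep <- a != b
  edges <- tibble(gene_a = pmin(a[keep], b[keep]),
                  gene_b = pmax(a[keep], b[keep]))
  anchor <- tibble(gene_a = seeds, gene_b = sample(setdiff(ids, seeds),
                                                   length(seeds)))
  # planted structure: associated genes wired directly to a random seed
  assoc <- ids[genes$is_associated]
  if (length(assoc) > 0 && config$ppi_rewire_prob > 0) {
    hit <- assoc[runif(length(assoc)) < config$ppi_rewire_prob]
    if (length(hit) > 0) {
      edges <- bind_rows(edges, tibble(
        gene_a = hit, gene_b = sample(seeds, length(hit), replace = TRUE)
      ))
    }
  }
  ppi <- bind_rows(edges, anchor) %>%
    mutate(lo = pmin(.data$gene_a, .data$gene_b),
           hi = pmax(.data$gene_a, .data$gene_b)) %>%
    distinct(.data$lo, .data$hi) %>%
    rename(gene_a = "lo", gene_b = "hi")

  k <- config$n_literature_categories
  labels <- if (k == 5) {
    c("disease_states", "neurotransmitters", "neuronal_features",
      "brain_development", "brain_structures")
  } else {
    paste0("category_", seq_len(k))
  }
  hit_p <- ifelse(genes$is_associated, config$lit_hit_p_assoc,
                  config$lit_hit_p_null)
  lit <- matrix(rbinom(n * k, 1L, rep(hit_p, k)), nrow = n)
  colnames(lit) <- labels
  literature <- bind_cols(tibble(gene_id = ids), as_tibble(lit))

  go <- bind_rows(
    tibble(gene_id = ids, term = "cellular process"),
    tibble(gene_id = ids[genes$is_neurodev], term = "nervous system development")
  ) %>% arrange(.data$gene_id, .data$term)

  list(expression = expression, ppi = ppi, literature = literature, go = go)
}

#' Generate per-SNP association results
#'
#' Places `snp_count` SNPs uniformly inside each gene's interval. Null SNPs
#' get Uniform(0,1) p-values; SNPs in associated genes get the p-value of a
#' 1-df chi-square draw with non-centrality implied by `effect_size` and
#' `n_trios` (see [tdt_ncp()]), emulating a family-based transmission test
#' without simulating genotypes for every SNP.
#'
#' @param genes Gene tibble from [sim_gene_universe()] (snp_count assigned).
#' @param config A [sim_config()].
#' @return A tibble (snp_id, chrom, pos, gene_id, p), one row per SNP.
#' @export
sim_association <- function(genes, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!"snp_count" %in% names(genes)) abort("`genes` must carry `snp_count`.")
  set.seed(stage_seed(config$rng_seed, "association"))

  cnt <- genes$snp_count
  total <- sum(cnt)
  gi <- rep(seq_len(nrow(genes)), cnt)
  pos <- floor(runif(total, genes$start[gi], genes$end[gi]))
  p <- runif(total)
  alt <- genes$is_associated[gi]
  if (any(alt)) {
    ncp <- tdt_ncp(config$effect_size, config$n_trios)
    stat <- rchisq(sum(alt), df = 1, ncp = ncp)
    p[alt] <- pchisq(stat, df = 1, lower.tail = FALSE)
  }
  tibble(
    snp_id = sprintf("rs%06d", seq_len(total)),
    chrom = genes$chrom[gi],
    pos = pos,
    gene_id = genes$gene_id[gi],
    p = p
  ) %>% arrange(.data$chrom, .data$pos)
}

#' Simulate trio genotypes with planted transmission distortion
#'
#' For end-to-end smoke testing of the transmission-test stand-in only:
#' simulates `n_trios` case-parent trios at the given SNPs. Parental alleles
#' are drawn at minor-allele frequency `maf`; heterozygous parents at causal
#' SNPs (one per associated gene, its first SNP) transmit the risk allele
#' ("2") with probability OR/(1+OR), and with probability 1/2 elsewhere.
#'
#' @param snps SNP tibble from [sim_association()].
#' @param genes Gene tibble (for `is_associated`).
#' @param config A [sim_config()].
#' @return A list: `ped` (tibble in 6-column PED layout plus two allele
#'   columns per SNP, coded 1/2) and `map` (chrom, snp_id, cm, pos_1based).
#'   PED/MAP positions are 1-based, unlike the package's internal convention.
#' @export
sim_trios <- function(snps, genes, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$rng_seed, "trios"))

  causal <- snps %>%
    semi_join(filter(genes, .data$is_associated), by = "gene_id") %>%
    group_by(.data$gene_id) %>%
    slice(1) %>%
    ungroup() %>%
    pull(.data$snp_id)
  t_risk <- config$effect_size / (1 + config$effect_size)

  n <- config$n_trios
  m <- nrow(snps)
  maf <- config$maf
  draw_allele <- function(k) ifelse(runif(k) < maf, 2L, 1L)
  transmit <- function(a1, a2, p_risk) {
    het <- a1 != a2
    out <- a1
    # homozygous parents transmit their only allele; heterozygous parents
    # transmit the risk allele with probability p_risk
    out[het] <- ifelse(runif(sum(het)) < p_risk, 2L, 1L)
    out
  }

  geno <- matrix(0L, nrow = 3 * n, ncol = 2 * m)
  for (j in seq_len(m)) {
    p_risk <- if (snps$snp_id[j] %in% causal) t_risk else 0.5
    f1 <- draw_allele(n); f2 <- draw_allele(n)
    m1 <- draw_allele(n); m2 <- draw_allele(n)
    c1 <- transmit(f1, f2, p_risk)
    c2 <- transmit(m1, m2, p_risk)
    cols <- c(2 * j - 1, 2 * j)
    fa <- seq(1, 3 * n, by = 3); mo <- fa + 1; ch <- fa + 2
    geno[fa, cols] <- cbind(f1, f2)
    geno[mo, cols] <- cbind(m1, m2)
    geno[ch, cols] <- cbind(c1, c2)
  }

  fam <- rep(sprintf("F%04d", seq_len(n)), each = 3)
  ind <- rep(c("father", "mother", "child"), n)
  ped_meta <- tibble(
    fam_id = fam,
    ind_id = paste0(fam, "_", ind),
    pat_id = ifelse(ind == "child", paste0(fam, "_father"), "0"),
    mat_id = ifelse(ind == "child", paste0(fam, "_mother"), "0"),
    sex = rep(c(1L, 2L, 1L), n),
    phenotype = rep(c(0L, 0L, 2L), n)
  )
  geno_tb <- as_tibble(geno, .name_repair = "minimal")
  names(geno_tb) <- paste0(rep(snps$snp_id, each = 2), c("_a1", "_a2"))
  ped <- bind_cols(ped_meta, geno_tb)
  map <- tibble(chrom = snps$chrom, snp_id = snps$snp_id, cm = 0,
                pos_1based = snps$pos + 1)
  list(ped = ped, map = map)
}

#' Generate genome-wide GWAS summary-statistic universes
#'
#' Builds a genome-wide gene universe with long-tailed (negative-binomial)
#' per-gene SNP counts so that SNP-count matching in the enrichment stage is a
#' real problem, then emits one summary-statistics table per study. Effect
#' sizes are null (beta_true = 0) except at planted loci
#' (`gwas_frac_associated` of genes, beta_true = log(effect_size)), which are
#' shared across studies; per-study betas add Normal(0, se) noise unless
#' `noise = FALSE`.
#'
#' @param config A [sim_config()].
#' @param noise If `FALSE`, per-study betas equal the shared true effects
#'   exactly (useful for determinism checks).
#' @return A list: `studies` (named list of tibbles with snp_id, chrom,
#'   pos_1based, gene_id, effect_allele, other_allele, beta, se, p),
#'   `gene_snp_counts` (gene_id, n_snps), and `snps` (per-SNP gene map with
#'   the study-invariant p of study 1 omitted).
#' @export
sim_gwas_universe <- function(config, noise = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$rng_seed, "gwas"))

  g <- config$gwas_n_genes
  gene_id <- sprintf("GW%05d", seq_len(g))
  n_snps <- 1L + rnbinom(g, size = config$gwas_nb_size,
                         mu = max(config$gwas_mean_snps - 1, 0.1))
  total <- sum(n_snps)
  gi <- rep(seq_len(g), n_snps)

  chrom <- paste0("chr", rep_len(seq_len(22), g))[gi]
  pos <- stats::ave(seq_len(total), chrom, FUN = seq_along) * 1000L
  bases <- c("A", "C", "G", "T")
  ea_idx <- sample.int(4, total, replace = TRUE)
  ea <- bases[ea_idx]
  oa <- bases[(ea_idx - 1 + sample.int(3, total, replace = TRUE)) %% 4 + 1]

  assoc_gene <- runif(g) < config$gwas_frac_associated
  beta_true <- ifelse(assoc_gene[gi], log(config$effect_size), 0)
  se_shared <- runif(total, 0.03, 0.08)

  studies <- list()
  for (s in seq_len(config$n_gwas_studies)) {
    beta <- if (noise) rnorm(total, beta_true, se_shared) else beta_true
    z <- beta / se_shared
    studies[[paste0("study", s)]] <- tibble(
      snp_id = sprintf("gwsnp%07d", seq_len(total)),
      chrom = chrom,
      pos_1based = pos,
      gene_id = gene_id[gi],
      effect_allele = ea,
      other_allele = oa,
      beta = beta,
      se = se_shared,
      p = 2 * pnorm(-abs(z))
    )
  }
  counts <- tibble(gene_id = gene_id, n_snps = as.integer(n_snps))
  list(studies = studies, gene_snp_counts = counts,
       snps = select(studies[[1]], "snp_id", "chrom", "pos_1based",
                     "gene_id", "p"))
}

#' Generate every pipeline input in one call
#'
#' Convenience wrapper running all generators off one config: the gene
#' universe and linkage regions, the three evidence domains, the per-SNP
#' association results, and the GWAS summary-statistic universes.
#'
#' @param config A [sim_config()].
#' @param trios If `TRUE`, also simulate trio genotypes (slow for many SNPs).
#' @return A named list with elements `genes`, `regions`, `expression`,
#'   `ppi`, `literature`, `go`, `snps`, `gwas`, and optionally `trios`.
#' @examples
#' inputs <- simulate_inputs(sim_config(n_genes = 50, gwas_n_genes = 100))
#' names(inputs)
#' @export
simulate_inputs <- function(config, trios = FALSE) {
  u <- sim_gene_universe(config)
  ev <- sim_evidence(u$genes, config)
  snps <- sim_association(u$genes, config)
  gwas <- sim_gwas_universe(config)
  out <- c(u, ev, list(snps = snps, gwas = gwas))
  if (trios) out$trios <- sim_trios(snps, u$genes, config)
  out
}
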