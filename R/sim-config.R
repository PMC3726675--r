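#' Configuration for the synthetic-data generators
#'
#' Collects every knob of the synthetic world in one validated list. Defaults
#' follow the design of the motivating study: 3819 protein-coding genes under
#' 26 autosomal linkage peaks (regions with a nonparametric-linkage maximum
#' score of at least 2.0), five literature term categories, a SNP budget
#' implying roughly 22 tag SNPs per genotyped gene, and three GWAS datasets
#' for meta-analysis. Quantities the design leaves open (the fraction of genes
#' carrying the neurodevelopment GO label, evidence-strength parameters for
#' planted signal) are free parameters with defaults argued in the package
#' vignette.
#'
#' @param n_genes Number of genes in the linkage-region universe.
#' @param n_linkage_regions Number of linkage regions the genes fall under.
#' @param genome_length Total genome length in bp available for placement.
#' @param ppi_n_edges Number of random edges in the protein-interaction graph.
#' @param ppi_seed_genes Character vector of seed gene ids (the established
#'   susceptibility genes whose network neighbourhood defines the PPI domain).
#'   `NULL` uses the first three gene ids of the universe.
#' @param n_literature_categories Number of literature term categories.
#' @param n_literature_terms Number of individual search terms behind the
#'   categories (a design constant of the emulated study: 29 terms over 3819
#'   genes give the 110,751 searches of the original screen; the hit matrix
#'   itself is consumed at the category level).
#' @param mean_snps_per_gene Poisson mean for per-gene tag-SNP counts
#'   (minimum 1 enforced).
#' @param frac_associated_genes Fraction of genes carrying planted association
#'   signal, in \[0, 1\].
#' @param effect_size Odds ratio of the planted signal (> 0; 1 = null).
#' @param n_trios Number of parent-parent-child trios behind the family-based
#'   association test (drives the non-centrality of planted p-values).
#' @param n_gwas_studies Number of GWAS summary-statistic studies to emit.
#' @param rng_seed Integer seed; identical configs give byte-identical output.
#' @param frac_neurodev Fraction of genes given the "nervous system
#'   development" GO label (default 0.03, about 115/3819).
#' @param concentrate_assoc_in_neurodev If `TRUE`, associated genes are drawn
#'   from the neurodev-labelled genes first, concentrating planted signal in
#'   the hypothesis set.
#' @param expr_beta_a Beta(a, 1) shape (< 1) for expression p-values of
#'   associated genes; null genes are Uniform(0, 1).
#' @param lit_hit_p_null,lit_hit_p_assoc Per-category literature hit
#'   probabilities for null and associated genes.
#' @param ppi_rewire_prob Probability that an associated gene receives a
#'   direct edge to a seed gene (0 = no planted network structure).
#' @param gwas_n_genes Genome-wide gene count of the GWAS universes.
#' @param gwas_mean_snps Mean per-gene SNP count in the GWAS universes; counts
#'   are negative-binomial (size `gwas_nb_size`) so they are long-tailed and
#'   SNP-count matching is a real problem.
#' @param gwas_nb_size Negative-binomial size (dispersion) parameter.
#' @param gwas_frac_associated Fraction of GWAS-universe genes with a shared
#'   true effect across studies (default 0: null universe).
#' @param maf Minor-allele frequency used when simulating trio genotypes.
#'
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_genes = 200, rng_seed = 1)
#' cfg$n_genes
#' @export
sim_config <- function(n_genes = 3819,
                       n_linkage_regions = 26,
                       genome_length = 5e8,
                       ppi_n_edges = 20000,
                       ppi_seed_genes = NULL,
                       n_literature_categories = 5,
                       n_literature_terms = 29,
                       mean_snps_per_gene = 22,
                       frac_associated_genes = 0.05,
                       effect_size = 1.3,
                       n_trios = 500,
                       n_gwas_studies = 3,
                       rng_seed = 1,
                       frac_neurodev = 0.03,
                       concentrate_assoc_in_neurodev = FALSE,
                       expr_beta_a = 0.3,
                       lit_hit_p_null = 0.05,
                       lit_hit_p_assoc = 0.4,
                       ppi_rewire_prob = 0.5,
                       gwas_n_genes = 15000,
                       gwas_mean_snps = 30,
                       gwas_nb_size = 0.8,
                       gwas_frac_associated = 0,
                       maf = 0.3) {
  cfg <- list(
    n_genes = n_genes, n_linkage_regions = n_linkage_regions,
    genome_length = genome_length, ppi_n_edges = ppi_n_edges,
    ppi_seed_genes = ppi_seed_genes,
    n_literature_categories = n_literature_categories,
    n_literature_terms = n_literature_terms,
    mean_snps_per_gene = mean_snps_per_gene,
    frac_associated_genes = frac_associated_genes,
    effect_size = effect_size, n_trios = n_trios,
    n_gwas_studies = n_gwas_studies, rng_seed = rng_seed,
    frac_neurodev = frac_neurodev,
    concentrate_assoc_in_neurodev = concentrate_assoc_in_neurodev,
    expr_beta_a = expr_beta_a,
    lit_hit_p_null = lit_hit_p_null, lit_hit_p_assoc = lit_hit_p_assoc,
    ppi_rewire_prob = ppi_rewire_prob,
    gwas_n_genes = gwas_n_genes, gwas_mean_snps = gwas_mean_snps,
    gwas_nb_size = gwas_nb_size,
    gwas_frac_associated = gwas_frac_associated,
    maf = maf
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  counts <- c("n_genes", "n_linkage_regions", "genome_length", "ppi_n_edges",
              "n_literature_categories", "n_literature_terms", "n_trios",
              "n_gwas_studies",
              "gwas_n_genes")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 1) {
      abort(sprintf("`%s` must be a positive count (got %s).", f, format(v)))
    }
  }
  for (f in c("frac_associated_genes", "frac_neurodev", "lit_hit_p_null",
              "lit_hit_p_assoc", "ppi_rewire_prob", "maf")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      abort(sprintf("`%s` must be a proportion in [0, 1].", f))
    }
  }
  if (cfg$effect_size <= 0) abort("`effect_size` must be a positive odds ratio.")
  if (cfg$mean_snps_per_gene <= 0) abort("`mean_snps_per_gene` must be positive.")
  if (cfg$expr_beta_a <= 0 || cfg$expr_beta_a >= 1) {
    abort("`expr_beta_a` must lie in (0, 1) so associated p-values skew small.")
  }
  if (!is.null(cfg$ppi_seed_genes) && !is.character(cfg$ppi_seed_genes)) {
    abort("`ppi_seed_genes` must be NULL or a character vector of gene ids.")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d genes in %d linkage regions over %.3g bp\n",
              x$n_genes, x$n_linkage_regions, x$genome_length))
  cat(sprintf("  planted signal: %.0f%% of genes at OR %.2f (%d trios)\n",
              100 * x$frac_associated_genes, x$effect_size, x$n_trios))
  cat(sprintf("  GWAS universes: %d studies, %d genes\n",
              x$n_gwas_studies, x$gwas_n_genes))
  cat(sprintf("  rng_seed: %d\n", x$rng_seed))
  invisible(x)
}
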