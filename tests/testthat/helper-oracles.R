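# Independent oracles used across the suite. These deliberately use
# different algorithms from the implementation (Floyd-Warshall vs BFS,
# explicit double-loop vs vectorized cummin).

# All-pairs shortest paths by Floyd-Warshall over an explicit node set.
# edges: tibble (gene_a, gene_b); returns the distance matrix over `nodes`.
fw_all_pairs <- function(edges, nodes) {
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  ai <- match(edges$gene_a, nodes)
  bi <- match(edges$gene_b, nodes)
  for (e in seq_along(ai)) {
    D[ai[e], bi[e]] <- 1
    D[bi[e], ai[e]] <- 1
  }
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  D
}

# Brute-force Benjamini-Hochberg step-up: for the i-th smallest p, take the
# minimum over all j >= i of N * p_(j) / j, clipped at 1.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q_sorted <- numeric(n)
  for (i in seq_len(n)) {
    m <- Inf
    for (j in i:n) {
      m <- min(m, n * ps[j] / j)
    }
    q_sorted[i] <- min(1, m)
  }
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

# Small ready-made synthetic world shared by several tests.
tiny_world <- function(seed = 11, ...) {
  cfg <- sim_config(n_genes = 120, n_linkage_regions = 6, genome_length = 4e7,
                    ppi_n_edges = 600, gwas_n_genes = 500,
                    gwas_mean_snps = 8, mean_snps_per_gene = 6,
                    frac_associated_genes = 0.1, frac_neurodev = 0.15,
                    rng_seed = seed, ...)
  simulate_inputs(cfg)
}
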