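#' Benjamini-Hochberg step-up q-values
#'
#' Step-up adjusted values q_(i) = min over j >= i of N * p_(j) / j, clipped
#' at 1, returned in the input order. Monotone non-decreasing in p.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order as `p`.
#' @examples
#' bh_qvalues(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_qvalues <- function(p) {
  assert_probabilities(p, "p")
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(n / seq(n, 1) * p[o]))[ro]
  q
}

#' Storey-style q-values with a fixed lambda
#'
#' Estimates the null proportion pi0 = #\{p > lambda\} / (N * (1 - lambda)),
#' capped at 1, and scales the Benjamini-Hochberg q-values by it. Provided as
#' an alternative to plain BH for the expression-domain FDR correction.
#'
#' @param p Numeric vector of p-values.
#' @param lambda Tuning point in (0, 1); default 0.5.
#' @return Numeric vector of q-values.
#' @export
storey_qvalues <- function(p, lambda = 0.5) {
  assert_probabilities(p, "p")
  stopifnot(lambda > 0, lambda < 1)
  pi0 <- min(1, mean(p > lambda) / (1 - lambda))
  pmin(1, pi0 * bh_qvalues(p))
}

#' Minimum network steps from seed genes
#'
#' For every gene in the node set (plus any extra ids supplied), the minimum
#' over the seed genes of the unweighted shortest-path length in the
#' protein-protein interaction graph (breadth-first search). Genes absent
#' from the network or disconnected from every seed are unreachable and get
#' `Inf`. Steps are 0 exactly for the seed genes themselves.
#'
#' @param ppi Tibble/data frame edge list with columns `gene_a`, `gene_b`.
#' @param seed_genes Nonempty character vector of seed gene ids, all present
#'   in the network.
#' @param gene_ids Optional character vector of genes to report on (ids not
#'   in the network are reported unreachable); default: all network nodes.
#' @return A tibble (gene_id, steps) with `steps` numeric (Inf = unreachable).
#' @examples
#' ppi <- tibble::tibble(gene_a = c("A", "B"), gene_b = c("B", "C"))
#' ppi_min_steps(ppi, "A")
#' @export
ppi_min_steps <- function(ppi, seed_genes, gene_ids = NULL) {
  if (length(seed_genes) == 0) abort("`seed_genes` must be nonempty.")
  g <- igraph::graph_from_data_frame(ppi[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  nodes <- igraph::V(g)$name
  missing <- setdiff(seed_genes, nodes)
  if (length(missing) > 0) {
    abort(paste0("Seed gene(s) absent from the PPI network: ",
                 paste(missing, collapse = ", ")))
  }
  d <- igraph::distances(g, v = seed_genes, to = nodes, mode = "all")
  steps <- apply(d, 2, min)
  out <- tibble(gene_id = nodes, steps = as.numeric(steps))
  if (!is.null(gene_ids)) {
    out <- tibble(gene_id = gene_ids) %>%
      left_join(out, by = "gene_id") %>%
      mutate(steps = ifelse(is.na(.data$steps), Inf, .data$steps))
  }
  out
}

#' Literature category score
#'
#' Counts, per gene, the number of term categories with at least one positive
#' literature hit.
#'
#' @param literature Tibble with `gene_id` and one 0/1 column per category.
#' @return A tibble (gene_id, lit_categories).
#' @export
literature_category_score <- function(literature) {
  hits <- as.matrix(literature[, setdiff(names(literature), "gene_id")])
  if (!all(hits %in% c(0, 1))) {
    abort("Literature hit matrix entries must all be 0 or 1.")
  }
  tibble(gene_id = literature$gene_id,
         lit_categories = as.integer(rowSums(hits)))
}

#' Convert evidence values to rank-based p-values
#'
#' Places heterogeneous evidence on a common probability scale: each item
#' gets p = midrank / N, where midrank is the average rank over ties (so tied
#' items share the mean of the ranks they span), giving p in (0, 1] with the
#' best untied item at 1/N. `Inf` (and `NA`) values are allowed and rank
#' worse than any finite value. The alternative convention rank / (N + 1) is
#' available via `method`.
#'
#' @param values Nonempty numeric vector (Inf allowed for "unreachable").
#' @param lower_is_better If `TRUE` (default) small values rank best.
#' @param method `"midrank_n"` (p = midrank/N, default) or `"midrank_n1"`
#'   (p = midrank/(N+1)).
#' @return Numeric vector of probabilities, same order as `values`.
#' @examples
#' rank_to_pvalue(c(5, 2, 9))
#' rank_to_pvalue(c(1, 1, 2))
#' @export
rank_to_pvalue <- function(values, lower_is_better = TRUE,
                           method = c("midrank_n", "midrank_n1")) {
  if (length(values) == 0) abort("`values` must be nonempty.")
  method <- match.arg(method)
  v <- as.numeric(values)
  v[is.na(v)] <- Inf
  if (!lower_is_better) v <- -v
  r <- rank(v, ties.method = "average")  # Inf ranks worst
  n <- length(v)
  if (method == "midrank_n") r / n else r / (n + 1)
}

#' Assemble the per-gene evidence table
#'
#' Computes the three domain p-values for every gene in the universe:
#' `p_expr` is the FDR-corrected expression meta-analysis p-value (BH by
#' default, Storey with fixed lambda = 0.5 optionally); `p_ppi` is the
#' rank-based p-value of the minimum number of network steps to a seed gene
#' (fewest steps best, unreachable genes share the worst midrank); `p_lit` is
#' the rank-based p-value of the literature category count (most categories
#' best). Genes missing from the expression table get p_expr = 1 (no
#' evidence), with a warning stating the count.
#'
#' @param expression Tibble (gene_id, p) of uncorrected expression p-values.
#' @param ppi Edge-list tibble (gene_a, gene_b).
#' @param literature Hit-matrix tibble (gene_id + 0/1 category columns).
#' @param seed_genes Seed gene ids for the network domain.
#' @param gene_ids Character vector defining the gene universe; default: the
#'   gene ids of `literature`.
#' @param fdr `"bh"` (default) or `"storey"`.
#' @param rank_method Passed to [rank_to_pvalue()].
#' @return A tibble (gene_id, p_expr, steps, p_ppi, lit_categories, p_lit).
#' @export
build_evidence <- function(expression, ppi, literature, seed_genes,
                           gene_ids = NULL, fdr = c("bh", "storey"),
                           rank_method = "midrank_n") {
  fdr <- match.arg(fdr)
  if (is.null(gene_ids)) gene_ids <- literature$gene_id
  universe <- tibble(gene_id = gene_ids)

  expr <- expression %>%
    mutate(p_expr = if (fdr == "bh") bh_qvalues(.data$p)
           else storey_qvalues(.data$p)) %>%
    select("gene_id", "p_expr")
  ev <- universe %>% left_join(expr, by = "gene_id")
  n_missing <- sum(is.na(ev$p_expr))
  if (n_missing > 0) {
    warn(sprintf(
      "%d gene(s) absent from the expression table; assigned p_expr = 1.",
      n_missing))
    ev$p_expr[is.na(ev$p_expr)] <- 1
  }

  ev <- ev %>%
    left_join(ppi_min_steps(ppi, seed_genes, gene_ids = gene_ids),
              by = "gene_id") %>%
    left_join(literature_category_score(literature), by = "gene_id") %>%
    mutate(
      lit_categories = ifelse(is.na(.data$lit_categories), 0L,
                              .data$lit_categories),
      p_ppi = rank_to_pvalue(.data$steps, lower_is_better = TRUE,
                             method = rank_method),
      p_lit = rank_to_pvalue(.data$lit_categories, lower_is_better = FALSE,
                             method = rank_method)
    ) %>%
    select("gene_id", "p_expr", "steps", "p_ppi", "lit_categories", "p_lit")
  ev
}

#' Combine domain p-values into a score and rank
#'
#' The combined evidence score is the sum of -log10 of the three domain
#' p-values; genes are ranked by descending score (rank 1 = best), with ties
#' broken deterministically by lexicographic gene id.
#'
#' @param evidence Tibble with columns gene_id, p_expr, p_ppi, p_lit (e.g.
#'   from [build_evidence()]).
#' @return The input with `score` and `rank` columns added, sorted by rank.
#' @examples
#' ev <- tibble::tibble(gene_id = c("A", "B"),
#'                      p_expr = c(0.1, 1), p_ppi = c(0.01, 1),
#'                      p_lit = c(0.001, 1))
#' combine_and_rank(ev)
#' @export
combine_and_rank <- function(evidence) {
  ps <- c(evidence$p_expr, evidence$p_ppi, evidence$p_lit)
  if (any(ps <= 0)) {
    abort("All domain p-values must be > 0 to take logarithms.")
  }
  if (any(ps > 1)) abort("Domain p-values must not exceed 1.")
  evidence %>%
    mutate(score = -log10(.data$p_expr) - log10(.data$p_ppi) -
             log10(.data$p_lit)) %>%
    arrange(dplyr::desc(.data$score), .data$gene_id) %>%
    mutate(rank = row_number())
}

#' Rank genes from the three raw evidence inputs
#'
#' One-call wrapper: [build_evidence()] then [combine_and_rank()].
#'
#' @inheritParams build_evidence
#' @param ... Passed on to [build_evidence()].
#' @return A tibble with evidence columns plus `score` and `rank`.
#' @export
rank_genes <- function(expression, ppi, literature, seed_genes, ...) {
  combine_and_rank(build_evidence(expression, ppi, literature, seed_genes,
                                  ...))
}
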