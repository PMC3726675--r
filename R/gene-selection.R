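#' Select genes by functional hypothesis
#'
#' Returns the gene ids annotated with any of the given GO-style term labels
#' (exact label match, case-insensitive). The default terms encode the
#' neurodevelopmental hypothesis: "nervous system development" and
#' "brain development".
#'
#' @param go Tibble (gene_id, term).
#' @param terms Nonempty character vector of term labels.
#' @return Character vector of selected gene ids.
#' @export
select_hypothesis_genes <- function(go,
                                    terms = c("nervous system development",
                                              "brain development")) {
  if (length(terms) == 0) abort("`terms` must be nonempty.")
  if (nrow(go) == 0) {
    warn("Empty GO table: hypothesis set is empty.")
    return(character(0))
  }
  hit <- tolower(go$term) %in% tolower(terms)
  sort(unique(go$gene_id[hit]))
}

#' Select top-ranked genes under a SNP budget
#'
#' Walks the ranking from best to worst and adds each gene whose tag-SNP
#' count still fits in the remaining budget; genes too large to fit are
#' skipped and iteration continues (skip-and-continue greedy), maximizing
#' inclusion. Hypothesis genes consume no budget here — their SNPs are
#' pre-allocated — so they are added without charge and do not count against
#' `snp_budget`.
#'
#' @param ranking Tibble with `gene_id` and `rank` (1 = best), e.g. from
#'   [rank_genes()].
#' @param snp_counts Tibble (gene_id, snp_count); every ranked gene needs one.
#' @param hypothesis_set Character vector of pre-allocated gene ids.
#' @param snp_budget Non-negative SNP budget for non-hypothesis genes.
#' @return A list: `genes` (character vector of rank-selected gene ids,
#'   including budget-free hypothesis genes encountered), `rank_cutoff`
#'   (worst rank reached), and `snps_used`.
#' @examples
#' rk <- tibble::tibble(gene_id = letters[1:5], rank = 1:5)
#' sc <- tibble::tibble(gene_id = letters[1:5], snp_count = c(3, 4, 2, 5, 1))
#' select_rank_based(rk, sc, character(0), snp_budget = 6)$genes
#' @export
select_rank_based <- function(ranking, snp_counts, hypothesis_set,
                              snp_budget) {
  if (snp_budget < 0) abort("`snp_budget` must be non-negative.")
  rk <- ranking %>%
    arrange(.data$rank) %>%
    left_join(snp_counts, by = "gene_id")
  if (anyNA(rk$snp_count)) {
    abort("Every ranked gene must have a SNP count.")
  }
  is_hyp <- rk$gene_id %in% hypothesis_set
  # smallest budget-consuming SNP count at or below each rank position:
  # iteration stops once no later non-hypothesis gene can possibly fit
  charge <- ifelse(is_hyp, Inf, rk$snp_count)
  suffix_min <- rev(cummin(rev(charge)))
  added <- logical(nrow(rk))
  cutoff <- 0L
  remaining <- snp_budget
  for (i in seq_len(nrow(rk))) {
    if (suffix_min[i] > remaining) break
    if (!is_hyp[i] && rk$snp_count[i] <= remaining) {
      added[i] <- TRUE
      remaining <- remaining - rk$snp_count[i]
      cutoff <- rk$rank[i]
    }
  }
  # hypothesis genes are pre-allocated: they belong to the rank set only
  # down to the cutoff actually reached while spending the budget
  in_set <- added | (is_hyp & rk$rank <= cutoff)
  list(genes = rk$gene_id[in_set], rank_cutoff = cutoff,
       snps_used = snp_budget - remaining)
}

#' Assign the three analysis categories
#'
#' Category 1: genes both in the hypothesis set and the rank-based set;
#' category 2: hypothesis only; category 3: rank only. The three categories
#' partition the selected union.
#'
#' @param hypothesis_set,rank_set Character vectors of gene ids.
#' @return A list: `selection`, a tibble (gene_id, selected, category,
#'   reason) covering the union, and `sizes`, a named integer vector with
#'   elements cat1, cat2, cat3, hypothesis, rank, total.
#' @examples
#' assign_categories(c("A", "B", "C"), c("B", "C", "D"))$sizes
#' @export
assign_categories <- function(hypothesis_set, rank_set) {
  hypothesis_set <- unique(hypothesis_set)
  rank_set <- unique(rank_set)
  all_genes <- sort(union(hypothesis_set, rank_set))
  in_h <- all_genes %in% hypothesis_set
  in_r <- all_genes %in% rank_set
  selection <- tibble(
    gene_id = all_genes,
    selected = TRUE,
    category = dplyr::case_when(in_h & in_r ~ 1L, in_h ~ 2L, TRUE ~ 3L),
    reason = dplyr::case_when(in_h & in_r ~ "both", in_h ~ "hypothesis",
                              TRUE ~ "rank")
  )
  sizes <- c(
    cat1 = sum(in_h & in_r), cat2 = sum(in_h & !in_r),
    cat3 = sum(!in_h & in_r), hypothesis = length(hypothesis_set),
    rank = length(rank_set), total = length(all_genes)
  )
  list(selection = selection, sizes = sizes)
}
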