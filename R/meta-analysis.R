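#' Inverse-variance fixed-effects meta-analysis of one SNP
#'
#' Pools study-specific log-odds effects under the fixed-effects model with
#' weights w_i = 1/se_i^2: beta = sum(w b) / sum(w), se = sqrt(1/sum(w)),
#' z = beta/se, two-sided normal p. All studies must report the same effect
#' allele; no silent allele flipping is performed. With at least two studies
#' Cochran's Q = sum(w (b - beta)^2), I^2 = max(0, (Q - (k-1))/Q) * 100
#' (0 when Q = 0) and the heterogeneity p from the chi-square with k-1 df
#' are attached; with one study they are `NA`.
#'
#' @param effects Tibble with columns `study`, `beta`, `se` and optionally
#'   `effect_allele`.
#' @return An object of class `fe_meta`; see [tidy.fe_meta()] and
#'   [glance.fe_meta()].
#' @examples
#' fe_meta(tibble::tibble(study = c("a", "b"), beta = c(0.2, -0.1),
#'                        se = c(0.1, 0.1)))
#' @export
fe_meta <- function(effects) {
  if (nrow(effects) < 1) abort("At least one study is required.")
  if (any(effects$se <= 0)) abort("All standard errors must be positive.")
  if ("effect_allele" %in% names(effects) &&
      length(unique(effects$effect_allele)) > 1) {
    abort(paste0(
      "Studies disagree on the effect allele (",
      paste(unique(effects$effect_allele), collapse = " vs "),
      "); harmonize alleles upstream, no silent flipping is done."))
  }
  w <- 1 / effects$se^2
  beta <- sum(w * effects$beta) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- beta / se
  p <- 2 * pnorm(-abs(z))
  k <- nrow(effects)
  if (k >= 2) {
    Q <- sum(w * (effects$beta - beta)^2)
    I2 <- if (Q <= 0) 0 else max(0, (Q - (k - 1)) / Q) * 100
    p_het <- pchisq(Q, df = k - 1, lower.tail = FALSE)
  } else {
    Q <- NA_real_; I2 <- NA_real_; p_het <- NA_real_
  }
  structure(
    list(effects = as_tibble(effects), beta = beta, se = se, z = z, p = p,
         Q = Q, I2 = I2, p_het = p_het, n_studies = k),
    class = "fe_meta"
  )
}

#' Heterogeneity statistics for a set of study effects
#'
#' Cochran's Q about a given pooled estimate, Higgins' I^2 (floored at 0,
#' defined 0 when Q = 0) and the asymptotic chi-square heterogeneity p-value
#' with k-1 degrees of freedom. Requires at least two studies.
#'
#' @param effects Tibble with `beta` and `se`.
#' @param beta_meta Pooled fixed-effects estimate (computed if missing).
#' @return A named list (Q, I2, p_het).
#' @export
heterogeneity <- function(effects, beta_meta = NULL) {
  if (nrow(effects) < 2) {
    abort("Heterogeneity is undefined for fewer than two studies.")
  }
  w <- 1 / effects$se^2
  if (is.null(beta_meta)) beta_meta <- sum(w * effects$beta) / sum(w)
  Q <- sum(w * (effects$beta - beta_meta)^2)
  k <- nrow(effects)
  I2 <- if (Q <= 0) 0 else max(0, (Q - (k - 1)) / Q) * 100
  list(Q = Q, I2 = I2, p_het = pchisq(Q, df = k - 1, lower.tail = FALSE))
}

#' @export
print.fe_meta <- function(x, ...) {
  cat(sprintf("Fixed-effects meta-analysis of %d study(ies)\n", x$n_studies))
  cat(sprintf("  beta = %.4f (se %.4f), z = %.3f, p = %.4g\n",
              x$beta, x$se, x$z, x$p))
  if (!is.na(x$Q)) {
    cat(sprintf("  Q = %.3f, I2 = %.1f%%, p_het = %.4g\n",
                x$Q, x$I2, x$p_het))
  }
  invisible(x)
}

#' Tidy a fixed-effects meta-analysis
#'
#' One row per study with its effect, standard error and weight share.
#'
#' @param x An `fe_meta` object.
#' @param ... Unused.
#' @return A tibble (study, beta, se, weight).
#' @export
tidy.fe_meta <- function(x, ...) {
  w <- 1 / x$effects$se^2
  tibble(study = x$effects$study, beta = x$effects$beta, se = x$effects$se,
         weight = w / sum(w))
}

#' Glance at a fixed-effects meta-analysis
#'
#' One-row pooled summary: estimate, standard error, z, p, heterogeneity
#' statistics and study count.
#'
#' @param x An `fe_meta` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.fe_meta <- function(x, ...) {
  tibble(beta = x$beta, se = x$se, z = x$z, p = x$p, Q = x$Q, I2 = x$I2,
         p_het = x$p_het, n_studies = x$n_studies)
}

#' Meta-analyze candidate SNPs across studies
#'
#' Runs the inverse-variance fixed-effects model per SNP over every study in
#' which it is reported. SNPs present in a single study are passed through
#' with missing heterogeneity statistics.
#'
#' @param studies Named list of study tibbles (snp_id, beta, se, optionally
#'   effect_allele, p).
#' @param candidates Optional character vector restricting the SNPs analyzed.
#' @return A tibble (snp_id, beta, se, z, p, Q, I2, p_het, n_studies) plus
#'   one `p_<study>` column per study.
#' @export
meta_analyze_snps <- function(studies, candidates = NULL) {
  if (is.null(names(studies))) {
    names(studies) <- paste0("study", seq_along(studies))
  }
  long <- purrr::imap_dfr(studies, function(d, nm) mutate(d, study = nm))
  if (!is.null(candidates)) long <- filter(long, .data$snp_id %in% candidates)
  if (nrow(long) == 0) return(tibble())
  per_study_p <- long %>%
    select("snp_id", "study", "p") %>%
    tidyr::pivot_wider(names_from = "study", values_from = "p",
                       names_prefix = "p_")
  pooled <- long %>%
    group_by(.data$snp_id) %>%
    dplyr::group_modify(function(d, key) glance(fe_meta(d))) %>%
    ungroup()
  left_join(pooled, per_study_p, by = "snp_id") %>% arrange(.data$p)
}

#' Screen meta-analysis results for heterogeneity and significance
#'
#' Removes SNPs with evidence of between-study heterogeneity
#' (p_het < `p_het_threshold`; single-study SNPs with missing p_het are
#' kept), sorts by pooled p, and flags nominal significance
#' (p < `report_threshold`) and Bonferroni significance over the candidate
#' count.
#'
#' @param meta_results Tibble from [meta_analyze_snps()].
#' @param p_het_threshold Heterogeneity exclusion threshold (default 0.05).
#' @param report_threshold Nominal significance threshold (default 0.05).
#' @return The screened tibble with `nominal` and `bonferroni_significant`
#'   columns; attribute `"n_removed_heterogeneity"` records the exclusions.
#' @export
meta_screen <- function(meta_results, p_het_threshold = 0.05,
                        report_threshold = 0.05) {
  if (nrow(meta_results) == 0) return(meta_results)
  n_cand <- nrow(meta_results)
  drop <- !is.na(meta_results$p_het) & meta_results$p_het < p_het_threshold
  out <- meta_results[!drop, , drop = FALSE] %>%
    arrange(.data$p) %>%
    mutate(nominal = .data$p < report_threshold,
           bonferroni_significant = .data$p < report_threshold / n_cand)
  attr(out, "n_removed_heterogeneity") <- sum(drop)
  out
}
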