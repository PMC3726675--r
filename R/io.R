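#' Write simulated pipeline inputs to a directory
#'
#' Emits the on-disk interface consumed by the downstream stages: `genes.tsv`,
#' `regions.bed` (BED3+1, 0-based half-open), `expression.tsv`, `ppi.tsv`,
#' `literature.tsv`, `go.tsv`, `snps.tsv`, one `gwas_<study>.tsv` per study
#' and, when present, `trios.ped` / `trios.map` (1-based positions).
#'
#' @param inputs The list returned by [simulate_inputs()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_synthetic_inputs <- function(inputs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, f) readr::write_tsv(x, file.path(dir, f), progress = FALSE)
  tsv(inputs$genes, "genes.tsv")
  readr::write_tsv(inputs$regions, file.path(dir, "regions.bed"),
                   col_names = FALSE, progress = FALSE)
  tsv(inputs$expression, "expression.tsv")
  tsv(inputs$ppi, "ppi.tsv")
  tsv(inputs$literature, "literature.tsv")
  tsv(inputs$go, "go.tsv")
  tsv(inputs$snps, "snps.tsv")
  for (nm in names(inputs$gwas$studies)) {
    tsv(inputs$gwas$studies[[nm]], paste0("gwas_", nm, ".tsv"))
  }
  if (!is.null(inputs$trios)) {
    readr::write_delim(inputs$trios$ped, file.path(dir, "trios.ped"),
                       delim = " ", col_names = FALSE, progress = FALSE)
    readr::write_tsv(inputs$trios$map, file.path(dir, "trios.map"),
                     col_names = FALSE, progress = FALSE)
  }
  invisible(dir)
}

#' Read a tab-separated pipeline input
#'
#' Thin readr wrapper used for all the package's TSV interfaces.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_input_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read trio genotypes from PED/MAP files
#'
#' Expects the plain-text PLINK layout written by [write_synthetic_inputs()]:
#' six leading PED columns then two allele columns per SNP (coded 1/2), and a
#' four-column MAP (chrom, snp_id, cm, 1-based position).
#'
#' @param ped_path,map_path File paths.
#' @return A list with `ped` and `map` tibbles matching [sim_trios()] output.
#' @export
read_ped_map <- function(ped_path, map_path) {
  map <- readr::read_tsv(map_path,
                         col_names = c("chrom", "snp_id", "cm", "pos_1based"),
                         show_col_types = FALSE, progress = FALSE)
  ped <- readr::read_delim(ped_path, delim = " ", col_names = FALSE,
                           show_col_types = FALSE, progress = FALSE)
  names(ped) <- c("fam_id", "ind_id", "pat_id", "mat_id", "sex", "phenotype",
                  paste0(rep(map$snp_id, each = 2), c("_a1", "_a2")))
  list(ped = ped, map = map)
}
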