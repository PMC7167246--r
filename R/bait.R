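#' Integrate GWAS lead SNPs into a non-redundant bait-gene set
#'
#' Each lead SNP carries a nearest-gene assignment taken from its source
#' GWAS (the assignments are inputs, not recomputed here). SNPs contributing
#' the same gene symbol — within or across studies — are merged into one
#' bait gene whose `sources` field records every contributing study.
#'
#' @param snps lead-SNP tibble (`rsid`, `chrom`, `pos`, `study`, `p`,
#'   `nearest_gene`, optional `locus_id`), e.g. from
#'   `read_table(path, "lead_snp")`.
#' @param genes gene spans: a tibble with `symbol`, `chrom`, `start`, `end`,
#'   or a [gene_models] object.
#' @return a bait tibble (`symbol`, `chrom`, `start`, `end`, `sources`,
#'   `lead_snps`), one row per unique symbol, ordered by chromosome and
#'   start. Nearest-gene symbols that cannot be resolved against `genes`
#'   are reported in a warning and attached as
#'   `attr(, "unresolved_symbols")`; SNPs with a missing nearest gene are
#'   dropped with a warning.
#' @export
#' @examples
#' snps <- tibble::tibble(
#'   rsid = c("rs1", "rs2"), chrom = c("1", "1"), pos = c(150L, 160L),
#'   study = c("A", "B"), p = c(1e-9, 1e-8),
#'   nearest_gene = c("G1", "G1"), locus_id = c("L1", "L1"))
#' genes <- tibble::tibble(symbol = "G1", chrom = "1",
#'                         start = 100L, end = 500L)
#' integrate_bait_genes(snps, genes)  # one gene, two sources
integrate_bait_genes <- function(snps, genes) {
  if (inherits(genes, "gene_models")) genes <- genes$genes
  genes <- mutate(genes, chrom = normalize_chrom(.data$chrom))
  snps <- mutate(snps, chrom = normalize_chrom(.data$chrom))

  no_gene <- is.na(snps$nearest_gene) | snps$nearest_gene == ""
  if (any(no_gene)) {
    warn(paste0(sum(no_gene), " lead SNP(s) without a nearest gene ",
                "excluded: ", paste(snps$rsid[no_gene], collapse = ", ")))
    snps <- snps[!no_gene, ]
  }
  unresolved <- sort(setdiff(unique(snps$nearest_gene), genes$symbol))
  if (length(unresolved) > 0) {
    warn(paste0(length(unresolved), " nearest-gene symbol(s) not ",
                "resolvable in the gene set: ",
                paste(unresolved, collapse = ", ")))
  }
  bait <- snps %>%
    filter(.data$nearest_gene %in% genes$symbol) %>%
    group_by(symbol = .data$nearest_gene) %>%
    summarise(
      sources = paste(sort(unique(.data$study)), collapse = ";"),
      lead_snps = paste(sort(unique(.data$rsid)), collapse = ";"),
      .groups = "drop"
    ) %>%
    left_join(genes[, c("symbol", "chrom", "start", "end")], by = "symbol") %>%
    arrange(chrom_order(.data$chrom), .data$start) %>%
    select("symbol", "chrom", "start", "end", "sources", "lead_snps")
  attr(bait, "unresolved_symbols") <- unresolved
  bait
}

#' Drop sex-chromosome genes from a bait set
#'
#' Genotype imputation on the X chromosome is incomplete in several of the
#' source GWAS cohorts, so only autosomal bait genes are carried forward.
#'
#' @param bait bait tibble from [integrate_bait_genes()].
#' @return the autosomal subset; the number of removed genes is reported
#'   with `inform()`.
#' @export
exclude_sex_chromosomes <- function(bait) {
  keep <- is_autosome(bait$chrom)
  if (any(!keep)) {
    inform(paste0("excluded ", sum(!keep),
                  " sex-chromosome gene(s) from the bait set"))
  }
  bait[keep, ]
}

#' Count distinct GWAS loci in a lead-SNP table
#'
#' A locus is the set of lead SNPs sharing a `locus_id`; SNPs without one
#' are each their own locus.
#'
#' @param snps lead-SNP tibble.
#' @return integer count of distinct loci.
#' @export
count_loci <- function(snps) {
  id <- snps$locus_id
  if (is.null(id)) id <- rep(NA_character_, nrow(snps))
  id <- ifelse(is.na(id) | id == "", paste0("snp:", snps$rsid), id)
  n_distinct(id)
}

# Numeric-aware chromosome ordering (1..22 then X, Y, others).
chrom_order <- function(chrom) {
  chrom <- normalize_chrom(chrom)
  n <- suppressWarnings(as.integer(chrom))
  ifelse(!is.na(n), n, 22L + match(chrom, c("X", "Y"), nomatch = 3L))
}
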