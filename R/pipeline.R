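#' Run the bait-and-pond pipeline on a simulated input bundle
#'
#' End-to-end driver over in-memory inputs: bait integration and
#' sex-chromosome exclusion, kilobase-bucket overlap of the pond with the
#' bait set, positional classification of every prey hit against the
#' multi-isoform annotation, and candidate (HIEG) selection with category
#' accounting.
#'
#' @param sim output of [simulate_inputs()], or any list providing
#'   `snps`, `pond`, and `genome$human`.
#' @return a list: `bait` (autosomal bait tibble), `prey`, `calls`,
#'   `hiegs`, `category_counts`, `prey_summary`.
#' @export
run_pipeline <- function(sim) {
  bait <- integrate_bait_genes(sim$snps, sim$genome$human)
  bait <- exclude_sex_chromosomes(bait)
  prey <- kb_bucket_overlap(sim$pond, bait)
  calls <- classify_positions(prey, sim$pond, sim$genome$human)
  sel <- select_hiegs(calls, genes = sim$genome$human$genes$symbol)
  list(bait = bait, prey = prey, calls = calls, hiegs = sel$hiegs,
       category_counts = sel$category_counts,
       prey_summary = prey_summary(prey))
}

#' Candidate selection on the packaged fixture
#'
#' Applies the selection and deduplication rules to the packaged
#' candidate-gene records ([table1_records()]): every record already
#' carries its positional class, so this is [select_hiegs()] on the
#' transcribed rows.
#'
#' @return the [select_hiegs()] result list (`hiegs`,
#'   `category_counts`).
#' @export
table1_hieg_selection <- function() {
  tab <- table1_records()
  calls <- tibble(
    gene_symbol = tab$gene,
    var_id = paste0(tab$gene, ":", tab$vtype, ":", tab$start),
    vtype = tab$vtype,
    pclass = tab$pclass,
    also_str = tab$also_str)
  select_hiegs(calls, genes = unique(tab$gene))
}

#' Genes carrying STR variation among prey hits
#'
#' Counts genes hit by STR records, including insertions co-identified as
#' STR expansions (`also_str`).
#'
#' @param prey prey tibble with `vtype`.
#' @param pond the pond the hits came from (for the `also_str` flag).
#' @return named integer vector: `str_total`, `str_contraction`,
#'   `str_expansion`.
#' @export
str_prey_gene_counts <- function(prey, pond) {
  vars <- pond_records(pond)
  hits <- left_join(prey, vars[, c("var_id", "also_str")], by = "var_id")
  con <- hits$gene_symbol[hits$vtype == "STR_CONTRACTION"]
  exp_ <- hits$gene_symbol[hits$vtype == "STR_EXPANSION" |
                             (hits$also_str %in% TRUE)]
  c(str_total = n_distinct(c(con, exp_)),
    str_contraction = n_distinct(con),
    str_expansion = n_distinct(exp_))
}
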