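#' Kilobase-bucket intersection of pond and bait
#'
#' The operative intersection method of the pipeline: chromosome positions
#' of genes and variations are integer-divided by `bucket_bp` (default
#' 1000) and a hit is emitted when the bucket ranges intersect on the same
#' chromosome. Dividing by 1000 was framed as a computational-efficiency
#' device, but it changes semantics — a variation up to `bucket_bp - 1` bp
#' outside a gene can still share a bucket — so every hit also records
#' `within_gene`, whether the exact 1-based spans intersect. Downstream
#' stages use `within_gene` to separate flank hits from true containments.
#'
#' @param pond a `variation_pond` (or pond-schema tibble).
#' @param bait bait tibble (`symbol`, `chrom`, `start`, `end`).
#' @param bucket_bp bucket width in bp, >= 1.
#' @return prey tibble (`gene_symbol`, `var_id`, `vtype`, `method`,
#'   `within_gene`), ordered by gene then variation id; independent of
#'   input row order.
#' @export
kb_bucket_overlap <- function(pond, bait, bucket_bp = 1000L) {
  stopifnot(bucket_bp >= 1)
  vars <- pond_records(pond)
  hits <- pair_by_chrom(vars, bait)
  if (nrow(hits) == 0) return(empty_prey("kb_bucket"))
  bucket <- function(x) floor(x / bucket_bp)
  hit <- intervals_overlap(bucket(hits$start), bucket(hits$end),
                           bucket(hits$gene_start), bucket(hits$gene_end))
  finish_prey(hits[hit, ], method = "kb_bucket")
}

#' Exact interval intersection of pond and bait
#'
#' Verification oracle for [kb_bucket_overlap()]: a hit if and only if the
#' 1-based inclusive spans share at least one base on the same chromosome.
#' Implemented on GenomicRanges.
#'
#' @inheritParams kb_bucket_overlap
#' @return prey tibble as in [kb_bucket_overlap()], `method = "exact"`,
#'   `within_gene` all `TRUE`.
#' @export
exact_overlap_oracle <- function(pond, bait) {
  vars <- pond_records(pond)
  if (nrow(vars) == 0 || nrow(bait) == 0) return(empty_prey("exact"))
  vr <- GenomicRanges::GRanges(vars$chrom,
                               IRanges::IRanges(vars$start, vars$end))
  gr <- GenomicRanges::GRanges(normalize_chrom(bait$chrom),
                               IRanges::IRanges(bait$start, bait$end))
  ov <- GenomicRanges::findOverlaps(vr, gr)
  out <- tibble(
    gene_symbol = bait$symbol[S4Vectors::subjectHits(ov)],
    var_id = vars$var_id[S4Vectors::queryHits(ov)],
    vtype = vars$vtype[S4Vectors::queryHits(ov)],
    method = "exact",
    within_gene = TRUE
  )
  arrange(out, .data$gene_symbol, .data$var_id)
}

pond_records <- function(pond) {
  if (inherits(pond, "variation_pond")) pond$records else as_tibble(pond)
}

pair_by_chrom <- function(vars, bait) {
  bait <- bait %>%
    mutate(chrom = normalize_chrom(.data$chrom)) %>%
    rename(gene_symbol = "symbol", gene_start = "start", gene_end = "end")
  inner_join(vars, bait[, c("gene_symbol", "chrom", "gene_start",
                            "gene_end")],
             by = "chrom", relationship = "many-to-many")
}

finish_prey <- function(paired, method) {
  tibble(
    gene_symbol = paired$gene_symbol,
    var_id = paired$var_id,
    vtype = paired$vtype,
    method = method,
    within_gene = intervals_overlap(paired$start, paired$end,
                                    paired$gene_start, paired$gene_end)
  ) %>%
    arrange(.data$gene_symbol, .data$var_id)
}

empty_prey <- function(method) {
  tibble(gene_symbol = character(), var_id = character(),
         vtype = character(), method = character(), within_gene = logical())
}

#' Summarise prey hits
#'
#' A gene hit by several variations counts once in the overall gene tally;
#' per-type tallies count distinct genes per variation type.
#'
#' @param hits prey tibble (needs a `vtype` column, as produced by the
#'   overlap functions).
#' @return a list with `n_genes`, `n_variations`, and `by_type` — a tibble
#'   of distinct gene and variation counts per variation type.
#' @export
prey_summary <- function(hits) {
  by_type <- hits %>%
    group_by(.data$vtype) %>%
    summarise(n_genes = n_distinct(.data$gene_symbol),
              n_variations = n_distinct(.data$var_id), .groups = "drop") %>%
    arrange(.data$vtype)
  list(n_genes = n_distinct(hits$gene_symbol),
       n_variations = n_distinct(hits$var_id),
       by_type = by_type)
}
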