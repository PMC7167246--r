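#' Positional classification of prey variations against gene structure
#'
#' Every prey hit is classified against every isoform of its gene and the
#' most consequential class across isoforms is reported, under the
#' precedence `CDS_EXON > UTR5/UTR3 > NONCODING_EXON > INTRON > FLANK`.
#' UTR side is resolved strand-aware (exonic bases upstream of the CDS are
#' the 5' UTR on the + strand, the 3' UTR on the - strand). `FLANK` is
#' only possible for kilobase-bucket hits whose exact spans do not
#' intersect the gene.
#'
#' @param prey prey tibble from [kb_bucket_overlap()] (needs
#'   `within_gene`).
#' @param pond a `variation_pond` or pond-schema tibble.
#' @param models a [gene_models] object holding the human annotation.
#' @return a tibble of positional calls: `gene_symbol`, `var_id`, `vtype`,
#'   `pclass`, `nearest_exon_distance`, `isoform_id`, `within_gene`.
#' @export
classify_positions <- function(prey, pond, models) {
  vars <- pond_records(pond)
  calls <- prey %>%
    left_join(vars[, c("var_id", "start", "end", "also_str")],
              by = "var_id")
  if (any(is.na(calls$start))) {
    abort(paste0("consistency error: prey hit references unknown ",
                 "variation: ",
                 paste(calls$var_id[is.na(calls$start)], collapse = ", ")))
  }
  human_tx <- filter(models$transcripts, .data$species == "human")
  res <- purrr::pmap(calls, function(gene_symbol, var_id, vtype, start,
                                     end, within_gene, also_str, ...) {
    cl <- classify_one(gene_symbol, start, end, within_gene,
                       human_tx, models)
    tibble(gene_symbol = gene_symbol, var_id = var_id, vtype = vtype,
           pclass = cl$pclass,
           nearest_exon_distance = cl$nearest_exon_distance,
           isoform_id = cl$isoform_id, within_gene = within_gene,
           also_str = isTRUE(also_str))
  })
  bind_rows(res)
}

# precedence rank; larger wins
.pclass_rank <- c(CDS_EXON = 5, UTR5 = 4, UTR3 = 4, NONCODING_EXON = 3,
                  INTRON = 2, FLANK = 1)

classify_one <- function(gene_symbol, vstart, vend, within_gene,
                         human_tx, models) {
  tx <- human_tx[human_tx$gene_symbol == gene_symbol, ]
  if (nrow(tx) == 0) {
    abort(paste0("annotation error: gene ", gene_symbol,
                 " has no transcripts"))
  }
  gene <- models$genes[models$genes$symbol == gene_symbol, ]
  strand <- gene$strand[1]
  ex_all <- models$exons[models$exons$transcript_id %in% tx$transcript_id, ]
  dist <- if (nrow(ex_all) > 0) {
    min(interval_distance(vstart, vend, ex_all$start, ex_all$end))
  } else NA_integer_

  if (!within_gene) {
    return(list(pclass = "FLANK", nearest_exon_distance = dist,
                isoform_id = NA_character_))
  }
  best <- list(pclass = "INTRON", isoform_id = tx$transcript_id[1])
  for (i in seq_len(nrow(tx))) {
    ex <- ex_all[ex_all$transcript_id == tx$transcript_id[i], ]
    hit_ex <- ex[intervals_overlap(vstart, vend, ex$start, ex$end), ]
    cl <- if (nrow(hit_ex) == 0) {
      "INTRON"
    } else if (is.na(tx$cds_start[i])) {
      "NONCODING_EXON"
    } else {
      # exonic portions overlapped by the variation, clipped to the CDS span
      cs <- pmax(pmax(hit_ex$start, vstart), tx$cds_start[i])
      ce <- pmin(pmin(hit_ex$end, vend), tx$cds_end[i])
      if (any(cs <= ce)) {
        "CDS_EXON"
      } else {
        upstream <- max(pmin(hit_ex$end, vend)) < tx$cds_start[i]
        if (upstream == (strand == "+")) "UTR5" else "UTR3"
      }
    }
    if (.pclass_rank[[cl]] > .pclass_rank[[best$pclass]]) {
      best <- list(pclass = cl, isoform_id = tx$transcript_id[i])
    }
  }
  list(pclass = best$pclass, nearest_exon_distance = dist,
       isoform_id = best$isoform_id)
}

#' Detect cross-species exon gain and loss
#'
#' A human exon is an exon gain when its sequence matches no exon of any
#' transcript of the gene in any supplied ape species; an ape exon matched
#' by no human exon of any isoform is an exon loss. Matching reuses the
#' validator's aligner: identity >= `min_identity` over >=
#' `min_coverage` of the exon length.
#'
#' @param gene_symbol gene symbol for the report.
#' @param human_exons tibble (`transcript_id`, `exon_rank`, `seq`).
#' @param ape_exons tibble (`species`, `transcript_id`, `exon_rank`,
#'   `seq`).
#' @param min_identity,min_coverage match thresholds (defaults 0.9, 0.8).
#' @return event tibble (`gene_symbol`, `event`, `species`,
#'   `transcript_id`, `exon_rank`, `length_bp`), empty when exon sets
#'   agree.
#' @export
detect_exon_gain_loss <- function(gene_symbol, human_exons, ape_exons,
                                  min_identity = 0.9, min_coverage = 0.8) {
  check_seqs <- function(df, who) {
    bad <- is.na(df$seq) | !nzchar(df$seq)
    if (any(bad)) {
      abort(paste0("missing exon sequence in ", who, " transcript(s): ",
                   paste(unique(df$transcript_id[bad]), collapse = ", ")))
    }
  }
  check_seqs(human_exons, "human")
  check_seqs(ape_exons, "ape")

  matches_any <- function(seq, targets) {
    any(vapply(targets, function(t)
      segment_found(seq, t, min_identity, min_coverage), logical(1)))
  }
  gains <- human_exons[!vapply(human_exons$seq, matches_any, logical(1),
                               targets = ape_exons$seq), ]
  losses <- ape_exons[!vapply(ape_exons$seq, matches_any, logical(1),
                              targets = human_exons$seq), ]
  # one event per distinct sequence, keeping the first carrier
  gains <- gains[!duplicated(gains$seq), ]
  losses <- losses[!duplicated(losses$seq), ]
  empty <- tibble(gene_symbol = character(), event = character(),
                  species = character(), transcript_id = character(),
                  exon_rank = integer(), length_bp = integer())
  bind_rows(
    empty,
    if (nrow(gains) > 0) tibble(
      gene_symbol = gene_symbol, event = "EXON_GAIN", species = "human",
      transcript_id = gains$transcript_id, exon_rank = gains$exon_rank,
      length_bp = nchar(gains$seq)),
    if (nrow(losses) > 0) tibble(
      gene_symbol = gene_symbol, event = "EXON_LOSS",
      species = losses$species, transcript_id = losses$transcript_id,
      exon_rank = losses$exon_rank, length_bp = nchar(losses$seq))
  )
}

#' Select human intelligence evolution gene (HIEG) candidates
#'
#' A gene is admitted when it carries (a) a variation located in exonic
#' sequence of any isoform — CDS exon, UTR, or an exon of a non-coding
#' isoform — or (b) any hCONDEL, HSD, or exon gain/loss regardless of
#' position (hCONDELs are intronic yet admitted for their high lineage
#' specificity). Inversions never admit a gene: an inversion spanning a
#' whole gene is audited for breakpoints instead (see
#' [check_inversion_breakpoints()]). Category accounting: exon gain/loss
#' events count under `EXON_GAIN_LOSS`; hCONDELs under `HCONDEL`; HSDs
#' under `HSD`; exon-located STRs — including insertions co-identified as
#' STR expansions (`also_str`) — under `STR`; remaining exon-located
#' insertions/deletions under `INDEL`. Output is deduplicated by gene with
#' categories unioned.
#'
#' @param calls positional-call tibble from [classify_positions()]
#'   (columns `gene_symbol`, `var_id`, `vtype`, `pclass`, optional
#'   `also_str`).
#' @param genes optional character vector of known gene symbols; calls
#'   referencing other genes raise a consistency error.
#' @return a list: `hiegs` (hieg-schema tibble, one row per gene) and
#'   `category_counts` (named integer vector over the five categories,
#'   counting distinct genes).
#' @export
select_hiegs <- function(calls, genes = NULL) {
  if (!"also_str" %in% names(calls)) calls$also_str <- FALSE
  calls$also_str[is.na(calls$also_str)] <- FALSE
  if (!is.null(genes)) {
    bad <- setdiff(unique(calls$gene_symbol), genes)
    if (length(bad) > 0) {
      abort(paste0("consistency error: call references unknown gene(s): ",
                   paste(bad, collapse = ", ")))
    }
  }
  exonic <- calls$pclass %in% c("CDS_EXON", "UTR5", "UTR3",
                                "NONCODING_EXON")
  unconditional <- calls$vtype %in% c("HCONDEL", "HSD", "EXON_GAIN",
                                      "EXON_LOSS")
  admitted <- calls[(exonic & calls$vtype != "INVERSION") | unconditional, ]
  if (nrow(admitted) == 0) {
    return(list(
      hiegs = tibble(gene_symbol = character(), variations = character(),
                     categories = character(), admit_rule = character()),
      category_counts = setNames(integer(length(HIEG_CATEGORIES)),
                                 HIEG_CATEGORIES)))
  }
  admitted <- admitted %>%
    mutate(
      category = case_when(
        .data$vtype %in% c("EXON_GAIN", "EXON_LOSS") ~ "EXON_GAIN_LOSS",
        .data$vtype == "HCONDEL" ~ "HCONDEL",
        .data$vtype == "HSD" ~ "HSD",
        .data$vtype %in% c("STR_CONTRACTION", "STR_EXPANSION") |
          .data$also_str ~ "STR",
        TRUE ~ "INDEL"),
      rule = ifelse(.data$vtype %in% c("HCONDEL", "HSD", "EXON_GAIN",
                                       "EXON_LOSS"),
                    paste0(tolower(.data$vtype),
                           " admitted regardless of position"),
                    paste0("exon-located ", tolower(.data$vtype)))
    )
  hiegs <- admitted %>%
    group_by(.data$gene_symbol) %>%
    summarise(
      variations = paste(sort(unique(.data$var_id)), collapse = ";"),
      categories = paste(intersect(HIEG_CATEGORIES,
                                   unique(.data$category)),
                         collapse = ";"),
      admit_rule = paste(sort(unique(.data$rule)), collapse = "; "),
      .groups = "drop") %>%
    arrange(.data$gene_symbol)
  counts <- admitted %>%
    distinct(.data$gene_symbol, .data$category) %>%
    count_categories()
  list(hiegs = hiegs, category_counts = counts)
}

count_categories <- function(gene_cat) {
  tab <- table(factor(gene_cat$category, levels = HIEG_CATEGORIES))
  setNames(as.integer(tab), HIEG_CATEGORIES)
}

#' Audit genes against inversion breakpoints
#'
#' For every gene overlapping an inversion span, reports whether the gene
#' contains an inversion breakpoint (`at_breakpoint`: the gene span
#' contains the inversion start or end), lies wholly inside the inversion
#' (`inside`), or does not overlap any inversion (`outside`).
#'
#' @param inversions pond-schema tibble of `INVERSION` records.
#' @param genes bait-like tibble (`symbol`, `chrom`, `start`, `end`).
#' @return tibble (`gene_symbol`, `var_id`, `status`); genes overlapping
#'   no inversion appear once with `status = "outside"` and `var_id` NA.
#' @export
check_inversion_breakpoints <- function(inversions, genes) {
  inv <- pond_records(inversions)
  inv <- inv[inv$vtype == "INVERSION" | !inv$vtype %in% VTYPES, ]
  genes <- mutate(genes, chrom = normalize_chrom(.data$chrom))
  paired <- pair_by_chrom(inv, genes)
  paired <- paired[intervals_overlap(paired$start, paired$end,
                                     paired$gene_start, paired$gene_end), ]
  status <- with(paired, ifelse(
    (gene_start <= start & start <= gene_end) |
      (gene_start <= end & end <= gene_end),
    "at_breakpoint",
    ifelse(gene_start >= start & gene_end <= end, "inside", "outside")))
  res <- tibble(gene_symbol = paired$gene_symbol, var_id = paired$var_id,
                status = status)
  untouched <- setdiff(genes$symbol, res$gene_symbol)
  bind_rows(res,
            tibble(gene_symbol = untouched, var_id = NA_character_,
                   status = "outside")) %>%
    arrange(.data$gene_symbol)
}
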