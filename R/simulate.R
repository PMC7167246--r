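#' Simulation configuration
#'
#' Defines the study conditions for the synthetic-data generator: a small
#' multi-chromosome genome with multi-isoform gene models, a typed
#' variation pond with planted exonic hits and intergenic decoys, GWAS
#' lead-SNP tables, alignment-validation sequence cases, and expression
#' matrices with planted cortex enrichment and species-specific neocortex
#' signatures. Random number streams are per component (genome, pond,
#' expression), derived from the master seed, so changing expression
#' parameters does not perturb the genome.
#'
#' @param seed master seed (integer).
#' @param n_chroms number of autosomes to simulate.
#' @param chrom_length length of each autosome in bp.
#' @param n_genes number of autosomal genes.
#' @param n_x_genes extra genes placed on the X chromosome (excluded by
#'   the bait stage).
#' @param n_exons_range,exon_len_range,intron_len_range per-gene structure
#'   ranges (counts / bp).
#' @param utr5_bp,utr3_bp UTR widths inside the terminal exons of coding
#'   isoforms.
#' @param gap_range intergenic gap range in bp (>= 4 kb so that decoys
#'   placed with a 2-kb margin can never reach a gene, even through the
#'   1-kb bucket).
#' @param n_loci number of GWAS loci the autosomal genes are grouped into.
#' @param dup_gene_frac fraction of bait genes reported by two studies
#'   (exercises redundancy removal).
#' @param planted_hieg_spec tibble (`gene` index, `vtype`, `pclass`,
#'   `also_str`, `n` records) of variations planted at a chosen positional
#'   class; these define the expected candidate genes.
#' @param prey_plan tibble (`vtype`, `n_genes`, `n_vars`, `gene_from`)
#'   of intronic/spanning prey variations (non-exonic hits) planted in
#'   gene blocks starting at index `gene_from`.
#' @param pond_counts named integer vector of total pond records per type;
#'   the difference from planted counts is made up with intergenic decoys.
#' @param n_flank_hits variations placed within 999 bp outside a gene
#'   (bucket-only hits).
#' @param decoy_len_ranges optional named list of per-type decoy length
#'   ranges overriding the built-in defaults.
#' @param false_specific_frac fraction of validation cases in which the
#'   ape carries the supposedly human-specific state (the validator must
#'   reject these).
#' @param flank_bp validation-case flank length per side.
#' @param expression list of expression-simulation parameters; see
#'   [make_expression()].
#' @param emit_sequences generate per-gene genomic sequences (FASTA) —
#'   kept off for large configurations.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 3L,
                       chrom_length = 500000L,
                       n_genes = 30L,
                       n_x_genes = 2L,
                       n_exons_range = c(5L, 7L),
                       exon_len_range = c(200L, 300L),
                       intron_len_range = c(500L, 1500L),
                       utr5_bp = 100L,
                       utr3_bp = 150L,
                       gap_range = c(6000L, 12000L),
                       n_loci = 10L,
                       dup_gene_frac = 0.2,
                       planted_hieg_spec = default_hieg_spec(),
                       prey_plan = default_prey_plan(),
                       pond_counts = c(STR_CONTRACTION = 30L,
                                       STR_EXPANSION = 60L,
                                       INSERTION = 80L, DELETION = 50L,
                                       HCONDEL = 20L, HSD = 10L,
                                       INVERSION = 8L),
                       n_flank_hits = 2L,
                       decoy_len_ranges = NULL,
                       false_specific_frac = 0,
                       flank_bp = 500L,
                       expression = expression_config(),
                       emit_sequences = TRUE) {
  stopifnot(seed >= 0, n_genes >= 0, all(pond_counts >= 0),
            expression$noise_sd >= 0)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' @rdname sim_config
#' @param n_expr_genes number of genes carried into the expression
#'   matrices.
#' @param n_strong,n_mild planted counts of strongly (> 2-fold) and mildly
#'   (1- to 2-fold) cortex-enriched genes.
#' @param strong_factor,mild_factor multiplicative cortex effects.
#' @param noise_sd log-scale Gaussian noise s.d. for both matrices.
#' @param species species of the cross-species brain dataset (first is
#'   the focal species).
#' @param species_effect_sd s.d. of the per-species, per-gene neocortex
#'   signature (log scale).
#' @param tissue_effect_sd s.d. of the shared non-neocortex tissue
#'   signature (log scale).
#' @param fc_up,fc_down planted focal/other neocortex fold changes:
#'   numbers of genes and the fold-change values.
#' @export
expression_config <- function(n_expr_genes = 40L, n_strong = 12L,
                              n_mild = 11L, strong_factor = 4,
                              mild_factor = 1.5, noise_sd = 0.25,
                              species = c("human", "chimpanzee",
                                          "gorilla", "gibbon"),
                              species_effect_sd = 2,
                              tissue_effect_sd = 3,
                              fc_up = list(n = 1, value = 4.8),
                              fc_down = list(n = 5, value = 0.25)) {
  as.list(environment())
}

default_hieg_spec <- function() {
  tibble(
    gene = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L, 10L),
    vtype = c("EXON_GAIN", "INSERTION", "INSERTION", "DELETION",
              "STR_EXPANSION", "STR_CONTRACTION", "INSERTION", "HCONDEL",
              "HSD", "HCONDEL", "INSERTION"),
    pclass = c("CDS_EXON", "CDS_EXON", "UTR3", "NONCODING_EXON",
               "NONCODING_EXON", "CDS_EXON", "NONCODING_EXON", "INTRON",
               "INTRON", "INTRON", "CDS_EXON"),
    also_str = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE,
                 FALSE, FALSE, FALSE),
    n = 1L
  )
}

default_prey_plan <- function() {
  tibble(vtype = c("INSERTION", "DELETION", "INVERSION"),
         n_genes = c(3L, 2L, 2L),
         n_vars = c(4L, 2L, 2L),
         gene_from = c(11L, 14L, 16L))
}

# Component seed streams derived from the master seed (kept < 2^31).
sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 10007 + k * 97) %% 2147483647)
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic multi-isoform genome annotation
#'
#' Places non-overlapping genes on the configured chromosomes. Every gene
#' gets a principal protein-coding isoform (all exons, CDS inset by the
#' UTR widths), a processed transcript consisting of one exon private to
#' an intron, and — for genes named in the exon-gain plan — a variant
#' isoform carrying an extra exon absent from every ape transcript of the
#' gene. Ape annotations (chimpanzee, gorilla, orangutan) mirror the human
#' principal isoform.
#'
#' @param config a [sim_config()].
#' @return a list: `human` ([gene_models]), `ape` ([gene_models]),
#'   `exon_seqs` (tibble `species`, `transcript_id`, `exon_rank`, `seq`
#'   for exon-gain genes), `gene_seqs` (named character, when
#'   `emit_sequences`).
#' @export
make_genome <- function(config) {
  old <- rng_snapshot()
  on.exit(rng_restore(old), add = TRUE)
  set.seed(sub_seed(config$seed, 1L))

  n_total <- config$n_genes + config$n_x_genes
  chroms <- c(rep(as.character(seq_len(config$n_chroms)),
                  length.out = config$n_genes),
              rep("X", config$n_x_genes))
  chroms <- chroms[order(match(chroms, c(as.character(seq_len(
    config$n_chroms)), "X")))]
  symbols <- c(sprintf("G%03d", seq_len(config$n_genes)),
               if (config$n_x_genes > 0)
                 sprintf("GX%02d", seq_len(config$n_x_genes)))

  exon_gain_genes <- integer()
  if (!is.null(config$planted_hieg_spec)) {
    exon_gain_genes <- config$planted_hieg_spec$gene[
      config$planted_hieg_spec$vtype == "EXON_GAIN"]
  }

  if (n_total == 0) {
    empty <- gene_models_empty()
    return(list(human = empty, ape = empty,
                exon_seqs = tibble(species = character(),
                                   transcript_id = character(),
                                   exon_rank = integer(),
                                   seq = character()),
                gene_seqs = if (isTRUE(config$emit_sequences))
                  character() else NULL))
  }
  genes <- list(); txs <- list(); exs <- list()
  cursor <- stats::setNames(rep(1000L, config$n_chroms + 1L),
                            c(as.character(seq_len(config$n_chroms)), "X"))
  for (i in seq_len(n_total)) {
    chrom <- chroms[i]
    sym <- symbols[i]
    n_ex <- sample(seq(config$n_exons_range[1], config$n_exons_range[2]),
                   1)
    ex_len <- sample(seq(config$exon_len_range[1],
                         config$exon_len_range[2]), n_ex, replace = TRUE)
    in_len <- sample(seq(config$intron_len_range[1],
                         config$intron_len_range[2]), n_ex - 1,
                     replace = TRUE)
    gap <- sample(seq(config$gap_range[1], config$gap_range[2]), 1)
    gstart <- cursor[[chrom]] + gap
    ex_start <- gstart + cumsum(c(0L, head(ex_len, -1) + in_len))
    ex_end <- ex_start + ex_len - 1L
    gend <- ex_end[n_ex]
    if (gend + config$gap_range[2] > config$chrom_length) {
      abort(paste0("infeasible packing: genes exceed chromosome ", chrom,
                   " length ", config$chrom_length))
    }
    cursor[[chrom]] <- gend
    strand <- if (i %% 2 == 0) "-" else "+"
    genes[[i]] <- tibble(symbol = sym, chrom = chrom, start = gstart,
                         end = gend, strand = strand, species = "human")

    # principal coding isoform over all exons
    tx_p <- paste0(sym, ".t1")
    cds_start <- ex_start[1] + config$utr5_bp
    cds_end <- ex_end[n_ex] - config$utr3_bp
    if (strand == "-") {
      cds_start <- ex_start[1] + config$utr3_bp
      cds_end <- ex_end[n_ex] - config$utr5_bp
    }
    txs[[length(txs) + 1]] <- tibble(
      transcript_id = tx_p, gene_symbol = sym, species = "human",
      biotype = "protein_coding", principal = TRUE,
      cds_start = cds_start, cds_end = cds_end)
    exs[[length(exs) + 1]] <- tibble(
      transcript_id = tx_p, start = ex_start, end = ex_end,
      exon_rank = seq_len(n_ex))

    # processed transcript: one exon private to intron 2
    nc_start <- ex_end[2] + 150L
    nc_end <- nc_start + 179L
    tx_nc <- paste0(sym, ".t2")
    txs[[length(txs) + 1]] <- tibble(
      transcript_id = tx_nc, gene_symbol = sym, species = "human",
      biotype = "processed_transcript", principal = FALSE,
      cds_start = NA_integer_, cds_end = NA_integer_)
    exs[[length(exs) + 1]] <- tibble(
      transcript_id = tx_nc, start = nc_start, end = nc_end,
      exon_rank = 1L)

    # variant isoform with a gained exon in intron 3 (exon-gain genes)
    if (i %in% exon_gain_genes) {
      gx_start <- ex_end[3] + 120L
      gx_end <- gx_start + 59L
      tx_v <- paste0(sym, ".t3")
      txs[[length(txs) + 1]] <- tibble(
        transcript_id = tx_v, gene_symbol = sym, species = "human",
        biotype = "protein_coding", principal = FALSE,
        cds_start = cds_start, cds_end = cds_end)
      ord <- order(c(ex_start, gx_start))
      exs[[length(exs) + 1]] <- tibble(
        transcript_id = tx_v,
        start = c(ex_start, gx_start)[ord],
        end = c(ex_end, gx_end)[ord],
        exon_rank = seq_len(n_ex + 1L))
    }
  }
  genes <- bind_rows(genes)
  human <- gene_models(genes, bind_rows(txs), bind_rows(exs))

  # ape annotations mirror the human principal isoform
  ape_species <- c("chimpanzee", "gorilla", "orangutan")
  p_tx <- filter(human$transcripts, .data$principal)
  p_ex <- filter(human$exons,
                 .data$transcript_id %in% p_tx$transcript_id)
  ape_tx <- purrr::map(ape_species, function(sp)
    mutate(p_tx, transcript_id = paste0(.data$transcript_id, ".", sp),
           species = sp)) %>% bind_rows()
  ape_ex <- purrr::map(ape_species, function(sp)
    mutate(p_ex, transcript_id = paste0(.data$transcript_id, ".", sp))) %>%
    bind_rows()
  ape <- gene_models(mutate(genes, species = "ape"), ape_tx, ape_ex)

  # exon sequences for exon-gain genes: ape exons copy the human
  # principal exons; the gained exon exists only in the human variant.
  exon_seqs <- list()
  for (gi in unique(exon_gain_genes)) {
    sym <- symbols[gi]
    pex <- exs_of(human, paste0(sym, ".t1"))
    seqs <- vapply(span_length(pex$start, pex$end), rand_dna, character(1))
    vex <- exs_of(human, paste0(sym, ".t3"))
    gained <- which(!vex$start %in% pex$start)
    vseqs <- character(nrow(vex))
    vseqs[-gained] <- seqs
    vseqs[gained] <- rand_dna(span_length(vex$start[gained],
                                          vex$end[gained]))
    exon_seqs[[length(exon_seqs) + 1]] <- bind_rows(
      tibble(species = "human", transcript_id = paste0(sym, ".t1"),
             exon_rank = pex$exon_rank, seq = seqs),
      tibble(species = "human", transcript_id = paste0(sym, ".t3"),
             exon_rank = vex$exon_rank, seq = vseqs),
      purrr::map(ape_species, function(sp)
        tibble(species = sp,
               transcript_id = paste0(sym, ".t1.", sp),
               exon_rank = pex$exon_rank, seq = seqs)) %>% bind_rows())
  }
  exon_seqs <- if (length(exon_seqs) > 0) bind_rows(exon_seqs) else
    tibble(species = character(), transcript_id = character(),
           exon_rank = integer(), seq = character())

  gene_seqs <- NULL
  if (isTRUE(config$emit_sequences)) {
    gene_seqs <- setNames(
      vapply(span_length(genes$start, genes$end), rand_dna, character(1)),
      genes$symbol)
  }
  list(human = human, ape = ape, exon_seqs = exon_seqs,
       gene_seqs = gene_seqs)
}

exs_of <- function(models, tx_id) {
  arrange(models$exons[models$exons$transcript_id == tx_id, ], .data$start)
}

gene_models_empty <- function() {
  structure(list(
    genes = tibble(symbol = character(), chrom = character(),
                   start = integer(), end = integer(),
                   strand = character(), species = character()),
    transcripts = tibble(transcript_id = character(),
                         gene_symbol = character(), species = character(),
                         biotype = character(), principal = logical(),
                         cds_start = integer(), cds_end = integer()),
    exons = tibble(transcript_id = character(), start = integer(),
                   end = integer(), exon_rank = integer())),
    class = "gene_models")
}

rng_snapshot <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

rng_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
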