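HPA_TISSUES <- c(
  "cerebral cortex", "adipose tissue", "adrenal gland", "appendix",
  "bone marrow", "breast", "colon", "duodenum", "endometrium",
  "epididymis", "esophagus", "fallopian tube", "gallbladder",
  "heart muscle", "kidney", "liver", "lung", "lymph node", "ovary",
  "pancreas", "parathyroid gland", "placenta", "prostate",
  "salivary gland", "seminal vesicle", "skeletal muscle", "skin",
  "small intestine", "smooth muscle", "spleen", "stomach", "testis",
  "thyroid gland", "tonsil", "urinary bladder", "vagina", "rectum")

BRAIN_REGIONS <- tibble::tibble(
  region = c("ACC", "DPFC", "VPFC", "PMC", "V1C", "HIP", "striatum",
             "CB"),
  region_class = c(rep("neocortex", 5), rep("non_neocortex", 3)))

#' Generate expression matrices with planted effects
#'
#' Produces two matrices emulating the pipeline's expression inputs:
#' \itemize{
#'   \item a gene x 37-tissue TPM matrix (human tissue panel) with
#'     multiplicative cerebral-cortex effects planted for the configured
#'     strongly (`strong_factor`) and mildly (`mild_factor`) enriched gene
#'     sets;
#'   \item a gene x (species x 8 brain regions) RPKM matrix with additive
#'     (log-scale) species-specific neocortex signatures, shared tissue
#'     signatures for the non-neocortical regions, and planted focal/other
#'     neocortex fold changes.
#' }
#' Both matrices are log-normal around per-gene baselines with Gaussian
#' log-scale noise `noise_sd`; deterministic per seed. One gene is left
#' out of the cross-species matrix, mirroring a candidate gene absent
#' from the brain dataset.
#'
#' @param config a [sim_config()].
#' @param genome output of [make_genome()].
#' @return a list: `tpm` and `rpkm` ([expr_matrix] objects),
#'   `ground_truth` (planted enriched sets, fold changes, species
#'   partition).
#' @export
make_expression <- function(config, genome) {
  old <- rng_snapshot()
  on.exit(rng_restore(old), add = TRUE)
  set.seed(sub_seed(config$seed, 3L))
  ec <- config$expression

  auto <- genome$human$genes[is_autosome(genome$human$genes$chrom), ]
  genes <- head(auto$symbol, ec$n_expr_genes)
  ng <- length(genes)
  if (ec$n_strong + ec$n_mild > ng) {
    abort("config error: more planted enriched genes than genes")
  }
  strong <- genes[seq_len(ec$n_strong)]
  mild <- genes[ec$n_strong + seq_len(ec$n_mild)]

  # --- human tissue panel (TPM) ------------------------------------------
  base <- rnorm(ng, mean = log(5), sd = 1)
  tpm <- exp(matrix(base, ng, length(HPA_TISSUES)) +
               matrix(rnorm(ng * length(HPA_TISSUES), 0, ec$noise_sd),
                      ng, length(HPA_TISSUES)))
  dimnames(tpm) <- list(genes, HPA_TISSUES)
  tpm[strong, "cerebral cortex"] <- tpm[strong, "cerebral cortex"] *
    ec$strong_factor
  tpm[mild, "cerebral cortex"] <- tpm[mild, "cerebral cortex"] *
    ec$mild_factor
  tpm_meta <- tibble(sample = HPA_TISSUES, tissue = HPA_TISSUES,
                     species = "human",
                     region_class = ifelse(HPA_TISSUES == "cerebral cortex",
                                           "neocortex", "non_brain"))

  # --- cross-species brain panel (RPKM) ----------------------------------
  rgenes <- head(genes, ng - 1L)   # one candidate absent from the dataset
  nrg <- length(rgenes)
  sp <- ec$species
  fc_genes_up <- head(rgenes, ec$fc_up$n)
  fc_genes_down <- rgenes[ec$fc_up$n + seq_len(ec$fc_down$n)]
  fc_planted <- c(setNames(rep(ec$fc_up$value, ec$fc_up$n), fc_genes_up),
                  setNames(rep(ec$fc_down$value, ec$fc_down$n),
                           fc_genes_down))

  species_sig <- matrix(rnorm(nrg * length(sp), 0, ec$species_effect_sd),
                        nrg, length(sp), dimnames = list(rgenes, sp))
  species_sig[names(fc_planted), ] <- 0   # keep planted fold changes exact
  non_neo <- BRAIN_REGIONS$region[BRAIN_REGIONS$region_class ==
                                    "non_neocortex"]
  tissue_sig <- matrix(rnorm(nrg * length(non_neo), 0, ec$tissue_effect_sd),
                       nrg, length(non_neo),
                       dimnames = list(rgenes, non_neo))

  samples <- tidyr::expand_grid(species = sp,
                                region = BRAIN_REGIONS$region) %>%
    left_join(BRAIN_REGIONS, by = "region") %>%
    mutate(sample = paste(.data$species, .data$region, sep = "_"),
           tissue = .data$region)
  base_r <- rnorm(nrg, mean = log(8), sd = 1)
  vals <- matrix(0, nrg, nrow(samples),
                 dimnames = list(rgenes, samples$sample))
  for (j in seq_len(nrow(samples))) {
    lv <- base_r
    if (samples$region_class[j] == "neocortex") {
      lv <- lv + species_sig[, samples$species[j]]
      if (samples$species[j] == sp[1]) {
        lv <- lv + ifelse(rgenes %in% names(fc_planted),
                          log(fc_planted[rgenes]), 0)
      }
    } else {
      lv <- lv + tissue_sig[, samples$region[j]]
    }
    vals[, j] <- exp(lv + rnorm(nrg, 0, ec$noise_sd))
  }

  list(
    tpm = expr_matrix(tpm, tpm_meta, "TPM"),
    rpkm = expr_matrix(vals,
                       samples[, c("sample", "tissue", "species",
                                   "region_class")], "RPKM"),
    ground_truth = list(
      strongly_enriched = strong, mildly_enriched = mild,
      enriched = c(strong, mild),
      fold_changes = tibble(gene_symbol = names(fc_planted),
                            fold_change = unname(fc_planted)),
      species_partition = setNames(samples$species, samples$sample),
      rpkm_genes = rgenes)
  )
}

#' Generate every pipeline input with ground truth
#'
#' Runs [make_genome()], [make_pond_and_gwas()] and [make_expression()]
#' under the configured per-component seed streams and assembles the full
#' simulated input bundle.
#'
#' @param config a [sim_config()].
#' @return a list: `config`, `genome`, `pond`, `pond_sources`, `snps`,
#'   `validation_cases`, `tpm`, `rpkm`, `ground_truth` (pond/bait/prey
#'   truth plus an `expression` element).
#' @export
simulate_inputs <- function(config) {
  genome <- make_genome(config)
  pg <- make_pond_and_gwas(config, genome)
  ex <- make_expression(config, genome)
  gt <- pg$ground_truth
  gt$expression <- ex$ground_truth
  list(config = config, genome = genome, pond = pg$pond,
       pond_sources = pg$pond_sources, snps = pg$snps,
       validation_cases = pg$validation_cases,
       tpm = ex$tpm, rpkm = ex$rpkm, ground_truth = gt)
}

#' Paper-shaped simulation preset
#'
#' Study conditions sized to the shape of the published integration: 549
#' autosomal bait genes across 271 loci from six GWAS (plus X-linked
#' genes that the bait stage must drop), pond totals of 1,465 STR
#' contractions, 4,921 STR expansions, 11,899 insertions, 5,894
#' deletions, 625 inversions and 218 large (> 5 kb) HSDs, with planted
#' prey structure: 26/74 genes hit by STR contractions/expansions, 144
#' insertion- and 94 deletion-carrying genes (298/148 variations), 31
#' genes wholly inside inversions, 28 hCONDEL genes, one HSD gene and two
#' exon-gain genes, of which the exon-located subset reproduces the
#' published candidate composition (40 genes across the five categories).
#' Sequence emission is off at this scale.
#'
#' @param seed master seed.
#' @return a [sim_config()].
#' @export
preset_paper_scale <- function(seed = 1L) {
  sim_config(
    seed = seed, n_chroms = 22L, chrom_length = 1500000L,
    n_genes = 549L, n_x_genes = 5L, gap_range = c(14000L, 20000L),
    n_loci = 271L, dup_gene_frac = 0.2,
    planted_hieg_spec = paper_hieg_spec(),
    prey_plan = paper_prey_plan(),
    pond_counts = c(STR_CONTRACTION = 1465L, STR_EXPANSION = 4921L,
                    INSERTION = 11899L, DELETION = 5894L,
                    HCONDEL = 510L, HSD = 218L, INVERSION = 625L),
    decoy_len_ranges = list(HSD = c(5001L, 9000L),
                            INVERSION = c(9000L, 9900L)),
    n_flank_hits = 0L, emit_sequences = FALSE)
}

# Exon-located/unconditional plants mirroring the published candidate
# composition: 2 exon-gain, 8 indel, 4 STR, 1 HSD and 28 hCONDEL genes
# (32 hCONDELs), with three dual-category genes.
paper_hieg_spec <- function() {
  bind_rows(
    tibble(gene = 1:2, vtype = "EXON_GAIN", pclass = "CDS_EXON",
           also_str = FALSE, n = 1L),
    tibble(gene = 3L, vtype = "INSERTION", pclass = "NONCODING_EXON",
           also_str = FALSE, n = 1L),
    tibble(gene = 3L, vtype = "HCONDEL", pclass = "INTRON",
           also_str = FALSE, n = 2L),
    tibble(gene = 4L, vtype = "INSERTION", pclass = "UTR3",
           also_str = FALSE, n = 1L),
    tibble(gene = 4L, vtype = "HCONDEL", pclass = "INTRON",
           also_str = FALSE, n = 1L),
    tibble(gene = 5L, vtype = "INSERTION", pclass = "CDS_EXON",
           also_str = FALSE, n = 1L),
    tibble(gene = 6:9, vtype = "INSERTION", pclass = "NONCODING_EXON",
           also_str = FALSE, n = 1L),
    tibble(gene = 10L, vtype = "DELETION", pclass = "NONCODING_EXON",
           also_str = FALSE, n = 1L),
    tibble(gene = 11L, vtype = "INSERTION", pclass = "NONCODING_EXON",
           also_str = TRUE, n = 1L),
    tibble(gene = 12:13, vtype = "STR_EXPANSION",
           pclass = "NONCODING_EXON", also_str = FALSE, n = 1L),
    tibble(gene = 14L, vtype = "STR_CONTRACTION", pclass = "CDS_EXON",
           also_str = FALSE, n = 1L),
    tibble(gene = 15L, vtype = "HSD", pclass = "INTRON",
           also_str = FALSE, n = 1L),
    tibble(gene = 15L, vtype = "HCONDEL", pclass = "INTRON",
           also_str = FALSE, n = 1L),
    tibble(gene = 16:18, vtype = "HCONDEL", pclass = "INTRON",
           also_str = FALSE, n = 2L),
    tibble(gene = 19:40, vtype = "HCONDEL", pclass = "INTRON",
           also_str = FALSE, n = 1L))
}

paper_prey_plan <- function() {
  tibble(
    vtype = c("STR_CONTRACTION", "STR_EXPANSION", "INSERTION",
              "DELETION", "INVERSION"),
    n_genes = c(25L, 71L, 136L, 93L, 31L),
    n_vars = c(25L, 71L, 290L, 147L, 31L),
    gene_from = c(41L, 66L, 137L, 273L, 366L))
}

#' Write a simulated input bundle to disk
#'
#' Emits the files a real analysis would start from: a GFF3 annotation,
#' per-type pond TSVs, the lead-SNP TSV, expression matrices with sample
#' metadata, validation-case FASTA/metadata (when sequences were
#' generated), gene-span FASTA, and a ground-truth JSON.
#'
#' @param sim output of [simulate_inputs()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_gff3(sim$genome$human, p("genes_human.gff3"))
  write_gff3(sim$genome$ape, p("genes_ape.gff3"))
  for (vt in names(sim$pond_sources)) {
    write_table(sim$pond_sources[[vt]],
                p(paste0("pond_", tolower(vt), ".tsv")), "pond")
  }
  readr::write_tsv(sim$snps, p("lead_snps.tsv"), progress = FALSE)
  write_expression(sim$tpm, p("expression_tpm.tsv"),
                   p("expression_tpm_samples.tsv"))
  write_expression(sim$rpkm, p("expression_rpkm.tsv"),
                   p("expression_rpkm_samples.tsv"))
  if (!is.null(sim$genome$gene_seqs)) {
    write_fasta(sim$genome$gene_seqs, p("gene_spans.fasta"))
  }
  if (length(sim$validation_cases) > 0) {
    seqs <- list(); meta <- list()
    for (cs in sim$validation_cases) {
      seqs[[paste0(cs$var_id, "|human")]] <- cs$human_seq
      for (spn in names(cs$ape_seqs)) {
        seqs[[paste0(cs$var_id, "|", spn)]] <- cs$ape_seqs[[spn]]
      }
      if (!is.null(cs$ancestral_seq)) {
        seqs[[paste0(cs$var_id, "|ancestral")]] <- cs$ancestral_seq
      }
      meta[[cs$var_id]] <- tibble(
        var_id = cs$var_id, vtype = cs$vtype,
        insert_at = cs$insert_at %||na% NA_integer_,
        insert_len = cs$insert_len %||na% NA_integer_)
    }
    write_fasta(unlist(seqs), p("validation_cases.fasta"))
    readr::write_tsv(bind_rows(meta), p("validation_cases.tsv"),
                     progress = FALSE)
  }
  gt <- sim$ground_truth
  jsonlite::write_json(
    list(bait_symbols = gt$bait_symbols, x_symbols = gt$x_symbols,
         n_loci = gt$n_loci, prey = gt$prey,
         hieg_genes = gt$expected_hieg$genes,
         category_counts = as.list(gt$expected_hieg$category_counts),
         validation = gt$validation,
         expression = gt$expression[c("strongly_enriched",
                                      "mildly_enriched")]),
    p("ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

`%||na%` <- function(a, b) if (is.null(a)) b else a
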