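#' Generate pond files, lead-SNP tables and validation cases
#'
#' Plants the configured variations at their requested positional classes
#' inside the synthetic genes (verified against the annotation), surrounds
#' them with intergenic decoys placed at least 2 kb from any gene (so that
#' not even the 1-kb bucket method can reach them), writes a lead-SNP
#' table whose nearest-gene assignments produce exactly the intended bait
#' set, and constructs an ape sequence for every planted insertion or
#' deletion by applying the reverse edit to the human sequence.
#'
#' @param config a [sim_config()].
#' @param genome output of [make_genome()].
#' @return a list: `pond` (a `variation_pond`), `pond_sources` (per-type
#'   record tibbles), `snps` (lead-SNP tibble), `validation_cases`
#'   (list of [validation_case()]), `ground_truth`.
#' @export
make_pond_and_gwas <- function(config, genome) {
  old <- rng_snapshot()
  on.exit(rng_restore(old), add = TRUE)
  set.seed(sub_seed(config$seed, 2L))

  human <- genome$human
  auto <- human$genes[is_autosome(human$genes$chrom), ]
  symbols <- auto$symbol
  planted <- list()
  gt_prey <- list()

  # --- planted candidate-gene variations ---------------------------------
  spec <- config$planted_hieg_spec
  if (!is.null(spec) && nrow(spec) > 0) {
    if (!"n" %in% names(spec)) spec$n <- 1L
    spec <- tidyr::uncount(spec, weights = .data$n)
    if (any(spec$gene > length(symbols))) {
      abort("planted spec references a gene index beyond n_genes")
    }
    for (i in seq_len(nrow(spec))) {
      sym <- symbols[spec$gene[i]]
      pl <- place_variation(human, sym, spec$vtype[i], spec$pclass[i])
      vid <- sprintf("P_%s_%03d", spec$vtype[i], i)
      planted[[length(planted) + 1]] <- tibble(
        var_id = vid, chrom = auto$chrom[spec$gene[i]],
        start = pl$start, end = pl$end, vtype = spec$vtype[i],
        length_bp = pl$length_bp, source = "planted",
        also_str = isTRUE(spec$also_str[i]), validated = "pending")
      gt_prey[[length(gt_prey) + 1]] <- tibble(
        gene_symbol = sym, var_id = vid, vtype = spec$vtype[i],
        pclass = spec$pclass[i], also_str = isTRUE(spec$also_str[i]))
    }
  }

  # --- non-exonic prey variations (intronic / gene-spanning) -------------
  plan <- config$prey_plan
  if (!is.null(plan) && nrow(plan) > 0) {
    for (r in seq_len(nrow(plan))) {
      idx <- seq(plan$gene_from[r],
                 length.out = plan$n_genes[r])
      if (max(idx) > length(symbols)) {
        abort("prey plan references a gene index beyond n_genes")
      }
      carriers <- idx[((seq_len(plan$n_vars[r]) - 1L) %%
                         plan$n_genes[r]) + 1L]
      for (j in seq_along(carriers)) {
        sym <- symbols[carriers[j]]
        pcl <- if (plan$vtype[r] == "INVERSION") "CDS_EXON" else "INTRON"
        pl <- place_variation(human, sym, plan$vtype[r],
                              if (plan$vtype[r] == "INVERSION")
                                "SPANNING" else "INTRON")
        vid <- sprintf("Q_%s_%03d_%02d", plan$vtype[r], carriers[j], j)
        planted[[length(planted) + 1]] <- tibble(
          var_id = vid, chrom = auto$chrom[carriers[j]],
          start = pl$start, end = pl$end, vtype = plan$vtype[r],
          length_bp = pl$length_bp, source = "planted",
          also_str = FALSE, validated = "pending")
        gt_prey[[length(gt_prey) + 1]] <- tibble(
          gene_symbol = sym, var_id = vid, vtype = plan$vtype[r],
          pclass = pcl, also_str = FALSE)
      }
    }
  }

  # --- near-gene flank placements (bucket-only hits) ---------------------
  if (config$n_flank_hits > 0) {
    fl_idx <- seq(length(symbols), by = -1L,
                  length.out = config$n_flank_hits)
    for (j in seq_along(fl_idx)) {
      g <- auto[fl_idx[j], ]
      planted[[length(planted) + 1]] <- tibble(
        var_id = sprintf("F_INSERTION_%02d", j), chrom = g$chrom,
        start = g$end + 1L, end = g$end + 60L, vtype = "INSERTION",
        length_bp = 60L, source = "planted-flank", also_str = FALSE,
        validated = "pending")
    }
  }
  planted <- bind_rows(planted)
  if (nrow(planted) == 0) planted <- empty_pond_records()
  gt_prey <- bind_rows(gt_prey)
  if (nrow(gt_prey) == 0) {
    gt_prey <- tibble(gene_symbol = character(), var_id = character(),
                      vtype = character(), pclass = character(),
                      also_str = logical())
  }

  # --- intergenic decoys --------------------------------------------------
  gaps <- intergenic_gaps(human$genes, config$chrom_length, margin = 2000L)
  planted_by_type <- table(factor(planted$vtype, levels = VTYPES))
  decoys <- list()
  for (vt in names(config$pond_counts)) {
    n_decoy <- config$pond_counts[[vt]] -
      as.integer(planted_by_type[[vt]])
    if (n_decoy <= 0) next
    lr <- decoy_len_range(config, vt)
    lens <- sample(seq(lr[1], lr[2]), n_decoy, replace = TRUE)
    point <- vt %in% c("HCONDEL", "DELETION")
    pos <- sample_in_gaps(gaps, if (point) rep(1L, n_decoy) else lens)
    decoys[[vt]] <- tibble(
      var_id = sprintf("D_%s_%05d", vt, seq_len(n_decoy)),
      chrom = pos$chrom, start = pos$start,
      end = pos$start + if (point) 0L else lens - 1L,
      vtype = vt, length_bp = lens, source = "decoy",
      also_str = FALSE, validated = "pending")
  }
  records <- bind_rows(planted, bind_rows(decoys))
  pond_sources <- if (nrow(records) > 0) split(records, records$vtype)
    else list()
  pond <- build_pond(pond_sources)

  # --- lead SNPs ----------------------------------------------------------
  snps <- make_lead_snps(config, human)

  # --- validation cases by reverse edit ----------------------------------
  cases <- list()
  gt_val <- tibble(var_id = character(), true_specific = logical())
  if (isTRUE(config$emit_sequences)) {
    indels <- planted[planted$vtype %in% c("INSERTION", "DELETION") &
                        planted$source == "planted", ]
    n_false <- round(config$false_specific_frac * nrow(indels))
    false_idx <- if (n_false > 0) sample(nrow(indels), n_false) else
      integer()
    for (i in seq_len(nrow(indels))) {
      cases[[indels$var_id[i]]] <- reverse_edit_case(
        indels[i, ], flank_bp = config$flank_bp,
        false_specific = i %in% false_idx)
    }
    gt_val <- tibble(var_id = indels$var_id,
                     true_specific = !seq_len(nrow(indels)) %in% false_idx)
  }

  ground_truth <- list(
    bait_symbols = sort(symbols),
    x_symbols = sort(setdiff(human$genes$symbol, symbols)),
    n_loci = config$n_loci,
    prey = gt_prey,
    expected_hieg = expected_hiegs(gt_prey),
    validation = gt_val
  )
  list(pond = pond, pond_sources = pond_sources, snps = snps,
       validation_cases = cases, ground_truth = ground_truth)
}

# Expected candidate set implied by the planted records (generator-side
# bookkeeping mirroring the admission rule).
expected_hiegs <- function(gt_prey) {
  exonic <- gt_prey$pclass %in% c("CDS_EXON", "UTR5", "UTR3",
                                  "NONCODING_EXON")
  uncond <- gt_prey$vtype %in% c("HCONDEL", "HSD", "EXON_GAIN",
                                 "EXON_LOSS")
  adm <- gt_prey[(exonic & gt_prey$vtype != "INVERSION") | uncond, ]
  if (nrow(adm) == 0) {
    return(list(genes = character(),
                category_counts = setNames(integer(5), HIEG_CATEGORIES)))
  }
  adm$category <- dplyr::case_when(
    adm$vtype %in% c("EXON_GAIN", "EXON_LOSS") ~ "EXON_GAIN_LOSS",
    adm$vtype == "HCONDEL" ~ "HCONDEL",
    adm$vtype == "HSD" ~ "HSD",
    adm$vtype %in% c("STR_CONTRACTION", "STR_EXPANSION") |
      adm$also_str ~ "STR",
    TRUE ~ "INDEL")
  list(genes = sort(unique(adm$gene_symbol)),
       category_counts = count_categories(
         distinct(adm, .data$gene_symbol, .data$category)),
       by_gene = adm %>%
         group_by(.data$gene_symbol) %>%
         summarise(categories = paste(intersect(HIEG_CATEGORIES,
                                                unique(.data$category)),
                                      collapse = ";"), .groups = "drop"))
}

# Candidate placement region of a gene for a requested positional class.
region_for <- function(models, sym, pclass) {
  tx <- models$transcripts
  p <- tx[tx$gene_symbol == sym & tx$principal &
            tx$species == "human", ][1, ]
  pex <- exs_of(models, p$transcript_id)
  g <- models$genes[models$genes$symbol == sym, ][1, ]
  n <- nrow(pex)
  switch(pclass,
    CDS_EXON = c(max(pex$start[2], p$cds_start),
                 min(pex$end[2], p$cds_end)),
    UTR5 = if (g$strand == "+") c(pex$start[1], p$cds_start - 1L) else
      c(p$cds_end + 1L, pex$end[n]),
    UTR3 = if (g$strand == "+") c(p$cds_end + 1L, pex$end[n]) else
      c(pex$start[1], p$cds_start - 1L),
    NONCODING_EXON = {
      nc <- exs_of(models, paste0(sym, ".t2"))
      c(nc$start[1], nc$end[1])
    },
    INTRON = c(pex$end[1] + 50L, pex$start[2] - 50L),
    abort(paste0("no placement region for positional class ", pclass))
  )
}

place_variation <- function(models, sym, vtype, pclass) {
  g <- models$genes[models$genes$symbol == sym, ][1, ]
  if (pclass == "SPANNING") {   # inversion containing the whole gene
    s <- g$start - sample(500:1500, 1)
    e <- g$end + sample(500:1500, 1)
    return(list(start = max(1L, as.integer(s)), end = as.integer(e),
                length_bp = span_length(max(1L, as.integer(s)),
                                        as.integer(e))))
  }
  if (vtype == "EXON_GAIN") {
    pex <- exs_of(models, paste0(sym, ".t1"))
    vex <- exs_of(models, paste0(sym, ".t3"))
    gained <- vex[!vex$start %in% pex$start, ][1, ]
    return(list(start = gained$start, end = gained$end,
                length_bp = span_length(gained$start, gained$end)))
  }
  reg <- region_for(models, sym, pclass)
  w <- reg[2] - reg[1] + 1L
  if (w < 3) abort(paste0("generation error: positional class ", pclass,
                          " unattainable in gene ", sym))
  if (vtype %in% c("HCONDEL", "DELETION")) {
    pos <- reg[1] + sample.int(w, 1) - 1L
    return(list(start = pos, end = pos,
                length_bp = sample(if (vtype == "DELETION") 100:3000 else
                  100:4000, 1)))
  }
  if (vtype == "HSD") {
    # span may extend past the gene ends but stays 2 kb clear of neighbours
    lo <- max(1L, g$start - 2000L)
    hi <- g$end + 2000L
    len <- sample(6000:min(12000L, hi - lo + 1L), 1)
    s <- lo + sample.int(hi - lo - len + 2L, 1) - 1L
    return(list(start = s, end = s + len - 1L, length_bp = len))
  }
  max_len <- min(if (vtype %in% c("STR_CONTRACTION", "STR_EXPANSION"))
    80L else 90L, w - 2L)
  if (max_len < 51L) {
    abort(paste0("generation error: region too narrow for ", vtype,
                 " in gene ", sym))
  }
  len <- sample(51:max_len, 1)
  s <- reg[1] + sample.int(w - len, 1) - 1L
  list(start = s, end = s + len - 1L, length_bp = len)
}

decoy_len_range <- function(config, vt) {
  r <- config$decoy_len_ranges
  if (!is.null(r) && vt %in% names(r)) return(r[[vt]])
  switch(vt,
    STR_CONTRACTION = c(30L, 80L), STR_EXPANSION = c(30L, 80L),
    INSERTION = c(51L, 800L), DELETION = c(51L, 800L),
    HCONDEL = c(100L, 3000L), HSD = c(1200L, 1800L),
    INVERSION = c(1000L, 1800L),
    c(51L, 200L))
}

intergenic_gaps <- function(genes, chrom_length, margin = 2000L) {
  if (nrow(genes) == 0) {
    return(tibble(chrom = character(), lo = integer(), hi = integer()))
  }
  purrr::map(split(genes, genes$chrom), function(g) {
    g <- arrange(g, .data$start)
    lo <- c(1L, g$end + margin + 1L)
    hi <- c(g$start - margin - 1L, chrom_length)
    tibble(chrom = g$chrom[1], lo = lo, hi = hi)
  }) %>%
    bind_rows() %>%
    filter(.data$hi - .data$lo >= 100L)
}

# Sample decoy start positions; only gaps wide enough for the longest
# requested span are eligible, so no decoy can leak into the 2-kb margin.
sample_in_gaps <- function(gaps, span_lens) {
  n <- length(span_lens)
  eligible <- gaps[gaps$hi - gaps$lo + 1L >= max(span_lens) + 2L, ]
  if (nrow(eligible) == 0) {
    abort("config error: no intergenic gap wide enough for decoys")
  }
  w <- eligible$hi - eligible$lo + 1L
  idx <- sample.int(nrow(eligible), n, replace = TRUE, prob = w)
  start <- as.integer(eligible$lo[idx] +
                        floor(runif(n) * (w[idx] - span_lens)))
  list(chrom = eligible$chrom[idx], start = start)
}

make_lead_snps <- function(config, human) {
  auto <- human$genes[is_autosome(human$genes$chrom), ]
  xg <- human$genes[!is_autosome(human$genes$chrom), ]
  studies <- gwas_studies()
  n <- nrow(auto)
  locus_sizes <- diff(floor(seq(0, n, length.out = config$n_loci + 1L)))
  locus_id <- sprintf("L%03d", rep(seq_len(config$n_loci), locus_sizes))
  snps <- tibble(
    rsid = sprintf("rs%06d", 100000L + seq_len(n)),
    chrom = auto$chrom,
    pos = auto$start + 123L,
    study = studies$study_id[((seq_len(n) - 1L) %% nrow(studies)) + 1L],
    p = 10^-stats::runif(n, 8, 15),
    nearest_gene = auto$symbol,
    locus_id = locus_id)
  k <- round(config$dup_gene_frac * n)
  if (k > 0) {   # the same gene reported by a second study
    dup <- snps[seq_len(k), ] %>%
      mutate(rsid = sprintf("rs%06d", 200000L + seq_len(k)),
             pos = .data$pos + 1000L,
             study = studies$study_id[((seq_len(k)) %% nrow(studies)) + 1L])
    snps <- bind_rows(snps, dup)
  }
  if (nrow(xg) > 0) {
    snps <- bind_rows(snps, tibble(
      rsid = sprintf("rs%06d", 300000L + seq_len(nrow(xg))),
      chrom = xg$chrom, pos = xg$start + 123L,
      study = studies$study_id[2],
      p = 10^-stats::runif(nrow(xg), 8, 15),
      nearest_gene = xg$symbol,
      locus_id = sprintf("LX%02d", seq_len(nrow(xg)))))
  }
  snps
}

#' The six source GWAS of the bait set
#'
#' @return tibble of study tags, sample sizes and phenotypes emulating the
#'   integrated GWAS panel.
#' @export
gwas_studies <- function() {
  tibble(
    study_id = paste0("S", 1:6),
    n = c(53949L, 112151L, 78308L, 35298L, 1238L, 269867L),
    phenotype = c("general cognitive function",
                  "cognitive function and educational attainment",
                  "fluid intelligence (Spearman g)",
                  "cognition meta-analysis, 24 cohorts",
                  "extremely high intelligence",
                  "intelligence meta-analysis, 14 cohorts"))
}

# Human/ape sequence pair for one planted indel, by reverse edit.
reverse_edit_case <- function(rec, flank_bp = 500L,
                              false_specific = FALSE) {
  seg_len <- max(60L, min(rec$length_bp, 2000L))
  seg <- rand_dna(seg_len)
  left <- rand_dna(flank_bp + 100L)
  right <- rand_dna(flank_bp + 100L)
  apes <- c("chimpanzee", "gorilla", "orangutan")
  if (rec$vtype == "INSERTION") {
    human <- paste0(left, seg, right)
    ape <- if (false_specific) human else paste0(left, right)
    validation_case(rec$var_id, "INSERTION", human,
                    setNames(as.list(rep(ape, 3)), apes),
                    insert_at = nchar(left) + 1L, insert_len = seg_len,
                    flank_bp = flank_bp)
  } else {
    human <- paste0(left, right)
    ape <- if (false_specific) human else paste0(left, seg, right)
    validation_case(rec$var_id, "DELETION", human,
                    setNames(as.list(rep(ape, 3)), apes),
                    ancestral_seq = seg, flank_bp = flank_bp)
  }
}

#' Construct a labelled panel of validation cases
#'
#' Builds `n_true` genuinely human-specific cases (the ape lacks the
#' inserted segment, or carries the deleted one) and `n_false` cases in
#' which the ape matches the human state, alternating insertions and
#' deletions; used to measure validator sensitivity and specificity.
#'
#' @param n_true,n_false panel composition.
#' @param seed RNG seed.
#' @param flank_bp flank length per side.
#' @param seg_len segment length in bp.
#' @return a list with `cases` (list of [validation_case()]) and `truth`
#'   (tibble `var_id`, `true_specific`).
#' @export
build_validation_panel <- function(n_true = 50L, n_false = 50L, seed = 1L,
                                   flank_bp = 500L, seg_len = 150L) {
  old <- rng_snapshot()
  on.exit(rng_restore(old), add = TRUE)
  set.seed(sub_seed(seed, 4L))
  n <- n_true + n_false
  truth <- tibble(
    var_id = sprintf("V%03d", seq_len(n)),
    vtype = rep(c("INSERTION", "DELETION"), length.out = n),
    true_specific = rep(c(TRUE, FALSE), times = c(n_true, n_false)))
  cases <- purrr::pmap(truth, function(var_id, vtype, true_specific) {
    reverse_edit_case(
      tibble(var_id = var_id, vtype = vtype, length_bp = seg_len),
      flank_bp = flank_bp, false_specific = !true_specific)
  })
  list(cases = setNames(cases, truth$var_id),
       truth = truth[, c("var_id", "true_specific")])
}
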