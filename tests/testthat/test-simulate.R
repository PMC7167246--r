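test_that("generation is deterministic per seed with independent streams", {
  g1 <- make_genome(sim_config(seed = 2))
  g2 <- make_genome(sim_config(seed = 2))
  expect_identical(g1$human$genes, g2$human$genes)
  expect_identical(g1$human$exons, g2$human$exons)
  expect_false(identical(g1$human$genes,
                         make_genome(sim_config(seed = 3))$human$genes))
  # changing expression parameters leaves the genome untouched
  cfg_a <- sim_config(seed = 2)
  cfg_b <- sim_config(seed = 2,
                      expression = expression_config(noise_sd = 0.9))
  expect_identical(make_genome(cfg_a)$human$genes,
                   make_genome(cfg_b)$human$genes)
})

test_that("generated gene models satisfy the structural invariants", {
  g <- make_genome(sim_config(seed = 4))
  m <- g$human
  expect_s3_class(m, "gene_models")   # constructor enforces invariants
  expect_true(all(m$transcripts$gene_symbol %in% m$genes$symbol))
  by_gene <- table(m$transcripts$gene_symbol[m$transcripts$principal])
  expect_true(all(by_gene == 1L))     # one flagged principal isoform each
  nc <- m$transcripts[m$transcripts$biotype == "processed_transcript", ]
  expect_true(all(is.na(nc$cds_start)))
  # infeasible packing is refused
  expect_error(make_genome(sim_config(seed = 1, chrom_length = 30000L)),
               "infeasible packing")
})

test_that("generated tables all parse back through the typed readers", {
  dir <- withr::local_tempdir()
  sim <- simulate_inputs(sim_config(seed = 6))
  write_simulation(sim, dir)
  for (f in list.files(dir, pattern = "^pond_.*tsv$", full.names = TRUE)) {
    expect_silent(read_table(f, "pond"))
  }
  snps <- read_table(file.path(dir, "lead_snps.tsv"), "lead_snp")
  expect_identical(nrow(snps), nrow(sim$snps))
  models <- read_gff3(file.path(dir, "genes_human.gff3"))
  expect_identical(models$genes$symbol, sim$genome$human$genes$symbol)
  expect_identical(
    dplyr::arrange(models$exons, transcript_id, start),
    dplyr::arrange(sim$genome$human$exons, transcript_id, start))
  em <- read_expression(file.path(dir, "expression_tpm.tsv"),
                        file.path(dir, "expression_tpm_samples.tsv"),
                        "TPM")
  expect_equal(em$values, sim$tpm$values)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_identical(length(gt$bait_symbols),
                   length(sim$ground_truth$bait_symbols))
})

test_that("planted exonic variations land in their requested class", {
  sim <- simulate_inputs(sim_config(seed = 10))
  res <- suppressMessages(run_pipeline(sim))
  gt <- sim$ground_truth$prey
  planted <- gt[gt$pclass != "INTRON", ]
  calls <- res$calls[match(planted$var_id, res$calls$var_id), ]
  expect_identical(calls$pclass, planted$pclass)
})

test_that("zero pond counts give an empty pond and zero genes an empty annotation", {
  cfg <- sim_config(seed = 1, pond_counts = integer(0),
                    planted_hieg_spec = NULL, prey_plan = NULL,
                    n_flank_hits = 0L)
  sim <- simulate_inputs(cfg)
  expect_identical(nrow(sim$pond$records), 0L)
  dir <- withr::local_tempdir()
  g0 <- make_genome(sim_config(seed = 1, n_genes = 0L, n_x_genes = 0L,
                               planted_hieg_spec = NULL,
                               prey_plan = NULL))
  write_gff3(g0$human, file.path(dir, "empty.gff3"))
  expect_identical(readLines(file.path(dir, "empty.gff3")),
                   "##gff-version 3")
})

test_that("the full pipeline recovers the planted truth at zero noise", {
  for (seed in c(3, 14)) {
    sim <- simulate_inputs(sim_config(
      seed = seed, expression = expression_config(noise_sd = 0)))
    res <- suppressMessages(run_pipeline(sim))
    gt <- sim$ground_truth
    expect_identical(sort(res$bait$symbol), gt$bait_symbols)
    expect_false(any(gt$x_symbols %in% res$bait$symbol))
    wg <- res$prey[res$prey$within_gene, c("gene_symbol", "var_id")]
    expect_identical(
      dplyr::arrange(wg, gene_symbol, var_id),
      dplyr::arrange(gt$prey[, c("gene_symbol", "var_id")],
                     gene_symbol, var_id))
    expect_identical(sort(res$hiegs$gene_symbol), gt$expected_hieg$genes)
    expect_identical(res$category_counts,
                     gt$expected_hieg$category_counts)
  }
})

test_that("false-specific validation cases are the ones rejected", {
  sim <- simulate_inputs(sim_config(seed = 8, false_specific_frac = 0.4))
  truth <- sim$ground_truth$validation
  expect_gt(sum(!truth$true_specific), 0L)
  verdicts <- vapply(sim$validation_cases[truth$var_id], function(cs)
    validate_variation(cs)$verdict, character(1))
  expect_identical(unname(verdicts == "validated"), truth$true_specific)
})
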