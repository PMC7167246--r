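panel_matrix <- function(values, tissues = NULL) {
  n <- ncol(values)
  tissues <- tissues %||% c("cerebral cortex", paste0("tissue", 2:n))
  colnames(values) <- tissues
  expr_matrix(values,
              tibble::tibble(sample = tissues, tissue = tissues,
                             species = "human",
                             region_class = ifelse(
                               tissues == "cerebral cortex", "neocortex",
                               "non_brain")),
              "TPM")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("cortex enrichment ratio and flags follow the arithmetic", {
  # gene "up": cortex 10 with a panel mean of 4 gives ratio 2.5
  vals <- rbind(up = c(10, rep((4 * 37 - 10) / 36, 36)),
                flat = rep(3, 37))
  em <- panel_matrix(vals)
  res <- cortex_enrichment(em)
  up <- res[res$gene_symbol == "up", ]
  expect_equal(up$ratio, 2.5)
  expect_true(up$strongly_enriched)
  flat <- res[res$gene_symbol == "flat", ]
  expect_equal(flat$ratio, 1.0)
  expect_false(flat$enriched)
  # ratio is invariant under rescaling a gene's row
  em2 <- panel_matrix(vals * 100)
  expect_equal(cortex_enrichment(em2)$ratio, res$ratio)
  expect_error(cortex_enrichment(panel_matrix(vals,
                                              paste0("t", 1:37))),
               "configuration error")
})

test_that("zero-noise planted cortex effects are recovered exactly", {
  sim <- simulate_inputs(sim_config(
    seed = 21, expression = expression_config(noise_sd = 0)))
  res <- cortex_enrichment(sim$tpm)
  gt <- sim$ground_truth$expression
  expect_identical(sort(res$gene_symbol[res$strongly_enriched]),
                   sort(gt$strongly_enriched))
  expect_identical(sort(res$gene_symbol[res$enriched]),
                   sort(gt$enriched))
  # sorted by descending ratio with the planted strong set on top
  expect_identical(sort(res$gene_symbol[seq_along(gt$strongly_enriched)]),
                   sort(gt$strongly_enriched))
})

test_that("relative isoform expression is a plain percentage with a guarded zero", {
  expect_equal(isoform_relative_expression(2.1, 10), 21)
  expect_equal(isoform_relative_expression(0, 10), 0)
  expect_warning(out <- isoform_relative_expression(c(1, 2), c(4, 0)),
                 "undefined")
  expect_equal(out, c(25, NA_real_))
  # planted ~21% ratio under log-normal noise averages back to ~21
  set.seed(33)
  principal <- exp(rnorm(10, log(10), 0.05))
  variant <- exp(rnorm(10, log(2.1), 0.05))
  est <- mean(isoform_relative_expression(variant, principal))
  expect_gt(est, 18)
  expect_lt(est, 24)
})

test_that("cross-species fold changes pool non-focal neocortex means", {
  vals <- matrix(c(2, 2, 4, 4, 8, 1), nrow = 1,
                 dimnames = list("g", paste0("s", 1:6)))
  meta <- tibble::tibble(
    sample = paste0("s", 1:6),
    tissue = c("ACC", "DPFC", "ACC", "DPFC", "ACC", "CB"),
    species = c("human", "human", "chimpanzee", "chimpanzee", "gorilla",
                "gorilla"),
    region_class = c(rep("neocortex", 5), "non_neocortex"))
  em <- expr_matrix(vals, meta, "RPKM")
  fc <- cross_species_neocortex_fc(em)
  expect_equal(fc$fold_change, 2 / mean(c(4, 4, 8)))
  # reciprocity: focal/other times other/focal is one
  vals2 <- matrix(c(2, 4), nrow = 1, dimnames = list("g", c("h", "c")))
  em2 <- expr_matrix(vals2, tibble::tibble(
    sample = c("h", "c"), tissue = "ACC",
    species = c("human", "chimpanzee"),
    region_class = "neocortex"), "RPKM")
  expect_equal(cross_species_neocortex_fc(em2)$fold_change, 0.5)
  expect_equal(cross_species_neocortex_fc(em2, "chimpanzee")$fold_change,
               2)
})

test_that("planted fold changes are exact at zero noise and reciprocal", {
  sim <- simulate_inputs(sim_config(
    seed = 5, expression = expression_config(noise_sd = 0)))
  fc <- cross_species_neocortex_fc(sim$rpkm)
  gt <- sim$ground_truth$expression$fold_changes
  got <- fc$fold_change[match(gt$gene_symbol, fc$gene_symbol)]
  expect_equal(got, gt$fold_change, tolerance = 1e-12)
})

test_that("clustering recovers planted species clades and is order-invariant", {
  sim <- simulate_inputs(sim_config(seed = 17))
  cl <- cluster_samples(sim$rpkm)
  neo <- cl$clade_report[cl$clade_report$kind == "species_neocortex", ]
  expect_identical(nrow(neo), 4L)
  expect_true(all(neo$monophyletic))
  tis <- cl$clade_report[cl$clade_report$kind == "tissue_across_species", ]
  expect_true(all(tis$monophyletic))
  expect_equal(neocortex_clade_purity(sim$rpkm), 1.0)
  # permutation invariance up to the sample-label tie-break
  perm <- sample(ncol(sim$rpkm$values))
  em_perm <- expr_matrix(sim$rpkm$values[, perm],
                         sim$rpkm$samples[perm, ], "RPKM")
  cl2 <- cluster_samples(em_perm)
  expect_identical(cl2$hclust$merge, cl$hclust$merge)
  expect_identical(cl2$clade_report, cl$clade_report)
})

test_that("degenerate and duplicated samples are handled deterministically", {
  vals <- matrix(c(1, 2, 3, 1, 2, 3, 2, 4, 8), nrow = 3,
                 dimnames = list(paste0("g", 1:3), c("a", "b", "c")))
  meta <- tibble::tibble(sample = c("a", "b", "c"), tissue = "ACC",
                         species = c("x", "x", "y"),
                         region_class = "neocortex")
  em <- expr_matrix(vals, meta, "RPKM")
  cl <- cluster_samples(em)
  # the duplicated pair sits at distance zero and merges first
  expect_identical(sort(cl$hclust$merge[1, ]), c(-2L, -1L))
  expect_equal(cl$hclust$height[1], 0)
  # all-identical samples: deterministic tree, degenerate report
  same <- matrix(rep(c(1, 5, 2), 3), nrow = 3,
                 dimnames = list(paste0("g", 1:3), c("a", "b", "c")))
  cls <- cluster_samples(expr_matrix(same, meta, "RPKM"))
  expect_true(cls$degenerate)
  expect_true(all(is.na(cls$clade_report$monophyletic)))
})
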