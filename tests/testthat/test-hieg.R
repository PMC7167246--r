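classify_toy <- function(start, end, strand = "+", within_gene = TRUE,
                         vtype = "INSERTION") {
  models <- toy_gene_models(strand)
  pond <- toy_pond_records("v", start, end, vtype = vtype)
  prey <- toy_prey("v", within_gene = within_gene)
  prey$vtype <- vtype
  classify_positions(prey, pond, models)
}

test_that("positional classes follow the precedence across isoforms", {
  # inside a coding exon clipped by the CDS
  expect_identical(classify_toy(2100L, 2160L)$pclass, "CDS_EXON")
  # terminal-exon bases before the CDS start: 5' UTR on +, 3' UTR on -
  expect_identical(classify_toy(1050L, 1100L)$pclass, "UTR5")
  expect_identical(classify_toy(1050L, 1100L, strand = "-")$pclass, "UTR3")
  expect_identical(classify_toy(4850L, 4900L)$pclass, "UTR3")
  # the processed transcript's private exon
  expect_identical(classify_toy(3150L, 3220L)$pclass, "NONCODING_EXON")
  # wholly between exons of every isoform
  call <- classify_toy(1600L, 1700L)
  expect_identical(call$pclass, "INTRON")
  expect_identical(call$nearest_exon_distance, 100L)
  # bucket-only hit outside the exact span
  expect_identical(classify_toy(5100L, 5160L,
                                within_gene = FALSE)$pclass, "FLANK")
  # a span straddling intron and coding exon takes the top class
  expect_identical(classify_toy(1900L, 2050L)$pclass, "CDS_EXON")
})

test_that("every overlapping variation receives exactly one class", {
  models <- toy_gene_models()
  set.seed(8)
  starts <- sample(900:5100, 60)
  pond <- toy_pond_records(sprintf("v%02d", 1:60), starts,
                           starts + sample(10:400, 60, replace = TRUE))
  within <- pond$start <= 5000L & pond$end >= 1000L
  prey <- toy_prey(pond$var_id, within_gene = within)
  calls <- classify_positions(prey, pond, models)
  expect_identical(nrow(calls), 60L)
  expect_true(all(calls$pclass %in% c("CDS_EXON", "UTR5", "UTR3",
                                      "NONCODING_EXON", "INTRON",
                                      "FLANK")))
  expect_true(all(calls$pclass[!calls$within_gene] == "FLANK"))
  expect_true(all(calls$nearest_exon_distance >= 0))
})

test_that("exon gain is a human exon matching no ape exon, and is antisymmetric", {
  exon_seqs <- function(n, len, seed) {
    set.seed(seed)
    vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = ""), character(1))
  }
  shared <- exon_seqs(4, 150, 31)
  gained <- exon_seqs(1, 60, 32)
  human <- tibble::tibble(
    transcript_id = c(rep("H.t1", 4), rep("H.t2", 5)),
    exon_rank = c(1:4, 1:5),
    seq = c(shared, shared[1:2], gained, shared[3:4]))
  ape <- tibble::tibble(
    species = "chimpanzee", transcript_id = "C.t1", exon_rank = 1:4,
    seq = shared)
  ev <- detect_exon_gain_loss("PCCB_LIKE", human, ape)
  expect_identical(ev$event, "EXON_GAIN")
  expect_identical(ev$length_bp, 60L)
  # swapping the species roles turns the gain into a loss
  human_as_ape <- dplyr::mutate(human, species = "human")
  rev <- detect_exon_gain_loss("PCCB_LIKE",
                               ape[, c("transcript_id", "exon_rank",
                                       "seq")],
                               human_as_ape)
  expect_identical(rev$event, "EXON_LOSS")
  expect_identical(rev$length_bp, 60L)
  # identical exon sets: no events
  none <- detect_exon_gain_loss(
    "SAME", human, dplyr::mutate(human, species = "gorilla"))
  expect_identical(nrow(none), 0L)
  # missing sequence errors name the transcript
  broken <- human
  broken$seq[2] <- NA_character_
  expect_error(detect_exon_gain_loss("X", broken, ape), "H.t1")
})

test_that("the exon-gain generator plants events the detector recovers", {
  sim <- simulate_inputs(sim_config(seed = 9))
  es <- sim$genome$exon_seqs
  sym <- sub("\\..*", "", es$transcript_id[1])
  human <- es[es$species == "human", c("transcript_id", "exon_rank",
                                       "seq")]
  ape <- es[es$species != "human", ]
  ev <- detect_exon_gain_loss(sym, human, ape)
  expect_identical(ev$event, "EXON_GAIN")
  expect_identical(ev$length_bp, 60L)
})

test_that("candidate selection reproduces the fixture's accounting rules", {
  sel <- table1_hieg_selection()
  expect_identical(nrow(sel$hiegs), 40L)
  # the flagged dual-identity insertion counts as STR, not INDEL
  arih2 <- sel$hiegs[sel$hiegs$gene_symbol == "ARIH2", ]
  expect_identical(arih2$categories, "STR")
  # intronic hCONDELs admit their genes despite the position
  kdm4a <- sel$hiegs[sel$hiegs$gene_symbol == "KDM4A", ]
  expect_match(kdm4a$admit_rule, "regardless of position")
  # category gene-count identity: slots = unique genes + dual genes
  n_dual <- sum(grepl(";", sel$hiegs$categories))
  expect_identical(sum(sel$category_counts),
                   nrow(sel$hiegs) + n_dual)
})

test_that("purely intronic indels select no candidates", {
  calls <- tibble::tibble(
    gene_symbol = c("A", "B"), var_id = c("v1", "v2"),
    vtype = "INSERTION", pclass = "INTRON", also_str = FALSE)
  sel <- select_hiegs(calls)
  expect_identical(nrow(sel$hiegs), 0L)
  expect_true(all(sel$category_counts == 0L))
  expect_error(select_hiegs(calls, genes = "A"), "unknown gene")
})

test_that("exon-covering inversions never admit a candidate", {
  calls <- tibble::tibble(
    gene_symbol = "A", var_id = "inv1", vtype = "INVERSION",
    pclass = "CDS_EXON", also_str = FALSE)
  expect_identical(nrow(select_hiegs(calls)$hiegs), 0L)
})

test_that("inversion breakpoint audit distinguishes inside from breakpoint", {
  genes <- tibble::tibble(
    symbol = c("IN", "BP", "OUT"), chrom = "1",
    start = c(150000L, 95000L, 300000L),
    end = c(160000L, 105000L, 310000L))
  inv <- toy_pond_records("inv1", 100000L, 200000L, vtype = "INVERSION")
  audit <- check_inversion_breakpoints(inv, genes)
  expect_identical(audit$status[audit$gene_symbol == "IN"], "inside")
  expect_identical(audit$status[audit$gene_symbol == "BP"],
                   "at_breakpoint")
  expect_identical(audit$status[audit$gene_symbol == "OUT"], "outside")
})

test_that("generator-planted inversions keep their genes clear of breakpoints", {
  sim <- simulate_inputs(sim_config(seed = 13))
  bait <- suppressMessages(exclude_sex_chromosomes(
    integrate_bait_genes(sim$snps, sim$genome$human)))
  audit <- check_inversion_breakpoints(sim$pond, bait)
  inv_genes <- unique(sim$ground_truth$prey$gene_symbol[
    sim$ground_truth$prey$vtype == "INVERSION"])
  hit <- audit[audit$gene_symbol %in% inv_genes & !is.na(audit$var_id), ]
  expect_true(all(hit$status == "inside"))
  expect_identical(sum(audit$status == "at_breakpoint"), 0L)
})
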