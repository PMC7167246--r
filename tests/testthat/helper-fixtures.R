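# Hand-built two-isoform gene for classifier tests: plus-strand coding
# isoform with three exons (UTRs in the terminal exons) and a processed
# transcript with one exon private to intron 2.
toy_gene_models <- function(strand = "+") {
  gene_models(
    genes = tibble::tibble(symbol = "TOY", chrom = "1", start = 1000L,
                           end = 5000L, strand = strand,
                           species = "human"),
    transcripts = tibble::tibble(
      transcript_id = c("TOY.t1", "TOY.t2"),
      gene_symbol = "TOY", species = "human",
      biotype = c("protein_coding", "processed_transcript"),
      principal = c(TRUE, FALSE),
      cds_start = c(1200L, NA), cds_end = c(4800L, NA)),
    exons = tibble::tibble(
      transcript_id = c("TOY.t1", "TOY.t1", "TOY.t1", "TOY.t2"),
      start = c(1000L, 2000L, 4500L, 3100L),
      end = c(1500L, 2400L, 5000L, 3300L),
      exon_rank = c(1L, 2L, 3L, 1L)))
}

toy_prey <- function(var_id, within_gene = TRUE) {
  tibble::tibble(gene_symbol = "TOY", var_id = var_id, vtype = "INSERTION",
                 method = "kb_bucket", within_gene = within_gene)
}

toy_pond_records <- function(var_id, start, end, vtype = "INSERTION",
                             also_str = FALSE) {
  tibble::tibble(var_id = var_id, chrom = "1", start = start, end = end,
                 vtype = vtype, length_bp = end - start + 1L,
                 source = "test", also_str = also_str,
                 validated = "pending")
}

# Brute-force interval-overlap oracle, independent of the package's
# GenomicRanges / bucket implementations.
brute_force_overlap <- function(vars, genes) {
  out <- list()
  for (i in seq_len(nrow(vars))) {
    for (j in seq_len(nrow(genes))) {
      if (vars$chrom[i] == genes$chrom[j] &&
          vars$start[i] <= genes$end[j] &&
          genes$start[j] <= vars$end[i]) {
        out[[length(out) + 1]] <- data.frame(
          gene_symbol = genes$symbol[j], var_id = vars$var_id[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(gene_symbol = character(), var_id = character()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$gene_symbol, res$var_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Random pond + gene set on a small genome for overlap property tests.
random_overlap_instance <- function(seed, n_genes = 100, n_vars = 500,
                                    genome_bp = 2e6, n_chroms = 2) {
  set.seed(seed)
  genes <- tibble::tibble(
    symbol = sprintf("R%03d", seq_len(n_genes)),
    chrom = as.character(sample(n_chroms, n_genes, replace = TRUE)),
    start = sample.int(genome_bp - 20000, n_genes))
  genes$end <- genes$start + sample(500:15000, n_genes, replace = TRUE)
  vstart <- sample.int(genome_bp, n_vars)
  vars <- tibble::tibble(
    var_id = sprintf("v%04d", seq_len(n_vars)),
    chrom = as.character(sample(n_chroms, n_vars, replace = TRUE)),
    start = vstart,
    end = vstart + sample(0:3000, n_vars, replace = TRUE),
    vtype = sample(c("INSERTION", "DELETION", "HCONDEL"), n_vars,
                   replace = TRUE))
  vars$length_bp <- vars$end - vars$start + 1L
  list(genes = genes, vars = vars)
}

expect_no_difference <- function(a, b) {
  expect_identical(as.data.frame(a), as.data.frame(b))
}
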