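test_that("BED coordinates convert to 1-based inclusive spans", {
  conv <- bed_to_one_based(48968204, 48968380)
  expect_identical(conv$start, 48968205L)
  expect_identical(conv$end, 48968380L)
  expect_identical(span_length(conv$start, conv$end), 176L)
  expect_identical(normalize_chrom(c("chr3", "3", "chrX")),
                   c("3", "3", "X"))
  expect_identical(is_autosome(c("1", "22", "X", "chr5")),
                   c(TRUE, TRUE, FALSE, TRUE))
})

test_that("pipeline tables round-trip through read/write for every schema", {
  dir <- withr::local_tempdir()
  fixtures <- list(
    lead_snp = tibble::tibble(
      rsid = c("rs1", "rs2"), chrom = c("1", "2"), pos = c(100L, 200L),
      study = c("S1", "S2"), p = c(1e-9, 1e-12),
      nearest_gene = c("A", "B"), locus_id = c("L1", "L2")),
    bait = tibble::tibble(
      symbol = c("A", "B"), chrom = c("1", "2"), start = c(10L, 20L),
      end = c(100L, 200L), sources = c("S1", "S1;S2"),
      lead_snps = c("rs1", "rs2;rs3")),
    pond = toy_pond_records(c("v1", "v2"), c(5L, 50L), c(60L, 120L)),
    prey = tibble::tibble(
      gene_symbol = "A", var_id = "v1", vtype = "INSERTION",
      method = "kb_bucket", within_gene = TRUE),
    hieg = tibble::tibble(
      gene_symbol = "A", variations = "v1;v2", categories = "INDEL;STR",
      admit_rule = "exon-located insertion"))
  for (schema in names(fixtures)) {
    path <- file.path(dir, paste0(schema, ".tsv"))
    write_table(fixtures[[schema]], path, schema)
    expect_identical(as.data.frame(read_table(path, schema)),
                     as.data.frame(fixtures[[schema]]),
                     info = schema)
  }
})

test_that("header-only files read as empty record lists", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "empty.tsv")
  write_table(toy_pond_records(character(), integer(), integer())[0, ],
              path, "pond")
  out <- read_table(path, "pond")
  expect_identical(nrow(out), 0L)
  expect_named(out, c("var_id", "chrom", "start", "end", "vtype",
                      "length_bp", "source", "also_str", "validated"))
})

test_that("schema violations are reported with line numbers", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "bad.tsv")
  writeLines(c("var_id\tchrom\tstart\tend\tvtype\tlength_bp",
               "v1\t1\t100\t50\tINSERTION\t60",
               "v2\t1\t10\t20\tWIBBLE\t11"), path)
  expect_error(read_table(path, "pond"), "line 2")
  expect_error(read_table(path, "pond"), "line 3")
  writeLines(c("var_id\tchrom\tstart", "v1\t1\t10"), path)
  expect_error(read_table(path, "pond"), "missing column")
})

test_that("BED pond input converts the half-open convention on read", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "strs.bed")
  writeLines(c("chr3\t48968204\t48968380\tstr1"), path)
  rec <- read_pond_bed(path, "STR_EXPANSION")
  expect_identical(rec$start, 48968205L)
  expect_identical(rec$length_bp, 176L)
  expect_identical(rec$chrom, "3")
})

test_that("the packaged fixture holds 47 records over 40 genes with consistent spans", {
  tab <- table1_records()
  expect_identical(nrow(tab), 47L)
  expect_identical(dplyr::n_distinct(tab$gene), 40L)
  # gene x category slots: 43 = 40 genes + 3 dual-category genes
  cat <- dplyr::case_when(
    tab$vtype %in% c("EXON_GAIN", "EXON_LOSS") ~ "EXON_GAIN_LOSS",
    tab$vtype == "HCONDEL" ~ "HCONDEL",
    tab$vtype == "HSD" ~ "HSD",
    tab$vtype %in% c("STR_CONTRACTION", "STR_EXPANSION") |
      tab$also_str ~ "STR",
    TRUE ~ "INDEL")
  slots <- unique(paste(tab$gene, cat))
  expect_identical(length(slots), 43L)
  ranged <- tab[tab$start != tab$end, ]
  ok <- ranged$length_flag == "ok"
  expect_true(all(ranged$end[ok] - ranged$start[ok] + 1L ==
                    ranged$length_bp[ok]))
  # the one convention-ambiguous span is off by exactly one base
  amb <- ranged[!ok, ]
  expect_identical(nrow(amb), 1L)
  expect_identical(amb$end - amb$start + 1L, amb$length_bp + 1L)
  # point-anchored records carry a multi-bp ancestral length
  pts <- tab[tab$start == tab$end, ]
  expect_true(all(pts$vtype %in% c("HCONDEL", "DELETION",
                                   "STR_CONTRACTION")))
  expect_true(all(pts$length_bp >= 1L))
})

test_that("gene model invariants are enforced", {
  expect_s3_class(toy_gene_models(), "gene_models")
  expect_error(gene_models(
    genes = tibble::tibble(symbol = "A", chrom = "1", start = 1L,
                           end = 10L),
    transcripts = tibble::tibble(transcript_id = character(),
                                 gene_symbol = character(),
                                 biotype = character(),
                                 principal = logical(),
                                 cds_start = integer(),
                                 cds_end = integer()),
    exons = tibble::tibble(transcript_id = character(), start = integer(),
                           end = integer(), exon_rank = integer())),
    "without transcripts")
  m <- toy_gene_models()
  bad_tx <- m$transcripts
  bad_tx$cds_start[2] <- 3150L
  bad_tx$cds_end[2] <- 3200L
  expect_error(gene_models(m$genes, bad_tx, m$exons),
               "processed_transcript")
})

test_that("gene models round-trip through GFF3", {
  dir <- withr::local_tempdir()
  m <- toy_gene_models()
  path <- file.path(dir, "toy.gff3")
  write_gff3(m, path)
  back <- read_gff3(path)
  expect_identical(back$genes$symbol, m$genes$symbol)
  expect_identical(back$genes$start, m$genes$start)
  expect_identical(back$genes$strand, m$genes$strand)
  tx <- dplyr::arrange(back$transcripts, transcript_id)
  expect_identical(tx$biotype, c("protein_coding", "processed_transcript"))
  expect_identical(tx$principal, c(TRUE, FALSE))
  expect_identical(tx$cds_start, c(1200L, NA_integer_))
  expect_identical(
    as.data.frame(dplyr::arrange(back$exons, transcript_id, start)),
    as.data.frame(dplyr::arrange(m$exons, transcript_id, start)))
})
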