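#' Multi-isoform gene models
#'
#' A `gene_models` object bundles three tibbles:
#' \describe{
#'   \item{genes}{`symbol`, `chrom`, `start`, `end`, `strand`, `species`}
#'   \item{transcripts}{`transcript_id`, `gene_symbol`, `species`,
#'     `biotype` (`protein_coding` or `processed_transcript`), `principal`,
#'     `cds_start`, `cds_end` (NA for non-coding isoforms)}
#'   \item{exons}{`transcript_id`, `start`, `end`, `exon_rank`}
#' }
#' All coordinates 1-based inclusive. Invariants: every gene has at least
#' one transcript; exons of a transcript are sorted and non-overlapping and
#' lie within the gene span; a CDS, if present, lies within the exon union;
#' processed transcripts carry no CDS.
#'
#' @param genes,transcripts,exons tibbles as described above.
#' @return an object of class `gene_models`.
#' @export
gene_models <- function(genes, transcripts, exons) {
  genes <- as_tibble(genes)
  transcripts <- as_tibble(transcripts)
  exons <- as_tibble(exons)
  if (!"species" %in% names(genes)) genes$species <- "human"
  if (!"species" %in% names(transcripts)) transcripts$species <- "human"
  if (!"strand" %in% names(genes)) genes$strand <- "+"
  genes$chrom <- normalize_chrom(genes$chrom)

  orphan <- setdiff(genes$symbol, transcripts$gene_symbol)
  if (length(orphan) > 0) {
    abort(paste0("gene(s) without transcripts: ",
                 paste(orphan, collapse = ", ")))
  }
  ex <- exons %>%
    left_join(transcripts[, c("transcript_id", "gene_symbol")],
              by = "transcript_id") %>%
    left_join(genes[, c("symbol", "start", "end")],
              by = c(gene_symbol = "symbol"), suffix = c("", ".gene"))
  out_of_span <- ex$start < ex$start.gene | ex$end > ex$end.gene
  if (any(out_of_span, na.rm = TRUE)) {
    abort(paste0("exon outside gene span in transcript(s): ",
                 paste(unique(ex$transcript_id[which(out_of_span)]),
                       collapse = ", ")))
  }
  chk <- exons %>%
    arrange(.data$transcript_id, .data$start) %>%
    group_by(.data$transcript_id) %>%
    summarise(ok = all(diff(.data$start) > 0) &&
                all(head(.data$end, -1) < tail(.data$start, -1)) ||
                n() == 1, .groups = "drop")
  if (any(!chk$ok)) {
    abort(paste0("overlapping or unsorted exons in transcript(s): ",
                 paste(chk$transcript_id[!chk$ok], collapse = ", ")))
  }
  nc_cds <- transcripts$biotype == "processed_transcript" &
    !is.na(transcripts$cds_start)
  if (any(nc_cds)) {
    abort(paste0("processed_transcript with a CDS: ",
                 paste(transcripts$transcript_id[nc_cds], collapse = ", ")))
  }
  coding <- transcripts[!is.na(transcripts$cds_start), ]
  for (i in seq_len(nrow(coding))) {
    tx_ex <- exons[exons$transcript_id == coding$transcript_id[i], ]
    covered <- any(tx_ex$start <= coding$cds_start[i] &
                     tx_ex$end >= coding$cds_start[i]) &&
      any(tx_ex$start <= coding$cds_end[i] & tx_ex$end >= coding$cds_end[i])
    if (!covered) {
      abort(paste0("CDS ends not contained in exons of ",
                   coding$transcript_id[i]))
    }
  }
  structure(list(genes = genes, transcripts = transcripts,
                 exons = arrange(exons, .data$transcript_id, .data$start)),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("<gene_models> ", nrow(x$genes), " genes, ",
      nrow(x$transcripts), " transcripts, ",
      nrow(x$exons), " exons; species: ",
      paste(unique(x$transcripts$species), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Subset gene models to one gene
#'
#' @param models a `gene_models` object.
#' @param symbol gene symbol (exact, case-sensitive match).
#' @return a `gene_models` object restricted to that gene.
#' @export
gene_subset <- function(models, symbol) {
  g <- models$genes[models$genes$symbol == symbol, ]
  if (nrow(g) == 0) abort(paste0("unknown gene symbol: ", symbol))
  tx <- models$transcripts[models$transcripts$gene_symbol == symbol, ]
  ex <- models$exons[models$exons$transcript_id %in% tx$transcript_id, ]
  structure(list(genes = g, transcripts = tx, exons = ex),
            class = "gene_models")
}

#' Read gene models from GFF3
#'
#' Expects `gene`, `mRNA`/`transcript`, `exon` and `CDS` features with
#' `ID`/`Parent` links and optional `biotype`, `principal` and `species`
#' attributes (defaults: `protein_coding` when a CDS is present, else
#' `processed_transcript`; not principal; human).
#'
#' @param path GFF3 file path.
#' @return a `gene_models` object.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$Parent <- vapply(df$Parent, function(p)
    if (length(p) == 0) NA_character_ else as.character(p[[1]]), character(1))
  attr_or <- function(col, default) {
    if (col %in% names(df)) {
      v <- as.character(df[[col]])
      ifelse(is.na(v), default, v)
    } else rep(default, nrow(df))
  }
  df$biotype_attr <- attr_or("biotype", NA_character_)
  df$principal_attr <- attr_or("principal", "false")
  df$species_attr <- attr_or("species", "human")

  g <- df[df$type == "gene", ]
  tx <- df[df$type %in% c("mRNA", "transcript"), ]
  ex <- df[df$type == "exon", ]
  cds <- df[df$type == "CDS", ]

  gene_by_id <- setNames(attr_or("Name", NA_character_)[df$type == "gene"],
                         g$ID)
  gene_by_id[is.na(gene_by_id)] <- g$ID[is.na(gene_by_id)]

  cds_tbl <- if (nrow(cds) > 0) {
    as_tibble(cds) %>%
      group_by(transcript_id = .data$Parent) %>%
      summarise(cds_start = min(.data$start), cds_end = max(.data$end),
                .groups = "drop")
  } else tibble(transcript_id = character(), cds_start = integer(),
                cds_end = integer())

  transcripts <- tibble(
    transcript_id = tx$ID,
    gene_symbol = unname(gene_by_id[tx$Parent]),
    species = tx$species_attr,
    principal = tolower(tx$principal_attr) %in% c("true", "1", "yes")
  ) %>%
    left_join(cds_tbl, by = "transcript_id") %>%
    mutate(biotype = ifelse(!is.na(tx$biotype_attr), tx$biotype_attr,
                            ifelse(is.na(.data$cds_start),
                                   "processed_transcript", "protein_coding")))

  exons <- tibble(transcript_id = ex$Parent,
                  start = ex$start, end = ex$end) %>%
    arrange(.data$transcript_id, .data$start) %>%
    group_by(.data$transcript_id) %>%
    mutate(exon_rank = row_number()) %>%
    ungroup()

  genes <- tibble(
    symbol = unname(gene_by_id[g$ID]),
    chrom = normalize_chrom(g$seqnames),
    start = g$start, end = g$end,
    strand = ifelse(as.character(g$strand) %in% c("+", "-"),
                    as.character(g$strand), "+"),
    species = g$species_attr
  )
  gene_models(genes, transcripts, exons)
}

#' Write gene models to GFF3
#'
#' @param models a `gene_models` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  g <- models$genes
  tx <- models$transcripts %>%
    left_join(g[, c("symbol", "chrom", "strand")],
              by = c(gene_symbol = "symbol"))
  ex <- models$exons %>%
    left_join(tx[, c("transcript_id", "gene_symbol", "chrom", "strand")],
              by = "transcript_id")
  ex_span <- if (nrow(ex) > 0) {
    ex %>%
      group_by(.data$transcript_id) %>%
      summarise(tx_start = min(.data$start), tx_end = max(.data$end),
                .groups = "drop")
  } else {
    tibble(transcript_id = character(), tx_start = integer(),
           tx_end = integer())
  }
  tx <- left_join(tx, ex_span, by = "transcript_id")

  rows <- c(
    sprintf("%s\tbaitpond\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s;species=%s",
            g$chrom, g$start, g$end, g$strand, g$symbol, g$symbol, g$species),
    sprintf(paste0("%s\tbaitpond\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s;",
                   "biotype=%s;principal=%s;species=%s"),
            tx$chrom, tx$tx_start, tx$tx_end, tx$strand, tx$transcript_id,
            tx$gene_symbol, tx$biotype,
            ifelse(tx$principal, "true", "false"), tx$species),
    sprintf("%s\tbaitpond\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
            ex$chrom, ex$start, ex$end, ex$strand, ex$transcript_id,
            ex$exon_rank, ex$transcript_id)
  )
  coding <- tx[!is.na(tx$cds_start), ]
  if (nrow(coding) > 0) {
    cds_rows <- purrr::pmap(coding, function(transcript_id, cds_start,
                                             cds_end, chrom, strand, ...) {
      tx_ex <- models$exons[models$exons$transcript_id == transcript_id, ]
      keep <- tx_ex$end >= cds_start & tx_ex$start <= cds_end
      tx_ex <- tx_ex[keep, ]
      sprintf("%s\tbaitpond\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s",
              chrom, pmax(tx_ex$start, cds_start), pmin(tx_ex$end, cds_end),
              strand, transcript_id, transcript_id)
    })
    rows <- c(rows, unlist(cds_rows))
  }
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}

#' Read/write FASTA sequence sets
#'
#' Thin wrappers around Biostrings with named character vectors as the
#' in-memory representation.
#'
#' @param path FASTA file path.
#' @return `read_fasta()`: a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), names(ss))
}

#' @rdname read_fasta
#' @param seqs named character vector of DNA sequences.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(unlist(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
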