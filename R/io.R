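#' Tabular input/output for the pipeline schemas
#'
#' Every stage of the pipeline exchanges plain TSV tables with fixed headers.
#' [read_table()] and [write_table()] are the single entry points; the
#' `schema` argument names one of the registered table kinds. Reading
#' enforces the record invariants and reports offending rows with their line
#' numbers; writing is the exact inverse so that a written table re-reads to
#' an identical tibble.
#'
#' @name table-io
NULL

VTYPES <- c("STR_CONTRACTION", "STR_EXPANSION", "INSERTION", "DELETION",
            "HCONDEL", "HSD", "INVERSION", "EXON_GAIN", "EXON_LOSS")

PCLASSES <- c("CDS_EXON", "UTR5", "UTR3", "NONCODING_EXON", "INTRON", "FLANK")

HIEG_CATEGORIES <- c("EXON_GAIN_LOSS", "HCONDEL", "HSD", "INDEL", "STR")

# Schema registry: column name -> readr collector shorthand.
.bp_schemas <- list(
  lead_snp = list(
    cols = c(rsid = "c", chrom = "c", pos = "i", study = "c", p = "d",
             nearest_gene = "c", locus_id = "c"),
    optional = c("p", "locus_id")
  ),
  bait = list(
    cols = c(symbol = "c", chrom = "c", start = "i", end = "i",
             sources = "c", lead_snps = "c"),
    optional = character()
  ),
  pond = list(
    cols = c(var_id = "c", chrom = "c", start = "i", end = "i", vtype = "c",
             length_bp = "i", source = "c", also_str = "l", validated = "c"),
    optional = c("source", "also_str", "validated")
  ),
  prey = list(
    cols = c(gene_symbol = "c", var_id = "c", vtype = "c", method = "c",
             within_gene = "l"),
    optional = c("vtype")
  ),
  hieg = list(
    cols = c(gene_symbol = "c", variations = "c", categories = "c",
             admit_rule = "c"),
    optional = character()
  ),
  sample_meta = list(
    cols = c(sample = "c", tissue = "c", species = "c", region_class = "c"),
    optional = character()
  )
)

#' Read a typed pipeline table
#'
#' @param path path to a TSV file with the schema's header.
#' @param schema one of `"lead_snp"`, `"bait"`, `"pond"`, `"prey"`,
#'   `"hieg"`, `"sample_meta"`.
#' @return a tibble with the schema's columns; invariants checked.
#' @export
read_table <- function(path, schema) {
  sc <- get_schema(schema)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  required <- setdiff(names(sc$cols), sc$optional)
  missing <- setdiff(required, hdr)
  if (length(missing) > 0) {
    abort(paste0("schema error [", schema, "]: missing column(s) ",
                 paste(missing, collapse = ", "), " in ", path))
  }
  present <- intersect(names(sc$cols), hdr)
  types <- do.call(readr::cols_only,
                   lapply(setNames(sc$cols[present], present), identity))
  df <- readr::read_tsv(path, col_types = types, na = c("", "NA"),
                        progress = FALSE)
  prob <- readr::problems(df)
  if (nrow(prob) > 0) {
    abort(paste0("parse error in ", path, ", row ", prob$row[1],
                 ": expected ", prob$expected[1], ", got ", prob$actual[1]))
  }
  # add absent optional columns with NA so the shape is stable
  for (col in setdiff(names(sc$cols), present)) {
    df[[col]] <- switch(sc$cols[[col]],
                        c = NA_character_, i = NA_integer_,
                        d = NA_real_, l = NA)
  }
  df <- df[, names(sc$cols)]
  validate_records(df, schema, path)
}

#' Write a typed pipeline table
#'
#' Inverse of [read_table()]: `read_table(write_table(x, p, s), s)`
#' returns `x`.
#'
#' @param records tibble matching the schema.
#' @param path output path.
#' @param schema table kind (see [read_table()]).
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, schema) {
  sc <- get_schema(schema)
  missing <- setdiff(setdiff(names(sc$cols), sc$optional), names(records))
  if (length(missing) > 0) {
    abort(paste0("cannot write ", schema, ": missing column(s) ",
                 paste(missing, collapse = ", ")))
  }
  for (col in setdiff(names(sc$cols), names(records))) {
    records[[col]] <- switch(sc$cols[[col]],
                             c = NA_character_, i = NA_integer_,
                             d = NA_real_, l = NA)
  }
  readr::write_tsv(records[, names(sc$cols)], path, na = "NA",
                   progress = FALSE)
  invisible(path)
}

get_schema <- function(schema) {
  sc <- .bp_schemas[[schema]]
  if (is.null(sc)) {
    abort(paste0("unknown schema '", schema, "'; available: ",
                 paste(names(.bp_schemas), collapse = ", ")))
  }
  sc
}

# Row-level invariant checks; line numbers are 1-based data rows + 1 header.
validate_records <- function(df, schema, path = "<in-memory>") {
  bad <- integer()
  msg <- character()
  note <- function(rows, what) {
    if (length(rows) > 0) {
      bad <<- c(bad, rows)
      msg <<- c(msg, paste0(what, " (line ",
                            paste(rows + 1L, collapse = ", "), ")"))
    }
  }
  if (schema %in% c("bait", "pond")) {
    note(bad_interval_rows(df), "invalid interval: need 1 <= start <= end")
  }
  if (schema == "lead_snp") {
    note(which(!is.na(df$p) & (df$p <= 0 | df$p > 1)),
         "p-value outside (0, 1]")
    note(which(is.na(df$pos) | df$pos < 1), "invalid SNP position")
  }
  if (schema == "pond") {
    note(which(!df$vtype %in% VTYPES),
         paste0("unknown variation type (allowed: ",
                paste(VTYPES, collapse = ", "), ")"))
    note(which(is.na(df$length_bp) | df$length_bp < 1), "length_bp < 1")
  }
  if (schema == "prey") {
    note(which(is.na(df$within_gene)), "within_gene must be TRUE/FALSE")
  }
  if (length(bad) > 0) {
    abort(paste0("invalid records in ", path, ":\n  ",
                 paste(msg, collapse = "\n  ")))
  }
  df
}

#' Read a BED file of variation spans into 1-based pond records
#'
#' Accepts 3+ column BED (chrom, start, end\[, name\]); coordinates are
#' converted from the 0-based half-open BED convention to the package's
#' 1-based inclusive convention.
#'
#' @param path BED/TSV path (no header).
#' @param vtype variation type to assign to every record.
#' @param source free-text provenance tag.
#' @return a pond-schema tibble.
#' @export
read_pond_bed <- function(path, vtype, source = basename(path)) {
  stopifnot(vtype %in% VTYPES)
  df <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(),
                        progress = FALSE)
  if (ncol(df) < 3) abort(paste0("BED file needs >= 3 columns: ", path))
  conv <- bed_to_one_based(df[[2]], df[[3]])
  tibble(
    var_id = if (ncol(df) >= 4) as.character(df[[4]]) else
      paste0(vtype, "_", seq_len(nrow(df))),
    chrom = normalize_chrom(df[[1]]),
    start = conv$start,
    end = conv$end,
    vtype = vtype,
    length_bp = span_length(conv$start, conv$end),
    source = source,
    also_str = FALSE,
    validated = "pending"
  )
}

#' The packaged candidate-gene fixture
#'
#' Forty intelligence-associated genes carrying 47 human-specific variation
#' records (hCONDELs, exon gains, STR expansions/contractions, insertions,
#' one deletion and one large segmental duplication), with the positional
#' class of each variation against the gene structure. One exon-gain span
#' is off by one base against its stated length under the inclusive
#' convention and is flagged `length_flag = "convention-ambiguous"`; the
#' stated `length_bp` is treated as authoritative.
#'
#' @return a tibble with one row per variation record: `gene`, `chrom`,
#'   `gene_start`, `gene_end`, `rsid`, `vtype`, `start`, `end`,
#'   `length_bp`, `also_str`, `pclass`, `length_flag`.
#' @export
#' @examples
#' tab <- table1_records()
#' nrow(tab)            # 47 variation records
#' dplyr::n_distinct(tab$gene)  # 40 genes
table1_records <- function() {
  path <- system.file("extdata", "table1_hiegs.tsv", package = "baitpond")
  readr::read_tsv(path, col_types = "cciicciiilcc", progress = FALSE)
}

#' Gene spans of the packaged candidate-gene fixture
#'
#' @return a bait-like tibble (`symbol`, `chrom`, `start`, `end`), one row
#'   per gene.
#' @export
table1_gene_spans <- function() {
  table1_records() %>%
    distinct(symbol = .data$gene, chrom = .data$chrom,
             start = .data$gene_start, end = .data$gene_end)
}
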