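#' Assemble the typed human-specific variation pond
#'
#' Pools per-type call sets of human-specific structural variation into one
#' "pond", applying the type-specific admission rules: insertions and
#' deletions must exceed 50 bp; human-specific segmental duplications (HSDs)
#' must exceed 1 kb (the published definition: > 1 kb with > 90% sequence
#' similarity). STRs, hCONDELs and inversions carry no size filter.
#'
#' @param sources a named list, one element per variation type (names from
#'   `STR_CONTRACTION`, `STR_EXPANSION`, `INSERTION`, `DELETION`,
#'   `HCONDEL`, `HSD`, `INVERSION`, `EXON_GAIN`, `EXON_LOSS`), each a
#'   tibble with at least `chrom`, `start`, `end` and optionally `var_id`,
#'   `length_bp`, `source`, `also_str`. For point-anchored records
#'   (hCONDEL, anchored deletions) `start == end` and `length_bp` gives
#'   the ancestral length; otherwise `length_bp` defaults to the span
#'   length.
#' @param indel_min_bp,hsd_min_bp admission thresholds (exclusive lower
#'   bounds), defaults 50 and 1000.
#' @return a `variation_pond`: list with `records` (pond-schema tibble),
#'   `counts_by_type` (named integer vector over all types) and `rejected`
#'   (records that failed admission, with a `reject_reason` column).
#' @export
#' @examples
#' pond <- build_pond(list(
#'   INSERTION = tibble::tibble(chrom = "1", start = 100L, end = 400L),
#'   HSD = tibble::tibble(chrom = "2", start = 1000L, end = 2200L)))
#' pond$counts_by_type[c("INSERTION", "HSD")]
build_pond <- function(sources, indel_min_bp = 50L, hsd_min_bp = 1000L) {
  if (length(sources) == 0) {
    return(new_pond(empty_pond_records(),
                    empty_pond_records()[0, ]))
  }
  unknown <- setdiff(names(sources), VTYPES)
  if (length(unknown) > 0 || is.null(names(sources)) ||
      any(names(sources) == "")) {
    abort(paste0("configuration error: unknown variation type tag(s): ",
                 paste(unknown, collapse = ", ")))
  }
  recs <- purrr::imap(sources, function(df, vt) {
    if (is.null(df) || nrow(df) == 0) return(NULL)
    df <- as_tibble(df)
    df$chrom <- normalize_chrom(df$chrom)
    if (!"length_bp" %in% names(df) || all(is.na(df$length_bp))) {
      df$length_bp <- span_length(df$start, df$end)
    }
    tibble(
      var_id = if ("var_id" %in% names(df)) df$var_id else
        paste0(vt, "_", seq_len(nrow(df))),
      chrom = df$chrom,
      start = as.integer(df$start),
      end = as.integer(df$end),
      vtype = vt,
      length_bp = as.integer(df$length_bp),
      source = if ("source" %in% names(df)) df$source else NA_character_,
      also_str = if ("also_str" %in% names(df)) df$also_str else FALSE,
      validated = if ("validated" %in% names(df)) df$validated else "pending"
    )
  }) %>% bind_rows()
  if (nrow(recs) == 0) recs <- empty_pond_records()

  recs <- validate_records(recs, "pond")
  reject_reason <- rep(NA_character_, nrow(recs))
  indel <- recs$vtype %in% c("INSERTION", "DELETION")
  reject_reason[indel & recs$length_bp <= indel_min_bp] <-
    paste0("indel length <= ", indel_min_bp, " bp")
  reject_reason[recs$vtype == "HSD" & recs$length_bp <= hsd_min_bp] <-
    paste0("HSD length <= ", hsd_min_bp, " bp")
  rejected <- recs[!is.na(reject_reason), ]
  rejected$reject_reason <- reject_reason[!is.na(reject_reason)]
  if (nrow(rejected) > 0) {
    inform(paste0("pond admission rejected ", nrow(rejected),
                  " record(s) by size rule"))
  }
  new_pond(recs[is.na(reject_reason), ], rejected)
}

new_pond <- function(records, rejected) {
  counts <- table(factor(records$vtype, levels = VTYPES))
  structure(list(records = records,
                 counts_by_type = setNames(as.integer(counts),
                                           names(counts)),
                 rejected = rejected),
            class = "variation_pond")
}

empty_pond_records <- function() {
  tibble(var_id = character(), chrom = character(), start = integer(),
         end = integer(), vtype = character(), length_bp = integer(),
         source = character(), also_str = logical(), validated = character())
}

#' @export
print.variation_pond <- function(x, ...) {
  cat("<variation_pond> ", nrow(x$records), " records\n", sep = "")
  nz <- x$counts_by_type[x$counts_by_type > 0]
  if (length(nz) > 0) {
    cat(paste0("  ", names(nz), ": ", nz, collapse = "\n"), "\n", sep = "")
  }
  invisible(x)
}

#' Large human-specific segmental duplications
#'
#' The published large-duplication set keeps HSDs longer than 5 kb; this
#' filter reproduces that subset from a pond.
#'
#' @param pond a `variation_pond`.
#' @param min_len exclusive length threshold in bp (default 5000).
#' @return pond-schema tibble of HSD records with `length_bp > min_len`.
#' @export
filter_hsd_large <- function(pond, min_len = 5000L) {
  stopifnot(inherits(pond, "variation_pond"))
  filter(pond$records, .data$vtype == "HSD", .data$length_bp > min_len)
}
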