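#' Genomic interval helpers
#'
#' All coordinates in this package are 1-based and inclusive on both ends,
#' the convention of Ensembl gene annotation. BED input (0-based, half-open)
#' is converted on read with [bed_to_one_based()].
#'
#' @name intervals
NULL

#' Normalize chromosome labels
#'
#' Strips a leading `"chr"` prefix so that `"chr3"` and `"3"` compare equal.
#'
#' @param chrom character vector of chromosome labels.
#' @return character vector of bare labels (`"1".."22"`, `"X"`, `"Y"`, ...).
#' @export
#' @examples
#' normalize_chrom(c("chr3", "3", "chrX"))
normalize_chrom <- function(chrom) {
  sub("^chr", "", as.character(chrom))
}

#' Is a chromosome label an autosome?
#'
#' @param chrom character vector (already normalized or not).
#' @return logical vector, `TRUE` for labels `"1".."22"`.
#' @export
is_autosome <- function(chrom) {
  normalize_chrom(chrom) %in% as.character(1:22)
}

#' Convert BED half-open coordinates to 1-based inclusive
#'
#' BED records are 0-based with an exclusive end; the 1-based inclusive
#' equivalent is `[start0 + 1, end0]`.
#'
#' @param start0,end0 integer vectors of BED start/end.
#' @return a list with elements `start` and `end` (1-based inclusive).
#' @export
#' @examples
#' bed_to_one_based(48968204, 48968380) # 176 bp span
bed_to_one_based <- function(start0, end0) {
  stopifnot(all(end0 > start0))
  list(start = as.integer(start0 + 1), end = as.integer(end0))
}

#' Inclusive span length
#'
#' @param start,end 1-based inclusive coordinates.
#' @return integer `end - start + 1`.
#' @export
span_length <- function(start, end) {
  as.integer(end - start + 1L)
}

# Vectorized 1-based inclusive interval intersection test.
intervals_overlap <- function(s1, e1, s2, e2) {
  s1 <= e2 & s2 <= e1
}

# Distance between two 1-based inclusive intervals (0 if they touch/overlap).
interval_distance <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s2 - e1, s1 - e2))
}

# Validate interval columns of a data frame; returns offending row indices.
bad_interval_rows <- function(df, start_col = "start", end_col = "end") {
  s <- df[[start_col]]
  e <- df[[end_col]]
  which(is.na(s) | is.na(e) | s < 1 | s > e)
}
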