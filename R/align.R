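#' Local alignment validation of candidate human-specific variations
#'
#' Candidate variations inherited from published call sets are confirmed by
#' local alignment of the human sequence context against the corresponding
#' ape sequence, the desk-scale analogue of a BLASTn false-positive filter.
#' A sequence segment counts as "found" in a target when Smith-Waterman
#' local alignment recovers it at identity >= `min_identity` over at least
#' `min_coverage` of the segment length (defaults 0.9 and 0.8). Scoring is
#' BLASTn-like: match +1, mismatch -2, gap open 5, gap extend 2.
#'
#' @name alignment-validator
NULL

#' Smith-Waterman local alignment
#'
#' @param query,subject DNA sequences (character).
#' @return the `PairwiseAlignments` object from
#'   [Biostrings::pairwiseAlignment()] with local type and the scoring
#'   above.
#' @export
sw_align <- function(query, subject) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = FALSE)
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = mat,
    gapOpening = 5, gapExtension = 2)
}

#' Is a segment recoverable from a target sequence?
#'
#' @param segment query segment (character).
#' @param target target sequence (character).
#' @param min_identity minimum fraction of identical positions over the
#'   local alignment.
#' @param min_coverage minimum fraction of the segment covered by the
#'   local alignment.
#' @return logical scalar.
#' @export
segment_found <- function(segment, target, min_identity = 0.9,
                          min_coverage = 0.8) {
  if (nchar(segment) == 0 || nchar(target) == 0) return(FALSE)
  aln <- sw_align(segment, target)
  if (Biostrings::score(aln) <= 0) return(FALSE)
  cov <-(IRanges::end(Biostrings::pattern(aln)) -
            IRanges::start(Biostrings::pattern(aln)) + 1) / nchar(segment)
  ident <- Biostrings::nmatch(aln) / Biostrings::nchar(aln)
  cov >= min_coverage && ident >= min_identity
}

#' Construct a validation case
#'
#' @param var_id variation identifier.
#' @param vtype variation type; `INSERTION` cases supply the inserted
#'   segment inside `human_seq`, deletion-like cases (`DELETION`,
#'   `HCONDEL`) supply the ancestral segment separately.
#' @param human_seq human sequence: variant plus flanks.
#' @param ape_seqs named list/character vector, one sequence per ape
#'   species.
#' @param insert_at,insert_len 1-based offset and length of the inserted
#'   segment within `human_seq` (insertion cases).
#' @param ancestral_seq the sequence conserved in apes but absent from
#'   human (deletion/hCONDEL cases).
#' @param flank_bp flank length per side used when anchoring (default 500).
#' @return a `validation_case` object.
#' @export
validation_case <- function(var_id, vtype, human_seq, ape_seqs,
                            insert_at = NULL, insert_len = NULL,
                            ancestral_seq = NULL, flank_bp = 500L) {
  vtype <- match.arg(vtype, VTYPES)
  check_bases <- function(s, what) {
    if (grepl("[^ACGTN]", s)) {
      abort(paste0(what, " contains characters outside {A,C,G,T,N}"))
    }
  }
  check_bases(human_seq, "human_seq")
  purrr::iwalk(as.list(ape_seqs), function(s, sp)
    check_bases(s, paste0("ape sequence (", sp, ")")))
  insertion_like <- vtype %in% c("INSERTION", "STR_EXPANSION", "EXON_GAIN",
                                 "HSD")
  if (insertion_like && (is.null(insert_at) || is.null(insert_len))) {
    abort("insertion-type case needs insert_at and insert_len")
  }
  if (!insertion_like && is.null(ancestral_seq)) {
    abort("deletion-type case needs the ancestral segment")
  }
  if (!is.null(ancestral_seq)) check_bases(ancestral_seq, "ancestral_seq")
  stopifnot(flank_bp >= 1)
  structure(list(var_id = var_id, vtype = vtype, human_seq = human_seq,
                 ape_seqs = as.list(ape_seqs), insert_at = insert_at,
                 insert_len = insert_len, ancestral_seq = ancestral_seq,
                 flank_bp = as.integer(flank_bp)),
            class = "validation_case")
}

#' Validate one candidate human-specific variation
#'
#' A case is `validated` when every supplied ape species shows the
#' human-specific state:
#' \itemize{
#'   \item insertion-type (insertion, STR expansion, exon gain, HSD): both
#'     human flanks anchor in the ape sequence but the inserted segment is
#'     not found there;
#'   \item deletion-type (deletion, hCONDEL): the ancestral segment is
#'     found in the ape sequence but not in the human sequence.
#' }
#' Otherwise the case is `rejected` and the failing species are named.
#' Species with a missing sequence are skipped with a warning. The flank
#' anchoring check uses a fixed identity of 0.9 so that the verdict is
#' monotone in `min_identity` (raising `min_identity` only makes ape
#' matches of the segment rarer).
#'
#' @param case a [validation_case()].
#' @param min_identity identity threshold for segment detection
#'   (default 0.9).
#' @param min_coverage coverage threshold for segment detection
#'   (default 0.8).
#' @return a list: `verdict` (`"validated"` or `"rejected"`), `evidence`
#'   (per-species tibble), `failing_species`.
#' @export
validate_variation <- function(case, min_identity = 0.9,
                               min_coverage = 0.8) {
  stopifnot(inherits(case, "validation_case"))
  apes <- case$ape_seqs
  missing <- vapply(apes, function(s) is.null(s) || is.na(s) || !nzchar(s),
                    logical(1))
  if (any(missing)) {
    warn(paste0("skipping species with missing sequence: ",
                paste(names(apes)[missing], collapse = ", ")))
    apes <- apes[!missing]
  }
  if (length(apes) == 0) abort("no ape sequence available for comparison")

  insertion_like <- case$vtype %in% c("INSERTION", "STR_EXPANSION",
                                      "EXON_GAIN", "HSD")
  if (insertion_like) {
    seg <- substr(case$human_seq, case$insert_at,
                  case$insert_at + case$insert_len - 1L)
    left <- substr(case$human_seq,
                   max(1L, case$insert_at - case$flank_bp),
                   case$insert_at - 1L)
    right <- substr(case$human_seq, case$insert_at + case$insert_len,
                    min(nchar(case$human_seq),
                        case$insert_at + case$insert_len +
                          case$flank_bp - 1L))
    evidence <- purrr::imap(apes, function(ape, sp) {
      if (nchar(ape) < case$flank_bp) {
        abort(paste0("insufficient context: ape sequence for ", sp,
                     " shorter than flank_bp"))
      }
      tibble(
        species = sp,
        flank_left_found = segment_found(left, ape, 0.9, min_coverage),
        flank_right_found = segment_found(right, ape, 0.9, min_coverage),
        segment_in_ape = segment_found(seg, ape, min_identity,
                                       min_coverage)
      ) %>%
        mutate(supports = .data$flank_left_found &
                 .data$flank_right_found & !.data$segment_in_ape)
    }) %>% bind_rows()
  } else {
    anc_in_human <- segment_found(case$ancestral_seq, case$human_seq,
                                  min_identity, min_coverage)
    evidence <- purrr::imap(apes, function(ape, sp) {
      if (nchar(ape) < case$flank_bp) {
        abort(paste0("insufficient context: ape sequence for ", sp,
                     " shorter than flank_bp"))
      }
      tibble(
        species = sp,
        ancestral_in_ape = segment_found(case$ancestral_seq, ape,
                                         min_identity, min_coverage),
        ancestral_in_human = anc_in_human
      ) %>%
        mutate(supports = .data$ancestral_in_ape &
                 !.data$ancestral_in_human)
    }) %>% bind_rows()
  }
  failing <- evidence$species[!evidence$supports]
  list(verdict = if (length(failing) == 0) "validated" else "rejected",
       evidence = evidence,
       failing_species = failing)
}

#' Read validation cases from FASTA plus a metadata table
#'
#' The FASTA holds one record per sequence with IDs `varID|human`,
#' `varID|<species>` and, for deletion-type cases, `varID|ancestral`. The
#' metadata TSV has columns `var_id`, `vtype`, and for insertion-type
#' cases `insert_at`, `insert_len`.
#'
#' @param fasta_path FASTA file of case sequences.
#' @param meta_path metadata TSV.
#' @param flank_bp flank length passed to each case.
#' @return a named list of [validation_case()] objects.
#' @export
read_validation_cases <- function(fasta_path, meta_path, flank_bp = 500L) {
  seqs <- read_fasta(fasta_path)
  meta <- readr::read_tsv(meta_path, col_types = readr::cols(),
                          progress = FALSE)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1)
  roles <- vapply(parts, `[`, character(1), 2)
  cases <- lapply(seq_len(nrow(meta)), function(i) {
    vid <- meta$var_id[i]
    sel <- ids == vid
    role <- roles[sel]
    s <- seqs[sel]
    validation_case(
      var_id = vid, vtype = meta$vtype[i],
      human_seq = unname(s[role == "human"]),
      ape_seqs = setNames(as.list(unname(s[!role %in%
                                             c("human", "ancestral")])),
                          role[!role %in% c("human", "ancestral")]),
      insert_at = na_null(if ("insert_at" %in% names(meta))
        meta$insert_at[i]),
      insert_len = na_null(if ("insert_len" %in% names(meta))
        meta$insert_len[i]),
      ancestral_seq = if (any(role == "ancestral"))
        unname(s[role == "ancestral"]),
      flank_bp = flank_bp)
  })
  setNames(cases, meta$var_id)
}

na_null <- function(x) if (is.null(x) || is.na(x)) NULL else x

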