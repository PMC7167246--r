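rand_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_frac <- function(seq, frac, seed) {
  set.seed(seed)
  chars <- strsplit(seq, "")[[1]]
  idx <- sample(length(chars), round(frac * length(chars)))
  swap <- c(A = "G", C = "T", G = "A", T = "C")
  chars[idx] <- swap[chars[idx]]
  paste(chars, collapse = "")
}

insertion_case <- function(seg_len = 100L, flank = 300L, seed = 1,
                           ape_override = NULL) {
  left <- rand_seq(flank + 50, seed)
  right <- rand_seq(flank + 50, seed + 1)
  seg <- rand_seq(seg_len, seed + 2)
  human <- paste0(left, seg, right)
  ape <- ape_override %||% paste0(left, right)
  validation_case("v1", "INSERTION", human,
                  list(chimpanzee = ape, gorilla = ape, orangutan = ape),
                  insert_at = nchar(left) + 1L, insert_len = seg_len,
                  flank_bp = flank)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("a planted insertion absent from the ape validates; an identical ape rejects", {
  case <- insertion_case()
  res <- validate_variation(case)
  expect_identical(res$verdict, "validated")
  expect_true(all(res$evidence$supports))
  # human and ape identical: the variation is undetectable
  same <- insertion_case(ape_override = insertion_case()$human_seq)
  res2 <- validate_variation(same)
  expect_identical(res2$verdict, "rejected")
  expect_identical(sort(res2$failing_species),
                   c("chimpanzee", "gorilla", "orangutan"))
})

test_that("a segment still present in the ape at 95% identity rejects the case", {
  base <- insertion_case()
  seg <- substr(base$human_seq, base$insert_at,
                base$insert_at + base$insert_len - 1L)
  left <- substr(base$human_seq, 1, base$insert_at - 1L)
  right <- substr(base$human_seq, base$insert_at + base$insert_len,
                  nchar(base$human_seq))
  ape <- paste0(left, mutate_frac(seg, 0.05, 7), right)
  case <- insertion_case(ape_override = ape)
  expect_identical(validate_variation(case)$verdict, "rejected")
  # at a stricter identity demand the mutated copy no longer counts as found
  expect_identical(validate_variation(case, min_identity = 0.99)$verdict,
                   "validated")
})

test_that("deletion cases need the ancestral segment in ape but not human", {
  left <- rand_seq(400, 21)
  right <- rand_seq(400, 22)
  seg <- rand_seq(300, 23)
  case <- validation_case(
    "d1", "HCONDEL", paste0(left, right),
    list(chimpanzee = paste0(left, seg, right),
         gorilla = paste0(left, seg, right)),
    ancestral_seq = seg, flank_bp = 300L)
  expect_identical(validate_variation(case)$verdict, "validated")
  # ape missing the segment too: nothing human-specific to confirm
  case2 <- validation_case(
    "d2", "HCONDEL", paste0(left, right),
    list(chimpanzee = paste0(left, right)),
    ancestral_seq = seg, flank_bp = 300L)
  expect_identical(validate_variation(case2)$verdict, "rejected")
})

test_that("verdicts are deterministic and species handling is explicit", {
  case <- insertion_case(seed = 5)
  v1 <- validate_variation(case)
  v2 <- validate_variation(case)
  expect_identical(v1, v2)
  short <- insertion_case(seed = 6)
  short$ape_seqs$gorilla <- "ACGT"
  expect_error(validate_variation(short), "insufficient context")
  gone <- insertion_case(seed = 6)
  gone$ape_seqs$gorilla <- NA_character_
  expect_warning(res <- validate_variation(gone), "missing sequence")
  expect_identical(res$verdict, "validated")
  expect_identical(nrow(res$evidence), 2L)
})

test_that("the validator separates a labelled true/false panel perfectly", {
  panel <- build_validation_panel(n_true = 15L, n_false = 15L, seed = 3)
  verdicts <- vapply(panel$cases, function(cs)
    validate_variation(cs)$verdict, character(1))
  truth <- panel$truth$true_specific
  expect_identical(unname(verdicts[truth]),
                   rep("validated", sum(truth)))
  expect_identical(unname(verdicts[!truth]),
                   rep("rejected", sum(!truth)))
})

test_that("validation cases round-trip through FASTA and metadata files", {
  dir <- withr::local_tempdir()
  sim <- simulate_inputs(sim_config(seed = 5))
  write_simulation(sim, dir)
  cases <- read_validation_cases(file.path(dir, "validation_cases.fasta"),
                                 file.path(dir, "validation_cases.tsv"))
  expect_identical(sort(names(cases)),
                   sort(names(sim$validation_cases)))
  one <- names(cases)[1]
  expect_identical(cases[[one]]$human_seq,
                   sim$validation_cases[[one]]$human_seq)
  expect_identical(validate_variation(cases[[one]])$verdict, "validated")
})
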