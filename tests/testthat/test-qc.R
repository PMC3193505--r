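test_that("longest_orf matches the genetic code on forced cases", {
  orf <- longest_orf("ATGAAATAA")
  expect_equal(orf$length_aa, 2L)
  expect_equal(orf$frame, 1L)
  expect_equal(c(orf$start, orf$end), c(1L, 6L))
  expect_equal(longest_orf("CCCCCCCCC")$length_aa, 0L)
  # ATG without a terminating stop does not count
  expect_equal(longest_orf("ATGAAAAAA")$length_aa, 0L)
})

test_that("longest_orf equals the exhaustive-scan oracle on random input", {
  set.seed(71)
  for (rep in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 1200, replace = TRUE),
               collapse = "")
    expect_equal(longest_orf(s)$length_aa, oracle_longest_orf(s), info = rep)
  }
})

test_that("ORF length boundary at 150 aa separates gene from pseudogene", {
  # codons over {C,G,T} contain no A: no ATG, no stop anywhere
  filler <- function(k) sample(apply(expand.grid(c("C","G","T"), c("C","G","T"),
                                                 c("C","G","T")), 1, paste0,
                                     collapse = ""), k, replace = TRUE)
  set.seed(8)
  mk <- function(n_aa) paste(c("ATG", filler(n_aa - 1), "TAA"), collapse = "")
  rec <- tibble::tibble(
    id = c("aa149", "aa150"),
    nt_sequence = c(mk(149), mk(150)),
    has_accurate_splice_sites = TRUE, has_est_match = TRUE,
    is_intronless = FALSE, has_promoter_signal = TRUE)
  out <- classify_candidates(rec)
  expect_equal(out$orf_length_aa, c(149L, 150L))
  expect_equal(out$status, c("pseudogene", "gene"))
  expect_match(out$reasons[1], "ORF < 150")
})

test_that("evidence rules classify as designed, unknowns never condemn", {
  base <- tibble::tibble(
    id = "x", nt_sequence = paste(c("ATG", rep("GGC", 899), "TAA"),
                                  collapse = ""),
    has_accurate_splice_sites = TRUE, has_est_match = TRUE,
    is_intronless = FALSE, has_promoter_signal = TRUE)
  expect_equal(classify_candidates(base)$status, "gene")
  est <- base; est$has_est_match <- FALSE
  expect_equal(classify_candidates(est)$status, "pseudogene")
  spl <- base; spl$has_accurate_splice_sites <- FALSE
  expect_equal(classify_candidates(spl)$status, "pseudogene")
  retro <- base; retro$is_intronless <- TRUE; retro$has_promoter_signal <- FALSE
  expect_equal(classify_candidates(retro)$status, "pseudogene")
  unk <- base; unk$has_est_match <- NA
  out <- classify_candidates(unk)
  expect_equal(out$status, "unresolved")
  expect_match(out$reasons, "unresolved")
})

test_that("classification is monotone: extra failing evidence never rescues", {
  set.seed(13)
  seqs <- paste(c("ATG", rep("GGC", 200), "TAA"), collapse = "")
  flags <- expand.grid(splice = c(TRUE, FALSE, NA),
                       est = c(TRUE, FALSE, NA))
  for (i in seq_len(nrow(flags))) {
    rec <- tibble::tibble(id = "x", nt_sequence = seqs,
                          has_accurate_splice_sites = flags$splice[i],
                          has_est_match = flags$est[i],
                          is_intronless = FALSE, has_promoter_signal = TRUE)
    st <- classify_candidates(rec)$status
    worse <- rec; worse$has_est_match <- FALSE
    st2 <- classify_candidates(worse)$status
    expect_true(!(st == "pseudogene" && st2 != "pseudogene"))
    expect_equal(st2, "pseudogene")
  }
})

test_that("coverage and identity behave at the definitions' edges", {
  set.seed(14)
  ref <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
               collapse = "")
  self <- pairwise_coverage_identity(ref, ref)
  expect_equal(self$coverage_pct, 100)
  expect_equal(self$identity_pct, 100)
  frag <- substr(ref, 1, 40)
  expect_equal(pairwise_coverage_identity(frag, ref)$coverage_pct, 40)
  expect_error(pairwise_coverage_identity("", ref), "non-empty")
})

test_that("alignment scoring agrees with an independent DP oracle", {
  set.seed(15)
  for (rep in 1:5) {
    a <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = "")
    b0 <- strsplit(a, "")[[1]]
    mut <- stats::runif(60) < 0.15
    b0[mut] <- sample(c("A", "C", "G", "T"), sum(mut), replace = TRUE)
    b <- paste(b0[stats::runif(60) > 0.05], collapse = "")  # a few deletions
    got <- pairwise_coverage_identity(a, b)$score
    expect_equal(got, oracle_semiglobal(a, b), info = rep)
  }
})

test_that("tree-inclusion filter applies the 40% coverage threshold", {
  res <- tibble::tibble(id = c("a", "b", "c"),
                        coverage_pct = c(39.9, 40.0, 95))
  kept <- filter_for_tree(res)
  expect_equal(kept$id, c("b", "c"))
  expect_equal(nrow(filter_for_tree(res[0, ])), 0)
  set.seed(16)
  res10 <- tibble::tibble(id = letters[1:10],
                          coverage_pct = stats::runif(10, 20, 60))
  expect_equal(filter_for_tree(res10)$id,
               res10$id[res10$coverage_pct >= 40])
})

test_that("solvent accessibility split is strict at 25%", {
  out <- classify_exposure(c(0, 24.9, 25.0, 80))
  expect_equal(out$exposure, c("buried", "buried", "exposed", "exposed"))
  expect_error(classify_exposure(c(10, 105)), "0, 100")
})

test_that("the six-candidate synthetic panel reproduces its designed labels", {
  panel <- synthetic_qc_panel(seed = 42)
  qc <- qc_candidates(panel$records, reference_nt = panel$reference)
  expect_equal(qc$status, panel$expected$status)
  expect_equal(qc$include_in_tree, panel$expected$include_in_tree)
  # the fragment sits exactly below the threshold
  expect_equal(qc$coverage_pct[qc$id == "low_coverage"], 39.9)
  expect_lt(qc$orf_length_aa[qc$id == "short_orf"], 150)
  # a 1200 nt exact fragment (with stop) reaches exactly 40% and is kept
  ref_codons <- substring(panel$reference,
                          seq(1, nchar(panel$reference) - 2, 3),
                          seq(3, nchar(panel$reference), 3))
  at40 <- paste(c(ref_codons[1:399], "TAA"), collapse = "")
  cov <- pairwise_coverage_identity(at40, panel$reference)$coverage_pct
  expect_equal(cov, 40)
})

test_that("candidate records round-trip through FASTA + metadata TSV", {
  panel <- synthetic_qc_panel(seed = 42)
  fa <- tempfile(fileext = ".fasta"); tsv <- tempfile(fileext = ".tsv")
  write_fasta(stats::setNames(panel$records$nt_sequence, panel$records$id), fa)
  utils::write.table(panel$records[, setdiff(names(panel$records),
                                             "nt_sequence")],
                     tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- read_candidates(fa, tsv)
  expect_equal(rec$nt_sequence, panel$records$nt_sequence)
  expect_equal(rec$has_est_match, panel$records$has_est_match)
  qc <- qc_candidates(rec, reference_nt = panel$reference)
  expect_equal(qc$status, panel$expected$status)
})
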