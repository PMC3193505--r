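# A deterministic six-candidate synthetic QC panel exercising every
# classification rule: an intact gene, a short-ORF pseudogene, an EST-less
# pseudogene, a splice-broken pseudogene, an intronless/promoterless
# retrocopy, and a low-coverage fragment excluded from tree building.

# Random sense codons drawn from a seeded stream (stops excluded).
.random_sense_codons <- function(n) {
  sample(.sense_codons(), n, replace = TRUE)
}

#' Synthetic candidate panel for QC tests
#'
#' Builds, from a seed, a 1000-codon reference CDS and six candidate
#' records with designed gene/pseudogene/tree-inclusion labels, including
#' the 39.9% coverage boundary case. All sequences are generated in code;
#' nothing is bundled.
#'
#' @param seed Integer seed.
#' @return A list: `reference` (CDS string), `records` (candidate tibble
#'   for [qc_candidates()]), `expected` (tibble of designed `status` and
#'   `include_in_tree` per id).
#' @export
synthetic_qc_panel <- function(seed = 42) {
  .build_code_tables()
  set.seed(as.integer(seed))
  # reference: ATG + 998 random sense codons (no ATG re-draw needed) + stop;
  # the candidate fragments below rely only on frame-1 structure
  body <- .random_sense_codons(998)
  reference <- paste(c("ATG", body, "TAA"), collapse = "")
  ref_codons <- c("ATG", body)   # 999 codons, ORF 999 aa

  frag <- function(first, last) paste(ref_codons[first:last], collapse = "")

  # 1. intact gene: full CDS, all evidence good
  intact <- reference

  # 2. short-ORF pseudogene: 50% fragment with in-frame stops every 141
  # codons, so no ORF reaches 150 aa (longest is 140)
  c2 <- ref_codons[1:500]
  c2[seq(141, 500, by = 141)] <- "TAA"
  short_orf <- paste(c2, collapse = "")

  # 3-5: full-length copies distinguished only by evidence flags
  est_less <- reference
  splice_broken <- reference
  retrocopy <- reference

  # 6. low-coverage fragment: 398 reference codons + stop = 1197 nt,
  # i.e. coverage 1197/3000 = 39.9%
  low_cov <- paste(c(ref_codons[1:398], "TAA"), collapse = "")

  records <- tibble::tibble(
    id = c("intact_gene", "short_orf", "est_less", "splice_broken",
           "retrocopy", "low_coverage"),
    species = "synthetic",
    chromosome = c("X", "X", "X", "X", "7", "X"),
    nt_sequence = c(intact, short_orf, est_less, splice_broken,
                    retrocopy, low_cov),
    is_reciprocal_best_hit = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    has_accurate_splice_sites = c(TRUE, TRUE, TRUE, FALSE, NA, TRUE),
    has_est_match = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    is_intronless = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    has_promoter_signal = c(TRUE, NA, NA, NA, FALSE, TRUE))

  expected <- tibble::tibble(
    id = records$id,
    status = c("gene", "pseudogene", "pseudogene", "pseudogene",
               "pseudogene", "gene"),
    include_in_tree = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))

  list(reference = reference, records = records, expected = expected)
}
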