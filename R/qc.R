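# Homolog quality control: open-reading-frame search, gene/pseudogene
# classification from splice/EST/ORF/promoter evidence, coverage and
# identity against a reference CDS, the coverage filter for tree building,
# and the buried/exposed call from relative solvent accessibility.

#' Longest ATG-initiated open reading frame
#'
#' Finds the longest ATG-initiated, stop-terminated reading frame under the
#' standard genetic code. Length is in amino acids and excludes the stop
#' codon; coordinates are 1-based inclusive on the input strand and exclude
#' the stop codon. An ORF without a terminating stop does not count.
#'
#' @param nt_sequence A nucleotide string (A, C, G, T, N).
#' @param frames `"forward"` (default: the three forward frames; inputs are
#'   oriented transcript candidates) or `"all"` (both strands).
#' @return A one-row tibble: `length_aa`, `start`, `end`, `frame`
#'   (1..3 forward, -1..-3 reverse). `length_aa = 0` with NA coordinates
#'   when no ORF exists.
#' @export
longest_orf <- function(nt_sequence, frames = c("forward", "all")) {
  frames <- match.arg(frames)
  s <- toupper(nt_sequence)
  if (!grepl("^[ACGTN]*$", s))
    stop("sequence alphabet must be A, C, G, T, N", call. = FALSE)
  n <- nchar(s)
  best <- list(length_aa = 0L, start = NA_integer_, end = NA_integer_,
               frame = NA_integer_)
  scan_strand <- function(seqstr, strand_sign) {
    for (f in 1:3) {
      L <- nchar(seqstr)
      if (L - f + 1 < 3) next
      last <- f + ((L - f + 1) %/% 3) * 3 - 1
      codons <- substring(seqstr, seq(f, last, 3), seq(f + 2, last, 3))
      atg <- which(codons == "ATG")
      stp <- which(codons %in% .stop_codons())
      if (!length(atg) || !length(stp)) next
      nxt <- stp[findInterval(atg, stp) + 1L]
      # findInterval gives the count of stops <= atg; the next stop index
      ok <- !is.na(nxt)
      if (!any(ok)) next
      len <- nxt[ok] - atg[ok]
      i <- which.max(len)
      if (len[i] > best$length_aa) {
        c_start <- atg[ok][i]; c_end <- nxt[ok][i] - 1L
        nt_start <- f + (c_start - 1L) * 3L
        nt_end <- f + c_end * 3L - 1L
        if (strand_sign < 0) {
          tmp <- nt_start
          nt_start <- n - nt_end + 1L
          nt_end <- n - tmp + 1L
        }
        best <<- list(length_aa = len[i], start = nt_start, end = nt_end,
                      frame = strand_sign * f)
      }
    }
  }
  scan_strand(s, 1L)
  if (frames == "all") {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    scan_strand(rc, -1L)
  }
  tibble::tibble(length_aa = best$length_aa, start = best$start,
                 end = best$end, frame = best$frame)
}

#' Classify candidate homologs as genes or pseudogenes
#'
#' Applies the pseudogene rules to a table of candidate records: a
#' candidate is a pseudogene when it lacks accurate splice sites, matches
#' no EST, has a longest open reading frame below `orf_min_aa` (default
#' 150 aa), or is an intronless copy without a promoter signal (the
#' retrocopy rule). Unknown evidence (NA flags) never triggers pseudogene
#' status by itself; a candidate with no firing rule but incomplete
#' evidence is `"unresolved"`.
#'
#' @param records A data frame with columns `id`, `nt_sequence`, and the
#'   logical (NA-able) evidence flags `has_accurate_splice_sites`,
#'   `has_est_match`, `is_intronless`, `has_promoter_signal`.
#' @param orf_min_aa Minimum ORF length in amino acids.
#' @param frames Passed to [longest_orf()].
#' @return `records` with added columns `orf_length_aa`, `status`
#'   (`"gene"`, `"pseudogene"`, `"unresolved"`), `reasons` (semicolon-joined
#'   triggered rules).
#' @export
classify_candidates <- function(records, orf_min_aa = 150,
                                frames = "forward") {
  needed <- c("id", "nt_sequence", "has_accurate_splice_sites",
              "has_est_match", "is_intronless", "has_promoter_signal")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("records lack columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  rows <- purrr::pmap(records[needed], function(id, nt_sequence,
                                                has_accurate_splice_sites,
                                                has_est_match, is_intronless,
                                                has_promoter_signal) {
    orf <- longest_orf(nt_sequence, frames = frames)$length_aa
    reasons <- character()
    if (isFALSE(has_accurate_splice_sites))
      reasons <- c(reasons, "no accurate splice sites")
    if (isFALSE(has_est_match)) reasons <- c(reasons, "no EST match")
    if (orf < orf_min_aa)
      reasons <- c(reasons, paste0("ORF < ", orf_min_aa, " aa"))
    if (isTRUE(is_intronless) && isFALSE(has_promoter_signal))
      reasons <- c(reasons, "intronless without promoter signal")
    unknown <- is.na(has_accurate_splice_sites) || is.na(has_est_match) ||
      (isTRUE(is_intronless) && is.na(has_promoter_signal))
    status <- if (length(reasons)) "pseudogene"
      else if (unknown) "unresolved" else "gene"
    if (!length(reasons) && unknown) reasons <- "unresolved evidence"
    tibble::tibble(orf_length_aa = orf, status = status,
                   reasons = paste(reasons, collapse = "; "))
  })
  dplyr::bind_cols(tibble::as_tibble(records), dplyr::bind_rows(rows))
}

#' Coverage and identity of a candidate against a reference
#'
#' Semi-global (end-gap-free) pairwise alignment of the candidate to the
#' reference with match +1, mismatch -1, gap open -4, gap extend -1
#' (configurable). Coverage is the percentage of reference positions
#' aligned to a non-gap candidate position; identity is matches over
#' aligned columns that are gapped in neither sequence.
#'
#' @param candidate_nt,reference_nt Nucleotide strings.
#' @param match,mismatch,gap_open,gap_extend Scoring scheme; `gap_open` is
#'   the total cost of the first gap position.
#' @return A one-row tibble: `coverage_pct`, `identity_pct`, `score`.
#' @export
pairwise_coverage_identity <- function(candidate_nt, reference_nt,
                                       match = 1, mismatch = -1,
                                       gap_open = 4, gap_extend = 1) {
  if (!nzchar(candidate_nt) || !nzchar(reference_nt))
    stop("sequences must be non-empty", call. = FALSE)
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(
    toupper(candidate_nt), toupper(reference_nt), type = "overlap",
    substitutionMatrix = sub,
    gapOpening = gap_open - gap_extend, gapExtension = gap_extend)
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  both <- p != "-" & s != "-"
  covered <- sum(s != "-" & p != "-")
  matches <- sum(p[both] == s[both])
  tibble::tibble(
    coverage_pct = 100 * covered / nchar(reference_nt),
    identity_pct = if (sum(both)) 100 * matches / sum(both) else NA_real_,
    score = Biostrings::score(pa))
}

#' Full QC of candidate homologs against a reference
#'
#' Runs [classify_candidates()] and, when a reference CDS is given,
#' [pairwise_coverage_identity()] per candidate, then flags the records
#' passing the tree-building coverage filter (`coverage_pct >=
#' min_coverage`).
#'
#' @inheritParams classify_candidates
#' @param reference_nt Reference CDS (the X-linked copy in each species);
#'   `NULL` skips coverage/identity.
#' @param min_coverage Coverage threshold (percent) for tree inclusion.
#' @return A tibble: the input columns plus `orf_length_aa`, `status`,
#'   `reasons`, `coverage_pct`, `identity_pct`, `include_in_tree`.
#' @export
qc_candidates <- function(records, reference_nt = NULL, orf_min_aa = 150,
                          min_coverage = 40, frames = "forward") {
  out <- classify_candidates(records, orf_min_aa = orf_min_aa,
                             frames = frames)
  if (!is.null(reference_nt)) {
    ci <- dplyr::bind_rows(purrr::map(out$nt_sequence, function(x)
      pairwise_coverage_identity(x, reference_nt)[, c("coverage_pct",
                                                      "identity_pct")]))
    out <- dplyr::bind_cols(out, ci)
    out$include_in_tree <- out$coverage_pct >= min_coverage
  } else {
    out$coverage_pct <- NA_real_
    out$identity_pct <- NA_real_
    out$include_in_tree <- NA
  }
  out
}

#' Filter QC results for tree building
#'
#' Keeps exactly the records with `coverage_pct >= min_coverage`,
#' preserving order.
#'
#' @param results A data frame with a `coverage_pct` column.
#' @param min_coverage Coverage threshold in percent.
#' @return The filtered subset.
#' @export
filter_for_tree <- function(results, min_coverage = 40) {
  stopifnot("coverage_pct" %in% names(results))
  results[!is.na(results$coverage_pct) &
            results$coverage_pct >= min_coverage, , drop = FALSE]
}

#' Classify residues as buried or exposed
#'
#' A residue is buried when its relative solvent accessibility is below
#' 25%, exposed otherwise.
#'
#' @param rsa A numeric vector of per-residue RSA percentages in [0, 100],
#'   or a data frame with an `rsa` column.
#' @param threshold Buried/exposed boundary (percent).
#' @return A tibble with `residue`, `rsa`, `exposure`.
#' @export
classify_exposure <- function(rsa, threshold = 25) {
  if (is.data.frame(rsa)) {
    stopifnot("rsa" %in% names(rsa))
    vals <- rsa$rsa
    res <- if ("residue" %in% names(rsa)) rsa$residue else seq_along(vals)
  } else {
    vals <- rsa
    res <- seq_along(vals)
  }
  if (any(is.na(vals)) || any(vals < 0 | vals > 100))
    stop("RSA values must lie in [0, 100]", call. = FALSE)
  tibble::tibble(residue = res, rsa = vals,
                 exposure = ifelse(vals < threshold, "buried", "exposed"))
}

#' Read candidate records from FASTA plus metadata TSV
#'
#' Assembles the [qc_candidates()] input table from a FASTA of candidate
#' sequences and a tab-separated metadata table with one row per record
#' (`id`, `species`, `chromosome`, and the evidence flags as
#' true/false/NA).
#'
#' @param fasta_path Candidate sequences (FASTA, nucleotide).
#' @param metadata_path TSV with columns `id`, `species`, `chromosome`,
#'   `is_reciprocal_best_hit`, `has_accurate_splice_sites`,
#'   `has_est_match`, `is_intronless`, `has_promoter_signal`.
#' @return A candidate tibble ready for [qc_candidates()].
#' @export
read_candidates <- function(fasta_path, metadata_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  meta <- utils::read.delim(metadata_path, sep = "\t",
                            stringsAsFactors = FALSE, na.strings = c("NA", ""))
  missing_seq <- setdiff(meta$id, names(seqs))
  if (length(missing_seq))
    stop("no sequence for: ", paste(missing_seq, collapse = ", "),
         call. = FALSE)
  flags <- c("is_reciprocal_best_hit", "has_accurate_splice_sites",
             "has_est_match", "is_intronless", "has_promoter_signal")
  for (f in intersect(flags, names(meta)))
    meta[[f]] <- as.logical(meta[[f]])
  meta$nt_sequence <- as.character(seqs[meta$id])
  tibble::as_tibble(meta)
}
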