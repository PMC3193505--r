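# Standard genetic code tables shared by the simulator, the Ka/Ks counting
# machinery and the codon substitution model. All indices are over the 61
# sense codons in fixed lexicographic (TCAG-free, plain ACGT) order.

.regsel <- new.env(parent = emptyenv())

.nt <- c("A", "C", "G", "T")

.build_code_tables <- function() {
  if (!is.null(.regsel$sense_codons)) return(invisible())
  all_codons <- as.vector(outer(outer(.nt, .nt, paste0), .nt, paste0))
  all_codons <- sort(all_codons)
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[all_codons])
  stops <- all_codons[aa == "*"]
  sense <- all_codons[aa != "*"]
  .regsel$all_codons <- all_codons
  .regsel$stop_codons <- stops
  .regsel$sense_codons <- sense
  .regsel$sense_aa <- unname(gc[sense])
  .regsel$codon_index <- stats::setNames(seq_along(sense), sense)

  # single-nucleotide neighbour structure among sense codons
  n <- length(sense)
  mat <- matrix(unlist(strsplit(sense, "")), nrow = n, byrow = TRUE)
  diff_count <- matrix(0L, n, n)
  for (p in 1:3) diff_count <- diff_count + outer(mat[, p], mat[, p], "!=")
  one_step <- diff_count == 1L
  is_ts <- matrix(FALSE, n, n)   # transition (A<->G, C<->T) at the differing site
  for (p in 1:3) {
    d <- outer(mat[, p], mat[, p], "!=")
    purine <- mat[, p] %in% c("A", "G")
    ts_p <- d & outer(purine, purine, "==")
    is_ts <- is_ts | (ts_p & one_step)
  }
  is_syn <- outer(.regsel$sense_aa, .regsel$sense_aa, "==") & one_step
  .regsel$one_step <- one_step
  .regsel$is_transition <- is_ts & one_step
  .regsel$is_synonymous <- is_syn
  invisible()
}

.sense_codons <- function() {
  .build_code_tables()
  .regsel$sense_codons
}

.stop_codons <- function() {
  .build_code_tables()
  .regsel$stop_codons
}

.codon_to_aa <- function(codon) {
  .build_code_tables()
  unname(Biostrings::GENETIC_CODE[codon])
}

.split_codons <- function(nt_sequence) {
  n <- nchar(nt_sequence)
  if (n %% 3L != 0L)
    stop("sequence length ", n, " is not a multiple of 3", call. = FALSE)
  substring(nt_sequence, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Translate a coding sequence under the standard genetic code
#'
#' @param nt_sequence A nucleotide string whose length is a multiple of 3.
#'   Gap codons (`"---"`) translate to `"-"`; stop codons to `"*"`.
#' @return A single amino-acid string.
#' @export
translate_cds <- function(nt_sequence) {
  .build_code_tables()
  codons <- toupper(.split_codons(nt_sequence))
  aa <- character(length(codons))
  gap <- codons == "---"
  aa[gap] <- "-"
  known <- !gap & codons %in% names(Biostrings::GENETIC_CODE)
  aa[known] <- unname(Biostrings::GENETIC_CODE[codons[known]])
  aa[!gap & !known] <- "X"
  paste(aa, collapse = "")
}
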