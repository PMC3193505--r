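# Molecular-clock dating of a duplication/retroposition event: corrected
# pairwise distances, lineage rate calibration against a dated species
# split, and the dating identity T = K / (2 * mean(gamma)).

#' Corrected pairwise nucleotide distance
#'
#' Proportion-based distance between two aligned nucleotide rows with
#' Jukes-Cantor (JC69) or Kimura two-parameter (K2P) correction. Columns
#' with a gap or ambiguity in either row are skipped. When the correction
#' is undefined (saturation) `NA` is returned with a warning.
#'
#' @param seq1,seq2 Aligned nucleotide strings of equal length.
#' @param model `"K2P"` (default) or `"JC69"`.
#' @return Corrected distance in substitutions per site.
#' @export
corrected_distance <- function(seq1, seq2, model = c("K2P", "JC69")) {
  model <- match.arg(model)
  a <- strsplit(toupper(seq1), "")[[1]]
  b <- strsplit(toupper(seq2), "")[[1]]
  if (length(a) != length(b))
    stop("sequences differ in length", call. = FALSE)
  use <- a %in% .nt & b %in% .nt
  a <- a[use]; b <- b[use]
  n <- length(a)
  if (n == 0L) stop("no comparable sites", call. = FALSE)
  if (model == "JC69") {
    p <- mean(a != b)
    if (p >= 0.75) { warning("JC69 correction undefined (saturation)"); return(NA_real_) }
    return(-0.75 * log(1 - 4 * p / 3))
  }
  purine <- c("A", "G")
  ts <- mean(a != b & (a %in% purine) == (b %in% purine))
  tv <- mean(a != b & (a %in% purine) != (b %in% purine))
  w1 <- 1 - 2 * ts - tv
  w2 <- 1 - 2 * tv
  if (w1 <= 0 || w2 <= 0) {
    warning("K2P correction undefined (saturation)")
    return(NA_real_)
  }
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Calibrate a lineage substitution rate
#'
#' Given the corrected distance `K_cal` between two lineages that diverged
#' `T_cal` million years ago, the per-lineage rate is
#' `gamma = K_cal / (2 * T_cal)` substitutions per site per MY.
#'
#' @param K_cal Corrected pairwise distance (substitutions/site), >= 0.
#' @param T_cal Calibration divergence time in MY, > 0.
#' @return The rate `gamma`.
#' @export
calibrate_rate <- function(K_cal, T_cal) {
  if (!is.numeric(T_cal) || T_cal <= 0)
    stop("T_cal must be > 0", call. = FALSE)
  if (K_cal < 0) stop("K_cal must be >= 0", call. = FALSE)
  K_cal / (2 * T_cal)
}

#' Date a duplication or retroposition event
#'
#' Dates the split of a paralog pair from its corrected divergence
#' `K_paralog` and one or more calibrated lineage rates:
#' `T_dup = K_paralog / (2 * mean(gammas))`, with the arithmetic mean of
#' the per-lineage rates.
#'
#' @param K_paralog Corrected distance between the duplicates
#'   (substitutions/site), >= 0.
#' @param gammas Numeric vector of calibrated lineage rates
#'   (substitutions/site/MY), from [calibrate_rate()].
#' @return A one-row tibble of class `duplication_dating`: `K_paralog`,
#'   `gamma_mean`, `n_calibrations`, `T_dup` (MY). `T_dup` is `NA` when
#'   all rates are zero.
#' @export
date_duplication <- function(K_paralog, gammas) {
  if (K_paralog < 0) stop("K_paralog must be >= 0", call. = FALSE)
  if (!length(gammas) || any(gammas < 0))
    stop("need >= 1 nonnegative calibrated rate", call. = FALSE)
  gm <- mean(gammas)
  T_dup <- if (gm == 0) {
    if (K_paralog == 0) 0 else { warning("zero mean rate"); NA_real_ }
  } else K_paralog / (2 * gm)
  out <- tibble::tibble(K_paralog = K_paralog, gamma_mean = gm,
                        n_calibrations = length(gammas), T_dup = T_dup)
  class(out) <- c("duplication_dating", class(out))
  out
}

#' Date a duplication directly from sequences
#'
#' Convenience wrapper: computes the paralog distance and the calibration
#' distances from aligned sequences, calibrates one rate per calibration
#' pair, and dates the event.
#'
#' @param paralog_pair Character vector of 2 aligned sequences.
#' @param calibrations List of `list(pair = c(seq1, seq2), T_cal = MY)`.
#' @param model Distance model, see [corrected_distance()].
#' @return As [date_duplication()], with a `gammas` attribute.
#' @export
date_duplication_from_sequences <- function(paralog_pair, calibrations,
                                            model = "K2P") {
  stopifnot(length(paralog_pair) == 2L)
  K <- corrected_distance(paralog_pair[1], paralog_pair[2], model = model)
  gammas <- vapply(calibrations, function(cc) {
    Kc <- corrected_distance(cc$pair[1], cc$pair[2], model = model)
    calibrate_rate(Kc, cc$T_cal)
  }, numeric(1))
  out <- date_duplication(K, gammas)
  attr(out, "gammas") <- gammas
  out
}
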