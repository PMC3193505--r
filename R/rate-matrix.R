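# Codon substitution model: a 61-state reversible generator with
# transition/transversion bias (kappa) and nonsynonymous scaling (omega),
# and its transition probabilities via symmetric eigendecomposition.

#' Build a 61-state codon rate matrix
#'
#' Constructs the reversible codon generator used throughout the package:
#' single-nucleotide changes only, rate proportional to the target codon
#' frequency, multiplied by `kappa` for transitions and by `omega` for
#' nonsynonymous changes. The diagonal is set so rows sum to zero and the
#' matrix is rescaled so the expected substitution rate at stationarity is
#' one (branch lengths are then expected substitutions per codon).
#'
#' @param kappa Transition/transversion rate ratio, > 0.
#' @param omega Nonsynonymous/synonymous rate ratio, > 0.
#' @param codon_freqs Either `"equal"` or a numeric vector of 61 stationary
#'   sense-codon frequencies (summing to 1) named or ordered as
#'   [sense_codons()].
#' @param scale `"unit"` (default): rescale so the expected substitution
#'   rate at stationarity is 1 for this generator, i.e. branch lengths are
#'   expected substitutions per codon under this omega. `"neutral"`: apply
#'   the common factor that makes the omega = 1 generator unit-rate, so
#'   that site classes sharing a branch length differ in rate (omega > 1
#'   classes evolve faster); this shared scaling is what the mixture models
#'   and the simulator use.
#' @return A 61 x 61 generator matrix with `rownames`/`colnames` the sense
#'   codons and attribute `"freqs"` carrying the stationary distribution.
#' @export
codon_rate_matrix <- function(kappa, omega, codon_freqs = "equal",
                              scale = c("unit", "neutral")) {
  scale <- match.arg(scale)
  .build_code_tables()
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) || kappa <= 0)
    stop("kappa must be a single positive number", call. = FALSE)
  if (!is.numeric(omega) || length(omega) != 1L || !is.finite(omega) || omega <= 0)
    stop("omega must be a single positive number", call. = FALSE)
  pi <- .resolve_codon_freqs(codon_freqs)
  n <- length(pi)
  Q <- matrix(0, n, n, dimnames = list(.regsel$sense_codons, .regsel$sense_codons))
  step <- .regsel$one_step
  Q[step] <- rep(pi, each = n)[step]   # q_ij proportional to pi_j
  Q[.regsel$is_transition] <- Q[.regsel$is_transition] * kappa
  nonsyn <- step & !.regsel$is_synonymous
  Q[nonsyn] <- Q[nonsyn] * omega
  diag(Q) <- -rowSums(Q)
  rate <- -sum(pi * diag(Q))
  if (rate <= 0) stop("degenerate rate matrix: zero total rate", call. = FALSE)
  if (scale == "neutral" && omega != 1) {
    # mean rate of the unscaled omega = 1 generator with the same kappa/freqs
    A1 <- matrix(0, n, n)
    A1[step] <- rep(pi, each = n)[step]
    A1[.regsel$is_transition] <- A1[.regsel$is_transition] * kappa
    rate <- sum(pi * rowSums(A1))
  }
  Q <- Q / rate
  attr(Q, "freqs") <- pi
  Q
}

#' Sense codons in package order
#'
#' @return Character vector of the 61 sense codons of the standard code, in
#'   the fixed order used by [codon_rate_matrix()] and the simulator.
#' @export
sense_codons <- function() .sense_codons()

.resolve_codon_freqs <- function(codon_freqs) {
  .build_code_tables()
  n <- length(.regsel$sense_codons)
  if (is.character(codon_freqs) && length(codon_freqs) == 1L) {
    if (codon_freqs != "equal")
      stop("unknown codon frequency model: ", codon_freqs, call. = FALSE)
    return(stats::setNames(rep(1 / n, n), .regsel$sense_codons))
  }
  if (!is.numeric(codon_freqs) || length(codon_freqs) != n)
    stop("codon_freqs must be 'equal' or a numeric vector of length ", n,
         call. = FALSE)
  if (!is.null(names(codon_freqs))) {
    if (!setequal(names(codon_freqs), .regsel$sense_codons))
      stop("codon_freqs names must be the 61 sense codons", call. = FALSE)
    codon_freqs <- codon_freqs[.regsel$sense_codons]
  }
  if (any(codon_freqs < 0)) stop("codon frequencies must be >= 0", call. = FALSE)
  s <- sum(codon_freqs)
  if (abs(s - 1) > 1e-8) stop("codon frequencies must sum to 1", call. = FALSE)
  stats::setNames(codon_freqs / s, .regsel$sense_codons)
}

#' Empirical F3x4 codon frequencies from a codon alignment
#'
#' Positional-nucleotide-product ("F3x4") frequencies: the empirical
#' nucleotide composition at each codon position, multiplied across
#' positions, restricted to sense codons and renormalized.
#'
#' @param codon_rows Character matrix or list of codon vectors (3-letter
#'   strings, `"---"` for gaps).
#' @return Named numeric vector of 61 sense-codon frequencies.
#' @export
codon_freqs_f3x4 <- function(codon_rows) {
  .build_code_tables()
  codons <- unlist(codon_rows, use.names = FALSE)
  codons <- codons[codons != "---" & !is.na(codons)]
  if (length(codons) == 0L) stop("no codons to estimate frequencies from", call. = FALSE)
  pos_freq <- lapply(1:3, function(p) {
    nt <- substr(codons, p, p)
    tab <- table(factor(nt, levels = .nt))
    f <- as.numeric(tab)
    if (all(f == 0)) f <- rep(1, 4)
    f / sum(f)
  })
  sc <- .regsel$sense_codons
  f <- pos_freq[[1]][match(substr(sc, 1, 1), .nt)] *
    pos_freq[[2]][match(substr(sc, 2, 2), .nt)] *
    pos_freq[[3]][match(substr(sc, 3, 3), .nt)]
  # zero positional frequencies can zero out codons present in the data; add
  # a small floor so the likelihood stays proper
  f <- pmax(f, 1e-12)
  stats::setNames(f / sum(f), sc)
}

# Eigendecomposition of the reversible generator via its symmetrization
# S = D^{1/2} Q D^{-1/2}; P(t) = D^{-1/2} V exp(Lt) V' D^{1/2}.
.codon_eigen <- function(Q) {
  pi <- attr(Q, "freqs")
  d <- sqrt(pi)
  S <- Q * (d %o% (1 / d))
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(values = e$values,
       left = e$vectors * d,        # D^{1/2} V  (column-scaled by rows)
       right = t(e$vectors / d),    # V' D^{-1/2} transposed for reuse
       inv_d = 1 / d, dmul = d, vectors = e$vectors, freqs = pi)
}

# Transition probability matrix P(t) from a cached eigendecomposition.
.transition_matrix <- function(eig, t) {
  if (t < 0) stop("negative branch length", call. = FALSE)
  if (t == 0) {
    P <- diag(length(eig$values))
    dimnames(P) <- list(names(eig$freqs), names(eig$freqs))
    return(P)
  }
  expl <- exp(eig$values * t)
  P <- (eig$vectors %*% (expl * t(eig$vectors))) * (eig$inv_d %o% eig$dmul)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(names(eig$freqs), names(eig$freqs))
  P
}
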