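# Ka/Ks (dN/dS) estimation by Nei-Gojobori (1986) site counting with
# pathway averaging and Jukes-Cantor correction, the 300 bp / 50 bp
# sliding-window scan, and the two-region comparison that localizes a
# regional shift in selective pressure.

# ---- NG86 lookup tables ----------------------------------------------------

# Per-codon fractional site counts and the pairwise difference-count table
# (averaged over all minimal mutational pathways avoiding stop codons) are
# precomputed once over the 61 sense codons and cached.
.ng86_tables <- function() {
  if (!is.null(.regsel$ng86)) return(.regsel$ng86)
  .build_code_tables()
  sense <- .regsel$sense_codons
  aa <- .regsel$sense_aa
  n <- length(sense)
  stops <- .regsel$stop_codons

  # site counts: at each position, fraction of the 3 single-nucleotide
  # mutants that are synonymous; mutants creating stops count nonsynonymous
  syn_sites <- numeric(n)
  for (i in seq_len(n)) {
    cd <- strsplit(sense[i], "")[[1]]
    syn <- 0L
    for (p in 1:3) for (b in setdiff(.nt, cd[p])) {
      mut <- cd; mut[p] <- b; mut <- paste(mut, collapse = "")
      if (!(mut %in% stops) && .codon_to_aa(mut) == aa[i]) syn <- syn + 1L
    }
    syn_sites[i] <- syn / 3
  }
  nonsyn_sites <- 3 - syn_sites

  # pathway-averaged difference counts for every ordered sense-codon pair
  ND <- matrix(0, n, n); SD <- matrix(0, n, n); OK <- matrix(TRUE, n, n)
  chars <- matrix(unlist(strsplit(sense, "")), nrow = n, byrow = TRUE)
  perms <- list(`1` = list(1L), `2` = list(c(1L, 2L), c(2L, 1L)),
                `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                           c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  code <- Biostrings::GENETIC_CODE
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    dpos <- which(chars[i, ] != chars[j, ])
    k <- length(dpos)
    tot_nd <- 0; tot_sd <- 0; n_ok <- 0L
    for (ord in perms[[as.character(k)]]) {
      cur <- chars[i, ]; nd <- 0; sd <- 0; valid <- TRUE
      for (step in ord) {
        prev <- paste(cur, collapse = "")
        cur[dpos[step]] <- chars[j, dpos[step]]
        nxt <- paste(cur, collapse = "")
        if (nxt %in% stops) { valid <- FALSE; break }
        if (code[[prev]] == code[[nxt]]) sd <- sd + 1 else nd <- nd + 1
      }
      if (valid) { tot_nd <- tot_nd + nd; tot_sd <- tot_sd + sd; n_ok <- n_ok + 1L }
    }
    if (n_ok == 0L) OK[i, j] <- FALSE
    else { ND[i, j] <- tot_nd / n_ok; SD[i, j] <- tot_sd / n_ok }
  }
  .regsel$ng86 <- list(syn_sites = syn_sites, nonsyn_sites = nonsyn_sites,
                       ND = ND, SD = SD, OK = OK)
  .regsel$ng86
}

#' NG86 fractional site counts for one codon
#'
#' Counts, for a sense codon, the expected numbers of nonsynonymous and
#' synonymous sites: at each of the three positions the fraction of the
#' three single-nucleotide mutants that are synonymous contributes to `s`,
#' and `n = 3 - s`. Mutations creating stop codons count as nonsynonymous.
#'
#' @param codon A 3-letter sense codon.
#' @return Named numeric vector `c(n = , s = )`.
#' @export
count_sites_ng86 <- function(codon) {
  tab <- .ng86_tables()
  codon <- toupper(codon)
  if (codon %in% .stop_codons()) stop("stop codon: ", codon, call. = FALSE)
  i <- .regsel$codon_index[[codon]]
  if (is.null(i)) stop("not a valid codon: ", codon, call. = FALSE)
  c(n = tab$nonsyn_sites[i], s = tab$syn_sites[i])
}

.jc_correct <- function(p) {
  ifelse(is.na(p) | p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

# Map codon cells to sense-codon indices; gaps/ambiguities/stops -> NA.
.codon_indices <- function(codons) {
  idx <- .regsel$codon_index[codons]
  unname(ifelse(is.na(idx), NA_integer_, idx))
}

#' Pairwise Ka and Ks by NG86 counting
#'
#' Estimates nonsynonymous (Ka) and synonymous (Ks) substitution rates per
#' site between two codon-aligned sequences: fractional site counts averaged
#' over the two sequences, per-codon difference counts averaged over all
#' minimal mutational pathways avoiding stop codons, and Jukes-Cantor
#' correction of the resulting proportions. Columns with a gap, ambiguity,
#' or stop codon in either row are skipped; codon pairs whose every pathway
#' crosses a stop are skipped and counted in `n_skipped`.
#'
#' @param row1,row2 Codon vectors (3-letter cells) or in-frame nucleotide
#'   strings of equal length.
#' @return A one-row tibble with `N_sites`, `S_sites`, `Nd`, `Sd`, `pN`,
#'   `pS`, `Ka`, `Ks`, `ratio`, `codons_compared`, `n_skipped`. `Ka`/`Ks`
#'   are `NA` when the correction is undefined (p >= 3/4); `ratio` is `NA`
#'   unless `Ks > 0`.
#' @export
pairwise_kaks <- function(row1, row2) {
  tab <- .ng86_tables()
  if (length(row1) == 1L && is.character(row1) && nchar(row1[1]) > 3L)
    row1 <- .split_codons(toupper(row1))
  if (length(row2) == 1L && is.character(row2) && nchar(row2[1]) > 3L)
    row2 <- .split_codons(toupper(row2))
  if (length(row1) != length(row2))
    stop("rows differ in codon length (", length(row1), " vs ",
         length(row2), ")", call. = FALSE)
  i1 <- .codon_indices(toupper(row1))
  i2 <- .codon_indices(toupper(row2))
  use <- !is.na(i1) & !is.na(i2)
  i1 <- i1[use]; i2 <- i2[use]
  pathable <- tab$OK[cbind(i1, i2)]
  n_skipped <- sum(!pathable)
  i1 <- i1[pathable]; i2 <- i2[pathable]
  ncmp <- length(i1)
  N <- (sum(tab$nonsyn_sites[i1]) + sum(tab$nonsyn_sites[i2])) / 2
  S <- (sum(tab$syn_sites[i1]) + sum(tab$syn_sites[i2])) / 2
  Nd <- sum(tab$ND[cbind(i1, i2)])
  Sd <- sum(tab$SD[cbind(i1, i2)])
  pN <- if (N > 0) Nd / N else NA_real_
  pS <- if (S > 0) Sd / S else NA_real_
  Ka <- .jc_correct(pN)
  Ks <- .jc_correct(pS)
  ratio <- if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
  tibble::tibble(N_sites = N, S_sites = S, Nd = Nd, Sd = Sd,
                 pN = pN, pS = pS, Ka = Ka, Ks = Ks, ratio = ratio,
                 codons_compared = ncmp, n_skipped = n_skipped)
}

#' Sliding-window Ka/Ks scan
#'
#' Computes [pairwise_kaks()] in fixed-size windows stepped along the
#' (trimmed) codon alignment. Windows are anchored at nucleotide positions
#' 1, 1+step, 1+2*step, ...; only codons lying entirely inside a window are
#' used; windows with fewer than `min_codons` usable codons are flagged
#' `low_support`.
#'
#' @param row1,row2 Codon vectors or in-frame nucleotide strings of equal
#'   length, codon-aligned.
#' @param window_nt Window width in nucleotides (default 300).
#' @param step_nt Step between window starts in nucleotides (default 50).
#' @param min_codons Usable-codon threshold below which a window is flagged.
#' @return A `kaks_profile`: a tibble with one row per window (`start_nt`,
#'   `end_nt`, `mid_codon`, `codons_used`, the [pairwise_kaks()] columns,
#'   `low_support`) and attributes `window_nt`, `step_nt`.
#' @export
sliding_window_kaks <- function(row1, row2, window_nt = 300, step_nt = 50,
                                min_codons = 10) {
  if (window_nt < 3) stop("window smaller than one codon", call. = FALSE)
  if (step_nt < 1) stop("step must be >= 1 nt", call. = FALSE)
  if (length(row1) == 1L && nchar(row1[1]) > 3L) row1 <- .split_codons(toupper(row1))
  if (length(row2) == 1L && nchar(row2[1]) > 3L) row2 <- .split_codons(toupper(row2))
  if (length(row1) != length(row2)) stop("rows differ in length", call. = FALSE)
  len_nt <- 3L * length(row1)
  if (len_nt < window_nt) stop("alignment shorter than one window", call. = FALSE)
  starts <- seq(1L, len_nt - window_nt + 1L, by = step_nt)
  rows <- purrr::map(starts, function(s) {
    e <- s + window_nt - 1L
    first_codon <- ceiling((s + 2L) / 3L)
    last_codon <- floor(e / 3L)
    span <- seq(first_codon, last_codon)
    kk <- pairwise_kaks(row1[span], row2[span])
    dplyr::bind_cols(tibble::tibble(start_nt = s, end_nt = e,
                                    mid_codon = ceiling(floor((s + e) / 2) / 3),
                                    codons_used = length(span)), kk)
  })
  out <- dplyr::bind_rows(rows)
  out$low_support <- out$codons_used < min_codons
  attr(out, "window_nt") <- window_nt
  attr(out, "step_nt") <- step_nt
  class(out) <- c("kaks_profile", class(out))
  out
}

#' Compare Ka/Ks between two regions of a window profile
#'
#' Assigns each window to the N-terminal or C-terminal region by its
#' midpoint codon (region 1: midpoint `<= boundary_codon`), then compares
#' the per-window Ka/Ks ratios between regions with a two-sided
#' Mann-Whitney U test and reports per-region means and medians. Windows
#' with an undefined ratio are excluded and counted.
#'
#' @param profile A `kaks_profile` from [sliding_window_kaks()], or any
#'   data frame with `mid_codon` and `ratio` columns.
#' @param boundary_codon Last codon of region 1 (default 529, i.e. a
#'   529/530 split).
#' @return A one-row tibble: `boundary_codon`, `n1`, `n2`, `n_undefined`,
#'   `mean1`, `mean2`, `median1`, `median2`, `statistic`, `p_value`.
#' @export
regional_comparison <- function(profile, boundary_codon = 529) {
  stopifnot(all(c("mid_codon", "ratio") %in% names(profile)))
  region <- ifelse(profile$mid_codon <= boundary_codon, 1L, 2L)
  defined <- !is.na(profile$ratio)
  r1 <- profile$ratio[defined & region == 1L]
  r2 <- profile$ratio[defined & region == 2L]
  if (length(r1) < 2L)
    stop("region 1 (N-terminal) has fewer than 2 usable windows", call. = FALSE)
  if (length(r2) < 2L)
    stop("region 2 (C-terminal) has fewer than 2 usable windows", call. = FALSE)
  wt <- suppressWarnings(
    stats::wilcox.test(r1, r2, alternative = "two.sided", exact = FALSE))
  tibble::tibble(boundary_codon = boundary_codon,
                 n1 = length(r1), n2 = length(r2),
                 n_undefined = sum(!defined),
                 mean1 = mean(r1), mean2 = mean(r2),
                 median1 = stats::median(r1), median2 = stats::median(r2),
                 statistic = unname(wt$statistic),
                 p_value = if (identical(r1, r2) ||
                               (stats::var(c(r1, r2)) == 0)) 1 else wt$p.value)
}

#' Estimate the change point of a window-ratio profile
#'
#' Fits every two-segment constant-mean split of the per-window Ka/Ks
#' sequence (undefined ratios dropped) and returns the split minimizing the
#' residual sum of squares, as a codon coordinate halfway between the last
#' window of segment 1 and the first window of segment 2.
#'
#' @param profile As in [regional_comparison()].
#' @return A list with `changepoint_codon`, `split_index`, `sse`.
#' @export
estimate_changepoint <- function(profile) {
  ok <- !is.na(profile$ratio)
  r <- profile$ratio[ok]
  mid <- profile$mid_codon[ok]
  n <- length(r)
  if (n < 4L) stop("need at least 4 defined windows", call. = FALSE)
  sse <- vapply(seq_len(n - 1L), function(k) {
    a <- r[seq_len(k)]; b <- r[seq(k + 1L, n)]
    sum((a - mean(a))^2) + sum((b - mean(b))^2)
  }, numeric(1))
  k <- which.min(sse)
  list(changepoint_codon = (mid[k] + mid[k + 1L]) / 2,
       split_index = k, sse = sse[k])
}
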