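# Independent brute-force oracles used to freeze expected values. These
# deliberately re-derive everything from the genetic code via their own
# minimal code paths, never through the package internals they check.

oracle_code <- Biostrings::GENETIC_CODE
oracle_nt <- c("A", "C", "G", "T")
oracle_stops <- names(oracle_code)[oracle_code == "*"]
oracle_sense <- setdiff(names(oracle_code)[order(names(oracle_code))],
                        oracle_stops)

# NG86 site counts: classify all nine single-nucleotide mutants.
oracle_site_counts <- function(codon) {
  cs <- strsplit(codon, "")[[1]]
  syn <- 0
  for (p in 1:3) for (b in setdiff(oracle_nt, cs[p])) {
    mut <- cs; mut[p] <- b; mut <- paste(mut, collapse = "")
    if (!(mut %in% oracle_stops) &&
        oracle_code[[mut]] == oracle_code[[codon]]) syn <- syn + 1
  }
  c(n = 3 - syn / 3, s = syn / 3)
}

# NG86 difference counts: recursively enumerate all orderings of the
# differing positions, dropping paths through stop codons.
oracle_pair_diffs <- function(c1, c2) {
  a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
  dpos <- which(a != b)
  if (!length(dpos)) return(c(nd = 0, sd = 0, paths = 1))
  walk <- function(cur, remaining) {
    if (!length(remaining)) return(list(c(nd = 0, sd = 0)))
    out <- list()
    for (p in remaining) {
      nxt <- cur; nxt[p] <- b[p]
      nxt_str <- paste(nxt, collapse = "")
      if (nxt_str %in% oracle_stops) next
      step <- if (oracle_code[[paste(cur, collapse = "")]] ==
                  oracle_code[[nxt_str]]) c(nd = 0, sd = 1) else c(nd = 1, sd = 0)
      for (rest in walk(nxt, setdiff(remaining, p)))
        out[[length(out) + 1]] <- step + rest
    }
    out
  }
  paths <- walk(a, dpos)
  if (!length(paths)) return(c(nd = NA_real_, sd = NA_real_, paths = 0))
  m <- do.call(rbind, paths)
  c(nd = mean(m[, "nd"]), sd = mean(m[, "sd"]), paths = nrow(m))
}

# Exhaustive ORF scan: every frame, every ATG, first downstream stop.
oracle_longest_orf <- function(s) {
  s <- toupper(s)
  best <- 0L
  for (f in 1:3) {
    L <- nchar(s)
    n_codon <- (L - f + 1) %/% 3
    if (n_codon < 2) next
    codons <- substring(s, f + 3 * (seq_len(n_codon) - 1),
                        f + 3 * seq_len(n_codon) - 1)
    for (i in which(codons == "ATG")) {
      j <- i + 1
      while (j <= n_codon && !(codons[j] %in% oracle_stops)) j <- j + 1
      if (j <= n_codon && j - i > best) best <- j - i
    }
  }
  best
}

# Semi-global alignment by plain dynamic programming (end gaps free in both
# sequences); affine gaps with first gap position costing `open`.
oracle_semiglobal <- function(a, b, match = 1, mismatch = -1,
                              open = 4, extend = 1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); Ia <- M; Ib <- M  # gap in b / gap in a
  M[1, 1] <- 0
  Ia[, 1] <- 0; Ia[1, ] <- NEG; Ia[1, 1] <- 0   # leading end gaps free
  Ib[1, ] <- 0; Ib[, 1] <- NEG; Ib[1, 1] <- 0
  for (i in 1:n) for (j in 1:m) {
    sc <- if (a[i] == b[j]) match else mismatch
    M[i + 1, j + 1] <- max(M[i, j], Ia[i, j], Ib[i, j]) + sc
    Ia[i + 1, j + 1] <- max(M[i, j + 1] - open, Ia[i, j + 1] - extend)
    Ib[i + 1, j + 1] <- max(M[i + 1, j] - open, Ib[i + 1, j] - extend)
  }
  # free trailing end gaps: best over last row / last column
  max(M[n + 1, ], Ib[n + 1, ], M[, m + 1], Ia[, m + 1])
}

# Brute-force tree likelihood: sum over all internal-node codon states.
oracle_tree_loglik <- function(states, tree, P_list, freqs) {
  freqs <- unname(freqs)
  ntip <- length(tree$tip.label)
  internal <- (ntip + 1):(ntip + tree$Nnode)
  root <- ntip + 1
  nsites <- ncol(states)
  total <- 0
  for (site in seq_len(nsites)) {
    grid <- do.call(expand.grid, rep(list(1:61), length(internal)))
    lik <- 0
    for (g in seq_len(nrow(grid))) {
      assign_state <- integer(ntip + tree$Nnode)
      assign_state[seq_len(ntip)] <- states[, site]
      assign_state[internal] <- as.integer(grid[g, ])
      pr <- freqs[assign_state[root]]
      for (e in seq_len(nrow(tree$edge))) {
        pa <- assign_state[tree$edge[e, 1]]
        ch <- assign_state[tree$edge[e, 2]]
        pr <- pr * P_list[[e]][pa, ch]
      }
      lik <- lik + pr
    }
    total <- total + log(lik)
  }
  total
}

# A fixed balanced 10-taxon tree used for the branch-site study conditions:
# every branch 0.2 substitutions/codon except the foreground stem of the
# (t1, t2) clade at 1.0 (a deeply diverged stem lineage).
power_study_tree <- function() {
  nwk <- paste0("((((t1:0.2,t2:0.2):1.0,(t3:0.2,t4:0.2):0.2):0.2,",
                "((t5:0.2,t6:0.2):0.2,(t7:0.2,t8:0.2):0.2):0.2):0.2,",
                "(t9:0.2,t10:0.2):0.4);")
  tr <- ape::read.tree(text = nwk)
  list(tree = tr,
       fg = which(tr$edge[, 2] == ape::getMRCA(tr, c("t1", "t2"))))
}
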