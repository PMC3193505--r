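# Codon-sequence simulator with site- and branch-heterogeneous omega:
# generates the data structures every downstream stage assumes (regional
# omega profiles, a foreground branch carrying positively selected sites,
# gametolog/retrocopy quartets with known divergence times, pseudogenized
# sequences), so the whole pipeline is testable without external data.

#' Simulation configuration
#'
#' Validates and bundles the parameters of [simulate_codon_alignment()].
#' `site_profile` is a list of site-class mixtures, each applying to a
#' 1-based inclusive codon range; the ranges must tile `1..n_codons`
#' without overlap. Each mixture has proportions `p = (p0, p1, p2a, p2b)`
#' over the four branch-site classes, a purifying `omega0` in (0, 1] and a
#' positive-selection `omega2 >= 1`; classes 2a/2b take `omega2` only on
#' the foreground branches.
#'
#' @param seed Integer seed; all randomness of the dataset flows from it.
#' @param tree An [ape::phylo] with branch lengths in expected
#'   substitutions per codon, or `NULL` to draw a random shape with
#'   `n_taxa` tips scaled to mean root-to-tip depth `depth`.
#' @param n_codons Number of codon sites.
#' @param kappa Transition/transversion rate ratio.
#' @param codon_freqs `"equal"` or 61 stationary sense-codon frequencies.
#' @param site_profile List of mixtures, each
#'   `list(range = c(first, last), p = c(p0, p1, p2a, p2b), omega0, omega2)`;
#'   `range = NULL` means the whole sequence. The default is a purifying
#'   background (`omega0 = 0.1`) with 10% of sites in the
#'   positive-selection classes at `omega2 = 4`.
#' @param foreground_edges Integer edge rows of `tree` treated as
#'   foreground.
#' @param n_taxa,depth Shape parameters used when `tree` is `NULL`.
#' @param pseudogenize Optional named list per taxon:
#'   `list(taxon = list(stop_rate = ...))`; premature stops are injected
#'   into that taxon's row after simulation (frame-preserving, so the
#'   alignment stays valid).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed, tree = NULL, n_codons = 300, kappa = 2,
                       codon_freqs = "equal",
                       site_profile = list(list(
                         range = NULL, p = c(0.45, 0.45, 0.05, 0.05),
                         omega0 = 0.1, omega2 = 4)),
                       foreground_edges = integer(),
                       n_taxa = 8, depth = 0.5,
                       pseudogenize = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (n_codons < 1) stop("n_codons must be >= 1", call. = FALSE)
  if (kappa < 0) stop("kappa must be >= 0", call. = FALSE)
  covered <- rep(FALSE, n_codons)
  for (cls in site_profile) {
    rng <- cls$range %||% c(1L, n_codons)
    if (rng[1] < 1 || rng[2] > n_codons || rng[1] > rng[2])
      stop("site_profile range out of bounds: ", rng[1], "-", rng[2],
           call. = FALSE)
    if (any(covered[rng[1]:rng[2]]))
      stop("site_profile ranges overlap", call. = FALSE)
    covered[rng[1]:rng[2]] <- TRUE
    p <- cls$p
    if (length(p) != 4L || any(p < 0) || abs(sum(p) - 1) > 1e-12)
      stop("mixture proportions must be >= 0 and sum to 1", call. = FALSE)
    if (cls$omega0 <= 0 || cls$omega0 > 1)
      stop("omega0 must lie in (0, 1]", call. = FALSE)
    if (cls$omega2 < 1) stop("omega2 must be >= 1", call. = FALSE)
  }
  if (!all(covered))
    stop("site_profile ranges must tile 1..n_codons", call. = FALSE)
  if (is.null(tree)) {
    set.seed(as.integer(seed))
    tree <- ape::rtree(n_taxa, br = stats::runif)
    dep <- mean(ape::node.depth.edgelength(tree)[seq_len(n_taxa)])
    tree$edge.length <- tree$edge.length * depth / dep
  }
  if (!inherits(tree, "phylo")) stop("tree must be a phylo", call. = FALSE)
  if (any(tree$edge.length < 0)) stop("negative branch lengths", call. = FALSE)
  if (length(foreground_edges) &&
      any(foreground_edges < 1 | foreground_edges > nrow(tree$edge)))
    stop("foreground edge index out of range", call. = FALSE)
  pi <- .resolve_codon_freqs(codon_freqs)
  structure(list(seed = as.integer(seed), tree = tree, n_codons = n_codons,
                 kappa = kappa, codon_freqs = pi, site_profile = site_profile,
                 foreground_edges = as.integer(foreground_edges),
                 pseudogenize = pseudogenize),
            class = "sim_config")
}

#' Simulate a codon alignment under the branch-site process
#'
#' Evolves codon sites independently down the tree under the 61-state model
#' of [codon_rate_matrix()]: the root sequence is drawn from the stationary
#' codon frequencies, and each branch applies the exact transition matrix
#' `exp(t Q(omega))` with the site's class omega on background branches and
#' the foreground omega on marked branches. All classes share the neutral
#' scaling of [codon_rate_matrix()] (`scale = "neutral"`): branch lengths
#' are expected substitutions per codon at omega = 1, so positively
#' selected sites evolve faster and purifying sites slower.
#'
#' @param config A [sim_config()].
#' @return A `simulated_dataset`: `alignment` ([codon_alignment()]), `tree`,
#'   `true_site_class` (per-codon labels `"0"`, `"1"`, `"2a"`, `"2b"`),
#'   `true_omega` (n_codons x n_edges matrix), `config`.
#' @export
simulate_codon_alignment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tree <- config$tree
  n_codons <- config$n_codons
  pi <- config$codon_freqs
  ntip <- length(tree$tip.label)
  nedge <- nrow(tree$edge)

  # per-codon site class and omegas
  cls_lab <- c("0", "1", "2a", "2b")
  site_class <- character(n_codons)
  omega_bg <- numeric(n_codons); omega_fg <- numeric(n_codons)
  for (cls in config$site_profile) {
    rng <- cls$range %||% c(1L, n_codons)
    idx <- rng[1]:rng[2]
    draw <- sample.int(4L, length(idx), replace = TRUE, prob = cls$p)
    site_class[idx] <- cls_lab[draw]
    omega_bg[idx] <- c(cls$omega0, 1, cls$omega0, 1)[draw]
    omega_fg[idx] <- c(cls$omega0, 1, cls$omega2, cls$omega2)[draw]
  }

  true_omega <- matrix(omega_bg, n_codons, nedge)
  if (length(config$foreground_edges))
    true_omega[, config$foreground_edges] <- omega_fg

  # eigendecompositions per distinct omega actually used
  omegas <- sort(unique(as.vector(true_omega)))
  eigs <- lapply(omegas, function(w)
    .codon_eigen(codon_rate_matrix(max(config$kappa, 1e-8), w, pi, scale = "neutral")))

  preorder <- rev(ape::reorder.phylo(tree, "postorder", index.only = TRUE))
  states <- matrix(NA_integer_, ntip + tree$Nnode, n_codons)
  root <- tree$edge[preorder[1], 1]
  states[root, ] <- sample.int(61L, n_codons, replace = TRUE, prob = pi)
  for (e in preorder) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    t_e <- tree$edge.length[e]
    child <- states[p, ]
    if (t_e > 0) {
      w_here <- true_omega[, e]
      for (w in unique(w_here)) {
        P <- .transition_matrix(eigs[[match(w, omegas)]], t_e)
        sites_w <- which(w_here == w)
        par_states <- states[p, sites_w]
        for (s in unique(par_states)) {
          at <- sites_w[par_states == s]
          child[at] <- sample.int(61L, length(at), replace = TRUE, prob = P[s, ])
        }
      }
    }
    states[ch, ] <- child
  }

  codons <- matrix(.sense_codons()[states[seq_len(ntip), ]], ntip,
                   dimnames = list(tree$tip.label, NULL))

  if (!is.null(config$pseudogenize)) {
    for (tx in names(config$pseudogenize)) {
      rate <- config$pseudogenize[[tx]]$stop_rate %||% 0.02
      hit <- stats::runif(n_codons) < rate
      if (any(hit))
        codons[tx, hit] <- sample(.stop_codons(), sum(hit), replace = TRUE)
    }
  }

  structure(list(alignment = codon_alignment(codons,
                                             allow_stops = !is.null(config$pseudogenize)),
                 tree = tree, true_site_class = site_class,
                 true_omega = true_omega, config = config),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("<simulated_dataset> ", length(x$tree$tip.label), " taxa x ",
      x$config$n_codons, " codons; foreground edges: ",
      paste(x$config$foreground_edges, collapse = ","), "\n", sep = "")
  invisible(x)
}

#' Simulate a gametolog/retrocopy quartet with known divergence times
#'
#' Generates four nucleotide sequences on the dated topology
#' `(Y, (retro, (X, cal)))`: the X/Y gametolog split at `t_split_xy`, the
#' retroposition of the autosomal copy from the X lineage at `t_retro`, and
#' a calibration ortholog of X at `t_cal` (million years ago, with
#' `t_split_xy >= t_retro >= t_cal`). Each lineage evolves under a
#' Jukes-Cantor process at its own rate, so the expected corrected distance
#' between lineages i and j separated for T MY is `(gamma_i + gamma_j) T`.
#' Used to test molecular-clock dating round trips.
#'
#' @param seed Integer seed.
#' @param t_split_xy,t_retro,t_cal Divergence times in MY.
#' @param gamma_by_lineage Substitution rate per site per MY: a single
#'   number, or a named vector with entries `X`, `Y`, `retro`, `cal`.
#' @param n_sites Sequence length.
#' @return A `gametolog_trio` list: `sequences` (named character: X, Y,
#'   retro, cal), `times`, `rates`.
#' @export
simulate_gametolog_trio <- function(seed, t_split_xy, t_retro, t_cal,
                                    gamma_by_lineage, n_sites = 10000) {
  if (any(c(t_split_xy, t_retro, t_cal) < 0))
    stop("times must be >= 0", call. = FALSE)
  if (!(t_split_xy >= t_retro && t_retro >= t_cal))
    stop("need t_split_xy >= t_retro >= t_cal", call. = FALSE)
  g <- gamma_by_lineage
  if (length(g) == 1L && is.null(names(g)))
    g <- c(X = g, Y = g, retro = g, cal = g)
  if (!all(c("X", "Y", "retro", "cal") %in% names(g)))
    stop("gamma_by_lineage must name X, Y, retro, cal (or be a scalar)",
         call. = FALSE)
  if (any(g < 0)) stop("rates must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  root <- sample.int(4L, n_sites, replace = TRUE)
  evolve <- function(s, rate, t) {
    if (rate * t == 0) return(s)
    p_change <- 0.75 * (1 - exp(-4 * rate * t / 3))
    hit <- stats::runif(length(s)) < p_change
    if (any(hit))  # uniform over the three other bases
      s[hit] <- ((s[hit] - 1L + sample.int(3L, sum(hit), replace = TRUE)) %% 4L) + 1L
    s
  }
  Y <- evolve(root, g[["Y"]], t_split_xy)
  n1 <- evolve(root, g[["X"]], t_split_xy - t_retro)
  retro <- evolve(n1, g[["retro"]], t_retro)
  n2 <- evolve(n1, g[["X"]], t_retro - t_cal)
  X <- evolve(n2, g[["X"]], t_cal)
  cal <- evolve(n2, g[["cal"]], t_cal)
  tostr <- function(s) paste(.nt[s], collapse = "")
  structure(list(sequences = c(X = tostr(X), Y = tostr(Y),
                               retro = tostr(retro), cal = tostr(cal)),
                 times = c(t_split_xy = t_split_xy, t_retro = t_retro,
                           t_cal = t_cal),
                 rates = g[c("X", "Y", "retro", "cal")]),
            class = "gametolog_trio")
}

#' Inject pseudogenizing mutations into a coding sequence
#'
#' Introduces premature stop codons and/or frameshifting indels at the
#' requested per-codon / per-nucleotide rates. With both rates zero the
#' input is returned unchanged.
#'
#' @param seq A nucleotide string (in-frame coding sequence).
#' @param seed Integer seed.
#' @param stop_rate Per-codon probability of replacement by a stop codon.
#' @param indel_rate Per-nucleotide probability of a 1-2 nt insertion or
#'   deletion.
#' @return The mutated sequence string.
#' @export
inject_pseudogenization <- function(seq, seed, stop_rate = 0, indel_rate = 0) {
  if (stop_rate == 0 && indel_rate == 0) return(seq)
  set.seed(as.integer(seed))
  codons <- .split_codons(toupper(seq))
  if (stop_rate > 0) {
    hit <- stats::runif(length(codons)) < stop_rate
    if (any(hit))
      codons[hit] <- sample(.stop_codons(), sum(hit), replace = TRUE)
  }
  nt <- strsplit(paste(codons, collapse = ""), "")[[1]]
  if (indel_rate > 0) {
    hit <- which(stats::runif(length(nt)) < indel_rate)
    for (pos in rev(hit)) {  # back to front so positions stay valid
      len <- sample.int(2L, 1L)
      if (stats::runif(1) < 0.5) {
        ins <- sample(.nt, len, replace = TRUE)
        nt <- append(nt, ins, after = pos)
      } else {
        drop <- pos:min(pos + len - 1L, length(nt))
        nt <- nt[-drop]
      }
    }
  }
  paste(nt, collapse = "")
}

#' Write a simulated dataset to plain-text files
#'
#' Writes the alignment (FASTA), the tree with foreground marks (Newick),
#' the true site classes (TSV), and an echo of the configuration
#' (key-value text) into a directory.
#'
#' @param dataset A `simulated_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "simulated_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(dataset$alignment, file.path(dir, "alignment.fasta"))
  fg <- logical(nrow(dataset$tree$edge))
  fg[dataset$config$foreground_edges] <- TRUE
  write_labeled_tree(dataset$tree, file.path(dir, "tree.nwk"), foreground = fg)
  utils::write.table(
    data.frame(codon = seq_along(dataset$true_site_class),
               class = dataset$true_site_class),
    file.path(dir, "true_site_classes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- dataset$config
  writeLines(c(
    paste0("seed\t", cfg$seed),
    paste0("n_codons\t", cfg$n_codons),
    paste0("kappa\t", cfg$kappa),
    paste0("n_taxa\t", length(cfg$tree$tip.label)),
    paste0("foreground_edges\t", paste(cfg$foreground_edges, collapse = ",")),
    vapply(seq_along(cfg$site_profile), function(i) {
      cl <- cfg$site_profile[[i]]
      rng <- cl$range %||% c(1L, cfg$n_codons)
      paste0("site_profile.", i, "\trange=", rng[1], "-", rng[2],
             " p=", paste(cl$p, collapse = ","),
             " omega0=", cl$omega0, " omega2=", cl$omega2)
    }, character(1))),
    file.path(dir, "config.txt"))
  invisible(dir)
}
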