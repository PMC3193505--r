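# Phylogenetic likelihood over codon states (Felsenstein pruning with
# per-pattern scaling) and the branch-site positive-selection machinery:
# the single-ratio (M0) fit used to estimate kappa and branch lengths, the
# branch-site model A and its null (omega2 = 1), per-branch likelihood
# ratio tests with Bonferroni correction, and per-site posterior
# identification of positively selected sites (NEB default, coarse-grid
# BEB optional).

# ---- alignment encoding ----------------------------------------------------

.encode_codon_states <- function(alignment) {
  .build_code_tables()
  codons <- .as_codon_matrix(alignment)
  idx <- matrix(.codon_indices(toupper(codons)), nrow(codons),
                dimnames = dimnames(codons))
  stops <- matrix(toupper(codons) %in% .stop_codons(), nrow(codons))
  if (any(stops)) {
    w <- which(stops, arr.ind = TRUE)[1, ]
    stop("in-frame stop codon in row ", rownames(codons)[w[1]],
         ", codon ", w[2], "; mask or remove before analysis", call. = FALSE)
  }
  idx
}

.compress_patterns <- function(states) {
  key <- apply(states, 2L, paste, collapse = ",")
  u <- !duplicated(key)
  pat <- states[, u, drop = FALSE]
  index <- match(key, key[u])
  list(pat = pat, weight = as.numeric(tabulate(index, sum(u))), index = index)
}

# ---- pruning ---------------------------------------------------------------

# Per-pattern log-likelihood by postorder pruning. P_list maps original
# edge-row index -> 61x61 transition matrix. states: n_taxa x npat integer
# matrix (NA = missing). Rows of `states` must be ordered as tree$tip.label.
.prune_loglik <- function(states, tree, edge_order, P_list, freqs) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  npat <- ncol(states)
  lik <- vector("list", nnode)
  logscale <- numeric(npat)
  edge <- tree$edge
  for (e in edge_order) {
    p <- edge[e, 1L]; ch <- edge[e, 2L]
    P <- P_list[[e]]
    if (ch <= ntip) {
      s <- states[ch, ]
      term <- matrix(1, 61L, npat)
      ok <- !is.na(s)
      if (any(ok)) term[, ok] <- P[, s[ok], drop = FALSE]
    } else {
      L <- lik[[ch]]
      sc <- colSums(L)
      sc[sc == 0] <- 1e-300
      L <- L / rep(sc, each = 61L)
      logscale <- logscale + log(sc)
      term <- P %*% L
    }
    lik[[p]] <- if (is.null(lik[[p]])) term else lik[[p]] * term
  }
  root <- edge[edge_order[length(edge_order)], 1L]
  site_l <- as.vector(freqs %*% lik[[root]])
  log(site_l) + logscale
}

# Transition matrices for all edges under a background/foreground omega
# assignment; eigendecompositions are passed in so they can be cached.
.edge_P_list <- function(tree, eig_bg, eig_fg = NULL, fg_edges = integer()) {
  lens <- tree$edge.length
  if (is.null(lens)) stop("tree has no branch lengths", call. = FALSE)
  lapply(seq_len(nrow(tree$edge)), function(e) {
    eg <- if (e %in% fg_edges && !is.null(eig_fg)) eig_fg else eig_bg
    .transition_matrix(eg, lens[e])
  })
}

.check_tree_alignment <- function(states, tree) {
  if (!setequal(rownames(states), tree$tip.label))
    stop("alignment taxa and tree tips differ: missing from tree {",
         paste(setdiff(rownames(states), tree$tip.label), collapse = ","),
         "}, missing from alignment {",
         paste(setdiff(tree$tip.label, rownames(states)), collapse = ","),
         "}", call. = FALSE)
  states[tree$tip.label, , drop = FALSE]
}

#' Codon tree log-likelihood
#'
#' Felsenstein pruning over the 61 sense-codon states with per-pattern
#' scaling, under the codon model of [codon_rate_matrix()]. A single
#' `omega` applies to all branches unless `per_branch_omega` (one value per
#' edge row of `tree`) is given.
#'
#' @param alignment A [codon_alignment()], codon matrix, or named character
#'   vector of in-frame sequences.
#' @param tree An [ape::phylo] with branch lengths in expected
#'   substitutions per codon.
#' @param kappa Transition/transversion ratio.
#' @param omega Single dN/dS applied to every branch.
#' @param codon_freqs `"equal"`, `"f3x4"` (estimated from the alignment),
#'   or 61 frequencies.
#' @param per_branch_omega Optional numeric vector over edge rows.
#' @return Total log-likelihood (numeric scalar) with attribute
#'   `"site_loglik"` carrying the per-site contributions.
#' @export
tree_loglik <- function(alignment, tree, kappa = 2, omega = 1,
                        codon_freqs = "equal", per_branch_omega = NULL) {
  states <- .encode_codon_states(alignment)
  states <- .check_tree_alignment(states, tree)
  if (identical(codon_freqs, "f3x4"))
    codon_freqs <- codon_freqs_f3x4(.as_codon_matrix(alignment))
  pi <- .resolve_codon_freqs(codon_freqs)
  cp <- .compress_patterns(states)
  edge_order <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  if (is.null(per_branch_omega)) per_branch_omega <- rep(omega, nrow(tree$edge))
  if (length(per_branch_omega) != nrow(tree$edge))
    stop("per_branch_omega must have one value per edge", call. = FALSE)
  eigs <- lapply(unique(per_branch_omega), function(w)
    .codon_eigen(codon_rate_matrix(kappa, w, pi, scale = "neutral")))
  names(eigs) <- as.character(unique(per_branch_omega))
  P_list <- lapply(seq_len(nrow(tree$edge)), function(e)
    .transition_matrix(eigs[[as.character(per_branch_omega[e])]],
                       tree$edge.length[e]))
  pat_ll <- .prune_loglik(cp$pat, tree, edge_order, P_list, pi)
  if (any(!is.finite(pat_ll))) {
    bad <- which(!is.finite(pat_ll[cp$index]))[1]
    stop("non-finite site likelihood at codon site ", bad, call. = FALSE)
  }
  ll <- sum(pat_ll * cp$weight)
  attr(ll, "site_loglik") <- pat_ll[cp$index]
  ll
}

# ---- M0 --------------------------------------------------------------------

#' Fit the single-ratio (M0) codon model
#'
#' Maximizes the likelihood over kappa, a single omega, and all branch
#' lengths. Used to fix kappa and branch lengths before the branch-site
#' fits.
#'
#' @inheritParams tree_loglik
#' @param init Optional list with `kappa`, `omega`, `branch_lengths`.
#' @param control Passed to [stats::nlminb()] (`iter.max`, `rel.tol`, ...).
#' @return An object of class `m0_fit`: `kappa`, `omega`, `tree` (with
#'   fitted branch lengths), `lnL`, `codon_freqs`, `convergence`.
#' @export
fit_m0 <- function(alignment, tree, codon_freqs = "equal", init = NULL,
                   control = list(iter.max = 500)) {
  states <- .encode_codon_states(alignment)
  states <- .check_tree_alignment(states, tree)
  if (identical(codon_freqs, "f3x4"))
    codon_freqs <- codon_freqs_f3x4(.as_codon_matrix(alignment))
  pi <- .resolve_codon_freqs(codon_freqs)
  cp <- .compress_patterns(states)
  edge_order <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  nedge <- nrow(tree$edge)

  bl0 <- tree$edge.length
  if (is.null(bl0) || any(!is.finite(bl0)) ) bl0 <- rep(0.1, nedge)
  bl0 <- pmax(bl0, 1e-4)
  k0 <- (init$kappa %||% 2); w0 <- (init$omega %||% 0.4)
  if (!is.null(init$branch_lengths)) bl0 <- pmax(init$branch_lengths, 1e-6)
  x0 <- c(log(k0), log(w0), log(bl0))

  negll <- function(x) {
    kappa <- exp(x[1]); omega <- exp(x[2]); bl <- exp(x[3:(nedge + 2)])
    eig <- .codon_eigen(codon_rate_matrix(kappa, omega, pi, scale = "neutral"))
    P_list <- lapply(seq_len(nedge), function(e) .transition_matrix(eig, bl[e]))
    ll <- sum(.prune_loglik(cp$pat, tree, edge_order, P_list, pi) * cp$weight)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  lower <- c(log(0.02), log(1e-4), rep(log(1e-8), nedge))
  upper <- c(log(50), log(50), rep(log(20), nedge))
  opt <- stats::nlminb(x0, negll, lower = lower, upper = upper,
                       control = control)
  fitted_tree <- tree
  fitted_tree$edge.length <- exp(opt$par[3:(nedge + 2)])
  structure(list(kappa = exp(opt$par[1]), omega = exp(opt$par[2]),
                 tree = fitted_tree, lnL = -opt$objective,
                 codon_freqs = pi, convergence = opt$convergence,
                 message = opt$message),
            class = "m0_fit")
}

#' @export
print.m0_fit <- function(x, ...) {
  cat("<m0_fit> lnL =", format(x$lnL, digits = 10),
      " kappa =", signif(x$kappa, 4), " omega =", signif(x$omega, 4), "\n")
  invisible(x)
}

# ---- branch-site model A / A-null ------------------------------------------

# Map the unconstrained parameter vector to the model-A mixture.
.bs_params <- function(x, null) {
  p01 <- stats::plogis(x[1])
  q <- stats::plogis(x[2])
  w0 <- 1e-4 + (1 - 1e-4) * stats::plogis(x[3])
  w2 <- if (null) 1 else 1 + 49 * stats::plogis(x[4])
  p0 <- p01 * q; p1 <- p01 * (1 - q); p2 <- 1 - p01
  list(p = c(p0 = p0, p1 = p1, p2a = p2 * q, p2b = p2 * (1 - q)),
       omega0 = w0, omega2 = w2)
}

#' Fit branch-site model A or its null
#'
#' Fits the four-class branch-site mixture on a designated foreground
#' branch: site classes with (background, foreground) omega pairs
#' (w0, w0), (1, 1), (w0, w2), (1, w2), with the standard constraint
#' p2a/p0 = p2b/p1. Kappa and branch lengths are held fixed (take them
#' from [fit_m0()]). The null model fixes w2 = 1.
#'
#' @inheritParams tree_loglik
#' @param foreground Edge row index of the foreground branch, or `"mark"`
#'   to use `tree$foreground` as set by [read_labeled_tree()].
#' @param null Fit the A-null model (`omega2` fixed at 1)?
#' @param n_restarts Number of optimizer starts (first from a fixed
#'   default, the rest random); increase for final analyses.
#' @param control Passed to [stats::nlminb()].
#' @return An object of class `branch_site_fit` with the fitted mixture
#'   (`proportions`, `omega0`, `omega2`), `lnL`, per-site class
#'   log-likelihoods, and the inputs needed for [site_posteriors()].
#' @export
fit_branch_site <- function(alignment, tree, foreground, null = FALSE,
                            kappa = 2, codon_freqs = "equal",
                            n_restarts = 1, control = list(iter.max = 400)) {
  states <- .encode_codon_states(alignment)
  states <- .check_tree_alignment(states, tree)
  if (identical(codon_freqs, "f3x4"))
    codon_freqs <- codon_freqs_f3x4(.as_codon_matrix(alignment))
  pi <- .resolve_codon_freqs(codon_freqs)
  cp <- .compress_patterns(states)
  edge_order <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  fg <- .resolve_foreground(tree, foreground)

  eng <- .bs_engine(states, tree, edge_order, cp, pi, kappa, fg)
  npar <- if (null) 3L else 4L
  # start near a mostly purifying mixture with a small, mildly positive
  # class: p0+p1 = 0.9, p0 = p1, omega0 = 0.3, omega2 = 2.5
  starts <- list(c(2.2, 0, -0.85, -3.4)[seq_len(npar)])
  if (n_restarts > 1)
    for (i in seq_len(n_restarts - 1))
      starts[[i + 1]] <- stats::runif(npar, -2, 2)

  best <- NULL
  for (x0 in starts) {
    opt <- stats::nlminb(x0, function(x) eng$negll(x, null), control = control)
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  par <- .bs_params(best$par, null)
  cls <- eng$class_loglik(best$par, null)   # 4 x npat
  structure(list(foreground_edge = fg, null = null,
                 proportions = par$p, omega0 = par$omega0, omega2 = par$omega2,
                 kappa = kappa, codon_freqs = pi, lnL = -best$objective,
                 class_loglik = cls, pattern_index = cp$index,
                 pattern_weight = cp$weight,
                 convergence = best$convergence,
                 engine = eng, par = best$par),
            class = "branch_site_fit")
}

.resolve_foreground <- function(tree, foreground) {
  if (identical(foreground, "mark")) {
    if (is.null(tree$foreground) || !any(tree$foreground))
      stop("no foreground branch marked on the tree", call. = FALSE)
    return(which(tree$foreground))
  }
  if (is.character(foreground)) {
    ids <- branch_ids(tree)
    idx <- match(foreground, ids)
    if (any(is.na(idx)))
      stop("unknown branch id: ", paste(foreground[is.na(idx)], collapse = ", "),
           call. = FALSE)
    return(idx)
  }
  fg <- as.integer(foreground)
  if (any(fg < 1L | fg > nrow(tree$edge)))
    stop("foreground edge index out of range", call. = FALSE)
  fg
}

# Closure bundling the cached quantities of one branch-site optimization:
# the (1,1)-class site likelihoods and the omega = 1 eigendecomposition are
# computed once; each evaluation redoes only what depends on (w0, w2).
.bs_engine <- function(states, tree, edge_order, cp, pi, kappa, fg_edges) {
  pat <- cp$pat
  eig1 <- .codon_eigen(codon_rate_matrix(kappa, 1, pi, scale = "neutral"))
  P1 <- .edge_P_list(tree, eig1)
  ll_class2 <- .prune_loglik(pat, tree, edge_order, P1, pi)

  class_loglik <- function(x, null) {
    p <- .bs_params(x, null)
    eig0 <- .codon_eigen(codon_rate_matrix(kappa, p$omega0, pi, scale = "neutral"))
    P0 <- .edge_P_list(tree, eig0)
    ll1 <- .prune_loglik(pat, tree, edge_order, P0, pi)           # (w0, w0)
    if (null) {
      # (w0, 1) foreground at omega 1
      P3 <- P0; for (e in fg_edges) P3[[e]] <- P1[[e]]
      ll3 <- .prune_loglik(pat, tree, edge_order, P3, pi)
      ll4 <- ll_class2
    } else {
      eig2 <- .codon_eigen(codon_rate_matrix(kappa, p$omega2, pi, scale = "neutral"))
      P3 <- P0; P4 <- P1
      for (e in fg_edges) {
        Pf <- .transition_matrix(eig2, tree$edge.length[e])
        P3[[e]] <- Pf; P4[[e]] <- Pf
      }
      ll3 <- .prune_loglik(pat, tree, edge_order, P3, pi)         # (w0, w2)
      ll4 <- .prune_loglik(pat, tree, edge_order, P4, pi)         # (1, w2)
    }
    rbind(ll1, ll_class2, ll3, ll4)
  }

  negll <- function(x, null) {
    p <- .bs_params(x, null)
    cls <- class_loglik(x, null)
    m <- apply(cls, 2L, max)
    lik <- p$p[1] * exp(cls[1, ] - m) + p$p[2] * exp(cls[2, ] - m) +
      p$p[3] * exp(cls[3, ] - m) + p$p[4] * exp(cls[4, ] - m)
    ll <- sum((log(lik) + m) * cp$weight)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  list(negll = negll, class_loglik = class_loglik, states = states,
       tree = tree, edge_order = edge_order, cp = cp, pi = pi,
       kappa = kappa, fg_edges = fg_edges)
}

#' Likelihood-ratio test for one foreground branch
#'
#' @param lnL_alt,lnL_null Log-likelihoods of model A and A-null.
#' @param n_branches_tested Number of branches in the scan, for the
#'   Bonferroni correction.
#' @return A one-row tibble: `two_delta_lnL`, `p_raw` (upper tail of
#'   chi-square with 1 df), `p_bonferroni`.
#' @export
lrt_branch <- function(lnL_alt, lnL_null, n_branches_tested = 1) {
  two_delta <- 2 * (lnL_alt - lnL_null)
  if (two_delta < -1e-6)
    stop("alternative log-likelihood below null by ", -two_delta / 2,
         "; optimizer failure", call. = FALSE)
  if (two_delta < 0) {
    warning("small negative 2*delta*lnL clamped to 0")
    two_delta <- 0
  }
  p_raw <- stats::pchisq(two_delta, df = 1, lower.tail = FALSE)
  tibble::tibble(two_delta_lnL = two_delta, p_raw = p_raw,
                 p_bonferroni = min(1, p_raw * n_branches_tested))
}

#' Per-site posterior probabilities of positive selection
#'
#' Posterior probability that each codon site belongs to the
#' positive-selection classes (2a + 2b) of a fitted branch-site model A.
#' The default ("NEB") plugs the maximum-likelihood estimates in; "BEB"
#' integrates over a coarse grid on the mixture parameters with uniform
#' priors.
#'
#' @param fit A `branch_site_fit` from the alternative model.
#' @param method `"NEB"` or `"BEB"`.
#' @param grid_points Per-axis grid size for BEB.
#' @return A tibble with `site`, `pp_positive`, `selected_80`,
#'   `selected_90`; attribute `"estimator"` records the method.
#' @export
site_posteriors <- function(fit, method = c("NEB", "BEB"), grid_points = 5) {
  stopifnot(inherits(fit, "branch_site_fit"))
  if (fit$null) stop("posteriors are computed from the alternative fit",
                     call. = FALSE)
  method <- match.arg(method)
  if (method == "NEB") {
    cls <- fit$class_loglik
    p <- fit$proportions
    m <- apply(cls, 2L, max)
    lik <- exp(cls - rep(m, each = 4L)) * p
    post <- lik / rep(colSums(lik), each = 4L)
    pp_pat <- post[3, ] + post[4, ]
  } else {
    eng <- fit$engine
    w <- fit$pattern_weight
    gp <- grid_points
    p01_g <- seq(0.05, 0.95, length.out = gp)
    q_g <- seq(0.05, 0.95, length.out = gp)
    w0_g <- seq(0.05, 0.95, length.out = gp)
    w2_g <- seq(1.5, 11, length.out = gp)
    # likelihood pieces depend on (w0, w2) only; proportions reweight them
    log_w <- c(); pp_list <- list(); k <- 0L
    for (w0 in w0_g) for (w2 in w2_g) {
      x <- c(0, 0, stats::qlogis((w0 - 1e-4) / (1 - 1e-4)),
             stats::qlogis((w2 - 1) / 49))
      cls <- eng$class_loglik(x, null = FALSE)
      m <- apply(cls, 2L, max)
      ecls <- exp(cls - rep(m, each = 4L))
      for (p01 in p01_g) for (q in q_g) {
        p0 <- p01 * q; p1 <- p01 * (1 - q); p2 <- 1 - p01
        pr <- c(p0, p1, p2 * q, p2 * (1 - q))
        lik <- pr[1] * ecls[1, ] + pr[2] * ecls[2, ] +
          pr[3] * ecls[3, ] + pr[4] * ecls[4, ]
        k <- k + 1L
        log_w[k] <- sum((log(lik) + m) * w)
        pp_list[[k]] <- (pr[3] * ecls[3, ] + pr[4] * ecls[4, ]) / lik
      }
    }
    log_w <- log_w - max(log_w)
    wts <- exp(log_w); wts <- wts / sum(wts)
    pp_pat <- Reduce(`+`, Map(`*`, pp_list, wts))
  }
  pp <- pp_pat[fit$pattern_index]
  out <- tibble::tibble(site = seq_along(pp), pp_positive = pp,
                        selected_80 = pp > 0.8, selected_90 = pp > 0.9)
  attr(out, "estimator") <- method
  out
}

#' Branch-site scan over a set of branches
#'
#' Runs the model A / A-null fit pair and the likelihood-ratio test for
#' every branch in `branch_set` (default: all branches), with Bonferroni
#' correction over the number of branches tested, and reports the sites
#' exceeding the 0.8 and 0.9 posterior thresholds for significant
#' branches. Branch lengths and kappa are taken from an M0 fit unless
#' supplied.
#'
#' @inheritParams tree_loglik
#' @param branch_set Integer edge rows to test (default all edges).
#' @param m0 Optional precomputed [fit_m0()] result.
#' @param alpha Significance level on the Bonferroni-corrected p-value.
#' @param posterior_method Passed to [site_posteriors()].
#' @param n_restarts Passed to [fit_branch_site()].
#' @return A `branch_site_scan` tibble: one row per branch with `branch`,
#'   `lnL_alt`, `lnL_null`, `two_delta_lnL`, `p_raw`, `p_bonferroni`,
#'   `omega2_hat`, `significant`, `n_sites_pp80`, `n_sites_pp90`, and
#'   list-columns `sites_pp80`, `sites_pp90`.
#' @export
scan_all_branches <- function(alignment, tree, branch_set = NULL,
                              codon_freqs = "equal", m0 = NULL,
                              alpha = 0.05, posterior_method = "NEB",
                              n_restarts = 1) {
  if (is.null(m0)) m0 <- fit_m0(alignment, tree, codon_freqs = codon_freqs)
  ftree <- m0$tree
  ftree$foreground <- tree$foreground
  if (is.null(branch_set)) branch_set <- seq_len(nrow(ftree$edge))
  ids <- branch_ids(ftree)
  nb <- length(branch_set)
  rows <- purrr::map(branch_set, function(b) {
    res <- tryCatch({
      alt <- fit_branch_site(alignment, ftree, foreground = b, null = FALSE,
                             kappa = m0$kappa, codon_freqs = m0$codon_freqs,
                             n_restarts = n_restarts)
      nul <- fit_branch_site(alignment, ftree, foreground = b, null = TRUE,
                             kappa = m0$kappa, codon_freqs = m0$codon_freqs,
                             n_restarts = n_restarts)
      lnL_alt <- max(alt$lnL, nul$lnL)  # guard tiny optimizer shortfalls
      lrt <- lrt_branch(lnL_alt, nul$lnL, nb)
      sig <- lrt$p_bonferroni < alpha
      pp <- site_posteriors(alt, method = posterior_method)
      s80 <- pp$site[pp$selected_80]; s90 <- pp$site[pp$selected_90]
      tibble::tibble(branch = ids[b], edge = b,
                     lnL_alt = lnL_alt, lnL_null = nul$lnL,
                     two_delta_lnL = lrt$two_delta_lnL, p_raw = lrt$p_raw,
                     p_bonferroni = lrt$p_bonferroni,
                     omega2_hat = alt$omega2, significant = sig,
                     n_sites_pp80 = length(s80), n_sites_pp90 = length(s90),
                     sites_pp80 = list(s80), sites_pp90 = list(s90),
                     error = NA_character_)
    }, error = function(e) {
      tibble::tibble(branch = ids[b], edge = b, lnL_alt = NA_real_,
                     lnL_null = NA_real_, two_delta_lnL = NA_real_,
                     p_raw = NA_real_, p_bonferroni = NA_real_,
                     omega2_hat = NA_real_, significant = NA,
                     n_sites_pp80 = NA_integer_, n_sites_pp90 = NA_integer_,
                     sites_pp80 = list(integer()), sites_pp90 = list(integer()),
                     error = conditionMessage(e))
    })
    res
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "n_branches_tested") <- nb
  attr(out, "m0") <- m0
  class(out) <- c("branch_site_scan", class(out))
  out
}
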