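# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a branch-site fit into per-site posteriors
#'
#' @param x A `branch_site_fit` (alternative model).
#' @param ... Passed to [site_posteriors()].
#' @return The [site_posteriors()] tibble.
#' @method tidy branch_site_fit
#' @export
tidy.branch_site_fit <- function(x, ...) {
  site_posteriors(x, ...)
}

#' One-row summary of a branch-site fit
#'
#' @param x A `branch_site_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the fitted mixture, omegas, and lnL.
#' @method glance branch_site_fit
#' @export
glance.branch_site_fit <- function(x, ...) {
  tibble::tibble(model = if (x$null) "A-null" else "A",
                 lnL = x$lnL,
                 p0 = x$proportions[["p0"]], p1 = x$proportions[["p1"]],
                 p2a = x$proportions[["p2a"]], p2b = x$proportions[["p2b"]],
                 omega0 = x$omega0, omega2 = x$omega2,
                 kappa = x$kappa, convergence = x$convergence)
}

#' Per-branch tidy view of an M0 fit
#'
#' @param x An `m0_fit`.
#' @param ... Unused.
#' @return A tibble with `branch`, `edge`, `length`.
#' @method tidy m0_fit
#' @export
tidy.m0_fit <- function(x, ...) {
  tibble::tibble(branch = branch_ids(x$tree),
                 edge = seq_len(nrow(x$tree$edge)),
                 length = x$tree$edge.length)
}

#' One-row summary of an M0 fit
#'
#' @param x An `m0_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `kappa`, `omega`, `lnL`, `tree_length`.
#' @method glance m0_fit
#' @export
glance.m0_fit <- function(x, ...) {
  tibble::tibble(kappa = x$kappa, omega = x$omega, lnL = x$lnL,
                 tree_length = sum(x$tree$edge.length),
                 convergence = x$convergence)
}
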