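#' Degree, weighted degree, betweenness and betweenness/degree per drug
#'
#' Degree counts similarity edges; weighted degree sums their weights.
#' Betweenness is computed on the unweighted topology (shortest paths by
#' hop count, endpoints excluded, multiple shortest paths credited
#' fractionally).  Two normalizations are offered:
#'
#' * `mode = "global"` (default): each node's shortest-path count is divided
#'   by the total number of node pairs \eqn{\sigma(G) = \binom{|V|}{2}}, so
#'   values lie in \eqn{[0, 1]}.  This is the normalization the
#'   prioritization score consumes.
#' * `mode = "standard"`: the conventional unnormalized sum of per-pair
#'   path fractions.
#'
#' The ratio `bd` divides betweenness by the unweighted degree; nodes with
#' degree 0 get `bd = 0` by convention.
#'
#' @param g A `ddsn` graph.
#' @param mode Betweenness normalization, `"global"` or `"standard"`.
#' @return A `ddsn_centrality` tibble with columns `drug_id`, `degree`,
#'   `weighted_degree`, `betweenness`, `bd`.
#' @export
drug_centrality <- function(g, mode = c("global", "standard")) {
  stopifnot(inherits(g, "igraph"))
  mode <- arg_match(mode)
  n <- igraph::vcount(g)
  deg <- igraph::degree(g)
  wdeg <- if (igraph::ecount(g) == 0) deg
          else igraph::strength(g, weights = edge_weights(g))
  b <- if (n < 2) rep(0, n)
       else igraph::betweenness(g, directed = FALSE, weights = NA)
  if (mode == "global") b <- b / choose(n, 2)
  out <- tibble(
    drug_id = igraph::V(g)$name,
    degree = as.integer(deg),
    weighted_degree = as.integer(round(wdeg)),
    betweenness = as.numeric(b),
    bd = unname(ifelse(deg > 0, as.numeric(b) / deg, 0))
  ) |>
    arrange(.data$drug_id)
  structure(out, class = c("ddsn_centrality", class(out)), mode = mode)
}

#' @method glance ddsn_centrality
#' @export
glance.ddsn_centrality <- function(x, ...) {
  tibble(
    n_drugs = nrow(x),
    mode = attr(x, "mode"),
    max_degree = max(x$degree, 0L),
    max_betweenness = if (nrow(x)) max(x$betweenness) else 0,
    max_bd = if (nrow(x)) max(x$bd) else 0
  )
}

#' Fit a power-law tail to a centrality distribution
#'
#' Clauset-style fit: at each candidate cutoff `xmin` the exponent `alpha`
#' is estimated by maximum likelihood (discrete or continuous, detected
#' from the data), and `xmin` is chosen to minimize the Kolmogorov-Smirnov
#' distance between the tail data and the fitted distribution.  The
#' numerical fit is delegated to the `plfit` implementation in
#' \pkg{igraph}.
#'
#' @param x Positive numeric values (e.g. a column of
#'   [drug_centrality()]); at least 10 distinct values are required.
#' @param xmin Optional fixed cutoff; by default chosen by KS minimization.
#' @return A `ddsn_plfit` object; see [tidy.ddsn_plfit()] for the fitted
#'   `alpha`, `xmin`, KS statistic and tail size.
#' @export
fit_power_law <- function(x, xmin = NULL) {
  x <- x[is.finite(x)]
  if (length(x) == 0 || any(x <= 0)) {
    abort("power-law fitting requires positive values")
  }
  if (dplyr::n_distinct(x) < 2) {
    abort("degenerate input: all values identical, no tail to fit")
  }
  if (dplyr::n_distinct(x) < 10) {
    abort("power-law fitting requires at least 10 distinct values")
  }
  fit <- igraph::fit_power_law(x, xmin = if (is.null(xmin)) NA else xmin,
                               implementation = "plfit")
  structure(
    list(alpha = fit$alpha, xmin = fit$xmin, ks_stat = fit$KS.stat,
         n_tail = sum(x >= fit$xmin), continuous = fit$continuous,
         data = x),
    class = "ddsn_plfit"
  )
}

#' @export
print.ddsn_plfit <- function(x, ...) {
  cat(sprintf(
    "# power-law tail fit: alpha = %.3f, xmin = %g, KS = %.4f, n_tail = %d\n",
    x$alpha, x$xmin, x$ks_stat, x$n_tail
  ))
  invisible(x)
}

#' Tidy a power-law tail fit
#'
#' @param x A `ddsn_plfit` object.
#' @param ... Unused.
#' @return One-row tibble with `alpha`, `xmin`, `ks_stat`, `n_tail`,
#'   `continuous`.
#' @method tidy ddsn_plfit
#' @export
tidy.ddsn_plfit <- function(x, ...) {
  tibble(alpha = x$alpha, xmin = x$xmin, ks_stat = x$ks_stat,
         n_tail = x$n_tail, continuous = x$continuous)
}

#' @method glance ddsn_plfit
#' @export
glance.ddsn_plfit <- function(x, ...) tidy.ddsn_plfit(x)

#' Plot a centrality distribution with its fitted power-law slope
#'
#' Histogram of the values on 8 linearly spaced bins with the fitted tail
#' exponent annotated.
#'
#' @param object A `ddsn_plfit` object.
#' @param bins Number of linearly spaced bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ddsn_plfit
#' @export
autoplot.ddsn_plfit <- function(object, bins = 8, ...) {
  df <- tibble(value = object$data)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey40") +
    ggplot2::geom_vline(xintercept = object$xmin, linetype = 2,
                        colour = "red") +
    ggplot2::labs(
      subtitle = sprintf("alpha = %.3f, xmin = %g", object$alpha,
                         object$xmin)
    ) +
    ggplot2::theme_minimal()
}

#' Sample from a power-law distribution
#'
#' Draws from a (discrete or continuous) power law with density
#' \eqn{p(x) \propto x^{-\alpha}} for \eqn{x \ge x_{min}}, via inverse
#' transform sampling; the discrete support is truncated where the tail
#' mass becomes negligible.  Used to exercise the tail-fitting machinery
#' with known ground truth.
#'
#' @param n Number of draws.
#' @param alpha Exponent, `> 1`.
#' @param xmin Lower cutoff.
#' @param discrete Draw integers (default) or continuous values.
#' @return Numeric vector of length `n`.
#' @export
rplaw <- function(n, alpha = 2.5, xmin = 1, discrete = TRUE) {
  stopifnot(alpha > 1, xmin >= 1, n >= 0)
  if (!discrete) {
    return(xmin * (1 - runif(n))^(-1 / (alpha - 1)))
  }
  support <- seq(from = ceiling(xmin), by = 1, length.out = 2e6)
  p <- support^(-alpha)
  cdf <- cumsum(p) / sum(p)
  support[findInterval(runif(n), cdf) + 1]
}
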