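#' Energy of a 2D layout under the weighted attraction-repulsion model
#'
#' The layout energy of coordinates \eqn{\gamma} is
#' \deqn{E = \sum_{(i,j) \in E} w_{ij} \frac{\delta_{ij}^{a+1}}{a+1}
#'        - \sum_{i < j} w_i w_j \frac{\delta_{ij}^{r+1}}{r+1},}
#' with \eqn{\delta_{ij}} the Euclidean distance, \eqn{w_{ij}} the edge
#' weight, and \eqn{w_i} the weighted degree of node \eqn{i}.  Attraction
#' acts along edges, repulsion between all distinct pairs.  When an
#' exponent makes \eqn{x^{p}/p} degenerate (\eqn{p = 0}) the logarithmic
#' limit \eqn{\ln\delta} is used, which yields the LinLog family.
#'
#' @param g A `ddsn` graph.
#' @param coords Tibble with columns `drug_id`, `x`, `y` covering the nodes
#'   of `g`.
#' @param a Attraction exponent, `a >= 0`.
#' @param r Repulsion exponent, `-1 < r <= 0` (with `r = -1` available as
#'   the logarithmic limit).
#' @return The scalar energy (finite as long as no two nodes coincide).
#' @export
layout_energy <- function(g, coords, a = 1, r = 0) {
  stopifnot(inherits(g, "igraph"), a >= 0, r <= 0)
  xy <- coords_matrix(g, coords)
  D <- as.matrix(stats::dist(xy))
  A <- ddsn_adjacency(g, weighted = TRUE)
  wdeg <- rowSums(A)
  up <- upper.tri(D)
  attraction <- sum(A[up] * power_term(D[up], a + 1))
  repulsion <- sum(outer(wdeg, wdeg)[up] * power_term(D[up], r + 1))
  attraction - repulsion
}

# x^p / p with the p = 0 logarithmic limit
power_term <- function(x, p) {
  if (p == 0) log(x) else x^p / p
}

coords_matrix <- function(g, coords) {
  stopifnot(is.data.frame(coords),
            all(c("drug_id", "x", "y") %in% names(coords)))
  nm <- igraph::V(g)$name
  i <- match(nm, coords$drug_id)
  if (anyNA(i)) abort("coords must cover every node of the graph")
  xy <- cbind(coords$x[i], coords$y[i])
  rownames(xy) <- nm
  if (!all(is.finite(xy))) abort("coordinates must be finite")
  xy
}

#' Energy-model force-directed layout of a DDSN
#'
#' Minimizes the weighted attraction-repulsion energy of [layout_energy()]
#' by gradient descent with an adaptive step and backtracking: a step is
#' only accepted when it lowers the energy, so the final energy never
#' exceeds the initial energy.  Initial coordinates are drawn uniformly at
#' random from the seeded generator, with jitter applied to coincident
#' nodes; the result is deterministic for a fixed seed.
#'
#' @inheritParams layout_energy
#' @param iterations Maximum number of accepted descent steps.
#' @param seed Integer seed for the initial placement.
#' @return A `ddsn_layout` tibble (`drug_id`, `x`, `y`) with attributes
#'   `energy_initial`, `energy_final`, `a`, `r`, `seed`.
#' @export
layout_ddsn <- function(g, a = 1, r = 0, iterations = 400, seed = 1L) {
  stopifnot(inherits(g, "igraph"), a >= 0, r <= 0, r >= -1)
  n <- igraph::vcount(g)
  if (n == 0) abort("cannot lay out an empty graph")
  set.seed(seed)
  side <- max(1, sqrt(n))
  xy <- matrix(runif(2 * n, -side / 2, side / 2), ncol = 2)
  while (anyDuplicated(xy)) {
    xy <- xy + matrix(runif(2 * n, -1e-6, 1e-6), ncol = 2)
  }
  A <- ddsn_adjacency(g, weighted = TRUE)
  wdeg <- rowSums(A)
  R <- outer(wdeg, wdeg)
  diag(R) <- 0

  energy_of <- function(m) {
    D <- as.matrix(stats::dist(m))
    up <- upper.tri(D)
    if (any(D[up] == 0)) return(Inf)
    sum(A[up] * power_term(D[up], a + 1)) -
      sum(R[up] * power_term(D[up], r + 1))
  }
  # gradient wrt node i: sum_j [w_ij d^(a-1) - w_i w_j d^(r-1)] (xi - xj)
  gradient_of <- function(m) {
    D <- as.matrix(stats::dist(m))
    diag(D) <- 1
    coef <- A * D^(a - 1) - R * D^(r - 1)
    diag(coef) <- 0
    rs <- rowSums(coef)
    cbind(rs * m[, 1] - drop(coef %*% m[, 1]),
          rs * m[, 2] - drop(coef %*% m[, 2]))
  }

  e <- energy_of(xy)
  e0 <- e
  step <- 0.1
  for (it in seq_len(iterations)) {
    gr <- gradient_of(xy)
    gnorm <- sqrt(max(rowSums(gr^2)))
    if (!is.finite(gnorm) || gnorm < 1e-12) break
    accepted <- FALSE
    for (try in 1:40) {
      cand <- xy - (step / gnorm) * gr
      ec <- energy_of(cand)
      if (is.finite(ec) && ec < e) {
        xy <- cand
        e <- ec
        step <- step * 1.5
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break
  }
  out <- tibble(drug_id = igraph::V(g)$name,
                x = unname(xy[, 1]), y = unname(xy[, 2]))
  structure(out, class = c("ddsn_layout", class(out)),
            energy_initial = e0, energy_final = e,
            a = a, r = r, seed = seed)
}

#' @method glance ddsn_layout
#' @export
glance.ddsn_layout <- function(x, ...) {
  tibble(
    n_drugs = nrow(x),
    energy_initial = attr(x, "energy_initial"),
    energy_final = attr(x, "energy_final"),
    a = attr(x, "a"), r = attr(x, "r"), seed = attr(x, "seed")
  )
}

#' @method autoplot ddsn_layout
#' @export
autoplot.ddsn_layout <- function(object, partition = NULL, ...) {
  pts <- as_tibble(object)
  if (!is.null(partition)) {
    pts <- left_join(pts, partition, by = "drug_id") |>
      mutate(community = factor(.data$community))
    ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y,
                                      colour = .data$community)) +
      ggplot2::geom_point() + ggplot2::coord_equal() +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
      ggplot2::geom_point() + ggplot2::coord_equal() +
      ggplot2::theme_minimal()
  }
}

#' Agreement between spatial layout clusters and modularity communities
#'
#' Clusters the 2D coordinates with k-means (k = number of modularity
#' communities unless overridden; seeded, best of `nstart` restarts) and
#' compares the geometric clustering with the modularity partition via
#' normalized mutual information.  Values near 1 indicate that the energy
#' layout and modularity maximization recover the same community
#' structure.
#'
#' @param coords A `ddsn_layout` (or tibble with `drug_id`, `x`, `y`).
#' @param partition A `ddsn_partition` (or tibble with `drug_id`,
#'   `community`) covering the same drugs.
#' @param k Number of geometric clusters; defaults to the number of
#'   communities in `partition`.
#' @param seed Integer seed for the k-means restarts.
#' @param nstart Number of k-means restarts.
#' @return Normalized mutual information in \eqn{[0, 1]}.
#' @export
layout_partition_nmi <- function(coords, partition, k = NULL, seed = 1L,
                                 nstart = 10) {
  stopifnot(is.data.frame(coords), is.data.frame(partition))
  joined <- inner_join(as_tibble(coords),
                       as_tibble(unclass_partition_safe(partition)),
                       by = "drug_id")
  if (nrow(joined) != nrow(coords) || nrow(joined) != nrow(partition)) {
    abort("coords and partition must cover the same drugs")
  }
  if (is.null(k)) k <- dplyr::n_distinct(joined$community)
  xy <- cbind(joined$x, joined$y)
  k <- min(k, nrow(unique(xy)))
  set.seed(seed)
  km <- kmeans(xy, centers = k, nstart = nstart)
  nmi_labels(km$cluster, joined$community)
}

unclass_partition_safe <- function(x) {
  if (inherits(x, "ddsn_partition")) unclass_partition(x) else x
}

# normalized mutual information between two labelings
nmi_labels <- function(a, b) {
  igraph::compare(as.integer(factor(a)), as.integer(factor(b)),
                  method = "nmi")
}
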