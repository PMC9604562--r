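# Macroscopic topology: centrality summaries, degree distributions against
# Poisson / power-law reference curves, and hub / neighbourhood reports.

#' Centrality summary of a network
#'
#' Reports node count N, link count L, average degree, density, diameter and
#' radius. Two conventions are exposed for the ratio measures: the
#' bipartite-report convention used throughout this pipeline (`k_avg = L/N`,
#' `density = L/(N(N-1))`) and the standard undirected ones
#' (`k_avg_undirected = 2L/N`, `density_undirected = 2L/(N(N-1))`).
#' Diameter and radius are computed on the largest connected component.
#'
#' @param graph a non-empty undirected igraph.
#' @return An object of class `centrality_summary` (a list with `N`, `L`,
#'   `k_avg`, `density`, `diameter`, `radius`, plus the undirected variants
#'   and `largest_component_size`).
#' @export
centrality_summary <- function(graph) {
  if (igraph::vcount(graph) == 0) stop("empty graph: no nodes")
  n <- igraph::vcount(graph)
  l <- igraph::ecount(graph)
  comp <- igraph::components(graph)
  sub <- igraph::induced_subgraph(
    graph, which(comp$membership == which.max(comp$csize)))
  d <- igraph::distances(sub)
  ecc <- apply(d, 1, max)
  structure(list(
    N = n, L = l,
    k_avg = l / n,
    k_avg_undirected = 2 * l / n,
    density = if (n > 1) l / (n * (n - 1)) else 0,
    density_undirected = if (n > 1) 2 * l / (n * (n - 1)) else 0,
    diameter = as.integer(max(ecc)),
    radius = as.integer(min(ecc)),
    largest_component_size = as.integer(max(comp$csize))),
    class = "centrality_summary")
}

#' @export
print.centrality_summary <- function(x, ...) {
  cat(sprintf(
    "N=%d  L=%d  <k>=%.3f  density=%.3g  diameter=%d  radius=%d\n",
    x$N, x$L, x$k_avg, x$density, x$diameter, x$radius))
  if (x$largest_component_size < x$N) {
    cat(sprintf("  (diameter/radius on largest component, %d nodes)\n",
                x$largest_component_size))
  }
  invisible(x)
}

#' Empirical degree distribution
#'
#' @param graph a non-empty undirected igraph, or a numeric degree sequence
#'   (useful for fitting reference curves to externally obtained degrees).
#' @return An object of class `degree_distribution_summary`: `counts` (node
#'   count per observed degree) and `pmf` (fraction per degree), plus the
#'   raw degree sequence.
#' @export
degree_distribution <- function(graph) {
  deg <- if (is.numeric(graph)) {
    if (length(graph) == 0) stop("empty degree sequence")
    graph
  } else {
    if (igraph::vcount(graph) == 0) stop("empty graph: no nodes")
    igraph::degree(graph)
  }
  tab <- table(deg)
  counts <- setNames(as.integer(tab), names(tab))
  structure(list(counts = counts, pmf = counts / sum(counts),
                 degrees = as.integer(deg)),
            class = "degree_distribution_summary")
}

#' @export
print.degree_distribution_summary <- function(x, ...) {
  cat("Degree distribution over", sum(x$counts), "nodes; degrees",
      min(x$degrees), "..", max(x$degrees), "\n")
  invisible(x)
}

# discrete power-law pmf on k >= 1: p(k) = k^-gamma / zeta(gamma)
.powerlaw_pmf <- function(k, gamma) k^(-gamma) / pracma::zeta(gamma)

# discrete MLE with k_min = 1: minimise n log zeta(g) + g sum(log k)
.fit_powerlaw <- function(degrees) {
  stopifnot(all(degrees >= 1))
  slk <- sum(log(degrees))
  n <- length(degrees)
  if (slk == 0) {  # all degrees equal 1: likelihood unbounded in gamma
    return(list(gamma = NA_real_, se = NA_real_, loglik = NA_real_,
                degenerate = TRUE))
  }
  nll <- function(g) n * log(pracma::zeta(g)) + g * slk
  opt <- stats::optimize(nll, interval = c(1.05, 20))
  g <- opt$minimum
  h <- 1e-4
  d2 <- (nll(g + h) - 2 * nll(g) + nll(g - h)) / h^2  # observed information
  list(gamma = g, se = if (d2 > 0) 1 / sqrt(d2) else NA_real_,
       loglik = -opt$objective, degenerate = FALSE)
}

#' Fit Poisson and power-law reference curves to a degree distribution
#'
#' The Poisson rate is the empirical mean of the degree sequence (the rate
#' that models the distribution itself, i.e. 2L/N on a simple graph); the
#' power-law exponent is fitted by discrete maximum likelihood with
#' `k_min = 1`. Both probability curves are returned on the observed degree
#' support together with their log-likelihoods, the basis of the
#' random-versus-scale-free verdict of [long_tail_verdict()].
#'
#' @param distribution a [degree_distribution()] result.
#' @return An object of class `reference_curves`: `lambda`, `gamma`,
#'   `gamma_se`, `support`, `poisson_pmf`, `powerlaw_pmf`,
#'   `loglik_poisson`, `loglik_powerlaw`, `powerlaw_degenerate`.
#' @export
reference_curves <- function(distribution) {
  stopifnot(inherits(distribution, "degree_distribution_summary"))
  deg <- distribution$degrees
  lambda <- mean(deg)
  support <- sort(unique(deg))
  pl <- .fit_powerlaw(deg[deg >= 1])
  if (pl$degenerate) {
    warning("degenerate degree sequence: power-law fit not identifiable; ",
            "Poisson curve still returned")
  }
  structure(list(
    lambda = lambda,
    gamma = pl$gamma, gamma_se = pl$se,
    support = support,
    poisson_pmf = stats::dpois(support, lambda),
    powerlaw_pmf = if (pl$degenerate) rep(NA_real_, length(support))
                   else .powerlaw_pmf(support, pl$gamma),
    loglik_poisson = sum(stats::dpois(deg, lambda, log = TRUE)),
    loglik_powerlaw = if (pl$degenerate) NA_real_
                      else sum(log(.powerlaw_pmf(deg, pl$gamma))),
    powerlaw_degenerate = pl$degenerate),
    class = "reference_curves")
}

#' @export
print.reference_curves <- function(x, ...) {
  cat(sprintf("Poisson lambda = %.3f (loglik %.1f)\n",
              x$lambda, x$loglik_poisson))
  if (x$powerlaw_degenerate) {
    cat("Power law: degenerate fit (all degrees equal)\n")
  } else {
    cat(sprintf("Power law gamma = %.3f (se %.3f, loglik %.1f)\n",
                x$gamma, x$gamma_se, x$loglik_powerlaw))
  }
  invisible(x)
}

#' Classify a degree distribution as scale-free-like or random-like
#'
#' Verdict is `"scale_free_like"` when the discrete power-law fit attains a
#' higher log-likelihood on the degree sequence than the Poisson fit (a
#' long-tail signature), `"random_like"` otherwise. A degenerate
#' single-degree sequence yields `"random_like"` with a warning.
#'
#' @param distribution a [degree_distribution()] result.
#' @param curves optional precomputed [reference_curves()].
#' @return `"scale_free_like"` or `"random_like"`.
#' @export
long_tail_verdict <- function(distribution, curves = NULL) {
  if (is.null(curves)) {
    curves <- suppressWarnings(reference_curves(distribution))
  }
  if (curves$powerlaw_degenerate) {
    warning("degenerate degree sequence; returning 'random_like'")
    return("random_like")
  }
  if (curves$loglik_powerlaw > curves$loglik_poisson) "scale_free_like"
  else "random_like"
}

#' Hub report: maximum-degree feature nodes and their neighbourhoods
#'
#' Ranks non-participant nodes (optionally restricted to given roles) by
#' degree, descending, ties broken by node id, and reports each hub's degree
#' and the average degree of its neighbours. An average neighbour degree
#' near 1 marks a hub-and-spoke pattern (carriers touch only the hub);
#' larger values mark hubs embedded in subnetworks of co-occurring features.
#'
#' @param graph a typed igraph from this package.
#' @param top_k number of hubs to report.
#' @param roles optional character vector of node roles to consider
#'   (default: every non-participant role).
#' @return data.frame with `node`, `label`, `role`, `degree`,
#'   `avg_neighbor_degree`.
#' @export
hub_report <- function(graph, top_k = 3, roles = NULL) {
  stopifnot(top_k >= 1)
  role <- igraph::V(graph)$role
  eligible <- if (is.null(roles)) role != "participant" else role %in% roles
  idx <- which(eligible)
  if (length(idx) == 0) stop("no eligible nodes for the given role filter")
  if (length(idx) < top_k) {
    warning("only ", length(idx), " eligible node(s); returning all")
    top_k <- length(idx)
  }
  deg <- igraph::degree(graph)
  nm <- igraph::V(graph)$name
  ord <- idx[order(-deg[idx], nm[idx])]
  top <- ord[seq_len(top_k)]
  annd <- vapply(top, function(v) {
    nb <- as.integer(igraph::neighbors(graph, v))
    mean(deg[nb])
  }, numeric(1))
  data.frame(node = nm[top], label = igraph::V(graph)$label[top],
             role = role[top], degree = as.integer(deg[top]),
             avg_neighbor_degree = annd, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Plot a degree distribution against its reference curves
#'
#' Log-scale probability-versus-degree plot of the empirical distribution
#' (points) with the fitted Poisson and power-law curves, the visual check
#' used to judge proximity to random versus scale-free structure.
#'
#' @param x a [degree_distribution()] result.
#' @param curves optional [reference_curves()]; fitted if absent.
#' @param k_max optional upper degree cutoff for the x axis.
#' @param p_min lower probability cutoff (default 1e-4).
#' @param ... passed to [plot()].
#' @return Invisibly, the curves object.
#' @export
plot_degree_distribution <- function(x, curves = NULL, k_max = NULL,
                                     p_min = 1e-4, ...) {
  stopifnot(inherits(x, "degree_distribution_summary"))
  if (is.null(curves)) curves <- suppressWarnings(reference_curves(x))
  k <- as.integer(names(x$pmf))
  keep <- if (is.null(k_max)) rep(TRUE, length(k)) else k <= k_max
  plot(k[keep], pmax(x$pmf[keep], p_min), log = "y", pch = 16,
       xlab = "degree k", ylab = "P(k)", ...)
  sup <- curves$support
  keep_s <- if (is.null(k_max)) rep(TRUE, length(sup)) else sup <= k_max
  graphics::lines(sup[keep_s], pmax(curves$poisson_pmf[keep_s], p_min),
                  col = "red")
  if (!curves$powerlaw_degenerate) {
    graphics::lines(sup[keep_s], pmax(curves$powerlaw_pmf[keep_s], p_min),
                    col = "blue")
  }
  graphics::legend("topright", legend = c("observed", "Poisson", "power law"),
                   col = c("black", "red", "blue"), pch = c(16, NA, NA),
                   lty = c(NA, 1, 1), bty = "n")
  invisible(curves)
}
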