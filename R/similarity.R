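# Per-diagnosis similarity networks: co-carrier projection of the bipartite
# participant-feature structure onto gene-gene or GO-GO graphs, with
# components, Louvain communities, modularity and risk annotation.

#' Project a per-diagnosis feature similarity network
#'
#' For one diagnosis, links two feature nodes (genes, or GO terms) when they
#' are carried by at least `min_shared` common participants of that
#' diagnosis. Each edge stores the shared-carrier count (`weight`) and the
#' Jaccard index of the two carrier sets (`jaccard`, a normalized similarity
#' in (0, 1]). This explicit co-carrier projection is the transparent
#' primitive behind generalized-similarity groupings of features shared
#' among similar participants.
#'
#' @param graph a typed igraph containing participant nodes (with the
#'   `diagnosis` vertex attribute) and feature nodes.
#' @param diagnosis diagnosis label selecting the participant set.
#' @param role `"gene"` or `"go"` (the latter pools all three GO aspects).
#' @param min_shared minimum number of shared carriers for an edge
#'   (default 1).
#' @return An object of class `similarity_network`: an igraph of feature
#'   nodes (`graph`), plus `diagnosis`, `role` and the carrier-set sizes.
#' @export
project_similarity <- function(graph, diagnosis, role = c("gene", "go"),
                               min_shared = 1) {
  role <- match.arg(role)
  vrole <- igraph::V(graph)$role
  vdiag <- igraph::V(graph)$diagnosis
  nm <- igraph::V(graph)$name
  p_idx <- which(vrole == "participant" & !is.na(vdiag) & vdiag == diagnosis)
  if (length(p_idx) == 0) {
    stop("empty network: no participants with diagnosis '", diagnosis, "'")
  }
  feat_roles <- if (role == "gene") "gene" else c("go_bp", "go_mf", "go_cc")
  f_idx <- which(vrole %in% feat_roles)
  if (length(f_idx) == 0) stop("graph has no '", role, "' feature nodes")

  el <- igraph::as_edgelist(graph, names = FALSE)
  # participant-feature incidence restricted to this diagnosis
  is_p <- seq_len(igraph::vcount(graph)) %in% p_idx
  is_f <- seq_len(igraph::vcount(graph)) %in% f_idx
  pf <- rbind(el[is_p[el[, 1]] & is_f[el[, 2]], , drop = FALSE],
              el[is_p[el[, 2]] & is_f[el[, 1]], 2:1, drop = FALSE])
  if (nrow(pf) == 0) {
    stop("empty network: no links between '", diagnosis,
         "' participants and ", role, " nodes")
  }
  pi <- match(pf[, 1], p_idx)
  fi <- match(pf[, 2], f_idx)
  A <- Matrix::sparseMatrix(i = pi, j = fi,
                            dims = c(length(p_idx), length(f_idx)), x = 1)
  carried <- which(Matrix::colSums(A) > 0)
  A <- A[, carried, drop = FALSE]
  fnames <- nm[f_idx][carried]
  sizes <- Matrix::colSums(A)
  C <- Matrix::crossprod(A)  # shared-carrier counts
  Cs <- methods::as(Matrix::triu(C, k = 1), "TsparseMatrix")
  keep <- Cs@x >= min_shared
  i <- Cs@i[keep] + 1L
  j <- Cs@j[keep] + 1L
  w <- Cs@x[keep]
  jac <- w / (sizes[i] + sizes[j] - w)
  edges <- data.frame(from = fnames[i], to = fnames[j],
                      weight = w, jaccard = as.numeric(jac),
                      stringsAsFactors = FALSE)
  vl <- igraph::V(graph)$label[f_idx][carried]
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = fnames, label = vl,
                          n_carriers = as.integer(sizes),
                          stringsAsFactors = FALSE))
  structure(list(graph = g, diagnosis = diagnosis, role = role,
                 min_shared = min_shared,
                 carrier_sizes = setNames(as.integer(sizes), fnames)),
            class = "similarity_network")
}

#' @export
print.similarity_network <- function(x, ...) {
  cat(sprintf("%s %s similarity network: %d nodes, %d links (min_shared=%d)\n",
              x$diagnosis, x$role, igraph::vcount(x$graph),
              igraph::ecount(x$graph), x$min_shared))
  invisible(x)
}

#' Connected components of a similarity network
#'
#' @param net a [project_similarity()] result.
#' @return A list with `n_components`, `sizes` and `membership` (an integer
#'   vector named by node; components are numbered in order of their
#'   smallest node id, so the labelling is deterministic).
#' @export
connected_components <- function(net) {
  stopifnot(inherits(net, "similarity_network"))
  g <- net$graph
  if (igraph::vcount(g) == 0) {
    return(list(n_components = 0L, sizes = integer(0),
                membership = setNames(integer(0), character(0))))
  }
  comp <- igraph::components(g)
  nm <- igraph::V(g)$name
  first <- tapply(nm, comp$membership, min)  # smallest node id per component
  rank_of <- rank(first)                     # 1 = component with smallest id
  membership <- setNames(as.integer(rank_of[as.character(comp$membership)]),
                         nm)
  list(n_components = comp$no,
       sizes = as.integer(table(membership)),
       membership = membership)
}

#' Detect communities by weighted modularity optimization
#'
#' Louvain-style multi-level modularity maximization on the normalized
#' (Jaccard) edge weights, seeded for reproducibility. The modularity Q of
#' the returned partition is reported with it.
#'
#' @param net a [project_similarity()] result with at least one node.
#' @param resolution resolution parameter (default 1, classic modularity).
#' @param seed integer RNG seed; the same seed yields the same partition.
#' @param weights `"jaccard"` (default) or `"count"`.
#' @return A list with `membership` (named integer vector), `n_communities`
#'   and `Q`.
#' @export
detect_communities <- function(net, resolution = 1, seed = 1L,
                               weights = c("jaccard", "count")) {
  stopifnot(inherits(net, "similarity_network"))
  weights <- match.arg(weights)
  g <- net$graph
  nm <- igraph::V(g)$name
  if (igraph::ecount(g) == 0) {
    warning("edgeless network: every node is its own community, Q = 0")
    return(list(membership = setNames(seq_along(nm), nm),
                n_communities = length(nm), Q = 0))
  }
  w <- if (weights == "jaccard") igraph::E(g)$jaccard else igraph::E(g)$weight
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, weights = w, resolution = resolution)
  memb <- igraph::membership(cl)
  q <- igraph::modularity(g, memb, weights = w)
  list(membership = setNames(as.integer(memb), nm),
       n_communities = length(unique(memb)), Q = q)
}

#' Annotate a gene similarity network with risk categories
#'
#' Tags each gene node with its risk category (e.g. a SFARI-style score:
#' high_evidence / strong_candidate / suggestive / unscored) and reports the
#' per-category counts.
#'
#' @param net a gene-role [project_similarity()] result.
#' @param genes a gene annotation data.frame with `gene_id` and
#'   `risk_category`.
#' @return `net`, with a `risk_category` vertex attribute on its graph and a
#'   `risk_summary` count table; unknown gene ids are tagged `unscored` with
#'   a warning.
#' @export
annotate_risk <- function(net, genes) {
  stopifnot(inherits(net, "similarity_network"))
  if (net$role != "gene") stop("risk annotation applies to gene networks")
  nm <- igraph::V(net$graph)$name
  idx <- match(nm, genes$gene_id)
  risk <- genes$risk_category[idx]
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " gene node(s) missing from the annotation ",
            "table; tagged 'unscored'")
    risk[is.na(idx)] <- "unscored"
  }
  net$graph <- igraph::set_vertex_attr(net$graph, "risk_category",
                                       value = risk)
  net$risk_summary <- table(factor(risk, levels = RISK_LEVELS))
  net
}
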