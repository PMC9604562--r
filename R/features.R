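# Signed network-importance encoding: each participant becomes a vector over
# feature nodes (genes and/or GO terms), where a feature's value is its
# node importance (degree / total links of its network) multiplied by the
# dosage sign of the participant's link(s), summed over contributing links.

#' Node importance of a feature node
#'
#' The importance of a node is its degree divided by the total number of
#' links in the network it belongs to; an exact ratio in (0, 1].
#'
#' @param graph a non-empty igraph.
#' @param node node name (or names).
#' @return Numeric vector of importances.
#' @export
node_importance <- function(graph, node) {
  l <- igraph::ecount(graph)
  if (l == 0) stop("network has no links")
  idx <- match(node, igraph::V(graph)$name)
  if (anyNA(idx)) stop("node(s) not in graph: ",
                       paste(node[is.na(idx)], collapse = ", "))
  deg <- igraph::degree(graph)[idx]
  if (any(deg == 0)) stop("isolated node has undefined importance")
  setNames(deg / l, node)
}

.importance_table <- function(graph) {
  deg <- igraph::degree(graph)
  setNames(deg / igraph::ecount(graph), igraph::V(graph)$name)
}

.agg_values <- function(contrib) {
  if (nrow(contrib) == 0) {
    return(data.frame(participant_id = character(0),
                      feature_id = character(0), value = numeric(0),
                      stringsAsFactors = FALSE))
  }
  aggregate(value ~ participant_id + feature_id, contrib, sum)
}

.feature_matrix <- function(values, cohort, dataset_kind) {
  # values: data.frame participant_id, feature_id, value (already summed)
  pids <- cohort$participants$participant_id
  feats <- sort(unique(values$feature_id))
  x <- matrix(0, nrow = length(pids), ncol = length(feats),
              dimnames = list(pids, feats))
  if (nrow(values) > 0) {
    x[cbind(match(values$participant_id, pids),
            match(values$feature_id, feats))] <- values$value
  }
  nonzero <- colSums(x != 0) > 0
  x <- x[, nonzero, drop = FALSE]
  structure(list(x = x,
                 labels = setNames(cohort$participants$diagnosis, pids),
                 dataset_kind = dataset_kind),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature matrix [%s]: %d participants x %d features\n",
              x$dataset_kind, nrow(x$x), ncol(x$x)))
  cat("  classes:", paste(sprintf("%s=%d", names(table(x$labels)),
                                  as.integer(table(x$labels))),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Gene-dosage feature matrix
#'
#' Encodes each participant over gene features: the value for gene g is the
#' sum over the participant's distinct signed links (p, g, s) of
#' `s * importance(g)`, with importances taken from the gene dosage network
#' (degree / L). A duplication and a deletion over the same gene cancel to
#' 0. Columns that are zero for every participant are dropped.
#'
#' @param cohort a [cohort_dataset()].
#' @param gene_graph the [build_gene_dosage_network()] graph of the cohort;
#'   built on the fly when omitted.
#' @return A `feature_matrix` (participants x genes, plus class labels).
#' @export
gene_features <- function(cohort, gene_graph = NULL) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  if (is.null(gene_graph)) {
    gene_graph <- build_gene_dosage_network(cohort)
  }
  imp <- .importance_table(gene_graph)
  links <- cohort$gene_links
  contrib <- data.frame(participant_id = links$participant_id,
                        feature_id = links$gene_id,
                        value = links$sign * imp[links$gene_id],
                        stringsAsFactors = FALSE)
  agg <- .agg_values(contrib)
  .feature_matrix(agg, cohort, "gene_dosage")
}

#' GO feature matrix
#'
#' Encodes each participant over GO-term features: the value for term t is
#' the sum, over the participant's distinct signed gene links whose gene is
#' annotated with t, of `s * importance(t)`; a term reached through several
#' duplicated genes accumulates its importance once per contributing link,
#' and mixed dup/del contributions may cancel. Importances come from the
#' participant-GO network.
#'
#' @param cohort a [cohort_dataset()].
#' @param go_graph the [build_go_network()] graph; built on the fly when
#'   omitted.
#' @return A `feature_matrix` (participants x GO terms).
#' @export
go_features <- function(cohort, go_graph = NULL) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  if (is.null(go_graph)) {
    go_graph <- suppressWarnings(build_go_network(cohort))
  }
  imp <- .importance_table(go_graph)
  exp <- suppressWarnings(.expand_links_to_go(cohort))
  contrib <- data.frame(participant_id = exp$participant_id,
                        feature_id = exp$go_id,
                        value = exp$sign * imp[exp$go_id],
                        stringsAsFactors = FALSE)
  agg <- .agg_values(contrib)
  .feature_matrix(agg, cohort, "go")
}

#' Combined gene + GO feature matrix
#'
#' Columns are the union of genes and GO terms, with every importance taken
#' from the combined participant-gene-GO network. Gene columns follow the
#' gene-dosage rule (`s * importance(g)` summed over links). A GO column's
#' value is the sum over the participant's signed links (p, g, s) with g
#' annotated by t of `s * (importance(g) + importance(t))`: the term's value
#' is weighted by the importance of each gene it is reached through, so
#' terms shared by several disrupted genes accumulate more signal.
#'
#' @param cohort a [cohort_dataset()].
#' @param combined_graph the [build_gene_go_network()] graph; built on the
#'   fly when omitted.
#' @return A `feature_matrix` (participants x (genes + GO terms)).
#' @export
gene_go_features <- function(cohort, combined_graph = NULL) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  if (is.null(combined_graph)) {
    combined_graph <- build_gene_go_network(cohort)
  }
  imp <- .importance_table(combined_graph)
  links <- cohort$gene_links
  gene_part <- data.frame(participant_id = links$participant_id,
                          feature_id = links$gene_id,
                          value = links$sign * imp[links$gene_id],
                          stringsAsFactors = FALSE)
  exp <- suppressWarnings(.expand_links_to_go(cohort))
  go_part <- data.frame(
    participant_id = exp$participant_id,
    feature_id = exp$go_id,
    value = exp$sign * (imp[exp$gene_id] + imp[exp$go_id]),
    stringsAsFactors = FALSE)
  contrib <- rbind(gene_part, go_part)
  agg <- .agg_values(contrib)
  .feature_matrix(agg, cohort, "gene_dosage_go")
}

#' Write a feature matrix to TSV
#'
#' Participants x features with a trailing `label` column.
#'
#' @param fm a `feature_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- data.frame(participant_id = rownames(fm$x), fm$x,
                   label = fm$labels[rownames(fm$x)],
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
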