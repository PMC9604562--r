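# Construction of the three undirected typed networks:
#   gene_dosage    : participants -- genes, signed edges
#   go             : participants -- GO terms, sign summed over genes
#   gene_dosage_go : union of both plus unsigned gene--GO annotation edges
# Nodes carry role in {participant, gene, go_bp, go_mf, go_cc}, a display
# label and (participants) the diagnosis; graphs are simple and exclude
# zero-degree entities.

.go_role <- function(aspect) {
  c(biological_process = "go_bp", molecular_function = "go_mf",
    cellular_component = "go_cc")[aspect]
}

# collapse distinct signed links on the same node pair into one edge:
# sign = sum of distinct signs (+1, -1, or 0), mixed = both signs present
.collapse_signed <- function(pairs) {
  key <- paste(pairs$from, pairs$to, sep = "\r")
  sgn <- tapply(pairs$sign, key, sum)
  npos <- tapply(pairs$sign > 0, key, any)
  nneg <- tapply(pairs$sign < 0, key, any)
  ft <- do.call(rbind, strsplit(names(sgn), "\r", fixed = TRUE))
  data.frame(from = ft[, 1], to = ft[, 2],
             sign = as.integer(sgn), mixed = as.logical(npos & nneg),
             stringsAsFactors = FALSE)
}

.typed_graph <- function(edges, roles, labels, diagnoses, name) {
  nodes <- unique(c(edges$from, edges$to))
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = nodes, role = roles[nodes],
                          label = labels[nodes],
                          diagnosis = diagnoses[nodes],
                          stringsAsFactors = FALSE))
  g <- igraph::set_graph_attr(g, "name", name)
  g
}

.node_metadata <- function(cohort) {
  roles <- c(setNames(rep("participant", nrow(cohort$participants)),
                      cohort$participants$participant_id),
             setNames(rep("gene", nrow(cohort$genes)), cohort$genes$gene_id),
             setNames(.go_role(cohort$go_terms$aspect), cohort$go_terms$go_id))
  labels <- c(setNames(cohort$participants$participant_id,
                       cohort$participants$participant_id),
              setNames(cohort$genes$symbol, cohort$genes$gene_id),
              setNames(cohort$go_terms$name, cohort$go_terms$go_id))
  diagnoses <- setNames(rep(NA_character_, length(roles)), names(roles))
  diagnoses[cohort$participants$participant_id] <-
    cohort$participants$diagnosis
  list(roles = roles, labels = labels, diagnoses = diagnoses)
}

#' Build the participant-gene dosage network
#'
#' Each participant is linked to a gene when a duplication or deletion covers
#' it. One simple edge is kept per distinct (participant, gene) pair; its
#' `sign` attribute is +1 when only duplications contributed, -1 when only
#' deletions did, and 0 with `mixed = TRUE` when the participant carries
#' both over the same gene. Entities without links are excluded.
#'
#' @param cohort a [cohort_dataset()].
#' @return An undirected igraph with vertex attributes `role`, `label`,
#'   `diagnosis` and edge attributes `sign`, `mixed`; graph attribute
#'   `name = "gene_dosage"`.
#' @export
build_gene_dosage_network <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  links <- cohort$gene_links
  if (nrow(links) == 0) {
    return(.typed_graph(data.frame(from = character(0), to = character(0),
                                   sign = integer(0), mixed = logical(0)),
                        character(0), character(0), character(0),
                        "gene_dosage"))
  }
  md <- .node_metadata(cohort)
  edges <- .collapse_signed(data.frame(from = links$participant_id,
                                       to = links$gene_id, sign = links$sign,
                                       stringsAsFactors = FALSE))
  .typed_graph(edges, md$roles, md$labels, md$diagnoses, "gene_dosage")
}

# expand signed gene links through the gene->GO map into signed
# participant--GO contributions (one row per link x annotation)
.expand_links_to_go <- function(cohort, warn_uncovered = TRUE) {
  links <- cohort$gene_links
  covered <- unique(cohort$gene_go$gene_id)
  uncovered <- setdiff(unique(links$gene_id), covered)
  if (warn_uncovered && length(uncovered) > 0) {
    warning(length(uncovered), " linked gene(s) have no GO annotation ",
            "and contribute no participant-GO edges: ",
            paste(head(uncovered, 5), collapse = ", "),
            if (length(uncovered) > 5) " ..." else "")
  }
  merge(links, cohort$gene_go[, c("gene_id", "go_id")], by = "gene_id")
}

#' Build the participant-GO network
#'
#' Obtained by replacing each gene with its associated GO terms: an edge
#' (participant, term) exists when the participant has a signed link to at
#' least one gene annotated with the term. The edge `sign` is the sum of the
#' contributing distinct signed gene links (0 is allowed when duplications
#' and deletions balance). Linked genes lacking any GO annotation are
#' reported with a warning; their participants keep their other edges.
#'
#' @inheritParams build_gene_dosage_network
#' @return An undirected igraph (`name = "go"`) with the attributes of
#'   [build_gene_dosage_network()].
#' @export
build_go_network <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  exp <- .expand_links_to_go(cohort)
  if (nrow(exp) == 0) {
    return(.typed_graph(data.frame(from = character(0), to = character(0),
                                   sign = integer(0), mixed = logical(0)),
                        character(0), character(0), character(0), "go"))
  }
  md <- .node_metadata(cohort)
  edges <- .collapse_signed(data.frame(from = exp$participant_id,
                                       to = exp$go_id, sign = exp$sign,
                                       stringsAsFactors = FALSE))
  .typed_graph(edges, md$roles, md$labels, md$diagnoses, "go")
}

#' Build the combined participant-gene-GO network
#'
#' Union of the signed participant-gene edges, the participant-GO edges of
#' [build_go_network()] and unsigned gene-GO annotation edges for every
#' linked gene, joining all three entity types in a single graph.
#'
#' @inheritParams build_gene_dosage_network
#' @return An undirected igraph (`name = "gene_dosage_go"`).
#' @export
build_gene_go_network <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  links <- cohort$gene_links
  if (nrow(links) == 0) {
    return(.typed_graph(data.frame(from = character(0), to = character(0),
                                   sign = integer(0), mixed = logical(0)),
                        character(0), character(0), character(0),
                        "gene_dosage_go"))
  }
  md <- .node_metadata(cohort)
  pg <- .collapse_signed(data.frame(from = links$participant_id,
                                    to = links$gene_id, sign = links$sign,
                                    stringsAsFactors = FALSE))
  exp <- .expand_links_to_go(cohort, warn_uncovered = FALSE)
  pt <- if (nrow(exp) > 0) {
    .collapse_signed(data.frame(from = exp$participant_id, to = exp$go_id,
                                sign = exp$sign, stringsAsFactors = FALSE))
  } else {
    data.frame(from = character(0), to = character(0), sign = integer(0),
               mixed = logical(0), stringsAsFactors = FALSE)
  }
  gt <- unique(exp[, c("gene_id", "go_id")])
  gt <- if (nrow(gt) > 0) {
    data.frame(from = gt$gene_id, to = gt$go_id, sign = NA_integer_,
               mixed = FALSE, stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(0), to = character(0), sign = integer(0),
               mixed = logical(0), stringsAsFactors = FALSE)
  }
  .typed_graph(rbind(pg, pt, gt), md$roles, md$labels, md$diagnoses,
               "gene_dosage_go")
}

#' Serialize a typed network
#'
#' Writes GraphML (roles, labels, diagnoses and edge signs preserved as
#' attributes) or a tab-separated edge list.
#'
#' @param graph an igraph built by this package.
#' @param path output file.
#' @param format `"graphml"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(graph, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    df <- igraph::as_data_frame(graph, what = "edges")
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
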