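#' @importFrom stats rbinom rpois runif sd aggregate setNames predict
#' @importFrom utils read.delim write.table head
#' @importFrom graphics lines legend
NULL

RISK_LEVELS <- c("high_evidence", "strong_candidate", "suggestive", "unscored")
GO_ASPECTS <- c("biological_process", "molecular_function", "cellular_component")

#' Construct a cohort dataset
#'
#' Bundles participants, CNV events, the participant-gene signed link set
#' derived from them, gene annotation and the gene-to-GO map into one
#' validated object. Most users obtain one via [load_cohort()] or
#' [generate_cohort()] rather than calling this directly.
#'
#' @param participants data.frame with columns `participant_id`, `diagnosis`,
#'   `sex` (one row per participant; `sex` defaults to `"not_specified"`).
#' @param events data.frame of CNV events: `participant_id`, `chromosome`,
#'   `start`, `end` (0-based half-open), `dosage` (+1 duplication, -1
#'   deletion) and optional `acmg_class`.
#' @param genes data.frame with `gene_id`, `symbol`, `chromosome`, `start`,
#'   `end`, `risk_category` (defaults to `"unscored"`).
#' @param gene_go data.frame with `gene_id`, `go_id`, `aspect`, `name`; GO
#'   term records are derived from its unique (`go_id`, `name`, `aspect`)
#'   rows.
#' @param gene_links optional data.frame `participant_id`, `gene_id`, `sign`;
#'   when `NULL` it is computed from `events` with [map_cnv_to_genes()].
#' @return An object of class `cohort_dataset` with elements `participants`,
#'   `events`, `genes`, `go_terms`, `gene_go`, `gene_links`.
#' @export
cohort_dataset <- function(participants, events, genes, gene_go,
                           gene_links = NULL) {
  participants <- as.data.frame(participants, stringsAsFactors = FALSE)
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  gene_go <- as.data.frame(gene_go, stringsAsFactors = FALSE)

  .require_cols(participants, c("participant_id", "diagnosis"), "participants")
  .require_cols(events, c("participant_id", "chromosome", "start", "end",
                          "dosage"), "cnvs")
  .require_cols(genes, c("gene_id", "symbol", "chromosome", "start", "end"),
                "genes")
  .require_cols(gene_go, c("gene_id", "go_id"), "gene_go")

  if (is.null(participants$sex)) {
    participants$sex <- rep("not_specified", nrow(participants))
  }
  participants$sex[is.na(participants$sex) | participants$sex == ""] <-
    "not_specified"
  if (is.null(genes$risk_category)) {
    genes$risk_category <- rep("unscored", nrow(genes))
  }
  genes$risk_category[is.na(genes$risk_category) |
                        genes$risk_category == ""] <- "unscored"
  if (is.null(gene_go$aspect)) {
    gene_go$aspect <- rep("biological_process", nrow(gene_go))
  }
  if (is.null(gene_go$name)) gene_go$name <- gene_go$go_id
  if (is.null(events$acmg_class)) {
    events$acmg_class <- rep(NA_character_, nrow(events))
  }

  dup <- unique(participants$participant_id[duplicated(participants$participant_id)])
  if (length(dup) > 0) {
    stop("integrity error: participants with multiple records/diagnoses ",
         "are not admitted: ", paste(head(dup, 10), collapse = ", "))
  }
  if (any(is.na(participants$diagnosis) | participants$diagnosis == "")) {
    stop("schema error: empty diagnosis for participant(s) ",
         paste(head(participants$participant_id[
           is.na(participants$diagnosis) | participants$diagnosis == ""], 10),
           collapse = ", "))
  }
  if (!all(events$dosage %in% c(-1L, 1L))) {
    bad <- which(!(events$dosage %in% c(-1L, 1L)))
    stop("schema error: dosage must be +1 (duplication) or -1 (deletion); ",
         length(bad), " offending CNV row(s), first at row ", bad[1])
  }
  if (any(events$start >= events$end)) {
    stop("schema error: CNV intervals must satisfy start < end ",
         "(0-based half-open)")
  }
  .check_fk(events$participant_id, participants$participant_id,
            "cnvs.participant_id", "participants")
  .check_fk(gene_go$gene_id, genes$gene_id, "gene_go.gene_id", "genes")
  if (anyDuplicated(genes$gene_id)) {
    stop("integrity error: duplicated gene_id in genes table")
  }
  bad_go <- !grepl("^GO:[0-9]{7}$", gene_go$go_id)
  if (any(bad_go)) {
    stop("schema error: go_id not matching 'GO:NNNNNNN': ",
         paste(head(unique(gene_go$go_id[bad_go]), 10), collapse = ", "))
  }
  if (!all(gene_go$aspect %in% GO_ASPECTS)) {
    stop("schema error: aspect must be one of ",
         paste(GO_ASPECTS, collapse = ", "))
  }

  go_terms <- unique(gene_go[, c("go_id", "name", "aspect")])
  conflict <- unique(go_terms$go_id[duplicated(go_terms$go_id)])
  if (length(conflict) > 0) {
    stop("integrity error: conflicting name/aspect for GO term(s) ",
         paste(head(conflict, 10), collapse = ", "))
  }
  go_terms <- go_terms[order(go_terms$go_id), , drop = FALSE]
  rownames(go_terms) <- NULL

  if (is.null(gene_links)) {
    gene_links <- map_cnv_to_genes(events, genes)
  } else {
    gene_links <- as.data.frame(gene_links, stringsAsFactors = FALSE)
    .require_cols(gene_links, c("participant_id", "gene_id", "sign"),
                  "gene_links")
    gene_links <- unique(gene_links)
    .check_fk(gene_links$gene_id, genes$gene_id, "gene_links.gene_id", "genes")
    .check_fk(gene_links$participant_id, participants$participant_id,
              "gene_links.participant_id", "participants")
  }
  gene_links <- gene_links[order(gene_links$participant_id,
                                 gene_links$gene_id, gene_links$sign), ,
                           drop = FALSE]
  rownames(gene_links) <- NULL

  structure(list(participants = participants, events = events, genes = genes,
                 go_terms = go_terms, gene_go = gene_go,
                 gene_links = gene_links),
            class = "cohort_dataset")
}

.require_cols <- function(df, cols, table) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop("schema error: table '", table, "' is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
}

.check_fk <- function(child, parent, what, parent_table) {
  dangling <- unique(child[!(child %in% parent)])
  if (length(dangling) > 0) {
    stop("integrity error: ", what, " values absent from ", parent_table,
         ": ", paste(head(dangling, 10), collapse = ", "),
         if (length(dangling) > 10) " ..." else "")
  }
}

#' Load a cohort from delimited tables
#'
#' Reads the four tab- or comma-separated tables (header row required),
#' validates them and joins them into a [cohort_dataset()]. CNV intervals are
#' mapped to genes by coordinate overlap; genomic coordinates are expected
#' 0-based half-open (use `one_based = TRUE` for 1-based inclusive input,
#' converted at this boundary).
#'
#' @param participants_path,cnv_path,genes_path,gene_go_path file paths.
#' @param sep field separator, default tab.
#' @param one_based logical; input coordinates are 1-based inclusive.
#' @param min_overlap minimum overlapping bases to assign a gene to a CNV.
#' @return A `cohort_dataset`.
#' @export
load_cohort <- function(participants_path, cnv_path, genes_path, gene_go_path,
                        sep = "\t", one_based = FALSE, min_overlap = 1L) {
  rd <- function(p) read.delim(p, sep = sep, stringsAsFactors = FALSE)
  participants <- rd(participants_path)
  events <- rd(cnv_path)
  genes <- rd(genes_path)
  gene_go <- rd(gene_go_path)
  if (is.character(events$dosage)) {
    events$dosage <- ifelse(grepl("^dup", events$dosage, ignore.case = TRUE),
                            1L,
                     ifelse(grepl("^del", events$dosage, ignore.case = TRUE),
                            -1L, suppressWarnings(as.integer(events$dosage))))
  }
  if (one_based) {
    events$start <- events$start - 1L
    genes$start <- genes$start - 1L
  }
  ds <- cohort_dataset(participants, events, genes, gene_go,
                       gene_links = map_cnv_to_genes(events, genes,
                                                     min_overlap = min_overlap))
  ds
}

#' Write a cohort back to delimited tables
#'
#' Inverse of [load_cohort()]: writes `participants.tsv`, `cnvs.tsv`,
#' `genes.tsv` and `gene_go.tsv` under `dir`. Reloading the written tables
#' reproduces the dataset.
#'
#' @param cohort a `cohort_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, name) {
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wr(cohort$participants, "participants.tsv")
  wr(cohort$events, "cnvs.tsv")
  wr(cohort$genes, "genes.tsv")
  wr(cohort$gene_go, "gene_go.tsv")
  invisible(dir)
}

#' Map CNV intervals to genes by coordinate overlap
#'
#' A signed link (participant, gene, sign) is emitted whenever one of the
#' participant's CNVs with that dosage sign overlaps the gene by at least
#' `min_overlap` bases; duplicates collapse to a single link. Coordinates are
#' 0-based half-open, so a CNV ending where a gene starts does not overlap
#' it.
#'
#' @param events CNV data.frame (`participant_id`, `chromosome`, `start`,
#'   `end`, `dosage`).
#' @param genes gene data.frame (`gene_id`, `chromosome`, `start`, `end`).
#' @param min_overlap minimum shared bases (default 1, the most permissive
#'   criterion).
#' @return data.frame with columns `participant_id`, `gene_id`, `sign`.
#' @export
map_cnv_to_genes <- function(events, genes, min_overlap = 1L) {
  empty <- data.frame(participant_id = character(0), gene_id = character(0),
                      sign = integer(0), stringsAsFactors = FALSE)
  if (nrow(events) == 0 || nrow(genes) == 0) return(empty)
  only_ev <- setdiff(unique(events$chromosome), unique(genes$chromosome))
  only_gn <- setdiff(unique(genes$chromosome), unique(events$chromosome))
  if (length(only_ev) > 0 || length(only_gn) > 0) {
    warning("chromosome name mismatch: ", length(only_ev),
            " chromosome(s) only in CNV table, ", length(only_gn),
            " only in gene table")
  }
  lev <- union(unique(events$chromosome), unique(genes$chromosome))
  # 0-based half-open -> IRanges 1-based closed: [start, end) == [start+1, end]
  ev <- GenomicRanges::GRanges(
    seqnames = factor(events$chromosome, levels = lev),
    ranges = IRanges::IRanges(start = events$start + 1L, end = events$end))
  gn <- GenomicRanges::GRanges(
    seqnames = factor(genes$chromosome, levels = lev),
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end))
  hits <- GenomicRanges::findOverlaps(ev, gn, minoverlap = min_overlap)
  links <- data.frame(
    participant_id = events$participant_id[S4Vectors::queryHits(hits)],
    gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
    sign = as.integer(events$dosage[S4Vectors::queryHits(hits)]),
    stringsAsFactors = FALSE)
  links <- unique(links)
  links <- links[order(links$participant_id, links$gene_id, links$sign), ,
                 drop = FALSE]
  rownames(links) <- NULL
  links
}

#' Restrict a cohort to selected diagnoses
#'
#' Keeps only participants whose diagnosis is in `keep`, removing their
#' orphaned CNV events and gene links; gene and GO annotation tables are left
#' untouched.
#'
#' @param cohort a `cohort_dataset`.
#' @param keep non-empty character vector of diagnosis labels.
#' @return A filtered `cohort_dataset`.
#' @export
filter_diagnoses <- function(cohort, keep) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  if (length(keep) == 0) stop("'keep' must name at least one diagnosis")
  sel <- cohort$participants$diagnosis %in% keep
  if (!any(sel)) {
    stop("empty cohort: no participants with diagnosis in {",
         paste(keep, collapse = ", "), "}")
  }
  kept_ids <- cohort$participants$participant_id[sel]
  out <- cohort
  out$participants <- cohort$participants[sel, , drop = FALSE]
  out$events <- cohort$events[cohort$events$participant_id %in% kept_ids, ,
                              drop = FALSE]
  out$gene_links <- cohort$gene_links[
    cohort$gene_links$participant_id %in% kept_ids, , drop = FALSE]
  rownames(out$participants) <- rownames(out$events) <-
    rownames(out$gene_links) <- NULL
  out
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("CNV cohort dataset\n")
  cat("  participants:", nrow(x$participants), "(",
      paste(sprintf("%s=%d", names(table(x$participants$diagnosis)),
                    as.integer(table(x$participants$diagnosis))),
            collapse = ", "), ")\n")
  cat("  CNV events:  ", nrow(x$events), "\n")
  cat("  genes:       ", nrow(x$genes), " | GO terms: ", nrow(x$go_terms),
      "\n", sep = "")
  cat("  signed participant-gene links:", nrow(x$gene_links), "\n")
  invisible(x)
}

#' @export
summary.cohort_dataset <- function(object, ...) {
  links <- object$gene_links
  deg <- table(links$participant_id)
  out <- list(
    n_participants = nrow(object$participants),
    diagnoses = table(object$participants$diagnosis),
    n_genes = nrow(object$genes),
    n_go = nrow(object$go_terms),
    n_links = nrow(links),
    dup_fraction = if (nrow(links)) mean(links$sign == 1) else NA_real_,
    links_per_participant = if (length(deg)) summary(as.integer(deg)) else NULL)
  class(out) <- "summary.cohort_dataset"
  out
}

#' @export
print.summary.cohort_dataset <- function(x, ...) {
  cat("Cohort:", x$n_participants, "participants,", x$n_genes, "genes,",
      x$n_go, "GO terms,", x$n_links, "signed links\n")
  cat("Diagnoses:\n")
  print(x$diagnoses)
  cat(sprintf("Duplication fraction among links: %.3f\n", x$dup_fraction))
  if (!is.null(x$links_per_participant)) {
    cat("Links per linked participant:\n")
    print(x$links_per_participant)
  }
  invisible(x)
}
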