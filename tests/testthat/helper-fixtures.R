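# Fixture builders and independent oracles shared across test files.

# Build a cohort_dataset directly from an explicit signed link table.
# diagnoses: named character vector participant_id -> label.
toy_cohort <- function(links, diagnoses, gene_go = NULL, extra_genes = NULL) {
  links <- as.data.frame(links, stringsAsFactors = FALSE)
  gene_ids <- sort(unique(c(links$gene_id, gene_go$gene_id, extra_genes)))
  genes <- data.frame(
    gene_id = gene_ids, symbol = toupper(gene_ids), chromosome = "chr1",
    start = (seq_along(gene_ids) - 1L) * 10000L,
    end = (seq_along(gene_ids) - 1L) * 10000L + 5000L,
    risk_category = "unscored", stringsAsFactors = FALSE)
  participants <- data.frame(participant_id = names(diagnoses),
                             diagnosis = unname(diagnoses),
                             sex = "not_specified", stringsAsFactors = FALSE)
  if (is.null(gene_go)) {
    gene_go <- data.frame(gene_id = character(0), go_id = character(0),
                          aspect = character(0), name = character(0),
                          stringsAsFactors = FALSE)
  }
  idx <- match(links$gene_id, genes$gene_id)
  events <- data.frame(participant_id = links$participant_id,
                       chromosome = genes$chromosome[idx],
                       start = genes$start[idx], end = genes$end[idx],
                       dosage = links$sign, stringsAsFactors = FALSE)
  cohort_dataset(participants, events, genes, gene_go, gene_links = links)
}

# Small on-disk fixture: 3 participants, 4 CNVs, 2 genes, 3 GO rows.
write_tiny_tables <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) write.table(df, file.path(dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  wr(data.frame(participant_id = c("P1", "P2", "P3"),
                diagnosis = c("ASD", "DD", "ASD"),
                sex = c("male", "female", "not_specified")),
     "participants.tsv")
  # gene A: [100, 600); gene B: [1000, 1500)
  wr(data.frame(participant_id = c("P1", "P1", "P2", "P3"),
                chromosome = "chr1",
                start = c(0L, 900L, 200L, 2000L),
                end = c(300L, 1200L, 700L, 2500L),
                dosage = c(1L, -1L, -1L, 1L),
                acmg_class = c("Pathogenic", NA, NA, "Benign")),
     "cnvs.tsv")
  wr(data.frame(gene_id = c("GA", "GB"), symbol = c("GENEA", "GENEB"),
                chromosome = "chr1", start = c(100L, 1000L),
                end = c(600L, 1500L),
                risk_category = c("high_evidence", "unscored")),
     "genes.tsv")
  wr(data.frame(gene_id = c("GA", "GA", "GB"),
                go_id = c("GO:0000001", "GO:0000002", "GO:0000002"),
                aspect = c("biological_process", "molecular_function",
                           "molecular_function"),
                name = c("term one", "term two", "term two")),
     "gene_go.tsv")
  dir
}

# Brute-force all-pairs interval overlap oracle (0-based half-open).
brute_overlap <- function(events, genes, min_overlap = 1L) {
  rows <- list()
  for (i in seq_len(nrow(events))) {
    for (j in seq_len(nrow(genes))) {
      if (events$chromosome[i] != genes$chromosome[j]) next
      ov <- min(events$end[i], genes$end[j]) -
        max(events$start[i], genes$start[j])
      if (ov >= min_overlap) {
        rows[[length(rows) + 1]] <- data.frame(
          participant_id = events$participant_id[i],
          gene_id = genes$gene_id[j],
          sign = as.integer(events$dosage[i]), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(participant_id = character(0), gene_id = character(0),
                      sign = integer(0), stringsAsFactors = FALSE))
  }
  out <- unique(do.call(rbind, rows))
  out <- out[order(out$participant_id, out$gene_id, out$sign), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# All-pairs BFS oracle for geodesic distances, independent of igraph's
# shortest-path machinery: plain queue-based BFS on an adjacency list.
bfs_ecc <- function(graph) {
  n <- igraph::vcount(graph)
  adj <- lapply(seq_len(n), function(v) as.integer(igraph::neighbors(graph, v)))
  ecc <- integer(n)
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (u in adj[[v]]) {
        if (is.na(dist[u])) {
          dist[u] <- dist[v] + 1L
          queue <- c(queue, u)
        }
      }
    }
    ecc[s] <- max(dist, na.rm = TRUE)
  }
  ecc
}

# Independent modularity: Q = sum_c (e_c / m - (d_c / 2m)^2) on weights.
modularity_oracle <- function(graph, membership, weights) {
  m <- sum(weights)
  el <- igraph::as_edgelist(graph, names = FALSE)
  strength <- rep(0, igraph::vcount(graph))
  for (e in seq_len(nrow(el))) {
    strength[el[e, 1]] <- strength[el[e, 1]] + weights[e]
    strength[el[e, 2]] <- strength[el[e, 2]] + weights[e]
  }
  q <- 0
  for (c in unique(membership)) {
    in_c <- membership == c
    e_c <- sum(weights[in_c[el[, 1]] & in_c[el[, 2]]])
    d_c <- sum(strength[in_c])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

# Sample from the discrete power law p(k) ~ k^-gamma, k = 1..kmax.
sample_zeta <- function(n, gamma, kmax = 1e5) {
  k <- seq_len(kmax)
  p <- k^(-gamma)
  sample(k, n, replace = TRUE, prob = p)
}

# Cohort yielding two disjoint gene triangles in the ASD similarity
# projection: two participants, each carrying a disjoint gene triple.
two_triangle_cohort <- function() {
  links <- data.frame(
    participant_id = rep(c("P1", "P2"), each = 3),
    gene_id = c("gA", "gB", "gC", "gD", "gE", "gF"),
    sign = 1L, stringsAsFactors = FALSE)
  toy_cohort(links, c(P1 = "ASD", P2 = "ASD"))
}

# Worked fixture for the signed-importance encodings: 5 participants,
# 4 genes, 3 GO terms, covering duplication/deletion mixing, shared terms,
# an unannotated gene and an unlinked participant.
golden_cohort <- function() {
  links <- data.frame(
    participant_id = c("P1", "P1", "P2", "P2", "P2", "P3", "P3", "P4"),
    gene_id = c("g1", "g2", "g1", "g1", "g3", "g2", "g3", "g4"),
    sign = c(1L, -1L, 1L, -1L, 1L, 1L, 1L, -1L),
    stringsAsFactors = FALSE)
  gg <- data.frame(
    gene_id = c("g1", "g2", "g2", "g3"),
    go_id = c("GO:0000001", "GO:0000001", "GO:0000002", "GO:0000003"),
    aspect = "biological_process",
    name = c("t1", "t1", "t2", "t3"), stringsAsFactors = FALSE)
  toy_cohort(links, c(P1 = "ASD", P2 = "DD", P3 = "ASD", P4 = "DD",
                      P5 = "ASD"),
             gene_go = gg)
}

# Brute-force encoders applying the stated rules literally, loop by loop.
oracle_gene <- function(co, imp) {
  p <- co$participants$participant_id
  f <- sort(unique(co$gene_links$gene_id))
  x <- matrix(0, length(p), length(f), dimnames = list(p, f))
  for (r in seq_len(nrow(co$gene_links))) {
    l <- co$gene_links[r, ]
    x[l$participant_id, l$gene_id] <-
      x[l$participant_id, l$gene_id] + l$sign * imp[l$gene_id]
  }
  x
}
oracle_go <- function(co, imp, gene_bonus = NULL) {
  p <- co$participants$participant_id
  f <- sort(unique(co$gene_go$go_id))
  x <- matrix(0, length(p), length(f), dimnames = list(p, f))
  for (r in seq_len(nrow(co$gene_links))) {
    l <- co$gene_links[r, ]
    terms <- co$gene_go$go_id[co$gene_go$gene_id == l$gene_id]
    for (t in terms) {
      v <- if (is.null(gene_bonus)) imp[t] else imp[t] + gene_bonus[l$gene_id]
      x[l$participant_id, t] <- x[l$participant_id, t] + l$sign * v
    }
  }
  x
}
drop_zero <- function(x) x[, colSums(x != 0) > 0, drop = FALSE]
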