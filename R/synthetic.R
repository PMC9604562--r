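#' Configuration for the synthetic CNV cohort generator
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: two diagnosis classes, a small curated gene panel, a few hub
#' genes attached to otherwise weakly connected participants (hub-and-spoke
#' pattern), blocks of genes that co-occur within participants (subnetwork
#' pattern), many-genes-to-one-GO convergence with functionally coherent
#' annotations (a GO term draws its genes preferentially from one gene
#' block), and signed dup/del dosage. Class labels correlate with block
#' membership through `class_profiles`.
#'
#' @param n_per_class participants per diagnosis class (default 1300, the
#'   scale of the cohorts this pipeline targets).
#' @param class_labels two diagnosis labels; the first is the positive class
#'   downstream.
#' @param n_genes,n_go panel sizes (defaults 125 genes, 110 GO terms).
#' @param n_hub_genes number of hub genes (default 3).
#' @param hub_attach_prob probability a participant links to a given hub.
#' @param subnetwork_blocks data.frame with columns `size` (genes in the
#'   block), `frac` (baseline probability a participant joins the block) and
#'   `mean_links` (mean genes linked per joining participant).
#' @param class_profiles matrix (classes x blocks) of multiplicative weights
#'   in `[0, 1]` applied to `frac` per class; rows must not sum to zero.
#' @param convergence_factor mean number of genes annotated with each GO
#'   term (>= 1).
#' @param go_per_gene length-2 integer range; the upper bound caps how many
#'   GO terms a single gene may receive (advisory; genes may remain
#'   unannotated).
#' @param dup_prob probability a link is a duplication (+1) rather than a
#'   deletion (-1).
#' @param seed integer seed; a fixed seed makes the generated dataset fully
#'   reproducible.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_class = 1300,
                             class_labels = c("ASD", "DD"),
                             n_genes = 125, n_go = 110,
                             n_hub_genes = 3, hub_attach_prob = 0.15,
                             subnetwork_blocks = data.frame(
                               size = c(20, 20, 20, 20, 42),
                               frac = c(0.08, 0.08, 0.08, 0.08, 0.12),
                               mean_links = c(3, 3, 3, 3, 4)),
                             class_profiles = rbind(
                               c(1, 1, 1, 1, 0.15),
                               c(0.15, 0.15, 0.15, 0.15, 1)),
                             convergence_factor = 3,
                             go_per_gene = c(0L, 15L),
                             dup_prob = 0.5,
                             seed = 1L) {
  subnetwork_blocks <- as.data.frame(subnetwork_blocks)
  n_blocks <- nrow(subnetwork_blocks)
  class_profiles <- matrix(class_profiles, nrow = length(class_labels))
  stopifnot(length(class_labels) == 2,
            n_hub_genes <= n_genes,
            hub_attach_prob >= 0, hub_attach_prob <= 1,
            dup_prob >= 0, dup_prob <= 1,
            convergence_factor >= 1,
            ncol(class_profiles) == n_blocks,
            all(class_profiles >= 0), all(class_profiles <= 1),
            all(subnetwork_blocks$frac >= 0),
            all(subnetwork_blocks$frac <= 1),
            n_hub_genes + sum(subnetwork_blocks$size) <= n_genes)
  if (n_blocks > 0 && any(rowSums(class_profiles) == 0)) {
    stop("config error: class_profiles row sums to 0 for at least one class")
  }
  structure(list(n_per_class = n_per_class, class_labels = class_labels,
                 n_genes = n_genes, n_go = n_go,
                 n_hub_genes = n_hub_genes, hub_attach_prob = hub_attach_prob,
                 subnetwork_blocks = subnetwork_blocks,
                 class_profiles = class_profiles,
                 convergence_factor = convergence_factor,
                 go_per_gene = as.integer(go_per_gene),
                 dup_prob = dup_prob, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Gene panel with non-overlapping intervals on one synthetic chromosome, so
# converting links to CNV events (one event spanning exactly the gene)
# round-trips through interval overlap mapping.
.synthetic_genes <- function(cfg) {
  n_genes <- cfg$n_genes
  data.frame(
    gene_id = sprintf("ENSG%011d", seq_len(n_genes)),
    symbol = sprintf("SYNG%03d", seq_len(n_genes)),
    chromosome = "chrS",
    start = (seq_len(n_genes) - 1L) * 100000L,
    end = (seq_len(n_genes) - 1L) * 100000L + 50000L,
    risk_category = sample(RISK_LEVELS, n_genes, replace = TRUE,
                           prob = c(0.025, 0.02, 0.12, 0.835)),
    stringsAsFactors = FALSE)
}

.synthetic_participants <- function(cfg) {
  data.frame(
    participant_id = sprintf("SP%05d", seq_len(2L * cfg$n_per_class)),
    diagnosis = rep(cfg$class_labels, each = cfg$n_per_class),
    sex = sample(c("male", "female", "not_specified"),
                 2L * cfg$n_per_class, replace = TRUE,
                 prob = c(0.3, 0.08, 0.62)),
    stringsAsFactors = FALSE)
}

# GO annotation with functional coherence: each term converges onto
# 1 + Poisson(convergence_factor - 1) genes drawn from one annotation pool
# (a gene block, the hub set, or the leftover genes), topping up from the
# whole panel only when the pool is smaller than the draw. The mean
# genes-per-term therefore equals convergence_factor while terms inherit the
# block structure of the genes they annotate.
.synthetic_annotation <- function(cfg, genes, pools) {
  pools <- pools[lengths(pools) > 0]
  if (length(pools) == 0) pools <- list(genes$gene_id)
  pool_w <- lengths(pools)
  aspects <- sample(GO_ASPECTS, cfg$n_go, replace = TRUE,
                    prob = c(0.69, 0.29, 0.02))
  go_ids <- sprintf("GO:%07d", seq_len(cfg$n_go))
  ann <- vector("list", cfg$n_go)
  for (t in seq_len(cfg$n_go)) {
    m <- min(1L + rpois(1, cfg$convergence_factor - 1), cfg$n_genes)
    pool <- pools[[sample.int(length(pools), 1, prob = pool_w)]]
    gs <- sample(pool, min(m, length(pool)))
    if (length(gs) < m) {
      gs <- c(gs, sample(setdiff(genes$gene_id, gs), m - length(gs)))
    }
    ann[[t]] <- data.frame(gene_id = gs, go_id = go_ids[t],
                           aspect = aspects[t],
                           name = sprintf("synthetic dopaminergic term %03d",
                                          t),
                           stringsAsFactors = FALSE)
  }
  gene_go <- do.call(rbind, ann)
  cap <- cfg$go_per_gene[2]  # advisory cap on annotations per gene
  if (is.finite(cap)) {
    keep <- unlist(lapply(split(seq_len(nrow(gene_go)), gene_go$gene_id),
                          function(i) head(i, cap)), use.names = FALSE)
    gene_go <- gene_go[sort(keep), , drop = FALSE]
  }
  rownames(gene_go) <- NULL
  gene_go
}

# Turn a signed link table into one CNV event per link spanning the gene.
.links_to_events <- function(links, genes) {
  idx <- match(links$gene_id, genes$gene_id)
  data.frame(participant_id = links$participant_id,
             chromosome = genes$chromosome[idx],
             start = genes$start[idx], end = genes$end[idx],
             dosage = links$sign,
             acmg_class = NA_character_,
             stringsAsFactors = FALSE)
}

.signed_links <- function(link_p, link_g, dup_prob) {
  sign <- ifelse(rbinom(length(link_g), 1, dup_prob) == 1, 1L, -1L)
  unique(data.frame(participant_id = link_p, gene_id = link_g, sign = sign,
                    stringsAsFactors = FALSE))
}

#' Generate a synthetic CNV cohort
#'
#' Draws a cohort under the mechanism described in [synthetic_config()]:
#' Bernoulli attachment to hub genes, within-block gene co-occurrence with
#' class-weighted block membership, signed dup/del links, and functionally
#' coherent GO annotations converging from several genes onto each term.
#' Participants that would end up with no CNV receive one link to a random
#' hub (or gene), matching the selection rule that every admitted
#' participant carries at least one event.
#'
#' @param config a [synthetic_config()].
#' @return A [cohort_dataset()]; the same seed yields an identical dataset.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  genes <- .synthetic_genes(config)
  parts <- .synthetic_participants(config)
  n_hub <- config$n_hub_genes
  blocks <- config$subnetwork_blocks
  n_blocks <- nrow(blocks)
  hub_ids <- genes$gene_id[seq_len(n_hub)]
  offset <- n_hub
  block_genes <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    block_genes[[b]] <- genes$gene_id[offset + seq_len(blocks$size[b])]
    offset <- offset + blocks$size[b]
  }
  leftover <- if (offset < config$n_genes) {
    genes$gene_id[(offset + 1):config$n_genes]
  } else character(0)
  gene_go <- .synthetic_annotation(
    config, genes, c(list(hub_ids), block_genes, list(leftover)))

  cls_idx <- match(parts$diagnosis, config$class_labels)
  link_p <- vector("list", nrow(parts))
  link_g <- vector("list", nrow(parts))
  for (i in seq_len(nrow(parts))) {
    gs <- character(0)
    if (n_hub > 0) {
      gs <- hub_ids[runif(n_hub) < config$hub_attach_prob]
    }
    for (b in seq_len(n_blocks)) {
      p_join <- blocks$frac[b] * config$class_profiles[cls_idx[i], b]
      if (runif(1) < p_join) {
        m <- min(length(block_genes[[b]]),
                 1L + rpois(1, blocks$mean_links[b] - 1))
        gs <- c(gs, sample(block_genes[[b]], m))
      }
    }
    if (length(gs) == 0) {
      gs <- if (n_hub > 0) sample(hub_ids, 1) else sample(genes$gene_id, 1)
    }
    gs <- unique(gs)
    link_p[[i]] <- rep(parts$participant_id[i], length(gs))
    link_g[[i]] <- gs
  }
  links <- .signed_links(unlist(link_p), unlist(link_g), config$dup_prob)
  events <- .links_to_events(links, genes)
  cohort_dataset(parts, events, genes, gene_go, gene_links = links)
}

#' Generate a cohort with tunable class separability
#'
#' Ground-truth generator for classifier-recovery experiments. Genes are
#' organised into four disjoint blocks reserved for the first class and one
#' larger block reserved for the second (mirroring a fragmented versus
#' unitary biological structure); each participant joins exactly one block,
#' drawn from a mixture between a shared uniform block distribution and the
#' class-specific one. No hub genes are generated, so at full separation the
#' per-class gene similarity networks have clean block-disjoint ground
#' truth.
#'
#' @param config a [synthetic_config()]; `n_per_class`, `n_genes`, `n_go`,
#'   `convergence_factor`, `dup_prob` and `seed` are honoured.
#' @param effect separation strength in `[0, 1]`: 0 makes the class label
#'   independent of the links, 1 makes block membership fully
#'   class-determined.
#' @return A [cohort_dataset()].
#' @export
generate_separable_cohort <- function(config = synthetic_config(),
                                      effect = 1) {
  stopifnot(inherits(config, "synthetic_config"),
            effect >= 0, effect <= 1)
  set.seed(config$seed)
  genes <- .synthetic_genes(config)
  parts <- .synthetic_participants(config)

  size_a <- max(2L, floor(config$n_genes * 0.48 / 4))
  size_b <- min(30L, config$n_genes - 4L * size_a)
  stopifnot(size_b >= 2)
  block_genes <- vector("list", 5)
  offset <- 0L
  for (b in 1:4) {
    block_genes[[b]] <- genes$gene_id[offset + seq_len(size_a)]
    offset <- offset + size_a
  }
  block_genes[[5]] <- genes$gene_id[offset + seq_len(size_b)]
  leftover <- if (offset + size_b < config$n_genes) {
    genes$gene_id[(offset + size_b + 1):config$n_genes]
  } else character(0)
  gene_go <- .synthetic_annotation(config, genes,
                                   c(block_genes, list(leftover)))

  specific <- rbind(c(0.25, 0.25, 0.25, 0.25, 0),  # class 1: four blocks
                    c(0, 0, 0, 0, 1))              # class 2: one block
  shared <- rep(0.2, 5)
  cls_idx <- match(parts$diagnosis, config$class_labels)
  mean_links <- 3
  link_p <- vector("list", nrow(parts))
  link_g <- vector("list", nrow(parts))
  for (i in seq_len(nrow(parts))) {
    w <- effect * specific[cls_idx[i], ] + (1 - effect) * shared
    b <- sample.int(5, 1, prob = w)
    m <- min(length(block_genes[[b]]), 1L + rpois(1, mean_links - 1))
    link_g[[i]] <- sample(block_genes[[b]], m)
    link_p[[i]] <- rep(parts$participant_id[i], m)
  }
  links <- .signed_links(unlist(link_p), unlist(link_g), config$dup_prob)
  events <- .links_to_events(links, genes)
  cohort_dataset(parts, events, genes, gene_go, gene_links = links)
}
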