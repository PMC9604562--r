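test_that("co-carrier projection computes shared counts and Jaccard weights", {
  # two genes carried by the same three participants
  links <- data.frame(
    participant_id = rep(c("P1", "P2", "P3"), 2),
    gene_id = rep(c("g1", "g2"), each = 3), sign = 1L)
  co <- toy_cohort(links, c(P1 = "ASD", P2 = "ASD", P3 = "ASD"))
  net <- project_similarity(build_gene_dosage_network(co), "ASD", "gene")
  expect_equal(igraph::ecount(net$graph), 1)
  expect_equal(igraph::E(net$graph)$weight, 3)
  expect_equal(igraph::E(net$graph)$jaccard, 1.0)

  # disjoint carrier sets produce no edge
  links2 <- data.frame(participant_id = c("P1", "P2"),
                       gene_id = c("g1", "g2"), sign = 1L)
  co2 <- toy_cohort(links2, c(P1 = "ASD", P2 = "ASD"))
  net2 <- project_similarity(build_gene_dosage_network(co2), "ASD", "gene")
  expect_equal(igraph::ecount(net2$graph), 0)
  expect_equal(igraph::vcount(net2$graph), 2)

  # projection is diagnosis-restricted
  co3 <- toy_cohort(links, c(P1 = "ASD", P2 = "DD", P3 = "ASD"))
  net3 <- project_similarity(build_gene_dosage_network(co3), "DD", "gene")
  expect_equal(igraph::E(net3$graph)$weight, 1)
  expect_error(project_similarity(build_gene_dosage_network(co3),
                                  "Epilepsy", "gene"), "empty network")
})

test_that("projection equals brute-force pairwise carrier intersection", {
  co <- generate_cohort(synthetic_config(n_per_class = 60, seed = 31))
  g <- build_gene_dosage_network(co)
  for (diag in c("ASD", "DD")) {
    net <- project_similarity(g, diag, "gene")
    ids <- co$participants$participant_id[co$participants$diagnosis == diag]
    links <- unique(co$gene_links[co$gene_links$participant_id %in% ids,
                                  c("participant_id", "gene_id")])
    carriers <- split(links$participant_id, links$gene_id)
    genes <- sort(names(carriers))
    exp_edges <- list()
    for (i in seq_along(genes)) {
      for (j in seq_len(i - 1)) {
        shared <- length(intersect(carriers[[genes[i]]],
                                   carriers[[genes[j]]]))
        if (shared >= 1) {
          un <- length(union(carriers[[genes[i]]], carriers[[genes[j]]]))
          exp_edges[[length(exp_edges) + 1]] <-
            data.frame(a = genes[j], b = genes[i], w = shared,
                       jac = shared / un)
        }
      }
    }
    oracle <- do.call(rbind, exp_edges)
    oracle <- oracle[order(oracle$a, oracle$b), ]
    el <- igraph::as_edgelist(net$graph)
    got <- data.frame(a = pmin(el[, 1], el[, 2]), b = pmax(el[, 1], el[, 2]),
                      w = igraph::E(net$graph)$weight,
                      jac = igraph::E(net$graph)$jaccard)
    got <- got[order(got$a, got$b), ]
    expect_equal(got$a, oracle$a)
    expect_equal(got$b, oracle$b)
    expect_equal(got$w, oracle$w)
    expect_equal(got$jac, oracle$jac, tolerance = 1e-12)
    expect_setequal(igraph::V(net$graph)$name, genes)
  }
})

test_that("raising min_shared never adds edges (monotonicity)", {
  co <- generate_cohort(synthetic_config(n_per_class = 80, seed = 32))
  g <- build_gene_dosage_network(co)
  counts <- vapply(1:4, function(ms) {
    igraph::ecount(project_similarity(g, "ASD", "gene",
                                      min_shared = ms)$graph)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("connected components are counted with deterministic labels", {
  net <- project_similarity(
    build_gene_dosage_network(two_triangle_cohort()), "ASD", "gene")
  cc <- connected_components(net)
  expect_equal(cc$n_components, 2)
  expect_equal(cc$sizes, c(3L, 3L))
  # component 1 contains the lexicographically smallest node
  expect_equal(unname(cc$membership[c("gA", "gB", "gC")]), rep(1L, 3))
  expect_equal(unname(cc$membership[c("gD", "gE", "gF")]), rep(2L, 3))
})

test_that("modularity of two equal disjoint cliques is 1/2", {
  net <- project_similarity(
    build_gene_dosage_network(two_triangle_cohort()), "ASD", "gene")
  cm <- detect_communities(net, seed = 1)
  expect_equal(cm$n_communities, 2)
  expect_equal(cm$Q, 0.5, tolerance = 1e-12)
  # partition matches the components
  expect_equal(length(unique(cm$membership[c("gA", "gB", "gC")])), 1)
})

test_that("a single clique admits no modular division", {
  links <- data.frame(participant_id = "P1",
                      gene_id = c("g1", "g2", "g3", "g4"), sign = 1L)
  co <- toy_cohort(links, c(P1 = "ASD"))
  net <- project_similarity(build_gene_dosage_network(co), "ASD", "gene")
  cm <- detect_communities(net, seed = 1)
  expect_equal(cm$n_communities, 1)
  expect_equal(cm$Q, 0)
})

test_that("edgeless networks degrade to singleton communities with warning", {
  links2 <- data.frame(participant_id = c("P1", "P2"),
                       gene_id = c("g1", "g2"), sign = 1L)
  co <- toy_cohort(links2, c(P1 = "ASD", P2 = "ASD"))
  net <- project_similarity(build_gene_dosage_network(co), "ASD", "gene")
  expect_warning(cm <- detect_communities(net, seed = 1), "edgeless")
  expect_equal(cm$n_communities, 2)
  expect_equal(cm$Q, 0)
})

test_that("reported Q matches an independent modularity computation", {
  for (s in c(41, 42)) {
    co <- generate_cohort(synthetic_config(n_per_class = 80, seed = s))
    net <- project_similarity(build_gene_dosage_network(co), "ASD", "gene")
    cm <- detect_communities(net, seed = 1)
    q_oracle <- modularity_oracle(net$graph, cm$membership,
                                  igraph::E(net$graph)$jaccard)
    expect_equal(cm$Q, q_oracle, tolerance = 1e-9)
  }
})

test_that("planted 4-block vs 1-block structure shows the modularity contrast", {
  co <- generate_separable_cohort(
    synthetic_config(n_per_class = 100, seed = 51), effect = 1)
  g <- build_gene_dosage_network(co)
  fragmented <- project_similarity(g, "ASD", "gene")
  unitary <- project_similarity(g, "DD", "gene")
  cm_a <- detect_communities(fragmented, seed = 1)
  cm_b <- detect_communities(unitary, seed = 1)
  expect_gte(cm_a$n_communities, 4)
  expect_gt(cm_a$Q, 0.5)
  expect_lt(cm_b$Q, 0.2)
})

test_that("class-structure recovery: >= 4 vs exactly 1 components over seeds", {
  for (s in 1:20) {
    co <- generate_separable_cohort(
      synthetic_config(n_per_class = 100, seed = s), effect = 1)
    g <- build_gene_dosage_network(co)
    cc_a <- connected_components(project_similarity(g, "ASD", "gene"))
    cc_b <- connected_components(project_similarity(g, "DD", "gene"))
    expect_gte(cc_a$n_components, 4)
    expect_equal(cc_b$n_components, 1)
  }
})

test_that("risk annotation tags nodes and summarizes categories", {
  links <- data.frame(participant_id = c("P1", "P1", "P2", "P2"),
                      gene_id = c("g1", "g2", "g1", "g2"), sign = 1L)
  co <- toy_cohort(links, c(P1 = "ASD", P2 = "ASD"))
  co$genes$risk_category <- c("high_evidence", "high_evidence")
  net <- project_similarity(build_gene_dosage_network(co), "ASD", "gene")
  net <- annotate_risk(net, co$genes)
  expect_equal(unname(net$risk_summary["high_evidence"]), 2L)
  expect_equal(igraph::V(net$graph)$risk_category, rep("high_evidence", 2))
  # unknown genes fall back to unscored with a warning
  expect_warning(net2 <- annotate_risk(net, co$genes[1, , drop = FALSE]),
                 "unscored")
  expect_equal(sum(igraph::V(net2$graph)$risk_category == "unscored"), 1)
  expect_error(annotate_risk(
    project_similarity(suppressWarnings(build_go_network(
      toy_cohort(links, c(P1 = "ASD", P2 = "ASD"),
                 gene_go = data.frame(gene_id = c("g1", "g2"),
                                      go_id = "GO:0000001",
                                      aspect = "biological_process",
                                      name = "t")))), "ASD", "go"),
    co$genes), "gene networks")
})
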