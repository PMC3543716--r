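graph_from_pairs <- function(a, b) {
  igraph::graph_from_data_frame(data.frame(gene_a = a, gene_b = b),
                                directed = FALSE)
}

clique_pairs <- function(names) {
  cmb <- combn(names, 2)
  list(a = cmb[1, ], b = cmb[2, ])
}

test_that("cut-offs threshold |assigned_r| strictly and drop isolated nodes", {
  land <- toy_landscape(c("a", "c", "e"), c("b", "d", "f"),
                        c(0.71, -0.86, 0.96))
  expect_equal(igraph::ecount(apply_cutoff(land, NULL)), 3)
  expect_equal(igraph::ecount(apply_cutoff(land, 0.7)), 3)
  expect_equal(igraph::ecount(apply_cutoff(land, 0.85)), 2)
  expect_equal(igraph::ecount(apply_cutoff(land, 0.95)), 1)
  g <- apply_cutoff(land, 0.95)
  expect_setequal(igraph::vertex_attr(g, "name"), c("e", "f"))
  # strictness: an edge exactly at the cut-off is dropped
  expect_equal(igraph::ecount(apply_cutoff(land, 0.71)), 2)
  expect_error(apply_cutoff(land, 1.0), "cutoff")
})

test_that("core numbers: cliques, trees, and agreement with the peeling oracle", {
  k5 <- clique_pairs(letters[1:5])
  g <- graph_from_pairs(k5$a, k5$b)
  expect_true(all(core_numbers(g) == 4))
  tree <- graph_from_pairs(c("a", "a", "b", "b", "c"),
                           c("b", "c", "d", "e", "f"))
  expect_true(all(core_numbers(tree) == 1))
  set.seed(91)
  nodes <- sprintf("v%02d", 1:50)
  pairs <- t(combn(nodes, 2))
  keep <- sample(nrow(pairs), 120)
  rg <- graph_from_pairs(pairs[keep, 1], pairs[keep, 2])
  expect_equal(core_numbers(rg)[names(igraph_to_adj(rg))],
               peel_cores(igraph_to_adj(rg)))
})

test_that("MCODE vertex weights: clique n-1, star centre 1/3, isolated 0", {
  k6 <- clique_pairs(letters[1:6])
  g <- graph_from_pairs(k6$a, k6$b)
  expect_true(all(mcode_vertex_weights(g) == 5))
  star <- graph_from_pairs(rep("hub", 5), paste0("leaf", 1:5))
  w <- mcode_vertex_weights(star)
  expect_equal(unname(w["hub"]), 1 / 3)
  iso <- igraph::add_vertices(star, 1, name = "lonely")
  expect_equal(unname(mcode_vertex_weights(iso)["lonely"]), 0)
})

test_that("two K6 cliques joined through a bridging vertex give exactly the two cliques", {
  a <- clique_pairs(paste0("a", 1:6))
  b <- clique_pairs(paste0("b", 1:6))
  g <- graph_from_pairs(c(a$a, b$a, "a1", "bridge"),
                        c(a$b, b$b, "bridge", "b1"))
  mods <- mcode_find_modules(g, mcode_params(vwp = 0.2))
  expect_length(mods, 2)
  expect_setequal(mods[[1]]$genes, paste0("a", 1:6))
  expect_setequal(mods[[2]]$genes, paste0("b", 1:6))
  # each recovered module is the densest: density 1
  expect_equal(mods[[1]]$score, 6)
  expect_equal(mods[[1]]$internal_edges, 15)
  expect_equal(mods[[1]]$boundary_edges, 1)
})

test_that("a direct bridge edge between equal-weight cliques merges them", {
  # all twelve vertices weigh 5, so the seed-relative admission rule crosses
  # the bridge; this documents the algorithm's behaviour on equal weights
  a <- clique_pairs(paste0("a", 1:6))
  b <- clique_pairs(paste0("b", 1:6))
  g <- graph_from_pairs(c(a$a, b$a, "a1"), c(a$b, b$b, "b1"))
  expect_true(all(mcode_vertex_weights(g) == 5))
  mods <- mcode_find_modules(g, mcode_params(vwp = 0.2))
  expect_length(mods, 1)
  expect_length(mods[[1]]$genes, 12)
})

test_that("haircut prunes pendant vertices: K4 plus pendant returns the K4", {
  k4 <- clique_pairs(paste0("k", 1:4))
  g <- graph_from_pairs(c(k4$a, "k1"), c(k4$b, "pendant"))
  mods <- mcode_find_modules(g, mcode_params(haircut = TRUE))
  expect_length(mods, 1)
  expect_setequal(mods[[1]]$genes, paste0("k", 1:4))
  mods2 <- mcode_find_modules(g, mcode_params(haircut = FALSE, vwp = 1))
  expect_setequal(mods2[[1]]$genes, c(paste0("k", 1:4), "pendant"))
})

test_that("edgeless graphs yield no modules and results are label-invariant", {
  empty <- igraph::make_empty_graph(5, directed = FALSE)
  expect_length(mcode_find_modules(empty), 0)
  a <- clique_pairs(paste0("a", 1:5))
  g1 <- graph_from_pairs(a$a, a$b)
  relabel <- setNames(paste0("z", 5:1), paste0("a", 1:5))
  g2 <- graph_from_pairs(unname(relabel[a$a]), unname(relabel[a$b]))
  m1 <- mcode_find_modules(g1)
  m2 <- mcode_find_modules(g2)
  expect_equal(m1[[1]]$score, m2[[1]]$score)
  expect_setequal(unname(relabel[m1[[1]]$genes]), m2[[1]]$genes)
})

test_that("modules are vertex-disjoint before fluff and deterministic", {
  set.seed(14)
  nodes <- sprintf("v%02d", 1:40)
  pairs <- t(combn(nodes, 2))
  keep <- sample(nrow(pairs), 150)
  g <- graph_from_pairs(pairs[keep, 1], pairs[keep, 2])
  mods <- mcode_find_modules(g, mcode_params(haircut = FALSE))
  all_genes <- unlist(lapply(mods, function(m) m$genes))
  expect_false(anyDuplicated(all_genes) > 0)
  mods2 <- mcode_find_modules(g, mcode_params(haircut = FALSE))
  expect_identical(mods, mods2)
})

test_that("sweep picks the largest size before a connectivity jump", {
  # hand-built landscape: a K5 core (r = 0.92) gains a well-connected sixth
  # member at r = 0.86, and a fringe of low-weight vertices whose boundary
  # edges appear only below the 0.8 cut-off
  k5 <- clique_pairs(paste0("m", 1:5))
  land <- toy_landscape(
    c(k5$a, rep("m6", 4), rep(c("m1", "m2"), each = 8)),
    c(k5$b, paste0("m", 1:4), rep(paste0("f", 1:8), 2)),
    c(rep(0.92, 10), rep(0.86, 4), rep(0.75, 16)))
  sw <- sweep_modules(land, c(0.9, 0.85, 0.8, 0.7), mcode_params(),
                      jump_factor = 2)
  lin1 <- sw$table[sw$table$lineage == 1, ]
  expect_equal(lin1$size[lin1$cutoff == 0.9], 5)
  expect_equal(lin1$size[lin1$cutoff == 0.85], 6)
  expect_equal(lin1$connectivity_ratio[lin1$cutoff == 0.8], 0)
  # at 0.7 the fringe boundary (16 edges vs 15 internal) is a major jump;
  # the chosen cut-off is the size immediately preceding it
  expect_gt(lin1$connectivity_ratio[lin1$cutoff == 0.7], 1)
  expect_equal(sw$chosen$chosen_cutoff[1], 0.8)
  expect_equal(sw$chosen$size[1], 6)
})

test_that("a module stable across cut-offs chooses the smallest cut-off", {
  k4 <- clique_pairs(paste0("s", 1:4))
  land <- toy_landscape(k4$a, k4$b, rep(0.99, 6))
  sw <- sweep_modules(land, c(0.9, 0.8, 0.7), mcode_params())
  expect_equal(nrow(sw$chosen), 1)
  expect_equal(sw$chosen$chosen_cutoff, 0.7)
  # single-cutoff sweep degenerates: no chosen-cutoff logic
  sw1 <- sweep_modules(land, 0.8, mcode_params())
  expect_true(is.na(sw1$chosen$chosen_cutoff))
})

test_that("planted modules are recovered from the synthetic AC landscape", {
  jacc <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  j_big <- j_small <- numeric()
  for (seed in 1:10) {
    sim <- generate_expression(default_simulation_config(seed = 100 + seed))
    expr <- sim$expression
    nets <- lapply(group_names(expr), function(g)
      build_network(filter_low_variation(expr, g), g))
    land <- intersect_networks(nets, reference_group = nets[[1]]$group)
    sw <- sweep_modules(land, c(0.95, 0.9, 0.85, 0.8, 0.7, NA), mcode_params())
    found <- lapply(sw$modules, function(m) m$genes)
    truth <- split(names(sim$truth$module_membership),
                   sim$truth$module_membership)
    j_big <- c(j_big, max(vapply(found, jacc, 0, b = truth$M1), 0))
    j_small <- c(j_small, max(vapply(found, jacc, 0, b = truth$M2), 0))
  }
  expect_gte(mean(j_big >= 0.8), 0.9)
  expect_gte(mean(j_small >= 0.8), 0.9)
})
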