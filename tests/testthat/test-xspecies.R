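test_that("build_mapping links confident symbols 1:1 and drops conflicts", {
  annot_a <- data.frame(
    gene_id = sprintf("a%02d", 1:12),
    symbol = c(sprintf("S%02d", 1:10), "DUP", "DUP"),
    status = c(rep("confident", 11), "confident"))
  annot_b <- data.frame(
    gene_id = sprintf("b%02d", 1:15),
    symbol = c(sprintf("S%02d", 1:9), "DUP", sprintf("T%02d", 1:5)),
    status = c(rep("confident", 9), "confident", rep("confident", 5)))
  m <- build_mapping(annot_a, annot_b)
  # S01..S09 linkable; DUP excluded on side A; T* and S10 unmatched
  expect_equal(m$universe_size, 9)
  expect_identical(m$pairs$gene_a, sprintf("a%02d", 1:9))
  expect_identical(m$pairs$gene_b, sprintf("b%02d", 1:9))
  expect_equal(attr(m, "n_conflicts"), 1)
  # identical annotations give the identity over confident genes
  ident <- data.frame(gene_id = c("x", "y", "z"), symbol = c("X", "Y", "Z"),
                      status = c("confident", "confident", "dubious"))
  mi <- build_mapping(ident, ident)
  expect_equal(mi$universe_size, 2)
  expect_identical(mi$pairs$gene_a, mi$pairs$gene_b)
})

test_that("identical landscapes under the identity mapping share everything", {
  land <- toy_landscape(c("a", "b", "c"), c("b", "c", "d"), c(0.9, -0.8, 0.7))
  map <- id_mapping(data.frame(gene_a = letters[1:6], gene_b = letters[1:6]))
  cmp <- compare_landscapes(land, land, map)
  expect_equal(cmp$nodes_shared, 4)
  expect_equal(cmp$nodes_a_only, 0)
  expect_equal(cmp$nodes_b_only, 0)
  expect_equal(cmp$shared_edges, 3)
  expect_equal(cmp$shared_edge_sign_agreement, 3)
})

test_that("disjoint node sets share nothing and are not significant", {
  la <- toy_landscape("a1", "a2", 0.9)
  lb <- toy_landscape("b1", "b2", 0.9)
  map <- id_mapping(data.frame(gene_a = c("a1", "a2", "z1", "z2"),
                               gene_b = c("y1", "y2", "b1", "b2")))
  cmp <- compare_landscapes(la, lb, map)
  expect_equal(cmp$nodes_shared, 0)
  expect_equal(cmp$shared_edges, 0)
  expect_equal(cmp$node_overlap_p, 1.0)
})

test_that("comparison is symmetric up to transposed counts", {
  set.seed(31)
  la <- toy_landscape(c("a1", "a1", "a2", "a4"), c("a2", "a3", "a3", "a5"),
                      runif(4, 0.7, 1))
  lb <- toy_landscape(c("b1", "b2", "b6"), c("b2", "b3", "b7"),
                      runif(3, 0.7, 1))
  map <- id_mapping(data.frame(gene_a = sprintf("a%d", 1:7),
                               gene_b = sprintf("b%d", 1:7)))
  rev_map <- id_mapping(data.frame(gene_a = map$pairs$gene_b,
                                   gene_b = map$pairs$gene_a))
  ab <- compare_landscapes(la, lb, map)
  ba <- compare_landscapes(lb, la, rev_map)
  expect_equal(ab$nodes_shared, ba$nodes_shared)
  expect_equal(ab$nodes_a_only, ba$nodes_b_only)
  expect_equal(ab$nodes_b_only, ba$nodes_a_only)
  expect_equal(ab$node_overlap_p, ba$node_overlap_p, tolerance = 1e-12)
  expect_equal(ab$shared_edges, ba$shared_edges)
})

test_that("per-module overlap rows sum to the comparable module sizes", {
  la <- toy_landscape(c("a1", "a2"), c("a2", "a3"), c(0.9, 0.9))
  lb <- toy_landscape(c("b1", "b2"), c("b2", "b4"), c(0.9, 0.9))
  map <- id_mapping(data.frame(gene_a = sprintf("a%d", 1:4),
                               gene_b = sprintf("b%d", 1:4)))
  mods_a <- list(ma = c("a1", "a2", "a3"))
  mods_b <- list(mb = c("b1", "b2", "b4"))
  cmp <- compare_landscapes(la, lb, map, mods_a, mods_b,
                            data.frame(id_a = "ma", id_b = "mb"))
  row <- cmp$module_overlap
  expect_equal(row$both, 2)        # b1, b2
  expect_equal(row$a_only + row$both, 3)
  expect_equal(row$b_only + row$both, 3)
  expect_error(
    compare_landscapes(la, lb, map, mods_a, mods_b,
                       data.frame(id_a = "ma", id_b = "nope")),
    "unpaired")
})

test_that("shared synthetic modules dominate the cross-landscape edge overlap", {
  base <- function(seed) simulation_config(
    n_genes = 120, groups = c(g1 = 25, g2 = 25, g3 = 25),
    modules = list(module_spec(12), module_spec(10), module_spec(8)),
    noise_sd = 0.3, seed = seed)
  conc <- shared <- numeric()
  for (seed in 1:10) {
    pair <- generate_species_pair(base(seed), base(seed + 50),
                                  shared_modules = 2,
                                  mapping_fraction = 0.9, seed = seed)
    build_land <- function(expr) {
      nets <- lapply(group_names(expr), function(g)
        build_network(filter_low_variation(expr, g), g))
      intersect_networks(nets, reference_group = nets[[1]]$group)
    }
    la <- build_land(pair$expression_a)
    lb <- build_land(pair$expression_b)
    cmp <- compare_landscapes(la, lb, pair$mapping)
    shared <- c(shared, cmp$shared_edges)
    # fraction of shared edges inside the shared modules (by A-side truth)
    ma <- pair$truth_a$module_membership
    shared_genes_b <- pair$mapping$pairs$gene_b[
      pair$mapping$pairs$gene_a %in% names(ma)[ma %in% c("M1", "M2")]]
    a2b <- setNames(pair$mapping$pairs$gene_b, pair$mapping$pairs$gene_a)
    ea <- la$edges[la$edges$gene_a %in% names(a2b) &
                     la$edges$gene_b %in% names(a2b), ]
    keys_a <- edge_key(unname(a2b[ea$gene_a]), unname(a2b[ea$gene_b]))
    keys_b <- edge_key(lb$edges$gene_a, lb$edges$gene_b)
    common <- intersect(keys_a, keys_b)
    inside <- vapply(strsplit(common, "|", fixed = TRUE), function(p)
      all(p %in% shared_genes_b), TRUE)
    conc <- c(conc, if (length(common)) mean(inside) else NA_real_)
  }
  expect_true(all(shared > 0))
  expect_gte(mean(conc, na.rm = TRUE), 0.8)
})
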