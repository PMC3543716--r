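test_that("correlation_matrix matches the two-pass covariance formula", {
  set.seed(12)
  v <- matrix(rnorm(40, 8), 4, 10,
              dimnames = list(sprintf("g%d", 1:4), sprintf("s%02d", 1:10)))
  expr <- toy_expr(v)
  r <- correlation_matrix(expr)
  naive <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(r[i, j], naive(v[i, ], v[j, ]), tolerance = 1e-12)
  expect_equal(diag(r), setNames(rep(1, 4), rownames(v)))
})

test_that("duplicated and negated genes give r = 1 and r = -1", {
  set.seed(3)
  x <- rnorm(10)
  v <- rbind(a = x, b = x, c = -x, d = rnorm(10))
  colnames(v) <- sprintf("s%02d", 1:10)
  r <- correlation_matrix(toy_expr(v))
  expect_equal(r["a", "b"], 1, tolerance = 1e-12)
  expect_equal(r["a", "c"], -1, tolerance = 1e-12)
  # zero-variance gene is an error naming the gene
  v2 <- rbind(v, e = rep(5, 10))
  expect_error(correlation_matrix(toy_expr(v2)), "e")
})

test_that("first_order_partial follows the standard formula", {
  expect_equal(first_order_partial(0.9, 0, 0), 0.9)
  expect_equal(first_order_partial(0.40, 0.8, 0.5), 0, tolerance = 1e-12)
  expect_equal(first_order_partial(0.7, 0.6, 0.5),
               (0.7 - 0.30) / sqrt(0.64 * 0.75), tolerance = 1e-4)
  expect_error(first_order_partial(0.5, 1, 0.2), "degenerate")
})

test_that("identity correlation matrix yields an empty mask", {
  r <- diag(6)
  dimnames(r) <- list(letters[1:6], letters[1:6])
  expect_false(any(pcit_mask(r)$keep))
})

test_that("constant-correlation matrices keep every edge (eps = 1/(1+rho))", {
  for (rho in c(0.3, 0.6, 0.9)) {
    r <- matrix(rho, 8, 8); diag(r) <- 1
    dimnames(r) <- list(letters[1:8], letters[1:8])
    m <- pcit_mask(r)
    expect_true(all(m$keep[upper.tri(m$keep)]),
                label = sprintf("all edges kept at rho = %s", rho))
  }
})

test_that("optimized mask equals the naive triple-loop oracle on random matrices", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(4:25, 1)
    r <- random_corr(n)
    m <- pcit_mask(r)
    expect_identical(m$keep, naive_pcit_mask(r),
                     label = sprintf("instance %d (n = %d)", i, n))
  }
})

test_that("absolute ratio mode and non-strict flags also match the oracle", {
  set.seed(77)
  for (i in 1:10) {
    r <- random_corr(12)
    expect_identical(pcit_mask(r, ratio_mode = "absolute")$keep,
                     naive_pcit_mask(r, absolute_ratio = TRUE))
    expect_identical(pcit_mask(r, strict = FALSE)$keep,
                     naive_pcit_mask(r, strict = FALSE))
  }
})

test_that("mask is invariant under gene permutation", {
  set.seed(55)
  r <- random_corr(15)
  perm <- sample(15)
  m1 <- pcit_mask(r)$keep
  m2 <- pcit_mask(r[perm, perm])$keep
  expect_identical(m2, m1[perm, perm])
})

test_that("kept edges are a subset of nonzero correlations; n = 2 keeps any nonzero r", {
  set.seed(5)
  r <- random_corr(10)
  m <- pcit_mask(r)
  expect_true(all(abs(r[m$keep]) > 0))
  r2 <- matrix(c(1, 0.5, 0.5, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_true(pcit_mask(r2)$keep["a", "b"])
})

test_that("duplicate genes keep their edge but trios containing them are skipped", {
  set.seed(6)
  x <- matrix(rnorm(50), 5, 10)
  x[2, ] <- x[1, ]                      # duplicate gene
  r <- cor(t(x)); diag(r) <- 1
  dimnames(r) <- list(letters[1:5], letters[1:5])
  expect_warning(m <- pcit_mask(r), "degenerate")
  expect_true(m$keep["a", "b"])
  expect_equal(m$n_degenerate_trios, 3)  # trios {a,b,*} for * in c,d,e
})

test_that("conditionally independent pairs are pruned preferentially", {
  # y and x both generated from z: the x-y edge should be removed more often
  # than the z-x / z-y edges
  set.seed(202)
  removed_xy <- removed_zx <- removed_zy <- 0
  for (i in 1:100) {
    z <- rnorm(60)
    x <- z + rnorm(60, sd = 1.5)
    y <- z + rnorm(60, sd = 1.5)
    b1 <- rnorm(60); b2 <- rnorm(60)   # background genes for extra trios
    r <- cor(cbind(z = z, x = x, y = y, b1 = b1, b2 = b2))
    m <- pcit_mask(r)
    removed_xy <- removed_xy + !m$keep["x", "y"]
    removed_zx <- removed_zx + !m$keep["z", "x"]
    removed_zy <- removed_zy + !m$keep["z", "y"]
  }
  expect_gt(removed_xy, removed_zx)
  expect_gt(removed_xy, removed_zy)
})

test_that("build_network recovers planted module edges and suppresses null pairs", {
  # a single network keeps a minority of null cross-module pairs (the trio
  # flag needs both flanking correlations to dominate, so weak edges survive
  # at a modest rate); it is the intersection across condition networks that
  # drives null pairs out of the AC landscape (see the landscape tests)
  hits <- misses <- 0
  for (seed in 1:10) {
    cfg <- simulation_config(
      n_genes = 60, groups = c(g1 = 40),
      modules = list(module_spec(10, loading = 1),
                     module_spec(10, loading = 1)),
      noise_sd = 0.5, seed = seed)
    sim <- generate_expression(cfg)
    net <- build_network(sim$expression, "g1")
    keys <- edge_key(net$edges$gene_a, net$edges$gene_b)
    planted <- sim$truth$always_pairs
    mm <- sim$truth$module_membership
    cross <- c(outer(names(mm)[mm == "M1"], names(mm)[mm == "M2"], edge_key))
    hits <- hits + mean(planted %in% keys)
    misses <- misses + length(intersect(keys, cross)) / length(cross)
  }
  expect_gte(hits / 10, 0.9)
  expect_lte(misses / 10, 0.25)
  expect_lt(misses / 10, hits / 10)
})

test_that("a 2-gene matrix yields one edge with the Pearson weight", {
  set.seed(10)
  x <- rnorm(20)
  y <- 0.5 * x + rnorm(20, sd = sqrt(1 - 0.25))
  v <- rbind(a = x, b = y)
  colnames(v) <- sprintf("s%02d", 1:20)
  net <- build_network(toy_expr(v))
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$r, cor(x, y))
})
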