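# Independent brute-force oracles used to cross-check the implementation.

# Naive PCIT: literal triple loop over trios, no shared code with the
# package's C++ kernel.
naive_pcit_mask <- function(r, absolute_ratio = FALSE, strict = TRUE) {
  n <- nrow(r)
  keep <- abs(r) > 0
  diag(keep) <- FALSE
  if (n < 3) return(keep)
  part <- function(rab, rac, rbc)
    max(-1, min(1, (rab - rac * rbc) / sqrt((1 - rac^2) * (1 - rbc^2))))
  for (x in 1:(n - 2)) for (y in (x + 1):(n - 1)) for (z in (y + 1):n) {
    rxy <- r[x, y]; rxz <- r[x, z]; ryz <- r[y, z]
    if (max(abs(c(rxy, rxz, ryz))) >= 1 - 1e-12) next
    p <- c(part(rxy, rxz, ryz), part(rxz, rxy, ryz), part(ryz, rxy, rxz))
    d <- c(rxy, rxz, ryz)
    ok <- abs(d) > 1e-12
    if (!any(ok)) next
    ratios <- p[ok] / d[ok]
    if (absolute_ratio) ratios <- abs(ratios)
    eps <- mean(ratios)
    cmp <- if (strict) `<` else `<=`
    if (cmp(abs(rxy), abs(eps * rxz)) && cmp(abs(rxy), abs(eps * ryz))) {
      keep[x, y] <- keep[y, x] <- FALSE
    }
    if (cmp(abs(rxz), abs(eps * rxy)) && cmp(abs(rxz), abs(eps * ryz))) {
      keep[x, z] <- keep[z, x] <- FALSE
    }
    if (cmp(abs(ryz), abs(eps * rxy)) && cmp(abs(ryz), abs(eps * rxz))) {
      keep[y, z] <- keep[z, y] <- FALSE
    }
  }
  dimnames(keep) <- dimnames(r)
  keep
}

# Random positive-definite correlation matrix (sample correlation of
# Gaussian data with more samples than genes).
random_corr <- function(n_genes, n_samples = 3 * n_genes) {
  x <- matrix(rnorm(n_samples * n_genes), n_samples, n_genes)
  r <- cor(x)
  dimnames(r) <- list(sprintf("g%02d", 1:n_genes), sprintf("g%02d", 1:n_genes))
  r
}

# Direct log-space summation for the hypergeometric upper tail.
hyper_upper_oracle <- function(k, K, n, N) {
  hi <- min(K, n)
  if (k > hi) return(0)
  terms <- vapply(k:hi, function(i)
    lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n), 0)
  m <- max(terms)
  exp(m) * sum(exp(terms - m))
}

# Union-find connected components over an edge data.frame.
union_find_components <- function(nodes, edges) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (i in seq_len(nrow(edges))) {
    ra <- find(edges$gene_a[i]); rb <- find(edges$gene_b[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, "")
  sets <- split(nodes, roots)
  sets <- lapply(unname(sets), sort)
  firsts <- vapply(sets, `[`, "", 1L)
  sets[order(-lengths(sets), firsts)]
}

# k-core by repeated deletion of minimum-degree vertices.
peel_cores <- function(adj_named) {
  # adj_named: named list vertex -> character vector of neighbours
  core <- stats::setNames(rep(0L, length(adj_named)), names(adj_named))
  adj <- adj_named
  k <- 0L
  while (length(adj)) {
    repeat {
      deg <- lengths(adj)
      low <- names(adj)[deg <= k]
      if (length(low) == 0) break
      core[low] <- k
      adj <- adj[!names(adj) %in% low]
      adj <- lapply(adj, function(nb) setdiff(nb, low))
    }
    k <- k + 1L
  }
  core
}

igraph_to_adj <- function(g) {
  nm <- igraph::vertex_attr(g, "name")
  a <- igraph::adjacent_vertices(g, igraph::V(g))
  stats::setNames(lapply(a, function(v) nm[as.integer(v)]), nm)
}

# Tiny ac_expression from a plain matrix.
toy_expr <- function(values, detection = NULL, groups = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  if (!is.null(detection)) dimnames(detection) <- dimnames(values)
  ac_expression(values, detection = detection, groups = groups)
}

# Landscape stub from an edge list with assigned correlations.
toy_landscape <- function(gene_a, gene_b, r) {
  edges <- data.frame(gene_a = pmin(gene_a, gene_b),
                      gene_b = pmax(gene_a, gene_b),
                      assigned_r = r, stringsAsFactors = FALSE)
  edges$sign <- ifelse(r < 0, "negative", "positive")
  edges$sign_consistent <- rep(TRUE, nrow(edges))
  structure(list(nodes = sort(unique(c(gene_a, gene_b))), edges = edges,
                 source_groups = "toy", reference_group = "toy"),
            class = "ac_landscape")
}
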