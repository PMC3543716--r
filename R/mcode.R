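#' MCODE parameters
#'
#' @param vwp Vertex weight percentage in `[0, 1]`: expansion admits
#'   neighbours whose weight is at least `(1 - vwp)` times the seed weight.
#' @param haircut Remove vertices singly connected within a module.
#' @param fluff Add boundary neighbours whose closed-neighbourhood density
#'   exceeds `fluff_density` (fluffed vertices may be shared).
#' @param fluff_density Density threshold for fluff.
#' @param max_depth Maximum BFS expansion depth from the seed.
#' @return A `mcode_params` list.
#' @export
mcode_params <- function(vwp = 0.2, haircut = TRUE, fluff = FALSE,
                         fluff_density = 0.2, max_depth = 100) {
  stopifnot(vwp >= 0, vwp <= 1, fluff_density >= 0, fluff_density <= 1,
            max_depth >= 1)
  structure(list(vwp = vwp, haircut = haircut, fluff = fluff,
                 fluff_density = fluff_density,
                 max_depth = as.integer(max_depth)),
            class = "mcode_params")
}

#' Threshold an AC landscape at a correlation cut-off
#'
#' Keeps edges with `|assigned_r|` strictly greater than the cut-off
#' (matching ">0.85"-style thresholds); `NA` or `NULL` keeps every edge.
#' Isolated nodes are dropped.
#'
#' @param landscape An `ac_landscape`.
#' @param cutoff Numeric in `[0, 1)`, or `NA`/`NULL` for no cut-off.
#' @return An undirected [igraph][igraph::graph_from_data_frame] graph whose
#'   vertex names are gene identifiers.
#' @export
apply_cutoff <- function(landscape, cutoff = NULL) {
  edges <- landscape$edges
  if (!is.null(cutoff) && !is.na(cutoff)) {
    if (cutoff < 0 || cutoff >= 1) stop("cutoff must lie in [0, 1) or be NA")
    edges <- edges[abs(edges$assigned_r) > cutoff, , drop = FALSE]
  }
  igraph::graph_from_data_frame(edges[, c("gene_a", "gene_b")],
                                directed = FALSE)
}

#' k-core indices of a graph
#'
#' Standard k-core decomposition by iterative peeling (via igraph).
#'
#' @param graph An undirected igraph graph.
#' @return Named integer vector: vertex -> core index.
#' @export
core_numbers <- function(graph) {
  igraph::coreness(graph)
}

# internal: density 2E / (n (n-1)) of an igraph (0 for n < 2)
graph_density2 <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) return(0)
  2 * igraph::ecount(g) / (n * (n - 1))
}

#' MCODE vertex weights
#'
#' The weight of vertex v is `k_max * density` of the highest k-core of the
#' subgraph induced by v's closed neighbourhood, where `k_max` is that
#' subgraph's maximum core index and density is `2E / (n (n - 1))`. Isolated
#' vertices weigh 0; a vertex inside K_n weighs `n - 1`.
#'
#' @param graph An undirected igraph graph.
#' @return Named numeric vector of weights, in vertex order.
#' @export
mcode_vertex_weights <- function(graph) {
  vs <- igraph::V(graph)
  nm <- igraph::vertex_attr(graph, "name")
  if (is.null(nm)) nm <- as.character(seq_along(vs))
  w <- numeric(length(vs))
  adj <- igraph::adjacent_vertices(graph, vs)
  for (i in seq_along(vs)) {
    nb <- c(i, as.integer(adj[[i]]))
    nb <- unique(nb)
    if (length(nb) < 2) { w[i] <- 0; next }
    sub <- igraph::induced_subgraph(graph, nb)
    cores <- igraph::coreness(sub)
    k_max <- max(cores)
    if (k_max == 0) { w[i] <- 0; next }
    core_sub <- igraph::induced_subgraph(sub, which(cores == k_max))
    w[i] <- k_max * graph_density2(core_sub)
  }
  names(w) <- nm
  w
}

# internal: edge counts of a gene set within a host graph
module_stats <- function(graph, genes) {
  sub <- igraph::induced_subgraph(graph, genes)
  internal <- igraph::ecount(sub)
  deg_total <- sum(igraph::degree(graph, genes))
  boundary <- deg_total - 2 * internal
  list(internal_edges = internal, boundary_edges = boundary,
       connectivity_ratio = if (internal == 0) Inf else boundary / internal,
       density = graph_density2(sub),
       score = graph_density2(sub) * length(genes))
}

#' MCODE module detection
#'
#' Seeds are unassigned vertices in decreasing weight order (ties broken by
#' the smallest gene identifier). From each seed, BFS expansion admits
#' unassigned neighbours whose weight is at least `seed_weight * (1 - vwp)`,
#' up to `max_depth` levels; every admitted vertex joins exactly one module.
#' Haircut then removes (iteratively) vertices with within-module degree
#' below 2; fluff adds boundary neighbours whose closed-neighbourhood
#' density exceeds `fluff_density`. Modules with fewer than two vertices are
#' discarded. Modules are returned by decreasing score (density x size; ties
#' by size then smallest gene).
#'
#' @param graph An undirected igraph graph with named vertices.
#' @param params An [mcode_params].
#' @return List of `ac_module` objects: `genes` (sorted), `score`,
#'   `internal_edges`, `boundary_edges`, `connectivity_ratio`, `cutoff`
#'   (NA here; filled by [sweep_modules()]).
#' @export
mcode_find_modules <- function(graph, params = mcode_params()) {
  stopifnot(inherits(params, "mcode_params"))
  n <- igraph::vcount(graph)
  if (n == 0 || igraph::ecount(graph) == 0) return(list())
  nm <- igraph::vertex_attr(graph, "name")
  if (is.null(nm)) {
    nm <- as.character(seq_len(n))
    graph <- igraph::set_vertex_attr(graph, "name", value = nm)
  }
  w <- mcode_vertex_weights(graph)
  adj <- igraph::adjacent_vertices(graph, igraph::V(graph))
  seed_order <- order(-w, nm)
  assigned <- rep(FALSE, n)
  raw_modules <- list()

  for (s in seed_order) {
    if (assigned[s]) next
    threshold <- w[s] * (1 - params$vwp)
    members <- s
    assigned[s] <- TRUE
    frontier <- s
    depth <- 0L
    while (length(frontier) > 0 && depth < params$max_depth) {
      nxt <- integer()
      for (v in frontier) {
        for (u in as.integer(adj[[v]])) {
          if (!assigned[u] && w[u] >= threshold) {
            assigned[u] <- TRUE
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1L
    }
    raw_modules[[length(raw_modules) + 1L]] <- members
  }

  finished <- list()
  for (members in raw_modules) {
    genes <- nm[members]
    if (params$haircut) {
      repeat {
        sub <- igraph::induced_subgraph(graph, genes)
        deg <- igraph::degree(sub)
        low <- igraph::vertex_attr(sub, "name")[deg < 2]
        if (length(low) == 0) break
        genes <- setdiff(genes, low)
        if (length(genes) == 0) break
      }
    }
    if (params$fluff && length(genes) > 0) {
      nbrs <- setdiff(nm[unique(unlist(lapply(match(genes, nm), function(v)
        as.integer(adj[[v]]))))], genes)
      add <- character()
      for (u in nbrs) {
        closed <- c(u, nm[as.integer(adj[[match(u, nm)]])])
        d <- graph_density2(igraph::induced_subgraph(graph, unique(closed)))
        if (d > params$fluff_density) add <- c(add, u)
      }
      genes <- union(genes, add)
    }
    if (length(genes) < 2) next
    st <- module_stats(graph, genes)
    finished[[length(finished) + 1L]] <- structure(
      list(genes = sort(genes), score = st$score,
           internal_edges = st$internal_edges,
           boundary_edges = st$boundary_edges,
           connectivity_ratio = st$connectivity_ratio,
           cutoff = NA_real_),
      class = "ac_module")
  }
  if (length(finished) == 0) return(list())
  scores <- vapply(finished, function(m) m$score, 0)
  sizes <- vapply(finished, function(m) length(m$genes), 0L)
  firsts <- vapply(finished, function(m) m$genes[1], "")
  finished[order(-scores, -sizes, firsts)]
}

#' @export
print.ac_module <- function(x, ...) {
  cat(sprintf("ac_module: %d genes, score %.3f, %d internal / %d boundary edges\n",
              length(x$genes), x$score, x$internal_edges, x$boundary_edges))
  invisible(x)
}

#' Correlation cut-off sweep with module lineage tracking
#'
#' Runs MCODE at each cut-off (sorted decreasing; `NA` means no cut-off and
#' comes last) and tracks module lineages across adjacent cut-offs by best
#' Jaccard overlap (>= 0.3). For each lineage the chosen cut-off is the one
#' giving maximal module size over its eligible cut-offs. A cut-off is
#' ineligible when the module's connectivity there is a major step: its
#' `connectivity_ratio` both reaches at least 1 (boundary edges outnumber
#' internal edges) and has grown by `jump_factor` or more relative to the
#' previous (higher) cut-off. Requiring the absolute condition keeps a
#' cohesive module that merely gains its first few boundary edges, or whose
#' ratio spikes transiently while the cut-off bisects it, from being frozen
#' at a fragment. Ties on size go to the lowest cut-off (the size
#' immediately preceding the jump).
#'
#' @param landscape An `ac_landscape`.
#' @param cutoffs Numeric vector sorted decreasing, `NA` allowed last.
#' @param params An [mcode_params].
#' @param jump_factor Relative connectivity growth deemed a major step.
#' @return A `sweep_result`: `table` (data.frame lineage, cutoff, size,
#'   connectivity_ratio, score), `chosen` (data.frame lineage,
#'   chosen_cutoff, size), `modules` (list: lineage -> `ac_module` at its
#'   chosen cut-off).
#' @export
sweep_modules <- function(landscape, cutoffs, params = mcode_params(),
                          jump_factor = 2.0) {
  num <- cutoffs[!is.na(cutoffs)]
  if (is.unsorted(rev(num))) stop("cutoffs must be sorted decreasing")
  lineages <- list()       # lineage id -> list of entries
  prev <- list()           # modules at previous cutoff with lineage ids
  rows <- list()
  for (ci in seq_along(cutoffs)) {
    cut <- cutoffs[ci]
    g <- apply_cutoff(landscape, cut)
    mods <- mcode_find_modules(g, params)
    cur <- list()
    prev_taken <- rep(FALSE, length(prev))
    for (m in mods) {
      m$cutoff <- cut
      lin <- NA_integer_
      if (length(prev)) {
        jac <- vapply(prev, function(p)
          length(intersect(p$module$genes, m$genes)) /
            length(union(p$module$genes, m$genes)), 0)
        jac[prev_taken] <- -1
        best <- which.max(jac)
        if (length(best) && jac[best] >= 0.3) {
          lin <- prev[[best]]$lineage
          prev_taken[best] <- TRUE
        }
      }
      if (is.na(lin)) {
        lin <- length(lineages) + 1L
        lineages[[lin]] <- list()
      }
      lineages[[lin]][[length(lineages[[lin]]) + 1L]] <- m
      cur[[length(cur) + 1L]] <- list(lineage = lin, module = m)
      rows[[length(rows) + 1L]] <- data.frame(
        lineage = lin, cutoff = cut, size = length(m$genes),
        connectivity_ratio = m$connectivity_ratio, score = m$score)
    }
    prev <- cur
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lineage = integer(), cutoff = numeric(), size = integer(),
               connectivity_ratio = numeric(), score = numeric())

  chosen_rows <- list()
  chosen_modules <- list()
  single <- length(cutoffs) < 2
  for (lin in seq_along(lineages)) {
    entries <- lineages[[lin]]
    if (single) {
      pick <- 1L
      chosen_cut <- NA_real_
    } else {
      ratios <- vapply(entries, function(e) e$connectivity_ratio, 0)
      # an entry is frozen out when its boundary outnumbers its interior
      # (ratio >= 1) and it just underwent a major (>= jump_factor) step;
      # the first entry is always eligible so every lineage has a choice
      eligible <- rep(TRUE, length(entries))
      if (length(entries) > 1) {
        for (i in 2:length(entries)) {
          eligible[i] <- !(ratios[i] >= 1 &&
                             ratios[i] >= jump_factor * ratios[i - 1])
        }
      }
      sizes <- vapply(entries, function(e) length(e$genes), 0L)
      sizes[!eligible] <- -1L
      pick <- max(which(sizes == max(sizes)))  # ties -> lowest cutoff
      chosen_cut <- entries[[pick]]$cutoff
    }
    chosen_rows[[lin]] <- data.frame(
      lineage = lin, chosen_cutoff = chosen_cut,
      size = length(entries[[pick]]$genes))
    chosen_modules[[lin]] <- entries[[pick]]
  }
  structure(list(table = tab,
                 chosen = if (length(chosen_rows)) do.call(rbind, chosen_rows)
                          else data.frame(lineage = integer(),
                                          chosen_cutoff = numeric(),
                                          size = integer()),
                 modules = chosen_modules),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("sweep_result: %d lineage(s) over %d cutoff row(s)\n",
              length(x$modules), nrow(x$table)))
  print(x$chosen)
  invisible(x)
}
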