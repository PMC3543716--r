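#' Intersect condition networks into an Always-Correlated landscape
#'
#' An edge enters the AC landscape iff the unordered gene pair is
#' PCIT-significant in *every* supplied network. Edge identity is the pair
#' alone; the per-network correlations are recorded, and the edge's assigned
#' weight and sign come from the reference network (weights need not agree
#' across networks). An edge whose per-network correlations do not all share
#' one sign is kept but flagged `sign_consistent = FALSE`.
#'
#' @param networks List of `ac_network` objects (from [build_network()]).
#' @param reference_group Name of the network supplying `assigned_r`
#'   (default `"Overall"`; must be among the inputs).
#' @return An `ac_landscape`: `nodes` (edge endpoints), `edges` (data.frame
#'   with `gene_a`, `gene_b`, one `r_<group>` column per network,
#'   `assigned_r`, `sign`, `sign_consistent`), `source_groups`,
#'   `reference_group`.
#' @export
intersect_networks <- function(networks, reference_group = "Overall") {
  if (length(networks) == 0) stop("empty network list")
  groups <- vapply(networks, function(n) n$group, "")
  if (anyDuplicated(groups)) stop("duplicate group names among networks")
  if (!reference_group %in% groups)
    stop("reference group '", reference_group, "' not among the networks")

  key_list <- lapply(networks, function(n)
    edge_key(n$edges$gene_a, n$edges$gene_b))
  common <- Reduce(intersect, key_list)
  common <- sort(common)
  edges <- edges_from_keys(common)
  for (i in seq_along(networks)) {
    k <- key_list[[i]]
    edges[[paste0("r_", groups[i])]] <-
      networks[[i]]$edges$r[match(common, k)]
  }
  r_cols <- paste0("r_", groups)
  edges$assigned_r <- edges[[paste0("r_", reference_group)]]
  edges$sign <- ifelse(edges$assigned_r < 0, "negative", "positive")
  if (nrow(edges)) {
    rr <- as.matrix(edges[r_cols])
    edges$sign_consistent <- apply(rr > 0, 1, function(z) all(z) || !any(z))
  } else {
    edges$sign_consistent <- logical()
  }
  structure(list(nodes = sort(unique(c(edges$gene_a, edges$gene_b))),
                 edges = edges, source_groups = groups,
                 reference_group = reference_group),
            class = "ac_landscape")
}

#' @export
print.ac_landscape <- function(x, ...) {
  cat(sprintf("ac_landscape: %d nodes, %d edges (intersection of %d networks)\n",
              length(x$nodes), nrow(x$edges), length(x$source_groups)))
  invisible(x)
}

# internal: igraph of a landscape (all edges)
landscape_graph <- function(landscape) {
  igraph::graph_from_data_frame(
    landscape$edges[, c("gene_a", "gene_b")], directed = FALSE,
    vertices = data.frame(name = landscape$nodes))
}

#' Connected components of an AC landscape
#'
#' @param landscape An `ac_landscape`.
#' @return List of character vectors (sorted gene sets), ordered by
#'   decreasing size then smallest gene identifier.
#' @export
landscape_components <- function(landscape) {
  if (nrow(landscape$edges) == 0) return(list())
  comp <- igraph::components(landscape_graph(landscape))
  sets <- split(names(comp$membership), comp$membership)
  sets <- lapply(unname(sets), sort)
  firsts <- vapply(sets, `[`, "", 1L)
  sets[order(-lengths(sets), firsts)]
}

#' Edge-sign and component report for an AC landscape
#'
#' Counts negative and positive edges by assigned sign, reports percentages
#' (one decimal, half-up rounding) and connected-component sizes. For a
#' landscape without edges all counts and percentages are zero.
#'
#' @param landscape An `ac_landscape`, or a list with an `edges` data.frame
#'   carrying a `sign` column (so reports can also be built from published
#'   edge tables).
#' @return List of class `ac_sign_report`: `component_sizes`, `edge_count`,
#'   `negative_edges`, `negative_pct`, `positive_edges`, `positive_pct`.
#' @examples
#' # a landscape of 5196 edges of which 1368 are negative
#' edges <- data.frame(gene_a = sprintf("g%04da", 1:5196),
#'                     gene_b = sprintf("g%04db", 1:5196),
#'                     sign = rep(c("negative", "positive"), c(1368, 3828)))
#' sign_report(list(edges = edges))$negative_pct  # 26.3
#' @export
sign_report <- function(landscape) {
  edges <- landscape$edges
  m <- nrow(edges)
  neg <- sum(edges$sign == "negative")
  pos <- sum(edges$sign == "positive")
  sizes <- if (inherits(landscape, "ac_landscape")) {
    lengths(landscape_components(landscape))
  } else {
    integer()
  }
  structure(list(
    component_sizes = as.integer(sizes),
    edge_count = m,
    negative_edges = neg,
    negative_pct = if (m > 0) round_half_up(100 * neg / m, 1) else 0,
    positive_edges = pos,
    positive_pct = if (m > 0) round_half_up(100 * pos / m, 1) else 0),
    class = "ac_sign_report")
}

#' @export
print.ac_sign_report <- function(x, ...) {
  cat(sprintf("edges: %d (%d negative, %.1f%%; %d positive, %.1f%%)\n",
              x$edge_count, x$negative_edges, x$negative_pct,
              x$positive_edges, x$positive_pct))
  if (length(x$component_sizes))
    cat("component sizes:",
        paste(head(x$component_sizes, 10), collapse = ", "),
        if (length(x$component_sizes) > 10) "..." else "", "\n")
  invisible(x)
}
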