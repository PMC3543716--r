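#' Confident 1:1 identifier mapping
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b`; both columns
#'   must be duplicate-free (strictly 1:1).
#' @return An `id_mapping`: list with `pairs` and `universe_size`
#'   (`= nrow(pairs)`, the number of confidently linked genes).
#' @export
id_mapping <- function(pairs) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_a", "gene_b") %in% names(pairs)))
  if (anyDuplicated(pairs$gene_a) || anyDuplicated(pairs$gene_b))
    stop("mapping is not 1:1")
  structure(list(pairs = pairs[, c("gene_a", "gene_b")],
                 universe_size = nrow(pairs)),
            class = "id_mapping")
}

#' Build a confident 1:1 mapping from two platform annotations
#'
#' Links the two platforms through a shared gene-symbol column: a symbol is
#' linkable when it is confidently annotated on both platforms and maps to
#' exactly one platform identifier on each side; symbols with multiple
#' candidates on either side are dropped (their count is recorded in the
#' `n_conflicts` attribute).
#'
#' @param annot_a,annot_b data.frames with columns `gene_id`, `symbol` and
#'   optionally `status` (`"confident"`/`"dubious"`; missing means
#'   confident).
#' @return An [id_mapping] from platform-A to platform-B identifiers.
#' @export
build_mapping <- function(annot_a, annot_b) {
  clean <- function(a) {
    a <- as.data.frame(a, stringsAsFactors = FALSE)
    stopifnot(all(c("gene_id", "symbol") %in% names(a)))
    if ("status" %in% names(a)) a <- a[a$status == "confident", , drop = FALSE]
    a <- unique(a[, c("gene_id", "symbol")])
    dup <- unique(a$symbol[duplicated(a$symbol)])
    list(tab = a[!a$symbol %in% dup, , drop = FALSE], n_conflicts = length(dup))
  }
  ca <- clean(annot_a)
  cb <- clean(annot_b)
  common <- intersect(ca$tab$symbol, cb$tab$symbol)
  common <- sort(common)
  pairs <- data.frame(
    gene_a = ca$tab$gene_id[match(common, ca$tab$symbol)],
    gene_b = cb$tab$gene_id[match(common, cb$tab$symbol)],
    symbol = common, stringsAsFactors = FALSE)
  out <- id_mapping(pairs[, c("gene_a", "gene_b")])
  out$pairs$symbol <- pairs$symbol
  attr(out, "n_conflicts") <- ca$n_conflicts + cb$n_conflicts
  out
}

#' Compare two AC landscapes under an identifier mapping
#'
#' All node statistics are computed inside the mapping universe (genes
#' measurable on both platforms): node overlap and its hypergeometric
#' p-value, identical-edge counts (an edge is shared when its mapped
#' unordered pair is an edge in both landscapes; sign agreement is reported
#' but not required), and per paired module the a-only / both / b-only gene
#' counts.
#'
#' @param land_a,land_b `ac_landscape` objects.
#' @param mapping An [id_mapping] from A-space to B-space identifiers.
#' @param modules_a,modules_b Named lists: module id -> character vector of
#'   member genes (optional when `module_pairing` is empty).
#' @param module_pairing data.frame with columns `id_a`, `id_b` naming the
#'   module pairs to tabulate.
#' @return A `landscape_comparison`: `nodes_a_only`, `nodes_shared`,
#'   `nodes_b_only`, `node_overlap_p`, `node_overlap_expected`,
#'   `shared_edges`, `shared_edge_sign_agreement`, `module_overlap`
#'   (data.frame `module_a`, `module_b`, `a_only`, `both`, `b_only`).
#' @export
compare_landscapes <- function(land_a, land_b, mapping,
                               modules_a = list(), modules_b = list(),
                               module_pairing = NULL) {
  stopifnot(inherits(mapping, "id_mapping"))
  if (nrow(mapping$pairs) == 0) stop("empty identifier mapping")
  a2b <- setNames(mapping$pairs$gene_b, mapping$pairs$gene_a)

  nodes_a_u <- intersect(land_a$nodes, mapping$pairs$gene_a)
  nodes_b_u <- intersect(land_b$nodes, mapping$pairs$gene_b)
  mapped_a <- unname(a2b[nodes_a_u])
  shared <- intersect(mapped_a, nodes_b_u)
  ot <- overlap_test(mapped_a, nodes_b_u, mapping$pairs$gene_b)

  edge_keys_in_universe <- function(edges, universe, translate = NULL) {
    ina <- edges$gene_a %in% universe & edges$gene_b %in% universe
    e <- edges[ina, , drop = FALSE]
    ga <- e$gene_a; gb <- e$gene_b
    if (!is.null(translate)) { ga <- unname(translate[ga]); gb <- unname(translate[gb]) }
    list(keys = edge_key(ga, gb), sign = e$sign)
  }
  ea <- edge_keys_in_universe(land_a$edges, mapping$pairs$gene_a, a2b)
  eb <- edge_keys_in_universe(land_b$edges, mapping$pairs$gene_b)
  shared_keys <- intersect(ea$keys, eb$keys)
  sign_agree <- if (length(shared_keys)) {
    sum(ea$sign[match(shared_keys, ea$keys)] ==
          eb$sign[match(shared_keys, eb$keys)])
  } else 0L

  module_rows <- NULL
  if (!is.null(module_pairing) && nrow(module_pairing) > 0) {
    bad <- c(setdiff(module_pairing$id_a, names(modules_a)),
             setdiff(module_pairing$id_b, names(modules_b)))
    if (length(bad))
      stop("unpaired module id(s): ", paste(unique(bad), collapse = ", "))
    module_rows <- do.call(rbind, lapply(seq_len(nrow(module_pairing)),
                                         function(i) {
      ga <- intersect(modules_a[[module_pairing$id_a[i]]], mapping$pairs$gene_a)
      gb <- intersect(modules_b[[module_pairing$id_b[i]]], mapping$pairs$gene_b)
      ga_mapped <- unname(a2b[ga])
      both <- length(intersect(ga_mapped, gb))
      data.frame(module_a = module_pairing$id_a[i],
                 module_b = module_pairing$id_b[i],
                 a_only = length(ga) - both, both = both,
                 b_only = length(gb) - both,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(
    nodes_a_only = length(nodes_a_u) - length(shared),
    nodes_shared = length(shared),
    nodes_b_only = length(nodes_b_u) - length(shared),
    node_overlap_p = ot$p,
    node_overlap_expected = ot$expected,
    shared_edges = length(shared_keys),
    shared_edge_sign_agreement = sign_agree,
    module_overlap = module_rows),
    class = "landscape_comparison")
}

#' @export
print.landscape_comparison <- function(x, ...) {
  cat(sprintf("nodes: %d a-only / %d shared / %d b-only (p = %.3g)\n",
              x$nodes_a_only, x$nodes_shared, x$nodes_b_only,
              x$node_overlap_p))
  cat(sprintf("shared edges: %d (%d with matching sign)\n",
              x$shared_edges, x$shared_edge_sign_agreement))
  if (!is.null(x$module_overlap)) print(x$module_overlap)
  invisible(x)
}
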