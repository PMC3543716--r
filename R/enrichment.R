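#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of drawing
#' at least `k` annotated genes when `n` genes are drawn without replacement
#' from a universe of `N` genes of which `K` are annotated. Evaluated in
#' log-space via [stats::phyper].
#'
#' @param k Observed overlap.
#' @param K Annotated genes in the universe.
#' @param n Drawn genes (e.g. module size).
#' @param N Universe size.
#' @return The upper-tail probability (1 when `k = 0`).
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (K > N || n > N) stop("K and n must not exceed N")
  if (k > min(K, n)) stop("k must not exceed min(K, n)")
  if (k < 0) stop("k must be non-negative")
  phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Read a GMT gene-set file
#'
#' @param path Path to a tab-separated GMT file (term, description,
#'   genes...).
#' @return A named list of character vectors with a `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, "", 1L)
  if (anyDuplicated(ids)) stop("duplicate term ids in GMT file")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- ids
  attr(sets, "description") <- setNames(vapply(parts, `[`, "", 2L), ids)
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets Named list of character vectors (optionally with a
#'   `description` attribute as produced by [read_gmt()]).
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(id)
    paste(c(id, desc[[id]], sets[[id]]), collapse = "\t"), "")
  writeLines(lines, path)
}

#' Gene-set over-representation in a module
#'
#' Flat hypergeometric enrichment of each term in a collection against a
#' module, with the term's genes intersected with the universe before
#' counting. Terms with no overlap with the module are omitted. Results are
#' sorted by increasing p-value.
#'
#' @param module_genes Character vector, a subset of `universe`.
#' @param universe Character vector, the reference gene set (e.g. the AC
#'   landscape node set, or all filtered genes).
#' @param collection Named list of character vectors (see [read_gmt()]).
#' @param correction `"BH"`, `"bonferroni"` or `"none"`; applied over the
#'   returned terms.
#' @return data.frame with columns `term_id`, `term_name`, `k`, `K`, `n`,
#'   `N`, `p`, `p_adj`.
#' @export
enrich <- function(module_genes, universe, collection,
                   correction = c("BH", "bonferroni", "none")) {
  correction <- match.arg(correction)
  module_genes <- unique(module_genes)
  universe <- unique(universe)
  outside <- setdiff(module_genes, universe)
  if (length(outside))
    stop("module gene(s) outside the universe: ",
         paste(outside, collapse = ", "))
  desc <- attr(collection, "description")
  N <- length(universe)
  n <- length(module_genes)
  rows <- lapply(names(collection), function(id) {
    term <- intersect(collection[[id]], universe)
    k <- length(intersect(term, module_genes))
    if (k < 1) return(NULL)
    data.frame(term_id = id,
               term_name = if (!is.null(desc)) desc[[id]] else id,
               k = k, K = length(term), n = n, N = N,
               p = hypergeom_upper_tail(k, length(term), n, N),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) {
    return(data.frame(term_id = character(), term_name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p = numeric(), p_adj = numeric()))
  }
  out <- do.call(rbind, rows)
  out$p_adj <- switch(correction,
                      BH = p.adjust(out$p, "BH"),
                      bonferroni = p.adjust(out$p, "bonferroni"),
                      none = out$p)
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypergeometric overlap of two gene sets
#'
#' Tests whether the intersection of two gene sets drawn from a common
#' universe is larger than expected by chance.
#'
#' @param set_a,set_b Character vectors, subsets of `universe`.
#' @param universe Character vector.
#' @return List with `overlap`, `expected` (`|a| |b| / N`) and `p`
#'   (upper-tail hypergeometric probability of at least the observed
#'   overlap).
#' @export
overlap_test <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  bad <- c(setdiff(set_a, universe), setdiff(set_b, universe))
  if (length(bad))
    stop("set member(s) outside the universe: ", paste(bad, collapse = ", "))
  ov <- length(intersect(set_a, set_b))
  N <- length(universe)
  list(overlap = ov,
       expected = length(set_a) * length(set_b) / N,
       p = hypergeom_upper_tail(ov, length(set_a), length(set_b), N))
}
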