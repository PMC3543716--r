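#' Pearson correlation matrix over one analysis group
#'
#' @param expr An [ac_expression].
#' @param group Group name (>= 3 samples); `NULL` uses all samples.
#' @return Symmetric correlation matrix with unit diagonal, genes as
#'   dimnames.
#' @export
correlation_matrix <- function(expr, group = NULL) {
  samples <- if (is.null(group)) colnames(expr$values) else group_samples(expr, group)
  if (length(samples) < 3) stop("need >= 3 samples for correlation")
  v <- expr$values[, samples, drop = FALSE]
  sds <- apply(v, 1, sd)
  if (any(sds == 0)) {
    stop("zero-variance gene(s) over group samples: ",
         paste(rownames(v)[sds == 0], collapse = ", "),
         " (variation filter bypassed?)")
  }
  r <- cor(t(v))
  diag(r) <- 1
  r
}

#' First-order partial correlation
#'
#' Correlation between x and y after removing the linear effect of a third
#' variable z: `(r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) (1 - r_yz^2))`,
#' clamped to `[-1, 1]`.
#'
#' @param rxy,rxz,ryz Pairwise Pearson correlations.
#' @return The partial correlation `r_xy.z`.
#' @export
first_order_partial <- function(rxy, rxz, ryz) {
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12)
    stop("degenerate trio: conditioning correlation at or near |r| = 1")
  p <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  max(-1, min(1, p))
}

#' PCIT significance mask
#'
#' Scans every unordered gene trio (x, y, z): the three first-order partial
#' correlations are formed, a trio-specific tolerance `eps` is the mean of
#' the partial/direct ratios (a ratio is skipped when its direct correlation
#' is zero within 1e-12), and edge (x, y) is flagged non-significant in the
#' trio when `|r_xy| < |eps * r_xz|` and `|r_xy| < |eps * r_yz|`. An edge is
#' kept iff its correlation is nonzero and no trio flags it; with two genes
#' (no trios) any nonzero correlation is kept. Trios containing a near-unit
#' correlation (|r| >= 1 - 1e-12, duplicated genes) are skipped and counted,
#' so such pairs keep their edge but never act as conditioning variables.
#'
#' @param corr Symmetric correlation matrix (unit diagonal) with gene
#'   dimnames.
#' @param ratio_mode `"signed"` (default) averages the ratios as-is;
#'   `"absolute"` averages their absolute values.
#' @param strict If `TRUE` (default) the flag inequality is strict (`<`);
#'   `FALSE` uses `<=`. Exposed so behaviour can be pinned to a reference.
#' @return A list of class `pcit_mask`: `keep` (symmetric logical matrix,
#'   FALSE diagonal), `n_degenerate_trios`, `n_no_ratio_trios`.
#' @examples
#' r <- matrix(0.6, 4, 4); diag(r) <- 1
#' dimnames(r) <- list(letters[1:4], letters[1:4])
#' pcit_mask(r)$keep["a", "b"]  # constant-rho matrices keep every edge
#' @export
pcit_mask <- function(corr, ratio_mode = c("signed", "absolute"),
                      strict = TRUE) {
  ratio_mode <- match.arg(ratio_mode)
  n <- nrow(corr)
  if (n < 2) stop("need >= 2 genes")
  if (is.null(rownames(corr))) stop("correlation matrix needs gene dimnames")
  if (max(abs(corr - t(corr))) > 1e-12) stop("correlation matrix not symmetric")
  res <- .pcit_mask_cpp(corr, ratio_mode == "absolute", strict)
  keep <- res$keep
  dimnames(keep) <- dimnames(corr)
  if (res$n_degenerate_trios > 0) {
    warning(sprintf("%d degenerate trio(s) skipped (near-unit correlation)",
                    res$n_degenerate_trios))
  }
  structure(list(keep = keep,
                 n_degenerate_trios = res$n_degenerate_trios,
                 n_no_ratio_trios = res$n_no_ratio_trios),
            class = "pcit_mask")
}

#' Build one condition group's co-expression network
#'
#' Computes the group's Pearson correlation matrix, applies the PCIT
#' significance mask, and returns the surviving edges weighted by the
#' Pearson correlation.
#'
#' @param expr An [ac_expression] already filtered for the group (or with a
#'   group table from which the samples are taken).
#' @param group Group name; `NULL` uses all samples (an "Overall" network).
#' @param ratio_mode,strict Passed to [pcit_mask()].
#' @return An `ac_network`: list with `group`, `nodes`, and `edges` (a
#'   data.frame `gene_a`, `gene_b`, `r` with `gene_a < gene_b`).
#' @export
build_network <- function(expr, group = NULL, ratio_mode = "signed",
                          strict = TRUE) {
  r <- correlation_matrix(expr, group)
  mask <- suppressWarnings(pcit_mask(r, ratio_mode = ratio_mode, strict = strict))
  keep <- mask$keep
  idx <- which(upper.tri(keep) & keep, arr.ind = TRUE)
  genes <- rownames(r)
  a <- genes[idx[, 1]]
  b <- genes[idx[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  edges <- data.frame(gene_a = a, gene_b = b,
                      r = r[idx], stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(group = if (is.null(group)) "Overall" else group,
                 nodes = genes, edges = edges),
            class = "ac_network")
}

#' @export
print.ac_network <- function(x, ...) {
  cat(sprintf("ac_network '%s': %d genes, %d significant edges\n",
              x$group, length(x$nodes), nrow(x$edges)))
  invisible(x)
}
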