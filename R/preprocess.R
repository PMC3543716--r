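#' Probe annotation table
#'
#' @param probe_id,gene_id,status Character vectors; `status` is `"confident"`
#'   or `"dubious"` (no or multiple predicted genes for the probe set).
#' @return A validated data.frame of class `probe_annotation`.
#' @export
probe_annotation <- function(probe_id, gene_id, status) {
  if (anyDuplicated(probe_id)) stop("duplicate probe_id in annotation")
  if (!all(status %in% c("confident", "dubious")))
    stop("status must be 'confident' or 'dubious'")
  if (any(status == "confident" & (is.na(gene_id) | gene_id == "")))
    stop("confident probes must carry a gene assignment")
  structure(data.frame(probe_id = probe_id, gene_id = gene_id,
                       status = status, stringsAsFactors = FALSE),
            class = c("probe_annotation", "data.frame"))
}

# internal: annotation rows for the expression rows, erroring on gaps
match_annotation <- function(expr, annot) {
  idx <- match(rownames(expr$values), annot$probe_id)
  if (anyNA(idx)) {
    stop("unannotated probe(s): ",
         paste(rownames(expr$values)[is.na(idx)], collapse = ", "))
  }
  annot[idx, , drop = FALSE]
}

#' Remove probes with a dubious gene assignment
#'
#' Drops probe sets annotated as dubious (no gene, or multiple genes,
#' predicted for the probe set); row order is preserved.
#'
#' @param expr An [ac_expression] keyed by probe.
#' @param annot A [probe_annotation] covering every row of `expr`.
#' @return The filtered [ac_expression].
#' @export
drop_dubious_probes <- function(expr, annot) {
  a <- match_annotation(expr, annot)
  subset_expression(expr, rows = which(a$status == "confident"))
}

#' Collapse probes to genes by highest mean expression
#'
#' For genes represented by several probe sets, retains the probe set with
#' the highest expression level averaged across all samples and relabels the
#' row with the gene identifier. Ties are broken by the lexicographically
#' smallest probe identifier, for determinism.
#'
#' @param expr An [ac_expression] of confident probes.
#' @param annot A [probe_annotation].
#' @return An [ac_expression] with one row per gene.
#' @export
collapse_to_genes <- function(expr, annot) {
  a <- match_annotation(expr, annot)
  if (any(a$status != "confident"))
    stop("collapse_to_genes expects only confident probes; drop dubious first")
  means <- rowMeans(expr$values)
  ord <- order(a$gene_id, -means, a$probe_id)
  keep_first <- !duplicated(a$gene_id[ord])
  chosen <- ord[keep_first]
  chosen <- sort(chosen)  # preserve original row order
  out <- subset_expression(expr, rows = chosen)
  rownames(out$values) <- a$gene_id[chosen]
  if (!is.null(out$detection)) rownames(out$detection) <- a$gene_id[chosen]
  out
}

#' Detection-flag filter
#'
#' Retains genes with a "Present" call in at least `min_timepoints` samples.
#' If a sample-to-timepoint table is supplied, the stricter reading is used:
#' a gene is retained if there is at least `min_timepoints` time point(s) in
#' which *all* samples are called Present.
#'
#' @param expr An [ac_expression] with detection calls.
#' @param min_timepoints Minimum number of qualifying samples (or time
#'   points, when `timepoints` is given).
#' @param timepoints Optional data.frame with columns `sample` and
#'   `timepoint`.
#' @return The filtered [ac_expression].
#' @export
filter_present <- function(expr, min_timepoints = 1, timepoints = NULL) {
  if (is.null(expr$detection)) stop("expression object carries no detection calls")
  pres <- expr$detection == "P"
  if (is.null(timepoints)) {
    n_ok <- rowSums(pres)
  } else {
    tp <- timepoints$timepoint[match(colnames(expr$values), timepoints$sample)]
    if (anyNA(tp)) stop("timepoint table does not cover all samples")
    per_tp <- vapply(unique(tp), function(t)
      apply(pres[, tp == t, drop = FALSE], 1, all), logical(nrow(pres)))
    n_ok <- rowSums(matrix(per_tp, nrow = nrow(pres)))
  }
  subset_expression(expr, rows = which(n_ok >= min_timepoints))
}

#' Variation filter within an analysis group
#'
#' Removes genes with no deviation of expression from their mean beyond
#' `k_sd` standard deviations across the group's samples, and restricts the
#' matrix to those samples. Under the default `global_sd` mode the yardstick
#' is the standard deviation of the whole subset's value distribution (all
#' genes, the group's samples); `gene_sd` uses each gene's own SD over the
#' group instead. A gene is kept iff its maximum absolute deviation from its
#' own group mean exceeds `k_sd` times the chosen SD.
#'
#' @param expr An [ac_expression].
#' @param group Group name (must have >= 3 samples).
#' @param k_sd Multiple of the SD a gene must exceed to be kept.
#' @param mode `"global_sd"` (default) or `"gene_sd"`.
#' @return An [ac_expression] restricted to the group's samples and
#'   surviving genes.
#' @export
filter_low_variation <- function(expr, group, k_sd = 1,
                                 mode = c("global_sd", "gene_sd")) {
  mode <- match.arg(mode)
  samples <- group_samples(expr, group)
  if (length(samples) < 3)
    stop(sprintf("group '%s' has %d samples; >= 3 required",
                 group, length(samples)))
  v <- expr$values[, samples, drop = FALSE]
  mu <- rowMeans(v)
  dev <- abs(v - mu)
  max_dev <- apply(dev, 1, max)
  yardstick <- if (mode == "global_sd") {
    rep(sd(as.vector(v)), nrow(v))
  } else {
    apply(v, 1, sd)
  }
  keep <- max_dev > k_sd * yardstick
  subset_expression(expr, rows = which(keep), samples = samples)
}
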