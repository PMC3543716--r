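#' Module-to-regulator ranking
#'
#' Scores each transcription factor in a catalogue against one module as the
#' mean absolute correlation between the TF and the module's genes
#' (excluding the TF itself when it is a member), using the overall
#' correlation matrix; correlations are not restricted to PCIT-significant
#' pairs. Alternatives are exposed: `statistic = "signed"` averages the
#' signed correlations, and `mask` restricts the average to PCIT-kept pairs.
#'
#' @param corr_overall Correlation matrix over all samples (genes as
#'   dimnames).
#' @param module_genes Character vector of module members (non-empty, all
#'   present in `corr_overall`).
#' @param catalog Character vector of transcription-factor gene identifiers;
#'   TFs absent from the matrix are skipped (counted in the
#'   `n_skipped_tfs` attribute).
#' @param top_n Number of top-ranked TFs to return.
#' @param landscape_nodes Optional gene set used to populate the
#'   `in_landscape` flag.
#' @param statistic `"absolute"` (default) or `"signed"`.
#' @param mask Optional [pcit_mask()] result; when given, only kept pairs
#'   enter the average.
#' @return data.frame `tf_id`, `score`, `rank`, `in_module`, `in_landscape`,
#'   sorted by rank; ties in score are broken by the smaller gene
#'   identifier.
#' @export
module_to_regulator <- function(corr_overall, module_genes, catalog,
                                top_n = 10, landscape_nodes = character(),
                                statistic = c("absolute", "signed"),
                                mask = NULL) {
  statistic <- match.arg(statistic)
  module_genes <- unique(module_genes)
  if (length(module_genes) == 0) stop("empty module")
  genes <- rownames(corr_overall)
  missing_mod <- setdiff(module_genes, genes)
  if (length(missing_mod))
    stop("module gene(s) absent from correlation matrix: ",
         paste(missing_mod, collapse = ", "))
  tfs <- unique(catalog)
  skipped <- setdiff(tfs, genes)
  tfs <- setdiff(tfs, skipped)
  if (length(tfs) == 0) stop("no catalogue TF present in the correlation matrix")

  score_one <- function(t) {
    targets <- setdiff(module_genes, t)
    if (length(targets) == 0) return(0)
    r <- corr_overall[t, targets]
    if (!is.null(mask)) {
      kept <- mask$keep[t, targets]
      r <- r[kept]
      if (length(r) == 0) return(0)
    }
    if (statistic == "absolute") mean(abs(r)) else mean(r)
  }
  scores <- vapply(tfs, score_one, 0)
  ord <- order(-scores, tfs)
  out <- data.frame(tf_id = tfs[ord],
                    score = scores[ord],
                    rank = seq_along(tfs),
                    in_module = tfs[ord] %in% module_genes,
                    in_landscape = tfs[ord] %in% landscape_nodes,
                    stringsAsFactors = FALSE)
  out <- head(out, top_n)
  rownames(out) <- NULL
  attr(out, "n_skipped_tfs") <- length(skipped)
  out
}

#' Cross-tabulate module membership against regulator ranking
#'
#' For each module, partitions the union of its member TFs and its top-n
#' ranked TFs into three disjoint, exhaustive columns: TFs that are module
#' members *and* top-ranked; TFs that are members only; and top-ranked TFs
#' that are not members.
#'
#' @param per_module_scores Named list: module id -> data.frame from
#'   [module_to_regulator()].
#' @param modules Named list: module id -> character vector of member genes.
#' @param catalog Character vector of TF identifiers.
#' @return data.frame with columns `module`, `tf_in_module_and_top`,
#'   `tf_in_module_only`, `tf_top_only` (comma-separated identifier lists,
#'   empty string when none).
#' @export
regulator_table <- function(per_module_scores, modules, catalog) {
  stopifnot(identical(sort(names(per_module_scores)), sort(names(modules))))
  rows <- lapply(names(per_module_scores), function(id) {
    top <- per_module_scores[[id]]$tf_id
    member_tfs <- intersect(modules[[id]], catalog)
    both <- intersect(member_tfs, top)
    data.frame(
      module = id,
      tf_in_module_and_top = paste(sort(both), collapse = ","),
      tf_in_module_only = paste(sort(setdiff(member_tfs, top)), collapse = ","),
      tf_top_only = paste(setdiff(top, member_tfs), collapse = ","),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
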