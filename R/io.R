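#' Write / read an expression matrix as TSV
#'
#' The first column (`gene_id`) carries row identifiers; the header carries
#' sample identifiers. Detection calls use the same layout with P/A/M codes.
#'
#' @param expr An [ac_expression].
#' @param path Output path.
#' @name expression_tsv
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname expression_tsv
#' @export
write_detection_tsv <- function(expr, path) {
  if (is.null(expr$detection)) stop("no detection calls to write")
  df <- data.frame(gene_id = rownames(expr$detection), expr$detection,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname expression_tsv
#' @param detection_path,groups_path Optional companion files (detection
#'   TSV, sample-to-group TSV).
#' @param log2_transform Apply `log2(x + 1)` on ingest (linear-scale data).
#' @export
read_expression_tsv <- function(path, detection_path = NULL,
                                groups_path = NULL, log2_transform = FALSE) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  detection <- NULL
  if (!is.null(detection_path)) {
    dd <- read.delim(detection_path, check.names = FALSE,
                     stringsAsFactors = FALSE)
    detection <- as.matrix(dd[, -1, drop = FALSE])
    rownames(detection) <- dd[[1]]
    detection <- detection[rownames(values), colnames(values), drop = FALSE]
  }
  groups <- if (!is.null(groups_path)) read_groups_tsv(groups_path) else NULL
  ac_expression(values, detection = detection, groups = groups,
                log2_transform = log2_transform)
}

#' Read / write a sample-to-group table (two-column TSV)
#'
#' @param path File path.
#' @name groups_tsv
#' @export
read_groups_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  names(df)[1:2] <- c("sample", "group")
  df
}

#' @rdname groups_tsv
#' @param groups data.frame with columns `sample`, `group`.
#' @export
write_groups_tsv <- function(groups, path) {
  write.table(groups[, c("sample", "group")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
}

#' Read a probe annotation CSV (probe_id, gene_id, status)
#'
#' @param path File path.
#' @return A [probe_annotation].
#' @export
read_annotation_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  probe_annotation(df$probe_id, df$gene_id, df$status)
}

#' Read a one-column gene list (e.g. a transcription-factor catalogue)
#'
#' Lines starting with `#` and a single header line named `gene_id` or
#' `tf_id` are skipped.
#'
#' @param path File path.
#' @return Character vector of identifiers.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  x[!x %in% c("gene_id", "tf_id")]
}

#' Write / read a network edge list (gene_a, gene_b, r)
#'
#' Edges are written with `gene_a < gene_b` lexicographically.
#'
#' @param network An `ac_network`.
#' @param path File path.
#' @name network_tsv
#' @export
write_network_tsv <- function(network, path) {
  write.table(network$edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
}

#' @rdname network_tsv
#' @param group Group name to attach to the read network.
#' @param nodes Optional full node set (defaults to edge endpoints).
#' @export
read_network_tsv <- function(path, group, nodes = NULL) {
  edges <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_a", "gene_b", "r") %in% names(edges)))
  if (is.null(nodes)) nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  structure(list(group = group, nodes = nodes, edges = edges),
            class = "ac_network")
}

#' Write a landscape as SIF plus an edge-attribute table
#'
#' The SIF file (`geneA pp geneB`) and the attribute TSV (per-network r,
#' assigned r, sign, sign consistency) are loadable into Cytoscape.
#'
#' @param landscape An `ac_landscape`.
#' @param sif_path,attr_path Output paths.
#' @export
write_sif <- function(landscape, sif_path, attr_path = NULL) {
  e <- landscape$edges
  writeLines(sprintf("%s\tpp\t%s", e$gene_a, e$gene_b), sif_path)
  if (!is.null(attr_path)) {
    write.table(e, attr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(NULL)
}

#' Write a report object as JSON
#'
#' @param x A list (scalars are unboxed).
#' @param path Output path.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
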