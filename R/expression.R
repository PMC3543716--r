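#' Expression matrix container
#'
#' Bundles a genes-by-samples matrix of (log2-scale) expression values with an
#' optional parallel detection-call matrix (`"P"`resent / `"A"`bsent /
#' `"M"`arginal) and a sample-to-group assignment table. This is the substrate
#' of all filtering and correlation steps: values are assumed already
#' normalised (e.g. MAS5) and log2-transformed.
#'
#' @param values Numeric matrix, rows = probes or genes (rownames required),
#'   columns = samples (colnames required). All values must be finite.
#' @param detection Optional character matrix of the same shape with entries
#'   in `c("P", "A", "M")`.
#' @param groups Optional data.frame with columns `sample` and `group`
#'   assigning each sample to an analysis group. Groups may overlap only via
#'   multiple rows per sample.
#' @param log2_transform If `TRUE`, applies `log2(x + 1)` to `values` for
#'   linear-scale inputs.
#' @return An object of class `ac_expression` with elements `values`,
#'   `detection` and `groups`.
#' @examples
#' m <- matrix(rnorm(12, 8), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' x <- ac_expression(m)
#' dim(x$values)
#' @export
ac_expression <- function(values, detection = NULL, groups = NULL,
                          log2_transform = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have row (gene/probe) and column (sample) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate row identifiers in expression matrix")
  if (!all(is.finite(values)))
    stop("expression values must all be finite")
  if (log2_transform) values <- log2(values + 1)
  if (!is.null(detection)) {
    if (!identical(dim(detection), dim(values)))
      stop("'detection' must have the same shape as 'values'")
    if (!all(detection %in% c("P", "A", "M")))
      stop("detection calls must be 'P', 'A' or 'M'")
    dimnames(detection) <- dimnames(values)
  }
  if (!is.null(groups)) {
    groups <- as.data.frame(groups, stringsAsFactors = FALSE)
    if (!all(c("sample", "group") %in% names(groups)))
      stop("'groups' needs columns 'sample' and 'group'")
    missing <- setdiff(groups$sample, colnames(values))
    if (length(missing))
      stop("group table refers to unknown samples: ",
           paste(missing, collapse = ", "))
  }
  structure(list(values = values, detection = detection, groups = groups),
            class = "ac_expression")
}

#' @export
print.ac_expression <- function(x, ...) {
  cat(sprintf("ac_expression: %d rows x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$detection)) {
    cat(sprintf("  detection calls: %.1f%% Present\n",
                100 * mean(x$detection == "P")))
  }
  if (!is.null(x$groups)) {
    tab <- table(x$groups$group)
    cat("  groups:", paste(sprintf("%s (%d)", names(tab), tab),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' Samples belonging to an analysis group
#'
#' @param expr An [ac_expression] with a group table.
#' @param group Group name. The special name `"Overall"` (when not an explicit
#'   group) returns all samples.
#' @return Character vector of sample identifiers, in matrix column order.
#' @export
group_samples <- function(expr, group) {
  stopifnot(inherits(expr, "ac_expression"))
  if (is.null(expr$groups)) {
    if (identical(group, "Overall")) return(colnames(expr$values))
    stop("expression object carries no group table")
  }
  if (!group %in% expr$groups$group) {
    if (identical(group, "Overall")) return(colnames(expr$values))
    stop("unknown group: ", group)
  }
  ids <- expr$groups$sample[expr$groups$group == group]
  intersect(colnames(expr$values), ids)
}

#' Names of all analysis groups
#'
#' @param expr An [ac_expression].
#' @return Character vector of group names (empty if no group table).
#' @export
group_names <- function(expr) {
  if (is.null(expr$groups)) character() else unique(expr$groups$group)
}

# internal: restrict an ac_expression to given rows/samples
subset_expression <- function(expr, rows = NULL, samples = NULL) {
  v <- expr$values
  d <- expr$detection
  if (!is.null(rows)) {
    v <- v[rows, , drop = FALSE]
    if (!is.null(d)) d <- d[rows, , drop = FALSE]
  }
  if (!is.null(samples)) {
    v <- v[, samples, drop = FALSE]
    if (!is.null(d)) d <- d[, samples, drop = FALSE]
  }
  g <- expr$groups
  if (!is.null(g) && !is.null(samples)) g <- g[g$sample %in% samples, , drop = FALSE]
  structure(list(values = v, detection = d, groups = g), class = "ac_expression")
}
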