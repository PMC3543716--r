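#' @useDynLib aclandscape, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor rnorm runif sd phyper p.adjust setNames
#' @importFrom utils read.delim write.table combn head
NULL

#' Canonical unordered edge keys
#'
#' Builds the canonical `"a|b"` key (endpoints sorted lexicographically) used
#' throughout the package to identify an unordered gene pair.
#'
#' @param a,b Character vectors of gene identifiers (recycled together).
#' @return Character vector of edge keys.
#' @export
edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Round half away from zero
#'
#' Base `round()` rounds half to even; reported percentages use the
#' conventional half-up rule instead (26.25 -> 26.3).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# internal: stop with a named-field configuration error
config_error <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

# internal: edge data.frame from keys (splits "a|b" back into columns)
edges_from_keys <- function(keys) {
  if (length(keys) == 0) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(keys, "|", fixed = TRUE)
  data.frame(gene_a = vapply(parts, `[`, "", 1L),
             gene_b = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}
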