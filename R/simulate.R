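#' Specification of one simulated co-expression module
#'
#' A module is a block of genes driven by a shared latent factor. The factor
#' is drawn independently per analysis group and per sample; a module active
#' in every group produces always-correlated gene pairs, one active in a
#' strict subset produces condition-specific pairs.
#'
#' @param size Number of member genes (>= 2), including any regulators.
#' @param loading Factor loading in (0, 1] shared by members.
#' @param negative_fraction Fraction of members given a negative loading,
#'   yielding negative within-module correlations.
#' @param active_groups Character vector of group names in which the module's
#'   factor is active. `NULL` means all groups (always-correlated).
#' @param regulator_count Number of members flagged as transcription factors;
#'   these receive loading `0.9 * loading` so module-to-regulator recovery is
#'   testable.
#' @return A `module_spec` list.
#' @export
module_spec <- function(size, loading = 1, negative_fraction = 0,
                        active_groups = NULL, regulator_count = 0) {
  if (size < 2) config_error("size", "module size must be >= 2")
  if (loading <= 0 || loading > 1)
    config_error("loading", "must lie in (0, 1]")
  if (negative_fraction < 0 || negative_fraction > 1)
    config_error("negative_fraction", "must lie in [0, 1]")
  if (regulator_count < 0 || regulator_count > size)
    config_error("regulator_count", "must lie in [0, size]")
  structure(list(size = as.integer(size), loading = loading,
                 negative_fraction = negative_fraction,
                 active_groups = active_groups,
                 regulator_count = as.integer(regulator_count)),
            class = "module_spec")
}

#' Configuration for the multi-condition expression simulator
#'
#' @param n_genes Total number of genes.
#' @param groups Named integer vector: analysis-group name -> number of
#'   samples. Names must be unique; correlation downstream needs >= 3 samples
#'   per group.
#' @param modules List of [module_spec] objects.
#' @param flat_gene_fraction Fraction of genes that are flat (constant mean
#'   8.0 with noise `noise_sd/100`), removed by the variation filter.
#' @param noise_sd Standard deviation of the additive Gaussian noise on
#'   module and background genes.
#' @param detection_missing_fraction Fraction of detection calls that are not
#'   "Present" (set to Absent/Marginal at random).
#' @param seed Integer RNG seed; fixed seed gives bit-identical output.
#' @return A `simulation_config` list, validated.
#' @export
simulation_config <- function(n_genes, groups, modules = list(),
                              flat_gene_fraction = 0, noise_sd = 0.5,
                              detection_missing_fraction = 0, seed = 1L) {
  if (n_genes < 1) config_error("n_genes", "must be positive")
  if (is.null(names(groups)) || anyDuplicated(names(groups)))
    config_error("groups", "group names must be present and unique")
  if (any(groups < 1)) config_error("groups", "each group needs >= 1 sample")
  if (flat_gene_fraction < 0 || flat_gene_fraction > 1)
    config_error("flat_gene_fraction", "must lie in [0, 1]")
  if (noise_sd < 0) config_error("noise_sd", "must be non-negative")
  if (detection_missing_fraction < 0 || detection_missing_fraction > 1)
    config_error("detection_missing_fraction", "must lie in [0, 1]")
  for (m in modules) {
    if (!inherits(m, "module_spec")) config_error("modules", "expected module_spec objects")
    bad <- setdiff(m$active_groups, names(groups))
    if (length(bad))
      config_error("modules", paste("unknown active group(s):",
                                    paste(bad, collapse = ", ")))
  }
  n_flat <- round(flat_gene_fraction * n_genes)
  n_module <- sum(vapply(modules, function(m) m$size, 0L))
  if (n_module + n_flat > n_genes)
    config_error("n_genes", sprintf(
      "module genes (%d) + flat genes (%d) exceed n_genes (%d)",
      n_module, n_flat, n_genes))
  structure(list(n_genes = as.integer(n_genes), groups = groups,
                 modules = modules, flat_gene_fraction = flat_gene_fraction,
                 noise_sd = noise_sd,
                 detection_missing_fraction = detection_missing_fraction,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Default six-group study design
#'
#' A design mirroring a six-condition skeletal-muscle study: five condition
#' subsets of 16, 19, 15, 20 and 40 arrays plus a sixth group of 20, two
#' always-active modules (sizes 30 and 15, one planted regulator each), one
#' module active in three of the six groups, 20% flat genes, loading 1.0 and
#' noise SD 0.5.
#'
#' @param seed Integer RNG seed.
#' @return A [simulation_config].
#' @export
default_simulation_config <- function(seed = 1L) {
  groups <- c(Callipyge = 16L, Normal = 19L, Prenatal = 15L,
              Postnatal = 20L, HighLow = 40L, Mixed = 20L)
  all_g <- names(groups)
  simulation_config(
    n_genes = 150,
    groups = groups,
    modules = list(
      module_spec(30, loading = 1, negative_fraction = 0.2,
                  active_groups = all_g, regulator_count = 1),
      module_spec(15, loading = 1, negative_fraction = 0.2,
                  active_groups = all_g, regulator_count = 1),
      module_spec(15, loading = 1, negative_fraction = 0,
                  active_groups = all_g[1:3], regulator_count = 0)),
    flat_gene_fraction = 0.2,
    noise_sd = 0.5,
    detection_missing_fraction = 0.02,
    seed = seed)
}

# internal: gene layout (member indices, names, flags) for a config.
# Modules occupy consecutive leading indices; flat genes the trailing block.
build_layout <- function(config, prefix = "") {
  n <- config$n_genes
  sizes <- vapply(config$modules, function(m) m$size, 0L)
  members <- list()
  at <- 1L
  for (k in seq_along(config$modules)) {
    members[[k]] <- seq.int(at, at + sizes[k] - 1L)
    at <- at + sizes[k]
  }
  n_flat <- round(config$flat_gene_fraction * n)
  flat_idx <- if (n_flat > 0) seq.int(n - n_flat + 1L, n) else integer()
  make_layout(n, members, flat_idx, config, prefix)
}

# internal: finalise names/regulator assignment for explicit member indices
make_layout <- function(n, members, flat_idx, config, prefix = "") {
  gene_names <- sprintf("%sG%04d", prefix, seq_len(n))
  tf_counter <- 0L
  regulator_map <- character()
  for (k in seq_along(members)) {
    rc <- config$modules[[k]]$regulator_count
    if (rc > 0) {
      idx <- members[[k]][seq_len(rc)]
      for (i in idx) {
        tf_counter <- tf_counter + 1L
        gene_names[i] <- sprintf("%sTF%03d", prefix, tf_counter)
        regulator_map[gene_names[i]] <- paste0("M", k)
      }
    }
  }
  list(n = n, members = members, flat_idx = flat_idx,
       gene_names = gene_names, regulator_map = regulator_map)
}

# internal: simulate from a layout using the current RNG state
generate_core <- function(config, layout) {
  n <- layout$n
  gene_names <- layout$gene_names
  sample_names <- unlist(lapply(names(config$groups), function(g)
    sprintf("%s_s%02d", g, seq_len(config$groups[[g]]))))
  groups_df <- data.frame(
    sample = sample_names,
    group = rep(names(config$groups), times = config$groups),
    stringsAsFactors = FALSE)

  baseline <- 8.0
  # per-gene loading (0 outside modules), sign draws inside modules
  loading <- numeric(n)
  module_of <- integer(n)  # 0 = none
  for (k in seq_along(layout$members)) {
    m <- config$modules[[k]]
    idx <- layout$members[[k]]
    l <- rep(m$loading, length(idx))
    if (m$regulator_count > 0) l[seq_len(m$regulator_count)] <- 0.9 * m$loading
    n_neg <- round(m$negative_fraction * length(idx))
    if (n_neg > 0) {
      neg <- sample(seq_along(idx), n_neg)
      l[neg] <- -l[neg]
    }
    loading[idx] <- l
    module_of[idx] <- k
  }

  values <- matrix(baseline, n, length(sample_names),
                   dimnames = list(gene_names, sample_names))
  is_flat <- seq_len(n) %in% layout$flat_idx
  for (g in names(config$groups)) {
    cols <- which(groups_df$group == g)
    ns <- length(cols)
    noise <- matrix(rnorm(n * ns, 0, config$noise_sd), n, ns)
    noise[is_flat, ] <- matrix(rnorm(sum(is_flat) * ns, 0, config$noise_sd / 100),
                               sum(is_flat), ns)
    values[, cols] <- values[, cols] + noise
    for (k in seq_along(layout$members)) {
      m <- config$modules[[k]]
      active <- is.null(m$active_groups) || g %in% m$active_groups
      if (!active) next
      factor_g <- rnorm(ns)
      idx <- layout$members[[k]]
      values[idx, cols] <- values[idx, cols] + outer(loading[idx], factor_g)
    }
  }

  detection <- matrix("P", n, length(sample_names),
                      dimnames = dimnames(values))
  if (config$detection_missing_fraction > 0) {
    miss <- runif(length(detection)) < config$detection_missing_fraction
    detection[miss] <- sample(c("A", "M"), sum(miss), replace = TRUE)
  }

  all_groups <- names(config$groups)
  pair_keys <- function(idx) {
    if (length(idx) < 2) return(character())
    nm <- gene_names[idx]
    cmb <- combn(sort(nm), 2)
    edge_key(cmb[1, ], cmb[2, ])
  }
  always_pairs <- character()
  conditional_pairs <- character()
  membership <- character()
  for (k in seq_along(layout$members)) {
    m <- config$modules[[k]]
    idx <- layout$members[[k]]
    membership[gene_names[idx]] <- paste0("M", k)
    active <- if (is.null(m$active_groups)) all_groups else m$active_groups
    if (setequal(active, all_groups)) {
      always_pairs <- c(always_pairs, pair_keys(idx))
    } else {
      conditional_pairs <- c(conditional_pairs, pair_keys(idx))
    }
  }

  truth <- list(module_membership = membership,
                always_pairs = always_pairs,
                conditional_pairs = conditional_pairs,
                flat_genes = gene_names[layout$flat_idx],
                regulator_map = layout$regulator_map)
  expr <- ac_expression(values, detection = detection, groups = groups_df)
  list(expression = expr, truth = truth)
}

#' Generate a multi-condition expression dataset with known ground truth
#'
#' Each analysis group draws an independent latent factor per active module
#' and per sample; a member gene's value is `8 + loading * factor + noise`.
#' Members of modules inactive in a group, and background genes, receive
#' noise only; flat genes sit at 8.0 with noise `noise_sd/100` so the
#' one-standard-deviation variation filter removes them. Detection calls are
#' "P" except for a configurable random fraction.
#'
#' Under this single-factor model the expected correlation of two members
#' with loadings `l_i`, `l_j` and noise SD `s` is
#' `l_i * l_j / sqrt((l_i^2 + s^2) * (l_j^2 + s^2))`.
#'
#' @param config A [simulation_config].
#' @return List with elements `expression` (an [ac_expression]) and `truth`
#'   (module membership, always/conditional gene-pair keys, flat genes,
#'   regulator map).
#' @examples
#' sim <- generate_expression(default_simulation_config(seed = 7))
#' sim$expression
#' length(sim$truth$always_pairs)
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  generate_core(config, build_layout(config))
}

#' Generate a paired two-platform ("two species") dataset
#'
#' The first `shared_modules` modules of both configurations use the same
#' member genes under the returned 1:1 identifier mapping; each dataset's
#' remaining modules occupy disjoint gene blocks so their edges cannot
#' overlap. The mapping covers `mapping_fraction` of the genes common to the
#' two platforms (paired by index), emulating the partial confident linkage
#' between two array annotations.
#'
#' @param config_a,config_b [simulation_config]s; the first `shared_modules`
#'   modules must have equal sizes and regulator counts.
#' @param shared_modules Number of leading modules shared between datasets.
#' @param mapping_fraction Fraction of common genes included in the mapping.
#' @param seed Integer RNG seed for the whole pair.
#' @return List with `expression_a`, `expression_b`, `mapping` (an
#'   `id_mapping`: data.frame `pairs` with columns `gene_a`, `gene_b`, plus
#'   `universe_size`), `truth_a`, `truth_b`.
#' @export
generate_species_pair <- function(config_a, config_b, shared_modules,
                                  mapping_fraction = 1, seed = 1L) {
  stopifnot(inherits(config_a, "simulation_config"),
            inherits(config_b, "simulation_config"))
  if (mapping_fraction < 0 || mapping_fraction > 1)
    config_error("mapping_fraction", "must lie in [0, 1]")
  if (shared_modules > min(length(config_a$modules), length(config_b$modules)))
    config_error("shared_modules", "exceeds a configuration's module count")
  sm <- seq_len(shared_modules)
  size_a <- vapply(config_a$modules, function(m) m$size, 0L)
  size_b <- vapply(config_b$modules, function(m) m$size, 0L)
  if (!identical(size_a[sm], size_b[sm]))
    config_error("shared_modules", "shared modules must have equal sizes")
  rc_a <- vapply(config_a$modules, function(m) m$regulator_count, 0L)
  rc_b <- vapply(config_b$modules, function(m) m$regulator_count, 0L)
  if (!identical(rc_a[sm], rc_b[sm]))
    config_error("shared_modules", "shared modules must have equal regulator counts")

  shared_span <- sum(size_a[sm])
  priv_a_span <- sum(size_a[-sm])
  # layout: [shared][A-private][B-private][tail: flat + background]
  members_a <- members_b <- list()
  at <- 1L
  for (k in sm) {
    members_a[[k]] <- members_b[[k]] <- seq.int(at, at + size_a[k] - 1L)
    at <- at + size_a[k]
  }
  at_a <- shared_span + 1L
  for (k in setdiff(seq_along(size_a), sm)) {
    members_a[[k]] <- seq.int(at_a, at_a + size_a[k] - 1L)
    at_a <- at_a + size_a[k]
  }
  at_b <- shared_span + priv_a_span + 1L
  for (k in setdiff(seq_along(size_b), sm)) {
    members_b[[k]] <- seq.int(at_b, at_b + size_b[k] - 1L)
    at_b <- at_b + size_b[k]
  }
  span <- shared_span + priv_a_span + sum(size_b[-sm])
  flat_a <- round(config_a$flat_gene_fraction * config_a$n_genes)
  flat_b <- round(config_b$flat_gene_fraction * config_b$n_genes)
  if (span + flat_a > config_a$n_genes)
    config_error("n_genes", "config_a too small for disjoint private modules")
  if (span + flat_b > config_b$n_genes)
    config_error("n_genes", "config_b too small for disjoint private modules")

  set.seed(seed)
  lay_a <- make_layout(config_a$n_genes, members_a,
                       flat_idx = if (flat_a > 0)
                         seq.int(config_a$n_genes - flat_a + 1L, config_a$n_genes)
                       else integer(),
                       config = config_a, prefix = "A_")
  lay_b <- make_layout(config_b$n_genes, members_b,
                       flat_idx = if (flat_b > 0)
                         seq.int(config_b$n_genes - flat_b + 1L, config_b$n_genes)
                       else integer(),
                       config = config_b, prefix = "B_")
  out_a <- generate_core(config_a, lay_a)
  out_b <- generate_core(config_b, lay_b)

  n_common <- min(config_a$n_genes, config_b$n_genes)
  n_map <- round(mapping_fraction * n_common)
  idx <- sort(sample.int(n_common, n_map))
  pairs <- data.frame(gene_a = lay_a$gene_names[idx],
                      gene_b = lay_b$gene_names[idx],
                      stringsAsFactors = FALSE)
  mapping <- structure(list(pairs = pairs, universe_size = nrow(pairs)),
                       class = "id_mapping")
  list(expression_a = out_a$expression, expression_b = out_b$expression,
       mapping = mapping, truth_a = out_a$truth, truth_b = out_b$truth)
}
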