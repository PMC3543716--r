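#' End-to-end pipeline configuration
#'
#' Bundles inputs and parameters for [run_pipeline()]. Inputs may be
#' in-memory objects or file paths (TSV/CSV/GMT, see the readers in this
#' package).
#'
#' @param expression An [ac_expression], or a path to an expression TSV.
#' @param detection_path,groups_path Companion files when `expression` is a
#'   path.
#' @param annotation A [probe_annotation] or annotation CSV path; when
#'   given, dubious-probe removal and probe-to-gene collapse run first.
#' @param analysis_groups Character vector of group names to build condition
#'   networks for; defaults to all groups in the expression object.
#' @param reference_group Network whose correlations label the AC edges
#'   (default `"Overall"`, computed over all samples and appended when not
#'   an explicit group).
#' @param tf_catalog Character vector of TF gene ids, or a path.
#' @param gene_sets Named list of gene sets, or a GMT path.
#' @param min_timepoints,k_sd,variation_mode Preprocessing parameters (see
#'   [filter_present()] and [filter_low_variation()]).
#' @param ratio_mode,strict PCIT options (see [pcit_mask()]).
#' @param cutoffs Decreasing cut-off grid for the module sweep (`NA` = no
#'   cut-off).
#' @param mcode An [mcode_params].
#' @param jump_factor Connectivity jump threshold for [sweep_modules()].
#' @param top_n Regulators returned per module.
#' @param seed Integer seed recorded in (and applied before) the run.
#' @param out_dir Optional output directory for artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(expression, detection_path = NULL,
                            groups_path = NULL, annotation = NULL,
                            analysis_groups = NULL,
                            reference_group = "Overall",
                            tf_catalog = NULL, gene_sets = NULL,
                            min_timepoints = 1, k_sd = 1,
                            variation_mode = "global_sd",
                            ratio_mode = "signed", strict = TRUE,
                            cutoffs = c(0.95, 0.9, 0.85, 0.8, 0.7, NA),
                            mcode = mcode_params(), jump_factor = 2.0,
                            top_n = 10, seed = 1L, out_dir = NULL) {
  num <- cutoffs[!is.na(cutoffs)]
  if (is.unsorted(rev(num))) stop("cutoff grid must be sorted decreasing")
  structure(list(expression = expression, detection_path = detection_path,
                 groups_path = groups_path, annotation = annotation,
                 analysis_groups = analysis_groups,
                 reference_group = reference_group,
                 tf_catalog = tf_catalog, gene_sets = gene_sets,
                 min_timepoints = min_timepoints, k_sd = k_sd,
                 variation_mode = variation_mode,
                 ratio_mode = ratio_mode, strict = strict,
                 cutoffs = cutoffs, mcode = mcode,
                 jump_factor = jump_factor, top_n = top_n,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full Always-Correlated landscape pipeline
#'
#' Executes preprocessing (dubious-probe removal, probe collapse, detection
#' filter, per-group variation filter), per-group PCIT network inference,
#' edge intersection into the AC landscape, the MCODE cut-off sweep,
#' optional gene-set enrichment of the chosen modules, and optional
#' module-to-regulator ranking against the overall correlation matrix.
#' When `out_dir` is set, writes per-group edge lists, the landscape (SIF +
#' attributes), module gene lists, the sweep table, enrichment and regulator
#' tables, and a JSON run report.
#'
#' @param config A [pipeline_config].
#' @return A list: `report` (per-stage counts, seed, parameters),
#'   `landscape`, `networks`, `sweep`, `modules` (named gene-set list),
#'   `enrichment`, `regulators`, `expression` (the preprocessed object).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  stage <- "load"
  res <- try({
    expr <- config$expression
    if (is.character(expr)) {
      expr <- read_expression_tsv(expr, config$detection_path,
                                  config$groups_path)
    }
    annot <- config$annotation
    if (is.character(annot)) annot <- read_annotation_csv(annot)
    tfs <- config$tf_catalog
    if (is.character(tfs) && length(tfs) == 1 && file.exists(tfs))
      tfs <- read_gene_list(tfs)
    sets <- config$gene_sets
    if (is.character(sets)) sets <- read_gmt(sets)

    counts <- list(input_rows = nrow(expr$values))
    stage <- "preprocess"
    if (!is.null(annot)) {
      expr <- drop_dubious_probes(expr, annot)
      counts$confident_probes <- nrow(expr$values)
      expr <- collapse_to_genes(expr, annot)
      counts$genes_after_collapse <- nrow(expr$values)
    }
    if (!is.null(expr$detection)) {
      expr <- filter_present(expr, config$min_timepoints)
      counts$genes_present <- nrow(expr$values)
    }

    groups <- config$analysis_groups
    if (is.null(groups)) groups <- group_names(expr)
    if (length(groups) == 0) stop("no analysis groups defined")

    stage <- "pcit"
    networks <- list()
    genes_per_group <- integer()
    for (g in groups) {
      fg <- filter_low_variation(expr, g, k_sd = config$k_sd,
                                 mode = config$variation_mode)
      genes_per_group[[g]] <- nrow(fg$values)
      networks[[g]] <- build_network(fg, group = g,
                                     ratio_mode = config$ratio_mode,
                                     strict = config$strict)
    }
    counts$genes_per_group <- as.list(genes_per_group)
    counts$edges_per_group <- lapply(networks, function(n) nrow(n$edges))

    ref <- config$reference_group
    if (!ref %in% groups) {
      # an overall network over all samples supplies the consensus weights
      fo <- filter_low_variation(expr, ref, k_sd = config$k_sd,
                                 mode = config$variation_mode)
      networks[[ref]] <- build_network(fo, group = NULL,
                                       ratio_mode = config$ratio_mode,
                                       strict = config$strict)
      networks[[ref]]$group <- ref
      counts$genes_per_group[[ref]] <- nrow(fo$values)
      counts$edges_per_group[[ref]] <- nrow(networks[[ref]]$edges)
    }

    stage <- "landscape"
    landscape <- intersect_networks(networks, reference_group = ref)
    report_sign <- sign_report(landscape)
    counts$landscape_nodes <- length(landscape$nodes)
    counts$landscape_edges <- nrow(landscape$edges)

    stage <- "modules"
    sweep <- sweep_modules(landscape, config$cutoffs, config$mcode,
                           config$jump_factor)
    modules <- lapply(sweep$modules, function(m) m$genes)
    if (length(modules))
      names(modules) <- paste0("module_", seq_along(modules))
    counts$modules <- length(modules)
    counts$module_sizes <- unname(lengths(modules))

    stage <- "enrichment"
    enrichment <- NULL
    if (!is.null(sets) && length(modules)) {
      enrichment <- lapply(modules, function(g) {
        enrich(intersect(g, landscape$nodes), landscape$nodes, sets)
      })
    }

    stage <- "regulators"
    regulators <- NULL
    if (!is.null(tfs) && length(modules)) {
      fo <- filter_low_variation(expr, "Overall", k_sd = 0)
      corr <- correlation_matrix(fo, group = NULL)
      scores <- lapply(modules, function(g)
        module_to_regulator(corr, intersect(g, rownames(corr)), tfs,
                            top_n = config$top_n,
                            landscape_nodes = landscape$nodes))
      regulators <- list(scores = scores,
                         table = regulator_table(scores, modules, tfs))
    }

    stage <- "write"
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      od <- config$out_dir
      for (g in names(networks)) {
        write_network_tsv(networks[[g]],
                          file.path(od, paste0("network_", g, ".tsv")))
      }
      write_sif(landscape, file.path(od, "ac_landscape.sif"),
                file.path(od, "ac_landscape_edges.tsv"))
      write.table(sweep$table, file.path(od, "sweep_table.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      for (id in names(modules)) {
        writeLines(modules[[id]], file.path(od, paste0(id, "_genes.tsv")))
      }
      if (!is.null(enrichment)) {
        for (id in names(enrichment)) {
          write.table(enrichment[[id]],
                      file.path(od, paste0(id, "_enrichment.tsv")),
                      sep = "\t", quote = FALSE, row.names = FALSE)
        }
      }
      if (!is.null(regulators)) {
        write.table(regulators$table, file.path(od, "regulators.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }

    report <- list(
      package_version = as.character(utils::packageVersion("aclandscape")),
      seed = config$seed,
      parameters = list(k_sd = config$k_sd,
                        variation_mode = config$variation_mode,
                        min_timepoints = config$min_timepoints,
                        ratio_mode = config$ratio_mode,
                        strict = config$strict,
                        cutoffs = config$cutoffs,
                        vwp = config$mcode$vwp,
                        haircut = config$mcode$haircut,
                        jump_factor = config$jump_factor,
                        reference_group = ref),
      counts = counts,
      sign_report = unclass(report_sign))
    if (!is.null(config$out_dir)) {
      write_json_report(report, file.path(config$out_dir, "run_report.json"))
    }
    list(report = report, landscape = landscape, networks = networks,
         sweep = sweep, modules = modules, enrichment = enrichment,
         regulators = regulators, expression = expr)
  }, silent = TRUE)
  if (inherits(res, "try-error")) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(attr(res, "condition"))), call. = FALSE)
  }
  res
}
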