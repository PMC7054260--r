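#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end workflow with its reference
#' defaults: the |ES| grid 0.8..3.0 in bins of 0.1,
#' selection criteria (co-abnormal count >= 2, lift > 2, q < 0.1), Welch
#' t-test as the accompanying exact test, a cap of 1e5 simple paths per
#' pathway endpoint, and community cuts k = 7 (PPAP level) and k = 4
#' (biological-system level). A single seed fans out to every stage.
#'
#' @param simulation a \code{\link{sim_config}} (NULL to ingest files
#'   instead).
#' @param measurements_path,annotation_path input TSVs when not simulating.
#' @param grid threshold grid.
#' @param min_co,min_lift,max_q rule-selection criteria.
#' @param exact_test accompanying significance test for calls.
#' @param max_paths simple-path cap for pathway conversion.
#' @param k_ppap,k_system community cuts.
#' @param out_dir output directory (NULL for no file output).
#' @param seed integer master seed.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(simulation = NULL,
                            measurements_path = NULL,
                            annotation_path = NULL,
                            grid = threshold_grid(),
                            min_co = 2, min_lift = 2, max_q = 0.1,
                            exact_test = c("welch", "wilcoxon"),
                            max_paths = 1e5,
                            k_ppap = 7, k_system = 4,
                            out_dir = NULL,
                            seed = 1L) {
  exact_test <- match.arg(exact_test)
  if (is.null(simulation) &&
      (is.null(measurements_path) || is.null(annotation_path))) {
    stop("either a simulation config or measurement + annotation paths ",
         "must be supplied")
  }
  structure(list(simulation = simulation,
                 measurements_path = measurements_path,
                 annotation_path = annotation_path,
                 grid = grid, min_co = min_co, min_lift = min_lift,
                 max_q = max_q, exact_test = exact_test,
                 max_paths = max_paths, k_ppap = k_ppap,
                 k_system = k_system, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Round-trips the flat fields of \code{\link{pipeline_config}}; a
#' \code{simulation:} block is passed to \code{\link{sim_config}}.
#'
#' @param path YAML file.
#' @return a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$simulation)) {
    sc <- y$simulation
    if (!is.null(sc$stage_type_mix)) {
      sc$stage_type_mix <- unlist(sc$stage_type_mix)
    }
    if (!is.null(sc$planted_pairs)) {
      sc$planted_pairs <- do.call(rbind,
        lapply(sc$planted_pairs, as.data.frame))
    }
    do.call(sim_config, sc)
  }
  args <- y[setdiff(names(y), "simulation")]
  if (!is.null(args$grid) && is.character(args$grid)) {
    # compact "from:to:by" form
    v <- as.numeric(strsplit(args$grid, ":", fixed = TRUE)[[1L]])
    args$grid <- threshold_grid(v[1], v[2], v[3])
  }
  do.call(pipeline_config, c(list(simulation = sim), args))
}

#' @rdname read_pipeline_config
#' @param config a \code{pipeline_config} to write.
#' @export
write_pipeline_config <- function(config, path) {
  y <- unclass(config)
  if (!is.null(y$simulation)) {
    y$simulation <- unclass(y$simulation)
    y$simulation$stage_type_mix <- as.list(y$simulation$stage_type_mix)
    if (!is.null(y$simulation$planted_pairs)) {
      pp <- y$simulation$planted_pairs
      y$simulation$planted_pairs <-
        lapply(seq_len(nrow(pp)), function(i) as.list(pp[i, ]))
    }
  }
  yaml::write_yaml(y[!vapply(y, is.null, logical(1))], path)
  invisible(path)
}

#' Run the end-to-end association-mining pipeline
#'
#' Executes simulate/ingest -> call -> mine -> select -> PPAP -> pathway ->
#' cluster -> enrich, writing artifacts to \code{out_dir} when set, and
#' returns a run manifest with per-stage counts. Deterministic given the
#' config seed.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return list of class \code{run_manifest}: config snapshot, package
#'   version, per-stage counts, and the computed objects (\code{atlas},
#'   \code{ppaps}, \code{phenome_pathway}, \code{clusters},
#'   \code{enrichment}, ...).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  counts <- list()

  if (!is.null(config$simulation)) {
    sim <- config$simulation
    annotation <- generate_catalog(sim)
    gen <- generate_measurements(sim, annotation)
    measurements <- gen$measurements
    truth <- gen$truth
  } else {
    measurements <- read_measurements(config$measurements_path)
    annotation <- read_annotation_map(config$annotation_path)
    truth <- NULL
  }
  counts$n_parameters <- length(unique(measurements$parameter_id))
  counts$n_strains <-
    length(setdiff(unique(measurements$strain_id), "control"))

  sweep <- sweep_call_matrices(measurements, annotation,
                               grid = config$grid,
                               exact_test = config$exact_test)
  counts$n_phenotypes_called <- nrow(sweep$matrices[[1L]])

  atlas <- select_significant_rules(sweep,
                                    min_co = config$min_co,
                                    min_lift = config$min_lift,
                                    max_q = config$max_q)
  counts$n_rules <- nrow(atlas$rules)
  counts$n_atlas_phenotypes <- length(atlas$phenotypes)

  graph <- build_rule_graph(atlas)
  ppaps <- lapply(atlas$phenotypes, function(q)
    extract_ppap(graph, q, annotation = annotation))
  names(ppaps) <- atlas$phenotypes
  counts$n_ppaps <- length(ppaps)

  pathways <- list()
  excluded <- character(0)
  for (p in ppaps) {
    pw <- tryCatch(convert_to_pathway(p, max_paths = config$max_paths),
                   phenorules_too_complex = function(e) NULL)
    if (is.null(pw)) {
      excluded <- c(excluded, p$query)
    } else {
      pathways[[p$query]] <- pw
    }
  }
  phenome <- build_phenome_pathway(pathways)
  counts$n_ppaps_converted <- length(pathways)
  counts$n_ppaps_too_complex <- length(excluded)
  counts$n_pathway_nodes <- length(phenome$nodes)
  counts$n_pathway_edges <- nrow(phenome$edges)

  calls_opt <- sweep$matrices[[1L]]
  clusters <- if (length(ppaps) >= config$k_ppap) {
    cluster_ppaps(ppaps, k = config$k_ppap)
  }
  degree_dev <- if (length(ppaps) > 0L) degree_deviation(graph)
  enrichment <- if (nrow(atlas$rules) > 0L) {
    list(stage_type = stage_type_rule_enrichment(atlas, annotation),
         system_pair = system_pair_enrichment(atlas, annotation))
  }

  manifest <- structure(
    list(package_version =
           as.character(utils::packageVersion("phenorules")),
         config = config, counts = counts, truth = truth,
         atlas = atlas, ppaps = ppaps, pathways = pathways,
         phenome_pathway = phenome, clusters = clusters,
         degree_deviation = degree_dev, enrichment = enrichment,
         excluded_ppaps = excluded),
    class = "run_manifest")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$out_dir, f)
    write_annotation_map(annotation, out("annotation.tsv"))
    write_rules_csv(atlas$rules, out("atlas.csv"))
    write.table(data.frame(phenotype_id = names(atlas$optimal_thresholds),
                           optimal_threshold = atlas$optimal_thresholds),
                out("optimal_thresholds.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (nrow(phenome$edges) > 0L) {
      export_graph(phenome, "edgelist", out("phenome_pathway.tsv"))
    }
    if (!is.null(truth)) {
      write_truth_set(truth, out("truth.json"))
    }
    jsonlite::write_json(
      list(package_version = manifest$package_version, counts = counts,
           seed = config$seed),
      out("manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("run_manifest:\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-24s %s\n", nm, format(x$counts[[nm]])))
  }
  invisible(x)
}
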