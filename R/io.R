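#' Read a long-format measurement table
#'
#' TSV with header \code{parameter_id  strain_id  cohort  value}; cohort
#' must be \code{mutant} or \code{control} and values numeric. Malformed
#' rows are reported with their line numbers.
#'
#' @param path file path.
#' @return measurement data.frame.
#' @export
read_measurements <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("parameter_id", "strain_id", "cohort", "value")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("parse error: missing columns: ", paste(miss, collapse = ", "))
  }
  line <- seq_len(nrow(df)) + 1L   # header is line 1
  bad_cohort <- !(df$cohort %in% c("mutant", "control"))
  if (any(bad_cohort)) {
    stop("parse error: unknown cohort at line(s) ",
         paste(head(line[bad_cohort], 5), collapse = ", "),
         " (expected 'mutant' or 'control')")
  }
  value <- suppressWarnings(as.numeric(df$value))
  bad_value <- is.na(value) & !is.na(df$value)
  if (any(bad_value)) {
    stop("parse error: non-numeric value at line(s) ",
         paste(head(line[bad_value], 5), collapse = ", "))
  }
  data.frame(parameter_id = df$parameter_id, strain_id = df$strain_id,
             cohort = df$cohort, value = value, stringsAsFactors = FALSE)
}

#' @rdname read_measurements
#' @param measurements measurement data.frame to write.
#' @export
write_measurements <- function(measurements, path) {
  write.table(measurements, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read / write an annotation map
#'
#' TSV mapping parameters to ontology-annotated phenotype ids
#' (\code{stage_type:ontology_name}) with stage/type and biological-system
#' labels.
#'
#' @param path file path.
#' @return annotation data.frame.
#' @export
read_annotation_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("parameter_id", "phenotype_id", "stage_type",
            "biological_systems")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("parse error: missing columns: ", paste(miss, collapse = ", "))
  }
  df
}

#' @rdname read_annotation_map
#' @param annotation annotation data.frame to write.
#' @export
write_annotation_map <- function(annotation, path) {
  write.table(annotation, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read / write a three-valued call matrix
#'
#' TSV with phenotype ids in the first column and one column per strain;
#' cells are \code{A}, \code{N} or \code{NT}.
#'
#' @param path file path.
#' @return a \code{\link{call_matrix}}.
#' @export
read_call_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop("parse error: empty call matrix")
  }
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    stop("parse error: duplicated phenotype id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- ids
  call_matrix(m)
}

#' @rdname read_call_matrix
#' @param calls call matrix to write.
#' @export
write_call_matrix <- function(calls, path) {
  df <- data.frame(phenotype_id = rownames(calls),
                   unclass(calls)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a truth set
#'
#' JSON serialisation of the synthetic generator's ground truth (latent
#' status matrix and planted pairs).
#'
#' @param path file path.
#' @return a \code{truth_set}.
#' @export
read_truth_set <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  latent <- as.matrix(x$latent_status)
  dimnames(latent) <- list(x$phenotypes, x$strains)
  pp <- if (!is.null(x$planted_pairs) && length(x$planted_pairs) > 0) {
    as.data.frame(x$planted_pairs)
  } else {
    NULL
  }
  structure(list(latent_status = latent, mask = NULL, planted_pairs = pp),
            class = "truth_set")
}

#' @rdname read_truth_set
#' @param truth a \code{truth_set} to write.
#' @export
write_truth_set <- function(truth, path) {
  jsonlite::write_json(
    list(phenotypes = rownames(truth$latent_status),
         strains = colnames(truth$latent_status),
         latent_status = unname(as.matrix(truth$latent_status)),
         planted_pairs = truth$planted_pairs),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a rule table as CSV
#'
#' @param rules rule data.frame (mined measures or atlas rules).
#' @param path file path.
#' @export
write_rules_csv <- function(rules, path) {
  write.csv(rules, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_rules_csv
#' @export
read_rules_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Export a graph as GraphML or an attribute edge list
#'
#' @param graph an \code{igraph} graph, \code{pathway_graph} or
#'   \code{ppap}.
#' @param format \code{"graphml"} or \code{"edgelist"} (TSV with edge
#'   attributes).
#' @param path output path.
#' @export
export_graph <- function(graph, format = c("graphml", "edgelist"), path) {
  format <- match.arg(format)
  g <- if (inherits(graph, "igraph")) {
    graph
  } else if (inherits(graph, "pathway_graph")) {
    igraph::graph_from_data_frame(graph$edges, directed = TRUE)
  } else if (inherits(graph, "ppap")) {
    graph$graph
  } else {
    stop("parameter error: unsupported graph object")
  }
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    df <- igraph::as_data_frame(g, what = "edges")
    names(df)[1:2] <- c("lhs", "rhs")
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname export_graph
#' @export
read_edge_list <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
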