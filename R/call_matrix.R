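#' Three-valued phenotypic call matrix
#'
#' A call matrix is a character matrix with phenotypes as rows and mutant
#' strains as columns; each cell is one of \code{"A"} (abnormal), \code{"N"}
#' (normal) or \code{"NT"} (not tested). The effect-size threshold under
#' which the calls were made (if any) is kept as the \code{threshold}
#' attribute.
#'
#' @param x character matrix with row and column names.
#' @param threshold |ES| threshold used for the calls, or NA.
#' @return object of class \code{call_matrix}.
#' @export
call_matrix <- function(x, threshold = NA_real_) {
  if (!is.matrix(x) || !is.character(x)) {
    stop("call matrix must be a character matrix")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("call matrix needs phenotype rownames and strain colnames")
  }
  if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x))) {
    stop("duplicated phenotype or strain ids in call matrix")
  }
  bad <- !(x %in% c("A", "N", "NT"))
  if (any(bad)) {
    stop("call matrix cells must be one of 'A', 'N', 'NT'; found: ",
         paste(unique(x[bad]), collapse = ", "))
  }
  structure(x, threshold = threshold, class = c("call_matrix", "matrix"))
}

#' @export
print.call_matrix <- function(x, ...) {
  cat(sprintf("call_matrix: %d phenotypes x %d strains (threshold %s)\n",
              nrow(x), ncol(x), format(attr(x, "threshold"))))
  tab <- table(factor(x, levels = c("A", "N", "NT")))
  cat(sprintf("  abnormal %d, normal %d, not-tested %d\n",
              tab[["A"]], tab[["N"]], tab[["NT"]]))
  invisible(x)
}

call_threshold <- function(x) attr(x, "threshold")
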