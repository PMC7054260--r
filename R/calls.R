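#' Unbiased Hedges' g between mutant and control measurements
#'
#' Standardized mean difference d = (mean_m - mean_c) / s_pooled with the
#' small-sample correction J = 1 - 3 / (4 df - 1), df = n_m + n_c - 2, giving
#' g = J d. The standard error uses the large-sample (Hedges-Olkin)
#' approximation se(g)^2 = (n_m + n_c) / (n_m n_c) + g^2 / (2 (n_m + n_c)),
#' with a normal-quantile 95\% CI and two-sided p for g != 0. The
#' accompanying exact significance test is a two-sided Welch t-test by
#' default, or an exact Wilcoxon rank-sum test.
#'
#' @param mutant_values,control_values numeric vectors, each with >= 2 finite
#'   values and non-zero pooled variance; otherwise the result is flagged
#'   not computable (the cell becomes not-tested downstream).
#' @param exact_test the accompanying significance test, \code{"welch"} or
#'   \code{"wilcoxon"}.
#' @return object of class \code{effect_size_result}: \code{g}, \code{se_g},
#'   \code{ci95} (low, high), \code{p_g}, \code{p_exact}, \code{n_mutant},
#'   \code{n_control}, \code{computable}.
#' @examples
#' hedges_g(c(3, 4, 5), c(1, 2, 3))$g   # 1.6
#' @export
hedges_g <- function(mutant_values, control_values,
                     exact_test = c("welch", "wilcoxon")) {
  exact_test <- match.arg(exact_test)
  m <- mutant_values[is.finite(mutant_values)]
  cv <- control_values[is.finite(control_values)]
  nm <- length(m)
  nc <- length(cv)
  not_computable <- structure(
    list(g = NA_real_, se_g = NA_real_, ci95 = c(NA_real_, NA_real_),
         p_g = NA_real_, p_exact = NA_real_, n_mutant = nm, n_control = nc,
         computable = FALSE),
    class = "effect_size_result")
  if (nm < 2L || nc < 2L) {
    return(not_computable)
  }
  df <- nm + nc - 2
  s2 <- ((nm - 1) * stats::var(m) + (nc - 1) * stats::var(cv)) / df
  if (!is.finite(s2) || s2 <= 0) {
    return(not_computable)
  }
  d <- (mean(m) - mean(cv)) / sqrt(s2)
  J <- 1 - 3 / (4 * df - 1)
  g <- J * d
  se <- sqrt((nm + nc) / (nm * nc) + g^2 / (2 * (nm + nc)))
  z <- qnorm(0.975)
  p_g <- 2 * pnorm(-abs(g) / se)
  p_exact <- if (exact_test == "welch") {
    stats::t.test(m, cv)$p.value
  } else {
    stats::wilcox.test(m, cv, exact = TRUE)$p.value
  }
  structure(list(g = g, se_g = se, ci95 = c(g - z * se, g + z * se),
                 p_g = p_g, p_exact = p_exact,
                 n_mutant = nm, n_control = nc, computable = TRUE),
            class = "effect_size_result")
}

#' Three-valued phenotypic call from an effect-size result
#'
#' A cell is called abnormal iff |g| >= threshold AND both prerequisites
#' hold: the effect is significant at the 95\% level (p for g < 0.05) and
#' the accompanying exact test has p < 0.05. Otherwise it is normal; a
#' non-computable effect size yields not-tested.
#'
#' @param es an \code{effect_size_result} from \code{\link{hedges_g}}.
#' @param threshold |ES| call threshold.
#' @return \code{"A"}, \code{"N"} or \code{"NT"}.
#' @export
make_call <- function(es, threshold) {
  stopifnot(inherits(es, "effect_size_result"), threshold > 0)
  if (!isTRUE(es$computable)) {
    return("NT")
  }
  if (abs(es$g) >= threshold && es$p_g < 0.05 && es$p_exact < 0.05) "A" else "N"
}

#' Collapse parameter-level calls to phenotype-level calls
#'
#' Multiple measured parameters can annotate the same ontology phenotype.
#' The phenotype-level call is abnormal if any constituent parameter is
#' abnormal, normal if none is abnormal and at least one was tested, and
#' not-tested if all constituents are not-tested.
#'
#' @param parameter_calls character matrix (parameters x strains) of
#'   \code{"A"/"N"/"NT"} with parameter rownames.
#' @param annotation annotation map with columns \code{parameter_id},
#'   \code{phenotype_id}; every parameter in \code{parameter_calls} must be
#'   mapped.
#' @param threshold |ES| threshold recorded on the result.
#' @return a \code{\link{call_matrix}} (phenotypes x strains).
#' @export
collapse_parameters <- function(parameter_calls, annotation,
                                threshold = NA_real_) {
  params <- rownames(parameter_calls)
  hit <- match(params, annotation$parameter_id)
  if (anyNA(hit)) {
    stop("annotation error: unmapped parameters: ",
         paste(params[is.na(hit)], collapse = ", "))
  }
  phen <- annotation$phenotype_id[hit]
  u <- unique(phen)
  abn <- rowsum((parameter_calls == "A") + 0L, phen)[u, , drop = FALSE]
  tested <- rowsum((parameter_calls != "NT") + 0L, phen)[u, , drop = FALSE]
  out <- matrix("NT", nrow = length(u), ncol = ncol(parameter_calls),
                dimnames = list(u, colnames(parameter_calls)))
  out[tested > 0L] <- "N"
  out[abn > 0L] <- "A"
  call_matrix(out, threshold = threshold)
}

#' Grid of |ES| call thresholds
#'
#' Default 0.8 to 3.0 in bins of 0.1 (23 values).
#'
#' @param from,to,by grid specification; must yield strictly increasing
#'   positive values.
#' @return numeric vector of thresholds.
#' @export
threshold_grid <- function(from = 0.8, to = 3.0, by = 0.1) {
  g <- round(seq(from, to, by = by), 10)
  if (length(g) < 1L || any(g <= 0) || any(diff(g) <= 0)) {
    stop("threshold grid must be strictly increasing and positive")
  }
  g
}

# Per-(parameter, strain) effect-size table, vectorised over cells: group
# means/variances are accumulated with rowsum() and the Welch test is
# computed from summary statistics. Returns one row per mutant cell.
effect_size_table <- function(measurements, exact_test = "welch") {
  cohort <- measurements$cohort
  ctrl <- measurements[cohort == "control", , drop = FALSE]
  mut <- measurements[cohort == "mutant", , drop = FALSE]
  if (nrow(ctrl) == 0L || nrow(mut) == 0L) {
    stop("measurements must contain both mutant and control rows")
  }
  gstat <- function(key, value) {
    n <- as.vector(rowsum(rep(1, length(value)), key))
    s <- as.vector(rowsum(value, key))
    s2 <- as.vector(rowsum(value^2, key))
    keys <- sort(unique(key))
    mean <- s / n
    var <- (s2 - n * mean^2) / pmax(n - 1, 1)
    var[n < 2] <- NA_real_
    data.frame(key = keys, n = n, mean = mean, var = pmax(var, 0),
               stringsAsFactors = FALSE)
  }
  cs <- gstat(ctrl$parameter_id, ctrl$value)
  mkey <- paste(mut$parameter_id, mut$strain_id, sep = "\r")
  ms <- gstat(mkey, mut$value)
  parts <- strsplit(ms$key, "\r", fixed = TRUE)
  ms$parameter_id <- vapply(parts, `[`, character(1), 1L)
  ms$strain_id <- vapply(parts, `[`, character(1), 2L)
  ci <- match(ms$parameter_id, cs$key)

  nm <- ms$n
  nc <- cs$n[ci]
  mm <- ms$mean
  mc <- cs$mean[ci]
  vm <- ms$var
  vc <- cs$var[ci]
  df <- nm + nc - 2
  s2 <- ((nm - 1) * vm + (nc - 1) * vc) / df
  ok <- !is.na(s2) & s2 > 0 & nm >= 2 & !is.na(nc) & nc >= 2
  d <- ifelse(ok, (mm - mc) / sqrt(s2), NA_real_)
  J <- 1 - 3 / (4 * df - 1)
  g <- J * d
  se <- sqrt((nm + nc) / (nm * nc) + g^2 / (2 * (nm + nc)))
  p_g <- 2 * pnorm(-abs(g) / se)
  if (exact_test == "welch") {
    wse2 <- vm / nm + vc / nc
    tstat <- (mm - mc) / sqrt(wse2)
    wdf <- wse2^2 / ((vm / nm)^2 / (nm - 1) + (vc / nc)^2 / (nc - 1))
    p_exact <- 2 * pt(-abs(tstat), wdf)
  } else {
    p_exact <- rep(NA_real_, length(g))
    cvals <- split(ctrl$value, ctrl$parameter_id)
    mvals <- split(mut$value, mkey)
    for (i in which(ok)) {
      p_exact[i] <- stats::wilcox.test(mvals[[ms$key[i]]],
                                       cvals[[ms$parameter_id[i]]],
                                       exact = TRUE)$p.value
    }
  }
  p_exact[!ok] <- NA_real_
  z <- qnorm(0.975)
  data.frame(parameter_id = ms$parameter_id, strain_id = ms$strain_id,
             g = g, se_g = se, ci_low = g - z * se, ci_high = g + z * se,
             p_g = p_g, p_exact = p_exact,
             n_mutant = nm, n_control = nc,
             computable = ok, stringsAsFactors = FALSE)
}

#' Compute call matrices over a grid of |ES| thresholds
#'
#' Effect sizes are computed once per (parameter, strain) cell; each grid
#' value then thresholds |g| under the two significance prerequisites (see
#' \code{\link{make_call}}) and parameter calls are collapsed to phenotype
#' level. The abnormal-cell count is non-increasing in the threshold by
#' construction.
#'
#' @param measurements long-format measurement data.frame
#'   (\code{parameter_id}, \code{strain_id}, \code{cohort}, \code{value}).
#' @param annotation annotation map (parameter -> phenotype).
#' @param grid thresholds from \code{\link{threshold_grid}}.
#' @param exact_test passed to the effect-size computation.
#' @return object of class \code{call_sweep}: list with \code{matrices}
#'   (named list of \code{\link{call_matrix}}, one per threshold),
#'   \code{effect_sizes} (per-cell table) and \code{grid}.
#' @export
sweep_call_matrices <- function(measurements, annotation,
                                grid = threshold_grid(),
                                exact_test = c("welch", "wilcoxon")) {
  exact_test <- match.arg(exact_test)
  grid <- threshold_grid(from = grid[1], to = grid[length(grid)],
                         by = if (length(grid) > 1) grid[2] - grid[1] else 0.1)
  es <- effect_size_table(measurements, exact_test = exact_test)
  params <- sort(unique(es$parameter_id))
  strains <- sort(unique(es$strain_id))
  ri <- match(es$parameter_id, params)
  ci <- match(es$strain_id, strains)
  idx <- (ci - 1L) * length(params) + ri
  base <- matrix(NA_real_, nrow = length(params), ncol = length(strains),
                 dimnames = list(params, strains))
  absg <- prereq <- base
  absg[idx] <- abs(es$g)
  prereq[idx] <- (es$p_g < 0.05 & es$p_exact < 0.05) + 0
  matrices <- lapply(grid, function(t) {
    pc <- matrix("NT", nrow = length(params), ncol = length(strains),
                 dimnames = list(params, strains))
    tested <- !is.na(absg)
    pc[tested] <- ifelse(absg[tested] >= t & prereq[tested] == 1, "A", "N")
    collapse_parameters(pc, annotation, threshold = t)
  })
  names(matrices) <- format(grid)
  structure(list(matrices = matrices, effect_sizes = es, grid = grid),
            class = "call_sweep")
}
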