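#' Configuration for the synthetic phenotyping-corpus generator
#'
#' The generator emulates the statistical shape of a large knockout-mouse
#' phenotyping screen: several hundred ontology-annotated phenotypes measured
#' over a few thousand single-gene mutant strains, a marginal abnormality
#' frequency of about 4\% at a stringent effect-size threshold, heavy
#' not-tested missingness, four stage/type phenotype categories, and a set of
#' planted phenotype pairs whose abnormalities co-occur more often than
#' expected under independence (quantified by a lift ratio).
#'
#' Planted pairs are coupled through a shared Bernoulli component: the latent
#' abnormal status of each member is \code{C | U}, with \code{C ~ Bern(c)}
#' shared and \code{U ~ Bern(u)} independent, so the joint abnormality
#' probability is \code{c + (1 - c) u^2} in closed form. The mixing weight
#' \code{c} is solved so the joint equals \code{lift * rate^2}, which is
#' feasible for lift between 1 and \code{1/rate}. Planted pairs may overlap
#' as long as they decompose into disjoint cliques with a uniform lift per
#' clique (each clique shares one Bernoulli component, giving every
#' within-clique pair exactly the configured pairwise lift) — this emulates
#' the module-structured co-abnormality of real phenotyping corpora, where a
#' phenotype participates in many correlated relationships at once.
#'
#' @param n_phenotypes,n_strains corpus dimensions.
#' @param n_controls_per_parameter control animals measured per parameter.
#' @param n_mutants_per_strain replicate mutant animals per strain.
#' @param abnormality_rate target marginal frequency of latent abnormality.
#' @param planted_pairs data.frame with columns \code{phenotype_i},
#'   \code{phenotype_j} (1-based phenotype indices) and \code{lift}
#'   (co-abnormality ratio >= 1); pairs must decompose into disjoint
#'   cliques with one lift value per clique (an isolated pair is a clique
#'   of two). NULL for none.
#' @param effect_size_abnormal standardized mean shift (in units of the
#'   control SD) of measurements in latently abnormal cells.
#' @param missing_rate probability that a (phenotype, strain) cell is not
#'   tested, independent of status (MCAR).
#' @param stage_type_mix named proportions over the four stage/type
#'   categories \code{adult_trait}, \code{adult_gene}, \code{embryo_trait},
#'   \code{embryo_gene}.
#' @param n_biological_systems number of biological-system labels to draw
#'   annotations from (each phenotype gets 1-2).
#' @param seed integer seed; identical config + seed gives byte-identical
#'   output.
#' @return validated object of class \code{sim_config}.
#' @export
sim_config <- function(n_phenotypes = 500,
                       n_strains = 3000,
                       n_controls_per_parameter = 100,
                       n_mutants_per_strain = 7,
                       abnormality_rate = 0.04,
                       planted_pairs = NULL,
                       effect_size_abnormal = 3,
                       missing_rate = 0.3,
                       stage_type_mix = c(adult_trait = 0.55,
                                          adult_gene = 0.30,
                                          embryo_trait = 0.10,
                                          embryo_gene = 0.05),
                       n_biological_systems = 60,
                       seed = 1L) {
  counts <- c(n_phenotypes = n_phenotypes, n_strains = n_strains,
              n_controls_per_parameter = n_controls_per_parameter,
              n_mutants_per_strain = n_mutants_per_strain,
              n_biological_systems = n_biological_systems)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("configuration error: counts must be integers >= 1")
  }
  probs <- c(abnormality_rate = abnormality_rate, missing_rate = missing_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("configuration error: probabilities must lie in [0, 1]")
  }
  stages <- c("adult_trait", "adult_gene", "embryo_trait", "embryo_gene")
  if (!setequal(names(stage_type_mix), stages) ||
      any(stage_type_mix < 0) || sum(stage_type_mix) <= 0) {
    stop("configuration error: stage_type_mix must be non-negative ",
         "proportions named ", paste(stages, collapse = ", "))
  }
  stage_type_mix <- stage_type_mix[stages] / sum(stage_type_mix)
  if (!is.null(planted_pairs)) {
    planted_pairs <- as.data.frame(planted_pairs)
    need <- c("phenotype_i", "phenotype_j", "lift")
    if (!all(need %in% names(planted_pairs))) {
      stop("configuration error: planted_pairs needs columns ",
           paste(need, collapse = ", "))
    }
    ids <- c(planted_pairs$phenotype_i, planted_pairs$phenotype_j)
    if (any(ids < 1 | ids > n_phenotypes) ||
        any(planted_pairs$phenotype_i == planted_pairs$phenotype_j)) {
      stop("configuration error: planted pair indices out of range or self")
    }
    if (any(planted_pairs$lift < 1)) {
      stop("configuration error: planted lift must be >= 1")
    }
    if (any(planted_pairs$lift * abnormality_rate > 1)) {
      stop("configuration error: infeasible coupling, ",
           "lift * abnormality_rate must be <= 1")
    }
    planted_cliques(planted_pairs)  # validates the clique decomposition
  }
  structure(list(n_phenotypes = as.integer(n_phenotypes),
                 n_strains = as.integer(n_strains),
                 n_controls_per_parameter = as.integer(n_controls_per_parameter),
                 n_mutants_per_strain = as.integer(n_mutants_per_strain),
                 abnormality_rate = abnormality_rate,
                 planted_pairs = planted_pairs,
                 effect_size_abnormal = effect_size_abnormal,
                 missing_rate = missing_rate,
                 stage_type_mix = stage_type_mix,
                 n_biological_systems = as.integer(n_biological_systems),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Decompose planted pairs into cliques (connected components) and check
# that every component is complete with a single lift value.
planted_cliques <- function(pp) {
  members <- sort(unique(c(pp$phenotype_i, pp$phenotype_j)))
  comp <- setNames(seq_along(members), members)
  find <- function(x) {
    while (comp[[as.character(x)]] != x) x <- comp[[as.character(x)]]
    x
  }
  for (r in seq_len(nrow(pp))) {
    a <- find(pp$phenotype_i[r])
    b <- find(pp$phenotype_j[r])
    if (a != b) comp[[as.character(max(a, b))]] <- min(a, b)
  }
  roots <- vapply(members, find, numeric(1))
  lapply(split(members, roots), function(m) {
    k <- length(m)
    rows <- pp$phenotype_i %in% m | pp$phenotype_j %in% m
    if (sum(rows) != k * (k - 1) / 2) {
      stop("configuration error: planted pairs must form disjoint cliques ",
           "(component {", paste(m, collapse = ","), "} is incomplete)")
    }
    lifts <- unique(pp$lift[rows])
    if (length(lifts) != 1L) {
      stop("configuration error: planted clique {",
           paste(m, collapse = ","), "} must have a single lift value")
    }
    list(members = m, lift = lifts)
  })
}

# Shared-Bernoulli mixing weight c such that, with u(c) chosen to keep the
# marginal at `rate`, P(both abnormal) = lift * rate^2.
solve_coupling <- function(rate, lift) {
  if (lift == 1 || rate == 0) {
    return(0)
  }
  target <- lift * rate^2
  if (target > rate + 1e-12) {
    stop("configuration error: infeasible coupling (lift > 1/rate)")
  }
  joint <- function(cc) {
    u <- 1 - (1 - rate) / (1 - cc)
    cc + (1 - cc) * u^2 - target
  }
  uniroot(joint, lower = 0, upper = rate, tol = 1e-12)$root
}

#' Planted-pair table for disjoint co-abnormality cliques
#'
#' Convenience constructor: consecutive phenotype indices (starting at
#' \code{start}) are grouped into cliques of the given sizes, and all
#' within-clique pairs are emitted with the given pairwise lift.
#'
#' @param sizes integer vector of clique sizes (>= 2).
#' @param lift pairwise co-abnormality lift shared by every clique.
#' @param start first phenotype index used.
#' @return data.frame suitable for \code{\link{sim_config}}'s
#'   \code{planted_pairs}.
#' @export
planted_clique_pairs <- function(sizes, lift, start = 1L) {
  stopifnot(all(sizes >= 2), lift >= 1)
  offset <- start - 1L
  out <- do.call(rbind, lapply(sizes, function(k) {
    m <- offset + seq_len(k)
    offset <<- offset + k
    idx <- utils::combn(m, 2)
    data.frame(phenotype_i = idx[1, ], phenotype_j = idx[2, ], lift = lift)
  }))
  rownames(out) <- NULL
  out
}

#' Generate a synthetic annotation catalog
#'
#' Produces one ontology-style phenotype id per phenotype, of the form
#' \code{stage_type:phenotype_NNN}, with a stage/type category drawn from the
#' configured mix and 1-2 biological-system labels. One measured parameter is
#' emitted per phenotype (\code{param_NNN}).
#'
#' @param config a \code{\link{sim_config}}.
#' @return annotation map data.frame with columns \code{parameter_id},
#'   \code{phenotype_id}, \code{stage_type}, \code{biological_systems}
#'   (semicolon-separated labels).
#' @export
generate_catalog <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_phenotypes
  stages <- sample(names(config$stage_type_mix), n, replace = TRUE,
                   prob = config$stage_type_mix)
  systems <- vapply(seq_len(n), function(i) {
    k <- sample(1:2, 1L)
    paste(sort(sprintf("system_%02d",
                       sample.int(config$n_biological_systems, k))),
          collapse = ";")
  }, character(1))
  data.frame(parameter_id = sprintf("param_%04d", seq_len(n)),
             phenotype_id = sprintf("%s:phenotype_%04d", stages, seq_len(n)),
             stage_type = stages,
             biological_systems = systems,
             stringsAsFactors = FALSE)
}

# Latent abnormal-status matrix (phenotypes x strains, 0/1) with planted
# pairs coupled by the shared-Bernoulli construction, plus the MCAR
# not-tested mask. RNG state must be set by the caller.
generate_latent <- function(config) {
  n <- config$n_phenotypes
  s <- config$n_strains
  rate <- config$abnormality_rate
  latent <- matrix(rbinom(n * s, 1L, rate), nrow = n)
  pp <- config$planted_pairs
  if (!is.null(pp) && nrow(pp) > 0L) {
    for (cl in planted_cliques(pp)) {
      cc <- solve_coupling(rate, cl$lift)
      u <- if (cc < 1) 1 - (1 - rate) / (1 - cc) else 0
      shared <- rbinom(s, 1L, cc)
      for (m in cl$members) {
        latent[m, ] <- pmax(shared, rbinom(s, 1L, u))
      }
    }
  }
  mask <- matrix(runif(n * s) < config$missing_rate, nrow = n)
  list(latent = latent, mask = mask)
}

#' Generate synthetic measurements with a ground-truth set
#'
#' Control values are standard normal per parameter. Each (phenotype, strain)
#' cell draws a latent abnormal status at the configured marginal rate (with
#' planted pairs coupled, see \code{\link{sim_config}}); mutant replicate
#' values are normal with mean \code{effect_size_abnormal} when latently
#' abnormal and 0 otherwise, unit SD throughout. Cells masked as not-tested
#' contribute no mutant rows.
#'
#' @param config a \code{\link{sim_config}}.
#' @param catalog annotation map from \code{\link{generate_catalog}}.
#' @return list with \code{measurements} (long-format data.frame:
#'   \code{parameter_id}, \code{strain_id}, \code{cohort}, \code{value}) and
#'   \code{truth} (a \code{truth_set}: \code{latent_status} matrix keyed by
#'   phenotype/strain ids, \code{planted_pairs}).
#' @export
generate_measurements <- function(config, catalog) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(catalog) != config$n_phenotypes) {
    stop("catalog does not match config (phenotype count)")
  }
  set.seed(config$seed + 1L)
  n <- config$n_phenotypes
  s <- config$n_strains
  lt <- generate_latent(config)
  strains <- sprintf("strain_%04d", seq_len(s))
  dimnames(lt$latent) <- list(catalog$phenotype_id, strains)

  nc <- config$n_controls_per_parameter
  controls <- data.frame(
    parameter_id = rep(catalog$parameter_id, each = nc),
    strain_id = "control",
    cohort = "control",
    value = rnorm(n * nc),
    stringsAsFactors = FALSE)

  tested <- which(!lt$mask)                      # cell indices, column-major
  nm <- config$n_mutants_per_strain
  phen_idx <- ((tested - 1L) %% n) + 1L
  strain_idx <- ((tested - 1L) %/% n) + 1L
  delta <- config$effect_size_abnormal * lt$latent[tested]
  mutants <- data.frame(
    parameter_id = rep(catalog$parameter_id[phen_idx], each = nm),
    strain_id = rep(strains[strain_idx], each = nm),
    cohort = "mutant",
    value = rnorm(length(tested) * nm, mean = rep(delta, each = nm)),
    stringsAsFactors = FALSE)

  truth <- structure(list(latent_status = lt$latent,
                          mask = lt$mask,
                          planted_pairs = config$planted_pairs),
                     class = "truth_set")
  list(measurements = rbind(controls, mutants), truth = truth)
}

#' Generate a call matrix directly from latent statuses
#'
#' Shortcut that bypasses the measurement and effect-size stages: abnormal
#' cells equal the latent statuses, with not-tested masking applied. Useful
#' for exercising the mining stages at scale, and for emulating categorical
#' parameters that never pass through the effect-size path.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{calls} (a \code{\link{call_matrix}}) and
#'   \code{truth} (a \code{truth_set}).
#' @export
generate_call_matrix <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  lt <- generate_latent(config)
  catalog <- generate_catalog(config)   # reseeds; latent already drawn
  strains <- sprintf("strain_%04d", seq_len(config$n_strains))
  dimnames(lt$latent) <- list(catalog$phenotype_id, strains)
  calls <- ifelse(lt$latent == 1L, "A", "N")
  calls[lt$mask] <- "NT"
  dimnames(calls) <- dimnames(lt$latent)
  truth <- structure(list(latent_status = lt$latent,
                          mask = lt$mask,
                          planted_pairs = config$planted_pairs),
                     class = "truth_set")
  list(calls = call_matrix(calls), truth = truth)
}
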