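#' Genotype concordance rate
#'
#' Percent of polymorphic markers at which the maximum-posterior (hard)
#' genotype call matches the true genotype, per individual. Only loci
#' polymorphic between the individual's own parents enter the denominator:
#' monomorphic loci impute with certainty and would inflate the rate.
#' Individuals with zero polymorphic loci are excluded with a warning.
#'
#' @param true Individuals x markers matrix of true dosages (0/2).
#' @param hard_call Individuals x markers matrix of hard calls, same
#'   dimnames.
#' @param polymorphic Logical individuals x markers matrix marking each
#'   individual's polymorphic loci (parents differ).
#' @return A `data.frame` with columns `individual`, `n_polymorphic`,
#'   `concordance` (percent).
#' @export
genotype_concordance <- function(true, hard_call, polymorphic) {
  stopifnot(all(dim(true) == dim(hard_call)),
            all(dim(true) == dim(polymorphic)))
  n_poly <- rowSums(polymorphic)
  conc <- rowSums((true == hard_call) & polymorphic) / n_poly * 100
  if (any(n_poly == 0))
    warning(sum(n_poly == 0), " individual(s) without polymorphic loci ",
            "excluded from concordance")
  out <- data.frame(individual = rownames(true), n_polymorphic = n_poly,
                    concordance = conc, stringsAsFactors = FALSE,
                    row.names = NULL)
  out[out$n_polymorphic > 0, , drop = FALSE]
}

#' Baseline concordance of fixed-genotype imputation
#'
#' The naive baseline assigns, at every polymorphic locus, one of the two
#' parental genotypes (chosen at random per locus, emulating imputation of
#' the most frequent genotype when both parental alleles are expected at
#' frequency 0.5) to all individuals of a population. In biparental
#' populations the expected concordance of this rule is 50%.
#'
#' @param populations List of populations from [simulate_populations()]
#'   (each with `genotypes` and `parents`).
#' @param parents A [parent_genotypes()] table (or the founder panel's
#'   genotype matrix with lines in rows, transposed automatically).
#' @param seed Optional integer seed.
#' @return List with `per_population` (mean concordance per population, %)
#'   and `mean` (average over populations).
#' @export
baseline_concordance <- function(populations, parents, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  geno_par <- if (inherits(parents, "parent_genotypes")) unclass(parents)
              else t(parents)
  per_pop <- vapply(populations, function(pop) {
    g1 <- geno_par[colnames(pop$genotypes), pop$parents[1]]
    g2 <- geno_par[colnames(pop$genotypes), pop$parents[2]]
    poly <- g1 != g2
    if (!any(poly)) return(NA_real_)
    pick <- ifelse(stats::runif(sum(poly)) < 0.5, g1[poly], g2[poly])
    imputed <- matrix(pick, nrow(pop$genotypes), sum(poly), byrow = TRUE)
    mean(pop$genotypes[, poly, drop = FALSE] == imputed) * 100
  }, 0)
  list(per_population = per_pop, mean = mean(per_pop, na.rm = TRUE))
}

#' Multi-polymorphism rate of a pool's populations
#'
#' For each member population: the percentage of its polymorphic loci that
#' are polymorphic between the parents of at least one other member of the
#' pool. Multi-polymorphic loci are the ones whose pool genotype cannot be
#' traced to a single population, which lowers imputation accuracy.
#'
#' @param pool A [pool_definition()] with at least two members.
#' @param parents A [parent_genotypes()] table.
#' @return Named numeric vector: rate (%) per member.
#' @export
multi_polymorphism_rate <- function(pool, parents) {
  if (nrow(pool) < 2) stop("multi-polymorphism needs a pool of >= 2 members")
  geno <- unclass(parents)
  poly <- matrix(sapply(seq_len(nrow(pool)), function(d)
    geno[, pool$parent1[d]] != geno[, pool$parent2[d]]),
    nrow = nrow(geno))
  rates <- vapply(seq_len(nrow(pool)), function(d) {
    own <- poly[, d]
    if (!any(own)) return(NA_real_)
    others <- poly[, -d, drop = FALSE]
    mean(rowSums(others[own, , drop = FALSE]) > 0) * 100
  }, 0)
  stats::setNames(rates, pool$individual)
}

#' Calibration of genotype call probabilities
#'
#' A probability assessment is calibrated when events predicted with p%
#' probability occur in p% of cases. Bins the call probabilities on
#' [0.5, 1] and reports, per bin, the mean call probability, the empirical
#' accuracy of the calls, and the number of calls.
#'
#' @param call_prob Numeric vector of call probabilities (in [0.5, 1]).
#' @param correct Logical vector: was the hard call correct?
#' @param bin_width Bin width on the probability axis (default 0.1).
#' @return A `data.frame` with `bin_lower`, `bin_upper`, `mean_prob`,
#'   `accuracy` (percent), `n`.
#' @export
calibration_table <- function(call_prob, correct, bin_width = 0.1) {
  stopifnot(length(call_prob) == length(correct))
  breaks <- seq(0.5, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  bin <- cut(call_prob, breaks, include.lowest = TRUE, right = FALSE)
  # put exact 1s in the top bin
  bin[call_prob >= breaks[length(breaks) - 1]] <-
    levels(bin)[length(levels(bin))]
  out <- data.frame(
    bin_lower = breaks[-length(breaks)],
    bin_upper = breaks[-1],
    mean_prob = as.numeric(tapply(call_prob, bin, mean)),
    accuracy = as.numeric(tapply(correct, bin, mean)) * 100,
    n = as.integer(table(bin)),
    row.names = NULL)
  out
}

#' Mean imputation uncertainty
#'
#' The imputation uncertainty of a call is summarised by the posterior
#' probability of the most likely genotype. Averages are reported overall
#' and split by whether the call was correct; well-behaved imputation gives
#' correct calls a higher average certainty than incorrect ones.
#'
#' @param call_prob Numeric vector of call probabilities.
#' @param correct Logical vector.
#' @return List with `overall`, `correct`, `incorrect` mean probabilities.
#' @export
mean_imputation_uncertainty <- function(call_prob, correct) {
  list(overall = mean(call_prob),
       correct = if (any(correct)) mean(call_prob[correct]) else NA_real_,
       incorrect = if (any(!correct)) mean(call_prob[!correct]) else NA_real_)
}

#' Genomic estimated breeding values
#'
#' Linear score of marker dosages weighted by estimated marker effects.
#' Fractional (posterior-weighted) dosages are accepted and recommended:
#' they weight each score by its certainty and buffer imputation error.
#'
#' @param dosages Individuals x markers dosage matrix.
#' @param marker_effects Named effect vector (names = markers) as returned
#'   by [ridge_effects()].
#' @return Named numeric vector of GEBV.
#' @export
gebv <- function(dosages, marker_effects) {
  eff <- marker_effects
  if (!is.null(names(eff))) {
    miss <- setdiff(names(eff), colnames(dosages))
    if (length(miss)) stop("dosage matrix lacks effect markers: ",
                           paste(utils::head(miss, 5), collapse = ", "))
    dosages <- dosages[, names(eff), drop = FALSE]
  }
  stats::setNames(as.numeric(dosages %*% eff), rownames(dosages))
}

#' Ridge estimation of whole-genome marker effects
#'
#' Closed-form ridge regression of phenotypes on centred marker dosages:
#' `effects = (X'X + lambda I)^-1 X'y`. A simple shrinkage estimator used
#' here for GEBV-concordance experiments, where the same estimator is
#' applied to both high-quality and pooled marker scores so its particular
#' form cancels to first order.
#'
#' @param genotypes Individuals x markers dosage matrix.
#' @param phenotypes Numeric vector.
#' @param lambda Non-negative ridge penalty (default: number of markers,
#'   a standard heuristic when marker effects are many and small).
#' @return Named numeric vector of marker effects (names = markers), with
#'   attribute `intercept`.
#' @export
ridge_effects <- function(genotypes, phenotypes, lambda = ncol(genotypes)) {
  stopifnot(nrow(genotypes) == length(phenotypes), lambda >= 0)
  X <- scale(genotypes, center = TRUE, scale = FALSE)
  y <- phenotypes - mean(phenotypes)
  p <- ncol(X)
  if (!is.finite(lambda) ) {
    eff <- rep(0, p)
  } else {
    A <- crossprod(X) + diag(lambda, p)
    eff <- as.numeric(solve(A, crossprod(X, y)))
  }
  out <- stats::setNames(eff, colnames(genotypes))
  attr(out, "intercept") <- mean(phenotypes) -
    sum(attr(X, "scaled:center") * eff)
  out
}

#' GEBV concordance
#'
#' Pearson correlation between GEBV computed from high-quality marker
#' scores and GEBV computed from pooled-imputation scores, either across
#' all target individuals or within each population (then averaged).
#' Within-population correlations that are undefined (constant GEBV) are
#' reported `NA` with a warning and dropped from the average.
#'
#' @param hq_gebv,pg_gebv Numeric vectors over the same individuals.
#' @param population Population label per individual (used by
#'   `mode = "within"`).
#' @param mode `"within"` or `"across"`.
#' @return For `"across"`, one correlation; for `"within"`, a list with
#'   `per_population` and `mean`.
#' @export
gebv_concordance <- function(hq_gebv, pg_gebv, population = NULL,
                             mode = c("within", "across")) {
  mode <- match.arg(mode)
  stopifnot(length(hq_gebv) == length(pg_gebv))
  if (mode == "across") return(stats::cor(hq_gebv, pg_gebv))
  if (is.null(population)) stop("mode 'within' needs population labels")
  per_pop <- vapply(split(seq_along(hq_gebv), population), function(idx) {
    if (stats::sd(hq_gebv[idx]) == 0 || stats::sd(pg_gebv[idx]) == 0)
      return(NA_real_)
    stats::cor(hq_gebv[idx], pg_gebv[idx])
  }, 0)
  if (anyNA(per_pop))
    warning("undefined within-population correlation (constant GEBV) in ",
            sum(is.na(per_pop)), " population(s)")
  list(per_population = per_pop, mean = mean(per_pop, na.rm = TRUE))
}
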