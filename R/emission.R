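#' Emission model configuration
#'
#' The Beta-Binomial emission model describes the probability of observing
#' `m` reference-allele reads out of `n` at a locus, given the expected
#' reference-allele frequency `pi` implied by an inheritance pattern and the
#' DNA fractions. `nu` is the dispersion: smaller values allow larger
#' deviations of the realised pool allele frequency from `pi` (technical
#' variation in DNA quantity/quality); `nu = 2` permits moderate deviation.
#'
#' For patterns in which all or none of the parents carry the reference
#' allele (`pi` of 1 or 0) the read distribution is a point mass. A nonzero
#' `error_floor` e softens these homogeneous-pattern emissions to
#' `1 - e` / `e`, accommodating a genotyping-error or contamination rate of
#' e; the default 0 assumes error-free reads.
#'
#' @param nu Dispersion, > 0. Default 2.
#' @param error_floor Probability in `[0, 0.5)` applied to homogeneous
#'   patterns. Default 0.
#' @param nu_overrides Optional named numeric vector of per-marker `nu`.
#' @return A list of class `emission_config`.
#' @export
emission_config <- function(nu = 2, error_floor = 0, nu_overrides = NULL) {
  if (!is.finite(nu) || nu <= 0) stop("nu must be positive")
  if (!is.finite(error_floor) || error_floor < 0 || error_floor >= 0.5)
    stop("error_floor must lie in [0, 0.5)")
  if (!is.null(nu_overrides) &&
      (is.null(names(nu_overrides)) || any(nu_overrides <= 0)))
    stop("nu_overrides must be a named vector of positive values")
  structure(list(nu = nu, error_floor = error_floor,
                 nu_overrides = nu_overrides),
            class = "emission_config")
}

#' Beta parameters for an expected allele frequency
#'
#' Maps the expected reference-allele frequency `pi` and dispersion `nu` to
#' the (alpha, beta) shape parameters of the Beta mixing distribution such
#' that the mean alpha/(alpha+beta) equals `pi` and the smaller shape equals
#' `nu`: for `pi < 0.5`, alpha = nu and beta = -(pi-1) nu / pi; otherwise
#' beta = nu and alpha = -pi nu / (pi-1).
#'
#' @param pi Expected reference-allele frequency, strictly in (0, 1).
#' @param nu Dispersion, > 0.
#' @return Numeric vector `c(alpha, beta)` (or a 2-column matrix for
#'   vectorised `pi`).
#' @export
alpha_beta <- function(pi, nu) {
  if (any(!is.finite(pi)) || any(pi <= 0) || any(pi >= 1))
    stop("pi must lie strictly in (0, 1); pi of 0/1 is a point mass")
  if (!is.finite(nu) || nu <= 0) stop("nu must be positive")
  alpha <- ifelse(pi < 0.5, nu, pi * nu / (1 - pi))
  beta <- ifelse(pi < 0.5, (1 - pi) * nu / pi, nu)
  if (length(pi) == 1L) c(alpha = alpha, beta = beta)
  else cbind(alpha = alpha, beta = beta)
}

#' Beta-Binomial probability mass
#'
#' `P(m | n, alpha, beta) = C(n, m) B(m + alpha, n - m + beta) / B(alpha,
#' beta)`, evaluated in log space. Vectorised over all arguments.
#'
#' @param m Reference-allele read count(s), `0 <= m <= n`.
#' @param n Total read count(s).
#' @param alpha,beta Positive Beta shape parameters.
#' @return Probability mass.
#' @export
beta_binomial_pmf <- function(m, n, alpha, beta) {
  if (any(m < 0) || any(n < 0) || any(m > n))
    stop("need 0 <= m <= n")
  if (any(alpha <= 0) || any(beta <= 0))
    stop("alpha and beta must be positive")
  exp(lchoose(n, m) + lbeta(m + alpha, n - m + beta) - lbeta(alpha, beta))
}

#' Expected reference-allele frequency of a pattern
#'
#' Under an inheritance pattern the pool's reference-allele frequency is the
#' sum of the DNA fractions of the members whose pattern-parent carries the
#' reference allele at the marker.
#'
#' @param space A `pattern_space`.
#' @param parents A [parent_genotypes()] table.
#' @param fractions DNA fractions of the members (sum 1).
#' @param marker Marker id (single).
#' @return Numeric vector of `pi` over patterns.
#' @export
expected_ref_frequency <- function(space, parents, fractions, marker) {
  .pattern_ref_frequency(space, parents, fractions, marker)[1, ]
}

# pi matrix over (markers x patterns); markers defaults to all table rows
.pattern_ref_frequency <- function(space, parents, fractions,
                                   markers = rownames(parents)) {
  S <- length(space$f0)
  P <- ncol(space$parent)
  geno <- unclass(parents)[markers, , drop = FALSE]
  pi_mat <- matrix(0, nrow = length(markers), ncol = S,
                   dimnames = list(markers, space$labels))
  for (s in seq_len(S)) {
    for (d in seq_len(P)) {
      pid <- space$parent[s, d]
      pi_mat[, s] <- pi_mat[, s] + fractions[d] * (geno[, pid] == 2)
    }
  }
  pi_mat
}

# Emission matrix (markers x patterns) for a set of observations aligned to
# `markers`. `m`,`n` are integer vectors (counts mode) or `call` a character
# vector (categorical mode). Rows are emission likelihoods per pattern (not
# normalised over patterns).
.emission_matrix <- function(pi_mat, m = NULL, n = NULL, call = NULL,
                             config = emission_config()) {
  M <- nrow(pi_mat)
  S <- ncol(pi_mat)
  E <- matrix(1, M, S, dimnames = dimnames(pi_mat))
  floor_ <- config$error_floor
  if (!is.null(call)) {
    hom_ref <- call == "homogeneous_ref"
    hom_alt <- call == "homogeneous_alt"
    het <- call == "heterogeneous"
    for (s in seq_len(S)) {
      p <- pi_mat[, s]
      E[hom_ref, s] <- as.numeric(p[hom_ref] == 1)
      E[hom_alt, s] <- as.numeric(p[hom_alt] == 0)
      E[het, s] <- as.numeric(p[het] > 0 & p[het] < 1)
    }
    return(E)
  }
  obs <- which(n > 0L)
  if (!length(obs)) return(E)
  nu <- rep(config$nu, M)
  if (!is.null(config$nu_overrides)) {
    hit <- intersect(names(config$nu_overrides), rownames(pi_mat))
    nu[match(hit, rownames(pi_mat))] <- config$nu_overrides[hit]
  }
  for (s in seq_len(S)) {
    p <- pi_mat[obs, s]
    e <- numeric(length(obs))
    mid <- p > 0 & p < 1
    if (any(mid)) {
      nus <- nu[obs][mid]  # nu may vary by locus
      alpha <- ifelse(p[mid] < 0.5, nus, p[mid] * nus / (1 - p[mid]))
      beta <- ifelse(p[mid] < 0.5, (1 - p[mid]) * nus / p[mid], nus)
      e[mid] <- beta_binomial_pmf(m[obs][mid], n[obs][mid], alpha, beta)
    }
    lo <- p == 0
    hi <- p == 1
    if (any(lo)) {
      consistent <- m[obs][lo] == 0L
      e[lo] <- if (floor_ > 0) ifelse(consistent, 1 - floor_, floor_)
               else as.numeric(consistent)
    }
    if (any(hi)) {
      consistent <- m[obs][hi] == n[obs][hi]
      e[hi] <- if (floor_ > 0) ifelse(consistent, 1 - floor_, floor_)
               else as.numeric(consistent)
    }
    E[obs, s] <- e
  }
  E
}

#' Emission likelihoods of one observation over all patterns
#'
#' For a read-count observation, each pattern's likelihood is the
#' Beta-Binomial probability of the observed counts at its expected
#' reference frequency (point masses for homogeneous patterns, optionally
#' softened by the error floor). A categorical call gives a 0/1 indicator
#' row over the patterns able to emit it, and a missing observation a row of
#' ones.
#'
#' @param observation One-row slice of a [pool_observations()] table (or a
#'   list with fields `ref_reads`/`total_reads` or `call`).
#' @param space A `pattern_space`.
#' @param parents A [parent_genotypes()] table.
#' @param fractions Member DNA fractions.
#' @param config An [emission_config()].
#' @param marker Marker id.
#' @return Numeric vector of emission likelihoods over patterns.
#' @export
emission_row <- function(observation, space, parents, fractions,
                         config = emission_config(), marker) {
  pi_mat <- .pattern_ref_frequency(space, parents, fractions, marker)
  if (!is.null(observation$call))
    .emission_matrix(pi_mat, call = observation$call, config = config)[1, ]
  else
    .emission_matrix(pi_mat, m = as.integer(observation$ref_reads),
                     n = as.integer(observation$total_reads),
                     config = config)[1, ]
}
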