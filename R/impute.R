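#' Convert posterior inheritance probabilities to imputed dosages
#'
#' The imputed reference-allele dosage of member `d` at locus `k` is
#' `g_dk = 2 (p_k . i_dk)`, where `i_dk` indicates the patterns whose
#' parent-of-origin for `d` carries the reference allele. The hard call is
#' the genotype with highest posterior probability (reference when
#' `P(ref) >= 0.5`; the exactly-tied case is called reference and flagged by
#' its call probability of 0.5), and the call probability is the posterior
#' probability of the hard call.
#'
#' @param posterior M x S posterior matrix (rownames = markers).
#' @param space A `pattern_space`.
#' @param parents A [parent_genotypes()] table.
#' @return A list of class `dosage_table` with matrices `dosage`,
#'   `hard_call`, `call_prob` (members x markers).
#' @export
impute_dosages <- function(posterior, space, parents) {
  markers <- rownames(posterior)
  geno <- unclass(parents)[markers, , drop = FALSE]
  members <- space$pool$individual
  P <- length(members)
  dosage <- matrix(NA_real_, P, length(markers),
                   dimnames = list(members, markers))
  for (d in seq_len(P)) {
    # incidence: markers x patterns, 1 where pattern-parent carries ref
    inc <- geno[, space$parent[, d], drop = FALSE] == 2
    dosage[d, ] <- 2 * rowSums(posterior * inc)
  }
  p_ref <- dosage / 2
  structure(list(dosage = dosage,
                 hard_call = ifelse(p_ref >= 0.5, 2, 0),
                 call_prob = pmax(p_ref, 1 - p_ref)),
            class = "dosage_table")
}

#' @export
as.data.frame.dosage_table <- function(x, ...) {
  members <- rownames(x$dosage)
  markers <- colnames(x$dosage)
  data.frame(individual = rep(members, each = length(markers)),
             marker = rep(markers, times = length(members)),
             dosage = as.vector(t(x$dosage)),
             hard_call = as.vector(t(x$hard_call)),
             call_prob = as.vector(t(x$call_prob)),
             stringsAsFactors = FALSE)
}

#' Direct imputation at monomorphic loci
#'
#' A locus where both parents of a member carry the same allele imputes with
#' certainty for that member, regardless of inheritance: the member's dosage
#' is the shared parental dosage. Loci monomorphic for *every* member carry
#' no linkage information and are removed from the HMM entirely; loci
#' segregating for at least one member stay in the HMM (where the
#' monomorphic members' dosages come out certain anyway).
#'
#' @param pool A [pool_definition()].
#' @param parents A [parent_genotypes()] table.
#' @return List with `member_dosage` (members x markers matrix, `NA` where
#'   the member's parents segregate) and `pool_monomorphic` (logical per
#'   marker: monomorphic for every member, i.e. excluded from the HMM).
#' @export
impute_monomorphic <- function(pool, parents) {
  geno <- unclass(parents)
  markers <- rownames(geno)
  P <- nrow(pool)
  member_dosage <- matrix(NA_real_, P, length(markers),
                          dimnames = list(pool$individual, markers))
  for (d in seq_len(P)) {
    g1 <- geno[, pool$parent1[d]]
    g2 <- geno[, pool$parent2[d]]
    mono <- g1 == g2
    member_dosage[d, mono] <- g1[mono]
  }
  list(member_dosage = member_dosage,
       pool_monomorphic = colSums(is.na(member_dosage)) == 0L)
}

#' Estimate member DNA fractions from differentially fixed loci
#'
#' Uses loci that are monomorphic within each member's population but fixed
#' for alternate alleles between populations: at such a locus the share of
#' reads carrying a population's private allele estimates that population's
#' DNA fraction directly. Per population the share is estimated as the
#' read-weighted mean over its informative loci; the shares are then
#' normalised to sum 1, and members from the same population split their
#' population's share equally. When no informative loci exist (or
#' observations are categorical) the members are assumed to have contributed
#' equal amounts of DNA, with a warning.
#'
#' @param observations A [pool_observations()] table (read counts).
#' @param pool A [pool_definition()].
#' @param parents A [parent_genotypes()] table.
#' @return Numeric vector of DNA fractions, one per member, summing to 1.
#' @export
estimate_dna_fractions <- function(observations, pool, parents) {
  P <- nrow(pool)
  equal <- rep(1 / P, P)
  if (attr(observations, "obs_type") != "counts") {
    warning("categorical observations: assuming equal DNA fractions")
    return(equal)
  }
  geno <- unclass(parents)
  # population identity = unordered parent pair
  pop_key <- mapply(function(a, b) paste(sort(c(a, b)), collapse = "|"),
                    pool$parent1, pool$parent2)
  groups <- unique(pop_key)
  obs_m <- observations$ref_reads[match(rownames(geno), observations$marker)]
  obs_n <- observations$total_reads[match(rownames(geno), observations$marker)]
  obs_m[is.na(obs_m)] <- 0L
  obs_n[is.na(obs_n)] <- 0L
  # fixed allele per population (NA where the population segregates)
  fixed <- sapply(groups, function(g) {
    d <- which(pop_key == g)[1]
    g1 <- geno[, pool$parent1[d]]
    g2 <- geno[, pool$parent2[d]]
    ifelse(g1 == g2, g1, NA_real_)
  })
  share <- rep(NA_real_, length(groups))
  for (j in seq_along(groups)) {
    own <- fixed[, j]
    others <- fixed[, -j, drop = FALSE]
    informative <- !is.na(own) & obs_n > 0
    if (ncol(others)) {
      for (h in seq_len(ncol(others)))
        informative <- informative & !is.na(others[, h]) & others[, h] != own
    }
    if (!any(informative)) next
    reads_own <- ifelse(own[informative] == 2,
                        obs_m[informative],
                        obs_n[informative] - obs_m[informative])
    # add-one smoothing keeps shares strictly inside (0, 1) when a
    # population's informative loci caught few or one-sided reads
    share[j] <- (sum(reads_own) + 1) / (sum(obs_n[informative]) + 2)
  }
  if (anyNA(share) || sum(share) <= 0) {
    warning("no informative (differentially fixed) loci with reads; ",
            "assuming equal DNA fractions")
    return(equal)
  }
  share <- share / sum(share)
  frac <- share[match(pop_key, groups)] / as.vector(table(pop_key)[pop_key])
  as.numeric(frac)
}

#' Impute pooled individuals' genotypes
#'
#' End-to-end parent-progeny imputation for one pool: validates the inputs,
#' removes loci monomorphic for every member (imputed directly from the
#' parents), estimates DNA fractions when not supplied, and runs the
#' forward-backward algorithm per chromosome over the retained loci with
#' Haldane recombination fractions between map-adjacent retained loci.
#'
#' @param parents A [parent_genotypes()] table covering all map markers.
#' @param map A [genetic_map()].
#' @param pool A [pool_definition()].
#' @param observations A [pool_observations()] table; markers absent from it
#'   are treated as missing.
#' @param config An [emission_config()].
#' @param fractions Optional member DNA fractions (overrides both the pool
#'   definition and estimation).
#' @return A list of class `pool_imputation`: `dosages` (a `dosage_table`
#'   over all map markers), `posterior` (retained markers x patterns),
#'   `fractions`, `space`, and `retained` (markers kept in the HMM).
#' @export
run_imputation <- function(parents, map, pool, observations,
                           config = emission_config(), fractions = NULL) {
  stopifnot(inherits(map, "genetic_map"), inherits(pool, "pool_definition"))
  geno <- unclass(parents)
  missing_parents <- setdiff(c(pool$parent1, pool$parent2), colnames(geno))
  if (length(missing_parents))
    stop("pool parents absent from genotype table: ",
         paste(missing_parents, collapse = ", "))
  absent <- setdiff(map$marker, rownames(geno))
  if (length(absent))
    stop("map markers missing from parent genotypes: ",
         paste(utils::head(absent, 5), collapse = ", "),
         if (length(absent) > 5) sprintf(" (and %d more)", length(absent) - 5))
  stray <- setdiff(observations$marker, map$marker)
  if (length(stray))
    stop("observed markers not in map: ",
         paste(utils::head(stray, 5), collapse = ", "),
         if (length(stray) > 5) sprintf(" (and %d more)", length(stray) - 5))

  categorical <- attr(observations, "obs_type") == "categorical"
  if (is.null(fractions)) {
    fractions <- if (!anyNA(pool$dna_fraction)) pool$dna_fraction
                 else if (categorical) rep(1 / nrow(pool), nrow(pool))
                 else estimate_dna_fractions(observations, pool, parents)
  }
  if (length(fractions) != nrow(pool) || abs(sum(fractions) - 1) > 1e-6)
    stop("fractions must have one entry per member and sum to 1")

  space <- enumerate_inheritance_patterns(pool)
  mono <- impute_monomorphic(pool, parents)
  retained_map <- map[!mono$pool_monomorphic[map$marker], , drop = FALSE]

  # align observations to retained markers
  idx <- match(retained_map$marker, observations$marker)
  if (categorical) {
    call <- observations$call[idx]
    call[is.na(call)] <- "missing"
    m <- n <- NULL
  } else {
    m <- observations$ref_reads[idx]
    n <- observations$total_reads[idx]
    m[is.na(m)] <- 0L
    n[is.na(n)] <- 0L
    call <- NULL
  }

  S <- length(space$f0)
  posterior <- matrix(NA_real_, nrow(retained_map), S,
                      dimnames = list(retained_map$marker, space$labels))
  if (nrow(retained_map)) {
    pi_mat <- .pattern_ref_frequency(space, parents, fractions,
                                     retained_map$marker)
    E <- .emission_matrix(pi_mat, m = m, n = n, call = call, config = config)
    for (ch in unique(retained_map$chrom)) {
      rows <- which(retained_map$chrom == ch)
      dist <- c(0, diff(retained_map$pos_cM[rows]))
      rvec <- recombination_fraction(dist)
      trans <- c(list(NULL),
                 lapply(rvec[-1], function(r)
                   build_transition_matrix(space, r)))
      fw <- forward_pass(trans, E[rows, , drop = FALSE], space$f0)
      bw <- backward_pass(trans, E[rows, , drop = FALSE])
      posterior[rows, ] <- posterior_inheritance(fw$f, bw$b)
    }
  }

  # dosages at HMM loci, then fill the pool-monomorphic loci directly
  all_markers <- map$marker
  members <- pool$individual
  P <- nrow(pool)
  full <- function(x) matrix(x, P, length(all_markers),
                             dimnames = list(members, all_markers))
  dos <- full(NA_real_); hard <- full(NA_real_); prob <- full(NA_real_)
  if (nrow(retained_map)) {
    dt <- impute_dosages(posterior, space, parents)
    dos[, retained_map$marker] <- dt$dosage
    hard[, retained_map$marker] <- dt$hard_call
    prob[, retained_map$marker] <- dt$call_prob
  }
  mono_markers <- map$marker[mono$pool_monomorphic[map$marker]]
  if (length(mono_markers)) {
    fill <- mono$member_dosage[, mono_markers, drop = FALSE]
    dos[, mono_markers] <- fill
    hard[, mono_markers] <- fill
    prob[, mono_markers] <- 1
  }
  structure(list(dosages = structure(list(dosage = dos, hard_call = hard,
                                          call_prob = prob),
                                     class = "dosage_table"),
                 posterior = posterior,
                 fractions = as.numeric(fractions),
                 space = space,
                 retained = retained_map$marker),
            class = "pool_imputation")
}
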