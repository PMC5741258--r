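#' Impute every pool of a simulated or observed experiment
#'
#' Thin driver over [run_imputation()]: pools are independent chains, so
#' they are processed one at a time (or in parallel from the command-line
#' tool). DNA fractions are estimated from the reads of each pool unless
#' `true_fractions = TRUE` (then the simulator's Dirichlet draws are used).
#'
#' @param parents A [parent_genotypes()] table (or a founder panel's
#'   `genotypes` matrix with lines in rows, transposed automatically).
#' @param map A [genetic_map()].
#' @param pool_set A [build_pools()] result.
#' @param gbs A [simulate_gbs()] result aligned with `pool_set`.
#' @param config An [emission_config()].
#' @param true_fractions Use the simulated DNA contributions instead of
#'   estimating them from reads.
#' @return List of `pool_imputation` objects, one per pool.
#' @export
impute_pools <- function(parents, map, pool_set, gbs,
                         config = emission_config(),
                         true_fractions = FALSE) {
  parents <- .as_parent_table(parents)
  lapply(seq_along(pool_set), function(i) {
    run_imputation(parents, map, pool_set[[i]]$definition,
                   gbs$pools[[i]]$observations, config = config,
                   fractions = if (true_fractions) gbs$pools[[i]]$fractions
                               else NULL)
  })
}

#' Score imputed pools against the simulated truth
#'
#' Gathers, over all pooled individuals, the per-individual genotype
#' concordance at their polymorphic loci together with the call
#' probabilities and correctness of every polymorphic call (for
#' calibration and uncertainty summaries).
#'
#' @param pool_set A [build_pools()] result (carries the true genotypes).
#' @param imputations Output of [impute_pools()].
#' @param parents Parent genotypes (as in [impute_pools()]).
#' @return List with `individuals` (data.frame: individual, pool,
#'   population, n_polymorphic, concordance, mean_call_prob) and `calls`
#'   (data.frame: call_prob, correct).
#' @export
evaluate_imputation <- function(pool_set, imputations, parents) {
  parents <- .as_parent_table(parents)
  geno_par <- unclass(parents)
  ind_rows <- list()
  probs <- list()
  corrects <- list()
  for (i in seq_along(pool_set)) {
    pl <- pool_set[[i]]
    imp <- imputations[[i]]
    def <- pl$definition
    markers <- colnames(pl$genotypes)
    for (d in seq_len(nrow(def))) {
      poly <- geno_par[markers, def$parent1[d]] !=
              geno_par[markers, def$parent2[d]]
      if (!any(poly)) next
      truth <- pl$genotypes[d, poly]
      hard <- imp$dosages$hard_call[d, markers][poly]
      prob <- imp$dosages$call_prob[d, markers][poly]
      ok <- hard == truth
      ind_rows[[length(ind_rows) + 1L]] <- data.frame(
        individual = def$individual[d],
        pool = i,
        population = pl$populations[d],
        n_polymorphic = sum(poly),
        concordance = mean(ok) * 100,
        mean_call_prob = mean(prob),
        stringsAsFactors = FALSE)
      probs[[length(probs) + 1L]] <- prob
      corrects[[length(corrects) + 1L]] <- ok
    }
  }
  list(individuals = do.call(rbind, ind_rows),
       calls = data.frame(call_prob = unlist(probs),
                          correct = unlist(corrects)))
}

.as_parent_table <- function(parents) {
  if (inherits(parents, "parent_genotypes")) return(parents)
  parent_genotypes(t(parents))
}
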