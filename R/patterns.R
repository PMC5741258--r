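#' Enumerate the inheritance patterns of a pool
#'
#' An inheritance pattern assigns to every pooled individual the parent it
#' inherited from at a locus; these are the hidden states of the imputation
#' HMM. A pool of P members has 2^P patterns (4 for a two-way pool, 8 for a
#' three-way, 16 for a four-way). Patterns are ordered lexicographically
#' over members with each member's first-listed parent ranked first, so for
#' a two-way pool of (I1 x I2) and (I3 x I4) the order is I1-I3, I1-I4,
#' I2-I3, I2-I4.
#'
#' The prior over patterns (the initial forward vector) is the product of
#' the expected parental genome contributions: 1/2 per parent for F1-derived
#' DH, and 3/4 (recurrent) / 1/4 (donor) for BC1-derived DH.
#'
#' @param pool A [pool_definition()].
#' @return A list of class `pattern_space` with elements `origin` (S x P
#'   matrix over `{1, 2}`: which listed parent each member inherits from),
#'   `parent` (S x P matrix of parent ids), `labels`, `f0` (prior vector),
#'   and `pool`.
#' @export
enumerate_inheritance_patterns <- function(pool) {
  stopifnot(inherits(pool, "pool_definition"))
  n <- nrow(pool)
  if (n < 1L) stop("empty pool")
  # last member varies fastest => lexicographic order over members
  origin <- as.matrix(expand.grid(rev(rep(list(1:2), n)),
                                  KEEP.OUT.ATTRS = FALSE))[, n:1, drop = FALSE]
  dimnames(origin) <- list(NULL, pool$individual)
  parent <- origin
  storage.mode(parent) <- "character"
  for (d in seq_len(n))
    parent[, d] <- ifelse(origin[, d] == 1L, pool$parent1[d], pool$parent2[d])
  priors <- lapply(seq_len(n), function(d)
    if (pool$cross_type[d] == "BC1DH") c(0.75, 0.25) else c(0.5, 0.5))
  f0 <- as.numeric(Reduce(kronecker, priors))
  labels <- apply(parent, 1, paste, collapse = "-")
  structure(list(origin = origin, parent = parent, labels = labels,
                 f0 = f0, pool = pool),
            class = "pattern_space")
}

#' Per-member 2-state transition matrix
#'
#' Transition probabilities of one pooled individual's parent-of-origin
#' process between adjacent loci with recombination fraction `r`. States are
#' ordered as the listed parents. For an F1-derived DH a single meiosis
#' separates the DH from its parents, giving the symmetric matrix
#' `[[1-r, r], [r, 1-r]]`. For a BC1-derived DH (states: recurrent, donor)
#' the donor genome is only retained where both the backcross and the DH
#' meiosis transmit it, giving `P(D->D) = (1-r)^2` and, by stationarity of
#' the (3/4, 1/4) genome composition, `P(R->D) = r(2-r)/3`.
#'
#' @param cross_type `"F1DH"` or `"BC1DH"`.
#' @param r Recombination fraction in `[0, 0.5]`.
#' @return Row-stochastic 2x2 matrix (rows = state at previous locus).
#' @export
member_transition <- function(cross_type, r) {
  if (!is.finite(r) || r < 0 || r > 0.5)
    stop("recombination fraction must lie in [0, 0.5]")
  switch(cross_type,
    F1DH = matrix(c(1 - r, r, r, 1 - r), 2, 2, byrow = TRUE),
    BC1DH = {
      d_loss <- r * (2 - r)            # donor segment lost over two meioses
      matrix(c(1 - d_loss / 3, d_loss / 3,
               d_loss, (1 - r)^2), 2, 2, byrow = TRUE)
    },
    stop("unknown cross type: ", cross_type))
}

#' Transition matrix over inheritance patterns
#'
#' Members recombine independently, so the pattern-level transition matrix
#' is the Kronecker product of the per-member 2x2 matrices in member order
#' (consistent with the lexicographic pattern order of
#' [enumerate_inheritance_patterns()]).
#'
#' @param space A `pattern_space`.
#' @param r Recombination fraction between the previous and current locus.
#' @return Row-stochastic S x S matrix, S = number of patterns.
#' @export
build_transition_matrix <- function(space, r) {
  stopifnot(inherits(space, "pattern_space"))
  mats <- lapply(space$pool$cross_type, member_transition, r = r)
  Reduce(kronecker, mats)
}
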