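# Brute-force posterior by enumeration over all inheritance-pattern
# sequences: P(seq) = f0[s1] * prod_k T_k[s_{k-1}, s_k] * prod_k E_k[s_k],
# marginalised per locus. Independent of the forward-backward code path.
oracle_posterior <- function(f0, transitions, emissions) {
  M <- nrow(emissions)
  S <- ncol(emissions)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(S)), M),
                                KEEP.OUT.ATTRS = FALSE))
  p <- f0[seqs[, 1]] * emissions[cbind(1, seqs[, 1])]
  if (M > 1) {
    for (k in 2:M) {
      p <- p * transitions[[k]][cbind(seqs[, k - 1], seqs[, k])] *
        emissions[cbind(k, seqs[, k])]
    }
  }
  post <- matrix(0, M, S)
  for (k in seq_len(M))
    post[k, ] <- tapply(p, factor(seqs[, k], seq_len(S)), sum)
  post / rowSums(post)
}

# random HMM instance (pool, transitions, emissions) for oracle checks
random_hmm_instance <- function(max_members = 3, max_loci = 8,
                                max_states_seqs = 65536) {
  repeat {
    P <- sample.int(max_members, 1)
    M <- sample(2:max_loci, 1)
    if ((2^P)^M <= max_states_seqs) break
  }
  cross <- sample(c("F1DH", "BC1DH"), P, replace = TRUE)
  pool <- pool_definition(paste0("P", seq_len(P)), paste0("A", seq_len(P)),
                          paste0("B", seq_len(P)), cross_type = cross)
  space <- enumerate_inheritance_patterns(pool)
  S <- length(space$f0)
  emissions <- matrix(stats::runif(M * S), M, S)
  rvec <- stats::runif(M, 0, 0.5)
  transitions <- c(list(NULL), lapply(rvec[-1], function(r)
    build_transition_matrix(space, r)))
  oracle_transitions <- transitions
  oracle_transitions[[1]] <- diag(S)
  list(space = space, emissions = emissions, transitions = transitions,
       oracle_transitions = oracle_transitions)
}
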