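#' Forward pass of the inheritance-pattern HMM
#'
#' Runs the forward recursion `f_k = c_k^-1 (T_k' f_{k-1}) o E_k[m,]` over
#' one chromosome's loci in map order, with each forward vector normalised
#' to sum 1 (`c_k` is the normalisation constant). At the first locus the
#' prior `f0` is used directly (`f_1` proportional to `f0 o E_1`): `f0` is
#' the stationary distribution of every transition matrix, so prepending a
#' transition would leave it unchanged.
#'
#' @param transitions List of S x S transition matrices, one per locus;
#'   element 1 is ignored (identity convention). May be `NULL` entries for
#'   identity.
#' @param emissions M x S matrix of emission likelihood rows.
#' @param f0 Prior over patterns.
#' @return List with `f` (M x S matrix of normalised forward vectors) and
#'   `c` (normalisation constants).
#' @export
forward_pass <- function(transitions, emissions, f0) {
  M <- nrow(emissions)
  S <- ncol(emissions)
  f <- matrix(NA_real_, M, S, dimnames = dimnames(emissions))
  cc <- numeric(M)
  prev <- f0
  for (k in seq_len(M)) {
    pred <- if (k == 1L || is.null(transitions[[k]])) prev
            else as.numeric(crossprod(transitions[[k]], prev))
    v <- pred * emissions[k, ]
    cc[k] <- sum(v)
    if (!is.finite(cc[k]) || cc[k] <= 0)
      stop("observations impossible under every inheritance pattern at ",
           "locus '", rownames(emissions)[k], "'")
    prev <- v / cc[k]
    f[k, ] <- prev
  }
  list(f = f, c = cc)
}

#' Backward pass of the inheritance-pattern HMM
#'
#' Runs the backward recursion `b_k = a_k^-1 T_k (b_{k+1} o E_k[m,])` from
#' `k = M` down to 1, initialised with `b_{M+1}` a vector of ones and with
#' each backward vector normalised by `a_k`. With this indexing `b_{k+1}`
#' carries the evidence of loci `k+1..M` conditional on the state at locus
#' `k`, which is the factor the posterior combines with `f_k`.
#'
#' @inheritParams forward_pass
#' @return List with `b` ((M+1) x S matrix, row M+1 = ones) and `a`
#'   (normalisation constants, length M).
#' @export
backward_pass <- function(transitions, emissions) {
  M <- nrow(emissions)
  S <- ncol(emissions)
  b <- matrix(NA_real_, M + 1L, S)
  a <- numeric(M)
  b[M + 1L, ] <- 1
  for (k in rev(seq_len(M))) {
    v <- b[k + 1L, ] * emissions[k, ]
    if (!(k == 1L || is.null(transitions[[k]])))
      v <- as.numeric(transitions[[k]] %*% v)
    a[k] <- sum(v)
    if (!is.finite(a[k]) || a[k] <= 0)
      stop("observations impossible under every inheritance pattern at ",
           "locus '", rownames(emissions)[k], "'")
    b[k, ] <- v / a[k]
  }
  list(b = b, a = a)
}

#' Posterior inheritance probabilities
#'
#' Combines forward and backward quantities: `p_k` is proportional to
#' `f_k o b_{k+1}`, normalised to sum 1 per locus.
#'
#' @param f M x S forward matrix from [forward_pass()].
#' @param b (M+1) x S backward matrix from [backward_pass()].
#' @return M x S posterior matrix (rows sum to 1).
#' @export
posterior_inheritance <- function(f, b) {
  M <- nrow(f)
  if (nrow(b) != M + 1L || ncol(b) != ncol(f))
    stop("dimension mismatch between forward and backward matrices")
  p <- f * b[-1L, , drop = FALSE]
  p <- p / rowSums(p)
  dimnames(p) <- dimnames(f)
  p
}
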