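#' GBS cost constants
#'
#' Per-sample genotyping cost (USD, 3,000 loci) at the supported coverage
#' levels, and the per-individual cost of high-quality (HQ) individual
#' genotyping. Pooling divides the per-sample cost by the number of pooled
#' individuals (the pooling step itself is assumed free).
#'
#' @param x Targeted coverage; one of 0.125, 0.25, 0.5, 1, 2, 4.
#' @param n_pooled Number of individuals in the pool (1 = single-sample).
#' @return Cost per individual in dollars.
#' @export
gbs_cost <- function(x, n_pooled = 1) {
  tab <- c("4" = 6.20, "2" = 5.60, "1" = 5.30,
           "0.5" = 5.15, "0.25" = 5.08, "0.125" = 5.04)
  key <- as.character(x)
  if (!key %in% names(tab))
    stop("no cost constant for coverage x = ", x,
         "; supported: ", paste(names(tab), collapse = ", "))
  stopifnot(n_pooled >= 1)
  tab[[key]] / n_pooled
}

#' @rdname gbs_cost
#' @export
hq_cost <- function() 8.00

#' Selection intensity of truncation selection
#'
#' The standardised selection differential when the best fraction `s` of a
#' Normal distribution is selected: `i = phi(Phi^-1(1 - s)) / s`.
#'
#' @param s Selected fraction in (0, 1].
#' @return Selection intensity (0 when everything is selected).
#' @export
selection_intensity <- function(s) {
  if (any(s <= 0) || any(s > 1)) stop("selected fraction must be in (0, 1]")
  stats::dnorm(stats::qnorm(1 - s)) / s
}

#' Selected fraction achievable with cheaper genotyping
#'
#' With a fixed genotyping budget and a fixed number of individuals to
#' select, cheaper genotyping lets more candidates be genotyped, shrinking
#' the selected fraction: `s_PG = s_HQ * C_PG / C_HQ`. Ratios above 1
#' (costlier genotyping) are clipped to 1 with a warning.
#'
#' @param s_HQ Selected fraction under HQ genotyping, in (0, 1].
#' @param C_PG,C_HQ Per-individual genotyping costs.
#' @return Selected fraction under pooled genotyping.
#' @export
scaled_selected_fraction <- function(s_HQ, C_PG, C_HQ) {
  stopifnot(s_HQ > 0, s_HQ <= 1, C_PG > 0, C_HQ > 0)
  s <- s_HQ * C_PG / C_HQ
  if (s > 1) {
    warning("cost ratio pushes selected fraction above 1; clipping")
    s <- 1
  }
  s
}

#' Relative merit of pooled over high-quality genotyping
#'
#' Viewing whole-genome selection as indirect selection, the response with
#' pooled genotyping relative to HQ genotyping is `(i_PG * h_PG) / i_HQ`:
#' the cheaper assay raises the selection intensity (more candidates per
#' dollar) while the GEBV concordance `h_PG` (the accuracy with which
#' PG-GEBV track HQ-GEBV) discounts it. Values above 1 favour pooling.
#'
#' @param s_HQ Selected fraction under HQ genotyping.
#' @param C_HQ,C_PG Per-individual genotyping costs (see [gbs_cost()]).
#' @param h_PG GEBV concordance in [0, 1].
#' @return List with `ratio`, `i_HQ`, `i_PG`, `s_PG`.
#' @export
relative_merit <- function(s_HQ, C_HQ, C_PG, h_PG) {
  stopifnot(h_PG >= 0, h_PG <= 1)
  s_PG <- scaled_selected_fraction(s_HQ, C_PG, C_HQ)
  i_HQ <- selection_intensity(s_HQ)
  i_PG <- selection_intensity(s_PG)
  ratio <- if (i_HQ == 0) {
    if (h_PG == 0) 0 else Inf  # selecting everyone under HQ: any gain wins
  } else i_PG * h_PG / i_HQ
  list(ratio = ratio, i_HQ = i_HQ, i_PG = i_PG, s_PG = s_PG)
}
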