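#' Construct a genetic map
#'
#' A genetic map lists biallelic markers with their chromosome and genetic
#' position in centimorgans. Markers are sorted by chromosome and position;
#' ties in position are kept in input order.
#'
#' @param marker Character vector of unique marker identifiers.
#' @param chrom Chromosome identifier per marker (coerced to character).
#' @param pos_cM Non-negative genetic position in centimorgans.
#' @param chr_lengths Optional named numeric vector of chromosome lengths in
#'   cM (used by the meiosis simulator; defaults to the maximum marker
#'   position per chromosome).
#'
#' @return A `data.frame` of class `genetic_map` with columns `marker`,
#'   `chrom`, `pos_cM`, and attribute `chr_lengths`.
#' @export
genetic_map <- function(marker, chrom, pos_cM, chr_lengths = NULL) {
  marker <- as.character(marker)
  chrom <- rep_len(as.character(chrom), length(marker))
  pos_cM <- as.numeric(pos_cM)
  if (length(marker) != length(chrom) || length(marker) != length(pos_cM))
    stop("marker, chrom and pos_cM must have equal length")
  if (anyDuplicated(marker))
    stop("duplicate marker identifiers: ",
         paste(unique(marker[duplicated(marker)]), collapse = ", "))
  if (any(!is.finite(pos_cM)) || any(pos_cM < 0))
    stop("map positions must be finite and non-negative")
  ord <- order(factor(chrom, levels = unique(chrom)), pos_cM)
  map <- data.frame(marker = marker[ord], chrom = chrom[ord],
                    pos_cM = pos_cM[ord], stringsAsFactors = FALSE)
  if (is.null(chr_lengths)) {
    chr_lengths <- tapply(map$pos_cM, factor(map$chrom, unique(map$chrom)), max)
    chr_lengths <- stats::setNames(as.numeric(chr_lengths),
                                   names(chr_lengths))
  } else {
    if (is.null(names(chr_lengths)) ||
        !all(unique(map$chrom) %in% names(chr_lengths)))
      stop("chr_lengths must be named with every chromosome in the map")
  }
  attr(map, "chr_lengths") <- chr_lengths
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Recombination fraction from map distance
#'
#' Inverse Haldane mapping function, `r = (1 - exp(-2 d / 100)) / 2` for a
#' distance `d` in centimorgans. This matches the no-interference (Poisson
#' crossover) meiosis model used throughout the package.
#'
#' @param distance_cM Non-negative map distance(s) in centimorgans.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @examples
#' recombination_fraction(10) # ~0.0906
#' @export
recombination_fraction <- function(distance_cM) {
  if (any(!is.finite(distance_cM)) || any(distance_cM < 0))
    stop("map distance must be finite and non-negative")
  0.5 * (1 - exp(-2 * distance_cM / 100))
}
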