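#' Construct a parent genotype table
#'
#' Parents are fully homozygous inbred lines, so genotypes are coded as the
#' dosage of a chosen reference allele: 0 (homozygous alternate) or 2
#' (homozygous reference). Every marker must be scored for every parent.
#'
#' @param genotypes Numeric matrix, markers in rows (rownames = marker ids),
#'   parents in columns (colnames = parent ids), entries in `{0, 2}`.
#' @return A matrix of class `parent_genotypes`.
#' @export
parent_genotypes <- function(genotypes) {
  genotypes <- as.matrix(genotypes)
  if (is.null(rownames(genotypes)) || is.null(colnames(genotypes)))
    stop("parent genotype matrix needs marker rownames and parent colnames")
  storage.mode(genotypes) <- "double"
  bad <- which(is.na(genotypes) | !(genotypes %in% c(0, 2)))
  if (length(bad)) {
    idx <- arrayInd(bad[1], dim(genotypes))
    stop("parent genotypes must be homozygous dosages 0 or 2; first offender: ",
         "parent '", colnames(genotypes)[idx[2]], "' at marker '",
         rownames(genotypes)[idx[1]], "'")
  }
  class(genotypes) <- c("parent_genotypes", class(genotypes))
  genotypes
}

#' Define a pool of doubled-haploid individuals
#'
#' Describes which DH individuals were pooled into one non-barcoded DNA
#' sample, the parent pair of each individual's biparental population, the
#' cross type, and (optionally) prior DNA fractions. For `BC1DH` members the
#' parents must be given as (recurrent, donor).
#'
#' @param individual Character vector of member ids (pool order matters).
#' @param parent1,parent2 Parent ids per member (first- and second-listed
#'   parent; recurrent and donor for BC1-derived DH).
#' @param cross_type `"F1DH"` or `"BC1DH"`, recycled.
#' @param dna_fraction Optional prior DNA fractions, positive and summing to
#'   1; `NULL` means unknown (estimated from data or assumed equal).
#' @return A `data.frame` of class `pool_definition`.
#' @export
pool_definition <- function(individual, parent1, parent2,
                            cross_type = "F1DH", dna_fraction = NULL) {
  individual <- as.character(individual)
  if (length(individual) < 1L) stop("a pool needs at least one member")
  if (anyDuplicated(individual)) stop("duplicate individual ids in pool")
  cross_type <- rep_len(as.character(cross_type), length(individual))
  if (!all(cross_type %in% c("F1DH", "BC1DH")))
    stop("cross_type must be 'F1DH' or 'BC1DH'")
  if (!is.null(dna_fraction)) {
    dna_fraction <- as.numeric(dna_fraction)
    if (length(dna_fraction) != length(individual) ||
        any(dna_fraction <= 0) || abs(sum(dna_fraction) - 1) > 1e-9)
      stop("dna_fraction must be positive per member and sum to 1")
  }
  pool <- data.frame(individual = individual,
                     parent1 = as.character(parent1),
                     parent2 = as.character(parent2),
                     cross_type = cross_type,
                     dna_fraction = if (is.null(dna_fraction)) NA_real_
                                    else dna_fraction,
                     stringsAsFactors = FALSE)
  class(pool) <- c("pool_definition", "data.frame")
  pool
}

#' Pool observations: allele read counts or categorical calls
#'
#' Read-count observations record, per marker, the number of reads of the
#' reference allele (`ref_reads`) out of all reads (`total_reads`); a total
#' of zero means the locus is missing. Categorical observations record a
#' pool genotype call: `homogeneous_ref`, `homogeneous_alt`, `heterogeneous`
#' or `missing` (homogeneous/heterogeneous describe the pool, not an
#' individual's zygosity).
#'
#' @param marker Marker identifiers.
#' @param ref_reads,total_reads Integer read counts (counts mode).
#' @param call Categorical calls (categorical mode); give either counts or
#'   calls, not both.
#' @return A `data.frame` of class `pool_observations` with attribute
#'   `obs_type` (`"counts"` or `"categorical"`).
#' @export
pool_observations <- function(marker, ref_reads = NULL, total_reads = NULL,
                              call = NULL) {
  marker <- as.character(marker)
  if (anyDuplicated(marker)) stop("duplicate markers in observations")
  if (!is.null(call)) {
    if (!is.null(ref_reads) || !is.null(total_reads))
      stop("give either read counts or categorical calls, not both")
    call <- as.character(call)
    call[is.na(call)] <- "missing"
    ok <- c("homogeneous_ref", "homogeneous_alt", "heterogeneous", "missing")
    if (!all(call %in% ok))
      stop("categorical calls must be one of: ", paste(ok, collapse = ", "))
    obs <- data.frame(marker = marker, call = call, stringsAsFactors = FALSE)
    attr(obs, "obs_type") <- "categorical"
  } else {
    ref_reads <- as.integer(ref_reads)
    total_reads <- as.integer(total_reads)
    ref_reads[is.na(ref_reads)] <- 0L
    total_reads[is.na(total_reads)] <- 0L
    if (any(ref_reads < 0) || any(total_reads < 0))
      stop("read counts must be non-negative")
    if (any(ref_reads > total_reads))
      stop("ref_reads exceeds total_reads at marker(s): ",
           paste(utils::head(marker[ref_reads > total_reads], 5),
                 collapse = ", "))
    obs <- data.frame(marker = marker, ref_reads = ref_reads,
                      total_reads = total_reads, stringsAsFactors = FALSE)
    attr(obs, "obs_type") <- "counts"
  }
  class(obs) <- c("pool_observations", "data.frame")
  obs
}
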