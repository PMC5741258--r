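#' Read a genetic map from TSV
#'
#' Expects tab-separated columns `marker`, `chrom`, `pos_cM`.
#'
#' @param path File path.
#' @return A [genetic_map()].
#' @export
read_genetic_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("marker", "chrom", "pos_cM")
  if (!all(need %in% names(df)))
    stop("map file needs columns: ", paste(need, collapse = ", "))
  genetic_map(df$marker, df$chrom, df$pos_cM)
}

#' @rdname read_genetic_map
#' @param map A [genetic_map()] to write.
#' @export
write_genetic_map <- function(map, path) {
  utils::write.table(as.data.frame(map)[c("marker", "chrom", "pos_cM")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read parent genotypes
#'
#' TSV format: one row per marker, first column `marker`, one column per
#' parent, cells the reference-allele dosage 0 or 2. VCF format: one sample
#' per parent with homozygous GT calls; the VCF REF allele is taken as the
#' reference allele (dosage 2 for `0/0`, 0 for `1/1`); heterozygous or
#' missing parent calls are an error since imputation requires complete
#' homozygous parent genotypes.
#'
#' @param path File path.
#' @param format `"tsv"` or `"vcf"`.
#' @return A [parent_genotypes()] table.
#' @export
read_parent_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
    if (names(df)[1] != "marker")
      stop("first column of a parent genotype TSV must be 'marker'")
    mat <- as.matrix(df[-1])
    rownames(mat) <- df$marker
    return(parent_genotypes(mat))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  markers <- rownames(gt)
  if (is.null(markers) || anyNA(markers))
    stop("VCF records need ID fields to serve as marker names")
  dosage <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dosage[clean %in% c("0/0", "0")] <- 2
  dosage[clean %in% c("1/1", "1")] <- 0
  if (anyNA(dosage)) {
    idx <- which(is.na(dosage), arr.ind = TRUE)[1, ]
    stop("parent '", colnames(gt)[idx[2]], "' has a heterozygous or ",
         "missing call at marker '", rownames(gt)[idx[1]],
         "'; parents must be complete homozygous lines")
  }
  parent_genotypes(dosage)
}

#' @rdname read_parent_genotypes
#' @param parents A [parent_genotypes()] table to write (TSV).
#' @export
write_parent_genotypes <- function(parents, path) {
  df <- data.frame(marker = rownames(parents),
                   unclass(parents)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read pool observations
#'
#' TSV format: columns `marker`, `ref_reads`, `total_reads` (read counts)
#' or `marker`, `call` (categorical). VCF format: the `AD` field of the
#' given pool sample; the first AD entry (the REF depth) is the
#' reference-allele count and the sum of the first two entries the total.
#'
#' @param path File path.
#' @param format `"tsv"` or `"vcf"`.
#' @param sample Sample name for VCF input (default: first sample).
#' @return A [pool_observations()] table.
#' @export
read_observations <- function(path, format = c("tsv", "vcf"),
                              sample = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    if ("call" %in% names(df))
      return(pool_observations(df$marker, call = df$call))
    if (!all(c("marker", "ref_reads", "total_reads") %in% names(df)))
      stop("observation TSV needs columns marker, ref_reads, total_reads ",
           "(or marker, call)")
    return(pool_observations(df$marker, ref_reads = df$ref_reads,
                             total_reads = df$total_reads))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(sample)) sample <- colnames(ad)[1]
  if (!sample %in% colnames(ad))
    stop("sample '", sample, "' not in VCF")
  vals <- ad[, sample]
  split_ad <- strsplit(ifelse(is.na(vals), "0,0", vals), ",")
  m <- vapply(split_ad, function(z) as.integer(z[1]), 0L)
  n <- m + vapply(split_ad, function(z)
    if (length(z) >= 2) as.integer(z[2]) else 0L, 0L)
  pool_observations(rownames(ad), ref_reads = m, total_reads = n)
}

#' @rdname read_observations
#' @param observations A [pool_observations()] table to write (TSV).
#' @export
write_observations <- function(observations, path) {
  utils::write.table(as.data.frame(observations), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pool definition from TSV
#'
#' Columns: `individual`, `parent1`, `parent2`, `cross_type`, and
#' optionally `dna_fraction`.
#'
#' @param path File path.
#' @return A [pool_definition()].
#' @export
read_pool_definition <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  frac <- if ("dna_fraction" %in% names(df) && !anyNA(df$dna_fraction))
    df$dna_fraction else NULL
  pool_definition(df$individual, df$parent1, df$parent2,
                  cross_type = df$cross_type, dna_fraction = frac)
}

#' Write imputed dosages to TSV
#'
#' Long format with columns `individual`, `marker`, `dosage`, `hard_call`,
#' `call_prob`; dosages and probabilities are serialised with 6 decimals,
#' at which precision write/read round-trips are lossless.
#'
#' @param dosages A `dosage_table` (or its long `data.frame`).
#' @param path File path.
#' @export
write_dosages <- function(dosages, path) {
  df <- if (inherits(dosages, "dosage_table")) as.data.frame(dosages)
        else dosages
  df$dosage <- sprintf("%.6f", df$dosage)
  df$call_prob <- sprintf("%.6f", df$call_prob)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosages
#' @return `read_dosages()`: a long `data.frame`.
#' @export
read_dosages <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "numeric",
                                   "numeric", "numeric"))
}

#' Write posterior inheritance probabilities to TSV
#'
#' One row per retained marker, one column per inheritance pattern.
#'
#' @param posterior Markers x patterns matrix.
#' @param path File path.
#' @export
write_posterior <- function(posterior, path) {
  df <- data.frame(marker = rownames(posterior), posterior,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the seed and parameters of a run as YAML so any output can be
#' reproduced from its manifest.
#'
#' @param manifest Named list of parameters (include the seed).
#' @param path File path.
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) yaml::read_yaml(path)
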