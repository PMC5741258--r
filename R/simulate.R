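#' Configuration for a synthetic founder panel
#'
#' The synthetic panel emulates the frequency structure of an applied
#' breeding panel split into differentiated germplasm (heterotic) groups: a
#' panel-level allele frequency per locus is drawn from a symmetric Beta,
#' and group-specific frequencies around it from a Balding-Nichols-style
#' divergence model. The defaults put ~3,000 markers on a maize-like genome
#' of 10 chromosomes of 160 cM each, with divergence tuned so that two-way
#' pools show multi-polymorphism rates near 37% within a group and 22%
#' across groups.
#'
#' @param lines Named integer vector: inbred lines per germplasm group.
#' @param n_markers Total marker count.
#' @param n_chr Number of chromosomes.
#' @param chr_length Chromosome length(s) in cM (recycled to `n_chr`).
#' @param beta_shape Shape of the symmetric Beta for panel frequencies.
#' @param divergence Balding-Nichols divergence parameter in (0, 1); 0 means
#'   exchangeable groups.
#' @return A list of class `founder_config`.
#' @export
founder_config <- function(lines = c(A = 120, B = 90), n_markers = 3000,
                           n_chr = 10, chr_length = 160,
                           beta_shape = 2, divergence = 0.48) {
  stopifnot(all(lines > 0), n_markers > 0, n_chr > 0, all(chr_length > 0),
            beta_shape > 0, divergence >= 0, divergence < 1)
  if (is.null(names(lines))) names(lines) <- LETTERS[seq_along(lines)]
  structure(list(lines = lines, n_markers = as.integer(n_markers),
                 n_chr = as.integer(n_chr),
                 chr_length = rep_len(chr_length, n_chr),
                 beta_shape = beta_shape, divergence = divergence),
            class = "founder_config")
}

#' Generate a synthetic founder panel and its genetic map
#'
#' Draws homozygous inbred lines per germplasm group under the frequency
#' model of [founder_config()]. Marker positions are uniform along each
#' chromosome. The reference allele at each marker is set to the panel-wide
#' major allele, so reference-allele frequencies are at least 0.5.
#'
#' @param config A [founder_config()].
#' @param seed Optional integer seed.
#' @return A list of class `founder_panel` with `genotypes` (lines x
#'   markers dosage matrix, entries 0/2), `group` (factor per line), `map`
#'   (a [genetic_map()]), and `config`.
#' @export
generate_founders <- function(config = founder_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  M <- config$n_markers
  per_chr <- diff(round(seq(0, M, length.out = config$n_chr + 1L)))
  chrom <- rep(sprintf("chr%02d", seq_len(config$n_chr)), per_chr)
  pos <- unlist(lapply(seq_len(config$n_chr), function(i)
    sort(stats::runif(per_chr[i], 0, config$chr_length[i]))))
  markers <- sprintf("M%05d", seq_len(M))
  chr_lengths <- stats::setNames(config$chr_length,
                                 sprintf("chr%02d", seq_len(config$n_chr)))
  map <- genetic_map(markers, chrom, pos, chr_lengths = chr_lengths)

  p <- stats::rbeta(M, config$beta_shape, config$beta_shape)
  FF <- config$divergence
  n_lines <- sum(config$lines)
  group <- factor(rep(names(config$lines), config$lines),
                  levels = names(config$lines))
  geno <- matrix(0, n_lines, M)
  offset <- 0L
  for (g in names(config$lines)) {
    q <- if (FF > 0) stats::rbeta(M, p * (1 - FF) / FF,
                                  (1 - p) * (1 - FF) / FF)
         else p
    ng <- config$lines[[g]]
    geno[offset + seq_len(ng), ] <-
      2 * matrix(stats::rbinom(ng * M, 1, rep(q, each = ng)), ng, M)
    offset <- offset + ng
  }
  # orient to the panel-wide major allele
  flip <- colMeans(geno) / 2 < 0.5
  geno[, flip] <- 2 - geno[, flip]
  line_ids <- paste0(group, sprintf("%03d", stats::ave(seq_len(n_lines),
                                                       group, FUN = seq_along)))
  dimnames(geno) <- list(line_ids, markers)
  # keep genotype columns in map (= position) order
  geno <- geno[, map$marker, drop = FALSE]
  structure(list(genotypes = geno, group = stats::setNames(group, line_ids),
                 map = map, config = config),
            class = "founder_panel")
}

# one set of gametes from a pair of haplotypes (values 0/1 allele dose),
# Haldane meiosis: Poisson crossover count, uniform positions, fair-coin
# start. Returns n x M matrix of allele doses.
.simulate_gametes <- function(hap1, hap2, map, n) {
  M <- length(hap1)
  out <- matrix(NA_real_, n, M)
  chr_lengths <- attr(map, "chr_lengths")
  for (ch in unique(map$chrom)) {
    cols <- which(map$chrom == ch)
    pos <- map$pos_cM[cols]
    L <- chr_lengths[[ch]]
    for (i in seq_len(n)) {
      n_co <- stats::rpois(1L, L / 100)
      phase <- rep(stats::rbinom(1L, 1L, 0.5), length(pos))
      if (n_co > 0L) {
        co <- sort(stats::runif(n_co, 0, L))
        phase <- (phase + findInterval(pos, co)) %% 2L
      }
      out[i, cols] <- ifelse(phase == 0L, hap1[cols], hap2[cols])
    }
  }
  out
}

#' Simulate doubled-haploid progeny of a biparental cross
#'
#' Each DH line is one recombinant gamete followed by chromosome doubling.
#' Meiosis follows the Haldane model: crossover counts are Poisson with
#' mean equal to the chromosome length in Morgans (no interference),
#' crossover positions uniform, and the starting haplotype a fair coin.
#' For `BC1DH`, a backcross meiosis (F1 gamete paired with the recurrent
#' parent) precedes the DH meiosis, so the donor genome is retained in
#' about one quarter of the genome.
#'
#' @param parent1,parent2 Homozygous parent dosage vectors (0/2) in map
#'   order; for `BC1DH`, `parent1` is the recurrent parent.
#' @param map A [genetic_map()].
#' @param n_progeny Number of DH lines to simulate.
#' @param cross_type `"F1DH"` or `"BC1DH"`.
#' @param seed Optional integer seed.
#' @return `n_progeny` x markers dosage matrix (entries 0/2).
#' @export
simulate_dh <- function(parent1, parent2, map, n_progeny,
                        cross_type = c("F1DH", "BC1DH"), seed = NULL) {
  cross_type <- match.arg(cross_type)
  if (!is.null(seed)) set.seed(seed)
  h1 <- as.numeric(parent1) / 2
  h2 <- as.numeric(parent2) / 2
  if (cross_type == "F1DH") {
    gam <- .simulate_gametes(h1, h2, map, n_progeny)
  } else {
    gam <- matrix(NA_real_, n_progeny, length(h1))
    for (i in seq_len(n_progeny)) {
      f1_gamete <- .simulate_gametes(h1, h2, map, 1L)[1, ]
      gam[i, ] <- .simulate_gametes(h1, f1_gamete, map, 1L)[1, ]
    }
  }
  colnames(gam) <- map$marker
  2 * gam
}

#' Simulate a set of biparental DH populations from a founder panel
#'
#' Draws parents at random from one germplasm group (each line parenting at
#' most one population) and simulates DH progeny for each cross.
#'
#' @param panel A [generate_founders()] result.
#' @param n_pops Number of populations.
#' @param n_progeny DH lines per population.
#' @param group Germplasm group to draw parents from.
#' @param cross_type Cross type for all populations.
#' @param seed Optional integer seed.
#' @return List of populations; each has `id`, `parents` (character 2),
#'   `group`, `cross_type` and `genotypes` (progeny x markers, rownames =
#'   individual ids).
#' @export
simulate_populations <- function(panel, n_pops, n_progeny = 25,
                                 group = levels(panel$group)[1],
                                 cross_type = "F1DH", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lines <- names(panel$group)[panel$group == group]
  if (length(lines) < 2 * n_pops)
    stop("not enough lines in group '", group, "' for ", n_pops,
         " populations")
  picked <- sample(lines, 2 * n_pops)
  lapply(seq_len(n_pops), function(i) {
    pr <- picked[c(2 * i - 1, 2 * i)]
    geno <- simulate_dh(panel$genotypes[pr[1], ], panel$genotypes[pr[2], ],
                        panel$map, n_progeny, cross_type)
    id <- sprintf("%s_P%03d", group, i)
    rownames(geno) <- sprintf("%s_D%02d", id, seq_len(n_progeny))
    list(id = id, parents = pr, group = group, cross_type = cross_type,
         genotypes = geno)
  })
}

#' Polygenic trait model
#'
#' @param n_causal Number of causal loci (sampled from the available loci
#'   and excluded from the marker set used for imputation).
#' @param h2 Narrow-sense heritability of the phenotype.
#' @return A list of class `trait_model`.
#' @export
trait_model <- function(n_causal = 200, h2 = 0.5) {
  stopifnot(n_causal >= 0, h2 > 0, h2 <= 1)
  structure(list(n_causal = as.integer(n_causal), h2 = h2),
            class = "trait_model")
}

#' Assign a polygenic trait to simulated individuals
#'
#' Samples causal loci, draws additive substitution effects from a standard
#' Normal, computes genetic values as the effect-weighted sum of causal
#' dosages, and adds Normal noise scaled so the realised heritability
#' equals `h2` exactly in the sample.
#'
#' @param genotypes Individuals x loci dosage matrix (all loci, causal
#'   candidates included).
#' @param model A [trait_model()].
#' @param seed Optional integer seed.
#' @return List with `causal` (locus names), `effects`, `genetic_value`,
#'   `phenotype` and `marker_loci` (the loci left for genotyping).
#' @export
assign_trait <- function(genotypes, model = trait_model(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  loci <- colnames(genotypes)
  causal <- sample(loci, model$n_causal)
  effects <- stats::setNames(stats::rnorm(model$n_causal), causal)
  g <- as.numeric(genotypes[, causal, drop = FALSE] %*% effects)
  if (model$h2 == 1 || stats::sd(g) == 0) {
    e <- numeric(length(g))
  } else {
    e <- stats::rnorm(length(g))
    e <- e / stats::sd(e) * stats::sd(g) *
      sqrt((1 - model$h2) / model$h2)
  }
  list(causal = causal, effects = effects,
       genetic_value = stats::setNames(g, rownames(genotypes)),
       phenotype = stats::setNames(g + e, rownames(genotypes)),
       marker_loci = setdiff(loci, causal))
}

#' Build pools of DH individuals from simulated populations
#'
#' Populations are combined on a by-population basis: population sets are
#' drawn at random subject to the strategy, and individuals are paired at
#' random within the paired populations so that every individual appears in
#' exactly one pool. Within-group pools combine populations of the same
#' germplasm group; across-group pools mix groups (two-way: one from each;
#' three-way: two from the first group, one from the second; four-way: two
#' from each).
#'
#' @param populations List of populations from [simulate_populations()].
#' @param size Pool size: 2, 3 or 4.
#' @param arrangement `"within"` or `"across"` germplasm groups.
#' @param seed Optional integer seed.
#' @return List of class `pool_set`; each element has `definition` (a
#'   [pool_definition()]), `genotypes` (members x markers true dosages) and
#'   `populations` (ids).
#' @export
build_pools <- function(populations, size = 2,
                        arrangement = c("within", "across"), seed = NULL) {
  arrangement <- match.arg(arrangement)
  stopifnot(size %in% 2:4)
  if (!is.null(seed)) set.seed(seed)
  groups <- vapply(populations, `[[`, "", "group")
  sets <- list()
  if (arrangement == "within") {
    for (g in unique(groups)) {
      idx <- sample(which(groups == g))
      n_sets <- length(idx) %/% size
      if (n_sets)
        sets <- c(sets, lapply(seq_len(n_sets), function(i)
          idx[(i - 1) * size + seq_len(size)]))
    }
    if (!length(sets))
      stop("not enough populations in any group for pool size ", size)
  } else {
    gl <- unique(groups)
    if (length(gl) < 2) stop("across-group pooling needs two groups")
    comp <- switch(as.character(size), "2" = c(1, 1), "3" = c(2, 1),
                   "4" = c(2, 2))
    a <- sample(which(groups == gl[1]))
    b <- sample(which(groups == gl[2]))
    n_sets <- min(length(a) %/% comp[1], length(b) %/% comp[2])
    if (!n_sets) stop("not enough populations for across-group pooling")
    sets <- lapply(seq_len(n_sets), function(i)
      c(a[(i - 1) * comp[1] + seq_len(comp[1])],
        b[(i - 1) * comp[2] + seq_len(comp[2])]))
  }
  pools <- list()
  for (set in sets) {
    pops <- populations[set]
    n_ind <- vapply(pops, function(p) nrow(p$genotypes), 0L)
    if (length(unique(n_ind)) != 1)
      stop("pooled populations must have equal size")
    perms <- lapply(pops, function(p) sample(rownames(p$genotypes)))
    for (i in seq_len(n_ind[1])) {
      members <- vapply(perms, `[`, "", i)
      geno <- do.call(rbind, lapply(seq_along(pops), function(j)
        pops[[j]]$genotypes[members[j], , drop = FALSE]))
      def <- pool_definition(
        individual = members,
        parent1 = vapply(pops, function(p) p$parents[1], ""),
        parent2 = vapply(pops, function(p) p$parents[2], ""),
        cross_type = vapply(pops, `[[`, "", "cross_type"))
      pools[[length(pools) + 1L]] <-
        list(definition = def, genotypes = geno,
             populations = vapply(pops, `[[`, "", "id"))
    }
  }
  structure(pools, class = "pool_set")
}

#' GBS simulation configuration
#'
#' @param x Targeted sequencing coverage multiplier (> 0, or 0 for the
#'   degenerate all-missing case).
#' @param concentration Dirichlet concentration for DNA contributions;
#'   default 50/29/18 for pool sizes 2/3/4 (giving a standard deviation of
#'   about 0.05 per contribution), and for other sizes the value implying
#'   the same 0.05 standard deviation.
#' @param gamma_shape,gamma_rate Parameters of the per-marker
#'   sequenceability distribution (mean `shape/rate`; the defaults 4, 4
#'   give mean 1).
#' @param shared_seq If `TRUE` (default) the sequenceability draw is shared
#'   by all pools, mirroring a shared library/flow-cell effect; `FALSE`
#'   redraws per pool.
#' @return A list of class `gbs_config`.
#' @export
gbs_config <- function(x, concentration = NULL, gamma_shape = 4,
                       gamma_rate = 4, shared_seq = TRUE) {
  stopifnot(x >= 0, gamma_shape > 0, gamma_rate > 0)
  if (!is.null(concentration)) stopifnot(concentration > 0)
  structure(list(x = x, concentration = concentration,
                 gamma_shape = gamma_shape, gamma_rate = gamma_rate,
                 shared_seq = shared_seq),
            class = "gbs_config")
}

.default_concentration <- function(P) {
  std <- c("2" = 50, "3" = 29, "4" = 18)
  if (as.character(P) %in% names(std)) return(std[[as.character(P)]])
  # concentration giving sd ~0.05 per Dirichlet component
  ((P - 1) / P^2 / 0.05^2 - 1) / P
}

.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Simulate pooled GBS read counts
#'
#' For each pool: DNA contributions are one Dirichlet draw; per marker the
#' total read count is Poisson with mean `x * seq_k` (`seq_k` the Gamma
#' sequenceability of the marker), and the reference-allele read count is
#' Binomial with success probability equal to the summed contributions of
#' the members carrying the reference genotype.
#'
#' @param pool_set A [build_pools()] result.
#' @param config A [gbs_config()].
#' @param seed Optional integer seed.
#' @return A list of class `gbs_experiment` with `seq` (sequenceability per
#'   marker, or `NULL` if redrawn per pool) and `pools`, a list of
#'   `observations` (a [pool_observations()]) and `fractions` (the true
#'   Dirichlet DNA contributions).
#' @export
simulate_gbs <- function(pool_set, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  markers <- colnames(pool_set[[1]]$genotypes)
  M <- length(markers)
  seq_shared <- if (config$shared_seq)
    stats::rgamma(M, config$gamma_shape, config$gamma_rate) else NULL
  pools <- lapply(pool_set, function(pl) {
    P <- nrow(pl$genotypes)
    conc <- if (is.null(config$concentration)) .default_concentration(P)
            else config$concentration
    d <- .rdirichlet(rep(conc, P))
    seq_k <- if (config$shared_seq) seq_shared
             else stats::rgamma(M, config$gamma_shape, config$gamma_rate)
    n <- stats::rpois(M, config$x * seq_k)
    p_ref <- pmin(pmax(as.numeric(d %*% (pl$genotypes == 2)), 0), 1)
    m <- stats::rbinom(M, n, p_ref)
    list(observations = pool_observations(markers, ref_reads = m,
                                          total_reads = n),
         fractions = d)
  })
  structure(list(seq = seq_shared, pools = pools), class = "gbs_experiment")
}

#' Empirical read-depth profile
#'
#' Summarises the Gamma-Poisson distribution of per-locus read counts at a
#' targeted coverage `x`: per-locus depth is Poisson with mean `x * seq_k`
#' where `seq_k ~ Gamma(shape, rate)` (mean 1 by default), so the marginal
#' mean depth is `x` and the missing fraction at `x = 1` is about 0.41.
#'
#' @param x Targeted coverage.
#' @param n_loci Number of simulated loci.
#' @param config A [gbs_config()] supplying the sequenceability shape/rate
#'   (its own `x` is ignored).
#' @param seed Optional integer seed.
#' @return List with `mean_depth`, `frac_missing`, and `depth_table` (a
#'   proportion table of read counts).
#' @export
read_depth_profile <- function(x, n_loci = 1e5, config = gbs_config(x),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seq_k <- stats::rgamma(n_loci, config$gamma_shape, config$gamma_rate)
  n <- stats::rpois(n_loci, x * seq_k)
  list(mean_depth = mean(n), frac_missing = mean(n == 0),
       depth_table = table(n) / n_loci)
}
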