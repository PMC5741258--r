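test_that("founder panels are homozygous, major-allele oriented, reproducible", {
  cfg <- founder_config(lines = c(A = 30, B = 20), n_markers = 400,
                        n_chr = 4, chr_length = 120)
  panel <- generate_founders(cfg, seed = 42)
  expect_true(all(panel$genotypes %in% c(0, 2)))
  expect_true(all(colMeans(panel$genotypes) / 2 >= 0.5))  # reference = major
  expect_equal(dim(panel$genotypes), c(50L, 400L))
  expect_equal(as.vector(table(panel$group)), c(30L, 20L))
  expect_identical(colnames(panel$genotypes), panel$map$marker)
  expect_false(is.unsorted(panel$map$pos_cM[panel$map$chrom == "chr01"]))

  panel2 <- generate_founders(cfg, seed = 42)
  expect_identical(panel, panel2)
  panel3 <- generate_founders(cfg, seed = 43)
  expect_false(identical(panel$genotypes, panel3$genotypes))
})

test_that("DH progeny carry only parental alleles at Haldane rates", {
  map <- genetic_map(c("La", "Lb"), "1", c(0, 10), chr_lengths = c("1" = 100))
  p_ref <- c(La = 2, Lb = 2)
  p_alt <- c(La = 0, Lb = 0)
  dh <- simulate_dh(p_ref, p_alt, map, 10000, seed = 7)
  expect_true(all(dh %in% c(0, 2)))
  # single-locus segregation 1:1
  expect_equal(mean(dh[, 1] == 2), 0.5, tolerance = 3 * 0.005)
  # two-point recombinant fraction at 10 cM
  r_hat <- mean(dh[, 1] != dh[, 2])
  r_exp <- recombination_fraction(10)
  se <- sqrt(r_exp * (1 - r_exp) / 10000)
  expect_lt(abs(r_hat - r_exp), 3 * se)

  # identical parents reproduce themselves
  same <- simulate_dh(p_ref, p_ref, map, 5, seed = 1)
  expect_true(all(same == 2))

  # progeny alleles always parental on a multi-chromosome map
  cfg <- founder_config(lines = c(A = 4), n_markers = 200, n_chr = 3)
  panel <- generate_founders(cfg, seed = 5)
  dh2 <- simulate_dh(panel$genotypes[1, ], panel$genotypes[2, ], panel$map,
                     20, seed = 8)
  ok <- t(dh2) == panel$genotypes[1, ] | t(dh2) == panel$genotypes[2, ]
  expect_true(all(ok))
})

test_that("BC1-derived DH retain about a quarter of the donor genome", {
  map <- genetic_map(sprintf("m%03d", 1:100), "1",
                     seq(0, 160, length.out = 100),
                     chr_lengths = c("1" = 160))
  recurrent <- rep(2, 100)
  donor <- rep(0, 100)
  dh <- simulate_dh(recurrent, donor, map, 3000, cross_type = "BC1DH",
                    seed = 31)
  donor_frac <- mean(dh == 0)
  se <- sqrt(0.25 * 0.75 / 3000)  # conservative: loci are correlated
  expect_lt(abs(donor_frac - 0.25), 0.03)
  expect_gt(donor_frac, 0.2)
})

test_that("traits hit the requested heritability exactly in-sample", {
  cfg <- founder_config(lines = c(A = 10), n_markers = 300, n_chr = 2)
  panel <- generate_founders(cfg, seed = 9)
  pops <- simulate_populations(panel, n_pops = 2, n_progeny = 100, seed = 10)
  geno <- do.call(rbind, lapply(pops, `[[`, "genotypes"))
  trait <- assign_trait(geno, trait_model(n_causal = 50, h2 = 0.5), seed = 3)
  g <- trait$genetic_value
  e <- trait$phenotype - g
  expect_equal(var(g) / (var(g) + var(e)), 0.5, tolerance = 1e-10)
  expect_equal(length(trait$marker_loci), 250L)
  expect_false(any(trait$causal %in% trait$marker_loci))

  full_h2 <- assign_trait(geno, trait_model(n_causal = 50, h2 = 1), seed = 3)
  expect_equal(full_h2$phenotype, full_h2$genetic_value)
})

test_that("pools use every individual once with the requested composition", {
  cfg <- founder_config(lines = c(A = 40, B = 20), n_markers = 100, n_chr = 2)
  panel <- generate_founders(cfg, seed = 21)
  pops_a <- simulate_populations(panel, 8, n_progeny = 10, group = "A",
                                 seed = 22)
  pops_b <- simulate_populations(panel, 4, n_progeny = 10, group = "B",
                                 seed = 23)

  two_way <- build_pools(pops_a, size = 2, arrangement = "within", seed = 1)
  expect_length(two_way, 40L)  # 8 populations of 10 -> 4 pairings x 10
  members <- unlist(lapply(two_way, function(p) p$definition$individual))
  expect_false(anyDuplicated(members) > 0)

  across <- build_pools(c(pops_a, pops_b), size = 3, arrangement = "across",
                        seed = 2)
  groups_per_pool <- t(vapply(across, function(p)
    as.vector(table(factor(substr(p$definition$individual, 1, 1),
                           c("A", "B")))), c(0L, 0L)))
  expect_true(all(groups_per_pool[, 1] == 2L & groups_per_pool[, 2] == 1L))

  expect_error(build_pools(pops_a[1], size = 2, arrangement = "within"),
               "not enough populations")
})

test_that("GBS read counts follow the Gamma-Poisson-Binomial cascade", {
  cfg <- founder_config(lines = c(A = 20), n_markers = 500, n_chr = 2)
  panel <- generate_founders(cfg, seed = 61)
  pops <- simulate_populations(panel, 4, n_progeny = 20, seed = 62)
  pools <- build_pools(pops, size = 2, arrangement = "within", seed = 63)

  # x = 0: everything missing
  empty <- simulate_gbs(pools, gbs_config(x = 0), seed = 64)
  expect_true(all(empty$pools[[1]]$observations$total_reads == 0L))

  gbs <- simulate_gbs(pools, gbs_config(x = 4), seed = 65)
  expect_identical(simulate_gbs(pools, gbs_config(x = 4), seed = 65), gbs)

  # loci where both members carry the reference read pure reference
  obs1 <- gbs$pools[[1]]$observations
  both_ref <- colSums(pools[[1]]$genotypes == 2) == 2L
  expect_equal(obs1$ref_reads[both_ref], obs1$total_reads[both_ref])

  # Dirichlet contributions: mean 1/2, sd ~ 0.05 at concentration 50
  d1 <- vapply(gbs$pools, function(p) p$fractions[1], 0)
  expect_equal(mean(d1), 0.5, tolerance = 0.02)
  expect_equal(sd(d1), sqrt(0.25 / 101), tolerance = 0.25 * sqrt(0.25 / 101))

  # marginal reference-read fraction matches the carrier fractions
  p_exp <- as.numeric(gbs$pools[[1]]$fractions %*%
                        (pools[[1]]$genotypes == 2))
  has_reads <- obs1$total_reads > 0 & p_exp > 0 & p_exp < 1
  frac <- sum(obs1$ref_reads[has_reads]) / sum(obs1$total_reads[has_reads])
  expect_equal(frac, sum(p_exp[has_reads] * obs1$total_reads[has_reads]) /
                 sum(obs1$total_reads[has_reads]), tolerance = 0.05)
})

test_that("read depth profile matches the Gamma-Poisson closed form", {
  prof <- read_depth_profile(1, n_loci = 2e5, seed = 99)
  expect_equal(prof$mean_depth, 1, tolerance = 0.02)
  # missing fraction: E[exp(-seq)] = (1 + 1/4)^-4
  expect_equal(prof$frac_missing, 1.25^-4, tolerance = 0.01)
  prof4 <- read_depth_profile(4, n_loci = 5e4, seed = 100)
  expect_lt(prof4$frac_missing, prof$frac_missing)
  expect_equal(prof4$mean_depth, 4, tolerance = 0.05)
})
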