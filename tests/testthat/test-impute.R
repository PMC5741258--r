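test_that("posterior mass converts to dosages, hard calls and probabilities", {
  fx <- fig1_fixture()
  space <- enumerate_inheritance_patterns(fx$pool)

  # all mass on I2-I3 at L2: P1 inherits alternate (I2), P2 reference (I3)
  post <- matrix(c(0, 0, 1, 0), 1, 4, dimnames = list("L2", space$labels))
  dt <- impute_dosages(post, space, fx$parents)
  expect_equal(dt$dosage["P1", "L2"], 0)
  expect_equal(dt$dosage["P2", "L2"], 2)
  expect_equal(dt$call_prob["P1", "L2"], 1)

  # uniform posterior at a locus segregating in both populations
  post_u <- matrix(0.25, 1, 4, dimnames = list("L2", space$labels))
  dt_u <- impute_dosages(post_u, space, fx$parents)
  expect_equal(unname(dt_u$dosage[, "L2"]), c(1, 1))
  expect_equal(unname(dt_u$call_prob[, "L2"]), c(0.5, 0.5))
  expect_equal(unname(dt_u$hard_call[, "L2"]), c(2, 2))  # tie calls reference
})

test_that("monomorphic loci impute directly and leave the HMM when shared", {
  markers <- c("m1", "m2", "m3")
  parents <- parent_genotypes(matrix(
    c(2, 2, 2, 2,    # m1: monomorphic everywhere
      0, 0, 2, 0,    # m2: member 1 monomorphic (0), member 2 segregates
      2, 0, 2, 0),   # m3: both segregate
    nrow = 3, byrow = TRUE,
    dimnames = list(markers, c("I1", "I2", "I3", "I4"))))
  pool <- pool_definition(c("P1", "P2"), c("I1", "I3"), c("I2", "I4"))
  mono <- impute_monomorphic(pool, parents)
  expect_equal(unname(mono$pool_monomorphic), c(TRUE, FALSE, FALSE))
  expect_equal(mono$member_dosage["P1", "m1"], 2)
  expect_equal(mono$member_dosage["P1", "m2"], 0)
  expect_true(is.na(mono$member_dosage["P2", "m2"]))
  expect_true(all(is.na(mono$member_dosage[, "m3"])))

  # fully polymorphic input: nothing leaves the HMM
  poly <- parent_genotypes(matrix(c(2, 0, 2, 0), 1, 4,
                                  dimnames = list("mX",
                                                  c("I1", "I2", "I3", "I4"))))
  mono2 <- impute_monomorphic(pool, poly)
  expect_false(any(mono2$pool_monomorphic))
  expect_true(all(is.na(mono2$member_dosage)))
})

test_that("DNA fractions are recovered from differentially fixed loci", {
  n_loc <- 40
  markers <- sprintf("m%02d", seq_len(n_loc))
  # population 1 (I1 x I2) fixed reference, population 2 (I3 x I4) fixed
  # alternate at every locus
  parents <- parent_genotypes(matrix(
    rep(c(2, 2, 0, 0), each = n_loc), n_loc, 4,
    dimnames = list(markers, c("I1", "I2", "I3", "I4"))))
  pool <- pool_definition(c("P1", "P2"), c("I1", "I3"), c("I2", "I4"))

  # 60% of reads carry population 1's allele
  obs <- pool_observations(markers, ref_reads = rep(6, n_loc),
                           total_reads = rep(10, n_loc))
  # add-one smoothing pulls the estimate negligibly toward 1/2
  expect_equal(estimate_dna_fractions(obs, pool, parents), c(0.6, 0.4),
               tolerance = 2e-3)

  obs50 <- pool_observations(markers, ref_reads = rep(5, n_loc),
                             total_reads = rep(10, n_loc))
  expect_equal(estimate_dna_fractions(obs50, pool, parents), c(0.5, 0.5))

  # no informative loci: equal fractions with a warning
  seg <- parent_genotypes(matrix(rep(c(2, 0, 2, 0), each = n_loc), n_loc, 4,
                                 dimnames = dimnames(parents)))
  expect_warning(fr <- estimate_dna_fractions(obs, pool, seg),
                 "equal DNA fractions")
  expect_equal(fr, c(0.5, 0.5))
})

test_that("end-to-end imputation handles certainty, missingness and linkage", {
  fx <- fig1_fixture()

  # singly-polymorphic loci with deep heterogeneous reads identify the
  # carrier member exactly: the homogeneous patterns are point masses and
  # drop out, pinning each call with certainty
  markers <- c("L1", "L2", "L3", "L4")
  single <- parent_genotypes(matrix(
    c(2, 2, 2, 0,
      2, 0, 2, 2,
      2, 2, 2, 0,
      2, 0, 2, 2), 4, 4, byrow = TRUE,
    dimnames = list(markers, c("I1", "I2", "I3", "I4"))))
  deep <- pool_observations(markers, ref_reads = rep(50, 4),
                            total_reads = rep(100, 4))
  res <- run_imputation(single, fx$map, fx$pool, deep,
                        fractions = c(0.5, 0.5))
  expect_true(all(res$dosages$hard_call %in% c(0, 2)))
  expect_true(all(res$dosages$call_prob > 0.97))
  expect_equal(unname(res$dosages$dosage["P2", c("L1", "L3")]), c(0, 0),
               tolerance = 1e-6)
  expect_equal(unname(res$dosages$dosage["P1", c("L2", "L4")]), c(0, 0),
               tolerance = 1e-6)

  # all loci missing: posterior is the prior, segregating dosages 1
  blank <- pool_observations("L1", ref_reads = 0, total_reads = 0)
  res_b <- run_imputation(fx$parents, fx$map, fx$pool, blank,
                          fractions = c(0.5, 0.5))
  expect_equal(unname(res_b$posterior),
               matrix(0.25, 4, 4), tolerance = 1e-12)
  expect_equal(unname(res_b$dosages$dosage["P2", c("L2", "L3", "L4")]),
               rep(1, 3))
  expect_equal(res_b$dosages$dosage[["P1", "L1"]], 2)  # monomorphic for P1

  # worked four-locus example: linkage favours the pattern needing a
  # recombination in the wider (10 cM) interval, so I2-I3 beats I1-I4 at L2
  res_f <- run_imputation(fx$parents, fx$map, fx$pool, fx$obs,
                          fractions = c(0.5, 0.5))
  expect_gt(res_f$posterior["L2", "I2-I3"], res_f$posterior["L2", "I1-I4"])
  expect_equal(names(which.max(res_f$posterior["L3", ])), "I2-I3")
  # most likely genotype: alternate for P1, reference for P2 at L2 and L3
  expect_equal(unname(res_f$dosages$hard_call["P1", c("L2", "L3")]), c(0, 0))
  expect_equal(unname(res_f$dosages$hard_call["P2", c("L2", "L3")]), c(2, 2))
})

test_that("imputation validates marker and parent consistency", {
  fx <- fig1_fixture()
  missing_parent <- fx$parents[, c("I1", "I2", "I3")]
  class(missing_parent) <- class(fx$parents)
  expect_error(run_imputation(missing_parent, fx$map, fx$pool, fx$obs),
               "I4")
  bad_obs <- pool_observations("LX", ref_reads = 1, total_reads = 2)
  expect_error(run_imputation(fx$parents, fx$map, fx$pool, bad_obs), "LX")
  short <- parent_genotypes(unclass(fx$parents)[1:3, ])
  expect_error(run_imputation(short, fx$map, fx$pool, fx$obs), "L4")
})

test_that("imputation is deterministic and respects chromosome boundaries", {
  fx <- fig1_fixture()
  r1 <- run_imputation(fx$parents, fx$map, fx$pool, fx$obs,
                       fractions = c(0.5, 0.5))
  r2 <- run_imputation(fx$parents, fx$map, fx$pool, fx$obs,
                       fractions = c(0.5, 0.5))
  expect_identical(r1, r2)

  # moving L3/L4 to another chromosome decouples them from L1/L2
  map2 <- genetic_map(c("L1", "L2", "L3", "L4"), c("1", "1", "2", "2"),
                      c(0, 10, 0, 3))
  obs2 <- pool_observations(c("L1", "L2"), ref_reads = c(1, 2),
                            total_reads = c(3, 4))
  res2 <- run_imputation(fx$parents, map2, fx$pool, obs2,
                         fractions = c(0.5, 0.5))
  # chromosome 2 has no data: its posteriors are the prior
  expect_equal(unname(res2$posterior[c("L3", "L4"), ]),
               matrix(0.25, 2, 4), tolerance = 1e-12)
})
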