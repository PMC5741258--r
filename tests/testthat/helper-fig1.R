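# Four-locus two-way pool mirroring the introductory worked example: two DH
# (P1 from I1 x I2, P2 from I3 x I4), four linked loci on one chromosome.
# L1 and L4 are polymorphic in one population only; L2/L3 in both.
fig1_fixture <- function() {
  markers <- c("L1", "L2", "L3", "L4")
  parents <- parent_genotypes(matrix(
    c(2, 2, 2, 0,    # L1: only I4 carries the alternate allele
      2, 0, 2, 0,    # L2: polymorphic in both populations
      2, 0, 2, 0,    # L3: polymorphic in both populations
      0, 0, 2, 0),   # L4: only I3 carries the reference allele
    nrow = 4, byrow = TRUE,
    dimnames = list(markers, c("I1", "I2", "I3", "I4"))))
  map <- genetic_map(markers, "1", c(0, 10, 14, 17))
  pool <- pool_definition(c("P1", "P2"), c("I1", "I3"), c("I2", "I4"))
  obs <- pool_observations(markers,
                           ref_reads = c(1, 2, 0, 1),
                           total_reads = c(3, 4, 0, 2))
  list(parents = parents, map = map, pool = pool, obs = obs)
}
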