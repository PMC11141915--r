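# Emission model and forward simulator

test_that("expected allele fraction formulas match their closed forms", {
  # VAF
  expect_equal(expected_vaf(1.0, 2, 1, 1.0), 0.5)
  expect_equal(expected_vaf(0.6, 1, 1, 1.0), 0.6 / 1.4)
  expect_equal(expected_vaf(0.5, 4, 4, 1.0), 2 / 3)
  expect_error(expected_vaf(1.0, 0, 0, 1.0), "homozygous-deletion")
  # BAF
  expect_equal(expected_baf(1.0, 1, 1), 0.5)
  expect_equal(expected_baf(1.0, 1, 0), 1.0)
  expect_equal(expected_baf(0.5, 2, 0), 0.75)
  expect_error(expected_baf(1.0, 0, 0), "homozygous-deletion")
  # logR
  expect_equal(expected_logr(1.0, 2, 2.0), 0)
  expect_equal(expected_logr(1.0, 1, 2.0), -1)
  expect_equal(expected_logr(0.5, 4, 2.0), log2(3 / 2))
})

test_that("simulation is bit-identical under a fixed seed", {
  p1 <- sim_patient(seed = 7)
  p2 <- sim_patient(seed = 7)
  expect_identical(p1$dataset$snps, p2$dataset$snps)
  expect_identical(p1$dataset$variants, p2$dataset$variants)
  expect_identical(p1$dataset$truth$monosomies_trunk,
                   p2$dataset$truth$monosomies_trunk)
  p3 <- sim_patient(seed = 8)
  expect_false(identical(p1$dataset$snps, p3$dataset$snps))
})

test_that("adding a region never perturbs existing regions", {
  g <- default_genome()
  sc2 <- chrcc_scenario(chr21 = "yes")
  extra <- sc2$regions[2, ]
  extra$region <- "R3"
  sc3 <- evolution_scenario(sc2$clones, sc2$events,
                            rbind(sc2$regions, extra), chr21 = "yes")
  d2 <- simulate_scenario(sc2, g, seed = 5)
  d3 <- simulate_scenario(sc3, g, seed = 5)
  for (rg in c("R1", "R2")) {
    expect_identical(d2$snps[d2$snps$region == rg, ],
                     d3$snps[d3$snps$region == rg, ])
    expect_identical(d2$variants[d2$variants$region == rg, ],
                     d3$variants[d3$variants$region == rg, ])
  }
})

test_that("WGD doubles every arm copy number and inherited multiplicity", {
  pat <- sim_patient(seed = 3, chr21 = "yes")
  tr <- pat$dataset$truth
  classic <- tr$clone_arm_cn$C1
  dediff <- tr$clone_arm_cn$D
  not_gained <- dediff$arm != "1q"
  expect_equal(dediff$mat[not_gained], 2L * classic$mat[not_gained])
  expect_equal(dediff$pat[not_gained], 2L * classic$pat[not_gained])
  # the 1q gain adds one further major-allele copy on top of the doubling
  expect_equal(dediff$mat[dediff$arm == "1q"] + dediff$pat[dediff$arm == "1q"],
               2L * (classic$mat[classic$arm == "1q"] +
                       classic$pat[classic$arm == "1q"]) + 1L)
  # trunk mutations double in the post-WGD clone
  m <- tr$mutations
  trunkers <- m$clone == "C"
  expect_true(all(m$D[trunkers] == 2L * m$C1[trunkers]))
  # post-WGD genotype ploidy = 2 x parent (before the 1q gain)
  w <- arm_table(pat$genome)
  w <- w$end - w$start
  pl_c <- sum(w * (classic$mat + classic$pat)) / sum(w)
  pl_d_nogain <- sum(w * (2 * (classic$mat + classic$pat))) / sum(w)
  expect_equal(pl_d_nogain, 2 * pl_c)
})

test_that("monosomy followed by WGD yields CN 2 with minor allele 0", {
  pat <- sim_patient(seed = 3, chr21 = "yes")
  d_cn <- pat$dataset$truth$clone_arm_cn$D
  lost <- pat$dataset$truth$monosomies_trunk
  expect_setequal(lost, c("1", "2", "6", "10", "13", "17", "21"))
  on_lost <- d_cn[d_cn$chrom %in% setdiff(lost, "1"), ]
  expect_true(all(on_lost$mat + on_lost$pat == 2L))
  expect_true(all(pmin(on_lost$mat, on_lost$pat) == 0L))
})

test_that("observed BAF matches the emission model within binomial error", {
  # classic region, chromosome 17 monosomy: major-allele fraction at
  # expected_baf(0.7, 1, 0)
  pat <- sim_patient(seed = 7, chr21 = "yes")
  s <- pat$dataset$snps
  s <- s[s$region == "R1" & s$chrom == "17", ]
  baf <- pmax(s$t_alt, s$t_ref) / (s$t_alt + s$t_ref)
  eb <- expected_baf(0.7, 1, 0)
  se <- sqrt(eb * (1 - eb) / mean(s$t_alt + s$t_ref)) / sqrt(nrow(s))
  # folding inflates the observed mean very slightly; 3 SE plus the folding
  # bias bound at this depth
  expect_lt(abs(mean(baf) - eb), 3 * se + 0.01)
})

test_that("observed VAF converges to expected_vaf by multiplicity stratum", {
  g <- default_genome()
  sc <- chrcc_scenario(purity = 0.6, coverage = 2000, chr21 = "yes")
  d <- simulate_scenario(sc, g, seed = 13)
  tr <- d$truth
  v <- d$variants[d$variants$region == "R2", ]
  m_of <- tr$mutations$D[match(v$id, tr$mutations$id)]
  segs <- tr$regions$R2$segments
  armid <- paste0(v$chrom, ifelse(
    v$pos < segs$start[match(paste0(v$chrom, "q"), segs$arm)], "p", "q"))
  cn_of <- segs$total[match(armid, segs$arm)]
  for (m in c(1, 2)) {
    for (cn in unique(cn_of[m_of == m & cn_of > 0])) {
      idx <- which(m_of == m & cn_of == cn)
      if (length(idx) < 3) next
      ev <- expected_vaf(0.6, cn, m)
      obs <- v$alt[idx] / (v$alt[idx] + v$ref[idx])
      se <- sqrt(ev * (1 - ev) / 2000) / sqrt(length(idx))
      expect_lt(abs(mean(obs) - ev), 3 * se + 1e-3)
    }
  }
})

test_that("a scenario with no mutations yields an empty variant table", {
  g <- default_genome()
  sc <- chrcc_scenario(rate_trunk = 0, rate_classic = 0, rate_dediff = 0,
                       syn_frac = 0, chr21 = "yes")
  sc$events$C$drivers <- sc$events$C$drivers[0, ]
  sc$events$D$drivers <- sc$events$D$drivers[0, ]
  d <- simulate_scenario(sc, g, seed = 2)
  expect_equal(nrow(d$variants), 0)
})

test_that("a region referencing an undefined clone is rejected", {
  sc <- chrcc_scenario()
  bad <- sc$regions
  bad$clone[1] <- "nope"
  expect_error(evolution_scenario(sc$clones, sc$events, bad),
               "undefined clone")
})

test_that("genome model enforces its invariants", {
  g <- default_genome()
  expect_equal(nrow(g$chromosomes), 22)
  bad <- g$chromosomes; bad$p_frac[1] <- 1.2
  expect_error(genome_model(bad, g$genes), "p-arm fractions")
  badg <- g$genes; badg$end[1] <- g$chromosomes$length[17] + 100000
  expect_error(genome_model(g$chromosomes, badg), "outside its chromosome")
})
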