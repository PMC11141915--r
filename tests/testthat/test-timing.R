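# Variant filtering, burden, multiplicity, zygosity and event ordering

test_that("variant filtering keeps nonsynonymous VAF >= 15% (boundary in)", {
  v <- data.frame(
    id = paste0("v", 1:10),
    alt = c(1, 2, 14, 15, 20, 50, 90, 30, 40, 16),
    ref = c(99, 98, 86, 85, 80, 50, 10, 70, 60, 84),
    class = c(rep("nonsynonymous", 9), "nonsynonymous"))
  out <- filter_variants(v)
  expect_equal(nrow(out), 7)                        # 3 below 15% dropped
  expect_true("v4" %in% out$id)                     # VAF exactly 0.15 kept
  expect_equal(attr(out, "filter_log")$n_in, 10)

  syn <- data.frame(id = "s", alt = 90, ref = 10, class = "synonymous")
  expect_equal(nrow(filter_variants(syn)), 0)

  nae <- data.frame(id = "n", alt = 90, ref = 10, class = NA_character_)
  out2 <- filter_variants(nae)
  expect_equal(nrow(out2), 0)
  expect_equal(attr(out2, "filter_log")$n_unannotated, 1)
})

test_that("TMB equals the row count of the filtered table", {
  v <- data.frame(id = paste0("v", 1:28), alt = 50, ref = 50,
                  class = "nonsynonymous")
  expect_equal(tmb(filter_variants(v)), 28)
  expect_equal(tmb(filter_variants(v[0, ])), 0)
})

test_that("classic and dediff burdens separate as designed (paired t)", {
  g <- default_genome(n_snps = 10)      # burden only; SNPs irrelevant
  hits <- 0
  for (r in 1:20) {
    t_cl <- t_dd <- numeric(7)
    for (k in 1:7) {
      sc <- chrcc_scenario(chr21 = "yes")
      d <- simulate_scenario(sc, g, seed = 1000 * r + k)
      for (rg in c("R1", "R2")) {
        fv <- filter_variants(d$variants[d$variants$region == rg, ])
        if (rg == "R1") t_cl[k] <- tmb(fv) else t_dd[k] <- tmb(fv)
      }
    }
    if (t.test(t_dd, t_cl, paired = TRUE)$p.value < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 16)                  # 80% power at n = 7 pairs
})

test_that("mutation logOR is the Haldane-corrected log count ratio", {
  expect_equal(mutation_logor(50, 50), 0)
  expect_equal(round(mutation_logor(60, 40), 4), 0.4013)
  expect_equal(mutation_logor(100, 0), log(100.5 / 0.5))
  expect_true(is.finite(mutation_logor(100, 0)))
})

test_that("multiplicity inverts the expected-VAF model", {
  est <- estimate_multiplicity(0.5, 1, 2)
  expect_equal(est$m_raw, 1); expect_equal(est$m, 1L)
  # invert expected_vaf at purity 0.6, CN 1
  v <- expected_vaf(0.6, 1, 1)
  est <- estimate_multiplicity(v, 0.6, 1)
  expect_equal(est$m_raw, 1, tolerance = 1e-12)
  est <- estimate_multiplicity(1.0, 1, 2)
  expect_equal(est$m_raw, 2); expect_equal(est$m, 2L)
  expect_false(est$subclonal)
  expect_true(estimate_multiplicity(0.05, 0.8, 2)$subclonal)
  expect_error(estimate_multiplicity(0.5, 0, 2), "purity")
})

test_that("zygosity labels follow the copy-number rules", {
  expect_equal(classify_zygosity(1, 1, 0), "hemizygous_loh")
  expect_equal(classify_zygosity(2, 2, 0), "homozygous")
  expect_equal(classify_zygosity(1, 2, 1), "heterozygous")
  expect_equal(classify_zygosity(1, 2, 0), "heterozygous")
  expect_equal(classify_zygosity(4, 4, 0), "homozygous")
  expect_equal(classify_zygosity(1, 2, 0, subclonal = TRUE), "subclonal")
  expect_equal(classify_zygosity(NA, NA, NA), "indeterminate")
  expect_error(classify_zygosity(3, 2, 0), "exceeds")
})

test_that("event ordering reproduces the canonical driver narratives", {
  mk <- function(sample, zyg, m, cnt, cnm) {
    data.frame(gene = "TP53L", chrom = "17", pos = 770, alt = 50, ref = 50,
               driver = "TP53L", zygosity = zyg, m = m, cn_total = cnt,
               cn_minor = cnm, sample = sample)
  }
  # hemizygous in classic, homozygous in doubled dediff -> before WGD
  ann <- list(R1 = mk("R1", "hemizygous_loh", 1, 1, 0),
              R2 = mk("R2", "homozygous", 2, 2, 0))
  out <- order_events(ann, wgd = c(R1 = FALSE, R2 = TRUE))
  expect_equal(out$verdict, "mutation_before_duplication")

  # absent pre-WGD, homozygous in the doubled sample -> still before WGD
  ann <- list(R2 = mk("R2", "homozygous", 2, 2, 0))
  out <- order_events(ann, wgd = c(R2 = TRUE))
  expect_equal(out$verdict, "mutation_before_duplication")

  # single copy on a doubled segment -> after WGD
  ann <- list(R2 = mk("R2", "heterozygous", 1, 2, 0))
  out <- order_events(ann, wgd = c(R2 = TRUE))
  expect_equal(out$verdict, "mutation_after_duplication")

  # contradictory evidence across samples -> unordered with conflict note
  ann <- list(R2 = mk("R2", "homozygous", 2, 2, 0),
              R3 = mk("R3", "heterozygous", 1, 2, 0))
  out <- order_events(ann, wgd = c(R2 = TRUE, R3 = TRUE))
  expect_equal(out$verdict, "unordered")
  expect_true(out$conflict)
})

test_that("single-sample verdicts agree with a brute-force rule oracle", {
  oracle <- function(zyg, m, cnt, cnm, wgd) {
    before <- (zyg == "homozygous" && wgd && m == cnt && cnt >= 2 && cnm == 0)
    after <- (m == 1 && cnt >= 2 && wgd && zyg != "subclonal")
    if (before && after) "unordered"
    else if (before) "mutation_before_duplication"
    else if (after) "mutation_after_duplication"
    else "unordered"
  }
  grid <- expand.grid(m = 1:4, cnt = 1:4, cnm = 0:2, wgd = c(TRUE, FALSE))
  grid <- grid[grid$m <= grid$cnt & grid$cnm <= grid$cnt / 2, ]
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    zyg <- classify_zygosity(g$m, g$cnt, g$cnm)
    ann <- list(S = data.frame(gene = "X", chrom = "1", pos = 1,
                               driver = "X", zygosity = zyg, m = g$m,
                               cn_total = g$cnt, cn_minor = g$cnm))
    out <- order_events(ann, wgd = c(S = g$wgd))
    expect_equal(out$verdict, oracle(zyg, g$m, g$cnt, g$cnm, g$wgd),
                 info = paste(unlist(g), collapse = "/"))
  }
})

test_that("excluded low-purity samples are dropped from ordering", {
  mk <- function(sample) {
    data.frame(gene = "TP53L", chrom = "17", pos = 770, driver = "TP53L",
               zygosity = "homozygous", m = 2, cn_total = 2, cn_minor = 0,
               sample = sample)
  }
  ann <- list(R1 = mk("R1"), R2 = mk("R2"))
  out <- order_events(ann, wgd = c(R1 = TRUE, R2 = TRUE),
                      excluded = c(R1 = TRUE, R2 = FALSE))
  ev <- jsonlite::fromJSON(out$evidence)
  expect_equal(ev$sample, "R2")
  expect_error(order_events(ann, wgd = c(R1 = TRUE, R2 = TRUE),
                            excluded = c(R1 = TRUE, R2 = TRUE)),
               "all samples excluded")
})
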