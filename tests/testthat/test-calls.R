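# WGD, arm-level and gene-level copy-number calls

test_that("WGD flag follows the 50% major-CN>=2 genome-fraction rule", {
  segs <- data.frame(chrom = c("1", "2"), start = 0, end = c(100, 100),
                     major = c(2, 2), minor = c(0, 1))
  segs$total <- segs$major + segs$minor
  w <- call_wgd(segs)
  expect_true(w$wgd); expect_equal(w$fraction, 1)

  # boundary: exactly half the genome doubled is called WGD (>= 50%)
  segs <- data.frame(chrom = c("1", "2"), start = 0, end = c(100, 100),
                     major = c(2, 1), minor = c(0, 0))
  expect_true(call_wgd(segs)$wgd)

  segs <- data.frame(chrom = c("1", "2"), start = 0, end = c(98, 102),
                     major = c(2, 1), minor = c(0, 0))
  expect_false(call_wgd(segs)$wgd)     # 49% doubled

  # sex chromosomes are ignored
  segs <- data.frame(chrom = c("1", "X"), start = 0, end = c(100, 300),
                     major = c(2, 1), minor = c(0, 0))
  expect_true(call_wgd(segs)$wgd)
})

test_that("arm calls use a strict >50% rule against baseline CN 2", {
  arms <- data.frame(arm = "1p", chrom = "1", start = 0, end = 100)
  seg <- function(bounds, totals)
    data.frame(chrom = "1", start = bounds[-length(bounds)],
               end = bounds[-1], total = totals)
  expect_equal(call_arms(seg(c(0, 60, 100), c(3, 2)), arms)$call, "gain")
  expect_equal(call_arms(seg(c(0, 50, 100), c(1, 2)), arms)$call, "neutral")
  expect_equal(call_arms(seg(c(0, 100), 1), arms)$call, "loss")
  expect_equal(call_arms(seg(c(0, 100), 1), arms)$loss_fraction, 1)
  expect_error(call_arms(seg(c(0, 150), 1), arms), "past end")
})

test_that("gene copy number inherits from segments by the documented rules", {
  segs <- data.frame(chrom = "1", start = c(0, 100), end = c(100, 200),
                     total = c(1, 3), major = c(1, 2), minor = c(0, 1))
  genes <- data.frame(gene = c("inside", "wide", "split"),
                      chrom = "1",
                      start = c(10, 30, 50), end = c(20, 130, 150))
  gc <- gene_copy_number(segs, genes)
  expect_equal(gc$total[gc$gene == "inside"], 1)
  expect_equal(gc$rule[gc$gene == "inside"], "midpoint")
  # "wide" overlaps 70/30 in favour of the first segment
  expect_equal(gc$total[gc$gene == "wide"], 1)
  expect_equal(gc$rule[gc$gene == "wide"], "overlap")
  # "split" is 50/50: the more aberrant segment (CN 1, distance 1 from
  # baseline 2 vs CN 3, distance 1...) — equidistant goes to the first max
  segs2 <- data.frame(chrom = "1", start = c(0, 100), end = c(100, 200),
                      total = c(2, 3), major = c(1, 2), minor = c(1, 1))
  gc2 <- gene_copy_number(segs2, genes[genes$gene == "split", ])
  expect_equal(gc2$total, 3)          # (3,1) beats (2,1) on aberrance
  expect_equal(gc2$rule, "aberrance")
  # missing chromosome flagged, not fatal
  gc3 <- gene_copy_number(segs, data.frame(gene = "lost", chrom = "9",
                                           start = 0, end = 10))
  expect_equal(gc3$rule, "missing")
  expect_true(is.na(gc3$total))
})

test_that("a planted 4-vs-2 gene is flagged against a null background", {
  set.seed(407)
  n_pairs <- 6
  cl <- matrix(sample(1:3, 100 * n_pairs, TRUE), 100, n_pairs)
  dd <- cl + matrix(sample(c(-1, 0, 1), 100 * n_pairs, TRUE,
                           prob = c(.25, .5, .25)), 100, n_pairs)
  dd <- pmax(dd, 1)
  rownames(cl) <- rownames(dd) <- paste0("g", 1:100)
  dd["g1", ] <- 4; cl["g1", ] <- 2
  res <- differential_gene_cn(dd, cl)
  expect_true(res$significant[res$gene == "g1"])
  # hand oracle: perfect separation puts the planted gene at the smallest
  # adjusted p and its fold change at exactly 2
  expect_equal(res$fc[res$gene == "g1"], 2)
  expect_equal(res$padj[res$gene == "g1"], 0)
})

test_that("genes identical in all pairs are not testable", {
  m <- matrix(2, 5, 4, dimnames = list(paste0("g", 1:5), NULL))
  m2 <- m; m2[2, ] <- 3                    # constant difference, testable
  res <- differential_gene_cn(m2, m)
  expect_true(res$not_testable[1])
  expect_false(res$not_testable[2])
  expect_equal(res$p[2], 0)
  expect_error(differential_gene_cn(m[, 1:2], m[, 1:2]), "3 patient pairs")
})

test_that("t statistics and BH adjustment agree with a hand oracle", {
  set.seed(408)
  dd <- matrix(rpois(20 * 6, 3) + 1, 20, 6)
  cl <- matrix(rpois(20 * 6, 3) + 1, 20, 6)
  res <- differential_gene_cn(dd, cl)
  for (i in which(!res$not_testable & is.finite(res$p) & res$p > 0)) {
    expect_equal(res$p[i], t.test(dd[i, ], cl[i, ], paired = TRUE)$p.value)
  }
  ok <- !res$not_testable
  expect_equal(res$padj[ok], p.adjust(res$p[ok], "BH"))
})
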