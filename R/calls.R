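## Genome-level calls from a fitted segment profile

#' Whole-genome doubling call
#'
#' A sample is WGD-positive when at least 50\% of the autosomal genome (by
#' length) has major allele copy number >= 2.
#'
#' @param segments segment table with `start`, `end`, `major` (and `chrom`);
#'   chromosomes named X or Y are ignored
#' @return list with `wgd` (logical) and `fraction` (length-weighted share of
#'   the autosomal genome at major CN >= 2)
#' @export
call_wgd <- function(segments) {
  s <- segments[!segments$chrom %in% c("X", "Y", "chrX", "chrY"), , drop = FALSE]
  w <- s$end - s$start
  fraction <- sum(w[s$major >= 2]) / sum(w)
  list(wgd = fraction >= 0.5, fraction = fraction)
}

#' Chromosome-arm gain/loss calls
#'
#' An arm is called gained (lost) when strictly more than 50\% of its length
#' has total copy number above (below) the baseline. The baseline is absolute
#' copy number 2 regardless of sample ploidy, so monosomies in hypodiploid
#' samples count as losses.
#'
#' @param segments fitted segment table (`chrom`, `start`, `end`, `total`)
#' @param arms arm table from [arm_table()]
#' @param baseline_cn baseline total copy number (default 2)
#' @return data.frame `arm`, `call` (gain/loss/neutral), `gain_fraction`,
#'   `loss_fraction`
#' @export
call_arms <- function(segments, arms, baseline_cn = 2) {
  out <- arms[c("arm", "chrom")]
  out$gain_fraction <- 0; out$loss_fraction <- 0
  for (i in seq_len(nrow(arms))) {
    a <- arms[i, ]
    s <- segments[segments$chrom == a$chrom, , drop = FALSE]
    if (!nrow(s)) next
    if (any(s$end > max(arms$end[arms$chrom == a$chrom]) + 1e-9))
      stop("segment extends past end of chromosome ", a$chrom)
    ov <- pmin(s$end, a$end) - pmax(s$start, a$start)
    ov[ov < 0] <- 0
    if (sum(ov) == 0) next
    out$gain_fraction[i] <- sum(ov[s$total > baseline_cn]) / sum(ov)
    out$loss_fraction[i] <- sum(ov[s$total < baseline_cn]) / sum(ov)
  }
  out$call <- ifelse(out$gain_fraction > 0.5, "gain",
                     ifelse(out$loss_fraction > 0.5, "loss", "neutral"))
  out[c("arm", "chrom", "call", "gain_fraction", "loss_fraction")]
}

#' Gene-level integer copy numbers inherited from segments
#'
#' Each gene takes the (total, major, minor) of the fine-pass segment
#' containing its midpoint. Genes spanning a breakpoint take the segment with
#' the larger overlap; exact overlap ties go to the more aberrant segment
#' (total copy number farther from the baseline). The rule used is recorded
#' per gene.
#'
#' @param segments fitted segment table
#' @param genes gene table (`gene`, `chrom`, `start`, `end`)
#' @param baseline_cn baseline for the aberrance tie-break (default 2)
#' @return data.frame `gene`, `chrom`, `total`, `major`, `minor`, `rule`
#'   (`midpoint`/`overlap`/`aberrance`/`missing`)
#' @export
gene_copy_number <- function(segments, genes, baseline_cn = 2) {
  res <- genes[c("gene", "chrom")]
  res$total <- NA_integer_; res$major <- NA_integer_; res$minor <- NA_integer_
  res$rule <- "missing"
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    s <- segments[segments$chrom == g$chrom, , drop = FALSE]
    if (!nrow(s)) next
    ov <- pmin(s$end, g$end) - pmax(s$start, g$start)
    ov[ov < 0] <- 0
    inside <- ov >= (g$end - g$start)          # fully contained
    if (any(inside)) {
      j <- which(inside)[1]; rule <- "midpoint"
    } else if (any(ov > 0)) {
      mx <- max(ov)
      cand <- which(ov == mx)
      if (length(cand) == 1L) {
        j <- cand; rule <- "overlap"
      } else {
        ab <- abs(s$total[cand] - baseline_cn)
        j <- cand[which.max(ab)]; rule <- "aberrance"
      }
    } else {
      mid <- (g$start + g$end) / 2             # gene in a coverage gap
      j <- which.min(pmax(s$start - mid, mid - s$end))
      rule <- "midpoint"
    }
    res$total[i] <- s$total[j]; res$major[i] <- s$major[j]
    res$minor[i] <- s$minor[j]; res$rule[i] <- rule
  }
  res
}

#' Differential gene-level copy number between paired sample groups
#'
#' Per gene, a paired two-tailed t test of integer total copy number across
#' patients, Benjamini-Hochberg adjusted across genes; a gene is flagged
#' significant when the adjusted p-value is at most `alpha` and the
#' copy-number fold change (mean of group 1 over mean of group 2) is at least
#' `fc_min`. Genes whose paired differences have zero variance are not
#' testable by the t statistic: with a zero mean difference they are flagged
#' `not_testable`; with a nonzero constant difference the groups are perfectly
#' separated and the p-value is reported as 0.
#'
#' @param cn1,cn2 either genes x patients matrices/data.frames of integer
#'   total copy number (same gene order and patients), or lists of fitted
#'   segment tables, one per patient, in which case `genes` must be supplied
#'   and gene copy numbers are derived via [gene_copy_number()]
#' @param genes gene table, required when `cn1`/`cn2` are segment-table lists
#' @param alpha adjusted-p significance cutoff (default 0.05)
#' @param fc_min minimum copy-number fold change (default 2)
#' @return data.frame `gene`, `mean_1`, `mean_2`, `fc`, `p`, `padj`,
#'   `significant`, `not_testable`
#' @export
differential_gene_cn <- function(cn1, cn2, genes = NULL,
                                 alpha = 0.05, fc_min = 2) {
  as_cn_matrix <- function(x) {
    if (is.list(x) && !is.data.frame(x)) {
      stopifnot(!is.null(genes))
      m <- vapply(x, function(s) gene_copy_number(s, genes)$total,
                  numeric(nrow(genes)))
      rownames(m) <- genes$gene
      m
    } else as.matrix(x)
  }
  m1 <- as_cn_matrix(cn1); m2 <- as_cn_matrix(cn2)
  stopifnot(nrow(m1) == nrow(m2), ncol(m1) == ncol(m2))
  if (ncol(m1) < 3) stop("need >= 3 patient pairs")
  gene_names <- rownames(m1) %||% as.character(seq_len(nrow(m1)))
  d <- m1 - m2
  sds <- apply(d, 1, stats::sd)
  means <- rowMeans(d)
  p <- rep(NA_real_, nrow(m1))
  testable <- !(sds == 0 & means == 0) & !apply(is.na(d), 1, any)
  for (i in which(testable)) {
    p[i] <- if (sds[i] == 0) 0 else
      stats::t.test(m1[i, ], m2[i, ], paired = TRUE)$p.value
  }
  padj <- rep(NA_real_, length(p))
  padj[testable] <- stats::p.adjust(p[testable], method = "BH")
  fc <- rowMeans(m1) / rowMeans(m2)
  data.frame(gene = gene_names,
             mean_1 = rowMeans(m1), mean_2 = rowMeans(m2), fc = fc,
             p = p, padj = padj,
             significant = !is.na(padj) & padj <= alpha & fc >= fc_min,
             not_testable = !testable,
             row.names = NULL, stringsAsFactors = FALSE)
}
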