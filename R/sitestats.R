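#' Per-site copy-number statistics from paired tumor/normal allelic depths
#'
#' Computes, for one tumor sample against its matched normal, the library-size
#' normalised depth log-ratio and the allelic log odds ratio at each
#' germline-heterozygous SNP site:
#' \itemize{
#'   \item `logr = log2((t_tot / n_tot) * (sum(n_tot) / sum(t_tot)))`
#'   \item `logor = ln(((t_alt + 0.5) / (t_ref + 0.5)) /
#'                    ((n_alt + 0.5) / (n_ref + 0.5)))` (Haldane correction)
#' }
#' Sites with normal depth below `min_normal_depth` are dropped before the
#' library sums are taken. A per-site variance estimate for the logOR
#' (`var_logor`, the sum of reciprocal corrected counts) is carried along for
#' downstream noise modelling.
#'
#' @param snp_table data.frame with columns `chrom`, `pos`, `t_alt`, `t_ref`,
#'   `n_alt`, `n_ref` for a single sample; positions must be strictly
#'   increasing within each chromosome.
#' @param min_normal_depth minimum normal depth for a site to be retained
#'   (default 10)
#' @return data.frame `chrom`, `pos`, `logr`, `logor`, `t_depth`, `n_depth`,
#'   `var_logor`
#' @export
site_stats <- function(snp_table, min_normal_depth = 10) {
  need <- c("chrom", "pos", "t_alt", "t_ref", "n_alt", "n_ref")
  stopifnot(is.data.frame(snp_table), all(need %in% names(snp_table)))
  if (nrow(snp_table) == 0) stop("empty SNP table")
  for (cc in unique(snp_table$chrom)) {
    p <- snp_table$pos[snp_table$chrom == cc]
    if (any(diff(p) <= 0)) {
      i <- which(diff(p) <= 0)[1]
      stop("SNP table not sorted: chromosome ", cc, " position ", p[i + 1],
           " does not follow ", p[i])
    }
  }
  t_tot <- snp_table$t_alt + snp_table$t_ref
  n_tot <- snp_table$n_alt + snp_table$n_ref
  keep <- n_tot >= min_normal_depth
  x <- snp_table[keep, , drop = FALSE]
  t_tot <- t_tot[keep]; n_tot <- n_tot[keep]
  if (nrow(x) == 0) stop("no sites left after normal-depth filter")
  logr <- log2((t_tot / n_tot) * (sum(n_tot) / sum(t_tot)))
  logor <- log((x$t_alt + 0.5) / (x$t_ref + 0.5)) -
    log((x$n_alt + 0.5) / (x$n_ref + 0.5))
  var_logor <- 1 / (x$t_alt + 0.5) + 1 / (x$t_ref + 0.5) +
    1 / (x$n_alt + 0.5) + 1 / (x$n_ref + 0.5)
  data.frame(chrom = x$chrom, pos = x$pos, logr = logr, logor = logor,
             t_depth = t_tot, n_depth = n_tot, var_logor = var_logor,
             stringsAsFactors = FALSE)
}
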