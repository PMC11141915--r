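## Joint purity / ploidy / integer allele-specific copy-number fit
##
## A grid search over purity and the diploid logR offset. For each candidate,
## every segment is assigned the integer (major, minor) pair minimising the
## squared distance between its observed (mean logR, mean |logOR|) and the
## model expectation; the candidate minimising the total length-weighted
## residual wins. The folded logOR channel is compared through the folded
## normal mean (the expected value of |logOR| at the segment's binomial noise
## level), which removes the upward bias |x| puts on balanced segments.
##
## The classic<->doubled genome degeneracy (a genome of (1,0)/(1,1) states at
## purity p has identical expected logR and folded logOR to (2,0)/(2,2) at
## purity p/(2-p)) is resolved by a near-tie rule: among candidates within a
## factor `1 + tie_rel` of the best residual, the lowest-ploidy cluster is
## preferred, mirroring the usual practice of reporting the most parsimonious
## genome. Scaled-up genomes fit marginally better than the truth (more
## integer states to absorb noise) while genuinely wrong scaled-down genomes
## misfit odd-copy segments by an order of magnitude, so a generous band
## separates the two cleanly.

# E|X| for X ~ N(mu, sd): folded normal mean
folded_normal_mean <- function(mu, sd) {
  sd * sqrt(2 / pi) * exp(-mu^2 / (2 * sd^2)) + mu * (1 - 2 * stats::pnorm(-mu / sd))
}

# candidate integer allele-specific states up to cn_max total copies
cn_state_grid <- function(cn_max) {
  g <- expand.grid(minor = 0:cn_max, major = 0:cn_max)
  g <- g[g$major >= g$minor & g$major + g$minor <= cn_max &
           g$major + g$minor > 0, c("major", "minor")]
  g$total <- g$major + g$minor
  rownames(g) <- NULL
  g
}

#' Fit purity, ploidy and integer allele-specific copy number
#'
#' @param segs segment table from [segment_genome()] (the coarse pass)
#' @param purity_grid candidate purities (default 0.05..1.00 step 0.01)
#' @param ploidy_grid candidate sample ploidies used to generate diploid-logR
#'   offsets (default 0.8..6 step 0.05)
#' @param cn_max maximum total copy number considered (default 8)
#' @param tie_rel near-tie band as a fraction of the best residual (default
#'   4, i.e. candidates within a factor 5 of the optimum); within the band the
#'   lowest-ploidy solution cluster is preferred, then the smallest residual,
#'   then the higher purity
#' @param low_purity_cutoff samples fitted below this purity are flagged
#'   `excluded` (default 0.3, the conventional cutoff for unreliable fits)
#' @return list with `purity`, `ploidy`, `offset` (diploid logR offset),
#'   `residual`, `segments` (input segments plus `total`, `major`, `minor`,
#'   `at_cn_max` flag), `low_confidence`, `excluded`
#' @export
fit_purity_ploidy <- function(segs,
                              purity_grid = seq(0.05, 1, by = 0.01),
                              ploidy_grid = seq(0.8, 6, by = 0.05),
                              cn_max = 8, tie_rel = 4,
                              low_purity_cutoff = 0.3) {
  stopifnot(is.data.frame(segs), nrow(segs) >= 1)
  if (sum(segs$n_sites) < 10)
    stop("need at least 10 informative het sites to fit purity")
  states <- cn_state_grid(cn_max)
  w <- (segs$end - segs$start)
  w <- w / sum(w)
  ## the folded mean acts on single-site |logOR|; the segment mean of |logOR|
  ## averages n_sites draws, so its expectation is the per-site folded mean
  sd_site <- sqrt(pmax(segs$mean_var_logor, 1e-12))

  n_seg <- nrow(segs); n_st <- nrow(states)
  results <- vector("list", length(purity_grid))
  for (ip in seq_along(purity_grid)) {
    p <- purity_grid[ip]
    b <- (p * states$major + (1 - p)) / (p * states$total + (1 - p) * 2)
    b <- pmin(pmax(b, 1e-4), 1 - 1e-4)
    mu <- abs(log(b / (1 - b)))
    logr0 <- log2((p * states$total + 2 * (1 - p)) / 2)
    ## folded-channel residual, independent of the offset
    EF <- outer(sd_site, mu, function(s, m) folded_normal_mean(m, s))
    B <- (segs$mean_fold - EF)^2
    A <- matrix(segs$mean_logr, n_seg, n_st) -
      matrix(logr0, n_seg, n_st, byrow = TRUE)
    C <- A^2 + B
    ## candidate offsets from the ploidy grid seed the assignment; the offset
    ## is then refined to its closed-form optimum for that assignment, so the
    ## grid resolution never penalises ploidies falling between grid points
    offs <- log2((p * ploidy_grid + 2 * (1 - p)) / 2)
    best_res <- rep(NA_real_, length(offs))
    best_off <- rep(NA_real_, length(offs))
    best_plo <- rep(NA_real_, length(offs))
    for (oi in seq_along(offs)) {
      d <- offs[oi]
      V <- C + 2 * A * d + d^2
      pick <- max.col(-V, ties.method = "first")
      idx <- cbind(seq_len(n_seg), pick)
      dstar <- -sum(w * A[idx])
      best_res[oi] <- sum(w * ((A[idx] + dstar)^2 + B[idx]))
      best_off[oi] <- dstar
      best_plo[oi] <- sum(w * states$total[pick])
    }
    results[[ip]] <- data.frame(purity = p, offset = best_off,
                                residual = best_res, ploidy = best_plo)
  }
  grid <- do.call(rbind, results)
  grid <- grid[is.finite(grid$residual), , drop = FALSE]
  if (!nrow(grid)) stop("degenerate fit: no finite candidate residuals")
  best <- min(grid$residual)
  tie <- grid[grid$residual <= best * (1 + tie_rel) + 1e-5, , drop = FALSE]
  keep <- tie[tie$ploidy < min(tie$ploidy) + 0.5, , drop = FALSE]
  keep <- keep[order(keep$residual, keep$ploidy, -keep$purity), , drop = FALSE]
  win <- keep[1, ]

  fitted <- assign_cn(segs, win$purity, win$offset, cn_max = cn_max)
  ploidy <- sum(w * fitted$total)

  ## identifiability: a flat, balanced genome carries no purity signal
  noise_floor <- sd_site * sqrt(2 / pi)
  low_conf <- max(segs$mean_fold - noise_floor) < 0.1 &&
    stats::sd(segs$mean_logr) < 0.1
  if (is.na(low_conf)) low_conf <- FALSE
  if (low_conf)
    warning("flat profile: purity is not identifiable, estimate is low-confidence")

  list(purity = win$purity, ploidy = ploidy, offset = win$offset,
       residual = win$residual, segments = fitted,
       low_confidence = low_conf,
       excluded = win$purity < low_purity_cutoff)
}

#' Assign integer allele-specific copy numbers to segments
#'
#' Given a fitted purity and diploid-logR offset, gives every segment the
#' integer (major, minor) pair minimising its squared (logR, folded logOR)
#' residual.
#'
#' @inheritParams fit_purity_ploidy
#' @param purity fitted purity
#' @param offset fitted diploid logR offset
#' @return `segs` with added columns `total`, `major`, `minor`, `at_cn_max`
#' @export
assign_cn <- function(segs, purity, offset, cn_max = 8) {
  states <- cn_state_grid(cn_max)
  p <- purity
  b <- (p * states$major + (1 - p)) / (p * states$total + (1 - p) * 2)
  b <- pmin(pmax(b, 1e-4), 1 - 1e-4)
  mu <- abs(log(b / (1 - b)))
  logr0 <- log2((p * states$total + 2 * (1 - p)) / 2)
  sd_site <- sqrt(pmax(segs$mean_var_logor, 1e-12))
  EF <- outer(sd_site, mu, function(s, m) folded_normal_mean(m, s))
  V <- (matrix(segs$mean_logr, nrow(segs), nrow(states)) -
          matrix(logr0 - offset, nrow(segs), nrow(states), byrow = TRUE))^2 +
    (segs$mean_fold - EF)^2
  pick <- max.col(-V, ties.method = "first")
  segs$total <- states$total[pick]
  segs$major <- states$major[pick]
  segs$minor <- states$minor[pick]
  segs$at_cn_max <- segs$total >= cn_max
  segs
}

#' Allele-specific copy-number fit of one tumor sample
#'
#' The full two-pass pipeline: per-site statistics, a coarse segmentation pass
#' feeding the joint purity/ploidy grid fit, then a fine segmentation pass
#' whose segments inherit integer allele-specific copy numbers from the fitted
#' purity and offset.
#'
#' @param snp_table paired tumor/normal SNP allelic-depth table for one sample
#'   (see [site_stats()])
#' @param genome optional `genome_model`; segment bounds then extend to
#'   chromosome ends for length weighting
#' @param critical_coarse,critical_fine critical values of the two
#'   segmentation passes
#' @param min_normal_depth minimum normal depth per retained site
#' @param cn_max maximum total copy number in the fit
#' @param ... further arguments passed to [fit_purity_ploidy()]
#' @return object of class `ascn_fit` with elements `purity`, `ploidy`,
#'   `offset`, `residual`, `segments` (the fine-pass `segment_profile`),
#'   `coarse_segments`, `sites`, `low_confidence`, `excluded`, `wgd`
#' @seealso [call_wgd()], [call_arms()], [gene_copy_number()]
#' @export
fit_ascn <- function(snp_table, genome = NULL,
                     critical_coarse = 35, critical_fine = 20,
                     min_normal_depth = 10, cn_max = 8, ...) {
  sites <- site_stats(snp_table, min_normal_depth = min_normal_depth)
  lens <- if (!is.null(genome))
    stats::setNames(genome$chromosomes$length, genome$chromosomes$chrom)
  coarse <- segment_genome(sites, critical = critical_coarse,
                           chrom_lengths = lens)
  fit <- fit_purity_ploidy(coarse, cn_max = cn_max, ...)
  fine <- segment_genome(sites, critical = critical_fine,
                         chrom_lengths = lens)
  fine <- assign_cn(fine, fit$purity, fit$offset, cn_max = cn_max)
  w <- fine$end - fine$start
  structure(list(purity = fit$purity,
                 ploidy = wmean(fine$total, w),
                 offset = fit$offset, residual = fit$residual,
                 segments = fine, coarse_segments = fit$segments,
                 sites = sites,
                 low_confidence = fit$low_confidence,
                 excluded = fit$excluded,
                 wgd = call_wgd(fine),
                 params = list(critical_coarse = critical_coarse,
                               critical_fine = critical_fine,
                               cn_max = cn_max)),
            class = "ascn_fit")
}

#' @export
print.ascn_fit <- function(x, ...) {
  cat("Allele-specific copy-number fit\n")
  cat(sprintf("  purity: %.2f%s   ploidy: %.2f   residual: %.4g\n",
              x$purity,
              if (x$low_confidence) " (low confidence)" else "",
              x$ploidy, x$residual))
  cat(sprintf("  segments: %d   WGD: %s (major CN >= 2 over %.0f%% of genome)\n",
              nrow(x$segments), if (x$wgd$wgd) "yes" else "no",
              100 * x$wgd$fraction))
  if (x$excluded)
    cat("  NOTE: purity < 0.3 - sample flagged excluded-by-default\n")
  invisible(x)
}

#' @export
summary.ascn_fit <- function(object, ...) {
  s <- object$segments
  cat("Allele-specific copy-number fit\n")
  print(object)
  agg <- stats::aggregate(cbind(len = end - start) ~ total + major + minor,
                          data = s, FUN = sum)
  agg$genome_frac <- round(agg$len / sum(agg$len), 3)
  agg <- agg[order(-agg$len), ]
  cat("\nCopy-number states by genome fraction:\n")
  print(agg[c("total", "major", "minor", "genome_frac")], row.names = FALSE)
  invisible(object)
}

#' @export
coef.ascn_fit <- function(object, ...) {
  c(purity = object$purity, ploidy = object$ploidy, offset = object$offset)
}

#' @export
residuals.ascn_fit <- function(object, ...) {
  s <- object$segments
  p <- object$purity
  exp_logr <- log2((p * s$total + 2 * (1 - p)) / 2) - object$offset
  s$mean_logr - exp_logr
}

#' Plot logR and folded logOR profiles with fitted segments
#'
#' @param x `ascn_fit`
#' @param ... passed to [graphics::plot()]
#' @export
plot.ascn_fit <- function(x, ...) {
  sites <- x$sites
  chroms <- unique(sites$chrom)
  off <- stats::setNames(cumsum(c(0, vapply(chroms, function(cc)
    max(sites$pos[sites$chrom == cc]) + 1, numeric(1))))[seq_along(chroms)],
    chroms)
  gx <- sites$pos + off[sites$chrom]
  op <- graphics::par(mfrow = c(2, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(gx, sites$logr, pch = ".", col = "grey40",
                 ylab = "logR", xlab = "", ...)
  segx0 <- x$segments$start + off[x$segments$chrom]
  segx1 <- x$segments$end + off[x$segments$chrom]
  p <- x$purity
  seg_logr <- log2((p * x$segments$total + 2 * (1 - p)) / 2) - x$offset
  graphics::segments(segx0, seg_logr, segx1, seg_logr, col = "red", lwd = 2)
  graphics::plot(gx, abs(sites$logor), pch = ".", col = "grey40",
                 ylab = "|logOR|", xlab = "genome position")
  b <- (p * x$segments$major + (1 - p)) /
    (p * x$segments$total + (1 - p) * 2)
  b <- pmin(pmax(b, 1e-4), 1 - 1e-4)
  seg_or <- abs(log(b / (1 - b)))
  graphics::segments(segx0, seg_or, segx1, seg_or, col = "red", lwd = 2)
  invisible(x)
}
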